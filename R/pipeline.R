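#' Build a pipeline run configuration
#'
#' All randomness of a run flows from the single `seed`.  When
#' `simulate = TRUE` the synthetic generator produces genome, annotation,
#' probe tables and PWM training sites; otherwise the file paths must point
#' at existing inputs.
#'
#' @param output_dir Directory for all artifacts (created if absent).
#' @param seed Integer master seed.
#' @param simulate Generate inputs with the synthetic module?
#' @param sim A [sim_params()] object (its seed is overridden by `seed`).
#' @param peak A [peak_params()] object.
#' @param genome_fasta,genes_gff3,probe_tables,sites_fasta Input paths when
#'   `simulate = FALSE`; `probe_tables` is a character vector of per-
#'   replicate TSVs.
#' @param span Loess span for dye-bias correction.
#' @param p_threshold Motif-scan p-value cutoff.
#' @param flank Peak/hit association half-window in bp.
#' @param circular Treat the chromosome as circular?
#' @param box Consensus planted by the simulator.
#' @param n_training_sites,training_max_mismatch Size and divergence of the
#'   simulated PWM training alignment.
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1L, simulate = TRUE,
                       sim = sim_params(), peak = peak_params(),
                       genome_fasta = NULL, genes_gff3 = NULL,
                       probe_tables = NULL, sites_fasta = NULL,
                       span = 0.4, p_threshold = 1e-6, flank = 50,
                       circular = TRUE, box = zur_box_consensus(),
                       n_training_sites = 40L, training_max_mismatch = 3L) {
  sim$seed <- as.integer(seed)
  cfg <- list(output_dir = output_dir, seed = as.integer(seed),
              simulate = isTRUE(simulate), sim = sim, peak = peak,
              genome_fasta = genome_fasta, genes_gff3 = genes_gff3,
              probe_tables = probe_tables, sites_fasta = sites_fasta,
              span = span, p_threshold = p_threshold, flank = flank,
              circular = isTRUE(circular), box = box,
              n_training_sites = as.integer(n_training_sites),
              training_max_mismatch = as.integer(training_max_mismatch))
  if (!cfg$simulate) {
    needed <- c(genome_fasta = cfg$genome_fasta,
                genes_gff3 = cfg$genes_gff3)
    for (nm in names(needed)) {
      if (is.null(needed[[nm]]))
        stop("config with simulate = FALSE requires ", nm)
    }
    for (f in c(cfg$genome_fasta, cfg$genes_gff3, cfg$probe_tables,
                cfg$sites_fasta)) {
      if (!is.null(f) && !file.exists(f))
        stop("input file does not exist: ", f)
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [run_config()] arguments; `sim:` and
#' `peak:` sub-maps are passed to [sim_params()] and [peak_params()].
#'
#' @param path YAML file path.
#' @param ... Overrides applied after reading.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  peak_args <- y$peak %||% list()
  y$sim <- NULL; y$peak <- NULL
  args <- utils::modifyList(y, list(...))
  args$sim <- do.call(sim_params, sim_args)
  args$peak <- do.call(peak_params, peak_args)
  do.call(run_config, args)
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> normalize -> callpeaks -> scan ->
#' annotate, writing every intermediate artifact under
#' `config$output_dir` and returning a manifest (parameters, per-stage
#' counts, md5 checksums of every written file).  Reruns with an identical
#' configuration reproduce identical artifacts and manifests.
#'
#' @param config A [run_config()] object.
#' @param quiet Suppress per-stage log lines?
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[zurchip] ", ...)
  art <- character(0)
  keep <- function(path) { art <<- c(art, path); path }
  counts <- list()

  # -- stage: inputs (simulate or load) --------------------------------
  if (config$simulate) {
    ds <- stage_wrap("simulate", simulate_chip_dataset(config$sim,
                                                       box = config$box))
    genome <- ds$sequence; genes <- ds$genes; truth <- ds$truth
    signals <- ds$signals
    sites <- simulate_aligned_sites(config$box,
                                    n = config$n_training_sites,
                                    max_mismatch = config$training_max_mismatch,
                                    seed = config$seed + 500L)
    keep(write_genome_fasta(genome, file.path(out, "genome.fasta")))
    keep(write_genes_gff3(genes, file.path(out, "genes.gff3")))
    keep(write_tsv(truth$sites, file.path(out, "truth_sites.tsv")))
    keep(write_sites_fasta(sites, file.path(out, "training_sites.fasta")))
    for (r in names(signals)) {
      keep(write_probe_tsv(signals[[r]],
                           file.path(out, paste0("probes_", r, ".tsv"))))
    }
    say("simulate: ", nchar(genome), " bp genome, ", nrow(genes),
        " genes, ", nrow(truth$sites), " planted sites, ",
        length(signals), " replicates")
  } else {
    genome <- stage_wrap("load", read_genome_fasta(config$genome_fasta))
    genes <- stage_wrap("load", read_genes_gff3(config$genes_gff3))
    if (is.null(config$probe_tables))
      stop("pipeline stage 'load' failed: no probe tables configured",
           call. = FALSE)
    signals <- stage_wrap("load", lapply(config$probe_tables, read_probe_tsv))
    names(signals) <- paste0("rep", seq_along(signals))
    sites <- if (!is.null(config$sites_fasta)) {
      stage_wrap("load", read_sites_fasta(config$sites_fasta))
    } else {
      stop("pipeline stage 'load' failed: missing file: sites_fasta",
           call. = FALSE)
    }
    truth <- NULL
  }
  L <- nchar(genome)
  counts$n_probes <- nrow(signals[[1]])
  counts$n_genes <- nrow(genes)

  # -- stage: normalize ------------------------------------------------
  tracks <- stage_wrap("normalize", lapply(signals, function(s) {
    loess_correct(compute_ma(s), span = config$span)
  }))
  for (r in names(tracks)) {
    keep(write_tsv(tracks[[r]], file.path(out, paste0("ratios_", r, ".tsv"))))
    keep(write_track_bedgraph(tracks[[r]],
                              file.path(out, paste0("ratios_", r, ".bedGraph")),
                              spacing = config$sim$probe_spacing))
  }
  say("normalize: ", length(tracks), " replicate tracks corrected (span ",
      config$span, ")")

  # -- stage: callpeaks ------------------------------------------------
  peaks <- stage_wrap("callpeaks", lapply(tracks, function(tr) {
    call_peaks(tr, config$peak, circular = config$circular,
               genome_length = L)
  }))
  for (r in names(peaks)) {
    keep(write_tsv(peaks[[r]], file.path(out, paste0("peaks_", r, ".tsv"))))
  }
  cons <- stage_wrap("callpeaks", consensus_peaks(
    peaks[[1]], peaks[[2]], config$peak,
    circular = config$circular, genome_length = L))
  keep(write_tsv(cons, file.path(out, "consensus_peaks.tsv")))
  keep(write_peaks_bed(cons, file.path(out, "consensus_peaks.bed")))
  counts$n_peaks_per_replicate <- vapply(peaks, nrow, numeric(1))
  counts$n_consensus_peaks <- nrow(cons)
  say("callpeaks: ", paste(vapply(peaks, nrow, numeric(1)),
                           collapse = " / "),
      " replicate peaks, ", nrow(cons), " consensus peaks at cutoff ",
      config$peak$score_cutoff)

  # -- stage: scan -----------------------------------------------------
  pwm <- stage_wrap("scan", build_pwm(sites))
  keep(write_meme_pwm(pwm, file.path(out, "motif.meme")))
  hits <- stage_wrap("scan", scan_pwm(genome, pwm,
                                      p_threshold = config$p_threshold,
                                      circular = config$circular))
  keep(write_tsv(hits, file.path(out, "hits.tsv")))
  keep(write_hits_gff3(hits, file.path(out, "hits.gff3"),
                       width = pwm$width))
  counts$n_hits <- nrow(hits)
  say("scan: ", nrow(hits), " motif hits at p <= ", config$p_threshold)

  # -- stage: annotate -------------------------------------------------
  ann <- stage_wrap("annotate", annotate_peaks(
    cons, genes, L, hits = hits, genome = genome,
    consensus = pwm$consensus, flank = config$flank,
    circular = config$circular))
  summ <- stage_wrap("annotate", summarize_annotations(ann))
  keep(write_tsv(summ$per_peak, file.path(out, "annotated_peaks.tsv")))
  keep(write_tsv(summ$score_vs_match, file.path(out, "score_vs_match.tsv")))
  keep(write_tsv(summ$score_vs_distance,
                 file.path(out, "score_vs_distance.tsv")))
  keep(write_tsv(summ$category_counts,
                 file.path(out, "category_counts.tsv")))
  cc <- summ$category_counts
  counts$category_counts <- stats::setNames(as.list(cc$count), cc$category)
  counts$n_motif_associated <- sum(ann$motif_associated)
  say("annotate: ", nrow(ann), " peaks classified (",
      paste(sprintf("%s=%d", cc$category, cc$count), collapse = ", "),
      "), ", sum(ann$motif_associated), " motif-associated")

  manifest <- list(
    package = "zurchip",
    version = as.character(utils::packageVersion("zurchip")),
    seed = config$seed,
    parameters = list(
      sim = unclass(config$sim), peak = unclass(config$peak),
      span = config$span, p_threshold = config$p_threshold,
      flank = config$flank, circular = config$circular,
      box = config$box
    ),
    counts = counts,
    checksums = as.list(stats::setNames(tools::md5sum(sort(art)),
                                        basename(sort(art))))
  )
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, file.path(out, "manifest.json"))
  invisible(manifest)
}
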