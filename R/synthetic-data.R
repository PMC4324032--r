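#' Simulation parameters for the synthetic tiling-array generator
#'
#' Bundles every knob of the synthetic ChIP-on-chip dataset: a circular
#' bacterial chromosome tiled by evenly spaced probes, planted 20-nt operator
#' boxes with multiplicative enrichment peaks of sonicated-fragment width,
#' an intensity-dependent dye bias, and independent per-replicate noise.
#'
#' @param genome_length Chromosome length in bp.
#' @param gc_content GC fraction of the random genome, in (0, 1).
#' @param probe_spacing Distance between probe centers in bp.
#' @param fragment_width Half-width in bp of the triangular enrichment kernel
#'   (first-order model of sonicated-fragment coverage around a site).
#' @param wce_log_mean,wce_log_sd Mean and sd of the control (WCE) channel on
#'   the log2-intensity scale; WCE is log2-normal.
#' @param replicate_noise_sd Per-probe log2 noise sd, drawn independently per
#'   replicate.
#' @param dye_bias_coeffs Polynomial coefficients (increasing power) of the
#'   intensity-dependent dye bias g(A), applied in log2 space.
#' @param n_sites Number of operator boxes to plant.
#' @param enrichment_range Length-2 numeric, min/max fold enrichment of
#'   planted sites (min must be >= 1).
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(genome_length = 200000L,
                       gc_content = 0.435,
                       probe_spacing = 11L,
                       fragment_width = 500L,
                       wce_log_mean = 10,
                       wce_log_sd = 1,
                       replicate_noise_sd = 0.25,
                       dye_bias_coeffs = c(-1, 0.15, -0.002),
                       n_sites = 20L,
                       enrichment_range = c(8, 32),
                       seed = 1L) {
  p <- list(
    genome_length = as.integer(genome_length),
    gc_content = gc_content,
    probe_spacing = as.integer(probe_spacing),
    fragment_width = as.integer(fragment_width),
    wce_log_mean = wce_log_mean,
    wce_log_sd = wce_log_sd,
    replicate_noise_sd = replicate_noise_sd,
    dye_bias_coeffs = dye_bias_coeffs,
    n_sites = as.integer(n_sites),
    enrichment_range = as.numeric(enrichment_range),
    seed = as.integer(seed)
  )
  if (!is.numeric(gc_content) || gc_content <= 0 || gc_content >= 1)
    stop("gc_content must lie strictly inside (0, 1)")
  if (p$genome_length <= 10L * p$fragment_width)
    stop("genome_length must exceed 10 * fragment_width")
  if (p$probe_spacing < 1L) stop("probe_spacing must be >= 1")
  if (length(p$enrichment_range) != 2L || p$enrichment_range[1] < 1)
    stop("enrichment_range must be c(min, max) with min >= 1")
  if (p$enrichment_range[2] < p$enrichment_range[1])
    stop("enrichment_range must be non-decreasing")
  if (p$wce_log_sd < 0 || p$replicate_noise_sd < 0)
    stop("standard deviations must be >= 0")
  if (p$n_sites < 0L) stop("n_sites must be >= 0")
  structure(p, class = "sim_params")
}

#' Default 20-nt operator-box consensus used by the simulator
#'
#' A synthetic perfect palindrome assembled from the canonical 9-nt
#' Fur/Zur-family half-site, `TAAATCGTAA` + reverse complement.  It carries
#' the 9-1-9 inverted-repeat structure of a Zur box implicitly and is
#' information-rich enough that exact occurrences are recovered at
#' p <= 1e-6 by [scan_pwm()].
#'
#' @return A 20-character string over ACGT.
#' @export
zur_box_consensus <- function() "TAAATCGTAATTACGATTTA"

#' Generate a random circular genome with a non-overlapping gene set
#'
#' Draws an i.i.d. nucleotide sequence at the requested GC content and tiles
#' it with non-overlapping CDS features separated by short intergenic gaps,
#' covering well over half the chromosome (as in a dense bacterial genome).
#' Each gene carries an explicit translational start: the `start` coordinate
#' on the + strand, the `end` coordinate on the - strand.
#'
#' @param params A [sim_params()] object.
#' @return A list with `sequence` (character string), `genes` (data.frame
#'   with columns name, start, end, strand), and `length`.
#' @export
generate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  gc <- params$gc_content
  L <- params$genome_length
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sequence <- paste(sample(names(base_probs), L, replace = TRUE,
                           prob = base_probs), collapse = "")

  # walk the chromosome: gap (50-250 bp) then gene (300-1800 bp)
  starts <- integer(0); ends <- integer(0)
  pos <- 1L
  repeat {
    gap <- sample(50:250, 1L)
    glen <- sample(300:1800, 1L)
    s <- pos + gap
    e <- s + glen - 1L
    if (e > L) break
    starts <- c(starts, s); ends <- c(ends, e)
    pos <- e + 1L
  }
  n <- length(starts)
  genes <- data.frame(
    name = sprintf("gene%04d", seq_len(n)),
    start = starts,
    end = ends,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(sequence = sequence, genes = genes, length = L)
}

#' Translational start coordinate of each gene
#'
#' @param genes Gene data.frame (name, start, end, strand).
#' @return Integer vector: `start` for + strand genes, `end` for - strand.
#' @export
gene_starts <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' Plant operator boxes into a genome and record the ground truth
#'
#' Writes the 20-nt box sequence (or its reverse complement, on - strand
#' sites) into the genome at each chosen location.  Site categories mirror
#' the classification the pipeline later applies: promoter-proximal sites
#' fall 50-150 bp upstream of a translational start, intragenic sites
#' 280-700 bp downstream of a start codon inside the CDS, intergenic sites
#' far from any start.  Pairwise center spacing is enforced so planted peaks
#' stay resolvable.
#'
#' @param genome Character genome sequence (from [generate_genome()]).
#' @param genes Gene data.frame.
#' @param box Either a consensus string or a `pwm` object (its consensus is
#'   planted).
#' @param params A [sim_params()] object; `n_sites` and `enrichment_range`
#'   are taken from it.
#' @param category_mix Named numeric giving the fraction of sites per
#'   category (`promoter_proximal`, `intragenic`, `intergenic`).
#' @param min_spacing Minimum pairwise circular distance between site
#'   centers, bp.
#' @param positions Optional integer vector of explicit box start positions
#'   (1-based, box occupies `positions[i] .. positions[i]+width-1`);
#'   overrides random placement and category assignment.
#' @return A list: `sequence` (modified genome) and `truth`, itself a list
#'   with `sites` (data.frame: site_id, center, box_start, strand, fold,
#'   category, box_seq) and `genes`.
#' @export
plant_sites <- function(genome, genes, box, params,
                        category_mix = c(promoter_proximal = 0.5,
                                         intragenic = 0.5,
                                         intergenic = 0),
                        min_spacing = 2000L,
                        positions = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (inherits(box, "pwm")) box <- box$consensus
  box <- toupper(box)
  if (grepl("[^ACGT]", box)) stop("box consensus must be over {A,C,G,T}")
  w <- nchar(box)
  L <- nchar(genome)
  n <- params$n_sites
  set.seed(params$seed + 1L)

  empty_truth <- list(
    sites = data.frame(site_id = character(0), center = integer(0),
                       box_start = integer(0), strand = character(0),
                       fold = numeric(0), category = character(0),
                       box_seq = character(0), stringsAsFactors = FALSE),
    genes = genes
  )
  if (n == 0L && is.null(positions))
    return(list(sequence = genome, truth = empty_truth))

  if (!is.null(positions)) {
    box_start <- as.integer(positions)
    n <- length(box_start)
    center <- box_start + w %/% 2L
    strand <- rep("+", n)
    category <- rep(NA_character_, n)
  } else {
    mix <- category_mix / sum(category_mix)
    n_cat <- floor(n * mix)
    rem <- n - sum(n_cat)
    if (rem > 0) {
      frac <- n * mix - n_cat
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      n_cat[add] <- n_cat[add] + 1L
    }
    gstart <- gene_starts(genes)
    glen <- genes$end - genes$start + 1L
    centers <- integer(0); category <- character(0)
    for (cat in names(n_cat)) {
      placed <- 0L
      tries <- 0L
      while (placed < n_cat[[cat]]) {
        tries <- tries + 1L
        if (tries > 1000L * max(n, 1L))
          stop("genome too small to place ", n,
               " non-overlapping sites with min_spacing ", min_spacing)
        cand <- switch(cat,
          promoter_proximal = {
            g <- sample(nrow(genes), 1L)
            d <- sample(50:150, 1L)
            if (genes$strand[g] == "+") gstart[g] - d else gstart[g] + d
          },
          intragenic = {
            ok <- which(glen >= 1100L)
            g <- ok[sample(length(ok), 1L)]
            d <- sample(280:700, 1L)
            if (genes$strand[g] == "+") gstart[g] + d else gstart[g] - d
          },
          intergenic = {
            p <- sample(L, 1L)
            if (min(circ_dist(p, gstart, L)) <= 300 ||
                any(p >= genes$start & p <= genes$end)) NA_integer_ else p
          })
        if (is.na(cand)) next
        cand <- wrap_pos(cand, L)
        # keep whole box off the origin so substring planting stays simple
        if (cand - w < 1L || cand + w > L) next
        if (length(centers) && min(circ_dist(cand, centers, L)) < min_spacing)
          next
        centers <- c(centers, cand)
        category <- c(category, cat)
        placed <- placed + 1L
      }
    }
    center <- centers
    strand <- sample(c("+", "-"), n, replace = TRUE)
    box_start <- center - w %/% 2L
  }

  fold <- runif(n, params$enrichment_range[1], params$enrichment_range[2])
  seqs <- character(n)
  for (i in seq_len(n)) {
    planted <- if (strand[i] == "+") box else revcomp(box)
    substr(genome, box_start[i], box_start[i] + w - 1L) <- planted
    seqs[i] <- planted
  }
  sites <- data.frame(
    site_id = sprintf("site%03d", seq_len(n)),
    center = as.integer(center),
    box_start = as.integer(box_start),
    strand = strand,
    fold = fold,
    category = category,
    box_seq = seqs,
    stringsAsFactors = FALSE
  )
  sites <- sites[order(sites$center), , drop = FALSE]
  sites$site_id <- sprintf("site%03d", seq_len(n))
  rownames(sites) <- NULL
  list(sequence = genome, truth = list(sites = sites, genes = genes))
}

#' Simulate two-channel probe intensities for one replicate
#'
#' Probes are placed every `probe_spacing` bp over the circular chromosome.
#' The control channel is log2-normal; the expected log2 enrichment at a
#' probe is the sum over planted sites of `log2(fold)` times a triangular
#' kernel of half-width `fragment_width` centered on the site (circular
#' distance).  The IP channel is
#' `IP = WCE * 2^(enrichment + g(A) + noise)`, where the dye bias polynomial
#' g is evaluated at the probe's noise-free mid log2-intensity
#' `A = log2(WCE) + enrichment/2` and `noise` is N(0, replicate_noise_sd).
#' Two calls with different `replicate_seed`s share the enrichment structure
#' but have independent WCE draws and noise.
#'
#' @param genome_length Chromosome length in bp.
#' @param truth Truth list from [plant_sites()] (its `sites` component is
#'   used; pass `NULL` or an empty truth for a null track).
#' @param params A [sim_params()] object.
#' @param replicate_seed Integer seed for this replicate's random draws.
#' @param replicate Replicate identifier stored in the output.
#' @return A data.frame with columns probe_id, position, ip, wce, replicate.
#' @export
simulate_probe_signals <- function(genome_length, truth, params,
                                   replicate_seed,
                                   replicate = "rep1") {
  stopifnot(inherits(params, "sim_params"))
  set.seed(as.integer(replicate_seed))
  n_probes <- genome_length %/% params$probe_spacing
  position <- seq.int(1L, by = params$probe_spacing, length.out = n_probes)

  enrich <- rep(0, n_probes)
  sites <- if (is.null(truth)) NULL else truth$sites
  if (!is.null(sites) && nrow(sites)) {
    fw <- params$fragment_width
    for (i in seq_len(nrow(sites))) {
      d <- circ_dist(position, sites$center[i], genome_length)
      k <- pmax(0, 1 - d / fw)
      enrich <- enrich + log2(sites$fold[i]) * k
    }
  }
  wce <- 2^rnorm(n_probes, params$wce_log_mean, params$wce_log_sd)
  a_mid <- log2(wce) + enrich / 2
  bias <- eval_poly(params$dye_bias_coeffs, a_mid)
  noise <- rnorm(n_probes, 0, params$replicate_noise_sd)
  ip <- wce * 2^(enrich + bias + noise)
  data.frame(
    probe_id = sprintf("probe_%06d", seq_len(n_probes)),
    position = position,
    ip = ip,
    wce = wce,
    replicate = replicate,
    stringsAsFactors = FALSE
  )
}

#' Mutated copies of a consensus for PWM training
#'
#' Emulates an alignment of in vivo binding sites: each sequence is the
#' consensus with 0..`max_mismatch` positions substituted by a random
#' different base.
#'
#' @param consensus Consensus string.
#' @param n Number of aligned sites.
#' @param max_mismatch Maximum substitutions per site.
#' @param seed Integer seed.
#' @return Character vector of `n` equal-length sequences.
#' @export
simulate_aligned_sites <- function(consensus = zur_box_consensus(),
                                   n = 40L, max_mismatch = 3L, seed = 1L) {
  set.seed(as.integer(seed))
  w <- nchar(consensus)
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    s <- strsplit(consensus, "")[[1]]
    k <- sample(0:max_mismatch, 1L)
    if (k > 0) {
      at <- sample(w, k)
      for (j in at) s[j] <- sample(setdiff(bases, s[j]), 1L)
    }
    paste(s, collapse = "")
  }, character(1))
}

#' Simulate a complete two-replicate ChIP-on-chip dataset
#'
#' Convenience wrapper: genome + genes, planted boxes, and one probe table
#' per replicate.  Replicate seeds are derived as `params$seed + 100 + r`.
#'
#' @param params A [sim_params()] object.
#' @param box Consensus string (or `pwm`) to plant; default
#'   [zur_box_consensus()].
#' @param n_replicates Number of independent replicates.
#' @param category_mix,min_spacing Passed to [plant_sites()].
#' @return A list: `sequence`, `genes`, `truth`, `signals` (list of probe
#'   data.frames named rep1, rep2, ...), `params`.
#' @export
simulate_chip_dataset <- function(params = sim_params(),
                                  box = zur_box_consensus(),
                                  n_replicates = 2L,
                                  category_mix = c(promoter_proximal = 0.5,
                                                   intragenic = 0.5,
                                                   intergenic = 0),
                                  min_spacing = 2000L) {
  gen <- generate_genome(params)
  planted <- plant_sites(gen$sequence, gen$genes, box, params,
                         category_mix = category_mix,
                         min_spacing = min_spacing)
  signals <- lapply(seq_len(n_replicates), function(r) {
    simulate_probe_signals(gen$length, planted$truth, params,
                           replicate_seed = params$seed + 100L + r,
                           replicate = paste0("rep", r))
  })
  names(signals) <- paste0("rep", seq_len(n_replicates))
  list(sequence = planted$sequence, genes = gen$genes,
       truth = planted$truth, signals = signals, params = params)
}
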