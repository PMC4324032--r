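#' Nearest translational start to a chromosomal position
#'
#' Finds the gene whose start codon minimizes the absolute strand-aware
#' signed distance to the query position.  Distances are measured along each
#' gene's strand: negative means the position lies upstream of the start
#' codon, positive downstream.  On a circular chromosome distances wrap.
#' Ties in absolute distance resolve toward the gene for which the position
#' is upstream.
#'
#' @param position Query position (bp, 1-based).
#' @param genes Gene data.frame (name, start, end, strand).
#' @param genome_length Chromosome length in bp.
#' @param circular Wrap distances around the origin?
#' @return A list: `gene` (name), `signed_distance`, and the gene's row
#'   index `index`.
#' @export
nearest_start <- function(position, genes, genome_length, circular = TRUE) {
  if (!nrow(genes)) stop("gene set is empty")
  starts <- gene_starts(genes)
  raw <- if (circular) {
    circ_signed_dist(starts, position, genome_length)
  } else {
    position - starts
  }
  d <- ifelse(genes$strand == "+", raw, -raw)
  best <- which(abs(d) == min(abs(d)))
  if (length(best) > 1L) {
    up <- best[d[best] < 0]
    best <- if (length(up)) up[1] else best[1]
  }
  list(gene = genes$name[best], signed_distance = unname(d[best]),
       index = best)
}

#' Classify a peak relative to the nearest translational start
#'
#' Categories follow the 200-bp rules used for bacterial operator sites:
#' `promoter_proximal` for peaks less than 200 bp upstream of a start
#' (-200 <= d < 0); `start_overlap` for peaks 0-200 bp downstream of a start
#' and inside the nearest gene's CDS; `intragenic` for peaks more than
#' 200 bp downstream of a start codon and inside a CDS; `distal` otherwise.
#' The categories are mutually exclusive and exhaustive.
#'
#' @param signed_distance Strand-aware distance from [nearest_start()].
#' @param in_nearest_cds Is the peak inside the nearest gene's CDS?
#' @param in_any_cds Is the peak inside any CDS?
#' @return One of `"promoter_proximal"`, `"start_overlap"`, `"intragenic"`,
#'   `"distal"`.
#' @export
classify_peak <- function(signed_distance, in_nearest_cds,
                          in_any_cds = in_nearest_cds) {
  d <- signed_distance
  if (d >= -200 && d < 0) return("promoter_proximal")
  if (d >= 0 && d <= 200 && in_nearest_cds) return("start_overlap")
  if (d > 200 && in_any_cds) return("intragenic")
  "distal"
}

# Is position inside gene i's CDS (forward-coordinate containment)?
in_cds <- function(position, genes, index = NULL) {
  if (is.null(index)) {
    any(position >= genes$start & position <= genes$end)
  } else {
    position >= genes$start[index] && position <= genes$end[index]
  }
}

#' Annotate consensus peaks against genes and motif hits
#'
#' For every consensus peak: nearest translational start with strand-aware
#' signed distance, 200-bp category, motif association within `flank` bp of
#' the peak maximum, and — when the genome and a consensus are supplied —
#' the number of nucleotides of the associated hit window matching the
#' consensus.
#'
#' @param peaks Consensus peak data.frame ([consensus_peaks()]).
#' @param genes Gene data.frame.
#' @param genome_length Chromosome length in bp.
#' @param hits Optional motif hit data.frame ([scan_pwm()]).
#' @param genome Optional genome sequence (for match counts).
#' @param consensus Optional consensus string (for match counts).
#' @param flank Association half-window in bp.
#' @param circular Treat the chromosome as circular?
#' @return A data.frame with one row per peak: peak_id, max_position,
#'   chip_score, nearest_gene, signed_distance, category, motif_associated,
#'   hit_position, hit_strand, hit_p, match_count.
#' @export
annotate_peaks <- function(peaks, genes, genome_length, hits = NULL,
                           genome = NULL, consensus = NULL, flank = 50,
                           circular = TRUE) {
  pk <- associate_hits(peaks, hits, flank = flank, circular = circular,
                       genome_length = genome_length)
  n <- nrow(pk)
  nearest_gene <- character(n)
  signed_distance <- numeric(n)
  category <- character(n)
  mcount <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ns <- nearest_start(pk$max_position[i], genes, genome_length,
                        circular = circular)
    nearest_gene[i] <- ns$gene
    signed_distance[i] <- ns$signed_distance
    category[i] <- classify_peak(
      ns$signed_distance,
      in_nearest_cds = in_cds(pk$max_position[i], genes, ns$index),
      in_any_cds = in_cds(pk$max_position[i], genes)
    )
    if (pk$motif_associated[i] && !is.null(genome) && !is.null(consensus)) {
      w <- nchar(consensus)
      s <- pk$hit_position[i]
      window <- if (s + w - 1L <= nchar(genome)) {
        substr(genome, s, s + w - 1L)
      } else {  # window wraps the origin
        paste0(substr(genome, s, nchar(genome)),
               substr(genome, 1L, w - (nchar(genome) - s + 1L)))
      }
      if (identical(pk$hit_strand[i], "-")) window <- revcomp(window)
      mcount[i] <- match_count(window, consensus)
    }
  }
  out <- data.frame(
    peak_id = if ("peak_id" %in% names(pk)) pk$peak_id
              else sprintf("peak%03d", seq_len(n)),
    max_position = pk$max_position,
    chip_score = pk$chip_score,
    nearest_gene = nearest_gene,
    signed_distance = signed_distance,
    category = category,
    motif_associated = pk$motif_associated,
    hit_position = pk$hit_position,
    hit_strand = pk$hit_strand,
    hit_p = pk$hit_p,
    match_count = mcount,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Summary tables for annotated peaks
#'
#' Produces the standard result tables: the per-peak table; ChIPScore versus
#' consensus match count split by inter/intragenic location; ChIPScore
#' versus distance to the nearest start split by with/without box; and the
#' category tally.
#'
#' @param annotations Data.frame from [annotate_peaks()].
#' @return A list of data.frames: `per_peak`, `score_vs_match`,
#'   `score_vs_distance`, `category_counts`.
#' @export
summarize_annotations <- function(annotations) {
  cats <- c("promoter_proximal", "start_overlap", "intragenic", "distal")
  counts <- vapply(cats, function(cl) sum(annotations$category == cl),
                   numeric(1))
  category_counts <- data.frame(category = cats, count = as.integer(counts),
                                stringsAsFactors = FALSE)
  with_box <- annotations[annotations$motif_associated, , drop = FALSE]
  score_vs_match <- data.frame(
    peak_id = with_box$peak_id,
    chip_score = with_box$chip_score,
    match_count = with_box$match_count,
    location = ifelse(with_box$category == "intragenic",
                      "intragenic", "intergenic"),
    stringsAsFactors = FALSE
  )
  score_vs_distance <- data.frame(
    peak_id = annotations$peak_id,
    chip_score = annotations$chip_score,
    signed_distance = annotations$signed_distance,
    with_box = annotations$motif_associated,
    stringsAsFactors = FALSE
  )
  list(per_peak = annotations,
       score_vs_match = score_vs_match,
       score_vs_distance = score_vs_distance,
       category_counts = category_counts)
}
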