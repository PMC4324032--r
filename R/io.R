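#' Read and write the pipeline's file formats
#'
#' Genomes travel as FASTA, annotation as GFF3 CDS features, probe signals
#' and result tables as TSV, tracks as bedGraph, peaks as BED6, motif hits
#' as GFF3, and PWMs in MEME minimal motif text format.  Coordinates are
#' 1-based inclusive internally (GFF3-native); emitted BED/bedGraph is
#' 0-based half-open, handled by `rtracklayer`.
#'
#' @name zurchip-io
NULL

#' @describeIn zurchip-io Write a genome sequence as FASTA.
#' @param sequence Character genome sequence.
#' @param path File path.
#' @param name Sequence name used in headers/seqnames.
#' @export
write_genome_fasta <- function(sequence, path, name = "chr") {
  x <- Biostrings::DNAStringSet(sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @describeIn zurchip-io Read the first sequence of a FASTA as a string.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as.character(x[[1]])
}

#' @describeIn zurchip-io Write genes as GFF3 CDS features.
#' @param genes Gene data.frame (name, start, end, strand).
#' @export
write_genes_gff3 <- function(genes, path, name = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    type = "CDS",
    phase = 0L,
    ID = genes$name,
    Name = genes$name
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @describeIn zurchip-io Read CDS features from a GFF3 file.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  nm <- if (!is.null(gr$Name)) as.character(gr$Name)
        else as.character(gr$ID)
  data.frame(
    name = nm,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' @describeIn zurchip-io Write a probe signal table as TSV.
#' @param signals Probe data.frame.
#' @export
write_probe_tsv <- function(signals, path) {
  utils::write.table(signals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @describeIn zurchip-io Read a probe signal table from TSV.
#' @export
read_probe_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @describeIn zurchip-io Write any result data.frame as TSV.
#' @param x A data.frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn zurchip-io Write a ratio track as bedGraph (one interval per
#'   probe spacing).
#' @param track Ratio track (position, m).
#' @param spacing Probe spacing in bp.
#' @export
write_track_bedgraph <- function(track, path, spacing = NULL,
                                 name = "chr") {
  if (is.null(spacing)) {
    dp <- diff(track$position)
    spacing <- if (length(dp)) min(dp) else 1L
  }
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(start = track$position,
                              width = as.integer(spacing)),
    score = track$m
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @describeIn zurchip-io Write consensus peaks as BED6 (score =
#'   ChIPScore x 100, capped at 1000).
#' @param peaks Consensus peak data.frame.
#' @export
write_peaks_bed <- function(peaks, path, name = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(start = peaks$max_position, width = 1L),
    strand = "*",
    name = peaks$peak_id,
    score = pmin(1000, round(peaks$chip_score * 100))
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @describeIn zurchip-io Write motif hits as GFF3 (type TF_binding_site,
#'   score = -log10 p).
#' @param hits Hit data.frame ([scan_pwm()]).
#' @param width Motif width in bp.
#' @export
write_hits_gff3 <- function(hits, path, width, name = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(start = hits$position, width = width),
    strand = hits$strand,
    type = "TF_binding_site",
    score = -log10(hits$p_value)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @describeIn zurchip-io Write a PWM in MEME minimal motif text format.
#' @param pwm A `pwm` object.
#' @param motif_name Motif name recorded in the file.
#' @export
write_meme_pwm <- function(pwm, path, motif_name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", names(pwm$background), pwm$background),
          collapse = " "),
    "",
    paste("MOTIF", motif_name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            pwm$width, round(sum(pwm$counts[, 1])))
  ), con)
  for (j in seq_len(pwm$width)) {
    writeLines(paste(sprintf("%.6f", pwm$probs[, j]), collapse = "  "), con)
  }
  invisible(path)
}

#' @describeIn zurchip-io Read the first motif of a MEME minimal format
#'   file as a `pwm` object (counts reconstructed from nsites).
#' @export
read_meme_pwm <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg <- vals[DNA_BASES]
  }
  hdr <- grep("^letter-probability matrix", lines)[1]
  if (is.na(hdr)) stop("no letter-probability matrix found in ", path)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
  nsites <- if (grepl("nsites=", lines[hdr])) {
    as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[hdr]))
  } else 20L
  probs <- t(vapply(lines[(hdr + 1L):(hdr + w)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }, numeric(4)))
  probs <- t(probs)  # 4 x w
  dimnames(probs) <- list(DNA_BASES, NULL)
  consensus <- paste(DNA_BASES[apply(probs, 2, which.max)], collapse = "")
  structure(list(width = w, counts = probs * nsites, probs = probs,
                 background = bg, consensus = consensus),
            class = "pwm")
}

#' @describeIn zurchip-io Write aligned sites as FASTA.
#' @param sites Character vector of sequences.
#' @export
write_sites_fasta <- function(sites, path) {
  x <- Biostrings::DNAStringSet(sites)
  names(x) <- sprintf("site%03d", seq_along(sites))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @describeIn zurchip-io Read aligned sites from FASTA as a character
#'   vector.
#' @export
read_sites_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path))
}
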