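DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from aligned binding sites
#'
#' Tallies per-column base counts from an alignment of equal-length sites
#' and converts them to column-stochastic probabilities with a pseudocount:
#' `probs = (counts + pseudocount) / (n + 4 * pseudocount)`.  The consensus
#' is the per-column argmax base (alphabetical tie-break).
#'
#' @param sites Character vector of at least two equal-length sequences over
#'   ACGT.
#' @param pseudocount Added to every cell before normalization.
#' @param background Named length-4 base-frequency vector summing to 1; the
#'   default is uniform.  [scan_pwm()] can override it with the scanned
#'   sequence's own composition.
#' @return An object of class `pwm`: list with width, counts, probs,
#'   background, consensus.
#' @export
build_pwm <- function(sites, pseudocount = 0.25,
                      background = c(A = 0.25, C = 0.25, G = 0.25,
                                     T = 0.25)) {
  if (length(sites) < 2L) stop("need at least 2 aligned sites")
  sites <- toupper(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("aligned sites must all have the same length")
  if (any(grepl("[^ACGT]", sites)))
    stop("aligned sites must contain only A, C, G, T")
  background <- background[DNA_BASES]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-6)
    stop("background must be a named ACGT frequency vector summing to 1")
  mat <- do.call(rbind, strsplit(sites, ""))
  counts <- vapply(seq_len(w), function(j) {
    tabulate(match(mat[, j], DNA_BASES), nbins = 4L)
  }, numeric(4))
  dimnames(counts) <- list(DNA_BASES, NULL)
  probs <- (counts + pseudocount) / (length(sites) + 4 * pseudocount)
  consensus <- paste(DNA_BASES[apply(probs, 2, which.max)], collapse = "")
  structure(list(width = w, counts = counts, probs = probs,
                 background = background, consensus = consensus),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM of width", x$width, "\n")
  cat("consensus:", x$consensus, "\n")
  cat("information content:", round(pwm_information(x), 2), "bits\n")
  invisible(x)
}

#' Total information content of a PWM (bits)
#'
#' Sum over columns of the Kullback-Leibler divergence from the background.
#'
#' @param pwm A `pwm` object.
#' @return Total information in bits.
#' @export
pwm_information <- function(pwm) {
  sum(pwm$probs * log2(pwm$probs / pwm$background))
}

#' Count matches to a consensus sequence
#'
#' Hamming agreement between a window and a consensus of the same length.
#'
#' @param window Sequence window (string).
#' @param consensus Consensus string of the same length.
#' @return Integer count of agreeing positions.
#' @export
match_count <- function(window, consensus) {
  if (nchar(window) != nchar(consensus))
    stop("window length (", nchar(window), ") must equal consensus length (",
         nchar(consensus), ")")
  sum(strsplit(toupper(window), "")[[1]] ==
        strsplit(toupper(consensus), "")[[1]])
}

# Integer log-odds score matrix on the discretized grid: each cell is
# round(log2(probs/background)/granularity).  Cells with probability zero get
# NA and are treated as "below any finite threshold".
pwm_score_grid <- function(pwm, background = NULL, granularity = 1e-3) {
  bg <- (background %||% pwm$background)[DNA_BASES]
  s <- log2(pwm$probs / bg)
  k <- round(s / granularity)
  k[!is.finite(s)] <- NA_integer_
  storage.mode(k) <- "integer"
  list(k = k, bg = bg, granularity = granularity)
}

#' Exact score distribution of a PWM under its background model
#'
#' Dynamic programming over per-column log-odds scores discretized at
#' `granularity` bits: the returned distribution is exact on that score
#' grid.  Sequence probabilities follow the (zero-order) background model.
#'
#' @param pwm A `pwm` object.
#' @param background Optional background override (named ACGT frequencies).
#' @param granularity Score grid width in bits.
#' @return A list: `score` (ascending numeric grid values, in bits), `k`
#'   (their integer grid indices), `prob` (point masses), `tail`
#'   (`P(score >= score[i])`), `granularity`.
#' @export
pwm_score_distribution <- function(pwm, background = NULL,
                                   granularity = 1e-3) {
  g <- pwm_score_grid(pwm, background, granularity)
  K <- g$k
  bg <- g$bg
  lo <- 0L; hi <- 0L
  dist <- 1
  for (j in seq_len(pwm$width)) {
    kj <- K[, j]
    ok <- !is.na(kj)  # zero-probability cells can never reach a finite score
    if (!any(ok)) stop("PWM column ", j, " has no scorable base")
    newlo <- lo + min(kj[ok]); newhi <- hi + max(kj[ok])
    new <- numeric(newhi - newlo + 1L)
    for (b in which(ok)) {
      at <- (lo + kj[b] - newlo + 1L):(hi + kj[b] - newlo + 1L)
      new[at] <- new[at] + dist * bg[b]
    }
    dist <- new; lo <- newlo; hi <- newhi
  }
  nz <- which(dist > 0)
  k <- (lo:hi)[nz]
  prob <- unname(dist[nz])
  tail <- rev(cumsum(rev(prob)))
  list(score = k * granularity, k = k, prob = prob, tail = tail,
       granularity = granularity)
}

#' Exact tail p-value of a PWM score threshold
#'
#' `P(score >= threshold)` for a random background sequence of the motif's
#' width, computed from the exact discretized score distribution.
#'
#' @param pwm A `pwm` object.
#' @param threshold Score threshold in bits (`-Inf` gives 1).
#' @param background Optional background override.
#' @param granularity Score grid width in bits.
#' @return A single p-value in (0, 1].
#' @export
score_pvalue <- function(pwm, threshold, background = NULL,
                         granularity = 1e-3) {
  if (threshold == -Inf) return(1)
  d <- pwm_score_distribution(pwm, background, granularity)
  kt <- round(threshold / granularity)
  idx <- findInterval(kt - 0.5, d$k) + 1L
  if (idx > length(d$k)) return(0)
  d$tail[idx]
}

# Reverse-complement a score grid matrix: base b at motif column j on the
# reverse strand reads as complement(b) at column w+1-j.
revcomp_grid <- function(K) {
  K[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(K))), drop = FALSE]
}

# Integer window scores at every start position for one strand's grid.
# codes: integer 1..4 (NA for ambiguous bases, which score 0).
window_scores <- function(codes, K, npos) {
  w <- ncol(K)
  S <- integer(npos)
  idx <- seq_len(npos)
  for (j in seq_len(w)) {
    col <- K[, j]
    col[is.na(col)] <- 0L      # zero-probability base: never a real hit anyway
    kj <- col[codes[idx + j - 1L]]
    kj[is.na(kj)] <- 0L        # N scores as background (zero log-odds)
    S <- S + kj
  }
  S
}

#' Scan a sequence with a PWM, reporting hits with exact p-values
#'
#' Slides the motif over the forward and (optionally) reverse strand and
#' reports windows whose exact tail p-value under the background model is at
#' most `p_threshold`.  Reverse-strand hits are reported by their
#' forward-strand start coordinate.  Because a palindromic motif reports
#' nearly coincident hits on both strands, overlapping opposite-strand hits
#' (overlap >= width/2) are deduplicated to the better-scoring strand.
#'
#' @param sequence Character DNA sequence (ambiguous bases score as
#'   background, i.e. contribute zero log-odds).
#' @param pwm A `pwm` object.
#' @param p_threshold Report hits with p-value at or below this.
#' @param both_strands Scan the reverse strand too?
#' @param background Named ACGT frequencies; `NULL` (default) uses the
#'   scanned sequence's own mononucleotide composition, `"uniform"` forces
#'   0.25 each.
#' @param circular Wrap windows around the origin?
#' @param granularity Score grid width in bits.
#' @return A data.frame of hits: position (1-based window start), strand,
#'   score (bits, on the grid), p_value; sorted by position.
#' @export
scan_pwm <- function(sequence, pwm, p_threshold = 1e-6,
                     both_strands = TRUE, background = NULL,
                     circular = FALSE, granularity = 1e-3) {
  empty <- data.frame(position = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  w <- pwm$width
  n <- nchar(sequence)
  if (n < w) return(empty)
  chars <- strsplit(toupper(sequence), "")[[1]]
  codes <- match(chars, DNA_BASES)
  if (identical(background, "uniform")) {
    bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  } else if (is.null(background)) {
    cnt <- tabulate(codes, nbins = 4L)
    bg <- if (sum(cnt) == 0 || any(cnt == 0)) {
      (cnt + 1) / (sum(cnt) + 4)
    } else {
      cnt / sum(cnt)
    }
    names(bg) <- DNA_BASES
  } else {
    bg <- background[DNA_BASES]
  }
  grid <- pwm_score_grid(pwm, bg, granularity)
  d <- pwm_score_distribution(pwm, bg, granularity)
  reachable <- d$tail <= p_threshold
  if (!any(reachable)) return(empty)
  kcut <- d$k[which(reachable)[1]]

  npos <- if (circular) n else n - w + 1L
  codes_ext <- if (circular) c(codes, codes[seq_len(w - 1L)]) else codes
  pval_at <- function(S) {
    idx <- findInterval(S, d$k)
    ifelse(idx < 1L, 1, d$tail[pmax(idx, 1L)])
  }
  hits <- list()
  Sf <- window_scores(codes_ext, grid$k, npos)
  hf <- which(Sf >= kcut)
  if (length(hf)) {
    hits[["+"]] <- data.frame(position = hf, strand = "+",
                              score = Sf[hf] * granularity,
                              p_value = pval_at(Sf[hf]),
                              stringsAsFactors = FALSE)
  }
  if (both_strands) {
    Sr <- window_scores(codes_ext, revcomp_grid(grid$k), npos)
    hr <- which(Sr >= kcut)
    if (length(hr)) {
      hits[["-"]] <- data.frame(position = hr, strand = "-",
                                score = Sr[hr] * granularity,
                                p_value = pval_at(Sr[hr]),
                                stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL

  # palindrome-aware deduplication: best hit wins, opposite-strand hits
  # overlapping it by >= width/2 are dropped
  ord <- order(out$p_value, -out$score, out$position,
               match(out$strand, c("+", "-")))
  keep <- logical(nrow(out))
  acc_pos <- numeric(0); acc_str <- character(0)
  max_sep <- w - ceiling(w / 2)  # overlap >= w/2  <=>  |delta| <= w - ceil(w/2)
  for (k in ord) {
    clash <- length(acc_pos) &&
      any(acc_str != out$strand[k] &
            abs(acc_pos - out$position[k]) <= max_sep)
    if (!clash) {
      keep[k] <- TRUE
      acc_pos <- c(acc_pos, out$position[k])
      acc_str <- c(acc_str, out$strand[k])
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Associate motif hits with consensus peaks
#'
#' A peak is motif-associated when a hit start lies within `flank` bp of the
#' peak maximum (circular distance when requested); the lowest-p hit in
#' range is attached.
#'
#' @param peaks Consensus peak data.frame ([consensus_peaks()]).
#' @param hits Hit data.frame ([scan_pwm()]).
#' @param flank Association half-window in bp.
#' @param circular Measure distances on the circle?
#' @param genome_length Required when `circular = TRUE`.
#' @return `peaks` with added columns motif_associated, hit_position,
#'   hit_strand, hit_score, hit_p.
#' @export
associate_hits <- function(peaks, hits, flank = 50, circular = TRUE,
                           genome_length = NULL) {
  if (circular && is.null(genome_length))
    stop("genome_length needed for circular association")
  n <- nrow(peaks)
  peaks$motif_associated <- logical(n)
  peaks$hit_position <- rep(NA_integer_, n)
  peaks$hit_strand <- rep(NA_character_, n)
  peaks$hit_score <- rep(NA_real_, n)
  peaks$hit_p <- rep(NA_real_, n)
  if (!n || is.null(hits) || !nrow(hits)) return(peaks)
  for (i in seq_len(n)) {
    d <- if (circular) {
      circ_dist(peaks$max_position[i], hits$position, genome_length)
    } else {
      abs(hits$position - peaks$max_position[i])
    }
    in_range <- which(d <= flank)
    if (!length(in_range)) next
    best <- in_range[order(hits$p_value[in_range], d[in_range])][1]
    peaks$motif_associated[i] <- TRUE
    peaks$hit_position[i] <- hits$position[best]
    peaks$hit_strand[i] <- hits$strand[best]
    peaks$hit_score[i] <- hits$score[best]
    peaks$hit_p[i] <- hits$p_value[best]
  }
  peaks
}
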