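#' Peak-calling parameters
#'
#' Defaults follow standard bacterial tiling-array practice: a 29-probe
#' smoothing window (about 320 bp at 11-bp spacing) applied twice, peak
#' merging within 300 bp, a ChIPScore cutoff of 4.0 required in both
#' replicates, and replicate peak matching within 300 bp.
#'
#' @param window_probes Odd window width in probes for smoothing and
#'   extremum detection.
#' @param smoothing_rounds Number of smoothing passes.
#' @param merge_window Maxima closer than this many bp are merged.
#' @param score_cutoff ChIPScore threshold applied per replicate.
#' @param replicate_match_dist Maximum bp between replicate maxima for
#'   cross-replicate matching.
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(window_probes = 29L, smoothing_rounds = 2L,
                        merge_window = 300L, score_cutoff = 4.0,
                        replicate_match_dist = 300L) {
  p <- list(window_probes = as.integer(window_probes),
            smoothing_rounds = as.integer(smoothing_rounds),
            merge_window = as.numeric(merge_window),
            score_cutoff = as.numeric(score_cutoff),
            replicate_match_dist = as.numeric(replicate_match_dist))
  if (p$window_probes < 3L || p$window_probes %% 2L == 0L)
    stop("window_probes must be odd and >= 3")
  if (p$smoothing_rounds < 0L) stop("smoothing_rounds must be >= 0")
  if (p$merge_window <= 0) stop("merge_window must be > 0")
  if (!is.finite(p$score_cutoff)) stop("score_cutoff must be finite")
  structure(p, class = "peak_params")
}

#' Sliding-window smoothing of a ratio track
#'
#' Centered moving mean of width `window_probes`, repeated
#' `smoothing_rounds` times.  On a circular chromosome windows wrap around
#' the origin; otherwise they truncate at the track ends (the mean is taken
#' over the probes actually covered).
#'
#' @param track Ratio track (data.frame with position, m).
#' @param params A [peak_params()] object.
#' @param circular Wrap windows around the origin?
#' @return The track with `m` replaced by the smoothed signal.
#' @export
smooth_track <- function(track, params = peak_params(), circular = TRUE) {
  w <- params$window_probes
  n <- nrow(track)
  if (w > n) stop("smoothing window (", w, " probes) larger than track (",
                  n, " probes)")
  m <- track$m
  half <- (w - 1L) %/% 2L
  for (r in seq_len(params$smoothing_rounds)) {
    if (circular) {
      m <- as.numeric(stats::filter(m, rep(1 / w, w), sides = 2,
                                    circular = TRUE))
    } else {
      cs <- cumsum(c(0, m))
      i <- seq_len(n)
      lo <- pmax(1L, i - half)
      hi <- pmin(n, i + half)
      m <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
  }
  track$m <- m
  attr(track, "smoothed") <- TRUE
  track
}

# Windowed running extreme (max or min) over a centered window of width w.
# Non-circular windows truncate, which the +/-Inf padding reproduces.
roll_extreme <- function(x, w, circular = TRUE, what = c("max", "min")) {
  what <- match.arg(what)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  pad <- if (what == "max") -Inf else Inf
  ext <- x
  comb <- if (what == "max") pmax else pmin
  for (k in seq_len(half)) {
    if (circular) {
      left <- x[c((n - k + 1L):n, seq_len(n - k))]
      right <- x[c((k + 1L):n, seq_len(k))]
    } else {
      left <- c(rep(pad, k), x[seq_len(n - k)])
      right <- c(x[(k + 1L):n], rep(pad, k))
    }
    ext <- comb(ext, left, right)
  }
  ext
}

# Collapse runs of consecutive candidate indices to their leftmost member;
# a run wrapping the origin is represented by its first index after the gap.
collapse_runs <- function(cand, n, circular) {
  if (!length(cand)) return(integer(0))
  keep <- cand[c(TRUE, diff(cand) > 1L)]
  if (circular && length(keep) > 1L &&
      cand[1L] == 1L && cand[length(cand)] == n) {
    keep <- keep[-1L]
  }
  keep
}

#' Locate window extrema of a smoothed track
#'
#' A probe is a maximum when its smoothed value equals the maximum over the
#' centered `window_probes` window (minima symmetric).  Ties within a run of
#' equal probes resolve to the leftmost probe of the run.
#'
#' @param track Smoothed ratio track.
#' @param params A [peak_params()] object.
#' @param circular Wrap windows around the origin?
#' @return A list of two data.frames, `maxima` and `minima`, each with
#'   columns index, position, value.
#' @export
find_extrema <- function(track, params = peak_params(), circular = TRUE) {
  m <- track$m
  n <- length(m)
  w <- params$window_probes
  if (w > n) stop("window larger than track")
  out <- lapply(c(max = "max", min = "min"), function(what) {
    ext <- roll_extreme(m, w, circular = circular, what = what)
    cand <- which(m == ext)
    idx <- collapse_runs(cand, n, circular)
    data.frame(index = idx, position = track$position[idx], value = m[idx])
  })
  names(out) <- c("maxima", "minima")
  out
}

#' Merge nearby maxima
#'
#' Single-linkage clustering of maxima whose positions lie within
#' `merge_window` bp of each other (circularly, if requested); each cluster
#' is represented by its highest maximum, leftmost on ties.
#'
#' @param maxima data.frame with columns position, value (and optionally
#'   index).
#' @param params A [peak_params()] object.
#' @param circular Treat the chromosome as circular?
#' @param genome_length Required when `circular = TRUE`.
#' @return The representative maxima, sorted by position.
#' @export
merge_peaks <- function(maxima, params = peak_params(), circular = TRUE,
                        genome_length = NULL) {
  if (!nrow(maxima)) return(maxima)
  if (circular && is.null(genome_length))
    stop("genome_length needed for circular merging")
  mx <- maxima[order(maxima$position), , drop = FALSE]
  gap <- diff(mx$position)
  cluster <- cumsum(c(1, gap > params$merge_window))
  if (circular && max(cluster) > 1L) {
    wrap_gap <- genome_length - mx$position[nrow(mx)] + mx$position[1L]
    if (wrap_gap <= params$merge_window) {
      cluster[cluster == max(cluster)] <- 1L
    }
  }
  reps <- vapply(split(seq_len(nrow(mx)), cluster), function(i) {
    v <- mx$value[i]
    i[which.max(v)]  # which.max takes the first (leftmost) on ties
  }, integer(1))
  out <- mx[sort(reps), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peak heights from merged maxima and flanking minima
#'
#' For each maximum, the nearest minimum on each side is located (wrapping
#' on a circular chromosome) and the height is the smoothed maximum minus
#' the mean of the two flanking minimum values, clipped at zero.  At a
#' non-circular track end with only one flank, that single minimum is used.
#'
#' @param maxima Merged maxima (position, value).
#' @param minima Minima data.frame (position, value).
#' @param circular Wrap flank search around the origin?
#' @param genome_length Required when `circular = TRUE`.
#' @return `maxima` with added columns left_min_position, right_min_position,
#'   height.
#' @export
peak_heights <- function(maxima, minima, circular = TRUE,
                         genome_length = NULL) {
  n <- nrow(maxima)
  if (!n) {
    maxima$left_min_position <- integer(0)
    maxima$right_min_position <- integer(0)
    maxima$height <- numeric(0)
    return(maxima)
  }
  if (!nrow(minima)) stop("no minima available to compute peak heights")
  mn <- minima[order(minima$position), , drop = FALSE]
  left_pos <- right_pos <- numeric(n)
  height <- numeric(n)
  for (i in seq_len(n)) {
    p <- maxima$position[i]
    lt <- which(mn$position < p)
    gt <- which(mn$position > p)
    li <- if (length(lt)) max(lt) else if (circular) nrow(mn) else NA_integer_
    ri <- if (length(gt)) min(gt) else if (circular) 1L else NA_integer_
    if (is.na(li) && is.na(ri)) {
      # only minimum coincides with the maximum (flat track)
      li <- ri <- which(mn$position == p)[1]
    }
    if (is.na(li)) li <- ri
    if (is.na(ri)) ri <- li
    left_pos[i] <- mn$position[li]
    right_pos[i] <- mn$position[ri]
    height[i] <- max(0, maxima$value[i] -
                       mean(c(mn$value[li], mn$value[ri])))
  }
  maxima$left_min_position <- left_pos
  maxima$right_min_position <- right_pos
  maxima$height <- height
  maxima
}

#' ChIPScore enrichment statistic
#'
#' Scores each peak by its height's position in the replicate-wide height
#' distribution: `(height - median) / (upper quartile - median)`, quantiles
#' by linear interpolation of order statistics.  A peak at the median scores
#' 0; a peak at the upper quartile scores 1.
#'
#' @param heights Numeric vector of peak heights for one replicate (at
#'   least 4, so quartiles are defined).
#' @return Numeric vector of ChIPScores.
#' @export
chip_scores <- function(heights) {
  if (length(heights) < 4L)
    stop("need at least 4 peaks to define the height quartiles")
  med <- unname(stats::quantile(heights, 0.5, type = 7))
  q3 <- unname(stats::quantile(heights, 0.75, type = 7))
  if (q3 - med < 1e-12) stop("degenerate height distribution")
  (heights - med) / (q3 - med)
}

#' Call and score peaks in one replicate
#'
#' Runs the full per-replicate chain: smoothing, window-extremum detection,
#' merging of nearby maxima, height computation against flanking minima, and
#' ChIPScore scoring.
#'
#' @param track Corrected ratio track ([loess_correct()]).
#' @param params A [peak_params()] object.
#' @param circular Treat the chromosome as circular?
#' @param genome_length Required when `circular = TRUE`; defaults to the
#'   last probe position plus one spacing when probes are evenly spaced.
#' @return A data.frame of scored peaks: replicate, max_position,
#'   left_min_position, right_min_position, smoothed_max, height,
#'   chip_score.
#' @export
call_peaks <- function(track, params = peak_params(), circular = TRUE,
                       genome_length = NULL) {
  if (circular && is.null(genome_length)) {
    sp <- diff(track$position)
    if (length(unique(sp)) == 1L) {
      genome_length <- max(track$position) + sp[1] - track$position[1] + 1
    } else {
      stop("genome_length required for circular peak calling")
    }
  }
  sm <- smooth_track(track, params, circular = circular)
  ex <- find_extrema(sm, params, circular = circular)
  mg <- merge_peaks(ex$maxima, params, circular = circular,
                    genome_length = genome_length)
  ph <- peak_heights(mg, ex$minima, circular = circular,
                     genome_length = genome_length)
  data.frame(
    replicate = if ("replicate" %in% names(track)) track$replicate[1]
                else "rep1",
    max_position = ph$position,
    left_min_position = ph$left_min_position,
    right_min_position = ph$right_min_position,
    smoothed_max = ph$value,
    height = ph$height,
    chip_score = chip_scores(ph$height),
    stringsAsFactors = FALSE
  )
}

#' Reconcile scored peaks across two replicates
#'
#' Greedy nearest-distance matching of replicate maxima: candidate pairs
#' within `replicate_match_dist` bp are taken in order of ascending
#' distance, each peak used at most once.  Matched pairs where both
#' ChIPScores reach `score_cutoff` become consensus peaks, positioned at the
#' (circular) midpoint of the two maxima and scored by the mean of the two
#' replicate scores.
#'
#' @param peaks1,peaks2 Scored peak data.frames from [call_peaks()].
#' @param params A [peak_params()] object.
#' @param circular Treat the chromosome as circular?
#' @param genome_length Required when `circular = TRUE`.
#' @return A data.frame: peak_id, max_position, chip_score, rep1_position,
#'   rep2_position, rep1_score, rep2_score, sorted by position.
#' @export
consensus_peaks <- function(peaks1, peaks2, params = peak_params(),
                            circular = TRUE, genome_length = NULL) {
  empty <- data.frame(peak_id = character(0), max_position = numeric(0),
                      chip_score = numeric(0), rep1_position = numeric(0),
                      rep2_position = numeric(0), rep1_score = numeric(0),
                      rep2_score = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(peaks1) || !nrow(peaks2)) return(empty)
  if (circular && is.null(genome_length))
    stop("genome_length needed for circular matching")
  dist_fun <- if (circular) {
    function(a, b) circ_dist(a, b, genome_length)
  } else {
    function(a, b) abs(b - a)
  }
  pairs <- expand.grid(i = seq_len(nrow(peaks1)), j = seq_len(nrow(peaks2)))
  pairs$d <- dist_fun(peaks1$max_position[pairs$i],
                      peaks2$max_position[pairs$j])
  pairs <- pairs[pairs$d <= params$replicate_match_dist, , drop = FALSE]
  pairs <- pairs[order(pairs$d, pairs$i, pairs$j), , drop = FALSE]
  used1 <- logical(nrow(peaks1)); used2 <- logical(nrow(peaks2))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used1[i] && !used2[j]) {
      used1[i] <- TRUE; used2[j] <- TRUE; keep[k] <- TRUE
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  ok <- peaks1$chip_score[pairs$i] >= params$score_cutoff &
        peaks2$chip_score[pairs$j] >= params$score_cutoff
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  p1 <- peaks1$max_position[pairs$i]
  p2 <- peaks2$max_position[pairs$j]
  pos <- if (circular) {
    round(wrap_pos(p1 + circ_signed_dist(p1, p2, genome_length) / 2,
                   genome_length))
  } else {
    round((p1 + p2) / 2)
  }
  out <- data.frame(
    max_position = pos,
    chip_score = (peaks1$chip_score[pairs$i] +
                    peaks2$chip_score[pairs$j]) / 2,
    rep1_position = p1,
    rep2_position = p2,
    rep1_score = peaks1$chip_score[pairs$i],
    rep2_score = peaks2$chip_score[pairs$j],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$max_position), , drop = FALSE]
  out <- cbind(peak_id = sprintf("peak%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
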