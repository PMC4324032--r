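#' Compute M and A values from raw two-channel probe intensities
#'
#' M is the log2 IP/WCE ratio; A is the average log2 intensity,
#' `(log2 IP + log2 WCE)/2`.  Probes are returned sorted by position.
#'
#' @param signals Probe data.frame with columns probe_id, position, ip, wce
#'   and optionally replicate (see [simulate_probe_signals()]).
#' @return A ratio track: data.frame with columns position, m, a, replicate,
#'   carrying attribute `corrected = FALSE`.
#' @export
compute_ma <- function(signals) {
  req <- c("position", "ip", "wce")
  if (!all(req %in% names(signals)))
    stop("signals must have columns position, ip, wce")
  bad <- which(!(signals$ip > 0) | !(signals$wce > 0))
  if (length(bad)) {
    id <- if ("probe_id" %in% names(signals)) signals$probe_id[bad[1]]
          else paste0("row ", bad[1])
    stop("non-positive intensity at probe ", id)
  }
  ord <- order(signals$position)
  s <- signals[ord, , drop = FALSE]
  track <- data.frame(
    position = s$position,
    m = log2(s$ip / s$wce),
    a = (log2(s$ip) + log2(s$wce)) / 2,
    replicate = if ("replicate" %in% names(s)) s$replicate else "rep1",
    stringsAsFactors = FALSE
  )
  rownames(track) <- NULL
  attr(track, "corrected") <- FALSE
  track
}

#' Correct intensity-dependent dye bias by loess regression on the MA plot
#'
#' Fits a locally weighted linear regression of M on A (robust Tukey
#' biweight fitting) and subtracts the fit, removing the curved dye-bias
#' trend while leaving genuine enrichment — a small fraction of probes on a
#' tiling array — essentially untouched.
#'
#' @param track Ratio track from [compute_ma()].
#' @param span Loess span (fraction of probes in each local fit).
#' @param degree Local polynomial degree.
#' @param family `"symmetric"` (robust, default) or `"gaussian"`.
#' @return The track with `m` replaced by the corrected residuals and
#'   attribute `corrected = TRUE`.  If A is degenerate (all equal) the mean
#'   of M is subtracted instead, with a warning.
#' @export
loess_correct <- function(track, span = 0.4, degree = 1,
                          family = "symmetric") {
  if (!all(c("position", "m", "a") %in% names(track)))
    stop("track must have columns position, m, a")
  if (nrow(track) < 50L) stop("need at least 50 probes for loess correction")
  if (!(span > 0 && span <= 1)) stop("span must lie in (0, 1]")
  if (diff(range(track$a)) < 1e-12) {
    warning("degenerate A values (all equal); subtracting mean of M instead")
    track$m <- track$m - mean(track$m)
  } else {
    fit <- stats::loess(m ~ a, data = track, span = span, degree = degree,
                        family = family,
                        control = stats::loess.control(
                          surface = "interpolate",
                          statistics = "approximate",
                          iterations = 4L))
    track$m <- track$m - stats::fitted(fit)
  }
  attr(track, "corrected") <- TRUE
  track
}
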