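# Independent brute-force oracles and small fixture builders.

# O(n*w) windowed mean, one round; truncating or circular windows.
brute_smooth_once <- function(m, w, circular = TRUE) {
  n <- length(m)
  half <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- (i - half):(i + half)
    if (circular) {
      idx <- ((idx - 1L) %% n) + 1L
    } else {
      idx <- idx[idx >= 1L & idx <= n]
    }
    mean(m[idx])
  }, numeric(1))
}

brute_smooth <- function(m, w, rounds, circular = TRUE) {
  for (r in seq_len(rounds)) m <- brute_smooth_once(m, w, circular)
  m
}

# Window extrema by direct scan: candidate probes equal to their window
# extreme, runs of consecutive candidates collapsed to the leftmost (a run
# wrapping the origin is represented by its first index after the gap).
brute_extrema <- function(m, w, circular = TRUE, what = "max") {
  n <- length(m)
  half <- (w - 1L) %/% 2L
  fn <- if (what == "max") max else min
  cand <- which(vapply(seq_len(n), function(i) {
    idx <- (i - half):(i + half)
    if (circular) idx <- ((idx - 1L) %% n) + 1L
    else idx <- idx[idx >= 1L & idx <= n]
    m[i] == fn(m[idx])
  }, logical(1)))
  if (!length(cand)) return(integer(0))
  keep <- cand[c(TRUE, diff(cand) > 1L)]
  if (circular && length(keep) > 1L && cand[1] == 1L &&
      cand[length(cand)] == n) {
    keep <- keep[-1]
  }
  keep
}

# Exhaustive tail probability over all 4^w sequences, on the same
# declared score grid (per-column log-odds rounded to `granularity` bits).
enum_pvalue <- function(pwm, threshold, background = pwm$background,
                        granularity = 1e-3) {
  bg <- background[c("A", "C", "G", "T")]
  w <- pwm$width
  K <- round(log2(pwm$probs / bg) / granularity)
  seqs <- as.matrix(expand.grid(rep(list(1:4), w)))
  ks <- rowSums(matrix(K[cbind(as.vector(seqs), rep(seq_len(w),
                                                    each = nrow(seqs)))],
                       nrow(seqs), w))
  pr <- exp(rowSums(log(matrix(bg[as.vector(seqs)], nrow(seqs), w))))
  kt <- round(threshold / granularity)
  sum(pr[ks >= kt])
}

random_pwm <- function(w, n_sites = 8L, pseudocount = NULL) {
  sites <- vapply(seq_len(n_sites), function(i) {
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
  }, character(1))
  build_pwm(sites, pseudocount = pseudocount %||% runif(1, 0.1, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal ratio track data.frame.
make_track <- function(m, spacing = 11L) {
  data.frame(position = seq.int(1L, by = spacing, length.out = length(m)),
             m = m, a = rep(10, length(m)), replicate = "rep1")
}

# Mirror an annotation problem: reverse-complement coordinates so every
# position p maps to L - p + 1 and strands flip.
flip_genes <- function(genes, L) {
  data.frame(name = genes$name,
             start = L - genes$end + 1L,
             end = L - genes$start + 1L,
             strand = ifelse(genes$strand == "+", "-", "+"),
             stringsAsFactors = FALSE)
}
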