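test_that("build_pwm tallies counts and applies the pseudocount formula", {
  p0 <- build_pwm(c("AA", "AA"), pseudocount = 0)
  expect_equal(p0$probs[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(p0$consensus, "AA")

  p1 <- build_pwm(c("A", "C"), pseudocount = 1)
  expect_equal(unname(p1$probs[, 1]), c(2 / 6, 2 / 6, 1 / 6, 1 / 6))

  sites <- simulate_aligned_sites(n = 40, seed = 3)
  p40 <- build_pwm(sites)
  expect_equal(p40$width, 20)
  expect_equal(unname(colSums(p40$counts)), rep(40, 20))
  expect_equal(unname(colSums(p40$probs)), rep(1, 20), tolerance = 1e-9)
})

test_that("build_pwm rejects bad alignments", {
  expect_error(build_pwm("ACGT"), "at least 2")
  expect_error(build_pwm(c("AC", "ACG")), "same length")
  expect_error(build_pwm(c("AN", "AC")), "only A, C, G, T")
})

test_that("match_count is the Hamming agreement with the consensus", {
  cons <- zur_box_consensus()
  expect_equal(match_count(cons, cons), 20)
  comp <- chartr("ACGT", "TGCA", cons)
  expect_equal(match_count(comp, cons), 0)
  mutated <- cons
  for (i in c(1, 4, 8, 12, 16, 20)) {
    substr(mutated, i, i) <- setdiff(c("A", "C", "G", "T"),
                                     substr(cons, i, i))[1]
  }
  expect_equal(match_count(mutated, cons), 14)
  expect_error(match_count("ACGT", cons), "length")
})

test_that("score_pvalue honours its boundary identities", {
  pwm1 <- build_pwm(c("A", "A", "A"), pseudocount = 0.5)
  smax <- log2(max(pwm1$probs) / 0.25)
  expect_equal(score_pvalue(pwm1, smax), 0.25)  # one base of four attains it
  expect_equal(score_pvalue(pwm1, -Inf), 1)
  expect_equal(score_pvalue(pwm1, smax + 10), 0)
})

test_that("p-values decrease as the threshold rises", {
  set.seed(21)
  pwm <- random_pwm(6)
  th <- seq(-10, 10, length.out = 30)
  pv <- vapply(th, function(t) score_pvalue(pwm, t), numeric(1))
  expect_true(all(diff(pv) <= 0))
  expect_true(all(pv >= 0 & pv <= 1))
})

test_that("the DP distribution matches exhaustive enumeration on small motifs", {
  set.seed(22)
  for (i in 1:8) {
    w <- sample(2:6, 1)
    pwm <- random_pwm(w)
    d <- pwm_score_distribution(pwm)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    thr <- sample(d$score, 1)
    expect_lt(abs(score_pvalue(pwm, thr) - enum_pvalue(pwm, thr)), 1e-9)
  }
})

test_that("scanning recovers a planted consensus exactly once at a stringent threshold", {
  set.seed(23)
  bg <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  box <- zur_box_consensus()
  seq_ <- paste0(substr(bg, 1, 2999), box, substr(bg, 3020, 5000))
  pwm <- build_pwm(simulate_aligned_sites(n = 40, seed = 7))
  expect_gte(pwm_information(pwm), 10)
  hits <- scan_pwm(seq_, pwm, p_threshold = 1e-6)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 3000)
  expect_lte(hits$p_value, 1e-6)
})

test_that("scanning an empty or too-short sequence yields no hits", {
  pwm <- build_pwm(simulate_aligned_sites(n = 10, seed = 8))
  expect_equal(nrow(scan_pwm("", pwm)), 0)
  expect_equal(nrow(scan_pwm("ACGTACGT", pwm)), 0)
})

test_that("a sequence and its reverse complement give the same hit count", {
  set.seed(24)
  pwm <- build_pwm(simulate_aligned_sites(n = 30, seed = 2))
  bg <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE,
                     prob = c(.3, .2, .2, .3)), collapse = "")
  seq_ <- paste0(bg, zur_box_consensus(),
                 substr(bg, 1, 500), zur_box_consensus())
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq_)))
  h1 <- scan_pwm(seq_, pwm, background = "uniform")
  h2 <- scan_pwm(rc, pwm, background = "uniform")
  expect_equal(nrow(h1), nrow(h2))
  expect_gte(nrow(h1), 2)
})

test_that("opposite-strand palindrome hits are deduplicated", {
  pwm <- build_pwm(simulate_aligned_sites(n = 40, seed = 9))
  set.seed(25)
  bg <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  seq_ <- paste0(bg, zur_box_consensus(), bg)
  hits <- scan_pwm(seq_, pwm, p_threshold = 1e-4)
  if (nrow(hits) > 1) {
    opp <- outer(hits$strand, hits$strand, "!=")
    sep <- abs(outer(hits$position, hits$position, "-"))
    overlap <- pwm$width - sep
    expect_false(any(opp & overlap >= pwm$width / 2 & upper.tri(opp)))
  }
  expect_gte(nrow(hits), 1)
})

test_that("ambiguous bases score as background and wrap-around hits are found", {
  pwm <- build_pwm(simulate_aligned_sites(n = 40, seed = 10))
  set.seed(26)
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  withN <- paste0(substr(bg, 1, 400), "NNNNN", substr(bg, 406, 1000))
  expect_silent(hN <- scan_pwm(withN, pwm))
  # a box straddling the origin is only found with circular = TRUE
  box <- zur_box_consensus()
  circ_seq <- paste0(substr(box, 11, 20), bg, substr(box, 1, 10))
  h_lin <- scan_pwm(circ_seq, pwm, circular = FALSE)
  h_circ <- scan_pwm(circ_seq, pwm, circular = TRUE)
  expect_equal(nrow(h_lin), 0)
  expect_equal(nrow(h_circ), 1)
  expect_equal(h_circ$position, nchar(circ_seq) - 9)
})

test_that("associate_hits applies the flank rule around the peak maximum", {
  peaks <- data.frame(peak_id = "pk1", max_position = 5000, chip_score = 8)
  hit <- function(pos) data.frame(position = pos, strand = "+",
                                  score = 20, p_value = 1e-9)
  a1 <- associate_hits(peaks, hit(4970), flank = 50, circular = FALSE)
  expect_true(a1$motif_associated)
  a2 <- associate_hits(peaks, hit(4920), flank = 50, circular = FALSE)
  expect_false(a2$motif_associated)
  a3 <- associate_hits(peaks, hit(4920)[0, ], flank = 50, circular = FALSE)
  expect_false(a3$motif_associated)
  # the lowest-p hit in range is attached
  hh <- rbind(hit(4990), hit(5010))
  hh$p_value <- c(1e-9, 1e-12)
  a4 <- associate_hits(peaks, hh, flank = 50, circular = FALSE)
  expect_equal(a4$hit_position, 5010)
})
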