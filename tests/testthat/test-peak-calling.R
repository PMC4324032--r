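test_that("peak_params validates its invariants", {
  expect_error(peak_params(window_probes = 28), "odd")
  expect_error(peak_params(window_probes = 1), "odd")
  expect_error(peak_params(merge_window = 0), "merge_window")
  expect_error(peak_params(score_cutoff = Inf), "finite")
})

test_that("smoothing preserves constants and spreads an impulse over the window", {
  pp <- peak_params(window_probes = 29, smoothing_rounds = 3)
  tr <- make_track(rep(2.5, 120))
  expect_equal(smooth_track(tr, pp)$m, rep(2.5, 120))

  imp <- rep(0, 100); imp[50] <- 29
  one <- peak_params(window_probes = 29, smoothing_rounds = 1)
  sm <- smooth_track(make_track(imp), one)$m
  expect_equal(sm[36:64], rep(1, 29))
  expect_equal(sm[-(36:64)], rep(0, 71))
})

test_that("smoothing matches the brute-force windowed mean, circular and truncating", {
  set.seed(11)
  for (circ in c(TRUE, FALSE)) {
    m <- rnorm(137)
    pp <- peak_params(window_probes = 15, smoothing_rounds = 2)
    got <- smooth_track(make_track(m), pp, circular = circ)$m
    expect_equal(got, brute_smooth(m, 15, 2, circular = circ),
                 tolerance = 1e-12)
  }
})

test_that("smoothing rejects a window wider than the track", {
  expect_error(smooth_track(make_track(rnorm(10)),
                            peak_params(window_probes = 29)), "larger")
})

test_that("extrema of simple shapes land where enumeration says", {
  pp <- peak_params(window_probes = 5)
  # strictly increasing, non-circular: max at the last probe, min at first
  inc <- make_track(seq(0, 1, length.out = 50))
  ex <- find_extrema(inc, pp, circular = FALSE)
  expect_equal(ex$maxima$index, 50)
  expect_equal(ex$minima$index, 1)

  # single triangular bump: one maximum at the apex, minima on the flanks
  bump <- make_track(c(seq(0, 1, length.out = 26),
                       seq(1, 0, length.out = 26)[-1]))
  exb <- find_extrema(bump, pp, circular = FALSE)
  expect_equal(exb$maxima$index, 26)
  expect_equal(nrow(exb$maxima), 1)
  expect_equal(exb$minima$index, c(1, 51))

  # plateau of 3 equal top probes: one maximum, at the leftmost
  plat <- c(seq(0, 0.9, length.out = 17), 1, 1, 1,
            seq(0.9, 0, length.out = 17))
  exp_ <- find_extrema(make_track(plat), pp, circular = FALSE)
  expect_equal(exp_$maxima$index, 18)
  expect_equal(nrow(exp_$maxima), 1)
})

test_that("extrema agree with the brute-force window scan on random tracks", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(60:400, 1)
    w <- sample(c(5, 9, 29), 1)
    circ <- sample(c(TRUE, FALSE), 1)
    m <- round(rnorm(n), sample(1:3, 1))  # rounding provokes ties
    pp <- peak_params(window_probes = w)
    ex <- find_extrema(make_track(m), pp, circular = circ)
    expect_identical(ex$maxima$index,
                     brute_extrema(m, w, circular = circ, what = "max"))
    expect_identical(ex$minima$index,
                     brute_extrema(m, w, circular = circ, what = "min"))
  }
})

test_that("merge_peaks clusters within the window and keeps the highest maximum", {
  pp <- peak_params(merge_window = 300)
  mx <- data.frame(position = c(100, 350), value = c(1, 2))
  expect_equal(merge_peaks(mx, pp, circular = FALSE)$position, 350)
  mx2 <- data.frame(position = c(100, 500), value = c(1, 2))
  expect_equal(merge_peaks(mx2, pp, circular = FALSE)$position, c(100, 500))
  empty <- data.frame(position = numeric(0), value = numeric(0))
  expect_equal(nrow(merge_peaks(empty, pp)), 0)
  # circular wrap: first and last maxima merge across the origin
  mx3 <- data.frame(position = c(50, 5000, 9950), value = c(1, 2, 3))
  got <- merge_peaks(mx3, pp, circular = TRUE, genome_length = 10000)
  expect_equal(got$position, c(5000, 9950))
  # leftmost wins on tied values
  mx4 <- data.frame(position = c(100, 200), value = c(1, 1))
  expect_equal(merge_peaks(mx4, pp, circular = FALSE)$position, 100)
})

test_that("peak height is the smoothed maximum minus the mean flanking minimum", {
  mx <- data.frame(position = c(100), value = c(2.0))
  mn <- data.frame(position = c(50, 150), value = c(0, 0))
  expect_equal(peak_heights(mx, mn, circular = FALSE)$height, 2.0)
  mn2 <- data.frame(position = c(50, 150), value = c(1.0, 2.0))
  got <- peak_heights(data.frame(position = 100, value = 3.0), mn2,
                      circular = FALSE)
  expect_equal(got$height, 1.5)
  expect_equal(got$left_min_position, 50)
  expect_equal(got$right_min_position, 150)
  # missing flank at a non-circular end: the single available minimum is used
  one <- peak_heights(data.frame(position = 10, value = 2.0),
                      data.frame(position = 60, value = 0.5),
                      circular = FALSE)
  expect_equal(one$height, 1.5)
  # circular flank search wraps around the origin
  wrapped <- peak_heights(data.frame(position = 10, value = 2.0),
                          data.frame(position = c(60, 9900),
                                     value = c(1.0, 0.0)),
                          circular = TRUE, genome_length = 10000)
  expect_equal(wrapped$height, 1.5)
  # heights clip at zero
  neg <- peak_heights(data.frame(position = 100, value = 0),
                      data.frame(position = c(50, 150), value = c(1, 1)),
                      circular = FALSE)
  expect_equal(neg$height, 0)
})

test_that("ChIPScore matches its defining identities", {
  h <- c(1, 2, 3, 4, 5)
  sc <- chip_scores(h)
  expect_equal(sc[h == 3], 0)   # median scores 0
  expect_equal(sc[h == 4], 1)   # upper quartile scores 1
  expect_equal(sc[h == 5], 2)   # (5 - 3) / (4 - 3)
  expect_error(chip_scores(c(1, 2, 3)), "at least 4")
  expect_error(chip_scores(rep(2, 10)), "degenerate")
})

test_that("consensus peaks require both replicates to pass the cutoff", {
  pp <- peak_params(score_cutoff = 4, replicate_match_dist = 300)
  mk <- function(pos, score) {
    data.frame(replicate = "r", max_position = pos, chip_score = score)
  }
  got <- consensus_peaks(mk(1000, 6), mk(1100, 5), pp, circular = FALSE)
  expect_equal(nrow(got), 1)
  expect_equal(got$max_position, 1050)
  expect_equal(got$chip_score, 5.5)
  expect_equal(nrow(consensus_peaks(mk(1000, 6), mk(1000, 3.9), pp,
                                    circular = FALSE)), 0)
  expect_equal(nrow(consensus_peaks(mk(1000, 6), mk(1400, 6), pp,
                                    circular = FALSE)), 0)
})

test_that("greedy matching pairs nearest maxima first and uses each peak once", {
  pp <- peak_params(score_cutoff = 0)
  p1 <- data.frame(max_position = c(1000, 1200), chip_score = c(5, 5))
  p2 <- data.frame(max_position = c(1150), chip_score = c(5))
  got <- consensus_peaks(p1, p2, pp, circular = FALSE)
  expect_equal(nrow(got), 1)
  expect_equal(got$rep1_position, 1200)  # 50 bp beats 150 bp
  # circular matching wraps around the origin
  g1 <- data.frame(max_position = 9990, chip_score = 5)
  g2 <- data.frame(max_position = 30, chip_score = 5)
  gc_ <- consensus_peaks(g1, g2, pp, circular = TRUE, genome_length = 10000)
  expect_equal(nrow(gc_), 1)
  expect_equal(gc_$max_position, 10)
})

test_that("raising the score cutoff never increases the consensus count", {
  set.seed(13)
  p1 <- data.frame(max_position = sort(sample(1e5, 40)),
                   chip_score = rexp(40, 1 / 3))
  p2 <- data.frame(max_position = p1$max_position +
                     sample(-200:200, 40, TRUE),
                   chip_score = rexp(40, 1 / 3))
  counts <- vapply(seq(0, 8, by = 0.5), function(cut) {
    nrow(consensus_peaks(p1, p2, peak_params(score_cutoff = cut),
                         circular = FALSE))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("heights and ChIPScores are invariant to adding a constant to the track", {
  p <- sim_params(genome_length = 60000, n_sites = 4, seed = 14)
  g <- generate_genome(p)
  planted <- plant_sites(g$sequence, g$genes, zur_box_consensus(), p,
                         min_spacing = 4000)
  tr <- compute_ma(simulate_probe_signals(g$length, planted$truth, p, 31))
  pk1 <- call_peaks(tr, genome_length = g$length)
  tr2 <- tr; tr2$m <- tr2$m + 3.7
  pk2 <- call_peaks(tr2, genome_length = g$length)
  expect_equal(pk1$max_position, pk2$max_position)
  expect_equal(pk1$height, pk2$height, tolerance = 1e-9)
  expect_equal(pk1$chip_score, pk2$chip_score, tolerance = 1e-9)
})
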