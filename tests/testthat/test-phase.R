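test_that("circular mean applies the dawn correction automatically", {
  expect_equal(as.numeric(circular_mean(c(2, 22))), 0)
  expect_equal(as.numeric(circular_mean(c(6, 6, 6))), 6)
  # vector-sum arithmetic: atan2 of summed sines/cosines
  expect_equal(as.numeric(circular_mean(c(1, 3, 23))), 1, tolerance = 1e-9)
  expect_error(circular_mean(numeric(0)), "empty")
})

test_that("antipodal phase sets break ties toward the smaller phase", {
  m <- circular_mean(c(3, 15))
  expect_equal(as.numeric(m), 3)
  expect_true(attr(m, "tie"))
  expect_false(attr(circular_mean(c(2, 22)), "tie"))
})

test_that("circular mean is rotation-equivariant", {
  set.seed(41)
  for (i in 1:25) {
    ph <- runif(sample(2:8, 1), 0, 24)
    cc <- runif(1, 0, 24)
    m0 <- as.numeric(circular_mean(ph))
    mc <- as.numeric(circular_mean((ph + cc) %% 24))
    expect_lt(circ_dist(mc, (m0 + cc) %% 24), 1e-6)
  }
})

test_that("dawn-straddling pairs are extended past 24 h", {
  expect_equal(adjust_pair(23, 1), c(23, 25))
  expect_equal(adjust_pair(1, 23), c(25, 23))
  expect_equal(adjust_pair(6, 10), c(6, 10))
  expect_equal(adjust_pair(0, 12), c(0, 12))  # strictly-greater rule
})

test_that("phase distance returns the shorter arc and its complement", {
  d <- phase_distance(1.6, 12.7)
  expect_equal(as.numeric(d), 11.1)
  expect_equal(attr(d, "complement"), 12.9)
  expect_equal(as.numeric(phase_distance(7.3, 7.3)), 0)
  expect_equal(as.numeric(phase_distance(0, 12)), 12)
})

test_that("phase distance is a metric on the circle", {
  set.seed(17)
  a <- runif(40, 0, 24); b <- runif(40, 0, 24); c <- runif(40, 0, 24)
  dab <- circ_dist(a, b)
  expect_equal(dab, circ_dist(b, a))
  expect_true(all(dab >= 0 & dab <= 12))
  expect_true(all(dab <= circ_dist(a, c) + circ_dist(c, b) + 1e-12))
})

test_that("agreement fraction counts circular windows", {
  p <- phase_pairs(letters[1:4], c(1, 23, 6, 12), c(23, 1, 6, 0))
  # distances: 2, 2, 0, 12
  expect_equal(agreement_fraction(p, window = 4), 0.75)
  same <- phase_pairs(letters[1:3], c(1, 2, 3), c(1, 2, 3))
  expect_equal(agreement_fraction(same, 4), 1)
  apart <- phase_pairs(letters[1:3], c(0, 6, 18), c(12, 18, 6))
  expect_equal(agreement_fraction(apart, 4), 0)
  expect_error(agreement_fraction(phase_pairs(character(0), numeric(0),
                                              numeric(0)), 4), "empty")
})

test_that("contour grid conserves counts and matches 1-D histograms", {
  set.seed(29)
  n <- 150
  p <- phase_pairs(sprintf("g%03d", 1:n), runif(n, 0, 24), runif(n, 0, 24))
  g <- contour_grid(p, bin = 2)
  expect_equal(sum(g), n)
  expect_equal(unname(rowSums(g)), unname(phase_histogram(p$phase_a, 2)))
  expect_equal(unname(colSums(g)), unname(phase_histogram(p$phase_b, 2)))

  ident <- phase_pairs(letters[1:5], rep(7, 5), rep(7, 5))
  gi <- contour_grid(ident, bin = 2)
  expect_equal(gi["ZT6", "ZT6"], 5L)
  expect_equal(sum(gi), 5L)
})

test_that("a 12 h-shifted cluster lands on the off-diagonal contour band", {
  spec <- synthetic_spec(noise_sd = 0, seed = 31)
  sc <- generate_comparative_scenario(60, 0, 0, phase_shift = 12, spec = spec)
  tr <- sc$truth
  p <- phase_pairs(tr$id, tr$phase_a, tr$phase_b)
  g <- contour_grid(p, bin = 4)
  hit <- which(g > 0, arr.ind = TRUE)
  centers <- seq(2, 22, by = 4)
  d <- circ_dist(centers[hit[, 1]], centers[hit[, 2]])
  expect_true(all(d >= 8))  # bin centers 12 h apart up to bin width
})

test_that("dawn-adjusted R^2 rescues dawn-straddling scatter", {
  # matched phases with jitter, several straddling ZT0: the raw Pearson is
  # wrecked by the wraparound pairs, the adjusted one is near-perfect
  a <- c(0.5, 23.5, 1, 23, 12, 6, 18, 2, 22, 9, 0.2, 23.8)
  b <- c(0.16, 0.05, 0.5, 23.03, 12.68, 5.76, 17.81, 1.75, 21.89, 9.06,
         0.69, 23.48)
  straddle <- phase_pairs(sprintf("g%d", seq_along(a)), a, b)
  expect_gt(adjusted_r_squared(straddle), 0.99)
  raw_r2 <- stats::cor(straddle$phase_a, straddle$phase_b)^2
  expect_lt(raw_r2, 0.7)

  exact <- phase_pairs(letters[1:5], c(1, 5, 9, 13, 17), c(1, 5, 9, 13, 17))
  expect_equal(adjusted_r_squared(exact), 1)

  # independent phases score far below matched ones; note the adjustment
  # rule itself induces some positive association (pairs > 12 h apart are
  # folded to the same side), so the floor sits near 0.38, not 0
  set.seed(53)
  indep <- phase_pairs(sprintf("g%d", 1:600), runif(600, 0, 24),
                       runif(600, 0, 24))
  expect_lt(adjusted_r_squared(indep), 0.5)

  flat <- phase_pairs(letters[1:3], c(4, 4, 4), c(9, 9, 9))
  expect_true(is.na(adjusted_r_squared(flat)))
})
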