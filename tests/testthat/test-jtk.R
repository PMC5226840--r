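test_that("reference orderings respect cosine symmetry and periodicity", {
  r24 <- reference_ordering(24, 0, zt_grid)
  # ZT0 and ZT24 share the top tie group
  top <- which(r24$ranks == max(r24$ranks))
  expect_setequal(zt_grid[top], c(0, 24))

  # a lag shift of one full period changes nothing
  r24b <- reference_ordering(24, 24, zt_grid)
  expect_equal(r24b$ranks, r24$ranks)

  # antiphase lag reverses the ordering
  r12 <- reference_ordering(24, 12, zt_grid)
  expect_equal(rank(-r24$values), r12$ranks)

  expect_error(reference_ordering(22, 0, zt_grid), "multiple")
  expect_error(reference_ordering(16, 0, zt_grid), "\\[20, 28\\]")
})

test_that("Kendall S matches the rescaled Kendall tau on tie-free data", {
  set.seed(61)
  n <- 12
  trials <- replicate(1000, {
    y <- rnorm(n)
    ref <- rnorm(n)
    s <- kendall_s(y, ref)
    tau <- stats::cor(y, ref, method = "kendall")
    s == round(tau * n * (n - 1) / 2)
  })
  expect_true(all(trials))
})

test_that("Kendall S is antisymmetric and maximal at the reference itself", {
  ref <- reference_ordering(24, 8, zt_grid)
  n <- length(ref$values)
  m_untied <- n * (n - 1) / 2 - sum(ref$tie_sizes * (ref$tie_sizes - 1) / 2)
  expect_equal(kendall_s(ref$values, ref), as.integer(m_untied))
  expect_equal(kendall_s(-ref$values, ref), -as.integer(m_untied))

  set.seed(67)
  y <- rnorm(12)
  expect_equal(kendall_s(rev(y), rev(ref$values)), kendall_s(y, ref$values))
})

test_that("exact null pmf equals brute-force enumeration for n <= 6", {
  cases <- list(c(1, 1, 1, 1), c(2, 1, 1), c(2, 2), c(1, 1, 1, 1, 1),
                c(2, 2, 1), c(3, 2), c(1, 1, 1, 1, 1, 1), c(2, 2, 2))
  for (ts in cases) {
    n <- sum(ts)
    ref <- rep(seq_along(ts), ts)  # tied reference realising the structure
    null <- exact_null(ts)
    brute <- vapply(all_perms(seq_len(n)), kendall_s, integer(1), ref = ref)
    tab <- table(factor(brute, levels = null$s)) / factorial(n)
    expect_equal(unname(as.numeric(tab)), null$p, tolerance = 1e-12,
                 info = paste(ts, collapse = ","))
    expect_equal(sum(null$p), 1)
    expect_equal(null$p, rev(null$p))  # symmetry about 0
  }
  # no ties, n = 4: P(S = max) = 1/24
  n4 <- exact_null(c(1, 1, 1, 1))
  expect_equal(n4$p[length(n4$p)], 1 / 24)
})

test_that("noiseless cosines are called at their true period and phase", {
  tp <- zt_grid
  mk <- function(per, ph) 5 + make_waveform("cosine", per, ph, tp)
  tc <- timecourse(c("p24ph8", "p20ph0", "p28ph4"), tp,
                   rbind(mk(24, 8), mk(20, 0), mk(28, 4)))
  calls <- call_rhythmic_jtk(tc)
  calls <- calls[order(calls$id), ]
  expect_equal(calls$id, c("p20ph0", "p24ph8", "p28ph4"))
  expect_equal(calls$period, c(20, 24, 28))
  expect_equal(calls$phase[calls$id == "p24ph8"], 8)
  expect_equal(calls$phase[calls$id == "p20ph0"], 0)
})

test_that("antiphasic rhythms report the shifted phase, not the raw lag", {
  tp <- zt_grid
  y <- 5 - make_waveform("cosine", 24, 0, tp)  # trough at ZT0, peak ZT12
  calls <- call_rhythmic_jtk(timecourse("g", tp, matrix(y, 1)))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$phase, 12)
})

test_that("calls are invariant under monotone transforms of expression", {
  spec <- synthetic_spec(n_genes = 60, frac_rhythmic = 0.5, noise_sd = 0.3,
                         baseline = 2, seed = 71)
  d <- generate_dataset(spec)
  base <- call_rhythmic_jtk(d$tc)
  warped <- d$tc
  warped$values <- exp(warped$values / 2)
  tr <- call_rhythmic_jtk(warped)
  expect_equal(tr$id, base$id)
  expect_equal(tr$phase, base$phase)
  expect_equal(tr$score, base$score)
})

test_that("adjusted p-values are Bonferroni over the period-lag lattice", {
  tp <- zt_grid
  y <- 5 + make_waveform("cosine", 24, 8, tp)
  calls <- call_rhythmic_jtk(timecourse("g", tp, matrix(y, 1)))
  res <- attr(calls, "results")
  expect_equal(attr(calls, "n_combinations"), 5 + 6 + 7)  # lags per period
  expect_equal(res$p_adj, pmin(1, res$p * 18))
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("the exact-null guard rejects oversized problems", {
  expect_error(exact_null(rep(2, 31)))
})
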