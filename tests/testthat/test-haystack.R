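test_that("model library enumerates shape x phase deterministically", {
  lib <- build_model_library(zt_grid)
  expect_equal(nrow(lib$patterns), 5 * 24)
  expect_equal(lib$patterns$shape[1:24], rep("cosine", 24))
  expect_equal(lib$patterns$phase[1:24], 0:23)
  w <- lib$values[lib$patterns$shape == "cosine" & lib$patterns$phase == 8, ]
  expect_equal(zt_grid[which.max(w)], 8)
  lib2 <- build_model_library(zt_grid)
  expect_identical(lib, lib2)
})

test_that("gene scoring is ordinary least squares with signed correlation", {
  patt <- make_waveform("cosine", 24, 8, zt_grid)
  fit <- score_gene(patt, patt)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  fit2 <- score_gene(3 + 2 * patt, patt)
  expect_equal(fit2$r, 1)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 3)

  fit3 <- score_gene(-patt, patt)
  expect_equal(fit3$r, -1)

  flat <- score_gene(rep(2, 12), patt)
  expect_equal(flat$r, 0)
  expect_true(flat$constant)
})

test_that("noiseless cosine genes are recovered at their exact phase", {
  vals <- t(vapply(0:23, function(ph) {
    8 + make_waveform("cosine", 24, ph, zt_grid)
  }, numeric(12)))
  tc <- timecourse(sprintf("g%02d", 0:23), zt_grid, vals)
  calls <- call_rhythmic_haystack(tc, n_perm = 100, seed = 1)
  expect_equal(nrow(calls), 24)
  expect_equal(calls$phase[order(calls$id)], 0:23)
  expect_equal(calls$shape, rep("cosine", 24))
  expect_true(all(calls$score > 0.999))
})

test_that("spike-shaped genes are called with shape spike", {
  spec <- synthetic_spec(n_genes = 50, frac_rhythmic = 1,
                         shapes = c(spike = 1), period_choices = 24,
                         noise_sd = 0.05, seed = 21)
  d <- generate_dataset(spec)
  # cutoff mode: shuffling a spike's time labels yields another perfect
  # spike, so the permutation null is degenerate for this shape family
  calls <- call_rhythmic_haystack(d$tc, mode = "cutoff")
  expect_gt(nrow(calls), 40)
  expect_true(all(calls$shape == "spike"))
})

test_that("an all-constant matrix yields zero calls", {
  tc <- timecourse(c("a", "b"), zt_grid, matrix(5, 2, 12))
  calls <- call_rhythmic_haystack(tc, n_perm = 100, seed = 1)
  expect_equal(nrow(calls), 0)
})

test_that("calls and phases are invariant under per-gene affine maps", {
  spec <- synthetic_spec(n_genes = 80, frac_rhythmic = 0.5, noise_sd = 0.2,
                         seed = 33)
  d <- generate_dataset(spec)
  base <- call_rhythmic_haystack(d$tc, mode = "cutoff")
  scaled <- d$tc
  a <- runif(80, 0.5, 3); b <- runif(80, -2, 2)
  scaled$values <- scaled$values * a + b
  tr <- call_rhythmic_haystack(scaled, mode = "cutoff")
  expect_equal(tr$id, base$id)
  expect_equal(tr$phase, base$phase)
  expect_equal(tr$shape, base$shape)
})

test_that("raising the cutoff never increases the number of calls", {
  spec <- synthetic_spec(n_genes = 100, frac_rhythmic = 0.4, noise_sd = 0.4,
                         seed = 37)
  d <- generate_dataset(spec)
  n_calls <- vapply(c(0.5, 0.7, 0.81, 0.9, 0.99), function(ct) {
    nrow(call_rhythmic_haystack(d$tc, cutoff = ct, mode = "cutoff"))
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("permutation threshold is reproducible and row-order invariant", {
  spec <- synthetic_spec(n_genes = 120, frac_rhythmic = 0, noise_sd = 1,
                         seed = 43)
  d <- generate_dataset(spec)
  lib <- build_model_library(zt_grid)
  t1 <- permutation_threshold(d$tc, lib, n_perm = 100, q = 5, seed = 10)
  t2 <- permutation_threshold(d$tc, lib, n_perm = 100, q = 5, seed = 10)
  expect_identical(t1, t2)

  shuf <- d$tc
  ord <- sample(120)
  shuf$ids <- shuf$ids[ord]; shuf$values <- shuf$values[ord, ]
  t3 <- permutation_threshold(shuf, lib, n_perm = 100, q = 5, seed = 10)
  expect_lt(abs(t3 - t1), 0.02)  # same distribution, new permutation draws

  expect_error(permutation_threshold(d$tc, lib, n_perm = 50), "n_perm")
})

test_that("top-fraction mode keeps at most the requested share of genes", {
  spec <- synthetic_spec(n_genes = 200, frac_rhythmic = 0.5, noise_sd = 0.3,
                         seed = 47)
  d <- generate_dataset(spec)
  calls <- call_rhythmic_haystack(d$tc, cutoff = 0, top_percent = 5,
                                  mode = "top_fraction")
  expect_lte(nrow(calls), 0.05 * 200 + 1)
})
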