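test_that("waveform shapes follow their stated conventions", {
  # cosine peaks at its phase (both cycles of a 48 h grid)
  w <- make_waveform("cosine", 24, 8, zt_grid)
  expect_setequal(zt_grid[w == max(w)], c(8, 32))

  # spike: a single nonzero residue, hit twice on two cycles
  s <- make_waveform("spike", 24, 8, zt_grid)
  expect_equal(sum(s != 0), 2)
  expect_setequal(zt_grid[s == 1], c(8, 32))

  # box: half-open [phase, phase + period/2) membership
  b <- make_waveform("box", 24, 0, zt_grid)
  expect_setequal(zt_grid[b == 1], c(0, 4, 8, 24, 28, 32))
  expect_equal(b[zt_grid == 12], 0)  # right edge excluded

  # ramps anchored at phase, linear over one period
  up <- make_waveform("ramp_up", 24, 0, zt_grid)
  expect_equal(up[1:6], (0:5) * 4 / 24)
  down <- make_waveform("ramp_down", 24, 0, zt_grid)
  expect_equal(up + down, rep(1, 12))

  expect_error(make_waveform("sawtooth", 24, 0, zt_grid), "unknown")
})

test_that("generation is deterministic and honours the rhythmic fraction", {
  spec <- synthetic_spec(n_genes = 200, frac_rhythmic = 0.1, seed = 5)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$tc$values, d2$tc$values)
  expect_identical(d1$truth, d2$truth)
  expect_equal(sum(d1$truth$is_rhythmic), 20)

  d3 <- generate_dataset(synthetic_spec(n_genes = 200, frac_rhythmic = 0.1,
                                        seed = 6))
  expect_false(identical(d1$tc$values, d3$tc$values))
})

test_that("noiseless cosine rows peak at the grid point nearest truth", {
  spec <- synthetic_spec(n_genes = 40, frac_rhythmic = 1,
                         shapes = c(cosine = 1), period_choices = 24,
                         noise_sd = 0, seed = 3)
  d <- generate_dataset(spec)
  argmax <- zt_grid[apply(d$tc$values, 1, which.max)] %% 24
  expect_true(all(circ_dist(argmax, d$truth$phase) <= 2 + 1e-9))
})

test_that("phase rotation by one interval permutes noiseless 24 h columns", {
  tp <- zt_grid
  for (shape in c("cosine", "spike", "box", "ramp_up", "ramp_down")) {
    for (ph in c(0, 5, 13.2)) {
      w0 <- make_waveform(shape, 24, ph, tp)
      w4 <- make_waveform(shape, 24, (ph + 4) %% 24, tp)
      # value at t after shifting equals value at t - 4 before
      expect_equal(w4, w0[match((tp - 4) %% 48, tp)],
                   info = paste(shape, ph))
    }
  }
})

test_that("comparative scenarios control overlap and phase shift exactly", {
  spec <- synthetic_spec(noise_sd = 0.1, seed = 9)
  sc <- generate_comparative_scenario(n_shared = 30, n_only_a = 20,
                                      n_only_b = 10, phase_shift = 12,
                                      spec = spec)
  tr <- sc$truth
  expect_equal(sum(tr$rhythmic_a & tr$rhythmic_b), 30)
  expect_equal(sum(tr$rhythmic_a & !tr$rhythmic_b), 20)
  expect_equal(sum(!tr$rhythmic_a & tr$rhythmic_b), 10)
  shared <- tr$rhythmic_a & tr$rhythmic_b
  expect_equal(circ_dist(tr$phase_a[shared], tr$phase_b[shared]),
               rep(12, 30))

  sc0 <- generate_comparative_scenario(10, 5, 5, phase_shift = 0, spec = spec)
  sh0 <- sc0$truth$rhythmic_a & sc0$truth$rhythmic_b
  expect_equal(sc0$truth$phase_a[sh0], sc0$truth$phase_b[sh0])

  # Venn partition of the truth sets reconciles with the requested counts
  set_a <- gene_set("a", tr$id[tr$rhythmic_a])
  set_b <- gene_set("b", tr$id[tr$rhythmic_b])
  expect_equal(unname(venn_counts(set_a, set_b)), c(20L, 30L, 10L))
})

test_that("wrapped-cluster phase distributions concentrate around their means", {
  clusters <- data.frame(mean = c(2, 14), sd = c(1, 1), weight = c(0.5, 0.5))
  spec <- synthetic_spec(n_genes = 400, frac_rhythmic = 1,
                         phase_dist = clusters, noise_sd = 0, seed = 13)
  d <- generate_dataset(spec)
  near <- pmin(circ_dist(d$truth$phase, 2), circ_dist(d$truth$phase, 14))
  expect_gt(mean(near <= 3), 0.95)
})

test_that("spec validation rejects out-of-range settings", {
  expect_error(synthetic_spec(frac_rhythmic = 1.2))
  expect_error(synthetic_spec(period_choices = c(16, 24)))
  expect_error(synthetic_spec(shapes = c(zigzag = 1)), "waveform")
})
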