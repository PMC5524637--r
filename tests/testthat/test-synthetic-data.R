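# Generators: determinism, ground-truth round trips, two-group studies.

test_that("a fixed seed reproduces a dataset bit for bit", {
  a <- generate(generator_spec("linescan", seed = 7, n_sparks = 10))
  b <- generate(generator_spec("linescan", seed = 7, n_sparks = 10))
  expect_identical(a, b)
  c <- generate(generator_spec("linescan", seed = 8, n_sparks = 10))
  expect_false(identical(a$data$img, c$data$img))
  # replicate index gives an independent stream
  d <- generate(generator_spec("linescan", seed = 7, replicate = 2,
                               n_sparks = 10))
  expect_false(identical(a$data$img, d$data$img))
})

test_that("generation does not disturb the session RNG state", {
  set.seed(123); before <- .Random.seed
  invisible(generate(generator_spec("binding", seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("unknown kinds are rejected", {
  expect_error(generator_spec("volcano", seed = 1), "unknown generator kind")
})

test_that("dyad mask construction round-trips through the distance report", {
  g <- generate(generator_spec("dyad_masks", seed = 5, geometry = "parallel",
                               gap_px = 12, pixel_size_nm = 1))
  expect_equal(dyad_distances(g$data)$mean_nm, g$truth$gap_nm)
})

test_that("ratiometric generator inverts the calibration equation", {
  g <- generate(generator_spec("ratiometric", seed = 1,
                               true_ca_nm = c(50, 245, 900)))
  ca <- ratiometric_calcium(g$data$r, g$data$r_min, g$data$r_max,
                            g$data$beta, g$data$kd_nm)
  expect_equal(as.numeric(ca), g$truth$true_ca_nm, tolerance = 1e-12)
})

test_that("transient generator truth is recovered by feature extraction", {
  g <- generate(generator_spec("transient", seed = 6, amplitude = 1.2,
                               tau_decay = 150, noise_sd = 0))
  f <- transient_features(g$data, smooth_window = 1)
  expect_equal(f$amplitude, 1.2, tolerance = 0.01)
  expect_equal(f$time_to_peak, g$truth$time_to_peak, tolerance = 0.05)
  # the decay fit window starts at the peak, where the rising exponential
  # still contaminates the decay, so recovery is approximate
  expect_equal(f$tau_relax, 150, tolerance = 0.15)
})

test_that("two-group generator delivers the declared effect and determinism", {
  s1 <- generate_two_group_study(30, effect_sd = 2, seed = 4)
  s2 <- generate_two_group_study(30, effect_sd = 2, seed = 4)
  expect_identical(s1, s2)
  expect_error(generate_two_group_study(1), "at least 2")

  # power at a 2 SD effect, n = 20 per group
  rej <- vapply(1:200, function(r) {
    s <- generate_two_group_study(20, effect_sd = 2, seed = 99, replicate = r)
    compare_groups(list(control = s$control, ko = s$ko))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.95)
})
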