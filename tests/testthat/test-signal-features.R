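# Transient landmarks, current fits, calibration and counting operators.

triangle_trace <- function(dt = 1) {
  # baseline 0, linear rise to 1 at t = 100 ms, linear return to 0 at 200 ms
  up <- seq(0, 1, length.out = 100 / dt + 1)
  dn <- seq(1, 0, length.out = 100 / dt + 1)[-1]
  new_trace(c(up, dn), dt)
}

test_that("triangular transient landmarks match the piecewise-linear closed form", {
  f <- transient_features(triangle_trace(), smooth_window = 1)
  # closed form: 50%-max upstroke at t = 50; x% recovery at 100 + 100 x/100
  expect_equal(f$time_to_peak, 100)
  expect_equal(f$amplitude, 1)
  expect_equal(f$cad50, 100)
  expect_equal(f$cad30, 80)
  expect_equal(f$cad70, 120)
})

test_that("landmark extraction survives noise with default smoothing", {
  set.seed(11)
  tr <- triangle_trace()
  tr$samples <- tr$samples + rnorm(length(tr$samples), 0, 0.02)
  f <- transient_features(tr)
  expect_equal(f$cad50, 100, tolerance = 0.05)
  expect_true(f$cad30 <= f$cad50 && f$cad50 <= f$cad70)
})

test_that("cad monotonicity holds across generated transients", {
  for (rep in 1:10) {
    g <- generate(generator_spec("transient", seed = 5, replicate = rep,
                                 noise_sd = 0.01))
    f <- transient_features(g$data)
    expect_true(f$cad30 <= f$cad50 && f$cad50 <= f$cad70)
    expect_gte(f$time_to_peak, 0)
  }
})

test_that("relaxation fit recovers a known exponential time constant", {
  t <- seq(0, 900, by = 1)
  x <- c(0, exp(-t / 120))            # instant rise, pure exponential decay
  f <- transient_features(new_trace(x, 1), smooth_window = 1)
  expect_equal(f$tau_relax, 120, tolerance = 1 / 120)
})

test_that("inactivation tau is recovered and failure modes are flagged", {
  tr <- new_trace(-10 * exp(-(0:399) / 15), 1)
  expect_equal(fit_inactivation_tau(tr), 15, tolerance = 0.1 / 15)

  set.seed(2)
  noise <- new_trace(rnorm(400, 0, 0.1), 1)
  expect_error(fit_inactivation_tau(noise), "fail|decay")
})

test_that("charge integration is the baseline-subtracted trapezoid", {
  rect <- new_trace(rep(-5, 101), 1)
  expect_equal(integrate_charge(rect), -0.5)
  # linearity
  rect2 <- new_trace(2 * rect$samples, 1)
  expect_equal(integrate_charge(rect2), 2 * integrate_charge(rect))
  # baseline subtraction
  expect_equal(integrate_charge(new_trace(rep(-4, 101), 1), baseline = -4), 0)
})

test_that("ratiometric calibration follows the two-wavelength equation", {
  expect_equal(as.numeric(ratiometric_calcium(1.3, 0.3, 3.3, beta = 2)), 245)
  r_mid <- (0.3 + 3.3) / 2
  expect_equal(as.numeric(ratiometric_calcium(r_mid, 0.3, 3.3, beta = 1.5)),
               245 * 1.5)
  low <- ratiometric_calcium(0.3, 0.3, 3.3, beta = 2)
  expect_equal(as.numeric(low), 0)
  expect_true(attr(low, "clipped"))
  expect_error(ratiometric_calcium(3.3, 0.3, 3.3, beta = 2), "r_max")
  # strictly increasing in r on (r_min, r_max)
  rs <- seq(0.35, 3.25, length.out = 50)
  cas <- as.numeric(ratiometric_calcium(rs, 0.3, 3.3, beta = 2))
  expect_true(all(diff(cas) > 0))
})

test_that("spark detection recovers generated events and units scale", {
  g <- generate(generator_spec("linescan", seed = 7, n_sparks = 10,
                               amplitude = 0.8, noise_sd = 0.05))
  s <- detect_sparks(g$data$img, g$data$dx_um, g$data$dt_ms,
                     baseline_rows = g$data$baseline_rows)
  expect_equal(s$n_events, 10)
  expect_equal(s$mean_amplitude, 1.8, tolerance = 0.1 / 1.8)

  blank <- generate(generator_spec("linescan", seed = 8, n_sparks = 0,
                                   noise_sd = 0.05))
  s0 <- detect_sparks(blank$data$img, blank$data$dx_um, blank$data$dt_ms,
                      baseline_rows = blank$data$baseline_rows)
  expect_equal(s0$n_events, 0)

  # doubling the line period halves the frequency per unit time
  s2 <- detect_sparks(g$data$img, g$data$dx_um, 2 * g$data$dt_ms,
                      baseline_rows = g$data$baseline_rows)
  expect_equal(s2$frequency_per_100um_s, s$frequency_per_100um_s / 2)

  expect_error(detect_sparks(g$data$img, g$data$dx_um, g$data$dt_ms),
               "baseline")
})

test_that("leak/load ratio contract", {
  expect_equal(leak_load_ratio(0, 5), 0)
  expect_equal(leak_load_ratio(1, 4), 0.25)
  expect_error(leak_load_ratio(2, 0), "load")
})

test_that("Hill binding fit recovers generating parameters", {
  g <- generate(generator_spec("binding", seed = 3, b_max = 1, ec50 = 300,
                               hill_n = 2, noise_sd = 0))
  fit <- fit_hill_binding(g$data$free_ca_nm, g$data$bound)
  expect_equal(fit$b_max, 1, tolerance = 1e-6)
  expect_equal(fit$ec50, 300, tolerance = 1e-6)
  expect_equal(fit$hill_n, 2, tolerance = 1e-6)
  # bound at EC50 equals Bmax/2 by definition
  at_ec50 <- fit$b_max * fit$ec50^fit$hill_n /
    (fit$ec50^fit$hill_n + fit$ec50^fit$hill_n)
  expect_equal(at_ec50, fit$b_max / 2)

  gn <- generate(generator_spec("binding", seed = 4, b_max = 1, ec50 = 300,
                                hill_n = 2, noise_sd = 0.02))
  fn <- fit_hill_binding(gn$data$free_ca_nm, gn$data$bound)
  expect_equal(fn$ec50, 300, tolerance = 0.1)
  expect_equal(fn$b_max, 1, tolerance = 0.1)

  expect_error(fit_hill_binding(c(100, 300, 1000), c(0.1, 0.5, 0.9)),
               "4 concentration")
})

test_that("Mitchell QTc formula", {
  expect_equal(qtc_mitchell(50, 100), 50)
  expect_equal(qtc_mitchell(50, 400), 25)
  expect_equal(qtc_mitchell(48, 144), 40)
  expect_error(qtc_mitchell(-1, 100), "positive")
  expect_error(qtc_mitchell(50, 0), "positive")
})

test_that("event counting uses half-open windows", {
  w <- 30 * 60 * 1000
  expect_equal(count_events_per_window(numeric(0), w), 0)
  g <- generate(generator_spec("event_times", seed = 9, n_events = 381,
                               window_ms = w))
  expect_equal(count_events_per_window(g$data, w), 381)
  expect_equal(count_events_per_window(c(0, w / 2, w), w), 2)
})
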