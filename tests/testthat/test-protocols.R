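# Clamp protocols: structure, gain formula, caffeine dump, pacing.

test_that("the gain statistic is the direct ratio formula", {
  expect_equal(ec_gain(2, 1, 4), 0.5)
  expect_equal(ec_gain(2, 1, -4), 0.5)        # sign of the current ignored
  # no release: peak equals baseline
  expect_equal(ec_gain(1, 1, 5), 1 / 5)
  expect_true(is.na(ec_gain(2, 1, 0)))
  expect_error(ec_gain(2, 0, 4))
})

test_that("the I-V protocol runs the stated step structure", {
  iv <- cached_iv_control()
  expect_equal(iv$steps$v_test, seq(-60, 40, by = 10))
  expect_equal(nrow(iv$steps), 11)
  expect_equal(iv$meta$step_ms, 400)
  expect_equal(iv$meta$interpulse_ms, 5000)
  # traces cover the step at the output resolution
  expect_equal(length(iv$traces[[1]]$current$samples), 4001)
})

test_that("the control I-V relation is bell-shaped with a peak near 0 mV", {
  iv <- cached_iv_control()
  pk <- abs(iv$steps$peak_density)
  imax <- which.max(pk)
  expect_true(iv$steps$v_test[imax] >= -10 && iv$steps$v_test[imax] <= 10)
  # increases to a single maximum, then decreases
  expect_true(all(diff(pk[1:imax]) > 0))
  expect_true(all(diff(pk[imax:length(pk)]) < 0))
})

test_that("removing the channels zeroes the I-V readouts", {
  p <- make_control_params()
  p$g_cal <- 0
  iv <- run_iv_protocol(p, v_tests = c(-20, 0, 20), pre_ms = 5000)
  expect_true(all(abs(iv$steps$peak_density) < 1e-6))
  expect_true(all(is.na(iv$steps$tau_inact)))
  expect_true(all(abs(iv$steps$charge_q) < 1e-6))
})

test_that("reported gain is self-consistent with the returned traces", {
  g <- run_gain_protocol(make_control_params(), v_tests = c(0, 20),
                         pre_ms = 120000)
  for (k in seq_len(nrow(g$steps))) {
    cur <- g$traces[[k]]$current
    ca <- g$traces[[k]]$ca
    in_step <- trace_time(cur) <= g$meta$step_ms
    recomputed <- ec_gain(max(ca$samples), g$steps$cai0[k],
                          max(abs(cur$samples[in_step])))
    expect_equal(g$steps$gain[k], recomputed)
  }
})

test_that("caffeine on an empty SR gives a unit load ratio", {
  p <- make_control_params()
  st <- rest_state(p)
  st["ca_nsr"] <- st[["ca_i"]]
  st["ca_jsr"] <- st[["ca_i"]]
  d <- run_caffeine_dump(p, mode = "intact", state0 = st, duration = 500)
  expect_equal(d$sr_load, 1, tolerance = 0.02)
})

test_that("caffeine dump empties the SR within the conservation bound", {
  d <- run_caffeine_dump(make_control_params(), mode = "intact",
                         duration = 1500)
  expect_gt(d$sr_load, 1.5)
  expect_false(is.na(d$t_depleted_ms))
  expect_lte(d$released_pmol, d$sr_content_pre_pmol)
  expect_gte(d$released_pmol, 0)
})

test_that("permeabilized baseline is clamped identically across variants", {
  dc <- cached("caff_perm_control",
               run_caffeine_dump(make_control_params(), "permeabilized"))
  dk <- cached("caff_perm_ko",
               run_caffeine_dump(make_pkp2cko_params(), "permeabilized"))
  expect_equal(dc$baseline, dk$baseline, tolerance = 0.01)
  expect_equal(dc$baseline, make_control_params()$bath_ca, tolerance = 0.05)
})

test_that("pacing elicits one transient per beat and reaches steady state", {
  pc <- cached("pace_control_1hz",
               run_pacing(make_control_params(), freq_hz = 1, n_beats = 10))
  expect_equal(nrow(pc$beats), 10)
  expect_true(all(is.finite(pc$beats$amplitude)))
  a <- tail(pc$beats$amplitude, 2)
  expect_equal(a[1], a[2], tolerance = 0.02)

  empty <- run_pacing(make_control_params(), freq_hz = 1, n_beats = 0)
  expect_equal(nrow(empty$beats), 0)
  expect_equal(nrow(empty$events), 0)
})
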