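# Numerical core: fixed points, conservation, flux bookkeeping, and the
# fixed-step Euler oracle for the adaptive solver.

test_that("the control rest state is a fixed point of the dynamics", {
  p <- make_control_params()
  rs <- rest_state(p)
  d <- model_derivatives(p, rs, -80)
  sc <- pmax(abs(rs), 1e-3)
  expect_lt(max(abs(d$dstate) / sc), 1e-9)

  tr <- integrate_model(p, rs, v_const(-80), 1000)
  fin <- attr(tr, "final_state")
  expect_lt(max(abs(fin - rs) / pmax(abs(rs), 1e-5)), 1e-6)
})

test_that("holding at rest for seconds leaves the state stationary", {
  p <- make_control_params()
  rs <- rest_state(p)
  tr <- integrate_model(p, rs, v_const(-80), 5000, dt_out = 1)
  d <- model_derivatives(p, attr(tr, "final_state"), -80)
  expect_lt(max(abs(d$dstate) / pmax(abs(rs), 1e-3)), 1e-9)
})

test_that("total calcium is conserved when sarcolemmal fluxes are removed", {
  p <- make_control_params()
  p$g_cal <- 0; p$g_ncx <- 0; p$g_cab <- 0
  rs <- rest_state(make_control_params())
  # perturb the closed system away from rest
  rs["ca_i"] <- rs["ca_i"] * 3
  rs["ca_jsr"] <- rs["ca_jsr"] * 1.2
  tot0 <- total_calcium(p, rs)
  tr <- integrate_model(p, rs, v_const(-80), 10000, dt_out = 10)
  tot1 <- total_calcium(p, attr(tr, "final_state"))
  expect_lt(abs(tot1 - tot0) / tot0, 1e-6)
})

test_that("the rate of total-calcium change equals the sarcolemmal flux sum", {
  p <- make_control_params()
  set.seed(31)
  bnd_slope <- function(ca, btot, kd) btot * kd / (kd + ca)^2
  for (k in 1:25) {
    st <- rest_state(p)
    st["ca_cleft"] <- runif(1, 1e-4, 0.05)
    st["ca_sub"] <- runif(1, 1e-4, 2e-3)
    st["ca_i"] <- runif(1, 5e-5, 1e-3)
    st["ca_nsr"] <- runif(1, 0.3, 1.2)
    st["ca_jsr"] <- runif(1, 0.2, 1.1)
    st["ryr_o"] <- runif(1, 0, 0.3)
    st["ryr_r"] <- runif(1, 0, 1 - st["ryr_o"])
    st["ryr_i"] <- 0
    v <- runif(1, -80, 40)
    out <- model_derivatives(p, st, v)
    dtot <- p$vol_cleft *
      (1 + bnd_slope(st[["ca_cleft"]], p$buf_cleft, p$kd_cleft)) *
      out$dstate[["ca_cleft"]] +
      p$vol_sub * (1 + bnd_slope(st[["ca_sub"]], p$buf_sub, p$kd_sub)) *
      out$dstate[["ca_sub"]] +
      p$vol_cyto * (1 + bnd_slope(st[["ca_i"]], p$buf_cyto1, p$kd_cyto1) +
                    bnd_slope(st[["ca_i"]], p$buf_cyto2, p$kd_cyto2)) *
      out$dstate[["ca_i"]] +
      p$vol_nsr * out$dstate[["ca_nsr"]] +
      p$vol_jsr * (1 + bnd_slope(st[["ca_jsr"]], p$csq_total, p$kd_csq)) *
      out$dstate[["ca_jsr"]]
    jsarc <- out$aux[["Jsarc_pmol"]] + out$aux[["Jbath_pmol"]]
    expect_equal(dtot, jsarc, tolerance = 1e-6)
  }
})

test_that("adaptive trajectories match the fixed-step Euler oracle", {
  p <- make_control_params()
  rs <- rest_state(p)
  vc <- v_step(-80, 0, 0, 400)
  ad <- integrate_model(p, rs, vc, 400, dt_out = 0.1)
  eu <- integrate_model_euler(p, rs, vc, 400, dt = 1e-4, dt_out = 0.1)
  pk_ad <- max(abs(ad$ICaL_pApF))
  pk_eu <- max(abs(eu$ICaL_pApF))
  expect_equal(pk_ad, pk_eu, tolerance = 0.005)
  dca_ad <- max(ad$ca_i) - ad$ca_i[1]
  dca_eu <- max(eu$ca_i) - eu$ca_i[1]
  expect_equal(dca_ad, dca_eu, tolerance = 0.005)
})

test_that("trajectories are well-formed and serialisable", {
  p <- make_control_params()
  rs <- rest_state(p)
  tr <- integrate_model(p, rs, v_step(-80, 0, 10, 60), 100)
  expect_true(all(diff(tr$t_ms) > 0))
  expect_true(all(c("t_ms", "V_mV", "ICaL_pApF", "ca_i", "ca_nsr",
                    "Jrel", "Jserca", "Jncx") %in% names(tr)))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read.csv(path)
  expect_equal(names(back), c("t_ms", "V_mV", "ICaL_pApF", "Cai_mM",
                              "CaSR_mM", "Jrel", "Jserca", "Jncx"))
  expect_equal(back$ICaL_pApF, tr$ICaL_pApF)
})

test_that("voltage commands validate their inputs", {
  expect_error(v_command(c(1, 2), c(0, 0)))        # must start at 0
  expect_error(v_command(c(0, 5, 3), c(1, 2, 3)))  # must increase
  vc <- v_step(-80, 0, 100, 500)
  expect_equal(cacycle:::v_at(vc, c(50, 100, 499, 500)), c(-80, 0, 0, -80))
})

test_that("steady-state search converges and flags quiescence", {
  p <- make_control_params()
  ss <- find_steady_state(p, -80)
  expect_true(ss$converged)
  expect_false(ss$periodic_discharges)
  expect_equal(sum(ss$state[c("ryr_r", "ryr_o", "ryr_i")]) <= 1 + 1e-9, TRUE)
})
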