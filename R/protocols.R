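# Voltage-clamp protocol drivers: current-voltage relation, e-c coupling
# gain, caffeine-evoked SR dump, and pacing.

newton_polish <- function(params, state, v, n_iter = 12) {
  # polish a relaxed state to the exact fixed point of the RHS
  pv <- params_vector(params)
  f <- function(y) .ca_rhs_cpp(y, pv, v)$dy
  y <- as.numeric(state[.state_names])
  fy <- f(y)
  for (it in seq_len(n_iter)) {
    if (max(abs(fy)) < 1e-14) break
    J <- matrix(0, length(y), length(y))
    for (j in seq_along(y)) {
      h <- 1e-7 * max(abs(y[j]), 1e-6)
      yh <- y; yh[j] <- yh[j] + h
      J[, j] <- (f(yh) - fy) / h
    }
    step <- tryCatch(solve(J, fy), error = function(e) NULL)
    if (is.null(step)) break
    y2 <- y - step
    f2 <- tryCatch(f(y2), error = function(e) NULL)
    if (is.null(f2) || !all(is.finite(f2)) || max(abs(f2)) > max(abs(fy)))
      break
    y <- y2; fy <- f2
  }
  setNames(y, .state_names)
}

equilibrated_state <- function(params, v_hold, max_duration) {
  ss <- find_steady_state(params, v_hold, max_duration = max_duration)
  if (ss$converged) {
    st <- newton_polish(params, ss$state, v_hold)
    if (!any(st[c("ca_cleft", "ca_sub", "ca_i", "ca_nsr", "ca_jsr")] < 0))
      return(list(state = st, ss = ss))
  }
  list(state = ss$state, ss = ss)
}

#' Current-voltage (I-V) protocol for the L-type calcium current
#'
#' Holds the model at -80 mV, then steps to test potentials from -60 to
#' +40 mV in 10 mV increments, 400 ms per step, with 5 s interpulse
#' intervals at the hold.  Per step, the peak current density, the
#' single-exponential inactivation time constant and the charge (time
#' integral of the current over the step) are extracted.
#'
#' @param params A `ca_params` object.
#' @param v_tests Test potentials (mV).
#' @param hold_mV Holding potential (mV).
#' @param step_ms Step duration (ms).
#' @param interpulse_ms Interval between steps at the hold (ms).
#' @param pre_ms Pre-equilibration at the hold before the first step (ms).
#' @param dt_out Output sampling (ms).
#' @return A `ca_protocol` object: `$steps` is a data frame with one row
#'   per test potential (`v_test`, `peak_density` in pA/pF, `tau_inact`
#'   in ms, `charge_q` in pC/pF, `dca_amplitude` in mM); `$traces` holds
#'   the per-step current and Ca2+ traces.
#' @export
run_iv_protocol <- function(params, v_tests = seq(-60, 40, by = 10),
                            hold_mV = -80, step_ms = 400,
                            interpulse_ms = 5000, pre_ms = 60000,
                            dt_out = 0.1) {
  validate_params(params)
  eq <- equilibrated_state(params, hold_mV, pre_ms)
  state <- eq$state
  steps <- vector("list", length(v_tests))
  traces <- vector("list", length(v_tests))
  for (k in seq_along(v_tests)) {
    v <- v_tests[k]
    i_hold <- model_derivatives(params, state, hold_mV)$aux[["ICaL_pApF"]]
    tr <- tryCatch(
      integrate_model(params, state, v_command(c(0, step_ms), c(v, hold_mV)),
                      step_ms + interpulse_ms, dt_out = dt_out),
      error = function(e) stop(sprintf("I-V step to %g mV failed: %s",
                                       v, conditionMessage(e)), call. = FALSE))
    state <- attr(tr, "final_state")
    in_step <- tr$t_ms <= step_ms
    cur <- new_trace(tr$ICaL_pApF[in_step], dt_out, units = "pA/pF")
    ca <- new_trace(tr$ca_i[in_step], dt_out, units = "mM")
    i_net <- cur$samples - i_hold
    ipk <- which.max(abs(i_net))
    peak <- i_net[ipk]
    tau <- if (abs(peak) < 1e-6) NA_real_ else
      tryCatch(fit_inactivation_tau(cur), error = function(e) NA_real_)
    q <- integrate_charge(cur, baseline = i_hold)
    steps[[k]] <- data.frame(v_test = v, peak_density = peak,
                             tau_inact = tau, charge_q = q,
                             dca_amplitude = max(ca$samples) - ca$samples[1])
    traces[[k]] <- list(current = cur, ca = ca)
  }
  structure(list(steps = do.call(rbind, steps), traces = traces,
                 meta = list(protocol = "iv", hold_mV = hold_mV,
                             step_ms = step_ms,
                             interpulse_ms = interpulse_ms,
                             pre_ms = pre_ms, variant = params$variant)),
            class = "ca_protocol")
}

#' Excitation-contraction coupling gain protocol
#'
#' Holds the model at -50 mV until steady state (600 s cap), then applies
#' 150 ms test steps from -40 to +60 mV.  The gain of each step is
#' (peak \[Ca2+\]i / pre-step \[Ca2+\]i) divided by the peak L-type
#' current magnitude.  If the hold settles on a limit cycle of
#' spontaneous SR discharges, each step is placed at least 500 ms after
#' the preceding discharge and at least 500 ms before the next one; if no
#' such window exists the protocol aborts naming the hold periodicity.
#'
#' @param params A `ca_params` object.
#' @param v_tests Test potentials (mV).
#' @param hold_mV Holding potential (mV).
#' @param step_ms Step duration (ms).
#' @param pre_ms Steady-state search cap at the hold (ms).
#' @param tail_ms Post-step window kept for locating the Ca2+ peak (ms).
#' @param dt_out Output sampling (ms).
#' @return A `ca_protocol` object whose `$steps` data frame has columns
#'   `v_test`, `peak_density`, `dca_amplitude`, `cai0`, and `gain`.
#' @export
run_gain_protocol <- function(params, v_tests = seq(-40, 60, by = 10),
                              hold_mV = -50, step_ms = 150, pre_ms = 600000,
                              tail_ms = 150, dt_out = 0.1) {
  validate_params(params)
  eq <- equilibrated_state(params, hold_mV, pre_ms)
  base <- eq$state
  if (!eq$ss$converged && eq$ss$periodic_discharges) {
    base <- discharge_free_state(params, eq$ss, hold_mV, step_ms)
  }
  i_hold <- model_derivatives(params, base, hold_mV)$aux[["ICaL_pApF"]]
  cai0 <- base[["ca_i"]]
  steps <- vector("list", length(v_tests))
  traces <- vector("list", length(v_tests))
  for (k in seq_along(v_tests)) {
    v <- v_tests[k]
    tr <- integrate_model(params, base,
                          v_command(c(0, step_ms), c(v, hold_mV)),
                          step_ms + tail_ms, dt_out = dt_out)
    in_step <- tr$t_ms <= step_ms
    i_net <- tr$ICaL_pApF[in_step] - i_hold
    ipk <- which.max(abs(i_net))
    peak <- i_net[ipk]
    peak_cai <- max(tr$ca_i)
    g <- ec_gain(peak_cai, cai0, peak)
    steps[[k]] <- data.frame(v_test = v, peak_density = peak,
                             dca_amplitude = peak_cai - cai0,
                             cai0 = cai0, gain = g)
    traces[[k]] <- list(current = new_trace(i_net, dt_out, units = "pA/pF"),
                        ca = new_trace(tr$ca_i, dt_out, units = "mM"))
  }
  structure(list(steps = do.call(rbind, steps), traces = traces,
                 meta = list(protocol = "gain", hold_mV = hold_mV,
                             step_ms = step_ms, pre_ms = pre_ms,
                             variant = params$variant,
                             hold_converged = eq$ss$converged,
                             hold_periodic = eq$ss$periodic_discharges)),
            class = "ca_protocol")
}

discharge_free_state <- function(params, ss, hold_mV, step_ms,
                                 guard_ms = 500) {
  tr <- integrate_model(params, ss$state, v_const(hold_mV),
                        30000, dt_out = 2)
  ev <- detect_discharges(tr$t_ms, tr$Jrel)
  if (length(ev) < 2)
    return(attr(tr, "final_state"))
  period <- median(diff(ev))
  if (period < 2 * guard_ms + step_ms)
    stop(sprintf(paste0("no discharge-free window at the hold: spontaneous",
                        " discharges recur every ~%.0f ms"), period),
         call. = FALSE)
  t_base <- ev[1] + guard_ms
  row <- which.min(abs(tr$t_ms - t_base))
  st <- as.numeric(tr[row, .state_names])
  setNames(st, .state_names)
}

#' Excitation-contraction coupling gain from recorded quantities
#'
#' The gain statistic: the calcium-release amplitude ratio divided by the
#' peak trigger current magnitude, `(ca_peak / ca0) / |ical_max|`.  Used
#' both for model traces (peak over pre-step \[Ca2+\]i, pA/pF) and for
#' experimental records (peak F/F0 over baseline vs current density).
#'
#' @param ca_peak Peak calcium signal during the step.
#' @param ca0 Pre-step (baseline) calcium signal, > 0.
#' @param ical_max Peak L-type current density (pA/pF); sign ignored.
#' @return The gain (1/(pA/pF)); `NA` if `ical_max` is zero.
#' @export
#' @examples
#' ec_gain(2, 1, -4)  # 0.5
ec_gain <- function(ca_peak, ca0, ical_max) {
  stopifnot(ca0 > 0)
  ifelse(abs(ical_max) > 0, (ca_peak / ca0) / abs(ical_max), NA_real_)
}

#' Caffeine-evoked SR calcium release (SR load estimate)
#'
#' Emulates a rapid 10 mM caffeine application by clamping the RyR2 open
#' fraction to 1, discharging the SR.  The SR load readout is the peak
#' cytosolic Ca2+ relative to the pre-dump baseline (F/F0 semantics).  In
#' `permeabilized` mode the sarcolemmal pathways are removed and the
#' cytosol exchanges with a clamped bath, so the baseline is identical
#' across parameter variants; in `intact` mode the cell is held at
#' -80 mV and baselines may differ between variants.
#'
#' @param params A `ca_params` object.
#' @param mode `"permeabilized"` or `"intact"`.
#' @param state0 Optional starting state (defaults to the steady state of
#'   the chosen mode).
#' @param duration Dump duration (ms).
#' @param dt_out Output sampling (ms).
#' @return A list: `sr_load` (peak/baseline), `baseline` and `peak`
#'   cytosolic free Ca2+ (mM), `t_depleted_ms` (time at which jSR free
#'   Ca2+ fell below 5% of its pre-dump value), `released_pmol` (net SR
#'   Ca2+ content released), and the trajectory.
#' @export
run_caffeine_dump <- function(params,
                              mode = c("permeabilized", "intact"),
                              state0 = NULL, duration = 2000, dt_out = 0.5) {
  mode <- match.arg(mode)
  validate_params(params)
  p <- params
  if (mode == "permeabilized") {
    p$perm <- 1; p$g_cal <- 0; p$g_ncx <- 0; p$g_cab <- 0
  }
  if (is.null(state0)) {
    state0 <- equilibrated_state(p, -80, 300000)$state
  }
  sr_total0 <- sr_content(p, state0)
  jsr0 <- state0[["ca_jsr"]]
  p$caffeine <- 1
  tr <- integrate_model(p, state0, v_const(-80), duration, dt_out = dt_out)
  baseline <- tr$ca_i[1]
  peak <- max(tr$ca_i)
  idx <- which(tr$ca_jsr < 0.05 * jsr0)
  sr_min <- min(vapply(seq_len(nrow(tr)), function(i)
    sr_content(p, setNames(as.numeric(tr[i, .state_names]), .state_names)),
    numeric(1)))
  list(sr_load = peak / baseline, baseline = baseline, peak = peak,
       t_depleted_ms = if (length(idx)) tr$t_ms[idx[1]] else NA_real_,
       released_pmol = sr_total0 - sr_min,
       sr_content_pre_pmol = sr_total0,
       mode = mode, trajectory = tr)
}

# total SR Ca content, free + calsequestrin bound (pmol)
sr_content <- function(params, state) {
  ca_j <- state[["ca_jsr"]]
  params$vol_nsr * state[["ca_nsr"]] +
    params$vol_jsr * (ca_j + params$csq_total * ca_j / (params$kd_csq + ca_j))
}

#' Paced train of depolarizing steps
#'
#' Applies `n_beats` depolarizing steps (default 0 mV for 100 ms) at a
#' fixed frequency from a -80 mV hold, extracts per-beat Ca2+ transient
#' features, and flags spontaneous release events occurring during the
#' elicited transient (early after-transient analogue) or between beats
#' (delayed after-transient analogue).
#'
#' @param params A `ca_params` object.
#' @param freq_hz Pacing frequency (Hz), > 0.
#' @param n_beats Number of beats (0 allowed: returns an empty result).
#' @param step_mV Step potential (mV).
#' @param step_ms Step duration (ms).
#' @param hold_mV Holding potential (mV).
#' @param pre_ms Pre-equilibration at the hold (ms).
#' @param pre_beats Unrecorded conditioning beats before the analysed
#'   train, mirroring pacing to steady state before recording.
#' @param dt_out Output sampling (ms).
#' @return A list with `trajectory`, `beats` (per-beat features:
#'   amplitude in mM, time_to_peak and tau_relax in ms) and `events`
#'   (spontaneous release events with type `early` or `delayed`).
#' @export
run_pacing <- function(params, freq_hz, n_beats, step_mV = 0, step_ms = 100,
                       hold_mV = -80, pre_ms = 60000, pre_beats = 20,
                       dt_out = 0.5) {
  validate_params(params)
  stopifnot(freq_hz > 0, n_beats >= 0)
  if (n_beats == 0) {
    return(list(trajectory = NULL,
                beats = data.frame(beat = integer(0), amplitude = numeric(0),
                                   time_to_peak = numeric(0),
                                   tau_relax = numeric(0)),
                events = data.frame(t_ms = numeric(0),
                                    type = character(0))))
  }
  period <- 1000 / freq_hz
  if (step_ms >= period) stop("step duration must be shorter than the period",
                              call. = FALSE)
  state <- equilibrated_state(params, hold_mV, pre_ms)$state
  if (pre_beats > 0) {
    pre_on <- (seq_len(pre_beats) - 1) * period
    times <- c(0, as.vector(rbind(pre_on, pre_on + step_ms))[-1])
    values <- as.vector(rbind(rep(step_mV, pre_beats),
                              rep(hold_mV, pre_beats)))
    pre_tr <- integrate_model(params, state, v_command(times, values),
                              pre_beats * period, dt_out = 2)
    state <- attr(pre_tr, "final_state")
  }
  onsets <- (seq_len(n_beats) - 1) * period
  times <- c(0, as.vector(rbind(onsets, onsets + step_ms))[-1])
  values <- c(as.vector(rbind(rep(step_mV, n_beats), rep(hold_mV, n_beats))))
  vc <- v_command(times, values)
  tr <- integrate_model(params, state, vc, n_beats * period, dt_out = dt_out)

  beats <- lapply(seq_len(n_beats), function(k) {
    w <- tr$t_ms >= onsets[k] & tr$t_ms < onsets[k] + period
    ca <- tr$ca_i[w]
    ft <- tryCatch(
      transient_features(new_trace(ca, dt_out, units = "mM"),
                         smooth_window = 1),
      error = function(e) NULL)
    if (is.null(ft))
      return(data.frame(beat = k, amplitude = NA_real_,
                        time_to_peak = NA_real_, tau_relax = NA_real_))
    data.frame(beat = k, amplitude = ft$amplitude,
               time_to_peak = ft$time_to_peak, tau_relax = ft$tau_relax)
  })

  ev <- detect_discharges(tr$t_ms, tr$Jrel)
  type <- character(0); t_ev <- numeric(0)
  for (t0 in ev) {
    k <- findInterval(t0, onsets)
    rel <- t0 - onsets[max(k, 1)]
    if (k >= 1 && rel <= step_ms + 20) next  # the elicited release itself
    t_ev <- c(t_ev, t0)
    type <- c(type, if (k >= 1 && rel <= 500) "early" else "delayed")
  }
  list(trajectory = tr, beats = do.call(rbind, beats),
       events = data.frame(t_ms = t_ev, type = type))
}

#' @export
print.ca_protocol <- function(x, ...) {
  cat("<ca_protocol>", x$meta$protocol, "| variant:", x$meta$variant, "\n")
  print(x$steps, digits = 4)
  invisible(x)
}
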