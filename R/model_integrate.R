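#' Piecewise-constant voltage-clamp commands
#'
#' A voltage command is a step function V(t): `values[i]` applies on
#' `[times[i], times[i+1])` and the last value extends to the end of the
#' simulation.  `v_const()` and `v_step()` build the two commands used by
#' the clamp protocols.
#'
#' @param times Numeric vector of segment onset times (ms), starting at 0,
#'   strictly increasing.
#' @param values Voltage (mV) per segment; same length as `times`.
#' @return An object of class `v_command`.
#' @export
#' @examples
#' v_step(-80, 0, 100, 500)  # hold -80, step to 0 mV from t=100 to t=500
v_command <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1,
            times[1] == 0, !is.unsorted(times, strictly = TRUE))
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "v_command")
}

#' @rdname v_command
#' @param v,hold,test Voltages (mV).
#' @param t_on,t_off Step onset/offset times (ms).
#' @export
v_const <- function(v) v_command(0, v)

#' @rdname v_command
#' @export
v_step <- function(hold, test, t_on, t_off) {
  if (t_on <= 0) return(v_command(c(0, t_off), c(test, hold)))
  v_command(c(0, t_on, t_off), c(hold, test, hold))
}

v_at <- function(vc, t) {
  vc$values[findInterval(t, vc$times, left.open = FALSE)]
}

#' Evaluate the model right-hand side at a state
#'
#' Returns the state derivative and the instantaneous fluxes (L-type
#' current density, release, uptake, NCX, net sarcolemmal molar flux) at a
#' given state and clamp voltage.  Used for fixed-point and
#' flux-bookkeeping diagnostics.
#'
#' @param params A `ca_params` object.
#' @param state Named state vector (see [rest_state()] for the layout).
#' @param v Clamp voltage (mV).
#' @return A list with `dstate` (named derivative vector) and `aux`
#'   (named flux vector).
#' @export
model_derivatives <- function(params, state, v) {
  validate_params(params)
  out <- .ca_rhs_cpp(as.numeric(state[.state_names]), params_vector(params), v)
  list(dstate = setNames(out$dy, .state_names), aux = out$aux)
}

#' Integrate the calcium-cycling model under a voltage command
#'
#' Adaptive stiff integration (deSolve, `lsoda`) of the voltage-clamped
#' model, split at the discontinuities of the piecewise-constant command.
#' Default tolerances are `rtol = 1e-8`, `atol = 1e-10`.
#'
#' @param params A `ca_params` object.
#' @param state0 Initial state (named vector as from [rest_state()]).
#' @param v_command A `v_command` object, or a single voltage (mV).
#' @param duration Total duration (ms), > 0.
#' @param dt_out Output sampling interval (ms); default 0.1.
#' @param rtol,atol Solver tolerances.
#' @return A `ca_trajectory`: a data frame with time, voltage, all state
#'   variables and flux columns (`ICaL_pApF`, `Jrel`, `Jserca`, `Jncx`,
#'   ...), with the final state in `attr(, "final_state")`.
#' @export
#' @examples
#' p <- make_control_params()
#' tr <- integrate_model(p, rest_state(p), v_step(-80, 0, 10, 60), 100)
#' min(tr$ICaL_pApF)  # peak inward L-type current density
integrate_model <- function(params, state0, v_command, duration,
                            dt_out = 0.1, rtol = 1e-8, atol = 1e-10) {
  validate_params(params)
  if (is.numeric(v_command) && length(v_command) == 1)
    v_command <- v_const(v_command)
  stopifnot(inherits(v_command, "v_command"), duration > 0)

  y <- as.numeric(state0[.state_names])
  names(y) <- .state_names
  .ca_set_params(params_vector(params))
  func <- function(t, y, parms) {
    out <- .ca_rhs_fast(y, parms)
    list(out[seq_along(.state_names)],
         out[length(.state_names) + seq_along(.aux_names)])
  }

  breaks <- unique(c(0, v_command$times[v_command$times > 0 &
                                        v_command$times < duration], duration))
  rows <- vector("list", length(breaks) - 1)
  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    v <- v_at(v_command, t0)
    times <- seq(t0, t1, by = dt_out)
    if (tail(times, 1) < t1) times <- c(times, t1)
    sol <- deSolve::lsoda(y, times, func, parms = v, rtol = rtol, atol = atol,
                          maxsteps = 50000)
    istate <- attr(sol, "istate")[1]
    if (is.null(istate) || istate != 2)
      stop(sprintf("integration failed in segment [%g, %g] ms (istate %s)",
                   t0, t1, istate), call. = FALSE)
    y <- sol[nrow(sol), 1 + seq_along(.state_names)]
    names(y) <- .state_names
    check_state_physical(y, t1)
    m <- as.data.frame(unclass(sol)[, , drop = FALSE])
    names(m) <- c("t_ms", .state_names, .aux_names)
    m$V_mV <- v
    if (k > 1) m <- m[-1, , drop = FALSE]  # segment boundary row kept once
    rows[[k]] <- m
  }
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  traj <- traj[, c("t_ms", "V_mV", .state_names, .aux_names)]
  structure(traj, class = c("ca_trajectory", "data.frame"),
            final_state = y, variant = params$variant)
}

check_state_physical <- function(y, t) {
  gates <- y[c("d", "f", "fca", "ryr_r", "ryr_o", "ryr_i")]
  if (any(gates < -1e-6 | gates > 1 + 1e-6)) {
    bad <- names(gates)[which(gates < -1e-6 | gates > 1 + 1e-6)[1]]
    stop(sprintf("state `%s` left [0, 1] at t = %g ms", bad, t),
         call. = FALSE)
  }
  occ <- sum(y[c("ryr_r", "ryr_o", "ryr_i")])
  if (occ > 1 + 1e-6)
    stop(sprintf("RyR occupancies exceed 1 at t = %g ms", t), call. = FALSE)
  cas <- y[c("ca_cleft", "ca_sub", "ca_i", "ca_nsr", "ca_jsr")]
  if (any(cas < -1e-9)) {
    bad <- names(cas)[which(cas < -1e-9)[1]]
    stop(sprintf("state `%s` became negative at t = %g ms", bad, t),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Fixed-step explicit-Euler integration (solver oracle)
#'
#' Integrates the same right-hand side with a plain forward-Euler scheme
#' at a caller-chosen fixed step.  At very small steps (`dt = 1e-4` ms)
#' this serves as a brute-force reference for the adaptive solver.
#'
#' @inheritParams integrate_model
#' @param dt Fixed Euler step (ms).
#' @return A data frame with the same columns as [integrate_model()].
#' @export
integrate_model_euler <- function(params, state0, v_command, duration,
                                  dt = 1e-4, dt_out = 0.1) {
  validate_params(params)
  if (is.numeric(v_command) && length(v_command) == 1)
    v_command <- v_const(v_command)
  m <- .ca_euler_cpp(as.numeric(state0[.state_names]),
                     params_vector(params),
                     v_command$times, v_command$values, duration, dt, dt_out)
  as.data.frame(m)
}

#' Total calcium content of the cell (free + buffered)
#'
#' Volume-weighted total Ca2+ (pmol) over all five compartments,
#' including rapid-buffer-bound Ca2+ (cytosolic, submembrane, cleft and
#' calsequestrin-bound jSR pools).  With sarcolemmal fluxes disabled this
#' quantity is conserved by the dynamics.
#'
#' @param params A `ca_params` object.
#' @param state Named state vector.
#' @return Total Ca2+ in pmol.
#' @export
total_calcium <- function(params, state) {
  bnd <- function(ca, btot, kd) btot * ca / (kd + ca)
  p <- params
  ca_c <- state[["ca_cleft"]]; ca_sl <- state[["ca_sub"]]
  ca_i <- state[["ca_i"]]; ca_n <- state[["ca_nsr"]]; ca_j <- state[["ca_jsr"]]
  p$vol_cleft * (ca_c + bnd(ca_c, p$buf_cleft, p$kd_cleft)) +
    p$vol_sub  * (ca_sl + bnd(ca_sl, p$buf_sub, p$kd_sub)) +
    p$vol_cyto * (ca_i + bnd(ca_i, p$buf_cyto1, p$kd_cyto1) +
                         bnd(ca_i, p$buf_cyto2, p$kd_cyto2)) +
    p$vol_nsr  * ca_n +
    p$vol_jsr  * (ca_j + bnd(ca_j, p$csq_total, p$kd_csq))
}

#' Write a trajectory to CSV
#'
#' Writes the standard trajectory columns (`t_ms`, `V_mV`, `ICaL_pApF`,
#' `Cai_mM`, `CaSR_mM`, `Jrel`, `Jserca`, `Jncx`) to a CSV file.
#'
#' @param traj A `ca_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- data.frame(t_ms = traj$t_ms, V_mV = traj$V_mV,
                    ICaL_pApF = traj$ICaL_pApF, Cai_mM = traj$ca_i,
                    CaSR_mM = traj$ca_nsr, Jrel = traj$Jrel,
                    Jserca = traj$Jserca, Jncx = traj$Jncx)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
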