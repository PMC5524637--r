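# Feature extraction and calibration operators for 1-D signals:
# calcium transients, step-evoked currents, ratiometric records,
# saturation-binding curves and ECG intervals.

#' Uniformly sampled 1-D trace
#'
#' @param samples Numeric samples.
#' @param dt_ms Sampling interval (ms), > 0.
#' @param units Unit tag (informational).
#' @param baseline_n Number of leading samples forming the declared
#'   pre-stimulus baseline window (optional).
#' @return A `ca_trace` object.
#' @export
new_trace <- function(samples, dt_ms, units = "", baseline_n = NULL) {
  stopifnot(is.numeric(samples), length(samples) >= 2, dt_ms > 0)
  structure(list(samples = as.numeric(samples), dt_ms = dt_ms,
                 units = units, baseline_n = baseline_n),
            class = "ca_trace")
}

trace_time <- function(trace) (seq_along(trace$samples) - 1) * trace$dt_ms

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  xp <- c(rep(x[1], w), x, rep(x[n], w))
  f <- stats::filter(xp, rep(1 / w, w), sides = 2)
  as.numeric(f[(w + 1):(w + n)])
}

# linear interpolation of the first time x crosses `level` within idx range
cross_time <- function(t, x, level, from, to, rising) {
  idx <- from:to
  if (rising) hit <- which(x[idx] >= level) else hit <- which(x[idx] <= level)
  if (!length(hit)) return(NA_real_)
  i <- idx[hit[1]]
  if (i == idx[1]) return(t[i])
  x0 <- x[i - 1]; x1 <- x[i]
  if (x1 == x0) return(t[i])
  t[i - 1] + (level - x0) / (x1 - x0) * (t[i] - t[i - 1])
}

#' Calcium-transient features: rise time, amplitude, decay, durations
#'
#' Extracts the standard single-transient descriptors: `time_to_peak`
#' (minimum-to-maximum rise time), `amplitude` (peak minus baseline),
#' `tau_relax` (single-exponential time constant of the decay fitted from
#' the peak to 90% recovery), and the transient durations `cad30`,
#' `cad50`, `cad70` - each measured from the time the upstroke crosses
#' 50% of maximum to the time the signal has recovered by 30, 50 or 70%
#' of the amplitude toward baseline.
#'
#' @param trace A `ca_trace` holding one transient (rise then decay).
#' @param smooth_window Moving-average window (samples) applied before
#'   landmark detection; 1 disables smoothing.
#' @param baseline Baseline level; defaults to the mean of the declared
#'   baseline window if the trace has one, otherwise the pre-peak
#'   minimum.
#' @return A list of class `ca_transient_features`.
#' @export
#' @examples
#' tri <- new_trace(c(seq(0, 1, length.out = 101),
#'                    seq(1, 0, length.out = 101)[-1]), 1)
#' f <- transient_features(tri, smooth_window = 1)
#' f$cad50  # 100 ms
transient_features <- function(trace, smooth_window = 5, baseline = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  x <- moving_average(trace$samples, smooth_window)
  t <- trace_time(trace)
  n <- length(x)

  sigma <- sd(diff(trace$samples)) / sqrt(2)
  if ((max(x) - min(x)) < max(6 * sigma / sqrt(max(smooth_window, 1)), 1e-12))
    stop("no transient detected: trace is flat relative to its noise",
         call. = FALSE)

  ipk <- which.max(x)
  imin <- which.min(x[1:ipk])
  if (is.null(baseline)) {
    baseline <- if (!is.null(trace$baseline_n))
      mean(x[seq_len(trace$baseline_n)]) else x[imin]
  }
  peak <- x[ipk]
  amp <- peak - baseline

  time_to_peak <- t[ipk] - t[imin]
  t_up50 <- cross_time(t, x, baseline + 0.5 * amp, imin, ipk, rising = TRUE)
  cad <- function(frac) {
    lv <- peak - frac * amp
    tc <- cross_time(t, x, lv, ipk, n, rising = FALSE)
    if (is.na(tc) || is.na(t_up50)) NA_real_ else tc - t_up50
  }

  # decay fit: peak to 90% recovery
  lv90 <- peak - 0.9 * amp
  t90 <- cross_time(t, x, lv90, ipk, n, rising = FALSE)
  iend <- if (is.na(t90)) n else max(which(t <= t90))
  tau_relax <- fit_exp_decay(t[ipk:iend] - t[ipk], x[ipk:iend], baseline)

  structure(list(time_to_peak = time_to_peak, amplitude = amp,
                 tau_relax = tau_relax,
                 cad30 = cad(0.30), cad50 = cad(0.50), cad70 = cad(0.70),
                 peak = peak, baseline = baseline),
            class = "ca_transient_features")
}

# single-exponential decay fit y ~ A exp(-t/tau) + C, log-linear init
fit_exp_decay <- function(t, y, floor_guess) {
  if (length(t) < 4) return(NA_real_)
  c0 <- min(min(y), floor_guess)
  z <- y - c0 + 1e-12 * max(abs(y), 1)
  ok <- z > 0
  if (sum(ok) < 3) return(NA_real_)
  lf <- lm(log(z[ok]) ~ t[ok])
  tau0 <- -1 / unname(coef(lf)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 2
  # start slightly off the log-linear solution: an exact-fit start makes
  # the nls gradient singular on noiseless data
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau) + C,
                      start = list(A = (y[1] - c0) * 1.02, tau = tau0 * 1.05,
                                   C = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- (y[1] - c0) * exp(-t / tau0) + c0
    ok <- sqrt(mean((y - pred)^2)) < 0.02 * diff(range(y))
    return(if (ok && is.finite(tau0) && tau0 > 0) tau0 else NA_real_)
  }
  tau <- coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0) NA_real_ else tau
}

#' Inactivation time constant of a step-evoked inward current
#'
#' Fits a single exponential `I(t) = A exp(-t/tau) + C` from the current
#' peak to the end of the step and returns `tau` (ms).
#'
#' @param current A `ca_trace` of current density during the step.
#' @return Inactivation time constant (ms).
#' @export
#' @examples
#' tr <- new_trace(-10 * exp(-(0:399) / 15), 1)
#' fit_inactivation_tau(tr)  # 15
fit_inactivation_tau <- function(current) {
  stopifnot(inherits(current, "ca_trace"))
  i <- current$samples
  t <- trace_time(current)
  ipk <- which.max(abs(i))
  if (ipk >= length(i) - 3)
    stop("current does not decay after its peak", call. = FALSE)
  seg_t <- t[ipk:length(i)] - t[ipk]
  seg_i <- i[ipk:length(i)]
  decay <- abs(seg_i[1]) - abs(seg_i[length(seg_i)])
  noise <- sd(diff(i)) / sqrt(2)
  if (!is.finite(decay) || decay < max(4 * noise, 0.05 * abs(seg_i[1])))
    stop("no decaying phase: inactivation fit failed", call. = FALSE)
  c0 <- seg_i[length(seg_i)]
  z <- abs(seg_i - c0) + 1e-12
  lf <- lm(log(z) ~ seg_t)
  tau0 <- -1 / unname(coef(lf)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(seg_t) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(seg_i ~ A * exp(-seg_t / tau) + C,
                      start = list(A = (seg_i[1] - c0) * 1.02,
                                   tau = tau0 * 1.05, C = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("inactivation fit did not converge", call. = FALSE)
  tau <- coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0)
    stop("inactivation fit returned a non-positive time constant",
         call. = FALSE)
  tau
}

#' Charge carried by a current trace
#'
#' Baseline-subtracted trapezoidal time integral of a current-density
#' trace, in pC/pF (pA/pF times ms divided by 1000).
#'
#' @param current A `ca_trace` (pA/pF).
#' @param baseline Baseline current density subtracted before
#'   integration (default 0).
#' @return Charge (pC/pF), signed.
#' @export
#' @examples
#' integrate_charge(new_trace(rep(-5, 101), 1))  # -0.5 pC/pF
integrate_charge <- function(current, baseline = 0) {
  stopifnot(inherits(current, "ca_trace"))
  i <- current$samples - baseline
  n <- length(i)
  sum((i[-1] + i[-n]) / 2) * current$dt_ms / 1000
}

#' Ratiometric calcium calibration
#'
#' Converts a two-wavelength fluorescence ratio to free calcium with the
#' standard ratiometric equation
#' `[Ca] = Kd * beta * (R - Rmin) / (Rmax - R)` (Kd = 245 nM for the
#' indicator used here).
#'
#' @param r Measured ratio(s).
#' @param r_min,r_max Calibration limits (`r_min < r_max`).
#' @param beta Ratio of the free/bound fluorescence at the denominator
#'   wavelength, > 0.
#' @param kd_nm Indicator dissociation constant (nM).
#' @return Free calcium (nM).  Ratios at or below `r_min` return 0 and
#'   are flagged in the `clipped` attribute; ratios at or above `r_max`
#'   are an error.
#' @export
#' @examples
#' ratiometric_calcium(1.3, 0.3, 3.3, beta = 2)  # 245 nM
ratiometric_calcium <- function(r, r_min, r_max, beta, kd_nm = 245) {
  stopifnot(r_min < r_max, beta > 0, kd_nm > 0)
  if (any(r >= r_max))
    stop("ratio at or above r_max: outside the calibration range",
         call. = FALSE)
  clipped <- r <= r_min
  ca <- kd_nm * beta * (r - r_min) / (r_max - r)
  ca[clipped] <- 0
  attr(ca, "clipped") <- clipped
  ca
}

#' Detect calcium sparks on a line-scan image
#'
#' Normalizes the image to F/F0 using a declared pre-event baseline
#' window, thresholds at baseline + `threshold_sd` baseline standard
#' deviations, and keeps 8-connected regions of at least `min_area`
#' pixels as spark events.  Frequency is reported per 100 um per second.
#'
#' @param img Matrix, rows = time, columns = position.
#' @param dx_um Pixel size along the scanned line (um).
#' @param dt_ms Line period (ms).
#' @param baseline_rows Indices of the pre-event baseline rows (required).
#' @param threshold_sd Detection threshold in baseline SD units.
#' @param min_area Minimum event area (pixels).
#' @return A `ca_spark_summary`: `events` (t_ms, x_um, amplitude F/F0),
#'   `n_events`, `frequency_per_100um_s`, `mean_amplitude`.
#' @export
detect_sparks <- function(img, dx_um, dt_ms, baseline_rows = NULL,
                          threshold_sd = 3.8, min_area = 4) {
  stopifnot(is.matrix(img), dx_um > 0, dt_ms > 0)
  if (is.null(baseline_rows))
    stop("a pre-event baseline window (`baseline_rows`) is required",
         call. = FALSE)
  f0 <- colMeans(img[baseline_rows, , drop = FALSE])
  if (any(f0 <= 0)) stop("non-positive baseline fluorescence", call. = FALSE)
  fn <- sweep(img, 2, f0, "/")
  base <- fn[baseline_rows, , drop = FALSE]
  mu <- mean(base); s <- sd(base)
  thr <- mu + threshold_sd * s
  bw <- fn > thr
  bw[baseline_rows, ] <- FALSE
  lab <- label_components(bw)
  n_lab <- max(lab)
  events <- NULL
  if (n_lab > 0) {
    areas <- tabulate(lab[lab > 0], nbins = n_lab)
    keep <- which(areas >= min_area)
    if (length(keep)) {
      events <- do.call(rbind, lapply(keep, function(id) {
        px <- which(lab == id, arr.ind = TRUE)
        amp_i <- which.max(fn[lab == id])
        data.frame(t_ms = (mean(px[, 1]) - 1) * dt_ms,
                   x_um = (mean(px[, 2]) - 1) * dx_um,
                   amplitude = max(fn[lab == id]))
      }))
    }
  }
  if (is.null(events))
    events <- data.frame(t_ms = numeric(0), x_um = numeric(0),
                         amplitude = numeric(0))
  total_s <- nrow(img) * dt_ms / 1000
  length_um <- ncol(img) * dx_um
  freq <- nrow(events) / (total_s * (length_um / 100))
  structure(list(events = events, n_events = nrow(events),
                 frequency_per_100um_s = freq,
                 mean_amplitude = if (nrow(events)) mean(events$amplitude)
                                  else NA_real_),
            class = "ca_spark_summary")
}

#' SR calcium leak/load ratio
#'
#' @param leak Leak measure (same units as `load`).
#' @param load SR load measure, > 0.
#' @return `leak / load`.
#' @export
leak_load_ratio <- function(leak, load) {
  if (any(load <= 0)) stop("`load` must be > 0", call. = FALSE)
  leak / load
}

#' Hill fit of a saturation-binding curve
#'
#' Least-squares fit of `bound = Bmax * ca^n / (EC50^n + ca^n)` to a
#' calcium-dependence curve (for example ryanodine binding versus free
#' calcium), returning the maximal binding, the half-activation
#' concentration and the Hill coefficient.
#'
#' @param free_ca Free calcium concentrations (nM), at least 4 points.
#' @param bound Bound signal at each concentration.
#' @return A `ca_binding_fit`: `b_max`, `ec50`, `hill_n`, `residuals`,
#'   `fitted`.
#' @export
#' @examples
#' ca <- 10^seq(2, 5, length.out = 8)
#' b <- 1 * ca^2 / (300^2 + ca^2)
#' fit_hill_binding(ca, b)$ec50  # 300
fit_hill_binding <- function(free_ca, bound) {
  stopifnot(length(free_ca) == length(bound))
  ok <- complete.cases(free_ca, bound)
  free_ca <- free_ca[ok]; bound <- bound[ok]
  if (length(free_ca) < 4)
    stop("at least 4 concentration points are required", call. = FALSE)
  if (any(free_ca <= 0)) stop("free calcium must be positive", call. = FALSE)

  bmax0 <- max(bound) * 1.02
  th <- pmin(pmax(bound / bmax0, 1e-4), 1 - 1e-4)
  lf <- lm(log(th / (1 - th)) ~ log(free_ca))
  n0 <- max(unname(coef(lf)[2]), 0.2)
  ec0 <- exp(-unname(coef(lf)[1] / coef(lf)[2]))
  if (!is.finite(ec0) || ec0 <= 0) ec0 <- median(free_ca)

  fit <- tryCatch(
    minpack.lm::nlsLM(bound ~ bmax * free_ca^n / (ec50^n + free_ca^n),
                      start = list(bmax = bmax0, ec50 = ec0, n = n0),
                      lower = c(1e-12, 1e-12, 0.05),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res <- bound - bmax0 * free_ca^n0 / (ec0^n0 + free_ca^n0)
    stop("Hill fit did not converge; residual SD at the initial guess: ",
         signif(sd(res), 3), call. = FALSE)
  }
  co <- coef(fit)
  structure(list(b_max = co[["bmax"]], ec50 = co[["ec50"]],
                 hill_n = co[["n"]],
                 residuals = as.numeric(residuals(fit)),
                 fitted = as.numeric(predict(fit))),
            class = "ca_binding_fit")
}

#' Rate-corrected QT interval (Mitchell formula for mice)
#'
#' `QTc = QT / sqrt(RR / 100)` with both intervals in ms.
#'
#' @param qt_ms QT interval (ms), > 0.
#' @param rr_ms RR interval (ms), > 0.
#' @return QTc (ms).
#' @export
#' @examples
#' qtc_mitchell(50, 100)  # 50
#' qtc_mitchell(48, 144)  # 40
qtc_mitchell <- function(qt_ms, rr_ms) {
  if (any(qt_ms <= 0) || any(rr_ms <= 0))
    stop("QT and RR must be positive", call. = FALSE)
  qt_ms / sqrt(rr_ms / 100)
}

#' Count events inside a half-open observation window
#'
#' Number of event times falling in `[0, window_ms)`; events at exactly
#' the window edge are excluded.
#'
#' @param event_times Event times (ms).
#' @param window_ms Window length (ms), > 0.
#' @return Integer count.
#' @export
count_events_per_window <- function(event_times, window_ms) {
  stopifnot(window_ms > 0)
  sum(event_times >= 0 & event_times < window_ms)
}
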