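# Seeded generators for every input the quantification operators
# consume, with ground truth recorded, so the full pipeline is testable
# without external data.

#' Specification for a synthetic dataset
#'
#' @param kind One of `"linescan"`, `"transient"`, `"ratiometric"`,
#'   `"binding"`, `"dyad_masks"`, `"tt_network"`, `"cluster_pair"`,
#'   `"event_times"`, `"qtrr_table"`.
#' @param seed Integer master seed; a fixed seed makes the output
#'   reproducible bit for bit.
#' @param replicate Replicate index (distinct seeded streams per
#'   replicate).
#' @param ... Kind-specific parameters (see [generate()]).
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(kind, seed, replicate = 1, ...) {
  kinds <- c("linescan", "transient", "ratiometric", "binding",
             "dyad_masks", "tt_network", "cluster_pair", "event_times",
             "qtrr_table")
  if (!kind %in% kinds)
    stop("unknown generator kind: ", kind, call. = FALSE)
  structure(list(kind = kind, seed = as.integer(seed),
                 replicate = as.integer(replicate), params = list(...)),
            class = "generator_spec")
}

# one pseudo-random stream per (seed, kind, replicate)
derive_seed <- function(seed, kind, replicate) {
  h <- sum(utf8ToInt(kind) * seq_along(utf8ToInt(kind)))
  as.integer((as.numeric(seed) * 1000003 + h * 10007 + replicate) %%
               2147483647)
}

with_stream <- function(spec, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(spec$seed, spec$kind, spec$replicate))
  force(expr)
}

#' Generate a synthetic dataset with recorded ground truth
#'
#' Produces, for each `kind`, the in-memory dataset the corresponding
#' analysis operator consumes plus a `truth` record of the generating
#' parameters:
#'
#' * `linescan`: F/F0 line-scan image (`nt` x `nx`) with Gaussian spark
#'   events (`n_sparks`, `amplitude` above baseline 1, `noise_sd`,
#'   `dt_ms`, `dx_um`) and a reserved pre-event baseline window.
#' * `transient`: double-exponential Ca2+ transient (`baseline`,
#'   `amplitude`, `tau_rise`, `tau_decay`, `dt_ms`, `noise_sd`).
#' * `ratiometric`: ratios from true \[Ca2+\] via the calibration
#'   equation (`true_ca_nm`, `r_min`, `r_max`, `beta`, `kd_nm`).
#' * `binding`: Hill saturation curve (`b_max`, `ec50`, `hill_n`,
#'   `n_points`, multiplicative `noise_sd`).
#' * `dyad_masks`: jSR/T-tubule boundary masks - `geometry`
#'   `"parallel"` (gap `gap_px`), `"concentric"` (radii `r_out`,
#'   `r_in`) or `"random"` blobs; `pixel_size_nm`.
#' * `tt_network`: line segments at `angles_deg` (equal counts per
#'   angle) in an `size` x `size` image.
#' * `cluster_pair`: two-channel image pair with Gaussian blobs at
#'   seeded centres, some shifted to overlap.
#' * `event_times`: uniform event times in a window (`n_events`,
#'   `window_ms`).
#' * `qtrr_table`: QT/RR interval table (`n`, `qt_mean`, `qt_sd`,
#'   `rr_mean`, `rr_sd`).
#'
#' @param spec A `generator_spec`.
#' @return A list with `kind`, `data` (kind-specific), and `truth`.
#' @export
#' @examples
#' g <- generate(generator_spec("binding", seed = 1, b_max = 1,
#'                              ec50 = 300, hill_n = 2, noise_sd = 0))
#' fit_hill_binding(g$data$free_ca_nm, g$data$bound)$ec50
generate <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  gen <- switch(spec$kind,
    linescan    = gen_linescan,
    transient   = gen_transient,
    ratiometric = gen_ratiometric,
    binding     = gen_binding,
    dyad_masks  = gen_dyad_masks,
    tt_network  = gen_tt_network,
    cluster_pair = gen_cluster_pair,
    event_times = gen_event_times,
    qtrr_table  = gen_qtrr_table)
  out <- with_stream(spec, gen(spec$params))
  c(list(kind = spec$kind), out)
}

pget <- function(p, name, default) if (is.null(p[[name]])) default else
  p[[name]]

gen_linescan <- function(p) {
  nt <- pget(p, "nt", 512); nx <- pget(p, "nx", 128)
  dt <- pget(p, "dt_ms", 3); dx <- pget(p, "dx_um", 0.2)
  n_sparks <- pget(p, "n_sparks", 10)
  amp <- pget(p, "amplitude", 0.8)        # F/F0 above the baseline of 1
  noise <- pget(p, "noise_sd", 0.05)
  baseline_rows <- seq_len(pget(p, "n_baseline", 50))
  st <- pget(p, "sigma_t_rows", 2.5); sx <- pget(p, "sigma_x_px", 3)
  img <- matrix(1, nt, nx)
  margin_t <- ceiling(4 * st); margin_x <- ceiling(4 * sx)
  t0 <- numeric(0); x0 <- numeric(0)
  if (n_sparks > 0) {
    # rejection-sample centres with a minimum separation
    while (length(t0) < n_sparks) {
      tc <- runif(1, max(baseline_rows) + margin_t, nt - margin_t)
      xc <- runif(1, 1 + margin_x, nx - margin_x)
      if (!length(t0) ||
          all(abs(tc - t0) > 6 * st | abs(xc - x0) > 6 * sx)) {
        t0 <- c(t0, tc); x0 <- c(x0, xc)
      }
    }
    tt <- matrix(seq_len(nt), nt, nx)
    xx <- matrix(seq_len(nx), nt, nx, byrow = TRUE)
    for (k in seq_len(n_sparks)) {
      img <- img + amp * exp(-((tt - t0[k])^2 / (2 * st^2) +
                               (xx - x0[k])^2 / (2 * sx^2)))
    }
  }
  img <- img * (1 + matrix(rnorm(nt * nx, 0, noise), nt, nx))
  list(data = list(img = img, dt_ms = dt, dx_um = dx,
                   baseline_rows = baseline_rows),
       truth = list(n_sparks = n_sparks, amplitude = 1 + amp,
                    t_rows = t0, x_px = x0,
                    frequency_per_100um_s =
                      n_sparks / (nt * dt / 1000 * nx * dx / 100)))
}

gen_transient <- function(p) {
  base <- pget(p, "baseline", 1); amp <- pget(p, "amplitude", 1)
  tr <- pget(p, "tau_rise", 15); td <- pget(p, "tau_decay", 120)
  dt <- pget(p, "dt_ms", 1); dur <- pget(p, "duration_ms", 1000)
  noise <- pget(p, "noise_sd", 0)
  t <- seq(0, dur, by = dt)
  shape <- exp(-t / td) - exp(-t / tr)
  shape <- shape / max(shape)
  x <- base + amp * shape + rnorm(length(t), 0, noise)
  t_peak <- log(td / tr) * tr * td / (td - tr)
  list(data = new_trace(x, dt, units = "F/F0"),
       truth = list(baseline = base, amplitude = amp, tau_rise = tr,
                    tau_decay = td, time_to_peak = t_peak))
}

gen_ratiometric <- function(p) {
  ca <- pget(p, "true_ca_nm", c(50, 100, 200, 400, 800))
  rmin <- pget(p, "r_min", 0.3); rmax <- pget(p, "r_max", 3.3)
  beta <- pget(p, "beta", 2); kd <- pget(p, "kd_nm", 245)
  r <- (rmin * kd * beta + rmax * ca) / (kd * beta + ca)
  list(data = list(r = r, r_min = rmin, r_max = rmax, beta = beta,
                   kd_nm = kd),
       truth = list(true_ca_nm = ca))
}

gen_binding <- function(p) {
  bmax <- pget(p, "b_max", 1); ec50 <- pget(p, "ec50", 300)
  n <- pget(p, "hill_n", 2); npts <- pget(p, "n_points", 8)
  noise <- pget(p, "noise_sd", 0)
  ca <- 10^seq(2, 5, length.out = npts)   # 100 nM .. 100 uM
  bound <- bmax * ca^n / (ec50^n + ca^n)
  bound <- bound * (1 + rnorm(npts, 0, noise))
  list(data = list(free_ca_nm = ca, bound = bound),
       truth = list(b_max = bmax, ec50 = ec50, hill_n = n))
}

gen_dyad_masks <- function(p) {
  geometry <- pget(p, "geometry", "parallel")
  px_nm <- pget(p, "pixel_size_nm", 1)
  size <- pget(p, "size", 64)
  jsr <- matrix(0L, size, size); tt <- matrix(0L, size, size)
  truth <- list(geometry = geometry, pixel_size_nm = px_nm)
  if (geometry == "parallel") {
    gap <- pget(p, "gap_px", 15)
    r0 <- pget(p, "row0", 20)
    cols <- 5:(size - 5)
    jsr[r0, cols] <- 1L
    tt[r0 + gap, cols] <- 1L
    truth$gap_px <- gap
    truth$gap_nm <- gap * px_nm
  } else if (geometry == "concentric") {
    r_out <- pget(p, "r_out", 25); r_in <- pget(p, "r_in", 15)
    ctr <- (size + 1) / 2
    rr <- matrix(seq_len(size), size, size)
    cc <- matrix(seq_len(size), size, size, byrow = TRUE)
    rad <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
    jsr[abs(rad - r_in) < 0.5] <- 1L
    tt[abs(rad - r_out) < 0.5] <- 1L
    truth$r_out <- r_out; truth$r_in <- r_in
    truth$gap_px <- r_out - r_in
  } else if (geometry == "random") {
    n_blobs <- pget(p, "n_blobs", 2)
    blob <- function(m) {
      for (i in seq_len(n_blobs)) {
        r0 <- sample(5:(size - 9), 1); c0 <- sample(5:(size - 9), 1)
        h <- sample(2:5, 1); w <- sample(2:5, 1)
        m[r0:(r0 + h), c0:(c0 + w)] <- 1L
      }
      m
    }
    jsr <- blob(jsr); tt <- blob(tt)
  } else stop("unknown dyad geometry: ", geometry, call. = FALSE)
  list(data = new_mask_pair(jsr, tt, px_nm), truth = truth)
}

gen_tt_network <- function(p) {
  size <- pget(p, "size", 200)
  angles <- pget(p, "angles_deg", c(0, 45))
  n_per <- pget(p, "n_lines_per_angle", 6)
  len <- pget(p, "length_px", 60)
  m <- matrix(0L, size, size)
  placed <- data.frame(angle = numeric(0))
  for (a in angles) {
    th <- a * pi / 180
    for (i in seq_len(n_per)) {
      # line through a random centre; x = col, y = -row (ccw-positive);
      # one pixel per step of the dominant axis, so every line contributes
      # exactly `len` pixels regardless of angle
      ctr <- runif(2, size * 0.2, size * 0.8)
      k <- seq_len(len) - (len + 1) / 2
      if (abs(cos(th)) >= abs(sin(th))) {
        cols <- round(ctr[2]) + k * sign(cos(th))
        rows <- round(round(ctr[1]) - k * sign(cos(th)) * tan(th))
      } else {
        rows <- round(ctr[1]) - k * sign(sin(th))
        cols <- round(round(ctr[2]) + k * sign(sin(th)) / tan(th))
      }
      ok <- rows >= 1 & rows <= size & cols >= 1 & cols <= size
      m[cbind(rows[ok], cols[ok])] <- 1L
      placed <- rbind(placed, data.frame(angle = a))
    }
  }
  list(data = m, truth = list(angles_deg = angles, n_per_angle = n_per,
                              lines = placed))
}

gen_cluster_pair <- function(p) {
  size <- pget(p, "size", 128)
  n_a <- pget(p, "n_a", 4); n_b <- pget(p, "n_b", 4)
  sigma <- pget(p, "sigma_px", 2.5)
  amp <- pget(p, "amplitude", 1)
  overlap_frac <- pget(p, "overlap_frac", 0.5)
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  blob_img <- function(centres) {
    img <- matrix(0, size, size)
    for (i in seq_len(nrow(centres)))
      img <- img + amp * exp(-((rr - centres[i, 1])^2 +
                               (cc - centres[i, 2])^2) / (2 * sigma^2))
    img
  }
  margin <- ceiling(5 * sigma)
  ca <- cbind(runif(n_a, margin, size - margin),
              runif(n_a, margin, size - margin))
  # keep a-centres separated so clusters do not merge
  for (i in seq_len(n_a)) {
    tries <- 0
    while (i > 1 && any(sqrt(rowSums(sweep(ca[seq_len(i - 1), , drop = FALSE],
                                           2, ca[i, ])^2)) < 8 * sigma) &&
           tries < 200) {
      ca[i, ] <- runif(2, margin, size - margin); tries <- tries + 1
    }
  }
  n_ov <- round(overlap_frac * n_b)
  cb <- ca[seq_len(min(n_ov, n_a)), , drop = FALSE] +
    matrix(runif(2 * min(n_ov, n_a), -sigma, sigma), ncol = 2)
  while (nrow(cb) < n_b) {
    cand <- runif(2, margin, size - margin)
    if (all(sqrt(rowSums(sweep(ca, 2, cand)^2)) > 10 * sigma))
      cb <- rbind(cb, cand)
  }
  list(data = list(channel_a = blob_img(ca), channel_b = blob_img(cb)),
       truth = list(centres_a = ca, centres_b = cb,
                    n_overlapping = min(n_ov, n_a)))
}

gen_event_times <- function(p) {
  n <- pget(p, "n_events", 100)
  window <- pget(p, "window_ms", 30 * 60 * 1000)
  t <- sort(runif(n, 0, window))
  list(data = t, truth = list(n_events = n, window_ms = window))
}

gen_qtrr_table <- function(p) {
  n <- pget(p, "n", 20)
  qt <- rnorm(n, pget(p, "qt_mean", 50), pget(p, "qt_sd", 4))
  rr <- rnorm(n, pget(p, "rr_mean", 140), pget(p, "rr_sd", 12))
  list(data = data.frame(qt_ms = qt, rr_ms = rr),
       truth = list(qt_mean = pget(p, "qt_mean", 50),
                    rr_mean = pget(p, "rr_mean", 140)))
}

#' Generate a paired control / knockout two-group study
#'
#' Draws two normal samples whose true difference in means equals the
#' declared effect, emulating a control-versus-knockout comparison for
#' end-to-end testing of the group statistics (including their null
#' calibration at zero effect).
#'
#' @param n_per_group Observations per group, at least 2.
#' @param effect_sd True group difference in units of the common SD.
#' @param mean0 Control mean.
#' @param sd Common SD.
#' @param seed Integer seed.
#' @param replicate Replicate index (independent stream per replicate).
#' @return A list with `control`, `ko` (numeric vectors) and `truth`.
#' @export
generate_two_group_study <- function(n_per_group, effect_sd = 0, mean0 = 1,
                                     sd = 0.2, seed = 1, replicate = 1) {
  if (n_per_group < 2) stop("need at least 2 observations per group",
                            call. = FALSE)
  spec <- structure(list(kind = "two_group", seed = as.integer(seed),
                         replicate = as.integer(replicate)),
                    class = "generator_spec")
  with_stream(spec, {
    control <- rnorm(n_per_group, mean0, sd)
    ko <- rnorm(n_per_group, mean0 + effect_sd * sd, sd)
    list(control = control, ko = ko,
         truth = list(effect_sd = effect_sd, mean0 = mean0, sd = sd))
  })
}
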