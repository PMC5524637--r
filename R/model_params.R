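#' Control parameter set for the voltage-clamped calcium-cycling model
#'
#' Returns the reference ("control") parameter set of the compartmental
#' mouse ventricular calcium-cycling model.  The model is the
#' voltage-clamped Ca2+ subsystem of a whole-myocyte formulation:
#' L-type Ca2+ channels (LTCC) gated by activation, voltage-dependent
#' inactivation and Ca2+-dependent inactivation with a GHK driving force;
#' a four-state RyR2 with luminal (jSR) regulation whose threshold scales
#' with calsequestrin content; SERCA uptake with a thermodynamic reversal
#' term; an RyR2-density-scaled SR leak; NCX extrusion; a background
#' sarcolemmal Ca2+ leak; and five Ca2+ pools (junctional cleft,
#' submembrane space, bulk cytosol, network SR, junctional SR) with
#' rapid-equilibrium buffering.
#'
#' All scale factors (`g_cal`, `k_close_cal`, `g_ryr`, `g_ncx`) equal 1 in
#' the control set, so a variant is expressed as multiplicative departures
#' from control.  Units are mV, ms, mM, pA/pF and pL; inward current is
#' negative.
#'
#' @return An object of class `ca_params`: a named list of parameters with
#'   a `variant` field equal to `"control"`.
#' @seealso [make_pkp2cko_params()], [integrate_model()], [rest_state()]
#' @export
#' @examples
#' p <- make_control_params()
#' p$g_cal
make_control_params <- function() {
  p <- list(
    variant = "control",

    # -- perturbation scales (dimensionless, 1 = control) ----------------
    g_cal       = 1,      # LTCC conductance/density scale
    k_close_cal = 1,      # LTCC voltage-dependent closing-rate scale
    f_junc      = 0.9,    # fraction of LTCC flux delivered to the cleft
    g_ryr       = 1,      # RyR2 release flux scale
    g_ncx       = 1,      # NCX scale

    # -- SR buffering and uptake ----------------------------------------
    csq_total   = 24,      # mM, total calsequestrin in jSR
    csq_ref     = 24,      # mM, reference CSQ for luminal RyR2 coupling
    csq_sens    = 2.5,       # exponent of the CSQ -> RyR2 threshold coupling
    kd_csq      = 0.63,    # mM
    v_serca     = 1.0e-3, # mM/ms (cytosol-referred maximal rate)
    k_serca     = 2.46e-4, # mM, forward half-saturation
    k_serca_sr  = 2.7,     # mM, reverse (luminal) half-saturation
    hill_serca  = 1.787,
    g_leak_sr   = 8.0e-5, # 1/ms, RyR2-density-scaled SR leak
    tau_tr      = 60,      # ms, network-SR -> jSR refill

    # -- geometry --------------------------------------------------------
    vol_cleft = 0.0160,   # pL
    vol_sub   = 0.61,
    vol_cyto  = 21.0,
    vol_nsr   = 0.96,
    vol_jsr   = 0.107,
    cm_pf     = 135,      # pF

    # -- LTCC kinetics ---------------------------------------------------
    p_cal       = 85,      # pA/pF per mM (permeability scale, GHK form)
    act_vhalf   = 0,       # mV
    act_slope   = 5.5,     # mV
    tau_d_base  = 2.0,     # ms
    tau_d_amp   = 1.5,
    tau_d_vmid  = -15,
    tau_d_vwidth = 30,
    f_vhalf     = -27.5,   # mV, voltage-dependent inactivation midpoint
    f_slope     = 6,
    f_pedestal  = 0.06,
    tau_f_base  = 22,      # ms
    tau_f_amp   = 30,
    tau_f_vmid  = -25,
    tau_f_vwidth = 20,
    k_fca       = 1.52e-2,  # mM, Ca-dependent inactivation half-point (cleft)
    tau_fca     = 0.1,      # ms

    # -- RyR2 ------------------------------------------------------------
    ko_ca   = 4,      # 1/(mM^2 ms)
    k_om    = 0.6,    # 1/ms
    ki_ca   = 0.5,     # 1/(mM ms)
    k_im    = 0.005,   # 1/ms
    ec50_sr = 0.45,    # mM, luminal activation midpoint at reference CSQ
    max_sr  = 15,
    min_sr  = 1,
    ks_rel  = 60,      # 1/ms

    # -- NCX and background sarcolemmal leak ------------------------------
    eta_ncx  = 0.35,
    ksat_ncx = 0.1,
    km_na    = 87.5,    # mM
    km_ca    = 1.38,    # mM
    v_ncx    = 3.0,     # pmol/ms scale
    na_i     = 10,      # mM (fixed; Na+ dynamics out of scope)
    na_o     = 140,
    ca_o     = 1.8,
    g_cab    = 1.42e-3, # pA/pF per mV

    # -- cytosolic / membrane buffers (rapid equilibrium) -----------------
    buf_cyto1 = 0.07,    # mM (troponin-like high affinity)
    kd_cyto1  = 6.0e-4,
    buf_cyto2 = 0.1,     # mM (low-affinity pool)
    kd_cyto2  = 1.0e-2,
    buf_sub   = 1.65,    # mM (sarcolemmal sites)
    kd_sub    = 1.3e-2,
    buf_cleft = 0.3,     # mM
    kd_cleft  = 1.3e-2,

    # -- compartment exchange ---------------------------------------------
    d_cleft_sub = 0.3,  # pL/ms
    d_sub_cyto  = 3.72,   # pL/ms

    # -- mode switches -----------------------------------------------------
    caffeine = 0,
    perm     = 0,
    bath_ca  = 1.0e-4,  # mM, bath free Ca in permeabilized mode
    k_bath   = 2.0e-2,  # 1/ms, cytosol-bath exchange in permeabilized mode

    temp = 310          # K
  )
  structure(p, class = "ca_params")
}

#' PKP2-deficient (PKP2-cKO) variant of the model parameters
#'
#' Applies the four molecular changes that characterise the
#' cardiomyocyte-specific PKP2 knockout to a control parameter set:
#' total calsequestrin reduced to 45.3% of control, the LTCC
#' voltage-dependent closing (inactivation) rate scaled to 75%, LTCC
#' current density scaled to 50%, and RyR2 flux scaled to 60%.  A fifth,
#' magnitude-unspecified change - reduced LTCC expression in the
#' T-tubules - is modelled by moving a fraction `junctional_shift` of the
#' LTCC flux from the junctional cleft to the submembrane space.
#'
#' @param control A `ca_params` object, normally [make_control_params()].
#' @param junctional_shift Fraction (in absolute percentage points of
#'   `f_junc`) moved from the cleft to the submembrane sarcolemma.
#'   Must lie in `[0, f_junc)`.  Default 0.1.
#' @return A `ca_params` object with `variant = "pkp2cko"`.
#' @export
#' @examples
#' ko <- make_pkp2cko_params()
#' ko$csq_total / make_control_params()$csq_total  # 0.453
make_pkp2cko_params <- function(control = make_control_params(),
                                junctional_shift = 0.1) {
  validate_params(control)
  if (!is.numeric(junctional_shift) || length(junctional_shift) != 1 ||
      junctional_shift < 0 || junctional_shift >= control$f_junc) {
    stop("`junctional_shift` must lie in [0, f_junc)", call. = FALSE)
  }
  p <- control
  p$variant      <- "pkp2cko"
  p$csq_total    <- control$csq_total * 0.453
  p$k_close_cal  <- control$k_close_cal * 0.75
  p$g_cal        <- control$g_cal * 0.50
  p$g_ryr        <- control$g_ryr * 0.60
  p$f_junc       <- control$f_junc - junctional_shift
  p
}

#' Validate a model parameter set
#'
#' Checks positivity of scales and volumes and the admissible range of
#' `f_junc`.  Called internally by every entry point that consumes
#' parameters.
#'
#' @param params A `ca_params` object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "ca_params")) stop("not a `ca_params` object",
                                           call. = FALSE)
  num <- params[setdiff(names(params), "variant")]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad)) stop("non-numeric parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  pos <- c("g_cal", "k_close_cal", "g_ryr", "csq_total", "v_serca",
           "k_serca", "tau_tr", "vol_cleft", "vol_sub", "vol_cyto",
           "vol_nsr", "vol_jsr", "cm_pf", "temp")
  for (nm in pos) {
    if (params[[nm]] < 0) stop("parameter `", nm, "` must be > 0",
                               call. = FALSE)
  }
  if (params$f_junc < 0 || params$f_junc > 1)
    stop("`f_junc` must lie in [0, 1]", call. = FALSE)
  invisible(params)
}

# Flatten to the named numeric vector consumed by the compiled RHS.
params_vector <- function(params) {
  nm <- setdiff(names(params), "variant")
  v <- vapply(params[nm], as.numeric, numeric(1))
  names(v) <- nm
  v
}

#' @export
print.ca_params <- function(x, ...) {
  cat("<ca_params> variant:", x$variant, "\n")
  cat(sprintf("  scales: g_cal=%.3g k_close_cal=%.3g g_ryr=%.3g f_junc=%.3g\n",
              x$g_cal, x$k_close_cal, x$g_ryr, x$f_junc))
  cat(sprintf("  csq_total=%.3g mM  v_serca=%.3g mM/ms  g_ncx=%.3g\n",
              x$csq_total, x$v_serca, x$g_ncx))
  invisible(x)
}

#' Write / read a parameter set as flat JSON
#'
#' The serialisation is a flat name-to-value map plus a `variant` field
#' (`"control"`, `"pkp2cko"` or `"custom"`).
#'
#' @param params A `ca_params` object.
#' @param path File path.
#' @return `write_params_json()` returns `path` invisibly;
#'   `read_params_json()` returns a `ca_params` object.
#' @export
write_params_json <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tmpl <- make_control_params()
  missing <- setdiff(names(tmpl), names(raw))
  if (length(missing)) stop("parameter JSON lacks field(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  p <- structure(raw[names(tmpl)], class = "ca_params")
  if (!p$variant %in% c("control", "pkp2cko", "custom"))
    p$variant <- "custom"
  validate_params(p)
  p
}
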