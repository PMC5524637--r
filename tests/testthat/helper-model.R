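# Shared lazily-computed model results, reused across test files so the
# expensive protocol simulations run once per suite.

.model_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .model_cache)) {
    assign(key, force(expr), envir = .model_cache)
  }
  get(key, envir = .model_cache)
}

cached_iv_control <- function() {
  cached("iv_control", run_iv_protocol(make_control_params()))
}

cached_iv_ltcc <- function() {
  # LTCC-only variant: closing rate x0.75, density x0.50
  cached("iv_ltcc", {
    p <- make_control_params()
    p$k_close_cal <- 0.75
    p$g_cal <- 0.5
    p$variant <- "custom"
    run_iv_protocol(p)
  })
}

cached_iv_ko <- function() {
  cached("iv_ko", run_iv_protocol(make_pkp2cko_params()))
}

cached_gain_control <- function() {
  cached("gain_control", run_gain_protocol(make_control_params()))
}

cached_gain_ko <- function() {
  cached("gain_ko", run_gain_protocol(make_pkp2cko_params()))
}

cached_hold50 <- function(variant = c("control", "ko")) {
  variant <- match.arg(variant)
  key <- paste0("hold50_", variant)
  p <- if (variant == "control") make_control_params() else
    make_pkp2cko_params()
  cached(key, find_steady_state(p, -50))
}
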