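// Compartmental calcium-cycling right-hand side for a voltage-clamped
// mouse ventricular myocyte.
//
// Compartments: junctional cleft, submembrane space, bulk cytosol,
// network SR, junctional SR.  Fluxes: L-type Ca current (GHK driving
// force, d*f*fCa gating with Ca-dependent inactivation sensed in the
// cleft), RyR2 release with luminal regulation, SERCA with a reversal
// term, passive SR leak, NCX, sarcolemmal background Ca leak,
// inter-compartment diffusion and network-SR -> jSR transfer.
// Cytosolic/submembrane/cleft/jSR buffering uses the rapid-buffering
// approximation, so free [Ca] is the state variable everywhere.
//
// Units: mV, ms, mM, pA/pF, pL.  Inward current is negative.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double FARADAY = 96.485;   // C/mmol
static const double RGAS    = 8.314;    // J/(mol K)

// State layout (shared with R; see .state_names in the R sources)
enum {
  iD = 0, iF, iFCA, iRYR_R, iRYR_O, iRYR_I,
  iCAC, iCASL, iCAI, iCANSR, iCAJSR, N_STATE
};

struct Params {
  double g_cal, k_close_cal, f_junc, g_ryr, csq_total, csq_ref, csq_sens;
  double v_serca, k_serca, hill_serca, k_serca_sr;
  double g_ncx, g_leak_sr, tau_tr;
  double vol_cleft, vol_sub, vol_cyto, vol_nsr, vol_jsr;
  double cm_pf, p_cal;
  double act_vhalf, act_slope, tau_d_base, tau_d_amp, tau_d_vmid, tau_d_vwidth;
  double f_vhalf, f_slope, f_pedestal, tau_f_base, tau_f_amp, tau_f_vmid, tau_f_vwidth;
  double k_fca, tau_fca;
  double ko_ca, k_om, ki_ca, k_im, ec50_sr, max_sr, min_sr, ks_rel;
  double eta_ncx, ksat_ncx, km_na, km_ca, v_ncx, na_i, na_o, ca_o;
  double g_cab;
  double buf_cyto1, kd_cyto1, buf_cyto2, kd_cyto2;
  double buf_sub, kd_sub, buf_cleft, kd_cleft, kd_csq;
  double d_cleft_sub, d_sub_cyto;
  double caffeine, perm, bath_ca, k_bath;
  double temp;
};

static double getp(const NumericVector& p, const char* nm) {
  // names() lookup once per integration entry point, not per step
  CharacterVector nms = p.names();
  for (R_xlen_t i = 0; i < p.size(); ++i)
    if (std::strcmp(nms[i], nm) == 0) return p[i];
  stop("model parameter '%s' missing", nm);
  return NA_REAL;
}

static Params unpack(const NumericVector& p) {
  Params q;
#define GET(field) q.field = getp(p, #field)
  GET(g_cal); GET(k_close_cal); GET(f_junc); GET(g_ryr); GET(csq_total);
  GET(csq_ref); GET(csq_sens);
  GET(v_serca); GET(k_serca); GET(hill_serca); GET(k_serca_sr);
  GET(g_ncx); GET(g_leak_sr); GET(tau_tr);
  GET(vol_cleft); GET(vol_sub); GET(vol_cyto); GET(vol_nsr); GET(vol_jsr);
  GET(cm_pf); GET(p_cal);
  GET(act_vhalf); GET(act_slope); GET(tau_d_base); GET(tau_d_amp);
  GET(tau_d_vmid); GET(tau_d_vwidth);
  GET(f_vhalf); GET(f_slope); GET(f_pedestal); GET(tau_f_base); GET(tau_f_amp);
  GET(tau_f_vmid); GET(tau_f_vwidth);
  GET(k_fca); GET(tau_fca);
  GET(ko_ca); GET(k_om); GET(ki_ca); GET(k_im); GET(ec50_sr);
  GET(max_sr); GET(min_sr); GET(ks_rel);
  GET(eta_ncx); GET(ksat_ncx); GET(km_na); GET(km_ca); GET(v_ncx);
  GET(na_i); GET(na_o); GET(ca_o);
  GET(g_cab);
  GET(buf_cyto1); GET(kd_cyto1); GET(buf_cyto2); GET(kd_cyto2);
  GET(buf_sub); GET(kd_sub); GET(buf_cleft); GET(kd_cleft); GET(kd_csq);
  GET(d_cleft_sub); GET(d_sub_cyto);
  GET(caffeine); GET(perm); GET(bath_ca); GET(k_bath);
  GET(temp);
#undef GET
  return q;
}

static inline double beta_one(double ca, double btot, double kd) {
  double d = kd + ca;
  return btot * kd / (d * d);
}

// GHK-type driving term for a divalent ion; per-unit-permeability current.
static inline double ghk_ca(double v, double cai, double cao, double frt) {
  const double gamma_i = 0.341, gamma_o = 0.341;
  // I = p_cal * x * (gi ci e^x - go co)/(e^x - 1), x = zVF/RT; remaining
  // constants are folded into p_cal, which carries pA/pF per mM.
  double x = 2.0 * v * frt;
  double num = gamma_i * cai * std::exp(x) - gamma_o * cao;
  if (std::fabs(x) < 1e-5) return num * (1.0 - x / 2.0); // x/(e^x-1) series
  return x * num / std::expm1(x);
}

struct Derivs {
  double dy[N_STATE];
  double ical;        // pA/pF, whole-cell L-type density
  double jrel;        // mM/ms, cytosol-referred release flux
  double jserca;      // mM/ms, cytosol-referred uptake flux
  double jncx;        // mM/ms, cytosol-referred NCX extrusion (positive out)
  double jsarc_pmol;  // pmol/ms, net sarcolemmal Ca influx (CaL + bkg - NCX)
  double jbath_pmol;  // pmol/ms, net influx from bath clamp (permeabilized)
  double jleak;       // mM/ms, cytosol-referred SR leak
};

static void rhs(const Params& q, const double* y, double v, Derivs& out) {
  double frt = FARADAY / (RGAS * q.temp) * 1.0; // 1/mV (F in C/mmol, R J/molK)

  double d = y[iD], f = y[iF], fca = y[iFCA];
  double rr = y[iRYR_R], ro = y[iRYR_O], ri = y[iRYR_I];
  double cac = y[iCAC], casl = y[iCASL], cai = y[iCAI];
  double cansr = y[iCANSR], cajsr = y[iCAJSR];

  // --- LTCC gating ---------------------------------------------------
  double dinf = 1.0 / (1.0 + std::exp(-(v - q.act_vhalf) / q.act_slope));
  double zd = (v - q.tau_d_vmid) / q.tau_d_vwidth;
  double taud = q.tau_d_base + q.tau_d_amp * std::exp(-zd * zd);
  double finf = q.f_pedestal +
    (1.0 - q.f_pedestal) / (1.0 + std::exp((v - q.f_vhalf) / q.f_slope));
  double zf = (v - q.tau_f_vmid) / q.tau_f_vwidth;
  double tauf = q.tau_f_base + q.tau_f_amp * std::exp(-zf * zf);
  double alpha_f = finf / tauf;             // reopening/recovery rate
  double beta_f  = (1.0 - finf) / tauf;     // closing (inactivation) rate
  double r2 = cac / q.k_fca;
  double fcainf = 1.0 / (1.0 + r2 * r2);

  out.dy[iD]   = (dinf - d) / taud;
  out.dy[iF]   = alpha_f * (1.0 - f) - q.k_close_cal * beta_f * f;
  out.dy[iFCA] = (fcainf - fca) / q.tau_fca;

  // --- L-type current (junctional + submembrane sarcolemma) ----------
  double gate = d * f * fca;
  double i_junc = q.g_cal * q.p_cal * q.f_junc * gate * ghk_ca(v, cac, q.ca_o, frt);
  double i_sl   = q.g_cal * q.p_cal * (1.0 - q.f_junc) * gate *
                  ghk_ca(v, casl, q.ca_o, frt);
  out.ical = i_junc + i_sl;

  // pA/pF * pF -> pA; pA * 1e-3 / (2 F[C/mmol]) -> pmol/ms (influx if inward)
  double cur2mol = q.cm_pf * 1e-3 / (2.0 * FARADAY);
  double jcal_junc_pmol = -i_junc * cur2mol;
  double jcal_sl_pmol   = -i_sl * cur2mol;

  // --- RyR2 with luminal (jSR) regulation -----------------------------
  // The luminal activation threshold scales with calsequestrin content:
  // calsequestrin is a negative regulator of RyR2, so the depleted-CSQ
  // variant opens at lower jSR free Ca.
  double ec50_eff = q.ec50_sr * std::pow(q.csq_total / q.csq_ref, q.csq_sens);
  double hsr = std::pow(cajsr > 0 ? ec50_eff / cajsr : 1e12, 2.5);
  double kcasr = q.max_sr - (q.max_sr - q.min_sr) / (1.0 + hsr);
  double kosrca = q.ko_ca / kcasr;
  double kisrca = q.ki_ca * kcasr;
  double rir = 1.0 - rr - ro - ri;
  out.dy[iRYR_R] = (q.k_im * rir - kisrca * cac * rr) -
                   (kosrca * cac * cac * rr - q.k_om * ro);
  out.dy[iRYR_O] = (kosrca * cac * cac * rr - q.k_om * ro) -
                   (kisrca * cac * ro - q.k_im * ri);
  out.dy[iRYR_I] = (kisrca * cac * ro - q.k_im * ri) -
                   (q.k_om * ri - kosrca * cac * cac * rir);

  double o_use = (q.caffeine > 0.5) ? 1.0 : ro;
  double jrel_pmol = q.ks_rel * q.g_ryr * o_use * (cajsr - cac) * q.vol_jsr;

  // --- SERCA (forward/reverse), SR leak, jSR refill -------------------
  double fw = std::pow(cai / q.k_serca, q.hill_serca);
  double rv = std::pow(cansr / q.k_serca_sr, q.hill_serca);
  double jserca_mm = q.v_serca * (fw - rv) / (1.0 + fw + rv); // mM/ms (cyto)
  double jserca_pmol = jserca_mm * q.vol_cyto;
  // diastolic leak is RyR2-mediated, hence scales with RyR2 density;
  // its product appears in the bulk cytosol
  double jleak_pmol = q.g_leak_sr * q.g_ryr * (cansr - cai) * q.vol_cyto;
  double jtr_pmol = (cansr - cajsr) / q.tau_tr * q.vol_jsr;

  // --- NCX and background sarcolemmal leak ----------------------------
  double ex1 = std::exp(q.eta_ncx * v * frt);
  double ex2 = std::exp((q.eta_ncx - 1.0) * v * frt);
  double na3 = q.na_i * q.na_i * q.na_i;
  double nao3 = q.na_o * q.na_o * q.na_o;
  double num = ex1 * na3 * q.ca_o - ex2 * nao3 * casl;
  double den = (q.km_na * q.km_na * q.km_na + nao3) * (q.km_ca + q.ca_o) *
               (1.0 + q.ksat_ncx * ex2);
  double jncx_pmol = -q.g_ncx * q.v_ncx * num / den; // pmol/ms, >0 = extrusion

  double eca = (1.0 / (2.0 * frt)) * std::log(q.ca_o / std::max(casl, 1e-12));
  double icab = q.g_cab * (v - eca);                 // pA/pF, outward positive
  double jcab_pmol = -icab * cur2mol;                // influx when inward

  // --- diffusion and bath exchange ------------------------------------
  double jdiff_cs_pmol = q.d_cleft_sub * (cac - casl);   // pL/ms * mM
  double jdiff_sc_pmol = q.d_sub_cyto * (casl - cai);
  double jbath_pmol = (q.perm > 0.5) ? q.k_bath * (q.bath_ca - cai) * q.vol_cyto
                                     : 0.0;

  // --- free-Ca balances with rapid buffering --------------------------
  double beta_c  = 1.0 / (1.0 + beta_one(cac, q.buf_cleft, q.kd_cleft));
  double beta_sl = 1.0 / (1.0 + beta_one(casl, q.buf_sub, q.kd_sub));
  double beta_i  = 1.0 / (1.0 + beta_one(cai, q.buf_cyto1, q.kd_cyto1) +
                                beta_one(cai, q.buf_cyto2, q.kd_cyto2));
  double beta_j  = 1.0 / (1.0 + beta_one(cajsr, q.csq_total, q.kd_csq));

  out.dy[iCAC]  = beta_c * (jcal_junc_pmol + jrel_pmol -
                            jdiff_cs_pmol) / q.vol_cleft;
  out.dy[iCASL] = beta_sl * (jcal_sl_pmol + jcab_pmol - jncx_pmol +
                             jdiff_cs_pmol - jdiff_sc_pmol) / q.vol_sub;
  out.dy[iCAI]  = beta_i * (jdiff_sc_pmol + jleak_pmol - jserca_pmol +
                             jbath_pmol) / q.vol_cyto;
  out.dy[iCANSR] = (jserca_pmol - jleak_pmol - jtr_pmol) / q.vol_nsr;
  out.dy[iCAJSR] = beta_j * (jtr_pmol - jrel_pmol) / q.vol_jsr;

  out.jrel = jrel_pmol / q.vol_cyto;
  out.jserca = jserca_mm;
  out.jncx = jncx_pmol / q.vol_cyto;
  out.jleak = jleak_pmol / q.vol_cyto;
  out.jsarc_pmol = jcal_junc_pmol + jcal_sl_pmol + jcab_pmol - jncx_pmol;
  out.jbath_pmol = jbath_pmol;
}

static const char* AUX_NAMES[] = {"ICaL_pApF", "Jrel", "Jserca", "Jncx",
                                  "Jsarc_pmol", "Jbath_pmol", "Jleak"};
static const int N_AUX = 7;

//' @noRd
// [[Rcpp::export(name = ".ca_rhs_cpp")]]
List ca_rhs_cpp(NumericVector y, NumericVector params, double v) {
  if (y.size() != N_STATE) stop("state vector must have %d elements", N_STATE);
  Params q = unpack(params);
  Derivs d;
  rhs(q, REAL(y), v, d);
  NumericVector dy(N_STATE);
  for (int i = 0; i < N_STATE; ++i) dy[i] = d.dy[i];
  NumericVector aux = NumericVector::create(
    _["ICaL_pApF"] = d.ical, _["Jrel"] = d.jrel, _["Jserca"] = d.jserca,
    _["Jncx"] = d.jncx, _["Jsarc_pmol"] = d.jsarc_pmol,
    _["Jbath_pmol"] = d.jbath_pmol, _["Jleak"] = d.jleak);
  return List::create(_["dy"] = dy, _["aux"] = aux);
}

// Fixed-step explicit Euler over a piecewise-constant voltage command.
// Serves as the brute-force integration oracle for the adaptive solver.
//' @noRd
// [[Rcpp::export(name = ".ca_euler_cpp")]]
NumericMatrix ca_euler_cpp(NumericVector y0, NumericVector params,
                           NumericVector v_times, NumericVector v_values,
                           double duration, double dt, double dt_out) {
  if (y0.size() != N_STATE) stop("state vector must have %d elements", N_STATE);
  Params q = unpack(params);
  double y[N_STATE];
  for (int i = 0; i < N_STATE; ++i) y[i] = y0[i];

  int n_out = (int) std::floor(duration / dt_out + 1e-9) + 1;
  NumericMatrix out(n_out, 2 + N_STATE + N_AUX);
  Derivs d;

  long n_steps = (long) std::llround(duration / dt);
  int out_every = (int) std::llround(dt_out / dt);
  if (out_every < 1) stop("dt_out must be >= dt");

  int vseg = 0, nv = v_times.size(), row = 0;
  for (long s = 0; s <= n_steps; ++s) {
    double t = s * dt;
    // a sample exactly at a command boundary reports the outgoing segment,
    // matching the adaptive integrator's boundary-row convention
    while (vseg + 1 < nv && t > v_times[vseg + 1]) ++vseg;
    double v = v_values[vseg];
    rhs(q, y, v, d);
    if (s % out_every == 0 && row < n_out) {
      out(row, 0) = t;
      out(row, 1) = v;
      for (int i = 0; i < N_STATE; ++i) out(row, 2 + i) = y[i];
      out(row, 2 + N_STATE + 0) = d.ical;
      out(row, 2 + N_STATE + 1) = d.jrel;
      out(row, 2 + N_STATE + 2) = d.jserca;
      out(row, 2 + N_STATE + 3) = d.jncx;
      out(row, 2 + N_STATE + 4) = d.jsarc_pmol;
      out(row, 2 + N_STATE + 5) = d.jbath_pmol;
      out(row, 2 + N_STATE + 6) = d.jleak;
      ++row;
    }
    for (int i = 0; i < N_STATE; ++i) y[i] += dt * d.dy[i];
  }

  CharacterVector cn(2 + N_STATE + N_AUX);
  cn[0] = "t_ms"; cn[1] = "V_mV";
  const char* st[] = {"d", "f", "fca", "ryr_r", "ryr_o", "ryr_i",
                      "ca_cleft", "ca_sub", "ca_i", "ca_nsr", "ca_jsr"};
  for (int i = 0; i < N_STATE; ++i) cn[2 + i] = st[i];
  for (int i = 0; i < N_AUX; ++i) cn[2 + N_STATE + i] = AUX_NAMES[i];
  colnames(out) = cn;
  return out;
}

// Module-level parameter cache so the adaptive-solver callback avoids a
// name lookup per derivative evaluation (single-threaded use).
static Params G_PAR;
static bool G_PAR_SET = false;

//' @noRd
// [[Rcpp::export(name = ".ca_set_params")]]
void ca_set_params(NumericVector params) {
  G_PAR = unpack(params);
  G_PAR_SET = true;
}

//' @noRd
// [[Rcpp::export(name = ".ca_rhs_fast")]]
NumericVector ca_rhs_fast(NumericVector y, double v) {
  if (!G_PAR_SET) stop("internal: parameters not set");
  if (y.size() != N_STATE) stop("state vector must have %d elements", N_STATE);
  Derivs d;
  rhs(G_PAR, REAL(y), v, d);
  NumericVector out(N_STATE + N_AUX);
  for (int i = 0; i < N_STATE; ++i) out[i] = d.dy[i];
  out[N_STATE + 0] = d.ical;
  out[N_STATE + 1] = d.jrel;
  out[N_STATE + 2] = d.jserca;
  out[N_STATE + 3] = d.jncx;
  out[N_STATE + 4] = d.jsarc_pmol;
  out[N_STATE + 5] = d.jbath_pmol;
  out[N_STATE + 6] = d.jleak;
  return out;
}
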