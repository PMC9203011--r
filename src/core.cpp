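// Numerical core: explicit buffered diffusion on a labelled voxel cube,
// per-voxel analytic buffer relaxation, analytic two-compartment membrane
// exchange across RyR faces, three-state SERCA cycling flux, and the
// stochastic two-state channel clock.  All randomness goes through R's RNG
// so that set.seed() makes whole simulations reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// voxel labels
static const int LAB_CYT = 0;
static const int LAB_JSR = 1;
static const int LAB_NSR = 2;
static const int LAB_TT = 3;

// neighbour codes in the precomputed stencil
static const int NB_REFLECT = -1; // interior no-flux wall (domain boundary)
static const int NB_CLAMP = -2;   // outer cube face in clamped mode

static inline bool in_domain(int lab, int dom) {
  // dom: 0 = cytosol, 1 = SR (junctional + network)
  if (dom == 0) return lab == LAB_CYT;
  return lab == LAB_JSR || lab == LAB_NSR;
}

// Build, for every voxel of `dom`, the 6 neighbour codes.
// boundary: 0 = sealed (outer faces reflect), 1 = clamped (outer faces see
// a ghost voxel held at the resting concentration).
static void build_stencil(const IntegerVector& labels, int n, int dom,
                          int boundary,
                          std::vector<int>& vox,      // linear indices in dom
                          std::vector<int>& neigh) {  // 6 codes per voxel
  vox.clear();
  const int n2 = n * n;
  std::vector<int> slot(labels.size(), -1);
  for (int i = 0; i < labels.size(); ++i)
    if (in_domain(labels[i], dom)) { slot[i] = (int)vox.size(); vox.push_back(i); }
  neigh.assign(vox.size() * 6, NB_REFLECT);
  const int dx_[6] = { -1, 1, 0, 0, 0, 0 };
  const int dy_[6] = { 0, 0, -1, 1, 0, 0 };
  const int dz_[6] = { 0, 0, 0, 0, -1, 1 };
  for (size_t v = 0; v < vox.size(); ++v) {
    int i = vox[v];
    int x = i % n, y = (i / n) % n, z = i / n2;
    for (int d = 0; d < 6; ++d) {
      int xx = x + dx_[d], yy = y + dy_[d], zz = z + dz_[d];
      if (xx < 0 || xx >= n || yy < 0 || yy >= n || zz < 0 || zz >= n) {
        neigh[6 * v + d] = (boundary == 1) ? NB_CLAMP : NB_REFLECT;
      } else {
        int j = xx + n * (yy + n * zz);
        neigh[6 * v + d] = in_domain(labels[j], dom) ? j : NB_REFLECT;
      }
    }
  }
}

// One explicit diffusion pass (possibly substepped for stability) for one
// species living on `dom`.  f is the full-grid field; only domain voxels
// are touched.  clampv is the ghost value used in clamped mode.
static void diffuse_inplace(std::vector<double>& f, std::vector<double>& tmp,
                            const std::vector<int>& vox,
                            const std::vector<int>& neigh,
                            double D, double dx, double dt, double clampv) {
  if (D <= 0.0 || vox.empty()) return;
  int nsub = (int)std::ceil(6.0 * D * dt / (dx * dx) / 0.9);
  if (nsub < 1) nsub = 1;
  double r = D * (dt / nsub) / (dx * dx);
  for (int s = 0; s < nsub; ++s) {
    for (size_t v = 0; v < vox.size(); ++v) {
      int i = vox[v];
      double fi = f[i], acc = 0.0;
      for (int d = 0; d < 6; ++d) {
        int code = neigh[6 * v + d];
        if (code >= 0) acc += f[code] - fi;
        else if (code == NB_CLAMP) acc += clampv - fi;
        // NB_REFLECT contributes 0 (no-flux)
      }
      tmp[i] = fi + r * acc;
    }
    for (size_t v = 0; v < vox.size(); ++v) f[vox[v]] = tmp[vox[v]];
  }
}

// exp(-y) with a cheap 4th-order Taylor fast path for the small exponents
// that dominate the buffer relaxation (relative error < 1e-10 for y < 0.02)
static inline double exp_neg(double y) {
  if (y < 0.02)
    return 1.0 - y * (1.0 - 0.5 * y * (1.0 - y / 3.0 * (1.0 - 0.25 * y)));
  return std::exp(-y);
}

// Relaxation of the calcium/buffer binding system in one voxel over dt.
// Each buffer follows the exact solution of its linear binding ODE at
// frozen free calcium -- frozen at a midpoint estimate obtained from a
// provisional half-step sweep -- and the change is subtracted from the
// free pool, so the per-voxel total (free + sum bound) is preserved
// exactly and the update is second-order accurate in dt.
static inline void react_voxel(double& c, double* b[], const double* kon,
                               const double* koff, const double* Btot,
                               int nb, double dt) {
  // provisional half-step to estimate midpoint free calcium
  double ch = c;
  for (int k = 0; k < nb; ++k) {
    double lam = kon[k] * ch + koff[k];
    if (lam <= 0.0) continue;
    double binf = kon[k] * ch * Btot[k] / lam;
    double bn = binf + (*b[k] - binf) * exp_neg(lam * 0.5 * dt);
    ch -= bn - *b[k];
  }
  // full step with coefficients frozen at the midpoint value
  for (int k = 0; k < nb; ++k) {
    double lam = kon[k] * ch + koff[k];
    if (lam <= 0.0) continue;
    double binf = kon[k] * ch * Btot[k] / lam;
    double bn = binf + (*b[k] - binf) * exp_neg(lam * dt);
    c -= bn - *b[k];
    *b[k] = bn;
  }
}

static void buffer_relax_multi(std::vector<double>& c,
                               std::vector<std::vector<double>>& b,
                               const std::vector<int>& bidx,
                               const std::vector<int>& vox,
                               const double* kon, const double* koff,
                               const double* Btot, double dt) {
  int nb = (int)bidx.size();
  std::vector<double*> bp(nb);
  std::vector<double> konl(nb), koffl(nb), Btotl(nb);
  for (int k = 0; k < nb; ++k) {
    konl[k] = kon[bidx[k]];
    koffl[k] = koff[bidx[k]];
    Btotl[k] = Btot[bidx[k]];
  }
  for (size_t v = 0; v < vox.size(); ++v) {
    int i = vox[v];
    for (int k = 0; k < nb; ++k) bp[k] = &b[bidx[k]][i];
    react_voxel(c[i], bp.data(), konl.data(), koffl.data(), Btotl.data(),
                nb, dt);
  }
}

// Steady-state cycling rate of a three-state pump (uptake-positive,
// dimensionless; scaled by vmax outside).  Forward path binds cytosolic
// calcium cooperatively (c^2), backward path binds luminal calcium (s^2).
static inline double serca_cycle(double c, double s,
                                 double k1p, double k2p, double k3p,
                                 double k1m, double k2m, double k3m) {
  double a1 = k1p * c * c, a2 = k2p, a3 = k3p;
  double b1 = k1m, b2 = k2m * s * s, b3 = k3m;
  double num = a1 * a2 * a3 - b1 * b2 * b3;
  double den = a2 * a3 + b1 * a3 + b1 * b2   // trees rooted at state 1
             + a3 * a1 + b2 * a1 + b2 * b3   // state 2
             + a1 * a2 + b3 * a2 + b3 * b1;  // state 3
  return num / den;
}

// Saturating power law f(x) = kmin + (kmax-kmin) * x^eta / (1 + x^eta).
static inline double rate_law(double x, double kmin, double kmax, double eta) {
  if (x <= 0.0) return kmin;
  double xe = std::pow(x, eta);
  return kmin + (kmax - kmin) * xe / (1.0 + xe);
}

// [[Rcpp::export]]
NumericVector cpp_diffuse(NumericVector field, IntegerVector labels, int n,
                          int domain, double D, double dx, double dt,
                          int boundary, double clamp_value) {
  std::vector<int> vox, neigh;
  build_stencil(labels, n, domain, boundary, vox, neigh);
  std::vector<double> f(field.begin(), field.end()), tmp(f);
  diffuse_inplace(f, tmp, vox, neigh, D, dx, dt, clamp_value);
  return NumericVector(f.begin(), f.end());
}

// R-facing reaction step: the full binding sweep over all buffers sharing
// the free pool, `nsteps` times at step `dt`.
// [[Rcpp::export]]
List cpp_buffer_step(NumericVector cfree, List bound, IntegerVector vox1,
                     NumericVector kon, NumericVector koff,
                     NumericVector Btot, double dt, int nsteps) {
  int nb = bound.size();
  std::vector<double> c(cfree.begin(), cfree.end());
  std::vector<std::vector<double>> b(nb);
  for (int k = 0; k < nb; ++k) {
    NumericVector bk = bound[k];
    b[k].assign(bk.begin(), bk.end());
  }
  std::vector<int> vox(vox1.size()), bidx(nb);
  for (int i = 0; i < vox1.size(); ++i) vox[i] = vox1[i] - 1;
  for (int k = 0; k < nb; ++k) bidx[k] = k;
  for (int s = 0; s < nsteps; ++s)
    buffer_relax_multi(c, b, bidx, vox, kon.begin(), koff.begin(),
                       Btot.begin(), dt);
  List bout(nb);
  for (int k = 0; k < nb; ++k)
    bout[k] = NumericVector(b[k].begin(), b[k].end());
  return List::create(_["c"] = NumericVector(c.begin(), c.end()),
                      _["b"] = bout);
}

// [[Rcpp::export]]
NumericVector cpp_serca_rate(NumericVector c, NumericVector s,
                             double k1p, double k2p, double k3p,
                             double k1m, double k2m, double k3m) {
  int m = c.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = serca_cycle(c[i], s[i], k1p, k2p, k3p, k1m, k2m, k3m);
  return out;
}

// Analytic two-compartment exchange for face pairs with equal voxel
// volumes: d(c)/dt = g (s - c), d(s)/dt = -g (s - c), so the difference
// decays as exp(-2 g t).
// [[Rcpp::export]]
List cpp_pair_exchange(NumericVector cfree, NumericVector sfree,
                       IntegerVector cyt1, IntegerVector sr1,
                       double g, double dt) {
  std::vector<double> c(cfree.begin(), cfree.end());
  std::vector<double> s(sfree.begin(), sfree.end());
  double decay = 0.5 * (1.0 - std::exp(-2.0 * g * dt));
  for (int f = 0; f < cyt1.size(); ++f) {
    int ic = cyt1[f] - 1, is = sr1[f] - 1;
    double d = (s[is] - c[ic]) * decay;
    c[ic] += d;
    s[is] -= d;
  }
  return List::create(_["c"] = NumericVector(c.begin(), c.end()),
                      _["s"] = NumericVector(s.begin(), s.end()));
}

// [[Rcpp::export]]
NumericVector cpp_rate_law(NumericVector x, double kmin, double kmax,
                           double eta) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = rate_law(x[i], kmin, kmax, eta);
  return out;
}

// Separable Gaussian blur with zero padding outside the cube (voxels
// outside the cytosol carry no dye and are simply zero in the input).
static void blur_axis(std::vector<double>& f, std::vector<double>& tmp,
                      int n, int axis, double sigma, int radius) {
  if (sigma <= 0.0 || radius < 1) return;
  std::vector<double> k(2 * radius + 1);
  double sum = 0.0;
  for (int j = -radius; j <= radius; ++j) {
    k[j + radius] = std::exp(-0.5 * (j * j) / (sigma * sigma));
    sum += k[j + radius];
  }
  for (double& w : k) w /= sum;
  const int n2 = n * n;
  int stride = (axis == 0) ? 1 : (axis == 1 ? n : n2);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b) {
      // base index of the line along `axis`
      int base;
      if (axis == 0) base = n * (a + n * b);
      else if (axis == 1) base = a + n2 * b;
      else base = a + n * b;
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = -radius; j <= radius; ++j) {
          int ii = i + j;
          if (ii < 0 || ii >= n) continue; // zero padding
          acc += k[j + radius] * f[base + ii * stride];
        }
        tmp[base + i * stride] = acc;
      }
    }
  f.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector field, int n,
                                NumericVector sigma_vox,
                                IntegerVector radius_vox) {
  std::vector<double> f(field.begin(), field.end()), tmp(f.size());
  for (int ax = 0; ax < 3; ++ax)
    blur_axis(f, tmp, n, ax, sigma_vox[ax], radius_vox[ax]);
  return NumericVector(f.begin(), f.end());
}

// Long constant-concentration gating trace used by the statistical tests:
// returns the open/closed state after every step.
// [[Rcpp::export]]
IntegerVector cpp_gating_trace(double c, double Kplus,
                               double kplus_min, double kplus_max,
                               double eta_plus, double Kminus,
                               double kminus_min, double kminus_max,
                               double eta_minus, double dt, int nsteps,
                               int open0) {
  IntegerVector out(nsteps);
  double kp = rate_law(c / Kplus, kplus_min, kplus_max, eta_plus);
  double km = rate_law(c / Kminus, kminus_min, kminus_max, eta_minus);
  double p_open = 1.0 - std::exp(-kp * dt);
  double p_close = 1.0 - std::exp(-km * dt);
  int open = open0;
  for (int i = 0; i < nsteps; ++i) {
    double u = unif_rand();
    if (open) { if (u < p_close) open = 0; }
    else      { if (u < p_open)  open = 1; }
    out[i] = open;
  }
  return out;
}

struct Species {
  std::vector<double>* f;
  int dom;       // 0 cytosol, 1 SR
  double D;
  double clamp;  // resting value for clamped outer faces
};

// Full spark simulation.  See run_spark() on the R side for the
// user-facing contract; this function is the inner loop.
// [[Rcpp::export]]
List cpp_run_spark(IntegerVector labels, int n, double dx,
                   List ryr_cyt, List ryr_sr, NumericVector Kplus,
                   IntegerVector serca_cyt, IntegerVector serca_sr,
                   List par, int init_channel) {  // init_channel is 0-based
  const int nch = ryr_cyt.size();
  const int ntot = n * n * n;
  const double Vvox = dx * dx * dx;   // μm^3
  const double Aface = dx * dx;       // μm^2

  // ---- unpack parameters -------------------------------------------------
  List buf = par["buffers"];          // kon, koff, Btot, D per buffer (5)
  NumericVector kon = buf["kon"], koff = buf["koff"], Btot = buf["Btot"],
                Dbuf = buf["D"];
  List tr = par["transport"];
  double D_c = tr["D_c"], D_s = tr["D_s"], nu_ryr = tr["nu_ryr"];
  double resting_c = tr["resting_c"], resting_s = tr["resting_s"];
  List sp = tr["serca"];
  double k1p = sp["k1p"], k2p = sp["k2p"], k3p = sp["k3p"];
  double k1m = sp["k1m"], k2m = sp["k2m"], k3m = sp["k3m"];
  double serca_vmax = sp["vmax"];     // μM·μm/ms scale of the cycle
  List ga = par["gating"];
  double kplus_min = ga["k_plus_min"], kplus_max = ga["k_plus_max"],
         eta_plus = ga["eta_plus"], Kminus = ga["K_minus"],
         kminus_min = ga["k_minus_min"], kminus_max = ga["k_minus_max"],
         eta_minus = ga["eta_minus"];
  List nm = par["numerics"];
  double dt = nm["dt"], dt_gate = nm["dt_gate"], t_max = nm["t_max"],
         record_dt = nm["record_dt"], terminate_after = nm["terminate_after"];
  int boundary = as<int>(nm["boundary"]); // 0 sealed, 1 clamped
  bool psf_on = as<bool>(nm["psf_on"]);
  bool store_fields = as<bool>(nm["store_fields"]);
  NumericVector psf_sigma = nm["psf_sigma_vox"];
  IntegerVector psf_radius = nm["psf_radius_vox"];
  bool serca_on = serca_cyt.size() > 0 && serca_vmax > 0.0;

  // ---- initial state -----------------------------------------------------
  auto b_rest = [&](int i, double cc) {
    return kon[i] * cc * Btot[i] / (kon[i] * cc + koff[i]);
  };
  std::vector<double> c(ntot, 0.0), s(ntot, 0.0);
  std::vector<std::vector<double>> b(5, std::vector<double>(ntot, 0.0));
  std::vector<int> cyt_vox, cyt_neigh, sr_vox, sr_neigh;
  build_stencil(labels, n, 0, boundary, cyt_vox, cyt_neigh);
  build_stencil(labels, n, 1, boundary, sr_vox, sr_neigh);
  for (int i : cyt_vox) {
    c[i] = resting_c;
    for (int k = 0; k < 4; ++k) b[k][i] = b_rest(k, resting_c);
  }
  for (int i : sr_vox) {
    s[i] = resting_s;
    b[4][i] = b_rest(4, resting_s);
  }
  std::vector<double> tmp(ntot, 0.0);

  std::vector<Species> species;
  species.push_back({ &c, 0, D_c, resting_c });
  for (int k = 0; k < 4; ++k)
    species.push_back({ &b[k], 0, Dbuf[k], b_rest(k, resting_c) });
  species.push_back({ &s, 1, D_s, resting_s });
  // calsequestrin (buffer index 4) is stationary; no diffusion entry

  // ---- channels ----------------------------------------------------------
  std::vector<std::vector<int>> ch_cyt(nch), ch_sr(nch), ch_cleft(nch);
  for (int k = 0; k < nch; ++k) {
    IntegerVector a = ryr_cyt[k], bb = ryr_sr[k];
    for (int f = 0; f < a.size(); ++f) {
      ch_cyt[k].push_back(a[f] - 1);
      ch_sr[k].push_back(bb[f] - 1);
    }
    ch_cleft[k] = ch_cyt[k]; // cleft voxels = cytosolic face voxels
  }
  std::vector<int> sf_cyt(serca_cyt.size()), sf_sr(serca_sr.size());
  for (int f = 0; f < serca_cyt.size(); ++f) {
    sf_cyt[f] = serca_cyt[f] - 1;
    sf_sr[f] = serca_sr[f] - 1;
  }

  const std::vector<int> cyt_bidx = { 0, 1, 2, 3 };
  const std::vector<int> sr_bidx = { 4 };

  std::vector<int> open(nch, 0);
  std::vector<std::vector<double>> t_open(nch), t_close(nch);
  open[init_channel] = 1;
  t_open[init_channel].push_back(0.0);

  // ---- recording ---------------------------------------------------------
  auto fluorescence = [&]() {
    // maximum of the (optionally blurred) bound-dye field
    if (psf_on) {
      std::vector<double> g = b[3];
      std::vector<double> scratch(g.size());
      for (int ax = 0; ax < 3; ++ax)
        blur_axis(g, scratch, n, ax, psf_sigma[ax], psf_radius[ax]);
      double m = 0.0;
      for (double v : g) if (v > m) m = v;
      return m;
    }
    double m = 0.0;
    for (int i : cyt_vox) if (b[3][i] > m) m = b[3][i];
    return m;
  };

  std::vector<double> rec_t, rec_F;
  std::vector<std::vector<double>> frames_c, frames_b4;
  auto snapshot = [&](double tt) {
    rec_t.push_back(tt);
    rec_F.push_back(fluorescence());
    if (store_fields) {
      frames_c.push_back(c);
      frames_b4.push_back(b[3]);
    }
  };
  snapshot(0.0);

  const int gate_every = std::max(1, (int)std::round(dt_gate / dt));
  const int rec_every = std::max(1, (int)std::round(record_dt / dt));
  const int max_steps = (int)std::ceil(t_max / dt);

  double last_closure = 0.0;
  bool any_open = true, capped = false;
  double t = 0.0;
  double termination = t_max;

  for (int step = 1; step <= max_steps; ++step) {
    // 1) diffusion
    for (auto& spp : species) {
      if (spp.dom == 0)
        diffuse_inplace(*spp.f, tmp, cyt_vox, cyt_neigh, spp.D, dx, dt, spp.clamp);
      else
        diffuse_inplace(*spp.f, tmp, sr_vox, sr_neigh, spp.D, dx, dt, spp.clamp);
    }
    // 2) buffering (exact per-buffer relaxation at midpoint-frozen calcium)
    buffer_relax_multi(c, b, cyt_bidx, cyt_vox, kon.begin(), koff.begin(),
                       Btot.begin(), dt);
    buffer_relax_multi(s, b, sr_bidx, sr_vox, kon.begin(), koff.begin(),
                       Btot.begin(), dt);
    // 3) membrane fluxes
    for (int k = 0; k < nch; ++k) {
      if (!open[k]) continue;
      double g = nu_ryr / (Vvox * ch_cyt[k].size());
      double decay = 0.5 * (1.0 - std::exp(-2.0 * g * dt));
      for (size_t f = 0; f < ch_cyt[k].size(); ++f) {
        int ic = ch_cyt[k][f], is = ch_sr[k][f];
        double d = (s[is] - c[ic]) * decay;
        c[ic] += d;
        s[is] -= d;
      }
    }
    if (serca_on) {
      double fac = serca_vmax * Aface * dt / Vvox; // μM per unit cycle rate
      for (size_t f = 0; f < sf_cyt.size(); ++f) {
        int ic = sf_cyt[f], is = sf_sr[f];
        double J = serca_cycle(c[ic], s[is], k1p, k2p, k3p, k1m, k2m, k3m);
        double d = J * fac;
        if (d > c[ic]) d = c[ic];          // cannot take more than is there
        if (-d > s[is]) d = -s[is];
        c[ic] -= d;
        s[is] += d;
      }
    }
    t = step * dt;
    // 4) gating on the slower channel clock
    if (step % gate_every == 0) {
      for (int k = 0; k < nch; ++k) {
        // local calcium: mean over the cleft voxels facing the channel
        double cl = 0.0;
        for (int i : ch_cleft[k]) cl += c[i];
        cl /= ch_cleft[k].size();
        double u = unif_rand();
        if (open[k]) {
          double km = rate_law(cl / Kminus, kminus_min, kminus_max, eta_minus);
          if (u < 1.0 - std::exp(-km * dt_gate)) {
            open[k] = 0;
            t_close[k].push_back(t);
            last_closure = t;
          }
        } else {
          double kp = rate_law(cl / Kplus[k], kplus_min, kplus_max, eta_plus);
          if (u < 1.0 - std::exp(-kp * dt_gate)) {
            open[k] = 1;
            t_open[k].push_back(t);
          }
        }
      }
      any_open = false;
      for (int k = 0; k < nch; ++k) if (open[k]) { any_open = true; break; }
    }
    if (step % rec_every == 0) snapshot(t);
    if (!any_open && (t - last_closure) >= terminate_after) {
      termination = last_closure + terminate_after;
      break;
    }
    if (step == max_steps) {
      capped = any_open || (t - last_closure) < terminate_after;
      termination = capped ? t_max : last_closure + terminate_after;
    }
  }
  if (rec_t.back() < termination) snapshot(termination);

  List intervals(nch);
  for (int k = 0; k < nch; ++k) {
    int ni = t_open[k].size();
    NumericMatrix m(ni, 2);
    for (int i = 0; i < ni; ++i) {
      m(i, 0) = t_open[k][i];
      m(i, 1) = (i < (int)t_close[k].size()) ? t_close[k][i] : NA_REAL;
    }
    colnames(m) = CharacterVector::create("t_open", "t_close");
    intervals[k] = m;
  }

  List fields = R_NilValue;
  if (store_fields) {
    List fc(frames_c.size()), fb(frames_b4.size());
    for (size_t i = 0; i < frames_c.size(); ++i) {
      fc[i] = NumericVector(frames_c[i].begin(), frames_c[i].end());
      fb[i] = NumericVector(frames_b4[i].begin(), frames_b4[i].end());
    }
    fields = List::create(_["c"] = fc, _["b4"] = fb);
  }

  return List::create(
    _["times"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["F"] = NumericVector(rec_F.begin(), rec_F.end()),
    _["fields"] = fields,
    _["open_intervals"] = intervals,
    _["termination_time"] = termination,
    _["capped"] = capped,
    _["final_c"] = NumericVector(c.begin(), c.end()),
    _["final_s"] = NumericVector(s.begin(), s.end()),
    _["final_b"] = List::create(
        NumericVector(b[0].begin(), b[0].end()),
        NumericVector(b[1].begin(), b[1].end()),
        NumericVector(b[2].begin(), b[2].end()),
        NumericVector(b[3].begin(), b[3].end()),
        NumericVector(b[4].begin(), b[4].end())));
}
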