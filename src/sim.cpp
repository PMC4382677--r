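// Mean-field trial integration engine.
//
// One simulated trial = pre-stimulus (200 ms) + stimulus (1000 ms) +
// intertrial (500 ms) integrated at dt = 1 ms with a Heun step on the
// synaptic gating variables. Rates come from the standard effective
// f-I curve r(I) = (aI - b) / (1 - exp(-d (aI - b))). Background noise
// is an Ornstein-Uhlenbeck current per unit, advanced with the exact
// one-step update so that its stationary SD is sigma_n for any dt.
//
// The training loop, plasticity and decision readout live in R; this
// file only advances the dynamics and accumulates stimulus-period
// rate averages, so it stays a pure function of (state, weights, seed).
// The inner loop is allocation-free: the two large matrix-vector
// products per step go through BLAS dgemv accumulating directly into
// the current buffer, everything else is fused per-unit arithmetic.

#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// single-precision gemv (resolved from the OpenBLAS that backs R's BLAS).
// The two large per-step matrix-vector products run in float: their
// rounding error (~1e-6 nA on currents of order 0.5 nA) is three orders of
// magnitude below the background-noise SD, while halving the dominant cost.
extern "C" void sgemv_(const char *trans, const int *m, const int *n,
                       const float *alpha, const float *A, const int *lda,
                       const float *x, const int *incx, const float *beta,
                       float *y, const int *incy, size_t trans_len);

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ with splitmix64 seeding, ziggurat normals
// (Marsaglia-Tsang, 128 layers). R-level RNG is far too slow for the
// ~4e5 normal draws needed per trial.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  uint32_t buf32 = 0;
  bool have32 = false;
  inline uint32_t next32() { // both halves of each 64-bit draw are used
    if (have32) { have32 = false; return buf32; }
    uint64_t v = next();
    buf32 = (uint32_t)v;
    have32 = true;
    return (uint32_t)(v >> 32);
  }
};

static uint32_t zig_kn[128];
static double zig_wn[128], zig_fn[128];
static bool zig_ready = false;

static void zig_init() {
  const double m1 = 2147483648.0;
  double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
  double q = vn / std::exp(-0.5 * dn * dn);
  zig_kn[0] = (uint32_t)((dn / q) * m1);
  zig_kn[1] = 0;
  zig_wn[0] = q / m1;
  zig_wn[127] = dn / m1;
  zig_fn[0] = 1.0;
  zig_fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; i--) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    zig_kn[i + 1] = (uint32_t)((dn / tn) * m1);
    tn = dn;
    zig_fn[i] = std::exp(-0.5 * dn * dn);
    zig_wn[i] = dn / m1;
  }
  zig_ready = true;
}

static inline double rnorm_zig(Xoshiro &rng) {
  for (;;) {
    int32_t hz = (int32_t)rng.next32();
    uint32_t iz = (uint32_t)hz & 127u;
    uint32_t ahz = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (ahz < zig_kn[iz]) return hz * zig_wn[iz];
    const double r = 3.442619855899;
    if (iz == 0) { // tail
      double x, y;
      do {
        x = -std::log(rng.unif()) / r;
        y = -std::log(rng.unif());
      } while (y + y < x * x);
      return (hz > 0) ? r + x : -r - x;
    }
    double x = hz * zig_wn[iz];
    if (zig_fn[iz] + rng.unif() * (zig_fn[iz - 1] - zig_fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
    // else resample (loop)
  }
}

// [[Rcpp::export]]
arma::vec zig_normals(double seed, int n) {
  if (!zig_ready) zig_init();
  Xoshiro rng((uint64_t)seed);
  arma::vec out(n);
  for (int i = 0; i < n; ++i) out[i] = rnorm_zig(rng);
  return out;
}

// ---------------------------------------------------------------------------
// Vectorized exp (SSE2, Cephes-style Pade reduction, ~1 ulp): the inner loop
// evaluates exp for every unit every step, and scalar libm calls dominate
// the step cost otherwise. SSE2 is part of the x86-64 baseline.
// ---------------------------------------------------------------------------

#ifdef __SSE2__
#include <emmintrin.h>

static inline __m128d fastexp_pd(__m128d x) {
  x = _mm_min_pd(_mm_max_pd(x, _mm_set1_pd(-700.0)), _mm_set1_pd(700.0));
  // n = round(x / ln 2)
  __m128d fx = _mm_add_pd(_mm_mul_pd(x, _mm_set1_pd(1.4426950408889634074)),
                          _mm_set1_pd(0.5));
  __m128d fl = _mm_cvtepi32_pd(_mm_cvttpd_epi32(fx)); // trunc
  __m128d mask = _mm_and_pd(_mm_cmpgt_pd(fl, fx), _mm_set1_pd(1.0));
  fl = _mm_sub_pd(fl, mask); // floor(x/ln2 + 1/2)
  // r = x - n ln 2 (split constant for accuracy)
  x = _mm_sub_pd(x, _mm_mul_pd(fl, _mm_set1_pd(6.93145751953125e-1)));
  x = _mm_sub_pd(x, _mm_mul_pd(fl, _mm_set1_pd(1.42860682030941723212e-6)));
  __m128d xx = _mm_mul_pd(x, x);
  __m128d px = _mm_set1_pd(1.26177193074810590878e-4);
  px = _mm_add_pd(_mm_mul_pd(px, xx), _mm_set1_pd(3.02994407707441961300e-2));
  px = _mm_add_pd(_mm_mul_pd(px, xx), _mm_set1_pd(9.99999999999999999910e-1));
  px = _mm_mul_pd(px, x);
  __m128d qx = _mm_set1_pd(3.00198505138664455042e-6);
  qx = _mm_add_pd(_mm_mul_pd(qx, xx), _mm_set1_pd(2.52448340349684104192e-3));
  qx = _mm_add_pd(_mm_mul_pd(qx, xx), _mm_set1_pd(2.27265548208155028766e-1));
  qx = _mm_add_pd(_mm_mul_pd(qx, xx), _mm_set1_pd(2.0));
  __m128d e = _mm_div_pd(px, _mm_sub_pd(qx, px));
  e = _mm_add_pd(_mm_add_pd(e, e), _mm_set1_pd(1.0));
  // scale by 2^n via exponent bits
  __m128i ni = _mm_cvtpd_epi32(fl); // exact, fl integral
  ni = _mm_slli_epi32(_mm_add_epi32(ni, _mm_set1_epi32(1023)), 20);
  __m128i pow2 = _mm_unpacklo_epi32(_mm_setzero_si128(), ni);
  return _mm_mul_pd(e, _mm_castsi128_pd(pow2));
}

// out[i] = exp(in[i])
static inline void fastexp_vec(const double *in, double *out, int n) {
  int i = 0;
  for (; i + 1 < n; i += 2)
    _mm_storeu_pd(out + i, fastexp_pd(_mm_loadu_pd(in + i)));
  for (; i < n; ++i) {
    double buf[2] = {in[i], 0.0};
    __m128d v = fastexp_pd(_mm_loadu_pd(buf));
    _mm_storeu_pd(buf, v);
    out[i] = buf[0];
  }
}
#else
static inline void fastexp_vec(const double *in, double *out, int n) {
  for (int i = 0; i < n; ++i) out[i] = std::exp(in[i]);
}
#endif

// [[Rcpp::export]]
arma::vec fastexp_check(const arma::vec &x) {
  arma::vec out(x.n_elem);
  fastexp_vec(x.memptr(), out.memptr(), x.n_elem);
  return out;
}

// ---------------------------------------------------------------------------
// Transfer function and Heun gating step
// ---------------------------------------------------------------------------

static inline double transfer_one(double I, double a, double b, double d) {
  double x = a * I - b;
  double y = d * x;
  if (std::fabs(y) < 1e-6) {
    // removable singularity: x / (1 - exp(-dx)) = (1/d)(1 + y/2 + y^2/12 + ...)
    return (1.0 / d) * (1.0 + 0.5 * y + y * y / 12.0);
  }
  return x / (1.0 - std::exp(-y));
}

// Heun update of ds/dt = -s/tau_s + (1 - s) * gamma * r, r held fixed over
// the step; time in ms, r in Hz (hence the 1e-3 factor).
static inline double heun_s(double s, double r, double dt, double tau_s,
                            double gamma) {
  double g = gamma * r * 1e-3;
  double k1 = -s / tau_s + (1.0 - s) * g;
  double s1 = s + dt * k1;
  double k2 = -s1 / tau_s + (1.0 - s1) * g;
  double out = s + 0.5 * dt * (k1 + k2);
  if (out < 0.0) out = 0.0;
  if (out > 1.0) out = 1.0;
  return out;
}
// ---------------------------------------------------------------------------
// Trial engine
// ---------------------------------------------------------------------------

struct EnginePar {
  double gamma, tau_s, a, b, d, tau_n, sigma_n, dt;
  double I0s, I0a, I0d, I_gate, I_reset, threshold;
  int n_pre, n_stim, n_iti, n_reset, n_window;
  bool noise_on;
};

static EnginePar parse_par(const List &par) {
  EnginePar ep;
  ep.gamma = par["gamma"]; ep.tau_s = par["tau_s"];
  ep.a = par["a"]; ep.b = par["b"]; ep.d = par["d"];
  ep.tau_n = par["tau_n"]; ep.sigma_n = par["sigma_n"]; ep.dt = par["dt"];
  ep.I0s = par["I0_sens"]; ep.I0a = par["I0_assoc"]; ep.I0d = par["I0_dec"];
  ep.I_gate = par["gating_current"]; ep.I_reset = par["reset_current"];
  ep.threshold = par["threshold"];
  ep.n_pre = par["n_pre"]; ep.n_stim = par["n_stim"]; ep.n_iti = par["n_iti"];
  ep.n_reset = par["n_reset"]; ep.n_window = par["n_window"];
  ep.noise_on = par["noise_on"];
  return ep;
}

struct TrialOut {
  arma::vec acc;        // per-unit stimulus-period rate sums
  double accW0, accW1;  // decision-window rate sums
  bool prestim_cross;
};

// One trial: pre-stimulus, stimulus, intertrial. Gall is the combined
// float coupling block [[GS, 0], [WSA, GA]] (pre-divided by presynaptic
// counts and scaled by g_max); wad (2 x nA) and wda (nA x 2, may be NULL)
// are the effective pooled/feedback couplings. s and noise are updated in
// place; rates are accumulated over the stimulus period into `out`.
static void integrate_trial(const arma::fmat &Gall, const double *wad,
                            const double *wda, double J11, double J12,
                            double J21, double J22, const double *stim,
                            arma::vec &s, arma::vec &noise,
                            const EnginePar &ep, Xoshiro &rng, TrialOut &out,
                            int nS, int nA, arma::mat *trD = nullptr,
                            arma::mat *trA = nullptr, arma::mat *trS = nullptr) {
  const int n_tot = nS + nA + 2;
  const int n_steps = ep.n_pre + ep.n_stim + ep.n_iti;
  const int iD = nS + nA;
  const double ou_decay = std::exp(-ep.dt / ep.tau_n);
  const double ou_scale = ep.sigma_n * std::sqrt(1.0 - ou_decay * ou_decay);

  arma::fvec sf(nS + nA), obig(nS + nA);
  arma::vec I(n_tot), r(n_tot), ybuf(n_tot), ebuf(n_tot);
  out.acc.zeros(n_tot);
  out.accW0 = out.accW1 = 0.0;
  out.prestim_cross = false;

  double *Ip = I.memptr(), *sp = s.memptr(), *np = noise.memptr();
  const int m_big = nS + nA;
  const int one_i = 1;

  for (int t = 0; t < n_steps; ++t) {
    const bool in_stim = (t >= ep.n_pre) && (t < ep.n_pre + ep.n_stim);
    const bool in_reset = (t >= ep.n_pre + ep.n_stim) &&
                          (t < ep.n_pre + ep.n_stim + ep.n_reset);

    // baseline + noise + external currents
    if (in_stim) {
      for (int i = 0; i < nS; ++i) Ip[i] = ep.I0s + np[i] + stim[i];
    } else {
      for (int i = 0; i < nS; ++i) Ip[i] = ep.I0s + np[i];
    }
    for (int i = nS; i < iD; ++i) Ip[i] = ep.I0a + np[i];
    {
      double ext = (in_stim ? ep.I_gate : 0.0) + (in_reset ? ep.I_reset : 0.0);
      Ip[iD] = ep.I0d + np[iD] + ext + J11 * sp[iD] + J12 * sp[iD + 1];
      Ip[iD + 1] = ep.I0d + np[iD + 1] + ext + J21 * sp[iD] + J22 * sp[iD + 1];
    }
    // feedback D -> A and pooled A -> D (small, fused loops)
    {
      const double sd0 = sp[iD], sd1 = sp[iD + 1];
      double d0 = 0.0, d1 = 0.0;
      const double *sa = sp + nS;
      if (wda) {
        for (int j = 0; j < nA; ++j) {
          Ip[nS + j] += wda[j] * sd0 + wda[nA + j] * sd1;
          d0 += wad[2 * j] * sa[j];
          d1 += wad[2 * j + 1] * sa[j];
        }
      } else {
        for (int j = 0; j < nA; ++j) {
          d0 += wad[2 * j] * sa[j];
          d1 += wad[2 * j + 1] * sa[j];
        }
      }
      Ip[iD] += d0; Ip[iD + 1] += d1;
    }
    // I[0:(nS+nA)) += [[GS, 0], [WSA, GA]] * [sS; sA]
    {
      float *sfp = sf.memptr(), *ob = obig.memptr();
      for (int i = 0; i < nS + nA; ++i) sfp[i] = (float)sp[i];
      const float onef = 1.0f, zerof = 0.0f;
      sgemv_("N", &m_big, &m_big, &onef, Gall.memptr(), &m_big,
             sfp, &one_i, &zerof, ob, &one_i, 1);
      for (int i = 0; i < nS + nA; ++i) Ip[i] += (double)ob[i];
    }

    // rates, accumulation, gating and noise updates
    const bool acc_now = in_stim;
    double *yp = ybuf.memptr(), *ep_ = ebuf.memptr(), *rp = r.memptr();
    double *accp = out.acc.memptr();
    for (int i = 0; i < n_tot; ++i) yp[i] = -ep.d * (ep.a * Ip[i] - ep.b);
    fastexp_vec(yp, ep_, n_tot); // exp(-d (aI - b))
    bool finite_ok = true;
    for (int i = 0; i < n_tot; ++i) {
      double y = -yp[i];
      double ri;
      if (std::fabs(y) < 1e-6)
        ri = (1.0 / ep.d) * (1.0 + 0.5 * y + y * y / 12.0);
      else
        ri = (ep.a * Ip[i] - ep.b) / (1.0 - ep_[i]);
      rp[i] = ri;
      finite_ok = finite_ok && std::isfinite(ri);
      if (acc_now) accp[i] += ri;
      sp[i] = heun_s(sp[i], ri, ep.dt, ep.tau_s, ep.gamma);
    }
    if (ep.noise_on) {
      for (int i = 0; i < n_tot; ++i)
        np[i] = np[i] * ou_decay + ou_scale * rnorm_zig(rng);
    } else {
      for (int i = 0; i < n_tot; ++i) np[i] *= ou_decay;
    }
    if (!finite_ok)
      stop("non-finite firing rate at step %d: integration diverged", t);

    if (t < ep.n_pre && (rp[iD] >= ep.threshold || rp[iD + 1] >= ep.threshold))
      out.prestim_cross = true;
    if (in_stim && t >= ep.n_pre + ep.n_stim - ep.n_window) {
      out.accW0 += rp[iD]; out.accW1 += rp[iD + 1];
    }
    if (trD) { (*trD)(t, 0) = rp[iD]; (*trD)(t, 1) = rp[iD + 1]; }
    if (trS) {
      for (int i = 0; i < nS; ++i) (*trS)(t, i) = rp[i];
      for (int i = 0; i < nA; ++i) (*trA)(t, i) = rp[nS + i];
    }
  }
}

// [[Rcpp::export]]
List sim_trial_cpp(const arma::mat &GS, const arma::mat &GA,
                   const arma::mat &WSA, const arma::mat &WAD,
                   const arma::mat &WDA, const arma::mat &Jdec,
                   const arma::vec &stim, const arma::vec &s0,
                   const arma::vec &n0, const List &par) {
  if (!zig_ready) zig_init();
  EnginePar ep = parse_par(par);
  const double seed = par["seed"];
  const int record = par["record"]; // 0 none, 1 decision traces, 2 + rates

  const int nS = GS.n_rows, nA = GA.n_rows;
  const int n_tot = nS + nA + 2;
  const int n_steps = ep.n_pre + ep.n_stim + ep.n_iti;
  if ((int)WSA.n_rows != nA || (int)WSA.n_cols != nS ||
      (int)WAD.n_cols != nA || WAD.n_rows != 2 ||
      (int)WDA.n_rows != nA || WDA.n_cols != 2 ||
      (int)stim.n_elem != nS || (int)s0.n_elem != n_tot ||
      (int)n0.n_elem != n_tot)
    stop("sim_trial_cpp: inconsistent dimensions");

  arma::fmat Gall(nS + nA, nS + nA, arma::fill::zeros);
  Gall.submat(0, 0, nS - 1, nS - 1) = arma::conv_to<arma::fmat>::from(GS);
  Gall.submat(nS, 0, nS + nA - 1, nS - 1) =
      arma::conv_to<arma::fmat>::from(WSA);
  Gall.submat(nS, nS, nS + nA - 1, nS + nA - 1) =
      arma::conv_to<arma::fmat>::from(GA);

  arma::vec s = s0, noise = n0;
  arma::mat traceD, traceA, traceS;
  if (record >= 1) traceD.set_size(n_steps, 2);
  if (record >= 2) { traceA.set_size(n_steps, nA); traceS.set_size(n_steps, nS); }

  Xoshiro rng((uint64_t)seed);
  TrialOut out;
  integrate_trial(Gall, WAD.memptr(), WDA.memptr(), Jdec(0, 0), Jdec(0, 1),
                  Jdec(1, 0), Jdec(1, 1), stim.memptr(), s, noise, ep, rng,
                  out, nS, nA, record >= 1 ? &traceD : nullptr,
                  record >= 2 ? &traceA : nullptr,
                  record >= 2 ? &traceS : nullptr);

  const int iD = nS + nA;
  List res = List::create(
      _["mean_r_sens"] = out.acc.subvec(0, nS - 1) / ep.n_stim,
      _["mean_r_assoc"] = out.acc.subvec(nS, iD - 1) / ep.n_stim,
      _["mean_r_dec"] = out.acc.subvec(iD, iD + 1) / ep.n_stim,
      _["window_r_dec"] = arma::vec({out.accW0 / ep.n_window,
                                     out.accW1 / ep.n_window}),
      _["prestim_cross"] = out.prestim_cross, _["s_end"] = s,
      _["noise_end"] = noise);
  if (record >= 1) res["trace_dec"] = traceD;
  if (record >= 2) { res["trace_assoc"] = traceA; res["trace_sens"] = traceS; }
  return res;
}

// clipped outer-product update  C += eta * post %o% pre, in place
static inline void hebb_outer(arma::mat &C, const double *post,
                              const double *pre, double eta) {
  const int nr = C.n_rows, nc = C.n_cols;
  double *cp = C.memptr();
  for (int j = 0; j < nc; ++j) {
    const double ej = eta * pre[j];
    double *col = cp + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      double v = col[i] + ej * post[i];
      col[i] = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
    }
  }
}

// Full training / frozen-evaluation loop. Stimulus sequence and per-trial
// engine seeds are drawn in R (so a pure-R loop over run_trial with the
// same vectors is an exact reference); this function owns the dynamics,
// decision readout, reward, reward-expectation tracking and plasticity.
// [[Rcpp::export]]
List train_loop_cpp(arma::mat c_sa, arma::mat c_ad, arma::mat c_da,
                    const arma::mat &GS, const arma::mat &GA,
                    const arma::mat &Jdec, const arma::mat &stim_mat,
                    const IntegerVector &theta_idx,
                    const IntegerVector &cat_idx,
                    const NumericVector &trial_seeds,
                    const NumericVector &rexp0,
                    arma::vec s, arma::vec noise, const List &par) {
  if (!zig_ready) zig_init();
  EnginePar ep = parse_par(par);
  const int nS = GS.n_rows, nA = GA.n_rows;
  const int n = theta_idx.size();
  const int K = stim_mat.n_cols;
  const double g_sa = par["g_max_sa"], g_ad = par["g_max_ad"],
               g_da = par["g_max_da"];
  const double q_sa = par["q_sa"], q_ad = par["q_ad"], q_da = par["q_da"];
  const double tau_r = par["tau_r"];
  const bool freeze_sa = par["freeze_sa"], plastic = par["plastic"];
  const bool has_da = c_da.n_elem > 0;
  const int record_rates = par["record_rates"]; // 0 / 1 (assoc) / 2 (+sens)
  if ((int)stim_mat.n_rows != nS || cat_idx.size() != K ||
      trial_seeds.size() != n || rexp0.size() != K)
    stop("train_loop_cpp: inconsistent dimensions");

  arma::fmat Gall(nS + nA, nS + nA, arma::fill::zeros);
  Gall.submat(0, 0, nS - 1, nS - 1) = arma::conv_to<arma::fmat>::from(GS);
  Gall.submat(nS, nS, nS + nA - 1, nS + nA - 1) =
      arma::conv_to<arma::fmat>::from(GA);
  // WSA block refreshed whenever c_sa changes
  auto refresh_wsa = [&]() {
    const double sc = g_sa / nS;
    float *gp = Gall.memptr();
    const double *cp = c_sa.memptr();
    const int m = nS + nA;
    for (int j = 0; j < nS; ++j) {
      float *col = gp + (size_t)j * m + nS;
      const double *cc = cp + (size_t)j * nA;
      for (int i = 0; i < nA; ++i) col[i] = (float)(sc * cc[i]);
    }
  };
  refresh_wsa();

  arma::vec wad_eff(2 * (size_t)nA), wda_eff(has_da ? 2 * (size_t)nA : 0);
  auto refresh_ad = [&]() {
    const double sc = g_ad / nA;
    for (int j = 0; j < nA; ++j) {
      wad_eff[2 * j] = sc * c_ad(0, j);
      wad_eff[2 * j + 1] = sc * c_ad(1, j);
    }
  };
  auto refresh_da = [&]() {
    if (!has_da) return;
    const double sc = g_da / 2.0;
    for (int j = 0; j < nA; ++j) {
      wda_eff[j] = sc * c_da(j, 0);
      wda_eff[nA + j] = sc * c_da(j, 1);
    }
  };
  refresh_ad(); refresh_da();

  std::vector<double> rexp(rexp0.begin(), rexp0.end());
  IntegerVector choice(n);      // 0 invalid, 1 C1, 2 C2
  NumericVector reward(n), rexp_log(n);
  arma::mat ratesA, ratesS;
  if (record_rates >= 1) ratesA.set_size(n, nA);
  if (record_rates >= 2) ratesS.set_size(n, nS);

  TrialOut out;
  arma::vec meanS(nS), meanA(nA), meanD(2);
  for (int t = 0; t < n; ++t) {
    const int k = theta_idx[t] - 1;
    if (k < 0 || k >= K) stop("train_loop_cpp: theta index out of range");
    Xoshiro rng((uint64_t)trial_seeds[t]);
    integrate_trial(Gall, wad_eff.memptr(),
                    has_da ? wda_eff.memptr() : nullptr,
                    Jdec(0, 0), Jdec(0, 1), Jdec(1, 0), Jdec(1, 1),
                    stim_mat.colptr(k), s, noise, ep, rng, out, nS, nA);
    const double w0 = out.accW0 / ep.n_window, w1 = out.accW1 / ep.n_window;
    const bool up0 = w0 > ep.threshold, up1 = w1 > ep.threshold;
    int ch = 0;
    if (!out.prestim_cross && (up0 != up1)) ch = up0 ? 1 : 2;
    choice[t] = ch;
    rexp_log[t] = rexp[k];
    for (int i = 0; i < nS; ++i) meanS[i] = out.acc[i] / ep.n_stim;
    for (int i = 0; i < nA; ++i) meanA[i] = out.acc[nS + i] / ep.n_stim;
    meanD[0] = out.acc[nS + nA] / ep.n_stim;
    meanD[1] = out.acc[nS + nA + 1] / ep.n_stim;
    if (record_rates >= 1) ratesA.row(t) = meanA.t();
    if (record_rates >= 2) ratesS.row(t) = meanS.t();
    if (ch == 0) {
      reward[t] = NA_REAL;
      continue;
    }
    const double R = (ch == cat_idx[k]) ? 1.0 : 0.0;
    reward[t] = R;
    if (plastic) {
      const double rpe = R - rexp[k];
      if (!freeze_sa && q_sa > 0) {
        hebb_outer(c_sa, meanA.memptr(), meanS.memptr(), q_sa * rpe);
        refresh_wsa();
      }
      if (q_ad > 0) {
        hebb_outer(c_ad, meanD.memptr(), meanA.memptr(), q_ad * rpe);
        refresh_ad();
      }
      if (has_da && q_da > 0) {
        hebb_outer(c_da, meanA.memptr(), meanD.memptr(), q_da * rpe);
        refresh_da();
      }
      rexp[k] += (R - rexp[k]) / tau_r;
    }
  }

  List res = List::create(
      _["choice"] = choice, _["reward"] = reward, _["rexp"] = rexp_log,
      _["c_sa"] = c_sa, _["c_ad"] = c_ad,
      _["c_da"] = has_da ? wrap(c_da) : R_NilValue,
      _["rexp_final"] = NumericVector(rexp.begin(), rexp.end()),
      _["s_end"] = s, _["noise_end"] = noise);
  if (record_rates >= 1) res["rates_assoc"] = ratesA;
  if (record_rates >= 2) res["rates_sens"] = ratesS;
  return res;
}
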