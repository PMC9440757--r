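#include <Rcpp.h>
using namespace Rcpp;

// Variant codes shared with R/variants.R:
// 1 sequestration, 2 sequestration_z, 3 repression, 4 mixed,
// 5 sequestration_S, 6 full_complex

namespace {

// integer-exponent fast paths for the Hill/self-repression powers
inline double powfast(double u, double n) {
  if (n == 1.0) return u;
  if (n == 2.0) return u * u;
  if (n == 3.0) return u * u * u;
  return std::pow(u, n);
}

struct Pars {
  double alpha_L, alpha, k_B, n;
  double gamma, k_W, h;
  double beta_L, beta, k_Z, c, alpha_0;
  double d_B, d_W, d_Z, lambda;
  double D_W, D_Z;
  double alpha_S, d_S, lambda_S, D_S;
  double k_on, k_off, d_C;
  double kBn, kZn; // precomputed k^n
  int variant, hillmode;
  bool self_rep, basal, mutant;
};

inline double prodB(const Pars& p, double act, double theta, double vi) {
  double r;
  if (p.hillmode) {
    double un = act > 0.0 ? powfast(act, p.n) : 0.0;
    r = p.alpha * un / (p.kBn + un) * theta;
  } else {
    r = p.alpha_L * act * theta;
  }
  if (p.basal) r += p.alpha_0 * vi;
  return r;
}

inline double prodW(const Pars& p, double W, double qc) {
  double r = p.gamma * qc;
  if (p.self_rep && r > 0.0) r /= 1.0 + powfast(W / p.k_W, p.h);
  return r;
}

inline double prodZ(const Pars& p, double W, double B) {
  double r;
  if (p.hillmode) {
    double un = W > 0.0 ? powfast(W, p.n) : 0.0;
    r = p.beta * un / (p.kZn + un);
  } else {
    r = p.beta_L * W;
  }
  if (p.variant == 3 || p.variant == 4) r /= 1.0 + p.c * B;
  return r;
}

} // namespace

// Forward-Euler integration of one 1D model variant on a uniform grid with
// zero-Dirichlet boundaries (periodic for the sequestrator S only).
// Reaction terms are evaluated pointwise; the Laplacian uses the standard
// central three-point stencil. Returns final fields plus convergence info.
// [[Rcpp::export(name = ".euler1d_cpp")]]
List euler1d_cpp(List pars, NumericVector qc, NumericVector theta,
                 NumericVector vi, double dx, double dt, int nsteps) {
  Pars p;
  p.alpha_L = pars["alpha_L"]; p.alpha = pars["alpha"];
  p.k_B = pars["k_B"]; p.n = pars["n"];
  p.gamma = pars["gamma"]; p.k_W = pars["k_W"]; p.h = pars["h"];
  p.beta_L = pars["beta_L"]; p.beta = pars["beta"]; p.k_Z = pars["k_Z"];
  p.c = pars["c"]; p.alpha_0 = pars["alpha_0"];
  p.d_B = pars["d_B"]; p.d_W = pars["d_W"]; p.d_Z = pars["d_Z"];
  p.lambda = pars["lambda"];
  p.D_W = pars["D_W"]; p.D_Z = pars["D_Z"];
  p.alpha_S = pars["alpha_S"]; p.d_S = pars["d_S"];
  p.lambda_S = pars["lambda_S"]; p.D_S = pars["D_S"];
  p.k_on = pars["k_on"]; p.k_off = pars["k_off"]; p.d_C = pars["d_C"];
  p.variant = pars["variant"]; p.hillmode = pars["hillmode"];
  p.self_rep = pars["self_rep"]; p.basal = pars["basal"];
  p.mutant = pars["mutant"];
  p.kBn = std::pow(p.k_B, p.n);
  p.kZn = std::pow(p.k_Z, p.n);

  const int n = qc.size();
  const bool has_z = (p.variant == 2 || p.variant == 3 || p.variant == 4);
  const bool has_s = (p.variant == 5);
  const bool has_c = (p.variant == 6);
  const double idx2 = 1.0 / (dx * dx);
  const double cW = p.D_W * idx2, cZ = p.D_Z * idx2, cS = p.D_S * idx2;
  const double* qcp = qc.begin();
  const double* thp = theta.begin();
  const double* vip = vi.begin();

  std::vector<double> B(n, 0.0), W(n, 0.0), Z(n, 0.0), S(n, 0.0), C(n, 0.0);
  std::vector<double> Wn(n, 0.0), Zn(n, 0.0), Sn(n, 0.0);
  std::vector<double> snapB, snapW, snapZ;
  int snap_at = (int)std::floor(0.99 * nsteps);
  if (snap_at >= nsteps) snap_at = nsteps - 1;

  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < n; ++i) {
      const double Wi = W[i], Bi = B[i];
      const double act = has_z ? Z[i] : Wi;
      const double pb = prodB(p, act, thp[i], vip[i]);
      const double pw = prodW(p, Wi, qcp[i]);
      const double bw = Bi * Wi;

      double dW = pw - p.d_W * Wi;
      if (has_c) {
        dW += -p.k_on * bw + p.k_off * C[i];
        if (!p.mutant) {
          B[i] += dt * (pb - p.d_B * Bi - p.k_on * bw + p.k_off * C[i]);
          C[i] += dt * (p.k_on * bw - (p.k_off + p.d_C) * C[i]);
        }
      } else {
        dW -= p.lambda * bw;
        if (!p.mutant) B[i] += dt * (pb - p.d_B * Bi - p.lambda * bw);
      }
      if (has_s) {
        dW -= p.lambda_S * S[i] * Wi;
        double dS = p.alpha_S - p.d_S * S[i] - p.lambda_S * S[i] * Wi;
        int im = (i == 0) ? n - 1 : i - 1;
        int ip = (i == n - 1) ? 0 : i + 1;
        dS += cS * (S[im] - 2.0 * S[i] + S[ip]); // periodic for S
        Sn[i] = S[i] + dt * dS;
      }
      if (i > 0 && i < n - 1)
        dW += cW * (W[i - 1] - 2.0 * Wi + W[i + 1]);
      Wn[i] = Wi + dt * dW;
      if (has_z) {
        double dZ = prodZ(p, Wi, Bi) - p.d_Z * Z[i];
        if (i > 0 && i < n - 1)
          dZ += cZ * (Z[i - 1] - 2.0 * Z[i] + Z[i + 1]);
        Zn[i] = Z[i] + dt * dZ;
      }
    }
    W.swap(Wn);
    if (has_z) Z.swap(Zn);
    if (has_s) S.swap(Sn);
    // zero-Dirichlet boundaries for B, W, Z (not S: periodic)
    B[0] = B[n - 1] = 0.0;
    W[0] = W[n - 1] = 0.0;
    if (has_z) { Z[0] = Z[n - 1] = 0.0; }
    if (has_c) { C[0] = C[n - 1] = 0.0; }

    if (!std::isfinite(W[n / 2]))
      stop("forward-Euler overflow (NaN/Inf) at step %d; reduce dt", step + 1);

    if (step == snap_at) { snapB = B; snapW = W; snapZ = Z; }
  }

  // final-state residual: max |du/dt| of the reaction-diffusion rhs
  double resid = 0.0, relchg = 0.0, scale = 0.0;
  for (int i = 1; i < n - 1; ++i) {
    double act = has_z ? Z[i] : W[i];
    double pb = prodB(p, act, thp[i], vip[i]);
    double pw = prodW(p, W[i], qcp[i]);
    double bw = B[i] * W[i];
    double rW = pw - p.d_W * W[i]
                + cW * (W[i - 1] - 2.0 * W[i] + W[i + 1]);
    rW -= has_c ? (p.k_on * bw - p.k_off * C[i]) : p.lambda * bw;
    if (has_s) rW -= p.lambda_S * S[i] * W[i];
    resid = std::max(resid, std::fabs(rW));
    if (!p.mutant) {
      double rB = has_c ? pb - p.d_B * B[i] - p.k_on * bw + p.k_off * C[i]
                        : pb - p.d_B * B[i] - p.lambda * bw;
      resid = std::max(resid, std::fabs(rB));
    }
    if (has_z) {
      double rZ = prodZ(p, W[i], B[i]) - p.d_Z * Z[i]
                  + cZ * (Z[i - 1] - 2.0 * Z[i] + Z[i + 1]);
      resid = std::max(resid, std::fabs(rZ));
    }
    scale = std::max(scale, std::fabs(W[i]));
    relchg = std::max(relchg, std::fabs(W[i] - snapW[i]));
    if (!p.mutant) relchg = std::max(relchg, std::fabs(B[i] - snapB[i]));
    if (has_z) relchg = std::max(relchg, std::fabs(Z[i] - snapZ[i]));
  }
  if (scale > 0.0) relchg /= scale;

  return List::create(_["B"] = NumericVector(B.begin(), B.end()),
                      _["W"] = NumericVector(W.begin(), W.end()),
                      _["Z"] = NumericVector(Z.begin(), Z.end()),
                      _["S"] = NumericVector(S.begin(), S.end()),
                      _["C"] = NumericVector(C.begin(), C.end()),
                      _["residual"] = resid, _["rel_change"] = relchg);
}
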