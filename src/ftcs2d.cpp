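#include <Rcpp.h>
using namespace Rcpp;

// Conservative (flux-form) heterogeneous-diffusion operator div(D grad u).
// Face diffusivity between two pixels is the arithmetic mean of the two
// pixel values, except that a face with a zero diffusivity on either side
// carries no flux at all: this makes zero-D regions (outside the root,
// walls for wall-blocked species) reflecting boundaries automatically.
static void het_lap(const double* u, const double* D, int nr, int nc,
                    double idx2, double idy2, double* out) {
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = i + j * nr;
      double acc = 0.0, Dk = D[k];
      if (Dk > 0.0) {
        if (i > 0 && D[k - 1] > 0.0)
          acc += 0.5 * (Dk + D[k - 1]) * (u[k - 1] - u[k]) * idx2;
        if (i < nr - 1 && D[k + 1] > 0.0)
          acc += 0.5 * (Dk + D[k + 1]) * (u[k + 1] - u[k]) * idx2;
        if (j > 0 && D[k - nr] > 0.0)
          acc += 0.5 * (Dk + D[k - nr]) * (u[k - nr] - u[k]) * idy2;
        if (j < nc - 1 && D[k + nr] > 0.0)
          acc += 0.5 * (Dk + D[k + nr]) * (u[k + nr] - u[k]) * idy2;
      }
      out[k] = acc;
    }
  }
}

// [[Rcpp::export(name = ".het_laplacian_cpp")]]
NumericMatrix het_laplacian_cpp(NumericMatrix u, NumericMatrix D,
                                double dx, double dy) {
  int nr = u.nrow(), nc = u.ncol();
  if (D.nrow() != nr || D.ncol() != nc) stop("field/D map shape mismatch");
  NumericMatrix out(nr, nc);
  het_lap(u.begin(), D.begin(), nr, nc, 1.0 / (dx * dx), 1.0 / (dy * dy),
          out.begin());
  return out;
}

// integer-exponent fast paths for the Hill/self-repression powers
static inline double powfast(double u, double n) {
  if (n == 1.0) return u;
  if (n == 2.0) return u * u;
  if (n == 3.0) return u * u * u;
  return std::pow(u, n);
}

static inline double hill_act(double u, double vmax, double kn, double n) {
  if (u <= 0.0 || vmax == 0.0) return 0.0;
  double un = powfast(u, n);
  return vmax * un / (kn + un);
}

// FTCS run of the 2D mixed model (and its lambda=0 / c=0 reductions) with
// GFP reporters on a labeled pixel lattice. Rate maps carry the per-pixel
// production rates (already masked by cell type); `cell` is 1 on pixels
// where reactions may occur (cell interiors), 0 on walls and outside.
// [[Rcpp::export(name = ".ftcs2d_cpp")]]
List ftcs2d_cpp(List fields, List Dmaps, NumericMatrix alpha_map,
                NumericMatrix alpha0_map, NumericMatrix gamma_map,
                NumericMatrix cell, List pars, double dx, double dy,
                double dt, int nsteps) {
  NumericMatrix B = clone(as<NumericMatrix>(fields["B"]));
  NumericMatrix W = clone(as<NumericMatrix>(fields["W"]));
  NumericMatrix Z = clone(as<NumericMatrix>(fields["Z"]));
  NumericMatrix BG = clone(as<NumericMatrix>(fields["B_GFP"]));
  NumericMatrix WG = clone(as<NumericMatrix>(fields["W_GFP"]));
  NumericMatrix ZG = clone(as<NumericMatrix>(fields["Z_GFP"]));
  NumericMatrix DB = Dmaps["B"], DW = Dmaps["W"], DZ = Dmaps["Z"],
                DG = Dmaps["GFP"];

  const double k_B = pars["k_B"], n = pars["n"], beta = pars["beta"],
               k_Z = pars["k_Z"], c = pars["c"], k_W = pars["k_W"],
               h = pars["h"], lambda = pars["lambda"], d_B = pars["d_B"],
               d_W = pars["d_W"], d_Z = pars["d_Z"], d_GFP = pars["d_GFP"];
  const bool self_rep = pars["self_rep"], mutant = pars["mutant"],
             has_z = pars["has_z"];

  const int nr = B.nrow(), nc = B.ncol(), npx = nr * nc;
  const double idx2 = 1.0 / (dx * dx), idy2 = 1.0 / (dy * dy);
  const double kBn = std::pow(k_B, n), kZn = std::pow(k_Z, n);

  // D maps are constant over a run: precompute the four face-diffusivity
  // arrays (zero where either side has zero D) once per species
  struct Faces { std::vector<double> N, S, Wf, E; };
  auto make_faces = [&](const NumericMatrix& D) {
    Faces f;
    f.N.assign(npx, 0.0); f.S.assign(npx, 0.0);
    f.Wf.assign(npx, 0.0); f.E.assign(npx, 0.0);
    const double* Dp = D.begin();
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        int k = i + j * nr;
        if (Dp[k] <= 0.0) continue;
        if (i > 0 && Dp[k - 1] > 0.0)
          f.N[k] = 0.5 * (Dp[k] + Dp[k - 1]) * idx2;
        if (i < nr - 1 && Dp[k + 1] > 0.0)
          f.S[k] = 0.5 * (Dp[k] + Dp[k + 1]) * idx2;
        if (j > 0 && Dp[k - nr] > 0.0)
          f.Wf[k] = 0.5 * (Dp[k] + Dp[k - nr]) * idy2;
        if (j < nc - 1 && Dp[k + nr] > 0.0)
          f.E[k] = 0.5 * (Dp[k] + Dp[k + nr]) * idy2;
      }
    return f;
  };
  Faces fB = make_faces(DB), fW = make_faces(DW), fZ = make_faces(DZ),
        fG = make_faces(DG);
  std::vector<double> buf(npx);

  // per-species update: u += dt * (reaction + div(D grad u))
  auto step_species = [&](NumericMatrix& u, const Faces& f,
                          const std::vector<double>& reac) {
    const double* up = u.begin();
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        int k = i + j * nr;
        double uk = up[k], acc = reac[k];
        if (f.N[k] != 0.0) acc += f.N[k] * (up[k - 1] - uk);
        if (f.S[k] != 0.0) acc += f.S[k] * (up[k + 1] - uk);
        if (f.Wf[k] != 0.0) acc += f.Wf[k] * (up[k - nr] - uk);
        if (f.E[k] != 0.0) acc += f.E[k] * (up[k + nr] - uk);
        buf[k] = uk + dt * acc;
      }
    }
    std::copy(buf.begin(), buf.end(), u.begin());
  };

  std::vector<double> rB(npx), rW(npx), rZ(npx), rBG(npx), rWG(npx), rZG(npx);

  for (int step = 0; step < nsteps; ++step) {
    const double* Bp = B.begin();
    const double* Wp = W.begin();
    const double* Zp = Z.begin();
    const double* BGp = BG.begin();
    const double* WGp = WG.begin();
    const double* ZGp = ZG.begin();
    const double* cp = cell.begin();
    for (int k = 0; k < npx; ++k) {
      if (cp[k] == 0.0) { // walls/outside: diffusion only
        rB[k] = rW[k] = rZ[k] = rBG[k] = rWG[k] = rZG[k] = 0.0;
        continue;
      }
      double act = has_z ? Zp[k] : Wp[k];
      double pB = hill_act(act, alpha_map[k], kBn, n) + alpha0_map[k];
      double pW = gamma_map[k];
      if (self_rep && pW > 0.0) pW /= 1.0 + powfast(Wp[k] / k_W, h);
      double pZ = hill_act(Wp[k], beta, kZn, n) / (1.0 + c * Bp[k]);
      double bw = lambda * Bp[k] * Wp[k];
      rB[k] = pB - d_B * Bp[k] - bw;
      rW[k] = pW - d_W * Wp[k] - bw;
      rZ[k] = pZ - d_Z * Zp[k];
      rBG[k] = pB - d_GFP * BGp[k];
      rWG[k] = pW - d_GFP * WGp[k];
      rZG[k] = pZ - d_GFP * ZGp[k];
    }
    if (!mutant) step_species(B, fB, rB);
    step_species(W, fW, rW);
    if (has_z) step_species(Z, fZ, rZ);
    step_species(BG, fG, rBG);
    step_species(WG, fG, rWG);
    if (has_z) step_species(ZG, fG, rZG);

    if (!std::isfinite(W[npx / 2]))
      stop("FTCS overflow (NaN/Inf) at step %d; reduce dt", step + 1);
  }

  return List::create(_["B"] = B, _["W"] = W, _["Z"] = Z, _["B_GFP"] = BG,
                      _["W_GFP"] = WG, _["Z_GFP"] = ZG);
}

// Zhang-Suen morphological thinning of a binary mask down to a 1-pixel
// skeleton (8-connected), used by the segmentation routine before the
// walls are re-dilated to their fixed 2-pixel width.
// [[Rcpp::export(name = ".thin_cpp")]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix im = clone(mask);
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return im(i, j) != 0;
  };
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!im(i, j)) continue;
          // neighbours P2..P9 clockwise from north
          int p[8] = {at(i - 1, j),     at(i - 1, j + 1), at(i, j + 1),
                      at(i + 1, j + 1), at(i + 1, j),     at(i + 1, j - 1),
                      at(i, j - 1),     at(i - 1, j - 1)};
          int bsum = 0, a = 0;
          for (int q = 0; q < 8; ++q) {
            bsum += p[q];
            if (!p[q] && p[(q + 1) % 8]) ++a;
          }
          if (bsum < 2 || bsum > 6 || a != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      for (size_t q = 0; q < kill.size(); ++q)
        im(kill[q].first, kill[q].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return im;
}
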