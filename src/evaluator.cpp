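// Incremental registration-cost evaluator.
//
// The composite cost  alpha1 * (-MI) + alpha2 * V  is evaluated over a fixed
// sample-point set whose B-spline interpolation weights are precomputed in R.
// Moving one control-point coordinate only changes the displacement (and
// hence the warped intensity, histogram bin and curvature terms) of the
// samples inside that control point's support, so a coordinate-descent trial
// move is O(support) instead of O(image): joint/marginal histogram counts and
// the entropy sums  S = sum c*log2(c)  are patched cell by cell, and the
// bending sum of squares is patched row by row. A full recompute at every
// sweep start bounds floating-point drift from the incremental updates.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

struct Evaluator {
  int nd = 2;                 // 2 or 3 spatial dimensions
  int n = 0;                  // sample points
  int K = 16;                 // 4^nd tensor weights per point
  int bins = 32;
  int ncp = 0;                // control points per displacement component
  int nterm = 3;              // unique second-derivative terms
  double alpha1 = 1.0, alpha2 = 0.0;

  std::vector<double> pts;    // n * nd, physical sample coordinates
  std::vector<double> W0;     // n * K displacement weights
  std::vector<int>    IDX;    // n * K 0-based control indices
  std::vector<double> W2;     // nterm * n * K second-derivative weights
  std::vector<double> wterm;  // term multipliers (cross terms doubled)
  std::vector<int> ia;        // 0-based reference bins per sample

  std::vector<double> Bimg;   // floating image, column-major
  int Bdim[3] = {1, 1, 1};
  double Borig[3] = {0, 0, 0}, Bspac[3] = {1, 1, 1};
  double blo = 0.0, bwidth = 1.0;   // fixed floating-intensity binning

  // reverse map: for control j, which (row, slot) pairs touch it
  std::vector<int> rev_ptr, rev_row, rev_k;

  // state
  std::vector<double> phi;    // nd * ncp
  std::vector<double> disp;   // nd * n (component-major)
  std::vector<double> d2;     // nterm * nd * n
  std::vector<int> ibv;       // current floating bin per sample, -1 = invalid
  std::vector<int> joint, ca, cb;
  int64_t Nvalid = 0;
  double S_j = 0, S_a = 0, S_b = 0;   // sum c*log2(c) of joint/marginals
  double Ssq = 0;                     // weighted bending sum of squares
  std::vector<double> xlog2;          // xlog2[c] = c*log2(c)

  double xl(int c) const { return xlog2[c]; }

  double sample_B(double x, double y, double z) const {
    // continuous 0-based voxel coords; bilinear/trilinear, NaN outside
    if (x < 0 || x > Bdim[0] - 1 || y < 0 || y > Bdim[1] - 1) return NA_REAL;
    int i0 = (int)std::floor(x); if (i0 > Bdim[0] - 2) i0 = Bdim[0] - 2; if (i0 < 0) i0 = 0;
    int j0 = (int)std::floor(y); if (j0 > Bdim[1] - 2) j0 = Bdim[1] - 2; if (j0 < 0) j0 = 0;
    double fx = x - i0, fy = y - j0;
    if (nd == 2) {
      const double *b = Bimg.data() + (size_t)j0 * Bdim[0] + i0;
      double v0 = b[0] * (1 - fx) + b[1] * fx;
      double v1 = b[Bdim[0]] * (1 - fx) + b[Bdim[0] + 1] * fx;
      return v0 * (1 - fy) + v1 * fy;
    }
    if (z < 0 || z > Bdim[2] - 1) return NA_REAL;
    int k0 = (int)std::floor(z); if (k0 > Bdim[2] - 2) k0 = Bdim[2] - 2; if (k0 < 0) k0 = 0;
    double fz = z - k0;
    size_t pl = (size_t)Bdim[0] * Bdim[1];
    double acc = 0;
    for (int dz = 0; dz <= 1; ++dz) {
      const double *b = Bimg.data() + (size_t)(k0 + dz) * pl + (size_t)j0 * Bdim[0] + i0;
      double v0 = b[0] * (1 - fx) + b[1] * fx;
      double v1 = b[Bdim[0]] * (1 - fx) + b[Bdim[0] + 1] * fx;
      acc += (v0 * (1 - fy) + v1 * fy) * (dz ? fz : 1 - fz);
    }
    return acc;
  }

  int bin_of(double v) const {
    int b = (int)std::floor((v - blo) / bwidth);
    if (b < 0) b = 0;
    if (b >= bins) b = bins - 1;
    return b;
  }

  // histogram bookkeeping -----------------------------------------------
  void hist_remove(int a, int b) {
    int &cj = joint[(size_t)b * bins + a];
    S_j += xl(cj - 1) - xl(cj); --cj;
    int &na = ca[a]; S_a += xl(na - 1) - xl(na); --na;
    int &nb = cb[b]; S_b += xl(nb - 1) - xl(nb); --nb;
    --Nvalid;
  }
  void hist_add(int a, int b) {
    int &cj = joint[(size_t)b * bins + a];
    S_j += xl(cj + 1) - xl(cj); ++cj;
    int &na = ca[a]; S_a += xl(na + 1) - xl(na); ++na;
    int &nb = cb[b]; S_b += xl(nb + 1) - xl(nb); ++nb;
    ++Nvalid;
  }

  void resample_row(int r) {
    double x = (pts[r] + disp[r] - Borig[0]) / Bspac[0];
    double y = (pts[(size_t)n + r] + disp[(size_t)n + r] - Borig[1]) / Bspac[1];
    double z = 0;
    if (nd == 3) z = (pts[2 * (size_t)n + r] + disp[2 * (size_t)n + r] - Borig[2]) / Bspac[2];
    double v = sample_B(x, y, z);
    int nb = ISNAN(v) ? -1 : bin_of(v);
    int ob = ibv[r];
    if (ob == nb && ob >= 0) {
      // bin unchanged: nothing to patch (value may differ inside the bin)
      return;
    }
    if (ob >= 0) hist_remove(ia[r], ob);
    if (nb >= 0) hist_add(ia[r], nb);
    ibv[r] = nb;
  }

  void full_recompute() {
    std::fill(joint.begin(), joint.end(), 0);
    std::fill(ca.begin(), ca.end(), 0);
    std::fill(cb.begin(), cb.end(), 0);
    Nvalid = 0; S_j = S_a = S_b = 0; Ssq = 0;
    // displacements and second derivatives from scratch
    for (int c = 0; c < nd; ++c) {
      for (int r = 0; r < n; ++r) {
        double acc = 0;
        for (int k = 0; k < K; ++k)
          acc += W0[(size_t)k * n + r] * phi[(size_t)c * ncp + IDX[(size_t)k * n + r]];
        disp[(size_t)c * n + r] = acc;
      }
      for (int t = 0; t < nterm; ++t) {
        const double *w2 = W2.data() + (size_t)t * n * K;
        for (int r = 0; r < n; ++r) {
          double acc = 0;
          for (int k = 0; k < K; ++k)
            acc += w2[(size_t)k * n + r] * phi[(size_t)c * ncp + IDX[(size_t)k * n + r]];
          d2[((size_t)t * nd + c) * n + r] = acc;
          Ssq += wterm[t] * acc * acc;
        }
      }
    }
    for (int r = 0; r < n; ++r) {
      ibv[r] = -1;
      double x = (pts[r] + disp[r] - Borig[0]) / Bspac[0];
      double y = (pts[(size_t)n + r] + disp[(size_t)n + r] - Borig[1]) / Bspac[1];
      double z = 0;
      if (nd == 3) z = (pts[2 * (size_t)n + r] + disp[2 * (size_t)n + r] - Borig[2]) / Bspac[2];
      double v = sample_B(x, y, z);
      if (!ISNAN(v)) { ibv[r] = bin_of(v); hist_add(ia[r], ibv[r]); }
    }
  }

  double mi() const {
    if (Nvalid == 0) return R_NegInf;
    double N = (double)Nvalid;
    return std::log2(N) - (S_a + S_b - S_j) / N;
  }
  double bending() const { return Ssq / n; }
  double total() const {
    if (Nvalid == 0) return R_PosInf;
    return alpha1 * (-mi()) + alpha2 * bending();
  }

  // apply a move of coordinate p (0-based over nd*ncp) by delta
  void apply_move(int p, double delta) {
    int j = p % ncp, c = p / ncp;
    phi[p] += delta;
    for (int e = rev_ptr[j]; e < rev_ptr[j + 1]; ++e) {
      int r = rev_row[e], k = rev_k[e];
      disp[(size_t)c * n + r] += W0[(size_t)k * n + r] * delta;
      for (int t = 0; t < nterm; ++t) {
        double w2 = W2[((size_t)t * K + k) * n + r];
        if (w2 != 0) {
          double &v = d2[((size_t)t * nd + c) * n + r];
          double nv = v + w2 * delta;
          Ssq += wterm[t] * (nv * nv - v * v);
          v = nv;
        }
      }
      resample_row(r);
    }
  }
};

static Evaluator* get_ev(SEXP xp) {
  Rcpp::XPtr<Evaluator> p(xp);
  return p.get();
}

// [[Rcpp::export(name = ".ev_new")]]
SEXP ev_new(int nd, NumericMatrix pts, NumericMatrix W0, IntegerMatrix IDX,
            List W2list, NumericVector wterm, IntegerVector ia, int bins,
            NumericVector Bimg, IntegerVector Bdim, NumericVector Borig,
            NumericVector Bspac, double blo, double bwidth, int ncp,
            double alpha1, double alpha2) {
  Evaluator *E = new Evaluator();
  E->nd = nd; E->n = pts.nrow(); E->K = W0.ncol(); E->bins = bins;
  E->ncp = ncp; E->alpha1 = alpha1; E->alpha2 = alpha2;
  E->nterm = W2list.size();
  E->pts.assign(pts.begin(), pts.end());
  E->W0.assign(W0.begin(), W0.end());
  E->IDX.resize(E->IDX.size());
  E->IDX.assign(IDX.begin(), IDX.end());
  for (auto &v : E->IDX) v -= 1;           // to 0-based
  E->W2.resize((size_t)E->nterm * E->n * E->K);
  for (int t = 0; t < E->nterm; ++t) {
    NumericMatrix m = W2list[t];
    std::copy(m.begin(), m.end(), E->W2.begin() + (size_t)t * E->n * E->K);
  }
  E->wterm.assign(wterm.begin(), wterm.end());
  E->ia.assign(ia.begin(), ia.end());
  for (auto &v : E->ia) v -= 1;
  E->Bimg.assign(Bimg.begin(), Bimg.end());
  for (int k = 0; k < nd; ++k) {
    E->Bdim[k] = Bdim[k]; E->Borig[k] = Borig[k]; E->Bspac[k] = Bspac[k];
  }
  E->blo = blo; E->bwidth = bwidth;
  E->phi.assign((size_t)nd * ncp, 0.0);
  E->disp.assign((size_t)nd * E->n, 0.0);
  E->d2.assign((size_t)E->nterm * nd * E->n, 0.0);
  E->ibv.assign(E->n, -1);
  E->joint.assign((size_t)bins * bins, 0);
  E->ca.assign(bins, 0);
  E->cb.assign(bins, 0);
  E->xlog2.resize((size_t)E->n + 2);
  E->xlog2[0] = 0.0;
  for (size_t c = 1; c < E->xlog2.size(); ++c) E->xlog2[c] = c * std::log2((double)c);
  // reverse map
  std::vector<int> cnt(ncp, 0);
  for (size_t e = 0; e < E->IDX.size(); ++e) cnt[E->IDX[e]]++;
  E->rev_ptr.assign(ncp + 1, 0);
  for (int j = 0; j < ncp; ++j) E->rev_ptr[j + 1] = E->rev_ptr[j] + cnt[j];
  E->rev_row.resize(E->IDX.size());
  E->rev_k.resize(E->IDX.size());
  std::vector<int> fill(E->rev_ptr.begin(), E->rev_ptr.end() - 1);
  for (int k = 0; k < E->K; ++k) {
    for (int r = 0; r < E->n; ++r) {
      int j = E->IDX[(size_t)k * E->n + r];
      int pos = fill[j]++;
      E->rev_row[pos] = r;
      E->rev_k[pos] = k;
    }
  }
  E->full_recompute();
  Rcpp::XPtr<Evaluator> xp(E, true);
  return xp;
}

// [[Rcpp::export(name = ".ev_set_phi")]]
NumericVector ev_set_phi(SEXP xp, NumericVector phi) {
  Evaluator *E = get_ev(xp);
  if ((int)phi.size() != E->nd * E->ncp) stop("phi length mismatch");
  std::copy(phi.begin(), phi.end(), E->phi.begin());
  E->full_recompute();
  return NumericVector::create(_["total"] = E->total(), _["mi"] = E->mi(),
                               _["bending"] = E->bending());
}

// [[Rcpp::export(name = ".ev_parts")]]
NumericVector ev_parts(SEXP xp) {
  Evaluator *E = get_ev(xp);
  return NumericVector::create(_["total"] = E->total(), _["mi"] = E->mi(),
                               _["bending"] = E->bending());
}

// [[Rcpp::export(name = ".ev_get_phi")]]
NumericVector ev_get_phi(SEXP xp) {
  Evaluator *E = get_ev(xp);
  return NumericVector(E->phi.begin(), E->phi.end());
}

// One greedy first-improvement sweep over `order` (1-based coordinate
// indices) at the given step; an accepted direction is repeated while it
// keeps improving. Returns the number of accepted coordinates.
// [[Rcpp::export(name = ".ev_sweep")]]
int ev_sweep(SEXP xp, IntegerVector order, double step) {
  Evaluator *E = get_ev(xp);
  E->full_recompute();                 // bound incremental drift per sweep
  int accepted = 0;
  for (int oi = 0; oi < order.size(); ++oi) {
    int p = order[oi] - 1;
    bool acc = false;
    for (int s = 0; s < 2 && !acc; ++s) {
      double delta = s == 0 ? step : -step;
      double before = E->total();
      E->apply_move(p, delta);
      if (E->total() < before - 1e-12) {
        acc = true;
        for (;;) {
          before = E->total();
          E->apply_move(p, delta);
          if (!(E->total() < before - 1e-12)) { E->apply_move(p, -delta); break; }
        }
      } else {
        E->apply_move(p, -delta);
      }
    }
    if (acc) ++accepted;
  }
  return accepted;
}
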