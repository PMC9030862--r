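#include <Rcpp.h>
using namespace Rcpp;

// Pixel indexing: images are h x w R matrices (column-major storage, 1-based in R).
// Per-pixel feature stores use row-major pixel index idx = (row-1)*w + col so that
// LUT member lists come out in row-major order, matching the documented convention.
// Points and offsets are (x = column offset, y = row offset) relative to a patch center.

static inline double bilinear(const NumericMatrix &img, double r, double c) {
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0;
  double v00 = img(r0, c0), v01 = img(r0, c0 + 1);
  double v10 = img(r0 + 1, c0), v11 = img(r0 + 1, c0 + 1);
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
}

// Hu's seven invariants from intensity-weighted central moments (orders <= 3).
// The moments are normalised to the unit-mass patch (v / mu00), i.e.
// eta_pq = mu_pq / mu00: invariant to intensity scaling (patch size is fixed,
// so no spatial scale normalisation is involved).
static void hu_from_central(double mu00, double mu11, double mu20, double mu02,
                            double mu30, double mu21, double mu12, double mu03,
                            double *phi) {
  if (mu00 <= 0.0) {
    for (int k = 0; k < 7; ++k) phi[k] = 0.0;
    return;
  }
  double n20 = mu20 / mu00, n02 = mu02 / mu00, n11 = mu11 / mu00;
  double n30 = mu30 / mu00, n03 = mu03 / mu00, n21 = mu21 / mu00, n12 = mu12 / mu00;
  double a = n30 + n12, b = n21 + n03;   // recurring sums
  double a2 = a * a, b2 = b * b;
  phi[0] = n20 + n02;
  phi[1] = (n20 - n02) * (n20 - n02) + 4.0 * n11 * n11;
  phi[2] = (n30 - 3.0 * n12) * (n30 - 3.0 * n12) + (3.0 * n21 - n03) * (3.0 * n21 - n03);
  phi[3] = a2 + b2;
  phi[4] = (n30 - 3.0 * n12) * a * (a2 - 3.0 * b2) + (3.0 * n21 - n03) * b * (3.0 * a2 - b2);
  phi[5] = (n20 - n02) * (a2 - b2) + 4.0 * n11 * a * b;
  phi[6] = (3.0 * n21 - n03) * a * (a2 - 3.0 * b2) - (n30 - 3.0 * n12) * b * (3.0 * a2 - b2);
}

// Per-pixel features over a reflect-padded guide image.
// padded is (h+2r) x (w+2r); for each of the h*w pixels returns the Hu vector of the
// full square patch and the intensity centroid over the inscribed circular support.
// [[Rcpp::export]]
List cpp_patch_features(const NumericMatrix &padded, int h, int w, int radius) {
  int n = 2 * radius + 1;
  int N = h * w;
  NumericMatrix hu(N, 7);
  NumericVector cx(N), cy(N), cmass(N);
  double r2 = (double)radius * radius;
  double phi[7];

  for (int r0 = 0; r0 < h; ++r0) {
    for (int c0 = 0; c0 < w; ++c0) {
      // raw moments about the patch center (x = dx, y = dy)
      double M00 = 0, M10 = 0, M01 = 0, M20 = 0, M11 = 0, M02 = 0;
      double M30 = 0, M21 = 0, M12 = 0, M03 = 0;
      double cs = 0, csx = 0, csy = 0;
      for (int dy = -radius; dy <= radius; ++dy) {
        for (int dx = -radius; dx <= radius; ++dx) {
          double v = padded(r0 + radius + dy, c0 + radius + dx);
          double x = dx, y = dy;
          M00 += v;
          M10 += v * x;  M01 += v * y;
          M20 += v * x * x;  M11 += v * x * y;  M02 += v * y * y;
          M30 += v * x * x * x;  M03 += v * y * y * y;
          M21 += v * x * x * y;  M12 += v * x * y * y;
          if ((double)(dx * dx + dy * dy) <= r2) {
            cs += v; csx += v * x; csy += v * y;
          }
        }
      }
      double mu00 = M00, mu11, mu20, mu02, mu30, mu21, mu12, mu03;
      if (M00 > 0.0) {
        double xc = M10 / M00, yc = M01 / M00;
        mu11 = M11 - xc * M01;
        mu20 = M20 - xc * M10;
        mu02 = M02 - yc * M01;
        mu30 = M30 - 3.0 * xc * M20 + 2.0 * xc * xc * M10;
        mu03 = M03 - 3.0 * yc * M02 + 2.0 * yc * yc * M01;
        mu21 = M21 - 2.0 * xc * M11 - yc * M20 + 2.0 * xc * xc * M01;
        mu12 = M12 - 2.0 * yc * M11 - xc * M02 + 2.0 * yc * yc * M10;
      } else {
        mu11 = mu20 = mu02 = mu30 = mu21 = mu12 = mu03 = 0.0;
      }
      hu_from_central(mu00, mu11, mu20, mu02, mu30, mu21, mu12, mu03, phi);
      int idx = r0 * w + c0; // row-major
      for (int k = 0; k < 7; ++k) hu(idx, k) = phi[k];
      if (cs != 0.0) { cx[idx] = csx / cs; cy[idx] = csy / cs; }
      else { cx[idx] = 0.0; cy[idx] = 0.0; }
      cmass[idx] = cs;
      (void)n;
    }
  }
  return List::create(_["hu"] = hu, _["cx"] = cx, _["cy"] = cy, _["mass"] = cmass);
}

// Nearest-center assignment with lowest-index tie-break (strict improvement only).
// [[Rcpp::export]]
List cpp_assign_clusters(const NumericMatrix &X, const NumericMatrix &C) {
  int N = X.nrow(), d = X.ncol(), K = C.nrow();
  IntegerVector lab(N);
  NumericVector dist2(N);
  for (int i = 0; i < N; ++i) {
    double best = R_PosInf;
    int bk = 0;
    for (int k = 0; k < K; ++k) {
      double s = 0;
      for (int j = 0; j < d; ++j) {
        double diff = X(i, j) - C(k, j);
        s += diff * diff;
        if (s >= best) break;
      }
      if (s < best) { best = s; bk = k; }
    }
    lab[i] = bk + 1;
    dist2[i] = best;
  }
  return List::create(_["labels"] = lab, _["dist2"] = dist2);
}

// Cluster-restricted rotation/mirror-compensated NLM restoration.
// padded: noisy image reflect-padded by margin M >= ceil(radius*sqrt(2));
// labels: per-pixel cluster id (1-based, row-major pixel index);
// members: per-cluster integer vectors of member pixel indices (1-based, row-major);
// phi7/cx/cy/cmass: per-pixel feature store computed on the blurred guide;
// supp: S x 2 matrix of circular-support offsets (dx, dy).
// [[Rcpp::export]]
NumericMatrix cpp_ribm_restore(const NumericMatrix &padded, int h, int w, int M,
                               const IntegerVector &labels, const List &members,
                               const NumericVector &phi7,
                               const NumericVector &cx, const NumericVector &cy,
                               double h2, bool rotate, double eps_c,
                               const IntegerMatrix &supp) {
  int N = h * w, S = supp.nrow();
  NumericMatrix out(h, w);
  std::vector<double> ux(N), uy(N);
  std::vector<bool> cvalid(N);
  for (int i = 0; i < N; ++i) {
    double nrm = std::sqrt(cx[i] * cx[i] + cy[i] * cy[i]);
    if (nrm >= eps_c) { ux[i] = cx[i] / nrm; uy[i] = cy[i] / nrm; cvalid[i] = true; }
    else { ux[i] = 0; uy[i] = 0; cvalid[i] = false; }
  }
  std::vector<const int *> memptr(members.size());
  std::vector<int> memlen(members.size());
  std::vector<IntegerVector> memvec(members.size());
  for (int k = 0; k < members.size(); ++k) {
    memvec[k] = members[k];
    memptr[k] = memvec[k].begin();
    memlen[k] = memvec[k].size();
  }

  const double *pp = padded.begin();
  const int np = padded.nrow();
  std::vector<int> qxv(S), qyv(S);
  std::vector<double> viv(S);
  for (int s = 0; s < S; ++s) { qxv[s] = supp(s, 0); qyv[s] = supp(s, 1); }
  // contributions with d/h2 beyond this are below double precision of the
  // weight sum (the self weight is always 1): drop them early
  const double dcut = 45.0 * h2;

  for (int idx = 0; idx < N; ++idx) {
    int ri = idx / w, ci = idx % w;
    int k = labels[idx] - 1;
    const int *mem = memptr[k];
    int L = memlen[k];
    for (int s = 0; s < S; ++s) {
      viv[s] = pp[(size_t)(M + ci + qxv[s]) * np + (M + ri + qyv[s])];
    }
    double wsum = 0.0, vsum = 0.0;
    for (int l = 0; l < L; ++l) {
      int jdx = mem[l] - 1;
      int rj = jdx / w, cj = jdx % w;
      double d = 0.0;
      if (jdx != idx) {
        bool mirrored = (phi7[idx] * phi7[jdx] < 0.0);
        bool framed = rotate && cvalid[idx] && cvalid[jdx];
        if (framed) {
          double vjx = mirrored ? -ux[jdx] : ux[jdx];
          double vjy = uy[jdx];
          double A = ux[idx] * vjx + uy[idx] * vjy;       // cos(theta_j - theta_i)
          double B = ux[idx] * vjy - uy[idx] * vjx;       // sin(theta_j - theta_i)
          // fold the outer mirror map (x sign flip) into the x-row coefficients
          double axx = mirrored ? -A : A, axy = mirrored ? B : -B;
          double base_r = M + rj, base_c = M + cj;
          for (int s = 0; s < S; ++s) {
            double qx = qxv[s], qy = qyv[s];
            double px = axx * qx + axy * qy;
            double py = B * qx + A * qy;
            double rr = base_r + py, cc = base_c + px;
            // padded coordinates are strictly positive: truncation == floor
            int r0 = (int)rr, c0 = (int)cc;
            double fr = rr - r0, fc = cc - c0;
            const double *col0 = pp + (size_t)c0 * np + r0;
            const double *col1 = col0 + np;
            double vj = (1 - fr) * ((1 - fc) * col0[0] + fc * col1[0]) +
                        fr * ((1 - fc) * col0[1] + fc * col1[1]);
            double diff = viv[s] - vj;
            d += diff * diff;
            if (d > dcut) break;
          }
        } else {
          const double *bj = pp + (size_t)(M + cj) * np + (M + rj);
          for (int s = 0; s < S; ++s) {
            double diff = viv[s] - bj[(ptrdiff_t)qxv[s] * np + qyv[s]];
            d += diff * diff;
            if (d > dcut) break;
          }
        }
        if (d > dcut) continue;
      }
      double wt = std::exp(-d / h2);
      wsum += wt;
      vsum += wt * pp[(size_t)(M + cj) * np + (M + rj)];
    }
    out(ri, ci) = vsum / wsum;
  }
  return out;
}
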