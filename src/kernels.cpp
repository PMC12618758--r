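#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// bilinear sample with zero fill outside the support
static inline double sample2(const NumericMatrix &img, double x, double y) {
  int nx = img.nrow(), ny = img.ncol();
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  double v = 0.0;
  for (int dx = 0; dx <= 1; ++dx) {
    int xi = x0 + dx;
    if (xi < 0 || xi >= nx) continue;
    double wx = dx ? fx : 1.0 - fx;
    if (wx == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      v += wx * wy * img(xi, yi);
    }
  }
  return v;
}

// Resample a slice under the in-plane rigid map used throughout the stitcher:
// out(x) = in(c + R(-theta) * (x + d - c)), rotation about the slice centre,
// i.e. rotate the content by +theta, then read it at coordinates shifted by d.
// [[Rcpp::export(name = ".rigid2d_resample")]]
NumericMatrix rigid2d_resample(const NumericMatrix &img, double theta_deg,
                               double dx, double dy) {
  int nx = img.nrow(), ny = img.ncol();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double ct = std::cos(-theta_deg * DEG), st = std::sin(-theta_deg * DEG);
  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j) {
    double py = j + dy - cy;
    for (int i = 0; i < nx; ++i) {
      double px = i + dx - cx;
      double qx = cx + ct * px - st * py;
      double qy = cy + st * px + ct * py;
      out(i, j) = sample2(img, qx, qy);
    }
  }
  return out;
}

// Rotation-and-shift cross-correlation search.
// For each angle the moving slice is rotated once about its centre (bilinear,
// zero fill); every integer shift of the grid centre +/- max_shift (stride
// shift_step) is then scored against the reference, either as the raw double
// sum  sum_xy A * B'  or as the zero-mean unit-norm (Pearson) correlation
// over the scored pixels. Ties resolved by smallest |theta|, then smallest
// |dx|+|dy|, then lexicographic (theta, dx, dy).
// [[Rcpp::export(name = ".cc_search")]]
List cc_search(const NumericMatrix &A, const NumericMatrix &B,
               const NumericVector &angles_deg, int max_shift,
               bool normalized, Nullable<LogicalMatrix> mask_ = R_NilValue,
               int shift_step = 1, int center_dx = 0, int center_dy = 0) {
  int nx = A.nrow(), ny = A.ncol();
  if (B.nrow() != nx || B.ncol() != ny)
    stop("reference and moving slice must share a grid");
  if (shift_step < 1) stop("shift_step must be >= 1");
  const double *Ap = &A[0];
  std::vector<unsigned char> mask;
  bool have_mask = mask_.isNotNull();
  if (have_mask) {
    LogicalMatrix m(mask_.get());
    mask.resize((size_t)nx * ny);
    for (size_t t = 0; t < mask.size(); ++t) mask[t] = m[t] ? 1 : 0;
  }
  const unsigned char *mp = have_mask ? mask.data() : NULL;

  // totals over the scored pixel set do not depend on the shift: only the
  // moving slice's nonzero pixels contribute to sb, sbb, sab (zero fill),
  // so each shift costs O(#nonzero) rather than O(#pixels)
  long n = 0;
  double sa = 0, saa = 0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (mp && !mp[(size_t)j * nx + i]) continue;
      double a = Ap[(size_t)j * nx + i];
      sa += a; saa += a * a; ++n;
    }
  if (n < 2) stop("fewer than two scored pixels");

  double best = -std::numeric_limits<double>::infinity();
  double bt = NA_REAL; int bdx = 0, bdy = 0;
  int na = angles_deg.size();
  NumericVector angle_best(na);
  std::vector<int> qi, qj;
  std::vector<double> qv;

  for (int ai = 0; ai < na; ++ai) {
    double th = angles_deg[ai];
    NumericMatrix Brot = rigid2d_resample(B, th, 0.0, 0.0);
    qi.clear(); qj.clear(); qv.clear();
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (Brot(i, j) != 0.0) { qi.push_back(i); qj.push_back(j); qv.push_back(Brot(i, j)); }
    size_t nq = qv.size();
    const int *qip = qi.data(); const int *qjp = qj.data();
    const double *qvp = qv.data();
    double abest = -std::numeric_limits<double>::infinity();
    for (int dy = center_dy - max_shift; dy <= center_dy + max_shift;
         dy += shift_step) {
      for (int dx = center_dx - max_shift; dx <= center_dx + max_shift;
           dx += shift_step) {
        double sb = 0, sbb = 0, sab = 0;
        for (size_t t = 0; t < nq; ++t) {
          int pi = qip[t] - dx, pj = qjp[t] - dy;  // scored pixel p with p + d = q
          if ((unsigned)pi >= (unsigned)nx || (unsigned)pj >= (unsigned)ny)
            continue;
          size_t lin = (size_t)pj * nx + pi;
          if (mp && !mp[lin]) continue;
          double v = qvp[t];
          sb += v; sbb += v * v; sab += v * Ap[lin];
        }
        double score;
        if (!normalized) {
          score = sab;
        } else {
          double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
          score = (va > 0 && vb > 0) ? (sab - sa * sb / n) / std::sqrt(va * vb)
                                     : 0.0;
        }
        if (score > abest) abest = score;
        double tol = std::isfinite(best) ? 1e-12 * std::max(1.0, std::fabs(best))
                                         : 0.0;
        bool better = score > best + tol;
        if (!better && std::fabs(score - best) <= tol) {
          // tie-break chain
          double c1 = std::fabs(th) - std::fabs(bt);
          if (c1 < -1e-12) better = true;
          else if (std::fabs(c1) <= 1e-12) {
            int c2 = (std::abs(dx) + std::abs(dy)) - (std::abs(bdx) + std::abs(bdy));
            if (c2 < 0) better = true;
            else if (c2 == 0) {
              if (th < bt - 1e-12) better = true;
              else if (std::fabs(th - bt) <= 1e-12 &&
                       (dx < bdx || (dx == bdx && dy < bdy))) better = true;
            }
          }
        }
        if (better) { best = score; bt = th; bdx = dx; bdy = dy; }
      }
    }
    angle_best[ai] = abest;
  }
  return List::create(_["theta"] = bt, _["dx"] = bdx, _["dy"] = bdy,
                      _["score"] = best, _["angle_scores"] = angle_best);
}

// trilinear sample of a 3D array at 0-based voxel coordinates
static inline double sample3(const double *v, int nx, int ny, int nz,
                             double x, double y, double z, bool clamp) {
  if (clamp) {
    x = std::min(std::max(x, 0.0), nx - 1.0);
    y = std::min(std::max(y, 0.0), ny - 1.0);
    z = std::min(std::max(z, 0.0), nz - 1.0);
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zi = z0 + dz;
    if (zi < 0 || zi >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx <= 1; ++dx) {
        int xi = x0 + dx;
        if (xi < 0 || xi >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        out += wz * wy * wx * v[(size_t)zi * nx * ny + (size_t)yi * nx + xi];
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".interp3")]]
NumericVector interp3(const NumericVector &vol, const NumericMatrix &pts,
                      bool clamp) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("vol must be a 3D array");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  for (int i = 0; i < n; ++i)
    out[i] = sample3(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2), clamp);
  return out;
}

// out(x) = in(c + R^T (x + d - c)); R = Rz(rz) Ry(ry) Rx(rx) content rotation
// [[Rcpp::export(name = ".rigid3d_resample")]]
NumericVector rigid3d_resample(const NumericVector &vol,
                               const NumericVector &rot_deg,
                               const NumericVector &shift_vox) {
  IntegerVector dims = vol.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  arma::mat33 Rx, Ry, Rz;
  double ax = rot_deg[0] * DEG, ay = rot_deg[1] * DEG, az = rot_deg[2] * DEG;
  Rx = {{1, 0, 0}, {0, std::cos(ax), -std::sin(ax)}, {0, std::sin(ax), std::cos(ax)}};
  Ry = {{std::cos(ay), 0, std::sin(ay)}, {0, 1, 0}, {-std::sin(ay), 0, std::cos(ay)}};
  Rz = {{std::cos(az), -std::sin(az), 0}, {std::sin(az), std::cos(az), 0}, {0, 0, 1}};
  arma::mat33 Rinv = (Rz * Ry * Rx).t();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  NumericVector out(vol.size());
  out.attr("dim") = dims;
  const double *v = vol.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double px = i + shift_vox[0] - cx;
        double py = j + shift_vox[1] - cy;
        double pz = k + shift_vox[2] - cz;
        double qx = cx + Rinv(0, 0) * px + Rinv(0, 1) * py + Rinv(0, 2) * pz;
        double qy = cy + Rinv(1, 0) * px + Rinv(1, 1) * py + Rinv(1, 2) * pz;
        double qz = cz + Rinv(2, 0) * px + Rinv(2, 1) * py + Rinv(2, 2) * pz;
        out[(size_t)k * nx * ny + (size_t)j * nx + i] =
            sample3(v, nx, ny, nz, qx, qy, qz, false);
      }
  return out;
}

// Connected-component labeling: 8-neighbourhood in 2D, 26-neighbourhood in 3D.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(const IntegerVector &mask) {
  IntegerVector dims0 = mask.hasAttribute("dim") ? (IntegerVector)mask.attr("dim")
                                                 : IntegerVector::create(mask.size());
  int nx = dims0[0];
  int ny = dims0.size() > 1 ? dims0[1] : 1;
  int nz = dims0.size() > 2 ? dims0[2] : 1;
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(mask.size(), 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            size_t t = (size_t)kk * nx * ny + (size_t)jj * nx + ii;
            if (mask[t] != 0 && lab[t] == 0) { lab[t] = next; stack.push_back(t); }
          }
        }
      }
    }
  }
  lab.attr("dim") = mask.attr("dim");
  return lab;
}

// Per-voxel log-linear diffusion tensor fit.
// S: q x n signal matrix (columns are voxels), design from bvals/bvecs.
// One WLS pass with weights S^2 after the OLS solution when weighted = true.
// Returns 6 x n tensors (xx, yy, zz, xy, xz, yz), FA, principal eigenvector,
// clipped eigenvalues and a validity flag.
// [[Rcpp::export(name = ".dti_fit")]]
List dti_fit(const arma::mat &S, const arma::vec &bvals, const arma::mat &bvecs,
             bool weighted) {
  int q = S.n_rows, n = S.n_cols;
  arma::mat X(q, 7);
  for (int i = 0; i < q; ++i) {
    double b = bvals(i);
    double gx = bvecs(0, i), gy = bvecs(1, i), gz = bvecs(2, i);
    X(i, 0) = 1.0;
    X(i, 1) = -b * gx * gx;
    X(i, 2) = -b * gy * gy;
    X(i, 3) = -b * gz * gz;
    X(i, 4) = -2.0 * b * gx * gy;
    X(i, 5) = -2.0 * b * gx * gz;
    X(i, 6) = -2.0 * b * gy * gz;
  }
  arma::mat P = arma::pinv(X);
  arma::mat tensors(6, n, arma::fill::zeros);
  arma::mat v1(3, n, arma::fill::zeros);
  arma::mat evals(3, n, arma::fill::zeros);
  arma::vec fa(n, arma::fill::zeros);
  arma::vec s0(n, arma::fill::zeros);
  LogicalVector valid(n);
  arma::vec y(q), beta(7);
  for (int v = 0; v < n; ++v) {
    arma::vec s = S.col(v);
    bool ok = s.is_finite() && arma::all(s > 0);
    if (!ok) { valid[v] = false; continue; }
    y = arma::log(s);
    beta = P * y;
    if (weighted) {
      arma::vec w = arma::square(s);
      arma::mat Xw = X.each_col() % w;
      arma::mat A = X.t() * Xw;
      arma::vec rhs = Xw.t() * y;
      arma::vec b2;
      if (arma::solve(b2, A, rhs, arma::solve_opts::no_approx)) beta = b2;
    }
    arma::mat33 D = {{beta(1), beta(4), beta(5)},
                     {beta(4), beta(2), beta(6)},
                     {beta(5), beta(6), beta(3)}};
    arma::vec3 ev; arma::mat33 evec;
    if (!arma::eig_sym(ev, evec, D)) { valid[v] = false; continue; }
    tensors(0, v) = beta(1); tensors(1, v) = beta(2); tensors(2, v) = beta(3);
    tensors(3, v) = beta(4); tensors(4, v) = beta(5); tensors(5, v) = beta(6);
    arma::vec3 lam = arma::clamp(ev, 0.0, arma::datum::inf);
    double mb = arma::mean(lam);
    double denom = arma::accu(arma::square(lam));
    fa(v) = denom > 0
      ? std::sqrt(1.5 * arma::accu(arma::square(lam - mb)) / denom) : 0.0;
    if (fa(v) > 1.0) fa(v) = 1.0;
    arma::vec3 pv = evec.col(2);            // eig_sym is ascending
    int imax = arma::abs(pv).index_max();
    if (pv(imax) < 0) pv = -pv;             // deterministic sign
    v1.col(v) = pv;
    evals.col(v) = lam;
    s0(v) = std::exp(beta(0));
    valid[v] = std::isfinite(s0(v)) && s0(v) > 0;
  }
  return List::create(_["tensors"] = tensors, _["fa"] = fa, _["v1"] = v1,
                      _["evals"] = evals, _["s0"] = s0, _["valid"] = valid);
}

// Deterministic streamline tracker: bidirectional Euler integration along the
// principal eigenvector field with sign continuity, trilinear interpolation of
// FA and (sign-aligned) v1; stops on FA below threshold, mask exit, turning
// angle above the limit, or the length cap.
// [[Rcpp::export(name = ".track_streamlines")]]
List track_streamlines(const NumericVector &fa, const NumericVector &v1,
                       const NumericVector &mask,
                       const NumericMatrix &seeds_world,
                       const NumericMatrix &inv_affine, double step_mm,
                       double fa_threshold, double angle_max_deg,
                       double max_len_mm) {
  IntegerVector dims = fa.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  const double *fap = fa.begin();
  const double *mp = mask.begin();
  const double *vx = v1.begin();
  const double *vy = vx + nvox;
  const double *vz = vy + nvox;
  double cos_lim = std::cos(angle_max_deg * DEG);
  int max_steps = (int)std::ceil(max_len_mm / step_mm) + 2;
  arma::mat44 Ai;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) Ai(i, j) = inv_affine(i, j);

  auto to_vox = [&](const arma::vec3 &w, arma::vec3 &v) {
    for (int i = 0; i < 3; ++i)
      v(i) = Ai(i, 0) * w(0) + Ai(i, 1) * w(1) + Ai(i, 2) * w(2) + Ai(i, 3);
  };
  auto in_mask = [&](const arma::vec3 &v) {
    int i = (int)std::lround(v(0)), j = (int)std::lround(v(1)),
        k = (int)std::lround(v(2));
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return false;
    return mp[(size_t)k * nx * ny + (size_t)j * nx + i] > 0.5;
  };
  // interpolate v1 with per-corner sign alignment to a previous direction
  auto dir_at = [&](const arma::vec3 &v, const arma::vec3 &prev,
                    arma::vec3 &out) {
    int x0 = (int)std::floor(v(0)), y0 = (int)std::floor(v(1)),
        z0 = (int)std::floor(v(2));
    double fx = v(0) - x0, fy = v(1) - y0, fz = v(2) - z0;
    out.zeros();
    for (int dz = 0; dz <= 1; ++dz) {
      int zi = z0 + dz; if (zi < 0 || zi >= nz) continue;
      double wz = dz ? fz : 1 - fz; if (wz == 0) continue;
      for (int dy = 0; dy <= 1; ++dy) {
        int yi = y0 + dy; if (yi < 0 || yi >= ny) continue;
        double wy = dy ? fy : 1 - fy; if (wy == 0) continue;
        for (int dx = 0; dx <= 1; ++dx) {
          int xi = x0 + dx; if (xi < 0 || xi >= nx) continue;
          double wx = dx ? fx : 1 - fx; if (wx == 0) continue;
          size_t t = (size_t)zi * nx * ny + (size_t)yi * nx + xi;
          arma::vec3 c = {vx[t], vy[t], vz[t]};
          if (arma::dot(c, prev) < 0) c = -c;
          out += wz * wy * wx * c;
        }
      }
    }
    double nrm = arma::norm(out);
    if (nrm < 1e-8) return false;
    out /= nrm;
    return true;
  };

  List result(seeds_world.nrow());
  for (int s = 0; s < seeds_world.nrow(); ++s) {
    arma::vec3 seed = {seeds_world(s, 0), seeds_world(s, 1), seeds_world(s, 2)};
    arma::vec3 vvox;
    to_vox(seed, vvox);
    if (!in_mask(vvox) ||
        sample3(fap, nx, ny, nz, vvox(0), vvox(1), vvox(2), false) < fa_threshold) {
      result[s] = R_NilValue;
      continue;
    }
    arma::vec3 d0;
    arma::vec3 up = {0, 0, 1};
    if (!dir_at(vvox, up, d0)) { result[s] = R_NilValue; continue; }

    std::vector<arma::vec3> half[2];
    for (int h = 0; h < 2; ++h) {
      arma::vec3 pos = seed;
      arma::vec3 prev = h == 0 ? d0 : arma::vec3(-d0);
      for (int st = 0; st < max_steps; ++st) {
        arma::vec3 v;
        to_vox(pos, v);
        if (!in_mask(v)) break;
        if (sample3(fap, nx, ny, nz, v(0), v(1), v(2), false) < fa_threshold)
          break;
        arma::vec3 dir;
        if (!dir_at(v, prev, dir)) break;
        if (arma::dot(dir, prev) < cos_lim) break;
        pos += step_mm * dir;
        prev = dir;
        half[h].push_back(pos);
      }
    }
    int n0 = half[1].size(), n1 = half[0].size();
    NumericMatrix line(n0 + 1 + n1, 3);
    for (int i = 0; i < n0; ++i)
      for (int c = 0; c < 3; ++c) line(i, c) = half[1][n0 - 1 - i](c);
    for (int c = 0; c < 3; ++c) line(n0, c) = seed(c);
    for (int i = 0; i < n1; ++i)
      for (int c = 0; c < 3; ++c) line(n0 + 1 + i, c) = half[0][i](c);
    result[s] = line;
  }
  return result;
}
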