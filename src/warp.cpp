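#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Piecewise-affine transform: a regular lattice of block centres over the
// template domain, one affine (A, t) per block, blended with trilinear
// weights between the 8 nearest centres.  Outside the centre lattice the
// weights clamp, so the map extends affinely.  All coordinates are world (mm).
//
// params: nb x 12 matrix (column-major), columns a11,a12,a13,a21,...,a33,t1,t2,t3
// block b at lattice position (i,j,k): b = i + m1*(j + m2*k), 0-based.
// centre_i = lo + (i + 0.5) * spacing.

struct PA {
  const double* par;
  int nb;
  int m[3];
  double lo[3], sp[3];
};

static inline void pa_weights(const PA& pa, const double* x,
                              int i0[3], int i1[3], double f[3], bool clamped[3]) {
  for (int d = 0; d < 3; ++d) {
    if (pa.m[d] == 1) { i0[d] = 0; i1[d] = 0; f[d] = 0.0; clamped[d] = true; continue; }
    double u = (x[d] - pa.lo[d]) / pa.sp[d] - 0.5;
    int lo = (int)std::floor(u);
    if (lo < 0) lo = 0;
    if (lo > pa.m[d] - 2) lo = pa.m[d] - 2;
    double ff = u - lo;
    clamped[d] = false;
    if (ff < 0.0) { ff = 0.0; clamped[d] = true; }
    if (ff > 1.0) { ff = 1.0; clamped[d] = true; }
    i0[d] = lo; i1[d] = lo + 1; f[d] = ff;
  }
}

// y = blended map at x; if Abar non-null, fill 3x3 blended linear part (row-major)
static inline void pa_point(const PA& pa, const double* x, double* y, double* Abar) {
  int i0[3], i1[3]; double f[3]; bool cl[3];
  pa_weights(pa, x, i0, i1, f, cl);
  y[0] = y[1] = y[2] = 0.0;
  if (Abar) for (int q = 0; q < 9; ++q) Abar[q] = 0.0;
  for (int cz = 0; cz < 2; ++cz) {
    int k = cz ? i1[2] : i0[2];
    double wz = cz ? f[2] : 1.0 - f[2];
    if (wz == 0.0) continue;
    for (int cy = 0; cy < 2; ++cy) {
      int j = cy ? i1[1] : i0[1];
      double wy = cy ? f[1] : 1.0 - f[1];
      if (wy == 0.0) continue;
      for (int cx = 0; cx < 2; ++cx) {
        int i = cx ? i1[0] : i0[0];
        double wx = cx ? f[0] : 1.0 - f[0];
        if (wx == 0.0) continue;
        double w = wx * wy * wz;
        int b = i + pa.m[0] * (j + pa.m[1] * k);
        const double* p = pa.par;
        int nb = pa.nb;
        double a[9];
        for (int q = 0; q < 9; ++q) a[q] = p[b + nb * q];
        double t1 = p[b + nb * 9], t2 = p[b + nb * 10], t3 = p[b + nb * 11];
        y[0] += w * (a[0] * x[0] + a[1] * x[1] + a[2] * x[2] + t1);
        y[1] += w * (a[3] * x[0] + a[4] * x[1] + a[5] * x[2] + t2);
        y[2] += w * (a[6] * x[0] + a[7] * x[1] + a[8] * x[2] + t3);
        if (Abar) for (int q = 0; q < 9; ++q) Abar[q] += w * a[q];
      }
    }
  }
}

// Full analytic Jacobian of the blended map, including the weight-gradient term
static inline void pa_jac(const PA& pa, const double* x, double* J) {
  int i0[3], i1[3]; double f[3]; bool cl[3];
  pa_weights(pa, x, i0, i1, f, cl);
  for (int q = 0; q < 9; ++q) J[q] = 0.0;
  for (int cz = 0; cz < 2; ++cz) {
    int k = cz ? i1[2] : i0[2];
    double g[3], dg[3];
    g[2] = cz ? f[2] : 1.0 - f[2];
    dg[2] = cl[2] ? 0.0 : (cz ? 1.0 : -1.0) / pa.sp[2];
    for (int cy = 0; cy < 2; ++cy) {
      int j = cy ? i1[1] : i0[1];
      g[1] = cy ? f[1] : 1.0 - f[1];
      dg[1] = cl[1] ? 0.0 : (cy ? 1.0 : -1.0) / pa.sp[1];
      for (int cx = 0; cx < 2; ++cx) {
        int i = cx ? i1[0] : i0[0];
        g[0] = cx ? f[0] : 1.0 - f[0];
        dg[0] = cl[0] ? 0.0 : (cx ? 1.0 : -1.0) / pa.sp[0];
        double w = g[0] * g[1] * g[2];
        double gw[3];
        gw[0] = dg[0] * g[1] * g[2];
        gw[1] = g[0] * dg[1] * g[2];
        gw[2] = g[0] * g[1] * dg[2];
        if (w == 0.0 && gw[0] == 0.0 && gw[1] == 0.0 && gw[2] == 0.0) continue;
        int b = i + pa.m[0] * (j + pa.m[1] * k);
        const double* p = pa.par;
        int nb = pa.nb;
        double a[9];
        for (int q = 0; q < 9; ++q) a[q] = p[b + nb * q];
        double yb[3];
        yb[0] = a[0]*x[0] + a[1]*x[1] + a[2]*x[2] + p[b + nb*9];
        yb[1] = a[3]*x[0] + a[4]*x[1] + a[5]*x[2] + p[b + nb*10];
        yb[2] = a[6]*x[0] + a[7]*x[1] + a[8]*x[2] + p[b + nb*11];
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c)
            J[3*r + c] += w * a[3*r + c] + yb[r] * gw[c];
      }
    }
  }
}

// Polar rotation factor of a 3x3 matrix by Higham's Newton iteration
// X <- (X + inv(X)^T)/2.  Returns false (identity) for near-singular input.
static inline bool polar_rotation(const double* A, double* R) {
  double X[9];
  for (int q = 0; q < 9; ++q) X[q] = A[q];
  for (int it = 0; it < 12; ++it) {
    double det = X[0]*(X[4]*X[8]-X[5]*X[7]) - X[1]*(X[3]*X[8]-X[5]*X[6])
               + X[2]*(X[3]*X[7]-X[4]*X[6]);
    if (std::fabs(det) < 1e-12) {
      R[0]=1;R[1]=0;R[2]=0;R[3]=0;R[4]=1;R[5]=0;R[6]=0;R[7]=0;R[8]=1;
      return false;
    }
    // inv(X)^T, cofactor form
    double invT[9];
    invT[0] = (X[4]*X[8]-X[5]*X[7])/det;
    invT[3] = -(X[1]*X[8]-X[2]*X[7])/det;
    invT[6] = (X[1]*X[5]-X[2]*X[4])/det;
    invT[1] = -(X[3]*X[8]-X[5]*X[6])/det;
    invT[4] = (X[0]*X[8]-X[2]*X[6])/det;
    invT[7] = -(X[0]*X[5]-X[2]*X[3])/det;
    invT[2] = (X[3]*X[7]-X[4]*X[6])/det;
    invT[5] = -(X[0]*X[7]-X[1]*X[6])/det;
    invT[8] = (X[0]*X[4]-X[1]*X[3])/det;
    double diff = 0.0;
    for (int q = 0; q < 9; ++q) {
      double nx = 0.5 * (X[q] + invT[q]);
      diff += std::fabs(nx - X[q]);
      X[q] = nx;
    }
    if (diff < 1e-12) break;
  }
  for (int q = 0; q < 9; ++q) R[q] = X[q];
  return true;
}

static inline void world_to_vox(const double* w2v, const double* y, double* v) {
  // w2v is a 4x4 column-major matrix
  v[0] = w2v[0]*y[0] + w2v[4]*y[1] + w2v[8]*y[2]  + w2v[12];
  v[1] = w2v[1]*y[0] + w2v[5]*y[1] + w2v[9]*y[2]  + w2v[13];
  v[2] = w2v[2]*y[0] + w2v[6]*y[1] + w2v[10]*y[2] + w2v[14];
}

static inline void vox_to_world(const double* v2w, int i, int j, int k, double* x) {
  x[0] = v2w[0]*i + v2w[4]*j + v2w[8]*k  + v2w[12];
  x[1] = v2w[1]*i + v2w[5]*j + v2w[9]*k  + v2w[13];
  x[2] = v2w[2]*i + v2w[6]*j + v2w[10]*k + v2w[14];
}

// Trilinear sample of nc-component volume at continuous voxel coords.
// Returns false if outside the grid; out must hold nc values; mval gets mask.
static inline bool sample_tri(const double* src, const double* mask, const int* dim,
                              int nc, const double* v, double* out, double* mval) {
  double x = v[0], y = v[1], z = v[2];
  if (x < 0 || y < 0 || z < 0 || x > dim[0]-1 || y > dim[1]-1 || z > dim[2]-1)
    return false;
  int x0 = (int)std::floor(x); if (x0 > dim[0]-2) x0 = dim[0]-2; if (dim[0]==1) x0=0;
  int y0 = (int)std::floor(y); if (y0 > dim[1]-2) y0 = dim[1]-2; if (dim[1]==1) y0=0;
  int z0 = (int)std::floor(z); if (z0 > dim[2]-2) z0 = dim[2]-2; if (dim[2]==1) z0=0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  size_t nxy = (size_t)dim[0] * dim[1];
  size_t nvol = nxy * dim[2];
  for (int c = 0; c < nc; ++c) out[c] = 0.0;
  *mval = 0.0;
  for (int cz = 0; cz < 2; ++cz) {
    int zz = z0 + cz; if (zz > dim[2]-1) zz = dim[2]-1;
    double wz = cz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int cy = 0; cy < 2; ++cy) {
      int yy = y0 + cy; if (yy > dim[1]-1) yy = dim[1]-1;
      double wy = cy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int cx = 0; cx < 2; ++cx) {
        int xx = x0 + cx; if (xx > dim[0]-1) xx = dim[0]-1;
        double wx = cx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        double w = wx * wy * wz;
        size_t idx = xx + (size_t)dim[0]*yy + nxy*zz;
        for (int c = 0; c < nc; ++c) out[c] += w * src[idx + (size_t)c*nvol];
        if (mask) *mval += w * mask[idx];
      }
    }
  }
  if (!mask) *mval = 1.0;
  return true;
}

static PA make_pa(const NumericMatrix& params, const IntegerVector& counts,
                  const NumericVector& lo, const NumericVector& sp) {
  PA pa;
  pa.par = params.begin();
  pa.nb = params.nrow();
  for (int d = 0; d < 3; ++d) { pa.m[d] = counts[d]; pa.lo[d] = lo[d]; pa.sp[d] = sp[d]; }
  return pa;
}

// [[Rcpp::export]]
NumericMatrix cpp_pa_points(NumericMatrix params, IntegerVector counts,
                            NumericVector lo, NumericVector sp, NumericMatrix X) {
  PA pa = make_pa(params, counts, lo, sp);
  int n = X.nrow();
  NumericMatrix Y(n, 3);
  double x[3], y[3];
  for (int i = 0; i < n; ++i) {
    x[0] = X(i,0); x[1] = X(i,1); x[2] = X(i,2);
    pa_point(pa, x, y, nullptr);
    Y(i,0) = y[0]; Y(i,1) = y[1]; Y(i,2) = y[2];
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix cpp_pa_jacobian(NumericMatrix params, IntegerVector counts,
                              NumericVector lo, NumericVector sp, NumericMatrix X) {
  PA pa = make_pa(params, counts, lo, sp);
  int n = X.nrow();
  NumericMatrix J(n, 9);
  double x[3], jj[9];
  for (int i = 0; i < n; ++i) {
    x[0] = X(i,0); x[1] = X(i,1); x[2] = X(i,2);
    pa_jac(pa, x, jj);
    for (int q = 0; q < 9; ++q) J(i,q) = jj[q];
  }
  return J;
}

static inline void lin_to_ijk(int lin, const int* dim, int* ijk) {
  ijk[0] = lin % dim[0];
  int r = lin / dim[0];
  ijk[1] = r % dim[1];
  ijk[2] = r / dim[1];
}

// Sample a tensor volume at arbitrary world points Y (n x 3), with optional
// finite-strain reorientation from per-point pull-back linear parts A (n x 9,
// row-major; pass a 0-row matrix to skip reorientation).
// [[Rcpp::export]]
List cpp_sample_tensor(NumericVector src, IntegerVector sdim, NumericVector smask,
                       NumericMatrix s_w2v, NumericMatrix Y, NumericMatrix A) {
  int sd[3] = { sdim[0], sdim[1], sdim[2] };
  int n = Y.nrow();
  bool reorient = A.nrow() == n;
  NumericMatrix comp(n, 6);
  NumericVector mval(n);
  LogicalVector inside(n);
  const double* w2v = s_w2v.begin();
  const double* msk = smask.size() > 0 ? smask.begin() : nullptr;
  double y[3], v[3], Ab[9], R[9], D[6];
  for (int i = 0; i < n; ++i) {
    y[0] = Y(i,0); y[1] = Y(i,1); y[2] = Y(i,2);
    world_to_vox(w2v, y, v);
    double mv = 0.0;
    bool in = sample_tri(src.begin(), msk, sd, 6, v, D, &mv);
    if (!in) {
      for (int c = 0; c < 6; ++c) comp(i,c) = 0.0;
      mval[i] = 0.0; inside[i] = false;
      continue;
    }
    if (reorient) {
      // finite strain: forward (source->output) rotation is the transpose of
      // the polar rotation of the pull-back linear part; D_out = R^T D R
      for (int q = 0; q < 9; ++q) Ab[q] = A(i,q);
      if (polar_rotation(Ab, R)) {
        double M[9] = { D[0], D[1], D[3],
                        D[1], D[2], D[4],
                        D[3], D[4], D[5] };
        double RM[9];
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c)
            RM[3*r+c] = R[r]*M[c] + R[3+r]*M[3+c] + R[6+r]*M[6+c];
        double Mo[9];
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c)
            Mo[3*r+c] = RM[3*r]*R[c] + RM[3*r+1]*R[3+c] + RM[3*r+2]*R[6+c];
        D[0] = Mo[0]; D[1] = Mo[1]; D[2] = Mo[4];
        D[3] = Mo[2]; D[4] = Mo[5]; D[5] = Mo[8];
      }
    }
    for (int c = 0; c < 6; ++c) comp(i,c) = D[c];
    mval[i] = mv; inside[i] = true;
  }
  return List::create(_["comp"] = comp, _["mask"] = mval, _["inside"] = inside);
}

// Sample a scalar volume at arbitrary world points (trilinear or nearest).
// [[Rcpp::export]]
List cpp_sample_scalar(NumericVector src, IntegerVector sdim, NumericVector smask,
                       NumericMatrix s_w2v, NumericMatrix Y, bool nearest) {
  int sd[3] = { sdim[0], sdim[1], sdim[2] };
  int n = Y.nrow();
  NumericVector val(n), mval(n);
  LogicalVector inside(n);
  const double* w2v = s_w2v.begin();
  const double* msk = smask.size() > 0 ? smask.begin() : nullptr;
  size_t nxy = (size_t)sd[0] * sd[1];
  double y[3], v[3], s;
  for (int i = 0; i < n; ++i) {
    y[0] = Y(i,0); y[1] = Y(i,1); y[2] = Y(i,2);
    world_to_vox(w2v, y, v);
    if (nearest) {
      long xi = std::lround(v[0]), yi = std::lround(v[1]), zi = std::lround(v[2]);
      if (xi < 0 || yi < 0 || zi < 0 || xi > sd[0]-1 || yi > sd[1]-1 || zi > sd[2]-1) {
        val[i] = 0.0; mval[i] = 0.0; inside[i] = false;
      } else {
        size_t li = xi + (size_t)sd[0]*yi + nxy*zi;
        val[i] = src[li];
        mval[i] = msk ? msk[li] : 1.0;
        inside[i] = true;
      }
    } else {
      double mv = 0.0;
      bool in = sample_tri(src.begin(), msk, sd, 1, v, &s, &mv);
      val[i] = in ? s : 0.0;
      mval[i] = in ? mv : 0.0;
      inside[i] = in;
    }
  }
  return List::create(_["value"] = val, _["mask"] = mval, _["inside"] = inside);
}

static const double METRIC_SCALE = 8.0 * M_PI / 15.0;

static inline double sq_tensor_dist(const double* D1, const double* D2) {
  // components xx, xy, yy, xz, yz, zz
  double dxx = D1[0]-D2[0], dxy = D1[1]-D2[1], dyy = D1[2]-D2[2];
  double dxz = D1[3]-D2[3], dyz = D1[4]-D2[4], dzz = D1[5]-D2[5];
  double f2 = dxx*dxx + dyy*dyy + dzz*dzz + 2.0*(dxy*dxy + dxz*dxz + dyz*dyz);
  double tr = dxx + dyy + dzz;
  double d2 = METRIC_SCALE * (f2 - tr*tr/3.0);
  return d2 > 0.0 ? d2 : 0.0;
}

// [[Rcpp::export]]
double cpp_tensor_obj(NumericVector src, IntegerVector sdim, NumericVector smask,
                      NumericMatrix s_w2v, NumericVector tgt, IntegerVector odim,
                      NumericMatrix o_v2w, NumericMatrix params, IntegerVector counts,
                      NumericVector lo, NumericVector sp, IntegerVector subset,
                      bool reorient, double oob_penalty) {
  PA pa = make_pa(params, counts, lo, sp);
  int sd[3] = { sdim[0], sdim[1], sdim[2] };
  int od[3] = { odim[0], odim[1], odim[2] };
  size_t nvol = (size_t)od[0] * od[1] * od[2];
  const double* v2w = o_v2w.begin();
  const double* w2v = s_w2v.begin();
  const double* msk = smask.size() > 0 ? smask.begin() : nullptr;
  double x[3], y[3], v[3], Ab[9], R[9], D[6], T[6];
  int ijk[3];
  double total = 0.0;
  int n = subset.size();
  for (int i = 0; i < n; ++i) {
    int lin = subset[i];
    lin_to_ijk(lin, od, ijk);
    vox_to_world(v2w, ijk[0], ijk[1], ijk[2], x);
    pa_point(pa, x, y, reorient ? Ab : nullptr);
    world_to_vox(w2v, y, v);
    double mv;
    bool in = sample_tri(src.begin(), msk, sd, 6, v, D, &mv);
    if (!in) { for (int c = 0; c < 6; ++c) D[c] = 0.0; mv = 0.0; }
    // penalize samples drawn from outside the source foreground, so the
    // search cannot profit from trading noisy tissue match for background
    total += oob_penalty * (1.0 - mv);
    if (in && reorient && polar_rotation(Ab, R)) {
      double M[9] = { D[0], D[1], D[3], D[1], D[2], D[4], D[3], D[4], D[5] };
      double RM[9];
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c)
          RM[3*r+c] = R[r]*M[c] + R[3+r]*M[3+c] + R[6+r]*M[6+c];
      double Mo[9];
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c)
          Mo[3*r+c] = RM[3*r]*R[c] + RM[3*r+1]*R[3+c] + RM[3*r+2]*R[6+c];
      D[0] = Mo[0]; D[1] = Mo[1]; D[2] = Mo[4];
      D[3] = Mo[2]; D[4] = Mo[5]; D[5] = Mo[8];
    }
    for (int c = 0; c < 6; ++c) T[c] = tgt[lin + (size_t)c*nvol];
    total += sq_tensor_dist(D, T);
  }
  return total;
}

// [[Rcpp::export]]
double cpp_scalar_obj(NumericVector src, IntegerVector sdim, NumericVector smask,
                      NumericMatrix s_w2v, NumericVector tgt, IntegerVector odim,
                      NumericMatrix o_v2w, NumericMatrix params, IntegerVector counts,
                      NumericVector lo, NumericVector sp, IntegerVector subset,
                      double oob_penalty) {
  PA pa = make_pa(params, counts, lo, sp);
  int sd[3] = { sdim[0], sdim[1], sdim[2] };
  int od[3] = { odim[0], odim[1], odim[2] };
  const double* v2w = o_v2w.begin();
  const double* w2v = s_w2v.begin();
  const double* msk = smask.size() > 0 ? smask.begin() : nullptr;
  double x[3], y[3], v[3], s;
  int ijk[3];
  double total = 0.0;
  int n = subset.size();
  for (int i = 0; i < n; ++i) {
    int lin = subset[i];
    lin_to_ijk(lin, od, ijk);
    vox_to_world(v2w, ijk[0], ijk[1], ijk[2], x);
    pa_point(pa, x, y, nullptr);
    world_to_vox(w2v, y, v);
    double mv;
    bool in = sample_tri(src.begin(), msk, sd, 1, v, &s, &mv);
    if (!in) { s = 0.0; mv = 0.0; }
    total += oob_penalty * (1.0 - mv);
    double d = s - tgt[lin];
    total += d * d;
  }
  return total;
}
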