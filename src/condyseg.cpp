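#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Connected component of a 3D admissible grid containing a seed voxel,
// by breadth-first search.  `adm` is a logical vector in column-major
// (R array) order with dimensions `dims`; `seed` is 1-based (i,j,k).
// connectivity: 6 (face neighbours) or 26 (face+edge+corner).
// A single-slice volume (n2 == 1 or any dim == 1) with connectivity 26
// reduces to 8-connected growth in the plane.
// [[Rcpp::export]]
LogicalVector cpp_seed_component(LogicalVector adm, IntegerVector dims,
                                 IntegerVector seed, int connectivity) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const R_xlen_t n = (R_xlen_t)n0 * n1 * n2;
  if (adm.size() != n) stop("admissible grid does not match dims");
  const int si = seed[0] - 1, sj = seed[1] - 1, sk = seed[2] - 1;
  if (si < 0 || si >= n0 || sj < 0 || sj >= n1 || sk < 0 || sk >= n2)
    stop("seed out of bounds");

  // neighbour offsets
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }

  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = FALSE;
  R_xlen_t sidx = si + (R_xlen_t)n0 * (sj + (R_xlen_t)n1 * sk);
  if (!adm[sidx]) stop("seed voxel is not admissible");

  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  out[sidx] = TRUE;
  stack.push_back(sidx);
  const int nn = (int)di.size();
  while (!stack.empty()) {
    R_xlen_t cur = stack.back(); stack.pop_back();
    int k = (int)(cur / ((R_xlen_t)n0 * n1));
    int rem = (int)(cur - (R_xlen_t)k * n0 * n1);
    int j = rem / n0;
    int i = rem - j * n0;
    for (int t = 0; t < nn; ++t) {
      int ni = i + di[t], nj = j + dj[t], nk = k + dk[t];
      if (ni < 0 || ni >= n0 || nj < 0 || nj >= n1 || nk < 0 || nk >= n2)
        continue;
      R_xlen_t nidx = ni + (R_xlen_t)n0 * (nj + (R_xlen_t)n1 * nk);
      if (adm[nidx] && !out[nidx]) {
        out[nidx] = TRUE;
        stack.push_back(nidx);
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// squared distance from point p to triangle (a,b,c); Ericson's
// closest-point-on-triangle region test.
static double tri_point_dist2(const double* p, const double* a,
                              const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int t = 0; t < 3; ++t) {
    ab[t] = b[t] - a[t]; ac[t] = c[t] - a[t]; ap[t] = p[t] - a[t];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { q[0]=a[0]; q[1]=a[1]; q[2]=a[2]; goto done; }
  {
    double bp[3];
    for (int t = 0; t < 3; ++t) bp[t] = p[t] - b[t];
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) { q[0]=b[0]; q[1]=b[1]; q[2]=b[2]; goto done; }
    double vc = d1*d4 - d3*d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
      double v = d1 / (d1 - d3);
      for (int t = 0; t < 3; ++t) q[t] = a[t] + v * ab[t];
      goto done;
    }
    double cp[3];
    for (int t = 0; t < 3; ++t) cp[t] = p[t] - c[t];
    double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
    double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
    if (d6 >= 0.0 && d5 <= d6) { q[0]=c[0]; q[1]=c[1]; q[2]=c[2]; goto done; }
    double vb = d5*d2 - d1*d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
      double w = d2 / (d2 - d6);
      for (int t = 0; t < 3; ++t) q[t] = a[t] + w * ac[t];
      goto done;
    }
    double va = d3*d6 - d5*d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int t = 0; t < 3; ++t) q[t] = b[t] + w * (c[t] - b[t]);
      goto done;
    }
    {
      double denom = 1.0 / (va + vb + vc);
      double v = vb * denom, w = vc * denom;
      for (int t = 0; t < 3; ++t) q[t] = a[t] + ab[t] * v + ac[t] * w;
    }
  }
done:
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// Distance from each row of `pts` to the closest point on the triangle
// mesh (V, F).  F is 1-based.  Uses a uniform grid over the mesh bounding
// box with expanding-shell search.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix pts, NumericMatrix V,
                                      IntegerMatrix F) {
  const int np = pts.nrow(), nv = V.nrow(), nt = F.nrow();
  if (nt == 0 || nv == 0) stop("mesh has no triangles");
  // copy vertices/faces to flat arrays
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) { vx[i]=V(i,0); vy[i]=V(i,1); vz[i]=V(i,2); }
  std::vector<int> fa(nt), fb(nt), fc(nt);
  for (int i = 0; i < nt; ++i) {
    fa[i] = F(i,0)-1; fb[i] = F(i,1)-1; fc[i] = F(i,2)-1;
    if (fa[i] < 0 || fa[i] >= nv || fb[i] < 0 || fb[i] >= nv ||
        fc[i] < 0 || fc[i] >= nv) stop("face index out of range");
  }
  double lo[3] = {vx[0], vy[0], vz[0]}, hi[3] = {vx[0], vy[0], vz[0]};
  for (int i = 1; i < nv; ++i) {
    lo[0]=std::min(lo[0],vx[i]); hi[0]=std::max(hi[0],vx[i]);
    lo[1]=std::min(lo[1],vy[i]); hi[1]=std::max(hi[1],vy[i]);
    lo[2]=std::min(lo[2],vz[i]); hi[2]=std::max(hi[2],vz[i]);
  }
  double ext[3];
  for (int t = 0; t < 3; ++t) ext[t] = std::max(hi[t]-lo[t], 1e-9);
  double h = std::cbrt(ext[0]*ext[1]*ext[2] / std::max(nt, 1));
  h = std::max(h, 1e-9);
  int g[3];
  for (int t = 0; t < 3; ++t)
    g[t] = std::min(128, std::max(1, (int)std::floor(ext[t]/h)));
  double cs[3];
  for (int t = 0; t < 3; ++t) cs[t] = ext[t] / g[t];
  const double hmin = std::min(cs[0], std::min(cs[1], cs[2]));
  const int ncell = g[0]*g[1]*g[2];

  // bin triangles by bounding box
  std::vector< std::vector<int> > cells(ncell);
  for (int i = 0; i < nt; ++i) {
    double tlo[3], thi[3];
    const double* pa[3];
    double A[3] = {vx[fa[i]], vy[fa[i]], vz[fa[i]]};
    double B[3] = {vx[fb[i]], vy[fb[i]], vz[fb[i]]};
    double C[3] = {vx[fc[i]], vy[fc[i]], vz[fc[i]]};
    pa[0]=A; pa[1]=B; pa[2]=C;
    for (int t = 0; t < 3; ++t) {
      tlo[t] = std::min(A[t], std::min(B[t], C[t]));
      thi[t] = std::max(A[t], std::max(B[t], C[t]));
    }
    (void)pa;
    int clo[3], chi[3];
    for (int t = 0; t < 3; ++t) {
      clo[t] = std::min(g[t]-1, std::max(0, (int)((tlo[t]-lo[t])/cs[t])));
      chi[t] = std::min(g[t]-1, std::max(0, (int)((thi[t]-lo[t])/cs[t])));
    }
    for (int a = clo[0]; a <= chi[0]; ++a)
      for (int b = clo[1]; b <= chi[1]; ++b)
        for (int c = clo[2]; c <= chi[2]; ++c)
          cells[a + g[0]*(b + g[1]*c)].push_back(i);
  }

  std::vector<int> stamp(nt, -1);
  NumericVector out(np);
  const int smax = g[0] + g[1] + g[2] + 2;
  for (int pi = 0; pi < np; ++pi) {
    double p[3] = {pts(pi,0), pts(pi,1), pts(pi,2)};
    int cc[3];
    for (int t = 0; t < 3; ++t)
      cc[t] = std::min(g[t]-1, std::max(0, (int)((p[t]-lo[t])/cs[t])));
    double best2 = R_PosInf;
    for (int s = 0; s <= smax; ++s) {
      if (s >= 1 && best2 <= (double)(s-1)*(s-1)*hmin*hmin) break;
      // enumerate cells at Chebyshev distance s from cc
      int alo = std::max(0, cc[0]-s), ahi = std::min(g[0]-1, cc[0]+s);
      int blo = std::max(0, cc[1]-s), bhi = std::min(g[1]-1, cc[1]+s);
      int clo = std::max(0, cc[2]-s), chi = std::min(g[2]-1, cc[2]+s);
      bool any = false;
      for (int a = alo; a <= ahi; ++a)
        for (int b = blo; b <= bhi; ++b)
          for (int c = clo; c <= chi; ++c) {
            int cheb = std::max(std::abs(a-cc[0]),
                       std::max(std::abs(b-cc[1]), std::abs(c-cc[2])));
            if (cheb != s) continue;
            any = true;
            const std::vector<int>& lst = cells[a + g[0]*(b + g[1]*c)];
            for (size_t u = 0; u < lst.size(); ++u) {
              int ti = lst[u];
              if (stamp[ti] == pi) continue;
              stamp[ti] = pi;
              double A[3] = {vx[fa[ti]], vy[fa[ti]], vz[fa[ti]]};
              double B[3] = {vx[fb[ti]], vy[fb[ti]], vz[fb[ti]]};
              double C[3] = {vx[fc[ti]], vy[fc[ti]], vz[fc[ti]]};
              double d2 = tri_point_dist2(p, A, B, C);
              if (d2 < best2) best2 = d2;
            }
          }
      if (!any && s > 0 && R_finite(best2)) {
        // whole grid enumerated at smaller shells; nothing left
        bool covered = (alo == 0 && blo == 0 && clo == 0 &&
                        ahi == g[0]-1 && bhi == g[1]-1 && chi == g[2]-1);
        if (covered) break;
      }
    }
    out[pi] = std::sqrt(best2);
  }
  return out;
}
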