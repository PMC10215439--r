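#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive nearest-vertex distance: for each query point, the minimum
// Euclidean distance to the target vertex set. O(N*M) but branch-free and
// cache-friendly; exact (no spatial-tree approximation to reason about).
// [[Rcpp::export]]
NumericVector cpp_nearest_vertex_distance(NumericMatrix query, NumericMatrix target) {
  const int n = query.nrow(), m = target.nrow();
  NumericVector out(n);
  std::vector<double> tx(m), ty(m), tz(m);
  for (int j = 0; j < m; ++j) {
    tx[j] = target(j, 0); ty[j] = target(j, 1); tz[j] = target(j, 2);
  }
  for (int i = 0; i < n; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = qx - tx[j], dy = qy - ty[j], dz = qz - tz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Closest point on triangle (a, b, c) to p; squared distance.
// Standard barycentric region walk (Ericson, Real-Time Collision Detection).
static inline double point_triangle_d2(const double *p, const double *a,
                                       const double *b, const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  const double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  const double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { q[0]=a[0]; q[1]=a[1]; q[2]=a[2]; goto done; }
  {
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
    const double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    const double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) { q[0]=b[0]; q[1]=b[1]; q[2]=b[2]; goto done; }
    const double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
      const double v = d1 / (d1 - d3);
      for (int k = 0; k < 3; ++k) q[k] = a[k] + v * ab[k];
      goto done;
    }
    double cp[3];
    for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
    const double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
    const double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
    if (d6 >= 0.0 && d5 <= d6) { q[0]=c[0]; q[1]=c[1]; q[2]=c[2]; goto done; }
    const double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
      const double w = d2 / (d2 - d6);
      for (int k = 0; k < 3; ++k) q[k] = a[k] + w * ac[k];
      goto done;
    }
    const double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
      const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int k = 0; k < 3; ++k) q[k] = b[k] + w * (c[k] - b[k]);
      goto done;
    }
    {
      const double denom = 1.0 / (va + vb + vc);
      const double v = vb * denom, w = vc * denom;
      for (int k = 0; k < 3; ++k) q[k] = a[k] + ab[k] * v + ac[k] * w;
    }
  }
done:
  const double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// Exact point-to-surface distance: minimum over all target triangles.
// faces0 is 0-based M x 3.
// [[Rcpp::export]]
NumericVector cpp_nearest_triangle_distance(NumericMatrix query,
                                            NumericMatrix verts,
                                            IntegerMatrix faces0) {
  const int n = query.nrow(), m = faces0.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < m; ++f) {
      const int ia = faces0(f, 0), ib = faces0(f, 1), ic = faces0(f, 2);
      double a[3] = {verts(ia, 0), verts(ia, 1), verts(ia, 2)};
      double b[3] = {verts(ib, 0), verts(ib, 1), verts(ib, 2)};
      double c[3] = {verts(ic, 0), verts(ic, 1), verts(ic, 2)};
      const double d2 = point_triangle_d2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
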