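#include <Rcpp.h>
using namespace Rcpp;

// distance from point p to segment [a,b] in 3D
static inline double seg_dist(const double *p, const double *a, const double *b) {
  double ab[3], ap[3];
  double dot = 0.0, len2 = 0.0;
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d] - a[d];
    ap[d] = p[d] - a[d];
    dot += ab[d] * ap[d];
    len2 += ab[d] * ab[d];
  }
  double t = (len2 > 0.0) ? dot / len2 : 0.0;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  double s = 0.0;
  for (int d = 0; d < 3; ++d) {
    double diff = ap[d] - t * ab[d];
    s += diff * diff;
  }
  return std::sqrt(s);
}

// Minimum Euclidean distance from each row of `pts` (n x 3, columns x,y,z)
// to the polyline `line` (m x 3). m == 1 degenerates to point distance.
// [[Rcpp::export]]
NumericVector cpp_polyline_distance(NumericMatrix pts, NumericMatrix line) {
  const int n = pts.nrow(), m = line.nrow();
  NumericVector out(n);
  std::vector<double> L(3 * m);
  for (int i = 0; i < m; ++i)
    for (int d = 0; d < 3; ++d) L[3 * i + d] = line(i, d);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = R_PosInf;
    if (m == 1) {
      best = seg_dist(p, &L[0], &L[0]);
    } else {
      for (int s = 0; s + 1 < m; ++s) {
        double d = seg_dist(p, &L[3 * s], &L[3 * (s + 1)]);
        if (d < best) best = d;
      }
    }
    out[i] = best;
  }
  return out;
}

// Distance from every voxel center of a grid to a polyline.
// Grid arrays are indexed (z, y, x) = (SI, AP, LR); axis coordinate vectors
// are passed explicitly. Polyline columns are (x, y, z) mm.
// [[Rcpp::export]]
NumericVector cpp_grid_polyline_distance(NumericVector zc, NumericVector yc,
                                         NumericVector xc, NumericMatrix line) {
  const int nz = zc.size(), ny = yc.size(), nx = xc.size();
  const int m = line.nrow();
  NumericVector out((R_xlen_t)nz * ny * nx);
  std::vector<double> L(3 * m);
  for (int i = 0; i < m; ++i)
    for (int d = 0; d < 3; ++d) L[3 * i + d] = line(i, d);
  R_xlen_t idx = 0;
  for (int k = 0; k < nx; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nz; ++i) {
        double p[3] = {xc[k], yc[j], zc[i]};
        double best = R_PosInf;
        if (m == 1) {
          best = seg_dist(p, &L[0], &L[0]);
        } else {
          for (int s = 0; s + 1 < m; ++s) {
            double d = seg_dist(p, &L[3 * s], &L[3 * (s + 1)]);
            if (d < best) best = d;
          }
        }
        // column-major over (z, y, x): z fastest
        out[(R_xlen_t)i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)] = best;
        (void)idx;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, ny, nx);
  return out;
}

// Even-odd (ray casting) point-in-polygon over an in-plane grid of voxel
// centers. polys: list of Vx2 matrices (x, y). Crossings are accumulated
// over all polygons so nested contours behave as holes (XOR rule).
// Returns ny x nx logical matrix, [j, k] <-> (yc[j], xc[k]).
// [[Rcpp::export]]
LogicalMatrix cpp_raster_slice(NumericVector yc, NumericVector xc, List polys) {
  const int ny = yc.size(), nx = xc.size();
  LogicalMatrix out(ny, nx);
  const int np = polys.size();
  std::vector<NumericMatrix> P(np);
  for (int p = 0; p < np; ++p) P[p] = as<NumericMatrix>(polys[p]);
  for (int k = 0; k < nx; ++k) {
    for (int j = 0; j < ny; ++j) {
      const double px = xc[k], py = yc[j];
      int crossings = 0;
      for (int p = 0; p < np; ++p) {
        const NumericMatrix &V = P[p];
        const int nv = V.nrow();
        for (int a = 0, b = nv - 1; a < nv; b = a++) {
          const double yA = V(a, 1), yB = V(b, 1);
          if ((yA > py) != (yB > py)) {
            const double xint = (V(b, 0) - V(a, 0)) * (py - yA) / (yB - yA) + V(a, 0);
            if (px < xint) ++crossings;
          }
        }
      }
      out(j, k) = (crossings % 2) == 1;
    }
  }
  return out;
}

// Rigid in-plane transform of a (z, y, x) or (z, y, x, c) volume by nearest
// neighbour resampling: rotation by `theta` radians about the SI (z) axis
// around the volume center, then translation by `shift` voxels (z, y, x).
// Out-of-range source voxels become `fill`. theta == 0 && shift == 0 is an
// exact identity.
// [[Rcpp::export]]
NumericVector cpp_rigid_nn(NumericVector vol, NumericVector theta_sincos,
                           NumericVector shift, double fill) {
  IntegerVector dm = vol.attr("dim");
  const int nd = dm.size();
  const int nz = dm[0], ny = dm[1], nx = dm[2];
  const int nc = (nd == 4) ? dm[3] : 1;
  const double st = theta_sincos[0], ct = theta_sincos[1];
  const double cy = (ny - 1) / 2.0, cx = (nx - 1) / 2.0;
  NumericVector out((R_xlen_t)nz * ny * nx * nc);
  out.attr("dim") = dm;
  const R_xlen_t plane = (R_xlen_t)nz * ny * nx;
  for (int k = 0; k < nx; ++k) {
    for (int j = 0; j < ny; ++j) {
      // inverse rotation of the (y, x) position about the plane center,
      // after undoing the translation
      const double yj = j - shift[1] - cy, xk = k - shift[2] - cx;
      const double ys = ct * yj - st * xk + cy;
      const double xs = st * yj + ct * xk + cx;
      const int js = (int)std::lround(ys);
      const int ks = (int)std::lround(xs);
      const bool in_plane = (js >= 0 && js < ny && ks >= 0 && ks < nx);
      for (int i = 0; i < nz; ++i) {
        const int is = (int)std::lround(i - shift[0]);
        const bool ok = in_plane && is >= 0 && is < nz;
        for (int c = 0; c < nc; ++c) {
          const R_xlen_t oi = (R_xlen_t)i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k) + plane * c;
          if (ok) {
            out[oi] = vol[(R_xlen_t)is + (R_xlen_t)nz * (js + (R_xlen_t)ny * ks) + plane * c];
          } else {
            out[oi] = fill;
          }
        }
      }
    }
  }
  return out;
}

// 6-neighbour boundary of a binary (z, y, x) mask: voxels in the mask with at
// least one face neighbour outside it (array edge counts as outside).
// [[Rcpp::export]]
LogicalVector cpp_boundary_mask(LogicalVector mask) {
  IntegerVector dm = mask.attr("dim");
  const int nz = dm[0], ny = dm[1], nx = dm[2];
  LogicalVector out((R_xlen_t)nz * ny * nx);
  out.attr("dim") = dm;
  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || i >= nz || j < 0 || j >= ny || k < 0 || k >= nx) return false;
    return mask[(R_xlen_t)i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)] != 0;
  };
  for (int k = 0; k < nx; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nz; ++i) {
        const R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
        if (mask[idx] == 0) { out[idx] = false; continue; }
        out[idx] = !(at(i - 1, j, k) && at(i + 1, j, k) && at(i, j - 1, k) &&
                     at(i, j + 1, k) && at(i, j, k - 1) && at(i, j, k + 1));
      }
  return out;
}

// Minimum Euclidean distance from each row of `query` to any row of `ref`
// (both n x 3, mm coordinates).
// [[Rcpp::export]]
NumericVector cpp_min_point_distance(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
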