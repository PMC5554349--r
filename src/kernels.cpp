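#include <Rcpp.h>
using namespace Rcpp;

// Net Fruchterman-Reingold displacement per node for one iteration.
// pos: n x d coordinates; edges: m x 2 zero-based endpoints; k: equilibrium
// length; wattr: per-edge attraction scale (1 = plain FR, 0 = edge cut).
// Repulsion k^2/d acts between all unordered node pairs, attraction d^2/k
// along edges. d is floored at 1e-9; true coincidences are jittered by the
// caller before entry.
// [[Rcpp::export]]
NumericMatrix fr_displacement(const NumericMatrix& pos,
                              const IntegerMatrix& edges,
                              double k,
                              const NumericVector& wattr) {
  const int n = pos.nrow(), d = pos.ncol(), m = edges.nrow();
  NumericMatrix disp(n, d);
  std::vector<double> delta(d);
  const double k2 = k * k;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dist2 = 0.0;
      for (int c = 0; c < d; ++c) {
        delta[c] = pos(i, c) - pos(j, c);
        dist2 += delta[c] * delta[c];
      }
      double dist = std::sqrt(dist2);
      if (dist < 1e-9) dist = 1e-9;
      const double f = k2 / (dist * dist);  // (k^2/dist) / dist for unit vec
      for (int c = 0; c < d; ++c) {
        const double push = delta[c] * f;
        disp(i, c) += push;
        disp(j, c) -= push;
      }
    }
  }
  for (int e = 0; e < m; ++e) {
    const double w = wattr[e];
    if (w == 0.0) continue;
    const int u = edges(e, 0), v = edges(e, 1);
    double dist2 = 0.0;
    for (int c = 0; c < d; ++c) {
      delta[c] = pos(u, c) - pos(v, c);
      dist2 += delta[c] * delta[c];
    }
    double dist = std::sqrt(dist2);
    if (dist < 1e-9) dist = 1e-9;
    const double f = w * dist / k;  // (dist^2/k) / dist
    for (int c = 0; c < d; ++c) {
      const double pull = delta[c] * f;
      disp(u, c) -= pull;
      disp(v, c) += pull;
    }
  }
  return disp;
}

// Gradient of the r-PolyLog energy.  repw holds per-node repulsion weights:
// all ones for the node-repulsion model, node degrees for edge repulsion.
// Energy = sum_edges (1/r) d^r - sum_{u<v} repw_u repw_v ln d.
// [[Rcpp::export]]
NumericMatrix linlog_gradient(const NumericMatrix& pos,
                              const IntegerMatrix& edges,
                              double r,
                              const NumericVector& repw) {
  const int n = pos.nrow(), d = pos.ncol(), m = edges.nrow();
  NumericMatrix grad(n, d);
  std::vector<double> delta(d);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dist2 = 0.0;
      for (int c = 0; c < d; ++c) {
        delta[c] = pos(i, c) - pos(j, c);
        dist2 += delta[c] * delta[c];
      }
      if (dist2 < 1e-18) dist2 = 1e-18;
      const double f = repw[i] * repw[j] / dist2;  // d(-w ln d)/dp = -w/dist^2 * delta
      for (int c = 0; c < d; ++c) {
        grad(i, c) -= delta[c] * f;
        grad(j, c) += delta[c] * f;
      }
    }
  }
  for (int e = 0; e < m; ++e) {
    const int u = edges(e, 0), v = edges(e, 1);
    double dist2 = 0.0;
    for (int c = 0; c < d; ++c) {
      delta[c] = pos(u, c) - pos(v, c);
      dist2 += delta[c] * delta[c];
    }
    double dist = std::sqrt(dist2);
    if (dist < 1e-9) dist = 1e-9;
    const double f = std::pow(dist, r - 2.0);  // d((1/r)d^r)/dp = d^{r-2} delta
    for (int c = 0; c < d; ++c) {
      grad(u, c) += delta[c] * f;
      grad(v, c) -= delta[c] * f;
    }
  }
  return grad;
}

// r-PolyLog energy value (see linlog_gradient for the model).
// [[Rcpp::export]]
double linlog_energy_cpp(const NumericMatrix& pos,
                         const IntegerMatrix& edges,
                         double r,
                         const NumericVector& repw) {
  const int n = pos.nrow(), d = pos.ncol(), m = edges.nrow();
  double att = 0.0, rep = 0.0;
  for (int e = 0; e < m; ++e) {
    const int u = edges(e, 0), v = edges(e, 1);
    double dist2 = 0.0;
    for (int c = 0; c < d; ++c) {
      const double dd = pos(u, c) - pos(v, c);
      dist2 += dd * dd;
    }
    att += std::pow(std::sqrt(dist2), r) / r;
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dist2 = 0.0;
      for (int c = 0; c < d; ++c) {
        const double dd = pos(i, c) - pos(j, c);
        dist2 += dd * dd;
      }
      if (dist2 <= 0.0) return R_NegInf;
      rep += repw[i] * repw[j] * 0.5 * std::log(dist2);
    }
  }
  return att - rep;
}

// Pairwise edge-compatibility scan.  ep1/ep2: m x 3 segment endpoints.
// Returns rows (a, b, compat, flip) for unordered pairs with total
// compatibility >= threshold; flip = 1 when the segments point in opposite
// directions.  Factors: angle |cos|, scale, position, mutual visibility.
static double seg_visibility(const double* p1, const double* p2,
                             const double* q1, const double* q2) {
  double vp[3], mp[3];
  double vpn2 = 0.0;
  for (int c = 0; c < 3; ++c) {
    vp[c] = p2[c] - p1[c];
    mp[c] = 0.5 * (p1[c] + p2[c]);
    vpn2 += vp[c] * vp[c];
  }
  double t0 = 0.0, t1 = 0.0;
  for (int c = 0; c < 3; ++c) {
    t0 += (q1[c] - p1[c]) * vp[c];
    t1 += (q2[c] - p1[c]) * vp[c];
  }
  t0 /= vpn2; t1 /= vpn2;
  double span2 = 0.0, md2 = 0.0;
  for (int c = 0; c < 3; ++c) {
    const double i0 = p1[c] + t0 * vp[c];
    const double i1 = p1[c] + t1 * vp[c];
    const double im = 0.5 * (i0 + i1);
    span2 += (i0 - i1) * (i0 - i1);
    md2 += (mp[c] - im) * (mp[c] - im);
  }
  if (span2 <= 0.0) return 0.0;
  const double v = 1.0 - 2.0 * std::sqrt(md2 / span2);
  return v > 0.0 ? v : 0.0;
}

// [[Rcpp::export]]
NumericMatrix compat_pairs(const NumericMatrix& ep1,
                           const NumericMatrix& ep2,
                           double threshold) {
  const int m = ep1.nrow();
  std::vector<double> out;
  for (int a = 0; a < m; ++a) {
    double va[3], ma[3];
    double la2 = 0.0;
    for (int c = 0; c < 3; ++c) {
      va[c] = ep2(a, c) - ep1(a, c);
      ma[c] = 0.5 * (ep1(a, c) + ep2(a, c));
      la2 += va[c] * va[c];
    }
    const double la = std::sqrt(la2);
    if (la <= 1e-12) continue;
    for (int b = a + 1; b < m; ++b) {
      double vb[3], mb[3];
      double lb2 = 0.0, dot = 0.0, mid2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        vb[c] = ep2(b, c) - ep1(b, c);
        mb[c] = 0.5 * (ep1(b, c) + ep2(b, c));
        lb2 += vb[c] * vb[c];
        dot += va[c] * vb[c];
        mid2 += (ma[c] - mb[c]) * (ma[c] - mb[c]);
      }
      const double lb = std::sqrt(lb2);
      if (lb <= 1e-12) continue;
      const double ca = std::fabs(dot) / (la * lb);
      const double lavg = 0.5 * (la + lb);
      const double lmin = la < lb ? la : lb;
      const double lmax = la < lb ? lb : la;
      const double cs = 2.0 / (lavg / lmin + lmax / lavg);
      const double cp = lavg / (lavg + std::sqrt(mid2));
      double tot = ca * cs * cp;
      if (tot < threshold) continue;   // visibility can only shrink it
      double p1[3], p2[3], q1[3], q2[3];
      for (int c = 0; c < 3; ++c) {
        p1[c] = ep1(a, c); p2[c] = ep2(a, c);
        q1[c] = ep1(b, c); q2[c] = ep2(b, c);
      }
      const double cv1 = seg_visibility(p1, p2, q1, q2);
      const double cv2 = seg_visibility(q1, q2, p1, p2);
      tot *= (cv1 < cv2 ? cv1 : cv2);
      if (tot >= threshold) {
        out.push_back(a + 1); out.push_back(b + 1);
        out.push_back(tot); out.push_back(dot < 0 ? 1.0 : 0.0);
      }
    }
  }
  NumericMatrix res(out.size() / 4, 4);
  for (int i = 0; i < res.nrow(); ++i)
    for (int j = 0; j < 4; ++j) res(i, j) = out[4 * i + j];
  colnames(res) = CharacterVector::create("a", "b", "compat", "flip");
  return res;
}

// One bundling cycle: `iters` iterations of spring + electrostatic forces on
// the interior subdivision points.  pts: (m*np) x 3 stacked polylines.
// pairs: rows (a, b, compat, flip), 1-based.  kp: per-edge spring constant.
// Per-point displacement is capped at `step`.
// [[Rcpp::export]]
NumericMatrix bundle_cycle(NumericMatrix pts, int m, int np,
                           const NumericMatrix& pairs,
                           const NumericVector& kp,
                           double step, int iters) {
  NumericMatrix cur(Rcpp::clone(pts));
  const int npairs = pairs.nrow();
  NumericMatrix force(m * np, 3);
  for (int it = 0; it < iters; ++it) {
    std::fill(force.begin(), force.end(), 0.0);
    // springs between consecutive points of each edge
    for (int e = 0; e < m; ++e) {
      const int base = e * np;
      const double k = kp[e];
      if (k == 0.0) continue;
      for (int i = 1; i < np - 1; ++i) {
        for (int c = 0; c < 3; ++c) {
          force(base + i, c) += k * (cur(base + i - 1, c) +
                                     cur(base + i + 1, c) -
                                     2.0 * cur(base + i, c));
        }
      }
    }
    // electrostatic attraction between corresponding points of compatible
    // edge pairs (magnitude 1/distance toward the partner point)
    for (int pr = 0; pr < npairs; ++pr) {
      const int a = (int)pairs(pr, 0) - 1;
      const int b = (int)pairs(pr, 1) - 1;
      const bool flip = pairs(pr, 3) != 0.0;
      const int ba = a * np, bb = b * np;
      for (int i = 1; i < np - 1; ++i) {
        const int j = flip ? (np - 1 - i) : i;
        double d[3];
        double dist2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          d[c] = cur(bb + j, c) - cur(ba + i, c);
          dist2 += d[c] * d[c];
        }
        const double dist = std::sqrt(dist2);
        if (dist > 1e-9) {
          for (int c = 0; c < 3; ++c) {
            const double f = d[c] / (dist * dist);
            force(ba + i, c) += f;
            force(bb + j, c) -= f;
          }
        }
      }
    }
    // apply, capped at step
    for (int e = 0; e < m; ++e) {
      const int base = e * np;
      for (int i = 1; i < np - 1; ++i) {
        double disp[3];
        double mag2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          disp[c] = step * force(base + i, c);
          mag2 += disp[c] * disp[c];
        }
        const double mag = std::sqrt(mag2);
        const double lim = (mag > step) ? (step / mag) : 1.0;
        for (int c = 0; c < 3; ++c) cur(base + i, c) += disp[c] * lim;
      }
    }
  }
  return cur;
}
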