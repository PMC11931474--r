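#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// 8-connected neighborhood offsets
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// reflect index into [0, n-1] (edge-pixel mirroring, "reflect" padding)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// [[Rcpp::export(name = ".median_filter_disc_cpp")]]
NumericMatrix median_filter_disc_cpp(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  if (radius <= 0) return clone(img);
  // disc structuring element: offsets with dr^2 + dc^2 <= r^2
  std::vector<int> odr, odc;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= radius * radius) {
        odr.push_back(dr);
        odc.push_back(dc);
      }
  int k = (int)odr.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      for (int j = 0; j < k; ++j) {
        int rr = reflect_idx(r + odr[j], nr);
        int cc = reflect_idx(c + odc[j], nc);
        buf[j] = img(rr, cc);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      double med = buf[k / 2];
      if (k % 2 == 0) {
        // even count: average the two central order statistics (R median())
        double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
        med = 0.5 * (med + lo);
      }
      out(r, c) = med;
    }
  }
  return out;
}

struct Component {
  double peak_val;
  double sum_r, sum_c; // centroid accumulator over peak-level plateau pixels
  int n_peak;
  double prominence; // NA until dethroned
  bool alive;
};

// Union-find with path compression
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Topographic-prominence local maxima (ImageJ noise-tolerance semantics).
// Returns all candidate maxima with their prominence; plateaus are merged and
// reported at the plateau centroid. The global maximum gets prominence
// peak - min(img). Thresholding by intensity / tolerance is done in R.
// [[Rcpp::export(name = ".find_maxima_cpp")]]
DataFrame find_maxima_cpp(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const double* px = &img[0]; // column-major
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return px[a] > px[b];
  });
  std::vector<int> parent(n, -1); // -1 = unprocessed
  std::vector<Component> comp;
  std::vector<int> comp_of(n, -1); // root pixel -> component index
  double vmin = *std::min_element(px, px + n);

  for (int oi = 0; oi < n; ++oi) {
    int p = order[oi];
    int r = p % nr, c = p / nr;
    double v = px[p];
    // distinct neighboring component roots among processed pixels
    int roots[8];
    int nroots = 0;
    for (int j = 0; j < 8; ++j) {
      int rr = r + DR[j], cc = c + DC[j];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int q = cc * nr + rr;
      if (parent[q] < 0) continue;
      int root = uf_find(parent, q);
      bool seen = false;
      for (int t = 0; t < nroots; ++t)
        if (roots[t] == root) { seen = true; break; }
      if (!seen) roots[nroots++] = root;
    }
    if (nroots == 0) {
      // new candidate maximum (possibly a plateau in progress)
      parent[p] = p;
      Component cm;
      cm.peak_val = v;
      cm.sum_r = r + 1; // 1-based for R
      cm.sum_c = c + 1;
      cm.n_peak = 1;
      cm.prominence = NA_REAL;
      cm.alive = true;
      comp_of[p] = (int)comp.size();
      comp.push_back(cm);
      continue;
    }
    // pick the component with the highest peak (ties: first encountered)
    int best = roots[0];
    for (int t = 1; t < nroots; ++t)
      if (comp[comp_of[roots[t]]].peak_val > comp[comp_of[best]].peak_val)
        best = roots[t];
    Component& bc = comp[comp_of[best]];
    parent[p] = best;
    if (v == bc.peak_val) {
      // still on the summit plateau of this component
      bc.sum_r += r + 1;
      bc.sum_c += c + 1;
      bc.n_peak += 1;
    }
    // merge all other components into the best one; v is their saddle level
    for (int t = 0; t < nroots; ++t) {
      if (roots[t] == best) continue;
      Component& dc = comp[comp_of[roots[t]]];
      dc.prominence = dc.peak_val - v;
      dc.alive = false;
      parent[roots[t]] = best;
    }
  }
  int nm = (int)comp.size();
  NumericVector out_r(nm), out_c(nm), out_v(nm), out_p(nm);
  for (int i = 0; i < nm; ++i) {
    out_r[i] = comp[i].sum_r / comp[i].n_peak;
    out_c[i] = comp[i].sum_c / comp[i].n_peak;
    out_v[i] = comp[i].peak_val;
    out_p[i] = comp[i].alive ? comp[i].peak_val - vmin : comp[i].prominence;
  }
  return DataFrame::create(_["row"] = out_r, _["col"] = out_c,
                           _["peak"] = out_v, _["prominence"] = out_p);
}

struct WsEntry {
  double value;
  long order;
  int pixel;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.value != b.value) return a.value < b.value; // max-heap on value
    return a.order > b.order;                         // then FIFO
  }
};

// Marker-seeded watershed on inverted intensity: regions grow from seeds
// downhill within the mask, brightest frontier pixel first. Deterministic.
// seeds: integer matrix, 0 = background, k > 0 = seed id.
// [[Rcpp::export(name = ".seeded_watershed_cpp")]]
IntegerMatrix seeded_watershed_cpp(NumericMatrix img, IntegerMatrix seeds,
                                   LogicalMatrix mask) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix labels(nr, nc);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long counter = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        labels(r, c) = seeds(r, c);
        pq.push({img(r, c), counter++, c * nr + r});
      }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    int r = e.pixel % nr, c = e.pixel / nr;
    int lab = labels(r, c);
    for (int j = 0; j < 8; ++j) {
      int rr = r + DR[j], cc = c + DC[j];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) || labels(rr, cc) != 0) continue;
      labels(rr, cc) = lab;
      pq.push({img(rr, cc), counter++, cc * nr + rr});
    }
  }
  return labels;
}

// 8-connected component labeling of a logical mask.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0)
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || labels(r0, c0) != 0) continue;
      ++next;
      stack.push_back(c0 * nr + r0);
      labels(r0, c0) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int r = p % nr, c = p / nr;
        for (int j = 0; j < 8; ++j) {
          int rr = r + DR[j], cc = c + DC[j];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && labels(rr, cc) == 0) {
            labels(rr, cc) = next;
            stack.push_back(cc * nr + rr);
          }
        }
      }
    }
  return labels;
}

// For each reference point, Euclidean distance to the nearest target point.
// [[Rcpp::export(name = ".nn_dist_cpp")]]
NumericVector nn_dist_cpp(NumericMatrix ref, NumericMatrix target) {
  int n = ref.nrow(), m = target.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double x = ref(i, 0), y = ref(i, 1);
    for (int j = 0; j < m; ++j) {
      double dx = x - target(j, 0), dy = y - target(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
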