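#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Maximally stable extremal regions by an explicit threshold sweep.
//
// The image is quantized to 256 gray levels.  For every level t (high to
// low, bright-on-dark) the binary mask q >= t is labeled into 4-connected
// components.  A component's branch is identified by its seed pixel (the
// brightest pixel it contains, ties broken by smaller linear index): the
// component at a higher threshold containing the seed is the branch child,
// the component at a lower threshold containing it is the branch parent.
// Stability at level t is (A(t - delta) - A(t + delta)) / A(t); per branch
// the most stable level with stability <= max_stability and area within
// [min_area, max_area] is reported, and regions whose seed lies inside a
// more stable accepted region are collapsed away.

typedef std::vector<int> ivec;

// label 4-connected components of (q >= t); labels are 1-based, 0 = bg.
// Fills comp areas and per-component seed pixel (max q, tie: min index).
static int label_level(const ivec &q, int t, int h, int w, ivec &labels,
                       ivec &areas, ivec &seeds, ivec &stack) {
  std::fill(labels.begin(), labels.end(), 0);
  areas.clear();
  seeds.clear();
  int ncomp = 0;
  const int n = h * w;
  for (int p = 0; p < n; ++p) {
    if (q[p] < t || labels[p] != 0) continue;
    ++ncomp;
    int area = 0, seed = p, seedq = q[p];
    stack.clear();
    stack.push_back(p);
    labels[p] = ncomp;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      ++area;
      if (q[u] > seedq || (q[u] == seedq && u < seed)) {
        seed = u;
        seedq = q[u];
      }
      int r = u % h, c = u / h; // column-major layout
      const int nb[4] = {(r > 0) ? u - 1 : -1, (r < h - 1) ? u + 1 : -1,
                         (c > 0) ? u - h : -1, (c < w - 1) ? u + h : -1};
      for (int k = 0; k < 4; ++k) {
        int v = nb[k];
        if (v >= 0 && labels[v] == 0 && q[v] >= t) {
          labels[v] = ncomp;
          stack.push_back(v);
        }
      }
    }
    areas.push_back(area);
    seeds.push_back(seed);
  }
  return ncomp;
}

// flood fill (q >= t) from seed, returning member pixel indices
static void region_pixels(const ivec &q, int t, int h, int w, int seed,
                          ivec &out, std::vector<char> &mark, ivec &stack) {
  out.clear();
  stack.clear();
  stack.push_back(seed);
  mark[seed] = 1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    out.push_back(u);
    int r = u % h, c = u / h;
    const int nb[4] = {(r > 0) ? u - 1 : -1, (r < h - 1) ? u + 1 : -1,
                       (c > 0) ? u - h : -1, (c < w - 1) ? u + h : -1};
    for (int k = 0; k < 4; ++k) {
      int v = nb[k];
      if (v >= 0 && !mark[v] && q[v] >= t) {
        mark[v] = 1;
        stack.push_back(v);
      }
    }
  }
  for (size_t i = 0; i < out.size(); ++i) mark[out[i]] = 0;
}

struct Candidate {
  int seed, level, area;
  double stability;
};

// [[Rcpp::export(name = ".mser_detect_cpp")]]
DataFrame mser_detect_cpp(NumericMatrix img, int delta, double min_area,
                          double max_area, double max_stability,
                          bool bright_on_dark) {
  const int h = img.nrow(), w = img.ncol(), n = h * w;
  if (n == 0) stop("empty image");
  if (delta < 1) stop("delta must be >= 1");

  double lo = R_PosInf, hi = R_NegInf;
  for (int p = 0; p < n; ++p) {
    double v = img[p];
    if (!R_finite(v)) stop("image contains non-finite values");
    if (v < lo) lo = v;
    if (v > hi) hi = v;
  }
  // quantize to 0..255 on a fixed 16-bit scale so absolute `delta` steps
  // are comparable across images
  ivec q(n);
  for (int p = 0; p < n; ++p) {
    int v = (int)std::lround(img[p] / 257.0);
    if (v < 0) v = 0;
    if (v > 255) v = 255;
    q[p] = bright_on_dark ? v : 255 - v;
  }

  int qmax = *std::max_element(q.begin(), q.end());
  int qmin = *std::min_element(q.begin(), q.end());

  // ring buffer of label images / component tables for 2*delta + 1 levels
  const int win = 2 * delta + 1;
  std::vector<ivec> lab(win, ivec(n));
  std::vector<ivec> areas(win), seeds(win);
  ivec stack;
  stack.reserve(n);

  std::vector<Candidate> cands;
  // levels are processed from qmax down; level t occupies slot t % win
  for (int t = qmax; t >= qmin; --t) {
    int s = ((t % win) + win) % win;
    label_level(q, t, h, w, lab[s], areas[s], seeds[s], stack);
    int tc = t + delta; // stability becomes computable once t = tc - delta
    if (tc > qmax || tc + delta > qmax + 0) {
      // branch child must exist at tc + delta <= qmax is not required per
      // component (checked via the seed's own level below)
    }
    if (tc > qmax) continue;
    int sc = ((tc % win) + win) % win;
    int shi = (((tc + delta) % win) + win) % win;
    if (tc + delta > qmax) continue; // no level above to compare with
    for (size_t ci = 0; ci < areas[sc].size(); ++ci) {
      int A = areas[sc][ci];
      if (A < min_area || A > max_area) continue;
      int seed = seeds[sc][ci];
      if (q[seed] < tc + delta) continue; // branch has no child at tc+delta
      int lab_hi = lab[shi][seed];
      if (lab_hi == 0) continue;
      int A_hi = areas[shi][lab_hi - 1];
      int lab_lo = lab[s][seed]; // level t = tc - delta
      int A_lo = areas[s][lab_lo - 1];
      double stab = (double)(A_lo - A_hi) / (double)A;
      if (stab <= max_stability) {
        Candidate cd;
        cd.seed = seed;
        cd.level = tc;
        cd.area = A;
        cd.stability = stab;
        cands.push_back(cd);
      }
    }
  }

  // collapse per branch (same seed): keep most stable, tie -> larger area
  std::sort(cands.begin(), cands.end(), [](const Candidate &a, const Candidate &b) {
    if (a.seed != b.seed) return a.seed < b.seed;
    if (a.stability != b.stability) return a.stability < b.stability;
    if (a.area != b.area) return a.area > b.area;
    return a.level < b.level;
  });
  std::vector<Candidate> branch;
  for (size_t i = 0; i < cands.size(); ++i) {
    if (branch.empty() || branch.back().seed != cands[i].seed) branch.push_back(cands[i]);
  }

  // collapse nested branches: accept in order of stability; drop a region
  // whose seed lies inside an already-accepted region
  std::sort(branch.begin(), branch.end(), [](const Candidate &a, const Candidate &b) {
    if (a.stability != b.stability) return a.stability < b.stability;
    if (a.area != b.area) return a.area > b.area;
    if (a.level != b.level) return a.level < b.level;
    return a.seed < b.seed;
  });
  std::vector<char> mark(n, 0);
  std::vector<ivec> accepted_px;
  std::vector<Candidate> accepted;
  ivec px;
  for (size_t i = 0; i < branch.size(); ++i) {
    bool nested = false;
    for (size_t j = 0; j < accepted.size() && !nested; ++j) {
      const ivec &ap = accepted_px[j];
      if (std::find(ap.begin(), ap.end(), branch[i].seed) != ap.end()) nested = true;
    }
    if (nested) continue;
    region_pixels(q, branch[i].level, h, w, branch[i].seed, px, mark, stack);
    accepted.push_back(branch[i]);
    accepted_px.push_back(px);
  }

  // intensity-weighted sub-pixel centroids (1-based x = col, y = row)
  int m = accepted.size();
  NumericVector cx(m), cy(m), stab(m);
  IntegerVector area(m), level(m);
  for (int i = 0; i < m; ++i) {
    const ivec &ap = accepted_px[i];
    double sw = 0, sx = 0, sy = 0;
    for (size_t k = 0; k < ap.size(); ++k) {
      int p = ap[k];
      double wgt = img[p];
      sw += wgt;
      sy += wgt * (double)(p % h + 1);
      sx += wgt * (double)(p / h + 1);
    }
    cx[i] = sx / sw;
    cy[i] = sy / sw;
    area[i] = accepted[i].area;
    level[i] = accepted[i].level;
    stab[i] = accepted[i].stability;
  }
  DataFrame out = DataFrame::create(
      Named("x") = cx, Named("y") = cy, Named("area") = area,
      Named("stability") = stab, Named("level") = level);
  return out;
}
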