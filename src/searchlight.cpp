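// Searchlight decoding with a linear soft-margin SVM trained by SMO.
// The decoder operates on per-run, per-condition average pattern vectors
// (one vector per condition per run), leave-one-run-out, per analysed time
// bin; accuracies are averaged over folds (and bins unless concatenated).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// SMO on a precomputed Gram matrix; y in {-1,+1}. Returns alpha and b.
struct SvmModel {
  std::vector<double> alpha;
  double b;
};

// Maximal-violating-pair SMO (working-set selection as in libsvm) on a
// precomputed Gram matrix; y in {-1,+1}. Solves
//   min 0.5 a'Qa - e'a,  0 <= a_i <= C,  y'a = 0,   Q_ij = y_i y_j K_ij
// to duality gap `eps`; b is the midpoint of the KKT-feasible interval,
// which is unique at the optimum (so decisions are path-independent and
// label negation flips them exactly).
SvmModel smo_train(const std::vector<double> &K, const std::vector<int> &y,
                   int n, double C, double eps = 1e-9, int max_iter = 2000) {
  SvmModel m;
  m.alpha.assign(n, 0.0);
  m.b = 0.0;
  std::vector<double> g(n, 0.0);  // g_i = sum_j alpha_j y_j K_ij
  for (int iter = 0; iter < max_iter; ++iter) {
    // second-order working-set selection (libsvm WSS2) on v_i = y_i - g_i
    int i_up = -1;
    double m_up = -1e300, m_low = 1e300;
    for (int t = 0; t < n; ++t) {
      double v = y[t] - g[t];
      bool in_up = (y[t] == 1) ? (m.alpha[t] < C) : (m.alpha[t] > 0);
      bool in_low = (y[t] == 1) ? (m.alpha[t] > 0) : (m.alpha[t] < C);
      if (in_up && v > m_up) { m_up = v; i_up = t; }
      if (in_low && v < m_low) m_low = v;
    }
    if (i_up < 0 || m_up - m_low <= eps) break;
    int i = i_up, j = -1;
    double best_gain = -1e300;
    for (int t = 0; t < n; ++t) {
      if (t == i) continue;
      bool in_low = (y[t] == 1) ? (m.alpha[t] > 0) : (m.alpha[t] < C);
      if (!in_low) continue;
      double diff = m_up - (y[t] - g[t]);
      if (diff <= eps) continue;
      // skip candidates whose clipped step cannot move
      double Lt, Ht;
      if (y[i] != y[t]) {
        Lt = std::max(0.0, m.alpha[t] - m.alpha[i]);
        Ht = std::min(C, C + m.alpha[t] - m.alpha[i]);
      } else {
        Lt = std::max(0.0, m.alpha[i] + m.alpha[t] - C);
        Ht = std::min(C, m.alpha[i] + m.alpha[t]);
      }
      if (Ht - Lt < 1e-14) continue;
      double eta_t = K[i * n + i] + K[t * n + t] - 2.0 * K[i * n + t];
      if (eta_t <= 1e-12) eta_t = 1e-12;
      double Ei = g[i] - y[i], Et = g[t] - y[t];
      double cand = m.alpha[t] + y[t] * (Ei - Et) / eta_t;
      cand = std::min(Ht, std::max(Lt, cand));
      if (std::fabs(cand - m.alpha[t]) < 1e-14) continue;
      double gain = diff * diff / eta_t;
      if (gain > best_gain) { best_gain = gain; j = t; }
    }
    if (j < 0) break;
    // analytic update of the pair (i, j)
    double ai = m.alpha[i], aj = m.alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj - ai);
      H = std::min(C, C + aj - ai);
    } else {
      L = std::max(0.0, ai + aj - C);
      H = std::min(C, ai + aj);
    }
    double eta = K[i * n + i] + K[j * n + j] - 2.0 * K[i * n + j];
    double aj_new;
    if (eta > 1e-12) {
      // Ei - Ej = (g_i - y_i) - (g_j - y_j) = m_low... derive directly
      double Ei = g[i] - y[i], Ej = g[j] - y[j];
      aj_new = aj + y[j] * (Ei - Ej) / eta;
    } else {
      aj_new = (y[i] - g[i] > y[j] - g[j]) ? H : L;  // linear in the pair
    }
    aj_new = std::min(H, std::max(L, aj_new));
    if (std::fabs(aj_new - aj) < 1e-14) break;
    double ai_new = ai + y[i] * y[j] * (aj - aj_new);
    // snap to the box within rounding tolerance so bound states are exact
    if (aj_new < 1e-12) aj_new = 0.0; else if (aj_new > C - 1e-12) aj_new = C;
    if (ai_new < 1e-12) ai_new = 0.0; else if (ai_new > C - 1e-12) ai_new = C;
    double di = (ai_new - ai) * y[i], dj = (aj_new - aj) * y[j];
    for (int t = 0; t < n; ++t)
      g[t] += di * K[i * n + t] + dj * K[j * n + t];
    m.alpha[i] = ai_new;
    m.alpha[j] = aj_new;
  }
  // b: midpoint of the feasible interval [max_up, min_low] at the optimum
  double lo = -1e300, hi = 1e300;
  for (int t = 0; t < n; ++t) {
    double v = y[t] - g[t];
    bool in_up = (y[t] == 1) ? (m.alpha[t] < C) : (m.alpha[t] > 0);
    bool in_low = (y[t] == 1) ? (m.alpha[t] > 0) : (m.alpha[t] < C);
    if (in_up && v > lo) lo = v;
    if (in_low && v < hi) hi = v;
  }
  if (lo > -1e299 && hi < 1e299) m.b = 0.5 * (lo + hi);
  else if (lo > -1e299) m.b = lo;
  else if (hi < 1e299) m.b = hi;
  return m;
}

} // namespace

// [[Rcpp::export(name = ".svm_smo_decision")]]
NumericVector svm_smo_decision(NumericMatrix Xtrain, IntegerVector y,
                               NumericMatrix Xtest, double C) {
  int n = Xtrain.nrow(), d = Xtrain.ncol();
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += Xtrain(i, k) * Xtrain(j, k);
      K[(size_t)i * n + j] = K[(size_t)j * n + i] = s;
    }
  std::vector<int> yy(y.begin(), y.end());
  SvmModel m = smo_train(K, yy, n, C);
  int nt = Xtest.nrow();
  NumericVector out(nt);
  for (int t = 0; t < nt; ++t) {
    double s = m.b;
    for (int i = 0; i < n; ++i) {
      if (m.alpha[i] <= 0) continue;
      double dot = 0.0;
      for (int k = 0; k < d; ++k) dot += Xtrain(i, k) * Xtest(t, k);
      s += m.alpha[i] * yy[i] * dot;
    }
    out[t] = s;
  }
  return out;
}

// fir: numeric array [n_vox, 2, n_bins, n_runs] flattened column-major.
// offsets: m x 3 integer matrix of lattice offsets (includes 0,0,0).
// bins: 1-based indices into the bin dimension to analyse.
// Returns per-voxel accuracy (NA outside mask).
// [[Rcpp::export(name = ".searchlight_cpp")]]
NumericVector searchlight_cpp(NumericVector fir, IntegerVector dims_grid,
                              LogicalVector mask, IntegerMatrix offsets,
                              int n_bins, int n_runs, IntegerVector bins,
                              double C, bool concatenate) {
  const int nx = dims_grid[0], ny = dims_grid[1], nz = dims_grid[2];
  const int n_vox = nx * ny * nz;
  const int n_off = offsets.nrow();
  const int n_sel = bins.size();
  const int n_train = 2 * (n_runs - 1);
  NumericVector acc(n_vox, NA_REAL);

  const double *F = fir.begin();
  // index into fir: v + n_vox*(c + 2*(b + n_bins*r))
  auto fidx = [&](int v, int c, int b, int r) {
    return (size_t)v + (size_t)n_vox * ((size_t)c + 2 * ((size_t)b + (size_t)n_bins * r));
  };

  std::vector<int> sphere;
  sphere.reserve(n_off);
  std::vector<int> ylab(n_train);

  for (int cz = 0; cz < nz; ++cz)
    for (int cy = 0; cy < ny; ++cy)
      for (int cx = 0; cx < nx; ++cx) {
        int centre = cx + nx * (cy + ny * cz);
        if (!mask[centre]) continue;
        sphere.clear();
        for (int o = 0; o < n_off; ++o) {
          int x = cx + offsets(o, 0), y = cy + offsets(o, 1),
              z = cz + offsets(o, 2);
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
            continue;
          int v = x + nx * (y + ny * z);
          if (mask[v]) sphere.push_back(v);
        }
        int d = (int)sphere.size();
        if (d == 0) continue;
        int dim_vec = concatenate ? d * n_sel : d;
        double correct = 0.0, total = 0.0;

        // buffers
        std::vector<double> Xtr((size_t)n_train * dim_vec);
        std::vector<double> xte0(dim_vec), xte1(dim_vec);

        for (int fold = 0; fold < n_runs; ++fold) {
          int n_pass = concatenate ? 1 : n_sel;
          for (int bp = 0; bp < n_pass; ++bp) {
            // assemble training matrix (rows = vectors) and test vectors
            int row = 0;
            for (int r = 0; r < n_runs; ++r) {
              if (r == fold) continue;
              for (int c = 0; c < 2; ++c) {
                double *dst = &Xtr[(size_t)row * dim_vec];
                if (concatenate) {
                  for (int s = 0; s < n_sel; ++s) {
                    int b = bins[s] - 1;
                    for (int q = 0; q < d; ++q)
                      dst[s * d + q] = F[fidx(sphere[q], c, b, r)];
                  }
                } else {
                  int b = bins[bp] - 1;
                  for (int q = 0; q < d; ++q)
                    dst[q] = F[fidx(sphere[q], c, b, r)];
                }
                ylab[row] = (c == 0) ? 1 : -1;
                ++row;
              }
            }
            for (int c = 0; c < 2; ++c) {
              double *dst = (c == 0) ? xte0.data() : xte1.data();
              if (concatenate) {
                for (int s = 0; s < n_sel; ++s) {
                  int b = bins[s] - 1;
                  for (int q = 0; q < d; ++q)
                    dst[s * d + q] = F[fidx(sphere[q], c, b, fold)];
                }
              } else {
                int b = bins[bp] - 1;
                for (int q = 0; q < d; ++q)
                  dst[q] = F[fidx(sphere[q], c, b, fold)];
              }
            }
            // per-fold mean removal (training mean applied to both sets)
            for (int q = 0; q < dim_vec; ++q) {
              double mu = 0.0;
              for (int i = 0; i < n_train; ++i) mu += Xtr[(size_t)i * dim_vec + q];
              mu /= n_train;
              for (int i = 0; i < n_train; ++i) Xtr[(size_t)i * dim_vec + q] -= mu;
              xte0[q] -= mu;
              xte1[q] -= mu;
            }
            // Gram
            std::vector<double> K((size_t)n_train * n_train);
            for (int i = 0; i < n_train; ++i)
              for (int j = i; j < n_train; ++j) {
                double s = 0.0;
                const double *xi = &Xtr[(size_t)i * dim_vec];
                const double *xj = &Xtr[(size_t)j * dim_vec];
                for (int q = 0; q < dim_vec; ++q) s += xi[q] * xj[q];
                K[(size_t)i * n_train + j] = K[(size_t)j * n_train + i] = s;
              }
            SvmModel mdl = smo_train(K, ylab, n_train, C);
            for (int c = 0; c < 2; ++c) {
              const double *xt = (c == 0) ? xte0.data() : xte1.data();
              double s = mdl.b;
              for (int i = 0; i < n_train; ++i) {
                if (mdl.alpha[i] <= 0) continue;
                const double *xi = &Xtr[(size_t)i * dim_vec];
                double dot = 0.0;
                for (int q = 0; q < dim_vec; ++q) dot += xi[q] * xt[q];
                s += mdl.alpha[i] * ylab[i] * dot;
              }
              int truth = (c == 0) ? 1 : -1;
              if (std::fabs(s) < 1e-9) correct += 0.5; // undecided: unbiased
              else if ((s > 0) == (truth > 0)) correct += 1.0;
              total += 1.0;
            }
          }
        }
        acc[centre] = correct / total;
      }
  return acc;
}

// 6-connectivity connected components of a 3-D logical array.
// [[Rcpp::export(name = ".label_clusters_cpp")]]
IntegerVector label_clusters_cpp(LogicalVector supra, IntegerVector dims_grid) {
  const int nx = dims_grid[0], ny = dims_grid[1], nz = dims_grid[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int v = 0; v < n; ++v) {
    if (!supra[v] || labels[v] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(v);
    labels[v] = next;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      int x = u % nx, y = (u / nx) % ny, z = u / (nx * ny);
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (supra[w] && labels[w] == 0) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// [[Rcpp::export(name = ".max_cluster_size_cpp")]]
int max_cluster_size_cpp(LogicalVector supra, IntegerVector dims_grid) {
  IntegerVector labels = label_clusters_cpp(supra, dims_grid);
  std::vector<int> counts;
  for (int i = 0; i < labels.size(); ++i) {
    int l = labels[i];
    if (l == 0) continue;
    if ((int)counts.size() < l) counts.resize(l, 0);
    counts[l - 1]++;
  }
  int mx = 0;
  for (size_t i = 0; i < counts.size(); ++i)
    if (counts[i] > mx) mx = counts[i];
  return mx;
}
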