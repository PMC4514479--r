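#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// EM for the ZOOPS / OOPS finite mixture motif model.
//
// Windows are candidate sites (either strand, reverse-complemented codes
// for the minus strand); X holds base codes 1..4, one row per window.
// Internally the codes are transposed to window-major storage so the
// scoring loop is contiguous. The log-likelihood omits the constant
// whole-sequence background term, so values are comparable across widths.
// The trace is evaluated at the current parameters before each update:
// a non-decreasing trace certifies EM monotonicity.

namespace {

struct EmState {
  std::vector<double> theta;  // 4 x W, column-major (base fastest)
  double gamma;
  double ll;
  std::vector<double> trace;
  std::vector<double> z;  // per-window responsibility
  std::vector<double> q;  // per-sequence occurrence posterior
};

void run_core(const std::vector<int>& xt, int n_win, int W,
              const std::vector<int>& seq0,
              const std::vector<double>& m_per_seq,
              const std::vector<double>& log_bg, bool zoops,
              double pseudocount, int max_iter, double tol, bool keep_z,
              EmState& st) {
  const int n_seq = (int)m_per_seq.size();
  std::vector<double> llr(4 * W), lr(n_win), s(n_seq), denom(n_seq),
      counts(4 * W);
  st.trace.clear();
  if (keep_z) st.z.assign(n_win, 0.0);
  st.q.assign(n_seq, 1.0);
  for (int it = 0; it < max_iter; ++it) {
    for (int w = 0; w < W; ++w)
      for (int b = 0; b < 4; ++b)
        llr[w * 4 + b] = std::log(st.theta[w * 4 + b]) - log_bg[b];
    std::fill(s.begin(), s.end(), 0.0);
    const int* xp = xt.data();
    for (int i = 0; i < n_win; ++i, xp += W) {
      double acc = 0;
      for (int w = 0; w < W; ++w) acc += llr[w * 4 + (xp[w] - 1)];
      lr[i] = std::exp(acc);
      s[seq0[i]] += lr[i];
    }
    double ll = 0, qsum = 0;
    for (int j = 0; j < n_seq; ++j) {
      if (zoops) {
        denom[j] = (1 - st.gamma) + st.gamma * s[j] / m_per_seq[j];
        ll += std::log(denom[j]);
        st.q[j] = st.gamma * (s[j] / m_per_seq[j]) / denom[j];
      } else {
        denom[j] = s[j];
        ll += std::log(s[j] / m_per_seq[j]);
        st.q[j] = 1.0;
      }
      qsum += st.q[j];
    }
    st.trace.push_back(ll);
    std::fill(counts.begin(), counts.end(), pseudocount);
    xp = xt.data();
    for (int i = 0; i < n_win; ++i, xp += W) {
      const int j = seq0[i];
      const double zi = zoops
          ? (st.gamma / m_per_seq[j]) * lr[i] / denom[j]
          : lr[i] / s[j];
      if (keep_z) st.z[i] = zi;
      for (int w = 0; w < W; ++w) counts[w * 4 + (xp[w] - 1)] += zi;
    }
    const bool conv = it > 0 &&
        std::fabs(st.trace[it] - st.trace[it - 1]) < tol;
    if (conv) break;
    for (int w = 0; w < W; ++w) {
      double cs = 0;
      for (int b = 0; b < 4; ++b) cs += counts[w * 4 + b];
      for (int b = 0; b < 4; ++b) st.theta[w * 4 + b] = counts[w * 4 + b] / cs;
    }
    st.gamma = zoops
        ? std::min(std::max(qsum / n_seq, 1e-3), 1 - 1e-3)
        : 1.0;
  }
  st.ll = st.trace.back();
}

std::vector<int> transpose_codes(const IntegerMatrix& X) {
  const int n = X.nrow(), W = X.ncol();
  std::vector<int> xt((size_t)n * W);
  for (int w = 0; w < W; ++w)
    for (int i = 0; i < n; ++i) xt[(size_t)i * W + w] = X(i, w);
  return xt;
}

}  // namespace

// Single EM run from an explicit starting matrix.
// [[Rcpp::export]]
List em_fit_cpp(IntegerMatrix X, IntegerVector seq_idx,
                NumericVector m_per_seq, NumericMatrix theta0,
                double gamma0, NumericVector bg, bool zoops,
                double pseudocount, int max_iter, double tol) {
  const int n_win = X.nrow(), W = X.ncol();
  std::vector<int> xt = transpose_codes(X);
  std::vector<int> seq0(n_win);
  for (int i = 0; i < n_win; ++i) seq0[i] = seq_idx[i] - 1;
  std::vector<double> mps(m_per_seq.begin(), m_per_seq.end());
  std::vector<double> log_bg(4);
  for (int b = 0; b < 4; ++b) log_bg[b] = std::log(bg[b]);
  EmState st;
  st.theta.assign(4 * W, 0.0);
  for (int w = 0; w < W; ++w)
    for (int b = 0; b < 4; ++b) st.theta[w * 4 + b] = theta0(b, w);
  st.gamma = gamma0;
  run_core(xt, n_win, W, seq0, mps, log_bg, zoops, pseudocount, max_iter,
           tol, true, st);
  NumericMatrix theta(4, W);
  for (int w = 0; w < W; ++w)
    for (int b = 0; b < 4; ++b) theta(b, w) = st.theta[w * 4 + b];
  return List::create(
      _["theta"] = theta, _["gamma"] = st.gamma, _["ll"] = st.ll,
      _["trace"] = NumericVector(st.trace.begin(), st.trace.end()),
      _["z"] = NumericVector(st.z.begin(), st.z.end()),
      _["q"] = NumericVector(st.q.begin(), st.q.end()));
}

// Full seeded discovery for one width: build a near-delta PWM (match
// probability match_p) from each seed window, screen every seed with a few
// EM iterations, refine the best n_refine to convergence, return the best
// final fit plus the screening log-likelihoods.
// [[Rcpp::export]]
List em_discover_cpp(IntegerMatrix X, IntegerVector seq_idx,
                     NumericVector m_per_seq, IntegerVector seed_rows,
                     double match_p, double gamma0, NumericVector bg,
                     bool zoops, double pseudocount, int screen_iter,
                     int n_refine, int max_iter, double tol) {
  const int n_win = X.nrow(), W = X.ncol();
  std::vector<int> xt = transpose_codes(X);
  std::vector<int> seq0(n_win);
  for (int i = 0; i < n_win; ++i) seq0[i] = seq_idx[i] - 1;
  std::vector<double> mps(m_per_seq.begin(), m_per_seq.end());
  std::vector<double> log_bg(4);
  for (int b = 0; b < 4; ++b) log_bg[b] = std::log(bg[b]);
  const double off_p = (1.0 - match_p) / 3.0;
  const int n_seed = seed_rows.size();

  auto seed_theta = [&](int row, std::vector<double>& theta) {
    theta.assign(4 * W, off_p);
    for (int w = 0; w < W; ++w)
      theta[w * 4 + (xt[(size_t)row * W + w] - 1)] = match_p;
  };

  std::vector<double> screen_ll(n_seed);
  std::vector<EmState> screened(n_seed);
  for (int k = 0; k < n_seed; ++k) {
    EmState& st = screened[k];
    seed_theta(seed_rows[k] - 1, st.theta);
    st.gamma = gamma0;
    run_core(xt, n_win, W, seq0, mps, log_bg, zoops, pseudocount,
             screen_iter, 0.0, false, st);
    screen_ll[k] = st.ll;
  }
  std::vector<int> ord(n_seed);
  for (int k = 0; k < n_seed; ++k) ord[k] = k;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return screen_ll[a] > screen_ll[b];
  });
  const int n_top = std::min(n_refine, n_seed);
  EmState best;
  double best_ll = -INFINITY;
  for (int t = 0; t < n_top; ++t) {
    EmState st = screened[ord[t]];
    run_core(xt, n_win, W, seq0, mps, log_bg, zoops, pseudocount, max_iter,
             tol, true, st);
    if (st.ll > best_ll) {
      best_ll = st.ll;
      best = st;
    }
  }
  NumericMatrix theta(4, W);
  for (int w = 0; w < W; ++w)
    for (int b = 0; b < 4; ++b) theta(b, w) = best.theta[w * 4 + b];
  return List::create(
      _["theta"] = theta, _["gamma"] = best.gamma, _["ll"] = best.ll,
      _["trace"] = NumericVector(best.trace.begin(), best.trace.end()),
      _["z"] = NumericVector(best.z.begin(), best.z.end()),
      _["q"] = NumericVector(best.q.begin(), best.q.end()),
      _["screen_ll"] = NumericVector(screen_ll.begin(), screen_ll.end()));
}
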