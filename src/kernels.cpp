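#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman
// convention): B = pairs of m-length templates within Chebyshev
// tolerance r, A = pairs whose (m+1)-length extensions also match.
// Self-matches excluded; i < j over the N - m usable templates.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (i + m < n && j + m < n && std::fabs(x[i + m] - x[j + m]) <= r)
        A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Suffix array by prefix doubling (O(n log^2 n)).
static std::vector<int> suffix_array(const std::vector<int>& s) {
  int n = s.size();
  std::vector<int> sa(n), rank_(s.begin(), s.end()), tmp(n);
  for (int i = 0; i < n; ++i) sa[i] = i;
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank_[a] != rank_[b]) return rank_[a] < rank_[b];
      int ra = a + k < n ? rank_[a + k] : -1;
      int rb = b + k < n ? rank_[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank_ = tmp;
    if (rank_[sa[n - 1]] == n - 1) break;
    if (k > n) break;
  }
  return sa;
}

// Kasai LCP: lcp[i] = longest common prefix of suffixes sa[i-1], sa[i].
static std::vector<int> lcp_array(const std::vector<int>& s,
                                  const std::vector<int>& sa) {
  int n = s.size();
  std::vector<int> rank_(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

// Longest previous factor (overlaps allowed), Crochemore & Ilie
// stack scheme over the suffix array.
static std::vector<int> lpf_array(const std::vector<int>& s) {
  int n = s.size();
  std::vector<int> sa = suffix_array(s);
  std::vector<int> lcp = lcp_array(s, sa);
  std::vector<int> lpf(n, 0);
  sa.push_back(-1);
  lcp.push_back(0);
  std::vector<std::pair<int,int> > st;  // (sa value, lcp value)
  for (int i = 0; i <= n; ++i) {
    int cur_lcp = lcp[i];
    while (!st.empty() &&
           (sa[i] < st.back().first ||
            (sa[i] > st.back().first && cur_lcp <= st.back().second))) {
      if (sa[i] < st.back().first) {
        lpf[st.back().first] = std::max(st.back().second, cur_lcp);
        cur_lcp = std::min(st.back().second, cur_lcp);
      } else {
        lpf[st.back().first] = st.back().second;
      }
      st.pop_back();
    }
    if (i < n) st.push_back(std::make_pair(sa[i], cur_lcp));
  }
  return lpf;
}

// Number of phrases in the LZ76 exhaustive-history parsing: the phrase
// starting at h spans LPF(h) reproducible characters plus the one
// innovative character that ends it (the final phrase may be truncated
// by the end of the sequence).
// [[Rcpp::export(name = ".lz76_phrases")]]
int lz76_phrases(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  std::vector<int> v(s.begin(), s.end());
  std::vector<int> lpf = lpf_array(v);
  int h = 0, c = 0;
  while (h < n) {
    h += lpf[h] + 1;
    ++c;
  }
  return c;
}

// Fenwick tree for the 2-d pair count below.
struct Fenwick {
  std::vector<int> t;
  int n;
  Fenwick(int n_) : t(n_ + 1, 0), n(n_) {}
  void add(int i, int v) { for (++i; i <= n; i += i & -i) t[i] += v; }
  int sum(int i) {            // prefix sum of [0, i]
    int s = 0;
    for (++i; i > 0; i -= i & -i) s += t[i];
    return s;
  }
  int range(int a, int b) {   // [a, b]
    if (b < a) return 0;
    return sum(b) - (a > 0 ? sum(a - 1) : 0);
  }
};

// Fast m = 1 template counts: B = unordered pairs i < j <= n-2 with
// |x_i - x_j| <= r (two-pointer over the sorted values); A additionally
// requires |x_{i+1} - x_{j+1}| <= r (sliding window over x with a
// Fenwick tree on the ranks of the successor values). Exactly matches
// the O(n^2) kernel.
// [[Rcpp::export(name = ".sampen_counts_m1")]]
NumericVector sampen_counts_m1(NumericVector x, double r) {
  int n = x.size();
  int nt = n - 1;  // usable templates of length 1
  if (nt < 2) return NumericVector::create(0.0, 0.0);
  // B
  std::vector<double> v(x.begin(), x.begin() + nt);
  std::vector<double> sv(v);
  std::sort(sv.begin(), sv.end());
  double B = 0.0;
  int lo = 0;
  for (int j = 0; j < nt; ++j) {
    while (sv[j] - sv[lo] > r) ++lo;
    B += j - lo;
  }
  // A: points (x_i, x_{i+1}), i = 0..n-2
  std::vector<int> ord(nt);
  for (int i = 0; i < nt; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  // ranks of successor values over the sorted unique successors
  std::vector<double> succ(nt);
  for (int i = 0; i < nt; ++i) succ[i] = x[i + 1];
  std::vector<double> us(succ);
  std::sort(us.begin(), us.end());
  us.erase(std::unique(us.begin(), us.end()), us.end());
  int m_u = us.size();
  Fenwick fw(m_u);
  double A = 0.0;
  int tail = 0;
  for (int k = 0; k < nt; ++k) {
    int j = ord[k];
    while (x[ord[tail]] < x[j] - r) {
      int i0 = ord[tail];
      int ri = std::lower_bound(us.begin(), us.end(), succ[i0]) -
               us.begin();
      fw.add(ri, -1);
      ++tail;
    }
    int rlo = std::lower_bound(us.begin(), us.end(), succ[j] - r) -
              us.begin();
    int rhi = std::upper_bound(us.begin(), us.end(), succ[j] + r) -
              us.begin() - 1;
    A += fw.range(rlo, rhi);
    int rj = std::lower_bound(us.begin(), us.end(), succ[j]) - us.begin();
    fw.add(rj, 1);
  }
  return NumericVector::create(A, B);
}

// Desaturation scanner. Baseline = maximum of the last `win` samples
// observed OUTSIDE events (frozen while an event is ongoing). An event
// opens when x drops to `drop` or more below baseline and closes on
// recovery to within `margin` of it. Returns one row per raw event:
// start index, end index (1-based, half-open), seconds spent at or
// below baseline - drop, and depth (baseline - minimum).
// [[Rcpp::export(name = ".desat_scan")]]
NumericMatrix desat_scan(NumericVector x, double fs, double drop,
                         double win_s, double margin) {
  int n = x.size();
  int win = std::max(1, (int)std::lround(win_s * fs));
  std::deque<std::pair<double,int> > dq;  // (value, push index) max-deque
  int pushed = 0;
  bool in_ev = false;
  double bl = x.size() ? x[0] : 0.0, ev_min = 0.0;
  int ev_start = 0;
  double below = 0.0;
  std::vector<double> out;
  for (int i = 0; i < n; ++i) {
    if (!in_ev) {
      while (!dq.empty() && dq.back().first <= x[i]) dq.pop_back();
      dq.push_back(std::make_pair(x[i], pushed));
      ++pushed;
      while (!dq.empty() && dq.front().second <= pushed - win - 1)
        dq.pop_front();
      bl = dq.front().first;
      if (pushed > win / 10 && x[i] <= bl - drop) {
        in_ev = true;
        ev_start = i;
        ev_min = x[i];
        below = 1.0;
      }
    } else {
      if (x[i] < ev_min) ev_min = x[i];
      if (x[i] <= bl - drop) below += 1.0;
      if (x[i] >= bl - margin) {
        out.push_back(ev_start + 1);
        out.push_back(i + 1);
        out.push_back(below / fs);
        out.push_back(bl - ev_min);
        in_ev = false;
      }
    }
  }
  if (in_ev) {
    out.push_back(ev_start + 1);
    out.push_back(n + 1);
    out.push_back(below / fs);
    out.push_back(bl - ev_min);
  }
  int rows = out.size() / 4;
  NumericMatrix res(rows, 4);
  for (int r2 = 0; r2 < rows; ++r2)
    for (int c2 = 0; c2 < 4; ++c2) res(r2, c2) = out[r2 * 4 + c2];
  return res;
}

// Airflow event scanner on an amplitude envelope. Reference = mean of
// the last `win` envelope samples observed outside events (frozen during
// events). An event opens when the envelope falls below hyp_frac * ref
// and closes on recovery above it. Returns start index, end index,
// seconds below ap_frac * ref, and 1 - min_env/ref (fractional drop).
// [[Rcpp::export(name = ".airflow_scan")]]
NumericMatrix airflow_scan(NumericVector env, double fs, double win_s,
                           double ap_frac, double hyp_frac) {
  int n = env.size();
  int win = std::max(1, (int)std::lround(win_s * fs));
  std::vector<double> ring(win, 0.0);
  int cnt = 0, head = 0;
  double sum = 0.0;
  bool in_ev = false;
  double ref = 0.0, ev_min = 0.0;
  int ev_start = 0;
  double below_ap = 0.0;
  std::vector<double> out;
  for (int i = 0; i < n; ++i) {
    if (!in_ev) {
      if (cnt == win) sum -= ring[head];
      ring[head] = env[i];
      sum += env[i];
      head = (head + 1) % win;
      if (cnt < win) ++cnt;
      ref = sum / cnt;
      if (cnt > win / 12 && env[i] < hyp_frac * ref) {
        in_ev = true;
        ev_start = i;
        ev_min = env[i];
        below_ap = env[i] < ap_frac * ref ? 1.0 : 0.0;
      }
    } else {
      if (env[i] < ev_min) ev_min = env[i];
      if (env[i] < ap_frac * ref) below_ap += 1.0;
      if (env[i] >= hyp_frac * ref) {
        out.push_back(ev_start + 1);
        out.push_back(i + 1);
        out.push_back(below_ap / fs);
        out.push_back(1.0 - ev_min / ref);
        in_ev = false;
      }
    }
  }
  if (in_ev) {
    out.push_back(ev_start + 1);
    out.push_back(n + 1);
    out.push_back(below_ap / fs);
    out.push_back(1.0 - ev_min / ref);
  }
  int rows = out.size() / 4;
  NumericMatrix res(rows, 4);
  for (int r2 = 0; r2 < rows; ++r2)
    for (int c2 = 0; c2 < 4; ++c2) res(r2, c2) = out[r2 * 4 + c2];
  return res;
}
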