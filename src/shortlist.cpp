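#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

namespace {

struct Cand {
  double tm;
  int start;    // backbone start offset (tie-break 1)
  int bidx;     // backbone index as supplied (tie-break 2)
  std::vector<int> mask;  // 1-based positions (tie-break 3, lexicographic)
};

// "better" ordering: higher Tm, then earlier start, then backbone order,
// then lexicographically smaller mask
struct Better {
  bool operator()(const Cand& a, const Cand& b) const {
    if (a.tm != b.tm) return a.tm > b.tm;
    if (a.start != b.start) return a.start < b.start;
    if (a.bidx != b.bidx) return a.bidx < b.bidx;
    return a.mask < b.mask;
  }
};

// design rules: no run of more than max_run consecutive positions, and no
// gc_run-long stretch of consecutive positions all carrying G or C
bool valid_mask(const std::vector<int>& comb, const std::vector<bool>& gc,
                int max_run, int gc_run) {
  int run = 1, gcrun = gc[comb[0] - 1] ? 1 : 0;
  for (size_t t = 1; t < comb.size(); ++t) {
    if (comb[t] == comb[t - 1] + 1) {
      ++run;
      if (run > max_run) return false;
      if (gc[comb[t] - 1]) {
        ++gcrun;
        if (gcrun >= gc_run) return false;
      } else {
        gcrun = 0;
      }
    } else {
      run = 1;
      gcrun = gc[comb[t] - 1] ? 1 : 0;
    }
  }
  return true;
}

}  // namespace

// Streaming top-k shortlist over every LNA mask of every backbone window.
// backbones: list of list(inc = numeric per-position Tm increments,
//                         gc  = logical per-position G/C flags,
//                         tm  = DNA-only backbone Tm,
//                         start = 1-based window start)
// [[Rcpp::export]]
List cpp_shortlist(List backbones, IntegerVector sizes, int k,
                   int max_run, int gc_run) {
  std::multiset<Cand, Better> top;
  std::vector<int> szs(sizes.begin(), sizes.end());
  std::sort(szs.begin(), szs.end());

  for (int bi = 0; bi < backbones.size(); ++bi) {
    List bb = backbones[bi];
    NumericVector inc = bb["inc"];
    LogicalVector gcv = bb["gc"];
    double base_tm = as<double>(bb["tm"]);
    int start = as<int>(bb["start"]);
    int n = inc.size();
    std::vector<bool> gc(n);
    for (int i = 0; i < n; ++i) gc[i] = gcv[i];

    for (int m : szs) {
      if (m > n) continue;
      std::vector<int> comb(m);
      for (int i = 0; i < m; ++i) comb[i] = i + 1;
      bool more = true;
      while (more) {
        if (valid_mask(comb, gc, max_run, gc_run)) {
          double tm = base_tm;
          for (int i = 0; i < m; ++i) tm += inc[comb[i] - 1];
          if ((int)top.size() < k) {
            top.insert({tm, start, bi + 1, comb});
          } else {
            const Cand& worst = *top.rbegin();
            Cand cand{tm, start, bi + 1, comb};
            if (Better()(cand, worst)) {
              top.insert(std::move(cand));
              top.erase(std::prev(top.end()));
            }
          }
        }
        // lexicographic successor
        int i = m - 1;
        while (i >= 0 && comb[i] == n - m + i + 1) --i;
        if (i < 0) {
          more = false;
        } else {
          ++comb[i];
          for (int j = i + 1; j < m; ++j) comb[j] = comb[j - 1] + 1;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  int out_n = top.size();
  NumericVector tm(out_n);
  IntegerVector bidx(out_n);
  List positions(out_n);
  int j = 0;
  for (const Cand& c : top) {
    tm[j] = c.tm;
    bidx[j] = c.bidx;
    positions[j] = IntegerVector(c.mask.begin(), c.mask.end());
    ++j;
  }
  return List::create(_["tm"] = tm, _["b_idx"] = bidx, _["positions"] = positions);
}
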