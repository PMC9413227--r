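#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <set>
#include <vector>
using namespace Rcpp;

// Sample-level core of the precise-timing spike detector.
//
// x    : voltage samples (uV)
// plp  : peak lifetime period in samples
// refr : refractory period in samples (accepted events differ by >= refr)
// thr  : differential (peak-to-peak) threshold in uV
//
// Scans the trace for relative extrema, pairs each extremum with the
// opposite-polarity extremum within the peak lifetime period that maximises
// the differential amplitude, accepts pairs exceeding the threshold, and
// timestamps the event at the extremum of larger absolute amplitude (ties
// broken toward the earlier one). Refractory conflicts keep the event of
// larger amplitude.
// [[Rcpp::export]]
DataFrame ptsd_core(NumericVector x, int plp, int refr, double thr) {
  const int n = x.size();
  std::vector<int> eidx;
  std::vector<int> etype; // +1 local max, -1 local min

  // relative extrema; plateaus contribute their first sample
  int dir = 0;
  int last_end = 0;
  for (int i = 1; i < n; ++i) {
    double d = x[i] - x[i - 1];
    if (d == 0.0) continue;
    int nd = d > 0 ? 1 : -1;
    if (dir != 0 && nd != dir) {
      eidx.push_back(last_end);
      etype.push_back(dir); // was rising -> max, falling -> min
    }
    dir = nd;
    last_end = i;
  }

  const int m = (int)eidx.size();
  std::vector<int> cpos;
  std::vector<double> camp;
  cpos.reserve(64);
  camp.reserve(64);

  for (int a = 0; a < m; ++a) {
    double best = -1.0;
    int bidx = -1;
    for (int b = a + 1; b < m && eidx[b] - eidx[a] <= plp; ++b) {
      if (etype[b] == etype[a]) continue;
      double amp = std::fabs(x[eidx[b]] - x[eidx[a]]);
      if (amp > best) {
        best = amp;
        bidx = b;
      }
    }
    if (bidx >= 0 && best >= thr && best > 0.0) {
      int p = (std::fabs(x[eidx[bidx]]) > std::fabs(x[eidx[a]]))
                  ? eidx[bidx]
                  : eidx[a];
      cpos.push_back(p);
      camp.push_back(best);
    }
  }

  // deduplicate by position, keep the largest amplitude
  const int nc = (int)cpos.size();
  std::vector<int> ord(nc);
  for (int i = 0; i < nc; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int i, int j) {
    if (cpos[i] != cpos[j]) return cpos[i] < cpos[j];
    return camp[i] > camp[j];
  });
  std::vector<int> upos;
  std::vector<double> uamp;
  for (int k = 0; k < nc; ++k) {
    int i = ord[k];
    if (!upos.empty() && upos.back() == cpos[i]) continue;
    upos.push_back(cpos[i]);
    uamp.push_back(camp[i]);
  }

  // refractory enforcement: greedy by amplitude (ties -> earlier event)
  const int nu = (int)upos.size();
  std::vector<int> ord2(nu);
  for (int i = 0; i < nu; ++i) ord2[i] = i;
  std::sort(ord2.begin(), ord2.end(), [&](int i, int j) {
    if (uamp[i] != uamp[j]) return uamp[i] > uamp[j];
    return upos[i] < upos[j];
  });
  std::set<int> accepted;
  std::vector<int> keep;
  for (int k = 0; k < nu; ++k) {
    int i = ord2[k];
    int p = upos[i];
    bool conflict = false;
    auto it = accepted.lower_bound(p);
    if (it != accepted.end() && *it - p < refr) conflict = true;
    if (!conflict && it != accepted.begin()) {
      --it;
      if (p - *it < refr) conflict = true;
    }
    if (!conflict) {
      accepted.insert(p);
      keep.push_back(i);
    }
  }
  std::sort(keep.begin(), keep.end(),
            [&](int i, int j) { return upos[i] < upos[j]; });

  IntegerVector out_idx(keep.size());
  NumericVector out_amp(keep.size());
  for (size_t k = 0; k < keep.size(); ++k) {
    out_idx[k] = upos[keep[k]] + 1; // 1-based for R
    out_amp[k] = uamp[keep[k]];
  }
  return DataFrame::create(_["sample"] = out_idx, _["amplitude"] = out_amp);
}
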