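#include <Rcpp.h>
using namespace Rcpp;

// Topographic prominence of local minima of `signal`, computed as the
// standard peak prominence on the inverted signal: for each trough,
// extend left and right until a deeper trough (higher inverted peak) or
// the signal edge is reached; the key col on each side is the highest
// signal value on that stretch; prominence = (lower key col) - trough.
// Candidates whose depth below the global maximum is smaller than
// `min_prominence` are skipped (their prominence cannot reach it).
// [[Rcpp::export]]
DataFrame minima_prominence(NumericVector signal, double min_prominence) {
  const int n = signal.size();
  std::vector<int> idx;
  std::vector<double> prom;
  if (n < 3) return DataFrame::create(_["index"] = idx, _["prominence"] = prom);
  const double gmax = *std::max_element(signal.begin(), signal.end());
  for (int i = 1; i < n - 1; ++i) {
    if (!(signal[i] < signal[i - 1] && signal[i] <= signal[i + 1])) continue;
    if (signal[i] == signal[i + 1]) {           // flat trough: keep first
      int j = i + 1;
      while (j < n - 1 && signal[j] == signal[i]) ++j;
      if (signal[j] < signal[i]) continue;      // descending shelf, not a min
    }
    if (gmax - signal[i] < min_prominence) continue;
    const double v = signal[i];
    double col_left = R_NegInf;
    for (int j = i - 1; j >= 0; --j) {
      if (signal[j] > col_left) col_left = signal[j];
      if (signal[j] < v) break;
    }
    double col_right = R_NegInf;
    for (int j = i + 1; j < n; ++j) {
      if (signal[j] > col_right) col_right = signal[j];
      if (signal[j] < v) break;
    }
    const double pr = std::min(col_left, col_right) - v;
    if (pr >= min_prominence) {
      idx.push_back(i + 1);                     // 1-based
      prom.push_back(pr);
    }
  }
  return DataFrame::create(_["index"] = idx, _["prominence"] = prom);
}
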