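// Connected-component labeling of binary masks with selectable 4- or
// 8-connectivity. Labels are assigned in column-major scan order (the order R
// stores matrices), starting at 1; background stays 0.

#include <Rcpp.h>
#include <vector>

// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_label_regions(Rcpp::IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> nb;
  nb.push_back({-1, 0});
  nb.push_back({1, 0});
  nb.push_back({0, -1});
  nb.push_back({0, 1});
  if (connectivity == 8) {
    nb.push_back({-1, -1});
    nb.push_back({-1, 1});
    nb.push_back({1, -1});
    nb.push_back({1, 1});
  }
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back({i, j});
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (const auto& d : nb) {
          const int rr = r + d.first, cc = c + d.second;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  return lab;
}
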