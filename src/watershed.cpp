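// Seeded preflooded watershed: priority-flood from seed pixels with
// deterministic (value, insertion order) processing.  Seeds whose floods
// meet at a level below the preflood depth are merged (union-find), so
// basins separated by a saddle shallower than the preflood level become
// one basin.  8-connectivity.

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  double v;
  long long order;
  int idx;
};

struct NodeCmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.v != b.v) return a.v > b.v;   // min-heap on value
    return a.order > b.order;           // FIFO among equal values
  }
};

int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix seeded_watershed_cpp(NumericMatrix field,
                                   IntegerVector seed_row,
                                   IntegerVector seed_col,
                                   double preflood_h) {
  const int H = field.nrow(), W = field.ncol();
  const int k = seed_row.size();
  if (k < 1) stop("no seeds");
  std::vector<int> label((size_t)H * W, 0);
  std::vector<int> parent(k + 1);
  for (int i = 0; i <= k; ++i) parent[i] = i;

  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;
  long long counter = 0;
  for (int s = 0; s < k; ++s) {
    int r = seed_row[s], c = seed_col[s];
    if (r < 0 || r >= H || c < 0 || c >= W) stop("seed outside field");
    int idx = c * H + r;
    if (label[idx] == 0) {
      label[idx] = s + 1;
      pq.push({field[idx], counter++, idx});
    } else {
      int r1 = find_root(parent, label[idx]);
      int r2 = find_root(parent, s + 1);
      if (r1 != r2) parent[std::max(r1, r2)] = std::min(r1, r2);
    }
  }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    const int idx = nd.idx;
    const int r = idx % H, c = idx / H;
    const int lab = label[idx];
    for (int d = 0; d < 8; ++d) {
      const int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      const int nidx = cc * H + rr;
      if (label[nidx] == 0) {
        label[nidx] = lab;
        pq.push({field[nidx], counter++, nidx});
      } else {
        int r1 = find_root(parent, label[nidx]);
        int r2 = find_root(parent, lab);
        if (r1 != r2) {
          // the two floods meet here; saddle level of the contact
          double meet = std::max(field[idx], field[nidx]);
          if (meet < preflood_h)
            parent[std::max(r1, r2)] = std::min(r1, r2);
        }
      }
    }
  }

  // densify root labels in order of first seed appearance
  std::vector<int> dense(k + 1, 0);
  int next = 0;
  for (int s = 1; s <= k; ++s) {
    int r = find_root(parent, s);
    if (dense[r] == 0) dense[r] = ++next;
  }
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int idx = c * H + r;
      out(r, c) = dense[find_root(parent, label[idx])];
    }
  return out;
}
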