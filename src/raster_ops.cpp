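#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Raster primitives with exact, deterministic contracts: connected-component
// labeling, border-seeded hole filling, boundary edge-segment perimeters,
// luminance relief, marker-seeded priority-flood watershed with FIFO
// tie-breaking, and Moore-neighbor boundary tracing.  All coordinates are
// (row, col), 1-based on the R side.

static inline int idx(int r, int c, int H) { return c * H + r; }

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix labels(H, W);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  // neighbor offsets: 4-connectivity first, then diagonals
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next;
      labels(r, c) = next;
      stack.push_back(idx(r, c, H));
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (mask(qr, qc) && labels(qr, qc) == 0) {
            labels(qr, qc) = next;
            stack.push_back(idx(qr, qc, H));
          }
        }
      }
    }
  }
  return labels;
}

// Fill enclosed holes: background (false) pixels not 4-connected to the
// image border become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix outside(H, W);  // background reachable from the border
  std::vector<int> stack;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      if ((r == 0 || r == H - 1 || c == 0 || c == W - 1) && !mask(r, c) &&
          !outside(r, c)) {
        outside(r, c) = true;
        stack.push_back(idx(r, c, H));
      }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int pr = p % H, pc = p / H;
    for (int k = 0; k < 4; ++k) {
      int qr = pr + dr[k], qc = pc + dc[k];
      if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
      if (!mask(qr, qc) && !outside(qr, qc)) {
        outside(qr, qc) = true;
        stack.push_back(idx(qr, qc, H));
      }
    }
  }
  LogicalMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) out(r, c) = mask(r, c) || !outside(r, c);
  return out;
}

// Per-component perimeter: number of unit edge segments between a pixel of
// the component and a pixel outside it (out-of-image counts as outside).
// [[Rcpp::export]]
IntegerVector cpp_component_perimeters(IntegerMatrix labels, int nlab) {
  const int H = labels.nrow(), W = labels.ncol();
  IntegerVector per(nlab);
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int l = labels(r, c);
      if (l <= 0) continue;
      for (int k = 0; k < 4; ++k) {
        int qr = r + dr[k], qc = c + dc[k];
        bool same = qr >= 0 && qr < H && qc >= 0 && qc < W &&
                    labels(qr, qc) == l;
        if (!same) per[l - 1] += 1;
      }
    }
  return per;
}

// Relief: per-pixel maximum absolute luminance difference to its existing
// 4-neighbors.
// [[Rcpp::export]]
NumericMatrix cpp_relief(NumericMatrix lum) {
  const int H = lum.nrow(), W = lum.ncol();
  NumericMatrix out(H, W);
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double m = 0.0;
      for (int k = 0; k < 4; ++k) {
        int qr = r + dr[k], qc = c + dc[k];
        if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
        double d = std::abs(lum(r, c) - lum(qr, qc));
        if (d > m) m = d;
      }
      out(r, c) = m;
    }
  return out;
}

struct QEntry {
  double relief;
  long long order;
  int pixel;
  int label;
};
struct QCmp {
  // min-heap on (relief, insertion order): FIFO among equal relief
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.relief != b.relief) return a.relief > b.relief;
    return a.order > b.order;
  }
};

// Marker-seeded priority-flood watershed.  Marker pixels keep their label.
// Initialization scans pixels in raster order (rows top to bottom, columns
// left to right) and enqueues unlabeled 4-neighbors of labeled pixels in
// neighbor order up, down, left, right; the queue pops the lowest-relief
// entry, FIFO among equal relief; a popped unlabeled pixel takes the label
// of the pixel that enqueued it and enqueues its own unlabeled neighbors.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix relief, IntegerMatrix markers) {
  const int H = relief.nrow(), W = relief.ncol();
  IntegerMatrix labels = clone(markers);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  long long counter = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      if (labels(r, c) <= 0) continue;
      for (int k = 0; k < 4; ++k) {
        int qr = r + dr[k], qc = c + dc[k];
        if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
        if (labels(qr, qc) == 0)
          pq.push({relief(qr, qc), counter++, idx(qr, qc, H), labels(r, c)});
      }
    }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int pr = e.pixel % H, pc = e.pixel / H;
    if (labels(pr, pc) != 0) continue;
    labels(pr, pc) = e.label;
    for (int k = 0; k < 4; ++k) {
      int qr = pr + dr[k], qc = pc + dc[k];
      if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
      if (labels(qr, qc) == 0)
        pq.push({relief(qr, qc), counter++, idx(qr, qc, H), e.label});
    }
  }
  return labels;
}

// Moore-neighbor boundary trace, clockwise on screen (rows increase
// downward), starting from the topmost-then-leftmost foreground pixel.
// Returns a closed contour (first row repeated last), 1-based coordinates.
// Termination: the (current, backtrack) state returns to its start value,
// so one-pixel-wide spurs are traversed on both sides.
// [[Rcpp::export]]
IntegerMatrix cpp_moore_boundary(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < H && sr < 0; ++r)
    for (int c = 0; c < W; ++c)
      if (mask(r, c)) { sr = r; sc = c; break; }
  if (sr < 0) stop("empty mask");
  // clockwise ring starting at N
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);
  int cr = sr, cc = sc;
  int bdir = 6;  // backtrack = W of start (start is topmost-leftmost)
  const int b0 = bdir;
  long long guard = 8LL * H * W + 16;
  while (guard-- > 0) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (bdir + k) % 8;
      int qr = cr + dr[d], qc = cc + dc[d];
      if (qr >= 0 && qr < H && qc >= 0 && qc < W && mask(qr, qc)) {
        found = d;
        break;
      }
    }
    if (found < 0) break;  // isolated pixel
    // backtrack for the next step: the neighbor examined just before the hit,
    // expressed as a direction from the new current pixel
    int prevd = (found + 7) % 8;
    int br = cr + dr[prevd], bc = cc + dc[prevd];
    cr += dr[found]; cc += dc[found];
    // direction from new current back to the last examined false pixel
    bdir = 0;
    for (int d = 0; d < 8; ++d)
      if (cr + dr[d] == br && cc + dc[d] == bc) { bdir = d; break; }
    if (cr == sr && cc == sc && bdir == b0) break;
    rows.push_back(cr); cols.push_back(cc);
  }
  rows.push_back(sr); cols.push_back(sc);  // close the contour
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i] + 1;
    out(i, 1) = cols[i] + 1;
  }
  return out;
}
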