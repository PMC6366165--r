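#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Grid convention: matrices are indexed (row, col) = (iy, ix) with iy = 0 at
// the lower-left of the landscape; x runs along columns, y along rows.

static inline bool in_grid(int ix, int iy, int W, int H) {
  return ix >= 0 && ix < W && iy >= 0 && iy < H;
}

// Sequential-seeding habitat generator.  Habitat cells are placed one at a
// time: with probability `agg` the next cell is drawn uniformly from the
// empty Moore-neighbours of existing habitat (the frontier, if non-empty),
// otherwise uniformly from all empty cells.  Guarantees the exact habitat
// count and clustering that increases monotonically with `agg`.
// [[Rcpp::export]]
LogicalMatrix generate_habitat_cpp(int width, int height, int n_habitat, double agg) {
  const int W = width, H = height, N = W * H;
  if (n_habitat < 0 || n_habitat > N)
    stop("habitat cell count out of range");
  std::vector<char> state(N, 0);        // 0 empty, 1 habitat
  // empty-cell pool with positional index for O(1) swap-removal
  std::vector<int> empty_pool(N), empty_pos(N);
  for (int i = 0; i < N; ++i) { empty_pool[i] = i; empty_pos[i] = i; }
  int n_empty = N;
  // frontier pool: empty cells Moore-adjacent to habitat
  std::vector<int> frontier;
  std::vector<int> frontier_pos(N, -1);
  frontier.reserve(N);

  auto remove_empty = [&](int cell) {
    int p = empty_pos[cell];
    int last = empty_pool[n_empty - 1];
    empty_pool[p] = last; empty_pos[last] = p;
    --n_empty;
    empty_pos[cell] = -1;
  };
  auto remove_frontier = [&](int cell) {
    int p = frontier_pos[cell];
    if (p < 0) return;
    int last = frontier.back();
    frontier[p] = last; frontier_pos[last] = p;
    frontier.pop_back();
    frontier_pos[cell] = -1;
  };
  auto add_frontier = [&](int cell) {
    if (frontier_pos[cell] >= 0 || state[cell] != 0) return;
    frontier_pos[cell] = (int) frontier.size();
    frontier.push_back(cell);
  };

  for (int placed = 0; placed < n_habitat; ++placed) {
    int cell;
    bool from_frontier = !frontier.empty() && unif_rand() < agg;
    if (from_frontier) {
      cell = frontier[(int)(unif_rand() * frontier.size()) % frontier.size()];
    } else {
      cell = empty_pool[(int)(unif_rand() * n_empty) % n_empty];
    }
    state[cell] = 1;
    remove_empty(cell);
    remove_frontier(cell);
    int ix = cell % W, iy = cell / W;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0) continue;
        int nx = ix + dx, ny = iy + dy;
        if (in_grid(nx, ny, W, H)) add_frontier(ny * W + nx);
      }
  }

  LogicalMatrix mask(H, W);
  for (int iy = 0; iy < H; ++iy)
    for (int ix = 0; ix < W; ++ix)
      mask(iy, ix) = state[iy * W + ix] == 1;
  return mask;
}

// Modified-random-cluster habitat generator.  A Bernoulli(p = agg) seed
// field is labelled into Moore-connected clusters (the neighbourhood used
// throughout the model); clusters are then assigned
// to habitat in random order until the exact target count is reached, the
// overflowing cluster being truncated to a BFS-connected subset.  Any
// shortfall (p below the habitat fraction) is filled cell by cell: with
// probability `agg` from the Moore frontier of existing habitat, otherwise
// uniformly from the empty cells.
// [[Rcpp::export]]
LogicalMatrix generate_habitat_cluster_cpp(int width, int height,
                                           int n_habitat, double agg) {
  const int W = width, H = height, N = W * H;
  if (n_habitat < 0 || n_habitat > N)
    stop("habitat cell count out of range");
  std::vector<char> seed(N, 0), habitat(N, 0);
  for (int i = 0; i < N; ++i) seed[i] = unif_rand() < agg ? 1 : 0;

  // label Moore-connected seed clusters
  std::vector<int> lab(N, 0);
  std::vector<std::vector<int> > clusters;
  std::queue<int> q;
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1},
            dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  for (int i = 0; i < N; ++i) {
    if (!seed[i] || lab[i]) continue;
    clusters.push_back(std::vector<int>());
    std::vector<int> &cl = clusters.back();
    int id = (int) clusters.size();
    lab[i] = id;
    q.push(i);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      cl.push_back(c);
      int cx = c % W, cy = c / W;
      for (int k = 0; k < 8; ++k) {
        int nx = cx + dx8[k], ny = cy + dy8[k];
        if (!in_grid(nx, ny, W, H)) continue;
        int n = ny * W + nx;
        if (seed[n] && !lab[n]) { lab[n] = id; q.push(n); }
      }
    }
  }

  // Fisher-Yates shuffle of cluster order
  std::vector<int> ord(clusters.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int) i;
  for (int i = (int) ord.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1)) % (i + 1);
    std::swap(ord[i], ord[j]);
  }

  // Assign clusters to habitat in random order.  A single patch is capped
  // at half the habitat budget so a landscape is always a mosaic of at
  // least two discrete patches (dispersal between patches stays defined
  // even when the seed field percolates into one giant cluster); capped
  // blobs carved from the same cluster are separated by a one-cell buffer.
  const int cap = std::max(1, (n_habitat + 1) / 2);
  int remaining = n_habitat;
  std::vector<char> blocked(N, 0);  // used or inside a separation buffer
  for (size_t oi = 0; oi < ord.size() && remaining > 0; ++oi) {
    std::vector<int> &cl = clusters[ord[oi]];
    if ((int) cl.size() <= std::min(remaining, cap)) {
      for (size_t j = 0; j < cl.size(); ++j) habitat[cl[j]] = 1;
      remaining -= (int) cl.size();
      continue;
    }
    // carve capped BFS blobs out of this cluster until it is exhausted
    // or the budget is met
    for (int blob = 0; remaining > 0; ++blob) {
      std::vector<int> avail;
      for (size_t j = 0; j < cl.size(); ++j)
        if (!habitat[cl[j]] && !blocked[cl[j]]) avail.push_back(cl[j]);
      if (avail.empty()) break;
      int start = avail[(int)(unif_rand() * avail.size()) % avail.size()];
      int want = std::min(remaining, cap);
      std::vector<int> taken;
      std::vector<char> seen(N, 0);
      std::queue<int> bq;
      bq.push(start);
      seen[start] = 1;
      while (!bq.empty() && (int) taken.size() < want) {
        int c = bq.front(); bq.pop();
        habitat[c] = 1;
        taken.push_back(c);
        int cx = c % W, cy = c / W;
        for (int k = 0; k < 8; ++k) {
          int nx = cx + dx8[k], ny = cy + dy8[k];
          if (!in_grid(nx, ny, W, H)) continue;
          int n = ny * W + nx;
          if (seed[n] && !habitat[n] && !blocked[n] && !seen[n]) {
            seen[n] = 1;
            bq.push(n);
          }
        }
      }
      remaining -= (int) taken.size();
      // one-cell Moore buffer so the next blob cannot touch this one
      for (size_t j = 0; j < taken.size(); ++j) {
        int cx = taken[j] % W, cy = taken[j] / W;
        for (int k = 0; k < 8; ++k) {
          int nx = cx + dx8[k], ny = cy + dy8[k];
          if (in_grid(nx, ny, W, H) && !habitat[ny * W + nx])
            blocked[ny * W + nx] = 1;
        }
      }
    }
  }

  // shortfall: accrete remaining cells (frontier with probability agg)
  if (remaining > 0) {
    std::vector<int> empties, empty_pos(N, -1);
    empties.reserve(N);
    for (int i = 0; i < N; ++i)
      if (!habitat[i]) { empty_pos[i] = (int) empties.size(); empties.push_back(i); }
    while (remaining > 0) {
      int cell = -1;
      if (unif_rand() < agg) {
        // collect frontier lazily: sample empties until one touches habitat
        for (int tries = 0; tries < 64; ++tries) {
          int cand = empties[(int)(unif_rand() * empties.size()) % empties.size()];
          int cx = cand % W, cy = cand / W;
          bool touches = false;
          for (int dy = -1; dy <= 1 && !touches; ++dy)
            for (int dxx = -1; dxx <= 1 && !touches; ++dxx) {
              if (dxx == 0 && dy == 0) continue;
              int nx = cx + dxx, ny = cy + dy;
              if (in_grid(nx, ny, W, H) && habitat[ny * W + nx]) touches = true;
            }
          if (touches) { cell = cand; break; }
        }
      }
      if (cell < 0)
        cell = empties[(int)(unif_rand() * empties.size()) % empties.size()];
      habitat[cell] = 1;
      --remaining;
      int p = empty_pos[cell], last = empties.back();
      empties[p] = last; empty_pos[last] = p;
      empties.pop_back();
      empty_pos[cell] = -1;
    }
  }

  LogicalMatrix mask(H, W);
  for (int iy = 0; iy < H; ++iy)
    for (int ix = 0; ix < W; ++ix)
      mask(iy, ix) = habitat[iy * W + ix] == 1;
  return mask;
}

// Blob-mosaic habitat generator.  Patch sizes are drawn from an
// exponential distribution whose mean grows geometrically with
// aggregation, s(agg) = (N/2)^(agg/0.75) cells, each patch capped at half
// the habitat budget so every landscape keeps at least two discrete
// patches.  Patches are placed largest-first at uniform random seeds and
// grown by uniform frontier accretion (Eden growth, giving compact
// organic shapes), keeping a two-cell Moore buffer from previously placed
// patches; when free space runs out the buffer is relaxed and patches may
// coalesce (the percolating regime at high habitat amounts).
// [[Rcpp::export]]
LogicalMatrix generate_habitat_blob_cpp(int width, int height,
                                        int n_habitat, double agg) {
  const int W = width, H = height, N = W * H;
  if (n_habitat < 0 || n_habitat > N)
    stop("habitat cell count out of range");
  LogicalMatrix mask(H, W);
  if (n_habitat == 0) return mask;
  // geometric size curve: 1 cell at agg = 0 up to ~N/25 cells at agg = 0.75
  // (on the default 100 x 100 grid: ~20-cell mean at the aggregation
  // midpoint, so settleable-patch density varies over the whole 1-50 cell
  // minimum-area range while larger patches stay present)
  const double s_mean = agg <= 0 ? 1.0
    : std::pow(N / 25.0, std::min(agg, 0.75) / 0.75);
  const int cap = std::max(1, (n_habitat + 1) / 2);

  // draw target patch sizes until they cover the habitat budget
  std::vector<int> sizes;
  int tot = 0;
  while (tot < n_habitat) {
    int sz = (int) std::ceil(R::rexp(s_mean));
    if (sz < 1) sz = 1;
    sz = std::min(sz, std::min(cap, n_habitat - tot));
    sizes.push_back(sz);
    tot += sz;
  }
  if (sizes.size() == 1 && sizes[0] > 1) {     // keep dispersal defined
    sizes[0] = n_habitat / 2;
    sizes.push_back(n_habitat - sizes[0]);
  }
  std::sort(sizes.begin(), sizes.end(), std::greater<int>());

  std::vector<char> habitat(N, 0), blocked(N, 0);
  std::vector<int> stamp(N, -1);
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1},
            dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  int placed = 0;
  size_t qi = 0;
  int guard = 0;
  while (qi < sizes.size() && placed < n_habitat && ++guard < 4 * n_habitat + 64) {
    int want = std::min(sizes[qi], n_habitat - placed);
    ++qi;
    if (want <= 0) continue;
    // choose a seed; prefer unblocked empty cells, then any empty cell
    int seed = -1;
    bool relaxed = false;
    for (int t = 0; t < 200; ++t) {
      int cand = (int)(unif_rand() * N) % N;
      if (!habitat[cand] && !blocked[cand]) { seed = cand; break; }
    }
    if (seed < 0) {
      relaxed = true;
      for (int t = 0; t < 1000 && seed < 0; ++t) {
        int cand = (int)(unif_rand() * N) % N;
        if (!habitat[cand]) seed = cand;
      }
      if (seed < 0) {
        for (int i = 0; i < N && seed < 0; ++i)
          if (!habitat[i]) seed = i;
      }
    }
    if (seed < 0) break;
    // Eden growth from the seed
    std::vector<int> blob, frontier;
    habitat[seed] = 1;
    blob.push_back(seed);
    ++placed;
    stamp[seed] = seed;
    auto push_neighbours = [&](int c) {
      int cx = c % W, cy = c / W;
      for (int k = 0; k < 8; ++k) {
        int nx = cx + dx8[k], ny = cy + dy8[k];
        if (!in_grid(nx, ny, W, H)) continue;
        int n = ny * W + nx;
        if (habitat[n] || stamp[n] == seed) continue;
        if (blocked[n] && !relaxed) continue;
        stamp[n] = seed;
        frontier.push_back(n);
      }
    };
    push_neighbours(seed);
    while ((int) blob.size() < want && placed < n_habitat) {
      int cell = -1;
      while (!frontier.empty()) {
        int j = (int)(unif_rand() * frontier.size()) % frontier.size();
        int cand = frontier[j];
        frontier[j] = frontier.back();
        frontier.pop_back();
        if (!habitat[cand]) { cell = cand; break; }
      }
      if (cell < 0) break;                     // trapped: accept short blob
      habitat[cell] = 1;
      blob.push_back(cell);
      ++placed;
      push_neighbours(cell);
    }
    int deficit = want - (int) blob.size();
    if (deficit > 0) sizes.push_back(deficit); // place the rest elsewhere
    // two-cell Moore buffer around the finished patch
    for (size_t j = 0; j < blob.size(); ++j) {
      int cx = blob[j] % W, cy = blob[j] / W;
      for (int dy = -2; dy <= 2; ++dy)
        for (int dxx = -2; dxx <= 2; ++dxx) {
          int nx = cx + dxx, ny = cy + dy;
          if (in_grid(nx, ny, W, H) && !habitat[ny * W + nx])
            blocked[ny * W + nx] = 1;
        }
    }
  }
  // safety net: the count invariant is exact even if placement stalled
  for (int i = 0; i < N && placed < n_habitat; ++i)
    if (!habitat[i]) { habitat[i] = 1; ++placed; }
  for (int iy = 0; iy < H; ++iy)
    for (int ix = 0; ix < W; ++ix)
      mask(iy, ix) = habitat[iy * W + ix] == 1;
  return mask;
}

// Connected-component labelling of a boolean mask (BFS flood fill).
// Labels are assigned contiguously from 1 in scan order (iy then ix).
// [[Rcpp::export]]
List label_patches_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix labels(H, W);
  std::vector<int> sizes;
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int iy = 0; iy < H; ++iy) {
    for (int ix = 0; ix < W; ++ix) {
      if (!mask(iy, ix) || labels(iy, ix) != 0) continue;
      ++next;
      int sz = 0;
      labels(iy, ix) = next;
      q.push(std::make_pair(ix, iy));
      while (!q.empty()) {
        int cx = q.front().first, cy = q.front().second;
        q.pop();
        ++sz;
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0) continue;
            if (connectivity == 4 && dx != 0 && dy != 0) continue;
            int nx = cx + dx, ny = cy + dy;
            if (!in_grid(nx, ny, W, H)) continue;
            if (mask(ny, nx) && labels(ny, nx) == 0) {
              labels(ny, nx) = next;
              q.push(std::make_pair(nx, ny));
            }
          }
      }
      sizes.push_back(sz);
    }
  }
  return List::create(_["patch_id"] = labels,
                      _["patch_sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// Cells of patch `label` having at least one Moore neighbour outside the
// patch (off-grid counts as outside).  Returns 0-based (ix, iy) pairs.
// [[Rcpp::export]]
IntegerMatrix edge_cells_cpp(IntegerMatrix patch_id, int label) {
  const int H = patch_id.nrow(), W = patch_id.ncol();
  std::vector<int> xs, ys;
  for (int iy = 0; iy < H; ++iy)
    for (int ix = 0; ix < W; ++ix) {
      if (patch_id(iy, ix) != label) continue;
      bool edge = false;
      for (int dy = -1; dy <= 1 && !edge; ++dy)
        for (int dx = -1; dx <= 1 && !edge; ++dx) {
          if (dx == 0 && dy == 0) continue;
          int nx = ix + dx, ny = iy + dy;
          if (!in_grid(nx, ny, W, H) || patch_id(ny, nx) != label) edge = true;
        }
      if (edge) { xs.push_back(ix); ys.push_back(iy); }
    }
  IntegerMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  colnames(out) = CharacterVector::create("ix", "iy");
  return out;
}
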