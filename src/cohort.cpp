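#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Agent movement core.  Positions are continuous (x, y) in cell units with
// (0,0) at the lower-left; the cell of a position is floor of each
// coordinate; matrices are indexed (iy, ix).

enum Mode { DISPERSING = 0, FORAGING = 1, APPROACHING = 2 };
enum Outcome { SUCCESS = 1, DIED = 2, TIMEOUT = 3 };

struct Grid {
  const int W, H;
  const int *patch;        // 0 = matrix, >=1 patch label
  const int *sizes;        // patch label -> cells (index label-1)
  const int *forage;       // 0/1
  std::vector<int> sat;    // summed-area table of habitat presence, (H+1) x (W+1)
  Grid(const IntegerMatrix &p, const IntegerVector &s, const LogicalMatrix &f)
    : W(p.ncol()), H(p.nrow()), patch(&p[0]), sizes(s.size() ? &s[0] : NULL),
      forage(&f[0]), sat((size_t)(p.nrow() + 1) * (p.ncol() + 1), 0) {
    for (int iy = 0; iy < H; ++iy)
      for (int ix = 0; ix < W; ++ix) {
        int hab = patch[(size_t)ix * H + iy] > 0 ? 1 : 0;
        sat[(size_t)(iy + 1) * (W + 1) + ix + 1] =
          hab + sat[(size_t)iy * (W + 1) + ix + 1]
              + sat[(size_t)(iy + 1) * (W + 1) + ix]
              - sat[(size_t)iy * (W + 1) + ix];
      }
  }
  inline int patch_at(int ix, int iy) const { return patch[(size_t)ix * H + iy]; }
  inline bool forage_at(int ix, int iy) const { return forage[(size_t)ix * H + iy] != 0; }
  inline int habitat_in(int x0, int y0, int x1, int y1) const {
    // inclusive cell window, clipped
    x0 = std::max(x0, 0); y0 = std::max(y0, 0);
    x1 = std::min(x1, W - 1); y1 = std::min(y1, H - 1);
    if (x0 > x1 || y0 > y1) return 0;
    return sat[(size_t)(y1 + 1) * (W + 1) + x1 + 1]
         - sat[(size_t)y0 * (W + 1) + x1 + 1]
         - sat[(size_t)(y1 + 1) * (W + 1) + x0]
         + sat[(size_t)y0 * (W + 1) + x0];
  }
};

struct Traits {
  double speed, range, mortality, min_area, forage_tendency;
};

struct Config {
  int max_steps, hard_cap;
  double max_turn, half_arc_cos;  // radians / cos of half perception arc
  double forage_speed, forage_gain;
  int boundary;                   // 0 reflect, 1 wrap
};

// Nearest suitable habitat cell within the perceptual window: centre within
// Euclidean distance <= range of the agent and within the forward arc of the
// heading; suitable iff patch size >= min_area and label != start_patch.
// Ties: nearer first, then lower patch label, then scan order (iy, then ix).
static bool perceive(const Grid &g, double x, double y, double hx, double hy,
                     const Traits &tr, int start_patch, double half_arc_cos,
                     double &tx, double &ty) {
  const double r = tr.range;
  const int cx = (int)std::floor(x), cy = (int)std::floor(y);
  const int c = (int)std::ceil(r + 0.7072);
  if (g.habitat_in(cx - c, cy - c, cx + c, cy + c) == 0) return false;
  const double r2 = r * r + 1e-9;
  double best_d2 = -1.0; int best_lab = 0;
  const int y0 = std::max(cy - c, 0), y1 = std::min(cy + c, g.H - 1);
  const int x0 = std::max(cx - c, 0), x1 = std::min(cx + c, g.W - 1);
  for (int iy = y0; iy <= y1; ++iy) {
    for (int ix = x0; ix <= x1; ++ix) {
      int lab = g.patch_at(ix, iy);
      if (lab == 0 || lab == start_patch) continue;
      if (g.sizes[lab - 1] < tr.min_area) continue;
      double dx = ix + 0.5 - x, dy = iy + 0.5 - y;
      double d2 = dx * dx + dy * dy;
      if (d2 > r2) continue;
      // forward-arc test without division: dot >= cos(arc/2) * dist
      double d = std::sqrt(d2);
      if (dx * hx + dy * hy < half_arc_cos * d - 1e-12) continue;
      if (best_d2 >= 0.0) {
        if (d2 > best_d2 + 1e-12) continue;
        if (d2 > best_d2 - 1e-12 && lab >= best_lab) continue;
      }
      best_d2 = d2; best_lab = lab;
      tx = ix + 0.5; ty = iy + 0.5;
    }
  }
  return best_d2 >= 0.0;
}

static void move_bounded(double &x, double &y, double &heading, double dist,
                         int W, int H, int boundary) {
  double dx = std::cos(heading), dy = std::sin(heading);
  x += dist * dx;
  y += dist * dy;
  if (boundary == 1) {            // wrap (floor division, not fmod)
    x -= W * std::floor(x / W);
    y -= H * std::floor(y / H);
  } else {                        // reflect, heading mirrored
    for (int it = 0; it < 64; ++it) {
      if (x < 0)      { x = -x;          dx = -dx; }
      else if (x > W) { x = 2.0 * W - x; dx = -dx; }
      else if (y < 0) { y = -y;          dy = -dy; }
      else if (y > H) { y = 2.0 * H - y; dy = -dy; }
      else break;
    }
    x = std::min(std::max(x, 0.0), W - 1e-9);
    y = std::min(std::max(y, 0.0), H - 1e-9);
    heading = std::atan2(dy, dx);
  }
}

struct AgentRun {
  int outcome;
  int steps;
  double energy;
};

static AgentRun sim_agent(const Grid &g, const Traits &tr, const Config &cf,
                          double x, double y, double heading, int start_patch,
                          std::vector<double> *trace) {
  int mode = DISPERSING;
  double energy = 0.0;
  int steps = 0;
  int last_cell = ((int)std::floor(x)) + g.W * (int)std::floor(y);
  AgentRun res;
  for (;;) {
    // step budget: foraging credit extends the cap; hard cap guarantees halt
    double budget = std::min((double)cf.max_steps + std::floor(energy),
                             (double)cf.hard_cap);
    if (steps >= budget) { res.outcome = TIMEOUT; break; }
    if (trace) {
      trace->push_back(steps); trace->push_back(x); trace->push_back(y);
      trace->push_back(mode); trace->push_back(energy);
    }
    // (1) background mortality
    if (unif_rand() < tr.mortality) { res.outcome = DIED; break; }
    // (2) perception: a detected suitable patch overrides any mode
    double tx = 0, ty = 0;
    double hx = std::cos(heading), hy = std::sin(heading);
    if (perceive(g, x, y, hx, hy, tr, start_patch, cf.half_arc_cos, tx, ty)) {
      mode = APPROACHING;
      heading = std::atan2(ty - y, tx - x);
    } else if (mode == APPROACHING) {
      mode = DISPERSING;
    }
    // (3) move: CRW turn unless on a directed approach.  The displacement
    // is walked in cell-resolution sub-steps so fast agents sample every
    // cell their path crosses (no flying over patches or forage cells);
    // the endpoint equals a single jump of the full distance.
    double dist = (mode == FORAGING) ? cf.forage_speed : tr.speed;
    if (mode != APPROACHING)
      heading += R::runif(-cf.max_turn, cf.max_turn);
    int nsub = std::max(1, (int)std::ceil(dist));
    double sub = dist / nsub;
    bool settled = false;
    for (int ss = 0; ss < nsub && !settled; ++ss) {
      move_bounded(x, y, heading, sub, g.W, g.H, cf.boundary);
      int ix = (int)std::floor(x), iy = (int)std::floor(y);
      int cell = ix + g.W * iy;
      // (4) foraging-mode bookkeeping (one draw per forage-cell entry)
      bool on_forage = g.forage_at(ix, iy);
      if (on_forage && mode == DISPERSING && cell != last_cell) {
        if (unif_rand() < tr.forage_tendency) mode = FORAGING;
      }
      last_cell = cell;
      // (5) settlement: the agent stops at the first suitable patch reached
      int lab = g.patch_at(ix, iy);
      if (lab > 0 && lab != start_patch && g.sizes[lab - 1] >= tr.min_area)
        settled = true;
    }
    if (mode == FORAGING) {
      energy += cf.forage_gain;
      int ix = (int)std::floor(x), iy = (int)std::floor(y);
      if (!g.forage_at(ix, iy)) mode = DISPERSING;
    }
    if (settled) {
      ++steps;
      res.outcome = SUCCESS;
      break;
    }
    // (6) step accounting
    ++steps;
  }
  res.steps = steps;
  res.energy = energy;
  return res;
}

// Initial placement: uniform patch, uniform edge cell of that patch, heading
// drawn uniformly among directions whose first full-speed step leaves the
// start patch (rejection sampling; uniform fallback).
static void init_agent(const Grid &g, const Traits &tr, const Config &cf,
                       const std::vector<std::vector<int> > &edges,
                       double &x, double &y, double &heading, int &start_patch) {
  int np = (int)edges.size();
  int p = std::min((int)(unif_rand() * np), np - 1);
  const std::vector<int> &ec = edges[p];
  int ci = std::min((int)(unif_rand() * ec.size()), (int)ec.size() - 1);
  int cell = ec[ci];
  x = (cell % g.W) + 0.5;
  y = (cell / g.W) + 0.5;
  start_patch = p + 1;
  heading = R::runif(0, 2.0 * M_PI);
  for (int t = 0; t < 200; ++t) {
    double h = R::runif(0, 2.0 * M_PI);
    double xx = x, yy = y, hh = h;
    move_bounded(xx, yy, hh, tr.speed, g.W, g.H, cf.boundary);
    int lab = g.patch_at((int)std::floor(xx), (int)std::floor(yy));
    if (lab != start_patch) { heading = h; break; }
  }
}

static std::vector<std::vector<int> > patch_edge_cells(const Grid &g, int n_patches) {
  std::vector<std::vector<int> > edges(n_patches);
  for (int iy = 0; iy < g.H; ++iy)
    for (int ix = 0; ix < g.W; ++ix) {
      int lab = g.patch_at(ix, iy);
      if (lab == 0) continue;
      bool edge = false;
      for (int dy = -1; dy <= 1 && !edge; ++dy)
        for (int dx = -1; dx <= 1 && !edge; ++dx) {
          if (dx == 0 && dy == 0) continue;
          int nx = ix + dx, ny = iy + dy;
          if (nx < 0 || nx >= g.W || ny < 0 || ny >= g.H) { edge = true; break; }
          if (g.patch_at(nx, ny) != lab) edge = true;
        }
      if (edge) edges[lab - 1].push_back(ix + g.W * iy);
    }
  return edges;
}

static Traits make_traits(List traits) {
  Traits tr;
  tr.speed = as<double>(traits["speed"]);
  tr.range = as<double>(traits["perceptual_range"]);
  tr.mortality = as<double>(traits["mortality"]);
  tr.min_area = as<double>(traits["min_area"]);
  tr.forage_tendency = as<double>(traits["foraging_tendency"]);
  return tr;
}

static Config make_config(List config) {
  Config cf;
  cf.max_steps = as<int>(config["max_steps"]);
  cf.hard_cap = as<int>(config["hard_step_cap"]);
  cf.max_turn = as<double>(config["max_turn"]) * M_PI / 180.0;
  cf.half_arc_cos = std::cos(as<double>(config["perception_arc"]) * M_PI / 360.0);
  cf.forage_speed = as<double>(config["forage_speed"]);
  cf.forage_gain = as<double>(config["forage_energy_gain"]);
  cf.boundary = as<std::string>(config["boundary"]) == "wrap" ? 1 : 0;
  return cf;
}

// [[Rcpp::export]]
List run_cohort_cpp(IntegerMatrix patch_id, IntegerVector patch_sizes,
                    LogicalMatrix forage, List traits, List config,
                    int n_agents) {
  Grid g(patch_id, patch_sizes, forage);
  Traits tr = make_traits(traits);
  Config cf = make_config(config);
  if (patch_sizes.size() == 0) stop("landscape has no habitat patches");
  std::vector<std::vector<int> > edges = patch_edge_cells(g, patch_sizes.size());
  int n_success = 0, n_died = 0, n_timeout = 0;
  IntegerVector outcomes(n_agents), steps(n_agents);
  for (int i = 0; i < n_agents; ++i) {
    double x, y, heading; int start_patch;
    init_agent(g, tr, cf, edges, x, y, heading, start_patch);
    AgentRun r = sim_agent(g, tr, cf, x, y, heading, start_patch, NULL);
    outcomes[i] = r.outcome;
    steps[i] = r.steps;
    if (r.outcome == SUCCESS) ++n_success;
    else if (r.outcome == DIED) ++n_died;
    else ++n_timeout;
  }
  return List::create(_["n_attempted"] = n_agents,
                      _["n_success"] = n_success,
                      _["n_died"] = n_died,
                      _["n_timeout"] = n_timeout,
                      _["outcomes"] = outcomes,
                      _["steps"] = steps);
}

// [[Rcpp::export]]
List run_agent_cpp(IntegerMatrix patch_id, IntegerVector patch_sizes,
                   LogicalMatrix forage, List traits, List config,
                   bool trace) {
  Grid g(patch_id, patch_sizes, forage);
  Traits tr = make_traits(traits);
  Config cf = make_config(config);
  if (patch_sizes.size() == 0) stop("landscape has no habitat patches");
  std::vector<std::vector<int> > edges = patch_edge_cells(g, patch_sizes.size());
  double x, y, heading; int start_patch;
  init_agent(g, tr, cf, edges, x, y, heading, start_patch);
  double x0 = x, y0 = y;
  std::vector<double> tbuf;
  AgentRun r = sim_agent(g, tr, cf, x, y, heading, start_patch,
                         trace ? &tbuf : NULL);
  List out = List::create(_["outcome"] = r.outcome,
                          _["steps"] = r.steps,
                          _["energy"] = r.energy,
                          _["start_patch"] = start_patch,
                          _["start_x"] = x0, _["start_y"] = y0);
  if (trace) {
    int nrow = (int)(tbuf.size() / 5);
    NumericMatrix tm(nrow, 5);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < 5; ++j) tm(i, j) = tbuf[(size_t)i * 5 + j];
    colnames(tm) = CharacterVector::create("step", "x", "y", "mode", "energy");
    out["trace"] = tm;
  }
  return out;
}
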