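// Center-based tumor / T-cell agent-based model.
//
// Cells are points with a radius in a continuous 2-D domain centered on the
// origin. Two variants share a common step loop:
//   ex1: tumor cells acquire PD-L1 in the presence of T cells and suppress
//        adjacent active T cells with probability equal to their PD-L1 level;
//        killed tumor cells are removed.
//   ex2: no PD-L1/suppression; tumor cells die spontaneously (elevated rate
//        inside a static central hypoxic disk) and dead cells persist in
//        place as immobile obstacles.
//
// All randomness is drawn from a private splitmix64 stream seeded explicitly,
// so a simulation is reproducible bit-for-bit from (params, config, seed)
// regardless of R's global RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// cell kinds (keep in sync with R's kind_levels())
static const int TUMOR_LIVE = 1;
static const int TUMOR_DEAD = 2;
static const int TCELL_ACTIVE = 3;
static const int TCELL_SUPPRESSED = 4;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {
    for (int i = 0; i < 4; ++i) next();  // decorrelate small seeds
  }
  uint64_t next() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int randint(int n) {  // in [0, n)
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
  double normal() {
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

// per-step substream: step t of simulation `seed` is independent of how many
// draws earlier steps consumed
static uint64_t step_seed(uint64_t seed, int t) {
  uint64_t z = seed * 0x9E3779B97f4A7C15ULL + static_cast<uint64_t>(t) + 1ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct State {
  std::vector<int> id, kind;
  std::vector<double> x, y, radius, pdl1;
  int next_id;
  size_t n() const { return id.size(); }
  void add(int k, double px, double py, double r, double p) {
    id.push_back(next_id++);
    kind.push_back(k);
    x.push_back(px);
    y.push_back(py);
    radius.push_back(r);
    pdl1.push_back(p);
  }
};

struct Events {
  bool enabled;
  std::vector<int> step, type, actor_id, actor_kind, target_id;
  void log(int t, int ty, int aid, int ak, int tid) {
    if (!enabled) return;
    step.push_back(t);
    type.push_back(ty);
    actor_id.push_back(aid);
    actor_kind.push_back(ak);
    target_id.push_back(tid);
  }
};

struct Params {
  // shared
  double kill_prob, infiltration;
  // ex1
  double pdl1_max, pdl1_rate;
  // ex2
  double basal_death_prob, hypoxic_radius, hypoxic_death_prob;
};

struct Config {
  double domain_size, cell_diameter, proliferation_prob, recruitment_rate,
      migration_step, interaction_radius_factor, init_tumor_radius,
      relax_tol_frac, hx, hy;
  int n_steps, relax_max_iter, variant;  // variant: 1 = ex1, 2 = ex2
};

// uniform bucket grid for near-neighbor queries; flat counting-sort layout
// so rebuilding every relaxation sweep costs no per-bin allocations
struct Grid {
  double h, minx, miny;
  int nx, ny;
  std::vector<int> start, order;  // bin offsets + cell indices sorted by bin
  void build(const State& st, double cell) {
    h = cell;
    size_t n = st.n();
    if (n == 0) {
      nx = ny = 1;
      minx = miny = 0;
      start.assign(2, 0);
      order.clear();
      return;
    }
    minx = *std::min_element(st.x.begin(), st.x.end());
    miny = *std::min_element(st.y.begin(), st.y.end());
    double maxx = *std::max_element(st.x.begin(), st.x.end());
    double maxy = *std::max_element(st.y.begin(), st.y.end());
    nx = std::max(1, static_cast<int>((maxx - minx) / h) + 1);
    ny = std::max(1, static_cast<int>((maxy - miny) / h) + 1);
    size_t nb = static_cast<size_t>(nx) * ny;
    start.assign(nb + 1, 0);
    binof.resize(n);
    for (size_t i = 0; i < n; ++i) {
      int ix = std::min(nx - 1, static_cast<int>((st.x[i] - minx) / h));
      int iy = std::min(ny - 1, static_cast<int>((st.y[i] - miny) / h));
      binof[i] = static_cast<size_t>(iy) * nx + ix;
      ++start[binof[i] + 1];
    }
    for (size_t b = 0; b < nb; ++b) start[b + 1] += start[b];
    order.resize(n);
    fill.assign(nb, 0);
    for (size_t i = 0; i < n; ++i)
      order[start[binof[i]] + fill[binof[i]]++] = static_cast<int>(i);
  }
  // indices of cells within `r` of point (px, py), excluding `self` (-1 = none)
  void query(const State& st, double px, double py, double r, int self,
             std::vector<int>& out, bool sort_out = true) const {
    out.clear();
    int ix0 = std::max(0, static_cast<int>((px - r - minx) / h));
    int ix1 = std::min(nx - 1, static_cast<int>((px + r - minx) / h));
    int iy0 = std::max(0, static_cast<int>((py - r - miny) / h));
    int iy1 = std::min(ny - 1, static_cast<int>((py + r - miny) / h));
    double r2 = r * r;
    for (int iy = iy0; iy <= iy1; ++iy)
      for (int ix = ix0; ix <= ix1; ++ix) {
        size_t b = static_cast<size_t>(iy) * nx + ix;
        for (int k = start[b]; k < start[b + 1]; ++k) {
          int j = order[k];
          if (j == self) continue;
          double dx = st.x[j] - px, dy = st.y[j] - py;
          if (dx * dx + dy * dy <= r2) out.push_back(j);
        }
      }
    // bin order is already deterministic; sorting is only needed where the
    // caller consumes neighbors in id order
    if (sort_out) std::sort(out.begin(), out.end());
  }

 private:
  std::vector<size_t> binof;
  std::vector<int> fill;
};

static void shuffle_idx(std::vector<int>& v, Rng& rng) {
  for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
    int j = rng.randint(i + 1);
    std::swap(v[i], v[j]);
  }
}

static bool tumor_centroid(const State& st, double& cx, double& cy) {
  double sx = 0, sy = 0;
  int n = 0;
  for (size_t i = 0; i < st.n(); ++i)
    if (st.kind[i] == TUMOR_LIVE || st.kind[i] == TUMOR_DEAD) {
      sx += st.x[i];
      sy += st.y[i];
      ++n;
    }
  if (n == 0) return false;
  cx = sx / n;
  cy = sy / n;
  return true;
}

static double tumor_radius_of(const State& st) {
  double cx, cy;
  if (!tumor_centroid(st, cx, cy))
    stop("state contains no tumor cells; tumor radius undefined");
  double r2max = 0;
  for (size_t i = 0; i < st.n(); ++i)
    if (st.kind[i] == TUMOR_LIVE || st.kind[i] == TUMOR_DEAD) {
      double dx = st.x[i] - cx, dy = st.y[i] - cy;
      r2max = std::max(r2max, dx * dx + dy * dy);
    }
  return std::sqrt(r2max);
}

static void clamp_domain(const Config& cfg, double& px, double& py) {
  double half = cfg.domain_size / 2.0;
  px = std::min(half, std::max(-half, px));
  py = std::min(half, std::max(-half, py));
}

// iterative pairwise overlap relaxation: overlapping live cells are pushed
// apart along the center line (equal shares; immobile dead cells push the
// mobile partner by the full overlap) until the worst overlap is below
// relax_tol_frac of a cell radius or relax_max_iter sweeps have run
static void relax(State& st, const Config& cfg, Rng& rng) {
  size_t n = st.n();
  if (n < 2) return;
  double tol = cfg.relax_tol_frac * (cfg.cell_diameter / 2.0);
  double maxr = 0;
  for (size_t i = 0; i < n; ++i) maxr = std::max(maxr, st.radius[i]);
  Grid grid;
  std::vector<double> dx(n), dy(n);
  std::vector<int> nb;
  for (int iter = 0; iter < cfg.relax_max_iter; ++iter) {
    grid.build(st, 2.0 * maxr);
    std::fill(dx.begin(), dx.end(), 0.0);
    std::fill(dy.begin(), dy.end(), 0.0);
    double worst = 0;
    for (size_t i = 0; i < n; ++i) {
      // displacement sums are order-independent up to floating rounding, and
      // the bin order itself is deterministic, so skip the sort here
      grid.query(st, st.x[i], st.y[i], st.radius[i] + maxr,
                 static_cast<int>(i), nb, false);
      for (int j : nb) {
        if (static_cast<size_t>(j) <= i) continue;  // each pair once
        double ddx = st.x[j] - st.x[i], ddy = st.y[j] - st.y[i];
        double d = std::sqrt(ddx * ddx + ddy * ddy);
        double target = st.radius[i] + st.radius[static_cast<size_t>(j)];
        double overlap = target - d;
        if (overlap <= 0) continue;
        worst = std::max(worst, overlap);
        double ux, uy;
        if (d < 1e-9) {  // coincident centers: random push direction
          double a = rng.unif() * 6.283185307179586;
          ux = std::cos(a);
          uy = std::sin(a);
        } else {
          ux = ddx / d;
          uy = ddy / d;
        }
        bool i_fix = st.kind[i] == TUMOR_DEAD;
        bool j_fix = st.kind[static_cast<size_t>(j)] == TUMOR_DEAD;
        if (i_fix && j_fix) continue;
        double si = i_fix ? 0.0 : (j_fix ? 1.0 : 0.5);
        double sj = j_fix ? 0.0 : (i_fix ? 1.0 : 0.5);
        dx[i] -= si * overlap * ux;
        dy[i] -= si * overlap * uy;
        dx[static_cast<size_t>(j)] += sj * overlap * ux;
        dy[static_cast<size_t>(j)] += sj * overlap * uy;
      }
    }
    if (worst < tol) break;
    for (size_t i = 0; i < n; ++i) {
      // half-step damping keeps the Jacobi sweep stable in dense clusters
      st.x[i] += 0.5 * dx[i];
      st.y[i] += 0.5 * dy[i];
      clamp_domain(cfg, st.x[i], st.y[i]);
      if (!std::isfinite(st.x[i]) || !std::isfinite(st.y[i]))
        stop("non-finite cell position after mechanics relaxation");
    }
  }
}

static double interaction_radius(const Config& cfg, const State& st, size_t i,
                                 size_t j) {
  return cfg.interaction_radius_factor *
         (st.radius[i] + st.radius[j]);
}

// one full update: proliferation -> PD-L1 (ex1) -> recruitment + migration ->
// killing -> suppression (ex1) -> death/removal -> relaxation
static void do_step(State& st, const Params& p, const Config& cfg, Rng& rng,
                    int t, Events& ev) {
  Grid grid;
  std::vector<int> nb;
  double rmax_int = cfg.interaction_radius_factor * cfg.cell_diameter;

  // (1) proliferation: each live tumor cell divides with prob
  // proliferation_prob; daughter placed one radius away, inherits PD-L1
  {
    std::vector<int> order;
    for (size_t i = 0; i < st.n(); ++i)
      if (st.kind[i] == TUMOR_LIVE) order.push_back(static_cast<int>(i));
    shuffle_idx(order, rng);
    for (int i : order) {
      if (rng.unif() < cfg.proliferation_prob) {
        double a = rng.unif() * 6.283185307179586;
        double px = st.x[static_cast<size_t>(i)] +
                    st.radius[static_cast<size_t>(i)] * std::cos(a);
        double py = st.y[static_cast<size_t>(i)] +
                    st.radius[static_cast<size_t>(i)] * std::sin(a);
        clamp_domain(cfg, px, py);
        st.add(TUMOR_LIVE, px, py, st.radius[static_cast<size_t>(i)],
               st.pdl1[static_cast<size_t>(i)]);
      }
    }
    relax(st, cfg, rng);
  }

  // (2) PD-L1 gain in the presence of T cells (ex1 only), capped at pdl1_max
  if (cfg.variant == 1) {
    grid.build(st, rmax_int);
    for (size_t i = 0; i < st.n(); ++i) {
      if (st.kind[i] != TUMOR_LIVE) continue;
      grid.query(st, st.x[i], st.y[i], rmax_int, static_cast<int>(i), nb);
      bool near_t = false;
      for (int j : nb) {
        int k = st.kind[static_cast<size_t>(j)];
        if ((k == TCELL_ACTIVE || k == TCELL_SUPPRESSED) &&
            std::hypot(st.x[static_cast<size_t>(j)] - st.x[i],
                       st.y[static_cast<size_t>(j)] - st.y[i]) <=
                interaction_radius(cfg, st, i, static_cast<size_t>(j))) {
          near_t = true;
          break;
        }
      }
      if (near_t) st.pdl1[i] = std::min(st.pdl1[i] + p.pdl1_rate, p.pdl1_max);
    }
  }

  // (3) recruitment at the tumor rim, then inward migration of active T cells
  double cx = 0, cy = 0;
  bool have_tumor = tumor_centroid(st, cx, cy);
  if (have_tumor) {
    double R = tumor_radius_of(st);
    double frac = cfg.recruitment_rate - std::floor(cfg.recruitment_rate);
    int n_rec = static_cast<int>(std::floor(cfg.recruitment_rate)) +
                (rng.unif() < frac ? 1 : 0);
    for (int k = 0; k < n_rec; ++k) {
      double a = rng.unif() * 6.283185307179586;
      double rr = R + cfg.cell_diameter;
      double px = cx + rr * std::cos(a), py = cy + rr * std::sin(a);
      clamp_domain(cfg, px, py);
      st.add(TCELL_ACTIVE, px, py, cfg.cell_diameter / 2.0, 0.0);
    }
    // active T cells step migration_step toward the tumor centroid and halt
    // at radial coordinate (1 - infiltration) * R
    double halt = (1.0 - p.infiltration) * R;
    std::vector<int> order;
    for (size_t i = 0; i < st.n(); ++i)
      if (st.kind[i] == TCELL_ACTIVE) order.push_back(static_cast<int>(i));
    shuffle_idx(order, rng);
    for (int ii : order) {
      size_t i = static_cast<size_t>(ii);
      double dx0 = st.x[i] - cx, dy0 = st.y[i] - cy;
      double r = std::sqrt(dx0 * dx0 + dy0 * dy0);
      if (r <= halt || r < 1e-12) continue;
      double rnew = std::max(r - cfg.migration_step, halt);
      st.x[i] = cx + dx0 * (rnew / r);
      st.y[i] = cy + dy0 * (rnew / r);
    }
  }

  // (4) killing: each active T cell kills each adjacent live tumor cell with
  // probability kill_prob
  std::vector<char> killed(st.n(), 0);
  {
    grid.build(st, rmax_int);
    std::vector<int> order;
    for (size_t i = 0; i < st.n(); ++i)
      if (st.kind[i] == TCELL_ACTIVE) order.push_back(static_cast<int>(i));
    shuffle_idx(order, rng);
    for (int ii : order) {
      size_t i = static_cast<size_t>(ii);
      grid.query(st, st.x[i], st.y[i], rmax_int, ii, nb);
      for (int j : nb) {
        size_t sj = static_cast<size_t>(j);
        if (st.kind[sj] != TUMOR_LIVE || killed[sj]) continue;
        if (std::hypot(st.x[sj] - st.x[i], st.y[sj] - st.y[i]) >
            interaction_radius(cfg, st, i, sj))
          continue;
        if (rng.unif() < p.kill_prob) {
          killed[sj] = 1;
          ev.log(t, 1, st.id[i], st.kind[i], st.id[sj]);
        }
      }
    }
  }

  // (5) suppression (ex1): each live tumor cell suppresses each adjacent
  // active T cell with probability equal to its PD-L1 level
  if (cfg.variant == 1) {
    grid.build(st, rmax_int);
    std::vector<int> order;
    for (size_t i = 0; i < st.n(); ++i)
      if (st.kind[i] == TUMOR_LIVE && !killed[i])
        order.push_back(static_cast<int>(i));
    shuffle_idx(order, rng);
    for (int ii : order) {
      size_t i = static_cast<size_t>(ii);
      if (st.pdl1[i] <= 0) continue;
      grid.query(st, st.x[i], st.y[i], rmax_int, ii, nb);
      for (int j : nb) {
        size_t sj = static_cast<size_t>(j);
        if (st.kind[sj] != TCELL_ACTIVE) continue;
        if (std::hypot(st.x[sj] - st.x[i], st.y[sj] - st.y[i]) >
            interaction_radius(cfg, st, i, sj))
          continue;
        if (rng.unif() < st.pdl1[i]) {
          st.kind[sj] = TCELL_SUPPRESSED;
          ev.log(t, 2, st.id[i], st.kind[i], st.id[sj]);
        }
      }
    }
  }

  // (6) death: ex1 removes killed cells; ex2 converts killed cells and
  // spontaneous deaths (elevated inside the hypoxic disk) to persistent
  // immobile tumor_dead cells
  if (cfg.variant == 2) {
    std::vector<int> order;
    for (size_t i = 0; i < st.n(); ++i)
      if (st.kind[i] == TUMOR_LIVE && !killed[i])
        order.push_back(static_cast<int>(i));
    shuffle_idx(order, rng);
    for (int ii : order) {
      size_t i = static_cast<size_t>(ii);
      double d = std::hypot(st.x[i] - cfg.hx, st.y[i] - cfg.hy);
      double pd = (d <= p.hypoxic_radius) ? p.hypoxic_death_prob
                                          : p.basal_death_prob;
      if (rng.unif() < pd) killed[i] = 1;
    }
    for (size_t i = 0; i < st.n(); ++i)
      if (killed[i]) st.kind[i] = TUMOR_DEAD;
  } else {
    State ns;
    ns.next_id = st.next_id;
    for (size_t i = 0; i < st.n(); ++i) {
      if (killed[i]) continue;
      ns.id.push_back(st.id[i]);
      ns.kind.push_back(st.kind[i]);
      ns.x.push_back(st.x[i]);
      ns.y.push_back(st.y[i]);
      ns.radius.push_back(st.radius[i]);
      ns.pdl1.push_back(st.pdl1[i]);
    }
    st = ns;
  }

  // (7) final overlap relaxation
  relax(st, cfg, rng);
}

static Params params_from_list(List pl, int variant) {
  Params p{};
  p.kill_prob = as<double>(pl["kill_prob"]);
  p.infiltration = as<double>(pl["infiltration"]);
  if (variant == 1) {
    p.pdl1_max = as<double>(pl["pdl1_max"]);
    p.pdl1_rate = as<double>(pl["pdl1_rate"]);
  } else {
    p.basal_death_prob = as<double>(pl["basal_death_prob"]);
    p.hypoxic_radius = as<double>(pl["hypoxic_radius"]);
    p.hypoxic_death_prob = as<double>(pl["hypoxic_death_prob"]);
  }
  return p;
}

static Config config_from_list(List cl) {
  Config c{};
  c.domain_size = as<double>(cl["domain_size"]);
  c.cell_diameter = as<double>(cl["cell_diameter"]);
  c.n_steps = as<int>(cl["n_steps"]);
  c.proliferation_prob = as<double>(cl["proliferation_prob"]);
  c.recruitment_rate = as<double>(cl["recruitment_rate"]);
  c.migration_step = as<double>(cl["migration_step"]);
  c.interaction_radius_factor = as<double>(cl["interaction_radius_factor"]);
  c.init_tumor_radius = as<double>(cl["init_tumor_radius"]);
  c.relax_tol_frac = as<double>(cl["relax_tol_frac"]);
  c.relax_max_iter = as<int>(cl["relax_max_iter"]);
  std::string v = as<std::string>(cl["variant"]);
  c.variant = (v == "ex1") ? 1 : 2;
  NumericVector hc = cl["hypoxic_center"];
  c.hx = hc[0];
  c.hy = hc[1];
  return c;
}

static State state_from_matrix(NumericMatrix m) {
  State st;
  size_t n = m.nrow();
  st.id.resize(n);
  st.kind.resize(n);
  st.x.resize(n);
  st.y.resize(n);
  st.radius.resize(n);
  st.pdl1.resize(n);
  int maxid = 0;
  for (size_t i = 0; i < n; ++i) {
    st.id[i] = static_cast<int>(m(i, 0));
    st.kind[i] = static_cast<int>(m(i, 1));
    st.x[i] = m(i, 2);
    st.y[i] = m(i, 3);
    st.radius[i] = m(i, 4);
    st.pdl1[i] = m(i, 5);
    maxid = std::max(maxid, st.id[i]);
    if (st.radius[i] <= 0) stop("cell radius must be positive");
  }
  st.next_id = maxid + 1;
  return st;
}

static NumericMatrix state_to_matrix(const State& st) {
  NumericMatrix m(static_cast<int>(st.n()), 6);
  for (size_t i = 0; i < st.n(); ++i) {
    m(i, 0) = st.id[i];
    m(i, 1) = st.kind[i];
    m(i, 2) = st.x[i];
    m(i, 3) = st.y[i];
    m(i, 4) = st.radius[i];
    m(i, 5) = st.pdl1[i];
  }
  colnames(m) = CharacterVector::create("id", "kind", "x", "y", "radius",
                                        "pdl1");
  return m;
}

static DataFrame events_to_df(const Events& ev) {
  return DataFrame::create(_["step"] = ev.step, _["type"] = ev.type,
                           _["actor_id"] = ev.actor_id,
                           _["actor_kind"] = ev.actor_kind,
                           _["target_id"] = ev.target_id);
}

// hexagonally packed disk of live tumor cells centered on the origin
static State init_state(const Config& cfg) {
  State st;
  st.next_id = 1;
  double r = cfg.cell_diameter / 2.0;
  double dx = cfg.cell_diameter;
  double dy = cfg.cell_diameter * 0.8660254037844386;  // sqrt(3)/2
  int nrow = static_cast<int>(cfg.init_tumor_radius / dy) + 1;
  for (int iy = -nrow; iy <= nrow; ++iy) {
    double py = iy * dy;
    double off = (iy % 2 == 0) ? 0.0 : dx / 2.0;
    int ncol = static_cast<int>(cfg.init_tumor_radius / dx) + 1;
    for (int ix = -ncol; ix <= ncol; ++ix) {
      double px = ix * dx + off;
      if (px * px + py * py <= cfg.init_tumor_radius * cfg.init_tumor_radius)
        st.add(TUMOR_LIVE, px, py, r, 0.0);
    }
  }
  return st;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_init_state(List cfg) {
  Config c = config_from_list(cfg);
  State st = init_state(c);
  return state_to_matrix(st);
}

// [[Rcpp::export]]
List cpp_step(NumericMatrix state, List params, List cfg, double seed, int t,
              bool log_events) {
  Config c = config_from_list(cfg);
  Params p = params_from_list(params, c.variant);
  State st = state_from_matrix(state);
  Events ev;
  ev.enabled = log_events;
  Rng rng(step_seed(static_cast<uint64_t>(seed), t));
  do_step(st, p, c, rng, t, ev);
  return List::create(_["state"] = state_to_matrix(st), _["t"] = t + 1,
                      _["events"] = events_to_df(ev));
}

// [[Rcpp::export]]
List cpp_simulate(List params, List cfg, double seed, bool log_events) {
  Config c = config_from_list(cfg);
  Params p = params_from_list(params, c.variant);
  State st = init_state(c);
  Events ev;
  ev.enabled = log_events;
  for (int t = 0; t < c.n_steps; ++t) {
    Rng rng(step_seed(static_cast<uint64_t>(seed), t));
    do_step(st, p, c, rng, t, ev);
  }
  bool any_live = false;
  for (size_t i = 0; i < st.n(); ++i)
    if (st.kind[i] == TUMOR_LIVE) {
      any_live = true;
      break;
    }
  return List::create(_["state"] = state_to_matrix(st),
                      _["extinct"] = !any_live,
                      _["events"] = events_to_df(ev));
}

// [[Rcpp::export]]
IntegerVector cpp_neighbors_within(NumericMatrix state, int focal_row,
                                   double radius) {
  // focal_row is 1-based; returns 1-based row indices sorted by cell id
  State st = state_from_matrix(state);
  size_t i = static_cast<size_t>(focal_row - 1);
  if (focal_row < 1 || i >= st.n()) stop("focal cell is not in the state");
  if (radius < 0) stop("radius must be non-negative");
  double ex = *std::max_element(st.x.begin(), st.x.end()) -
              *std::min_element(st.x.begin(), st.x.end());
  double ey = *std::max_element(st.y.begin(), st.y.end()) -
              *std::min_element(st.y.begin(), st.y.end());
  Grid grid;
  double h = std::max({radius, std::max(ex, ey) / 64.0, 1e-6});
  grid.build(st, h);
  std::vector<int> nb;
  grid.query(st, st.x[i], st.y[i], radius, static_cast<int>(i), nb);
  std::sort(nb.begin(), nb.end(),
            [&st](int a, int b) { return st.id[a] < st.id[b]; });
  IntegerVector out(nb.size());
  for (size_t k = 0; k < nb.size(); ++k) out[k] = nb[k] + 1;
  return out;
}

// [[Rcpp::export]]
double cpp_tumor_radius(NumericMatrix state) {
  State st = state_from_matrix(state);
  return tumor_radius_of(st);
}
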