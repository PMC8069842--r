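// Simulation core for the toroidal predator-prey lattice ecosystem.
//
// All stochastic draws use R's RNG stream (unif_rand), so set.seed() on the
// R side makes every rollout fully reproducible.  State crosses the R/C++
// boundary as a plain list; the heavy loops (multi-step rollouts, data
// collection for training) stay inside C++.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int SP_PRED = 1;
static const int SP_PREY = 2;
static const int N_ACTIONS = 9;

// ---------------------------------------------------------------- config ---

struct Cfg {
  int N;
  double bX, bY;
  int TX, TY, TXage;   // TXage == 0 means predator aging disabled
  int nX, nY;
  int r, max_steps;
  bool pad;            // pad observations beyond the edge instead of wrapping
};

static Cfg parse_cfg(const List& cl) {
  Cfg c;
  c.N = as<int>(cl["N"]);
  c.bX = as<double>(cl["bX"]);
  c.bY = as<double>(cl["bY"]);
  c.TX = as<int>(cl["TX"]);
  c.TY = as<int>(cl["TY"]);
  c.TXage = 0;
  if (cl.containsElementNamed("TX_age")) {
    RObject o = cl["TX_age"];
    if (!o.isNULL()) {
      double v = as<double>(o);
      if (!ISNA(v) && v > 0) c.TXage = (int)v;
    }
  }
  c.nX = as<int>(cl["nX"]);
  c.nY = as<int>(cl["nY"]);
  c.r = as<int>(cl["r"]);
  c.max_steps = as<int>(cl["max_steps"]);
  c.pad = false;
  if (cl.containsElementNamed("obs_padding")) c.pad = as<bool>(cl["obs_padding"]);
  return c;
}

// ----------------------------------------------------------------- agents ---

struct Ag {
  int id, sp, row, col, starv, age;
  bool alive, ate;
};

struct Ev {
  long cap_pred = 0, cap_prey = 0, b_pred = 0, b_prey = 0;
  long d_starv = 0, d_age_prey = 0, d_age_pred = 0;
  void add(const Ev& o) {
    cap_pred += o.cap_pred; cap_prey += o.cap_prey;
    b_pred += o.b_pred; b_prey += o.b_prey;
    d_starv += o.d_starv; d_age_prey += o.d_age_prey; d_age_pred += o.d_age_pred;
  }
};

struct Collector;  // fwd

struct Env {
  Cfg cfg;
  List cfg_list;            // original R config, echoed back
  int t, next_id;
  std::vector<int> occ;     // N*N row-major, 0 = empty, else agent id
  std::vector<Ag> ags;
  std::unordered_map<int, int> ix;  // id -> index into ags
  int n_pred, n_prey;
  Collector* col = nullptr;

  int cell(int r_, int c_) const { return r_ * cfg.N + c_; }
};

// Pending transition record: an action whose successor observation is not
// yet known.  Closed at the agent's next turn, at its death, or at flush.
struct Pend {
  arma::vec obs;
  int act, sp;
  double rew;
};

struct Sink {
  std::vector<arma::vec> obs, nxt;
  std::vector<int> act, sp, done, id;
  std::vector<double> rew;
  void push(const arma::vec& o, int a, double r_, const arma::vec& nx,
            bool dn, int sp_, int id_) {
    obs.push_back(o); act.push_back(a); rew.push_back(r_);
    nxt.push_back(nx); done.push_back(dn ? 1 : 0); sp.push_back(sp_);
    id.push_back(id_);
  }
  size_t size() const { return obs.size(); }
};

struct Collector {
  bool pending_mode = false;
  int D = 0;
  Sink sink;
  std::unordered_map<int, Pend> pend;

  void close(int agent_id, bool done_, const arma::vec* nxt_obs) {
    auto it = pend.find(agent_id);
    if (it == pend.end()) return;
    arma::vec nx = nxt_obs ? *nxt_obs : arma::vec(D, arma::fill::zeros);
    sink.push(it->second.obs, it->second.act, it->second.rew, nx, done_,
              it->second.sp, agent_id);
    pend.erase(it);
  }
};

// ------------------------------------------------------------- conversion ---

static Env env_from_state(const List& st) {
  Env e;
  e.cfg_list = st["config"];
  e.cfg = parse_cfg(e.cfg_list);
  e.t = as<int>(st["t"]);
  e.next_id = as<int>(st["next_id"]);
  List ag = st["agents"];
  IntegerVector id = ag["id"], sp = ag["species"], row = ag["row"],
                col = ag["col"], sv = ag["starvation"], age = ag["age"];
  int n = id.size(), N = e.cfg.N;
  e.occ.assign((size_t)N * N, 0);
  e.n_pred = e.n_prey = 0;
  e.ags.reserve(n);
  for (int i = 0; i < n; ++i) {
    Ag a{id[i], sp[i], row[i], col[i], sv[i], age[i], true, false};
    if (a.row < 0 || a.row >= N || a.col < 0 || a.col >= N)
      stop("agent position outside the grid");
    int c = e.cell(a.row, a.col);
    if (e.occ[c] != 0) stop("occupancy violation: two agents share a cell");
    e.occ[c] = a.id;
    e.ix[a.id] = i;
    e.ags.push_back(a);
    if (a.sp == SP_PRED) e.n_pred++; else e.n_prey++;
  }
  return e;
}

static List agents_to_list(const Env& e) {
  int n = 0;
  for (const Ag& a : e.ags) if (a.alive) ++n;
  IntegerVector id(n), sp(n), row(n), col(n), sv(n), age(n);
  int k = 0;
  for (const Ag& a : e.ags) {
    if (!a.alive) continue;
    id[k] = a.id; sp[k] = a.sp; row[k] = a.row; col[k] = a.col;
    sv[k] = a.starv; age[k] = a.age; ++k;
  }
  return List::create(_["id"] = id, _["species"] = sp, _["row"] = row,
                      _["col"] = col, _["starvation"] = sv, _["age"] = age);
}

static List env_to_state(const Env& e) {
  int N = e.cfg.N;
  IntegerMatrix occ(N, N);
  for (int r_ = 0; r_ < N; ++r_)
    for (int c_ = 0; c_ < N; ++c_) occ(r_, c_) = e.occ[(size_t)r_ * N + c_];
  return List::create(_["config"] = e.cfg_list, _["t"] = e.t,
                      _["next_id"] = e.next_id, _["agents"] = agents_to_list(e),
                      _["occ"] = occ);
}

static List ev_to_list(const Ev& ev) {
  return List::create(
      _["captures_by_predator_action"] = (double)ev.cap_pred,
      _["captures_by_prey_action"] = (double)ev.cap_prey,
      _["predator_births"] = (double)ev.b_pred,
      _["prey_births"] = (double)ev.b_prey,
      _["starvation_deaths"] = (double)ev.d_starv,
      _["age_deaths"] = (double)ev.d_age_prey,
      _["predator_age_deaths"] = (double)ev.d_age_pred);
}

// ---------------------------------------------------------------- network ---

struct Net {
  arma::mat W1, W2, W3;
  arma::vec b1, b2, b3;
  bool valid = false;
};

static Net parse_net(RObject o) {
  Net n;
  if (o.isNULL()) return n;
  List l(o);
  n.W1 = as<arma::mat>(l["W1"]); n.b1 = as<arma::vec>(l["b1"]);
  n.W2 = as<arma::mat>(l["W2"]); n.b2 = as<arma::vec>(l["b2"]);
  n.W3 = as<arma::mat>(l["W3"]); n.b3 = as<arma::vec>(l["b3"]);
  n.valid = true;
  return n;
}

static arma::vec net_logits(const Net& n, const arma::vec& x) {
  arma::vec h1 = arma::tanh(n.W1 * x + n.b1);
  arma::vec h2 = arma::tanh(n.W2 * h1 + n.b2);
  return n.W3 * h2 + n.b3;
}

static arma::vec softmax_vec(const arma::vec& z) {
  arma::vec y = arma::exp(z - z.max());
  return y / arma::accu(y);
}

static int sample_cat(const arma::vec& p) {
  double u = unif_rand(), c = 0.0;
  for (arma::uword a = 0; a < p.n_elem; ++a) {
    c += p(a);
    if (u < c) return (int)a;
  }
  return (int)p.n_elem - 1;
}

static int sample_uniform_action() {
  int a = (int)(unif_rand() * N_ACTIONS);
  return a > N_ACTIONS - 1 ? N_ACTIONS - 1 : a;
}

// ------------------------------------------------------------ observation ---

static arma::vec observe_vec(const Env& e, int idx) {
  int r = e.cfg.r, half = r / 2, N = e.cfg.N, D = r * r;
  arma::vec v((size_t)2 * D, arma::fill::zeros);
  const Ag& a = e.ags[idx];
  for (int ch = 0; ch < 2; ++ch) {
    int want = (ch == 0) ? SP_PRED : SP_PREY;
    for (int dr = -half; dr <= half; ++dr) {
      for (int dc = -half; dc <= half; ++dc) {
        int rr = a.row + dr, cc = a.col + dc;
        int k = ch * D + (dr + half) * r + (dc + half);
        if (e.cfg.pad && (rr < 0 || rr >= N || cc < 0 || cc >= N)) continue;
        rr = ((rr % N) + N) % N;
        cc = ((cc % N) + N) % N;
        int id = e.occ[(size_t)rr * N + cc];
        if (id != 0 && e.ags.at(e.ix.at(id)).sp == want) v(k) = 1.0;
      }
    }
  }
  return v;
}

// ----------------------------------------------------------------- deaths ---

static void kill_agent(Env& e, int idx) {
  Ag& a = e.ags[idx];
  if (!a.alive) return;
  e.occ[e.cell(a.row, a.col)] = 0;
  a.alive = false;
  e.ix.erase(a.id);
  if (a.sp == SP_PRED) e.n_pred--; else e.n_prey--;
  if (e.col && e.col->pending_mode) e.col->close(a.id, true, nullptr);
}

static void spawn_agent(Env& e, int sp, int row, int col) {
  Ag a{e.next_id++, sp, row, col, 0, 0, true, false};
  e.occ[e.cell(row, col)] = a.id;
  e.ix[a.id] = (int)e.ags.size();
  e.ags.push_back(a);
  if (sp == SP_PRED) e.n_pred++; else e.n_prey++;
}

// ---------------------------------------------------------------- actions ---

// Applies one agent action; returns the reward.  died_self is set when the
// acting agent is removed by its own move (prey walking onto a predator).
static int apply_action(Env& e, int idx, int action, Ev& ev, int* died_self) {
  if (action < 0 || action >= N_ACTIONS) stop("invalid action (must be 0..8)");
  if (action == 4) return 0;  // remain
  int N = e.cfg.N;
  int sp = e.ags[idx].sp;
  int dr = action / 3 - 1, dc = action % 3 - 1;
  int nr = ((e.ags[idx].row + dr) % N + N) % N;
  int nc = ((e.ags[idx].col + dc) % N + N) % N;
  int tid = e.occ[(size_t)nr * N + nc];

  if (sp == SP_PRED) {
    if (tid == 0) {
      Ag& a = e.ags[idx];
      e.occ[e.cell(a.row, a.col)] = 0;
      a.row = nr; a.col = nc;
      e.occ[e.cell(nr, nc)] = a.id;
      return 0;
    }
    int tj = e.ix.at(tid);
    if (e.ags[tj].sp == SP_PREY) {
      // move-and-eat; offspring in the vacated origin cell w.p. bX
      kill_agent(e, tj);
      ev.cap_pred++;
      int orow, ocol;
      {
        Ag& a = e.ags[idx];
        orow = a.row; ocol = a.col;
        e.occ[e.cell(a.row, a.col)] = 0;
        a.row = nr; a.col = nc;
        e.occ[e.cell(nr, nc)] = a.id;
        a.starv = 0;
        a.ate = true;
      }
      if (unif_rand() < e.cfg.bX) {
        spawn_agent(e, SP_PRED, orow, ocol);
        ev.b_pred++;
      }
      return 1;
    }
    return 0;  // blocked by another predator
  }

  // prey
  if (tid == 0) {
    int orow, ocol;
    {
      Ag& a = e.ags[idx];
      orow = a.row; ocol = a.col;
      e.occ[e.cell(a.row, a.col)] = 0;
      a.row = nr; a.col = nc;
      e.occ[e.cell(nr, nc)] = a.id;
    }
    if (unif_rand() < e.cfg.bY) {
      spawn_agent(e, SP_PREY, orow, ocol);
      ev.b_prey++;
    }
    return 0;
  }
  int tj = e.ix.at(tid);
  if (e.ags[tj].sp == SP_PRED) {
    // prey walks onto a predator and is eaten; no predator reproduction
    kill_agent(e, idx);
    ev.cap_prey++;
    e.ags[tj].starv = 0;
    e.ags[tj].ate = true;
    if (died_self) *died_self = 1;
    return -1;
  }
  return 0;  // blocked by another prey
}

static void advance_clocks(Env& e, Ev& ev) {
  size_t n = e.ags.size();
  for (size_t i = 0; i < n; ++i) {
    Ag& a = e.ags[i];
    if (!a.alive) continue;
    if (a.sp == SP_PRED) {
      if (!a.ate) {
        a.starv++;
        if (a.starv >= e.cfg.TX) {
          kill_agent(e, (int)i);
          ev.d_starv++;
          continue;
        }
      }
      if (e.cfg.TXage > 0) {
        a.age++;
        if (a.age >= e.cfg.TXage) {
          kill_agent(e, (int)i);
          ev.d_age_pred++;
        }
      }
    } else {
      a.age++;
      if (a.age >= e.cfg.TY) {
        kill_agent(e, (int)i);
        ev.d_age_prey++;
      }
    }
  }
}

// ------------------------------------------------------------------- step ---

// One uniformly random permutation over all living agents, redrawn each step.
static std::vector<int> step_permutation(const Env& e) {
  std::vector<int> perm;
  perm.reserve(e.ags.size());
  for (size_t i = 0; i < e.ags.size(); ++i)
    if (e.ags[i].alive) perm.push_back((int)i);
  for (int i = (int)perm.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }
  return perm;
}

struct SimpleRow {
  int id, sp, act;
  double rew;
  arma::vec obs;
};

// One environment step with sequential updates.  If `simple` is non-null,
// same-step records (next_obs = end-of-step observation) are appended to it.
// If e.col is set in pending mode, training records are maintained there.
static void step_env(Env& e, const Net& np, const Net& ny, bool randP,
                     bool randY, Ev& ev, std::vector<SimpleRow>* simple) {
  for (Ag& a : e.ags) a.ate = false;
  std::vector<int> perm = step_permutation(e);
  for (int idx : perm) {
    if (!e.ags[idx].alive) continue;  // captured earlier in this step
    arma::vec obs = observe_vec(e, idx);
    int sp = e.ags[idx].sp;
    int aid = e.ags[idx].id;
    if (e.col && e.col->pending_mode) e.col->close(aid, false, &obs);
    int action;
    bool rnd = (sp == SP_PRED) ? randP : randY;
    if (rnd) {
      action = sample_uniform_action();
    } else {
      const Net& n = (sp == SP_PRED) ? np : ny;
      if (!n.valid) stop("missing policy network for a species");
      action = sample_cat(softmax_vec(net_logits(n, obs)));
    }
    int died_self = 0;
    int rew = apply_action(e, idx, action, ev, &died_self);
    if (e.col && e.col->pending_mode) {
      if (died_self) {
        arma::vec z(e.col->D, arma::fill::zeros);
        e.col->sink.push(obs, action, rew, z, true, sp, aid);
      } else {
        e.col->pend[aid] = Pend{obs, action, sp, (double)rew};
      }
    }
    if (simple) simple->push_back(SimpleRow{aid, sp, action, (double)rew, obs});
  }
  advance_clocks(e, ev);
  e.t++;
}

static std::string terminal_reason(const Env& e) {
  if (e.n_pred == 0 || e.n_prey == 0) return "extinction";
  if (e.t >= e.cfg.max_steps) return "max_steps";
  return "";
}

// -------------------------------------------------------------- placement ---

static void place_agents(Env& e) {
  int N = e.cfg.N, total = e.cfg.nX + e.cfg.nY;
  if (total > N * N) stop("invalid config: nX + nY exceeds the number of cells");
  std::vector<int> cells((size_t)N * N);
  for (int i = 0; i < N * N; ++i) cells[i] = i;
  // partial Fisher-Yates: draw `total` distinct cells uniformly
  for (int i = 0; i < total; ++i) {
    int j = i + (int)(unif_rand() * (N * N - i));
    if (j > N * N - 1) j = N * N - 1;
    std::swap(cells[i], cells[j]);
  }
  e.occ.assign((size_t)N * N, 0);
  e.ags.clear();
  e.ix.clear();
  e.n_pred = e.n_prey = 0;
  e.t = 0;
  for (int i = 0; i < total; ++i) {
    int sp = (i < e.cfg.nX) ? SP_PRED : SP_PREY;
    spawn_agent(e, sp, cells[i] / N, cells[i] % N);
  }
}

// =================================================================== API ===

// [[Rcpp::export]]
List cpp_init_env(List config) {
  Env e;
  e.cfg_list = config;
  e.cfg = parse_cfg(config);
  e.next_id = 1;
  place_agents(e);
  return env_to_state(e);
}

// [[Rcpp::export]]
NumericVector cpp_observe(List state, int id) {
  Env e = env_from_state(state);
  auto it = e.ix.find(id);
  if (it == e.ix.end()) stop("stale agent: no living agent with this id");
  arma::vec v = observe_vec(e, it->second);
  return NumericVector(v.begin(), v.end());
}

// [[Rcpp::export]]
List cpp_apply_action(List state, int id, int action) {
  Env e = env_from_state(state);
  auto it = e.ix.find(id);
  if (it == e.ix.end()) stop("stale agent: no living agent with this id");
  int idx = it->second;
  int expect = e.ags[idx].sp;
  Ev ev;
  int died_self = 0;
  int rew = apply_action(e, idx, action, ev, &died_self);
  // ids of predators whose starvation was reset by eating during this call
  std::vector<int> ate;
  for (const Ag& a : e.ags)
    if (a.alive && a.sp == SP_PRED && a.ate) ate.push_back(a.id);
  (void)expect;
  return List::create(_["state"] = env_to_state(e), _["reward"] = rew,
                      _["events"] = ev_to_list(ev),
                      _["ate_ids"] = IntegerVector(ate.begin(), ate.end()),
                      _["died"] = died_self == 1);
}

// [[Rcpp::export]]
List cpp_advance_clocks(List state, IntegerVector ate_ids) {
  Env e = env_from_state(state);
  for (int i = 0; i < ate_ids.size(); ++i) {
    auto it = e.ix.find(ate_ids[i]);
    if (it != e.ix.end()) e.ags[it->second].ate = true;
  }
  Ev ev;
  advance_clocks(e, ev);
  return List::create(_["state"] = env_to_state(e), _["events"] = ev_to_list(ev));
}

static List simple_rows_to_list(const Env& e, const std::vector<SimpleRow>& rows,
                                int D) {
  int B = (int)rows.size();
  NumericMatrix OBS(B, D), NXT(B, D);
  IntegerVector ID(B), SP(B), ACT(B), DONE(B);
  NumericVector REW(B);
  for (int b = 0; b < B; ++b) {
    const SimpleRow& r = rows[b];
    for (int k = 0; k < D; ++k) OBS(b, k) = r.obs(k);
    ID[b] = r.id; SP[b] = r.sp; ACT[b] = r.act; REW[b] = r.rew;
    auto it = e.ix.find(r.id);
    if (it == e.ix.end()) {
      DONE[b] = 1;  // removed during this step; zero next observation
    } else {
      DONE[b] = 0;
      arma::vec nx = observe_vec(e, it->second);
      for (int k = 0; k < D; ++k) NXT(b, k) = nx(k);
    }
  }
  return List::create(_["id"] = ID, _["species"] = SP, _["obs"] = OBS,
                      _["action"] = ACT, _["reward"] = REW, _["next_obs"] = NXT,
                      _["done"] = DONE);
}

// [[Rcpp::export]]
List cpp_env_step(List state, RObject net_pred, RObject net_prey,
                  bool random_pred, bool random_prey, bool collect) {
  Env e = env_from_state(state);
  Net np = parse_net(net_pred), ny = parse_net(net_prey);
  Ev ev;
  int D = 2 * e.cfg.r * e.cfg.r;
  std::vector<SimpleRow> rows;
  step_env(e, np, ny, random_pred, random_prey, ev, collect ? &rows : nullptr);
  List out = List::create(_["state"] = env_to_state(e),
                          _["events"] = ev_to_list(ev),
                          _["n_predator"] = e.n_pred, _["n_prey"] = e.n_prey);
  if (collect) out["records"] = simple_rows_to_list(e, rows, D);
  return out;
}

static NumericMatrix series_matrix(const std::vector<std::array<double, 10>>& s) {
  NumericMatrix m((int)s.size(), 10);
  for (int i = 0; i < (int)s.size(); ++i)
    for (int j = 0; j < 10; ++j) m(i, j) = s[i][j];
  colnames(m) = CharacterVector::create(
      "t", "n_predator", "n_prey", "captures_pred_action", "captures_prey_action",
      "births_pred", "births_prey", "deaths_starvation", "deaths_age",
      "deaths_age_pred");
  return m;
}

static std::array<double, 10> series_row(const Env& e, const Ev& ev) {
  return {(double)e.t, (double)e.n_pred, (double)e.n_prey,
          (double)ev.cap_pred, (double)ev.cap_prey, (double)ev.b_pred,
          (double)ev.b_prey, (double)ev.d_starv, (double)ev.d_age_prey,
          (double)ev.d_age_pred};
}

// [[Rcpp::export]]
List cpp_run_episode(List state, RObject net_pred, RObject net_prey,
                     int switch_t, IntegerVector snapshot_ts) {
  Env e = env_from_state(state);
  Net np = parse_net(net_pred), ny = parse_net(net_prey);
  std::unordered_set<int> snaps(snapshot_ts.begin(), snapshot_ts.end());
  std::vector<std::array<double, 10>> series;
  List snapshots;
  CharacterVector snap_names;
  if (snaps.count(e.t)) {
    snapshots.push_back(agents_to_list(e));
    snap_names.push_back(std::to_string(e.t));
  }
  std::string reason = terminal_reason(e);
  while (reason.empty()) {
    bool rnd = e.t < switch_t;
    Ev ev;
    step_env(e, np, ny, rnd, rnd, ev, nullptr);
    series.push_back(series_row(e, ev));
    if (snaps.count(e.t)) {
      snapshots.push_back(agents_to_list(e));
      snap_names.push_back(std::to_string(e.t));
    }
    reason = terminal_reason(e);
  }
  snapshots.attr("names") = snap_names;
  return List::create(_["state"] = env_to_state(e),
                      _["series"] = series_matrix(series),
                      _["snapshots"] = snapshots, _["reason"] = reason);
}

static List sink_to_list(const Sink& s, int D, int want_sp) {
  std::vector<int> sel;
  for (size_t i = 0; i < s.size(); ++i)
    if (s.sp[i] == want_sp) sel.push_back((int)i);
  int B = (int)sel.size();
  NumericMatrix OBS(B, D), NXT(B, D);
  IntegerVector ACT(B), DONE(B), ID(B);
  NumericVector REW(B);
  for (int b = 0; b < B; ++b) {
    int i = sel[b];
    for (int k = 0; k < D; ++k) {
      OBS(b, k) = s.obs[i](k);
      NXT(b, k) = s.nxt[i](k);
    }
    ACT[b] = s.act[i]; DONE[b] = s.done[i]; REW[b] = s.rew[i]; ID[b] = s.id[i];
  }
  return List::create(_["obs"] = OBS, _["action"] = ACT, _["reward"] = REW,
                      _["next_obs"] = NXT, _["done"] = DONE, _["id"] = ID);
}

static NumericMatrix obsvecs_to_matrix(const std::vector<arma::vec>& v, int D) {
  NumericMatrix m((int)v.size(), D);
  for (int i = 0; i < (int)v.size(); ++i)
    for (int k = 0; k < D; ++k) m(i, k) = v[i](k);
  return m;
}

// Collects h environment steps of off-policy training data.  Episodes that
// terminate mid-horizon are reset (fresh random placement) and collection
// continues; episode-start observations are recorded for the mu0 term.
// [[Rcpp::export]]
List cpp_collect(List state, RObject net_pred, RObject net_prey, int h,
                 bool random_pred, bool random_prey) {
  Env e = env_from_state(state);
  Net np = parse_net(net_pred), ny = parse_net(net_prey);
  int D = 2 * e.cfg.r * e.cfg.r;
  Collector col;
  col.pending_mode = true;
  col.D = D;
  e.col = &col;
  std::vector<arma::vec> init_pred, init_prey;
  auto push_init = [&]() {
    for (size_t i = 0; i < e.ags.size(); ++i) {
      if (!e.ags[i].alive) continue;
      arma::vec o = observe_vec(e, (int)i);
      if (e.ags[i].sp == SP_PRED) init_pred.push_back(o);
      else init_prey.push_back(o);
    }
  };
  if (e.t == 0) push_init();
  int terminations = 0;
  std::vector<std::array<double, 10>> series;
  for (int s = 0; s < h; ++s) {
    std::string reason = terminal_reason(e);
    if (!reason.empty()) {
      // flush remaining pendings: extinction ends the episode for everyone
      bool extinct = reason == "extinction";
      std::vector<int> ids;
      for (auto& kv : col.pend) ids.push_back(kv.first);
      for (int aid : ids) {
        auto it = e.ix.find(aid);
        if (extinct || it == e.ix.end()) {
          col.close(aid, true, nullptr);
        } else {
          arma::vec o = observe_vec(e, it->second);
          col.close(aid, false, &o);
        }
      }
      terminations++;
      place_agents(e);
      push_init();
    }
    Ev ev;
    step_env(e, np, ny, random_pred, random_prey, ev, nullptr);
    series.push_back(series_row(e, ev));
  }
  // final flush
  {
    bool extinct = terminal_reason(e) == "extinction";
    std::vector<int> ids;
    for (auto& kv : col.pend) ids.push_back(kv.first);
    for (int aid : ids) {
      auto it = e.ix.find(aid);
      if (extinct || it == e.ix.end()) {
        col.close(aid, true, nullptr);
      } else {
        arma::vec o = observe_vec(e, it->second);
        col.close(aid, false, &o);
      }
    }
  }
  e.col = nullptr;
  return List::create(
      _["state"] = env_to_state(e),
      _["predator"] = sink_to_list(col.sink, D, SP_PRED),
      _["prey"] = sink_to_list(col.sink, D, SP_PREY),
      _["series"] = series_matrix(series), _["terminations"] = terminations,
      _["init_obs_predator"] = obsvecs_to_matrix(init_pred, D),
      _["init_obs_prey"] = obsvecs_to_matrix(init_prey, D));
}

// [[Rcpp::export]]
List cpp_policy_forward(List net, NumericVector obs) {
  Net n = parse_net(net);
  arma::vec x(obs.begin(), obs.size());
  if ((int)n.W1.n_cols != (int)x.n_elem)
    stop("observation length does not match the network input size");
  arma::vec z = net_logits(n, x);
  arma::vec p = softmax_vec(z);
  return List::create(_["logits"] = NumericVector(z.begin(), z.end()),
                      _["probabilities"] = NumericVector(p.begin(), p.end()));
}

// [[Rcpp::export]]
List cpp_policy_forward_batch(List net, NumericMatrix X) {
  Net n = parse_net(net);
  arma::mat Xa(X.begin(), X.nrow(), X.ncol(), false);
  if ((int)n.W1.n_cols != (int)Xa.n_cols)
    stop("observation length does not match the network input size");
  arma::mat H1 = arma::tanh(Xa * n.W1.t() + arma::repmat(n.b1.t(), Xa.n_rows, 1));
  arma::mat H2 = arma::tanh(H1 * n.W2.t() + arma::repmat(n.b2.t(), Xa.n_rows, 1));
  arma::mat L = H2 * n.W3.t() + arma::repmat(n.b3.t(), Xa.n_rows, 1);
  arma::mat P = L;
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    arma::rowvec row = L.row(i);
    row -= row.max();
    row = arma::exp(row);
    P.row(i) = row / arma::accu(row);
  }
  return List::create(_["logits"] = wrap(L), _["probabilities"] = wrap(P));
}
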