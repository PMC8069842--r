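# Shared fixtures: tiny configurations, hand-built states, observation
# constructors, and tabular MDP oracles.

tiny_cfg <- function(...) {
  args <- list(N = 10L, nX = 3L, nY = 8L, max_steps = 200L)
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(env_config, args)
}

# hand-placed state: agents is a data-frame-like list of
# (id, species ("predator"/"prey"), row, col, starvation, age)
make_state <- function(cfg, id, species, row, col, starvation = NULL,
                       age = NULL) {
  n <- length(id)
  if (is.null(starvation)) starvation <- rep(0L, n)
  if (is.null(age)) age <- rep(0L, n)
  sp <- ifelse(species == "predator", 1L, 2L)
  structure(list(config = cfg, t = 0L,
                 next_id = if (n) max(id) + 1L else 1L,
                 agents = list(id = as.integer(id), species = as.integer(sp),
                               row = as.integer(row), col = as.integer(col),
                               starvation = as.integer(starvation),
                               age = as.integer(age))),
            class = "grid_state")
}

n_of <- function(state, species) {
  sum(state$agents$species == (if (species == "predator") 1L else 2L))
}

# observation vector builder: 5x5 window, cells are (row, col) in 1..5 with
# the observer at (3, 3)
make_obs <- function(self_species, pred_cells = list(), prey_cells = list(),
                     r = 5L) {
  D <- r * r
  v <- numeric(2 * D)
  idx <- function(rr, cc) (rr - 1) * r + (cc - 1) + 1
  ctr <- (r + 1) / 2
  if (self_species == "predator") v[idx(ctr, ctr)] <- 1
  else v[D + idx(ctr, ctr)] <- 1
  for (p in pred_cells) v[idx(p[1], p[2])] <- 1
  for (p in prey_cells) v[D + idx(p[1], p[2])] <- 1
  v
}

# deterministic tabular MDP with K states and 9 actions, encoded with
# one-hot observations; policy/critic objects built over that encoding
random_tabular_mdp <- function(K, seed) {
  set.seed(seed)
  list(K = K,
       nxt = matrix(sample(1:K, K * 9, TRUE), K, 9),
       rew = matrix(round(stats::runif(K * 9, -1, 1), 2), K, 9),
       mu0 = rep(1 / K, K))
}

toy_policy <- function(d_in, species = "predator", hidden = c(16L, 16L),
                       zero = FALSE) {
  structure(list(species = species,
                 net = ppcoevo:::mlp_init(d_in, hidden, 9L, last_zero = zero),
                 input_dim = d_in, hidden = hidden, n_actions = 9L,
                 iteration = 0L, seed = NA_integer_),
            class = "pp_policy")
}

toy_critic <- function(d_in, species = "predator", hidden = c(16L, 16L),
                       zero = TRUE) {
  structure(list(species = species,
                 net = ppcoevo:::mlp_init(d_in, hidden, 9L, last_zero = zero),
                 input_dim = d_in, hidden = hidden),
            class = "pp_critic")
}

# exact discounted return of the policy implemented by `pol` on the MDP,
# via the linear-solve occupancy oracle
mdp_exact_return <- function(mdp, pol, gamma) {
  K <- mdp$K
  P <- ppcoevo:::softmax_rows(ppcoevo:::mlp_forward(pol$net, diag(K))$out)
  SA <- K * 9
  ix <- function(s, a) (s - 1) * 9 + a
  Pp <- matrix(0, SA, SA)
  rv <- m0 <- numeric(SA)
  for (s in 1:K) {
    for (a in 1:9) {
      rv[ix(s, a)] <- mdp$rew[s, a]
      m0[ix(s, a)] <- mdp$mu0[s] * P[s, a]
      sp <- mdp$nxt[s, a]
      for (ap in 1:9) Pp[ix(s, a), ix(sp, ap)] <- P[sp, ap]
    }
  }
  dpi <- solve(diag(SA) - gamma * t(Pp), (1 - gamma) * m0)
  sum(dpi * rv)
}

# enumeration batch over all (s, a) pairs (uniform d_D) of the MDP
mdp_full_batch <- function(mdp) {
  K <- mdp$K
  obs1h <- diag(K)
  list(obs = obs1h[rep(1:K, each = 9), , drop = FALSE],
       action = rep(0:8, K),
       reward = as.vector(t(mdp$rew)),
       next_obs = obs1h[as.vector(t(mdp$nxt)), , drop = FALSE],
       done = rep(0L, K * 9))
}

uniform9 <- rep(1 / 9, 9)
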