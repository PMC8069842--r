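#' Initialize a state-action value network
#'
#' Q(s, a) over the same observation encoding as the policy, with nine
#' outputs (one per action).  The final layer starts at zero so Q is
#' identically zero before training.
#'
#' @inheritParams policy_init
#' @return An object of class `pp_critic`.
#' @export
critic_init <- function(species, r = 5L, hidden = c(64L, 64L), seed = NULL) {
  species <- match.arg(species, SPECIES_LEVELS)
  if (!is.null(seed)) set.seed(seed)
  d_in <- as.integer(2L * r * r)
  net <- mlp_init(d_in, hidden, 9L, last_zero = TRUE)
  structure(list(species = species, net = net, r = as.integer(r),
                 hidden = as.integer(hidden), input_dim = d_in),
            class = "pp_critic")
}

# ------------------------------------------------------------------ buffer ---

#' Create a replay buffer
#'
#' Capacity-bounded FIFO store of per-agent transition records, kept
#' separately per species, plus a pool of episode-start observations for the
#' initial-distribution term of the training objective.
#'
#' @param capacity Maximum records retained per species.
#' @param init_capacity Maximum episode-start observations retained per
#'   species.
#' @return An environment of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity = 1e5, init_capacity = 4096L) {
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$init_capacity <- as.integer(init_capacity)
  for (sp in SPECIES_LEVELS) {
    buf[[sp]] <- list(obs = NULL, action = integer(0), reward = numeric(0),
                      next_obs = NULL, done = integer(0))
    buf[[paste0("init_", sp)]] <- NULL
  }
  class(buf) <- "replay_buffer"
  buf
}

fifo_bind <- function(old, new, cap) {
  out <- if (is.null(old)) new else rbind(old, new)
  if (nrow(out) > cap) out <- out[(nrow(out) - cap + 1):nrow(out), , drop = FALSE]
  out
}

#' Append collected transitions to a replay buffer
#'
#' @param buf A [replay_buffer()].
#' @param collected Output of [collect_rollout()] (fields `predator`, `prey`,
#'   `init_obs_predator`, `init_obs_prey`).
#' @return The buffer, invisibly.
#' @export
buffer_append <- function(buf, collected) {
  for (sp in SPECIES_LEVELS) {
    tr <- collected[[sp]]
    if (!is.null(tr) && nrow(tr$obs) > 0) {
      cur <- buf[[sp]]
      cur$obs <- fifo_bind(cur$obs, tr$obs, buf$capacity)
      cur$next_obs <- fifo_bind(cur$next_obs, tr$next_obs, buf$capacity)
      n <- nrow(cur$obs)
      cur$action <- utils::tail(c(cur$action, tr$action), n)
      cur$reward <- utils::tail(c(cur$reward, tr$reward), n)
      cur$done <- utils::tail(c(cur$done, tr$done), n)
      buf[[sp]] <- cur
    }
    io <- collected[[paste0("init_obs_", sp)]]
    if (!is.null(io) && nrow(io) > 0) {
      key <- paste0("init_", sp)
      buf[[key]] <- fifo_bind(buf[[key]], io, buf$init_capacity)
    }
  }
  invisible(buf)
}

#' Number of stored records for a species
#' @param buf A [replay_buffer()].
#' @param species `"predator"` or `"prey"`.
#' @export
buffer_size <- function(buf, species) {
  species <- match.arg(species, SPECIES_LEVELS)
  if (is.null(buf[[species]]$obs)) 0L else nrow(buf[[species]]$obs)
}

#' Sample a minibatch (with replacement) from one species' records
#' @inheritParams buffer_size
#' @param n Minibatch size.
#' @return `list(obs, action, reward, next_obs, done)` with `obs`/`next_obs`
#'   as n x D matrices and actions in 0..8.
#' @export
buffer_sample <- function(buf, species, n) {
  species <- match.arg(species, SPECIES_LEVELS)
  sz <- buffer_size(buf, species)
  if (sz == 0L) stop("no data: replay buffer is empty for ", species,
                     call. = FALSE)
  idx <- sample.int(sz, n, replace = TRUE)
  cur <- buf[[species]]
  list(obs = cur$obs[idx, , drop = FALSE], action = cur$action[idx],
       reward = cur$reward[idx],
       next_obs = cur$next_obs[idx, , drop = FALSE], done = cur$done[idx])
}

buffer_sample_init <- function(buf, species, n) {
  io <- buf[[paste0("init_", species)]]
  if (is.null(io) || nrow(io) == 0)
    stop("no data: no episode-start observations stored for ", species,
         call. = FALSE)
  io[sample.int(nrow(io), min(n, nrow(io))), , drop = FALSE]
}

# ----------------------------------------------------------- rollout (R side)

#' Collect off-policy training data
#'
#' Runs `h` environment steps from `state` under the given policies (or
#' uniform-random behavior for a species whose policy is `NULL`).  Episodes
#' that terminate mid-horizon are reset with a fresh random placement and
#' collection continues; observations of all agents at each episode start
#' are recorded for the initial-distribution term.  Each action yields one
#' transition record, closed at the agent's next decision point, at its
#' death (`done = 1`), or bootstrapped at the horizon end.
#'
#' @param state A grid state.
#' @param policy_pred,policy_prey `pp_policy` objects or `NULL`.
#' @param h Number of environment steps.
#' @return List with the advanced `state`, per-species transition sets,
#'   a per-step `series` matrix, the number of episode `terminations`, and
#'   episode-start observation matrices.
#' @export
collect_rollout <- function(state, policy_pred, policy_prey, h) {
  np <- if (is.null(policy_pred)) NULL else policy_pred$net
  ny <- if (is.null(policy_prey)) NULL else policy_prey$net
  out <- cpp_collect(state, np, ny, as.integer(h), is.null(policy_pred),
                     is.null(policy_prey))
  class(out$state) <- "grid_state"
  out
}

# -------------------------------------------------------------- objectives ---

# batch pieces shared by the critic and actor gradients
eval_batch <- function(critic, policy, batch, init_obs, gamma) {
  B <- nrow(batch$obs)
  fq <- mlp_forward(critic$net, batch$obs)
  fq2 <- mlp_forward(critic$net, batch$next_obs)
  fq0 <- mlp_forward(critic$net, init_obs)
  fp2 <- mlp_forward(policy$net, batch$next_obs)
  fp0 <- mlp_forward(policy$net, init_obs)
  P2 <- softmax_rows(fp2$out)
  P0 <- softmax_rows(fp0$out)
  V2 <- rowSums(P2 * fq2$out)
  V0 <- rowSums(P0 * fq0$out)
  ai <- cbind(seq_len(B), batch$action + 1L)
  Qsa <- fq$out[ai]
  delta <- batch$reward + gamma * (1 - batch$done) * V2 - Qsa
  list(B = B, M = nrow(init_obs), fq = fq, fq2 = fq2, fq0 = fq0,
       fp2 = fp2, fp0 = fp0, P2 = P2, P0 = P0, V2 = V2, V0 = V0, ai = ai,
       delta = delta)
}

#' Regularized Bellman residual of a single record
#'
#' `r + gamma * E_[a' ~ pi(.|s')] Q(s', a') - Q(s, a)`, with the expectation
#' over next actions computed exactly over the nine actions, and zero
#' continuation for terminal records.
#'
#' @param critic A `pp_critic`.
#' @param policy A `pp_policy` of the same species.
#' @param rec A record: list with `observation`, `action` (0..8), `reward`,
#'   `next_observation` (may be `NULL` when `done`), `done`.
#' @param gamma Discount factor.
#' @return Scalar residual.
#' @export
bellman_residual <- function(critic, policy, rec, gamma) {
  if (!identical(critic$species, policy$species))
    stop("species mismatch between critic and policy", call. = FALSE)
  obs <- as_obs_vector(rec$observation)
  Q <- mlp_forward(critic$net, matrix(obs, nrow = 1))$out
  cont <- 0
  done <- isTRUE(rec$done) || (is.numeric(rec$done) && rec$done == 1)
  if (!done) {
    nxt <- as_obs_vector(rec$next_observation)
    Q2 <- mlp_forward(critic$net, matrix(nxt, nrow = 1))$out
    P2 <- softmax_rows(mlp_forward(policy$net, matrix(nxt, nrow = 1))$out)
    cont <- sum(P2 * Q2)
  }
  as.numeric(rec$reward + gamma * cont - Q[1, rec$action + 1L])
}

#' Regularized primal training objective
#'
#' The off-policy estimate of the policy's discounted return:
#' `(1 - gamma) * E_[s0 ~ mu0, a ~ pi] Q(s0, a) + E_batch f*(residual)` with
#' `f*(y) = y^2 / 2`, the convex conjugate of the f-divergence regularizer
#' `f(x) = x^2 / 2`.  Minimizing over Q recovers the discounted return of
#' the policy; the actor ascends the same objective.
#'
#' @param critic A `pp_critic`.
#' @param policy A `pp_policy` of the same species.
#' @param batch Minibatch as returned by [buffer_sample()].
#' @param init_obs Matrix of episode-start observations (rows).
#' @param gamma Discount factor.
#' @return Scalar objective value.
#' @export
algaedice_objective <- function(critic, policy, batch, init_obs, gamma) {
  if (!identical(critic$species, policy$species))
    stop("species mismatch between critic and policy", call. = FALSE)
  if (is.null(batch$obs) || nrow(batch$obs) == 0)
    stop("empty batch", call. = FALSE)
  if (is.null(init_obs) || nrow(init_obs) == 0)
    stop("empty initial-observation sample", call. = FALSE)
  ev <- eval_batch(critic, policy, batch, init_obs, gamma)
  (1 - gamma) * mean(ev$V0) + mean(ev$delta^2 / 2)
}

#' Off-policy estimate of the discounted return
#'
#' `(1 - gamma) * E_[s0, a ~ pi] Q(s0, a) + E_batch[residual^2]`.  At the
#' minimizer of [algaedice_objective()] the residual equals the occupancy
#' ratio `d_pi / d_D`, making this expression exactly the discounted return
#' of the policy (the objective itself equals the return minus the
#' f-divergence regularizer's value).
#'
#' @inheritParams algaedice_objective
#' @return Scalar return estimate on the (1 - gamma)-normalized scale.
#' @export
estimated_return <- function(critic, policy, batch, init_obs, gamma) {
  ev <- eval_batch(critic, policy, batch, init_obs, gamma)
  (1 - gamma) * mean(ev$V0) + mean(ev$delta^2)
}

# gradient of the objective w.r.t. the critic parameters (for descent)
critic_grad <- function(critic, policy, batch, init_obs, gamma, ev = NULL) {
  if (is.null(ev)) ev <- eval_batch(critic, policy, batch, init_obs, gamma)
  G <- matrix(0, ev$B, 9)
  G[ev$ai] <- -ev$delta / ev$B
  G2 <- (gamma * (1 - batch$done) * ev$delta / ev$B) * ev$P2
  G0 <- ((1 - gamma) / ev$M) * ev$P0
  g <- mlp_backward(critic$net, ev$fq, G)
  g <- grads_add(g, mlp_backward(critic$net, ev$fq2, G2))
  g <- grads_add(g, mlp_backward(critic$net, ev$fq0, G0))
  list(value = (1 - gamma) * mean(ev$V0) + mean(ev$delta^2 / 2), grads = g,
       ev = ev)
}

# gradient of (objective + entropy bonus) w.r.t. the policy parameters,
# with the critic detached (for ascent)
actor_grad <- function(policy, critic, batch, init_obs, gamma, entropy_coef,
                       ev = NULL) {
  if (is.null(ev)) ev <- eval_batch(critic, policy, batch, init_obs, gamma)
  # d/dlogits of sum_a pi(a|s) v(a) is p * (v - sum p v)
  GL0 <- ((1 - gamma) / ev$M) * (ev$P0 * (ev$fq0$out - ev$V0))
  # f*'(residual) estimates the occupancy ratio d_pi/d_D, which is
  # nonnegative; project negative residuals (critic estimation error) to 0
  # so the actor never ascends toward low-value actions.
  w <- pmax(ev$delta, 0)
  GL2 <- (gamma * (1 - batch$done) * w / ev$B) *
    (ev$P2 * (ev$fq2$out - ev$V2))
  g <- mlp_backward(policy$net, ev$fp0, GL0)
  g <- grads_add(g, mlp_backward(policy$net, ev$fp2, GL2))
  ent <- 0
  if (entropy_coef > 0) {
    fp <- mlp_forward(policy$net, batch$obs)
    P <- softmax_rows(fp$out)
    H <- entropy_rows(P)
    logP <- ifelse(P > 0, log(P), 0)
    GH <- -(entropy_coef / ev$B) * (P * (logP + H))
    g <- grads_add(g, mlp_backward(policy$net, fp, GH))
    ent <- mean(H)
  }
  value <- (1 - gamma) * mean(ev$V0) +
    mean(w * gamma * (1 - batch$done) * ev$V2) + entropy_coef * ent
  list(value = value, grads = g, entropy = ent)
}

# advantage policy-gradient update on freshly collected (on-policy) records:
# grad = E[ dlog pi(a|s) * A(s,a) ] + entropy bonus, with the advantage
# A = r + gamma (1-done) V(s') - V(s) computed from the critic under the
# current policy.  This is the data-gathering-stage update; it carries the
# dense per-action signal (captures for predators, fatal moves for prey).
pg_update <- function(policy, critic, records, opt, cfg, n_steps = 10L) {
  B_all <- nrow(records$obs)
  if (is.null(B_all) || B_all == 0) return(list(policy = policy, opt = opt))
  for (k in seq_len(n_steps)) {
    idx <- sample.int(B_all, min(2048L, B_all))
    obs <- records$obs[idx, , drop = FALSE]
    act <- records$action[idx]
    rew <- records$reward[idx]
    nxt <- records$next_obs[idx, , drop = FALSE]
    done <- records$done[idx]
    B <- length(idx)
    fq <- mlp_forward(critic$net, obs)
    fq2 <- mlp_forward(critic$net, nxt)
    fp <- mlp_forward(policy$net, obs)
    P <- softmax_rows(fp$out)
    fp2 <- mlp_forward(policy$net, nxt)
    P2 <- softmax_rows(fp2$out)
    V <- rowSums(P * fq$out)
    V2 <- rowSums(P2 * fq2$out)
    adv <- rew + cfg$gamma * (1 - done) * V2 - V
    # dlog pi(a|s)/dlogits = onehot(a) - pi;  ascend E[log pi * A] + c H
    G <- -P * adv / B
    G[cbind(seq_len(B), act + 1L)] <- G[cbind(seq_len(B), act + 1L)] + adv / B
    if (cfg$entropy_coef > 0) {
      H <- entropy_rows(P)
      logP <- ifelse(P > 0, log(P), 0)
      G <- G - (cfg$entropy_coef / B) * (P * (logP + H))
    }
    g <- mlp_backward(policy$net, fp, G)
    st <- adamw_step(policy$net, g, opt, cfg$actor_lr, cfg$weight_decay,
                     maximize = TRUE)
    policy$net <- st$net
    opt <- st$opt
  }
  list(policy = policy, opt = opt)
}

# ------------------------------------------------------------ best response ---

#' One best-response stage for a species
#'
#' Performs `n_inner` interleaved gradient steps on the learner's value
#' network (descent on the regularized objective) and policy (ascent on the
#' same objective plus the entropy bonus), using off-policy minibatches of
#' the learner's species from the buffer.  The opponent's parameters are
#' never touched: detachment is structural.
#'
#' @param learner `list(policy = , critic = , opt_policy = , opt_critic = )`;
#'   optimizer states are created when missing.
#' @param opponent The frozen opponent `pp_policy` (unused by the update;
#'   accepted to make the detachment contract explicit).
#' @param buffer A [replay_buffer()].
#' @param cfg A [train_config()].
#' @return Updated learner with a `diagnostics` list (mean critic loss,
#'   actor objective, entropy).
#' @export
best_response_update <- function(learner, opponent, buffer, cfg) {
  sp <- learner$policy$species
  if (buffer_size(buffer, sp) == 0L)
    stop("no data: replay buffer is empty for ", sp, call. = FALSE)
  if (is.null(learner$opt_policy)) learner$opt_policy <- adamw_init(learner$policy$net)
  if (is.null(learner$opt_critic)) learner$opt_critic <- adamw_init(learner$critic$net)
  closs <- aval <- entr <- numeric(cfg$n_inner)
  for (i in seq_len(cfg$n_inner)) {
    batch <- buffer_sample(buffer, sp, cfg$batch_size)
    init_obs <- buffer_sample_init(buffer, sp, cfg$init_obs_batch)
    cg <- critic_grad(learner$critic, learner$policy, batch, init_obs,
                      cfg$gamma)
    if (cfg$critic_lr > 0) {
      st <- adamw_step(learner$critic$net, cg$grads, learner$opt_critic,
                       cfg$critic_lr, cfg$weight_decay)
      learner$critic$net <- st$net
      learner$opt_critic <- st$opt
    }
    ag <- actor_grad(learner$policy, learner$critic, batch, init_obs,
                     cfg$gamma, cfg$entropy_coef)
    if (cfg$actor_lr > 0) {
      st <- adamw_step(learner$policy$net, ag$grads, learner$opt_policy,
                       cfg$actor_lr, cfg$weight_decay, maximize = TRUE)
      learner$policy$net <- st$net
      learner$opt_policy <- st$opt
    }
    closs[i] <- cg$value
    aval[i] <- ag$value
    entr[i] <- ag$entropy
  }
  learner$diagnostics <- list(critic_loss = mean(closs),
                              actor_objective = mean(aval),
                              entropy = mean(entr))
  learner
}

# --------------------------------------------------------------- coevolve ---

#' Co-evolution of predator and prey policies
#'
#' The iterated approximate-best-response procedure: initialize both
#' species' policy and value networks; then for each outer iteration run a
#' best-response stage for the prey and then the predator (off-policy
#' gradient updates on the regularized objective with entropy bonus),
#' collect `h` environment steps under the current policies into the shared
#' experience buffer (episodes reset on termination), and check the
#' stopping criterion (the iteration cap).  The buffer is reset once at
#' procedure start.
#'
#' The stopping criterion combines the iteration cap with performance
#' monitoring: after each iteration a short evaluation episode (the
#' "probe", `probe_steps` long, on its own seed stream) measures whether
#' the current policy pair sustains coexistence and at what population
#' levels.  With `select_best = TRUE` the returned pair is the iterate
#' with the best probe performance — survival first, then total
#' population — so that training that over-sharpens the predators (and
#' collapses the ecosystem) falls back to the best co-adapted pair seen.
#'
#' @param env_cfg An [env_config()].
#' @param cfg A [train_config()].
#' @param verbose Print per-iteration progress.
#' @return List with `policy_predator`, `policy_prey`, the two critics, the
#'   buffer, `best_iteration`, and `history` (one data-frame row per
#'   iteration: populations, losses, entropies, episode terminations,
#'   probe results).
#' @export
coevolve <- function(env_cfg, cfg, verbose = FALSE) {
  streams <- seed_streams(cfg$seed)
  set.seed(streams$policy_init)
  learners <- list(
    predator = list(policy = policy_init("predator", r = env_cfg$r,
                                         hidden = cfg$hidden),
                    critic = critic_init("predator", r = env_cfg$r,
                                         hidden = cfg$hidden)),
    prey = list(policy = policy_init("prey", r = env_cfg$r,
                                     hidden = cfg$hidden),
                critic = critic_init("prey", r = env_cfg$r,
                                     hidden = cfg$hidden)))
  buffer <- replay_buffer(cfg$buffer_capacity)
  state <- init_env(env_cfg, seed = streams$placement)
  set.seed(streams$rollout)
  history <- vector("list", cfg$n_iterations)
  best <- NULL
  for (it in seq_len(cfg$n_iterations)) {
    diag <- list()
    for (sp in c("prey", "predator")) {   # prey stage first
      if (buffer_size(buffer, sp) > 0L) {
        opp <- if (sp == "prey") learners$predator$policy else learners$prey$policy
        learners[[sp]] <- best_response_update(learners[[sp]], opp, buffer, cfg)
        diag[[sp]] <- learners[[sp]]$diagnostics
      }
    }
    col <- collect_rollout(state, learners$predator$policy,
                           learners$prey$policy, cfg$h)
    state <- col$state
    buffer_append(buffer, col)
    # data-gathering-stage policy-gradient update on the fresh records
    for (sp in c("prey", "predator")) {
      if (is.null(learners[[sp]]$opt_policy))
        learners[[sp]]$opt_policy <- adamw_init(learners[[sp]]$policy$net)
      up <- pg_update(learners[[sp]]$policy, learners[[sp]]$critic,
                      col[[sp]], learners[[sp]]$opt_policy, cfg)
      learners[[sp]]$policy <- up$policy
      learners[[sp]]$opt_policy <- up$opt
    }
    # performance probe for the stopping criterion: does the current pair
    # sustain coexistence, and at what population level?  Runs on its own
    # seed without disturbing the training RNG stream.
    probe_steps <- NA_real_
    probe_pop <- NA_real_
    if (cfg$probe_steps > 0) {
      rng_state <- .Random.seed
      pcfg <- env_cfg
      pcfg$max_steps <- cfg$probe_steps
      pe <- run_episode(list(predator = learners$predator$policy,
                             prey = learners$prey$policy), pcfg,
                        seed = (streams$policy_init + 7919L * it) %% 2147483629L,
                        switch_t = 0)
      assign(".Random.seed", rng_state, envir = globalenv())
      probe_steps <- max(pe$series$t)
      probe_pop <- mean(pe$series$n_predator + pe$series$n_prey)
      cand <- list(iteration = it,
                   policy_predator = learners$predator$policy,
                   policy_prey = learners$prey$policy,
                   steps = probe_steps, pop = probe_pop)
      # prefer the most co-adapted (latest) iterate among those that
      # sustain coexistence for the whole probe
      if (is.null(best) || cand$steps >= best$steps)
        best <- cand
    }
    s <- col$series
    history[[it]] <- data.frame(
      iteration = it,
      mean_n_predator = mean(s[, "n_predator"]),
      mean_n_prey = mean(s[, "n_prey"]),
      terminations = col$terminations,
      buffer_predator = buffer_size(buffer, "predator"),
      buffer_prey = buffer_size(buffer, "prey"),
      critic_loss_predator = diag$predator$critic_loss %||% NA_real_,
      critic_loss_prey = diag$prey$critic_loss %||% NA_real_,
      entropy_predator = diag$predator$entropy %||% NA_real_,
      entropy_prey = diag$prey$entropy %||% NA_real_,
      probe_steps = probe_steps, probe_pop = probe_pop)
    if (verbose)
      message(sprintf("iter %d: pop = (%.1f, %.1f), resets = %d", it,
                      history[[it]]$mean_n_predator,
                      history[[it]]$mean_n_prey, col$terminations))
  }
  pol_pred <- learners$predator$policy
  pol_prey <- learners$prey$policy
  best_iteration <- cfg$n_iterations
  if (cfg$select_best && !is.null(best)) {
    pol_pred <- best$policy_predator
    pol_prey <- best$policy_prey
    best_iteration <- best$iteration
  }
  pol_pred$iteration <- best_iteration
  pol_prey$iteration <- best_iteration
  list(policy_predator = pol_pred,
       policy_prey = pol_prey,
       critic_predator = learners$predator$critic,
       critic_prey = learners$prey$critic,
       buffer = buffer,
       best_iteration = best_iteration,
       history = do.call(rbind, history))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ------------------------------------------------------------ DQN baseline ---

#' Sparse Q-table for the deep-Q-learning baseline
#'
#' The baseline follows the classical update
#' `Q(s,a) <- (1 - alpha) Q(s,a) + alpha [r + gamma max_a' Q(s',a')]`
#' keyed on the exact observation window, with unseen entries at zero.
#'
#' @return An environment of class `dqn_qtable`.
#' @export
dqn_qtable <- function() {
  q <- new.env(parent = emptyenv())
  class(q) <- "dqn_qtable"
  q
}

obs_key <- function(obs) paste(as.integer(as_obs_vector(obs)), collapse = "")

dqn_lookup <- function(qtab, obs) {
  k <- obs_key(obs)
  if (is.null(qtab[[k]])) numeric(9) else qtab[[k]]
}

#' One tabular Q-learning update
#'
#' @param qtab A [dqn_qtable()].
#' @param rec A record: list with `observation`, `action` (0..8), `reward`,
#'   `next_observation`, `done`.
#' @param alpha Learning rate.
#' @param gamma Discount factor.
#' @return The table, invisibly (updated in place).
#' @export
dqn_baseline_update <- function(qtab, rec, alpha, gamma) {
  k <- obs_key(rec$observation)
  q <- if (is.null(qtab[[k]])) numeric(9) else qtab[[k]]
  done <- isTRUE(rec$done) || (is.numeric(rec$done) && rec$done == 1)
  target <- rec$reward +
    if (done) 0 else gamma * max(dqn_lookup(qtab, rec$next_observation))
  a <- rec$action + 1L
  q[a] <- (1 - alpha) * q[a] + alpha * target
  qtab[[k]] <- q
  invisible(qtab)
}

#' Epsilon-greedy action from a Q-table
#'
#' @inheritParams dqn_baseline_update
#' @param obs An observation.
#' @param eps Exploration probability (default 0.05).
#' @return Integer action 0..8.
#' @export
dqn_action <- function(qtab, obs, eps = 0.05) {
  if (stats::runif(1) < eps) return(sample.int(9L, 1L) - 1L)
  q <- dqn_lookup(qtab, obs)
  best <- which(q == max(q))
  as.integer(best[sample.int(length(best), 1L)] - 1L)
}

#' Train the DQN baseline at desk scale
#'
#' Both species act epsilon-greedily from sparse Q-tables which are updated
#' online with the classical rule; per-species learning rates default to the
#' asymmetric values used for this baseline (1e-5 predators, 1e-3 prey).
#' Driven by the fine-grained environment operations, so intended for small
#' grids.
#'
#' @param env_cfg An [env_config()].
#' @param steps Environment steps to train for.
#' @param alpha_pred,alpha_prey Learning rates.
#' @param eps Exploration probability.
#' @param gamma Discount factor.
#' @param seed Seed.
#' @return List with the two Q-tables and the population series.
#' @export
train_dqn <- function(env_cfg, steps, alpha_pred = 1e-5, alpha_prey = 1e-3,
                      eps = 0.05, gamma = 0.99, seed = 1L) {
  set.seed(seed)
  qp <- dqn_qtable()
  qy <- dqn_qtable()
  state <- init_env(env_cfg)
  series <- matrix(NA_real_, steps, 3,
                   dimnames = list(NULL, c("t", "n_predator", "n_prey")))
  for (s in seq_len(steps)) {
    if (is_terminal(state)$terminal) state <- init_env(env_cfg)
    ids <- state$agents$id
    perm <- if (length(ids) > 1) sample(ids) else ids
    ate <- integer(0)
    pending <- list()
    for (id in perm) {
      if (!(id %in% state$agents$id)) next  # captured earlier this step
      sp <- state$agents$species[match(id, state$agents$id)]
      obs <- cpp_observe(state, id)
      qtab <- if (sp == 1L) qp else qy
      a <- dqn_action(qtab, obs, eps)
      res <- cpp_apply_action(state, id, a)
      state <- res$state
      class(state) <- "grid_state"
      ate <- union(ate, res$ate_ids)
      pending[[as.character(id)]] <-
        list(observation = obs, action = a, reward = res$reward, sp = sp)
    }
    state <- advance_clocks(state, ate)$state
    state$t <- state$t + 1L
    for (key in names(pending)) {
      p <- pending[[key]]
      id <- as.integer(key)
      alive <- id %in% state$agents$id
      rec <- list(observation = p$observation, action = p$action,
                  reward = p$reward,
                  next_observation = if (alive) cpp_observe(state, id) else NULL,
                  done = !alive)
      if (p$sp == 1L) dqn_baseline_update(qp, rec, alpha_pred, gamma)
      else dqn_baseline_update(qy, rec, alpha_prey, gamma)
    }
    series[s, ] <- c(state$t, sum(state$agents$species == 1L),
                     sum(state$agents$species == 2L))
  }
  list(q_predator = qp, q_prey = qy, series = as.data.frame(series))
}
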