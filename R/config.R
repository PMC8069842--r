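#' Environment configuration
#'
#' Builds and validates the parameter set of the lattice ecosystem.  Defaults
#' are the reference simulation conditions: a 50 x 50 torus, predator
#' reproduction probability `bX = 0.2`, prey reproduction probability
#' `bY = 0.6`, predator maximum starvation `TX = 15` steps, prey maximum age
#' `TY = 30` steps, initial populations `nX = 100` predators and `nY = 500`
#' prey, and a 5 x 5 egocentric observation window.
#'
#' @param N Grid side length (cells).
#' @param bX Predator reproduction probability on a successful capture.
#' @param bY Prey reproduction probability on a successful move.
#' @param TX Predator maximum starvation level (steps without eating).
#' @param TY Prey maximum age (steps).
#' @param TX_age Optional predator maximum age (steps); `NULL` disables
#'   predator aging (the default).
#' @param nX,nY Initial predator and prey counts.
#' @param r Observation window side (odd number of cells).
#' @param max_steps Episode cap (steps).
#' @param obs_padding If `TRUE`, cells beyond the grid edge are observed as
#'   empty padding instead of wrapping around the torus.  Movement always
#'   wraps; this toggle only affects observations.
#' @return A validated list of class `env_config`.
#' @export
env_config <- function(N = 50L, bX = 0.2, bY = 0.6, TX = 15L, TY = 30L,
                       TX_age = NULL, nX = 100L, nY = 500L, r = 5L,
                       max_steps = 2000L, obs_padding = FALSE) {
  cfg <- list(N = as.integer(N), bX = as.numeric(bX), bY = as.numeric(bY),
              TX = as.integer(TX), TY = as.integer(TY),
              TX_age = if (is.null(TX_age)) NULL else as.integer(TX_age),
              nX = as.integer(nX), nY = as.integer(nY), r = as.integer(r),
              max_steps = as.integer(max_steps),
              obs_padding = isTRUE(obs_padding))
  class(cfg) <- "env_config"
  validate_env_config(cfg)
  cfg
}

validate_env_config <- function(cfg) {
  stopifnot(is.list(cfg))
  fail <- function(field, msg) {
    stop(sprintf("invalid config: field '%s' %s", field, msg), call. = FALSE)
  }
  if (cfg$N < 1) fail("N", "must be >= 1")
  if (cfg$r < 1 || cfg$r %% 2 == 0) fail("r", "must be odd and >= 1")
  if (cfg$N < cfg$r) fail("N", "must be >= r")
  if (cfg$bX < 0 || cfg$bX > 1) fail("bX", "must lie in [0, 1]")
  if (cfg$bY < 0 || cfg$bY > 1) fail("bY", "must lie in [0, 1]")
  if (cfg$TX < 1) fail("TX", "must be >= 1")
  if (cfg$TY < 1) fail("TY", "must be >= 1")
  if (!is.null(cfg$TX_age) && cfg$TX_age < 1) fail("TX_age", "must be >= 1")
  if (cfg$nX < 0) fail("nX", "must be >= 0")
  if (cfg$nY < 0) fail("nY", "must be >= 0")
  if (cfg$nX + cfg$nY > cfg$N^2)
    fail("nX", sprintf("+ nY exceeds the %d cells of the grid", cfg$N^2))
  if (cfg$max_steps < 0) fail("max_steps", "must be >= 0")
  invisible(cfg)
}

#' Training configuration
#'
#' Parameters of the co-evolution procedure: the discount, the sampling
#' horizon between policy updates, outer-iteration budget (the stopping
#' criterion), optimizer step sizes, entropy-bonus weight, and replay-buffer
#' geometry.  The f-divergence used for regularizing the off-policy objective
#' is fixed to f(x) = x^2/2 (so its convex conjugate is f*(y) = y^2/2).
#'
#' @param gamma Discount factor in (0, 1).
#' @param h Sampling horizon: environment steps collected per outer iteration.
#' @param n_iterations Outer-loop iteration cap (stopping criterion).
#' @param entropy_coef Weight of the policy-entropy bonus in the actor update.
#' @param critic_lr,actor_lr AdamW step sizes for the value network and policy.
#' @param batch_size Minibatch size drawn from the replay buffer per gradient
#'   step.
#' @param buffer_capacity Replay-buffer capacity per species (FIFO eviction).
#' @param n_inner Gradient steps (one critic + one actor update each) per
#'   best-response stage.
#' @param hidden Widths of the two hidden layers of policy and value networks.
#' @param weight_decay Decoupled weight decay of the AdamW updates.
#' @param init_obs_batch Episode-start observations sampled per gradient step
#'   for the initial-distribution term of the objective.
#' @param probe_steps Length of the per-iteration evaluation probe used by
#'   the performance-based part of the stopping criterion (see
#'   [coevolve()]); 0 disables probing.
#' @param select_best If `TRUE`, [coevolve()] returns the iterate with the
#'   best probe performance (sustained coexistence, then populations)
#'   rather than the last one.
#' @param seed Master seed; expanded into named per-component streams.
#' @return A validated list of class `train_config`.
#' @export
train_config <- function(gamma = 0.99, h = 70L, n_iterations = 20L,
                         entropy_coef = 0.01, critic_lr = 1e-3,
                         actor_lr = 1e-4, batch_size = 256L,
                         buffer_capacity = 1e5, n_inner = 50L,
                         hidden = c(64L, 64L), weight_decay = 1e-4,
                         init_obs_batch = 64L, probe_steps = 1000L,
                         select_best = TRUE, seed = 1L) {
  cfg <- list(gamma = as.numeric(gamma), h = as.integer(h),
              n_iterations = as.integer(n_iterations),
              entropy_coef = as.numeric(entropy_coef),
              critic_lr = as.numeric(critic_lr),
              actor_lr = as.numeric(actor_lr),
              batch_size = as.integer(batch_size),
              buffer_capacity = as.integer(buffer_capacity),
              n_inner = as.integer(n_inner), hidden = as.integer(hidden),
              weight_decay = as.numeric(weight_decay),
              init_obs_batch = as.integer(init_obs_batch),
              probe_steps = as.integer(probe_steps),
              select_best = isTRUE(select_best),
              f_divergence = "x^2/2", seed = as.integer(seed))
  class(cfg) <- "train_config"
  if (cfg$gamma <= 0 || cfg$gamma >= 1)
    stop("invalid config: field 'gamma' must lie in (0, 1)", call. = FALSE)
  if (cfg$h < 1) stop("invalid config: field 'h' must be >= 1", call. = FALSE)
  if (cfg$n_iterations < 0)
    stop("invalid config: field 'n_iterations' must be >= 0", call. = FALSE)
  if (length(cfg$hidden) != 2)
    stop("invalid config: field 'hidden' must give two layer widths",
         call. = FALSE)
  cfg
}

env_keys <- function() names(formals(env_config))
train_keys <- function() setdiff(names(formals(train_config)), "f_divergence")

#' Load a configuration file
#'
#' Reads a YAML document with optional `env:` and `train:` sections (flat
#' dotted keys such as `env.N` are also accepted).  Unspecified keys take the
#' package defaults; every field is validated.
#'
#' @param path Path to a YAML file.  An empty file yields the full defaults.
#' @return `list(env = <env_config>, train = <train_config>)`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  env_args <- list()
  train_args <- list()
  # YAML 1.1 parses a bare key `N` as boolean false; map it back
  fix_key <- function(k) if (identical(k, "FALSE")) "N" else k
  put <- function(section, key, value) {
    key <- fix_key(key)
    if (section == "env") {
      if (!(key %in% env_keys()))
        stop(sprintf("unknown config key 'env.%s'; valid keys: %s", key,
                     paste(env_keys(), collapse = ", ")), call. = FALSE)
      env_args[[key]] <<- value
    } else if (section == "train") {
      if (!(key %in% train_keys()))
        stop(sprintf("unknown config key 'train.%s'; valid keys: %s", key,
                     paste(train_keys(), collapse = ", ")), call. = FALSE)
      train_args[[key]] <<- value
    } else {
      stop(sprintf("unknown config section '%s'; valid sections: env, train",
                   section), call. = FALSE)
    }
  }
  for (nm0 in names(raw)) {
    nm <- fix_key(nm0)
    raw[[nm]] <- raw[[nm0]]
    if (is.list(raw[[nm]])) {
      for (k in names(raw[[nm]])) put(nm, k, raw[[nm]][[k]])
    } else if (grepl(".", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      put(parts[1], paste(parts[-1], collapse = "."), raw[[nm]])
    } else if (nm %in% env_keys()) {
      put("env", nm, raw[[nm]])
    } else if (nm %in% train_keys()) {
      put("train", nm, raw[[nm]])
    } else {
      stop(sprintf("unknown config key '%s'; valid keys: %s", nm,
                   paste(c(env_keys(), train_keys()), collapse = ", ")),
           call. = FALSE)
    }
  }
  list(env = do.call(env_config, env_args),
       train = do.call(train_config, train_args))
}

#' Save a configuration to YAML
#'
#' @param config A `list(env = , train = )` pair as returned by
#'   [load_config()], or a single `env_config`.
#' @param path Output file path.
#' @export
save_config <- function(config, path) {
  if (inherits(config, "env_config")) config <- list(env = config)
  out <- list()
  if (!is.null(config$env)) {
    e <- unclass(config$env)
    e$TX_age <- if (is.null(e$TX_age)) NULL else e$TX_age
    out$env <- e
  }
  if (!is.null(config$train)) {
    tr <- unclass(config$train)
    tr$f_divergence <- NULL
    out$train <- tr
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Derive named seed streams from one master seed
#'
#' Each pipeline stage (placement, policy initialization, rollout, training)
#' draws from its own stream so that changing one stage's randomness does not
#' perturb the others.
#'
#' @param seed Master seed (integer).
#' @return Named list of integer seeds.
#' @export
seed_streams <- function(seed) {
  seed <- as.integer(seed)
  base <- (abs(seed) %% 1000003L)
  list(placement = (base * 7L + 11L) %% 2147483629L,
       policy_init = (base * 13L + 29L) %% 2147483629L,
       rollout = (base * 31L + 47L) %% 2147483629L,
       training = (base * 61L + 83L) %% 2147483629L)
}
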