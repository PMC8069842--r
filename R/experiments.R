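#' Run one evaluation episode
#'
#' Deterministic-given-seed rollout under a policy schedule: steps with
#' `t < switch_t` use uniform-random actions for both species, later steps
#' use the supplied trained policies.  Use `switch_t = 0` for trained-only
#' runs and `switch_t = Inf` for the random baseline.
#'
#' @param policies `list(predator = , prey = )` of `pp_policy` objects (may
#'   be `NULL` when the schedule never reaches the trained phase).
#' @param env_cfg An [env_config()].
#' @param seed Integer seed (placement and rollout).
#' @param switch_t First step at which trained policies act.
#' @param snapshot_ts Steps at which to store agent-location snapshots
#'   (0 stores the initial state).
#' @return List with `series` (data frame: t, populations, per-step event
#'   counts; the first row is the initial state), `snapshots` (named by t;
#'   each has `agents` and `N`), termination `reason`, and the final
#'   `state`.
#' @export
run_episode <- function(policies, env_cfg, seed, switch_t = 0,
                        snapshot_ts = integer(0)) {
  validate_env_config(env_cfg)
  if (!is.finite(switch_t)) switch_t <- .Machine$integer.max
  needs_trained <- switch_t < env_cfg$max_steps
  np <- ny <- NULL
  if (needs_trained) {
    if (is.null(policies$predator) || is.null(policies$prey))
      stop("missing checkpoint: trained policies required for the schedule",
           call. = FALSE)
    np <- policies$predator$net
    ny <- policies$prey$net
  }
  state <- init_env(env_cfg, seed = seed)
  first <- data.frame(t = 0, n_predator = env_cfg$nX, n_prey = env_cfg$nY,
                      captures_pred_action = 0, captures_prey_action = 0,
                      births_pred = 0, births_prey = 0, deaths_starvation = 0,
                      deaths_age = 0, deaths_age_pred = 0)
  out <- cpp_run_episode(state, np, ny, as.integer(switch_t),
                         as.integer(snapshot_ts))
  series <- rbind(first, as.data.frame(out$series))
  snaps <- lapply(out$snapshots, function(s) list(agents = s, N = env_cfg$N))
  list(series = series, snapshots = snaps, reason = out$reason,
       state = structure(out$state, class = "grid_state"))
}

#' Phase-plane trajectory of a population series
#'
#' Re-indexes a series as ordered (n_predator, n_prey) pairs, labels the
#' random and trained segments, and reports per-segment centroids, maximum
#' excursion radii, and whether the trained-segment centroid dominates the
#' random-segment centroid componentwise (both populations larger).
#'
#' @param series The `series` data frame of [run_episode()].
#' @param switch_t Step at which the schedule switched (0 = all trained).
#' @return List of class `phase_trajectory`: `points` data frame with
#'   segment labels, `centroids`, `radii`, and `trained_dominates`.
#' @export
phase_trajectory <- function(series, switch_t = 0) {
  if (nrow(series) == 0) stop("empty series", call. = FALSE)
  if (switch_t > max(series$t) && switch_t != 0)
    stop("switch_t outside the series", call. = FALSE)
  seg <- ifelse(series$t < switch_t, "random", "trained")
  pts <- data.frame(t = series$t, n_predator = series$n_predator,
                    n_prey = series$n_prey, segment = seg,
                    stringsAsFactors = FALSE)
  cent <- lapply(split(pts, pts$segment), function(d)
    c(n_predator = mean(d$n_predator), n_prey = mean(d$n_prey)))
  radii <- mapply(function(d, ct) {
    max(sqrt((d$n_predator - ct["n_predator"])^2 +
             (d$n_prey - ct["n_prey"])^2))
  }, split(pts, pts$segment), cent[names(split(pts, pts$segment))])
  dominates <- NA
  if (all(c("random", "trained") %in% names(cent)))
    dominates <- all(cent$trained > cent$random)
  structure(list(points = pts, centroids = cent, radii = radii,
                 trained_dominates = dominates), class = "phase_trajectory")
}

#' Signed enclosed area of a closed phase loop (shoelace formula)
#'
#' @param x,y Coordinates of the loop vertices in order.
#' @return Signed area.
#' @export
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

toroidal_nn_dist <- function(row, col, N) {
  n <- length(row)
  dr <- abs(outer(row, row, `-`)); dr <- pmin(dr, N - dr)
  dc <- abs(outer(col, col, `-`)); dc <- pmin(dc, N - dc)
  d <- sqrt(dr^2 + dc^2)
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Clark-Evans aggregation index on the torus
#'
#' `R = mean nearest-neighbor distance / (0.5 / sqrt(density))`, with
#' toroidal (wrapped) Euclidean distances and density `n / N^2`.  Values
#' near 1 indicate complete spatial randomness; values below 1 indicate
#' clustering (swarming).
#'
#' @param snapshot A snapshot from [run_episode()] (`list(agents, N)`) or a
#'   grid state.
#' @param species `"predator"` or `"prey"`.
#' @return List of class `swarm_stat`: `R`, `mean_nn`, `expected_nn`, `n`,
#'   `species`.
#' @export
swarming_index <- function(snapshot, species) {
  species <- match.arg(species, SPECIES_LEVELS)
  N <- if (!is.null(snapshot$N)) snapshot$N else snapshot$config$N
  ag <- snapshot$agents
  sel <- ag$species == species_code(species)
  n <- sum(sel)
  if (n < 2)
    stop("undefined statistic: fewer than 2 agents of species ", species,
         call. = FALSE)
  nn <- toroidal_nn_dist(ag$row[sel], ag$col[sel], N)
  expected <- 0.5 / sqrt(n / N^2)
  structure(list(R = mean(nn) / expected, mean_nn = mean(nn),
                 expected_nn = expected, n = n, species = species),
            class = "swarm_stat")
}

#' Monte-Carlo reference of the Clark-Evans index under random placement
#'
#' Places `n` agents uniformly on distinct cells of the N x N torus and
#' computes the index, repeatedly; used as the complete-spatial-randomness
#' envelope that discretization onto the lattice implies.
#'
#' @param n Number of agents.
#' @param N Grid side.
#' @param reps Replicates.
#' @return Numeric vector of `reps` index values.
#' @export
clark_evans_csr <- function(n, N, reps = 100) {
  vapply(seq_len(reps), function(i) {
    cells <- sample.int(N * N, n) - 1L
    snap <- list(agents = list(species = rep(2L, n), row = cells %/% N,
                               col = cells %% N), N = N)
    swarming_index(snap, "prey")$R
  }, numeric(1))
}

#' Summary statistics of a population series
#'
#' Post-burn-in means, standard deviations and coefficients of variation
#' per species, the prey-over-predator dominance gap, an extinction flag,
#' and the dominant oscillation period, estimated as the lag of the first
#' local autocorrelation peak above 0.2.
#'
#' @param series The `series` data frame of [run_episode()].
#' @param burn_in Steps discarded before computing the statistics.
#' @return List of class `series_summary`.
#' @export
summarize_series <- function(series, burn_in = 500) {
  if (burn_in >= max(series$t))
    stop("burn_in must be smaller than the series length", call. = FALSE)
  post <- series[series$t >= burn_in, ]
  msd <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    c(mean = m, sd = s, cv = if (m > 0) s / m else NA_real_)
  }
  pred <- msd(post$n_predator)
  prey <- msd(post$n_prey)
  extinct <- min(post$n_predator) == 0 || min(post$n_prey) == 0
  structure(list(
    predator = pred, prey = prey,
    dominance_gap = mean(post$n_prey - post$n_predator),
    extinct = extinct,
    period = oscillation_period(post$n_prey),
    n_steps = nrow(post)), class = "series_summary")
}

# first local acf peak above threshold; NA when none (e.g. constant series)
oscillation_period <- function(x, threshold = 0.2) {
  if (stats::sd(x) == 0) return(NA_real_)
  max_lag <- min(length(x) - 1, floor(length(x) / 2))
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  n <- length(a)
  if (n < 3) return(NA_real_)
  peaks <- which(a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n]) + 1
  peaks <- peaks[a[peaks] > threshold]
  if (!length(peaks)) return(NA_real_)
  as.numeric(peaks[1])
}

#' Robustness sweep of trained policies
#'
#' Re-runs evaluation episodes with the unchanged trained policies under
#' configuration variants (rescaled initial counts, different grid sides,
#' predator maximum-age settings) and reports, per variant and seed,
#' whether both species survived to the episode cap plus post-burn-in
#' population statistics.
#'
#' @param trained `list(predator = , prey = )` trained policies.
#' @param base_cfg The nominal [env_config()].
#' @param variants Named list; each element is a named list of config
#'   overrides (e.g. `list(N = 40)` or `list(nX = 120, nY = 600)`).
#' @param seeds Integer vector of evaluation seeds.
#' @param burn_in Burn-in passed to [summarize_series()].
#' @return Data frame with one row per variant x seed.
#' @export
robustness_suite <- function(trained, base_cfg, variants, seeds,
                             burn_in = 500) {
  rows <- list()
  for (vn in names(variants)) {
    args <- unclass(base_cfg)
    for (k in names(variants[[vn]])) args[[k]] <- variants[[vn]][[k]]
    cfg <- do.call(env_config, args)
    for (sd in seeds) {
      ep <- run_episode(trained, cfg, seed = sd, switch_t = 0)
      surv <- ep$reason == "max_steps"
      sm <- summarize_series(ep$series, burn_in = min(burn_in, max(ep$series$t) - 1))
      rows[[length(rows) + 1]] <- data.frame(
        variant = vn, seed = sd, survived = surv,
        steps = max(ep$series$t),
        mean_n_predator = sm$predator[["mean"]],
        mean_n_prey = sm$prey[["mean"]],
        cv_predator = sm$predator[["cv"]], cv_prey = sm$prey[["cv"]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
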