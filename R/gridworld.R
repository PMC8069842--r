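#' @useDynLib ppcoevo, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

SPECIES_LEVELS <- c("predator", "prey")

species_code <- function(species) {
  i <- match(species, SPECIES_LEVELS)
  if (any(is.na(i))) stop("species must be 'predator' or 'prey'", call. = FALSE)
  as.integer(i)
}

#' Initialize the lattice ecosystem
#'
#' Places `nX` predators and `nY` prey uniformly at random on distinct cells
#' of the N x N torus.  Starvation and age clocks start at 0 and the step
#' counter at `t = 0`.
#'
#' @param config An [env_config()].
#' @param seed Optional integer seed for the placement draw.
#' @return A grid-state list with elements `config`, `t`, `next_id`,
#'   `agents` (parallel vectors `id`, `species` (1 = predator, 2 = prey),
#'   `row`, `col`, `starvation`, `age`; 0-based coordinates) and `occ`
#'   (N x N occupancy matrix of agent ids, 0 = empty).
#' @export
init_env <- function(config, seed = NULL) {
  validate_env_config(config)
  if (!is.null(seed)) set.seed(seed)
  st <- cpp_init_env(config)
  class(st) <- "grid_state"
  st
}

#' Destination cell of an action under torus arithmetic
#'
#' Action encoding: 0 up-left, 1 up, 2 up-right, 3 left, 4 remain, 5 right,
#' 6 down-left, 7 down, 8 down-right ("up" decreases the row index).
#'
#' @param pos Length-2 integer vector `(row, col)`, 0-based.
#' @param action Integer in 0..8.
#' @param N Grid side length.
#' @return `(row, col)` of the destination cell.
#' @export
neighbor_cell <- function(pos, action, N) {
  if (length(action) != 1 || is.na(action) || action < 0 || action > 8)
    stop("invalid action (must be 0..8)", call. = FALSE)
  action <- as.integer(action)
  dr <- action %/% 3L - 1L
  dc <- action %% 3L - 1L
  c(((pos[1] + dr) %% N + N) %% N, ((pos[2] + dc) %% N + N) %% N)
}

find_agent <- function(state, agent_id) {
  i <- match(agent_id, state$agents$id)
  if (is.na(i))
    stop("stale agent: no living agent with id ", agent_id, call. = FALSE)
  i
}

#' Apply a single predator action
#'
#' Moving onto an empty cell relocates the predator.  Moving onto a prey
#' captures it (reward +1), resets the predator's starvation clock, and with
#' probability `bX` leaves a newborn predator in the vacated origin cell.
#' Moving onto another predator is blocked.
#'
#' @param state A grid state.
#' @param agent_id Id of a living predator.
#' @param action Integer 0..8.
#' @return `list(state, reward, events, ate_ids)` where `ate_ids` are the
#'   predators whose starvation was reset by eating during this call.
#' @export
apply_predator_action <- function(state, agent_id, action) {
  i <- find_agent(state, agent_id)
  if (state$agents$species[i] != 1L)
    stop("agent ", agent_id, " is not a predator", call. = FALSE)
  out <- cpp_apply_action(state, as.integer(agent_id), as.integer(action))
  class(out$state) <- "grid_state"
  out
}

#' Apply a single prey action
#'
#' Moving onto an empty cell relocates the prey and with probability `bY`
#' leaves a newborn prey in the vacated origin cell.  Moving onto a predator
#' gets the prey eaten (reward -1; the stationary predator's starvation is
#' reset but it does not reproduce).  Moving onto another prey is blocked.
#'
#' @inheritParams apply_predator_action
#' @param agent_id Id of a living prey.
#' @return `list(state, reward, events, ate_ids, died)`.
#' @export
apply_prey_action <- function(state, agent_id, action) {
  i <- find_agent(state, agent_id)
  if (state$agents$species[i] != 2L)
    stop("agent ", agent_id, " is not a prey", call. = FALSE)
  out <- cpp_apply_action(state, as.integer(agent_id), as.integer(action))
  class(out$state) <- "grid_state"
  out
}

#' Advance starvation and age clocks
#'
#' Predators that did not eat this step gain one starvation unit and are
#' removed on reaching `TX`; every living prey ages one step and is removed
#' on reaching `TY`.  Predator aging applies only when `TX_age` is enabled.
#' Call exactly once per environment step, after all agents have acted.
#'
#' @param state A grid state.
#' @param ate_ids Integer ids of predators that ate during this step (their
#'   starvation clock is not incremented).
#' @return `list(state, events)`.
#' @export
advance_clocks <- function(state, ate_ids = integer(0)) {
  out <- cpp_advance_clocks(state, as.integer(ate_ids))
  class(out$state) <- "grid_state"
  out
}

#' Egocentric observation window
#'
#' The r x r x 2 window of species indicators centered on the observing
#' agent (channel 1: predators, channel 2: prey), wrapping around the torus
#' unless `obs_padding` is set in the configuration.  The center cell reports
#' the observer itself in its own species channel.
#'
#' @param state A grid state.
#' @param agent_id Id of a living agent.
#' @return An object of class `observation`: list with `window` (r x r x 2
#'   array), `vector` (the flat encoding fed to policies: row-major cells,
#'   predator channel first), and `species_of_observer`.
#' @export
observe <- function(state, agent_id) {
  i <- find_agent(state, agent_id)
  v <- cpp_observe(state, as.integer(agent_id))
  r <- state$config$r
  D <- r * r
  win <- array(0, dim = c(r, r, 2))
  for (ch in 1:2)
    win[, , ch] <- matrix(v[(ch - 1) * D + seq_len(D)], nrow = r, byrow = TRUE)
  structure(list(window = win, vector = v,
                 species_of_observer = SPECIES_LEVELS[state$agents$species[i]]),
            class = "observation")
}

#' Flatten an observation window to the policy input encoding
#'
#' Row-major cell order within each channel, predator channel first.
#'
#' @param window An r x r x 2 array (or an `observation` object).
#' @return Numeric vector of length `2 * r^2`.
#' @export
obs_flatten <- function(window) {
  if (inherits(window, "observation")) return(window$vector)
  c(as.vector(t(window[, , 1])), as.vector(t(window[, , 2])))
}

#' Full-grid tensor view
#'
#' The H x W x C occupancy-indicator representation of the global state,
#' with C = 2 species channels.
#'
#' @param state A grid state.
#' @return An N x N x 2 array of 0/1 indicators.
#' @export
state_tensor <- function(state) {
  N <- state$config$N
  arr <- array(0, dim = c(N, N, 2))
  ag <- state$agents
  if (length(ag$id))
    arr[cbind(ag$row + 1L, ag$col + 1L, ag$species)] <- 1
  arr
}

#' One environment step with sequential agent updates
#'
#' Draws a single uniformly random permutation over all living agents; each
#' agent in turn observes, samples an action from its species policy (or
#' uniformly at random when the policy is `NULL`), and the action is applied
#' immediately.  Clocks are then advanced and `t` incremented.
#'
#' @param state A grid state.
#' @param policy_pred,policy_prey [policy_init()] objects, or `NULL` for
#'   uniform-random behavior.
#' @param collect If `TRUE`, per-agent transition records for this step are
#'   returned (`next_obs` is the end-of-step observation; agents removed
#'   mid-step get `done = 1` and a zero next observation).
#' @return `list(state, events, n_predator, n_prey[, records])`.
#' @export
env_step <- function(state, policy_pred = NULL, policy_prey = NULL,
                     collect = TRUE) {
  np <- if (is.null(policy_pred)) NULL else policy_pred$net
  ny <- if (is.null(policy_prey)) NULL else policy_prey$net
  out <- cpp_env_step(state, np, ny, is.null(policy_pred),
                      is.null(policy_prey), collect)
  class(out$state) <- "grid_state"
  out
}

#' Episode termination test
#'
#' An episode ends when one species is extinct or when the step counter
#' reaches the episode cap.
#'
#' @param state A grid state.
#' @return `list(terminal = logical, reason = "extinction" | "max_steps" |
#'   NA)`.
#' @export
is_terminal <- function(state) {
  n_pred <- sum(state$agents$species == 1L)
  n_prey <- sum(state$agents$species == 2L)
  if (n_pred == 0L || n_prey == 0L)
    return(list(terminal = TRUE, reason = "extinction"))
  if (state$t >= state$config$max_steps)
    return(list(terminal = TRUE, reason = "max_steps"))
  list(terminal = FALSE, reason = NA_character_)
}

#' Living agents as a data frame
#'
#' @param state A grid state (or a snapshot's `agents` element).
#' @return data.frame with columns id, species, row, col, starvation, age.
#' @export
agents_df <- function(state) {
  ag <- if (!is.null(state$agents)) state$agents else state
  data.frame(id = ag$id, species = SPECIES_LEVELS[ag$species], row = ag$row,
             col = ag$col, starvation = ag$starvation, age = ag$age,
             stringsAsFactors = FALSE)
}

#' @export
print.grid_state <- function(x, ...) {
  n_pred <- sum(x$agents$species == 1L)
  n_prey <- sum(x$agents$species == 2L)
  cat(sprintf("<grid_state> %dx%d torus, t = %d, %d predators, %d prey\n",
              x$config$N, x$config$N, x$t, n_pred, n_prey))
  invisible(x)
}
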