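#' Initialize a species policy
#'
#' A stochastic policy over the nine movement actions, shared by every agent
#' of one species.  The network is a two-hidden-layer multilayer perceptron
#' (tanh activations) mapping the flattened r x r x 2 observation to action
#' logits; the final layer is initialized to zero so that the initial policy
#' is exactly uniform over the nine actions, making the random-policy
#' baseline a special case of the same machinery.
#'
#' @param species `"predator"` or `"prey"`.
#' @param r Observation window side (must match the environment).
#' @param hidden Two hidden-layer widths.
#' @param seed Optional seed for the weight initialization.
#' @return An object of class `pp_policy`.
#' @export
policy_init <- function(species, r = 5L, hidden = c(64L, 64L), seed = NULL) {
  species <- match.arg(species, SPECIES_LEVELS)
  if (!is.null(seed)) set.seed(seed)
  d_in <- as.integer(2L * r * r)
  net <- mlp_init(d_in, hidden, 9L, last_zero = TRUE)
  structure(list(species = species, net = net, r = as.integer(r),
                 hidden = as.integer(hidden), input_dim = d_in,
                 n_actions = 9L, iteration = 0L,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "pp_policy")
}

as_obs_vector <- function(obs) {
  if (inherits(obs, "observation")) return(obs$vector)
  if (is.array(obs) && length(dim(obs)) == 3) return(obs_flatten(obs))
  as.numeric(obs)
}

#' Action distribution of a policy at an observation
#'
#' Deterministic forward pass: returns the probability vector and logits
#' over the nine actions.
#'
#' @param params A `pp_policy`.
#' @param obs An `observation`, an r x r x 2 array, or a flat numeric vector.
#' @return An object of class `action_distribution` with fields
#'   `probabilities` and `logits` (length 9 each).
#' @export
policy_forward <- function(params, obs) {
  if (inherits(obs, "observation") &&
      !identical(obs$species_of_observer, params$species))
    stop("observation species does not match the policy species",
         call. = FALSE)
  v <- as_obs_vector(obs)
  if (length(v) != params$input_dim)
    stop(sprintf("observation length %d does not match policy input size %d",
                 length(v), params$input_dim), call. = FALSE)
  out <- cpp_policy_forward(params$net, v)
  structure(list(probabilities = out$probabilities, logits = out$logits),
            class = "action_distribution")
}

#' Sample an action from an action distribution
#'
#' Inverse-CDF draw on R's RNG stream (identical to the draw performed
#' inside the compiled rollout loop), so seeded runs are reproducible across
#' the R and C++ entry points.
#'
#' @param dist An `action_distribution` (or a bare probability vector).
#' @return An integer action in 0..8.
#' @export
sample_action <- function(dist) {
  p <- if (inherits(dist, "action_distribution")) dist$probabilities else dist
  stopifnot(length(p) == 9, all(p >= 0))
  p <- p / sum(p)
  u <- stats::runif(1)
  as.integer(which(u < cumsum(p))[1] - 1L)
}

#' Shannon entropy of an action distribution
#'
#' In nats; bounded by `log(9)` for the nine-action space.
#'
#' @param dist An `action_distribution` (or a bare probability vector).
#' @return Non-negative scalar.
#' @export
policy_entropy <- function(dist) {
  p <- if (inherits(dist, "action_distribution")) dist$probabilities else dist
  p <- p / sum(p)
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Save a policy checkpoint
#'
#' JSON container recording species, architecture, the flat parameter
#' vector at full precision, training iteration and seed.  Round-trip
#' loading reproduces bit-identical action distributions.
#'
#' @param policy A `pp_policy`.
#' @param path Output path (`.json`).
#' @export
save_checkpoint <- function(policy, path) {
  rec <- list(format = "ppcoevo-policy-v1", species = policy$species,
              r = policy$r, hidden = policy$hidden,
              input_dim = policy$input_dim, n_actions = policy$n_actions,
              iteration = policy$iteration, seed = policy$seed,
              # 17 significant digits keep the round trip bit-exact
              weights = sprintf("%.17g", flatten_params(policy$net)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a policy checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A `pp_policy`.
#' @export
load_checkpoint <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(rec$format, "ppcoevo-policy-v1"))
    stop("not a ppcoevo policy checkpoint: ", path, call. = FALSE)
  pol <- policy_init(rec$species, r = rec$r, hidden = rec$hidden)
  pol$net <- unflatten_params(pol$net, as.numeric(rec$weights))
  pol$iteration <- as.integer(rec$iteration)
  pol$seed <- if (is.null(rec$seed)) NA_integer_
              else suppressWarnings(as.integer(rec$seed))
  pol
}

#' @export
print.pp_policy <- function(x, ...) {
  cat(sprintf("<pp_policy> %s, MLP %d-%d-%d-9, iteration %d\n", x$species,
              x$input_dim, x$hidden[1], x$hidden[2], x$iteration))
  invisible(x)
}
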