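test_that("initial placement puts the right counts on distinct cells with zero clocks", {
  st <- init_env(env_config(), seed = 1)
  expect_equal(n_of(st, "predator"), 100)
  expect_equal(n_of(st, "prey"), 500)
  expect_equal(anyDuplicated(st$agents$row * 50 + st$agents$col), 0)
  expect_true(all(st$agents$starvation == 0))
  expect_true(all(st$agents$age == 0))
  expect_equal(st$t, 0)

  st0 <- init_env(tiny_cfg(nX = 0, nY = 0), seed = 1)
  expect_equal(length(st0$agents$id), 0)
  expect_error(init_env(env_config(N = 3, r = 3, nX = 9, nY = 1)), "cells")
})

test_that("placement is uniform over cells (chi-squared over many draws)", {
  counts <- numeric(16)
  for (s in 1:400) {
    st <- init_env(env_config(N = 4, r = 3, nX = 2, nY = 2, max_steps = 10),
                   seed = 5000 + s)
    cells <- st$agents$row * 4 + st$agents$col + 1
    counts[cells] <- counts[cells] + 1
  }
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-4)
})

test_that("neighbor_cell follows the nine-action encoding with periodic wrap", {
  expect_equal(neighbor_cell(c(0, 0), 0, 50), c(49, 49))
  expect_equal(neighbor_cell(c(5, 5), 4, 50), c(5, 5))
  expect_equal(neighbor_cell(c(5, 5), 5, 50), c(5, 6))
  expect_equal(neighbor_cell(c(5, 5), 1, 50), c(4, 5))
  expect_equal(neighbor_cell(c(49, 49), 8, 50), c(0, 0))
  expect_error(neighbor_cell(c(0, 0), 9, 50), "action")
  expect_error(neighbor_cell(c(0, 0), -1, 50), "action")
  # torus closure: N steps right return to the start
  pos <- c(3, 7)
  for (k in 1:11) pos <- neighbor_cell(pos, 5, 11)
  expect_equal(pos, c(3, 7))
})

test_that("predator move-and-eat captures, reproduces by bX, and blocks on predators", {
  cfg <- tiny_cfg(bX = 1)  # reproduction certain
  st <- make_state(cfg, id = 1:2, species = c("predator", "prey"),
                   row = c(2, 2), col = c(2, 3))
  out <- apply_predator_action(st, 1L, 5L)
  expect_equal(out$reward, 1)
  expect_equal(out$events$captures_by_predator_action, 1)
  expect_equal(out$events$predator_births, 1)
  expect_equal(n_of(out$state, "prey"), 0)
  expect_equal(n_of(out$state, "predator"), 2)  # mover + newborn in origin
  ag <- agents_df(out$state)
  expect_true(any(ag$row == 2 & ag$col == 3))   # moved onto the prey cell
  expect_true(any(ag$row == 2 & ag$col == 2))   # offspring in vacated cell
  expect_equal(out$ate_ids, 1L)

  cfg0 <- tiny_cfg(bX = 0)  # reproduction never succeeds
  st <- make_state(cfg0, id = 1:2, species = c("predator", "prey"),
                   row = c(2, 2), col = c(2, 3))
  out <- apply_predator_action(st, 1L, 5L)
  expect_equal(out$reward, 1)
  expect_equal(out$events$predator_births, 0)
  expect_equal(n_of(out$state, "predator"), 1)

  # blocked by another predator: nothing changes, reward 0
  st <- make_state(cfg, id = 1:2, species = c("predator", "predator"),
                   row = c(2, 2), col = c(2, 3))
  out <- apply_predator_action(st, 1L, 5L)
  expect_equal(out$reward, 0)
  expect_equal(agents_df(out$state)$col, c(2, 3))

  # lone predator remaining in place: no interaction
  st <- make_state(cfg, id = 1L, species = "predator", row = 2, col = 2)
  out <- apply_predator_action(st, 1L, 4L)
  expect_equal(out$reward, 0)
  expect_equal(agents_df(out$state)$col, 2)

  expect_error(apply_predator_action(st, 99L, 4L), "stale")
})

test_that("prey moves reproduce by bY, walking onto a predator is fatal, prey block prey", {
  cfg1 <- tiny_cfg(bY = 1)
  st <- make_state(cfg1, id = 1L, species = "prey", row = 1, col = 1)
  out <- apply_prey_action(st, 1L, 5L)
  expect_equal(out$reward, 0)
  expect_equal(out$events$prey_births, 1)
  expect_equal(n_of(out$state, "prey"), 2)
  ag <- agents_df(out$state)
  expect_setequal(ag$col, c(1, 2))

  # walking onto a predator: eaten, reward -1, no predator reproduction,
  # predator starvation reset
  cfg <- tiny_cfg(bX = 1)
  st <- make_state(cfg, id = 1:2, species = c("prey", "predator"),
                   row = c(1, 1), col = c(1, 2), starvation = c(0L, 7L))
  out <- apply_prey_action(st, 1L, 5L)
  expect_equal(out$reward, -1)
  expect_equal(out$events$captures_by_prey_action, 1)
  expect_equal(out$events$predator_births, 0)
  expect_true(out$died)
  expect_equal(n_of(out$state, "prey"), 0)
  ag <- agents_df(out$state)
  expect_equal(ag$starvation, 0)     # reset by eating
  expect_equal(out$ate_ids, 2L)

  # blocked by another prey
  st <- make_state(cfg, id = 1:2, species = c("prey", "prey"),
                   row = c(1, 1), col = c(1, 2))
  out <- apply_prey_action(st, 1L, 5L)
  expect_equal(out$reward, 0)
  expect_equal(agents_df(out$state)$col, c(1, 2))
})

test_that("clocks: starvation removal at TX, age removal at TY, eating interrupts starvation", {
  cfg <- tiny_cfg()
  st <- make_state(cfg, id = 1L, species = "predator", row = 1, col = 1,
                   starvation = 14L)
  out <- advance_clocks(st)
  expect_equal(n_of(out$state, "predator"), 0)
  expect_equal(out$events$starvation_deaths, 1)

  st <- make_state(cfg, id = 1L, species = "prey", row = 1, col = 1,
                   age = 29L)
  out <- advance_clocks(st)
  expect_equal(n_of(out$state, "prey"), 0)
  expect_equal(out$events$age_deaths, 1)

  # a predator that ate this step does not starve further
  st <- make_state(cfg, id = 1L, species = "predator", row = 1, col = 1,
                   starvation = 14L)
  out <- advance_clocks(st, ate_ids = 1L)
  expect_equal(n_of(out$state, "predator"), 1)

  # predator aging only when TX_age is enabled
  cfga <- tiny_cfg(TX_age = 5L)
  st <- make_state(cfga, id = 1L, species = "predator", row = 1, col = 1,
                   age = 4L)
  out <- advance_clocks(st, ate_ids = 1L)
  expect_equal(out$events$predator_age_deaths, 1)
})

test_that("a solitary predator is removed after exactly TX steps, a lone prey after TY", {
  s <- init_env(tiny_cfg(nX = 1, nY = 0), seed = 1)
  steps <- 0
  while (n_of(s, "predator") > 0) {
    s <- env_step(s, collect = FALSE)$state
    steps <- steps + 1
    expect_lt(steps, 50)
  }
  expect_equal(steps, 15)

  s <- init_env(tiny_cfg(nX = 0, nY = 1, bY = 0), seed = 1)
  steps <- 0
  while (n_of(s, "prey") > 0) {
    s <- env_step(s, collect = FALSE)$state
    steps <- steps + 1
    expect_lt(steps, 80)
  }
  expect_equal(steps, 30)
})

test_that("observations: shape, self at center, wrap across the corner", {
  cfg <- tiny_cfg(N = 8L, r = 3L, nX = 1L, nY = 1L)
  st <- make_state(cfg, id = 1:2, species = c("predator", "prey"),
                   row = c(0, 7), col = c(0, 7))
  o <- observe(st, 1L)
  expect_equal(dim(o$window), c(3, 3, 2))
  expect_equal(o$species_of_observer, "predator")
  expect_equal(o$window[2, 2, 1], 1)  # self in predator channel
  expect_equal(o$window[2, 2, 2], 0)
  # neighbor at (7,7) is up-left of (0,0) via wrap -> window (1,1) prey channel
  expect_equal(o$window[1, 1, 2], 1)
  expect_equal(sum(o$window), 2)
  # flat encoding round-trips
  expect_equal(obs_flatten(o$window), o$vector)

  # independent modular-index enumeration oracle for the full window
  r <- 3L; half <- 1L; N <- 8L
  expected <- array(0, c(r, r, 2))
  occupants <- list(c(0, 0, 1), c(7, 7, 2))
  for (dr in -half:half) for (dc in -half:half) {
    rr <- (0 + dr) %% N; cc <- (0 + dc) %% N
    for (oc in occupants)
      if (oc[1] == rr && oc[2] == cc)
        expected[dr + half + 1, dc + half + 1, oc[3]] <- 1
  }
  expect_equal(o$window, expected)

  # lone agent on an empty grid: only its own channel at center
  st1 <- make_state(tiny_cfg(nX = 1, nY = 0), id = 1L, species = "predator",
                    row = 4, col = 4)
  o1 <- observe(st1, 1L)
  expect_equal(sum(o1$window), 1)
  expect_equal(o1$window[3, 3, 1], 1)
  expect_error(observe(st1, 42L), "stale")
})

test_that("observation padding toggle blanks out-of-grid cells instead of wrapping", {
  cfg <- tiny_cfg(N = 8L, r = 3L, nX = 1L, nY = 1L, obs_padding = TRUE)
  st <- make_state(cfg, id = 1:2, species = c("predator", "prey"),
                   row = c(0, 7), col = c(0, 7))
  o <- observe(st, 1L)
  expect_equal(sum(o$window), 1)  # the wrapped neighbor is not visible
  expect_equal(o$window[2, 2, 1], 1)
})

test_that("the grid tensor view is consistent with the agent table", {
  st <- init_env(tiny_cfg(), seed = 3)
  tv <- state_tensor(st)
  expect_equal(dim(tv), c(10, 10, 2))
  expect_equal(sum(tv), length(st$agents$id))
  # at most one nonzero channel per cell
  expect_true(all(tv[, , 1] + tv[, , 2] <= 1))
  ag <- agents_df(st)
  for (i in seq_len(nrow(ag)))
    expect_equal(tv[ag$row[i] + 1, ag$col[i] + 1,
                    if (ag$species[i] == "predator") 1 else 2], 1)
})

test_that("termination: extinction, step cap, neither", {
  cfg <- tiny_cfg()
  st <- make_state(cfg, id = 1:2, species = c("prey", "prey"),
                   row = c(1, 2), col = c(1, 2))
  expect_equal(is_terminal(st)$reason, "extinction")
  st <- make_state(cfg, id = 1:2, species = c("predator", "prey"),
                   row = c(1, 2), col = c(1, 2))
  st$t <- 200L
  expect_equal(is_terminal(st)$reason, "max_steps")
  st$t <- 5L
  expect_false(is_terminal(st)$terminal)
})

test_that("empty grid steps forward with no transitions", {
  s <- init_env(tiny_cfg(nX = 0, nY = 0), seed = 1)
  out <- env_step(s)
  expect_equal(out$state$t, 1)
  expect_equal(length(out$records$id), 0)
})

test_that("seeded determinism: identical seed and policies give identical trajectories", {
  cfg <- tiny_cfg(N = 12L, nX = 5L, nY = 20L)
  run <- function() {
    s <- init_env(cfg, seed = 77)
    traj <- list()
    for (k in 1:30) {
      s <- env_step(s, collect = FALSE)$state
      traj[[k]] <- agents_df(s)
    }
    traj
  }
  expect_identical(run(), run())
})
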