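test_that("em_step implements x + F dt + sqrt(2 D dt) w", {
  land <- landscape_quadratic(c(0, 0), eta = 1)
  cfg <- sim_config(dt = 0.01, D = 0.5)
  # zero drift, zero noise: identity
  expect_equal(em_step(land, c(0, 0), cfg, c(0, 0)), c(0, 0))
  # drift only
  expect_equal(em_step(land, c(1, 0), cfg, c(0, 0)), c(0.99, 0))
  # unit normal draws contribute exactly the per-step sd
  expect_equal(em_step(land, c(0, 0), cfg, c(1, 1)), c(0.1, 0.1))
})

test_that("sim_config validates its fields", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(D = -1), "D")
  expect_error(sim_config(n_steps = 0), "n_steps")
  expect_error(sim_config(escape_radius = 0), "escape_radius")
  expect_error(sim_config(x0 = c(1, 2, 3)), "x0")
})

test_that("trajectories are internally consistent and reproducible", {
  land <- landscape_quadratic(c(0, 0), eta = 1)
  cfg <- sim_config(n_steps = 400L, seed = 7L, x0 = c(1, 0))
  tr <- sde_trajectory(land, cfg)
  expect_equal(length(tr$times), nrow(tr$states))
  expect_true(all(is.finite(tr$states)))
  expect_equal(diff(tr$times), rep(cfg$dt, length(tr$times) - 1L))
  # determinism contract
  expect_identical(tr$states, sde_trajectory(land, cfg)$states)
  # seed isolation
  cfg2 <- sim_config(n_steps = 400L, seed = 8L, x0 = c(1, 0))
  expect_false(identical(tr$states, sde_trajectory(land, cfg2)$states))
})

test_that("noise-free quadratic dynamics contract monotonically to the optimum", {
  land <- landscape_quadratic(c(0, 0), eta = 1)
  cfg <- sim_config(n_steps = 2000L, D = 0, x0 = c(1, 0))
  tr <- sde_trajectory(land, cfg)
  expect_equal(tr$status, "completed")
  d <- sqrt(rowSums(tr$states^2))
  expect_true(all(diff(d) <= 0))
  expect_lt(d[length(d)], 1e-6)
})

test_that("a repulsive cusp ejects noisy trajectories in finite time", {
  land <- landscape_cusp(alpha = 1.5, k = 1, repulsive = TRUE)
  for (s in 1:20) {
    tr <- sde_trajectory(land, sim_config(seed = s, x0 = c(0.1, 0)))
    expect_equal(tr$status, "escaped")
    expect_true(is.finite(tr$t_event))
    expect_equal(tr$t_event, tr$times[length(tr$times)])
  }
})

test_that("deterministic double-well runs respect equilibria and basins", {
  land <- landscape_double_well(a = 1, b = 1, h = 0)
  # well bottom is an equilibrium
  tr1 <- deterministic_solve(land, c(1, 0), n_steps = 100L)
  expect_true(all(tr1$states[, 1] == 1))
  # the saddle has zero drift: a noise-free lineage started there stays put
  tr2 <- deterministic_solve(land, c(0, 0), n_steps = 100L)
  expect_true(all(tr2$states == 0))
  # interior starts relax to the right well bottom
  tr3 <- deterministic_solve(land, c(0.3, 0.2), n_steps = 3000L)
  expect_lt(sqrt(sum((tr3$states[nrow(tr3$states), ] - c(1, 0))^2)), 1e-3)
})

test_that("noise-free attractive-cusp runs are absorbed at the singular point", {
  land <- landscape_cusp(alpha = 1.5, k = 1, repulsive = FALSE)
  tr <- deterministic_solve(land, c(0.5, 0), dt = 1e-3, n_steps = 10000L,
                            absorb_tol = 1e-6)
  expect_equal(tr$status, "absorbed")
  expect_lt(tr$t_event, 10)
})

test_that("first_passage_time reads off the recorded grid", {
  land <- landscape_quadratic()
  tr <- sde_trajectory(land, sim_config(n_steps = 50L, seed = 1L))
  expect_equal(first_passage_time(tr, function(s) TRUE), 0)
  expect_true(is.na(first_passage_time(tr, function(s) FALSE)))
  hand <- structure(list(times = c(0, 0.5, 1),
                         states = rbind(c(0, 0), c(1, 0), c(2, 0)),
                         status = "completed", t_event = NA_real_, seed = 1L,
                         config = sim_config(), landscape_name = "hand"),
                    class = "sde_trajectory")
  expect_equal(first_passage_time(hand, function(s) s[1] > 0.5), 0.5)
})

test_that("trajectories round-trip through TSV + JSON sidecar", {
  land <- landscape_cusp(alpha = 1.5, k = 1, repulsive = TRUE)
  tr <- sde_trajectory(land, sim_config(n_steps = 300L, seed = 3L, x0 = c(0.1, 0)))
  prefix <- file.path(tempdir(), "traj_rt")
  write_trajectory(tr, prefix)
  back <- read_trajectory(prefix)
  expect_identical(unname(back$states), unname(tr$states))
  expect_identical(back$times, tr$times)
  expect_identical(back$status, tr$status)
  expect_identical(back$t_event, tr$t_event)
  expect_identical(back$config$D, tr$config$D)
})

test_that("ensemble replicates reproduce standalone runs with derived seeds", {
  land <- landscape_double_well()
  cfg <- sim_config(n_steps = 300L, x0 = c(0, 0))
  ens <- run_ensemble(land, cfg, n_rep = 5, base_seed = 30L)
  for (i in 1:5) {
    cfg_i <- cfg
    cfg_i$seed <- 30L + i - 1L
    solo <- sde_trajectory(land, cfg_i)
    expect_identical(as.numeric(ens$final_states[i, ]),
                     as.numeric(solo$states[nrow(solo$states), ]))
    expect_identical(ens$statuses[i], solo$status)
  }
  # two calls with the same base seed agree entirely
  ens2 <- run_ensemble(land, cfg, n_rep = 5, base_seed = 30L)
  expect_identical(ens$final_states, ens2$final_states)
})
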