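# clade-demonstrator conditions: shallow enough for dwell-splits, deep
# enough for a niche-residence phase (see clade_scaling_experiment)
clade_land <- landscape_double_well(a = 0.4, b = 0.5, h = 0)
clade_cfg <- sim_config(D = 0.01, x0 = c(0, 0))

test_that("split_eps = 0 disables splitting: the tree is a single root lineage", {
  sim <- simulate_clade(clade_land, clade_cfg, split_eps = 0, t_max = 10,
                        base_seed = 1L)
  expect_equal(nrow(sim$tree$nodes), 1L)
  expect_equal(sim$tree$nodes$cause, "horizon")
  expect_true(all(sim$series$diversity == 1))
  expect_true(all(sim$series$disparity == 0))
})

test_that("a clade seeded on the watershed splits first, with exact daughter offsets", {
  for (s in seq(100, 2000, by = 100)) {
    sim <- simulate_clade(clade_land, clade_cfg, t_max = 40, base_seed = s)
    nd <- sim$tree$nodes
    ev <- nd[!is.na(nd$death), ]
    expect_gt(nrow(ev), 0)
    expect_equal(ev$cause[which.min(ev$death)], "split")
    # daughters are born at the parent's split phenotype +/- split_offset
    kids <- nd[!is.na(nd$parent), ]
    pa <- nd[match(kids$parent, nd$id), ]
    expect_true(all(abs(abs(kids$x_birth - pa$x_end) - 0.05) < 1e-12))
    expect_equal(kids$y_birth, pa$y_end)
    expect_equal(kids$birth, pa$death)
  }
})

test_that("tree structure is consistent with the diversity series", {
  sim <- simulate_clade(clade_land, clade_cfg, t_max = 60, base_seed = 700L,
                        max_lineages = 20)
  nd <- sim$tree$nodes
  splits <- nd$cause == "split"
  expect_true(all(table(nd$parent[!is.na(nd$parent)]) == 2))
  expect_equal(sum(splits) * 2 + 1, nrow(nd))
  for (t in sim$series$t) {
    extant <- sum(nd$birth <= t & (is.na(nd$death) | nd$death > t))
    expect_equal(sim$series$diversity[sim$series$t == t], extant)
  }
  expect_true(all(sim$series$disparity >= 0))
  expect_true(all(sim$series$disparity[sim$series$diversity <= 1] == 0))
})

test_that("disparity is the trace of the phenotypic covariance (divisor n)", {
  tree <- make_two_leaf_tree()
  ser <- diversity_disparity(tree)
  expect_equal(ser$diversity, c(1, 1, 2, 2, 2, 2, 2))
  # two lineages at x = -1 and +1: Var(x) = 1 with divisor n, Var(y) = 0
  expect_equal(ser$disparity[ser$t >= 1], rep(1, 5))
  expect_equal(ser$disparity[ser$t < 1], c(0, 0))
  # permuting lineage order leaves the series unchanged
  perm <- tree
  perm$nodes <- perm$nodes[c(3, 1, 2), ]
  expect_equal(diversity_disparity(perm), ser)
})

test_that("scaling_exponent recovers constructed slopes and flags thin data", {
  div <- c(2, 3, 5, 8, 13, 21)
  quad <- structure(data.frame(t = seq_along(div), diversity = div,
                               disparity = div^2),
                    class = c("clade_series", "data.frame"))
  expect_equal(scaling_exponent(quad)$slope, 2, tolerance = 1e-12)
  flat <- structure(data.frame(t = seq_along(div), diversity = div,
                               disparity = rep(3.7, 6)),
                    class = c("clade_series", "data.frame"))
  expect_equal(scaling_exponent(flat)$slope, 0, tolerance = 1e-12)
  thin <- structure(data.frame(t = 1:6, diversity = c(1, 1, 1, 1, 2, 2),
                               disparity = c(0, 0, 0, 0, 1, 1)),
                    class = c("clade_series", "data.frame"))
  expect_false(scaling_exponent(thin)$defined)
})

test_that("mutational effects scale with the field's regularity", {
  lin <- landscape_quadratic(eta = 2)
  el <- dfe_sample(lin, x0 = c(0, 0), step_sd = 0.05, n = 500, seed = 1)
  set.seed(1)
  delta <- matrix(rnorm(1000, sd = 0.05), ncol = 2)
  expect_equal(el, 2 * sqrt(rowSums(delta^2)))     # linear: effect = eta ||delta||
  cusp <- landscape_cusp(alpha = 1.5, k = 1)
  ec <- dfe_sample(cusp, step_sd = 0.05, n = 500, seed = 1)
  fit <- lm(log(ec) ~ log(sqrt(rowSums(delta^2))))
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 1e-9)
  expect_error(dfe_sample(lin, n = 0), "n")
  expect_error(dfe_sample(lin, step_sd = 0), "step_sd")
})

test_that("the Hill estimator is consistent on Pareto tails and scale-invariant", {
  set.seed(11)
  x <- runif(10000)^(-1 / 2)            # exact Pareto, tail exponent 2
  est <- tail_index(x, 500)
  expect_true(est$defined)
  expect_lt(abs(est$index - 2), 0.2)
  expect_equal(tail_index(10 * x, 500)$index, est$index)
  flat <- tail_index(rep(3, 100), 20)
  expect_false(flat$defined)
  expect_error(tail_index(c(-1, 2, 3), 1), "positive")
  expect_error(tail_index(x, 9000), "half")
})

test_that("the mutational amplification factor is power-law heavy at a cusp", {
  cusp <- landscape_cusp(alpha = 1.5, k = 1)
  lin <- landscape_quadratic(eta = 1)
  amp_c <- dfe_sample(cusp, step_sd = 0.05, n = 10000, seed = 3, relative = TRUE)
  amp_l <- dfe_sample(lin, x0 = c(0, 0), step_sd = 0.05, n = 10000, seed = 3,
                      relative = TRUE)
  # cusp amplification ~ r^(alpha - 2): Pareto tail with index 2 / (2 - alpha)
  est <- tail_index(amp_c, 500)
  expect_true(est$defined)
  expect_lt(abs(est$index - 4), 1)
  # a Lipschitz field amplifies every mutation equally: degenerate, flagged
  expect_lt(stats::sd(amp_l), 1e-12)
  expect_false(tail_index(amp_l, 500)$defined)
})

test_that("Newick export is valid, labelled and round-trips through ape", {
  solo <- make_two_leaf_tree()
  solo$nodes <- solo$nodes[1, ]
  solo$nodes$death <- NA_real_
  solo$nodes$cause <- "horizon"
  solo$t_max <- 5
  expect_equal(write_newick(solo), "L1:5;")
  two <- make_two_leaf_tree()           # split at 1, horizon 3
  txt <- write_newick(two)
  expect_equal(txt, "(L2:2,L3:2)L1:1;")
  skip_if_not_installed("ape")
  ph <- ape::read.tree(text = txt)
  expect_equal(ape::Ntip(ph), 2L)
  expect_equal(sort(ph$edge.length), c(2, 2))
  # write -> parse -> write is stable
  expect_equal(ape::write.tree(ph), ape::write.tree(ape::read.tree(
    text = ape::write.tree(ph))))
  bad <- two
  bad$nodes$parent[2] <- 99L
  expect_error(write_newick(bad), "orphan|root|children")
})

test_that("the lineage cap truncates cleanly instead of erroring", {
  sim <- simulate_clade(clade_land, clade_cfg, t_max = 60, base_seed = 700L,
                        max_lineages = 5)
  expect_true(sim$tree$truncated)
  expect_lte(nrow(sim$tree$nodes), 5)
  expect_true(all(sim$series$diversity >= 1))
})
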