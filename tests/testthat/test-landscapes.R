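test_that("constructors reject invalid parameters", {
  expect_error(landscape_quadratic(eta = 0), "eta")
  expect_error(landscape_quadratic(eta = -1), "eta")
  expect_error(landscape_cusp(alpha = 1), "alpha")
  expect_error(landscape_cusp(alpha = 2), "alpha")
  expect_error(landscape_cusp(alpha = 1.5, k = 0), "k")
  expect_error(landscape_double_well(a = 0), "a")
  expect_error(landscape_double_well(a = 1, b = -1), "b")
  expect_error(landscape_limit_cycle(R = 0), "R")
  expect_error(landscape_limit_cycle(beta = 1.2), "beta")
})

test_that("quadratic family: drift and potential match the linear restoring force", {
  land <- landscape_quadratic(c(0, 0), eta = 2)
  expect_equal(drift(land, c(0, 0)), c(0, 0))
  expect_equal(drift(land, c(1, 0)), c(-2, 0))
  # potential rise one unit from the optimum is (eta/2) r^2
  expect_equal(potential(land, c(1, 0)) - potential(land, c(0, 0)), 1.0)
})

test_that("cusp family: Holder drift with the declared exponent and center value", {
  land <- landscape_cusp(alpha = 1.5, k = 1, repulsive = FALSE)
  expect_equal(sqrt(sum(drift(land, c(1, 0))^2)), 1.5)          # k alpha r^(a-1), r=1
  expect_equal(drift(land, c(0, 0)), c(0, 0))                   # defined value at cusp
  expect_equal(sqrt(sum(drift(land, c(0.01, 0))^2)), 1.5 * sqrt(0.01))
  expect_equal(land$declared_exponent, 0.5)
  # attractive points inward, repulsive outward
  rep_land <- landscape_cusp(alpha = 1.5, k = 1, repulsive = TRUE)
  expect_lt(drift(land, c(0.5, 0))[1], 0)
  expect_gt(drift(rep_land, c(0.5, 0))[1], 0)
})

test_that("double-well family: wells, barrier and tilt", {
  land <- landscape_double_well(a = 1, b = 1, h = 0)
  expect_equal(drift(land, c(1, 0)), c(0, 0))
  expect_equal(drift(land, c(-1, 0)), c(0, 0))
  # barrier height a^4
  expect_equal(potential(land, c(0, 0)) - potential(land, c(1, 0)), 1.0)
  tilted <- landscape_double_well(a = 1, b = 1, h = 0.5)
  expect_equal(drift(tilted, c(0, 0)), c(0.5, 0))
})

test_that("limit-cycle family: radial law, tangential speed, origin", {
  land <- landscape_limit_cycle(R = 1, kappa = 1, beta = 0.5, omega0 = 1,
                                omega1 = 0.5)
  FF <- drift(land, c(1, 0))                 # on the circle
  expect_equal(FF[1], 0)                     # radial component vanishes
  expect_equal(abs(FF[2]), 1)                # tangential speed r * omega = R
  # radial drift at r = R + 0.04 with beta = 0.5 is -sqrt(0.04) = -0.2
  F2 <- drift(land, c(1.04, 0))
  expect_equal(F2[1], -0.2)
  expect_equal(drift(land, c(0, 0)), c(0, 0))
  expect_error(potential(land, c(1, 0)), "non-gradient")
})

test_that("lande_drift computes G beta and rejects bad matrices", {
  expect_equal(lande_drift(diag(2), c(0.3, -0.1)), c(0.3, -0.1))
  expect_equal(lande_drift(2 * diag(2), c(1, 0)), c(2, 0))
  expect_equal(lande_drift(matrix(c(1, 0.5, 0.5, 2), 2), c(1, 1)), c(1.5, 2.5))
  expect_error(lande_drift(matrix(c(1, 0.2, 0.5, 2), 2), c(1, 1)), "symmetric")
  expect_error(lande_drift(matrix(c(1, 2, 2, 1), 2), c(1, 1)), "positive definite")
})

test_that("gradient families satisfy drift = -grad U away from the singular locus", {
  fams <- list(landscape_quadratic(c(0.3, -0.2), eta = 1.7),
               landscape_cusp(c(0.1, 0.1), alpha = 1.4, k = 0.8, repulsive = TRUE),
               landscape_cusp(alpha = 1.8, k = 2, repulsive = FALSE),
               landscape_double_well(a = 1.2, b = 0.6, h = 0.3))
  set.seed(42)
  for (land in fams) {
    Uf <- function(p) potential(land, p)
    n_ok <- 0L
    while (n_ok < 100L) {
      x <- stats::runif(2, -2, 2)
      ref <- if (land$singular_locus$type == "point") land$singular_locus$center
             else land$center
      if (land$family == "cusp" && sqrt(sum((x - ref)^2)) < 0.1) next
      FF <- drift(land, x)
      g <- num_grad(Uf, x)
      expect_lt(sqrt(sum((FF + g)^2)) / (1 + sqrt(sum(FF^2))), 1e-4)
      n_ok <- n_ok + 1L
    }
  }
})

test_that("the cusp drift is Holder but not Lipschitz at its center", {
  land <- landscape_cusp(alpha = 1.5, k = 1)
  rr <- 10^seq(-6, -1, length.out = 11)
  inc <- vapply(rr, function(r) sqrt(sum(drift(land, c(r, 0))^2)), 0)
  holder_ratio <- inc / rr^0.5
  lipschitz_ratio <- inc / rr
  # Holder ratio pinned at k * alpha across five decades
  expect_true(all(abs(holder_ratio - 1.5) < 1e-9))
  # Lipschitz ratio diverges as r -> 0
  expect_true(all(diff(lipschitz_ratio) < 0))
  expect_gt(lipschitz_ratio[1] / lipschitz_ratio[11], 100)
})

test_that("cusp and limit-cycle drifts commute with rotations", {
  ctr <- c(0.5, -0.2)
  cusp <- landscape_cusp(ctr, alpha = 1.6, k = 1.3)
  lc <- landscape_limit_cycle(R = 1.5, kappa = 0.7, beta = 0.5,
                              omega0 = 1, omega1 = 0.5)
  d <- c(0.21, -0.13)
  for (th in c(0.3, 1.1, 2.5, 4.0)) {
    Rm <- rot2(th)
    expect_equal(drift(cusp, ctr + as.numeric(Rm %*% d)),
                 as.numeric(Rm %*% drift(cusp, ctr + d)))
    x <- c(0.9, 0.4)
    expect_equal(drift(lc, as.numeric(Rm %*% x)),
                 as.numeric(Rm %*% drift(lc, x)))
  }
})

test_that("landscapes round-trip through YAML and JSON configs", {
  spec <- list(family = "cusp", center = c(0.2, -0.1), alpha = 1.3, k = 2,
               repulsive = FALSE)
  direct <- landscape_from_config(spec)
  yml <- file.path(tempdir(), "land.yaml")
  yaml::write_yaml(spec, yml)
  jsn <- file.path(tempdir(), "land.json")
  jsonlite::write_json(spec, jsn, auto_unbox = TRUE, digits = NA)
  for (path in c(yml, jsn)) {
    land <- landscape_from_config(path)
    expect_equal(land$params, direct$params)
    expect_equal(land$family, "cusp")
  }
  expect_error(landscape_from_config(list(alpha = 1.5)), "family")
  expect_error(landscape_from_config(list(family = "volcano")), "family")
})

test_that("field grids export x, y, Fx, Fy, U with U empty for non-gradient fields", {
  f1 <- file.path(tempdir(), "grid_dw.tsv")
  write_field_grid(landscape_double_well(), f1, n = 5)
  g <- read.delim(f1)
  expect_named(g, c("x", "y", "Fx", "Fy", "U"))
  expect_true(all(is.finite(g$U)))
  expect_equal(nrow(g), 25)
  f2 <- file.path(tempdir(), "grid_lc.tsv")
  write_field_grid(landscape_limit_cycle(), f2, n = 5)
  g2 <- read.delim(f2)
  expect_true(all(is.na(g2$U)))
  expect_true(all(is.finite(g2$Fx)))
})
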