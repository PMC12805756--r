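# Canonical fitness-landscape drift families.
#
# Every landscape is a two-dimensional drift field F(x), optionally the
# negative gradient of a scalar potential U(x).  The interesting families are
# the ones whose drift is Holder- but not Lipschitz-continuous at a declared
# singular locus: a fractional-exponent cusp (singular point) and a
# non-gradient limit cycle (singular circle).

.new_landscape <- function(name, family, params, center, has_potential,
                           singular_locus, declared_exponent) {
  structure(list(name = name, family = family, dim = 2L, params = params,
                 center = as.numeric(center), has_potential = has_potential,
                 singular_locus = singular_locus,
                 declared_exponent = declared_exponent),
            class = "landscape")
}

.no_locus <- list(type = "none", description = "empty (drift is Lipschitz everywhere)")

#' Quadratic (single-niche) landscape
#'
#' A linear restoring drift `F(x) = eta * (center - x)` derived from the
#' quadratic potential `U(x) = (eta / 2) * ||x - center||^2`.  This is the
#' Lipschitz benchmark family: a lineage placed anywhere converges smoothly
#' to the niche optimum at `center`, the dynamical picture of stasis.  Under
#' isotropic noise the process is an Ornstein-Uhlenbeck process with
#' stationary per-component variance `D / eta`.
#'
#' @param center optimum phenotype, a length-2 numeric vector.
#' @param eta positive restoring rate (strength of stabilising selection).
#' @return A `landscape` object.
#' @seealso [landscape_cusp()], [landscape_double_well()], [landscape_limit_cycle()]
#' @examples
#' land <- landscape_quadratic(c(0, 0), eta = 2)
#' drift(land, c(1, 0))   # (-2, 0)
#' @export
landscape_quadratic <- function(center = c(0, 0), eta = 1) {
  center <- .check_vec2(center, "center")
  .check_scalar(eta, "eta", lower = 0, strict_lower = TRUE)
  .new_landscape("quadratic basin", "quadratic",
                 list(center = center, eta = eta), center,
                 has_potential = TRUE, singular_locus = .no_locus,
                 declared_exponent = 1)
}

#' Fractional-exponent cusp landscape
#'
#' The potential `U(x) = s * k * ||x - center||^alpha` with `1 < alpha < 2`,
#' where `s = +1` for an attractive basin and `s = -1` for a repulsive cusp.
#' The drift `-grad U` has magnitude `k * alpha * r^(alpha - 1)` at distance
#' `r` from the center and is therefore Holder continuous with exponent
#' `alpha - 1 < 1` at the cusp, but not Lipschitz: its derivative diverges
#' there.  The repulsive variant models catastrophic ejection of a lineage
#' (finite-time escape, i.e. extinction); the attractive variant reaches the
#' cusp in finite time.  The drift is defined to be the zero vector exactly
#' at the cusp, the unique rotationally symmetric completion.
#'
#' `alpha = 1` and `alpha = 2` are different regularity classes (a conical
#' kink and a smooth quadratic respectively) and are rejected rather than
#' silently accepted.
#'
#' @param center the singular point, length-2 numeric.
#' @param alpha potential exponent, strictly between 1 and 2.
#' @param k positive scale of the potential.
#' @param repulsive logical; `TRUE` (default) flips the potential sign so the
#'   cusp ejects trajectories.
#' @return A `landscape` object with `declared_exponent = alpha - 1`.
#' @examples
#' land <- landscape_cusp(alpha = 1.5, k = 1, repulsive = FALSE)
#' sqrt(sum(drift(land, c(1, 0))^2))  # k * alpha = 1.5
#' @export
landscape_cusp <- function(center = c(0, 0), alpha = 1.5, k = 1, repulsive = TRUE) {
  center <- .check_vec2(center, "center")
  .check_scalar(alpha, "alpha", lower = 1, upper = 2,
                strict_lower = TRUE, strict_upper = TRUE)
  .check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  .new_landscape(if (repulsive) "repulsive cusp" else "attractive cusp",
                 "cusp",
                 list(center = center, alpha = alpha, k = k, repulsive = repulsive),
                 center, has_potential = TRUE,
                 singular_locus = list(type = "point", center = center,
                                       description = "the cusp point"),
                 declared_exponent = alpha - 1)
}

#' Tilted double-well landscape
#'
#' `U(x, y) = (x^2 - a^2)^2 + b * y^2 - h * x`, two niches at roughly
#' `x = -a` and `x = +a` separated by a saddle ridge (the watershed, the line
#' `x = 0` when `h = 0`).  The tilt `h` is an environmental control
#' parameter: it breaks the symmetry between the wells and drives the
#' tipping-point behaviour explored by [bifurcation_sweep()].  The drift is
#' smooth (Lipschitz); the family's role is the watershed geometry along
#' which trajectory outcomes become contingent under noise.
#'
#' @param a positive well half-separation; the barrier height at `h = 0` is `a^4`.
#' @param b positive transverse (y) stiffness.
#' @param h tilt, any real number.
#' @return A `landscape` object centred at the origin.
#' @examples
#' land <- landscape_double_well(a = 1, b = 1, h = 0)
#' drift(land, c(1, 0))  # (0, 0): well bottom
#' @export
landscape_double_well <- function(a = 1, b = 1, h = 0) {
  .check_scalar(a, "a", lower = 0, strict_lower = TRUE)
  .check_scalar(b, "b", lower = 0, strict_lower = TRUE)
  .check_scalar(h, "h")
  .new_landscape("tilted double well", "double_well",
                 list(a = a, b = b, h = h), c(0, 0),
                 has_potential = TRUE, singular_locus = .no_locus,
                 declared_exponent = 1)
}

#' Non-gradient limit-cycle landscape
#'
#' A rotational drift field, defined in polar coordinates about the origin,
#' that pushes the state onto the circle `r = R` with radial component
#' `kappa * sign(R - r) * |R - r|^beta` and rotates it with state-dependent
#' angular velocity `omega(r) = omega0 + omega1 * (r - R)`.  For `beta < 1`
#' the radial attraction is Holder but not Lipschitz on the circle, so orbits
#' reach the cycle in finite time; the cycle models dynamic equilibria such
#' as coevolutionary arms races.  The field has no potential.  The drift at
#' the origin (a coordinate singularity with no preferred radial direction)
#' is defined as zero.
#'
#' @param R positive target radius.
#' @param kappa positive radial gain.
#' @param beta radial exponent in (0, 1]; `beta = 1` gives a Lipschitz field.
#' @param omega0 base angular rate on the cycle.
#' @param omega1 radial shear of the rotation rate.
#' @return A `landscape` object with `has_potential = FALSE`.
#' @export
landscape_limit_cycle <- function(R = 1, kappa = 1, beta = 0.5,
                                  omega0 = 1, omega1 = 0.5) {
  .check_scalar(R, "R", lower = 0, strict_lower = TRUE)
  .check_scalar(kappa, "kappa", lower = 0, strict_lower = TRUE)
  .check_scalar(beta, "beta", lower = 0, upper = 1, strict_lower = TRUE)
  .check_scalar(omega0, "omega0")
  .check_scalar(omega1, "omega1")
  locus <- if (beta < 1) {
    list(type = "circle", center = c(0, 0), radius = R,
         description = "the circle r = R")
  } else .no_locus
  .new_landscape("limit cycle", "limit_cycle",
                 list(R = R, kappa = kappa, beta = beta,
                      omega0 = omega0, omega1 = omega1),
                 c(0, 0), has_potential = FALSE, singular_locus = locus,
                 declared_exponent = beta)
}

# Vectorised drift kernels: X is an n x 2 matrix, the return value likewise.
.drift_eval <- function(landscape, X) {
  p <- landscape$params
  switch(landscape$family,
    quadratic = cbind(p$eta * (p$center[1] - X[, 1]),
                      p$eta * (p$center[2] - X[, 2])),
    cusp = {
      dx <- X[, 1] - p$center[1]
      dy <- X[, 2] - p$center[2]
      r <- sqrt(dx * dx + dy * dy)
      s <- if (p$repulsive) -1 else 1
      coef <- numeric(length(r))
      pos <- r > 0
      coef[pos] <- -s * p$k * p$alpha * r[pos]^(p$alpha - 2)
      cbind(coef * dx, coef * dy)
    },
    double_well = cbind(-4 * X[, 1] * (X[, 1]^2 - p$a^2) + p$h,
                        -2 * p$b * X[, 2]),
    limit_cycle = {
      x <- X[, 1]; y <- X[, 2]
      r <- sqrt(x * x + y * y)
      rad <- p$kappa * sign(p$R - r) * abs(p$R - r)^p$beta
      ux <- ifelse(r > 0, x / r, 0)
      uy <- ifelse(r > 0, y / r, 0)
      om <- p$omega0 + p$omega1 * (r - p$R)
      cbind(rad * ux - om * y, rad * uy + om * x)
    },
    stop("unknown landscape family: ", landscape$family, call. = FALSE))
}

# Scalar drift closure for tight integration loops.  The arithmetic mirrors
# .drift_eval expression-for-expression so scalar and vectorised paths give
# bitwise-identical results.
.scalar_drift <- function(landscape) {
  p <- landscape$params
  switch(landscape$family,
    quadratic = function(x, y) c(p$eta * (p$center[1] - x),
                                 p$eta * (p$center[2] - y)),
    cusp = {
      s <- if (p$repulsive) -1 else 1
      function(x, y) {
        dx <- x - p$center[1]; dy <- y - p$center[2]
        r <- sqrt(dx * dx + dy * dy)
        if (r > 0) {
          coef <- -s * p$k * p$alpha * r^(p$alpha - 2)
          c(coef * dx, coef * dy)
        } else c(0, 0)
      }
    },
    double_well = function(x, y) c(-4 * x * (x^2 - p$a^2) + p$h,
                                   -2 * p$b * y),
    limit_cycle = function(x, y) {
      r <- sqrt(x * x + y * y)
      rad <- p$kappa * sign(p$R - r) * abs(p$R - r)^p$beta
      ux <- if (r > 0) x / r else 0
      uy <- if (r > 0) y / r else 0
      om <- p$omega0 + p$omega1 * (r - p$R)
      c(rad * ux - om * y, rad * uy + om * x)
    },
    stop("unknown landscape family: ", landscape$family, call. = FALSE))
}

#' Evaluate the drift field of a landscape
#'
#' @param object a `landscape`.
#' @param x a length-2 state or an n x 2 matrix of states.
#' @param ... unused.
#' @return Drift vector(s) in the same shape as `x`.
#' @export
drift <- function(object, x, ...) UseMethod("drift")

#' @rdname drift
#' @export
drift.landscape <- function(object, x, ...) {
  X <- .as_state_matrix(x)
  out <- .drift_eval(object, X)
  if (is.matrix(x)) out else as.numeric(out)
}

#' Evaluate the potential of a gradient landscape
#'
#' Defined for families with `has_potential = TRUE`; the drift is the
#' negative gradient of this function.  Proportionality constants are fixed
#' so `-grad U` reproduces the drift: `U = (eta/2) r^2` for the quadratic
#' family and `U = +/- k r^alpha` for the cusp.
#'
#' @param object a `landscape`.
#' @param x a length-2 state or an n x 2 matrix of states.
#' @param ... unused.
#' @return Potential value(s).
#' @export
potential <- function(object, x, ...) UseMethod("potential")

#' @rdname potential
#' @export
potential.landscape <- function(object, x, ...) {
  if (!object$has_potential)
    stop("landscape '", object$name, "' is non-gradient: no potential is defined",
         call. = FALSE)
  X <- .as_state_matrix(x)
  p <- object$params
  switch(object$family,
    quadratic = {
      dx <- X[, 1] - p$center[1]; dy <- X[, 2] - p$center[2]
      p$eta / 2 * (dx * dx + dy * dy)
    },
    cusp = {
      dx <- X[, 1] - p$center[1]; dy <- X[, 2] - p$center[2]
      s <- if (p$repulsive) -1 else 1
      s * p$k * (dx * dx + dy * dy)^(p$alpha / 2)
    },
    double_well = (X[, 1]^2 - p$a^2)^2 + p$b * X[, 2]^2 - p$h * X[, 1])
}

#' Selection response from quantitative-genetics inputs
#'
#' Computes the Lande response `G %*% beta_sel`: the expected per-generation
#' drift of the mean phenotype given an additive genetic covariance matrix
#' `G` and a selection gradient `beta_sel`.  Useful for building a
#' constant-drift interpretation of field-estimated selection.
#'
#' @param G symmetric positive-definite genetic covariance matrix.
#' @param beta_sel selection gradient vector, `length(beta_sel) == nrow(G)`.
#' @return The response vector `G %*% beta_sel`.
#' @examples
#' lande_drift(diag(2), c(0.3, -0.1))
#' @export
lande_drift <- function(G, beta_sel) {
  if (!is.matrix(G) || nrow(G) != ncol(G))
    stop("'G' must be a square matrix", call. = FALSE)
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G))))
    stop("'G' must be symmetric: asymmetry exceeds tolerance", call. = FALSE)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("'G' must be positive definite: smallest eigenvalue is ",
         format(min(ev)), call. = FALSE)
  if (length(beta_sel) != nrow(G))
    stop("'beta_sel' must have length nrow(G)", call. = FALSE)
  as.numeric(G %*% beta_sel)
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", x$name, " (family: ", x$family, ")\n", sep = "")
  pp <- x$params[setdiff(names(x$params), "center")]
  cat("  params: ",
      paste(names(pp), vapply(pp, function(v) format(v), ""),
            sep = " = ", collapse = ", "), "\n", sep = "")
  cat("  center: (", paste(format(x$center), collapse = ", "), ")\n", sep = "")
  cat("  potential: ", if (x$has_potential) "yes" else "no (non-gradient)",
      "\n", sep = "")
  cat("  singular locus: ", x$singular_locus$description,
      "; Holder exponent ", format(x$declared_exponent), "\n", sep = "")
  invisible(x)
}

#' Build a landscape from a configuration list or file
#'
#' The configuration is a list (or a YAML/JSON file containing one) with a
#' `family` entry — one of `"quadratic"`, `"cusp"`, `"double_well"`,
#' `"limit_cycle"` — and the corresponding constructor arguments.
#'
#' @param spec a list, or the path to a YAML/JSON file.
#' @return A `landscape` object.
#' @export
landscape_from_config <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) spec <- .read_config_file(spec)
  if (!is.list(spec)) stop("landscape spec must be a list", call. = FALSE)
  if (is.null(spec$family))
    stop("landscape config is missing required field 'family'", call. = FALSE)
  ctor <- switch(as.character(spec$family),
                 quadratic = landscape_quadratic,
                 cusp = landscape_cusp,
                 double_well = landscape_double_well,
                 limit_cycle = landscape_limit_cycle,
                 stop("unknown landscape 'family': ", spec$family, call. = FALSE))
  args <- spec[setdiff(names(spec), "family")]
  if (!is.null(args$center)) args$center <- as.numeric(unlist(args$center))
  do.call(ctor, args)
}

#' Export a vector-field grid for phase-portrait plotting
#'
#' Writes a TSV with columns `x, y, Fx, Fy, U` (`U` is left empty for
#' non-gradient families) on a regular lattice, suitable for drawing phase
#' portraits of the drift field.
#'
#' @param landscape a `landscape`.
#' @param file output path.
#' @param xlim,ylim axis ranges.
#' @param n grid points per axis.
#' @return The data frame that was written, invisibly.
#' @export
write_field_grid <- function(landscape, file, xlim = c(-2, 2), ylim = c(-2, 2),
                             n = 41) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  X <- cbind(g$x, g$y)
  FF <- .drift_eval(landscape, X)
  U <- if (landscape$has_potential) potential(landscape, X) else NA_real_
  df <- data.frame(x = g$x, y = g$y, Fx = FF[, 1], Fy = FF[, 2], U = U)
  .write_tsv(df, file)
  invisible(df)
}
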