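# Equilibrium analysis and tipping-point location for the tilted double well.
#
# Along y = 0 the drift zeros solve 4 x^3 - 4 mu x - h = 0 with mu = a^2;
# an equilibrium is stable iff U'' = 12 x^2 - 4 mu > 0 (the y direction is
# always stable for b > 0).

# Real roots of 4 x^3 - 4 mu x - h = 0, Newton-polished.
.cubic_equilibria <- function(mu, h) {
  rts <- polyroot(c(-h, -4 * mu, 0, 4))
  re <- Re(rts)[abs(Im(rts)) < 1e-8 * (1 + abs(Re(rts)))]
  for (it in 1:3) {
    dp <- 12 * re^2 - 4 * mu
    ok <- is.finite(dp) & abs(dp) > 1e-12
    re[ok] <- re[ok] - (4 * re[ok]^3 - 4 * mu * re[ok] - h) / dp[ok]
  }
  re <- re[is.finite(re)]
  re <- sort(re)
  # collapse numerically coincident roots (fold point)
  if (length(re) > 1L) re <- re[c(TRUE, diff(re) > 1e-7 * (1 + abs(re[-1])))]
  data.frame(x = re, stable = 12 * re^2 - 4 * mu > 0)
}

#' Equilibria of the tilted double well along the x axis
#'
#' Returns the real roots of the x-drift `-4x(x^2 - a^2) + h = 0`, i.e. of
#' the cubic `4x^3 - 4a^2 x - h`, each classified as stable iff
#' `U'' = 12x^2 - 4a^2 > 0`.  The y coordinate of every equilibrium is 0.
#' The number of real roots changes from 3 to 1 exactly when `|h|` crosses
#' the fold threshold `8 a^3 / (3 sqrt(3))`.
#'
#' @param a positive well half-separation.
#' @param h tilt.
#' @return A data frame with columns `x` (sorted) and `stable` (logical).
#' @examples
#' equilibria_1d(1, 0)  # -1 (stable), 0 (unstable), 1 (stable)
#' @export
equilibria_1d <- function(a, h = 0) {
  .check_scalar(a, "a", lower = 0, strict_lower = TRUE)
  .check_scalar(h, "h")
  .cubic_equilibria(a^2, h)
}

#' Equilibria of the pitchfork normal form
#'
#' The un-tilted family `U = (x^2 - mu)^2` parameterised by `mu = a^2`,
#' allowed to take either sign: for `mu <= 0` the only equilibrium is the
#' stable origin; as `mu` crosses 0 the origin destabilises and two stable
#' branches appear at exactly `x = +/- sqrt(mu)` — the supercritical
#' pitchfork.
#'
#' @param mu bifurcation parameter (`a^2`, any real value).
#' @param h optional tilt (default 0; a nonzero tilt unfolds the pitchfork).
#' @return A data frame with columns `x` and `stable`.
#' @export
pitchfork_equilibria <- function(mu, h = 0) {
  .check_scalar(mu, "mu")
  .check_scalar(h, "h")
  .cubic_equilibria(mu, h)
}

#' Sweep the tilt of the double well and track equilibria and modes
#'
#' For each tilt value `h` the deterministic equilibria are computed with
#' [equilibria_1d()], and an ensemble of replicates from `x0 = (0, 0)` is
#' simulated whose final-x histogram yields mode locations and counts via
#' [count_modes()].  The ensemble for the i-th tilt value uses base seed
#' `base_seed + i - 1`.
#'
#' @param h_values strictly increasing tilt values, at least 5.
#' @param a,b double-well shape parameters.
#' @param config a [sim_config()]; its `x0` is forced to `(0, 0)`.
#' @param n_rep replicates per tilt value.
#' @param base_seed root seed.
#' @param n_bins,bandwidth,min_prominence histogram/mode-count settings.
#' @param hist_limits histogram range; defaults to `c(-1, 1) * (2 * a + 0.5)`.
#' @return A `bifurcation_diagram` with per-value equilibria, mode
#'   locations, dominant-mode location and sign.
#' @export
bifurcation_sweep <- function(h_values, a = 1, b = 1, config = sim_config(),
                              n_rep = 200, base_seed = 1L, n_bins = 60,
                              bandwidth = 3, min_prominence = 0.1,
                              hist_limits = NULL) {
  h_values <- as.numeric(h_values)
  if (length(h_values) < 5L) stop("sweep needs at least 5 parameter values",
                                  call. = FALSE)
  if (any(diff(h_values) <= 0)) stop("'h_values' must be strictly increasing",
                                     call. = FALSE)
  if (is.null(hist_limits)) hist_limits <- c(-1, 1) * (2 * a + 0.5)
  config$x0 <- c(0, 0)

  eq <- vector("list", length(h_values))
  modes <- vector("list", length(h_values))
  n_modes <- integer(length(h_values))
  dom_loc <- numeric(length(h_values))
  for (i in seq_along(h_values)) {
    land <- landscape_double_well(a = a, b = b, h = h_values[i])
    eq[[i]] <- equilibria_1d(a, h_values[i])
    ens <- run_ensemble(land, config, n_rep = n_rep,
                        base_seed = base_seed + i - 1L)
    fx <- ens$final_states[ens$statuses == "completed", 1]
    hst <- trait_histogram(fx, n_bins = n_bins, limits = hist_limits,
                           label = "final x")
    m <- count_modes(hst, bandwidth = bandwidth,
                     min_prominence = min_prominence)
    locs <- attr(m, "locations")
    hts <- attr(m, "heights")
    n_modes[i] <- as.integer(m)
    dom_loc[i] <- if (length(locs)) locs[which.max(hts)] else NA_real_
    modes[[i]] <- data.frame(location = locs, height = hts)
  }
  structure(list(h = h_values, equilibria = eq, modes = modes,
                 n_modes = n_modes, dominant_loc = dom_loc,
                 dominant_sign = sign(dom_loc),
                 a = a, b = b, n_rep = n_rep, base_seed = base_seed,
                 config = config),
            class = "bifurcation_diagram")
}

#' Locate the tipping point of a bifurcation diagram
#'
#' Fits the single change point of the dominant-mode sign across the sweep:
#' the split index maximising the number of values whose dominant sign
#' agrees with a one-switch pattern, which for a clean single switch reduces
#' to the midpoint of the two adjacent parameter values between which the
#' dominant final-phenotype mode changes sign.  Resolution is the sweep
#' spacing.
#'
#' @param diagram a `bifurcation_diagram` (any list with fields `h` and
#'   `dominant_sign` works, e.g. a hand-built one).
#' @return A list with `estimate` (the parameter value), `defined`, and the
#'   bracketing interval `lower`, `upper`.  If the dominant sign never
#'   changes, `defined = FALSE` and the estimate is `NA`.
#' @export
critical_point_estimate <- function(diagram) {
  h <- diagram$h
  s <- diagram$dominant_sign
  ok <- !is.na(s)
  if (!any(s[ok] < 0) || !any(s[ok] > 0)) {
    return(list(estimate = NA_real_, defined = FALSE,
                lower = NA_real_, upper = NA_real_,
                reason = "dominant-mode sign never switches in the sweep"))
  }
  m <- length(s)
  score_up <- vapply(seq_len(m - 1L), function(i)
    sum(s[seq_len(i)] < 0, na.rm = TRUE) + sum(s[(i + 1):m] > 0, na.rm = TRUE), 0)
  score_dn <- vapply(seq_len(m - 1L), function(i)
    sum(s[seq_len(i)] > 0, na.rm = TRUE) + sum(s[(i + 1):m] < 0, na.rm = TRUE), 0)
  i <- if (max(score_up) >= max(score_dn)) which.max(score_up) else which.max(score_dn)
  list(estimate = (h[i] + h[i + 1L]) / 2, defined = TRUE,
       lower = h[i], upper = h[i + 1L])
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram> tilt sweep over [", format(min(x$h)), ",",
      format(max(x$h)), "] in", length(x$h), "values; a =", x$a,
      ", n_rep =", x$n_rep, "\n")
  cp <- critical_point_estimate(x)
  if (cp$defined) cat("  dominant-mode switch at h ~", format(cp$estimate), "\n")
  else cat("  no dominant-mode sign switch detected\n")
  invisible(x)
}

#' @export
plot.bifurcation_diagram <- function(x, ...) {
  eq_all <- do.call(rbind, lapply(seq_along(x$h), function(i)
    cbind(h = x$h[i], x$equilibria[[i]])))
  graphics::plot(eq_all$h, eq_all$x, type = "n", xlab = "tilt h",
                 ylab = "phenotype x", ...)
  graphics::points(eq_all$h[eq_all$stable], eq_all$x[eq_all$stable], pch = 16)
  graphics::points(eq_all$h[!eq_all$stable], eq_all$x[!eq_all$stable], pch = 1)
  graphics::points(x$h, x$dominant_loc, pch = 4, col = 2)
  graphics::legend("topleft", pch = c(16, 1, 4), col = c(1, 1, 2),
                   legend = c("stable equilibrium", "unstable equilibrium",
                              "dominant simulated mode"), bty = "n")
  invisible(x)
}

#' Export a bifurcation diagram
#'
#' Writes `<prefix>.tsv` (one row per tilt value: equilibria, mode count,
#' dominant mode) and `<prefix>.json` (the critical-point estimate and sweep
#' settings).
#'
#' @param diagram a `bifurcation_diagram`.
#' @param prefix path prefix.
#' @return The prefix, invisibly.
#' @export
write_bifurcation <- function(diagram, prefix) {
  rows <- lapply(seq_along(diagram$h), function(i) {
    eq <- diagram$equilibria[[i]]
    data.frame(h = diagram$h[i],
               stable_equilibria = paste(sprintf("%.17g", eq$x[eq$stable]),
                                         collapse = ","),
               unstable_equilibria = paste(sprintf("%.17g", eq$x[!eq$stable]),
                                           collapse = ","),
               n_modes = diagram$n_modes[i],
               dominant_mode = diagram$dominant_loc[i],
               dominant_sign = diagram$dominant_sign[i])
  })
  .write_tsv(do.call(rbind, rows), paste0(prefix, ".tsv"))
  cp <- critical_point_estimate(diagram)
  .write_json(list(a = diagram$a, b = diagram$b, n_rep = diagram$n_rep,
                   base_seed = diagram$base_seed,
                   h_range = range(diagram$h),
                   critical_point = cp),
              paste0(prefix, ".json"))
  invisible(prefix)
}
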