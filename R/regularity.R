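# Local regularity estimation of drift fields.
#
# A field F is Holder continuous with exponent alpha at x0 if
# ||F(x) - F(y)|| <= K ||x - y||^alpha near x0; alpha = 1 is the Lipschitz
# condition.  The estimator probes the field at log-spaced radii around x0
# and regresses the log maximal increment on the log radius.

.as_field <- function(field) {
  if (inherits(field, "landscape")) {
    land <- field
    return(function(p) drift(land, p))
  }
  if (!is.function(field))
    stop("'field' must be a function of a length-2 state or a landscape",
         call. = FALSE)
  field
}

#' Estimate the local Holder exponent of a vector field
#'
#' For each probe radius `r` the maximal increment
#' `M(r) = max_u || field(x0 + r u) - field(x0) ||` over `n_dirs` sampled
#' unit directions `u` (the same directions are reused at every radius) is
#' computed; the estimate is the least-squares slope of `log M(r)` against
#' `log r`, with `K = exp(intercept)`.  A slope near 1 indicates local
#' Lipschitz continuity; a slope `alpha < 1` indicates a Holder singularity,
#' e.g. `sqrt(|x|)` yields 0.5 at the origin.
#'
#' @param field a function mapping a length-2 state to a length-2 vector, or
#'   a `landscape` (whose drift is probed).
#' @param x0 probe point, length-2.
#' @param scales probe radii, log-spaced, spanning at least three decades,
#'   none below `1e-8` (a floor guarding against floating-point cancellation
#'   dominating the increments).
#' @param n_dirs number of probe directions per radius.
#' @param seed RNG seed for the direction sample.
#' @return A `regularity_estimate` with elements `exponent`, `constant`,
#'   `scales`, `fit_quality` (R-squared of the log-log fit), `center`,
#'   `defined`.  A field that is constant around `x0` (all increments zero)
#'   yields `defined = FALSE` and `NA` estimates rather than a number.
#' @examples
#' land <- landscape_quadratic(eta = 2)
#' holder_exponent(land, c(0.3, 0.2))  # exponent 1, constant 2: Lipschitz
#' @export
holder_exponent <- function(field, x0 = c(0, 0),
                            scales = 10^seq(-1, -6, length.out = 24),
                            n_dirs = 16, seed = 1L) {
  f <- .as_field(field)
  x0 <- .check_vec2(x0, "x0")
  scales <- sort(as.numeric(scales), decreasing = TRUE)
  if (length(scales) < 2L || any(scales <= 0))
    stop("'scales' must be positive radii", call. = FALSE)
  if (min(scales) < 1e-8)
    stop("'scales' below the 1e-8 floor are unreliable in double precision",
         call. = FALSE)
  if (log10(max(scales) / min(scales)) < 3)
    stop("'scales' must span at least three decades", call. = FALSE)
  .check_scalar(n_dirs, "n_dirs", lower = 2, integer = TRUE)

  set.seed(seed)
  theta <- stats::runif(n_dirs, 0, 2 * pi)
  U <- cbind(cos(theta), sin(theta))
  f0 <- f(x0)
  M <- vapply(scales, function(r) {
    inc <- vapply(seq_len(n_dirs), function(j) {
      .norm2(f(x0 + r * U[j, ]) - f0)
    }, 0)
    max(inc)
  }, 0)

  if (all(M == 0)) {
    return(structure(list(exponent = NA_real_, constant = NA_real_,
                          scales = scales, fit_quality = NA_real_,
                          center = x0, defined = FALSE,
                          reason = "all increments are zero (locally constant field)"),
                     class = "regularity_estimate"))
  }
  keep <- M > 0
  lr <- log(scales[keep])
  lM <- log(M[keep])
  fit <- stats::lm(lM ~ lr)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((lM - mean(lM))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 constant = unname(exp(stats::coef(fit)[1])),
                 scales = scales,
                 fit_quality = r2,
                 center = x0, defined = TRUE),
            class = "regularity_estimate")
}

#' @export
print.regularity_estimate <- function(x, ...) {
  cat("<regularity_estimate> at (", paste(format(x$center), collapse = ", "),
      ")\n", sep = "")
  if (!x$defined) {
    cat("  undefined:", x$reason, "\n")
  } else {
    cat("  Holder exponent:", format(x$exponent),
        "  constant:", format(x$constant),
        "  R^2:", format(x$fit_quality), "\n")
    cat("  scales: [", format(min(x$scales)), ",", format(max(x$scales)),
        "] (", length(x$scales), "radii )\n")
  }
  invisible(x)
}

#' Scan increment ratios for a Lipschitz constant
#'
#' Samples point pairs in a box and tracks the maximum of
#' `||F(x) - F(y)|| / ||x - y||` stratified by the decade of the pair
#' separation.  For a Lipschitz field the per-decade maxima stabilise at the
#' Lipschitz constant; for a field with a Holder (`alpha < 1`) singularity
#' inside the box they grow without bound as the separation shrinks.
#'
#' Pair separations are drawn log-uniformly so small decades are populated,
#' and half of the base points are drawn log-uniformly by radius around the
#' box center, which zooms the scan toward the center.  Center the box on
#' the suspected singular locus for a sharp diagnostic.
#'
#' @param field function or `landscape`, as in [holder_exponent()].
#' @param box numeric `c(xmin, xmax, ymin, ymax)`.
#' @param n_pairs number of sampled pairs.
#' @param seed RNG seed.
#' @param min_sep smallest pair separation sampled.
#' @return A `lipschitz_scan`: data frame with columns `decade` (lower bound
#'   of the separation decade), `max_ratio`, `n_pairs`.
#' @export
lipschitz_constant_scan <- function(field, box = c(-1, 1, -1, 1),
                                    n_pairs = 4000, seed = 1L,
                                    min_sep = 1e-6) {
  f <- .as_field(field)
  if (length(box) != 4L || box[2] <= box[1] || box[4] <= box[3])
    stop("'box' must be c(xmin, xmax, ymin, ymax) with positive extent",
         call. = FALSE)
  .check_scalar(n_pairs, "n_pairs", lower = 10, integer = TRUE)
  L <- min(box[2] - box[1], box[4] - box[3])
  ctr <- c(mean(box[1:2]), mean(box[3:4]))

  set.seed(seed)
  ratios <- numeric(n_pairs)
  seps <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    if (i %% 2L == 0L) {
      x <- c(stats::runif(1, box[1], box[2]), stats::runif(1, box[3], box[4]))
    } else {
      # zoomed base point: log-uniform radius around the box center
      rr <- 10^stats::runif(1, log10(min_sep), log10(L / 2))
      aa <- stats::runif(1, 0, 2 * pi)
      x <- ctr + rr * c(cos(aa), sin(aa))
    }
    d <- 10^stats::runif(1, log10(min_sep), log10(L / 2))
    th <- stats::runif(1, 0, 2 * pi)
    y <- x + d * c(cos(th), sin(th))
    ratios[i] <- .norm2(f(x) - f(y)) / d
    seps[i] <- d
  }
  dec <- floor(log10(seps))
  agg <- tapply(ratios, dec, max)
  out <- data.frame(decade = 10^as.numeric(names(agg)),
                    max_ratio = as.numeric(agg),
                    n_pairs = as.integer(table(dec)))
  out <- out[order(out$decade), ]
  rownames(out) <- NULL
  class(out) <- c("lipschitz_scan", "data.frame")
  out
}

#' Closed-form arrival time at a one-dimensional cusp
#'
#' For the deterministic dynamics `dx/dt = -k * sign(x) * |x|^beta` with
#' `0 < beta < 1`, the origin is reached in the finite time
#' `t* = |x0|^(1 - beta) / (k * (1 - beta))`.  This is the exact oracle for
#' the finite-time singularity property of sub-Lipschitz attraction; for
#' `beta >= 1` arrival takes infinite time and the request is rejected.
#'
#' @param x0 starting point (scalar).
#' @param k positive scale of the drift.
#' @param beta exponent in (0, 1).
#' @return The arrival time at 0.
#' @examples
#' arrival_time_closed_form(1, 1, 0.5)  # 2
#' @export
arrival_time_closed_form <- function(x0, k = 1, beta = 0.5) {
  .check_scalar(x0, "x0")
  .check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0 || beta >= 1)
    stop("'beta' must lie in (0, 1): for beta >= 1 there is no finite-time arrival",
         call. = FALSE)
  abs(x0)^(1 - beta) / (k * (1 - beta))
}
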