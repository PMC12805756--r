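# Replicate ensembles and distributional summaries.

#' Run an ensemble of independent replicate trajectories
#'
#' Runs `n_rep` trajectories of [sde_trajectory()] with per-replicate seeds
#' `base_seed + 0, base_seed + 1, ...`.  Replicate `i` is bitwise
#' reproducible in isolation: it equals a standalone run with
#' `seed = base_seed + i - 1`.  Only the terminal state, status and event
#' time of each replicate are retained.
#'
#' @param landscape a `landscape`.
#' @param config a [sim_config()] (its `seed` field is ignored; seeding is
#'   controlled by `base_seed`).
#' @param n_rep number of replicates, `>= 1`.
#' @param base_seed integer root seed.
#' @return An `ensemble_result` with `final_states` (n x 2 matrix),
#'   `statuses`, `event_times`, `n_rep`, `base_seed`, `config`.
#' @export
run_ensemble <- function(landscape, config = sim_config(), n_rep = 100,
                         base_seed = 1L) {
  stopifnot(inherits(landscape, "landscape"), inherits(config, "sim_config"))
  .check_scalar(n_rep, "n_rep", lower = 1, integer = TRUE)
  .check_scalar(base_seed, "base_seed", integer = TRUE)
  res <- .sim_engine_multi(landscape, config, as.integer(n_rep),
                           as.integer(base_seed))
  colnames(res$final_states) <- c("x", "y")
  structure(list(final_states = res$final_states, statuses = res$statuses,
                 event_times = res$event_times, n_rep = as.integer(n_rep),
                 base_seed = as.integer(base_seed), config = config,
                 landscape_name = landscape$name),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> ", x$n_rep, " replicates on '", x$landscape_name,
      "' (base seed ", x$base_seed, ")\n", sep = "")
  print(table(status = x$statuses))
  invisible(x)
}

#' @export
summary.ensemble_result <- function(object, ...) {
  comp <- object$statuses == "completed"
  out <- list(n_rep = object$n_rep,
              status_counts = table(object$statuses),
              final_mean = colMeans(object$final_states[comp, , drop = FALSE]),
              final_var = apply(object$final_states[comp, , drop = FALSE], 2,
                                stats::var),
              extinction = extinction_time_stats(object))
  class(out) <- "summary.ensemble_result"
  out
}

#' @export
print.summary.ensemble_result <- function(x, ...) {
  cat("Ensemble of", x$n_rep, "replicates\n")
  print(x$status_counts)
  cat("completed-replicate final mean: (",
      paste(format(x$final_mean, digits = 4), collapse = ", "), ")\n")
  invisible(x)
}

#' Uniform-bin histogram of a trait
#'
#' @param values numeric vector.
#' @param n_bins number of uniform bins (`>= 2`).
#' @param limits bin range `c(lo, hi)`; values outside are clamped into the
#'   end bins so the counts always sum to the number of contributing values.
#' @param label axis label.
#' @return A `trait_histogram` with `edges`, `counts`, `mids`, `label`.
#' @export
trait_histogram <- function(values, n_bins = 60, limits = range(values),
                            label = "trait") {
  .check_scalar(n_bins, "n_bins", lower = 2, integer = TRUE)
  if (length(values) < 1L) stop("no values to bin", call. = FALSE)
  if (limits[2] <= limits[1]) stop("'limits' must have positive width", call. = FALSE)
  edges <- seq(limits[1], limits[2], length.out = n_bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(edges = edges, counts = counts,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 label = label),
            class = "trait_histogram")
}

#' @export
print.trait_histogram <- function(x, ...) {
  cat("<trait_histogram> ", length(x$counts), " bins over [",
      format(x$edges[1]), ", ", format(x$edges[length(x$edges)]), "], ",
      sum(x$counts), " observations\n", sep = "")
  invisible(x)
}

#' @export
plot.trait_histogram <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = round(x$mids, 2), xlab = x$label,
                    ylab = "count", ...)
  invisible(x)
}

# Moving average with shrinking windows at the edges.
.smooth_counts <- function(counts, bandwidth) {
  n <- length(counts)
  half <- (bandwidth - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half + (bandwidth - 1L) %% 2L)
    mean(counts[lo:hi])
  }, 0)
}

# scipy-style peak prominence: height above the highest of the two lowest
# points separating the peak from higher ground (or the signal edge).
.peak_prominences <- function(s, peaks) {
  vapply(peaks, function(p) {
    lmin <- s[p]
    i <- p
    while (i > 1L && s[i - 1L] <= s[p]) {
      i <- i - 1L
      if (s[i] < lmin) lmin <- s[i]
    }
    rmin <- s[p]
    j <- p
    n <- length(s)
    while (j < n && s[j + 1L] <= s[p]) {
      j <- j + 1L
      if (s[j] < rmin) rmin <- s[j]
    }
    left_base <- if (i == 1L && s[1L] <= s[p]) lmin else lmin
    right_base <- if (j == n && s[n] <= s[p]) rmin else rmin
    s[p] - max(left_base, right_base)
  }, 0)
}

#' Count modes of a histogram
#'
#' Smooths the counts with a moving average of `bandwidth` bins and counts
#' the local maxima whose prominence exceeds `min_prominence` times the
#' global maximum of the smoothed counts.  Deterministic: no randomness is
#' involved.
#'
#' @param hist a [trait_histogram()] with at least 20 bins.
#' @param bandwidth moving-average width, in bins.
#' @param min_prominence prominence threshold, as a fraction of the global
#'   smoothed maximum.
#' @return Integer mode count; the accepted mode locations (bin mids) and
#'   heights are attached as attributes `"locations"` and `"heights"`.
#' @export
count_modes <- function(hist, bandwidth = 3, min_prominence = 0.1) {
  stopifnot(inherits(hist, "trait_histogram"))
  if (length(hist$counts) < 20L)
    stop("mode counting needs at least 20 bins", call. = FALSE)
  if (sum(hist$counts) == 0L) stop("empty histogram", call. = FALSE)
  .check_scalar(bandwidth, "bandwidth", lower = 1, integer = TRUE)
  s <- .smooth_counts(hist$counts, as.integer(bandwidth))
  n <- length(s)
  # local maxima, collapsing plateaus to their first index
  cand <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    left_ok <- i == 1L || s[i - 1L] < s[i]
    right_ok <- j == n || s[j + 1L] < s[i]
    if (left_ok && right_ok && s[i] > 0) cand <- c(cand, i)
    i <- j + 1L
  }
  if (!length(cand)) return(structure(0L, locations = numeric(0), heights = numeric(0)))
  prom <- .peak_prominences(s, cand)
  keep <- prom > min_prominence * max(s)
  structure(sum(keep),
            locations = hist$mids[cand[keep]],
            heights = s[cand[keep]])
}

#' Basin occupancy fractions for a double-well ensemble
#'
#' Classifies each completed replicate by the sign of its final `x`
#' coordinate relative to the watershed (left basin `x < 0`, right basin
#' `x > 0`); replicates landing exactly on the watershed are reported
#' separately as unresolved.
#'
#' @param ensemble an `ensemble_result` run on a double-well landscape.
#' @param watershed x-coordinate of the separating ridge (0 for the
#'   canonical family).
#' @return A list with `left`, `right` (fractions over resolved completed
#'   replicates), `n_resolved`, `n_unresolved`, `defined`.
#' @export
branch_fractions <- function(ensemble, watershed = 0) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  fx <- ensemble$final_states[ensemble$statuses == "completed", 1]
  n_unres <- sum(fx == watershed)
  res <- fx[fx != watershed]
  if (!length(res)) {
    warning("all replicates unresolved: no basin assignment possible")
    return(list(left = NA_real_, right = NA_real_, n_resolved = 0L,
                n_unresolved = n_unres, defined = FALSE))
  }
  list(left = mean(res < watershed), right = mean(res > watershed),
       n_resolved = length(res), n_unresolved = n_unres, defined = TRUE)
}

#' Escape-time statistics of an ensemble
#'
#' Summaries are computed over the replicates with `escaped` status only;
#' the escaped count is reported alongside so censoring by the step horizon
#' stays explicit.
#'
#' @param ensemble an `ensemble_result`.
#' @return A list with `n_escaped`, `mean`, `median`, `max`, `defined`.
#' @export
extinction_time_stats <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  tt <- ensemble$event_times[ensemble$statuses == "escaped"]
  if (!length(tt)) {
    return(list(n_escaped = 0L, mean = NA_real_, median = NA_real_,
                max = NA_real_, defined = FALSE))
  }
  list(n_escaped = length(tt), mean = mean(tt), median = stats::median(tt),
       max = max(tt), defined = TRUE)
}

#' Boltzmann stationary density on a grid
#'
#' For a gradient landscape with constant isotropic diffusion `D`, the
#' stationary density of the dynamics is proportional to `exp(-U / D)`.
#' This analytic oracle evaluates it on a lattice and normalises it to sum
#' to one.  The one-dimensional form evaluates `U` along `y = center_y`,
#' which equals the x-marginal for families whose potential separates in x
#' and y (quadratic, double well).
#'
#' @param landscape a gradient `landscape` (`has_potential = TRUE`).
#' @param D positive diffusion constant.
#' @param x grid of x values.
#' @param y optional grid of y values; if supplied a 2-D density matrix is
#'   returned.
#' @return For the 1-D form, a data frame with columns `x`, `density`; for
#'   the 2-D form, a list with `x`, `y` and the density matrix `density`
#'   (rows index `x`).
#' @export
stationary_density_oracle <- function(landscape, D, x, y = NULL) {
  stopifnot(inherits(landscape, "landscape"))
  if (!landscape$has_potential)
    stop("the Boltzmann oracle requires a gradient landscape", call. = FALSE)
  .check_scalar(D, "D", lower = 0, strict_lower = TRUE)
  if (is.null(y)) {
    U <- potential(landscape, cbind(x, landscape$center[2]))
    dens <- exp(-(U - min(U)) / D)
    return(data.frame(x = x, density = dens / sum(dens)))
  }
  g <- expand.grid(x = x, y = y, KEEP.OUT.ATTRS = FALSE)
  U <- potential(landscape, cbind(g$x, g$y))
  dens <- exp(-(U - min(U)) / D)
  list(x = x, y = y,
       density = matrix(dens / sum(dens), nrow = length(x)))
}

#' Export ensemble outputs
#'
#' Writes `<prefix>_final_states.tsv` (replicate, status, event time, final
#' x and y) and `<prefix>_summary.json`.
#'
#' @param ensemble an `ensemble_result`.
#' @param prefix path prefix.
#' @return The prefix, invisibly.
#' @export
write_ensemble <- function(ensemble, prefix) {
  df <- data.frame(replicate = seq_len(ensemble$n_rep),
                   status = ensemble$statuses,
                   t_event = ensemble$event_times,
                   x = ensemble$final_states[, 1],
                   y = ensemble$final_states[, 2])
  .write_tsv(df, paste0(prefix, "_final_states.tsv"))
  ext <- extinction_time_stats(ensemble)
  .write_json(list(landscape = ensemble$landscape_name,
                   n_rep = ensemble$n_rep, base_seed = ensemble$base_seed,
                   status_counts = as.list(table(ensemble$statuses)),
                   extinction = ext[c("n_escaped", "mean", "median", "max")],
                   config = unclass(ensemble$config)),
              paste0(prefix, "_summary.json"))
  invisible(prefix)
}

#' Export a histogram as TSV
#'
#' Columns: `bin_lo`, `bin_hi`, `mid`, `count`.
#'
#' @param hist a [trait_histogram()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_histogram <- function(hist, file) {
  n <- length(hist$counts)
  .write_tsv(data.frame(bin_lo = hist$edges[-(n + 1L)],
                        bin_hi = hist$edges[-1L],
                        mid = hist$mids, count = hist$counts), file)
  invisible(file)
}
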