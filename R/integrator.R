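# Euler-Maruyama integration with event detection.
#
# The discrete map is x_{k+1} = x_k + F(x_k) dt + sqrt(2 D dt) W_k with W_k a
# pair of independent standard normals, so the per-component noise standard
# deviation per step is sqrt(2 D dt).  The printed study settings dt = 0.01
# and per-step sd 0.1 correspond to D = 0.5.

#' Simulation configuration
#'
#' Bundles the integration settings.  The defaults reproduce the reference
#' settings: `dt = 0.01` and `D = 0.5`, i.e. per-step per-component noise
#' standard deviation `sqrt(2 * D * dt) = 0.1`.
#'
#' @param dt positive time step.
#' @param n_steps maximum number of steps.
#' @param D diffusion constant, `>= 0`; noise sd per step per component is
#'   `sqrt(2 * D * dt)`.
#' @param seed integer RNG seed for the trajectory.
#' @param x0 initial state, length-2 numeric.
#' @param escape_radius distance from the landscape's reference center beyond
#'   which the lineage is declared escaped (operational extinction).
#' @param step_guard maximum allowed `||F(x)|| * dt` before the run is
#'   declared numerically diverged.
#' @param absorb_tol radius around an attractive cusp within which a
#'   deterministic (`D = 0`) run is declared absorbed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(dt = 0.01, n_steps = 10000L, D = 0.5, seed = 1L,
                       x0 = c(0, 0), escape_radius = 10, step_guard = 100,
                       absorb_tol = 1e-6) {
  .check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  .check_scalar(n_steps, "n_steps", lower = 1, integer = TRUE)
  .check_scalar(D, "D", lower = 0)
  .check_scalar(seed, "seed", integer = TRUE)
  x0 <- .check_vec2(x0, "x0")
  .check_scalar(escape_radius, "escape_radius", lower = 0, strict_lower = TRUE)
  .check_scalar(step_guard, "step_guard", lower = 0, strict_lower = TRUE)
  .check_scalar(absorb_tol, "absorb_tol", lower = 0)
  structure(list(dt = dt, n_steps = as.integer(n_steps), D = D,
                 seed = as.integer(seed), x0 = x0,
                 escape_radius = escape_radius, step_guard = step_guard,
                 absorb_tol = absorb_tol),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> dt =", x$dt, " n_steps =", x$n_steps, " D =", x$D,
      "(per-step sd", format(sqrt(2 * x$D * x$dt)), ")\n")
  cat("  seed =", x$seed, " x0 = (", paste(format(x$x0), collapse = ", "), ")",
      " escape_radius =", x$escape_radius, "\n")
  invisible(x)
}

#' One Euler-Maruyama step
#'
#' Pure function of its inputs: returns
#' `x + F(x) * dt + sqrt(2 * D * dt) * w`.
#'
#' @param landscape a `landscape`.
#' @param x current state, length-2.
#' @param config a [sim_config()].
#' @param w length-2 vector of standard normal draws.
#' @return The next state.
#' @export
em_step <- function(landscape, x, config, w) {
  x <- .check_vec2(x, "x")
  w <- .check_vec2(w, "w")
  FF <- drift(landscape, x)
  if (!all(is.finite(FF)))
    stop("non-finite drift at x = (", paste(format(x), collapse = ", "),
         "): the step diverges", call. = FALSE)
  x + FF * config$dt + sqrt(2 * config$D * config$dt) * w
}

# Core single-trajectory engine.  W is a 2 x n_steps matrix of standard
# normal draws (column k is used at step k) or NULL for noise-free runs.
.sim_engine_single <- function(landscape, config, W) {
  dt <- config$dt
  n <- config$n_steps
  sig <- sqrt(2 * config$D * dt)
  f <- .scalar_drift(landscape)
  ctr <- landscape$center
  attract_cusp <- landscape$family == "cusp" && !landscape$params$repulsive
  det_run <- is.null(W)

  states <- matrix(NA_real_, n + 1L, 2L)
  x1 <- config$x0[1]; x2 <- config$x0[2]
  states[1L, ] <- c(x1, x2)
  status <- "completed"
  t_event <- NA_real_
  k_last <- 0L
  for (k in seq_len(n)) {
    Fv <- f(x1, x2)
    nf <- sqrt(Fv[1] * Fv[1] + Fv[2] * Fv[2])
    if (!is.finite(nf) || nf * dt > config$step_guard) {
      status <- "diverged"
      t_event <- (k - 1L) * dt
      break
    }
    x1 <- x1 + Fv[1] * dt
    x2 <- x2 + Fv[2] * dt
    if (!det_run) {
      x1 <- x1 + sig * W[1L, k]
      x2 <- x2 + sig * W[2L, k]
    }
    states[k + 1L, ] <- c(x1, x2)
    k_last <- k
    d1 <- x1 - ctr[1]; d2 <- x2 - ctr[2]
    if (sqrt(d1 * d1 + d2 * d2) > config$escape_radius) {
      status <- "escaped"
      t_event <- k * dt
      break
    }
    if (det_run && attract_cusp) {
      c1 <- x1 - landscape$params$center[1]; c2 <- x2 - landscape$params$center[2]
      if (sqrt(c1 * c1 + c2 * c2) < config$absorb_tol) {
        status <- "absorbed"
        t_event <- k * dt
        break
      }
    }
  }
  states <- states[seq_len(k_last + 1L), , drop = FALSE]
  colnames(states) <- c("x", "y")
  structure(list(times = dt * (0:k_last), states = states, status = status,
                 t_event = t_event, seed = config$seed, config = config,
                 landscape_name = landscape$name),
            class = "sde_trajectory")
}

#' Simulate one stochastic trajectory
#'
#' Iterates the Euler-Maruyama map from `config$x0` for up to
#' `config$n_steps` steps or until an event: *escaped* when the distance
#' from the landscape's reference center exceeds `escape_radius` (the
#' operational model of extinction by ejection into unviable phenotype
#' space), *diverged* when a drift step exceeds `step_guard`, or *absorbed*
#' when a noise-free run reaches an attractive cusp within `absorb_tol`.
#' The run is bitwise reproducible given the landscape, configuration and
#' seed: all noise is drawn from `config$seed`, two consecutive standard
#' normals per step.
#'
#' @param landscape a `landscape`.
#' @param config a [sim_config()].
#' @return An `sde_trajectory` with elements `times`, `states` (matrix with
#'   columns `x`, `y`), `status` (one of `"completed"`, `"escaped"`,
#'   `"absorbed"`, `"diverged"`), `t_event`, `seed`, `config`.
#' @export
sde_trajectory <- function(landscape, config = sim_config()) {
  stopifnot(inherits(landscape, "landscape"), inherits(config, "sim_config"))
  W <- NULL
  if (config$D > 0) {
    set.seed(config$seed)
    W <- matrix(stats::rnorm(2L * config$n_steps), nrow = 2L)
  }
  .sim_engine_single(landscape, config, W)
}

#' Noise-free (deterministic) trajectory
#'
#' Runs the integrator with `D = 0` and no RNG consumption; used as an
#' oracle for relaxation, convergence and finite-time arrival properties.
#'
#' @param landscape a `landscape`.
#' @param x0 initial state.
#' @param dt positive step.
#' @param n_steps maximum step count.
#' @param escape_radius,absorb_tol as in [sim_config()].
#' @return An `sde_trajectory`.
#' @export
deterministic_solve <- function(landscape, x0, dt = 0.01, n_steps = 10000L,
                                escape_radius = 10, absorb_tol = 1e-6) {
  config <- sim_config(dt = dt, n_steps = n_steps, D = 0, seed = 0L, x0 = x0,
                       escape_radius = escape_radius, absorb_tol = absorb_tol)
  .sim_engine_single(landscape, config, NULL)
}

#' First passage time into a region
#'
#' Returns the first recorded time whose state satisfies `region`, or `NA`
#' if none does.  The lookup uses the recorded grid only; no interpolation
#' between steps is attempted.
#'
#' @param trajectory an `sde_trajectory`.
#' @param region predicate: a function of a length-2 state returning `TRUE`
#'   or `FALSE`.
#' @return A time, or `NA_real_`.
#' @export
first_passage_time <- function(trajectory, region) {
  stopifnot(inherits(trajectory, "sde_trajectory"), is.function(region))
  for (i in seq_along(trajectory$times)) {
    if (isTRUE(region(trajectory$states[i, ]))) return(trajectory$times[i])
  }
  NA_real_
}

#' @export
print.sde_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("<sde_trajectory> on '", x$landscape_name, "': ", n, " states over t = [0, ",
      format(x$times[n]), "]\n", sep = "")
  cat("  status: ", x$status,
      if (!is.na(x$t_event)) paste0(" at t = ", format(x$t_event)) else "",
      "  (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.sde_trajectory <- function(x, ...) {
  s <- x$states
  cols <- grDevices::hcl.colors(nrow(s), "viridis")
  graphics::plot(s[, 1], s[, 2], type = "n", xlab = "x", ylab = "y",
                 main = paste0(x$landscape_name, " (", x$status, ")"), ...)
  graphics::segments(s[-nrow(s), 1], s[-nrow(s), 2], s[-1, 1], s[-1, 2],
                     col = cols[-1])
  invisible(x)
}

#' Write / read a trajectory as TSV plus a JSON sidecar
#'
#' `write_trajectory` writes `<prefix>.tsv` with columns
#' `step, t, x, y` (full round-trip precision) and `<prefix>.json` echoing
#' the configuration, status, event time and seed.  `read_trajectory`
#' reconstructs the trajectory object.
#'
#' @param trajectory an `sde_trajectory`.
#' @param prefix output path prefix.
#' @return `write_trajectory`: the prefix, invisibly. `read_trajectory`: an
#'   `sde_trajectory`.
#' @export
write_trajectory <- function(trajectory, prefix) {
  df <- data.frame(step = seq_along(trajectory$times) - 1L,
                   t = trajectory$times,
                   x = trajectory$states[, 1],
                   y = trajectory$states[, 2])
  .write_tsv(df, paste0(prefix, ".tsv"))
  meta <- list(landscape = trajectory$landscape_name,
               status = trajectory$status,
               t_event = if (is.na(trajectory$t_event)) NULL else trajectory$t_event,
               seed = trajectory$seed,
               config = unclass(trajectory$config))
  .write_json(meta, paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(prefix) {
  df <- .read_tsv(paste0(prefix, ".tsv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  cfg <- meta$config
  config <- sim_config(dt = cfg$dt, n_steps = cfg$n_steps, D = cfg$D,
                       seed = cfg$seed, x0 = as.numeric(cfg$x0),
                       escape_radius = cfg$escape_radius,
                       step_guard = cfg$step_guard, absorb_tol = cfg$absorb_tol)
  states <- cbind(x = df$x, y = df$y)
  structure(list(times = df$t, states = states, status = meta$status,
                 t_event = if (is.null(meta$t_event)) NA_real_ else meta$t_event,
                 seed = meta$seed, config = config,
                 landscape_name = meta$landscape),
            class = "sde_trajectory")
}

# Vectorised multi-replicate engine: advances n_rep trajectories in
# lockstep.  Replicate i consumes exactly the stream produced by
# set.seed(base_seed + i - 1), so it is bitwise identical to a standalone
# sde_trajectory() run with that seed (only final states are kept).
.sim_engine_multi <- function(landscape, config, n_rep, base_seed) {
  n <- config$n_steps
  dt <- config$dt
  sig <- sqrt(2 * config$D * dt)
  ctr <- landscape$center
  attract_cusp <- landscape$family == "cusp" && !landscape$params$repulsive
  noisy <- config$D > 0

  A <- NULL
  if (noisy) {
    A <- array(0, c(2L, n, n_rep))
    for (i in seq_len(n_rep)) {
      set.seed(base_seed + i - 1L)
      A[, , i] <- stats::rnorm(2L * n)
    }
  }
  X <- matrix(config$x0, n_rep, 2L, byrow = TRUE)
  status <- rep("completed", n_rep)
  t_event <- rep(NA_real_, n_rep)
  done <- logical(n_rep)

  for (k in seq_len(n)) {
    idx <- which(!done)
    if (!length(idx)) break
    Xa <- X[idx, , drop = FALSE]
    FF <- .drift_eval(landscape, Xa)
    nf <- .row_norms(FF)
    bad <- !is.finite(nf) | nf * dt > config$step_guard
    if (any(bad)) {
      b <- idx[bad]
      status[b] <- "diverged"
      t_event[b] <- (k - 1L) * dt
      done[b] <- TRUE
      idx <- idx[!bad]
      if (!length(idx)) next
      Xa <- Xa[!bad, , drop = FALSE]
      FF <- FF[!bad, , drop = FALSE]
    }
    Xn <- Xa + FF * dt
    if (noisy) {
      Wk <- t(matrix(A[, k, idx], nrow = 2L))
      Xn <- Xn + sig * Wk
    }
    X[idx, ] <- Xn
    d1 <- Xn[, 1] - ctr[1]; d2 <- Xn[, 2] - ctr[2]
    esc <- sqrt(d1 * d1 + d2 * d2) > config$escape_radius
    if (any(esc)) {
      e <- idx[esc]
      status[e] <- "escaped"
      t_event[e] <- k * dt
      done[e] <- TRUE
    }
    if (!noisy && attract_cusp) {
      c1 <- Xn[, 1] - landscape$params$center[1]
      c2 <- Xn[, 2] - landscape$params$center[2]
      ab <- sqrt(c1 * c1 + c2 * c2) < config$absorb_tol & !esc
      if (any(ab)) {
        aa <- idx[ab]
        status[aa] <- "absorbed"
        t_event[aa] <- k * dt
        done[aa] <- TRUE
      }
    }
  }
  list(final_states = X, statuses = status, event_times = t_event)
}
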