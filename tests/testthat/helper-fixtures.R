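# Small in-code fixtures and numerical helpers shared across tests.

# central-difference gradient of a scalar function R^2 -> R
num_grad <- function(f, x, h = 1e-5) {
  c((f(x + c(h, 0)) - f(x - c(h, 0))) / (2 * h),
    (f(x + c(0, h)) - f(x - c(0, h))) / (2 * h))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# hand-built ensemble result (final x values, optional statuses/event times)
make_test_ensemble <- function(final_x, statuses = rep("completed", length(final_x)),
                               event_times = rep(NA_real_, length(final_x))) {
  structure(list(final_states = cbind(x = final_x, y = numeric(length(final_x))),
                 statuses = statuses, event_times = event_times,
                 n_rep = length(final_x), base_seed = 1L,
                 config = sim_config(), landscape_name = "hand-built"),
            class = "ensemble_result")
}

# hand-built lineage tree: root splits at t = 1 into two daughters that sit
# at x = -1 and x = +1 until the horizon t = 3
make_two_leaf_tree <- function(t_split = 1, t_max = 3, x_left = -1, x_right = 1) {
  nodes <- data.frame(
    id = 1:3, parent = c(NA_integer_, 1L, 1L),
    birth = c(0, t_split, t_split),
    death = c(t_split, NA_real_, NA_real_),
    cause = c("split", "horizon", "horizon"),
    x_birth = c(0, x_left, x_right), y_birth = 0,
    x_end = c(0, x_left, x_right), y_end = 0)
  grid <- seq(0, t_max, by = 0.5)
  hist_of <- function(from, x) {
    tt <- grid[grid >= from]
    list(times = tt, x = rep(x, length(tt)), y = rep(0, length(tt)))
  }
  structure(list(nodes = nodes,
                 history = list(hist_of(0, 0), hist_of(t_split, x_left),
                                hist_of(t_split, x_right)),
                 t_max = t_max, truncated = FALSE, base_seed = 1L,
                 sample_times = grid),
            class = "lineage_tree")
}

# histogram with prescribed counts (via repeated bin-mid values)
make_count_histogram <- function(counts, lo = 0, hi = length(counts)) {
  edges <- seq(lo, hi, length.out = length(counts) + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  trait_histogram(rep(mids, counts), n_bins = length(counts),
                  limits = c(lo, hi))
}
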