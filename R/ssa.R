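# R interface to the compiled Gillespie simulator and snapshot-data tools.

ssa_args <- function(net, theta = NULL, t_end = NULL) {
  cm <- net$compiled
  k <- reaction_rates(net, theta)
  has_input <- any(cm$input_idx > 0L)
  input_bound <- rep(1, net$R)
  input_eval <- function(t) rep(1, net$R)
  if (has_input) {
    if (is.null(t_end)) stop("t_end needed to bound inputs", call. = FALSE)
    # per-reaction upper bound of the input factor over the horizon,
    # evaluated on a fine grid with 5% headroom (thinning envelope)
    grid <- seq(0, t_end, length.out = 512L)
    input_bound <- vapply(seq_len(net$R), function(r) {
      if (cm$input_idx[r] == 0L) return(1)
      max(net$inputs[[cm$input_idx[r]]](grid)) * 1.05
    }, numeric(1))
    if (any(input_bound <= 0)) {
      stop("input factors must be positive for SSA thinning", call. = FALSE)
    }
    input_eval <- function(t) input_factors(net, t)
  }
  list(nu = cm$nu, k = k, order = cm$order, i1 = cm$idx1 - 1L,
       i2 = cm$idx2 - 1L, omega_r = cm$omega_r, has_input = has_input,
       input_idx = cm$input_idx, input_bound = input_bound,
       input_eval = input_eval)
}

default_counts <- function(net, mu0) {
  round(net$compiled$omega_i * mu0)
}

#' Simulate one exact trajectory of the chemical master equation
#'
#' Gillespie direct method; statistically exact sampling of the CME path
#' measure. Time-dependent rate modifiers are handled by thinning against a
#' per-reaction upper bound of the input function.
#'
#' @param net a [reaction_network()].
#' @param n0 initial molecule counts (length M), or `NULL` to use
#'   `round(omega_i * mu0)`.
#' @param t_end end time (s), must be positive.
#' @param seed RNG seed (integer); `NULL` leaves the RNG state alone.
#' @param mu0 initial concentrations used when `n0` is `NULL`.
#' @param t0 start time.
#' @param theta optional parameter overrides.
#' @param max_events event cap guarding against runaway simulations.
#' @return A `"trajectory"`: list with `times` (event times, strictly
#'   increasing), `states` (event x species count matrix) and `seed`.
#' @export
simulate_trajectory <- function(net, n0 = NULL, t_end, seed = NULL,
                                mu0 = NULL, t0 = 0, theta = NULL,
                                max_events = 1e7) {
  stopifnot(t_end > t0)
  if (is.null(n0)) {
    if (is.null(mu0)) stop("supply n0 or mu0", call. = FALSE)
    n0 <- default_counts(net, mu0)
  }
  if (length(n0) != net$M || any(n0 < 0) || any(n0 != round(n0))) {
    stop("n0 must be non-negative integer counts of length M", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  a <- ssa_args(net, theta, t_end)
  res <- ssa_path_cpp(a$nu, as.numeric(n0), t0, t_end, a$k, a$order, a$i1,
                      a$i2, a$omega_r, a$has_input, a$input_idx,
                      a$input_bound, a$input_eval, max_events)
  colnames(res$states) <- net$species
  structure(list(times = res$times, states = res$states, seed = seed,
                 net = net),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("SSA trajectory: ", nrow(x$states) - 1, " reaction events over [",
      min(x$times), ", ", max(x$times), "] s\n", sep = "")
  invisible(x)
}

#' Generate a synthetic single-cell snapshot dataset
#'
#' For every timepoint `t_k`, `n_cells[k]` fresh, independent cells are
#' simulated from the initial condition and their observable concentrations
#' recorded. Trajectory identity is deliberately destroyed across timepoints:
#' these are population snapshots, not time-lapse data.
#'
#' @param net a [reaction_network()].
#' @param mu0 initial mean concentrations; cells start deterministically at
#'   `round(omega_i * mu0)` molecules unless `init_draw` is given.
#' @param timepoints sorted vector of snapshot times (s).
#' @param n_cells number of cells per timepoint (scalar or per-timepoint).
#' @param seed RNG seed.
#' @param theta optional parameter overrides.
#' @param replicate replicate label stored with the data.
#' @param init_draw optional function returning one cell's initial counts
#'   (distributed initial conditions).
#' @param max_events per-cell event cap.
#' @return A `"snapshot_data"` data.frame with columns `time`, `observable`,
#'   `cell_id`, `value`, `replicate`; attributes record volume, parameters
#'   and seed.
#' @export
simulate_snapshot_ensemble <- function(net, mu0, timepoints, n_cells,
                                       seed = NULL, theta = NULL,
                                       replicate = 1L, init_draw = NULL,
                                       max_events = 1e7) {
  if (is.unsorted(timepoints)) stop("timepoints must be sorted", call. = FALSE)
  n_cells <- rep_len(n_cells, length(timepoints))
  if (any(n_cells < 1)) stop("n_cells must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  a <- ssa_args(net, theta, max(timepoints))
  n0 <- default_counts(net, mu0)
  random_init <- !is.null(init_draw)
  snaps <- ssa_snapshot_cpp(a$nu, as.numeric(n0), 0, timepoints,
                            as.integer(n_cells), a$k, a$order, a$i1, a$i2,
                            a$omega_r, a$has_input, a$input_idx,
                            a$input_bound, a$input_eval, random_init,
                            init_draw %||% function() numeric(0), max_events)
  omega_i <- net$compiled$omega_i
  pars <- net$parameters
  if (!is.null(theta)) pars[names(theta)] <- theta
  rows <- list()
  for (kk in seq_along(timepoints)) {
    x <- snaps[[kk]] / rep(omega_i, each = n_cells[kk])  # concentrations
    for (ob in net$observables) {
      w <- numeric(net$M)
      w[match(names(ob$weights), net$species)] <- ob$weights
      val <- resolve_param(ob$scale, pars) * drop(x %*% w) +
        resolve_param(ob$offset, pars)
      rows[[length(rows) + 1L]] <- data.frame(
        time = timepoints[kk], observable = ob$name,
        cell_id = seq_len(n_cells[kk]), value = val,
        replicate = replicate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "volume") <- net$volume
  attr(out, "theta") <- if (is.null(theta)) net$parameters else
    replace(net$parameters, names(theta), theta)
  attr(out, "seed") <- seed
  class(out) <- c("snapshot_data", "data.frame")
  out
}

#' Add replicate-level technical noise to a snapshot dataset
#'
#' Technical noise depends on the replicate, not the cell: one normal draw
#' `epsilon ~ N(0, sigma2)` per (observable, timepoint, replicate) is added
#' to all cells of that replicate, leaving within-replicate sample variances
#' unchanged.
#'
#' @param data a [simulate_snapshot_ensemble()] result.
#' @param noise named numeric vector of technical variances per observable
#'   (recycled if unnamed scalar). Variances must be non-negative.
#' @param seed RNG seed.
#' @return the dataset with shifted values.
#' @export
apply_technical_noise <- function(data, noise, seed = NULL) {
  if (any(noise < 0)) stop("noise variances must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- unique(data$observable)
  if (is.null(names(noise))) {
    noise <- stats::setNames(rep_len(noise, length(obs)), obs)
  }
  key <- interaction(data$observable, data$time, data$replicate, drop = TRUE)
  for (g in levels(key)) {
    sel <- key == g
    ob <- data$observable[sel][1]
    s2 <- if (ob %in% names(noise)) noise[[ob]] else 0
    if (s2 > 0) data$value[sel] <- data$value[sel] + stats::rnorm(1, 0, sqrt(s2))
  }
  data
}

#' Write / read snapshot data as tidy CSV
#'
#' Columns: `time, observable, cell_id, value, replicate`.
#' @param data a snapshot dataset.
#' @param path file path.
#' @export
write_snapshot_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot_csv
#' @export
read_snapshot_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("snapshot_data", "data.frame")
  out
}
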