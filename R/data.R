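# Snapshot summary statistics and the estimator-variance model.

#' Summarize single-cell snapshot data
#'
#' Computes, per (observable, timepoint, replicate), the sample mean, the
#' 1/N sample variance, and the 1/N fourth central moment:
#' \deqn{\hat\mu = \frac1N \sum_j y^{(j)},\quad
#'       \hat\Sigma = \frac1N \sum_j (y^{(j)}-\hat\mu)^2,\quad
#'       \hat\Sigma_{4} = \frac1N \sum_j (y^{(j)}-\hat\mu)^4.}
#'
#' @param data a `snapshot_data` data.frame (columns `time`, `observable`,
#'   `cell_id`, `value`, `replicate`).
#' @param require_variance if `TRUE` (default), timepoints with fewer than 2
#'   cells raise an insufficient-sample error; otherwise their variance
#'   fields are `NA` and flagged.
#' @return A `"snapshot_summary"` data.frame with columns `time`,
#'   `observable`, `mean`, `var`, `m4`, `n_cells`, `replicate`.
#' @export
summarize_snapshots <- function(data, require_variance = TRUE) {
  sp <- split(seq_len(nrow(data)),
              list(data$observable, data$time, data$replicate), drop = TRUE)
  rows <- lapply(sp, function(ii) {
    y <- data$value[ii]
    N <- length(y)
    if (N < 2 && require_variance) {
      stop("insufficient sample: N < 2 cells at time ", data$time[ii][1],
           " for observable ", data$observable[ii][1], call. = FALSE)
    }
    m <- mean(y)
    d <- y - m
    data.frame(time = data$time[ii][1], observable = data$observable[ii][1],
               mean = m,
               var = if (N >= 2) mean(d^2) else NA_real_,
               m4 = if (N >= 2) mean(d^4) else NA_real_,
               n_cells = N, replicate = data$replicate[ii][1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$observable, out$time, out$replicate), ]
  rownames(out) <- NULL
  class(out) <- c("snapshot_summary", "data.frame")
  out
}

#' Technical-noise model
#'
#' Mode (a): a fixed technical variance per observable (estimated from
#' replicates). Mode (b): the technical variance is an estimated parameter;
#' name the parameter holding `sigma2_T` for the observable (positive,
#' optimized on the log scale, equivalent to the 10^theta parameterization).
#'
#' @param variances named vector: numeric entries are fixed technical
#'   variances, character entries name estimated parameters.
#' @param mode `"snapshot"` (statistical + technical variance) or
#'   `"population_average"` (the statistical term is dropped: population
#'   averages pool so many cells that finite-sample uncertainty is ignored
#'   and only the variance-of-the-mean block exists).
#' @return A `"noise_model"`.
#' @export
noise_model <- function(variances = 0, mode = c("snapshot",
                                                "population_average")) {
  mode <- match.arg(mode)
  fixed <- !is.character(variances)
  if (fixed && any(unlist(variances) < 0)) {
    stop("technical variances must be >= 0", call. = FALSE)
  }
  structure(list(variances = variances, mode = mode), class = "noise_model")
}

noise_variance <- function(noise, observable, theta = NULL) {
  v <- noise$variances
  x <- if (!is.null(names(v)) && observable %in% names(v)) v[[observable]]
       else if (length(v) == 1L) v[[1]] else 0
  if (is.character(x)) {
    if (is.null(theta) || !x %in% names(theta)) {
      stop("noise parameter ", x, " not in theta", call. = FALSE)
    }
    unname(theta[[x]])
  } else {
    x
  }
}

#' Estimator variances of snapshot summaries
#'
#' Implements the sampling-variance model of the mean and variance
#' estimators:
#' \deqn{\sigma^2_{\hat\mu} = \frac1N \hat\Sigma + \sigma^2_{\hat\mu,T}(\theta),
#' \qquad \sigma^2_{\hat\Sigma} = \frac1N\Big(\hat\Sigma_4 -
#'   \frac{N-3}{N-1}\hat\Sigma^2\Big),}
#' using the sample-based plug-in moments. In population-average mode the
#' statistical term is dropped (`sigma2_mean = sigma2_T`) and no variance
#' block is produced.
#'
#' @param summary a [summarize_snapshots()] result.
#' @param noise a [noise_model()] (or a bare numeric/named vector of fixed
#'   technical variances).
#' @param theta parameters, needed when technical variances are estimated.
#' @param floor lower floor applied (with a warning) when a computed
#'   estimator variance is non-positive.
#' @return the summary with columns `sigma2_mean` and `sigma2_var` added
#'   (`sigma2_var` is `NA` in population-average mode).
#' @export
estimator_variances <- function(summary, noise = noise_model(0),
                                theta = NULL, floor = 1e-12) {
  if (!inherits(noise, "noise_model")) noise <- noise_model(noise)
  s2T <- vapply(summary$observable, function(ob) {
    noise_variance(noise, ob, theta)
  }, numeric(1))
  N <- summary$n_cells
  if (noise$mode == "population_average") {
    summary$sigma2_mean <- s2T
    summary$sigma2_var <- NA_real_
  } else {
    summary$sigma2_mean <- summary$var / N + s2T
    summary$sigma2_var <- (summary$m4 - (N - 3) / (N - 1) * summary$var^2) / N
  }
  for (col in c("sigma2_mean", "sigma2_var")) {
    bad <- !is.na(summary[[col]]) & summary[[col]] <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive ", col, " value(s) floored at ",
              floor, call. = FALSE)
      summary[[col]][bad] <- floor
    }
  }
  summary
}

#' Write / read a snapshot summary as CSV
#'
#' Canonical data input to inference. Columns: `time, observable, mean, var,
#' m4, n_cells, sigma2_mean, sigma2_var, replicate`.
#' @param summary a snapshot summary.
#' @param path file path.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("snapshot_summary", "data.frame")
  out
}
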