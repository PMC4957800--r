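# Model selection (AIC/BIC, Akaike weights) and chi-square model rejection.

#' Akaike and Bayesian information criteria with model weights
#'
#' For each fitted model, `AIC = -2 log L(theta_hat) + 2 n_theta` (the number
#' of estimated parameters, nuisance parameters included) and the Akaike
#' weight `w = exp(-dAIC/2) / sum exp(-dAIC/2)` relative to the best model.
#' BIC (`-2 log L + n_theta log n_data`) and BIC weights are computed
#' alongside as a reliability cross-check.
#'
#' `log L` is recovered from the fitted objective as `-J(theta_hat)`.
#'
#' @param fits list of [fit()] results on the identical dataset.
#' @param labels model labels (default the method tags).
#' @return A `"model_score"` data.frame with columns `label`, `logL`,
#'   `n_par`, `n_data`, `AIC`, `dAIC`, `w_AIC`, `BIC`, `w_BIC`.
#' @export
akaike_weights <- function(fits, labels = NULL) {
  if (inherits(fits, "estimation_result")) fits <- list(fits)
  labels <- labels %||% vapply(fits, function(f) f$spec$method, character(1))
  datasets <- lapply(fits, function(f) {
    d <- f$spec$data
    d[c("time", "observable", "mean", "n_cells")]
  })
  if (length(fits) > 1) {
    for (q in 2:length(fits)) {
      if (!isTRUE(all.equal(datasets[[1]], datasets[[q]],
                            check.attributes = FALSE))) {
        stop("all fits must use the identical dataset", call. = FALSE)
      }
    }
  }
  logL <- vapply(fits, function(f) -f$J, numeric(1))
  n_par <- vapply(fits, function(f) length(f$spec$estimate), numeric(1))
  n_data <- vapply(fits, function(f) n_datapoints(f$spec), numeric(1))
  AIC <- -2 * logL + 2 * n_par
  BIC <- -2 * logL + n_par * log(n_data)
  dA <- AIC - min(AIC)
  wA <- exp(-dA / 2) / sum(exp(-dA / 2))
  dB <- BIC - min(BIC)
  wB <- exp(-dB / 2) / sum(exp(-dB / 2))
  out <- data.frame(label = labels, logL = logL, n_par = n_par,
                    n_data = n_data, AIC = AIC, dAIC = dA, w_AIC = wA,
                    BIC = BIC, w_BIC = wB, stringsAsFactors = FALSE)
  class(out) <- c("model_score", "data.frame")
  out
}

# Number of fitted data points: mean entries, plus variance entries when the
# variance block is part of the likelihood (documented convention,
# configurable through the objective's data mode).
n_datapoints <- function(spec) {
  n <- nrow(spec$data)
  if (spec$data_mode == "mean+variance") n <- 2L * n
  n
}

#' Chi-square goodness-of-fit model rejection
#'
#' The sum of squared residuals at the optimum,
#' \deqn{\chi^2(\hat\theta) = \sum r_\mu^2 + \sum r_\Sigma^2,}
#' is referred to a chi-square distribution with `n_data - n_par` degrees of
#' freedom; the model is rejected when the upper-tail p-value falls below
#' `alpha` (default 0.01).
#'
#' @param fit an [fit()] result.
#' @param spec the objective specification (defaults to the fit's own).
#' @param alpha rejection confidence level (default 0.01).
#' @return A `"rejection_verdict"`: list with `chisq`, `dof`, `p_value`,
#'   `alpha`, `reject`.
#' @export
chi_square_rejection <- function(fit, spec = NULL, alpha = 0.01) {
  spec <- spec %||% fit$spec
  e <- eval_objective(spec, fit$theta_hat)
  chisq <- sum(e$residuals_mean^2)
  if (!is.null(e$residuals_var)) chisq <- chisq + sum(e$residuals_var^2)
  dof <- n_datapoints(spec) - length(spec$estimate)
  if (dof <= 0) {
    stop("chi-square test undefined: degrees of freedom <= 0", call. = FALSE)
  }
  p <- stats::pchisq(chisq, df = dof, lower.tail = FALSE)
  structure(list(chisq = chisq, dof = dof, p_value = p, alpha = alpha,
                 reject = p < alpha),
            class = "rejection_verdict")
}

#' @export
print.rejection_verdict <- function(x, ...) {
  cat("chi-square rejection test: chi2 = ", format(x$chisq, digits = 6),
      ", dof = ", x$dof, ", p = ", format(x$p_value, digits = 4),
      if (x$reject) " -> REJECTED" else " -> not rejected",
      " (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}
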