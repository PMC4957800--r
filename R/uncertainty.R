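# Profile-likelihood and MCMC-based uncertainty quantification.
#
# Both tools operate on the optimization scale x (x = log theta for model
# objective specifications; raw coordinates for custom objectives supplied as
# a list). A custom objective is a list with fields `fobj` (function of x),
# optional `fgrad`, `lower`, `upper` (bounds on x) and `names`.

as_objective_interface <- function(spec) {
  if (inherits(spec, "objective_spec")) {
    list(
      fobj = function(x) {
        th <- stats::setNames(exp(x), spec$estimate)
        J <- eval_objective(spec, th)$J
        if (!is.finite(J)) 1e12 else J
      },
      fgrad = function(x) {
        th <- stats::setNames(exp(x), spec$estimate)
        eval_objective(spec, th, need_grad = TRUE)$grad
      },
      lower = log(spec$lower), upper = log(spec$upper),
      names = spec$estimate, to_natural = exp
    )
  } else {
    stopifnot(is.function(spec$fobj))
    list(fobj = spec$fobj, fgrad = spec$fgrad,
         lower = spec$lower, upper = spec$upper,
         names = spec$names %||% paste0("p", seq_along(spec$lower)),
         to_natural = identity)
  }
}

#' Profile likelihood of one parameter
#'
#' Steps the profiled parameter outward from the optimum in both directions
#' with adaptive step control (targeting an objective increase of about 0.1
#' per step), re-optimizing all remaining parameters (warm-started) at every
#' grid point, until the profile exceeds the chi-square threshold of the
#' highest requested level or a bound is reached. Flat profiles (structural
#' non-identifiability) are detected and flagged.
#'
#' @param spec an [objective_spec()] or a custom objective list.
#' @param fit an [fit()] result (or a list with `xi_hat` and `J`).
#' @param param parameter name or index.
#' @param levels confidence levels for later interval extraction.
#' @param step_target target objective increase per step (default 0.1).
#' @param min_step,max_step bounds on the step (optimization scale).
#' @param max_points per-direction cap on grid points.
#' @return A `"profile_result"`: data.frame `grid` (columns `value`
#'   (natural scale), `x`, `J`, `ok`), plus the optimum, flags per side and
#'   interval endpoints per level.
#' @export
profile_likelihood <- function(spec, fit, param,
                               levels = c(0.8, 0.9, 0.95, 0.99),
                               step_target = 0.1, min_step = 1e-3,
                               max_step = 0.5, max_points = 200) {
  oi <- as_objective_interface(spec)
  i <- if (is.character(param)) match(param, oi$names) else param
  if (is.na(i)) stop("unknown parameter: ", param, call. = FALSE)
  x_hat <- fit$xi_hat %||% fit$x_hat
  J0 <- fit$J
  L <- length(x_hat)
  thr <- stats::qchisq(max(levels), df = 1) / 2
  Jstop <- J0 + thr + 0.5

  reopt <- function(xi_i, warm) {
    if (L == 1L) {
      return(list(J = oi$fobj(xi_i), warm = warm, ok = TRUE))
    }
    ins <- function(rest) append(rest, xi_i, after = i - 1L)
    fo <- function(rest) oi$fobj(ins(rest))
    gr <- if (!is.null(oi$fgrad)) function(rest) oi$fgrad(ins(rest))[-i]
    res <- try(stats::nlminb(warm, fo, gradient = gr,
                             lower = oi$lower[-i], upper = oi$upper[-i],
                             control = list(rel.tol = 1e-8)), silent = TRUE)
    if (inherits(res, "try-error")) {
      return(list(J = NA_real_, warm = warm, ok = FALSE))
    }
    list(J = res$objective, warm = res$par, ok = TRUE)
  }

  # initial step calibrated to the local curvature when available
  step0 <- 0.05
  if (!is.null(fit$fim)) {
    cii <- fit$fim[i, i]
    if (is.finite(cii) && cii > 0) {
      step0 <- sqrt(2 * step_target / cii)
    }
  }
  step0 <- min(max(step0, min_step), max_step)

  grid <- data.frame(x = x_hat[i], J = J0, ok = TRUE)
  side_flags <- c(lower = FALSE, upper = FALSE)  # TRUE = flat/unbounded
  for (dir in c(-1, 1)) {
    step <- step0
    xi_i <- x_hat[i]
    warm <- x_hat[-i]
    Jprev <- J0
    for (q in seq_len(max_points)) {
      xi_prop <- xi_i + dir * step
      at_bound <- FALSE
      if (xi_prop <= oi$lower[i]) { xi_prop <- oi$lower[i]; at_bound <- TRUE }
      if (xi_prop >= oi$upper[i]) { xi_prop <- oi$upper[i]; at_bound <- TRUE }
      r <- reopt(xi_prop, warm)
      if (!r$ok) {
        # restart the inner optimization from the optimum, flag the point
        r <- reopt(xi_prop, x_hat[-i])
        r$ok <- FALSE
      }
      dJ <- if (is.na(r$J)) Inf else abs(r$J - Jprev)
      if (is.finite(dJ) && dJ > 4 * step_target && step > min_step &&
          !at_bound) {
        step <- max(step / 2, min_step)  # overshoot: retract and retry
        next
      }
      if (r$ok) warm <- r$warm
      xi_i <- xi_prop
      grid <- rbind(grid, data.frame(x = xi_i, J = r$J, ok = r$ok))
      if (is.na(r$J)) break
      Jprev <- r$J
      if (dJ < step_target / 4) step <- min(step * 2, max_step)
      if (r$J > Jstop) break
      if (at_bound) {
        if (r$J < J0 + stats::qchisq(min(levels), df = 1) / 2) {
          side_flags[if (dir < 0) "lower" else "upper"] <- TRUE
        }
        break
      }
    }
  }
  grid <- grid[order(grid$x), ]
  grid$value <- oi$to_natural(grid$x)
  rownames(grid) <- NULL
  prof <- structure(
    list(param = oi$names[i], index = i, grid = grid, J0 = J0,
         x_hat = x_hat[i], value_hat = oi$to_natural(x_hat[i]),
         flat = side_flags, levels = levels,
         log_scale = identical(oi$to_natural, exp),
         x_bounds = c(oi$lower[i], oi$upper[i]),
         bounds = oi$to_natural(c(oi$lower[i], oi$upper[i]))),
    class = "profile_result"
  )
  prof$intervals <- do.call(rbind, lapply(levels, function(lv) {
    ci <- profile_confidence_interval(prof, lv)
    data.frame(level = lv, lower = ci[1], upper = ci[2],
               lower_unbounded = attr(ci, "unbounded")[1],
               upper_unbounded = attr(ci, "unbounded")[2])
  }))
  prof
}

#' @export
print.profile_result <- function(x, ...) {
  cat("profile_result for ", x$param, ": ", nrow(x$grid), " grid points",
      if (any(x$flat)) " [flat profile: structural non-identifiability]"
      else "", "\n", sep = "")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Profile-likelihood confidence interval
#'
#' Endpoints where `2 * (J_profile - J_hat)` crosses the chi-square(1)
#' quantile of the requested level, linearly interpolated between grid
#' points. Sides that never cross are reported at the parameter bound and
#' flagged unbounded.
#'
#' @param profile a [profile_likelihood()] result.
#' @param level confidence level in (0, 1).
#' @return numeric `c(lower, upper)` on the natural parameter scale, with an
#'   attribute `unbounded` (two logicals).
#' @export
profile_confidence_interval <- function(profile, level) {
  thr <- profile$J0 + stats::qchisq(level, df = 1) / 2
  g <- profile$grid[profile$grid$ok & !is.na(profile$grid$J), ]
  ihat <- which.min(abs(g$x - profile$x_hat))
  unb <- c(FALSE, FALSE)
  cross <- function(seg, decreasing) {
    # seg ordered moving away from the optimum
    above <- which(seg$J > thr)
    if (!length(above)) return(NA_real_)
    q <- above[1]
    if (q == 1L) return(seg$x[1])
    x0 <- seg$x[q - 1]; x1 <- seg$x[q]
    J0 <- seg$J[q - 1]; J1 <- seg$J[q]
    x0 + (thr - J0) / (J1 - J0) * (x1 - x0)
  }
  lo_seg <- g[seq(ihat, 1L), ]
  hi_seg <- g[seq(ihat, nrow(g)), ]
  xlo <- cross(lo_seg)
  xhi <- cross(hi_seg)
  if (is.na(xlo)) { xlo <- profile$x_bounds[1]; unb[1] <- TRUE }
  if (is.na(xhi)) { xhi <- profile$x_bounds[2]; unb[2] <- TRUE }
  to_nat <- if (isTRUE(profile$log_scale)) exp else identity
  out <- c(to_nat(xlo), to_nat(xhi))
  attr(out, "unbounded") <- unb
  out
}

#' Delayed-rejection adaptive Metropolis (DRAM) posterior sampling
#'
#' Samples the posterior `p(theta | D) ~ L(theta)` under a log-uniform prior
#' over the parameter domain (uniform in `x = log theta`). The proposal
#' covariance adapts to the chain history (adaptive Metropolis) and each
#' rejected proposal is retried once at a scaled-down covariance (delayed
#' rejection).
#'
#' @param spec an [objective_spec()] or a custom objective list (see
#'   [profile_likelihood()]).
#' @param init initial point on the optimization scale (defaults to the
#'   midpoint of the domain; pass `fit$xi_hat` in practice).
#' @param n_samples samples kept after burn-in (default 1e5).
#' @param burnin burn-in length (default 1e4).
#' @param seed RNG seed.
#' @param adapt_start iteration at which covariance adaptation begins.
#' @param adapt_interval recompute the empirical covariance this often.
#' @param dr_scale delayed-rejection proposal shrinkage (default 0.2).
#' @param cov0 initial proposal covariance (default scaled identity).
#' @return A `"posterior_chain"`: matrix `samples` (x scale), `theta`
#'   (natural scale), log-posterior values, acceptance rate, seed, settings.
#' @export
run_mcmc <- function(spec, init = NULL, n_samples = 1e5, burnin = 1e4,
                     seed = NULL, adapt_start = 1e3, adapt_interval = 100,
                     dr_scale = 0.2, cov0 = NULL) {
  oi <- as_objective_interface(spec)
  L <- length(oi$lower)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(init, "estimation_result")) {
    # start at the MLE with the inverse FIM as initial proposal covariance
    if (is.null(cov0)) {
      ch <- try(chol(init$fim), silent = TRUE)
      if (!inherits(ch, "try-error")) cov0 <- chol2inv(ch)
    }
    init <- init$xi_hat
  }
  x <- init %||% (oi$lower + oi$upper) / 2
  logpost <- function(x) {
    if (any(x < oi$lower | x > oi$upper)) return(-Inf)
    J <- try(oi$fobj(x), silent = TRUE)
    if (inherits(J, "try-error") || !is.finite(J)) return(-Inf)
    -J
  }
  lp <- logpost(x)
  if (!is.finite(lp)) stop("initial point has zero posterior", call. = FALSE)
  n_total <- n_samples + burnin
  out <- matrix(NA_real_, n_total, L)
  lps <- numeric(n_total)
  sd0 <- 2.38^2 / L
  C <- cov0 %||% diag(pmin((oi$upper - oi$lower) / 20, 0.5)^2, L)
  cholC <- chol(sd0 * C)
  acc <- 0
  eps <- 1e-10
  mvn_draw <- function(center, ch) center + drop(stats::rnorm(L) %*% ch)
  for (it in seq_len(n_total)) {
    y1 <- mvn_draw(x, cholC)
    lp1 <- logpost(y1)
    a1 <- min(1, exp(lp1 - lp))
    if (stats::runif(1) < a1) {
      x <- y1; lp <- lp1; acc <- acc + 1
    } else {
      # one delayed-rejection stage at a shrunken proposal
      ch2 <- cholC * sqrt(dr_scale)
      y2 <- mvn_draw(x, ch2)
      lp2 <- logpost(y2)
      if (is.finite(lp2)) {
        Cinv <- chol2inv(cholC)
        qd <- function(a, b) {
          d <- a - b
          exp(-0.5 * drop(t(d) %*% Cinv %*% d))
        }
        a1_rev <- min(1, exp(lp1 - lp2))
        num <- exp(lp2) * qd(y1, y2) * (1 - a1_rev)
        den <- exp(lp) * qd(y1, x) * (1 - a1)
        a2 <- if (den > 0) min(1, num / den) else 0
        if (stats::runif(1) < a2) {
          x <- y2; lp <- lp2; acc <- acc + 1
        }
      }
    }
    out[it, ] <- x
    lps[it] <- lp
    if (it >= adapt_start && it %% adapt_interval == 0L) {
      Ce <- stats::cov(out[seq_len(it), , drop = FALSE]) + eps * diag(L)
      ch <- try(chol(sd0 * Ce), silent = TRUE)
      if (!inherits(ch, "try-error")) cholC <- ch
    }
  }
  keep <- seq.int(burnin + 1L, n_total)
  samples <- out[keep, , drop = FALSE]
  colnames(samples) <- oi$names
  structure(
    list(samples = samples, theta = oi$to_natural(samples),
         log_posterior = lps[keep], acceptance_rate = acc / n_total,
         burnin = burnin, n_samples = n_samples, seed = seed,
         prior = "log-uniform over the parameter domain",
         lower = oi$lower, upper = oi$upper),
    class = "posterior_chain"
  )
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("posterior_chain: ", nrow(x$samples), " samples after ", x$burnin,
      " burn-in; acceptance rate ", round(x$acceptance_rate, 3), "\n",
      sep = "")
  invisible(x)
}

#' Equal-tailed credibility interval
#'
#' @param chain a [run_mcmc()] result, or a numeric vector/matrix of
#'   samples.
#' @param param parameter name or column index (ignored for vectors).
#' @param level credibility level; `level = 1` returns the sample range.
#' @param natural if `TRUE` (default) intervals are on the natural theta
#'   scale for model chains.
#' @return numeric `c(lower, upper)`.
#' @export
credibility_interval <- function(chain, param = 1, level = 0.95,
                                 natural = TRUE) {
  s <- if (inherits(chain, "posterior_chain")) {
    m <- if (natural) chain$theta else chain$samples
    if (is.character(param)) m[, param] else m[, param]
  } else if (is.matrix(chain)) {
    chain[, param]
  } else {
    chain
  }
  a <- (1 - level) / 2
  unname(stats::quantile(s, c(a, 1 - a), names = FALSE, type = 7))
}

#' Write a posterior chain to CSV
#'
#' Post burn-in samples (natural scale) with the log-posterior column.
#' @param chain a [run_mcmc()] result.
#' @param path output path.
#' @export
write_chain_csv <- function(chain, path) {
  df <- as.data.frame(chain$theta)
  df$log_posterior <- chain$log_posterior
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
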