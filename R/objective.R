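# Maximum-likelihood estimation: the negative log-likelihood J, its analytic
# gradient via forward sensitivities, the Fisher information matrix as
# Hessian approximation, and multi-start latin-hypercube local optimization.

#' Specify an estimation problem
#'
#' Binds a model (network + approximation method + observables), a snapshot
#' summary dataset, the estimated parameters with their box domain, the
#' initial condition, and the technical-noise model into an objective
#' specification for [negative_log_likelihood()], [fit()] and the
#' uncertainty-analysis tools.
#'
#' Estimation is performed on the log scale `xi = log(theta)`; all bounds
#' must therefore be strictly positive.
#'
#' @param net a [reaction_network()].
#' @param method approximation method tag (see [generate_system()]).
#' @param data a [summarize_snapshots()] result (or [read_summary_csv()]).
#' @param estimate character vector of estimated parameter names.
#' @param lower,upper named (or recycled) positive bounds on the natural
#'   scale.
#' @param mu0 initial mean concentrations: vector over species whose entries
#'   are numbers or names of (estimated) initial-concentration parameters.
#' @param data_mode `"mean"` (only the mean block of the likelihood; the
#'   variance part is set to one) or `"mean+variance"`.
#' @param noise a [noise_model()]; defaults to zero technical noise in
#'   snapshot mode.
#' @param t0 initial time.
#' @param Sigma0 initial covariance (default 0: deterministic start).
#' @param rtol,atol integration tolerances.
#' @return An object of class `"objective_spec"`.
#' @export
objective_spec <- function(net, method, data, estimate, lower, upper,
                           mu0, data_mode = c("mean", "mean+variance"),
                           noise = noise_model(0), t0 = 0, Sigma0 = 0,
                           rtol = 1e-8, atol = 1e-10) {
  method <- normalize_method(method)
  data_mode <- match.arg(data_mode)
  if (!inherits(noise, "noise_model")) noise <- noise_model(noise)
  if (data_mode == "mean+variance" && method == "RRE") {
    stop("RRE carries no covariance block; use data_mode = 'mean'",
         call. = FALSE)
  }
  if (data_mode == "mean+variance" && noise$mode == "population_average") {
    stop("population-average data carry no variance information",
         call. = FALSE)
  }
  lower <- expand_bounds(lower, estimate)
  upper <- expand_bounds(upper, estimate)
  if (any(lower <= 0) || any(upper <= lower)) {
    stop("bounds must satisfy 0 < lower < upper (log-transformable)",
         call. = FALSE)
  }
  if (length(mu0) != net$M) stop("mu0 must cover all species", call. = FALSE)

  # classify estimated parameters
  rate_names <- net$compiled$rate_name
  ic_species <- character(0)
  mu0_chr <- vapply(mu0, function(v) if (is.character(v)) v else NA_character_,
                    character(1))
  for (p in estimate) {
    if (p %in% mu0_chr) {
      ic_species[p] <- net$species[match(p, mu0_chr)]
    }
  }
  obs_names <- vapply(net$observables, `[[`, character(1), "name")
  scale_of <- offset_of <- stats::setNames(rep(NA_character_, length(obs_names)),
                                           obs_names)
  for (ob in net$observables) {
    if (is.character(ob$scale)) scale_of[ob$name] <- ob$scale
    if (is.character(ob$offset)) offset_of[ob$name] <- ob$offset
  }
  noise_of <- stats::setNames(rep(NA_character_, length(obs_names)), obs_names)
  nv <- noise$variances
  if (is.character(nv)) {
    if (is.null(names(nv))) nv <- stats::setNames(rep(nv, length(obs_names)),
                                                  obs_names)
    noise_of[names(nv)] <- nv
  }
  dynamic <- estimate[estimate %in% rate_names]
  ic <- names(ic_species)
  aug_params <- unique(c(dynamic, ic))
  other <- setdiff(estimate, c(aug_params, stats::na.omit(scale_of),
                               stats::na.omit(offset_of),
                               stats::na.omit(noise_of)))
  if (length(other)) {
    known <- estimate %in% names(net$parameters)
    if (!all(known)) {
      stop("estimated parameter(s) not in model: ",
           paste(estimate[!known], collapse = ", "), call. = FALSE)
    }
  }
  if (!all(data$observable %in% obs_names)) {
    stop("data reference unknown observables", call. = FALSE)
  }

  sys <- generate_system(net, method)
  aug <- if (length(aug_params)) {
    augment_with_sensitivities(sys, aug_params, ic_species)
  } else NULL

  structure(
    list(net = net, method = method, sys = sys, aug = aug, data = data,
         estimate = estimate, lower = lower, upper = upper, mu0 = mu0,
         data_mode = data_mode, noise = noise, t0 = t0, Sigma0 = Sigma0,
         rtol = rtol, atol = atol, ic_species = ic_species,
         scale_of = scale_of, offset_of = offset_of, noise_of = noise_of,
         cache = new.env(parent = emptyenv())),
    class = "objective_spec"
  )
}

expand_bounds <- function(b, estimate) {
  if (is.null(names(b))) b <- stats::setNames(rep_len(b, length(estimate)),
                                              estimate)
  b[estimate]
}

#' @export
print.objective_spec <- function(x, ...) {
  cat("objective_spec [", x$method, "]: ", nrow(x$data), " data rows, ",
      length(x$estimate), " estimated parameters, mode ", x$data_mode,
      "\n", sep = "")
  invisible(x)
}

resolve_mu0 <- function(spec, theta) {
  vapply(spec$mu0, function(v) {
    if (is.character(v)) unname(theta[[v]]) else as.numeric(v)
  }, numeric(1))
}

full_theta <- function(spec, theta) {
  th <- spec$net$parameters
  th[names(theta)] <- theta
  th
}

# Core evaluation: model predictions (and sensitivities) at the data rows,
# plus J, gradient and FIM. Results cached on the estimated-parameter vector.
eval_objective <- function(spec, theta, need_grad = FALSE) {
  theta_est <- theta[spec$estimate]
  key <- paste(format(theta_est, digits = 17), collapse = "|")
  hit <- spec$cache$entry
  if (!is.null(hit) && identical(hit$key, key) &&
      (!need_grad || hit$has_grad)) {
    return(hit$value)
  }
  th <- full_theta(spec, theta_est)
  data <- spec$data
  times <- sort(unique(data$time))
  t_grid <- unique(c(spec$t0, times))
  keep <- match(data$time, t_grid)
  mu0 <- resolve_mu0(spec, th)
  y0 <- initial_state(spec$net, mu0, spec$Sigma0, spec$sys)

  use_sens <- need_grad && !is.null(spec$aug)
  sim <- try({
    if (use_sens) {
      simulate_sensitivities(spec$aug, th, t_grid, y0,
                             rtol = spec$rtol, atol = spec$atol)
    } else {
      list(traj = simulate_moments(spec$sys, th, t_grid, y0 = y0,
                                   rtol = spec$rtol, atol = spec$atol))
    }
  }, silent = TRUE)
  if (inherits(sim, "try-error")) {
    val <- list(J = Inf, grad = rep(0, length(spec$estimate)),
                fim = diag(length(spec$estimate)),
                failure = attr(sim, "condition")$message)
    spec$cache$entry <- list(key = key, has_grad = TRUE, value = val)
    return(val)
  }
  traj <- sim$traj

  # per-row model mean/var and their sensitivities w.r.t. estimated params
  L <- length(spec$estimate)
  nrows <- nrow(data)
  mu_m <- var_m <- numeric(nrows)
  dmu <- dvar <- matrix(0, nrows, L)
  sp <- spec$net$species
  have_sigma <- !is.null(spec$sys$idx$Sigma)
  mean_block <- if (!is.null(spec$sys$idx$mu)) spec$sys$idx$mu else
    spec$sys$idx$Phi
  for (ob in spec$net$observables) {
    rows <- which(data$observable == ob$name)
    if (!length(rows)) next
    w <- numeric(spec$net$M)
    w[match(names(ob$weights), sp)] <- ob$weights
    sc <- resolve_param(ob$scale, th)
    of <- resolve_param(ob$offset, th)
    ti <- keep[rows]
    raw_mean <- drop(traj$mean[ti, , drop = FALSE] %*% w)
    mu_m[rows] <- sc * raw_mean + of
    raw_var <- rep(NA_real_, length(rows))
    if (have_sigma) {
      raw_var <- vapply(seq_along(ti), function(q) {
        drop(t(w) %*% trajectory_cov(traj, ti[q]) %*% w)
      }, numeric(1))
      var_m[rows] <- sc^2 * raw_var
    }
    if (use_sens) {
      for (j in seq_along(spec$aug$params)) {
        l <- match(spec$aug$params[j], spec$estimate)
        if (is.na(l)) next
        smean <- sim$sens[ti, mean_block, j, drop = FALSE]
        dim(smean) <- c(length(ti), length(mean_block))
        dmu[rows, l] <- sc * drop(smean %*% w)
        if (have_sigma) {
          sSig <- sim$sens[ti, spec$sys$idx$Sigma, j, drop = FALSE]
          dvar[rows, l] <- sc^2 * vapply(seq_along(ti), function(q) {
            Sj <- sym_unpack(sSig[q, , 1], spec$net$M, spec$sys$sym)
            drop(t(w) %*% Sj %*% w)
          }, numeric(1))
        }
      }
    }
    # scale / offset parameter derivatives (analytic)
    sname <- spec$scale_of[ob$name]
    if (!is.na(sname) && sname %in% spec$estimate) {
      l <- match(sname, spec$estimate)
      dmu[rows, l] <- dmu[rows, l] + raw_mean
      if (have_sigma) dvar[rows, l] <- dvar[rows, l] + 2 * sc * raw_var
    }
    oname <- spec$offset_of[ob$name]
    if (!is.na(oname) && oname %in% spec$estimate) {
      l <- match(oname, spec$estimate)
      dmu[rows, l] <- dmu[rows, l] + 1
    }
  }

  # estimator variances (parameter-dependent through technical noise)
  s2T <- vapply(data$observable, function(o) noise_variance(spec$noise, o, th),
                numeric(1))
  ds2T <- matrix(0, nrows, L)
  for (obn in names(spec$noise_of)) {
    pn <- spec$noise_of[obn]
    if (!is.na(pn) && pn %in% spec$estimate) {
      ds2T[data$observable == obn, match(pn, spec$estimate)] <- 1
    }
  }
  if (spec$noise$mode == "population_average") {
    s2mu <- s2T
  } else {
    s2mu <- data$var / data$n_cells + s2T
  }
  if (any(s2mu <= 0)) {
    s2mu <- pmax(s2mu, 1e-12)
  }
  rmu <- (mu_m - data$mean) / sqrt(s2mu)
  J <- 0.5 * sum(log(2 * pi * s2mu) + rmu^2)
  use_var <- spec$data_mode == "mean+variance"
  if (use_var) {
    N <- data$n_cells
    s2S <- pmax((data$m4 - (N - 3) / (N - 1) * data$var^2) / N, 1e-12)
    rS <- (var_m - data$var) / sqrt(s2S)
    J <- J + 0.5 * sum(log(2 * pi * s2S) + rS^2)
  }

  grad <- rep(0, L)
  fim <- matrix(0, L, L)
  if (need_grad) {
    theta_vec <- unname(theta_est)
    # d J / d theta, then chain rule to xi = log theta
    for (l in seq_len(L)) {
      gl <- sum((1 - rmu^2) / (2 * s2mu) * ds2T[, l] +
                  rmu * dmu[, l] / sqrt(s2mu))
      if (use_var) {
        gl <- gl + sum(rS * dvar[, l] / sqrt(s2S))
      }
      grad[l] <- gl * theta_vec[l]
    }
    dmu_xi <- dmu * rep(theta_vec, each = nrows)
    ds2_xi <- ds2T * rep(theta_vec, each = nrows)
    fim <- t(dmu_xi) %*% (dmu_xi / s2mu) +
      t(ds2_xi) %*% (ds2_xi / (2 * s2mu^2))
    if (use_var) {
      dvar_xi <- dvar * rep(theta_vec, each = nrows)
      fim <- fim + t(dvar_xi) %*% (dvar_xi / s2S)
    }
  }

  val <- list(J = J, grad = grad, fim = fim,
              residuals_mean = rmu,
              residuals_var = if (use_var) rS else NULL,
              predicted_mean = mu_m,
              predicted_var = if (have_sigma) var_m else NULL,
              sigma2_mean = s2mu,
              sigma2_var = if (use_var) s2S else NULL,
              negative_variance = isTRUE(traj$negative_variance))
  spec$cache$entry <- list(key = key, has_grad = need_grad, value = val)
  val
}

#' Negative log-likelihood J
#'
#' \deqn{J(\theta) = \frac12\sum_{k,i}\Big[\log 2\pi\sigma^2_{\hat\mu} +
#'   \Big(\frac{\mu-\hat\mu}{\sigma_{\hat\mu}}\Big)^2\Big] +
#'   \frac12\sum_{k,i}\Big[\log 2\pi\sigma^2_{\hat\Sigma} +
#'   \Big(\frac{\Sigma-\hat\Sigma}{\sigma_{\hat\Sigma}}\Big)^2\Big],}
#' with the variance block omitted for mean-only data. Integrator failures
#' yield `Inf` (multi-start robustness) rather than an error.
#'
#' @param spec an [objective_spec()].
#' @param theta named parameter vector (natural scale; must cover
#'   `spec$estimate`).
#' @return scalar J.
#' @export
negative_log_likelihood <- function(spec, theta) {
  eval_objective(spec, theta, need_grad = FALSE)$J
}

#' Analytic objective gradient on the log-parameter scale
#'
#' Forward-sensitivity gradient of J with respect to `xi = log(theta)`,
#' including the technical-noise variance derivative terms.
#'
#' @inheritParams negative_log_likelihood
#' @return gradient vector (length of `spec$estimate`).
#' @export
objective_gradient <- function(spec, theta) {
  stats::setNames(eval_objective(spec, theta, need_grad = TRUE)$grad,
                  spec$estimate)
}

#' Fisher information matrix (Hessian approximation)
#'
#' Outer products of the observable sensitivities weighted by the estimator
#' variances, on the log-parameter scale; positive semidefinite by
#' construction and used as the optimizer's Hessian model
#' (Levenberg-Marquardt-type curvature).
#'
#' @inheritParams negative_log_likelihood
#' @return symmetric PSD matrix.
#' @export
fisher_information <- function(spec, theta) {
  f <- eval_objective(spec, theta, need_grad = TRUE)$fim
  dimnames(f) <- list(spec$estimate, spec$estimate)
  f
}

#' Multi-start maximum-likelihood fit
#'
#' Latin-hypercube starting points on the log-parameter hypercube, each
#' refined by a bound-constrained quasi-Newton (PORT) local optimizer
#' supplied with the analytic gradient and the FIM as Hessian model.
#' Convergence is asserted when at least `min_agree` starts reach the best
#' objective within `agree_tol`; otherwise the result recommends doubling
#' the number of starts.
#'
#' @param spec an [objective_spec()].
#' @param n_starts number of local optimizations (default 50).
#' @param seed RNG seed for the latin hypercube.
#' @param min_agree required number of agreeing starts (default 5).
#' @param agree_tol absolute objective agreement tolerance (default 1e-3).
#' @param control passed to [stats::nlminb()]; parameter and objective
#'   tolerances default to 1e-6.
#' @param starts optional matrix of starting points (log scale), overriding
#'   the latin hypercube.
#' @return An `"estimation_result"` with fields `theta_hat`, `J`, `starts`
#'   (per-start table), `fim`, `converged`, `recommendation`, `seed`.
#' @export
fit <- function(spec, n_starts = 50, seed = NULL, min_agree = 5,
                agree_tol = 1e-3, control = list(), starts = NULL) {
  stopifnot(n_starts >= 1)
  L <- length(spec$estimate)
  lo <- log(spec$lower); hi <- log(spec$upper)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(starts)) {
    H <- lhs::randomLHS(n_starts, L)
    starts <- H * rep(hi - lo, each = n_starts) + rep(lo, each = n_starts)
  }
  ctrl <- utils::modifyList(list(rel.tol = 1e-6, x.tol = 1e-6,
                                 iter.max = 300, eval.max = 600), control)

  fobj <- function(xi) {
    th <- stats::setNames(exp(xi), spec$estimate)
    J <- eval_objective(spec, th)$J
    if (!is.finite(J)) 1e12 else J
  }
  fgrad <- function(xi) {
    th <- stats::setNames(exp(xi), spec$estimate)
    eval_objective(spec, th, need_grad = TRUE)$grad
  }
  fhess <- function(xi) {
    th <- stats::setNames(exp(xi), spec$estimate)
    e <- eval_objective(spec, th, need_grad = TRUE)
    e$fim + diag(1e-8, L)
  }

  recs <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    res <- try(stats::nlminb(starts[s, ], objective = fobj, gradient = fgrad,
                             hessian = fhess, lower = lo, upper = hi,
                             control = ctrl), silent = TRUE)
    if (inherits(res, "try-error")) {
      recs[[s]] <- list(start = starts[s, ], xi = rep(NA_real_, L),
                        J = Inf, convergence = NA_integer_,
                        message = attr(res, "condition")$message,
                        iterations = NA_integer_, grad_norm = NA_real_)
      next
    }
    gn <- sqrt(sum(fgrad(res$par)^2))
    recs[[s]] <- list(start = starts[s, ], xi = res$par, J = res$objective,
                      convergence = res$convergence, message = res$message,
                      iterations = res$iterations, grad_norm = gn)
  }
  Js <- vapply(recs, `[[`, numeric(1), "J")
  if (all(!is.finite(Js))) {
    stop("estimation failed: no start converged; per-start messages: ",
         paste(vapply(recs, `[[`, character(1), "message"), collapse = "; "),
         call. = FALSE)
  }
  Jbest <- min(Js)
  cand <- which(Js <= Jbest + agree_tol)
  gns <- vapply(recs, `[[`, numeric(1), "grad_norm")[cand]
  best <- cand[order(gns, cand)][1]
  theta_hat <- stats::setNames(exp(recs[[best]]$xi), spec$estimate)
  n_agree <- length(cand)
  converged <- n_agree >= min_agree
  start_tab <- data.frame(
    start_index = seq_along(recs),
    J = Js,
    convergence = vapply(recs, `[[`, numeric(1), "convergence"),
    iterations = vapply(recs, `[[`, numeric(1), "iterations"),
    grad_norm = vapply(recs, `[[`, numeric(1), "grad_norm")
  )
  structure(
    list(theta_hat = theta_hat, xi_hat = recs[[best]]$xi,
         J = Jbest, starts = start_tab, start_points = starts,
         n_agree = n_agree, converged = converged,
         recommendation = if (converged) "converged" else
           paste0("only ", n_agree, " starts agree; double n_starts to ",
                  2 * nrow(starts)),
         fim = fisher_information(spec, theta_hat),
         spec = spec, seed = seed),
    class = "estimation_result"
  )
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("estimation_result [", x$spec$method, "]: J = ",
      format(x$J, digits = 8), ", ", x$n_agree, "/", nrow(x$starts),
      " agreeing starts (", x$recommendation, ")\n", sep = "")
  print(x$theta_hat)
  invisible(x)
}

#' Save an estimation result as JSON
#'
#' @param result an [fit()] result.
#' @param path output path.
#' @export
write_result_json <- function(result, path) {
  out <- list(method = result$spec$method,
              theta_hat = as.list(result$theta_hat),
              J = result$J, n_agree = result$n_agree,
              converged = result$converged,
              recommendation = result$recommendation,
              fim = unclass(result$fim),
              starts = result$starts, seed = result$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
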