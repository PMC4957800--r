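# Forward sensitivity systems: the base moment system is augmented with
# d(state)/d(theta_l) blocks and integrated jointly. The sensitivity
# right-hand sides are the exact directional derivatives of the moment
# equations (chain rule through the mass-action coefficient structure); for
# the 3MA the directional derivative is evaluated by complex-step
# differentiation of the polynomial RHS, which is exact to machine precision.

# Directional derivative of the gradient matrix: row r = (H_r s)' (the
# quadratic part of d/d eps Jf(x + eps s)).
grad_quad_dir <- function(co, s, M, u = NULL) {
  R <- length(co$k)
  D <- matrix(if (is.complex(s)) 0i else 0, R, M)
  wh <- which(co$het)
  if (length(wh)) {
    D[cbind(wh, co$i1[wh])] <- co$k[wh] * s[co$i2[wh]]
    D[cbind(wh, co$i2[wh])] <- D[cbind(wh, co$i2[wh])] + co$k[wh] * s[co$i1[wh]]
  }
  wo <- which(co$hom)
  if (length(wo)) {
    D[cbind(wo, co$i1[wo])] <- D[cbind(wo, co$i1[wo])] +
      2 * co$k[wo] * s[co$i1[wo]]
  }
  if (!is.null(u)) D <- D * u
  D
}

#' Augment a moment system with forward sensitivities
#'
#' Builds the joint ODE system for the base moments and their derivatives
#' with respect to a set of parameters. Sensitivities are propagated on the
#' natural (theta) scale; the chain rule to the log-parameter optimization
#' scale is applied once at the objective boundary.
#'
#' @param sys a [generate_system()] result.
#' @param params character vector of parameter names to differentiate
#'   against. Each must be a rate constant of some reaction, an
#'   initial-condition parameter named in `ic_species`, or a non-dynamic
#'   (noise/scale/offset) parameter of the network, whose sensitivity blocks
#'   are then identically zero.
#' @param ic_species optional named character vector mapping
#'   initial-condition parameters to species names.
#' @return An object of class `"sensitivity_system"`.
#' @export
augment_with_sensitivities <- function(sys, params, ic_species = NULL) {
  net <- sys$net
  rate_names <- net$compiled$rate_name
  rho <- lapply(params, function(p) which(rate_names == p))
  names(rho) <- params
  known <- names(net$parameters)
  for (p in params) {
    if (!(p %in% known) && !(p %in% names(ic_species))) {
      stop("parameter '", p, "' is absent from the model", call. = FALSE)
    }
  }
  ic_idx <- integer(length(params))
  if (!is.null(ic_species)) {
    for (j in seq_along(params)) {
      if (params[j] %in% names(ic_species)) {
        ic_idx[j] <- match(ic_species[[params[j]]], net$species)
      }
    }
  }
  L <- length(params)
  IND <- matrix(0, net$R, L)
  for (j in seq_len(L)) IND[rho[[j]], j] <- 1
  structure(
    list(sys = sys, params = params, rho = rho, ic_idx = ic_idx, IND = IND,
         L = L, dim = sys$dim * (1L + L)),
    class = "sensitivity_system"
  )
}

#' @export
print.sensitivity_system <- function(x, ...) {
  cat("sensitivity_system [", x$sys$method, "]: base dimension ", x$sys$dim,
      " + ", x$L, " parameter blocks = ", x$dim, "\n", sep = "")
  invisible(x)
}

# Initial augmented state: base y0 plus d y0 / d theta_l (nonzero only for
# initial-condition parameters, in the Phi and mu blocks).
sens_initial_state <- function(aug, y0) {
  sys <- aug$sys
  s0 <- matrix(0, sys$dim, aug$L)
  for (j in seq_len(aug$L)) {
    i <- aug$ic_idx[j]
    if (i > 0L) {
      if (!is.null(sys$idx$Phi)) s0[sys$idx$Phi[i], j] <- 1
      if (!is.null(sys$idx$mu)) s0[sys$idx$mu[i], j] <- 1
    }
  }
  c(y0, as.numeric(s0))
}

# Augmented RHS. theta: full named parameter vector (needed for the 3MA
# complex-step path).
sens_rhs <- function(aug, t, y, ctx, theta) {
  sys <- aug$sys
  M <- sys$M
  L <- aug$L
  nd <- sys$dim
  base <- y[seq_len(nd)]
  S <- matrix(y[-seq_len(nd)], nd, L)
  dbase <- moment_rhs(sys, t, base, ctx)
  dS <- matrix(0, nd, L)
  u <- ctx_inputs(ctx, t)
  A <- ctx$A; P <- ctx$P
  method <- sys$method

  if (method == "3MA") {
    h <- 1e-20
    for (j in seq_len(L)) {
      th <- theta
      pj <- aug$params[j]
      if (pj %in% names(th)) th[pj] <- th[pj] + (0+1i) * h
      ctxc <- rhs_context(sys, th)
      yc <- base + (0+1i) * h * S[, j]
      dS[, j] <- Im(moment_rhs(sys, t, yc, ctxc)) / h
    }
    return(c(dbase, as.numeric(dS)))
  }

  U <- aug$IND / ctx$co_mac$k  # per-parameter 1/k indicator (R x L)

  if (method == "RRE") {
    phi <- base
    f <- eval_rates(ctx$co_mac, phi, u)
    Jf <- eval_grad(ctx$co_mac, phi, M, u)
    J <- A %*% Jf
    dS <- J %*% S + A %*% (f * U)
    return(c(dbase, as.numeric(dS)))
  }

  if (method %in% c("LNA", "EMRE")) {
    phi <- base[sys$idx$Phi]
    Sig <- sym_unpack(base[sys$idx$Sigma], M, sys$sym)
    co <- ctx$co_mac
    f <- eval_rates(co, phi, u)
    Jf <- eval_grad(co, phi, M, u)
    J <- A %*% Jf
    if (method == "EMRE") {
      mu <- base[sys$idx$mu]
      delta <- mu - phi
      Jfd <- drop(Jf %*% delta)
      HcS <- hess_contract(co, Sig, u)
      hphi <- hess_diag_phi(co, phi, u)
    }
    for (j in seq_len(L)) {
      sphi <- S[sys$idx$Phi, j]
      sSig <- sym_unpack(S[sys$idx$Sigma, j], M, sys$sym)
      ul <- U[, j]
      dfl <- drop(Jf %*% sphi) + f * ul
      dJf <- grad_quad_dir(co, sphi, M, u) + Jf * ul
      dJ <- A %*% dJf
      dS[sys$idx$Phi, j] <- A %*% dfl
      dSig <- J %*% sSig + sSig %*% t(J) + dJ %*% Sig + Sig %*% t(dJ) +
        P %*% (dfl * t(P))
      dS[sys$idx$Sigma, j] <- sym_pack(dSig, sys$sym)
      if (method == "EMRE") {
        smu <- S[sys$idx$mu, j]
        de <- dfl + hess_bilinear(co, sphi, delta, u) +
          drop(Jf %*% (smu - sphi)) + Jfd * ul +
          0.5 * (hess_contract(co, sSig, u) + HcS * ul) -
          (hess_diag_phi(co, sphi, u) + hphi * ul) / (2 * ctx$omega_r)
        dS[sys$idx$mu, j] <- A %*% de
      }
    }
    return(c(dbase, as.numeric(dS)))
  }

  if (method == "2MA") {
    mu <- base[sys$idx$mu]
    Sig <- sym_unpack(base[sys$idx$Sigma], M, sys$sym)
    co <- ctx$co_mic
    g <- eval_rates(co, mu, u)
    G <- g + 0.5 * hess_contract(co, Sig, u)
    Jh <- eval_grad(co, mu, M, u)
    J <- A %*% Jh
    for (j in seq_len(L)) {
      smu <- S[sys$idx$mu, j]
      sSig <- sym_unpack(S[sys$idx$Sigma, j], M, sys$sym)
      ul <- U[, j]
      dG <- drop(Jh %*% smu) + 0.5 * hess_contract(co, sSig, u) + G * ul
      dJ <- A %*% (grad_quad_dir(co, smu, M, u) + Jh * ul)
      dS[sys$idx$mu, j] <- A %*% dG
      dSig <- J %*% sSig + sSig %*% t(J) + dJ %*% Sig + Sig %*% t(dJ) +
        P %*% (dG * t(P))
      dS[sys$idx$Sigma, j] <- sym_pack(dSig, sys$sym)
    }
    return(c(dbase, as.numeric(dS)))
  }

  # IOS: Phi as RRE, mu as EMRE, Sigma as the closed covariance at mu
  phi <- base[sys$idx$Phi]
  mu <- base[sys$idx$mu]
  Sig <- sym_unpack(base[sys$idx$Sigma], M, sys$sym)
  com <- ctx$co_mac
  coh <- ctx$co_mic
  f <- eval_rates(com, phi, u)
  Jf <- eval_grad(com, phi, M, u)
  delta <- mu - phi
  Jfd <- drop(Jf %*% delta)
  HcS <- hess_contract(com, Sig, u)
  hphi <- hess_diag_phi(com, phi, u)
  g <- eval_rates(coh, mu, u)
  G <- g + 0.5 * hess_contract(coh, Sig, u)
  Jh <- eval_grad(coh, mu, M, u)
  Jmu <- A %*% Jh
  for (j in seq_len(L)) {
    sphi <- S[sys$idx$Phi, j]
    smu <- S[sys$idx$mu, j]
    sSig <- sym_unpack(S[sys$idx$Sigma, j], M, sys$sym)
    ul <- U[, j]
    dfl <- drop(Jf %*% sphi) + f * ul
    dS[sys$idx$Phi, j] <- A %*% dfl
    de <- dfl + hess_bilinear(com, sphi, delta, u) +
      drop(Jf %*% (smu - sphi)) + Jfd * ul +
      0.5 * (hess_contract(com, sSig, u) + HcS * ul) -
      (hess_diag_phi(com, sphi, u) + hphi * ul) / (2 * ctx$omega_r)
    dS[sys$idx$mu, j] <- A %*% de
    dG <- drop(Jh %*% smu) + 0.5 * hess_contract(coh, sSig, u) + G * ul
    dJ <- A %*% (grad_quad_dir(coh, smu, M, u) + Jh * ul)
    dSig <- Jmu %*% sSig + sSig %*% t(Jmu) + dJ %*% Sig + Sig %*% t(dJ) +
      P %*% (dG * t(P))
    dS[sys$idx$Sigma, j] <- sym_pack(dSig, sys$sym)
  }
  c(dbase, as.numeric(dS))
}

#' Integrate a sensitivity-augmented system
#'
#' @param aug an [augment_with_sensitivities()] result.
#' @param theta named parameter vector (values for all overridden
#'   parameters, including the differentiated ones).
#' @param t_grid sorted output times.
#' @param y0 base initial state ([initial_state()]).
#' @param s0 optional initial sensitivity matrix (dim x L); defaults to the
#'   derivative of the initial state (nonzero for initial-condition
#'   parameters only).
#' @param rtol,atol integration tolerances.
#' @return list with the base `"moment_trajectory"` (`$traj`) and `$sens`, a
#'   (time x dim x L) array of state sensitivities.
#' @export
simulate_sensitivities <- function(aug, theta = NULL, t_grid, y0,
                                   s0 = NULL, rtol = 1e-8, atol = 1e-10) {
  sys <- aug$sys
  ctx <- rhs_context(sys, theta)
  theta_full <- sys$net$parameters
  if (!is.null(theta)) theta_full[names(theta)] <- theta
  yaug0 <- if (is.null(s0)) sens_initial_state(aug, y0) else c(y0, as.numeric(s0))
  f <- function(t, y, parms) list(sens_rhs(aug, t, y, ctx, theta_full))
  sol <- try(suppressWarnings(
    deSolve::ode(y = yaug0, times = t_grid, func = f, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol)),
    silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(t_grid) ||
      anyNA(sol)) {
    stop("integrator failure [method=", sys$method, ", sensitivities]: ",
         if (inherits(sol, "try-error")) attr(sol, "condition")$message
         else "incomplete solution", call. = FALSE)
  }
  states <- unname(sol[, -1, drop = FALSE])
  nd <- sys$dim
  base_states <- states[, seq_len(nd), drop = FALSE]
  sens <- array(states[, -seq_len(nd)],
                c(length(t_grid), nd, aug$L))
  traj <- fabricate_trajectory(sys, t_grid, base_states, theta)
  list(traj = traj, sens = sens, aug = aug)
}

# Build a moment_trajectory object from precomputed states.
fabricate_trajectory <- function(sys, t_grid, states, theta) {
  mean_block <- if (!is.null(sys$idx$mu)) sys$idx$mu else sys$idx$Phi
  means <- states[, mean_block, drop = FALSE]
  colnames(means) <- sys$net$species
  vars <- NULL
  neg_var <- FALSE
  if (!is.null(sys$idx$Sigma)) {
    dpos <- sys$idx$Sigma[cumsum(seq_len(sys$M))]
    vars <- states[, dpos, drop = FALSE]
    colnames(vars) <- sys$net$species
    neg_var <- any(vars < 0)
  }
  structure(
    list(times = t_grid, states = states, mean = means, var = vars,
         sys = sys, theta = theta, negative_variance = neg_var),
    class = "moment_trajectory"
  )
}

#' Central finite-difference gradient
#'
#' Validation-only gradient: central differences of an objective on the
#' optimization (log-parameter) scale. Never used by the optimizer by
#' default.
#'
#' @param objective function of a numeric vector returning a scalar.
#' @param x evaluation point (interior to any bounds).
#' @param step per-coordinate step (default 1e-4).
#' @return list with `gradient`, `step`, and per-coordinate `failed` flags
#'   (objective failures at perturbed points are reported, not raised).
#' @export
finite_difference_gradient <- function(objective, x, step = 1e-4) {
  L <- length(x)
  g <- numeric(L)
  failed <- logical(L)
  step <- rep_len(step, L)
  for (j in seq_len(L)) {
    xp <- x; xp[j] <- x[j] + step[j]
    xm <- x; xm[j] <- x[j] - step[j]
    fp <- try(objective(xp), silent = TRUE)
    fm <- try(objective(xm), silent = TRUE)
    if (inherits(fp, "try-error") || inherits(fm, "try-error") ||
        !is.finite(fp) || !is.finite(fm)) {
      failed[j] <- TRUE
      g[j] <- NA_real_
    } else {
      g[j] <- (fp - fm) / (2 * step[j])
    }
  }
  list(gradient = g, step = step, failed = failed)
}

#' Gradient consistency check
#'
#' Compares the forward-sensitivity gradient of an objective specification
#' with central finite differences at a point, and optionally writes a JSON
#' diagnostic report.
#'
#' @param spec an [objective_spec()].
#' @param theta named parameter vector (natural scale).
#' @param step finite-difference step on the log scale.
#' @param tol relative-error threshold for the pass verdict.
#' @param file optional JSON report path.
#' @return list with per-parameter relative errors, the two gradients and a
#'   `pass` flag.
#' @export
gradient_check <- function(spec, theta, step = 1e-4, tol = 1e-3,
                           file = NULL) {
  xi <- log(theta[spec$estimate])
  gs <- objective_gradient(spec, theta)
  fd <- finite_difference_gradient(function(x) {
    th <- theta
    th[spec$estimate] <- exp(x)
    negative_log_likelihood(spec, th)
  }, xi, step)
  scale <- pmax(abs(gs), abs(fd$gradient), 1e-8)
  rel <- abs(gs - fd$gradient) / scale
  out <- list(parameters = spec$estimate, sensitivity_gradient = unname(gs),
              finite_difference_gradient = unname(fd$gradient),
              relative_error = unname(rel), step = unname(fd$step),
              failed = unname(fd$failed),
              pass = all(!fd$failed & rel < tol))
  if (!is.null(file)) {
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  }
  out
}
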