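# Generation and integration of approximate moment ODE systems.
#
# Six methods are supported:
#   RRE  - reaction rate equations (macroscopic mean), blocks {Phi}
#   LNA  - linear noise approximation, blocks {Phi, Sigma}
#   EMRE - effective mesoscopic rate equation (1/Omega mean correction),
#          blocks {Phi, mu, Sigma}
#   IOS  - next-order covariance correction beyond the LNA, blocks
#          {Phi, mu, Sigma}
#   2MA  - second-order moment closure, blocks {mu, Sigma}
#   3MA  - third-order moment closure, blocks {mu, Sigma, T3}
# Sigma is stored as its M(M+1)/2 unique entries and T3 as its
# M(M+1)(M+2)/6 unique entries.

moment_methods <- c("RRE", "LNA", "EMRE", "IOS", "2MA", "3MA")

normalize_method <- function(method) {
  m <- toupper(method)
  if (!m %in% moment_methods) {
    stop("unknown method '", method, "'; use one of ",
         paste(moment_methods, collapse = ", "), call. = FALSE)
  }
  m
}

# --- symmetric packing ------------------------------------------------------

sym_maps <- function(M) {
  iu <- which(upper.tri(diag(M), diag = TRUE))
  # map from full M x M linear index to packed index
  pk <- matrix(0L, M, M)
  pk[iu] <- seq_along(iu)
  pk <- pmax(pk, t(pk))
  list(iu = iu, full_from_packed = as.integer(pk))
}

sym_pack <- function(S, maps) S[maps$iu]
sym_unpack <- function(v, M, maps) matrix(v[maps$full_from_packed], M, M)

t3_maps <- function(M) {
  idx <- do.call(rbind, lapply(seq_len(M), function(i) {
    do.call(rbind, lapply(i:M, function(j) {
      cbind(i, j, j:M)
    }))
  }))
  full <- array(0L, c(M, M, M))
  for (q in seq_len(nrow(idx))) {
    p <- as.integer(idx[q, ])
    perms <- unique(rbind(p, p[c(1, 3, 2)], p[c(2, 1, 3)], p[c(2, 3, 1)],
                          p[c(3, 1, 2)], p[c(3, 2, 1)]))
    full[perms] <- q
  }
  first <- idx[, 1] + (idx[, 2] - 1L) * M + (idx[, 3] - 1L) * M * M
  list(first = as.integer(first), full_from_packed = as.integer(full),
       n = nrow(idx))
}

t3_pack <- function(T3, maps) T3[maps$first]
t3_unpack <- function(v, M, maps) array(v[maps$full_from_packed], c(M, M, M))

# --- system generation ------------------------------------------------------

#' Generate a moment ODE system for a reaction network
#'
#' Derives, from the network's mass-action propensity structure, the ordinary
#' differential equation system of the chosen approximation method. The state
#' is composed of ordered blocks among: `Phi` (macroscopic concentrations),
#' `mu` (corrected or closed mean concentrations), `Sigma` (unique entries of
#' the symmetric concentration covariance) and `T3` (unique third central
#' moments, 3MA only). The right-hand side is an exact implementation of the
#' method's equations; see the methods vignette for their derivation.
#'
#' @param net a [reaction_network()].
#' @param method one of `"RRE"`, `"LNA"`, `"EMRE"`, `"IOS"`, `"2MA"`, `"3MA"`
#'   (case-insensitive).
#' @return An object of class `"moment_system"` with fields `method`, `net`,
#'   `blocks` (named block sizes), `dim` (total state dimension), `idx`
#'   (block index map) and an internal right-hand-side evaluator.
#' @examples
#' net <- trimerization_network()
#' sys <- generate_system(net, "EMRE")
#' sys$dim  # 3 Phi + 3 mu + 6 Sigma = 12
#' @export
generate_system <- function(net, method) {
  method <- normalize_method(method)
  M <- net$M
  nsig <- as.integer(M * (M + 1L) / 2L)
  nt3 <- as.integer(M * (M + 1L) * (M + 2L) / 6L)
  blocks <- switch(method,
    RRE = c(Phi = M),
    LNA = c(Phi = M, Sigma = nsig),
    EMRE = c(Phi = M, mu = M, Sigma = nsig),
    IOS = c(Phi = M, mu = M, Sigma = nsig),
    `2MA` = c(mu = M, Sigma = nsig),
    `3MA` = c(mu = M, Sigma = nsig, T3 = nt3)
  )
  ends <- cumsum(blocks)
  idx <- mapply(function(a, b) seq.int(a, b), ends - blocks + 1L, ends,
                SIMPLIFY = FALSE)
  sys <- structure(
    list(method = method, net = net, M = M, blocks = blocks,
         dim = as.integer(sum(blocks)), idx = idx, sym = sym_maps(M),
         t3 = if (method == "3MA") t3_maps(M) else NULL),
    class = "moment_system"
  )
  sys
}

#' @export
print.moment_system <- function(x, ...) {
  cat("moment_system [", x$method, "] for ", x$M, "-species network: ",
      "dimension ", x$dim, " (",
      paste(names(x$blocks), x$blocks, sep = "=", collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

# --- right-hand sides -------------------------------------------------------

# Context shared by rhs evaluations: coefficient structures at theta plus
# precompiled network matrices.
rhs_context <- function(sys, theta = NULL) {
  net <- sys$net
  list(
    co_mac = reaction_coefficients(net, theta, microscopic = FALSE),
    co_mic = reaction_coefficients(net, theta, microscopic = TRUE),
    A = net$compiled$A, P = net$compiled$P,
    omega_r = net$compiled$omega_r,
    has_input = any(net$compiled$input_idx > 0L),
    net = net
  )
}

ctx_inputs <- function(ctx, t) {
  if (!ctx$has_input) NULL else input_factors(ctx$net, t)
}

# Evaluate the RHS of a moment system at (t, y) given a context. Works for
# complex-valued y and complex rate constants (pure arithmetic).
moment_rhs <- function(sys, t, y, ctx) {
  M <- sys$M
  u <- ctx_inputs(ctx, t)
  A <- ctx$A; P <- ctx$P
  method <- sys$method
  out <- y * 0

  if (method == "RRE") {
    f <- eval_rates(ctx$co_mac, y, u)
    return(drop(A %*% f))
  }

  if (method %in% c("LNA", "EMRE", "IOS")) {
    phi <- y[sys$idx$Phi]
    Sig <- sym_unpack(y[sys$idx$Sigma], M, sys$sym)
    f <- eval_rates(ctx$co_mac, phi, u)
    out[sys$idx$Phi] <- A %*% f
    if (method %in% c("LNA", "EMRE")) {
      Jf <- eval_grad(ctx$co_mac, phi, M, u)
      J <- A %*% Jf
      dS <- J %*% Sig + Sig %*% t(J) + P %*% (f * t(P))
      out[sys$idx$Sigma] <- sym_pack(dS, sys$sym)
    }
    if (method %in% c("EMRE", "IOS")) {
      mu <- y[sys$idx$mu]
      Jf <- eval_grad(ctx$co_mac, phi, M, u)
      e <- f + drop(Jf %*% (mu - phi)) + 0.5 * hess_contract(ctx$co_mac, Sig, u) -
        hess_diag_phi(ctx$co_mac, phi, u) / (2 * ctx$omega_r)
      out[sys$idx$mu] <- A %*% e
    }
    if (method == "IOS") {
      mu <- y[sys$idx$mu]
      gmu <- eval_rates(ctx$co_mic, mu, u)
      G <- gmu + 0.5 * hess_contract(ctx$co_mic, Sig, u)
      Jh <- eval_grad(ctx$co_mic, mu, M, u)
      J <- A %*% Jh
      dS <- J %*% Sig + Sig %*% t(J) + P %*% (G * t(P))
      out[sys$idx$Sigma] <- sym_pack(dS, sys$sym)
    }
    return(out)
  }

  # 2MA / 3MA
  mu <- y[sys$idx$mu]
  Sig <- sym_unpack(y[sys$idx$Sigma], M, sys$sym)
  co <- ctx$co_mic
  gmu <- eval_rates(co, mu, u)
  G <- gmu + 0.5 * hess_contract(co, Sig, u)
  out[sys$idx$mu] <- A %*% G
  Jh <- eval_grad(co, mu, M, u)

  if (method == "2MA") {
    J <- A %*% Jh
    dS <- J %*% Sig + Sig %*% t(J) + P %*% (G * t(P))
    out[sys$idx$Sigma] <- sym_pack(dS, sys$sym)
    return(out)
  }

  # 3MA: third-central-moment hierarchy closed by zeroing the 4th cumulant
  T3 <- t3_unpack(y[sys$idx$T3], M, sys$t3)
  R <- length(co$k)
  uu <- if (is.null(u)) rep(1, R) else u
  # C[, r] = <g_r delta> = Sigma Jh_r' + (1/2) H_r : T3[ , , j]
  Cg <- Sig %*% t(Jh)
  for (r in seq_len(R)) {
    Cg[, r] <- Cg[, r] + 0.5 * uu[r] * hess_t3(co, r, T3)
  }
  dS <- A %*% t(Cg) + Cg %*% t(A) + P %*% (G * t(P))
  out[sys$idx$Sigma] <- sym_pack(dS, sys$sym)

  Tm <- matrix(T3, M, M * M)  # T3[s, (j,k)]
  dT <- array(y[1] * 0, c(M, M, M))
  for (r in seq_len(R)) {
    # Qt_r = sum_s Jh[r, s] T3[s, , ] + Sigma H_r Sigma (both symmetric)
    Qt <- matrix(drop(Jh[r, ] %*% Tm), M, M) + uu[r] * sig_h_sig(co, r, Sig)
    w1 <- A[, r] %o% Qt                      # W1[i, j, k] = A_ir Qt[j, k]
    dT <- dT + w1 + aperm(w1, c(2, 1, 3)) + aperm(w1, c(3, 1, 2))
    w2 <- (P[, r] %o% P[, r]) %o% Cg[, r]    # sym in first two indices
    dT <- dT + w2 + aperm(w2, c(1, 3, 2)) + aperm(w2, c(2, 3, 1))
    dT <- dT + (G[r] / sqrt(ctx$omega_r[r])) *
      ((P[, r] %o% P[, r]) %o% P[, r])
  }
  out[sys$idx$T3] <- t3_pack(dT, sys$t3)
  out
}

# --- initial state ----------------------------------------------------------

#' Pack initial moments into a method's state vector
#'
#' `Phi` and `mu` blocks are both initialized at `mu0`; the `Sigma` block at
#' `Sigma0` (default 0, the deterministic single-cell start); third central
#' moments at `T30` (default 0).
#'
#' @param net a [reaction_network()].
#' @param mu0 initial mean concentrations (length M).
#' @param Sigma0 initial covariance matrix (M x M, symmetric positive
#'   semidefinite) or a single 0.
#' @param method method tag or a `moment_system`.
#' @param T30 optional initial third central moments (M x M x M array).
#' @return numeric state vector of the system's dimension.
#' @export
initial_state <- function(net, mu0, Sigma0 = 0, method = "RRE", T30 = NULL) {
  sys <- if (inherits(method, "moment_system")) method
         else generate_system(net, method)
  M <- sys$M
  if (length(mu0) != M) stop("mu0 must have length M", call. = FALSE)
  if (identical(Sigma0, 0)) Sigma0 <- matrix(0, M, M)
  if (!isTRUE(all.equal(Sigma0, t(Sigma0), tolerance = 1e-10))) {
    stop("Sigma0 must be symmetric", call. = FALSE)
  }
  ev <- eigen(Sigma0, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(1, abs(ev)))) {
    stop("Sigma0 must be positive semidefinite", call. = FALSE)
  }
  y <- numeric(sys$dim)
  if (!is.null(sys$idx$Phi)) y[sys$idx$Phi] <- mu0
  if (!is.null(sys$idx$mu)) y[sys$idx$mu] <- mu0
  if (!is.null(sys$idx$Sigma)) y[sys$idx$Sigma] <- sym_pack(Sigma0, sys$sym)
  if (!is.null(sys$idx$T3)) {
    if (!is.null(T30)) y[sys$idx$T3] <- t3_pack(T30, sys$t3)
  }
  y
}

# --- integration ------------------------------------------------------------

#' Integrate a moment system
#'
#' Solves the generated (possibly stiff) ODE system with `deSolve::lsoda`.
#' Integrator failures raise a diagnostic error carrying method and time
#' context; callers performing optimization catch it and treat the objective
#' as infinite.
#'
#' @param sys a [generate_system()] result.
#' @param theta optional named parameter overrides.
#' @param t_grid sorted output times; the initial condition applies at
#'   `t_grid[1]`.
#' @param y0 initial state from [initial_state()]; defaults to all-zero
#'   moments if omitted and `mu0` given.
#' @param mu0,Sigma0 convenience alternative to `y0`.
#' @param rtol,atol integration tolerances (defaults 1e-8 / 1e-10).
#' @param ... passed to [deSolve::ode()].
#' @return A `"moment_trajectory"`: list with `times`, `states` (time x
#'   state matrix), per-time `mean` and `var` (M columns), the system, and a
#'   `negative_variance` flag (the IOS covariance is permitted to go negative
#'   at small volumes; this is flagged, not an error).
#' @export
simulate_moments <- function(sys, theta = NULL, t_grid, y0 = NULL,
                             mu0 = NULL, Sigma0 = 0, rtol = 1e-8,
                             atol = 1e-10, ...) {
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  if (is.null(y0)) {
    if (is.null(mu0)) stop("supply y0 or mu0", call. = FALSE)
    y0 <- initial_state(sys$net, mu0, Sigma0, sys)
  }
  ctx <- rhs_context(sys, theta)
  f <- function(t, y, parms) list(moment_rhs(sys, t, y, ctx))
  sol <- try(suppressWarnings(
    deSolve::ode(y = y0, times = t_grid, func = f, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol, ...)),
    silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(t_grid) ||
      anyNA(sol)) {
    stop("integrator failure [method=", sys$method, ", t up to ",
         max(t_grid), "]: ",
         if (inherits(sol, "try-error")) attr(sol, "condition")$message
         else "incomplete solution", call. = FALSE)
  }
  states <- unname(sol[, -1, drop = FALSE])
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

#' @export
print.moment_trajectory <- function(x, ...) {
  cat("moment_trajectory [", x$sys$method, "]: ", length(x$times),
      " timepoints, state dimension ", x$sys$dim,
      if (isTRUE(x$negative_variance)) " (negative variances flagged)" else "",
      "\n", sep = "")
  invisible(x)
}

# Full covariance matrix at output row i.
trajectory_cov <- function(traj, i) {
  sys <- traj$sys
  if (is.null(sys$idx$Sigma)) return(NULL)
  sym_unpack(traj$states[i, sys$idx$Sigma], sys$M, sys$sym)
}

#' Map a moment trajectory to observable space
#'
#' For a linear observable with weights `w`, scale `s` and offset `o`:
#' `mean_obs = s * (w' mu) + o` and `var_obs = s^2 * (w' Sigma w)`.
#'
#' @param traj a [simulate_moments()] result.
#' @param net the network (defaults to the trajectory's).
#' @param theta optional parameter overrides for scale/offset parameters.
#' @return data.frame with columns `time`, `observable`, `mean`, `var`
#'   (`var` is `NA` for methods without a covariance block).
#' @export
map_observables <- function(traj, net = NULL, theta = NULL) {
  net <- net %||% traj$sys$net
  pars <- net$parameters
  if (!is.null(theta)) pars[names(theta)] <- theta
  sys <- traj$sys
  out <- list()
  for (ob in net$observables) {
    w <- numeric(net$M)
    w[match(names(ob$weights), net$species)] <- ob$weights
    sc <- resolve_param(ob$scale, pars, "scale parameter")
    of <- resolve_param(ob$offset, pars, "offset parameter")
    m <- sc * drop(traj$mean %*% w) + of
    v <- rep(NA_real_, length(traj$times))
    if (!is.null(sys$idx$Sigma)) {
      v <- vapply(seq_along(traj$times), function(i) {
        drop(t(w) %*% trajectory_cov(traj, i) %*% w)
      }, numeric(1)) * sc^2
    }
    out[[ob$name]] <- data.frame(time = traj$times, observable = ob$name,
                                 mean = m, var = v,
                                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Serialize a generated system's structure as JSON
#'
#' Writes the method tag, block layout, dimensions and the per-reaction
#' rate-law structure (order, species indices, rate parameter, volumes) so
#' generated systems can be cached and compared across sessions.
#'
#' @param sys a `moment_system`.
#' @param path output JSON path.
#' @export
write_system_json <- function(sys, path) {
  cm <- sys$net$compiled
  out <- list(
    method = sys$method,
    species = sys$net$species,
    blocks = as.list(sys$blocks),
    dimension = sys$dim,
    volume = sys$net$volume,
    reactions = lapply(seq_len(sys$net$R), function(r) {
      list(order = cm$order[r],
           species = sys$net$species[c(cm$idx1[r], cm$idx2[r])[
             c(cm$idx1[r], cm$idx2[r]) > 0]],
           rate = cm$rate_name[r],
           compartment = cm$reaction_compartment[r],
           omega = cm$omega_r[r],
           nu = unname(cm$nu[, r]))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Human-readable listing of a generated system
#'
#' Renders the generated equations as plain text: one line per state
#' variable with its per-reaction right-hand-side contributions.
#'
#' @param sys a `moment_system`.
#' @param file optional path; if given, the listing is written there.
#' @return character vector of lines, invisibly if written to file.
#' @export
describe_system <- function(sys, file = NULL) {
  net <- sys$net
  sp <- net$species
  cm <- net$compiled
  lines <- c(
    sprintf("%s system for %d-species network (dimension %d)",
            sys$method, sys$M, sys$dim),
    sprintf("state blocks: %s",
            paste(names(sys$blocks), sys$blocks, sep = "[", collapse = "] ")),
    "reaction rate functions (concentration units):"
  )
  k <- vapply(net$reactions, function(rx) {
    if (is.character(rx$rate)) rx$rate else format(rx$rate)
  }, character(1))
  for (r in seq_len(net$R)) {
    form <- switch(cm$order[r] + 1L,
      k[r],
      paste0(k[r], " * ", sp[cm$idx1[r]]),
      if (cm$idx1[r] == cm$idx2[r]) {
        paste0(k[r], " * ", sp[cm$idx1[r]], " * (", sp[cm$idx1[r]],
               " - 1/Omega_r)")
      } else {
        paste0(k[r], " * ", sp[cm$idx1[r]], " * ", sp[cm$idx2[r]])
      })
    u <- if (cm$input_idx[r] > 0L) {
      paste0(" * ", names(net$inputs)[cm$input_idx[r]], "(t)")
    } else ""
    lines <- c(lines, sprintf("  f%d = %s%s", r, form, u))
  }
  lines <- c(lines, "mean equations: d<x_i>/dt = sum_r A_ir <f_r>",
             "effective stoichiometry A (volume-rescaled nu):")
  am <- net$compiled$A
  for (i in seq_len(net$M)) {
    lines <- c(lines, sprintf("  d%s/dt: %s", sp[i],
                              paste(sprintf("%+g*f%d", am[i, ], seq_len(net$R))[am[i, ] != 0],
                                    collapse = " ")))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
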