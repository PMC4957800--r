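# Exact polynomial representation of mass-action rate functions.
#
# Every mass-action propensity up to bimolecular is a quadratic polynomial in
# the concentration vector,
#   g_r(x) = c_r + b_r' x + (1/2) x' H_r x,
# with at most two nonzero coefficients. All moment-equation and sensitivity
# code evaluates g_r, its gradient and Hessian contractions exactly from the
# stored (order, species index, rate constant) structure; this is the closed
# symbolic form of the rate laws. The microscopic form (f-hat) differs from
# the macroscopic limit (f) only for homodimerization, where
# f-hat = k x (x - 1/Omega_r) versus f = k x^2.
#
# All evaluators are pure arithmetic so that they can be called with complex
# rate constants or states (complex-step differentiation).

# Build the coefficient structure for a network at parameter values theta.
reaction_coefficients <- function(net, theta = NULL, microscopic = TRUE) {
  cm <- net$compiled
  pars <- as.list(net$parameters)
  if (!is.null(theta)) pars[names(theta)] <- theta
  k <- lapply(net$reactions, function(rx) {
    if (is.character(rx$rate)) pars[[rx$rate]] else rx$rate
  })
  k <- do.call(c, k)
  list(k = k, order = cm$order, i1 = cm$idx1, i2 = cm$idx2,
       omega_r = cm$omega_r, micro = microscopic,
       het = cm$order == 2L & cm$idx1 != cm$idx2,
       hom = cm$order == 2L & cm$idx1 == cm$idx2)
}

# g_r(x) for all reactions; u = per-reaction input factors (or NULL).
eval_rates <- function(co, x, u = NULL) {
  f <- co$k
  w1 <- which(co$order == 1L)
  if (length(w1)) f[w1] <- co$k[w1] * x[co$i1[w1]]
  wh <- which(co$het)
  if (length(wh)) f[wh] <- co$k[wh] * x[co$i1[wh]] * x[co$i2[wh]]
  wo <- which(co$hom)
  if (length(wo)) {
    xx <- x[co$i1[wo]]
    f[wo] <- if (isTRUE(co$micro)) {
      co$k[wo] * xx * (xx - 1 / co$omega_r[wo])
    } else {
      co$k[wo] * xx * xx
    }
  }
  if (!is.null(u)) f <- f * u
  f
}

# Gradient matrix: row r = d g_r / d x (R x M).
eval_grad <- function(co, x, M, u = NULL) {
  R <- length(co$k)
  Jf <- matrix(if (is.complex(x) || is.complex(co$k)) 0i else 0, R, M)
  w1 <- which(co$order == 1L)
  if (length(w1)) Jf[cbind(w1, co$i1[w1])] <- co$k[w1]
  wh <- which(co$het)
  if (length(wh)) {
    Jf[cbind(wh, co$i1[wh])] <- Jf[cbind(wh, co$i1[wh])] +
      co$k[wh] * x[co$i2[wh]]
    Jf[cbind(wh, co$i2[wh])] <- Jf[cbind(wh, co$i2[wh])] +
      co$k[wh] * x[co$i1[wh]]
  }
  wo <- which(co$hom)
  if (length(wo)) {
    xx <- x[co$i1[wo]]
    g <- if (isTRUE(co$micro)) co$k[wo] * (2 * xx - 1 / co$omega_r[wo])
         else 2 * co$k[wo] * xx
    Jf[cbind(wo, co$i1[wo])] <- Jf[cbind(wo, co$i1[wo])] + g
  }
  if (!is.null(u)) Jf <- Jf * u
  Jf
}

# Hessian contraction H_r : W for a symmetric matrix W (per reaction).
hess_contract <- function(co, W, u = NULL) {
  h <- co$k * 0
  wh <- which(co$het)
  if (length(wh)) h[wh] <- 2 * co$k[wh] * W[cbind(co$i1[wh], co$i2[wh])]
  wo <- which(co$hom)
  if (length(wo)) h[wo] <- 2 * co$k[wo] * W[cbind(co$i1[wo], co$i1[wo])]
  if (!is.null(u)) h <- h * u
  h
}

# Bilinear form a' H_r b (per reaction); H_r is symmetric.
hess_bilinear <- function(co, a, b, u = NULL) {
  h <- co$k * 0
  wh <- which(co$het)
  if (length(wh)) {
    h[wh] <- co$k[wh] * (a[co$i1[wh]] * b[co$i2[wh]] +
                         a[co$i2[wh]] * b[co$i1[wh]])
  }
  wo <- which(co$hom)
  if (length(wo)) h[wo] <- 2 * co$k[wo] * a[co$i1[wo]] * b[co$i1[wo]]
  if (!is.null(u)) h <- h * u
  h
}

# sum_s phi_s d^2 f_r / d phi_s^2 (per reaction): nonzero for homodimers.
hess_diag_phi <- function(co, phi, u = NULL) {
  h <- co$k * 0
  wo <- which(co$hom)
  if (length(wo)) h[wo] <- 2 * co$k[wo] * phi[co$i1[wo]]
  if (!is.null(u)) h <- h * u
  h
}

# Matrix-vector product H_r v for reaction r (length-M vector).
hess_vec <- function(co, r, v, M) {
  out <- rep(v[1] * 0, M)
  if (co$het[r]) {
    out[co$i1[r]] <- co$k[r] * v[co$i2[r]]
    out[co$i2[r]] <- out[co$i2[r]] + co$k[r] * v[co$i1[r]]
  } else if (co$hom[r]) {
    out[co$i1[r]] <- 2 * co$k[r] * v[co$i1[r]]
  }
  out
}

# Sigma H_r Sigma (M x M) for reaction r.
sig_h_sig <- function(co, r, Sig) {
  if (co$het[r]) {
    co$k[r] * (Sig[, co$i1[r]] %o% Sig[co$i2[r], ] +
               Sig[, co$i2[r]] %o% Sig[co$i1[r], ])
  } else if (co$hom[r]) {
    2 * co$k[r] * (Sig[, co$i1[r]] %o% Sig[co$i1[r], ])
  } else {
    matrix(Sig[1, 1] * 0, nrow(Sig), nrow(Sig))
  }
}

# H_r : T[, , j] for all j (length-M vector), T a third-moment array.
hess_t3 <- function(co, r, T3) {
  if (co$het[r]) {
    2 * co$k[r] * T3[co$i1[r], co$i2[r], ]
  } else if (co$hom[r]) {
    2 * co$k[r] * T3[co$i1[r], co$i1[r], ]
  } else {
    rep(T3[1] * 0, dim(T3)[1])
  }
}
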