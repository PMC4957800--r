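#' Define a single mass-action reaction
#'
#' A reaction is specified by integer reactant and product stoichiometries,
#' a rate parameter, and optionally a time-dependent input modifier.
#' Reactant-side molecularity is restricted to at most 2 (zeroth, first and
#' second order mass-action kinetics).
#'
#' @param reactants named integer vector of reactant stoichiometries
#'   (e.g. `c(A = 2)`); use `NULL` or an empty vector for a source reaction.
#' @param products named integer vector of product stoichiometries.
#' @param rate name of a (strictly positive) rate constant in the network's
#'   parameter list, or a positive number.
#' @param input optional name of a network input function `u(t)` that
#'   multiplies the reaction rate.
#' @param compartment optional compartment in which the reaction takes place;
#'   defaults to the compartment of the reactants (or of the first product
#'   for source reactions).
#'
#' @return An object of class `"reaction"`.
#' @export
reaction <- function(reactants = NULL, products = NULL, rate, input = NULL,
                     compartment = NULL) {
  reactants <- normalize_stoich(reactants)
  products <- normalize_stoich(products)
  if (sum(reactants) > 2L) {
    stop("unsupported reaction: reactant-side molecularity ",
         sum(reactants), " exceeds 2 (only mass-action reactions up to ",
         "bimolecular are supported)", call. = FALSE)
  }
  structure(
    list(reactants = reactants, products = products, rate = rate,
         input = input, compartment = compartment),
    class = "reaction"
  )
}

normalize_stoich <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("stoichiometries must be named by species", call. = FALSE)
  }
  if (any(x != round(x)) || any(x < 0)) {
    stop("stoichiometric coefficients must be non-negative integers",
         call. = FALSE)
  }
  x <- x[x > 0]
  stats::setNames(as.integer(x), names(x))
}

#' Define an observable
#'
#' Observables are linear read-outs of species concentrations with an
#' optional multiplicative scale and additive offset (nuisance parameters of
#' the measurement process, e.g. Western-blot scaling factors).
#'
#' @param name observable name.
#' @param species a species name, or a named numeric vector of weights for a
#'   linear combination of species concentrations.
#' @param scale scale parameter name or number (default 1).
#' @param offset offset parameter name or number (default 0).
#' @return An object of class `"observable"`.
#' @export
observable <- function(name, species, scale = 1, offset = 0) {
  if (is.character(species) && is.null(names(species))) {
    species <- stats::setNames(rep(1, length(species)), species)
  }
  structure(list(name = name, weights = species, scale = scale,
                 offset = offset),
            class = "observable")
}

#' Build a validated reaction network
#'
#' Constructs the central model object: an ordered species list with
#' compartment assignments, a set of mass-action reactions (molecularity at
#' most 2), named positive parameters, the reference reaction volume
#' \eqn{\Omega}, optional time-dependent inputs, and observables. The
#' constructor validates all invariants and precompiles the stoichiometric
#' and propensity structure used by the simulators and moment-system
#' generators.
#'
#' Concentrations are measured in molecules per \eqn{\mu m^3} and
#' \eqn{\Omega} in \eqn{\mu m^3} (multiply by [nM_per_molecule_per_um3] to
#' convert concentrations to nM). The dimerization propensity convention is
#' \eqn{a = k\, n_A (n_A - 1)/\Omega}: the 1/2 symmetry factor is absorbed
#' into the rate constant \eqn{k}, so calibrate rate constants accordingly.
#'
#' For reactions transporting species between compartments the propensity is
#' evaluated in the source compartment's volume and the concentration
#' increment in the target compartment is scaled by the source/target volume
#' ratio. This is the unique convention that conserves molecule counts and
#' keeps rate-constant units compartment-independent; see the methods
#' vignette. Bimolecular reactants must share a compartment.
#'
#' @param species character vector of species names, or a named character
#'   vector mapping species to compartments.
#' @param reactions list of [reaction()] objects.
#' @param parameters named numeric vector of strictly positive parameters
#'   (rate constants, initial concentrations, noise parameters).
#' @param volume reference reaction volume \eqn{\Omega > 0} (\eqn{\mu m^3}).
#' @param compartments named numeric vector of compartment volume fractions
#'   relative to `volume` (default a single compartment `cell = 1`).
#' @param inputs named list of functions of time multiplying reaction rates.
#' @param observables list of [observable()] objects; defaults to one
#'   identity observable per species.
#'
#' @return An object of class `"reaction_network"`.
#' @seealso [microscopic_propensity()], [macroscopic_rate()],
#'   [stoichiometry_matrices()], [read_network_yaml()]
#' @examples
#' net <- reaction_network(
#'   species = "A",
#'   reactions = list(
#'     reaction(NULL, c(A = 1), rate = "k"),
#'     reaction(c(A = 1), NULL, rate = "gamma")
#'   ),
#'   parameters = c(k = 10, gamma = 2),
#'   volume = 1
#' )
#' @export
reaction_network <- function(species, reactions, parameters, volume,
                             compartments = NULL, inputs = NULL,
                             observables = NULL) {
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    stop("reaction volume must be a positive number", call. = FALSE)
  }
  if (is.null(compartments)) compartments <- c(cell = 1)
  if (is.null(names(compartments)) || any(compartments <= 0)) {
    stop("compartments must be a named vector of positive volume fractions",
         call. = FALSE)
  }
  if (!is.null(names(species)) && all(nzchar(names(species)))) {
    sp_names <- names(species)
    sp_comp <- unname(species)
  } else {
    sp_names <- as.character(species)
    sp_comp <- rep(names(compartments)[1], length(sp_names))
  }
  if (anyDuplicated(sp_names)) stop("duplicate species names", call. = FALSE)
  if (!all(sp_comp %in% names(compartments))) {
    stop("unknown compartment in species assignment: ",
         paste(setdiff(sp_comp, names(compartments)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(parameters)) parameters <- stats::setNames(numeric(0), character(0))
  if (length(parameters) && (is.null(names(parameters)) ||
                             any(!nzchar(names(parameters))))) {
    stop("parameters must be named", call. = FALSE)
  }
  if (any(!is.finite(parameters)) || any(parameters <= 0)) {
    stop("all parameters must be strictly positive and finite", call. = FALSE)
  }
  inputs <- inputs %||% list()
  if (length(inputs) && !all(vapply(inputs, is.function, logical(1)))) {
    stop("inputs must be functions of time", call. = FALSE)
  }

  M <- length(sp_names)
  R <- length(reactions)
  if (R == 0L) stop("network needs at least one reaction", call. = FALSE)
  for (r in reactions) {
    if (!inherits(r, "reaction")) {
      stop("reactions must be built with reaction()", call. = FALSE)
    }
    unknown <- setdiff(c(names(r$reactants), names(r$products)), sp_names)
    if (length(unknown)) {
      stop("reaction references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  net <- structure(
    list(species = sp_names, species_compartment = sp_comp,
         compartments = compartments, reactions = reactions,
         parameters = parameters, volume = volume, inputs = inputs,
         observables = observables, M = M, R = R),
    class = "reaction_network"
  )
  if (is.null(observables)) {
    net$observables <- lapply(sp_names, function(s) observable(s, s))
  }
  compile_network(net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a rate/scale/offset entry to a numeric value given parameters.
resolve_param <- function(x, parameters, what = "parameter") {
  if (is.character(x)) {
    if (!x %in% names(parameters)) {
      stop("unknown ", what, " name: ", x, call. = FALSE)
    }
    parameters[[x]]
  } else {
    x
  }
}

# Precompile stoichiometry, reaction orders and volume factors.
compile_network <- function(net) {
  M <- net$M; R <- net$R
  sp <- net$species
  nu_minus <- matrix(0L, M, R, dimnames = list(sp, NULL))
  nu_plus <- matrix(0L, M, R, dimnames = list(sp, NULL))
  order <- integer(R); idx1 <- integer(R); idx2 <- integer(R)
  rate_name <- character(R); input_idx <- integer(R)
  comp_r <- character(R)
  comp_of <- stats::setNames(net$species_compartment, sp)

  for (r in seq_len(R)) {
    rx <- net$reactions[[r]]
    for (s in names(rx$reactants)) nu_minus[s, r] <- rx$reactants[[s]]
    for (s in names(rx$products)) nu_plus[s, r] <- rx$products[[s]]
    ord <- sum(rx$reactants)
    order[r] <- ord
    if (ord == 1L) {
      idx1[r] <- match(names(rx$reactants), sp)
    } else if (ord == 2L) {
      if (length(rx$reactants) == 1L) {       # homodimerization 2A -> ...
        idx1[r] <- idx2[r] <- match(names(rx$reactants), sp)
      } else {                                 # heterodimerization A+B -> ...
        ii <- match(names(rx$reactants), sp)
        idx1[r] <- ii[1]; idx2[r] <- ii[2]
        if (comp_of[ii[1]] != comp_of[ii[2]]) {
          stop("bimolecular reactants must share a compartment (reaction ",
               r, ")", call. = FALSE)
        }
      }
    }
    kval <- resolve_param(rx$rate, net$parameters, "rate parameter")
    if (!is.finite(kval) || kval <= 0) {
      stop("rate constant of reaction ", r, " must be strictly positive",
           call. = FALSE)
    }
    rate_name[r] <- if (is.character(rx$rate)) rx$rate else NA_character_
    if (!is.null(rx$input)) {
      if (!rx$input %in% names(net$inputs)) {
        stop("reaction ", r, " references unknown input: ", rx$input,
             call. = FALSE)
      }
      input_idx[r] <- match(rx$input, names(net$inputs))
    }
    # reaction compartment: reactants' compartment, else explicit, else the
    # first product's compartment (source reactions)
    comp_r[r] <- rx$compartment %||% {
      if (ord > 0L) comp_of[[names(rx$reactants)[1]]]
      else if (length(rx$products)) comp_of[[names(rx$products)[1]]]
      else names(net$compartments)[1]
    }
    if (!comp_r[r] %in% names(net$compartments)) {
      stop("reaction ", r, " in unknown compartment: ", comp_r[r],
           call. = FALSE)
    }
    if (ord >= 1L && comp_r[r] != comp_of[[names(rx$reactants)[1]]]) {
      stop("reaction ", r, ": reactions occur in their reactants' ",
           "compartment", call. = FALSE)
    }
  }

  omega_i <- net$volume * unname(net$compartments[net$species_compartment])
  omega_r <- net$volume * unname(net$compartments[comp_r])
  nu <- nu_plus - nu_minus

  net$compiled <- list(
    nu_minus = nu_minus, nu_plus = nu_plus, nu = nu,
    order = order, idx1 = idx1, idx2 = idx2,
    rate_name = rate_name, input_idx = input_idx,
    reaction_compartment = comp_r,
    omega_i = omega_i, omega_r = omega_r,
    # effective concentration-space stoichiometry and diffusion factor:
    # dx_i per firing = nu_ir / omega_i; firing rate = omega_r * f_r(x)
    A = nu * rep(omega_r, each = M) / omega_i,
    P = nu * rep(sqrt(omega_r), each = M) / omega_i
  )
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network: ", x$M, " species, ", x$R, " reactions, ",
      length(x$parameters), " parameters, volume ", x$volume, "\n", sep = "")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  inv <- stoichiometry_matrices(x)
  for (r in seq_len(x$R)) {
    rx <- x$reactions[[r]]
    lhs <- fmt_side(rx$reactants); rhs <- fmt_side(rx$products)
    cat(sprintf("  R%d: %s -> %s  [%s%s]\n", r, lhs, rhs,
                if (is.character(rx$rate)) rx$rate else format(rx$rate),
                if (!is.null(rx$input)) paste0(" * ", rx$input, "(t)") else ""))
  }
  invisible(x)
}

fmt_side <- function(st) {
  if (!length(st)) return("0")
  paste(ifelse(st > 1, paste0(st, " "), ""), names(st),
        sep = "", collapse = " + ")
}

#' Rate-constant values of a network, optionally overridden
#'
#' @param net a [reaction_network()].
#' @param theta optional named numeric vector overriding parameters.
#' @return numeric vector of per-reaction rate constants.
#' @keywords internal
reaction_rates <- function(net, theta = NULL) {
  pars <- net$parameters
  if (!is.null(theta)) pars[names(theta)] <- theta
  vapply(net$reactions, function(rx) resolve_param(rx$rate, pars), numeric(1))
}

#' Microscopic propensities
#'
#' Evaluates the per-reaction firing rates \eqn{a_r(n, t) = \Omega_r
#' \hat f_r(n, t)} (units 1/s) at a molecule-count state, using mass-action
#' combinatorics: \eqn{k \Omega_r} (zeroth order), \eqn{k n_A} (first
#' order), \eqn{k n_A n_B / \Omega_r} (heterodimeric) and
#' \eqn{k n_A (n_A - 1)/\Omega_r} (homodimeric). Propensities are zero
#' whenever reactant counts are insufficient, so molecule counts can never
#' go negative.
#'
#' @param net a [reaction_network()].
#' @param state integer vector of molecule counts (length `net$M`).
#' @param t time (s), used for time-dependent inputs.
#' @param theta optional parameter overrides.
#' @return numeric vector of length `net$R` of non-negative firing rates.
#' @export
microscopic_propensity <- function(net, state, t = 0, theta = NULL) {
  cm <- net$compiled
  if (length(state) != net$M) stop("state dimension must equal M", call. = FALSE)
  if (any(state < 0)) stop("negative molecule counts", call. = FALSE)
  k <- reaction_rates(net, theta)
  n1 <- ifelse(cm$order >= 1L, state[pmax(cm$idx1, 1L)], 1)
  a <- numeric(net$R)
  for (r in seq_len(net$R)) {
    a[r] <- switch(cm$order[r] + 1L,
      k[r] * cm$omega_r[r],
      k[r] * state[cm$idx1[r]],
      if (cm$idx1[r] == cm$idx2[r]) {
        k[r] * state[cm$idx1[r]] * (state[cm$idx1[r]] - 1) / cm$omega_r[r]
      } else {
        k[r] * state[cm$idx1[r]] * state[cm$idx2[r]] / cm$omega_r[r]
      })
  }
  a <- pmax(a, 0)
  a * input_factors(net, t)
}

input_factors <- function(net, t) {
  cm <- net$compiled
  u <- rep(1, net$R)
  has <- which(cm$input_idx > 0L)
  for (r in has) u[r] <- net$inputs[[cm$input_idx[r]]](t)
  u
}

#' Macroscopic rate functions
#'
#' Evaluates \eqn{f_r(\phi, t) = \lim_{\Omega\to\infty} \hat f_r(\Omega
#' \phi)}: \eqn{k}, \eqn{k\phi_A}, \eqn{k\phi_A\phi_B}, \eqn{k\phi_A^2} for
#' molecularities 0, 1, 2 (hetero) and 2 (homo).
#'
#' @param net a [reaction_network()].
#' @param phi non-negative concentration vector (molecules per \eqn{\mu m^3}).
#' @param t time (s).
#' @param theta optional parameter overrides.
#' @return numeric vector of macroscopic rates, length `net$R`.
#' @export
macroscopic_rate <- function(net, phi, t = 0, theta = NULL) {
  if (length(phi) != net$M) stop("phi dimension must equal M", call. = FALSE)
  if (any(phi < 0)) stop("negative concentrations", call. = FALSE)
  co <- reaction_coefficients(net, theta, microscopic = FALSE)
  drop(eval_rates(co, phi, input_factors(net, t)))
}

#' Stoichiometry matrices
#'
#' @param net a [reaction_network()].
#' @return list with integer matrices `nu_minus`, `nu_plus` and
#'   `nu = nu_plus - nu_minus`, each species-by-reaction.
#' @export
stoichiometry_matrices <- function(net) {
  net$compiled[c("nu_minus", "nu_plus", "nu")]
}

#' Cubic-spline input helper
#'
#' Builds a smooth time-dependent input function through given knots, for use
#' as a reaction-rate modifier (e.g. a measured upstream activation signal
#' driving a phosphorylation reaction).
#'
#' @param times,values spline knots.
#' @return a function of time.
#' @export
input_spline <- function(times, values) {
  stats::splinefun(times, values, method = "natural")
}

#' Conversion constant: molecules per cubic micrometre to nanomolar
#'
#' One molecule per \eqn{\mu m^3} equals `nM_per_molecule_per_um3` nM
#' (1/0.602214, from Avogadro's number). The package core carries no implicit
#' Avogadro factors; apply this constant at the interface when data are in nM.
#' @export
nM_per_molecule_per_um3 <- 1 / 0.602214076
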