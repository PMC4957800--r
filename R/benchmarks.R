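# Built-in benchmark networks and the in-silico estimation-error protocol:
# generate SSA snapshot datasets across volumes and sample sizes, fit the
# moment-based descriptions, and quantify squared estimation error, model
# weights and rejection frequencies.

#' Trimerization benchmark network
#'
#' Bursty synthesis of monomers (realized as a fixed burst of size 2,
#' `0 -> 2A`), reversible dimerization `2A <-> B`, reversible trimerization
#' `A + B <-> C` and monomer degradation `A -> 0`: 3 species, 6 reactions,
#' 6 kinetic parameters plus the reaction volume (7 parameters), two of the
#' reactions bimolecular. Monomer, dimer and trimer concentrations are
#' observable. The default rates are the package's canonical fixture
#' constants: strongly bimolecular kinetics at low copy numbers (order 1-100
#' molecules at volumes of order 10) with relaxation times of order 1-10 s,
#' so that finite-volume fluctuation corrections are substantial in the
#' intermediate volume regime.
#'
#' @param volume reaction volume (default 6).
#' @param parameters named rate-constant overrides.
#' @return a [reaction_network()].
#' @export
trimerization_network <- function(volume = 6, parameters = NULL) {
  pars <- c(k_syn = 0.4, k_dim = 1.5, k_undim = 0.1,
            k_tri = 1.2, k_untri = 0.1, k_deg = 0.8)
  if (!is.null(parameters)) pars[names(parameters)] <- parameters
  reaction_network(
    species = c("A", "B", "C"),
    reactions = list(
      reaction(NULL, c(A = 2), rate = "k_syn"),
      reaction(c(A = 2), c(B = 1), rate = "k_dim"),
      reaction(c(B = 1), c(A = 2), rate = "k_undim"),
      reaction(c(A = 1, B = 1), c(C = 1), rate = "k_tri"),
      reaction(c(C = 1), c(A = 1, B = 1), rate = "k_untri"),
      reaction(c(A = 1), NULL, rate = "k_deg")
    ),
    parameters = pars,
    volume = volume
  )
}

#' Enzymatic degradation benchmark network
#'
#' Transcription, translation, mRNA turnover and enzymatic degradation of
#' the protein through a protein-enzyme complex: species mRNA, protein P,
#' enzyme E and complex C; 6 reactions of which one (complex formation) is
#' bimolecular; 6 kinetic parameters plus the initial enzyme concentration
#' `E0` and the reaction volume (8 parameters). mRNA, protein and complex
#' concentrations are observable.
#'
#' @param volume reaction volume (default 6).
#' @param parameters named parameter overrides (kinetic rates and `E0`).
#' @return a [reaction_network()].
#' @export
enzymatic_degradation_network <- function(volume = 6, parameters = NULL) {
  pars <- c(k_tx = 1, k_tl = 2, k_mdeg = 0.5,
            k_bind = 0.1, k_unbind = 0.5, k_cat = 0.5, E0 = 4)
  if (!is.null(parameters)) pars[names(parameters)] <- parameters
  reaction_network(
    species = c("mRNA", "P", "E", "C"),
    reactions = list(
      reaction(NULL, c(mRNA = 1), rate = "k_tx"),
      reaction(c(mRNA = 1), c(mRNA = 1, P = 1), rate = "k_tl"),
      reaction(c(mRNA = 1), NULL, rate = "k_mdeg"),
      reaction(c(P = 1, E = 1), c(C = 1), rate = "k_bind"),
      reaction(c(C = 1), c(P = 1, E = 1), rate = "k_unbind"),
      reaction(c(C = 1), c(E = 1), rate = "k_cat")
    ),
    parameters = pars,
    volume = volume,
    observables = list(observable("mRNA", "mRNA"), observable("P", "P"),
                       observable("C", "C"))
  )
}

#' Initial concentrations for the enzymatic degradation fixture
#'
#' @param net the fixture network.
#' @return vector usable as `mu0` (enzyme at `E0`, everything else empty).
#' @export
enzymatic_degradation_mu0 <- function(net) {
  c(mRNA = 0, P = 0, E = unname(net$parameters["E0"]), C = 0)
}

#' Two-compartment STAT-pathway skeleton (structural fixture)
#'
#' An 8-species, two-compartment signaling skeleton: cytoplasmic STAT is
#' phosphorylated under a time-dependent upstream input, phosphorylated STAT
#' dimerizes (the nonlinear reaction), the dimer translocates to the nucleus
#' and its delayed export back to the cytoplasm is described by a sequence
#' of four intermediate states. This fixture is used for
#' equation-generation and state-count tests only, not for fitting
#' experimental data.
#'
#' @param volume reference (cytoplasmic) volume.
#' @param nucleus_fraction nuclear volume as a fraction of the reference.
#' @return a [reaction_network()] with 8 species.
#' @export
jakstat_skeleton <- function(volume = 1.4, nucleus_fraction = 0.32) {
  u <- input_spline(c(0, 5, 10, 20, 40, 60), c(0.05, 0.7, 1, 0.75, 0.4, 0.2))
  reaction_network(
    species = c(STAT = "cyt", pSTAT = "cyt", pDim = "cyt", nDim = "nuc",
                nExp1 = "nuc", nExp2 = "nuc", nExp3 = "nuc", nExp4 = "nuc"),
    compartments = c(cyt = 1, nuc = nucleus_fraction),
    reactions = list(
      reaction(c(STAT = 1), c(pSTAT = 1), rate = "p1", input = "pEpoR"),
      reaction(c(pSTAT = 2), c(pDim = 1), rate = "p2"),
      reaction(c(pDim = 1), c(nDim = 1), rate = "p3"),
      reaction(c(nDim = 1), c(nExp1 = 1), rate = "p4"),
      reaction(c(nExp1 = 1), c(nExp2 = 1), rate = "p4"),
      reaction(c(nExp2 = 1), c(nExp3 = 1), rate = "p4"),
      reaction(c(nExp3 = 1), c(nExp4 = 1), rate = "p4"),
      reaction(c(nExp4 = 1), c(STAT = 2), rate = "p4")
    ),
    parameters = c(p1 = 0.02, p2 = 0.5, p3 = 0.1, p4 = 0.2, STAT0 = 120,
                   s_tSTAT = 1, s_pSTAT = 1),
    volume = volume,
    inputs = list(pEpoR = u),
    observables = list(
      observable("tSTAT", c(STAT = 1, pSTAT = 1, pDim = 2), scale = "s_tSTAT"),
      observable("pSTAT", c(pSTAT = 1, pDim = 2), scale = "s_pSTAT")
    )
  )
}

#' Birth-death fixture
#'
#' `0 -> A` at rate `k`, `A -> 0` at rate `gamma`; the stationary CME is
#' Poisson with mean `k/gamma * volume` molecules. Used throughout the test
#' suite as the analytically solvable reference.
#'
#' @param volume reaction volume.
#' @param k,gamma birth and death rates.
#' @return a [reaction_network()].
#' @export
birth_death_network <- function(volume = 1, k = 10, gamma = 2) {
  reaction_network(
    species = "A",
    reactions = list(
      reaction(NULL, c(A = 1), rate = "k"),
      reaction(c(A = 1), NULL, rate = "gamma")
    ),
    parameters = c(k = k, gamma = gamma),
    volume = volume
  )
}

#' Canonical in-silico protocol settings for the trimerization study
#'
#' The desk-scale study conditions used by the package's estimation-error
#' benchmark: four volumes spanning one decade of the intermediate regime,
#' 1000 cells per timepoint, 20 replicate datasets, ten snapshot times
#' covering the transient and the approach to steady state, no technical
#' noise, and box bounds one order of magnitude around the true rates.
#'
#' @return list with `volumes`, `n_cells`, `replicates`, `timepoints`,
#'   `mu0`, `theta_true`, `n_starts`, `bounds_factor`.
#' @export
trimerization_protocol <- function() {
  list(
    volumes = 6.3 * 10^(seq(0, 1, length.out = 4)),
    n_cells = 1000,
    replicates = 20,
    timepoints = c(0.25, 0.5, 1, 1.5, 2.5, 4, 6, 9, 13, 18),
    mu0 = c(A = 0, B = 0, C = 0),
    theta_true = trimerization_network()$parameters,
    n_starts = 8,
    bounds_factor = 10
  )
}

method_set_for_mode <- function(data_mode) {
  if (data_mode == "mean") c("RRE", "EMRE", "2MA") else c("LNA", "IOS", "3MA")
}

#' Estimation-error sweep over volumes and sample sizes
#'
#' The in-silico benchmarking protocol: for every grid cell (volume, sample
#' size) and replicate, generate an SSA snapshot dataset at the true
#' parameters, summarize it, fit each requested approximation by multi-start
#' maximum likelihood, and record the squared estimation error
#' `error2 = ||theta_true - theta_hat||^2` together with per-replicate
#' Akaike weights across the fitted methods and chi-square rejection
#' outcomes. Mean-only data are fitted with RRE/EMRE/2MA, mean+variance data
#' with LNA/IOS/3MA (the default method sets).
#'
#' @param net_factory function of the volume returning the network.
#' @param theta_true named true kinetic parameters (the estimated set).
#' @param volumes vector of reaction volumes.
#' @param sample_sizes vector of cells per timepoint.
#' @param replicates replicate datasets per grid cell (>= 2).
#' @param data_mode `"mean"` or `"mean+variance"`.
#' @param methods methods to fit (defaults chosen from `data_mode`).
#' @param timepoints snapshot times.
#' @param mu0 initial concentrations (or a function of the network).
#' @param seed master seed; per-cell seeds are derived deterministically.
#' @param n_starts multi-start count per fit (desk-scale default 10).
#' @param bounds_factor box bounds `theta_true / f` to `theta_true * f`.
#' @param alpha rejection level (default 0.01).
#' @param min_agree convergence criterion forwarded to [fit()].
#' @param verbose print per-cell progress.
#' @return A `"sweep_result"` with `$results` (one row per replicate and
#'   method: error2, J, converged, rejected, AIC weight) and `$summary`
#'   (per cell and method: median error2, symmetric 80% percentile
#'   interval, MSE decomposition into squared bias plus estimator variance,
#'   median AIC weight, rejection frequency).
#' @export
estimation_error_sweep <- function(net_factory, theta_true, volumes,
                                   sample_sizes, replicates = 20,
                                   data_mode = c("mean", "mean+variance"),
                                   methods = NULL, timepoints,
                                   mu0, seed = 1, n_starts = 10,
                                   bounds_factor = 10, alpha = 0.01,
                                   min_agree = 3, verbose = FALSE) {
  data_mode <- match.arg(data_mode)
  stopifnot(replicates >= 2)
  methods <- methods %||% method_set_for_mode(data_mode)
  methods <- vapply(methods, normalize_method, character(1))
  set.seed(seed)
  seed_tab <- array(sample.int(.Machine$integer.max %/% 2,
                               length(volumes) * length(sample_sizes) *
                                 replicates * 2),
                    c(length(volumes), length(sample_sizes), replicates, 2))
  rows <- list()
  for (vi in seq_along(volumes)) {
    net <- net_factory(volumes[vi])
    mu0v <- if (is.function(mu0)) mu0(net) else mu0
    for (ni in seq_along(sample_sizes)) {
      N <- sample_sizes[ni]
      for (rep in seq_len(replicates)) {
        if (verbose) {
          message(sprintf("volume %g, N %d, replicate %d", volumes[vi],
                          N, rep))
        }
        dat <- simulate_snapshot_ensemble(net, mu0v, timepoints, N,
                                          seed = seed_tab[vi, ni, rep, 1],
                                          theta = theta_true)
        summ <- summarize_snapshots(dat)
        fits <- list()
        for (m in methods) {
          sp <- objective_spec(net, m, summ, estimate = names(theta_true),
                               lower = theta_true / bounds_factor,
                               upper = theta_true * bounds_factor,
                               mu0 = mu0v, data_mode = data_mode)
          f <- try(fit(sp, n_starts = n_starts,
                       seed = seed_tab[vi, ni, rep, 2],
                       min_agree = min_agree), silent = TRUE)
          fits[[m]] <- f
        }
        ok <- !vapply(fits, inherits, logical(1), "try-error")
        wts <- rep(NA_real_, length(methods))
        names(wts) <- methods
        if (sum(ok) > 1) {
          aw <- akaike_weights(fits[ok])
          wts[names(fits)[ok]] <- aw$w_AIC
        } else if (sum(ok) == 1) {
          wts[names(fits)[ok]] <- 1
        }
        for (m in methods) {
          f <- fits[[m]]
          failed <- inherits(f, "try-error")
          err2 <- conv <- rej <- NA
          theta_hat <- NULL
          if (!failed) {
            err2 <- sum((theta_true - f$theta_hat[names(theta_true)])^2)
            conv <- f$converged
            rej <- try(chi_square_rejection(f, alpha = alpha)$reject,
                       silent = TRUE)
            if (inherits(rej, "try-error")) rej <- NA
            theta_hat <- f$theta_hat
          }
          row <- data.frame(volume = volumes[vi], n_cells = N,
                            replicate = rep, method = m, failed = failed,
                            error2 = as.numeric(err2),
                            J = if (failed) NA_real_ else f$J,
                            converged = as.logical(conv),
                            rejected = as.logical(rej),
                            w_AIC = wts[[m]], stringsAsFactors = FALSE)
          for (p in names(theta_true)) {
            row[[paste0("hat_", p)]] <- if (failed) NA_real_ else
              unname(theta_hat[p])
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summary <- aggregate_sweep(results, theta_true)
  structure(list(results = results, summary = summary,
                 theta_true = theta_true, volumes = volumes,
                 sample_sizes = sample_sizes, replicates = replicates,
                 data_mode = data_mode, methods = methods, seed = seed),
            class = "sweep_result")
}

aggregate_sweep <- function(results, theta_true) {
  sp <- split(results, list(results$volume, results$n_cells,
                            results$method), drop = TRUE)
  rows <- lapply(sp, function(g) {
    ok <- !g$failed & is.finite(g$error2)
    frac_ok <- mean(ok)
    e <- g$error2[ok]
    hats <- as.matrix(g[ok, paste0("hat_", names(theta_true)), drop = FALSE])
    bias2 <- variance <- NA_real_
    if (sum(ok) >= 2) {
      bias2 <- sum((colMeans(hats) - theta_true)^2)
      variance <- sum(apply(hats, 2, function(x) mean((x - mean(x))^2)))
    }
    data.frame(volume = g$volume[1], n_cells = g$n_cells[1],
               method = g$method[1], n_ok = sum(ok),
               excluded = frac_ok < 0.5,
               median_error2 = if (sum(ok)) stats::median(e) else NA_real_,
               q10 = if (sum(ok)) stats::quantile(e, 0.1, names = FALSE)
                     else NA_real_,
               q90 = if (sum(ok)) stats::quantile(e, 0.9, names = FALSE)
                     else NA_real_,
               mean_error2 = if (sum(ok)) mean(e) else NA_real_,
               bias2 = bias2, variance = variance,
               median_w_AIC = stats::median(g$w_AIC[ok], na.rm = TRUE),
               rejection_rate = mean(g$rejected[ok], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, out$n_cells, out$volume), ]
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result: ", length(x$volumes), " volumes x ",
      length(x$sample_sizes), " sample sizes x ", x$replicates,
      " replicates; methods ", paste(x$methods, collapse = ", "), "\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Log-log convergence slope of the median squared estimation error
#'
#' Ordinary least squares of `log(median error2)` on `log(volume)`.
#'
#' @param sweep a [estimation_error_sweep()] result (or its `$summary`).
#' @param method method tag.
#' @param volumes optional volume subset (default all).
#' @param n_cells optional sample-size selector (default the largest).
#' @return list with `slope`, `intercept`, `n_points`.
#' @export
convergence_slope <- function(sweep, method, volumes = NULL, n_cells = NULL) {
  s <- if (inherits(sweep, "sweep_result")) sweep$summary else sweep
  method <- normalize_method(method)
  s <- s[s$method == method & !is.na(s$median_error2), ]
  n_cells <- n_cells %||% max(s$n_cells)
  s <- s[s$n_cells == n_cells, ]
  if (!is.null(volumes)) s <- s[s$volume %in% volumes, ]
  if (nrow(s) < 3) {
    stop("convergence slope undefined: fewer than 3 volumes", call. = FALSE)
  }
  fit <- stats::lm(log(median_error2) ~ log(volume), data = s)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n_points = nrow(s))
}

#' Write sweep results to CSV
#'
#' @param sweep a sweep result.
#' @param path base path; `<path>_results.csv` and `<path>_summary.csv` are
#'   written.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep$results, paste0(path, "_results.csv"),
                   row.names = FALSE)
  utils::write.csv(sweep$summary, paste0(path, "_summary.csv"),
                   row.names = FALSE)
  invisible(path)
}
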