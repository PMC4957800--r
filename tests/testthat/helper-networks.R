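# Small fixture networks shared across tests.

# reversible dimerization 2A <-> B (closed system)
dimerization_net <- function(volume = 1, kf = 1, kb = 0.5) {
  reaction_network(
    species = c("A", "B"),
    reactions = list(
      reaction(c(A = 2), c(B = 1), rate = "kf"),
      reaction(c(B = 1), c(A = 2), rate = "kb")
    ),
    parameters = c(kf = kf, kb = kb), volume = volume
  )
}

# open dimerization with birth and death (4 parameters, bimolecular)
open_dimer_net <- function(volume = 5) {
  reaction_network(
    species = c("A", "B"),
    reactions = list(
      reaction(c(A = 2), c(B = 1), rate = "kf"),
      reaction(c(B = 1), c(A = 2), rate = "kb"),
      reaction(NULL, c(A = 1), rate = "kin"),
      reaction(c(A = 1), NULL, rate = "kd")
    ),
    parameters = c(kf = 1, kb = 0.5, kin = 2, kd = 0.4), volume = volume
  )
}

# purely unimolecular open chain: 0 -> A -> B -> 0
linear_chain_net <- function(volume = 2, kin = 4, kc = 1, kd = 0.7) {
  reaction_network(
    species = c("A", "B"),
    reactions = list(
      reaction(NULL, c(A = 1), rate = "kin"),
      reaction(c(A = 1), c(B = 1), rate = "kc"),
      reaction(c(B = 1), NULL, rate = "kd")
    ),
    parameters = c(kin = kin, kc = kc, kd = kd), volume = volume
  )
}

# snapshot summary built directly from model trajectories (pseudo-data with
# chosen estimator variances); var column chosen so sigma2_mean = var / N
model_summary <- function(net, method, theta = NULL, timepoints, mu0,
                          n_cells = 1000, mean_override = NULL,
                          var_override = NULL) {
  sys <- generate_system(net, method)
  tr <- simulate_moments(sys, theta, t_grid = unique(c(0, timepoints)),
                         mu0 = mu0)
  obs <- map_observables(tr, net, theta)
  obs <- obs[obs$time %in% timepoints, ]
  v <- if (is.null(var_override)) pmax(obs$var, 1e-8) else var_override
  if (all(is.na(v))) v <- rep(1e-8, nrow(obs))
  out <- data.frame(time = obs$time, observable = obs$observable,
                    mean = if (is.null(mean_override)) obs$mean else
                      mean_override,
                    var = v, m4 = 3 * v^2, n_cells = n_cells, replicate = 1,
                    stringsAsFactors = FALSE)
  class(out) <- c("snapshot_summary", "data.frame")
  out
}
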