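test_that("the negative log-likelihood has the printed closed form", {
  net <- birth_death_network(volume = 2, k = 10, gamma = 2)
  tg <- 1
  tr <- simulate_moments(generate_system(net, "RRE"), t_grid = c(0, 1),
                         mu0 = 0)
  mu_model <- unname(tr$mean[2, 1])

  # one datapoint, mu = mu_hat, sigma^2 = 1/(2 pi): both terms vanish
  s <- data.frame(time = 1, observable = "A", mean = mu_model,
                  var = 500 / (2 * pi), m4 = 1, n_cells = 500, replicate = 1)
  class(s) <- c("snapshot_summary", "data.frame")
  spec <- objective_spec(net, "RRE", s, estimate = c("k", "gamma"),
                         lower = c(1, 0.2), upper = c(100, 20), mu0 = c(A = 0))
  expect_equal(negative_log_likelihood(spec, c(k = 10, gamma = 2)), 0,
               tolerance = 1e-6)

  # one datapoint, residual 1 at sigma^2 = 1: J = (log 2 pi + 1)/2
  s2 <- s
  s2$mean <- mu_model - 1
  s2$var <- 500  # sigma2_mean = var/N = 1
  spec2 <- objective_spec(net, "RRE", s2, estimate = c("k", "gamma"),
                          lower = c(1, 0.2), upper = c(100, 20), mu0 = c(A = 0))
  expect_equal(negative_log_likelihood(spec2, c(k = 10, gamma = 2)),
               0.5 * (log(2 * pi) + 1), tolerance = 1e-6)

  # doubling sigma at fixed residual: quadratic term /4, log term + log 4
  s3 <- s2
  s3$var <- 2000
  spec3 <- objective_spec(net, "RRE", s3, estimate = c("k", "gamma"),
                          lower = c(1, 0.2), upper = c(100, 20), mu0 = c(A = 0))
  J2 <- negative_log_likelihood(spec2, c(k = 10, gamma = 2))
  J3 <- negative_log_likelihood(spec3, c(k = 10, gamma = 2))
  expect_equal(J3 - J2, 0.5 * log(4) - 0.5 * (1 - 1 / 4), tolerance = 1e-6)
})

test_that("gradient vanishes at a perfect interior fit and matches FD elsewhere", {
  net <- open_dimer_net(volume = 5)
  summ <- model_summary(net, "2MA", timepoints = c(0.5, 1, 2),
                        mu0 = c(2, 0), n_cells = 1000)
  spec <- objective_spec(net, "2MA", summ,
                         estimate = c("kf", "kb", "kin", "kd"),
                         lower = net$parameters[1:4] / 10,
                         upper = net$parameters[1:4] * 10,
                         mu0 = c(A = 2, B = 0), data_mode = "mean")
  g0 <- objective_gradient(spec, net$parameters[1:4])
  expect_lt(max(abs(g0)), 1e-4)
  gc <- gradient_check(spec, net$parameters[1:4] * c(1.4, 0.7, 1.2, 0.9))
  expect_true(gc$pass)
})

test_that("technical-noise parameter gradient equals 1/2 per datapoint at zero residual", {
  # sigma^2 estimated on the log scale: dJ/dxi = (1/2) (1/sigma^2) sigma^2
  net <- birth_death_network(volume = 2)
  summ <- model_summary(net, "RRE", timepoints = c(0.5, 1), mu0 = 0,
                        n_cells = 1e6)
  summ$var <- 1e-12  # statistical part negligible against technical noise
  net$parameters <- c(net$parameters, s2_T = 0.5)
  spec <- objective_spec(net, "RRE", summ, estimate = c("s2_T"),
                         lower = c(s2_T = 1e-4), upper = c(s2_T = 10),
                         mu0 = c(A = 0),
                         noise = noise_model(c(A = "s2_T")))
  g <- objective_gradient(spec, c(s2_T = 0.5))
  expect_equal(unname(g), 0.5 * nrow(summ), tolerance = 1e-4)
})

test_that("the FIM is PSD, flags non-identifiability, and approximates the Hessian", {
  net <- open_dimer_net(volume = 5)
  # noise-free pseudo data generated by the model itself: residuals vanish,
  # so the Gauss-Newton FIM equals the exact Hessian of J at the optimum
  summ <- model_summary(net, "RRE", timepoints = c(0.5, 1, 2),
                        mu0 = c(2, 0), n_cells = 1000)
  est <- c("kf", "kb", "kin", "kd")
  spec <- objective_spec(net, "RRE", summ, estimate = est,
                         lower = net$parameters[est] / 10,
                         upper = net$parameters[est] * 10,
                         mu0 = c(A = 2, B = 0), data_mode = "mean")
  th <- net$parameters[est]
  fim <- fisher_information(spec, th)
  ev <- eigen(fim, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  xi <- log(th)
  H <- matrix(0, 4, 4)
  h <- 1e-4
  for (j in 1:4) {
    xp <- xi; xp[j] <- xi[j] + h
    xm <- xi; xm[j] <- xi[j] - h
    gp <- objective_gradient(spec, setNames(exp(xp), est))
    gm <- objective_gradient(spec, setNames(exp(xm), est))
    H[j, ] <- (gp - gm) / (2 * h)
  }
  expect_equal(unname(fim), (H + t(H)) / 2, tolerance = 5e-3)

  # a parameter with zero sensitivity gives a zero row/column
  net2 <- birth_death_network(volume = 2)
  net2$parameters <- c(net2$parameters, dead = 1)
  summ2 <- model_summary(net2, "RRE", timepoints = 1, mu0 = 0,
                         n_cells = 100)
  spec2 <- objective_spec(net2, "RRE", summ2, estimate = c("k", "dead"),
                          lower = c(1, 0.1), upper = c(100, 10),
                          mu0 = c(A = 0))
  f2 <- fisher_information(spec2, c(k = 10, dead = 1))
  expect_equal(unname(f2["dead", ]), c(0, 0))
})

test_that("multi-start fitting recovers parameters and reports convergence", {
  net <- birth_death_network(volume = 4)
  summ <- model_summary(net, "LNA", timepoints = c(0.25, 0.5, 1, 2),
                        mu0 = 0, n_cells = 2000)
  spec <- objective_spec(net, "LNA", summ, estimate = c("k", "gamma"),
                         lower = c(k = 0.5, gamma = 0.1),
                         upper = c(k = 200, gamma = 40), mu0 = c(A = 0),
                         data_mode = "mean+variance")
  f <- fit(spec, n_starts = 10, seed = 1)
  expect_true(f$converged)
  expect_equal(unname(f$theta_hat), c(10, 2), tolerance = 1e-3)
  expect_equal(nrow(f$starts), 10L)
  # reproducibility: identical seed, identical estimate
  f2 <- fit(spec, n_starts = 10, seed = 1)
  expect_identical(f$theta_hat, f2$theta_hat)
  expect_identical(f$start_points, f2$start_points)

  # too few agreeing starts: explicit doubling recommendation
  f3 <- fit(spec, n_starts = 2, seed = 1, min_agree = 5)
  expect_match(f3$recommendation, "double")

  # result JSON export
  path <- tempfile(fileext = ".json")
  write_result_json(f, path)
  out <- jsonlite::read_json(path)
  expect_equal(out$method, "LNA")
  expect_equal(out$theta_hat$k, unname(f$theta_hat["k"]), tolerance = 1e-10)
})

test_that("integrator failures yield an infinite objective, not an error", {
  net <- trimerization_network(0.5)
  summ <- model_summary(net, "RRE", timepoints = c(1, 2), mu0 = c(0, 0, 0),
                        n_cells = 100)
  spec <- objective_spec(net, "IOS", summ, estimate = names(net$parameters),
                         lower = net$parameters / 10,
                         upper = net$parameters * 10,
                         mu0 = c(A = 0, B = 0, C = 0),
                         data_mode = "mean")
  J <- suppressWarnings(negative_log_likelihood(spec, net$parameters))
  expect_true(!is.finite(J) || J > 0)
})
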