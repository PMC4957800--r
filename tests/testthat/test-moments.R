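test_that("generated systems have the prescribed block structure", {
  tri <- trimerization_network()
  expect_equal(generate_system(tri, "RRE")$dim, 3L)
  expect_equal(generate_system(tri, "LNA")$dim, 3L + 6L)
  expect_equal(generate_system(tri, "EMRE")$dim, 3L + 3L + 6L)
  expect_equal(generate_system(tri, "IOS")$dim, 12L)
  expect_equal(generate_system(tri, "2MA")$dim, 3L + 6L)
  expect_equal(generate_system(tri, "3MA")$dim, 3L + 6L + 10L)
  expect_error(generate_system(tri, "4MA"), "unknown method")
  expect_equal(names(generate_system(tri, "EMRE")$blocks),
               c("Phi", "mu", "Sigma"))
})

test_that("the 8-species signaling skeleton reproduces the printed state counts", {
  net <- jakstat_skeleton()
  expect_equal(net$M, 8L)
  expect_equal(generate_system(net, "RRE")$dim, 8L)
  expect_equal(generate_system(net, "2MA")$dim, 44L)
  expect_equal(generate_system(net, "EMRE")$dim, 52L)
})

test_that("initial state packing and validation", {
  net <- dimerization_net()
  expect_equal(initial_state(net, c(5, 0), method = "RRE"), c(5, 0))
  y <- initial_state(net, c(1, 2), diag(2), method = "2MA")
  expect_equal(y, c(1, 2, 1, 0, 1))
  expect_error(initial_state(net, c(1, 2), matrix(c(1, 2, 2, 1), 2),
                             method = "2MA"),
               "positive semidefinite")
  expect_error(initial_state(net, c(1, 2), matrix(c(1, 0.5, 0, 1), 2),
                             method = "2MA"), "symmetric")
})

test_that("birth-death closed forms: RRE relaxation and LNA Poisson variance", {
  net <- birth_death_network(volume = 4, k = 10, gamma = 2)
  tr <- simulate_moments(generate_system(net, "RRE"), t_grid = c(0, 1),
                         mu0 = 0)
  expect_equal(unname(tr$mean[2, 1]), 5 * (1 - exp(-2)), tolerance = 1e-7)
  tl <- simulate_moments(generate_system(net, "LNA"), t_grid = c(0, 10),
                         mu0 = 0)
  expect_equal(unname(tl$var[2, 1]), 1.25, tolerance = 1e-5)
})

test_that("all methods are exact on purely unimolecular networks", {
  net <- linear_chain_net()
  orc <- cme_oracle(net, c(4, 0), c(1, 2), c(30, 30))
  for (m in c("RRE", "LNA", "EMRE", "IOS", "2MA", "3MA")) {
    tr <- simulate_moments(generate_system(net, m), t_grid = c(0, 1, 2),
                           mu0 = c(2, 0), rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(tr$mean[2:3, ] - orc$mu) / pmax(abs(orc$mu), 1e-8)),
              1e-6)
    if (!is.null(tr$var)) {
      vex <- rbind(diag(orc$Sig[[1]]), diag(orc$Sig[[2]]))
      expect_lt(max(abs(tr$var[2:3, ] - vex) / pmax(vex, 1e-8)), 1e-6)
    }
  }
})

test_that("closures rank as expected against the CME on dimerization", {
  net <- dimerization_net(volume = 4)
  tg <- seq(0.25, 2, 0.25)
  orc <- cme_oracle(net, c(16, 0), tg, c(16, 8))
  errs <- sapply(c("RRE", "EMRE", "2MA", "3MA"), function(m) {
    tr <- simulate_moments(generate_system(net, m), t_grid = c(0, tg),
                           mu0 = c(4, 0))
    max(abs(tr$mean[-1, 1] - orc$mu[, 1]))
  })
  # the closed-moment mean beats the macroscopic mean; third order beats second
  expect_lt(errs["2MA"], errs["RRE"])
  expect_lt(errs["EMRE"], errs["RRE"])
  expect_lt(errs["3MA"], errs["2MA"])
})

test_that("2MA reduces to RRE for linear propensities and EMRE correction is O(1/Omega)", {
  # purely unimolecular: 2MA mean RHS equals RRE RHS at mu = phi
  lin <- linear_chain_net()
  sysr <- generate_system(lin, "RRE")
  sys2 <- generate_system(lin, "2MA")
  ctxr <- momentinfer:::rhs_context(sysr)
  ctx2 <- momentinfer:::rhs_context(sys2)
  phi <- c(1.3, 0.4)
  d1 <- momentinfer:::moment_rhs(sysr, 0, phi, ctxr)
  d2 <- momentinfer:::moment_rhs(sys2, 0, c(phi, 0.2, 0.1, 0.3), ctx2)
  expect_equal(unname(d2[1:2]), unname(d1), tolerance = 1e-12)

  gaps <- emre_gap <- c()
  for (Om in c(10, 1e2, 1e3, 1e4)) {
    net <- dimerization_net(volume = Om)
    se <- generate_system(net, "EMRE")
    tr <- simulate_moments(se, t_grid = c(0, 1), mu0 = c(4, 0))
    phi1 <- tr$states[2, se$idx$Phi[1]]
    mu1 <- tr$states[2, se$idx$mu[1]]
    t2 <- simulate_moments(generate_system(net, "2MA"), t_grid = c(0, 1),
                           mu0 = c(4, 0))
    gaps <- c(gaps, abs(t2$mean[2, 1] - mu1))
    emre_gap <- c(emre_gap, Om * (mu1 - phi1))
  }
  # |2MA - EMRE| decreases monotonically with volume
  expect_true(all(diff(gaps) < 0))
  # Omega * (mu_EMRE - phi) approaches a finite limit
  expect_lt(abs(emre_gap[4] - emre_gap[3]), 1e-3 * abs(emre_gap[4]))
})

test_that("LNA covariance stays PSD; IOS flags negative variances", {
  net <- open_dimer_net(volume = 2)
  sys <- generate_system(net, "LNA")
  tr <- simulate_moments(sys, t_grid = seq(0, 5, 0.5), mu0 = c(2, 1),
                         Sigma0 = diag(c(0.5, 0.2)))
  for (q in seq_along(tr$times)) {
    ev <- eigen(momentinfer:::trajectory_cov(tr, q), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }

  # small-volume IOS: variance goes negative, flagged but not an error
  net2 <- reaction_network(
    species = c("A", "B"),
    reactions = list(
      reaction(NULL, c(A = 1), rate = "k"),
      reaction(c(A = 2), c(B = 1), rate = "kd")
    ),
    parameters = c(k = 2, kd = 1), volume = 1
  )
  tr2 <- simulate_moments(generate_system(net2, "IOS"),
                          t_grid = seq(0, 1, 0.1), mu0 = c(0.2, 0))
  expect_true(tr2$negative_variance)
  expect_true(min(tr2$var) < 0)
})

test_that("observable mapping applies weights, scale and offset", {
  net <- reaction_network(
    species = c("A", "B"),
    reactions = list(reaction(c(A = 1), c(B = 1), rate = "k")),
    parameters = c(k = 1, sc = 2, off = 3), volume = 1,
    observables = list(
      observable("ident", "A"),
      observable("scaled", "A", scale = "sc", offset = "off"),
      observable("sum", c(A = 1, B = 1))
    )
  )
  sys <- generate_system(net, "LNA")
  tr <- simulate_moments(sys, t_grid = c(0, 0.5), mu0 = c(2, 0),
                         Sigma0 = diag(2))
  obs <- map_observables(tr)
  i1 <- obs$observable == "ident" & obs$time == 0
  i2 <- obs$observable == "scaled" & obs$time == 0
  i3 <- obs$observable == "sum" & obs$time == 0
  expect_equal(obs$mean[i2], 2 * obs$mean[i1] + 3)
  expect_equal(obs$var[i2], 4 * obs$var[i1])   # scale 2 -> variance x4
  expect_equal(obs$var[i3], 2)                 # w'Sigma w with Sigma = I
})

test_that("integrator failure carries method context", {
  net <- trimerization_network(0.5)
  expect_error(
    suppressWarnings(simulate_moments(generate_system(net, "IOS"),
                                      t_grid = seq(0, 10, 1),
                                      mu0 = c(0, 0, 0))),
    "integrator failure \\[method=IOS")
})

test_that("equation listings render", {
  lines <- describe_system(generate_system(trimerization_network(), "2MA"))
  expect_true(any(grepl("2MA system", lines)))
  expect_true(any(grepl("k_dim \\* A \\* \\(A - 1/Omega_r\\)", lines)))
  path <- tempfile(fileext = ".txt")
  describe_system(generate_system(birth_death_network(), "RRE"), path)
  expect_true(file.exists(path))

  jpath <- tempfile(fileext = ".json")
  write_system_json(generate_system(trimerization_network(), "EMRE"), jpath)
  meta <- jsonlite::read_json(jpath)
  expect_equal(meta$method, "EMRE")
  expect_equal(meta$dimension, 12L)
  expect_equal(length(meta$reactions), 6L)
})
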