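test_that("network construction validates and counts structure", {
  net <- birth_death_network()
  expect_s3_class(net, "reaction_network")
  expect_equal(net$M, 1L)
  expect_equal(net$R, 2L)

  tri <- trimerization_network()
  expect_equal(tri$R, 6L)
  # 6 kinetic parameters plus the reaction volume = 7
  expect_equal(length(tri$parameters) + 1L, 7L)
  expect_equal(sum(tri$compiled$order == 2L), 2L)

  enz <- enzymatic_degradation_network()
  expect_equal(enz$R, 6L)
  # 6 kinetic + E0 + volume = 8
  expect_equal(length(enz$parameters) + 1L, 8L)
  expect_equal(sum(enz$compiled$order == 2L), 1L)

  expect_error(
    reaction_network("A",
                     list(reaction(c(A = 3), NULL, rate = "k")),
                     c(k = 1), 1),
    "molecularity")
  expect_error(
    reaction_network("A",
                     list(reaction(c(Z = 1), NULL, rate = "k")),
                     c(k = 1), 1),
    "unknown species")
  expect_error(
    reaction_network("A", list(reaction(c(A = 1), NULL, rate = "k")),
                     c(k = 1), volume = -2),
    "positive")
  expect_error(
    reaction_network("A", list(reaction(c(A = 1), NULL, rate = "k")),
                     c(k = -1), 1),
    "positive")
})

test_that("microscopic propensities follow mass-action combinatorics", {
  net <- reaction_network(
    species = c("A", "B", "C"),
    reactions = list(
      reaction(c(A = 1), c(B = 1), rate = "k1"),
      reaction(c(A = 1, B = 1), c(C = 1), rate = "k2"),
      reaction(c(A = 2), c(B = 1), rate = "k3")
    ),
    parameters = c(k1 = 2, k2 = 0.5, k3 = 1), volume = 2
  )
  a <- microscopic_propensity(net, c(4, 10, 0))
  expect_equal(a[1], 2 * 4)            # k n_A
  expect_equal(a[2], 0.5 * 4 * 10 / 2) # k n_A n_B / Omega = 10
  expect_equal(a[3], 1 * 4 * 3 / 2)    # k n_A (n_A - 1) / Omega = 6
  # insufficient reactants: all propensities vanish, counts cannot go negative
  expect_equal(microscopic_propensity(net, c(1, 0, 0))[2:3], c(0, 0))
  expect_equal(microscopic_propensity(net, c(0, 5, 1)), c(0, 0, 0))
  expect_error(microscopic_propensity(net, c(-1, 0, 0)), "negative")
})

test_that("macroscopic rates are the large-volume limit of the propensities", {
  net <- reaction_network(
    species = "A",
    reactions = list(reaction(c(A = 2), NULL, rate = "k")),
    parameters = c(k = 1), volume = 1
  )
  expect_equal(macroscopic_rate(net, 3), 9)   # k phi^2
  expect_error(macroscopic_rate(net, -1), "negative")
  # |f_hat(Omega phi) - f(phi)| -> 0 as Omega grows at fixed phi
  phi <- 3
  for (Om in c(1e2, 1e4, 1e6)) {
    net2 <- reaction_network(
      species = "A", list(reaction(c(A = 2), NULL, rate = "k")),
      c(k = 1), volume = Om)
    fhat <- microscopic_propensity(net2, round(Om * phi)) / Om
    expect_lt(abs(fhat - 9), 10 * 9 / Om + 1e-9)
  }
  # zeroth and first order: f_hat and f agree exactly at n = Omega phi
  bd <- birth_death_network(volume = 50)
  n <- c(200)
  expect_equal(unname(microscopic_propensity(bd, n) / 50),
               unname(macroscopic_rate(bd, n / 50)))
})

test_that("time-dependent inputs multiply the rates identically in f-hat and f", {
  u <- function(t) sin(t)^2 + 1
  net <- reaction_network(
    species = "A",
    reactions = list(reaction(NULL, c(A = 1), rate = "k", input = "u")),
    parameters = c(k = 2), volume = 3, inputs = list(u = u)
  )
  expect_equal(macroscopic_rate(net, 0, t = 0), 2)  # k * u(0), u(0) = 1
  expect_equal(macroscopic_rate(net, 0, t = 1), 2 * (sin(1)^2 + 1))
  expect_equal(microscopic_propensity(net, 0, t = 1), 3 * 2 * (sin(1)^2 + 1))
})

test_that("stoichiometry matrices are exact", {
  bd <- birth_death_network()
  expect_equal(unname(stoichiometry_matrices(bd)$nu), matrix(c(1, -1), 1, 2))
  d <- dimerization_net()
  expect_equal(unname(stoichiometry_matrices(d)$nu[, 1]), c(-2, 1))
  enz <- enzymatic_degradation_network()
  expect_equal(ncol(stoichiometry_matrices(enz)$nu), 6L)
  expect_equal(stoichiometry_matrices(enz)$nu,
               stoichiometry_matrices(enz)$nu_plus -
                 stoichiometry_matrices(enz)$nu_minus)
})

test_that("transport reactions conserve molecules across compartments", {
  net <- reaction_network(
    species = c(X = "cyt", Y = "nuc"),
    compartments = c(cyt = 1, nuc = 0.25),
    reactions = list(
      reaction(c(X = 1), c(Y = 1), rate = "kin"),
      reaction(c(Y = 1), c(X = 1), rate = "kout")
    ),
    parameters = c(kin = 1, kout = 0.5), volume = 4
  )
  # molecule-count stoichiometry stays integer: counts are conserved exactly
  expect_equal(colSums(stoichiometry_matrices(net)$nu), c(0, 0))
  # concentration-space jumps carry the volume rescaling
  A <- net$compiled$A
  expect_equal(unname(A[, 1]), c(-1, 4), tolerance = 1e-12)
  tr <- simulate_trajectory(net, n0 = c(20, 0), t_end = 5, seed = 1)
  expect_true(all(rowSums(tr$states) == 20))
})

test_that("YAML model documents round-trip", {
  tri <- trimerization_network()
  path <- tempfile(fileext = ".yaml")
  write_network_yaml(tri, path)
  tri2 <- read_network_yaml(path)
  expect_equal(tri2$species, tri$species)
  expect_equal(tri2$parameters, tri$parameters)
  expect_equal(stoichiometry_matrices(tri2), stoichiometry_matrices(tri))
  expect_equal(macroscopic_rate(tri2, c(1, 2, 3)),
               macroscopic_rate(tri, c(1, 2, 3)))
})

test_that("SBML import accepts mass action and rejects other kinetics", {
  skip_if_not_installed("xml2")
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
 <model id="m">
  <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>
  <listOfSpecies>
   <species id="A" compartment="cell"/><species id="B" compartment="cell"/>
  </listOfSpecies>
  <listOfParameters><parameter id="k1" value="2"/></listOfParameters>
  <listOfReactions>
   <reaction id="r1">
    <listOfReactants><speciesReference species="A" stoichiometry="2"/></listOfReactants>
    <listOfProducts><speciesReference species="B"/></listOfProducts>
    <kineticLaw>
     <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><ci>k1</ci><ci>A</ci><ci>A</ci></apply>
     </math>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  path <- tempfile(fileext = ".xml")
  writeLines(sbml, path)
  net <- read_network_sbml(path)
  expect_equal(net$M, 2L)
  expect_equal(net$R, 1L)
  expect_equal(unname(stoichiometry_matrices(net)$nu[, 1]), c(-2, 1))
  expect_equal(macroscopic_rate(net, c(3, 0)), 2 * 9)

  hill <- sub("<apply><times/><ci>k1</ci><ci>A</ci><ci>A</ci></apply>",
              "<apply><divide/><ci>k1</ci><ci>A</ci></apply>", sbml,
              fixed = TRUE)
  writeLines(hill, path)
  expect_error(read_network_sbml(path), "mass")
})

test_that("bimolecular reactants must share a compartment", {
  expect_error(
    reaction_network(
      species = c(X = "cyt", Y = "nuc"),
      compartments = c(cyt = 1, nuc = 0.5),
      reactions = list(reaction(c(X = 1, Y = 1), NULL, rate = "k")),
      parameters = c(k = 1), volume = 1),
    "share a compartment")
})
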