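# Model input: YAML network documents and restricted SBML import.

#' Read a reaction network from a YAML document
#'
#' Expected keys: `species` (vector, or map species -> compartment),
#' `compartments` (map name -> volume fraction, optional), `volume`,
#' `parameters` (map), `reactions` (list with `reactants`, `products`,
#' `rate`, optional `input` and `compartment`), `observables` (list with
#' `name`, `species` (name or weight map), optional `scale`, `offset`).
#'
#' @param path YAML file path.
#' @param inputs named list of input functions referenced by the document.
#' @return a [reaction_network()].
#' @export
read_network_yaml <- function(path, inputs = NULL) {
  doc <- yaml::read_yaml(path)
  for (key in c("species", "volume", "parameters", "reactions")) {
    if (is.null(doc[[key]])) stop("YAML model lacks key '", key, "'",
                                  call. = FALSE)
  }
  species <- if (is.list(doc$species) && !is.null(names(doc$species))) {
    stats::setNames(unlist(doc$species), names(doc$species))
  } else {
    unlist(doc$species)
  }
  reactions <- lapply(doc$reactions, function(rx) {
    reaction(reactants = unlist(rx$reactants), products = unlist(rx$products),
             rate = rx$rate, input = rx$input, compartment = rx$compartment)
  })
  observables <- NULL
  if (!is.null(doc$observables)) {
    observables <- lapply(doc$observables, function(ob) {
      w <- if (is.character(ob$species)) ob$species else unlist(ob$species)
      observable(ob$name, w, scale = ob$scale %||% 1,
                 offset = ob$offset %||% 0)
    })
  }
  reaction_network(
    species = species,
    reactions = reactions,
    parameters = unlist(doc$parameters),
    volume = doc$volume,
    compartments = if (!is.null(doc$compartments)) unlist(doc$compartments),
    inputs = inputs,
    observables = observables
  )
}

#' Write a reaction network to YAML
#'
#' @param net a [reaction_network()].
#' @param path output path.
#' @export
write_network_yaml <- function(net, path) {
  doc <- list(
    species = as.list(stats::setNames(net$species_compartment, net$species)),
    compartments = as.list(net$compartments),
    volume = net$volume,
    parameters = as.list(net$parameters),
    reactions = lapply(net$reactions, function(rx) {
      out <- list(reactants = as.list(rx$reactants),
                  products = as.list(rx$products), rate = rx$rate)
      if (!is.null(rx$input)) out$input <- rx$input
      if (!is.null(rx$compartment)) out$compartment <- rx$compartment
      out
    }),
    observables = lapply(net$observables, function(ob) {
      list(name = ob$name, species = as.list(ob$weights),
           scale = ob$scale, offset = ob$offset)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Import a mass-action SBML model (restricted)
#'
#' Minimal SBML level-2/3 reader: species, compartments, global parameters
#' and reactions whose kinetic laws are pure mass-action products
#' (`k * reactant1 [* reactant2]`, with the compartment factor optional).
#' Anything else (Hill, Michaelis-Menten, assignments, events, local
#' parameters) is rejected with a clear error.
#'
#' @param path SBML file path.
#' @param volume reference volume assigned to the model (SBML compartment
#'   sizes are used as volume fractions relative to the first compartment).
#' @return a [reaction_network()].
#' @export
read_network_sbml <- function(path, volume = NULL) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("SBML import requires the xml2 package", call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  comp <- stats::setNames(
    as.numeric(xml2::xml_attr(comp_nodes, "size")),
    xml2::xml_attr(comp_nodes, "id"))
  if (!length(comp)) comp <- c(cell = 1)
  comp[is.na(comp)] <- 1
  ref <- comp[1]
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_comp[is.na(sp_comp)] <- names(comp)[1]
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))
  for (bad in c(".//listOfRules/*", ".//listOfEvents/*",
                ".//listOfFunctionDefinitions/*")) {
    if (length(xml2::xml_find_all(doc, bad))) {
      stop("unsupported SBML construct: ", bad,
           "; only plain mass-action models are supported", call. = FALSE)
    }
  }
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(nd) {
    get_side <- function(tag) {
      refs <- xml2::xml_find_all(nd, paste0("./", tag, "/speciesReference"))
      if (!length(refs)) return(NULL)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(st, xml2::xml_attr(refs, "species"))
    }
    reactants <- get_side("listOfReactants")
    products <- get_side("listOfProducts")
    if (length(xml2::xml_find_all(nd, ".//kineticLaw//listOfLocalParameters/*")) ||
        length(xml2::xml_find_all(nd, ".//kineticLaw//listOfParameters/*"))) {
      stop("local kinetic-law parameters are not supported", call. = FALSE)
    }
    ops <- xml2::xml_name(xml2::xml_find_all(nd, ".//kineticLaw//apply/*[1]"))
    if (length(setdiff(ops, c("times", "ci", "cn")))) {
      stop("non-mass-action kinetic law in reaction '",
           xml2::xml_attr(nd, "id"), "' (operator ",
           paste(setdiff(ops, "times"), collapse = ", "),
           "); only mass-action models can be imported", call. = FALSE)
    }
    ci <- xml2::xml_text(xml2::xml_find_all(nd, ".//kineticLaw//ci"))
    ci <- trimws(ci)
    rate <- ci[ci %in% names(pars)]
    if (length(rate) != 1L) {
      stop("kinetic law of reaction '", xml2::xml_attr(nd, "id"),
           "' must reference exactly one rate parameter", call. = FALSE)
    }
    used_species <- ci[ci %in% sp_id]
    expected <- rep(names(reactants %||% character(0)),
                    times = reactants %||% integer(0))
    if (!setequal(used_species, unique(expected))) {
      stop("kinetic law of reaction '", xml2::xml_attr(nd, "id"),
           "' is not mass action in its reactants", call. = FALSE)
    }
    reaction(reactants = reactants, products = products, rate = rate)
  })
  reaction_network(
    species = stats::setNames(sp_comp, sp_id),
    reactions = reactions,
    parameters = pars,
    volume = volume %||% unname(ref),
    compartments = comp / ref
  )
}
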