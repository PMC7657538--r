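mini_sbml <- system.file("extdata", "mini_model.xml", package = "phylomint")

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("edge lists parse with set semantics and comment handling", {
  net <- read_edge_list(write_lines_tmp(c("A B", "B C")))
  expect_equal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 2L)

  empty <- read_edge_list(write_lines_tmp(character(0)))
  expect_length(empty$nodes, 0L)
  expect_equal(nrow(empty$edges), 0L)

  dup <- read_edge_list(write_lines_tmp(c("# comment", "A B", "", "A B")))
  expect_equal(dup$nodes, c("A", "B"))
  expect_equal(nrow(dup$edges), 1L)
})

test_that("malformed edge-list lines are reported with their line number", {
  path <- write_lines_tmp(c("A B", "oops"))
  expect_error(read_edge_list(path), "line 2")
})

test_that("SBML reader flags boundary reactions and catches degenerate input", {
  rxns <- read_sbml(mini_sbml)
  expect_s3_class(rxns, "reaction_set")
  expect_length(rxns$reactions, 5L)
  boundary <- vapply(rxns$reactions, `[[`, logical(1), "is_boundary")
  expect_equal(sum(!boundary), 4L)
  expect_equal(rxns$reactions[[which(boundary)]]$id, "R_EX_glc__D_e")

  no_rxn <- write_lines_tmp(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="empty"><listOfSpecies/><listOfReactions/></model></sbml>'))
  expect_error(read_sbml(no_rxn), "empty model",
               class = "phylomint_empty_model")
  expect_error(read_sbml(write_lines_tmp("not xml at all <")),
               "cannot parse")
})

test_that("single irreversible reaction survives the SBML round trip", {
  net <- metabolic_network("one", c("S", "P"),
                           data.frame(from = "S", to = "P"))
  path <- withr::local_tempfile(fileext = ".xml")
  phylomint:::write_sbml_from_network(net, path)
  rxns <- read_sbml(path)
  expect_length(rxns$reactions, 1L)
  expect_false(rxns$reactions[[1]]$reversible)
  expect_identical(project_to_metabolite_graph(rxns)$edges, net$edges)
})

test_that("projection expands substrate x product pairs, doubled if reversible", {
  irrev <- structure(list(model_id = "m", reactions = list(
    list(id = "r1", substrates = c("S1", "S2"), products = "P1",
         reversible = FALSE, is_boundary = FALSE))), class = "reaction_set")
  net <- project_to_metabolite_graph(irrev, graph_options(strip_compartments = FALSE))
  expect_equal(net$edges,
               data.frame(from = c("S1", "S2"), to = c("P1", "P1")))

  rev <- structure(list(model_id = "m", reactions = list(
    list(id = "r1", substrates = "S", products = "P",
         reversible = TRUE, is_boundary = FALSE))), class = "reaction_set")
  net2 <- project_to_metabolite_graph(rev, graph_options(strip_compartments = FALSE))
  expect_setequal(paste(net2$edges$from, net2$edges$to), c("S P", "P S"))
})

test_that("compartment stripping merges per-compartment metabolite copies", {
  rxns <- structure(list(model_id = "m", reactions = list(
    list(id = "t", substrates = "glc__D_e", products = "glc__D_c",
         reversible = FALSE, is_boundary = FALSE))), class = "reaction_set")
  net <- project_to_metabolite_graph(rxns, graph_options())
  # both copies collapse to one node; the transport edge becomes a self-loop
  # and is dropped
  expect_equal(net$nodes, "glc__D")
  expect_equal(nrow(net$edges), 0L)

  kept <- project_to_metabolite_graph(rxns, graph_options(strip_compartments = FALSE))
  expect_setequal(kept$nodes, c("glc__D_e", "glc__D_c"))
})

test_that("default mini-model projection drops the exchange artifact", {
  net <- project_to_metabolite_graph(read_sbml(mini_sbml))
  expect_false("glc__D_e" %in% net$nodes) # merged into glc__D
  expect_true(all(c("glc__D", "g6p", "f6p", "pyr", "atp", "adp") %in% net$nodes))
  s <- network_stats(net)
  expect_equal(unname(s["n_sources"]), 2L) # glc__D and atp
})

test_that("network_stats counts sources and sinks by degree", {
  chain <- metabolic_network("c", c("A", "B", "C"),
                             data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_equal(network_stats(chain),
               c(n_nodes = 3L, n_edges = 2L, n_sources = 1L, n_sinks = 1L))
  cyc <- metabolic_network("c2", c("A", "B"),
                           data.frame(from = c("A", "B"), to = c("B", "A")))
  expect_equal(network_stats(cyc),
               c(n_nodes = 2L, n_edges = 2L, n_sources = 0L, n_sinks = 0L))
  toyA <- toy_networks_fig6()$netA
  expect_equal(unname(network_stats(toyA)["n_sources"]), 1L) # node A only
})

test_that("projection edge count matches brute-force pair enumeration", {
  withr::local_seed(42)
  opts <- graph_options(strip_compartments = FALSE)
  for (i in 1:20) {
    mets <- sprintf("x%02d", 1:12)
    rxns <- lapply(1:8, function(j) {
      subs <- sample(mets, sample(1:3, 1))
      prods <- sample(mets, sample(1:3, 1))
      list(id = paste0("r", j), substrates = subs, products = prods,
           reversible = runif(1) < 0.3, is_boundary = FALSE)
    })
    rs <- structure(list(model_id = "m", reactions = rxns),
                    class = "reaction_set")
    net <- project_to_metabolite_graph(rs, opts)
    expected <- unique(do.call(rbind, lapply(rxns, function(r) {
      pairs <- expand.grid(from = r$substrates, to = r$products,
                           stringsAsFactors = FALSE)
      if (r$reversible) pairs <- rbind(pairs,
                                       data.frame(from = pairs$to,
                                                  to = pairs$from))
      pairs
    })))
    expected <- expected[expected$from != expected$to, ]
    expect_equal(nrow(net$edges), nrow(expected))
  }
})

test_that("projection round-trips through the edge-list dialect", {
  withr::local_seed(7)
  mods <- random_models(synthetic_spec(rng_seed = 7), n_models = 3)
  for (m in mods) {
    net <- project_to_metabolite_graph(m$reactions)
    path <- withr::local_tempfile(fileext = ".tsv")
    suppressWarnings(write_edge_list(net, path))
    back <- read_edge_list(path, model_id = net$model_id)
    expect_identical(back$edges, net$edges)
  }
})

test_that("stripping compartments never increases the node count", {
  withr::local_seed(11)
  comps <- c("_c", "_e", "_p", "")
  for (i in 1:10) {
    mets <- paste0(sample(letters, 8), sample(comps, 8, replace = TRUE))
    rxns <- lapply(1:5, function(j) {
      list(id = paste0("r", j), substrates = sample(mets, 2),
           products = sample(mets, 2), reversible = FALSE,
           is_boundary = FALSE)
    })
    rs <- structure(list(model_id = "m", reactions = rxns),
                    class = "reaction_set")
    n_raw <- length(project_to_metabolite_graph(
      rs, graph_options(strip_compartments = FALSE))$nodes)
    n_strip <- length(project_to_metabolite_graph(rs, graph_options())$nodes)
    expect_lte(n_strip, n_raw)
  }
})
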