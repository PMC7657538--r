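#' Canonical two-species toy networks
#'
#' A minimal pair of metabolite networks whose seed structure exercises
#' every part of the index calculation: network A has seeds
#' \{A, F, G, H\} with F, G, H forming a 3-cycle (C = 1/3 each) and A a
#' singleton source (C = 1); network B has seeds \{F, I, J, K\} with I, J a
#' 2-cycle. Metabolites A and F both occur in network B, A as a non-seed
#' there, giving competition(A,B) = (1/3)/2 = 1/6 and
#' complementarity(A,B) = 1/2.
#'
#' @return A list with `metabolic_network` elements `netA` and `netB`.
#' @export
#' @examples
#' toy <- toy_networks_fig6()
#' competition_index(detect_seed_set(toy$netA), detect_seed_set(toy$netB))
toy_networks_fig6 <- function() {
  netA <- metabolic_network("netA",
    nodes = c("A", "B", "F", "G", "H"),
    edges = data.frame(
      from = c("A", "F", "G", "H", "H"),
      to   = c("B", "G", "H", "F", "B")))
  netB <- metabolic_network("netB",
    nodes = c("F", "I", "J", "K", "A", "L"),
    edges = data.frame(
      from = c("F", "I", "J", "K", "J"),
      to   = c("A", "J", "I", "L", "L")))
  list(netA = netA, netB = netB)
}

#' Specification for a random synthetic model
#'
#' @param n_metabolites Total number of metabolites.
#' @param n_reactions Number of random (non-planted) reactions.
#' @param reversible_fraction Probability that a random reaction is
#'   reversible.
#' @param planted_source_sccs Integer sizes of source SCCs planted into the
#'   graph; members of a planted component of size k are guaranteed seeds
#'   with confidence 1/k.
#' @param rng_seed Seed for reproducible generation.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_metabolites = 20L, n_reactions = 15L,
                           reversible_fraction = 0.2,
                           planted_source_sccs = c(1L, 3L),
                           rng_seed = 1L) {
  planted_source_sccs <- as.integer(planted_source_sccs)
  if (any(planted_source_sccs < 1L)) abort("planted SCC sizes must be >= 1")
  if (sum(planted_source_sccs) >= n_metabolites) {
    abort("infeasible spec: planted SCC nodes (", sum(planted_source_sccs),
          ") must be fewer than n_metabolites (", n_metabolites, ")")
  }
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_reactions = as.integer(n_reactions),
                 reversible_fraction = reversible_fraction,
                 planted_source_sccs = planted_source_sccs,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate random reaction sets with planted source SCCs
#'
#' Builds reaction sets whose projected metabolite graphs contain the
#' planted components as guaranteed source SCCs: planted metabolites form
#' irreversible cycles, feed outward into the random part of the network,
#' and receive no incoming edges. The random part draws substrates and
#' products only from non-planted metabolites, so additional source SCCs
#' may arise there but never absorb a planted one. Ground truth is emitted
#' alongside each model for oracle tests.
#'
#' @param spec A [synthetic_spec()].
#' @param n_models Number of models to generate; ids `sp01`, `sp02`, ...
#' @return A list of length `n_models`; each element has `reactions`
#'   (a `reaction_set`) and `truth` (list of planted components, each with
#'   `members` and `confidence`).
#' @export
random_models <- function(spec, n_models = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng_seed(spec$rng_seed, {
    lapply(seq_len(n_models), function(i) {
      random_model_one(spec, sprintf("sp%02d", i))
    })
  })
}

random_model_one <- function(spec, model_id) {
  n <- spec$n_metabolites
  mets <- sprintf("m%03d", seq_len(n))
  planted_sizes <- spec$planted_source_sccs
  planted <- mets[seq_len(sum(planted_sizes))]
  free <- setdiff(mets, planted)
  reactions <- list()
  truth <- list()
  offset <- 0L
  for (k in planted_sizes) {
    members <- planted[offset + seq_len(k)]
    offset <- offset + k
    if (k > 1L) {
      for (j in seq_len(k)) { # irreversible cycle => one SCC of size k
        reactions[[length(reactions) + 1L]] <- list(
          id = sprintf("%s_cyc%d", members[1], j),
          substrates = members[j],
          products = members[j %% k + 1L],
          reversible = FALSE, is_boundary = FALSE)
      }
    }
    # one outgoing reaction keeps the component in the graph and makes the
    # rest of the network reachable from it; nothing ever points back in
    reactions[[length(reactions) + 1L]] <- list(
      id = sprintf("%s_out", members[1]),
      substrates = members[1],
      products = sample(free, 1L),
      reversible = FALSE, is_boundary = FALSE)
    truth[[length(truth) + 1L]] <- list(members = members, confidence = 1 / k)
  }
  for (j in seq_len(spec$n_reactions)) {
    subs <- sample(free, sample(1:2, 1L))
    prods <- sample(setdiff(free, subs), sample(1:2, 1L))
    reactions[[length(reactions) + 1L]] <- list(
      id = sprintf("rxn%03d", j), substrates = subs, products = prods,
      reversible = stats::runif(1) < spec$reversible_fraction,
      is_boundary = FALSE)
  }
  list(reactions = structure(list(model_id = model_id, reactions = reactions),
                             class = "reaction_set"),
       truth = truth)
}

#' Generate a random bifurcating tree as a Newick string
#'
#' @param labels Leaf labels (at least two).
#' @param rng_seed Seed for reproducible topology and branch lengths.
#' @return A Newick string with strictly positive branch lengths.
#' @export
random_tree <- function(labels, rng_seed = 1L) {
  labels <- as.character(labels)
  if (length(labels) < 2L) abort("need at least 2 labels, got ",
                                 length(labels))
  with_rng_seed(rng_seed, {
    tree <- ape::rtree(length(labels), tip.label = labels,
                       br = function(m) stats::runif(m, 0.01, 1))
    ape::write.tree(tree)
  })
}

#' Write a self-contained demo data set
#'
#' Emits the toy networks (edge lists, plus SBML copies under `sbml/`), a
#' demo tree over the model ids and a demo taxonomy, so the full pipeline
#' can be run end to end without any external data.
#'
#' @param dir Output directory (created if needed).
#' @param rng_seed Seed for the demo tree.
#' @return Invisibly, the paths written.
#' @export
write_demo_fixtures <- function(dir, rng_seed = 1L) {
  dir.create(file.path(dir, "models"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "sbml"), showWarnings = FALSE)
  toy <- toy_networks_fig6()
  paths <- c(
    models_dir = file.path(dir, "models"),
    netA = file.path(dir, "models", "netA.tsv"),
    netB = file.path(dir, "models", "netB.tsv"),
    netA_sbml = file.path(dir, "sbml", "netA.xml"),
    netB_sbml = file.path(dir, "sbml", "netB.xml"),
    tree = file.path(dir, "tree.nwk"),
    taxonomy = file.path(dir, "taxonomy.tsv"))
  write_edge_list(toy$netA, paths["netA"])
  write_edge_list(toy$netB, paths["netB"])
  write_sbml_from_network(toy$netA, paths["netA_sbml"])
  write_sbml_from_network(toy$netB, paths["netB_sbml"])
  writeLines(random_tree(c("netA", "netB"), rng_seed), paths["tree"])
  utils::write.table(
    data.frame(model_id = c("netA", "netB"), genus = c("Toya", "Toya")),
    paths["taxonomy"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# minimal SBML serialisation: one irreversible reaction per edge; enough for
# round-tripping toy and synthetic networks through the SBML reader
write_sbml_from_network <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  rx <- vapply(seq_len(nrow(net$edges)), function(i) {
    paste0(
      '      <reaction id="rxn', i, '" reversible="false">\n',
      '        <listOfReactants><speciesReference species="',
      esc(net$edges$from[i]), '"/></listOfReactants>\n',
      '        <listOfProducts><speciesReference species="',
      esc(net$edges$to[i]), '"/></listOfProducts>\n',
      '      </reaction>')
  }, character(1))
  sp <- paste0('      <species id="', esc(net$nodes),
               '" boundaryCondition="false"/>')
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    paste0('  <model id="', esc(net$model_id), '">'),
    '    <listOfSpecies>', sp, '    </listOfSpecies>',
    '    <listOfReactions>', rx, '    </listOfReactions>',
    '  </model>', '</sbml>')
  writeLines(xml, path)
  invisible(path)
}
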