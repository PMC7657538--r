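#' Options controlling metabolite-graph construction
#'
#' Collects the switches shared by [read_sbml()] and
#' [project_to_metabolite_graph()].
#'
#' @param strip_compartments Drop trailing compartment tags (`_c`, `_e`,
#'   `_p`, ...) from metabolite ids so namespaces align across models.
#' @param drop_boundary Exclude boundary/exchange reactions from the graph.
#'   Exchange reactions would otherwise turn every exchanged metabolite into
#'   an artifactual source or sink.
#' @param drop_biomass Exclude the biomass objective pseudo-reaction.
#' @param boundary_prefixes Reaction-id prefixes (after an optional `R_`
#'   SBML prefix) that mark exchange/demand/sink reactions.
#' @param compartment_pattern Regular expression matched against the end of
#'   a metabolite id and removed when `strip_compartments` is `TRUE`.
#' @param exclude_mets Character vector of metabolite ids (post
#'   normalisation) to drop entirely, e.g. a user-supplied currency-compound
#'   blacklist. Empty by default.
#' @return A list of class `graph_options`.
#' @export
#' @examples
#' graph_options(strip_compartments = FALSE)
graph_options <- function(strip_compartments = TRUE,
                          drop_boundary = TRUE,
                          drop_biomass = TRUE,
                          boundary_prefixes = c("EX_", "DM_", "SK_", "sink_"),
                          compartment_pattern = "_(c|e|p|m|x|r|v|g|n|h|l|im|um|cm)[0-9]*$",
                          exclude_mets = character()) {
  structure(list(
    strip_compartments = isTRUE(strip_compartments),
    drop_boundary = isTRUE(drop_boundary),
    drop_biomass = isTRUE(drop_biomass),
    boundary_prefixes = as.character(boundary_prefixes),
    compartment_pattern = compartment_pattern,
    exclude_mets = as.character(exclude_mets)
  ), class = "graph_options")
}

normalize_met_ids <- function(ids, options) {
  if (options$strip_compartments) {
    ids <- sub(options$compartment_pattern, "", ids)
  }
  ids
}

#' Construct a directed metabolite network
#'
#' Low-level constructor for the container every downstream computation
#' operates on: metabolite ids as nodes, directed substrate-to-product
#' relations as edges. Self-loops and duplicate edges are dropped; nodes and
#' edges are kept in sorted order so identical networks compare identical.
#'
#' @param model_id Identifier of the model the network came from.
#' @param nodes Character vector of metabolite ids.
#' @param edges Two-column data frame (`from`, `to`) of directed edges.
#' @return An object of class `metabolic_network` with elements `model_id`,
#'   `nodes` (sorted character) and `edges` (sorted data frame).
#' @export
metabolic_network <- function(model_id, nodes, edges) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  edges <- unique(edges)
  missing <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(missing)) {
    abort("edge endpoints absent from node set: ",
          paste(missing, collapse = ", "))
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(model_id = as.character(model_id), nodes = nodes,
                 edges = edges),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf("<metabolic_network '%s': %d metabolites, %d edges, %d sources, %d sinks>\n",
              x$model_id, s["n_nodes"], s["n_edges"], s["n_sources"], s["n_sinks"]))
  invisible(x)
}

#' Convert a metabolite network to an igraph object
#'
#' @param net A `metabolic_network`.
#' @return A directed `igraph` graph whose vertex names are metabolite ids.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' Read a genome-scale metabolic model from SBML
#'
#' Parses an SBML Level 2 or 3 file into a reaction set: one record per
#' reaction with substrate and product metabolite ids, reversibility and a
#' boundary flag. Boundary status is inferred from species marked
#' `boundaryCondition="true"` or from exchange-style reaction-id prefixes
#' (see [graph_options()]). The biomass objective pseudo-reaction is
#' dropped when `options$drop_biomass` is set.
#'
#' @param path Path to an SBML file.
#' @param options A [graph_options()] object.
#' @return An object of class `reaction_set`: `model_id` plus a list of
#'   reactions, each with `id`, `substrates`, `products`, `reversible`,
#'   `is_boundary`.
#' @export
read_sbml <- function(path, options = graph_options()) {
  if (!file.exists(path)) abort("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort("cannot parse SBML file '", path,
                                            "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) {
    abort("cannot parse SBML file '", path, "': no <model> element")
  }
  model_id <- xml2::xml_attr(model, "id")
  if (is.na(model_id) || !nzchar(model_id)) {
    model_id <- sub("\\.(xml|sbml)$", "", basename(path), ignore.case = TRUE)
  }

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- tolower(xml2::xml_attr(sp_nodes, "boundaryCondition")) %in% "true"
  boundary_species <- sp_ids[sp_boundary]

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0L) {
    abort("empty model: '", path, "' contains no reactions",
          class = "phylomint_empty_model")
  }

  strip_r <- function(id) sub("^R_", "", id)
  is_exchange_id <- function(id) {
    any(startsWith(strip_r(id), options$boundary_prefixes))
  }

  reactions <- lapply(rx_nodes, function(rx) {
    id <- xml2::xml_attr(rx, "id")
    rev_attr <- xml2::xml_attr(rx, "reversible")
    reversible <- if (is.na(rev_attr)) TRUE else tolower(rev_attr) == "true"
    subs <- xml2::xml_attr(
      xml2::xml_find_all(rx, "./listOfReactants/speciesReference"), "species")
    prods <- xml2::xml_attr(
      xml2::xml_find_all(rx, "./listOfProducts/speciesReference"), "species")
    boundary <- is_exchange_id(id) ||
      any(c(subs, prods) %in% boundary_species) ||
      length(subs) == 0L || length(prods) == 0L
    list(id = id, substrates = unique(subs), products = unique(prods),
         reversible = reversible, is_boundary = boundary)
  })
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    abort("duplicate reaction ids in '", path, "': ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (options$drop_biomass) {
    is_biomass <- grepl("biomass|growth", ids, ignore.case = TRUE)
    reactions <- reactions[!is_biomass]
    if (length(reactions) == 0L) {
      abort("empty model: '", path,
            "' contains only biomass reactions",
            class = "phylomint_empty_model")
    }
  }
  structure(list(model_id = model_id, reactions = reactions),
            class = "reaction_set")
}

#' @export
print.reaction_set <- function(x, ...) {
  nb <- sum(vapply(x$reactions, `[[`, logical(1), "is_boundary"))
  cat(sprintf("<reaction_set '%s': %d reactions (%d boundary)>\n",
              x$model_id, length(x$reactions), nb))
  invisible(x)
}

#' Project a reaction set onto a directed metabolite graph
#'
#' Every non-boundary reaction contributes one edge substrate -> product for
#' each (substrate, product) pair; reversible reactions additionally
#' contribute the opposite edges, so that interconvertible metabolites end
#' up in one strongly connected component. Self-loops are dropped and
#' duplicate edges merged. Metabolite ids are normalised per `options`
#' (compartment suffixes stripped, blacklist applied).
#'
#' @param rxns A `reaction_set` from [read_sbml()].
#' @param options A [graph_options()] object.
#' @return A `metabolic_network`.
#' @export
project_to_metabolite_graph <- function(rxns, options = graph_options()) {
  stopifnot(inherits(rxns, "reaction_set"))
  keep <- rxns$reactions
  if (options$drop_boundary) {
    keep <- keep[!vapply(keep, `[[`, logical(1), "is_boundary")]
  }
  nodes <- character()
  from <- character()
  to <- character()
  for (rx in keep) {
    subs <- normalize_met_ids(rx$substrates, options)
    prods <- normalize_met_ids(rx$products, options)
    subs <- setdiff(subs, options$exclude_mets)
    prods <- setdiff(prods, options$exclude_mets)
    nodes <- c(nodes, subs, prods)
    if (length(subs) && length(prods)) {
      pairs <- expand.grid(from = subs, to = prods,
                           stringsAsFactors = FALSE)
      from <- c(from, pairs$from)
      to <- c(to, pairs$to)
      if (isTRUE(rx$reversible)) {
        from <- c(from, pairs$to)
        to <- c(to, pairs$from)
      }
    }
  }
  metabolic_network(rxns$model_id, nodes,
                    data.frame(from = from, to = to,
                               stringsAsFactors = FALSE))
}

#' Read a directed network from a plain edge list
#'
#' The dialect is one `source target` pair per line, whitespace separated;
#' blank lines and lines starting with `#` are ignored. Duplicate lines
#' collapse to a single edge (set semantics).
#'
#' @param path Path to the edge-list file.
#' @param model_id Model identifier; defaults to the file name without
#'   extension.
#' @return A `metabolic_network`.
#' @export
read_edge_list <- function(path, model_id = NULL) {
  if (!file.exists(path)) abort("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad)) {
    abort("malformed edge-list line ", keep[bad[1]], " in '", path,
          "': expected 'source target', got '", lines[keep[bad[1]]], "'")
  }
  from <- vapply(toks, `[[`, character(1), 1L)
  to <- vapply(toks, `[[`, character(1), 2L)
  model_id <- model_id %||% sub("\\.[^.]*$", "", basename(path))
  metabolic_network(model_id, c(from, to),
                    data.frame(from = from, to = to,
                               stringsAsFactors = FALSE))
}

#' Write a network to the plain edge-list dialect
#'
#' @param net A `metabolic_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  lines <- c(paste("#", net$model_id),
             paste(net$edges$from, net$edges$to))
  # the dialect has no node-only line, so isolated nodes cannot round-trip
  isolated <- setdiff(net$nodes, unique(c(net$edges$from, net$edges$to)))
  if (length(isolated)) {
    warning("edge-list format cannot represent ", length(isolated),
            " isolated node(s); they will be lost on re-read")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a network to GraphML
#'
#' @param net A `metabolic_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Basic node/edge/source/sink counts of a network
#'
#' Source nodes have in-degree zero, sink nodes out-degree zero; both feed
#' the robustness evaluation of reconstructed networks.
#'
#' @param net A `metabolic_network`.
#' @return Named integer vector `n_nodes`, `n_edges`, `n_sources`, `n_sinks`.
#' @export
#' @examples
#' net <- metabolic_network("toy", c("A", "B", "C"),
#'                          data.frame(from = c("A", "B"), to = c("B", "C")))
#' network_stats(net) # chain: 1 source, 1 sink
network_stats <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  indeg <- table(factor(net$edges$to, levels = net$nodes))
  outdeg <- table(factor(net$edges$from, levels = net$nodes))
  c(n_nodes = length(net$nodes),
    n_edges = nrow(net$edges),
    n_sources = sum(indeg == 0L),
    n_sinks = sum(outdeg == 0L))
}
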