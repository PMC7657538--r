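#' Strongly connected components and their condensation
#'
#' Partitions the metabolite graph into maximal strongly connected
#' components (SCCs) and returns the condensation, the directed acyclic
#' graph obtained by contracting each SCC to a single node. Component
#' indices are renumbered by the sorted order of each component's first
#' member, so the assignment is independent of node iteration order.
#'
#' @param net A `metabolic_network`.
#' @return A list with `membership` (named integer vector mapping metabolite
#'   to SCC index), `sizes` (integer vector of component sizes, indexed by
#'   SCC), and `edges` (two-column data frame of condensation edges between
#'   SCC indices, deduplicated, no self-loops).
#' @export
condense_sccs <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (length(net$nodes) == 0L) {
    return(list(membership = integer(0), sizes = integer(0),
                edges = data.frame(from = integer(0), to = integer(0))))
  }
  g <- as_igraph(net)
  comp <- igraph::components(g, mode = "strong")
  membership <- comp$membership[net$nodes] # nodes are sorted; fixes numbering
  # renumber by first appearance over the sorted node order
  relabel <- match(membership, unique(membership))
  names(relabel) <- net$nodes
  membership <- relabel
  sizes <- as.integer(table(factor(membership, levels = seq_len(max(membership)))))
  ce <- data.frame(from = membership[net$edges$from],
                   to = membership[net$edges$to])
  ce <- unique(ce[ce$from != ce$to, , drop = FALSE])
  rownames(ce) <- NULL
  list(membership = membership, sizes = sizes, edges = ce)
}

#' Detect the seed set of a metabolic network
#'
#' The seed set is the minimal set of compounds the network cannot
#' synthesise from other compounds and must acquire exogenously. It is
#' operationalised as the members of source SCCs: components with no
#' incoming edge in the SCC condensation. Each member of a source SCC of
#' size k receives confidence C = 1/k, the probability-like weight that the
#' compound is truly a seed, and members are retained when C is at least
#' `threshold`. Because C is constant within an SCC, thresholding removes
#' whole components.
#'
#' @param net A `metabolic_network`.
#' @param threshold Minimum confidence for a compound to be retained, in
#'   (0, 1]. The default 0.2 keeps source SCCs of at most 5 metabolites.
#' @return An object of class `seed_set` with elements `model_id`,
#'   `confidence` (named numeric, retained members only), `scc_of` (named
#'   integer, SCC index of every network node), `scc_sizes`, and
#'   `source_confidence` (named numeric over all source-SCC members, before
#'   thresholding).
#' @export
#' @examples
#' toy <- toy_networks_fig6()
#' detect_seed_set(toy$netA)$confidence # A = 1, F = G = H = 1/3
detect_seed_set <- function(net, threshold = 0.2) {
  stopifnot(inherits(net, "metabolic_network"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    abort("threshold must be a single number in (0, 1], got ",
          format(threshold))
  }
  scc <- condense_sccs(net)
  n_scc <- length(scc$sizes)
  has_incoming <- rep(FALSE, n_scc)
  has_incoming[unique(scc$edges$to)] <- TRUE
  source_sccs <- which(!has_incoming)

  in_source <- scc$membership %in% source_sccs
  source_conf <- 1 / scc$sizes[scc$membership[in_source]]
  names(source_conf) <- names(scc$membership)[in_source]
  source_conf <- source_conf[order(names(source_conf))]

  # C >= threshold, with a tolerance so 1/5 >= 0.2 survives floating point
  retained <- source_conf >= threshold - 1e-12
  structure(list(model_id = net$model_id,
                 confidence = source_conf[retained],
                 scc_of = scc$membership,
                 scc_sizes = scc$sizes,
                 source_confidence = source_conf,
                 threshold = threshold),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set '%s': %d seeds (%d before C >= %g threshold)>\n",
              x$model_id, length(x$confidence), length(x$source_confidence),
              x$threshold))
  invisible(x)
}

#' Members of a seed set
#'
#' @param seeds A `seed_set`.
#' @param pre_threshold Return all source-SCC members instead of only those
#'   passing the confidence threshold.
#' @return Character vector of metabolite ids.
#' @export
seed_members <- function(seeds, pre_threshold = FALSE) {
  stopifnot(inherits(seeds, "seed_set"))
  names(if (pre_threshold) seeds$source_confidence else seeds$confidence)
}
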