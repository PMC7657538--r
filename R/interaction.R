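#' Metabolic competition index
#'
#' Confidence-weighted fraction of A's seed set that is also in B's seed
#' set: sum of A's confidences over the shared seeds divided by the sum
#' over all of A's seeds. Measures baseline nutritional overlap; 1 for
#' identical seed profiles, 0 for disjoint ones. The index is asymmetric:
#' confidences are taken from A only.
#'
#' @param seedA,seedB `seed_set` objects for the focal species A and the
#'   partner B.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' toy <- toy_networks_fig6()
#' sA <- detect_seed_set(toy$netA); sB <- detect_seed_set(toy$netB)
#' competition_index(sA, sB) # 1/6
competition_index <- function(seedA, seedB) {
  stopifnot(inherits(seedA, "seed_set"), inherits(seedB, "seed_set"))
  confA <- seedA$confidence
  if (length(confA) == 0L) {
    abort("competition index undefined: seed set of '", seedA$model_id,
          "' is empty", class = "phylomint_undefined_index")
  }
  shared <- intersect(names(confA), names(seedB$confidence))
  sum(confA[shared]) / sum(confA)
}

#' Metabolic complementarity index
#'
#' Fraction of A's seed compounds that occur in B's metabolic network as
#' non-seeds of B, normalised by the number of A's seeds occurring anywhere
#' in B's network. A seed of A that B can synthesise internally is a
#' compound A could in principle obtain from B, so higher values indicate
#' greater potential for A to feed on B's metabolic output. Unweighted
#' cardinalities are used (unlike the competition index). When none of A's
#' seeds occurs in B's network the two species share no metabolite
#' namespace and the index is defined as 0.
#'
#' @param seedA `seed_set` of the focal species A.
#' @param netB `metabolic_network` of the partner B.
#' @param seedB `seed_set` of the partner B.
#' @return A number in \[0, 1\], with attribute `shared_namespace` set to
#'   `FALSE` when the denominator was empty.
#' @export
#' @examples
#' toy <- toy_networks_fig6()
#' sA <- detect_seed_set(toy$netA); sB <- detect_seed_set(toy$netB)
#' complementarity_index(sA, toy$netB, sB) # 0.5
complementarity_index <- function(seedA, netB, seedB) {
  stopifnot(inherits(seedA, "seed_set"), inherits(netB, "metabolic_network"),
            inherits(seedB, "seed_set"))
  SA <- names(seedA$confidence)
  if (length(SA) == 0L) {
    abort("complementarity index undefined: seed set of '", seedA$model_id,
          "' is empty", class = "phylomint_undefined_index")
  }
  in_B <- intersect(SA, netB$nodes)
  if (length(in_B) == 0L) {
    return(structure(0, shared_namespace = FALSE))
  }
  non_seed_B <- setdiff(netB$nodes, names(seedB$confidence))
  structure(length(intersect(SA, non_seed_B)) / length(in_B),
            shared_namespace = TRUE)
}

#' Pairwise interaction indices over a model collection
#'
#' Computes competition and complementarity for every ordered pair of
#' models; with n models this yields n(n-1) records, and the (A, B) and
#' (B, A) records are independent because both indices are asymmetric.
#'
#' @param models A list where each element is a list with components
#'   `network` (`metabolic_network`) and `seeds` (`seed_set`).
#' @return A data frame with one row per ordered pair: `source`, `target`,
#'   `competition`, `complementarity`, `seedA_size`, `seedB_size`, and
#'   `shared_namespace` (`FALSE` when no seed of the source occurs in the
#'   target's network).
#' @export
all_pairs <- function(models) {
  if (length(models) < 2L) abort("need at least 2 models, got ", length(models))
  for (m in models) {
    stopifnot(inherits(m$network, "metabolic_network"),
              inherits(m$seeds, "seed_set"))
  }
  ids <- vapply(models, function(m) m$network$model_id, character(1))
  if (anyDuplicated(ids)) {
    abort("duplicate model ids: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(models) <- ids
  n <- length(models)
  rows <- vector("list", n * (n - 1L))
  k <- 0L
  for (a in ids) {
    for (b in ids) {
      if (a == b) next
      k <- k + 1L
      comp <- competition_index(models[[a]]$seeds, models[[b]]$seeds)
      cmpl <- complementarity_index(models[[a]]$seeds, models[[b]]$network,
                                    models[[b]]$seeds)
      rows[[k]] <- data.frame(
        source = a, target = b,
        competition = comp,
        complementarity = as.numeric(cmpl),
        seedA_size = length(models[[a]]$seeds$confidence),
        seedB_size = length(models[[b]]$seeds$confidence),
        shared_namespace = isTRUE(attr(cmpl, "shared_namespace")),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
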