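#' Read a phylogenetic tree from a Newick file
#'
#' Trees are consumed, never inferred: the contract is a Newick tree with
#' branch lengths on every edge and unique leaf labels matching the
#' metabolic-model identifiers.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort("cannot parse Newick file '",
                                             path, "': ",
                                             conditionMessage(e)))
  if (is.null(tree)) abort("cannot parse Newick file '", path, "'")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_tree(tree, path)
  tree
}

validate_tree <- function(tree, label = "tree") {
  if (is.null(tree$edge.length)) {
    abort("tree '", label, "' has no branch lengths; ",
          "patristic distances are undefined")
  }
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    abort("tree '", label, "' is missing a branch length on edge ",
          tree$edge[bad, 1], "->", tree$edge[bad, 2])
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    abort("tree '", label, "' has duplicate leaf labels: ",
          paste(dup, collapse = ", "))
  }
  invisible(tree)
}

#' Patristic distances between tree leaves
#'
#' The phylogenetic distance between two species is the sum of branch
#' lengths on the unique tree path between their leaves. This additive
#' (patristic) metric is invariant under re-rooting.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param labels Leaf labels to compute distances for; defaults to all
#'   leaves. Must be a subset of the tree's leaves.
#' @return A data frame with one row per unordered pair: `label_a`,
#'   `label_b` (with `label_a < label_b`), `distance`. The full symmetric
#'   matrix is attached as attribute `matrix`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
#' patristic_distances(tr) # d(A,B)=3, d(A,C)=4.5, d(B,C)=5.5
patristic_distances <- function(tree, labels = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  validate_tree(tree)
  labels <- as.character(labels)
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing)) {
    abort("labels absent from tree: ", paste(missing, collapse = ", "))
  }
  labels <- sort(unique(labels))
  D <- stats::cophenetic(tree)[labels, labels, drop = FALSE]
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  out <- data.frame(label_a = labels[pairs[, "row"]],
                    label_b = labels[pairs[, "col"]],
                    distance = D[pairs],
                    stringsAsFactors = FALSE)
  out <- out[order(out$label_a, out$label_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "matrix") <- D
  out
}

#' Look up distances for ordered pairs
#'
#' @param dist_table Output of [patristic_distances()].
#' @param a,b Character vectors of labels (recycled to common length).
#' @return Numeric vector of distances, 0 on the diagonal.
#' @export
distance_lookup <- function(dist_table, a, b) {
  D <- attr(dist_table, "matrix")
  if (is.null(D)) abort("dist_table lacks its distance matrix attribute")
  missing <- setdiff(unique(c(a, b)), rownames(D))
  if (length(missing)) {
    abort("labels absent from distance table: ",
          paste(missing, collapse = ", "))
  }
  D[cbind(a, b)]
}

#' Write a distance table to long-format TSV
#'
#' @param dist_table Output of [patristic_distances()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dist_table, path) {
  utils::write.table(format_num_df(dist_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
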