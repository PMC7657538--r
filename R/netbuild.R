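#' Build the directed cooperation network from a Z-score table
#'
#' A directed edge A -> B is added when the pair shows significantly high
#' complementarity (z above `complement_threshold`) together with low
#' competition (z below `competition_threshold`); both inequalities are
#' strict. The competition threshold is deliberately more permissive than
#' the Tukey fence: demanding a full -2.698 competition outlier on top of a
#' complementarity outlier leaves almost no edges.
#'
#' @param z A `ztable` (long format) holding both metrics for every ordered
#'   pair, as produced by [zscores_within_bins()].
#' @param complement_threshold Minimum complementarity Z-score; default
#'   2.698.
#' @param competition_threshold Maximum competition Z-score; default -1.
#' @param drop_isolated Drop nodes with no incident edge (default `TRUE`).
#' @return An object of class `interaction_graph`: `nodes` (model ids) and
#'   `edges` (data frame `from`, `to`, `z_complementarity`,
#'   `z_competition`).
#' @export
build_graph <- function(z, complement_threshold = 2.698,
                        competition_threshold = -1.000,
                        drop_isolated = TRUE) {
  stopifnot(is.data.frame(z),
            all(c("source", "target", "metric", "z") %in% names(z)))
  cmpl <- z[z$metric == "complementarity", c("source", "target", "z")]
  comp <- z[z$metric == "competition", c("source", "target", "z")]
  names(cmpl)[3] <- "z_complementarity"
  names(comp)[3] <- "z_competition"
  wide <- merge(cmpl, comp, by = c("source", "target"), all = TRUE)
  incomplete <- is.na(wide$z_complementarity) | is.na(wide$z_competition)
  if (any(incomplete)) {
    bad <- wide[incomplete, c("source", "target")]
    abort("pairs missing one metric: ",
          paste(paste0(bad$source, "->", bad$target), collapse = ", "))
  }
  hit <- wide$z_complementarity > complement_threshold &
    wide$z_competition < competition_threshold
  edges <- wide[hit, , drop = FALSE]
  names(edges)[1:2] <- c("from", "to")
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- if (drop_isolated) {
    sort(unique(c(edges$from, edges$to)))
  } else {
    sort(unique(c(z$source, z$target)))
  }
  structure(list(nodes = nodes, edges = edges), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph: %d species, %d cooperation edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export an interaction graph in Infomap link-list format
#'
#' Writes the zero-based integer link list Infomap consumes (one
#' `source target` line per edge) together with a two-column TSV mapping
#' integer ids back to model ids. Community detection itself is delegated
#' to an external Infomap run, e.g.
#' `Infomap --directed --zero-based-numbering --num-trials 10 links.txt out/`.
#'
#' @param g An `interaction_graph` with at least one node.
#' @param path Output path for the link list.
#' @param mapping_path Output path for the id mapping TSV; defaults to
#'   `path` + ".ids.tsv".
#' @return Invisibly, `c(links = path, mapping = mapping_path)`.
#' @export
export_infomap <- function(g, path, mapping_path = paste0(path, ".ids.tsv")) {
  stopifnot(inherits(g, "interaction_graph"))
  if (length(g$nodes) == 0L) abort("cannot export an empty graph")
  id <- stats::setNames(seq_along(g$nodes) - 1L, g$nodes)
  writeLines(paste(id[g$edges$from], id[g$edges$to]), path)
  utils::write.table(
    data.frame(node_id = unname(id), model_id = names(id)),
    mapping_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(links = path, mapping = mapping_path))
}

#' Parse Infomap hierarchical module output
#'
#' Reads Infomap ".tree"-style output (`path flow "name" node_id` per line,
#' `#` comments ignored) and translates node ids back to model ids via the
#' mapping written by [export_infomap()]. The module path is hierarchical:
#' "1:3:2" places the node under sub-module 3 of top module 1.
#'
#' @param tree_output Path to the Infomap tree file.
#' @param mapping Path to the id-mapping TSV.
#' @return Named character vector: model id -> hierarchical module path.
#' @export
parse_infomap_modules <- function(tree_output, mapping) {
  map <- utils::read.table(mapping, sep = "\t", header = TRUE,
                           colClasses = c("integer", "character"))
  lines <- readLines(tree_output, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  toks <- regmatches(lines, regexec(
    '^([0-9:]+)\\s+(\\S+)\\s+"?([^"]*)"?\\s+(\\d+)\\s*$', lines))
  bad <- which(lengths(toks) != 5L)
  if (length(bad)) {
    abort("unparsable Infomap tree line: '", lines[bad[1]], "'")
  }
  node_id <- as.integer(vapply(toks, `[[`, character(1), 5L))
  module <- vapply(toks, `[[`, character(1), 2L)
  idx <- match(node_id, map$node_id)
  if (anyNA(idx)) {
    abort("node id(s) absent from mapping: ",
          paste(unique(node_id[is.na(idx)]), collapse = ", "))
  }
  stats::setNames(module, map$model_id[idx])
}

#' Proportion of significant same-genus pairs, per genus
#'
#' For each genus with at least two members, counts the ordered same-genus
#' pairs, how many of them are flagged as significant cooperators, and the
#' resulting proportion — the summary used to detect habitat-filtering
#' signatures (clades whose members cooperate more than expected).
#'
#' @param flags Data frame with columns `source`, `target` and logical
#'   `significant` (e.g. edges of [build_graph()] marked `TRUE`, or a full
#'   pair table with the edge rule applied).
#' @param taxonomy Named character vector mapping model id to genus; must
#'   cover every model appearing in `flags`.
#' @return Data frame `genus`, `n_members`, `n_pairs`, `n_significant`,
#'   `proportion`, one row per genus with >= 2 members.
#' @export
within_genus_proportions <- function(flags, taxonomy) {
  stopifnot(is.data.frame(flags),
            all(c("source", "target", "significant") %in% names(flags)))
  models <- unique(c(flags$source, flags$target))
  missing <- setdiff(models, names(taxonomy))
  if (length(missing)) {
    abort("taxonomy does not cover: ", paste(missing, collapse = ", "))
  }
  counts <- table(taxonomy[names(taxonomy) %in% models])
  genera <- sort(names(counts[counts >= 2L]))
  same <- taxonomy[flags$source] == taxonomy[flags$target]
  rows <- lapply(genera, function(g) {
    n <- as.integer(counts[[g]])
    in_genus <- same & taxonomy[flags$source] == g
    n_sig <- sum(flags$significant[in_genus])
    data.frame(genus = g, n_members = n, n_pairs = n * (n - 1L),
               n_significant = n_sig,
               proportion = n_sig / (n * (n - 1L)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(genus = character(0), n_members = integer(0),
               n_pairs = integer(0), n_significant = integer(0),
               proportion = numeric(0))
  rownames(out) <- NULL
  out
}
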