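#' Configuration for an end-to-end pipeline run
#'
#' Bundles the inputs and the method parameters: seed-confidence threshold
#' (default 0.2), phylogenetic bin width (default 0.01), complementarity
#' Z-score threshold (default 2.698) and the relaxed competition Z-score
#' threshold (default -1).
#'
#' @param model_dir Directory of model files: `.xml`/`.sbml` are read as
#'   SBML, `.tsv`/`.txt` as plain edge lists.
#' @param tree_path Newick tree whose leaf labels match the model ids.
#' @param output_dir Directory for the result tables and manifest.
#' @param seed_threshold Minimum seed confidence C.
#' @param bin_width Phylogenetic-distance bin width.
#' @param z_high Complementarity Z-score above which an edge is considered.
#' @param z_low_competition Competition Z-score below which an edge is
#'   considered.
#' @param rng_seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic, but fixture generation upstream may not be).
#' @param options [graph_options()] controlling graph construction.
#' @return A list of class `run_config`.
#' @export
run_config <- function(model_dir, tree_path, output_dir,
                       seed_threshold = 0.2, bin_width = 0.01,
                       z_high = 2.698, z_low_competition = -1.000,
                       rng_seed = 1L, options = graph_options()) {
  if (!dir.exists(model_dir)) abort("model directory not found: ", model_dir)
  if (!file.exists(tree_path)) abort("tree file not found: ", tree_path)
  structure(list(model_dir = model_dir, tree_path = tree_path,
                 output_dir = output_dir, seed_threshold = seed_threshold,
                 bin_width = bin_width, z_high = z_high,
                 z_low_competition = z_low_competition,
                 rng_seed = as.integer(rng_seed), options = options),
            class = "run_config")
}

load_model_file <- function(path, options) {
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
    project_to_metabolite_graph(read_sbml(path, options), options)
  } else {
    read_edge_list(path)
  }
}

#' Run the full interaction-inference pipeline
#'
#' Stages, in fixed order: load models and build metabolite graphs; detect
#' seed sets; compute all pairwise indices; compute patristic distances;
#' bin pairs by distance and merge small bins; Z-score both indices within
#' bins; flag outliers; build the cooperation network. Writes
#' `indices.tsv`, `dist.tsv`, `ztable.tsv`, `network.tsv`, `network.links`
#' (+ id mapping, when the network is non-empty) and `manifest.json` to the
#' output directory. A pre-flight check verifies that every model id is a
#' tree leaf before anything is computed or written.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress stage logging to stderr.
#' @return The manifest, invisibly: input hashes, parameters, per-stage row
#'   counts and output paths.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message("[phylomint] ", ...)

  model_files <- list.files(cfg$model_dir,
                            pattern = "\\.(xml|sbml|tsv|txt)$",
                            full.names = TRUE, ignore.case = TRUE)
  if (length(model_files) < 2L) {
    abort("need at least 2 model files in ", cfg$model_dir, ", found ",
          length(model_files))
  }
  tree <- read_newick(cfg$tree_path)

  say("loading ", length(model_files), " models")
  nets <- lapply(model_files, load_model_file, options = cfg$options)
  ids <- vapply(nets, `[[`, character(1), "model_id")
  if (anyDuplicated(ids)) {
    abort("duplicate model ids: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  absent <- setdiff(ids, tree$tip.label)
  if (length(absent)) {
    abort("pre-flight failure: model ids missing from tree: ",
          paste(absent, collapse = ", "))
  }

  say("detecting seed sets (C >= ", cfg$seed_threshold, ")")
  models <- lapply(nets, function(net) {
    list(network = net,
         seeds = detect_seed_set(net, threshold = cfg$seed_threshold))
  })

  say("computing pairwise indices")
  indices <- all_pairs(models)

  say("computing patristic distances")
  dist_table <- patristic_distances(tree, ids)
  indices$distance <- distance_lookup(dist_table, indices$source,
                                      indices$target)

  say("binning (width ", cfg$bin_width, ") and merging small bins")
  bins <- merge_small_bins(assign_bins(indices$distance, cfg$bin_width))

  say("Z-scoring within bins and flagging outliers")
  ztab <- flag_outliers(zscores_within_bins(indices, bins))

  say("building cooperation network (z_compl > ", cfg$z_high,
      ", z_compet < ", cfg$z_low_competition, ")")
  graph <- build_graph(ztab, cfg$z_high, cfg$z_low_competition)

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(cfg$output_dir, name)
  write_tsv <- function(df, path) {
    utils::write.table(format_num_df(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(indices, out("indices.tsv"))
  write_distances(dist_table, out("dist.tsv"))
  ztab_wide <- ztable_wide(ztab)
  write_tsv(ztab_wide, out("ztable.tsv"))
  write_tsv(graph$edges, out("network.tsv"))
  outputs <- c(indices = out("indices.tsv"), dist = out("dist.tsv"),
               ztable = out("ztable.tsv"), network = out("network.tsv"))
  if (length(graph$nodes)) {
    export_infomap(graph, out("network.links"))
    outputs <- c(outputs, links = out("network.links"),
                 mapping = out("network.links.ids.tsv"))
  }

  manifest <- list(
    inputs = list(
      models = as.list(stats::setNames(unname(tools::md5sum(model_files)),
                                       basename(model_files))),
      tree = unname(tools::md5sum(cfg$tree_path))),
    parameters = list(seed_threshold = cfg$seed_threshold,
                      bin_width = cfg$bin_width, z_high = cfg$z_high,
                      z_low_competition = cfg$z_low_competition,
                      rng_seed = cfg$rng_seed,
                      strip_compartments = cfg$options$strip_compartments,
                      drop_boundary = cfg$options$drop_boundary,
                      drop_biomass = cfg$options$drop_biomass),
    stages = list(n_models = length(ids),
                  n_pairs = nrow(indices),
                  n_bins = length(bins$sizes),
                  n_ztable_rows = nrow(ztab),
                  n_network_nodes = length(graph$nodes),
                  n_network_edges = nrow(graph$edges)),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  say("done: ", nrow(indices), " pairs, ", nrow(graph$edges),
      " network edges")
  invisible(manifest)
}

#' Pivot a long Z-table to one row per ordered pair
#'
#' @param ztab A `ztable` from [zscores_within_bins()] / [flag_outliers()].
#' @return Data frame with columns `source`, `target`, `bin`,
#'   `complementarity`, `competition`, `z_complementarity`,
#'   `z_competition`, `flag_complementarity`, `flag_competition`.
#' @export
ztable_wide <- function(ztab) {
  cmpl <- ztab[ztab$metric == "complementarity", ]
  comp <- ztab[ztab$metric == "competition", ]
  names(cmpl)[names(cmpl) %in% c("value", "z", "flag")] <-
    c("complementarity", "z_complementarity", "flag_complementarity")
  names(comp)[names(comp) %in% c("value", "z", "flag")] <-
    c("competition", "z_competition", "flag_competition")
  comp$bin <- NULL
  wide <- merge(cmpl, comp, by = c("source", "target"), sort = TRUE)
  wide$metric.x <- NULL
  wide$metric.y <- NULL
  wide[order(wide$source, wide$target),
       c("source", "target", "bin", "complementarity", "competition",
         "z_complementarity", "z_competition", "flag_complementarity",
         "flag_competition")]
}
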