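#' A CDS catalog: the ordered gene complement of one genome
#'
#' Order matters: adjacency in the catalog defines "neighbouring" coding
#' sequences, and genes missing from incomplete assemblies tend to be
#' missing in neighbouring blocks rather than independently at random.
#'
#' @param genome_id Genome identifier.
#' @param cds Character vector of CDS ids, in genome order.
#' @return An object of class `cds_catalog`.
#' @export
cds_catalog <- function(genome_id, cds) {
  cds <- as.character(cds)
  if (anyDuplicated(cds)) {
    abort("duplicate CDS ids: ",
          paste(unique(cds[duplicated(cds)]), collapse = ", "))
  }
  structure(list(genome_id = as.character(genome_id), cds = cds),
            class = "cds_catalog")
}

#' Read a CDS catalog from a FASTA or one-id-per-line file
#'
#' @param path Input path. Files whose first non-blank character is `>` are
#'   treated as FASTA (ids taken from the headers, in file order);
#'   otherwise one CDS id per line.
#' @param genome_id Genome id; defaults to the file name without extension.
#' @return A `cds_catalog`.
#' @export
read_cds_catalog <- function(path, genome_id = NULL) {
  if (!file.exists(path)) abort("CDS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(trimws(lines[1]), ">")) {
    ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[startsWith(lines, ">")])
  } else {
    ids <- trimws(lines)
  }
  cds_catalog(genome_id %||% sub("\\.[^.]*$", "", basename(path)), ids)
}

#' Remove random blocks of neighbouring CDSs down to a target fraction
#'
#' Emulates gene loss in incomplete metagenome-assembled genomes: blocks of
#' `block` consecutive CDSs are deleted at uniformly random start positions,
#' with replacement (overlapping draws remove fewer new genes), until the
#' retained fraction first drops to or below `target_fraction`. No
#' wraparound block spans the end of the catalog. The retained fraction is
#' guaranteed to lie in (target - block/n, target].
#'
#' @param catalog A `cds_catalog` (or plain character vector of CDS ids).
#' @param target_fraction Fraction of CDSs to retain, in (0, 1].
#' @param block Number of consecutive CDSs removed per draw; default 3.
#' @param rng_seed Optional seed for reproducible subsampling.
#' @return Character vector of retained CDS ids, in catalog order.
#' @export
subsample_cds <- function(catalog, target_fraction, block = 3L,
                          rng_seed = NULL) {
  cds <- if (inherits(catalog, "cds_catalog")) catalog$cds
         else as.character(catalog)
  n <- length(cds)
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0 || target_fraction > 1) {
    abort("target_fraction must be in (0, 1], got ", format(target_fraction))
  }
  if (!is.numeric(block) || block < 1L) abort("block must be >= 1")
  block <- as.integer(min(block, n))
  with_rng_seed(rng_seed, {
    removed <- logical(n)
    while (sum(!removed) / n > target_fraction) {
      start <- sample.int(n - block + 1L, 1L)
      removed[start:(start + block - 1L)] <- TRUE
    }
    cds[!removed]
  })
}

#' Jaccard similarity of two sets
#'
#' |intersection| / |union|, with the convention that two empty sets have
#' similarity 1.
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return A number in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

edge_keys <- function(net) paste(net$edges$from, net$edges$to, sep = "\r")

#' Degradation experiment: network stability under simulated incompleteness
#'
#' For each target fraction and replicate, subsamples the CDS catalog in
#' neighbouring blocks, rebuilds the metabolic network with the supplied
#' `builder`, and compares it to the network built from the full catalog
#' via node/edge Jaccard similarity and source/sink counts. Model
#' reconstruction is a pluggable hook: pass a wrapper around your
#' reconstruction tool, or a synthetic rule for testing. The
#' `baseline_similarity` column records the retained fraction itself, the
#' reference line (intercept 1, slope -1 against fraction removed) that a
#' proportionally degrading network would follow.
#'
#' @param catalog A `cds_catalog`.
#' @param builder Function mapping a character vector of retained CDS ids
#'   to a `metabolic_network`.
#' @param fractions Target retained fractions; default 0.70 to 1.00 in
#'   steps of 0.05.
#' @param replicates Replicates per fraction; default 50.
#' @param block Block size for [subsample_cds()]; default 3.
#' @param rng_seed Seed governing the whole experiment.
#' @return Data frame with one row per fraction x replicate:
#'   `fraction_target`, `replicate`, `retained_count`, `retained_fraction`,
#'   `n_sources`, `n_sinks`, `jaccard_nodes`, `jaccard_edges`,
#'   `baseline_similarity`.
#' @export
run_degradation <- function(catalog, builder,
                            fractions = seq(0.70, 1.00, by = 0.05),
                            replicates = 50L, block = 3L, rng_seed = 1L) {
  stopifnot(inherits(catalog, "cds_catalog"), is.function(builder))
  reference <- builder(catalog$cds)
  stopifnot(inherits(reference, "metabolic_network"))
  ref_edges <- edge_keys(reference)
  n <- length(catalog$cds)
  with_rng_seed(rng_seed, {
    rows <- list()
    for (f in fractions) {
      for (r in seq_len(replicates)) {
        retained <- subsample_cds(catalog, f, block = block)
        net <- tryCatch(builder(retained), error = function(e) {
          abort("builder failed at fraction ", f, ", replicate ", r, ": ",
                conditionMessage(e))
        })
        s <- network_stats(net)
        rows[[length(rows) + 1L]] <- data.frame(
          fraction_target = f, replicate = r,
          retained_count = length(retained),
          retained_fraction = length(retained) / n,
          n_sources = unname(s["n_sources"]),
          n_sinks = unname(s["n_sinks"]),
          jaccard_nodes = jaccard_similarity(net$nodes, reference$nodes),
          jaccard_edges = jaccard_similarity(edge_keys(net), ref_edges),
          baseline_similarity = length(retained) / n)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
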