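#' Bin species pairs by phylogenetic distance
#'
#' First step of the discretisation that decouples interaction indices from
#' phylogeny: pairs are assigned to contiguous half-open distance intervals
#' [k*w, (k+1)*w) of fixed width w, so a distance of exactly one width
#' boundary falls in the upper bin.
#'
#' @param distances Non-negative numeric vector of pairwise phylogenetic
#'   distances, one per observation.
#' @param width Bin width in branch-length units; default 0.01.
#' @return An object of class `bin_assignment`: `bin` (integer bin index
#'   per observation, 0-based by distance), `sizes` (named integer vector
#'   of occupied-bin sizes, increasing bin order), `width`, and
#'   `merged = FALSE`.
#' @export
assign_bins <- function(distances, width = 0.01) {
  if (!is.numeric(distances)) abort("distances must be numeric")
  if (anyNA(distances) || any(distances < 0)) {
    abort("distances must be non-negative and non-missing")
  }
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    abort("width must be a single positive number")
  }
  bin <- as.integer(floor(distances / width))
  sizes <- table(bin)
  sizes <- stats::setNames(as.integer(sizes),
                           names(sizes))[order(as.integer(names(sizes)))]
  structure(list(bin = bin, sizes = sizes, width = width, merged = FALSE),
            class = "bin_assignment")
}

#' Merge under-populated distance bins
#'
#' Z-scores within a near-empty bin are meaningless, so bins smaller than a
#' minimum size are merged away. The minimum is the size of the first
#' (lowest-distance) occupied bin. Scanning bins in increasing-distance
#' order, each small bin is merged into the closest preceding bin whose
#' current size meets the minimum; a small bin with no qualifying
#' predecessor is merged forward into the first subsequent qualifying bin.
#' After merging every bin meets the minimum unless only one bin remains.
#'
#' @param bins A `bin_assignment` from [assign_bins()].
#' @return A `bin_assignment` with `merged = TRUE`, merged `bin` labels
#'   (each merged bin keeps the index of its absorbing bin) and `min_size`
#'   recording the reference size.
#' @export
merge_small_bins <- function(bins) {
  stopifnot(inherits(bins, "bin_assignment"))
  sizes <- bins$sizes
  if (length(sizes) == 0L) {
    out <- bins
    out$merged <- TRUE
    out$min_size <- 0L
    return(out)
  }
  ids <- as.integer(names(sizes))
  cur <- as.integer(sizes)
  min_size <- cur[1]
  target <- ids # absorbing bin for each original occupied bin
  for (i in seq_along(ids)) {
    if (cur[i] >= min_size || cur[i] == 0L) next
    pred <- which(cur[seq_len(i - 1L)] >= min_size)
    if (length(pred)) {
      j <- max(pred)
    } else {
      succ <- which(cur[-seq_len(i)] >= min_size)
      if (length(succ) == 0L) next # no qualifying bin anywhere; leave as is
      j <- i + min(succ)
    }
    cur[j] <- cur[j] + cur[i]
    cur[i] <- 0L
    target[target == ids[i]] <- target[j]
  }
  new_bin <- target[match(bins$bin, ids)]
  keep <- cur > 0L
  out <- bins
  out$bin <- new_bin
  out$sizes <- stats::setNames(cur[keep], ids[keep])
  out$merged <- TRUE
  out$min_size <- min_size
  out
}

#' Z-scores within a vector of bins
#'
#' Standardises `x` within each bin: z = (x - bin mean) / bin sd, using the
#' sample (n - 1) standard deviation. Singleton bins and bins with zero
#' variance yield z = 0 for their members, since no outlier is detectable
#' there.
#'
#' @param x Numeric vector of raw metric values.
#' @param bin Bin label per observation (same length as `x`).
#' @return Numeric vector of Z-scores.
#' @export
bin_zscores <- function(x, bin) {
  stopifnot(length(x) == length(bin))
  z <- numeric(length(x))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    if (length(idx) < 2L) next
    s <- stats::sd(x[idx])
    if (!is.finite(s) || s == 0) next
    z[idx] <- (x[idx] - mean(x[idx])) / s
  }
  z
}

#' Per-bin Z-scores for an interaction table
#'
#' Standardises the complementarity and competition indices independently
#' within each phylogenetic-distance bin, on the same bin assignment.
#'
#' @param pairs Data frame with columns `source`, `target`, and one column
#'   per metric (by default `complementarity` and `competition`).
#' @param bins A `bin_assignment` whose `bin` vector aligns with the rows
#'   of `pairs`.
#' @param metrics Character vector of metric column names.
#' @return A long-format data frame of class `ztable`: `source`, `target`,
#'   `metric`, `value`, `bin`, `z`, `flag` (initialised to "none"; see
#'   [flag_outliers()]).
#' @export
zscores_within_bins <- function(pairs, bins,
                                metrics = c("complementarity", "competition")) {
  stopifnot(inherits(bins, "bin_assignment"),
            length(bins$bin) == nrow(pairs))
  missing <- setdiff(c("source", "target", metrics), names(pairs))
  if (length(missing)) {
    abort("pairs table lacks columns: ", paste(missing, collapse = ", "))
  }
  out <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(source = pairs$source, target = pairs$target,
               metric = m, value = pairs[[m]], bin = bins$bin,
               z = bin_zscores(pairs[[m]], bins$bin),
               flag = "none", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("ztable", "data.frame")
  out
}

#' Flag Z-score outliers (Tukey-equivalent thresholds)
#'
#' Under normality, Tukey's 1.5 * IQR fences correspond to |z| > 2.698;
#' values strictly above `high` are flagged "high", strictly below `low`
#' flagged "low". Boundary values are not flagged.
#'
#' @param z A `ztable` from [zscores_within_bins()], or any data frame with
#'   a `z` column.
#' @param high,low Flagging thresholds; defaults +/- 2.698. `high` must
#'   exceed `low`.
#' @return The input with its `flag` column set to "high"/"low"/"none".
#' @export
flag_outliers <- function(z, high = 2.698, low = -2.698) {
  stopifnot(is.data.frame(z), "z" %in% names(z))
  if (!(high > low)) abort("high threshold must exceed low threshold")
  z$flag <- ifelse(z$z > high, "high", ifelse(z$z < low, "low", "none"))
  z
}
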