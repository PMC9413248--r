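# Expression-profile module: per-protein z-scores across all injections
# and agglomerative complete-linkage clustering on Pearson distance,
# exporting heatmap-ready tables and dendrograms.

#' Row-standardize a Top3 matrix (z-scores)
#'
#' For each protein row, `z = (x - mu) / sigma` where `mu` and `sigma`
#' are the mean and sample SD (n-1 denominator) of its Top3 abundance
#' over all injections, both conditions pooled. Missing cells stay
#' missing. Rows with zero SD (or fewer than two observations) are
#' emitted as all-zero and flagged degenerate rather than erroring.
#'
#' @param x A `protein_quant_matrix` or a plain numeric matrix
#'   (proteins x runs, `NA` = missing).
#' @return A list with `z` (matrix), `degenerate` (named logical) and
#'   `sd_convention = "sample"`.
#' @export
zscore_rows <- function(x) {
  m <- if (inherits(x, "protein_quant_matrix")) x$abundance else as.matrix(x)
  mu <- rowMeans(m, na.rm = TRUE)
  sigma <- apply(m, 1L, stats::sd, na.rm = TRUE)
  n_obs <- rowSums(!is.na(m))
  degenerate <- n_obs < 2L | is.na(sigma) | sigma == 0
  z <- (m - mu) / sigma
  if (any(degenerate)) {
    z[degenerate, ] <- ifelse(is.na(m[degenerate, , drop = FALSE]), NA_real_, 0)
  }
  list(z = z,
       degenerate = stats::setNames(degenerate, rownames(m)),
       sd_convention = "sample")
}

#' Pearson distance between two profiles
#'
#' `d = 1 - r` over the mutually non-missing positions, so `d` lies in
#' `[0, 2]`: identical shapes give 0, perfectly anticorrelated shapes 2.
#'
#' @param a,b Numeric vectors of equal length with at least 3 mutually
#'   non-missing positions and nonzero variance on those positions.
#' @return Pearson distance in `[0, 2]`.
#' @export
pearson_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("fewer than 3 mutually non-missing positions")
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    stop("zero variance over shared positions")
  }
  1 - stats::cor(a[ok], b[ok])
}

pearson_distance_matrix <- function(m) {
  # pairwise-complete Pearson distances; rows that cannot be placed
  # (zero variance, or <3 shared positions with some other row) get NA
  suppressWarnings(d <- 1 - stats::cor(t(m), use = "pairwise.complete.obs"))
  n_shared <- tcrossprod(!is.na(m))
  d[n_shared < 3L] <- NA_real_
  diag(d) <- 0
  d
}

#' Complete-linkage clustering on Pearson distance
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise Pearson distance (1 - r) between their members.
#' Items that cannot be placed — zero variance, or fewer than 3
#' mutually observed positions against some other item — are excluded
#' and listed. Merge heights are non-decreasing; ties are resolved
#' deterministically by the order of the distance matrix.
#'
#' @param z Numeric matrix (items in rows when `axis = "rows"`).
#' @param axis Cluster `"rows"` or `"cols"`.
#' @return A list with `tree` (`hclust`), `order` (leaf order as labels)
#'   and `excluded` (labels left out).
#' @export
cluster_complete <- function(z, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  m <- if (axis == "cols") t(z) else z
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
  d <- pearson_distance_matrix(m)
  # greedily drop the item causing the most undefined distances until
  # the remaining distance matrix is complete
  usable <- rep(TRUE, nrow(d))
  repeat {
    na_counts <- rowSums(is.na(d[usable, usable, drop = FALSE]))
    if (sum(usable) < 2L || all(na_counts == 0L)) break
    worst <- which(usable)[which.max(na_counts)]
    usable[worst] <- FALSE
  }
  excluded <- rownames(m)[!usable]
  if (sum(usable) < 2L) stop("fewer than 2 clusterable items")
  d <- d[usable, usable]
  tree <- stats::hclust(stats::as.dist(d), method = "complete")
  list(tree = tree, order = tree$labels[tree$order], excluded = excluded)
}

#' Build the full z-score clustering profile
#'
#' Row-standardizes the matrix and clusters both proteins (rows) and
#' runs (columns) by complete linkage on Pearson distance. Degenerate
#' rows are excluded from row clustering but kept in the z matrix.
#'
#' @param pqm A `protein_quant_matrix` or numeric matrix.
#' @return A list of class `"zscore_profile"`: `z`, `row_tree`,
#'   `col_tree`, `row_order`, `col_order`, `degenerate_rows`,
#'   `excluded_rows`.
#' @export
zscore_profile <- function(pqm) {
  zs <- zscore_rows(pqm)
  z <- zs$z
  clusterable <- !zs$degenerate
  rows <- cluster_complete(z[clusterable, , drop = FALSE], axis = "rows")
  cols <- cluster_complete(z[clusterable, , drop = FALSE], axis = "cols")
  out <- list(z = z,
              row_tree = rows$tree, col_tree = cols$tree,
              row_order = rows$order, col_order = cols$order,
              degenerate_rows = names(zs$degenerate)[zs$degenerate],
              excluded_rows = union(names(zs$degenerate)[zs$degenerate],
                                    rows$excluded))
  class(out) <- "zscore_profile"
  out
}

#' @export
print.zscore_profile <- function(x, ...) {
  cat(sprintf("z-score profile: %d proteins x %d runs\n",
              nrow(x$z), ncol(x$z)))
  cat(sprintf("  clustered rows: %d (excluded: %d)\n",
              length(x$row_order), length(x$excluded_rows)))
  cat("  column order:", paste(x$col_order, collapse = ", "), "\n")
  invisible(x)
}

#' Cut a clustering into k groups
#'
#' Thin wrapper over [stats::cutree()] returning named memberships.
#'
#' @param clustering Output of [cluster_complete()] (or an `hclust`).
#' @param k Number of groups.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(clustering, k) {
  tree <- if (inherits(clustering, "hclust")) clustering else clustering$tree
  stats::cutree(tree, k = k)
}

#' Top split of a column dendrogram
#'
#' Returns the two leaf sets separated by the root of the tree — used to
#' check that the runs of the two conditions segregate.
#'
#' @param tree An `hclust`.
#' @return A list of two character vectors of leaf labels.
#' @export
top_split <- function(tree) {
  membership <- stats::cutree(tree, k = 2L)
  split(names(membership), membership)
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two partitions agree (both together
#' or both apart); 1 means identical partitions.
#'
#' @param a,b Cluster membership vectors over the same items.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  pairs <- utils::combn(length(a), 2L)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}

#' Write a z-score profile's exports
#'
#' Writes the z matrix, the row/column-ordered z matrix, the two Newick
#' dendrograms and the degenerate-row list under a directory.
#'
#' @param profile A [zscore_profile()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  z_df <- data.frame(protein_id = rownames(profile$z), profile$z,
                     check.names = FALSE, stringsAsFactors = FALSE)
  p1 <- file.path(dir, "zscores.tsv")
  data.table::fwrite(z_df, p1, sep = "\t")
  ordered <- profile$z[profile$row_order, profile$col_order, drop = FALSE]
  o_df <- data.frame(protein_id = rownames(ordered), ordered,
                     check.names = FALSE, stringsAsFactors = FALSE)
  p2 <- file.path(dir, "zscores_ordered.tsv")
  data.table::fwrite(o_df, p2, sep = "\t")
  p3 <- file.path(dir, "row_dendrogram.nwk")
  writeLines(write_newick(profile$row_tree), p3)
  p4 <- file.path(dir, "col_dendrogram.nwk")
  writeLines(write_newick(profile$col_tree), p4)
  p5 <- file.path(dir, "degenerate_rows.txt")
  writeLines(profile$excluded_rows, p5)
  invisible(c(p1, p2, p3, p4, p5))
}
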