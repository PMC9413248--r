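# Independent brute-force oracles and small fixture builders. These are
# deliberately written in a different style from the package internals
# (straight-line, no shared code paths) so they can serve as
# cross-checks.

# Build a peptide table from an explicit long specification.
toy_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(peptide = r[[1]], protein = r[[2]], unique = as.logical(r[[3]]),
               run = r[[4]], intensity = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)
  }))
}

# Build a protein_quant_matrix directly from an abundance matrix.
toy_pqm <- function(abundance, peptides_per_protein = NULL,
                    unique_per_protein = NULL) {
  ids <- rownames(abundance)
  if (is.null(peptides_per_protein)) {
    peptides_per_protein <- stats::setNames(rep(3L, length(ids)), ids)
  }
  if (is.null(unique_per_protein)) {
    unique_per_protein <- stats::setNames(rep(2L, length(ids)), ids)
  }
  structure(list(abundance = abundance,
                 used_peptides = (!is.na(abundance)) * 3L,
                 peptides_per_protein = peptides_per_protein,
                 unique_peptides_per_protein = unique_per_protein,
                 protein_ids = ids, run_ids = colnames(abundance)),
            class = "protein_quant_matrix")
}

# Independent single-pass reimplementation of the filter cascade.
oracle_cascade_class <- function(id, values_tumor, values_control,
                                 n_tumor_runs, n_control_runs,
                                 n_pep, n_uni, th) {
  if (substr(id, 1, nchar(th$decoy_prefix)) == th$decoy_prefix) {
    return("discarded_decoy")
  }
  vt <- values_tumor[!is.na(values_tumor)]
  vc <- values_control[!is.na(values_control)]
  if (length(vt) == n_tumor_runs && length(vc) == 0) return("exclusive_tumor")
  if (length(vc) == n_control_runs && length(vt) == 0) return("exclusive_control")
  need_t <- if (th$require_full_replication) n_tumor_runs else 2
  need_c <- if (th$require_full_replication) n_control_runs else 2
  if (length(vt) < need_t || length(vc) < need_c) return("filtered_out")
  if (n_pep < th$min_peptides) return("filtered_out")
  if (n_uni < th$min_unique) return("filtered_out")
  cv_t <- stats::sd(vt) / mean(vt)
  cv_c <- stats::sd(vc) / mean(vc)
  if (!(cv_t <= th$max_cv && cv_c <= th$max_cv)) return("filtered_out")
  lt <- log2(vt); lc <- log2(vc)
  if (stats::var(lt) == 0 && stats::var(lc) == 0) {
    p <- if (isTRUE(all.equal(mean(lt), mean(lc)))) 1 else 0
  } else {
    p <- stats::t.test(lt, lc, var.equal = TRUE)$p.value
  }
  l2r <- log2(mean(vt) / mean(vc))
  if (p <= th$alpha && l2r >= th$log2_cutoff) return("up_in_tumor")
  if (p <= th$alpha && l2r <= -th$log2_cutoff) return("up_in_control")
  "unchanged"
}

oracle_cascade <- function(pqm, design, th) {
  tr <- design$run_id[design$condition == "tumor"]
  cr <- design$run_id[design$condition == "control"]
  vapply(pqm$protein_ids, function(id) {
    oracle_cascade_class(id,
                         pqm$abundance[id, tr], pqm$abundance[id, cr],
                         length(tr), length(cr),
                         pqm$peptides_per_protein[[id]],
                         pqm$unique_peptides_per_protein[[id]], th)
  }, character(1))
}

# Naive agglomerative complete-linkage clustering on a distance matrix:
# returns the sorted merge heights and the partitions at every k.
oracle_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list(seq_len(n))   # k = n partition as membership vector
  membership <- seq_len(n)
  partitions <- list()
  partitions[[n]] <- membership
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
    membership <- integer(n)
    for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- membership
  }
  list(heights = heights, partitions = partitions)
}

# Hand application of the BH step-up rule.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- numeric(0)
    for (j in i:m) cands <- c(cands, p[o[j]] * m / j)
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact hypergeometric upper tail by enumerating all n-subsets of 1..N,
# the first K of which are "in the set".
oracle_hyper_tail <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# Canonical label-invariant encoding of a partition, for comparisons.
canonical_partition <- function(m) {
  as.integer(factor(m, levels = unique(m)))
}

# All permutations of 1..n as a list of index vectors.
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub + (sub >= n) * 0L, n, after = pos - 1L)
    }
  }
  out
}
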