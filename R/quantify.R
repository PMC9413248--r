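# Run normalization, Top3 (Hi-3) peptide-to-protein rollup, and the
# peptide-level QC the pipeline reports (ppm mass accuracy, dynamic range).

#' Median-log-ratio normalization of runs
#'
#' Picks a middle run as reference — the run whose run-median-centered
#' total log-intensity is the (lower) median across runs, a criterion
#' that is invariant to per-run rescaling so that normalization is
#' idempotent — then scales every other run by `exp(-median log-ratio)`
#' to the reference over the peptides observed in both runs. After
#' normalization the median log-ratio of every run to the reference is
#' zero, and renormalizing returns factors of 1.
#'
#' @param tbl Peptide measurement data.frame (columns `peptide`,
#'   `protein`, `run`, `intensity`, ...).
#' @param design Optional [study_design()]; when given, every design run
#'   must carry at least one row.
#' @return A list with `table` (the scaled measurements), `scale`
#'   (data.frame `run_id`, `scale_factor`) and `reference_run`.
#' @export
normalize_runs <- function(tbl, design = NULL) {
  stopifnot(is.data.frame(tbl), nrow(tbl) > 0L)
  runs <- sort(unique(tbl$run))
  if (!is.null(design)) {
    empty <- setdiff(design$run_id, runs)
    if (length(empty) > 0L) {
      stop("run(s) with zero measurements: ", paste(empty, collapse = ", "))
    }
    runs <- design$run_id
  }
  # reference election: primarily on run-median-centered log totals
  # (invariant to per-run rescaling, so renormalizing elects the same
  # run); exact scalar-multiple ties fall back to raw totals, then to
  # run order
  centered <- numeric(length(runs))
  raw_totals <- numeric(length(runs))
  for (i in seq_along(runs)) {
    l <- log(tbl$intensity[tbl$run == runs[i]])
    centered[i] <- sum(l - stats::median(l))
    raw_totals[i] <- sum(l)
  }
  tol <- 1e-9 * max(1, max(abs(centered)))
  ord <- order(round(centered / tol), raw_totals, seq_along(runs))
  reference <- runs[ord[floor((length(runs) + 1) / 2)]]

  key <- paste(tbl$peptide, tbl$protein, sep = "\r")
  ref_rows <- tbl$run == reference
  ref_int <- stats::setNames(tbl$intensity[ref_rows], key[ref_rows])

  scale_factor <- vapply(runs, function(r) {
    if (r == reference) return(1)
    rows <- tbl$run == r
    shared <- key[rows] %in% names(ref_int)
    if (!any(shared)) {
      warning("run ", r, " shares no peptides with the reference; factor 1")
      return(1)
    }
    lr <- log(tbl$intensity[rows][shared]) - log(ref_int[key[rows][shared]])
    exp(-stats::median(lr))
  }, numeric(1))

  out <- tbl
  out$intensity <- out$intensity * scale_factor[match(out$run, runs)]
  list(table = out,
       scale = data.frame(run_id = runs, scale_factor = unname(scale_factor),
                          stringsAsFactors = FALSE),
       reference_run = reference)
}

#' Roll peptide intensities up to Top3 protein abundances
#'
#' Per protein and run, the Top3 abundance is the arithmetic mean of the
#' three largest peptide intensities; when only one or two peptides are
#' measured, the mean of those is used and the count is recorded.
#' Intensity ties are broken lexicographically by peptide sequence, so
#' the rollup is deterministic.
#'
#' @param tbl Peptide measurement data.frame.
#' @param design Optional [study_design()] fixing the run (column) order.
#' @return A list of class `"protein_quant_matrix"`: `abundance`
#'   (proteins x runs matrix, `NA` = protein unobserved in that run),
#'   `used_peptides` (matching matrix of counts in 1..3),
#'   `peptides_per_protein` and `unique_peptides_per_protein` (named
#'   integer vectors over the whole table), `protein_ids`, `run_ids`.
#' @export
rollup_top3 <- function(tbl, design = NULL) {
  if (!is.data.frame(tbl) || nrow(tbl) == 0L) {
    stop("empty measurement collection")
  }
  dt <- data.table::as.data.table(tbl)
  data.table::setorder(dt, protein, run, -intensity, peptide)
  agg <- dt[, {
    top <- intensity[seq_len(min(3L, .N))]
    list(top3 = mean(top), used = length(top))
  }, by = list(protein, run)]

  protein_ids <- sort(unique(dt$protein))
  run_ids <- if (!is.null(design)) design$run_id else sort(unique(dt$run))
  abundance <- matrix(NA_real_, length(protein_ids), length(run_ids),
                      dimnames = list(protein_ids, run_ids))
  used <- matrix(NA_integer_, length(protein_ids), length(run_ids),
                 dimnames = list(protein_ids, run_ids))
  abundance[cbind(agg$protein, agg$run)] <- agg$top3
  used[cbind(agg$protein, agg$run)] <- agg$used

  per_prot <- dt[, list(n_pep = data.table::uniqueN(peptide),
                        n_unique = data.table::uniqueN(peptide[unique == TRUE])),
                 by = protein]
  peptides_per_protein <- stats::setNames(rep(0L, length(protein_ids)), protein_ids)
  unique_per_protein <- peptides_per_protein
  peptides_per_protein[per_prot$protein] <- per_prot$n_pep
  unique_per_protein[per_prot$protein] <- per_prot$n_unique

  out <- list(abundance = abundance, used_peptides = used,
              peptides_per_protein = peptides_per_protein,
              unique_peptides_per_protein = unique_per_protein,
              protein_ids = protein_ids, run_ids = run_ids)
  class(out) <- "protein_quant_matrix"
  out
}

#' @export
print.protein_quant_matrix <- function(x, ...) {
  cat(sprintf("Top3 protein quantification matrix: %d proteins x %d runs\n",
              nrow(x$abundance), ncol(x$abundance)))
  cat(sprintf("  missing cells: %.1f%%; mean peptides/protein: %.1f\n",
              100 * mean(is.na(x$abundance)), mean(x$peptides_per_protein)))
  invisible(x)
}

#' Peptide mass-accuracy QC
#'
#' Computes the ppm error `1e6 * (observed - theoretical) / theoretical`
#' for every row carrying the mass pair and reports the fraction within
#' the tolerance (boundary inclusive) plus a 1-ppm-bin histogram.
#'
#' @param tbl Peptide measurement data.frame.
#' @param tolerance_ppm Tolerance in ppm (default 10).
#' @return A list of class `"mass_qc"`: `available`, `n_rows`,
#'   `fraction_within`, `tolerance_ppm`, `histogram` (data.frame of bin
#'   mid-points and counts).
#' @export
mass_accuracy_qc <- function(tbl, tolerance_ppm = 10) {
  has_mass <- all(c("mz_theoretical", "mz_observed") %in% names(tbl))
  if (has_mass) {
    ok <- !is.na(tbl$mz_theoretical) & !is.na(tbl$mz_observed)
    tbl <- tbl[ok, ]
  }
  if (!has_mass || nrow(tbl) == 0L) {
    out <- list(available = FALSE, n_rows = 0L, fraction_within = NA_real_,
                tolerance_ppm = tolerance_ppm, histogram = NULL)
    class(out) <- "mass_qc"
    return(out)
  }
  ppm <- 1e6 * (tbl$mz_observed - tbl$mz_theoretical) / tbl$mz_theoretical
  breaks <- seq(floor(min(ppm)) - 0.5, ceiling(max(ppm)) + 0.5, by = 1)
  counts <- table(cut(ppm, breaks))
  hist_df <- data.frame(ppm_bin_mid = breaks[-length(breaks)] + 0.5,
                        count = as.integer(counts))
  out <- list(available = TRUE, n_rows = length(ppm),
              fraction_within = mean(abs(ppm) <= tolerance_ppm),
              tolerance_ppm = tolerance_ppm,
              histogram = hist_df[hist_df$count > 0L, ])
  class(out) <- "mass_qc"
  out
}

#' @export
print.mass_qc <- function(x, ...) {
  if (!x$available) {
    cat("Mass-accuracy QC unavailable (no rows carry mass fields)\n")
    return(invisible(x))
  }
  cat(sprintf("Mass-accuracy QC: %.2f%% of %d peptide-run rows within +/-%g ppm\n",
              100 * x$fraction_within, x$n_rows, x$tolerance_ppm))
  invisible(x)
}

#' Dynamic range of Top3 abundances
#'
#' `log10(max Top3 / min Top3)` over the non-missing cells of the
#' requested scope.
#'
#' @param pqm A [rollup_top3()] matrix.
#' @param scope `"global"` (all cells), `"run"` (one run) or
#'   `"condition"` (all runs of one condition).
#' @param run,condition Selector for the non-global scopes.
#' @param design [study_design()], required for `scope = "condition"`.
#' @return Dynamic range in orders of magnitude (log10 units).
#' @export
dynamic_range <- function(pqm, scope = c("global", "run", "condition"),
                          run = NULL, condition = NULL, design = NULL) {
  scope <- match.arg(scope)
  cells <- switch(scope,
    global = pqm$abundance,
    run = {
      if (is.null(run) || !run %in% pqm$run_ids) stop("unknown run: ", run)
      pqm$abundance[, run]
    },
    condition = {
      if (is.null(design) || is.null(condition)) {
        stop("condition scope needs 'design' and 'condition'")
      }
      pqm$abundance[, runs_of(design, condition), drop = FALSE]
    })
  cells <- cells[!is.na(cells)]
  if (length(cells) < 2L) stop("fewer than 2 non-missing cells in scope")
  log10(max(cells) / min(cells))
}
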