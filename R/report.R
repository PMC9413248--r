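# End-of-run reporting: class-count summary with the partition
# invariant enforced, and the ligand-conjugation mass-balance worked
# example (transferrin bound to a functionalized core-shell
# nanoparticle, quantified by difference from the supernatant).

#' Ligand binding yield by mass difference
#'
#' The binding assay starts from a known ligand mass; after magnetic
#' separation of the nanoparticle-ligand complex, the unbound ligand is
#' quantified in the supernatant and the bound mass is the difference:
#' `bound = initial - supernatant`, with
#' `binding_fraction = bound / initial`.
#'
#' @param initial_ug Ligand mass put into the assay (micrograms).
#' @param supernatant_ug Unbound ligand recovered in the supernatant
#'   (micrograms); must not exceed `initial_ug`.
#' @return A list of class `"conjugation_account"`: `initial_ug`,
#'   `supernatant_ug`, `bound_ug`, `binding_fraction`. Values are kept
#'   at full precision; printing rounds to 2 decimals.
#' @examples
#' binding_yield(15, 10.34)   # 4.66 ug bound
#' @export
binding_yield <- function(initial_ug, supernatant_ug) {
  if (initial_ug <= 0) stop("initial mass must be positive")
  if (supernatant_ug < 0) stop("supernatant mass cannot be negative")
  if (supernatant_ug > initial_ug) {
    stop("impossible mass balance: supernatant (", supernatant_ug,
         " ug) exceeds initial mass (", initial_ug, " ug)")
  }
  bound <- initial_ug - supernatant_ug
  out <- list(initial_ug = initial_ug,
              supernatant_ug = supernatant_ug,
              bound_ug = bound,
              binding_fraction = bound / initial_ug)
  class(out) <- "conjugation_account"
  out
}

#' @export
print.conjugation_account <- function(x, ...) {
  cat(sprintf("Ligand binding yield: %.2f ug bound of %.2f ug initial (%.1f%%); %.2f ug in supernatant\n",
              x$bound_ug, x$initial_ug, 100 * x$binding_fraction,
              x$supernatant_ug))
  invisible(x)
}

PIPELINE_CLASSES <- c("up_in_tumor", "up_in_control", "unchanged",
                      "exclusive_tumor", "exclusive_control",
                      "discarded_decoy", "filtered_out")

#' Summarize a pipeline run
#'
#' Counts the differential classes (which must partition the quantified
#' proteins — a mismatch is an internal-consistency error) and rolls up
#' the QC figures.
#'
#' @param records Records from [apply_filter_cascade()].
#' @param qc Optional [mass_accuracy_qc()] result.
#' @param pqm Optional `protein_quant_matrix` (adds the dynamic range
#'   and cross-checks the partition size).
#' @param n_peptide_rows Optional count of peptide-table rows.
#' @return A list of class `"pipeline_summary"` with the class counts,
#'   `n_proteins_quantified`, `dynamic_range_orders` and
#'   `ppm_within_tolerance_fraction`.
#' @export
summarize_pipeline <- function(records, qc = NULL, pqm = NULL,
                               n_peptide_rows = NA_integer_) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("empty record set")
  }
  bad <- setdiff(unique(records$class), PIPELINE_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  counts <- vapply(PIPELINE_CLASSES, function(cl) sum(records$class == cl),
                   integer(1))
  if (sum(counts) != nrow(records)) {
    stop("internal consistency error: class counts (", sum(counts),
         ") do not partition the record set (", nrow(records), ")")
  }
  if (!is.null(pqm) && nrow(records) != length(pqm$protein_ids)) {
    stop("internal consistency error: ", nrow(records),
         " records for ", length(pqm$protein_ids), " quantified proteins")
  }
  out <- list(
    n_peptide_rows = n_peptide_rows,
    n_proteins_quantified = nrow(records),
    class_counts = counts,
    n_up_tumor = counts[["up_in_tumor"]],
    n_up_control = counts[["up_in_control"]],
    n_unchanged = counts[["unchanged"]],
    n_exclusive_tumor = counts[["exclusive_tumor"]],
    n_exclusive_control = counts[["exclusive_control"]],
    n_decoys_discarded = counts[["discarded_decoy"]],
    n_filtered_out = counts[["filtered_out"]],
    dynamic_range_orders = if (!is.null(pqm)) dynamic_range(pqm) else NA_real_,
    ppm_within_tolerance_fraction =
      if (!is.null(qc) && isTRUE(qc$available)) qc$fraction_within else NA_real_
  )
  class(out) <- "pipeline_summary"
  out
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("Pipeline summary\n")
  if (!is.na(x$n_peptide_rows)) {
    cat(sprintf("  peptide-run rows: %d\n", x$n_peptide_rows))
  }
  cat(sprintf("  proteins quantified: %d\n", x$n_proteins_quantified))
  cat(sprintf("  up in tumor: %d; up in control: %d; unchanged: %d\n",
              x$n_up_tumor, x$n_up_control, x$n_unchanged))
  cat(sprintf("  exclusive (tumor/control): %d / %d\n",
              x$n_exclusive_tumor, x$n_exclusive_control))
  cat(sprintf("  decoys discarded: %d; filtered out: %d\n",
              x$n_decoys_discarded, x$n_filtered_out))
  if (!is.na(x$dynamic_range_orders)) {
    cat(sprintf("  dynamic range: %.2f orders of magnitude\n",
                x$dynamic_range_orders))
  }
  if (!is.na(x$ppm_within_tolerance_fraction)) {
    cat(sprintf("  peptide rows within mass tolerance: %.2f%%\n",
                100 * x$ppm_within_tolerance_fraction))
  }
  invisible(x)
}

#' Run the full simulation-to-summary pipeline
#'
#' Chains truth generation, peptide-table simulation, normalization,
#' Top3 rollup, the filter cascade, exclusive calls, QC and the summary;
#' optionally the z-score clustering profile.
#'
#' @param params [sim_params()].
#' @param design [study_design()] (default [design_two_by_three()]).
#' @param thresholds [filter_thresholds()].
#' @param profile Also compute the z-score clustering profile
#'   (default FALSE; it is the slowest stage on large matrices).
#' @return A list with `truth`, `table`, `normalization`, `pqm`,
#'   `records`, `qc`, `summary` and (optionally) `profile`.
#' @export
run_pipeline <- function(params = sim_params(),
                         design = design_two_by_three(),
                         thresholds = filter_thresholds(),
                         profile = FALSE) {
  truth <- generate_truth(params)
  tbl <- simulate_peptide_table(truth, design, params)
  norm <- normalize_runs(tbl, design)
  pqm <- rollup_top3(norm$table, design)
  records <- apply_filter_cascade(pqm, design, thresholds)
  qc <- mass_accuracy_qc(tbl)
  summary <- summarize_pipeline(records, qc, pqm, n_peptide_rows = nrow(tbl))
  out <- list(truth = truth, table = tbl, normalization = norm, pqm = pqm,
              records = records, qc = qc, summary = summary)
  if (profile) out$profile <- zscore_profile(pqm)
  out
}
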