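#' Construct and validate a study design
#'
#' A study design lists the MS injections (runs) of a two-condition
#' label-free experiment: a tumor-like line versus a control-like line,
#' each measured in replicate injections.
#'
#' @param runs A data.frame with columns `run_id` (character, unique),
#'   `condition` (`"tumor"` or `"control"`) and `replicate`
#'   (positive integer within condition).
#' @return The validated data.frame with class `"study_design"`.
#' @examples
#' design_two_by_three()
#' @export
study_design <- function(runs) {
  stopifnot(is.data.frame(runs))
  needed <- c("run_id", "condition", "replicate")
  missing_cols <- setdiff(needed, names(runs))
  if (length(missing_cols) > 0L) {
    stop("study design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  runs <- as.data.frame(runs)[, needed]
  runs$run_id <- as.character(runs$run_id)
  runs$condition <- as.character(runs$condition)
  if (anyDuplicated(runs$run_id)) {
    stop("run_ids must be unique; duplicated: ",
         paste(unique(runs$run_id[duplicated(runs$run_id)]), collapse = ", "))
  }
  if (!setequal(unique(runs$condition), c("tumor", "control"))) {
    stop("design must contain exactly the two conditions 'tumor' and 'control'")
  }
  if (!is.numeric(runs$replicate) || any(runs$replicate < 1) ||
      any(runs$replicate != round(runs$replicate))) {
    stop("replicate must be a positive integer")
  }
  n_rep <- table(runs$condition)
  if (any(n_rep < 2L)) {
    stop("every condition needs at least 2 replicate runs")
  }
  runs$replicate <- as.integer(runs$replicate)
  class(runs) <- c("study_design", "data.frame")
  runs
}

#' Default 2 x 3 study design
#'
#' Two conditions (tumor, control) with three replicate injections each,
#' matching the full-replication ("3/3") design the filter cascade assumes.
#'
#' @param n_replicates Replicates per condition (default 3).
#' @return A `study_design`.
#' @export
design_two_by_three <- function(n_replicates = 3L) {
  n_replicates <- as.integer(n_replicates)
  study_design(data.frame(
    run_id = c(paste0("tumor_", seq_len(n_replicates)),
               paste0("control_", seq_len(n_replicates))),
    condition = rep(c("tumor", "control"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2L),
    stringsAsFactors = FALSE
  ))
}

#' Swap the condition labels of a design
#'
#' Utility for symmetry checks: relabels tumor runs as control and vice
#' versa, keeping run ids and replicate numbers.
#'
#' @param design A `study_design`.
#' @return A `study_design` with conditions swapped.
#' @export
swap_conditions <- function(design) {
  design <- as.data.frame(design)
  design$condition <- ifelse(design$condition == "tumor", "control", "tumor")
  study_design(design)
}

runs_of <- function(design, condition) {
  design$run_id[design$condition == condition]
}
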