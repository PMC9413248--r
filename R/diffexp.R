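# Differential-abundance filter cascade: reversed-decoy removal,
# replication, peptide-count, unique-peptide and CV filters, one-way
# ANOVA, and volcano fold-change classification. Exclusive proteins
# (all replicates of one condition, none of the other) are called
# separately from the tested set.

FILTER_ORDER <- c("decoy", "replication", "peptide_count", "unique_peptide",
                  "cv", "anova", "fold_change")

#' Filter thresholds of the differential-abundance cascade
#'
#' @param max_cv Maximum coefficient of variation per condition
#'   (default 0.30).
#' @param min_peptides Minimum peptides per protein (default 2).
#' @param min_unique Minimum unique peptides per protein (default 1).
#' @param require_full_replication If `TRUE` (default) a tested protein
#'   must be quantified in every replicate of both conditions ("3/3");
#'   with `FALSE`, two replicates per condition suffice.
#' @param alpha ANOVA significance level (default 0.05).
#' @param log2_cutoff Volcano |log2 fold-change| cutoff (default 1.2).
#' @param decoy_prefix Protein-id prefix marking reversed decoys
#'   (default `"REV_"`).
#' @return A validated list of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(max_cv = 0.30, min_peptides = 2L,
                              min_unique = 1L,
                              require_full_replication = TRUE,
                              alpha = 0.05, log2_cutoff = 1.2,
                              decoy_prefix = "REV_") {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (max_cv <= 0) stop("max_cv must be > 0")
  if (log2_cutoff < 0) stop("log2_cutoff must be >= 0")
  if (min_peptides < 1L) stop("min_peptides must be >= 1")
  if (min_unique < 0L) stop("min_unique must be >= 0")
  out <- list(max_cv = max_cv, min_peptides = as.integer(min_peptides),
              min_unique = as.integer(min_unique),
              require_full_replication = isTRUE(require_full_replication),
              alpha = alpha, log2_cutoff = log2_cutoff,
              decoy_prefix = decoy_prefix)
  class(out) <- "filter_thresholds"
  out
}

#' Per-protein, per-condition replicate statistics
#'
#' Mean, sample SD (n-1 denominator) and CV = SD/mean of the linear-scale
#' Top3 abundances over the non-missing replicates of each condition,
#' plus the count of replicates observed.
#'
#' @param pqm A [rollup_top3()] matrix.
#' @param design A [study_design()].
#' @return A data.frame with one row per protein: `protein_id`,
#'   `mean_tumor`, `sd_tumor`, `cv_tumor`, `n_tumor` and the control
#'   counterparts.
#' @export
compute_condition_stats <- function(pqm, design) {
  design <- if (inherits(design, "study_design")) design else study_design(design)
  stat_block <- function(cond) {
    sub <- pqm$abundance[, runs_of(design, cond), drop = FALSE]
    n <- rowSums(!is.na(sub))
    mean_ <- rowMeans(sub, na.rm = TRUE)
    mean_[n == 0L] <- NA_real_
    sd_ <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    sd_[n < 2L] <- NA_real_
    data.frame(mean = mean_, sd = sd_, cv = sd_ / mean_, n = n)
  }
  t_ <- stat_block("tumor")
  c_ <- stat_block("control")
  data.frame(protein_id = pqm$protein_ids,
             mean_tumor = t_$mean, sd_tumor = t_$sd, cv_tumor = t_$cv,
             n_tumor = t_$n,
             mean_control = c_$mean, sd_control = c_$sd, cv_control = c_$cv,
             n_control = c_$n,
             row.names = NULL, stringsAsFactors = FALSE)
}

# One-way fixed-effects ANOVA p for a two-group split of log2 abundances.
# Degenerate zero-within-variance cases are resolved deterministically:
# identical constant groups -> p = 1; separated constants -> p = 0.
anova_p_two_groups <- function(x, g) {
  groups <- split(x, g)
  within_var <- vapply(groups, function(v) stats::var(v), numeric(1))
  if (all(within_var == 0)) {
    means <- vapply(groups, mean, numeric(1))
    return(if (isTRUE(all.equal(means[[1]], means[[2]]))) 1 else 0)
  }
  stats::oneway.test(x ~ g, var.equal = TRUE)$p.value
}

#' Per-protein one-way ANOVA on log2 Top3 abundances
#'
#' Fixed-effects one-way ANOVA of the two condition groups on
#' log2-transformed Top3 values (with two groups, F equals the squared
#' pooled-variance t statistic). Proteins observed in fewer than two
#' replicates of either condition get `NA` (they fail the replication
#' filter instead of being tested).
#'
#' @param pqm A [rollup_top3()] matrix.
#' @param design A [study_design()].
#' @return Named numeric vector of p-values (NA where untestable).
#' @export
anova_per_protein <- function(pqm, design) {
  design <- if (inherits(design, "study_design")) design else study_design(design)
  tumor_runs <- runs_of(design, "tumor")
  control_runs <- runs_of(design, "control")
  vapply(pqm$protein_ids, function(p) {
    tv <- pqm$abundance[p, tumor_runs]
    cv <- pqm$abundance[p, control_runs]
    tv <- tv[!is.na(tv)]
    cv <- cv[!is.na(cv)]
    if (length(tv) < 2L || length(cv) < 2L) return(NA_real_)
    x <- log2(c(tv, cv))
    g <- factor(rep(c("tumor", "control"), c(length(tv), length(cv))))
    anova_p_two_groups(x, g)
  }, numeric(1))
}

trail_string <- function(stages, status) {
  paste(paste0(stages, "=", status), collapse = "|")
}

#' Apply the differential-abundance filter cascade
#'
#' Filters are applied in a fixed order: decoy, replication, peptide
#' count, unique peptide, CV, ANOVA, fold change. Decoys are discarded
#' regardless of other filters. The replication filter demands full
#' replication in both conditions for tested proteins; the all-vs-none
#' presence pattern is routed to the exclusive call instead. Proteins
#' failing an eliminating stage (replication through CV) are
#' `filtered_out`; survivors are classified by the joint ANOVA p /
#' fold-change volcano rule as `up_in_tumor`, `up_in_control` or
#' `unchanged`. Every protein's record carries the filter trail up to
#' its first failure.
#'
#' @param pqm A [rollup_top3()] matrix.
#' @param design A [study_design()].
#' @param thresholds A [filter_thresholds()] object.
#' @return A data.frame of differential records: per-condition stats,
#'   `ratio` (tumor/control), `log2_ratio`, `p_value`, `filter_trail`,
#'   `class`.
#' @export
apply_filter_cascade <- function(pqm, design, thresholds = filter_thresholds()) {
  if (!inherits(thresholds, "filter_thresholds")) {
    stop("thresholds must be a filter_thresholds() object")
  }
  design <- if (inherits(design, "study_design")) design else study_design(design)
  stats_df <- compute_condition_stats(pqm, design)
  p_values <- anova_per_protein(pqm, design)
  n_tumor_runs <- length(runs_of(design, "tumor"))
  n_control_runs <- length(runs_of(design, "control"))
  min_rep_t <- if (thresholds$require_full_replication) n_tumor_runs else 2L
  min_rep_c <- if (thresholds$require_full_replication) n_control_runs else 2L

  records <- stats_df
  records$ratio <- NA_real_
  records$log2_ratio <- NA_real_
  records$p_value <- NA_real_
  records$filter_trail <- NA_character_
  records$class <- NA_character_

  for (i in seq_len(nrow(records))) {
    id <- records$protein_id[i]
    trail <- character(0)

    if (startsWith(id, thresholds$decoy_prefix)) {
      records$filter_trail[i] <- trail_string("decoy", "fail")
      records$class[i] <- "discarded_decoy"
      next
    }
    trail <- c(trail, "decoy=pass")

    nt <- records$n_tumor[i]; nc <- records$n_control[i]
    if ((nt == n_tumor_runs && nc == 0L) || (nc == n_control_runs && nt == 0L)) {
      records$filter_trail[i] <- paste(c(trail, "replication=exclusive"),
                                       collapse = "|")
      records$class[i] <- if (nt > 0L) "exclusive_tumor" else "exclusive_control"
      next
    }
    if (nt < min_rep_t || nc < min_rep_c) {
      records$filter_trail[i] <- paste(c(trail, "replication=fail"), collapse = "|")
      records$class[i] <- "filtered_out"
      next
    }
    trail <- c(trail, "replication=pass")

    if (pqm$peptides_per_protein[id] < thresholds$min_peptides) {
      records$filter_trail[i] <- paste(c(trail, "peptide_count=fail"), collapse = "|")
      records$class[i] <- "filtered_out"
      next
    }
    trail <- c(trail, "peptide_count=pass")

    if (pqm$unique_peptides_per_protein[id] < thresholds$min_unique) {
      records$filter_trail[i] <- paste(c(trail, "unique_peptide=fail"), collapse = "|")
      records$class[i] <- "filtered_out"
      next
    }
    trail <- c(trail, "unique_peptide=pass")

    if (!(records$cv_tumor[i] <= thresholds$max_cv &&
          records$cv_control[i] <= thresholds$max_cv)) {
      records$filter_trail[i] <- paste(c(trail, "cv=fail"), collapse = "|")
      records$class[i] <- "filtered_out"
      next
    }
    trail <- c(trail, "cv=pass")

    records$ratio[i] <- records$mean_tumor[i] / records$mean_control[i]
    records$log2_ratio[i] <- log2(records$ratio[i])
    records$p_value[i] <- p_values[[id]]
    anova_pass <- records$p_value[i] <= thresholds$alpha
    fc_pass <- abs(records$log2_ratio[i]) >= thresholds$log2_cutoff
    trail <- c(trail,
               paste0("anova=", if (anova_pass) "pass" else "fail"),
               paste0("fold_change=", if (fc_pass) "pass" else "fail"))
    records$filter_trail[i] <- paste(trail, collapse = "|")
    records$class[i] <- volcano_class(records$log2_ratio[i], records$p_value[i],
                                      thresholds)
  }
  records
}

volcano_class <- function(log2_ratio, p, thresholds) {
  if (is.na(log2_ratio) || is.na(p)) return("unchanged")
  if (p <= thresholds$alpha && log2_ratio >= thresholds$log2_cutoff) {
    "up_in_tumor"
  } else if (p <= thresholds$alpha && log2_ratio <= -thresholds$log2_cutoff) {
    "up_in_control"
  } else {
    "unchanged"
  }
}

#' Volcano classification of cascade survivors
#'
#' Joint thresholding, boundaries inclusive: `up_in_tumor` iff
#' `log2_ratio >= log2_cutoff` and `p <= alpha`; `up_in_control` iff
#' `log2_ratio <= -log2_cutoff` and `p <= alpha`; otherwise
#' `unchanged`. Non-survivor classes (decoys, exclusives, filtered_out)
#' are left untouched, so the classification can be re-run with new
#' cutoffs on an existing record set.
#'
#' @param records Records from [apply_filter_cascade()].
#' @param thresholds A [filter_thresholds()] object.
#' @return The records with the `class` column reassigned for survivors.
#' @export
classify_volcano <- function(records, thresholds = filter_thresholds()) {
  survivor <- records$class %in% c("up_in_tumor", "up_in_control", "unchanged")
  records$class[survivor] <- vapply(which(survivor), function(i) {
    volcano_class(records$log2_ratio[i], records$p_value[i], thresholds)
  }, character(1))
  records
}

#' Call condition-exclusive proteins
#'
#' A non-decoy protein is exclusive to a condition iff it is quantified
#' in every replicate of that condition and in none of the other;
#' partial presence patterns are not exclusive.
#'
#' @param pqm A [rollup_top3()] matrix.
#' @param design A [study_design()].
#' @param decoy_prefix Decoy id prefix excluded from the call.
#' @return A data.frame `protein_id`, `class` restricted to
#'   `exclusive_tumor` / `exclusive_control` proteins.
#' @export
call_exclusive <- function(pqm, design, decoy_prefix = "REV_") {
  design <- if (inherits(design, "study_design")) design else study_design(design)
  tumor_runs <- runs_of(design, "tumor")
  control_runs <- runs_of(design, "control")
  nt <- rowSums(!is.na(pqm$abundance[, tumor_runs, drop = FALSE]))
  nc <- rowSums(!is.na(pqm$abundance[, control_runs, drop = FALSE]))
  decoy <- startsWith(pqm$protein_ids, decoy_prefix)
  excl_t <- !decoy & nt == length(tumor_runs) & nc == 0L
  excl_c <- !decoy & nc == length(control_runs) & nt == 0L
  data.frame(
    protein_id = pqm$protein_ids[excl_t | excl_c],
    class = ifelse(excl_t[excl_t | excl_c], "exclusive_tumor",
                   "exclusive_control"),
    stringsAsFactors = FALSE
  )
}

#' Volcano-plot data table
#'
#' @param records Records from [apply_filter_cascade()].
#' @return Data.frame `protein_id`, `log2_ratio`, `neg_log10_p`, `class`
#'   for records carrying a test result.
#' @export
volcano_table <- function(records) {
  keep <- !is.na(records$log2_ratio) & !is.na(records$p_value)
  data.frame(protein_id = records$protein_id[keep],
             log2_ratio = records$log2_ratio[keep],
             neg_log10_p = -log10(pmax(records$p_value[keep], 1e-300)),
             class = records$class[keep],
             stringsAsFactors = FALSE)
}
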