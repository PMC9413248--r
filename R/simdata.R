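# Synthetic DIA-style peptide-table generator with a ground-truth ledger.
# The defaults emulate the reported structure of the membrane-proteome
# dataset the pipeline was designed around: ~1300 quantifiable proteins,
# ~9 peptides per protein, ~6.5 orders of magnitude of abundance, mass
# errors with ~87% of rows within +/-10 ppm, a small fraction of
# condition-exclusive proteins and reversed decoys, and
# intensity-dependent missing values.

# Monoisotopic residue masses (Da); water added per peptide.
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.WATER_MASS <- 18.010565

#' Simulation parameters for the synthetic peptide-table generator
#'
#' @param n_proteins Number of proteins in the catalogue (default 1300,
#'   the order of the shared quantifiable proteome the defaults emulate).
#' @param mean_peptides_per_protein Mean peptides per protein (default 9);
#'   counts are drawn as 1 + Poisson(mean - 1) so every protein has at
#'   least one peptide.
#' @param abundance_span_orders Width of the log-uniform base-abundance
#'   distribution in log10 units (default 6.5).
#' @param min_abundance Lower edge of the base-abundance range, arbitrary
#'   MS intensity units (default 100).
#' @param frac_diff Proportion of proteins given a nonzero true log2
#'   fold change (default 0.15).
#' @param log2_effect_mean,log2_effect_sd Normal distribution of the
#'   spiked log2 effects (defaults 0 and 2: symmetric up/down effects,
#'   many beyond the 1.2 volcano cutoff).
#' @param frac_exclusive_per_condition Proportion of proteins observed
#'   only in one condition, per condition (default 0.025, i.e. about
#'   30+ exclusives per side at the default catalogue size).
#' @param frac_decoy Proportion of reversed-decoy proteins (default 0.05).
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   replicate noise on linear-scale intensities (default 0.15).
#' @param dropout_midpoint Intensity at which the logistic dropout curve
#'   gives 50% detection probability; `NULL` disables dropout
#'   (default 10^2.8).
#' @param dropout_steepness Logistic steepness per log10 intensity unit
#'   (default 1.5).
#' @param ppm_error_sd SD of the normal mass error in ppm (default 6.6,
#'   which puts the expected within-+/-10-ppm fraction at
#'   2*pnorm(10/6.6) - 1, about 0.870).
#' @param frac_shared_peptides Fraction of peptides additionally assigned
#'   to a second protein and therefore flagged non-unique (default 0.05).
#' @param ionization_sdlog Log-scale SD of per-peptide ionization factors
#'   before the per-protein Top3 rescaling (default 0.3).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `"sim_params"`.
#' @export
sim_params <- function(n_proteins = 1300L,
                       mean_peptides_per_protein = 9,
                       abundance_span_orders = 6.5,
                       min_abundance = 100,
                       frac_diff = 0.15,
                       log2_effect_mean = 0,
                       log2_effect_sd = 2,
                       frac_exclusive_per_condition = 0.025,
                       frac_decoy = 0.05,
                       replicate_cv = 0.15,
                       dropout_midpoint = 10^2.8,
                       dropout_steepness = 1.5,
                       ppm_error_sd = 6.6,
                       frac_shared_peptides = 0.05,
                       ionization_sdlog = 0.3,
                       seed = 1L) {
  p <- list(
    n_proteins = as.integer(n_proteins),
    mean_peptides_per_protein = mean_peptides_per_protein,
    abundance_span_orders = abundance_span_orders,
    min_abundance = min_abundance,
    frac_diff = frac_diff,
    log2_effect_mean = log2_effect_mean,
    log2_effect_sd = log2_effect_sd,
    frac_exclusive_per_condition = frac_exclusive_per_condition,
    frac_decoy = frac_decoy,
    replicate_cv = replicate_cv,
    dropout_midpoint = dropout_midpoint,
    dropout_steepness = dropout_steepness,
    ppm_error_sd = ppm_error_sd,
    frac_shared_peptides = frac_shared_peptides,
    ionization_sdlog = ionization_sdlog,
    seed = as.integer(seed)
  )
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  if (p$n_proteins < 1L) stop("n_proteins must be a positive integer")
  if (p$mean_peptides_per_protein < 1) {
    stop("mean_peptides_per_protein must be >= 1")
  }
  if (p$abundance_span_orders <= 0) stop("abundance_span_orders must be > 0")
  if (p$min_abundance <= 0) stop("min_abundance must be > 0")
  props <- c(frac_diff = p$frac_diff,
             frac_exclusive_per_condition = p$frac_exclusive_per_condition,
             frac_decoy = p$frac_decoy,
             frac_shared_peptides = p$frac_shared_peptides)
  bad <- names(props)[props < 0 | props > 1]
  if (length(bad) > 0L) {
    stop("proportion(s) outside [0, 1]: ", paste(bad, collapse = ", "))
  }
  budget <- p$frac_diff + 2 * p$frac_exclusive_per_condition + p$frac_decoy
  if (budget > 1) {
    stop("frac_diff + 2*frac_exclusive_per_condition + frac_decoy must be <= 1 ",
         "(got ", format(budget), ")")
  }
  if (p$replicate_cv < 0) stop("replicate_cv must be >= 0")
  if (p$ppm_error_sd < 0) stop("ppm_error_sd must be >= 0")
  if (p$log2_effect_sd < 0) stop("log2_effect_sd must be >= 0")
  if (!is.null(p$dropout_midpoint)) {
    if (p$dropout_midpoint <= 0) stop("dropout_midpoint must be > 0 or NULL")
    if (p$dropout_steepness <= 0) stop("dropout_steepness must be > 0")
  }
  invisible(p)
}

random_tryptic_peptides <- function(n) {
  # Tryptic-like: 7-20 residues, K/R-terminated, no internal K/R.
  lens <- sample(7:20, n, replace = TRUE)
  internal <- setdiff(names(.RESIDUE_MASS), c("K", "R"))
  seqs <- vapply(lens, function(L) {
    paste0(paste(sample(internal, L - 1L, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
  # collisions are rare at these lengths; regenerate any duplicates
  while (anyDuplicated(seqs)) {
    idx <- which(duplicated(seqs))
    seqs[idx] <- vapply(lens[idx], function(L) {
      paste0(paste(sample(internal, L - 1L, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L))
    }, character(1))
  }
  seqs
}

peptide_monoisotopic_mass <- function(sequences) {
  vapply(strsplit(sequences, ""), function(aa) {
    sum(.RESIDUE_MASS[aa]) + .WATER_MASS
  }, numeric(1))
}

#' Generate the ground-truth ledger of a synthetic proteome
#'
#' Draws protein base abundances log-uniformly over the configured span,
#' assigns differential / condition-exclusive / decoy labels with
#' deterministic rounding of the configured proportions, and builds a
#' peptide catalogue (tryptic-like sequences, ionization factors,
#' monoisotopic masses, uniqueness flags). Ionization factors are
#' rescaled per protein so that the ideal noise-free Top3 abundance
#' equals `base_abundance`, which makes the ledger directly comparable
#' to the quantified matrix.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `"synthetic_truth"` with elements `proteins`
#'   (protein_id, base_abundance, true_log2fc, is_decoy, exclusivity)
#'   and `peptides` (protein_id, peptide, ionization_factor,
#'   theoretical_mass, is_unique), plus the generating `params`.
#' @seealso [simulate_peptide_table()], [recovery_report()]
#' @export
generate_truth <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  n <- params$n_proteins

  n_decoy <- round(params$frac_decoy * n)
  n_excl <- round(params$frac_exclusive_per_condition * n)
  n_diff <- round(params$frac_diff * n)

  ids <- sprintf("P%05d", seq_len(n))
  roles <- rep("null", n)
  pool <- sample.int(n)               # random but seed-deterministic assignment
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  if (n_decoy > 0L) roles[take(n_decoy)] <- "decoy"
  if (n_excl > 0L) roles[take(n_excl)] <- "tumor_only"
  if (n_excl > 0L) roles[take(n_excl)] <- "control_only"
  if (n_diff > 0L) roles[take(n_diff)] <- "diff"

  is_decoy <- roles == "decoy"
  ids[is_decoy] <- paste0("REV_", ids[is_decoy])
  exclusivity <- ifelse(roles %in% c("tumor_only", "control_only"), roles, "none")

  true_log2fc <- numeric(n)
  true_log2fc[roles == "diff"] <-
    stats::rnorm(sum(roles == "diff"), params$log2_effect_mean, params$log2_effect_sd)
  true_log2fc[exclusivity != "none"] <- NA_real_   # undefined for exclusives

  base_abundance <- 10^stats::runif(n, log10(params$min_abundance),
                                    log10(params$min_abundance) +
                                      params$abundance_span_orders)

  n_pep <- 1L + stats::rpois(n, params$mean_peptides_per_protein - 1)
  pep_protein <- rep.int(ids, n_pep)
  total_pep <- sum(n_pep)
  pep_seq <- random_tryptic_peptides(total_pep)
  ionization <- stats::rlnorm(total_pep, 0, params$ionization_sdlog)
  # per-protein rescale: ideal Top3 (mean of the <=3 largest factors) is 1
  ion_split <- split(ionization, factor(pep_protein, levels = ids))
  ionization <- unlist(lapply(ion_split, function(f) {
    top <- sort(f, decreasing = TRUE)[seq_len(min(3L, length(f)))]
    f / mean(top)
  }), use.names = FALSE)

  peptides <- data.frame(
    protein_id = pep_protein,
    peptide = pep_seq,
    ionization_factor = ionization,
    theoretical_mass = peptide_monoisotopic_mass(pep_seq),
    is_unique = TRUE,
    stringsAsFactors = FALSE
  )

  # a fraction of peptides is shared with a second protein; both copies
  # lose the uniqueness flag, exercising the unique-peptide filter
  n_shared <- round(params$frac_shared_peptides * nrow(peptides))
  if (n_shared > 0L && n > 1L) {
    shared_idx <- sample.int(nrow(peptides), n_shared)
    host <- peptides$protein_id[shared_idx]
    other <- vapply(host, function(h) sample(setdiff(ids, h), 1L), character(1))
    extra <- peptides[shared_idx, ]
    extra$protein_id <- other
    extra$ionization_factor <- stats::rlnorm(n_shared, 0, params$ionization_sdlog)
    peptides$is_unique[shared_idx] <- FALSE
    extra$is_unique <- FALSE
    shared_seqs <- peptides$peptide[shared_idx]
    peptides <- rbind(peptides, extra)
    peptides$is_unique[peptides$peptide %in% shared_seqs] <- FALSE
    peptides <- peptides[order(peptides$protein_id, peptides$peptide), ]
    rownames(peptides) <- NULL
  }

  truth <- list(
    proteins = data.frame(
      protein_id = ids,
      base_abundance = base_abundance,
      true_log2fc = true_log2fc,
      is_decoy = is_decoy,
      exclusivity = exclusivity,
      stringsAsFactors = FALSE
    ),
    peptides = peptides,
    params = params
  )
  class(truth) <- "synthetic_truth"
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  p <- x$proteins
  cat("Synthetic proteome truth ledger\n")
  cat(sprintf("  proteins: %d (%d decoy, %d tumor-only, %d control-only, %d differential)\n",
              nrow(p), sum(p$is_decoy), sum(p$exclusivity == "tumor_only"),
              sum(p$exclusivity == "control_only"),
              sum(!is.na(p$true_log2fc) & p$true_log2fc != 0)))
  cat(sprintf("  peptides: %d catalogued (%.1f per protein; %.1f%% non-unique)\n",
              nrow(x$peptides), nrow(x$peptides) / nrow(p),
              100 * mean(!x$peptides$is_unique)))
  cat(sprintf("  base abundance span: %.2f orders of magnitude\n",
              log10(max(p$base_abundance) / min(p$base_abundance))))
  invisible(x)
}

#' Simulate a peptide-level quantification table
#'
#' Expands the truth ledger over the runs of a study design. Per run,
#' peptide intensity is `base_abundance * 2^(true_log2fc * [tumor]) *
#' ionization_factor * noise`, where the noise is multiplicative
#' log-normal with the configured replicate CV (mean 1). Exclusive
#' proteins emit no rows in their excluded condition. Observed masses are
#' `theoretical * (1 + eps/1e6)` with `eps ~ Normal(0, ppm_error_sd)`.
#' Intensity-dependent dropout removes rows with probability
#' `1 - plogis(steepness * (log10(I_true) - log10(midpoint)))`, acting on
#' the pre-noise intensity. Missing values are absent rows, never zeros.
#'
#' @param truth A `synthetic_truth` ledger from [generate_truth()].
#' @param design A [study_design()].
#' @param params The [sim_params()] used for the ledger (noise, dropout
#'   and ppm settings are read from here).
#' @return A data.frame with columns `peptide`, `protein`, `unique`,
#'   `run`, `intensity`, `mz_theoretical`, `mz_observed` — one row per
#'   observed peptide x run.
#' @export
simulate_peptide_table <- function(truth, design, params = truth$params) {
  stopifnot(inherits(truth, "synthetic_truth"))
  design <- if (inherits(design, "study_design")) design else study_design(design)
  validate_sim_params(params)
  bad_cond <- setdiff(unique(design$condition), c("tumor", "control"))
  if (length(bad_cond) > 0L) {
    stop("unknown condition label(s) in design: ", paste(bad_cond, collapse = ", "))
  }
  set.seed(params$seed + 1L)

  pep <- merge(truth$peptides, truth$proteins, by = "protein_id", sort = FALSE)
  n_runs <- nrow(design)
  n_pep <- nrow(pep)

  idx <- rep(seq_len(n_pep), times = n_runs)
  run <- rep(design$run_id, each = n_pep)
  cond <- rep(design$condition, each = n_pep)

  fc <- pep$true_log2fc[idx]
  fc[is.na(fc)] <- 0                       # exclusives: flat, presence-coded
  effect <- ifelse(cond == "tumor", 2^fc, 1)
  true_intensity <- pep$base_abundance[idx] * effect * pep$ionization_factor[idx]

  keep <- rep(TRUE, length(idx))
  excl <- pep$exclusivity[idx]
  keep[excl == "tumor_only" & cond == "control"] <- FALSE
  keep[excl == "control_only" & cond == "tumor"] <- FALSE

  if (!is.null(params$dropout_midpoint)) {
    p_obs <- stats::plogis(params$dropout_steepness *
                             (log10(true_intensity) - log10(params$dropout_midpoint)))
    keep <- keep & (stats::runif(length(idx)) < p_obs)
  }

  if (params$replicate_cv > 0) {
    sdlog <- sqrt(log(1 + params$replicate_cv^2))
    noise <- stats::rlnorm(length(idx), -sdlog^2 / 2, sdlog)
  } else {
    noise <- 1
  }
  intensity <- true_intensity * noise

  if (params$ppm_error_sd > 0) {
    eps <- stats::rnorm(length(idx), 0, params$ppm_error_sd)
  } else {
    eps <- 0
  }
  theo <- pep$theoretical_mass[idx]
  observed <- theo * (1 + eps / 1e6)

  out <- data.frame(
    peptide = pep$peptide[idx],
    protein = pep$protein_id[idx],
    unique = pep$is_unique[idx],
    run = run,
    intensity = intensity,
    mz_theoretical = theo,
    mz_observed = observed,
    stringsAsFactors = FALSE
  )[keep, ]
  rownames(out) <- NULL
  out
}

#' Compare differential-abundance calls against the simulation truth
#'
#' Measures how well the pipeline recovered the planted effects: bias and
#' RMSE of estimated versus true log2 fold changes (over non-decoy,
#' non-exclusive proteins quantified in all runs), a confusion table of
#' truth class versus called class, and the realized false-positive rate
#' (fraction of true-null proteins that reached the ANOVA stage and have
#' p <= alpha).
#'
#' @param truth A `synthetic_truth` ledger.
#' @param records Differential records from [apply_filter_cascade()].
#' @param thresholds [filter_thresholds()] used to derive the truth
#'   classes (log2 cutoff, alpha).
#' @param strict If `TRUE` (default), error when `records` omit a truth
#'   protein id; with `FALSE` unquantified proteins are counted and
#'   skipped (useful under dropout, which can erase a low-abundance
#'   protein from the table entirely).
#' @return A list of class `"recovery_report"`: `bias`, `rmse`,
#'   `n_compared`, `confusion` (truth x called table), `fpr`,
#'   `n_null_tested`, `n_missing`.
#' @export
recovery_report <- function(truth, records, thresholds = filter_thresholds(),
                            strict = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"), is.data.frame(records))
  unknown <- setdiff(records$protein_id, truth$proteins$protein_id)
  if (length(unknown) > 0L) {
    stop("records contain protein ids absent from the truth ledger: ",
         paste(utils::head(unknown, 10L), collapse = ", "))
  }
  missing_ids <- setdiff(truth$proteins$protein_id, records$protein_id)
  if (strict && length(missing_ids) > 0L) {
    stop("records are missing ", length(missing_ids), " truth protein id(s): ",
         paste(utils::head(missing_ids, 10L), collapse = ", "))
  }

  tr <- truth$proteins
  m <- merge(tr, records, by = "protein_id")

  truth_class <- function(row) {
    if (row$is_decoy) return("decoy")
    if (row$exclusivity == "tumor_only") return("exclusive_tumor")
    if (row$exclusivity == "control_only") return("exclusive_control")
    if (!is.na(row$true_log2fc) && row$true_log2fc >= thresholds$log2_cutoff) return("up_in_tumor")
    if (!is.na(row$true_log2fc) && row$true_log2fc <= -thresholds$log2_cutoff) return("up_in_control")
    "unchanged"
  }
  m$truth_class <- vapply(seq_len(nrow(m)), function(i) truth_class(m[i, ]), character(1))

  est <- m[!m$is_decoy & m$exclusivity == "none" & !is.na(m$log2_ratio), ]
  errs <- est$log2_ratio - est$true_log2fc
  bias <- if (nrow(est) > 0L) mean(errs) else NA_real_
  rmse <- if (nrow(est) > 0L) sqrt(mean(errs^2)) else NA_real_

  confusion <- table(truth = m$truth_class, called = m$class)

  null_tested <- m[!m$is_decoy & m$exclusivity == "none" &
                     !is.na(m$true_log2fc) & m$true_log2fc == 0 &
                     !is.na(m$p_value), ]
  fpr <- if (nrow(null_tested) > 0L) {
    mean(null_tested$p_value <= thresholds$alpha)
  } else NA_real_

  out <- list(bias = bias, rmse = rmse, n_compared = nrow(est),
              confusion = confusion, fpr = fpr,
              n_null_tested = nrow(null_tested),
              n_missing = length(missing_ids))
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery report\n")
  cat(sprintf("  log2 fold-change bias: %.4g, RMSE: %.4g (n = %d)\n",
              x$bias, x$rmse, x$n_compared))
  cat(sprintf("  realized false-positive rate among %d tested null proteins: %s\n",
              x$n_null_tested,
              ifelse(is.na(x$fpr), "NA", sprintf("%.3f", x$fpr))))
  if (x$n_missing > 0L) {
    cat(sprintf("  %d truth proteins were not quantified\n", x$n_missing))
  }
  cat("  confusion (truth x called):\n")
  print(x$confusion)
  invisible(x)
}

#' Write the truth ledger to TSV files
#'
#' @param truth A `synthetic_truth`.
#' @param proteins_path,peptides_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_truth <- function(truth, proteins_path, peptides_path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  data.table::fwrite(truth$proteins, proteins_path, sep = "\t")
  data.table::fwrite(truth$peptides, peptides_path, sep = "\t")
  invisible(c(proteins_path, peptides_path))
}
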