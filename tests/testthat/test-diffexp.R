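design6 <- design_two_by_three()

mat6 <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(r) r[[2]]))
  rownames(m) <- vapply(rows, `[[`, character(1), 1)
  colnames(m) <- design6$run_id
  m
}

test_that("condition stats use the sample SD and count observed replicates", {
  m <- mat6(list("P1", c(100, 100, 100, 90, 100, 110)),
            list("P2", c(90, 100, 110, 100, 100, NA)))
  s <- compute_condition_stats(toy_pqm(m), design6)
  expect_equal(s$mean_tumor[s$protein_id == "P1"], 100)
  expect_equal(s$cv_tumor[s$protein_id == "P1"], 0)
  # {90,100,110}: sample variance ((-10)^2 + 0 + 10^2)/2 = 100
  expect_equal(s$sd_control[s$protein_id == "P1"], 10)
  expect_equal(s$cv_control[s$protein_id == "P1"], 0.1)
  expect_equal(s$n_control[s$protein_id == "P2"], 2)
})

test_that("ANOVA handles identical and degenerate groups deterministically", {
  m <- mat6(list("PEQ", 2^c(1, 2, 3, 1, 2, 3)),       # identical groups
            list("PSEP", 2^c(0, 0, 0, 5, 5, 5)),      # separated constants
            list("PFLAT", 2^c(2, 2, 2, 2, 2, 2)))     # equal constants
  p <- anova_per_protein(toy_pqm(m), design6)
  expect_equal(unname(p["PEQ"]), 1)    # F = 0
  expect_equal(unname(p["PSEP"]), 0)
  expect_equal(unname(p["PFLAT"]), 1)
})

test_that("two-group ANOVA equals the squared pooled t-test (F = t^2)", {
  m <- mat6(list("P1", 2^c(1.0, 1.1, 0.9, 2.0, 2.1, 1.9)))
  p <- anova_per_protein(toy_pqm(m), design6)
  tt <- t.test(c(1.0, 1.1, 0.9), c(2.0, 2.1, 1.9), var.equal = TRUE)
  expect_equal(unname(p["P1"]), tt$p.value)

  # property over random instances
  set.seed(101)
  for (i in 1:50) {
    vals <- rnorm(6, sd = runif(1, 0.1, 2)) + rep(rnorm(2), each = 3)
    mi <- mat6(list("PX", 2^vals))
    pa <- anova_per_protein(toy_pqm(mi), design6)
    tt <- t.test(vals[1:3], vals[4:6], var.equal = TRUE)
    expect_equal(unname(pa["PX"]), tt$p.value, tolerance = 1e-12)
  }
})

test_that("proteins below the replication precondition are not tested", {
  m <- mat6(list("P1", c(100, 110, NA, 90, 95, 100)))
  p <- anova_per_protein(toy_pqm(m), design6)
  expect_equal(unname(p["P1"]), t.test(log2(c(100, 110)),
                                       log2(c(90, 95, 100)),
                                       var.equal = TRUE)$p.value)
  m2 <- mat6(list("P1", c(100, NA, NA, 90, 95, 100)))
  expect_true(is.na(anova_per_protein(toy_pqm(m2), design6)["P1"]))
})

test_that("each cascade stage fails exactly where constructed, with audit trail", {
  m <- mat6(
    list("REV_P9", c(100, 101, 99, 50, 51, 49)),        # decoy, perfect data
    list("P_rep", c(100, 101, NA, 50, 51, 49)),         # partial replication
    list("P_pep", c(100, 101, 99, 50, 51, 49)),         # 1 peptide
    list("P_uni", c(100, 101, 99, 50, 51, 49)),         # 0 unique peptides
    list("P_cv", c(100, 300, 20, 50, 51, 49)),          # tumor CV > 0.3
    list("P_up", c(400, 401, 399, 50, 51, 49)),         # clean up-regulation
    list("P_flat", c(100, 101, 99, 100, 99, 101)))      # clean null
  n_pep <- setNames(c(3L, 3L, 1L, 3L, 3L, 3L, 3L), rownames(m))
  n_uni <- setNames(c(2L, 2L, 1L, 0L, 2L, 2L, 2L), rownames(m))
  pqm <- toy_pqm(m, n_pep, n_uni)
  rec <- apply_filter_cascade(pqm, design6)
  cls <- setNames(rec$class, rec$protein_id)
  expect_equal(unname(cls["REV_P9"]), "discarded_decoy")
  expect_equal(unname(cls["P_rep"]), "filtered_out")
  expect_equal(unname(cls["P_pep"]), "filtered_out")
  expect_equal(unname(cls["P_uni"]), "filtered_out")
  expect_equal(unname(cls["P_cv"]), "filtered_out")
  expect_equal(unname(cls["P_up"]), "up_in_tumor")
  expect_equal(unname(cls["P_flat"]), "unchanged")

  trail <- setNames(rec$filter_trail, rec$protein_id)
  expect_equal(unname(trail["REV_P9"]), "decoy=fail")
  expect_match(unname(trail["P_rep"]), "replication=fail$")
  expect_match(unname(trail["P_pep"]), "peptide_count=fail$")
  expect_match(unname(trail["P_uni"]), "unique_peptide=fail$")
  expect_match(unname(trail["P_cv"]), "cv=fail$")
  expect_match(unname(trail["P_up"]), "anova=pass\\|fold_change=pass$")

  # classes match the independent brute-force oracle
  expect_equal(unname(oracle_cascade(pqm, design6, filter_thresholds())),
               unname(cls[pqm$protein_ids]))
})

test_that("volcano classification is boundary-inclusive on both axes", {
  th <- filter_thresholds()
  rec <- data.frame(protein_id = paste0("P", 1:4),
                    log2_ratio = c(1.3, 1.0, -1.2, 1.2),
                    p_value = c(0.01, 0.001, 0.05, 0.051),
                    class = "unchanged", stringsAsFactors = FALSE)
  got <- classify_volcano(rec, th)
  expect_equal(got$class, c("up_in_tumor",   # clears both cutoffs
                            "unchanged",     # below magnitude cutoff
                            "up_in_control", # boundaries inclusive
                            "unchanged"))    # p just over alpha
})

test_that("exclusive calls require the strict all-vs-none pattern", {
  m <- mat6(list("P_t", c(10, 12, 11, NA, NA, NA)),
            list("P_partial", c(10, 12, NA, NA, NA, NA)),
            list("P_c", c(NA, NA, NA, 10, 12, 11)),
            list("REV_X", c(10, 12, 11, NA, NA, NA)))
  got <- call_exclusive(toy_pqm(m), design6)
  expect_setequal(got$protein_id, c("P_c", "P_t"))
  expect_equal(got$class[got$protein_id == "P_t"], "exclusive_tumor")
  expect_equal(got$class[got$protein_id == "P_c"], "exclusive_control")
})

test_that("planted exclusives are recovered exactly in a clean simulation", {
  p <- sim_params(n_proteins = 120, replicate_cv = 0, dropout_midpoint = NULL,
                  frac_exclusive_per_condition = 0.1, seed = 33)
  truth <- generate_truth(p)
  pqm <- rollup_top3(simulate_peptide_table(truth, design6, p), design6)
  got <- call_exclusive(pqm, design6)
  planted_t <- truth$proteins$protein_id[truth$proteins$exclusivity == "tumor_only"]
  planted_c <- truth$proteins$protein_id[truth$proteins$exclusivity == "control_only"]
  expect_setequal(got$protein_id[got$class == "exclusive_tumor"], planted_t)
  expect_setequal(got$protein_id[got$class == "exclusive_control"], planted_c)
})

test_that("every protein receives exactly one class (partition invariant)", {
  p <- sim_params(n_proteins = 150, seed = 44)
  res <- run_pipeline(p)
  expect_equal(sum(table(res$records$class)), length(res$pqm$protein_ids))
  expect_false(any(is.na(res$records$class)))
})

test_that("swapping condition labels mirrors classes and negates log2 ratios", {
  p <- sim_params(n_proteins = 120, seed = 55)
  truth <- generate_truth(p)
  tbl <- simulate_peptide_table(truth, design6, p)
  pqm <- rollup_top3(tbl, design6)
  fwd <- apply_filter_cascade(pqm, design6)
  swp <- apply_filter_cascade(pqm, swap_conditions(design6))
  map <- c(up_in_tumor = "up_in_control", up_in_control = "up_in_tumor",
           exclusive_tumor = "exclusive_control",
           exclusive_control = "exclusive_tumor",
           unchanged = "unchanged", filtered_out = "filtered_out",
           discarded_decoy = "discarded_decoy")
  expect_equal(unname(map[fwd$class]), swp$class)
  both <- !is.na(fwd$log2_ratio) & !is.na(swp$log2_ratio)
  expect_equal(fwd$log2_ratio[both], -swp$log2_ratio[both])
})

test_that("relaxing thresholds never loses up/down calls (monotonicity)", {
  p <- sim_params(n_proteins = 200, seed = 66)
  res <- run_pipeline(p)
  pqm <- res$pqm
  n_calls <- function(th) {
    r <- apply_filter_cascade(pqm, design6, th)
    sum(r$class %in% c("up_in_tumor", "up_in_control"))
  }
  base <- n_calls(filter_thresholds())
  expect_gte(n_calls(filter_thresholds(max_cv = 0.5)), base)
  expect_gte(n_calls(filter_thresholds(alpha = 0.1)), base)
  expect_gte(n_calls(filter_thresholds(log2_cutoff = 0.8)), base)
})

test_that("threshold validation rejects impossible settings", {
  expect_error(filter_thresholds(alpha = 0), "alpha")
  expect_error(filter_thresholds(alpha = 1.5), "alpha")
  expect_error(filter_thresholds(max_cv = -0.1), "max_cv")
  expect_error(filter_thresholds(log2_cutoff = -1), "log2_cutoff")
  expect_error(apply_filter_cascade(toy_pqm(mat6(list("P1", rep(1, 6)))),
                                    design6, thresholds = list(alpha = 0.05)),
               "filter_thresholds")
})
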