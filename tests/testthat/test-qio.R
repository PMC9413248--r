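make_design <- function() design_two_by_three(2L)

write_toy_file <- function(lines, ext = "tsv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("well-formed peptide tables round-trip exactly", {
  d <- design_two_by_three()
  p <- sim_params(n_proteins = 25, seed = 4)
  tbl <- simulate_peptide_table(generate_truth(p), d, p)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(tbl, path)
  back <- read_peptide_table(path, d)
  expect_equal(attr(back, "n_accepted"), nrow(tbl))
  attr(back, "n_accepted") <- NULL
  expect_equal(back, tbl)
})

test_that("peptide-table validation names the offending row or column", {
  d <- make_design()
  ok <- c("peptide\tprotein\tunique\trun\tintensity",
          "AAK\tP1\t1\ttumor_1\t10",
          "AAK\tP1\t1\ttumor_2\t12")
  expect_equal(attr(read_peptide_table(write_toy_file(ok), d), "n_accepted"), 2)

  zero <- c("peptide\tprotein\tunique\trun\tintensity",
            "AAK\tP1\t1\ttumor_1\t10",
            "CCK\tP1\t1\ttumor_1\t0")
  expect_error(read_peptide_table(write_toy_file(zero), d), "row\\(s\\): 2")

  unknown <- c("peptide\tprotein\tunique\trun\tintensity",
               "AAK\tP1\t1\trun_X\t10")
  expect_error(read_peptide_table(write_toy_file(unknown), d), "run_X")

  dup <- c("peptide\tprotein\tunique\trun\tintensity",
           "AAK\tP1\t1\ttumor_1\t10",
           "AAK\tP1\t1\ttumor_1\t11")
  expect_error(read_peptide_table(write_toy_file(dup), d),
               "duplicate.*AAK, P1, tumor_1")

  nocol <- c("peptide\tprotein\trun\tintensity", "AAK\tP1\ttumor_1\t10")
  expect_error(read_peptide_table(write_toy_file(nocol), d), "unique")

  halfmass <- c("peptide\tprotein\tunique\trun\tintensity\tmz_theoretical",
                "AAK\tP1\t1\ttumor_1\t10\t500.1")
  expect_error(read_peptide_table(write_toy_file(halfmass), d),
               "mz_theoretical and mz_observed")
})

test_that("csv delimiter is auto-detected from the extension", {
  d <- make_design()
  csv <- c("peptide,protein,unique,run,intensity", "AAK,P1,1,tumor_1,10")
  got <- read_peptide_table(write_toy_file(csv, ext = "csv"), d)
  expect_equal(got$intensity, 10)
})

test_that("reversed decoys double the FASTA and reverse each sequence", {
  fa <- write_toy_file(c(">P1", "PEPTIDEK", ">P2", "ACDEFGHIK"), ext = "fasta")
  out <- make_reversed_decoys(fa)
  expect_length(out, 4)
  expect_equal(names(out), c("P1", "P2", "REV_P1", "REV_P2"))
  expect_equal(as.character(out[["REV_P1"]]), "KEDITPEP")
  expect_equal(as.character(out[["REV_P2"]]), "KIHGFEDCA")
})

test_that("decoy generation is an involution on sequence content", {
  fa <- write_toy_file(c(">A", "MKWVTFISLLK", ">B", "GDVEK"), ext = "fasta")
  path2 <- withr::local_tempfile(fileext = ".fasta")
  once <- make_reversed_decoys(fa, out_path = path2)
  rev_of_rev <- Biostrings::reverse(once[c("REV_A", "REV_B")])
  expect_equal(unname(as.character(rev_of_rev)),
               unname(as.character(once[c("A", "B")])))
})

test_that("decoy generation errors on empty input and id collisions", {
  empty <- write_toy_file(character(0), ext = "fasta")
  expect_error(make_reversed_decoys(empty), "empty FASTA")
  collide <- write_toy_file(c(">P1", "PEPK", ">REV_P1", "KAAR"), ext = "fasta")
  expect_error(make_reversed_decoys(collide), "collision.*REV_P1")
})

test_that("GMT reading deduplicates members and skips short lines", {
  gmt <- write_toy_file(c("S1\tdesc one\tA\tB\tA",
                          "bad_line\tonly-two-fields",
                          "S2\tdesc two\tC"))
  expect_warning(sets <- read_gmt(gmt), "fewer than 3 fields")
  expect_equal(sets$set_id, c("S1", "S2"))
  expect_equal(sets$members$S1, c("A", "B"))
  expect_equal(sets$members$S2, "C")

  empty <- write_toy_file(character(0))
  expect_warning(none <- read_gmt(empty), "empty GMT")
  expect_length(none$set_id, 0)
})

test_that("newick export writes ultrametric branch lengths", {
  two <- structure(list(merge = matrix(c(-1L, -2L), 1),
                        height = 0.4, order = 1:2,
                        labels = c("A", "B")), class = "hclust")
  expect_equal(write_newick(two), "(A:0.4,B:0.4);")

  three <- structure(list(merge = rbind(c(-1L, -2L), c(1L, -3L)),
                          height = c(0.2, 0.6), order = 1:3,
                          labels = c("A", "B", "C")), class = "hclust")
  expect_equal(write_newick(three), "((A:0.2,B:0.2):0.4,C:0.6);")

  one <- structure(list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                        order = 1L, labels = "A"), class = "hclust")
  expect_error(write_newick(one), "at least 2 leaves")
})

test_that("newick labels with metacharacters are quoted and ape can parse them", {
  skip_if_not_installed("ape")
  awkward <- structure(list(merge = rbind(c(-1L, -2L), c(1L, -3L)),
                            height = c(0.1, 0.5), order = 1:3,
                            labels = c("pro,tein", "with space", "plain")),
                       class = "hclust")
  nwk <- write_newick(awkward)
  expect_match(nwk, "'pro,tein'", fixed = TRUE)
  tree <- ape::read.tree(text = nwk)
  tips <- gsub("^'|'$", "", tree$tip.label)   # ape keeps the quote marks
  expect_setequal(tips, c("pro,tein", "with space", "plain"))
  # leaf depths reconstruct the merge heights (ultrametric contract)
  depths <- ape::node.depth.edgelength(tree)[seq_len(3)]
  expect_equal(unname(depths), rep(0.5, 3))
})

test_that("newick serialization agrees with ape on a real clustering", {
  skip_if_not_installed("ape")
  set.seed(99)
  m <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("P", 1:8), paste0("r", 1:5)))
  cl <- cluster_complete(m, axis = "rows")
  tree <- ape::read.tree(text = write_newick(cl$tree))
  expect_setequal(tree$tip.label, rownames(m))
  # pairwise cophenetic distances: ape path lengths = 2 * merge height
  coph <- as.matrix(stats::cophenetic(cl$tree))
  ape_d <- ape::cophenetic.phylo(tree)[rownames(coph), colnames(coph)]
  expect_equal(ape_d, coph * 2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("config files reconstruct design, parameters and thresholds", {
  cfg <- write_toy_file(c(
    "design:",
    "  - {run_id: tumor_1, condition: tumor, replicate: 1}",
    "  - {run_id: tumor_2, condition: tumor, replicate: 2}",
    "  - {run_id: control_1, condition: control, replicate: 1}",
    "  - {run_id: control_2, condition: control, replicate: 2}",
    "sim_params: {n_proteins: 42, seed: 7}",
    "thresholds: {max_cv: 0.2, alpha: 0.01}"), ext = "yaml")
  got <- read_config(cfg)
  expect_s3_class(got$design, "study_design")
  expect_equal(nrow(got$design), 4)
  expect_equal(got$sim_params$n_proteins, 42)
  expect_equal(got$thresholds$max_cv, 0.2)
  expect_equal(got$thresholds$log2_cutoff, 1.2)  # default preserved
})
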