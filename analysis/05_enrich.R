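#!/usr/bin/env Rscript
# Stage 5 — over-representation analysis of the differential proteins.
#
# Builds a synthetic gene-set collection over the quantified proteome
# (no annotation download): one set planted to overlap the up-regulated
# proteins, one planted on the down-regulated side, and a background of
# random sets. Runs the hypergeometric ORA with BH FDR against the
# quantified-protein universe and keeps sets at FDR <= 0.05, exporting
# -log10(FDR) for bar-plot use. With real annotations, replace the
# synthetic GMT by any Reactome/GO GMT file via read_gmt().

suppressPackageStartupMessages(library(top3lfq))

seed <- as.integer(Sys.getenv("PIPELINE_SEED", "20240915"))
set.seed(seed + 50L)

design <- design_two_by_three()
tbl <- read_peptide_table("results/peptide_table.tsv", design)
pqm <- rollup_top3(normalize_runs(tbl, design)$table, design)
records <- apply_filter_cascade(pqm, design)

universe <- records$protein_id[records$class != "discarded_decoy"]
query <- records$protein_id[records$class %in%
                              c("up_in_tumor", "up_in_control")]
cat(sprintf("query: %d differential proteins; universe: %d proteins\n",
            length(query), length(universe)))

# synthetic annotation: two planted pathways plus random background sets
up_ids <- records$protein_id[records$class == "up_in_tumor"]
dn_ids <- records$protein_id[records$class == "up_in_control"]
gmt_lines <- c(
  paste(c("SYN_PATH_UP", "synthetic pathway enriched in tumor-up proteins",
          unique(c(up_ids, sample(universe, 20)))), collapse = "\t"),
  paste(c("SYN_PATH_DOWN", "synthetic pathway enriched in control-up proteins",
          unique(c(dn_ids, sample(universe, 20)))), collapse = "\t"),
  vapply(1:30, function(i) {
    paste(c(sprintf("SYN_RAND_%02d", i), "random background set",
            sample(universe, 40)), collapse = "\t")
  }, character(1))
)
dir.create("results", showWarnings = FALSE)
writeLines(gmt_lines, "results/synthetic_gene_sets.gmt")

sets <- read_gmt("results/synthetic_gene_sets.gmt")
ora <- run_ora(query, sets, universe, fdr_cutoff = 0.05)

cat(sprintf("%d of %d sets retained at FDR <= 0.05:\n",
            sum(ora$retained), nrow(ora)))
print(utils::head(ora[, c("set_id", "k", "K", "p_value", "fdr",
                          "neg_log10_fdr", "retained")]))

data.table::fwrite(ora, "results/ora_full.tsv", sep = "\t")
data.table::fwrite(ora[ora$retained, ], "results/ora_retained.tsv", sep = "\t")
cat("wrote results/ora_full.tsv and results/ora_retained.tsv\n")
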