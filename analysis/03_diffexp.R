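#!/usr/bin/env Rscript
# Stage 3 — differential-abundance filter cascade and volcano calls.
#
# Applies the cascade in its fixed order (reversed-decoy removal, 3/3
# replication, >=2 peptides, >=1 unique peptide, CV <= 0.30 in both
# conditions, one-way ANOVA on log2 Top3) and classifies survivors by
# the volcano rule (|log2 ratio| >= 1.2 and p <= 0.05). Exclusive
# proteins — quantified in every replicate of one condition and none
# of the other — are reported separately.

suppressPackageStartupMessages(library(top3lfq))

design <- design_two_by_three()
tbl <- read_peptide_table("results/peptide_table.tsv", design)
pqm <- rollup_top3(normalize_runs(tbl, design)$table, design)

thresholds <- filter_thresholds()
records <- apply_filter_cascade(pqm, design, thresholds)

cat("class counts:\n")
print(table(records$class))
excl <- call_exclusive(pqm, design)
cat(sprintf("exclusive proteins: %d tumor, %d control\n",
            sum(excl$class == "exclusive_tumor"),
            sum(excl$class == "exclusive_control")))

data.table::fwrite(records, "results/diff_records.tsv", sep = "\t")
data.table::fwrite(volcano_table(records), "results/volcano.tsv", sep = "\t")
cat("wrote results/diff_records.tsv and results/volcano.tsv\n")
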