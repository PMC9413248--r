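# top3lfq

Simulation-driven label-free quantitative proteomics in R: Top3 (Hi-3)
protein quantification from peptide-level intensities, the
differential-abundance filter cascade used in membrane-proteome
comparisons of tumor versus control cell lines, z-score expression
profiling with complete-linkage/Pearson clustering, and local
hypergeometric over-representation analysis.

## Who this is for

Proteomics analysts who receive a peptide-level quantification table
from upstream DIA software (one row per peptide × injection) and need
a reproducible, auditable path from that table to a differential
protein list — plus a ground-truth simulator to validate every stage
of that path without touching raw spectra.

## The model in brief

- **Top3 quantification**: a protein's abundance in a run is the mean
  MS signal of its three most intense peptides,
  `Top3 = mean(I_(1), I_(2), I_(3))`; the tumor/control abundance
  ratio per protein is `R = Top3_tumor / Top3_control`.
- **Filter cascade** (fixed order, audit trail kept): reversed-decoy
  removal (`REV_` prefix) → full replication (3/3 in both conditions;
  all-vs-none presence is called *exclusive* instead) → ≥2
  peptides/protein → ≥1 unique peptide → CV ≤ 0.30 per condition →
  one-way ANOVA on log2 Top3 → volcano rule |log2 R| ≥ 1.2 with
  p ≤ 0.05 (boundaries inclusive).
- **Profiles**: per-protein standardization `z = (x − μ)/σ` over all
  injections; hierarchical clustering of proteins and runs with
  complete linkage on Pearson distance `d = 1 − r`; Newick export.
- **Enrichment**: per gene set, hypergeometric upper tail
  `P(X ≥ k)` for `X ~ Hypergeom(N, K, n)` against the
  quantified-protein universe, Benjamini–Hochberg FDR, retention at
  FDR ≤ 0.05, `−log10(FDR)` for plotting.
- **Simulator**: log-uniform protein abundances over 6.5 orders of
  magnitude, `1 + Poisson(8)` peptides per protein (mean 9),
  log-normal replicate noise (CV 0.15), normal mass errors
  (σ = 6.6 ppm, so ~87% of rows fall within ±10 ppm), planted log2
  effects, condition-exclusive proteins, reversed decoys, and logistic
  intensity-dependent dropout — with a truth ledger for
  parameter-recovery scoring.

## Worked example

```r
library(top3lfq)
params <- sim_params(n_proteins = 300, seed = 7)
res <- run_pipeline(params)
res$summary
```

```
Pipeline summary
  peptide-run rows: 13830
  proteins quantified: 300
  up in tumor: 13; up in control: 10; unchanged: 230
  exclusive (tumor/control): 8 / 8
  decoys discarded: 15; filtered out: 16
  dynamic range: 7.54 orders of magnitude
  peptide rows within mass tolerance: 87.27%
```

Reading: of 300 simulated proteins, 15 were reversed decoys
(discarded), 8 + 8 were quantified in every replicate of exactly one
condition (exclusive calls), 16 failed a reproducibility or
identification filter, and the volcano rule called 13 + 10
differential; 87.27% of peptide rows had a mass error within ±10 ppm,
matching the generator's 6.6-ppm error model. Scoring against the
truth ledger:

```r
recovery_report(res$truth, res$records, strict = FALSE)
```

```
Parameter-recovery report
  log2 fold-change bias: 0.0115, RMSE: 0.1222 (n = 253)
  realized false-positive rate among 213 tested null proteins: 0.108
  ...
```

The RMSE of 0.12 log2 units reflects the replicate CV of 0.15 at
n = 3; the elevated false-positive rate under dropout is a real
property of sparse DIA tables discussed in the methods vignette.

The binding-assay mass balance used when conjugating transferrin to a
targeting nanoparticle:

```r
binding_yield(15, 10.34)
#> Ligand binding yield: 4.66 ug bound of 15.00 ug initial (31.1%); 10.34 ug in supernatant
```

## The analysis workflow

The numbered scripts under `analysis/` run the full-size study
(1300 proteins, 2 × 3 runs) stage by stage, each writing its tables
under `results/`:

```sh
Rscript analysis/01_simulate.R   # peptide table + truth ledger
Rscript analysis/02_quantify.R   # normalization, Top3 matrix, ppm/dynamic-range QC
Rscript analysis/03_diffexp.R    # filter cascade, volcano table, exclusives
Rscript analysis/04_profile.R    # z-scores, row/run dendrograms (Newick)
Rscript analysis/05_enrich.R     # ORA against a synthetic GMT
Rscript analysis/06_report.R     # summary, truth recovery, manifest
```

Set `PIPELINE_SEED` to change the simulation seed (default 20240915).

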