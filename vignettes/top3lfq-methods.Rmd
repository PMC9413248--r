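---
title: "Methods: simulation-driven Top3 label-free quantification and the differential-abundance cascade"
author: "top3lfq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-driven Top3 label-free quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(top3lfq)
```

## The problem this package addresses

Label-free quantitative proteomics of two cell populations — here a
drug-resistant small-cell lung cancer line playing the "tumor" role
against a normal fibroblast line as "control" — produces a peptide-level
intensity table: one MS signal per peptide per injection. Turning that
table into a defensible list of differentially abundant proteins takes a
chain of steps (normalization, peptide-to-protein rollup, reproducibility
and identification-quality filters, a significance test, a fold-change
rule), each with thresholds that interact. This package implements that
chain as composable functions, and pairs it with a synthetic-data
generator whose ground-truth ledger makes every stage testable: we can
ask not just whether the code runs, but whether the pipeline recovers
effects we planted.

## The quantification model

**Top3 (Hi-3) rollup.** A protein's abundance in a run is the arithmetic
mean of its three most intense peptides in that run. The Top3 statistic
rests on the empirical observation that the summed signal of the best
ionizing peptides is approximately proportional to protein amount. When
only one or two peptides are measured in a run we average what is there
and record `used_peptide_count` rather than dropping the cell: the
downstream filter cascade already demands at least two peptides per
protein, so a strict three-peptide rule at rollup would silently
tighten that published filter. Intensity ties are broken
lexicographically by peptide sequence so the rollup is deterministic.

**Shared peptides** contribute their full intensity to every protein
that lists them; no apportionment is attempted. The unique-peptide
filter (at least one unique peptide per protein) is what protects
inference from shared-peptide ambiguity.

**Normalization** happens at the peptide level, before rollup. Each
run is scaled by `exp(-m)` where `m` is the median log-ratio of its
peptides to a reference run over peptides observed in both. The
reference is a "middle" run, elected on run-median-centered log totals.
That centering matters: it makes the election invariant to per-run
rescaling, so normalizing an already-normalized table returns factors
of exactly 1 (a projection). Electing on raw totals — the more obvious
rule — is not idempotent, because scaling moves the totals and a second
pass can elect a different reference and emit spurious ~2% corrections.
Exact scalar-multiple ties (which arise in constructed tests, not in
noisy data) fall back to raw totals, then run order.

## The filter cascade

Filters apply in a fixed, audited order; each protein's record carries
the trail up to its first failure:

1. **decoy** — ids with the `REV_` prefix are discarded outright;
2. **replication** — a tested protein must be quantified in every
   replicate of *both* conditions ("3/3"); the all-of-one,
   none-of-the-other pattern is not a failure but an
   **exclusive-protein** call, reported separately;
3. **peptide count** — at least 2 peptides per protein;
4. **unique peptide** — at least 1 unique peptide;
5. **CV** — coefficient of variation (sample SD over mean, linear
   scale) at most 0.30 in each condition separately. CV is
   conventionally a linear-scale quantity; requiring both conditions to
   pass is the conservative reading of a per-protein reproducibility
   rule;
6. **ANOVA** — one-way fixed-effects ANOVA on log2 Top3 across the two
   condition groups (log2 stabilizes the multiplicative noise; with two
   groups F equals the squared pooled-variance t statistic, which the
   tests exploit as an identity check);
7. **fold change** — the volcano rule, boundaries inclusive:
   up in tumor iff log2(tumor/control) >= 1.2 and p <= 0.05; up in
   control iff log2 ratio <= -1.2 and p <= 0.05.

Stages 2–5 eliminate (class `filtered_out`); stages 6–7 jointly
*classify* the survivors as up/down/`unchanged`. That reading keeps a
protein with a reproducible but non-significant ratio in the reported
set, which is what a volcano plot displays, and it is also what makes
type-I calibration measurable: the realized false-positive rate is the
fraction of stage-6 entrants with p below the level.

Degenerate ANOVA inputs are resolved deterministically: two constant
groups with equal means give p = 1 (indistinguishable), with unequal
means p = 0 (perfectly separated); these arise in noise-free
simulations and would otherwise be floating-point lottery. No
multiple-testing correction is applied in the cascade — the published
filter is a raw per-protein p <= 0.05; `bh_fdr()` is available for
users who want an FDR-controlled variant.

Ratios are oriented tumor/control throughout, so "up in tumor" is a
positive log2 ratio.

## Expression profiles and clustering

For the heat-map view each protein row is standardized across all six
injections, both conditions pooled: `z = (x - mu) / sigma`. We use the
sample SD (n−1); the convention is recorded in the output
(`sd_convention`) since the population convention differs only by a
constant factor per row and either choice leaves the clustering
unchanged (Pearson distance is affine-invariant). Zero-variance rows
become all-zero and are flagged rather than erroring, and are excluded
from clustering.

Clustering is agglomerative with **complete linkage** on **Pearson
distance** `d = 1 - r`, for both rows (proteins) and columns (runs).
Rows with missing cells use pairwise-complete correlations when at
least 3 positions are shared; items that cannot be placed (zero
variance or insufficient overlap with some other item) are greedily
excluded — the item causing the most undefined distances is dropped
first — and listed in the output. Complete linkage cannot invert, so
merge heights are non-decreasing; ties are resolved by the order of the
distance matrix, which is fixed by the row order of the input. Trees
are exported as ultrametric Newick strings whose branch lengths are
merge-height differences, with metacharacter-containing labels
single-quoted.

On data with genuine two-sided differential structure this produces the
familiar four-quadrant heat map: the run dendrogram's top split
separates the conditions, and cutting the protein dendrogram at k = 2
separates up- from down-regulated blocks.

## Over-representation analysis

Pathway enrichment is a local computation over GMT files: per gene set,
the one-sided hypergeometric tail probability of the query overlap
(`P(X >= k)` via `phyper`, numerically stable), Benjamini–Hochberg FDR
across all tested sets, retention at FDR <= 0.05, and `-log10(FDR)` for
bar-plot export. The universe defaults to the quantified proteins, not
a whole annotation: a membrane-enriched experiment measured against a
whole-genome background would be anticonservative for membrane
pathways. Identifier matching is exact-string and case-sensitive. The
test and FDR procedure are named in the result's attributes, because
web services make their own (sometimes undocumented) choices and
results should say which surrogate was used.

## The synthetic-data generator

The generator emulates the reported structure of the study this
pipeline was built around; its defaults are the study conditions, not
tuning knobs:

| parameter | default | what it emulates |
|---|---|---|
| `n_proteins` | 1300 | ~1300 shared quantifiable proteins |
| `mean_peptides_per_protein` | 9 | average of nine peptides per protein |
| `abundance_span_orders` | 6.5 | ~6.5 orders of magnitude dynamic range |
| `ppm_error_sd` | 6.6 | puts `2*pnorm(10/6.6)-1 = 0.8698` of mass errors within ±10 ppm, the ~87% regime |
| `frac_exclusive_per_condition` | 0.025 | ~30+ exclusive proteins per side |
| `frac_decoy` | 0.05 | reversed decoys that must survive to the discard stage |
| `replicate_cv` | 0.15 | replicate-level multiplicative noise |
| `frac_diff` | 0.15 | fraction of proteins with a real effect — a generator choice, since the true fraction is unknowable from a processed dataset |
| `log2_effect_mean`, `log2_effect_sd` | 0, 2 | symmetric spiked effects, many beyond the 1.2 cutoff |
| `dropout_midpoint`, `dropout_steepness` | `10^2.8`, 1.5 | intensity-dependent missingness |

Peptide counts are `1 + Poisson(mean - 1)`, guaranteeing at least one
peptide while matching the mean. Base abundances are log-uniform over
the configured span. Peptide sequences are synthetic tryptic-like
strings (7–20 residues, K/R-terminated, no internal K/R) with
monoisotopic masses computed from the standard residue-mass table; a
configurable fraction of peptides is shared with a second protein and
flagged non-unique, exercising the unique-peptide filter. Decoys are
simulated exactly like ordinary null proteins — they are discarded
*after* quantification, so they must be quantifiable.

Per run, a peptide's intensity is
`base_abundance * 2^(true_log2fc * [tumor]) * ionization_factor * noise`,
with log-normal noise of mean 1 and the configured CV. Ionization
factors are log-normal, then rescaled per protein so the ideal
noise-free Top3 equals the catalogued base abundance; this makes the
truth ledger directly comparable to the quantified matrix and the
noise-free recovery checks exact. Dropout acts on the *pre-noise*
intensity through a logistic detection curve — low-intensity rows are
the ones that vanish, as in real DIA data — and missingness is encoded
by row absence, never by zeros. Mass errors are
`observed = theoretical * (1 + eps/1e6)` with normal `eps`.

All randomness flows from one seed: the ledger consumes `seed`, the
table draw `seed + 1`, so truth and measurements are independently
reproducible.

### What the generator does and does not capture

It reproduces the *marginal* structure the pipeline's filters see:
abundance span, peptides per protein, mass-error width, replicate CV,
exclusivity and decoy fractions, intensity-dependent missingness. It
does **not** simulate spectra, chromatography, ion mobility,
identification error, interference between co-eluting peptides, or
correlated (batch) noise. Passing the recovery tests therefore
demonstrates that the pipeline's arithmetic and decision logic are
correct under the stated noise model — not that any real dataset will
be this well behaved. Two emergent caveats are worth knowing:

* **Observed dynamic range exceeds the catalogue span.** Spiked
  effects multiply tumor abundances (up to `2^|effect|`), and dropout
  leaves low-abundance proteins represented by their weaker-ionizing
  peptides, so the quantified matrix spans ~8 orders when the base
  catalogue spans 6.5. The noise-free, effect-free matrix reproduces
  the 6.5-order span exactly.
* **Dropout inflates the realized type-I rate.** With dropout on,
  different peptide subsets enter the Top3 mean in different runs,
  adding a selection component to the replicate variance that the
  3-per-group ANOVA does not model; we observe ~0.11 at a nominal
  0.05. This mirrors a real hazard of sparse DIA tables. Calibration
  is therefore assessed on measurement-noise-only nulls (dropout off),
  where the realized rate is nominal (~0.05).

## Numerical and design choices

* Boundary comparisons are inclusive exactly as printed: CV <= 0.30,
  p <= 0.05, |log2 ratio| >= 1.2, |ppm| <= 10.
* ppm error is `1e6 * (observed - theoretical) / theoretical`.
* The CV filter is evaluated per condition (both must pass). Whether
  the original analysis pooled all six runs is not documentable from a
  processed table; the per-condition choice is the stricter one and the
  filter trail records the stage, so the other reading can be audited.
* Exclusivity is strict all-vs-none; a 2/3-vs-0/3 pattern is neither
  exclusive nor testable and lands in `filtered_out` at replication.
* `recovery_report()` errors on truth/record id mismatches by default;
  under dropout a low-abundance protein can vanish from the table
  entirely, so pipeline drivers pass `strict = FALSE` and the count of
  unquantified proteins is reported instead.
* Problem sizes in the test suite (500–2000 proteins, 10–20 seeds,
  100–200 property instances) were chosen as the smallest sizes at
  which the binomial/Monte-Carlo noise of each check is comfortably
  inside its assertion band.

## A small worked run

```{r pipeline, eval = FALSE}
params <- sim_params(n_proteins = 300, seed = 7)
res <- run_pipeline(params)
res$summary
#> Pipeline summary
#>   peptide-run rows: 13830
#>   proteins quantified: 300
#>   up in tumor: 13; up in control: 10; unchanged: 230
#>   exclusive (tumor/control): 8 / 8
#>   decoys discarded: 15; filtered out: 16
#>   dynamic range: 7.54 orders of magnitude
#>   peptide rows within mass tolerance: 87.27%
recovery_report(res$truth, res$records, strict = FALSE)
```

The numbered scripts under `analysis/` run the same chain at the full
default size, stage by stage, writing every intermediate table under
`results/`.

## Known limitations

* Two conditions only; the ANOVA generalizes to more groups but the
  cascade's replication/exclusivity logic is written for the
  two-condition design.
* No moderated-variance (empirical Bayes) testing and no imputation —
  both deliberate, to stay faithful to the published filter chain.
* No protein inference/grouping: peptide-to-protein assignment is taken
  as given, as it comes from upstream software.
* The ORA module is a surrogate for web-service enrichment; with the
  same GMT and universe its p-values are exact, but it will not
  reproduce a web service's numbers unless that service's universe and
  test are known.
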