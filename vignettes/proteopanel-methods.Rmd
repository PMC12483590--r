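---
title: "Methods: models, parameters and design choices in proteopanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in proteopanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteopanel)
```

`proteopanel` analyses multi-platform proteomic profiles of cell-line
panels: a label-free MS proteome, an IMAC-enriched phosphoproteome and
co-enriched glycoproteome, and an antibody-based RPPA panel, measured
across dozens of cell lines in replicate. This vignette documents the
statistical machinery, the tunable parameters and the design decisions
that were genuinely open.

## The abundance model and preprocessing chain

All intensity layers share one container, the `AbundanceMatrix`:
features × samples with per-sample (cell line, replicate, lineage)
metadata and a *scale tag*. The tag encodes pipeline position — `raw`
(linear intensities, missing as `NA`), `log2p1`, `lognorm`, `collapsed`
— and every operation checks it, so calling stages out of order fails
loudly rather than silently producing numbers on the wrong scale.

The preprocessing chain is:

1. **Detection filter** (`filter_low_detection`, default
   `min_frac = 0.05`): a feature must be non-missing *and* positive in at
   least 5% of samples. The threshold is deliberately lenient because a
   lineage-diverse panel legitimately contains lineage-restricted
   proteins.
2. **Global-minimum imputation** (`impute_global_min`): every missing
   cell becomes the single smallest observed intensity of the whole
   matrix. MS missingness is predominantly left-censoring of
   low-abundance peptides, so a global floor is the conservative choice.
   Imputation happens on the raw scale, before any transform: the
   imputed floor then propagates through the same transforms as real
   data.
3. **log2(x+1) + median adjustment** (`log2p1_median_normalize`): the
   target of the per-sample shift is the grand median of the column
   medians. Any common target gives the same matrix up to one additive
   constant; the grand median keeps values in the input's range. The
   post-condition — every column median equal — holds exactly and is
   asserted in the tests.
4. **Replicate collapse** (`collapse_replicates`): arithmetic mean of
   replicate columns on the log scale, one column per cell line.

`lognormalize` (per-sample `ln(1 + 10^4 · x / colsum)`) is provided as
the alternative scaling used by single-cell toolkits; the scale factor
10<sup>4</sup> is that ecosystem's default and is configurable. The two
normalizations are alternatives, not stages of one chain.

**Fold change** is defined as the difference of log2 means (group minus
complement), not the log of the ratio of linear means. The two differ
under skew; the log-mean difference is the one that makes fold changes
additive and antisymmetric, and it is what the Wilcoxon effect-size
filter below uses. Technical reproducibility is summarized by
`compute_cv`: per-feature SD/mean across one line's replicates on the
*linear* scale, excluding features with a missing replicate.

## Differential expression and marker scoring

`wilcoxon_de` runs two-sided one-vs-rest Wilcoxon rank-sum tests per
feature per group, Bonferroni-adjusted by the total feature count, and
flags significance only when **both** |log2 FC| > 2 and adjusted
p < 0.05 hold. Constant features get p = 1 by convention. The `exact`
argument is passed to `stats::wilcox.test`; simulations at 54 samples
use the normal approximation, which the tests verify agrees with
`wilcox.test` and which differs negligibly from the exact tail at these
sample sizes. Under a simulated global null (54 exchangeable samples,
2,000 features) the joint rule yields zero discoveries in ≥95 of 100
runs: the fold-change clause removes the near-separations that survive
Bonferroni by chance.

`cosine_marker_score` implements the published COSG formulation: with
\(\lambda_k\) the cosine similarity between a feature's vector across
lines and group \(k\)'s normalized indicator,

\[ s_k \;=\; \lambda_k \cdot
   \frac{\lambda_k^2}{\mu \sum_j \lambda_j^2 + (1-\mu)\lambda_k^2}, \]

with penalty weight \(\mu\) (default 1) down-weighting similarity to the
other groups. Two choices matter here:

- **Scores are computed on the back-transformed linear scale**
  (`2^v − 1`). The cosine geometry assumes non-negative vectors whose
  norm is dominated by group-restricted signal — true of the sparse
  expression data the score was designed for, and true of linear LFQ
  intensities, but *not* of log2 intensities, which are uniformly
  positive and nearly constant relative to their mean. On the log scale
  a planted 4-fold marker scores ~0.15; on the linear scale it scores
  0.6–0.9 and a perfectly group-exclusive feature scores exactly 1 for
  any \(\mu\).
- A feature with no signal in any line (zero norm) scores 0 by
  convention. A feature *constant and nonzero* across all lines scores
  \((g/n)^{3/2}\) for a group of \(g\) of \(n\) lines under \(\mu = 1\) —
  the value the formulation implies, well below the 0.5 marker flag.

## Glycoproteomics: site-specific glycans

The quantification unit is the *site-specific glycan*: one glycan
composition at one glycosylation site of one protein. Its abundance per
sample is the spectral count — the number of glycopeptide-spectrum
matches with that (protein, site, composition), pooled over peptide
sequence, missed cleavages (0–2) and charge (2–4). Duplicate spectrum
identifiers abort the aggregation, since they would double-count.

Compositions are parsed from `Token(count)` strings with canonical
token order HexNAc, Hex, Fuc, NeuAc, then others alphabetically.
Classification is by mutually exclusive priority:
**sialylated** (any NeuAc) ≻ **fucosylated** (any Fuc) ≻
**high-mannose** (HexNAc = 2 and Hex ≥ 5, the chitobiose core carrying
five or more mannoses) ≻ **other**. The priority is a design decision:
class fractions reported for such data sum to ~100%, implying exclusive
classes, but no tie-break for NeuAc+Fuc glycans is standard; we assign
them to sialylated and document it. High-mannose is operationalized by
its standard biochemical definition. Class fractions enumerate distinct
row keys, not spectral counts, matching how "site-specific glycans" are
counted as a resource statistic.

The **consistency filter** keeps a site-glycan if, in at least one cell
line, it has nonzero counts in *strictly more than half* of that line's
replicates ("more than half" read strictly: 1 of 2 replicates does not
qualify), and reports per row the number of lines where this holds.

## Kinase activity

**Localization filter**: sites with localization probability strictly
greater than 0.75 (class I sites) are kept; missing probabilities drop
with a warning by default.

**KSEA**: for a cell line with per-site log2 fold changes (one line vs
the mean of the rest, the same contrast as protein fold changes), a
kinase with \(m\) measured substrate sites scores

\[ z = \frac{(\bar s - \bar p)\sqrt{m}}{\sigma_p} \]

where \(\bar s\) is its substrates' mean and \(\bar p, \sigma_p\) the
mean and SD of *all* site fold changes in that line. Two-sided normal
p-values are BH-adjusted **within each line across kinases** (the
grouping is a design choice; per-line adjustment matches per-line
activity calling), and a kinase is *active* at FDR < 0.05 with more than
five substrates (m ≥ 6, "more than five" read strictly). Under
exchangeability z is approximately standard normal (verified by
simulation: mean within ±0.1, SD within (0.9, 1.1) over 1,000 kinases),
and z is strictly increasing in any uniform substrate shift.

**Driver screen** (`screen_driver_kinases`): a feature is a driver hit
for a line when, at *both* the total-protein and summed-phosphorylation
level, (a) that line's linear mean is at least 1.5× every other line's
mean, and (b) the line's lowest replicate still exceeds 50% of the
highest replicate observed in any other line. Clause (b)'s reference
("the highest replicate in the rest") is ambiguous between the other
lines' replicates and the top line's own; we default to the stricter
cross-line reading and expose `floor_within` for the other.
Fold comparisons are made on the linear scale after back-transforming
log2 values — a 1.5-fold criterion is naturally a linear statement.
Per-protein phosphorylation for the screen is the sum of the protein's
site intensities per sample on the linear scale.

**Phospho–protein correlation**: Spearman per site against its parent
protein across lines (≥5 shared non-missing lines), binned as strong
(r > 0.6), moderate (0.4, 0.6], weak (0.2, 0.4], none (≤ 0.2).
`adjust_phospho_by_protein` subtracts the parent's log2 value per line,
so residual variation reflects kinase/phosphatase regulation; a constant
parent shifts all values equally and leaves rank correlations intact.

## MS ↔ RPPA comparison

RPPA normalization (`rppa_normalize`) median-centers each antibody
across samples, then each sample across antibodies, on log2 values.
Each step's own post-condition is exact for odd dimensions (the centered
direction's medians are 0); the sequential procedure is *not* idempotent
— re-running it re-centers the antibody direction that the sample step
disturbed — so the tests assert the per-step post-conditions rather
than a fixed point. The optional linearization is the antilog
`2^x`: "squaring" a median-centered log2 matrix would destroy sign
information, so the antilog (the standard normalized-linear convention)
is the only reading that yields a usable linear dataset; it is exposed
via `linearize = TRUE`.

Antibodies map to MS features through a representative accession (one
per antibody, chosen from its target list). Coverage classes partition
the non-phospho panel at a strict 50% detection boundary: `ms_majority`
(detected in more than half of MS samples), `ms_minority` (detected, but
in at most half), `ms_absent` (never detected). Cross-platform agreement
is summarized two ways, per-protein Spearman across lines (values) and
Spearman of per-protein log2 fold changes between two line groups
computed identically on both platforms (fold changes). Because group
averaging suppresses line-level measurement noise while preserving the
planted biological contrast, fold-change concordance systematically
exceeds the median per-protein value correlation — the synthetic panels
reproduce this relationship at calibrated noise (≈0.78 vs ≈0.6).

## CNA association

Copy number is carried as log2(CN ratio + 1), so diploid (ratio 1) maps
to exactly 1 and values are non-negative. `cna_feature_correlation`
computes Spearman correlations between genes' copy-number and features'
abundance across shared lines; *cis* means the feature's own gene.
Because the full gene × feature cross-product is quadratic, trans
scanning defaults to the top-variance subset (100 × 100) with a `full`
mode behind a flag. Hotspot summaries (`cis_trans_summary`) threshold on
|r| (default 0.5, configurable) rather than a p-value — the hotspot use
is pattern-finding across chromosome arms, and no canonical significance
rule exists for it.

## The synthetic-data generator

The generator defines the study conditions every test runs under. Its
model, per feature and layer:

\[ x_{f,\ell,r} = \beta_f + u_{f,\mathrm{lin}(\ell)} + b_{f,\ell}
   + \varepsilon_{f,\ell,r} \quad (\log_2), \]

with base abundance \(\beta_f \sim N(20, 2^2)\) (a typical LFQ dynamic
range on the log2 scale), per-feature lineage shifts
\(u \sim N(0, 0.8^2)\), between-line biological variation
\(b \sim N(0, 0.8^2)\), and replicate noise
\(\varepsilon \sim N(0, 0.2^2)\) (≈14% linear CV, typical technical
replication). Lineage markers replace their lineage shift with
log2(`marker_fold`), default 4-fold. Default panel shape is 20 lines ×
3 replicates in 4 lineages; at 54 lines × 7 lineages the default lineage
sizes are 7/8/8/5/5/5/16, the composition of a typical pan-cancer panel.
Missingness is logistic in standardized log-intensity with the intercept
solved so the overall rate equals `dropout_rate` — low-abundance cells
drop out more, emulating left-censoring, which is also why the pipeline
imputes with the global minimum. One global seed fans out to fixed
per-table child seeds, so adding one generator never perturbs another's
stream and identical configs are bit-identical.

Other layers:

- **Phosphosites** inherit the same variance components; substrate
  sites of each planted (kinase, line) pair shift by `kinase_effect`
  (default +1.5 log2) in that line. Localization probabilities place a
  `loc_below_frac` fraction (default 10%) at or below 0.75.
- **Glyco PSMs** are emitted *exactly* from drawn ground-truth counts
  (Poisson per key × sample, every key guaranteed ≥1 PSM), with peptide
  length, missed cleavages and charge randomized — conservation of
  counts is exact by construction and asserted in the tests. The class
  mixture defaults to 49.7 / 25.2 / 25.1% sialylated / fucosylated /
  high-mannose, the composition typical of IMAC co-enrichment.
- **RPPA** values are antibody-specific affine transforms of the target's
  MS log2 intensity plus Gaussian noise. The default
  `rppa_noise_sd = 1.2` was fixed once by Monte-Carlo calibration so the
  default panel yields a median per-protein MS~RPPA Spearman near 0.6;
  a configurable subset of targets is absent from MS entirely.
- **CNA**: cis genes' latent values correlate with the gene's protein
  line-means at target Spearman `cis_corr`, using the bivariate-normal
  conversion \(\rho_P = 2\sin(\pi\rho_S/6)\), then map monotonically to
  log2(CN ratio + 1); an optional hotspot arm carries genes correlated
  with designated trans features.

**What the generator does not emulate**: spectrum-level data (generation
starts at search-engine output), retention time and m/z, correlated
missingness across features, batch effects, antibody cross-reactivity,
and heavy-tailed intensity noise. Passing tests therefore demonstrate
correctness of the computations and recoverability of planted signal
under a realistic variance budget — not robustness to every artifact of
real instruments.

## Numerical choices and experiment sizes

- Spearman correlations use average ranks for ties
  (`stats::cor(method = "spearman")`); pairs need ≥5 shared non-missing
  lines, otherwise they are excluded and counted.
- KSEA errors on a zero background SD; kinases with no matched
  substrates are omitted rather than scored.
- Validation experiments are sized to be decisive yet quick: the
  brute-force spectral-counting oracle runs on ~1,000 PSMs, the
  consistency-filter oracle on 500 rows × 5 lines × 3 replicates, KSEA
  null calibration on 1,000 kinases over 3,000 sites, KSEA power and the
  driver screen on 100 planted/null panels each, type-I control on
  100 × (54 samples × 2,000 features), and CNA cis recovery on 100
  54-line panels. The CNA and cross-platform recovery experiments run
  the generator without dropout so they measure correlation recovery
  itself rather than the (real, expected) attenuation that global-minimum
  imputation adds under missingness.
- The driver-screen experiments use replicate-only noise (no between-line
  biological variation): the screen's null is *exchangeable* lines, and
  with genuine per-line biology the screen is supposed to fire — that is
  its purpose.

## Known limitations

- Spectral counts are integer and sparse; no saturation or
  detectability model links counts to true glycan abundance.
- KSEA treats substrates as exchangeable draws from the site population;
  correlated substrates (shared peptides, co-regulation) inflate |z|.
- The RPPA affine model has no antibody saturation or off-target
  binding; concordance estimates are therefore upper bounds relative to
  real arrays.
- `run_pipeline` wires the stages for the synthetic panel; applying the
  package to real exports requires only the documented table schemas
  (`read_table`, `read_abundance_matrix`) but no search-engine parsing
  is included.
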