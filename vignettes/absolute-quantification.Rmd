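---
title: "Absolute proteome quantification with anchorQuant: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute proteome quantification with anchorQuant: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorQuant)
```

## The quantification model

Label-free protein-group intensities (iBAQ, LFQ, Top3, PG.Quantity, ...)
are proportional, within an experiment, to the amount of protein injected,
but the proportionality constant is unknown and drifts between runs. The
package's core assumption is the standard anchor-protein calibration: for
proteins spiked at known amounts $A_i$ (fmol, at the MS-injection level),
the measured intensity $I_i$ obeys

$$\log_{10} I_i = a + b\,\log_{10} A_i + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),$$

a straight line in log–log space. `fitAnchors()` estimates $(a, b)$ by
ordinary least squares and `estimateAmounts()` inverts the line for every
protein:

$$\widehat{\mathrm{fmol}} = 10^{(\log_{10} I - a)/b}.$$

With an ideal proportional response $b = 1$; letting $b$ float absorbs
compression of the intensity scale (common for iBAQ at the extremes of the
dynamic range). A spike-in standard spanning several orders of magnitude —
the default synthetic design imitates the UPS2 standard's staggered
decades, 48 proteins in six equal groups from 0.05 to 5000 fmol — anchors
the line across the proteome's abundance range.

OLS on the log scale was chosen over a robust variant because it is the
reproducible baseline and, with $\geq 3$ and typically 48 anchors, single
outliers are visible in $R^2$ rather than silently down-weighted. Anchors
are matched on the *first* accession of a protein group (anchor sheets
list single accessions); an anchor claimed by two groups is ambiguous and
dropped with a warning, and anchors whose intensity was imputed are
excluded by default — an imputed value is not a measurement.

Calibration is fitted **per sample** by default: spike-ins are added per
injection, so each run gets its own response line, which absorbs
run-to-run drift. A pooled fit over all samples (`scope = "pooled"`) is
available when per-run anchor coverage is thin.

## From injection to cell

The experimental-parameters table connects the MS scale to the sample:
per condition it records the extract volume digested $V_s$ (µL), the
protein concentration $c_p$ (µg/µL), the injected amount $m$ (µg), the
culture cell density (cells/mL) and the harvested culture volume.
`toAbsolute()` computes, per protein and sample,

* total fmol in the extract: $\mathrm{fmol}_{\mathrm{total}} =
  \mathrm{fmol}_{\mathrm{MS}} \cdot V_s c_p / m$;
* mass share: $\mathrm{ng/µg} = \mathrm{fmol}_{\mathrm{MS}} \cdot
  M_r(\mathrm{kDa}) \cdot 10^{-3} / m$ (since fmol × kDa × 10⁻³ = ng);
* copy number: $\mathrm{molecules/cell} = \mathrm{fmol}_{\mathrm{total}}
  \cdot 10^{-15} N_A / N_{\mathrm{cells}}$, with $N_A =
  6.02214076 \times 10^{23}$ (exact SI value).

The harvested-volume column is parsed in µL, following the canonical
table schema, with a `cultureVolumeUnit = "mL"` switch because most wet-lab
records use millilitres. The digested extract is assumed to represent the
whole harvested biomass; if only a fraction of the pellet was lysed, cell
counts must be scaled by the caller.

### Enrichment and concentration steps

When a subproteome (membrane, secretome) is enriched or concentrated
during preparation, measured amounts overstate native per-cell amounts by
an unknown factor $f$. Two estimators are provided. With spiked
enrichment standards of known stock concentration, dilution and volume,
the expected MS-share of each standard is computable from the parameters
table, and $f$ is the median over standards of measured/expected, averaged
over the condition's replicates (`computeEnrichment()`). Alternatively,
externally measured SRM amounts of listed proteins give
$f$ as the median of calibrated/supplied ratios (`srmEnrichment()`); SRM
fmol are interpreted on the per-injection basis, the same basis as the
calibrated `fmolMS`. The median is used in both because two or three
standards admit no meaningful outlier model and the median degrades
gracefully.

Correction divides `fmolTotal` (and hence molecules/cell) by $f$,
identically for the "Enrichment" and "Concentration" modes: both inflate
apparent abundance multiplicatively, so a single well-defined contract is
preferable to two speculative formulas; the mode is carried as metadata.
The mass share `ngPerUg` is deliberately *not* corrected — it describes
the composition of the measured (enriched) fraction.

## Preprocessing choices

Preprocessing operates in log2 space, the convention of proteomics QC,
while calibration uses log10, the convention of standard curves; the
report object always stores raw-scale intensities so the two never mix.
Zero intensities are coerced to missing at ingestion: label-free engines
write 0 for "not quantified", and a literal zero would be $-\infty$ after
the log transform.

* **Validity filtering** keeps a protein if at least one replicate group
  reaches the minimum fraction of observed values (default 2/3, i.e. 2 of
  3 replicates), the common label-free rule.
* **Normalization**: `median` shifts each sample's log2 values so all
  sample medians equal the global median of medians; `quantile` replaces
  each value by the mean of its quantile across samples (ties averaged,
  delegated to `limma::normalizeQuantiles`, which interpolates through
  missing values); `total_sum` rescales raw values to equal sample
  totals. Samples with fewer than two finite values are left alone with a
  warning rather than failing the run.
* **Imputation** models left censoring by the Gaussian downshift: missing
  values are drawn from
  $N(\bar{x} - 1.8\,s,\; (0.3\,s)^2)$ of the sample's observed log2
  distribution. The 1.8/0.3 defaults are the field-standard downshift
  parameters for left-censored label-free data. Imputed cells are marked
  and the mark travels to the final table as `provenance`, so every
  absolute value can be traced to a measurement or a draw. Normalization
  runs **before** imputation, so draws come from the corrected
  distributions.
* **Group inference** tokenizes sample names on `_`, `-`, `.`, space,
  letter/digit boundaries and lower-to-upper case changes; a trailing
  integer, roman numeral (≤ IV) or single letter is a replicate token, and
  labels sharing all other tokens form a group. Labels without a partner
  stay singleton groups. The procedure is deterministic and
  order-invariant.

The consultant (`consult()`) ranks (method, normalization) candidates by
mean per-sample anchor $R^2$ — the one quantity the calibration itself
certifies — with ties broken by the larger mean anchor count, then
lexicographically, so the recommendation is reproducible. Note that a
per-sample constant shift (what median normalization removes) leaves each
sample's own $R^2$ unchanged; the consultant therefore discriminates
between normalizations only when distortions are not purely multiplicative
per run, which is the realistic failure mode it exists for.

## What the synthetic generator emulates — and what it does not

All validation runs on generated data with known truth
(`syntheticSpec()`, `makeReport()`, `makeGroupingBenchmark()`,
`makeEnrichmentScenario()`):

* per-protein amounts log-uniform over 10⁻²–10³ fmol (about the dynamic
  range label-free experiments resolve);
* intensities from the log-log response with multiplicative lognormal
  noise, `noiseSigma` being the sd of the log10 response (0.1–0.15 ≈
  26–41% CV, typical of label-free protein-level precision);
* missingness as an intensity threshold (left censoring) plus Bernoulli
  dropout; planted `CON__`/`REV__` rows; dialect-faithful headers for all
  four supported engines.

The naming benchmark draws 2–6 conditions × 2–5 replicates per set,
separators from `_`, `-`, `.`, space or none, replicate tokens as
integers, letters or `repN`; 30% of sets use timepoint-series condition
names (`t0`, `t1`, ...) and 30% of plain condition words carry a digit
suffix — frequencies fixed a priori from common naming practice. Under
these conditions the grouping rule scores ~98% exact partitions on 500
sets; the residual failures are genuinely ambiguous names (a series like
`qpr0…qpr5` concatenated directly with integer replicates), which no
rule could resolve without external information.

The generator does **not** emulate peptide-level effects (shared
peptides, digestion efficiency, ionisation bias), intensity-dependent
missingness curvature, batch structure, or correlated noise between
samples. Passing tests therefore certify the *arithmetic and inference*
of the pipeline, not the biases real search-engine output inherits from
peptide space.

## Numerical and degenerate-input conventions

* Fits require ≥ 3 usable anchors and nonzero variance of log10(fmol);
  both violations are errors, not silent fallbacks.
* $R^2$ is computed as $1 - \mathrm{RSS}/\mathrm{TSS}$ on the fitted
  points (TSS = 0 gives $R^2 = 1$), and equals the squared Pearson
  correlation, a cross-checked invariant.
* Every stochastic operation takes an explicit integer seed and restores
  the caller's RNG state; pipeline outputs contain no timestamps, so one
  config + seed reproduces byte-identical files.
* An empty filter result is a warning, not an error — downstream code
  decides whether an empty table is fatal.
* Validation problem sizes: 50–400 proteins, 1–2 conditions × 1–4
  replicates, 500 benchmark sets — small enough that the whole suite runs
  in seconds while the statistical checks (3-standard-error bands,
  binomial dropout counts, median-relative-error bounds) remain
  informative.

## Known limitations

* Only protein-group-level reports of the four named engines are read; no
  peptide/PSM tables, no mzML, no spreadsheets (export anchor and
  parameter sheets to TSV/CSV).
* Calibration assumes the anchors share the sample's matrix behaviour;
  heavy matrix effects or a saturating detector break the single-line
  model and surface only as a lower $R^2$.
* The enrichment correction is a single multiplicative factor per
  condition; protein-specific enrichment efficiencies are not modelled.
* SRM amounts are consumed, never computed, and are assumed to be on the
  per-injection scale.
* Condition-to-sample mapping requires the condition label to equal or
  prefix the sample label; anything else needs the caller to rename.
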