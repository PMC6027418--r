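---
title: "Consensus pairwise differential expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus pairwise differential expression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftDE)
```

## The problem

Liver grafts biopsied shortly after reperfusion carry a transcriptional
signature of acute-phase injury. Contrasting grafts from recipients who later
developed tumour recurrence against those who did not is a small-cohort,
two-group bulk RNA-seq problem: here 6 recurrence profiles (group A) versus
5 non-recurrence profiles (group B), eleven in total. At these sample sizes
a model-based test has little power to estimate per-gene dispersions, and
the workflow this package implements instead takes a conservative,
ratio-based route: demand that a gene's direction of change replicate in
*every* individual cross-group comparison.

## The procedure

1. **Quantification.** Counts become RPKM:
   $\mathrm{RPKM}_{gs} = 10^9\, c_{gs} / (L_g T_s)$, with $L_g$ the gene
   length in bp and $T_s$ the per-sample mapped total. By default $T_s$ is
   the column sum of the count matrix; whether a mapped total should count
   all genome-mapped reads or only gene-assigned reads is a convention the
   caller can impose through the `total_mapped_reads` override. A useful
   identity for testing: with column-sum totals,
   $\sum_g \mathrm{RPKM}_{gs} L_g = 10^9$ exactly in every sample.

2. **Pairwise lists.** Each of the $|A|\times|B|$ ordered sample pairs gets
   its own up/down gene lists from the pseudocounted ratio
   $(\mathrm{RPKM}_A + c)/(\mathrm{RPKM}_B + c)$ at a per-pair fold
   threshold $t$ (default 2): 30 lists for the 6-vs-5 design.

3. **Merge and consistency filter.** The lists are merged; a gene is kept
   only if its calls never disagree in direction. Strict mode (default)
   requires a call in the same direction in *all* pairs; majority mode
   (fraction $f \in (0.5, 1]$) tolerates a minority of absent or opposite
   calls. Everything else that was called at least once is `removed`;
   uncalled genes are `null`.

4. **Averaging and selection.** The consensus effect size is the mean of
   per-pair log2 ratios (the log geometric-mean ratio), and candidates are
   genes whose consensus fold change is *strictly* greater than the cutoff
   (default 2) or below its reciprocal — "more than two-fold" is a strict
   inequality, so a gene at exactly 2.0 is not selected.

5. **Over-representation.** Candidates are tested against gene-set
   collections (GMT) with the one-sided hypergeometric upper tail,
   $P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, adjusted across
   sets with Benjamini–Hochberg. The default universe is every gene that
   survived the expression floor — the population from which candidates
   could actually have been drawn.

6. **qPCR validation.** Relative quantification uses the Livak
   $2^{-\Delta\Delta Ct}$ model at fixed efficiency 2:
   $\Delta Ct = Ct_\text{target} - Ct_\text{reference}$ per sample,
   baseline $=$ the arithmetic mean of calibrator $\Delta Ct$ values
   (healthy-donor livers), $\Delta\Delta Ct = \Delta Ct - \text{baseline}$.
   Groups are compared two-sidedly with the Mann–Whitney U test.

7. **Correlation panels.** Candidate genes are correlated (Pearson) against
   interaction-neighbour genes supplied as flat files, on the log2 scale,
   with a positive verdict at $r > 0$ and $p < \alpha$ (default 0.05).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `per_pair_fold_threshold` | 2 | fold | the within-pair call; the source procedure leaves it unstated, so it is an explicit, logged flag |
| `pseudocount` | 0.1 | RPKM | stabilises ratios where one side is zero; 0.1 RPKM is far below biologically meaningful expression |
| `expression_floor` | 0.1 | RPKM | genes never reaching it in any sample are pure pseudocount noise and are excluded (logged) |
| `mode` / `majority_fraction` | strict / 0.9 | — | "inconsistent changes were removed" reads as absolute, hence strict by default |
| `fold_cutoff` | 2 | fold | candidate selection; strict inequality |
| `alpha` | 0.05 | — | significance level throughout |

Two deliberate interpretation choices, both exposed as flags because the
source procedure does not pin them down: the consensus average is computed
on the **log2 scale** (geometric-mean ratio), which makes relabelling the
groups exactly antisymmetric, with an arithmetic-mean-of-ratios mode
(`ratio_scale = "linear"`) for fidelity comparisons; and the calibrator
baseline averages **ΔCt values** (the Livak convention) rather than linear
expression levels — the two differ by a Jensen gap whenever donors vary,
and `baseline_scale = "linear"` provides the alternative.

## What the simulator emulates — and what it does not

`simulate_counts()` draws negative-binomial counts with mean
$\mu_{gs} = m\, a_g\, \ell_s\, f_g^{[s \in A]}$: a grand baseline $m$,
log-normal gene abundance $a_g$ (sdlog 1, so RPKM spans realistic orders of
magnitude), a uniform library factor $\ell_s$ (0.8–1.25), and the planted
fold $f_g$ applied to group A. Dispersion enters as
$\mathrm{Var} = \mu + \phi\mu^2$; $\phi = 0$ degenerates to Poisson. The
count model is a deliberate choice — the workflow being emulated states
none — and NB is the field's standard overdispersed model.

`simulate_figure2_fixture()` reproduces the qualitative candidate pattern:
ITGA8, SELE, HFE and CDH26 planted down (folds 1/4 to 1/8) and HLA-DQA2 and
CD274 planted up (folds 4 and 6) among 600 null genes, with the designated
"cell adhesion molecules" set holding the planted genes plus four null
decoys. Its defaults — dispersion 0.01, baseline mean 1000 counts, planted
abundance factors drawn in [0.8, 2] — were fixed from a power argument
before any testing: for the weakest planted effect (fold 4 at baseline
$\approx 800$ counts), the per-pair log2-ratio noise is about 0.2, putting
the per-pair miss probability near $10^{-6}$, so a unanimous 30-pair
consensus recovers all six plants with high probability while a null gene
essentially never passes 30 unanimous two-fold calls. These magnitudes are
simulation choices: the real screen's fold sizes are unknown beyond "more
than two-fold". The fixture's problem size (606 genes × 11 samples, 20
replicate seeds in the property suites) keeps every check comfortably fast
while leaving the statistics non-trivial.

What the simulator does **not** model: correlated genes (each gene draws
independently), sample-level covariates, batch structure, length biases
beyond the RPKM definition, or the real cohort's expression distribution.
Passing the planted-recovery suite therefore shows the procedure is
*correct and well-calibrated under its own assumptions*, not that the
original cohort's 75-gene or six-gene lists would be reproduced — those
depend on unpublished raw data.

`simulate_ct_table()` is constructed to invert exactly: the reference gene
is flat, calibrator and non-recurrence samples share a common target
ΔCt, and recurrence samples are shifted by $-\log_2 f$; at zero cycle noise
$2^{-\Delta\Delta Ct}$ returns the planted fold identically, which anchors
the closed-loop test. Gaussian cycle noise is added independently to every
Ct value.

## Numerical and degenerate-input choices

- Counts must be integers; fractional values are rejected rather than
  rounded (no multi-mapping fractionation convention is assumed).
- Gene identifiers are opaque and case-sensitive; no alias resolution.
- Per-pair boundary convention: a gene is called up when its
  pseudocounted fold is `>=` the threshold (and down at `<=` the
  reciprocal); candidate selection is strict (`>` / `<`).
- Ties in the output ordering break lexicographically by gene id, so
  outputs are byte-stable across runs.
- Mann–Whitney uses the exact permutation null when the pooled sample size
  is at most 12 and values are untied, and the normal approximation with
  tie correction otherwise.
- Fisher's 2×2 test returns 1 for any table with an empty margin (only one
  table is consistent with the margins).
- Correlations require at least 3 complete pairs and non-zero variance on
  both sides; anything less is an explicit error, not an `NA`.
- Missing Ct values are kept as `NA`, excluded pairwise, and counted in
  log messages; samples lacking the reference gene are dropped with a
  warning at table construction.

## A worked run

```{r pipeline}
fx <- simulate_figure2_fixture(seed = 1)
run <- consensus_de_pipeline(fx$counts)
length(run$pairwise)                       # 30 pairwise lists
run$candidates[, c("gene", "direction", "fold_change")]
enrich(run$candidates$gene, fx$sets,
       attr(run$pairwise, "genes"))[1, c("set", "overlap", "p_value")]
```

## Known limitations

- The procedure is ratio-based by design: no dispersion estimation, no
  p-values at the DE stage, and power depends directly on the per-pair
  threshold. Single outlier samples veto genes in strict mode — that is
  the point of the filter, but it makes the gene list sensitive to sample
  quality.
- Over-representation treats genes as exchangeable; no gene-length or
  expression-level bias correction is applied to the hypergeometric test.
- The qPCR model fixes amplification efficiency at 2; efficiency-corrected
  designs need upstream calibration the package does not perform.
- Headline counts from the motivating cohort (the 75-gene adhesion list
  and the identity of its six candidates) are not reproducible from code
  alone because the underlying sequencing data are not public; the
  package's claims are therefore calibrated on planted synthetic truth.
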