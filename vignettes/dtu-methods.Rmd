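---
title: "Models and methods behind dtukit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dtukit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dtukit tests for differential transcript usage (DTU): changes across
conditions in the *within-gene proportions* of a gene's isoforms, which can
occur with or without a change in the gene's total expression. This
vignette describes the statistical models, the data conventions, the
tunable parameters, and the design choices made where more than one
reasonable implementation exists. It states no empirical claim that the
package's tests and acceptance script do not themselves compute.

## Input conventions: counts from abundance

Quantifiers such as Salmon report, per transcript and sample, a relative
abundance (TPM), an effective length, and an estimated fragment count.
Estimated fragment counts scale with transcript length: a longer isoform
yields more fragments at equal molarity. If isoform usage shifts between
isoforms of different lengths, raw counts change the apparent gene total
even when gene expression is constant, which biases proportion estimates.
`counts_from_abundance()` therefore supports three conventions:

* **raw** — the estimated fragment counts, unchanged;
* **scaledTPM** — each sample's TPM vector rescaled to sum to that
  sample's total mapped reads (taken as the column sum of `NumReads`).
  These counts do *not* scale with transcript length, so proportions of
  scaledTPM counts equal proportions of abundance. This is the recommended
  input for DTU testing and the pipeline default;
* **lengthScaledTPM** — TPM first multiplied by the transcript's average
  effective length over samples, then rescaled per sample. Appropriate for
  gene-level analyses, not for DTU.

For gene-level differential expression the recommended input is instead
raw counts summarized per gene with an abundance-weighted average
transcript length offset, which `summarize_to_gene()` provides.

## Pre-filtering

`dm_style_filter()` applies three rules before modeling: a transcript must
reach a count of `min_feature_expr` (default 10) in at least `n.small`
samples and a within-gene proportion of `min_feature_prop` (default 0.1)
in at least `n.small` samples, and the gene total must reach
`min_gene_expr` (default 10) in all `n` samples, where `n.small` defaults
to the smallest condition-group size. Proportions are computed against
gene totals over all transcripts present before any removal, in a single
pass; genes with fewer than two surviving transcripts are dropped, since
usage is undefined for a single isoform. The reference workflow these
rules follow does not state whether proportions are recomputed after
transcript removal; the single-pass reading is frozen here and tested
against a literal enumeration oracle.

The proportion rule deliberately removes small effects: a transcript
moving from 0% to 9% of its gene is filtered at the 10% threshold.

## The Dirichlet-multinomial test

For one gene with $K$ transcripts, sample $i$ contributes counts
$y_{\cdot i}$ with total $n_i$. The Dirichlet-multinomial (DM) model treats
the total as fixed and the proportions $\pi$ as the quantity of interest,
with a single gene-level precision $\gamma$ ($\alpha_k = \gamma\pi_k$).
The log-likelihood (multinomial coefficient omitted — it cancels in every
likelihood ratio):

$$\ell(\pi, \gamma) = \sum_i \Big[\ln\Gamma(\gamma) - \ln\Gamma(n_i+\gamma)
 + \sum_k \big(\ln\Gamma(y_{ki}+\gamma\pi_k) - \ln\Gamma(\gamma\pi_k)\big)\Big]$$

Precision relates to dispersion via $d = 1/(1+\gamma)$: the higher the
precision, the closer proportions stay to their expectation across
replicates. As $\gamma \to \infty$ the DM converges to the multinomial.

Proportions may depend on the design through a softmax (multinomial-logit)
link: $\pi_{ik} \propto \exp(x_i^\top \beta_k)$ with the last transcript as
reference. The gene-level test compares the full design against the design
without the tested coefficient by a likelihood ratio with
$(K-1)\times q$ degrees of freedom ($q$ = number of tested coefficients).
Transcript-level tests collapse the gene to (focal, rest) two-category
counts — a beta-binomial — reusing the gene's precision, with $q$ degrees
of freedom; for a two-transcript gene the two transcript tests are
mirror images and return identical statistics.

### Numerical choices

* Proportion maximization uses BFGS on the unconstrained softmax
  coefficients with an analytic gradient, started from the pooled
  empirical log-ratios and restarted until the log-likelihood improves by
  less than 1e-8. The restart matters: a cold Hessian on the steep DM
  surface at high precision can otherwise stall.
* $\gamma$ is estimated per gene by a bounded 1-D search on
  $\log\gamma \in [\ln 10^{-2}, \ln 10^{6}]$, maximizing the *Cox-Reid
  adjusted* profile likelihood: the profile log-likelihood minus
  $\tfrac12 \log\det I(\hat\beta)$, the observed information of the fitted
  proportion coefficients. Without the adjustment the precision is biased
  upward at realistic sample sizes and the test becomes anti-conservative.
* Precision is profiled under the **null** design. Profiling under the
  full design removes condition-associated variability from the dispersion
  and measurably inflates the type-I error for two-transcript genes at
  6 vs 6; null-design profiling keeps the test calibrated, at the price
  that a *total* isoform switch (zero within-group variance) is partially
  confounded with extreme dispersion and receives a strong but finite
  likelihood ratio rather than an unbounded one. This trade-off is
  inherent to a single-precision DM; the package chooses calibration.
* Proportions are floored at 1e-12 inside the likelihood so boundary fits
  stay finite; the LR is floored at 0; p-values are `NA` only on genuine
  numerical failure, and `sanitize_pvalues()` maps `NA` to 1 before
  stage-wise testing (a failed test is a non-discovery).
* No precision moderation is applied (shrinkage factor 0), and no plug-in
  common precision is substituted for degenerate genes.
* `estimate_common_precision()` maximizes the summed adjusted profile
  likelihood over a seeded random subset of genes (default fraction 0.1).
  Because the per-gene search is a bounded global optimization, the common
  value serves as the reference starting bracket and a dataset-level
  summary rather than changing any per-gene optimum.

## The negative-binomial interaction test

The second path models each transcript marginally. For transcript $t$ the
counts are augmented to (this, rest-of-gene) pairs per sample — $2n$
observations — and an NB GLM with log link is fit with designs

```
full:    ~ sample + feature + condition:feature
reduced: ~ sample + feature
```

where `feature` indicates the focal transcript against the rest. The
interaction asks whether the focal proportion depends on condition after
accounting for per-sample totals; the LRT has 1 df in a two-group design.
Log size factors enter as offsets; size factors are median-of-ratios on
the transcript count matrix, normalized to geometric mean 1, computed once
(not per augmented pair).

Dispersion ($\mathrm{Var} = \mu + \alpha\mu^2$) is per transcript:

1. an MLE maximizing the Cox-Reid adjusted profile likelihood on
   $\log\alpha \in [\ln 10^{-8}, \ln 30]$;
2. a parametric trend $\alpha(\mu) = a_1/\mu + a_0$ fit by iterated
   gamma-family regression with outlier-ratio trimming;
3. maximum-a-posteriori shrinkage toward the trend under a log-normal
   prior whose variance is the spread of log residuals (MAD-based) minus
   the expected sampling variance $\psi'((m-p)/2)$, floored at 0.25.
   Transcripts whose MLE sits more than twice the residual spread *above*
   the trend are dispersion outliers and keep their unshrunken MLE
   (shrinkage is one-sided, cap-free).

GLM fits use iteratively reweighted least squares with a fixed-dispersion
NB family; non-converged fits yield a missing p-value, reported rather
than fatal. Per-gene screening p-values aggregate the minimum transcript
p-value with the Šidák formula $1-(1-\min_t p_t)^{K}$ and are BH-adjusted
across genes; BH is used rather than the reference's q-value estimator for
transparency, and alternative aggregation schemes are out of scope.

## Stage-wise testing and OFDR

`stage_wise_adjust()` screens genes and confirms transcripts at a target
*overall false discovery rate* (OFDR): the expected fraction of screened
genes that either contain no DTU at all or contain a falsely confirmed
transcript. The target `alpha` must be fixed in advance; re-thresholding
the output at other levels is invalid.

1. Screening: BH over gene p-values (skipped when the input is already
   FDR-adjusted, as with the NB path's q-values); screened set $S$.
2. Confirmation level $\alpha' = \alpha\,|S|/G$ with $G$ the screened
   universe size.
3. Within each screened gene, Holm over the $K$ transcript p-values with
   the Shaffer reduction: on the simplex, a changed transcript implies a
   second changed transcript, so the smallest p-value faces $K-1$ (not
   $K$) hypotheses. The multiplier sequence is $\max(K-j, 1)$ for the
   $j$-th smallest p-value with a running maximum; a two-transcript gene
   leaves both transcripts at their raw p-value.
4. Reported transcript values are the within-gene adjusted p-values scaled
   by $G/|S|$ and capped at 1, so comparing against `alpha` enacts
   $\alpha'$; this scaled form is decision-equivalent to comparing the
   unscaled values against $\alpha'$.

Gene and transcript identifiers are truncated to their first 15 characters
before joining, which strips Ensembl/GENCODE version suffixes.

Because the DM transcript-level tests can exceed their nominal FDR, the
pipeline applies a post-hoc filter on the DM path (only): transcripts
whose per-sample proportion standard deviation (unbiased, $n-1$) falls
below 0.1 get p-value and adjusted p-value set to 1, without recomputing
the adjustment. The statistic ignores condition labels. It is not applied
to the NB path, which controls its error rates without it.

## The benchmark simulator

`simulate_truth()` and `simulate_counts()` generate count-level benchmark
data with known DGE/DTE/DTU status. Genes carry 1–7 isoforms
(probabilities 0.35, 0.30, 0.18, 0.09, 0.05, 0.02, 0.01); baseline
per-transcript abundances are log-normal ($\log_2$TPM ~ N(2.5, 2)) with
30% structural zeros; transcripts whose expected baseline count falls
below 10 are thresholded to zero abundance and every gene keeps at least
one expressed isoform. Categories receive exactly
$\lfloor \text{frac} \times n_\text{genes} \rfloor$ genes each (so 15,017
genes at 10% fractions give 1,501 per category and 10,514 null):

* **DGE** — all expressed isoforms scaled by a common fold change
  $2^{U(1, 2.58)}$ (fold 2–6) in a fair-coin-chosen group; proportions
  unchanged, so these genes are DGE- and DTE-true but never DTU-true.
* **DTE** — one randomly chosen expressed isoform scaled. The gene total
  changes, so the gene is always DGE-true; when other expressed isoforms
  exist, every expressed isoform's proportion shifts and the gene (and all
  its expressed isoforms) are DTU-true; when the scaled isoform was the
  only expressed one, the gene is DGE-true only.
* **DTU** — the TPMs of two expressed isoforms with distinct abundances
  are exchanged in one group (or the sole expressed isoform exchanged with
  an unexpressed one); gene totals are conserved exactly, so these genes
  are DTU- and DTE-true but not DGE-true. DTU genes are drawn only from
  genes with at least two annotated isoforms, where a swap exists.

Expected fragment counts are proportional to group TPM × effective length,
scaled to per-sample library sizes (default Uniform(31.4, 38.5) million
reads scaled by $n_\text{genes}/15017$, holding per-gene depth at
genome-wide-experiment levels); counts are negative-binomial with
dispersion $\alpha(\mu) = 4/\mu + 0.05$ times log-normal jitter (sdlog
0.3), either per transcript ("main") or shared within a gene matched on
the gene-level mean ("fixed_per_gene"). Transcript lengths are log-normal
(median 1.8 kb); effective length is length − 200, floored at 50.
A Salmon-like quantification set is emitted with TPM recomputed from the
realized counts, so the import and counts-from-abundance code paths are
exercised end to end.

What the simulator does **not** emulate: read-level sampling,
quantification uncertainty (counts are generated directly, so the extra
transcript-level noise a quantifier introduces is absent), fragment-GC
bias, unannotated transcripts, and correlated library composition effects.
Passing calibration on these data therefore shows the statistical
machinery is sound under NB noise with realistic depth and isoform
structure, not that real-data FDR will match exactly.

## Evaluation conventions

`fdr_tpr()` uses FDR $= FP/\max(1, FP+TP)$ (empty calls give 0) and TPR
against the truth universe; `ofdr_sensitivity()` applies the OFDR
definition above with identifiers compared after 15-character truncation,
excludes screened genes missing from the truth tables from both numerator
and denominator (reported as a diagnostic count), and reports sensitivity
as the fraction of true DTU transcripts confirmed. The evaluation universe
is the post-filter gene and transcript set.

## Problem sizes used in the checks

The packaged checks run at deliberately moderate scale, chosen as the
smallest sizes at which the statistical properties are stable: null-DM
calibration on 500 genes (6 vs 6, precision 20, totals ~800), the mixed
benchmark on 1,000 genes with default fractions, and property tests on
dozens-to-hundreds of random fixtures. The genome-scale category
arithmetic (15,017 genes) runs in full since it is cheap. Precision
recovery uses 24 samples where the estimator's sampling error is small
enough for a 25% relative-error bound.

## Known limitations

* Only full-rank fixed-effect designs; the tested path is the two-group
  comparison with a single tested coefficient.
* A single precision per gene (the DM path) underfits genes whose isoforms
  have genuinely different biological variability; the NB path models
  per-transcript dispersion and is the more robust default on that axis.
* A total isoform switch receives strong but finite evidence from the DM
  path (see the calibration trade-off above); the NB path detects it
  without that confound.
* No bootstrap/Gibbs inferential replicates, no time-course stage-wise
  modes, no functional-consequence annotation.
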