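---
title: "Reference-gene stability analysis: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability analysis: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
library(dplyr)
```

## The problem

RT-qPCR reports a quantification cycle Cq per reaction: the PCR cycle at
which fluorescence crosses a threshold. Cq is (approximately) linear in the
log2 of the starting template amount — one cycle less means roughly twice
as much template, exactly twice when the amplification efficiency is
perfect. Because loading, RNA quality, and reverse-transcription yield vary
between samples, a target gene's Cq is only interpretable relative to
reference genes measured in the same samples. A reference is useful exactly
to the extent that its expression is constant across the conditions under
study, and that must be demonstrated, not assumed — and demonstrated per
condition: genes stable across tissues need not be stable across
developmental stages, still less across their interaction. This package
implements the four standard stability algorithms, their aggregation, and
a simulation framework to validate all of it against known truth.

## Data model

The canonical input is a long table with columns `sample`, `gene`,
`bio_rep`, `tech_rep`, `cq` plus a design mapping `sample → (tissue,
stage)`. Cq must lie in (0, 45]: values above 45 cycles are beyond common
cycler limits and treated as non-detects (rejected at read time, with the
row number). Technical replicates are collapsed by the arithmetic mean of
Cq (`collapse_technical_replicates()`): Cq is already a log-scale quantity,
so mean-of-Cq corresponds to a geometric mean of template amounts, the
community convention; a median policy is available for outlier-prone
plates. After collapsing, every (gene, sample) cell must be unique, and the
stability engines require a complete gene × sample grid — the default on
missing cells is a hard error, with `drop_incomplete_samples()` as the
explicit opt-in that keeps all pairwise statistics balanced. Wherever a
standard deviation is named it is the sample SD (n−1), except BestKeeper's
"SD (±Cq)", which that tool defines as a mean absolute deviation (below).

## Amplification efficiency

A standard curve fits Cq against log10 relative concentration of a tenfold
dilution series by ordinary least squares. The percent efficiency is

$$E = \left(10^{-1/\text{slope}} - 1\right) \times 100,$$

so a slope of $-1/\log_{10} 2 \approx -3.322$ cycles per decade gives
E = 100% (perfect doubling). Fits require at least three distinct dilution
levels and a negative slope. The conventional primer acceptance window is
90–110%, boundaries inclusive (`check_efficiency_range()`). Downstream,
efficiencies enter as fold-per-cycle values $E_f = 1 + E/100$; the default
everywhere is $E_f = 2$, mirroring the convention of the classic
spreadsheet tools, with gene-specific values accepted from a fitted
efficiency table.

## The four stability measures

All ratio-based engines work on relative quantities
$q_{ij} = E_{f,i}^{\,Cq^{\min}_i - Cq_{ij}}$, calibrated per gene to its
most abundant sample so $q \in (0, 1]$.

**geNorm.** For genes $j, k$ the pairwise variation is
$V_{jk} = \mathrm{SD}_j\!\left[\log_2 (q_j/q_k)\right]$ and the stability
measure is $M_j = \mathrm{mean}_{k \ne j} V_{jk}$ (log2 units; lower is
more stable). Ranking proceeds by iterative exclusion: recompute $M$ on the
surviving set, drop the gene with the largest $M$ (ties broken
deterministically by dropping the later gene in input order), until two
genes remain. Those two cannot be resolved — their mutual log-ratio SD is
all that is left — so both take rank 1 and the next gene takes rank 3
(competition ranking). The reported per-gene value is the M at exclusion
time (the final pair shares its mutual M); first-round M on the full panel
is also emitted (`m_all`). Removing the worst gene can never increase the
survivors' average M: the average M over a set equals the average over
gene pairs of $V_{jk}$, and the removed gene's pairs average above the
overall mean, which is why the exclusion path is monotone (tested).

**Number of references.** $NF_n$ is the per-sample geometric mean of $q$
over the $n$ top-ranked genes, and
$V_{n/n+1} = \mathrm{SD}\!\left[\log_2(NF_n / NF_{n+1})\right]$ for
$n = 2, \dots, k-1$. The recommended number of references is the smallest
$n$ with $V$ below the cutoff (0.15 by convention, a tunable parameter):
past that point an additional gene no longer moves the normalization
factor.

**NormFinder.** On the working scale
$x_{ij} = \log_2(E_{f,i})\,(\overline{Cq}_{i\cdot} - Cq_{ij})$, expression
is modeled as gene effect + sample effect + noise with per-gene variance
$\sigma_i^2$. Two-way centering removes gene and sample effects, but the
centered residuals of gene $i$ still contain a leakage of the *other*
genes' noise through the per-sample means:
$E[v_i] = \sigma_i^2 (1 - 2/k) + \overline{\sigma^2}/k$, where
$v_i = \sum_j r_{ij}^2/(n-1)$. Inverting this linear system gives the
unbiased estimator

$$\hat\sigma_i^2 = \frac{k}{k-2}\left(v_i - \frac{\bar v}{k-1}\right),$$

which is why at least three genes are required. The reported stability is
$SV_i = \sqrt{\max(\hat\sigma_i^2, 0)}$; the unclamped estimate is kept in
the output (`var_est`) because the clamp, while necessary before the square
root, inflates the mean for genes whose true variance is near zero. The
test suite verifies the estimator against the closed-form solve of the
linear system on arbitrary data, and its unbiasedness by Monte-Carlo.

In grouped mode (tissue, stage, or their interaction), the same estimator
runs within each group, the gene × group mean table is double-centered to
give intergroup deviations $d_{ig}$, the between-group variance component
$\hat\gamma^2 = \max\!\big(\sum d_{ig}^2 / ((k-1)(G-1)) -
\mathrm{mean}(\hat\sigma^2_{ig}/n_g), 0\big)$ shrinks them,
$\tilde d_{ig} = d_{ig}\,\hat\gamma^2/(\hat\gamma^2 +
\hat\sigma^2_{ig}/n_g)$, and

$$SV_i = \frac{1}{G} \sum_g \left[\,|\tilde d_{ig}| +
\sqrt{\frac{\hat\gamma^2\,\hat\sigma^2_{ig}/n_g}
{\hat\gamma^2 + \hat\sigma^2_{ig}/n_g}}\,\right].$$

A gene that is quiet within groups but systematically shifted between them
is thus still penalised. Each analysis condition maps to a grouping:
ungrouped when none is given; `"tissue"`, `"stage"`, or `"tissue:stage"`
otherwise, and the fit records which was used.

**BestKeeper.** Works directly on Cq. Per gene: mean Cq, the mean absolute
deviation about the mean (the "SD ±Cq" of the original applet — note this
is *not* the n−1 SD), CV = 100·MAD/mean, and the Pearson correlation of
the gene's Cq with the BestKeeper index, the per-sample geometric mean of
all candidates' Cq (including the gene itself, the applet behaviour; an
option excludes it). The default stability ranking is ascending MAD. The
tool's own description emphasises the correlation, but its dispersion
column is what orders published tables (values well above 1 cannot be
correlations), so MAD-ascending is the default and `rank_by = "abs_r"` is
available; both statistics are always reported. Zero-variance genes have
undefined r and are ranked by MAD.

**Comparative ΔCt.** For every gene pair, the SD over samples of
$\Delta Cq = Cq_i - Cq_l$; gene $i$'s stability is the mean of its pair
SDs. With all efficiencies equal to 2 this is *exactly* first-round geNorm
M — $\log_2(q_i/q_l)$ is an affine function of $Cq_i - Cq_l$ — an identity
the suite checks to 1e-10 on random datasets, which also cross-validates
the two independent implementations.

## Comprehensive ranking and comparison

Each method contributes a competition-ranked table (ties share the minimal
rank; the next distinct value's rank is 1 + the number of strictly better
genes). The aggregate stability of gene $i$ is the geometric mean of its
four ranks, $(\prod_m r_{im})^{1/4}$, displayed half-up to 2 decimals
(matching the spreadsheet rounding of the field's tools) while the final
ranking uses full precision. Treating the "weights" as plain ranks is
confirmed by a shipped benchmark (`published_component_ranks()`): the
transcribed per-method ranks of 14 candidate genes in two licorice species
under three conditions reproduce every published comprehensive value to 2
decimals, e.g. $(1 \cdot 1 \cdot 3 \cdot 1)^{1/4} = 1.32$ and
$(13 \cdot 14 \cdot 14 \cdot 13)^{1/4} = 13.49$.

`compare_top_k()` takes the top-k sets of several rankings (ties at the
k-th aggregate value are all included and flagged) and reports pairwise and
global intersections — the genes recommended under every condition.

## Target-gene validation

The normalization factor of a reference set is the per-sample geometric
mean of the references' relative quantities; target expression is
$q_t / NF$. The seven canonical schemes stress-test a ranking: top 1, top
2, top 3, worst 1, worst 2, worst 3, and all candidates. Normalized
expressions are scaled so the largest group mean equals 1, so plots read as
fractions of the peak tissue (the natural choice when no absolute units
exist). Group differences are tested by one-way ANOVA; the compact letter
display is built from all-pairs Welch t-tests with Holm correction at
α = 0.05. The post-hoc method is a deliberate choice — published analyses
of this kind state "one-way ANOVA with letters" without naming one — and a
documented divergence risk when comparing letters against other software.
Group standard errors use biological replicates only (technical replicates
are collapsed beforehand). If every group mean is identical the ANOVA F is
reported as 0 with p = 1.

## The synthetic-data generator

`generate_cq()` simulates Cq additively on the log2 scale:

$$Cq = \text{baseline} + \text{tissue effect} + \text{stage effect} +
\text{interaction} + \text{sample effect} + \varepsilon_{bio} +
\varepsilon_{tech},$$

with Gaussian noise — multiplicative (log-normal) error in template space,
the standard qPCR error model. Per-sample effects emulate loading and RT
yield and are shared by all genes of a sample; every stability statistic is
expected to cancel them, and an end-to-end invariance test verifies this.

`licorice_preset()` encodes a realistic spatio-temporal design: 14
candidate genes plus one target across 3 tissues (root, rhizome, leaf) and
4 stages (April through October), 3 biological × 3 technical replicates,
baselines spread over 19–27 cycles. Defaults: technical SD 0.15 cycles,
biological residual SD 0.25, sample-effect SD 0.5 — chosen so the
candidates' CV of Cq brackets what real panels show (stable genes under
5%, the worst genes around 10%). Three candidates are designed stable
(condition effects at most 0.1 cycles), eight moderate (0.4–0.9), three
unstable (up to 1.5 cycles per factor, with the three sharing a same-sign
root–leaf contrast — the realistic failure mode where poor references drift
with tissue physiology rather than cancelling each other). Effects are
fixed structured patterns (rotating centered shapes; interactions are outer
products of centered margins, hence pure interactions that cannot leak into
main effects): the preset defines the conditions and only the noise varies
with the seed. The target gene is root/rhizome-specific with leaves 4
cycles higher (~16-fold lower expression). Truth (per-gene condition-effect
dispersion, class labels, noiseless cell means) is always returned, and
`simulation_report()` writes it alongside the data.

What the simulator does *not* emulate: non-detects and censoring at high
Cq, amplification inhibitors, efficiency drift between plates,
co-regulation between candidate genes beyond shared sample effects, and
non-Gaussian outliers. Passing the recovery tests therefore demonstrates
correctness of the statistical machinery under the stated model, not
robustness to every pathology of real plates.

```{r recovery-example}
sim <- generate_cq(licorice_preset(), seed = 1)
d <- collapse_technical_replicates(sim$data) |> filter(gene != "bAS")
an <- stability_workflow(d, condition = "tissue:stage")
an$ranking |>
  left_join(sim$truth$genes, by = "gene") |>
  arrange(final_rank) |>
  select(gene, class, geomean_display, final_rank)
```

## Numerical conventions and edge cases

- Display rounding is half-up to 2 decimals (`round_half_up()`); all
  comparisons and final ranks use full precision.
- geNorm exclusion ties remove the later gene in input order — degenerate
  all-identical panels are thereby reproducible.
- Negative NormFinder variance estimates clamp to 0 before the square
  root; the unclamped value is reported.
- Zero-variance genes: geNorm and ΔCt return 0 contributions; BestKeeper
  reports r as missing and ranks by MAD.
- Efficiencies must exceed 1 fold per cycle; standard curves with
  non-negative slope are errors, not warnings.
- Monte-Carlo checks in the test suite run at sizes chosen so each check's
  own sampling error is small relative to the tolerance it asserts
  (e.g. 2000 replicates for the unbiasedness check, where the smallest
  true variance has a ~3.5% relative Monte-Carlo SE of the mean; 20
  preset seeds for end-to-end class recovery; 200 replicates for grouped
  detection power).

## Known limitations

- The absolute published stability values of any given study cannot be
  recomputed without that study's raw Cq tables; what this package
  guarantees is the arithmetic (benchmarked against published rank
  aggregations), cross-method identities, and statistically calibrated
  recovery on simulated truth.
- BestKeeper's regression output (per-gene slope/intercept against the
  index and p-values) is out of scope; only the statistics used for
  ranking are implemented.
- NormFinder's "best pair" recommendation is not implemented; single-gene
  SVs only.
- The compact letter display assumes enough within-group replication for
  Welch tests; groups of size 1 yield no letters beyond the default.
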