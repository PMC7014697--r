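---
title: "Methods: mixed-model association scans for SNPs, haplotype alleles and haplotype blocks"
author: "hapscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model association scans for SNPs, haplotype alleles and haplotype blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and assumptions

hapscan performs genome-wide association scans on panels of fully
homozygous inbred lines. Because each line is homozygous, its genotype
at a set of linked SNPs *is* its haplotype: no phasing or genotype
likelihood handling is needed, and a SNP can be coded 0/1 for the two
homozygous classes. The package assumes:

* complete genotypes (missing calls are rejected at load time rather
  than imputed — imputation tools exist for that job, and silently
  mode-imputing would corrupt multi-SNP haplotype patterns);
* one phenotype record per line, so the incidence matrix of the
  polygenic term is the identity;
* phenotypes pre-adjusted for systematic covariates; the only fixed
  effects in the scan are the intercept and the tested unit.

## The model

For a trait $\mathbf{y}$ on $n$ lines and a tested unit with design
$\mathbf{X}$ ($n \times df_\beta$):

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{X}\boldsymbol\beta + \mathbf{a}
  + \boldsymbol\varepsilon,\qquad
  \mathbf{a} \sim N(\mathbf{0}, \mathbf{K}\sigma_a^2),\qquad
  \boldsymbol\varepsilon \sim N(\mathbf{0}, \mathbf{I}\sigma_\varepsilon^2),$$

with $\mathbf{K}$ the realized relationship matrix built from all
markers. Substituting the polygenic heritability
$h^2 = \sigma_a^2/(\sigma_a^2 + \sigma_\varepsilon^2)$ gives
$\operatorname{Var}(\mathbf{y}\mid\boldsymbol\beta) =
\left(\tfrac{h^2}{1-h^2}\mathbf{K} + \mathbf{I}\right)\sigma_\varepsilon^2$,
so a single parameter controls the covariance shape. One spectral
decomposition $\mathbf{K} = \mathbf{U}\mathbf{S}\mathbf{U}^\top$,
computed once per dataset, diagonalises it: with
$\tilde{\mathbf{y}} = \mathbf{U}^\top\mathbf{y}$ and
$\tilde{\mathbf{X}} = \mathbf{U}^\top[\mathbf{1}\;\mathbf{X}]$ the model
becomes an ordinary linear model with independent heteroscedastic
errors, weights $w_i = \tfrac{h^2}{1-h^2} S_i + 1$. Every unit test is
then a weighted regression: whiten by $w_i^{-1/2}$ and solve by QR.

Two numerical conventions matter for cross-checking against other code:

* the reported residual variance uses the $1/(n-1)$ divisor,
  $\hat\sigma_\varepsilon^2 = \mathrm{RSS}_w/(n-1)$;
* the profiled likelihood is
  $-2\log L \propto n\log(\mathrm{RSS}_w/n) + \sum_i \log w_i$,
  constants dropped. Absolute values are therefore not comparable
  across implementations; differences are, and the test suite checks
  likelihood *differences* against a dense GLS evaluation of
  $\mathbf{V} = \tfrac{h^2}{1-h^2}\mathbf{K} + \mathbf{I}$ on the
  original scale.

## The unified F statistic

Units differ in degrees of freedom: a SNP or a haplotype-allele
carrier indicator contributes one column; a $k$-allele block
contributes $k-1$ indicator columns (the last allele in the sorted
order is dropped, since the carrier indicators of all $k$ alleles sum
to one and would be confounded with the intercept). All are tested
with the nested-model F statistic in the whitened space,

$$F = \frac{(\mathrm{RSS}_0 - \mathrm{RSS}_1)/df_\beta}
           {\mathrm{RSS}_1/df_\varepsilon},\qquad
  df_\varepsilon = n - df_\beta - 1,$$

where $\mathrm{RSS}_0$ and $\mathrm{RSS}_1$ are the weighted residual
sums of squares of the intercept-only and full models *at the same*
$h^2$. This choice — rather than plugging the reported
$\hat\sigma_\varepsilon^2$ with its $(n-1)$ divisor into a one-model
formula — is deliberate: only the RSS-ratio form is exactly
$F(df_\beta, df_\varepsilon)$-distributed under the null, which is the
reference distribution the test claims. For $df_\beta = 1$ it
coincides with the squared t test. A large-sample
$\chi^2(df_\beta)$ p-value ($df_\beta F \sim \chi^2$) is available via
`chisq_pvalues = TRUE`.

The per-unit explained variance is reported as
$100\cdot\operatorname{var}(\mathbf{X}\hat\beta)/\operatorname{var}(\mathbf{y})$
on the original (unrotated) scale, clipped to $[0, 100]$.

## Heritability profiling and the two-pass scan

The genomic heritability $\hat h^2_g$ is estimated once under the
intercept-only null by minimising $-2\log L$ over $h^2 \in (0,1)$ with
a 21-point coarse grid followed by Brent refinement (tolerance
$10^{-4}$ on $h^2$). The grid guards against the occasional flatness
of the profile at small $n$; a boundary optimum is flagged.

Per tested unit, $h^2$ is then re-optimised by a *downward* search on
$(10^{-6}, \hat h^2_g]$: a unit that is not a QTL leaves the polygenic
signal essentially intact, so its optimum lies at or just below the
null estimate, while a true QTL's optimum lies below it by roughly the
unit's own variance share. If the optimum presses against the upper
end, the interval is extended by 0.05 (capped below 1) and the search
repeated. The per-unit search uses Brent alone, without the coarse
grid: the profile restricted to the downward interval is empirically
unimodal, and grid seeding for every screened unit would multiply the
scan cost several-fold, breaking the design goal that a two-pass scan
stays within two genome-wide regression rounds. The null-model fit,
run once, keeps the full grid-plus-Brent search.

Scan modes:

* **emmax** — every unit tested in a single weighted regression at
  $h^2 = \hat h^2_g$ (the intercept-only fit at $\hat h^2_g$ is shared
  across all units);
* **exact** — per-unit profiling for every unit;
* **two_pass** (default) — EMMAX screen over all units, then exact
  re-testing only of units with screen $p \le$ `screen_alpha`
  (default 0.05); re-tested results overwrite screen results. An
  internal counter of weighted fits reports the realised cost as
  genome-wide regression-scan equivalents $i$ = fits / units; on a
  null panel with `screen_alpha = 0.05` this lands around 1.8–2,
  and the acceptance suite asserts $1 < i \le 2$ there. On panels
  carrying strong QTLs the screened set grows with the signal, and
  $i$ can exceed 2 slightly — the cost contract is about the
  genome-wide null bulk.

All unit design columns are rotated into the eigenbasis in one batch
matrix product per scan (a single $O(n^2 m)$ multiply), which is the
main computational economy of the single-decomposition approach.

## Kinship

`compute_rrm` uses the VanRaden-style construction on 0/1 inbred
coding: centre each polymorphic marker column by its allele frequency
$p_j$ and scale the cross-product by $c = \sum_j p_j(1-p_j)$. The
haploid-equivalent $c$ (not $2\sum p_j(1-p_j)$) keeps the diagonal
near 1 for inbred data. The choice of scaling is not critical: any
positive rescaling $\mathbf{K} \to c\mathbf{K}$ is absorbed by $h^2$
and leaves every test statistic unchanged, a property the test suite
asserts directly rather than resolving by fiat. Markers of the tested
unit are *not* excluded from $\mathbf{K}$ (single global kinship, one
decomposition); the resulting proximal contamination mildly inflates
$\hat h^2_g$ on QTL-bearing panels and can make screens slightly
conservative. A leave-one-chromosome-out kinship is available through
`compute_rrm(G, exclude_chrom = ...)` for users who want it, at the
price of one decomposition per chromosome.

Eigenvalues in $(-10^{-10}, 0)$ are clipped to zero (rounding noise of
a PSD matrix); anything more negative aborts, since it indicates
genuine corruption upstream rather than roundoff.

## Haplotype blocks

The Four Gamete Test declares recombination evidence for a marker pair
iff all four two-locus gamete classes (0,0), (0,1), (1,0), (1,1) are
observed at frequency $\ge$ `fgt_cutoff` (default 1%); in an inbred
panel every line is an observed gamete, so the classes are counted
directly. Blocks are grown greedily left to right within each
chromosome, and a candidate marker joins only if it passes the test
against **every** marker already in the block. The all-pairs criterion
(rather than adjacent-pair chaining) prevents recombinant pairs from
hiding inside long blocks. Single markers left over are "unblocked"
and still tested as SNPs. No maximum block span is imposed.

Within a block, distinct row patterns are the haplotype alleles;
patterns with frequency below `rare_freq` (default 0.02) are pooled
into one `_rare` class — but only when at least two patterns pool: a
lone sub-threshold pattern carries the same information as a named
allele and keeps its ordinary label. Alleles are ordered by descending
frequency with lexicographic pattern as tie-break, which fixes the
"last allele" dropped for identifiability deterministically.

## Thresholds and diagnostics

Significance uses the Bonferroni threshold $-\log_{10}(\alpha/\text{n
tests})$ only. The genomic-control inflation factor converts every
p-value to its 1-df $\chi^2$ quantile and divides the median by
$\chi^2_1$'s median ($\approx 0.4549$), putting mixed-df scans on a
common scale; $\lambda \approx 1$ indicates calibrated tests. QQ plot
expected values use the $(i - 0.5)/n$ plotting positions.

## The simulator

`simulate_genotypes` draws block lengths from a geometric model (mean
`block_length_mean`, default 6 markers) and fills each block by
founder-pool copying: `n_founders` (default 4) founder haplotypes are
drawn marker-wise at frequencies from `maf_range` (default
0.1–0.5), each line copies one founder, and each call is re-drawn
from the marker's base frequency with probability
1 − `within_block_r` (default 0.98). This yields a handful of common
alleles per block plus rare mutation-derived patterns — the qualitative
structure of a diverse inbred panel (most blocks short, 3–6 common
alleles) — with `within_block_r = 0` collapsing to fully independent
markers. `simulate_phenotype` realises the generative model above and
rescales each component (polygenic, each QTL, residual) to its exact
target sample-variance fraction, so the empirical decomposition
matches the specification; the truth is recorded in a sidecar
attribute for recovery tests.

The simulator is deliberately not a coalescent: no recombination maps,
mutation model, or demography. Consequently the tests demonstrate
statistical correctness (calibration, parameter recovery, cost
contracts) under the model's own assumptions; they cannot certify
behaviour under strong population structure beyond what $\mathbf{K}$
induces, ascertainment bias, or real LD decay patterns.

## Problem sizes and degenerate inputs

The test suite exercises the pipeline at sizes chosen to make
Monte-Carlo checks sharp while keeping a full run comfortably
interactive: dense-GLS equivalence at $n \le 15$; calibration at
$n = 300$ with 2,000 null units per df in {1, 3, 6}; heritability
recovery at $n = 400$ over 100 replicates per true value; QTL power at
$n = 500$, 2,000 SNPs, 100 replicates (a 10%-variance QTL is required
to clear the genome-wide Bonferroni threshold in ≥ 90% of them).

Degenerate cases are handled loudly: monomorphic or aliased unit
designs raise a rank-deficiency error that the scan catches, logs and
skips (never silently); a monomorphic block is an upstream error;
a constant phenotype or an all-monomorphic marker set aborts; a
perfect fit (zero residual) returns a flagged $p = 0$ sentinel and is
excluded from genomic control with a warning.

## Known limitations

* No covariates beyond the intercept — pre-adjust phenotypes upstream.
* ML, not REML: variance components are mildly shrunk at small $n$;
  test statistics are unaffected in calibration checks.
* Single-trait scans only; no FDR (Bonferroni by design).
* The estimator of $h^2$ is boundary-censored at 0, so its sampling
  distribution at true $h^2 = 0$ piles up at zero; recovery checks
  there are distributional (median near 0) rather than mean-bias.
* Proximal contamination from the global kinship (see above).
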