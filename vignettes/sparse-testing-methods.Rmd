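---
title: "Sparse-testing genomic selection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-testing genomic selection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsegs)
```

## The problem

Early-stage (stage-1) maize yield testing evaluates testcross hybrids of
thousands of doubled-haploid (DH) lines in only a handful of environments,
typically two well-watered (WW) locations and one managed water-stress (WS)
site. Phenotyping every line everywhere is unaffordable; *sparse testing*
phenotypes different subsets of each bi-parental family in different
environments and relies on genomic relationships plus the genetic correlation
between environments to predict the unobserved cells of the line-by-environment
grid. `sparsegs` implements this strategy end to end: trial simulation,
relationship-matrix construction from dominant presence/absence markers,
reliability-based (CDmean) allocation of sibs to environments, REML estimation
of the multi-environment GBLUP, and cross-validated accuracy evaluation.

## The model

For plot-level yields the package fits

$$ y = 1\mu + X_1 b_1 + Z_1 u_1 + Z_2 u_2 + Z_3 u_3 + Z_4 u_4 + Z_5 u_5 + \varepsilon $$

with fixed location effects $b_1$ and iid random effects for tester ($u_2$),
trial ($u_3$), replication nested within environment and trial ($u_4$), and
incomplete block nested within replication ($u_5$); nesting is encoded by
compound factor keys, and factors that collapse to a single level are dropped
with a message. The genetic term is the line-by-environment interaction

$$ u_1 \sim N\left(0,\; G_o \otimes G\right), $$

where $G$ is the $g \times g$ genomic relationship matrix and $G_o$ the
$v \times v$ genetic covariance between analysis environments. Residuals are
independent with a separate variance per analysis environment. $G_o$ can be

* **US** — unstructured, one variance per environment and one covariance per
  pair;
* **FA** — factor analytic, $G_o = \Lambda\Lambda' + \Psi$ with $m$ latent
  factors ($m = 1$ below four environments, $m = 2$ for four to six, following
  the usual parsimony rule; specific variances $\Psi_v$ may reach zero, giving
  the reduced-rank "XFA" regime);
* **DIAG** — zero between-environment covariance, retained purely as a
  no-borrowing baseline for experiments.

Plot heritability per environment is
$h^2_v = \sigma^2_{g_v} / (\sigma^2_{g_v} + \sigma^2_{\varepsilon_v})$ with
$\sigma^2_{g_v}$ the $v$-th diagonal element of $\widehat{G}_o$. Because $G$
carries the scale of realized relationships (the diagonal for fully homozygous
DH lines exceeds 1), $\sigma^2_{g_v}$ is the variance coefficient on $G$, and
the simulator defines its target heritabilities on the same scale, so
estimates and truths are directly comparable.

Environments can be grouped before analysis: `LM` (location-by-management),
`M` (management, single year), `MY` (management-by-year), `M_plus`
(management pooled over years) and `LMY` (location-by-management-by-year).
Grouping coarsens $G_o$ and shrinks the parameter count; single-year schemes
refuse multi-year data. The fixed location term is retained under all
groupings, including `M`, where it still absorbs the WW location contrast.

## REML estimation

Variance components are estimated by REML with an EM backbone and
average-information (AI) acceleration. EM updates are derived from the
mixed-model-equation (MME) solutions and conditional (co)variances, so every
EM step provably does not decrease the restricted likelihood — the property
the test suite asserts per iteration. AI steps use the analytic score and the
average-information matrix; variances move on the log scale so steps cannot
leave the parameter space, and for FA the score and AI matrix are mapped onto
$(\Lambda, \Psi)$ by the chain rule through $G_o = \Lambda\Lambda' + \Psi$
(with $\Lambda$ rotated lower-triangular first; the rotation is
likelihood-free). An AI step that would reduce the likelihood is discarded in
favour of an EM step, and AI is disabled after three consecutive rejections.
The fit always returns the best visited point, and non-convergence within
`max_iter` is flagged, never silent — with six environments and small
training sets the US model genuinely fails to converge at times, which is one
of the arguments for the FA structure.

Two numerically equivalent solvers compute each iteration (they agree to
machine precision in the tests):

* a **balanced-design solver** used when every line has the same plot count in
  every environment (e.g. full-observation fits): in the eigenbasis of $G$
  the genetic block of the MME decomposes into $g$ independent $v \times v$
  systems, which are inverted simultaneously through one generalized
  eigendecomposition; the fixed/nuisance block is absorbed by a Schur
  complement. A full-data fit with 840 lines and three environments takes a
  few seconds;
* a **general solver** for arbitrary missingness (the sparse-testing case),
  which builds the full MME — also in the eigenbasis of $G$, since forming
  $G_o^{-1} \otimes G^{-1}$ densely is numerically catastrophic when the
  smallest eigenvalues of a DH relationship matrix sit at the regularization
  ridge.

Numerical guards: relationship matrices are ridge-regularized
(`regularize_grm`, default $10^{-6}$ on the diagonal) before inversion;
variances are floored at $10^{-8} \times \mathrm{var}(y)$ and pinned
components are reported; convergence is declared when the change in REML
log-likelihood falls below `tol` (default $10^{-6}$).

## Markers and relationships

Markers are dominant sequence tags coded 0/2 for absence/presence. The MAF
filter is strict (`MAF > 0.05`). No relationship-matrix formula is canonical
for dominant codings; the package treats the 0/2 code as a dosage and applies
the standard centered cross-product form (VanRaden method 1), $G = WW' /
\sum_m 2p_m(1-p_m)$, with allele frequencies estimated from all genotyped
lines jointly so current and historical material share one scale. This is an
assumption, flagged as such: it yields a PSD kernel and behaves correctly in
the package's own recovery experiments, which is the property that matters
here. Missing calls are imputed at load time to the column-mean homozygote.

## CDmean and the CV2 split

The reliability of predicting contrast $K$ from a candidate calibration set is

$$ \mathrm{CD}(K) = \mathrm{diag}\left[\frac{K'\left(G - \lambda(Z'DZ + \lambda G^{-1})^{-1}\right)K}{K'GK}\right] $$

with $Z$ the incidence of calibration phenotypes, $\lambda$ the
residual-to-genetic variance ratio and $D$ a projection removing fixed
effects of the calibration records. Within a full-sib family, each individual
$g$ in turn is treated as the sole calibration record, and CDmean($g$) is the
mean reliability of the family-mean contrasts of the other $N-1$ sibs.

One design decision deserves emphasis: with a single calibration record, an
intercept projection degenerates ($D = I - X(X'X)^{-1}X' = 0$ for one record),
making every CD identically zero and the criterion useless. Because the
contrasts are already mean-invariant ($1'K = 0$), the package defaults to $D =
I$ (`fixed = "none"`), which keeps the criterion informative, equal to 1 at
$\lambda = 0$, strictly decreasing in $\lambda$, and bounded in $[0,1]$ — all
verified against a naive dense transcription of the formula. The intercept
projection remains available for calibration sets of two or more records.
$\lambda$ defaults to 0.5, an intermediate value whose adequacy rests on the
criterion depending far more on relationship structure than on trait
heritability; it is overridable. The prose defining the per-individual score
admits a second reading (score $g$ by how well *others* predict *it*); both
are implemented (`mode = "calibrate"` / `"validate"`) with the first as
default.

The CV2 design then places the top half of each family (by CDmean, ties broken
by line ID) in the first WW environment and the bottom half in the second; the
WS calibration set takes the higher-CDmean half of each WW-observed subset
(ceiling from the first, floor from the second), so WS sees material from both
WW groups while half of the WW-phenotyped lines stay masked in WS. Odd family
sizes put the extra line in the first WW environment. Every tie-break is
lexicographic in line ID: reproducibility is preferred over arbitrariness.

Historical training individuals are selected per target family by
`avg_grm_select`: the mean relationship between candidate $j$ and the family,
$\overline{G}_{\cdot j}$, taking the top 300 by default.

## Cross-validation

* **CV1** (new families): each repeat masks a random half of the families
  entirely in the first WW environment (observed in the second) and vice
  versa; $\lfloor k/2 \rfloor$ families from each WW-observed group are masked
  in WS. With 12 families this is the 6/6 WW split with 3 + 3 WS maskings.
  Ten repeats by default.
* **CV2** (split families): deterministic, from the CDmean splits.

Validation targets are per-environment BLUEs of line means computed from the
complete data — genotype fixed, trial/replication/block random, the standard
stage-one analysis (fitted with `lme4`); in balanced designs they reduce to
plot means. Accuracy is the Pearson correlation between masked lines' GEBVs
and their BLUEs per family and environment (cells with fewer than three
masked lines are skipped), averaged unweighted across families. Masked
records are removed from the training data before any computation touches
them; the test suite verifies bit-identical fits after replacing masked
yields with sentinel values. When historical data are appended
(`augment_with_historical`, modes `all`/`optimized`), single-year groupings
are refused and BLUEs continue to come from the complete current-year data.

## The simulator

The generator emulates the trial system the analysis assumes, so parameter
recovery is well-posed: founder inbreds with per-marker presence frequencies
drawn from $U(0.02, 0.98)$ (placing realized MAFs on both sides of the 0.05
filter); DH progeny as doubled recombinant F1 gametes with interference-free
(Haldane) crossovers on a uniform genetic map — the simplest defensible
meiosis model, testable against the closed-form recombination fraction
$(1 - e^{-2d})/2$; genetic values drawn directly from $G_o \otimes G$ (marker
effects are never explicit); and plot records built from an alpha-lattice-like
layout: families packed contiguously into trials, one tester per family, two
replications, lines re-randomized into incomplete blocks within each
replication, and tester/trial/rep/block effects drawn iid from configurable
variances. Default conditions follow the study system: 12 families of 70 DH
lines per year, 2 WW + 1 WS environments (Kiboko/Kakamega), plot
heritabilities 0.30 (WW) and 0.35 (WS) against unit residual variance,
between-environment genetic correlations 0.6 within and 0.3 across
managements (damped by 0.8 across years), overall mean 5 with a 0.25 location
offset, and nuisance variances an order of magnitude below the residual.
Multi-year configurations can re-use founders across years
(`founder_reuse`), creating the historical relatedness that training-set
augmentation exploits.

What the simulator does *not* emulate: real linkage maps and recombination
hot spots, QTL-level dominance and epistasis, selection during DH production,
shared check plots connecting trials (connection is carried entirely by $G$),
spatial field trends, and year-specific agronomy. Passing tests therefore
demonstrate correctness of the machinery and calibration under the assumed
generative model, not performance on any particular real data set.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to exercise the claims while keeping
a full run on one CPU comfortably short: oracle equivalence of the
reliability criterion on 50 simulated DH families of 5–15 sibs; the
closed-form REML limit at 180 lines; FA/US equivalence on ten simulated
600-line two-environment datasets; parameter recovery over 20 replicates at
the full trial scale (12 families × 70 DH, three environments, balanced
solver); the FA-versus-DIAG sparse-testing contrast and the null (zero
heritability) calibration on 8 × 24- and 6 × 20-line systems, where the
masked refits use the general solver. The acceptance script mirrors these:
variance components at full scale, cross-validation on an 8 × 30 system.

## Known limitations

* The general solver builds a dense MME of order $gv$; it is comfortable to a
  few thousand line-environment combinations but is not an ASReml-scale
  sparse implementation. The balanced solver lifts this for full-observation
  fits only.
* The sparse-equation tricks of the XFA literature are not implemented; FA
  here reduces parameters, not equation-system size.
* BLUE computation assumes trials are connectable within an environment;
  fully disconnected designs rely on the random trial effect for linkage.
* `avg_grm_select` and the CDmean split optimize within-family representation;
  they do not optimize tester assignment or plot counts, and the
  exchange-algorithm variants of calibration-set optimization are out of
  scope.
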