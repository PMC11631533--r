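---
title: "Principal-component BLUP: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal-component BLUP: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

A multitrait genetic evaluation fits the pedigree animal model

$$
y = Xb + Za + e, \qquad
a \sim N(0,\, G_0 \otimes A), \qquad
e \sim N(0,\, R_0 \otimes I),
$$

where $y$ stacks $m$ traits over $n$ phenotyped individuals, $A$ is the
additive relationship matrix implied by the pedigree, and $G_0$, $R_0$ are
the $m \times m$ genetic and residual trait covariance matrices. The
practical bottleneck is estimating $G_0$ and $R_0$: multivariate REML over
$m(m+1)$ parameters converges slowly or not at all once $m$ reaches the
10–30 traits common in breeding programs.

`pcblup` implements the principal-component shortcut. Let
$\Lambda$ be the eigenvectors of the phenotypic covariance and
$S = (Y - \mu)\Lambda$ the component scores. The scores are orthogonal in
the phenotypic space, so each column is analysed with an *independent
univariate* REML/BLUP animal model, and the component EBVs are mapped back
to the trait scale by

$$
\hat G_{\mathrm{orig}} = \hat G_{\mathrm{ebv}}\,\Lambda' \,\mathrm{diag}(s) + \mu,
$$

which is exact (no information loss) when all $p = m$ components are kept.
The method's implicit assumption is that the *genetic* covariance is
reasonably aligned with the phenotypic one: if $G_0 = \gamma P_0$ and
$R_0 = (1-\gamma) P_0$ for some phenotypic covariance $P_0$, the stacked
mixed-model equations decouple exactly in the component basis and
back-transformed per-component BLUP *equals* multitrait BLUP at the same
covariances (the package asserts this identity to 1e-6 in its tests). For
general $G_0$ the components carry nonzero genetic cross-covariances that
the univariate fits ignore, and concordance with the full multivariate
analysis degrades gracefully; `concordance_experiment()` measures exactly
this.

## Pedigree algebra

Pedigrees are topologically sorted trio tables; parents referenced but never
declared become founders. $A$ is built by the tabular recursion
$a_{ij} = \tfrac12(a_{j,s(i)} + a_{j,d(i)})$,
$a_{ii} = 1 + \tfrac12 a_{s(i),d(i)}$, with unknown-parent terms dropped.
Inbreeding coefficients are `diag(A) - 1`, computed either via the tabular
matrix (up to 2,000 individuals) or by the Meuwissen–Luo ancestor traversal,
which never forms $A$; the two agree to 1e-12 in the tests. $A^{-1}$ is
assembled directly from Henderson's rules with Mendelian-sampling variances
$d_i = \tfrac12 - \tfrac14(F_s + F_d)$ (¾, 1 with one or both parents
unknown); a flag disables the inbreeding correction for compatibility with
software that ignores it, and the default keeps it on.

## PCA, and model-based imputation

SVD-PCA is `stats::prcomp` behind a thin, deterministic surface: centring on
by default, scaling off (breeding phenotypes are usually pre-adjusted to
comparable residual scales; a `scale` flag is provided and is recorded in the
model so the back-transformation stays exact either way). Eigenvalues are
score variances with denominator $n-1$. Because the sign of a singular
vector is arbitrary, each loading column is flipped so its largest-magnitude
entry is positive; re-running on identical input is bitwise reproducible.
Eigenvalue ties keep `prcomp`'s ordering, which preserves original trait
order.

Missing cells break plain SVD. `fit_bpca()` fits the probabilistic PCA model
$y_i = W x_i + \mu + \varepsilon$, $x \sim N(0, I_q)$,
$\varepsilon \sim N(0, \sigma^2 I)$, by an EM scheme whose E-step regresses
each individual's factor score on its *observed* coordinates (with the full
posterior score covariance $\sigma^2 M^{-1}$), predicts missing cells as
$W_{\mathrm{miss}} x$, and whose M-step updates $\mu$, the principal axes
and $\sigma^2$ trait-by-trait over observed cells. Convergence is monitored
on the relative Frobenius change of the imputed matrix
(default threshold 1e-6, at most 10,000 steps — generous for the problem
sizes here); non-convergence returns the last iterate with
`converged = FALSE` and a warning, never silently. Axes are initialised from
the SVD of the mean-imputed matrix, so on complete data the fitted subspace
coincides with SVD-PCA immediately. Observed cells are never modified.

Loading diagnostics follow standard practice: per-trait contributions are
$100\,\Lambda_{jk}^2$ (orthonormal columns make them sum to 100); trait
clustering is Ward's method on Euclidean distances between loading rows
(`hclust(method = "ward.D2")`, checked against a naive $O(n^3)$
agglomeration oracle); two ordinations are compared by a Mantel test on the
trait-distance matrices (vegan's implementation; one-sided, 999 permutations
by default — the conventional direction for a concordance hypothesis).

## REML and BLUP

`solve_mme()` solves Henderson's equations with the sparse $A^{-1}$ at
given variances. A near-singular coefficient matrix gets a logged ridge of
$10^{-8}\,\mathrm{tr}(C)/\dim(C)$ and the solve continues — singularities
are reported, not fatal.

`reml_univariate()` runs its iterations in the eigenbasis of
$A_{\mathrm{obs}}$, the relationship submatrix of the phenotyped
individuals: there $V = \sigma_a^2 D + \sigma_e^2 I$ is diagonal and every
restricted-likelihood functional costs $O(n)$ after one eigendecomposition
(which is shared across components in `evaluate_pcs()`). This collapsed
representation leaves the restricted likelihood identical to the
full-pedigree formulation; breeding values for *all* pedigree members come
from one final sparse MME solve at the converged components.

Two algorithms are provided. EM (the reference) uses the Harville P-matrix
updates, whose restricted log-likelihood is provably non-decreasing — the
trace is stored and tested at every iteration. AI (the accelerator) takes
average-information steps with step-halving and falls back to an EM step
whenever a proposal would decrease the likelihood, so it inherits EM's
robustness; the two agree to 1e-3 relative on converged estimates in the
tests. Convergence requires relative parameter change below `tol`
(default 1e-8) *and* likelihood change below 1e-6; a stall rule (five
consecutive iterations with $|\Delta \ell_R| < 10^{-8}$ and parameter
movement below 1e-5) catches boundary limit cycles at the numerical noise
floor. Estimates are clamped at $10^{-8}\,\mathrm{var}(y)$ and flagged as
boundary solutions instead of going negative. Standard errors come from the
inverse average-information matrix at the optimum, and the heritability SE
uses the first-order Taylor (delta) approximation
$\mathrm{SD}(A/B) = (A/B)\sqrt{(\mathrm{SD}(A)/A)^2 + (\mathrm{SD}(B)/B)^2}$
with $A = \hat\sigma_a^2$, $B = \hat\sigma_a^2 + \hat\sigma_e^2$, treating
$A$ and $B$ as uncorrelated.

### Bivariate REML and the staged multivariate reference

The reference multivariate procedure is staged: (a) univariate REML per
trait for starting values and covariance diagonals, (b) bivariate REML per
trait pair for the off-diagonals — $m(m-1)/2$ fits, 325 at $m = 26$ —
and (c) a full multitrait BLUP with the assembled $G_0$, $R_0$ held fixed.

For the bivariate fits the package maximises the restricted likelihood
directly over a log-Cholesky parameterisation of $(G_0, R_0)$ (BFGS),
rather than running a multitrait EM. This was a deliberate design choice:
with complete records the likelihood decouples in the eigenbasis of
$A_{\mathrm{obs}}$ into $n$ independent 2×2 Gaussian terms, making each
evaluation $O(n)$ and the whole fit fractions of a second, whereas a correct
multitrait EM E-step under per-trait missingness is substantially more
intricate for no statistical gain — both maximise the same restricted
likelihood. With missing records a dense-covariance likelihood over the
observed (individual, trait) cells is used instead. Identical trait pairs
are rejected up front (degenerate residual covariance).

Assembled covariance matrices that are not positive semi-definite are
"bent": eigenvalues are clipped at $10^{-6}$ of the largest, then the matrix
is rescaled to restore the trusted univariate diagonals exactly; the repair
is logged. Stage (c) builds the stacked MME with
$G_0^{-1} \otimes A^{-1}$ and a per-individual residual precision over each
individual's observed traits, so per-cell missingness is handled uniformly;
with $m = 1$ it delegates to the identical Henderson solve as the
univariate path.

## Indices and rank statistics

A selection index is $\sum_j w_j \tilde g_{ij}$ with signed weights
normalised to unit absolute sum. By default each trait's EBVs are
standardised to unit variance first, because traits in these programs live
on incommensurate scales (metres, millimetres, densities) and raw weighting
would let one trait dominate; `standardize = FALSE` gives the raw mode, and
the choice is recorded on the result. Ranks are descending with ties broken
by individual id, so output is deterministic.

Rank agreement is reported three ways: Pearson $r$ of the index values over
the whole population; Kendall $\tau_b$ over the *reference-defined* top-k
individuals' ranks in both full lists (membership by the reference method,
as a breeder comparing against the standard analysis would do); and the size
of the top-k intersection. $\tau_b$ is tie-corrected; its two-sided p-value
is exact by enumeration of the inversion-count distribution for $n \le 10$
without ties and otherwise uses the tie-adjusted normal approximation.
P-values are reported, never used to gate decisions.

`pc_index_contribution()` decomposes index variance over components as
$(w'\lambda_k)^2 \mathrm{Var}(\hat g_k)$, normalised to one — per-component
EBVs are treated as uncorrelated, consistent with the method's working
assumption.

## The synthetic test bed

The generator emulates the controlled-cross designs of conifer breeding
trials: founders, then generations of full-sib families whose parents are
random distinct pairs from the previous generation. True breeding values
follow the exact generative model of the analysis — founder rows
$\sim N(0, G_0)$, offspring rows the parent average plus a
Mendelian-sampling deviation $N(0, (\tfrac12 - \tfrac14(F_s + F_d))G_0)$ —
so recovery tests have a ground truth; this recursion is $O(nm^2)$ and
matches the $G_0 \otimes A$ construction in distribution (checked by moment
matching against $A$). Residuals are iid rows from $R_0$, and missingness
is MCAR only, the simplest mechanism consistent with how incomplete field
data are usually treated. Presets scale real population structures down to
at most ~600 individuals with per-trait heritabilities spanning 0.05–0.65
and a 13.3% missing rate for the incomplete-data preset; their correlation
structures are drawn once per preset from a fixed internal seed so a preset
always means the same population.

What the generator does *not* emulate — spatial field trends, selection and
assortative mating across generations, genotype-by-environment interaction,
non-Gaussian and threshold traits, informative missingness — bounds what
passing tests show: they validate the estimation machinery and the
component-space approximation under the model's own assumptions, not
robustness to field-data pathologies. Phenotypes are assumed pre-adjusted
for design and environmental effects, which is why the default fixed-effect
structure is an intercept (arbitrary covariates are accepted through the
model formula in the univariate path).

## Problem sizes and what the checks show

The test suite and `scripts/acceptance.R` use sizes chosen to finish in a
few minutes on one CPU while keeping Monte-Carlo error informative:
relationship algebra on 100 random pedigrees up to $n = 500$; heritability
recovery at $h^2 \in \{0.1, 0.3, 0.6\}$ with 50 replicates of a 500-member
pedigree; end-to-end index concordance on 20 seeds per covariance scenario
with $m = 6$ traits and ~400 individuals (44 full-sib families of 8 from 50
founders, common heritability 0.35 in the proportional scenario, per-trait
heritabilities uniform on 0.15–0.45 in the general one).

One honest caveat the experiments quantify: in the proportional scenario
the component/multitrait equivalence is exact *at known variance
components* (asserted to 1e-6), but at ~400 individuals the per-component
REML estimates carry enough shrinkage noise (SE of $h^2$ around 0.1) that
the PCA-pipeline index correlates with the staged multivariate reference at
roughly 0.95–0.99 rather than indistinguishably from 1; the agreement
tightens as $n$ grows. `concordance_experiment()` therefore also reports
the correlation against BLUP at the true simulated covariances, separating
estimation noise from approximation error.

## Known limitations

Genomic (marker-based) relationship matrices, dominance and
genetic-group extensions, heterogeneous residual variances, maternal and
permanent-environment effects, Bayesian samplers, and spatial pre-adjustment
are out of scope. The bivariate missing-data path is dense and intended for
moderate $n$; the staged reference at large $m$ costs $O(m^2)$ bivariate
fits by construction. BPCA assumes an isotropic residual; strongly
heteroscedastic traits should be scaled first.
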