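---
title: "Multivariate TWAS by structural equation modeling: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate TWAS by structural equation modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsem)
```

## The problem

Univariate transcriptome-wide association studies (TWAS) test, one trait at
a time, whether genetically imputed tissue-specific gene expression is
associated with a phenotype. Many complex traits are strongly genetically
correlated, and a gene that truly acts on the shared dimension will
produce correlated univariate signals across all of them; conversely a
gene that acts on a single trait can masquerade as a "shared" association
when traits are analysed jointly without a model of their covariance.
`tsem` implements a two-stage multivariate TWAS that makes the shared
dimension explicit: a latent factor is defined over the genetic components
of the traits, imputed gene expression regresses the factor, and a
heterogeneity statistic (Q\_Gene) tests whether the gene's effects are
consistent with acting *through* the factor at all.

## Stage 1: genetic covariance and gene expansion

**Multivariable LD score regression.** For traits $i, j$ with per-SNP
Z-statistics $z_{ij}$, the product $z_{ij} z_{jk}$ is regressed on
$\sqrt{N_i N_j}\,\ell(s)/M$ with a free intercept. The slope estimates the
genetic covariance $\sigma_{g_{ij}}$ (the SNP heritability $h^2_i$ on the
diagonal); the intercept captures confounding and sample-overlap
(cross-trait) effects. Heteroscedasticity weights
$1/\big[(1 + N_i h_i^2 \ell/M)(1 + N_j h_j^2 \ell/M)\big]$ are updated once
from a first-pass unweighted fit; the literature does not prescribe a
unique weighting and this two-step scheme is the conventional one. The
sampling covariance $V$ of all $k(k+1)/2$ nonredundant elements of $S$
comes from a delete-one block jackknife over 200 contiguous SNP blocks
(both defaults are exposed). Off-diagonal elements of $V$ are what let
downstream models produce correct standard errors under unknown sample
overlap.

**TWAS and rescaling.** The summary-based TWAS statistic is
$Z = w^\top z / \sqrt{w^\top R w}$ for functional weights $w$ and a
reference LD correlation matrix $R$ (ridge $10^{-3}$ on the diagonal; genes
with more than half their weight SNPs missing are skipped rather than
imputed). Each trait's $Z$ is converted to a partially standardized
coefficient: $b = Z/\sqrt{N\sigma^2_{\text{Gene}}}$ with
$SE = 1/\sqrt{N\sigma^2_{\text{Gene}}}$ for continuous traits; for binary
traits the logit-scale coefficient
$Z/\sqrt{(N_{\text{eff}}/4)\sigma^2_{\text{Gene}}}$ and its SE are divided
by $\sqrt{\sigma^2_{\text{Gene}} b^{*2} + \pi^2/3}$. Multiplying by
$\sigma^2_{\text{Gene}}$ gives the gene-phenotype covariance appended to
$S$ (gene first). The gene block of the expanded $V$ carries squared SEs
on the covariance scale; its off-diagonals reuse the cross-trait LDSC
intercepts, rescaled by the gene-trait SEs, because those intercepts are
exactly the sampling correlations induced by participant overlap. The
cross-block between the gene row and the genome-wide LDSC entries is zero:
a single gene occupies a negligible share of the LD blocks that drive the
genome-wide sampling error.

**The expression-variance metric.** The variance assigned to the gene,
$\sigma^2_{\text{Gene}}$, is the cis-heritability reported by the weight
pipeline, and it is *treated as known*: the model fixes the gene-variance
parameter at the observed value, and the nominal sampling variance of
$10^{-4}$ stored in $V$ exists to keep the weight matrix well defined, not
to express real uncertainty. This choice is what makes all downstream
inference exactly invariant to the metric: multiplying
$\sigma^2_{\text{Gene}}$ by any $c > 0$ rescales the gene column by
$\sqrt{c}$, a pure change of units of the latent expression variable, and
the gene-effect Z, its p-value and the Q\_Gene p-value are unchanged (a
property the test suite verifies end to end). Had the gene variance been
freely estimated, the fixed absolute $10^{-4}$ would inject
metric-dependent uncertainty and the invariance would only hold
approximately.

## Stage 2: the structural model

The measurement model loads the $k$ traits on one factor; the structural
part regresses the factor on the gene. Fitting is by diagonally weighted
least squares: minimize $r^\top W r$, $r = \mathrm{vech}(S) -
\mathrm{vech}(\Sigma(\theta))$, $W = \mathrm{diag}(V)^{-1}$, with a damped
Gauss-Newton iteration on an analytic RAM Jacobian (relative tolerance
$10^{-10}$, at most 500 iterations — deterministic given inputs, which
matters for reproducible simulation tallies). Parameter uncertainty uses
the sandwich $(\Delta^\top W\Delta)^{-1}\Delta^\top W V W
\Delta(\Delta^\top W\Delta)^{-1}$, which restores correct SEs although $W$
ignores the off-diagonal of $V$.

Two identifications are offered: unit loading (one loading fixed to 1,
factor residual variance free) and unit variance (factor residual variance
fixed to 1, so the total factor variance is
$1 + \gamma^2\sigma^2_{\text{Gene}}$; with $\gamma\sigma_{\text{Gene}} =
0.05$ this is the worked value 1.0025). Wald statistics of raw parameters
are not invariant to such reparameterizations, so the gene-effect test is
computed on the unit-variance-factor scale, $\gamma/\mathrm{sd}(F)$, via
the delta method: this quantity is the same function of the fitted moments
under every identification and anchor choice, making the reported Z and
p identical across them to numerical precision.

**Model fit and Q\_Gene.** The model chi-square is the residual-based
statistic $T = r^\top U r$ with $U$ a generalized inverse of $V_r = A V
A^\top$, $A = I - \Delta(\Delta^\top W \Delta)^{-1}\Delta^\top W$,
computed in the SE-standardized metric for conditioning; its degrees of
freedom are the numerical rank of $V_r$. The exact weight-matrix
construction used by earlier genome-wide SEM software is not published in
full detail, so this construction is validated by calibration rather than
by citation: under a correctly specified model the suite requires the
empirical rejection rate at $\alpha = 0.05$ to sit within binomial bounds,
and it does. Q\_Gene is the chi-square *difference* between the Step-1
common pathway model and a Step-2 common-plus-independent-pathways model
in which loadings and the gene effect are fixed at their Step-1 estimates
while direct gene-on-trait effects and residual variances are free. The
difference reading yields $df = k-1$ by construction. For cross-model
comparability the statistic is also mapped to a $\chi^2(1)$ value through
its p-value (a quantile transform, not division by df), preserving p to
machine precision; the two-indicator case requires equality-constrained
loadings for local identification, and there Q equals its own
$\chi^2(1)$ value.

**Mediation.** For a gene predicting two factors with a free residual
factor covariance $r_u$, the mediated share of the factors' genetic
overlap is the ghost parameter
$$\%\,\text{mediated} = \frac{b_1\,\sigma^2_{\text{Gene}}\,b_2}
{b_1\,\sigma^2_{\text{Gene}}\,b_2 + r_u},$$
evaluated at the estimates with a delta-method SE. Two-indicator factors
use equality-constrained loadings; factor residual variances are fixed at
1.

## The simulators and what they do (and do not) show

**Covariance-level simulator.** Genetic covariance matrices are drawn from
a multivariate normal centred on a scenario-perturbed model-implied
population, paired with the same sampling covariance used for the draws,
and analysed with the full Stage-2 machinery. The seven scenarios perturb
the gene-trait covariances: unchanged; zeroed for the smallest-loading
trait; for the largest; for all but the largest; for all but the
smallest; for all; and sign-flipped for a designated three-trait subset.
Because the empirical seven-trait matrices are not shipped, a synthetic
population stands in: loadings spanning 0.45–0.86 (standardized) with
designated smallest (`rt`) and largest (`trailsb`) traits, trait
heritabilities 0.10–0.25, gene expression variance 0.2 (a realistic
cis-heritability for a well-imputed gene), standardized gene effect 0.05,
gene-column SEs from the continuous-trait scaling at $N = 10^5$, and a
Wishart-form trait-block sampling covariance at effective df 1000. The
calibration targets the significance scale of a top empirical hit; exact
per-scenario percentages therefore have no external referent and the
tests assert the *ordering* of factor power and Q\_Gene signal, the null
false-positive rates, and the co-occurrence of factor and Q hits under
sign reversal. One structural fact discovered while building the tests:
with homoscedastic gene-column SEs, zeroing a trait subset and zeroing
its complement give exactly equal Q noncentrality
($a^2 S_A S_{A^c}/S_{\text{total}}$), so scenarios 3/4 (and 2/5) are tied
pairs here and are compared as groups.

**SNP-level simulator.** Genome-wide Z-statistics for five traits are
drawn per SNP from the LD score sampling model
($N h^2 \ell/M + 1 + a$ on the diagonal, $\sqrt{N_iN_j}\sigma_g\ell/M$
plus a zero cross-intercept off it, at $h^2 = 0.2$, $r_g = 0.7$,
$N = 150{,}000$, intercept 1.04, no overlap), exactly as
$L_0^\top u + \sqrt{\ell}\,L_1^\top v$ with Cholesky factors of the two
constant matrices. A focal eQTL ($\sigma_{\text{SNP}} = 0.706$, training
$n = 144$, $b_{\text{eQTL}} = 0.442$, hence a single-SNP weight of
$0.442\cdot0.706\cdot\sqrt{143}$ and expression variance
$b_{\text{eQTL}}^2\sigma^2_{\text{SNP}}$) injects trait effects
$b_{\text{eQTL}}\cdot\gamma\cdot\lambda_i$ with $\gamma = -0.089$ and
equal loadings $\sqrt{r_g h^2} = 0.374$; observed betas are drawn with
variance $(1 - \sigma^2_{\text{SNP}} b^2)/(\sigma^2_{\text{SNP}}(N-1))$.
The display of the observed-beta sampling distribution is missing from
the available source text, so this single-SNP form — the same algebra as
the eQTL-effect variance — is a reconstruction, validated through the
power/FPR checks. Five scenarios perturb the population betas (none;
sign-reversed for three traits; reversed and doubled; zeroed for three;
zeroed for all), and an optional mode redraws the population eQTL effect
per replicate from its sampling distribution while the weight stays
fixed. Each replicate runs multivariable LDSC on the genome-wide draws,
then both the T-SEM path and an ad hoc factor-TWAS path (the focal
SNP-phenotype covariances appended to $(S, V)$, the SNP-on-factor Z used
as the factor TWAS statistic). The focal SNP is excluded from the LD
panel so the two generative layers stay independent.

**Problem sizes.** The package's working scale for the SNP-level study is
$M = 100{,}000$ synthetic LD-score SNPs and 50 replicates per scenario
(the full design uses the genome-wide SNP count and 100 replicates);
synthetic LD scores are $1 + \Gamma(2)$ with mean 100, used for both
generation and estimation, which preserves calibration by construction.
At this scale the per-SNP signal is denser than in the genome-wide
design, which mostly inflates the variability of intercept estimates;
slope estimates and their jackknife variances stay unbiased (the suite
checks jackknife-vs-empirical agreement within a factor of two). What
these simulations cannot show: behaviour under real LD (the generator
draws SNPs independently given their LD scores), under allele-frequency-
dependent architectures, under real sample overlap, or with multi-SNP
weights — only the top1 single-SNP weight path is exercised, for which
the TWAS Z collapses to the focal SNP's GWAS Z.

## Numerical choices and degenerate inputs

Indefinite $S$ or $V$ matrices are smoothed by eigenvalue clipping at a
small floor; when SEs are available the largest pre/post change in
Z-units is reported and a change above 1.96 raises a warning. Start
values: loadings $0.4\sqrt{\overline{\mathrm{diag}\,S}}$, residual
variances half the corresponding diagonal, regressions 0. Residual
variances are not bounded below, matching unconstrained moment fitting;
Heywood-style negative estimates propagate to the caller. Saturated
models return $\chi^2 = 0$ on 0 df. Strand-ambiguous SNPs are dropped
during alignment (no frequency-based resolution); SNPs whose alleles are
incompatible with the reference are dropped and counted, never
sign-guessed. Rows lacking INFO are dropped by default and kept under a
permissive flag. Filter boundaries are inclusive (`maf >= maf_min`),
with the thresholds themselves exposed as configuration. RNG substreams
are derived per scenario and replicate from one base seed, so every
report is reproducible from its seed.

## Known limitations

The LDSC weights and the chi-square weight matrix are conventional
choices validated by calibration, not by numerical parity with any other
implementation. Missing weight SNPs are dropped rather than imputed.
Only one- and two-factor structural layouts are provided as high-level
wrappers (the grammar accepts more, but multi-group models, means, and
categorical thresholds are out of scope). The liability-scale conversion
assumes the standard threshold model. Intercept estimates at the reduced
SNP count are noticeably noisier than slopes; analyses that lean on
cross-trait intercepts (strong sample overlap) deserve the full SNP
count.
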