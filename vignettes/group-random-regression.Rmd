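---
title: "Random regression evaluation of longitudinal group records"
author: "groupRR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random regression evaluation of longitudinal group records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupRR)
```

## The problem

Feed intake (FI) in growing pigs is expensive to record per animal, but a
pen scale delivers the *summed* intake of the 12 pen mates at essentially no
marginal cost. If breeding values for the FI trajectory can be estimated
from such pooled longitudinal records, routine genetic evaluation becomes
much cheaper. `groupRR` implements, end to end, the machinery needed to
study this question by simulation:

1. a generative model for individual weekly FI curves in a pedigreed
   population,
2. pen-formation designs differing in the genetic relatedness of pen mates,
   and drop-out processes that remove animals mid-test,
3. random regression models for individual and for summed records, with
   AI-REML variance-component estimation and BLUP breeding values,
4. validation of each configuration by the accuracy and bias of a
   whole-trajectory selection index against the simulated truth.

## Generative model

Each animal is measured at $T = 6$ weekly time points, mapped affinely onto
$[-1, 1]$. With $\phi(x_t) = (\phi_0(x_t), \phi_1(x_t))'$ the first-order
*normalized* Legendre covariates, $\phi_k(x) = \sqrt{(2k+1)/2}\,P_k(x)$, the
phenotype of animal $i$ at time $t$ is

$$y_{it} = \phi(x_t)'a_i + \phi(x_t)'p_i + e_{it},$$

with additive-genetic coefficients $a_i$ (intercept and slope of the genetic
curve), permanent-environment coefficients $p_i \sim N(0, P)$, and
$e_{it} \sim N(0, \sigma_e^2)$ homogeneous over time. Founders draw
$a_i \sim N(0, G)$; descendants receive the parent average plus a Mendelian
sampling term $m_i \sim N(0, \tfrac12(1 - F_i)G)$ with
$F_i = \tfrac12(F_s + F_d)$ computed from the pedigree by the
Meuwissen–Luo recursion. The default parameters are

```{r params}
trait_params()
```

These defaults produce a heritability trajectory that starts around 0.33
and declines to about 0.21 by week six:

```{r h2, fig.width = 5, fig.height = 3.5}
L <- legendre_matrix(1:6, 1)
h2 <- heritability_trajectory(trait_params(), L)
plot(1:6, h2, type = "b", xlab = "week on test", ylab = "heritability",
     ylim = c(0, 0.4))
```

A note on conventions: only the *dimension* of the Legendre design is fixed
by the model; its scaling is a convention. We use the normalized basis, the
standard choice in random regression test-day models. An unnormalized basis
would rescale $G$ and $P$ (column $k$ by $(2k+1)/2$) while leaving every
variance trajectory, heritability, likelihood and breeding-value ranking
unchanged, provided simulation and analysis share the convention — which
they do here.

The population design is 11 discrete generations: 630 unrelated founders
(30 males, 600 females), then in every generation 30 sires and 600 dams are
selected *at random* from the previous one (no selection pressure, one
parity per sow), each dam producing a litter of 6 with Bernoulli(0.5) sex.
The founder layout (exact counts and sex split) is our design choice; it is
the minimal closed population compatible with the mating design. Phenotypes
are simulated for the last five generations (18,000 animals). Every
stochastic stage (pedigree, breeding values, permanent environment +
residuals, pen formation, drop out) runs on its own seed sub-stream, so any
stage can be re-run in isolation and replicate $k$ of a scenario uses
master seed $+\,k$.

## Pens and drop out

Pens of 12 animals are formed within generation under three designs that
differ in how related the pen mates are: `group3x4` (each litter split into
two random triples; four triples from four litters per pen), `group6x2`
(two whole litters per pen), and `group1x12` (twelve animals from twelve
litters). The pooled record of pen $j$ at time $t$ is the *sum*
$y^*_{jt} = \sum_{i \in \text{active}(j,t)} y_{it}$.

Fifteen percent of the phenotyped cohort can drop out before the end of the
test. Under `random` drop out the animals and their drop-out weeks are
uniform. Under `phenotypic` drop out, each week removes
$c_t \sim \text{Poisson}(0.15N/6)$ of the not-yet-dropped animals with the
*lowest* phenotype that week — emulating culling of poor performers; the
ranking is over the whole cohort (the wording of the culling rule is
cohort-level, and pen-level ranking would entangle the drop-out process
with pen allocation). A dropped animal's records from its drop-out week
onward are missing, so its pen's active size $n_{jt}$ shrinks; a pen may
empty entirely, in which case it simply contributes no further records.
Drop-out plans are drawn once per replicate and shared by the individual
and group analyses, keeping scenario contrasts paired.

## Statistical models

The individual-record analysis is the random regression model

$$y_{it} = \sum_k \phi_{tk}\beta_k + \sum_k \phi_{tk}a_{ik}
         + \sum_k \phi_{tk}p_{ik} + e_{it},$$

with $a \sim N(0, A \otimes G)$, $p \sim N(0, I \otimes P)$,
$e \sim N(0, I\sigma_e^2)$, and $A$ the numerator relationship matrix. The
group-record model is obtained by summing the individual model over the
active members of a pen: the additive and permanent-environment covariates
of *every* active member enter the record's row, and the residual variance
is $n_{jt}\sigma_e^2$ (records of independent animals sum), i.e.
$R = D\sigma_e^2$ with $D = \mathrm{diag}(n_{jt})$.

Two structural choices deserve comment:

* **Group-size fixed effects.** The group model needs a fixed curve whose
  level can depend on the current group size class $m = n_{jt}$ (a pen of 8
  sums fewer animals than a pen of 12). A group-size main effect plus
  size-nested regression intercepts is confounded, so we fit *one fixed
  regression curve per observed size class*, which absorbs the main effect.
  An alternative — scaling a single common curve by $n_{jt}$ — differs only
  through the fixed part, which is essentially zero here because the
  simulated trait mean is zero.
* **Current versus formation size.** The size class uses the *current*
  active size $n_{jt}$, not the formation size 12; classes below 12 only
  arise through drop out.

Permanent-environment equations are included only for animals with at
least one observed record (a PE effect with no data is unidentifiable; its
absence changes nothing else). All pedigree animals keep their additive
equations, so ancestors without records are evaluated through relatives.

When every pen holds exactly one animal, the group model collapses to the
individual model — same equations, same REML likelihood, same estimates —
which the test suite verifies exactly.

## AI-REML implementation

Variance components $\theta = (G_{11}, G_{12}, G_{22}, P_{11}, P_{12},
P_{22}, \sigma_e^2)$ are estimated by restricted maximum likelihood. The
deviance is evaluated through the sparse mixed model equations
$C = W'R^{-1}W + \mathrm{blockdiag}(0,\ A^{-1}\!\otimes G^{-1},\ I \otimes
P^{-1})$ using a CHOLMOD simplicial LDL' factorization:

$$-2\log L_R = \log|C| + \log|R| + 2\log|A| + q\log|G| + n_{pe}\log|P|
             + y'Py,$$

where $\log|A|$ is the sum of log Mendelian-sampling variances, free from
the inbreeding recursion. This equals the dense formula
$\log|V| + \log|X'V^{-1}X| + y'Py$, which the tests assert to $10^{-8}$ on
small fixtures.

Each iteration updates $\theta$ by a Newton step with the average
information matrix, $\mathrm{AI}_{ij} = \tfrac12 f_i'Pf_j$ with
$f_i = (\partial V/\partial\theta_i)Py$; all seven $f_i$ come from the BLUP
solutions, so the AI matrix costs one multi-right-hand-side solve. The
score needs traces of selected elements of $C^{-1}$: the additive block on
the sparsity pattern of $A^{-1}$ and the per-animal PE diagonal blocks.
These are computed *exactly* by a Takahashi selected inverse of the sparse
factor (compiled code; the symbolic analysis is done once per fit and
reused across iterations since the pattern of $C$ is fixed), with a dense
inverse fallback below 5,000 equations. No Monte Carlo trace estimation is
involved anywhere.

Numerical safeguards, in order of application:

* starting values split the raw phenotypic variance: half to the residual,
  a quarter to each intercept variance, $1/T$ of a quarter to the slopes;
* a proposed step leaving the parameter space (eigenvalue floor $10^{-8}$)
  or failing to improve the likelihood is halved up to 15 times; if the
  step remains unusable, an EM-REML step — which cannot leave the space and
  cannot decrease the likelihood — is substituted for that iteration;
* convergence requires both max relative parameter change $< 10^{-8}$ and
  score norm $< 10^{-6}$ (typical AI-REML practice; the reference for
  comparison is statistical, means over replicates, not machine identity);
* estimates at the boundary of the parameter space (e.g. a PE covariance
  heading to singularity at reduced data sizes) make the AI step unusable
  and the EM step creep; once five successive EM steps no longer move the
  likelihood the fit stops and reports `stalled` — its estimates are the
  boundary values, its `converged` flag stays `FALSE`;
* for the *group* model a relative ridge of $10^{-8}$ is added to the
  fixed-effect diagonal: a rare size class observed at a single time point
  makes that class's two-parameter curve rank deficient. The individual
  model uses no ridge, and the ridge is forced on only when a fixed
  equation has no data at all (the zero-record edge case, where BLUP
  correctly returns the prior mean of zero).

## Validation

Breeding values are predicted by BLUP at the replicate's own REML
estimates (a flag allows the true values instead, for diagnostics). The
selection index of an animal sums its EBVs over the six weeks with unit
weights, $I_i = \sum_t \phi(x_t)'\hat a_i = (\sum_t \phi(x_t))'\hat a_i$;
because the slope column of the basis is antisymmetric this equals
$4.24\,\hat a_{i0}$, but the index is computed in full generality for
arbitrary weights. Over the validation cohort — animals with at least one
observed record; week-1 drop outs have none and are excluded — we report

* accuracy $r$: the Pearson correlation between estimated and true index,
* bias $b_1$: the slope of regressing the *true* index on the estimated
  one (1 = unbiased; $> 1$ means deflated EBVs).

The correlation is computed on the index scale (per-time-point EBVs are
also available in the EBV table for per-trait correlations).

## The reference experiment and what the tests show

The full design (11 generations, 18,000 phenotyped animals, 10 replicates
per scenario) is available via `scenario_config(scale = "paper")`. The
package's own reference experiment — used by the test suite and the
acceptance script — runs a desk-scale profile chosen so the whole grid
completes in minutes on one core: 6 generations of 10 sires × 10 dams ×
litter 6, last 3 generations phenotyped (1,800 animals, MME of roughly
9,800 equations), 5 replicates per scenario. At this scale the experiment
reproduces the study's qualitative findings with comfortable margins:

* individual-record AI-REML recovers the generating $G_{11}$, $P_{22}$ and
  $\sigma_e^2$ within Monte Carlo error of the replicate means;
* phenotype-dependent drop out biases $\hat G_{11}$ and $\hat\sigma_e^2$
  downward and pushes $b_1$ above 1, while random drop out does neither;
* accuracy orders individual > `group6x2` > `group1x12` — pooling loses
  information, and related pen mates lose least.

What passing these tests does *not* show: the simulation has no litter or
pen environmental effects, no social interaction effects, no selection, a
single trait, and a zero trait mean with no systematic environment — so
the experiment isolates exactly (and only) the consequences of pooling,
pen composition and drop out under the stated generative model. Estimates
of the permanent-environment block from *group* records at the reduced
scale are only weakly identified (their replicate spread is large, and
individual replicates can stall at the boundary); the genetic block and
the residual, the quantities of interest, are well behaved.

## Session info

```{r session, eval = FALSE}
sessionInfo()
```
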