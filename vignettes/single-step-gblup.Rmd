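---
title: "Single-step genomic BLUP for partially genotyped populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic BLUP for partially genotyped populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgblup)
```

## The problem

Genomic selection predicts the additive genetic merit (breeding value) of
animals from dense SNP genotypes, but in real pig and cattle programs only a
fraction of the population is ever genotyped — typically elite sires and
selection candidates. Phenotypes, however, are recorded on many more
animals, and the pedigree connects everyone. The single-step approach fits
one mixed model that uses all three sources at once, instead of first
computing traditional EBVs and then regressing them on markers.

## The model

For phenotypes $y$ with fixed effects $\beta$, the animal model is

$$ y = X\beta + Z\bar g + e, \qquad
   \bar g = g + a, $$

where $g$ is a genomic genetic effect and $a$ a residual polygenic effect.
Writing $w$ for the relative weight of the polygenic part, the combined
effect has

$$ \mathrm{Var}(\bar g) = \sigma^2_{\bar g}\, H_w, \qquad
   H_w = (1 - w)\, G^*(m^{obs}) + w A , $$

with $A$ the pedigree numerator relationship matrix and $G^*$ the marker
relationship matrix extended to non-genotyped animals.

**Gene contents and $G$.** SNP genotypes are coded $m_{ij} \in \{-1, 0,
1\}$ (the two homozygotes and the heterozygote). With second-allele
frequencies $\rho_j$, centring values $p_j = 2(\rho_j - \tfrac12)$ and
$s = \sum_j 2\rho_j(1-\rho_j)$, the genotyped block is

$$ G = (m - \mathbf{1}p')(m - \mathbf{1}p')'/s , $$

the VanRaden-type matrix whose expectation under the marker model equals
$A$. A weighted form $(m - \mathbf 1 p')\,\mathrm{diag}(h)\,(m-\mathbf
1p')'$ with user-supplied nonnegative per-locus weights (for example squared
SNP-effect estimates) is available through `grm(weights =)`; no
renormalisation of user weights is attempted, since the defining condition
$E[G] = A$ fixes only the default $h_j = 1/s$.

**Extension to non-genotyped animals.** Treating unobserved gene contents
as random with mean $\mathbf 1 p_j$ and covariance proportional to $A$, and
marginalising them, gives the conditional covariance of the genomic effect:

$$ G^* = \begin{pmatrix} G & G P' \\ P G & A_{22} - P (A_{11} - G) P'
   \end{pmatrix}, \qquad P = A_{21} A_{11}^{-1} . $$

$G^*$ equals $G$ when everyone is genotyped and $A$ when no one is.
Between-locus covariances of gene contents cancel in this derivation, so no
linkage-disequilibrium model is needed — this is a property of the result,
not a simplification. The conditional distribution of $g$ given observed
genotypes is treated as Gaussian; for discrete gene contents this is an
approximation, visible in the fact that the true conditional variance of an
ungenotyped animal's content depends on the realised parental genotypes
while the linear projection variance does not. The two agree in expectation
over observed configurations (law of total variance), which is what the
test suite checks.

**Sparse inverse.** The estimation path never materialises $G^*$. The
combined matrix has

$$ H_w^{-1} = A^{-1} +
   \begin{pmatrix} G_w^{-1} - A_{11}^{-1} & 0 \\ 0 & 0 \end{pmatrix},
   \qquad G_w = (1-w) G + w A_{11}, $$

$$ \log\det H_w = \log\det G_w +
   \log\det(A_{22} - A_{21}A_{11}^{-1}A_{12}), $$

so everything reduces to the sparse pedigree inverse (Henderson's rules
with inbreeding from the Meuwissen–Luo recursion; inbreeding is accounted
for because the non-inbred shortcut would break $A A^{-1} = I$), plus dense
algebra on the small genotyped block. $A_{11}$ itself comes from the
partitioned-inverse identity applied to sparse $A^{-1}$, and the Schur
log-determinant is $-\log\det[(A^{-1})_{22}]$, read off a sparse Cholesky.
$G_w$ is positive definite for any $w > 0$ even when $G$ is singular —
which it always is when allele frequencies are estimated from the genotyped
sample itself, since column-centring puts $\mathbf 1$ in the null space.

## Estimation

The mixed-model equations in $\lambda$-parameterisation
($\lambda = \sigma^2_e / \sigma^2_{\bar g}$)

$$ \begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda H_w^{-1} \end{pmatrix}
   \begin{pmatrix} \hat\beta \\ \hat{\bar g} \end{pmatrix} =
   \begin{pmatrix} X'y \\ Z'y \end{pmatrix} $$

are solved by sparse Cholesky factorisation. The REML log-likelihood is
assembled from the factorisation as
$-2\ell = (n-p)\log\sigma^2_e - q\log\lambda + \log\det H_w + \log\det M +
y'Py$, which equals the dense criterion
$\log|V| + \log|X'V^{-1}X| + y'Py$ exactly (verified against the dense
form in the tests, not merely up to a constant).

Variance components are maximised by **AI-REML with EM fallback**:

* The average-information matrix uses only data-side quantities
  ($\tfrac12 f_i' P f_j$ with $f_1 = Z\hat u/\sigma^2_g$,
  $f_2 = \hat e/\sigma^2_e$), each $Pf$ costing one extra MME solve.
* The score's trace term $\mathrm{tr}(H_w^{-1} M_{qq}^{-1})$ is the
  $\lambda$-derivative of $\log\det M(\lambda)$ and is evaluated by central
  differencing of that analytic, smooth scalar (relative step $10^{-4}$) —
  this avoids a selected-inverse (Takahashi) implementation without
  approximating the algorithm's fixed point.
* An AI step that leaves the parameter space or decreases the likelihood is
  halved up to ten times, then replaced by an EM step (guaranteed ascent).
* Near the $\sigma^2_e \to 0$ boundary (e.g. the two-step model fitted to
  smooth EBVs) EM converges only linearly; when three consecutive EM steps
  gain less than $10^{-5}$ in log-likelihood the exact one-dimensional
  profile over $\lambda$ is optimised by Brent search instead. Given
  $\lambda$, $\hat\sigma^2_e = y'Py/(n-p)$ in closed form, so this profile
  optimum *is* the joint REML optimum — the safeguard changes the route,
  not the target. Agreement with a two-dimensional grid search of the dense
  criterion is part of the test suite.

Starting values are $0.3\,\mathrm{Var}(y)$ and $0.7\,\mathrm{Var}(y)$ (a
neutral split); convergence is declared at relative parameter change
$< 10^{-8}$ or log-likelihood change $< 10^{-10}$; components are floored
at $10^{-10}\,\mathrm{Var}(y)$. Rank-deficient fixed-effect designs are
reparameterised by pivoted QR with a warning rather than an error.

**The polygenic weight.** $w$ is not estimated inside AI-REML; it is
profiled on a grid (default $w = 0.01, 0.03, \ldots, 0.19$) by
`profile(fit)`. The reported uncertainty set is
$\{w : \log L(w) > \log L(\hat w) - c\}$ with $c = 3.84$, the 95% quantile
of $\chi^2(1)$, applied literally as a drop in log-likelihood. The standard
likelihood-ratio construction would use $3.84/2$; the `ci_drop` argument
makes the choice explicit and switchable, and the default follows the
literal rule. The interval is reported as the min/max of qualifying grid
points, extended to $0$ when the lowest grid point qualifies. Ties in the
argmax resolve to the smallest $w$ (favouring the genomic information).

## Prediction beyond the estimation run

`predict(fit, ids, newped, genotypes, method =)` offers two routes.

*Extended system*: re-solve the MME over the full pedigree at the fitted
components, with all relationship blocks rebuilt. Record-less,
non-genotyped extras never change the estimation animals' solutions (exact
block-elimination identity, asserted at $10^{-8}$); genotyped extras *do*
carry information through $G^*$, and the resulting shift is reported as an
attribute rather than hidden — comparing a fit with and without candidate
genotypes is precisely the one-step vs candidate-excluded comparison.

*Shortcut* (genotyped candidates only):
$\hat{\bar g}_3 = G_{w,31} G_{w,11}^{-1} \hat{\bar g}_1$ with
$G_{w,31} = (1-w)G_{31} + wA_{31}$, where $A_{31}$ is obtained from sparse
solves against the full-pedigree $A^{-1}$ (unit right-hand sides on the
genotyped columns); the candidate self-block is never formed. The formula
is exact when $A_{32} - A_{31}A_{11}^{-1}A_{12} = 0$, i.e. when every
pedigree path from a candidate to a non-genotyped animal passes through
genotyped animals — true for terminal genotyped offspring of genotyped
parents, and violated (mildly) when candidate dams are non-genotyped, as in
the simulated scheme. The condition is not checked in production runs
(cost); `check = TRUE` verifies it numerically on small problems and warns
when it fails. No PEV is produced on this route (point prediction only, a
documented limitation).

## The breeding-program simulator

`sim_breeding_program()` generates the data the method is validated on: a
simplified pig nucleus program. Genome: 10 chromosomes of 160 cM, 5000
equidistant SNPs, 500 QTL at uniform random positions, meiosis by a Haldane
(no-interference) crossover process. Base population: founders at frequency
0.5 drift through 50 generations of random mating at effective size 100
(implemented as 50 males + 50 females), then expand to 150 boars and 1500
sows. Selection: five generations, each sow mated to a random selected
boar, litters of 10 with exactly half males; the next boars are the top 150
phenotyped males on own phenotype (ties by id), sows drawn at random.
Genotyping: the base boars (the allele-frequency source), the selected
boars of the last three generations, and 300 record-less generation-6
candidates for prediction.

Choices the design left open, fixed once:

* **QTL effect law**: "Gamma(5.4, 0.42)" is read as rate 5.4, shape 0.42
  (the parameter order used in the QTL-effect literature this echoes),
  signs $\pm$ with probability $\tfrac12$; both parameters overridable.
* **Heritability**: not stated by the scheme; effects are rescaled so the
  base-herd additive variance is exactly $\sigma^2_g = 4$ against residual
  $\sigma^2_e = 16$ ($h^2 = 0.2$), consistent with the magnitude of the
  estimated components the method reports.
* **Records**: phenotyping all males would give $5 \times 7500 = 37500$
  records; the scheme's stated total of 35000 is honoured by recording 7000
  random males per generation (`phenotype_all_males = TRUE` restores
  37500).
* **Phenotype model**: $y = \mu + TBV + e$ with a single fixed mean
  ($\mu = 10$) — no other fixed effects are part of the design.
* **Mutation**: none after the founders; drift alone shapes base LD and
  allele frequencies.

What the simulator does *not* emulate: sequence-level variation, mutation–
drift equilibrium, genotyping errors, non-additive gene action, environment
or herd structure, overlapping generations. Passing tests therefore
demonstrate correctness of the algebra and estimation machinery and the
qualitative behaviour of the method under drift, linkage and strong
selection — not calibrated performance on any real livestock population.

## Problem sizes used by the tests and the acceptance script

Exact algebraic identities (inverse, determinant, GLS/BLUP equivalence,
shortcut, augmentation) are checked on random pedigrees of up to 200
animals at tolerances $10^{-8}$–$10^{-6}$. Parameter recovery runs 20
replicates of 1000 animals × 5 records drawn from the model at
$(\sigma^2_g, \sigma^2_e, w) = (4, 16, 0.05)$, asserting recovery of the
truth within three standard errors of the replicate mean. The accuracy
experiment runs the simulator at 1/10 scale (15 boars × 150 sows × 1500
offspring per generation) over 10 seeds; the evaluation set is kept at the
full-design 300 candidates because the candidate-set correlation is the
measurement instrument — at 30 animals its sampling error (about 0.15)
exceeds the between-method differences being measured. Under these
conditions the one-step > two-step > pedigree ordering holds in the
majority of seeds, and excluding candidate genotypes from estimation moves
the one-step accuracy by about $10^{-4}$. `scripts/acceptance.R` reruns one
such replicate end to end and emits the per-method accuracies, one-step
variance components and the profile-likelihood summary as JSON.

## Known limitations

Single trait, Gaussian phenotypes only; no genetic groups or metafounders
(unknown parents are unrelated base animals); construction and inversion of
the genotyped block are dense, so the genotyped set should stay in the low
tens of thousands; the two-step comparator fits EBVs with iid residuals
(no deregression or reliability weighting, mirroring the comparison it
reproduces); PEVs require solves against the full MME and are therefore
computed on demand (automatically only for pedigrees up to 2000 animals);
the shortcut route returns no PEV. Estimation is sensitive to the allele
frequencies used for centring when the base population is unavailable —
`allele_freq_sensitivity()` demonstrates this by profiling $\hat w$ under
base-sample, current-sample and mixed-model (GLS) frequency estimates.
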