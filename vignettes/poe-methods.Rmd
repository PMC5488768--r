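---
title: "Parent-of-origin effect models in poeBLUP: methods and design"
author: "poeBLUP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-of-origin effect models in poeBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poeBLUP)
```

## The model

Genomic imprinting makes the effect of an allele depend on the parent it
was inherited from. In a pedigreed livestock population this shows up as
two distinct transmitting abilities (TA) per animal: the value of its
gametes when transmitted *as sire* (paternal expression pattern) and when
transmitted *as dam* (maternal pattern). The linear mixed model fitted to
slaughter records of non-parent fattening bulls is

$$y = X\beta + Z_s a_s + Z_d a_d + e^{*},$$

where $a_s$ and $a_d$ are the TA-as-sire and TA-as-dam vectors over all
pedigree animals,

$$\mathrm{var}\begin{pmatrix} a_s \\ a_d \end{pmatrix} =
  \begin{pmatrix} \sigma^2_s & \sigma_{sd} \\
                  \sigma_{sd} & \sigma^2_d \end{pmatrix} \otimes A
  = G_0 \otimes A,$$

and $A$ is the numerator relationship matrix. Because the recorded bulls
are not parents themselves, their own Mendelian-sampling deviation is
absorbed into the residual: record $k$ has

$$\mathrm{var}(e^{*}_k) = \sigma^2_e + (1-F_{s(k)})\sigma^2_s +
  (1-F_{d(k)})\sigma^2_d = w_k\,\sigma^2_e,$$

with $F_{s(k)}, F_{d(k)}$ the parental inbreeding coefficients — the
diagonal weights returned by `mendelianWeights()`. All components are on
the TA scale (founder TA variance $\sigma^2_s$); gametic-scale variances
are exactly twice these, and the factor cancels in every reported ratio.

The **imprinting effect** of an animal is the difference between its two
transmitting abilities, $i = a_d - a_s$; its variance
$\sigma^2_i = \sigma^2_s + \sigma^2_d - 2\sigma_{sd}$ is the imprinting
variance, and $\sigma^2_a = \sigma^2_s + \sigma^2_d + 2\sigma_{sd}$ is
the total additive genetic variance. The sign convention ($a_d - a_s$
rather than the reverse) is arbitrary and documented; it flips the sign
of every POE but no variance.

### The equivalent reparameterisation

Predicting $i$ from the two-effects model requires the prediction error
*covariance* between $\hat a_{s,k}$ and $\hat a_{d,k}$, i.e. off-diagonal
elements of the inverse MME coefficient matrix. The package therefore
also implements the reparameterised ("equivalent") model

$$y_{ijk} = x'\beta + a_{s,i} + a_{s,j} + i_j + e^{*}_{ijk},$$

in which the dam's contribution is written as her TA-as-sire plus her
imprinting effect. Each row of the TA incidence matrix now carries two
ones (sire and dam columns) and the imprinting-effect incidence matrix
one (dam column). The genetic covariance becomes

$$G_0^{eq} = \begin{pmatrix}
  \sigma^2_s & \sigma_{sd} - \sigma^2_s \\
  \sigma_{sd} - \sigma^2_s & \sigma^2_i\end{pmatrix},$$

a non-singular linear congruence of $G_0$, so the two models are
equivalent in Henderson's sense: solutions, likelihoods and prediction
error variances map into each other exactly
(`transformComponents()` is the bijection; the test suite asserts
$\hat i = \hat a_d - \hat a_s$ and equality of REML log-likelihoods to
$10^{-8}$). The payoff is that $\mathrm{PEV}(\hat i)$ is a *diagonal*
element of the inverted coefficient matrix, and the reliability

$$r^2_k = 1 - \frac{\mathrm{PEV}(\hat i_k)}{(1+F_k)\,\sigma^2_i}$$

follows immediately. The denominator uses $a_{kk} = 1 + F_k$; whether a
plain $\sigma^2_i$ denominator is preferable is a matter of convention,
so `reliability()` exposes both.

### Derived genetic parameters

`derivedGeneticParameters()` reports the relative imprinting variance
$100\,\sigma^2_i/\sigma^2_a$, the heritability
$h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$ (a documented convention:
the Mendelian-sampling share of the residual is part of $\sigma^2_a$,
not of $\sigma^2_e$), the correlation between parental effects, and the
paternal and maternal gametic contributions
$100(\sigma^2_s - \sigma_{sd})/\sigma^2_i$ and
$100(\sigma^2_d - \sigma_{sd})/\sigma^2_i$. The contributions always sum
to 100%; either one may be negative when the covariance exceeds one of
the variances, a signature of partially imprinted loci.

## Estimation

`fitReml()` maximises the REML log-likelihood by average-information
(AI) steps with an optional EM warm-up. Two computational routes
coexist deliberately:

* the exported `remlLoglik()` evaluates
  $-\tfrac12[\log|C| + \log|R| + \log|G| + y'Py + (n-p)\log 2\pi]$
  through the sparse mixed model equations (CHOLMOD factorisation);
* the fitting engine works with the dense phenotypic covariance
  $V = ZGZ' + R$ built by indexing the tabular $A$ over the parents that
  actually carry records (a few hundred to a few thousand animals), which
  makes scores, the AI matrix and the EM conditional moments exact —
  including the $\partial R/\partial\theta$ terms that arise because the
  Mendelian-sampling weights depend on $\sigma^2_s$ and $\sigma^2_d$.

The two routes are asserted equal in the tests; the dense engine is
guarded by a configurable record-count limit (default 5 000) chosen so a
20-replicate recovery study of roughly 2 000 records each completes in a
few minutes on one core.

**Feasible region.** Following the convention that the parental-effect
correlation is left unconstrained (so the imprinting test stays fully
general), only the two physical TA variances and the residual are pinned
at a small positive floor; the covariance — and hence the implied
$\sigma^2_i$ — may move outside the positive-semidefinite cone during
and at the end of estimation. The pinning acts on the
imprinting-scale coordinates for *every* parameterisation, which makes
the feasible region identical under the bijection; this is what lets the
imprinting and equivalent fits agree to machine precision rather than
merely approximately. When an indefinite $G_0$ must be *used* (solving
MME, reporting derived ratios), it is projected onto the nearest PSD
matrix with a tiny ridge, with a warning; estimates themselves are never
silently altered.

EM steps freeze the weights within an iteration and refresh them
afterwards; a step-halving safeguard keeps the log-likelihood monotone
to within $10^{-10}$ and also protects AI steps near boundaries.
Default tolerances: $10^{-8}$ on the log-likelihood change and $10^{-6}$
relative on components, at most 200 iterations; starting values are
$0.1, 0.09, 0.1, 0.8$ times $\mathrm{var}(y)$ for
$(\sigma^2_s, \sigma_{sd}, \sigma^2_d, \sigma^2_e)$.

**Testing.** `rlrt()` compares the imprinting model against the
animal-model null ($\sigma^2_s = \sigma^2_d = \sigma_{sd}$, a single TA
per animal) and refers $2\Delta\ell$ to $\chi^2_2$. The asymptotic null
is a mixture of $\chi^2_1$ and $\chi^2_2$ with proportions that are
unknown for correlated data, so the 2-DF reference is deliberately
conservative; the suite verifies empirically (200 null replicates) that
the size at the 5% level stays at or below nominal. Mixture references
are intentionally not implemented.

**Standard errors.** `deltaSE()` propagates the inverse AI matrix
through analytic gradients of each derived parameter. The delta
approximation is a linearisation: for ratio parameters it is accurate
when component SEs are small relative to the estimates, and the test
suite checks it against brute-force sampling from the asymptotic normal
in that regime. At desk-scale sample sizes the per-replicate estimate of
the relative imprinting variance is heavy-tailed (the denominator
$\sigma^2_a$ is itself noisy), which is why the recovery study reports
the replicate mean with its Monte-Carlo standard error.

## Genetic groups and pedigree utilities

Unknown parents can be materialised as phantom records
(`addPhantomParents()`) and assigned to genetic groups by sex and
expected birth-year bin (`assignPhantomGroups()`): one open bin below
1974, interior bins of width 3 up to 1996, one open bin above, duplicated
for phantom sires and dams — all configurable, since published group
layouts differ in exactly where the edges fall. The expected birth year
of a phantom is the mean over its dated offspring of (offspring year
minus a per-path generation-interval offset, default 6 years for all
four selection paths); undated chains fall into a configured fallback
bin, with a message. `buildAInverse()` implements Henderson's rules with
inbreeding and, when groups are supplied, the Quaas–Pollak/Westell
modification: group columns replace phantom parents, the
Mendelian-sampling variance of an animal is driven by its known real
parents only, and phantoms carry no equations. One reference group
(default the last label) is pinned to zero, removing the intrinsic
confounding between the group means and the intercept. Because the
grouped relationship structure is singular by construction, REML
estimation is restricted to ungrouped pedigrees; the pipeline estimates
components ungrouped and solves with groups when configured — consistent
with the empirical observation that groups barely move variance
components in data of this kind.

Inbreeding uses the Meuwissen–Luo accumulation of $A = LDL'$ diagonals;
`relationshipBlock()` is the independent tabular recursion, and pruning
(`prunePedigree()`) restricts the pedigree to the anchor animals plus
all their ancestors. The published pruning tool this mirrors is cited in
the literature without an algorithmic description; the package keeps
every ancestor rather than absorbing single links, trading size for an
exactly unchanged relationship matrix. That rule is idempotent, which
the suite checks on random pedigrees.

## The binary-trait (PQL) route

Carcass conformation and fat score are near-binary in practice, so the
package fits them as binary traits with a logit link: class zero
collects the better conformations (E, U, R) or lean fat scores (1, 2).
`pqlFit()` iterates the standard penalised quasi-likelihood loop: with
$t = 1$ for class-zero records and $p = \mathrm{logit}^{-1}(\eta)$, the
working variable is $\zeta = \eta + (t - p)/(p(1-p))$, fitted by REML
with the residual variance fixed at 1 and heterogeneous residual weights
$1/(p(1-p))$; BLUP solutions update $\eta$ and the loop repeats until
$\max|\Delta\zeta| < 10^{-6}$ (at most 50 outer iterations). No
Mendelian-sampling inflation is applied on the quasi-likelihood scale.
Logit-scale heritabilities use $\pi^2/3$ as the residual contribution.
Once the working variable has stabilised, the imprinting and equivalent
parameterisations of the inner REML problem agree to machine precision —
the same equivalence as on the linear scale, now conditional on the
working data. PQL point estimates for binary data carry the well-known
mild downward bias; the recovery test operates at half-sib family sizes
(around 50 progeny per sire) where that bias stays within the
Monte-Carlo uncertainty of a small replicate study, and the
LMM-vs-GLMM comparison is asserted as a rank correlation rather than as
equality of scales.

Records near separation ($|\eta|$ beyond a guard of 15) raise an error
naming the affected comparison groups rather than returning degenerate
weights.

## The simulator

`simulateDataset()` generates the exact structure the estimators assume,
so every claim above is testable without proprietary data:

* **Pedigree**: discrete generations with parent pools spanning the two
  preceding generations, a configurable number of sires per generation
  (default 20, giving strong paternal half-sib families), dams reused
  across matings (parity), optional sire–daughter matings for inbred
  loops, and twinning at rate 0.03.
* **Genetic effects**: whole-gamete infinitesimal gene dropping —
  founder TA pairs $\sim N(0, G_0)$, descendants the parental mean plus
  a Mendelian deviation with covariance
  $(\tfrac12 - \tfrac14(F_s + F_d))G_0$ — which reproduces
  $G_0 \otimes A$ exactly (checked by Monte-Carlo against the tabular
  $A$).
* **Phenotypes** on non-parent animals only (fattening bulls carry no
  equations in the reduced model): fixed comparison-group, parity and
  birth-type effects, a cubic regression on slaughter age, the genetic
  part $a_s(\mathrm{sire}) + a_d(\mathrm{dam})$, the record-level
  Mendelian deviation $\phi$ with variance
  $(1-F_s)\sigma^2_s + (1-F_d)\sigma^2_d$, and an i.i.d. residual.
* **Binary classes** drawn Bernoulli from a logit linear predictor built
  on the true genetic values (or from a thresholded Gaussian latent
  variable, for LMM/GLMM concordance checks).

Default generating components are $\sigma^2_s = 0.8$,
$\sigma^2_d = 1.3$, $\sigma_{sd} = 0.859$, $\sigma^2_e = 11.45$: a
maternally dominated relative imprinting variance of 10% of
$\sigma^2_a$, a parental-effect correlation of about 0.84 and a
heritability of 0.25 — the shape reported for slaughter traits in
dairy-breed fattening bulls, on an arbitrary trait scale. The defaults
deliberately yield a *negative* paternal contribution
($\sigma_{sd} > \sigma^2_s$), so the reporting path for partially
imprinted architectures is exercised routinely.

What the simulator does **not** emulate: selection over generations
(parents are drawn at random, so genetic trend is absent by design),
locus-level recombination (the infinitesimal covariance is all the
estimators use), maternal environmental effects, heterogeneous residual
variances across comparison groups, and any genetic link between the
birth-type factor and actual twinning. Passing tests therefore establish
correctness of the machinery under the model's own assumptions, not
robustness to violations of them.

## Problem sizes and numerical choices

The shipped studies use sizes chosen to give informative Monte-Carlo
checks at interactive runtimes on a single core: model-equivalence and
PEV identities on populations of roughly 500–700 pedigree animals with
300+ records; component recovery over 20 replicates of about 1 800
records on pedigrees of about 2 800 animals; RLRT size over 200 null
replicates of about 250 records; PQL recovery over 6 replicates of about
830 binary records. Dense-engine fits at the recovery size take a few
seconds per replicate; the full recovery study runs in about four
minutes. PEV extraction inverts the sparse coefficient matrix (default
guard: 20 000 equations) — exactness is the point of the equivalent
model, so no approximate reliability algorithm is included.

Other numerical choices worth knowing: fixed-effect factors drop their
first level and the age polynomial is centred (conditioning of $C$);
single-level factors and constant ages are dropped from the design
entirely; degenerate records with sire equal to dam are rejected;
`computePEV()` clips tiny negative diagonal round-off at zero; and
reliabilities are clipped to $[0, 1)$.
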