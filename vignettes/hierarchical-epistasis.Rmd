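---
title: "Modelling hierarchical epistasis in overdispersed branching counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hierarchical epistasis in overdispersed branching counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierepi)
```

## The scientific problem

Tomato inflorescence branching is controlled by a small regulatory network
of two paralogue pairs: the PLETHORA transcription factors *PLT3*/*PLT7*
and their downstream SEP-clade MADS-box targets *J2*/*EJ2*. Mutations in
any single gene are largely cryptic — wild-type plants rarely branch — but
combinations of coding mutations and *EJ2* promoter alleles of graded
strength produce anything from a handful of branches to massive meristem
overproliferation. `hierepi` provides the statistical machinery to analyse
such genotype–phenotype maps: per-plant branching totals over a counted
number of inflorescences, for hundreds of genotypes segregating in F2
populations.

## Data model and filtering

The unit of likelihood evaluation is the plant: total branching events
$y_i$ over $t_i$ countable inflorescences. Per-inflorescence observations
are summarized by `summarize_plants()` with the field protocol's rules:

* counts above 60 were recorded as "too many to count" (TMTC) and are
  treated as 60 — the value is taken at face value, with no
  censored-likelihood correction (matching how such data are analysed in
  practice; see *Known limitations*);
* proliferated or inhibited inflorescences are excluded entirely and
  contribute to neither $t_i$ nor $y_i$;
* plants left without countable inflorescences are dropped (the likelihood
  requires $t_i \ge 1$).

## Count likelihoods

Branching counts are substantially more variable between plants than a
Poisson model allows (`dispersion_summary()` makes this check). The
package therefore models

$$y_i \sim \mathrm{NB}\big(t_i \, f^{-1}(\mu(x_i)),\ \alpha\big),
\qquad \mathrm{Var}(y_i) = m_i + \alpha m_i^2,$$

the NB2 parameterization with a single overdispersion parameter $\alpha$
shared across genotypes, interpreted as plant-to-plant variability. A
Poisson family and both the log and identity links are available; the
additive genotype basis under the log link is the *multiplicative* model
of gene action (fold effects of loci multiply).

Genotypes are encoded with the standard additive/dominance scheme,
$s^a \in \{-1, 0, 1\}$ and $s^d \in \{0, 1, 0\}$ for homozygous wild type,
heterozygous and homozygous mutant. The multi-allelic *EJ2* promoter
series is represented as six mutually exclusive biallelic loci:
non-carriers are coded wild type, and no interaction columns are built
between two *EJ2* alleles (they never co-occur in an F2 plant). The
pairwise basis adds the four products ($aa$, $ad$, $da$, $dd$) for every
compatible locus pair; constant and duplicate columns are dropped
data-driven and logged, so term counts can be reconciled for any cross
design.

## The hierarchical multilinear model

Within each paralogue pair, the model is saturated: every non-wild-type
within-pair genotype class $g$ gets a free log-scale effect
($\theta^{\mathrm{PLT}}_g$ or $\theta^{\mathrm{SEP}}_g$), which is
equivalent to a full additive + dominance + pairwise-interaction model
inside the pair. The two within-pair phenotypes
$\varphi_{\mathrm{PLT}}$ and $\varphi_{\mathrm{SEP}}$ are then combined
through a multilinear interaction with a single masking parameter:

$$\mu(x_i) = \theta_{\mathrm{WT}} + \varphi_{\mathrm{PLT}}(x_i) +
\varphi_{\mathrm{SEP}}(x_i) - \theta_{\mathrm{Int}}\,
\varphi_{\mathrm{PLT}}(x_i)\,\varphi_{\mathrm{SEP}}(x_i),$$

and the expected branching rate per inflorescence is $e^{\mu}$. With
$\theta_{\mathrm{Int}} = 0$ the pairs combine multiplicatively; with
$\theta_{\mathrm{Int}} > 0$ mutations in one pair progressively shrink
(mask) the effects of mutations in the other, with complete masking at
$\varphi = 1/\theta_{\mathrm{Int}}$. Two consequences used throughout the
package:

* the fold effect of a combination in pair A, placed in a background of
  pair B with effect $\varphi_B$, is the wild-type-background fold effect
  raised to the power $1 - \theta_{\mathrm{Int}} \varphi_B$;
* plotting log phenotypes of pair-A combinations in a mutant background
  against the wild-type background gives a straight line of slope
  $1 - \theta_{\mathrm{Int}} \varphi_B$ — exactly 1 under multiplicative
  gene action. `background_rescaling()` estimates these slopes by total
  least squares (both variables are estimates, so orthogonal regression is
  the appropriate fit).

## Fitting and numerical choices

All fits are exact maximum likelihood with analytic gradients.

* Poisson log-link fits use IRLS (`stats::glm`). All other count GLMs
  (negative binomial, identity link) are fit by BFGS over
  $(\theta, \log\alpha)$, initialized from a Poisson or weighted
  least-squares fit; coefficient covariance comes from the observed
  information. Identity-link fits whose means turn non-positive are refit
  with a softplus positivity barrier and flagged — the unconstrained
  identity-link NB problem is not well defined otherwise.
* The hierarchical model is fit with the Adam optimizer (learning rate
  0.01, up to 10,000 iterations, stopping early when the gradient
  infinity-norm falls below $10^{-5}$), followed by a BFGS polish so the
  optimum is deterministic and independent of stopping wobble.
  Initialization starts at the multiplicative model: $\theta_\mathrm{WT}$
  and the $\varphi$ tables are seeded from the additive log-link fit and
  $\theta_{\mathrm{Int}} = 0$. Genotype classes never observed in the data
  are not parameterized (nothing is imputed). If only one pair segregates,
  $\theta_{\mathrm{Int}}$ is unidentifiable and is fixed at 0 with a
  warning.
* Confidence intervals for $\theta_{\mathrm{Int}}$ use the profile
  likelihood (`confint_theta_int()`), since the curvature can be
  asymmetric near masking saturation; all other parameters are
  re-optimized at each candidate value from a warm start.
* Genotype–season phenotype estimates (`genotype_season_mle()`) come from
  a joint NB fit with one dummy per combination and a shared $\alpha$,
  profiled over $\log\alpha$ with the per-combination log means solved by
  Newton steps. With constant exposure the means reduce to the closed
  form $\sum y / \sum t$. Wald intervals are computed on the log scale;
  intervals spanning more than a thousand-fold range are flagged for
  display only, never used to filter fitting. All-zero combinations sit on
  the $\mu = 0$ boundary and are flagged degenerate.
* Deviances are computed against the plant-level saturated model at each
  fit's own $\hat\alpha$ (standard GLM reporting). Because per-model
  $\hat\alpha$'s break comparability across nested models — the
  intercept-only fit absorbs genotype structure into a very large
  $\hat\alpha$ — `deviance_explained()` also accepts a `common_alpha`
  argument; monotonicity in model size is guaranteed only for the
  common-$\alpha$ variant, and both are reported by the acceptance
  script.
* Model comparison uses AIC ($2k - 2\ell$, counting $\alpha$) and its
  evidence ratio $\exp(\Delta\mathrm{AIC}/2)$, plus likelihood-ratio
  tests; testing the NB against the Poisson puts $\alpha$ on its boundary,
  which is noted in the output (the $\chi^2_1$ reference is
  conservative).
* Cross-validation (`cross_validate()`) leaves out whole seasons or
  genotype groups, re-estimates held-out genotype(-season) means with
  `genotype_season_mle()` on the held-out plants only, and scores the
  squared Pearson correlation on the $\log(1+x)$ scale on which branching
  phenotypes are conventionally displayed.

## The synthetic-data generator

`simulate_branching_study()` emulates the study design: six F2
populations, each segregating *PLT3*, *PLT7*, *J2* and one *EJ2* promoter
allele with Mendelian 1:2:1 ratios at unlinked loci, 10 inflorescences
scored per plant (four primary plus six axillary), populations of a few
hundred plants across one or more seasons. Phenotypes are drawn from the
hierarchical model: a per-plant gamma multiplier (mean 1, variance
$\alpha$) shared across the plant's inflorescences makes plant totals
exactly NB2 — matching the likelihood's unit of analysis and the
plant-to-plant interpretation of $\alpha$.

The default generative truth (`default_truth()`) uses effect sizes of the
magnitude reported for this network: a wild type with 0.15 branching
events per inflorescence, an 11.24-fold homozygous *plt3* effect, an
~81-fold *plt3 plt7/+* combination, several-fold super-multiplicative
within-pair synergies for the *EJ2* allelic series crossed to *j2*
(roughly 6- to 17-fold excesses), masking $\theta_{\mathrm{Int}} = 0.12$
and overdispersion $\alpha = 0.3$. These defaults were fixed once as the
package's study conditions.

Observational artifacts are configurable but default to *off*: the
per-inflorescence probabilities of proliferated/inhibited records are 0,
and no censoring is applied (`censor_value = Inf`). The field protocol's
TMTC cap is emulated by passing `censor_value = 60`. The default is
deliberate: the likelihoods carry no censored-data correction, so a clean
closed loop (simulate, then re-estimate) is exact only without censoring.
With the cap active, counts from the strongest genotype classes are
truncated at the cap, which necessarily biases the largest within-pair
effects — and through them the masking parameter — so parameter-recovery
claims are made under the artifact-free default, while the cap itself is
exercised in robustness tests. Consequently, what the passing recovery tests show
about real data is limited: real studies do censor and do lose extreme
genotypes to proliferation, and estimates of strong effects are
correspondingly conservative there. The generator also does not emulate
spatial field structure, genotyping error, linkage, or season-by-genotype
interactions (season offsets are a simple log-scale shift, default 0).

## Problem sizes used by the tests

The test suite runs the full closed loop at 4,000 plants (six populations,
10 inflorescences each) with 20 replicate studies for parameter recovery,
and 2,000 plants per population for the model-ranking experiment; unit
tests use a two-population design of a few hundred plants. These sizes
were chosen to mirror the study scale (populations of 192–384 plants,
~10 inflorescences per plant) while keeping Monte-Carlo error on recovery
summaries a small fraction of the 5% bias budget.

## Known limitations

* No censored-likelihood option: TMTC = 60 is treated as observed. For
  datasets where a large fraction of inflorescences exceed the cap, all
  strong effects (and the masking parameter) are biased toward the cap.
* The hierarchical model covers exactly two interacting groups; deeper
  hierarchies (three or more pairs) are out of scope.
* Season enters only as an optional offset in the generator; the fitted
  hierarchical mean is pooled across seasons, as in the study's pooled
  analysis.
* Wald intervals for genotype–season means ignore the (small) covariance
  with the shared $\hat\alpha$.
* No linkage or selfing-generation dynamics beyond the F2; no
  zero-inflated or quasi-likelihood families; no random-effect terms.

## A compact worked example

```{r example, eval = FALSE}
sim <- simulate_branching_study(cross_design(n_plants = 384), seed = 1)
mult <- fit_count_glm(sim$records, basis = "additive", link = "log")
pw   <- fit_count_glm(sim$records, basis = "pairwise", link = "log")
hier <- fit_hierarchical(sim$records)
glance(hier)
synergy_fold_excess(pw, c("PLT3", "PLT7"), c("HET", "MUT"))
confint_theta_int(hier, sim$records)
autoplot(response_surface(hier))
```
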