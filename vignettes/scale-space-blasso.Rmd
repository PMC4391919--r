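---
title: "Scale-space Bayesian LASSO for QTL mapping: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-space Bayesian LASSO for QTL mapping: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssblasso)
```

## The problem

In QTL association mapping one regresses a quantitative phenotype on
hundreds of marker genotypes, coded $-1/+1$ for the two genotype classes of
a line cross, with fewer individuals than markers and only a handful of
truly associated loci.  The Bayesian LASSO handles this with the model

$$
\mathbf{y} = \mu \mathbf{1} + \mathbf{X}\boldsymbol\beta + \boldsymbol\varepsilon,
\qquad \varepsilon_i \sim N(0, \sigma^2),
$$

a conditional Laplace prior on each effect,
$p(\beta_j \mid \sigma^2) \propto e^{-\lambda |\beta_j| / \sigma},$
expressed through the usual exponential scale mixture
($\beta_j \mid \sigma^2, \tau_j^2 \sim N(0, \sigma^2\tau_j^2)$,
$\tau_j^2 \sim \text{Exp}(\lambda^2/2)$), the improper priors
$p(\sigma^2) \propto 1/\sigma^2$ and $p(\mu) \propto 1$, and — when the
tuning parameter is random — $p(\lambda) \propto 1/\lambda$.  Scaling the
Laplace rate by $\sigma$ keeps the joint posterior unimodal.

Four practical difficulties motivate everything else in the package:

1. **False positives at weak shrinkage.**  When $\lambda$ is small and
   $m \approx n$, the fitted values track the data, the posterior of
   $\sigma^2$ collapses, and many null effects look credibly non-zero.
2. **Collinearity.**  Neighboring markers in a line cross are strongly
   correlated, so one association is smeared over several coefficients and
   none of them is individually credible.
3. **Multiplicity.**  Flagging each coefficient at a marginal level ignores
   that hundreds are tested at once.
4. **Choice of $\lambda$.**  Detection conclusions change with the penalty,
   and committing to a single value (random, cross-validated, or otherwise)
   hides that sensitivity.

## What the package computes

**Scale space.**  Instead of one $\lambda$, `ss_scan()` fits an independent
Gibbs chain at every value of a logarithmic grid
(`lambda_grid(-0.7, 2, 80)` is the canonical line-cross choice) and
assembles maps with loci on one axis and $\log_{10}\lambda$ on the other:
the posterior-mean effects quantized to seven bands (`quantize_effects()`;
bands at $B/20$, $B/5$, $2B/5$ of the map-wide maximum $B$, signed), and
per-locus credibility types.  Persistent color bars across many scales are
the signature of a real association.

**Detection.**  `pw_detect()` flags an effect when the proportion of
posterior draws sharing a sign strictly exceeds `alpha_pw` (default 0.975,
the two-sided 95% credible-interval convention).  `hpw_select()` performs
simultaneous inference: candidates are visited in descending marginal sign
probability and kept while the *joint* probability that all selected
effects carry their signs exceeds `alpha_hpw` (default 0.95), so the number
of irrelevant candidates does not dilute the strongest signals.

**Combined effects.**  For every marker pair whose genotype agreement
(disagreement) proportion strictly exceeds `rho` (default 0.8),
`enumerate_pairs()` registers a sum (difference) candidate
$\delta_{jk} = \beta_j \pm \beta_k$, and `combined_effect_draws()` forms its
posterior draws by adding or subtracting the parent columns draw by draw.
A QTL lying between two markers, or deliberately removed from the design,
remains detectable through the combined effect of its flanking markers even
when neither single coefficient is credible.  Per-locus credibility types
encode the outcome: $\pm 1$ for a credible single effect, $\pm 0.75$ for
the stronger member of a credible combined effect (by the singles' own
marginal probabilities), $\pm 0.25$ for the weaker member, with the largest
magnitude winning when several conditions hold.

**Permutation calibration.**  `permutation_lambda_threshold()` permutes the
phenotype (breaking all associations), rebuilds the credibility map for
each permutation, counts per-$\lambda$ false positives (types $\pm 1$ or
$\pm 0.75$ — weaker members are not counted, because one real association
legitimately creates several credible combined effects), and reports the
smallest grid value from which on at least 95% of permutations are clean.
`alpha_curve()` instead raises the credibility level with shrinkage: per
$\lambda$, $\alpha(\lambda)$ is the 0.95 empirical quantile of the
permutation maxima of the marginal sign probability, and
`detect_with_alpha_curve()` flags effects above
$\max\{\alpha(\lambda), 0.975\}$.

## Sampler details

All full conditionals of the hierarchy are conjugate and are iterated in
compiled code: normal draws for each $\beta_j$ and for $\mu$, inverse-gamma
for $\sigma^2$ (shape $(n+m)/2$), inverse-Gaussian for each $1/\tau_j^2$
(mean $\lambda\sigma/|\beta_j|$, shape $\lambda^2$), and — with a random
tuning parameter — $\lambda^2 \mid \boldsymbol\tau^2 \sim
\text{Gamma}(m, \sum_j \tau_j^2/2)$, the conditional implied by
$p(\lambda) \propto 1/\lambda$.  The samplers were validated against
dense-grid quadrature of the analytic posterior for one and two markers
(see `tests/testthat/test-acceptance.R`).

Numerical choices worth knowing:

* $|\beta_j|$ is clamped at $10^{-10}$ before the inverse-Gaussian draw;
  its mean diverges as $\beta_j \to 0$ and the clamp trades an unmeasurably
  small bias for unconditional stability.
* The design is *not* column-standardized by default — $-1/+1$ genotype
  codings are conventionally used as-is — but `standardize = TRUE` is
  available for non-genetic regressors.
* The intercept is sampled under its flat prior by default;
  `center_y = TRUE` centers the phenotype and fixes $\mu = 0$ instead.
* All randomness flows through R's RNG from the recorded seed, so chains
  are bit-reproducible.  Scans and calibrations derive one seed per
  (chain, grid index, permutation), which makes the result independent of
  evaluation order.
* Default schedules: burn-in 25000, thin 4, 10000 draws for fixed
  $\lambda$; burn-in 70000, thin 10, 15000 draws for random $\lambda$.
  The test schedule (burn-in 2000, thin 2, 2000 draws) was checked to give
  sign probabilities indistinguishable from the long schedule on the
  bundled designs.

**Bayesian ridge.**  `gibbs_bridge()` swaps the Laplace prior for
$\boldsymbol\beta \mid \sigma^2, \lambda \sim N(0, \sigma^2/\lambda\, I)$.
This parametrization was chosen so that $\lambda$ plays the same penalty
role as in the LASSO (larger is sparser/smoother) and the prior scales with
$\sigma^2$ exactly as the Laplace prior does; other parametrizations (e.g.
prior variance free of $\sigma^2$) are defensible, and this is a design
choice, not a derived fact.

## Decisions where the design was genuinely open

* **Strictness at thresholds.**  "Exceeds" is read strictly everywhere: a
  sign proportion of exactly 0.975, or a pair agreement of exactly
  $\rho$, does not qualify.
* **HPW tie-breaking.**  Candidates with equal marginal probability are
  ordered combined-before-single, then by ascending column index — an
  arbitrary but fixed rule that makes selection deterministic.
* **Difference signs.**  A credibly negative difference
  $\beta_j - \beta_k$ is reported as positive evidence at locus $k$ and
  negative at locus $j$; member strength always compares the singles' own
  marginal probabilities.
* **Quantization edges.**  Magnitudes exactly on a band edge take the lower
  band; $B$ is computed over the whole map so colors are comparable across
  rows.
* **$\lambda^*$ as a grid element.**  The permutation threshold is
  reported as the smallest grid value from which on the zero-false-positive
  fraction stays at or above the level (a monotone envelope, no
  interpolation); if even the largest grid value fails, the threshold is
  `NA` with a warning.
* **Quantile rule for $\alpha(\lambda)$.**  The smallest observed
  permutation maximum whose rank fraction reaches the level — conservative
  and interpolation-free.
* **One permutation set.**  The same permutations are reused across the
  grid so that per-$\lambda$ comparisons share their nulls; this reduces
  Monte-Carlo noise in the shape of the false-positive profile.

## The synthetic designs

`barley_fixture()` emulates a collinear line-cross experiment: 145
individuals, 127 markers simulated as two-state Markov chains whose
adjacent-marker correlation is $1 - 2r \approx 0.8$ ($r = 0.1$, the regime
of a dense line-cross map), eight QTLs with effects 3, 3.5, 4, −2.5, −3,
−2, 3, −3 at loci 3, 10, 20, 34, 51, 72, 84, 108, genotypes 3.4% missing
at random and singly imputed with fair $\pm 1$ draws, five designated
high-missingness markers removed, and — the deliberately hard part — four
of the eight QTL markers (3, 51, 84, 108) removed before analysis so that
only their flanking markers carry the signal.  The removal bookkeeping
reproduces the canonical adjusted indexing (kept QTLs at 9, 19, 33, 67;
flanking pairs (2,3), (48,49), (78,79), (100,101)).

`wheat_fixture()` emulates an association panel: 300 individuals, 400
mutually independent markers, nine QTLs (effects 1.75 to 2.5 in magnitude),
40 non-QTL markers at strong allele-frequency imbalance (majority 0.95) and
two QTLs (loci 7 and 76) at moderate imbalance (0.86/0.87) to reproduce the
hard-to-detect cases and the imbalance-driven spurious combined-effect
candidates such panels exhibit.

**Noise level.**  Both fixtures default to `noise_sd = sqrt(8)`.  The
package targets realized heritabilities
$h^2 = \mathrm{Var}(\mathbf{X}\boldsymbol\beta)/\mathrm{Var}(\mathbf{y})$
near 0.9 (line cross) and 0.8 (panel), the canonical regime for these
designs: with the effect tables above, $\sum_j \beta_j^2 \approx 74.5$
(line cross) and $\approx 40$ (panel), so unit-variance $\pm 1$ markers
give those heritabilities only when the noise *variance* is about 8.  A
noise *SD* of 8 would put $h^2$ at roughly 0.56 and 0.36 — a different and
much harder regime than the one these designs are meant to represent.  The
generator takes `noise_sd` literally, so either regime can be simulated
explicitly.

What the generator does *not* emulate: real line-cross maps have
heterogeneous marker spacing (local correlation often far above 0.8),
segregation distortion, chromosome structure, and missingness concentrated
at particular markers.  Passing tests on these fixtures therefore show the
machinery is correct under the stated statistical structure, not that any
particular real data set will yield the same thresholds or detection
counts.  In particular, with homogeneous adjacent correlation 0.8 the
weaker QTL signals stop being credible around $\lambda \approx 10^{1.2}$,
while the permutation threshold sits near $10^{1.4}$–$10^{1.6}$, so
simultaneous inference above the threshold recovers only the strongest
half of the regions; heterogeneous real maps with tighter local LD retain
more.  The scaled-down study sizes used in the tests (20-value grid, 20
permutations, 2000-draw chains, 10 seeds) were chosen as the smallest
sizes at which the thresholds stabilize.

## Known limitations

* Combined effects are pairwise only; triples and larger groups are out of
  scope.
* The permutation calibration runs one chain per (permutation, grid value)
  — the dominant cost.  Chain-reuse schemes (importance reweighting across
  neighboring $\lambda$, permutation-within-chain) are deliberately not
  implemented: their statistical justification is unsettled.
* The frequentist LASSO path and its BIC/CV tuning are out of scope; the
  ridge variant is included for comparison only.
* Exchangeability of phenotypes under the null is assumed by the
  permutation procedures; structured populations violate it.

## A miniature walk-through

```{r example, eval = FALSE}
fx <- barley_fixture(seed = 1)
grid <- lambda_grid(-0.7, 2, 20)
cfg <- sampler_config(lambda = 1, burn_in = 2000, thin = 2, n_draws = 2000,
                      seed = 1)
maps <- ss_scan(fx$X, fx$y, grid, cfg, use_combined = TRUE)
cal <- permutation_lambda_threshold(fx$X, fx$y, grid, cfg, n_perm = 20,
                                    mode = "hpw")
render_maps(maps, "maps", qtl = unlist(fx$truth$regions),
            lambda_threshold = cal$lambda_threshold)
```
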