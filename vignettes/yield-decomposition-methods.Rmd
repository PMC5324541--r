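---
title: "Decomposing domestication's effect on grain yield: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing domestication's effect on grain yield: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldparts)
```

## The scientific question

Domesticated cereals and pulses out-yield their wild progenitors, but a
higher seed yield per plant can arise through very different routes: a
bigger plant, faster or longer growth, a larger share of biomass committed
to reproduction, less of that share wasted on chaff or pod walls, heavier
individual seeds, or more of them. `yieldparts` implements the quantitative
machinery for telling these routes apart in a common-garden comparison of
crop landraces with their wild progenitors: two exact decompositions of
yield, a delta-method apportionment of yield variance among traits, a
functional growth analysis giving growth rate at a common size, and
phylogenetically controlled crop-versus-progenitor contrasts.

## The two yield decompositions

Write $Y$ for total seed mass per plant (g), $M_s$ for mean individual seed
mass at sowing (g), $\tilde\lambda$ for the average relative growth rate
(g g$^{-1}$ day$^{-1}$), $d$ for the duration of growth (days), $A_r$ for
the fraction of above-ground biomass in reproductive structures, and $c$
for the fraction of reproductive mass that is chaff or pod material. The
growth/allocation route is

$$Y = M_s \, e^{\tilde\lambda d} A_r (1 - c).$$

Because $\tilde\lambda$ is *defined* as $\ln(M_d/M_s)/d$ with $M_d$ the
final above-ground mass, substituting it back gives the exact identity
$Y = M_d A_r (1 - c)$ — the package treats this as an invariant and tests it
to $10^{-12}$ on noiseless synthetic data. The packaging route is

$$Y = M_s N_s N_i,$$

with $M_s$ now the seed mass at final harvest, $N_s$ seeds per
infructescence and $N_i$ infructescences per plant; for pulses, whose pods
were not counted individually, the product $N_s N_i$ is replaced by the
total seed count. The harvest index is $Y/M_d$.

Two conventions deserve note. First, masses are stored in the field units
(seed masses in mg, plant masses in g) and converted once, inside
`deriveComponents()`. Second, reproductive biomass includes culm and chaff;
the package's default bookkeeping places culm mass inside the chaff
component so that reproductive mass equals chaff + grain exactly, which is
what makes both identities exact. A `culm_in_chaff = FALSE` switch computes
$c$ from chaff and grain only; the recorded masses never change, only the
derived proportion.

## Variance decomposition with covariances

With the component vector $\theta = (M_s, \tilde\lambda, d, A_r, c)$ (or
the packaging set), the first-order approximation

$$\mathrm{Var}(Y) \approx \sum_i \sum_j \mathrm{Cov}(\theta_i, \theta_j)
\frac{\partial Y}{\partial \theta_i}\frac{\partial Y}{\partial \theta_j}$$

defines a square contribution matrix; a trait's contribution to the
variance in yield is its row sum divided by the grand total
(`contributionTable()`). Row sums retain the covariance terms, so shares
can exceed one or fall below zero when traits covary — that is the point of
the method, not an artifact. Shares always total exactly one by
construction.

The gradients are analytic ($\partial Y/\partial M_s = Y/M_s$,
$\partial Y/\partial \tilde\lambda = Yd$, $\partial Y/\partial d =
Y\tilde\lambda$, $\partial Y/\partial A_r = Y/A_r$, $\partial Y/\partial c
= -Y/(1-c)$) and are verified against central finite differences in the
test suite.

**Accuracy of the first-order approximation.** The small parameter is not a
trait's CV but its *elasticity times* its CV. For most components the
elasticity of $Y$ is 1, but for $\tilde\lambda$ and $d$ it is
$\tilde\lambda d = \ln(M_d/M_s)$, typically 5–8 in these data: a 10% CV in
$\tilde\lambda$ perturbs $Y$ by 50–80% and the delta total then
underestimates the Monte-Carlo variance badly. `deltaAccuracy()` reports
the delta/empirical variance ratio and flags departures; the test suite
demonstrates agreement within 5% when the amplified CVs are small (CVs of
10% on $M_s$, $A_r$, $c$; 1% on $\tilde\lambda$ and $d$) and flags the
large-CV regime. Analysis units default to species means on the
measurement scale, since the delta method differentiates $Y$ in natural
units; a `per_plant` switch exists, and the sample covariance uses the
$n-1$ denominator.

## Functional growth analysis

Average RGR conflates size and growth-rate differences: a big-seeded
species can convert seed mass to plant mass efficiently while growing
slowly at any given size. The growth-analysis experiment therefore fits
log mass against time with a four-parameter logistic,

$$m(t) = A + \frac{B - A}{1 + e^{(t_{mid} - t)/s}},$$

and reads off the slope where the fitted curve crosses a common size
$M_c$: with $p^\ast = (\ln M_c - A)/(B - A)$,

$$\lambda_s = \frac{(B - A)\,p^\ast(1 - p^\ast)}{s}, \qquad
t^\ast = t_{mid} - s \ln\frac{1 - p^\ast}{p^\ast}.$$

At $p^\ast = 1/2$ this is the maximum slope $(B-A)/(4s)$. $\lambda_s$ is
invariant to the mass unit as long as the common size is converted
consistently (a unit change shifts $A$ and $B$ by the same constant). Fits
are in grams of ln mass; the common size is supplied in mg and converted.

The common size is the largest, across a family's species, of the minimum
seedling mass at first harvest — every species passes through it early,
before resource limitation. The values used in the original greenhouse
analysis (42.1 mg for grasses, 64.7 mg for legumes) ship as
`commonSizeDefaults` for replication runs.

Numerically, the fit is nonlinear least squares under a reparameterization
enforcing $s > 0.01$ day and $B - A > 0.1$ (both on the log scale), started
from a data-driven heuristic plus five jittered restarts drawn from a
fixed internal stream (so fits are deterministic and do not disturb the
caller's RNG); the lowest residual sum of squares wins and the convergence
flag is reported honestly. Flat or decreasing series are refused rather
than fitted, and a common size outside $(A, B)$ is an error rather than an
extrapolation.

## Phylogenetic contrasts

Crop/progenitor pairs are not independent samples; species means are
compared with generalized least squares whose residual covariance follows
the shared branch lengths, scaled by Pagel's $\lambda$:
$V(\lambda)$ multiplies the off-diagonal entries of the Brownian matrix
$C$ by $\lambda$, leaving tip variances alone. `pglsML()` profiles the
Gaussian likelihood over $\lambda \in [0, 1]$ (Brent-style bounded search,
tolerance $10^{-6}$, endpoints evaluated explicitly; a flat profile — e.g.
on a star phylogeny — is flagged rather than reported as a spurious
interior optimum). Solving is by Cholesky whitening and QR, never explicit
inversion.

Choices made where the convention was genuinely open, and why:

* **ML, not REML**, for $\lambda$ and $\sigma^2$, matching the default
  behaviour of the standard `pgls` model call in this literature.
* **Coefficient standard errors** use the residual-variance estimator
  RSS$/(n-p)$ (as the field's reference implementation does), while the
  reported $\sigma^2$ is the ML value.
* **Confidence intervals on ratios** are Wald intervals with $t$ quantiles
  on the log scale, then exponentiated; the back-transform is monotone, so
  coverage is inherited.
* **Transforms** follow the field convention: size-like traits (yield,
  seed masses, biomass, counts, height) are ln-transformed, so effects are
  crop:progenitor ratios; proportions and rates ($d$, $A_r$, $c$,
  $\tilde\lambda$, $\lambda_s$) stay untransformed, with effects reported
  as absolute differences and as percent of the progenitor mean (the
  "38% less chaff" style). Species means of ln-traits are means of logs
  (log geometric means), never logs of means — transform first, then
  aggregate.
* **F statistics** are squared $t$ ratios on $(1, n-2)$ degrees of
  freedom: $(1, 15)$ for the 17-taxon set, $(1, 8)$ for the 10 cereals.

The test suite cross-checks the GLS machinery against an independent
implementation (`nlme::gls` with `ape::corPagel`) at fixed $\lambda$; the
profile itself is validated by recovery simulations (data generated with
$\lambda = 0$ and $\lambda = 1$).

## What the synthetic data emulate — and what they do not

`simulateTraitTable()` reproduces the statistical structure of the two
randomized-block greenhouse experiments: 17 species in a fixed
crop/progenitor pairing; 20 blocks in experiment 1 and 10 in experiment 2;
oat and rye absent from experiment 2 (so 20 replicates instead of 30);
replicates divided evenly among three accessions per species. Species
effects are Brownian motion on a hard-coded ultrametric tree whose clades
mirror grass and legume phylogeny with each crop sister to its progenitor
(`makeTree()`); the tree is a simulation stand-in, not an inferred
chronogram. Traits are log-normal around species means (logit-normal for
proportions), with a shared log-normal block effect on biomass.

Planted crop:progenitor multipliers default to the reported domestication
effects: sown seed mass ×1.9, final biomass ×1.4, seeds per infructescence
×1.3, chaff proportion reduced by 38%, with no planted change in
allocation, duration, height or growth rate. Because the generator
enforces the exact identities (grain mass *is*
$M_d A_r (1-c)$; infructescence count *is* $Y/(M_s N_s)$), the yield ratio
is implied rather than planted: with the default baselines it is
$1.4 \times (1 - 0.39 \times 0.62)/(1 - 0.39) \approx 1.74$, and the
implied total-seed-number and infructescence-count ratios are 0.92 and
0.70. `impliedEffects()` reports all of them, and recovery tests compare
estimates to these implied values. (Recovered yield ratios drift upward by
roughly 1% of their value because logit-scale chaff noise is not
mean-preserving on the proportion scale; the drift is well inside Monte
Carlo error at the default noise levels.)

Progenitor baselines (grass seed 10 mg, legume seed 30 mg, biomass 20 g,
$A_r = 0.4$, chaff 0.39, duration 100 days, 20 seeds per spike) are
plausible magnitudes anchored to the one printed progenitor mean (chaff
39.0%); they are configuration, not ground truth. Noise magnitudes
(between-species Brownian SDs 0.2–0.4, block SD 0.1, residual SDs
0.05–0.2 on the log/logit scales) are assumptions chosen once so that the
planted effects are recovered with power comparable to the original
significance pattern — the true block and residual variances are
unpublished. The growth generator plants per-species logistic parameters
with no status effect (the original analysis found none), observed at six
harvests on days 8–28, two plants per species per harvest.

What passing tests on these data do **not** show: robustness to real
data's unbalanced replication, measurement error correlated across traits
within a plant, non-lognormal tails, genuine accession structure, or a
misspecified tree. The generator exists to verify the machinery, not to
certify field performance.

Every dataset is reproducible from one root seed: child seeds for the
species, plant and growth streams are drawn from it, and the caller's RNG
state is restored afterwards.

## Pipeline, configuration, degenerate inputs

`simulateDataset()` writes the four files (trait CSV, growth CSV, Newick
tree, species-level truth CSV) and `analyseDataset()` runs every stage —
components, species means, both variance decompositions for
all/cereals/pulses, growth fits with RGR at common size, and the PGLS
contrast table — writing CSVs, a markdown report and a run log. A failed
stage is recorded and the rest still run. Run configuration is an R list
or a YAML file (`readRunConfig()`); YAML was chosen as the configuration
format because it is the structured-text format with first-class support
in the R toolchain here.

Degenerate inputs are handled explicitly rather than coerced: zero
chaff+grain makes the chaff proportion an error, not NaN; a plant whose
final mass is below its seed mass gives a negative average RGR with a
warning (biologically odd, data-possible); constant component samples make
the delta-accuracy ratio "undefined", not a crash; subsampled packaging
counts whose product disagrees with the recorded total are surfaced as a
warning and never silently reconciled.

## Problem sizes

The shipped tests run the full pipeline on default-size datasets (470
plants, 17 species), 100-replicate noise studies for the growth fits, 30
datasets for effect-recovery checks, $10^5$-draw Monte-Carlo oracles for
the variance decomposition, and 1000 null datasets for the type-I-error
calibration of the PGLS stage — sizes chosen to give Monte-Carlo standard
errors comfortably below the tolerances being asserted.

## Known limitations

* The delta method is first-order only; no second-moment correction is
  offered, and with strongly varying $\tilde\lambda$ or $d$ the
  decomposition should be read qualitatively (use `deltaAccuracy()`).
* Pagel's $\lambda$ is profiled on $[0, 1]$; estimates piling up at 1 with
  an unconstrained optimum beyond it are reported as 1.
* The pipeline performs no imputation; a trait missing for a species is
  simply absent from that contrast.
* Phylogenetic mixed models with nested accession random effects (the
  cross-check analyses in the original study) are out of scope.
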