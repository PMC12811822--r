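---
title: "Models and methods behind thermoplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermoplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

thermoplast implements the statistical core of a thermal-acclimation
study design: hierarchical thermal-performance-curve (TPC) inference
anchored by critical thermal limits, permutation tests for the
behavioural experiments, a signed co-expression network with a bootstrap
stability score, and strand-aware regulatory-window operations. This
vignette records the models, the numerical choices, and the design
decisions that were genuinely open, in enough detail that a maintainer
could re-derive every default.

## The thermal performance curve model

Performance (sprint speed, m/s) as a function of body temperature T is
modelled with the asymmetric double-exponential form

$$P(T) = a\,\bigl(1 - e^{-b (T - t_{\min})}\bigr)\,
          \bigl(1 - e^{-c (t_{\max} - T)}\bigr),$$

which is zero at the two critical temperatures and rises with rate $b$
and falls with rate $c$ between them. Predicted performance is clamped
at zero: `kamykowski_performance()` never returns negative values, and
all derived quantities (Pmax, Topt, posterior bands) use the clamped
curve.

Each individual $i$ carries its own parameter vector
$\theta_i = (t_{\min}, t_{\max}, a, b, c)_i$. Every parameter is
expressed on an unconstrained scale through a logit mapping into a box
$(L_k, U_k)$,

$$\theta_{ik} = L_k + (U_k - L_k)\,\mathrm{logit}^{-1}(\mu_k + \sigma_k z_{ik}),
\qquad z_{ik} \sim \mathcal N(0, 1),$$

a non-centred parameterisation in which the population location $\mu_k$
and spread $\sigma_k$ are separated from the standardised individual
deviations. The boxes come from `estimate_start_bounds()`:
$t_{\min}$/$t_{\max}$ are initialised at the mean of the CTmin/CTmax
anchor temperatures with ±10 °C bounds, $a$ at the largest observed
speed with bounds (0.1, 10)× that value, and the rates at 0.1 with
bounds $(10^{-3}, 10)$ — a re-specification of the usual
nonlinear-least-squares warm start.

**Likelihood.** Observations (sprint rows and the two anchor rows per
individual, which enter as ordinary records with $y = 0$) are modelled
as $y \sim \mathcal N(\tilde P(T;\theta_i), \sigma_{\mathrm{obs}})$,
where $\tilde P$ is the *unclamped* double-exponential. This is a
deliberate choice: with a clamped mean, an anchor at temperature
$T_a$ is fitted perfectly by *any* $t_{\max,i} \le T_a$, so the anchors
bound the limits from one side only, and $(t_{\max}, c)$ acquires a
flat likelihood ridge above the hottest test temperature. We verified
numerically that under a clamped-mean likelihood the posterior median
of $t_{\max}$ sits 2–4 °C below the generating value while *fitting the
data better* than the truth — a property of the model, not of any
sampler. With the unclamped mean the curve is negative beyond the
limits, the anchors penalise misplacement in both directions, and the
zero crossings are identified; this also mirrors how zero-performance
anchors behave in standard nonlinear-least-squares TPC fitting, from
which the warm start is borrowed. The clamp is applied to every
*predicted* performance. The Gaussian likelihood is untruncated despite
$y \ge 0$; with observation noise around 0.05 m/s this is a documented
approximation, not a fitted choice.

**Priors.** The study design this package follows does not pin priors
down, so weakly informative ones centred on the warm start are used:
$\mu_k \sim \mathcal N(\eta^0_k, 1.5)$ with $\eta^0_k$ the unconstrained
image of the initialisation, $\sigma_k \sim \mathcal N^+(0, 0.5)$,
$\sigma_{\mathrm{obs}} \sim \mathcal N^+(0, \mathrm{sd}(y))$. On the
logit scale of a box spanning several orders of magnitude (the rates),
an sd of 1.5 is still mildly informative; widening it to 2.5 changes
the recovery behaviour by less than the seed-to-seed variation, so the
stated default is kept.

**Sampler.** Inference uses an adaptive Metropolis-within-Gibbs kernel
written for this model (run lengths default to 4 chains of 1000 warmup
plus 1000 sampling iterations; the test suite and the acceptance script
use 2 chains of 500 + 500 and smaller, documented sizes):

* scalar random-walk updates of each $\mu_k$, $\log\sigma_k$ and
  $\log\sigma_{\mathrm{obs}}$, with Robbins–Monro scale adaptation
  toward a 0.44 acceptance rate during warmup;
* a joint update of the 5-vector $\mu$ with a Haario-style empirical
  covariance proposal, which traverses the correlated
  $(t_{\max}, c, a, b)$ directions;
* per-individual 5-dimensional block updates of $z_i$, each with its own
  adapted covariance (target acceptance 0.25);
* interweaved *centred* moves that hold every individual-level
  $\eta_{ik} = \mu_k + \sigma_k z_{ik}$ fixed: an exact Gibbs draw of
  $\mu_k$ (conjugate normal given $\eta$ and $\sigma$) and a scale move
  on each $\sigma_k$ with $z$ rescaled so the likelihood is untouched.
  The interweaving is what lets the population location and spread mix
  when the individual curves are tightly identified.

Adaptation stops at the end of warmup, so the sampling phase is a fixed
Markov kernel. Two sweeps of the full cycle are run per stored draw.
All randomness derives from a user seed (per-chain sub-seeds via
`derive_seed()`), so runs are bit-reproducible. Convergence is
diagnosed with split R-hat and a Geyer-truncated effective sample size
for every stored quantity; any split R-hat above 1.05 flags the fit as
non-converged with a warning — the result is returned, never silently
discarded. Divergence-style failures (non-finite log-posterior at a
proposal) are counted and reported. The 0.95 target-acceptance setting
of gradient-based samplers has no analogue in a random-walk kernel; the
standard optimal-scaling targets above play the corresponding role.

**Derived quantities.** For each posterior draw, the population-level
curve (not an average of individual curves — the group-level posterior
is the object of interest) is evaluated on a 50-point grid over
$[t_{\min}, t_{\max}]$; a 100-point fine grid spans one coarse step
either side of the coarse argmax (clipped at the limits); Topt is the
fine argmax and Pmax its value. The fine step bounds the error, which
the tests verify against a derivative-root oracle. Pointwise posterior
bands (2.5/25/50/75/97.5%) are quantiles across draws and are nested by
construction.

**What recovery tests show.** On the default synthetic configuration
the population limits are recovered within a fraction of a degree. The
plateau parameter $a$ is different: with test temperatures ending at
37 °C and a gecko-realistic rise rate, $a$ sits on a likelihood ridge
with $(b, c)$, its marginal posterior is right-skewed, and its median
scatters 5–25% around the truth across generator seeds — long, well
mixed chains reproduce this, so it is a property of the study design,
not of the sampler. Pmax, the identified combination, is recovered
tightly.

## Synthetic thermal data

`gen_thermal_dataset()` draws individual parameters as
$\theta_i = \theta_{\mathrm{pop}} + \mathcal N(0, \mathrm{sd_{ind}})$
on the natural scale (the spread is specified in parameter units;
positivity and ordering are enforced), records each individual's true
limits as its CTmin/CTmax anchor rows (performance exactly zero, with a
ramp-rate covariate drawn uniformly from the configured range), and
adds Gaussian noise to the clamped curve at the test temperatures,
floored at zero. The default population parameters are solved so that
each group's curve realises a realistic acclimation contrast —
Pmax 0.73 and 0.85 m/s and Topt 36.9 and 38.2 °C for the cool- and
warm-acclimated groups — with critical limits at (6.5, 42.5) and
(8.0, 44.5) °C and a common rise rate b = 0.09; the remaining defaults
(sd 0.7 °C for limits, observation noise 0.05 m/s, test temperatures
15–37 °C) are fixed at values typical for gecko sprint assays. What the
generator does *not* emulate: measurement-protocol artefacts (best-of-3
trials), temperature-dependent noise, and any misspecification of the
curve family itself — recovery tests therefore validate the inference
machinery, not robustness to model misspecification.

## Permutation inference

`perm_ancova()` tests a group effect adjusted for a continuous
covariate with the Freedman–Lane scheme: the covariate-only model is
fitted, its residuals are permuted and added back to its fitted values,
and the group-plus-covariate F statistic is recomputed on each
pseudo-dataset. This preserves the covariate's contribution under the
null and is the standard recommendation for permutation ANCOVA. The
statistic is evaluated through orthonormal projections, so all
permutations reduce to one matrix product.

`perm_splitplot()` computes the classical split-plot decomposition
(between-subject effect tested against subjects-within-groups, within
and interaction against the within-subject residual; the observed F
values match `aov()` with an `Error(subject)` term exactly). Two
permutation schemes are used: whole-subject profiles are permuted
across between-group labels for the between effect, and within-level
labels are permuted independently inside each subject — one shared
permutation per iteration — for the within and interaction effects.
The exchangeability unit is thus the subject for the former and the
within-subject cell for the latter; the scheme for the interaction is a
declared choice, since split-plot permutation has no single canonical
scheme. The between-effect null distribution depends on the data only
through subject means, so it is vectorised across all permutations.

p-values use the add-one estimator $(b+1)/(m+1)$ with ties counted as
exceedances (conservative); $b = 0$ sets a `below_floor` flag and the
reporting floor $1/m$ — at the default $m = 50{,}000$ the printed bound
is $2\times10^{-5}$. Fixed seeds give bit-identical p-values.
`holm_adjust()`/`bh_adjust()` implement the step-down and step-up rules
directly (five lines each) and are cross-checked against
`stats::p.adjust` to $10^{-12}$ on random vectors; `rank_tests()`
delegates to `stats::wilcox.test`, using exact enumeration when the
effective sample size is ≤ 12 without ties and the tie-corrected normal
approximation otherwise, and raises an error when all paired
differences vanish.

## Co-expression network statistics

Counts are filtered (CPM > 1 in ≥ 20% of samples, strict inequality on
both counts of that sentence) and transformed to log2(CPM + 1). This
package uses the log-CPM transform as its variance-stabilising step;
the downstream statistics are built on the biweight midcorrelation and
are insensitive to the precise monotone transform. Outlier samples can
be removed by average-linkage clustering with a height cutoff (largest
branch retained), and the top-n most variable genes (ties broken
lexicographically, for reproducibility) enter the network.

The biweight midcorrelation weights observations by
$(1 - u^2)^2$ for $|u| < 1$, $u = (x - \mathrm{med})/(9\,\mathrm{MAD})$
with the unscaled MAD, and falls back to Pearson (with a warning) for
zero-MAD vectors. The soft power is the lowest $\beta \in 1..20$ whose
signed adjacency $((1 + r)/2)^\beta$ (Pearson at this step) yields a
scale-free fit $R^2 > 0.80$, where $R^2$ is the squared correlation of
log-frequency versus log-mean connectivity over 10 equal-width
connectivity bins (empty bins dropped) — equal-occupancy bins would
make the frequency side constant and the fit undefined, so equal-width
binning, the field convention, is used. If no power reaches the target
the best one is returned with a flag.

Modules come from average-linkage clustering of 1 − TOM, where
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij})/(\min(k_i,k_j) + 1 -
a_{ij})$ on the signed bicor adjacency. In place of the dynamic hybrid
tree cut of the reference workflow (whose deepSplit tuning has no
meaning here and is recorded as non-replicated), a *static* cut is
used: the tree is cut at the `cut_quantile` quantile (default 0.05) of
the pairwise dissimilarities — a cut that should bound the
within-module dissimilarity range, which occupies the lower few percent
of pairs when modules are a minority of genes — or at an explicit
`cut_height`; branches below `min_size` (30) become "unassigned", and
modules whose eigengene correlation exceeds $1 - 0.25$ are merged
iteratively, closest pair first. The default quantile is calibrated to
the planted-module geometry the generator produces; for data whose
module fraction differs substantially, `cut_height` is the control to
set, and the merge test in the suite shows both behaviours.

Eigengenes are first right-singular vectors of the gene-standardised
module submatrix, sign-oriented to correlate positively with the module
mean profile. kME is the bicor of each gene with each eigengene;
module–trait association encodes each group as a one-vs-rest binary
indicator, computes bicor r, converts with the Student approximation
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, and applies BH across all
module × trait cells jointly. Hub genes are assigned genes with
|kME| > 0.8 (strict).

The bootstrap stability score resamples samples with replacement
(draws with fewer than three distinct samples are redrawn and counted),
recomputes eigengenes under the *original* assignment, takes each
assigned gene's kME to its own module, averages over genes, and then
averages the per-bootstrap means. "Mean kME across genes and modules"
is interpreted as the signed mean of own-module kME over assigned
genes — with sign-oriented eigengenes this is the quantity that is ~1
for coherent modules and ~0 for random labels; the alternative grand
mean over the full gene × module matrix would mix in cross-module
terms and is not used. The suite verifies the score exceeds 0.7 for
planted modules at within-module correlation 0.8 and decreases
monotonically through 0.5 and 0.2.

Fisher's exact test for module overlaps reports the sample odds ratio
$ad/bc$ and a two-sided p-value summing hypergeometric probabilities no
larger than the observed table's; the gene universe is a required
argument, because overlap significance is meaningless without it.

## Synthetic expression data

Module genes share a per-sample latent factor with weight
$\sqrt{\rho}$ against $\sqrt{1-\rho}$ independent noise, giving
pairwise latent correlation $\rho$ (default 0.8); the first module's
factor mean is shifted in group 2 (default 2 latent SDs), making it the
trait-associated module. Module-gene latent variation is scaled by
`module_var_boost` (default 2) so planted modules are more variable
than the lognormal-baseline background — as trait-responsive modules
are in real data — and survive variance-based selection; the boost
leaves pairwise correlations unchanged. Counts are Poisson (or
negative binomial with configurable dispersion) around
baseline × exp(0.7 × latent), column-scaled to the target library
size. The generator does not emulate batch effects, gene-length bias,
or compositional effects; tests on it validate the network statistics,
not normalisation choices.

## Regulatory windows

All data-frame coordinates are 0-based half-open (BED convention);
GFF3's 1-based closed coordinates are converted at the I/O boundary
(`read_gff3()`/`write_gff3()` via rtracklayer). Gene-proximal windows
are the gene body ±5 kb, strand-independent (slop semantics), clipped
to the chromosome. Promoter windows are strand-aware flank windows
around the transcription start site — for a minus-strand gene the TSS
is the 3′-most stored coordinate — spanning 1000 bp upstream to 100 bp
downstream. Overlap requires at least one base under half-open
semantics (`a.start < b.end && b.start < a.end`); a peak that merely
abuts a window does not count. Differential peaks are consumed as
given, with no additional fold-change gate before DPG classification.
Footprint filtering accepts log2 fold changes or raw ratios (declared
by column name) and applies the threshold on the raw-ratio scale with a
strict inequality, taking the union over the requested motif ids.
Interval intersection goes through GenomicRanges; the test suite
checks every operation against a quadratic brute-force scan.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → {tpc, perm, coexpr, windows} from
a validated configuration (YAML or list; unknown keys are rejected by
name), derives every stage's seed from the global seed with a
documented string-keyed hash, writes all outputs in plain-text formats,
and reports per-stage status, wall time and md5 digests. Identical
configurations produce byte-identical outputs; a failed stage marks its
dependents as skipped. The shipped demo configuration
(`inst/extdata/demo_config.yaml`) runs every stage in about a minute at
reduced sizes (8 individuals, 2 chains of 250 + 250, m = 2000, 1200
genes, 40-gene toy genome); the analysis-scale defaults are larger and
stated on each function.

## Known limitations

* The Gaussian likelihood is untruncated although performance is
  non-negative; near-zero observations are slightly over-weighted.
* The plateau parameter $a$ is weakly identified when test temperatures
  stop short of the descending limb, as discussed above; report Pmax
  when a point summary of curve height is needed.
* The static tree cut trades the adaptivity of dynamic tree cutting for
  reproducibility and simplicity; its default quantile assumes modules
  are a minority of the genes under consideration.
* The stability score is computed under the original assignment, so it
  measures coherence of the given modules under resampling, not
  re-detectability.
* Exact replication of any published module gene lists would require
  the deposited expression data, which this package deliberately does
  not consume.
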