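---
title: "Quantitative interpretation of STR mixtures: model, sampler and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative interpretation of STR mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgmix)
```

This vignette is the package's account of its science: the probability model
and its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations. The companion README shows the user-facing workflow.

## The model

An STR mixture profile is a set of electropherogram peaks per locus, each
with an allele label (repeat count), a fragment size in bp and a height in
RFU. The model explains the height vector **d** at a locus from:

* `K` contributor genotypes, one unordered allele pair `g_k` per contributor;
* mixture weights `W = (w_1..w_K)`, positive, summing to 1, shared across
  loci (the DNA proportion each person contributed);
* a per-locus template mass `M` in RFU — the combined allelic fluorescence
  the locus would show without degradation;
* a back-stutter rate `s`: a PCR artifact places a fraction `s` of each
  allele's signal one repeat unit shorter. Stutter is modelled as
  mass-conserving: the parent keeps `1 - s`, the stutter position gains `s`.
  A single back-stutter position is the whole artifact model; forward
  stutter is out of scope;
* a degradation rate `delta` per 100 bp: longer fragments amplify less, as
  `exp(-delta * size / 100)`.

The mean pattern is the weighted sum of the contributors' allele doses,

```
mu(a) = M * sum_k w_k * dose_k(a) / 2 * exp(-delta * size_a / 100),
```

followed by the stutter shift. Observed heights are modelled as a
multivariate normal around `mu` with diagonal covariance and per-peak
variance affine in the expected height,

```
var(a) = sigma0^2 + tau * mu(a),
```

with `sigma0^2` the baseline variance floor (default 100 RFU^2) and `tau`
the variance-per-RFU scale (default 5 RFU). Replicate PCR is
heteroscedastic — tall peaks vary more in absolute terms — and the affine
form is the simplest diagonal covariance with that property. The Gaussian is
not truncated at zero; for peaks more than a few standard deviations above
zero the truncation mass is negligible, and the approximation keeps every
full conditional in closed form.

The evidence grid at a locus is the union of observed peak positions, the
hypothesized genotype alleles and their back-stutter positions; grid
positions without an observed peak carry data height 0, so a hypothesis that
predicts an unobserved peak pays the corresponding Gaussian penalty
(dropout is evidence against the hypothesis, not missing data).

Genotype priors come from population allele frequencies with a co-ancestry
(theta) correction, using the Balding–Nichols genotype sampling
probabilities: homozygote `p (theta + (1 - theta) p)`, heterozygote
`2 (1 - theta) p_i p_j`, renormalized over the locus allele universe when
the table leaves a rare-allele remainder. This form was chosen over the
conditional match-probability formulas sometimes quoted for theta
corrections because it is a genuine probability distribution over the pair
space: it sums to exactly 1, reduces to Hardy–Weinberg at `theta = 0`, and
strictly enriches every homozygote for `theta > 0` — three properties the
package treats as contracts (the conditional formulas violate the first and,
after forced renormalization, the third). Default `theta = 0.01`. Reference
alleles absent from a frequency table are substituted at a minimum frequency
of `5 / 2N` (database size `N`, fallback 0.001) with a warning, so an unseen
allele never receives a zero prior.

## Inference

The posterior over `(G, W, M, s, tau)` is sampled by Metropolis-within-Gibbs
MCMC:

* each contributor's allele pair at each locus is redrawn from its **exact
  full conditional**, enumerated over the locus pair support (likelihood
  times prior). Discrete enumeration makes small cases exactly checkable
  against brute force, and `enumerate_genotype_posterior()` provides that
  brute-force oracle;
* `W` takes a random walk on the softmax-parameterized simplex under a flat
  Dirichlet prior; per-locus `M` and the variance scale `tau` take lognormal
  random walks; `s` takes a logit random walk on (0, 0.3);
* three mixing devices address the label-permutation structure of mixture
  posteriors: weights start at descending ratios (2:1 for two contributors)
  and are held fixed for the first half of burn-in, so the contributor slots
  settle into coherent major/minor roles before the weights move; a per-locus
  Metropolis move proposes swapping two contributors' pairs outright; and
  every fifth sweep the two slots are redrawn **jointly** from all pairs of
  observed alleles — an independence draw within that subspace that is
  always accepted when the current state lies inside it (and skipped
  otherwise, which keeps the kernel valid). The joint draw is what crosses
  likelihood valleys between states like "two homozygotes" and "two
  heterozygotes sharing those alleles", which single-coordinate updates
  essentially never traverse;
* genotype marginals are **Rao-Blackwellized**: the sampler accumulates each
  full conditional rather than the sampled indicator. This shrinks
  Monte-Carlo error and avoids reporting probability exactly 0 for a pair
  the data merely disfavors — important because a posterior of 0 at a
  reference pair reports LR 0 with no smoothing applied.

Internally the sampler evaluates all hypotheses at a locus on one fixed
grid (the prior support, its stutter positions and the observed peaks), so
the Gaussian normalizing constants are comparable across hypotheses; the
exported `log_likelihood()` builds the per-hypothesis grid described above,
which is the natural convention for a single evaluation.

The number of contributors is an input, not an estimate:
`suggest_contributor_count()` offers the allele-count lower bound, and
`infer_contributor_range()` runs `K` and `K + 1` for side-by-side review.
Known contributors (e.g. the victim in an intimate sample) can be pinned
via `assumed =`. At reporting time contributor slots are ordered by
posterior mean weight, assumed contributors first. Replicate-run agreement
is checked with `check_concordance()`, which compares genotype marginals by
symmetrized Kullback–Leibler divergence in ban (tolerance 0.05 by default)
and posterior mean weights.

Defaults are 20,000 sweeps with 5,000 burn-in. On the simulated profiles
used in the test suite the chain reaches replicate-concordant answers within
a few hundred sweeps, so the tests and the acceptance script run 1,200–4,000
sweeps per profile; those desk-scale sizes (20 two-contributor, 15-locus
profiles; 1,000 noncontributor references per evidence genotype; 200 KS
replications) are the package's chosen experiment sizes.

## Match statistics

The likelihood ratio at a locus is the posterior-to-prior probability ratio
at the reference's allele pair; per-locus LRs multiply across loci (linkage
between loci is not modelled), and `log10 LR` is reported in ban. The
classification band is ±0.5 ban around zero ("inconclusive") by default and
is configurable. When several population databases are available,
`min_over_populations()` applies the conservative smallest-statistic rule.
LRs are displayed to 3 significant figures (full precision retained
internally).

The comparator methods are the mechanical threshold rules only: analyst
judgment steps (choosing contributor numbers, judging possible dropout) are
out of scope. Allele calling uses `>=` at the threshold — a peak exactly at
threshold is called — and the dye-specific analytical thresholds (73/84/75/52
RFU for blue/green/yellow/red) and injection-specific stochastic thresholds
(210/320/460 RFU at 2/5/10 s) are configuration, not constants. CPI's
inclusion probability uses the squared sum of called-allele frequencies;
with `theta > 0` the restricted-prior formulation is used instead, and
`theta = 0` (where both agree exactly) is the comparator default, matching
how the manual arithmetic is usually printed. Stutter peaks above threshold
are treated as alleles by the comparators, as manual rules do; a
sensitivity-analysis option can remove them first.

## The synthetic-data generator

`simulate_profile()` emulates a PowerPlex-16-like 15-locus profile:
fragment sizes are `offset + repeat * unit` from the bundled panel file,
peak means follow the model above, and multiplicative lognormal noise with
coefficient of variation `cv` (default 0.1) preserves the mean. Defaults —
3,000 RFU total mass, 5% stutter, no degradation, 5 s injection, 10 RFU
detection floor — describe a clean, well-amplified casework-like sample.
`synthetic_frequencies()` generates seeded three-population allele
frequencies with a unimodal shape along the allele ladder; it is a labelled
synthetic stand-in, since real laboratory databases are not distributable.

What the generator does **not** emulate: baseline noise peaks and other
artifacts (pull-up, spikes), forward stutter, off-ladder alleles,
inter-locus amplification imbalance, and PCR variance beyond the lognormal
form. Passing tests therefore show that inference recovers what this
generative family produces — they do not certify performance on real
electropherograms, where the variance model and artifact landscape are
richer.

## Numerical choices and degenerate inputs

* `cv = 0` bypasses the noise draw entirely, so noise-free simulation is
  bit-exact against the closed-form means — the basis of several tests.
* Allele labels are strings ordered numerically when all parse (microvariant
  "9.3" sorts between "9" and "10"), lexically otherwise; repeat arithmetic
  is rounded to 6 decimals before re-labelling to absorb floating-point fuzz.
* Loci whose peaks all fall below the detection floor are flagged and
  skipped by inference (their posterior is the prior).
* Weights of evidence below -30 ban are clamped at -30 for aggregation in
  the specificity report (the clamp count is reported); a combined LR of 0
  is reported as -Inf ban, exclusionary support.
* The within-group precision estimator uses the n-divisor within-pair
  variance (`d^2/4` for a pair differing by `d`), the two-level ANOVA
  maximum-likelihood form; a single pair (10.0, 10.2) gives 0.1 ban.
* KS uniformity tests use the exact null distribution for `n <= 50` and the
  asymptotic Kolmogorov form otherwise.
* Variance hyperparameters default to a method-of-moments pass over
  heterozygote balance at clean two-peak loci when the sampler is run with
  `sample_variance = FALSE`; when sampled (the default) they start from the
  configured values.

## Known limitations

* Two contributors with nearly equal weights are statistically
  near-exchangeable: the exact posterior (verified by exhaustive
  enumeration) spreads each slot's genotype mass over both contributors'
  pairs, so per-locus modes stop tracking "the major" once weights come
  within a few percent of 50/50. This is an identifiability property of the
  model, not a sampler artifact; expect resolved genotypes for weight splits
  of roughly 55/45 or wider at these signal levels.
* The diagonal covariance ignores the negative correlation stutter induces
  between parent and stutter peaks, and the affine variance understates the
  spread of very tall peaks under multiplicative noise; the sampled `tau`
  compensates on average.
* Degradation is a single exponential in fragment size; per-dye variance
  families and locus-specific amplification efficiency are not modelled.
* Contributor count is assumed, not inferred; a wrong `K` is only softly
  flagged (an allele-count warning).
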