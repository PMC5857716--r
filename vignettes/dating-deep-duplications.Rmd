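---
title: "Dating deep gene duplications: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating deep gene duplications: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoclock)
```

## The problem

Photosystem I is built around two homologous core subunits, PsaA and PsaB,
that arose by gene duplication from a single ancestral (homodimeric)
reaction-centre protein. Every oxygenic phototroph carries both copies at
roughly 42--43% mutual amino-acid identity, so the duplication predates the
cyanobacterial radiation — but by how much? `paleoclock` implements two
complementary chronometers for this kind of question: a deliberately simple
*identity-decay* extrapolation, and a Bayesian *relaxed molecular clock*
with fossil calibrations. Both operate on ordinary tabular inputs (tibbles
of sequences, identities, calibrations) and return tibbles, so results
compose with the usual tidyverse verbs.

## Track 1: the identity-decay chronometer

The model is a straight line. If two paralogues have each lost
$\Delta$ percent identity since an anchoring split of age $T$ Ma, the
implied pace is $k = T/\Delta$ Ma per percent, and an observed identity
$p$ extrapolates to an age $(100 - p)\,k$. `calibrate_rate()`,
`predict_identity()` and `extrapolate_age()` expose exactly this
arithmetic; `mrca_sensitivity_scan()` repeats it across anchoring
assumptions, and `fossil_consistency_check()` asks whether fossil-dated
species pairs fall inside the identity band the rate predicts for their
age window.

Assumptions worth stating plainly:

* **No correction for multiple substitutions.** Raw identity saturates at
  the stationary 5% for amino acids, so the linear model *understates*
  deep ages. This is intentional: the chronometer is a transparent
  lower-bound-style argument, not a substitution model.
* **Rate constancy.** The fossil cross-checks (ages 100--1600 Ma) test
  this assumption empirically; the scan over anchor ages (2.0--3.0 Ga for
  the cyanobacterial MRCA) brackets its violation at the deep end.
* **Presentation conventions.** Printed rate constants are floored to
  whole Ma per percent (2000/30 reports as 66) and printed Ga values are
  truncated to two decimals (3795 Ma prints as 3.79 Ga); extrapolations
  that reproduce printed tables therefore use the floored rate
  (`use_reported_rate = TRUE`, the default in the scan). Full-precision
  arithmetic is always available and is what every internal computation
  uses.

The anchoring divergence defaults to the conventional simplification of
30%; the exact paralogue-averaged value (30.35 from identities 66.5 and
72.8) is available through `anchor_divergence()`.

## Track 2: the relaxed molecular clock

`clock_mcmc()` samples the posterior of node ages on a *fixed* rooted
binary topology. Topology inference is out of scope — the tree is an
input, as is the alignment.

**Substitution model.** Amino acids evolve under the Poisson model: equal
exchangeabilities, equal stationary frequencies (1/20). Among-site rate
variation uses four equal-probability discrete-gamma categories
(mean-of-category rates, shape $\alpha$ estimated). For this model the
transition kernel has the closed form
$P_{\text{same}}(d) = \tfrac{1}{20} + \tfrac{19}{20}e^{-\frac{20}{19}d}$,
which the pruning kernel exploits; correctness is pinned to a
matrix-exponential oracle and to brute-force state enumeration in the test
suite. Site-heterogeneous profile mixtures (CAT-style) are *not*
implemented; this is a known fidelity gap relative to the analyses that
motivated the package, and one reason the package validates itself on
synthetic data rather than claiming to reproduce published posteriors.
Gaps and `X` are missing data (an all-ones conditional vector).

**Rate model.** Branch rates follow the autocorrelated log-normal
(geometric Brownian) process: for a child node at distance $\Delta t$ Ma
below its parent,
$\log r_c \sim \mathcal{N}(\log r_p - \sigma^2 \Delta t / 2,\;
\sigma^2 \Delta t)$.
The $-\sigma^2 \Delta t/2$ drift makes the process mean-preserving
($E[r_c \mid r_p] = r_p$). The branch rate entering the likelihood is the
arithmetic mean of the endpoint rates, chosen for symmetry and continuity
(the parent-only alternative makes the likelihood discontinuous in
ancestry). $\sigma^2$ has an exponential hyperprior with mean 1 per Ga
(i.e. $10^{-3}$ per Ma); the root node's rate has a wide log-normal prior
(default centre $2.5\times10^{-4}$ subst/site/Ma, log-sd 1.5).

**Age prior and calibrations.** The root age has a Normal prior (the
"3.5 ± 0.05 Ga" convention maps to `root_prior(3500, 50)`), truncated
below at the oldest calibrated minimum. Conditional on the root, the
remaining internal ages are uniform on the order-constrained simplex
(contributing $-(m-1)\log t_{\text{root}}$ to the log prior); no
birth--death tree prior is layered on top — the simplest proper prior
consistent with treating calibrations, not the tree process, as the
information source. Each calibrated node multiplies in a *soft-bound*
density: a uniform core on $[\min, \max]$ with exponential tails carrying
exactly 2.5% of the mass beyond each bound (5% below a minimum-only
bound). The tail scale is 10% of the window width (10% of the bound for
single-bound calibrations) — a smoothing choice only; the tail *mass* is
what the model pins down. A minimum-only calibration keeps its uniform
core up to the current root age, the natural ceiling for an internal node
under the order-constrained prior.

**Sampler.** One sweep updates every parameter by Metropolis--Hastings:
each internal node age by a global uniform slide between its parent and
oldest child plus a tuned local slide; the root age, every node rate,
$\sigma^2$ and $\alpha$ by log-scale multipliers. Proposals respect the
parent-older-than-child constraint by construction, so no retained sample
can violate it. Step sizes adapt toward ~30% acceptance during burn-in
and are frozen afterwards, preserving detailed balance of the recorded
portion. Chains are bit-reproducible: chain $i$ seeds its own generator
with `seed + i - 1` and the update order is fixed. Convergence is
summarised by split-$\hat R$ (threshold 1.05 on the root age, $\sigma^2$
and, with data, $\alpha$); failure warns and flags the result rather than
aborting. A likelihood-off mode (`likelihood = FALSE`) samples the prior,
which is how the calibration densities are verified against their
analytic form.

**Numerical details.** The pruning kernel caches per-node conditional
likelihoods; a proposal recomputes only the path from the touched node to
the root, into a shadow buffer that is swapped in on acceptance. Site
patterns are compressed with weights (likelihood-invariant). Impossible
sites on zero-length trees give $-\infty$, and the sampler treats a
$-\infty$ current state as always-escapable rather than sticky. If the
automatic initialisation lands a calibrated node so far outside its
window that the tail density underflows, calibrated nodes are pulled to
their window midpoints and the age ordering is repaired bottom-up before
sampling starts.

## The synthetic generator

`simulate_chronogram()` (Yule topology rescaled to an exact root age),
`simulate_rates()` (the forward process of the rate prior — scored
exactly by `log_prior_rates()`, which the tests verify), and
`simulate_alignment()` (root states from the stationary distribution,
per-site gamma categories fixed along the tree) provide ground truth for
every inference stage. `make_duplication_fixture()` assembles the
PsaA/PsaB-shaped benchmark: a rooted tree whose oldest post-root split is
a duplication joining two mirrored paralogue subtrees over the same
species, plus a small outgroup clade.

Generator defaults are the package's frozen study conditions: root age
3500 Ma, duplication at 75--95% of the root age, $\sigma^2 = 10^{-4}$ per
Ma (0.1 per Ga), $\alpha = 0.5$, 200 sites, and a root rate of
$1.5\times10^{-4}$ subst/site/Ma (0.15 changes/site/Ga, the order of the
slow Proterozoic rates observed for the Photosystem I core; it also
places the simulated cross-paralogue identity in the observed ~40%
regime). Calibrations are synthesised as ±15% windows around the true
ages of three nodes — both paralogue MRCAs and one shallow
within-paralogue node — emulating informative fossil windows.

What the generator does **not** emulate: indels and alignment error,
site-specific amino-acid profiles (CAT-style heterogeneity),
non-ultrametric sampling, lineage-specific compositional bias, and the
taxon sampling imbalance of real reaction-centre datasets. Passing the
synthetic benchmark therefore demonstrates internal correctness of the
model-inference loop, not robustness to these real-data features.

## The validation benchmark

The acceptance suite (and `scripts/acceptance.R`) runs, per replicate, a
3000-sweep chain (1000 burn-in, thinned by 4) on the 8-taxon fixture —
20 replicates dated twice: once with all three calibration windows and
once with every calibration deeper than 600 Ma removed. Reported
quantities: 95% credible-interval coverage of the true duplication age
(expected ≥ 16/20), mean bias relative to the root age, and a one-sided
sign test that removing deep calibrations widens the duplication-node
interval. Prior fidelity is checked by a likelihood-off run on a node
calibrated to [82, 127] Ma with 2.5% tails: 10,000 thinned samples against
the analytic soft-bound CDF (Kolmogorov--Smirnov) and empirical tail
masses. These problem sizes are the package's chosen benchmark scale;
single chains are used per replicate, with multi-chain split-$\hat R$
exercised in the unit tests.

## Known limitations

* Homogeneous Poisson+$\Gamma_4$ only; no profile mixtures, no
  uncorrelated-rates clock, no nucleotide or codon models.
* The order-constrained uniform age prior is not a speciation-process
  prior; with few calibrations, deep node ages lean on the root prior.
* The identity-decay track is linear by design and will compress truly
  deep ages as identity approaches saturation.
* Minimum-only soft bounds condition their core on the current root age,
  so their normalisation moves with the root; this is accounted for in
  the acceptance ratio but differs from formulations that fix an absolute
  ceiling.
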