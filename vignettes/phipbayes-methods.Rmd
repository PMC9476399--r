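---
title: "Detecting antibody-reactive peptides in PhIP-Seq data: model and methods"
author: "phipbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting antibody-reactive peptides in PhIP-Seq data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(phipbayes)
```

## The problem

Phage ImmunoPrecipitation Sequencing (PhIP-Seq) displays proteome-spanning
peptide libraries on bacteriophages, immunocaptures them with a person's
serum antibodies, and sequences the bound library members. The data arrive
as a peptides-by-samples matrix of read counts $Y_{ij}$, together with
per-sample library sizes $n_j = \sum_i Y_{ij}$ (typically above $10^6$
reads). Unlike RNA-Seq, the scientific question is per *sample*: which
peptides pulled more reads in serum sample $j$ than expected from
background? Background is defined by beads-only wells — mock
immunoprecipitations with no antibody input, usually 4–8 per 96-well plate
— so every analysis is an "$N$ mock IPs versus 1 serum sample" comparison.
Two empirical features dominate: background binding is strongly
peptide-dependent (mean read-pull proportions span orders of magnitude),
and between-sample variability exceeds what binomial sampling alone
predicts. Peptides with low counts can still be biologically relevant, so
nothing is filtered by abundance.

## The hierarchical model

For one serum sample $j$ with library size $n$ and peptides
$i = 1, \dots, P$:

$$
\begin{aligned}
Y_{ij} \mid \theta_{ij} &\sim \mathrm{Binomial}(n_j, \theta_{ij}) \\
\theta_{ij} \mid c_j, \phi_{ij}
  &\sim \mathrm{Beta}\!\big(f_a(c_j \phi_{ij} \mu_{i0}, \sigma^2_{i0}),\;
                            f_b(c_j \phi_{ij} \mu_{i0}, \sigma^2_{i0})\big) \\
c_j &\sim \mathrm{Beta}(a_c, b_c) \\
\phi_{ij} \mid Z_{ij} &\sim (1 - Z_{ij})\cdot 1 +
  Z_{ij}\,\big(\phi_{\min} + \mathrm{Gamma}(a_\phi, b_\phi)\big) \\
Z_{ij} \mid \pi_j &\sim \mathrm{Bernoulli}(\pi_j) \\
\pi_j &\sim \mathrm{Beta}(a_\pi, b_\pi)
\end{aligned}
$$

where $f_a(\mu, \sigma^2) = \mu^2(1-\mu)/\sigma^2 - \mu$ and
$f_b = f_a \cdot (1/\mu - 1)$ map a mean and variance to Beta shapes, and
$(\mu_{i0}, \sigma^2_{i0})$ are the beads-only background moments of
peptide $i$. The quantity of interest is the posterior probability of the
spike-and-slab indicator $Z_{ij}$ — whether peptide $i$ is enriched in
sample $j$ — together with the fold change $\phi_{ij} > 1$ under
enrichment. The attenuation constant $c_j \le 1$ captures read
competition: reactive peptides consume sequencing reads, so non-reactive
peptides in a serum sample pull slightly less than their beads-only
expectation (the same role a TMM scale factor plays in count
normalization; $c_j = 1$ in mock IPs by definition).

### Hyperparameters

| parameter | default | role |
|---|---|---|
| $a_\pi, b_\pi$ | 2, 300 | fraction of enriched peptides per sample; mean 0.66%, diffuse |
| $a_\phi, b_\phi$ | 1.25, 0.1 | Gamma slab of the enriched fold change, shifted by $\phi_{\min}$ |
| $\phi_{\min}$ | 1 | minimum fold change of an enriched peptide |
| $a_c, b_c$ | 80, 20 | attenuation prior, mean 0.8, mass on (0.6, 1) |
| pre-filter | 15 | initial fold-change cutoff for removing super-enriched peptides |
| $n_{\text{burn}}, n_{\text{iter}}$ | 1000, 10000 | chain length |

All are exposed through `beer_config()`. Chain lengths are our choice (the
model converges quickly because most peptides are decisively null or
decisively enriched); the calibration checks in the test suite pass at
these defaults.

## Beads-only prior estimation

The background moments are plug-in empirical-Bayes estimates from the
beads-only columns; the chain never resamples them. Three routes are
implemented:

* **Method of moments** (`estimate_mom`): per-peptide sample mean and
  variance of the observed proportions $\hat\theta_{ij} = Y_{ij}/n_j$.
* **Maximum likelihood** (`estimate_mle`): per-peptide Beta likelihood of
  the same proportions, maximized by L-BFGS-B with both shapes box-bounded
  in $[10^{-6}, 10^6]$. The Beta density is undefined at 0 and 1, so
  proportions are clipped to $[10^{-10}, 1 - 10^{-10}]$ — our choice, made
  explicit here because the boundary case is otherwise unspecified.
* **Dispersion-derived** (`estimate_dispersion_derived`, the default):
  $\sigma^2_{i0} = \tau_i \hat\theta_{i0}^2$, with $\tau_i$ the tagwise
  negative-binomial dispersion (squared coefficient of variation) from
  edgeR's weighted-likelihood empirical Bayes, shrunk toward the
  plate-wide common value with 10 prior degrees of freedom. Borrowing
  strength across peptides matters because a plate carries only a handful
  of mock IPs; with 2–8 observations per peptide the raw variance
  estimates of MOM/MLE are unstable, and this route dominates them in
  discrimination performance.

Three degenerate cases get documented fallbacks: a zero or infeasible
variance ($\sigma^2 \ge \mu(1-\mu)$) is replaced by a binomial-scale
variance at the mean beads library size, $\mu(1-\mu)/(\bar n + 1)$; an
all-zero peptide's mean by half a pseudo-read, $1/(2\bar n)$. Finally the
first shape is guarded at $a \ge 1$ (`apply_guard`) — pseudo-count shapes
below one destabilize samplers — recomputing $b$ so the mean, the
better-identified moment, is preserved exactly.

## Sampling scheme

Peptides are conditionally independent given $(c, \pi)$, so the whole
state updates in vectorized sweeps:

1. **$(Z_i, \phi_i)$ jointly, $\theta_i$ collapsed.** A flip of $Z_i$ is
   proposed with the fold change of a proposed enrichment drawn from its
   prior slab, and accepted by the Metropolis–Hastings ratio of
   Beta-Binomial marginal likelihoods times the prior odds
   $\pi/(1-\pi)$ (the slab density cancels against the proposal).
   Currently-enriched peptides then get a multiplicative random-walk
   refinement of $\phi_i$ (log-normal step, sd 0.3, Jacobian-corrected),
   which sharpens fold-change estimates at million-read library sizes
   where the marginal likelihood is much narrower than the slab.
2. **$\theta_i$** from its conjugate conditional
   $\mathrm{Beta}(a_i + Y_i,\, b_i + n - Y_i)$.
3. **$c$** by univariate slice sampling (stepping-out and shrinkage) of
   its full conditional on $(0,1)$.
4. **$\pi$** from the conjugate
   $\mathrm{Beta}(a_\pi + \sum Z,\, b_\pi + P - \sum Z)$.

Because $(Z, \phi)$ is drawn from the $\theta$-marginalized conditional
and $\theta$ is refreshed immediately after, the joint stationary
distribution is preserved (a partially collapsed Gibbs sampler). Whether
$\phi$ is held at 1 between enrichment episodes or refreshed is an engine
detail with no effect on the stationary law; we hold it at 1.

Numerical safeguards: $\theta$ is clipped to
$[10^{-12}, 1 - 10^{-12}]$ inside density evaluations; elevated means
$c\phi\mu_0$ are clipped below 1; if a variance becomes infeasible at an
elevated mean (only possible near 1) the mean-preserving $a = 1$ guard is
substituted. Chains are seeded and exactly reproducible.

### Initialization and pre-filter

Starting values are plug-in estimates: $\theta^{\text{init}} = Y/n$;
$Z^{\text{init}} = 1$ when the observed count is at least twice the
beads-only expectation ($Y \ge 2 n \mu_0$); $c^{\text{init}}$ is the
through-origin regression slope of observed on expected counts over the
non-enriched peptides; $\pi^{\text{init}}$ the fraction initialized
enriched; $\phi^{\text{init}} = Y / (n\, c^{\text{init}} \mu_0)$ for
enriched peptides. Boundary values are moved into the open support —
$c = 1$ by an offset of $10^{-4}$, $\pi \in \{0, 1\}$ by $1/P$; the offset
magnitudes are our choice and only need to enter the support.

Peptides with $\phi^{\text{init}}$ above the pre-filter threshold
(default 15) are unambiguously enriched; extreme fold changes destabilize
inference for the rest, so their reads are removed from beads and serum
columns alike, library sizes are recomputed, the prior is re-estimated on
the filtered matrix, and the excluded peptides are reported with posterior
probability exactly 1 (which is what unfiltered chains assign them).

## The exact-test comparator

`nb_exact_test()` is the standard RNA-Seq-style route applied to the
"$N$ versus 1" design: TMM normalization (trim fractions 0.3/0.05,
reference the beads sample of median library size), tagwise NB dispersions
with 10 prior degrees of freedom, and the overdispersion-adapted analogue
of Fisher's exact test, all via edgeR. Since the only alternative to no
reactivity is *enrichment*, two-sided p-values are converted to one-sided
(halved in the enriched direction, reflected otherwise) before
Benjamini-Hochberg control. The edgeR settings (shrinkage weight, trim
fractions, reference selection) are our documented defaults, stated in
the function documentation. At dispersion zero the test reduces to a
conditional binomial doubletail, which the test suite checks against an
independent enumeration oracle to $10^{-8}$.

## Synthetic data

`generate_beads_prior()` emulates the two dominant features of real mock
IP counts without requiring any external dataset:

* peptide background means $\mu_{i0}$ from a log-normal with
  $\mathrm{sdlog} = 1.5$ normalized to sum to one — about four orders of
  magnitude between the 1st and 99th percentile, matching the strongly
  peptide-dependent library representation seen on real plates;
* between-sample variances $\sigma^2_{i0} = \tau_i \mu_{i0}^2$, with
  $\tau_i \sim \mathrm{Gamma}(4, 80)$ (mean 0.05, i.e. a typical 22%
  coefficient of variation between mock IPs, consistent with tagwise
  dispersions around 0.04 seen in such data) plus an abundance-dependent
  floor $1/(\mu_i \cdot 5\times10^5)$ that keeps every peptide
  overdispersed relative to binomial sampling at million-read depth and
  mirrors the elevated relative variability of rarely-pulled peptides.

`simulate_dataset()` then draws plates from the hierarchical model
itself: library sizes uniform in $[10^6, 2\times10^6]$; serum attenuation
constants from the $\mathrm{Beta}(80, 20)$ prior (1 for beads and null
columns); 50 enriched peptides per serum column, 10 in each fold-change
bin (1,2], (2,4], (4,8], (8,16], (16,32], with fold changes uniform
within bins (the bins are stated design, the within-bin law is our
choice). The default plate layout is 8 beads-only plus 12 serum columns,
of which one is a beads-only sample run as a sample and two form a
technical-replicate pair sharing $(Z, \phi, c)$ with fresh count noise —
the layout description is ambiguous about whether the replicate pair is
among or in addition to the twelve; we chose among. Whether serum
attenuation constants were drawn or fixed is likewise unstated; we draw
them from the prior.

**What passing tests do and do not show.** The generator reproduces
marginal count structure (abundance spread, overdispersion, spike-ins),
not sequencing artifacts (PCR duplicates, mapping error), peptide-peptide
correlation, or any abundance–dispersion trend; its per-peptide
dispersions are drawn independently. That last simplification has a
visible consequence: on round-robins over synthetic null plates, both the
Bayesian model and the exact test occasionally (about 1 decision in 1000)
flag a genuine 2-fold tail excursion of an abundant peptide whose
peptide-specific dispersion exceeds its shrinkage estimate. Real plates,
whose mock IPs are more homogeneous, show clean round-robins for both
methods; the synthetic null is in this respect harder than real data, and
results on it bound real-data specificity from below.

## Evaluation machinery

ROC and precision-recall points are computed per dataset from a score
that orients larger-is-more-enriched (posterior probability; $1 - p$ for
the exact test), linearly interpolated onto a shared grid of 501 evenly
spaced support points (grid density is our choice), averaged point-wise
across datasets, and integrated by trapezoid. ROC curves are anchored at
(0,0); PR curves start at recall 0 with perfect positive predictive
value. Per-bin curves use all non-enriched serum-column peptides plus the
enriched peptides of the bin; beads-only columns are never scored.

For power comparisons at matched specificity, `fdr_matched_cutoff()`
scans all achievable posterior-probability thresholds and returns the
smallest one whose empirical false-discovery proportion is at or below
the target, and `power_curve()` fits a logistic regression of detection
on log2 fold change, reporting the fold change with 50% detection
probability (with explicit flags for complete separation and flat fits).
Ranked-list agreement between technical replicates is summarized by
`topk_concordance()`, the fraction of peptides shared by the two top-$k$
sets — one concrete operationalization of "concordance", with ties broken
deterministically by peptide id.

## Problem sizes used in the checks

The packaged checks simulate plates of 300–1000 peptides with 2–8
beads-only and up to 4 serum columns, and run chains at the default
11,000 total iterations; these sizes give Monte-Carlo error comfortably
inside every asserted tolerance while keeping the suite quick to run.
The same machinery scales unchanged to full plates (thousands of
peptides, 12 serum columns); runtime grows linearly in peptides, samples,
and iterations.

## A worked example

```{r example, eval = FALSE}
prior <- generate_beads_prior(1000, seed = 42)
sim <- simulate_dataset(prior,
  design = sim_design(n_beads = 8, n_serum = 3, n_null = 0,
                      n_replicate_pairs = 0),
  seed = 43)
res <- run_beer(sim$matrix, config = beer_config(), seed = 101)

inp <- bin_curve_input(res, sim$truth, "post_prob", fc_range = c(4, 16))
roc_pr_curves(inp$scores, inp$labels)$roc$auc
```

## Known limitations

* Beads-only information enters only through plug-in prior shapes; their
  estimation uncertainty is not propagated (matching the three estimation
  routes described above). Joint multi-sample chains are deliberately out
  of scope.
* `phi_hat` is the posterior mean fold change *conditional on
  enrichment*; for peptides with low posterior probability it describes a
  hypothesis, not an estimate.
* The independence proposal from the fold-change slab mixes slowly for
  extreme fold changes; the pre-filter removes exactly those peptides,
  and the random-walk refinement covers the remaining range.
* The synthetic null is harder than real mock IPs (see above); absolute
  false-positive counts on it should not be read as real-data estimates.
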