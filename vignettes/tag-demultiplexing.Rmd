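---
title: "A mechanism-based model for demultiplexing sample-tagged single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanism-based model for demultiplexing sample-tagged single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdemux)
```

## The problem

In a multiplexed single-cell experiment each sample is labeled with a
sample-specific oligonucleotide tag (an LMO, CMO, or antibody-derived tag)
before the samples are pooled for droplet capture. After sequencing, every
droplet carries a vector of tag UMI counts, and demultiplexing means
deciding which tag (if any, or more than one) genuinely labeled the cell in
each droplet. The difficulty is contamination: once samples are pooled,
free tags bind to every cell's surface and ambient tags are co-encapsulated
in droplets, so every cell shows counts for tags it was never stained with.

## The contamination model

`tagdemux` models the contamination mechanistically, with two components.

**Cell-bound contamination.** Binding of a free tag B to a cell surface is
a simple bimolecular reaction far from equilibrium, so the amount bound is
proportional to the available surface area. The cell's total tag count
`N_total` is used as the surface-area proxy (it is much less cell-type
dependent than gene counts), giving an expected contaminating count

    mu_B = p_B * N_total

with `p_B` the fraction of total counts that tag B contributes on cells not
labeled with B.

**Ambient contamination.** Droplets additionally capture free-floating or
debris-bound tags, with a constant expected count `M_B` per tag across
droplets of consistent size. Combining the two components and absorbing the
tag-specific constant into regression coefficients (the relationship
between `ln(N_total + C)` and `ln(N_total)` is close to linear over the one
to two orders of magnitude that cell totals actually span), the negative
cells of a tag satisfy

    X ~ NB(mu, theta_neg),   ln(mu) = beta1_neg * ln(N_total) + beta0_neg

— a negative-binomial GLM of the observed tag count on the log total
count. In the limit of zero ambient contamination `beta1_neg` is exactly 1;
ambient contamination pulls it below 1, which is also the signature by
which the two sources can be distinguished in real data.

**Positive cells** are handled by the complementary observation that the
cells positive for tag B are negative for everything else. The pooled
contamination `N_total - X` of a positive cell — the sum of all other
tags, which share binding chemistry and can be treated as one contaminating
meta-tag — follows a second NB-GLM of the same form in the
`N_total - X` vs `N_total` space. Positive cells are badly non-linear in
the first space (they hug the `y = x` line) and negative cells are
non-linear in the second, which is precisely why the two-space formulation
separates them so well.

## Classification by EM

For each tag, a latent indicator `Z_i` says whether cell `i` was truly
labeled. The E step computes, in log space,

    P(Z_i = 1 | X_i) = p(N_total - X_i | Z=1) pi_1 /
        [p_adj(X_i | Z=0) pi_0 + p(N_total - X_i | Z=1) pi_1]

and the M step refits the two GLMs on the cells currently assigned to each
class (thresholding the posterior at 0.5). Priors are the class fractions
of the previous assignment. Two practical details matter:

* **Density floor.** A cell whose tag count is *below* the fitted negative
  mean is, if anything, more clearly negative, yet its NB density is small.
  `p_adj` therefore replaces the negative-model density of below-mean cells
  by the density at the rounded fitted mean in the first iteration and by 1
  afterwards.
* **Down-sampling.** Each class is independently subsampled to at most
  `max_fit_cells = 5000` cells before fitting; a few thousand cells fit the
  two GLMs robustly, which keeps the cost flat in dataset size.

**Initialization.** EM is sensitive to starting points, and tag data are
heavily imbalanced. The cosine similarity between a cell's count vector and
the canonical basis vector of a tag gives a near-bimodal statistic that
separates positives from negatives much more cleanly than raw counts; cells
at cosine `>= 0.5` start positive. Any cutoff in roughly 0.2–0.9 converges
to near-identical calls on data of low to moderate noise (this is one of
the package's acceptance properties). The exception is doublets: a doublet
sits near cosine `1/sqrt(2)` for both of its tags, so extreme cutoffs place
it on opposite sides of the initialization, and on very clean data the EM
can settle in either of two self-consistent basins for those droplets.
Singlet calls are unaffected; it is another face of the doublet-calling
limitation discussed below.

**Convergence.** Iteration stops when the thresholded assignment is
unchanged between consecutive iterations, or after `max_iter = 30`. Because
the M step refits on thresholded assignments (a classification EM, as in
the original method) and the density floor changes between iteration 1 and
later iterations, the observed-data log-likelihood is not strictly
monotone: it jumps sharply after the first refit and then wiggles within a
few percent. The recorded `loglik_trace` exposes this, and the test suite
asserts the honest property — a large net gain from initialization to
convergence with only small fluctuations afterwards — rather than strict
monotonicity, which this class of EM does not guarantee.

**Calls.** A cell is a singlet of tag T iff T is the only tag with
posterior strictly above `prob_cutoff = 0.5`, a multiplet if several tags
exceed it, negative if none does (posteriors exactly at the cutoff count as
negative; cosine exactly at its cutoff counts as positive — fixed,
documented conventions). The margin is typically wide: moving the cutoff
from 0.3 to 0.7 changes under 2% of calls on moderate-noise data.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `init_cutoff` | 0.5 | cosine similarity that starts a cell positive |
| `prob_cutoff` | 0.5 | posterior needed to call a cell positive |
| `max_fit_cells` | 5000 | per-class subsampling cap for GLM fitting |
| `max_iter` | 30 | EM iteration cap per tag |
| `min_cells` | 10 | minimum initial cells per class; below it a tag is "unfit" |
| `seed` | 1 | governs all subsampling; per-tag streams are derived from it |

Unfit tags (for example an unused tag column, or a sample with almost no
cells on one side of the cosine cutoff) are excluded with a warning and
all-zero posteriors rather than aborting the run. Cells with zero total
count are excluded from fitting and called negative.

## Diagnostics: randomized quantile residuals

Pearson residuals of count GLMs are far from normal, so goodness-of-fit is
diagnosed with randomized quantile residuals: `r_i = qnorm(u_i)` with `u_i`
uniform on `(F(y_i - 1), F(y_i)]` under the fitted NB distribution. Under a
correct model the residuals are standard normal; `residuals()` on a fit
returns them per cell and tag, `qq_points()` prepares Q-Q coordinates, and
`cap_infinite()` applies the plotting convention of replacing `+Inf` (cells
far above the fitted negative model — i.e. positives) by the maximum
finite residual plus 1.

A numerical subtlety: the deterministic mid-quantile variant (`mid = TRUE`,
the interval midpoint instead of a uniform draw) removes randomization
noise and is the right choice for formal normality tests *when the fitted
mean varies across observations*, as it does in these GLMs. At a single
fixed mean the residuals are discrete and a one-sample KS test will reject
on ties alone at large n; there the randomized mode is the calibrated one.
The test suite exercises both regimes accordingly. On predicted (rather
than true) negatives the residuals are close to normal but right-skewed,
reflecting genuine ambiguity at the positive/negative boundary.

## The simulator

`simulate_tags()` generates data from the same mechanism, in three steps:

1. **Staining.** Each sample's mean staining level is drawn on the natural
   log scale from a Normal centred on the midpoint of `staining_range`
   (default 5–7) with sd a quarter of the range width, clamped to the
   range; each cell's true count is log-normal around it (sd 0.7), rounded
   and floored at 1. This yields the clean matrix `x_true`.
2. **Cell-bound contamination.** Taking the cell's own staining count as
   `N_total`, each other tag contributes `NB(p_B * N_total, theta_B)`
   counts. The cell's own tag receives no contamination draw by default
   (its entry *is* the staining signal; drawing again would double-count —
   settable via `self_contamination`).
3. **Ambient contamination.** Every droplet receives `NB(M_k, theta_k)`
   counts of every tag.

Doublets merge randomly sampled singlet pairs without replacement (summing
their `x_true` and cell-bound rows) and receive a single fresh ambient draw,
since a doublet occupies one droplet; the doublet count is chosen so
doublets are the requested fraction of final droplets. An optional
zero-inflation step then drops entry `x` to 0 with probability
`exp(-lambda * x^2)` — at `lambda = 2` a count of 1 drops with probability
`exp(-2)` (about 14%), at `lambda = 0.5` with `exp(-0.5)` (about 61%).
`downsample_reads()` (multivariate hypergeometric within each cell, the
distribution induced by uniform read sampling without replacement) and
`downsample_cells()` emulate lower sequencing depth and smaller experiments.

The default configuration is the package's reference study condition, a
large imbalanced experiment: 30 tags; cells per sample log-normal
(`meanlog = log(500)`, `sdlog = 0.8`) bounded to [50, 5000], about 20,000
droplets in expectation; per-tag contamination fractions uniform in
0.005–0.02 and ambient means in 1–5 ("moderate" contamination — chosen
once as a realistic middle ground, roughly 10–30% of a typical cell's
counts being contamination); `theta` uniform in 2–10; 10% doublets;
`lambda = 2`. On this condition the classifier recovers over 99% of true
singlets (recomputed by `scripts/acceptance.R` and the test suite).

What the simulator does **not** emulate: cell-type structure (staining is
unimodal per sample), batch effects, variation in droplet size (ambient
means are constant per tag), empty-droplet backgrounds, and any coupling
between tag counts and the transcriptome. Passing tests on simulated data
therefore demonstrate correctness of the implementation under the model's
own assumptions, not performance on arbitrary real data.

## Numerical choices

* All GLM fitting is maximum likelihood via `MASS::glm.nb`; `theta` is
  clamped to `[1e-3, 1e5]` and hitting a bound clears the convergence flag.
  Degenerate inputs (constant covariate, all-zero response) return flagged
  fallback fits instead of failing, so a single pathological tag cannot
  abort a run.
* Posteriors are computed in log space with a log-sum-exp guard; underflow
  of both densities can never yield NaN.
* Subsampling draws cells after ordering candidates by barcode, making
  results invariant under row permutation of the input; per-tag RNG streams
  are derived from the top-level seed so results are independent of tag
  iteration order and bitwise reproducible.
* Logs are natural logs throughout.

## Problem sizes

The shipped tests fit the full 30-tag reference simulation (about 12,000
droplets in the seeded realization used) twice — once subsampled, once on
all cells — in a few minutes; unit tests use 3–8 tag simulations of a few
hundred cells per sample, and oracle checks (brute-force NB summation,
grid-search MLE, Monte-Carlo hypergeometric) run at small n. These sizes
were chosen as the smallest that make the statistical assertions sharp.

## Limitations

Doublets are not modeled explicitly: a doublet is called when two tags'
posteriors both exceed the cutoff, which misses doublets lowly stained in
both samples and can misread a high/low doublet as a singlet. Tag counts
alone cannot fully resolve this; transcriptome-based doublet detection is
the appropriate complement. The linear approximation behind the two GLMs
assumes totals span no more than about two orders of magnitude — datasets
with extreme cell-size heterogeneity may need a better estimate of the
ambient constant. And the classifier inherits the model's assumption that
contamination conditions are uniform across cells after pooling.
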