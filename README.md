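# tagdemux

Sample demultiplexing for tag-multiplexed single-cell RNA-seq, built on a
mechanistic model of tag cross-contamination.

## The problem

Pooling samples labeled with sample-specific oligonucleotide tags (LMOs,
CMOs, hashtag antibodies) is the standard way to scale single-cell
experiments, but after pooling every cell picks up counts of tags it was
never stained with — free tags bind cell surfaces, and ambient tags are
co-encapsulated in droplets. Demultiplexing then requires drawing a
boundary between genuinely labeled (positive) and contaminated (negative)
cells for every tag, under heavy class imbalance and sample-to-sample
variation in signal-to-noise. Methods that assume a bimodal count
distribution per tag fail exactly when experiments get large and noisy.

## The model

`tagdemux` models the contaminating count of tag B on a negative cell as
cell-bound plus ambient contamination. With the cell's total tag count
`N_total` as a surface-area proxy, both sources combine into a
negative-binomial GLM on the log scale:

    X_B ~ NB(mu_B, theta_neg),   ln(mu_B) = beta1_neg ln(N_total) + beta0_neg

(`beta1_neg = 1` exactly when there is no ambient contamination). The cells
*positive* for B are negative for the pooled "meta-tag" of all other tags,
so their total contamination obeys a second GLM of the same form:

    N_total - X_B ~ NB(mu_pos, theta_pos),
    ln(mu_pos) = beta1_pos ln(N_total) + beta0_pos

An EM algorithm — initialized by thresholding each cell's cosine
similarity with the tag's canonical unit vector at 0.5 — alternates between
fitting the two GLMs on the currently assigned classes (subsampled to 5000
cells each) and recomputing the posterior probability that each cell is
positive. Cells are finally called a **singlet** of the one tag whose
posterior exceeds 0.5, a **multiplet** if several do, or **negative**.
Randomized quantile residuals of the fitted GLMs (standard normal under a
correct model) serve as goodness-of-fit diagnostics and as a normalization
of the tag counts.

The package also implements the matching generative simulator (true
staining + cell-bound + ambient components, doublets, zero-inflation, read
and cell down-sampling), UMI tabulation from raw paired tag-library FASTQ
files, and precision/recall/F-score benchmarking against ground truth.

## Worked example

```r
library(tagdemux)

# a small, clean 4-sample experiment with known ground truth
sim <- simulate_tags(sim_config(n_tags = 4, n_cells = 300,
                                p_range = c(0.002, 0.005),
                                ambient_range = c(0.5, 2),
                                doublet_frac = 0.05, lambda = NULL,
                                seed = 3))
fit <- demultiplex(sim$counts, seed = 1)
fit
#> Tag demultiplexing fit (two-space NB-GLM EM)
#>   1143 cells, 4 tags; 0 zero-total cells excluded
#>   calls: 1097 singlet (96.0%), 46 multiplet, 0 negative

evaluate_demux(sim$truth$labels, fit$calls)
#> Demultiplexing evaluation
#>   macro precision 0.9900, recall 1.0000, F-score 0.9950
#>   overall singlet recall 1.0000, precision 0.9900
#>   doublet recall 0.8070
#>   4 tags scored (worst F-score 0.9928)

head(coef(fit), 2)
#>       beta0_neg beta1_neg theta_neg beta0_pos beta1_pos theta_pos
#> tag01 -3.329541 0.6919154  8.093415 -5.695553  1.488782 0.9544004
#> tag02 -1.561927 0.4577216 11.134948 -6.854127  1.671885 0.7478959
```

Every true singlet is recovered (recall 1.0) at 99% precision; the lost
1% are doublets lowly stained in one sample, the known hard case for
tag-only data. `beta1_neg` below 1 reflects the simulated ambient
contamination. `residuals(fit)` returns per-cell quantile residuals,
`plot(fit, tag = "tag01")` shows the fit and Q-Q diagnostics, and
`predict(fit, newdata)` scores new cells with the fitted models.

Raw FASTQ input goes through
`count_tags_from_fastq(r1, r2, tag_reference(...), layout = read_layout())`,
matrices on disk through `read_tag_matrix()` /`write_tag_matrix()`
(CSV/TSV/MatrixMarket), and `run_pipeline(out_dir, ...)` orchestrates
simulate → demultiplex → diagnose → evaluate into an artifact directory.
A thin command-line wrapper with the same verbs lives at
`inst/cli/tagdemux.R`.

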