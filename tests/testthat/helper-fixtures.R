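# Shared fixtures and independent oracles, built in code at test time.

# --- cache (shared across test files within one run) ----------------------
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Low-noise 4-tag simulation: clean staining, little contamination,
# a few doublets, no zero-inflation.
low_noise_sim <- function(seed = 3) {
  simulate_tags(sim_config(
    n_tags = 4, n_cells = 300, p_range = c(0.002, 0.005),
    ambient_range = c(0.5, 2), doublet_frac = 0.05, lambda = NULL,
    seed = seed))
}

# Moderate-noise 8-tag simulation used by robustness checks.
moderate_sim <- function(seed = 5) {
  simulate_tags(sim_config(
    n_tags = 8, n_cells = 400, p_range = c(0.005, 0.02),
    ambient_range = c(1, 5), doublet_frac = 0.1, lambda = 2, seed = seed))
}

# The large imbalanced 30-tag study condition (package defaults); shared by
# the recall and down-sampling-robustness checks because both need the same
# ~20k-droplet dataset.
big_sim <- function() cached("big_sim", simulate_tags(sim_config(seed = 11)))
big_fit <- function() cached("big_fit", demultiplex(big_sim()$counts, seed = 1))

# --- independent NB oracle (lgamma formula, no dnbinom) -------------------
oracle_nb_pmf <- function(y, mu, theta) {
  exp(lgamma(y + theta) - lgamma(theta) - lfactorial(y) +
      theta * (log(theta) - log(theta + mu)) +
      y * (log(mu) - log(theta + mu)))
}

oracle_nb_cdf <- function(y, mu, theta) {
  vapply(y, function(q) {
    if (q < 0) return(0)
    sum(oracle_nb_pmf(0:q, mu, theta))
  }, numeric(1))
}

# Coarse grid-search ML oracle for the NB-GLM (independent of the fitter).
oracle_grid_mle <- function(y, lt, b0_grid, b1_grid, th_grid) {
  best <- c(NA, NA, NA); best_ll <- -Inf
  for (b0 in b0_grid) for (b1 in b1_grid) for (th in th_grid) {
    ll <- glm_nb_loglik(y, lt, b0, b1, th)
    if (ll > best_ll) { best_ll <- ll; best <- c(b0, b1, th) }
  }
  list(par = best, loglik = best_ll)
}

# --- FASTQ fixture writer -------------------------------------------------
write_fastq <- function(path, seqs, ids = sprintf("read%d", seq_along(seqs))) {
  qual <- vapply(seqs, function(s) strrep("I", nchar(s)), character(1))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}

# Build a read-1 sequence from cell barcode + UMI under the default layout.
r1_seq <- function(cb, umi) paste0(cb, umi)
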