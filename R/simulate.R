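#' Simulation configuration
#'
#' Parameters of the three-step generative model of tag counts. Defaults
#' describe a large, imbalanced, moderately contaminated experiment: 30
#' tags, cells per sample drawn from a bounded log-normal (roughly 20,000
#' droplets in total), per-sample staining log-means in 5-7 (natural log),
#' NB overdispersion between 2 and 10, moderate cell-bound and ambient
#' contamination, 10% doublets, and zero-inflation with decay 2.
#'
#' Per-tag parameters (`p`, `theta`, `ambient`, `staining_logmean`,
#' `n_cells`) may be supplied explicitly as vectors; otherwise they are
#' drawn once per simulation from the corresponding ranges.
#'
#' @param n_tags Number of sample tags.
#' @param n_cells Optional cells per tag: scalar or length-`n_tags` vector.
#'   When `NULL`, drawn per tag from a log-normal with `cells_meanlog`,
#'   `cells_sdlog`, clamped to `cells_bounds`.
#' @param cells_meanlog,cells_sdlog,cells_bounds Log-normal parameters and
#'   (lower, upper) bounds of the per-sample cell count.
#' @param staining_range Range of per-sample mean staining level on the
#'   natural-log scale (default `c(5, 7)`); per-sample log-means are drawn
#'   from a Normal centred on the range midpoint with sd a quarter of the
#'   range width, clamped to the range.
#' @param staining_logmean Optional explicit per-tag staining log-means.
#' @param staining_sdlog Per-cell log-normal sd of the staining level.
#' @param p,p_range Per-tag cell-bound contamination fraction(s): the
#'   expected contaminating count of tag B on a negative cell is
#'   `p_B * N_total`.
#' @param theta,theta_range Per-tag NB overdispersion.
#' @param ambient,ambient_range Per-tag expected ambient count `M_k`,
#'   constant across cells.
#' @param ambient_theta Overdispersion of ambient draws; defaults to the
#'   tag's `theta`.
#' @param doublet_frac Fraction of final droplets that are doublets, in
#'   `[0, 0.5)`.
#' @param lambda Zero-inflation decay: an entry of value x is dropped to 0
#'   with probability `exp(-lambda * x^2)`. `NULL` disables the step.
#' @param self_contamination If `TRUE`, a cell's own tag also receives a
#'   cell-bound contamination draw (off by default: the own-tag entry is the
#'   staining signal itself).
#' @param seed Integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_tags = 30L, n_cells = NULL,
                       cells_meanlog = log(500), cells_sdlog = 0.8,
                       cells_bounds = c(50L, 5000L),
                       staining_range = c(5, 7),
                       staining_logmean = NULL, staining_sdlog = 0.7,
                       p = NULL, p_range = c(0.005, 0.02),
                       theta = NULL, theta_range = c(2, 10),
                       ambient = NULL, ambient_range = c(1, 5),
                       ambient_theta = NULL,
                       doublet_frac = 0.1, lambda = 2,
                       self_contamination = FALSE, seed = 1L) {
  stopifnot(n_tags >= 1, cells_bounds[1] <= cells_bounds[2],
            staining_range[1] <= staining_range[2], staining_sdlog >= 0,
            doublet_frac >= 0, doublet_frac < 0.5)
  chk_vec <- function(v, name, lo, hi = Inf, strict_hi = FALSE) {
    if (is.null(v)) return(NULL)
    v <- rep_len(v, n_tags)
    bad <- v < lo | (if (strict_hi) v >= hi else v > hi)
    if (any(bad)) stop("'", name, "' out of range")
    v
  }
  if (!is.null(lambda) && lambda <= 0)
    stop("'lambda' must be positive; use NULL to disable zero-inflation")
  cfg <- list(n_tags = as.integer(n_tags),
              n_cells = chk_vec(n_cells, "n_cells", 1),
              cells_meanlog = cells_meanlog, cells_sdlog = cells_sdlog,
              cells_bounds = cells_bounds,
              staining_range = staining_range,
              staining_logmean = chk_vec(staining_logmean,
                                         "staining_logmean", -Inf),
              staining_sdlog = staining_sdlog,
              p = chk_vec(p, "p", 0, 1, strict_hi = TRUE),
              p_range = p_range,
              theta = chk_vec(theta, "theta", 1e-8),
              theta_range = theta_range,
              ambient = chk_vec(ambient, "ambient", 0),
              ambient_range = ambient_range,
              ambient_theta = chk_vec(ambient_theta, "ambient_theta", 1e-8),
              doublet_frac = doublet_frac, lambda = lambda,
              self_contamination = isTRUE(self_contamination),
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' Simulate a multiplexed tag count matrix with known truth
#'
#' Generates tag counts in three steps mirroring the labeling, pooling and
#' contamination process: (1) per-sample staining levels drawn log-normally
#' give the clean matrix `x_true` (rounded, floored at 1, one nonzero tag
#' per cell); (2) treating each cell's own staining count as its total tag
#' count, cell-bound contamination for every other tag B is drawn from
#' `NB(p_B * N_total, theta_B)`; (3) ambient contamination for every tag k
#' is drawn from `NB(M_k, theta_k)` per droplet. Doublets merge randomly
#' sampled singlet pairs (summing `x_true` and cell-bound rows; ambient is
#' drawn once per droplet), and an optional zero-inflation step drops entry
#' x to 0 with probability `exp(-lambda x^2)`. The observed matrix is the
#' elementwise sum of the three components (before zero-inflation).
#'
#' @param config A [sim_config()].
#' @return A `tag_sim` list: `counts` (observed matrix, after any
#'   zero-inflation), `truth` (components `x_true`, `c_cell_bound`,
#'   `c_ambient`, pre-dropout `observed`, `labels` — tag name or
#'   `"multiplet"` — and `tag_pairs`), and the resolved per-tag `params`.
#' @examples
#' sim <- simulate_tags(sim_config(n_tags = 3, n_cells = 100, seed = 7))
#' table(sim$truth$labels)
#' @export
simulate_tags <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    nt <- config$n_tags
    tag_names <- sprintf("tag%02d", seq_len(nt))
    draw_range <- function(v, range) if (!is.null(v)) v else
      stats::runif(nt, range[1], range[2])
    n_cells <- if (!is.null(config$n_cells)) config$n_cells else
      pmin(pmax(round(stats::rlnorm(nt, config$cells_meanlog,
                                    config$cells_sdlog)),
                config$cells_bounds[1]), config$cells_bounds[2])
    sl <- if (!is.null(config$staining_logmean)) config$staining_logmean else {
      r <- config$staining_range
      pmin(pmax(stats::rnorm(nt, mean(r), diff(r) / 4), r[1]), r[2])
    }
    p_k <- draw_range(config$p, config$p_range)
    theta_k <- draw_range(config$theta, config$theta_range)
    m_k <- draw_range(config$ambient, config$ambient_range)
    atheta_k <- if (!is.null(config$ambient_theta)) config$ambient_theta
                else theta_k

    n0 <- sum(n_cells)
    owner <- rep(seq_len(nt), n_cells)
    stain <- pmax(round(stats::rlnorm(n0, sl[owner], config$staining_sdlog)),
                  1)
    x_true <- matrix(0, n0, nt, dimnames = list(NULL, tag_names))
    x_true[cbind(seq_len(n0), owner)] <- stain

    ntot_true <- stain
    c_bound <- matrix(0, n0, nt, dimnames = list(NULL, tag_names))
    for (k in seq_len(nt)) {
      mu <- p_k[k] * ntot_true
      if (!config$self_contamination) mu[owner == k] <- 0
      c_bound[, k] <- stats::rnbinom(n0, size = theta_k[k], mu = mu)
    }

    labels <- tag_names[owner]
    db <- make_doublets(x_true, c_bound, labels, config$doublet_frac)
    nd <- nrow(db$x_true)

    c_amb <- matrix(0, nd, nt, dimnames = list(NULL, tag_names))
    for (k in seq_len(nt))
      c_amb[, k] <- stats::rnbinom(nd, size = atheta_k[k], mu = m_k[k])

    observed <- db$x_true + db$c_cell_bound + c_amb
    counts <- if (!is.null(config$lambda))
      zero_inflate(observed, config$lambda) else observed

    bc <- sprintf("cell%06d", seq_len(nd))
    rownames(counts) <- rownames(observed) <- bc
    rownames(db$x_true) <- rownames(db$c_cell_bound) <- rownames(c_amb) <- bc
    names(db$labels) <- names(db$tag_pairs) <- bc

    structure(list(
      counts = counts,
      truth = list(x_true = db$x_true, c_cell_bound = db$c_cell_bound,
                   c_ambient = c_amb, observed = observed,
                   labels = db$labels, tag_pairs = db$tag_pairs),
      params = data.frame(tag = tag_names, n_cells = n_cells,
                          staining_logmean = sl, p = p_k, theta = theta_k,
                          ambient = m_k, ambient_theta = atheta_k),
      config = config), class = "tag_sim")
  })
}

#' @export
print.tag_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated tag experiment: %d droplets x %d tags (%d doublets)\n",
    nrow(x$counts), ncol(x$counts), sum(x$truth$labels == "multiplet")))
  invisible(x)
}

#' Merge random singlet pairs into doublets
#'
#' Samples pairs of singlets without replacement, removes them, and appends
#' one droplet per pair whose `x_true` and cell-bound contamination rows are
#' the pair sums. The number of doublets is chosen so that they make up
#' `fraction` of the final droplet count. Ambient contamination is not
#' handled here: it is drawn once per final droplet by the caller.
#'
#' @param x_true,c_cell_bound Singlet component matrices (cells x tags).
#' @param labels Per-singlet tag labels.
#' @param fraction Doublet fraction of final droplets, in `[0, 0.5)`.
#' @return List with merged `x_true`, `c_cell_bound`, `labels` (doublets
#'   labelled `"multiplet"`), `tag_pairs` (e.g. `"tag01+tag03"`, NA for
#'   singlets) and `n_doublets`.
#' @export
make_doublets <- function(x_true, c_cell_bound, labels, fraction) {
  stopifnot(nrow(x_true) == nrow(c_cell_bound),
            nrow(x_true) == length(labels),
            fraction >= 0, fraction < 0.5)
  n0 <- nrow(x_true)
  n_d <- floor(fraction * n0 / (1 + fraction))
  if (n_d == 0)
    return(list(x_true = x_true, c_cell_bound = c_cell_bound,
                labels = labels, tag_pairs = rep(NA_character_, n0),
                n_doublets = 0L))
  if (2 * n_d > n0)
    stop("too few singlets to form ", n_d, " doublets")
  pick <- sample.int(n0, 2 * n_d)
  a <- pick[seq_len(n_d)]
  b <- pick[n_d + seq_len(n_d)]
  dx <- x_true[a, , drop = FALSE] + x_true[b, , drop = FALSE]
  dc <- c_cell_bound[a, , drop = FALSE] + c_cell_bound[b, , drop = FALSE]
  pair <- vapply(seq_len(n_d), function(i)
    paste(sort(c(labels[a[i]], labels[b[i]])), collapse = "+"),
    character(1))
  keep <- setdiff(seq_len(n0), pick)
  list(x_true = rbind(x_true[keep, , drop = FALSE], dx),
       c_cell_bound = rbind(c_cell_bound[keep, , drop = FALSE], dc),
       labels = c(labels[keep], rep("multiplet", n_d)),
       tag_pairs = c(rep(NA_character_, length(keep)), pair),
       n_doublets = n_d)
}

#' Drop-out probability of the zero-inflation step
#'
#' @param x Non-negative count value(s).
#' @param lambda Positive exponential decay parameter.
#' @return `exp(-lambda * x^2)`, the probability that an entry of value `x`
#'   is dropped to zero.
#' @examples
#' dropout_prob(1, 2)    # ~ 0.135
#' dropout_prob(1, 0.5)  # ~ 0.607
#' @export
dropout_prob <- function(x, lambda) {
  if (!is.numeric(lambda) || lambda <= 0) stop("'lambda' must be positive")
  if (any(x < 0)) stop("'x' must be non-negative")
  exp(-lambda * x^2)
}

#' Apply zero-inflation to a count matrix
#'
#' Each entry of value x is independently set to 0 with probability
#' `exp(-lambda * x^2)` (zeros are unchanged).
#'
#' @param counts Count matrix.
#' @param lambda Positive decay parameter.
#' @return Matrix of the same shape with extra zeros.
#' @export
zero_inflate <- function(counts, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    stop("'lambda' must be a positive scalar (disable the step by omitting it)")
  drop <- stats::runif(length(counts)) < dropout_prob(as.vector(counts),
                                                     lambda)
  out <- counts
  out[matrix(drop, nrow(counts), ncol(counts))] <- 0
  out
}

# Multivariate hypergeometric draw: partition k of sum(counts) uniformly
# sampled reads (without replacement) across the tags.
rmvhyper <- function(counts, k) {
  out <- integer(length(counts))
  rest <- sum(counts)
  for (j in seq_along(counts)) {
    if (k == 0) break
    if (j == length(counts)) { out[j] <- k; break }
    rest <- rest - counts[j]
    out[j] <- stats::rhyper(1, m = counts[j], n = rest, k = k)
    k <- k - out[j]
  }
  out
}

#' Down-sample reads within each cell
#'
#' Uniformly down-samples each cell's reads without replacement to a target
#' total, partitioning kept reads across tags; per-tag kept counts follow
#' the multivariate hypergeometric distribution induced by uniform sampling.
#'
#' @param counts Cells x tags count matrix.
#' @param rate Keep fraction in (0, 1]; per-cell kept total is
#'   `round(rate * N_total)`.
#' @param target Alternative to `rate`: per-cell kept total (scalar or
#'   vector); must not exceed any cell's total.
#' @return Down-sampled matrix of the same shape.
#' @export
downsample_reads <- function(counts, rate = NULL, target = NULL) {
  counts <- as_tag_counts(counts)
  m <- as.matrix(counts)
  ntot <- rowSums(m)
  if (is.null(rate) == is.null(target))
    stop("supply exactly one of 'rate' or 'target'")
  if (!is.null(rate)) {
    if (rate <= 0 || rate > 1) stop("'rate' must be in (0, 1]")
    kept <- round(rate * ntot)
  } else {
    kept <- rep_len(target, nrow(m))
    if (any(kept > ntot)) stop("'target' exceeds a cell's total count")
    if (any(kept < 0)) stop("'target' must be non-negative")
  }
  out <- m
  for (i in seq_len(nrow(m)))
    if (kept[i] < ntot[i])
      out[i, ] <- rmvhyper(m[i, ], kept[i])
  out
}

#' Down-sample droplets
#'
#' Uniform sampling of droplets without replacement, with the ground-truth
#' object subset consistently when given.
#'
#' @param counts Cells x tags count matrix.
#' @param truth Optional truth list as produced by [simulate_tags()].
#' @param n Number of droplets to keep (or use `fraction`).
#' @param fraction Fraction of droplets to keep.
#' @return If `truth` is `NULL`, the subset matrix; otherwise a list with
#'   `counts` and `truth`.
#' @export
downsample_cells <- function(counts, truth = NULL, n = NULL,
                             fraction = NULL) {
  counts <- as_tag_counts(counts)
  if (is.null(n) == is.null(fraction))
    stop("supply exactly one of 'n' or 'fraction'")
  if (is.null(n)) n <- round(fraction * nrow(counts))
  if (n < 1 || n > nrow(counts)) stop("'n' out of range")
  idx <- sort(sample.int(nrow(counts), n))
  cm <- counts[idx, , drop = FALSE]
  if (is.null(truth)) return(cm)
  tr <- truth
  for (f in c("x_true", "c_cell_bound", "c_ambient", "observed"))
    if (!is.null(tr[[f]])) tr[[f]] <- tr[[f]][idx, , drop = FALSE]
  tr$labels <- tr$labels[idx]
  tr$tag_pairs <- tr$tag_pairs[idx]
  list(counts = cm, truth = tr)
}
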