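test_that("component matrices sum exactly to the observed matrix", {
  sim <- simulate_tags(sim_config(n_tags = 5, n_cells = 200,
                                  doublet_frac = 0.1, lambda = 2, seed = 2))
  with(sim$truth, {
    expect_equal(observed, x_true + c_cell_bound + c_ambient)
  })
  # zero-inflation only removes counts
  expect_true(all(sim$counts <= sim$truth$observed))
  # doublet rows of x_true carry two positive tags (one if the pair came
  # from the same sample)
  db <- sim$truth$labels == "multiplet"
  expect_true(all(rowSums(sim$truth$x_true[db, ] > 0) %in% 1:2))
})

test_that("the noise-free limit returns the clean staining matrix", {
  cfg <- sim_config(n_tags = 3, n_cells = 50, p = 0, ambient = 0,
                    doublet_frac = 0, lambda = NULL, seed = 4)
  sim <- simulate_tags(cfg)
  expect_equal(sim$counts, sim$truth$x_true)
  expect_true(all(rowSums(sim$counts > 0) == 1))
  expect_true(all(sim$counts[sim$counts > 0] >= 1))
})

test_that("contamination draws match their stated NB means and variances", {
  # cell-bound: mean contaminating count of tag B ~ p_B * mean(N_total)
  cfg <- sim_config(n_tags = 4, n_cells = 2500, p = 0.05, theta = 5,
                    ambient = 0, doublet_frac = 0, lambda = NULL, seed = 6)
  sim <- simulate_tags(cfg)
  own <- sim$truth$labels
  for (tg in colnames(sim$counts)[1:2]) {
    neg <- own != tg
    x <- sim$truth$c_cell_bound[neg, tg]
    mu_expect <- 0.05 * mean(rowSums(sim$truth$x_true)[neg])
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - mu_expect), 3 * se + 1e-9)
  }
  # ambient-only: column means ~ M_k, variance ~ mu + mu^2/theta
  cfg2 <- sim_config(n_tags = 3, n_cells = 4000, p = 0, ambient = 3,
                     theta = 4, doublet_frac = 0, lambda = NULL, seed = 7)
  sim2 <- simulate_tags(cfg2)
  amb <- sim2$truth$c_ambient
  for (k in 1:3) {
    se <- sd(amb[, k]) / sqrt(nrow(amb))
    expect_lt(abs(mean(amb[, k]) - 3), 3 * se)
    expect_equal(var(amb[, k]), 3 + 9 / 4, tolerance = 0.15 * (3 + 9 / 4))
  }
})

test_that("doublet formation merges pairs and keeps the books straight", {
  x <- rbind(c(10, 0), c(20, 0), c(0, 5), c(0, 30))
  colnames(x) <- c("A", "B")
  cb <- matrix(1L, 4, 2, dimnames = list(NULL, c("A", "B")))
  labs <- c("A", "A", "B", "B")
  # fraction 0 is the identity
  id <- make_doublets(x, cb, labs, 0)
  expect_equal(id$x_true, x)
  expect_equal(id$n_doublets, 0L)
  set.seed(1)
  db <- make_doublets(x, cb, labs, 0.4)
  n_d <- db$n_doublets
  expect_equal(n_d, floor(0.4 * 4 / 1.4))
  expect_equal(nrow(db$x_true), 4 - n_d)
  # merging loses no counts and the doublet row is a pair sum
  expect_equal(sum(db$x_true), sum(x))
  expect_equal(unname(db$c_cell_bound[nrow(db$c_cell_bound), ]), c(2, 2))
  expect_true(grepl("\\+", db$tag_pairs[length(db$tag_pairs)]))
  # the requested count tracks fraction x final droplets within rounding
  sim <- simulate_tags(sim_config(n_tags = 4, n_cells = 500,
                                  doublet_frac = 0.1, lambda = NULL,
                                  seed = 9))
  nd <- sum(sim$truth$labels == "multiplet")
  expect_lte(abs(nd - 0.1 * nrow(sim$counts)), 1)
})

test_that("zero-inflation drops entries at the stated exponential rate", {
  expect_equal(dropout_prob(1, 2), exp(-2))
  expect_equal(dropout_prob(1, 0.5), exp(-0.5))
  expect_error(zero_inflate(matrix(1), 0), "positive")
  expect_error(dropout_prob(1, -1), "positive")
  m <- matrix(1L, 100, 100)
  set.seed(3)
  z <- zero_inflate(m, 2)
  emp <- mean(z == 0)
  se <- sqrt(exp(-2) * (1 - exp(-2)) / length(m))
  expect_lt(abs(emp - exp(-2)), 3 * se)
  # zeros stay zero; large values essentially never drop
  m2 <- cbind(rep(0L, 50), rep(100L, 50))
  expect_true(all(zero_inflate(m2, 2)[, 2] == 100))
  expect_true(all(zero_inflate(m2, 2)[, 1] == 0))
})

test_that("read down-sampling is hypergeometric within each cell", {
  m <- rbind(a = c(8L, 2L), b = c(5L, 5L))
  colnames(m) <- c("t1", "t2")
  expect_equal(downsample_reads(m, rate = 1), m)
  z <- downsample_reads(m, target = 0)
  expect_true(all(z == 0))
  expect_error(downsample_reads(m, target = 11), "exceeds")
  expect_error(downsample_reads(m, rate = 0), "in \\(0, 1\\]")
  # Monte-Carlo: keeping 5 of (8, 2) gives tag-1 mean 4 (5 * 8/10)
  set.seed(10)
  draws <- replicate(1e5, downsample_reads(m[1, , drop = FALSE],
                                           target = 5)[1, 1])
  expect_true(all(draws + downsample_reads(m, target = 5)[1, 2] <= 8 + 2))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 4), 4 * se)
  # exact hypergeometric variance as an independent check
  v_exp <- 5 * 0.8 * 0.2 * (10 - 5) / (10 - 1)
  expect_equal(var(draws), v_exp, tolerance = 0.05 * v_exp)
  # row totals always equal the requested kept count
  big <- matrix(rpois(200, 20), 20, 10,
                dimnames = list(paste0("c", 1:20), paste0("t", 1:10)))
  ds <- downsample_reads(big, rate = 0.3)
  expect_equal(unname(rowSums(ds)), unname(round(0.3 * rowSums(big))))
  expect_true(all(ds <= big))
})

test_that("cell down-sampling subsets droplets and truth consistently", {
  sim <- simulate_tags(sim_config(n_tags = 3, n_cells = 100,
                                  doublet_frac = 0.1, lambda = NULL,
                                  seed = 5))
  n <- nrow(sim$counts)
  set.seed(2)
  ds <- downsample_cells(sim$counts, sim$truth, n = 50)
  expect_equal(nrow(ds$counts), 50L)
  expect_equal(rownames(ds$counts), names(ds$truth$labels))
  expect_equal(ds$truth$x_true + ds$truth$c_cell_bound +
                 ds$truth$c_ambient, ds$truth$observed)
  all_of_them <- downsample_cells(sim$counts, n = n)
  expect_equal(as.matrix(all_of_them), as.matrix(sim$counts))
  expect_error(downsample_cells(sim$counts, n = n + 1), "out of range")
})

test_that("seeds reproduce bitwise and different seeds match in distribution", {
  cfg <- sim_config(n_tags = 5, n_cells = 400, seed = 21)
  a <- simulate_tags(cfg)
  b <- simulate_tags(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  # with per-tag parameters held fixed, only the count draws differ between
  # seeds, so the per-cell totals agree in distribution
  fixed <- function(seed) sim_config(
    n_tags = 5, n_cells = 400, staining_logmean = 6, p = 0.01, theta = 5,
    ambient = 2, doublet_frac = 0.1, lambda = 2, seed = seed)
  t1 <- rowSums(simulate_tags(fixed(21))$counts)
  t2 <- rowSums(simulate_tags(fixed(22))$counts)
  ks <- suppressWarnings(ks.test(t1, t2))
  expect_gt(ks$p.value, 0.01)
})
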