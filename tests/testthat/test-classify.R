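test_that("cosine similarity with canonical vectors has its closed forms", {
  m <- rbind(a = c(10, 0), b = c(3, 4), c = c(5, 5), d = c(0, 0))
  colnames(m) <- c("t1", "t2")
  cs <- cosine_canonical(m)
  expect_equal(rownames(cs), c("a", "b", "c"))  # zero cell excluded
  expect_equal(unname(cs["a", ]), c(1, 0))
  expect_equal(unname(cs["b", ]), c(0.6, 0.8))
  expect_equal(unname(cs["c", ]), rep(1 / sqrt(2), 2))
  # uniform cell over n tags
  u <- matrix(3, 1, 5, dimnames = list("u", paste0("t", 1:5)))
  expect_equal(unname(cosine_canonical(u)[1, ]), rep(1 / sqrt(5), 5))
})

test_that("initial assignment thresholds cosines and flags sparse tags", {
  ia <- init_assignment(c(0.9, 0.1), cutoff = 0.5, min_cells = 1)
  expect_equal(ia$z, c(TRUE, FALSE))
  expect_false(ia$unfit)
  expect_true(init_assignment(runif(50, 0, 0.4), 0.5, 10)$unfit)
  expect_error(init_assignment(0.5, cutoff = 1), "in \\(0, 1\\)")
  # ties: cosine equal to the cutoff counts as positive
  expect_true(init_assignment(0.5, 0.5, 1)$z)
  # on low-noise data the initialization is close to truth
  sim <- low_noise_sim()
  keep <- Matrix::rowSums(sim$counts) > 0
  cs <- cosine_canonical(sim$counts)
  z <- cs[, "tag01"] >= 0.5
  truth_pos <- sim$truth$labels[keep][match(rownames(cs),
                                            rownames(sim$counts)[keep])]
  expect_gt(mean(z == (truth_pos == "tag01")), 0.95)
})

test_that("the E step yields normalized, extreme-pattern posteriors", {
  sim <- low_noise_sim()
  ms <- m_step(sim$counts, "tag01",
               z = cosine_canonical(sim$counts)[, "tag01"] >= 0.5)
  # negative-space slope is near 1 when ambient contamination is small
  expect_equal(ms$fit_neg$beta1, 1, tolerance = 0.35)
  ntot <- as.numeric(Matrix::rowSums(sim$counts))
  p <- e_step(as.numeric(sim$counts[, "tag01"]), ntot,
              ms$fit_neg, ms$fit_pos, c(0.75, 0.25), iteration = 1)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(is.finite(p)))
  # pure-contamination pattern (X = 0, large total) -> posterior near 0
  p0 <- e_step(0L, 2000, ms$fit_neg, ms$fit_pos, c(0.5, 0.5), 2)
  expect_lt(p0, 0.01)
  # pure-positive pattern (X = N_total) -> posterior near 1
  p1 <- e_step(2000L, 2000, ms$fit_neg, ms$fit_pos, c(0.5, 0.5), 2)
  expect_gt(p1, 0.99)
  # underflow of both densities never yields NaN
  pu <- e_step(5e5L, 1e6, ms$fit_neg, ms$fit_pos, c(0.5, 0.5), 2)
  expect_true(is.finite(pu))
})

test_that("posterior is monotone in the tag count after the final E step", {
  sim <- moderate_sim()
  fit <- demultiplex(sim$counts, seed = 2)
  tf <- fit$tag_fits[["tag01"]]
  other <- 40                       # fixed counts on the other tags
  xs <- 0:500
  post <- e_step(xs, other + xs, tf$fit_neg, tf$fit_pos,
                 tf$prior_trace[nrow(tf$prior_trace), ],
                 iteration = max(tf$n_iter, 2L))
  expect_true(all(diff(post) >= -1e-8))
})

test_that("EM recovers low-noise truth, is robust to the cosine cutoff, and is deterministic", {
  sim <- low_noise_sim()
  fit <- demultiplex(sim$counts, seed = 7)
  ev <- evaluate_demux(sim$truth$labels, fit$calls)
  expect_true(all(ev$per_tag$f_score >= 0.99))
  # EM initialized anywhere in the broad cosine range agrees on singlet
  # cells; doublets (cosine ~ 1/sqrt(2) for both tags, straddling extreme
  # cutoffs) are the only initialization-sensitive droplets here
  fit_lo <- demultiplex(sim$counts, init_cutoff = 0.2, seed = 7)
  fit_hi <- demultiplex(sim$counts, init_cutoff = 0.9, seed = 7)
  sg <- sim$truth$labels != "multiplet"
  expect_gte(mean(fit_lo$calls[sg] == fit_hi$calls[sg]), 0.99)
  expect_gte(mean(fit_lo$calls == fit_hi$calls), 0.95)
  # bitwise determinism under a fixed seed
  fit2 <- demultiplex(sim$counts, seed = 7)
  expect_identical(fit$posterior, fit2$posterior)
  expect_identical(fit$calls, fit2$calls)
})

test_that("EM objective improves greatly from initialization and stabilizes", {
  sim <- moderate_sim()
  fit <- demultiplex(sim$counts, seed = 2)
  for (tf in fit$tag_fits) {
    tr <- tf$loglik_trace
    if (length(tr) < 2) next
    gain <- tr[length(tr)] - tr[1]
    expect_gt(gain, 0)
    if (length(tr) > 2) {
      wiggle <- max(abs(diff(tr[-1])))
      expect_lt(wiggle, 0.15 * gain)
    }
  }
  expect_true(all(vapply(fit$tag_fits, `[[`, integer(1), "n_iter") <= 30))
})

test_that("calls follow the posterior-count rule with strict cutoff", {
  post <- rbind(c(0.99, 0.01, 0.02),
                c(0.90, 0.80, 0.10),
                c(0.20, 0.30, 0.10),
                c(0.50, 0.10, 0.10))   # exactly at cutoff -> negative
  dimnames(post) <- list(paste0("c", 1:4), paste0("t", 1:3))
  expect_equal(unname(call_cells(post)),
               c("t1", "multiplet", "negative", "negative"))
  expect_error(call_cells(post * 2), "in \\[0,1\\]")
})

test_that("degenerate tags and cells are handled gracefully", {
  sim <- low_noise_sim()
  m <- as.matrix(sim$counts)
  m <- cbind(m, dead = 0L)            # an all-zero tag
  m <- rbind(m, empty = 0L)           # an all-zero cell
  expect_warning(fit <- demultiplex(m, seed = 1), "unfit")
  expect_true(fit$tag_fits[["dead"]]$unfit)
  expect_true(all(fit$posterior[, "dead"] == 0))
  expect_equal(unname(fit$calls["empty"]), "negative")
  expect_equal(fit$excluded, "empty")
  ev <- evaluate_demux(sim$truth$labels, fit$calls[rownames(sim$counts)])
  expect_true(all(ev$per_tag$f_score >= 0.99))
  # a matrix where no tag can be fit errors with a diagnostic
  flat <- matrix(1L, 40, 3, dimnames = list(paste0("c", 1:40),
                                            paste0("t", 1:3)))
  expect_error(suppressWarnings(demultiplex(flat, seed = 1)), "unfit")
})

test_that("results are equivariant under permutation of cell order", {
  sim <- low_noise_sim()
  fit <- demultiplex(sim$counts, seed = 5)
  set.seed(123)
  perm <- sample(nrow(sim$counts))
  fitp <- demultiplex(sim$counts[perm, ], seed = 5)
  expect_identical(fitp$calls, fit$calls[perm])
  expect_equal(fitp$posterior, fit$posterior[perm, ], tolerance = 1e-12)
})

test_that("the decision boundary has a wide margin in the cutoff", {
  sim <- moderate_sim()
  fit <- demultiplex(sim$counts, seed = 2)
  c3 <- call_cells(fit$posterior, 0.3)
  c7 <- call_cells(fit$posterior, 0.7)
  expect_lt(mean(c3 != c7), 0.02)
})

test_that("predict scores new data with the fitted models", {
  sim <- low_noise_sim()
  fit <- demultiplex(sim$counts, seed = 1)
  idx <- seq_len(200)
  newm <- as.matrix(sim$counts)[idx, ]
  post <- predict(fit, newm)
  expect_equal(dim(post), c(200L, 4L))
  calls <- predict(fit, newm, type = "call")
  expect_gt(mean(calls == fit$calls[idx]), 0.98)
  expect_error(predict(fit, newm[, 1:2]), "same tag columns")
})
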