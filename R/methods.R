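#' @export
print.demux_fit <- function(x, ...) {
  n <- length(x$calls)
  tab <- table(factor(ifelse(x$calls %in% c("multiplet", "negative"),
                             x$calls, "singlet"),
                      levels = c("singlet", "multiplet", "negative")))
  cat("Tag demultiplexing fit (two-space NB-GLM EM)\n")
  cat(sprintf("  %d cells, %d tags; %d zero-total cells excluded\n",
              n, ncol(x$posterior), length(x$excluded)))
  cat(sprintf("  calls: %d singlet (%.1f%%), %d multiplet, %d negative\n",
              tab["singlet"], 100 * tab["singlet"] / n,
              tab["multiplet"], tab["negative"]))
  unfit <- vapply(x$tag_fits, `[[`, logical(1), "unfit")
  if (any(unfit))
    cat("  unfit tags:", paste(names(unfit)[unfit], collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a demultiplexing fit
#'
#' Per-tag table of singlet counts, EM iterations, convergence, priors and
#' GLM coefficients, plus the overall call breakdown.
#'
#' @param object A `demux_fit`.
#' @param ... Unused.
#' @return A `summary.demux_fit` object (list with `calls` table and
#'   per-tag data frame), printed nicely.
#' @export
summary.demux_fit <- function(object, ...) {
  tags <- colnames(object$posterior)
  per_tag <- data.frame(
    tag = tags,
    n_called = vapply(tags, function(t) sum(object$calls == t), integer(1)),
    n_iter = vapply(object$tag_fits, `[[`, integer(1), "n_iter"),
    converged = vapply(object$tag_fits, `[[`, logical(1), "converged"),
    unfit = vapply(object$tag_fits, `[[`, logical(1), "unfit"),
    row.names = NULL)
  cf <- coef(object)
  structure(list(call_table = table(object$calls),
                 per_tag = cbind(per_tag, as.data.frame(cf)),
                 n_excluded = length(object$excluded)),
            class = "summary.demux_fit")
}

#' @export
print.summary.demux_fit <- function(x, ...) {
  cat("Call breakdown:\n")
  print(x$call_table)
  cat("\nPer-tag fits:\n")
  print(x$per_tag, digits = 4)
  cat("\nZero-total cells excluded:", x$n_excluded, "\n")
  invisible(x)
}

#' Extract GLM coefficients from a demultiplexing fit
#'
#' @param object A `demux_fit`.
#' @param ... Unused.
#' @return Tags x 6 matrix of `beta0`/`beta1`/`theta` for the negative- and
#'   positive-space models (NA rows for unfit tags).
#' @export
coef.demux_fit <- function(object, ...) {
  out <- t(vapply(object$tag_fits, function(tf) {
    if (tf$unfit) return(rep(NA_real_, 6))
    c(coef(tf$fit_neg), coef(tf$fit_pos))
  }, numeric(6)))
  colnames(out) <- c("beta0_neg", "beta1_neg", "theta_neg",
                     "beta0_pos", "beta1_pos", "theta_pos")
  out
}

#' Posterior probabilities or calls for new (or fitted) data
#'
#' Applies the fitted per-tag models and final priors in a single E step
#' (with the converged-density floor) to compute posterior probabilities,
#' either for the training matrix or for a new matrix with the same tags.
#'
#' @param object A `demux_fit`.
#' @param newdata Optional cells x tags count matrix with the same tag
#'   names; defaults to the training matrix.
#' @param type `"posterior"` for the probability matrix, `"call"` for final
#'   labels.
#' @param prob_cutoff Cutoff used when `type = "call"`; defaults to the
#'   fitted value.
#' @param ... Unused.
#' @return Matrix of posteriors or character vector of calls.
#' @export
predict.demux_fit <- function(object, newdata = NULL,
                              type = c("posterior", "call"),
                              prob_cutoff = object$params$prob_cutoff, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    post <- object$posterior
  } else {
    counts <- as_tag_counts(newdata)
    tags <- colnames(object$posterior)
    if (!identical(colnames(counts), tags))
      stop("'newdata' must have the same tag columns as the fit")
    ntot <- as.numeric(Matrix::rowSums(counts))
    post <- matrix(0, nrow(counts), length(tags),
                   dimnames = list(rownames(counts), tags))
    keep <- ntot > 0
    for (k in seq_along(tags)) {
      tf <- object$tag_fits[[k]]
      if (tf$unfit) next
      priors <- tf$prior_trace[nrow(tf$prior_trace), ]
      post[keep, k] <- e_step(as.numeric(counts[keep, k]), ntot[keep],
                              tf$fit_neg, tf$fit_pos, priors,
                              iteration = max(tf$n_iter, 2L))
    }
  }
  if (type == "posterior") post else call_cells(post, prob_cutoff)
}

#' Randomized quantile residuals of a demultiplexing fit
#'
#' Computes per-cell, per-tag quantile residuals under one of the two fitted
#' model spaces. In the negative space the observed tag count is referred to
#' the negative-cell NB-GLM: true negative cells yield approximately
#' standard-normal residuals while positive cells blow up towards `+Inf`
#' (cap with [cap_infinite()] for plotting). The positive space refers
#' `N_total - X` to the positive-cell model.
#'
#' @param object A `demux_fit`.
#' @param space `"negative"` (default) or `"positive"`.
#' @param type `"mid"` for deterministic mid-quantile residuals (default) or
#'   `"randomized"` for the classical randomized form.
#' @param seed Optional seed for the randomized draw.
#' @param ... Unused.
#' @return Cells x tags matrix of residuals; zero-total cells and unfit tags
#'   are NA.
#' @export
residuals.demux_fit <- function(object, space = c("negative", "positive"),
                                type = c("mid", "randomized"),
                                seed = NULL, ...) {
  space <- match.arg(space)
  type <- match.arg(type)
  counts <- object$counts
  tags <- colnames(object$posterior)
  ntot <- object$n_total
  keep <- ntot > 0
  res <- matrix(NA_real_, nrow(counts), length(tags),
                dimnames = list(rownames(counts), tags))
  compute <- function() {
    for (k in seq_along(tags)) {
      tf <- object$tag_fits[[k]]
      if (tf$unfit) next
      x <- as.numeric(counts[keep, k])
      lt <- log(ntot[keep])
      if (space == "negative") {
        fit <- tf$fit_neg; y <- x
      } else {
        fit <- tf$fit_pos; y <- ntot[keep] - x
      }
      res[keep, k] <<- rqr(y, glm_nb_mu(fit, lt), fit$theta,
                           mid = (type == "mid"))
    }
  }
  if (!is.null(seed)) local_seed(seed, compute()) else compute()
  res
}

#' Diagnostic plot of a demultiplexing fit
#'
#' For one tag, plots the observed tag count against the total tag count on
#' log axes, coloured by posterior probability, with the fitted negative-cell
#' NB-GLM mean curve and the y = x line; optionally the Q-Q plot of the
#' (capped) negative-space residuals of predicted negative cells.
#'
#' @param x A `demux_fit`.
#' @param tag Tag name or index to plot (default first fit tag).
#' @param which `"fit"` (count space), `"qq"`, or both.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.demux_fit <- function(x, tag = NULL,
                           which = c("fit", "qq"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  tags <- colnames(x$posterior)
  if (is.null(tag)) {
    ok <- !vapply(x$tag_fits, `[[`, logical(1), "unfit")
    if (!any(ok)) stop("no fit tags to plot")
    tag <- tags[which(ok)[1]]
  }
  tf <- x$tag_fits[[tag]]
  if (tf$unfit) stop("tag '", tag, "' is unfit")
  keep <- x$n_total > 0
  xt <- as.numeric(x$counts[keep, tag])
  nt <- x$n_total[keep]
  post <- x$posterior[keep, tag]
  if ("fit" %in% which) {
    cols <- grDevices::rgb(post, 0.2, 1 - post, alpha = 0.5)
    graphics::plot(log1p(nt), log1p(xt), col = cols, pch = 16, cex = 0.4,
                   xlab = "log(1 + total tag count)",
                   ylab = paste0("log(1 + ", tag, " count)"),
                   main = paste0(tag, ": negative-space fit"), ...)
    ord <- order(nt)
    graphics::lines(log1p(nt[ord]),
                    log1p(glm_nb_mu(tf$fit_neg, log(nt[ord]))),
                    col = "steelblue", lwd = 2)
    graphics::abline(0, 1, col = "grey40")
  }
  if ("qq" %in% which) {
    r <- stats::residuals(x, space = "negative", type = "mid")[keep, tag]
    r <- r[x$calls[keep] != tag]
    r <- cap_infinite(r[is.finite(r) | is.infinite(r)])
    qq <- qq_points(as.numeric(r))
    graphics::plot(qq$theoretical, qq$sample, pch = 16, cex = 0.4,
                   xlab = "standard normal quantiles",
                   ylab = "quantile residuals",
                   main = paste0(tag, ": Q-Q, predicted negatives"))
    graphics::abline(0, 1, col = "grey40")
  }
  invisible(x)
}
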