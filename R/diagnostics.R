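#' Randomized quantile residuals for NB counts
#'
#' Maps each count to a standard-normal quantile through the fitted NB
#' distribution function: `r_i = qnorm(u_i)` with `u_i` drawn uniformly from
#' the interval `(F(y_i - 1), F(y_i)]` (and `F(-1) = 0`). Under a correctly
#' specified model the residuals are standard normal. The deterministic
#' mid-quantile mode replaces the draw by the interval midpoint, which
#' removes randomization noise and is preferred for formal normality tests.
#'
#' @param y Non-negative integer counts.
#' @param mu Fitted NB mean(s), recycled against `y`.
#' @param theta NB overdispersion.
#' @param mid If `TRUE`, use the interval midpoint instead of a random draw.
#' @return Numeric vector of residuals; `+Inf` where `F(y)` is numerically 1
#'   (cap with [cap_infinite()] if needed).
#' @export
rqr <- function(y, mu, theta, mid = FALSE) {
  check_counts(y)
  f_lo <- nb_cdf(y - 1, mu, theta)
  f_hi <- nb_cdf(y, mu, theta)
  u <- if (mid) (f_lo + f_hi) / 2
       else f_lo + stats::runif(length(y)) * (f_hi - f_lo)
  stats::qnorm(u)
}

#' Cap infinite quantile residuals
#'
#' Replaces `+Inf` residuals by the maximum finite residual plus 1 (a
#' plotting convention for cells whose counts sit entirely above the fitted
#' model's numerical support). The original values are preserved in the
#' `"original"` attribute and `"cap_applied"` records whether any value was
#' replaced.
#'
#' @param residuals Numeric vector with at least one finite value.
#' @return The capped vector, with attributes `cap_applied` and `original`.
#' @export
cap_infinite <- function(residuals) {
  fin <- is.finite(residuals)
  if (!any(fin)) stop("all residuals are infinite; nothing to cap to")
  capped <- residuals
  inf_hi <- is.infinite(residuals) & residuals > 0
  capped[inf_hi] <- max(residuals[fin]) + 1
  structure(capped, cap_applied = any(inf_hi), original = residuals)
}

#' Q-Q plot coordinates against the standard normal
#'
#' @param residuals Finite residuals (cap infinities first).
#' @return List with `theoretical` (normal quantiles at `(k - 0.5)/n`) and
#'   `sample` (sorted residuals).
#' @export
qq_points <- function(residuals) {
  residuals <- as.numeric(residuals)
  n <- length(residuals)
  if (n == 0) stop("no residuals")
  if (any(!is.finite(residuals)))
    stop("residuals must be finite; apply cap_infinite() first")
  list(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
       sample = sort(residuals))
}

#' Evaluate demultiplexing calls against ground truth
#'
#' Per-tag one-vs-rest precision, recall and F-score over singlet calls: for
#' tag T, a true positive is a true singlet of T called T; a false positive
#' is any other cell called T; a false negative is a true singlet of T
#' called anything else (including multiplet or negative). Multiplets do not
#' enter the per-tag scores; their recovery is summarized separately.
#' Undefined ratios (zero denominators) are reported as 0 and flagged.
#'
#' @param truth Character vector of true labels: a tag name, `"multiplet"`,
#'   or `"negative"`.
#' @param calls Character vector of predicted labels, same length and order.
#' @param tags Optional tag vocabulary; defaults to all singlet labels seen
#'   in `truth` or `calls`.
#' @return A `demux_eval` object: data frame `per_tag` (precision, recall,
#'   f_score, support, flags), `macro` averages, overall `singlet_recall`
#'   and `singlet_precision`, `doublet_recall`, and a `confusion` table.
#' @export
evaluate_demux <- function(truth, calls, tags = NULL) {
  if (length(truth) != length(calls))
    stop("'truth' and 'calls' must have the same length")
  truth <- as.character(truth); calls <- as.character(calls)
  special <- c("multiplet", "negative")
  if (is.null(tags))
    tags <- sort(setdiff(union(truth, calls), special))
  per_tag <- do.call(rbind, lapply(tags, function(t) {
    tp <- sum(truth == t & calls == t)
    fp <- sum(truth != t & calls == t)
    fn <- sum(truth == t & calls != t)
    p_und <- (tp + fp) == 0
    r_und <- (tp + fn) == 0
    p <- if (p_und) 0 else tp / (tp + fp)
    r <- if (r_und) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(tag = t, precision = p, recall = r, f_score = f,
               support = tp + fn, undefined = p_und || r_und)
  }))
  is_true_singlet <- truth %in% tags
  singlet_recall <- if (any(is_true_singlet))
    mean(calls[is_true_singlet] == truth[is_true_singlet]) else NA_real_
  called_singlet <- calls %in% tags
  singlet_precision <- if (any(called_singlet))
    mean(calls[called_singlet] == truth[called_singlet]) else NA_real_
  doublet_recall <- if (any(truth == "multiplet"))
    mean(calls[truth == "multiplet"] == "multiplet") else NA_real_
  lv <- c(tags, special)
  confusion <- table(truth = factor(truth, levels = lv),
                     call = factor(calls, levels = lv))
  structure(list(per_tag = per_tag,
                 macro = c(precision = mean(per_tag$precision),
                           recall = mean(per_tag$recall),
                           f_score = mean(per_tag$f_score)),
                 singlet_recall = singlet_recall,
                 singlet_precision = singlet_precision,
                 doublet_recall = doublet_recall,
                 confusion = confusion),
            class = "demux_eval")
}

#' @export
print.demux_eval <- function(x, ...) {
  cat("Demultiplexing evaluation\n")
  cat(sprintf("  macro precision %.4f, recall %.4f, F-score %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f_score"]))
  cat(sprintf("  overall singlet recall %.4f, precision %.4f\n",
              x$singlet_recall, x$singlet_precision))
  if (!is.na(x$doublet_recall))
    cat(sprintf("  doublet recall %.4f\n", x$doublet_recall))
  cat(sprintf("  %d tags scored (worst F-score %.4f)\n",
              nrow(x$per_tag), min(x$per_tag$f_score)))
  invisible(x)
}
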