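#' Negative binomial log probability mass
#'
#' Log density of the negative binomial distribution in the mean/overdispersion
#' parameterization used throughout the package: mean `mu`, dispersion `theta`,
#' variance `mu + mu^2 / theta`.
#'
#' @param y Vector of non-negative integer counts.
#' @param mu Positive mean(s), recycled against `y`.
#' @param theta Positive overdispersion parameter (scalar).
#' @return Vector of finite log-probabilities, one per element of `y`.
#' @examples
#' nb_log_pmf(0, mu = 2, theta = 1)  # log(1/3)
#' @export
nb_log_pmf <- function(y, mu, theta) {
  check_counts(y)
  if (any(mu <= 0) || !is.finite(theta) || theta <= 0)
    stop("'mu' and 'theta' must be positive")
  stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
}

#' Negative binomial cumulative distribution function
#'
#' @param y Integer quantile(s); values below 0 give probability 0.
#' @param mu Positive mean(s).
#' @param theta Positive overdispersion parameter.
#' @return `P(Y <= y)` under NB(`mu`, `theta`).
#' @export
nb_cdf <- function(y, mu, theta) {
  if (any(mu <= 0) || !is.finite(theta) || theta <= 0)
    stop("'mu' and 'theta' must be positive")
  stats::pnbinom(y, size = theta, mu = mu)
}

check_counts <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0) ||
      any(abs(y - round(y)) > 1e-8))
    stop("'y' must be non-negative integers")
  invisible(TRUE)
}

THETA_MIN <- 1e-3
THETA_MAX <- 1e5

#' Fit a negative binomial GLM of counts on log total tag count
#'
#' Fits `ln(mu) = beta0 + beta1 * log_total` with NB errors by maximum
#' likelihood (via [MASS::glm.nb]). This is the workhorse behind both model
#' spaces of the classifier: the negative-cell space (observed tag count vs
#' `ln(N_total)`) and the positive-cell space (total contamination
#' `N_total - X` vs `ln(N_total)`).
#'
#' Degenerate inputs are handled without failing: a constant covariate drops
#' the slope and flags the fit; an all-zero response returns a floor fit with
#' a tiny mean (used by the EM driver for perfectly clean tags); and
#' non-convergence returns the best iterate with `converged = FALSE`. The
#' dispersion estimate is clamped to `[1e-3, 1e5]`; hitting a bound also
#' clears the convergence flag.
#'
#' @param y Non-negative integer response counts.
#' @param log_total Covariate, the natural log of per-cell total tag counts.
#' @param slope If `FALSE`, fit intercept-only.
#' @param space Label carried on the fit, `"negative"` or `"positive"`.
#' @param min_obs Minimum number of observations required (default 20; the
#'   EM driver enforces its own per-class minimum before calling this).
#' @return An object of class `glm_nb_fit`: list with elements `beta0`,
#'   `beta1`, `theta`, `space`, `converged`, `degenerate`, `n_obs`.
#' @export
fit_glm_nb <- function(y, log_total, slope = TRUE,
                       space = c("negative", "positive"), min_obs = 20L) {
  space <- match.arg(space)
  check_counts(y)
  if (length(y) != length(log_total))
    stop("'y' and 'log_total' must have the same length")
  if (length(y) < min_obs)
    stop("need at least ", min_obs, " observations, got ", length(y))
  if (any(!is.finite(log_total)))
    stop("'log_total' must be finite")

  if (all(y == 0)) {
    # perfectly clean class: no likelihood information on theta or slope;
    # floor mean keeps downstream densities well defined
    return(new_glm_nb_fit(beta0 = log(1e-2), beta1 = 0, theta = 100,
                          space = space, converged = TRUE,
                          degenerate = "all_zero", n_obs = length(y)))
  }

  degenerate <- "none"
  if (slope && diff(range(log_total)) < 1e-10) {
    slope <- FALSE
    degenerate <- "constant_covariate"
  }

  fml <- if (slope) y ~ lt else y ~ 1
  dat <- data.frame(y = as.numeric(y), lt = as.numeric(log_total))
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(MASS::glm.nb(fml, data = dat),
             error = function(e) NULL),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })

  if (is.null(fit)) {
    # fall back to Poisson point estimate for the mean plus ML theta
    pfit <- stats::glm(fml, family = stats::poisson(), data = dat)
    th <- tryCatch(
      suppressWarnings(MASS::theta.ml(dat$y, stats::fitted(pfit),
                                      limit = 25)),
      error = function(e) THETA_MAX)
    cf <- stats::coef(pfit)
    return(new_glm_nb_fit(
      beta0 = unname(cf[1]),
      beta1 = if (slope) unname(cf[2]) else 0,
      theta = clamp_theta(as.numeric(th)),
      space = space, converged = FALSE, degenerate = degenerate,
      n_obs = length(y)))
  }

  cf <- stats::coef(fit)
  theta <- clamp_theta(fit$theta)
  if (theta != fit$theta) converged <- FALSE
  new_glm_nb_fit(beta0 = unname(cf[1]),
                 beta1 = if (slope) unname(cf[2]) else 0,
                 theta = theta, space = space,
                 converged = converged && isTRUE(fit$converged),
                 degenerate = degenerate, n_obs = length(y))
}

clamp_theta <- function(theta) min(max(theta, THETA_MIN), THETA_MAX)

new_glm_nb_fit <- function(beta0, beta1, theta, space, converged,
                           degenerate, n_obs) {
  structure(list(beta0 = beta0, beta1 = beta1, theta = theta,
                 space = space, converged = converged,
                 degenerate = degenerate, n_obs = n_obs),
            class = "glm_nb_fit")
}

#' @export
print.glm_nb_fit <- function(x, ...) {
  cat(sprintf(
    "NB-GLM fit (%s space): beta0 = %.4f, beta1 = %.4f, theta = %.4g\n",
    x$space, x$beta0, x$beta1, x$theta))
  cat(sprintf("  n = %d, converged = %s%s\n", x$n_obs, x$converged,
              if (x$degenerate != "none")
                paste0(", degenerate = ", x$degenerate) else ""))
  invisible(x)
}

# Fitted NB mean at given log total counts.
glm_nb_mu <- function(fit, log_total) {
  exp(fit$beta0 + fit$beta1 * log_total)
}

#' @export
coef.glm_nb_fit <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1, theta = object$theta)
}

#' NB-GLM log-likelihood
#'
#' Log-likelihood of counts `y` at covariate `log_total` under a fitted or
#' hypothesized parameter triple. Used by tests to verify local optimality.
#'
#' @param y Counts; `log_total` covariate as in [fit_glm_nb()].
#' @param beta0,beta1,theta Parameters of the NB-GLM.
#' @return Scalar log-likelihood.
#' @export
glm_nb_loglik <- function(y, log_total, beta0, beta1, theta) {
  mu <- exp(beta0 + beta1 * log_total)
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}
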