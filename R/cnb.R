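#' Continuous negative binomial density
#'
#' Density of the continuous negative binomial distribution,
#' \deqn{f(k, r, p) = \frac{\Gamma(k+r)}{\Gamma(k+1)\,\Gamma(r)}
#'   p^k (1-p)^r,}
#' the gamma-function continuation of the discrete negative binomial
#' probability mass function to real-valued \eqn{k \ge 0}. Under this
#' parameterization the mean is \eqn{r p/(1-p)} and the variance
#' \eqn{r p/(1-p)^2}. Evaluation is in log-space, so large `k` and `r`
#' neither overflow nor underflow.
#'
#' @param k Non-negative real value(s).
#' @param r Dispersion (size) parameter, `> 0`.
#' @param p Probability parameter in `(0, 1)`.
#' @param log Return the log density.
#' @return Density value(s).
#' @export
cnb_density <- function(k, r, p, log = FALSE) {
  if (any(!is.finite(k)) || any(k < 0))
    stop_nbloop("domain", "k must be finite and >= 0")
  if (any(r <= 0) || any(!is.finite(r)))
    stop_nbloop("domain", "r must be finite and > 0")
  if (any(p <= 0) || any(p >= 1))
    stop_nbloop("domain", "p must be in (0, 1)")
  lf <- lgamma(k + r) - lgamma(k + 1) - lgamma(r) + k * log(p) + r * log1p(-p)
  if (log) lf else exp(lf)
}

# Right-tail survival of the continuous negative binomial: the regularized
# incomplete beta continuation of the discrete tail,
#   S(m) = P(X >= m) = I_p(m, r) = pbeta(p, m, r),
# which at integer m equals the discrete tail sum sum_{x >= m} f(x) exactly
# and decreases continuously and monotonically in m, with S(0+) -> 1.
cnb_survival <- function(m, r, p) {
  out <- rep(1, length(m))
  pos <- m > 0
  if (any(pos)) out[pos] <- stats::pbeta(p, m[pos], r)
  out
}

#' Right-tail p-value under a fitted continuous negative binomial
#'
#' For an observed/expected value `m_star > 0` returns the right-tail
#' probability \eqn{P(X \ge m^*)} under the continuous negative binomial
#' model of its genomic distance; a zero observed/expected value has
#' p-value exactly 1. The result lies in `[0, 1]` and is non-increasing in
#' `m_star`.
#'
#' @param m_star Non-negative observed/expected value(s).
#' @param model A `distance_model` (see [fit_distance_model()]) with
#'   `fit_ok = TRUE`, or any list with elements `r` and `p`.
#' @return p-value(s).
#' @export
cnb_pvalue <- function(m_star, model) {
  if (any(!is.finite(m_star)) || any(m_star < 0))
    stop_nbloop("domain", "m_star must be finite and >= 0")
  if (!is.null(model$fit_ok) && !isTRUE(model$fit_ok))
    stop_nbloop("domain", "model was not successfully fitted")
  cnb_survival(m_star, model$r, model$p)
}

#' Fit a continuous negative binomial per genomic distance
#'
#' Method-of-moments initialization (`p = 1 - mean/var`,
#' `r = mean^2/(var - mean)`), refined by numerical maximum likelihood on
#' the continuous density; if the optimizer fails, the moment estimate is
#' kept. Samples that are too small, degenerate (zero variance) or
#' underdispersed (variance `<=` mean, for which no negative binomial
#' exists) yield `fit_ok = FALSE` and the distance is skipped downstream --
#' no exception is raised.
#'
#' @param values Non-negative real values at one genomic distance.
#' @param d Genomic distance in bins (metadata only).
#' @param min_n Minimum sample size to attempt a fit.
#' @return An object of class `distance_model` with fields `d`, `r`, `p`,
#'   `n_obs`, `fit_ok`, `method`.
#' @export
fit_distance_model <- function(values, d = NA_integer_, min_n = 100) {
  values <- values[is.finite(values)]
  n <- length(values)
  bad <- function(why) structure(
    list(d = d, r = NA_real_, p = NA_real_, n_obs = n,
         fit_ok = FALSE, method = why), class = "distance_model")
  if (n < min_n) return(bad("too_few_values"))
  m <- mean(values); v <- stats::var(values)
  if (!is.finite(v) || v <= 0) return(bad("degenerate"))
  if (v <= m || m <= 0) return(bad("underdispersed"))
  p0 <- 1 - m / v
  r0 <- m^2 / (v - m)
  r <- r0; p <- p0; method <- "moments"
  nll <- function(th) {
    rr <- exp(th[1L]); pp <- stats::plogis(th[2L])
    if (!is.finite(rr) || pp <= 0 || pp >= 1) return(Inf)
    -sum(lgamma(values + rr) - lgamma(values + 1) - lgamma(rr) +
           values * log(pp) + rr * log1p(-pp))
  }
  opt <- tryCatch(
    stats::optim(c(log(r0), stats::qlogis(p0)), nll,
                 method = "Nelder-Mead", control = list(maxit = 500)),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value) &&
      opt$value <= nll(c(log(r0), stats::qlogis(p0)))) {
    r <- exp(opt$par[1L])
    p <- stats::plogis(opt$par[2L])
    method <- "mle"
  }
  if (!is.finite(r) || r <= 0 || p <= 0 || p >= 1) return(bad("degenerate"))
  structure(list(d = d, r = r, p = p, n_obs = n, fit_ok = TRUE,
                 method = method), class = "distance_model")
}

#' @export
print.distance_model <- function(x, ...) {
  if (x$fit_ok)
    cat(sprintf("<distance_model> d=%s r=%.4g p=%.4g (n=%d, %s)\n",
                format(x$d), x$r, x$p, x$n_obs, x$method))
  else
    cat(sprintf("<distance_model> d=%s not fitted (%s, n=%d)\n",
                format(x$d), x$method, x$n_obs))
  invisible(x)
}

#' Fit continuous negative binomial models for every genomic distance
#'
#' Per distance, nonzero observed/expected values below `prefit_threshold`
#' are removed (thinning the fit input to the enriched tail, mirroring the
#' candidate-gate threshold), then [fit_distance_model()] is applied.
#' Distances whose fit fails carry no model.
#'
#' @param obsexp An `obs_exp_matrix` (see [transform_obs_exp()]).
#' @param prefit_threshold Exclude values below this threshold before
#'   fitting; `0` fits all nonzero values.
#' @param min_n Minimum number of values per distance.
#' @return An object of class `model_set`: a list keyed by distance (in
#'   bins, as character) of fitted `distance_model`s.
#' @export
fit_all_distances <- function(obsexp, prefit_threshold = 1.5, min_n = 100) {
  d <- obsexp$j - obsexp$i
  keep <- obsexp$value > 0 & obsexp$value >= prefit_threshold
  sp <- split(obsexp$value[keep], d[keep])
  models <- lapply(names(sp), function(dd)
    fit_distance_model(sp[[dd]], d = as.integer(dd), min_n = min_n))
  names(models) <- names(sp)
  ok <- vapply(models, function(m) m$fit_ok, logical(1L))
  structure(models[ok], class = "model_set",
            n_attempted = length(models), n_fitted = sum(ok))
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set> %d fitted distances (of %d attempted)\n",
              length(x), attr(x, "n_attempted")))
  invisible(x)
}

#' Cameron-Trivedi overdispersion diagnostic
#'
#' Auxiliary ordinary-least-squares test for overdispersion in count data:
#' with sample mean \eqn{\hat m}, the statistic regresses
#' \eqn{(x - \hat m)^2 - x} on \eqn{\hat m} without intercept and flags
#' overdispersion when the one-sided t-statistic exceeds the critical value
#' at level `alpha`. Constant input returns statistic 0 and no flag, by
#' convention.
#'
#' @param raw_values At least 30 counts.
#' @param alpha One-sided significance level.
#' @return A list with `statistic` (t value), `overdispersed` (flag) and
#'   `alpha`.
#' @export
overdispersion_diagnostic <- function(raw_values, alpha = 0.05) {
  x <- raw_values[is.finite(raw_values)]
  n <- length(x)
  if (n < 30) stop_nbloop("domain", "need at least 30 counts")
  m <- mean(x)
  if (stats::var(x) == 0 || m == 0)
    return(list(statistic = 0, overdispersed = FALSE, alpha = alpha))
  z <- (x - m)^2 - x
  # no-intercept OLS of z on the constant regressor m
  bhat <- sum(z * m) / (n * m^2)
  resid <- z - bhat * m
  se <- sqrt(sum(resid^2) / (n - 1) / (n * m^2))
  tstat <- bhat / se
  list(statistic = tstat,
       overdispersed = tstat > stats::qt(1 - alpha, df = n - 1),
       alpha = alpha)
}
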