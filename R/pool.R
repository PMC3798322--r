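#' DerSimonian-Laird random-effects pooling of per-study estimates
#'
#' Inverse-variance pooling with the method-of-moments (DerSimonian-Laird)
#' estimator of the between-study variance.  This is the single pooling
#' engine behind both [pool_dl()] (log-hazard ratios from per-cohort Cox
#' fits) and [pool_corr()] (Fisher-z transformed Pearson correlations), so
#' the two meta-analytic arms of the pipeline share identical algebra.
#'
#' With per-study estimates \eqn{y_k} and variances \eqn{v_k}:
#' fixed-effect weights \eqn{w_k = 1/v_k} give
#' \eqn{\bar y_F = \sum w_k y_k / \sum w_k} and Cochran's
#' \eqn{Q = \sum w_k (y_k - \bar y_F)^2}; the between-study variance is
#' \eqn{\tau^2 = \max(0, (Q - (K-1)) / (\sum w_k - \sum w_k^2 / \sum w_k))};
#' random-effects weights \eqn{w^*_k = 1/(v_k + \tau^2)} give the pooled
#' estimate \eqn{\hat y = \sum w^*_k y_k / \sum w^*_k} with standard error
#' \eqn{(\sum w^*_k)^{-1/2}}.  The combined p-value is the two-sided Wald
#' p of the pooled estimate.  A single study passes through unchanged with
#' \eqn{\tau^2 = 0}.
#'
#' @param y numeric vector of per-study estimates (length K >= 1).
#' @param v numeric vector of per-study variances, all > 0.
#' @return A list with elements `est` (pooled estimate), `se`, `tau2`,
#'   `q_stat`, `p` (two-sided Wald p of est/se) and `k` (number of
#'   studies pooled).
#' @examples
#' dl_pool(c(0, 1), c(0.01, 0.01))   # Q = 50, tau2 = 0.49, est = 0.5
#' @export
dl_pool <- function(y, v) {
  stopifnot(is.numeric(y), is.numeric(v), length(y) == length(v))
  if (length(y) == 0L)
    stop("dl_pool() needs at least one study", call. = FALSE)
  if (anyNA(y) || anyNA(v))
    stop("dl_pool() does not accept missing estimates or variances",
         call. = FALSE)
  if (any(v <= 0))
    stop("all study variances must be strictly positive", call. = FALSE)

  k <- length(y)
  w <- 1 / v
  sw <- sum(w)
  y_fixed <- sum(w * y) / sw
  q_stat <- sum(w * (y - y_fixed)^2)

  if (k == 1L) {
    tau2 <- 0
    est <- y
    se <- sqrt(v)
  } else {
    denom <- sw - sum(w^2) / sw
    tau2 <- max(0, (q_stat - (k - 1)) / denom)
    w_star <- 1 / (v + tau2)
    est <- sum(w_star * y) / sum(w_star)
    se <- sqrt(1 / sum(w_star))
  }

  list(est = unname(est), se = unname(se), tau2 = tau2,
       q_stat = q_stat, p = 2 * stats::pnorm(-abs(est / se)), k = k)
}
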