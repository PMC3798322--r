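#' Per-cohort Cox screen of a single gene
#'
#' Fits a univariate Cox proportional-hazards model of the cohort's
#' survival endpoint on the gene's expression, standardized to unit SD
#' within the cohort so that the log-hazard ratio is per 1 SD of
#' expression and comparable across platforms.  Ties are handled with the
#' Efron approximation.  Samples with missing expression are dropped
#' listwise.  Degenerate inputs (constant expression, too few events,
#' non-convergence) yield a result flagged `usable = FALSE` rather than an
#' error, so a whole-locus screen can skip them.
#'
#' @param bundle a [cohort_bundle].
#' @param gene gene identifier (must be a rowname of the expression
#'   matrix).
#' @param min_events minimum number of events required (default 10).
#' @return one-row data.frame: `cohort_id`, `gene`, `beta` (log-HR per
#'   SD), `se`, `wald_z`, `p` (two-sided), `n`, `events`, `usable`.
#' @export
cox_per_gene <- function(bundle, gene, min_events = 10) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!gene %in% rownames(bundle$expression))
    stop("gene '", gene, "' not measured in cohort ", bundle$cohort_id,
         call. = FALSE)
  x <- bundle$expression[gene, ]
  fit <- cox_fit_fast(x, bundle$clinical$time, bundle$clinical$event,
                      min_events = min_events)
  data.frame(cohort_id = bundle$cohort_id, gene = gene,
             beta = fit$beta, se = fit$se, wald_z = fit$z, p = fit$p,
             n = fit$n, events = fit$events, usable = fit$usable,
             stringsAsFactors = FALSE)
}

# Minimal fast path around survival's Cox fitter: listwise-complete cases,
# unit-SD standardization, Efron ties, Wald inference.  Returns a flagged
# non-result instead of erroring on degenerate input.
cox_fit_fast <- function(x, time, event, min_events = 10) {
  bad <- list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
              n = sum(!is.na(x)), events = sum(event[!is.na(x)]),
              usable = FALSE)
  ok <- !is.na(x) & !is.na(time) & !is.na(event)
  x <- x[ok]; time <- time[ok]; event <- event[ok]
  n <- length(x); events <- sum(event)
  bad$n <- n; bad$events <- events
  s <- stats::sd(x)
  if (n < 3 || events < min_events || !is.finite(s) || s == 0) return(bad)
  z <- (x - mean(x)) / s
  fit <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      matrix(z, ncol = 1), survival::Surv(time, event),
      strata = NULL, offset = NULL, init = 0,
      control = survival::coxph.control(), weights = NULL,
      method = "efron", rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  beta <- unname(fit$coefficients[1])
  se <- sqrt(fit$var[1, 1])
  if (!is.finite(beta) || !is.finite(se) || se <= 0) return(bad)
  wz <- beta / se
  list(beta = beta, se = se, z = wz,
       p = 2 * stats::pnorm(-abs(wz)), n = n, events = events,
       usable = TRUE)
}

#' Pool per-cohort Cox results for one gene
#'
#' DerSimonian-Laird random-effects pooling of per-cohort log-hazard
#' ratios (see [dl_pool()] for the algebra).  Unusable cohort results are
#' excluded before pooling.
#'
#' @param results data.frame of per-cohort rows as returned by
#'   [cox_per_gene()], all for the same gene.
#' @return one-row data.frame: `gene`, `beta_re` (pooled log-HR), `se_re`,
#'   `hr = exp(beta_re)`, `tau2`, `q_stat`, `p_combined`, `k`.
#' @export
pool_dl <- function(results) {
  stopifnot(is.data.frame(results))
  if ("usable" %in% names(results)) results <- results[results$usable, ]
  if (nrow(results) == 0)
    stop("no usable per-cohort results to pool", call. = FALSE)
  gene <- unique(results$gene)
  if (length(gene) > 1)
    stop("pool_dl() pools one gene at a time", call. = FALSE)
  pooled <- dl_pool(results$beta, results$se^2)
  data.frame(gene = if (length(gene)) gene else NA_character_,
             beta_re = pooled$est, se_re = pooled$se,
             hr = exp(pooled$est), tau2 = pooled$tau2,
             q_stat = pooled$q_stat, p_combined = pooled$p,
             k = pooled$k, stringsAsFactors = FALSE)
}

#' Filter policy for the multi-cohort consistency cascade
#'
#' A gene passes the screen when it reaches per-cohort significance
#' `p < alpha_cohort` in at least `min_sig_cohorts` cohorts AND its pooled
#' (random-effects) p-value is below `alpha_combined`.  Genes measured in
#' fewer than `min_measured_cohorts` cohorts are reported but can never
#' pass.  Defaults are the stringent cascade used for locus-wide screens:
#' p < 0.005 in >= 3 cohorts, combined p < 0.005.
#'
#' @param alpha_cohort per-cohort Wald p threshold.
#' @param min_sig_cohorts minimum cohorts individually significant.
#' @param alpha_combined threshold on the pooled p.
#' @param min_measured_cohorts minimum cohorts where the gene is measured.
#' @return object of class `filter_policy`.
#' @export
filter_policy <- function(alpha_cohort = 0.005, min_sig_cohorts = 3,
                          alpha_combined = 0.005,
                          min_measured_cohorts = 3) {
  stopifnot(alpha_cohort > 0, alpha_cohort < 1,
            alpha_combined > 0, alpha_combined < 1,
            min_sig_cohorts >= 1, min_measured_cohorts >= 1)
  structure(list(alpha_cohort = alpha_cohort,
                 min_sig_cohorts = as.integer(min_sig_cohorts),
                 alpha_combined = alpha_combined,
                 min_measured_cohorts = as.integer(min_measured_cohorts)),
            class = "filter_policy")
}

#' Apply the consistency cascade to per-cohort Cox results
#'
#' Pools each gene's usable per-cohort results and applies the
#' [filter_policy()] cascade.  Exposed separately from [screen_locus()] so
#' that precomputed (or externally supplied) per-cohort results can be
#' screened directly.
#'
#' @param cox_results data.frame of [cox_per_gene()] rows covering one or
#'   more genes.
#' @param policy a [filter_policy()].
#' @return data.frame with one row per gene: pooled columns from
#'   [pool_dl()] plus `n_sig_cohorts` and `passes`, sorted by `p_combined`
#'   ascending.  The full table is retained, not only passers.
#' @export
screen_from_results <- function(cox_results, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  usable <- cox_results[cox_results$usable, , drop = FALSE]
  if (nrow(usable) == 0) stop("no usable results", call. = FALSE)
  parts <- split(usable, usable$gene)
  rows <- lapply(parts, function(d) {
    out <- pool_dl(d)
    out$n_sig_cohorts <- sum(d$p < policy$alpha_cohort)
    out$passes <- out$k >= policy$min_measured_cohorts &&
      out$n_sig_cohorts >= policy$min_sig_cohorts &&
      out$p_combined < policy$alpha_combined
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$p_combined), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Screen a locus gene set across cohorts
#'
#' Runs the per-gene Cox screen ([cox_per_gene()]) in every cohort where
#' the gene is measured, pools the per-cohort log-hazard ratios with the
#' DerSimonian-Laird estimator, and applies the consistency cascade.
#'
#' @param bundles list of [cohort_bundle]s.
#' @param gene_universe character vector of genes to screen (e.g. the
#'   locus gene set from [restrict_to_locus()]).
#' @param policy a [filter_policy()].
#' @param min_events forwarded to [cox_per_gene()].
#' @return the [screen_from_results()] table.
#' @export
screen_locus <- function(bundles, gene_universe, policy = filter_policy(),
                         min_events = 10) {
  stopifnot(length(gene_universe) > 0)
  if (length(bundles) < policy$min_measured_cohorts)
    stop("need at least ", policy$min_measured_cohorts, " cohorts",
         call. = FALSE)
  res <- vector("list", length(bundles))
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    genes <- intersect(gene_universe, rownames(b$expression))
    time <- b$clinical$time; event <- b$clinical$event
    rows <- lapply(genes, function(g) {
      fit <- cox_fit_fast(b$expression[g, ], time, event,
                          min_events = min_events)
      data.frame(cohort_id = b$cohort_id, gene = g, beta = fit$beta,
                 se = fit$se, wald_z = fit$z, p = fit$p, n = fit$n,
                 events = fit$events, usable = fit$usable,
                 stringsAsFactors = FALSE)
    })
    res[[i]] <- do.call(rbind, rows)
  }
  screen_from_results(do.call(rbind, res), policy)
}

#' Kaplan-Meier stratification at the median
#'
#' Splits samples into marker-high and marker-low at the median of a
#' per-sample score (ties at the median go to the low group), estimates
#' Kaplan-Meier curves per arm, and tests the split with a two-sided
#' log-rank test.
#'
#' @param bundle a [cohort_bundle], or a data.frame with columns `time`
#'   and `event`.
#' @param score numeric per-sample score, same order as the samples.
#' @param min_per_arm minimum samples required in each arm.
#' @return list: `fit` (a [survival::survfit] object over both arms),
#'   `group` (factor "low"/"high"), `chisq` (log-rank statistic), `p`
#'   (two-sided log-rank p).
#' @export
km_stratify <- function(bundle, score, min_per_arm = 10) {
  clin <- if (inherits(bundle, "cohort_bundle")) bundle$clinical else bundle
  stopifnot(length(score) == nrow(clin))
  group <- factor(ifelse(score > stats::median(score), "high", "low"),
                  levels = c("low", "high"))
  if (min(table(group)) < min_per_arm)
    stop("degenerate median split: fewer than ", min_per_arm,
         " samples in one arm", call. = FALSE)
  sv <- survival::Surv(clin$time, clin$event)
  sd_fit <- survival::survdiff(sv ~ group)
  list(fit = survival::survfit(sv ~ group),
       group = group,
       chisq = sd_fit$chisq,
       p = stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate and multivariate Cox models with clinical covariates
#'
#' Tests a median-split marker (e.g. seed-gene or module expression)
#' against / alongside standard clinical covariates.  Univariate mode fits
#' one model per variable; multivariate mode fits one joint model.
#' Constant (or otherwise degenerate) covariates are dropped with a
#' warning.  Grade enters as an ordered numeric (1-3); ER and nodal
#' status as factors.
#'
#' @param bundle a [cohort_bundle].
#' @param score numeric per-sample score; dichotomized at its median
#'   (ties low) into the `marker` term.
#' @param covariates subset of `c("age", "size", "grade", "er", "node")`.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param min_events minimum number of events.
#' @return data.frame: `term`, `beta`, `hr`, `lower95`, `upper95`, `p`,
#'   `mode`.
#' @export
cox_covariates <- function(bundle, score,
                           covariates = c("age", "size", "grade", "er",
                                          "node"),
                           mode = c("univariate", "multivariate"),
                           min_events = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(bundle, "cohort_bundle"))
  clin <- bundle$clinical
  covariates <- match.arg(covariates, several.ok = TRUE)
  missing_cov <- setdiff(covariates, names(clin))
  if (length(missing_cov))
    stop("covariate(s) absent from clinical table: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  if (sum(clin$event) < min_events)
    stop("fewer than ", min_events, " events", call. = FALSE)

  dat <- data.frame(
    time = clin$time, event = clin$event,
    marker = factor(ifelse(score > stats::median(score), "high", "low"),
                    levels = c("low", "high")))
  for (cv in covariates) {
    v <- clin[[cv]]
    if (cv %in% c("er", "node")) v <- factor(v)
    dat[[cv]] <- v
  }

  terms_all <- c("marker", covariates)
  keep <- vapply(terms_all, function(tm) {
    v <- dat[[tm]]
    n_distinct <- length(unique(v[!is.na(v)]))
    if (n_distinct < 2) {
      warning("covariate '", tm, "' is constant; dropped", call. = FALSE)
      FALSE
    } else TRUE
  }, logical(1))
  terms_all <- terms_all[keep]
  if (!length(terms_all)) stop("no usable model terms", call. = FALSE)

  extract <- function(fit, mode) {
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               beta = s$coefficients[, "coef"],
               hr = s$conf.int[, "exp(coef)"],
               lower95 = s$conf.int[, "lower .95"],
               upper95 = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               mode = mode, row.names = NULL,
               stringsAsFactors = FALSE)
  }

  if (mode == "univariate") {
    out <- lapply(terms_all, function(tm) {
      f <- stats::as.formula(paste("survival::Surv(time, event) ~", tm))
      extract(survival::coxph(f, data = dat, ties = "efron"), "univariate")
    })
    do.call(rbind, out)
  } else {
    f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms_all, collapse = " + ")))
    extract(survival::coxph(f, data = dat, ties = "efron"), "multivariate")
  }
}
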