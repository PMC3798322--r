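sim_one <- function(seed, n = 300, beta = numeric(0), n_genes = 20,
                    loading = 0, module_size = 2, cens = 0.3) {
  simulate_cohorts(sim_config(
    n_cohorts = 1, samples_per_cohort = n, n_genes = n_genes,
    module_size = module_size, module_loading = loading,
    prognostic_genes = beta, censoring_rate = cens, seed = seed))[[1]]
}

test_that("cox_per_gene agrees with a formula-interface coxph fit", {
  b <- sim_one(101, beta = c(G0003 = 0.4))
  got <- cox_per_gene(b, "G0003")
  z <- as.vector(scale(b$expression["G0003", ]))
  ref <- survival::coxph(
    survival::Surv(b$clinical$time, b$clinical$event) ~ z, ties = "efron")
  expect_equal(got$beta, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(got$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-8)
  expect_equal(got$wald_z, got$beta / got$se)
  expect_true(got$usable)
  expect_equal(got$events, sum(b$clinical$event))
})

test_that("null gene estimates are small with uniform p over replicates", {
  b <- sim_one(202, n = 500, n_genes = 120)
  nulls <- sprintf("G%04d", 21:120)
  res <- do.call(rbind, lapply(nulls, cox_per_gene, bundle = b))
  expect_true(all(abs(res$beta) < 0.2))
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("planted log-hazard ratio is recovered on average", {
  est <- vapply(1:50, function(i) {
    b <- sim_one(3000 + i, n = 500, beta = c(G0010 = 0.5))
    cox_per_gene(b, "G0010")$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.07)
})

test_that("degenerate expression is flagged unusable, not an error", {
  b <- sim_one(55, n = 50)
  b$expression["G0002", ] <- 7.3    # constant
  res <- cox_per_gene(b, "G0002")
  expect_false(res$usable)
  expect_true(is.na(res$beta))
  few <- sim_one(56, n = 60, cens = 0)
  few$clinical$event[] <- c(rep(1, 5), rep(0, 55))  # < 10 events
  expect_false(cox_per_gene(few, "G0003")$usable)
})

test_that("the consistency cascade needs both cohort-level and pooled evidence", {
  mk <- function(gene, beta, se) {
    p <- 2 * pnorm(-abs(beta / se))
    data.frame(cohort_id = sprintf("c%d", seq_along(beta)), gene = gene,
               beta = beta, se = se, wald_z = beta / se, p = p,
               n = 200, events = 140, usable = TRUE)
  }
  # 3 of 6 cohorts individually significant, pooled estimate consistent
  strong <- mk("gA", c(0.55, 0.60, 0.50, 0.35, 0.30, 0.40),
               c(0.15, 0.15, 0.15, 0.30, 0.30, 0.30))
  # only 2 cohorts significant, everything else identical
  weak <- mk("gB", c(0.55, 0.60, 0.10, 0.35, 0.30, 0.40),
             c(0.15, 0.15, 0.15, 0.30, 0.30, 0.30))
  tab <- screen_from_results(rbind(strong, weak), filter_policy())
  expect_true(tab$passes[tab$gene == "gA"])
  expect_equal(tab$n_sig_cohorts[tab$gene == "gA"], 3)
  expect_false(tab$passes[tab$gene == "gB"])
  # pooled significance alone is not enough below min_sig_cohorts
  expect_lt(tab$p_combined[tab$gene == "gB"], 0.005)
  # table is sorted by combined p and keeps non-passers
  expect_equal(nrow(tab), 2)
  expect_true(!is.unsorted(tab$p_combined))
})

test_that("tightening any policy threshold never adds a passing gene", {
  set.seed(606)
  genes <- paste0("g", 1:40)
  res <- do.call(rbind, lapply(genes, function(g) {
    k <- sample(3:6, 1)
    beta <- rnorm(k, sample(c(0, 0.5), 1), 0.2)
    se <- runif(k, 0.08, 0.3)
    data.frame(cohort_id = paste0("c", 1:k), gene = g, beta = beta,
               se = se, wald_z = beta / se, p = 2 * pnorm(-abs(beta / se)),
               n = 150, events = 100, usable = TRUE)
  }))
  base <- filter_policy(0.01, 2, 0.01, 3)
  passers <- function(policy)
    with(screen_from_results(res, policy), gene[passes])
  p0 <- passers(base)
  expect_true(all(passers(filter_policy(0.005, 2, 0.01, 3)) %in% p0))
  expect_true(all(passers(filter_policy(0.01, 3, 0.01, 3)) %in% p0))
  expect_true(all(passers(filter_policy(0.01, 2, 0.001, 3)) %in% p0))
  expect_true(all(passers(filter_policy(0.01, 2, 0.01, 5)) %in% p0))
})

test_that("screen_locus recovers planted genes across cohorts", {
  planted <- sprintf("G%04d", 31:40)
  beta <- setNames(rep(0.6, 10), planted)
  cfg <- sim_config(n_cohorts = 6, samples_per_cohort = 300, n_genes = 60,
                    module_size = 2, module_loading = 0,
                    prognostic_genes = beta, censoring_rate = 0.3,
                    seed = 88)
  bundles <- simulate_cohorts(cfg)
  tab <- screen_locus(bundles, rownames(bundles[[1]]$expression))
  expect_gte(sum(tab$passes & tab$gene %in% planted), 8)
  # null background stays out
  expect_lte(sum(tab$passes & !tab$gene %in% planted), 1)
})

test_that("random-effects CI covers a homogeneous planted effect", {
  hits <- vapply(1:200, function(i) {
    cfg <- sim_config(n_cohorts = 3, samples_per_cohort = 120,
                      n_genes = 6, module_size = 2, module_loading = 0,
                      prognostic_genes = c(G0004 = 0.4),
                      censoring_rate = 0.3, seed = 40000 + i)
    res <- do.call(rbind, lapply(simulate_cohorts(cfg), cox_per_gene,
                                 gene = "G0004"))
    out <- pool_dl(res)
    abs(out$beta_re - 0.4) <= 1.96 * out$se_re
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("median-split stratification and the log-rank test behave", {
  # identical arms: statistic exactly 0, p = 1
  times <- rep(c(5, 10, 15, 20), 10)
  events <- rep(c(1, 0), 20)
  km <- km_stratify(data.frame(time = c(times, times),
                               event = c(events, events)),
                    rep(c(0, 1), each = 40), min_per_arm = 10)
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p, 1)
  # Kaplan-Meier closed form on three uncensored times
  fit <- survival::survfit(survival::Surv(c(1, 2, 3), c(1, 1, 1)) ~ 1)
  expect_equal(fit$surv, c(2 / 3, 1 / 3, 0))
  # ties at the median go to the low group
  sc <- c(1:12, rep(13, 5), 14:24)        # median is 13, with 5 ties
  g <- km_stratify(data.frame(time = seq_along(sc) + 1,
                              event = rep(1, length(sc))),
                   sc, min_per_arm = 5)$group
  expect_true(all(g[sc == 13] == "low"))
  expect_true(all(g[sc > 13] == "high"))
  # degenerate split rejected
  expect_error(km_stratify(data.frame(time = 1:20, event = rep(1, 20)),
                           rep(1, 20)), "degenerate")
})

test_that("a planted prognostic module separates survival at the median", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 400, n_genes = 50,
                    module_size = 10, module_loading = sqrt(0.7),
                    prognostic_genes = c(G0001 = 0.6),
                    censoring_rate = 0.3, seed = 14)
  b <- simulate_cohorts(cfg)
  ms <- module_score(b[[1]], attr(b, "truth")$module_genes)
  expect_lt(km_stratify(b[[1]], ms)$p, 0.01)
})

test_that("multivariate adjustment retains an unconfounded marker", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 350, n_genes = 30,
                    module_size = 8, module_loading = sqrt(0.7),
                    prognostic_genes = c(G0001 = 0.6),
                    censoring_rate = 0.3, grade_confounding = 0,
                    seed = 21)
  b <- simulate_cohorts(cfg)
  ms <- module_score(b[[1]], attr(b, "truth")$module_genes)
  uni <- cox_covariates(b[[1]], ms, mode = "univariate")
  expect_true("markerhigh" %in% uni$term)
  multi <- cox_covariates(b[[1]], ms, mode = "multivariate")
  expect_lt(multi$p[multi$term == "markerhigh"], 0.05)
})

test_that("a survival-independent marker gives null multivariate p", {
  p <- vapply(1:40, function(i) {
    b <- sim_one(70000 + i, n = 150, n_genes = 10)
    score <- b$expression["G0005", ]
    multi <- cox_covariates(b, score, covariates = c("age", "grade"),
                            mode = "multivariate")
    multi$p[multi$term == "markerhigh"]
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.1)
  expect_gt(mean(p), 0.3)
})

test_that("constant covariates are dropped with a warning, fit succeeds", {
  b <- sim_one(99, n = 120)
  b$clinical$grade <- 2
  score <- b$expression["G0004", ]
  expect_warning(out <- cox_covariates(b, score, mode = "multivariate"),
                 "constant")
  expect_false(any(grepl("grade", out$term)))
  expect_true("markerhigh" %in% out$term)
})
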