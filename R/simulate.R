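#' Configuration for the synthetic multi-cohort generator
#'
#' Captures the statistical design of a simulated multi-cohort breast-tumor
#' expression + survival study: K independent cohorts with heterogeneous
#' sample sizes and platform scales, a planted seed-centred co-expression
#' module driven by a shared latent factor, planted prognostic genes with
#' specified log-hazard ratios under a proportional-hazards model with
#' censoring, and a background of null genes.  Defaults emulate a
#' six-cohort design totalling 1635 tumor samples.
#'
#' @param n_cohorts number of independent cohorts (K).
#' @param samples_per_cohort integer vector of per-cohort sample counts,
#'   recycled to length `n_cohorts`; every count must be >= 10.
#' @param n_genes total genes in the simulated universe.
#' @param module_size number of genes in the planted co-expression module
#'   (the seed gene is the first module member).
#' @param module_loading latent-factor loading lambda in [0, 1); zero
#'   means no latent structure (module genes become plain noise).  Module
#'   genes are generated as `lambda * f + sqrt(1 - lambda^2) * eps` with a
#'   per-sample latent factor `f` and unit noise `eps`, so the expected
#'   pairwise correlation among module genes (seed included) is `lambda^2`.
#' @param prognostic_genes named numeric vector mapping gene name to its
#'   true log-hazard ratio per 1 SD of expression; may be empty (pure null).
#' @param censoring_rate target fraction of censored samples, in [0, 1].
#' @param baseline_hazard baseline event rate, events per month.
#' @param noise_sd per-cohort scale factor applied to the expression
#'   values (platform dynamic range), recycled to length `n_cohorts`.
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @param locus_fraction fraction of the gene universe annotated to the
#'   target chromosome arm (the module and prognostic genes are always
#'   annotated there, mirroring a locus-restricted screen).
#' @param channel per-cohort channel type, `"single"` (log2 intensities on
#'   a positive baseline) or `"dual"` (mean-centred log-ratios), recycled.
#' @param grade_confounding in [0, 1); when positive, tumor grade is
#'   generated from the latent factor plus noise so that grade confounds
#'   module expression (for multivariate-adjustment tests).  Default 0:
#'   covariates independent of expression.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohorts()]
#' @export
sim_config <- function(n_cohorts = 6,
                       samples_per_cohort = c(198, 286, 159, 345, 251, 396),
                       n_genes = 1000,
                       module_size = 30,
                       module_loading = sqrt(0.7),
                       prognostic_genes = numeric(0),
                       censoring_rate = 0.3,
                       baseline_hazard = 0.01,
                       noise_sd = 1,
                       seed = 1L,
                       locus_fraction = 0.3,
                       channel = c("single", "dual"),
                       grade_confounding = 0) {
  samples_per_cohort <- rep_len(as.integer(samples_per_cohort), n_cohorts)
  noise_sd <- rep_len(noise_sd, n_cohorts)
  channel <- rep_len(match.arg(channel, several.ok = TRUE), n_cohorts)

  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = samples_per_cohort,
              n_genes = as.integer(n_genes),
              module_size = as.integer(module_size),
              module_loading = module_loading,
              prognostic_genes = prognostic_genes,
              censoring_rate = censoring_rate,
              baseline_hazard = baseline_hazard,
              noise_sd = noise_sd,
              seed = as.integer(seed),
              locus_fraction = locus_fraction,
              channel = channel,
              grade_confounding = grade_confounding)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_cohorts < 1) stop("need at least one cohort", call. = FALSE)
    if (any(samples_per_cohort < 10))
      stop("all cohort sample counts must be >= 10", call. = FALSE)
    if (module_size >= n_genes)
      stop("module_size must be smaller than n_genes", call. = FALSE)
    if (module_size < 1) stop("module_size must be >= 1", call. = FALSE)
    if (module_loading < 0 || module_loading >= 1)
      stop("module_loading must lie in [0, 1)", call. = FALSE)
    if (censoring_rate < 0 || censoring_rate > 1)
      stop("censoring_rate must lie in [0, 1]", call. = FALSE)
    if (baseline_hazard <= 0)
      stop("baseline_hazard must be positive", call. = FALSE)
    if (any(noise_sd <= 0)) stop("noise_sd must be positive", call. = FALSE)
    if (locus_fraction <= 0 || locus_fraction > 1)
      stop("locus_fraction must lie in (0, 1]", call. = FALSE)
    if (grade_confounding < 0 || grade_confounding >= 1)
      stop("grade_confounding must lie in [0, 1)", call. = FALSE)
    if (length(prognostic_genes) &&
        is.null(names(prognostic_genes)))
      stop("prognostic_genes must be a named numeric vector", call. = FALSE)
  })
  invisible(cfg)
}

sim_gene_names <- function(n_genes) sprintf("G%04d", seq_len(n_genes))

#' Construct a per-sample cohort bundle
#'
#' The unit of data the whole pipeline operates on: one cohort's
#' genes-by-samples expression matrix plus the matching clinical table.
#'
#' @param cohort_id cohort label.
#' @param expression numeric matrix, genes in rows (unique rownames),
#'   samples in columns.
#' @param clinical data.frame with rownames = sample ids and columns
#'   `time` (months, > 0), `event` (0/1), `endpoint` ("RFS" or "OS") and
#'   optionally `age`, `size`, `grade`, `er`, `node`.
#' @param channel `"single"` or `"dual"` channel platform.
#' @return An object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(cohort_id, expression, clinical,
                          channel = c("single", "dual")) {
  channel <- match.arg(channel)
  if (is.null(rownames(expression)) || anyDuplicated(rownames(expression)))
    stop("expression rownames must be unique gene identifiers",
         call. = FALSE)
  if (is.null(colnames(expression)))
    stop("expression must have sample ids as colnames", call. = FALSE)
  if (!identical(colnames(expression), rownames(clinical)))
    stop("sample ids of expression columns and clinical rows must match ",
         "in the same order (use align_samples())", call. = FALSE)
  for (col in c("time", "event", "endpoint"))
    if (is.null(clinical[[col]]))
      stop("clinical table lacks required column '", col, "'",
           call. = FALSE)
  if (any(clinical$time <= 0))
    stop("survival times must be strictly positive", call. = FALSE)
  if (!all(clinical$event %in% c(0, 1)))
    stop("event indicator must be 0/1", call. = FALSE)
  structure(list(cohort_id = cohort_id,
                 expression = expression,
                 clinical = clinical,
                 channel = channel),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %s: %d genes x %d samples, %d events, %s endpoint, %s channel\n",
    x$cohort_id, nrow(x$expression), ncol(x$expression),
    sum(x$clinical$event), x$clinical$endpoint[1], x$channel))
  invisible(x)
}

# Solve the uniform-censoring horizon C so that with T ~ Exp(rate_i) and
# U ~ Unif(0, C) independently, P(U < T) equals the target rate:
# P(cens) = mean_i (1 - exp(-rate_i * C)) / (rate_i * C).
censoring_horizon <- function(rates, target) {
  f <- function(C) mean((1 - exp(-rates * C)) / (rates * C)) - target
  # P(cens) decreases from 1 (C -> 0) to 0 (C -> Inf)
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Simulate a multi-cohort expression + survival study
#'
#' Generates `config$n_cohorts` independent [cohort_bundle]s.  Module genes
#' (the first `module_size` genes; the first of them, by convention, is the
#' seed) load on a per-sample latent factor with loading
#' `module_loading`, so their expected pairwise correlation is
#' `module_loading^2`; all remaining genes are i.i.d. unit Gaussian noise.
#' Survival times are exponential under proportional hazards with linear
#' predictor `sum(beta_g * x_g)` over the planted prognostic genes (on the
#' unit-variance latent scale, so betas are per SD), and censoring is
#' administrative-uniform on [0, C] with C solved numerically for the
#' requested censoring rate.  Single-channel cohorts are shifted onto a
#' positive log2-intensity baseline; dual-channel cohorts stay mean-centred
#' like log-ratios.  Clinical covariates (age, tumor size, grade, ER and
#' nodal status) are drawn independently of expression unless
#' `grade_confounding > 0`.
#'
#' @param config a [sim_config()].
#' @return A list of `cohort_bundle`s with attributes `truth` (the planted
#'   design: `seed_gene`, `module_genes`, `prognostic_genes`) and `locus`
#'   (a gene-locus annotation table placing the module, the prognostic
#'   genes and a `locus_fraction` share of the universe on chromosome 1q).
#' @examples
#' cfg <- sim_config(n_cohorts = 2, samples_per_cohort = 50, n_genes = 40,
#'                   module_size = 5, seed = 7)
#' bundles <- simulate_cohorts(cfg)
#' attr(bundles, "truth")$seed_gene
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  bad <- setdiff(names(config$prognostic_genes),
                 sim_gene_names(config$n_genes))
  if (length(bad))
    stop("prognostic gene(s) not in the simulated universe: ",
         paste(bad, collapse = ", "), call. = FALSE)

  set.seed(config$seed)
  genes <- sim_gene_names(config$n_genes)
  module_genes <- genes[seq_len(config$module_size)]
  seed_gene <- module_genes[1]
  lam <- config$module_loading

  beta <- config$prognostic_genes

  # 1q annotation: module + prognostic genes always on-arm, remaining slots
  # filled from the background at random (fixed by the seed).
  n_locus <- max(ceiling(config$locus_fraction * config$n_genes),
                 length(union(module_genes, names(beta))))
  forced <- union(module_genes, names(beta))
  extra <- sample(setdiff(genes, forced), n_locus - length(forced))
  on_arm <- genes %in% c(forced, extra)
  locus <- data.frame(
    gene = genes,
    chromosome = ifelse(on_arm, "1", "2"),
    arm = ifelse(on_arm, "q", "p"),
    start = ifelse(on_arm,
                   143e6 + seq_along(genes) * 1e5,   # 1q spans ~143-249 Mb
                   1e6 + seq_along(genes) * 1e5),
    stringsAsFactors = FALSE)

  bundles <- vector("list", config$n_cohorts)
  for (k in seq_len(config$n_cohorts)) {
    n <- config$samples_per_cohort[k]
    sample_ids <- sprintf("C%02dS%04d", k, seq_len(n))

    f <- stats::rnorm(n)                               # latent factor
    x <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                dimnames = list(genes, sample_ids))
    x[module_genes, ] <- lam * rep(f, each = config$module_size) +
      sqrt(1 - lam^2) * x[module_genes, ]

    eta <- if (length(beta))
      as.vector(crossprod(x[names(beta), , drop = FALSE], beta))
    else rep(0, n)
    rate <- config$baseline_hazard * exp(eta)
    t_event <- stats::rexp(n, rate)
    if (config$censoring_rate > 0) {
      C <- censoring_horizon(rate, config$censoring_rate)
      u <- stats::runif(n, 0, C)
    } else u <- rep(Inf, n)
    time <- pmin(t_event, u)
    event <- as.integer(t_event <= u)
    time <- pmax(time, 1e-4)          # strictly positive

    if (config$grade_confounding > 0) {
      g_lat <- config$grade_confounding * f +
        sqrt(1 - config$grade_confounding^2) * stats::rnorm(n)
      grade <- cut(g_lat, breaks = stats::qnorm(c(0, 0.2, 0.65, 1)),
                   labels = FALSE)
    } else {
      grade <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.45, 0.35))
    }
    clinical <- data.frame(
      time = time,
      event = event,
      endpoint = if (k %% 2 == 1) "RFS" else "OS",
      age = round(stats::rnorm(n, 57, 11)),
      size = round(stats::rlnorm(n, log(22), 0.45)),
      grade = grade,
      er = sample(c("pos", "neg"), n, replace = TRUE, prob = c(0.7, 0.3)),
      node = sample(c("pos", "neg"), n, replace = TRUE,
                    prob = c(0.45, 0.55)),
      row.names = sample_ids,
      stringsAsFactors = FALSE)

    expr <- config$noise_sd[k] * x
    if (config$channel[k] == "single") {
      expr <- expr + 8                      # log2-intensity-like baseline
    } else {
      expr <- expr - rowMeans(expr)         # log-ratio-like, mean-centred
    }

    bundles[[k]] <- cohort_bundle(sprintf("cohort%02d", k), expr, clinical,
                                  channel = config$channel[k])
  }

  attr(bundles, "truth") <- list(seed_gene = seed_gene,
                                 module_genes = module_genes,
                                 prognostic_genes = beta)
  attr(bundles, "locus") <- locus
  bundles
}

#' Write cohort bundles as plain-text fixtures
#'
#' One expression TSV (first column `gene`) and one clinical TSV (first
#' column `sample`) per cohort plus a `manifest.tsv` naming them.  Numeric
#' values are serialized with 17 significant digits so they round-trip the
#' readers bit-identically.
#'
#' @param bundles list of [cohort_bundle]s (may be empty).
#' @param dir output directory, created if absent.
#' @return The manifest data.frame (cohort_id, expression, clinical,
#'   channel), invisibly.
#' @seealso [read_fixture()]
#' @export
write_fixture <- function(bundles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  manifest <- data.frame(cohort_id = character(0),
                         expression = character(0),
                         clinical = character(0),
                         channel = character(0),
                         stringsAsFactors = FALSE)
  for (b in bundles) {
    ef <- paste0(b$cohort_id, "_expression.tsv")
    cf <- paste0(b$cohort_id, "_clinical.tsv")
    write_expression_tsv(b$expression, file.path(dir, ef))
    clin <- cbind(sample = rownames(b$clinical), b$clinical)
    clin$time <- sprintf("%.17g", clin$time)
    utils::write.table(clin, file.path(dir, cf), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- rbind(manifest,
                      data.frame(cohort_id = b$cohort_id, expression = ef,
                                 clinical = cf, channel = b$channel,
                                 stringsAsFactors = FALSE))
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

write_expression_tsv <- function(mat, path) {
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))
  tab <- cbind(gene = rownames(mat), chr)
  colnames(tab) <- c("gene", colnames(mat))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
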