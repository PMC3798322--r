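#' Per-cohort Pearson correlations with a seed gene
#'
#' Computes the Pearson correlation between the seed gene and every other
#' gene in the cohort, on pairwise-complete observations, together with
#' the Fisher z-transform `z = atanh(r)` and its large-sample variance
#' `1/(n - 3)`.  Correlations of exactly +/-1 (e.g. a probe duplicating
#' the seed) are clamped to +/-0.999999 so z stays finite; clamped rows
#' carry `clamped = TRUE`.  Genes with fewer than 4 complete pairs are
#' omitted.
#'
#' @param bundle a [cohort_bundle].
#' @param seed seed gene identifier.
#' @return data.frame: `cohort_id`, `gene`, `r`, `n`, `z`, `var_z`,
#'   `clamped`.
#' @export
corr_with_seed <- function(bundle, seed) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  expr <- bundle$expression
  if (!seed %in% rownames(expr))
    stop("seed gene '", seed, "' not measured in cohort ",
         bundle$cohort_id, call. = FALSE)
  sv <- expr[seed, ]
  seed_sd <- stats::sd(sv, na.rm = TRUE)
  if (!is.finite(seed_sd) || seed_sd == 0)
    stop("seed gene is constant (or all-missing) in cohort ",
         bundle$cohort_id, call. = FALSE)
  others <- setdiff(rownames(expr), seed)
  mat <- expr[others, , drop = FALSE]
  r <- suppressWarnings(
    as.vector(stats::cor(t(mat), sv, use = "pairwise.complete.obs")))
  n <- as.vector((!is.na(mat)) %*% (!is.na(sv)) * 1)
  ok <- !is.na(r) & n >= 4
  r <- r[ok]; n <- n[ok]; genes <- others[ok]
  clamped <- abs(r) >= 1
  r_safe <- pmin(pmax(r, -0.999999), 0.999999)
  data.frame(cohort_id = bundle$cohort_id, gene = genes, r = r_safe,
             n = as.integer(n), z = atanh(r_safe), var_z = 1 / (n - 3),
             clamped = clamped, stringsAsFactors = FALSE)
}

#' Pool per-cohort correlations for one gene
#'
#' DerSimonian-Laird random-effects pooling on the Fisher-z scale with
#' study variances `1/(n - 3)`; the pooled correlation is
#' `tanh(z_pooled)`.  Uses the same [dl_pool()] engine as the survival
#' meta-analysis.
#'
#' @param studies data.frame of [corr_with_seed()] rows for one gene.
#' @return one-row data.frame: `gene`, `r_pooled`, `z_pooled`, `se_z`,
#'   `tau2_z`, `p_combined`, `k`.
#' @export
pool_corr <- function(studies) {
  stopifnot(is.data.frame(studies), nrow(studies) >= 1)
  gene <- unique(studies$gene)
  if (length(gene) > 1)
    stop("pool_corr() pools one gene at a time", call. = FALSE)
  if (any(studies$n < 4))
    stop("all studies need n >= 4 for var_z = 1/(n-3)", call. = FALSE)
  pooled <- dl_pool(studies$z, studies$var_z)
  data.frame(gene = gene, r_pooled = tanh(pooled$est),
             z_pooled = pooled$est, se_z = pooled$se,
             tau2_z = pooled$tau2, p_combined = pooled$p, k = pooled$k,
             stringsAsFactors = FALSE)
}

#' Derive a seed-gene co-expression module across cohorts
#'
#' Computes per-cohort Pearson correlations of every gene with the seed,
#' pools them on the Fisher-z scale with the random-effects model, and
#' declares module members at a threshold on the back-transformed pooled
#' correlation: `r_pooled >= threshold_r` (positive co-expression) with
#' `p_combined < threshold_p`.  Genes measured alongside the seed in
#' fewer than `min_cohorts` cohorts are excluded from candidacy; the seed
#' itself is never a member.
#'
#' @param bundles list of [cohort_bundle]s.
#' @param seed seed gene identifier; must be measured in at least
#'   `min_cohorts` cohorts.
#' @param threshold_r pooled-correlation cut-off (default 0.6).
#' @param threshold_p combined-p cut-off (default 0.001).
#' @param min_cohorts minimum cohorts contributing (default 3).
#' @return object of class `module_def`: list with `seed_gene`,
#'   `threshold_r`, `threshold_p`, `members` (data.frame sorted by
#'   `r_pooled` descending) and `table` (the full pooled table with an
#'   `in_module` flag).
#' @export
define_module <- function(bundles, seed, threshold_r = 0.6,
                          threshold_p = 0.001, min_cohorts = 3) {
  has_seed <- vapply(bundles, function(b)
    seed %in% rownames(b$expression), logical(1))
  if (sum(has_seed) < min_cohorts)
    stop("seed gene measured in only ", sum(has_seed),
         " cohort(s); need >= ", min_cohorts, call. = FALSE)
  studies <- do.call(rbind, lapply(bundles[has_seed], corr_with_seed,
                                   seed = seed))
  parts <- split(studies, studies$gene)
  parts <- parts[vapply(parts, nrow, integer(1)) >= min_cohorts]
  if (!length(parts))
    stop("no gene measured with the seed in >= ", min_cohorts, " cohorts",
         call. = FALSE)
  tab <- do.call(rbind, lapply(parts, pool_corr))
  tab$in_module <- tab$r_pooled >= threshold_r &
    tab$p_combined < threshold_p
  tab <- tab[order(-tab$r_pooled), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(seed_gene = seed, threshold_r = threshold_r,
                 threshold_p = threshold_p,
                 members = tab[tab$in_module, , drop = FALSE],
                 table = tab),
            class = "module_def")
}

#' @export
print.module_def <- function(x, ...) {
  cat(sprintf(
    "<module_def> seed %s: %d member(s) at r_pooled >= %g, p < %g (%d genes tested)\n",
    x$seed_gene, nrow(x$members), x$threshold_r, x$threshold_p,
    nrow(x$table)))
  invisible(x)
}

#' Per-sample module expression score
#'
#' The module score of a sample is the arithmetic mean of the module
#' genes' expression values in that sample; with `standardize = TRUE`
#' each gene is z-scored across samples first.  At least half of the
#' module genes must be measured in the cohort; missing members are
#' reported in a message.
#'
#' @param bundle a [cohort_bundle].
#' @param module a `module_def` (from [define_module()]) or a character
#'   vector of gene identifiers.
#' @param standardize average per-gene z-scores instead of raw values.
#' @return named numeric vector, one score per sample.
#' @export
module_score <- function(bundle, module, standardize = FALSE) {
  genes <- if (inherits(module, "module_def")) module$members$gene
           else as.character(module)
  if (!length(genes)) stop("empty module", call. = FALSE)
  present <- intersect(genes, rownames(bundle$expression))
  if (length(present) < length(genes) / 2)
    stop("only ", length(present), " of ", length(genes),
         " module genes measured in cohort ", bundle$cohort_id,
         " (need >= 50%)", call. = FALSE)
  if (length(present) < length(genes))
    message(length(genes) - length(present),
            " module gene(s) missing from cohort ", bundle$cohort_id)
  mat <- bundle$expression[present, , drop = FALSE]
  if (standardize) mat <- t(scale(t(mat)))
  colMeans(mat, na.rm = TRUE)
}
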