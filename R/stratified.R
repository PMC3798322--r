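#' Stratify samples by a gene's expression percentiles
#'
#' Splits a cohort into a marker-high arm (expression strictly above the
#' `high_pct` percentile) and a marker-low arm (strictly below the
#' `low_pct` percentile); the middle band is discarded.  With the default
#' cuts this contrasts the top 40% of samples against the bottom 10%.
#' Ties at a cut point fall into the discarded middle band (strict
#' inequalities).
#'
#' @param bundle a [cohort_bundle].
#' @param gene gene identifier.
#' @param high_pct upper percentile cut (default 0.60).
#' @param low_pct lower percentile cut (default 0.10).
#' @param min_per_arm minimum samples per arm (default 5).
#' @return list: `high` and `low` (character sample ids), `cuts` (the two
#'   expression cut points).
#' @export
stratify_by_gene <- function(bundle, gene, high_pct = 0.60,
                             low_pct = 0.10, min_per_arm = 5) {
  stopifnot(inherits(bundle, "cohort_bundle"), low_pct < high_pct)
  if (!gene %in% rownames(bundle$expression))
    stop("gene '", gene, "' not measured", call. = FALSE)
  x <- bundle$expression[gene, ]
  x <- x[!is.na(x)]
  hi_cut <- stats::quantile(x, high_pct, names = FALSE)
  lo_cut <- stats::quantile(x, low_pct, names = FALSE)
  high <- names(x)[x > hi_cut]
  low <- names(x)[x < lo_cut]
  if (length(high) < min_per_arm || length(low) < min_per_arm)
    stop("stratification arms too small (high ", length(high), ", low ",
         length(low), "; need >= ", min_per_arm, " each)", call. = FALSE)
  list(high = high, low = low, cuts = c(low = lo_cut, high = hi_cut))
}

# Vectorized Welch two-sample t over matrix rows.
welch_rows <- function(mh, ml) {
  n1 <- rowSums(!is.na(mh)); n2 <- rowSums(!is.na(ml))
  m1 <- rowMeans(mh, na.rm = TRUE); m2 <- rowMeans(ml, na.rm = TRUE)
  v1 <- apply(mh, 1, stats::var, na.rm = TRUE)
  v2 <- apply(ml, 1, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  data.frame(gene = rownames(mh), t_stat = t_stat, df = df, p = p,
             delta = m1 - m2, var_high = v1, var_low = v2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential expression between marker-high and marker-low arms
#'
#' Welch's two-sample t-test per gene (high minus low), keeping genes
#' with `p < alpha` and `|delta| >= min_delta`, sorted by |t| descending.
#' Genes with zero variance in both arms are untestable and are skipped
#' with a message.  An optional Benjamini-Hochberg adjustment can be
#' switched on; it is off by default so the raw-p query-building
#' behaviour is the primary path.
#'
#' @param bundle a [cohort_bundle].
#' @param high,low character sample ids from [stratify_by_gene()].
#' @param alpha p-value threshold (default 0.05).
#' @param min_delta minimum |mean difference| in log2 units (default 0).
#' @param adjust apply BH-FDR to the p-values before filtering.
#' @return data.frame: `gene`, `t_stat`, `df`, `p` (plus `p_adj` when
#'   `adjust`), `delta`, `direction` ("up" iff delta > 0).
#' @export
differential_expression <- function(bundle, high, low, alpha = 0.05,
                                    min_delta = 0, adjust = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"),
            length(high) > 0, length(low) > 0)
  expr <- bundle$expression
  mh <- expr[, high, drop = FALSE]
  ml <- expr[, low, drop = FALSE]
  res <- welch_rows(mh, ml)
  dead <- (res$var_high == 0 & res$var_low == 0) |
    !is.finite(res$t_stat)
  dead[is.na(dead)] <- TRUE
  if (any(dead))
    message(sum(dead), " zero-variance/untestable gene(s) skipped")
  res <- res[!dead, , drop = FALSE]
  res$var_high <- res$var_low <- NULL
  crit <- if (adjust) {
    res$p_adj <- stats::p.adjust(res$p, method = "BH")
    res$p_adj
  } else res$p
  res <- res[crit < alpha & abs(res$delta) >= min_delta, , drop = FALSE]
  res$direction <- ifelse(res$delta > 0, "up", "down")
  res <- res[order(-abs(res$t_stat)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export a connectivity-map-style reversal query
#'
#' Splits the differential-expression table by direction, takes the top
#' genes by |t| on each side (capped at `max_per_list`), and optionally
#' writes them as GRP files (one gene symbol per line, `up.grp` /
#' `down.grp`) for submission to perturbation-profile matching tools.
#'
#' @param results data.frame from [differential_expression()].
#' @param max_per_list cap per list (default 500).
#' @param dir if non-NULL, directory to write `up.grp` and `down.grp` to.
#' @param min_per_list minimum genes required on each side (default 10).
#' @return object of class `reversal_query`: list `up_list`, `down_list`
#'   (disjoint, ordered by |t| descending).
#' @export
export_query <- function(results, max_per_list = 500, dir = NULL,
                         min_per_list = 10) {
  up <- results$gene[results$direction == "up"]
  down <- results$gene[results$direction == "down"]
  if (length(up) < min_per_list || length(down) < min_per_list)
    stop("need >= ", min_per_list, " genes on each side (up ",
         length(up), ", down ", length(down), ")", call. = FALSE)
  up <- utils::head(up, max_per_list)
  down <- utils::head(down, max_per_list)
  stopifnot(length(intersect(up, down)) == 0)   # by construction
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(up, file.path(dir, "up.grp"))
    writeLines(down, file.path(dir, "down.grp"))
  }
  structure(list(up_list = up, down_list = down,
                 max_per_list = max_per_list),
            class = "reversal_query")
}

#' Score a drug profile against a reversal query
#'
#' Given a perturbation profile as a ranked gene list (most up-regulated
#' by the drug first, most down-regulated last), each query list gets a
#' normalized rank-position score in [-1, 1]: the mean profile rank of
#' the list, linearly rescaled so that a list occupying the very top of
#' the profile scores +1 and one occupying the very bottom scores -1
#' (equivalently, a rescaled Mann-Whitney statistic of the list against
#' the rest of the profile; a randomly placed list scores 0 in
#' expectation).  The reversal score is `score(up_list) -
#' score(down_list)`, in [-2, 2]: -2 means the drug perfectly reverses
#' the query, +2 perfect concordance.
#'
#' @param query a `reversal_query`.
#' @param drug_profile character vector of genes ranked by drug-induced
#'   change, most up-regulated first.
#' @param min_coverage minimum fraction of query genes that must be in
#'   the profile (default 0.5).
#' @return numeric scalar in [-2, 2], with attribute `coverage`.
#' @export
reversal_score <- function(query, drug_profile, min_coverage = 0.5) {
  stopifnot(inherits(query, "reversal_query"))
  if (anyDuplicated(drug_profile))
    stop("drug profile must rank each gene once", call. = FALSE)
  qgenes <- c(query$up_list, query$down_list)
  present <- qgenes %in% drug_profile
  coverage <- mean(present)
  if (coverage < min_coverage)
    stop("only ", round(100 * coverage), "% of query genes in the ",
         "profile (need >= ", round(100 * min_coverage), "%)",
         call. = FALSE)
  G <- length(drug_profile)
  # rank from the bottom: 1 = most down-regulated, G = most up-regulated
  rank_bottom <- function(genes) {
    genes <- genes[genes %in% drug_profile]
    G - match(genes, drug_profile) + 1
  }
  list_score <- function(genes) {
    rb <- rank_bottom(genes)
    m <- length(rb)
    if (m == 0 || m == G) return(0)
    2 * (mean(rb) - (m + 1) / 2) / (G - m) - 1
  }
  out <- list_score(query$up_list) - list_score(query$down_list)
  attr(out, "coverage") <- coverage
  out
}
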