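#' Construct an up/down-tag signature
#'
#' A transcriptional signature is a named pair of gene lists: genes that
#' go up under the phenotype (`up_tags`, required) and genes that go down
#' (`down_tags`, may be empty).  The two halves must be disjoint.
#'
#' @param name signature label.
#' @param up_tags character vector of up-regulated genes (non-empty).
#' @param down_tags character vector of down-regulated genes.
#' @return object of class `signature`.
#' @export
signature <- function(name, up_tags, down_tags = character(0)) {
  up_tags <- toupper(unique(as.character(up_tags)))
  down_tags <- toupper(unique(as.character(down_tags)))
  if (!length(up_tags)) stop("up_tags must be non-empty", call. = FALSE)
  if (length(intersect(up_tags, down_tags)))
    stop("up_tags and down_tags must be disjoint", call. = FALSE)
  structure(list(name = as.character(name), up_tags = up_tags,
                 down_tags = down_tags),
            class = "signature")
}

#' Read unsigned gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.  Each set becomes a
#' [signature] with up tags only.
#'
#' @param path GMT file.
#' @return list of `signature`s.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line: ", substr(ln, 1, 40), call. = FALSE)
    signature(parts[1], parts[-(1:2)])
  })
}

#' Read a signed signature from a two-column TSV
#'
#' Dialect for tagged (directional) signatures: columns `gene` and
#' `direction` (values `up` or `down`).
#'
#' @param path TSV file.
#' @param name signature label.
#' @return a [signature].
#' @export
read_signed_signature <- function(path, name) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(tab)))
    stop("signed signature needs columns gene, direction", call. = FALSE)
  if (!all(tab$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'", call. = FALSE)
  signature(name, tab$gene[tab$direction == "up"],
            tab$gene[tab$direction == "down"])
}

#' Score one signature against an expression matrix
#'
#' Every gene is z-scored across samples; a sample's activation score is
#' the mean z over the signature's present up tags minus the mean z over
#' its present down tags (zero when the down list is empty).  Genes with
#' zero variance across samples carry no information and are treated as
#' absent.  At least `min_up` up tags must be present.
#'
#' @param mat genes x samples expression matrix (log2 scale).
#' @param sig a [signature].
#' @param min_up minimum mappable up tags (default 5).
#' @return named numeric per-sample score vector with attributes
#'   `coverage_up` and `coverage_down` (fraction of tags present).
#' @export
score_signature <- function(mat, sig, min_up = 5) {
  stopifnot(inherits(sig, "signature"))
  genes <- toupper(rownames(mat))
  sds <- apply(mat, 1, stats::sd, na.rm = TRUE)
  informative <- genes[is.finite(sds) & sds > 0]
  up <- intersect(sig$up_tags, informative)
  down <- intersect(sig$down_tags, informative)
  if (length(up) < min_up)
    stop("signature '", sig$name, "': only ", length(up),
         " up tag(s) mappable (need >= ", min_up, ")", call. = FALSE)
  zmat <- t(scale(t(mat)))
  rownames(zmat) <- genes
  score <- colMeans(zmat[up, , drop = FALSE], na.rm = TRUE)
  if (length(down))
    score <- score - colMeans(zmat[down, , drop = FALSE], na.rm = TRUE)
  attr(score, "coverage_up") <- length(up) / length(sig$up_tags)
  attr(score, "coverage_down") <-
    if (length(sig$down_tags)) length(down) / length(sig$down_tags)
    else NA_real_
  score
}

#' Score a battery of signatures into an activation matrix
#'
#' Applies [score_signature()] to each signature; unscoreable signatures
#' (too few mappable tags) are excluded from the matrix but listed, with
#' the reason, in the `excluded` attribute rather than silently dropped.
#' Duplicate signature names are suffixed deterministically
#' (`make.unique`).
#'
#' @param mat genes x samples expression matrix.
#' @param sigs list of [signature]s.
#' @param min_up forwarded to [score_signature()].
#' @return signatures x samples matrix of class `activation_matrix` with
#'   attributes `excluded` (named character of reasons) and `provenance`.
#' @export
activation_matrix <- function(mat, sigs, min_up = 5) {
  stopifnot(length(sigs) >= 1)
  nm <- make.unique(vapply(sigs, function(s) s$name, character(1)))
  rows <- list(); excluded <- character(0)
  for (i in seq_along(sigs)) {
    sc <- tryCatch(score_signature(mat, sigs[[i]], min_up = min_up),
                   error = function(e) e)
    if (inherits(sc, "error")) {
      excluded[nm[i]] <- conditionMessage(sc)
    } else {
      rows[[nm[i]]] <- as.vector(sc)
    }
  }
  if (!length(rows)) stop("no scoreable signature", call. = FALSE)
  out <- do.call(rbind, rows)
  colnames(out) <- colnames(mat)
  structure(out, class = c("activation_matrix", class(out)),
            excluded = excluded,
            provenance = vapply(sigs, function(s) s$name, character(1)))
}

#' Associate signature activation with a gene's expression
#'
#' For each signature, fits the simple linear regression of the gene's
#' expression on the activation score and reports slope, r-squared and
#' two-sided p.  Also returns the PCA of the activation matrix with
#' samples projected on the first two components; component signs are
#' fixed by forcing the loading of the first signature to be
#' non-negative, so the projection is deterministic.
#'
#' @param act an [activation_matrix()].
#' @param gene_expr numeric per-sample expression of the gene of
#'   interest, same sample order as `act` columns.
#' @param min_samples minimum samples (default 20).
#' @return list: `regression` (data.frame signature, slope, r_squared,
#'   p), `pca` (list `scores` samples x 2, `sdev`, `rotation`).
#' @export
associate_with_gene <- function(act, gene_expr, min_samples = 20) {
  stopifnot(ncol(act) == length(gene_expr))
  if (ncol(act) < min_samples)
    stop("need >= ", min_samples, " samples", call. = FALSE)
  if (stats::sd(gene_expr) == 0)
    stop("gene expression is constant", call. = FALSE)
  reg <- do.call(rbind, lapply(rownames(act), function(s) {
    fit <- summary(stats::lm(gene_expr ~ act[s, ]))
    co <- fit$coefficients
    data.frame(signature = s,
               slope = co[2, "Estimate"],
               r_squared = fit$r.squared,
               p = co[2, "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  }))
  pc <- stats::prcomp(t(unclass(act)), center = TRUE, scale. = FALSE)
  n_comp <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  scores <- pc$x[, seq_len(n_comp), drop = FALSE]
  for (j in seq_len(n_comp)) {
    if (rot[1, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  list(regression = reg,
       pca = list(scores = scores, sdev = pc$sdev, rotation = rot))
}

#' Hypergeometric over-representation of one gene set in another
#'
#' Tests whether the overlap between two gene sets drawn from a common
#' universe is larger than chance: `p = P(X >= k)` with X hypergeometric
#' (universe size N, |A| successes, |B| draws).
#'
#' @param set_a,set_b character gene sets.
#' @param universe_n size of the gene universe both sets live in.
#' @return list: `k_overlap`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe_n) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (universe_n < length(union(set_a, set_b)))
    stop("universe smaller than the union of the two sets", call. = FALSE)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), universe_n - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(k_overlap = k, p = p)
}
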