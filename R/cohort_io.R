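#' Read a genes-by-samples expression TSV
#'
#' First column holds the gene (or probe) identifier; remaining columns are
#' samples.  Duplicate identifiers are only tolerated when a probe map will
#' collapse them later.
#'
#' @param path TSV file path.
#' @return numeric matrix with identifier rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs >= 1 sample column",
                          call. = FALSE)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

#' Read a clinical TSV
#'
#' First column `sample`; must contain at least `time`, `event`,
#' `endpoint`.
#' @param path TSV file path.
#' @return data.frame with sample ids as rownames.
#' @export
read_clinical_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  rownames(tab) <- as.character(tab[[1]])
  tab[[1]] <- NULL
  tab
}

#' Read a probe-to-gene mapping table
#'
#' Two columns, `probe_id` and `gene_symbol`; probes mapping to several
#' distinct symbols are ambiguous and are rejected during collapsing.
#' Symbols are upper-cased so dialects differing only in case agree.
#' @param path TSV file path.
#' @return data.frame (probe_id, gene_symbol).
#' @export
read_probe_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(tab)))
    stop("probe map needs columns probe_id and gene_symbol", call. = FALSE)
  tab$gene_symbol <- toupper(tab$gene_symbol)
  tab <- tab[!is.na(tab$gene_symbol) & nzchar(tab$gene_symbol), ]
  tab
}

#' Read a gene-locus annotation table
#'
#' Columns `gene`, `chromosome`, `arm` (p/q) and `start` (1-based bp).
#' Defines the gene universe of a chromosomal-arm screen, e.g. the set of
#' genes annotated to 1q.
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_locus_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chromosome", "arm", "start")
  if (!all(need %in% names(tab)))
    stop("locus table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$gene)) stop("duplicated genes in locus table",
                                    call. = FALSE)
  if (any(tab$start <= 0)) stop("locus start must be positive",
                                call. = FALSE)
  tab$gene <- toupper(tab$gene)
  tab
}

# "Already logged" heuristic: microarray log2 values live in roughly
# [-10, 30]; raw intensities exceed that range.
looks_logged <- function(mat) {
  rng <- range(mat, na.rm = TRUE)
  rng[2] <= 30 && rng[1] >= -10
}

#' Load, collapse and normalize an expression matrix
#'
#' Reads a genes-or-probes by samples TSV, optionally collapses probes to
#' gene symbols (multiple probes per gene averaged), and puts
#' single-channel data on the log2 scale: matrices already within the
#' log2 range (max <= 30, min >= -10) pass through untouched, anything
#' else is transformed as `log2(x + 1)`.  Dual-channel log-ratio data is
#' used as is.  Genes missing in more than 20% of samples are dropped from
#' the cohort; remaining missing values stay `NA` (excluded pairwise in
#' correlations and listwise in Cox fits downstream).
#'
#' @param path expression TSV (first column gene/probe id).
#' @param probe_map optional data.frame from [read_probe_map()].
#' @param channel `"single"` or `"dual"`.
#' @param max_missing per-gene missing fraction above which the gene is
#'   dropped from this cohort.
#' @return numeric matrix genes x samples, log2 scale.
#' @export
load_expression <- function(path, probe_map = NULL,
                            channel = c("single", "dual"),
                            max_missing = 0.2) {
  channel <- match.arg(channel)
  mat <- read_expression_tsv(path)
  if (!is.null(probe_map)) {
    mat <- collapse_probes(mat, probe_map)
  } else {
    rownames(mat) <- toupper(rownames(mat))
    if (anyDuplicated(rownames(mat)))
      stop("duplicated gene identifiers and no probe map given",
           call. = FALSE)
  }
  if (channel == "single" && !looks_logged(mat)) {
    if (min(mat, na.rm = TRUE) < 0)
      stop("negative intensities cannot be log2-transformed", call. = FALSE)
    mat <- log2(mat + 1)
  }
  miss <- rowMeans(is.na(mat))
  if (any(miss > max_missing)) {
    message(sum(miss > max_missing), " gene(s) dropped for >",
            round(100 * max_missing), "% missing values")
    mat <- mat[miss <= max_missing, , drop = FALSE]
  }
  if (nrow(mat) == 0) stop("no genes left after filtering", call. = FALSE)
  mat
}

#' Collapse probe rows to gene rows
#'
#' Each gene's row becomes the arithmetic mean of its probes' rows.
#' Probes absent from the map, or ambiguously mapped to several genes, are
#' dropped (with a message).  Output genes are in lexicographic order, so
#' the operation is deterministic and idempotent.
#'
#' @param mat probes x samples matrix (probe ids as rownames).
#' @param probe_map data.frame (probe_id, gene_symbol).
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(mat, probe_map) {
  probe_map <- unique(probe_map[, c("probe_id", "gene_symbol")])
  ambig <- unique(probe_map$probe_id[duplicated(probe_map$probe_id)])
  if (length(ambig)) {
    message(length(ambig), " probe(s) mapped to multiple genes; dropped")
    probe_map <- probe_map[!probe_map$probe_id %in% ambig, ]
  }
  keep <- rownames(mat) %in% probe_map$probe_id
  if (!any(keep)) stop("zero mappable probes", call. = FALSE)
  if (any(!keep))
    message(sum(!keep), " unmapped probe(s) dropped")
  mat <- mat[keep, , drop = FALSE]
  sym <- probe_map$gene_symbol[match(rownames(mat), probe_map$probe_id)]
  genes <- sort(unique(sym))
  out <- matrix(NA_real_, length(genes), ncol(mat),
                dimnames = list(genes, colnames(mat)))
  for (g in genes) {
    rows <- mat[sym == g, , drop = FALSE]
    out[g, ] <- colMeans(rows, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Restrict an expression matrix to one chromosome arm
#'
#' Keeps only genes annotated to the requested arm, preserving their
#' original matrix order; genes absent from the locus table are dropped
#' and counted in a message.
#'
#' @param mat genes x samples matrix.
#' @param locus locus table ([read_locus_table()]).
#' @param chromosome chromosome label, e.g. `"1"`.
#' @param arm `"p"` or `"q"`.
#' @return the restricted matrix.
#' @export
restrict_to_locus <- function(mat, locus, chromosome = "1", arm = "q") {
  arm <- match.arg(arm, c("p", "q"))
  unannotated <- sum(!rownames(mat) %in% locus$gene)
  if (unannotated)
    message(unannotated, " gene(s) absent from the locus table; dropped")
  on_arm <- locus$gene[locus$chromosome == as.character(chromosome) &
                         locus$arm == arm]
  keep <- rownames(mat) %in% on_arm
  if (!any(keep))
    stop("no genes annotated to ", chromosome, arm, call. = FALSE)
  mat[keep, , drop = FALSE]
}

#' Align expression and clinical tables into a cohort bundle
#'
#' Restricts both sides to their sample-id intersection (in the expression
#' matrix's column order) and rejects cohorts with fewer than
#' `min_samples` common samples.
#'
#' @param expression genes x samples matrix.
#' @param clinical clinical data.frame (sample ids as rownames).
#' @param cohort_id label for the resulting bundle.
#' @param channel `"single"` or `"dual"`.
#' @param min_samples minimum usable intersection (default 10).
#' @return a [cohort_bundle].
#' @export
align_samples <- function(expression, clinical, cohort_id = "cohort",
                          channel = c("single", "dual"), min_samples = 10) {
  channel <- match.arg(channel)
  common <- intersect(colnames(expression), rownames(clinical))
  if (length(common) < min_samples)
    stop("only ", length(common), " samples shared between expression and ",
         "clinical tables (need >= ", min_samples, "); cohort rejected",
         call. = FALSE)
  common <- colnames(expression)[colnames(expression) %in% common]
  cohort_bundle(cohort_id,
                expression[, common, drop = FALSE],
                clinical[common, , drop = FALSE],
                channel = channel)
}

#' Read cohort bundles back from a fixture directory
#'
#' Companion reader for [write_fixture()]: loads every cohort listed in
#' `manifest.tsv` and aligns expression with clinical data.
#'
#' @param dir directory containing `manifest.tsv` and the per-cohort TSVs.
#' @return list of [cohort_bundle]s.
#' @export
read_fixture <- function(dir) {
  mf_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf_path)) stop("no manifest.tsv in ", dir, call. = FALSE)
  manifest <- utils::read.delim(mf_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    expr <- read_expression_tsv(file.path(dir, manifest$expression[i]))
    clin <- read_clinical_tsv(file.path(dir, manifest$clinical[i]))
    align_samples(expr, clin, cohort_id = manifest$cohort_id[i],
                  channel = manifest$channel[i])
  })
}
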