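# Expression matrices are plain numeric matrices (genes x samples) with
# rownames = gene (or probe) IDs and colnames = sample IDs. The log2/raw
# state travels as the "scale" attribute ("RAW" or "LOG2").

.check_expr <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs row (gene) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene/probe IDs in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample IDs in expression matrix")
  invisible(values)
}

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample IDs and a first column of gene (or probe)
#' IDs; remaining cells are numeric intensities (`NA` allowed for missing
#' measurements).
#'
#' @param path file path.
#' @param scale `"RAW"` or `"LOG2"`, recorded as the `scale` attribute.
#' @return numeric matrix, genes x samples, with attribute `scale`.
#' @export
read_expression <- function(path, scale = c("LOG2", "RAW")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs an ID column and >=1 sample")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  .check_expr(m)
  attr(m, "scale") <- scale
  m
}

#' Write an expression or indicator matrix as TSV
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @param id_label header label for the ID column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_label = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV `probe<TAB>gene`, one row per probe-gene pair; a probe
#' mapping to several genes appears on several rows, and a probe mapping to
#' no gene appears once with an empty gene field.
#'
#' @param path file path.
#' @return named list: probe ID -> character vector of gene symbols
#'   (possibly empty).
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != 2L) stop("probe map must have exactly 2 columns")
  probes <- df[[1L]]; genes <- df[[2L]]
  out <- split(genes, factor(probes, levels = unique(probes)))
  lapply(out, function(g) unique(g[nzchar(g)]))
}

#' Filter probes and collapse to gene level
#'
#' Probes mapping to several genes or to no gene are removed; surviving
#' probes are relabeled by their unique gene. When several retained probes
#' map to the same gene their rows are collapsed to one row per gene
#' (mean by default, `NA`s ignored).
#'
#' @param raw numeric matrix, probes x samples.
#' @param probe_map named list, probe ID -> character vector of gene
#'   symbols, as returned by [read_probe_map()]. Every row of `raw` must be
#'   a key of `probe_map`.
#' @param collapse function used to summarize multiple probe rows for one
#'   gene; receives a probes x samples sub-matrix and must return one value
#'   per column. Default: column means over observed values.
#' @return gene-level numeric matrix with attributes `n_dropped_multi`,
#'   `n_dropped_none`, `n_collapsed` (number of probes merged into an
#'   already-represented gene) and the input's `scale`.
#' @export
filter_probes <- function(raw, probe_map,
                          collapse = function(m) colMeans(m, na.rm = TRUE)) {
  .check_expr(raw)
  probes <- rownames(raw)
  missing_probes <- setdiff(probes, names(probe_map))
  if (length(missing_probes) > 0L)
    stop("probe(s) absent from map: ",
         paste(utils::head(missing_probes, 5L), collapse = ", "))
  ngenes <- lengths(probe_map[probes])
  keep <- ngenes == 1L
  n_multi <- sum(ngenes > 1L)
  n_none <- sum(ngenes == 0L)
  if (!any(keep)) stop("no probe maps to a unique gene")
  kept <- raw[keep, , drop = FALSE]
  gene <- vapply(probe_map[probes[keep]], `[[`, character(1L), 1L)
  groups <- split(seq_len(nrow(kept)), gene)
  rows <- lapply(groups, function(idx) {
    if (length(idx) == 1L) kept[idx, ] else collapse(kept[idx, , drop = FALSE])
  })
  vals <- do.call(rbind, rows)
  rownames(vals) <- names(groups)
  colnames(vals) <- colnames(kept)
  vals <- vals[order(rownames(vals)), , drop = FALSE]
  attr(vals, "scale") <- attr(raw, "scale")
  attr(vals, "n_dropped_multi") <- n_multi
  attr(vals, "n_dropped_none") <- n_none
  attr(vals, "n_collapsed") <- nrow(kept) - length(groups)
  vals
}

#' Preprocess an expression matrix
#'
#' Applies, in order, an elementwise log2 transform and per-gene
#' mean-centering (each row minus its mean over all columns passed in,
#' tumors and references jointly; missing entries are ignored when
#' computing the mean). Centering over the full cohort cannot change
#' downstream indicator values, because [fold_change()] subtracts the
#' reference mean per gene anyway; it is offered because it is the
#' conventional preparation for visualisation of log-intensity data.
#'
#' @param expr numeric matrix, genes x samples.
#' @param do_log2 apply log2? Requires all observed values > 0.
#' @param do_mean_center subtract each gene's row mean?
#' @return the transformed matrix; attribute `scale` is set to `"LOG2"`
#'   when `do_log2` is `TRUE`.
#' @export
preprocess <- function(expr, do_log2 = TRUE, do_mean_center = TRUE) {
  .check_expr(expr)
  sc <- attr(expr, "scale")
  if (do_log2) {
    bad <- which(!is.na(expr) & expr <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("non-positive value under log2 at gene ",
           sQuote(rownames(expr)[bad[1L, 1L]]), ", sample ",
           sQuote(colnames(expr)[bad[1L, 2L]]))
    expr <- log2(expr)
    sc <- "LOG2"
  }
  if (do_mean_center)
    expr <- expr - rowMeans(expr, na.rm = TRUE)
  attr(expr, "scale") <- sc
  expr
}

#' Per-sample log2 fold change against a reference set
#'
#' For gene i and tumor j the fold change is `x_ij - mean_k(y_ik)`: the
#' tumor's log2 value minus the mean log2 value of the gene over the
#' reference samples. The sign convention is fixed so that over-expression
#' in the tumor gives a positive value. A missing tumor value gives a
#' missing fold change; reference means ignore missing entries.
#'
#' @param expr numeric matrix on the log2 scale (attribute `scale` must not
#'   be `"RAW"`), genes x samples, containing both tumor and reference
#'   columns.
#' @param tumor_ids,reference_ids disjoint subsets of `colnames(expr)`;
#'   `reference_ids` must be non-empty.
#' @return numeric matrix, genes x tumors.
#' @export
fold_change <- function(expr, tumor_ids, reference_ids) {
  .check_expr(expr)
  if (identical(attr(expr, "scale"), "RAW"))
    stop("fold_change expects log2-scale expression; run preprocess() first")
  if (length(reference_ids) == 0L) stop("reference sample set is empty")
  unknown <- setdiff(c(tumor_ids, reference_ids), colnames(expr))
  if (length(unknown) > 0L)
    stop("unknown sample ID(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(tumor_ids, reference_ids)) > 0L)
    stop("tumor and reference sample sets overlap")
  ref_mean <- rowMeans(expr[, reference_ids, drop = FALSE], na.rm = TRUE)
  fc <- expr[, tumor_ids, drop = FALSE] - ref_mean
  attr(fc, "scale") <- "LOG2"
  fc
}

#' Ternary gene-activity indicator matrix
#'
#' Discretizes a log2 fold-change matrix at fold-change cutoff `K` (linear
#' scale): entries become `+1` (over-expressed) when `fc >= log2(K)`, `-1`
#' (under-expressed) when `fc <= -log2(K)`, and `0` otherwise. The boundary
#' is inclusive ("at least a K-fold difference"). Missing fold changes map
#' to `0`: a gene with no measurement cannot support a regulation. The
#' default `K = 2` is the conventional two-fold cutoff.
#'
#' @param fc numeric matrix of log2 fold changes, genes x tumors.
#' @param K fold-change cutoff on the linear scale; must be > 1.
#' @return integer matrix with entries in `{-1, 0, 1}`, same dimnames as
#'   `fc`, with attribute `cutoff_K`.
#' @export
indicator <- function(fc, K = 2) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 1)
    stop("K must be a single number > 1 (K <= 1 would label everything)")
  thr <- log2(K)
  ind <- matrix(0L, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  ind[!is.na(fc) & fc >= thr] <- 1L
  ind[!is.na(fc) & fc <= -thr] <- -1L
  attr(ind, "cutoff_K") <- K
  ind
}
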