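# Expression matrices with condition labels, normalization, and
# per-condition summaries.

#' Construct an expression matrix with condition labels
#'
#' A light container in the matrix-plus-targets idiom: a numeric matrix of
#' normalized intensities (entities x samples) and a condition label per
#' sample (`CONTROL`, `RRMS`, `PPMS`, `SPMS`).
#'
#' @param values numeric matrix, rownames = entity symbols, colnames =
#'   sample ids.
#' @param condition character or factor of conditions, one per sample;
#'   either named by sample id or in column order.
#' @return Object of class `grn_expr`: list with `values` and `condition`
#'   (factor named by sample id).
#' @details Duplicate entity ids are an error. Conditions present with
#'   fewer than 3 samples trigger a warning (the design criterion for the
#'   cohorts this container models is a minimum of three samples per
#'   condition), not an error, so that toy fixtures remain expressible.
#' @export
grn_expression <- function(values, condition) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must have entity rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate entity ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  condition <- setNames(as.character(condition), names(condition))
  if (!is.null(names(condition))) {
    miss <- setdiff(colnames(values), names(condition))
    if (length(miss))
      stopf("samples without a condition label: %s", paste(miss, collapse = ", "))
    condition <- condition[colnames(values)]
  } else if (length(condition) != ncol(values)) {
    stopf("condition must label every sample")
  }
  bad <- !condition %in% CONDITIONS
  if (any(bad))
    stopf("unknown condition label(s): %s",
          paste(unique(condition[bad]), collapse = ", "))
  condition <- factor(condition, levels = CONDITIONS)
  names(condition) <- colnames(values)
  small <- table(condition)
  small <- small[small > 0 & small < 3]
  if (length(small))
    warnf("condition(s) with fewer than 3 samples: %s",
          paste(names(small), small, sep = "=", collapse = ", "))
  structure(list(values = values, condition = condition), class = "grn_expr")
}

#' @export
print.grn_expr <- function(x, ...) {
  cnt <- table(x$condition)
  cat(sprintf("grn_expr: %d entities x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(names(cnt), cnt, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Read an expression matrix and its sample table from TSV
#'
#' @param expr_path TSV: first column entity id, remaining columns samples.
#' @param samples_path TSV with columns `sample_id`, `condition`.
#' @return A [grn_expression()] object.
#' @export
read_expression <- function(expr_path, samples_path) {
  df <- read_tsv(expr_path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- canon_symbol(df[[1]])
  smp <- read_tsv(samples_path)
  assert_cols(smp, c("sample_id", "condition"), "sample table")
  grn_expression(mat, setNames(toupper(smp$condition), smp$sample_id))
}

#' Row-bind two expression matrices on their shared samples
#'
#' Used to join the gene and miRNA matrices profiled in the same
#' individuals; samples are intersected by id and condition labels must
#' agree.
#'
#' @param a,b [grn_expression()] objects.
#' @return A combined `grn_expr` over the shared samples.
#' @export
merge_expression <- function(a, b) {
  stopifnot(inherits(a, "grn_expr"), inherits(b, "grn_expr"))
  shared <- intersect(colnames(a$values), colnames(b$values))
  if (!length(shared)) stopf("no shared samples between the two matrices")
  if (!identical(as.character(a$condition[shared]),
                 as.character(b$condition[shared])))
    stopf("condition labels disagree on shared samples")
  overlap <- intersect(rownames(a$values), rownames(b$values))
  if (length(overlap))
    stopf("entity ids present in both matrices: %s",
          paste(head(overlap, 5), collapse = ", "))
  grn_expression(rbind(a$values[, shared, drop = FALSE],
                       b$values[, shared, drop = FALSE]),
                 setNames(as.character(a$condition[shared]), shared))
}

#' Normalize an expression matrix
#'
#' `quantile` aligns the per-sample distributions (delegated to
#' limma's rank-average quantile normalization); `log2_shift` computes
#' `log2(x + 1)` and then shifts the matrix minimum to just above zero.
#' Both methods guarantee a strictly positive output matrix, as required by
#' downstream integrity scoring.
#'
#' @param raw a [grn_expression()] object with finite values.
#' @param method `"quantile"` or `"log2_shift"`.
#' @return A normalized `grn_expr`.
#' @export
normalize_expression <- function(raw, method = c("quantile", "log2_shift")) {
  stopifnot(inherits(raw, "grn_expr"))
  method <- match.arg(method)
  v <- raw$values
  if (any(!is.finite(v))) {
    idx <- which(!is.finite(v), arr.ind = TRUE)[1, ]
    stopf("non-finite expression value at entity %s, sample %s",
          rownames(v)[idx[1]], colnames(v)[idx[2]])
  }
  out <- switch(method,
    quantile = limma::normalizeQuantiles(v),
    log2_shift = log2(v + 1))
  m <- min(out)
  if (m <= 0) out <- out - m + .Machine$double.eps
  dimnames(out) <- dimnames(v)
  grn_expression(out, setNames(as.character(raw$condition), colnames(v)))
}

#' Summarize expression per entity per condition
#'
#' Produces the per-condition expression values (`e_tf`, `e_gene`,
#' `e_mir`) consumed by the integrity score: one strictly positive summary
#' per entity per condition.
#'
#' @param expr a normalized [grn_expression()] object.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return Numeric matrix entities x conditions (only conditions present).
#' @export
condition_summary <- function(expr, statistic = c("mean", "median")) {
  stopifnot(inherits(expr, "grn_expr"))
  statistic <- match.arg(statistic)
  conds <- levels(droplevels(expr$condition))
  cols_of <- lapply(conds, function(cn) {
    cols <- expr$condition == cn
    if (statistic == "mean") rowMeans(expr$values[, cols, drop = FALSE])
    else apply(expr$values[, cols, drop = FALSE], 1L, median)
  })
  out <- matrix(unlist(cols_of), nrow = nrow(expr$values),
                dimnames = list(rownames(expr$values), conds))
  if (any(out <= 0))
    stopf("condition summaries must be strictly positive; normalize first")
  out
}
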