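# qPCR validation: 2^-dCt relative expression, group comparison, integrity
# scoring on qPCR means, and concordance of direction calls against the
# expression-array pipeline.

#' Relative expression from Ct values (2^-dCt)
#'
#' `2^-(Ct_target - Ct_reference)`, the standard single-reference relative
#' quantification (GAPDH for mRNA/TF targets, U6 snRNA for miRNAs).
#' Vectorized.
#'
#' @param ct_target,ct_reference numeric cycle-threshold values.
#' @return Positive numeric vector.
#' @examples
#' relative_expression(25, 20)  # 2^-5 = 0.03125
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(is.na(ct_target))) stopf("missing target Ct value")
  if (any(is.na(ct_reference))) stopf("missing reference Ct value")
  if (any(!is.finite(ct_target) | !is.finite(ct_reference)))
    stopf("Ct values must be finite")
  2^(-(ct_target - ct_reference))
}

#' Read a qPCR Ct table from TSV
#'
#' Columns: `sample_id`, `group` (CONTROL/RRMS/PPMS/SPMS), `target`,
#' `ct_target`, `ct_reference`.
#'
#' @param path TSV file path.
#' @return data.frame with a `rel_expr` column appended (2^-dCt).
#' @export
read_ct <- function(path) {
  df <- read_tsv(path)
  assert_cols(df, c("sample_id", "group", "target", "ct_target", "ct_reference"),
              "Ct table")
  df$group <- toupper(df$group)
  bad <- !df$group %in% CONDITIONS
  if (any(bad))
    stopf("unknown group label(s): %s", paste(unique(df$group[bad]), collapse = ", "))
  df$target <- canon_symbol(df$target)
  df$rel_expr <- relative_expression(df$ct_target, df$ct_reference)
  df
}

#' Two-group comparison of relative expression
#'
#' Fold change `mean(b) / mean(a)` plus a two-sided Student's t-test
#' (equal variances by default; Welch behind `var_equal = FALSE`). The
#' degenerate case of zero variance in both groups with equal means
#' returns t = 0, p = 1 by convention.
#'
#' @param values_a,values_b positive numeric vectors (e.g. control vs a
#'   disease group), each of length >= 2.
#' @param var_equal assume equal variances (classical Student's t);
#'   default TRUE.
#' @return List: `fold_change`, `t`, `p`, `n_a`, `n_b`.
#' @export
group_compare <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stopf("each group needs at least 2 values")
  fc <- mean(values_b) / mean(values_a)
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(fold_change = fc, t = 0, p = 1,
                  n_a = length(values_a), n_b = length(values_b)))
    stopf("zero variance in both groups with unequal means: t undefined")
  }
  tt <- t.test(values_b, values_a, var.equal = var_equal)
  list(fold_change = fc, t = unname(tt$statistic), p = tt$p.value,
       n_a = length(values_a), n_b = length(values_b))
}

#' Group-mean relative expression per target
#'
#' @param ct data.frame from [read_ct()] (needs `target`, `group`,
#'   `rel_expr`).
#' @return Numeric matrix targets x groups of mean 2^-dCt values.
#' @export
qpcr_group_means <- function(ct) {
  assert_cols(ct, c("target", "group", "rel_expr"), "Ct table")
  tapply(ct$rel_expr, list(ct$target, factor(ct$group, levels = CONDITIONS)),
         mean)[, CONDITIONS, drop = FALSE]
}

#' Integrity RFCs from qPCR expression
#'
#' Scores a motif's integrity N per group from the group-mean 2^-dCt
#' relative expression of its three components, then forms the regulatory
#' fold change and direction for each disease contrast.
#'
#' @param rel_means numeric matrix targets x groups (see
#'   [qpcr_group_means()]).
#' @param grn one-row data.frame (or list) with `tf`, `gene`, `mirna`.
#' @param w a [regulatory_weights()] object.
#' @return data.frame: `contrast`, `rfc`, `direction`.
#' @export
qpcr_rfc <- function(rel_means, grn, w = regulatory_weights()) {
  comp <- c(tf = canon_symbol(grn$tf), gene = canon_symbol(grn$gene),
            mirna = canon_symbol(grn$mirna))
  missing <- comp[!comp %in% rownames(rel_means)]
  if (length(missing))
    stopf("component(s) not measured: %s",
          paste(names(missing), missing, sep = "=", collapse = ", "))
  sub <- rel_means[comp, CONDITIONS, drop = FALSE]
  if (any(is.na(sub)))
    stopf("component(s) lack measurements in some group")
  n <- integrity_score(sub[1, ], sub[2, ], sub[3, ], w)
  rfc <- regulatory_fold_change(n[MS_CONDITIONS], n[["CONTROL"]])
  data.frame(contrast = CONTRASTS, rfc = unname(rfc),
             direction = rfc_direction(unname(rfc)),
             stringsAsFactors = FALSE)
}

#' Concordance of qPCR and array direction calls
#'
#' A (motif, contrast) cell is concordant iff the qPCR-derived and
#' array-derived directions agree *and* the cell is not in the failed set
#' (cells whose qPCR component expression lacked statistical significance
#' count as failures regardless of direction agreement). Accuracy is the
#' concordant fraction of all cells.
#'
#' @param qpcr_dirs,array_dirs data.frames with columns `grn_id`,
#'   `contrast`, `direction`; the two key sets must be identical.
#' @param failed optional data.frame with columns `grn_id`, `contrast`
#'   marking failed cells.
#' @return List: `accuracy`, `grid` (data.frame with per-cell
#'   `concordant` logical), `n_concordant`, `n_total`.
#' @export
concordance_accuracy <- function(qpcr_dirs, array_dirs, failed = NULL) {
  assert_cols(qpcr_dirs, c("grn_id", "contrast", "direction"), "qPCR calls")
  assert_cols(array_dirs, c("grn_id", "contrast", "direction"), "array calls")
  key <- function(d) paste(d$grn_id, d$contrast, sep = "\r")
  kq <- key(qpcr_dirs); ka <- key(array_dirs)
  if (anyDuplicated(kq) || anyDuplicated(ka))
    stopf("duplicate (grn_id, contrast) keys")
  if (!setequal(kq, ka))
    stopf("qPCR and array call key sets differ")
  m <- merge(qpcr_dirs, array_dirs, by = c("grn_id", "contrast"),
             suffixes = c("_qpcr", "_array"))
  failed_key <- if (is.null(failed) || !nrow(failed)) character()
                else key(failed)
  m$failed <- key(m) %in% failed_key
  m$concordant <- m$direction_qpcr == m$direction_array & !m$failed
  list(accuracy = mean(m$concordant),
       grid = m[, c("grn_id", "contrast", "direction_qpcr",
                    "direction_array", "failed", "concordant")],
       n_concordant = sum(m$concordant), n_total = nrow(m))
}
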