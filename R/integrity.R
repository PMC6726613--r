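# Integrity scoring of motifs, regulatory fold change, ranking and
# cross-contrast overlap.
#
# The integrity score of a motif with component expressions e_tf, e_gene,
# e_mir and regulatory weights r_tf, r_gene, r_mir is the sum of the three
# pairwise products of weighted expressions:
#
#   N = (r_tf e_tf)(r_mir e_mir) + (r_mir e_mir)(r_gene e_gene)
#       + (r_gene e_gene)(r_tf e_tf)
#
# The default weights reflect the regulatory hierarchy: the TF carries the
# highest weight (1) as the initiator of transcription, the gene a moderate
# weight (0.75), and the miRNA the lowest (0.5) as a post-transcriptional
# suppressor. N is a degree-2 form, so scaling all three expressions by c
# scales N by c^2; the regulatory fold change RFC = N_MS / N_control is
# therefore invariant to a common rescaling of both conditions.

#' Regulatory weights for the integrity score
#'
#' @param r_tf weight of the transcription factor; default 1.
#' @param r_gene weight of the gene; default 0.75.
#' @param r_mir weight of the miRNA; default 0.5.
#' @return Named list of class `regulatory_weights`.
#' @export
regulatory_weights <- function(r_tf = 1, r_gene = 0.75, r_mir = 0.5) {
  w <- list(r_tf = r_tf, r_gene = r_gene, r_mir = r_mir)
  bad <- vapply(w, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x <= 0, TRUE)
  if (any(bad))
    stopf("regulatory weights must be strictly positive scalars: %s",
          paste(names(w)[bad], collapse = ", "))
  structure(w, class = "regulatory_weights")
}

#' Integrity score N of a motif
#'
#' `N = (r_tf e_tf)(r_mir e_mir) + (r_mir e_mir)(r_gene e_gene) +
#' (r_gene e_gene)(r_tf e_tf)`. Vectorized over the expression arguments.
#'
#' @param e_tf,e_gene,e_mir strictly positive expression summaries of the
#'   TF, gene and miRNA components.
#' @param w a [regulatory_weights()] object.
#' @return Strictly positive numeric vector of scores.
#' @examples
#' integrity_score(1, 1, 1)  # 0.5 + 0.375 + 0.75 = 1.625
#' @export
integrity_score <- function(e_tf, e_gene, e_mir, w = regulatory_weights()) {
  stopifnot(inherits(w, "regulatory_weights"))
  for (role in c("e_tf", "e_gene", "e_mir")) {
    v <- get(role)
    if (any(!is.finite(v) | v <= 0))
      stopf("%s must be strictly positive and finite", role)
  }
  a <- w$r_tf * e_tf
  g <- w$r_gene * e_gene
  m <- w$r_mir * e_mir
  a * m + m * g + g * a
}

#' Score all motifs in every condition
#'
#' Emits one integrity record per motif per condition (4 conditions), using
#' per-condition expression summaries from [condition_summary()]. Motifs
#' with any component missing a summary in any condition are dropped and
#' counted.
#'
#' @param grns data.frame of motifs from [enumerate_triples()].
#' @param summaries numeric matrix entities x conditions
#'   (CONTROL/RRMS/PPMS/SPMS), strictly positive.
#' @param w a [regulatory_weights()] object.
#' @return data.frame with columns `grn_id`, `condition`, `e_tf`, `e_gene`,
#'   `e_mir`, `N`; exactly `4 * nrow(grns_kept)` rows, attribute
#'   `n_dropped` counting dropped motifs.
#' @export
score_all <- function(grns, summaries, w = regulatory_weights()) {
  assert_cols(grns, c("grn_id", "tf", "gene", "mirna"), "motif table")
  conds <- intersect(CONDITIONS, colnames(summaries))
  if (length(conds) != length(CONDITIONS))
    stopf("summaries must cover all conditions; missing: %s",
          paste(setdiff(CONDITIONS, colnames(summaries)), collapse = ", "))
  ent <- rownames(summaries)
  ok <- grns$tf %in% ent & grns$gene %in% ent & grns$mirna %in% ent
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    msgf("score_all: dropped %d motif(s) lacking expression summaries",
         n_dropped)
  g <- grns[ok, , drop = FALSE]
  K <- nrow(g)
  out <- data.frame(
    grn_id = rep(g$grn_id, times = length(conds)),
    condition = rep(conds, each = K),
    e_tf = as.vector(summaries[g$tf, conds, drop = FALSE]),
    e_gene = as.vector(summaries[g$gene, conds, drop = FALSE]),
    e_mir = as.vector(summaries[g$mirna, conds, drop = FALSE]),
    stringsAsFactors = FALSE)
  out$N <- integrity_score(out$e_tf, out$e_gene, out$e_mir, w)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Regulatory fold change
#'
#' `RFC = N_MS / N_control`; RFC > 1 is up-regulation in disease, RFC < 1
#' down-regulation.
#'
#' @param n_ms,n_control strictly positive integrity scores (vectorized).
#' @return Positive numeric vector of fold changes.
#' @export
regulatory_fold_change <- function(n_ms, n_control) {
  if (any(!is.finite(n_ms) | n_ms <= 0))
    stopf("n_ms must be strictly positive and finite")
  if (any(!is.finite(n_control) | n_control <= 0))
    stopf("n_control must be strictly positive and finite")
  n_ms / n_control
}

#' Direction call from an RFC
#'
#' @param rfc positive numeric vector.
#' @return `"UP"` where rfc > 1, `"DOWN"` where rfc < 1, `NA` at exactly 1
#'   (excluded from ranking).
#' @export
rfc_direction <- function(rfc) {
  ifelse(rfc > 1, "UP", ifelse(rfc < 1, "DOWN", NA_character_))
}

# Internal: per-contrast RFC table from integrity records.
contrast_rfc <- function(records, contrast) {
  if (!contrast %in% CONTRASTS)
    stopf("unknown contrast '%s'; expected one of %s", contrast,
          paste(CONTRASTS, collapse = ", "))
  ms_cond <- sub("_vs_CONTROL$", "", contrast)
  ctl <- records[records$condition == "CONTROL", c("grn_id", "N")]
  ms <- records[records$condition == ms_cond, c("grn_id", "N")]
  if (!nrow(ms))
    stopf("records contain no rows for condition %s", ms_cond)
  m <- merge(ctl, ms, by = "grn_id", suffixes = c("_control", "_ms"))
  m$rfc <- regulatory_fold_change(m$N_ms, m$N_control)
  m$direction <- rfc_direction(m$rfc)
  m
}

#' Select the top differentially regulated motifs for one contrast
#'
#' Per motif type, selects the `k_up` largest RFCs among RFC > 1 (ranked
#' descending) and the `k_down` smallest among RFC < 1 (ranked ascending:
#' most extreme first); RFC = 1 exactly is excluded. Ties are broken by
#' `grn_id` lexicographic order for reproducibility. If fewer candidates
#' exist than requested, all are returned with a warning.
#'
#' @param records integrity records from [score_all()].
#' @param grns motif table carrying `grn_id` and `motif_type` (used to
#'   group the selection by type).
#' @param contrast one of `"RRMS_vs_CONTROL"`, `"PPMS_vs_CONTROL"`,
#'   `"SPMS_vs_CONTROL"`.
#' @param k_up,k_down list sizes per direction; default 10 each.
#' @return data.frame: `grn_id`, `motif_type`, `contrast`, `rfc`,
#'   `direction`, `rank` (1..k within each type x direction).
#' @export
rank_and_select <- function(records, grns, contrast, k_up = 10L, k_down = 10L) {
  assert_cols(records, c("grn_id", "condition", "N"), "integrity records")
  assert_cols(grns, c("grn_id", "motif_type"), "motif table")
  m <- contrast_rfc(records, contrast)
  m <- merge(m, grns[, c("grn_id", "motif_type")], by = "grn_id")
  m <- m[!is.na(m$direction), , drop = FALSE]

  pick <- function(d, direction, k) {
    dd <- d[d$direction == direction, , drop = FALSE]
    ord <- if (direction == "UP") order(-dd$rfc, dd$grn_id)
           else order(dd$rfc, dd$grn_id)
    dd <- dd[ord, , drop = FALSE]
    if (nrow(dd) < k)
      warnf("only %d %s candidate(s) for motif type %s in %s (requested %d)",
            nrow(dd), direction, dd$motif_type[1] %||% "?", contrast, k)
    dd <- head(dd, k)
    if (nrow(dd)) dd$rank <- seq_len(nrow(dd))
    else dd$rank <- integer(0)
    dd
  }
  per_type <- lapply(split(m, m$motif_type), function(d)
    rbind(pick(d, "UP", k_up), pick(d, "DOWN", k_down)))
  out <- do.call(rbind, per_type)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(grn_id = character(), motif_type = character(),
                      contrast = character(), rfc = numeric(),
                      direction = character(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  out$contrast <- contrast
  out <- out[, c("grn_id", "motif_type", "contrast", "rfc", "direction", "rank")]
  rownames(out) <- NULL
  out
}

#' Top selections across all three disease contrasts
#'
#' Convenience wrapper running [rank_and_select()] for RRMS, PPMS and SPMS
#' versus control and binding the results.
#'
#' @inheritParams rank_and_select
#' @return Row-bound data.frame over the three contrasts.
#' @export
rank_all_contrasts <- function(records, grns, k_up = 10L, k_down = 10L) {
  do.call(rbind, lapply(CONTRASTS, function(ct)
    rank_and_select(records, grns, ct, k_up, k_down)))
}

#' Common and unique selected motifs across contrasts
#'
#' For each motif type, partitions the selected motif ids into the seven
#' Venn regions over the three disease contrasts.
#'
#' @param selections data.frame from [rank_all_contrasts()] (or row-bound
#'   [rank_and_select()] results covering all three contrasts).
#' @return Named list per motif type; each element is a list of id vectors
#'   with names `RRMS_only`, `PPMS_only`, `SPMS_only`, `RRMS_PPMS`,
#'   `RRMS_SPMS`, `PPMS_SPMS`, `all_three`.
#' @export
overlap_summary <- function(selections) {
  assert_cols(selections, c("grn_id", "motif_type", "contrast"), "selections")
  missing <- setdiff(CONTRASTS, unique(selections$contrast))
  if (length(missing))
    stopf("selections lack contrast(s): %s", paste(missing, collapse = ", "))
  regions_of <- function(d) {
    s <- lapply(CONTRASTS, function(ct) unique(d$grn_id[d$contrast == ct]))
    names(s) <- MS_CONDITIONS
    r <- s$RRMS; p <- s$PPMS; q <- s$SPMS
    list(
      RRMS_only = setdiff(r, union(p, q)),
      PPMS_only = setdiff(p, union(r, q)),
      SPMS_only = setdiff(q, union(r, p)),
      RRMS_PPMS = setdiff(intersect(r, p), q),
      RRMS_SPMS = setdiff(intersect(r, q), p),
      PPMS_SPMS = setdiff(intersect(p, q), r),
      all_three = Reduce(intersect, list(r, p, q)))
  }
  lapply(split(selections, selections$motif_type), regions_of)
}
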