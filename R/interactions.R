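# Regulatory interaction catalog: normalization, evidence filtering,
# feed-forward / feedback tagging.
#
# An interaction table is a data.frame with columns
#   source, source_class, target, target_class, tfbs_z, mem_p, cometa_score
# where an NA evidence cell means that evidence type does not apply to (or
# was not available for) the edge. Valid edge kinds are TF->GENE, TF->MIRNA,
# MIRNA->TF and MIRNA->GENE.

INTERACTION_COLS <- c("source", "source_class", "target", "target_class",
                      "tfbs_z", "mem_p", "cometa_score")

edge_kind <- function(source_class, target_class) {
  paste0(source_class, ">", target_class)
}
VALID_KINDS <- c("TF>GENE", "TF>MIRNA", "MIRNA>TF", "MIRNA>GENE")

#' Read an interaction edge table from TSV
#'
#' Columns: `source`, `source_class`, `target`, `target_class`, `tfbs_z`,
#' `mem_p`, `cometa_score`; empty evidence cells are read as NA (absent).
#'
#' @param path TSV file path.
#' @return data.frame of interactions.
#' @export
read_interactions <- function(path) {
  df <- read_tsv(path)
  assert_cols(df, c("source", "target"), "interaction file")
  for (col in c("tfbs_z", "mem_p", "cometa_score"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  df
}

#' Normalize interaction symbols against a lexicon
#'
#' Rewrites aliases to official symbols, assigns entity classes from the
#' lexicon, drops edges with endpoints absent from the lexicon or with an
#' invalid edge kind (only TF->gene, TF->miRNA, miRNA->TF and miRNA->gene
#' are regulatory edges here), removes self-edges, and collapses exact
#' duplicate (source, target) edges keeping the strongest evidence per
#' field: largest |Z|, smallest MEM p, largest CoMeTa score.
#'
#' @param raw_edges data.frame with at least `source` and `target` columns;
#'   evidence columns `tfbs_z`, `mem_p`, `cometa_score` are optional.
#' @param lexicon a [grn_lexicon()].
#' @return data.frame of normalized interactions with attribute `drops`, a
#'   named integer vector counting dropped rows by reason
#'   (`unknown_symbol`, `invalid_kind`, `self_edge`, `duplicate`).
#' @export
normalize_symbols <- function(raw_edges, lexicon) {
  assert_cols(raw_edges, c("source", "target"), "edge table")
  stopifnot(inherits(lexicon, "grn_lexicon"))
  df <- as.data.frame(raw_edges)
  for (col in c("tfbs_z", "mem_p", "cometa_score"))
    if (!col %in% names(df)) df[[col]] <- NA_real_

  src <- resolve_symbols(df$source, lexicon)
  tgt <- resolve_symbols(df$target, lexicon)
  known <- !is.na(src) & !is.na(tgt)
  n_unknown <- sum(!known)

  src <- src[known]; tgt <- tgt[known]; df <- df[known, , drop = FALSE]
  scls <- entity_class(src, lexicon)
  tcls <- entity_class(tgt, lexicon)
  valid <- edge_kind(scls, tcls) %in% VALID_KINDS
  n_invalid <- sum(!valid)
  src <- src[valid]; tgt <- tgt[valid]; df <- df[valid, , drop = FALSE]
  scls <- scls[valid]; tcls <- tcls[valid]

  selfy <- src == tgt
  n_self <- sum(selfy)
  src <- src[!selfy]; tgt <- tgt[!selfy]; df <- df[!selfy, , drop = FALSE]
  scls <- scls[!selfy]; tcls <- tcls[!selfy]

  dt <- data.table::data.table(
    source = src, source_class = scls, target = tgt, target_class = tcls,
    tfbs_z = as.numeric(df$tfbs_z), mem_p = as.numeric(df$mem_p),
    cometa_score = as.numeric(df$cometa_score))
  n_before <- nrow(dt)
  best_abs <- function(x) if (all(is.na(x))) NA_real_ else x[which.max(abs(x))]
  min_na <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  max_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  out <- dt[, list(source_class = source_class[1L],
                   target_class = target_class[1L],
                   tfbs_z = best_abs(tfbs_z),
                   mem_p = min_na(mem_p),
                   cometa_score = max_na(cometa_score)),
            by = c("source", "target")]
  data.table::setcolorder(out, INTERACTION_COLS)
  n_dup <- n_before - nrow(out)

  drops <- c(unknown_symbol = n_unknown, invalid_kind = n_invalid,
             self_edge = n_self, duplicate = n_dup)
  if (sum(drops) > 0)
    msgf("normalize_symbols: dropped %d row(s) (%s)", sum(drops),
         paste(names(drops)[drops > 0], drops[drops > 0],
               sep = "=", collapse = ", "))
  out <- as.data.frame(out)
  attr(out, "drops") <- drops
  out
}

#' Evidence-filter an interaction table
#'
#' An edge is retained iff every evidence field that is present passes its
#' threshold: TFBS Z-score `>= z_cut`, MEM co-expression p-value
#' `<= mem_cut`, CoMeTa score `>= cometa_cut` (all boundaries inclusive).
#' Edges with no evidence field present are dropped.
#'
#' @param catalog data.frame of interactions (see [normalize_symbols()]).
#' @param z_cut TFBS Z-score cut-off; default 2.33.
#' @param mem_cut MEM p-value cut-off in (0, 1]; default 0.05.
#' @param cometa_cut CoMeTa score cut-off, non-negative; default 4.
#' @return The retained subset, with attribute `n_dropped`.
#' @export
filter_evidence <- function(catalog, z_cut = 2.33, mem_cut = 0.05,
                            cometa_cut = 4) {
  assert_cols(catalog, INTERACTION_COLS, "interaction table")
  if (!is.finite(z_cut) || !is.finite(mem_cut) || !is.finite(cometa_cut))
    stopf("evidence thresholds must be finite")
  if (mem_cut <= 0 || mem_cut > 1)
    stopf("mem_cut must lie in (0, 1], got %g", mem_cut)
  if (cometa_cut < 0)
    stopf("cometa_cut must be non-negative, got %g", cometa_cut)

  z_ok <- is.na(catalog$tfbs_z) | catalog$tfbs_z >= z_cut
  p_ok <- is.na(catalog$mem_p) | catalog$mem_p <= mem_cut
  c_ok <- is.na(catalog$cometa_score) | catalog$cometa_score >= cometa_cut
  any_evidence <- !(is.na(catalog$tfbs_z) & is.na(catalog$mem_p) &
                      is.na(catalog$cometa_score))
  keep <- z_ok & p_ok & c_ok & any_evidence
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Tag feedback pairs and feed-forward edges
#'
#' A (TF, miRNA) pair in which the TF regulates the miRNA *and* the miRNA
#' regulates the TF is a feedback (FB) pair; every other edge — including
#' all TF->gene and miRNA->gene edges and unreciprocated TF–miRNA edges —
#' is feed-forward (FF).
#'
#' @param interactions normalized interaction data.frame.
#' @return An object of class `interaction_catalog`: list with
#'   `interactions` (the input plus a `loop_class` column, `"FB"`/`"FF"`),
#'   `fb_pairs` (data.frame: tf, mirna) and `ff_edges` (the FF subset).
#' @export
tag_fb_ff <- function(interactions) {
  assert_cols(interactions, c("source", "source_class", "target", "target_class"),
              "interaction table")
  kind <- edge_kind(interactions$source_class, interactions$target_class)
  tm_key <- ifelse(kind == "TF>MIRNA",
                   paste(interactions$source, interactions$target),
                   ifelse(kind == "MIRNA>TF",
                          paste(interactions$target, interactions$source), NA))
  is_tm <- kind == "TF>MIRNA"
  is_mt <- kind == "MIRNA>TF"
  fb_keys <- intersect(tm_key[is_tm], tm_key[is_mt])
  loop_class <- ifelse(!is.na(tm_key) & tm_key %in% fb_keys, "FB", "FF")

  out <- interactions
  out$loop_class <- loop_class
  fb_pairs <- unique(data.frame(
    tf = sub(" .*$", "", fb_keys),
    mirna = sub("^[^ ]+ ", "", fb_keys),
    stringsAsFactors = FALSE))
  fb_pairs <- fb_pairs[order(fb_pairs$tf, fb_pairs$mirna), , drop = FALSE]
  rownames(fb_pairs) <- NULL
  structure(list(interactions = out,
                 fb_pairs = fb_pairs,
                 ff_edges = out[out$loop_class == "FF", , drop = FALSE]),
            class = "interaction_catalog")
}

#' @export
print.interaction_catalog <- function(x, ...) {
  cat(sprintf("interaction_catalog: %d edges (%d FF, %d in %d FB pairs)\n",
              nrow(x$interactions), nrow(x$ff_edges),
              nrow(x$interactions) - nrow(x$ff_edges), nrow(x$fb_pairs)))
  invisible(x)
}
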