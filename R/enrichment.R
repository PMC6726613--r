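# Pathway assignment per motif (intersection of the three components'
# annotations) and hypergeometric over-representation.

#' Read pathway annotations from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated `name`, `description`,
#' then member gene symbols. Pathways duplicated by exact name are
#' collapsed to the first occurrence (exact-name deduplication); empty
#' member sets are dropped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (pathway -> member symbols,
#'   uppercase).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    warnf("read_gmt: dropped %d pathway line(s) with no members", sum(short))
  parts <- parts[!short]
  sets <- lapply(parts, function(p) unique(canon_symbol(p[-(1:2)])))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets <- sets[lengths(sets) > 0]
  sets[!duplicated(names(sets))]
}

#' Read a miRNA -> target gene map from TSV
#'
#' Columns `mirna`, `target`.
#'
#' @param path TSV file path.
#' @return Named list: miRNA symbol -> character vector of target genes.
#' @export
read_mirna_targets <- function(path) {
  df <- read_tsv(path)
  assert_cols(df, c("mirna", "target"), "miRNA target map")
  split(canon_symbol(df$target), canon_symbol(df$mirna))
}

#' Pathway annotations of one motif component
#'
#' TFs and genes map to the pathways that contain the symbol; a miRNA maps
#' to the union of pathways containing any of its target genes (the
#' standard indirect annotation of non-coding regulators).
#'
#' @param symbol entity symbol.
#' @param role `"TF"`, `"GENE"` or `"MIRNA"`.
#' @param annotations named list of pathway member sets (see [read_gmt()]).
#' @param mirna_targets named list miRNA -> target genes; required for the
#'   MIRNA role. A miRNA absent from the map yields an empty set with a
#'   warning.
#' @return Character vector of pathway ids.
#' @export
annotate_entity <- function(symbol, role = c("TF", "GENE", "MIRNA"),
                            annotations, mirna_targets = NULL) {
  role <- match.arg(role)
  symbol <- canon_symbol(symbol)
  members <- if (role == "MIRNA") {
    if (is.null(mirna_targets))
      stopf("mirna_targets map required to annotate a miRNA")
    tg <- mirna_targets[[symbol]]
    if (is.null(tg)) {
      warnf("miRNA %s absent from target map; empty annotation", symbol)
      return(character())
    }
    tg
  } else symbol
  names(annotations)[vapply(annotations,
                            function(s) any(members %in% s), TRUE)]
}

#' Pathways shared by all three motif components
#'
#' The motif's pathway set is the intersection of its TF's, gene's and
#' miRNA's pathway annotations — the pathways commonly represented by all
#' three components. An empty intersection is a valid result.
#'
#' @param triple one-row data.frame (or list) with `tf`, `gene`, `mirna`.
#' @param annotations named list of pathway member sets.
#' @param mirna_targets named list miRNA -> target genes.
#' @return List with `grn_id`, `pathways` (the intersection) and
#'   `per_entity` (list of the three per-role pathway sets).
#' @export
grn_pathways <- function(triple, annotations, mirna_targets) {
  per <- list(
    tf = annotate_entity(triple$tf, "TF", annotations),
    gene = annotate_entity(triple$gene, "GENE", annotations),
    mirna = annotate_entity(triple$mirna, "MIRNA", annotations, mirna_targets))
  list(grn_id = triple$grn_id %||%
         paste(triple$tf, triple$gene, triple$mirna, sep = "_"),
       pathways = Reduce(intersect, per),
       per_entity = per)
}

#' Hypergeometric pathway over-representation
#'
#' One-sided hypergeometric tail (probability of an overlap at least as
#' large as observed) per pathway, against a fixed gene universe; raw
#' p-values, no multiple-testing correction by default (Benjamini-Hochberg
#' available via `adjust`). Pathways with p below `p_cut` are returned,
#' sorted by p then pathway id.
#'
#' @param query_genes character vector, must be a subset of `universe`.
#' @param annotations named list of pathway member sets.
#' @param universe character vector of all assayable symbols.
#' @param p_cut retention cut-off (strict: p < p_cut); default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `pathway_id`, `overlap`, `pathway_size`, `p` (and
#'   `p_adj` when adjusted; the cut-off then applies to `p_adj`).
#' @export
overrepresentation <- function(query_genes, annotations, universe,
                               p_cut = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  universe <- unique(canon_symbol(universe))
  if (!length(universe)) stopf("universe must be non-empty")
  query <- unique(canon_symbol(query_genes))
  outside <- setdiff(query, universe)
  if (length(outside))
    stopf("query gene(s) outside the universe: %s",
          paste(head(outside, 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(annotations), function(pw) {
    memb <- intersect(annotations[[pw]], universe)
    K <- length(memb)
    k <- length(intersect(query, memb))
    # P(X >= k) for X ~ Hypergeometric(N, K, n)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pw, overlap = k, pathway_size = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(pathway_id = character(), overlap = integer(),
                      pathway_size = integer(), p = numeric(),
                      stringsAsFactors = FALSE))
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    keep <- out$p_adj < p_cut
  } else keep <- out$p < p_cut
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
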