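# Enumeration and classification of (TF, gene, miRNA) regulatory motifs.
#
# Edge codes within a trio:
#   TG = TF -> gene, TM = TF -> miRNA, MT = miRNA -> TF, MG = miRNA -> gene.
# Motif types:
#   CL1  closed loop with reciprocal TF <=> miRNA regulators (all 4 edges)
#   CL2  closed loop with a single TF-miRNA edge (either direction)
#   G    common-gene motif: TF and miRNA both regulate the gene, no
#        TF-miRNA edge
#   TFC  common-TF motif: the TF regulates both the gene and the miRNA
#        (no miRNA -> gene edge)
#   MIR  common-miRNA motif: the miRNA regulates both the TF and the gene
#        (no TF -> gene edge)
# Precedence CL1 > CL2 > G > TFC > MIR makes the classification a partition.

classify_motif_flags <- function(tg, tm, mt, mg) {
  out <- rep(NA_character_, length(tg))
  out[mt & mg & !tg] <- "MIR"
  out[tg & tm & !mg] <- "TFC"
  out[tg & mg] <- "G"
  out[tg & mg & (tm | mt)] <- "CL2"
  out[tg & mg & tm & mt] <- "CL1"
  out
}

#' Classify a trio's edge pattern into a motif type
#'
#' @param edges character vector, a subset of `c("TG","TM","MT","MG")`
#'   (TG = TF->gene, TM = TF->miRNA, MT = miRNA->TF, MG = miRNA->gene).
#' @return One of `"CL1"`, `"CL2"`, `"G"`, `"TFC"`, `"MIR"`, or `NA` when
#'   the pattern does not form a three-node motif (a valid outcome).
#' @examples
#' classify_motif(c("TG", "MG"))                  # "G"
#' classify_motif(c("TG", "TM", "MT", "MG"))      # "CL1"
#' classify_motif("TM")                           # NA
#' @export
classify_motif <- function(edges) {
  bad <- setdiff(edges, EDGE_CODES)
  if (length(bad)) stopf("unknown edge code(s): %s", paste(bad, collapse = ", "))
  classify_motif_flags("TG" %in% edges, "TM" %in% edges,
                       "MT" %in% edges, "MG" %in% edges)
}

# Split an interaction table into the four per-kind edge tables.
split_edge_kinds <- function(edges) {
  kind <- edge_kind(edges$source_class, edges$target_class)
  list(
    TG = unique(data.table::data.table(tf = edges$source[kind == "TF>GENE"],
                                       gene = edges$target[kind == "TF>GENE"])),
    TM = unique(data.table::data.table(tf = edges$source[kind == "TF>MIRNA"],
                                       mirna = edges$target[kind == "TF>MIRNA"])),
    MT = unique(data.table::data.table(mirna = edges$source[kind == "MIRNA>TF"],
                                       tf = edges$target[kind == "MIRNA>TF"])),
    MG = unique(data.table::data.table(mirna = edges$source[kind == "MIRNA>GENE"],
                                       gene = edges$target[kind == "MIRNA>GENE"])))
}

#' Enumerate classified (TF, gene, miRNA) triples
#'
#' Every trio whose induced edge subset classifies to a motif type appears
#' exactly once; classification follows [classify_motif()]. The result is
#' independent of input edge order (rows are sorted by `grn_id`).
#'
#' @param catalog an `interaction_catalog` from [tag_fb_ff()] or a plain
#'   interaction data.frame of retained edges.
#' @return data.frame with columns `grn_id` (`"TF_gene_miRNA"`), `tf`,
#'   `gene`, `mirna`, `edges` (comma-joined codes) and `motif_type`.
#' @export
enumerate_triples <- function(catalog) {
  edges <- if (inherits(catalog, "interaction_catalog")) catalog$interactions
           else as.data.frame(catalog)
  if (!nrow(edges)) {
    return(data.frame(grn_id = character(), tf = character(),
                      gene = character(), mirna = character(),
                      edges = character(), motif_type = character(),
                      stringsAsFactors = FALSE))
  }
  assert_cols(edges, c("source", "source_class", "target", "target_class"),
              "interaction table")
  ek <- split_edge_kinds(edges)

  # Any classifiable trio must contain one of the three two-edge cores:
  # {TG, MG} (common gene), {TG, TM} (common TF), {MT, MG} (common miRNA).
  cand <- list()
  if (nrow(ek$TG) && nrow(ek$MG))
    cand$g <- merge(ek$TG, ek$MG, by = "gene", allow.cartesian = TRUE)
  if (nrow(ek$TG) && nrow(ek$TM))
    cand$t <- merge(ek$TG, ek$TM, by = "tf", allow.cartesian = TRUE)
  if (nrow(ek$MT) && nrow(ek$MG))
    cand$m <- merge(ek$MT, ek$MG, by = "mirna", allow.cartesian = TRUE)
  cand <- lapply(cand, function(d) d[, c("tf", "gene", "mirna"), with = FALSE])
  if (!length(cand)) {
    return(data.frame(grn_id = character(), tf = character(),
                      gene = character(), mirna = character(),
                      edges = character(), motif_type = character(),
                      stringsAsFactors = FALSE))
  }
  trio <- unique(data.table::rbindlist(cand))

  has_edge <- function(tab, keys) {
    if (!nrow(tab)) return(rep(FALSE, nrow(trio)))
    do.call(paste, c(as.list(trio[, keys, with = FALSE]), sep = "\r")) %in%
      do.call(paste, c(as.list(tab[, keys, with = FALSE]), sep = "\r"))
  }
  tg <- has_edge(ek$TG, c("tf", "gene"))
  tm <- has_edge(ek$TM, c("tf", "mirna"))
  mt <- has_edge(ek$MT, c("mirna", "tf"))
  mg <- has_edge(ek$MG, c("mirna", "gene"))

  type <- classify_motif_flags(tg, tm, mt, mg)
  keep <- !is.na(type)
  trio <- trio[keep]
  edge_str <- apply(cbind(ifelse(tg, "TG", NA), ifelse(tm, "TM", NA),
                          ifelse(mt, "MT", NA), ifelse(mg, "MG", NA))[keep, ,
                                                                      drop = FALSE],
                    1L, function(z) paste(z[!is.na(z)], collapse = ","))
  out <- data.frame(
    grn_id = paste(trio$tf, trio$gene, trio$mirna, sep = "_"),
    tf = trio$tf, gene = trio$gene, mirna = trio$mirna,
    edges = edge_str, motif_type = type[keep], stringsAsFactors = FALSE)
  out <- out[order(out$grn_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif census
#'
#' Counts triples per motif type. The two closed-loop subclasses are
#' reported both separately (`CL1`, `CL2`) and together (`cl`); per-type
#' counts sum exactly to the total.
#'
#' @param triples data.frame from [enumerate_triples()].
#' @return Named list: `cl`, `g`, `tf`, `mir`, `CL1`, `CL2`, `total`.
#' @export
motif_census <- function(triples) {
  assert_cols(triples, "motif_type", "triple table")
  n <- function(t) sum(triples$motif_type == t)
  list(cl = n("CL1") + n("CL2"), g = n("G"), tf = n("TFC"), mir = n("MIR"),
       CL1 = n("CL1"), CL2 = n("CL2"), total = nrow(triples))
}
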