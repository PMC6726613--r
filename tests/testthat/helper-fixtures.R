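# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (row-by-row, O(E^2), exhaustive enumeration) and never call the
# code paths they check.

tiny_lexicon <- function() {
  grn_lexicon(
    symbol = c("STAT3", "POU3F2", "MEIS1", "TCF4",
               "OGG1", "CDK6", "CASC3", "FMR1", "CAT",
               "HSA-MIR-298", "HSA-MIR-590-3P", "HSA-MIR-1261", "HSA-MIR-301B"),
    class = c(rep("TF", 4), rep("GENE", 5), rep("MIRNA", 4)),
    aliases = list(character(), "BRN2", character(), "E2-2",
                   character(), character(), character(), character(),
                   character(), "MIR298", character(), character(),
                   character()))
}

edge_row <- function(source, source_class, target, target_class,
                     tfbs_z = NA_real_, mem_p = NA_real_,
                     cometa_score = NA_real_) {
  data.frame(source = source, source_class = source_class, target = target,
             target_class = target_class, tfbs_z = tfbs_z, mem_p = mem_p,
             cometa_score = cometa_score, stringsAsFactors = FALSE)
}

write_tmp_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

# random interaction table over small symbol pools (symbols drawn uppercase
# so no lexicon normalization is needed)
random_edges <- function(n_tf, n_gene, n_mirna, p_edge, seed) {
  set.seed(seed)
  tfs <- sprintf("T%02d", seq_len(n_tf))
  genes <- sprintf("G%02d", seq_len(n_gene))
  mirs <- sprintf("M%02d", seq_len(n_mirna))
  pick <- function(srcs, scls, tgts, tcls) {
    grid <- expand.grid(source = srcs, target = tgts,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    grid <- grid[stats::runif(nrow(grid)) < p_edge, , drop = FALSE]
    if (!nrow(grid)) return(NULL)
    edge_row(grid$source, scls, grid$target, tcls)
  }
  edges <- rbind(pick(tfs, "TF", genes, "GENE"),
                 pick(tfs, "TF", mirs, "MIRNA"),
                 pick(mirs, "MIRNA", tfs, "TF"),
                 pick(mirs, "MIRNA", genes, "GENE"))
  list(edges = edges, tfs = tfs, genes = genes, mirs = mirs)
}

# hand-frozen truth table for all 16 edge subsets (independent of
# classify_motif); names are comma-joined sorted edge codes
motif_truth_table <- setNames(
  c(NA, NA, NA, NA, NA,
    "TFC", NA, "G", NA, NA, "MIR",
    "TFC", "CL2", "CL2", "MIR", "CL1"),
  c("", "TG", "TM", "MT", "MG",
    "TG,TM", "TG,MT", "TG,MG", "TM,MT", "TM,MG", "MT,MG",
    "TG,TM,MT", "TG,TM,MG", "TG,MT,MG", "TM,MT,MG", "TG,TM,MT,MG"))

motif_truth <- function(edges) {
  key <- paste(intersect(c("TG", "TM", "MT", "MG"), edges), collapse = ",")
  unname(motif_truth_table[match(key, names(motif_truth_table))])
}

# cubic brute-force triple enumeration using the frozen truth table
oracle_enumerate <- function(edges, tfs, genes, mirs) {
  has <- function(s, t) any(edges$source == s & edges$target == t)
  out <- list()
  for (tf in tfs) for (g in genes) for (m in mirs) {
    codes <- c("TG", "TM", "MT", "MG")[c(has(tf, g), has(tf, m),
                                         has(m, tf), has(m, g))]
    ty <- motif_truth(codes)
    if (!is.na(ty))
      out[[length(out) + 1L]] <- data.frame(
        grn_id = paste(tf, g, m, sep = "_"), tf = tf, gene = g, mirna = m,
        motif_type = ty, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(grn_id = character(), tf = character(),
                      gene = character(), mirna = character(),
                      motif_type = character()))
  res <- do.call(rbind, out)
  res[order(res$grn_id), , drop = FALSE]
}

# O(E^2) reciprocal-pair scan
oracle_fb_pairs <- function(edges) {
  fb <- character()
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (e$source_class == "TF" && e$target_class == "MIRNA") {
      recip <- any(edges$source == e$target & edges$target == e$source)
      if (recip) fb <- c(fb, paste(e$source, e$target))
    }
  }
  sort(unique(fb))
}

# exhaustive hypergeometric upper tail: P(overlap >= k) by direct
# enumeration of the hypergeometric mass
oracle_hyper_tail <- function(k, K, N, n) {
  js <- max(0, k):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# textbook pooled-variance two-sample t
oracle_t2 <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(abs(t), na + nb - 2, lower.tail = FALSE)
  list(t = t, p = p)
}

# second, independently written evaluation of the integrity formula
oracle_integrity <- function(e_tf, e_gene, e_mir,
                             r_tf = 1, r_gene = 0.75, r_mir = 0.5) {
  terms <- c(r_tf * e_tf * r_mir * e_mir,
             r_mir * e_mir * r_gene * e_gene,
             r_gene * e_gene * r_tf * e_tf)
  sum(terms)
}

# a minimal, positive 4-condition expression object; fixtures are
# intentionally tiny, so the <3-samples-per-condition warning is silenced
toy_expression <- function(values, n_per_cond = c(3, 3, 3, 3)) {
  conds <- rep(c("CONTROL", "RRMS", "PPMS", "SPMS"), n_per_cond)
  ids <- paste0("S", seq_along(conds))
  colnames(values) <- ids
  suppressWarnings(grn_expression(values, stats::setNames(conds, ids)))
}
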