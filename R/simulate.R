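# Seed-deterministic generators for every input the pipeline consumes,
# with ground truth recorded alongside. The expression generator emulates
# the shape of the paired gene/miRNA microarray cohort the pipeline was
# designed for: the same individuals profiled on both platforms, condition
# groups CONTROL/RRMS/PPMS/SPMS with default sizes 14/7/6/6, log-normal
# intensities, and planted differentially regulated motifs.

#' Generator configuration
#'
#' @param n_tf,n_gene,n_mirna entity pool sizes.
#' @param edge_probs per-kind background edge probabilities, named
#'   `TG`, `TM`, `MT`, `MG`.
#' @param planted_motifs counts of planted motifs per type, named `cl`,
#'   `g`, `tf`, `mir` (cl motifs are planted as full reciprocal closed
#'   loops, i.e. CL1).
#' @param n_samples samples per condition, named by condition; default
#'   `c(CONTROL = 14, RRMS = 7, PPMS = 6, SPMS = 6)`, the array cohort
#'   shape this generator emulates.
#' @param effect_fold default multiplicative perturbation applied to all
#'   three components of a perturbed motif; default 2.
#' @param noise_sd log-scale (natural log) SD of multiplicative expression
#'   noise; default 0.1.
#' @param background_fail_frac fraction of background edges drawn with
#'   evidence failing the default cut-offs; default 0.3.
#' @param seed integer RNG seed; fixed seed implies identical outputs.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_tf = 40L, n_gene = 80L, n_mirna = 40L,
                             edge_probs = c(TG = 0.02, TM = 0.01,
                                            MT = 0.01, MG = 0.02),
                             planted_motifs = c(cl = 5L, g = 5L,
                                                tf = 5L, mir = 5L),
                             n_samples = c(CONTROL = 14L, RRMS = 7L,
                                           PPMS = 6L, SPMS = 6L),
                             effect_fold = 2, noise_sd = 0.1,
                             background_fail_frac = 0.3, seed = 1L) {
  stopifnot(all(edge_probs >= 0 & edge_probs <= 1),
            all(c("TG", "TM", "MT", "MG") %in% names(edge_probs)),
            all(c("cl", "g", "tf", "mir") %in% names(planted_motifs)),
            all(planted_motifs >= 0),
            all(CONDITIONS %in% names(n_samples)), all(n_samples >= 1),
            effect_fold > 0, noise_sd >= 0,
            background_fail_frac >= 0, background_fail_frac <= 1,
            length(seed) == 1L, is.finite(seed))
  n_planted <- sum(planted_motifs)
  if (n_tf < n_planted || n_gene < n_planted || n_mirna < n_planted)
    stopf("entity pools must hold at least %d (one node per planted motif)",
          n_planted)
  structure(list(n_tf = n_tf, n_gene = n_gene, n_mirna = n_mirna,
                 edge_probs = edge_probs, planted_motifs = planted_motifs,
                 n_samples = n_samples, effect_fold = effect_fold,
                 noise_sd = noise_sd,
                 background_fail_frac = background_fail_frac,
                 seed = as.integer(seed)),
            class = "generator_config")
}

sim_symbols <- function(cfg) {
  list(tf = sprintf("TF%03d", seq_len(cfg$n_tf)),
       gene = sprintf("GENE%03d", seq_len(cfg$n_gene)),
       mirna = sprintf("HSA-MIR-%04d", seq_len(cfg$n_mirna)))
}

# evidence draws; pass/fail relative to the default cut-offs Z>=2.33,
# p<=0.05, CoMeTa>=4
draw_tg_evidence <- function(n, pass) {
  data.frame(tfbs_z = ifelse(pass, runif(n, 2.33, 6), runif(n, 0, 2.32)),
             mem_p = ifelse(pass, runif(n, 1e-4, 0.05), runif(n, 0.051, 0.5)),
             cometa_score = NA_real_)
}
draw_cometa_evidence <- function(n, pass) {
  data.frame(tfbs_z = NA_real_, mem_p = NA_real_,
             cometa_score = ifelse(pass, runif(n, 4, 10), runif(n, 0, 3.9)))
}

#' Generate a synthetic interaction network with planted motifs
#'
#' Plants the configured number of motifs of each type on dedicated,
#' non-overlapping node triples (so background edges cannot change their
#' type), with evidence values guaranteed to pass the default cut-offs.
#' Background edges are drawn independently per kind among the remaining
#' nodes; a configurable fraction carries failing evidence.
#'
#' @param cfg a [generator_config()].
#' @return List: `lexicon` (a [grn_lexicon()]; every 5th symbol also gets
#'   an `<symbol>-ALT` alias), `interactions` (data.frame in the standard
#'   interaction layout), `truth` (data.frame of planted motifs: `grn_id`,
#'   `tf`, `gene`, `mirna`, `motif_type`, `edges`).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  sym <- sim_symbols(cfg)

  pm <- cfg$planted_motifs
  n_planted <- sum(pm)
  types <- rep(c("CL1", "G", "TFC", "MIR"), times = pm[c("cl", "g", "tf", "mir")])
  edge_sets <- list(CL1 = c("TG", "TM", "MT", "MG"), G = c("TG", "MG"),
                    TFC = c("TG", "TM"), MIR = c("MT", "MG"))
  truth <- data.frame(
    tf = sym$tf[seq_len(n_planted)],
    gene = sym$gene[seq_len(n_planted)],
    mirna = sym$mirna[seq_len(n_planted)],
    motif_type = types, stringsAsFactors = FALSE)
  truth$grn_id <- paste(truth$tf, truth$gene, truth$mirna, sep = "_")
  truth$edges <- vapply(truth$motif_type,
                        function(t) paste(edge_sets[[t]], collapse = ","), "")
  truth <- truth[, c("grn_id", "tf", "gene", "mirna", "motif_type", "edges")]

  planted_edges <- do.call(rbind, lapply(seq_len(n_planted), function(i) {
    codes <- edge_sets[[truth$motif_type[i]]]
    src <- c(TG = truth$tf[i], TM = truth$tf[i],
             MT = truth$mirna[i], MG = truth$mirna[i])[codes]
    tgt <- c(TG = truth$gene[i], TM = truth$mirna[i],
             MT = truth$tf[i], MG = truth$gene[i])[codes]
    scls <- c(TG = "TF", TM = "TF", MT = "MIRNA", MG = "MIRNA")[codes]
    tcls <- c(TG = "GENE", TM = "MIRNA", MT = "TF", MG = "GENE")[codes]
    ev <- do.call(rbind, lapply(codes, function(cd)
      if (cd == "TG") draw_tg_evidence(1L, TRUE)
      else draw_cometa_evidence(1L, TRUE)))
    cbind(data.frame(source = unname(src), source_class = unname(scls),
                     target = unname(tgt), target_class = unname(tcls),
                     stringsAsFactors = FALSE), ev)
  }))

  # background edges among non-reserved nodes only
  bg_tf <- sym$tf[-seq_len(n_planted)]
  bg_gene <- sym$gene[-seq_len(n_planted)]
  bg_mirna <- sym$mirna[-seq_len(n_planted)]
  bg_kind <- function(srcs, tgts, prob, scls, tcls, tg_like) {
    if (!length(srcs) || !length(tgts) || prob <= 0) return(NULL)
    grid <- expand.grid(source = srcs, target = tgts,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) < prob, , drop = FALSE]
    if (!nrow(grid)) return(NULL)
    pass <- runif(nrow(grid)) >= cfg$background_fail_frac
    ev <- if (tg_like) draw_tg_evidence(nrow(grid), pass)
          else draw_cometa_evidence(nrow(grid), pass)
    cbind(data.frame(source = grid$source, source_class = scls,
                     target = grid$target, target_class = tcls,
                     stringsAsFactors = FALSE), ev)
  }
  background <- rbind(
    bg_kind(bg_tf, bg_gene, cfg$edge_probs[["TG"]], "TF", "GENE", TRUE),
    bg_kind(bg_tf, bg_mirna, cfg$edge_probs[["TM"]], "TF", "MIRNA", FALSE),
    bg_kind(bg_mirna, bg_tf, cfg$edge_probs[["MT"]], "MIRNA", "TF", FALSE),
    bg_kind(bg_mirna, bg_gene, cfg$edge_probs[["MG"]], "MIRNA", "GENE", FALSE))

  interactions <- rbind(planted_edges, background)
  rownames(interactions) <- NULL

  all_sym <- c(sym$tf, sym$gene, sym$mirna)
  all_cls <- rep(c("TF", "GENE", "MIRNA"),
                 c(cfg$n_tf, cfg$n_gene, cfg$n_mirna))
  aliases <- rep(list(character()), length(all_sym))
  every5 <- seq(1L, length(all_sym), by = 5L)
  aliases[every5] <- lapply(all_sym[every5], function(s) paste0(s, "-ALT"))
  lexicon <- grn_lexicon(all_sym, all_cls, aliases)

  list(lexicon = lexicon, interactions = interactions, truth = truth)
}

#' Generate paired gene and miRNA expression matrices
#'
#' Baseline intensities are log-normal per entity; components of each
#' planted motif share a per-sample latent factor in every condition so
#' that planted edges survive Pearson co-expression confirmation on
#' controls. Multiplicative log-normal noise (`cfg$noise_sd`, natural-log
#' scale) is applied cell-wise. Perturbations multiply all three
#' components of a motif by a fold in the samples of one condition.
#'
#' @param cfg a [generator_config()].
#' @param network output of [generate_network()].
#' @param perturb optional data.frame with columns `grn_id`, `condition`
#'   (an MS condition), `fold`; components are looked up in
#'   `network$truth`.
#' @param latent_sd SD of the shared latent log-factor inducing
#'   co-expression within planted motifs; default 0.4.
#' @return List: `genes` and `mirnas` ([grn_expression()] objects over the
#'   same sample ids), `samples` (data.frame sample_id, condition),
#'   `perturb` (the applied perturbation table).
#' @export
generate_expression <- function(cfg, network, perturb = NULL,
                                latent_sd = 0.4) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 1L)
  truth <- network$truth
  sample_ids <- unlist(lapply(CONDITIONS, function(cn)
    sprintf("%s_%02d", cn, seq_len(cfg$n_samples[[cn]]))))
  condition <- setNames(rep(CONDITIONS, cfg$n_samples[CONDITIONS]), sample_ids)
  n_s <- length(sample_ids)

  entities <- network$lexicon$table
  n_e <- nrow(entities)
  baseline <- 2^runif(n_e, 5, 10)
  mat <- matrix(baseline, n_e, n_s) *
    exp(matrix(rnorm(n_e * n_s, 0, cfg$noise_sd), n_e, n_s))
  rownames(mat) <- entities$symbol
  colnames(mat) <- sample_ids

  # shared latent factor per planted motif
  if (nrow(truth) && latent_sd > 0) {
    for (i in seq_len(nrow(truth))) {
      z <- rnorm(n_s, 0, latent_sd)
      comp <- c(truth$tf[i], truth$gene[i], truth$mirna[i])
      mat[comp, ] <- mat[comp, , drop = FALSE] *
        matrix(exp(z), 3L, n_s, byrow = TRUE)
    }
  }

  if (!is.null(perturb) && nrow(perturb)) {
    assert_cols(perturb, c("grn_id", "condition", "fold"), "perturbation table")
    unknown <- setdiff(perturb$grn_id, truth$grn_id)
    if (length(unknown))
      stopf("perturbed grn_id(s) not in truth: %s",
            paste(head(unknown, 5), collapse = ", "))
    for (i in seq_len(nrow(perturb))) {
      tr <- truth[truth$grn_id == perturb$grn_id[i], ]
      cols <- condition == perturb$condition[i]
      comp <- c(tr$tf, tr$gene, tr$mirna)
      mat[comp, cols] <- mat[comp, cols, drop = FALSE] * perturb$fold[i]
    }
  }

  is_mir <- entities$class == "MIRNA"
  list(genes = grn_expression(mat[!is_mir, , drop = FALSE], condition),
       mirnas = grn_expression(mat[is_mir, , drop = FALSE], condition),
       samples = data.frame(sample_id = sample_ids,
                            condition = unname(condition),
                            stringsAsFactors = FALSE),
       perturb = perturb)
}

# Pronounceable, symbol-free filler vocabulary.
make_filler_vocab <- function(n, lexicon) {
  syll <- c("ba", "re", "mo", "ti", "lu", "ka", "ne", "so", "vi", "du",
            "pa", "fe", "go", "ri", "zu")
  words <- unique(apply(expand.grid(syll, syll, syll)[seq_len(3 * n), ],
                        1L, paste, collapse = ""))
  words <- words[is.na(resolve_symbols(words, lexicon))]
  head(words, n)
}

#' Generate a synthetic abstract corpus with planted symbol mentions
#'
#' Abstracts are filler text from a symbol-free vocabulary; each planted
#' symbol is inserted as a whole token into one or more abstracts. Ground
#' truth (which symbols were planted where) is attached.
#'
#' @param cfg a [generator_config()].
#' @param lexicon a [grn_lexicon()].
#' @param planted_symbols character vector of symbols to mention.
#' @param n_abstracts number of abstracts; default 50.
#' @param words_per_abstract filler words per abstract; default 30.
#' @param mentions_per_symbol abstracts mentioning each symbol; default 2.
#' @return data.frame `record_id`, `text`, with attribute `truth` (list
#'   symbol -> record ids mentioning it).
#' @export
generate_corpus <- function(cfg, lexicon, planted_symbols,
                            n_abstracts = 50L, words_per_abstract = 30L,
                            mentions_per_symbol = 2L) {
  stopifnot(inherits(cfg, "generator_config"), inherits(lexicon, "grn_lexicon"))
  set.seed(cfg$seed + 2L)
  planted_symbols <- canon_symbol(planted_symbols)
  unknown <- planted_symbols[is.na(resolve_symbols(planted_symbols, lexicon))]
  if (length(unknown))
    stopf("planted symbol(s) not in lexicon: %s",
          paste(head(unknown, 5), collapse = ", "))
  vocab <- make_filler_vocab(200L, lexicon)
  texts <- vapply(seq_len(n_abstracts), function(i)
    paste(sample(vocab, words_per_abstract, replace = TRUE), collapse = " "),
    "")
  ids <- sprintf("PMID%05d", seq_len(n_abstracts))
  truth <- list()
  m <- min(mentions_per_symbol, n_abstracts)
  for (s in planted_symbols) {
    at <- sample.int(n_abstracts, m)
    texts[at] <- paste(texts[at], s)
    truth[[s]] <- ids[sort(at)]
  }
  out <- data.frame(record_id = ids, text = texts, stringsAsFactors = FALSE)
  attr(out, "truth") <- truth
  out
}

#' Write a corpus in the plain-text record format
#'
#' Records separated by blank lines, first line the record id (the format
#' [read_corpus()] reads).
#'
#' @param corpus data.frame `record_id`, `text`.
#' @param path output file.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(paste(corpus$record_id, corpus$text, sep = "\n",
                   collapse = "\n\n"), path)
  invisible(path)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates a qPCR validation cohort (default group sizes 30 controls and
#' 14/13/12 RRMS/PPMS/SPMS). Reference Ct is near-constant (GAPDH for
#' TF/gene targets, U6 for miRNAs); target Ct is baseline plus an optional
#' planted per-group shift (in cycles; a shift of -1 doubles relative
#' expression in expectation) plus Gaussian noise.
#'
#' @param cfg a [generator_config()] (its seed is used, offset by 3).
#' @param target_class named character vector: class (`TF`/`GENE`/`MIRNA`)
#'   per target symbol.
#' @param shifts optional data.frame `target`, `group`, `shift` (cycles,
#'   added to the target Ct in that group).
#' @param group_sizes samples per group; default
#'   `c(CONTROL = 30, RRMS = 14, PPMS = 13, SPMS = 12)`.
#' @param ct_sd measurement noise SD in cycles; default 0.25.
#' @return data.frame `sample_id`, `group`, `target`, `ct_target`,
#'   `ct_reference`, `rel_expr`.
#' @export
generate_ct <- function(cfg, target_class, shifts = NULL,
                        group_sizes = c(CONTROL = 30L, RRMS = 14L,
                                        PPMS = 13L, SPMS = 12L),
                        ct_sd = 0.25) {
  stopifnot(inherits(cfg, "generator_config"),
            all(CONDITIONS %in% names(group_sizes)))
  set.seed(cfg$seed + 3L)
  targets <- canon_symbol(names(target_class))
  cls <- toupper(unname(target_class))
  if (!all(cls %in% ENTITY_CLASSES)) stopf("invalid target class")
  base_ct <- setNames(runif(length(targets), 22, 28), targets)
  ref_base <- ifelse(cls == "MIRNA", 18, 20)  # U6 vs GAPDH
  names(ref_base) <- targets

  rows <- lapply(CONDITIONS, function(gp) {
    n <- group_sizes[[gp]]
    sample_ids <- sprintf("Q_%s_%02d", gp, seq_len(n))
    do.call(rbind, lapply(seq_along(targets), function(j) {
      tg <- targets[j]
      shift <- 0
      if (!is.null(shifts) && nrow(shifts)) {
        hit <- shifts$target == tg & shifts$group == gp
        if (any(hit)) shift <- sum(shifts$shift[hit])
      }
      data.frame(sample_id = sample_ids, group = gp, target = tg,
                 ct_target = base_ct[[tg]] + shift + rnorm(n, 0, ct_sd),
                 ct_reference = ref_base[[tg]] + rnorm(n, 0, ct_sd / 2),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$rel_expr <- relative_expression(out$ct_target, out$ct_reference)
  out
}
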