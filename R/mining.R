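# Dictionary-based mining of disease-associated gene/TF symbols from an
# abstract corpus, and filtering of motifs to mined symbols.

# Whole-token tokenizer: split on anything that is not alphanumeric or a
# hyphen, so "CAT" never matches inside "LOCATION" but "hsa-miR-298"
# survives as one token. Case-insensitive via canonical uppercase.
tokenize_text <- function(text) {
  toks <- strsplit(toupper(text), "[^A-Za-z0-9-]+")
  lapply(toks, function(t) unique(t[nzchar(t)]))
}

#' Read an abstract corpus from plain text
#'
#' Records are separated by blank lines; the first line of each record is
#' its id, the remainder its text.
#'
#' @param path text file path.
#' @return data.frame with columns `record_id`, `text`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grp <- cumsum(c(TRUE, !nzchar(trimws(lines[-length(lines)]))))
  recs <- split(lines, grp)
  recs <- lapply(recs, function(r) r[nzchar(trimws(r))])
  recs <- recs[lengths(recs) > 0]
  data.frame(
    record_id = vapply(recs, `[`, "", 1L),
    text = vapply(recs, function(r) paste(r[-1L], collapse = " "), ""),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Mine gene and TF symbols from an abstract corpus
#'
#' A lexicon symbol is reported iff it, or one of its aliases, occurs as a
#' whole token (case-insensitive) in at least `min_hits` distinct
#' abstracts. Only genes and TFs are mined; miRNA symbols are ignored.
#'
#' @param corpus data.frame with columns `record_id`, `text` (see
#'   [read_corpus()]), or a character vector of abstract texts.
#' @param lexicon a [grn_lexicon()].
#' @param min_hits minimum number of abstracts mentioning the symbol;
#'   default 1.
#' @return Object of class `assoc_lists`: list with `genes` and `tfs`
#'   (character vectors of mined symbols) and `hits` (data.frame: symbol,
#'   class, hit_count for every symbol with at least one hit).
#' @export
mine_symbols <- function(corpus, lexicon, min_hits = 1L) {
  stopifnot(inherits(lexicon, "grn_lexicon"))
  if (is.character(corpus))
    corpus <- data.frame(record_id = as.character(seq_along(corpus)),
                         text = corpus, stringsAsFactors = FALSE)
  assert_cols(corpus, "text", "corpus")
  empty <- function() {
    structure(list(genes = character(), tfs = character(),
                   hits = data.frame(symbol = character(), class = character(),
                                     hit_count = integer(),
                                     stringsAsFactors = FALSE)),
              class = "assoc_lists")
  }
  if (!nrow(corpus)) {
    warnf("empty corpus: returning empty association lists")
    return(empty())
  }
  mined_classes <- c("GENE", "TF")
  toks <- tokenize_text(corpus$text)
  # resolve every token through the alias map, count distinct abstracts
  per_abstract <- lapply(toks, function(t) {
    hit <- lexicon$alias_map[t]
    unique(hit[!is.na(hit)])
  })
  counts <- table(unlist(per_abstract))
  if (!length(counts)) return(empty())
  hits <- data.frame(symbol = names(counts),
                     hit_count = as.integer(counts),
                     stringsAsFactors = FALSE)
  hits$class <- entity_class(hits$symbol, lexicon)
  hits <- hits[hits$class %in% mined_classes, c("symbol", "class", "hit_count")]
  hits <- hits[order(-hits$hit_count, hits$symbol), , drop = FALSE]
  rownames(hits) <- NULL
  kept <- hits[hits$hit_count >= min_hits, , drop = FALSE]
  structure(list(genes = kept$symbol[kept$class == "GENE"],
                 tfs = kept$symbol[kept$class == "TF"],
                 hits = hits),
            class = "assoc_lists")
}

#' @export
print.assoc_lists <- function(x, ...) {
  cat(sprintf("assoc_lists: %d genes, %d TFs mined\n",
              length(x$genes), length(x$tfs)))
  invisible(x)
}

#' Filter motifs to disease-associated components
#'
#' @param triples data.frame from [enumerate_triples()].
#' @param assoc an `assoc_lists` from [mine_symbols()] (or a list with
#'   `genes` and `tfs` character vectors).
#' @param mode `"any"` (default): keep a trio when its gene is in
#'   `assoc$genes` *or* its TF is in `assoc$tfs`; `"both"`: require both.
#' @return The retained subset of `triples`; attribute `retained_by_type`
#'   gives per-motif-type retained counts.
#' @export
filter_grns <- function(triples, assoc, mode = c("any", "both")) {
  mode <- match.arg(mode)
  assert_cols(triples, c("tf", "gene", "motif_type"), "triple table")
  g <- triples$gene %in% assoc$genes
  t <- triples$tf %in% assoc$tfs
  keep <- if (mode == "any") g | t else g & t
  out <- triples[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained_by_type") <-
    table(factor(out$motif_type, levels = MOTIF_TYPES))
  out
}
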