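# Entity lexicon: official symbols, entity classes, alias resolution.

ENTITY_CLASSES <- c("TF", "GENE", "MIRNA")

#' Build an entity lexicon
#'
#' The lexicon maps official symbols (HGNC-style, uppercase) to an entity
#' class (`TF`, `GENE` or `MIRNA`) and resolves aliases to official symbols.
#' Symbol matching is case-insensitive on input; symbols are stored uppercase.
#'
#' @param symbol character vector of official symbols.
#' @param class character vector of entity classes, one of `TF`, `GENE`,
#'   `MIRNA`.
#' @param aliases list of character vectors (or a pipe-separated character
#'   vector) of aliases per symbol; optional.
#' @return An object of class `grn_lexicon`: a list with `table`
#'   (data.frame: symbol, class) and `alias_map` (named character vector
#'   mapping every known name, including the official symbols themselves, to
#'   the official symbol).
#' @details An alias that collides with another entry's official symbol is
#'   dropped with a warning (official symbols take priority). An alias
#'   claimed by two different symbols is kept for the first symbol in input
#'   order, with a warning. Duplicate symbol rows with the same class are
#'   collapsed; duplicate symbols with conflicting classes are an error.
#' @seealso [load_lexicon()]
#' @export
grn_lexicon <- function(symbol, class, aliases = NULL) {
  symbol <- canon_symbol(symbol)
  class <- toupper(trimws(as.character(class)))
  if (length(symbol) != length(class))
    stopf("symbol and class must have equal length")
  bad <- !class %in% ENTITY_CLASSES
  if (any(bad))
    stopf("unknown entity class(es): %s", paste(unique(class[bad]), collapse = ", "))

  if (is.null(aliases)) aliases <- rep(list(character()), length(symbol))
  if (is.character(aliases)) aliases <- strsplit(aliases, "|", fixed = TRUE)
  aliases <- lapply(aliases, function(a) canon_symbol(a[nzchar(trimws(a)) & !is.na(a)]))

  # collapse duplicate symbols; conflicting classes are a hard error
  tab <- data.frame(symbol = symbol, class = class, stringsAsFactors = FALSE)
  cls_per_sym <- tapply(tab$class, tab$symbol, function(x) length(unique(x)))
  conflicts <- names(cls_per_sym)[cls_per_sym > 1L]
  if (length(conflicts))
    stopf("symbol(s) assigned conflicting classes: %s",
          paste(conflicts, collapse = ", "))
  keep <- !duplicated(tab$symbol)
  if (any(!keep)) {
    merged <- lapply(split(aliases, tab$symbol), function(a) unique(unlist(a)))
    tab <- tab[keep, , drop = FALSE]
    aliases <- merged[tab$symbol]
  } else {
    names(aliases) <- tab$symbol
  }

  # alias -> symbol map; official symbols outrank aliases
  alias_sym <- rep(tab$symbol, lengths(aliases[tab$symbol]))
  alias_name <- unlist(aliases[tab$symbol], use.names = FALSE)
  if (length(alias_name)) {
    clash <- alias_name %in% tab$symbol
    if (any(clash)) {
      warnf("dropping %d alias(es) that collide with official symbols: %s",
            sum(clash), paste(unique(alias_name[clash]), collapse = ", "))
      alias_sym <- alias_sym[!clash]
      alias_name <- alias_name[!clash]
    }
    dup <- duplicated(alias_name)
    if (any(dup)) {
      warnf("alias(es) claimed by multiple symbols kept for first claimant: %s",
            paste(unique(alias_name[dup]), collapse = ", "))
      alias_sym <- alias_sym[!dup]
      alias_name <- alias_name[!dup]
    }
  }
  alias_map <- c(setNames(tab$symbol, tab$symbol), setNames(alias_sym, alias_name))

  structure(list(table = tab, alias_map = alias_map), class = "grn_lexicon")
}

#' @export
print.grn_lexicon <- function(x, ...) {
  cnt <- table(factor(x$table$class, levels = ENTITY_CLASSES))
  cat(sprintf("grn_lexicon: %d symbols (%d TF, %d GENE, %d MIRNA), %d aliases\n",
              nrow(x$table), cnt[["TF"]], cnt[["GENE"]], cnt[["MIRNA"]],
              length(x$alias_map) - nrow(x$table)))
  invisible(x)
}

#' Load an entity lexicon from TSV
#'
#' Expects columns `symbol`, `class` (one of TF/GENE/MIRNA) and `aliases`
#' (pipe-separated, may be empty). Malformed rows (empty symbol or unknown
#' class) are skipped and counted; the count is reported as a message and
#' attached as attribute `n_skipped`.
#'
#' @param path TSV file path.
#' @return A [grn_lexicon()] object.
#' @export
load_lexicon <- function(path) {
  df <- read_tsv(path)
  assert_cols(df, c("symbol", "class", "aliases"), "lexicon file")
  sym <- canon_symbol(df$symbol)
  cls <- toupper(trimws(ifelse(is.na(df$class), "", df$class)))
  ok <- nzchar(sym) & !is.na(df$symbol) & cls %in% ENTITY_CLASSES
  if (any(!ok))
    msgf("load_lexicon: skipped %d malformed row(s)", sum(!ok))
  aliases <- ifelse(is.na(df$aliases), "", df$aliases)
  lex <- grn_lexicon(sym[ok], cls[ok], aliases[ok])
  attr(lex, "n_skipped") <- sum(!ok)
  lex
}

#' Resolve names to official symbols
#'
#' @param x character vector of symbols or aliases (case-insensitive).
#' @param lexicon a [grn_lexicon()].
#' @return Character vector of official symbols, `NA` where unknown.
#' @export
resolve_symbols <- function(x, lexicon) {
  stopifnot(inherits(lexicon, "grn_lexicon"))
  unname(lexicon$alias_map[canon_symbol(x)])
}

#' Entity class lookup
#'
#' @param x character vector of official symbols.
#' @param lexicon a [grn_lexicon()].
#' @return Character vector of classes (`TF`/`GENE`/`MIRNA`), `NA` if unknown.
#' @export
entity_class <- function(x, lexicon) {
  stopifnot(inherits(lexicon, "grn_lexicon"))
  idx <- match(canon_symbol(x), lexicon$table$symbol)
  lexicon$table$class[idx]
}
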