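# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

#' @importFrom data.table fread fwrite data.table as.data.table setDT setkeyv
#' @importFrom stats cor median pt phyper rnorm runif sd setNames t.test
#' @importFrom utils head
NULL

CONDITIONS <- c("CONTROL", "RRMS", "PPMS", "SPMS")
MS_CONDITIONS <- c("RRMS", "PPMS", "SPMS")
CONTRASTS <- paste0(MS_CONDITIONS, "_vs_CONTROL")
EDGE_CODES <- c("TG", "TM", "MT", "MG")
MOTIF_TYPES <- c("CL1", "CL2", "G", "TFC", "MIR")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf  <- function(fmt, ...) message(sprintf(fmt, ...))

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}

# HGNC-style canonical form: case-insensitive in, uppercase out.
canon_symbol <- function(x) toupper(trimws(as.character(x)))

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = c("", "NA"), ...))
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}
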