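# Pearson co-expression confirmation of FF/FB interactions on control
# samples.

# Vectorized Pearson r between paired rows of two matrices.
row_pearson <- function(x, y) {
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(rowSums(yc^2))
  r <- rowSums(xc * yc) / (sx * sy)
  # clamp numerical spill outside [-1, 1]
  pmin(1, pmax(-1, r))
}

# Two-sided p from Pearson r via the exact Student-t transform at n-2 df.
pearson_p <- function(r, n) {
  df <- n - 2L
  t <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * pt(t, df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  pmin(p, 1)
}

#' Confirm interactions by Pearson correlation on control samples
#'
#' For each edge, computes the Pearson correlation between the source and
#' target expression profiles across CONTROL samples only, with the
#' two-sided p-value from the exact Student-t transform at n - 2 degrees of
#' freedom. An edge is retained iff p <= `p_cut`; with `require_sign` the
#' correlation must additionally be negative for miRNA-source edges
#' (repression) and positive otherwise. Edges with a zero-variance
#' endpoint have undefined r and are dropped with a warning; edges with an
#' endpoint missing from the matrix are dropped and counted.
#'
#' @param catalog an [tag_fb_ff()] `interaction_catalog`, or a plain
#'   interaction data.frame.
#' @param expr a [grn_expression()] holding both gene and miRNA profiles
#'   (see [merge_expression()]).
#' @param p_cut retention p-value cut-off; default 0.05.
#' @param require_sign logical; default FALSE (sign-agnostic).
#' @return data.frame of retained edges with `r` and `p` columns appended;
#'   attribute `drops` counts edges lost to `missing_endpoint` and
#'   `zero_variance`, attribute `n_tested` the number tested.
#' @export
pearson_validate <- function(catalog, expr, p_cut = 0.05, require_sign = FALSE) {
  edges <- if (inherits(catalog, "interaction_catalog")) catalog$interactions
           else as.data.frame(catalog)
  assert_cols(edges, c("source", "source_class", "target"), "interaction table")
  stopifnot(inherits(expr, "grn_expr"))
  ctrl <- expr$condition == "CONTROL"
  if (sum(ctrl) < 3)
    stopf("need at least 3 control samples, have %d", sum(ctrl))
  v <- expr$values[, ctrl, drop = FALSE]

  present <- edges$source %in% rownames(v) & edges$target %in% rownames(v)
  n_missing <- sum(!present)
  edges <- edges[present, , drop = FALSE]
  if (!nrow(edges)) {
    out <- cbind(edges, r = numeric(0), p = numeric(0))
    attr(out, "drops") <- c(missing_endpoint = n_missing, zero_variance = 0L)
    attr(out, "n_tested") <- 0L
    return(out)
  }

  x <- v[edges$source, , drop = FALSE]
  y <- v[edges$target, , drop = FALSE]
  var0 <- apply(x, 1L, sd) == 0 | apply(y, 1L, sd) == 0
  if (any(var0))
    warnf("dropping %d edge(s) with a zero-variance endpoint", sum(var0))
  edges <- edges[!var0, , drop = FALSE]
  x <- x[!var0, , drop = FALSE]; y <- y[!var0, , drop = FALSE]

  r <- row_pearson(x, y)
  p <- pearson_p(r, ncol(v))
  keep <- p <= p_cut
  if (isTRUE(require_sign))
    keep <- keep & ifelse(edges$source_class == "MIRNA", r < 0, r > 0)

  out <- edges[keep, , drop = FALSE]
  out$r <- r[keep]
  out$p <- p[keep]
  rownames(out) <- NULL
  attr(out, "drops") <- c(missing_endpoint = n_missing,
                          zero_variance = sum(var0))
  attr(out, "n_tested") <- length(r)
  out
}
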