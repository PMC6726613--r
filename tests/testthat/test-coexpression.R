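# Expression container, normalization, Pearson confirmation, summaries.

test_that("grn_expression validates its inputs", {
  m <- matrix(1:12, 2, 6,
              dimnames = list(c("A", "B"), paste0("S", 1:6)))
  cond <- setNames(rep(c("CONTROL", "RRMS"), each = 3), paste0("S", 1:6))
  e <- grn_expression(m, cond)
  expect_equal(levels(e$condition), c("CONTROL", "RRMS", "PPMS", "SPMS"))

  m2 <- m; rownames(m2) <- c("A", "A")
  expect_error(grn_expression(m2, cond), "duplicate")
  expect_error(grn_expression(m, cond[-1]), "S1")
  expect_error(grn_expression(m, setNames(rep("WEIRD", 6), colnames(m))),
               "WEIRD")
  expect_warning(
    grn_expression(m, setNames(c(rep("CONTROL", 4), "RRMS", "RRMS"),
                               colnames(m))),
    "fewer than 3")
})

test_that("normalize_expression is strictly positive and errors on non-finite", {
  set.seed(3)
  m <- matrix(2^rnorm(80, 8), 8, 10,
              dimnames = list(paste0("E", 1:8), paste0("S", 1:10)))
  e <- toy_expression(m, c(3, 3, 2, 2))
  for (method in c("quantile", "log2_shift")) {
    out <- suppressWarnings(normalize_expression(e, method))
    expect_gt(min(out$values), 0)
    expect_equal(dimnames(out$values), dimnames(m))
  }
  m[2, 3] <- NA
  e2 <- toy_expression(m, c(3, 3, 2, 2))
  expect_error(suppressWarnings(normalize_expression(e2)), "E2.*S3")
})

test_that("quantile normalization matches the rank-average reference", {
  set.seed(4)
  m <- matrix(rexp(60, 1 / 50) + 1, 10, 6,
              dimnames = list(paste0("E", 1:10), paste0("S", 1:6)))
  e <- toy_expression(m, c(2, 2, 1, 1))
  out <- suppressWarnings(normalize_expression(e, "quantile"))
  # reference: replace each column's order statistics by the row means of
  # the column-sorted matrix (no ties in random continuous data)
  ref_quants <- rowMeans(apply(m, 2, sort))
  ref <- apply(m, 2, function(col) ref_quants[rank(col)])
  expect_equal(unname(out$values), unname(ref), tolerance = 1e-12)
  expect_true(all(abs(colMeans(out$values) - mean(colMeans(out$values))) < 1e-9))

  # a matrix with identical columns is unchanged
  m2 <- matrix(rep(c(1, 5, 9), 4), 3, 4,
               dimnames = list(paste0("E", 1:3), paste0("S", 1:4)))
  e2 <- suppressWarnings(toy_expression(m2, c(1, 1, 1, 1)))
  out2 <- suppressWarnings(normalize_expression(e2, "quantile"))
  expect_equal(out2$values, m2)
})

test_that("pearson_validate retains by exact t-transform p-values", {
  set.seed(5)
  n_ctrl <- 8
  m <- matrix(2^rnorm(6 * (n_ctrl + 3), 8), 6,
              dimnames = list(paste0("E", 1:6), NULL))
  e <- toy_expression(m, c(n_ctrl, 1, 1, 1))
  edges <- rbind(edge_row("E1", "TF", "E2", "GENE"),
                 edge_row("E3", "TF", "E4", "GENE"),
                 edge_row("E5", "TF", "E6", "GENE"))
  out <- suppressWarnings(pearson_validate(edges, e, p_cut = 1))
  # p_cut = 1 retains every edge with defined r
  expect_equal(nrow(out), 3L)
  # r and p agree with cor.test on control samples to 1e-10
  ctrl <- e$values[, e$condition == "CONTROL"]
  for (i in 1:3) {
    ct <- cor.test(ctrl[edges$source[i], ], ctrl[edges$target[i], ])
    expect_equal(out$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(out$p[i], ct$p.value, tolerance = 1e-10)
  }
})

test_that("pearson_validate edge cases: identical, constant, missing, sign", {
  v <- c(1, 2, 3, 4, 5)
  m <- rbind(A = v, B = v, C = rep(2, 5), D = 6 - v, E = v + 100)
  colnames(m) <- paste0("S", 1:5)
  e <- suppressWarnings(grn_expression(
    m, setNames(c(rep("CONTROL", 4), "RRMS"), colnames(m))))
  # identical profiles: r = 1, retained
  out <- pearson_validate(edge_row("A", "TF", "B", "GENE"), e)
  expect_equal(out$r, 1)
  # constant profile dropped with warning
  expect_warning(
    out2 <- pearson_validate(edge_row("A", "TF", "C", "GENE"), e),
    "zero-variance")
  expect_equal(nrow(out2), 0L)
  # missing endpoint dropped and counted
  out3 <- pearson_validate(edge_row("A", "TF", "ZZ", "GENE"), e, p_cut = 1)
  expect_equal(unname(attr(out3, "drops")["missing_endpoint"]), 1L)
  # sign constraint: miRNA-source edges need r < 0
  edges <- rbind(edge_row("A", "MIRNA", "D", "GENE"),
                 edge_row("A", "MIRNA", "B", "GENE"))
  out4 <- pearson_validate(edges, e, p_cut = 1, require_sign = TRUE)
  expect_equal(out4$target, "D")
  expect_lt(out4$r, 0)
  # fewer than 3 controls is an error
  e2 <- suppressWarnings(grn_expression(
    m, setNames(c("CONTROL", "CONTROL", rep("RRMS", 3)), colnames(m))))
  expect_error(pearson_validate(edges, e2, p_cut = 1), "3 control")
})

test_that("retention is symmetric under swapping source and target", {
  set.seed(6)
  m <- matrix(2^rnorm(40, 8), 4, 10,
              dimnames = list(paste0("E", 1:4), paste0("S", 1:10)))
  e <- suppressWarnings(grn_expression(
    m, setNames(c(rep("CONTROL", 8), "RRMS", "RRMS"), colnames(m))))
  fwd <- pearson_validate(edge_row("E1", "TF", "E2", "GENE"), e, p_cut = 1)
  rev <- pearson_validate(edge_row("E2", "TF", "E1", "GENE"), e, p_cut = 1)
  expect_equal(fwd$r, rev$r)
  expect_equal(fwd$p, rev$p)
})

test_that("planted correlations are recovered with high power", {
  set.seed(7)
  n <- 14   # control cohort size this pipeline targets
  n_planted <- 20
  n_noise <- 180
  rho <- 0.95
  vals <- matrix(rnorm(2 * (n_planted + n_noise) * n), ncol = n)
  for (i in seq_len(n_planted)) {
    x <- vals[2 * i - 1, ]
    vals[2 * i, ] <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  }
  vals <- 2^(vals + 8)  # positive, intensity-like
  rownames(vals) <- paste0("E", seq_len(nrow(vals)))
  colnames(vals) <- paste0("S", seq_len(n))
  e <- suppressWarnings(grn_expression(
    vals, setNames(rep("CONTROL", n), colnames(vals))))
  edges <- edge_row(paste0("E", 2 * seq_len(n_planted + n_noise) - 1), "TF",
                    paste0("E", 2 * seq_len(n_planted + n_noise)), "GENE")
  out <- pearson_validate(edges, e, p_cut = 0.05)
  planted_sources <- paste0("E", 2 * seq_len(n_planted) - 1)
  expect_gte(sum(out$source %in% planted_sources), 18)
  # false positive rate near nominal
  expect_lte(sum(!out$source %in% planted_sources), 0.15 * n_noise)
})

test_that("condition_summary equals grouped means/medians", {
  m <- matrix(c(2, 4, 1, 2, 9, 3, 5, 7, 8, 6, 4, 2), 1,
              dimnames = list("A", paste0("S", 1:12)))
  e <- toy_expression(m, c(2, 3, 4, 3))
  s_mean <- condition_summary(e)
  expect_equal(s_mean["A", "CONTROL"], 3)       # mean of (2, 4)
  s_med <- condition_summary(e, "median")
  expect_equal(s_med["A", "RRMS"], 2)           # median of (1, 2, 9)

  set.seed(8)
  m2 <- matrix(2^rnorm(5 * 12, 8), 5, 12,
               dimnames = list(paste0("E", 1:5), paste0("S", 1:12)))
  e2 <- toy_expression(m2, c(3, 3, 3, 3))
  s2 <- condition_summary(e2)
  for (cn in colnames(s2)) {
    ref <- rowMeans(m2[, e2$condition == cn, drop = FALSE])
    expect_equal(s2[, cn], ref)
  }
  expect_true(all(s2 > 0))
})
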