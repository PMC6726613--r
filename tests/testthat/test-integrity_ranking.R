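# Integrity score, regulatory fold change, ranking and overlaps.

test_that("integrity_score evaluates the printed formula", {
  expect_equal(integrity_score(1, 1, 1), 1.625)       # 0.5 + 0.375 + 0.75
  expect_equal(integrity_score(2, 1, 1), 2.875)       # 1.0 + 0.375 + 1.5
  # dual-path check on random positive triples
  set.seed(41)
  for (i in 1:50) {
    e <- runif(3, 0.1, 50)
    expect_equal(integrity_score(e[1], e[2], e[3]),
                 oracle_integrity(e[1], e[2], e[3]))
  }
  # custom weights flow through
  w <- regulatory_weights(2, 1, 0.25)
  e <- c(3, 4, 5)
  expect_equal(integrity_score(e[1], e[2], e[3], w),
               oracle_integrity(e[1], e[2], e[3], 2, 1, 0.25))
})

test_that("integrity_score validates inputs and weights", {
  expect_error(integrity_score(0, 1, 1), "e_tf")
  expect_error(integrity_score(1, -2, 1), "e_gene")
  expect_error(integrity_score(1, 1, Inf), "e_mir")
  expect_error(regulatory_weights(r_mir = 0), "r_mir")
})

test_that("scale law: N(c e) = c^2 N(e), so RFC ignores common rescaling", {
  set.seed(42)
  for (i in 1:100) {
    e <- runif(3, 0.05, 100)
    c_ <- runif(1, 0.1, 10)
    expect_equal(integrity_score(c_ * e[1], c_ * e[2], c_ * e[3]),
                 c_^2 * integrity_score(e[1], e[2], e[3]),
                 tolerance = 1e-12)
  }
  n1 <- integrity_score(2, 3, 4); n2 <- integrity_score(5, 1, 2)
  s <- 3.7
  expect_equal(regulatory_fold_change(s^2 * n1, s^2 * n2),
               regulatory_fold_change(n1, n2), tolerance = 1e-12)
})

test_that("score_all emits 4 records per motif and spot-checks", {
  grns <- data.frame(grn_id = c("A_B_C", "D_E_F"),
                     tf = c("A", "D"), gene = c("B", "E"),
                     mirna = c("C", "F"), motif_type = c("G", "CL1"),
                     stringsAsFactors = FALSE)
  summ <- matrix(runif(24, 1, 10), 6, 4,
                 dimnames = list(c("A", "B", "C", "D", "E", "F"),
                                 c("CONTROL", "RRMS", "PPMS", "SPMS")))
  rec <- score_all(grns, summ)
  expect_equal(nrow(rec), 8L)
  expect_equal(sort(unique(rec$condition)),
               sort(c("CONTROL", "RRMS", "PPMS", "SPMS")))
  for (i in sample(nrow(rec), 5)) {
    r <- rec[i, ]
    g <- grns[grns$grn_id == r$grn_id, ]
    expect_equal(r$N, integrity_score(summ[g$tf, r$condition],
                                      summ[g$gene, r$condition],
                                      summ[g$mirna, r$condition]))
  }
  # missing-summary motifs dropped with count
  grns2 <- rbind(grns, data.frame(grn_id = "X_Y_Z", tf = "X", gene = "Y",
                                  mirna = "Z", motif_type = "G"))
  expect_message(rec2 <- score_all(grns2, summ), "dropped 1")
  expect_equal(nrow(rec2), 8L)
  expect_equal(attr(rec2, "n_dropped"), 1L)
})

test_that("regulatory_fold_change and direction rules", {
  expect_equal(regulatory_fold_change(1.625, 3.25), 0.5)
  expect_equal(rfc_direction(0.5), "DOWN")
  expect_equal(regulatory_fold_change(3.25, 1.625), 2)
  expect_equal(rfc_direction(2), "UP")
  expect_true(is.na(rfc_direction(1)))   # boundary excluded from ranking
  expect_error(regulatory_fold_change(1, 0), "n_control")
  expect_error(regulatory_fold_change(-1, 1), "n_ms")
})

# build an integrity-record table from an explicit per-GRN RFC vector
records_from_rfc <- function(rfc, type = "G") {
  ids <- sprintf("GRN%03d_%s", seq_along(rfc), type)
  data.frame(grn_id = rep(ids, 2),
             condition = rep(c("CONTROL", "RRMS"), each = length(rfc)),
             N = c(rep(1.625, length(rfc)), 1.625 * rfc),
             stringsAsFactors = FALSE)
}

test_that("rank_and_select matches a full-sort-then-slice oracle", {
  set.seed(43)
  rfc <- round(exp(rnorm(60, 0, 0.6)), 6)
  rfc[rfc == 1] <- 1.01
  rec <- records_from_rfc(rfc)
  grns <- data.frame(grn_id = unique(rec$grn_id), motif_type = "G",
                     stringsAsFactors = FALSE)
  sel <- suppressWarnings(
    rank_and_select(rec, grns, "RRMS_vs_CONTROL", k_up = 10, k_down = 10))
  # oracle: full sort then slice
  names(rfc) <- unique(rec$grn_id)
  up <- sort(rfc[rfc > 1], decreasing = TRUE)
  down <- sort(rfc[rfc < 1])
  expect_equal(sel$grn_id[sel$direction == "UP"],
               names(head(up, 10)))
  expect_equal(sel$grn_id[sel$direction == "DOWN"],
               names(head(down, 10)))
  expect_equal(sel$rank[sel$direction == "UP"], seq_len(min(10, length(up))))
  expect_equal(unique(sel$contrast), "RRMS_vs_CONTROL")
})

test_that("rank_and_select ties break by grn_id and degenerate counts warn", {
  rfc <- c(2, 2, 2, 0.5, 0.5)
  rec <- records_from_rfc(rfc)
  grns <- data.frame(grn_id = unique(rec$grn_id), motif_type = "G")
  expect_warning(
    sel <- rank_and_select(rec, grns, "RRMS_vs_CONTROL", 2, 10),
    "candidate")
  up <- sel[sel$direction == "UP", ]
  expect_equal(nrow(up), 2L)
  expect_equal(up$grn_id, sort(up$grn_id))  # lexicographic tie-break
  down <- sel[sel$direction == "DOWN", ]
  expect_equal(nrow(down), 2L)              # only 2 candidates, all returned

  expect_error(rank_and_select(rec, grns, "XX_vs_CONTROL"), "unknown contrast")
})

test_that("RFC = 1 is excluded from both directions", {
  rec <- records_from_rfc(c(1, 2, 0.5))
  grns <- data.frame(grn_id = unique(rec$grn_id), motif_type = "G")
  sel <- suppressWarnings(rank_and_select(rec, grns, "RRMS_vs_CONTROL"))
  expect_equal(nrow(sel), 2L)
  expect_false(unique(rec$grn_id)[1] %in% sel$grn_id)
})

test_that("overlap_summary computes the 7 Venn regions", {
  mk <- function(ids, contrast)
    data.frame(grn_id = ids, motif_type = "G", contrast = contrast,
               stringsAsFactors = FALSE)
  # identical selections: everything in the triple region
  same <- rbind(mk(c("a", "b"), "RRMS_vs_CONTROL"),
                mk(c("a", "b"), "PPMS_vs_CONTROL"),
                mk(c("a", "b"), "SPMS_vs_CONTROL"))
  ov <- overlap_summary(same)$G
  expect_setequal(ov$all_three, c("a", "b"))
  expect_equal(lengths(ov[names(ov) != "all_three"]),
               setNames(rep(0L, 6), setdiff(names(ov), "all_three")))

  # disjoint selections: singleton regions only
  disj <- rbind(mk("a", "RRMS_vs_CONTROL"), mk("b", "PPMS_vs_CONTROL"),
                mk("c", "SPMS_vs_CONTROL"))
  ov2 <- overlap_summary(disj)$G
  expect_equal(ov2$RRMS_only, "a")
  expect_equal(ov2$PPMS_only, "b")
  expect_equal(ov2$SPMS_only, "c")
  expect_equal(length(ov2$all_three), 0L)

  # random selections against brute-force set algebra
  set.seed(44)
  ids <- sprintf("g%02d", 1:30)
  r <- sample(ids, 12); p <- sample(ids, 12); s <- sample(ids, 12)
  ov3 <- overlap_summary(rbind(mk(r, "RRMS_vs_CONTROL"),
                               mk(p, "PPMS_vs_CONTROL"),
                               mk(s, "SPMS_vs_CONTROL")))$G
  expect_setequal(ov3$RRMS_PPMS, setdiff(intersect(r, p), s))
  expect_setequal(ov3$all_three, intersect(intersect(r, p), s))
  # regions partition the union
  expect_equal(sum(lengths(ov3)), length(union(union(r, p), s)))

  expect_error(overlap_summary(mk("a", "RRMS_vs_CONTROL")), "lack contrast")
})
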