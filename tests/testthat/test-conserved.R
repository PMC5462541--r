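mk_matrix <- function(V, chrom = "chr1") {
  w <- data.table::data.table(chrom = chrom,
                              start = seq(0L, by = 100L,
                                          length.out = nrow(V)),
                              end = seq(100L, by = 100L,
                                        length.out = nrow(V)))
  rownames(V) <- sprintf("%s:%d-%d", w$chrom, w$start, w$end)
  structure(list(values = V, windows = w, context = "CG"),
            class = "DmrMatrix")
}

test_that("master lists deduplicate windows across comparisons", {
  a <- data.table::data.table(chrom = "chr1", start = c(0L, 100L),
                              end = c(100L, 200L), context = "CG",
                              direction = "hyper")
  b <- data.table::data.table(chrom = "chr1", start = c(100L, 300L),
                              end = c(200L, 400L), context = "CG",
                              direction = "hyper")
  m <- build_master_list(list(a, b))
  expect_equal(nrow(m), 3L)  # the shared window appears once
  expect_gte(nrow(m), nrow(a))
  expect_gte(nrow(m), nrow(b))
})

test_that("methylation matrix pools, rounds to three decimals, and flags missing", {
  w <- data.table::data.table(chrom = "chr1", start = c(0L, 100L),
                              end = c(100L, 200L))
  s1 <- tiny_sample(data.frame(
    chrom = "chr1", pos = c(10L, 20L, 150L), strand = "+", context = "CG",
    m = c(4L, 4L, 2L), n = c(4L, 4L, 3L)))          # 150: below floor
  s2 <- tiny_sample(data.frame(
    chrom = "chr1", pos = c(10L, 20L, 150L), strand = "+", context = "CG",
    m = c(2L, 2L, 4L), n = c(4L, 8L, 6L)), "s2")
  mm <- suppressMessages(
    methylation_matrix(w, list(s1 = s1, s2 = s2), "CG"))
  expect_equal(mm$values["chr1:0-100", "s1"], 1.000)
  expect_equal(mm$values["chr1:0-100", "s2"], round(4 / 12, 3))  # 0.333
  expect_true(is.na(mm$values["chr1:100-200", "s1"]))
  expect_equal(mm$values["chr1:100-200", "s2"], round(4 / 6, 3))  # 0.667
  # matrix values equal targeted quantification over the same window
  q <- quantify_region(s2, 0, 100, one_based = FALSE)
  expect_equal(mm$values["chr1:0-100", "s2"],
               round(q[context == "CG"]$percent / 100, 3))
  # all-missing windows are dropped with a message
  w2 <- rbind(w, data.table::data.table(chrom = "chr1", start = 900L,
                                        end = 1000L))
  expect_message(methylation_matrix(w2, list(s1 = s1, s2 = s2), "CG"),
                 "dropping 1")
})

test_that("row clustering is average-linkage on 1 - |r|", {
  set.seed(10)
  V <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(paste0("chr1:", 0:14 * 100, "-",
                                     0:14 * 100 + 100), paste0("s", 1:6)))
  hc <- cluster_rows(V)
  d <- 1 - abs(cor(t(V)))
  want <- oracle_average_linkage_cophenetic(d)
  got <- as.matrix(stats::cophenetic(hc))
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
  # identical rows merge first at height 0
  V[2, ] <- V[1, ]
  hc2 <- cluster_rows(V)
  expect_equal(min(hc2$height), 0)
  expect_setequal(abs(hc2$merge[1, ]), c(1, 2))
  # a row and its negation are maximally similar under |r|
  V[3, ] <- -V[1, ]
  d3 <- 1 - abs(cor(t(V)))
  expect_equal(d3[1, 3], 0)
  # constant rows get maximal distance, with a message
  V[4, ] <- 0.5
  expect_message(cluster_rows(V), "zero-variance")
  expect_error(cluster_rows(V[1, , drop = FALSE]), "two complete rows")
})

test_that("sign-concordance selects windows where every mutant exceeds controls", {
  V <- rbind(c(0.8, 0.7, 0.9, 0.75, 0.85, 0.2, 0.25, 0.2),
             c(0.8, 0.7, 0.1, 0.75, 0.85, 0.2, 0.25, 0.2),
             c(0.1, 0.2, 0.15, 0.1, 0.2, 0.8, 0.9, 0.7))
  colnames(V) <- c(paste0("m", 1:5), paste0("c", 1:3))
  mm <- mk_matrix(V)
  sel <- suppressWarnings(select_concordant(mm, paste0("m", 1:5),
                                            paste0("c", 1:3), "hyper"))
  expect_equal(sel$start, 0L)    # row 2 fails: one mutant below controls
  sel <- suppressWarnings(select_concordant(mm, paste0("m", 1:5),
                                            paste0("c", 1:3), "hypo"))
  expect_equal(sel$start, 200L)
  # incomplete rows are never selectable
  V[1, 1] <- NA
  expect_warning(
    out <- select_concordant(mk_matrix(V), paste0("m", 1:5),
                             paste0("c", 1:3), "hyper"),
    "no concordant")
  expect_equal(nrow(out), 0L)
})

test_that("cluster-cut selection returns whole sign-consistent clusters", {
  set.seed(8)
  hyp <- matrix(rep(c(0.9, 0.9, 0.9, 0.1, 0.1), 3), 3, 5, byrow = TRUE) +
    rnorm(15, 0, 0.01)
  nul <- matrix(runif(15, 0.3, 0.7), 3, 5)
  V <- rbind(hyp, nul)
  colnames(V) <- c("m1", "m2", "m3", "c1", "c2")
  mm <- mk_matrix(V)
  sel <- suppressWarnings(
    select_concordant(mm, c("m1", "m2", "m3"), c("c1", "c2"), "hyper",
                      mode = "cluster", k = 2))
  sign_sel <- suppressWarnings(
    select_concordant(mm, c("m1", "m2", "m3"), c("c1", "c2"), "hyper"))
  # cluster mode selects a subset of the sign-rule windows
  expect_true(all(sel$start %in% sign_sel$start))
})

test_that("body-methylation filtering removes CG windows overlapping genes by 1 bp", {
  w <- data.table::data.table(
    chrom = "chr1", start = c(0L, 200L, 500L), end = c(100L, 300L, 600L),
    context = c("CG", "CG", "CHH"))
  genes <- data.table::data.table(chrom = "chr1", start = 99L, end = 250L)
  out <- filter_body_methylated(w, genes)
  # both CG windows touch the gene (1 bp and full overlap); CHH is kept
  expect_equal(out$start, 500L)
  expect_equal(out$context, "CHH")
  # zero-overlap CG window survives
  genes2 <- data.table::data.table(chrom = "chr1", start = 100L, end = 200L)
  expect_equal(nrow(filter_body_methylated(w, genes2)), 3L)
})

test_that("mean-difference ranking orders rows with coordinate tie-breaks", {
  V <- rbind(c(0.9, 0.9, 0.1, 0.1),
             c(0.5, 0.5, 0.2, 0.2),
             c(0.5, 0.5, 0.2, 0.2),
             c(0.2, 0.2, 0.9, 0.9))
  colnames(V) <- c("m1", "m2", "c1", "c2")
  r <- rank_by_mean_difference(mk_matrix(V), c("m1", "m2"), c("c1", "c2"))
  expect_equal(r$score, c(0.8, 0.3, 0.3, -0.7))
  expect_equal(r$start[2:3], c(100L, 200L))  # tie broken by coordinate
  expect_equal(nrow(r), 4L)                  # a permutation: nothing lost
  V[2, 1] <- NA
  expect_message(
    r2 <- rank_by_mean_difference(mk_matrix(V), c("m1", "m2"),
                                  c("c1", "c2")),
    "excluding 1")
  expect_equal(nrow(r2), 3L)
})

test_that("rounding to three decimals cannot flip clear selections", {
  # differences larger than 0.002 survive rounding
  V <- rbind(c(0.5005, 0.5006, 0.4975), c(0.501, 0.5, 0.5))
  colnames(V) <- c("m1", "m2", "c1")
  Vr <- round(V, 3)
  d_raw <- V[1, 1:2] - mean(V[1, 3])
  d_rnd <- Vr[1, 1:2] - mean(Vr[1, 3])
  expect_true(all(d_raw > 0) && all(d_rnd > 0))
})
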