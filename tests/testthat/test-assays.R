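toy_clones <- function() {
  # amplicon with cytosines at known positions/contexts
  clone_alignment(
    patterns = rbind(c(1, 1, 1, 1), c(1, 0, 1, NA), c(0, 0, 0, 0),
                     c(1, 1, 1, 1)),
    positions = c(5L, 12L, 20L, 30L),
    contexts = c("CG", "CHG", "CHH", "CG"),
    clone_ids = paste0("cl", 1:4))
}

test_that("region quantification pools observations per context", {
  s <- tiny_sample(data.frame(
    chrom = "chr1", pos = c(281L, 300L, 300L + 1L, 1035L, 1036L),
    strand = c("+", "+", "-", "+", "+"),
    context = c("CG", "CHH", "CHH", "CG", "CG"),
    m = c(4L, 4L, 4L, 4L, 4L), n = c(4L, 4L, 4L, 4L, 4L)))
  # 1-based inclusive bounds 282-1036 include pos0 281 and 1035, not 1036
  q <- quantify_region(s, 282, 1036)
  expect_equal(q[context == "CG"]$n_cytosines, 2L)
  expect_equal(q[context == "CG"]$percent, 100)
  expect_equal(q[context == "CHH"]$n_cytosines, 2L)
  expect_true(is.na(q[context == "CHG"]$percent))  # undefined, not 0
  # single-strand scope drops the minus-strand cytosine
  q1 <- quantify_region(s, 282, 1036, strand_scope = "plus_only")
  expect_equal(q1[context == "CHH"]$n_cytosines, 1L)
})

test_that("quantification over a union equals the count-weighted pool of parts", {
  set.seed(19)
  calls <- data.frame(chrom = "chr1", pos = 0:199, strand = "+",
                      context = sample(c("CG", "CHG", "CHH"), 200, TRUE),
                      n = rpois(200, 20))
  calls$m <- rbinom(200, calls$n, 0.4)
  s <- tiny_sample(calls)
  a <- quantify_region(s, 0, 100, one_based = FALSE)
  b <- quantify_region(s, 100, 200, one_based = FALSE)
  u <- quantify_region(s, 0, 200, one_based = FALSE)
  expect_equal(u$m_sum, a$m_sum + b$m_sum)
  expect_equal(u$n_sum, a$n_sum + b$n_sum)
  expect_equal(u$percent, 100 * (a$m_sum + b$m_sum) / (a$n_sum + b$n_sum))
})

test_that("clone summaries exclude ambiguities and expose modality", {
  cl <- toy_clones()
  sm <- clone_summary(cl)
  expect_equal(sm$per_cytosine$percent, c(75, 50, 75, 200 / 3))
  expect_equal(sm$per_cytosine$n_informative, c(4L, 4L, 4L, 3L))
  expect_equal(unname(sm$per_clone),
               c(1, 2 / 3, 0, 1))
  # invariant to clone order
  perm <- clone_alignment(cl$patterns[4:1, ], cl$positions, cl$contexts)
  expect_equal(clone_summary(perm)$per_cytosine$percent,
               sm$per_cytosine$percent)
  # bimodal fixture: per-clone means split at 0 and 1
  bim <- clone_alignment(rbind(matrix(1, 3, 4), matrix(0, 3, 4)),
                         cl$positions, cl$contexts)
  expect_setequal(unique(clone_summary(bim)$per_clone), c(0, 1))
  # all-ambiguous clones are dropped with a message
  amb <- clone_alignment(rbind(c(1, 1, 0, 1), c(NA, NA, NA, NA)),
                         cl$positions, cl$contexts)
  expect_message(sm2 <- clone_summary(amb), "all-ambiguous")
  expect_equal(sm2$per_cytosine$n_informative, rep(1L, 4))
})

test_that("clone filtering removes duplicates and non-conversion artifacts", {
  # duplicate collapse
  cl <- clone_alignment(rbind(c(1, 0, 1, 0), c(1, 0, 1, 0), c(0, 0, 0, 0)),
                        positions = c(1L, 5L, 9L, 15L),
                        contexts = rep("CG", 4))
  out <- suppressMessages(filter_clones(cl))
  expect_equal(nrow(out$patterns), 2L)
  expect_equal(attr(out, "removed")$reason, "duplicate")

  # a clone fully methylated over a CHH run in an otherwise unmethylated
  # amplicon is flagged as non-converted
  set.seed(3)
  n_chh <- 20
  pos <- seq(0L, by = 7L, length.out = n_chh)
  pat <- rbind(matrix(rbinom(9 * n_chh, 1, 0.05), 9, n_chh),
               rep(1, n_chh))
  cl2 <- clone_alignment(pat, pos, rep("CHH", n_chh))
  out2 <- suppressMessages(filter_clones(cl2))
  expect_equal(attr(out2, "removed")[reason == "non_conversion"]$clone,
               "clone10")
  # a genuinely methylated amplicon (high population mean) is NOT flagged
  cl3 <- clone_alignment(matrix(1, 10, n_chh), pos, rep("CHH", n_chh))
  out3 <- suppressMessages(filter_clones(cl3, dedup = FALSE))
  expect_equal(nrow(out3$patterns), 10L)
  # duplicates of a single pattern leave one representative, never zero
  cl4 <- clone_alignment(rbind(c(1, 0), c(1, 0)), c(1L, 5L),
                         rep("CG", 2))
  out4 <- suppressMessages(filter_clones(cl4))
  expect_equal(nrow(out4$patterns), 1L)
})

test_that("clone FASTA reads are scored C=methylated, T=unmethylated", {
  ref <- "AACGTCAGTT"          # plus-strand Cs: pos2 (CG), pos5 (CHG)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">cl1", "AATGTCAGTT",   # pos2 T -> unmethylated, pos5 C -> methylated
               ">cl2", "AACGTTAGTT",   # pos2 C -> methylated,  pos5 T -> unmethylated
               ">cl3", "AANGTCAGTT"),  # pos2 N -> ambiguous
             fa)
  cl <- read_clone_fasta(fa, ref)
  expect_equal(cl$positions, c(2L, 5L))
  expect_equal(cl$contexts, c("CG", "CHG"))
  expect_equal(unname(cl$patterns[, 1]), c(0, 1, NA))
  expect_equal(unname(cl$patterns[, 2]), c(1, 0, 1))
  q <- quantify_region(cl, 0, 10, one_based = FALSE)
  expect_equal(q[context == "CG"]$percent, 50)
  # pattern table round-trips as text
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_tsv(cl, tsv)
  tab <- read.table(tsv, header = TRUE, sep = "\t",
                    colClasses = "character")
  expect_equal(tab$CG_2, c("U", "M", "."))
})

test_that("McrBC relative methylation follows the Ct closed form", {
  expect_equal(mcrbc_relative_methylation(20, 20), 0)
  expect_equal(mcrbc_relative_methylation(20, 21), 50)
  expect_equal(mcrbc_relative_methylation(20, 22), 75)
  # strictly increasing in Ct_treated, bounded above by 100
  v <- mcrbc_relative_methylation(rep(20, 30), seq(20, 35, length.out = 30))
  expect_true(all(diff(v) > 0))
  expect_true(all(v < 100))
  # noise below zero is preserved with a warning, or clipped on request
  expect_warning(neg <- mcrbc_relative_methylation(21, 20), "noise")
  expect_equal(neg, -100)
  expect_equal(suppressWarnings(
    mcrbc_relative_methylation(21, 20, clip0 = TRUE)), 0)
  # no amplification handling
  expect_equal(mcrbc_relative_methylation(20, NA), 100)
  expect_true(is.na(mcrbc_relative_methylation(NA, 20)))
})
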