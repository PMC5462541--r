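iv <- function(starts, ends, chrom = "chr1", ...) {
  data.table::data.table(chrom = chrom, start = as.integer(starts),
                         end = as.integer(ends), ...)
}

test_that("direct intersection chops to the nominal window size", {
  out <- intersect_direct(list(iv(0, 100), iv(50, 150)))
  expect_equal(out[, .(start, end)], iv(50, 100)[, .(start, end)])
  # a 250-bp intersection decomposes into 100 + 100 + 50
  out <- intersect_direct(list(iv(0, 250), iv(0, 300)))
  expect_equal(out$start, c(0L, 100L, 200L))
  expect_equal(out$end, c(100L, 200L, 250L))
  expect_error(intersect_direct(list()), "empty")
  expect_error(intersect_direct(list(iv(0, 10))), "two")
})

test_that("direct intersection is commutative and associative", {
  set.seed(91)
  sets <- replicate(4, rand_intervals(30, 1e4), simplify = FALSE)
  base <- intersect_direct(sets)
  for (perm in list(c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    expect_equal(intersect_direct(sets[perm])[, .(chrom, start, end)],
                 base[, .(chrom, start, end)])
  }
})

test_that("overlap depth counts windows shared by at least k sets", {
  sets <- list(iv(0, 100), iv(0, 100), iv(50, 150))
  d <- overlap_depth(sets)
  expect_equal(d$k, 2:3)
  expect_equal(d[k == 3]$bp, 50L)   # all three share [50, 100)
  expect_equal(d[k == 2]$bp, 100L)  # at least two share [0, 100)
})

test_that("merging bridges gaps up to the distance, not beyond", {
  m <- merge_within(iv(c(0, 350), c(100, 450)), distance = 300)
  expect_equal(m[, .(start, end)], iv(0, 450)[, .(start, end)])
  m <- merge_within(iv(c(0, 401), c(100, 501)), distance = 300)
  expect_equal(nrow(m), 2L)  # gap 301 stays split
  m <- merge_within(iv(c(0, 400), c(100, 500)), distance = 300)
  expect_equal(nrow(m), 1L)  # gap 300 merges (boundary)
})

test_that("merging is idempotent, context-restricted, and bp-conserving", {
  set.seed(14)
  x <- rand_intervals(40, 8e3)
  m1 <- merge_within(x, 300)
  expect_identical(merge_within(m1, 300), m1)
  # separations all exceed the distance
  expect_true(all(m1$start[-1] - m1$end[-nrow(m1)] > 300))
  # covered bp never decreases
  expect_gte(sum(m1$end - m1$start),
             sum(runs_of(bitmap_of(x, 8e3))[, sum(end - start)]))
  # same-context restriction: CG and CHH neighbours stay apart
  x2 <- iv(c(0, 150), c(100, 250), context = c("CG", "CHH"))
  by_ctx <- merge_within(x2, 300, by = "context")
  expect_equal(nrow(by_ctx), 2L)
  expect_equal(nrow(merge_within(x2, 300)), 1L)
})

test_that("cross-context union joins overlapping or directly adjacent regions", {
  u <- union_across_contexts(list(CG = iv(0, 100), CHH = iv(100, 200)))
  expect_equal(u[, .(start, end)], iv(0, 200)[, .(start, end)])
  u <- union_across_contexts(list(CG = iv(0, 100), CHH = iv(150, 250)))
  expect_equal(nrow(u), 2L)
})

test_that("annotation overlap keeps 1-bp contacts and partitions the query", {
  q <- iv(0, 100)
  f <- iv(99, 200)
  expect_equal(nrow(overlap_annotation(q, f, "element_of")), 1L)
  expect_equal(nrow(overlap_annotation(q, iv(100, 200), "element_of")), 0L)
  # empty features: element_of empty, not_element_of everything
  empty <- iv(integer(), integer())
  expect_equal(nrow(overlap_annotation(q, empty, "element_of")), 0L)
  expect_equal(overlap_annotation(q, empty, "not_element_of"), q)
  # partition property on random fixtures, against the bitmap oracle
  set.seed(5)
  for (rep in 1:10) {
    qq <- rand_intervals(25, 1e3, max_width = 60)
    ff <- rand_intervals(10, 1e3, max_width = 80)
    keep <- overlap_annotation(qq, ff, "element_of")
    drop <- overlap_annotation(qq, ff, "not_element_of")
    expect_equal(nrow(keep) + nrow(drop), nrow(qq))
    want <- oracle_element_of(qq, ff, 1e3)
    expect_equal(keep[, .(chrom, start, end)],
                 qq[want][, .(chrom, start, end)])
  }
})

test_that("locus convergence groups windows like connected components", {
  x <- iv(c(0, 20, 50), c(100, 120, 150),
          context = c("CG", "CHG", "CHH"), direction = "hyper")
  loci <- converge_to_loci(x)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$contexts, "CG,CHG,CHH")
  expect_equal(loci$direction, "hyper")
  expect_equal(loci$n_members, 3L)
  # mixed directions are flagged
  x$direction <- c("hyper", "hypo", "hyper")
  expect_equal(converge_to_loci(x)$direction, "mixed")
  # locus count equals union-find components under the gap relation
  set.seed(41)
  for (rep in 1:5) {
    w <- rand_intervals(34, 2e4, max_width = 100)
    w[, `:=`(context = "CG", direction = "hyper")]
    expect_equal(nrow(converge_to_loci(w, 300)), oracle_components(w, 300))
  }
})

test_that("intersect/chop/merge agree with the per-bp bitmap oracle", {
  set.seed(77)
  for (rep in 1:15) {
    len <- 1e4
    sets <- replicate(sample(2:4, 1), rand_intervals(25, len),
                      simplify = FALSE)
    got <- intersect_direct(sets, window = 100)
    want <- oracle_intersect(sets, len, window = 100)
    expect_equal(got[, .(chrom, start, end)],
                 want[, .(chrom, start, end)], ignore_attr = TRUE)
    m <- merge_within(sets[[1]], 300)
    expect_equal(m[, .(chrom, start, end)],
                 oracle_merge(sets[[1]], 300, len), ignore_attr = TRUE)
  }
})
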