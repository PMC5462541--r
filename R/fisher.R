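#' Vectorised two-sided Fisher exact test for 2x2 count tables
#'
#' For each table `[(m1, n1 - m1), (m2, n2 - m2)]` the two-sided p-value
#' is the sum of all hypergeometric outcome probabilities not exceeding
#' the probability of the observed outcome (the classic "sum of small
#' p's" definition, with the conventional relative tolerance of 1e-7 on
#' the comparison to absorb floating-point ties).
#'
#' The implementation enumerates each table's hypergeometric support with
#' `dhyper`, batched across tables so that millions of bin-level tests
#' run in seconds.
#'
#' @param m1,n1 Methylated and total counts in sample 1.
#' @param m2,n2 Methylated and total counts in sample 2.
#' @param chunk_size Maximum expanded support length per batch.
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact_2x2 <- function(m1, n1, m2, n2, chunk_size = 5e6) {
  N <- length(m1)
  stopifnot(length(n1) == N, length(m2) == N, length(n2) == N,
            all(m1 >= 0), all(m2 >= 0), all(m1 <= n1), all(m2 <= n2))
  K <- m1 + m2                 # methylated margin
  B <- (n1 + n2) - K           # unmethylated margin
  k <- n1                      # draws (sample-1 column total)
  x <- m1                      # observed
  lo <- pmax(0L, k - B)
  hi <- pmin(k, K)
  len <- hi - lo + 1L
  d0 <- dhyper(x, K, B, k) * (1 + 1e-7)
  p <- numeric(N)
  i <- 1L
  while (i <= N) {
    j <- i
    tot <- 0
    while (j <= N && tot + len[j] <= chunk_size) {
      tot <- tot + len[j]
      j <- j + 1L
    }
    if (j == i) j <- i + 1L    # single huge table: do it alone
    idx <- i:(j - 1L)
    rep_i <- rep.int(idx, len[idx])
    xs <- sequence(len[idx], from = lo[idx])
    d <- dhyper(xs, K[rep_i], B[rep_i], k[rep_i])
    keep <- d <= d0[rep_i]
    p[idx] <- rowsum(d * keep, rep_i, reorder = TRUE)[, 1L]
    i <- j
  }
  pmin(p, 1)
}
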