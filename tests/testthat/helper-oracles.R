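# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct combinatorics for the Fisher test, a
# naive sort-based BH, per-basepair bitmaps for interval algebra, and a
# cubic-time agglomeration for average-linkage clustering.

# two-sided Fisher exact p by explicit hypergeometric enumeration with
# log-binomial coefficients (no dhyper)
oracle_fisher_p <- function(m1, n1, m2, n2) {
  K <- m1 + m2
  B <- (n1 + n2) - K
  k <- n1
  xs <- max(0, k - B):min(k, K)
  logp <- lchoose(K, xs) + lchoose(B, k - xs) - lchoose(K + B, k)
  pr <- exp(logp)
  p0 <- pr[xs == m1]
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

# naive BH: q_(i) = min_{j >= i} p_(j) * n / j on the sorted p-values
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# --- per-basepair bitmap interval oracles (single chromosome) ---------------

bitmap_of <- function(intervals, len) {
  b <- logical(len)
  for (i in seq_len(nrow(intervals)))
    b[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  b
}

runs_of <- function(bitmap, chrom = "chr1") {
  r <- rle(bitmap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.table::data.table(chrom = chrom, start = starts[r$values],
                         end = ends[r$values])
}

# chop runs into fixed windows with a plain loop (independent of the package)
oracle_chop <- function(intervals, window) {
  rows <- list()
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]
    while (s < intervals$end[i]) {
      rows[[length(rows) + 1]] <- data.table::data.table(
        chrom = intervals$chrom[i], start = s,
        end = min(s + window, intervals$end[i]))
      s <- s + window
    }
  }
  data.table::rbindlist(rows)
}

oracle_intersect <- function(sets, len, window = 100L) {
  b <- Reduce(`&`, lapply(sets, bitmap_of, len = len))
  oracle_chop(runs_of(b), window)
}

oracle_merge <- function(intervals, distance, len) {
  b <- bitmap_of(intervals, len)
  r <- runs_of(b)
  if (nrow(r) <= 1) return(r)
  out <- r[1]
  for (i in 2:nrow(r)) {
    if (r$start[i] - out$end[nrow(out)] <= distance) {
      out$end[nrow(out)] <- r$end[i]
    } else {
      out <- rbind(out, r[i])
    }
  }
  out
}

oracle_element_of <- function(query, features, len, min_overlap = 1L) {
  fb <- bitmap_of(features, len)
  ov <- vapply(seq_len(nrow(query)), function(i)
    sum(fb[(query$start[i] + 1):query$end[i]]), 0)
  ov >= min_overlap
}

# connected components of windows under "gap <= distance" (union-find)
oracle_components <- function(intervals, distance) {
  n <- nrow(intervals)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || intervals$chrom[i] != intervals$chrom[j]) next
    gap <- max(intervals$start[i], intervals$start[j]) -
      min(intervals$end[i], intervals$end[j])
    if (gap <= distance) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri  # union
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

# --- naive average-linkage agglomeration ------------------------------------
# returns the cophenetic distance matrix implied by successive merging of
# the closest cluster pair, with inter-cluster distance = mean of all
# pairwise original distances
oracle_average_linkage_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < bestd) { bestd <- dd; best <- c(a, b) }
    }
    ca <- clusters[[best[1]]]; cb <- clusters[[best[2]]]
    coph[ca, cb] <- bestd; coph[cb, ca] <- bestd
    clusters[[best[1]]] <- c(ca, cb)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# --- fixture builders -------------------------------------------------------

tiny_sample <- function(calls, id = "s1", genotype = "control",
                        replicate = "r1") {
  methylome_sample(as.data.frame(calls), id, genotype, replicate)
}

rand_intervals <- function(n, len, max_width = 400L, chrom = "chr1") {
  s <- sort(sample.int(len - max_width, n))
  w <- sample.int(max_width, n)
  unique(data.table::data.table(chrom = chrom, start = s,
                                end = pmin(s + w, len)))
}

# small reference shared by several test files (cached per session)
small_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_reference(c(chr1 = 1e5), seed = 402L)
    cache
  }
})
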