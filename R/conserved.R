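#' Build a master DMR list across comparisons
#'
#' Union of all DMR windows from every comparison for one context and
#' direction (the per-direction, per-context "master lists" from which
#' relaxed conserved DMRs are selected), deduplicated and sorted.
#'
#' @param sets List of [dmr_intervals()] tables, or one combined table.
#' @param context,direction Optional filters applied before the union.
#' @return data.table of unique windows with `context` and `direction`.
#' @export
build_master_list <- function(sets, context = NULL, direction = NULL) {
  dt <- if (is.data.frame(sets)) as.data.table(sets)
        else rbindlist(sets, use.names = TRUE, fill = TRUE)
  keep <- rep(TRUE, nrow(dt))
  if (!is.null(context)) keep <- keep & dt$context %in% context
  if (!is.null(direction)) keep <- keep & dt$direction %in% direction
  dt <- dt[keep]
  out <- unique(dt[, .(chrom, start, end, context, direction)],
                by = c("chrom", "start", "end"))
  setkey(out, chrom, start)
  out[]
}

#' DMR-by-sample methylation matrix
#'
#' For every window and sample, the pooled methylation level
#' (`sum(m) / sum(n)`) over the window's cytosines of the given context
#' passing the coverage floor, rounded to `digits` decimals. Windows with
#' no covered cytosine in a sample are `NA`; windows missing in every
#' sample are dropped (with a message).
#'
#' @param windows Interval table (e.g. a master list).
#' @param samples Named list of `MethylomeSample`s.
#' @param context Context to quantify.
#' @param min_site_coverage Per-cytosine coverage floor (default 4).
#' @param digits Rounding precision (default 3).
#' @return A `DmrMatrix`: list with `values` (windows x samples matrix,
#'   rownames `chrom:start-end`), `windows` and `context`.
#' @export
methylation_matrix <- function(windows, samples, context,
                               min_site_coverage = 4L, digits = 3L) {
  stopifnot(context %in% CONTEXTS, length(samples) >= 1)
  w <- as.data.table(windows)[, .(chrom, start, end)]
  if (is.null(names(samples)))
    names(samples) <- vapply(samples, `[[`, "", "sample_id")
  wgr <- as_granges0(w)
  V <- sapply(samples, function(s) {
    cl <- s$calls
    sub <- cl[cl$context == context & cl$n >= min_site_coverage]
    v <- rep(NA_real_, nrow(w))
    if (nrow(sub)) {
      pgr <- GenomicRanges::GRanges(sub$chrom,
               IRanges::IRanges(sub$pos + 1L, sub$pos + 1L))
      h <- GenomicRanges::findOverlaps(pgr, wgr)
      if (length(h)) {
        dd <- data.table(win = S4Vectors::subjectHits(h),
                         m = sub$m[S4Vectors::queryHits(h)],
                         n = sub$n[S4Vectors::queryHits(h)])
        agg <- dd[, .(m = sum(m), n = sum(n)), by = win]
        v[agg$win] <- round(agg$m / agg$n, digits)
      }
    }
    v
  })
  V <- matrix(V, nrow = nrow(w), dimnames =
                list(sprintf("%s:%d-%d", w$chrom, w$start, w$end),
                     names(samples)))
  all_na <- rowSums(!is.na(V)) == 0L
  if (any(all_na)) {
    message("dropping ", sum(all_na), " window(s) with no coverage in any sample")
    V <- V[!all_na, , drop = FALSE]
    w <- w[!all_na]
  }
  structure(list(values = V, windows = w[], context = context),
            class = "DmrMatrix")
}

mat_values <- function(x) {
  if (inherits(x, "DmrMatrix")) x$values else as.matrix(x)
}

mat_windows <- function(x) {
  if (inherits(x, "DmrMatrix")) return(x$windows)
  V <- as.matrix(x)
  parts <- do.call(rbind, regmatches(rownames(V),
    regexec("^(.+):(\\d+)-(\\d+)$", rownames(V))))
  data.table(chrom = parts[, 2L], start = as.integer(parts[, 3L]),
             end = as.integer(parts[, 4L]))
}

#' @export
print.DmrMatrix <- function(x, ...) {
  cat(sprintf("DmrMatrix (%s): %d windows x %d samples\n", x$context,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Hierarchically cluster matrix rows by absolute correlation
#'
#' Average-linkage agglomerative clustering of rows only (columns keep
#' their input order) with distance `1 - |Pearson r|`, so a row and its
#' negation are maximally similar. Rows with zero variance have an
#' undefined correlation and are assigned the maximal distance (1) to
#' every other row (reported via a message).
#'
#' @param x A `DmrMatrix` or numeric matrix with >= 2 complete rows.
#' @param linkage `hclust` method (default `"average"`).
#' @return An `hclust` object; `$order` is the displayed row order.
#' @export
cluster_rows <- function(x, linkage = "average") {
  V <- mat_values(x)
  V <- V[complete.cases(V), , drop = FALSE]
  if (nrow(V) < 2) stop("need at least two complete rows to cluster")
  r <- suppressWarnings(cor(t(V)))
  d <- 1 - abs(r)
  if (anyNA(d)) {
    message("zero-variance row(s) assigned maximal distance to all others")
    d[is.na(d)] <- 1
  }
  diag(d) <- 0
  hclust(as.dist(d), method = linkage)
}

#' Select concordant ("relaxed") DMR windows
#'
#' Default `"sign"` rule: a window is selected when the difference
#' between EVERY mutant value and the mean of the control values has the
#' sign of `direction` -- concordant change in all mutants with no
#' magnitude or coverage cutoff re-imposed. `"cluster"` mode instead cuts
#' the row dendrogram into `k` clusters and selects entire clusters in
#' which all rows satisfy the sign rule, mirroring a cluster-highlighting
#' workflow. Rows with missing values in any named column are never
#' selectable.
#'
#' @param x A `DmrMatrix` or matrix.
#' @param mutant_ids,control_ids Column names.
#' @param direction `"hyper"` or `"hypo"`.
#' @param mode `"sign"` or `"cluster"`.
#' @param k Number of clusters for `"cluster"` mode (default
#'   `max(2, floor(nrow / 10))`).
#' @return data.table of selected windows (may be empty, with a warning).
#' @export
select_concordant <- function(x, mutant_ids, control_ids,
                              direction = c("hyper", "hypo"),
                              mode = c("sign", "cluster"), k = NULL) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  V <- mat_values(x)
  stopifnot(all(c(mutant_ids, control_ids) %in% colnames(V)))
  w <- mat_windows(x)
  sub <- V[, c(mutant_ids, control_ids), drop = FALSE]
  complete <- complete.cases(sub)
  ctrl_mean <- rowMeans(sub[, control_ids, drop = FALSE])
  diffs <- sub[, mutant_ids, drop = FALSE] - ctrl_mean
  pass <- if (direction == "hyper") rowSums(diffs > 0) == length(mutant_ids)
          else rowSums(diffs < 0) == length(mutant_ids)
  pass <- pass & complete
  sel <- if (mode == "sign") {
    pass
  } else {
    idx <- which(complete)
    if (length(idx) < 2) stop("need at least two complete rows to cluster")
    hc <- cluster_rows(V[idx, , drop = FALSE])
    grp <- cutree(hc, k = k %||% max(2L, floor(length(idx) / 10)))
    good <- names(which(tapply(pass[idx], grp, all)))
    out <- rep(FALSE, nrow(V))
    out[idx[grp %in% as.integer(good)]] <- TRUE
    out
  }
  if (!any(sel)) warning("no concordant windows selected")
  w[sel]
}

#' Remove windows overlapping body-methylated genes
#'
#' Windows overlapping (>= 1 bp) a body-methylated gene are removed.
#' Body-methylated genes carry CG-exclusive methylation with high natural
#' variability, so by default only CG-context windows are filtered;
#' windows without a `context` column are all treated as in scope.
#'
#' @param windows Interval table (optionally with a `context` column).
#' @param body_meth_genes Interval table of body-methylated genes.
#' @param contexts Contexts subject to filtering (default `"CG"`).
#' @param min_overlap Overlap threshold in bp (default 1).
#' @return Filtered windows.
#' @export
filter_body_methylated <- function(windows, body_meth_genes,
                                   contexts = "CG", min_overlap = 1L) {
  dt <- as.data.table(windows)
  if (!nrow(dt)) return(dt)
  in_scope <- if ("context" %in% names(dt)) dt$context %in% contexts
              else rep(TRUE, nrow(dt))
  hit <- rep(FALSE, nrow(dt))
  if (nrow(as.data.table(body_meth_genes)))
    hit[unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
      as_granges0(dt), as_granges0(body_meth_genes),
      minoverlap = min_overlap)))] <- TRUE
  dt[!(in_scope & hit)]
}

#' Order matrix rows by mutant-minus-control mean difference
#'
#' Score = mean over mutant columns minus mean over control columns;
#' rows are returned largest to smallest (the heatmap display order),
#' ties broken by genomic coordinate. Rows with missing values in the
#' named columns are excluded with a message.
#'
#' @param x A `DmrMatrix` or matrix.
#' @param mutant_ids,control_ids Column names.
#' @return data.table of windows with `score`, in display order.
#' @export
rank_by_mean_difference <- function(x, mutant_ids, control_ids) {
  V <- mat_values(x)
  stopifnot(all(c(mutant_ids, control_ids) %in% colnames(V)))
  w <- mat_windows(x)
  sub <- V[, c(mutant_ids, control_ids), drop = FALSE]
  keep <- complete.cases(sub)
  if (any(!keep))
    message("excluding ", sum(!keep), " row(s) with missing values")
  score <- rowMeans(V[, mutant_ids, drop = FALSE]) -
    rowMeans(V[, control_ids, drop = FALSE])
  out <- cbind(w, score = score)[keep]
  out[order(-score, chrom, start)]
}

#' Write a DmrMatrix as TSV
#'
#' @param x A `DmrMatrix`.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "DmrMatrix"))
  con <- open_write(path)
  on.exit(close(con))
  dt <- cbind(x$windows, as.data.table(x$values))
  write.table(dt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
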