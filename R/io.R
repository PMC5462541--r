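#' Construct a methylome sample from per-cytosine calls
#'
#' @param calls `data.frame`/`data.table` with columns `chrom`, `pos`
#'   (0-based), `strand` (`"+"`/`"-"`), `context` (`CG`/`CHG`/`CHH`),
#'   `m` (methylated reads) and `n` (total reads), `0 <= m <= n`.
#' @param sample_id Sample identifier.
#' @param genotype `"control"` or `"mutant"`.
#' @param replicate Replicate tag.
#' @return A `MethylomeSample`: list with metadata and the sorted,
#'   duplicate-free `calls` table.
#' @export
methylome_sample <- function(calls, sample_id, genotype = "control",
                             replicate = "r1") {
  calls <- as.data.table(calls)
  req <- c("chrom", "pos", "strand", "context", "m", "n")
  if (!all(req %in% names(calls)))
    stop("calls must have columns: ", paste(req, collapse = ", "))
  calls <- calls[, req, with = FALSE]
  if (any(calls$m > calls$n) || any(calls$m < 0) || any(calls$n < 0))
    stop("invalid counts: require 0 <= m <= n")
  if (!all(calls$context %in% CONTEXTS))
    stop("unknown context token(s): ",
         paste(unique(setdiff(calls$context, CONTEXTS)), collapse = ", "))
  if (!all(calls$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (anyDuplicated(calls, by = c("chrom", "pos", "strand")))
    stop("duplicate (chrom, pos, strand) keys in calls")
  new_methylome_sample(calls, sample_id, genotype, replicate)
}

# fast path used by the simulator (input already validated/sorted)
new_methylome_sample <- function(calls, sample_id, genotype, replicate) {
  setkey(calls, chrom, pos, strand)
  structure(list(sample_id = sample_id, genotype = genotype,
                 replicate = replicate, calls = calls[]),
            class = "MethylomeSample")
}

#' @export
print.MethylomeSample <- function(x, ...) {
  cat(sprintf("MethylomeSample %s (%s, %s): %d cytosine calls on %d chromosome(s)\n",
              x$sample_id, x$genotype, x$replicate, nrow(x$calls),
              length(unique(x$calls$chrom))))
  invisible(x)
}

open_read <- function(path) gzfile(path)  # gzip-transparent, plain ok
open_write <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "w")
}

#' Write a per-cytosine call table
#'
#' Tab-separated with header `chrom pos strand context m n` (a CGmap-style
#' per-cytosine table). Positions are written 0-based unless
#' `one_based = TRUE`. A `.gz` suffix writes gzip.
#'
#' @param sample A `MethylomeSample`.
#' @param path Output path.
#' @param one_based Write 1-based positions.
#' @export
write_calls <- function(sample, path, one_based = FALSE) {
  stopifnot(inherits(sample, "MethylomeSample"))
  dt <- copy(sample$calls)
  if (one_based) dt[, pos := pos + 1L]
  con <- open_write(path)
  on.exit(close(con))
  write.table(dt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cytosine call table
#'
#' Rejects malformed rows (`m > n`, negative counts, unknown context)
#' with the offending line numbers. `one_based = TRUE` converts 1-based
#' input positions to the internal 0-based convention.
#'
#' @param path Input path (gzip-transparent).
#' @param sample_id,genotype,replicate Metadata for the sample.
#' @param one_based Input positions are 1-based.
#' @return A `MethylomeSample`.
#' @export
read_calls <- function(path, sample_id = basename(path),
                       genotype = "control", replicate = "r1",
                       one_based = FALSE) {
  df <- read.table(open_read(path), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "strand", "context", "m", "n")
  if (!all(req %in% names(df)))
    stop("call table must have columns: ", paste(req, collapse = ", "))
  bad <- which(df$m > df$n | df$m < 0 | df$n < 0)
  if (length(bad))
    stop("malformed counts (m > n or negative) at line(s): ",
         paste(head(bad + 1L, 10), collapse = ", "))
  badc <- which(!df$context %in% CONTEXTS)
  if (length(badc))
    stop("unknown context token at line(s): ",
         paste(head(badc + 1L, 10), collapse = ", "))
  dt <- as.data.table(df)
  if (one_based) dt[, pos := pos - 1L]
  methylome_sample(dt, sample_id, genotype, replicate)
}

#' Export a genome-browser methylation track
#'
#' Writes percent methylation (`100 * m / n`) for all cytosines of one
#' context with coverage `n >= min_coverage`, as bedGraph (0-based
#' half-open) or wiggle `variableStep` (1-based).
#'
#' @param sample A `MethylomeSample`.
#' @param path Output path.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param min_coverage Coverage filter (default 4; dense targeted tracks
#'   conventionally use 5).
#' @param format `"bedGraph"` or `"wig"`.
#' @return The path, invisibly. Warns (and still writes a valid, empty
#'   track) when no site passes the filter.
#' @export
export_track <- function(sample, path, context = "CG", min_coverage = 4L,
                         format = c("bedGraph", "wig")) {
  stopifnot(inherits(sample, "MethylomeSample"), min_coverage >= 1,
            context %in% CONTEXTS)
  format <- match.arg(format)
  cl <- sample$calls
  dt <- cl[cl$context == context & cl$n >= min_coverage]
  if (!nrow(dt)) warning("no sites pass the coverage filter; empty track")
  con <- open_write(path)
  on.exit(close(con))
  name <- paste0(sample$sample_id, "_", context)
  if (format == "bedGraph") {
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
    if (nrow(dt))
      writeLines(sprintf("%s\t%d\t%d\t%s", dt$chrom, dt$pos, dt$pos + 1L,
                         format(100 * dt$m / dt$n, trim = TRUE)), con)
  } else {
    writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
    for (cn in unique(dt$chrom)) {
      sub <- dt[dt$chrom == cn]
      writeLines(sprintf("variableStep chrom=%s", cn), con)
      writeLines(sprintf("%d %s", sub$pos + 1L,
                         format(100 * sub$m / sub$n, trim = TRUE)), con)
    }
  }
  invisible(path)
}

#' Global methylation level per context
#'
#' Pooled `sum(m) / sum(n)` per context over all cytosines meeting the
#' coverage floor. A context with no qualifying coverage is reported as
#' `NA` (undefined), not 0.
#'
#' @param sample A `MethylomeSample`.
#' @param min_coverage Per-cytosine coverage floor (default 4).
#' @return Named numeric fraction in `[0, 1]` for `CG`, `CHG`, `CHH`.
#' @export
global_methylation <- function(sample, min_coverage = 4L) {
  stopifnot(inherits(sample, "MethylomeSample"))
  cl <- sample$calls
  agg <- cl[cl$n >= min_coverage, .(m = sum(m), n = sum(n)), by = context]
  out <- setNames(rep(NA_real_, 3), CONTEXTS)
  ok <- agg$n > 0
  out[agg$context[ok]] <- agg$m[ok] / agg$n[ok]
  out
}

#' Estimate the bisulfite conversion rate from unmethylated regions
#'
#' Pools all contexts over cytosines in designated truly-unmethylated
#' regions and returns `1 - sum(m) / sum(n)`: any apparent methylation
#' there is attributed to failed conversion. The choice of designated
#' regions (e.g. chloroplast or regions known to be unmethylated) is the
#' caller's; this estimator only defines the arithmetic.
#'
#' @param sample A `MethylomeSample`.
#' @param regions Intervals (`chrom`, `start`, `end`, 0-based half-open).
#' @param min_sites Minimum covered cytosines required (default 100).
#' @return Estimated conversion fraction in `[0, 1]`.
#' @export
estimate_conversion <- function(sample, regions, min_sites = 100L) {
  stopifnot(inherits(sample, "MethylomeSample"))
  sub <- calls_in_regions(sample$calls, as.data.table(regions))
  sub <- sub[sub$n > 0]
  if (nrow(sub) < min_sites)
    stop(sprintf("insufficient covered cytosines in designated regions: found %d, need >= %d",
                 nrow(sub), min_sites))
  1 - sum(sub$m) / sum(sub$n)
}

# subset calls falling inside any of the given 0-based half-open regions
calls_in_regions <- function(calls, regions) {
  if (!nrow(regions)) return(calls[0])
  q <- GenomicRanges::GRanges(calls$chrom,
                              IRanges::IRanges(calls$pos + 1L, calls$pos + 1L))
  f <- as_granges0(regions)
  hits <- S4Vectors::queryHits(GenomicRanges::findOverlaps(q, f))
  calls[sort(unique(hits))]
}

#' Read a BED file of intervals
#'
#' BED3/BED6; returns 0-based half-open intervals.
#'
#' @param path Input path (gzip-transparent).
#' @return data.table with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- read.table(open_read(path), sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- nm[seq_len(min(ncol(df), 6L))]
  dt <- as.data.table(df)
  if (any(dt$start >= dt$end)) stop("BED intervals require start < end")
  setkey(dt, chrom, start)
  dt[]
}

#' Write intervals as BED
#'
#' @param intervals data.table/data.frame with `chrom`, `start`, `end`
#'   and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  dt <- as.data.table(intervals)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(dt))
  con <- open_write(path)
  on.exit(close(con))
  if (nrow(dt))
    write.table(dt[, cols, with = FALSE], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}
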