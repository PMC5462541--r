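# Interval algebra over 0-based half-open intervals, delegated to
# GenomicRanges/IRanges internally (converted to 1-based closed and back).

as_granges0 <- function(x) {
  x <- as.data.table(x)
  if (!nrow(x))
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

as_intervals0 <- function(gr) {
  if (!length(gr))
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  setkey(dt, chrom, start)
  dt[]
}

#' Decompose intervals into fixed-width windows
#'
#' Each interval is chopped into consecutive `window`-bp pieces starting
#' at its own start; the final sub-window shorter than `window` is kept,
#' so covered basepairs are conserved. Extra columns are carried over.
#'
#' @param intervals data.table with `chrom`, `start`, `end`.
#' @param window Window width (default 100).
#' @return data.table of windows.
#' @export
chop_windows <- function(intervals, window = 100L) {
  dt <- as.data.table(intervals)
  if (!nrow(dt))
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  nwin <- as.integer(ceiling((dt$end - dt$start) / window))
  idx <- rep.int(seq_len(nrow(dt)), nwin)
  off <- (sequence(nwin) - 1L) * as.integer(window)
  out <- dt[idx]
  out[, start := dt$start[idx] + off]
  out[, end := pmin(start + as.integer(window), dt$end[idx])]
  setkey(out, chrom, start)
  out[]
}

#' Direct N-way DMR intersection, decomposed into windows
#'
#' Genomic intersection of every input set (a "direct" overlap: present
#' in all N comparisons), then chopped into `window`-bp pieces so that
#' the common regions keep the nominal DMR size.
#'
#' @param sets List of >= 2 interval tables (same context/direction).
#' @param window Window width for the decomposition (default 100).
#' @return data.table of intersection windows.
#' @export
intersect_direct <- function(sets, window = 100L) {
  if (!length(sets)) stop("empty input: need at least two DMR sets")
  if (length(sets) < 2) stop("need at least two DMR sets to intersect")
  grs <- lapply(sets, function(s) GenomicRanges::reduce(as_granges0(s)))
  inter <- Reduce(GenomicRanges::intersect, grs)
  chop_windows(as_intervals0(inter), window)
}

#' Windows shared by at least k of N interval sets
#'
#' Depth-stacking overlap count: for every k from 2 to N, reports the
#' regions covered by at least k sets, decomposed into windows.
#'
#' @param sets List of interval tables.
#' @param window Window width (default 100).
#' @return data.table with `k`, `n_regions`, `n_windows`, `bp`.
#' @export
overlap_depth <- function(sets, window = 100L) {
  stopifnot(length(sets) >= 2)
  grs <- lapply(sets, function(s) GenomicRanges::reduce(as_granges0(s)))
  all_gr <- do.call(c, unname(grs))
  if (!length(all_gr))
    return(data.table(k = 2:length(sets), n_regions = 0L, n_windows = 0L,
                      bp = 0L))
  cov <- GenomicRanges::coverage(all_gr)
  rbindlist(lapply(2:length(sets), function(k) {
    sl <- IRanges::slice(cov, lower = k, rangesOnly = TRUE)
    regions <- rbindlist(lapply(names(sl), function(cn) {
      ir <- sl[[cn]]
      if (!length(ir)) return(NULL)
      data.table(chrom = cn, start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir))
    }))
    if (is.null(regions) || !nrow(regions))
      return(data.table(k = k, n_regions = 0L, n_windows = 0L, bp = 0L))
    data.table(k = k, n_regions = nrow(regions),
               n_windows = nrow(chop_windows(regions, window)),
               bp = sum(regions$end - regions$start))
  }))
}

#' Merge intervals separated by at most a given gap
#'
#' Intervals whose gap (`next start - previous end` in half-open
#' coordinates) is `<= distance` are merged transitively. With
#' `by = "context"` merging is restricted within each context.
#'
#' @param intervals Interval table.
#' @param distance Maximum gap to bridge (default 300).
#' @param by Optional column name(s) to merge within (e.g. `"context"`).
#' @return Merged interval table (plus the `by` columns, when used).
#' @export
merge_within <- function(intervals, distance = 300L, by = NULL) {
  dt <- as.data.table(intervals)
  merge1 <- function(x)
    as_intervals0(GenomicRanges::reduce(as_granges0(x),
                                        min.gapwidth = distance + 1L))
  if (is.null(by)) return(merge1(dt))
  out <- dt[, merge1(.SD), by = by]
  setcolorder(out, c("chrom", "start", "end"))
  setkey(out, chrom, start)
  out[]
}

#' Combine per-context merged DMRs into context-agnostic regions
#'
#' Multiset union of the per-context sets, then overlapping or directly
#' adjacent (gap exactly 0) regions are joined. This produces the merged
#' "hyper mC" regions used for cross-mutant comparisons.
#'
#' @param merged_by_context List of interval tables (one per context) or
#'   a single table.
#' @return Joined interval table.
#' @export
union_across_contexts <- function(merged_by_context) {
  dt <- if (is.data.frame(merged_by_context)) as.data.table(merged_by_context)
        else rbindlist(lapply(merged_by_context, function(x)
          as.data.table(x)[, .(chrom, start, end)]), use.names = TRUE)
  as_intervals0(GenomicRanges::reduce(as_granges0(dt)))  # gap 0 joined
}

#' Keep or drop intervals by annotation overlap
#'
#' `element_of` keeps query intervals overlapping at least `min_overlap`
#' bp of any feature; `not_element_of` keeps the complement. The two
#' modes partition the query.
#'
#' @param query Interval table.
#' @param features Interval table of annotation features.
#' @param mode `"element_of"` or `"not_element_of"`.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Subset of `query` (all columns preserved).
#' @export
overlap_annotation <- function(query, features,
                               mode = c("element_of", "not_element_of"),
                               min_overlap = 1L) {
  mode <- match.arg(mode)
  q <- as.data.table(query)
  hits <- integer()
  if (nrow(q) && nrow(as.data.table(features)))
    hits <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
      as_granges0(q), as_granges0(features), minoverlap = min_overlap)))
  keep <- seq_len(nrow(q)) %in% hits
  if (mode == "not_element_of") keep <- !keep
  q[keep]
}

#' Converge DMR windows into loci
#'
#' Merges DMRs across contexts and directions when they overlap or lie
#' within `merge_distance` bp, and summarises each resulting locus by its
#' member count, the contexts present and a direction summary (`"hyper"`,
#' `"hypo"` or `"mixed"`).
#'
#' @param dmrs Interval table with `context` and `direction` columns.
#' @param merge_distance Maximum gap to bridge (default 300).
#' @return data.table of loci: `chrom`, `start`, `end`, `n_members`,
#'   `contexts`, `direction`.
#' @export
converge_to_loci <- function(dmrs, merge_distance = 300L) {
  dt <- as.data.table(dmrs)
  if (!nrow(dt))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      contexts = character(), direction = character()))
  gr <- as_granges0(dt)
  loci <- GenomicRanges::reduce(gr, min.gapwidth = merge_distance + 1L)
  hits <- GenomicRanges::findOverlaps(gr, loci)
  mem <- data.table(locus = S4Vectors::subjectHits(hits),
                    context = dt$context[S4Vectors::queryHits(hits)],
                    direction = dt$direction[S4Vectors::queryHits(hits)])
  summ <- mem[, .(n_members = .N,
                  contexts = paste(sort(unique(context)), collapse = ","),
                  direction = if (uniqueN(direction) == 1L) direction[1L]
                              else "mixed"),
              by = locus][order(locus)]
  # keep the reduce() order so locus indices align with the summary rows
  li <- data.table(chrom = as.character(GenomicRanges::seqnames(loci)),
                   start = GenomicRanges::start(loci) - 1L,
                   end = GenomicRanges::end(loci))
  out <- cbind(li, summ[, -"locus"])
  setkey(out, chrom, start)
  out[]
}
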