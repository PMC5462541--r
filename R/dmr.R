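#' DMR-calling thresholds
#'
#' Context-specific absolute methylation-difference minima (0.40 CG,
#' 0.20 CHG, 0.10 CHH), an FDR ceiling of 0.01, and bin eligibility
#' rules: at least 4 cytosines of the context covered by at least
#' 4 reads in both samples, over 100-bp non-overlapping bins.
#'
#' @param delta_min Named minima per context.
#' @param q_max BH-adjusted p-value ceiling.
#' @param min_sites Minimum eligible cytosines per bin (both samples).
#' @param min_coverage Minimum reads per cytosine to count it.
#' @param bin_width Bin width in bp.
#' @return A `dmr_thresholds` list.
#' @export
dmr_thresholds <- function(delta_min = c(CG = 0.40, CHG = 0.20, CHH = 0.10),
                           q_max = 0.01, min_sites = 4L,
                           min_coverage = 4L, bin_width = 100L) {
  stopifnot(all(CONTEXTS %in% names(delta_min)),
            all(delta_min > 0), all(delta_min <= 1),
            q_max > 0, q_max < 1, min_sites >= 1, min_coverage >= 1,
            bin_width >= 1)
  structure(list(delta_min = delta_min[CONTEXTS], q_max = q_max,
                 min_sites = as.integer(min_sites),
                 min_coverage = as.integer(min_coverage),
                 bin_width = as.integer(bin_width)),
            class = "dmr_thresholds")
}

#' Tile chromosomes into non-overlapping bins
#'
#' Half-open windows from position 0; the final partial window is kept.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin_width Bin width in bp (default 100).
#' @return data.table with `chrom`, `start`, `end`.
#' @export
bin_genome <- function(chrom_lengths, bin_width = 100L) {
  stopifnot(bin_width > 0)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  rbindlist(lapply(names(chrom_lengths), function(cn) {
    L <- as.integer(chrom_lengths[[cn]])
    starts <- seq(0L, L - 1L, by = bin_width)
    data.table(chrom = cn, start = starts, end = pmin(starts + bin_width, L))
  }))
}

#' Aggregate per-cytosine calls into bins for one context
#'
#' Pools methylated and total counts over all cytosines of the context
#' (both strands) with coverage `n >= min_site_coverage`, per bin, and
#' records the number of contributing cytosines.
#'
#' @param sample A `MethylomeSample`.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param bin_width Bin width in bp.
#' @param min_site_coverage Per-cytosine coverage floor.
#' @return data.table keyed by (`chrom`, `start`) with `end`, `sites`,
#'   `m_sum`, `n_sum`, `level`; attributes `context` and `bin_width`.
#' @export
aggregate_bins <- function(sample, context, bin_width = 100L,
                           min_site_coverage = 4L) {
  stopifnot(inherits(sample, "MethylomeSample"), context %in% CONTEXTS)
  cl <- sample$calls
  sel <- cl$context == context & cl$n >= min_site_coverage
  agg <- cl[sel, .(sites = .N, m_sum = sum(m), n_sum = sum(n)),
            by = .(chrom, start = (pos %/% as.integer(bin_width)) *
                     as.integer(bin_width))]
  agg[, `:=`(end = start + as.integer(bin_width),
             level = fifelse(n_sum > 0, m_sum / n_sum, NA_real_))]
  setcolorder(agg, c("chrom", "start", "end"))
  setkey(agg, chrom, start)
  setattr(agg, "context", context)
  setattr(agg, "bin_width", as.integer(bin_width))
  agg[]
}

#' Call DMRs between one mutant and its paired control
#'
#' Bins eligible in both samples (`sites >= min_sites` and `n_sum > 0`)
#' are tested with a two-sided Fisher exact test on the pooled 2x2 count
#' table, adjusted by Benjamini-Hochberg across all eligible bins of this
#' context and comparison. A bin is a DMR when `q <= q_max` and
#' `|level_mut - level_ctl| >= delta_min[context]`; direction follows the
#' sign of the difference (hyper = higher in the mutant).
#'
#' @param mutant,control [aggregate_bins()] tables over the same tiling
#'   and context.
#' @param thresholds A [dmr_thresholds()].
#' @param comparison_id Label recorded on every row.
#' @return data.table of all eligible bins with `delta`, `p`, `q`,
#'   `direction` and logical `called`; class `dmr_calls`.
#' @export
call_dmrs <- function(mutant, control, thresholds = dmr_thresholds(),
                      comparison_id = "mut_vs_ctl") {
  ctx <- attr(mutant, "context")
  if (!identical(ctx, attr(control, "context")))
    stop("context mismatch between aggregates")
  if (!identical(attr(mutant, "bin_width"), attr(control, "bin_width")))
    stop("mismatched bin tilings")
  j <- merge(mutant, control, by = c("chrom", "start", "end"),
             suffixes = c("_mut", "_ctl"))
  e <- j[sites_mut >= thresholds$min_sites &
           sites_ctl >= thresholds$min_sites &
           n_sum_mut > 0 & n_sum_ctl > 0]
  e[, delta := level_mut - level_ctl]
  if (nrow(e)) {
    e[, p := fisher_exact_2x2(m_sum_mut, n_sum_mut, m_sum_ctl, n_sum_ctl)]
    e[, q := p.adjust(p, method = "BH")]
  } else {
    e[, `:=`(p = numeric(), q = numeric())]
  }
  e[, direction := fifelse(delta > 0, "hyper",
                           fifelse(delta < 0, "hypo", NA_character_))]
  e[, called := q <= thresholds$q_max &
      abs(delta) >= thresholds$delta_min[[ctx]]]
  e[, `:=`(context = ctx, comparison = comparison_id)]
  setkey(e, chrom, start)
  setattr(e, "thresholds", thresholds)
  setattr(e, "class", c("dmr_calls", class(e)))
  e[]
}

#' Call DMRs in all three contexts for one sample pair
#'
#' @param mutant_sample,control_sample `MethylomeSample`s.
#' @param thresholds A [dmr_thresholds()].
#' @param contexts Contexts to test.
#' @param comparison_id Label for the comparison.
#' @return Combined `dmr_calls` table across contexts (BH adjustment is
#'   per context, as contexts are tested independently).
#' @export
compare_methylomes <- function(mutant_sample, control_sample,
                               thresholds = dmr_thresholds(),
                               contexts = CONTEXTS,
                               comparison_id = NULL) {
  comparison_id <- comparison_id %||%
    paste0(mutant_sample$sample_id, "_vs_", control_sample$sample_id)
  out <- rbindlist(lapply(contexts, function(ctx) {
    call_dmrs(
      aggregate_bins(mutant_sample, ctx, thresholds$bin_width,
                     thresholds$min_coverage),
      aggregate_bins(control_sample, ctx, thresholds$bin_width,
                     thresholds$min_coverage),
      thresholds, comparison_id)
  }))
  setattr(out, "thresholds", thresholds)
  setattr(out, "class", c("dmr_calls", class(out)))
  out[]
}

#' Extract called DMRs as intervals
#'
#' @param calls A [call_dmrs()]/[compare_methylomes()] table.
#' @param context,direction Optional filters.
#' @return data.table of DMR intervals with `context`, `direction`,
#'   `delta`, `p`, `q`, `comparison`.
#' @export
dmr_intervals <- function(calls, context = NULL, direction = NULL) {
  d <- calls[calls$called]
  # compute filters outside `[` so argument names never collide with columns
  keep <- rep(TRUE, nrow(d))
  if (!is.null(context)) keep <- keep & d$context %in% context
  if (!is.null(direction)) keep <- keep & d$direction %in% direction
  d <- d[keep]
  out <- d[, .(chrom, start, end, context, direction, delta, p, q,
               comparison)]
  setkey(out, chrom, start)
  out[]
}

#' Write called DMRs as BED6
#'
#' Name is `context:direction`; score is `-10 * log10(q)` capped at 1000.
#'
#' @param dmrs A [dmr_intervals()] table.
#' @param path Output BED path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dt <- as.data.table(dmrs)
  out <- dt[, .(chrom, start, end,
                name = paste(context, direction, sep = ":"),
                score = pmin(round(-10 * log10(pmax(q, 1e-100))), 1000),
                strand = ".")]
  write_bed(out, path)
}

#' Write the full DMR test table as TSV
#'
#' @param calls A `dmr_calls` table.
#' @param path Output path.
#' @export
write_dmr_tsv <- function(calls, path) {
  con <- open_write(path)
  on.exit(close(con))
  write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
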