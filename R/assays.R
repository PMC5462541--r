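#' Construct a clone-based bisulfite alignment
#'
#' Holds the methylation pattern of Sanger-sequenced clones of one
#' bisulfite PCR amplicon: for each reference cytosine (single strand),
#' each clone is methylated (1), unmethylated (0) or ambiguous (`NA`).
#'
#' @param patterns Matrix (clones x cytosines) of 1/0/`NA`.
#' @param positions 0-based positions of the reference cytosines on the
#'   amplicon.
#' @param contexts Context (`CG`/`CHG`/`CHH`) per cytosine.
#' @param clone_ids Optional clone identifiers.
#' @return A `CloneAlignment` object.
#' @export
clone_alignment <- function(patterns, positions, contexts,
                            clone_ids = NULL) {
  patterns <- as.matrix(patterns)
  stopifnot(ncol(patterns) == length(positions),
            length(contexts) == length(positions),
            all(contexts %in% CONTEXTS),
            all(patterns %in% c(0, 1) | is.na(patterns)))
  o <- order(positions)
  patterns <- patterns[, o, drop = FALSE]
  rownames(patterns) <- clone_ids %||% rownames(patterns) %||%
    paste0("clone", seq_len(nrow(patterns)))
  structure(list(patterns = patterns, positions = as.integer(positions[o]),
                 contexts = contexts[o]),
            class = "CloneAlignment")
}

#' @export
print.CloneAlignment <- function(x, ...) {
  cat(sprintf("CloneAlignment: %d clones x %d cytosines (%s)\n",
              nrow(x$patterns), ncol(x$patterns),
              paste(sprintf("%s=%d", CONTEXTS,
                            tabulate(match(x$contexts, CONTEXTS), 3L)),
                    collapse = " ")))
  invisible(x)
}

#' Read clone bisulfite reads aligned to an amplicon reference
#'
#' Reads a FASTA of bisulfite clone sequences pre-aligned to the
#' reference (equal lengths, gaps as `-`). At each plus-strand reference
#' cytosine, a clone `C` is methylated, `T` unmethylated, anything else
#' ambiguous. Traditional bisulfite sequencing captures one strand only,
#' so only plus-strand cytosines are scored.
#'
#' @param path FASTA of aligned clone sequences.
#' @param reference Amplicon reference sequence (character string).
#' @return A `CloneAlignment`.
#' @export
read_clone_fasta <- function(path, reference) {
  seqs <- Biostrings::readDNAStringSet(path)
  ref <- toupper(reference)
  if (!all(Biostrings::width(seqs) == nchar(ref)))
    stop("clone sequences must be pre-aligned to the reference (equal length)")
  sites <- cytosine_sites(ref)
  sites <- sites[sites$strand == "+"]
  chars <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  obs <- chars[, sites$pos + 1L, drop = FALSE]
  pat <- matrix(NA_real_, nrow(obs), ncol(obs))
  pat[obs == "C"] <- 1
  pat[obs == "T"] <- 0
  clone_alignment(pat, sites$pos, sites$context,
                  clone_ids = names(seqs))
}

#' Filter clones: de-duplication and non-conversion screening
#'
#' Removes exact-duplicate methylation patterns (keeping one
#' representative) and clones showing runs of apparent methylation that
#' are better explained by failed bisulfite conversion. The default
#' non-conversion rule flags a clone when, within any `window_bp` window
#' containing at least `min_chh` informative CHH positions, the clone is
#' methylated at `>= clone_meth_min` of them while the across-clone mean
#' CHH methylation of that window is `< pop_mean_max`.
#'
#' @param clones A `CloneAlignment`.
#' @param dedup Collapse identical patterns (default `TRUE`).
#' @param window_bp Sliding window width in bp (default 150).
#' @param clone_meth_min Within-clone CHH methylated fraction that
#'   triggers the rule (default 0.95).
#' @param pop_mean_max Across-clone CHH mean below which the run is
#'   deemed non-conversion rather than true methylation (default 0.20).
#' @param min_chh Minimum informative CHH positions per window (default 5).
#' @return Filtered `CloneAlignment`; removals are reported via messages
#'   and recorded in `attr(, "removed")`. Errors if no clone survives.
#' @export
filter_clones <- function(clones, dedup = TRUE, window_bp = 150L,
                          clone_meth_min = 0.95, pop_mean_max = 0.20,
                          min_chh = 5L) {
  stopifnot(inherits(clones, "CloneAlignment"))
  pat <- clones$patterns
  removed <- data.table(clone = character(), reason = character())
  key <- apply(pat, 1L, function(r) paste(ifelse(is.na(r), ".", r),
                                          collapse = ""))
  if (dedup) {
    dup <- duplicated(key)
    if (any(dup)) {
      message("removing ", sum(dup), " duplicate clone pattern(s): ",
              paste(rownames(pat)[dup], collapse = ", "))
      removed <- rbind(removed, data.table(clone = rownames(pat)[dup],
                                           reason = "duplicate"))
      pat <- pat[!dup, , drop = FALSE]
    }
  }
  chh <- which(clones$contexts == "CHH")
  if (length(chh)) {
    pos <- clones$positions
    pop_mean <- colMeans(pat[, chh, drop = FALSE], na.rm = TRUE)
    flag <- rep(FALSE, nrow(pat))
    for (a in chh) {  # windows anchored at each CHH position
      inwin <- chh[pos[chh] >= pos[a] & pos[chh] < pos[a] + window_bp]
      if (length(inwin) < min_chh) next
      wmean <- mean(pop_mean[match(inwin, chh)], na.rm = TRUE)
      if (is.nan(wmean) || wmean >= pop_mean_max) next
      sub <- pat[, inwin, drop = FALSE]
      inf <- rowSums(!is.na(sub))
      frac <- rowSums(sub == 1, na.rm = TRUE) / inf
      flag <- flag | (inf >= min_chh & frac >= clone_meth_min)
    }
    if (any(flag)) {
      message("removing ", sum(flag), " clone(s) with apparent non-conversion: ",
              paste(rownames(pat)[flag], collapse = ", "))
      removed <- rbind(removed, data.table(clone = rownames(pat)[flag],
                                           reason = "non_conversion"))
      pat <- pat[!flag, , drop = FALSE]
    }
  }
  if (!nrow(pat)) stop("all clones removed by filtering")
  out <- clone_alignment(pat, clones$positions, clones$contexts,
                         clone_ids = rownames(pat))
  setattr(out, "removed", removed[])
  out
}

#' Summarise a clone alignment
#'
#' Per-cytosine percent methylation across clones (ambiguous calls
#' excluded from numerator and denominator) and the per-clone mean
#' methylation distribution, which distinguishes a uniform population
#' from a bimodal mixture of fully methylated and unmethylated clones.
#' Clones with only ambiguous calls are dropped with a message.
#'
#' @param clones A `CloneAlignment`.
#' @return List with `per_cytosine` (data.table: `pos`, `context`,
#'   `percent`, `n_informative`) and `per_clone` (named mean methylation
#'   per clone).
#' @export
clone_summary <- function(clones) {
  stopifnot(inherits(clones, "CloneAlignment"))
  pat <- clones$patterns
  allna <- rowSums(!is.na(pat)) == 0L
  if (any(allna)) {
    message("dropping ", sum(allna), " all-ambiguous clone(s): ",
            paste(rownames(pat)[allna], collapse = ", "))
    pat <- pat[!allna, , drop = FALSE]
  }
  if (!nrow(pat)) stop("no informative clones")
  list(per_cytosine = data.table(
         pos = clones$positions, context = clones$contexts,
         percent = 100 * colMeans(pat == 1, na.rm = TRUE),
         n_informative = colSums(!is.na(pat))),
       per_clone = rowMeans(pat == 1, na.rm = TRUE))
}

#' Write a clone pattern table
#'
#' Plain-text methylation pattern table (one row per clone, one column
#' per cytosine; `M` methylated, `U` unmethylated, `.` ambiguous).
#'
#' @param clones A `CloneAlignment`.
#' @param path Output path.
#' @export
write_pattern_tsv <- function(clones, path) {
  stopifnot(inherits(clones, "CloneAlignment"))
  sym <- matrix(".", nrow(clones$patterns), ncol(clones$patterns))
  sym[clones$patterns == 1] <- "M"
  sym[clones$patterns == 0] <- "U"
  df <- data.frame(clone = rownames(clones$patterns), sym)
  names(df)[-1L] <- sprintf("%s_%d", clones$contexts, clones$positions)
  con <- open_write(path)
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantify average methylation over a target region
#'
#' Pooled percent methylation per context within a window, plus the
#' count of distinct reference cytosines contributing. Region bounds are
#' 1-based inclusive by default, matching how targeted regions are
#' conventionally printed (e.g. a promoter "282-1036"); set
#' `one_based = FALSE` for 0-based half-open bounds.
#'
#' For call tables both strands are counted unless
#' `strand_scope = "plus_only"`; clone alignments are single-strand by
#' construction, so their cytosine counts over the same window differ
#' from double-strand sequencing counts.
#'
#' @param x A `MethylomeSample` or `CloneAlignment`.
#' @param start,end Region bounds.
#' @param ... Method-specific arguments.
#' @return data.table with one row per requested context: `percent`
#'   (`NA` when no covered cytosine), `n_cytosines`, `m_sum`, `n_sum`.
#' @export
quantify_region <- function(x, start, end, ...) UseMethod("quantify_region")

#' @rdname quantify_region
#' @param chrom Chromosome (defaults to the sample's only chromosome).
#' @param contexts Contexts to report.
#' @param min_coverage Per-cytosine coverage floor (default 4).
#' @param one_based Bounds are 1-based inclusive (default `TRUE`).
#' @param strand_scope `"both"` or `"plus_only"`.
#' @export
quantify_region.MethylomeSample <- function(x, start, end, chrom = NULL,
                                            contexts = CONTEXTS,
                                            min_coverage = 4L,
                                            one_based = TRUE,
                                            strand_scope = c("both", "plus_only"),
                                            ...) {
  strand_scope <- match.arg(strand_scope)
  if (is.null(chrom)) {
    chrom <- unique(x$calls$chrom)
    if (length(chrom) != 1L)
      stop("sample has multiple chromosomes; specify `chrom`")
  }
  s0 <- if (one_based) start - 1L else start
  e0 <- end
  cl <- x$calls
  sel <- cl$chrom == chrom & cl$pos >= s0 & cl$pos < e0 &
    cl$n >= min_coverage
  if (strand_scope == "plus_only") sel <- sel & cl$strand == "+"
  pool_contexts(cl[sel], contexts)
}

#' @rdname quantify_region
#' @export
quantify_region.CloneAlignment <- function(x, start, end,
                                           contexts = CONTEXTS,
                                           one_based = TRUE, ...) {
  s0 <- if (one_based) start - 1L else start
  e0 <- end
  keep <- x$positions >= s0 & x$positions < e0
  pat <- x$patterns[, keep, drop = FALSE]
  ctx <- x$contexts[keep]
  rbindlist(lapply(contexts, function(cc) {
    cols <- which(ctx == cc)
    sub <- pat[, cols, drop = FALSE]
    n_sum <- sum(!is.na(sub))
    m_sum <- sum(sub == 1, na.rm = TRUE)
    data.table(context = cc,
               percent = if (n_sum > 0) 100 * m_sum / n_sum else NA_real_,
               n_cytosines = length(cols), m_sum = m_sum, n_sum = n_sum)
  }))
}

pool_contexts <- function(calls, contexts) {
  rbindlist(lapply(contexts, function(cc) {
    sub <- calls[calls$context == cc]
    n_sum <- sum(sub$n)
    data.table(context = cc,
               percent = if (n_sum > 0) 100 * sum(sub$m) / n_sum else NA_real_,
               n_cytosines = nrow(sub), m_sum = sum(sub$m), n_sum = n_sum)
  }))
}

#' McrBC-qPCR relative methylation
#'
#' `100 - 100 * 2^(Ct_mock - Ct_treated)`: McrBC cleaves methylated DNA,
#' so a later treated Ct (positive `Ct_treated - Ct_mock`) means more
#' template was destroyed, i.e. more methylation. Values are bounded
#' above by 100 and strictly increasing in `Ct_treated - Ct_mock`.
#'
#' Negative values (treated amplifying earlier than mock, i.e. assay
#' noise) are reported as-is with a warning unless `clip0 = TRUE`. A
#' treated reaction with no amplification (`NA`) is reported as 100;
#' no amplification in mock is undefined (`NA`).
#'
#' @param ct_mock,ct_treated qPCR cycle thresholds (vectors).
#' @param clip0 Clip negative values to 0 (default `FALSE`).
#' @return Numeric percent relative methylation.
#' @export
mcrbc_relative_methylation <- function(ct_mock, ct_treated, clip0 = FALSE) {
  stopifnot(length(ct_mock) == length(ct_treated))
  out <- 100 - 100 * 2^(ct_mock - ct_treated)
  out[is.na(ct_treated) & !is.na(ct_mock)] <- 100
  out[is.na(ct_mock)] <- NA_real_
  if (any(out < 0, na.rm = TRUE))
    warning("negative relative methylation (treated amplified before mock): ",
            "likely assay noise")
  if (clip0) out <- pmax(out, 0)
  out
}
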