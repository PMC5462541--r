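#' Build a seeded synthetic reference genome with methylation compartments
#'
#' Generates random nucleotide sequences and partitions each chromosome
#' into blocks assigned to one of three compartment classes that emulate
#' the large-scale organisation of a plant methylome:
#' `TE_like` (transposons/repeats, heavily methylated in all contexts),
#' `gene_body_CG` (body-methylated genes, CG-only methylation) and
#' `unmethylated` (unmethylated genes and intergenic space).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp),
#'   each at least 10 kb. Unnamed vectors get names `chr1`, `chr2`, ...
#' @param seed Integer seed; identical inputs give byte-identical output.
#' @param compartments Optional `data.frame` with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `class`; must be non-overlapping and
#'   within chromosome bounds. When `NULL`, compartments are generated by
#'   assigning `block_bp` blocks to classes with probabilities
#'   `compartment_fractions`.
#' @param compartment_fractions Named fractions for `TE_like`,
#'   `gene_body_CG` and `unmethylated`; must sum to at most 1, any
#'   remainder goes to `unmethylated`.
#' @param block_bp Block size used when generating compartments.
#' @return A `ReferenceModel`: list with `chrom_names`, `chrom_lengths`,
#'   `sequences` (named character), `compartments` (data.table) and
#'   `sites` (data.table of every context-resolved cytosine with its
#'   compartment class).
#' @export
build_reference <- function(chrom_lengths,
                            seed = 1L,
                            compartments = NULL,
                            compartment_fractions = c(TE_like = 0.2,
                                                      gene_body_CG = 0.2,
                                                      unmethylated = 0.6),
                            block_bp = 2000L) {
  chrom_lengths <- as.integer(chrom_lengths)
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (any(chrom_lengths < 1e4))
    stop("chromosome lengths must be >= 10,000 bp")
  classes <- c("TE_like", "gene_body_CG", "unmethylated")

  set.seed(seed)
  sequences <- vapply(chrom_lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))

  if (is.null(compartments)) {
    fr <- compartment_fractions[classes]
    fr[is.na(fr)] <- 0
    names(fr) <- classes
    if (sum(fr) > 1 + 1e-8) stop("compartment fractions must sum to <= 1")
    fr["unmethylated"] <- fr["unmethylated"] + (1 - sum(fr))
    compartments <- rbindlist(lapply(names(chrom_lengths), function(cn) {
      L <- chrom_lengths[[cn]]
      starts <- seq(0L, L - 1L, by = block_bp)
      data.table(chrom = cn, start = starts,
                 end = pmin(starts + block_bp, L),
                 class = sample(classes, length(starts), replace = TRUE,
                                prob = fr))
    }))
  } else {
    compartments <- as.data.table(compartments)[, .(chrom, start, end, class)]
    compartments[, `:=`(start = as.integer(start), end = as.integer(end))]
    if (!all(compartments$class %in% classes))
      stop("unknown compartment class: ",
           paste(setdiff(compartments$class, classes), collapse = ", "))
    setkey(compartments, chrom, start)
    bad <- compartments[, any(start < 0 | end > chrom_lengths[chrom] |
                              start >= end), by = chrom]$V1
    if (any(bad)) stop("compartments outside chromosome bounds")
    ovl <- compartments[, any(start[-1L] < end[-.N]), by = chrom]$V1
    if (any(ovl)) stop("overlapping compartments are not allowed")
  }
  setkey(compartments, chrom, start)

  sites <- rbindlist(lapply(names(sequences), function(cn)
    cytosine_sites(sequences[[cn]], chrom = cn)))
  # assign each cytosine the class of the compartment covering it;
  # unannotated sequence defaults to "unmethylated"
  sites[, class := "unmethylated"]
  for (cn in unique(sites$chrom)) {
    cmp <- compartments[chrom == cn]
    if (!nrow(cmp)) next
    i <- findInterval(sites[chrom == cn, pos], cmp$start)
    cls <- rep("unmethylated", length(i))
    hit <- i >= 1L
    hit[hit] <- sites[chrom == cn, pos][hit] < cmp$end[i[hit]]
    cls[hit] <- cmp$class[i[hit]]
    sites[chrom == cn, class := cls]
  }
  setkey(sites, chrom, pos, strand)

  structure(list(chrom_names = names(chrom_lengths),
                 chrom_lengths = chrom_lengths,
                 sequences = sequences,
                 compartments = compartments[],
                 sites = sites[]),
            class = "ReferenceModel")
}

#' @export
print.ReferenceModel <- function(x, ...) {
  cat("ReferenceModel:", length(x$chrom_names), "chromosome(s),",
      format(sum(as.numeric(x$chrom_lengths)), big.mark = ","), "bp,",
      nrow(x$sites), "context-resolved cytosines\n")
  print(context_counts(x))
  invisible(x)
}

#' Cytosine context counts per compartment class
#'
#' @param ref A `ReferenceModel`.
#' @return data.table of counts by compartment class and context.
#' @export
context_counts <- function(ref) {
  stopifnot(inherits(ref, "ReferenceModel"))
  dcast(ref$sites[, .N, by = .(class, context)],
        class ~ context, value.var = "N", fill = 0L)
}

#' Write the reference sequences as FASTA
#'
#' @param ref A `ReferenceModel`.
#' @param path Output FASTA path.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "ReferenceModel"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$sequences), path)
  invisible(path)
}

#' Compartment annotation as BED-style intervals
#'
#' @param ref A `ReferenceModel`.
#' @param class Optional compartment class to restrict to.
#' @return data.table with `chrom`, `start`, `end`, `name`.
#' @export
compartment_intervals <- function(ref, class = NULL) {
  stopifnot(inherits(ref, "ReferenceModel"))
  cmp <- copy(ref$compartments)
  if (!is.null(class)) {
    keep <- cmp$class %in% class
    cmp <- cmp[keep]
  }
  setnames(cmp, "class", "name")
  cmp[]
}
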