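#' Enumerate cytosine sites and their sequence contexts
#'
#' Scans a nucleotide sequence on both strands and returns every cytosine
#' (a `C` on the plus strand, a `G` on the minus strand) together with its
#' trinucleotide context class: `CG`, `CHG` or `CHH`, where H is A, T or C.
#' The context is read 5'->3' on the cytosine's own strand. Symmetric CG
#' sites are reported as two separate records, one per strand, matching
#' per-cytosine call files produced by bisulfite mapping tools.
#'
#' Cytosines within two bases of a sequence end whose context cannot be
#' resolved (the needed downstream bases are missing) are dropped.
#'
#' @param sequence Single character string of A/C/G/T (case-insensitive).
#' @param chrom Chromosome name to attach to the records.
#' @return A `data.table` with columns `chrom`, `pos` (0-based), `strand`
#'   (`"+"`/`"-"`) and `context`, sorted by position.
#' @examples
#' cytosine_sites("ACGT")  # one CG pair
#' @export
cytosine_sites <- function(sequence, chrom = "chr1") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  L <- length(ch)
  at <- function(i) {
    out <- rep(NA_character_, length(i))
    ok <- i >= 1L & i <= L
    out[ok] <- ch[i[ok]]
    out
  }
  ip <- which(ch == "C")
  im <- which(ch == "G")
  dt <- data.table(
    chrom = chrom,
    pos = c(ip, im) - 1L,
    strand = rep(c("+", "-"), c(length(ip), length(im))),
    context = c(classify_context(at(ip + 1L), at(ip + 2L), "G"),
                classify_context(at(im - 1L), at(im - 2L), "C")))
  dt <- dt[!is.na(context)]
  setkey(dt, chrom, pos, strand)
  dt[]
}

# b1/b2: first and second base downstream of the cytosine on its own strand
# (already complement-free: for the minus strand we compare against "C" on
# the plus-strand sequence, which is "G" on the minus strand).
classify_context <- function(b1, b2, partner) {
  ifelse(!is.na(b1) & b1 == partner, "CG",
    ifelse(!is.na(b2) & b2 == partner, "CHG",
      ifelse(!is.na(b2), "CHH", NA_character_)))
}
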