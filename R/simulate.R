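#' Default per-compartment methylation baselines
#'
#' True methylation probabilities per compartment class and context,
#' chosen to match typical Arabidopsis methylome organisation: heavy
#' methylation of transposon-like sequence in all three contexts,
#' CG-exclusive gene-body methylation, and an unmethylated background.
#'
#' @return Named list of named numeric vectors (`CG`, `CHG`, `CHH`).
#' @export
default_baselines <- function() {
  list(TE_like      = c(CG = 0.85, CHG = 0.65, CHH = 0.10),
       gene_body_CG = c(CG = 0.40, CHG = 0.00, CHH = 0.00),
       unmethylated = c(CG = 0.00, CHG = 0.00, CHH = 0.00))
}

#' Describe one sequencing sample to be simulated
#'
#' @param sample_id Unique sample identifier.
#' @param genotype `"control"` or `"mutant"`.
#' @param replicate Replicate tag, e.g. `"r1"`.
#' @param mean_coverage Mean reads per cytosine (Poisson), default 30.
#' @param conversion Bisulfite conversion rate in `[0, 1]`; unconverted
#'   unmethylated cytosines read as methylated, so the observed
#'   methylation probability is `p + (1 - p) * (1 - conversion)`.
#' @param baselines Compartment baselines, see [default_baselines()].
#' @param seed Integer seed for this sample's draws.
#' @return A `SampleProfile` object.
#' @export
sample_profile <- function(sample_id,
                           genotype = c("control", "mutant"),
                           replicate = "r1",
                           mean_coverage = 30,
                           conversion = 0.995,
                           baselines = default_baselines(),
                           seed = 1L) {
  genotype <- match.arg(genotype)
  stopifnot(mean_coverage > 0, conversion >= 0, conversion <= 1)
  for (b in baselines)
    stopifnot(all(b >= 0), all(b <= 1), all(CONTEXTS %in% names(b)))
  structure(list(sample_id = sample_id, genotype = genotype,
                 replicate = replicate, mean_coverage = mean_coverage,
                 conversion = conversion, baselines = baselines,
                 seed = as.integer(seed)),
            class = "SampleProfile")
}

#' Plant differential and hypervariable methylation regions
#'
#' Places non-overlapping regions on a reference in which the true
#' methylation probability of one context is shifted by `delta` for a
#' designated set of samples. Regions affecting every mutant sample are
#' recorded as shared planted DMRs; regions affecting a subset (e.g. a
#' single replicate) are recorded as hypervariable, emulating natural
#' methylation variation between sibling individuals.
#'
#' Placement is restricted to bin-grid-aligned windows lying entirely
#' within a compartment of the requested class and containing at least
#' `min_sites` cytosines of the requested context, so that planted
#' regions are eligible for bin-based DMR calling.
#'
#' @param ref A [build_reference()] `ReferenceModel`.
#' @param requests `data.frame` with one row per batch of regions:
#'   columns `n` (how many), `context`, `direction` (`"hyper"`/`"hypo"`),
#'   `delta` (absolute shift in (0, 1]), and optionally `width`
#'   (default 100), `compartment` (default `"unmethylated"` for hyper,
#'   `"TE_like"` for hypo) and `samples` (`NA` = all `mutant_ids`,
#'   otherwise `";"`-separated sample ids).
#' @param mutant_ids Character vector of all mutant sample ids.
#' @param seed Integer seed for placement.
#' @param min_sites Minimum context cytosines per planted window.
#' @param align Grid alignment of placed windows (bp), default 100.
#' @return A `SyntheticTruth` object whose `planted` table records
#'   `chrom`, `start`, `end`, `context`, `direction`, `delta` (signed),
#'   `samples` and `type` (`"shared"`/`"hypervariable"`).
#' @export
plant_dmrs <- function(ref, requests, mutant_ids, seed = 1L,
                       min_sites = 4L, align = 100L) {
  stopifnot(inherits(ref, "ReferenceModel"), nrow(requests) >= 1)
  requests <- as.data.table(requests)
  if (!"width" %in% names(requests)) requests[, width := align]
  if (!"compartment" %in% names(requests))
    requests[, compartment := ifelse(direction == "hyper",
                                     "unmethylated", "TE_like")]
  if (!"samples" %in% names(requests)) requests[, samples := NA_character_]
  stopifnot(all(requests$context %in% CONTEXTS),
            all(requests$direction %in% c("hyper", "hypo")),
            all(requests$delta > 0), all(requests$delta <= 1),
            all(requests$width %% align == 0))

  set.seed(seed)
  # candidate windows: grid-aligned, entirely inside one compartment,
  # with enough context cytosines
  win_sites <- ref$sites[, .N, by = .(chrom, win = (pos %/% align) * align,
                                      context, class)]
  used <- data.table(chrom = character(), start = integer(),
                     end = integer())
  planted <- vector("list", nrow(requests))
  for (r in seq_len(nrow(requests))) {
    rq <- requests[r]
    nw <- rq$width %/% align
    cand <- win_sites[context == rq$context & class == rq$compartment &
                        N >= min_sites]
    if (nw > 1L) {
      # every sub-window of the wider region must qualify
      setkey(cand, chrom, win)
      ok <- cand[, {
        w <- win
        keep <- vapply(w, function(s)
          all((s + align * (seq_len(nw) - 1L)) %in% w), logical(1))
        .(win = w[keep])
      }, by = chrom]
      cand <- ok
    }
    if (nrow(used)) {
      cand <- cand[!used, on = .(chrom, win = start)]
    }
    cand <- unique(cand[, .(chrom, win)])
    if (nrow(cand) < rq$n)
      stop(sprintf(paste0("request %d: only %d candidate windows for %d ",
                          "requested %s regions in %s compartments"),
                   r, nrow(cand), rq$n, rq$context, rq$compartment))
    pick <- cand[sample(.N, rq$n)]
    smp <- if (is.na(rq$samples)) paste(mutant_ids, collapse = ";")
           else rq$samples
    affected <- strsplit(smp, ";", fixed = TRUE)[[1]]
    type <- if (setequal(affected, mutant_ids)) "shared" else "hypervariable"
    planted[[r]] <- data.table(
      chrom = pick$chrom, start = pick$win, end = pick$win + rq$width,
      context = rq$context, direction = rq$direction,
      delta = ifelse(rq$direction == "hyper", rq$delta, -rq$delta),
      samples = smp, type = type)
    # block all grid windows covered by the new regions
    blk <- planted[[r]][, .(start = start + align * (seq_len(nw) - 1L)),
                        by = .(chrom, s0 = start)][, .(chrom, start)]
    blk[, end := start + align]
    used <- rbind(used, blk)
  }
  planted <- rbindlist(planted)
  setkey(planted, chrom, start)
  structure(list(planted = planted[], min_sites = min_sites, align = align),
            class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth:", nrow(x$planted), "planted regions (",
      sum(x$planted$type == "shared"), "shared,",
      sum(x$planted$type == "hypervariable"), "hypervariable )\n")
  invisible(x)
}

#' Write planted truth regions as BED
#'
#' @param truth A `SyntheticTruth`.
#' @param path Output BED path.
#' @param type Optional filter, `"shared"` or `"hypervariable"`.
#' @export
write_truth_bed <- function(truth, path, type = NULL) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  p <- truth$planted
  if (!is.null(type)) {
    keep <- p$type %in% type
    p <- p[keep]
  }
  out <- p[, .(chrom, start, end,
               name = paste(context, direction, type, sep = ":"))]
  write_bed(out, path)
}

#' Simulate one sample's per-cytosine methylation calls
#'
#' For every cytosine of the reference, the true methylation probability
#' is taken from the compartment baseline for its context, shifted by any
#' planted region covering it that affects this sample. Coverage is drawn
#' as Poisson(`mean_coverage`) per site; the methylated read count is
#' Binomial with observed probability `p + (1 - p) * (1 - conversion)`,
#' so incomplete conversion inflates apparent methylation.
#'
#' @param ref A `ReferenceModel`.
#' @param profile A [sample_profile()].
#' @param truth Optional [plant_dmrs()] `SyntheticTruth`.
#' @return A [methylome_sample()] with one call per cytosine.
#' @export
simulate_sample <- function(ref, profile, truth = NULL) {
  stopifnot(inherits(ref, "ReferenceModel"),
            inherits(profile, "SampleProfile"))
  set.seed(profile$seed)
  s <- ref$sites
  M <- do.call(rbind, profile$baselines)[, CONTEXTS]
  p <- M[cbind(match(s$class, rownames(M)), match(s$context, CONTEXTS))]
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "SyntheticTruth"))
    for (r in seq_len(nrow(truth$planted))) {
      tr <- truth$planted[r]
      if (!profile$sample_id %in% strsplit(tr$samples, ";")[[1]]) next
      idx <- which(s$chrom == tr$chrom & s$pos >= tr$start &
                     s$pos < tr$end & s$context == tr$context)
      p[idx] <- clip01(p[idx] + tr$delta)
    }
  }
  p_obs <- p + (1 - p) * (1 - profile$conversion)
  n <- rpois(length(p_obs), profile$mean_coverage)
  m <- rbinom(length(p_obs), n, p_obs)
  calls <- s[, .(chrom, pos, strand, context)]
  calls[, `:=`(m = m, n = n)]
  new_methylome_sample(calls, profile$sample_id, profile$genotype,
                       profile$replicate)
}

#' Simulate a roster of samples
#'
#' @param ref A `ReferenceModel`.
#' @param profiles List of [sample_profile()]s.
#' @param truth Optional `SyntheticTruth` shared by all samples.
#' @return Named list of `MethylomeSample`s (names = sample ids).
#' @export
simulate_experiment <- function(ref, profiles, truth = NULL) {
  out <- lapply(profiles, simulate_sample, ref = ref, truth = truth)
  names(out) <- vapply(profiles, `[[`, "", "sample_id")
  out
}
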