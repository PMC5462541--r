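#' Default six-comparison sample roster
#'
#' Mirrors a common mutant-screen design: three biological replicates of
#' one mutant allele, each with its own paired control, plus three
#' further mutant alleles with their respective controls -- six pairwise
#' mutant-vs-control comparisons in total.
#'
#' @return data.frame with `comparison`, `mutant`, `control`, `replicate`.
#' @export
default_roster <- function() {
  data.frame(
    comparison = c("mutA_r1", "mutA_r2", "mutA_r3",
                   "mutB", "mutC", "mutD"),
    mutant = c("mutA_r1", "mutA_r2", "mutA_r3",
               "mutB_r1", "mutC_r1", "mutD_r1"),
    control = c("ctlA_r1", "ctlA_r2", "ctlA_r3",
                "ctlB_r1", "ctlC_r1", "ctlD_r1"),
    replicate = c("r1", "r2", "r3", "r1", "r1", "r1"),
    stringsAsFactors = FALSE)
}

#' Build a pipeline run configuration
#'
#' One structured object carrying every tunable parameter of an
#' end-to-end run: the synthetic genome, the planted effects, the sample
#' roster and the analysis thresholds. Defaults follow the standard
#' bin-based WGBS DMR workflow: 100-bp bins, delta 0.4/0.2/0.1
#' (CG/CHG/CHH), FDR 0.01, >= 4 cytosines and >= 4 reads in both
#' samples, 300-bp merging, 1-bp annotation overlap.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Global seed; every random draw in the run derives from it.
#' @param chrom_lengths Synthetic genome (named lengths).
#' @param compartment_fractions Compartment mix for the reference.
#' @param mean_coverage,conversion Sequencing model per sample.
#' @param n_shared_dmrs Shared planted hyper-DMRs per context in
#'   `shared_contexts` (affect every mutant).
#' @param shared_delta Methylation shift of shared planted DMRs.
#' @param shared_contexts Context(s) of shared planted DMRs.
#' @param n_private_per_sample Hypervariable regions planted per mutant
#'   sample (replicate-private natural variation).
#' @param private_delta_range Range of per-replicate hypervariable delta
#'   draws.
#' @param thresholds [dmr_thresholds()].
#' @param merge_distance Same-context merge gap (bp).
#' @param roster Comparison roster, see [default_roster()].
#' @return A `RunConfig` list.
#' @export
run_config <- function(out_dir = file.path(tempdir(), "methbin_run"),
                       seed = 1L,
                       chrom_lengths = c(chr1 = 1e6),
                       compartment_fractions = c(TE_like = 0.2,
                                                 gene_body_CG = 0.2,
                                                 unmethylated = 0.6),
                       mean_coverage = 30,
                       conversion = 0.995,
                       n_shared_dmrs = 10L,
                       shared_delta = 0.5,
                       shared_contexts = "CG",
                       n_private_per_sample = 8L,
                       private_delta_range = c(0.45, 0.7),
                       thresholds = dmr_thresholds(),
                       merge_distance = 300L,
                       roster = default_roster()) {
  stopifnot(inherits(thresholds, "dmr_thresholds"),
            !anyDuplicated(roster$mutant), !anyDuplicated(roster$control),
            all(c("comparison", "mutant", "control", "replicate") %in%
                  names(roster)))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 chrom_lengths = chrom_lengths,
                 compartment_fractions = compartment_fractions,
                 mean_coverage = mean_coverage, conversion = conversion,
                 n_shared_dmrs = n_shared_dmrs, shared_delta = shared_delta,
                 shared_contexts = shared_contexts,
                 n_private_per_sample = n_private_per_sample,
                 private_delta_range = private_delta_range,
                 thresholds = thresholds, merge_distance = merge_distance,
                 roster = roster),
            class = "RunConfig")
}

#' Read/write a run configuration as YAML
#'
#' @param config A `RunConfig`.
#' @param path YAML path.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  x$thresholds$delta_min <- as.list(x$thresholds$delta_min)
  x$chrom_lengths <- as.list(x$chrom_lengths)
  x$compartment_fractions <- as.list(x$compartment_fractions)
  x$roster <- as.list(as.data.frame(config$roster))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(out_dir = x$out_dir, seed = x$seed,
             chrom_lengths = unlist(x$chrom_lengths),
             compartment_fractions = unlist(x$compartment_fractions),
             mean_coverage = x$mean_coverage, conversion = x$conversion,
             n_shared_dmrs = x$n_shared_dmrs, shared_delta = x$shared_delta,
             shared_contexts = unlist(x$shared_contexts),
             n_private_per_sample = x$n_private_per_sample,
             private_delta_range = unlist(x$private_delta_range),
             thresholds = dmr_thresholds(
               delta_min = unlist(x$thresholds$delta_min),
               q_max = x$thresholds$q_max,
               min_sites = x$thresholds$min_sites,
               min_coverage = x$thresholds$min_coverage,
               bin_width = x$thresholds$bin_width),
             merge_distance = x$merge_distance,
             roster = as.data.frame(x$roster, stringsAsFactors = FALSE))
}

#' Run the full simulate-call-intersect-relax-merge pipeline
#'
#' Stages: (1) build the seeded reference; (2) plant shared DMRs and
#' per-sample hypervariable regions; (3) simulate every sample in the
#' roster; (4) call DMRs per comparison and context; (5) direct N-way
#' intersection per context/direction with k-way depth counts;
#' (6) converge direct windows to loci; (7) master lists, methylation
#' matrices, sign-concordant "relaxed" selection, body-methylated-gene
#' filtering and mean-difference ranking; (8) same-context 300-bp
#' merging and cross-context union into merged hyper-mC regions;
#' (9) quantification of a planted region across samples. Every filter
#' logs counts in and out, so the DMR -> window -> locus funnel is
#' auditable from the manifest.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return A manifest list (also written as `manifest.json` in
#'   `config$out_dir`) with stage outputs, funnel counts and file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  th <- config$thresholds
  roster <- config$roster

  say("[1/9] reference")
  ref <- build_reference(config$chrom_lengths, seed = config$seed,
                         compartment_fractions = config$compartment_fractions)

  say("[2/9] planting truth")
  set.seed(config$seed + 1L)
  reqs <- list()
  for (ctx in config$shared_contexts)
    reqs[[length(reqs) + 1L]] <- data.table(
      n = config$n_shared_dmrs, context = ctx, direction = "hyper",
      delta = config$shared_delta, samples = NA_character_)
  if (config$n_private_per_sample > 0) {
    for (sid in roster$mutant) {
      deltas <- round(runif(config$n_private_per_sample,
                            config$private_delta_range[1],
                            config$private_delta_range[2]), 3)
      ctxs <- sample(CONTEXTS, config$n_private_per_sample, replace = TRUE)
      for (i in seq_len(config$n_private_per_sample))
        reqs[[length(reqs) + 1L]] <- data.table(
          n = 1L, context = ctxs[i], direction = "hyper",
          delta = deltas[i], samples = sid)
    }
  }
  truth <- plant_dmrs(ref, rbindlist(reqs, fill = TRUE),
                      mutant_ids = roster$mutant,
                      seed = config$seed + 2L,
                      min_sites = th$min_sites, align = th$bin_width)
  write_truth_bed(truth, file.path(config$out_dir, "truth.bed"))

  say("[3/9] simulating ", 2 * nrow(roster), " samples")
  ids <- c(roster$mutant, roster$control)
  genos <- rep(c("mutant", "control"), each = nrow(roster))
  reps <- rep(roster$replicate, 2)
  profiles <- Map(function(id, g, r, i)
    sample_profile(id, g, r, mean_coverage = config$mean_coverage,
                   conversion = config$conversion,
                   seed = config$seed + 100L + i),
    ids, genos, reps, seq_along(ids))
  samples <- simulate_experiment(ref, profiles, truth)

  say("[4/9] calling DMRs per comparison")
  calls <- list()
  per_comparison <- list()
  for (i in seq_len(nrow(roster))) {
    cmp <- roster$comparison[i]
    cc <- compare_methylomes(samples[[roster$mutant[i]]],
                             samples[[roster$control[i]]],
                             thresholds = th, comparison_id = cmp)
    calls[[cmp]] <- cc
    write_dmr_tsv(cc, file.path(config$out_dir,
                                paste0("dmr_calls_", cmp, ".tsv")))
    d <- dmr_intervals(cc)
    write_dmr_bed(d, file.path(config$out_dir, paste0("dmrs_", cmp, ".bed")))
    per_comparison[[cmp]] <- list(
      eligible_bins = nrow(cc), dmrs = nrow(d),
      by_context = as.list(table(d$context)))
    say("  ", cmp, ": ", nrow(d), " DMRs / ", nrow(cc), " eligible bins")
  }

  say("[5/9] direct N-way intersection")
  direct <- list()
  depth <- list()
  for (ctx in CONTEXTS) for (dir in c("hyper", "hypo")) {
    sets <- lapply(calls, dmr_intervals, context = ctx, direction = dir)
    key <- paste(ctx, dir, sep = "_")
    direct[[key]] <- intersect_direct(sets, window = th$bin_width)
    depth[[key]] <- overlap_depth(sets, window = th$bin_width)
    if (nrow(direct[[key]])) {
      direct[[key]][, `:=`(context = ctx, direction = dir)]
      write_bed(direct[[key]][, .(chrom, start, end,
                                  name = paste(ctx, dir, sep = ":"))],
                file.path(config$out_dir,
                          paste0("direct_", key, ".bed")))
    }
  }
  direct_all <- rbindlist(direct[vapply(direct, nrow, 0L) > 0],
                          use.names = TRUE)
  say("  direct windows: ", if (nrow(direct_all)) nrow(direct_all) else 0L)

  say("[6/9] converging to loci")
  loci <- converge_to_loci(direct_all, merge_distance = config$merge_distance)
  write_bed(loci[, .(chrom, start, end,
                     name = paste(direction, contexts, sep = ":"))],
            file.path(config$out_dir, "loci.bed"))
  say("  loci: ", nrow(loci))

  say("[7/9] relaxed conserved DMRs")
  body_meth <- compartment_intervals(ref, class = "gene_body_CG")
  relaxed <- list()
  ranked <- list()
  for (ctx in CONTEXTS) {
    master <- build_master_list(lapply(calls, dmr_intervals, context = ctx,
                                       direction = "hyper"))
    if (!nrow(master)) {
      relaxed[[ctx]] <- master
      next
    }
    mm <- methylation_matrix(master, samples, context = ctx,
                             min_site_coverage = th$min_coverage)
    write_matrix_tsv(mm, file.path(config$out_dir,
                                   paste0("matrix_", ctx, "_hyper.tsv")))
    sel <- suppressWarnings(
      select_concordant(mm, mutant_ids = roster$mutant,
                        control_ids = roster$control,
                        direction = "hyper"))
    sel[, context := ctx]
    n_before <- nrow(sel)
    sel <- filter_body_methylated(sel, body_meth, contexts = "CG")
    say("  ", ctx, ": master ", nrow(master), " -> concordant ", n_before,
        " -> after body-methylation filter ", nrow(sel))
    relaxed[[ctx]] <- sel
    ranked[[ctx]] <- rank_by_mean_difference(mm, roster$mutant,
                                             roster$control)
    if (nrow(sel))
      write_bed(sel[, .(chrom, start, end, name = paste0(ctx, ":hyper"))],
                file.path(config$out_dir, paste0("relaxed_", ctx, ".bed")))
  }

  say("[8/9] merged hyper-mC regions")
  merged_ctx <- lapply(relaxed[vapply(relaxed, nrow, 0L) > 0], merge_within,
                       distance = config$merge_distance)
  hyper_mc <- if (length(merged_ctx)) union_across_contexts(merged_ctx)
              else data.table(chrom = character(), start = integer(),
                              end = integer())
  write_bed(hyper_mc, file.path(config$out_dir, "hyper_mC_merged.bed"))
  say("  merged regions: ", nrow(hyper_mc))

  say("[9/9] targeted quantification")
  quant <- NULL
  shared <- truth$planted[truth$planted$type == "shared"]
  if (nrow(shared)) {
    tgt <- shared[1L]
    quant <- rbindlist(lapply(names(samples), function(id)
      cbind(sample = id,
            quantify_region(samples[[id]], tgt$start, tgt$end,
                            chrom = tgt$chrom, one_based = FALSE,
                            min_coverage = th$min_coverage))))
    write.table(quant, file.path(config$out_dir, "quant_planted_region.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    genome_bp = sum(as.numeric(config$chrom_lengths)),
    n_samples = length(samples),
    truth_counts = list(
      shared = sum(truth$planted$type == "shared"),
      hypervariable = sum(truth$planted$type == "hypervariable")),
    per_comparison = per_comparison,
    funnel = list(
      per_comparison_dmrs = vapply(per_comparison, `[[`, 0L, "dmrs"),
      direct_windows = nrow(direct_all),
      loci = nrow(loci),
      relaxed = vapply(relaxed, nrow, 0L),
      merged_hyper_mc = nrow(hyper_mc)),
    depth_counts = lapply(depth, function(d)
      setNames(as.list(d$n_windows), paste0("k", d$k))),
    files = list.files(config$out_dir))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest,
              list(reference = ref, truth = truth, samples = samples,
                   calls = calls, direct = direct_all, loci = loci,
                   relaxed = relaxed, ranked = ranked,
                   hyper_mc = hyper_mc, quant = quant)))
}
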