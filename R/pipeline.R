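#' Default pipeline configuration
#'
#' All thresholds of the analysis pipeline with their standard defaults:
#' individual missingness 0.10, SNP missingness 0.05, rare-MAF 0.01, LD
#' pruning r^2 0.2 in 50 kb windows stepping 10 kb, relatedness PI_HAT
#' 0.375, focal-ancestry minimum 0.99, IBD minimum 2 cM at support 3 with
#' 0.6 cM gap merging, 5 cM average-sharing pair inclusion, period cuts at
#' 8.4 and 28 cM, 28 years per generation, the PLINK-style ROH parameter
#' block, F4 significance Z > 4, graph-fit acceptance worst |Z| < 3, and a
#' minimum of 5 samples for founder-event fits.
#'
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    stages = c("qc", "relate", "ancestry", "ordinate", "fstats", "ibd",
               "roh", "network", "founder", "ne", "amova"),
    qc = list(snp_missing_max = 0.05, ind_missing_max = 0.10,
              maf_rare_threshold = 0.01, hwe_p_min = 1e-8,
              ld_r2_max = 0.2, ld_window_bp = 50000, ld_step_bp = 10000),
    relate = list(pi_hat_threshold = 0.375),
    ancestry = list(focal = NULL, min_focal = 0.99, reference_pops = NULL),
    fstats = list(outgroup = NULL, block_size_cm = 5, z_threshold = 4,
                  good_fit_z = 3),
    ibd = list(min_cm = 2, min_support = 3, error_tolerance = 0.002,
               max_gap_cm = 0.6, max_discordant_hom = 1),
    roh = list(window_snps = 50, max_het_per_window = 1,
               max_miss_per_window = 5, min_overlap_frac = 0.05,
               min_snp_density_kb = 50, max_gap_kb = 100,
               min_length_kb = 500),
    network = list(min_avg_cm = 5, min_len_cm = 2,
                   periods = c("precolumbian", "colonial", "recent")),
    founder = list(min_samples = 5, max_cm = 30, bin_cm = 0.1,
                   bootstrap_n = 100, n_outgroup = 15,
                   years_per_generation = 28),
    ne = list(horizon = 100, n_epochs = 10, bootstrap_n = 50),
    amova = list(n_perm = 999)
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Values in the file override the defaults; unknown keys error.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  merge_in <- function(base, user, prefix = "") {
    for (k in names(user)) {
      if (!(k %in% names(base)) && prefix != "")
        stop("unknown configuration key: ", prefix, k)
      if (is.list(user[[k]]) && is.list(base[[k]]))
        base[[k]] <- merge_in(base[[k]], user[[k]], paste0(prefix, k, "."))
      else base[[k]] <- user[[k]]
    }
    base
  }
  merge_in(base, user)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order on a genotype panel:
#' QC and LD pruning, relatedness filtering, supervised-ancestry filtering,
#' ordination, outgroup-f3 distances, IBD detection with gap merging,
#' ROH and F_ROH, sharing networks per period, founder-event fitting, N_e
#' history, and AMOVA. Stage results are returned (and written as
#' tab-separated tables when `out_dir` is given) together with a run
#' manifest recording derived seeds and per-stage row counts; reruns with
#' the same configuration are identical apart from timestamps.
#'
#' @param panel A `genotype_panel` (phased input enables the IBD stages).
#' @param config Configuration list from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Optional output directory for stage artifacts.
#' @return List with `results` (per stage) and `manifest`.
#' @export
run_pipeline <- function(panel, config = default_pipeline_config(),
                         out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- list(); manifest <- list()
  stage_on <- function(s) s %in% config$stages
  stage_seed <- function(s) config$seed + match(s, config$stages)
  note <- function(stage, rows, extra = NULL) {
    manifest[[stage]] <<- c(list(stage = stage, rows = rows,
                                 seed = stage_seed(stage)), extra)
  }
  emit <- function(stage, df) {
    if (!is.null(out_dir) && is.data.frame(df))
      utils::write.table(df, file.path(out_dir, paste0(stage, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  skipped <- function(stage, why) {
    manifest[[stage]] <<- list(stage = stage, skipped = TRUE, reason = why)
    message("stage '", stage, "' skipped: ", why)
  }

  cur <- panel
  if (stage_on("qc")) {
    q <- config$qc
    out <- qc_filter(cur, q$snp_missing_max, q$ind_missing_max,
                     q$maf_rare_threshold, q$hwe_p_min)
    pruned <- ld_prune(out$panel, q$ld_r2_max, q$ld_window_bp, q$ld_step_bp)
    res$qc <- out$report
    res$pruned_panel <- pruned
    cur <- out$panel
    note("qc", n_snps(cur))
  } else pruned <- cur

  unrelated <- cur$sample_ids
  if (stage_on("relate")) {
    kin <- suppressWarnings(pairwise_pi_hat(pruned, ld_pruned = TRUE))
    unrelated <- max_unrelated_set(kin, config$relate$pi_hat_threshold)
    res$kinship <- kin
    res$unrelated <- unrelated
    emit("kinship", as.data.frame(kin))
    note("relate", nrow(kin), list(n_unrelated = length(unrelated)))
  }

  unadmixed <- cur$sample_ids
  if (stage_on("ancestry") && !is.null(config$ancestry$focal)) {
    ref_pops <- config$ancestry$reference_pops
    rf <- allele_frequencies(pruned)
    rf$freq <- rf$freq[ref_pops, , drop = FALSE]
    rf$count <- rf$count[ref_pops, , drop = FALSE]
    keep_snp <- colSums(is.na(rf$freq)) == 0
    rp <- subset_panel(pruned, snps = which(keep_snp))
    rf$freq <- rf$freq[, keep_snp, drop = FALSE]
    anc <- supervised_ancestry(rp, rf$freq)
    admx <- flag_admixed(anc, config$ancestry$focal,
                         1 - config$ancestry$min_focal)
    unadmixed <- names(admx)[!admx]
    res$ancestry <- anc
    emit("ancestry", data.frame(id = rownames(anc$q), anc$q,
                                admixed = admx))
    note("ancestry", nrow(anc$q), list(n_unadmixed = length(unadmixed)))
  }

  analysis_ids <- intersect(unrelated, unadmixed)
  apanel <- subset_panel(cur, samples = analysis_ids)
  res$analysis_panel <- apanel

  if (stage_on("ordinate")) {
    res$pca <- pca_panel(subset_panel(pruned,
                                      samples = intersect(analysis_ids,
                                                          pruned$sample_ids)))
    emit("pca", data.frame(id = rownames(res$pca$coords), res$pca$coords))
    note("ordinate", nrow(res$pca$coords))
  }

  if (stage_on("fstats") && !is.null(config$fstats$outgroup)) {
    fr <- allele_frequencies(apanel)
    dm <- outgroup_f3_matrix(fr, config$fstats$outgroup, units = "one_minus",
                             block_size_cm = config$fstats$block_size_cm)
    res$f3_distances <- dm
    res$f3_mds <- tryCatch(classical_mds(dm, 2), error = function(e) NULL)
    emit("f3_distances", as.data.frame(dm$matrix))
    note("fstats", nrow(dm$matrix))
  }

  segs <- NULL
  if (stage_on("ibd")) {
    if (!is_phased(apanel)) skipped("ibd", "panel is not phased")
    else {
      cfg <- config$ibd
      segs <- detect_ibd(apanel, cfg$min_cm, cfg$min_support,
                         cfg$error_tolerance, hbd = "include")
      segs <- merge_gaps(segs, apanel, cfg$max_gap_cm, cfg$max_discordant_hom)
      res$ibd <- segs
      emit("ibd_segments", as.data.frame(segs))
      note("ibd", nrow(segs))
    }
  }

  if (stage_on("roh")) {
    r <- config$roh
    rohs <- call_roh(apanel, r$window_snps, r$max_het_per_window,
                     r$max_miss_per_window, r$min_overlap_frac,
                     r$min_snp_density_kb, r$max_gap_kb, r$min_length_kb)
    ft <- froh(rohs, panel_covered_bp(apanel), apanel$sample_table)
    res$roh <- rohs; res$froh <- ft
    emit("roh", as.data.frame(rohs)); emit("froh", as.data.frame(ft))
    note("roh", nrow(rohs))
  }

  if (stage_on("network")) {
    if (is.null(segs)) skipped("network", "requires the ibd stage")
    else {
      grouping <- stats::setNames(apanel$sample_table$population,
                                  apanel$sample_ids)
      res$networks <- lapply(stats::setNames(config$network$periods,
                                             config$network$periods),
        function(p) sharing_network(segs, grouping, p,
                                    config$network$min_avg_cm,
                                    config$network$min_len_cm))
      note("network", length(res$networks))
    }
  }

  if (stage_on("founder")) {
    f <- config$founder
    pops <- table(apanel$sample_table$population)
    eligible <- names(pops)[pops >= f$min_samples]
    set.seed(stage_seed("founder"))
    res$founder <- list()
    for (p0 in eligible) {
      outg <- sample(setdiff(apanel$sample_ids,
                             apanel$sample_ids[apanel$sample_table$population == p0]),
                     min(f$n_outgroup,
                         sum(apanel$sample_table$population != p0)))
      curve <- allele_sharing_decay(apanel, p0, outg, f$max_cm, f$bin_cm)
      res$founder[[p0]] <- fit_founder_event(curve, f$bootstrap_n,
                                             seed = stage_seed("founder"),
                                             years_per_generation =
                                               f$years_per_generation)
    }
    note("founder", length(res$founder))
  }

  if (stage_on("ne")) {
    if (is.null(segs) || nrow(segs) == 0) skipped("ne", "no IBD segments")
    else {
      ib <- segs[segs$sample1 != segs$sample2, , drop = FALSE]
      npair <- choose(2 * n_samples(apanel), 2) - n_samples(apanel)
      G <- sum(tapply(apanel$snp_table$cm, apanel$snp_table$chrom, max)) / 100
      res$ne <- fit_ne_history(ib, n_pairs = npair, genome_morgans = G,
                               horizon_generations = config$ne$horizon,
                               n_epochs = config$ne$n_epochs,
                               bootstrap_n = config$ne$bootstrap_n,
                               seed = stage_seed("ne"))
      emit("ne_trajectory",
           data.frame(generation = res$ne$generations, ne = res$ne$ne,
                      ci_low = res$ne$ci_low, ci_high = res$ne$ci_high))
      note("ne", length(res$ne$ne))
    }
  }

  if (stage_on("amova")) {
    res$amova <- amova(apanel, n_perm = config$amova$n_perm,
                       seed = stage_seed("amova"))
    emit("amova", res$amova$table)
    note("amova", nrow(res$amova$table))
  }

  manifest_df <- data.frame(
    stage = vapply(manifest, function(m) m$stage, character(1)),
    rows = vapply(manifest, function(m)
      if (is.null(m$rows)) NA_integer_ else as.integer(m$rows), integer(1)),
    seed = vapply(manifest, function(m)
      if (is.null(m$seed)) NA_integer_ else as.integer(m$seed), integer(1)),
    skipped = vapply(manifest, function(m) isTRUE(m$skipped), logical(1)),
    row.names = NULL)
  if (!is.null(out_dir))
    jsonlite::write_json(list(config = config, manifest = manifest_df,
                              timestamp = format(Sys.time())),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  list(results = res, manifest = manifest_df)
}
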