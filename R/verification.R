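# Simulation studies used to verify the pipeline against planted truth.
# Each study fixes its scenario (sample sizes, event ages, intensities) as
# the package's reference conditions and takes only a seed.

#' Planted-truth detector exactness study
#'
#' Plants IBD segments and ROH of assorted lengths into i.i.d. background
#' haplotypes (no coalescent sharing, so any unplanted call is a false
#' positive), runs [detect_ibd()] and [call_roh()], and scores precision,
#' recall and boundary error in SNPs.
#'
#' @param seed Random seed.
#' @return List with `ibd` and `roh` components, each carrying `precision`,
#'   `recall` and `max_boundary_error_snps`.
#' @export
study_detector_exactness <- function(seed = 1) {
  panel <- local({
    set.seed(seed)
    n <- 12; S <- 3000; n_chrom <- 2; len <- 60
    snp_table <- do.call(rbind, lapply(seq_len(n_chrom), function(c0) {
      cm <- len * (seq_len(S) - 0.5) / S
      data.frame(chrom = as.character(c0), pos = as.integer(round(cm * 1e6)),
                 cm = cm, ref = "A", alt = "G",
                 id = paste0(c0, "_", seq_len(S)), stringsAsFactors = FALSE)
    }))
    p <- stats::runif(nrow(snp_table), 0.2, 0.8)
    H <- matrix(stats::rbinom(2L * n * nrow(snp_table), 1L,
                              rep(p, each = 2L * n)), 2L * n)
    storage.mode(H) <- "integer"
    geno <- H[seq(1, 2 * n, 2), ] + H[seq(2, 2 * n, 2), ]
    st <- data.frame(id = sprintf("S%03d", seq_len(n)), population = "P",
                     major_group = "G", lat = NA_real_, lon = NA_real_,
                     stringsAsFactors = FALSE)
    genotype_panel(geno, snp_table, st, haplotypes = H)
  })
  plants <- list(
    list(kind = "ibd", sample1 = "S001", sample2 = "S002", chrom = "1",
         start_cm = 5, end_cm = 15),
    list(kind = "ibd", sample1 = "S003", sample2 = "S004", chrom = "1",
         start_cm = 30, end_cm = 33),
    list(kind = "ibd", sample1 = "S005", sample2 = "S006", chrom = "2",
         start_cm = 10, end_cm = 12.6),
    list(kind = "ibd", sample1 = "S007", sample2 = "S008", chrom = "2",
         start_cm = 40, end_cm = 55),
    list(kind = "roh", sample = "S009", chrom = "1",
         start_cm = 20, end_cm = 21),
    list(kind = "roh", sample = "S010", chrom = "2",
         start_cm = 30, end_cm = 32))
  pl <- plant_fixtures(panel, plants, seed = seed + 1)
  spacing_cm <- 60 / 3000
  spacing_bp <- spacing_cm * 1e6

  segs <- detect_ibd(pl$panel, hbd = "exclude")
  truth_ibd <- pl$truth$ibd
  match_ibd <- function(sg) {
    hit <- truth_ibd$sample1 == sg$sample1 & truth_ibd$sample2 == sg$sample2 &
      truth_ibd$chrom == sg$chrom &
      pmin(truth_ibd$end_cm, sg$end_cm) > pmax(truth_ibd$start_cm, sg$start_cm)
    if (!any(hit)) return(NA_real_)
    t0 <- truth_ibd[which(hit)[1], ]
    max(abs(sg$start_cm - t0$start_cm), abs(sg$end_cm - t0$end_cm))
  }
  berr <- vapply(seq_len(nrow(segs)),
                 function(r) match_ibd(segs[r, ]), numeric(1))
  ibd_tp <- sum(!is.na(berr))
  ibd <- list(
    precision = if (nrow(segs)) ibd_tp / nrow(segs) else NA_real_,
    recall = ibd_tp / nrow(truth_ibd),
    max_boundary_error_snps = if (ibd_tp) max(berr, na.rm = TRUE) / spacing_cm
                              else NA_real_)

  rohs <- call_roh(pl$panel, min_length_kb = 500)
  truth_roh <- pl$truth$roh
  match_roh <- function(rr) {
    hit <- truth_roh$sample == rr$sample & truth_roh$chrom == rr$chrom &
      pmin(truth_roh$end_bp, rr$end_bp) > pmax(truth_roh$start_bp, rr$start_bp)
    if (!any(hit)) return(NA_real_)
    t0 <- truth_roh[which(hit)[1], ]
    max(abs(rr$start_bp - t0$start_bp), abs(rr$end_bp - t0$end_bp))
  }
  rerr <- vapply(seq_len(nrow(rohs)),
                 function(r) match_roh(rohs[r, ]), numeric(1))
  roh_tp <- sum(!is.na(rerr))
  roh <- list(
    precision = if (nrow(rohs)) roh_tp / nrow(rohs) else NA_real_,
    recall = roh_tp / nrow(truth_roh),
    max_boundary_error_snps = if (roh_tp) max(rerr, na.rm = TRUE) / spacing_bp
                              else NA_real_)
  list(ibd = ibd, roh = roh)
}

#' Null calibration of the f4 statistic
#'
#' Draws unrelated samples from a single panmictic gene pool, splits them
#' into four arbitrary groups, and measures how often |Z| of
#' `f4(A, B; C, D)` stays below 3.
#'
#' @param n_reps Number of replicates (default 100).
#' @param seed Random seed.
#' @return List with `frac_abs_z_lt3` and the vector of `z` values.
#' @export
study_f4_null <- function(n_reps = 100, seed = 1) {
  m <- demographic_model(c(P = 80),
                         data.frame(chrom = as.character(1:2),
                                    length_cm = 100, n_snps = 1500),
                         n_generations = 0, fst = 0)
  zs <- vapply(seq_len(n_reps), function(r) {
    p <- simulate_panel(m, 40, seed = seed * 1000 + r,
                        track_ancestry = FALSE)$panel
    grouping <- stats::setNames(rep(c("A", "B", "C", "D"), each = 10),
                                p$sample_ids)
    ft <- allele_frequencies(p, grouping)
    f_statistic(ft, "f4", c("A", "B", "C", "D"))$z
  }, numeric(1))
  list(frac_abs_z_lt3 = mean(abs(zs) < 3), z = zs)
}

#' Founder-event recovery study
#'
#' Forward-simulates a deme of 800 diploids that passes through a
#' one-generation bottleneck of `bottleneck_size` ten generations before
#' sampling (10 chromosomes of 40 cM; the event is strong so background
#' drift cannot bias the fitted age), fits the founder event from the
#' allele-sharing decay curve (to 20 cM, so slowly-decaying post-event
#' drift is absorbed by the baseline) with a chromosome-block bootstrap,
#' and scores whether each replicate's 95% CI covers the true age.
#'
#' @param n_reps Number of replicates (default 50).
#' @param seed Random seed.
#' @param bottleneck_size Bottleneck diploid size (default 10).
#' @param bootstrap_n Bootstrap resamples per replicate (default 100).
#' @return List with `coverage` (fraction of CIs covering 10 generations),
#'   `fa` (estimates), `fi` (intensities), `ci` (matrix of bounds).
#' @export
study_founder_recovery <- function(n_reps = 50, seed = 1,
                                   bottleneck_size = 10, bootstrap_n = 100) {
  m <- demographic_model(
    c(F = 800, O = 300),
    data.frame(chrom = as.character(1:10), length_cm = 40, n_snps = 400),
    n_generations = 11, fst = 0.05,
    events = list(list(type = "bottleneck", deme = "F", start_gen = 1,
                       duration = 1, size = bottleneck_size)))
  fa <- fi <- numeric(n_reps)
  ci <- matrix(NA_real_, n_reps, 2)
  for (r in seq_len(n_reps)) {
    sim <- simulate_panel(m, c(F = 25, O = 15), seed = seed * 1000 + r,
                          track_ancestry = FALSE)
    p <- sim$panel
    outg <- p$sample_ids[p$sample_table$population == "O"]
    curve <- allele_sharing_decay(p, "F", outg, max_cm = 20, bin_cm = 0.25)
    fe <- fit_founder_event(curve, bootstrap_n = bootstrap_n,
                            seed = seed * 1000 + r)
    fa[r] <- fe$fa_generations; fi[r] <- fe$fi_percent
    if (fe$converged) ci[r, ] <- fe$fa_ci
  }
  covered <- !is.na(ci[, 1]) & ci[, 1] <= 10 & ci[, 2] >= 10
  list(coverage = mean(covered), fa = fa, fi = fi, ci = ci,
       true_age = 10)
}

#' N_e-history recovery study
#'
#' Samples IBD length spectra from the forward model under (i) a constant
#' N_e of 1000 and (ii) a 10-fold crash at generation 20 (500 recent,
#' 5000 older), fits the trajectories, and summarizes recovery.
#'
#' @param seed Random seed.
#' @param n_pairs Haplotype pairs (default 5000).
#' @return List with `constant` (fitted trajectory, `median_ne`,
#'   `within_factor2`) and `crash` (`decline_fold`).
#' @export
study_ne_recovery <- function(seed = 1, n_pairs = 5000) {
  bins <- c(2, 3, 4, 5, 6, 8, 10, 14, 18, 24, 32, 45, 60)
  segs <- sample_ibd_spectrum(rep(1000, 100), 35, bins, n_pairs = n_pairs,
                              seed = seed)
  fit <- fit_ne_history(segs, n_pairs, 35, bootstrap_n = 0, seed = seed)
  ne3 <- c(rep(500, 20), rep(5000, 80))
  segs3 <- sample_ibd_spectrum(ne3, 35, bins, n_pairs = n_pairs,
                               seed = seed + 1)
  fit3 <- fit_ne_history(segs3, n_pairs, 35, bootstrap_n = 0, seed = seed)
  list(constant = list(fit = fit, median_ne = stats::median(fit$ne),
                       within_factor2 = all(fit$ne > 500 & fit$ne < 2000)),
       crash = list(fit = fit3,
                    decline_fold = mean(fit3$ne[30:60]) /
                      mean(fit3$ne[1:12])))
}

#' IBD spectrum closed form versus breakpoint oracle
#'
#' Compares [expected_ibd_spectrum()] against the generative
#' breakpoint-scattering oracle for a constant and a two-epoch trajectory,
#' over bins with at least 20 expected segments. The trajectories keep N
#' small so the compared bins are populated by typical pairs: with large
#' N, the long bins are driven by rare recently-coalescing pairs whose
#' segments cluster (one coalescence time per pair), and that
#' overdispersion - not any failure of the closed form - dominates the
#' comparison. The pair count keeps every bin far above the 20-expected
#' floor, where bare Poisson noise (22%) would swamp a 10% check.
#'
#' @param seed Random seed.
#' @param n_pairs Haplotype pairs per scenario (default 12000).
#' @return List with `max_rel_err` (worst over both scenarios) and the
#'   per-scenario tables.
#' @export
study_spectrum_oracle <- function(seed = 1, n_pairs = 12000) {
  bins <- c(2, 3, 4, 6, 8, 12, 16)
  res <- lapply(list(constant = rep(25, 40),
                     two_epoch = c(rep(30, 15), rep(200, 100))),
                function(ne) {
    seg <- simulate_ibd_breakpoints(ne, 1, n_pairs, seed = seed)
    obs <- tabulate(findInterval(seg$length_cm, bins), nbins = length(bins))
    expe <- expected_ibd_spectrum(ne, 1, bins, n_pairs = n_pairs)
    ok <- expe >= 20
    data.frame(bin = bins, observed = obs, expected = expe, used = ok)
  })
  errs <- vapply(res, function(tb)
    max(abs(tb$observed - tb$expected)[tb$used] / tb$expected[tb$used]),
    numeric(1))
  list(max_rel_err = max(errs), tables = res)
}

#' AMOVA type-I error study
#'
#' Simulates unstructured panels (i.i.d. panmictic draws), assigns random
#' population and group labels (12 populations in 3 groups, 4 individuals
#' each), and measures the rejection rate of each permutation test at
#' alpha = 0.05.
#'
#' @param n_reps Number of null replicates (default 200).
#' @param seed Random seed.
#' @param n_perm Permutations per test (default 59, so alpha = 0.05 sits
#'   on the achievable grid 3/60).
#' @return List with `rejection_rates` per level and the p-value matrix.
#' @export
study_amova_null <- function(n_reps = 200, seed = 1, n_perm = 59) {
  m <- demographic_model(c(P = 48),
                         data.frame(chrom = "1", length_cm = 50,
                                    n_snps = 250),
                         n_generations = 0, fst = 0)
  pops <- paste0("p", 1:12)
  gmap <- stats::setNames(rep(paste0("g", 1:3), each = 4), pops)
  ps <- t(vapply(seq_len(n_reps), function(r) {
    p <- simulate_panel(m, 48, seed = seed * 1000 + r,
                        track_ancestry = FALSE)$panel
    set.seed(seed * 1000 + r + 5e5)
    hier <- data.frame(id = p$sample_ids,
                       population = sample(rep(pops, each = 4)), group = NA,
                       stringsAsFactors = FALSE)
    hier$group <- gmap[hier$population]
    amova(p, hier, n_perm = n_perm, seed = seed * 1000 + r)$p_values
  }, numeric(3)))
  list(rejection_rates = colMeans(ps <= 0.05), p_values = ps)
}

#' Serial-founder F_ROH gradient study
#'
#' Simulates a five-deme eastward colonization chain with successively
#' smaller deme sizes (400 -> 60 -> 30 -> 15 -> 8, each founded from the
#' previous deme, the first through a 12-founder event), averages
#' population-mean F_ROH over `n_chains` replicate chains, and correlates
#' it with longitude.
#'
#' @param seed Random seed.
#' @param n_chains Replicate chains averaged (default 3).
#' @return List with `means` (per deme), `strictly_increasing`,
#'   `spearman_r`, `spearman_p`.
#' @export
study_serial_founder <- function(seed = 1, n_chains = 3) {
  chain_means <- function(s) {
    splits <- list(
      list(type = "split", parent = "d1", child = "d2", generation = 3,
           size = 60, founders = 12),
      list(type = "split", parent = "d2", child = "d3", generation = 6,
           size = 30),
      list(type = "split", parent = "d3", child = "d4", generation = 9,
           size = 15),
      list(type = "split", parent = "d4", child = "d5", generation = 12,
           size = 8))
    m <- demographic_model(c(d1 = 400),
                           data.frame(chrom = c("1", "2"), length_cm = 60,
                                      n_snps = 1500),
                           n_generations = 16, fst = 0, events = splits)
    ns <- stats::setNames(c(12, 12, 12, 12, 8), paste0("d", 1:5))
    sim <- simulate_panel(m, ns, seed = s, track_ancestry = FALSE)
    p <- sim$panel
    rohs <- call_roh(p)
    ft <- froh(rohs, panel_covered_bp(p), p$sample_table)
    attr(ft, "population_means")[paste0("d", 1:5)]
  }
  pm <- rowMeans(vapply(seq_len(n_chains),
                        function(k) chain_means(seed * 1000 + k),
                        numeric(5)))
  lon <- seq(-75, -55, 5)
  ct <- suppressWarnings(stats::cor.test(pm, lon, method = "spearman"))
  list(means = pm, strictly_increasing = all(diff(pm) > 0),
       spearman_r = unname(ct$estimate), spearman_p = ct$p.value)
}
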