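#' Exact test for Hardy-Weinberg proportions
#'
#' Exact conditional test on the heterozygote count given the allele counts
#' (the array-QC standard), returned as a mid-p value by default: the
#' probability of tables at most as likely as the observed one, counting the
#' observed table with weight one half.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major hom, het, minor hom in any
#'   order; the test is symmetric in the two homozygote classes).
#' @param midp Use the mid-p correction (default `TRUE`).
#' @return P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb, midp = TRUE) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_minor <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  if (n_minor == 0) return(if (midp) 0.5 else 1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # P(het = h | allele counts) up to a constant: n! 2^h / (hom1! h! hom2!)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lfactorial(hom_min) - lfactorial(h) - lfactorial(hom_maj)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[match(n_ab, hets)]
  tail_p <- sum(p[p <= p_obs + 1e-12])
  if (midp) tail_p - 0.5 * p_obs else min(1, tail_p)
}

#' Quality-control filter for a genotype panel
#'
#' Applies, in order: removal of multi-allelic sites, chromosome-arm end
#' trimming (when an arm table is given), SNP and individual missingness
#' filters (iterated jointly to a fixed point, so the filter is idempotent),
#' and an exact-test Hardy-Weinberg filter on the pooled samples. Rare
#' alleles (MAF below `maf_rare_threshold`) are counted, not removed.
#'
#' @param panel A `genotype_panel`.
#' @param snp_missing_max Maximum per-SNP missingness fraction (default 0.05).
#' @param ind_missing_max Maximum per-sample missingness fraction (default 0.10).
#' @param maf_rare_threshold MAF below which an allele is counted as rare
#'   (default 0.01).
#' @param hwe_p_min SNPs with HWE mid-p value `<=` this are removed
#'   (default 1e-8; set to 0 to disable).
#' @param arm_trim_bp Distance from an arm boundary within which SNPs are
#'   removed (default 2e6); only used when `arm_table` is supplied.
#' @param arm_table Optional data frame (chrom, start, end) of chromosome-arm
#'   spans; SNPs within `arm_trim_bp` of a start or end are dropped.
#' @return A list with elements `panel` (filtered) and `report` (class
#'   `qc_report`: removal counts per rule and the rare-allele fraction).
#' @export
qc_filter <- function(panel, snp_missing_max = 0.05, ind_missing_max = 0.10,
                      maf_rare_threshold = 0.01, hwe_p_min = 1e-8,
                      arm_trim_bp = 2e6, arm_table = NULL) {
  stopifnot(snp_missing_max >= 0, snp_missing_max <= 1,
            ind_missing_max >= 0, ind_missing_max <= 1)
  report <- list(snps_in = n_snps(panel), samples_in = n_samples(panel))

  tri <- grepl(",", panel$snp_table$alt, fixed = TRUE)
  report$snps_triallelic <- sum(tri)
  if (any(tri)) panel <- subset_panel(panel, snps = which(!tri))

  if (!is.null(arm_table)) {
    st <- panel$snp_table
    near <- rep(FALSE, nrow(st))
    for (k in seq_len(nrow(arm_table))) {
      a <- arm_table[k, ]
      on <- st$chrom == a$chrom & st$pos >= a$start & st$pos <= a$end
      near <- near | (on & (st$pos < a$start + arm_trim_bp |
                            st$pos > a$end - arm_trim_bp))
    }
    report$snps_arm_trimmed <- sum(near)
    if (any(near)) panel <- subset_panel(panel, snps = which(!near))
  } else report$snps_arm_trimmed <- 0L

  snps_missing_removed <- 0L; samples_missing_removed <- 0L
  repeat {
    miss <- is.na(panel$genotypes)
    snp_bad <- colMeans(miss) > snp_missing_max
    ind_bad <- rowMeans(miss) > ind_missing_max
    if (!any(snp_bad) && !any(ind_bad)) break
    snps_missing_removed <- snps_missing_removed + sum(snp_bad)
    samples_missing_removed <- samples_missing_removed + sum(ind_bad)
    if (all(snp_bad) || all(ind_bad)) stop("panel empty after missingness filtering")
    panel <- subset_panel(panel, samples = which(!ind_bad), snps = which(!snp_bad))
  }
  report$snps_missingness <- snps_missing_removed
  report$samples_missingness <- samples_missing_removed

  if (hwe_p_min > 0) {
    g <- panel$genotypes
    n_bb <- colSums(g == 2L, na.rm = TRUE)
    n_ab <- colSums(g == 1L, na.rm = TRUE)
    n_aa <- colSums(g == 0L, na.rm = TRUE)
    hwe_p <- vapply(seq_len(ncol(g)),
                    function(j) hwe_exact_test(n_aa[j], n_ab[j], n_bb[j]),
                    numeric(1))
    hwe_bad <- hwe_p <= hwe_p_min
    report$snps_hwe <- sum(hwe_bad)
    if (all(hwe_bad)) stop("panel empty after HWE filtering")
    if (any(hwe_bad)) panel <- subset_panel(panel, snps = which(!hwe_bad))
  } else report$snps_hwe <- 0L

  if (n_snps(panel) == 0 || n_samples(panel) == 0)
    stop("panel empty after QC filtering")

  p_alt <- colMeans(panel$genotypes, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  report$rare_allele_fraction <- mean(maf < maf_rare_threshold)
  report$snps_out <- n_snps(panel); report$samples_out <- n_samples(panel)
  class(report) <- "qc_report"
  list(panel = panel, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("QC report: %d -> %d SNPs, %d -> %d samples\n",
                     "  removed: %d triallelic, %d arm-trimmed, %d SNP missingness,\n",
                     "  %d HWE; %d samples by missingness\n",
                     "  rare-allele (MAF) fraction: %.4f\n"),
              x$snps_in, x$snps_out, x$samples_in, x$samples_out,
              x$snps_triallelic, x$snps_arm_trimmed, x$snps_missingness,
              x$snps_hwe, x$samples_missingness, x$rare_allele_fraction))
  invisible(x)
}

#' LD pruning by sliding bp windows
#'
#' Greedy left-to-right scan: windows of `window_bp` advance by `step_bp`
#' along each chromosome; within a window, for every pair of still-kept SNPs
#' whose squared genotype correlation (pairwise-complete dosages) exceeds
#' `r2_max`, the SNP with the higher bp position is dropped. Deterministic
#' for a given panel.
#'
#' @param panel A `genotype_panel` with at least two SNPs.
#' @param r2_max Squared-correlation threshold (default 0.2).
#' @param window_bp Window size in bp (default 50 kb).
#' @param step_bp Step size in bp (default 10 kb).
#' @return The pruned `genotype_panel`.
#' @export
ld_prune <- function(panel, r2_max = 0.2, window_bp = 50000, step_bp = 10000) {
  if (n_snps(panel) < 2) stop("ld_prune requires at least 2 SNPs")
  st <- panel$snp_table
  keep <- rep(TRUE, n_snps(panel))
  g <- panel$genotypes
  for (ch in unique(st$chrom)) {
    idx <- which(st$chrom == ch)
    pos <- st$pos[idx]
    starts <- seq(min(pos), max(pos), by = step_bp)
    for (w0 in starts) {
      inw <- idx[pos >= w0 & pos < w0 + window_bp]
      inw <- inw[keep[inw]]
      if (length(inw) < 2) next
      r <- suppressWarnings(stats::cor(g[, inw, drop = FALSE],
                                       use = "pairwise.complete.obs"))
      r2 <- r^2
      for (a in seq_along(inw)) {
        if (!keep[inw[a]]) next
        for (b in seq_along(inw)) {
          if (b <= a || !keep[inw[b]]) next
          if (!is.na(r2[a, b]) && r2[a, b] > r2_max) keep[inw[b]] <- FALSE
        }
      }
    }
  }
  subset_panel(panel, snps = which(keep))
}
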