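#' Construct a genotype panel
#'
#' The central container of the package: a samples x SNPs matrix of ALT-allele
#' dosages (0, 1, 2 or `NA` for missing), an optional phased haplotype matrix
#' (2 rows per sample, alleles 0/1), a per-SNP map table and a per-sample
#' metadata table.
#'
#' @param genotypes Integer matrix, samples x SNPs, values in \{0, 1, 2, NA\}.
#' @param snp_table Data frame with columns `chrom`, `pos` (1-based bp),
#'   `cm` (genetic position), `ref`, `alt`, `id`. Must be sorted by
#'   (chrom, pos) with non-decreasing `cm` within each chromosome.
#' @param sample_table Data frame with columns `id`, `population`,
#'   `major_group`, `lat`, `lon` (and optionally `admixed`, `related`).
#' @param haplotypes Optional integer matrix (2 * samples) x SNPs with values
#'   in \{0, 1, NA\}; rows `2i - 1` and `2i` are the two haplotypes of sample
#'   `i`, and their sum must equal the genotype at every non-missing site.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, snp_table, sample_table, haplotypes = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes); s <- ncol(genotypes)
  stopifnot(nrow(sample_table) == n, nrow(snp_table) == s)
  if (anyDuplicated(sample_table$id)) stop("duplicate sample ids")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype values must be 0, 1, 2 or NA")
  rl <- rle(as.character(snp_table$chrom))
  if (anyDuplicated(rl$values))
    stop("snp_table must be sorted by (chrom, pos): chromosomes not contiguous")
  if (any(tapply(snp_table$pos, factor(snp_table$chrom,
                                       levels = rl$values), is.unsorted)))
    stop("snp_table must be sorted by (chrom, pos)")
  for (ch in unique(snp_table$chrom)) {
    cm <- snp_table$cm[snp_table$chrom == ch]
    if (is.unsorted(cm)) stop("cM positions must be non-decreasing within chromosome")
  }
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
    stopifnot(nrow(haplotypes) == 2L * n, ncol(haplotypes) == s)
    g2 <- haplotypes[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      haplotypes[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    ok <- is.na(genotypes) | is.na(g2) | g2 == genotypes
    if (!all(ok)) stop("haplotype pair sums disagree with genotypes")
  }
  rownames(genotypes) <- sample_table$id
  structure(list(
    sample_ids = as.character(sample_table$id),
    genotypes = genotypes,
    haplotypes = haplotypes,
    snp_table = as.data.frame(snp_table),
    sample_table = as.data.frame(sample_table)
  ), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d SNPs (%s), %d chromosome(s)\n",
              n_samples(x), n_snps(x),
              if (is_phased(x)) "phased" else "unphased",
              length(unique(x$snp_table$chrom))))
  invisible(x)
}

#' Number of samples in a panel
#' @param panel A `genotype_panel`.
#' @return Integer count.
#' @export
n_samples <- function(panel) nrow(panel$genotypes)

#' Number of SNPs in a panel
#' @param panel A `genotype_panel`.
#' @return Integer count.
#' @export
n_snps <- function(panel) ncol(panel$genotypes)

#' Is the panel phased?
#' @param panel A `genotype_panel`.
#' @return Logical.
#' @export
is_phased <- function(panel) !is.null(panel$haplotypes)

#' Subset a panel by samples and/or SNPs
#'
#' @param panel A `genotype_panel`.
#' @param samples Sample index or id vector (default: all).
#' @param snps SNP index vector (default: all).
#' @return A `genotype_panel` restricted to the selection.
#' @export
subset_panel <- function(panel, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(panel))
        else if (is.character(samples)) match(samples, panel$sample_ids)
        else samples
  if (anyNA(si)) stop("unknown sample id in subset")
  vi <- if (is.null(snps)) seq_len(n_snps(panel)) else snps
  hap <- NULL
  if (is_phased(panel)) {
    hi <- as.vector(rbind(2L * si - 1L, 2L * si))
    hap <- panel$haplotypes[hi, vi, drop = FALSE]
  }
  genotype_panel(panel$genotypes[si, vi, drop = FALSE],
                 panel$snp_table[vi, , drop = FALSE],
                 panel$sample_table[si, , drop = FALSE],
                 haplotypes = hap)
}

#' Genomic span covered by the panel's SNPs
#'
#' Sum over chromosomes of (last bp - first bp + 1); the denominator of
#' F_ROH.
#'
#' @param panel A `genotype_panel`.
#' @return Total covered length in bp.
#' @export
panel_covered_bp <- function(panel) {
  sum(tapply(panel$snp_table$pos, panel$snp_table$chrom,
             function(p) max(p) - min(p) + 1))
}

#' Construct a genetic map
#'
#' @param anchors Data frame with columns `chrom`, `pos` (bp) and `cm`;
#'   within each chromosome `pos` must be strictly increasing and `cm`
#'   non-decreasing.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(anchors) {
  anchors <- as.data.frame(anchors)
  stopifnot(all(c("chrom", "pos", "cm") %in% names(anchors)))
  anchors <- anchors[order(anchors$chrom, anchors$pos), ]
  for (ch in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == ch, ]
    if (any(diff(a$pos) <= 0)) stop("map anchors must be strictly increasing in bp")
    if (any(diff(a$cm) < 0)) stop("map cM must be non-decreasing")
  }
  structure(list(anchors = anchors), class = "genetic_map")
}

#' Interpolate genetic position
#'
#' Piecewise-linear interpolation of cM between map anchors; positions
#' outside the anchored range take the boundary cM value (constant
#' extrapolation).
#'
#' @param map A `genetic_map`.
#' @param chrom Chromosome identifier (scalar).
#' @param bp Vector of 1-based physical positions.
#' @return Numeric vector of cM positions.
#' @export
interpolate_cm <- function(map, chrom, bp) {
  a <- map$anchors[map$anchors$chrom == chrom, ]
  if (nrow(a) == 0) stop(sprintf("chromosome '%s' not in genetic map", chrom))
  if (nrow(a) == 1) return(rep(a$cm, length(bp)))
  stats::approx(a$pos, a$cm, xout = bp, rule = 2, ties = "ordered")$y
}
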