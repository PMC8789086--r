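#' Per-population allele frequencies
#'
#' @param panel A `genotype_panel`.
#' @param grouping Named character vector or factor mapping sample id to
#'   population; defaults to the panel's `population` column. To treat each
#'   individual as its own population (individual-level distance matrices),
#'   pass `grouping = "individual"`.
#' @return A `freq_table`: list with `freq` (populations x SNPs ALT
#'   frequency, `NA` where no calls), `count` (haplotype counts, 2 x
#'   non-missing diploids) and `snp_table`.
#' @export
allele_frequencies <- function(panel, grouping = NULL) {
  if (identical(grouping, "individual"))
    grouping <- stats::setNames(panel$sample_ids, panel$sample_ids)
  if (is.null(grouping))
    grouping <- stats::setNames(panel$sample_table$population, panel$sample_ids)
  grouping <- grouping[!is.na(grouping)]
  if (!all(names(grouping) %in% panel$sample_ids))
    stop("grouping names must be panel sample ids")
  pops <- unique(as.character(grouping))
  g <- panel$genotypes
  freq <- matrix(NA_real_, length(pops), n_snps(panel),
                 dimnames = list(pops, NULL))
  count <- matrix(0L, length(pops), n_snps(panel), dimnames = list(pops, NULL))
  for (p in pops) {
    ids <- names(grouping)[grouping == p]
    if (length(ids) == 0) stop("empty population: ", p)
    gp <- g[match(ids, panel$sample_ids), , drop = FALSE]
    nn <- colSums(!is.na(gp))
    count[p, ] <- 2L * nn
    freq[p, ] <- ifelse(nn > 0, colSums(gp, na.rm = TRUE) / (2 * nn), NA_real_)
  }
  structure(list(freq = freq, count = count, snp_table = panel$snp_table),
            class = "freq_table")
}

# Contiguous map blocks of block_size_cm for the block jackknife.
jackknife_blocks <- function(snp_table, block_size_cm) {
  ids <- integer(nrow(snp_table)); nxt <- 0L
  for (ch in unique(snp_table$chrom)) {
    i <- snp_table$chrom == ch
    cm <- snp_table$cm[i]
    ids[i] <- nxt + as.integer(floor((cm - cm[1]) / block_size_cm))
    nxt <- max(ids[i]) + 1L
  }
  ids
}

# Weighted delete-one-block jackknife (Busing-style) for a mean statistic.
# x: per-SNP contributions; blocks: integer block id per SNP.
block_jackknife <- function(x, blocks) {
  keep <- !is.na(x)
  x <- x[keep]; blocks <- blocks[keep]
  n <- length(x)
  tot <- sum(x)
  fb <- factor(blocks)
  bsum <- as.vector(rowsum(x, fb))
  m <- as.vector(table(fb))
  g <- length(bsum)
  if (g < 2) stop("fewer than 2 jackknife blocks with usable SNPs")
  theta <- tot / n
  theta_mj <- (tot - bsum) / (n - m)
  h <- n / m
  est_j <- g * theta - sum((1 - m / n) * theta_mj)
  tau <- h * theta - (h - 1) * theta_mj
  var_j <- mean((tau - est_j)^2 / (h - 1))
  list(estimate = theta, se = sqrt(var_j), n_blocks = g, n_snps = n)
}

#' f2, f3 and f4 statistics with block-jackknife errors
#'
#' Per-SNP moments `f2 = (a-b)^2`, `f3(C; A, B) = (c-a)(c-b)` and
#' `f4(A, B; C, D) = (a-b)(c-d)` averaged over SNPs with non-missing
#' frequencies in all argument populations (listwise complete cases).
#' Finite-sample heterozygosity corrections `p(1-p)/(n-1)` (haplotype
#' counts) are subtracted for f2 (both populations) and f3 (the target
#' population). Standard errors come from a weighted block jackknife over
#' contiguous map blocks; `Z = estimate / SE`.
#'
#' @param freqs A `freq_table` from [allele_frequencies()].
#' @param kind One of `"f2"`, `"f3"`, `"f4"`.
#' @param pops Character vector of population arguments: `(A, B)` for f2,
#'   `(C, A, B)` for f3 (C the target/outgroup), `(A, B, C, D)` for f4.
#' @param block_size_cm Jackknife block length in cM (default 5).
#' @param correct Apply the finite-sample corrections (default `TRUE`).
#' @return An `fstat_result`: one-row data frame with `kind`, `pops`,
#'   `estimate`, `se`, `z`, `n_blocks`, `n_snps`.
#' @export
f_statistic <- function(freqs, kind = c("f2", "f3", "f4"), pops,
                        block_size_cm = 5, correct = TRUE) {
  kind <- match.arg(kind)
  need <- c(f2 = 2L, f3 = 3L, f4 = 4L)[[kind]]
  if (length(pops) != need) stop(kind, " requires ", need, " populations")
  miss <- setdiff(pops, rownames(freqs$freq))
  if (length(miss)) stop("populations absent from table: ",
                         paste(miss, collapse = ", "))
  f <- freqs$freq[pops, , drop = FALSE]
  n <- freqs$count[pops, , drop = FALSE]
  use <- colSums(is.na(f)) == 0 & colSums(n < 2) == 0
  if (!any(use)) stop("no usable SNPs (complete cases across populations)")
  het <- function(i) f[i, ] * (1 - f[i, ]) / (n[i, ] - 1)
  x <- switch(kind,
    f2 = {
      v <- (f[1, ] - f[2, ])^2
      if (correct) v <- v - het(1) - het(2)
      v
    },
    f3 = {
      v <- (f[1, ] - f[2, ]) * (f[1, ] - f[3, ])
      if (correct) v <- v - het(1)
      v
    },
    f4 = (f[1, ] - f[2, ]) * (f[3, ] - f[4, ]))
  x[!use] <- NA
  blocks <- jackknife_blocks(freqs$snp_table, block_size_cm)
  jk <- block_jackknife(x, blocks)
  structure(data.frame(kind = kind, pops = paste(pops, collapse = ","),
                       estimate = jk$estimate, se = jk$se,
                       z = if (jk$se > 0) jk$estimate / jk$se else NA_real_,
                       n_blocks = jk$n_blocks, n_snps = jk$n_snps,
                       stringsAsFactors = FALSE),
            class = c("fstat_result", "data.frame"))
}

#' Outgroup-f3 distance matrix
#'
#' Computes `f3(outgroup; Y, Z)` for all pairs of non-outgroup populations
#' and returns it either raw or as the genetic distance `1 - f3`.
#'
#' @param freqs A `freq_table` (possibly individual-level).
#' @param outgroup Population used as the f3 target.
#' @param units `"raw"` (f3 values) or `"one_minus"` (1 - f3 distances).
#' @param block_size_cm Jackknife block size passed to [f_statistic()].
#' @return A `dist_matrix`: list with `labels`, symmetric `matrix` (zero
#'   diagonal) and a `units` tag.
#' @export
outgroup_f3_matrix <- function(freqs, outgroup, units = c("raw", "one_minus"),
                               block_size_cm = 5) {
  units <- match.arg(units)
  pops <- setdiff(rownames(freqs$freq), outgroup)
  if (!(outgroup %in% rownames(freqs$freq))) stop("outgroup not in table")
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    est <- f_statistic(freqs, "f3", c(outgroup, pops[i], pops[j]),
                       block_size_cm = block_size_cm)$estimate
    m[i, j] <- m[j, i] <- if (units == "one_minus") 1 - est else est
  }
  structure(list(labels = pops, matrix = m, units = units),
            class = "dist_matrix")
}

#' Summarize F4 affinity counts
#'
#' For a collection of f4 results of the form `f4(outgroup, X; Y, Z)`,
#' counts the tests with `Z > z_threshold` (strict) grouped by the pair
#' `(X, Z)` and summed over `Y`.
#'
#' @param results Data frame of `fstat_result` rows (stackable via `rbind`),
#'   all of kind `"f4"` sharing the same first (outgroup) argument.
#' @param z_threshold Significance threshold on Z (default 4; strict `>`).
#' @return Data frame with columns `X`, `Z_pop`, `n_significant`.
#' @export
summarize_f4_affinity <- function(results, z_threshold = 4) {
  if (!all(results$kind == "f4")) stop("all results must be f4 statistics")
  args <- do.call(rbind, strsplit(results$pops, ",", fixed = TRUE))
  if (length(unique(args[, 1])) != 1) stop("mixed outgroups in f4 collection")
  key <- data.frame(X = args[, 2], Z_pop = args[, 4], stringsAsFactors = FALSE)
  sig <- results$z > z_threshold
  agg <- stats::aggregate(sig, by = key, FUN = sum)
  names(agg)[3] <- "n_significant"
  agg[order(agg$X, agg$Z_pop), , drop = FALSE]
}
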