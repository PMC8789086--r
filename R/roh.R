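#' Call runs of homozygosity (PLINK-style scanning)
#'
#' Sliding windows of `window_snps` SNPs pass when they contain at most
#' `max_het_per_window` heterozygous and `max_miss_per_window` missing
#' calls; each SNP is scored by the fraction of spanning windows that pass
#' (terminal SNPs use the windows that exist). SNPs scoring at least
#' `min_overlap_frac` seed candidate runs, which are then extended outward
#' over consecutive non-missing homozygous SNPs, split at inter-SNP gaps
#' above `max_gap_kb`, and filtered by SNP density and minimum length.
#'
#' @param panel A `genotype_panel` with sorted SNPs.
#' @param window_snps Window size in SNPs (default 50).
#' @param max_het_per_window Maximum heterozygous calls per window (default 1).
#' @param max_miss_per_window Maximum missing calls per window (default 5).
#' @param min_overlap_frac Minimum fraction of passing spanning windows
#'   (default 0.05).
#' @param min_snp_density_kb Maximum kb per SNP inside a run (default 50,
#'   i.e. at least one SNP per 50 kb).
#' @param max_gap_kb Maximum gap between consecutive run SNPs (default 100).
#' @param min_length_kb Minimum run length (default 500).
#' @return A `roh_set` data frame: `sample`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`.
#' @export
call_roh <- function(panel, window_snps = 50, max_het_per_window = 1,
                     max_miss_per_window = 5, min_overlap_frac = 0.05,
                     min_snp_density_kb = 50, max_gap_kb = 100,
                     min_length_kb = 500) {
  st <- panel$snp_table
  if (is.unsorted(order(st$chrom, st$pos))) stop("unsorted SNPs")
  g <- panel$genotypes
  out <- list()
  for (ch in unique(st$chrom)) {
    idx <- which(st$chrom == ch)
    pos <- st$pos[idx]
    S <- length(idx)
    w <- min(window_snps, S)
    for (i in seq_len(n_samples(panel))) {
      gi <- g[i, idx]
      het <- as.numeric(gi == 1L); het[is.na(het)] <- 0
      mis <- as.numeric(is.na(gi))
      if (S >= w) {
        ch_cum <- c(0, cumsum(het)); mi_cum <- c(0, cumsum(mis))
        nw <- S - w + 1L
        wh <- ch_cum[(w + 1):(S + 1)] - ch_cum[1:nw]
        wm <- mi_cum[(w + 1):(S + 1)] - mi_cum[1:nw]
        pass <- wh <= max_het_per_window & wm <= max_miss_per_window
        # per-SNP: fraction of spanning windows (those that exist) passing
        pass_cum <- c(0, cumsum(pass))
        lo <- pmax(1L, seq_len(S) - w + 1L); hi <- pmin(seq_len(S), nw)
        nspan <- hi - lo + 1L
        npass <- pass_cum[hi + 1L] - pass_cum[lo]
        score <- ifelse(nspan > 0, npass / nspan, 0)
      } else score <- rep(0, S)
      qual <- score >= min_overlap_frac
      if (!any(qual)) next
      rl <- rle(qual)
      ends <- cumsum(rl$lengths); starts <- c(1L, ends[-length(ends)] + 1L)
      segs <- cbind(starts[rl$values], ends[rl$values])
      hom <- !is.na(gi) & gi != 1L
      merged <- list()
      for (k in seq_len(nrow(segs))) {
        a <- segs[k, 1]; b <- segs[k, 2]
        # trim het/missing terminal SNPs (an isolated flanking het can pass
        # the window rule), then close boundaries over homozygous runs
        while (a <= b && !hom[a]) a <- a + 1L
        while (b >= a && !hom[b]) b <- b - 1L
        if (a > b) next
        while (a > 1L && hom[a - 1L]) a <- a - 1L
        while (b < S && hom[b + 1L]) b <- b + 1L
        merged[[k]] <- c(a, b)
      }
      if (!length(merged)) next
      # overlapping extended runs collapse
      mg <- do.call(rbind, merged)
      mg <- mg[order(mg[, 1]), , drop = FALSE]
      coll <- list(mg[1, ])
      if (nrow(mg) > 1) for (k in 2:nrow(mg)) {
        last <- coll[[length(coll)]]
        if (mg[k, 1] <= last[2] + 1L)
          coll[[length(coll)]] <- c(last[1], max(last[2], mg[k, 2]))
        else coll[[length(coll) + 1L]] <- mg[k, ]
      }
      for (seg in coll) {
        a <- seg[1]; b <- seg[2]
        # split at gaps exceeding max_gap_kb
        pieces <- list()
        cur <- a
        if (b > a) for (t in seq(a + 1L, b)) {
          if (pos[t] - pos[t - 1L] > max_gap_kb * 1000) {
            pieces[[length(pieces) + 1L]] <- c(cur, t - 1L); cur <- t
          }
        }
        pieces[[length(pieces) + 1L]] <- c(cur, b)
        for (pc in pieces) {
          len <- pos[pc[2]] - pos[pc[1]] + 1L
          nsnp <- pc[2] - pc[1] + 1L
          if (len < min_length_kb * 1000) next
          if (len / nsnp > min_snp_density_kb * 1000) next
          out[[length(out) + 1L]] <- data.frame(
            sample = panel$sample_ids[i], chrom = ch,
            start_bp = pos[pc[1]], end_bp = pos[pc[2]],
            n_snps = nsnp, length_bp = len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(0), chrom = character(0),
               start_bp = integer(0), end_bp = integer(0),
               n_snps = integer(0), length_bp = integer(0))
  class(res) <- c("roh_set", "data.frame")
  res
}

#' Inbreeding coefficient from runs of homozygosity
#'
#' `F_ROH` = total ROH length divided by the genomic span covered by the
#' panel's SNPs.
#'
#' @param rohs A `roh_set` from [call_roh()].
#' @param covered_bp Total genomic span covered by the SNPs (e.g.
#'   [panel_covered_bp()]).
#' @param sample_table Optional panel `sample_table` giving the full sample
#'   list (so ROH-free samples get F_ROH = 0) and population labels.
#' @return A `froh_table`: data frame (`id`, `population`, `froh`) with a
#'   `population_means` attribute.
#' @export
froh <- function(rohs, covered_bp, sample_table = NULL) {
  stopifnot(covered_bp > 0)
  if (nrow(rohs) && any(rohs$length_bp > covered_bp))
    stop("ROH longer than the covered span")
  tot <- if (nrow(rohs)) tapply(as.numeric(rohs$length_bp), rohs$sample, sum)
         else numeric(0)
  if (is.null(sample_table))
    sample_table <- data.frame(id = names(tot), population = NA,
                               stringsAsFactors = FALSE)
  v <- as.numeric(tot[sample_table$id])
  v[is.na(v)] <- 0
  fr <- v / covered_bp
  if (any(fr > 1)) stop("total ROH length exceeds covered span")
  out <- data.frame(id = sample_table$id, population = sample_table$population,
                    froh = fr, stringsAsFactors = FALSE)
  attr(out, "population_means") <-
    tapply(out$froh, out$population, mean)
  class(out) <- c("froh_table", "data.frame")
  out
}

#' F_ROH versus geography
#'
#' Spearman correlation of population-mean F_ROH with longitude, plus a
#' Wilcoxon rank-sum comparison of individual F_ROH between two labeled
#' regions (exact for small samples, continuity-corrected normal
#' approximation for n > 20 per group).
#'
#' @param froh_table A `froh_table`.
#' @param coords Data frame with `population` and `lon` (one row per
#'   population).
#' @param region Optional named vector mapping population to one of two
#'   region labels for the rank-sum test.
#' @return List with `spearman_r`, `spearman_p`, and (when `region` is
#'   given) `wilcoxon_p`.
#' @export
froh_geography <- function(froh_table, coords, region = NULL) {
  pm <- attr(froh_table, "population_means")
  pops <- names(pm)
  if (length(pops) < 3) stop("need at least 3 populations")
  lon <- coords$lon[match(pops, coords$population)]
  if (stats::sd(pm) == 0 || stats::sd(lon, na.rm = TRUE) == 0)
    stop("constant input")
  ct <- suppressWarnings(stats::cor.test(pm, lon, method = "spearman"))
  out <- list(spearman_r = unname(ct$estimate), spearman_p = ct$p.value)
  if (!is.null(region)) {
    rg <- region[froh_table$population]
    lv <- unique(stats::na.omit(rg))
    if (length(lv) != 2) stop("region must have exactly two labels")
    x <- froh_table$froh[rg == lv[1]]
    y <- froh_table$froh[rg == lv[2]]
    ex <- min(length(x), length(y)) <= 20
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = ex, correct = TRUE))
    out$wilcoxon_p <- wt$p.value
  }
  out
}
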