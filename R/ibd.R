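#' Detect IBD (and HBD) segments on phased haplotypes
#'
#' Seed-and-extend matching over haplotype pairs: exact-match runs of at
#' least `seed_cm` seed candidate segments, which are extended in both
#' directions under a per-site log10 likelihood-ratio score (mismatches as
#' genotyping errors at `error_tolerance` under IBD, versus the
#' allele-frequency-expected opposite-allele rate `2p(1-p)` under
#' background) with an X-drop stopping rule. Maximal segments longer than
#' `min_cm` with support above `min_support` are emitted. HBD segments are
#' detected identically on an individual's own haplotype pair.
#'
#' @param panel A phased `genotype_panel`.
#' @param min_cm Minimum segment length in cM (strict `>`; default 2).
#' @param min_support Minimum log10 likelihood-ratio support (strict `>`;
#'   default 3, the "LOD > 3" rule).
#' @param error_tolerance Per-site error rate under the IBD hypothesis
#'   (default 0.002).
#' @param hbd `"exclude"` (between-individual pairs only, default),
#'   `"include"` (both) or `"only"` (within-individual pairs).
#' @param seed_cm Minimum exact-match seed length (default 0.5).
#' @param xdrop Score drop at which extension stops (default 3).
#' @return An `ibd_segments` data frame: `sample1`, `hap1`, `sample2`,
#'   `hap2`, `chrom`, `start_bp`, `end_bp`, `start_cm`, `end_cm`,
#'   `length_cm`, `support`, `n_snps`, `ancestry` (NA until masked).
#' @export
detect_ibd <- function(panel, min_cm = 2, min_support = 3,
                       error_tolerance = 0.002,
                       hbd = c("exclude", "include", "only"),
                       seed_cm = 0.5, xdrop = 3) {
  hbd <- match.arg(hbd)
  if (!is_phased(panel)) stop("detect_ibd requires a phased panel")
  H <- panel$haplotypes
  st <- panel$snp_table
  n <- n_samples(panel)
  p <- pmin(pmax(colMeans(H, na.rm = TRUE), 1e-3), 1 - 1e-3)
  eps <- error_tolerance
  s_mis_all <- log10(eps) - log10(2 * p * (1 - p))
  s_mat_all <- log10(1 - eps) - log10(1 - 2 * p * (1 - p))
  layout <- chrom_layout(st)

  pairs <- list()
  if (hbd != "only")
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      for (a in 1:2) for (b in 1:2)
        pairs[[length(pairs) + 1L]] <- c(i, a, j, b)
  if (hbd != "exclude")
    for (i in seq_len(n))
      pairs[[length(pairs) + 1L]] <- c(i, 1L, i, 2L)

  out <- list()
  for (pr in pairs) {
    r1 <- 2L * pr[1] - 2L + pr[2]; r2 <- 2L * pr[3] - 2L + pr[4]
    for (ly in layout) {
      idx <- ly$idx; cm <- ly$cm
      h1 <- H[r1, idx]; h2 <- H[r2, idx]
      valid <- !is.na(h1) & !is.na(h2)
      mism <- valid & h1 != h2
      s <- numeric(length(idx))
      s[valid & !mism] <- s_mat_all[idx][valid & !mism]
      s[mism] <- s_mis_all[idx][mism]
      # seeds: exact-match runs (no mismatch) of at least seed_cm
      rl <- rle(!mism)
      ends <- cumsum(rl$lengths); starts <- c(1L, ends[-length(ends)] + 1L)
      ok <- rl$values & (cm[ends] - cm[starts]) >= seed_cm
      if (!any(ok)) next
      seeds <- cbind(starts[ok], ends[ok])
      S <- length(idx)
      segs <- list()
      done_until <- 0L
      for (k in seq_len(nrow(seeds))) {
        a <- seeds[k, 1]; b <- seeds[k, 2]
        if (b <= done_until) next
        # extend right
        if (b < S) {
          cs <- cumsum(s[(b + 1L):S])
          stopi <- which(cummax(cs) - cs >= xdrop)[1]
          lim <- if (is.na(stopi)) length(cs) else stopi
          gain <- max(cs[seq_len(lim)])
          if (gain > 0) b <- b + which.max(cs[seq_len(lim)])
        }
        # extend left
        if (a > 1L) {
          cs <- cumsum(s[(a - 1L):1L])
          stopi <- which(cummax(cs) - cs >= xdrop)[1]
          lim <- if (is.na(stopi)) length(cs) else stopi
          gain <- max(cs[seq_len(lim)])
          if (gain > 0) a <- a - which.max(cs[seq_len(lim)])
        }
        done_until <- max(done_until, b)
        segs[[length(segs) + 1L]] <- c(a, b)
      }
      if (!length(segs)) next
      mg <- do.call(rbind, segs)
      mg <- mg[order(mg[, 1]), , drop = FALSE]
      coll <- list(mg[1, ])
      if (nrow(mg) > 1) for (k in 2:nrow(mg)) {
        last <- coll[[length(coll)]]
        if (mg[k, 1] <= last[2])
          coll[[length(coll)]] <- c(last[1], max(last[2], mg[k, 2]))
        else coll[[length(coll) + 1L]] <- mg[k, ]
      }
      for (sg in coll) {
        a <- sg[1]; b <- sg[2]
        len <- cm[b] - cm[a]
        sup <- sum(s[a:b])
        if (len > min_cm && sup > min_support)
          out[[length(out) + 1L]] <- data.frame(
            sample1 = panel$sample_ids[pr[1]], hap1 = pr[2],
            sample2 = panel$sample_ids[pr[3]], hap2 = pr[4],
            chrom = st$chrom[idx[1]],
            start_bp = st$pos[idx[a]], end_bp = st$pos[idx[b]],
            start_cm = cm[a], end_cm = cm[b], length_cm = len,
            support = sup, n_snps = b - a + 1L, ancestry = NA_character_,
            stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_ibd_df()
  class(res) <- c("ibd_segments", "data.frame")
  res
}

empty_ibd_df <- function() {
  data.frame(sample1 = character(0), hap1 = integer(0),
             sample2 = character(0), hap2 = integer(0), chrom = character(0),
             start_bp = integer(0), end_bp = integer(0),
             start_cm = numeric(0), end_cm = numeric(0),
             length_cm = numeric(0), support = numeric(0),
             n_snps = integer(0), ancestry = character(0),
             stringsAsFactors = FALSE)
}

#' Merge IBD segments across short gaps
#'
#' Consecutive segments of the same haplotype pair separated by at most
#' `max_gap_cm` and with at most `max_discordant_hom` opposite-homozygote
#' genotype sites in the gap are merged.
#'
#' @param segments An `ibd_segments` data frame.
#' @param panel The `genotype_panel` the segments came from (genotypes are
#'   needed to count discordant homozygotes in gaps).
#' @param max_gap_cm Maximum gap length in cM (default 0.6).
#' @param max_discordant_hom Maximum opposite-homozygote sites in the gap
#'   (default 1).
#' @return The merged `ibd_segments`.
#' @export
merge_gaps <- function(segments, panel, max_gap_cm = 0.6,
                       max_discordant_hom = 1) {
  if (nrow(segments) == 0) return(segments)
  st <- panel$snp_table
  key <- interaction(segments$sample1, segments$hap1, segments$sample2,
                     segments$hap2, segments$chrom, drop = TRUE)
  res <- list()
  for (k in levels(key)) {
    sub <- segments[key == k, , drop = FALSE]
    sub <- sub[order(sub$start_cm), , drop = FALSE]
    i1 <- match(sub$sample1[1], panel$sample_ids)
    i2 <- match(sub$sample2[1], panel$sample_ids)
    cur <- sub[1, , drop = FALSE]
    for (r in seq_len(nrow(sub))[-1]) {
      gap_cm <- sub$start_cm[r] - cur$end_cm
      in_gap <- which(st$chrom == cur$chrom &
                      st$pos > cur$end_bp & st$pos < sub$start_bp[r])
      g1 <- panel$genotypes[i1, in_gap]; g2 <- panel$genotypes[i2, in_gap]
      disc <- sum(!is.na(g1) & !is.na(g2) & abs(g1 - g2) == 2L)
      if (gap_cm <= max_gap_cm && disc <= max_discordant_hom) {
        cur$end_bp <- sub$end_bp[r]; cur$end_cm <- sub$end_cm[r]
        cur$length_cm <- cur$end_cm - cur$start_cm
        cur$support <- cur$support + sub$support[r]
        cur$n_snps <- cur$n_snps + sub$n_snps[r]
      } else {
        res[[length(res) + 1L]] <- cur
        cur <- sub[r, , drop = FALSE]
      }
    }
    res[[length(res) + 1L]] <- cur
  }
  out <- do.call(rbind, res)
  out <- out[order(out$sample1, out$sample2, out$chrom, out$start_bp), ]
  rownames(out) <- NULL
  class(out) <- c("ibd_segments", "data.frame")
  out
}

#' Window-likelihood local ancestry classification
#'
#' Per haplotype and per genetic-map window of `window_cm`, assigns the
#' source population maximizing the window log-likelihood under source
#' allele frequencies, with posteriors from the normalized likelihoods;
#' adjacent same-label windows merge into tracts. Windows without usable
#' data inherit the previous window's label (flagged in `inherited`).
#'
#' @param panel A phased `genotype_panel`.
#' @param reference_freqs K x SNPs source-frequency matrix with rownames
#'   (or a `freq_table`).
#' @param window_cm Window size in cM (default 0.2).
#' @param eps Frequency clipping bound (default 1e-3).
#' @return An `ancestry_tracts` data frame: `sample`, `hap`, `chrom`,
#'   `start_cm`, `end_cm`, `start_bp`, `end_bp`, `label`,
#'   `mean_posterior`, `inherited` (any window inherited).
#' @export
classify_local_ancestry <- function(panel, reference_freqs, window_cm = 0.2,
                                    eps = 1e-3) {
  if (!is_phased(panel)) stop("requires a phased panel")
  if (inherits(reference_freqs, "freq_table"))
    reference_freqs <- reference_freqs$freq
  K <- nrow(reference_freqs)
  if (is.null(K) || K < 2) stop("need at least 2 source populations")
  f <- pmin(pmax(reference_freqs, eps), 1 - eps)
  lf <- log(f); lq <- log(1 - f)
  st <- panel$snp_table
  layout <- chrom_layout(st)
  H <- panel$haplotypes
  n2 <- nrow(H)
  out <- list()
  for (ly in layout) {
    idx <- ly$idx; cm <- ly$cm
    ch <- st$chrom[idx[1]]
    breaks <- seq(0, ly$L + window_cm, by = window_cm)
    win <- findInterval(cm, breaks, rightmost.closed = FALSE)
    W <- max(win)
    winf <- factor(win, levels = seq_len(W))
    # window bp bounds by linear interpolation of the chromosome's SNPs
    wb <- breaks[seq_len(W)]; we <- breaks[seq_len(W) + 1L]
    bp_of <- function(x) stats::approx(cm, st$pos[idx], xout = x, rule = 2)$y
    for (r in seq_len(n2)) {
      x <- H[r, idx]
      use <- !is.na(x)
      llk <- matrix(0, K, W)
      for (k in seq_len(K)) {
        contrib <- ifelse(use, x * lf[k, idx] + (1 - x) * lq[k, idx], 0)
        contrib[is.na(contrib)] <- 0
        v <- tapply(contrib, winf, sum)
        v[is.na(v)] <- 0
        llk[k, ] <- as.vector(v)
      }
      hv <- tapply(as.numeric(use), winf, sum)
      hv[is.na(hv)] <- 0
      have <- as.vector(hv) > 0
      lab <- max.col(t(llk), ties.method = "first")
      po <- apply(llk, 2, function(v) {
        e <- exp(v - max(v)); max(e) / sum(e)
      })
      inh <- rep(FALSE, W)
      for (w in seq_len(W)) {
        if (!have[w]) {
          lab[w] <- if (w > 1) lab[w - 1] else lab[which(have)[1]]
          po[w] <- NA
          inh[w] <- TRUE
        }
      }
      rl <- rle(lab)
      e <- cumsum(rl$lengths); s <- c(1L, e[-length(e)] + 1L)
      out[[length(out) + 1L]] <- data.frame(
        sample = panel$sample_ids[(r + 1L) %/% 2L], hap = 2L - r %% 2L,
        chrom = ch, start_cm = wb[s], end_cm = we[e],
        start_bp = round(bp_of(wb[s])), end_bp = round(bp_of(we[e])),
        label = rownames(f)[rl$values],
        mean_posterior = vapply(seq_along(s), function(t)
          mean(po[s[t]:e[t]], na.rm = TRUE), numeric(1)),
        inherited = vapply(seq_along(s), function(t)
          any(inh[s[t]:e[t]]), logical(1)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ancestry_tracts", "data.frame")
  res
}

#' Mask IBD segments by local ancestry
#'
#' Keeps segments whose cM span overlaps tracts of `target_label` by at
#' least `min_overlap_frac` of the segment length on both participating
#' haplotypes.
#'
#' @param segments An `ibd_segments` data frame.
#' @param tracts An `ancestry_tracts` data frame covering the segments.
#' @param target_label Ancestry label to require.
#' @param min_overlap_frac Required overlap fraction (default 1.0, i.e.
#'   full-length target ancestry on both haplotypes).
#' @return The masked `ibd_segments` (with `ancestry` set).
#' @export
mask_by_ancestry <- function(segments, tracts, target_label,
                             min_overlap_frac = 1.0) {
  if (nrow(segments) == 0) return(segments)
  frac_for <- function(sample, hap, chrom, a, b) {
    tt <- tracts[tracts$sample == sample & tracts$hap == hap &
                 tracts$chrom == chrom, , drop = FALSE]
    if (nrow(tt) == 0) stop("missing ancestry tracts for sample ", sample)
    tt <- tt[tt$label == target_label, , drop = FALSE]
    if (nrow(tt) == 0) return(0)
    ov <- pmax(0, pmin(tt$end_cm, b) - pmax(tt$start_cm, a))
    sum(ov) / (b - a)
  }
  keep <- vapply(seq_len(nrow(segments)), function(r) {
    sg <- segments[r, ]
    f1 <- frac_for(sg$sample1, sg$hap1, sg$chrom, sg$start_cm, sg$end_cm)
    f2 <- frac_for(sg$sample2, sg$hap2, sg$chrom, sg$start_cm, sg$end_cm)
    min(f1, f2) >= min_overlap_frac - 1e-9
  }, logical(1))
  out <- segments[keep, , drop = FALSE]
  out$ancestry <- rep(target_label, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ibd_segments", "data.frame")
  out
}

#' Expected age of an IBD segment from its length
#'
#' `E(generations ago) ~ 3 / (2 I)` with I the segment length in morgans;
#' years use a fixed generation interval.
#'
#' @param length_cm Segment length(s) in cM (> 0).
#' @param years_per_generation Generation interval in years (default 28).
#' @return Data frame with `generations` and `years`.
#' @export
segment_age <- function(length_cm, years_per_generation = 28) {
  if (any(length_cm <= 0)) stop("segment length must be positive")
  gen <- 3 / (2 * (length_cm / 100))
  data.frame(generations = gen, years = gen * years_per_generation)
}

#' Classify segment lengths into historical periods
#'
#' Pre-Columbian (length <= 8.4 cM), colonial (8.4 < length <= 28 cM),
#' recent (length > 28 cM).
#'
#' @param length_cm Segment length(s) in cM.
#' @return Character vector of period labels.
#' @export
bin_to_period <- function(length_cm) {
  ifelse(length_cm <= 8.4, "precolumbian",
         ifelse(length_cm <= 28, "colonial", "recent"))
}

#' Population-pair IBD sharing network
#'
#' Restricts to segments of the given period with length at least
#' `min_len_cm`, then for each population pair computes the average number
#' of segments and the average total length, each normalized by the
#' product of the two sample sizes (the within-population diagonal uses
#' n x n for consistency with the product rule). Pairs with average
#' length at or below `min_avg_cm` are excluded and recorded.
#'
#' @param segments An `ibd_segments` data frame (HBD rows are ignored).
#' @param grouping Named vector mapping sample id to population.
#' @param period One of `"precolumbian"`, `"colonial"`, `"recent"`, or
#'   `"all"`.
#' @param min_avg_cm Minimum average shared length per pair (strict `>`;
#'   default 5).
#' @param min_len_cm Minimum segment length considered (default 2).
#' @return A `sharing_network`: list with `edges` (kept pairs), `excluded`
#'   (with reasons) and the `period` tag.
#' @export
sharing_network <- function(segments, grouping, period = "all",
                            min_avg_cm = 5, min_len_cm = 2) {
  segs <- segments[segments$sample1 != segments$sample2, , drop = FALSE]
  segs <- segs[segs$length_cm >= min_len_cm, , drop = FALSE]
  if (period != "all")
    segs <- segs[bin_to_period(segs$length_cm) == period, , drop = FALSE]
  sizes <- table(grouping)
  if (any(sizes == 0)) stop("population of size 0")
  pops <- names(sizes)
  p1 <- as.character(grouping[segs$sample1])
  p2 <- as.character(grouping[segs$sample2])
  a <- pmin(p1, p2); b <- pmax(p1, p2)
  edges <- list(); excluded <- list()
  for (i in seq_along(pops)) for (j in seq(i, length(pops))) {
    pi <- pops[i]; pj <- pops[j]
    sel <- a == min(pi, pj) & b == max(pi, pj)
    denom <- as.numeric(sizes[pi]) * as.numeric(sizes[pj])
    avg_count <- sum(sel) / denom
    avg_len <- sum(segs$length_cm[sel]) / denom
    row <- data.frame(pop1 = pi, pop2 = pj, n_segments = sum(sel),
                      avg_count = avg_count, avg_length_cm = avg_len,
                      stringsAsFactors = FALSE)
    if (avg_len > min_avg_cm) edges[[length(edges) + 1L]] <- row
    else {
      row$reason <- sprintf("avg length %.3f cM <= %g", avg_len, min_avg_cm)
      excluded[[length(excluded) + 1L]] <- row
    }
  }
  structure(list(
    edges = if (length(edges)) do.call(rbind, edges) else NULL,
    excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
    period = period), class = "sharing_network")
}

#' Summaries of IBD/HBD by length category
#'
#' Bins segments into the five length categories 1-2, 2-4, 4-8, 8-16 and
#' >16 cM (lower-inclusive) and reports, per population and bin, the
#' number of segments, their mean length, and the average count per
#' sampled unit (individual pairs for IBD, individuals for HBD).
#'
#' @param segments An `ibd_segments` data frame (intra-population IBD
#'   and/or HBD rows).
#' @param grouping Named vector mapping sample id to population.
#' @param bins Lower bin edges (default `c(1, 2, 4, 8, 16)`; last bin
#'   unbounded).
#' @return Data frame: `population`, `type`, `bin`, `n_segments`,
#'   `mean_cm`, `avg_count`.
#' @export
length_category_summary <- function(segments, grouping,
                                    bins = c(1, 2, 4, 8, 16)) {
  labs <- c(paste0(bins[-length(bins)], "-", bins[-1]),
            paste0(">", bins[length(bins)]))
  sizes <- table(grouping)
  pops <- names(sizes)
  grid <- expand.grid(population = pops, type = c("ibd", "hbd"),
                      bin = labs, stringsAsFactors = FALSE)
  grid$n_segments <- 0L; grid$mean_cm <- 0; grid$avg_count <- 0
  if (nrow(segments)) {
    type <- ifelse(segments$sample1 == segments$sample2, "hbd", "ibd")
    pop <- as.character(grouping[segments$sample1])
    pop2 <- as.character(grouping[segments$sample2])
    intra <- pop == pop2
    bi <- findInterval(segments$length_cm, bins)
    for (r in which(intra & bi >= 1)) {
      gi <- which(grid$population == pop[r] & grid$type == type[r] &
                  grid$bin == labs[bi[r]])
      grid$n_segments[gi] <- grid$n_segments[gi] + 1L
      grid$mean_cm[gi] <- grid$mean_cm[gi] + segments$length_cm[r]
    }
  }
  grid$mean_cm <- ifelse(grid$n_segments > 0,
                         grid$mean_cm / grid$n_segments, 0)
  nn <- as.numeric(sizes[grid$population])
  denom <- ifelse(grid$type == "ibd", nn * (nn - 1) / 2, nn)
  grid$avg_count <- ifelse(denom > 0, grid$n_segments / denom, 0)
  grid
}
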