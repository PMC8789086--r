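#' Allele-sharing correlation decay curve
#'
#' For pairs of individuals, the per-SNP allele-sharing indicator is
#' `(g_i - 1)(g_j - 1)` (1 for identical homozygotes, -1 for opposite
#' homozygotes, 0 when either is heterozygous). Indicators are centered per
#' SNP across pairs and the average product over SNP pairs, binned by cM
#' separation within chromosomes, gives the within-population curve; the
#' same quantity for focal-versus-outgroup pairs gives the cross curve, and
#' the corrected curve is their difference (removing ancestral sharing).
#'
#' @param panel A `genotype_panel`.
#' @param focal_population Population whose founder history is probed
#'   (needs at least 5 samples).
#' @param outgroup_samples Sample ids used as the outgroup panel.
#' @param max_cm Maximum SNP-pair separation (default 30).
#' @param bin_cm Bin width (default 0.1).
#' @return A `decay_curve`: data frame (`bin_cm`, `within`, `cross`,
#'   `corrected`, `n_pairs`) with per-chromosome curves in attribute
#'   `per_chrom` for block bootstraps.
#' @export
allele_sharing_decay <- function(panel, focal_population, outgroup_samples,
                                 max_cm = 30, bin_cm = 0.1) {
  foc <- which(panel$sample_table$population == focal_population)
  if (length(foc) < 5)
    stop("focal population needs at least 5 unrelated samples (got ",
         length(foc), ")")
  outg <- match(outgroup_samples, panel$sample_ids)
  if (anyNA(outg)) stop("unknown outgroup sample id")
  g <- panel$genotypes
  sharing_rows <- function(pairs_i, pairs_j) {
    x <- (g[pairs_i, , drop = FALSE] - 1) * (g[pairs_j, , drop = FALSE] - 1)
    x[is.na(x)] <- 0
    x
  }
  wi <- utils::combn(foc, 2)
  Xw <- sharing_rows(wi[1, ], wi[2, ])
  cr <- expand.grid(i = foc, j = outg)
  cr <- cr[cr$i != cr$j, ]
  Xc <- sharing_rows(cr$i, cr$j)
  st <- panel$snp_table
  nb <- round(max_cm / bin_cm)
  centers <- (seq_len(nb) - 0.5) * bin_cm
  per_chrom <- list()
  for (ch in unique(st$chrom)) {
    idx <- which(st$chrom == ch)
    cm <- st$cm[idx]
    bin_curve <- function(X) {
      Xc0 <- sweep(X[, idx, drop = FALSE], 2, colMeans(X[, idx, drop = FALSE]))
      C <- crossprod(Xc0) / nrow(Xc0)
      ut <- which(upper.tri(C), arr.ind = TRUE)
      d <- cm[ut[, 2]] - cm[ut[, 1]]
      sel <- d > 0 & d <= max_cm
      b <- pmin(nb, floor(d[sel] / bin_cm) + 1L)
      v <- C[ut][sel]
      sums <- tapply(v, factor(b, levels = seq_len(nb)), sum)
      cnts <- tapply(rep(1, length(v)), factor(b, levels = seq_len(nb)), sum)
      sums[is.na(sums)] <- 0; cnts[is.na(cnts)] <- 0
      list(sum = as.vector(sums), n = as.vector(cnts))
    }
    w <- bin_curve(Xw); cx <- bin_curve(Xc)
    per_chrom[[as.character(ch)]] <- list(within_sum = w$sum, n = w$n,
                                          cross_sum = cx$sum)
  }
  tot_n <- Reduce(`+`, lapply(per_chrom, `[[`, "n"))
  within <- Reduce(`+`, lapply(per_chrom, `[[`, "within_sum")) / pmax(tot_n, 1)
  cross <- Reduce(`+`, lapply(per_chrom, `[[`, "cross_sum")) / pmax(tot_n, 1)
  out <- data.frame(bin_cm = centers, within = within, cross = cross,
                    corrected = within - cross, n_pairs = tot_n)
  attr(out, "per_chrom") <- per_chrom
  class(out) <- c("decay_curve", "data.frame")
  out
}

fit_decay_exponential <- function(d, y, w) {
  c0 <- mean(y[d >= stats::quantile(d, 0.8)])
  a0 <- max(mean(y[seq_len(max(3, round(length(y) * 0.05)))]) - c0, 1e-5)
  pos <- y - c0 > a0 / 20 & d < stats::median(d)
  fa0 <- if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(y[pos] - c0) ~ d[pos]))[2]
    min(max(-sl / 2, 1), 300)
  } else 20
  fit <- try(minpack.lm::nlsLM(
    y ~ A * exp(-2 * FA * d) + C,
    start = list(A = a0, FA = fa0, C = c0),
    lower = c(0, 0.1, -Inf), upper = c(1, 1000, Inf),
    weights = w, control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  as.list(stats::coef(fit))
}

#' Fit a founder event to a decay curve
#'
#' Weighted nonlinear least squares of
#' `corrected(d) = A exp(-2 FA d) + c` with d in morgans: FA is the founder
#' age in generations and the founder intensity FI is the fitted
#' zero-distance amplitude A expressed in percent. Confidence intervals
#' come from a block bootstrap over chromosomes, with the interval formed
#' as `estimate +/- t(B-1, 0.975) x bootstrap SD` (B = chromosome blocks):
#' raw bootstrap percentiles undercover at the block counts typical of
#' array data.
#'
#' @param curve A `decay_curve` with at least 20 bins.
#' @param bootstrap_n Bootstrap resamples (default 100).
#' @param seed Bootstrap seed.
#' @param years_per_generation Generation interval (default 28).
#' @return A `founder_event`: list with `fa_generations`, `fa_years`,
#'   `fi_percent`, 95% CIs, `converged`, and `flagged` (non-convergence or
#'   unidentifiable FA when A is indistinguishable from 0).
#' @export
fit_founder_event <- function(curve, bootstrap_n = 100, seed = 1,
                              years_per_generation = 28) {
  if (nrow(curve) < 20) stop("decay curve needs at least 20 bins")
  d <- curve$bin_cm / 100
  est <- fit_decay_exponential(d, curve$corrected, curve$n_pairs)
  per_chrom <- attr(curve, "per_chrom")
  boots <- NULL
  if (!is.null(est) && !is.null(per_chrom) && length(per_chrom) >= 2) {
    set.seed(seed)
    chs <- names(per_chrom)
    boots <- t(vapply(seq_len(bootstrap_n), function(b) {
      take <- sample(chs, length(chs), replace = TRUE)
      n <- Reduce(`+`, lapply(per_chrom[take], `[[`, "n"))
      wsum <- Reduce(`+`, lapply(per_chrom[take], `[[`, "within_sum"))
      csum <- Reduce(`+`, lapply(per_chrom[take], `[[`, "cross_sum"))
      y <- (wsum - csum) / pmax(n, 1)
      e <- fit_decay_exponential(d, y, n)
      if (is.null(e)) c(NA_real_, NA_real_) else c(e$FA, 100 * e$A)
    }, numeric(2)))
  }
  flagged <- NULL
  if (is.null(est)) {
    return(structure(list(fa_generations = NA, fa_years = NA,
                          fi_percent = NA, converged = FALSE,
                          flagged = "non-convergence"),
                     class = "founder_event"))
  }
  resid_sd <- stats::sd(curve$corrected - (est$A * exp(-2 * est$FA * d) + est$C))
  if (est$A < 2 * resid_sd / sqrt(nrow(curve)) || est$A < 1e-6)
    flagged <- "amplitude ~ 0: founder age unidentifiable"
  n_blocks <- length(per_chrom)
  ci <- function(k, center) {
    if (is.null(boots)) return(c(NA, NA))
    hw <- stats::qt(0.975, max(n_blocks - 1, 1)) * stats::sd(boots[, k],
                                                             na.rm = TRUE)
    c(max(center - hw, 0), center + hw)
  }
  structure(list(fa_generations = est$FA,
                 fa_years = est$FA * years_per_generation,
                 fi_percent = 100 * est$A,
                 baseline = est$C,
                 fa_ci = ci(1, est$FA), fi_ci = ci(2, 100 * est$A),
                 converged = TRUE, flagged = flagged,
                 n_boot_ok = if (is.null(boots)) 0 else sum(!is.na(boots[, 1]))),
            class = "founder_event")
}

#' @export
print.founder_event <- function(x, ...) {
  if (!x$converged) { cat("founder_event: fit did not converge\n"); return(invisible(x)) }
  cat(sprintf("founder_event: FA = %.1f generations (%.0f y), FI = %.2f%%\n",
              x$fa_generations, x$fa_years, x$fi_percent))
  if (!is.null(x$flagged)) cat("  flagged:", x$flagged, "\n")
  invisible(x)
}

# P(coalescence at generation g) for a haplotype pair under piecewise N(g),
# extended at the final value beyond the supplied horizon.
coalescence_probs <- function(ne, g_max) {
  ne_ext <- c(ne, rep(ne[length(ne)], max(0, g_max - length(ne))))[seq_len(g_max)]
  rate <- 1 / (2 * ne_ext)
  surv <- cumprod(1 - rate)
  p <- rate * c(1, surv[-g_max])
  p
}

#' Expected IBD segment counts per length bin
#'
#' Closed-form forward model: a pair coalescing at generation g accumulates
#' crossover breakpoints as a Poisson process of rate 2g per morgan, so on
#' a genome of G morgans the expected number of maximal segments longer
#' than u is `(2 g (G - u) + 1) exp(-2 g u)` (the exact finite-interval
#' form; for G >> u this is the familiar `(2 g G + 1) exp(-2 g u)`). Bin
#' expectations follow by differencing, weighted by the coalescence
#' probabilities implied by the N_e trajectory. (Validated against the
#' breakpoint-scattering oracle [simulate_ibd_breakpoints()].)
#'
#' @param ne Per-generation diploid N_e (generation 1 = most recent);
#'   extended at its final value beyond the horizon.
#' @param genome_morgans Total map length G in morgans.
#' @param length_bins_cm Bin edges in cM (last bin extends to infinity).
#' @param n_pairs Number of haplotype pairs (default 1).
#' @param g_max Generations over which coalescence mass is accumulated
#'   (default: enough for the shortest bin, capped at 5000).
#' @return Numeric vector of expected counts, one per bin.
#' @export
expected_ibd_spectrum <- function(ne, genome_morgans, length_bins_cm,
                                  n_pairs = 1, g_max = NULL) {
  stopifnot(all(ne > 0))
  u <- length_bins_cm / 100
  if (is.null(g_max)) {
    g_max <- length(ne)
    while (g_max < 5000 &&
           (2 * g_max * genome_morgans + 1) * exp(-2 * g_max * u[1]) > 1e-6)
      g_max <- g_max + 50
  }
  p <- coalescence_probs(ne, g_max)
  tail_contrib <- (1 - sum(p)) * (2 * g_max * genome_morgans + 1) *
    exp(-2 * g_max * u[1])
  if (tail_contrib > 1e-3)
    warning("horizon captures < 99% of relevant coalescence mass")
  gg <- seq_len(g_max)
  ev_gt <- outer(gg, u, function(g, uu)
    ifelse(uu < genome_morgans,
           (2 * g * (genome_morgans - uu) + 1) * exp(-2 * g * uu), 0))
  per_g <- cbind(ev_gt[, -1, drop = FALSE], 0)
  bin_e <- ev_gt - per_g                       # count in [u_k, u_{k+1})
  n_pairs * as.vector(p %*% bin_e)
}

#' Breakpoint-scattering oracle for the IBD spectrum
#'
#' Generative simulation of the same model as
#' [expected_ibd_spectrum()]: each pair draws a coalescence generation g
#' from the trajectory's coalescence distribution, scatters
#' `Poisson(2 g G)` crossover breakpoints uniformly on a genome of G
#' morgans, and the resulting maximal tracts are the pair's IBD segments.
#'
#' @param ne Per-generation diploid N_e as in [expected_ibd_spectrum()].
#' @param genome_morgans Genome length G in morgans.
#' @param n_pairs Number of haplotype pairs.
#' @param seed Random seed.
#' @param g_max Horizon for the coalescence draw (default as in the closed
#'   form).
#' @return Data frame with `pair` and `length_cm` of every segment.
#' @export
simulate_ibd_breakpoints <- function(ne, genome_morgans, n_pairs, seed,
                                     g_max = NULL) {
  set.seed(seed)
  if (is.null(g_max)) g_max <- min(5000, max(length(ne) * 20, 1000))
  p <- coalescence_probs(ne, g_max)
  gs <- sample.int(g_max, n_pairs, replace = TRUE, prob = p)
  out <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    k <- stats::rpois(1, 2 * gs[i] * genome_morgans)
    br <- sort(stats::runif(k, 0, genome_morgans))
    len <- diff(c(0, br, genome_morgans))
    out[[i]] <- data.frame(pair = i, length_cm = len * 100)
  }
  do.call(rbind, out)
}

#' Sample an IBD segment set from the spectrum model
#'
#' Draws per-pair, per-bin Poisson counts at the closed-form expectations
#' (segment lengths are placed uniformly within their bin); a fast
#' generative sampler for parameter-recovery studies of
#' [fit_ne_history()].
#'
#' @param ne,genome_morgans,length_bins_cm,n_pairs,g_max As in
#'   [expected_ibd_spectrum()].
#' @param seed Random seed.
#' @return Data frame with `pair` and `length_cm`.
#' @export
sample_ibd_spectrum <- function(ne, genome_morgans, length_bins_cm, n_pairs,
                                seed, g_max = NULL) {
  set.seed(seed)
  lam <- expected_ibd_spectrum(ne, genome_morgans, length_bins_cm,
                               n_pairs = 1, g_max = g_max)
  nb <- length(lam)
  lo <- length_bins_cm
  hi <- c(length_bins_cm[-1], length_bins_cm[nb] * 1.5)
  out <- list()
  for (b in seq_len(nb)) {
    cnt <- stats::rpois(n_pairs, lam[b])
    tot <- sum(cnt)
    if (tot == 0) next
    out[[b]] <- data.frame(pair = rep(seq_len(n_pairs), cnt),
                           length_cm = stats::runif(tot, lo[b], hi[b]))
  }
  if (!length(out)) return(data.frame(pair = integer(0), length_cm = numeric(0)))
  do.call(rbind, out)
}

#' Fit an N_e history to an IBD length spectrum
#'
#' Piecewise-constant diploid N_e on log-spaced epochs over the horizon,
#' chosen to minimize the Poisson deviance between observed and expected
#' length-bin counts (forward model [expected_ibd_spectrum()]) with a
#' smoothness penalty on adjacent log-N_e; confidence band by bootstrap
#' over pairs.
#'
#' @param segments Data frame with `length_cm` and a pair identifier
#'   (`pair`, or `sample1`/`sample2` from which one is built).
#' @param n_pairs Number of haplotype pairs the segments were called from.
#' @param genome_morgans Genome length G in morgans.
#' @param horizon_generations Horizon (default 100).
#' @param n_epochs Number of log-spaced epochs (default 10).
#' @param length_bins_cm Bin edges (default `c(2,3,4,5,6,8,10,14,18,24,32,45,60)`).
#' @param lambda Smoothness penalty weight (default 1).
#' @param bootstrap_n Bootstrap resamples (default 100; 0 disables).
#' @param seed Seed for the bootstrap.
#' @param filter_related Set `FALSE` to declare that related pairs were
#'   retained; a bias note for the most recent generations is recorded.
#' @return An `ne_trajectory`: `generations`, `ne`, `ci_low`/`ci_high`,
#'   epoch structure, observed and fitted counts, and `flags`.
#' @export
fit_ne_history <- function(segments, n_pairs, genome_morgans,
                           horizon_generations = 100, n_epochs = 10,
                           length_bins_cm = c(2, 3, 4, 5, 6, 8, 10, 14, 18,
                                              24, 32, 45, 60),
                           lambda = 1, bootstrap_n = 100, seed = 1,
                           filter_related = TRUE) {
  if (is.null(segments$pair))
    segments$pair <- paste(segments$sample1, segments$sample2, sep = "|")
  flags <- character(0)
  if (nrow(segments) < 50)
    flags <- c(flags, "fewer than 50 segments: low-confidence fit")
  if (!filter_related)
    flags <- c(flags, paste("related pairs retained: estimates for the most",
                            "recent generations are expected to be",
                            "particularly biased"))
  nb <- length(length_bins_cm)
  count_bins <- function(seg) {
    bi <- findInterval(seg$length_cm, length_bins_cm)
    tabulate(bi[bi >= 1], nbins = nb)
  }
  obs <- count_bins(segments)
  edges <- unique(round(exp(seq(0, log(horizon_generations + 1),
                                length.out = n_epochs + 1))))
  epoch_of <- findInterval(seq_len(horizon_generations), edges,
                           rightmost.closed = TRUE)
  epoch_of[epoch_of > length(edges) - 1] <- length(edges) - 1
  ne_of <- function(theta) exp(pmin(pmax(theta, log(2)), log(1e8)))[epoch_of]
  objective <- function(theta, o) {
    e <- expected_ibd_spectrum(ne_of(theta), genome_morgans, length_bins_cm,
                               n_pairs = n_pairs)
    e <- pmax(e, 1e-9)
    dev <- 2 * sum(e - o + ifelse(o > 0, o * log(o / e), 0))
    dev + lambda * sum(diff(theta)^2)
  }
  fit_once <- function(o, inits) {
    best <- NULL
    for (th0 in inits) {
      f <- try(stats::optim(th0, objective, o = o, method = "BFGS",
                            control = list(maxit = 300)), silent = TRUE)
      if (inherits(f, "try-error")) next
      if (is.null(best) || f$value < best$value) best <- f
    }
    best
  }
  nep <- length(edges) - 1
  inits <- list(rep(log(500), nep), rep(log(5000), nep))
  fit <- fit_once(obs, inits)
  if (is.null(fit)) stop("N_e optimization failed")
  ne_hat <- ne_of(fit$par)
  ci_low <- ci_high <- rep(NA_real_, horizon_generations)
  if (bootstrap_n > 0) {
    set.seed(seed)
    upairs <- unique(segments$pair)
    # pairs with no segments must be resampled too
    n_empty <- max(0, n_pairs - length(upairs))
    seg_by_pair <- split(segments$length_cm, segments$pair)
    bt <- matrix(NA_real_, bootstrap_n, horizon_generations)
    for (b in seq_len(bootstrap_n)) {
      take <- sample.int(length(upairs) + n_empty, n_pairs, replace = TRUE)
      take <- take[take <= length(upairs)]
      lens <- unlist(seg_by_pair[upairs[take]], use.names = FALSE)
      ob <- if (length(lens))
        count_bins(data.frame(length_cm = lens)) else rep(0L, nb)
      fb <- fit_once(ob, list(fit$par))
      if (!is.null(fb)) bt[b, ] <- ne_of(fb$par)
    }
    ci_low <- apply(bt, 2, stats::quantile, 0.025, na.rm = TRUE)
    ci_high <- apply(bt, 2, stats::quantile, 0.975, na.rm = TRUE)
  }
  fitted <- expected_ibd_spectrum(ne_hat, genome_morgans, length_bins_cm,
                                  n_pairs = n_pairs)
  structure(list(generations = seq_len(horizon_generations), ne = ne_hat,
                 ci_low = ci_low, ci_high = ci_high,
                 epoch_edges = edges, theta = fit$par,
                 observed_counts = obs, fitted_counts = fitted,
                 length_bins_cm = length_bins_cm, flags = flags),
            class = "ne_trajectory")
}

#' Percent change of an N_e trajectory over a window
#'
#' `100 (N_e(from) - N_e(to)) / N_e(from)`: positive values are declines
#' toward the present, growth is reported as a negative reduction.
#'
#' @param traj An `ne_trajectory` (or list with `generations` and `ne`).
#' @param from_gen,to_gen Generations before present bounding the window
#'   (`from_gen` the older).
#' @return Percent change (scalar).
#' @export
trajectory_change <- function(traj, from_gen, to_gen) {
  i <- match(from_gen, traj$generations)
  j <- match(to_gen, traj$generations)
  if (is.na(i) || is.na(j)) stop("generation outside trajectory horizon")
  100 * (traj$ne[i] - traj$ne[j]) / traj$ne[i]
}
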