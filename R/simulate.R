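#' Specify a demographic model for the forward simulator
#'
#' @param demes Named integer vector of diploid deme sizes at founding
#'   (demes created later by `split` events are declared in the event).
#' @param chromosomes Data frame with columns `chrom`, `length_cm`,
#'   `n_snps`; SNPs are placed evenly along the genetic map with bp =
#'   cM x 1e6.
#' @param n_generations Number of discrete Wright-Fisher generations to
#'   simulate forward from the founder generation.
#' @param fst Balding-Nichols differentiation parameter used to draw
#'   per-deme founder allele frequencies around the ancestral frequency
#'   (0 = identical founder frequencies in all demes).
#' @param p_anc_range Range of the uniform ancestral allele-frequency draw.
#' @param events List of event lists, each with a `type` field:
#'   \describe{
#'     \item{bottleneck}{`deme`, `start_gen`, `duration`, `size` - the deme
#'       reproduces through `size` diploids for `duration` generations
#'       starting at `start_gen`.}
#'     \item{admixture}{`source`, `target`, `fraction`, `generation` - at
#'       that generation each gamete of the target deme is drawn from the
#'       source deme with probability `fraction`.}
#'     \item{split}{`parent`, `child`, `generation`, `size`, optional
#'       `founders` - a new deme of `size` diploids is founded at
#'       `generation` from gametes of the parent deme; when `founders` is
#'       given, only that many randomly chosen parent individuals
#'       contribute gametes (a founder event at the split).}
#'   }
#' @param migration Optional data frame (`from`, `to`, `rate`): per
#'   generation, each gamete of deme `to` is drawn from deme `from` with
#'   probability `rate`.
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(demes,
                              chromosomes = data.frame(chrom = "1",
                                                       length_cm = 100,
                                                       n_snps = 5000),
                              n_generations = 10,
                              fst = 0.05,
                              p_anc_range = c(0.05, 0.95),
                              events = list(),
                              migration = NULL) {
  stopifnot(length(demes) >= 1, all(demes >= 2), !is.null(names(demes)))
  for (ev in events) {
    stopifnot(is.list(ev), !is.null(ev$type))
    if (ev$type == "admixture")
      stopifnot(ev$fraction > 0, ev$fraction < 1, ev$generation >= 0)
    if (ev$type == "bottleneck")
      stopifnot(ev$size >= 2, ev$start_gen >= 0, ev$duration >= 1)
    if (ev$type == "split") stopifnot(ev$size >= 2, ev$generation >= 1)
  }
  structure(list(demes = demes, chromosomes = as.data.frame(chromosomes),
                 n_generations = as.integer(n_generations), fst = fst,
                 p_anc_range = p_anc_range, events = events,
                 migration = migration),
            class = "demographic_model")
}

# Per-chromosome SNP layout used by the recombination machinery.
chrom_layout <- function(snp_table, length_cm = NULL) {
  chs <- unique(snp_table$chrom)
  lapply(stats::setNames(chs, chs), function(ch) {
    idx <- which(snp_table$chrom == ch)
    cm <- snp_table$cm[idx]
    list(idx = idx, cm = cm,
         L = if (is.null(length_cm)) max(cm) else length_cm[[as.character(ch)]])
  })
}

# One recombinant gamete from a pair of haplotype rows (vectors over all
# SNPs); crossovers are a Poisson process on the cM map, no interference.
# Returns the logical selector of sites copied from the second haplotype.
gamete_take2 <- function(layout) {
  sel <- logical(sum(vapply(layout, function(x) length(x$idx), integer(1))))
  for (ly in layout) {
    k <- stats::rpois(1L, ly$L / 100)
    start <- sample.int(2L, 1L) - 1L
    if (k == 0L) {
      if (start == 1L) sel[ly$idx] <- TRUE
    } else {
      breaks <- sort(stats::runif(k, 0, ly$L))
      phase <- (start + findInterval(ly$cm, breaks)) %% 2L
      sel[ly$idx] <- phase == 1L
    }
  }
  sel
}

#' Forward Wright-Fisher simulation of a structured population
#'
#' Discrete-generation diploid forward simulation with Poisson crossovers on
#' the genetic map (no interference). Founder haplotypes are drawn site-wise
#' from per-deme Balding-Nichols allele frequencies around a uniform
#' ancestral frequency; deme-of-origin ancestry labels are propagated
#' through admixture pulses, migration and splits, so sampled haplotypes
#' carry exact ancestry tracts. Output is fully phased and reproducible
#' under `seed`.
#'
#' @param model A `demographic_model`.
#' @param n_samples_per_deme Scalar or named vector of diploid sample sizes
#'   drawn (without replacement) from the final generation of each deme.
#' @param seed Integer random seed (mandatory).
#' @param track_ancestry Propagate founder-deme labels and return ancestry
#'   tracts (default `TRUE`; disable to halve simulation cost when tracts
#'   are not needed).
#' @return A list with `panel` (phased `genotype_panel`; `population` is the
#'   deme name) and `truth` (list with `tracts`: per-haplotype ancestry
#'   intervals, when tracked).
#' @export
simulate_panel <- function(model, n_samples_per_deme, seed,
                           track_ancestry = TRUE) {
  stopifnot(inherits(model, "demographic_model"), !missing(seed))
  set.seed(seed)
  chrs <- model$chromosomes
  snp_table <- do.call(rbind, lapply(seq_len(nrow(chrs)), function(i) {
    n <- chrs$n_snps[i]
    cm <- chrs$length_cm[i] * (seq_len(n) - 0.5) / n
    data.frame(chrom = as.character(chrs$chrom[i]),
               pos = as.integer(round(cm * 1e6)), cm = cm,
               ref = "A", alt = "G",
               id = paste0(chrs$chrom[i], "_", seq_len(n)),
               stringsAsFactors = FALSE)
  }))
  S <- nrow(snp_table)
  layout <- chrom_layout(snp_table,
                         stats::setNames(chrs$length_cm, as.character(chrs$chrom)))

  p_anc <- stats::runif(S, model$p_anc_range[1], model$p_anc_range[2])
  deme_names <- names(model$demes)
  splits <- Filter(function(e) e$type == "split", model$events)
  all_names <- c(deme_names, vapply(splits, `[[`, character(1), "child"))
  if (anyDuplicated(all_names)) stop("duplicate deme names across splits")

  # Internal state is SNPs x haplotypes (columns contiguous per haplotype).
  found_deme <- function(N, label) {
    p <- if (model$fst <= 0) p_anc else {
      F <- model$fst
      stats::rbeta(S, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    }
    H <- matrix(stats::rbinom(S * 2L * N, 1L, rep(p, times = 2L * N)), S, 2L * N)
    storage.mode(H) <- "integer"
    A <- if (track_ancestry) matrix(label, S, 2L * N) else NULL
    list(H = H, A = A, N = N)
  }
  state <- list()
  for (d in deme_names)
    state[[d]] <- found_deme(model$demes[[d]], match(d, all_names))

  size_at <- function(d, g) {
    N <- if (d %in% deme_names) model$demes[[d]] else
      Filter(function(e) e$type == "split" && e$child == d, model$events)[[1]]$size
    for (ev in model$events)
      if (ev$type == "bottleneck" && ev$deme == d &&
          g >= ev$start_gen && g < ev$start_gen + ev$duration) N <- ev$size
    if (N < 1) stop("population size 0 for deme ", d)
    N
  }

  # 2N gametes, grouped by source deme, block-copied when no crossover fell
  # on a chromosome and spliced column-wise otherwise.
  reproduce <- function(sources, N) {
    Hn <- matrix(0L, S, 2L * N)
    An <- if (track_ancestry) matrix(0L, S, 2L * N) else NULL
    for (sd in unique(sources)) {
      src <- state[[sd]]
      cols <- which(sources == sd)
      m <- length(cols)
      par <- sample.int(src$N, m, replace = TRUE)
      hap1 <- 2L * par - 1L
      for (ly in layout) {
        idx <- ly$idx
        k <- stats::rpois(m, ly$L / 100)
        start <- sample.int(2L, m, replace = TRUE) - 1L
        plain <- k == 0L
        if (any(plain)) {
          from <- hap1[plain] + start[plain]
          Hn[idx, cols[plain]] <- src$H[idx, from]
          if (track_ancestry) An[idx, cols[plain]] <- src$A[idx, from]
        }
        for (j in which(!plain)) {
          breaks <- sort(stats::runif(k[j], 0, ly$L))
          phase <- (start[j] + findInterval(ly$cm, breaks)) %% 2L
          rows1 <- idx[phase == 0L]; rows2 <- idx[phase == 1L]
          Hn[rows1, cols[j]] <- src$H[rows1, hap1[j]]
          Hn[rows2, cols[j]] <- src$H[rows2, hap1[j] + 1L]
          if (track_ancestry) {
            An[rows1, cols[j]] <- src$A[rows1, hap1[j]]
            An[rows2, cols[j]] <- src$A[rows2, hap1[j] + 1L]
          }
        }
      }
    }
    list(H = Hn, A = An, N = N)
  }

  gamete_sources <- function(d, g) {
    N <- size_at(d, g)
    sources <- rep(d, 2L * N)
    pulls <- list()
    for (ev in model$events)
      if (ev$type == "admixture" && ev$target == d && ev$generation == g)
        pulls[[length(pulls) + 1L]] <- list(p = ev$fraction, src = ev$source)
    if (!is.null(model$migration))
      for (k in seq_len(nrow(model$migration)))
        if (model$migration$to[k] == d)
          pulls[[length(pulls) + 1L]] <- list(p = model$migration$rate[k],
                                              src = model$migration$from[k])
    if (length(pulls)) {
      u <- stats::runif(2L * N)
      lo <- 0
      for (pl in pulls) {
        sources[u >= lo & u < lo + pl$p] <- pl$src
        lo <- lo + pl$p
      }
    }
    list(sources = sources, N = N)
  }

  for (g in seq_len(model$n_generations)) {
    for (ev in model$events)
      if (ev$type == "split" && ev$generation == g) {
        if (!is.null(ev$founders) && ev$founders < state[[ev$parent]]$N) {
          pool <- state[[ev$parent]]
          take <- sort(sample.int(pool$N, ev$founders))
          cols <- as.vector(rbind(2L * take - 1L, 2L * take))
          fkey <- paste0(".founders_", ev$child)
          state[[fkey]] <- list(H = pool$H[, cols, drop = FALSE],
                                A = if (track_ancestry)
                                      pool$A[, cols, drop = FALSE] else NULL,
                                N = ev$founders)
          state[[ev$child]] <- reproduce(rep(fkey, 2L * ev$size), ev$size)
          state[[fkey]] <- NULL
        } else {
          state[[ev$child]] <- reproduce(rep(ev$parent, 2L * ev$size),
                                         ev$size)
        }
      }
    new_state <- state
    for (d in names(state)) {
      created <- Filter(function(e) e$type == "split" && e$child == d,
                        model$events)
      if (length(created) && created[[1]]$generation == g) next
      gs <- gamete_sources(d, g)
      new_state[[d]] <- reproduce(gs$sources, gs$N)
    }
    state <- new_state
  }

  if (length(n_samples_per_deme) == 1 && is.null(names(n_samples_per_deme)))
    n_samples_per_deme <- stats::setNames(
      rep(n_samples_per_deme, length(state)), names(state))
  Hcols <- list(); Acols <- list(); ids <- character(0); pops <- character(0)
  for (d in names(state)) {
    ns <- n_samples_per_deme[[d]]
    if (is.null(ns) || ns == 0) next
    if (ns > state[[d]]$N) stop("requested more samples than deme size for ", d)
    take <- sort(sample.int(state[[d]]$N, ns))
    cols <- as.vector(rbind(2L * take - 1L, 2L * take))
    Hcols[[d]] <- state[[d]]$H[, cols, drop = FALSE]
    if (track_ancestry) Acols[[d]] <- state[[d]]$A[, cols, drop = FALSE]
    ids <- c(ids, sprintf("%s_%03d", d, seq_len(ns)))
    pops <- c(pops, rep(d, ns))
  }
  H <- t(do.call(cbind, Hcols))                     # haplotypes x SNPs
  n <- length(ids)
  geno <- H[seq(1L, 2L * n, 2L), , drop = FALSE] +
          H[seq(2L, 2L * n, 2L), , drop = FALSE]
  sample_table <- data.frame(id = ids, population = pops, major_group = pops,
                             lat = NA_real_, lon = NA_real_,
                             stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, snp_table, sample_table, haplotypes = H)

  truth <- list()
  if (track_ancestry) {
    A <- t(do.call(cbind, Acols))
    tr <- lapply(seq_len(nrow(A)), function(r) {
      samp <- ids[(r + 1L) %/% 2L]; hapno <- 2L - r %% 2L
      do.call(rbind, lapply(layout, function(ly) {
        rl <- rle(A[r, ly$idx])
        e <- cumsum(rl$lengths); s <- c(1L, e[-length(e)] + 1L)
        data.frame(sample = samp, hap = hapno,
                   chrom = snp_table$chrom[ly$idx[1]],
                   start_bp = snp_table$pos[ly$idx[s]],
                   end_bp = snp_table$pos[ly$idx[e]],
                   start_cm = ly$cm[s], end_cm = ly$cm[e],
                   deme = all_names[rl$values],
                   stringsAsFactors = FALSE)
      }))
    })
    tracts <- do.call(rbind, tr)
    rownames(tracts) <- NULL
    truth$tracts <- tracts
  }
  list(panel = panel, truth = truth)
}
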