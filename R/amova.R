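#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Four-level genotypic AMOVA on allele-count distances: haplotypes nested
#' in individuals, nested in populations, nested in (linguistic) groups.
#' Unphased genotypes are expanded into allele pairs (the squared
#' allele-difference distance does not depend on phase). Sums of squared
#' deviations are computed from pairwise squared distances within each
#' stratum; variance components solve the standard nested method-of-moments
#' equations with unequal sizes, and Phi-statistics and permutation
#' p-values are computed per level with the level-appropriate scheme:
#' whole populations among groups, individuals among populations within
#' groups, haplotypes among individuals within populations.
#'
#' @param panel A `genotype_panel`.
#' @param hierarchy Data frame with columns `id`, `population`, `group`;
#'   defaults to the panel's `population` / `major_group` columns.
#' @param n_perm Permutations per level (default 999).
#' @param seed Permutation seed.
#' @return An `amova_result`: components table (sigma, raw and truncated
#'   percentages), Phi-statistics, p-values, df, and the permutation
#'   counts; untestable levels are flagged.
#' @export
amova <- function(panel, hierarchy = NULL, n_perm = 999, seed = 1) {
  if (is.null(hierarchy))
    hierarchy <- data.frame(id = panel$sample_table$id,
                            population = panel$sample_table$population,
                            group = panel$sample_table$major_group,
                            stringsAsFactors = FALSE)
  i <- match(panel$sample_ids, hierarchy$id)
  if (anyNA(i)) stop("hierarchy does not cover all samples")
  pop <- as.character(hierarchy$population[i])
  grp <- as.character(hierarchy$group[i])
  if (length(unique(grp)) < 2) stop("need at least 2 groups")
  pops_per_group <- tapply(pop, grp, function(x) length(unique(x)))
  if (!any(pops_per_group >= 2))
    warning("no group contains 2 populations: among-population level untestable")

  # haplotype expansion: allele matrix (2n x S); the allele order of
  # heterozygotes is randomized so neither pseudo-haplotype is systematically
  # ALT-enriched (phase is irrelevant to the distances themselves)
  set.seed(seed)
  g <- panel$genotypes
  n <- nrow(g)
  A1 <- ifelse(g >= 1L, 1L, 0L); A2 <- ifelse(g == 2L, 1L, 0L)
  het <- !is.na(g) & g == 1L
  flip <- matrix(stats::runif(length(g)) < 0.5, nrow(g), ncol(g)) & het
  A1[flip] <- 0L; A2[flip] <- 1L
  A1[is.na(g)] <- NA; A2[is.na(g)] <- NA
  X <- matrix(NA_integer_, 2L * n, ncol(g))
  X[seq(1L, 2L * n, 2L), ] <- A1
  X[seq(2L, 2L * n, 2L), ] <- A2
  # squared allele-count distance summed over loci (missing -> locus skipped
  # for that pair, rescaled by the number of complete loci)
  M <- X; M[is.na(M)] <- 0
  obs <- !is.na(X) + 0
  cross <- tcrossprod(M)
  nobs <- tcrossprod(obs)
  sq <- tcrossprod(M^2, obs)
  D2 <- sq + t(sq) - 2 * cross
  D2 <- D2 * ncol(g) / pmax(nobs, 1)

  hap_ind <- rep(seq_len(n), each = 2)
  hap_pop <- pop[hap_ind]
  hap_grp <- grp[hap_ind]

  ss_within <- function(cl) {
    cl <- as.character(cl)
    B <- rowsum(D2, cl)                    # cluster x hap block row sums
    BB <- rowsum(t(B), cl)                 # cluster x cluster block sums
    sz <- table(cl)[rownames(BB)]
    sum(diag(BB) / (2 * as.numeric(sz)))
  }
  components <- function(hap_pop, hap_grp) {
    N <- length(hap_ind)
    ss_tot <- sum(D2) / (2 * N)
    ss_wg <- ss_within(hap_grp)
    ss_wp <- ss_within(hap_pop)
    ss_wi <- ss_within(hap_ind)
    ss <- c(ag = ss_tot - ss_wg, ap = ss_wg - ss_wp,
            ai = ss_wp - ss_wi, wi = ss_wi)
    # E[SS_within(level)] coefficient rows over (s_wi, s_ai, s_ap, s_ag);
    # closed forms using the fact that every individual has 2 haplotypes
    np <- table(hap_pop); ng <- table(hap_grp)
    grp_of <- tapply(hap_grp, hap_pop, function(x) x[1])
    n_grp <- length(ng); n_pop <- length(np); n_indv <- N / 2
    gp <- as.character(grp_of[names(np)])
    s2g <- tapply(as.numeric(np)^2, gp, sum)  # per-group sum of pop sizes^2
    T3 <- sum(s2g / as.numeric(ng[names(s2g)]))
    row_tot <- c(N - 1, N - 2, N - sum(np^2) / N, N - sum(ng^2) / N)
    row_wg <- c(N - n_grp, N - 2 * n_grp, N - T3, 0)
    row_wp <- c(N - n_pop, N - 2 * n_pop, 0, 0)
    row_wi <- c(N - n_indv, 0, 0, 0)
    Mm <- rbind(ag = row_tot - row_wg, ap = row_wg - row_wp,
                ai = row_wp - row_wi, wi = row_wi)
    comp_names <- c("within_individuals", "among_individuals",
                    "among_populations", "among_groups")
    dfs <- c(ag = n_grp - 1, ap = n_pop - n_grp, ai = n_indv - n_pop,
             wi = n_indv)
    sig <- stats::setNames(numeric(4), comp_names)
    keep_row <- dfs > 0                       # zero-df levels carry nothing
    keep_col <- c(TRUE, dfs["ai"] > 0, dfs["ap"] > 0, dfs["ag"] > 0)
    sig[keep_col] <- solve(Mm[keep_row, keep_col, drop = FALSE],
                           ss[keep_row])      # order: s_wi, s_ai, s_ap, s_ag
    df <- c(among_groups = n_grp - 1, among_populations = n_pop - n_grp,
            among_individuals = n_indv - n_pop, within_individuals = n_indv)
    list(sigma = sig, ss = ss, df = df)
  }

  cmp <- components(hap_pop, hap_grp)
  sig <- cmp$sigma
  tot <- sum(pmax(sig, 0))
  pct <- 100 * pmax(sig, 0) / tot
  phi <- c(
    phi_CT = unname(sig["among_groups"] / sum(sig)),
    phi_SC = unname(sig["among_populations"] /
                    sum(sig[c("within_individuals", "among_individuals",
                              "among_populations")])),
    phi_IS = unname(sig["among_individuals"] /
                    sum(sig[c("within_individuals", "among_individuals")])),
    phi_IT = unname(sum(sig[c("among_individuals", "among_populations",
                              "among_groups")]) / sum(sig)))

  set.seed(seed)
  p_values <- c(among_groups = NA_real_, among_populations = NA_real_,
                among_individuals = NA_real_)
  untestable <- character(0)

  # among groups: permute whole populations among groups
  upops <- unique(pop)
  grp_of_pop <- tapply(grp, pop, function(x) x[1])[upops]
  if (length(unique(grp)) >= 2 && length(upops) > length(unique(grp))) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      pg <- sample(as.character(grp_of_pop))
      hg <- pg[match(hap_pop, upops)]
      s <- components(hap_pop, hg)$sigma
      if (s["among_groups"] >= sig["among_groups"] - 1e-12) exceed <- exceed + 1L
    }
    p_values["among_groups"] <- (exceed + 1) / (n_perm + 1)
  } else untestable <- c(untestable, "among_groups")

  # among populations within groups: permute individuals among populations
  # of the same group
  if (any(pops_per_group >= 2)) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      newpop <- pop
      for (g0 in unique(grp)) {
        m <- which(grp == g0)
        newpop[m] <- pop[m][sample.int(length(m))]
      }
      s <- components(newpop[hap_ind], hap_grp)$sigma
      if (s["among_populations"] >= sig["among_populations"] - 1e-12)
        exceed <- exceed + 1L
    }
    p_values["among_populations"] <- (exceed + 1) / (n_perm + 1)
  } else untestable <- c(untestable, "among_populations")

  # among individuals within populations: permute haplotypes among
  # individuals of the same population
  {
    exceed <- 0L
    ord <- seq_len(2L * n)
    ss_wp0 <- ss_within(hap_pop)
    for (b in seq_len(n_perm)) {
      perm <- ord
      for (p0 in unique(pop)) {
        m <- which(hap_pop == p0)
        perm[m] <- m[sample.int(length(m))]
      }
      # under this scheme only the within-individual SS changes
      o <- perm[seq(1L, 2L * n, 2L)]; e <- perm[seq(2L, 2L * n, 2L)]
      ssw <- sum(D2[cbind(o, e)]) / 2
      sai <- ss_wp0 - ssw
      if (sai >= cmp$ss["ai"] - 1e-12) exceed <- exceed + 1L
    }
    p_values["among_individuals"] <- (exceed + 1) / (n_perm + 1)
  }

  tab <- data.frame(
    level = c("among_groups", "among_populations_within_groups",
              "among_individuals_within_populations", "within_individuals"),
    df = as.integer(cmp$df),
    sigma = sig[c("among_groups", "among_populations", "among_individuals",
                  "within_individuals")],
    percent = pct[c("among_groups", "among_populations", "among_individuals",
                    "within_individuals")],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, sigma = sig, percent = pct, phi = phi,
                 p_values = p_values, n_perm = n_perm,
                 untestable = untestable),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (haplotype-level, nested individuals/populations/groups)\n")
  print(x$table, digits = 4)
  cat("Phi: ", paste(sprintf("%s = %.4f", names(x$phi), x$phi),
                     collapse = ", "), "\n")
  cat("permutation p:",
      paste(sprintf("%s = %.4g", names(x$p_values), x$p_values),
            collapse = ", "), "\n")
  if (length(x$untestable))
    cat("untestable levels:", paste(x$untestable, collapse = ", "), "\n")
  invisible(x)
}
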