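#' Pairwise IBD-state probabilities and PI_HAT
#'
#' PLINK-style method-of-moments estimator: genome-wide IBS0/IBS1/IBS2
#' counts per pair are compared with their allele-frequency expectations
#' under IBD states 0/1/2, solved sequentially, truncated to [0, 1] and
#' renormalized. `PI_HAT = P(IBD=2) + 0.5 P(IBD=1)`.
#'
#' @param panel A `genotype_panel` (LD-pruned recommended; a warning is
#'   emitted otherwise unless `ld_pruned = TRUE`).
#' @param ld_pruned Set `TRUE` to declare the panel pruned and silence the
#'   warning.
#' @return A `kinship_matrix`: data frame with one row per unordered sample
#'   pair (`id1`, `id2`, `z0`, `z1`, `z2`, `pi_hat`) plus a `pi_hat` matrix
#'   attribute.
#' @export
pairwise_pi_hat <- function(panel, ld_pruned = FALSE) {
  if (n_snps(panel) < 50) stop("fewer than 50 SNPs: IBD estimator unstable")
  if (!ld_pruned) warning("panel not declared LD-pruned; PI_HAT assumes weak LD")
  g <- panel$genotypes
  n <- nrow(g)
  p <- colMeans(g, na.rm = TRUE) / 2
  q <- 1 - p
  # expected IBS-state probabilities per SNP given IBD state
  e0_ibs0 <- 2 * p^2 * q^2
  e0_ibs1 <- 4 * p^3 * q + 4 * p * q^3
  e1_ibs1 <- 2 * p^2 * q + 2 * p * q^2
  e0_ibs2 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibs2 <- p^3 + q^3 + p^2 * q + p * q^2
  ids <- panel$sample_ids
  rows <- vector("list", n * (n - 1) / 2)
  r <- 0L
  pm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(pm) <- 1
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    gi <- g[i, ]; gj <- g[j, ]
    use <- !is.na(gi) & !is.na(gj)
    d <- abs(gi[use] - gj[use])
    n_ibs0 <- sum(d == 2); n_ibs1 <- sum(d == 1); n_ibs2 <- sum(d == 0)
    s0_0 <- sum(e0_ibs0[use]); s0_1 <- sum(e0_ibs1[use])
    s1_1 <- sum(e1_ibs1[use]); s0_2 <- sum(e0_ibs2[use])
    s1_2 <- sum(e1_ibs2[use]); s2_2 <- sum(use)
    z0 <- n_ibs0 / s0_0
    z1 <- (n_ibs1 - z0 * s0_1) / s1_1
    z2 <- (n_ibs2 - z0 * s0_2 - z1 * s1_2) / s2_2
    z <- pmax(c(z0, z1, z2), 0)
    z <- z / sum(z)
    pi_hat <- min(max(z[3] + 0.5 * z[2], 0), 1)
    r <- r + 1L
    rows[[r]] <- data.frame(id1 = ids[i], id2 = ids[j], z0 = z[1], z1 = z[2],
                            z2 = z[3], pi_hat = pi_hat,
                            stringsAsFactors = FALSE)
    pm[i, j] <- pm[j, i] <- pi_hat
  }
  out <- do.call(rbind, rows)
  attr(out, "pi_hat_matrix") <- pm
  class(out) <- c("kinship_matrix", "data.frame")
  out
}

# Exact maximum independent set by branch and bound on an adjacency list.
mis_exact <- function(adj, verts) {
  if (length(verts) == 0) return(character(0))
  deg <- vapply(verts, function(v) length(intersect(adj[[v]], verts)), integer(1))
  if (all(deg == 0)) return(verts)
  v <- verts[order(-deg, verts)][1]
  # branch 1: exclude v
  a <- mis_exact(adj, setdiff(verts, v))
  # branch 2: include v, drop its neighbours
  b <- c(v, mis_exact(adj, setdiff(verts, c(v, adj[[v]]))))
  if (length(b) > length(a)) b else if (length(a) > length(b)) a
  else if (paste(sort(a), collapse = ",") <= paste(sort(b), collapse = ",")) a else b
}

#' Maximum set of unrelated samples
#'
#' Builds the graph of pairs with `PI_HAT > threshold` and returns a
#' maximum-cardinality subset with no related pair: exact (branch-and-bound
#' maximum independent set) for connected components of at most
#' `exact_max_vertices` vertices, greedy (iteratively dropping the
#' highest-degree vertex) beyond that. Ties break by sample id order.
#'
#' @param kinship A `kinship_matrix` from [pairwise_pi_hat()].
#' @param threshold Relatedness threshold (default 0.375, first degree).
#' @param exact_max_vertices Component size up to which the exact search is
#'   used (default 30).
#' @return Character vector of retained sample ids, with attribute `mode`
#'   (`"exact"`, `"greedy"` or `"mixed"`).
#' @export
max_unrelated_set <- function(kinship, threshold = 0.375,
                              exact_max_vertices = 30) {
  stopifnot(threshold > 0, threshold < 1)
  ids <- sort(unique(c(kinship$id1, kinship$id2)))
  rel <- kinship[kinship$pi_hat > threshold, , drop = FALSE]
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(rel))) {
    adj[[rel$id1[k]]] <- c(adj[[rel$id1[k]]], rel$id2[k])
    adj[[rel$id2[k]]] <- c(adj[[rel$id2[k]]], rel$id1[k])
  }
  # connected components over related vertices
  related <- ids[vapply(ids, function(v) length(adj[[v]]) > 0, logical(1))]
  keep <- setdiff(ids, related)
  modes <- character(0)
  seen <- character(0)
  for (v in related) {
    if (v %in% seen) next
    comp <- v; frontier <- v
    while (length(frontier)) {
      nb <- setdiff(unique(unlist(adj[frontier])), comp)
      comp <- c(comp, nb); frontier <- nb
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    if (length(comp) <= exact_max_vertices) {
      keep <- c(keep, mis_exact(adj, comp))
      modes <- c(modes, "exact")
    } else {
      verts <- comp
      repeat {
        deg <- vapply(verts, function(u) length(intersect(adj[[u]], verts)),
                      integer(1))
        if (all(deg == 0)) break
        verts <- setdiff(verts, verts[order(-deg, verts)][1])
      }
      keep <- c(keep, verts)
      modes <- c(modes, "greedy")
    }
  }
  out <- sort(keep)
  attr(out, "mode") <- if (length(modes) == 0) "exact"
                       else if (all(modes == "exact")) "exact"
                       else if (all(modes == "greedy")) "greedy" else "mixed"
  out
}
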