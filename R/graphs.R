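#' Build an admixture graph
#'
#' A rooted directed acyclic graph of populations: drift edges carry a
#' length (in f2 units, >= 0) and weight 1; the two in-edges of an
#' admixture node carry mixing weights summing to 1 (their drift length is
#' conventionally 0 and is not fitted).
#'
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `length` (default 0) and `weight` (default `NA`; set on admixture
#'   in-edges).
#' @return An `admixture_graph`: edges, node list, root, leaves, and the
#'   set of admixture nodes.
#' @export
admixture_graph <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$length)) edges$length <- 0
  if (is.null(edges$weight)) edges$weight <- NA_real_
  nodes <- unique(c(edges$from, edges$to))
  n_in <- table(factor(edges$to, levels = nodes))
  roots <- nodes[n_in[nodes] == 0]
  if (length(roots) != 1) stop("graph must have exactly one root")
  admix <- nodes[n_in[nodes] == 2]
  if (any(n_in > 2)) stop("nodes may have at most two parents")
  for (a in admix) {
    w <- edges$weight[edges$to == a]
    if (anyNA(w)) {
      edges$weight[edges$to == a] <- c(0.5, 0.5)
    } else if (abs(sum(w) - 1) > 1e-8)
      stop("admixture in-edge weights must sum to 1 at node ", a)
  }
  edges$weight[is.na(edges$weight)] <- 1
  leaves <- nodes[!(nodes %in% edges$from)]
  g <- structure(list(edges = edges, nodes = nodes, root = roots,
                      leaves = leaves, admix_nodes = admix),
                 class = "admixture_graph")
  graph_depths(g)  # errors on cycles
  g
}

# Longest-path depth from the root; children always deeper than parents.
graph_depths <- function(g) {
  depth <- stats::setNames(rep(-Inf, length(g$nodes)), g$nodes)
  depth[g$root] <- 0
  for (pass in seq_len(length(g$nodes) + 1)) {
    changed <- FALSE
    for (k in seq_len(nrow(g$edges))) {
      d <- depth[g$edges$from[k]] + 1
      if (is.finite(d) && d > depth[g$edges$to[k]]) {
        depth[g$edges$to[k]] <- d; changed <- TRUE
      }
    }
    if (!changed) break
    if (pass > length(g$nodes)) stop("cyclic graph")
  }
  depth
}

# Probability that a lineage sampled at `leaf` traverses each edge,
# following in-edges rootward and splitting by admixture weights.
# `ord` (nodes by decreasing depth) may be precomputed once per topology.
edge_probabilities <- function(g, leaf, ord = NULL) {
  if (is.null(ord))
    ord <- names(sort(graph_depths(g), decreasing = TRUE))
  at <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  at[leaf] <- 1
  pe <- numeric(nrow(g$edges))
  for (v in ord) {
    if (at[v] == 0) next
    ein <- which(g$edges$to == v)
    for (k in ein) {
      pe[k] <- pe[k] + at[v] * g$edges$weight[k]
      at[g$edges$from[k]] <- at[g$edges$from[k]] + at[v] * g$edges$weight[k]
    }
  }
  pe
}

#' Expected f-statistics under an admixture graph
#'
#' Path-overlap rules: with `p_X(e)` the probability that a lineage from
#' leaf X traverses edge e, `f2(A,B) = sum_e l_e (p_A - p_B)^2`,
#' `f3(C;A,B) = sum_e l_e (p_C - p_A)(p_C - p_B)` and
#' `f4(A,B;C,D) = sum_e l_e (p_A - p_B)(p_C - p_D)`.
#'
#' @param graph An `admixture_graph` with edge lengths set.
#' @param kind `"f2"`, `"f3"` or `"f4"`.
#' @param pops Population (leaf) arguments in the same order as
#'   [f_statistic()].
#' @return The predicted statistic (numeric scalar).
#' @export
expected_f_stat <- function(graph, kind = c("f2", "f3", "f4"), pops) {
  kind <- match.arg(kind)
  p <- lapply(pops, function(x) edge_probabilities(graph, x))
  l <- graph$edges$length
  switch(kind,
    f2 = sum(l * (p[[1]] - p[[2]])^2),
    f3 = sum(l * (p[[1]] - p[[2]]) * (p[[1]] - p[[3]])),
    f4 = sum(l * (p[[1]] - p[[2]]) * (p[[3]] - p[[4]])))
}

#' Expected f-statistics for a table of requested statistics
#'
#' @param graph An `admixture_graph`.
#' @param stats Data frame with columns `kind` and `pops`
#'   (comma-separated), e.g. observed [f_statistic()] rows.
#' @return Numeric vector of predictions, one per row.
#' @export
expected_f_stats <- function(graph, stats) {
  ord <- names(sort(graph_depths(graph), decreasing = TRUE))
  pops_list <- strsplit(stats$pops, ",", fixed = TRUE)
  leaves <- unique(unlist(pops_list))
  pe <- lapply(stats::setNames(leaves, leaves),
               function(x) edge_probabilities(graph, x, ord = ord))
  l <- graph$edges$length
  vapply(seq_len(nrow(stats)), function(i) {
    p <- pe[pops_list[[i]]]
    switch(stats$kind[i],
      f2 = sum(l * (p[[1]] - p[[2]])^2),
      f3 = sum(l * (p[[1]] - p[[2]]) * (p[[1]] - p[[3]])),
      f4 = sum(l * (p[[1]] - p[[2]]) * (p[[3]] - p[[4]])))
  }, numeric(1))
}

# Free parameters: lengths of non-admixture in-edges, one weight per
# admixture node. Lengths are parameterized as theta^2, weights by logit.
graph_free_params <- function(g) {
  len_edges <- which(!(g$edges$to %in% g$admix_nodes))
  list(len_edges = len_edges, admix = g$admix_nodes)
}

graph_set_params <- function(g, par, fp) {
  nl <- length(fp$len_edges)
  g$edges$length[fp$len_edges] <- par[seq_len(nl)]^2
  if (length(fp$admix)) {
    w <- stats::plogis(par[nl + seq_along(fp$admix)])
    for (i in seq_along(fp$admix)) {
      ein <- which(g$edges$to == fp$admix[i])
      g$edges$weight[ein] <- c(w[i], 1 - w[i])
    }
  }
  g
}

#' Fit an admixture graph to observed f-statistics
#'
#' Drift lengths (>= 0) and admixture weights (in (0,1)) are chosen to
#' minimize the maximum absolute residual Z between graph-expected and
#' observed statistics (Z uses the observed jackknife SEs), via a
#' least-squares warm start followed by a minimax polish; ties are broken
#' by the sum of squared residuals. A fit is "good" when the worst |Z| is
#' below 3.
#'
#' @param graph An `admixture_graph` giving the topology.
#' @param observed Data frame of observed statistics (`kind`, `pops`,
#'   `estimate`, `se`, optionally `n_snps`).
#' @param min_snps Rows with fewer usable SNPs are dropped (default 0).
#' @param n_restarts Random restarts for the warm start (default 3).
#' @param seed Seed for restart draws (default 1).
#' @return A `graph_fit`: the fitted graph, `residuals` table, `worst_z`,
#'   `good`, `identifiable`, and the outlier count (|Z| > 3).
#' @export
fit_admixture_graph <- function(graph, observed, min_snps = 0,
                                n_restarts = 3, seed = 1) {
  if (!is.null(observed$n_snps) && min_snps > 0)
    observed <- observed[observed$n_snps >= min_snps, , drop = FALSE]
  if (nrow(observed) == 0) stop("no observed statistics to fit")
  if (any(observed$se <= 0)) stop("observed statistics need positive SEs")
  leaves_used <- unique(unlist(strsplit(observed$pops, ",", fixed = TRUE)))
  if (!all(leaves_used %in% graph$leaves))
    stop("observed statistics mention non-leaf populations")
  fp <- graph_free_params(graph)
  npar <- length(fp$len_edges) + length(fp$admix)
  resid_z <- function(par) {
    gg <- graph_set_params(graph, par, fp)
    (expected_f_stats(gg, observed) - observed$estimate) / observed$se
  }
  obj_ls <- function(par) sum(resid_z(par)^2)
  obj_minimax <- function(par) {
    z <- resid_z(par)
    max(abs(z)) + 1e-4 * sum(z^2)   # tie-break on SSQ
  }
  set.seed(seed)
  scale0 <- sqrt(max(mean(abs(observed$estimate)), 1e-6))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    p0 <- c(stats::runif(length(fp$len_edges), 0.1, 1) * scale0,
            stats::rnorm(length(fp$admix), 0, 0.5))
    fit <- stats::optim(p0, obj_ls, method = "BFGS",
                        control = list(maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pol <- stats::optim(best$par, obj_minimax, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  par <- if (pol$value < obj_minimax(best$par)) pol$par else best$par
  gg <- graph_set_params(graph, par, fp)
  z <- resid_z(par)
  # flat directions indicate a non-identifiable topology
  f0 <- obj_ls(par)
  flat <- vapply(seq_len(npar), function(i) {
    d <- numeric(npar); d[i] <- max(abs(par[i]), 0.05) * 0.5
    max(abs(obj_ls(par + d) - f0), abs(obj_ls(par - d) - f0)) < 1e-9
  }, logical(1))
  res <- cbind(observed[, c("kind", "pops", "estimate", "se")],
               expected = expected_f_stats(gg, observed), z = z)
  structure(list(graph = gg, residuals = res, worst_z = max(abs(z)),
                 good = max(abs(z)) < 3, outliers = sum(abs(z) > 3),
                 identifiable = !any(flat), flat_params = which(flat)),
            class = "graph_fit")
}

#' @export
print.graph_fit <- function(x, ...) {
  cat(sprintf("graph_fit: worst |Z| = %.3f (%s), %d outliers%s\n",
              x$worst_z, if (x$good) "good fit" else "poor fit", x$outliers,
              if (x$identifiable) "" else " [non-identifiable topology]"))
  invisible(x)
}

#' Insert a new leaf on a graph edge
#'
#' Splits edge `k` with a fresh internal node and hangs `leaf` below it;
#' the building block of one-way placements.
#'
#' @param g An `admixture_graph`.
#' @param k Edge row index.
#' @param leaf New leaf name.
#' @param tag Prefix for generated node names.
#' @return The extended `admixture_graph`.
#' @export
add_leaf_on_edge <- function(g, k, leaf, tag = "x") {
  mid <- paste0(tag, "_n")
  e <- g$edges
  new <- rbind(e[-k, c("from", "to", "length", "weight")],
               data.frame(from = e$from[k], to = mid, length = e$length[k] / 2,
                          weight = e$weight[k]),
               data.frame(from = mid, to = e$to[k], length = e$length[k] / 2,
                          weight = 1),
               data.frame(from = mid, to = leaf, length = 0.01, weight = 1))
  admixture_graph(new)
}

#' Insert an admixed leaf drawing from two graph edges
#'
#' Splits edges `k1` and `k2`, joins the fresh nodes through an admixture
#' node, and hangs `leaf` below it; the building block of two-way
#' placements.
#'
#' @param g An `admixture_graph`.
#' @param k1,k2 Distinct edge row indices.
#' @param leaf New leaf name.
#' @param tag Prefix for generated node names.
#' @return The extended `admixture_graph`.
#' @export
add_admixed_leaf_on_edges <- function(g, k1, k2, leaf, tag = "x") {
  stopifnot(k1 != k2)
  e <- g$edges
  m1 <- paste0(tag, "_n1"); m2 <- paste0(tag, "_n2"); ad <- paste0(tag, "_ad")
  keep <- e[-c(k1, k2), c("from", "to", "length", "weight")]
  split1 <- rbind(
    data.frame(from = e$from[k1], to = m1, length = e$length[k1] / 2,
               weight = e$weight[k1]),
    data.frame(from = m1, to = e$to[k1], length = e$length[k1] / 2, weight = 1))
  split2 <- rbind(
    data.frame(from = e$from[k2], to = m2, length = e$length[k2] / 2,
               weight = e$weight[k2]),
    data.frame(from = m2, to = e$to[k2], length = e$length[k2] / 2, weight = 1))
  newe <- rbind(keep, split1, split2,
                data.frame(from = c(m1, m2), to = ad, length = 0,
                           weight = c(0.5, 0.5)),
                data.frame(from = ad, to = leaf, length = 0.01, weight = 1))
  admixture_graph(newe)
}

#' Search placements of a test population on a fitted scaffold
#'
#' Enumerates one-way placements (the test leaf attached to every scaffold
#' edge) and optionally two-way placements (an admixed leaf drawing from
#' every pair of edges), fits each candidate, and ranks them: one-way
#' models with a good fit (worst |Z| < 3) are preferred as the more
#' parsimonious scenario, then candidates sort by worst |Z|, then by
#' outlier count.
#'
#' @param scaffold An `admixture_graph` (topology; lengths refitted per
#'   candidate).
#' @param test_population Name of the leaf to place.
#' @param observed Observed statistics covering scaffold leaves and the
#'   test population.
#' @param two_way Also try admixed placements (default `TRUE`).
#' @param min_snps,seed Passed to [fit_admixture_graph()].
#' @return A list of candidate results (`model`, `edges`, `fit`), ranked
#'   best first.
#' @export
placement_search <- function(scaffold, test_population, observed,
                             two_way = TRUE, min_snps = 0, seed = 1) {
  ne <- nrow(scaffold$edges)
  cands <- list()
  for (k in seq_len(ne)) {
    g <- add_leaf_on_edge(scaffold, k, test_population, tag = paste0("ow", k))
    fit <- fit_admixture_graph(g, observed, min_snps = min_snps, seed = seed)
    cands[[length(cands) + 1L]] <- list(model = "one_way", edges = k, fit = fit)
  }
  if (two_way && ne >= 2) {
    for (k1 in seq_len(ne - 1)) for (k2 in seq(k1 + 1, ne)) {
      g <- try(add_admixed_leaf_on_edges(scaffold, k1, k2, test_population,
                                         tag = paste0("tw", k1, "_", k2)),
               silent = TRUE)
      if (inherits(g, "try-error")) next
      fit <- fit_admixture_graph(g, observed, min_snps = min_snps, seed = seed)
      cands[[length(cands) + 1L]] <- list(model = "two_way",
                                          edges = c(k1, k2), fit = fit)
    }
  }
  pref <- vapply(cands, function(cc)
    !(cc$model == "one_way" && cc$fit$good), logical(1))
  wz <- vapply(cands, function(cc) cc$fit$worst_z, numeric(1))
  out <- vapply(cands, function(cc) cc$fit$outliers, numeric(1))
  cands[order(pref, wz, out)]
}

#' Export an admixture graph as DOT text
#'
#' @param graph An `admixture_graph`.
#' @param path Optional file to write; otherwise the text is returned.
#' @return Character vector of DOT lines, invisibly when written.
#' @export
graph_to_dot <- function(graph, path = NULL) {
  e <- graph$edges
  lab <- ifelse(e$to %in% graph$admix_nodes,
                sprintf("w=%.2f", e$weight), sprintf("%.4f", e$length))
  lines <- c("digraph G {",
             sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];", e$from, e$to, lab),
             "}")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
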