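#' Supervised ancestry proportions by EM
#'
#' Per-sample maximization of the binomial admixture log-likelihood
#' `sum_j [ g_j log(sum_k q_k f_kj) + (2 - g_j) log(sum_k q_k (1 - f_kj)) ]`
#' over the K-simplex, given fixed reference allele frequencies (the
#' likelihood model of supervised ADMIXTURE). EM from a uniform start,
#' deterministic, run to a relative log-likelihood change below `tol`.
#'
#' @param panel A `genotype_panel`.
#' @param reference_freqs K x SNPs matrix of source ALT frequencies with
#'   rownames (or a `freq_table`, all of whose populations are used).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 2000).
#' @param eps Reference frequencies are clipped to `[eps, 1 - eps]`
#'   (default 1e-6).
#' @return An `ancestry_proportions`: list with `q` (samples x K simplex
#'   matrix), `loglik` (per sample, at the optimum), `iterations`.
#' @export
supervised_ancestry <- function(panel, reference_freqs, tol = 1e-6,
                                max_iter = 2000, eps = 1e-6) {
  if (inherits(reference_freqs, "freq_table")) {
    if (n_snps(panel) != ncol(reference_freqs$freq))
      stop("reference table SNP count differs from panel")
    reference_freqs <- reference_freqs$freq
  }
  K <- nrow(reference_freqs)
  if (is.null(K) || K < 2) stop("need at least 2 reference components")
  if (anyNA(reference_freqs))
    stop("reference frequencies must be non-missing for used SNPs")
  f <- pmin(pmax(reference_freqs, eps), 1 - eps)      # K x S
  G <- panel$genotypes
  n <- nrow(G)
  q <- matrix(NA_real_, n, K, dimnames = list(panel$sample_ids, rownames(f)))
  ll_out <- numeric(n); iters <- integer(n)
  for (i in seq_len(n)) {
    g <- G[i, ]
    use <- !is.na(g)
    gj <- g[use]; fj <- f[, use, drop = FALSE]
    qi <- rep(1 / K, K)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      pa <- as.vector(qi %*% fj)          # P(ALT allele)
      pr <- as.vector(qi %*% (1 - fj))
      ll <- sum(gj * log(pa) + (2 - gj) * log(pr))
      # EM: expected fraction of allele draws attributed to component k
      w_alt <- fj * rep(gj / pa, each = K)
      w_ref <- (1 - fj) * rep((2 - gj) / pr, each = K)
      qi <- qi * (rowSums(w_alt) + rowSums(w_ref)) / (2 * length(gj))
      qi <- qi / sum(qi)
      if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
      ll_old <- ll
    }
    q[i, ] <- qi; ll_out[i] <- ll; iters[i] <- it
  }
  structure(list(q = q, loglik = ll_out, iterations = iters),
            class = "ancestry_proportions")
}

#' Flag samples as admixed by a focal-component threshold
#'
#' A sample is admixed when its summed non-focal ancestry exceeds
#' `max_nonfocal` (default 1%, i.e. focal component below 99%).
#'
#' @param anc An `ancestry_proportions`.
#' @param focal Name (or index) of the focal component.
#' @param max_nonfocal Threshold on the non-focal sum (default 0.01,
#'   strict `>`).
#' @return Named logical vector.
#' @export
flag_admixed <- function(anc, focal, max_nonfocal = 0.01) {
  qf <- anc$q[, focal]
  stats::setNames((1 - qf) > max_nonfocal + 1e-12, rownames(anc$q))
}

#' Principal component analysis of genotype dosages
#'
#' SNP dosages are centered and scaled by `sqrt(p(1-p))` (allele-frequency
#' normalization); missing dosages are mean-imputed per SNP. The sign of
#' each axis is fixed by making its largest-magnitude SNP loading positive.
#'
#' @param panel A `genotype_panel` with >= 2 samples.
#' @param n_components Number of axes to return (default 10, capped).
#' @return An `ordination`: `coords` (samples x k), `eigenvalues`,
#'   `var_explained`, `method = "pca"`.
#' @export
pca_panel <- function(panel, n_components = 10) {
  if (n_samples(panel) < 2) stop("PCA requires at least 2 samples")
  g <- panel$genotypes
  if (any(colSums(!is.na(g)) == 0)) stop("all-missing SNP in panel")
  p <- colMeans(g, na.rm = TRUE) / 2
  x <- sweep(g, 2, 2 * p)
  x[is.na(x)] <- 0                       # mean imputation after centering
  sdv <- sqrt(p * (1 - p))
  ok <- sdv > 0
  x <- sweep(x[, ok, drop = FALSE], 2, sdv[ok], "/")
  k <- min(n_components, nrow(x) - 1, ncol(x))
  sv <- svd(x, nu = k, nv = k)
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  coords <- sv$u %*% diag(sv$d[seq_len(k)], k)
  rownames(coords) <- panel$sample_ids
  colnames(coords) <- paste0("PC", seq_len(k))
  ev <- sv$d^2 / (nrow(x) - 1)
  structure(list(coords = coords, eigenvalues = ev[seq_len(k)],
                 var_explained = ev[seq_len(k)] / sum(ev), method = "pca"),
            class = "ordination")
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centering of squared distances and eigen-decomposition (via
#' `stats::cmdscale`); axes are taken from the top `k` non-negative
#' eigenvalues, and negative eigenvalues are reported but never used.
#'
#' @param dist A `dist_matrix` (or plain symmetric matrix with dimnames).
#' @param k Number of dimensions requested.
#' @return An `ordination` with `coords`, `eigenvalues` (all, including
#'   negatives), `var_explained` over positive eigenvalues, and
#'   `method = "classical_mds"`.
#' @export
classical_mds <- function(dist, k = 2) {
  m <- if (inherits(dist, "dist_matrix")) dist$matrix else as.matrix(dist)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  diag(m) <- 0
  fit <- stats::cmdscale(stats::as.dist(m), k = min(k, nrow(m) - 1), eig = TRUE)
  pos <- sum(fit$eig > 1e-12)
  if (k > pos) stop("k exceeds the number of positive eigenvalues (", pos, ")")
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Dim", seq_len(k))
  structure(list(coords = coords, eigenvalues = fit$eig,
                 var_explained = pmax(fit$eig, 0)[seq_len(k)] /
                   sum(pmax(fit$eig, 0)),
                 method = "classical_mds"),
            class = "ordination")
}

#' Regression of a per-sample value on latitude or longitude
#'
#' Ordinary least squares with the two-sided slope t-test.
#'
#' @param values Numeric vector (e.g. an ordination axis), one per sample.
#' @param coords Data frame or matrix with `lat` and `lon` columns.
#' @param axis `"latitude"` or `"longitude"`.
#' @return List with `slope`, `r_squared`, `p_value`, and the `lm` fit.
#' @export
geo_regression <- function(values, coords, axis = c("latitude", "longitude")) {
  axis <- match.arg(axis)
  x <- if (axis == "latitude") coords[, "lat"] else coords[, "lon"]
  x <- as.numeric(x)
  if (length(values) < 3) stop("need at least 3 samples")
  if (stats::var(x, na.rm = TRUE) == 0) stop("zero-variance predictor")
  fit <- stats::lm(values ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]), r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4], fit = fit)
}

#' Great-circle distance matrix
#'
#' Haversine distances on a sphere of radius 6371.0088 km.
#'
#' @param coords Data frame with `lat`, `lon` in degrees and optionally an
#'   id column used for labels (else rownames).
#' @return A `dist_matrix` in km.
#' @export
great_circle_matrix <- function(coords) {
  lat <- as.numeric(coords$lat); lon <- as.numeric(coords$lon)
  if (any(lat < -90 | lat > 90, na.rm = TRUE)) stop("latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180, na.rm = TRUE)) stop("longitude out of [-180, 180]")
  labels <- if (!is.null(coords$id)) as.character(coords$id)
            else if (!is.null(rownames(coords))) rownames(coords)
            else as.character(seq_along(lat))
  m <- geosphere::distm(cbind(lon, lat),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
  dimnames(m) <- list(labels, labels)
  structure(list(labels = labels, matrix = m, units = "km"),
            class = "dist_matrix")
}

#' Isolation-by-distance regression with a permutation test
#'
#' OLS of the vectorized upper triangle of the genetic distance matrix on
#' the geographic one. Because distance-matrix entries are not independent,
#' the naive t-test p-value is reported as descriptive only; the primary
#' p-value is a Mantel-style permutation of labels.
#'
#' @param genetic,geographic `dist_matrix` objects with matching labels.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Permutation seed (default 1).
#' @return List with `slope`, `r_squared`, `p_permutation` (primary,
#'   one-sided for positive association), `p_naive`.
#' @export
isolation_by_distance <- function(genetic, geographic, n_perm = 999, seed = 1) {
  gm <- genetic$matrix; dm <- geographic$matrix
  if (!identical(dim(gm), dim(dm))) stop("matrix dimensions differ")
  if (!is.null(genetic$labels) && !is.null(geographic$labels)) {
    if (!setequal(genetic$labels, geographic$labels))
      stop("mismatched labels between matrices")
    dm <- dm[genetic$labels, genetic$labels]
  }
  ut <- upper.tri(gm)
  y <- gm[ut]; x <- dm[ut]
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  obs <- stats::cor(x, y)
  set.seed(seed)
  n <- nrow(gm)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    pp <- sample.int(n)
    yp <- gm[pp, pp][ut]
    if (stats::cor(x, yp) >= obs) exceed <- exceed + 1L
  }
  list(slope = unname(stats::coef(fit)[2]), r_squared = sm$r.squared,
       p_permutation = (exceed + 1) / (n_perm + 1),
       p_naive = sm$coefficients[2, 4], correlation = obs)
}
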