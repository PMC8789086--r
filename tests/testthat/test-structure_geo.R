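test_that("supervised ancestry recovers pure and 50/50 admixed samples", {
  set.seed(21)
  S <- 10000
  fA <- runif(S, 0.05, 0.95)
  fB <- pmin(pmax(fA + rnorm(S, 0, 0.25), 0.02), 0.98)  # well-separated
  ref <- rbind(A = fA, B = fB)
  draw <- function(q) rbinom(S, 1, q %*% ref) + rbinom(S, 1, q %*% ref)
  g <- rbind(draw(c(1, 0)), draw(c(0, 1)), draw(c(0.5, 0.5)),
             draw(c(0.5, 0.5)))
  st <- data.frame(chrom = "1", pos = seq_len(S), cm = seq_len(S) * 0.01,
                   ref = "A", alt = "G", id = paste0("s", seq_len(S)))
  smp <- data.frame(id = c("pureA", "pureB", "mix1", "mix2"),
                    population = "X", major_group = "X", lat = NA, lon = NA)
  panel <- genotype_panel(g, st, smp)
  anc <- supervised_ancestry(subset_panel(panel, snps = 1:5000), ref[, 1:5000])
  expect_gte(anc$q["pureA", "A"], 0.95)
  expect_gte(anc$q["pureB", "B"], 0.95)
  anc10 <- supervised_ancestry(panel, ref)
  expect_lt(max(abs(anc10$q[c("mix1", "mix2"), "A"] - 0.5)), 0.05)
  # simplex invariant
  expect_equal(unname(rowSums(anc10$q)), rep(1, 4), tolerance = 1e-9)
  # admixture flag at the 1% non-focal rule (strict >)
  q <- rbind(a = c(A = 0.99, B = 0.01), b = c(A = 0.985, B = 0.015))
  fake <- list(q = q)
  class(fake) <- "ancestry_proportions"
  flags <- flag_admixed(fake, "A", 0.01)
  expect_false(unname(flags["a"]))
  expect_true(unname(flags["b"]))
})

test_that("EM log-likelihood is non-decreasing over iterations", {
  # run EM manually via decreasing iteration caps
  set.seed(22)
  S <- 800
  ref <- rbind(A = runif(S, 0.1, 0.9), B = runif(S, 0.1, 0.9))
  g <- matrix(rbinom(S, 2, 0.3 * ref["A", ] + 0.7 * ref["B", ]), 1)
  st <- data.frame(chrom = "1", pos = seq_len(S), cm = seq_len(S) * 0.01,
                   ref = "A", alt = "G", id = paste0("s", seq_len(S)))
  smp <- data.frame(id = "x", population = "X", major_group = "X",
                    lat = NA, lon = NA)
  panel <- genotype_panel(g, st, smp)
  lls <- sapply(c(2, 5, 10, 30, 100), function(mi)
    supervised_ancestry(panel, ref, max_iter = mi)$loglik)
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("PCA separates demes, is invariant to duplication and bounded", {
  m <- demographic_model(c(A = 150, B = 150),
                         data.frame(chrom = "1", length_cm = 80,
                                    n_snps = 2000),
                         n_generations = 2, fst = 0.1)
  p <- simulate_panel(m, 25, seed = 31, track_ancestry = FALSE)$panel
  pc <- pca_panel(p, 4)
  lab <- p$sample_table$population
  # silhouette of PC1 for the two demes
  x <- pc$coords[, 1]
  sil <- sapply(seq_along(x), function(i) {
    own <- mean(abs(x[i] - x[lab == lab[i]][-which(which(lab == lab[i]) == i)]))
    oth <- mean(abs(x[i] - x[lab != lab[i]]))
    (oth - own) / max(oth, own)
  })
  expect_gt(mean(sil), 0.8)
  expect_lte(sum(pc$var_explained), 1 + 1e-9)
  # duplicated sample lands on identical coordinates
  g2 <- rbind(p$genotypes, p$genotypes[1, , drop = FALSE])
  st2 <- rbind(p$sample_table, within(p$sample_table[1, ], id <- "dup"))
  p2 <- genotype_panel(g2, p$snp_table, st2)
  pc2 <- pca_panel(p2, 2)
  expect_equal(unname(pc2$coords["dup", ]), unname(pc2$coords[1, ]),
               tolerance = 1e-8)
})

test_that("classical MDS reproduces planted Euclidean configurations", {
  set.seed(23)
  pts <- cbind(runif(12, -5, 5), runif(12, -5, 5))
  rownames(pts) <- paste0("p", 1:12)
  d <- as.matrix(dist(pts))
  mds <- classical_mds(d, 2)
  # Procrustes alignment via vegan (independent implementation)
  pr <- vegan::procrustes(pts, mds$coords)
  expect_lt(sqrt(abs(pr$ss) / nrow(pts)), 1e-6)
  # 2-point matrix: one dimension at +/- d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  m2 <- classical_mds(d2, 1)
  expect_equal(sort(unname(m2$coords[, 1])), c(-1.5, 1.5), tolerance = 1e-9)
  expect_error(classical_mds(d2, 2), "positive eigenvalues")
})

test_that("pca and classical MDS agree on Euclidean-embeddable data", {
  panel <- make_iid_panel(n = 15, snps_per_chrom = 500, n_chrom = 1,
                          seed = 41, phased = FALSE)
  pc <- pca_panel(panel, 3)
  d <- as.matrix(dist(pc$coords))
  mds <- classical_mds(d, 3)
  pr <- vegan::procrustes(pc$coords, mds$coords)
  expect_lt(sqrt(abs(pr$ss) / nrow(pc$coords)) / sd(pc$coords[, 1]), 1e-6)
})

test_that("geo regression recovers exact linear relations and calibrates", {
  coords <- data.frame(lat = runif(50, -30, 10), lon = runif(50, -80, -40))
  vals <- 2 * coords$lon
  r <- geo_regression(vals, coords, "longitude")
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  # type-I error under independence
  set.seed(24)
  ps <- replicate(200, geo_regression(rnorm(40), coords[1:40, ],
                                      "latitude")$p_value)
  expect_gt(mean(ps <= 0.05), 0.01)
  expect_lt(mean(ps <= 0.05), 0.10)
  # duplicated points equal a weighted fit
  cd <- coords[1:10, ]; v <- rnorm(10)
  dup <- geo_regression(rep(v, 2), rbind(cd, cd), "longitude")
  wfit <- lm(v ~ cd$lon, weights = rep(2, 10))
  expect_equal(dup$slope, unname(coef(wfit)[2]), tolerance = 1e-10)
  expect_error(geo_regression(v, within(cd, lon <- 1), "longitude"),
               "zero-variance")
})

test_that("great-circle distances match haversine closed forms", {
  coords <- data.frame(id = c("o", "east", "anti"),
                       lat = c(0, 0, 0), lon = c(0, 1, 180))
  dm <- great_circle_matrix(coords)
  expect_equal(dm$matrix["o", "o"], 0)
  expect_equal(dm$matrix["o", "east"], 111.195, tolerance = 1e-3)
  expect_equal(dm$matrix["o", "anti"], pi * 6371.0088, tolerance = 1e-3)
  expect_error(great_circle_matrix(data.frame(lat = 100, lon = 0)),
               "latitude")
})

test_that("isolation by distance is detected and calibrated", {
  # exact affine relation
  set.seed(25)
  coords <- data.frame(id = paste0("p", 1:10),
                       lat = runif(10, -20, 0), lon = runif(10, -75, -45))
  geo <- great_circle_matrix(coords)
  gen <- geo
  gen$matrix <- 0.001 + 2e-5 * geo$matrix
  gen$units <- "1 - f3"
  r <- isolation_by_distance(gen, geo, n_perm = 199, seed = 3)
  expect_equal(r$r_squared, 1)
  expect_equal(r$p_permutation, 1 / 200)
  # label permutation breaks the signal: slope centered on zero
  slopes <- sapply(1:30, function(s) {
    set.seed(s)
    pp <- sample(10)
    genp <- gen
    genp$matrix <- gen$matrix[pp, pp]
    dimnames(genp$matrix) <- dimnames(gen$matrix)
    isolation_by_distance(genp, geo, n_perm = 49, seed = s)$slope
  })
  expect_lt(abs(mean(slopes)) / (2e-5), 0.5)
  # stepping-stone simulation: genetic distance grows along the chain
  m <- demographic_model(
    c(d1 = 80, d2 = 80, d3 = 80, d4 = 80, d5 = 80),
    data.frame(chrom = "1", length_cm = 60, n_snps = 1500),
    n_generations = 12, fst = 0,
    migration = do.call(rbind, lapply(1:4, function(i)
      data.frame(from = c(paste0("d", i), paste0("d", i + 1)),
                 to = c(paste0("d", i + 1), paste0("d", i)), rate = 0.05))))
  p <- simulate_panel(m, 10, seed = 71, track_ancestry = FALSE)$panel
  # neighbouring demes exchange migrants; ends of the chain diverge most
  ft <- allele_frequencies(p)
  fst_mat <- matrix(0, 5, 5, dimnames = list(paste0("d", 1:5), paste0("d", 1:5)))
  for (i in 1:4) for (j in (i + 1):5) {
    fij <- f_statistic(ft, "f2", paste0("d", c(i, j)), block_size_cm = 10)
    fst_mat[i, j] <- fst_mat[j, i] <- fij$estimate
  }
  gen2 <- structure(list(labels = paste0("d", 1:5), matrix = fst_mat,
                         units = "f2"), class = "dist_matrix")
  coords2 <- data.frame(id = paste0("d", 1:5), lat = 0, lon = seq(-70, -50, 5))
  geo2 <- great_circle_matrix(coords2)
  ibd <- isolation_by_distance(gen2, geo2, n_perm = 999, seed = 9)
  expect_gt(ibd$slope, 0)
  expect_lt(ibd$p_permutation, 0.05)
})
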