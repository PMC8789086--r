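test_that("planted IBD is recovered exactly and short tracts are rejected", {
  panel <- make_iid_panel(n = 8, snps_per_chrom = 2500, n_chrom = 2,
                          length_cm = 50, seed = 61)
  pl <- plant_fixtures(panel, list(
    list(kind = "ibd", sample1 = "S001", sample2 = "S002", chrom = "1",
         start_cm = 20, end_cm = 30),
    list(kind = "ibd", sample1 = "S003", sample2 = "S004", chrom = "2",
         start_cm = 5, end_cm = 6.5)), seed = 10)     # 1.5 cM -> below 2 cM
  segs <- detect_ibd(pl$panel)
  got <- segs[segs$sample1 == "S001" & segs$sample2 == "S002", ]
  expect_equal(nrow(got), 1L)
  truth <- pl$truth$ibd[1, ]
  spacing <- 50 / 2500
  expect_lte(abs(got$start_cm - truth$start_cm), spacing + 1e-9)
  expect_lte(abs(got$end_cm - truth$end_cm), spacing + 1e-9)
  expect_gt(got$support, 3)
  # the 1.5 cM plant is never emitted (> 2 cM rule)
  expect_equal(nrow(segs[segs$sample1 == "S003" & segs$sample2 == "S004", ]),
               0L)
  # precision: nothing beyond the planted truth
  expect_equal(nrow(segs), 1L)
})

test_that("a single flipped site survives under the error tolerance", {
  panel <- make_iid_panel(n = 4, snps_per_chrom = 2500, n_chrom = 1,
                          length_cm = 50, seed = 62)
  pl <- plant_fixtures(panel, list(
    list(kind = "ibd", sample1 = "S001", sample2 = "S002", chrom = "1",
         start_cm = 10, end_cm = 20)), seed = 11)
  p <- pl$panel
  H <- p$haplotypes
  mid <- which(p$snp_table$cm > 14.99 & p$snp_table$cm < 15.03)[1]
  H[3, mid] <- 1L - H[3, mid]       # flip inside the tract on S002 hap 1
  n <- n_samples(p)
  g <- H[seq(1, 2 * n, 2), ] + H[seq(2, 2 * n, 2), ]
  p2 <- genotype_panel(g, p$snp_table, p$sample_table, haplotypes = H)
  segs <- detect_ibd(p2, error_tolerance = 0.002)
  got <- segs[segs$sample1 == "S001" & segs$sample2 == "S002", ]
  expect_equal(nrow(got), 1L)       # still one segment spanning the flip
  expect_gt(got$end_cm - got$start_cm, 9.5)
})

test_that("HBD is detected on an individual's own haplotype pair", {
  panel <- make_iid_panel(n = 4, snps_per_chrom = 2500, n_chrom = 1,
                          length_cm = 50, seed = 63)
  pl <- plant_fixtures(panel, list(
    list(kind = "roh", sample = "S001", chrom = "1",
         start_cm = 12, end_cm = 22)), seed = 12)
  segs <- detect_ibd(pl$panel, hbd = "only")
  got <- segs[segs$sample1 == "S001", ]
  expect_equal(nrow(got), 1L)
  expect_equal(got$sample2, "S001")
  expect_lt(abs(got$start_cm - 12), 0.1)
})

test_that("gap merging respects the gap length and discordance rules", {
  panel <- make_iid_panel(n = 4, snps_per_chrom = 5000, n_chrom = 1,
                          length_cm = 50, seed = 64)
  # make the gap region between the two segments homozygous-concordant
  # except for a controllable number of opposite-homozygote sites
  H <- panel$haplotypes
  gap <- which(panel$snp_table$cm > 15.0 & panel$snp_table$cm < 15.4)
  H[1:2, gap] <- 0L; H[3:4, gap] <- 0L
  disc1 <- gap[5]
  H[3:4, disc1] <- 1L                         # one opposite homozygote
  n <- n_samples(panel)
  g <- H[seq(1, 2 * n, 2), ] + H[seq(2, 2 * n, 2), ]
  p2 <- genotype_panel(g, panel$snp_table, panel$sample_table,
                       haplotypes = H)
  seg_row <- function(s_cm, e_cm) data.frame(
    sample1 = "S001", hap1 = 1L, sample2 = "S002", hap2 = 1L, chrom = "1",
    start_bp = round(s_cm * 1e6), end_bp = round(e_cm * 1e6),
    start_cm = s_cm, end_cm = e_cm, length_cm = e_cm - s_cm,
    support = 50, n_snps = 100, ancestry = NA_character_,
    stringsAsFactors = FALSE)
  segs <- rbind(seg_row(10, 15), seg_row(15.4, 20.4))
  class(segs) <- c("ibd_segments", "data.frame")
  merged <- merge_gaps(segs, p2)
  expect_equal(nrow(merged), 1L)              # 0.4 cM gap, 1 discordant
  expect_equal(merged$length_cm, 10.4)
  expect_equal(merged$start_cm, 10)
  # a 0.7 cM gap is not merged
  far <- rbind(seg_row(10, 15), seg_row(15.7, 20.7))
  class(far) <- c("ibd_segments", "data.frame")
  expect_equal(nrow(merge_gaps(far, p2)), 2L)
  # two discordant homozygotes block the merge
  H[3:4, gap[10]] <- 1L
  g <- H[seq(1, 2 * n, 2), ] + H[seq(2, 2 * n, 2), ]
  p3 <- genotype_panel(g, panel$snp_table, panel$sample_table,
                       haplotypes = H)
  expect_equal(nrow(merge_gaps(segs, p3)), 2L)
})

test_that("window-likelihood local ancestry recovers planted tracts", {
  set.seed(65)
  S <- 12000                                       # 60 cM at 0.005 cM spacing
  fA <- runif(S, 0.1, 0.9)
  fB <- pmin(pmax(fA + rnorm(S, 0, 0.3), 0.02), 0.98)   # F_ST ~ 0.15
  ref <- rbind(A = fA, B = fB)
  st <- data.frame(chrom = "1", pos = as.integer(seq_len(S) * 5e3),
                   cm = seq_len(S) * 0.005, ref = "A", alt = "G",
                   id = paste0("s", seq_len(S)))
  H <- matrix(0L, 4, S)
  H[1, ] <- rbinom(S, 1, fA)                      # pure A haplotype
  H[2, ] <- rbinom(S, 1, fA)
  bidx <- st$cm >= 20 & st$cm <= 40                # planted 20 cM B tract
  H[3, ] <- rbinom(S, 1, fA)
  H[3, bidx] <- rbinom(sum(bidx), 1, fB[bidx])
  H[4, ] <- rbinom(S, 1, fA)
  g <- H[c(1, 3), ] + H[c(2, 4), ]
  smp <- data.frame(id = c("pure", "mix"), population = "X",
                    major_group = "X", lat = NA, lon = NA)
  panel <- genotype_panel(g, st, smp, haplotypes = H)
  tr <- classify_local_ancestry(panel, ref, window_cm = 0.2)
  pure <- tr[tr$sample == "pure" & tr$hap == 1, ]
  frac_a <- sum((pure$end_cm - pure$start_cm)[pure$label == "A"]) /
    sum(pure$end_cm - pure$start_cm)
  expect_gte(frac_a, 0.95)
  mix <- tr[tr$sample == "mix" & tr$hap == 1 & tr$label == "B", ]
  expect_gte(nrow(mix), 1L)
  # boundary recovery: some B tract edge within 1 cM of each truth edge
  expect_lt(min(abs(mix$start_cm - 20)), 1)
  expect_lt(min(abs(mix$end_cm - 40)), 1)
  # and the planted span is covered by B calls with little spillover
  cover <- sum(pmax(0, pmin(mix$end_cm, 40) - pmax(mix$start_cm, 20)))
  expect_gte(cover / 20, 0.9)
  spill <- sum(mix$end_cm - mix$start_cm) - cover
  expect_lte(spill, 2)
  # indistinguishable sources give 0.5 posteriors
  tr2 <- classify_local_ancestry(panel, rbind(A = fA, B = fA))
  expect_true(all(abs(tr2$mean_posterior - 0.5) < 1e-9))
})

test_that("ancestry masking keeps only covered segments and never adds", {
  seg <- data.frame(sample1 = "x", hap1 = 1L, sample2 = "y", hap2 = 1L,
                    chrom = "1", start_bp = 1e6, end_bp = 2e6,
                    start_cm = 10, end_cm = 20, length_cm = 10,
                    support = 50, n_snps = 100, ancestry = NA,
                    stringsAsFactors = FALSE)
  tract <- function(sample, from, to, label)
    data.frame(sample = sample, hap = 1L, chrom = "1", start_cm = from,
               end_cm = to, start_bp = from * 1e5, end_bp = to * 1e5,
               label = label, mean_posterior = 1, inherited = FALSE,
               stringsAsFactors = FALSE)
  full <- rbind(tract("x", 0, 60, "NAT"), tract("y", 0, 60, "NAT"))
  expect_equal(nrow(mask_by_ancestry(seg, full, "NAT")), 1L)
  half <- rbind(tract("x", 0, 60, "NAT"),
                tract("y", 0, 15, "NAT"), tract("y", 15, 60, "EUR"))
  expect_equal(nrow(mask_by_ancestry(seg, half, "NAT", 1.0)), 0L)
  expect_equal(nrow(mask_by_ancestry(seg, half, "NAT", 0.5)), 1L)
  expect_equal(nrow(mask_by_ancestry(seg, half, "NAT", 0.51)), 0L)
  expect_error(mask_by_ancestry(seg, tract("x", 0, 60, "NAT"), "NAT"),
               "missing ancestry tracts")
})

test_that("segment ages reproduce the generation-time arithmetic", {
  a <- segment_age(8.4)
  expect_equal(a$generations, 3 / (2 * 0.084))
  expect_equal(a$generations, 17.857, tolerance = 1e-3)
  expect_equal(a$years, 500, tolerance = 0.1)
  b <- segment_age(28)
  expect_equal(b$generations, 5.357, tolerance = 1e-3)
  expect_equal(b$years, 150, tolerance = 0.1)
  expect_equal(segment_age(150)$generations, 1)
  # strictly decreasing in length
  lens <- c(1, 2, 5, 8.4, 28, 100)
  expect_true(all(diff(segment_age(lens)$generations) < 0))
  expect_error(segment_age(0), "positive")
})

test_that("period bins use the quoted inclusive boundaries", {
  expect_equal(bin_to_period(8.4), "precolumbian")
  expect_equal(bin_to_period(8.41), "colonial")
  expect_equal(bin_to_period(10), "colonial")
  expect_equal(bin_to_period(28), "colonial")
  expect_equal(bin_to_period(30), "recent")
  # consistency with segment_age at the stated year boundaries
  expect_lt(segment_age(8.4)$years, 520)   # ~1500 CE from a ~2000 CE present
  expect_gt(segment_age(8.41)$years, 140)
  expect_equal(round(segment_age(28)$years), 150)
})

test_that("sharing networks normalize by sample-size products", {
  grouping <- setNames(c("P", "P", "Q", "Q", "Q"),
                       c("a1", "a2", "b1", "b2", "b3"))
  seg <- function(s1, s2, len) data.frame(
    sample1 = s1, hap1 = 1L, sample2 = s2, hap2 = 1L, chrom = "1",
    start_bp = 1, end_bp = 2, start_cm = 0, end_cm = len, length_cm = len,
    support = 10, n_snps = 50, ancestry = NA, stringsAsFactors = FALSE)
  one <- seg("a1", "b1", 6)
  net <- sharing_network(one, grouping, period = "precolumbian")
  expect_null(net$edges)                       # avg 6/(2*3) = 1 <= 5 cM
  expect_equal(net$excluded$avg_length_cm[
    net$excluded$pop1 == "P" & net$excluded$pop2 == "Q"], 1)
  many <- do.call(rbind, lapply(1:10, function(i) seg("a1", "b1", 6)))
  net2 <- sharing_network(many, grouping, period = "precolumbian")
  e <- net2$edges[net2$edges$pop1 == "P" & net2$edges$pop2 == "Q", ]
  expect_equal(e$avg_length_cm, 10)            # 60 / 6 -> retained
  expect_equal(e$avg_count, 10 / 6)
  # symmetric by construction: unordered pairs counted once
  many_rev <- do.call(rbind, lapply(1:10, function(i) seg("b1", "a1", 6)))
  rev <- sharing_network(many_rev, grouping, "precolumbian")
  expect_equal(rev$edges$avg_length_cm[rev$edges$pop1 == "P"], 10)
  # periods filter segments by their length class
  colonial <- sharing_network(seg("a1", "b1", 20), grouping, "precolumbian")
  expect_equal(sum(colonial$excluded$n_segments), 0)
})

test_that("length-category summaries bin lower-inclusively and recover counts", {
  grouping <- setNames(rep("P", 4), c("a", "b", "c", "d"))
  seg <- function(s1, s2, len) data.frame(
    sample1 = s1, hap1 = 1L, sample2 = s2, hap2 = 2L, chrom = "1",
    start_bp = 1, end_bp = 2, start_cm = 0, end_cm = len, length_cm = len,
    support = 10, n_snps = 50, ancestry = NA, stringsAsFactors = FALSE)
  segs <- rbind(seg("a", "b", 1.5), seg("a", "c", 4.0), seg("b", "c", 7.9),
                seg("a", "a", 17), seg("c", "d", 2))
  tab <- length_category_summary(segs, grouping)
  get <- function(type, bin) tab$n_segments[tab$type == type & tab$bin == bin]
  expect_equal(get("ibd", "1-2"), 1L)
  expect_equal(get("ibd", "4-8"), 2L)      # 4.0 goes in "4-8", boundary rule
  expect_equal(get("ibd", "2-4"), 1L)
  expect_equal(get("hbd", ">16"), 1L)
  expect_equal(sum(tab$n_segments), 5L)
  # per-pair normalization: 4 diploids -> 6 pairs
  expect_equal(tab$avg_count[tab$type == "ibd" & tab$bin == "2-4"], 1 / 6)
  # empty input gives the all-zero grid
  tab0 <- length_category_summary(segs[0, ], grouping)
  expect_true(all(tab0$n_segments == 0))
})

test_that("masking never increases segment count or total length", {
  panel <- make_iid_panel(n = 6, snps_per_chrom = 1500, n_chrom = 1,
                          length_cm = 50, seed = 66)
  pl <- plant_fixtures(panel, list(
    list(kind = "ibd", sample1 = "S001", sample2 = "S002", chrom = "1",
         start_cm = 10, end_cm = 25)), seed = 14)
  segs <- detect_ibd(pl$panel)
  tracts <- do.call(rbind, lapply(panel$sample_ids, function(s)
    do.call(rbind, lapply(1:2, function(h)
      data.frame(sample = s, hap = h, chrom = "1", start_cm = 0, end_cm = 50,
                 start_bp = 1, end_bp = 50e6, label = "NAT",
                 mean_posterior = 1, inherited = FALSE)))))
  masked <- mask_by_ancestry(segs, tracts, "NAT")
  expect_lte(nrow(masked), nrow(segs))
  expect_lte(sum(masked$length_cm), sum(segs$length_cm) + 1e-12)
})
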