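# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write.

# A small deterministic panel with i.i.d. background haplotypes (no
# coalescent sharing), mid-range MAF, suitable for planting detector truth.
make_iid_panel <- function(n = 10, snps_per_chrom = 1500, n_chrom = 2,
                           length_cm = 50, seed = 99, maf = c(0.2, 0.8),
                           phased = TRUE) {
  set.seed(seed)
  snp_table <- do.call(rbind, lapply(seq_len(n_chrom), function(c0) {
    cm <- length_cm * (seq_len(snps_per_chrom) - 0.5) / snps_per_chrom
    data.frame(chrom = as.character(c0), pos = as.integer(round(cm * 1e6)),
               cm = cm, ref = "A", alt = "G",
               id = paste0(c0, "_", seq_len(snps_per_chrom)),
               stringsAsFactors = FALSE)
  }))
  S <- nrow(snp_table)
  p <- runif(S, maf[1], maf[2])
  H <- matrix(rbinom(2L * n * S, 1L, rep(p, each = 2L * n)), 2L * n, S)
  storage.mode(H) <- "integer"
  geno <- H[seq(1, 2 * n, 2), , drop = FALSE] + H[seq(2, 2 * n, 2), , drop = FALSE]
  st <- data.frame(id = sprintf("S%03d", seq_len(n)),
                   population = rep_len(c("P1", "P2"), n),
                   major_group = "G1", lat = NA_real_, lon = NA_real_,
                   stringsAsFactors = FALSE)
  genotype_panel(geno, snp_table, st, haplotypes = if (phased) H else NULL)
}

# A tiny hand-constructed panel (3 samples x 5 SNPs) used in IO tests.
make_tiny_panel <- function(phased = TRUE) {
  snp_table <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L),
                          cm = c(0.01, 0.02, 0.03, 0.04, 0.05),
                          ref = c("A", "C", "G", "T", "A"),
                          alt = c("G", "T", "A", "C", "T"),
                          id = paste0("rs", 1:5), stringsAsFactors = FALSE)
  H <- matrix(c(0L, 1L, 1L, 0L, 0L,
                1L, 1L, 0L, 0L, 1L,
                0L, 0L, 1L, 1L, 0L,
                0L, 1L, 0L, 1L, 1L,
                1L, 0L, 0L, 0L, 0L,
                0L, 0L, 1L, 1L, 1L), nrow = 6, byrow = TRUE)
  geno <- H[c(1, 3, 5), ] + H[c(2, 4, 6), ]
  geno[2, 3] <- NA; H[3:4, 3] <- NA  # one missing call
  st <- data.frame(id = c("ind1", "ind2", "ind3"),
                   population = c("A", "A", "B"), major_group = "M",
                   lat = c(-10, -12, 3), lon = c(-70, -68, -55),
                   stringsAsFactors = FALSE)
  genotype_panel(geno, snp_table, st, haplotypes = if (phased) H else NULL)
}

# Frequency table built directly from given frequency/count matrices.
make_freq_table <- function(freq, count = NULL, cm = NULL) {
  if (is.null(count)) count <- matrix(1e9, nrow(freq), ncol(freq),
                                      dimnames = dimnames(freq))
  if (is.null(cm)) cm <- seq_len(ncol(freq))
  snp_table <- data.frame(chrom = "1", pos = seq_len(ncol(freq)), cm = cm,
                          ref = "A", alt = "G",
                          id = paste0("s", seq_len(ncol(freq))),
                          stringsAsFactors = FALSE)
  structure(list(freq = freq, count = count, snp_table = snp_table),
            class = "freq_table")
}
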