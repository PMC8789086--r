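#' Read a genotype panel from file
#'
#' Supported formats:
#' \describe{
#'   \item{`vcf`}{VCF 4.x with GT calls; phase is taken from `|` separators
#'     (all-`|` records populate the haplotype matrix). Genetic positions are
#'     read from a `CM` INFO tag when present, else set to bp / 1e6.}
#'   \item{`plink_text`}{`path.ped` + `path.map`. The map dialect used here
#'     has six columns (chrom, id, cm, pos, ref, alt) so that allele coding
#'     round-trips; the `.ped` allele pairs are stored in haplotype order.}
#'   \item{`eigenstrat_text`}{`path.geno` (one digit row per SNP, 0/1/2/9 =
#'     ALT dosage), `path.snp` (id, chrom, cm, pos, ref, alt), `path.ind`
#'     (id, sex, population).}
#' }
#' A sidecar metadata table `path.meta` (tab-separated: id, population,
#' major_group, lat, lon) is read when present.
#'
#' @param path File path (for `plink_text`/`eigenstrat_text`, the prefix).
#' @param format One of `"vcf"`, `"plink_text"`, `"eigenstrat_text"`.
#' @return A `genotype_panel`.
#' @export
read_panel <- function(path, format = c("vcf", "plink_text", "eigenstrat_text")) {
  format <- match.arg(format)
  panel <- switch(format,
    vcf = read_panel_vcf(path),
    plink_text = read_panel_plink(path),
    eigenstrat_text = read_panel_eigenstrat(path))
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    i <- match(panel$sample_ids, meta$id)
    if (anyNA(i)) stop("metadata table does not cover all samples")
    st <- meta[i, , drop = FALSE]
    rownames(st) <- NULL
    panel <- genotype_panel(panel$genotypes, panel$snp_table, st,
                            haplotypes = panel$haplotypes)
  }
  panel
}

#' Write a genotype panel to file
#'
#' Inverse of [read_panel()]; the round trip is lossless for genotypes,
#' positions, alleles and cM, and for phase in the VCF format (the PLINK and
#' EIGENSTRAT text dialects are genotype-level; phase is dropped with a
#' warning).
#'
#' @param panel A `genotype_panel`.
#' @param path Output path (prefix for the multi-file formats).
#' @param format One of `"vcf"`, `"plink_text"`, `"eigenstrat_text"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("vcf", "plink_text", "eigenstrat_text")) {
  format <- match.arg(format)
  switch(format,
    vcf = write_panel_vcf(panel, path),
    plink_text = write_panel_plink(panel, path),
    eigenstrat_text = write_panel_eigenstrat(panel, path))
  st <- panel$sample_table
  for (col in c("population", "major_group", "lat", "lon"))
    if (is.null(st[[col]])) st[[col]] <- NA
  utils::write.table(st[, c("id", "population", "major_group", "lat", "lon")],
                     paste0(path, ".meta"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_panel_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic ALT records are not supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  n <- ncol(gt); s <- nrow(gt)
  flat <- as.vector(gt)
  flat[is.na(flat)] <- "./."
  phased_call <- grepl("|", flat, fixed = TRUE)
  alleles <- strsplit(gsub("|", "/", flat, fixed = TRUE), "/", fixed = TRUE)
  len <- lengths(alleles)
  if (any(len != 2L)) {
    bad <- which(len != 2L)[1]
    stop(sprintf("inconsistent ploidy at SNP line %d (GT '%s')",
                 (bad - 1L) %% s + 1L, flat[bad]))
  }
  am <- matrix(suppressWarnings(as.integer(unlist(alleles))), nrow = 2L)
  a1 <- matrix(am[1L, ], nrow = s); a2 <- matrix(am[2L, ], nrow = s)
  geno <- t(a1 + a2)                      # samples x SNPs
  cm <- NULL
  if (!is.null(fix$INFO) && any(grepl("CM=", fix$INFO)))
    cm <- suppressWarnings(as.numeric(sub(".*CM=([0-9eE.+-]+).*", "\\1", fix$INFO)))
  if (is.null(cm) || anyNA(cm)) cm <- as.numeric(fix$POS) / 1e6
  snp_table <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                          cm = cm, ref = fix$REF, alt = fix$ALT,
                          id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                      paste0(fix$CHROM, "_", fix$POS), fix$ID),
                          stringsAsFactors = FALSE)
  haplotypes <- NULL
  called <- grepl("^[0-9]", flat)
  if (any(called) && all(phased_call[called])) {
    haplotypes <- matrix(NA_integer_, 2L * n, s)
    haplotypes[seq(1L, 2L * n, 2L), ] <- t(a1)
    haplotypes[seq(2L, 2L * n, 2L), ] <- t(a2)
  }
  sample_table <- data.frame(id = colnames(gt), population = NA,
                             major_group = NA, lat = NA, lon = NA,
                             stringsAsFactors = FALSE)
  genotype_panel(geno, snp_table, sample_table, haplotypes = haplotypes)
}

write_panel_vcf <- function(panel, path) {
  st <- panel$snp_table
  n <- n_samples(panel)
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic position in cM\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  sep <- if (is_phased(panel)) "|" else "/"
  if (is_phased(panel)) {
    a1 <- t(panel$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE])
    a2 <- t(panel$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE])
  } else {
    g <- t(panel$genotypes)                         # SNPs x samples
    a1 <- ifelse(g >= 1L, 1L, 0L); a2 <- ifelse(g == 2L, 1L, 0L)
    a1[is.na(g)] <- NA; a2[is.na(g)] <- NA
  }
  gt <- matrix(paste(a1, a2, sep = sep), nrow = n_snps(panel))
  gt[is.na(a1)] <- paste0(".", sep, ".")
  lines <- paste(st$chrom, st$pos, st$id, st$ref, st$alt, ".", "PASS",
                 sprintf("CM=%.8g", st$cm), "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, lines), path)
}

read_panel_plink <- function(path) {
  map_path <- paste0(path, ".map"); ped_path <- paste0(path, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path))
    stop("missing .ped/.map pair at prefix ", path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 6) stop("map dialect requires 6 columns (chrom id cm pos ref alt)")
  names(map) <- c("chrom", "id", "cm", "pos", "ref", "alt")
  s <- nrow(map)
  ped <- readLines(ped_path)
  toks <- strsplit(trimws(ped), "[ \t]+")
  n <- length(toks)
  geno <- matrix(NA_integer_, n, s)
  ids <- character(n)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) != 6 + 2 * s)
      stop(sprintf("malformed .ped record at line %d: %d fields, expected %d",
                   i, length(tk), 6 + 2 * s))
    ids[i] <- tk[2]
    al <- tk[-(1:6)]
    a1 <- al[seq(1, 2 * s, 2)]; a2 <- al[seq(2, 2 * s, 2)]
    d <- (a1 == map$alt) + (a2 == map$alt)
    d[a1 == "0" | a2 == "0"] <- NA
    bad <- !(a1 %in% c("0", map$ref, map$alt) & a2 %in% c("0", map$ref, map$alt))
    if (any(bad & !is.na(d)))
      stop(sprintf("malformed allele in .ped line %d", i))
    geno[i, ] <- as.integer(d)
  }
  snp_table <- data.frame(chrom = map$chrom, pos = as.integer(map$pos),
                          cm = as.numeric(map$cm), ref = map$ref,
                          alt = map$alt, id = map$id, stringsAsFactors = FALSE)
  sample_table <- data.frame(id = ids, population = NA, major_group = NA,
                             lat = NA, lon = NA, stringsAsFactors = FALSE)
  genotype_panel(geno, snp_table, sample_table)
}

write_panel_plink <- function(panel, path) {
  if (is_phased(panel))
    warning("plink_text is a genotype-level format; phase is not written")
  st <- panel$snp_table
  utils::write.table(st[, c("chrom", "id", "cm", "pos", "ref", "alt")],
                     paste0(path, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- panel$genotypes
  pop <- panel$sample_table$population
  pop[is.na(pop)] <- "0"
  lines <- vapply(seq_len(n_samples(panel)), function(i) {
    gi <- g[i, ]
    a1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, st$alt, st$ref))
    a2 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, st$alt, st$ref))
    paste(c(pop[i], panel$sample_ids[i], "0", "0", "0", "-9",
            as.vector(rbind(a1, a2))), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(path, ".ped"))
}

read_panel_eigenstrat <- function(path) {
  snp_path <- paste0(path, ".snp"); geno_path <- paste0(path, ".geno")
  ind_path <- paste0(path, ".ind")
  for (p in c(snp_path, geno_path, ind_path))
    if (!file.exists(p)) stop("missing EIGENSTRAT file: ", p)
  snp <- utils::read.table(snp_path, header = FALSE, stringsAsFactors = FALSE)
  names(snp) <- c("id", "chrom", "cm", "pos", "ref", "alt")[seq_len(ncol(snp))]
  rows <- readLines(geno_path)
  if (length(rows) != nrow(snp)) stop(".geno row count disagrees with .snp")
  wid <- nchar(rows)
  if (length(unique(wid)) != 1)
    stop(sprintf("malformed .geno record at line %d: ragged row widths",
                 which(wid != wid[1])[1]))
  m <- matrix(as.integer(unlist(strsplit(rows, "", fixed = TRUE))),
              nrow = length(rows), byrow = TRUE)
  m[m == 9L] <- NA_integer_
  ind <- utils::read.table(ind_path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(ind) != ncol(m)) stop(".ind row count disagrees with .geno columns")
  snp_table <- data.frame(chrom = snp$chrom, pos = as.integer(snp$pos),
                          cm = as.numeric(snp$cm), ref = snp$ref,
                          alt = snp$alt, id = snp$id, stringsAsFactors = FALSE)
  sample_table <- data.frame(id = ind[[1]], population = ind[[3]],
                             major_group = NA, lat = NA, lon = NA,
                             stringsAsFactors = FALSE)
  genotype_panel(t(m), snp_table, sample_table)
}

write_panel_eigenstrat <- function(panel, path) {
  if (is_phased(panel))
    warning("eigenstrat_text is a genotype-level format; phase is not written")
  st <- panel$snp_table
  utils::write.table(st[, c("id", "chrom", "cm", "pos", "ref", "alt")],
                     paste0(path, ".snp"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- t(panel$genotypes)                            # SNPs x samples
  g[is.na(g)] <- 9L
  writeLines(apply(g, 1L, paste, collapse = ""), paste0(path, ".geno"))
  pop <- panel$sample_table$population
  pop[is.na(pop)] <- "Unknown"
  utils::write.table(data.frame(panel$sample_ids, "U", pop),
                     paste0(path, ".ind"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
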