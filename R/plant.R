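#' Plant ground-truth fixtures into a phased panel
#'
#' Constructive fixtures for detector tests: exact IBD is created by copying
#' a haplotype stretch between designated haplotypes; HBD/ROH by copying one
#' of an individual's haplotypes over its partner; relatives by Mendelian
#' transmission with Poisson crossovers. An optional per-site error rate is
#' applied after planting.
#'
#' @param panel A phased `genotype_panel`.
#' @param plants List of plant requests, each a list with a `kind` field:
#'   \describe{
#'     \item{ibd}{`sample1`, `hap1`, `sample2`, `hap2`, `chrom`, `start_cm`,
#'       `end_cm`: copies the stretch from haplotype (`sample1`, `hap1`) onto
#'       (`sample2`, `hap2`).}
#'     \item{roh}{`sample`, `chrom`, `start_cm`, `end_cm` (omit the bounds
#'       for the whole chromosome): copies haplotype 1 over haplotype 2.}
#'     \item{parent_offspring}{`parent`, `child`: haplotype 1 of the child is
#'       replaced by a recombinant gamete of the parent (expected PI_HAT 0.5).}
#'     \item{full_sibs}{`parent1`, `parent2`, `child1`, `child2`: both
#'       children rebuilt from gametes of the same two parents.}
#'   }
#' @param seed Integer seed for crossovers and planted errors.
#' @param error_rate Per-site allele flip probability applied after planting
#'   (default 0).
#' @param flank_mismatch Sharpen planted interval boundaries by forcing the
#'   two SNPs immediately outside each end to mismatch (IBD) or be
#'   heterozygous (ROH), so the planted truth is defined to the SNP
#'   (default `TRUE`).
#' @return A list with `panel` (modified) and `truth` (data frames `ibd`,
#'   `roh`, `relatives` recording the planted coordinates/classes).
#' @export
plant_fixtures <- function(panel, plants, seed = 1, error_rate = 0,
                           flank_mismatch = TRUE) {
  if (!is_phased(panel)) stop("plant_fixtures requires a phased panel")
  set.seed(seed)
  H <- panel$haplotypes
  st <- panel$snp_table
  layout <- chrom_layout(st)
  hap_row <- function(sample, hap) {
    i <- match(sample, panel$sample_ids)
    if (is.na(i)) stop("unknown sample: ", sample)
    2L * i - 2L + as.integer(hap)
  }
  written <- list()  # per target hap row: list of written index ranges
  claim <- function(row, idx) {
    key <- as.character(row)
    for (rg in written[[key]])
      if (max(min(idx), min(rg)) <= min(max(idx), max(rg)))
        stop("overlapping contradictory plant requests on haplotype row ", row)
    written[[key]] <<- c(written[[key]], list(range(idx)))
  }
  span_idx <- function(chrom, start_cm, end_cm) {
    ly <- layout[[as.character(chrom)]]
    if (is.null(ly)) stop("unknown chromosome: ", chrom)
    if (is.null(start_cm)) return(ly$idx)
    ly$idx[ly$cm >= start_cm & ly$cm <= end_cm]
  }
  truth_ibd <- list(); truth_roh <- list(); truth_rel <- list()

  for (pl in plants) {
    kind <- pl$kind
    if (kind == "ibd") {
      idx <- span_idx(pl$chrom, pl$start_cm, pl$end_cm)
      if (length(idx) == 0) stop("empty planted interval")
      r1 <- hap_row(pl$sample1, pl$hap1 %||% 1L)
      r2 <- hap_row(pl$sample2, pl$hap2 %||% 1L)
      claim(r2, idx)
      H[r2, idx] <- H[r1, idx]
      if (flank_mismatch) {
        ly <- layout[[as.character(pl$chrom)]]
        for (fl in c(idx[1] - 1:2, idx[length(idx)] + 1:2))
          if (fl %in% ly$idx) H[r2, fl] <- 1L - H[r1, fl]
      }
      truth_ibd[[length(truth_ibd) + 1L]] <- data.frame(
        sample1 = pl$sample1, hap1 = pl$hap1 %||% 1L,
        sample2 = pl$sample2, hap2 = pl$hap2 %||% 1L,
        chrom = as.character(pl$chrom),
        start_bp = st$pos[idx[1]], end_bp = st$pos[idx[length(idx)]],
        start_cm = st$cm[idx[1]], end_cm = st$cm[idx[length(idx)]],
        length_cm = st$cm[idx[length(idx)]] - st$cm[idx[1]],
        stringsAsFactors = FALSE)
    } else if (kind == "roh" || kind == "hbd") {
      idx <- span_idx(pl$chrom, pl$start_cm, pl$end_cm)
      r1 <- hap_row(pl$sample, 1L); r2 <- hap_row(pl$sample, 2L)
      claim(r2, idx)
      H[r2, idx] <- H[r1, idx]
      if (flank_mismatch) {
        ly <- layout[[as.character(pl$chrom)]]
        for (fl in c(idx[1] - 1:2, idx[length(idx)] + 1:2))
          if (fl %in% ly$idx) H[r2, fl] <- 1L - H[r1, fl]
      }
      truth_roh[[length(truth_roh) + 1L]] <- data.frame(
        sample = pl$sample, chrom = as.character(pl$chrom),
        start_bp = st$pos[idx[1]], end_bp = st$pos[idx[length(idx)]],
        start_cm = st$cm[idx[1]], end_cm = st$cm[idx[length(idx)]],
        stringsAsFactors = FALSE)
    } else if (kind == "parent_offspring") {
      rp <- hap_row(pl$parent, 1L); rc <- hap_row(pl$child, 1L)
      claim(rc, seq_len(ncol(H)))
      sel <- gamete_take2(layout)
      g <- H[rp, ]; g[sel] <- H[rp + 1L, ][sel]
      H[rc, ] <- g
      truth_rel[[length(truth_rel) + 1L]] <- data.frame(
        sample1 = pl$parent, sample2 = pl$child,
        class = "parent_offspring", stringsAsFactors = FALSE)
    } else if (kind == "full_sibs") {
      for (ch in c(pl$child1, pl$child2)) {
        for (k in 1:2) {
          rp <- hap_row(if (k == 1) pl$parent1 else pl$parent2, 1L)
          rc <- hap_row(ch, k)
          claim(rc, seq_len(ncol(H)))
          sel <- gamete_take2(layout)
          g <- H[rp, ]; g[sel] <- H[rp + 1L, ][sel]
          H[rc, ] <- g
        }
      }
      truth_rel[[length(truth_rel) + 1L]] <- data.frame(
        sample1 = pl$child1, sample2 = pl$child2,
        class = "full_sibs", stringsAsFactors = FALSE)
    } else stop("unknown plant kind: ", kind)
  }

  if (error_rate > 0) {
    flip <- matrix(stats::runif(length(H)) < error_rate, nrow(H), ncol(H))
    flip[is.na(H)] <- FALSE
    H[flip] <- 1L - H[flip]
  }
  n <- n_samples(panel)
  geno <- H[seq(1L, 2L * n, 2L), , drop = FALSE] +
          H[seq(2L, 2L * n, 2L), , drop = FALSE]
  out <- genotype_panel(geno, st, panel$sample_table, haplotypes = H)
  bind0 <- function(x) if (length(x)) do.call(rbind, x) else NULL
  list(panel = out,
       truth = list(ibd = bind0(truth_ibd), roh = bind0(truth_roh),
                    relatives = bind0(truth_rel)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
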