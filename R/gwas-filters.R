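#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the heterozygote count given the allele
#' counts: enumerates every attainable heterozygote count, computes its
#' conditional probability under HWE, and sums the probabilities of all
#' tables no more probable than the observed one (two-sided, the standard
#' exact HWE p-value).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)      # monomorphic: single table
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  # log P(het | allele counts) up to a constant
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    h * log(2) - lfactorial(aa) - lfactorial(h) - lfactorial(bb)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Variant quality-control filtering
#'
#' Applies the standard imputation-era SNP filters — imputation INFO score,
#' call rate, minor allele frequency and Hardy-Weinberg equilibrium — and
#' returns the per-SNP pass/fail table with the reason for every
#' exclusion. MAF, call rate and (for integral dosages) HWE are computed
#' from the dosage matrix when not supplied in `variant_meta`.
#'
#' @param genotypes n x M dosage matrix in [0, 2] (NA = missing).
#' @param variant_meta data.frame with `snp_id` and optionally `info`,
#'   `maf`, `call_rate`, `hwe_p` columns (computed values used otherwise).
#' @param info_min,call_rate_min,maf_min,hwe_p_min filter thresholds;
#'   variants failing any are excluded.
#' @return data.frame of class `variant_filter`: snp_id, maf, call_rate,
#'   hwe_p, info, keep, reason ("" when kept).
#' @export
filter_variants <- function(genotypes, variant_meta,
                            info_min = 0.8, call_rate_min = 0.95,
                            maf_min = 0.01, hwe_p_min = 1e-6) {
  M <- ncol(genotypes)
  stopifnot(nrow(variant_meta) == M)
  ok_range <- genotypes >= 0 & genotypes <= 2
  if (any(!ok_range, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  call_rate <- variant_meta$call_rate %||% colMeans(!is.na(genotypes))
  freq <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- variant_meta$maf %||% pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  hwe_p <- variant_meta$hwe_p
  if (is.null(hwe_p)) {
    hwe_p <- vapply(seq_len(M), function(j) {
      g <- genotypes[, j]
      g <- g[!is.na(g)]
      if (!length(g) || any(abs(g - round(g)) > 1e-6)) return(1)  # dosage data
      g <- round(g)
      hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    }, 0)
  }
  info <- variant_meta$info %||% rep(1, M)
  reason <- character(M)
  reason[hwe_p < hwe_p_min] <- "hwe"
  reason[maf < maf_min] <- "maf"
  reason[call_rate < call_rate_min] <- "call_rate"
  reason[info < info_min] <- "info"
  keep <- reason == ""
  if (!any(keep)) warning("no variants pass the QC filters")
  out <- data.frame(snp_id = variant_meta$snp_id, maf = maf,
                    call_rate = call_rate, hwe_p = hwe_p, info = info,
                    keep = keep, reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("variant_filter", "data.frame")
  out
}

#' Ancestry principal components from LD-pruned common variants
#'
#' Selects high-call-rate common SNPs, greedily prunes for linkage
#' disequilibrium (scanning by position, a SNP is kept only if its r^2
#' with every already-kept SNP within the window is below `r2_max`), and
#' returns the leading principal-component scores of the standardized
#' dosage matrix — the usual adjustment for population structure.
#'
#' @param genotypes n x M dosage matrix.
#' @param variant_meta data.frame with `chrom` and `pos` (1-based).
#' @param n_pcs number of PCs to return (4 by default).
#' @param maf_min,call_rate_min marker inclusion thresholds.
#' @param r2_max pairwise r^2 ceiling for pruning.
#' @param window_bp pruning window (10 Mb).
#' @return n x n_pcs matrix of PC scores, with attributes `kept_snps`
#'   (column indices used) and `var_explained`.
#' @export
compute_ancestry_pcs <- function(genotypes, variant_meta, n_pcs = 4L,
                                 maf_min = 0.05, call_rate_min = 0.95,
                                 r2_max = 0.1, window_bp = 1e7) {
  M <- ncol(genotypes)
  stopifnot(nrow(variant_meta) == M)
  freq <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  call_rate <- colMeans(!is.na(genotypes))
  cand <- which(maf >= maf_min & call_rate >= call_rate_min)
  # standardize once (mean-impute missing) so pairwise r is a cross product
  Gs <- genotypes[, cand, drop = FALSE]
  Gs <- apply(Gs, 2L, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    s <- sd(g)
    if (s == 0) rep(0, length(g)) else (g - mean(g)) / s
  })
  n <- nrow(genotypes)
  kept <- integer(0)
  ord <- order(variant_meta$chrom[cand], variant_meta$pos[cand])
  for (jj in ord) {
    j <- cand[jj]
    near <- which(variant_meta$chrom[kept] == variant_meta$chrom[j] &
                    abs(variant_meta$pos[kept] - variant_meta$pos[j]) <=
                    window_bp)
    ok <- TRUE
    if (length(near)) {
      r <- crossprod(Gs[, match(kept[near], cand), drop = FALSE],
                     Gs[, jj]) / (n - 1)
      if (any(r^2 >= r2_max, na.rm = TRUE)) ok <- FALSE
    }
    if (ok) kept <- c(kept, j)
  }
  if (length(kept) < n_pcs) {
    stop("only ", length(kept), " SNPs survive LD pruning; need >= ", n_pcs)
  }
  G <- genotypes[, kept, drop = FALSE]
  G <- apply(G, 2L, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  G <- scale(G)
  G[, colSums(is.na(G)) > 0] <- 0
  pc <- prcomp(G, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  attr(scores, "kept_snps") <- kept
  attr(scores, "var_explained") <-
    (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pcs)]
  scores
}
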