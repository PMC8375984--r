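#' Simulate genotype dosages with population divergence and local LD
#'
#' Draws ancestral allele frequencies uniformly on `maf_range`, diverges
#' them into per-population frequencies with the Balding-Nichols Beta model
#' (variance `fst * p * (1 - p)`), and samples two haplotypes per subject
#' from a latent Gaussian first-order autoregressive process (parameter
#' `ld_rho`) thresholded at each SNP's frequency. The latent-AR construction
#' preserves the per-SNP marginal frequency exactly while inducing
#' decaying linkage disequilibrium between neighbouring SNPs; for SNPs of
#' similar frequency the adjacent-genotype correlation is approximately
#' `ld_rho` (attenuated by the dichotomization).
#'
#' @param n_subjects number of diploid subjects.
#' @param n_snps number of SNPs on a single chromosome, positions spaced
#'   5 kb apart so a +/-500 kb locus holds about 200 SNPs.
#' @param maf_range length-2 numeric in (0, 0.5], range of ancestral minor
#'   allele frequencies.
#' @param fst Balding-Nichols divergence in [0, 1); 0 reuses the ancestral
#'   frequencies unchanged.
#' @param ld_rho latent AR(1) parameter in [0, 1).
#' @param seed integer seed.
#' @param ancestral_freqs optional vector of ancestral frequencies to reuse
#'   (as when simulating a second cohort from the same ancestral pool).
#' @param chrom chromosome name for the variant metadata.
#' @return list with `genotypes` (n x M dosage matrix in 0..2, column names
#'   = snp ids), `variant_meta` (data.frame: snp_id, chrom, pos, ref, alt,
#'   info, freq), and `ancestral_freqs`.
#' @export
simulate_genotypes <- function(n_subjects, n_snps, maf_range = c(0.05, 0.5),
                               fst = 0, ld_rho = 0, seed = 1L,
                               ancestral_freqs = NULL, chrom = "1") {
  stopifnot(length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  set.seed(seed)
  p_anc <- ancestral_freqs %||% runif(n_snps, maf_range[1], maf_range[2])
  stopifnot(length(p_anc) == n_snps)
  if (fst > 0) {
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    p <- rbeta(n_snps, a, b)
    # keep SNPs polymorphic so downstream QC has something to retain
    p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  } else {
    p <- p_anc
  }
  thr <- qnorm(p)
  hap <- function() {
    z <- matrix(rnorm(n_subjects * n_snps), n_subjects, n_snps)
    if (ld_rho > 0 && n_snps > 1L) {
      for (j in 2:n_snps) {
        z[, j] <- ld_rho * z[, j - 1L] + sqrt(1 - ld_rho^2) * z[, j]
      }
    }
    # allele = 1 when the latent value falls below the frequency threshold
    (z < matrix(thr, n_subjects, n_snps, byrow = TRUE)) + 0
  }
  G <- hap() + hap()
  ids <- sprintf("rs%06d", seq_len(n_snps))
  colnames(G) <- ids
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  meta <- data.frame(snp_id = ids, chrom = chrom,
                     pos = 5000L * seq_len(n_snps),
                     ref = ref, alt = unname(alt),
                     info = round(runif(n_snps, 0.82, 1), 4),
                     freq = p, stringsAsFactors = FALSE)
  list(genotypes = G, variant_meta = meta, ancestral_freqs = p_anc)
}
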