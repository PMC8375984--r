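#' Canonical correlation association test for one SNP
#'
#' Tests a single SNP against a multivariate segment phenotype by
#' canonical correlation under the additive model. With a univariate
#' predictor the first (only) canonical correlation satisfies
#' \code{r^2 = R^2} of the regression of dosage on the k PC columns, and
#' Rao's F approximation is exact:
#' \code{F = (r^2 / k) / ((1 - r^2) / (n - k - 1))} on (k, n - k - 1)
#' degrees of freedom, with the p-value from the right tail (one-sided).
#' The canonical loading is the unit-norm PC weight vector that maximizes
#' the correlation, its sign fixed by making its largest-magnitude entry
#' positive.
#'
#' @param dosage length-n dosage vector in [0, 2] (NA = missing; subjects
#'   missing this SNP are dropped for this SNP only).
#' @param scores n x k matrix of retained PC scores.
#' @param snp_id,segment_id identifiers copied into the record.
#' @return list of class `association_record`: snp_id, segment_id,
#'   canonical_r, f_stat, df1, df2, p, loading, n, flag
#'   ("zero_variance" when the dosage does not vary, in which case p = 1).
#' @export
cca_association <- function(dosage, scores, snp_id = NA_character_,
                            segment_id = NA_integer_) {
  scores <- as.matrix(scores)
  keep <- !is.na(dosage) & stats::complete.cases(scores)
  g <- dosage[keep]
  Y <- scores[keep, , drop = FALSE]
  n <- length(g)
  k <- ncol(Y)
  if (n <= k + 1L) stop("insufficient complete cases (n = ", n,
                        ") for k = ", k, " phenotype dimensions")
  rec <- list(snp_id = snp_id, segment_id = segment_id, canonical_r = 0,
              f_stat = 0, df1 = k, df2 = n - k - 1L, p = 1,
              loading = rep(0, k), n = n, flag = "")
  if (var(g) == 0) {
    rec$flag <- "zero_variance"
    class(rec) <- "association_record"
    return(rec)
  }
  gc <- g - mean(g)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  fit <- lm.fit(Yc, gc)
  rss <- sum(fit$residuals^2)
  tss <- sum(gc^2)
  r2 <- max(0, min(1, 1 - rss / tss))
  b <- fit$coefficients
  b[is.na(b)] <- 0
  nb <- sqrt(sum(b^2))
  if (nb > 0) {
    b <- b / nb
    i <- which.max(abs(b))
    if (b[i] < 0) b <- -b
  }
  f <- (r2 / k) / ((1 - r2) / (n - k - 1L))
  rec$canonical_r <- sqrt(r2)
  rec$f_stat <- f
  rec$p <- pf(f, k, n - k - 1L, lower.tail = FALSE)
  rec$loading <- b
  class(rec) <- "association_record"
  rec
}

#' Li-Ji effective number of independent tests
#'
#' From the eigenvalues of the absolute-value correlation matrix:
#' \code{Meff = sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]}.
#' Perfectly correlated traits collapse to one effective test; independent
#' traits each count fully.
#'
#' @param correlation_matrix symmetric correlation matrix with unit
#'   diagonal.
#' @return Meff (real, between 1 and M).
#' @export
liji_meff <- function(correlation_matrix) {
  C <- as.matrix(correlation_matrix)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8) {
    stop("correlation matrix must be symmetric")
  }
  lam <- eigen(abs(C), symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  sum((lam >= 1) + (lam - floor(lam)))
}

#' Genome-wide and study-wide significance thresholds
#'
#' The study-wide threshold divides the genome-wide threshold by the
#' effective number of independent phenotypes (Li-Ji Meff), Bonferroni
#' style.
#'
#' @param genome_wide genome-wide per-SNP threshold (default 2.5e-8, the
#'   conventional value for African-ancestry panels).
#' @param meff_phenotypes effective number of independent phenotypes.
#' @return list of class `scan_thresholds`: genome_wide, meff_phenotypes,
#'   study_wide.
#' @export
derive_thresholds <- function(genome_wide = 2.5e-8, meff_phenotypes) {
  stopifnot(meff_phenotypes >= 1)
  structure(list(genome_wide = genome_wide,
                 meff_phenotypes = meff_phenotypes,
                 study_wide = genome_wide / meff_phenotypes),
            class = "scan_thresholds")
}

#' CCA genome scan over all segment phenotypes
#'
#' Runs the canonical correlation association of every SNP against every
#' segment's retained-PC phenotype, computes the Li-Ji effective number of
#' phenotypes from the correlation matrix of the segments' first PC
#' scores, derives the study-wide threshold, and summarizes each SNP's
#' best segment and its count of genome-wide-significant segments.
#'
#' @param segment_models list of `segment_model`s (e.g. from
#'   [fit_all_segments()]).
#' @param genotypes n x M dosage matrix (columns named by SNP id).
#' @param variant_meta data.frame with snp_id, chrom, pos (joined onto the
#'   outputs; optional).
#' @param genome_wide genome-wide significance threshold.
#' @return list of class `scan_result`: `associations` (data.frame, one
#'   row per SNP x segment), `per_snp` (best segment, min p, significant
#'   segment count, chrom/pos), `meff`, `thresholds`.
#' @export
run_scan <- function(segment_models, genotypes, variant_meta = NULL,
                     genome_wide = 2.5e-8) {
  n <- nrow(genotypes)
  M <- ncol(genotypes)
  for (sm in segment_models) {
    if (nrow(sm$scores) != n) stop("subject mismatch between phenotypes ",
                                   "and genotypes")
  }
  snp_ids <- colnames(genotypes) %||% sprintf("snp%06d", seq_len(M))
  res <- vector("list", length(segment_models))
  has_na <- anyNA(genotypes)
  for (si in seq_along(segment_models)) {
    sm <- segment_models[[si]]
    k <- ncol(sm$scores)
    seg_id <- sm$segment_id
    if (M == 0L) {
      res[[si]] <- data.frame(snp_id = character(0), segment_id = integer(0),
                              canonical_r = numeric(0), f_stat = numeric(0),
                              df1 = integer(0), df2 = integer(0),
                              p = numeric(0))
      next
    }
    if (!has_na) {
      Z <- scale(sm$scores, center = TRUE, scale = FALSE)
      Q <- qr.Q(qr(Z))
      Gc <- scale(genotypes, center = TRUE, scale = FALSE)
      tot <- colSums(Gc^2)
      expl <- colSums(crossprod(Q, Gc)^2)
      r2 <- ifelse(tot > 0, pmin(1, expl / tot), 0)
      f <- (r2 / k) / ((1 - r2) / (n - k - 1L))
      p <- pf(f, k, n - k - 1L, lower.tail = FALSE)
      p[tot == 0] <- 1
      f[tot == 0] <- 0
      res[[si]] <- data.frame(snp_id = snp_ids, segment_id = seg_id,
                              canonical_r = sqrt(r2), f_stat = f, df1 = k,
                              df2 = n - k - 1L, p = p,
                              stringsAsFactors = FALSE)
    } else {
      rows <- lapply(seq_len(M), function(j) {
        r <- cca_association(genotypes[, j], sm$scores, snp_ids[j], seg_id)
        data.frame(snp_id = r$snp_id, segment_id = r$segment_id,
                   canonical_r = r$canonical_r, f_stat = r$f_stat,
                   df1 = r$df1, df2 = r$df2, p = r$p,
                   stringsAsFactors = FALSE)
      })
      res[[si]] <- do.call(rbind, rows)
    }
  }
  assoc <- do.call(rbind, res)
  pc1 <- vapply(segment_models, function(sm) sm$scores[, 1L], numeric(n))
  meff <- liji_meff(cor(pc1))
  thresholds <- derive_thresholds(genome_wide, meff)
  per_snp <- NULL
  if (M > 0L) {
    sp <- split(assoc, assoc$snp_id)
    per_snp <- do.call(rbind, lapply(sp, function(d) {
      i <- which.min(d$p)
      data.frame(snp_id = d$snp_id[1], best_segment_id = d$segment_id[i],
                 min_p = d$p[i],
                 n_significant_segments = sum(d$p < genome_wide),
                 stringsAsFactors = FALSE)
    }))
    per_snp <- per_snp[match(snp_ids, per_snp$snp_id), ]
    rownames(per_snp) <- NULL
    if (!is.null(variant_meta)) {
      mi <- match(per_snp$snp_id, variant_meta$snp_id)
      per_snp$chrom <- variant_meta$chrom[mi]
      per_snp$pos <- variant_meta$pos[mi]
    }
  }
  structure(list(associations = assoc, per_snp = per_snp, meff = meff,
                 thresholds = thresholds),
            class = "scan_result")
}

#' Greedy clumping of significant SNPs into loci
#'
#' Repeatedly takes the most significant unassigned SNP as the lead and
#' absorbs every significant SNP within the window on the same chromosome.
#' Ties on p are broken by smaller position, then lexicographic SNP id.
#'
#' @param per_snp data.frame with snp_id, chrom, pos, min_p (e.g. the
#'   `per_snp` table of a `scan_result`), plus optionally
#'   best_segment_id / n_significant_segments which are copied onto the
#'   locus.
#' @param threshold significance threshold defining which SNPs seed/join
#'   loci.
#' @param window half-width in bp (default 500 kb: the locus is lead
#'   position +/- window).
#' @return data.frame of class `locus_table`: one row per locus with
#'   lead_snp, chrom, pos, window_start, window_end, n_members,
#'   member_snps (list column), best_segment_id, n_significant_segments,
#'   min_p.
#' @export
define_loci <- function(per_snp, threshold = 2.5e-8, window = 500000L) {
  sig <- per_snp[!is.na(per_snp$min_p) & per_snp$min_p < threshold, ,
                 drop = FALSE]
  loci <- list()
  while (nrow(sig) > 0L) {
    ord <- order(sig$min_p, sig$pos, sig$snp_id)
    lead <- sig[ord[1L], ]
    inwin <- sig$chrom == lead$chrom & abs(sig$pos - lead$pos) <= window
    members <- sig[inwin, ]
    loci[[length(loci) + 1L]] <- data.frame(
      lead_snp = lead$snp_id, chrom = lead$chrom, pos = lead$pos,
      window_start = max(1L, lead$pos - window), window_end = lead$pos + window,
      n_members = nrow(members),
      best_segment_id = if (!is.null(lead$best_segment_id))
        lead$best_segment_id else NA_integer_,
      n_significant_segments = if (!is.null(lead$n_significant_segments))
        lead$n_significant_segments else NA_integer_,
      min_p = lead$min_p, stringsAsFactors = FALSE)
    loci[[length(loci)]]$member_snps <- I(list(members$snp_id))
    sig <- sig[!inwin, , drop = FALSE]
  }
  out <- if (length(loci)) do.call(rbind, loci) else
    data.frame(lead_snp = character(0), chrom = character(0),
               pos = integer(0), window_start = integer(0),
               window_end = integer(0), n_members = integer(0),
               best_segment_id = integer(0),
               n_significant_segments = integer(0), min_p = numeric(0),
               member_snps = I(list()))
  class(out) <- c("locus_table", "data.frame")
  out
}
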