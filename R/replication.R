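#' Projection model: a source cohort's segment phenotype, portable to
#' another cohort
#'
#' Bundles everything needed to express a target cohort's faces in the
#' source cohort's phenotype coordinate system: the segment's landmark
#' set, the source segment consensus (rotation reference), the source PC
#' basis and the SNP-specific canonical loading.
#'
#' @param segment_model a source `segment_model`.
#' @param loading unit-norm canonical loading of length
#'   `ncol(segment_model$scores)` (from [cca_association()]).
#' @return list of class `projection_model`.
#' @export
projection_model <- function(segment_model, loading) {
  stopifnot(inherits(segment_model, "segment_model"))
  loading <- as.numeric(loading)
  if (length(loading) != ncol(segment_model$eigenvectors)) {
    stop("loading length must match the number of retained PCs")
  }
  nl <- sqrt(sum(loading^2))
  if (nl == 0) stop("loading must be non-zero")
  structure(list(landmarks = segment_model$landmarks,
                 consensus = segment_model$consensus,
                 center = segment_model$center,
                 eigenvectors = segment_model$eigenvectors,
                 loading = loading / nl,
                 scale = segment_model$scale),
            class = "projection_model")
}

#' Project a cohort onto a source-derived univariate phenotype (T1 trait)
#'
#' For each subject: extract the segment's landmarks, Procrustes-fit them
#' (translation, scaling, rotation — same conventions as the source
#' segment superimposition) onto the source segment consensus, subtract
#' the source mean, project onto the source eigenvectors and take the
#' inner product with the source canonical loading. Projecting the source
#' cohort onto its own model reproduces its in-sample canonical variate
#' exactly.
#'
#' @param adjusted the target cohort's covariate-adjusted shapes
#'   (`adjusted_shapes`), adjusted within the target cohort's own model.
#' @param model a `projection_model`.
#' @return numeric trait vector, one value per subject.
#' @export
project_phenotype <- function(adjusted, model) {
  stopifnot(inherits(model, "projection_model"))
  n_coord <- ncol(if (inherits(adjusted, "adjusted_shapes"))
    adjusted$residuals else adjusted)
  if (max(model$landmarks) * 3L > n_coord) {
    stop("template mismatch: projection model indexes landmarks beyond ",
         "the target shapes")
  }
  configs <- segment_configurations(adjusted, model$landmarks)
  n <- dim(configs)[1]
  traits <- numeric(n)
  w <- model$eigenvectors %*% model$loading
  for (i in seq_len(n)) {
    al <- opa_to_reference(configs[i, , ], model$consensus,
                           scale = model$scale)
    traits[i] <- sum((flatten_config(al) - model$center) * w)
  }
  traits
}

#' SNP-level linear regression of a projected trait (T1)
#'
#' Two-sided test of the slope of the trait on the dosage; for a single
#' predictor this is the same F test as the k = 1 canonical correlation.
#'
#' @param trait numeric trait vector.
#' @param dosage dosage vector aligned on subjects.
#' @return list: p, beta (slope), r, n, flag ("zero_variance" with p = 1
#'   when the dosage does not vary).
#' @export
t1_regression <- function(trait, dosage) {
  keep <- !is.na(trait) & !is.na(dosage)
  x <- dosage[keep]
  y <- trait[keep]
  n <- length(x)
  if (n < 4L) stop("too few complete cases for regression")
  if (var(x) == 0) {
    return(list(p = 1, beta = 0, r = 0, n = n, flag = "zero_variance"))
  }
  r <- cor(x, y)
  f <- (n - 2) * r^2 / (1 - r^2)
  list(p = pf(f, 1, n - 2, lower.tail = FALSE),
       beta = r * sd(y) / sd(x), r = r, n = n, flag = "")
}

# assemble a replication-result row
replication_result <- function(test, snp_id, p, threshold, detail = list()) {
  structure(list(test = test, snp_id = snp_id, p = p, threshold = threshold,
                 replicated = is.finite(p) && p < threshold,
                 status = if (is.na(p)) "NA" else "ok", detail = detail),
            class = "replication_result")
}

#' Best-segment SNP look-up in a target scan (T2)
#'
#' The replication p-value is the SNP's minimum p across all target
#' segments; the threshold is 0.05 divided by the number of discovery
#' signals tested and further by the effective number of independent
#' segments.
#'
#' @param snp_id SNP to look up.
#' @param target_scan a `scan_result` for the target cohort.
#' @param n_signals number of discovery signals under replication (never
#'   inferred: e.g. 20 discovery loci, or 203 in the reverse direction).
#' @param meff_segments effective number of independent segments (40 for
#'   the canonical 63-segment hierarchy).
#' @return a `replication_result`; status "NA" when the SNP is absent
#'   from the target scan (e.g. monomorphic in the target population).
#' @export
best_segment_lookup <- function(snp_id, target_scan, n_signals,
                                meff_segments = 40) {
  thr <- 0.05 / n_signals / meff_segments
  d <- target_scan$associations[target_scan$associations$snp_id == snp_id, ,
                                drop = FALSE]
  if (!nrow(d)) {
    return(replication_result("T2", snp_id, NA_real_, thr))
  }
  i <- which.min(d$p)
  replication_result("T2", snp_id, d$p[i], thr,
                     detail = list(best_segment_id = d$segment_id[i]))
}

#' Locus-level look-up in a target scan (T3 / T5)
#'
#' Takes the minimum p over all target SNPs within the window around the
#' queried SNP — across all segments (T3, "best segment") or within one
#' designated segment (T5, "similar segment"). The Bonferroni base
#' (0.05 / n_signals, further / meff_segments for T3) is divided by the
#' Li-Ji effective number of SNPs at the locus, and floored at the
#' European genome-wide threshold 5e-8: the final threshold is whichever
#' is greater.
#'
#' @param snp_id queried (discovery lead) SNP.
#' @param target_scan a `scan_result` whose `per_snp` table carries
#'   chrom/pos.
#' @param target_genotypes dosage matrix of the target cohort (for the
#'   local LD correlation matrix).
#' @param n_signals number of discovery signals tested.
#' @param meff_segments effective segment count; used (T3) unless
#'   `segment_id` designates one segment (T5).
#' @param segment_id optional designated target segment (switches to T5).
#' @param window half-width in bp.
#' @param floor genome-wide threshold floor (5e-8).
#' @param position optional chrom/pos of the queried SNP when it is absent
#'   from the target panel (list with `chrom`, `pos`).
#' @return a `replication_result` (test "T3" or "T5"); status "NA" when
#'   no target SNPs fall in the window.
#' @export
locus_lookup <- function(snp_id, target_scan, target_genotypes, n_signals,
                         meff_segments = 40, segment_id = NULL,
                         window = 500000L, floor = 5e-8, position = NULL) {
  test <- if (is.null(segment_id)) "T3" else "T5"
  base <- if (is.null(segment_id)) 0.05 / n_signals / meff_segments
          else 0.05 / n_signals
  ps <- target_scan$per_snp
  if (is.null(position)) {
    i <- match(snp_id, ps$snp_id)
    if (is.na(i)) {
      return(replication_result(test, snp_id, NA_real_, base))
    }
    position <- list(chrom = ps$chrom[i], pos = ps$pos[i])
  }
  inwin <- ps$chrom == position$chrom & abs(ps$pos - position$pos) <= window
  win_snps <- ps$snp_id[inwin]
  if (!length(win_snps)) {
    return(replication_result(test, snp_id, NA_real_, base))
  }
  cols <- intersect(win_snps, colnames(target_genotypes))
  local_meff <- if (length(cols) >= 2L) {
    C <- suppressWarnings(cor(target_genotypes[, cols, drop = FALSE],
                              use = "pairwise.complete.obs"))
    C[is.na(C)] <- 0
    diag(C) <- 1
    liji_meff(C)
  } else 1
  thr <- max(base / local_meff, floor)
  a <- target_scan$associations
  a <- a[a$snp_id %in% win_snps, , drop = FALSE]
  if (!is.null(segment_id)) {
    a <- a[a$segment_id == segment_id, , drop = FALSE]
  }
  if (!nrow(a)) return(replication_result(test, snp_id, NA_real_, thr))
  i <- which.min(a$p)
  replication_result(test, snp_id, a$p[i], thr,
                     detail = list(window = c(position$pos - window,
                                              position$pos + window),
                                   n_window_snps = length(win_snps),
                                   local_meff = local_meff,
                                   best_snp = a$snp_id[i],
                                   best_segment_id = a$segment_id[i]))
}

#' Match a source segment to its most similar target segment (T4/T5)
#'
#' Operationalizes "qualitatively similar facial segment" as the target
#' segment at the same hierarchy level with the maximum Dice coefficient
#' of landmark index sets; ties go to the smaller segment id.
#'
#' @param source_tree,target_tree `segment_tree`s on the shared template.
#' @param source_segment source segment id.
#' @return target segment id, with attribute `dice`.
#' @export
match_similar_segment <- function(source_tree, target_tree, source_segment) {
  lvl <- source_tree$nodes$level[source_tree$nodes$segment_id ==
                                   source_segment]
  src <- source_tree$landmarks[[source_segment]]
  cand <- target_tree$nodes$segment_id[target_tree$nodes$level == lvl]
  dice <- vapply(cand, function(id) {
    tgt <- target_tree$landmarks[[id]]
    2 * length(intersect(src, tgt)) / (length(src) + length(tgt))
  }, 0)
  best <- cand[which.max(dice)]   # which.max takes the first = smallest id
  attr(best, "dice") <- max(dice)
  best
}

#' Run the full T1-T5 replication battery for a set of discovery signals
#'
#' For every discovery locus: T1 regresses the target cohort's projection
#' onto the source phenotype (segment + PCs + canonical loading of the
#' lead SNP) on the lead-SNP dosage; T2/T3 look up the best target
#' segment at SNP and locus level; T4/T5 do the same for the target
#' segment most similar to the discovery segment. The machinery is
#' direction-agnostic: swap the cohorts' roles to replicate in the other
#' direction.
#'
#' @param loci discovery `locus_table` (from [define_loci()]).
#' @param source_models source-cohort `segment_model` list.
#' @param source_scan source `scan_result` (for the discovery loadings).
#' @param source_tree,target_tree segment trees of the two cohorts.
#' @param target_adjusted target cohort's covariate-adjusted shapes.
#' @param target_scan target `scan_result`.
#' @param target_genotypes target dosage matrix.
#' @param source_genotypes source dosage matrix (for the discovery
#'   loading).
#' @param n_signals number of signals tested (defaults to `nrow(loci)`).
#' @param meff_segments effective number of independent segments.
#' @return data.frame: one row per locus x test with snp_id, test, p,
#'   threshold, replicated, status, segment ids used.
#' @export
replicate_signals <- function(loci, source_models, source_scan,
                              source_tree, target_tree, target_adjusted,
                              target_scan, target_genotypes,
                              source_genotypes,
                              n_signals = nrow(loci), meff_segments = 40) {
  rows <- list()
  seg_index <- vapply(source_models, function(m) m$segment_id, 0L)
  for (li in seq_len(nrow(loci))) {
    lead <- loci$lead_snp[li]
    seg <- loci$best_segment_id[li]
    sm <- source_models[[match(seg, seg_index)]]
    disc <- cca_association(source_genotypes[, lead], sm$scores, lead, seg)
    pm <- projection_model(sm, disc$loading)
    in_target <- lead %in% colnames(target_genotypes)
    t1 <- if (in_target) {
      trait <- project_phenotype(target_adjusted, pm)
      reg <- t1_regression(trait, target_genotypes[, lead])
      replication_result("T1", lead, reg$p, 0.05 / n_signals)
    } else replication_result("T1", lead, NA_real_, 0.05 / n_signals)
    t2 <- best_segment_lookup(lead, target_scan, n_signals, meff_segments)
    t3 <- locus_lookup(lead, target_scan, target_genotypes, n_signals,
                       meff_segments,
                       position = list(chrom = loci$chrom[li],
                                       pos = loci$pos[li]))
    sim <- match_similar_segment(source_tree, target_tree, seg)
    a <- target_scan$associations
    a4 <- a[a$snp_id == lead & a$segment_id == sim, , drop = FALSE]
    t4 <- replication_result("T4", lead,
                             if (nrow(a4)) a4$p[1] else NA_real_,
                             0.05 / n_signals,
                             detail = list(segment_id = sim))
    t5 <- locus_lookup(lead, target_scan, target_genotypes, n_signals,
                       segment_id = sim,
                       position = list(chrom = loci$chrom[li],
                                       pos = loci$pos[li]))
    for (r in list(t1, t2, t3, t4, t5)) {
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = lead, test = r$test, p = r$p, threshold = r$threshold,
        replicated = r$replicated, status = r$status,
        discovery_segment = seg,
        target_segment = r$detail$best_segment_id %||%
          r$detail$segment_id %||% NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
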