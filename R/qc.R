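#' Flag atypical shapes by PCA-subspace Mahalanobis distance
#'
#' Computes each subject's Mahalanobis distance in the principal-component
#' subspace of the aligned shapes (components up to `var_cutoff` of the
#' total variance), converts distances to z-scores, and flags subjects with
#' z > 2 as outliers for visual inspection.
#'
#' @param aligned an `aligned_cohort` (or n x 3L shape matrix).
#' @param var_cutoff fraction of shape variance spanned by the PCA
#'   subspace used for the metric.
#' @return list of class `qc_report`: `mahalanobis_z` (n-vector),
#'   `flagged` (subject indices with z > 2), `n_dims`.
#' @export
flag_outliers <- function(aligned, var_cutoff = 0.98) {
  X <- if (inherits(aligned, "aligned_cohort")) aligned$shapes else aligned
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nv = 0)
  ev <- sv$d^2 / (n - 1)
  ev <- ev[ev > max(ev) * 1e-12]
  k <- which(cumsum(ev) / sum(ev) >= var_cutoff)[1]
  if (n <= k + 1L) {
    stop("too few shapes (n = ", n, ") to estimate a ", k,
         "-dimensional covariance for the Mahalanobis metric")
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] * rep(sv$d[seq_len(k)],
                                                   each = n)
  d <- sqrt(rowSums(sweep(scores^2, 2, ev[seq_len(k)], `/`)))
  z <- as.vector(scale(d))
  structure(list(mahalanobis_z = z, flagged = which(z > 2), n_dims = k),
            class = "qc_report")
}

#' Residualize shapes on covariates
#'
#' Regresses every shape coordinate on an intercept plus the requested
#' covariates by least squares and returns the residuals, which are exactly
#' orthogonal to every covariate column. `age2` is derived from `age` on
#' the fly and `size` refers to centroid size (taken from the aligned
#' cohort); any additional column of `covariates` (e.g. an eye-state
#' indicator or ancestry PCs) can be named in `covariate_list` or supplied
#' via `extra`.
#'
#' @param aligned an `aligned_cohort`, or an n x 3L shape matrix.
#' @param covariates data.frame with one row per subject.
#' @param covariate_list character vector of covariate names to adjust for.
#' @param extra optional numeric matrix of additional covariate columns
#'   (e.g. ancestry PC scores).
#' @return list of class `adjusted_shapes`: `residuals` (n x 3L),
#'   `consensus` (L x 3 mean shape added back when segments are re-fit),
#'   `covariate_names`.
#' @export
adjust_covariates <- function(aligned, covariates,
                              covariate_list = c("age", "age2", "sex",
                                                 "height", "weight", "size"),
                              extra = NULL) {
  X <- if (inherits(aligned, "aligned_cohort")) aligned$shapes else aligned
  n <- nrow(X)
  stopifnot(nrow(covariates) == n)
  cols <- list()
  for (nm in covariate_list) {
    v <- if (nm == "age2") {
      covariates$age^2
    } else if (nm == "size") {
      if (!inherits(aligned, "aligned_cohort")) {
        stop("covariate 'size' requires an aligned_cohort input")
      }
      aligned$centroid_sizes
    } else {
      covariates[[nm]]
    }
    if (is.null(v)) stop("covariate '", nm, "' not found")
    if (anyNA(v)) stop("covariate '", nm, "' has missing values")
    cols[[nm]] <- as.numeric(v)
  }
  design <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (is.null(colnames(extra))) {
      colnames(extra) <- paste0("extra", seq_len(ncol(extra)))
    }
    design <- cbind(design, extra)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- X - design %*% qr.coef(qrd, X)
  consensus <- if (inherits(aligned, "aligned_cohort")) {
    aligned$consensus
  } else {
    unflatten_config(colMeans(X))
  }
  structure(list(residuals = res, consensus = consensus,
                 covariate_names = setdiff(colnames(design), "(Intercept)")),
            class = "adjusted_shapes")
}

#' Sample-retention accounting for a QC manifest
#'
#' Applies named exclusion flags to a subject manifest sequentially and
#' returns the audit trail: the input count, the number newly excluded by
#' each rule, and the retained count — the style of reporting used when a
#' cohort's recruitment funnel is summarized (n recruited, n excluded, n
#' analyzed).
#'
#' @param manifest data.frame with one row per subject; flag columns are
#'   logical, TRUE = excluded by that rule.
#' @param flag_cols names of the exclusion flag columns, applied in order.
#' @return list of class `retention_report`: `n_input`, `steps`
#'   (data.frame: rule, n_excluded, n_remaining), `n_retained`,
#'   `retained` (row indices kept).
#' @export
apply_exclusions <- function(manifest, flag_cols) {
  stopifnot(is.data.frame(manifest), all(flag_cols %in% names(manifest)))
  keep <- rep(TRUE, nrow(manifest))
  steps <- data.frame(rule = character(0), n_excluded = integer(0),
                      n_remaining = integer(0), stringsAsFactors = FALSE)
  for (fc in flag_cols) {
    flag <- as.logical(manifest[[fc]])
    flag[is.na(flag)] <- FALSE
    newly <- sum(keep & flag)
    keep <- keep & !flag
    steps <- rbind(steps, data.frame(rule = fc, n_excluded = newly,
                                     n_remaining = sum(keep),
                                     stringsAsFactors = FALSE))
  }
  structure(list(n_input = nrow(manifest), steps = steps,
                 n_retained = sum(keep), retained = which(keep)),
            class = "retention_report")
}

#' @export
print.retention_report <- function(x, ...) {
  cat("retention: input", x$n_input, "\n")
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  - %s: excluded %d -> %d remain\n", x$steps$rule[i],
                x$steps$n_excluded[i], x$steps$n_remaining[i]))
  }
  cat("retained:", x$n_retained, "\n")
  invisible(x)
}
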