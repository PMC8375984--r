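#' Per-segment GPA + PCA phenotype with Horn's parallel analysis
#'
#' Extracts one segment's landmarks from the adjusted shapes (mean shape
#' added back so the subset forms proper configurations), re-runs a
#' Procrustes superimposition restricted to the segment, performs PCA of
#' the aligned coordinates, and retains the leading principal components
#' whose eigenvalues exceed the chosen percentile of eigenvalues obtained
#' from column-permuted data (Horn's parallel analysis; at least one PC is
#' always kept). The retained scores are the segment's multivariate
#' phenotype for association testing.
#'
#' @param adjusted an `adjusted_shapes` object (or an n x 3L matrix, in
#'   which case its column means act as the mean shape).
#' @param segment landmark index set of the segment, or a `segment_tree`
#'   plus `segment_id`.
#' @param segment_id segment to extract when `segment` is a tree.
#' @param n_permutations,percentile parallel-analysis settings.
#' @param seed seed for the permutations (required for reproducibility).
#' @param scale passed to the segment-level Procrustes step.
#' @return list of class `segment_model`: `segment_id`, `landmarks`,
#'   `consensus` (|S| x 3), `eigenvectors` (3|S| x k, orthonormal),
#'   `eigenvalues` (k), `all_eigenvalues`, `scores` (n x k),
#'   `variance_explained`, `scale`.
#' @export
fit_segment_pca <- function(adjusted, segment, segment_id = NULL,
                            n_permutations = 100L, percentile = 95,
                            seed = 1L, scale = TRUE) {
  if (inherits(segment, "segment_tree")) {
    stopifnot(!is.null(segment_id))
    landmarks <- segment$landmarks[[segment_id]]
  } else {
    landmarks <- as.integer(segment)
    segment_id <- segment_id %||% NA_integer_
  }
  if (!length(landmarks)) stop("empty segment")
  configs <- segment_configurations(adjusted, landmarks)
  n <- dim(configs)[1]
  if (n <= 3L) stop("need more than 3 subjects for a segment PCA")
  if (length(landmarks) == 1L) stop("zero-variance segment: a single ",
                                    "landmark has no shape")
  aligned <- gpa_align(configs, scale = scale)
  Xc <- scale(aligned$shapes, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-14)) stop("zero-variance segment")
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)
  set.seed(seed)
  p <- ncol(Xc)
  r <- min(n - 1L, p)
  perm_ev <- matrix(0, n_permutations, r)
  for (b in seq_len(n_permutations)) {
    Xp <- apply(Xc, 2L, sample)
    dp <- svd(Xp, nu = 0, nv = 0)$d
    perm_ev[b, ] <- (dp^2 / (n - 1))[seq_len(r)]
  }
  thr <- apply(perm_ev, 2L, quantile, probs = percentile / 100)
  keep <- ev[seq_len(r)] > thr
  k <- if (any(!keep)) which(!keep)[1] - 1L else sum(keep)
  k <- max(1L, k)
  vectors <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  scores <- Xc %*% vectors
  structure(list(segment_id = segment_id, landmarks = landmarks,
                 consensus = aligned$consensus,
                 mean_shape = unflatten_config(colMeans(aligned$shapes)),
                 center = colMeans(aligned$shapes),
                 eigenvectors = vectors,
                 eigenvalues = ev[seq_len(k)],
                 all_eigenvalues = ev,
                 scores = scores,
                 variance_explained = sum(ev[seq_len(k)]) / sum(ev),
                 scale = scale),
            class = "segment_model")
}

# Rebuild per-subject segment configurations (n x |S| x 3) from adjusted
# residuals by adding the cohort mean shape back.
segment_configurations <- function(adjusted, landmarks) {
  if (inherits(adjusted, "adjusted_shapes")) {
    res <- adjusted$residuals
    consensus <- adjusted$consensus
  } else {
    res <- adjusted
    consensus <- unflatten_config(colMeans(res))
    res <- scale(res, center = TRUE, scale = FALSE)
  }
  cols <- coord_cols(landmarks)
  base <- flatten_config(consensus[landmarks, , drop = FALSE])
  sub <- sweep(res[, cols, drop = FALSE], 2L, base, `+`)
  unflatten_shapes(sub)
}

#' Fit segment models for every node of a segmentation tree
#'
#' @param adjusted an `adjusted_shapes` object.
#' @param tree a `segment_tree`.
#' @param ... passed to [fit_segment_pca()]; the permutation seed is
#'   offset per segment so each segment has its own stream.
#' @param seed base seed for parallel analysis.
#' @return list of `segment_model`s indexed by segment id.
#' @export
fit_all_segments <- function(adjusted, tree, seed = 1L, ...) {
  stopifnot(inherits(tree, "segment_tree"))
  lapply(tree$nodes$segment_id, function(id) {
    fit_segment_pca(adjusted, tree, segment_id = id, seed = seed + id, ...)
  })
}
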