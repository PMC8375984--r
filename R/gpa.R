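#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid, the standard geometric-morphometric size measure.
#'
#' @param coords L x 3 coordinate matrix (mm).
#' @return centroid size (mm).
#' @export
centroid_size <- function(coords) {
  ctr <- colMeans(coords)
  sqrt(sum(sweep(coords, 2, ctr)^2))
}

# Optimal rotation (no reflection) aligning centered config X onto centered
# reference R: Kabsch solution from the SVD of t(X) %*% R.
optimal_rotation <- function(X, R) {
  A <- crossprod(X, R)
  sv <- svd(A)
  s <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
}

# Center (and optionally scale to unit centroid size) one configuration.
center_scale <- function(coords, scale = TRUE) {
  ctr <- colMeans(coords)
  out <- sweep(coords, 2, ctr)
  cs <- sqrt(sum(out^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide")
  if (scale) out <- out / cs
  list(coords = out, size = cs)
}

#' Generalized Procrustes alignment of a landmark cohort
#'
#' Removes position (centering), optionally size (scaling each
#' configuration to unit centroid size) and orientation (optimal rotations,
#' reflections disallowed) from a set of configurations by iterating
#' rotation to the consensus until the consensus stabilizes. After
#' convergence every shape is re-aligned to the final consensus, so each
#' aligned shape is in ordinary-Procrustes-optimal position with respect to
#' the returned consensus.
#'
#' @param shapes n x L x 3 array, list of L x 3 matrices, or a
#'   `cohort_bundle`.
#' @param scale scale to unit centroid size (default TRUE; the pre-scaling
#'   centroid sizes are always returned so size can be used as a
#'   covariate).
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus.
#' @param max_iter iteration cap.
#' @return list of class `aligned_cohort`: `shapes` (n x 3L matrix,
#'   interleaved x,y,z per landmark), `centroid_sizes` (mm, pre-scaling),
#'   `consensus` (L x 3), `n_iter`, `objective_trace` (sum of squared
#'   distances to the consensus at each iteration; non-increasing).
#' @export
gpa_align <- function(shapes, scale = TRUE, tol = 1e-8, max_iter = 100L) {
  if (inherits(shapes, "cohort_bundle")) shapes <- shapes$shapes
  if (is.list(shapes) && !is.array(shapes)) {
    shapes <- simplify2array(shapes)      # L x 3 x n
    shapes <- aperm(shapes, c(3, 1, 2))
  }
  stopifnot(length(dim(shapes)) == 3L, dim(shapes)[3] == 3L)
  n <- dim(shapes)[1]
  L <- dim(shapes)[2]
  if (n < 2L) stop("need at least 2 configurations")
  confs <- vector("list", n)
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    cs <- center_scale(shapes[i, , ], scale = scale)
    confs[[i]] <- cs$coords
    sizes[i] <- cs$size
  }
  consensus <- Reduce(`+`, confs) / n
  align_all <- function(ref) lapply(confs, function(x) {
    x %*% optimal_rotation(x, ref)
  })
  objective <- numeric(0)
  for (iter in seq_len(max_iter)) {
    rotated <- align_all(consensus)
    new_consensus <- Reduce(`+`, rotated) / n
    objective <- c(objective, sum(vapply(rotated, function(x) {
      sum((x - new_consensus)^2)
    }, 0)))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) break
  }
  rotated <- align_all(consensus)        # final pass onto final consensus
  mat <- t(vapply(rotated, flatten_config, numeric(3L * L)))
  structure(list(shapes = mat, centroid_sizes = sizes, consensus = consensus,
                 n_iter = iter, objective_trace = objective),
            class = "aligned_cohort")
}

# Ordinary Procrustes fit of one configuration onto a fixed reference,
# using the same conventions as gpa_align (center, optional unit-size
# scaling, rotation only). Returns the aligned L x 3 matrix.
opa_to_reference <- function(coords, reference, scale = TRUE) {
  cs <- center_scale(coords, scale = scale)
  cs$coords %*% optimal_rotation(cs$coords, reference)
}

#' Symmetrize aligned shapes by left/right averaging
#'
#' Replaces every configuration by the average of itself and its relabeled
#' mirror image (reflection across the template midline plane with paired
#' landmarks swapped), retaining only the symmetric component of shape
#' variation. The output is exactly invariant under reflection plus
#' relabeling.
#'
#' @param aligned an `aligned_cohort`.
#' @param template the `facial_template` providing the bilateral pairing.
#' @return an `aligned_cohort` of symmetrized shapes (consensus updated).
#' @export
symmetrize <- function(aligned, template) {
  stopifnot(inherits(aligned, "aligned_cohort"),
            inherits(template, "facial_template"))
  L <- template$landmark_count
  covered <- sort(c(template$bilateral_pairs, template$midline))
  if (!identical(as.integer(covered), seq_len(L))) {
    stop("bilateral pairing plus midline must cover every landmark exactly once")
  }
  out <- aligned
  for (i in seq_len(nrow(aligned$shapes))) {
    m <- unflatten_config(aligned$shapes[i, ])
    sym <- (m + reflect_relabel(m, template)) / 2
    out$shapes[i, ] <- flatten_config(sym)
  }
  out$consensus <- unflatten_config(colMeans(out$shapes))
  out
}
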