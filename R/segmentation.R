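#' Pairwise RV coefficients between landmark displacement blocks
#'
#' The RV coefficient between two landmarks' n x 3 displacement matrices
#' measures how strongly the two landmarks covary as 3D points,
#' irrespective of the axes along which they move:
#' \code{RV(i, j) = ||Xi' Xj||_F^2 / (||Xi' Xi||_F ||Xj' Xj||_F)}.
#' Computed for all pairs in one pass from the 3L x 3L cross-product
#' matrix.
#'
#' @param residuals n x 3L matrix of (covariate-adjusted, column-centered)
#'   shape coordinates, or an `adjusted_shapes` object.
#' @return L x L symmetric matrix of RV coefficients in [0, 1].
#' @export
rv_similarity <- function(residuals) {
  X <- if (inherits(residuals, "adjusted_shapes")) residuals$residuals
       else residuals
  X <- scale(X, center = TRUE, scale = FALSE)
  L <- ncol(X) / 3L
  M2 <- crossprod(X)^2
  idx <- rep(seq_len(L), each = 3L)
  S <- rowsum(t(rowsum(M2, idx)), idx)     # L x L sums of squared blocks
  d <- sqrt(diag(S))
  d[d == 0] <- 1                           # zero-variance landmark -> RV 0
  RV <- S / tcrossprod(d)
  RV[diag(S) == 0, ] <- 0
  RV[, diag(S) == 0] <- 0
  diag(RV) <- 1
  (RV + t(RV)) / 2
}

# Spectral bipartition of a similarity submatrix by the sign of the Fiedler
# vector of the normalized graph Laplacian. Entries exactly 0 join the
# smaller cluster; the eigenvector sign is fixed by making its
# largest-magnitude entry positive.
spectral_bipartition <- function(W) {
  m <- nrow(W)
  if (m == 2L) return(list(left = 1L, right = 2L))
  A <- W
  diag(A) <- 0
  deg <- rowSums(A)
  deg[deg <= 0] <- 1e-12
  dis <- 1 / sqrt(deg)
  Lsym <- diag(m) - (dis * A) * rep(dis, each = m)  # D^-1/2 A D^-1/2 form
  Lsym <- (Lsym + t(Lsym)) / 2
  ei <- eigen(Lsym, symmetric = TRUE)
  v <- ei$vectors[, m - 1L]                # second-smallest eigenvalue
  f <- dis * v                             # random-walk Fiedler vector
  imax <- which.max(abs(f))
  if (f[imax] < 0) f <- -f
  pos <- which(f > 0)
  neg <- which(f < 0)
  zero <- which(f == 0)
  if (length(zero)) {
    if (length(pos) <= length(neg)) pos <- c(pos, zero) else neg <- c(neg, zero)
  }
  if (!length(pos) || !length(neg)) {
    # disconnected or degenerate graph: split off the weakest vertex
    iso <- which.min(rowSums(A))
    pos <- iso
    neg <- setdiff(seq_len(m), iso)
  }
  list(left = sort(pos), right = sort(neg))
}

#' Global-to-local hierarchical segmentation of the landmark set
#'
#' Builds the bifurcating segment hierarchy: landmark-pair similarity is
#' the RV coefficient of their residual displacement blocks, and each node
#' is split in two by the sign of the Fiedler vector of the normalized
#' Laplacian of its similarity subgraph, recursively for `depth` rounds
#' below the root. With the default `depth = 5` this yields the 63
#' partially overlapping segments (1 whole face + 2 + 4 + 8 + 16 + 32),
#' numbered breadth-first with the root as segment 1 at level 0.
#'
#' @param residuals `adjusted_shapes` or an n x 3L residual matrix.
#' @param depth number of bifurcation rounds below the root.
#' @return list of class `segment_tree`: `nodes` (data.frame: segment_id,
#'   level, parent_id, n_landmarks), `landmarks` (list of landmark index
#'   sets keyed by segment id), `depth`.
#' @export
build_segment_tree <- function(residuals, depth = 5L) {
  RV <- rv_similarity(residuals)
  L <- nrow(RV)
  n_nodes <- 2L^(depth + 1L) - 1L
  landmarks <- vector("list", n_nodes)
  landmarks[[1L]] <- seq_len(L)
  for (id in seq_len(2L^depth - 1L)) {          # internal nodes only
    set <- landmarks[[id]]
    if (length(set) < 2L) {
      stop("segment ", id, " has fewer than 2 landmarks and cannot be ",
           "split; use a larger template or smaller depth")
    }
    sp <- spectral_bipartition(RV[set, set, drop = FALSE])
    landmarks[[2L * id]] <- set[sp$left]
    landmarks[[2L * id + 1L]] <- set[sp$right]
  }
  ids <- seq_len(n_nodes)
  nodes <- data.frame(segment_id = ids,
                      level = floor(log2(ids)),
                      parent_id = c(NA_integer_, ids[-1L] %/% 2L),
                      n_landmarks = vapply(landmarks, length, 0L))
  structure(list(nodes = nodes, landmarks = landmarks, depth = depth),
            class = "segment_tree")
}

#' @export
print.segment_tree <- function(x, ...) {
  cat("segment_tree:", nrow(x$nodes), "segments, depth", x$depth, "(",
      x$nodes$n_landmarks[1], "landmarks at root )\n")
  invisible(x)
}
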