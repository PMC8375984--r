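#' Build a mirror-symmetric synthetic landmark template
#'
#' Generates a face-like, bilaterally symmetric quasi-landmark template: a
#' half-ellipsoid point cloud (axes roughly matching a face in mm) in which
#' every landmark with x > 0 has a mirror partner at x < 0, plus an optional
#' set of midline landmarks on the x = 0 plane. Landmarks are grouped into
#' contiguous spatial patches (recorded in \code{region_labels}) that serve
#' as units for planting localized genetic and latent shape effects.
#'
#' @param landmark_count total number of quasi-landmarks; must be at least
#'   64 so that five bifurcation rounds can always split every node.
#' @param seed integer seed; the template is a deterministic function of
#'   `landmark_count`, `seed`, `n_midline` and `n_regions`.
#' @param n_midline number of unpaired midline landmarks. Defaults to
#'   `landmark_count %% 2`; `landmark_count - n_midline` must be even.
#' @param n_regions number of contiguous patches used for region labels.
#' @return an object of class `facial_template` with fields
#'   `landmark_count`, `coordinates` (L x 3, mm), `bilateral_pairs`
#'   (m x 2 integer matrix), `midline` (integer vector) and
#'   `region_labels` (length-L integer vector).
#' @examples
#' tpl <- make_template(64, seed = 1)
#' nrow(tpl$coordinates)
#' @export
make_template <- function(landmark_count, seed = 1L,
                          n_midline = landmark_count %% 2L,
                          n_regions = 32L) {
  if (landmark_count < 64L) {
    stop("landmark_count must be at least 64 (got ", landmark_count,
         "): five bifurcation rounds need >= 64 landmarks")
  }
  n_paired <- landmark_count - n_midline
  if (n_paired %% 2L != 0L) {
    stop("landmark_count minus n_midline must be even; declare a midline ",
         "landmark for odd counts")
  }
  set.seed(seed)
  half <- n_paired / 2L
  # half-ellipsoid (x > 0); face-scale axes in mm
  ax <- c(55, 75, 45)
  u <- runif(half, 0.05, 0.95) * pi / 2      # azimuth, kept off the midline
  v <- runif(half, -0.45, 0.45) * pi         # elevation
  right <- cbind(ax[1] * cos(v) * sin(u),
                 ax[2] * sin(v),
                 ax[3] * cos(v) * cos(u))
  left <- right
  left[, 1] <- -left[, 1]
  mid <- NULL
  if (n_midline > 0L) {
    vm <- runif(n_midline, -0.45, 0.45) * pi
    mid <- cbind(0, ax[2] * sin(vm), ax[3] * cos(vm))
  }
  coords <- rbind(right, left, mid)
  pairs <- cbind(seq_len(half), half + seq_len(half))
  midline <- if (n_midline > 0L) n_paired + seq_len(n_midline) else integer(0)

  # contiguous patches by sorted position along the ellipsoid surface, kept
  # mirror-consistent: the label of a left landmark equals its right partner
  n_regions <- min(n_regions, half)
  ord <- order(right[, 2], right[, 3])
  lab_half <- integer(half)
  lab_half[ord] <- as.integer(cut(seq_len(half), breaks = n_regions,
                                  labels = FALSE))
  labels <- c(lab_half, lab_half, rep(n_regions, n_midline))

  structure(list(landmark_count = as.integer(landmark_count),
                 coordinates = coords,
                 bilateral_pairs = pairs,
                 midline = midline,
                 region_labels = as.integer(labels)),
            class = "facial_template")
}

#' @export
print.facial_template <- function(x, ...) {
  cat("facial_template:", x$landmark_count, "landmarks (",
      nrow(x$bilateral_pairs), "bilateral pairs,",
      length(x$midline), "midline ),",
      length(unique(x$region_labels)), "regions\n")
  invisible(x)
}

# reflect a configuration across x = 0 and relabel paired landmarks; the
# result is comparable landmark-by-landmark with the input
reflect_relabel <- function(coords, template) {
  out <- coords
  out[, 1] <- -out[, 1]
  perm <- seq_len(nrow(coords))
  perm[template$bilateral_pairs[, 1]] <- template$bilateral_pairs[, 2]
  perm[template$bilateral_pairs[, 2]] <- template$bilateral_pairs[, 1]
  out[perm, , drop = FALSE]
}
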