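#' Simulate a ChIP-seq-like window coverage matrix
#'
#' Per-window baseline intensities are drawn from a Gamma distribution and
#' per-sample counts from a negative binomial around them, mimicking the
#' overdispersion of H3K27ac coverage. "Target" samples (e.g. craniofacial
#' cell types) have their expected counts multiplied by `fold` at the
#' designated hit windows only; with `fold = 1` the two groups are
#' exchangeable by construction.
#'
#' @param windows a `GenomeWindows` data.frame from [make_windows()] (only
#'   its row count is used) or an integer window count.
#' @param n_target,n_background samples per group.
#' @param hit_windows integer indices of the elevated windows (subset of
#'   the window rows).
#' @param fold signal multiplier at hit windows for target samples, >= 1.
#' @param seed integer seed.
#' @param base_mean,dispersion negative-binomial baseline mean scale and
#'   size parameter.
#' @return list of class `window_coverage`: `counts` (windows x samples),
#'   `samples` (data.frame: sample_id, group), `normalization` ("raw").
#' @export
simulate_coverage_tracks <- function(windows, n_target, n_background,
                                     hit_windows = integer(0), fold = 1,
                                     seed = 1L, base_mean = 50,
                                     dispersion = 5) {
  n_win <- if (is.data.frame(windows)) nrow(windows) else as.integer(windows)
  if (fold < 1) stop("fold must be >= 1")
  if (length(hit_windows) && any(hit_windows < 1L | hit_windows > n_win)) {
    stop("hit_windows must index into the window set")
  }
  set.seed(seed)
  n_samp <- n_target + n_background
  groups <- c(rep("target", n_target), rep("background", n_background))
  ids <- sprintf("%s_%02d", groups, c(seq_len(n_target),
                                      seq_len(n_background)))
  counts <- matrix(0, n_win, n_samp, dimnames = list(NULL, ids))
  if (n_win > 0L) {
    lambda <- rgamma(n_win, shape = 2, scale = base_mean / 2)
    for (s in seq_len(n_samp)) {
      mu <- lambda
      if (groups[s] == "target" && length(hit_windows)) {
        mu[hit_windows] <- mu[hit_windows] * fold
      }
      counts[, s] <- rnbinom(n_win, mu = mu, size = dispersion)
    }
  }
  structure(list(counts = counts,
                 samples = data.frame(sample_id = ids, group = groups,
                                      stringsAsFactors = FALSE),
                 normalization = "raw"),
            class = "window_coverage")
}
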