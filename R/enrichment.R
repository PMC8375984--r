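#' Tile a genome into fixed-width windows
#'
#' Half-open 0-based windows of `width` bp tiling each chromosome exactly;
#' the terminal window of a chromosome is truncated at its end.
#'
#' @param chrom_sizes named numeric vector (or data.frame with `chrom`,
#'   `size`) of chromosome lengths in bp.
#' @param width window width (20 kb by default).
#' @return data.frame of class `genome_windows`: chrom, start (0-based,
#'   inclusive), end (exclusive).
#' @export
make_windows <- function(chrom_sizes, width = 20000L) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  }
  if (any(chrom_sizes == 0)) {
    warning("skipping zero-length chromosome(s): ",
            paste(names(chrom_sizes)[chrom_sizes == 0], collapse = ", "))
    chrom_sizes <- chrom_sizes[chrom_sizes > 0]
  }
  stopifnot(all(chrom_sizes > 0))
  if (!length(chrom_sizes)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("genome_windows", "data.frame")
    return(out)
  }
  tiles <- GenomicRanges::tileGenome(chrom_sizes, tilewidth = width,
                                     cut.last.tile.in.chrom = TRUE)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(tiles)),
                    start = GenomicRanges::start(tiles) - 1,
                    end = GenomicRanges::end(tiles),
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_windows", "data.frame")
  out
}

# windows data.frame -> GRanges (1-based closed, as GenomicRanges expects)
windows_to_granges <- function(windows) {
  GenomicRanges::GRanges(windows$chrom,
                         IRanges::IRanges(start = windows$start + 1,
                                          end = windows$end))
}

#' Read a BED file of aligned read intervals
#'
#' Minimal 3+ column BED reader (chrom, start 0-based, end exclusive);
#' extra columns are ignored.
#'
#' @param path BED file path.
#' @return data.frame: chrom, start, end.
#' @export
read_bed <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop("BED file needs at least 3 columns: ", path)
  data.frame(chrom = as.character(d[[1]]), start = as.numeric(d[[2]]),
             end = as.numeric(d[[3]]), stringsAsFactors = FALSE)
}

#' Reads-per-million window coverage for one sample
#'
#' Counts the reads overlapping each window — a read spanning a window
#' boundary is counted once in every window it overlaps — and scales by
#' 1e6 over the sample's total read count.
#'
#' @param reads data.frame of read intervals (chrom, start 0-based, end)
#'   or a BED file path.
#' @param windows a `genome_windows` data.frame.
#' @return numeric RPM vector, one entry per window.
#' @export
window_coverage_rpm <- function(reads, windows) {
  if (is.character(reads)) reads <- read_bed(reads)
  n_reads <- nrow(reads)
  if (n_reads == 0L) stop("sample has zero reads")
  win_gr <- windows_to_granges(windows)
  read_gr <- GenomicRanges::GRanges(reads$chrom,
                                    IRanges::IRanges(start = reads$start + 1,
                                                     end = reads$end))
  # reads on untiled contigs legitimately count nowhere
  counts <- suppressWarnings(GenomicRanges::countOverlaps(win_gr, read_gr))
  counts * 1e6 / n_reads
}

#' Quantile normalization of a coverage matrix
#'
#' Forces every column (sample) to share a common value distribution:
#' each value is replaced by the mean of the row-sorted columns at its
#' rank, ties receiving the mean of their ranks' reference values.
#'
#' @param mat numeric matrix (windows x samples), >= 2 columns, no
#'   missing values.
#' @return matrix of the same shape, columns sharing identical sorted
#'   values.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 columns")
  if (anyNA(mat)) stop("missing values not supported")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Windows containing the lead SNPs of significant loci
#'
#' Converts each 1-based lead-SNP position to the 0-based window
#' containing it (`start <= pos - 1 < end`), collapsing duplicates.
#'
#' @param loci `locus_table` (or data.frame with chrom, pos).
#' @param windows `genome_windows` data.frame.
#' @return sorted integer vector of window row indices.
#' @export
lead_snp_windows <- function(loci, windows) {
  idx <- integer(0)
  for (i in seq_len(nrow(loci))) {
    pos0 <- loci$pos[i] - 1
    j <- which(windows$chrom == loci$chrom[i] & windows$start <= pos0 &
                 pos0 < windows$end)
    if (!length(j)) {
      stop("lead SNP ", loci$lead_snp[i] %||% i, " at ", loci$chrom[i], ":",
           loci$pos[i], " falls outside the tiled chromosome")
    }
    idx <- c(idx, j)
  }
  sort(unique(idx))
}

#' Target-vs-background enrichment test at the hit windows
#'
#' Summarizes each sample by its mean transformed signal over the hit
#' windows and compares target against background samples with a
#' one-sided Wilcoxon rank-sum test (target greater). Being rank-based,
#' the p-value is invariant to any monotone rescaling applied to all
#' samples jointly.
#'
#' @param mat normalized coverage matrix (windows x samples).
#' @param hit_windows window row indices (e.g. [lead_snp_windows()]).
#' @param groups character vector per sample, "target" or "background".
#' @param transform signal transform applied before averaging (default
#'   `log10(x + 1)`).
#' @return list of class `enrichment_result`: `summary` (per-sample mean
#'   transformed signal), `groups`, `p`.
#' @export
enrichment_test <- function(mat, hit_windows, groups,
                            transform = function(x) log10(x + 1)) {
  stopifnot(length(groups) == ncol(mat))
  if (!length(hit_windows)) stop("need at least one hit window")
  if (!all(c("target", "background") %in% groups)) {
    stop("both 'target' and 'background' groups must be non-empty")
  }
  sub <- transform(mat[hit_windows, , drop = FALSE])
  summ <- colMeans(sub)
  p <- wilcox.test(summ[groups == "target"], summ[groups == "background"],
                   alternative = "greater", exact = FALSE)$p.value
  structure(list(summary = summ, groups = groups, p = p),
            class = "enrichment_result")
}
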