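#' Write genotypes as a minimal VCF
#'
#' Emits CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO (`INFO=` imputation
#' score) and either hard genotypes (`GT`, requires integral dosages) or
#' dosages (`DS`).
#'
#' @param genotypes n x M dosage matrix (columns named by SNP id).
#' @param variant_meta data.frame: snp_id, chrom, pos, ref, alt, info.
#' @param path output path.
#' @param format "DS" (dosage) or "GT".
#' @param sample_ids subject ids (defaults to rownames or S0001...).
#' @export
write_vcf <- function(genotypes, variant_meta, path, format = c("DS", "GT"),
                      sample_ids = NULL) {
  format <- match.arg(format)
  n <- nrow(genotypes)
  M <- ncol(genotypes)
  stopifnot(nrow(variant_meta) == M)
  sample_ids <- sample_ids %||% rownames(genotypes) %||%
    sprintf("S%04d", seq_len(n))
  if (format == "GT" && any(abs(genotypes - round(genotypes)) > 1e-9,
                            na.rm = TRUE)) {
    stop("GT output requires integral dosages; use format = 'DS'")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation INFO score\">",
               if (format == "DS")
                 "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">"
               else
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(M)) {
    g <- genotypes[, j]
    field <- if (format == "DS") {
      ifelse(is.na(g), ".", sprintf("%.4g", g))
    } else {
      ifelse(is.na(g), "./.", gt_code[round(g) + 1L])
    }
    writeLines(paste(c(variant_meta$chrom[j], variant_meta$pos[j],
                       variant_meta$snp_id[j], variant_meta$ref[j],
                       variant_meta$alt[j], ".", "PASS",
                       sprintf("INFO=%.4g", variant_meta$info[j] %||% 1),
                       format, field), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF or TSV dosage matrix
#'
#' VCF: `DS` dosages are used when present, otherwise diploid `GT` fields
#' are converted to alt-allele counts (mixed or non-diploid ploidy is an
#' error). TSV: a header row of SNP ids, first column subject id, numeric
#' dosages elsewhere. The INFO score key is configurable.
#'
#' @param path input file.
#' @param info_key INFO field key holding the imputation score.
#' @return list: `genotypes` (n x M dosage matrix, NA = missing),
#'   `variant_meta` (snp_id, chrom, pos, ref, alt, info),
#'   `sample_ids`.
#' @export
read_genotypes <- function(path, info_key = "INFO") {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    fmt <- v@gt[, 1L]
    if (all(grepl("DS", fmt))) {
      ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
      G <- t(ds)
    } else {
      gt <- vcfR::extract.gt(v, element = "GT")
      bad <- !is.na(gt) & !grepl("^[0-9.]([/|][0-9.])?$", gt)
      if (any(bad)) {
        rowi <- which(bad, arr.ind = TRUE)[1, 1]
        stop("unsupported (non-diploid) GT at variant row ", rowi)
      }
      haploid <- !is.na(gt) & !grepl("[/|]", gt)
      if (any(haploid) && !all(haploid | is.na(gt))) {
        stop("mixed ploidy in GT fields")
      }
      count_alt <- function(x) {
        if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
        sum(as.numeric(strsplit(x, "[/|]")[[1]]) > 0)
      }
      G <- t(apply(gt, c(1, 2), count_alt))
      dim(G) <- rev(dim(gt))
      dimnames(G) <- rev(dimnames(gt))
    }
    info <- vapply(fix[, "INFO"], function(s) {
      m <- regmatches(s, regexec(paste0(info_key, "=([0-9.eE+-]+)"), s))[[1]]
      if (length(m) == 2L) as.numeric(m[2]) else NA_real_
    }, 0, USE.NAMES = FALSE)
    meta <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                       alt = fix[, "ALT"], info = info,
                       stringsAsFactors = FALSE)
    colnames(G) <- meta$snp_id
    list(genotypes = G, variant_meta = meta, sample_ids = rownames(G))
  } else {
    d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
    G <- as.matrix(d[, -1L, drop = FALSE])
    rownames(G) <- d[[1L]]
    meta <- data.frame(snp_id = colnames(G), chrom = NA_character_,
                       pos = NA_integer_, ref = NA_character_,
                       alt = NA_character_, info = NA_real_,
                       stringsAsFactors = FALSE)
    list(genotypes = G, variant_meta = meta, sample_ids = d[[1L]])
  }
}

#' Write a dosage matrix as TSV
#' @param genotypes n x M dosage matrix.
#' @param path output path.
#' @param sample_ids subject ids.
#' @export
write_dosage_tsv <- function(genotypes, path, sample_ids = NULL) {
  sample_ids <- sample_ids %||% rownames(genotypes) %||%
    sprintf("S%04d", seq_len(nrow(genotypes)))
  d <- data.frame(subject_id = sample_ids, genotypes, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write landmark configurations as a long TSV
#'
#' One row per subject x landmark: subject_id, landmark_id, x, y, z (mm,
#' full double precision, so a write/read roundtrip is exact to 1e-12).
#'
#' @param shapes n x L x 3 array (or `cohort_bundle`).
#' @param path output path.
#' @param subject_ids subject identifiers.
#' @export
write_shapes <- function(shapes, path, subject_ids = NULL) {
  if (inherits(shapes, "cohort_bundle")) {
    subject_ids <- subject_ids %||% shapes$covariates$subject_id
    shapes <- shapes$shapes
  }
  n <- dim(shapes)[1]
  L <- dim(shapes)[2]
  subject_ids <- subject_ids %||% sprintf("S%04d", seq_len(n))
  d <- data.frame(subject_id = rep(subject_ids, each = L),
                  landmark_id = rep(seq_len(L), n),
                  x = sprintf("%.17g", as.vector(t(shapes[, , 1]))),
                  y = sprintf("%.17g", as.vector(t(shapes[, , 2]))),
                  z = sprintf("%.17g", as.vector(t(shapes[, , 3]))),
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read landmark configurations from a long TSV
#' @param path TSV written by [write_shapes()] (subject_id, landmark_id,
#'   x, y, z).
#' @return list: `shapes` (n x L x 3 array), `subject_ids`.
#' @export
read_shapes <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!nrow(d)) return(list(shapes = array(0, c(0, 0, 3)),
                            subject_ids = character(0)))
  need <- c("subject_id", "landmark_id", "x", "y", "z")
  if (!all(need %in% names(d))) {
    stop("shape table must have columns: ", paste(need, collapse = ", "))
  }
  subjects <- unique(d$subject_id)
  L <- max(d$landmark_id)
  counts <- table(d$subject_id)
  if (any(counts != L)) {
    stop("missing landmark rows for subject(s): ",
         paste(names(counts)[counts != L], collapse = ", "))
  }
  arr <- array(NA_real_, c(length(subjects), L, 3))
  for (i in seq_along(subjects)) {
    di <- d[d$subject_id == subjects[i], ]
    di <- di[order(di$landmark_id), ]
    arr[i, , ] <- cbind(di$x, di$y, di$z)
  }
  list(shapes = arr, subject_ids = subjects)
}

#' Write per-SNP x segment summary statistics as TSV
#'
#' Fixed header order (snp_id, chrom, pos, ref, alt, maf, segment_id,
#' canonical_r, f_stat, df1, df2, p); p in scientific notation with 7
#' significant digits for bit-reproducible formatting.
#'
#' @param associations association data.frame from a `scan_result`.
#' @param path output path.
#' @param variant_meta optional data.frame to supply chrom/pos/ref/alt/maf.
#' @export
write_summary_stats <- function(associations, path, variant_meta = NULL) {
  cols <- c("snp_id", "chrom", "pos", "ref", "alt", "maf", "segment_id",
            "canonical_r", "f_stat", "df1", "df2", "p")
  d <- associations
  if (!is.null(variant_meta)) {
    mi <- match(d$snp_id, variant_meta$snp_id)
    for (nm in c("chrom", "pos", "ref", "alt")) {
      d[[nm]] <- variant_meta[[nm]][mi]
    }
    fr <- variant_meta$freq[mi]
    d$maf <- if (!is.null(fr)) pmin(fr, 1 - fr) else variant_meta$maf[mi]
  }
  for (nm in cols) if (is.null(d[[nm]])) d[[nm]] <- rep(NA, nrow(d))
  d <- d[, cols]
  d$p <- sprintf("%.6e", as.numeric(d$p))
  for (nm in c("canonical_r", "f_stat", "maf")) {
    d[[nm]] <- sprintf("%.10g", as.numeric(d[[nm]]))
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read summary statistics written by [write_summary_stats()]
#' @param path TSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_summary_stats <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a truth record of planted effects as structured text
#' @param truth the `truth` element of a `cohort_bundle`.
#' @param path output path (YAML).
#' @export
write_truth <- function(truth, path) {
  tr <- truth
  tr$causal_effects <- lapply(tr$causal_effects, function(e) {
    list(snp_index = e$snp_index, landmarks = as.integer(e$landmarks),
         direction = as.numeric(t(e$direction)), beta = e$beta)
  })
  yaml::write_yaml(tr, path)
  invisible(path)
}
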