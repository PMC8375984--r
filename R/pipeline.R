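#' Phenotype one cohort: GPA, symmetrization, QC, adjustment,
#' segmentation, per-segment PCA
#'
#' The standard phenotyping chain for one cohort of landmark
#' configurations: Procrustes superimposition (size removed to unit
#' centroid size), left/right symmetrization, Mahalanobis outlier
#' flagging, ancestry PCs from the cohort's own genotypes, covariate
#' residualization (sex, age, age squared, height, weight, centroid size
#' and the ancestry PCs), global-to-local segmentation and per-segment
#' PCA phenotypes.
#'
#' @param bundle a `cohort_bundle` (or list with shapes, covariates,
#'   genotypes, variant_meta, template).
#' @param depth segmentation depth (5 gives 63 segments).
#' @param n_pcs ancestry PCs to adjust for.
#' @param n_permutations,seed parallel-analysis settings.
#' @param drop_outliers drop subjects flagged by the Mahalanobis QC
#'   (default FALSE: the study inspected rather than auto-dropped them).
#' @param log function receiving progress lines (e.g. `message`).
#' @return list of class `phenotyped_cohort`: aligned, qc, ancestry_pcs,
#'   adjusted, tree, models, retained (subject indices), genotypes,
#'   variant_meta, covariates.
#' @export
phenotype_cohort <- function(bundle, depth = 5L, n_pcs = 4L,
                             n_permutations = 100L, seed = 1L,
                             drop_outliers = FALSE, log = NULL) {
  say <- function(...) if (!is.null(log)) log(paste0(...))
  n <- dim(bundle$shapes)[1]
  say("phenotype: ", n, " subjects, ", dim(bundle$shapes)[2], " landmarks")
  aligned <- gpa_align(bundle$shapes, scale = TRUE)
  aligned <- symmetrize(aligned, bundle$template)
  qc <- flag_outliers(aligned)
  say("phenotype: QC flagged ", length(qc$flagged),
      " of ", n, " subjects (|z| > 2)")
  retained <- seq_len(n)
  if (drop_outliers && length(qc$flagged)) {
    retained <- setdiff(retained, qc$flagged)
    aligned$shapes <- aligned$shapes[retained, , drop = FALSE]
    aligned$centroid_sizes <- aligned$centroid_sizes[retained]
    say("phenotype: dropped ", n - length(retained), " -> ",
        length(retained), " retained")
  }
  covariates <- bundle$covariates[retained, , drop = FALSE]
  genotypes <- bundle$genotypes[retained, , drop = FALSE]
  pcs <- compute_ancestry_pcs(genotypes, bundle$variant_meta, n_pcs = n_pcs)
  colnames(pcs) <- paste0("ancestry_pc", seq_len(ncol(pcs)))
  adjusted <- adjust_covariates(aligned, covariates, extra = pcs)
  tree <- build_segment_tree(adjusted, depth = depth)
  say("phenotype: segmentation -> ", nrow(tree$nodes), " segments (depth ",
      depth, ")")
  models <- fit_all_segments(adjusted, tree, seed = seed,
                             n_permutations = n_permutations)
  ks <- vapply(models, function(m) ncol(m$scores), 0L)
  say("phenotype: retained PCs per segment: ", min(ks), "-", max(ks))
  structure(list(aligned = aligned, qc = qc, ancestry_pcs = pcs,
                 adjusted = adjusted, tree = tree, models = models,
                 retained = retained, genotypes = genotypes,
                 variant_meta = bundle$variant_meta,
                 covariates = covariates),
            class = "phenotyped_cohort")
}

#' Read a pipeline configuration file
#'
#' Flat YAML key-value file; anything omitted falls back to the defaults
#' of [run_pipeline()]. Overrides supplied in `...` win over the file.
#'
#' @param path YAML file path (optional).
#' @param ... named overrides.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  dots <- list(...)
  cfg[names(dots)] <- dots
  defaults <- list(seed = 1L, n_subjects = 300L, n_snps = 1500L,
                   depth = 5L, n_pcs = 4L, n_permutations = 50L,
                   genome_wide = 2.5e-8, n_signals = NULL,
                   window = 500000L, enrichment_fold = 3,
                   n_target_tracks = 10L, n_background_tracks = 60L,
                   landmark_count = 256L, out_dir = NULL)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full demonstration pipeline on a simulated cohort pair
#'
#' End-to-end driver: simulates two cohorts with shared planted signals,
#' phenotypes both, QC-filters variants, scans cohort A, defines loci,
#' runs the T1-T5 replication battery in cohort B, and tests enhancer
#' enrichment at the lead-SNP windows on simulated coverage tracks. Every
#' stage logs its input count, the filter applied, and its output count;
#' all outputs are TSV/YAML files in `out_dir`.
#'
#' @param config a [pipeline_config()] (or path to one).
#' @param shared_causal optional list of causal effects; when NULL, two
#'   shared effects are planted along local latent modes with betas
#'   calibrated for 2\% segment variance explained.
#' @return list of class `pipeline_result` with the stage outputs and the
#'   log; files are written when `config$out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config(), shared_causal = NULL) {
  if (is.character(config)) config <- pipeline_config(config)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  say("config: seed=", config$seed, " n_subjects=", config$n_subjects,
      " n_snps=", config$n_snps, " depth=", config$depth)

  template <- make_template(config$landmark_count, seed = config$seed)
  struct <- latent_structure(template)
  if (is.null(shared_causal)) {
    regions <- sort(unique(template$region_labels))
    pick <- regions[c(3L, 20L) %% length(regions) + 1L]
    shared_causal <- lapply(seq_along(pick), function(i) {
      lms <- which(template$region_labels == pick[i])
      snp <- as.integer(round(config$n_snps * i / 3))
      list(snp_index = snp, landmarks = lms,
           direction = node_direction(struct, lms, level = 4L),
           beta = calibrate_beta(struct, 0.3, lms, 0.3, target_r2 = 0.02))
    })
  }
  cfg_a <- simulation_config(seed = config$seed,
                             n_subjects = config$n_subjects,
                             n_snps = config$n_snps, fst = 0.1)
  cfg_b <- simulation_config(seed = config$seed + 1000L,
                             n_subjects = config$n_subjects,
                             n_snps = config$n_snps, fst = 0.1)
  pair <- simulate_cohort_pair(cfg_a, cfg_b, template,
                               shared_causal = shared_causal)
  say("simulate: 2 cohorts x ", config$n_subjects, " subjects, ",
      config$n_snps, " SNPs, ", length(shared_causal), " shared signals")

  vf_a <- filter_variants(pair$a$genotypes, pair$a$variant_meta)
  vf_b <- filter_variants(pair$b$genotypes, pair$b$variant_meta)
  say("variant QC: cohort A ", ncol(pair$a$genotypes), " -> ",
      sum(vf_a$keep), " retained; cohort B ", ncol(pair$b$genotypes),
      " -> ", sum(vf_b$keep), " retained")
  keep_a <- which(vf_a$keep)
  keep_b <- which(vf_b$keep)
  ga <- pair$a
  gb <- pair$b
  ga$genotypes <- ga$genotypes[, keep_a, drop = FALSE]
  ga$variant_meta <- ga$variant_meta[keep_a, , drop = FALSE]
  gb$genotypes <- gb$genotypes[, keep_b, drop = FALSE]
  gb$variant_meta <- gb$variant_meta[keep_b, , drop = FALSE]

  ph_a <- phenotype_cohort(ga, depth = config$depth, n_pcs = config$n_pcs,
                           n_permutations = config$n_permutations,
                           seed = config$seed, log = say)
  ph_b <- phenotype_cohort(gb, depth = config$depth, n_pcs = config$n_pcs,
                           n_permutations = config$n_permutations,
                           seed = config$seed + 1L, log = say)

  scan_a <- run_scan(ph_a$models, ph_a$genotypes, ph_a$variant_meta,
                     genome_wide = config$genome_wide)
  scan_b <- run_scan(ph_b$models, ph_b$genotypes, ph_b$variant_meta,
                     genome_wide = config$genome_wide)
  say("scan: Meff = ", round(scan_a$meff, 2), "; study-wide threshold = ",
      signif(scan_a$thresholds$study_wide, 3))
  loci <- define_loci(scan_a$per_snp, threshold = config$genome_wide,
                      window = config$window)
  say("loci: ", nrow(loci), " genome-wide significant loci in cohort A")

  replication <- NULL
  if (nrow(loci)) {
    n_signals <- config$n_signals %||% nrow(loci)
    replication <- replicate_signals(loci, ph_a$models, scan_a, ph_a$tree,
                                     ph_b$tree, ph_b$adjusted, scan_b,
                                     gb$genotypes, ga$genotypes,
                                     n_signals = n_signals,
                                     meff_segments = scan_a$meff)
    say("replication: ", sum(replication$replicated), " of ",
        nrow(replication), " locus x test combinations replicate")
  }

  enrichment <- NULL
  if (nrow(loci)) {
    chrom_sizes <- tapply(ga$variant_meta$pos, ga$variant_meta$chrom, max) +
      20000
    windows <- make_windows(chrom_sizes)
    hits <- lead_snp_windows(loci, windows)
    cov <- simulate_coverage_tracks(windows, config$n_target_tracks,
                                    config$n_background_tracks,
                                    hit_windows = hits,
                                    fold = config$enrichment_fold,
                                    seed = config$seed)
    rpm <- sweep(cov$counts, 2, colSums(cov$counts), `/`) * 1e6
    normed <- quantile_normalize(rpm)
    enrichment <- enrichment_test(normed, hits, cov$samples$group)
    say("enrichment: ", length(hits), " lead-SNP windows, one-sided p = ",
        signif(enrichment$p, 3))
  }

  if (!is.null(out_dir)) {
    write_summary_stats(scan_a$associations,
                        file.path(out_dir, "scan_a_summary.tsv"),
                        ga$variant_meta)
    write.table(loci[, setdiff(names(loci), "member_snps")],
                file.path(out_dir, "loci.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(replication)) {
      write.table(replication, file.path(out_dir, "replication.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_truth(pair$a$truth, file.path(out_dir, "truth_a.yaml"))
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    say("outputs written to ", out_dir)
  }
  structure(list(template = template, pair = pair,
                 phenotypes = list(a = ph_a, b = ph_b),
                 scans = list(a = scan_a, b = scan_b), loci = loci,
                 replication = replication, enrichment = enrichment,
                 log = log_lines, config = config),
            class = "pipeline_result")
}
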