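#' Hierarchical latent shape-variation structure for a template
#'
#' Facial shape covariation is integrated at multiple scales: global modes
#' (overall face shape) coexist with increasingly local, regionally
#' confined modes. The generator emulates this with a balanced binary
#' hierarchy over the template's regions: every node of the hierarchy
#' carries one mirror-symmetric displacement field (a unit 3-vector per
#' landmark of the node, zero elsewhere), and every subject receives an
#' independent standard-normal score per node, scaled by that node level's
#' amplitude. Landmarks that share many nodes therefore covary strongly,
#' which is exactly the signal the RV-based segmentation recovers.
#'
#' @param template a `facial_template`.
#' @param structure_seed seed for the fields; cohorts that share a
#'   `structure_seed` share their covariance structure.
#' @param level_sd amplitudes (mm) of the node fields by hierarchy level,
#'   level 0 (whole face) first. Length sets the hierarchy depth. The
#'   default rises slightly toward the local levels: between-landmark
#'   similarity contrasts scale with the fourth power of the amplitudes,
#'   so comparable per-level amplitudes with stronger local integration
#'   keep every level of the hierarchy identifiable at moderate n.
#' @return list of class `latent_structure`: `nodes` (per node: id, level,
#'   region set, landmark set), `fields` (per node: L x 3 displacement
#'   field), `level_sd`.
#' @export
latent_structure <- function(template, structure_seed = 99L,
                             level_sd = c(1.0, 1.0, 1.1, 1.2, 1.3, 1.4)) {
  stopifnot(inherits(template, "facial_template"))
  depth <- length(level_sd) - 1L
  regions <- sort(unique(template$region_labels))
  if (length(regions) < 2^depth) {
    stop("template has ", length(regions), " regions; need >= ", 2^depth,
         " for a depth-", depth, " latent hierarchy")
  }
  set.seed(structure_seed)
  L <- template$landmark_count
  nodes <- list()
  fields <- list()
  id <- 0L
  for (lev in 0:depth) {
    blocks <- split(regions, ceiling(seq_along(regions) / (length(regions) / 2^lev)))
    for (b in blocks) {
      id <- id + 1L
      lms <- which(template$region_labels %in% b)
      nodes[[id]] <- list(id = id, level = lev, regions = b, landmarks = lms)
      fields[[id]] <- symmetric_field(template, lms)
    }
  }
  structure(list(nodes = nodes, fields = fields, level_sd = level_sd),
            class = "latent_structure")
}

# Mirror-symmetric random displacement field: unit 3-vectors on `landmarks`
# (zero elsewhere); a left landmark's vector is the x-reflection of its
# right partner's. Uses the current RNG stream.
symmetric_field <- function(template, landmarks) {
  L <- template$landmark_count
  f <- matrix(0, L, 3)
  partner <- integer(L)
  partner[template$bilateral_pairs[, 1]] <- template$bilateral_pairs[, 2]
  partner[template$bilateral_pairs[, 2]] <- template$bilateral_pairs[, 1]
  is_left <- logical(L)
  is_left[template$bilateral_pairs[, 2]] <- TRUE
  for (i in landmarks) {
    if (is_left[i] && partner[i] %in% landmarks) next  # filled via partner
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    if (i %in% template$midline) v[1] <- 0  # keep midline on the plane
    nv <- sqrt(sum(v^2))
    if (nv == 0) v <- c(0, 1, 0) else v <- v / nv
    f[i, ] <- v
    if (!is_left[i] && partner[i] != 0 && partner[i] %in% landmarks) {
      f[partner[i], ] <- v * c(-1, 1, 1)
    }
  }
  f
}

#' Simulation configuration for a synthetic cohort
#'
#' Bundles every knob of the generator. The defaults are the package's
#' reference study conditions: a single 5 kb-spaced chromosome, moderate
#' local LD, allometric covariate effects on a cohort aged 3-21, a
#' six-level latent shape hierarchy, and 0.3 mm isotropic landmark noise.
#'
#' @param seed integer; fully determines the cohort.
#' @param n_subjects,n_snps cohort and marker panel size.
#' @param maf_range,fst,ld_rho see [simulate_genotypes()].
#' @param causal_effects list of planted SNP effects, each a list with
#'   `snp_index`, `landmarks` (index set), `direction` (unit 3-vector or
#'   m x 3 matrix of per-landmark unit vectors) and `beta` (mm per alt
#'   allele).
#' @param covariate_effects named coefficients (mm per unit) for `age`,
#'   `age2`, `sex`, `height`, `weight` plus the relative `size` spread.
#' @param noise_sd isotropic per-coordinate landmark noise (mm).
#' @param structure_seed,level_sd latent hierarchy; see [latent_structure()].
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_subjects = 500L, n_snps = 2000L,
                              maf_range = c(0.05, 0.5), fst = 0,
                              ld_rho = 0.3,
                              causal_effects = list(),
                              covariate_effects = list(age = 0.15,
                                                       age2 = -0.003,
                                                       sex = 1.2,
                                                       height = 0.02,
                                                       weight = 0.02,
                                                       size = 0.03),
                              noise_sd = 0.3,
                              structure_seed = 99L,
                              level_sd = c(1.0, 1.0, 1.1, 1.2, 1.3, 1.4)) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              n_snps = as.integer(n_snps), maf_range = maf_range, fst = fst,
              ld_rho = ld_rho, causal_effects = causal_effects,
              covariate_effects = covariate_effects, noise_sd = noise_sd,
              structure_seed = as.integer(structure_seed),
              level_sd = level_sd)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a cohort of landmark configurations, covariates and genotypes
#'
#' Each subject's shape is the template mean plus (i) covariate effects
#' along fixed mirror-symmetric fields, (ii) hierarchical latent shape
#' variation, (iii) additive per-SNP displacements
#' (`dosage * beta * direction` on the effect's landmark set) and (iv)
#' isotropic Gaussian landmark noise; an overall size factor scales the
#' configuration. All planted effects are stored in the returned `truth`
#' record.
#'
#' @param config a [simulation_config()].
#' @param template a [make_template()] template.
#' @param ancestral_freqs optional shared ancestral allele frequencies
#'   (used by [simulate_cohort_pair()]).
#' @return list of class `cohort_bundle`: `shapes` (n x L x 3 array, mm),
#'   `covariates` (data.frame: subject_id, age, sex, height, weight),
#'   `genotypes` (n x M dosage matrix), `variant_meta`, `truth`,
#'   `template`.
#' @export
simulate_cohort <- function(config, template, ancestral_freqs = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(template, "facial_template"))
  L <- template$landmark_count
  n <- config$n_subjects
  for (eff in config$causal_effects) {
    if (any(eff$landmarks < 1L | eff$landmarks > L)) {
      stop("causal effect landmark index out of range 1..", L)
    }
    if (eff$snp_index < 1L || eff$snp_index > config$n_snps) {
      stop("causal effect snp_index out of range 1..", config$n_snps)
    }
  }
  structure_obj <- latent_structure(template, config$structure_seed,
                                    config$level_sd)
  # covariate fields share the structure stream so cohort pairs agree
  cov_fields <- list(age = symmetric_field(template, 1:L),
                     sex = symmetric_field(template, 1:L),
                     height = symmetric_field(template, 1:L),
                     weight = symmetric_field(template, 1:L))
  cov_fields$age2 <- cov_fields$age

  geno <- simulate_genotypes(n, config$n_snps, config$maf_range, config$fst,
                             config$ld_rho, seed = config$seed + 1L,
                             ancestral_freqs = ancestral_freqs)

  set.seed(config$seed)
  age <- runif(n, 3, 21)
  sex <- rbinom(n, 1L, 0.5)
  height <- 85 + 4.8 * age + rnorm(n, 0, 7)
  weight <- 8 + 2.6 * age + rnorm(n, 0, 5)
  covariates <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                           age = age, sex = sex, height = height,
                           weight = weight, stringsAsFactors = FALSE)

  X <- matrix(rep(flatten_config(template$coordinates), each = n), nrow = n)
  ce <- config$covariate_effects
  add_field <- function(X, values, field) {
    X + tcrossprod(values, flatten_config(field))
  }
  cvals <- list(age = age - mean(age), age2 = age^2 - mean(age^2),
                sex = sex - mean(sex), height = height - mean(height),
                weight = weight - mean(weight))
  for (nm in intersect(names(cvals), names(ce))) {
    if (!is.null(ce[[nm]]) && ce[[nm]] != 0) {
      X <- add_field(X, ce[[nm]] * cvals[[nm]], cov_fields[[nm]])
    }
  }
  for (k in seq_along(structure_obj$nodes)) {
    amp <- structure_obj$level_sd[structure_obj$nodes[[k]]$level + 1L]
    if (amp > 0) X <- add_field(X, amp * rnorm(n), structure_obj$fields[[k]])
  }
  for (eff in config$causal_effects) {
    f <- matrix(0, L, 3)
    dir <- eff$direction
    if (is.null(dim(dir))) {
      dir <- matrix(rep(dir / sqrt(sum(dir^2)), length(eff$landmarks)),
                    ncol = 3, byrow = TRUE)
    }
    f[eff$landmarks, ] <- dir
    X <- add_field(X, eff$beta * geno$genotypes[, eff$snp_index], f)
  }
  if (config$noise_sd > 0) {
    X <- X + matrix(rnorm(n * 3L * L, 0, config$noise_sd), n)
  }
  size_coef <- ce$size %||% 0
  if (size_coef != 0) X <- X * (1 + size_coef * rnorm(n))

  truth <- list(causal_effects = config$causal_effects,
                structure_seed = config$structure_seed,
                level_sd = config$level_sd,
                covariate_effects = ce, noise_sd = config$noise_sd)
  structure(list(shapes = unflatten_shapes(X), covariates = covariates,
                 genotypes = geno$genotypes, variant_meta = geno$variant_meta,
                 truth = truth, template = template,
                 ancestral_freqs = geno$ancestral_freqs),
            class = "cohort_bundle")
}

#' Simulate two cohorts sharing a template, with shared and
#' population-specific causal SNPs
#'
#' Both cohorts draw their allele frequencies from one ancestral pool (the
#' per-cohort `fst` applies Balding-Nichols divergence to each) and share
#' the latent shape-covariance structure; shared causal SNPs act with
#' identical landmark sets, directions and betas in both cohorts, while
#' specific effects act in one cohort only.
#'
#' @param config_a,config_b [simulation_config()]s for the two cohorts;
#'   their `structure_seed`/`level_sd` must agree.
#' @param template shared `facial_template`.
#' @param shared_causal,specific_a,specific_b lists of causal-effect
#'   specifications as in [simulation_config()].
#' @param ancestral_freqs optional ancestral allele-frequency vector for
#'   the shared pool (drawn uniformly on `config_a$maf_range` otherwise);
#'   useful to pin a causal SNP's frequency.
#' @return list with cohorts `a` and `b` (each a `cohort_bundle`).
#' @export
simulate_cohort_pair <- function(config_a, config_b, template,
                                 shared_causal = list(),
                                 specific_a = list(), specific_b = list(),
                                 ancestral_freqs = NULL) {
  if (!identical(config_a$structure_seed, config_b$structure_seed) ||
      !identical(config_a$level_sd, config_b$level_sd)) {
    stop("cohort pair must share structure_seed and level_sd")
  }
  if (config_a$n_snps != config_b$n_snps) {
    stop("cohort pair must share the marker panel (n_snps differ)")
  }
  set.seed(config_a$seed + 7L)
  p_anc <- ancestral_freqs %||%
    runif(config_a$n_snps, min(config_a$maf_range), max(config_a$maf_range))
  stopifnot(length(p_anc) == config_a$n_snps)
  config_a$causal_effects <- c(shared_causal, specific_a)
  config_b$causal_effects <- c(shared_causal, specific_b)
  a <- simulate_cohort(config_a, template, ancestral_freqs = p_anc)
  b <- simulate_cohort(config_b, template, ancestral_freqs = p_anc)
  list(a = a, b = b)
}

#' Analytic effect-size calibration for a planted SNP effect
#'
#' Chooses `beta` (mm per allele) so that the SNP explains a target
#' fraction of the total shape variance of its landmark set, using the
#' generator's closed-form variance components: per landmark, latent
#' variance is the sum of squared level amplitudes over the nodes covering
#' it, and noise contributes `3 * noise_sd^2` (halved when the pipeline
#' symmetrizes shapes, which averages away half of the asymmetric noise).
#'
#' @param structure a [latent_structure()].
#' @param noise_sd generator noise (mm).
#' @param landmarks effect landmark set.
#' @param maf allele frequency of the causal SNP.
#' @param target_r2 target fraction of segment shape variance explained.
#' @param symmetrized whether downstream phenotyping symmetrizes shapes.
#' @return beta in mm per alt allele.
#' @export
calibrate_beta <- function(structure, noise_sd, landmarks, maf,
                           target_r2 = 0.02, symmetrized = TRUE) {
  stopifnot(inherits(structure, "latent_structure"), target_r2 > 0,
            target_r2 < 1)
  per_lm <- vapply(landmarks, function(i) {
    sum(vapply(seq_along(structure$nodes), function(k) {
      if (i %in% structure$nodes[[k]]$landmarks) {
        structure$level_sd[structure$nodes[[k]]$level + 1L]^2
      } else 0
    }, 0))
  }, 0)
  noise_var <- 3 * noise_sd^2 * (if (symmetrized) 0.5 else 1)
  v_rest <- sum(per_lm) + length(landmarks) * noise_var
  m <- length(landmarks)
  sqrt(target_r2 / (1 - target_r2) * v_rest / (2 * maf * (1 - maf) * m))
}

#' Extract a node's displacement field restricted to a landmark set
#'
#' Convenience for planting causal effects along an existing mode of
#' variation (so the effect lives inside the subspace the per-segment PCA
#' retains): returns the per-landmark unit vectors of the latent node that
#' covers `landmarks` at the requested level.
#'
#' @param structure a [latent_structure()].
#' @param landmarks landmark index set (must be covered by one node at
#'   `level`).
#' @param level hierarchy level of the node to use.
#' @return m x 3 matrix of unit direction vectors, rows ordered as
#'   `landmarks`.
#' @export
node_direction <- function(structure, landmarks, level) {
  for (k in seq_along(structure$nodes)) {
    nd <- structure$nodes[[k]]
    if (nd$level == level && all(landmarks %in% nd$landmarks)) {
      return(structure$fields[[k]][landmarks, , drop = FALSE])
    }
  }
  stop("no level-", level, " latent node covers the requested landmark set")
}
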