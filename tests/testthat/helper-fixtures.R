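# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small template: 64 landmarks, 32 two-landmark regions
small_template <- function() fixture("tpl64", function() {
  make_template(64, seed = 11)
})

# standard template: 256 landmarks, 32 eight-landmark regions
std_template <- function() fixture("tpl256", function() {
  make_template(256, seed = 1)
})

# a phenotyped null cohort on the small template (no planted SNP effects)
small_cohort <- function() fixture("cohort64", function() {
  tpl <- small_template()
  cfg <- simulation_config(seed = 5, n_subjects = 120, n_snps = 150)
  bundle <- simulate_cohort(cfg, tpl)
  aligned <- symmetrize(gpa_align(bundle$shapes), tpl)
  adjusted <- adjust_covariates(aligned, bundle$covariates)
  list(template = tpl, bundle = bundle, aligned = aligned,
       adjusted = adjusted)
})

# segment tree + models on the small cohort (depth 3: deeper trees on a
# 64-landmark template produce <= 2-landmark segments, which have no shape
# degrees of freedom after Procrustes alignment)
small_models <- function() fixture("models64", function() {
  sc <- small_cohort()
  tree <- build_segment_tree(sc$adjusted, depth = 3)
  models <- fit_all_segments(sc$adjusted, tree, seed = 3,
                             n_permutations = 30)
  list(tree = tree, models = models)
})

# phenotype one simulated bundle up to adjusted shapes (no ancestry PCs,
# which need a wide marker panel)
adjust_bundle <- function(bundle) {
  aligned <- symmetrize(gpa_align(bundle$shapes), bundle$template)
  adjust_covariates(aligned, bundle$covariates)
}

# deepest tree segment with maximal Dice overlap with a landmark set
containing_segment <- function(tree, landmarks, level = 5L) {
  ids <- tree$nodes$segment_id[tree$nodes$level == level]
  dice <- vapply(ids, function(id) {
    s <- tree$landmarks[[id]]
    2 * length(intersect(s, landmarks)) / (length(s) + length(landmarks))
  }, 0)
  ids[which.max(dice)]
}
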