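test_that("GPA removes position, size and orientation and its objective is monotone", {
  # centroid size: 4-point planar square at (+/-1, +/-1, 0)
  sq <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 0)
  expect_equal(centroid_size(sq), sqrt(8))

  tpl <- small_template()
  base <- tpl$coordinates
  # identical configurations: zero Procrustes distance, consensus equals them
  al0 <- gpa_align(array(rep(base, each = 2), c(2, 64, 3)))
  expect_lt(max(abs(al0$shapes[1, ] - al0$shapes[2, ])), 1e-12)
  cs <- facegwas:::center_scale(base)$coords
  expect_equal(al0$consensus, cs, tolerance = 1e-8)

  # rotated + translated copy aligns back onto the original
  th <- pi / 2
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(base %*% t(Rz), 2, c(10, 5, 0), `+`)
  al1 <- gpa_align(list(base, moved))
  expect_lt(sqrt(mean((al1$shapes[1, ] - al1$shapes[2, ])^2)), 1e-6)
  # centroid sizes reported pre-scaling
  expect_equal(al1$centroid_sizes, rep(centroid_size(base), 2),
               tolerance = 1e-9)

  # aligned shapes are centered with unit centroid size
  sc <- small_cohort()
  al <- gpa_align(sc$bundle$shapes)
  m1 <- facegwas:::unflatten_config(al$shapes[1, ])
  expect_lt(max(abs(colMeans(m1))), 1e-10)
  expect_equal(sum(m1^2), 1, tolerance = 1e-10)
  # objective (sum of squared distances to consensus) never increases
  expect_true(all(diff(al$objective_trace) <= 1e-12))

  # degenerate all-coincident configuration
  degen <- array(0, c(2, 64, 3))
  degen[2, , ] <- base
  expect_error(gpa_align(degen), "degenerate")
})

test_that("symmetrization averages left/right and is a projection", {
  # hand-computable 2-landmark case: pair at x = 1 and x = -2 maps to +/-1.5
  fake_tpl <- structure(list(landmark_count = 2L,
                             coordinates = rbind(c(1, 0, 0), c(-1, 0, 0)),
                             bilateral_pairs = rbind(c(1L, 2L)),
                             midline = integer(0)),
                        class = "facial_template")
  fake_al <- structure(list(shapes = rbind(c(1, 0, 0, -2, 0, 0)),
                            centroid_sizes = 1,
                            consensus = rbind(c(1, 0, 0), c(-1, 0, 0))),
                       class = "aligned_cohort")
  out <- symmetrize(fake_al, fake_tpl)
  expect_equal(out$shapes[1, ], c(1.5, 0, 0, -1.5, 0, 0))

  tpl <- small_template()
  sc <- small_cohort()
  sym <- symmetrize(gpa_align(sc$bundle$shapes), tpl)
  # output is exactly invariant under reflect + relabel
  for (i in c(1, 7)) {
    m <- facegwas:::unflatten_config(sym$shapes[i, ])
    expect_equal(facegwas:::reflect_relabel(m, tpl), m, tolerance = 1e-12)
  }
  # fixed point: symmetrizing twice changes nothing
  sym2 <- symmetrize(sym, tpl)
  expect_equal(sym2$shapes, sym$shapes, tolerance = 1e-12)
  # incomplete pairing errors
  bad_tpl <- tpl
  bad_tpl$midline <- integer(0)
  bad_tpl$bilateral_pairs <- tpl$bilateral_pairs[-1, ]
  expect_error(symmetrize(sym, bad_tpl), "cover every landmark")
})

test_that("Mahalanobis QC flags planted outliers at the expected rate", {
  tpl <- small_template()
  set.seed(42)
  # identical shapes + tiny iid jitter: ~2.3% beyond z = 2 in expectation
  fracs <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(150 * 30, sd = 0.01), 150, 30) +
      rep(1, 150) %o% rnorm(30)
    qc <- flag_outliers(X)
    length(qc$flagged) / 150
  }, 0)
  expect_gt(mean(fracs), 0.005)
  expect_lt(mean(fracs), 0.05)

  # one planted shape far from the mean is flagged
  sc <- small_cohort()
  X <- sc$aligned$shapes
  mu <- colMeans(X)
  X[3, ] <- mu + 10 * apply(X, 2, sd) * sign(rnorm(ncol(X)))
  qc <- flag_outliers(X)
  expect_true(3 %in% qc$flagged)
  # n too small for the covariance estimate
  expect_error(flag_outliers(X[1:2, ]), "too few")
})

test_that("covariate adjustment removes spanned effects exactly", {
  sc <- small_cohort()
  adj <- sc$adjusted
  covs <- sc$bundle$covariates
  # residuals orthogonal to every covariate column
  for (v in list(covs$age, covs$age^2, covs$sex, covs$height, covs$weight,
                 sc$aligned$centroid_sizes)) {
    expect_lt(max(abs(cor(adj$residuals[, 1:30], v))), 1e-10)
  }
  # covariate orthogonal to shapes by construction: residuals = centered input
  set.seed(8)
  X <- matrix(rnorm(50 * 12), 50, 12)
  v <- rnorm(50)
  v_orth <- qr.resid(qr(cbind(1, X)), v)
  ctab <- data.frame(age = v_orth)
  adj2 <- adjust_covariates(X, ctab, covariate_list = "age")
  expect_equal(adj2$residuals, scale(X, scale = FALSE),
               tolerance = 1e-10, ignore_attr = TRUE)

  # planted pure-age effect with no noise is removed to machine zero
  tpl <- small_template()
  cfg <- simulation_config(seed = 4, n_subjects = 100, n_snps = 10,
                           covariate_effects = list(age = 0.4),
                           noise_sd = 0, level_sd = rep(0, 6))
  b <- simulate_cohort(cfg, tpl)
  Xf <- facegwas:::flatten_shapes(b$shapes)
  adj3 <- adjust_covariates(Xf, b$covariates, covariate_list = "age")
  expect_lt(max(apply(adj3$residuals, 2, var)), 1e-20)

  # rank-deficient design names the collinear column
  ctab2 <- data.frame(age = covs$age, sex = covs$sex, dup = covs$age)
  expect_error(adjust_covariates(sc$aligned$shapes, ctab2,
                                 covariate_list = c("age", "sex", "dup")),
               "dup")
  expect_error(adjust_covariates(sc$aligned$shapes,
                                 data.frame(age = c(NA, covs$age[-1])),
                                 covariate_list = "age"), "missing")
})

test_that("segmentation yields the full bifurcating hierarchy and recovers planted blocks", {
  sc <- small_cohort()
  tree <- build_segment_tree(sc$adjusted, depth = 5)
  expect_equal(nrow(tree$nodes), 63)
  expect_equal(sum(tree$nodes$level == 5), 32)
  # children partition their parent everywhere
  for (id in 1:31) {
    kids <- sort(c(tree$landmarks[[2 * id]], tree$landmarks[[2 * id + 1]]))
    expect_identical(kids, sort(tree$landmarks[[id]]))
    expect_length(intersect(tree$landmarks[[2 * id]],
                            tree$landmarks[[2 * id + 1]]), 0)
  }
  expect_identical(sort(tree$landmarks[[1]]), 1:64)
  # depth 1 gives 3 segments
  expect_equal(nrow(build_segment_tree(sc$adjusted, depth = 1)$nodes), 3)

  # planted two-block covariance: the level-1 split recovers the blocks
  set.seed(10)
  n <- 150
  blockA <- 1:20
  blockB <- 21:40
  X <- matrix(rnorm(n * 120, sd = 0.05), n, 120)
  for (r in 1:3) {
    fA <- rnorm(n)
    fB <- rnorm(n)
    X[, facegwas:::coord_cols(blockA)] <-
      X[, facegwas:::coord_cols(blockA)] + fA %o% rnorm(60)
    X[, facegwas:::coord_cols(blockB)] <-
      X[, facegwas:::coord_cols(blockB)] + fB %o% rnorm(60)
  }
  tr <- build_segment_tree(X, depth = 1)
  split1 <- lapply(2:3, function(i) sort(tr$landmarks[[i]]))
  expect_true(identical(split1, list(blockA, blockB)) ||
                identical(split1, list(blockB, blockA)))
  # too-small node errors with advice
  expect_error(build_segment_tree(X[, 1:6], depth = 5), "larger template")
})

test_that("segment PCA retains dimensions per parallel analysis and keeps PCA identities", {
  sc <- small_cohort()
  sm <- fit_segment_pca(sc$adjusted, 1:8, seed = 2)
  # scores centered with diagonal covariance equal to the eigenvalues
  expect_lt(max(abs(colMeans(sm$scores))), 1e-12)
  cv <- crossprod(sm$scores) / (nrow(sm$scores) - 1)
  expect_equal(cv, diag(sm$eigenvalues, ncol(sm$scores)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(crossprod(sm$eigenvectors),
               diag(ncol(sm$eigenvectors)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # trace identity: eigenvalues sum to the total variance of the centered
  # segment-aligned data (recomputed independently)
  configs <- facegwas:::segment_configurations(sc$adjusted, 1:8)
  al <- gpa_align(configs)
  tot <- sum(scale(al$shapes, scale = FALSE)^2) / (nrow(al$shapes) - 1)
  expect_equal(sum(sm$all_eigenvalues), tot, tolerance = 1e-10)

  # rank-3 signal + small noise: k lands in {2, 3, 4} across seeds
  ks <- vapply(1:20, function(s) {
    set.seed(s + 100)
    n <- 120
    Y <- matrix(rnorm(n * 3), n, 3) %*% matrix(rnorm(3 * 24), 3, 24)
    Y <- Y + matrix(rnorm(n * 24, sd = 0.25), n, 24)
    sv <- svd(scale(Y, scale = FALSE))
    ev <- sv$d^2 / (n - 1)
    perm <- replicate(100, {
      Yp <- apply(Y, 2, sample)
      (svd(scale(Yp, scale = FALSE), nu = 0, nv = 0)$d^2 / (n - 1))[1:24]
    })
    thr <- apply(perm, 1, quantile, probs = 0.95)
    keep <- ev > thr
    if (any(!keep)) which(!keep)[1] - 1L else sum(keep)
  }, 0L)
  expect_true(all(ks >= 2 & ks <= 4))

  # pure iid noise keeps at most 2 PCs in >= 90% of seeds (end to end; a
  # 16-landmark segment keeps the Procrustes rank reduction of 7 dims well
  # inside the permutation-null eigenvalue bulk)
  tpl <- small_template()
  ks_null <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(80 * 192, sd = 0.1), 80, 192)
    X <- sweep(X, 2, facegwas:::flatten_config(tpl$coordinates), `+`)
    adj <- adjust_covariates(X, data.frame(age = runif(80, 3, 21)),
                             covariate_list = "age")
    ncol(fit_segment_pca(adj, 1:16, seed = s)$scores)
  }, 0L)
  expect_gte(mean(ks_null <= 2), 0.9)

  expect_error(fit_segment_pca(sc$adjusted, integer(0)), "empty")
  expect_error(fit_segment_pca(sc$adjusted, 3), "single|zero-variance")
})

test_that("a planted local effect concentrates genotype R2 in its containing segment", {
  tpl <- std_template()
  struct <- latent_structure(tpl)
  # first pass: segment the null cohort and pick one level-5 segment, so
  # the planted effect is confined to an actual segment's landmark set
  cfg0 <- simulation_config(seed = 31, n_subjects = 250, n_snps = 50,
                            noise_sd = 0)
  tree0 <- build_segment_tree(adjust_bundle(simulate_cohort(cfg0, tpl)))
  lms <- tree0$landmarks[[40]]
  eff <- list(list(snp_index = 5, landmarks = lms,
                   direction = node_direction(struct, lms, level = 0),
                   beta = calibrate_beta(struct, 0, lms, 0.3,
                                         target_r2 = 0.05,
                                         symmetrized = TRUE)))
  cfg <- simulation_config(seed = 31, n_subjects = 250, n_snps = 50,
                           causal_effects = eff, noise_sd = 0)
  b <- simulate_cohort(cfg, tpl)
  adj <- adjust_bundle(b)
  tree <- build_segment_tree(adj)
  target <- containing_segment(tree, lms)
  g <- b$genotypes[, 5]
  r2s <- vapply(tree$nodes$segment_id[tree$nodes$level == 5], function(id) {
    sm <- fit_segment_pca(adj, tree, segment_id = id, seed = id,
                          n_permutations = 30)
    cca_association(g, sm$scores)$canonical_r^2
  }, 0)
  names(r2s) <- tree$nodes$segment_id[tree$nodes$level == 5]
  disjoint <- vapply(names(r2s), function(id) {
    !length(intersect(tree$landmarks[[as.integer(id)]], lms))
  }, TRUE)
  expect_gt(r2s[as.character(target)], max(r2s[disjoint]))
})
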