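# brute-force HWE oracle: enumerate heterozygote counts with choose()
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) -
          lchoose(2 * n, nA))
  }, 0)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hets)] * (1 + 1e-12)])
}

test_that("HWE exact test matches full enumeration and its symmetries", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
  set.seed(1)
  for (i in 1:25) {
    counts <- rmultinom(1, sample(20:200, 1), prob = runif(3))[, 1]
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 hwe_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-12)
    # allele-label symmetry
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 hwe_exact_test(counts[3], counts[2], counts[1]),
                 tolerance = 1e-12)
  }
  # gross heterozygote excess is detected
  expect_lt(hwe_exact_test(0, 100, 0), 1e-6)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("variant filters apply INFO, call rate, MAF and HWE thresholds", {
  # hand-checkable toy table: SNP 1 fails MAF, 2 fails HWE, 3 fails INFO
  make_geno <- function(f, n = 200) {
    g <- rbinom(n, 1, f) + rbinom(n, 1, f)
    if (sum(g) == 0) g[1] <- 1
    g
  }
  set.seed(2)
  G <- cbind(c(rep(0, 199), 1),          # maf 0.0025
             c(rep(0, 100), rep(1, 100)),  # all hets: HWE fails
             make_geno(0.25), make_geno(0.4), make_geno(0.3),
             make_geno(0.1))
  meta <- data.frame(snp_id = paste0("s", 1:6),
                     info = c(0.9, 0.9, 0.5, 0.95, 0.85, 0.99))
  vf <- filter_variants(G, meta)
  expect_identical(vf$keep, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(vf$reason[1:3], c("maf", "hwe", "info"))
  # monomorphic SNP excluded
  G2 <- cbind(rep(0, 200), make_geno(0.3))
  vf2 <- filter_variants(G2, data.frame(snp_id = c("m", "p")))
  expect_false(vf2$keep[1])
  # all-pass table is retained in full
  vf3 <- filter_variants(G[, 4:6], meta[4:6, ])
  expect_true(all(vf3$keep))
  expect_warning(filter_variants(G[, 1, drop = FALSE], meta[1, ]),
                 "no variants")
})

test_that("ancestry PCs separate diverged populations and prune duplicated SNPs", {
  tplmeta <- function(M) data.frame(snp_id = sprintf("s%d", 1:M),
                                    chrom = "1", pos = 5000L * (1:M))
  # two populations at fst = 0.15: PC1 separates them almost perfectly
  gA <- simulate_genotypes(250, 2000, fst = 0.15, ld_rho = 0.2, seed = 41)
  gB <- simulate_genotypes(250, 2000, fst = 0.15, ld_rho = 0.2, seed = 42,
                           ancestral_freqs = gA$ancestral_freqs)
  G <- rbind(gA$genotypes, gB$genotypes)
  pcs <- compute_ancestry_pcs(G, tplmeta(2000))
  pop <- rep(0:1, each = 250)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)

  # duplicated SNP columns: only the first survives pruning
  g <- simulate_genotypes(100, 10, seed = 5)
  Gd <- cbind(g$genotypes, g$genotypes[, 1])
  kept <- attr(compute_ancestry_pcs(Gd, tplmeta(11)), "kept_snps")
  expect_true(1 %in% kept)
  expect_false(11 %in% kept)

  # fst = 0: no PC separates the (arbitrary) halves in >= 90% of seeds
  seps <- vapply(1:10, function(s) {
    g0 <- simulate_genotypes(200, 400, fst = 0, ld_rho = 0, seed = 100 + s)
    p0 <- compute_ancestry_pcs(g0$genotypes, tplmeta(400))
    max(abs(cor(p0, rep(0:1, each = 100))))
  }, 0)
  expect_gte(mean(seps < 0.2), 0.9)
  expect_error(compute_ancestry_pcs(matrix(1, 50, 3), tplmeta(3)),
               "survive")
})

test_that("CCA association equals the overall-regression F test and its oracles", {
  set.seed(7)
  # perfect correlation: Y's single column is the dosage
  g <- rbinom(40, 2, 0.4)
  rec <- cca_association(g, matrix(g, ncol = 1))
  expect_equal(rec$canonical_r, 1)
  expect_lt(rec$p, 1e-200)

  # n = 12, k = 1, empirical r exactly 0.6: F = 0.36*10/0.64 = 5.625
  g12 <- scale(rnorm(12))[, 1]
  e <- qr.resid(qr(cbind(1, g12)), rnorm(12))
  e <- e / sqrt(sum(e^2) / 11)
  y <- 0.6 * g12 + sqrt(1 - 0.36) * e
  rec12 <- cca_association(g12, matrix(y, ncol = 1))
  expect_equal(rec12$canonical_r, 0.6, tolerance = 1e-10)
  expect_equal(rec12$f_stat, 5.625, tolerance = 1e-9)
  expect_equal(rec12$p, pf(5.625, 1, 10, lower.tail = FALSE),
               tolerance = 1e-12)

  # random k = 5 instance: two independent oracles
  n <- 50
  Y <- matrix(rnorm(n * 5), n, 5)
  g5 <- rbinom(n, 2, 0.3) + 0.0
  rec5 <- cca_association(g5, Y)
  # oracle 1: brute-force maximization of |cor(g, Y w)| over random unit w
  set.seed(99)
  W <- matrix(rnorm(5 * 1e5), 5)
  W <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
  brute <- max(abs(cor(g5, Y %*% W)))
  expect_lt(abs(brute - rec5$canonical_r), 1e-3)
  # oracle 2: overall F test of the multivariate regression
  fs <- summary(lm(g5 ~ Y))$fstatistic
  p_lm <- pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  expect_lt(abs(rec5$p - p_lm), 1e-10)
  # loading is unit norm with positive largest entry, and reproduces the
  # canonical correlate
  expect_equal(sum(rec5$loading^2), 1, tolerance = 1e-12)
  expect_equal(as.numeric(abs(cor(g5, scale(Y, scale = FALSE) %*%
                                    rec5$loading))),
               rec5$canonical_r, tolerance = 1e-10)

  # zero-variance dosage is flagged, not an error
  rec0 <- cca_association(rep(1, 30), matrix(rnorm(60), 30))
  expect_equal(rec0$p, 1)
  expect_equal(rec0$flag, "zero_variance")
  expect_error(cca_association(g5[1:4], Y[1:4, ]), "insufficient")

  # allele flip leaves everything but the loading sign unchanged
  recf <- cca_association(2 - g5, Y)
  expect_equal(recf$canonical_r, rec5$canonical_r, tolerance = 1e-12)
  expect_equal(recf$p, rec5$p, tolerance = 1e-12)
})

test_that("Li-Ji Meff handles exact cases and is monotone under duplication", {
  expect_equal(liji_meff(diag(8)), 8, tolerance = 1e-9)
  expect_equal(liji_meff(matrix(1, 2, 2)), 1, tolerance = 1e-9)
  eq3 <- matrix(0.9, 3, 3)
  diag(eq3) <- 1
  expect_equal(liji_meff(eq3), 2.0, tolerance = 1e-9)
  set.seed(3)
  X <- matrix(rnorm(200 * 6), 200, 6)
  C <- cor(X)
  m0 <- liji_meff(C)
  expect_gte(m0, 1)
  expect_lte(m0, 6)
  # duplicating a trait never increases Meff
  C2 <- cor(cbind(X, X[, 1]))
  expect_lte(liji_meff(C2), m0 + 1e-9)
  expect_error(liji_meff(matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
})

test_that("threshold derivation is the Bonferroni quotient", {
  thr <- derive_thresholds(2.5e-8, 40)
  expect_equal(thr$study_wide, 6.25e-10)
  expect_equal(derive_thresholds(5e-8, 40)$study_wide, 1.25e-9)
  expect_equal(derive_thresholds(3e-7, 1)$study_wide, 3e-7)
  expect_error(derive_thresholds(2.5e-8, 0.5), "meff")
})

test_that("run_scan produces per-record F tests, Meff and per-SNP summaries", {
  sc <- small_cohort()
  sm <- small_models()
  scan <- run_scan(sm$models, sc$bundle$genotypes, sc$bundle$variant_meta)
  expect_equal(nrow(scan$associations), 150 * 15)
  expect_true(all(scan$associations$p > 0 & scan$associations$p <= 1))
  expect_gte(scan$meff, 1)
  expect_lte(scan$meff, 15)
  expect_equal(scan$thresholds$study_wide, 2.5e-8 / scan$meff)
  # fast path agrees with the per-SNP cca on a spot check
  j <- 17
  seg <- 12
  rec <- cca_association(sc$bundle$genotypes[, j],
                         sm$models[[seg]]$scores)
  row <- scan$associations[scan$associations$snp_id ==
                             colnames(sc$bundle$genotypes)[j] &
                             scan$associations$segment_id == seg, ]
  expect_equal(row$p, rec$p, tolerance = 1e-12)
  expect_equal(row$canonical_r, rec$canonical_r, tolerance = 1e-12)
  # missing dosages: complete cases per SNP only
  G <- sc$bundle$genotypes
  G[1:5, j] <- NA
  scan_na <- run_scan(list(sm$models[[seg]]), G, sc$bundle$variant_meta)
  rec_na <- cca_association(G[, j], sm$models[[seg]]$scores)
  row_na <- scan_na$associations[scan_na$associations$snp_id ==
                                   colnames(G)[j], ]
  expect_equal(row_na$p, rec_na$p, tolerance = 1e-12)
  expect_equal(rec_na$n, 115)
  # zero SNPs: empty table, valid thresholds
  scan0 <- run_scan(sm$models, G[, 0, drop = FALSE], NULL)
  expect_equal(nrow(scan0$associations), 0)
  expect_s3_class(scan0$thresholds, "scan_thresholds")
  # subject mismatch errors
  expect_error(run_scan(sm$models, G[1:50, ], NULL), "mismatch")
})

test_that("greedy clumping partitions significant SNPs into loci", {
  ps <- function(id, pos, p) data.frame(snp_id = id, chrom = "1",
                                        pos = pos, min_p = p,
                                        best_segment_id = 1L,
                                        n_significant_segments = 1L,
                                        stringsAsFactors = FALSE)
  # 100 kb apart: one locus
  t1 <- rbind(ps("a", 1e6, 1e-10), ps("b", 1.1e6, 1e-9))
  l1 <- define_loci(t1)
  expect_equal(nrow(l1), 1)
  expect_equal(l1$lead_snp, "a")
  expect_setequal(l1$member_snps[[1]], c("a", "b"))
  # 1.2 Mb apart: two loci
  t2 <- rbind(ps("a", 1e6, 1e-10), ps("b", 2.2e6, 1e-9))
  expect_equal(nrow(define_loci(t2)), 2)
  # planted 3-locus table: exact recovery with correct leads
  t3 <- rbind(ps("l1a", 1.0e6, 1e-12), ps("l1b", 1.2e6, 1e-9),
              ps("l2a", 5.0e6, 1e-15), ps("l2b", 5.4e6, 1e-10),
              ps("l3a", 9.0e6, 1e-9), ps("null", 12e6, 0.5))
  l3 <- define_loci(t3)
  expect_equal(nrow(l3), 3)
  expect_setequal(l3$lead_snp, c("l1a", "l2a", "l3a"))
  # members partition the significant SNPs within the window of their lead
  all_members <- unlist(l3$member_snps)
  expect_setequal(all_members, c("l1a", "l1b", "l2a", "l2b", "l3a"))
  expect_equal(anyDuplicated(all_members), 0)
  # p ties break by position
  t4 <- rbind(ps("right", 2e6, 1e-9), ps("left", 1.9e6, 1e-9))
  expect_equal(define_loci(t4)$lead_snp, "left")
})
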