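test_that("size factors follow the median-of-ratios hand computation", {
  # identical samples -> unit factors
  m <- matrix(c(5L, 9L, 5L, 9L), ncol = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(compute_size_factors(m)), c(1, 1))

  # hand-computed: geometric means (2.828, 11.314); ratio medians 1/sqrt(2)
  # and sqrt(2)
  m2 <- matrix(c(2L, 8L, 4L, 16L), ncol = 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(compute_size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # equivariance: scaling one sample's counts by c scales its factor by c
  # relative to the others (factors are defined up to a common rescaling;
  # the absolute factor moves by c^((m-1)/m) because the geometric-mean
  # reference absorbs c^(1/m))
  m3 <- m2
  m3[, 2] <- m3[, 2] * 5L
  s0 <- compute_size_factors(m2)
  s1 <- compute_size_factors(m3)
  expect_equal(s1[["s2"]] / s1[["s1"]], 5 * s0[["s2"]] / s0[["s1"]],
               tolerance = 1e-12)

  # no barcode nonzero everywhere -> informative error
  m4 <- matrix(c(1L, 0L, 0L, 1L), ncol = 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(compute_size_factors(m4), "pseudo-reference")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(41)
  m <- matrix(rnbinom(200 * 6, mu = 300, size = 10), nrow = 200,
              dimnames = list(sprintf("b%03d", 1:200), sprintf("s%d", 1:6)))
  ours <- compute_size_factors(m)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  # same up to the overall rescaling convention
  expect_equal(unname(ours / theirs), rep(ours[[1]] / theirs[[1]], 6),
               tolerance = 1e-8)
})

test_that("dispersion estimates behave like method-of-moments", {
  set.seed(51)
  cond <- rep(c("control", "treated"), each = 50)
  sf <- rep(1, 100)
  # Poisson counts: alpha near the floor
  mp <- matrix(rpois(60 * 100, lambda = 200), nrow = 60,
               dimnames = list(sprintf("b%02d", 1:60), sprintf("s%d", 1:100)))
  ap <- estimate_dispersions(mp, sf, cond)
  expect_true(all(ap <= 0.05))

  # NB with alpha = 0.5 at 20 + 20 replicates
  cond2 <- rep(c("control", "treated"), each = 20)
  mn <- matrix(rnbinom(50 * 40, mu = 1000, size = 2), nrow = 50,
               dimnames = list(sprintf("b%02d", 1:50), sprintf("s%d", 1:40)))
  an <- estimate_dispersions(mn, rep(1, 40), cond2)
  expect_true(all(an >= 0.25 & an <= 1.0))

  # all-zero barcode pinned at the floor and flagged
  mz <- rbind(mn[1:5, ], zero = 0L)
  az <- estimate_dispersions(mz, rep(1, 40), cond2, moderate = FALSE)
  expect_equal(unname(az[["zero"]]), 1e-8)
  expect_true(attr(az, "flagged")[["zero"]])

  # single replicate per condition is rejected
  expect_error(estimate_dispersions(mp[, 1:2], c(1, 1),
                                    c("control", "treated")),
               ">= 2 replicates")
})

test_that("the NB LRT is null on identical groups and antisymmetric", {
  m <- matrix(rep(c(10L, 40L, 7L), 4), nrow = 3,
              dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  cond <- factor(c("control", "treated", "control", "treated"),
                 levels = c("control", "treated"))
  sf <- rep(1, 4)
  al <- rep(0.01, 3)
  names(al) <- rownames(m)
  res <- lrt_test(m, sf, al, cond)
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))

  # label swap negates log2fc and leaves p unchanged
  set.seed(61)
  m2 <- matrix(rnbinom(30 * 8, mu = 500, size = 20), nrow = 30,
               dimnames = list(sprintf("b%02d", 1:30), sprintf("s%d", 1:8)))
  cond2 <- factor(rep(c("control", "treated"), each = 4),
                  levels = c("control", "treated"))
  sf2 <- compute_size_factors(m2)
  al2 <- estimate_dispersions(m2, sf2, cond2)
  r1 <- lrt_test(m2, sf2, al2, cond2)
  r2 <- lrt_test(m2, sf2, al2, factor(cond2, levels = c("treated", "control")))
  expect_equal(r2$log2fc, -r1$log2fc, tolerance = 1e-9)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-7)
})

test_that("a planted 4x barcode is recovered near log2fc = 2", {
  ref <- generate_reference(100, seed = 71)
  delta <- rep(0, 100)
  # effect sized so the barcode sits at exactly 4x the neutral normalized
  # mean after renormalization: 2^d / ((99 + 2^d)/100) = 4 -> 2^d = 4.125
  delta[7] <- log2(4.125)
  design <- sim_design(n_barcodes = 100, read_depth = 1e5, n_replicates = 4,
                       overdispersion = 0, seed = 72)
  sim <- simulate_screen_counts(ref, delta, design)
  expect_equal(sim$truth$expected_log2fc[7], 2, tolerance = 1e-12)
  tab <- diffabund(sim$matrix, "drugX")
  est <- tab$log2fc[tab$barcode_id == ref$records$strain_id[7]]
  expect_lt(abs(est - 2), 0.1)
  expect_identical(tab$call[tab$barcode_id == ref$records$strain_id[7]],
                   "enriched")
})

test_that("all-zero barcodes are degenerate, flagged fits", {
  m <- matrix(c(0L, 0L, 0L, 0L, 5L, 6L, 4L, 7L), nrow = 2, byrow = TRUE,
              dimnames = list(c("zero", "ok"), sprintf("s%d", 1:4)))
  cond <- factor(rep(c("control", "treated"), 2),
                 levels = c("control", "treated"))
  al <- c(zero = 1e-8, ok = 1e-2)
  res <- lrt_test(m, rep(1, 4), al, cond)
  expect_equal(res$p_value[1], 1)
  expect_equal(res$log2fc[1], 0)
  expect_true(res$flagged[1])
  expect_false(res$flagged[2])
})

test_that("BH adjustment matches the step-up oracle and is order-invariant", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(81)
  for (k in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
    o <- sample(length(p))
    expect_equal(adjust_bh(p[o]), adjust_bh(p)[o], tolerance = 1e-12)
  }
})

test_that("hit calls apply the joint log2FC / p / padj rule", {
  rows <- data.frame(barcode_id = c("a", "b", "c", "d"),
                     log2fc = c(0.6, 0.6, -2.0, 0.4),
                     p_value = c(1e-4, 0.002, 1e-6, 1e-9),
                     padj = c(0.05, 0.05, 0.01, 1e-8))
  called <- call_hits(rows)
  expect_identical(called$call, c("enriched", "ns", "depleted", "ns"))
  # b fails only the raw-p condition; d fails only the fold-change condition
})

test_that("shifted log transform has the stated fixed points and invariance", {
  m <- matrix(c(0L, 7L, 3L, 1L), ncol = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  tr <- shifted_log_transform(m, c(1, 1))
  expect_equal(tr["a", "s1"], 0)
  expect_equal(tr["b", "s1"], 3)  # log2(7 + 1)
  tr2 <- shifted_log_transform(m * 2L, c(2, 2))
  expect_equal(tr2, tr)
})

test_that("PCA centers features and matches an eigendecomposition oracle", {
  # identical samples: no variance, zero scores
  m <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  p <- run_pca(m)
  expect_equal(sum(p$var_explained), 0)
  expect_equal(unname(p$scores), matrix(0, 2, 2), tolerance = 1e-12)

  # two 2-feature points: PC1 along (1,1)/sqrt(2), all variance on PC1
  m2 <- matrix(c(0, 0, 2, 2), ncol = 2,
               dimnames = list(c("f1", "f2"), c("s1", "s2")))
  p2 <- run_pca(m2)
  expect_equal(p2$var_explained[1], 1)
  expect_equal(abs(p2$scores[, 1]), c(s1 = sqrt(2), s2 = sqrt(2)),
               tolerance = 1e-12)

  # oracle equivalence on random matrices
  set.seed(101)
  for (k in 1:5) {
    mm <- matrix(rnorm(60), nrow = 10)
    rownames(mm) <- sprintf("f%02d", 1:10)
    colnames(mm) <- sprintf("s%d", 1:6)
    p3 <- run_pca(mm)
    x <- scale(t(mm), center = TRUE, scale = FALSE)
    eig <- eigen(stats::cov(x), symmetric = TRUE)
    scores_oracle <- x %*% eig$vectors
    r <- 5L  # rank of a centered 6-sample cloud
    expect_equal(abs(unname(p3$scores[, 1:r])),
                 abs(unname(scores_oracle[, 1:r])), tolerance = 1e-8)
    expect_equal(p3$var_explained[1:r],
                 (eig$values / sum(eig$values))[1:r], tolerance = 1e-8)
  }
  expect_error(run_pca(m[, 1, drop = FALSE]), "two samples")
})

test_that("profile correlation has its fixed points and subset rule", {
  tab <- data.frame(barcode_id = sprintf("b%02d", 1:20),
                    log2fc = rnorm(20))
  self <- profile_correlation(tab, tab)
  expect_equal(self$r, 1)
  expect_equal(self$r_squared, 1)
  expect_equal(self$n_shared, 20L)
  neg <- tab
  neg$log2fc <- -neg$log2fc
  expect_equal(profile_correlation(tab, neg)$r, -1)
  sub <- profile_correlation(tab, tab, barcode_subset = sprintf("b%02d", 1:5))
  expect_equal(sub$n_shared, 5L)
  expect_error(profile_correlation(tab[1, ], tab[1, ]), "two shared")
})

test_that("a null screen stays calibrated at the raw-p threshold", {
  ref <- generate_reference(300, seed = 111)
  design <- sim_design(n_barcodes = 300, read_depth = 3e5, n_replicates = 4,
                       seed = 112)
  sim <- simulate_screen_counts(ref, 0, design)
  tab <- diffabund(sim$matrix, "drugX")
  expect_lte(mean(tab$p_value <= 0.001), 0.01)
  # BH at FDR 0.1 tolerates occasional null calls across repeated screens,
  # so no stronger assertion than calibration is made here
})
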