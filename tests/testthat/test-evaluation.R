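test_that("unbiased MMD reproduces hand and brute-force values", {
  # identical degenerate samples: every kernel value 1, so 1 + 1 - 2 = 0
  z <- matrix(c(0, 0), ncol = 1)
  expect_equal(mmd_unbiased(z, z, gamma = 5), 0)
  # x = y = {0, 1}, gamma = 1: within terms e^-1 each, cross (2 + 2 e^-1)/4
  x <- matrix(c(0, 1), ncol = 1)
  expect_equal(mmd_unbiased(x, x, gamma = 1), exp(-1) - 1, tolerance = 1e-12)
  expect_error(mmd_unbiased(matrix(0), x, gamma = 1), "at least two")

  # brute-force double-loop oracle on random samples
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:50, 1); m <- sample(2:50, 1); d <- sample(1:10, 1)
    X <- matrix(rnorm(n * d), n, d)
    Y <- matrix(rnorm(m * d) + 0.3, m, d)
    gamma <- 10^runif(1, -2, 1)
    expect_lt(abs(mmd_unbiased(X, Y, gamma) - mmd_bruteforce(X, Y, gamma)),
              1e-10)
  }
})

test_that("MMD is symmetric and centred at zero between identical laws", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  Y <- matrix(rnorm(45), 15, 3)
  expect_identical(mmd_unbiased(X, Y, 0.5), mmd_unbiased(Y, X, 0.5))
  # E[mmd] = 0 when both samples come from the same distribution
  vals <- replicate(100, {
    Z <- matrix(rnorm(40 * 2), 40, 2)
    idx <- sample.int(40, 20)
    mmd_unbiased(Z[idx, ], Z[-idx, ], gamma = 1)
  })
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("multiscale MMD matches single-scale calls and averages them", {
  set.seed(6)
  X <- matrix(rnorm(60), 20, 3)
  Y <- matrix(rnorm(60) + 1, 20, 3)
  res <- mmd_multiscale(X, Y)
  expect_length(res$per_bandwidth$gamma, 50)
  expect_equal(res$per_bandwidth$gamma, 10^seq(1, -3, length.out = 50))
  for (i in c(1, 17, 50))
    expect_equal(res$per_bandwidth$mmd[i],
                 mmd_unbiased(X, Y, res$per_bandwidth$gamma[i]),
                 tolerance = 1e-12)
  expect_equal(res$mean, mean(res$per_bandwidth$mmd))
  one <- mmd_multiscale(X, Y, gammas = 0.3)
  expect_equal(one$mean, mmd_unbiased(X, Y, 0.3))
  expect_error(mmd_multiscale(X, Y, gammas = numeric(0)), "non-empty")
  # degenerate identical samples: every kernel value is 1, zero at all scales
  res0 <- mmd_multiscale(x = matrix(c(0, 0), ncol = 1),
                         y = matrix(c(0, 0), ncol = 1))
  expect_true(all(abs(res0$per_bandwidth$mmd) < 1e-12))
  # identical non-degenerate samples are NOT zero under the U-statistic:
  # diagonals are excluded within samples but not across
  res1 <- mmd_multiscale(matrix(c(0, 1), ncol = 1),
                         matrix(c(0, 1), ncol = 1), gammas = 1)
  expect_equal(res1$mean, exp(-1) - 1, tolerance = 1e-12)
})

test_that("feature-mean metrics obey their closed forms", {
  A <- matrix(rnorm(40), 10, 4)
  expect_equal(l2_feature_means(A, A), 0)
  B <- sweep(A, 2, c(3, 4, 0, 0), "+")
  expect_equal(l2_feature_means(B, A), 5)           # 3-4-5 triangle
  expect_equal(l2_feature_means(matrix(c(1, 1), 1), matrix(c(2, 2), 1)),
               sqrt(2))
  # translation equivariance
  C <- sweep(A, 2, c(1, -2, 0.5, 0), "+")
  expect_equal(colMeans(C) - colMeans(A), c(1, -2, 0.5, 0),
               ignore_attr = TRUE)

  expect_equal(r2_feature_means(A, A), 1)
  expect_equal(r2_feature_means(2 * A + 1, A), 1)   # affine invariance
  const <- matrix(1, 10, 4)
  r2 <- r2_feature_means(A, const)
  expect_true(is.na(r2))
  expect_true(isTRUE(attr(r2, "undefined")))
  expect_error(l2_feature_means(A, matrix(0, 10, 3)), "same number")
})

test_that("marker ranking recovers shifted genes and matches Welch t", {
  set.seed(8)
  ctl <- matrix(rnorm(300), 100, 3,
                dimnames = list(NULL, c("g1", "g2", "g3")))
  trt <- ctl + 0.03 * matrix(rnorm(300), 100, 3)
  trt[, 2] <- trt[, 2] + 5                         # strong marker
  expect_identical(rank_marker_genes(ctl, trt, n = 1), "g2")

  # full ranking equals an explicit Welch-t computation
  welch <- vapply(1:3, function(j)
    unname(stats::t.test(trt[, j], ctl[, j])$statistic), 0)
  expect_identical(rank_marker_genes(ctl, trt, n = 3),
                   c("g1", "g2", "g3")[order(-abs(welch))])

  # a gene identical in both groups ranks last
  trt2 <- trt; trt2[, 3] <- ctl[, 3]
  trt2[, 1] <- trt2[, 1] + 1
  expect_identical(rank_marker_genes(ctl, trt2, n = 3)[3], "g3")

  # invariant to row permutations of either group
  expect_identical(rank_marker_genes(ctl[sample.int(100), ],
                                     trt[sample.int(100), ], n = 3),
                   rank_marker_genes(ctl, trt, n = 3))
  expect_error(rank_marker_genes(ctl, trt, n = 9), "3 features")
})

test_that("evaluation bundles metrics and orders baselines sensibly", {
  set.seed(10)
  d <- 5
  ctl <- matrix(rnorm(400 * d), 400, d)
  obs <- matrix(rnorm(400 * d), 400, d)
  obs[, 1] <- obs[, 1] + 4                         # strong shift
  obs2 <- matrix(rnorm(400 * d), 400, d)           # disjoint observed draw
  obs2[, 1] <- obs2[, 1] + 4

  same <- evaluate_prediction(obs2, obs)
  expect_s3_class(same, "eval_report")
  expect_lt(abs(same$mmd_mean), 0.01)              # same law, near zero
  expect_gt(same$r2_means, 0.9)
  expect_equal(same$mmd_mean, mean(same$mmd_per_bandwidth$mmd))

  ident <- evaluate_prediction(baseline_identity(ctl), obs,
                               baseline_tag = "identity")
  expect_gt(ident$mmd_mean, same$mmd_mean)         # identity clearly worse

  # marker restriction: uses top-k features ranked control vs obs
  rep_m <- evaluate_prediction(obs2, obs, control = ctl,
                               feature_mode = "top_k_markers", k = 2)
  expect_length(rep_m$feature_subset, 2)
  expect_true("feature_1" %in% rep_m$feature_subset ||
                1 %in% rep_m$feature_subset ||
                any(grepl("1$", rep_m$feature_subset)))
  expect_error(evaluate_prediction(obs2, obs, ctl, "top_k_markers", k = 50),
               "markers")

  td <- tidy(rep_m)
  expect_true(all(c("baseline", "metric", "value") %in% names(td)))
  gl <- glance(rep_m)
  expect_identical(nrow(gl), 1L)
})

test_that("baselines pass populations through with tags and guards", {
  pop <- cell_population(matrix(rnorm(20), 10, 2), condition = "control")
  ident <- baseline_identity(pop)
  expect_equal(pop_matrix(ident), pop_matrix(pop))
  expect_identical(attr(ident, "baseline_tag"), "identity")

  per <- cell_population(matrix(rnorm(20), 10, 2), condition = "perturbed",
                         cell_id = paste0("p", 1:10))
  eval_half <- per[1:5, ]
  test_half <- per[6:10, ]
  expect_identical(attr(baseline_observed(eval_half, test_half),
                        "baseline_tag"), "observed")
  expect_error(baseline_observed(per[1:6, ], test_half), "disjoint")
})
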