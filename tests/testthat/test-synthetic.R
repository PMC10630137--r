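test_that("Gaussian pair sampling is seeded, labelled, and SPD-guarded", {
  sp <- gaussian_spec(0, 1, 2, 1, n_source = 10000, n_target = 100, seed = 3)
  pair <- sample_gaussian_pair(sp)
  expect_identical(unique(pair$source$condition), "control")
  expect_identical(unique(pair$target$condition), "perturbed")
  # CLT bound on the sample mean
  expect_lt(abs(mean(pop_matrix(pair$source))), 3 / sqrt(10000))
  # determinism
  pair2 <- sample_gaussian_pair(sp)
  expect_identical(pop_matrix(pair$source), pop_matrix(pair2$source))
  # non-SPD covariance rejected
  expect_error(gaussian_spec(c(0, 0), matrix(c(1, 2, 2, 1), 2),
                             c(0, 0), diag(2)), "positive definite")
  expect_error(gaussian_spec(c(0, 0), matrix(c(1, 0.5, 0.2, 1), 2),
                             c(0, 0), diag(2)), "symmetric")
})

test_that("closed-form Gaussian maps satisfy their defining identities", {
  # pure translation
  m <- closed_form_gaussian_map(0, 1, 2, 1)
  expect_equal(as.numeric(m$A), 1)
  expect_equal(m$offset, 2)
  expect_equal(as.numeric(m$map(matrix(c(-1, 0, 3)))), c(1, 2, 5))
  # pure scaling N(0,1) -> N(0,4): T(x) = 2x
  m2 <- closed_form_gaussian_map(0, 1, 0, 4)
  expect_equal(as.numeric(m2$A), 2)
  expect_equal(m2$offset, 0)
  # diagonal case
  m3 <- closed_form_gaussian_map(c(0, 0), diag(2), c(0, 0), diag(c(4, 9)))
  expect_equal(m3$A, diag(c(2, 3)))
  # pushforward identity A Sigma_s A' = Sigma_t on random SPD pairs
  set.seed(12)
  for (i in 1:100) {
    d <- sample(1:4, 1)
    R1 <- matrix(rnorm(d * d), d); R2 <- matrix(rnorm(d * d), d)
    Ss <- crossprod(R1) + diag(d) * 0.1
    St <- crossprod(R2) + diag(d) * 0.1
    mm <- closed_form_gaussian_map(rep(0, d), Ss, rep(0, d), St)
    expect_lt(max(abs(mm$A %*% Ss %*% t(mm$A) - St)), 1e-8)
  }
})

test_that("Gaussian squared Wasserstein-2 has its closed-form values", {
  expect_equal(gaussian_w2(0, 1, 2, 1), 4)
  expect_equal(gaussian_w2(c(1, -1), diag(2), c(1, -1), diag(2)), 0)
  expect_equal(gaussian_w2(0, 1, 0, 4), 1)    # 1 + 4 - 2*2
  set.seed(2)
  R <- matrix(rnorm(9), 3); S <- crossprod(R) + diag(3) * 0.2
  expect_gte(gaussian_w2(rep(0, 3), S, rep(0.5, 3), diag(3)), 0)
})

test_that("discrete OT solves small cases exactly", {
  # single pair
  res <- discrete_ot_barycentric(matrix(0), matrix(5))
  expect_equal(res$coupling, matrix(1))
  expect_equal(as.numeric(res$projected), 5)
  expect_equal(res$cost, 25)
  # two points, monotone matching wins over the crossing one
  res2 <- discrete_ot_barycentric(matrix(c(0, 10)), matrix(c(1, 11)))
  expect_equal(as.numeric(res2$projected), c(1, 11))
  expect_equal(res2$cost, 1)  # 2 * (1^2) * (1/2)
  # brute-force check over both permutations
  costs <- c((0 - 1)^2 + (10 - 11)^2, (0 - 11)^2 + (10 - 1)^2) / 2
  expect_equal(res2$cost, min(costs))
})

test_that("1-D couplings are the sorting permutation; marginals are uniform", {
  set.seed(14)
  x <- matrix(rnorm(40), 40, 1)
  y <- matrix(rnorm(40, 2), 40, 1)
  res <- discrete_ot_barycentric(x, y)
  # sorted-order oracle
  expected <- matrix(0, 40, 40)
  expected[cbind(order(x), order(y))] <- 1 / 40
  expect_equal(res$coupling, expected)
  expect_equal(rowSums(res$coupling), rep(1 / 40, 40))
  expect_equal(colSums(res$coupling), rep(1 / 40, 40))
  # unequal sizes in 1-D: still exact, marginals uniform
  res2 <- discrete_ot_barycentric(matrix(rnorm(6)), matrix(rnorm(9)))
  expect_equal(rowSums(res2$coupling), rep(1 / 6, 6))
  expect_equal(colSums(res2$coupling), rep(1 / 9, 9))
  # unequal sizes in 2-D via the lcm lift
  res3 <- discrete_ot_barycentric(matrix(rnorm(8), 4, 2),
                                  matrix(rnorm(12), 6, 2))
  expect_equal(rowSums(res3$coupling), rep(1 / 4, 4))
  expect_equal(colSums(res3$coupling), rep(1 / 6, 6))
})

test_that("empirical discrete OT cost approaches the Gaussian W2", {
  sp <- gaussian_spec(c(0, 0), diag(2), c(2, 0), diag(2) * 1.5,
                      n_source = 500, n_target = 500, seed = 21)
  pair <- sample_gaussian_pair(sp)
  res <- discrete_ot_barycentric(pop_matrix(pair$source),
                                 pop_matrix(pair$target))
  w2 <- gaussian_w2(c(0, 0), diag(2), c(2, 0), diag(2) * 1.5)
  expect_lt(abs(res$cost - w2) / w2, 0.15)
})

test_that("mixture pairs carry opposite component shifts and stay seeded", {
  sp <- mixture_spec(c(0.5, 0.5), list(-3, 3), list(0.25, 0.25),
                     shifts = list(3, -3), n_source = 4000, n_target = 4000,
                     seed = 5)
  pair <- sample_mixture_pair(sp)
  tgt <- pop_matrix(pair$target)[, 1]
  comp <- pair$target$cell_type
  # each target component sits near its shifted mean: -3 + 3 = 0 and 3 - 3 = 0
  expect_lt(abs(mean(tgt[comp == "component_1"]) - 0), 0.1)
  expect_lt(abs(mean(tgt[comp == "component_2"]) - 0), 0.1)
  # bimodality of a two-sided construction
  sp2 <- mixture_spec(c(0.5, 0.5), list(0, 0), list(0.25, 0.25),
                      shifts = list(3, -3), n_source = 4000, n_target = 4000,
                      seed = 6)
  p2 <- sample_mixture_pair(sp2)
  t2 <- pop_matrix(p2$target)[, 1]
  dens <- stats::density(t2)
  modes <- dens$x[which(diff(sign(diff(dens$y))) == -2) + 1]
  expect_true(any(abs(modes - 3) < 0.5) && any(abs(modes + 3) < 0.5))
  # one component reduces to a plain Gaussian pair
  sp1 <- mixture_spec(1, list(1), list(1), shifts = list(2),
                      n_source = 50, n_target = 50, seed = 7)
  p1 <- sample_mixture_pair(sp1)
  expect_identical(unique(p1$source$cell_type), "component_1")
  expect_error(mixture_spec(c(0.7, 0.4), list(0, 0), list(1, 1),
                            shifts = list(1, 1)), "sum to 1")
})
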