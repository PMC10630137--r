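test_that("4i normalization divides by control quartiles then log1p", {
  # feature f1: control 75th percentile = 2 (values 0,1,2,2)
  X <- matrix(c(0, 1, 2, 2, 3,
                0, 0, 0, 0, 1), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  pop <- cell_population(X, condition = c(rep("control", 4), "drug"))
  expect_warning(norm <- normalize_4i(pop), "f2")   # all-zero control feature
  expect_false("f2" %in% pop_feature_names(norm))
  # treated value 3 -> log(1 + 3/2)
  expect_equal(norm$f1[5], log1p(1.5))
  # zero maps to zero
  expect_equal(norm$f1[1], 0)
  # percentiles computed on control cells only and reusable downstream
  q <- attr(norm, "percentiles")
  expect_equal(unname(q["f1"]), 2)
  held <- cell_population(matrix(c(5, 1), 1, 2,
                                 dimnames = list(NULL, c("f1", "f2"))),
                          condition = "drug")
  norm_held <- suppressWarnings(normalize_4i(held, percentiles = q))
  expect_equal(norm_held$f1[1], log1p(5 / 2))
  expect_error(normalize_4i(pop, control_label = "missing"), "missing")
})

test_that("scRNA normalization filters, rescales, and logs counts", {
  X <- rbind(c(2, 2, 0), c(0, 0, 0), c(4, 0, 0))
  colnames(X) <- c("g1", "g2", "g3")
  pop <- cell_population(X, condition = "control")
  out <- normalize_scrna(pop, target_sum = 4, min_genes = 1, min_cells = 1)
  # cell 2 (no genes) removed; gene g3 (no cells) removed
  expect_equal(nrow(out), 2)
  expect_identical(pop_feature_names(out), c("g1", "g2"))
  # cell (2,2) scaled to total 4 then log1p
  expect_equal(unlist(out[1, c("g1", "g2")], use.names = FALSE),
               c(log1p(2), log1p(2)))
  expect_error(normalize_scrna(cell_population(-X)), "non-negative")
  expect_error(normalize_scrna(pop, min_genes = 10), "no cells")
})

test_that("highly variable genes are ranked by binned normalized dispersion", {
  set.seed(19)
  n <- 200
  X <- cbind(matrix(rnorm(n * 4, 5, 0.3), n, 4),
             rnorm(n, 5, 3))                      # gene 5: far higher variance
  colnames(X) <- paste0("g", 1:5)
  pop <- cell_population(abs(X), condition = "control")
  top1 <- select_hvg(pop, n_genes = 1)
  expect_identical(names(top1), "g5")
  # n_genes = feature count returns all features
  all5 <- select_hvg(pop, n_genes = 5)
  expect_setequal(names(all5), paste0("g", 1:5))
  # a constant gene ranks last
  X2 <- cbind(X[, 1:4], g_const = 3)
  pop2 <- cell_population(abs(X2), condition = "control")
  expect_identical(names(select_hvg(pop2, 5))[5], "g_const")
  expect_error(select_hvg(pop, 6), "5 features")
})

test_that("hvg selection ignores held-out cells entirely", {
  set.seed(23)
  X <- matrix(abs(rnorm(100 * 6)), 100, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  pop <- cell_population(X, condition = "control")
  train <- pop[1:60, ]
  idx1 <- select_hvg(train, 3)
  # perturbing held-out rows must not change the training-only selection
  pop2 <- pop
  pop2[61:100, pop_feature_names(pop2)] <- pop2[61:100, pop_feature_names(pop2)] * 100
  expect_identical(select_hvg(pop2[1:60, ], 3), idx1)
})

test_that("iid splits partition every condition with the requested sizes", {
  pop <- cell_population(matrix(rnorm(2 * 5000 * 2), ncol = 2),
                         condition = rep(c("control", "drug"), each = 5000))
  sp <- split_spec("iid", test_size = 500, eval_size = 500, seed = 4)
  s <- make_splits(pop, sp)
  for (cc in c("control", "drug")) {
    sub <- s[s$condition == cc, ]
    expect_equal(sum(sub$split == "test"), 500)
    expect_equal(sum(sub$split == "eval"), 500)
    expect_equal(sum(sub$split == "train"), 4000)
    expect_false(any(duplicated(sub$cell_id)))
  }
  # deterministic under the seed
  expect_identical(make_splits(pop, sp), s)
  # small conditions shrink with a warning
  small <- cell_population(matrix(rnorm(120), 60, 2), condition = "control")
  expect_warning(s2 <- make_splits(small, sp), "shrinking")
  expect_gt(sum(s2$split == "train"), 0)
})

test_that("ood splits exclude the holdout sample from training", {
  set.seed(6)
  pop <- cell_population(matrix(rnorm(1200 * 2), ncol = 2),
                         condition = rep(rep(c("control", "drug"), each = 300), 2),
                         sample_id = rep(c("mouse", "rat"), each = 600))
  sp <- split_spec("ood", holdout = "rat", test_size = 50, eval_size = 50,
                   seed = 8)
  s <- make_splits(pop, sp)
  # no rat cell in the o.o.d. training set
  rat_rows <- which(pop$sample_id == "rat")
  expect_false(any(s$split[rat_rows] == "train"))
  # test/eval drawn from rat only
  expect_true(all(s$row[s$split %in% c("test", "eval")] %in% rat_rows))
  # the iid counterpart sees extra holdout cells that are not test/eval
  heldback <- s$row[s$split == "heldback"]
  expect_true(length(heldback) > 0 && all(heldback %in% rat_rows))
  expect_error(make_splits(pop, split_spec("ood", holdout = "gerbil")),
               "gerbil")
})

test_that("the split size rule tracks condition size within [500, 1000]", {
  expect_identical(split_size_rule(2000), 500L)
  expect_identical(split_size_rule(7000), 700L)
  expect_identical(split_size_rule(50000), 1000L)
})
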