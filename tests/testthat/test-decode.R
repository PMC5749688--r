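test_that("make_folds partitions participants into near-equal seeded folds", {
  p24 <- make_folds(1:24, k = 3, seed = 5)
  expect_equal(as.vector(table(p24$assignment)), c(8, 8, 8))
  expect_setequal(names(p24$assignment), as.character(1:24))

  p25 <- make_folds(1:25, k = 3, seed = 5)
  expect_equal(sort(as.vector(table(p25$assignment))), c(8, 8, 9))

  expect_identical(make_folds(1:24, seed = 9), make_folds(1:24, seed = 9))
  expect_false(identical(make_folds(1:24, seed = 9)$assignment,
                         make_folds(1:24, seed = 10)$assignment))
  expect_error(make_folds(1:2, k = 3), "exceeds")
})

test_that("standardize uses training statistics only", {
  tr <- cbind(rnorm(50, 10, 2), rnorm(50, -3, 5), rep(7, 50))
  te <- tr[1:20, ] + 100  # grossly shifted test set
  s <- standardize(tr, list(test = te))
  expect_equal(unname(colMeans(s$train)), c(0, 0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(s$train[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-8)
  # constant column: centered, divisor 1
  expect_equal(unname(s$train[, 3]), rep(0, 50))
  expect_equal(unname(s$scale[3]), 1)
  # test transformed with train stats, not its own
  expect_equal(s$test, sweep(sweep(te, 2, s$center), 2, s$scale, "/"))
  expect_gt(mean(s$test[, 1]), 10)
})

test_that("upsample_minority replicates whole sets toward parity", {
  X <- matrix(seq_len(250), ncol = 2)
  y <- rep(c("a", "b"), c(100, 25))
  up <- upsample_minority(X, y)
  expect_equal(as.vector(table(up$y)), c(100, 100))  # 4 whole copies of b
  expect_equal(up$copies[["b"]], 4L)
  # copies are whole-set replications
  b_rows <- up$X[up$y == "b", 1]
  expect_equal(b_rows, rep(X[y == "b", 1], 4))

  y3 <- rep(c("a", "b", "c"), c(90, 60, 30))
  up3 <- upsample_minority(matrix(seq_len(180)), y3)
  expect_equal(as.vector(table(up3$y)[c("a", "b", "c")]), c(90, 60, 90))
  expect_equal(unname(up3$copies[c("a", "b", "c")]), c(1L, 1L, 3L))

  bal <- upsample_minority(X[1:50, ], rep(c("a", "b"), 25))
  expect_equal(length(bal$y), 50)  # balanced input unchanged
})

test_that("train_linear fits a deterministic maximum-margin classifier", {
  # linearly separable toy set: zero training errors at C = 0.1
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 2), ncol = 2), matrix(rnorm(40, -2), ncol = 2))
  y <- rep(c("p", "q"), each = 20)
  m <- train_linear(X, y, C = 0.1)
  expect_equal(predict_linear(m, X), y)

  # two symmetric points: the boundary passes through the origin
  m2 <- train_linear(rbind(c(1, 0), c(-1, 0)), c("p", "q"), C = 0.1)
  expect_lt(abs(decision_values(m2, matrix(0, 1, 2))), 1e-6)

  # retraining on identical input gives identical predictions
  m3 <- train_linear(X, y, C = 0.1)
  expect_identical(predict_linear(m3, X), predict_linear(m, X))

  expect_error(train_linear(X, rep("p", 40), C = 0.1), "2 classes")
})

test_that("one-vs-one voting handles ternary problems with ordered tie-break", {
  set.seed(4)
  cent <- rbind(c(4, 0), c(-2, 4), c(-2, -4))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(60, 0, 0.5), ncol = 2), 2, cent[k, ], "+")))
  y <- rep(c("u", "n", "p"), each = 30)
  m <- train_linear(X, y, C = 0.1, class_order = c("u", "n", "p"))
  expect_gt(mean(predict_linear(m, X) == y), 0.95)
  expect_equal(m$classes, c("u", "n", "p"))
})

test_that("tune_C maximizes validation UAR with smallest-C tie-break", {
  # construct a problem where heavy regularization fails: two informative
  # dimensions among many noisy ones, small sample
  set.seed(11)
  n <- 60
  Xtr <- cbind(matrix(rnorm(n * 2, rep(c(1.2, -1.2), each = n / 2)), n, 2),
               matrix(rnorm(n * 30), n, 30))
  ytr <- rep(c("a", "b"), each = n / 2)
  Xva <- cbind(matrix(rnorm(n * 2, rep(c(1.2, -1.2), each = n / 2)), n, 2),
               matrix(rnorm(n * 30), n, 30))
  res <- tune_C(Xtr, ytr, Xva, ytr)
  # oracle: exhaustive evaluation over the grid
  oracle <- vapply(c_grid(), function(C)
    uar(ytr, predict_linear(train_linear(Xtr, ytr, C), Xva)), numeric(1))
  expect_equal(res$C, c_grid()[which.max(oracle)])
  expect_equal(unname(res$uar_by_C), oracle)

  # all-identical UARs resolve to the smallest C
  Xconst <- matrix(rnorm(40), 20, 2)
  yconst <- rep(c("a", "b"), 10)
  Xva0 <- matrix(100, 4, 2)  # every model predicts one side
  res0 <- tune_C(Xconst, yconst, Xva0, rep(c("a", "b"), 2))
  if (length(unique(res0$uar_by_C)) == 1L) expect_equal(res0$C, 1e-5)
})

test_that("run_sicv emits 30 participant-disjoint, reproducible evaluations", {
  ep <- tiny_epochs(seed = 6, scale = 12, participants = 6,
                    trials_per_cell = 6)
  ft <- extract_feature_table(relabel(ep, "novelty"))
  res <- run_sicv(ft, seed = 21)
  expect_length(res$evals, 30)
  expect_equal(sum(!vapply(res$evals, `[[`, logical(1), "bootstrap")), 3)
  expect_true(all(res$C_by_fold %in% c_grid()))

  # participant disjointness: test participants of each rotation never in train
  fold_of <- res$plan$assignment
  for (i in 1:3) {
    te_pp <- names(fold_of)[fold_of == i]
    tr_pp <- names(fold_of)[fold_of != i]
    expect_length(intersect(te_pp, tr_pp), 0)
  }

  # full reproducibility given (data, config, seed)
  res2 <- run_sicv(ft, seed = 21)
  expect_identical(lapply(res$evals, `[[`, "pred"),
                   lapply(res2$evals, `[[`, "pred"))

  # bootstrap sets resample the fold's original test set
  orig <- res$evals[[1]]
  boot <- res$evals[[2]]
  expect_equal(length(boot$truth), length(orig$truth))
  expect_true(all(boot$truth %in% orig$truth))
})
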