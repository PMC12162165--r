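test_that("softmax gradients and Hessians match the analytic forms", {
  gh <- softmax_grad_hess(1, matrix(0, 1, 5))
  expect_equal(gh$g[1, ], c(-0.8, 0.2, 0.2, 0.2, 0.2))
  expect_equal(gh$h[1, ], rep(0.16, 5))

  sat <- softmax_grad_hess(1, matrix(c(100, 0, 0), 1, 3))
  expect_equal(sat$g[1, ], rep(0, 3), tolerance = 1e-12)

  expect_error(softmax_grad_hess(1, matrix(c(Inf, 0), 1, 2)), "finite")
})

test_that("gradients and Hessians agree with finite differences", {
  set.seed(8)
  raw <- matrix(rnorm(12), 3, 4)
  y <- c(2, 4, 1)
  gh <- softmax_grad_hess(y, raw)
  loss <- function(r, i) {
    p <- exp(r - max(r)); p <- p / sum(p)
    -log(p[y[i]])
  }
  eps <- 1e-5
  eps_h <- 1e-4  # wider step: second differences amplify rounding noise
  for (i in 1:3) for (c in 1:4) {
    rp <- raw[i, ]; rm <- raw[i, ]
    rp[c] <- rp[c] + eps; rm[c] <- rm[c] - eps
    g_num <- (loss(rp, i) - loss(rm, i)) / (2 * eps)
    expect_lt(abs(gh$g[i, c] - g_num), 1e-5)
    rp2 <- raw[i, ]; rm2 <- raw[i, ]
    rp2[c] <- rp2[c] + eps_h; rm2[c] <- rm2[c] - eps_h
    h_num <- (loss(rp2, i) - 2 * loss(raw[i, ], i) + loss(rm2, i)) / eps_h^2
    expect_lt(abs(gh$h[i, c] - h_num), 1e-5)
  }
})

test_that("leaf weights minimize the second-order objective", {
  expect_equal(leaf_weight(0, 5, 1), 0)
  expect_equal(leaf_weight(2, 3, 1), -0.5)
  expect_error(leaf_weight(1, 0, 0), "degenerate")

  # squared-error toy: targets {1,2,3} in one leaf, lambda 0 ->
  # g_i = -y_i, h_i = 1; the optimum must be the mean, and must agree
  # with brute-force minimization of sum(g w + h w^2 / 2)
  g <- -c(1, 2, 3); h <- rep(1, 3)
  w_star <- leaf_weight(sum(g), sum(h), 0)
  expect_equal(w_star, 2)
  grid <- seq(-5, 5, by = 1e-4)
  obj <- vapply(grid, function(w) sum(g * w + 0.5 * h * w^2), 0)
  expect_equal(grid[which.min(obj)], w_star, tolerance = 1e-3)
})

test_that("structure scores reproduce direct arithmetic and split gains", {
  expect_equal(structure_score(rep(1, 3), rep(-2, 3), rep(1, 3), 0, 0), -6)
  expect_equal(structure_score(rep(1, 3), rep(-2, 3), rep(1, 3), 0, 1), -5)
  expect_error(structure_score(c(1, 3), c(1, 1), c(1, 1)), "empty leaf")

  # any binary split: parent score minus children's equals the oracle gain
  set.seed(10)
  X <- matrix(runif(16), 8, 2)
  g <- rnorm(8); h <- runif(8, 0.5, 2)
  lam <- 0.7; gam <- 0.05
  parent <- structure_score(rep(1, 8), g, h, lam, gam)
  for (f in 1:2) {
    thr <- median(X[, f])
    assign_lr <- ifelse(X[, f] < thr, 1, 2)
    children <- structure_score(assign_lr, g, h, lam, gam)
    gain <- parent - children
    left <- X[, f] < thr
    direct <- 0.5 * (sum(g[left])^2 / (sum(h[left]) + lam) +
                     sum(g[!left])^2 / (sum(h[!left]) + lam) -
                     sum(g)^2 / (sum(h) + lam)) - gam
    expect_equal(gain, direct, tolerance = 1e-12)
  }
})

test_that("tree growth matches the exhaustive split oracle on small toys", {
  # 1-D perfectly split targets
  x <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9), ncol = 1)
  g <- c(1, 1, 1, 1, -1, -1, -1, -1); h <- rep(1, 8)
  tr <- grow_tree(x, g, h, gbt_params(max_depth = 1, lambda_reg = 0))
  expect_false(tr[[1]]$is_leaf)
  expect_gt(tr[[1]]$threshold, 0.4)
  expect_lte(tr[[1]]$threshold, 0.6)

  # huge gamma forbids any split
  tr1 <- grow_tree(x, g, h, gbt_params(max_depth = 3, gamma = 100))
  expect_length(tr1, 1)
  expect_true(tr1[[1]]$is_leaf)

  # constant features give a single leaf
  trc <- grow_tree(matrix(1, 6, 2), rnorm(6), rep(1, 6), gbt_params())
  expect_length(trc, 1)

  # random toys n <= 16, d <= 3, depth <= 2: every chosen split equals the
  # exhaustive-oracle argmax, recursively
  set.seed(11)
  check_node <- function(tree, node_id, X, g, h, idx, lam, gam, depth) {
    nd <- tree[[node_id]]
    or <- oracle_best_split(X[idx, , drop = FALSE], g[idx], h[idx],
                            lambda = lam, gamma = gam,
                            min_child_hessian = 1e-3)
    if (nd$is_leaf) {
      if (depth < 2) expect_lte(or$gain, 1e-12)
      return(invisible())
    }
    expect_equal(nd$feature, or$feature)
    expect_equal(nd$threshold, or$threshold, tolerance = 1e-12)
    left <- idx[X[idx, nd$feature] < nd$threshold]
    right <- idx[X[idx, nd$feature] >= nd$threshold]
    check_node(tree, nd$left, X, g, h, left, lam, gam, depth + 1)
    check_node(tree, nd$right, X, g, h, right, lam, gam, depth + 1)
  }
  for (i in 1:25) {
    n <- sample(4:16, 1); d <- sample(1:3, 1)
    X <- matrix(rnorm(n * d), n, d)
    g <- rnorm(n); h <- runif(n, 0.3, 1.5)
    lam <- runif(1, 0, 2); gam <- runif(1, 0, 0.3)
    tr <- grow_tree(X, g, h, gbt_params(max_depth = 2, lambda_reg = lam,
                                        gamma = gam))
    check_node(tr, 1, X, g, h, seq_len(n), lam, gam, 0)
  }
})

test_that("the gain oracle note: oracle gain for grown splits is positive", {
  # cross-check that .best_split's gain definition matches the oracle's
  set.seed(12)
  X <- matrix(rnorm(20), 10, 2)
  g <- rnorm(10); h <- rep(1, 10)
  tr <- grow_tree(X, g, h, gbt_params(max_depth = 1, lambda_reg = 1))
  if (!tr[[1]]$is_leaf) {
    or <- oracle_best_split(X, g, h, lambda = 1, min_child_hessian = 1e-3)
    expect_gt(or$gain, 0)
  }
})

test_that("boosting drives a separable toy to perfect training accuracy
           with a non-increasing regularized objective", {
  set.seed(13)
  d <- data.frame(x1 = c(rnorm(10, -2), rnorm(10, 2)),
                  x2 = rnorm(20),
                  y = rep(c("a", "b"), each = 10))
  m <- gbt(y ~ ., d, n_rounds = 10, max_depth = 2)
  expect_equal(mean(predict(m, d) == d$y), 1.0)
  expect_true(all(diff(m$eval_log$objective) <= 1e-9))

  # multi-class fixture
  set.seed(14)
  X <- matrix(rnorm(60 * 4), 60, 4); colnames(X) <- paste0("f", 1:4)
  y <- factor(apply(X[, 1:3], 1, which.max))
  m2 <- gbt_fit(X, y, gbt_params(eta = 0.3, max_depth = 3, n_rounds = 20))
  expect_true(all(diff(m2$eval_log$objective) <= 1e-9))

  expect_error(gbt_fit(X, rep("a", 60), gbt_params()), "2 classes")
})

test_that("stored leaf weights reproduce -G/(H+lambda) exactly", {
  set.seed(15)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- factor(rep(c("a", "b"), 20))
  lam <- 1.3
  m <- gbt_fit(X, y, gbt_params(lambda_reg = lam, n_rounds = 5,
                                max_depth = 3))
  for (rt in m$trees) for (tr in rt) for (nd in tr) {
    if (nd$is_leaf) {
      expect_identical(nd$weight, leaf_weight(nd$G, nd$H, lam))
    }
  }
})

test_that("predictions are proper probabilities; empty ensembles are
           uniform; row order does not matter", {
  set.seed(16)
  X <- matrix(rnorm(50 * 3), 50, 3); colnames(X) <- paste0("f", 1:3)
  y <- factor(sample(c("a", "b", "c"), 50, replace = TRUE))
  m <- gbt_fit(X, y, gbt_params(n_rounds = 5, max_depth = 2))
  p <- predict(m, X, type = "prob")
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))

  m0 <- m
  m0$trees <- list()
  p0 <- predict(m0, X, type = "prob")
  expect_true(all(abs(p0 - 1 / 3) < 1e-15))

  perm <- sample(50)
  m_perm <- gbt_fit(X[perm, ], y[perm],
                    gbt_params(n_rounds = 5, max_depth = 2))
  expect_equal(predict(m_perm, X, type = "prob"),
               predict(m, X, type = "prob"), tolerance = 1e-12)

  expect_error(predict(m, X[, 1:2]), "columns")
  expect_error(predict(m, data.frame(f1 = 1, f2 = 2)), "lacks")
})

test_that("regularization acts monotonically", {
  set.seed(17)
  X <- matrix(rnorm(30 * 2), 30, 2)
  g <- rnorm(30); h <- runif(30, 0.5, 1.5)
  max_abs_w <- vapply(c(0, 0.5, 2, 8), function(lam) {
    tr <- grow_tree(X, g, h, gbt_params(max_depth = 1, lambda_reg = lam))
    max(abs(vapply(Filter(function(nd) nd$is_leaf, tr), `[[`, 0,
                   "weight")))
  }, 0)
  expect_true(all(diff(max_abs_w) <= 1e-12))

  leaves <- vapply(c(0, 0.05, 0.2, 1), function(gam) {
    tr <- grow_tree(X, g, h, gbt_params(max_depth = 3, gamma = gam))
    attr(tr, "n_leaves")
  }, 0L)
  expect_true(all(diff(leaves) <= 0))
})

test_that("models serialize to JSON and reload bit-stably", {
  set.seed(18)
  X <- matrix(rnorm(40 * 3), 40, 3); colnames(X) <- paste0("f", 1:3)
  y <- factor(rep(c("a", "b"), 20))
  m <- gbt_fit(X, y, gbt_params(n_rounds = 4, max_depth = 3))
  path <- file.path(tempdir(), "model.json")
  gbt_save(m, path)
  m2 <- gbt_load(path)
  expect_identical(predict(m, X, type = "prob"),
                   predict(m2, X, type = "prob"))
  expect_identical(m2$classes, m$classes)
  expect_error(gbt_load(tempfile()), "")
  unlink(path)

  expect_output(print(m), "gradient-boosted")
  expect_output(print(summary(m)), "total leaves")
})
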