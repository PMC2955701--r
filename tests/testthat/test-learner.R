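test_that("f_beta closed forms and properties", {
  expect_equal(f_beta(0.7, 0.7, 1), 0.7)
  expect_equal(f_beta(1, 0, 1), 0)
  expect_equal(f_beta(0, 0, 1), 0)                 # 0/0 convention
  expect_equal(f_beta(0.5, 0.25, 1), 1 / 3)        # 2pr/(p+r)
  expect_equal(f_beta(0.5, 0.25, 1), f_beta(0.25, 0.5, 1))  # symmetry
  # harmonic mean at beta = 1; monotone in p and r
  set.seed(70)
  for (i in 1:50) {
    p <- runif(1); r <- runif(1)
    expect_equal(f_beta(p, r, 1), 2 * p * r / (p + r))
    eps <- runif(1, 0, 1 - p)
    expect_gte(f_beta(p + eps, r, 2), f_beta(p, r, 2))
    expect_gte(f_beta(p, min(1, r + eps), 0.5), f_beta(p, r, 0.5))
  }
})

test_that("mutual information: independence, identity, hand-computed table", {
  set.seed(71)
  n <- 20000
  x <- sample(0:1, n, TRUE); y <- sample(0:1, n, TRUE)
  expect_lt(mutual_information(x, y), 0.01)        # independent
  expect_equal(mutual_information(x, x), 1, tolerance = 0.01)  # 1 bit
  expect_equal(mutual_information(rep(1, 100), sample(0:1, 100, TRUE)), 0)
  # small printed joint table: p(0,0)=.4 p(0,1)=.1 p(1,0)=.1 p(1,1)=.4
  x2 <- c(rep(0, 40), rep(0, 10), rep(1, 10), rep(1, 40))
  y2 <- c(rep(0, 40), rep(1, 10), rep(0, 10), rep(1, 40))
  direct <- sum(c(.4, .1, .1, .4) * log2(c(.4, .1, .1, .4) / .25))
  expect_equal(mutual_information(x2, y2), direct, tolerance = 1e-12)
})

test_that("mRMR ranks informative first and penalizes duplicates", {
  set.seed(72)
  n <- 400
  y <- rep(0:1, each = n / 2)
  informative <- y + rnorm(n, sd = 0.3)
  X <- cbind(informative, matrix(rnorm(n * 4), n, 4))
  expect_equal(mrmr_rank(X, y)[1], 1L)
  # a duplicated feature ranks strictly after its twin
  X2 <- cbind(informative, informative, matrix(rnorm(n * 3), n, 3))
  r2 <- mrmr_rank(X2, y)
  expect_equal(r2[1], 1L)                # tie broken to lower index
  expect_gt(which(r2 == 2L), 2)          # twin pushed down by redundancy
})

test_that("mRMR greedy equals the brute-force greedy on small instances", {
  set.seed(73)
  for (rep in 1:10) {
    n <- 150
    d <- sample(4:10, 1)
    y <- rep(0:1, length.out = n)
    X <- matrix(rnorm(n * d), n, d)
    X[, 1] <- X[, 1] + y
    if (d >= 5) X[, 5] <- X[, 1] + rnorm(n, sd = 0.1)
    expect_identical(mrmr_rank(X, y), oracle_mrmr(X, y))
  }
})

test_that("forward search keeps the informative feature and shuns noise", {
  set.seed(74)
  n <- 200
  y <- rep(0:1, each = n / 2)
  X <- cbind(y + rnorm(n, sd = 0.2), matrix(rnorm(n * 6), n, 6))
  colnames(X) <- paste0("f", 1:7)
  cfg <- train_config(folds = 5, seed = 74, sfs_max = 7, sfs_C = 1)
  ranked <- mrmr_rank(X, y)
  sel <- sequential_forward_search(ranked, X, y, cfg)
  expect_equal(sel$features[1], 1L)
  expect_gt(sel$cv_f, 0.9)
  # adding pure noise prefixes never improves materially on feature 1 alone
  f1_only <- sequential_forward_search(1L, X, y, cfg)
  expect_lte(sel$cv_f, f1_only$cv_f + 0.05)
  # flat-gain data returns the minimum subset (tie rule)
  Xf <- matrix(rnorm(n * 3), n, 3); colnames(Xf) <- paste0("g", 1:3)
  yperm <- sample(y)
  self <- sequential_forward_search(1:3, Xf, yperm, cfg)
  expect_lte(length(self$features), 3)
})

test_that("grid search separates blobs, collapses on permuted labels, deterministic", {
  set.seed(75)
  n <- 120
  y <- rep(0:1, each = n / 2)
  X <- cbind(rnorm(n, mean = 3 * y), rnorm(n, mean = -2 * y))
  colnames(X) <- c("a", "b")
  cfg <- train_config(c_grid = 4^(0:2), gamma_grid = 4^(-2:1), seed = 75)
  m1 <- grid_search_train(X, y, cfg, "site")
  expect_s3_class(m1, "StageModel")
  expect_gte(m1$cv_f, 0.95)
  m2 <- grid_search_train(X, y, cfg, "site")
  expect_identical(c(m1$C, m1$gamma), c(m2$C, m2$gamma))   # deterministic
  # label permutation: CV F near the class-prior baseline
  yp <- sample(y)
  m3 <- grid_search_train(X, yp, cfg, "site")
  expect_lt(m3$cv_f, 0.75)
  expect_error(grid_search_train(X, rep(1, n), cfg), "both classes")
  # decision scores separate training blobs
  sc <- predict_stage(m1, X)
  expect_gt(mean(sc[y == 1] > 0), 0.9)
  expect_gt(mean(sc[y == 0] < 0), 0.9)
  # schema mismatch is caught
  Xbad <- X; colnames(Xbad) <- c("a", "zz")
  expect_error(predict_stage(m1, Xbad), "schema")
})

test_that("cost ratio shifts decisions toward the minority positive class", {
  set.seed(76)
  n <- 300
  y <- c(rep(1, 30), rep(0, 270))
  X <- cbind(rnorm(n, mean = 1.0 * y), rnorm(n))
  colnames(X) <- c("a", "b")
  cfg_w <- train_config(c_grid = 4, gamma_grid = 0.25, seed = 76)
  m_w <- grid_search_train(X, y, cfg_w, "site")
  cfg_u <- train_config(c_grid = 4, gamma_grid = 0.25, seed = 76,
                        cost_ratio = 1)
  m_u <- grid_search_train(X, y, cfg_u, "site")
  expect_gte(sum(predict_stage(m_w, X) > 0), sum(predict_stage(m_u, X) > 0))
})

test_that("predict_targets ranks a planted target first and is a total order", {
  setup <- get_tiny_setup()
  m <- setup$corpus$mirnas[[1]]
  test_utrs <- setup$parts$test$utrs
  r <- predict_targets(m, test_utrs, setup$model$site_model,
                       setup$model$utr_model)
  expect_equal(nrow(r), length(test_utrs))
  expect_true(!is.unsorted(-r$score))
  lab <- grepl("_pos", r$utr_id)
  # every siteless negative carries the floor and sorts last
  expect_true(all(r$score[!lab & r$n_sites == 0] == score_floor()))
  expect_lt(mean(which(lab)), mean(which(!lab)))      # positives rank higher
  # duplicate UTR entries get identical scores; ties break by utr_id
  dup <- test_utrs[c(1, 1)]
  names(dup) <- c("dupA", "dupB")
  dup$dupA$id <- "dupA"; dup$dupB$id <- "dupB"
  r2 <- predict_targets(m, dup, setup$model$site_model,
                        setup$model$utr_model)
  expect_equal(r2$score[1], r2$score[2])
  expect_equal(r2$utr_id, c("dupA", "dupB"))
})
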