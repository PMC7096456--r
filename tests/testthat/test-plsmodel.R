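test_that("PLS reproduces a noiseless linear system exactly", {
  # y built from 3 singular directions of centered X: the least-squares
  # solution spans a 3-dimensional Krylov space, so 3 components fit it
  set.seed(5)
  X <- scale(matrix(rnorm(20 * 6), 20, 6), scale = FALSE)
  sv <- svd(X)
  y <- as.numeric(X %*% (sv$v[, 1:3] %*% c(1, -2, 0.5)))
  m <- fit_pls(X, y, n_lv = 3, scale = FALSE)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
})

test_that("single-variable PLS equals the simple regression line", {
  set.seed(8)
  x <- rnorm(15, mean = 2)
  y <- 3 + 1.7 * x + rnorm(15, sd = 0.3)
  m <- fit_pls(cbind(x), y, n_lv = 1)
  b <- cov(x, y) / var(x)           # closed-form univariate least squares
  a <- mean(y) - b * mean(x)
  expect_equal(predict(m, cbind(x)), a + b * x, tolerance = 1e-10)
})

test_that("full-rank PLS matches the least-squares oracle", {
  set.seed(12)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  m <- fit_pls(X, y, n_lv = 5)
  ls_fit <- lm(y ~ X)
  expect_lt(max(abs(predict(m, X) - fitted(ls_fit))), 1e-6)
})

test_that("calibration scores are orthogonal and self-consistent", {
  d <- linear_dataset(n = 30, p = 12, noise = 0.2)
  m <- fit_pls(d$X, d$y, n_lv = 6)
  G <- crossprod(m$cal_scores)
  offdiag <- abs(G - diag(diag(G)))
  expect_lt(max(offdiag) / max(diag(G)), 1e-8)
  expect_lt(max(abs(project_scores(m, d$X) - m$cal_scores)), 1e-10)
})

test_that("a sample at the calibration centroid predicts the mean response", {
  d <- linear_dataset(n = 25, p = 10, noise = 0.1)
  m <- fit_pls(d$X, d$y, n_lv = 4)
  ctr <- rbind(m$scaler$column_means)
  expect_equal(as.numeric(predict(m, ctr)), mean(d$y), tolerance = 1e-10)
  expect_lt(max(abs(project_scores(m, ctr))), 1e-10)
})

test_that("batch prediction equals row-by-row prediction", {
  d <- linear_dataset(n = 20, p = 8, noise = 0.1)
  m <- fit_pls(d$X, d$y, n_lv = 3)
  set.seed(2)
  Xn <- matrix(rnorm(4 * 8), 4, 8)
  batch <- predict(m, Xn)
  single <- vapply(1:4, function(i) predict(m, Xn[i, , drop = FALSE]), numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("coefficients are invariant to calibration row order", {
  d <- linear_dataset(n = 30, p = 10, noise = 0.2)
  m1 <- fit_pls(d$X, d$y, n_lv = 5)
  set.seed(4)
  perm <- sample(30)
  m2 <- fit_pls(d$X[perm, ], d$y[perm], n_lv = 5)
  expect_lt(max(abs(m1$coefficients - m2$coefficients)), 1e-8)
})

test_that("fit_pls validates its inputs", {
  d <- linear_dataset(n = 10, p = 4)
  expect_error(fit_pls(d$X, d$y, n_lv = 5), "exceeds min")
  expect_error(fit_pls(d$X, rep(1, 10), n_lv = 2), "zero variance")
  # rank-1 X cannot support 2 components
  X1 <- outer(rnorm(10), rnorm(4))
  expect_error(fit_pls(X1 + 0, rnorm(10) , n_lv = 2), "effective rank|zero-variance")
})

test_that("RMSECV on a noiseless rank-2 system is flat beyond 2 LVs", {
  set.seed(21)
  TT <- matrix(rnorm(40 * 2), 40, 2)
  P <- matrix(rnorm(2 * 10), 2, 10)
  y <- as.numeric(TT %*% c(2, -1))
  X <- TT %*% P
  sel <- suppressWarnings(select_lv(X, y, max_lv = 6, folds = 5))
  expect_length(sel$rmsecv_curve, 6)
  expect_equal(sel$n_lv, 2L)
  expect_lt(sel$rmsecv_curve[2], 1e-8)
  expect_equal(sel$rmsecv_curve[3:6], rep(sel$rmsecv_curve[2], 4),
               tolerance = 1e-10)
  expect_true(all(diff(sel$rmsecv_curve[1:2]) <= 0))
})

test_that("cross-validation recovers the intrinsic dimension", {
  for (s in 1:10) {
    set.seed(100 + s)
    TT <- matrix(rnorm(80 * 3), 80, 3)
    P <- matrix(rnorm(3 * 25), 3, 25)
    X <- TT %*% P + matrix(rnorm(80 * 25, sd = 0.01), 80, 25)
    y <- as.numeric(TT %*% c(1, 0.5, -0.8))
    y <- y + rnorm(80, sd = 0.01 * sd(y))
    sel <- select_lv(X, y, max_lv = 10, folds = 5)
    expect_true(sel$n_lv %in% c(3L, 4L),
                label = sprintf("seed %d chose %d LVs", s, sel$n_lv))
  }
})

test_that("leave-one-out cross-validation returns a full curve", {
  d <- linear_dataset(n = 20, p = 10, noise = 0.1)
  sel <- select_lv(d$X, d$y, max_lv = 5, folds = 20)
  expect_length(sel$rmsecv_curve, 5)
  expect_true(all(is.finite(sel$rmsecv_curve)))
})

test_that("select_lv is deterministic and truncates infeasible max_lv", {
  d <- linear_dataset(n = 25, p = 6, noise = 0.1)
  s1 <- select_lv(d$X, d$y, max_lv = 6)
  s2 <- select_lv(d$X, d$y, max_lv = 6)
  expect_identical(s1, s2)
  expect_warning(sel <- select_lv(d$X, d$y, max_lv = 50), "truncating")
  expect_length(sel$rmsecv_curve, 6)
})

test_that("Monte-Carlo screening passes clean data and rejects small n_runs", {
  d <- linear_dataset(n = 40, p = 20, noise = 0.05, seed = 31)
  expect_error(mc_outlier_detect(d$X, d$y, n_lv = 5, n_runs = 50),
               "n_runs must be >= 100")
  rep1 <- mc_outlier_detect(d$X, d$y, n_lv = 5, n_runs = 300, seed = 1)
  expect_false(any(rep1$flagged))
  expect_equal(rep1$n_runs, 300L)
})

test_that("Monte-Carlo screening flags a planted response outlier", {
  d <- linear_dataset(n = 40, p = 20, noise = 0.05, seed = 17)
  y <- d$y
  y[7] <- y[7] + 10 * sd(y)
  rep1 <- mc_outlier_detect(d$X, y, n_lv = 5, n_runs = 300, seed = 1)
  expect_true(rep1$flagged[7])
  expect_equal(sum(rep1$flagged), 1L)
})
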