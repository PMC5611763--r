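centered <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("v", 1:p)))
  sweep(X, 2, colMeans(X))
}

test_that("PCA explained variation matches the SVD partial sums", {
  X <- centered(10, 5)
  sv <- svd(X)
  pc <- pca_fit(X, 2)
  expect_equal(pc$r2x_cum, cumsum(sv$d[1:2]^2) / sum(sv$d^2), tolerance = 1e-12)
  expect_equal(abs(pc$T), abs(sv$u[, 1:2] %*% diag(sv$d[1:2])),
               tolerance = 1e-8, ignore_attr = TRUE)
  # scores are mutually orthogonal
  expect_lt(abs(crossprod(pc$T[, 1], pc$T[, 2])),
            1e-8 * sqrt(sum(pc$T[, 1]^2) * sum(pc$T[, 2]^2)))

  # a rank-1 matrix is explained entirely by one component
  expect_equal(pca_fit(tcrossprod(1:8, c(1, -2, 3, 1)), 1)$r2x_cum, 1)
  expect_error(pca_fit(X, 11), "min\\(n, p\\)")
})

test_that("OPLS with no orthogonal components is NIPALS PLS1", {
  X <- centered(20, 15, seed = 2)
  y <- rep(c(0, 1), 10)
  m <- opls_fit(X, factor(c("organic", "conventional"))[y + 1], a_orth = 0)
  o <- pls1_oracle(X, y)
  flip <- sign(sum(m$W[, 1] * o$w))
  expect_equal(unname(m$W[, 1]), unname(flip * o$w), tolerance = 1e-8)
  expect_equal(unname(m$T[, 1]), unname(flip * o$t), tolerance = 1e-8)
  expect_equal(unname(m$P[, 1]), unname(flip * o$p), tolerance = 1e-8)
})

test_that("predictive and orthogonal scores are orthogonal; R2Y grows with a_orth", {
  set.seed(6)
  X <- centered(30, 40, seed = 6)
  X[, 1:5] <- X[, 1:5] + rep(c(-1, 1), each = 15)
  y <- factor(rep(c("organic", "conventional"), each = 15))
  r2y_prev <- -Inf
  for (a in 0:3) {
    m <- opls_fit(X, y, a_orth = a)
    for (k in seq_len(a)) {
      expect_lt(abs(sum(m$T[, 1] * m$T_o[, k])),
                1e-8 * sqrt(sum(m$T[, 1]^2) * sum(m$T_o[, k]^2)))
    }
    expect_gte(m$r2y, r2y_prev - 1e-12)
    expect_true(m$r2y >= 0 && m$r2y <= 1)
    r2y_prev <- m$r2y
  }
  expect_error(opls_fit(X, y, a_orth = 50), "rank")
  expect_error(opls_fit(X, factor(rep("organic", 30)), 0), "class")
})

test_that("perfectly separated classes are fit almost exactly", {
  set.seed(7)
  X <- matrix(rnorm(40 * 30, sd = 0.01), 40, 30)
  X[1:20, 1:10] <- X[1:20, 1:10] + 5
  X <- sweep(X, 2, colMeans(X))
  y <- factor(rep(c("conventional", "organic"), each = 20))
  m <- opls_fit(X, y, a_orth = 0)
  expect_gte(m$r2y, 0.99)
  pr <- opls_predict(m, X)
  expect_identical(unname(pr$labels), as.character(y))
})

test_that("prediction obeys the threshold rule and row equivariance", {
  X <- centered(24, 12, seed = 8)
  X[, 1] <- X[, 1] + rep(c(-2, 2), 12)
  y <- factor(rep(c("organic", "conventional"), 12))
  m <- opls_fit(X, y, a_orth = 1)
  pr <- opls_predict(m, X)
  expect_identical(unname(pr$labels),
                   unname(ifelse(drop(pr$response) > 0.5,
                                 "conventional", "organic")))
  perm <- sample(24)
  pr2 <- opls_predict(m, X[perm, ])
  expect_equal(unname(drop(pr2$response)), unname(drop(pr$response))[perm])
  expect_error(opls_predict(m, X[, 1:5]), "variables")
})

test_that("multi-class year models use classes - 1 predictive components", {
  set.seed(9)
  X <- centered(40, 25, seed = 9)
  yr <- factor(rep(2005:2008, each = 10))
  for (k in 1:4) X[yr == levels(yr)[k], k] <- X[yr == levels(yr)[k], k] + 3
  m <- opls_fit(sweep(X, 2, colMeans(X)), yr, a_orth = 1)
  expect_equal(m$a_pred, 3L)
  expect_output(print(m), "3 \\+ 1 \\+ 0")
  pr <- opls_predict(m, sweep(X, 2, colMeans(X)))
  expect_gt(mean(pr$labels == as.character(yr)), 0.9)
})

test_that("binary model component shape is reported as 1 + a_orth + 0", {
  set.seed(10)
  X <- centered(30, 60, seed = 10)
  X[, 1:6] <- X[, 1:6] + rep(c(-1, 1), each = 15)
  y <- factor(rep(c("organic", "conventional"), each = 15))
  m <- opls_fit(X, y, a_orth = 5)
  expect_equal(c(m$a_pred, m$a_orth), c(1L, 5L))
  expect_output(print(m), "1 \\+ 5 \\+ 0")
})

test_that("cross-validation: fold shape, noise null, planted signal, bounds", {
  ds <- small_ds()
  tab <- prepare_dataset(ds)
  meta <- align_meta(tab, ds$meta)
  cv <- cross_validate(tab, meta$system, a_orth_max = 2,
                       order_keys = meta[, c("year", "sample_id")])
  sizes <- table(cv$folds)
  expect_equal(length(sizes), 7L)
  expect_lte(max(sizes) - min(sizes), 1)
  # folds are class-balanced by construction
  for (f in 1:7) {
    expect_true(all(table(meta$system[cv$folds == f]) >= 1))
  }
  expect_true(all(cv$q2 <= 1))
  # a strong planted system effect is predicted well out of fold
  expect_gt(max(cv$q2), 0.5)

  # pure-noise response has no predictive ability
  set.seed(12)
  noise <- matrix(rlnorm(42 * 30), 42, 30,
                  dimnames = list(paste0("s", 1:42), paste0("b", 1:30)))
  yn <- factor(rep(c("organic", "conventional"), 21))
  cvn <- cross_validate(feature_table(noise), yn, a_orth_max = 2)
  expect_true(all(cvn$q2 <= 0))

  # identical inputs give identical reports (deterministic folds)
  cv2 <- cross_validate(tab, meta$system, a_orth_max = 2,
                        order_keys = meta[, c("year", "sample_id")])
  expect_identical(cv$q2, cv2$q2)
})

test_that("component selection applies the greedy 0.01 rule", {
  mk_report <- function(q2) structure(list(q2 = q2, a_pred = 1L,
                                           a_orth_max = length(q2) - 1L),
                                      class = "cv_report")
  expect_equal(select_components(mk_report(c(0.30, 0.50, 0.505)))$a_orth, 1L)
  expect_equal(select_components(mk_report(c(0.30, 0.305, 0.60)))$a_orth, 0L)
  expect_warning(sel <- select_components(mk_report(c(0.1, 0.2, 0.3))),
                 "a_orth_max")
  expect_equal(sel$a_orth, 2L)
})

test_that("fitted OPLS models survive serialization bit for bit", {
  ds <- small_ds()
  tab <- prepare_dataset(ds)
  meta <- align_meta(tab, ds$meta)
  m <- opls_train(tab, meta$system, a_orth = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_opls(m, path)
  back <- read_opls(path)
  pr1 <- opls_predict(m, tab)
  pr2 <- opls_predict(back, tab)
  expect_identical(pr1$response, pr2$response)
  expect_identical(pr1$labels, pr2$labels)
})
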