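toy_meta <- function(n_per_cell = 3, years = 2005:2006) {
  grid <- expand.grid(system = c("organic", "conventional"), year = years,
                      rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("s%02d", seq_len(nrow(grid))),
             year = grid$year, system = grid$system,
             cultivar = rep(c("Nerac", "Namur"), each = 2,
                            length.out = nrow(grid)),
             field_code = paste0(grid$year, substr(grid$system, 1, 1)),
             location = "loc1", stringsAsFactors = FALSE)
}

test_that("splits have the documented shapes", {
  meta <- toy_meta(3)  # 12 samples
  # n = 21: the random third holds exactly 7 test samples
  meta21 <- toy_meta(3)[rep(1:12, length.out = 21), ]
  meta21$sample_id <- sprintf("s%02d", 1:21)
  sp <- make_split(meta21, "random_third", seed = 5)
  expect_length(sp$test, 7)
  expect_length(sp$train, 14)
  expect_setequal(c(sp$train, sp$test), meta21$sample_id)

  # stratification keeps both classes and every year in the training set
  expect_true(all(table(meta21$system[meta21$sample_id %in% sp$train]) > 0))

  sp_y <- make_split(meta, "leave_year_out", year = 2006)
  expect_setequal(sp_y$test, meta$sample_id[meta$year == 2006])
  expect_true(all(meta$year[meta$sample_id %in% sp_y$train] == 2005))

  sp_c <- make_split(meta, "leave_cultivar_out", cultivar = "Namur")
  expect_true(all(meta$cultivar[meta$sample_id %in% sp_c$train] == "Nerac"))

  sp_f <- make_split(meta, "leave_fields_out",
                     field_codes = c("2005o", "2005c"))
  expect_setequal(sp_f$test, meta$sample_id[meta$year == 2005])

  # a split that strips one class from training is refused
  meta_bad <- meta
  meta_bad$system[meta_bad$year == 2005] <- "organic"
  meta_bad$system[meta_bad$year == 2006] <- "conventional"
  expect_error(make_split(meta_bad, "leave_year_out", year = 2006),
               "without class")
  expect_error(make_split(meta, "leave_year_out", year = 1999), "not in")
})

test_that("evaluation reports rate, sensitivity and specificity correctly", {
  ds <- small_ds()
  tab <- prepare_dataset(ds)
  meta <- align_meta(tab, ds$meta)
  sp <- make_split(meta, "random_third", seed = 2)
  tr <- subset_table(tab, samples = sp$train)
  trm <- align_meta(tr, meta[meta$sample_id %in% sp$train, ])
  m <- opls_train(tr, trm$system, a_orth = 1)
  te <- subset_table(tab, samples = sp$test)
  tem <- align_meta(te, meta[meta$sample_id %in% sp$test, ])
  rep_ <- evaluate(m, te, tem)
  # rate equals the brute-force match count
  expect_equal(rep_$rate,
               100 * mean(rep_$predictions$predicted == rep_$predictions$truth))
  # rate is the class-size weighted mean of sensitivity and specificity
  n_c <- sum(tem$system == "conventional"); n_o <- sum(tem$system == "organic")
  expect_equal(rep_$rate,
               (n_c * rep_$sensitivity + n_o * rep_$specificity) / (n_c + n_o))
  expect_true(all(c(rep_$rate, rep_$sensitivity, rep_$specificity) >= 0))
  expect_true(all(c(rep_$rate, rep_$sensitivity, rep_$specificity) <= 100))
})

test_that("a constant 'conventional' classifier has sensitivity 100, specificity 0", {
  # minimal hand-built model: zero weights, response pinned above threshold
  enc <- class_encoding(c("organic", "conventional"))
  m <- structure(list(W = matrix(0, 3, 1), P = matrix(0, 3, 1),
                      T = matrix(0, 4, 1), C = matrix(0, 1, 1),
                      W_o = matrix(0, 3, 0), P_o = matrix(0, 3, 0),
                      T_o = matrix(0, 4, 0), a_pred = 1L, a_orth = 0L,
                      r2y = 0, r2x = 0, y_means = 0.9, encoding = enc,
                      scaling = NULL, variables = c("a", "b", "c")),
                 class = "opls_model")
  v <- matrix(1, 4, 3, dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  meta <- data.frame(sample_id = paste0("s", 1:4), year = 2005,
                     system = rep(c("organic", "conventional"), 2))
  rep_ <- evaluate(m, feature_table(v), meta)
  expect_equal(rep_$sensitivity, 100)
  expect_equal(rep_$specificity, 0)
  expect_equal(rep_$rate, 50)
})

test_that("ROC/AUC closed forms, null behavior and rank invariance", {
  r <- roc(c(0.1, 0.2, 0.8, 0.9),
           c("organic", "organic", "conventional", "conventional"))
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))

  set.seed(33)
  resp <- rnorm(600)
  labs <- sample(c("organic", "conventional"), 600, TRUE)
  r0 <- roc(resp, labs)
  expect_lt(abs(r0$auc - 0.5), 0.08)
  # AUC is a rank statistic: monotone transforms leave it unchanged
  expect_equal(roc(exp(resp), labs)$auc, r0$auc, tolerance = 1e-12)
  expect_error(roc(resp, rep("organic", 600)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic with ties", {
  set.seed(34)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    resp <- sample(seq(0, 1, 0.125), n, TRUE)  # heavy ties
    labs <- c("organic", "conventional",
              sample(c("organic", "conventional"), n - 2, TRUE))
    a <- roc(resp, labs, positive = "conventional")$auc
    expect_equal(a, auc_mw_oracle(resp, labs, "conventional"),
                 tolerance = 1e-12)
  }
})

test_that("in-package AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(35)
  for (i in 1:10) {
    resp <- rnorm(40)
    labs <- c("organic", "conventional",
              sample(c("organic", "conventional"), 38, TRUE))
    ours <- roc(resp, labs, positive = "conventional")$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = factor(labs, levels = c("organic", "conventional")),
      predictor = resp, quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})
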