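test_that("VIP obeys the mean-square-one identity and symmetry", {
  # identical copies of one informative signal: every VIP is exactly 1
  set.seed(21)
  sig <- rep(c(-1, 1), each = 10) + rnorm(20, sd = 0.1)
  X <- matrix(sig, 20, 8)
  colnames(X) <- paste0("v", 1:8); rownames(X) <- paste0("s", 1:20)
  X <- sweep(X, 2, colMeans(X))
  y <- factor(rep(c("organic", "conventional"), each = 10))
  v <- vip_scores(opls_fit(X, y, a_orth = 0))
  expect_equal(unname(v$vip), rep(1, 8), tolerance = 1e-10)

  # one informative variable among noise carries the top VIP, > 1
  Xn <- matrix(rnorm(20 * 40), 20, 40,
               dimnames = list(paste0("s", 1:20), paste0("v", 1:40)))
  Xn[, 17] <- Xn[, 17] + 4 * rep(c(-1, 1), each = 10)
  Xn <- sweep(Xn, 2, colMeans(Xn))
  vn <- vip_scores(opls_fit(Xn, y, a_orth = 1))
  expect_equal(which.max(vn$vip), c(v17 = 17L))
  expect_gt(vn$vip[17], 1)
  # mean squared VIP is 1 on any fitted model, multi-class included
  expect_equal(mean(vn$vip^2), 1, tolerance = 1e-6)
  yr <- factor(rep(2005:2008, 5))
  vy <- vip_scores(opls_fit(Xn, yr, a_orth = 1))
  expect_equal(mean(vy$vip^2), 1, tolerance = 1e-6)
})

test_that("VIP filtering is strict and order-preserving", {
  v <- structure(list(vip = c(a = 0.5, b = 1.0, c = 1.5),
                      ssy = 1), class = "vip_result")
  tab <- feature_table(matrix(1:6, 2, dimnames = list(c("s1", "s2"),
                                                      c("a", "b", "c"))))
  kept <- filter_by_vip(tab, v, 1)
  expect_identical(bucket_ids(kept), "c")       # ties at 1.0 are dropped
  expect_identical(bucket_ids(filter_by_vip(tab, v, 0)), c("a", "b", "c"))
  expect_error(filter_by_vip(tab, v, 99), "threshold")
  expect_error(filter_by_vip(subset_table(tab, buckets = 1:2), v), "aligned")
})

test_that("VIP refinement keeps the class signal in a much smaller table", {
  ds <- small_ds()
  tab <- prepare_dataset(ds)
  meta <- align_meta(tab, ds$meta)
  m0 <- opls_train(tab, meta$system, a_orth = 1)
  refined <- filter_by_vip(tab, vip_scores(m0), 1)
  # refinement discards the bulk of the variables...
  expect_lt(ncol(refined$values), 0.6 * ncol(tab$values))
  # ...while the refit retains essentially all of the explained response
  m1 <- opls_train(refined, meta$system, a_orth = 1)
  expect_gte(m1$r2y, m0$r2y - 0.03)
  expect_gte(m1$r2y, 0.9)
})

test_that("year deconfounding removes year signal but spares the markers", {
  ds <- small_ds()
  tab <- prepare_dataset(ds)
  meta <- align_meta(tab, ds$meta)
  dec <- deconfound_factor(tab, meta, "year", a_orth = 2)
  # removals come exactly from the year model's VIP > 1 set
  expect_identical(dec$removed,
                   names(dec$vip$vip)[dec$vip$vip > 1])
  # substantial chunk of the planted year variables goes...
  expect_gte(mean(ds$truth$year_id %in% dec$removed), 0.25)
  # ...but at most 10% of the planted system markers (disjoint case)
  expect_lte(mean(ds$truth$marker_id %in% dec$removed), 0.10)
  expect_false(any(setdiff(bucket_ids(tab), names(dec$vip$vip)) %in%
                     dec$removed))
})

test_that("deconfounding is harmless when no year effect exists", {
  ds0 <- generate_dataset(small_config(year_effect_sd = 0, seed = 31))
  tab <- prepare_dataset(ds0)
  meta <- align_meta(tab, ds0$meta)
  dec <- deconfound_factor(tab, meta, "year", a_orth = 1)
  sp <- make_split(meta, "random_third", seed = 31)
  tr <- subset_table(dec$table, samples = sp$train)
  trm <- align_meta(tr, meta[meta$sample_id %in% sp$train, ])
  m <- opls_train(tr, trm$system, a_orth = 1)
  te <- subset_table(dec$table, samples = sp$test)
  tem <- align_meta(te, meta[meta$sample_id %in% sp$test, ])
  expect_gte(evaluate(m, te, tem)$rate, 85)
})

test_that("a confounder aliased with the class is refused", {
  ds <- small_ds()
  tab <- prepare_dataset(ds)
  meta <- align_meta(tab, ds$meta)
  meta$aliased <- ifelse(meta$system == "organic", "A", "B")
  expect_error(deconfound_factor(tab, meta, "aliased"), "confounded 1:1")
  meta$one <- "x"
  expect_error(deconfound_factor(tab, meta, "one"), "fewer than 2 levels")
})

test_that("the S-plot ranks variables by class-discriminating correlation", {
  ds <- small_ds()
  tab <- prepare_dataset(ds)
  meta <- align_meta(tab, ds$meta)
  m <- opls_train(tab, meta$system, a_orth = 1)
  Xs <- apply_scaling(tab, m$scaling)
  # a copy of the score itself correlates perfectly; a constant is flagged
  probe <- cbind(Xs, t_copy = m$T[, 1], flatvar = 0)
  sp <- s_plot(m, probe)
  expect_equal(sp$corr[sp$bucket_id == "t_copy"], 1, tolerance = 1e-12)
  expect_true(sp$flat[sp$bucket_id == "flatvar"])
  expect_equal(sp$corr[sp$bucket_id == "flatvar"], 0)
  expect_true(all(abs(sp$corr) <= 1 + 1e-12))
  # cov and corr agree in sign
  nz <- abs(sp$cov) > 1e-14 & !sp$flat
  expect_true(all(sign(sp$cov[nz]) == sign(sp$corr[nz])))

  # planted markers fill the tails; pure-noise variables sit in the middle
  real <- s_plot(m, Xs)
  is_marker <- real$bucket_id %in% ds$truth$marker_id
  expect_gt(mean(abs(real$corr[is_marker])), 2 * mean(abs(real$corr[!is_marker])))
  tails <- real$bucket_id[order(-abs(real$corr))][1:24]
  expect_gte(mean(tails %in% ds$truth$marker_id), 0.7)
})

test_that("marker candidates combine the S-plot tails and top VIP", {
  ds <- small_ds()
  tab <- prepare_dataset(ds)
  meta <- align_meta(tab, ds$meta)
  m <- opls_train(tab, meta$system, a_orth = 1)
  Xs <- apply_scaling(tab, m$scaling)
  cand <- select_candidates(m, Xs, n_top = 24)
  expect_lte(length(cand), 48)
  recall <- mean(ds$truth$marker_id %in% cand)
  expect_gte(recall, 0.7)
})
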