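# build matching feature/mask matrices from vectors
as_maps <- function(feats, labs) {
  n <- length(feats)
  nc <- max(2, ceiling(n / 2))
  pad <- nc * 2 - n
  list(map = matrix(c(feats, rep(feats[1], pad)), 2, nc),
       mask = matrix(c(labs, rep(labs[1], pad)), 2, nc))
}

test_that("threshold training separates well-separated classes", {
  mm <- as_maps(c(0.7, 0.8, 0.9, 0.1, 0.2, 0.3), c(1, 1, 1, 0, 0, 0))
  model <- train_threshold(mm$map, mm$mask, excluded_border = 0)
  expect_equal(model$youden_j, 1)
  expect_equal(model$polarity, "tumor_above")
  expect_gt(model$threshold, 0.3)
  expect_lt(model$threshold, 0.7)
  expect_false(model$uninformative)
  # identical class distributions carry no signal
  mm2 <- as_maps(rep(c(0.4, 0.5), 4), rep(c(0, 0, 1, 1), 2))
  expect_warning(m2 <- train_threshold(mm2$map, mm2$mask,
                                       excluded_border = 0),
                 "uninformative")
  expect_lt(m2$youden_j, 0.05)
  # pooling invariance: duplicating the training map changes nothing
  m1 <- train_threshold(list(mm$map, mm$map), list(mm$mask, mm$mask),
                        excluded_border = 0)
  m0 <- train_threshold(mm$map, mm$mask, excluded_border = 0)
  expect_equal(m1$threshold, m0$threshold)
  expect_equal(m1$youden_j, m0$youden_j)
  expect_error(train_threshold(mm$map, matrix(0, 2, 3),
                               excluded_border = 0), "both classes")
})

test_that("threshold sweep agrees exactly with the brute-force oracle", {
  set.seed(10)
  for (i in 1:8) {
    n <- sample(20:60, 1)
    feats <- round(runif(n, 0, pi), 2)   # force ties
    labs <- rbinom(n, 1, plogis(4 * (feats - 1)))
    if (length(unique(labs)) < 2) next
    mm <- as_maps(feats, labs)
    model <- train_threshold(mm$map, mm$mask, excluded_border = 0)
    # oracle on the same pooled pixels (including the pad pixel)
    oracle <- brute_youden(as.vector(mm$map), as.vector(mm$mask))
    expect_equal(model$youden_j, oracle$j)
    expect_equal(model$threshold, oracle$threshold)
    expect_equal(model$polarity, oracle$polarity)
  }
})

test_that("classification uses strict inequality on the tumor side", {
  model <- structure(list(threshold = 0.3, polarity = "tumor_above",
                          youden_j = 1, uninformative = FALSE,
                          band_pair = c(446.6, 632)),
                     class = "threshold_model")
  expect_equal(classify(matrix(0, 4, 4), model), matrix(0L, 4, 4))
  expect_equal(classify(matrix(0.3, 4, 4), model), matrix(0L, 4, 4))
  expect_equal(classify(matrix(0.31, 4, 4), model), matrix(1L, 4, 4))
  model$polarity <- "tumor_below"
  expect_equal(classify(matrix(0.29, 4, 4), model), matrix(1L, 4, 4))
})

test_that("confusion counts and the three metrics follow their definitions", {
  t1 <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_s3_class(cc <- confusion(t1, t1), "confusion_counts")
  expect_equal(cc$FP + cc$FN, 0)
  cc2 <- confusion(1 - t1, t1)
  expect_equal(cc2$TP + cc2$TN, 0)
  # constructed 2000-pixel tally: TP 916, FN 84, TN 952, FP 48
  pred <- matrix(c(rep(1, 916), rep(0, 84), rep(0, 952), rep(1, 48)),
                 40, 50)
  truth <- matrix(c(rep(1, 1000), rep(0, 1000)), 40, 50)
  cc3 <- confusion(pred, truth)
  expect_equal(cc3$TP, 916); expect_equal(cc3$FN, 84)
  expect_equal(cc3$TN, 952); expect_equal(cc3$FP, 48)
  expect_equal(sensitivity(cc3), 0.916)
  expect_equal(specificity(cc3), 0.952)
  expect_equal(accuracy(cc3), 0.934)
  # excluded regions drop out of the tally
  excl <- matrix(FALSE, 2, 2); excl[1, 1] <- TRUE
  expect_equal(confusion(t1, t1, excl)$TP, 1)
  # degenerate denominators raise, never NaN
  cc0 <- confusion(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_error(sensitivity(cc0), "undefined")
  cc1 <- confusion(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_error(specificity(cc1), "undefined")
})

test_that("metric rows keep the complement identities exactly", {
  pred <- matrix(c(1, 0, 1, 0, 1, 1), 2, 3)
  truth <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3)
  row <- metrics_row("s1", confusion(pred, truth))
  expect_equal(row$sen_pct + row$fn_ratio_pct, 100)
  expect_equal(row$spec_pct + row$fp_ratio_pct, 100)
  tab <- metrics_table(row)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$sample_id[2], "Mean")
  expect_equal(tab$sen_pct[2], round(row$sen_pct, 3))
})

test_that("stronger phase contrast never hurts training separability", {
  js <- vapply(c(0.25, 0.3, 0.35), function(csc) {
    sc <- small_scene(seed = 21)
    sc$tumor_medium$c_sc <- csc
    po <- render_phantom(sc)
    pm <- suppressWarnings(lapply(c(446.6, 632), function(wl)
      extract_band_phase(po$cube, wl, strip_rows(sc))))
    sm <- phase_shift_map(pm[[1]], pm[[2]])
    excl <- matrix(FALSE, sc$rows, sc$cols); excl[strip_rows(sc), ] <- TRUE
    train_threshold(sm, po$truth, exclude = excl)$youden_j
  }, 0)
  expect_true(all(diff(js) >= -1e-9))
})

test_that("repeated acquisitions give stable sensitivity and specificity", {
  sens <- c(); specs <- c()
  for (s in c(31, 32, 33)) {
    sc <- small_scene(seed = s)
    po <- render_phantom(sc)
    cfg <- pipeline_config(output_dir = withr::local_tempdir())
    res <- suppressWarnings(
      pipeline_run(po$cube, strip_rows(sc), cfg, mask = po$truth))
    sens <- c(sens, res$metrics$sen_pct)
    specs <- c(specs, res$metrics$spec_pct)
  }
  expect_lt(diff(range(sens)), 5)
  expect_lt(diff(range(specs)), 5)
  expect_true(all(sens > 90) && all(specs > 90))
})

test_that("mask overlays blend only tumor pixels", {
  base <- array(runif(4 * 5 * 3), c(4, 5, 3))
  mask <- matrix(0L, 4, 5); mask[2, 3] <- 1L
  expect_equal(overlay(mask, base, alpha = 0), base)
  solid <- overlay(matrix(1L, 4, 5), base, alpha = 1)
  expect_equal(solid[, , 1], matrix(1, 4, 5))
  expect_equal(solid[, , 2], matrix(0, 4, 5))
  out <- overlay(mask, base, alpha = 0.5)
  expect_equal(out[1, 1, ], base[1, 1, ])
  expect_equal(out[2, 3, 1], 0.5 * base[2, 3, 1] + 0.5)
  expect_equal(overlay(matrix(0L, 4, 5), base, alpha = 1), base)
})

test_that("bundled specimen ratios satisfy the complement identities", {
  tab <- stained_specimen_ratios()
  expect_equal(nrow(tab), 10)
  expect_equal(tab$sen_pct + tab$fn_ratio_pct, rep(100, 10))
  expect_equal(tab$spec_pct + tab$fp_ratio_pct, rep(100, 10))
})
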