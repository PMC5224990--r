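test_that("min-max normalization maps training columns to [0,1] and inverts", {
  expect_equal(unname(normalize_apply(normalize_fit(cbind(c(0, 5, 10))),
                                      cbind(c(0, 5, 10)))[, 1]),
               c(0, 0.5, 1))
  expect_equal(unname(normalize_apply(normalize_fit(cbind(c(3, 3, 3))),
                                      cbind(c(3, 3, 3)))[, 1]),
               c(0, 0, 0))
  expect_error(normalize_apply(list(), cbind(1)), "before")

  set.seed(61)
  x <- matrix(rnorm(200), 40, 5)
  par <- normalize_fit(x)
  z <- normalize_apply(par, x)
  # invert the affine map and recover the originals
  back <- sweep(sweep(z, 2, par$max - par$min, "*"), 2, par$min, "+")
  expect_equal(back, x, tolerance = 1e-12)
})

test_that("the symbolic gamma resolves against the training-set size", {
  expect_equal(resolve_gamma("1/n", 111), 1 / 111)
  expect_equal(resolve_gamma(0.25, 111), 0.25)
  expect_error(resolve_gamma("2/n", 10), "1/n")
  expect_error(resolve_gamma(-1, 10), "positive")
})

test_that("the SVM separates well-separated blobs and resolves its gamma", {
  ds <- blob_dataset()
  cfg <- model_config(C = 15, gamma = "1/n", seed = 9)
  model <- train_svm(ds, cfg)
  expect_equal(model$gamma, 1 / nrow(ds))
  pred <- predict(model, ds)
  expect_equal(pred$pred, ds$label)  # training accuracy 1.0
  expect_error(train_svm(make_ds(matrix(rnorm(10), 5),
                                 rep("som", 5))), "training error")
})

test_that("decision values match an explicit kernel-matrix dual evaluation", {
  set.seed(62)
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(c("nonsom", "som"), each = 5)
  ds <- make_ds(x, y)
  cfg <- model_config(C = 2, gamma = 0.5, normalize = FALSE,
                      probability = FALSE, seed = 1)
  model <- train_svm(ds, cfg)
  fit <- model$fit
  rbf <- function(a, b) exp(-0.5 * sum((a - b)^2))
  manual <- apply(x, 1, function(row) {
    sum(fit$coefs * apply(fit$SV, 1, rbf, b = row)) - fit$rho
  })
  pred <- predict(model, ds)
  # e1071 orients the decision value toward the first class seen (nonsom),
  # while the score column is oriented toward som
  expect_equal(unname(pred$score), -manual, tolerance = 1e-10)
})

test_that("confusion counts follow the declared positive class", {
  # the published test-set outcome: 33/36 SOMs and 64/81 non-SOMs correct
  labels <- c(rep("som", 36), rep("nonsom", 81))
  preds <- c(rep("som", 33), rep("nonsom", 3),
             rep("nonsom", 64), rep("som", 17))
  cts <- confusion(labels, preds, positive = "nonsom")
  expect_equal(cts$TP, 64); expect_equal(cts$FN, 17)
  expect_equal(cts$TN, 33); expect_equal(cts$FP, 3)

  flipped <- confusion(labels, preds, positive = "som")
  expect_equal(flipped$TP, cts$TN); expect_equal(flipped$TN, cts$TP)
  expect_equal(flipped$FP, cts$FN); expect_equal(flipped$FN, cts$FP)

  perfect <- confusion(labels, labels, "nonsom")
  expect_equal(perfect$FN + perfect$FP, 0L)
  expect_error(confusion(c("som", "other"), c("som", "som")), "som")
})

test_that("SE/SP/ACC/MCC reproduce the published arithmetic", {
  cts <- confusion(c(rep("som", 36), rep("nonsom", 81)),
                   c(rep("som", 33), rep("nonsom", 3),
                     rep("nonsom", 64), rep("som", 17)), "nonsom")
  m <- som_metrics(cts)
  expect_equal(round(m$SE, 3), 0.790)
  expect_equal(round(m$SP, 3), 0.917)
  expect_equal(round(m$ACC, 3), 0.829)
  expect_equal(round(m$MCC, 3), 0.659)

  unit <- structure(list(TP = 1, FN = 1, TN = 1, FP = 1,
                         positive_class = "nonsom"),
                    class = "confusion_counts")
  expect_equal(som_metrics(unit)$ACC, 0.5)
  expect_equal(som_metrics(unit)$MCC, 0)

  degenerate <- structure(list(TP = 0, FN = 0, TN = 3, FP = 2,
                               positive_class = "nonsom"),
                          class = "confusion_counts")
  expect_true(is.na(som_metrics(degenerate)$SE))
})

test_that("MCC equals the phi coefficient of the two binary vectors", {
  set.seed(63)
  for (rep in 1:500) {
    n <- sample(10:60, 1)
    y <- sample(c("som", "nonsom"), n, replace = TRUE)
    p <- sample(c("som", "nonsom"), n, replace = TRUE)
    if (length(unique(y)) < 2 || length(unique(p)) < 2) next
    mcc <- som_metrics(confusion(y, p, "nonsom"))$MCC
    phi <- suppressWarnings(stats::cor(y == "nonsom", p == "nonsom"))
    expect_equal(mcc, phi, tolerance = 1e-12)
  }
})

test_that("metric identities: self-prediction is perfect, swap is symmetric", {
  set.seed(64)
  y <- sample(c("som", "nonsom"), 30, replace = TRUE)
  y[1:2] <- c("som", "nonsom")
  self <- som_metrics(confusion(y, y, "nonsom"))
  expect_equal(unlist(self), c(SE = 1, SP = 1, ACC = 1, MCC = 1))

  p <- sample(c("som", "nonsom"), 30, replace = TRUE)
  a <- som_metrics(confusion(y, p, "nonsom"))
  b <- som_metrics(confusion(y, p, "som"))
  expect_equal(a$MCC, b$MCC)
  expect_equal(a$ACC, b$ACC)
  expect_equal(a$SE, b$SP)
  expect_equal(a$SP, b$SE)
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1),
                     c("som", "som", "nonsom", "nonsom"), positive = "som")
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$points[1, ], data.frame(FPR = 0, TPR = 0),
               ignore_attr = TRUE)
  expect_equal(unlist(perfect$points[nrow(perfect$points), ]),
               c(FPR = 1, TPR = 1))

  constant <- roc_auc(rep(0.5, 10), rep(c("som", "nonsom"), 5), "som")
  expect_equal(constant$auc, 0.5)

  expect_error(roc_auc(1:3, rep("som", 3), "som"), "both classes")

  set.seed(65)
  for (rep in 1:200) {
    n <- sample(10:80, 1)
    y <- sample(c("som", "nonsom"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # plenty of ties
    auc <- roc_auc(s, y, "som")$auc
    pos <- s[y == "som"]; neg <- s[y != "som"]
    u <- sum(vapply(pos, function(a) sum(a > neg) + 0.5 * sum(a == neg), 0))
    expect_equal(auc, u / (length(pos) * length(neg)), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(66)
  y <- sample(c("som", "nonsom"), 40, replace = TRUE)
  y[1:2] <- c("som", "nonsom")
  s <- rnorm(40)
  base <- roc_auc(s, y, "som")$auc
  expect_equal(roc_auc(exp(s), y, "som")$auc, base)
  expect_equal(roc_auc(rank(s), y, "som")$auc, base)
})

test_that("cross-validation is stratified, seeded and reproducible", {
  ds <- blob_dataset(n_per_class = 15, sep = 6, seed = 67)
  cfg <- model_config(C = 4, gamma = 0.2, seed = 5)
  r1 <- cross_validate(ds, cfg, k = 5)
  r2 <- cross_validate(ds, cfg, k = 5)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$metrics, r2$metrics)
  expect_equal(r1$auc, 1.0)  # separable fixture hits the ceiling
  expect_error(cross_validate(ds, cfg, k = 20), "fold error")
})

test_that("jackknife runs one fit per instance and ignores row order", {
  ds <- blob_dataset(n_per_class = 6, sep = 6, seed = 68)
  cfg <- model_config(C = 4, gamma = 0.2, probability = FALSE, seed = 5)
  r <- jackknife(ds, cfg)
  expect_equal(nrow(r$predictions), nrow(ds))
  shuffled <- structure(ds[rev(seq_len(nrow(ds))), ],
                        qm_features = character(), schema = NULL,
                        class_convention = "nonsom",
                        class = c("som_dataset", "data.frame"))
  r2 <- jackknife(shuffled, cfg)
  expect_equal(r2$metrics, r$metrics)
  expect_equal(r2$auc, r$auc)
})

test_that("grid search maximizes CV AUC with smaller-C tie-breaking", {
  ds <- blob_dataset(n_per_class = 10, sep = 8, seed = 69)
  single <- grid_search(ds, C_grid = 7, gamma_grid = 0.3, folds = 5)
  expect_equal(single$best$C, 7)
  expect_equal(single$best$gamma, 0.3)
  expect_equal(nrow(single$table), 1L)

  # separable data scores AUC 1 everywhere: ties resolve to the smallest C
  tied <- grid_search(ds, C_grid = c(8, 2), gamma_grid = 0.3, folds = 5)
  expect_equal(max(tied$table$score), 1.0)
  expect_equal(tied$best$C, 2)

  # best really is the argmax over the returned table
  mixed <- grid_search(ds, C_grid = c(0.01, 5), gamma_grid = c(0.01, 1),
                       folds = 5)
  expect_equal(max(mixed$table$score),
               mixed$table$score[mixed$table$C == mixed$best$C &
                                   mixed$table$gamma == mixed$best$gamma])
})

test_that("probability calibration preserves the score ranking (AUC shift < 0.02)", {
  sp <- fixture_spec(n_compounds = 30, seed = 71)
  st_p <- run_fixture_study(sp, grid = FALSE,
                            cfg = model_config(probability = TRUE, seed = 1))
  st_d <- run_fixture_study(sp, grid = FALSE,
                            cfg = model_config(probability = FALSE, seed = 1))
  expect_lt(abs(st_p$report$auc - st_d$report$auc), 0.02)
})
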