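test_that("autoscaling centres and scales on training statistics only", {
  tab <- random_table(15, seed = 31)
  sc <- autoscale_fit(tab)
  X <- autoscale_apply(sc, tab)
  expect_equal(colMeans(X), setNames(rep(0, 7), composition_vars),
               tolerance = 1e-9)
  expect_equal(apply(X, 2, sd), setNames(rep(1, 7), composition_vars),
               tolerance = 1e-9)
  # a shifted test table is not re-centred
  shifted <- tab
  shifted$protein <- shifted$protein + 1
  Xs <- autoscale_apply(sc, shifted)
  expect_equal(mean(Xs[, "protein"]), 1 / sc$scale[["protein"]], tolerance = 1e-9)
  degen <- tab
  degen$fat <- 4
  expect_error(autoscale_fit(degen), "zero-SD")
})

test_that("KNN scores match a brute-force neighbour search", {
  train <- random_table(15, seed = 32)
  model <- calibrate_threshold(occ_spec("knn", k = 3, repetitions = 10),
                               train, seed = 1)
  test <- random_table(10, seed = 33)
  got <- predict(model, test)$score
  # exhaustive all-pairs oracle in the autoscaled space
  sc <- model$scaling
  Xtr <- autoscale_apply(sc, train)
  Xte <- autoscale_apply(sc, test)
  want <- vapply(seq_len(nrow(Xte)), function(i) {
    d <- sqrt(colSums((t(Xtr) - Xte[i, ])^2))
    mean(sort(d)[1:3])
  }, 0)
  expect_equal(got, want, tolerance = 1e-9)
  # a record equal to a training vector has score 0 at k = 1
  m1 <- calibrate_threshold(occ_spec("knn", k = 1, repetitions = 10),
                            train, seed = 1)
  expect_equal(predict(m1, train[4, ])$score, 0, tolerance = 1e-12)
  # duplicating a training point never increases any score
  dup <- rbind(train, train[1, ])
  mdup <- calibrate_threshold(occ_spec("knn", k = 3, repetitions = 10),
                              dup, seed = 1)
  mdup$scaling <- model$scaling  # same metric, enlarged neighbour pool
  mdup$state$train <- rbind(Xtr, Xtr[1, , drop = FALSE])
  expect_true(all(predict(mdup, test)$score <= got + 1e-12))
})

test_that("SIMCA distances agree with an independent eigendecomposition", {
  train <- random_table(15, seed = 41)
  model <- calibrate_threshold(occ_spec("simca", n_factors = 3, repetitions = 10),
                               train, seed = 2)
  test <- random_table(8, seed = 42)
  sc <- model$scaling
  Xtr <- autoscale_apply(sc, train)
  Xte <- autoscale_apply(sc, test)
  ev <- eigen(cov(Xtr), symmetric = TRUE)
  V <- ev$vectors[, 1:3]
  ctr <- colMeans(Xtr)
  resid_oracle <- vapply(seq_len(nrow(Xte)), function(i) {
    x <- Xte[i, ] - ctr
    sqrt(sum((x - V %*% crossprod(V, x))^2))
  }, 0)
  Xc <- sweep(Xte, 2, model$state$center)
  got_resid <- sqrt(rowSums((Xc - (Xc %*% model$state$V) %*% t(model$state$V))^2))
  expect_equal(as.numeric(got_resid), resid_oracle, tolerance = 1e-9)
  # the training mean has zero score-space distance for any factor count
  ctr_rec <- as.data.frame(as.list(setNames(sc$center, composition_vars)))
  ctr_rec$sample_id <- "mean"
  Xm <- sweep(autoscale_apply(sc, ctr_rec), 2, model$state$center)
  expect_equal(sum((Xm %*% model$state$V)^2), 0, tolerance = 1e-9)
  # at full rank the residual component of any training record vanishes
  full <- calibrate_threshold(occ_spec("simca", n_factors = 7, repetitions = 10),
                              train, seed = 2)
  Xc7 <- sweep(autoscale_apply(full$scaling, train), 2, full$state$center)
  res7 <- Xc7 - (Xc7 %*% full$state$V) %*% t(full$state$V)
  expect_equal(max(abs(res7)), 0, tolerance = 1e-9)
  expect_error(calibrate_threshold(occ_spec("simca", n_factors = 7),
                                   train[1:6, ], seed = 1), "rank")
})

test_that("one-class SVM: gamma grid, kernel limit, duplication invariance", {
  expect_error(occ_spec("svm", gamma = 0.3), "gamma")
  train <- random_table(15, seed = 51)
  test <- rbind(random_table(10, seed = 52),
                variance_adjust(random_table(10, seed = 53), factor = 6))
  test$sample_id <- paste0("T", seq_len(nrow(test)))
  model <- calibrate_threshold(occ_spec("svm", gamma = 0.1, repetitions = 20),
                               train, seed = 3)
  # gamma -> 0: all pairwise kernel values approach 1 (single global region)
  K <- exp(-1e-9 * as.matrix(dist(autoscale_apply(model$scaling, train)))^2)
  expect_true(all(abs(K - 1) < 1e-6))
  # duplicated training set yields the same classifications
  dup <- rbind(train, train)
  mdup <- calibrate_threshold(occ_spec("svm", gamma = 0.1, repetitions = 20),
                              dup, seed = 3)
  expect_equal(predict(mdup, test)$inside, predict(model, test)$inside)
})

test_that("threshold calibration: coverage, determinism, holdout size, alpha", {
  train <- random_table(15, seed = 61)
  spec <- occ_spec("knn", k = 3, repetitions = 100)
  m1 <- calibrate_threshold(spec, train, seed = 9)
  m2 <- calibrate_threshold(spec, train, seed = 9)
  expect_identical(m1$threshold, m2$threshold)
  # >= 99% of pooled CV scores fall within the threshold by construction
  expect_gte(mean(m1$cv_scores <= m1$threshold), 0.99)
  expect_gte(m1$cv_accuracy, 99)
  # leave-30%-out of 15 holds out 5 (round-half-up), pooling 5 x reps scores
  expect_equal(length(m1$cv_scores), 5L * 100L)
  # smaller alpha gives a larger (more permissive) threshold
  m_strict <- calibrate_threshold(occ_spec("knn", k = 3, alpha = 0.10,
                                           repetitions = 100), train, seed = 9)
  expect_gte(m1$threshold, m_strict$threshold)
  expect_error(calibrate_threshold(spec, train[1:3, ], seed = 1), "at least 5")
})

test_that("classification is invariant to row and feature order", {
  train <- random_table(15, seed = 71)
  test <- random_table(10, seed = 72)
  perm_rows <- train[withr::with_seed(1, sample(nrow(train))), ]
  perm_cols <- test[, rev(names(test))]
  for (kind in c("knn", "simca")) {
    spec <- occ_spec(kind, repetitions = 10)
    base <- calibrate_threshold(spec, train, seed = 4)
    rows <- calibrate_threshold(spec, perm_rows, seed = 4)
    expect_equal(predict(rows, test)$score, predict(base, test)$score,
                 tolerance = 1e-9)
    expect_equal(predict(base, perm_cols)$score, predict(base, test)$score,
                 tolerance = 1e-9)
  }
})

test_that("model evaluation and selection follow the overall-performance rule", {
  train <- random_table(15, seed = 81)
  model <- calibrate_threshold(occ_spec("knn", k = 3, repetitions = 20),
                               train, seed = 5)
  # training vectors scored by their own model sit deep inside the class
  expect_gte(evaluate_occ(model, train)$pct_inside, 99)
  copies <- train[rep(1:15, 2), ]
  expect_equal(evaluate_occ(model, copies)$pct_inside, 100)
  expect_error(predict(model, train[0, ]), "empty")

  grid <- data.frame(kind = "knn", param = c(2, 3), cv_pct = c(92, 90),
                     adulterant_pct = c(77, 79))
  sel <- select_model(grid)
  expect_equal(sel$overall, 84.5)  # mean of CV and adulterant percentages
  expect_equal(sel$param, 2)       # tie on overall broken by smaller k
  single <- select_model(grid[2, ])
  expect_equal(single$param, 3)
  expect_error(select_model(grid[0, ]), "empty")
})

test_that("fitted models serialize to JSON with spec, scaling and threshold", {
  train <- random_table(15, seed = 91)
  model <- calibrate_threshold(occ_spec("simca", n_factors = 2, repetitions = 10),
                               train, seed = 6)
  js <- jsonlite::fromJSON(occ_to_json(model))
  expect_equal(js$spec$kind, "simca")
  expect_equal(js$threshold, model$threshold)
  expect_equal(unname(unlist(js$scaling$center)),
               unname(model$scaling$center))
})
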