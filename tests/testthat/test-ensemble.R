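# Small sub-dataset fixture with a clean motif/background separation.
make_sub <- function(n = 20, separation = 1, seed = 1) {
  list(positives = gen_motif_positives(n, motif_model(strength = separation),
                                       seed = seed),
       negatives = gen_background_peptides(n, seed = seed + 500))
}

test_that("grid search selects by CV accuracy with deterministic tie-breaks", {
  set.seed(71)
  X <- rbind(matrix(rnorm(40, mean = 0), ncol = 2),
             matrix(rnorm(40, mean = 4), ncol = 2))
  y <- rep(c(0, 1), each = 20)
  # grid of one
  one <- grid_search_rbf(X, y, c_grid = 2, gamma_grid = 0.25, seed = 1)
  expect_equal(c(one$c, one$gamma), c(2, 0.25))
  # well-separated blobs reach perfect CV accuracy
  best <- grid_search_rbf(X, y, c_grid = c(1, 4), gamma_grid = c(0.1, 0.5),
                          seed = 1)
  expect_equal(best$accuracy, 1.0)
  # all four pairs are perfect here, so the tie rule picks the candidate
  # nearest the default operating point (cost 1, gamma 1/n_features = 0.5)
  expect_equal(c(best$c, best$gamma), c(1, 0.5))
  expect_error(grid_search_rbf(X, rep(0, 40)), "both classes")
})

test_that("submodel training learns a separable motif and is deterministic", {
  sub <- make_sub(n = 20)
  sm <- train_submodel(sub, n_features = 60, seed = 1,
                       c_grid = SMALL_C_GRID, gamma_grid = SMALL_GAMMA_GRID)
  expect_s3_class(sm, "ngpd_submodel")
  expect_length(sm$selected_features, 60)
  expect_gte(sm$cv_metrics[["Acc"]], 0.9)
  sm2 <- train_submodel(sub, n_features = 60, seed = 1,
                        c_grid = SMALL_C_GRID, gamma_grid = SMALL_GAMMA_GRID)
  expect_identical(sm$hyperparams, sm2$hyperparams)
  expect_identical(sm$cv_metrics, sm2$cv_metrics)
})

test_that("shuffled labels give chance-level cross-validated AUROC", {
  sub <- make_sub(n = 40, seed = 3)
  pool <- c(sub$positives, sub$negatives)
  shuffled <- withr::with_seed(9, sample(pool))
  null_sub <- list(positives = shuffled[1:40], negatives = shuffled[41:80])
  sm <- train_submodel(null_sub, n_features = 60, seed = 1,
                       c_grid = SMALL_C_GRID, gamma_grid = SMALL_GAMMA_GRID)
  expect_gte(sm$cv_metrics[["AUROC"]], 0.3)
  expect_lte(sm$cv_metrics[["AUROC"]], 0.7)
})

test_that("the ensemble trains one submodel per sub-dataset", {
  subs <- lapply(1:3, function(i) make_sub(n = 15, seed = i))
  ens <- train_ensemble(subs, seed = 1, n_features = 50,
                        c_grid = SMALL_C_GRID,
                        gamma_grid = SMALL_GAMMA_GRID)
  expect_length(ens$submodels, 3)
  expect_error(train_ensemble(list()), "at least one")

  # a one-submodel ensemble returns that submodel's probability
  ens1 <- train_ensemble(subs[1], seed = 1, n_features = 50,
                         c_grid = SMALL_C_GRID,
                         gamma_grid = SMALL_GAMMA_GRID)
  query <- gen_background_peptides(5, seed = 99)
  pred <- predict(ens1, query)
  sm <- ens1$submodels[[1]]
  X <- encode_peptides(query)
  Xs <- minmax_apply(sm$scaler, X[, sm$selected_features, drop = FALSE])
  direct <- attr(predict(sm$svm, Xs, probability = TRUE),
                 "probabilities")[, "1"]
  expect_equal(pred$prob, unname(direct), tolerance = 1e-12)
})

test_that("averaging voting obeys the >= tp decision rule and bounds", {
  subs <- lapply(1:3, function(i) make_sub(n = 15, seed = i + 10))
  ens <- train_ensemble(subs, seed = 2, n_features = 50,
                        c_grid = SMALL_C_GRID,
                        gamma_grid = SMALL_GAMMA_GRID)
  query <- c(gen_motif_positives(10, motif_model(), seed = 7),
             gen_background_peptides(10, seed = 8))
  pred <- predict(ens, query, tp = 0.5, verbose_probs = TRUE)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  P <- as.matrix(pred[, grepl("^prob_sub", names(pred))])
  expect_equal(pred$prob, unname(rowMeans(P)), tolerance = 1e-12)
  expect_equal(pred$votes, unname(as.integer(rowSums(P >= 0.5))))
  expect_equal(pred$label, ifelse(pred$prob >= 0.5, "binder", "non-binder"))
  # boundary thresholds
  p1 <- predict(ens, query, tp = 1.0)
  expect_true(all(p1$label[p1$prob < 1] == "non-binder"))
  p0 <- predict(ens, query, tp = 0.0)
  expect_true(all(p0$label == "binder"))  # prob >= 0 always
  expect_error(predict(ens, query, tp = 1.5), "tp")
})

test_that("raising tp never increases the number of predicted binders", {
  subs <- lapply(1:2, function(i) make_sub(n = 15, seed = i + 20))
  ens <- train_ensemble(subs, seed = 3, n_features = 50,
                        c_grid = SMALL_C_GRID,
                        gamma_grid = SMALL_GAMMA_GRID)
  query <- c(gen_motif_positives(15, motif_model(strength = 0.6), seed = 30),
             gen_background_peptides(15, seed = 31))
  counts <- vapply(seq(0, 1, by = 0.05), function(tp) {
    sum(predict(ens, query, tp = tp)$label == "binder")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("model archives round-trip and reject foreign files", {
  subs <- list(make_sub(n = 12, seed = 41))
  ens <- train_ensemble(subs, seed = 4, n_features = 30,
                        c_grid = SMALL_C_GRID,
                        gamma_grid = SMALL_GAMMA_GRID)
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(ens, path)
  back <- load_ensemble(path)
  query <- gen_background_peptides(5, seed = 42)
  expect_equal(predict(back, query), predict(ens, query))

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_ensemble(bad), "not a compatible")

  rep <- cv_report(ens)
  expect_equal(rownames(rep), c("submodel_1", "mean", "sd"))
  expect_true(all(rep["mean", ] >= 0))
})
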