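test_that("training records the scheduled loss switch in its history", {
  fx <- tiny_trained_model()
  h <- fx$model$history
  expect_equal(nrow(h), 15)
  expect_identical(h$active_cla_loss, c(rep("cross_entropy", 5),
                                        rep("focal", 10)))
  expect_true(all(is.finite(h$total)))
  expect_true(all(h$l_mse >= 0 & h$l_con >= 0 & h$l_cla >= 0))
})

test_that("disabling the contrastive term zeroes l_con throughout", {
  fx <- tiny_trained_model()
  tc <- train_config(learning_rate = 3e-3, batch_size = 32, epochs = 2,
                     switch_epoch = 1, seed = 11, use_scl = FALSE)
  m <- ddi_train(fx$prof, fx$syn$ddis$records, tc, fx$netcfg, n_classes = 3)
  expect_true(all(m$history$l_con == 0))
})

test_that("training is reproducible from the seed", {
  fx <- tiny_trained_model()
  tc <- train_config(learning_rate = 3e-3, batch_size = 32, epochs = 2,
                     switch_epoch = 1, seed = 99)
  m1 <- ddi_train(fx$prof, fx$syn$ddis$records, tc, fx$netcfg, n_classes = 3)
  m2 <- ddi_train(fx$prof, fx$syn$ddis$records, tc, fx$netcfg, n_classes = 3)
  expect_equal(m1$history$total, m2$history$total, tolerance = 1e-12)
  expect_identical(m1$net$params, m2$net$params)
})

test_that("prediction is a proper, deterministic probability matrix", {
  fx <- tiny_trained_model()
  pairs <- fx$syn$ddis$records[1:10, ]
  p1 <- ddi_predict(fx$model, fx$prof, pairs)
  expect_equal(dim(p1), c(10, 3))
  expect_equal(rowSums(p1), rep(1, 10), tolerance = 1e-6)
  expect_identical(p1, ddi_predict(fx$model, fx$prof, pairs))
})

test_that("unknown drugs in prediction raise a missing-drug error", {
  fx <- tiny_trained_model()
  err <- tryCatch(
    ddi_predict(fx$model, fx$prof,
                data.frame(drugA = "nosuchdrug", drugB = "drug001")),
    condition = identity)
  expect_s3_class(err, "ddiscl_invalid_input")
  expect_match(conditionMessage(err), "nosuchdrug")
})

test_that("symmetrized models predict identically for both pair orders", {
  fx <- tiny_trained_model()
  nc <- network_config(ncol(fx$prof$matrix), 3, n_tokens = 4, h1 = 32,
                       h2 = 16, dropout_rate = 0.1, symmetrize_pairs = TRUE,
                       seed = 11)
  tc <- train_config(learning_rate = 3e-3, batch_size = 32, epochs = 2,
                     switch_epoch = 1, seed = 11)
  m <- ddi_train(fx$prof, fx$syn$ddis$records, tc, nc, n_classes = 3)
  pr <- fx$syn$ddis$records[1:5, ]
  fwd <- ddi_predict(m, fx$prof, pr)
  rev <- ddi_predict(m, fx$prof,
                     data.frame(drugA = pr$drugB, drugB = pr$drugA))
  expect_equal(fwd, rev, tolerance = 1e-12)
})

test_that("empty training sets are rejected", {
  fx <- tiny_trained_model()
  expect_error(ddi_train(fx$prof, fx$syn$ddis$records[0, ],
                         train_config(), fx$netcfg),
               class = "ddiscl_invalid_input")
})

test_that("a trained model learns the planted tiny problem", {
  fx <- tiny_trained_model()
  prob <- ddi_predict(fx$model, fx$prof, fx$syn$ddis$records)
  acc <- mean(max.col(prob) == fx$syn$ddis$records$label)
  expect_gt(acc, 0.8)
})

test_that("model checkpoints round-trip through JSON", {
  fx <- tiny_trained_model()
  path <- tempfile(fileext = ".json")
  write_model(fx$model, path)
  m2 <- read_model(path)
  pairs <- fx$syn$ddis$records[1:8, ]
  expect_equal(ddi_predict(m2, fx$prof, pairs),
               ddi_predict(fx$model, fx$prof, pairs), tolerance = 1e-12)
  expect_identical(m2$feature_types, fx$model$feature_types)
})

test_that("class_similarity_gap separates a labelled mixture", {
  set.seed(31)
  z <- rbind(matrix(rnorm(20 * 4, mean = 3), 20),
             matrix(rnorm(20 * 4, mean = -3), 20))
  y <- rep(1:2, each = 20)
  g <- class_similarity_gap(z, y)
  expect_gt(g$intra, g$inter)
  expect_equal(g$gap, g$intra - g$inter)
})
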