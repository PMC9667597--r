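make_ds <- function(n_drugs = 20, n_pairs = 80, n_classes = 4, seed = 1) {
  set.seed(seed)
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  all_pairs <- t(combn(drugs, 2))
  sel <- sample(nrow(all_pairs), n_pairs)
  ddi_dataset(data.frame(drugA = all_pairs[sel, 1],
                         drugB = all_pairs[sel, 2],
                         label = sample(n_classes, n_pairs, replace = TRUE)),
              n_classes = n_classes)
}

test_that("ddi_dataset validates pairs and re-indexes labels", {
  expect_error(ddi_dataset(data.frame(drugA = "a", drugB = "a", label = 1)),
               class = "ddiscl_invalid_input")
  expect_error(
    ddi_dataset(data.frame(drugA = c("a", "b"), drugB = c("b", "a"),
                           label = c(1, 2))),
    class = "ddiscl_invalid_input")
  ds <- ddi_dataset(data.frame(drugA = c("a", "b"), drugB = c("b", "c"),
                               label = c("increase", "decrease")))
  expect_identical(ds$records$label, c(2L, 1L))   # sorted level order
  expect_identical(ds$label_levels, c("decrease", "increase"))
})

test_that("Task1 folds partition the records, stratified by class", {
  ds <- make_ds(n_pairs = 100)
  plan <- split_task1(ds, seed = 3)
  test_idx <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_identical(test_idx, seq_len(100))         # exact partition
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_identical(sort(c(f$train, f$test)), seq_len(100))
    expect_true(abs(length(f$test) - 20) <= 1)
  }
  # a class with support >= 5 appears in every test fold
  counts <- table(ds$records$label)
  big <- as.integer(names(counts)[counts >= 5][1])
  in_folds <- vapply(plan$folds, function(f)
    any(ds$records$label[f$test] == big), logical(1))
  expect_true(all(in_folds))
})

test_that("cold-start folds respect the held-out drug contracts", {
  ds <- make_ds(n_drugs = 25, n_pairs = 120)
  p2 <- split_task2(ds, seed = 5)
  p3 <- split_task3(ds, seed = 5)
  for (k in 1:5) {
    f2 <- p2$folds[[k]]; f3 <- p3$folds[[k]]
    held <- f2$held_out_drugs
    expect_identical(held, f3$held_out_drugs)      # same drug partition
    n_held <- function(idx) (ds$records$drugA[idx] %in% held) +
      (ds$records$drugB[idx] %in% held)
    expect_true(all(n_held(f2$test) == 1))
    expect_true(all(n_held(f3$test) == 2))
    expect_true(all(n_held(f2$train) == 0))
    expect_true(all(n_held(f3$train) == 0))
    expect_length(intersect(f2$test, f3$test), 0)  # exactly-one vs both
    expect_lt(length(f2$train) + length(f2$test), nrow(ds$records) + 1)
  }
})

test_that("splits regenerate bit-identically from the seed", {
  ds <- make_ds()
  for (fn in list(split_task1, split_task2, split_task3)) {
    expect_identical(fn(ds, seed = 9), fn(ds, seed = 9))
    expect_false(identical(fn(ds, seed = 9), fn(ds, seed = 10)))
  }
})

test_that("split plans survive a JSON round trip", {
  ds <- make_ds()
  plan <- split_task2(ds, seed = 2)
  path <- tempfile(fileext = ".json")
  write_split_plan(plan, path)
  expect_identical(read_split_plan(path), plan)
})

test_that("perfect predictions score 1 on all six metrics", {
  set.seed(11)
  y <- sample(3, 30, replace = TRUE)
  prob <- matrix(1e-9, 30, 3)
  prob[cbind(1:30, y)] <- 1
  prob <- prob / rowSums(prob)
  rep <- compute_metrics(y, prob)
  for (m in c("acc", "aupr", "auc", "f1", "precision", "recall")) {
    expect_equal(rep[[m]], 1, tolerance = 1e-9, label = m)
  }
})

test_that("argmax accuracy counts agreement directly", {
  prob <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.3, 0.7))
  rep <- compute_metrics(c(1, 1, 2), prob)
  expect_equal(rep$acc, 2 / 3)
})

test_that("uninformative predictions give chance-level AUC", {
  set.seed(12)
  n <- 2000
  y <- sample(2, n, replace = TRUE)
  prob <- matrix(runif(n), n, 1)
  prob <- cbind(prob, 1 - prob)
  rep <- compute_metrics(y, prob)
  expect_equal(rep$auc, 0.5, tolerance = 0.05)
})

test_that("macro-F1 is invariant to class relabeling", {
  set.seed(13)
  y <- sample(4, 60, replace = TRUE)
  prob <- matrix(runif(60 * 4), 60)
  prob <- prob / rowSums(prob)
  r1 <- compute_metrics(y, prob)
  perm <- c(3, 1, 4, 2)
  r2 <- compute_metrics(perm[y], prob[, order(perm)])
  expect_equal(r2$f1, r1$f1, tolerance = 1e-12)
})

test_that("metric input validation", {
  expect_error(compute_metrics(c(1, 3), rbind(c(0.5, 0.5), c(0.5, 0.5))),
               class = "ddiscl_invalid_input")
  expect_error(compute_metrics(c(1, 2), rbind(c(0.9, 0.4), c(0.5, 0.5))),
               class = "ddiscl_invalid_input")
})
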