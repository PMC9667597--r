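# Cross-validation schemes for the three prediction settings and the
# six-metric evaluation report.
#
# Task1: 5-CV over interaction records (both drugs of a test pair may be
#        known from training).
# Task2: 5-CV over drugs; test pairs have exactly one held-out drug
#        (cold-start for one drug), train pairs touch no held-out drug.
# Task3: as Task2 but test pairs have both drugs held out.

#' Construct a DDI dataset
#'
#' @param records data.frame with columns `drugA`, `drugB` (character ids)
#'   and `label` (integer in 1..n_classes, or factor/character which is
#'   re-indexed).
#' @param n_classes number of interaction types; defaults to the number of
#'   observed label levels.
#' @param drug_universe optional character vector of all drug ids; defaults
#'   to the drugs occurring in `records`.
#' @return An object of class `ddi_dataset` with integer labels in
#'   1..n_classes and a `label_levels` mapping back to the original labels.
#' @export
ddi_dataset <- function(records, n_classes = NULL, drug_universe = NULL) {
  req <- c("drugA", "drugB", "label")
  if (!all(req %in% names(records))) {
    stop_invalid("records must have columns drugA, drugB, label")
  }
  records <- as.data.frame(records)[req]
  records$drugA <- as.character(records$drugA)
  records$drugB <- as.character(records$drugB)
  if (any(records$drugA == records$drugB)) {
    stop_invalid("self-pairs (A, A) are not valid DDI records")
  }
  if (is.numeric(records$label)) {
    labels <- as.integer(records$label)
    label_levels <- as.character(sort(unique(labels)))
    if (is.null(n_classes)) n_classes <- max(labels)
    if (any(labels < 1L | labels > n_classes)) {
      stop_invalid("integer labels must lie in 1..n_classes")
    }
  } else {
    f <- factor(as.character(records$label))
    label_levels <- levels(f)
    labels <- as.integer(f)
    if (is.null(n_classes)) n_classes <- nlevels(f)
  }
  records$label <- labels
  key <- pair_key(records$drugA, records$drugB)
  if (anyDuplicated(key)) {
    stop_invalid("duplicate unordered drug pairs: ",
                 paste(utils::head(unique(key[duplicated(key)]), 3),
                       collapse = ", "))
  }
  if (is.null(drug_universe)) {
    drug_universe <- sort(unique(c(records$drugA, records$drugB)))
  } else {
    drug_universe <- sort(unique(as.character(drug_universe)))
    miss <- setdiff(unique(c(records$drugA, records$drugB)), drug_universe)
    if (length(miss)) {
      stop_invalid("record drugs missing from drug_universe: ",
                   paste(utils::head(miss, 5), collapse = ", "))
    }
  }
  structure(list(records = records, n_classes = as.integer(n_classes),
                 drug_universe = drug_universe, label_levels = label_levels),
            class = "ddi_dataset")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' @export
print.ddi_dataset <- function(x, ...) {
  cat("<ddi_dataset> ", nrow(x$records), " pairs, ",
      length(x$drug_universe), " drugs, ", x$n_classes, " classes\n", sep = "")
  invisible(x)
}

# seed-scoped RNG that restores the caller's stream
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

new_split_plan <- function(task, folds, seed) {
  structure(list(task = task, folds = folds, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> Task", x$task, ", ", length(x$folds),
      " folds (seed ", x$seed, ")\n", sep = "")
  for (i in seq_along(x$folds)) {
    f <- x$folds[[i]]
    cat(sprintf("  fold %d: %d train / %d test%s\n", i,
                length(f$train), length(f$test),
                if (!is.null(f$held_out_drugs))
                  paste0(" (", length(f$held_out_drugs), " held-out drugs)")
                else ""))
  }
  invisible(x)
}

#' Five-fold split over interaction records (known drugs)
#'
#' Partitions the records into five folds at random, stratified by class
#' where a class has at least `n_folds` records. Drugs may occur on both
#' sides of the split: this evaluates prediction of unobserved interactions
#' between known drugs.
#'
#' @param ds a [ddi_dataset()].
#' @param seed integer seed; the same seed reproduces the same plan.
#' @param n_folds number of folds (default 5).
#' @return A `split_plan` whose folds carry integer `train` / `test` record
#'   indices.
#' @export
split_task1 <- function(ds, seed = 0, n_folds = 5) {
  n <- nrow(ds$records)
  if (n < n_folds) stop_invalid("need at least ", n_folds, " records, got ", n)
  fold_of <- integer(n)
  with_seed(seed, {
    small <- integer(0)
    for (cl in sort(unique(ds$records$label))) {
      idx <- which(ds$records$label == cl)
      if (length(idx) >= n_folds) {
        idx <- sample(idx)
        fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
      } else {
        small <- c(small, idx)
      }
    }
    if (length(small)) {
      fold_of[sample(small)] <- rep_len(seq_len(n_folds), length(small))
    }
  })
  folds <- lapply(seq_len(n_folds), function(k) {
    list(train = which(fold_of != k), test = which(fold_of == k))
  })
  new_split_plan(1L, folds, seed)
}

drug_folds <- function(ds, seed, n_folds) {
  drugs <- ds$drug_universe
  if (length(drugs) < n_folds) {
    stop_invalid("need at least ", n_folds, " drugs, got ", length(drugs))
  }
  with_seed(seed, {
    shuffled <- sample(drugs)
    split(shuffled, rep_len(seq_len(n_folds), length(shuffled)))
  })
}

split_cold_start <- function(ds, seed, n_folds, n_new) {
  dfolds <- drug_folds(ds, seed, n_folds)
  folds <- lapply(seq_len(n_folds), function(k) {
    held <- dfolds[[k]]
    in_held_a <- ds$records$drugA %in% held
    in_held_b <- ds$records$drugB %in% held
    n_held <- in_held_a + in_held_b
    list(train = which(n_held == 0L), test = which(n_held == n_new),
         held_out_drugs = sort(held))
  })
  folds
}

#' Five-fold cold-start split, one new drug per test pair
#'
#' Drugs (not records) are partitioned into five folds. For each fold, the
#' training set holds the records whose drugs are both training drugs; the
#' test set holds the records with exactly one held-out drug. Records with
#' both drugs held out are excluded from that fold.
#'
#' @inheritParams split_task1
#' @return A `split_plan`; each fold also records `held_out_drugs`.
#' @export
split_task2 <- function(ds, seed = 0, n_folds = 5) {
  new_split_plan(2L, split_cold_start(ds, seed, n_folds, 1L), seed)
}

#' Five-fold cold-start split, both drugs new per test pair
#'
#' As [split_task2()] but the test set holds records whose drugs are both
#' held out; records with exactly one held-out drug are excluded from that
#' fold.
#'
#' @inheritParams split_task1
#' @return A `split_plan`; each fold also records `held_out_drugs`.
#' @export
split_task3 <- function(ds, seed = 0, n_folds = 5) {
  new_split_plan(3L, split_cold_start(ds, seed, n_folds, 2L), seed)
}

#' Write / read a split plan as JSON
#'
#' @param plan a `split_plan`.
#' @param path file path.
#' @return `read_split_plan` returns the `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  folds <- lapply(x$folds, function(f) {
    out <- list(train = as.integer(unlist(f$train)),
                test = as.integer(unlist(f$test)))
    if (!is.null(f$held_out_drugs)) {
      out$held_out_drugs <- as.character(unlist(f$held_out_drugs))
    }
    out
  })
  new_split_plan(as.integer(x$task), folds, as.integer(x$seed))
}
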