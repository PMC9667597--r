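# Jaccard similarity profiles: the model's input representation.
#
# Each drug carries one binary descriptor vector per feature type
# (substructures, targets, enzymes, pathways, ...). Because those vectors are
# high-dimensional and sparse, a drug is represented instead by its Jaccard
# similarity to every drug in the dataset, one n_drugs-wide block per feature
# type, concatenated in a fixed, persisted order.

#' Jaccard similarity of two binary vectors
#'
#' Treats the vectors as indicator sets and returns
#' \eqn{|A \cap B| / (|A| + |B| - |A \cap B|)}.
#'
#' Two all-zero vectors have an undefined (0/0) Jaccard similarity; by
#' convention this returns 0 with a warning, since an empty descriptor set
#' carries no similarity evidence.
#'
#' @param a,b binary (0/1) vectors of equal length.
#' @return A number in \[0, 1\], symmetric in `a` and `b`.
#' @examples
#' jaccard_similarity(c(1, 1, 1, 0), c(0, 1, 1, 1)) # 0.5
#' @export
jaccard_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop_invalid("jaccard_similarity: vectors differ in length (",
                 length(a), " vs ", length(b), ")")
  }
  check_binary(a, "a")
  check_binary(b, "b")
  inter <- sum(a == 1 & b == 1)
  union <- sum(a == 1) + sum(b == 1) - inter
  if (union == 0) {
    warning("jaccard_similarity: both vectors are all-zero; returning 0",
            call. = FALSE)
    return(0)
  }
  inter / union
}

#' Construct a descriptor set
#'
#' Bundles per-drug binary descriptor vectors, one matrix ("block") per
#' feature type, sharing one drug ordering.
#'
#' @param drug_ids character vector of drug identifiers (ordered, unique).
#' @param blocks named list of binary matrices, one per feature type, each
#'   with `length(drug_ids)` rows (drugs) and one column per descriptor.
#' @return An object of class `descriptor_set`.
#' @export
descriptor_set <- function(drug_ids, blocks) {
  drug_ids <- as.character(drug_ids)
  if (length(drug_ids) < 2) {
    stop_invalid("descriptor_set: need at least 2 drugs, got ", length(drug_ids))
  }
  if (anyDuplicated(drug_ids)) {
    stop_invalid("descriptor_set: duplicate drug ids")
  }
  if (!is.list(blocks) || length(blocks) == 0 || is.null(names(blocks)) ||
      any(!nzchar(names(blocks)))) {
    stop_invalid("descriptor_set: blocks must be a non-empty named list")
  }
  blocks <- lapply(blocks, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  for (nm in names(blocks)) {
    m <- blocks[[nm]]
    if (nrow(m) != length(drug_ids)) {
      stop_invalid("descriptor_set: block '", nm, "' has ", nrow(m),
                   " rows but there are ", length(drug_ids), " drugs")
    }
    check_binary(m, paste0("block '", nm, "'"))
    rownames(blocks[[nm]]) <- drug_ids
  }
  structure(list(drug_ids = drug_ids, blocks = blocks),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat("<descriptor_set> ", length(x$drug_ids), " drugs, ",
      length(x$blocks), " feature types\n", sep = "")
  for (nm in names(x$blocks)) {
    cat("  ", nm, ": ", ncol(x$blocks[[nm]]), " descriptors\n", sep = "")
  }
  invisible(x)
}

# All-pairs Jaccard for one binary matrix (rows = drugs). Vectorised:
# intersections via tcrossprod, set sizes via rowSums.
jaccard_matrix <- function(m) {
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, "+") - inter
  j <- inter / union
  j[union == 0] <- 0
  j
}

#' Build Jaccard similarity profiles from a descriptor set
#'
#' For every feature type and drug pair (i, j), computes the Jaccard
#' similarity of the two drugs' descriptor vectors of that type. The profile
#' of a drug is the concatenation of its similarity to all `n` drugs over all
#' `T` feature types, giving a row of width `T * n` — the model input. Blocks
#' keep the feature-type order of the descriptor set, which is persisted with
#' the profile (and any trained model) because the downstream network is
#' order-sensitive.
#'
#' Profiles are computed against every drug in the descriptor table,
#' including drugs that later fall into test folds: the profile width is a
#' property of the dataset, not of a split.
#'
#' @param d a [descriptor_set()].
#' @param include_self include each drug's self-similarity column (the block
#'   diagonal, 1 for any drug with a non-empty descriptor set). Default TRUE;
#'   set FALSE to zero the diagonal instead (profile width is unchanged).
#' @return An object of class `similarity_profile` with elements `drug_ids`,
#'   `matrix` (n x T*n), `feature_types`, and `block_starts` (1-based column
#'   offsets of each feature-type block).
#' @export
build_similarity_profiles <- function(d, include_self = TRUE) {
  if (!inherits(d, "descriptor_set")) {
    stop_invalid("build_similarity_profiles: 'd' must be a descriptor_set")
  }
  n <- length(d$drug_ids)
  types <- names(d$blocks)
  empty <- vapply(d$blocks, function(m) any(rowSums(m) == 0), logical(1))
  if (any(empty)) {
    warning("build_similarity_profiles: all-zero descriptor rows in block(s) ",
            paste(types[empty], collapse = ", "),
            "; their undefined self-similarities are set to 0", call. = FALSE)
  }
  mats <- lapply(d$blocks, function(m) {
    j <- jaccard_matrix(m)
    if (!include_self) diag(j) <- 0
    j
  })
  prof <- do.call(cbind, mats)
  rownames(prof) <- d$drug_ids
  colnames(prof) <- unlist(lapply(types, function(t) paste0(t, ".", d$drug_ids)),
                           use.names = FALSE)
  structure(
    list(drug_ids = d$drug_ids,
         matrix = prof,
         feature_types = types,
         block_starts = setNames(seq(1L, by = n, length.out = length(types)),
                                 types),
         include_self = include_self),
    class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat("<similarity_profile> ", length(x$drug_ids), " drugs x ",
      ncol(x$matrix), " (", length(x$feature_types),
      " feature-type blocks: ", paste(x$feature_types, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# shared validators -----------------------------------------------------------

check_binary <- function(x, what) {
  v <- as.vector(x)
  if (anyNA(v) || !all(v == 0 | v == 1)) {
    stop_invalid("non-binary values in ", what, " (entries must be 0 or 1)")
  }
  invisible(TRUE)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("ddiscl_invalid_input", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("ddiscl_invalid_config", "error")))
}

stop_divergence <- function(...) {
  stop(errorCondition(paste0(...), class = c("ddiscl_divergence", "error")))
}
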