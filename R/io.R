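# CSV readers/writers for descriptors, DDI tables, and similarity profiles,
# plus YAML run-config parsing. CSV (UTF-8, header row) is the canonical
# interchange format; upstream databases are converted to per-feature-type
# CSVs before use (see README).

#' Read drug descriptors from CSV
#'
#' Accepts either one wide CSV per feature type (first column `drug_id`,
#' remaining columns binary descriptor values) or a single long-format CSV
#' with columns `drug_id`, `feature_type`, `descriptor_id` (one row per set
#' bit). Drugs missing from a wide file get an all-zero block for that type,
#' with a warning.
#'
#' @param paths named character vector of wide CSV paths (names = feature
#'   types), or a single unnamed path to a long-format CSV.
#' @return A [descriptor_set()].
#' @export
read_descriptors <- function(paths) {
  if (length(paths) == 1 && is.null(names(paths))) {
    return(read_descriptors_long(paths))
  }
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop_invalid("wide descriptor paths must be named by feature type")
  }
  raw <- lapply(paths, function(p) {
    df <- utils::read.csv(p, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"drug_id" %in% names(df)) {
      stop_invalid("descriptor file ", p, " lacks a drug_id column")
    }
    m <- as.matrix(df[setdiff(names(df), "drug_id")])
    bad <- which(!(m %in% c(0, 1)) | is.na(m))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(m))
      stop_invalid("non-binary value in ", p, " at row ", rc[1] + 1L,
                   ", column '", colnames(m)[rc[2]], "'")
    }
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df$drug_id)
    m
  })
  all_ids <- sort(unique(unlist(lapply(raw, rownames))))
  shared <- Reduce(intersect, lapply(raw, rownames))
  if (length(shared) == 0) {
    stop_invalid("no drug ids shared across the descriptor files")
  }
  blocks <- lapply(names(raw), function(t) {
    m <- raw[[t]]
    missing <- setdiff(all_ids, rownames(m))
    if (length(missing)) {
      warning("drugs without '", t, "' descriptors get all-zero blocks: ",
              paste(utils::head(missing, 5), collapse = ", "),
              if (length(missing) > 5) ", ...", call. = FALSE)
      m <- rbind(m, matrix(0, length(missing), ncol(m),
                           dimnames = list(missing, colnames(m))))
    }
    m[all_ids, , drop = FALSE]
  })
  names(blocks) <- names(raw)
  descriptor_set(all_ids, blocks)
}

read_descriptors_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("drug_id", "feature_type", "descriptor_id")
  if (!all(req %in% names(df))) {
    stop_invalid("long-format descriptor file needs columns ",
                 paste(req, collapse = ", "))
  }
  ids <- sort(unique(as.character(df$drug_id)))
  blocks <- lapply(split(df, df$feature_type), function(d) {
    desc <- sort(unique(as.character(d$descriptor_id)))
    m <- matrix(0, length(ids), length(desc), dimnames = list(ids, desc))
    m[cbind(match(as.character(d$drug_id), ids),
            match(as.character(d$descriptor_id), desc))] <- 1
    m
  })
  descriptor_set(ids, blocks)
}

#' Write a descriptor set as one wide CSV per feature type
#'
#' @param d a [descriptor_set()].
#' @param dir output directory; files are named `descriptors_<type>.csv`.
#' @return Named vector of written paths (readable by [read_descriptors()]).
#' @export
write_descriptors <- function(d, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(d$blocks), function(t) {
    p <- file.path(dir, paste0("descriptors_", t, ".csv"))
    df <- data.frame(drug_id = d$drug_ids, d$blocks[[t]],
                     check.names = FALSE)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }, character(1))
  paths
}

#' Read a DDI table from CSV
#'
#' Expects columns `drugA`, `drugB`, `label`. Labels may be arbitrary
#' strings; they are re-indexed to contiguous integers (sorted order) and
#' the mapping is kept in the returned dataset (`label_levels`). Duplicate
#' unordered pairs and self-pairs are rejected.
#'
#' @param path CSV path.
#' @param n_classes optional total class count (>= observed levels).
#' @return A [ddi_dataset()].
#' @export
read_ddis <- function(path, n_classes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("drugA", "drugB", "label") %in% names(df))) {
    stop_invalid("DDI file ", path, " needs columns drugA, drugB, label")
  }
  key <- pair_key(as.character(df$drugA), as.character(df$drugB))
  dup <- duplicated(key)
  if (any(dup)) {
    stop_invalid("duplicate unordered pair(s) in ", path, ": ",
                 paste(utils::head(gsub("\r", "/", key[dup]), 3),
                       collapse = ", "))
  }
  ddi_dataset(df, n_classes = n_classes)
}

#' Write a DDI dataset to CSV (original label strings restored)
#'
#' @param ds a [ddi_dataset()].
#' @param path CSV path.
#' @export
write_ddis <- function(ds, path) {
  df <- ds$records
  df$label <- ds$label_levels[df$label]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a similarity-profile matrix
#'
#' The matrix goes to CSV (drug_id index column); a JSON sidecar
#' (`<path>.meta.json`) records the feature-type order and block boundaries
#' so the profile reconstructs exactly.
#'
#' @param sp a [build_similarity_profiles()] result.
#' @param path CSV path.
#' @return `read_profiles` returns the `similarity_profile`.
#' @export
write_profiles <- function(sp, path) {
  df <- data.frame(drug_id = sp$drug_ids, sp$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(feature_types = sp$feature_types,
         block_starts = as.list(sp$block_starts),
         include_self = sp$include_self),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  m <- as.matrix(df[setdiff(names(df), "drug_id")])
  rownames(m) <- as.character(df$drug_id)
  structure(list(drug_ids = as.character(df$drug_id), matrix = m,
                 feature_types = as.character(meta$feature_types),
                 block_starts = setNames(as.integer(unlist(meta$block_starts)),
                                         names(meta$block_starts)),
                 include_self = isTRUE(meta$include_self)),
            class = "similarity_profile")
}

#' Read a YAML run configuration
#'
#' Recognised top-level sections: `train` (fields of [train_config()]),
#' `network` (fields of [network_config()]), `synthetic` (fields of
#' [synth_config()]); unknown fields raise an error.
#'
#' @param path YAML file path.
#' @return List with `train`, `network` (NULL if the network section is
#'   absent, since `fea_dim` may only be known after profiles are built),
#'   `network_args`, and `synthetic`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  apply_section <- function(fn, args, what) {
    if (is.null(args)) return(NULL)
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) {
      stop_invalid("unknown ", what, " config field(s): ",
                   paste(bad, collapse = ", "))
    }
    do.call(fn, args)
  }
  list(train = apply_section(train_config, y$train, "train"),
       network = if (!is.null(y$network) && !is.null(y$network$fea_dim)) {
         apply_section(network_config, y$network, "network")
       } else NULL,
       network_args = y$network,
       synthetic = apply_section(synth_config, y$synthetic, "synthetic"))
}
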