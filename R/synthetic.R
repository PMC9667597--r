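# Synthetic descriptor sets and DDI tables with planted, recoverable class
# structure.
#
# Drugs belong to latent archetypes; each archetype has one template bit
# pattern per feature type and drug bits are the template XOR sparse noise.
# Every unordered archetype pair is deterministically keyed to one
# interaction class, so class identity is recoverable from descriptors alone
# (through the Jaccard-profile pathway, not memorization). Class sizes follow
# a power law to emulate the heavy imbalance of curated DDI tables.

#' Synthetic dataset configuration
#'
#' @param n_drugs number of drugs.
#' @param n_feature_types number of descriptor feature types.
#' @param descriptors_per_type descriptor count per feature type.
#' @param bit_density probability a template bit is set.
#' @param bit_noise per-bit XOR flip probability applied to each drug's copy
#'   of its archetype template.
#' @param n_classes number of interaction classes (>= 2).
#' @param n_archetypes number of latent drug groups; archetype pairs key the
#'   classes, so `n_archetypes * (n_archetypes + 1) / 2 >= n_classes` must
#'   hold.
#' @param pair_coverage fraction of all unordered drug pairs that receive a
#'   label.
#' @param imbalance_exponent power-law exponent for class sizes (class k
#'   gets mass proportional to `k^-imbalance_exponent`); 0 = balanced.
#' @param label_noise probability a pair's label is replaced by a uniformly
#'   random other class.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 60, n_feature_types = 4,
                         descriptors_per_type = 64, bit_density = 0.1,
                         bit_noise = 0.02, n_classes = 6, n_archetypes = NULL,
                         pair_coverage = 0.5, imbalance_exponent = 1,
                         label_noise = 0, seed = 0) {
  if (n_classes < 2) stop_invalid("n_classes must be >= 2")
  if (is.null(n_archetypes)) {
    n_archetypes <- ceiling((sqrt(8 * n_classes + 1) - 1) / 2) + 2
  }
  if (n_archetypes > n_drugs) stop_invalid("n_archetypes must be <= n_drugs")
  if (n_archetypes * (n_archetypes + 1) / 2 < n_classes) {
    stop_invalid("infeasible config: ", n_classes, " classes but only ",
                 n_archetypes * (n_archetypes + 1) / 2, " archetype pairs")
  }
  if (pair_coverage <= 0 || pair_coverage > 1) {
    stop_invalid("pair_coverage must be in (0, 1]")
  }
  if (bit_density <= 0 || bit_density >= 1) {
    stop_invalid("bit_density must be in (0, 1)")
  }
  if (label_noise < 0 || label_noise >= 1) {
    stop_invalid("label_noise must be in [0, 1)")
  }
  if (imbalance_exponent < 0) stop_invalid("imbalance_exponent must be >= 0")
  structure(list(n_drugs = as.integer(n_drugs),
                 n_feature_types = as.integer(n_feature_types),
                 descriptors_per_type = as.integer(descriptors_per_type),
                 bit_density = bit_density, bit_noise = bit_noise,
                 n_classes = as.integer(n_classes),
                 n_archetypes = as.integer(n_archetypes),
                 pair_coverage = pair_coverage,
                 imbalance_exponent = imbalance_exponent,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic descriptor set and DDI table
#'
#' @param cfg a [synth_config()].
#' @return A list with `descriptors` (a [descriptor_set()]), `ddis` (a
#'   [ddi_dataset()]), and `ground_truth` (archetype assignment, per-type
#'   templates, the archetype-pair to class map, and the pre-noise labels).
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    drug_ids <- sprintf("drug%03d", seq_len(cfg$n_drugs))
    m <- cfg$n_archetypes
    archetype <- rep_len(seq_len(m), cfg$n_drugs)[sample(cfg$n_drugs)]
    templates <- lapply(seq_len(cfg$n_feature_types), function(t) {
      matrix(as.numeric(stats::runif(m * cfg$descriptors_per_type) <
                          cfg$bit_density), m, cfg$descriptors_per_type)
    })
    names(templates) <- default_feature_types(cfg$n_feature_types)
    blocks <- lapply(templates, function(tm) {
      bits <- tm[archetype, , drop = FALSE]
      flips <- matrix(stats::runif(length(bits)) < cfg$bit_noise,
                      nrow(bits), ncol(bits))
      out <- abs(bits - as.numeric(flips))
      # guarantee non-empty descriptor sets so Jaccard is defined
      zero <- rowSums(out) == 0
      if (any(zero)) out[cbind(which(zero), sample(ncol(out), sum(zero),
                                                   replace = TRUE))] <- 1
      rownames(out) <- drug_ids
      out
    })
    descr <- descriptor_set(drug_ids, blocks)

    # class demands from the power law
    n_pairs_total <- choose(cfg$n_drugs, 2)
    n_target <- round(cfg$pair_coverage * n_pairs_total)
    shares <- seq_len(cfg$n_classes)^(-cfg$imbalance_exponent)
    shares <- shares / sum(shares)
    demand <- pmax(1L, round(shares * n_target))

    # archetype-pair combos and capacities
    combos <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
    combos <- combos[order(combos[, 1], combos[, 2]), , drop = FALSE]
    size_a <- tabulate(archetype, m)
    cap <- ifelse(combos[, 1] == combos[, 2],
                  choose(size_a[combos[, 1]], 2),
                  size_a[combos[, 1]] * size_a[combos[, 2]])
    # greedy: hand the largest-capacity combo to the class with the largest
    # unmet demand until all combos are assigned a class
    combo_class <- integer(nrow(combos))
    unmet <- as.numeric(demand)
    for (ci in order(cap, decreasing = TRUE)) {
      cl <- which.max(unmet)
      combo_class[ci] <- cl
      unmet[cl] <- unmet[cl] - cap[ci]
    }

    # sample pairs per class from its combos' pair pools
    drugs_by_arch <- split(seq_len(cfg$n_drugs), archetype)
    recA <- character(0); recB <- character(0); recY <- integer(0)
    for (cl in seq_len(cfg$n_classes)) {
      pool_a <- integer(0); pool_b <- integer(0)
      for (ci in which(combo_class == cl)) {
        a <- combos[ci, 1]; b <- combos[ci, 2]
        if (a == b) {
          ds <- drugs_by_arch[[as.character(a)]]
          if (length(ds) >= 2) {
            cmb <- utils::combn(ds, 2)
            pool_a <- c(pool_a, cmb[1, ]); pool_b <- c(pool_b, cmb[2, ])
          }
        } else {
          g <- expand.grid(drugs_by_arch[[as.character(a)]],
                           drugs_by_arch[[as.character(b)]])
          pool_a <- c(pool_a, g[, 1]); pool_b <- c(pool_b, g[, 2])
        }
      }
      take <- min(demand[cl], length(pool_a))
      if (take > 0) {
        sel <- sample.int(length(pool_a), take)
        recA <- c(recA, drug_ids[pool_a[sel]])
        recB <- c(recB, drug_ids[pool_b[sel]])
        recY <- c(recY, rep(cl, take))
      }
    }
    true_y <- recY
    if (cfg$label_noise > 0 && cfg$n_classes > 1) {
      flip <- stats::runif(length(recY)) < cfg$label_noise
      if (any(flip)) {
        shift <- sample.int(cfg$n_classes - 1L, sum(flip), replace = TRUE)
        recY[flip] <- 1L + (recY[flip] - 1L + shift) %% cfg$n_classes
      }
    }
    ord <- sample(length(recY))   # shuffle record order
    ddis <- ddi_dataset(data.frame(drugA = recA[ord], drugB = recB[ord],
                                   label = recY[ord],
                                   stringsAsFactors = FALSE),
                        n_classes = cfg$n_classes, drug_universe = drug_ids)
    class_of_combo <- data.frame(arch_a = combos[, 1], arch_b = combos[, 2],
                                 class = combo_class)
    list(descriptors = descr, ddis = ddis,
         ground_truth = list(archetype = setNames(archetype, drug_ids),
                             templates = templates,
                             combo_classes = class_of_combo,
                             true_labels = true_y[ord]))
  })
}

default_feature_types <- function(t) {
  base <- c("substructure", "target", "enzyme", "pathway")
  if (t <= length(base)) base[seq_len(t)] else c(base, paste0("type", seq_len(t - length(base))))
}

#' Dataset-shaped synthetic presets
#'
#' Returns a [synth_config()] whose drug and class counts are those of the
#' reference DDI benchmarks scaled by `scale` (e.g. `scale = 0.1` of the
#' 572-drug / 65-type benchmark gives ~57 drugs and 7 classes). Because pair
#' counts cannot scale linearly with drug counts, the preset preserves the
#' benchmark's pair *coverage* — the fraction of all unordered drug pairs
#' that are labelled (0.456 for dataset1, 0.409 for dataset2) — so that
#' `scale = 1` reproduces the benchmark's pair count. Feature-type counts are
#' the benchmarks' (4 and 3).
#'
#' @param which `"dataset1"` (572 drugs, 74,528 pairs, 65 types, 4 feature
#'   types) or `"dataset2"` (1,258 drugs, 323,539 pairs, 100 types, 3
#'   feature types).
#' @param scale size multiplier in (0, 1].
#' @param seed forwarded to the config.
#' @return A `synth_config`.
#' @export
paper_shaped_preset <- function(which = c("dataset1", "dataset2"), scale = 1,
                                seed = 0) {
  which <- match.arg(which)
  if (scale <= 0 || scale > 1) stop_invalid("scale must be in (0, 1]")
  ref <- switch(which,
    dataset1 = list(drugs = 572, pairs = 74528, classes = 65, types = 4),
    dataset2 = list(drugs = 1258, pairs = 323539, classes = 100, types = 3))
  n_drugs <- max(10L, round(ref$drugs * scale))
  n_classes <- ceiling(ref$classes * scale)
  if (n_classes < 2) stop_invalid("scale ", scale, " yields fewer than 2 classes")
  synth_config(
    n_drugs = n_drugs,
    n_feature_types = ref$types,
    descriptors_per_type = max(32L, round(400 * scale)),
    bit_density = 0.1,
    bit_noise = 0.03,
    n_classes = n_classes,
    pair_coverage = ref$pairs / choose(ref$drugs, 2),
    imbalance_exponent = 1.5,
    label_noise = 0,
    seed = seed)
}

#' Heavily imbalanced synthetic preset
#'
#' A fixture for rare-class experiments: 100 drugs, 18 classes under a
#' power law with exponent 1.5 and coverage 0.45, which leaves the three
#' rarest classes each under 1% of all pairs while still holding enough
#' records (~12) per rare class to measure per-class F1.
#'
#' @param seed forwarded to the config.
#' @return A `synth_config`.
#' @export
imbalanced_preset <- function(seed = 0) {
  synth_config(n_drugs = 100, n_feature_types = 4, descriptors_per_type = 48,
               bit_density = 0.1, bit_noise = 0.03, n_classes = 18,
               pair_coverage = 0.45, imbalance_exponent = 1.5,
               label_noise = 0, seed = seed)
}
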