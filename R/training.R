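# Training loop wiring profiles -> network -> three-level loss, with the
# reference hyper-parameters as defaults, plus prediction and embedding
# extraction for trained models.

#' Training configuration
#'
#' Defaults are the reference settings: learning rate 2e-5, batch size 512,
#' 120 epochs, label smoothing 0.3, temperature 0.05, switch from
#' cross-entropy to focal loss at epoch 40, RAdam. The ablation switches
#' mirror the method's component studies.
#'
#' @param learning_rate RAdam step size.
#' @param batch_size pairs per gradient step; the last batch of an epoch may
#'   be smaller and the contrastive loss uses the actual batch length.
#' @param epochs training epochs.
#' @param smoothing label-smoothing parameter for the cross-entropy phase.
#' @param temperature contrastive temperature.
#' @param switch_epoch first (0-based) epoch using focal loss.
#' @param focal_gamma focal focusing parameter.
#' @param use_scl include the supervised contrastive term.
#' @param use_focal if FALSE, cross-entropy is used for all epochs.
#' @param use_label_smoothing if FALSE, the cross-entropy phase is unsmoothed.
#' @param grad_clip global L2 gradient-norm ceiling per step; gradients with
#'   a larger norm are rescaled to it. Guards the adaptive optimizer against
#'   late-training step spikes when near-convergence gradients have shrunk.
#'   `Inf` disables clipping.
#' @param seed master seed for initialisation, shuffling, and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-5, batch_size = 512, epochs = 120,
                         smoothing = 0.3, temperature = 0.05,
                         switch_epoch = 40, focal_gamma = 2, use_scl = TRUE,
                         use_focal = TRUE, use_label_smoothing = TRUE,
                         grad_clip = 5, seed = 0) {
  if (learning_rate <= 0 || batch_size < 1 || epochs < 1) {
    stop_config("learning_rate, batch_size, epochs must be positive")
  }
  if (switch_epoch > epochs) stop_config("switch_epoch must be <= epochs")
  if (grad_clip <= 0) stop_config("grad_clip must be positive")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), smoothing = smoothing,
                 temperature = temperature,
                 switch_epoch = as.integer(switch_epoch),
                 focal_gamma = focal_gamma, use_scl = use_scl,
                 use_focal = use_focal,
                 use_label_smoothing = use_label_smoothing,
                 grad_clip = grad_clip, seed = as.integer(seed)),
            class = "train_config")
}

clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  flat <- flatten_params(grads)
  nrm <- sqrt(sum(vapply(flat, function(g) sum(g^2), numeric(1))))
  if (nrm <= max_norm) return(grads)
  scale <- max_norm / nrm
  for (grp in names(grads)) {
    for (k in names(grads[[grp]])) {
      grads[[grp]][[k]] <- grads[[grp]][[k]] * scale
    }
  }
  grads
}

#' Compact training preset for small synthetic problems
#'
#' The reference learning rate (2e-5) is calibrated for ~75k training pairs
#' over 120 epochs; a few hundred pairs over 30 epochs yield well under a
#' hundred gradient steps, where such a step size cannot move the weights.
#' This preset keeps the loss structure (smoothing 0.3, temperature 0.05,
#' CE-to-focal switch at one third of training) and adopts a step size and
#' batch size suited to the small regime.
#'
#' @param epochs training epochs (default 30).
#' @param seed master seed.
#' @param ... overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
toy_train_config <- function(epochs = 30, seed = 0, ...) {
  train_config(learning_rate = 5e-3, batch_size = 32, epochs = epochs,
               switch_epoch = max(1L, epochs %/% 3L), seed = seed, ...)
}

#' Compact network preset for small synthetic problems
#'
#' @param fea_dim profile width.
#' @param n_classes number of interaction types.
#' @param n_feature_types tokens for the encoder attention (one per
#'   feature-type block).
#' @param dropout_rate dropout probability (default 0.1, lighter than the
#'   full-scale default because the small regime underfits).
#' @param ... overrides passed to [network_config()].
#' @return A `network_config`.
#' @export
toy_network_config <- function(fea_dim, n_classes, n_feature_types = 4,
                               dropout_rate = 0.1, ...) {
  network_config(fea_dim = fea_dim, n_classes = n_classes,
                 n_tokens = n_feature_types, h1 = 64, h2 = 32,
                 dropout_rate = dropout_rate, ...)
}

# RAdam (rectified Adam) ------------------------------------------------------

radam_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(x) 0 * x),
       v = lapply(flat, function(x) 0 * x), t = 0L)
}

radam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  p <- flatten_params(params)
  g <- flatten_params(grads)
  state$t <- state$t + 1L
  t <- state$t
  rho_inf <- 2 / (1 - beta2) - 1
  rho_t <- rho_inf - 2 * t * beta2^t / (1 - beta2^t)
  for (nm in names(p)) {
    gi <- g[[nm]]
    if (is.null(gi)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gi
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gi^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    if (rho_t > 4) {
      r <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                  ((rho_inf - 4) * (rho_inf - 2) * rho_t))
      vhat <- sqrt(state$v[[nm]] / (1 - beta2^t))
      p[[nm]] <- p[[nm]] - lr * r * mhat / (vhat + eps)
    } else {
      p[[nm]] <- p[[nm]] - lr * mhat
    }
  }
  list(params = unflatten_params(p, params), state = state)
}

flatten_params <- function(params) {
  out <- list()
  for (grp in names(params)) {
    for (k in names(params[[grp]])) {
      out[[paste0(grp, ".", k)]] <- params[[grp]][[k]]
    }
  }
  out
}

unflatten_params <- function(flat, template) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    template[[parts[1]]][[parts[2]]] <- flat[[nm]]
  }
  template
}

# -----------------------------------------------------------------------------

profile_rows <- function(profiles, ids, what = "pairs") {
  miss <- setdiff(unique(ids), profiles$drug_ids)
  if (length(miss)) {
    stop_invalid("no similarity profile for drug(s) in ", what, ": ",
                 paste(utils::head(miss, 10), collapse = ", "))
  }
  profiles$matrix[ids, , drop = FALSE]
}

#' Train the pair-classification model
#'
#' Runs mini-batch training of the full architecture under the three-level
#' loss: per batch, the reconstruction MSE (averaged over the two drugs of
#' each pair), the supervised contrastive loss over the batch CFVs (if
#' `use_scl`), and the scheduled classification loss; their unweighted sum is
#' backpropagated through the whole network with RAdam. All randomness
#' (shuffling, initialisation, dropout) flows from `cfg$seed`.
#'
#' @param profiles a [build_similarity_profiles()] result covering every
#'   drug referenced by `records`.
#' @param records data.frame of training pairs with columns `drugA`,
#'   `drugB`, `label` (integer in 1..n_classes).
#' @param cfg a [train_config()].
#' @param netcfg a [network_config()]; by default a configuration derived
#'   from the profile width and the label range.
#' @param n_classes number of classes; defaults to `max(records$label)`.
#' @return An object of class `ddiscl_model`: the trained network (`net`),
#'   the configs, the feature-type order, and `history` — a data.frame with
#'   one row per epoch (epoch, l_mse, l_con, l_cla, total, active_cla_loss).
#' @export
ddi_train <- function(profiles, records, cfg = train_config(),
                      netcfg = NULL, n_classes = NULL) {
  if (nrow(records) == 0) stop_invalid("empty training set")
  labels <- as.integer(records$label)
  if (is.null(n_classes)) n_classes <- max(labels)
  check_labels(labels, n_classes, nrow(records))
  if (is.null(netcfg)) {
    netcfg <- network_config(fea_dim = ncol(profiles$matrix),
                             n_classes = n_classes,
                             n_tokens = length(profiles$feature_types),
                             seed = cfg$seed)
  }
  if (netcfg$n_classes < n_classes) {
    stop_invalid("netcfg has ", netcfg$n_classes, " classes but labels reach ",
                 n_classes)
  }
  XA_all <- profile_rows(profiles, records$drugA, "train records")
  XB_all <- profile_rows(profiles, records$drugB, "train records")
  if (netcfg$symmetrize_pairs) {
    tmp <- rbind(XA_all, XB_all)
    XB_all <- rbind(XB_all, XA_all)
    XA_all <- tmp
    labels <- c(labels, labels)
  }
  n <- nrow(XA_all)
  cla_cfg <- classification_loss_config(
    smoothing = if (cfg$use_label_smoothing) cfg$smoothing else 0,
    focal_gamma = cfg$focal_gamma,
    switch_epoch = if (cfg$use_focal) cfg$switch_epoch else cfg$epochs,
    total_epochs = cfg$epochs)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  net <- init_network(netcfg)
  opt <- radam_init(net$params)
  hist <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs) - 1L) {
    active <- select_classification_loss(epoch, cla_cfg)
    ord <- sample(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    sums <- c(l_mse = 0, l_con = 0, l_cla = 0)
    for (st in starts) {
      idx <- ord[st:min(st + cfg$batch_size - 1L, n)]
      step <- train_step(net, XA_all[idx, , drop = FALSE],
                         XB_all[idx, , drop = FALSE], labels[idx],
                         cfg, cla_cfg, active)
      net$buffers <- step$buffers
      upd <- radam_step(net$params, clip_grads(step$grads, cfg$grad_clip),
                        opt, cfg$learning_rate)
      net$params <- upd$params
      opt <- upd$state
      w <- length(idx) / n
      sums <- sums + w * c(step$l_mse, step$l_con, step$l_cla)
    }
    bundle <- total_loss(sums[["l_mse"]], sums[["l_con"]], sums[["l_cla"]])
    hist[[epoch + 1L]] <- data.frame(epoch = epoch, l_mse = bundle$l_mse,
                                     l_con = bundle$l_con,
                                     l_cla = bundle$l_cla,
                                     total = bundle$total,
                                     active_cla_loss = active)
  }
  structure(list(net = net, train_cfg = cfg, net_cfg = netcfg,
                 feature_types = profiles$feature_types,
                 n_classes = as.integer(netcfg$n_classes),
                 history = do.call(rbind, hist)),
            class = "ddiscl_model")
}

train_step <- function(net, XA, XB, y, cfg, cla_cfg, active) {
  fw <- forward_pair(net, XA, XB, training = TRUE)
  net$buffers <- fw$buffers
  nb <- nrow(XA)
  fd <- net$cfg$fea_dim
  l_mse <- (mean((XA - fw$encA$recon)^2) + mean((XB - fw$encB$recon)^2)) / 2
  dReconA <- (fw$encA$recon - XA) / (fd * nb)
  dReconB <- (fw$encB$recon - XB) / (fd * nb)
  if (cfg$use_scl && nb >= 2) {
    scl <- supervised_contrastive_loss(fw$CFV, y, cfg$temperature,
                                       return_grad = TRUE)
    l_con <- scl$loss
    dCFV <- scl$grad
  } else {
    l_con <- 0
    dCFV <- matrix(0, nb, ncol(fw$CFV))
  }
  if (active == "cross_entropy") {
    l_cla <- smoothed_cross_entropy(fw$logits, y, cla_cfg$smoothing)
    dlogits <- ce_smoothed_grad(fw$logits, y, cla_cfg$smoothing)
  } else {
    l_cla <- focal_loss(fw$logits, y, cla_cfg$focal_gamma)
    dlogits <- focal_grad(fw$logits, y, cla_cfg$focal_gamma)
  }
  bundle <- total_loss(l_mse, l_con, l_cla)   # aborts on non-finite parts
  grads <- backward_pair(net, fw, dlogits, dCFV, dReconA, dReconB)
  list(grads = grads, l_mse = bundle$l_mse, l_con = bundle$l_con,
       l_cla = bundle$l_cla, buffers = net$buffers)
}

#' @export
print.ddiscl_model <- function(x, ...) {
  cat("<ddiscl_model> ", x$n_classes, " classes, fea_dim ",
      x$net$cfg$fea_dim, "; trained ", nrow(x$history), " epochs (final loss ",
      sprintf("%.4f", x$history$total[nrow(x$history)]), ")\n", sep = "")
  invisible(x)
}

#' Predict interaction-type probabilities for drug pairs
#'
#' Runs the network in evaluation mode (no dropout, batch-norm running
#' statistics), so repeated calls are identical. With
#' `symmetrize_pairs = TRUE` in the network config, both pair orders are
#' evaluated and their softmax outputs averaged.
#'
#' @param model a trained [ddi_train()] model.
#' @param profiles similarity profiles covering every drug in `pairs`.
#' @param pairs data.frame with columns `drugA`, `drugB`.
#' @return N x C matrix of class probabilities (rows sum to 1).
#' @export
ddi_predict <- function(model, profiles, pairs) {
  XA <- profile_rows(profiles, as.character(pairs$drugA))
  XB <- profile_rows(profiles, as.character(pairs$drugB))
  p <- softmax_rows(forward_pair(model$net, XA, XB, training = FALSE)$logits)
  if (model$net$cfg$symmetrize_pairs) {
    p2 <- softmax_rows(forward_pair(model$net, XB, XA,
                                    training = FALSE)$logits)
    p <- (p + p2) / 2
  }
  dimnames(p) <- NULL
  p
}

#' Extract pair embeddings (CFVs) for drug pairs
#'
#' @inheritParams ddi_predict
#' @return N x c matrix of pair embeddings, evaluation mode.
#' @export
pair_embeddings <- function(model, profiles, pairs) {
  XA <- profile_rows(profiles, as.character(pairs$drugA))
  XB <- profile_rows(profiles, as.character(pairs$drugB))
  cfv <- forward_pair(model$net, XA, XB, training = FALSE)$CFV
  dimnames(cfv) <- NULL
  cfv
}

#' Mean intra- and inter-class cosine similarity of embeddings
#'
#' The contrastive term exists to make embeddings of same-type interactions
#' more similar than embeddings of different types; this measures that
#' geometry on a set of (typically held-out) pairs.
#'
#' @param cfvs embedding matrix, one row per pair.
#' @param labels integer class labels.
#' @return List with `intra`, `inter`, and `gap = intra - inter`.
#' @export
class_similarity_gap <- function(cfvs, labels) {
  z <- as.matrix(cfvs)
  u <- z / sqrt(rowSums(z^2))
  s <- tcrossprod(u)
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  off <- !is.na(same)
  intra <- mean(s[off & same])
  inter <- mean(s[off & !same])
  list(intra = intra, inter = inter, gap = intra - inter)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single JSON file embedding the network parameters,
#' batch-norm buffers, both configs, and the feature-type order.
#'
#' @param model a `ddiscl_model`.
#' @param path file path (JSON).
#' @return `read_model` returns the `ddiscl_model`.
#' @export
write_model <- function(model, path) {
  ser <- list(
    params = lapply(model$net$params, function(grp)
      lapply(grp, function(x)
        if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
        else list(dim = NULL, data = as.vector(x)))),
    buffers = model$net$buffers,
    net_cfg = unclass(model$net$cfg),
    train_cfg = unclass(model$train_cfg),
    feature_types = model$feature_types,
    n_classes = model$n_classes,
    history = model$history)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(x$params, function(grp)
    lapply(grp, function(p) {
      v <- as.numeric(unlist(p$data))
      if (!is.null(p$dim) && length(p$dim) == 2) {
        matrix(v, p$dim[1], p$dim[2])
      } else v
    }))
  buffers <- lapply(x$buffers, function(b) lapply(b, as.numeric))
  ncfg <- x$net_cfg
  netcfg <- network_config(
    fea_dim = ncfg$fea_dim, n_classes = ncfg$n_classes,
    n_tokens = ncfg$n_tokens, n_heads = ncfg$n_heads, h1 = ncfg$h1,
    h2 = ncfg$h2, L = ncfg$L, n_heads_reduce = ncfg$n_heads_reduce,
    clf_hidden = ncfg$clf_hidden, dropout_rate = ncfg$dropout_rate,
    fusion_mode = ncfg$fusion_mode, symmetrize_pairs = ncfg$symmetrize_pairs,
    n_attn_layers = ncfg$n_attn_layers, seed = ncfg$seed)
  tcfg <- x$train_cfg
  traincfg <- train_config(
    learning_rate = tcfg$learning_rate, batch_size = tcfg$batch_size,
    epochs = tcfg$epochs, smoothing = tcfg$smoothing,
    temperature = tcfg$temperature, switch_epoch = tcfg$switch_epoch,
    focal_gamma = tcfg$focal_gamma, use_scl = tcfg$use_scl,
    use_focal = tcfg$use_focal,
    use_label_smoothing = tcfg$use_label_smoothing,
    grad_clip = if (is.null(tcfg$grad_clip)) 5 else as.numeric(tcfg$grad_clip),
    seed = tcfg$seed)
  structure(list(net = list(params = params, buffers = buffers, cfg = netcfg),
                 train_cfg = traincfg, net_cfg = netcfg,
                 feature_types = as.character(x$feature_types),
                 n_classes = as.integer(x$n_classes),
                 history = as.data.frame(x$history)),
            class = "ddiscl_model")
}
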