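# The three-level loss: reconstruction MSE, supervised contrastive loss over
# pair embeddings, and a scheduled label-smoothed cross-entropy / focal
# classification loss, summed without weights.

#' Reconstruction mean squared error
#'
#' Sum of squared differences between a drug's similarity-profile vector and
#' its autoencoder reconstruction, divided by the feature dimensionality.
#'
#' @param x numeric vector (or matrix, one row per drug).
#' @param x_recon reconstruction of the same shape.
#' @return For vectors, a single non-negative number; for matrices, the mean
#'   over rows.
#' @export
mse_loss <- function(x, x_recon) {
  if (length(x) != length(x_recon)) {
    stop_invalid("mse_loss: shapes differ (", length(x), " vs ",
                 length(x_recon), ")")
  }
  mean((x - x_recon)^2)
}

#' Supervised contrastive loss over a batch of pair embeddings
#'
#' For each anchor i with at least one same-class batchmate, averages
#' \eqn{-\log\frac{\exp(\mathrm{sim}(z_i,z_j)/\tau)}{\sum_{k\ne i}\exp(\mathrm{sim}(z_i,z_k)/\tau)}}
#' over its positives j (same label, j != i), normalised by
#' \eqn{N_{y_i} - 1}; the batch loss is the mean of anchor losses over the
#' full batch size. Similarity is cosine. Anchors whose class is a singleton
#' in the batch contribute 0 (their normaliser would be 0/0).
#'
#' @param cfvs numeric matrix, one embedding per row; rows must be non-zero.
#' @param labels integer class labels, one per row.
#' @param temperature positive scalar temperature (default 0.05).
#' @param return_grad also return the gradient with respect to `cfvs`.
#' @return The loss (non-negative scalar), or if `return_grad` a list with
#'   elements `loss` and `grad`.
#' @export
supervised_contrastive_loss <- function(cfvs, labels, temperature = 0.05,
                                        return_grad = FALSE) {
  z <- as.matrix(cfvs)
  n <- nrow(z)
  if (n < 2) stop_invalid("supervised_contrastive_loss: need at least 2 samples")
  if (length(labels) != n) {
    stop_invalid("supervised_contrastive_loss: ", n, " rows but ",
                 length(labels), " labels")
  }
  if (temperature <= 0) stop_invalid("temperature must be positive")
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) {
    stop_invalid("supervised_contrastive_loss: zero embedding vector(s) at row(s) ",
                 paste(which(nrm == 0), collapse = ", "))
  }
  u <- z / nrm
  s <- tcrossprod(u)                     # cosine similarities
  e <- s / temperature
  diag(e) <- -Inf                        # k != i
  emax <- apply(e, 1, max)
  ex <- exp(e - emax)
  denom <- rowSums(ex)
  lse <- emax + log(denom)               # log sum_{k != i} exp(s_ik / tau)
  pos <- outer(labels, labels, "==")
  diag(pos) <- FALSE
  npos <- rowSums(pos)
  active <- npos > 0
  li <- numeric(n)
  li[active] <- lse[active] -
    rowSums(pos * s)[active] / (temperature * npos[active])
  loss <- sum(li) / n
  if (!return_grad) return(loss)

  # d(loss)/d(s_ik): softmax weight minus positive-indicator term, anchors
  # without positives contribute nothing.
  a <- ex / denom
  g <- matrix(0, n, n)
  g[active, ] <- (a[active, , drop = FALSE] -
                    pos[active, , drop = FALSE] / npos[active]) /
    (temperature * n)
  diag(g) <- 0
  du <- (g + t(g)) %*% u
  # back through row normalisation u_i = z_i / ||z_i||
  dz <- (du - u * rowSums(du * u)) / nrm
  list(loss = loss, grad = dz)
}

softmax_rows <- function(logits) {
  m <- as.matrix(logits)
  mx <- apply(m, 1, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

as_logit_matrix <- function(logits) {
  if (is.matrix(logits)) logits else matrix(logits, nrow = 1)
}

check_labels <- function(labels, n_classes, n) {
  if (length(labels) != n) {
    stop_invalid("expected ", n, " labels, got ", length(labels))
  }
  if (any(labels < 1L | labels > n_classes)) {
    stop_invalid("class label out of range [1, ", n_classes, "]: ",
                 paste(labels[labels < 1L | labels > n_classes], collapse = ", "))
  }
  invisible(TRUE)
}

#' Label-smoothed cross-entropy
#'
#' Cross-entropy against the softened target
#' \eqn{(1-\epsilon)\,\mathrm{onehot}(y) + \epsilon / K} (uniform mass over
#' all K classes, including the true one).
#'
#' @param logits numeric vector of length K, or an N x K matrix.
#' @param label integer class label(s) in 1..K.
#' @param smoothing smoothing parameter in \[0, 1) (default 0.3).
#' @return Mean loss over the batch (scalar).
#' @export
smoothed_cross_entropy <- function(logits, label, smoothing = 0.3) {
  if (smoothing < 0 || smoothing >= 1) {
    stop_invalid("smoothing must be in [0, 1)")
  }
  m <- as_logit_matrix(logits)
  k <- ncol(m)
  check_labels(label, k, nrow(m))
  lp <- log(softmax_rows(m))
  true_lp <- lp[cbind(seq_len(nrow(m)), label)]
  mean(-(1 - smoothing) * true_lp - smoothing * rowMeans(lp))
}

#' Focal loss
#'
#' Multi-class focal loss \eqn{-(1-p_t)^\gamma \log p_t} with \eqn{p_t} the
#' softmax probability of the true class; no per-class alpha weighting.
#' Down-weights well-classified samples so rare/hard classes dominate the
#' gradient.
#'
#' @param logits numeric vector of length K, or an N x K matrix.
#' @param label integer class label(s) in 1..K.
#' @param gamma non-negative focusing parameter (default 2).
#' @return Mean loss over the batch (scalar).
#' @export
focal_loss <- function(logits, label, gamma = 2) {
  if (gamma < 0) stop_invalid("gamma must be non-negative")
  m <- as_logit_matrix(logits)
  check_labels(label, ncol(m), nrow(m))
  p <- softmax_rows(m)
  pt <- p[cbind(seq_len(nrow(m)), label)]
  mean(-(1 - pt)^gamma * log(pmax(pt, 1e-12)))
}

#' Classification-loss schedule configuration
#'
#' @param smoothing label-smoothing parameter (default 0.3).
#' @param focal_gamma focal focusing parameter (default 2).
#' @param switch_epoch first (0-based) epoch that uses focal loss; earlier
#'   epochs use cross-entropy (default 40).
#' @param total_epochs total training epochs (default 120).
#' @return An object of class `classification_loss_config`.
#' @export
classification_loss_config <- function(smoothing = 0.3, focal_gamma = 2,
                                       switch_epoch = 40, total_epochs = 120) {
  if (smoothing < 0 || smoothing >= 1) stop_config("smoothing must be in [0, 1)")
  if (focal_gamma < 0) stop_config("focal_gamma must be non-negative")
  if (switch_epoch < 0 || switch_epoch > total_epochs) {
    stop_config("switch_epoch must lie in [0, total_epochs]")
  }
  structure(list(smoothing = smoothing, focal_gamma = focal_gamma,
                 switch_epoch = switch_epoch, total_epochs = total_epochs),
            class = "classification_loss_config")
}

#' Which classification loss is active at a given epoch
#'
#' Cross-entropy (with label smoothing) for epochs before `switch_epoch`,
#' focal loss from `switch_epoch` on — cross-entropy in the first part of
#' training, focal loss in the rest.
#'
#' @param epoch 0-based epoch index in `[0, total_epochs)`.
#' @param cfg a [classification_loss_config()].
#' @return `"cross_entropy"` or `"focal"`.
#' @export
select_classification_loss <- function(epoch, cfg) {
  if (epoch < 0 || epoch >= cfg$total_epochs) {
    stop_invalid("epoch ", epoch, " out of range [0, ", cfg$total_epochs, ")")
  }
  if (epoch < cfg$switch_epoch) "cross_entropy" else "focal"
}

#' Combine the three loss components
#'
#' The model's total loss is the unweighted sum of the reconstruction MSE,
#' the supervised contrastive loss, and the classification loss.
#'
#' @param l_mse,l_con,l_cla the three component values.
#' @return An object of class `loss_bundle` with fields `l_mse`, `l_con`,
#'   `l_cla`, `total`.
#' @export
total_loss <- function(l_mse, l_con, l_cla) {
  comp <- c(l_mse = l_mse, l_con = l_con, l_cla = l_cla)
  bad <- !is.finite(comp)
  if (any(bad)) {
    stop_divergence("non-finite loss component(s): ",
                    paste(names(comp)[bad], collapse = ", "))
  }
  structure(list(l_mse = l_mse, l_con = l_con, l_cla = l_cla,
                 total = l_mse + l_con + l_cla),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf("<loss_bundle> total %.6g (mse %.6g + con %.6g + cla %.6g)\n",
              x$total, x$l_mse, x$l_con, x$l_cla))
  invisible(x)
}

# gradient of the batch-mean classification loss w.r.t. logits -----------------

ce_smoothed_grad <- function(logits, label, smoothing) {
  p <- softmax_rows(logits)
  n <- nrow(p); k <- ncol(p)
  t <- matrix(smoothing / k, n, k)
  t[cbind(seq_len(n), label)] <- t[cbind(seq_len(n), label)] + (1 - smoothing)
  (p - t) / n
}

focal_grad <- function(logits, label, gamma) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), label)
  pt <- pmax(p[idx], 1e-12)
  # dL/dpt for L = -(1-pt)^g log pt
  dldpt <- gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
  g <- p * (dldpt * pt)          # chain rule through softmax: pt*(delta - p_j)
  g[idx] <- g[idx] - dldpt * pt
  -g / n
}
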