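# The pair-classification network:
#   per-drug encoder   = multi-head self-attention (token view of the
#                        similarity profile, residual) + two-layer
#                        autoencoder with GELU,
#   pair fusion        = cross-depth concatenations DA1+DB3, DA2+DB2, DA3+DB1
#                        through per-scale fully connected layers,
#   latent reduction   = self-attention over the concatenated blocks followed
#                        by L width-halving (linear, GELU, dropout,
#                        batch-norm) layers producing the pair embedding CFV,
#   classifier head    = two fully connected layers, the last one n_classes
#                        wide.
#
# Everything is plain matrix code with hand-derived reverse-mode gradients;
# each *_fwd returns a cache consumed by the matching *_bwd. Gradient
# correctness is pinned down by finite-difference tests.

#' Network configuration
#'
#' Widths and structural settings of the pair-classification network. With
#' the defaults, `h1` is roughly half the input width rounded to a multiple
#' of `2^(L+1)` so that every later halving stays integral, `h2 = h1/2`, the
#' fusion width equals `h2` (required: the reduction attention treats the
#' five concatenated blocks as tokens), and the pair embedding CFV has width
#' `5*h2 / 2^L`.
#'
#' @param fea_dim input width (drug similarity-profile length).
#' @param n_classes number of interaction types (>= 2).
#' @param n_tokens token count for the encoder attention; `fea_dim` must be
#'   divisible by it. Conventionally one token per feature-type block.
#' @param n_heads encoder attention heads; must divide `fea_dim / n_tokens`.
#'   Default: largest divisor <= 4.
#' @param h1,h2 encoder layer widths (`fea_dim > h1 > h2`).
#' @param L number of width-halving reduction layers (default 2).
#' @param n_heads_reduce attention heads in the reduction sub-module; must
#'   divide `h2`. Default: largest divisor <= 4.
#' @param clf_hidden width of the first classifier layer.
#' @param dropout_rate dropout probability in reduction/classifier layers.
#' @param fusion_mode `"multi_scale"` (DA1+DB3, DA2+DB2, DA3+DB1),
#'   `"single_scale"` (DA1+DB1, DA2+DB2, DA3+DB3), or `"none"`
#'   (only DA3 and DB3, no fusion layers).
#' @param symmetrize_pairs if TRUE, training also sees each pair swapped and
#'   prediction averages both orders.
#' @param n_attn_layers number of stacked encoder attention layers.
#' @param seed seed for weight initialisation.
#' @return An object of class `network_config`.
#' @export
network_config <- function(fea_dim, n_classes, n_tokens = 4, n_heads = NULL,
                           h1 = NULL, h2 = NULL, L = 2, n_heads_reduce = NULL,
                           clf_hidden = NULL, dropout_rate = 0.3,
                           fusion_mode = c("multi_scale", "single_scale", "none"),
                           symmetrize_pairs = FALSE, n_attn_layers = 1,
                           seed = 1) {
  fusion_mode <- match.arg(fusion_mode)
  if (n_classes < 2) stop_config("n_classes must be >= 2")
  if (fea_dim %% n_tokens != 0) {
    stop_config("fea_dim (", fea_dim, ") not divisible by n_tokens (",
                n_tokens, ")")
  }
  d_tok <- fea_dim %/% n_tokens
  if (is.null(n_heads)) n_heads <- largest_divisor(d_tok, 4)
  if (d_tok %% n_heads != 0) {
    stop_config("token width ", d_tok, " not divisible by n_heads ", n_heads)
  }
  if (is.null(h1)) {
    step <- 2^(L + 1)
    h1 <- max(step, round(fea_dim / 2 / step) * step)
  }
  if (is.null(h2)) h2 <- h1 %/% 2
  if (!(h2 < h1 && h1 < fea_dim)) {
    stop_config("widths must satisfy h2 < h1 < fea_dim, got ",
                h2, " / ", h1, " / ", fea_dim)
  }
  n_blocks <- if (fusion_mode == "none") 2L else 5L
  w0 <- n_blocks * h2
  if (L > 0 && w0 %% 2^L != 0) {
    stop_config("reduction input width ", w0, " not divisible by 2^L = ", 2^L)
  }
  if (is.null(n_heads_reduce)) n_heads_reduce <- largest_divisor(h2, 4)
  if (h2 %% n_heads_reduce != 0) {
    stop_config("h2 (", h2, ") not divisible by n_heads_reduce (",
                n_heads_reduce, ")")
  }
  cfv_dim <- w0 %/% 2^L
  if (is.null(clf_hidden)) clf_hidden <- max(8L, cfv_dim %/% 2L)
  structure(list(
    fea_dim = as.integer(fea_dim), n_classes = as.integer(n_classes),
    n_tokens = as.integer(n_tokens), n_heads = as.integer(n_heads),
    h1 = as.integer(h1), h2 = as.integer(h2), f = as.integer(h2),
    L = as.integer(L), n_heads_reduce = as.integer(n_heads_reduce),
    n_blocks = n_blocks, cfv_dim = as.integer(cfv_dim),
    clf_hidden = as.integer(clf_hidden), dropout_rate = dropout_rate,
    fusion_mode = fusion_mode, symmetrize_pairs = symmetrize_pairs,
    n_attn_layers = as.integer(n_attn_layers), seed = as.integer(seed)),
    class = "network_config")
}

largest_divisor <- function(n, upto) {
  for (h in seq(min(upto, n), 1)) if (n %% h == 0) return(as.integer(h))
  1L
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config> fea_dim ", x$fea_dim, " -> h1 ", x$h1, " -> h2 ",
      x$h2, "; fusion ", x$fusion_mode, "; CFV ", x$cfv_dim, " -> ",
      x$clf_hidden, " -> ", x$n_classes, " classes\n", sep = "")
  invisible(x)
}

# parameter initialisation ----------------------------------------------------

glorot <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

attn_params <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d), bq = numeric(d), bk = numeric(d),
       bv = numeric(d), bo = numeric(d))
}

bn_params <- function(w) list(gamma = rep(1, w), beta = numeric(w))

#' Initialise network parameters
#'
#' @param cfg a [network_config()].
#' @return A list with `params` (trainable arrays), `buffers` (batch-norm
#'   running statistics), and `cfg`.
#' @export
init_network <- function(cfg) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  d_tok <- cfg$fea_dim %/% cfg$n_tokens
  p <- list()
  for (l in seq_len(cfg$n_attn_layers)) {
    p[[paste0("enc_attn", l)]] <- attn_params(d_tok)
  }
  p$enc1 <- list(W = glorot(cfg$fea_dim, cfg$h1), b = numeric(cfg$h1))
  p$enc2 <- list(W = glorot(cfg$h1, cfg$h2), b = numeric(cfg$h2))
  p$dec1 <- list(W = glorot(cfg$h2, cfg$h1), b = numeric(cfg$h1))
  p$dec2 <- list(W = glorot(cfg$h1, cfg$fea_dim), b = numeric(cfg$fea_dim))
  if (cfg$fusion_mode != "none") {
    widths_in <- list(f1 = cfg$fea_dim + cfg$h2, f2 = 2L * cfg$h1,
                      f3 = cfg$h2 + cfg$fea_dim)
    if (cfg$fusion_mode == "single_scale") {
      widths_in <- list(f1 = 2L * cfg$fea_dim, f2 = 2L * cfg$h1,
                        f3 = 2L * cfg$h2)
    }
    for (nm in names(widths_in)) {
      p[[paste0("fuse_", nm)]] <- list(W = glorot(widths_in[[nm]], cfg$f),
                                       b = numeric(cfg$f))
    }
  }
  p$red_attn <- attn_params(cfg$h2)
  buffers <- list()
  w <- cfg$n_blocks * cfg$h2
  for (l in seq_len(cfg$L)) {
    p[[paste0("red", l)]] <- c(list(W = glorot(w, w %/% 2L),
                                    b = numeric(w %/% 2L)),
                               bn_params(w %/% 2L))
    buffers[[paste0("red", l)]] <- list(mean = numeric(w %/% 2L),
                                        var = rep(1, w %/% 2L))
    w <- w %/% 2L
  }
  p$clf1 <- c(list(W = glorot(cfg$cfv_dim, cfg$clf_hidden),
                   b = numeric(cfg$clf_hidden)), bn_params(cfg$clf_hidden))
  buffers$clf1 <- list(mean = numeric(cfg$clf_hidden),
                       var = rep(1, cfg$clf_hidden))
  p$clf2 <- list(W = glorot(cfg$clf_hidden, cfg$n_classes),
                 b = numeric(cfg$n_classes))
  list(params = p, buffers = buffers, cfg = cfg)
}

# primitive layers (forward caches feed the matching backward) ----------------

addb <- function(m, b) m + rep(b, each = nrow(m))

lin_fwd <- function(x, p) addb(x %*% p$W, p$b)
lin_bwd <- function(dy, x, p) {
  list(dx = dy %*% t(p$W), dW = crossprod(x, dy), db = colSums(dy))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_bwd <- function(dy, x) dy * (stats::pnorm(x) + x * stats::dnorm(x))

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x)) / (1 - rate)
  list(y = x * mask, mask = mask)
}
dropout_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

bn_fwd <- function(x, p, buf, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    n <- nrow(x)
    vu <- if (n > 1) v * n / (n - 1) else v      # unbiased for running stats
    buf$var <- (1 - momentum) * buf$var + momentum * vu
  } else {
    mu <- buf$mean
    v <- buf$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep_cols(x, mu) * rep(istd, each = nrow(x))
  y <- addb(xhat * rep(p$gamma, each = nrow(x)), p$beta)
  list(y = y, cache = list(xhat = xhat, istd = istd, training = training),
       buf = buf)
}

sweep_cols <- function(x, mu) x - rep(mu, each = nrow(x))

bn_bwd <- function(dy, p, cache) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(p$gamma, each = n)
  if (cache$training) {
    dx <- (dxhat - rep(colMeans(dxhat), each = n) -
             xhat * rep(colMeans(dxhat * xhat), each = n)) *
      rep(cache$istd, each = n)
  } else {
    dx <- dxhat * rep(cache$istd, each = n)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# multi-head self-attention over a token view of a flat vector ----------------
# x: n x (T*d); tokens are contiguous column slices of width d.

mha_fwd <- function(x, p, n_tok, n_heads) {
  n <- nrow(x)
  d <- ncol(x) %/% n_tok
  dh <- d %/% n_heads
  scale <- 1 / sqrt(dh)
  tok_idx <- lapply(seq_len(n_tok), function(t) ((t - 1L) * d + 1L):(t * d))
  xt <- lapply(tok_idx, function(ix) x[, ix, drop = FALSE])
  q <- lapply(xt, function(m) addb(m %*% p$Wq, p$bq))
  k <- lapply(xt, function(m) addb(m %*% p$Wk, p$bk))
  v <- lapply(xt, function(m) addb(m %*% p$Wv, p$bv))
  head_idx <- lapply(seq_len(n_heads), function(h) ((h - 1L) * dh + 1L):(h * dh))
  A <- vector("list", n_tok)        # A[[t]][[h]]: n x n_tok softmax weights
  o <- vector("list", n_tok)        # pre-projection head concat per token
  for (t in seq_len(n_tok)) {
    A[[t]] <- vector("list", n_heads)
    ot <- matrix(0, n, d)
    for (h in seq_len(n_heads)) {
      hi <- head_idx[[h]]
      e <- matrix(0, n, n_tok)
      for (s in seq_len(n_tok)) {
        e[, s] <- rowSums(q[[t]][, hi, drop = FALSE] *
                            k[[s]][, hi, drop = FALSE]) * scale
      }
      a <- softmax_rows(e)
      A[[t]][[h]] <- a
      oth <- matrix(0, n, dh)
      for (s in seq_len(n_tok)) {
        oth <- oth + a[, s] * v[[s]][, hi, drop = FALSE]
      }
      ot[, hi] <- oth
    }
    o[[t]] <- ot
  }
  y <- do.call(cbind, lapply(o, function(m) addb(m %*% p$Wo, p$bo)))
  list(y = y, cache = list(xt = xt, q = q, k = k, v = v, A = A, o = o,
                           tok_idx = tok_idx, head_idx = head_idx,
                           scale = scale, n_tok = n_tok, n_heads = n_heads,
                           d = d))
}

mha_bwd <- function(dy, p, cache) {
  n <- nrow(dy)
  n_tok <- cache$n_tok; n_heads <- cache$n_heads; d <- cache$d
  dh <- d %/% n_heads
  g <- list(Wq = 0 * p$Wq, Wk = 0 * p$Wk, Wv = 0 * p$Wv, Wo = 0 * p$Wo,
            bq = 0 * p$bq, bk = 0 * p$bk, bv = 0 * p$bv, bo = 0 * p$bo)
  dq <- lapply(seq_len(n_tok), function(t) matrix(0, n, d))
  dk <- dq; dv <- dq
  for (t in seq_len(n_tok)) {
    dyt <- dy[, cache$tok_idx[[t]], drop = FALSE]
    g$Wo <- g$Wo + crossprod(cache$o[[t]], dyt)
    g$bo <- g$bo + colSums(dyt)
    dot <- dyt %*% t(p$Wo)
    for (h in seq_len(n_heads)) {
      hi <- cache$head_idx[[h]]
      doth <- dot[, hi, drop = FALSE]
      a <- cache$A[[t]][[h]]
      da <- matrix(0, n, n_tok)
      for (s in seq_len(n_tok)) {
        da[, s] <- rowSums(doth * cache$v[[s]][, hi, drop = FALSE])
        dv[[s]][, hi] <- dv[[s]][, hi, drop = FALSE] + a[, s] * doth
      }
      de <- a * (da - rowSums(a * da))          # softmax jacobian, rowwise
      for (s in seq_len(n_tok)) {
        dq[[t]][, hi] <- dq[[t]][, hi, drop = FALSE] +
          de[, s] * cache$k[[s]][, hi, drop = FALSE] * cache$scale
        dk[[s]][, hi] <- dk[[s]][, hi, drop = FALSE] +
          de[, s] * cache$q[[t]][, hi, drop = FALSE] * cache$scale
      }
    }
  }
  dx <- matrix(0, n, n_tok * d)
  for (t in seq_len(n_tok)) {
    g$Wq <- g$Wq + crossprod(cache$xt[[t]], dq[[t]])
    g$Wk <- g$Wk + crossprod(cache$xt[[t]], dk[[t]])
    g$Wv <- g$Wv + crossprod(cache$xt[[t]], dv[[t]])
    g$bq <- g$bq + colSums(dq[[t]])
    g$bk <- g$bk + colSums(dk[[t]])
    g$bv <- g$bv + colSums(dv[[t]])
    dx[, cache$tok_idx[[t]]] <- dq[[t]] %*% t(p$Wq) + dk[[t]] %*% t(p$Wk) +
      dv[[t]] %*% t(p$Wv)
  }
  list(dx = dx, grads = g)
}

# encoder: attention (+ residual) then two-layer autoencoder ------------------

encode_fwd <- function(x, net) {
  p <- net$params; cfg <- net$cfg
  attn <- vector("list", cfg$n_attn_layers)
  cur <- x
  for (l in seq_len(cfg$n_attn_layers)) {
    a <- mha_fwd(cur, p[[paste0("enc_attn", l)]], cfg$n_tokens, cfg$n_heads)
    attn[[l]] <- a
    cur <- cur + a$y                       # residual
  }
  da1 <- cur
  z1 <- lin_fwd(da1, p$enc1); da2 <- gelu(z1)
  z2 <- lin_fwd(da2, p$enc2); da3 <- gelu(z2)
  zd1 <- lin_fwd(da3, p$dec1); gd1 <- gelu(zd1)
  recon <- lin_fwd(gd1, p$dec2)
  list(DA1 = da1, DA2 = da2, DA3 = da3, recon = recon,
       cache = list(x = x, attn = attn, z1 = z1, z2 = z2, zd1 = zd1,
                    gd1 = gd1))
}

# dDA1/dDA2/dDA3/dRecon are the total upstream gradients flowing into each
# exposed tensor; returns parameter grads (named like params) and dx.
encode_bwd <- function(dDA1, dDA2, dDA3, dRecon, enc, net) {
  p <- net$params; cfg <- net$cfg; ca <- enc$cache
  g <- list()
  l2 <- lin_bwd(dRecon, ca$gd1, p$dec2)
  g$dec2 <- list(W = l2$dW, b = l2$db)
  dzd1 <- gelu_bwd(l2$dx, ca$zd1)
  l1 <- lin_bwd(dzd1, enc$DA3, p$dec1)
  g$dec1 <- list(W = l1$dW, b = l1$db)
  dDA3 <- dDA3 + l1$dx
  dz2 <- gelu_bwd(dDA3, ca$z2)
  e2 <- lin_bwd(dz2, enc$DA2, p$enc2)
  g$enc2 <- list(W = e2$dW, b = e2$db)
  dDA2 <- dDA2 + e2$dx
  dz1 <- gelu_bwd(dDA2, ca$z1)
  e1 <- lin_bwd(dz1, enc$DA1, p$enc1)
  g$enc1 <- list(W = e1$dW, b = e1$db)
  dcur <- dDA1 + e1$dx
  for (l in rev(seq_len(cfg$n_attn_layers))) {
    ab <- mha_bwd(dcur, p[[paste0("enc_attn", l)]], ca$attn[[l]]$cache)
    g[[paste0("enc_attn", l)]] <- ab$grads
    dcur <- dcur + ab$dx                   # residual: dx flows both ways
  }
  list(dx = dcur, grads = g)
}

# fusion ----------------------------------------------------------------------

fusion_inputs <- function(encA, encB, mode) {
  switch(mode,
    multi_scale = list(f1 = cbind(encA$DA1, encB$DA3),
                       f2 = cbind(encA$DA2, encB$DA2),
                       f3 = cbind(encA$DA3, encB$DA1)),
    single_scale = list(f1 = cbind(encA$DA1, encB$DA1),
                        f2 = cbind(encA$DA2, encB$DA2),
                        f3 = cbind(encA$DA3, encB$DA3)),
    none = list())
}

fuse_fwd <- function(encA, encB, net) {
  cfg <- net$cfg
  ins <- fusion_inputs(encA, encB, cfg$fusion_mode)
  out <- list(); zs <- list()
  for (nm in names(ins)) {
    z <- lin_fwd(ins[[nm]], net$params[[paste0("fuse_", nm)]])
    zs[[nm]] <- z
    out[[nm]] <- gelu(z)
  }
  list(FD = out, cache = list(ins = ins, zs = zs))
}

# returns grads for fusion params plus the gradients flowing back into the
# six encoder tensors, as a list dA/dB of (d1, d2, d3).
fuse_bwd <- function(dFD, fus, net) {
  cfg <- net$cfg
  g <- list()
  zero <- function(m) matrix(0, nrow(m), ncol(m))
  dA <- list(d1 = NULL, d2 = NULL, d3 = NULL)
  dB <- list(d1 = NULL, d2 = NULL, d3 = NULL)
  acc <- function(cur, add) if (is.null(cur)) add else cur + add
  for (nm in names(dFD)) {
    z <- fus$cache$zs[[nm]]
    dz <- gelu_bwd(dFD[[nm]], z)
    lb <- lin_bwd(dz, fus$cache$ins[[nm]], net$params[[paste0("fuse_", nm)]])
    g[[paste0("fuse_", nm)]] <- list(W = lb$dW, b = lb$db)
    din <- lb$dx
    split_at <- ncol(fus$cache$ins[[nm]]) -
      switch(cfg$fusion_mode,
             multi_scale = switch(nm, f1 = net$cfg$h2, f2 = net$cfg$h1,
                                  f3 = net$cfg$fea_dim),
             single_scale = ncol(fus$cache$ins[[nm]]) %/% 2L)
    dleft <- din[, seq_len(split_at), drop = FALSE]
    dright <- din[, (split_at + 1L):ncol(din), drop = FALSE]
    if (cfg$fusion_mode == "multi_scale") {
      if (nm == "f1") { dA$d1 <- acc(dA$d1, dleft); dB$d3 <- acc(dB$d3, dright) }
      if (nm == "f2") { dA$d2 <- acc(dA$d2, dleft); dB$d2 <- acc(dB$d2, dright) }
      if (nm == "f3") { dA$d3 <- acc(dA$d3, dleft); dB$d1 <- acc(dB$d1, dright) }
    } else {
      lv <- substr(nm, 2, 2)
      dA[[paste0("d", lv)]] <- acc(dA[[paste0("d", lv)]], dleft)
      dB[[paste0("d", lv)]] <- acc(dB[[paste0("d", lv)]], dright)
    }
  }
  list(grads = g, dA = dA, dB = dB)
}

# latent reduction ------------------------------------------------------------

reduce_fwd <- function(blocks, net, training) {
  cfg <- net$cfg; p <- net$params
  x0 <- do.call(cbind, blocks)
  a <- mha_fwd(x0, p$red_attn, cfg$n_blocks, cfg$n_heads_reduce)
  cur <- x0 + a$y                          # residual
  layers <- vector("list", cfg$L)
  bufs <- net$buffers
  for (l in seq_len(cfg$L)) {
    pn <- paste0("red", l)
    z <- lin_fwd(cur, p[[pn]])
    gz <- gelu(z)
    dp <- dropout_fwd(gz, cfg$dropout_rate, training)
    bn <- bn_fwd(dp$y, p[[pn]], bufs[[pn]], training)
    bufs[[pn]] <- bn$buf
    layers[[l]] <- list(x_in = cur, z = z, gz = gz, mask = dp$mask,
                        bn_cache = bn$cache)
    cur <- bn$y
  }
  list(CFV = cur, buffers = bufs,
       cache = list(x0 = x0, attn = a, layers = layers,
                    block_widths = vapply(blocks, ncol, integer(1))))
}

reduce_bwd <- function(dCFV, red, net) {
  cfg <- net$cfg; p <- net$params
  g <- list()
  dcur <- dCFV
  for (l in rev(seq_len(cfg$L))) {
    pn <- paste0("red", l)
    la <- red$cache$layers[[l]]
    bb <- bn_bwd(dcur, p[[pn]], la$bn_cache)
    ddp <- dropout_bwd(bb$dx, la$mask)
    dz <- gelu_bwd(ddp, la$z)
    lb <- lin_bwd(dz, la$x_in, p[[pn]])
    g[[pn]] <- list(W = lb$dW, b = lb$db, gamma = bb$dgamma, beta = bb$dbeta)
    dcur <- lb$dx
  }
  ab <- mha_bwd(dcur, p$red_attn, red$cache$attn$cache)
  g$red_attn <- ab$grads
  dx0 <- dcur + ab$dx
  # split back into the input blocks
  w <- red$cache$block_widths
  ends <- cumsum(w)
  starts <- c(1L, head(ends, -1L) + 1L)
  dblocks <- lapply(seq_along(w), function(i) {
    dx0[, starts[i]:ends[i], drop = FALSE]
  })
  list(grads = g, dblocks = dblocks)
}

# classifier head -------------------------------------------------------------

classify_fwd <- function(cfv, net, training) {
  p <- net$params; cfg <- net$cfg
  z1 <- lin_fwd(cfv, p$clf1)
  g1 <- gelu(z1)
  dp <- dropout_fwd(g1, cfg$dropout_rate, training)
  bn <- bn_fwd(dp$y, p$clf1, net$buffers$clf1, training)
  logits <- lin_fwd(bn$y, p$clf2)
  buffers <- net$buffers
  buffers$clf1 <- bn$buf
  list(logits = logits, buffers = buffers,
       cache = list(cfv = cfv, z1 = z1, g1 = g1, mask = dp$mask,
                    bn_cache = bn$cache, bn_y = bn$y))
}

classify_bwd <- function(dlogits, clf, net) {
  p <- net$params
  g <- list()
  l2 <- lin_bwd(dlogits, clf$cache$bn_y, p$clf2)
  g$clf2 <- list(W = l2$dW, b = l2$db)
  bb <- bn_bwd(l2$dx, p$clf1, clf$cache$bn_cache)
  ddp <- dropout_bwd(bb$dx, clf$cache$mask)
  dz1 <- gelu_bwd(ddp, clf$cache$z1)
  l1 <- lin_bwd(dz1, clf$cache$cfv, p$clf1)
  g$clf1 <- list(W = l1$dW, b = l1$db, gamma = bb$dgamma, beta = bb$dbeta)
  list(grads = g, dcfv = l1$dx)
}

# full pair forward / backward ------------------------------------------------

# XA, XB: n x fea_dim batches of similarity-profile rows.
forward_pair <- function(net, XA, XB, training = FALSE) {
  encA <- encode_fwd(XA, net)
  encB <- encode_fwd(XB, net)
  fus <- fuse_fwd(encA, encB, net)
  blocks <- c(list(encA$DA3, encB$DA3), unname(fus$FD))
  red <- reduce_fwd(blocks, net, training)
  net$buffers <- red$buffers
  clf <- classify_fwd(red$CFV, net, training)
  net$buffers <- clf$buffers
  list(encA = encA, encB = encB, fus = fus, red = red, clf = clf,
       CFV = red$CFV, logits = clf$logits, buffers = net$buffers)
}

# dlogits, dCFV, dReconA/B: upstream grads from the three loss terms.
backward_pair <- function(net, fw, dlogits, dCFV, dReconA, dReconB) {
  cfg <- net$cfg
  cb <- classify_bwd(dlogits, fw$clf, net)
  dcfv_total <- cb$dcfv + dCFV
  rb <- reduce_bwd(dcfv_total, fw$red, net)
  n_fd <- length(fw$fus$FD)
  dDA3_red <- rb$dblocks[[1]]
  dDB3_red <- rb$dblocks[[2]]
  zero_like <- function(m) matrix(0, nrow(m), ncol(m))
  if (n_fd > 0) {
    dFD <- setNames(rb$dblocks[3:(2 + n_fd)], names(fw$fus$FD))
    fb <- fuse_bwd(dFD, fw$fus, net)
  } else {
    fb <- list(grads = list(),
               dA = list(d1 = NULL, d2 = NULL, d3 = NULL),
               dB = list(d1 = NULL, d2 = NULL, d3 = NULL))
  }
  nz <- function(d, like) if (is.null(d)) zero_like(like) else d
  ebA <- encode_bwd(nz(fb$dA$d1, fw$encA$DA1), nz(fb$dA$d2, fw$encA$DA2),
                    nz(fb$dA$d3, fw$encA$DA3) + dDA3_red, dReconA,
                    fw$encA, net)
  ebB <- encode_bwd(nz(fb$dB$d1, fw$encB$DA1), nz(fb$dB$d2, fw$encB$DA2),
                    nz(fb$dB$d3, fw$encB$DA3) + dDB3_red, dReconB,
                    fw$encB, net)
  grads <- add_grads(cb$grads, rb$grads)
  grads <- add_grads(grads, fb$grads)
  grads <- add_grads(grads, ebA$grads)
  grads <- add_grads(grads, ebB$grads)
  grads
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) {
      a[[nm]] <- b[[nm]]
    } else {
      for (k in names(b[[nm]])) a[[nm]][[k]] <- a[[nm]][[k]] + b[[nm]][[k]]
    }
  }
  a
}

# user-facing wrappers --------------------------------------------------------

as_profile_batch <- function(x, fea_dim, what = "x") {
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(m) != fea_dim) {
    stop_invalid(what, " has width ", ncol(m), ", expected fea_dim = ", fea_dim)
  }
  m
}

#' Encode a drug profile
#'
#' Runs the per-drug encoder: multi-head self-attention over the token view
#' of the similarity profile (with residual), then the two encoder layers,
#' then the mirrored decoder. Deterministic in evaluation mode.
#'
#' @param x profile vector of width `fea_dim`, or a matrix of such rows.
#' @param net a network as returned by [init_network()] (or the `net` field
#'   of a trained model).
#' @return List with `DA1` (post-attention, width `fea_dim`), `DA2`
#'   (width `h1`), `DA3` (width `h2`), and `recon` (width `fea_dim`).
#' @export
encode_drug <- function(x, net) {
  m <- as_profile_batch(x, net$cfg$fea_dim)
  e <- encode_fwd(m, net)
  e$cache <- NULL
  e
}

#' Fuse the encoder outputs of a drug pair
#'
#' Multi-scale fusion concatenates DA1 with DB3, DA2 with DB2, and DA3 with
#' DB1, passing each through its own fully connected layer to a common width;
#' the construction is order-sensitive in (A, B) by design.
#'
#' @param encA,encB encoder outputs from [encode_drug()] for the two drugs.
#' @param net the network.
#' @return List of matrices `FD1`, `FD2`, `FD3` (or empty for
#'   `fusion_mode = "none"`).
#' @export
fuse_pair <- function(encA, encB, net) {
  if (net$cfg$fusion_mode == "none") return(list())
  fus <- fuse_fwd(encA, encB, net)
  setNames(fus$FD, c("FD1", "FD2", "FD3"))
}

#' Same-level (ablation) pair fusion
#'
#' Pairs encoder outputs at equal depths (DA1+DB1, DA2+DB2, DA3+DB3); an
#' ablation of the cross-depth multi-scale scheme with identical output
#' shapes so downstream layers are reusable. The network must have been
#' configured with `fusion_mode = "single_scale"`.
#'
#' @inheritParams fuse_pair
#' @return List of matrices `FD1`, `FD2`, `FD3`.
#' @export
single_scale_fuse <- function(encA, encB, net) {
  if (net$cfg$fusion_mode != "single_scale") {
    stop_config("single_scale_fuse requires fusion_mode = 'single_scale'")
  }
  fus <- fuse_fwd(encA, encB, net)
  setNames(fus$FD, c("FD1", "FD2", "FD3"))
}

#' Reduce pair features to the CFV embedding
#'
#' Concatenates DA3, DB3, and the fused features, applies self-attention over
#' the concatenated blocks (with residual), then `L` width-halving layers of
#' linear, GELU, dropout, batch-norm. The output CFV is the pair embedding
#' consumed by the contrastive loss and the classifier.
#'
#' @param DA3,DB3 encoder outputs (width `h2`).
#' @param FD1,FD2,FD3 fused features (width `f = h2`); omit (NULL) for
#'   `fusion_mode = "none"`.
#' @param net the network.
#' @param training use batch statistics and dropout (default FALSE).
#' @return CFV matrix of width `n_blocks * h2 / 2^L`.
#' @export
reduce_latent <- function(DA3, DB3, FD1 = NULL, FD2 = NULL, FD3 = NULL,
                          net, training = FALSE) {
  blocks <- Filter(Negate(is.null), list(DA3, DB3, FD1, FD2, FD3))
  if (length(blocks) != net$cfg$n_blocks) {
    stop_invalid("expected ", net$cfg$n_blocks, " input blocks, got ",
                 length(blocks))
  }
  blocks <- lapply(blocks, function(b) as_profile_batch(b, net$cfg$h2, "block"))
  reduce_fwd(blocks, net, training)$CFV
}

#' Classify a pair embedding
#'
#' Two fully connected layers; the second has one neuron per interaction
#' type. Softmax of the returned logits is the predicted type distribution.
#'
#' @param CFV pair embedding (vector or matrix of rows).
#' @param net the network.
#' @return Logits matrix with `n_classes` columns.
#' @export
classify <- function(CFV, net) {
  m <- as_profile_batch(CFV, net$cfg$cfv_dim, "CFV")
  classify_fwd(m, net, training = FALSE)$logits
}
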