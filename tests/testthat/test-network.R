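test_that("shape contracts hold across random valid configurations", {
  set.seed(21)
  for (rep in 1:8) {
    n_tok <- sample(2:4, 1)
    d_tok <- sample(c(16, 24), 1)
    fea <- n_tok * d_tok
    h1 <- 24; h2 <- 12
    mode <- sample(c("multi_scale", "single_scale", "none"), 1)
    L <- sample(0:2, 1)
    cfg <- network_config(fea_dim = fea, n_classes = sample(2:6, 1),
                          n_tokens = n_tok, h1 = h1, h2 = h2, L = L,
                          fusion_mode = mode, seed = rep)
    net <- init_network(cfg)
    nb <- 5
    x <- matrix(rnorm(nb * fea), nb)
    enc <- encode_drug(x, net)
    expect_equal(dim(enc$DA1), c(nb, fea))
    expect_equal(dim(enc$DA2), c(nb, h1))
    expect_equal(dim(enc$DA3), c(nb, h2))
    expect_equal(dim(enc$recon), c(nb, fea))
    encB <- encode_drug(matrix(rnorm(nb * fea), nb), net)
    fw <- ddiscl:::forward_pair(net, x, matrix(rnorm(nb * fea), nb))
    n_blocks <- if (mode == "none") 2 else 5
    expect_equal(ncol(fw$CFV), n_blocks * h2 / 2^L)
    expect_equal(dim(fw$logits), c(nb, cfg$n_classes))
    if (mode != "none") {
      fd <- if (mode == "multi_scale") fuse_pair(encB, enc, net)
            else single_scale_fuse(encB, enc, net)
      expect_named(fd, c("FD1", "FD2", "FD3"))
      for (m in fd) expect_equal(ncol(m), cfg$f)
    }
  }
})

test_that("fusion concatenation widths follow the cross-depth scheme", {
  cfg <- network_config(fea_dim = 64, n_classes = 3, n_tokens = 4,
                        h1 = 32, h2 = 16, seed = 1)
  expect_equal(nrow(init_network(cfg)$params$fuse_f1$W), 64 + 16)  # DA1+DB3
  expect_equal(nrow(init_network(cfg)$params$fuse_f2$W), 32 + 32)  # DA2+DB2
  expect_equal(nrow(init_network(cfg)$params$fuse_f3$W), 16 + 64)  # DA3+DB1
})

test_that("pair fusion is order-sensitive; classifier softmax normalises", {
  cfg <- network_config(fea_dim = 32, n_classes = 4, n_tokens = 4,
                        h1 = 16, h2 = 8, seed = 3)
  net <- init_network(cfg)
  a <- encode_drug(matrix(rnorm(32), 1), net)
  b <- encode_drug(matrix(rnorm(32), 1), net)
  ab <- fuse_pair(a, b, net)
  ba <- fuse_pair(b, a, net)
  expect_gt(max(abs(ab$FD1 - ba$FD1)), 1e-8)
  cfv <- reduce_latent(a$DA3, b$DA3, ab$FD1, ab$FD2, ab$FD3, net = net)
  p <- ddiscl:::softmax_rows(classify(cfv, net))
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("evaluation-mode forward is deterministic bitwise", {
  cfg <- network_config(fea_dim = 48, n_classes = 3, n_tokens = 4,
                        h1 = 24, h2 = 12, dropout_rate = 0.5, seed = 5)
  net <- init_network(cfg)
  x <- matrix(rnorm(4 * 48), 4)
  y <- matrix(rnorm(4 * 48), 4)
  f1 <- ddiscl:::forward_pair(net, x, y, training = FALSE)
  f2 <- ddiscl:::forward_pair(net, x, y, training = FALSE)
  expect_identical(f1$logits, f2$logits)
  expect_identical(f1$CFV, f2$CFV)
})

test_that("zeroed attention projection reduces DA1 to the residual input", {
  cfg <- network_config(fea_dim = 32, n_classes = 2, n_tokens = 4,
                        h1 = 16, h2 = 8, seed = 6)
  net <- init_network(cfg)
  net$params$enc_attn1$Wo[] <- 0
  net$params$enc_attn1$bo[] <- 0
  x <- matrix(rnorm(3 * 32), 3)
  enc <- encode_drug(x, net)
  expect_equal(enc$DA1, x)
})

test_that("invalid configurations are rejected", {
  expect_error(network_config(fea_dim = 30, n_classes = 3, n_tokens = 4),
               class = "ddiscl_invalid_config")
  expect_error(network_config(fea_dim = 32, n_classes = 1, n_tokens = 4),
               class = "ddiscl_invalid_config")
  expect_error(network_config(fea_dim = 32, n_classes = 3, n_tokens = 4,
                              h1 = 16, h2 = 6, L = 2),
               class = "ddiscl_invalid_config")
  expect_error(network_config(fea_dim = 32, n_classes = 3, n_tokens = 4,
                              n_heads = 3),
               class = "ddiscl_invalid_config")
  cfg <- network_config(fea_dim = 32, n_classes = 2, n_tokens = 4,
                        h1 = 16, h2 = 8)
  net <- init_network(cfg)
  expect_error(encode_drug(matrix(rnorm(10), 1), net),
               class = "ddiscl_invalid_input")
})

test_that("whole-model gradients match finite differences", {
  cfg <- network_config(fea_dim = 24, n_classes = 3, n_tokens = 4,
                        h1 = 16, h2 = 8, dropout_rate = 0, seed = 7)
  net <- init_network(cfg)
  set.seed(42)
  n <- 5
  XA <- matrix(rnorm(n * 24), n)
  XB <- matrix(rnorm(n * 24), n)
  y <- c(1, 2, 3, 1, 2)
  tc <- train_config(seed = 1)
  clc <- classification_loss_config(total_epochs = 10, switch_epoch = 5)
  loss_at <- function(net, active) {
    fw <- ddiscl:::forward_pair(net, XA, XB, training = TRUE)
    l_mse <- (mean((XA - fw$encA$recon)^2) + mean((XB - fw$encB$recon)^2)) / 2
    l_con <- supervised_contrastive_loss(fw$CFV, y, 0.05)
    l_cla <- if (active == "cross_entropy") {
      smoothed_cross_entropy(fw$logits, y, 0.3)
    } else focal_loss(fw$logits, y, 2)
    l_mse + l_con + l_cla
  }
  eps <- 1e-5
  for (active in c("cross_entropy", "focal")) {
    step <- ddiscl:::train_step(net, XA, XB, y, tc, clc, active)
    fg <- ddiscl:::flatten_params(step$grads)
    fp <- ddiscl:::flatten_params(net$params)
    for (nm in names(fp)) {
      i <- sample(length(fp[[nm]]), 1)
      np <- net
      fp2 <- fp; fp2[[nm]][i] <- fp2[[nm]][i] + eps
      np$params <- ddiscl:::unflatten_params(fp2, net$params)
      lp <- loss_at(np, active)
      fp2[[nm]][i] <- fp2[[nm]][i] - 2 * eps
      np$params <- ddiscl:::unflatten_params(fp2, net$params)
      lm <- loss_at(np, active)
      num <- (lp - lm) / (2 * eps)
      expect_equal(fg[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, "entry", i, "under", active))
    }
  }
})

test_that("L = 0 reduction degenerates to the attention passthrough width", {
  cfg <- network_config(fea_dim = 32, n_classes = 2, n_tokens = 4,
                        h1 = 16, h2 = 8, L = 0, seed = 8)
  expect_equal(cfg$cfv_dim, 5 * 8)
  net <- init_network(cfg)
  fw <- ddiscl:::forward_pair(net, matrix(rnorm(2 * 32), 2),
                              matrix(rnorm(2 * 32), 2))
  expect_equal(ncol(fw$CFV), 40)
})
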