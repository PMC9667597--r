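softmax_probs <- function(x) exp(x) / sum(exp(x))

test_that("mse_loss follows the per-dimension normalisation", {
  x <- c(0.2, 0.8, 0.5)
  expect_equal(mse_loss(x, x), 0)
  expect_equal(mse_loss(c(1, 0), c(0, 0)), 0.5)
  a <- runif(6); b <- runif(6)
  expect_equal(mse_loss(3 * a, 3 * b), 9 * mse_loss(a, b))
  expect_error(mse_loss(1:3, 1:4), class = "ddiscl_invalid_input")
})

test_that("contrastive loss vanishes in its analytic limit cases", {
  set.seed(1)
  z <- matrix(rnorm(2 * 5), 2)
  expect_equal(supervised_contrastive_loss(z, c(3, 3)), 0)
  z4 <- matrix(rnorm(4 * 6), 4)
  expect_equal(supervised_contrastive_loss(z4, 1:4), 0)
})

test_that("contrastive loss input validation", {
  expect_error(supervised_contrastive_loss(matrix(1, 1, 4), 1),
               class = "ddiscl_invalid_input")
  z <- matrix(rnorm(8), 2)
  z[2, ] <- 0
  expect_error(supervised_contrastive_loss(z, c(1, 1)),
               class = "ddiscl_invalid_input")
  expect_error(supervised_contrastive_loss(matrix(rnorm(8), 2), c(1, 1),
                                           temperature = 0),
               class = "ddiscl_invalid_input")
})

test_that("contrastive loss matches the triple-loop oracle and is >= 0", {
  set.seed(2)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    z <- matrix(rnorm(n * 8), n)
    y <- sample(1:3, n, replace = TRUE)
    got <- supervised_contrastive_loss(z, y, temperature = 0.05)
    expect_true(got >= 0)
    expect_equal(got, scl_loop_oracle(z, y, 0.05), tolerance = 1e-9)
  }
})

test_that("contrastive loss is invariant to permutation, rotation, scaling", {
  set.seed(3)
  n <- 8; d <- 6
  z <- matrix(rnorm(n * d), n)
  y <- c(1, 1, 2, 2, 2, 3, 3, 1)
  base <- supervised_contrastive_loss(z, y, 0.05)
  p <- sample(n)
  expect_equal(supervised_contrastive_loss(z[p, ], y[p], 0.05), base,
               tolerance = 1e-10)
  q <- qr.Q(qr(matrix(rnorm(d * d), d)))       # common orthogonal rotation
  expect_equal(supervised_contrastive_loss(z %*% q, y, 0.05), base,
               tolerance = 1e-8)
  z2 <- z
  z2[4, ] <- 7.5 * z2[4, ]                     # cosine: scale-free per vector
  expect_equal(supervised_contrastive_loss(z2, y, 0.05), base,
               tolerance = 1e-10)
})

test_that("contrastive gradient matches finite differences", {
  set.seed(4)
  n <- 6; d <- 5
  z <- matrix(rnorm(n * d), n)
  y <- c(1, 1, 2, 2, 3, 1)
  res <- supervised_contrastive_loss(z, y, 0.05, return_grad = TRUE)
  eps <- 1e-6
  for (probe in 1:12) {
    i <- sample(n, 1); j <- sample(d, 1)
    zp <- z; zp[i, j] <- zp[i, j] + eps
    zm <- z; zm[i, j] <- zm[i, j] - eps
    num <- (supervised_contrastive_loss(zp, y, 0.05) -
              supervised_contrastive_loss(zm, y, 0.05)) / (2 * eps)
    expect_equal(res$grad[i, j], num, tolerance = 1e-4)
  }
})

test_that("smoothed cross-entropy implements the uniform-mass convention", {
  logits <- c(2, -1, 0.5)
  # epsilon = 0 reduces to plain cross-entropy
  expect_equal(smoothed_cross_entropy(logits, 1, smoothing = 0),
               -log(softmax_probs(logits))[1])
  # epsilon = 0.3, K = 3, label 1: target (0.8, 0.1, 0.1)
  lp <- log(softmax_probs(logits))
  expect_equal(smoothed_cross_entropy(logits, 1, smoothing = 0.3),
               -sum(c(0.8, 0.1, 0.1) * lp))
  expect_error(smoothed_cross_entropy(logits, 5, 0.3),
               class = "ddiscl_invalid_input")
  expect_error(smoothed_cross_entropy(logits, 1, 1),
               class = "ddiscl_invalid_input")
})

test_that("focal loss limits and hand-computed value", {
  big <- c(50, 0, 0)
  expect_equal(focal_loss(big, 1, gamma = 2), 0, tolerance = 1e-10)
  # p_t = 0.5, gamma = 2 -> 0.25 * ln 2
  logits <- c(log(0.5), log(0.25), log(0.25))
  expect_equal(focal_loss(logits, 1, gamma = 2), 0.25 * log(2),
               tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:50) {
    lg <- rnorm(4, sd = 2)
    lab <- sample(4, 1)
    expect_equal(focal_loss(lg, lab, gamma = 0),
                 smoothed_cross_entropy(lg, lab, smoothing = 0),
                 tolerance = 1e-9)
    expect_lte(focal_loss(lg, lab, gamma = 2),
               smoothed_cross_entropy(lg, lab, smoothing = 0) + 1e-12)
  }
})

test_that("focal gradient matches finite differences", {
  set.seed(6)
  lg <- matrix(rnorm(3 * 4), 3)
  y <- c(2, 4, 1)
  g <- ddiscl:::focal_grad(lg, y, 2)
  eps <- 1e-6
  for (probe in 1:8) {
    i <- sample(3, 1); j <- sample(4, 1)
    lp <- lg; lp[i, j] <- lp[i, j] + eps
    lm <- lg; lm[i, j] <- lm[i, j] - eps
    num <- (focal_loss(lp, y, 2) - focal_loss(lm, y, 2)) / (2 * eps)
    expect_equal(g[i, j], num, tolerance = 1e-5)
  }
})

test_that("classification loss schedule switches at the configured epoch", {
  cfg <- classification_loss_config(switch_epoch = 40, total_epochs = 120)
  expect_identical(select_classification_loss(10, cfg), "cross_entropy")
  expect_identical(select_classification_loss(39, cfg), "cross_entropy")
  expect_identical(select_classification_loss(40, cfg), "focal")
  expect_identical(select_classification_loss(119, cfg), "focal")
  expect_error(select_classification_loss(120, cfg),
               class = "ddiscl_invalid_input")
  cfg0 <- classification_loss_config(switch_epoch = 0, total_epochs = 10)
  expect_identical(select_classification_loss(0, cfg0), "focal")
})

test_that("total_loss sums components and flags divergence", {
  b <- total_loss(0.1, 0.2, 0.3)
  expect_equal(b$total, 0.6)
  expect_equal(total_loss(0, 0, 0)$total, 0)
  expect_equal(total_loss(0.3, 0.1, 0.2)$total, b$total)
  err <- tryCatch(total_loss(0.1, NaN, 0.2), condition = identity)
  expect_s3_class(err, "ddiscl_divergence")
  expect_match(conditionMessage(err), "l_con")
})
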