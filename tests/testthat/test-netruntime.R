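test_that("conv_forward matches the brute-force oracle for both strides and paths", {
  set.seed(1)
  x <- array(stats::rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
  w <- array(stats::rnorm(4 * 3 * 3 * 3), c(4, 3, 3, 3))
  for (s in 1:2) for (p in 0:2) {
    ref <- conv_reference(x, w, s, p)
    fast <- mvcnet:::conv_forward(x, w, s, p)
    cached <- mvcnet:::conv_forward(x, w, s, p, keep_cache = TRUE)
    expect_equal(fast, ref, tolerance = 1e-12)
    expect_equal(cached, ref, tolerance = 1e-12,
                 ignore_attr = "cache")
  }
  # 1x1 channel edge cases
  x1 <- array(stats::rnorm(1 * 1 * 5 * 5), c(1, 1, 5, 5))
  w1 <- array(stats::rnorm(1 * 1 * 3 * 3), c(1, 1, 3, 3))
  expect_equal(mvcnet:::conv_forward(x1, w1, 1, 1),
               conv_reference(x1, w1, 1, 1), tolerance = 1e-12)
})

test_that("train_step gradients agree with finite differences", {
  # unmasked two-region graph: the loss surface is locally smooth at the
  # probed points, so central differences are exact; the masked variant
  # is checked separately (masked entries are excluded from updates by
  # contract, so their finite difference is intentionally nonzero)
  regions <- data.frame(name = c("A4", "A5"), area = "A",
                        layer = c("L4", "L5"), n = 256, grid = 8L,
                        channels = c(4L, 4L), stringsAsFactors = FALSE)
  edges <- data.frame(source = c("input", "A4"), target = c("A4", "A5"),
                      cin = c(2L, 4L), cout = c(4L, 4L), k = 3L,
                      stride = 1L, padding = 1L, dtw = NA, dp = NA,
                      masked = FALSE, stringsAsFactors = FALSE)
  arch <- new_architecture(regions, edges, n_classes = 2L,
                           input_size = 8L, input_channels = 2L)
  net <- net_init(arch, seed = 3)
  set.seed(5)
  x <- array(stats::rnorm(4 * 2 * 8 * 8), c(4, 2, 8, 8))
  y <- c(1L, 2L, 1L, 2L)
  loss_at <- function(n) {
    fw <- mvcnet:::net_forward_impl(n, x, train = TRUE)
    mvcnet:::softmax_xent(fw$logits, y)$loss
  }
  r <- train_step(net, x, y, lr = 1, momentum = 0)  # w_old - w_new = grad
  eps <- 1e-5
  for (ei in 1:2) {
    ana <- net$conv[[ei]]$w - r$net$conv[[ei]]$w
    set.seed(40 + ei)
    for (i in sample(length(ana), 5)) {
      np <- net; np$conv[[ei]]$w[i] <- np$conv[[ei]]$w[i] + eps
      nm <- net; nm$conv[[ei]]$w[i] <- nm$conv[[ei]]$w[i] - eps
      num <- (loss_at(np) - loss_at(nm)) / (2 * eps)
      expect_equal(ana[i], num, tolerance = 1e-5)
    }
  }
  # classifier weight gradient
  np <- net; np$Wc[7, 2] <- np$Wc[7, 2] + eps
  nm <- net; nm$Wc[7, 2] <- nm$Wc[7, 2] - eps
  num <- (loss_at(np) - loss_at(nm)) / (2 * eps)
  expect_equal(net$Wc[7, 2] - r$net$Wc[7, 2], num, tolerance = 1e-5)
  # batch-norm gamma gradient
  np <- net; np$bn$A4$gamma[2] <- np$bn$A4$gamma[2] + eps
  nm <- net; nm$bn$A4$gamma[2] <- nm$bn$A4$gamma[2] - eps
  num <- (loss_at(np) - loss_at(nm)) / (2 * eps)
  expect_equal(net$bn$A4$gamma[2] - r$net$bn$A4$gamma[2], num,
               tolerance = 1e-5)
  # masked contract: a masked-off weight never moves, even though the
  # loss is locally sensitive to it
  archm <- toy_architecture(dp = 1)
  netm <- net_init(archm, seed = 3)
  off <- which(netm$conv[[2]]$mask == 0)[1]
  rm_ <- train_step(netm, x, y, lr = 1, momentum = 0)
  expect_identical(rm_$net$conv[[2]]$w[off], 0)
})

test_that("region_forward sums inbound convs and applies ReLU", {
  x <- array(stats::rnorm(2 * 3 * 6 * 6), c(2, 3, 6, 6))
  wz <- array(0, c(4, 3, 3, 3))
  zero <- region_forward(list(a = x), list(list(w = wz, stride = 1,
                                                padding = 1)))
  expect_true(all(zero == 0))
  # identity-like 1x1 kernel, no BN: output = relu of channel mix
  wi <- array(0, c(3, 3, 1, 1))
  for (c in 1:3) wi[c, c, 1, 1] <- 1
  out <- region_forward(list(a = x), list(list(w = wi, stride = 1,
                                               padding = 0)))
  expect_equal(out, x * (x > 0), tolerance = 1e-12)
  # two inbound edges sum before the nonlinearity
  two <- region_forward(list(a = x, b = x),
                        list(list(w = wi, stride = 1, padding = 0),
                             list(w = wi, stride = 1, padding = 0)))
  expect_equal(two, 2 * x * (x > 0), tolerance = 1e-12)
  # mismatched inbound shapes name a wiring error
  half <- array(0, c(2, 3, 3, 3))
  expect_error(
    region_forward(list(a = x, b = half),
                   list(list(w = wi, stride = 1, padding = 0),
                        list(w = wi, stride = 1, padding = 0))),
    class = "mvcnet_config_error")
})

test_that("full published network forward has the printed shapes", {
  net <- net_init(published_arch, seed = 1)
  x <- gen_natural_images(2, 64, 3, seed = 2)
  out <- net_forward(net, x)
  expect_identical(dim(out$act$VISp4), c(2L, 26L, 64L, 64L))
  expect_identical(dim(out$act$VISal4), c(2L, 9L, 32L, 32L))
  expect_identical(dim(out$act$`VISpor2/3`), c(2L, 29L, 32L, 32L))
  expect_identical(dim(out$logits), c(2L, 1000L))
  expect_identical(published_arch$classifier$feature_width,
                   16 * (32 + 15 + 20 + 11 + 19 + 18 + 29))
  expect_true(all(vapply(out$act[-1], function(a) all(a >= 0), logical(1))))
  expect_error(net_forward(net, x[, , 1:32, , drop = FALSE]),
               class = "mvcnet_invalid_input")
})

test_that("eval-mode forward is deterministic and respects subgraph extraction", {
  arch <- toy_architecture()
  net <- net_init(arch, seed = 2)
  set.seed(9)
  imgs <- array(stats::rnorm(3 * 2 * 8 * 8), c(3, 2, 8, 8))
  imgs[3, , , ] <- imgs[1, , , ]  # duplicated image
  net <- net_calibrate(net, imgs)
  m1 <- extract_layer_activations(net, imgs, "A4")
  m2 <- extract_layer_activations(net, imgs, "A4")
  expect_identical(m1, m2)                   # bit-identical repeats
  expect_identical(m1[1, ], m1[3, ])         # identical inputs, identical rows
  expect_identical(dim(m1), c(3L, 4L * 8L * 8L))
  expect_error(extract_layer_activations(net, imgs, "nope"),
               class = "mvcnet_invalid_input")
  # batch-size split does not change values
  m3 <- extract_layer_activations(net, imgs, "A5", batch_size = 1L)
  m4 <- extract_layer_activations(net, imgs, "A5", batch_size = 3L)
  expect_equal(m3, m4, tolerance = 1e-12)
})

test_that("toy training: learns separable data, masks stay exactly zero", {
  arch <- toy_architecture(dp = 0.8)
  net <- net_init(arch, seed = 7)
  mask <- net$conv[[2]]$mask
  expect_true(any(mask == 0))  # the mask actually bites
  batch <- separable_batch()
  st <- NULL
  losses <- numeric(0)
  for (s in 1:200) {
    r <- train_step(net, batch$x, batch$y, lr = 0.05, momentum = 0.9,
                    state = st)
    net <- r$net; st <- r$state; losses <- c(losses, r$loss)
  }
  acc <- mean(max.col(r$logits) == batch$y)
  expect_gt(acc, 0.9)
  # mask preservation after the full schedule: exact zeros, same mask
  expect_identical(net$conv[[2]]$mask, mask)
  expect_identical(max(abs(net$conv[[2]]$w * (1 - mask))), 0)
})

test_that("repeated identical small-lr steps do not increase the loss", {
  arch <- toy_architecture(dp = 1)
  net <- net_init(arch, seed = 13)
  batch <- separable_batch(n = 16, seed = 21)
  r1 <- train_step(net, batch$x, batch$y, lr = 1e-3, momentum = 0)
  r2 <- train_step(r1$net, batch$x, batch$y, lr = 1e-3, momentum = 0)
  # tolerance for batch-norm statistics interacting across steps
  expect_lte(r2$loss, r1$loss + 1e-3)
  expect_true(is.finite(r2$loss))
})
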