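test_that("all variants preserve spatial dims and emit 3 channels", {
  img <- matrix(runif(64 * 64, -200, 300), 64, 64)
  for (v in c("unet", "attention_unet", "segnet")) {
    net <- build_network(network_config(v, depth = 4, base_channels = 2),
                         seed = 1)
    logits <- forward(net, img)
    expect_equal(dim(logits), c(64, 64, 3))
    expect_true(all(is.finite(logits)))
    # eval determinism
    expect_identical(logits, forward(net, img))
  }
})

test_that("depth-4 config has four down/upsampling stages and rejects bad sizes", {
  cfg <- network_config("unet", depth = 4, base_channels = 2)
  net <- build_network(cfg, seed = 1)
  expect_equal(sum(grepl("^enc", names(net$params))) / 2, 4)  # convA+convB
  expect_equal(sum(grepl("^dec\\d+\\.up$", names(net$params))), 4)
  expect_error(forward(net, matrix(0, 24, 24)), "divisible")
  expect_error(forward(net, matrix(c(NA, rep(0, 63 * 64 + 63)), 64, 64)),
               "finite")
})

test_that("parameter counts match hand-derived totals; skip concat widens U-Net", {
  unet <- build_network(network_config("unet", depth = 1, base_channels = 4),
                        seed = 1)
  segnet <- build_network(network_config("segnet", depth = 1,
                                         base_channels = 4), seed = 1)
  # U-Net depth 1 base 4: enc (40 + 148), bottleneck (296 + 584),
  # decoder (up 132 + convA 292 + convB 148), final 1x1 (15)
  expect_equal(n_parameters(unet), 40 + 148 + 296 + 584 + 132 + 292 + 148 + 15)
  # SegNet depth 1 base 4: enc convs 40 + 148 with norms 8 + 8,
  # dec convs 148 + 148 with norms 8 + 8, final 15
  expect_equal(n_parameters(segnet), 40 + 8 + 148 + 8 + 148 + 8 + 148 + 8 + 15)
  expect_gt(n_parameters(unet), n_parameters(segnet))
})

test_that("bottleneck spatial dims shrink by 2^depth", {
  bc <- asNamespace("bodycomp")
  net <- build_network(network_config("unet", depth = 4, base_channels = 2),
                       seed = 1)
  fw <- bc$forward_network(net, array(runif(64 * 64), c(64, 64, 1)),
                           keep_tape = TRUE)
  # last pool node output is the bottleneck input
  pool_dims <- vapply(fw$tape$nodes, function(n)
    if (n$op == "pool") dim(n$value)[1] else NA_integer_, 1L)
  expect_equal(min(pool_dims, na.rm = TRUE), 64 / 2^4)
})

test_that("zero final-layer weights give logits 0 and probability one-half", {
  net <- build_network(network_config("unet", depth = 2, base_channels = 2),
                       seed = 1)
  net$params$final$W[] <- 0
  net$params$final$b[] <- 0
  logits <- forward(net, matrix(runif(256), 16, 16))
  expect_true(all(logits == 0))
  expect_true(all(predict_mask(logits) == 1L))  # p = 0.5 >= 0.5 convention
})

test_that("predict_mask thresholds each channel independently at sigmoid >= t", {
  logits <- array(c(2, -2, 0, 5), dim = c(2, 2, 1))
  m <- predict_mask(logits)
  expect_equal(as.vector(m), c(1L, 0L, 1L, 1L))     # sigma(2)=.881, sigma(-2)=.119
  expect_equal(as.vector(predict_mask(logits, threshold = 0.9)),
               c(0L, 0L, 0L, 1L))
  expect_error(predict_mask(logits, threshold = 1), "\\(0,1\\)")
})

test_that("segnet unpooling restores max positions and zeros elsewhere", {
  bc <- asNamespace("bodycomp")
  x <- array(0, dim = c(4, 4, 1))
  x[, , 1] <- matrix(c(5, 1, 2, 0,
                       0, 3, 0, 1,
                       7, 2, 9, 4,
                       1, 0, 2, 3), 4, 4, byrow = TRUE)
  p <- bc$maxpool2_fwd(x)
  expect_equal(as.vector(p$out), c(5, 7, 2, 9))   # column-major pooled 2x2
  up <- bc$maxunpool2_fwd(p$out, p$idx, 4L, 4L)
  expect_equal(sum(up != 0), 4)
  expect_equal(up[x == 5], 5)
  expect_equal(up[x == 9], 9)
  expect_equal(sum(up), 5 + 7 + 2 + 9)
})

test_that("attention coefficients are bounded and gate limits behave", {
  bc <- asNamespace("bodycomp")
  net <- build_network(network_config("attention_unet", depth = 2,
                                      base_channels = 2), seed = 3)
  fw <- bc$forward_network(net, array(runif(256), c(16, 16, 1)),
                           keep_tape = TRUE)
  sig <- Filter(function(n) n$op == "sigmoid", fw$tape$nodes)
  expect_gt(length(sig), 0)
  for (n in sig) {
    expect_true(all(n$value >= 0 & n$value <= 1))
  }
  # closed gate (psi bias -> -inf) zeroes the skip contribution;
  # open gate (bias -> +inf) passes it through unchanged
  skip <- array(runif(32), c(4, 4, 2))
  alpha0 <- array(0, c(4, 4, 1)); alpha1 <- array(1, c(4, 4, 1))
  tp <- bc$tape_new()
  s_id <- bc$tp_input(tp, skip)
  expect_equal(bc$tp_value(tp, bc$tp_gate_mul(tp, s_id, bc$tp_input(tp, alpha0))),
               skip * 0)
  expect_equal(bc$tp_value(tp, bc$tp_gate_mul(tp, s_id, bc$tp_input(tp, alpha1))),
               skip)
})

test_that("backpropagation matches finite differences through every variant", {
  bc <- asNamespace("bodycomp")
  loss_of <- function(net, img, mask) {
    fw <- bc$forward_network(net, img)
    combined_loss(1 / (1 + exp(-fw$logits)), mask)
  }
  for (v in c("unet", "attention_unet", "segnet")) {
    net <- build_network(network_config(v, depth = 2, base_channels = 2),
                         seed = 42)
    set.seed(7)
    img <- array(runif(64), c(8, 8, 1))
    mask <- array(rbinom(192, 1, 0.4), c(8, 8, 3))
    fw <- bc$forward_network(net, img, keep_tape = TRUE)
    g <- bc$loss_grad_logits(fw$logits, mask)
    pg <- bc$tape_backward(fw$tape, fw$out_id, g, net$params)
    eps <- 1e-6
    for (nm in sample(names(pg), 5)) {
      comp <- names(pg[[nm]])[1]
      i <- sample(length(pg[[nm]][[comp]]), 1)
      n1 <- net; n1$params[[nm]][[comp]][i] <- n1$params[[nm]][[comp]][i] + eps
      n2 <- net; n2$params[[nm]][[comp]][i] <- n2$params[[nm]][[comp]][i] - eps
      fd <- (loss_of(n1, img, mask) - loss_of(n2, img, mask)) / (2 * eps)
      an <- pg[[nm]][[comp]][i]
      expect_lt(abs(fd - an) / max(1e-2, abs(fd) + abs(an)), 1e-2)
    }
  }
})
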