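#' Network configuration for the U-shaped segmentation models
#'
#' @param variant one of `"unet"`, `"attention_unet"`, `"segnet"`.
#' @param depth number of downsampling/upsampling stages (default 4).
#' @param base_channels feature channels of the first encoder block. The
#'   default (16) is a light profile suitable for CPU training; widths double
#'   at each stage.
#' @param in_channels input image channels (CT slices are single-channel).
#' @param out_channels output channels; fixed at 3 tissue classes
#'   (subcutaneous fat, visceral fat, muscle).
#' @param hu_window Hounsfield-unit window clipped and rescaled to \[0, 1\]
#'   before the network.
#' @return an object of class `network_config`.
#' @export
network_config <- function(variant = c("unet", "attention_unet", "segnet"),
                           depth = 4L, base_channels = 16L,
                           in_channels = 1L, out_channels = 3L,
                           hu_window = c(-200, 300)) {
  variant <- match.arg(variant)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  if (out_channels != 3L) stop("out_channels is fixed at 3 tissue classes")
  structure(list(variant = variant, depth = depth,
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 hu_window = hu_window),
            class = "network_config")
}

new_conv <- function(cin, cout, k) {
  sdw <- sqrt(2 / (k * k * cin))
  list(W = matrix(rnorm(k * k * cin * cout, sd = sdw), ncol = cout),
       b = numeric(cout), kh = k, kw = k)
}

new_upconv <- function(cin, cout) {
  sdw <- sqrt(2 / (4 * cin))
  list(W = matrix(rnorm(4 * cin * cout, sd = sdw), ncol = cout),
       b = numeric(cout))
}

new_norm <- function(c) list(gamma = rep(1, c), beta = numeric(c))

#' Build a segmentation network
#'
#' Constructs randomly initialized weights for one of three U-shaped
#' encoder-decoder architectures. All use encoder blocks of two 3x3
#' convolutions with ReLU followed by 2x2 max pooling (stride 2, channel
#' doubling) and end in a 1x1 convolution to 3 channels with independent
#' per-channel sigmoids. The U-Net decoder upsamples with 2x2 up-convolutions
#' and concatenates the encoder skip features; the Attention U-Net adds an
#' additive attention gate on each skip path; SegNet has no skip
#' concatenation and upsamples by unpooling with the encoder's max-pooling
#' indices, with per-channel feature normalization in its blocks.
#' Convolutions use same-padding so output spatial dims equal input dims.
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialization (He-scaled normal).
#' @return an object of class `seg_network` with elements `config` and
#'   `params` (named list of weight tensors).
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  set.seed(seed)
  d <- config$depth
  base <- config$base_channels
  ch <- base * 2^(seq_len(d) - 1)         # encoder widths
  params <- list()
  cin <- config$in_channels
  for (i in seq_len(d)) {
    params[[sprintf("enc%d.convA", i)]] <- new_conv(cin, ch[i], 3L)
    params[[sprintf("enc%d.convB", i)]] <- new_conv(ch[i], ch[i], 3L)
    if (config$variant == "segnet") {
      params[[sprintf("enc%d.normA", i)]] <- new_norm(ch[i])
      params[[sprintf("enc%d.normB", i)]] <- new_norm(ch[i])
    }
    cin <- ch[i]
  }
  if (config$variant != "segnet") {
    cb <- base * 2^d                      # bottleneck width
    params[["bott.convA"]] <- new_conv(ch[d], cb, 3L)
    params[["bott.convB"]] <- new_conv(cb, cb, 3L)
    above <- cb
    for (i in seq(d, 1L)) {
      params[[sprintf("dec%d.up", i)]] <- new_upconv(above, ch[i])
      if (config$variant == "attention_unet") {
        ci <- max(1L, ch[i] %/% 2L)
        params[[sprintf("dec%d.attX", i)]] <- new_conv(ch[i], ci, 1L)
        params[[sprintf("dec%d.attG", i)]] <- new_conv(ch[i], ci, 1L)
        params[[sprintf("dec%d.attPsi", i)]] <- new_conv(ci, 1L, 1L)
      }
      params[[sprintf("dec%d.convA", i)]] <- new_conv(2L * ch[i], ch[i], 3L)
      params[[sprintf("dec%d.convB", i)]] <- new_conv(ch[i], ch[i], 3L)
      above <- ch[i]
    }
  } else {
    for (i in seq(d, 1L)) {
      cout <- if (i > 1L) ch[i - 1L] else ch[1L]
      params[[sprintf("dec%d.convA", i)]] <- new_conv(ch[i], ch[i], 3L)
      params[[sprintf("dec%d.convB", i)]] <- new_conv(ch[i], cout, 3L)
      params[[sprintf("dec%d.normA", i)]] <- new_norm(ch[i])
      params[[sprintf("dec%d.normB", i)]] <- new_norm(cout)
    }
  }
  params[["final"]] <- new_conv(ch[1L], config$out_channels, 1L)
  structure(list(config = config, params = params), class = "seg_network")
}

#' @export
print.seg_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<seg_network> %s, depth %d, base %d channels, %d parameters\n",
              cfg$variant, cfg$depth, cfg$base_channels, n_parameters(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param network a `seg_network` or `seg_fit`.
#' @return integer parameter count.
#' @export
n_parameters <- function(network) {
  if (inherits(network, "seg_fit")) network <- network$network
  sum(vapply(network$params, function(p) {
    sum(vapply(p[names(p) %in% c("W", "b", "gamma", "beta")], length, 0L))
  }, 0))
}

check_input_dims <- function(x, depth) {
  d <- dim(x)
  if (any(d[1:2] %% 2^depth != 0))
    stop("input spatial dims (", d[1], "x", d[2],
         ") must be divisible by 2^depth = ", 2^depth)
  if (!all(is.finite(x))) stop("input contains non-finite pixels")
}

# additive attention gate: alpha = sigmoid(psi(relu(Wx*x + Wg*g)))
tp_attention <- function(tp, skip_id, gate_id, i, params) {
  tx <- tp_conv(tp, skip_id, sprintf("dec%d.attX", i),
                params[[sprintf("dec%d.attX", i)]])
  tg <- tp_conv(tp, gate_id, sprintf("dec%d.attG", i),
                params[[sprintf("dec%d.attG", i)]])
  s <- tp_relu(tp, tp_add2(tp, tx, tg))
  a <- tp_sigmoid(tp, tp_conv(tp, s, sprintf("dec%d.attPsi", i),
                              params[[sprintf("dec%d.attPsi", i)]]))
  tp_gate_mul(tp, skip_id, a)
}

# Forward pass; returns logits and, if keep_tape, the tape for backprop.
forward_network <- function(network, image, keep_tape = FALSE) {
  cfg <- network$config
  params <- network$params
  if (length(dim(image)) == 2L)
    image <- array(image, dim = c(dim(image), 1L))
  check_input_dims(image, cfg$depth)
  tp <- tape_new()
  h <- tp_input(tp, image)
  d <- cfg$depth
  skips <- integer(d); pools <- integer(d)
  segnet <- cfg$variant == "segnet"
  for (i in seq_len(d)) {
    h <- tp_conv(tp, h, sprintf("enc%d.convA", i), params[[sprintf("enc%d.convA", i)]])
    if (segnet) h <- tp_norm(tp, h, sprintf("enc%d.normA", i), params[[sprintf("enc%d.normA", i)]])
    h <- tp_relu(tp, h)
    h <- tp_conv(tp, h, sprintf("enc%d.convB", i), params[[sprintf("enc%d.convB", i)]])
    if (segnet) h <- tp_norm(tp, h, sprintf("enc%d.normB", i), params[[sprintf("enc%d.normB", i)]])
    h <- tp_relu(tp, h)
    skips[i] <- h
    h <- tp_pool(tp, h)
    pools[i] <- h
  }
  if (!segnet) {
    h <- tp_relu(tp, tp_conv(tp, h, "bott.convA", params[["bott.convA"]]))
    h <- tp_relu(tp, tp_conv(tp, h, "bott.convB", params[["bott.convB"]]))
    for (i in seq(d, 1L)) {
      u <- tp_upconv(tp, h, sprintf("dec%d.up", i), params[[sprintf("dec%d.up", i)]])
      s <- if (cfg$variant == "attention_unet")
        tp_attention(tp, skips[i], u, i, params) else skips[i]
      h <- tp_concat(tp, s, u)
      h <- tp_relu(tp, tp_conv(tp, h, sprintf("dec%d.convA", i), params[[sprintf("dec%d.convA", i)]]))
      h <- tp_relu(tp, tp_conv(tp, h, sprintf("dec%d.convB", i), params[[sprintf("dec%d.convB", i)]]))
    }
  } else {
    for (i in seq(d, 1L)) {
      h <- tp_unpool(tp, h, pools[i])
      h <- tp_conv(tp, h, sprintf("dec%d.convA", i), params[[sprintf("dec%d.convA", i)]])
      h <- tp_norm(tp, h, sprintf("dec%d.normA", i), params[[sprintf("dec%d.normA", i)]])
      h <- tp_relu(tp, h)
      h <- tp_conv(tp, h, sprintf("dec%d.convB", i), params[[sprintf("dec%d.convB", i)]])
      h <- tp_norm(tp, h, sprintf("dec%d.normB", i), params[[sprintf("dec%d.normB", i)]])
      h <- tp_relu(tp, h)
    }
  }
  out <- tp_conv(tp, h, "final", params[["final"]])
  logits <- tp_value(tp, out)
  if (keep_tape) list(logits = logits, tape = tp, out_id = out)
  else list(logits = logits)
}

#' Run a network forward on a CT slice
#'
#' Produces per-pixel, per-tissue logits; probabilities are the elementwise
#' sigmoid of these. The Hounsfield window from the network config is applied
#' first unless `normalize = FALSE`.
#'
#' @param network a `seg_network`.
#' @param image 2D numeric matrix (HU values).
#' @param normalize apply the config's HU window/rescale (default TRUE).
#' @return 3D array (H, W, 3) of logits, channel order
#'   (subcutaneous fat, visceral fat, muscle).
#' @export
forward <- function(network, image, normalize = TRUE) {
  if (normalize) image <- normalize_hu(image, network$config$hu_window)
  forward_network(network, image)$logits
}

#' Clip a HU image to a window and rescale to \[0, 1\]
#' @param image numeric matrix or array of HU values.
#' @param window length-2 numeric, lower and upper HU bound.
#' @export
normalize_hu <- function(image, window = c(-200, 300)) {
  (pmin(pmax(image, window[1]), window[2]) - window[1]) / diff(window)
}

#' Threshold logits into a binary composition mask
#'
#' Each channel is thresholded independently: pixel i of channel c is
#' foreground iff sigmoid(logit) >= threshold.
#'
#' @param logits 3D array of per-channel logits.
#' @param threshold probability threshold in (0, 1), default 0.5.
#' @return integer array of 0/1 with the same dims.
#' @export
predict_mask <- function(logits, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  p <- 1 / (1 + exp(-logits))
  array((p >= threshold) + 0L, dim = dim(logits))
}
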