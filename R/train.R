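#' Training configuration
#'
#' Defaults follow the segmentation training protocol: Adam, four images per
#' minibatch, learning rate 1e-3, 100 epochs, 8:1:1 patient-level split.
#'
#' @param batch_size images per minibatch.
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the training set.
#' @param seed integer seed controlling shuffling.
#' @param split_ratio train/validation/test proportions.
#' @export
training_config <- function(batch_size = 4L, learning_rate = 1e-3,
                            epochs = 100L, seed = 1L,
                            split_ratio = c(8, 1, 1)) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (any(split_ratio <= 0)) stop("split ratios must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), split_ratio = split_ratio),
            class = "training_config")
}

#' Split items into train/validation/test at the patient level
#'
#' No patient's images span two sets. Set sizes are the largest-remainder
#' apportionment of the ratio over patients (60 patients at 8:1:1 gives
#' 48/6/6).
#'
#' @param patient_ids vector of patient identifiers, one per item (items
#'   belonging to the same patient share an id).
#' @param ratio positive weights for (train, validation, test).
#' @param seed integer seed for the random patient assignment.
#' @return list of integer index vectors `train`, `val`, `test` into the
#'   original items.
#' @export
split_dataset <- function(patient_ids, ratio = c(8, 1, 1), seed = 1L) {
  pats <- unique(patient_ids)
  np <- length(pats)
  if (np < length(ratio)) stop("fewer patients (", np, ") than groups")
  frac <- ratio / sum(ratio)
  sizes <- floor(np * frac)
  rem <- np - sum(sizes)
  if (rem > 0) {
    extra <- order(np * frac - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  set.seed(seed)
  shuffled <- sample(pats)
  grp <- rep(c("train", "val", "test"), times = sizes)
  assign <- setNames(grp, shuffled)
  membership <- unname(assign[as.character(patient_ids)])
  list(train = which(membership == "train"),
       val   = which(membership == "val"),
       test  = which(membership == "test"))
}

adam_init <- function(params) {
  lapply(params, function(p) {
    lapply(p[names(p) %in% c("W", "b", "gamma", "beta")], function(v)
      list(m = v * 0, v = v * 0))
  })
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    for (comp in names(g)) {
      st <- state[[nm]][[comp]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[comp]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[comp]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[nm]][[comp]] <- params[[nm]][[comp]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[nm]][[comp]] <- st
    }
  }
  list(params = params, state = state)
}

#' Train a segmentation network
#'
#' Minimizes the combined BCE + soft Dice loss with Adam. Inputs are
#' HU-windowed and rescaled using the network config. The returned fit keeps
#' the weights with the lowest validation loss (or the final weights when no
#' validation set is given).
#'
#' @param network a [build_network()] object.
#' @param train_data list of samples, each `list(image = matrix, mask = HxWx3
#'   binary array)`.
#' @param val_data optional validation samples in the same format.
#' @param config a [training_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `seg_fit`: the trained `network`, a `history`
#'   data frame (epoch, train_loss, val_loss, val_dsc per tissue) and the
#'   `config`.
#' @export
train_model <- function(network, train_data, val_data = NULL,
                        config = training_config(), verbose = FALSE) {
  stopifnot(inherits(network, "seg_network"), length(train_data) > 0)
  params <- network$params
  state <- adam_init(params)
  set.seed(config$seed)
  hw <- network$config$hu_window
  prep <- function(s) {
    s$image <- normalize_hu(s$image, hw)
    s$mask <- array(as.numeric(s$mask), dim = dim(s$mask))
    s
  }
  train_data <- lapply(train_data, prep)
  if (!is.null(val_data)) val_data <- lapply(val_data, prep)
  nt <- length(train_data)
  hist_rows <- vector("list", config$epochs)
  best <- list(loss = Inf, params = params)
  t <- 0L
  net <- network
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(nt)
    epoch_loss <- 0
    for (start in seq(1L, nt, by = config$batch_size)) {
      batch <- train_data[ord[start:min(start + config$batch_size - 1L, nt)]]
      grads <- NULL
      for (s in batch) {
        net$params <- params
        fw <- forward_network(net, s$image, keep_tape = TRUE)
        if (!all(is.finite(fw$logits)))
          stop("training diverged: non-finite logits at epoch ", epoch)
        prob <- 1 / (1 + exp(-fw$logits))
        epoch_loss <- epoch_loss + combined_loss(prob, s$mask)
        g <- loss_grad_logits(fw$logits, s$mask)
        pg <- tape_backward(fw$tape, fw$out_id, g, params)
        grads <- if (is.null(grads)) pg else merge_grads(grads, pg)
      }
      t <- t + 1L
      upd <- adam_step(params, grads, state, config$learning_rate, t)
      params <- upd$params; state <- upd$state
    }
    row <- data.frame(epoch = epoch, train_loss = epoch_loss,
                      val_loss = NA_real_, val_dsc_subq = NA_real_,
                      val_dsc_visceral = NA_real_, val_dsc_muscle = NA_real_)
    if (!is.null(val_data)) {
      net$params <- params
      ev <- evaluate_on(net, val_data)
      row$val_loss <- ev$loss
      row[c("val_dsc_subq", "val_dsc_visceral", "val_dsc_muscle")] <-
        as.list(ev$dsc)
      if (ev$loss < best$loss) best <- list(loss = ev$loss, params = params)
    }
    hist_rows[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d  train %.3f  val %s", epoch, epoch_loss,
                      ifelse(is.na(row$val_loss), "-",
                             sprintf("%.3f", row$val_loss))))
  }
  net$params <- if (is.finite(best$loss)) best$params else params
  structure(list(network = net, history = do.call(rbind, hist_rows),
                 config = config),
            class = "seg_fit")
}

merge_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- acc_param(a[[nm]], b[[nm]])
  a
}

# mean loss/DSC over a (already HU-normalized) sample list
evaluate_on <- function(net, samples) {
  loss <- 0
  dsc <- matrix(NA_real_, length(samples), 3)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    logits <- forward_network(net, s$image)$logits
    prob <- 1 / (1 + exp(-logits))
    loss <- loss + combined_loss(prob, s$mask)
    pred <- predict_mask(logits)
    for (k in 1:3)
      dsc[i, k] <- agreement(confusion_counts(pred[, , k], s$mask[, , k]))$dsc
  }
  list(loss = loss, dsc = colMeans(dsc))
}

#' @export
print.seg_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<seg_fit> %s trained %d epochs; final train loss %.4f\n",
              x$network$config$variant, nrow(h), h$train_loss[nrow(h)]))
  if (!all(is.na(h$val_loss)))
    cat(sprintf("  best val loss %.4f (epoch %d)\n", min(h$val_loss),
                which.min(h$val_loss)))
  invisible(x)
}

#' @export
plot.seg_fit <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "training history", ...)
  if (!all(is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

#' Segment CT slices with a trained network
#'
#' @param object a `seg_fit`.
#' @param image a 2D HU matrix or a `ct_volume` (each slice segmented).
#' @param type `"mask"` for thresholded binary channels, `"prob"` for
#'   sigmoid probabilities.
#' @param threshold probability threshold for `type = "mask"`.
#' @param ... unused.
#' @return an (H, W, 3) array for one slice, or a list of them for a volume.
#' @export
predict.seg_fit <- function(object, image, type = c("mask", "prob"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  one <- function(img) {
    logits <- forward(object$network, img)
    if (type == "mask") predict_mask(logits, threshold)
    else 1 / (1 + exp(-logits))
  }
  if (inherits(image, "ct_volume"))
    lapply(seq_len(n_slices(image)), function(i) one(image$slices[, , i]))
  else one(image)
}
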