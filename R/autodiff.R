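# Minimal reverse-mode engine over feature-map cubes (H x W x C arrays).
# Each forward helper appends a node to the tape; backward() walks the tape in
# reverse, accumulating gradients for node values and named parameters.
# Parameters are named list entries in the network's parameter store; their
# gradients are returned as a parallel named list.

tape_new <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$n <- 0L
  env
}

tp_push <- function(tp, op, value, inputs = integer(), param = NULL,
                    cache = NULL) {
  tp$n <- tp$n + 1L
  tp$nodes[[tp$n]] <- list(op = op, value = value, inputs = inputs,
                           param = param, cache = cache)
  tp$n
}

tp_value <- function(tp, id) {
  force(id)  # id may be a nested helper call that pushes onto the tape
  tp$nodes[[id]]$value
}

tp_input <- function(tp, x) tp_push(tp, "input", x)

tp_conv <- function(tp, id, pname, p) {
  x <- tp_value(tp, id)
  y <- conv2d_fwd(x, p$W, p$b, p$kh, p$kw)
  tp_push(tp, "conv", y, id, param = pname, cache = list(kh = p$kh, kw = p$kw))
}

tp_relu <- function(tp, id) {
  y <- tp_value(tp, id)
  y[y < 0] <- 0
  tp_push(tp, "relu", y, id)
}

tp_sigmoid <- function(tp, id) {
  y <- 1 / (1 + exp(-tp_value(tp, id)))
  tp_push(tp, "sigmoid", y, id)
}

tp_pool <- function(tp, id) {
  x <- tp_value(tp, id)
  r <- maxpool2_fwd(x)
  tp_push(tp, "pool", r$out, id,
          cache = list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
}

# SegNet unpooling; pool_id names the encoder pool node whose indices are used
tp_unpool <- function(tp, id, pool_id) {
  x <- tp_value(tp, id)
  pc <- tp$nodes[[pool_id]]$cache
  y <- maxunpool2_fwd(x, pc$idx, pc$H, pc$W)
  tp_push(tp, "unpool", y, id, cache = list(idx = pc$idx))
}

tp_upconv <- function(tp, id, pname, p) {
  y <- upconv2_fwd(tp_value(tp, id), p$W, p$b)
  tp_push(tp, "upconv", y, id, param = pname)
}

tp_concat <- function(tp, id1, id2) {
  x1 <- tp_value(tp, id1); x2 <- tp_value(tp, id2)
  d1 <- dim(x1); d2 <- dim(x2)
  y <- array(c(x1, x2), dim = c(d1[1], d1[2], d1[3] + d2[3]))
  tp_push(tp, "concat", y, c(id1, id2), cache = list(c1 = d1[3]))
}

tp_add2 <- function(tp, id1, id2) {
  tp_push(tp, "add", tp_value(tp, id1) + tp_value(tp, id2), c(id1, id2))
}

# elementwise product with broadcast of a single-channel gate over channels
tp_gate_mul <- function(tp, skip_id, alpha_id) {
  s <- tp_value(tp, skip_id); a <- tp_value(tp, alpha_id)
  C <- dim(s)[3]
  y <- s * as.vector(a)   # recycles the (H*W) gate plane across channels
  tp_push(tp, "gate_mul", y, c(skip_id, alpha_id), cache = list(C = C))
}

# per-channel spatial normalization with learnable scale/shift
tp_norm <- function(tp, id, pname, p, eps = 1e-5) {
  x <- tp_value(tp, id)
  d <- dim(x); m <- d[1] * d[2]
  xm <- matrix(x, nrow = m)
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  sdv <- sqrt(v + eps)
  z <- sweep(sweep(xm, 2, mu), 2, sdv, "/")
  y <- sweep(sweep(z, 2, p$gamma, "*"), 2, p$beta, "+")
  tp_push(tp, "norm", array(y, d), id, param = pname,
          cache = list(z = z, sdv = sdv))
}

tape_backward <- function(tp, out_id, grad_out, params) {
  vgrads <- vector("list", tp$n)
  pgrads <- list()
  acc <- function(slot, g) {
    if (is.null(vgrads[[slot]])) vgrads[[slot]] <<- g
    else vgrads[[slot]] <<- vgrads[[slot]] + g
  }
  vgrads[[out_id]] <- grad_out
  for (nid in seq(tp$n, 1L)) {
    g <- vgrads[[nid]]
    if (is.null(g)) next
    nd <- tp$nodes[[nid]]
    switch(nd$op,
      input = NULL,
      conv = {
        p <- params[[nd$param]]
        x <- tp_value(tp, nd$inputs[1])
        r <- conv2d_bwd(x, p$W, g, nd$cache$kh, nd$cache$kw)
        acc(nd$inputs[1], r$gx)
        pgrads[[nd$param]] <- acc_param(pgrads[[nd$param]],
                                        list(W = r$gW, b = as.numeric(r$gb)))
      },
      relu = acc(nd$inputs[1], g * (nd$value > 0)),
      sigmoid = acc(nd$inputs[1], g * nd$value * (1 - nd$value)),
      pool = acc(nd$inputs[1],
                 maxpool2_bwd(g, nd$cache$idx, nd$cache$H, nd$cache$W)),
      unpool = acc(nd$inputs[1], maxunpool2_bwd(g, nd$cache$idx)),
      upconv = {
        p <- params[[nd$param]]
        x <- tp_value(tp, nd$inputs[1])
        r <- upconv2_bwd(x, p$W, g)
        acc(nd$inputs[1], r$gx)
        pgrads[[nd$param]] <- acc_param(pgrads[[nd$param]],
                                        list(W = r$gW, b = as.numeric(r$gb)))
      },
      concat = {
        c1 <- nd$cache$c1
        d <- dim(nd$value)
        acc(nd$inputs[1], array(g[, , seq_len(c1), drop = FALSE],
                                dim = c(d[1], d[2], c1)))
        acc(nd$inputs[2], array(g[, , (c1 + 1):d[3], drop = FALSE],
                                dim = c(d[1], d[2], d[3] - c1)))
      },
      add = { acc(nd$inputs[1], g); acc(nd$inputs[2], g) },
      gate_mul = {
        s <- tp_value(tp, nd$inputs[1])
        a <- tp_value(tp, nd$inputs[2])
        acc(nd$inputs[1], g * as.vector(a))
        ga <- apply(g * s, c(1, 2), sum)
        acc(nd$inputs[2], array(ga, dim = dim(a)))
      },
      norm = {
        p <- params[[nd$param]]
        d <- dim(nd$value); m <- d[1] * d[2]
        gm <- matrix(g, nrow = m)
        z <- nd$cache$z
        ggamma <- colSums(gm * z)
        gbeta <- colSums(gm)
        gz <- sweep(gm, 2, p$gamma, "*")
        # d/dx of (x - mu)/sd with spatial mean/var
        gx <- sweep(gz - matrix(colMeans(gz), m, ncol(gz), byrow = TRUE) -
                      z * matrix(colMeans(gz * z), m, ncol(gz), byrow = TRUE),
                    2, nd$cache$sdv, "/")
        acc(nd$inputs[1], array(gx, d))
        pgrads[[nd$param]] <- acc_param(pgrads[[nd$param]],
                                        list(gamma = ggamma, beta = gbeta))
      },
      stop("unknown op: ", nd$op)
    )
  }
  pgrads
}

acc_param <- function(old, new) {
  if (is.null(old)) return(new)
  for (nm in names(new)) old[[nm]] <- old[[nm]] + new[[nm]]
  old
}
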