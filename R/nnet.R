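# Minimal computational layers for the encoder-decoder segmenter.
# Tensors are column-major R arrays [h, w, c, n]; conv / pool kernels live
# in src/ops.cpp, everything else is plain array arithmetic.

conv_fwd <- function(x, p) .conv2d_fwd(x, p$W, p$b)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

downsum2 <- function(dy) {
  # gradient of nearest-neighbour x2 upsampling: sum each 2x2 block
  d <- dim(dy)
  odd_r <- seq(1L, d[1], 2L); odd_c <- seq(1L, d[2], 2L)
  dy[odd_r, odd_c, , , drop = FALSE] +
    dy[odd_r + 1L, odd_c, , , drop = FALSE] +
    dy[odd_r, odd_c + 1L, , , drop = FALSE] +
    dy[odd_r + 1L, odd_c + 1L, , , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

he_init <- function(k, ci, co) {
  list(W = array(stats::rnorm(k * k * ci * co, 0, sqrt(2 / (k * k * ci))),
                 c(k, k, ci, co)),
       b = numeric(co))
}

# ---- network definition --------------------------------------------------

# Parameter layout for depth d, base width w0 (w_i = w0 * 2^(i-1)):
#   enc{i}_c1, enc{i}_c2  : two 3x3 convs per encoder level, then 2x2 maxpool
#   bott_c1, bott_c2      : bottleneck convs at width w0 * 2^d
#   up{i}, mrg{i}         : x2 upsample + 3x3 conv to w_i, concat skip,
#                           3x3 merge conv (2 w_i -> w_i)
#   head                  : 1x1 conv to a single logit channel
init_params <- function(depth, base_width, in_channels = 3L) {
  widths <- base_width * 2^(seq_len(depth) - 1L)
  p <- list()
  ci <- in_channels
  for (i in seq_len(depth)) {
    p[[sprintf("enc%d_c1", i)]] <- he_init(3L, ci, widths[i])
    p[[sprintf("enc%d_c2", i)]] <- he_init(3L, widths[i], widths[i])
    ci <- widths[i]
  }
  wb <- base_width * 2^depth
  p[["bott_c1"]] <- he_init(3L, ci, wb)
  p[["bott_c2"]] <- he_init(3L, wb, wb)
  ci <- wb
  for (i in rev(seq_len(depth))) {
    p[[sprintf("up%d", i)]] <- he_init(3L, ci, widths[i])
    p[[sprintf("mrg%d", i)]] <- he_init(3L, 2L * widths[i], widths[i])
    ci <- widths[i]
  }
  p[["head"]] <- he_init(1L, ci, 1L)
  p
}

n_parameters <- function(params) {
  sum(vapply(params, function(p) length(p$W) + length(p$b), 0))
}

# Forward pass; returns logits and, optionally, the cache needed by backward.
net_forward <- function(params, x, depth, keep_cache = FALSE) {
  d <- dim(x)
  if (d[1] %% 2^depth != 0 || d[2] %% 2^depth != 0) {
    stopf("patch size %d x %d is not divisible by 2^depth = %d",
          d[1], d[2], 2^depth)
  }
  cache <- list(x = x)
  skips <- vector("list", depth)
  h <- x
  for (i in seq_len(depth)) {
    a1 <- conv_fwd(h, params[[sprintf("enc%d_c1", i)]]); r1 <- relu(a1)
    a2 <- conv_fwd(r1, params[[sprintf("enc%d_c2", i)]]); r2 <- relu(a2)
    pool <- .maxpool2_fwd(r2)
    if (keep_cache) {
      cache[[sprintf("enc%d", i)]] <- list(in1 = h, r1 = r1, r2 = r2,
                                           argmax = pool$argmax)
    }
    skips[[i]] <- r2
    h <- pool$y
  }
  b1 <- conv_fwd(h, params$bott_c1); rb1 <- relu(b1)
  b2 <- conv_fwd(rb1, params$bott_c2); rb2 <- relu(b2)
  if (keep_cache) cache$bott <- list(in1 = h, rb1 = rb1, rb2 = rb2)
  h <- rb2
  for (i in rev(seq_len(depth))) {
    up_in <- upsample2(h)
    au <- conv_fwd(up_in, params[[sprintf("up%d", i)]]); ru <- relu(au)
    z <- concat_c(ru, skips[[i]])
    am <- conv_fwd(z, params[[sprintf("mrg%d", i)]]); rm <- relu(am)
    if (keep_cache) {
      cache[[sprintf("dec%d", i)]] <- list(up_in = up_in, ru = ru, z = z,
                                           rm = rm)
    }
    h <- rm
  }
  logits <- conv_fwd(h, params$head)
  if (keep_cache) cache$head_in <- h
  list(logits = logits, cache = if (keep_cache) cache else NULL,
       skips = NULL)
}

# Backward pass; dlogits has the shape of the logits. Returns gradients as a
# list parallel to params.
net_backward <- function(params, cache, dlogits, depth) {
  grads <- list()
  bw <- .conv2d_bwd(cache$head_in, params$head$W, dlogits)
  grads$head <- list(W = bw$dW, b = bw$db)
  dh <- bw$dx
  for (i in seq_len(depth)) {
    dc <- cache[[sprintf("dec%d", i)]]
    dam <- dh * (dc$rm > 0)
    bw <- .conv2d_bwd(dc$z, params[[sprintf("mrg%d", i)]]$W, dam)
    grads[[sprintf("mrg%d", i)]] <- list(W = bw$dW, b = bw$db)
    nc_up <- dim(dc$ru)[3]
    dru <- bw$dx[, , seq_len(nc_up), , drop = FALSE]
    dskip <- bw$dx[, , nc_up + seq_len(dim(bw$dx)[3] - nc_up), , drop = FALSE]
    dau <- dru * (dc$ru > 0)
    bw <- .conv2d_bwd(dc$up_in, params[[sprintf("up%d", i)]]$W, dau)
    grads[[sprintf("up%d", i)]] <- list(W = bw$dW, b = bw$db)
    dh <- downsum2(bw$dx)
    # store skip gradient for the encoder pass
    grads[[sprintf(".skip%d", i)]] <- dskip
  }
  bc <- cache$bott
  db2 <- dh * (bc$rb2 > 0)
  bw <- .conv2d_bwd(bc$rb1, params$bott_c2$W, db2)
  grads$bott_c2 <- list(W = bw$dW, b = bw$db)
  db1 <- bw$dx * (bc$rb1 > 0)
  bw <- .conv2d_bwd(bc$in1, params$bott_c1$W, db1)
  grads$bott_c1 <- list(W = bw$dW, b = bw$db)
  dh <- bw$dx
  for (i in rev(seq_len(depth))) {
    ec <- cache[[sprintf("enc%d", i)]]
    dr2 <- .maxpool2_bwd(dh, ec$argmax, dim(ec$r2)) +
      grads[[sprintf(".skip%d", i)]]
    grads[[sprintf(".skip%d", i)]] <- NULL
    da2 <- dr2 * (ec$r2 > 0)
    bw <- .conv2d_bwd(ec$r1, params[[sprintf("enc%d_c2", i)]]$W, da2)
    grads[[sprintf("enc%d_c2", i)]] <- list(W = bw$dW, b = bw$db)
    da1 <- bw$dx * (ec$r1 > 0)
    bw <- .conv2d_bwd(ec$in1, params[[sprintf("enc%d_c1", i)]]$W, da1)
    grads[[sprintf("enc%d_c1", i)]] <- list(W = bw$dW, b = bw$db)
    dh <- bw$dx
  }
  grads
}

# ---- optimizers ----------------------------------------------------------

make_optimizer <- function(kind, params, lr, momentum = 0.9) {
  state <- lapply(params, function(p) {
    list(vW = array(0, dim(p$W)), vb = numeric(length(p$b)),
         mW = array(0, dim(p$W)), mb = numeric(length(p$b)),
         uW = array(0, dim(p$W)), ub = numeric(length(p$b)))
  })
  t <- 0L
  step <- if (kind == "sgd") {
    function(params, grads) {
      for (nm in names(params)) {
        s <- state[[nm]]
        s$vW <- momentum * s$vW + grads[[nm]]$W
        s$vb <- momentum * s$vb + grads[[nm]]$b
        params[[nm]]$W <- params[[nm]]$W - lr * s$vW
        params[[nm]]$b <- params[[nm]]$b - lr * s$vb
        state[[nm]] <<- s
      }
      params
    }
  } else if (kind == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    function(params, grads) {
      t <<- t + 1L
      for (nm in names(params)) {
        s <- state[[nm]]
        s$mW <- b1 * s$mW + (1 - b1) * grads[[nm]]$W
        s$mb <- b1 * s$mb + (1 - b1) * grads[[nm]]$b
        s$uW <- b2 * s$uW + (1 - b2) * grads[[nm]]$W^2
        s$ub <- b2 * s$ub + (1 - b2) * grads[[nm]]$b^2
        ch <- lr * sqrt(1 - b2^t) / (1 - b1^t)
        params[[nm]]$W <- params[[nm]]$W - ch * s$mW / (sqrt(s$uW) + eps)
        params[[nm]]$b <- params[[nm]]$b - ch * s$mb / (sqrt(s$ub) + eps)
        state[[nm]] <<- s
      }
      params
    }
  } else {
    stopf("unknown optimizer '%s'", kind)
  }
  step
}
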