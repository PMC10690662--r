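# Minimal 3D convolutional network engine.
#
# Feature maps are stored as (B * n_voxels) x C matrices, voxels in R's
# column-major order, batch items stacked row-wise.  Convolutions are
# evaluated as im2col gathers followed by BLAS matrix products; backward
# passes scatter-add through the same index maps.  Layers are environments so
# parameters, gradients and optimizer state mutate in place.

.nn_cache <- new.env(parent = emptyenv())

# im2col index map for a k^3 convolution, stride s, zero padding p.
# Entry 0 marks an out-of-bounds (zero-padded) tap.
conv_index <- function(dims, k, s, p, batch = 1L) {
  key <- paste(c(dims, k, s, p, batch), collapse = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  dout <- (dims + 2L * p - k) %/% s + 1L
  nout <- prod(dout)
  oi <- rep.int(seq_len(dout[1]), dout[2] * dout[3])
  oj <- rep.int(rep(seq_len(dout[2]), each = dout[1]), dout[3])
  ok <- rep(seq_len(dout[3]), each = dout[1] * dout[2])
  idx <- matrix(0L, nout, k^3)
  col <- 0L
  for (c3 in 0:(k - 1)) for (c2 in 0:(k - 1)) for (c1 in 0:(k - 1)) {
    col <- col + 1L
    ii <- s * (oi - 1L) - p + c1 + 1L
    jj <- s * (oj - 1L) - p + c2 + 1L
    kk <- s * (ok - 1L) - p + c3 + 1L
    ok_tap <- ii >= 1L & ii <= dims[1] & jj >= 1L & jj <= dims[2] &
      kk >= 1L & kk <= dims[3]
    lin <- ii + (jj - 1L) * dims[1] + (kk - 1L) * dims[1] * dims[2]
    lin[!ok_tap] <- 0L
    idx[, col] <- lin
  }
  if (batch > 1L) {
    nvox <- prod(dims)
    blocks <- lapply(0:(batch - 1L), function(b) {
      m <- idx
      nz <- m != 0L
      m[nz] <- m[nz] + b * nvox
      m
    })
    idx <- do.call(rbind, blocks)
  }
  out <- list(idx = idx, dims_out = dout, nvox_in = prod(dims) * batch)
  .nn_cache[[key]] <- out
  out
}

# gather the rows of x addressed by one tap column (0 = zero pad)
tap_gather <- function(x0, idx_col) x0[idx_col + 1L, , drop = FALSE]

# index map for the gradient wrt the convolution input: for input voxel v and
# forward tap t, the output position whose tap t reads v (0 if none) — so the
# backward pass is itself a gather + matmul rather than a scatter
conv_bwd_index <- function(dims, k, s, p, batch = 1L) {
  key <- paste(c("B", dims, k, s, p, batch), collapse = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  dout <- (dims + 2L * p - k) %/% s + 1L
  vi <- rep.int(seq_len(dims[1]), dims[2] * dims[3])
  vj <- rep.int(rep(seq_len(dims[2]), each = dims[1]), dims[3])
  vk <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  idx <- matrix(0L, prod(dims), k^3)
  col <- 0L
  for (c3 in 0:(k - 1)) for (c2 in 0:(k - 1)) for (c1 in 0:(k - 1)) {
    col <- col + 1L
    # s*(o-1) - p + c + 1 = v  =>  o = (v - 1 + p - c)/s + 1
    n1 <- vi - 1L + p - c1; n2 <- vj - 1L + p - c2; n3 <- vk - 1L + p - c3
    ok <- n1 %% s == 0L & n2 %% s == 0L & n3 %% s == 0L
    o1 <- n1 %/% s + 1L; o2 <- n2 %/% s + 1L; o3 <- n3 %/% s + 1L
    ok <- ok & o1 >= 1L & o1 <= dout[1] & o2 >= 1L & o2 <= dout[2] &
      o3 >= 1L & o3 <= dout[3]
    lin <- o1 + (o2 - 1L) * dout[1] + (o3 - 1L) * dout[1] * dout[2]
    lin[!ok] <- 0L
    idx[, col] <- lin
  }
  if (batch > 1L) {
    nvo <- prod(dout)
    blocks <- lapply(0:(batch - 1L), function(b) {
      m <- idx; nz <- m != 0L; m[nz] <- m[nz] + b * nvo; m
    })
    idx <- do.call(rbind, blocks)
  }
  .nn_cache[[key]] <- idx
  idx
}

new_conv <- function(cin, cout, k = 3L, s = 1L, p = (k - 1L) %/% 2L) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$cin <- cin; e$cout <- cout; e$k <- k; e$s <- s; e$p <- p
  e$W <- matrix(stats::rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
                k^3 * cin, cout)
  e$b <- numeric(cout)
  e$trainable <- c("W", "b")
  e
}

# convolution as shift-and-accumulate: one row gather + GEMM per kernel tap,
# avoiding materialization of the full im2col matrix
conv_fwd <- function(e, x, dims, batch, keep_cache = TRUE) {
  ci <- conv_index(dims, e$k, e$s, e$p, batch)
  cin <- e$cin
  x0 <- rbind(matrix(0, 1L, cin), x)
  kk <- e$k^3
  y <- matrix(rep(e$b, each = nrow(ci$idx)), nrow(ci$idx), e$cout)
  shifts <- if (keep_cache) vector("list", kk)
  for (k in seq_len(kk)) {
    sk <- tap_gather(x0, ci$idx[, k])
    y <- y + sk %*% e$W[((k - 1L) * cin + 1L):(k * cin), , drop = FALSE]
    if (keep_cache) shifts[[k]] <- sk
  }
  list(y = y, dims = ci$dims_out,
       cache = if (keep_cache) list(shifts = shifts, dims_in = dims,
                                    batch = batch) else NULL)
}

conv_bwd <- function(e, cache, dy) {
  cin <- e$cin; kk <- e$k^3
  e$gb <- e$gb + colSums(dy)
  bidx <- conv_bwd_index(cache$dims_in, e$k, e$s, e$p, cache$batch)
  dy0 <- rbind(matrix(0, 1L, e$cout), dy)
  dx <- matrix(0, nrow(bidx), cin)
  for (k in seq_len(kk)) {
    rows <- ((k - 1L) * cin + 1L):(k * cin)
    wk <- e$W[rows, , drop = FALSE]
    e$gW[rows, ] <- e$gW[rows, , drop = FALSE] + crossprod(cache$shifts[[k]], dy)
    dx <- dx + tcrossprod(tap_gather(dy0, bidx[, k]), wk)
  }
  dx
}

# transpose convolution, kernel 2, stride 2: each input voxel emits a 2^3 block
tconv_index <- function(dims, batch = 1L) {
  key <- paste(c("T", dims, batch), collapse = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  dout <- dims * 2L
  ii <- rep.int(seq_len(dims[1]), dims[2] * dims[3])
  jj <- rep.int(rep(seq_len(dims[2]), each = dims[1]), dims[3])
  kk <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  omat <- matrix(0L, prod(dims), 8L)
  col <- 0L
  for (c3 in 0:1) for (c2 in 0:1) for (c1 in 0:1) {
    col <- col + 1L
    omat[, col] <- (2L * ii - 1L + c1) + (2L * jj - 2L + c2) * dout[1] +
      (2L * kk - 2L + c3) * dout[1] * dout[2]
  }
  if (batch > 1L) {
    nvo <- prod(dout)
    omat <- do.call(rbind, lapply(0:(batch - 1L), function(b) omat + b * nvo))
  }
  out <- list(omat = omat, dims_out = dout, nvox_out = prod(dout) * batch)
  .nn_cache[[key]] <- out
  out
}

new_tconv <- function(cin, cout) {
  e <- new.env(parent = emptyenv())
  e$type <- "tconv"; e$cin <- cin; e$cout <- cout
  e$W <- array(stats::rnorm(cin * cout * 8L, 0, sqrt(2 / cin)), c(cin, cout, 8L))
  e$b <- numeric(cout)
  e$trainable <- c("W", "b")
  e
}

tconv_fwd <- function(e, x, dims, batch, keep_cache = TRUE) {
  ti <- tconv_index(dims, batch)
  y <- matrix(0, ti$nvox_out, e$cout)
  for (k in 1:8) y[ti$omat[, k], ] <- x %*% e$W[, , k]
  y <- y + rep(e$b, each = nrow(y))
  list(y = y, dims = ti$dims_out,
       cache = if (keep_cache) list(x = x, ti = ti) else NULL)
}

tconv_bwd <- function(e, cache, dy) {
  dx <- matrix(0, nrow(cache$x), e$cin)
  for (k in 1:8) {
    dyk <- dy[cache$ti$omat[, k], , drop = FALSE]
    e$gW[, , k] <- e$gW[, , k] + crossprod(cache$x, dyk)
    dx <- dx + tcrossprod(dyk, e$W[, , k])
  }
  e$gb <- e$gb + colSums(dy)
  dx
}

new_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"; e$c <- c; e$momentum <- momentum; e$eps <- eps
  e$gamma <- rep(1, c); e$beta <- numeric(c)
  e$run_mean <- numeric(c); e$run_var <- rep(1, c)
  e$trainable <- c("gamma", "beta")
  e
}

bn_fwd <- function(e, x, training, keep_cache = TRUE) {
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = nrow(x))
    v <- colMeans(xc * xc)
    e$run_mean <- e$momentum * e$run_mean + (1 - e$momentum) * mu
    e$run_var <- e$momentum * e$run_var + (1 - e$momentum) * v
  } else {
    mu <- e$run_mean; v <- e$run_var
    xc <- x - rep(mu, each = nrow(x))
  }
  istd <- 1 / sqrt(v + e$eps)
  xhat <- xc * rep(istd, each = nrow(x))
  y <- xhat * rep(e$gamma, each = nrow(x)) + rep(e$beta, each = nrow(x))
  list(y = y, cache = if (keep_cache) list(xhat = xhat, istd = istd) else NULL)
}

bn_bwd <- function(e, cache, dy) {
  n <- nrow(dy)
  xhat <- cache$xhat
  e$ggamma <- e$ggamma + colSums(dy * xhat)
  e$gbeta <- e$gbeta + colSums(dy)
  gi <- rep(e$gamma * cache$istd, each = n)
  m1 <- rep(colMeans(dy), each = n)
  m2 <- xhat * rep(colMeans(dy * xhat), each = n)
  gi * (dy - m1 - m2)
}

new_prelu <- function(c, init = 0.25) {
  e <- new.env(parent = emptyenv())
  e$type <- "prelu"; e$c <- c
  e$a <- rep(init, c)
  e$trainable <- "a"
  e
}

prelu_fwd <- function(e, x, keep_cache = TRUE) {
  neg <- pmin.int(x, 0)
  y <- pmax.int(x, 0) + neg * rep(e$a, each = nrow(x))
  dim(y) <- dim(x)
  list(y = y, cache = if (keep_cache) list(x = x) else NULL)
}

prelu_bwd <- function(e, cache, dy) {
  x <- cache$x
  e$ga <- e$ga + colSums(dy * pmin.int(x, 0))
  dy * ((x > 0) + (x <= 0) * rep(e$a, each = nrow(x)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# binary cross-entropy with logits against a constant target; returns loss
# and d(loss)/d(logits) for a mean reduction
bce_logits <- function(z, target) {
  loss <- mean(ifelse(z > 0, z - target * z + log1p(exp(-z)),
                      -target * z + log1p(exp(z))))
  list(loss = loss, dz = (sigmoid(z) - target) / length(z))
}

# ---- composite blocks -------------------------------------------------------

new_cbr <- function(cin, cout, k = 3L, s = 1L) {
  list(conv = new_conv(cin, cout, k, s), bn = new_bn(cout), act = new_prelu(cout))
}

cbr_fwd <- function(blk, x, dims, batch, training, keep_cache = TRUE) {
  c1 <- conv_fwd(blk$conv, x, dims, batch, keep_cache)
  b1 <- bn_fwd(blk$bn, c1$y, training, keep_cache)
  a1 <- prelu_fwd(blk$act, b1$y, keep_cache)
  list(y = a1$y, dims = c1$dims,
       cache = list(conv = c1$cache, bn = b1$cache, act = a1$cache))
}

cbr_bwd <- function(blk, cache, dy) {
  dy <- prelu_bwd(blk$act, cache$act, dy)
  dy <- bn_bwd(blk$bn, cache$bn, dy)
  conv_bwd(blk$conv, cache$conv, dy)
}

# residual unit: conv-bn-prelu-conv-bn (+ identity skip) -prelu
new_resunit <- function(c) {
  list(conv1 = new_conv(c, c), bn1 = new_bn(c), act1 = new_prelu(c),
       conv2 = new_conv(c, c), bn2 = new_bn(c), act2 = new_prelu(c))
}

res_fwd <- function(ru, x, dims, batch, training, keep_cache = TRUE) {
  c1 <- conv_fwd(ru$conv1, x, dims, batch, keep_cache)
  b1 <- bn_fwd(ru$bn1, c1$y, training, keep_cache)
  a1 <- prelu_fwd(ru$act1, b1$y, keep_cache)
  c2 <- conv_fwd(ru$conv2, a1$y, dims, batch, keep_cache)
  b2 <- bn_fwd(ru$bn2, c2$y, training, keep_cache)
  s <- b2$y + x
  a2 <- prelu_fwd(ru$act2, s, keep_cache)
  list(y = a2$y, dims = dims,
       cache = list(c1 = c1$cache, b1 = b1$cache, a1 = a1$cache,
                    c2 = c2$cache, b2 = b2$cache, a2 = a2$cache))
}

res_bwd <- function(ru, cache, dy) {
  ds <- prelu_bwd(ru$act2, cache$a2, dy)
  d2 <- bn_bwd(ru$bn2, cache$b2, ds)
  d2 <- conv_bwd(ru$conv2, cache$c2, d2)
  d2 <- prelu_bwd(ru$act1, cache$a1, d2)
  d2 <- bn_bwd(ru$bn1, cache$b1, d2)
  d2 <- conv_bwd(ru$conv1, cache$c1, d2)
  d2 + ds
}

# ---- parameter bookkeeping --------------------------------------------------

collect_layers <- function(x) {
  if (is.environment(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_layers)))
  list()
}

zero_grads <- function(layers) {
  for (e in layers) for (nm in e$trainable)
    e[[paste0("g", nm)]] <- array(0, dim = dim(e[[nm]]) %||% length(e[[nm]]))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_params <- function(layers) sum(vapply(layers, function(e)
  sum(vapply(e$trainable, function(nm) length(e[[nm]]), 0)), 0))

adam_init <- function(layers) {
  for (e in layers) e$opt <- lapply(stats::setNames(e$trainable, e$trainable),
                                    function(nm) list(m = 0 * e[[nm]], v = 0 * e[[nm]]))
  invisible(NULL)
}

adam_step <- function(layers, lr, t, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  for (e in layers) for (nm in e$trainable) {
    g <- e[[paste0("g", nm)]]
    st <- e$opt[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    e$opt[[nm]] <- st
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    e[[nm]] <- e[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

# serialize layer parameters to plain lists (for checkpoints) and back
params_export <- function(layers) lapply(layers, function(e) {
  out <- lapply(stats::setNames(e$trainable, e$trainable), function(nm) e[[nm]])
  if (e$type == "bn") out[c("run_mean", "run_var")] <- list(e$run_mean, e$run_var)
  out
})

params_import <- function(layers, saved) {
  stopifnot(length(layers) == length(saved))
  for (i in seq_along(layers)) {
    e <- layers[[i]]
    for (nm in names(saved[[i]])) e[[nm]] <- saved[[i]][[nm]]
  }
  invisible(NULL)
}

# ---- generator: 3D U-Net with residual units --------------------------------

build_generator_net <- function(channels) {
  d <- length(channels)
  net <- list(
    inblock = new_cbr(1L, channels[1]),
    enc_res = lapply(channels, new_resunit),
    down = lapply(seq_len(d - 1L),
                  function(i) new_cbr(channels[i], channels[i + 1L], s = 2L)),
    up = lapply(seq_len(d - 1L), function(i)
      list(tconv = new_tconv(channels[i + 1L], channels[i]),
           bn = new_bn(channels[i]), act = new_prelu(channels[i]),
           fuse = new_cbr(2L * channels[i], channels[i]),
           res = new_resunit(channels[i]))),
    head = new_conv(channels[1], 1L))
  net$depth <- d
  net$channels <- channels
  net
}

generator_fwd <- function(net, x, dims, batch, training, keep_cache = TRUE) {
  d <- net$depth
  caches <- list(); skips <- list(); sdims <- list()
  f <- cbr_fwd(net$inblock, x, dims, batch, training, keep_cache)
  caches$inblock <- f$cache
  r <- res_fwd(net$enc_res[[1]], f$y, f$dims, batch, training, keep_cache)
  caches$enc_res <- vector("list", d); caches$down <- vector("list", d - 1L)
  caches$enc_res[[1]] <- r$cache
  skips[[1]] <- r$y; sdims[[1]] <- r$dims
  h <- r$y; hd <- r$dims
  for (i in seq_len(d - 1L)) {
    dn <- cbr_fwd(net$down[[i]], h, hd, batch, training, keep_cache)
    caches$down[[i]] <- dn$cache
    r <- res_fwd(net$enc_res[[i + 1L]], dn$y, dn$dims, batch, training, keep_cache)
    caches$enc_res[[i + 1L]] <- r$cache
    h <- r$y; hd <- r$dims
    if (i < d - 1L) { skips[[i + 1L]] <- h; sdims[[i + 1L]] <- hd }
  }
  caches$up <- vector("list", d - 1L)
  for (i in rev(seq_len(d - 1L))) {
    u <- net$up[[i]]
    t1 <- tconv_fwd(u$tconv, h, hd, batch, keep_cache)
    b1 <- bn_fwd(u$bn, t1$y, training, keep_cache)
    a1 <- prelu_fwd(u$act, b1$y, keep_cache)
    cat_y <- cbind(a1$y, skips[[i]])
    fu <- cbr_fwd(u$fuse, cat_y, t1$dims, batch, training, keep_cache)
    rr <- res_fwd(u$res, fu$y, fu$dims, batch, training, keep_cache)
    caches$up[[i]] <- list(t = t1$cache, bn = b1$cache, act = a1$cache,
                           fuse = fu$cache, res = rr$cache,
                           nup = ncol(a1$y))
    h <- rr$y; hd <- rr$dims
  }
  hc <- conv_fwd(net$head, h, hd, batch, keep_cache)
  caches$head <- hc$cache
  y <- sigmoid(hc$y)
  caches$y <- if (keep_cache) y else NULL
  list(y = y, dims = hd, caches = caches)
}

generator_bwd <- function(net, caches, dy) {
  d <- net$depth
  dz <- dy * caches$y * (1 - caches$y)          # through sigmoid
  dh <- conv_bwd(net$head, caches$head, dz)
  dskip <- vector("list", d - 1L)
  for (i in seq_len(d - 1L)) {
    u <- net$up[[i]]; cc <- caches$up[[i]]
    dh <- res_bwd(u$res, cc$res, dh)
    dcat <- cbr_bwd(u$fuse, cc$fuse, dh)
    dup <- dcat[, seq_len(cc$nup), drop = FALSE]
    dskip[[i]] <- dcat[, -seq_len(cc$nup), drop = FALSE]
    dup <- prelu_bwd(u$act, cc$act, dup)
    dup <- bn_bwd(u$bn, cc$bn, dup)
    dh <- tconv_bwd(u$tconv, cc$t, dup)
  }
  for (i in rev(seq_len(d - 1L))) {
    dh <- res_bwd(net$enc_res[[i + 1L]], caches$enc_res[[i + 1L]], dh)
    dh <- cbr_bwd(net$down[[i]], caches$down[[i]], dh)
    dh <- dh + dskip[[i]]
  }
  dh <- res_bwd(net$enc_res[[1]], caches$enc_res[[1]], dh)
  cbr_bwd(net$inblock, caches$inblock, dh)
}

# ---- discriminator: conditional PatchGAN ------------------------------------

build_discriminator_net <- function(channels, cin = 2L) {
  nl <- length(channels)
  layers <- vector("list", nl)
  prev <- cin
  for (i in seq_len(nl)) {
    if (i == nl) {
      layers[[i]] <- list(conv = new_conv(prev, channels[i], s = 2L))
    } else if (i == 1L) {
      layers[[i]] <- list(conv = new_conv(prev, channels[i], s = 2L),
                          act = new_prelu(channels[i]))
    } else {
      layers[[i]] <- list(conv = new_conv(prev, channels[i], s = 2L),
                          bn = new_bn(channels[i]), act = new_prelu(channels[i]))
    }
    prev <- channels[i]
  }
  list(layers = layers, channels = channels)
}

discriminator_fwd <- function(net, x, dims, batch, training, keep_cache = TRUE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    cv <- conv_fwd(ly$conv, x, dims, batch, keep_cache)
    cc <- list(conv = cv$cache)
    x <- cv$y; dims <- cv$dims
    if (!is.null(ly$bn)) { b <- bn_fwd(ly$bn, x, training, keep_cache); cc$bn <- b$cache; x <- b$y }
    if (!is.null(ly$act)) { a <- prelu_fwd(ly$act, x, keep_cache); cc$act <- a$cache; x <- a$y }
    caches[[i]] <- cc
  }
  list(z = x, dims = dims, caches = caches)
}

discriminator_bwd <- function(net, caches, dz) {
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]; cc <- caches[[i]]
    if (!is.null(ly$act)) dz <- prelu_bwd(ly$act, cc$act, dz)
    if (!is.null(ly$bn)) dz <- bn_bwd(ly$bn, cc$bn, dz)
    dz <- conv_bwd(ly$conv, cc$conv, dz)
  }
  dz
}
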