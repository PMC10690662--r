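# Small configurations keep these structural tests fast; the learning-signal
# check on phantoms lives in test-acceptance.R.

toy_cfg <- function(...) gan_config(gen_channels = c(4L, 8L),
                                    dis_channels = c(4L, 1L),
                                    patch = 8L, profile = "toy", ...)

test_that("generator maps a patch to a same-shape patch and is deterministic", {
  cfg <- toy_cfg(seed = 5)
  m <- build_models(cfg)
  set.seed(1)
  x <- matrix(runif(8^3), ncol = 1)
  y1 <- sipcom:::generator_fwd(m$generator, x, rep(8L, 3), 1L,
                               training = FALSE, keep_cache = FALSE)$y
  y2 <- sipcom:::generator_fwd(m$generator, x, rep(8L, 3), 1L,
                               training = FALSE, keep_cache = FALSE)$y
  expect_equal(dim(y1), dim(x))
  expect_true(all(is.finite(y1)))
  expect_identical(y1, y2)
  # identical seeds give identical initializations
  m2 <- build_models(toy_cfg(seed = 5))
  y3 <- sipcom:::generator_fwd(m2$generator, x, rep(8L, 3), 1L,
                               training = FALSE, keep_cache = FALSE)$y
  expect_identical(y1, y3)
})

test_that("parameter count strictly increases when channel widths double", {
  n1 <- sipcom:::n_params(build_models(toy_cfg())$gen_layers)
  n2 <- sipcom:::n_params(build_models(
    gan_config(gen_channels = c(8L, 16L), dis_channels = c(4L, 1L),
               patch = 8L, profile = "toy"))$gen_layers)
  expect_gt(n2, n1)
})

test_that("patch sizes not divisible by 2^(depth-1) are rejected", {
  expect_error(gan_config(gen_channels = c(4L, 8L, 16L), patch = 10L,
                          dis_channels = c(4L, 1L), profile = "toy"),
               "divisible")
})

test_that("generator backprop matches numerical finite differences", {
  set.seed(42)
  cfg <- gan_config(gen_channels = c(2L, 4L), dis_channels = c(3L, 1L),
                    patch = 4L, profile = "toy")
  m <- build_models(cfg)
  x <- matrix(rnorm(2 * 64), ncol = 1)          # batch of 2
  r <- matrix(rnorm(2 * 64), ncol = 1)
  pd <- rep(4L, 3)
  loss <- function() mean((sipcom:::generator_fwd(m$generator, x, pd, 2L,
                                                  training = TRUE)$y - r)^2)
  f <- sipcom:::generator_fwd(m$generator, x, pd, 2L, training = TRUE)
  sipcom:::zero_grads(m$gen_layers)
  invisible(sipcom:::generator_bwd(m$generator, f$caches,
                                   2 * (f$y - r) / length(f$y)))
  worst <- 0
  for (e in m$gen_layers) for (nm in e$trainable) {
    g_an <- e[[paste0("g", nm)]]
    for (j in sample(length(e[[nm]]), min(2L, length(e[[nm]])))) {
      eps <- 1e-5; orig <- e[[nm]][j]
      e[[nm]][j] <- orig + eps; lp <- loss()
      e[[nm]][j] <- orig - eps; lm <- loss()
      e[[nm]][j] <- orig
      g_num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(g_num - g_an[j]) /
                     max(1e-6, abs(g_num) + abs(g_an[j])))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("patch sampling honours the mask, the seed, and n = 0", {
  st <- tiny_study(seed = 8)
  expect_identical(sample_patches(st, 0L, 8L), list())
  p1 <- sample_patches(st, 10L, 8L, seed = 3)
  p2 <- sample_patches(st, 10L, 8L, seed = 3)
  expect_identical(lapply(p1, `[[`, "corner"), lapply(p2, `[[`, "corner"))
  p3 <- sample_patches(st, 10L, 8L, seed = 4)
  expect_false(identical(lapply(p1, `[[`, "corner"), lapply(p3, `[[`, "corner")))
  for (p in p1) {
    ctr <- p$corner + 4L                        # centre of an 8-patch
    expect_true(st$mask[ctr[1], ctr[2], ctr[3]])
    expect_identical(dim(p$t1w), rep(8L, 3))
    # both modalities cut at identical coordinates
    expect_identical(p$t1w,
                     st$t1w$data[p$corner[1] + 0:7, p$corner[2] + 0:7,
                                 p$corner[3] + 0:7])
  }
  small <- st
  small$mask <- array(FALSE, dim(st$mask)); small$mask[2, 2, 2] <- TRUE
  expect_error(sample_patches(small, 1L, 20L), "mask too small|not fit")
})

test_that("sliding-window stitching is exact for the identity and order-invariant", {
  set.seed(9)
  arr <- array(runif(20 * 18 * 16), c(20, 18, 16))
  res <- sliding_window_apply(arr, identity, window = 8L)
  expect_equal(res$out, arr, tolerance = 1e-10)
  expect_true(all(res$weight > 0))
  # independent stitcher: same windows accumulated in random order
  d <- dim(arr)
  stride <- 4L; window <- 8L
  nw <- pmax(1L, ceiling((d - window) / stride) + 1L)
  span <- (nw - 1L) * stride + window
  padded <- arr
  for (ax in 1:3) {
    n <- dim(padded)[ax]; pad <- span[ax] - n
    if (pad > 0) {
      idx <- c(seq_len(n), n - seq_len(pad))
      padded <- switch(ax, padded[idx, , ], padded[, idx, ], padded[, , idx])
    }
  }
  w1 <- sin(pi * (seq_len(window) - 0.5) / window)^2
  wk <- array(outer(outer(w1, w1), w1), rep(window, 3))
  acc <- array(0, dim(padded)); wsum <- array(0, dim(padded))
  grid <- expand.grid(i = seq_len(nw[1]), j = seq_len(nw[2]), k = seq_len(nw[3]))
  grid <- grid[sample(nrow(grid)), ]
  fn <- function(b) sqrt(b + 1)                  # arbitrary nonlinear map
  for (g in seq_len(nrow(grid))) {
    o <- (as.integer(grid[g, ]) - 1L) * stride
    ix <- o[1] + seq_len(window); iy <- o[2] + seq_len(window); iz <- o[3] + seq_len(window)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + wk * fn(padded[ix, iy, iz])
    wsum[ix, iy, iz] <- wsum[ix, iy, iz] + wk
  }
  want <- (acc / wsum)[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  got <- sliding_window_apply(arr, fn, window = 8L)$out
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("one-epoch training runs, records losses, and reacts to lambda", {
  st1 <- tiny_study(seed = 11, shape = 24, axes = c(18, 20, 16))
  st2 <- tiny_study(seed = 12, shape = 24, axes = c(18, 20, 16))
  cfg <- toy_cfg(epochs = 1L, patches_per_volume = 2L, batch_size = 2L, seed = 2)
  state <- train_gan(list(st1, st2), cfg)
  expect_s3_class(state, "sipcom_generator")
  expect_equal(nrow(state$history), 1L)
  expect_true(all(is.finite(unlist(state$history))))
  expect_equal(state$meta$epochs_run, 1L)
  # lambda changes the optimization trajectory
  cfg0 <- toy_cfg(epochs = 1L, patches_per_volume = 2L, batch_size = 2L,
                  seed = 2, lambda = 0)
  state0 <- train_gan(list(st1, st2), cfg0)
  expect_false(identical(state$params, state0$params))
})

test_that("save/load round-trips to bit-identical predictions", {
  st <- tiny_study(seed = 13, shape = 24, axes = c(18, 20, 16))
  cfg <- toy_cfg(epochs = 1L, patches_per_volume = 2L, batch_size = 2L, seed = 3)
  state <- train_gan(list(st), cfg)
  t1 <- minmax_scale(st$t1w)
  before <- predict_volume(state, t1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_generator(state, f)
  after <- predict_volume(load_generator(f), t1)
  expect_identical(before$data, after$data)
  expect_equal(dim(before$data), dim(st$t1w$data))
})
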