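#' Configuration of the MRI-to-PET conditional adversarial model
#'
#' Defaults follow the published full-scale setup: a five-stage U-Net
#' generator with residual units (encoder channels 32-512, mirrored decoder),
#' a five-layer PatchGAN discriminator (64, 128, 256, 512, 1), 32^3 voxel
#' patches, generator loss 1/2 (lambda * MSE + adversarial) with lambda 200,
#' Adam at a constant learning rate 2e-4 with betas (0.5, 0.999), batch size
#' 20, 1000 epochs.  `profile = "toy"` selects a small configuration of the
#' same architecture suitable for CPU-scale training on phantoms.
#'
#' @param gen_channels encoder channel widths (decoder mirrors them).
#' @param dis_channels discriminator channel widths; last must be 1.
#' @param patch cubic patch edge length in voxels; must be divisible by
#'   2^(depth - 1).
#' @param lambda weight of the MSE term in the generator loss (> 0).
#' @param lr constant Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size patches per optimization step.
#' @param patches_per_volume patches sampled from each training pair per
#'   epoch (sampling density is not a published value; exposed here).
#' @param adv_loss adversarial loss form: `"bce"` (default) or `"lsgan"`.
#' @param betas Adam (beta1, beta2).
#' @param seed integer seed controlling initialization and patch sampling.
#' @param profile `"full"` (the published full-scale configuration) or `"toy"`; explicit arguments override either.
#' @return A `sipcom_gan_config` list.
#' @export
gan_config <- function(gen_channels = NULL, dis_channels = NULL, patch = NULL,
                       lambda = 200, lr = NULL, epochs = NULL,
                       batch_size = NULL, patches_per_volume = NULL,
                       adv_loss = c("bce", "lsgan"), betas = c(0.5, 0.999),
                       seed = 1L, profile = c("full", "toy")) {
  profile <- match.arg(profile)
  adv_loss <- match.arg(adv_loss)
  def <- if (profile == "full") {
    list(gen_channels = c(32L, 64L, 128L, 256L, 512L),
         dis_channels = c(64L, 128L, 256L, 512L, 1L),
         patch = 32L, lr = 2e-4, epochs = 1000L, batch_size = 20L,
         patches_per_volume = 20L)
  } else {
    list(gen_channels = c(8L, 16L, 32L),
         dis_channels = c(8L, 16L, 1L),
         patch = 16L, lr = 2e-3, epochs = 40L, batch_size = 4L,
         patches_per_volume = 8L)
  }
  cfg <- list(gen_channels = as.integer(gen_channels %||% def$gen_channels),
              dis_channels = as.integer(dis_channels %||% def$dis_channels),
              patch = as.integer(patch %||% def$patch),
              lambda = lambda, lr = lr %||% def$lr,
              epochs = as.integer(epochs %||% def$epochs),
              batch_size = as.integer(batch_size %||% def$batch_size),
              patches_per_volume = as.integer(patches_per_volume %||% def$patches_per_volume),
              adv_loss = adv_loss, betas = betas, seed = as.integer(seed))
  if (cfg$lambda < 0) stop("lambda must be >= 0")
  depth <- length(cfg$gen_channels)
  if (cfg$patch %% 2L^(depth - 1L) != 0L)
    stop("patch size ", cfg$patch, " is not divisible by 2^(depth-1) = ",
         2L^(depth - 1L))
  if (utils::tail(cfg$dis_channels, 1L) != 1L)
    stop("last discriminator channel width must be 1 (score map)")
  class(cfg) <- "sipcom_gan_config"
  cfg
}

#' Build generator and discriminator networks
#'
#' The generator is a 3D U-Net: the encoder downsamples by strided
#' convolutions, the decoder upsamples by transpose convolutions, with one
#' residual unit per stage and skip concatenation; PReLU activations and
#' batch normalization throughout, sigmoid output.  The discriminator is a
#' conditional PatchGAN scoring concatenated (T1w, PET) patches.
#' Initialization is reproducible under `config$seed`.
#'
#' @param config a [gan_config()].
#' @return List with elements `generator`, `discriminator` (each with an
#'   attached flat `layers` list), and `config`.
#' @export
build_models <- function(config) {
  stopifnot(inherits(config, "sipcom_gan_config"))
  set.seed(config$seed)
  gen <- build_generator_net(config$gen_channels)
  dis <- build_discriminator_net(config$dis_channels)
  list(generator = gen, discriminator = dis, config = config,
       gen_layers = collect_layers(gen[c("inblock", "enc_res", "down", "up", "head")]),
       dis_layers = collect_layers(dis$layers))
}

#' Sample co-located training patches from a paired study
#'
#' Draws `n` cubic patches whose centres lie inside the brain mask and whose
#' support fits inside the volume, at identical coordinates in both
#' modalities; reproducible under `seed`.
#'
#' @param pair list with `t1w`, `pet` ([volume3d()]) and `mask`
#'   (logical array), e.g. a [generate_phantom()] study.
#' @param n number of patches.
#' @param patch_edge cubic patch edge in voxels.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return List of `n` items, each `list(t1w=, pet=, corner=)` with arrays of
#'   dim `patch_edge^3` and the 1-based corner index.
#' @export
sample_patches <- function(pair, n, patch_edge, seed = NULL) {
  check_same_lattice(pair$t1w, pair$pet)
  m <- as_mask(pair$mask, pair$t1w)
  d <- dim(m)
  if (any(patch_edge > d)) stop("patch does not fit inside the volume")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(list())
  half <- patch_edge %/% 2L
  ctr <- which(m, arr.ind = TRUE)
  # patch corner = centre - half; require corner in [1, d - patch + 1]
  corner_ok <- function(c1, dd) c1 - half >= 1L & c1 - half <= dd - patch_edge + 1L
  fits <- corner_ok(ctr[, 1], d[1]) & corner_ok(ctr[, 2], d[2]) & corner_ok(ctr[, 3], d[3])
  ctr <- ctr[fits, , drop = FALSE]
  if (nrow(ctr) == 0L) stop("mask too small: no in-mask patch centre fits the volume")
  pick <- ctr[sample.int(nrow(ctr), n, replace = TRUE), , drop = FALSE]
  lapply(seq_len(n), function(i) {
    cnr <- pick[i, ] - half
    ix <- cnr[1]:(cnr[1] + patch_edge - 1L)
    iy <- cnr[2]:(cnr[2] + patch_edge - 1L)
    iz <- cnr[3]:(cnr[3] + patch_edge - 1L)
    list(t1w = pair$t1w$data[ix, iy, iz],
         pet = pair$pet$data[ix, iy, iz],
         corner = cnr)
  })
}

stack_patches <- function(patches, field) {
  cols <- lapply(patches, function(p) as.numeric(p[[field]]))
  matrix(unlist(cols), ncol = 1L)
}

adv_terms <- function(z, target, form) {
  if (form == "lsgan") {
    n <- length(z)
    list(loss = mean((z - target)^2), dz = 2 * (z - target) / n)
  } else bce_logits(z, target)
}

#' Train the conditional adversarial model
#'
#' Alternating discriminator/generator Adam updates at a constant learning
#' rate.  Generator loss: 1/2 (lambda * MSE(fake, real) + adversarial);
#' discriminator loss: 1/2 (real term + fake term).  Training is a pure
#' function of the data and `config` (seeded).
#'
#' @param pairs list of paired studies (each with `t1w`, `pet`, `mask`).
#' @param config a [gan_config()].
#' @param verbose print per-epoch losses.
#' @return A `sipcom_generator` state: serialized parameters, the config, and
#'   training metadata including the per-epoch loss history.
#' @export
train_gan <- function(pairs, config, verbose = FALSE) {
  stopifnot(inherits(config, "sipcom_gan_config"))
  if (length(pairs) < 1L) stop("need at least one training pair")
  models <- build_models(config)
  gl <- models$gen_layers; dl <- models$dis_layers
  adam_init(gl); adam_init(dl)
  pdim <- rep(config$patch, 3L)
  history <- data.frame(epoch = integer(), g_loss = numeric(),
                        d_loss = numeric(), mse = numeric())
  t_g <- 0L; t_d <- 0L
  for (ep in seq_len(config$epochs)) {
    pool <- do.call(c, lapply(pairs, sample_patches,
                              n = config$patches_per_volume,
                              patch_edge = config$patch))
    pool <- pool[sample.int(length(pool))]
    nb <- ceiling(length(pool) / config$batch_size)
    eg <- ed <- em <- 0
    for (b in seq_len(nb)) {
      sel <- pool[(((b - 1L) * config$batch_size + 1L):
                     min(b * config$batch_size, length(pool)))]
      bs <- length(sel)
      x <- stack_patches(sel, "t1w")
      r <- stack_patches(sel, "pet")
      gfwd <- generator_fwd(models$generator, x, pdim, bs, training = TRUE)
      fake <- gfwd$y

      # discriminator step (fake detached)
      zero_grads(dl)
      fr <- discriminator_fwd(models$discriminator, cbind(x, r), pdim, bs, TRUE)
      ff <- discriminator_fwd(models$discriminator, cbind(x, fake), pdim, bs, TRUE)
      tr <- adv_terms(fr$z, 1, config$adv_loss)
      tf <- adv_terms(ff$z, 0, config$adv_loss)
      d_loss <- 0.5 * (tr$loss + tf$loss)
      discriminator_bwd(models$discriminator, fr$caches, 0.5 * tr$dz)
      discriminator_bwd(models$discriminator, ff$caches, 0.5 * tf$dz)
      t_d <- t_d + 1L
      adam_step(dl, config$lr, t_d, config$betas[1], config$betas[2])

      # generator step
      zero_grads(gl); zero_grads(dl)
      fg <- discriminator_fwd(models$discriminator, cbind(x, fake), pdim, bs, TRUE)
      ta <- adv_terms(fg$z, 1, config$adv_loss)
      mse <- mean((fake - r)^2)
      g_loss <- 0.5 * (config$lambda * mse + ta$loss)
      if (!is.finite(g_loss) || !is.finite(d_loss))
        stop("non-finite loss at epoch ", ep, " (G=", g_loss, ", D=", d_loss,
             "); lower the learning rate")
      din <- discriminator_bwd(models$discriminator, fg$caches, 0.5 * ta$dz)
      dfake <- din[, 2L, drop = FALSE] +
        0.5 * config$lambda * 2 * (fake - r) / length(fake)
      generator_bwd(models$generator, gfwd$caches, dfake)
      t_g <- t_g + 1L
      adam_step(gl, config$lr, t_g, config$betas[1], config$betas[2])

      eg <- eg + g_loss; ed <- ed + d_loss; em <- em + mse
    }
    history[ep, ] <- list(ep, eg / nb, ed / nb, em / nb)
    if (verbose)
      message(sprintf("epoch %d: G %.4f D %.4f mse %.5f", ep, eg / nb, ed / nb, em / nb))
  }
  new_generator_state(models, history)
}

new_generator_state <- function(models, history) {
  structure(list(params = params_export(models$gen_layers),
                 dis_params = params_export(models$dis_layers),
                 config = models$config,
                 meta = list(epochs_run = nrow(history),
                             final_g_loss = if (nrow(history)) utils::tail(history$g_loss, 1) else NA_real_,
                             final_d_loss = if (nrow(history)) utils::tail(history$d_loss, 1) else NA_real_),
                 history = history),
            class = "sipcom_generator")
}

#' Untrained generator state
#'
#' Freshly initialized (seeded, untrained) model — the baseline against which
#' training improvement is measured.
#'
#' @param config a [gan_config()].
#' @return A `sipcom_generator`.
#' @export
untrained_generator <- function(config) {
  models <- build_models(config)
  new_generator_state(models, data.frame(epoch = integer(), g_loss = numeric(),
                                         d_loss = numeric(), mse = numeric()))
}

#' @export
print.sipcom_generator <- function(x, ...) {
  cat(sprintf("<sipcom_generator> depth %d (channels %s), patch %d^3, %d epoch(s) trained\n",
              length(x$config$gen_channels),
              paste(x$config$gen_channels, collapse = "/"),
              x$config$patch, x$meta$epochs_run))
  invisible(x)
}

#' Save / load a generator checkpoint
#'
#' A single-file archive of the parameters, config and training metadata.
#' Load-then-predict is bit-identical to predicting before the save.
#'
#' @param state a `sipcom_generator`.
#' @param path checkpoint file path.
#' @return `path` / the restored `sipcom_generator`.
#' @export
save_generator <- function(state, path) {
  stopifnot(inherits(state, "sipcom_generator"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_generator
#' @export
load_generator <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "sipcom_generator")) stop("not a generator checkpoint: ", path)
  state
}

# materialize networks (environments) from a serialized state
instantiate_generator <- function(state) {
  net <- build_generator_net(state$config$gen_channels)
  layers <- collect_layers(net[c("inblock", "enc_res", "down", "up", "head")])
  params_import(layers, state$params)
  net
}

#' Apply a patch-wise function over a volume with overlapping windows
#'
#' Sliding-window evaluation with 50% overlap (by default), cosine-tapered
#' (Hann) blending weights and reflect padding to a whole number of windows.
#' Accumulated blending weights are normalized to sum to one at every voxel,
#' so a patch-wise identity function reproduces the input.
#'
#' @param arr 3D numeric array.
#' @param fn function taking a `window^3` array and returning a same-shape
#'   array.
#' @param window cubic window edge (voxels).
#' @param overlap fractional overlap between neighbouring windows in \[0, 1).
#' @return List with `out` (the blended array) and `weight` (the accumulated,
#'   pre-normalization weight field on the padded grid).
#' @export
sliding_window_apply <- function(arr, fn, window, overlap = 0.5) {
  d <- dim(arr)
  if (any(window > d)) stop("window larger than volume")
  stride <- max(1L, as.integer(round(window * (1 - overlap))))
  nw <- pmax(1L, ceiling((d - window) / stride) + 1L)
  span <- (nw - 1L) * stride + window
  pad <- span - d
  # reflect padding on the high side
  padded <- arr
  for (ax in 1:3) {
    n <- dim(padded)[ax]
    if (pad[ax] > 0L) {
      idx <- c(seq_len(n), n - seq_len(pad[ax]))
      padded <- switch(ax, padded[idx, , , drop = FALSE],
                       padded[, idx, , drop = FALSE],
                       padded[, , idx, drop = FALSE])
    }
  }
  w1 <- sin(pi * (seq_len(window) - 0.5) / window)^2
  wk <- array(outer(outer(w1, w1), w1), rep(window, 3L))
  out <- array(0, dim(padded))
  wsum <- array(0, dim(padded))
  for (k in seq_len(nw[3])) for (j in seq_len(nw[2])) for (i in seq_len(nw[1])) {
    o <- (c(i, j, k) - 1L) * stride
    ix <- o[1] + seq_len(window); iy <- o[2] + seq_len(window); iz <- o[3] + seq_len(window)
    block <- fn(padded[ix, iy, iz])
    out[ix, iy, iz] <- out[ix, iy, iz] + wk * block
    wsum[ix, iy, iz] <- wsum[ix, iy, iz] + wk
  }
  out <- out / wsum
  list(out = out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE],
       weight = wsum)
}

#' Predict a whole pseudo-normal PET volume from T1w MRI
#'
#' Sliding-window inference of the trained generator (eval mode: batch-norm
#' running statistics), with overlap blending; the output lies on the input
#' lattice.
#'
#' @param state a `sipcom_generator`.
#' @param t1w the T1w [volume3d()] (expected scaled to \[0, 1\]).
#' @param mask optional brain mask; if given, the output is zeroed outside it.
#' @param overlap window overlap fraction (default 0.5).
#' @return The predicted PET as a [volume3d()].
#' @export
predict_volume <- function(state, t1w, mask = NULL, overlap = 0.5) {
  stopifnot(inherits(state, "sipcom_generator"), inherits(t1w, "sipcom_volume"))
  net <- instantiate_generator(state)
  patch <- state$config$patch
  pdim <- rep(patch, 3L)
  fn <- function(block) {
    x <- matrix(as.numeric(block), ncol = 1L)
    y <- generator_fwd(net, x, pdim, 1L, training = FALSE, keep_cache = FALSE)$y
    array(y, dim(block))
  }
  res <- sliding_window_apply(t1w$data, fn, patch, overlap)
  out <- res$out
  if (!is.null(mask)) out[!as_mask(mask, t1w)] <- 0
  volume3d(out, t1w$voxel_mm, t1w$affine, "pet_predicted")
}
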