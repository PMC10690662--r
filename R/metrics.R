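#' Masked mean absolute error
#'
#' Mean of |a - b| over in-mask voxels only.
#'
#' @param a,b [volume3d()] objects on the same lattice.
#' @param mask logical brain mask.
#' @return Non-negative scalar.
#' @export
masked_mae <- function(a, b, mask) {
  check_same_lattice(a, b)
  m <- as_mask(mask, a)
  mean(abs(a$data[m] - b$data[m]))
}

#' Masked peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)` with the MSE over in-mask voxels; identical
#' images return `Inf`.
#'
#' @inheritParams masked_mae
#' @param data_range dynamic range of the data (default 1, for volumes scaled
#'   to \[0, 1\]).
#' @return PSNR in dB (possibly `Inf`).
#' @export
masked_psnr <- function(a, b, mask, data_range = 1) {
  if (data_range <= 0) stop("data_range must be positive")
  check_same_lattice(a, b)
  m <- as_mask(mask, a)
  mse <- mean((a$data[m] - b$data[m])^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Masked structural similarity index
#'
#' Local-window SSIM with a cubic box window: per-voxel local means,
#' variances (population form) and covariance are computed with replicate
#' padding at the edges, combined with the standard stabilizing constants
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2`, and the SSIM map is averaged over
#' windows whose centres are in-mask (`mask_mode = "centers"`), after
#' zeroing both volumes outside the mask.  `mask_mode = "global"` averages
#' over the whole volume without masking.
#'
#' @inheritParams masked_psnr
#' @param window odd cubic window edge (default 7).
#' @param K1,K2 stabilizing constants (defaults 0.01, 0.03).
#' @param mask_mode `"centers"` (default) or `"global"`.
#' @return SSIM in \[-1, 1\]; exactly 1 iff the compared windows are identical.
#' @export
masked_ssim <- function(a, b, mask, data_range = 1, window = 7L,
                        K1 = 0.01, K2 = 0.03,
                        mask_mode = c("centers", "global")) {
  mask_mode <- match.arg(mask_mode)
  check_same_lattice(a, b)
  if (window %% 2L == 0L) stop("window must be odd")
  if (any(window > dim(a$data))) stop("window does not fit inside the volume")
  xa <- a$data; xb <- b$data
  if (mask_mode == "centers") {
    m <- as_mask(mask, a)
    xa[!m] <- 0; xb[!m] <- 0
  }
  ssim_map <- ssim_map_box(xa, xb, window, data_range, K1, K2)
  if (mask_mode == "centers") mean(ssim_map[m]) else mean(ssim_map)
}

# voxel-wise SSIM map with a box window and replicate padding
ssim_map_box <- function(xa, xb, window, data_range, K1, K2) {
  kern <- rep(1 / window, window)
  box <- function(v) separable_filter(v, list(kern, kern, kern))
  mu_a <- box(xa); mu_b <- box(xb)
  va <- box(xa * xa) - mu_a^2
  vb <- box(xb * xb) - mu_b^2
  cab <- box(xa * xb) - mu_a * mu_b
  va <- pmax(va, 0); vb <- pmax(vb, 0)   # guard tiny negative round-off
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
}

#' Image-quality metric bundle
#'
#' Computes masked MAE, PSNR and SSIM for one predicted/ground-truth pair.
#'
#' @inheritParams masked_psnr
#' @return List with `mae`, `psnr`, `ssim`.
#' @export
quality_metrics <- function(a, b, mask, data_range = 1) {
  list(mae = masked_mae(a, b, mask),
       psnr = masked_psnr(a, b, mask, data_range),
       ssim = masked_ssim(a, b, mask, data_range))
}

#' Aggregate per-subject metrics
#'
#' Mean and sample SD of each metric across subjects, mirroring cohort-level
#' "mean +/- SD" reporting.
#'
#' @param metric_list list of [quality_metrics()] results.
#' @return data.frame with columns metric, mean, sd, n.
#' @export
aggregate_metrics <- function(metric_list) {
  stopifnot(length(metric_list) >= 1L)
  do.call(rbind, lapply(c("mae", "psnr", "ssim"), function(nm) {
    v <- vapply(metric_list, `[[`, 0, nm)
    data.frame(metric = nm, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v))
  }))
}
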