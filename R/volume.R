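#' 3D volume container
#'
#' A `sipcom_volume` is the common currency of the pipeline: a 3D numeric
#' voxel array together with its voxel size (mm per axis), a voxel-to-world
#' affine (0-based voxel indices, RAS-style mm coordinates, NIfTI convention)
#' and an optional modality tag.
#'
#' @param data 3D numeric array of voxel values.
#' @param voxel_mm numeric(3), voxel edge lengths in mm (all > 0).
#' @param affine 4x4 voxel-to-world affine. Default: axis-aligned with the
#'   volume centre at the world origin.
#' @param modality optional character tag, e.g. `"t1w"` or `"pet"`.
#' @return An object of class `sipcom_volume`.
#' @export
volume3d <- function(data, voxel_mm, affine = NULL, modality = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array, got ", length(dim(data)), " dimension(s)")
  if (!all(is.finite(data)))
    stop("volume contains non-finite values")
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(voxel_mm <= 0)) stop("voxel sizes must be positive")
  if (is.null(affine)) {
    d <- dim(data)
    # centre of the grid at world origin; world = vox * (i0 - (d-1)/2), i0 0-based
    affine <- rbind(cbind(diag(voxel_mm), -voxel_mm * (d - 1) / 2), c(0, 0, 0, 1))
  }
  affine <- matrix(as.numeric(affine), 4L, 4L)
  structure(list(data = data, voxel_mm = voxel_mm, affine = affine,
                 modality = modality),
            class = "sipcom_volume")
}

#' @export
print.sipcom_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sipcom_volume%s> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              if (is.null(x$modality)) "" else paste0(" ", x$modality),
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.sipcom_volume <- function(x) dim(x$data)

as_volume <- function(x, like = NULL) {
  if (inherits(x, "sipcom_volume")) return(x)
  if (is.array(x) && !is.null(like))
    return(volume3d(x, like$voxel_mm, like$affine, like$modality))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a volume")
}

# voxel (1-based ijk matrix) -> world mm using the stored affine
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  h <- cbind(ijk - 1, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

# checks two volumes (or a volume and a logical mask) share a lattice
check_same_lattice <- function(a, b, what = "volumes") {
  da <- if (inherits(a, "sipcom_volume")) dim(a$data) else dim(a)
  db <- if (inherits(b, "sipcom_volume")) dim(b$data) else dim(b)
  if (!identical(da, db))
    stop(what, " are on different lattices: ", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"))
  if (inherits(a, "sipcom_volume") && inherits(b, "sipcom_volume") &&
      max(abs(a$voxel_mm - b$voxel_mm)) > 1e-6)
    stop(what, " have different voxel sizes")
  invisible(TRUE)
}

as_mask <- function(mask, vol = NULL) {
  m <- if (inherits(mask, "sipcom_volume")) mask$data else mask
  if (!is.array(m) || length(dim(m)) != 3L) stop("mask must be a 3D array")
  m <- array(as.logical(m != 0 & !is.na(m)), dim(m))
  if (!any(m)) stop("mask is empty")
  if (!is.null(vol)) check_same_lattice(vol, m, "volume and mask")
  m
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param modality optional modality tag to attach.
#' @return A [volume3d()] object preserving voxel sizes and world transform.
#' @export
read_volume <- function(path, modality = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D: ", path)
  vox <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  volume3d(array(as.numeric(img), d), vox, aff, modality)
}

#' Write a volume to NIfTI
#'
#' @param vol a [volume3d()] object (or logical mask array with `like` geometry
#'   via [volume3d()] first).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "sipcom_volume"))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, vol$voxel_mm)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Min-max intensity scaling to [0, 1]
#'
#' Affine rescaling so the scaling domain (whole volume by default, or the
#' mask if given) spans exactly \[0, 1\].
#'
#' @param vol a [volume3d()] object.
#' @param mask optional logical mask restricting the domain over which min and
#'   max are taken; the affine map is applied to the whole volume.
#' @return The rescaled volume.
#' @export
minmax_scale <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "sipcom_volume"))
  dom <- if (is.null(mask)) vol$data else vol$data[as_mask(mask, vol)]
  lo <- min(dom); hi <- max(dom)
  if (hi - lo <= 0)
    stop("cannot min-max scale a constant volume (zero dynamic range)")
  out <- (vol$data - lo) / (hi - lo)
  volume3d(out, vol$voxel_mm, vol$affine, vol$modality)
}

# 1D correlation of a 3D array along one axis with an odd symmetric kernel,
# replicate (edge-clamp) padding.  Shared by gaussian_smooth() and the SSIM
# window statistics.
filter_axis <- function(arr, axis, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- dim(arr)[axis]
  out <- array(0, dim(arr))
  for (j in seq(-r, r)) {
    idx <- pmin.int(pmax.int(seq_len(n) + j, 1L), n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kernel[j + r + 1L] * shifted
  }
  out
}

separable_filter <- function(arr, kernels) {
  for (ax in 1:3) if (!is.null(kernels[[ax]])) arr <- filter_axis(arr, ax, kernels[[ax]])
  arr
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(NULL)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-0.5 * (seq(-r, r) / sigma_vox)^2)
  k / sum(k)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with the kernel width specified as a
#' full-width-at-half-maximum in mm; the per-axis kernel is scaled by the
#' voxel size (sigma = FWHM / sqrt(8 ln 2)).  Edges use replicate padding so
#' constant volumes are exactly preserved.  `fwhm_mm = 0` is the identity.
#'
#' @param vol a [volume3d()] object.
#' @param fwhm_mm kernel full width at half maximum, in mm (>= 0).
#' @return The smoothed volume.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "sipcom_volume"))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / sqrt(8 * log(2))
  kernels <- lapply(1:3, function(ax) gaussian_kernel_1d(sigma_mm / vol$voxel_mm[ax]))
  volume3d(separable_filter(vol$data, kernels), vol$voxel_mm, vol$affine, vol$modality)
}

# offsets of a 3D structuring element / neighbourhood, excluding the origin
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

# shift a logical array by an integer offset, filling with FALSE
shift_logical <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    src[[ax]] <- if (o >= 0) seq_len(d[ax] - o) + o else seq_len(d[ax] + o)
    dst[[ax]] <- if (o >= 0) seq_len(d[ax] - o) else seq_len(d[ax] + o) - o
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Morphological erosion of a brain mask
#'
#' Applies `n_voxels` iterations of one-voxel erosion with the chosen
#' structuring element (face-connected cross by default).  Voxels outside the
#' volume count as background, as is standard.
#'
#' @param mask logical 3D array (or a `sipcom_volume` holding 0/1 data).
#' @param n_voxels number of erosion iterations (>= 0); 0 is the identity.
#' @param connectivity structuring element: 6 (cross), 18, or 26 (box).
#' @return The eroded logical mask.
#' @export
erode_mask <- function(mask, n_voxels, connectivity = 6L) {
  m <- as_mask(mask)
  if (!is.finite(n_voxels) || n_voxels < 0 || n_voxels != round(n_voxels))
    stop("n_voxels must be a non-negative integer")
  offs <- connectivity_offsets(connectivity)
  for (i in seq_len(n_voxels)) {
    out <- m
    for (r in seq_len(nrow(offs))) out <- out & shift_logical(m, offs[r, ])
    m <- out
    if (!any(m))
      stop("erosion by ", i, " voxel(s) emptied the mask; mask too small")
  }
  m
}
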