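#' Specification of a paired T1w/PET phantom
#'
#' Describes a synthetic head: an ellipsoidal brain with three concentric
#' tissue shells (WM core, GM shell, CSF rim) whose T1w and PET intensities
#' are tissue-class lookups, plus additive Gaussian noise added *before*
#' smoothing so the noise is spatially correlated as in PSF-limited PET.
#' T1w and PET share the same tissue geometry, so the PET is a deterministic
#' function of the T1w tissue map up to noise — the property an MRI-to-PET
#' translation model is expected to learn.
#'
#' @param shape integer(3) grid size in voxels.
#' @param voxel_mm isotropic voxel size in mm.
#' @param semi_axes_mm ellipsoid semi-axes (a, b, c) in mm.
#' @param tissue data.frame with columns `class`, `t1w`, `pet` giving mean
#'   intensities (in \[0, 1\]) for csf/gm/wm. GM is brightest on PET,
#'   WM brightest on T1w by default.
#' @param noise_sd additive Gaussian noise SD, as a fraction of the \[0, 1\]
#'   intensity range (>= 0).
#' @param fwhm_mm Gaussian smoothing FWHM applied after noise (0 = none).
#' @param seed integer random seed; the full phantom is a pure function of
#'   this spec including the seed.
#' @return A `sipcom_phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), voxel_mm = 2,
                         semi_axes_mm = c(50, 60, 50),
                         tissue = data.frame(
                           class = c("csf", "gm", "wm"),
                           t1w = c(0.10, 0.45, 0.85),
                           pet = c(0.05, 0.80, 0.45)),
                         noise_sd = 0.02, fwhm_mm = 3, seed = 1L) {
  shape <- rep_len(as.integer(shape), 3L)
  if (any(shape <= 0)) stop("grid shape must be positive")
  if (voxel_mm <= 0) stop("voxel size must be positive")
  if (any(semi_axes_mm <= 0)) stop("semi-axes must be positive")
  stopifnot(is.data.frame(tissue),
            all(c("class", "t1w", "pet") %in% names(tissue)))
  if (any(tissue$t1w < 0 | tissue$t1w > 1 | tissue$pet < 0 | tissue$pet > 1))
    stop("tissue intensities must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  structure(list(shape = shape, voxel_mm = voxel_mm,
                 semi_axes_mm = as.numeric(rep_len(semi_axes_mm, 3L)),
                 tissue = tissue, noise_sd = noise_sd, fwhm_mm = fwhm_mm,
                 seed = as.integer(seed)),
            class = "sipcom_phantom_spec")
}

#' Specification of a focal hypometabolic lesion
#'
#' A spherical multiplicative intensity reduction standing in for the
#' hypometabolic epileptogenic zone: PET values inside the sphere are
#' multiplied by `factor` (< 1 models hypometabolism), with optional Gaussian
#' feathering of the edge over `softness_mm`.
#'
#' @param center_mm lesion centre in world mm coordinates.
#' @param radius_mm sphere radius in mm (> 0).
#' @param factor multiplier in (0, 1]; 1 leaves the volume untouched.
#' @param softness_mm Gaussian feathering scale at the edge (0 = hard edge).
#' @return A `sipcom_lesion_spec` list.
#' @export
lesion_spec <- function(center_mm = c(0, 0, 0), radius_mm = 8, factor = 0.7,
                        softness_mm = 0) {
  if (radius_mm <= 0) stop("radius must be positive")
  if (factor <= 0 || factor > 1) stop("factor must lie in (0, 1]")
  if (softness_mm < 0) stop("softness must be >= 0")
  structure(list(center_mm = as.numeric(rep_len(center_mm, 3L)),
                 radius_mm = radius_mm, factor = factor,
                 softness_mm = softness_mm),
            class = "sipcom_lesion_spec")
}

# world coordinates (mm, volume centre at origin) of every voxel, per axis
phantom_world_axes <- function(shape, voxel_mm) {
  lapply(1:3, function(ax) (seq_len(shape[ax]) - (shape[ax] + 1) / 2) * voxel_mm)
}

# canonical short codes of the 18 bilateral cortical regions (see evaluate.R)
phantom_region_codes <- function() region_codes()

#' Generate a paired T1w/PET phantom study
#'
#' Produces a T1w volume, a PET volume sharing the same tissue geometry, a
#' brain mask (the ellipsoid support) and a 36-label toy atlas (18 regions x
#' 2 hemispheres) built by geometric sectoring: hemispheres split by the
#' world x sign, 18 sectors from 3 axial slabs x 6 angular wedges.  Every
#' in-mask voxel carries exactly one label; background is 0.
#'
#' @param spec a [phantom_spec()].
#' @return A `sipcom_study` list with elements `t1w`, `pet` (both
#'   [volume3d()]), `mask` (logical array), `atlas` (integer array),
#'   `atlas_table` (data.frame: label_id, region_code, hemisphere) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "sipcom_phantom_spec"))
  d <- spec$shape; vox <- spec$voxel_mm; ax <- spec$semi_axes_mm
  if (any(2 * ax > d * vox))
    stop("grid too small to contain the brain ellipsoid: needs ",
         paste(ceiling(2 * ax / vox), collapse = "x"), " voxels")
  w <- phantom_world_axes(d, vox)
  x <- array(w[[1]], d)
  y <- array(rep(w[[2]], each = d[1]), d)
  z <- array(rep(w[[3]], each = d[1] * d[2]), d)
  r2 <- (x / ax[1])^2 + (y / ax[2])^2 + (z / ax[3])^2
  mask <- r2 <= 1
  r <- sqrt(r2)
  tis <- array(0L, d)                      # 0 bg, 1 csf, 2 gm, 3 wm
  tis[mask & r > 0.85] <- 1L
  tis[mask & r <= 0.85] <- 2L
  tis[r <= 0.55] <- 3L

  tt <- spec$tissue
  lut_t1 <- c(0, tt$t1w[match(c("csf", "gm", "wm"), tt$class)])
  lut_pet <- c(0, tt$pet[match(c("csf", "gm", "wm"), tt$class)])
  t1 <- array(lut_t1[tis + 1L], d)
  pet <- array(lut_pet[tis + 1L], d)

  nmask <- sum(mask)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    t1[mask] <- t1[mask] + stats::rnorm(nmask, 0, spec$noise_sd)
    pet[mask] <- pet[mask] + stats::rnorm(nmask, 0, spec$noise_sd)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()) else
    rm(".Random.seed", envir = globalenv())

  t1v <- volume3d(t1, vox, modality = "t1w")
  petv <- volume3d(pet, vox, modality = "pet")
  if (spec$fwhm_mm > 0) {
    t1v <- gaussian_smooth(t1v, spec$fwhm_mm)
    petv <- gaussian_smooth(petv, spec$fwhm_mm)
  }

  # toy atlas: 3 axial slabs x 6 wedges (mirror-symmetric via |x|), 2 hemis
  slab <- pmin.int(2L, pmax.int(0L, floor((z + ax[3]) / (2 * ax[3] / 3))))
  # within a hemisphere |x| >= 0, so the (|x|, y) angle spans [-pi/2, pi/2];
  # divide that half-circle into the 6 lobe-like wedges
  wedge <- pmin.int(5L, pmax.int(0L, floor((atan2(y, abs(x)) + pi / 2) / (pi / 6))))
  sector <- slab * 6L + wedge + 1L                   # 1..18
  hemi_right <- x >= 0
  atlas <- array(0L, d)
  atlas[mask] <- sector[mask] + ifelse(hemi_right[mask], 18L, 0L)
  codes <- phantom_region_codes()
  atlas_table <- data.frame(
    label_id = 1:36,
    region_code = rep(codes, 2L),
    hemisphere = rep(c("L", "R"), each = 18L),
    stringsAsFactors = FALSE)

  structure(list(t1w = t1v, pet = petv, mask = mask, atlas = atlas,
                 atlas_table = atlas_table, spec = spec),
            class = "sipcom_study")
}

#' @export
print.sipcom_study <- function(x, ...) {
  d <- x$spec$shape
  cat(sprintf("<sipcom_study> %dx%dx%d @ %g mm, brain %d voxels (%.1f mL), seed %d\n",
              d[1], d[2], d[3], x$spec$voxel_mm, sum(x$mask),
              sum(x$mask) * x$spec$voxel_mm^3 / 1000, x$spec$seed))
  invisible(x)
}

# signed multiplicative field of a lesion over a volume's grid; 1 = untouched
lesion_weight <- function(vol, lesion) {
  d <- dim(vol$data)
  wax <- phantom_world_axes(d, vol$voxel_mm[1])
  x <- array(wax[[1]], d)
  y <- array(rep(wax[[2]], each = d[1]), d)
  z <- array(rep(wax[[3]], each = d[1] * d[2]), d)
  dist <- sqrt((x - lesion$center_mm[1])^2 + (y - lesion$center_mm[2])^2 +
                 (z - lesion$center_mm[3])^2)
  g <- array(0, d)
  g[dist <= lesion$radius_mm] <- 1
  if (lesion$softness_mm > 0) {
    edge <- dist > lesion$radius_mm & dist <= lesion$radius_mm + 3 * lesion$softness_mm
    g[edge] <- exp(-((dist[edge] - lesion$radius_mm)^2) / (2 * lesion$softness_mm^2))
  }
  1 + (lesion$factor - 1) * g
}

#' Binary mask of a lesion's spherical core
#'
#' @param vol a [volume3d()] defining the grid geometry.
#' @param lesion a [lesion_spec()].
#' @return Logical array, TRUE within `radius_mm` of the lesion centre.
#' @export
lesion_mask <- function(vol, lesion) {
  lesion_weight(vol, lesion_spec(lesion$center_mm, lesion$radius_mm,
                                 factor = 0.5, softness_mm = 0)) != 1
}

#' Inject a hypometabolic lesion into a PET volume
#'
#' Multiplies voxel values inside the lesion sphere by `factor`, with optional
#' Gaussian feathering of the edge; voxels outside the lesion support
#' (sphere plus 3 x softness) are returned bit-for-bit unchanged.
#'
#' @param pet a PET [volume3d()].
#' @param lesion a [lesion_spec()].
#' @param mask optional brain mask; if given, the lesion centre must fall
#'   inside it.
#' @return A modified copy of `pet`.
#' @export
inject_lesion <- function(pet, lesion, mask = NULL) {
  stopifnot(inherits(pet, "sipcom_volume"), inherits(lesion, "sipcom_lesion_spec"))
  if (!is.null(mask)) {
    m <- as_mask(mask, pet)
    d <- dim(pet$data)
    ctr_vox <- round(lesion$center_mm / pet$voxel_mm + (d + 1) / 2)
    if (any(ctr_vox < 1 | ctr_vox > d) || !m[ctr_vox[1], ctr_vox[2], ctr_vox[3]])
      stop("lesion centre lies outside the brain mask")
  }
  w <- lesion_weight(pet, lesion)
  out <- pet
  touched <- w != 1
  out$data[touched] <- pet$data[touched] * w[touched]
  out
}

#' Write a phantom study to disk
#'
#' Writes the four volumes as NIfTI (`t1w.nii.gz`, `pet.nii.gz`,
#' `mask.nii.gz`, `atlas.nii.gz`) and the atlas label table as
#' `atlas_labels.csv` in `dir`.
#'
#' @param study a `sipcom_study` from [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sipcom_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(study$t1w, file.path(dir, "t1w.nii.gz"))
  write_volume(study$pet, file.path(dir, "pet.nii.gz"))
  g <- study$t1w
  write_volume(volume3d(array(as.numeric(study$mask), dim(g$data)),
                        g$voxel_mm, g$affine, "mask"),
               file.path(dir, "mask.nii.gz"))
  write_volume(volume3d(array(as.numeric(study$atlas), dim(g$data)),
                        g$voxel_mm, g$affine, "atlas"),
               file.path(dir, "atlas.nii.gz"))
  utils::write.csv(study$atlas_table, file.path(dir, "atlas_labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}
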