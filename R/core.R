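#' Detection configuration for Z-map clustering
#'
#' @param z_threshold voxel threshold on the (sign-adjusted) Z value
#'   (default 2.33, i.e. one-sided p ~ 0.01).
#' @param min_volume_ml minimum cluster volume in mL (default 1; equal to
#'   1000 voxels on a 1 mm isotropic grid, converted via the voxel volume
#'   elsewhere).
#' @param connectivity voxel connectivity for clustering: 6, 18 or 26.
#' @param erosion_voxels brain-mask erosion iterations applied before
#'   thresholding, to suppress low-intensity border artifacts (default 3).
#' @param erosion_connectivity structuring element of the erosion (default 6).
#' @param hypo_positive if TRUE (default) the standardized difference is
#'   negated so that hypometabolism (clinical < predicted) scores positive Z
#'   and the `Z > z_threshold` rule targets hypometabolic foci; set FALSE to
#'   threshold the raw clinical-minus-predicted tail.
#' @return A `sipcom_detection_config` list.
#' @export
detection_config <- function(z_threshold = 2.33, min_volume_ml = 1,
                             connectivity = 26L, erosion_voxels = 3L,
                             erosion_connectivity = 6L, hypo_positive = TRUE) {
  if (z_threshold <= 0) stop("z_threshold must be positive")
  if (min_volume_ml <= 0) stop("min_volume_ml must be positive")
  connectivity_offsets(connectivity)  # validates
  structure(list(z_threshold = z_threshold, min_volume_ml = min_volume_ml,
                 connectivity = as.integer(connectivity),
                 erosion_voxels = as.integer(erosion_voxels),
                 erosion_connectivity = as.integer(erosion_connectivity),
                 hypo_positive = isTRUE(hypo_positive)),
            class = "sipcom_detection_config")
}

#' Match the predicted PET's global mean to the clinical PET
#'
#' Multiplies the predicted volume by the ratio of in-mask mean intensities,
#' clinical over predicted, so the two means agree exactly.
#'
#' @param predicted,clinical [volume3d()] objects on the same lattice.
#' @param mask brain mask defining the mean-intensity domain.
#' @return The rescaled predicted volume.
#' @export
scale_predicted <- function(predicted, clinical, mask) {
  check_same_lattice(predicted, clinical)
  m <- as_mask(mask, predicted)
  mp <- mean(predicted$data[m])
  if (abs(mp) < 1e-12) stop("predicted PET has zero mean within the mask")
  ratio <- mean(clinical$data[m]) / mp
  out <- predicted
  out$data <- predicted$data * ratio
  attr(out, "scaling_ratio") <- ratio
  out
}

#' Standardized difference map (Z-map)
#'
#' Subtracts the (mean-matched) predicted PET from the clinical PET and
#' converts the difference to Z-scores, `Z = (D - mu) / sigma`, with mean and
#' population standard deviation taken over in-mask voxels.  Under the
#' default hypometabolism-positive convention the map is negated so that
#' clinical < predicted yields positive Z.
#'
#' @param clinical,scaled_predicted [volume3d()] objects on the same lattice.
#' @param mask brain mask (standardization domain).
#' @param hypo_positive see [detection_config()].
#' @return A `sipcom_zmap`: the Z volume, the mask, and provenance
#'   (`mu`, `sigma` of the raw difference, sign convention).
#' @export
difference_zmap <- function(clinical, scaled_predicted, mask,
                            hypo_positive = TRUE) {
  check_same_lattice(clinical, scaled_predicted)
  m <- as_mask(mask, clinical)
  d <- clinical$data - scaled_predicted$data
  dv <- d[m]
  mu <- mean(dv)
  sigma <- sqrt(mean((dv - mu)^2))       # population SD
  if (sigma <= 0)
    stop("difference image has zero variance within the mask ",
         "(clinical and predicted are identical?)")
  z <- (d - mu) / sigma
  if (hypo_positive) z <- -z
  structure(list(z = volume3d(z, clinical$voxel_mm, clinical$affine, "zmap"),
                 mask = m, mu = mu, sigma = sigma,
                 hypo_positive = hypo_positive,
                 scaling_ratio = attr(scaled_predicted, "scaling_ratio")),
            class = "sipcom_zmap")
}

#' @export
print.sipcom_zmap <- function(x, ...) {
  cat(sprintf("<sipcom_zmap> %s; mu=%.4g sigma=%.4g, %s convention\n",
              paste(dim(x$z$data), collapse = "x"), x$mu, x$sigma,
              if (x$hypo_positive) "hypometabolism-positive" else "raw-difference"))
  invisible(x)
}

# connected components of a logical array via an adjacency edge list
# (igraph backend); returns integer label array, 0 = background
label_components <- function(supra, connectivity) {
  d <- dim(supra)
  vox <- which(supra)
  n <- length(vox)
  lab <- array(0L, d)
  if (n == 0L) return(lab)
  rank <- integer(prod(d))
  rank[vox] <- seq_len(n)
  co <- arrayInd(vox, d)
  offs <- connectivity_offsets(connectivity)
  keep_half <- offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  offs <- offs[keep_half, , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    ni <- co[, 1] + offs[r, 1]; nj <- co[, 2] + offs[r, 2]; nk <- co[, 3] + offs[r, 3]
    inb <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    nl <- ni[inb] + (nj[inb] - 1L) * d[1] + (nk[inb] - 1L) * d[1] * d[2]
    nr <- rank[nl]
    src <- seq_len(n)[inb]
    hit <- nr > 0L
    edges[[r]] <- cbind(src[hit], nr[hit])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(em) && nrow(em)) g <- igraph::add_edges(g, t(em))
  lab[vox] <- igraph::components(g)$membership
  lab
}

#' Extract supra-threshold clusters from a Z-map
#'
#' Thresholds the Z-map (strictly above `z_threshold`) within the eroded
#' brain mask, groups supra-threshold voxels into connected components at the
#' configured connectivity, discards components below the minimum volume
#' (mL, converted through the voxel volume), and reports per-cluster
#' statistics sorted by peak Z.
#'
#' @param zmap a `sipcom_zmap` from [difference_zmap()].
#' @param config a [detection_config()].
#' @param atlas optional integer label array (plus `atlas_table`) for region
#'   assignment; see [assign_cluster_regions()].
#' @param atlas_table data.frame mapping `label_id` to `region_code` and
#'   `hemisphere` (required when `atlas` is given).
#' @return A `sipcom_clusters` data.frame: `cluster_id`, `n_voxels`,
#'   `volume_ml`, `peak_z`, `mean_z`, centroid in voxel and world mm
#'   coordinates, and (with an atlas) `regions` / `overlap_fractions`.
#'   Cluster voxel memberships are kept in `attr(, "voxels")`.
#' @export
extract_clusters <- function(zmap, config = detection_config(), atlas = NULL,
                             atlas_table = NULL) {
  stopifnot(inherits(zmap, "sipcom_zmap"),
            inherits(config, "sipcom_detection_config"))
  emask <- if (config$erosion_voxels > 0L)
    erode_mask(zmap$mask, config$erosion_voxels, config$erosion_connectivity)
  else zmap$mask
  zd <- zmap$z$data
  supra <- emask & zd > config$z_threshold
  lab <- label_components(supra, config$connectivity)
  voxvol_ml <- prod(zmap$z$voxel_mm) / 1000
  ids <- setdiff(unique(as.integer(lab)), 0L)
  keep <- list(); vox_list <- list()
  for (id in ids) {
    v <- which(lab == id)
    vol_ml <- length(v) * voxvol_ml
    if (vol_ml >= config$min_volume_ml - 1e-9) {
      keep[[length(keep) + 1L]] <- v
    }
  }
  geom <- zmap$z
  if (length(keep) == 0L) {
    tab <- empty_cluster_table()
  } else {
    rows <- lapply(keep, function(v) {
      co <- arrayInd(v, dim(zd))
      ctr_vox <- colMeans(co)
      ctr_mm <- as.numeric(voxel_to_world(geom, matrix(ctr_vox, 1)))
      data.frame(n_voxels = length(v),
                 volume_ml = length(v) * voxvol_ml,
                 peak_z = max(zd[v]), mean_z = mean(zd[v]),
                 centroid_i = ctr_vox[1], centroid_j = ctr_vox[2],
                 centroid_k = ctr_vox[3],
                 centroid_x_mm = ctr_mm[1], centroid_y_mm = ctr_mm[2],
                 centroid_z_mm = ctr_mm[3])
    })
    tab <- do.call(rbind, rows)
    ord <- order(-tab$peak_z)
    tab <- tab[ord, , drop = FALSE]
    keep <- keep[ord]
    tab <- cbind(cluster_id = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
  }
  attr(tab, "voxels") <- keep
  attr(tab, "geometry") <- list(dim = dim(zd), voxel_mm = geom$voxel_mm,
                                affine = geom$affine)
  class(tab) <- c("sipcom_clusters", "data.frame")
  if (!is.null(atlas)) tab <- assign_cluster_regions(tab, atlas, atlas_table)
  tab
}

empty_cluster_table <- function() {
  data.frame(cluster_id = integer(), n_voxels = integer(), volume_ml = numeric(),
             peak_z = numeric(), mean_z = numeric(),
             centroid_i = numeric(), centroid_j = numeric(), centroid_k = numeric(),
             centroid_x_mm = numeric(), centroid_y_mm = numeric(),
             centroid_z_mm = numeric())
}

#' @export
print.sipcom_clusters <- function(x, ...) {
  cat(sprintf("<sipcom_clusters> %d cluster(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write a cluster table to CSV
#'
#' @param clusters a `sipcom_clusters` table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.csv(as.data.frame(clusters), path, row.names = FALSE)
  invisible(path)
}

#' Run the full subtraction pipeline on one subject
#'
#' Composes the stages: preprocessing of the clinical PET (Gaussian
#' smoothing, then min-max scaling), pseudo-normal PET prediction from T1w
#' via a trained generator (skipped when `predicted` is supplied directly,
#' in which case the same preprocessing is applied to it), global-mean
#' matching, Z standardization within the brain mask, and cluster
#' extraction within the eroded mask.
#'
#' @param clinical clinical PET [volume3d()].
#' @param mask brain mask (logical array on the same lattice).
#' @param t1w T1w [volume3d()] (required when `predicted` is NULL).
#' @param state trained `sipcom_generator` (required when `predicted` is NULL).
#' @param predicted optionally, a pseudo-normal PET supplied directly.
#' @param detection a [detection_config()].
#' @param fwhm_mm PET smoothing FWHM in mm (default 2; 0 disables).
#' @param scale if TRUE (default), min-max scale volumes to \[0, 1\].
#' @param prep_order `"smooth_then_scale"` (default) or `"scale_then_smooth"`.
#' @param atlas,atlas_table optional region atlas for cluster localisation.
#' @return A `sipcom_result`: `zmap`, `clusters`, and a `provenance` list
#'   (preprocessing, scaling ratio, detection parameters).
#' @export
run_sipcom <- function(clinical, mask, t1w = NULL, state = NULL,
                       predicted = NULL, detection = detection_config(),
                       fwhm_mm = 2, scale = TRUE,
                       prep_order = c("smooth_then_scale", "scale_then_smooth"),
                       atlas = NULL, atlas_table = NULL) {
  prep_order <- match.arg(prep_order)
  m <- as_mask(mask, clinical)
  prep <- function(v) {
    if (prep_order == "smooth_then_scale") {
      if (fwhm_mm > 0) v <- gaussian_smooth(v, fwhm_mm)
      if (scale) v <- minmax_scale(v)
    } else {
      if (scale) v <- minmax_scale(v)
      if (fwhm_mm > 0) v <- gaussian_smooth(v, fwhm_mm)
    }
    v
  }
  clin <- prep(clinical)
  if (is.null(predicted)) {
    if (is.null(t1w) || is.null(state))
      stop("supply either 'predicted' or both 't1w' and 'state'")
    t1in <- if (scale) minmax_scale(t1w) else t1w
    pred <- predict_volume(state, t1in, mask = NULL)
  } else {
    check_same_lattice(clinical, predicted)
    pred <- prep(predicted)
  }
  pred <- scale_predicted(pred, clin, m)
  zmap <- difference_zmap(clin, pred, m, hypo_positive = detection$hypo_positive)
  clusters <- extract_clusters(zmap, detection, atlas = atlas,
                               atlas_table = atlas_table)
  structure(list(zmap = zmap, clusters = clusters,
                 provenance = list(
                   fwhm_mm = fwhm_mm, scale = scale, prep_order = prep_order,
                   predicted_supplied = !is.null(predicted),
                   scaling_ratio = attr(pred, "scaling_ratio"),
                   mu = zmap$mu, sigma = zmap$sigma,
                   detection = unclass(detection))),
            class = "sipcom_result")
}

#' @export
print.sipcom_result <- function(x, ...) {
  cat("<sipcom_result>\n")
  print(x$zmap)
  print(x$clusters)
  invisible(x)
}

#' Write a provenance record as JSON
#'
#' @param result a `sipcom_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(result, path) {
  jsonlite::write_json(result$provenance, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
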