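test_that("mean-ratio scaling matches the clinical mean exactly", {
  set.seed(21)
  d <- c(8, 8, 8); m <- array(TRUE, d)
  clin <- volume3d(array(runif(prod(d), 1, 3), d), 1)
  pred <- volume3d(array(runif(prod(d), 0.5, 1.5), d), 1)
  sc <- scale_predicted(pred, clin, m)
  expect_equal(mean(sc$data[m]), mean(clin$data[m]), tolerance = 1e-9)
  # clinical mean 2, predicted mean 1 -> doubled everywhere
  c2 <- volume3d(array(2, d), 1); p1 <- volume3d(array(1, d), 1)
  expect_equal(scale_predicted(p1, c2, m)$data, array(2, d))
  # already equal means -> unchanged
  expect_equal(scale_predicted(clin, clin, m)$data, clin$data)
  expect_error(scale_predicted(volume3d(array(0, d), 1), clin, m), "zero mean")
})

test_that("Z standardization uses the in-mask population SD and sign convention", {
  d <- c(3, 3, 3)
  clin <- volume3d(array(c(1, 2, 3, rep(0, 24)), d), 1)
  pred <- volume3d(array(0, d), 1)
  msk <- array(FALSE, d); msk[1:3] <- TRUE
  z <- difference_zmap(clin, pred, msk, hypo_positive = FALSE)
  expect_equal(z$z$data[1:3], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z$sigma, sqrt(2 / 3), tolerance = 1e-12)
  # hypometabolism-positive convention flips the sign
  zn <- difference_zmap(clin, pred, msk, hypo_positive = TRUE)
  expect_equal(zn$z$data[1:3], -z$z$data[1:3])
  # normalization invariant
  expect_lt(abs(mean(zn$z$data[msk])), 1e-6)
  expect_lt(abs(sqrt(mean(zn$z$data[msk]^2)) - 1), 1e-6)
  # degenerate difference images are rejected
  expect_error(difference_zmap(clin, clin, msk), "zero variance")
  shift <- clin; shift$data <- clin$data + 5
  expect_error(difference_zmap(shift, clin, msk), "zero variance")
})

test_that("a hypometabolic lesion scores positive Z under the default convention", {
  st <- tiny_study(seed = 31, noise = 0.01, fwhm = 2, shape = 48, vox = 1,
                   axes = c(20, 22, 18))
  clean <- generate_phantom(phantom_spec(shape = rep(48, 3), voxel_mm = 1,
                                         semi_axes_mm = c(20, 22, 18),
                                         noise_sd = 0, fwhm_mm = 2, seed = 31))
  les <- lesion_spec(c(6, 4, 0), radius_mm = 6, factor = 0.7)
  lesioned <- inject_lesion(st$pet, les, st$mask)
  z <- difference_zmap(lesioned, scale_predicted(clean$pet, lesioned, st$mask),
                       st$mask)
  core <- lesion_mask(st$pet, lesion_spec(c(6, 4, 0), radius_mm = 3, factor = 0.7))
  expect_gt(mean(z$z$data[core]), 1)
})

test_that("cluster extraction matches the worked 5^3 example at the volume boundary", {
  z <- array(0, c(5, 5, 5))
  z[2:3, 2:3, 2:3] <- 3
  zm <- as_test_zmap(z)
  cfg <- detection_config(z_threshold = 2.33, min_volume_ml = 0.004,
                          erosion_voxels = 0L)
  tab <- extract_clusters(zm, cfg)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_voxels, 8L)
  expect_equal(tab$peak_z, 3)
  expect_equal(tab$volume_ml, 0.008)
  # 8 voxels = 0.008 mL < 0.009 -> dropped
  cfg2 <- detection_config(z_threshold = 2.33, min_volume_ml = 0.009,
                           erosion_voxels = 0L)
  expect_equal(nrow(extract_clusters(zm, cfg2)), 0L)
  # all-zero map -> empty table
  expect_equal(nrow(extract_clusters(as_test_zmap(array(0, c(5, 5, 5))), cfg)), 0L)
})

test_that("connected-component labelling agrees with a flood-fill oracle", {
  for (i in 1:12) {
    dims <- sample(10:16, 3, replace = TRUE)
    z <- random_zfield(dims, seed = 100 + i, fwhm = 1.5)
    thr <- stats::quantile(z, 0.9)
    for (conn in c(6L, 18L, 26L)) {
      got <- sipcom:::label_components(z > thr, conn)
      want <- brute_components(z > thr, conn)
      expect_identical(component_signature(got), component_signature(want))
    }
  }
})

test_that("detections shrink monotonically as thresholds tighten", {
  z <- random_zfield(c(24, 24, 24), seed = 55, fwhm = 2)
  z <- (z - mean(z)) / sd(z)
  zm <- as_test_zmap(z)
  ext <- function(thr, mv) extract_clusters(
    zm, detection_config(z_threshold = thr, min_volume_ml = mv,
                         erosion_voxels = 0L))
  # raising the minimum volume never increases the cluster count
  mvs <- c(0.001, 0.004, 0.016, 0.064)
  counts_mv <- vapply(mvs, function(mv) nrow(ext(0.8, mv)), 0L)
  expect_true(all(diff(counts_mv) <= 0))
  # raising the Z threshold: every surviving cluster is contained in a
  # cluster found at the lower threshold, and the total supra voxel volume
  # never grows (a big cluster may split, so the count itself may rise)
  lo <- ext(0.8, 0.001); hi <- ext(1.6, 0.001)
  expect_lte(sum(hi$n_voxels), sum(lo$n_voxels))
  lo_vox <- unlist(attr(lo, "voxels"))
  for (v in attr(hi, "voxels")) expect_true(all(v %in% lo_vox))
})

test_that("cluster statistics and eroded-mask restriction are honoured", {
  st <- tiny_study(seed = 41, noise = 0, fwhm = 0, shape = 32, vox = 2,
                   axes = c(26, 28, 24))
  z <- array(0, dim(st$mask))
  z[14:17, 14:17, 14:17] <- 4                   # 64 voxels * 8 mm3 = 0.512 mL
  zm <- as_test_zmap(z, mask = st$mask, voxel_mm = 2)
  cfg <- detection_config(min_volume_ml = 0.5, erosion_voxels = 3L)
  tab <- extract_clusters(zm, cfg)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$volume_ml, 64 * 8 / 1000)
  expect_equal(tab$centroid_i, 15.5)
  em <- erode_mask(st$mask, 3)
  expect_true(all(em[attr(tab, "voxels")[[1]]]))
  # clusters cannot survive outside the eroded mask
  z2 <- array(0, dim(st$mask))
  edge <- which(st$mask & !em)
  z2[edge[1:80]] <- 4
  expect_equal(nrow(extract_clusters(as_test_zmap(z2, st$mask, 2), cfg)), 0L)
})

test_that("the full subtraction run recovers an injected lesion with an oracle predictor", {
  axes <- c(26, 28, 24)
  spec_noisy <- phantom_spec(shape = rep(64, 3), voxel_mm = 1,
                             semi_axes_mm = axes, noise_sd = 0.02,
                             fwhm_mm = 3, seed = 61)
  spec_clean <- phantom_spec(shape = rep(64, 3), voxel_mm = 1,
                             semi_axes_mm = axes, noise_sd = 0,
                             fwhm_mm = 3, seed = 61)
  st <- generate_phantom(spec_noisy)
  clean <- generate_phantom(spec_clean)
  les <- lesion_spec(c(10, 6, 2), radius_mm = 7.816, factor = 0.7)  # ~2 mL
  clinical <- inject_lesion(st$pet, les, st$mask)
  res <- run_sipcom(clinical, st$mask, predicted = clean$pet,
                    atlas = st$atlas, atlas_table = st$atlas_table)
  expect_gte(nrow(res$clusters), 1L)
  lm <- lesion_mask(st$pet, les)
  cl_mask <- array(FALSE, dim(st$mask))
  cl_mask[attr(res$clusters, "voxels")[[1]]] <- TRUE
  expect_gt(dice_coef(cl_mask, lm), 0.3)
  # centroid within one lesion radius of the true centre
  ctr <- c(res$clusters$centroid_x_mm[1], res$clusters$centroid_y_mm[1],
           res$clusters$centroid_z_mm[1])
  expect_lt(sqrt(sum((ctr - les$center_mm)^2)), les$radius_mm)
  # region assignment attached and non-empty for the lesion cluster
  expect_true(nzchar(res$clusters$regions[1]))
  # supplying predicted = clinical is degenerate
  expect_error(run_sipcom(clinical, st$mask, predicted = clinical),
               "zero variance")
})
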