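# Independent oracles used by the tests: deliberately naive implementations
# (loops, flood fill, direct formulas) against which the package's vectorized
# code paths are checked.

# connected components by breadth-first flood fill over an explicit queue
brute_components <- function(supra, connectivity) {
  d <- dim(supra)
  offs <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  nz <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1), ]
  lab <- array(0L, d)
  cur <- 0L
  queue <- integer(sum(supra))
  for (v in which(supra)) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue[1] <- v; head <- 1L; tail <- 1L
    lab[v] <- cur
    while (head <= tail) {
      q <- queue[head]; head <- head + 1L
      co <- arrayInd(q, d)
      for (r in seq_len(nrow(offs))) {
        ni <- co[1] + offs$a[r]; nj <- co[2] + offs$b[r]; nk <- co[3] + offs$c[r]
        if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] || nk < 1 || nk > d[3]) next
        if (!supra[ni, nj, nk]) next
        l <- ni + (nj - 1) * d[1] + (nk - 1) * d[1] * d[2]
        if (lab[l] == 0L) { lab[l] <- cur; tail <- tail + 1L; queue[tail] <- l }
      }
    }
  }
  lab
}

# canonical signature of a labelling: list of sorted voxel-index sets,
# ordered by their smallest member (invariant to label permutation)
component_signature <- function(lab) {
  ids <- setdiff(unique(as.integer(lab)), 0L)
  sets <- lapply(ids, function(i) sort(which(lab == i)))
  sets[order(vapply(sets, min, 0L))]
}

# mean absolute error by explicit loop over mask voxels
naive_masked_mae <- function(a, b, mask) {
  tot <- 0; n <- 0
  for (v in which(mask)) { tot <- tot + abs(a[v] - b[v]); n <- n + 1 }
  tot / n
}

# SSIM by direct per-window formula with edge-clamped (replicated) sampling,
# matching the replicate-padding convention of the box-filter implementation
naive_ssim <- function(xa, xb, window, data_range = 1, K1 = 0.01, K2 = 0.03) {
  d <- dim(xa)
  r <- (window - 1) %/% 2
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  out <- array(NA_real_, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    ii <- pmin(pmax(i + (-r:r), 1), d[1])
    jj <- pmin(pmax(j + (-r:r), 1), d[2])
    kk <- pmin(pmax(k + (-r:r), 1), d[3])
    wa <- xa[ii, jj, kk]; wb <- xb[ii, jj, kk]
    ma <- mean(wa); mb <- mean(wb)
    va <- mean((wa - ma)^2); vb <- mean((wb - mb)^2)
    cab <- mean((wa - ma) * (wb - mb))
    out[i, j, k] <- ((2 * ma * mb + C1) * (2 * cab + C2)) /
      ((ma^2 + mb^2 + C1) * (va + vb + C2))
  }
  out
}

# small smoothed random field useful for cluster tests
random_zfield <- function(dims, seed, fwhm = 2) {
  set.seed(seed)
  v <- volume3d(array(rnorm(prod(dims)), dims), 1)
  gaussian_smooth(v, fwhm)$data
}

# a Z-map object wrapped around an arbitrary array (unit standardization not
# required for cluster-extraction geometry tests)
as_test_zmap <- function(zarr, mask = NULL, voxel_mm = 1) {
  vol <- volume3d(zarr, voxel_mm)
  structure(list(z = vol,
                 mask = if (is.null(mask)) array(TRUE, dim(zarr)) else mask,
                 mu = 0, sigma = 1, hypo_positive = TRUE),
            class = "sipcom_zmap")
}

# small phantom pair used across tests
tiny_study <- function(seed = 1, noise = 0.02, fwhm = 2, shape = 32, vox = 2,
                       axes = c(24, 26, 22)) {
  generate_phantom(phantom_spec(shape = rep(shape, 3), voxel_mm = vox,
                                semi_axes_mm = axes, noise_sd = noise,
                                fwhm_mm = fwhm, seed = seed))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
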