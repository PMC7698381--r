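mask_all <- function(dims) array(TRUE, dims)

full_lesion <- function(dims) {
  lesion_mask(array(1, dims), "L1", "ovary", "pelvis")
}

test_that("rescale/discretize maps endpoints and degenerate input correctly", {
  dims <- c(6, 6, 2)
  # constant volume: degenerate range -> all level 1 with a warning
  vol <- ct_volume(array(7, dims))
  ls <- lesion_set(list(full_lesion(dims)), "p")
  expect_warning(d <- rescale_discretize(vol, ls), "degenerate")
  expect_true(all(d$levels == 1L))
  # two-valued volume: endpoints map to levels 1 and 32
  v <- array(100, dims); v[1, 1, 1] <- -50
  d2 <- rescale_discretize(ct_volume(v, patient_id = "p"), ls)
  expect_equal(sort(unique(as.integer(d2$levels))), c(1L, 32L))
})

test_that("linear ramp discretization matches the brute-force affine map", {
  dims <- c(40, 80, 1)  # 3200 voxels
  v <- array(seq(0, 3199), dim = dims)
  ls <- lesion_set(list(full_lesion(dims)), "p")
  d <- rescale_discretize(ct_volume(v, patient_id = "p"), ls)
  # oracle: affine map onto [0,255] then uniform 32-binning, top clamped
  y <- (as.vector(v) - 0) / 3199 * 255
  lev_oracle <- pmin(32, floor(y / 255 * 32) + 1)
  expect_identical(as.integer(d$levels), as.integer(lev_oracle))
  counts <- tabulate(d$levels, 32)
  expect_true(all(counts >= 99 & counts <= 101))
})

test_that("degenerate and hand-worked patches give exact Haralick values", {
  # constant patch: single-cell GLCM
  dims <- c(11, 11, 1)
  lev <- array(5L, dims)
  cfg <- texture_config()
  m <- haralick_maps(lev, full_lesion(dims), cfg)
  c0 <- c(6, 6, 1)
  expect_equal(m$energy[6, 6, 1], 1)
  expect_equal(m$entropy[6, 6, 1], 0)
  expect_equal(m$homogeneity[6, 6, 1], 1)
  expect_equal(m$contrast[6, 6, 1], 0)

  # strict 2-level checkerboard, horizontal offset only, symmetric
  lev2 <- array(0L, dims)
  for (x in 1:11) for (y in 1:11) lev2[x, y, 1] <- 1L + (x + y) %% 2L
  cfg_h <- texture_config(directions = matrix(c(1L, 0L, 0L), 1))
  m2 <- haralick_maps(lev2, full_lesion(dims), cfg_h)
  expect_equal(m2$energy[6, 6, 1], 0.5)
  expect_equal(m2$entropy[6, 6, 1], 1)       # 1 bit
  expect_equal(m2$homogeneity[6, 6, 1], 0.5)
  expect_equal(m2$contrast[6, 6, 1], 1)
})

test_that("per-voxel maps equal the naive brute-force GLCM oracle", {
  set.seed(401)
  cfg <- texture_config(n_levels = 8L)
  for (rep in 1:3) {
    dims <- c(20, 20, 1)
    lev <- array(sample.int(8, prod(dims), replace = TRUE), dims)
    les <- full_lesion(dims)
    m <- haralick_maps(lev, les, cfg)
    # spot-check a random sample of voxels against the oracle
    for (k in 1:25) {
      x <- sample.int(20, 1); y <- sample.int(20, 1)
      o <- oracle_haralick_voxel(lev, les$mask, x, y, 1, 5, 5, 0,
                                 cfg$directions, 8)
      expect_equal(m$energy[x, y, 1], o["energy"], tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(m$entropy[x, y, 1], o["entropy"], tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(m$homogeneity[x, y, 1], o["homogeneity"],
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(m$contrast[x, y, 1], o["contrast"], tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("co-occurrences never cross the lesion mask boundary", {
  set.seed(402)
  dims <- c(16, 16, 1)
  lev <- array(sample.int(6, prod(dims), replace = TRUE), dims)
  msk <- array(FALSE, dims)
  msk[3:14, 3:14, 1] <- TRUE
  msk[7:9, 7:9, 1] <- FALSE  # hole
  les <- lesion_mask(msk + 0, "L1", "ovary", "pelvis")
  cfg <- texture_config(n_levels = 6L)
  m <- haralick_maps(lev, les, cfg)
  idx <- which(msk, arr.ind = TRUE)
  for (k in sample(nrow(idx), 20)) {
    x <- idx[k, 1]; y <- idx[k, 2]
    o <- oracle_haralick_voxel(lev, msk, x, y, 1, 5, 5, 0, cfg$directions, 6)
    expect_equal(m$entropy[x, y, 1], o["entropy"], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_true(all(is.na(m$energy[!msk])))
})

test_that("gray-level permutation preserves energy/entropy but not contrast", {
  set.seed(403)
  dims <- c(15, 15, 1)
  lev <- array(sample.int(6, prod(dims), replace = TRUE), dims)
  perm <- sample(6)  # relabel levels
  lev_p <- array(perm[lev], dims)
  cfg <- texture_config(n_levels = 6L)
  les <- full_lesion(dims)
  m1 <- haralick_maps(lev, les, cfg)
  m2 <- haralick_maps(lev_p, les, cfg)
  expect_equal(m1$energy, m2$energy, tolerance = 1e-12)
  expect_equal(m1$entropy, m2$entropy, tolerance = 1e-12)
  expect_gt(max(abs(m1$contrast - m2$contrast), na.rm = TRUE), 0.1)
})

test_that("texture maps export as NIfTI with a config sidecar", {
  p <- tiny_patient(seed = 21, n_lesions = 1)
  maps <- patient_texture_maps(p$volume, p$lesions)[[1]]
  dir <- withr::local_tempdir()
  paths <- write_texture_maps(maps, p$volume, dir)
  expect_length(paths, 5L)
  expect_true(all(file.exists(paths)))
  back <- RNifti::readNifti(paths[1])
  idx <- which(!is.na(maps$energy))
  expect_equal(as.numeric(back)[idx], maps$energy[idx], tolerance = 1e-6)
})
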