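#' Texture patch configuration
#'
#' Controls the intensity rescaling/discretization and the per-voxel GLCM
#' patch. Defaults follow the pipeline's reference settings: intensities
#' rescaled to 0-255 and discretized into 32 levels, an 11 x 11 x 1 in-plane
#' patch, co-occurrences at distance 1 along the four standard in-plane
#' directions, pooled into a single symmetric GLCM per voxel.
#'
#' @param n_levels number of gray levels (>= 2).
#' @param rescale_max upper end of the intermediate rescale range.
#' @param patch_size odd integer dimensions of the sliding patch.
#' @param glcm_distance offset length in voxels.
#' @param directions integer matrix of offsets (rows = offsets); `NULL` means
#'   the four in-plane directions at `glcm_distance`.
#' @param rescale_scope `"lesions"` (min/max over the union of lesion voxels;
#'   default, tumor-focused window) or `"image"` (whole volume).
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(n_levels = 32L, rescale_max = 255,
                           patch_size = c(11L, 11L, 1L), glcm_distance = 1L,
                           directions = NULL, rescale_scope = c("lesions", "image")) {
  rescale_scope <- match.arg(rescale_scope)
  patch_size <- as.integer(patch_size)
  if (length(patch_size) != 3L || any(patch_size < 1L) || any(patch_size %% 2L == 0L))
    stop("patch_size must be three odd positive integers", call. = FALSE)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2", call. = FALSE)
  if (is.null(directions)) {
    d <- as.integer(glcm_distance)
    directions <- rbind(c(d, 0L, 0L), c(0L, d, 0L), c(d, d, 0L), c(d, -d, 0L))
  }
  directions <- matrix(as.integer(directions), ncol = 3)
  structure(
    list(n_levels = n_levels, rescale_max = rescale_max,
         patch_size = patch_size, glcm_distance = as.integer(glcm_distance),
         directions = directions, rescale_scope = rescale_scope),
    class = "texture_config")
}

#' Rescale and discretize a CT volume
#'
#' Min-max affine map of the reference intensity range onto
#' `[0, rescale_max]`, then uniform binning into `n_levels` integer levels
#' (1-based). The reference range is taken over the union of lesion voxels
#' (`rescale_scope = "lesions"`, default) or the whole image. A degenerate
#' range (max == min) maps every voxel to level 1 with a warning.
#' Out-of-range intensities (possible under lesion scope) are clipped.
#'
#' @param volume a [ct_volume].
#' @param lesions a [lesion_set] (required for lesion scope).
#' @param config a [texture_config()].
#' @return list: `levels` (3D integer array, 1..n_levels), `rescaled`
#'   (3D numeric array on `[0, rescale_max]`), `range` (reference min/max).
#' @export
rescale_discretize <- function(volume, lesions = NULL,
                               config = texture_config()) {
  v <- volume$voxels
  if (config$rescale_scope == "lesions") {
    if (is.null(lesions))
      stop("lesion scope requires a lesion_set", call. = FALSE)
    u <- union_mask(lesions)
    if (!any(u)) stop("union of lesion masks is empty", call. = FALSE)
    ref <- range(v[u])
  } else {
    ref <- range(v)
  }
  if (diff(ref) <= 0) {
    warning("degenerate intensity range; all voxels mapped to level 1")
    lev <- array(1L, dim = dim(v))
    return(list(levels = lev, rescaled = array(0, dim = dim(v)), range = ref))
  }
  resc <- (v - ref[1]) / (ref[2] - ref[1])
  resc <- pmin(pmax(resc, 0), 1) * config$rescale_max
  lev <- pmin(config$n_levels,
              as.integer(floor(resc / config$rescale_max * config$n_levels)) + 1L)
  list(levels = array(lev, dim = dim(v)),
       rescaled = array(resc, dim = dim(v)), range = ref)
}

union_mask <- function(lesions) {
  u <- lesions$lesions[[1]]$mask
  if (length(lesions$lesions) > 1L)
    for (l in lesions$lesions[-1]) u <- u | l$mask
  u
}

#' Per-voxel Haralick texture maps for one lesion
#'
#' Slides the configured patch over every lesion voxel and accumulates a
#' symmetric GLCM from ordered voxel pairs at the configured offsets where
#' both endpoints lie inside the patch and inside the lesion mask (no
#' contamination from surrounding tissue), normalizes it to sum 1, and
#' computes energy = sum p^2, entropy = -sum p log2 p, homogeneity =
#' sum p / (1 + |i - j|) and contrast = sum p (i - j)^2. A patch with zero
#' valid pairs takes the degenerate convention (1, 0, 1, 0).
#'
#' @param levels discretized 3D integer array from [rescale_discretize()].
#' @param lesion a [lesion_mask].
#' @param config a [texture_config()].
#' @return object of class `texture_maps`: list of four 3D arrays (`energy`,
#'   `entropy`, `homogeneity`, `contrast`; `NA` outside the lesion), plus
#'   `lesion_id`, `region`, `config`.
#' @export
haralick_maps <- function(levels, lesion, config = texture_config()) {
  if (!any(lesion$mask)) stop("empty lesion mask", call. = FALSE)
  if (!identical(dim(levels), dim(lesion$mask)))
    stop("geometry error: levels and mask grids differ", call. = FALSE)
  h <- (config$patch_size - 1L) %/% 2L
  res <- haralick_maps_cpp(as.integer(levels), as.integer(lesion$mask),
                           as.integer(dim(levels)), h[1], h[2], h[3],
                           config$directions, config$n_levels)
  maps <- lapply(res, function(m) array(m, dim = dim(levels)))
  structure(
    list(energy = maps$energy, entropy = maps$entropy,
         homogeneity = maps$homogeneity, contrast = maps$contrast,
         lesion_id = lesion$lesion_id, region = lesion$region,
         config = config),
    class = "texture_maps")
}

#' Export texture maps as NIfTI files
#'
#' One file per statistic plus a JSON sidecar recording the configuration.
#'
#' @param maps a `texture_maps` object.
#' @param volume the parent [ct_volume] (for geometry).
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return invisibly, the written paths.
#' @export
write_texture_maps <- function(maps, volume, dir, prefix = maps$lesion_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("energy", "entropy", "homogeneity", "contrast")) {
    img <- RNifti::asNifti(maps[[nm]])
    RNifti::pixdim(img) <- volume$spacing
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  cfg <- maps$config
  cfg$directions <- apply(cfg$directions, 1, paste, collapse = ",")
  sidecar <- file.path(dir, sprintf("%s_texture_config.json", prefix))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE), sidecar)
  invisible(c(paths, sidecar))
}

#' Texture maps for every lesion of a patient
#'
#' Convenience wrapper: rescale/discretize once per patient, then compute
#' per-voxel Haralick maps for each lesion.
#'
#' @inheritParams rescale_discretize
#' @return list of `texture_maps`, one per lesion, in lesion order.
#' @export
patient_texture_maps <- function(volume, lesions, config = texture_config()) {
  disc <- rescale_discretize(volume, lesions, config)
  lapply(lesions$lesions, function(l) haralick_maps(disc$levels, l, config))
}
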