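#' @useDynLib iish, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd dist rnorm runif rbinom rexp quantile
#'   wilcox.test cor.test p.adjust kmeans var aggregate setNames complete.cases
#' @importFrom utils read.csv write.csv head
NULL

GEOM_TOL_SPACING <- 1e-4  # mm
GEOM_TOL_ORIGIN  <- 1e-3  # mm

#' Construct a calibrated CT volume
#'
#' A `ct_volume` is a 3D scalar grid (Hounsfield units, or phantom
#' intensities) with physical spacing and origin. All downstream geometry
#' checks (mask compatibility, volume computation) run against these fields.
#'
#' @param voxels 3D numeric array.
#' @param spacing length-3 positive numeric, voxel size in mm.
#' @param origin length-3 numeric, physical position of voxel (1,1,1) in mm.
#' @param patient_id scalar character identifier.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      patient_id = "anonymous") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop("voxels must be a non-empty 3D array", call. = FALSE)
  if (!all(is.finite(voxels)))
    stop("voxels must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         patient_id = as.character(patient_id)),
    class = "ct_volume")
}

#' @exportS3Method base::print
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> patient %s: %s voxels @ %s mm\n", x$patient_id,
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Construct a lesion mask
#'
#' A binary volume of interest (VOI) on the same lattice as its parent CT
#' volume, carrying the lesion identity, the radiologist-assigned anatomic
#' site label and the coarse region (pelvis or abdomen) used for
#' region-scoped heterogeneity analysis.
#'
#' @param mask 3D array, nonzero marks lesion voxels.
#' @param lesion_id scalar character.
#' @param site_label scalar character anatomic site.
#' @param region one of `"pelvis"`, `"abdomen"`.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(mask, lesion_id, site_label, region) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  m <- mask != 0
  if (!any(m))
    stop(sprintf("lesion '%s' has no foreground voxels", lesion_id),
         call. = FALSE)
  region <- as.character(region)
  if (!region %in% c("pelvis", "abdomen"))
    stop(sprintf("lesion '%s': unknown region label '%s' (must be pelvis or abdomen)",
                 lesion_id, region), call. = FALSE)
  structure(
    list(mask = m, lesion_id = as.character(lesion_id),
         site_label = as.character(site_label), region = region),
    class = "lesion_mask")
}

#' Construct a lesion set
#'
#' The per-patient collection of lesion masks together with the scanner
#' manufacturer label used by the robustness screen. Every mask must live on
#' the grid of the supplied CT volume (shape exactly; spacing within
#' 1e-4 mm, origin within 1e-3 mm when masks are loaded from files).
#'
#' @param lesions list of [lesion_mask()] objects.
#' @param patient_id scalar character.
#' @param scanner manufacturer label, e.g. `"GE"` or `"Siemens"`.
#' @param volume optional [ct_volume()] to validate geometry against.
#' @return An object of class `lesion_set`.
#' @export
lesion_set <- function(lesions, patient_id, scanner = "GE", volume = NULL) {
  if (length(lesions) < 1L)
    stop("a lesion set needs at least one lesion", call. = FALSE)
  ids <- vapply(lesions, function(l) l$lesion_id, character(1))
  if (anyDuplicated(ids))
    stop("lesion ids must be unique", call. = FALSE)
  if (!is.null(volume)) {
    for (l in lesions) {
      if (!identical(dim(l$mask), dim(volume$voxels)))
        stop(sprintf("geometry error: mask '%s' has shape %s but volume is %s",
                     l$lesion_id, paste(dim(l$mask), collapse = "x"),
                     paste(dim(volume$voxels), collapse = "x")), call. = FALSE)
    }
  }
  structure(
    list(patient_id = as.character(patient_id), lesions = lesions,
         scanner = as.character(scanner)),
    class = "lesion_set")
}

#' @exportS3Method base::print
print.lesion_set <- function(x, ...) {
  cat(sprintf("<lesion_set> patient %s: %d lesion(s) [%s], scanner %s\n",
              x$patient_id, length(x$lesions),
              paste(vapply(x$lesions, function(l) l$region, character(1)),
                    collapse = ", "),
              x$scanner))
  invisible(x)
}

nifti_geometry <- function(img) {
  pd <- RNifti::pixdim(img)[seq_len(3)]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  list(spacing = as.numeric(pd), origin = as.numeric(org))
}

read_volume_nifti <- function(path, patient_id = "anonymous") {
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img)
  arr <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
  ct_volume(arr, spacing = geo$spacing, origin = geo$origin,
            patient_id = patient_id)
}

check_mask_geometry <- function(vol, img, mask_path) {
  geo <- nifti_geometry(img)
  if (!identical(dim(img)[seq_len(3)], dim(vol$voxels)))
    stop(sprintf("geometry error: mask '%s' shape (%s) does not match volume (%s)",
                 mask_path, paste(dim(img)[seq_len(3)], collapse = "x"),
                 paste(dim(vol$voxels), collapse = "x")), call. = FALSE)
  if (max(abs(geo$spacing - vol$spacing)) > GEOM_TOL_SPACING)
    stop(sprintf("geometry error: mask '%s' spacing differs from volume beyond %g mm",
                 mask_path, GEOM_TOL_SPACING), call. = FALSE)
  if (max(abs(geo$origin - vol$origin)) > GEOM_TOL_ORIGIN)
    stop(sprintf("geometry error: mask '%s' origin differs from volume beyond %g mm",
                 mask_path, GEOM_TOL_ORIGIN), call. = FALSE)
  invisible(TRUE)
}

#' Load a patient's CT volume and lesion masks
#'
#' Reads a NIfTI volume and the per-lesion NIfTI masks declared in a lesion
#' table, validating every mask against the volume grid (shape exact,
#' spacing within 1e-4 mm, origin within 1e-3 mm) and attaching site/region
#' labels.
#'
#' @param volume_path path to the CT volume (.nii / .nii.gz).
#' @param lesion_table data frame with columns `patient_id`, `lesion_id`,
#'   `mask_path`, `site_label`, `region`; or the path of such a CSV.
#' @param patient_id patient to select from the table (default: its only
#'   patient).
#' @param scanner manufacturer label to attach.
#' @param base_dir directory against which relative `mask_path`s resolve
#'   (default: the volume's directory).
#' @return list with elements `volume` ([ct_volume]) and
#'   `lesions` ([lesion_set]).
#' @export
load_patient <- function(volume_path, lesion_table, patient_id = NULL,
                         scanner = "GE", base_dir = NULL) {
  if (is.character(lesion_table))
    lesion_table <- read_lesion_table(lesion_table)
  validate_lesion_table(lesion_table)
  if (is.null(base_dir)) base_dir <- dirname(volume_path)
  if (is.null(patient_id)) {
    pids <- unique(lesion_table$patient_id)
    if (length(pids) != 1L)
      stop("lesion table holds several patients; supply patient_id",
           call. = FALSE)
    patient_id <- pids
  }
  rows <- lesion_table[lesion_table$patient_id == patient_id, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("no lesions declared for patient '%s'", patient_id),
         call. = FALSE)
  vol <- read_volume_nifti(volume_path, patient_id = patient_id)
  lesions <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    mp <- rows$mask_path[i]
    if (!file.exists(mp)) mp <- file.path(base_dir, rows$mask_path[i])
    if (!file.exists(mp))
      stop(sprintf("mask file not found: '%s'", rows$mask_path[i]),
           call. = FALSE)
    img <- RNifti::readNifti(mp)
    check_mask_geometry(vol, img, rows$mask_path[i])
    arr <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
    lesions[[i]] <- lesion_mask(arr, rows$lesion_id[i], rows$site_label[i],
                                rows$region[i])
  }
  list(volume = vol,
       lesions = lesion_set(lesions, patient_id, scanner = scanner,
                            volume = vol))
}

read_lesion_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_lesion_table(tab)
  tab
}

validate_lesion_table <- function(tab) {
  need <- c("patient_id", "lesion_id", "mask_path", "site_label", "region")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("schema error: lesion table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- setdiff(unique(tab$region), c("pelvis", "abdomen"))
  if (length(bad))
    stop(sprintf("schema error: unknown region label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(tab)
}

#' Write a patient's volume and masks as NIfTI
#'
#' Inverse of [load_patient()]: writes the volume, one mask file per lesion,
#' and the lesion-table CSV declaring them. Voxel data round-trip bit-exactly
#' (volumes as float64, masks as uint8).
#'
#' @param volume a [ct_volume].
#' @param lesions a [lesion_set].
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the written lesion table.
#' @export
write_patient <- function(volume, lesions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aff <- diag(4)
  aff[1, 1] <- -volume$spacing[1]  # RAS convention: x/y flipped vs voxel axes
  aff[2, 2] <- -volume$spacing[2]
  aff[3, 3] <- volume$spacing[3]
  aff[1:3, 4] <- volume$origin
  put <- function(arr, path, datatype) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- volume$spacing
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path, datatype = datatype)
  }
  vol_path <- file.path(dir, sprintf("%s_ct.nii.gz", volume$patient_id))
  put(volume$voxels, vol_path, "double")
  rows <- lapply(lesions$lesions, function(l) {
    mp <- sprintf("%s_mask_%s.nii.gz", volume$patient_id, l$lesion_id)
    put(l$mask + 0, file.path(dir, mp), "uint8")
    data.frame(patient_id = volume$patient_id, lesion_id = l$lesion_id,
               mask_path = mp, site_label = l$site_label, region = l$region,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab_path <- file.path(dir, sprintf("%s_lesions.csv", volume$patient_id))
  write.csv(tab, tab_path, row.names = FALSE)
  invisible(list(volume = vol_path, table = tab_path))
}

#' Split an integer labelmap into individual lesion masks
#'
#' Convenience importer for segmentations stored as a single labelmap: each
#' distinct positive label becomes one lesion mask. Site/region metadata is
#' supplied through a small lookup table since a labelmap cannot carry it.
#'
#' @param labelmap 3D integer array; 0 = background.
#' @param label_info data frame with columns `label`, `lesion_id`,
#'   `site_label`, `region`.
#' @param patient_id scalar character.
#' @param scanner manufacturer label.
#' @return A [lesion_set].
#' @export
labelmap_to_lesions <- function(labelmap, label_info, patient_id,
                                scanner = "GE") {
  labs <- sort(unique(labelmap[labelmap > 0]))
  lesions <- lapply(labs, function(lb) {
    row <- label_info[label_info$label == lb, , drop = FALSE]
    if (nrow(row) != 1L)
      stop(sprintf("schema error: label %d not described in label_info", lb),
           call. = FALSE)
    lesion_mask(labelmap == lb, row$lesion_id, row$site_label, row$region)
  })
  lesion_set(lesions, patient_id, scanner = scanner)
}

#' Load and validate the clinical table
#'
#' Reads the per-patient clinical/genomic CSV. Rows with
#' `platinum_status == "unknown"` are retained but flagged via the
#' `platinum_known` column; resistance classification must subset to
#' `platinum_known`. Validation is strict: missing mandatory columns,
#' non-numeric age/cnb, out-of-range cnb and negative follow-up all raise
#' typed errors.
#'
#' @param path CSV path with columns `patient_id`, `age`, `stage`,
#'   `resection`, `cnb`, `platinum_status`, `pfs_months`, `pfs_event`,
#'   `scanner`.
#' @return data frame of validated clinical records with an added logical
#'   `platinum_known` column.
#' @export
load_clinical_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("schema error: unreadable clinical CSV",
                                           call. = FALSE))
  if (nrow(tab) == 0L || ncol(tab) <= 1L)
    stop("schema error: clinical table is empty", call. = FALSE)
  validate_clinical_table(tab)
}

validate_clinical_table <- function(tab) {
  need <- c("patient_id", "age", "stage", "resection", "cnb",
            "platinum_status", "pfs_months", "pfs_event", "scanner")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("schema error: clinical table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (col in c("age", "cnb", "pfs_months")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (any(is.na(v)))
      stop(sprintf("parse error: non-numeric value in column '%s'", col),
           call. = FALSE)
    tab[[col]] <- v
  }
  if (any(tab$cnb < 0 | tab$cnb > 1))
    stop("validation error: cnb (fraction genome altered) must lie in [0,1]",
         call. = FALSE)
  if (any(tab$pfs_months < 0))
    stop("validation error: pfs_months must be non-negative", call. = FALSE)
  if (!all(tab$stage %in% c("III", "IV")))
    stop("schema error: stage must be III or IV", call. = FALSE)
  if (!all(tab$resection %in% c("complete", "optimal", "suboptimal")))
    stop("schema error: resection must be complete/optimal/suboptimal",
         call. = FALSE)
  if (!all(tab$platinum_status %in% c("sensitive", "resistant", "unknown")))
    stop("schema error: platinum_status must be sensitive/resistant/unknown",
         call. = FALSE)
  tab$pfs_event <- as.logical(tab$pfs_event)
  if (any(is.na(tab$pfs_event)))
    stop("parse error: pfs_event must be logical (TRUE/FALSE or 0/1)",
         call. = FALSE)
  tab$platinum_known <- tab$platinum_status != "unknown"
  tab
}

#' Ordinal encoding of cytoreduction outcome
#'
#' complete = 0, optimal = 1, suboptimal = 2; used when resection enters the
#' linear risk scores.
#'
#' @param resection character vector of resection outcomes.
#' @return integer vector.
#' @export
encode_resection <- function(resection) {
  codes <- c(complete = 0L, optimal = 1L, suboptimal = 2L)
  out <- codes[resection]
  if (any(is.na(out)))
    stop("schema error: resection must be complete/optimal/suboptimal",
         call. = FALSE)
  unname(out)
}

#' Numeric encoding of FIGO stage (III = 0, IV = 1)
#' @param stage character vector.
#' @return integer vector.
#' @export
encode_stage <- function(stage) {
  codes <- c(III = 0L, IV = 1L)
  out <- codes[stage]
  if (any(is.na(out)))
    stop("schema error: stage must be III or IV", call. = FALSE)
  unname(out)
}
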