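#' A synthetic texture class
#'
#' Lesion texture is emulated as a stationary Gaussian random field: white
#' noise smoothed with an isotropic Gaussian kernel of the class
#' correlation length, renormalized and mapped to the class mean/SD.
#' Classes that differ in correlation length and noise SD separate cleanly
#' in Haralick descriptor space, which is what the clustering-recovery and
#' heterogeneity-monotonicity checks need; no anatomical realism is
#' attempted.
#'
#' @param mean mean intensity (phantom HU).
#' @param sd noise standard deviation (>= 0).
#' @param corr_len spatial correlation length in voxels (0 = white noise).
#' @param id class identifier.
#' @return object of class `texture_class`.
#' @export
texture_class <- function(mean, sd, corr_len = 0, id = NA_character_) {
  if (sd < 0 || corr_len < 0)
    stop("sd and corr_len must be >= 0", call. = FALSE)
  structure(list(mean = mean, sd = sd, corr_len = corr_len,
                 id = as.character(id)),
            class = "texture_class")
}

#' Default texture class palette
#'
#' Eight classes spanning noise amplitude and correlation length, ordered
#' so that consecutive classes are texturally distinct. Intensity means are
#' held in a narrow band so the patient-level rescaling window stays
#' comparable across patients.
#'
#' @return list of eight [texture_class()] objects.
#' @export
default_texture_classes <- function() {
  specs <- list(
    c(70, 22, 0), c(65, 22, 2.5), c(75, 7, 0), c(60, 7, 2.5),
    c(80, 22, 1.2), c(55, 12, 0.6), c(85, 12, 3.5), c(50, 17, 1.8))
  lapply(seq_along(specs), function(i)
    texture_class(specs[[i]][1], specs[[i]][2], specs[[i]][3],
                  id = paste0("class", i)))
}

#' Paired texture palette (coarse/fine lesion lobes)
#'
#' Eight class pairs designed for reliable subregion extraction and a
#' stable dissimilarity spectrum: within a pair the "coarse" member has
#' higher amplitude and shorter correlation length than its "fine"
#' partner (well separated in z-scored descriptor space, so the two lobes
#' of a lesion are recovered as distinct subregions), while amplitudes are
#' graded across pairs so different lesions are texturally distinct. All
#' classes are spatially smooth, which keeps the heavy-tailed GLCM
#' contrast channel small and makes descriptor dissimilarities -- hence
#' the cluDiss level structure -- reproducible across field realizations.
#' The grade sequence puts the widest-amplitude pair first so the
#' patient-level rescale window of gradient cohorts is anchored by the
#' first lesion.
#'
#' @return list of 16 [texture_class()] objects; elements 2p-1 and 2p form
#'   pair p.
#' @export
paired_texture_classes <- function() {
  p_seq <- c(8L, 1L, 5L, 3L, 7L, 2L, 6L, 4L)
  out <- list()
  for (j in 1:8) {
    p <- p_seq[j]
    s <- 8 + 3 * p
    out[[2 * j - 1]] <- texture_class(mean = 50 + 3 * p, sd = s,
                                      corr_len = 0.8,
                                      id = paste0("coarse", p))
    out[[2 * j]] <- texture_class(mean = 48 + 3 * p, sd = s * 0.55,
                                  corr_len = 2.0,
                                  id = paste0("fine", p))
  }
  out
}

# isotropic separable Gaussian smoothing of a 3D array (in voxel units)
gauss_smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm1 <- function(a, dim_idx) {
    ap <- aperm(a, c(dim_idx, setdiff(1:3, dim_idx)))
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    n <- d[1]
    # reflect-pad then convolve each column
    idx <- c(pmin(n, pmax(1, (1 - r):0)), 1:n, pmin(n, pmax(1, (n + 1):(n + r))))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    res <- array(out, dim = d)
    aperm(res, order(c(dim_idx, setdiff(1:3, dim_idx))))
  }
  arr <- sm1(arr, 1); arr <- sm1(arr, 2); arr <- sm1(arr, 3)
  arr
}

# realize a texture class over the whole grid
realize_class_field <- function(dims, cls) {
  w <- array(rnorm(prod(dims)), dim = dims)
  f <- gauss_smooth3d(w, cls$corr_len)
  s <- sd(f)
  if (s < 1e-12) f <- array(0, dim = dims) else f <- (f - mean(f)) / s
  cls$mean + cls$sd * f
}

ellipsoid_mask <- function(dims, center, radii) {
  x <- seq_len(dims[1]); y <- seq_len(dims[2]); z <- seq_len(dims[3])
  dx2 <- ((x - center[1]) / radii[1])^2
  dy2 <- ((y - center[2]) / radii[2])^2
  dz2 <- ((z - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Specify one phantom lesion
#'
#' @param center ellipsoid center (voxel coordinates).
#' @param radii ellipsoid semi-axes (voxels).
#' @param site_label anatomic site label.
#' @param region `"pelvis"` or `"abdomen"`.
#' @param classes one [texture_class()] (homogeneous lesion) or a list of
#'   several (the lesion is split into that many sub-lobes along z, each
#'   filled from its own class).
#' @return object of class `phantom_lesion_spec`.
#' @export
phantom_lesion <- function(center, radii, site_label, region, classes) {
  if (inherits(classes, "texture_class")) classes <- list(classes)
  structure(list(center = center, radii = radii, site_label = site_label,
                 region = region, classes = classes),
            class = "phantom_lesion_spec")
}

#' Specify a phantom patient
#'
#' @param lesions list of [phantom_lesion()] specs.
#' @param dims grid shape (default 96 x 96 x 32).
#' @param spacing voxel size in mm (default 1 x 1 x 3).
#' @param background_mean,background_sd background intensity model.
#' @param patient_id identifier.
#' @param seed mandatory integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(lesions, dims = c(96L, 96L, 32L),
                         spacing = c(1, 1, 3), background_mean = 20,
                         background_sd = 4, patient_id = "phantom",
                         seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  for (l in lesions) {
    lo <- l$center - l$radii; hi <- l$center + l$radii
    if (any(lo < 1) || any(hi > dims))
      stop(sprintf("lesion at (%s) exceeds the grid",
                   paste(l$center, collapse = ",")), call. = FALSE)
  }
  structure(list(lesions = lesions, dims = as.integer(dims),
                 spacing = spacing, background_mean = background_mean,
                 background_sd = background_sd,
                 patient_id = patient_id, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one synthetic multi-lesion patient
#'
#' Deterministic given the spec seed. Each lesion is an ellipsoid filled
#' with its Gaussian-random-field texture class(es); multi-class lesions
#' are split into equal-width sub-lobes along z. Overlapping lesions are an
#' error. Ground-truth voxel class labels are returned for
#' clustering-recovery tests.
#'
#' @param spec a [phantom_spec()].
#' @param scanner scanner label to attach to the lesion set.
#' @return list with `volume` ([ct_volume]), `lesions` ([lesion_set]) and
#'   `truth` (integer array of ground-truth class codes; 0 = background).
#' @export
make_patient <- function(spec, scanner = "GE") {
  with_seed_local(spec$seed, {
    dims <- spec$dims
    vox <- spec$background_mean +
      spec$background_sd * array(rnorm(prod(dims)), dim = dims)
    truth <- array(0L, dim = dims)
    occupied <- array(FALSE, dim = dims)
    masks <- list()
    class_ids <- unique(unlist(lapply(spec$lesions, function(l)
      vapply(l$classes, function(c0) c0$id, character(1)))))
    # realize each distinct class field once per patient
    fields <- list()
    for (l in spec$lesions) for (c0 in l$classes)
      if (is.null(fields[[c0$id]]))
        fields[[c0$id]] <- realize_class_field(dims, c0)
    for (li in seq_along(spec$lesions)) {
      l <- spec$lesions[[li]]
      m <- ellipsoid_mask(dims, l$center, l$radii)
      if (any(m & occupied))
        stop("overlapping lesions; respecify centers/radii", call. = FALSE)
      occupied <- occupied | m
      nc <- length(l$classes)
      # sub-lobes: equal-width z slabs across the lesion extent (the texture
      # patch is in-plane, so slice boundaries produce no mixed patches)
      zs <- arrayInd(which(m), dims)[, 3]
      brk <- seq(min(zs), max(zs) + 1, length.out = nc + 1)
      lobe <- findInterval(zs, brk, rightmost.closed = TRUE)
      lobe[lobe > nc] <- nc
      lobe[lobe < 1L] <- 1L
      mi <- which(m)
      for (ci in seq_len(nc)) {
        sel <- mi[lobe == ci]
        cls <- l$classes[[ci]]
        vox[sel] <- fields[[cls$id]][sel]
        truth[sel] <- match(cls$id, class_ids)
      }
      masks[[li]] <- lesion_mask(m, sprintf("L%02d", li), l$site_label,
                                 l$region)
    }
    list(volume = ct_volume(vox, spacing = spec$spacing,
                            patient_id = spec$patient_id),
         lesions = lesion_set(masks, spec$patient_id, scanner = scanner),
         truth = truth)
  })
}

#' Specify a phantom cohort
#'
#' The cohort emulates a multi-lesion CT study population with controllable
#' heterogeneity and outcome structure: each patient receives a number of
#' lesions in `lesion_range`, drawing from `n_classes_range` distinct
#' texture classes (the ground-truth heterogeneity knob); platinum
#' resistance follows a logistic link on the z-scored class count and the
#' PFS hazard a log-linear link, with exponential event times and uniform
#' administrative censoring tuned to `censor_rate`.
#'
#' @param n_patients cohort size.
#' @param lesion_range min/max lesions per patient.
#' @param n_classes_range min/max distinct texture classes per patient
#'   (capped at the lesion count and the palette size).
#' @param resist_intercept,resist_slope logistic link of resistance on
#'   z-scored heterogeneity (defaults give ~23% prevalence at zero slope,
#'   matching a 14/61 imbalance).
#' @param hazard_base,hazard_slope exponential PFS hazard
#'   `hazard_base * exp(hazard_slope * z(heterogeneity))` per month.
#' @param censor_rate target censoring fraction.
#' @param dims,spacing grid geometry.
#' @param radii_range list of three min/max pairs for the ellipsoid
#'   semi-axes in voxels (defaults give lesions of roughly 0.4-1.4 cc,
#'   small peritoneal-implant scale, keeping a full-cohort analysis fast).
#' @param classes texture palette (default [default_texture_classes()];
#'   with `paired_lobes = TRUE` a paired palette such as
#'   [paired_texture_classes()], whose consecutive elements form pairs).
#' @param paired_lobes if `TRUE`, every lesion is built from one class
#'   PAIR (two z-lobes, coarse/fine), and the heterogeneity knob counts
#'   distinct pairs; the within-lesion contrast makes subregion extraction
#'   reliable, so computed cluDiss tracks the knob.
#' @param lesion_counts optional integer vector; patient i receives
#'   `lesion_counts[(i - 1) %% length + 1]` lesions (deterministic
#'   balanced design, e.g. `2:8` for a heterogeneity-gradient cohort),
#'   with one distinct class/pair per lesion. Overrides `lesion_range` and
#'   `n_classes_range`.
#' @param lobed_levels optional integer vector (requires `paired_lobes`);
#'   each patient draws a ground-truth heterogeneity level h from it and
#'   its first h lesions become two-lobe (coarse + fine) while the rest
#'   stay homogeneous (coarse only); pairs are distinct per lesion. Use
#'   e.g. `c(0L, n)` for a homogeneous-vs-heterogeneous two-arm cohort in
#'   which conventional measures (lesion count, sites, volume) carry no
#'   outcome signal; the outcome links then act on h.
#' @param nonge_fraction fraction of patients labeled with a non-GE
#'   scanner (metadata only).
#' @param seed mandatory cohort seed; per-patient seeds are derived as
#'   `seed * 10000 + patient index`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 30L, lesion_range = c(2L, 5L),
                        n_classes_range = c(1L, 4L),
                        resist_intercept = -1.2, resist_slope = 0,
                        hazard_base = 1 / 18, hazard_slope = 0,
                        censor_rate = 0.3, dims = c(96L, 96L, 32L),
                        spacing = c(1, 1, 3),
                        radii_range = list(c(4, 6), c(4, 6), c(2, 3)),
                        classes = default_texture_classes(),
                        paired_lobes = FALSE, lesion_counts = NULL,
                        lobed_levels = NULL, nonge_fraction = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (hazard_base <= 0) stop("hazard must be positive", call. = FALSE)
  if (paired_lobes && length(classes) %% 2L != 0L)
    stop("paired_lobes requires an even-length paired palette", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 lesion_range = as.integer(lesion_range),
                 n_classes_range = as.integer(n_classes_range),
                 resist_intercept = resist_intercept,
                 resist_slope = resist_slope, hazard_base = hazard_base,
                 hazard_slope = hazard_slope, censor_rate = censor_rate,
                 dims = as.integer(dims), spacing = spacing,
                 radii_range = radii_range,
                 classes = classes, paired_lobes = paired_lobes,
                 lesion_counts = if (is.null(lesion_counts)) NULL
                                 else as.integer(lesion_counts),
                 lobed_levels = if (is.null(lobed_levels)) NULL
                                else as.integer(lobed_levels),
                 nonge_fraction = nonge_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Heterogeneity-gradient cohort specification
#'
#' The load-bearing fixture for heterogeneity-response checks: patients
#' differ only in their number of texturally distinct lesions (cycling
#' through `lesion_counts`); every lesion is a two-lobe (coarse/fine)
#' phantom drawn from its own class pair, so the ground-truth distinct
#' texture count equals the lesion count and the computed cluDiss should
#' increase with it.
#'
#' @param n_patients cohort size (default 40).
#' @param lesion_counts lesion-count gradient (default `2:8`).
#' @param seed mandatory cohort seed.
#' @param ... further arguments passed to [cohort_spec()].
#' @return object of class `cohort_spec`.
#' @export
heterogeneity_cohort_spec <- function(n_patients = 40L, lesion_counts = 2:8,
                                      seed, ...) {
  cohort_spec(n_patients = n_patients, lesion_counts = lesion_counts,
              classes = paired_texture_classes(), paired_lobes = TRUE,
              radii_range = list(c(8, 8), c(8, 8), c(3, 3)),
              seed = seed, ...)
}

# sample one integer uniformly from lo..hi (safe when lo == hi)
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# non-overlapping lesion placement on a jittered lattice
place_lesions <- function(n, dims, radii_range = list(c(4, 6), c(4, 6), c(2, 3))) {
  margin <- c(radii_range[[1]][2], radii_range[[2]][2],
              radii_range[[3]][2]) + 1
  # lattice of candidate centers with enough clearance
  step <- 2 * margin[1:2] + 1
  cx <- seq(margin[1] + 1, dims[1] - margin[1], by = step[1])
  cy <- seq(margin[2] + 1, dims[2] - margin[2], by = step[2])
  cz <- seq(margin[3] + 1, dims[3] - margin[3],
            by = 2 * margin[3] + 1)
  grid <- expand.grid(x = cx, y = cy, z = cz)
  if (nrow(grid) < n)
    stop("infeasible lesion packing: enlarge the grid or reduce lesion count/radii",
         call. = FALSE)
  pick <- grid[sample.int(nrow(grid), n), , drop = FALSE]
  lapply(seq_len(n), function(i) {
    radii <- c(runif(1, radii_range[[1]][1], radii_range[[1]][2]),
               runif(1, radii_range[[2]][1], radii_range[[2]][2]),
               runif(1, radii_range[[3]][1], radii_range[[3]][2]))
    list(center = as.numeric(pick[i, ]), radii = radii)
  })
}

#' Generate a phantom cohort
#'
#' Returns in-memory patients plus the clinical table and ground-truth
#' table; optionally writes everything to disk in the exact layout the
#' imaging I/O layer expects (per-patient NIfTI volume + mask files, a
#' lesion-table CSV and a cohort-level clinical CSV).
#'
#' @param spec a [cohort_spec()].
#' @param dir `NULL` for in-memory only, or an output directory.
#' @return list with `patients` (list of [make_patient()] results),
#'   `clinical` (validated clinical data frame) and `truth` (per-patient
#'   ground-truth: lesion count, distinct class count, site count).
#' @export
make_cohort <- function(spec, dir = NULL) {
  site_pool <- c("ovary", "omentum", "peritoneum", "liver_surface",
                 "diaphragm", "bowel_serosa", "pelvic_sidewall", "spleen")
  site_region <- c("pelvis", "abdomen", "abdomen", "abdomen", "abdomen",
                   "abdomen", "pelvis", "abdomen")
  patients <- vector("list", spec$n_patients)
  clin <- truth <- list()
  for (i in seq_len(spec$n_patients)) {
    pseed <- as.integer((as.numeric(spec$seed) * 10000 + i) %% 2147483647)
    pw <- with_seed_local(pseed, {
      n_units <- if (spec$paired_lobes) length(spec$classes) %/% 2L
                 else length(spec$classes)
      n_lobed <- NA_integer_
      if (!is.null(spec$lobed_levels)) {
        # heterogeneity level = number of two-lobe lesions; distinct pairs
        n_les <- sample_range(spec$lesion_range[1], spec$lesion_range[2])
        n_lobed <- spec$lobed_levels[sample.int(length(spec$lobed_levels), 1)]
        n_lobed <- min(n_lobed, n_les)
        n_cls <- n_les + n_lobed
        assign_cls <- ((seq_len(n_les) - 1L) %% n_units) + 1L
      } else if (!is.null(spec$lesion_counts)) {
        # deterministic gradient: one distinct class/pair per lesion
        n_les <- spec$lesion_counts[(i - 1L) %% length(spec$lesion_counts) + 1L]
        n_cls <- min(n_les, n_units)
        assign_cls <- ((seq_len(n_les) - 1L) %% n_units) + 1L
      } else {
        n_les <- sample_range(spec$lesion_range[1], spec$lesion_range[2])
        ncl_max <- min(spec$n_classes_range[2], n_les, n_units)
        ncl_min <- min(spec$n_classes_range[1], ncl_max)
        n_cls <- sample_range(ncl_min, ncl_max)
        cls_pick <- sample.int(n_units)[seq_len(n_cls)]
        # every lesion draws one unit; all picked units used at least once
        extra <- cls_pick[sample.int(n_cls, max(0, n_les - n_cls),
                                     replace = TRUE)]
        assign_cls <- c(cls_pick, extra)[seq_len(n_les)]
      }
      geom <- place_lesions(n_les, spec$dims, spec$radii_range)
      site_idx <- sample(seq_along(site_pool), n_les, replace = n_les > length(site_pool))
      lesions <- lapply(seq_len(n_les), function(li) {
        cl <- if (spec$paired_lobes)
          spec$classes[(2L * assign_cls[li] - 1L):(2L * assign_cls[li])]
        else spec$classes[[assign_cls[li]]]
        if (!is.na(n_lobed) && li > n_lobed) cl <- cl[1]  # homogeneous lesion
        phantom_lesion(geom[[li]]$center, geom[[li]]$radii,
                       site_pool[site_idx[li]], site_region[site_idx[li]], cl)
      })
      list(lesions = lesions, n_les = n_les, n_cls = n_cls,
           n_lobed = n_lobed, sites = site_pool[site_idx])
    })
    ps <- phantom_spec(pw$lesions, dims = spec$dims, spacing = spec$spacing,
                       patient_id = sprintf("P%03d", i), seed = pseed + 1L)
    scanner <- with_seed_local(pseed + 2L,
      if (runif(1) < spec$nonge_fraction) "Siemens" else "GE")
    patients[[i]] <- make_patient(ps, scanner = scanner)
    truth[[i]] <- data.frame(patient_id = sprintf("P%03d", i),
                             n_lesions = pw$n_les, n_classes = pw$n_cls,
                             n_lobed = pw$n_lobed,
                             n_sites = length(unique(pw$sites)))
  }
  # outcome model on z-scored ground-truth heterogeneity
  tr <- do.call(rbind, truth)
  h <- if (all(!is.na(tr$n_lobed))) tr$n_lobed else tr$n_classes
  z <- if (sd(h) > 0) (h - mean(h)) / sd(h) else rep(0, length(h))
  clin <- with_seed_local(spec$seed + 777L, {
    p_res <- stats::plogis(spec$resist_intercept + spec$resist_slope * z)
    res <- rbinom(length(z), 1, p_res)
    lam <- spec$hazard_base * exp(spec$hazard_slope * z)
    t_event <- rexp(length(z), rate = lam)
    # exponential censoring with rate lam_c = lam0 * q/(1-q) gives a
    # censoring fraction of exactly q under the base hazard
    q <- spec$censor_rate
    t_cens <- if (q <= 0) rep(Inf, length(z)) else
      rexp(length(z), rate = spec$hazard_base * q / (1 - q))
    pfs <- pmin(t_event, t_cens)
    ev <- t_event <= t_cens
    data.frame(
      patient_id = tr$patient_id,
      age = round(rnorm(length(z), 60, 10)),
      stage = sample(c("III", "IV"), length(z), replace = TRUE,
                     prob = c(0.75, 0.25)),
      resection = sample(c("complete", "optimal", "suboptimal"), length(z),
                         replace = TRUE, prob = c(0.45, 0.35, 0.2)),
      cnb = pmin(1, pmax(0, stats::rbeta(length(z), 5, 4))),
      platinum_status = ifelse(res == 1, "resistant", "sensitive"),
      pfs_months = round(pfs, 2), pfs_event = ev,
      scanner = vapply(patients, function(p) p$lesions$scanner,
                       character(1)),
      stringsAsFactors = FALSE)
  })
  clin <- validate_clinical_table(clin)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in patients) write_patient(p$volume, p$lesions, dir)
    write.csv(clin[setdiff(names(clin), "platinum_known")],
              file.path(dir, "clinical.csv"), row.names = FALSE)
    write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(patients = patients, clinical = clin, truth = tr)
}
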