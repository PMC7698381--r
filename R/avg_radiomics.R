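# 13 unique 3D 26-neighborhood directions (first nonzero component positive)
offsets_3d_26 <- function() {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    v <- c(dx, dy, dz)
    if (all(v == 0)) next
    nz <- v[v != 0][1]
    if (nz > 0) out <- rbind(out, v)
  }
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Average-radiomics discretization configuration
#'
#' @param n_levels gray levels for the matrix families (default 32, on the
#'   0-255 rescaled range, matching the per-voxel texture-map scheme).
#' @param rescale_scope `"lesions"` or `"image"` (see [texture_config()]).
#' @param aggregation `"pooled_voxels"` (default; one matrix per patient
#'   over the union of VOIs, burden-sensitive) or `"volume_weighted"`
#'   (per-lesion features averaged with voxel-count weights).
#' @return object of class `radiomics_config`.
#' @export
radiomics_config <- function(n_levels = 32L,
                             rescale_scope = c("lesions", "image"),
                             aggregation = c("pooled_voxels", "volume_weighted")) {
  structure(list(n_levels = as.integer(n_levels),
                 rescale_scope = match.arg(rescale_scope),
                 aggregation = match.arg(aggregation)),
            class = "radiomics_config")
}

#' The frozen 75-feature manifest
#'
#' Deterministic ordered list of the 75 average-heterogeneity features with
#' family tags: first-order (4), GLCM (5), GLRLM (13), GLSZM (13; includes
#' GLN and SZN), NGTDM (5; includes coarseness), NGLDM (15; includes DCN),
#' Sobel statistics (4) and Gabor statistics at orientations 0/45/90/135
#' degrees, wavelength 2 px, bandwidth sqrt(2) (16 = 4 stats x 4
#' orientations). All downstream tables use this ordering.
#'
#' @return data frame with columns `name` and `family` (75 rows).
#' @export
feature_manifest <- function() {
  fo <- paste0("FirstOrder.", c("mean", "sd", "skewness", "kurtosis"))
  glcm <- paste0("GLCM.", c("energy", "entropy", "homogeneity", "contrast",
                            "correlation"))
  glrlm <- paste0("GLRLM.", c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE",
                              "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
                              "GLV", "RLV"))
  glszm <- paste0("GLSZM.", c("SAE", "LAE", "GLN", "SZN", "ZP", "LGZE",
                              "HGZE", "SALGE", "SAHGE", "LALGE", "LAHGE",
                              "GLV", "ZV"))
  ngtdm <- paste0("NGTDM.", c("coarseness", "contrast", "busyness",
                              "complexity", "strength"))
  ngldm <- paste0("NGLDM.", c("SDE", "LDE", "LGLE", "HGLE", "SDLGLE",
                              "SDHGLE", "LDLGLE", "LDHGLE", "GLN", "GLNN",
                              "DCN", "DCNN", "GLV", "DCV", "DCE"))
  sobel <- paste0("Sobel.", c("mean", "sd", "skewness", "kurtosis"))
  gabor <- as.vector(t(outer(paste0("Gabor", c(0, 45, 90, 135)),
                             c(".mean", ".sd", ".skewness", ".kurtosis"),
                             paste0)))
  data.frame(
    name = c(fo, glcm, glrlm, glszm, ngtdm, ngldm, sobel, gabor),
    family = rep(c("firstorder", "GLCM", "GLRLM", "GLSZM", "NGTDM", "NGLDM",
                   "Sobel", "Gabor"),
                 times = c(4, 5, 13, 13, 5, 15, 4, 16)),
    stringsAsFactors = FALSE)
}

moment_stats <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0)
    return(c(mean = m, sd = 0, skewness = 0, kurtosis = 0))
  c(mean = m, sd = sqrt(m2),
    skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2)
}

glcm_features <- function(counts) {
  tot <- sum(counts)
  nl <- nrow(counts)
  if (tot <= 0)
    return(c(energy = 1, entropy = 0, homogeneity = 1, contrast = 0,
             correlation = 1))
  P <- counts / tot
  i <- row(P); j <- col(P)
  pi_m <- rowSums(P)
  mu <- sum(seq_len(nl) * pi_m)
  s2 <- sum((seq_len(nl) - mu)^2 * pi_m)
  pos <- P > 0
  c(energy = sum(P^2),
    entropy = -sum(P[pos] * log2(P[pos])),
    homogeneity = sum(P / (1 + abs(i - j))),
    contrast = sum(P * (i - j)^2),
    correlation = if (s2 <= 0) 1 else (sum(i * j * P) - mu^2) / s2)
}

# generic features of a (gray level x size) accumulation matrix;
# prefix selects the naming family; n_norm is the run-percentage style
# denominator (NA = skip that feature)
gl_size_features <- function(mat, names13, n_norm = NA) {
  ns <- sum(mat)
  g <- row(mat); l <- col(mat)
  p <- mat / ns
  mg <- rowSums(mat); ml <- colSums(mat)
  mug <- sum(seq_len(nrow(mat)) * rowSums(p))
  mul <- sum(seq_len(ncol(mat)) * colSums(p))
  vals <- c(
    sum(mat / l^2) / ns,            # small emphasis
    sum(mat * l^2) / ns,            # large emphasis
    sum(mg^2) / ns,                 # gray level non-uniformity
    sum(ml^2) / ns,                 # size/run non-uniformity
    if (is.na(n_norm)) NA else ns / n_norm,  # percentage
    sum(mat / g^2) / ns,            # low gray level
    sum(mat * g^2) / ns,            # high gray level
    sum(mat / (g^2 * l^2)) / ns,
    sum(mat * g^2 / l^2) / ns,
    sum(mat * l^2 / g^2) / ns,
    sum(mat * g^2 * l^2) / ns,
    sum(p * (g - mug)^2),           # gray level variance
    sum(p * (l - mul)^2))           # size variance
  names(vals) <- names13
  vals
}

ngtdm_features <- function(acc, nlevels) {
  n_i <- acc[, 1]
  s_i <- acc[, 2]
  nv <- sum(n_i)
  if (nv <= 0) {
    out <- c(1e6, 0, 0, 0, 0)
    names(out) <- c("coarseness", "contrast", "busyness", "complexity",
                    "strength")
    return(out)
  }
  p_i <- n_i / nv
  lv <- seq_len(nlevels)
  act <- which(p_i > 0)
  ngp <- length(act)
  den_co <- sum(p_i * s_i)
  coarseness <- if (den_co > 0) 1 / den_co else 1e6
  contrast <- 0
  if (ngp > 1) {
    ii <- outer(lv[act], lv[act], "-")^2
    pp <- outer(p_i[act], p_i[act])
    contrast <- sum(pp * ii) / (ngp * (ngp - 1)) * sum(s_i) / nv
  }
  den_bus <- sum(abs(outer(lv[act] * p_i[act], lv[act] * p_i[act], "-")))
  busyness <- if (den_bus > 0) sum(p_i * s_i) / den_bus else 0
  # complexity and strength over active level pairs
  complexity <- 0; strength <- 0
  if (ngp > 0) {
    for (a in act) for (b in act) {
      complexity <- complexity +
        abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
      strength <- strength + (p_i[a] + p_i[b]) * (a - b)^2
    }
    complexity <- complexity / nv
    strength <- if (sum(s_i) > 0) strength / sum(s_i) else 0
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

ngldm_features <- function(s_mat) {
  ns <- sum(s_mat)
  g <- row(s_mat); j <- col(s_mat)
  p <- s_mat / ns
  sg <- rowSums(s_mat); sj <- colSums(s_mat)
  mug <- sum(seq_len(nrow(s_mat)) * rowSums(p))
  muj <- sum(seq_len(ncol(s_mat)) * colSums(p))
  pos <- p > 0
  c(SDE = sum(s_mat / j^2) / ns,
    LDE = sum(s_mat * j^2) / ns,
    LGLE = sum(s_mat / g^2) / ns,
    HGLE = sum(s_mat * g^2) / ns,
    SDLGLE = sum(s_mat / (g^2 * j^2)) / ns,
    SDHGLE = sum(s_mat * g^2 / j^2) / ns,
    LDLGLE = sum(s_mat * j^2 / g^2) / ns,
    LDHGLE = sum(s_mat * g^2 * j^2) / ns,
    GLN = sum(sg^2) / ns,
    GLNN = sum(sg^2) / ns^2,
    DCN = sum(sj^2) / ns,
    DCNN = sum(sj^2) / ns^2,
    GLV = sum(p * (g - mug)^2),
    DCV = sum(p * (j - muj)^2),
    DCE = -sum(p[pos] * log2(p[pos])))
}

# Gabor kernel pair (even/odd) for orientation theta (degrees), wavelength
# lambda (px) and half-response spatial-frequency bandwidth b (octaves).
gabor_kernels <- function(theta_deg, lambda = 2, bandwidth = sqrt(2),
                          gamma = 1) {
  sigma <- lambda / pi * sqrt(log(2) / 2) * (2^bandwidth + 1) / (2^bandwidth - 1)
  r <- max(3L, ceiling(3.5 * sigma))
  xs <- -r:r
  th <- theta_deg * pi / 180
  xp <- outer(xs, xs, function(x, y) x * cos(th) + y * sin(th))
  yp <- outer(xs, xs, function(x, y) -x * sin(th) + y * cos(th))
  env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
  list(even = env * cos(2 * pi * xp / lambda),
       odd = env * sin(2 * pi * xp / lambda))
}

sobel_kernels <- function() {
  gx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  list(gx = gx, gy = t(gx))
}

filter_magnitude <- function(vol, k1, k2) {
  dims <- dim(vol)
  r1 <- conv2d_stack_cpp(as.numeric(vol), as.integer(dims), k1)
  r2 <- conv2d_stack_cpp(as.numeric(vol), as.integer(dims), k2)
  array(sqrt(r1^2 + r2^2), dim = dims)
}

# core: all 75 features for one binary mask on a discretized/rescaled volume
features_for_mask <- function(levels, rescaled, mask, nlevels) {
  dims <- dim(levels)
  mi <- as.integer(mask)
  di <- as.integer(levels)
  man <- feature_manifest()
  out <- setNames(numeric(nrow(man)), man$name)

  fo <- moment_stats(rescaled[mask])
  out[paste0("FirstOrder.", names(fo))] <- fo

  offs <- offsets_3d_26()
  out[paste0("GLCM.", c("energy", "entropy", "homogeneity", "contrast",
                        "correlation"))] <-
    glcm_features(glcm_counts_cpp(di, mi, dims, offs, nlevels))

  rlm <- glrlm_counts_cpp(di, mi, dims, offs, nlevels)
  rlm <- rlm[, seq_len(max(1L, max(which(colSums(rlm) > 0)))), drop = FALSE]
  out[paste0("GLRLM.", c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                         "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV"))] <-
    gl_size_features(rlm,
                     c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                       "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV"),
                     n_norm = sum(mask) * nrow(offs))

  zones <- glszm_zones_cpp(di, mi, dims)
  zmax <- max(zones[, 2])
  szm <- matrix(0, nlevels, zmax)
  for (r in seq_len(nrow(zones)))
    szm[zones[r, 1], zones[r, 2]] <- szm[zones[r, 1], zones[r, 2]] + 1
  out[paste0("GLSZM.", c("SAE", "LAE", "GLN", "SZN", "ZP", "LGZE", "HGZE",
                         "SALGE", "SAHGE", "LALGE", "LAHGE", "GLV", "ZV"))] <-
    gl_size_features(szm,
                     c("SAE", "LAE", "GLN", "SZN", "ZP", "LGZE", "HGZE",
                       "SALGE", "SAHGE", "LALGE", "LAHGE", "GLV", "ZV"),
                     n_norm = sum(mask))

  out[paste0("NGTDM.", c("coarseness", "contrast", "busyness", "complexity",
                         "strength"))] <-
    ngtdm_features(ngtdm_counts_cpp(di, mi, dims, nlevels), nlevels)

  out[paste0("NGLDM.", c("SDE", "LDE", "LGLE", "HGLE", "SDLGLE", "SDHGLE",
                         "LDLGLE", "LDHGLE", "GLN", "GLNN", "DCN", "DCNN",
                         "GLV", "DCV", "DCE"))] <-
    ngldm_features(ngldm_counts_cpp(di, mi, dims, nlevels, 0L))

  sk <- sobel_kernels()
  sob <- filter_magnitude(rescaled, sk$gx, sk$gy)
  ss <- moment_stats(sob[mask])
  out[paste0("Sobel.", names(ss))] <- ss

  for (ang in c(0, 45, 90, 135)) {
    gk <- gabor_kernels(ang)
    gb <- filter_magnitude(rescaled, gk$even, gk$odd)
    gs <- moment_stats(gb[mask])
    out[paste0("Gabor", ang, ".", names(gs))] <- gs
  }
  out
}

#' Extract the 75 average-heterogeneity radiomic features
#'
#' Computes the full feature vector of [feature_manifest()] for one patient.
#' Intensities are rescaled to 0-255 over the tumor-scoped reference range
#' and discretized into 32 levels (matching the per-voxel texture-map
#' scheme); matrix families (GLCM/GLRLM/GLSZM/NGTDM/NGLDM) use 3D
#' 26-neighborhood offsets merged before statistics; Sobel and Gabor
#' filters are applied slice-wise to the rescaled image and summarized by
#' mean, sd, skewness and kurtosis of the response magnitudes over lesion
#' voxels. Under the default pooled aggregation all lesions contribute to
#' one accumulation per family (burden-sensitive, across all disease
#' sites); `volume_weighted` computes per-lesion vectors and averages them
#' with voxel-count weights.
#'
#' @param volume a [ct_volume].
#' @param lesions a [lesion_set].
#' @param config a [radiomics_config()].
#' @return named numeric vector of length 75 (manifest order) with
#'   attribute `patient_id`.
#' @export
extract_features <- function(volume, lesions, config = radiomics_config()) {
  u <- union_mask(lesions)
  if (!any(u)) stop("union of lesion masks is empty", call. = FALSE)
  tcfg <- texture_config(n_levels = config$n_levels,
                         rescale_scope = config$rescale_scope)
  disc <- rescale_discretize(volume, lesions, tcfg)
  if (config$aggregation == "pooled_voxels") {
    out <- features_for_mask(disc$levels, disc$rescaled, u, config$n_levels)
  } else {
    per <- lapply(lesions$lesions, function(l)
      features_for_mask(disc$levels, disc$rescaled, l$mask, config$n_levels))
    w <- vapply(lesions$lesions, function(l) sum(l$mask), numeric(1))
    out <- Reduce(`+`, Map(function(f, wi) f * wi, per, w)) / sum(w)
  }
  stopifnot(length(out) == 75L, all(is.finite(out)))
  attr(out, "patient_id") <- lesions$patient_id
  out
}

#' Feature table for a list of patients
#'
#' @param patients list of lists with elements `volume` and `lesions` (the
#'   shape returned by [load_patient()] / [make_patient()]).
#' @param config a [radiomics_config()].
#' @return data frame: `patient_id` column plus 75 feature columns.
#' @export
extract_feature_table <- function(patients, config = radiomics_config()) {
  rows <- lapply(patients, function(p) {
    f <- extract_features(p$volume, p$lesions, config)
    cbind(data.frame(patient_id = p$lesions$patient_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f), check.names = FALSE))
  })
  do.call(rbind, rows)
}
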