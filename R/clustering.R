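#' Subregion clustering configuration
#'
#' Controls the kernel K-means extraction of texturally homogeneous
#' subregions. Each voxel is described by its four Haralick map values plus
#' its spatial coordinates; all seven channels are z-scored and the spatial
#' channels down-weighted by `spatial_weight`, so clusters are driven by
#' texture but respect spatial relatedness. An RBF kernel with bandwidth
#' equal to the median pairwise descriptor distance (estimated on a
#' subsample) is used; k-means++ initialization with `n_restarts` restarts
#' makes the result deterministic given `seed`.
#'
#' @param max_clusters maximum number of subregions per lesion (default 5).
#' @param spatial_weight weight of the z-scored spatial channels
#'   (default 0.1).
#' @param n_restarts k-means++ restarts (default 10).
#' @param max_sample voxels used for kernel clustering; larger lesions are
#'   subsampled and remaining voxels assigned by kernel distance.
#' @param criterion model-selection rule for the number of clusters:
#'   `"separation"` (default) accepts the largest k whose cluster mean
#'   descriptors are all mutually separated by at least `sep_threshold` in
#'   the z-scored texture space (units of the per-lesion marginal SD) with
#'   no tiny clusters -- the operational definition of "texturally
#'   distinct" subregions. `"mixture_aic"` (AIC of a pooled-variance spherical
#'   Gaussian mixture parameterized from the partition) and `"wcss_aic"`
#'   (the classical k-means surrogate n d log(WCSS/(n d)) + 2 k d) are
#'   provided for comparison; note that per-voxel descriptors from
#'   overlapping patches are strongly spatially autocorrelated, which makes
#'   likelihood-based penalties systematically over-segment (see the
#'   methods vignette).
#' @param sep_threshold minimum between-cluster mean separation in
#'   z-scored texture units (default 3).
#' @param min_cluster_frac smallest admissible cluster, as a fraction of
#'   the lesion voxels (default 0.02, floor of 5 voxels).
#' @param seed integer seed for all clustering randomness.
#' @return An object of class `clustering_config`.
#' @export
clustering_config <- function(max_clusters = 5L, spatial_weight = 0.1,
                              n_restarts = 10L, max_sample = 2000L,
                              criterion = c("separation", "mixture_aic",
                                            "wcss_aic"),
                              sep_threshold = 3, min_cluster_frac = 0.02,
                              seed = 1L) {
  criterion <- match.arg(criterion)
  if (max_clusters < 1L) stop("max_clusters must be >= 1", call. = FALSE)
  if (spatial_weight < 0) stop("spatial_weight must be >= 0", call. = FALSE)
  structure(
    list(max_clusters = as.integer(max_clusters),
         spatial_weight = spatial_weight,
         n_restarts = as.integer(n_restarts),
         max_sample = as.integer(max_sample),
         criterion = criterion, sep_threshold = sep_threshold,
         min_cluster_frac = min_cluster_frac, seed = as.integer(seed)),
    class = "clustering_config")
}

# z-score columns, mapping zero-variance channels to 0
zscore_cols <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s < 1e-12] <- Inf
  sweep(sweep(X, 2, mu, "-"), 2, s, "/")
}

# k-means++ seeding followed by Lloyd assignment in kernel space.
# Km is the n x n kernel matrix. Returns integer labels 1..k.
kernel_kmeans_once <- function(Km, k, max_iter = 50L) {
  n <- nrow(Km)
  kd <- diag(Km)
  # kernel-space squared distances between points for ++ seeding
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- kd + kd[centers[1]] - 2 * Km[, centers[1]]
  if (k > 1) for (j in 2:k) {
    d2 <- pmax(d2, 0)
    if (sum(d2) <= 0) centers[j] <- sample.int(n, 1)
    else centers[j] <- sample.int(n, 1, prob = d2)
    d2 <- pmin(d2, kd + kd[centers[j]] - 2 * Km[, centers[j]])
  }
  lab <- max.col(-vapply(centers, function(c0) kd + kd[c0] - 2 * Km[, c0],
                         numeric(n)), ties.method = "first")
  D <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    sizes <- tabulate(lab, k)
    if (any(sizes == 0L)) {
      # re-seed each empty cluster at the point farthest from its center
      for (c0 in which(sizes == 0L)) {
        far <- which.max(D[cbind(seq_len(n), lab)])
        lab[far] <- c0
        sizes <- tabulate(lab, k)
      }
    }
    Z <- matrix(0, n, k)
    Z[cbind(seq_len(n), lab)] <- 1
    S <- Km %*% Z                      # S[x, c] = sum_{y in c} K(x, y)
    t2 <- sweep(S, 2, sizes, "/")
    t3 <- colSums(Z * S) / sizes^2
    D <- kd - 2 * t2 + matrix(t3, n, k, byrow = TRUE)
    newlab <- max.col(-D, ties.method = "first")
    if (all(newlab == lab)) break
    lab <- newlab
  }
  obj <- sum(D[cbind(seq_len(n), lab)])
  list(labels = lab, objective = obj)
}

kernel_kmeans <- function(Km, k, n_restarts = 10L) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- kernel_kmeans_once(Km, k)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best
}

# AIC of a pooled-variance spherical Gaussian mixture parameterized from a
# hard partition: pi_k = n_k/n, mu_k = cluster means, sigma^2 = WCSS/(n d).
mixture_aic <- function(X, labels, k) {
  n <- nrow(X); d <- ncol(X)
  mus <- matrix(0, k, d)
  wcss <- 0
  for (c0 in seq_len(k)) {
    idx <- which(labels == c0)
    mus[c0, ] <- colMeans(X[idx, , drop = FALSE])
    wcss <- wcss + sum(sweep(X[idx, , drop = FALSE], 2, mus[c0, ], "-")^2)
  }
  sigma2 <- max(wcss / (n * d), 1e-9)
  pis <- tabulate(labels, k) / n
  # log-density under the mixture, computed stably
  ll <- 0
  logcomp <- matrix(0, n, k)
  for (c0 in seq_len(k)) {
    dif <- sweep(X, 2, mus[c0, ], "-")
    logcomp[, c0] <- log(pis[c0]) - 0.5 * d * log(2 * pi * sigma2) -
      rowSums(dif^2) / (2 * sigma2)
  }
  m <- apply(logcomp, 1, max)
  ll <- sum(m + log(rowSums(exp(logcomp - m))))
  p <- k * d + (k - 1) + 1
  -2 * ll + 2 * p
}

wcss_aic <- function(X, labels, k) {
  n <- nrow(X); d <- ncol(X)
  wcss <- 0
  for (c0 in seq_len(k)) {
    idx <- which(labels == c0)
    mu <- colMeans(X[idx, , drop = FALSE])
    wcss <- wcss + sum(sweep(X[idx, , drop = FALSE], 2, mu, "-")^2)
  }
  n * d * log(max(wcss, 1e-12) / (n * d)) + 2 * k * d
}

# partition validity by between-cluster separation: TRUE iff every cluster
# pair's mean descriptors are >= tau apart in the z-scored texture space
# (units of the per-lesion marginal SD) and no cluster is tiny. Using the
# marginal rather than the within-cluster SD as the unit keeps the rule
# stable when tight clusters would otherwise inflate the ratio.
separation_valid <- function(Xt, labels, k, tau, min_n) {
  if (k == 1L) return(TRUE)
  sizes <- tabulate(labels, k)
  if (any(sizes < min_n)) return(FALSE)
  mus <- do.call(rbind, lapply(seq_len(k), function(c0)
    colMeans(Xt[labels == c0, , drop = FALSE])))
  md <- as.matrix(dist(mus))
  min(md[upper.tri(md)]) >= tau
}

# Cluster one lesion's descriptor matrix; returns labels and selected k.
# Xt carries the unweighted texture channels used by the separation rule.
cluster_lesion <- function(X, config, Xt = X[, 1:4, drop = FALSE]) {
  n <- nrow(X)
  kmax <- min(config$max_clusters, n)
  if (kmax == 1L || n < 3L)
    return(list(labels = rep(1L, n), k = 1L))
  sub <- seq_len(n)
  if (n > config$max_sample) sub <- sort(sample.int(n, config$max_sample))
  Xs <- X[sub, , drop = FALSE]
  D2 <- as.matrix(dist(Xs))^2
  sigma <- median(sqrt(D2[upper.tri(D2)]))
  if (!is.finite(sigma) || sigma <= 0)
    return(list(labels = rep(1L, n), k = 1L))
  Km <- exp(-D2 / (2 * sigma^2))
  min_n <- max(5L, ceiling(config$min_cluster_frac * length(sub)))
  best <- NULL
  for (k in seq_len(kmax)) {
    lab <- if (k == 1L) rep(1L, nrow(Xs)) else kernel_kmeans(Km, k, config$n_restarts)$labels
    # guard: merged/empty clusters collapse the candidate
    k_eff <- length(unique(lab))
    if (k_eff < k) next
    if (config$criterion == "separation") {
      if (separation_valid(Xt[sub, , drop = FALSE], lab, k,
                           config$sep_threshold, min_n))
        best <- list(labels = lab, k = k)  # largest valid k wins
      next
    }
    crit_fun <- if (config$criterion == "mixture_aic") mixture_aic else wcss_aic
    aic <- crit_fun(Xs, lab, k)
    if (is.null(best) || aic < best$aic) best <- list(labels = lab, k = k, aic = aic)
  }
  if (is.null(best)) best <- list(labels = rep(1L, nrow(Xs)), k = 1L)
  lab_sub <- best$labels
  if (length(sub) < n) {
    # out-of-sample assignment by kernel distance to each cluster
    rest <- setdiff(seq_len(n), sub)
    CD2 <- outer(rowSums(X[rest, , drop = FALSE]^2),
                 rowSums(Xs^2), "+") -
      2 * X[rest, , drop = FALSE] %*% t(Xs)
    Kc <- exp(-pmax(CD2, 0) / (2 * sigma^2))
    D <- matrix(0, length(rest), best$k)
    for (c0 in seq_len(best$k)) {
      idx <- which(lab_sub == c0)
      D[, c0] <- 1 - 2 * rowMeans(Kc[, idx, drop = FALSE]) +
        mean(Km[idx, idx, drop = FALSE])
    }
    lab <- integer(n)
    lab[sub] <- lab_sub
    lab[rest] <- max.col(-D, ties.method = "first")
  } else lab <- lab_sub
  list(labels = lab, k = best$k)
}

#' Extract texturally homogeneous subregions
#'
#' Each lesion is independently partitioned into k subregions,
#' k in 1..min(max_clusters, n_voxels), by kernel K-means on the z-scored
#' 7-channel descriptor (energy, entropy, homogeneity, contrast, weighted
#' x/y/z); k is chosen by minimizing the configured AIC. Subregions from all
#' lesions are pooled into one patient-level list, each described by the
#' mean of its four Haralick map values and carrying its lesion and region
#' provenance. Deterministic given `config$seed`.
#'
#' @param maps_list list of `texture_maps` (one per lesion), e.g. from
#'   [patient_texture_maps()].
#' @param config a [clustering_config()].
#' @return list of subregions; each is a list with `descriptor` (named
#'   4-vector), `voxels` (linear indices), `lesion_id`, `region`, `n_voxels`.
#' @export
segment_subregions <- function(maps_list, config = clustering_config()) {
  if (length(maps_list) == 0L) stop("no texture maps supplied", call. = FALSE)
  out <- list()
  for (li in seq_along(maps_list)) {
    tm <- maps_list[[li]]
    idx <- which(!is.na(tm$energy))
    if (length(idx) == 0L)
      stop(sprintf("lesion '%s' has zero texture voxels", tm$lesion_id),
           call. = FALSE)
    dims <- dim(tm$energy)
    coords <- arrayInd(idx, dims)
    Teng <- cbind(energy = tm$energy[idx], entropy = tm$entropy[idx],
                  homogeneity = tm$homogeneity[idx],
                  contrast = tm$contrast[idx])
    X <- zscore_cols(cbind(Teng, coords))
    X[, 5:7] <- X[, 5:7] * config$spatial_weight
    # per-lesion derived seed keeps lesion subsets reproducible
    seed_li <- as.integer((as.numeric(config$seed) * 1000 + li) %% 2147483647)
    fit <- with_seed_local(seed_li, cluster_lesion(X, config))
    for (c0 in seq_len(fit$k)) {
      vi <- idx[fit$labels == c0]
      desc <- c(energy = mean(tm$energy[vi]), entropy = mean(tm$entropy[vi]),
                homogeneity = mean(tm$homogeneity[vi]),
                contrast = mean(tm$contrast[vi]))
      out[[length(out) + 1L]] <- list(
        descriptor = desc, voxels = vi,
        lesion_id = tm$lesion_id, region = tm$region,
        n_voxels = length(vi))
    }
  }
  out
}

# run expr under a local RNG state
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
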