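#' Pairwise subregion dissimilarity matrix
#'
#' Euclidean distance between the 4-channel mean-texture descriptors of all
#' subregions of a patient (pooled across lesions). Symmetric with a zero
#' diagonal.
#'
#' @param subregions list from [segment_subregions()].
#' @return object of class `dissimilarity_matrix`: list with `d` (n x n
#'   matrix) and `subregions`.
#' @export
dissimilarity_matrix <- function(subregions) {
  if (length(subregions) < 1L) stop("no subregions", call. = FALSE)
  X <- do.call(rbind, lapply(subregions, function(s) s$descriptor))
  d <- as.matrix(dist(X))
  dimnames(d) <- NULL
  structure(list(d = d, subregions = subregions),
            class = "dissimilarity_matrix")
}

# equal-width level assignment of x in [lo, hi] into nbins, top clamped;
# a numerically degenerate range (all values equal to floating-point
# precision) collapses to level 1
minmax_level <- function(x, lo, hi, nbins) {
  if (hi - lo <= 1e-9 * max(abs(hi), 1)) return(rep(1L, length(x)))
  u <- (x - lo) / (hi - lo)
  pmin(nbins, as.integer(floor(u * nbins)) + 1L)
}

#' Build the group dissimilarity matrix (GDM)
#'
#' A K x M 2D histogram over (dissimilarity level, group-size level)
#' summarizing how subregions group by shared levels of dissimilarity:
#' the upper-triangle dissimilarities are min-max normalized per patient and
#' cut into K equal-width levels; for each subregion s and level l, the
#' group size c(s, l) counts the other subregions whose dissimilarity to s
#' falls in level l; the positive group sizes are min-max normalized and cut
#' into M levels; G(i, j) counts (s, l) entries at dissimilarity level i and
#' group-size level j. Fewer than two subregions yield an empty GDM.
#'
#' @param D a [dissimilarity_matrix()].
#' @param K number of dissimilarity levels (default 10).
#' @param M number of group-size levels (default 10).
#' @return object of class `gdm`: list with `G` (K x M counts), `K`, `M`,
#'   `n_subregions`, and the binning ranges `diss_range`, `size_range`.
#' @export
build_gdm <- function(D, K = 10L, M = 10L) {
  n <- nrow(D$d)
  if (n < 2L) {
    return(structure(list(G = matrix(0, K, M), K = as.integer(K),
                          M = as.integer(M), n_subregions = n,
                          diss_range = c(NA_real_, NA_real_),
                          size_range = c(NA_real_, NA_real_)),
                     class = "gdm"))
  }
  dv <- D$d[upper.tri(D$d)]
  dr <- range(dv)
  # per-pair dissimilarity levels, applied to the full matrix off-diagonal
  lev <- matrix(0L, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    l <- minmax_level(D$d[a, b], dr[1], dr[2], K)
    lev[a, b] <- l; lev[b, a] <- l
  }
  # group sizes c(s, l)
  entries <- list()
  for (s in seq_len(n)) {
    ls <- lev[s, -s]
    tab <- tabulate(ls, nbins = K)
    for (l in which(tab > 0L))
      entries[[length(entries) + 1L]] <- c(s = s, level = l, size = tab[l])
  }
  ent <- do.call(rbind, entries)
  sr <- range(ent[, "size"])
  jlev <- minmax_level(ent[, "size"], sr[1], sr[2], M)
  G <- matrix(0, K, M)
  for (r in seq_len(nrow(ent)))
    G[ent[r, "level"], jlev[r]] <- G[ent[r, "level"], jlev[r]] + 1
  structure(list(G = G, K = as.integer(K), M = as.integer(M),
                 n_subregions = n, diss_range = dr, size_range = sr),
            class = "gdm")
}

#' The cluster dissimilarity (cluDiss) statistic
#'
#' Fourth central moment of the GDM about its normalized mean indices:
#' with normalized indices u_i = i/K, v_j = j/M, weights P = G / sum(G),
#' mu_D = sum u_i P(i,j) and mu_A = sum v_j P(i,j),
#' cluDiss = (1 / (K M)) * sum_i sum_j (u_i + v_j - mu_D - mu_A)^4 G(i,j),
#' with G entering as raw counts so the statistic grows with the number of
#' subregions and lesions. An empty GDM (fewer than two subregions) gives 0.
#'
#' @param gdm a [build_gdm()] result.
#' @param region_scope provenance tag (`"all"`, `"pelvis"` or `"abdomen"`).
#' @param n_lesions optional lesion count for provenance.
#' @return object of class `cludiss_result`: list with `value`,
#'   `region_scope`, `n_subregions`, `n_lesions`, `evaluable`, `gdm`.
#' @export
cludiss <- function(gdm, region_scope = "all", n_lesions = NA_integer_) {
  tot <- sum(gdm$G)
  if (tot <= 0) {
    return(structure(list(value = 0, region_scope = region_scope,
                          n_subregions = gdm$n_subregions,
                          n_lesions = n_lesions, evaluable = TRUE, gdm = gdm),
                     class = "cludiss_result"))
  }
  u <- (seq_len(gdm$K)) / gdm$K
  v <- (seq_len(gdm$M)) / gdm$M
  P <- gdm$G / tot
  muD <- sum(u * rowSums(P))
  muA <- sum(v * colSums(P))
  dev <- outer(u, v, "+") - muD - muA
  val <- sum(dev^4 * gdm$G) / (gdm$K * gdm$M)
  structure(list(value = val, region_scope = region_scope,
                 n_subregions = gdm$n_subregions, n_lesions = n_lesions,
                 evaluable = TRUE, gdm = gdm),
            class = "cludiss_result")
}

#' @exportS3Method base::print
print.cludiss_result <- function(x, ...) {
  if (!x$evaluable)
    cat(sprintf("<cluDiss> scope %s: not evaluable (fewer than 2 lesions in scope)\n",
                x$region_scope))
  else
    cat(sprintf("<cluDiss> scope %s: %.6g (%d subregions, %s lesions)\n",
                x$region_scope, x$value, x$n_subregions,
                ifelse(is.na(x$n_lesions), "?", x$n_lesions)))
  invisible(x)
}

#' Full cluDiss chain for one patient
#'
#' Runs texture mapping, subregion extraction, dissimilarity matrix, GDM
#' and cluDiss on the lesions within the requested anatomic scope. Fewer
#' than two lesions in scope (the measure needs at least two tumor sites)
#' yields a not-evaluable result rather than an error.
#'
#' @param volume a [ct_volume].
#' @param lesions a [lesion_set].
#' @param scope `"all"`, `"pelvis"` or `"abdomen"`.
#' @param texture_cfg a [texture_config()].
#' @param clustering_cfg a [clustering_config()].
#' @param K,M GDM dimensions.
#' @return a `cludiss_result`.
#' @export
cludiss_for_patient <- function(volume, lesions, scope = c("all", "pelvis", "abdomen"),
                                texture_cfg = texture_config(),
                                clustering_cfg = clustering_config(),
                                K = 10L, M = 10L) {
  scope <- match.arg(scope)
  keep <- if (scope == "all") lesions$lesions
          else Filter(function(l) l$region == scope, lesions$lesions)
  if (length(keep) < 2L) {
    return(structure(list(value = NA_real_, region_scope = scope,
                          n_subregions = 0L, n_lesions = length(keep),
                          evaluable = FALSE, gdm = NULL),
                     class = "cludiss_result"))
  }
  ls <- lesion_set(keep, lesions$patient_id, scanner = lesions$scanner)
  maps <- patient_texture_maps(volume, ls, texture_cfg)
  subs <- segment_subregions(maps, clustering_cfg)
  D <- dissimilarity_matrix(subs)
  g <- build_gdm(D, K = K, M = M)
  res <- cludiss(g, region_scope = scope, n_lesions = length(keep))
  res$n_subregions <- length(subs)
  res
}

#' Conventional imaging measures
#'
#' Total tumor volume (TTV) in cc -- the total number of lesion voxels
#' multiplied by the voxel size -- and the number of distinct anatomic site
#' labels.
#'
#' @param lesions a [lesion_set].
#' @param spacing voxel spacing in mm (length 3).
#' @return list with `ttv` (cc) and `n_sites`.
#' @export
conventional_measures <- function(lesions, spacing) {
  if (length(lesions$lesions) < 1L) stop("empty lesion set", call. = FALSE)
  vox_cc <- prod(spacing) / 1000  # mm^3 to cc
  nvox <- sum(vapply(lesions$lesions, function(l) sum(l$mask), numeric(1)))
  sites <- unique(vapply(lesions$lesions, function(l) l$site_label,
                         character(1)))
  list(ttv = nvox * vox_cc, n_sites = length(sites))
}
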