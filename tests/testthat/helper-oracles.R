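# Independent brute-force oracles. Deliberately naive (plain loops, no
# shared code with the package internals) so they can arbitrate.

# per-voxel patch GLCM statistics, straight from the definitions
oracle_haralick_voxel <- function(levels, mask, x, y, z, hx, hy, hz,
                                  offsets, nlevels) {
  dims <- dim(levels)
  glcm <- matrix(0, nlevels, nlevels)
  total <- 0
  for (pz in max(1, z - hz):min(dims[3], z + hz))
    for (py in max(1, y - hy):min(dims[2], y + hy))
      for (px in max(1, x - hx):min(dims[1], x + hx)) {
        if (!mask[px, py, pz]) next
        for (o in seq_len(nrow(offsets))) {
          qx <- px + offsets[o, 1]; qy <- py + offsets[o, 2]
          qz <- pz + offsets[o, 3]
          if (qx < max(1, x - hx) || qx > min(dims[1], x + hx)) next
          if (qy < max(1, y - hy) || qy > min(dims[2], y + hy)) next
          if (qz < max(1, z - hz) || qz > min(dims[3], z + hz)) next
          if (!mask[qx, qy, qz]) next
          a <- levels[px, py, pz]; b <- levels[qx, qy, qz]
          glcm[a, b] <- glcm[a, b] + 1
          glcm[b, a] <- glcm[b, a] + 1
          total <- total + 2
        }
      }
  if (total == 0)
    return(c(energy = 1, entropy = 0, homogeneity = 1, contrast = 0))
  p <- glcm / total
  en <- sum(p^2)
  pp <- p[p > 0]
  ent <- -sum(pp * log2(pp))
  hom <- 0; con <- 0
  for (i in seq_len(nlevels)) for (j in seq_len(nlevels)) {
    hom <- hom + p[i, j] / (1 + abs(i - j))
    con <- con + p[i, j] * (i - j)^2
  }
  c(energy = en, entropy = ent, homogeneity = hom, contrast = con)
}

oracle_glcm_counts <- function(levels, mask, offsets, nlevels) {
  dims <- dim(levels)
  glcm <- matrix(0, nlevels, nlevels)
  for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
    if (!mask[x, y, z]) next
    for (o in seq_len(nrow(offsets))) {
      qx <- x + offsets[o, 1]; qy <- y + offsets[o, 2]; qz <- z + offsets[o, 3]
      if (qx < 1 || qx > dims[1] || qy < 1 || qy > dims[2] ||
          qz < 1 || qz > dims[3]) next
      if (!mask[qx, qy, qz]) next
      a <- levels[x, y, z]; b <- levels[qx, qy, qz]
      glcm[a, b] <- glcm[a, b] + 1
      glcm[b, a] <- glcm[b, a] + 1
    }
  }
  glcm
}

oracle_glrlm <- function(levels, mask, dirs, nlevels) {
  dims <- dim(levels)
  runs <- list()
  inb <- function(x, y, z) x >= 1 && x <= dims[1] && y >= 1 && y <= dims[2] &&
    z >= 1 && z <= dims[3]
  for (d in seq_len(nrow(dirs))) {
    dx <- dirs[d, 1]; dy <- dirs[d, 2]; dz <- dirs[d, 3]
    for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
      if (!mask[x, y, z]) next
      g <- levels[x, y, z]
      bx <- x - dx; by <- y - dy; bz <- z - dz
      if (inb(bx, by, bz) && mask[bx, by, bz] && levels[bx, by, bz] == g)
        next
      len <- 1
      cx <- x + dx; cy <- y + dy; cz <- z + dz
      while (inb(cx, cy, cz) && mask[cx, cy, cz] && levels[cx, cy, cz] == g) {
        len <- len + 1
        cx <- cx + dx; cy <- cy + dy; cz <- cz + dz
      }
      runs[[length(runs) + 1]] <- c(g, len)
    }
  }
  rm0 <- do.call(rbind, runs)
  out <- matrix(0, nlevels, max(rm0[, 2]))
  for (r in seq_len(nrow(rm0))) out[rm0[r, 1], rm0[r, 2]] <-
      out[rm0[r, 1], rm0[r, 2]] + 1
  out
}

# 26-connected equal-level zones by repeated label propagation
oracle_glszm_zones <- function(levels, mask) {
  dims <- dim(levels)
  lab <- array(0L, dims)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    g <- levels[start]
    while (length(queue)) {
      c0 <- queue[1]; queue <- queue[-1]
      co <- arrayInd(c0, dims)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- co + c(dx, dy, dz)
        if (any(q < 1) || any(q > dims)) next
        qi <- q[1] + dims[1] * (q[2] - 1) + dims[1] * dims[2] * (q[3] - 1)
        if (!mask[qi] || lab[qi] > 0 || levels[qi] != g) next
        lab[qi] <- nxt
        queue <- c(queue, qi)
      }
    }
  }
  sizes <- table(lab[lab > 0])
  lv <- sapply(as.integer(names(sizes)), function(l) levels[which(lab == l)[1]])
  cbind(level = lv, size = as.integer(sizes))
}

oracle_ngtdm <- function(levels, mask, nlevels) {
  dims <- dim(levels)
  n_g <- s_g <- numeric(nlevels)
  for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
    if (!mask[x, y, z]) next
    nb <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      qx <- x + dx; qy <- y + dy; qz <- z + dz
      if (qx < 1 || qx > dims[1] || qy < 1 || qy > dims[2] ||
          qz < 1 || qz > dims[3]) next
      if (mask[qx, qy, qz]) nb <- c(nb, levels[qx, qy, qz])
    }
    if (length(nb) == 0) next
    g <- levels[x, y, z]
    n_g[g] <- n_g[g] + 1
    s_g[g] <- s_g[g] + abs(g - mean(nb))
  }
  cbind(n_g, s_g)
}

oracle_ngldm <- function(levels, mask, nlevels, alpha = 0) {
  dims <- dim(levels)
  s <- matrix(0, nlevels, 27)
  for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
    if (!mask[x, y, z]) next
    dep <- 1
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      qx <- x + dx; qy <- y + dy; qz <- z + dz
      if (qx < 1 || qx > dims[1] || qy < 1 || qy > dims[2] ||
          qz < 1 || qz > dims[3]) next
      if (mask[qx, qy, qz] &&
          abs(levels[qx, qy, qz] - levels[x, y, z]) <= alpha)
        dep <- dep + 1
    }
    s[levels[x, y, z], dep] <- s[levels[x, y, z], dep] + 1
  }
  s
}

# GDM built verbatim from its stated construction
oracle_gdm <- function(d, K = 10, M = 10) {
  n <- nrow(d)
  if (n < 2) return(matrix(0, K, M))
  level_of <- function(x, lo, hi, nb) {
    if (hi <= lo) return(1L)
    min(nb, floor((x - lo) / (hi - lo) * nb) + 1)
  }
  dv <- d[upper.tri(d)]
  lo <- min(dv); hi <- max(dv)
  entries <- NULL
  for (s in 1:n) {
    cnt <- integer(K)
    for (t in setdiff(1:n, s))
      cnt[level_of(d[s, t], lo, hi, K)] <- cnt[level_of(d[s, t], lo, hi, K)] + 1L
    for (l in which(cnt > 0))
      entries <- rbind(entries, c(l, cnt[l]))
  }
  slo <- min(entries[, 2]); shi <- max(entries[, 2])
  G <- matrix(0, K, M)
  for (r in seq_len(nrow(entries))) {
    j <- level_of(entries[r, 2], slo, shi, M)
    G[entries[r, 1], j] <- G[entries[r, 1], j] + 1
  }
  G
}

# tiny in-memory phantom patient for quick module tests
tiny_patient <- function(seed, n_lesions = 2, two_class = FALSE,
                         dims = c(48L, 48L, 16L), radii = c(5, 5, 2)) {
  cls <- paired_texture_classes()
  centers <- list(c(14, 14, 6), c(34, 34, 10), c(14, 34, 8), c(34, 14, 8))
  regions <- c("pelvis", "abdomen", "abdomen", "pelvis")
  sites <- c("ovary", "omentum", "peritoneum", "pelvic_sidewall")
  lesions <- lapply(seq_len(n_lesions), function(i) {
    classes <- if (two_class) cls[(2 * i - 1):(2 * i)] else cls[[2 * i - 1]]
    phantom_lesion(centers[[i]], radii, sites[i], regions[i], classes)
  })
  make_patient(phantom_spec(lesions, dims = dims, seed = seed))
}
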