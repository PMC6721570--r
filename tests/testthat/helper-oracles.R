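# Independent brute-force oracles: naive per-voxel / per-pair loops used
# to verify the vectorized texture engines, plus a textbook log-rank
# tabulation. Deliberately slow and literal.

# a quantized_roi with random levels on a random blob-ish mask
random_quantized_roi <- function(seed, dims = c(8, 8, 8), ng = 6L,
                                 p_mask = 0.6) {
  set.seed(seed)
  msk <- array(stats::runif(prod(dims)) < p_mask, dims)
  if (!any(msk)) msk[1, 1, 1] <- TRUE
  lev <- array(0L, dims)
  lev[msk] <- sample.int(ng, sum(msk), replace = TRUE)
  structure(list(levels = lev, n_levels = ng, spacing_mm = c(1, 1, 1)),
            class = "quantized_roi")
}

all_26_offsets <- function() {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ])
}

naive_glcm <- function(q) {
  lev <- q$levels
  ng <- q$n_levels
  d <- dim(lev)
  counts <- matrix(0, ng, ng)
  offs <- all_26_offsets()  # both orders of every pair
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lev[x, y, z]
    if (a == 0L) next
    for (k in seq_len(nrow(offs))) {
      xx <- x + offs[k, 1]; yy <- y + offs[k, 2]; zz <- z + offs[k, 3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
          zz < 1 || zz > d[3]) next
      b <- lev[xx, yy, zz]
      if (b > 0L) counts[a, b] <- counts[a, b] + 1
    }
  }
  counts / sum(counts)
}

naive_glcm_features <- function(p) {
  ng <- nrow(p)
  l2 <- function(v) if (v > 0) log2(v) else 0
  mux <- muy <- 0
  for (i in 1:ng) for (j in 1:ng) {
    mux <- mux + i * p[i, j]; muy <- muy + j * p[i, j]
  }
  sx2 <- sy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    sx2 <- sx2 + (i - mux)^2 * p[i, j]; sy2 <- sy2 + (j - muy)^2 * p[i, j]
  }
  ac <- ct <- ds <- en <- et <- hg <- id <- sv <- ctd <- csh <- cpr <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    ac <- ac + i * j * v
    ct <- ct + (i - j)^2 * v
    ds <- ds + abs(i - j) * v
    en <- en + v^2
    et <- et - v * l2(v)
    hg <- hg + v / (1 + (i - j)^2)
    id <- id + v / (1 + abs(i - j))
    sv <- sv + (i - mux)^2 * v
    ctd <- ctd + (i + j - mux - muy)^2 * v
    csh <- csh + (i + j - mux - muy)^3 * v
    cpr <- cpr + (i + j - mux - muy)^4 * v
  }
  cor_ <- if (sx2 > 0 && sy2 > 0) (ac - mux * muy) / sqrt(sx2 * sy2) else 0
  psum <- numeric(2 * ng); pdif <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  sa <- se <- de <- da <- dv <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * psum[k]; se <- se - psum[k] * l2(psum[k])
  }
  for (k in 0:(ng - 1)) {
    de <- de - pdif[k + 1] * l2(pdif[k + 1]); da <- da + k * pdif[k + 1]
  }
  for (k in 0:(ng - 1)) dv <- dv + (k - da)^2 * pdif[k + 1]
  px <- rowSums(p); py <- colSums(p)
  hx <- -sum(sapply(px, function(v) v * l2(v)))
  hy <- -sum(sapply(py, function(v) v * l2(v)))
  hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    hxy1 <- hxy1 - p[i, j] * l2(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * l2(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) > 0) (et - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - et))))
  c(glcm_autocorrelation = ac, glcm_cluster_prominence = cpr,
    glcm_cluster_shade = csh, glcm_cluster_tendency = ctd,
    glcm_contrast = ct, glcm_correlation = cor_,
    glcm_difference_entropy = de, glcm_difference_variance = dv,
    glcm_dissimilarity = ds, glcm_energy = en, glcm_entropy = et,
    glcm_homogeneity = hg, glcm_imc1 = imc1, glcm_imc2 = imc2,
    glcm_maximum_probability = max(p), glcm_sum_average = sa,
    glcm_sum_entropy = se, glcm_sum_of_squares_variance = sv,
    glcm_inverse_difference = id)
}

# zones by breadth-first search over 26-connected equal-level voxels
naive_glszm_zones <- function(q) {
  lev <- q$levels
  d <- dim(lev)
  offs <- all_26_offsets()
  seen <- array(FALSE, d)
  zones <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lev[x, y, z] == 0L || seen[x, y, z]) next
    g <- lev[x, y, z]
    queue <- matrix(c(x, y, z), 1)
    seen[x, y, z] <- TRUE
    size <- 0L
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        w <- v + offs[k, ]
        if (any(w < 1) || any(w > d)) next
        if (!seen[w[1], w[2], w[3]] && lev[w[1], w[2], w[3]] == g) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue <- rbind(queue, w)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = g, size = size)
  }
  do.call(rbind, zones)
}

naive_glszm_features <- function(q) {
  zn <- naive_glszm_zones(q)
  nz <- nrow(zn)
  np <- sum(q$levels > 0L)
  i <- zn[, "level"]; j <- zn[, "size"]
  gl <- tapply(rep(1, nz), i, sum)
  zs <- tapply(rep(1, nz), j, sum)
  c(glszm_small_zone_emphasis = sum(1 / j^2) / nz,
    glszm_large_zone_emphasis = sum(j^2) / nz,
    glszm_gray_level_nonuniformity = sum(gl^2) / nz,
    glszm_zone_size_nonuniformity = sum(zs^2) / nz,
    glszm_zone_percentage = nz / np,
    glszm_low_gray_zone_emphasis = sum(1 / i^2) / nz,
    glszm_high_gray_zone_emphasis = sum(i^2) / nz,
    glszm_small_zone_low_gray_emphasis = sum(1 / (i^2 * j^2)) / nz,
    glszm_small_zone_high_gray_emphasis = sum(i^2 / j^2) / nz,
    glszm_large_zone_low_gray_emphasis = sum(j^2 / i^2) / nz,
    glszm_large_zone_high_gray_emphasis = sum(i^2 * j^2) / nz)
}

# per-voxel NGTDM under the masked complete-neighbourhood rule: every
# in-grid 26-neighbour position must be in-mask
naive_ngtdm <- function(q) {
  lev <- q$levels
  ng <- q$n_levels
  d <- dim(lev)
  offs <- all_26_offsets()
  s <- numeric(ng); n <- integer(ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    g <- lev[x, y, z]
    if (g == 0L) next
    nb <- integer(0); complete <- TRUE
    for (k in seq_len(nrow(offs))) {
      w <- c(x, y, z) + offs[k, ]
      if (any(w < 1) || any(w > d)) next
      gv <- lev[w[1], w[2], w[3]]
      if (gv == 0L) { complete <- FALSE; break }
      nb <- c(nb, gv)
    }
    if (!complete || !length(nb)) next
    s[g] <- s[g] + abs(g - mean(nb))
    n[g] <- n[g] + 1L
  }
  nv <- sum(n)
  list(s = s, p = if (nv > 0) n / nv else numeric(ng), n = n,
       n_valid = nv, n_levels = ng)
}

naive_ngtdm_features <- function(tm) {
  eps <- 1e-6
  p <- tm$p; s <- tm$s; nv <- tm$n_valid
  act <- which(p > 0); ngp <- length(act)
  coars <- min(1 / (eps + sum(p * s)), 1e6)
  if (ngp < 2 || nv == 0)
    return(c(ngtdm_coarseness = coars, ngtdm_contrast = 0,
             ngtdm_busyness = 0, ngtdm_complexity = 0, ngtdm_strength = 0))
  ctr <- bden <- cplx <- stren <- 0
  for (i in act) for (j in act) {
    ctr <- ctr + p[i] * p[j] * (i - j)^2
    bden <- bden + abs(i * p[i] - j * p[j])
    cplx <- cplx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
    stren <- stren + (p[i] + p[j]) * (i - j)^2
  }
  c(ngtdm_coarseness = coars,
    ngtdm_contrast = ctr / (ngp * (ngp - 1)) * sum(s) / nv,
    ngtdm_busyness = if (bden > 0) sum(p * s) / bden else 0,
    ngtdm_complexity = cplx / nv,
    ngtdm_strength = stren / (eps + sum(s)))
}

# textbook two-group log-rank: O-E and hypergeometric variance summed
# over distinct event times
naive_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[2]
  o1 <- e1 <- v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at <- time >= tt
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (o1 - e1)^2 / v
  list(statistic = chi,
       p_value = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# convenience: a small textured lesion ready for extraction
small_lesion <- function(seed, shape = c(20, 20, 20), radius = 6,
                         scale = 2.5) {
  ls <- generate_lesion(shape, c(1, 1, 1), radius_mm = radius,
                        texture_scale_mm = scale, seed = seed)
  list(volume = normalize_intensity(ls$volume), mask = ls$mask)
}
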