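#' Gray-level size-zone matrix of a quantized ROI
#'
#' A zone is a maximal 26-connected component of in-mask voxels sharing a
#' gray level; entry s(i, j) counts zones of level i and size j voxels.
#' Mass conservation holds by construction: the size-weighted sum of all
#' entries equals the number of in-mask voxels.
#'
#' @param q a `quantized_roi`.
#' @return a `glszm` object: list with integer matrix `s` (Ng x Zmax),
#'   total zone count `n_zones`, in-mask voxel count `n_voxels`, and
#'   `n_levels`.
#' @export
compute_glszm <- function(q) {
  lev <- q$levels
  ng <- q$n_levels
  d <- dim(lev)
  dirs <- glcm_directions()
  zones <- list()  # per zone: (level, size)
  for (g in seq_len(ng)) {
    vox <- which(lev == g)
    if (!length(vox)) next
    id <- array(0L, d)
    id[vox] <- seq_along(vox)
    edges <- integer(0)
    for (k in seq_len(nrow(dirs))) {
      o <- dirs[k, ]
      x1 <- safe_seq(max(1, 1 - o[1]), min(d[1], d[1] - o[1]))
      y1 <- safe_seq(max(1, 1 - o[2]), min(d[2], d[2] - o[2]))
      z1 <- safe_seq(max(1, 1 - o[3]), min(d[3], d[3] - o[3]))
      if (!length(x1) || !length(y1) || !length(z1)) next
      a <- id[x1, y1, z1, drop = FALSE]
      b <- id[x1 + o[1], y1 + o[2], z1 + o[3], drop = FALSE]
      keep <- a > 0L & b > 0L
      if (any(keep)) edges <- c(edges, rbind(a[keep], b[keep]))
    }
    comp <- if (length(edges)) {
      gr <- igraph::make_graph(edges, n = length(vox), directed = FALSE)
      igraph::components(gr)$membership
    } else {
      seq_along(vox)
    }
    sizes <- tabulate(comp)
    zones[[length(zones) + 1L]] <- cbind(g, sizes[sizes > 0])
  }
  zt <- do.call(rbind, zones)
  zmax <- max(zt[, 2])
  s <- matrix(0L, ng, zmax)
  for (r in seq_len(nrow(zt)))
    s[zt[r, 1], zt[r, 2]] <- s[zt[r, 1], zt[r, 2]] + 1L
  structure(list(s = s, n_zones = nrow(zt), n_voxels = sum(lev > 0L),
                 n_levels = ng), class = "glszm")
}

#' Size-zone texture features from a GLSZM
#'
#' The 11 standard emphasis and nonuniformity statistics; with s(i, j)
#' the zone counts, Nz the total zone count and Np the in-mask voxel
#' count, e.g. small zone high gray emphasis = sum s(i,j) i^2 / j^2 / Nz
#' and large zone low gray emphasis = sum s(i,j) j^2 / i^2 / Nz.
#'
#' @param z a `glszm` object.
#' @return named numeric vector of 11 features, `glszm_`-prefixed.
#' @export
glszm_features <- function(z) {
  s <- z$s
  nz <- z$n_zones
  np <- z$n_voxels
  i <- matrix(seq_len(nrow(s)), nrow(s), ncol(s))
  j <- t(matrix(seq_len(ncol(s)), ncol(s), nrow(s)))
  gl_counts <- rowSums(s)
  zs_counts <- colSums(s)
  c(glszm_small_zone_emphasis = sum(s / j^2) / nz,
    glszm_large_zone_emphasis = sum(s * j^2) / nz,
    glszm_gray_level_nonuniformity = sum(gl_counts^2) / nz,
    glszm_zone_size_nonuniformity = sum(zs_counts^2) / nz,
    glszm_zone_percentage = nz / np,
    glszm_low_gray_zone_emphasis = sum(s / i^2) / nz,
    glszm_high_gray_zone_emphasis = sum(s * i^2) / nz,
    glszm_small_zone_low_gray_emphasis = sum(s / (i^2 * j^2)) / nz,
    glszm_small_zone_high_gray_emphasis = sum(s * i^2 / j^2) / nz,
    glszm_large_zone_low_gray_emphasis = sum(s * j^2 / i^2) / nz,
    glszm_large_zone_high_gray_emphasis = sum(s * i^2 * j^2) / nz)
}
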