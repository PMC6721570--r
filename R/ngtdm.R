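#' Neighbourhood gray-tone difference matrix of a quantized ROI
#'
#' For each contributing voxel the mean gray level of its 26-neighbourhood
#' is computed and the absolute deviation |level - mean| accumulated into
#' s_i per gray level. A voxel contributes only if its complete
#' neighbourhood lies inside the mask: every 26-neighbour position that
#' falls inside the grid must be in-mask (and at least one neighbour must
#' exist). Level probabilities p_i are the level fractions among
#' contributing voxels.
#'
#' @param q a `quantized_roi`.
#' @return an `ngtdm` object: list with per-level deviation sums `s`,
#'   probabilities `p`, level counts `n`, number of contributing voxels
#'   `n_valid`, and `n_levels`.
#' @export
compute_ngtdm <- function(q) {
  lev <- q$levels
  ng <- q$n_levels
  d <- dim(lev)
  inmask <- lev > 0L

  nb_sum <- array(0, d)    # sum of in-mask neighbour levels
  nb_msk <- array(0L, d)   # number of in-mask neighbours
  nb_grid <- array(0L, d)  # number of in-grid neighbour positions
  dirs <- glcm_directions()
  offs <- rbind(dirs, -dirs)  # the full 26-neighbourhood
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    x1 <- safe_seq(max(1, 1 - o[1]), min(d[1], d[1] - o[1]))
    y1 <- safe_seq(max(1, 1 - o[2]), min(d[2], d[2] - o[2]))
    z1 <- safe_seq(max(1, 1 - o[3]), min(d[3], d[3] - o[3]))
    if (!length(x1) || !length(y1) || !length(z1)) next
    nbl <- lev[x1 + o[1], y1 + o[2], z1 + o[3], drop = FALSE]
    nb_sum[x1, y1, z1] <- nb_sum[x1, y1, z1] + c(nbl)
    nb_msk[x1, y1, z1] <- nb_msk[x1, y1, z1] + c(nbl > 0L)
    nb_grid[x1, y1, z1] <- nb_grid[x1, y1, z1] + 1L
  }

  valid <- inmask & nb_msk > 0L & nb_msk == nb_grid
  s <- numeric(ng)
  n <- integer(ng)
  if (any(valid)) {
    lv <- lev[valid]
    dev <- abs(lv - nb_sum[valid] / nb_msk[valid])
    s <- vapply(seq_len(ng), function(g) sum(dev[lv == g]), numeric(1))
    n <- tabulate(lv, ng)
  }
  nv <- sum(n)
  p <- if (nv > 0) n / nv else numeric(ng)
  structure(list(s = s, p = p, n = n, n_valid = nv, n_levels = ng),
            class = "ngtdm")
}

#' Amadasun texture features from an NGTDM
#'
#' Coarseness, contrast, busyness, complexity and strength. Coarseness is
#' 1 / (1e-6 + sum p_i s_i), capped at 1e6 so a homogeneous ROI yields a
#' finite, testable value; busyness and strength are defined as 0 when
#' their denominators vanish, and contrast is 0 when fewer than two gray
#' levels occur.
#'
#' @param tm an `ngtdm` object.
#' @return named numeric vector of the five features, `ngtdm_`-prefixed.
#' @export
ngtdm_features <- function(tm) {
  eps <- 1e-6
  p <- tm$p
  s <- tm$s
  nv <- tm$n_valid
  lev <- seq_len(tm$n_levels)
  act <- p > 0
  ngp <- sum(act)

  coars <- min(1 / (eps + sum(p * s)), 1e6)

  if (ngp >= 2 && nv > 0) {
    ii <- matrix(lev[act], ngp, ngp)
    jj <- matrix(lev[act], ngp, ngp, byrow = TRUE)
    pi_ <- p[act]
    pij <- outer(pi_, pi_)
    contr <- (sum(pij * (ii - jj)^2) / (ngp * (ngp - 1))) * (sum(s) / nv)
    busy_den <- sum(abs(outer(lev[act] * pi_, lev[act] * pi_, `-`)))
    busy <- if (busy_den > 0) sum(p * s) / busy_den else 0
    si <- s[act]
    cplx <- sum(abs(ii - jj) * (outer(pi_ * si, pi_ * si, `+`) /
                                  outer(pi_, pi_, `+`))) / nv
    stren <- sum(outer(pi_, pi_, `+`) * (ii - jj)^2) / (eps + sum(s))
  } else {
    contr <- 0
    busy <- 0
    cplx <- 0
    stren <- 0
  }

  c(ngtdm_coarseness = coars, ngtdm_contrast = contr,
    ngtdm_busyness = busy, ngtdm_complexity = cplx,
    ngtdm_strength = stren)
}
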