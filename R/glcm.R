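#' The 13 unique 3D direction offsets at distance 1
#'
#' Half of the 26-neighbourhood: one representative per opposite pair.
#' @return integer matrix with 13 rows and columns dx, dy, dz.
#' @export
glcm_directions <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

#' Gray-level co-occurrence matrix of a quantized ROI
#'
#' Co-occurrences of gray-level pairs at distance 1 are accumulated over
#' the supplied direction offsets (all 13 unique 3D directions by
#' default), counting only voxel pairs both inside the mask and counting
#' each pair in both orders, so the matrix is symmetric. Counts from all
#' directions are summed into a single matrix and normalized to sum 1.
#'
#' @param q a `quantized_roi`.
#' @param directions integer matrix of direction offsets (rows dx,dy,dz).
#' @return a `glcm` object: list with normalized matrix `p` (Ng x Ng) and
#'   `n_levels`.
#' @export
compute_glcm <- function(q, directions = glcm_directions()) {
  lev <- q$levels
  ng <- q$n_levels
  d <- dim(lev)
  counts <- matrix(0, ng, ng)
  for (k in seq_len(nrow(directions))) {
    o <- directions[k, ]
    x1 <- safe_seq(max(1, 1 - o[1]), min(d[1], d[1] - o[1]))
    y1 <- safe_seq(max(1, 1 - o[2]), min(d[2], d[2] - o[2]))
    z1 <- safe_seq(max(1, 1 - o[3]), min(d[3], d[3] - o[3]))
    if (!length(x1) || !length(y1) || !length(z1)) next
    a <- lev[x1, y1, z1, drop = FALSE]
    b <- lev[x1 + o[1], y1 + o[2], z1 + o[3], drop = FALSE]
    keep <- a > 0L & b > 0L
    if (!any(keep)) next
    tab <- tabulate(a[keep] + ng * (b[keep] - 1L), ng * ng)
    counts <- counts + matrix(tab, ng, ng)
    counts <- counts + t(matrix(tab, ng, ng))  # reverse order of each pair
  }
  if (sum(counts) == 0)
    stop("degenerate ROI: no in-mask voxel pair in any direction")
  structure(list(p = counts / sum(counts), n_levels = ng), class = "glcm")
}

#' Haralick-family texture features from a GLCM
#'
#' The 19 classical co-occurrence statistics. Logarithms are base 2 with
#' the convention 0 log 0 = 0. For a degenerate matrix with zero marginal
#' variance, correlation and the first informational measure are defined
#' as 0.
#'
#' @param m a `glcm` object.
#' @return named numeric vector of 19 features, `glcm_`-prefixed.
#' @export
glcm_features <- function(m) {
  p <- m$p
  ng <- m$n_levels
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))

  # sum and difference marginals: k = i + j in 2..2Ng, k = |i - j| in 0..Ng-1
  psum <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), numeric(1))
  ksum <- 2:(2 * ng)
  pdiff <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  kdiff <- 0:(ng - 1)

  ent2 <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }

  autocorr <- sum(i * j * p)
  contrast <- sum((i - j)^2 * p)
  dissim <- sum(abs(i - j) * p)
  energy <- sum(p^2)
  entropy <- ent2(p)
  homog <- sum(p / (1 + (i - j)^2))
  invdiff <- sum(p / (1 + abs(i - j)))
  maxprob <- max(p)
  ssvar <- sum((i - mux)^2 * p)
  correl <- if (sx > 0 && sy > 0) (autocorr - mux * muy) / (sx * sy) else 0
  clus <- i + j - mux - muy
  ctend <- sum(clus^2 * p)
  cshade <- sum(clus^3 * p)
  cprom <- sum(clus^4 * p)

  savg <- sum(ksum * psum)
  sent <- ent2(psum)
  dent <- ent2(pdiff)
  davg <- sum(kdiff * pdiff)
  dvar <- sum((kdiff - davg)^2 * pdiff)

  hx <- ent2(px)
  hy <- ent2(py)
  hxy <- entropy
  pxy <- outer(px, py)
  pos <- p > 0 & pxy > 0
  hxy1 <- -sum(p[pos] * log2(pxy[pos]))
  hxy2 <- ent2(pxy)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  c(glcm_autocorrelation = autocorr,
    glcm_cluster_prominence = cprom,
    glcm_cluster_shade = cshade,
    glcm_cluster_tendency = ctend,
    glcm_contrast = contrast,
    glcm_correlation = correl,
    glcm_difference_entropy = dent,
    glcm_difference_variance = dvar,
    glcm_dissimilarity = dissim,
    glcm_energy = energy,
    glcm_entropy = entropy,
    glcm_homogeneity = homog,
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_maximum_probability = maxprob,
    glcm_sum_average = savg,
    glcm_sum_entropy = sent,
    glcm_sum_of_squares_variance = ssvar,
    glcm_inverse_difference = invdiff)
}
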