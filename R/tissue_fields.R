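## Diffusion-tensor voxel processing: eigen-decomposition and fractional
## anisotropy, tissue QC gating, invariant tensor interpolation, helix
## (inclination) angle extraction, AHA 17-segment regionalization, and
## continuous tissue-health fields from binary infarct segmentations.

#' Diffusion-tensor voxel grid
#'
#' Container for a regular grid of symmetric 3x3 diffusion tensors.
#'
#' @param tensors numeric array, dims `c(nx, ny, nz, 6)` storing the
#'   lower-triangular components (dxx, dxy, dyy, dxz, dyz, dzz) in mm^2/s,
#'   or `c(nx, ny, nz, 3, 3)` full tensors.
#' @param spacing voxel spacing, length-3, mm (all > 0).
#' @param origin world coordinates of voxel (1,1,1) center, mm.
#' @param mask optional logical validity array `c(nx, ny, nz)`.
#' @return object of class `dt_voxel_grid`.
#' @export
dt_voxel_grid <- function(tensors, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          mask = NULL) {
  d <- dim(tensors)
  if (length(d) == 5 && all(d[4:5] == 3)) {
    full <- tensors
    asym <- max(abs(full - aperm(full, c(1, 2, 3, 5, 4))))
    if (asym > 1e-12) stop("tensors must be symmetric (max asymmetry ",
                           signif(asym, 3), ")")
    t6 <- array(0, c(d[1:3], 6))
    t6[, , , 1] <- full[, , , 1, 1]; t6[, , , 2] <- full[, , , 1, 2]
    t6[, , , 3] <- full[, , , 2, 2]; t6[, , , 4] <- full[, , , 1, 3]
    t6[, , , 5] <- full[, , , 2, 3]; t6[, , , 6] <- full[, , , 3, 3]
    tensors <- t6
    d <- dim(tensors)
  }
  if (length(d) != 4 || d[4] != 6)
    stop("tensors must be (nx, ny, nz, 6) lower-triangular or (nx, ny, nz, 3, 3)")
  if (any(spacing <= 0)) stop("spacing components must be positive")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  structure(list(tensors = tensors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), mask = mask, dim = d[1:3]),
            class = "dt_voxel_grid")
}

#' @export
print.dt_voxel_grid <- function(x, ...) {
  cat(sprintf("Diffusion-tensor grid %d x %d x %d, spacing %s mm, %d/%d valid voxels\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(signif(x$spacing, 3), collapse = " x "),
              sum(x$mask), prod(x$dim)))
  invisible(x)
}

tensor_at <- function(grid, i, j, k) {
  t6 <- grid$tensors[i, j, k, ]
  matrix(c(t6[1], t6[2], t6[4],
           t6[2], t6[3], t6[5],
           t6[4], t6[5], t6[6]), 3, 3)
}

fa_from_eigenvalues <- function(lam) {
  nl <- sqrt(sum(lam^2))
  if (nl == 0) return(0)
  sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) / nl
}

#' Eigen-decomposition and fractional anisotropy of a diffusion tensor
#'
#' Eigenvalues are returned in descending order with orthonormal
#' eigenvectors; the primary eigenvector (myofiber direction) has its sign
#' fixed to a non-negative dot product with `ref_dir`. FA is the normalized
#' eigenvalue dispersion `sqrt(3/2) ||lambda - mean|| / ||lambda||`.
#'
#' @param tensor symmetric 3x3 matrix (mm^2/s).
#' @param ref_dir reference direction for the primary eigenvector sign.
#' @return list with `values` (descending), `vectors` (columns), `fa`.
#' @export
tensor_eigen_fa <- function(tensor, ref_dir = c(1, 0, 0)) {
  if (max(abs(tensor - t(tensor))) > 1e-9 * max(1, max(abs(tensor))))
    stop("tensor must be symmetric")
  e <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)
  v <- e$vectors
  if (sum(v[, 1] * ref_dir) < 0) v[, 1] <- -v[, 1]
  if (det(v) < 0) v[, 3] <- -v[, 3]
  list(values = e$values, vectors = v, fa = fa_from_eigenvalues(e$values))
}

#' Quality-control gate for diffusion voxels
#'
#' A voxel is kept iff all eigenvalues are strictly positive and its
#' fractional anisotropy exceeds `fa_min` (default 0.12, the tissue
#' threshold separating myocardium from fat, air and voids).
#'
#' @param grid a [dt_voxel_grid()].
#' @param fa_min FA threshold.
#' @return logical validity array (also combined with the grid's own mask).
#' @export
qc_filter <- function(grid, fa_min = 0.12) {
  d <- grid$dim
  keep <- array(FALSE, d)
  t6 <- grid$tensors
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!grid$mask[i, j, k]) next
    lam <- eigen(tensor_at(grid, i, j, k), symmetric = TRUE,
                 only.values = TRUE)$values
    keep[i, j, k] <- all(lam > 0) && fa_from_eigenvalues(lam) > fa_min
  }
  keep
}

voxel_index_frac <- function(grid, x) (x - grid$origin) / grid$spacing + 1

#' Invariant interpolation of a tensor field
#'
#' Interpolates the diffusion tensor to an arbitrary world point by
#' decomposing the 8 surrounding valid voxels into invariants (the three
#' eigenvalues) and orientations (rotation quaternions), trilinearly
#' averaging each, and reassembling `R diag(lambda) R'`. Eigenvector sets
#' are sign/order aligned to the largest-weight neighbor before quaternion
#' averaging, and quaternion signs are matched to that neighbor.
#'
#' @param grid a [dt_voxel_grid()]; its `mask` marks usable voxels
#'   (typically the output of [qc_filter()]).
#' @param x world point, mm, length 3.
#' @param mask optional validity array overriding `grid$mask`.
#' @return symmetric positive-definite 3x3 tensor.
#' @export
interpolate_tensor <- function(grid, x, mask = NULL) {
  if (is.null(mask)) mask <- grid$mask
  fi <- voxel_index_frac(grid, x)
  i0 <- pmin(pmax(floor(fi), 1), grid$dim - 1)
  fr <- fi - i0
  fr <- pmin(pmax(fr, 0), 1)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  w <- apply(corners, 1, function(cc)
    prod(ifelse(cc == 1, fr, 1 - fr)))
  idx <- sweep(corners, 2, i0, "+")
  valid <- mask[idx]
  if (!any(valid)) stop("no tissue support: all 8 neighboring voxels invalid")
  w <- w * valid
  w <- w / sum(w)
  keep <- which(w > 0)
  eigs <- lapply(keep, function(m)
    tensor_eigen_fa(tensor_at(grid, idx[m, 1], idx[m, 2], idx[m, 3])))
  ref <- eigs[[which.max(w[keep])]]
  lam <- rep(0, 3); qsum <- rep(0, 4)
  for (m in seq_along(keep)) {
    e <- eigs[[m]]
    V <- e$vectors
    ## align eigenvector signs (and possible near-degenerate swaps are left
    ## to the eigenvalue ordering) to the reference frame
    for (c2 in 1:3) if (sum(V[, c2] * ref$vectors[, c2]) < 0) V[, c2] <- -V[, c2]
    if (det(V) < 0) V[, 3] <- -V[, 3]
    q <- quat_from_rotmat(V)
    qref <- quat_from_rotmat(ref$vectors)
    if (sum(q * qref) < 0) q <- -q
    wi <- w[keep[m]]
    lam <- lam + wi * e$values
    qsum <- qsum + wi * q
  }
  R <- rotmat_from_quat(qsum / sqrt(sum(qsum^2)))
  Tm <- R %*% diag(lam) %*% t(R)
  (Tm + t(Tm)) / 2
}

#' Fiber inclination (helix) angle
#'
#' Projects the fiber direction into the circumferential-longitudinal
#' tangent plane and measures its angle from the circumferential direction,
#' mapped to (-90, 90] degrees using the fiber sign ambiguity (+/- e_f are
#' equivalent). 0 deg = circumferential, +/-90 deg = longitudinal.
#'
#' @param e_f fiber direction (3-vector, need not be unit).
#' @param circ_dir,long_dir orthogonal unit vectors spanning the tangent
#'   plane.
#' @return angle in degrees, or `NA` (with attribute `undefined = TRUE`)
#'   when the in-plane projection is negligible (fiber nearly radial).
#' @export
inclination_angle <- function(e_f, circ_dir, long_dir) {
  if (abs(sum(circ_dir * long_dir)) > 1e-8)
    stop("circ_dir and long_dir must be orthogonal")
  pc <- sum(e_f * circ_dir)
  pl <- sum(e_f * long_dir)
  if (sqrt(pc^2 + pl^2) < 1e-6 * sqrt(sum(e_f^2))) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  a <- atan2(pl, pc) * 180 / pi
  ## fold antipodal fiber into (-90, 90]
  if (a > 90) a <- a - 180
  if (a <= -90) a <- a + 180
  a
}

#' AHA 17-segment assignment
#'
#' Assigns left-ventricular points to the standard 17-segment model: the
#' base-to-apex extent is split into basal, mid and apical thirds with 6,
#' 6 and 4 circumferential sectors (60/60/90 degrees) plus the apical cap
#' (region 17, the most apical ninth of the long axis). Sectors are
#' anchored so that the anterior RV insertion marks the boundary at which
#' sector 1 (anterior) starts, the standard convention.
#'
#' @param points n x 3 matrix of LV points (mm).
#' @param lv_long_axis unit vector pointing from base toward apex.
#' @param base_point a point on the basal plane (mm).
#' @param apex_point the apex (mm).
#' @param anterior_rv_insertion a point (mm) marking the anterior RV
#'   insertion; its circumferential angle defines the sector-1 boundary.
#' @param transmural optional numeric vector of transmural coordinates in
#'   \[-1, 1\] (endo -1, epi +1) carried through to the output.
#' @return data.frame with `region` (1-17), `long_frac` (0 base, 1 apex),
#'   `theta` (deg), `transmural`; points beyond the basal plane get
#'   `region = NA` and their count is reported via attribute `n_excluded`.
#' @export
aha17_assign <- function(points, lv_long_axis, base_point, apex_point,
                         anterior_rv_insertion, transmural = NA_real_) {
  points <- rbind(points)
  ax <- unit3(lv_long_axis)
  L <- sum((apex_point - base_point) * ax)
  if (!is.finite(L) || abs(L) < 1e-9) stop("degenerate base/apex landmarks")
  ## orthonormal in-plane basis; u0 anchored at the RV insertion
  ins <- anterior_rv_insertion - base_point
  ins_p <- ins - sum(ins * ax) * ax
  if (sqrt(sum(ins_p^2)) < 1e-9) stop("degenerate RV insertion landmark")
  u0 <- unit3(ins_p)
  ## angles increase counterclockwise when viewed from the base (apical view)
  v0 <- c(u0[2] * ax[3] - u0[3] * ax[2],
          u0[3] * ax[1] - u0[1] * ax[3],
          u0[1] * ax[2] - u0[2] * ax[1])
  rel <- sweep(points, 2, base_point)
  lf <- (rel %*% ax) / L
  theta <- atan2(rel %*% v0, rel %*% u0) * 180 / pi  # 0 at insertion
  theta <- (theta + 360) %% 360
  region <- rep(NA_integer_, nrow(points))
  sector6 <- function(th) as.integer(th %/% 60) + 1L   # 1..6 from insertion
  sector4 <- function(th) as.integer(((th + 45) %% 360) %/% 90) + 1L
  inside <- lf >= 0 & lf <= 1 + 1e-9
  band <- findInterval(pmin(lf, 1), c(0, 1 / 3, 2 / 3, 8 / 9), left.open = FALSE)
  for (irow in which(inside)) {
    b <- band[irow]
    region[irow] <- switch(b,
      sector6(theta[irow]),                    # basal 1-6
      6L + sector6(theta[irow]),               # mid 7-12
      12L + sector4(theta[irow]),              # apical 13-16
      17L)                                     # apical cap
  }
  out <- data.frame(region = region, long_frac = as.numeric(lf),
                    theta = as.numeric(theta),
                    transmural = rep_len(transmural, nrow(points)))
  attr(out, "n_excluded") <- sum(!inside)
  out
}

#' Transmural inclination-angle and infarct-fraction profiles
#'
#' Bins samples by AHA region and normalized transmural depth and reports
#' the per-bin mean and SD of the inclination angle plus each region's
#' infarct fraction `1 - mean(h)`.
#'
#' @param field data.frame with columns `alpha` (deg), `h` (tissue health),
#'   plus whatever [aha17_assign()] returned alongside.
#' @param map data.frame from [aha17_assign()] (same row order), with a
#'   finite `transmural` column.
#' @param n_bins number of equal-width depth bins spanning \[-1, 1\].
#' @return data.frame `region, depth_bin, depth_mid, alpha_mean, alpha_sd,
#'   n, infarct_fraction`; empty bins yield `NaN` rows with a warning.
#' @export
transmural_profile <- function(field, map, n_bins = 5) {
  stopifnot(nrow(field) == nrow(map))
  ok <- !is.na(map$region) & is.finite(field$alpha)
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(map$transmural, breaks, all.inside = TRUE),
                   1), n_bins)
  regs <- sort(unique(map$region[ok]))
  rows <- list()
  empties <- 0L
  for (r in regs) {
    in_r <- ok & map$region == r
    infarct <- 1 - mean(field$h[in_r])
    for (bidx in seq_len(n_bins)) {
      sel <- in_r & bin == bidx
      n <- sum(sel)
      if (n == 0) empties <- empties + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, depth_bin = bidx,
        depth_mid = (breaks[bidx] + breaks[bidx + 1]) / 2,
        alpha_mean = if (n) mean(field$alpha[sel]) else NaN,
        alpha_sd = if (n > 1) stats::sd(field$alpha[sel]) else NaN,
        n = n, infarct_fraction = infarct)
    }
  }
  if (empties) warning(empties, " empty region/depth bin(s) reported as NaN")
  do.call(rbind, rows)
}

#' Continuous tissue-health field from a binary infarct segmentation
#'
#' Trilinearly interpolates a binary health grid (1 = healthy, 0 = infarct)
#' to arbitrary target points, producing a continuous h-field whose values
#' lie strictly between 0 and 1 only in the border zone (within one voxel
#' of the infarct boundary).
#'
#' @param binary_grid list with `values` (0/1 array), `spacing`, `origin`
#'   (as in [dt_voxel_grid()]), or a `dt_voxel_grid`-like object carrying a
#'   `values` array.
#' @param target_points n x 3 matrix of world points (mm).
#' @return numeric vector of h values in \[0, 1\]; points outside the grid
#'   fall back to the nearest voxel with a warning.
#' @export
health_field_from_segmentation <- function(binary_grid, target_points) {
  v <- binary_grid$values
  d <- dim(v)
  target_points <- rbind(target_points)
  out <- numeric(nrow(target_points))
  clamped <- 0L
  for (r in seq_len(nrow(target_points))) {
    fi <- (target_points[r, ] - binary_grid$origin) / binary_grid$spacing + 1
    if (any(fi < 1) || any(fi > d)) clamped <- clamped + 1L
    fi <- pmin(pmax(fi, 1), d)
    i0 <- pmin(pmax(floor(fi), 1), d - 1)
    fr <- fi - i0
    acc <- 0
    for (ci in 0:1) for (cj in 0:1) for (ck in 0:1) {
      w <- prod(ifelse(c(ci, cj, ck) == 1, fr, 1 - fr))
      acc <- acc + w * v[i0[1] + ci, i0[2] + cj, i0[3] + ck]
    }
    out[r] <- acc
  }
  if (clamped) warning(clamped, " point(s) outside the grid; ",
                       "nearest-voxel fallback used")
  pmin(pmax(out, 0), 1)
}
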