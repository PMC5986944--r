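## Seeded synthetic-data generators emulating every input class the
## pipeline consumes: diffusion-tensor voxel grids with a transmural fiber
## rule, binary infarct segmentations, six-mode shear curves, analytic
## ventricular motion sequences, and hemodynamic target sets. Every
## generator is deterministic per seed and returns ground truth alongside
## the data, so downstream tests never depend on the generator's internal
## choices.

#' Phantom specification for the synthetic generators
#'
#' @param a_endo,c_endo,a_epi,c_epi,z_base wall geometry, mm (matching
#'   [ventricle_geometry()] semantics; defaults give a normal-sized LV).
#' @param alpha_endo,alpha_epi transmural fiber rule end points, degrees.
#' @param eigenvalues diffusion-tensor eigenvalues, mm^2/s.
#' @param noise_sd orientation noise (rotation about a random axis with
#'   this angular SD), degrees.
#' @param background_frac fraction of wall voxels replaced by isotropic
#'   background (FA below the QC gate by construction).
#' @param spacing voxel spacing, mm.
#' @param infarct_center,infarct_radii ellipsoidal infarct blob, mm (NULL
#'   for none).
#' @param torsion_deg,long_shortening,circ_shortening,wall_thickening
#'   motion amplitudes: apex-to-base twist (degrees) and fractional
#'   shortenings at end systole.
#' @param n_frames frames per motion sequence.
#' @param seed mandatory RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(a_endo = 14, c_endo = 28, a_epi = 23, c_epi = 46,
                         z_base = 9.8, alpha_endo = 60, alpha_epi = -60,
                         eigenvalues = c(1.0, 0.7, 0.5) * 1e-3,
                         noise_sd = 5, background_frac = 0.1,
                         spacing = c(2, 2, 2),
                         infarct_center = NULL, infarct_radii = NULL,
                         torsion_deg = 0, long_shortening = 0.15,
                         circ_shortening = 0.15, wall_thickening = 0,
                         n_frames = 11, seed) {
  if (missing(seed)) stop("a seed is mandatory for every synthetic generator")
  stopifnot(background_frac >= 0, background_frac <= 1,
            long_shortening < 1, circ_shortening < 1)
  structure(as.list(environment()), class = "phantom_spec")
}

## transmural shell coordinate s in [0, 1] of points relative to the
## phantom's similar-ellipsoid wall (s < 0 inside cavity, s > 1 outside)
shell_coordinate <- function(spec, pts) {
  pts <- rbind(pts)
  e <- spec$c_endo / spec$a_endo
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2 + (pts[, 3] / e)^2)
  (r - spec$a_endo) / (spec$a_epi - spec$a_endo)
}

## local circumferential / longitudinal / radial directions on the
## similar-ellipsoid family (cartesian), plus the rule-based fiber vector
phantom_frame <- function(spec, pts) {
  pts <- rbind(pts)
  e <- spec$c_endo / spec$a_endo
  n <- nrow(pts)
  rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  phi <- atan2(pts[, 2], pts[, 1])
  e_c <- cbind(-sin(phi), cos(phi), rep(0, n))
  ## meridional tangent of the shell through the point
  zy <- pts[, 3] / e
  rY <- sqrt(rho^2 + zy^2)
  mu <- zy / rY
  sq <- sqrt(pmax(1 - mu^2, 1e-12))
  tr <- -mu / sq * rep(1, n); tz <- rep(e, n)
  tn <- sqrt(tr^2 + tz^2)
  e_l <- cbind((tr / tn) * cos(phi), (tr / tn) * sin(phi), tz / tn)
  e_r <- cbind(e_l[, 3] * cos(phi) - 0, e_l[, 3] * sin(phi),
               -(tr / tn) * 0)  # replaced below
  ## radial = e_c x e_l
  e_r <- cbind(e_c[, 2] * e_l[, 3] - e_c[, 3] * e_l[, 2],
               e_c[, 3] * e_l[, 1] - e_c[, 1] * e_l[, 3],
               e_c[, 1] * e_l[, 2] - e_c[, 2] * e_l[, 1])
  s <- shell_coordinate(spec, pts)
  alpha <- spec$alpha_endo + pmin(pmax(s, 0), 1) *
    (spec$alpha_epi - spec$alpha_endo)
  ar <- alpha * pi / 180
  e_f <- cos(ar) * e_c + sin(ar) * e_l
  list(e_c = e_c, e_l = e_l, e_r = e_r, e_f = e_f, alpha = alpha, s = s,
       mu = mu)
}

rotation_about_axis <- function(axis, angle_rad) {
  a <- unit3(axis)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * K %*% K
}

#' Generate a synthetic diffusion-tensor voxel grid
#'
#' Wall voxels carry tensors whose primary eigenvector follows the
#' transmural inclination-angle rule (plus seeded orientation noise);
#' secondary/tertiary eigenvectors are the radial and remaining directions.
#' A seeded fraction of wall voxels is replaced by isotropic background
#' (FA = 0, removed by the QC gate), and voxels outside the wall are
#' isotropic background as well. Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `grid` (a [dt_voxel_grid()]), `truth` (data.frame of
#'   wall voxel centers, rule angles, transmural coordinate, background
#'   flag), and `spec`.
#' @export
gen_dt_grid <- function(spec) {
  set.seed(spec$seed)
  sp <- spec$spacing
  lim <- c(spec$a_epi + 2 * sp[1], spec$a_epi + 2 * sp[2],
           spec$c_epi + 2 * sp[3])
  nx <- ceiling(2 * lim[1] / sp[1]); ny <- ceiling(2 * lim[2] / sp[2])
  nz <- ceiling(2 * lim[3] / sp[3])
  origin <- -c(nx - 1, ny - 1, nz - 1) / 2 * sp
  xs <- origin[1] + (seq_len(nx) - 1) * sp[1]
  ys <- origin[2] + (seq_len(ny) - 1) * sp[2]
  zs <- origin[3] + (seq_len(nz) - 1) * sp[3]
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  s <- shell_coordinate(spec, pts)
  in_wall <- s >= 0 & s <= 1 & pts[, 3] <= spec$z_base
  t6 <- array(0, c(nx, ny, nz, 6))
  iso <- mean(spec$eigenvalues)
  ## everything starts isotropic background
  t6[, , , 1] <- iso; t6[, , , 3] <- iso; t6[, , , 6] <- iso
  widx <- which(in_wall)
  bg <- rep(FALSE, length(widx))
  if (spec$background_frac > 0)
    bg[sample.int(length(widx), round(spec$background_frac * length(widx)))] <- TRUE
  fr <- phantom_frame(spec, pts[widx, , drop = FALSE])
  lam <- spec$eigenvalues
  truth <- data.frame(x = pts[widx, 1], y = pts[widx, 2], z = pts[widx, 3],
                      alpha = fr$alpha, s = fr$s, background = bg)
  dims <- c(nx, ny, nz)
  sub <- arrayInd(widx, dims)
  for (m in seq_along(widx)) {
    if (bg[m]) next
    R <- cbind(fr$e_f[m, ], fr$e_r[m, ], 0)
    R[, 3] <- c(R[2, 1] * R[3, 2] - R[3, 1] * R[2, 2],
                R[3, 1] * R[1, 2] - R[1, 1] * R[3, 2],
                R[1, 1] * R[2, 2] - R[2, 1] * R[1, 2])
    if (spec$noise_sd > 0) {
      ax <- stats::rnorm(3)
      ang <- stats::rnorm(1, 0, spec$noise_sd * pi / 180)
      R <- rotation_about_axis(ax, ang) %*% R
    }
    Tm <- R %*% diag(lam) %*% t(R)
    i <- sub[m, 1]; j <- sub[m, 2]; k <- sub[m, 3]
    t6[i, j, k, ] <- c(Tm[1, 1], Tm[1, 2], Tm[2, 2], Tm[1, 3], Tm[2, 3],
                       Tm[3, 3])
  }
  grid <- dt_voxel_grid(t6, spacing = sp, origin = origin)
  list(grid = grid, truth = truth, spec = spec)
}

#' Generate a binary infarct segmentation
#'
#' Ellipsoidal infarct blob rasterized on the phantom grid (0 = infarct,
#' 1 = healthy), with ground-truth continuous h values at arbitrary points
#' computed by the same trilinear rule used by
#' [health_field_from_segmentation()].
#'
#' @param spec a [phantom_spec()] with `infarct_center` and
#'   `infarct_radii` set (the blob must intersect the wall).
#' @return list with `binary_grid` (list: `values`, `spacing`, `origin`),
#'   `h_at` (function of points), `blob_volume_ml`, `spec`.
#' @export
gen_infarct <- function(spec) {
  if (is.null(spec$infarct_center) || is.null(spec$infarct_radii))
    stop("phantom_spec must define infarct_center and infarct_radii")
  sc <- shell_coordinate(spec, spec$infarct_center)
  if (sc < 0 || sc > 1)
    stop("infarct blob center must lie inside the wall")
  sp <- spec$spacing
  lim <- c(spec$a_epi + 2 * sp[1], spec$a_epi + 2 * sp[2],
           spec$c_epi + 2 * sp[3])
  nx <- ceiling(2 * lim[1] / sp[1]); ny <- ceiling(2 * lim[2] / sp[2])
  nz <- ceiling(2 * lim[3] / sp[3])
  origin <- -c(nx - 1, ny - 1, nz - 1) / 2 * sp
  xs <- origin[1] + (seq_len(nx) - 1) * sp[1]
  ys <- origin[2] + (seq_len(ny) - 1) * sp[2]
  zs <- origin[3] + (seq_len(nz) - 1) * sp[3]
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  d2 <- ((pts[, 1] - spec$infarct_center[1]) / spec$infarct_radii[1])^2 +
    ((pts[, 2] - spec$infarct_center[2]) / spec$infarct_radii[2])^2 +
    ((pts[, 3] - spec$infarct_center[3]) / spec$infarct_radii[3])^2
  values <- array(1, c(nx, ny, nz))
  values[d2 <= 1] <- 0
  bg <- list(values = values, spacing = sp, origin = origin)
  list(binary_grid = bg,
       h_at = function(points) health_field_from_segmentation(bg, points),
       blob_volume_ml = sum(values == 0) * prod(sp) / 1000,
       spec = spec)
}

#' Generate six-mode simple-shear curves
#'
#' Forward curves from [simple_shear_curve()] with seeded multiplicative
#' Gaussian noise, standing in for tri-axial shear experiments on
#' myocardial cubes (shear range 0 to 0.5).
#'
#' @param params a [passive_params()] (ground truth).
#' @param gammas shear grid in `[0, 0.5]`.
#' @param noise_sd multiplicative noise SD (0 = noiseless).
#' @param seed RNG seed.
#' @return a [shear_dataset()] with attribute `truth = params`.
#' @export
gen_shear_data <- function(params = passive_params(),
                           gammas = seq(0.025, 0.5, length.out = 20),
                           noise_sd = 0, seed = 1) {
  if (any(gammas < 0 | gammas > 0.5)) stop("gamma grid must lie in [0, 0.5]")
  set.seed(seed)
  out <- do.call(rbind, lapply(SHEAR_MODES, function(m) {
    st <- simple_shear_curve(m, gammas, params)
    if (noise_sd > 0) st <- st * (1 + stats::rnorm(length(st), 0, noise_sd))
    data.frame(mode = m, gamma = gammas, stress_kpa = st)
  }))
  out <- shear_dataset(out)
  attr(out, "truth") <- params
  out
}

## analytic endocardial motion: circumferential shortening, base-anchored
## long-axis shortening, linear apex twist, ramped over frames
motion_map <- function(spec, g) {
  cs <- spec$circ_shortening * g
  ls <- spec$long_shortening * g
  tw <- spec$torsion_deg * pi / 180 * g
  zb <- spec$z_base
  ctot <- spec$c_endo + zb  # base-to-apex extent along z
  function(v) {
    lf <- (zb - v[, 3]) / ctot                 # 0 base .. 1 apex
    rho <- sqrt(v[, 1]^2 + v[, 2]^2) * (1 - cs)
    phi <- atan2(v[, 2], v[, 1]) + tw * lf
    z <- zb - (zb - v[, 3]) * (1 - ls)
    cbind(rho * cos(phi), rho * sin(phi), z)
  }
}

#' Generate an analytic endocardial motion sequence
#'
#' Ellipsoidal endocardial surface deformed by prescribed circumferential
#' shortening, base-anchored long-axis shortening and linear apex twist,
#' ramped from 0 at ED to the full amplitudes at ES (last frame) with a
#' smooth half-cosine time course. Ground-truth per-segment engineering
#' strains are computed from dense arc-length quadrature of the analytic
#' map (independent of the spline machinery under test).
#'
#' @param spec a [phantom_spec()].
#' @param n_long,n_phi surface mesh resolution.
#' @return list with `sequence` (a [surface_sequence()]), `truth_es`
#'   (ground-truth per-segment circumferential/longitudinal ES strains and
#'   GLS/GCS), `spec`.
#' @export
gen_motion_sequence <- function(spec, n_long = 36, n_phi = 72) {
  set.seed(spec$seed)
  nf <- spec$n_frames
  zb <- spec$z_base
  a <- spec$a_endo; c_ <- spec$c_endo
  u <- min(zb / c_, 1)
  mu <- seq(u, -1, length.out = n_long + 1)[-(n_long + 1)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  base <- NULL
  for (m in mu)
    base <- rbind(base, cbind(a * sqrt(1 - m^2) * cos(phi),
                              a * sqrt(1 - m^2) * sin(phi), c_ * m))
  base <- rbind(base, c(0, 0, -c_))
  nv <- nrow(base)
  tri <- NULL
  vid <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  for (i in seq_len(n_long - 1L)) for (j in seq_len(n_phi))
    tri <- rbind(tri,
                 c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                 c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  for (j in seq_len(n_phi))
    tri <- rbind(tri, c(vid(n_long, j), nv, vid(n_long, j + 1L)))
  verts <- array(0, c(nv, 3, nf))
  ramp <- (1 - cos(pi * (seq_len(nf) - 1) / (nf - 1))) / 2
  for (f in seq_len(nf)) verts[, , f] <- motion_map(spec, ramp[f])(base)
  sq <- surface_sequence(verts, tri, ed_frame = 1, es_frame = nf,
                         apex_point = c(0, 0, -c_),
                         base_point = c(0, 0, zb),
                         long_axis = c(0, 0, -1),
                         ref_direction = c(1, 0, 0))
  ## ground truth at ES by dense analytic arc length per segment
  truth <- gen_motion_truth(spec, n_dense = 400)
  list(sequence = sq, truth_es = truth, spec = spec)
}

## dense-quadrature ES strains of the analytic motion, per 16-segment layout
gen_motion_truth <- function(spec, n_dense = 400) {
  zb <- spec$z_base; a <- spec$a_endo; c_ <- spec$c_endo
  u <- min(zb / c_, 1)
  fmap <- motion_map(spec, 1)
  ctot <- c_ + zb
  lf_to_z <- function(lf) zb - lf * ctot
  arc <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))
  rho_of_z <- function(z) a * sqrt(pmax(1 - (z / c_)^2, 0))
  seg_rows <- list()
  bands <- rbind(c(0, 1 / 3), c(1 / 3, 2 / 3), c(2 / 3, 1))
  nsect <- c(6, 6, 4)
  sid <- 0
  for (b in 1:3) {
    for (k in seq_len(nsect[b])) {
      sid <- sid + 1
      th <- (c(k - 1, k) / nsect[b]) * 2 * pi
      lf <- bands[b, ]
      ## longitudinal line at mid-theta
      lfs <- seq(lf[1], min(lf[2], 0.999), length.out = n_dense)
      zs <- lf_to_z(lfs)
      thm <- mean(th)
      ptsL <- cbind(rho_of_z(zs) * cos(thm), rho_of_z(zs) * sin(thm), zs)
      ## circumferential line at mid-lf
      ths <- seq(th[1], th[2], length.out = n_dense)
      zm <- lf_to_z(mean(lf))
      ptsC <- cbind(rho_of_z(zm) * cos(ths), rho_of_z(zm) * sin(ths),
                    rep(zm, n_dense))
      l0 <- arc(ptsL); c0 <- arc(ptsC)
      l1 <- arc(fmap(ptsL)); c1 <- arc(fmap(ptsC))
      seg_rows[[sid]] <- data.frame(
        segment = sid,
        long_strain_pct = 100 * (l1 - l0) / l0,
        circ_strain_pct = 100 * (c1 - c0) / c0)
    }
  }
  out <- do.call(rbind, seg_rows)
  out$gls <- mean(out$long_strain_pct)
  out$gcs <- mean(out$circ_strain_pct)
  out
}

#' Hemodynamic target profiles
#'
#' Printed subject targets: the normal profile (EDV 57.8 ml, SV 30.9 ml,
#' EF 53.4%, RV EDP 4 mmHg) and the heart-failure profile (EDV 103.0 ml,
#' SV 33.0 ml, EF 32.0%, RV EDP 8 mmHg). LV end-diastolic pressures are
#' documented package assumptions (10 / 20 mmHg; the failing subject's EDP
#' was roughly double the normal one's), flagged via `edp_assumed`.
#'
#' @param profile `"normal"` or `"heart_failure"`.
#' @return object of class `hemo_targets`: list with `EDV`, `EDP`, `SV`,
#'   `ESV`, `EF`, `LVLS_target`, `RV_EDP`, `V0`, `edp_assumed`.
#' @export
gen_targets <- function(profile = c("normal", "heart_failure")) {
  profile <- match.arg(profile)
  out <- if (profile == "normal") {
    list(profile = profile, EDV = 57.8, SV = 30.9, EF = 0.534,
         EDP = 10, RV_EDP = 4, V0 = 17.5, LVLS_target = 15,
         edp_assumed = TRUE)
  } else {
    list(profile = profile, EDV = 103.0, SV = 33.0, EF = 0.320,
         EDP = 20, RV_EDP = 8, V0 = 47.1, LVLS_target = 15,
         edp_assumed = TRUE)
  }
  out$ESV <- out$EDV - out$SV
  stopifnot(abs(out$SV / out$EDV - out$EF) < 0.01)
  structure(out, class = "hemo_targets")
}

#' @export
print.hemo_targets <- function(x, ...) {
  cat(sprintf("%s targets: EDV %.1f ml, SV %.1f ml (EF %.1f%%), ESV %.1f ml\n",
              x$profile, x$EDV, x$SV, 100 * x$EF, x$ESV))
  cat(sprintf("  LV EDP %g mmHg%s, RV EDP %g mmHg, V0 %.1f ml\n",
              x$EDP, if (x$edp_assumed) " (assumed)" else "", x$RV_EDP, x$V0))
  invisible(x)
}
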