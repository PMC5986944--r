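## Reduced-order mechanical ventricle: a thick-walled truncated prolate
## ellipsoid with a transmural fiber rule and two kinematic degrees of
## freedom (cavity volume V, long-axis stretch lambda_L). The endocardial
## and epicardial surfaces are geometrically similar ellipsoids (common
## long-to-short axis ratio e), so a fixed axial scaling maps the wall onto
## a spherical shell. The deformation is the composition of (i) the
## classical incompressible thick-sphere inflation r'^3 = r^3 + k in that
## spherical frame and (ii) an isochoric global long-axis stretch
## diag(1/sqrt(lamL), 1/sqrt(lamL), lamL). The map is exactly
## volume-preserving pointwise (J = 1 everywhere), injective at any
## inflation, and reduces to the classical thick-sphere solution in the
## spherical degenerate case. Cavity pressure and the equilibrium long-axis
## stretch follow from virtual work of the total (passive + active) stress
## over the wall quadrature.

## truncated-ellipsoid cap "shape" factor: volume = pi a^2 c g(u),
## u = z_base / c in (-1, 1]
cap_g <- function(u) 2 / 3 + u - u^3 / 3

#' Build a reduced-order ventricle geometry
#'
#' Thick-walled truncated prolate ellipsoid: endocardial and epicardial
#' surfaces are geometrically similar ellipsoids (`c_endo/a_endo` must equal
#' `c_epi/a_epi`; the kinematic family requires it) truncated by a common
#' basal plane at height `z_base` above the center (`z_base >= c_epi` gives
#' closed ellipsoids, the spherical degenerate case). Wall quadrature uses
#' Gauss-Legendre points in the transmural coordinate `s` (0 = endo,
#' 1 = epi) and the normalized long-axis coordinate `mu = z / c(s)`, with
#' `n_phi` circumferential stations (1 suffices for axisymmetric tissue;
#' use more when an infarct breaks axisymmetry).
#'
#' @param a_endo,c_endo endocardial semi-minor/semi-major axes, mm.
#' @param a_epi,c_epi epicardial semi-minor/semi-major axes, mm.
#' @param z_base basal truncation height above center, mm.
#' @param fiber_angles length-2 vector `c(alpha_endo, alpha_epi)` in
#'   degrees for the default linear transmural fiber rule, or a function
#'   `alpha(s)` returning degrees.
#' @param h_fun tissue-health field: scalar, or function `h(s, mu, phi)`
#'   returning values in \[0,1\] (1 healthy).
#' @param n_trans,n_long,n_phi quadrature resolution (transmural x
#'   longitudinal Gauss points x circumferential stations).
#' @return object of class `ventricle_geometry` with unloaded cavity volume
#'   `V0` (ml), wall volume (ml), and precomputed quadrature tables.
#' @export
ventricle_geometry <- function(a_endo, c_endo, a_epi, c_epi, z_base,
                               fiber_angles = c(60, -60), h_fun = 1,
                               n_trans = 5, n_long = 8, n_phi = 1) {
  if (any(c(a_endo, c_endo, a_epi, c_epi) <= 0)) stop("axes must be positive")
  if (!(a_epi > a_endo && c_epi > c_endo))
    stop("epicardial axes must exceed endocardial axes (non-nested surfaces)")
  e <- c_endo / a_endo
  if (abs(c_epi / a_epi - e) > 1e-6)
    stop("endo and epi surfaces must be geometrically similar ",
         "(c_endo/a_endo == c_epi/a_epi); the kinematic family requires it")
  if (z_base <= -0.9 * c_endo)
    stop("basal plane must lie above the apex region")
  alpha_fun <- if (is.function(fiber_angles)) fiber_angles else
    function(s) fiber_angles[1] + s * (fiber_angles[2] - fiber_angles[1])
  hf <- if (is.function(h_fun)) h_fun else {
    hv <- h_fun
    function(s, mu, phi) rep(hv, length(s))
  }

  gs <- gauss_legendre(n_trans, 0, 1)
  gm <- gauss_legendre(n_long, -1, 1)   # mapped per shell below

  tab <- expand.grid(is = seq_len(n_trans), im = seq_len(n_long),
                     ip = seq_len(n_phi))
  s <- gs$x[tab$is]
  R <- a_endo + s * (a_epi - a_endo)   # spherical-frame shell radius = a(s)
  R_s <- a_epi - a_endo
  ## truncation latitude mu = z/c(s); clamp to 1 when the shell is closed
  u <- pmin(z_base / (e * R), 1)
  half <- (u + 1) / 2
  mu <- -1 + half * (gm$x[tab$im] + 1)
  wmu <- gm$w[tab$im] * half
  ws <- gs$w[tab$is]
  phi <- 2 * pi * (tab$ip - 0.5) / n_phi
  wphi <- 2 * pi / n_phi

  ## reference volume element: dV_X = e dV_Y = e R^2 R_s ds dmu dphi
  w <- e * R^2 * R_s * ws * wmu * wphi

  V0 <- e * pi * a_endo^3 * cap_g(min(z_base / c_endo, 1))
  V_epi <- e * pi * a_epi^3 * cap_g(min(z_base / c_epi, 1))
  wall_analytic <- V_epi - V0
  if (abs(sum(w) - wall_analytic) > 5e-3 * wall_analytic)
    stop("quadrature weights deviate from the analytic wall volume by > 0.5%")

  ## local frame in the cylindrical (rho, phi, z) basis at the reference
  ## point X = (a(s) sqrt(1-mu^2), z = c(s) mu), a = R, c = e R
  sq <- sqrt(pmax(1 - mu^2, 1e-14))
  rho0 <- R * sq
  Tr <- -R * mu / sq; Tz <- e * R        # meridional tangent (toward base)
  Tn <- sqrt(Tr^2 + Tz^2)
  e_l <- cbind(Tr / Tn, rep(0, length(s)), Tz / Tn)
  e_c <- cbind(rep(0, length(s)), rep(1, length(s)), rep(0, length(s)))
  e_r <- cbind(e_l[, 3], rep(0, length(s)), -e_l[, 1])  # e_c x e_l, outward
  alpha <- alpha_fun(s)
  ar <- alpha * pi / 180
  f0 <- cos(ar) * e_c + sin(ar) * e_l
  s0 <- e_r
  h <- hf(s, mu, phi)
  if (any(h < 0 | h > 1)) stop("h_fun must return values in [0, 1]")

  structure(list(
    a_endo = a_endo, c_endo = c_endo, a_epi = a_epi, c_epi = c_epi,
    z_base = z_base, e = e, V0 = V0 / 1000, wall_volume = wall_analytic / 1000,
    alpha_fun = alpha_fun, h_fun = hf,
    n_trans = n_trans, n_long = n_long, n_phi = n_phi,
    q = list(s = s, mu = mu, phi = phi, w = w, R = R, R_s = R_s, sq = sq,
             rho0 = rho0, f0 = f0, s0 = s0, e_l = e_l, e_r = e_r,
             alpha = alpha, h = h)),
    class = "ventricle_geometry")
}

#' @export
print.ventricle_geometry <- function(x, ...) {
  cat(sprintf(paste0("Truncated-ellipsoid ventricle: endo %.1f x %.1f mm, ",
                     "epi %.1f x %.1f mm, base at %.1f mm\n"),
              x$a_endo, x$c_endo, x$a_epi, x$c_epi, x$z_base))
  cat(sprintf("  V0 = %.2f ml, wall volume = %.2f ml, quadrature %d x %d x %d\n",
              x$V0, x$wall_volume, x$n_trans, x$n_long, x$n_phi))
  invisible(x)
}

#' Preset left/right ventricle geometries
#'
#' Convenience constructors matched to the unloaded cavity volumes used in
#' the subject profiles (`V0` = 17.5 ml normal, 47.1 ml heart failure for
#' the LV). Shape ratios (long axis twice the short axis, basal truncation
#' at 70% of the short-axis radius above center, 9 mm equatorial wall for
#' the LV, a 6 mm wall and 0.7 x LV `V0` for the RV — sized so both
#' chambers deliver matched stroke outputs in the closed loop) are package
#' defaults.
#'
#' @param profile `"normal"` or `"heart_failure"`.
#' @param chamber `"lv"` or `"rv"`.
#' @param ... passed to [ventricle_geometry()] (e.g. `h_fun`, `n_phi`).
#' @return a `ventricle_geometry`.
#' @export
preset_geometry <- function(profile = c("normal", "heart_failure"),
                            chamber = c("lv", "rv"), ...) {
  profile <- match.arg(profile)
  chamber <- match.arg(chamber)
  v0_lv <- c(normal = 17.5, heart_failure = 47.1)[[profile]]
  v0 <- if (chamber == "lv") v0_lv else 0.7 * v0_lv
  e <- 2
  ## solve a_endo for the cavity volume at fixed shape ratios
  a <- (v0 * 1000 / (e * pi * cap_g(0.35)))^(1 / 3)
  th <- if (chamber == "lv") 9 else 6
  ventricle_geometry(a_endo = a, c_endo = e * a, a_epi = a + th,
                     c_epi = e * (a + th), z_base = 0.35 * e * a, ...)
}

#' Per-point deformation gradients of the reduced kinematics
#'
#' Maps the wall quadrature points of a [ventricle_geometry()] to the
#' deformed configuration for a cavity volume `V` and long-axis stretch
#' `lamL`: the incompressible thick-sphere map `r'^3 = r^3 + k` (with
#' `k = a_endo^3 (V/V0 - 1)` in the spherical frame) composed with the
#' isochoric long-axis stretch. The deformation gradient is exactly
#' volume-preserving (`J = 1` pointwise, reported as a round-off
#' diagnostic), and the enclosed volume of every transmural shell is
#' conserved exactly.
#'
#' @param geom a `ventricle_geometry`.
#' @param V cavity volume, ml.
#' @param lamL long-axis stretch (dimensionless, > 0).
#' @return list with `F` (n x 9 row-wise deformation gradients in the local
#'   cylindrical basis), `J` (pointwise volume ratio), `t` (per-point
#'   spherical-frame scale factors).
#' @export
kinematic_deformation <- function(geom, V, lamL) {
  kin <- kin_with_derivs(geom, V, lamL)
  list(F = kin$F, J = m3_det(kin$F), t = kin$t)
}

## kinematics plus analytic derivatives of F with respect to lamL and V.
## F = D(lamL) %*% K where D = diag(1/sqrt(lamL), 1/sqrt(lamL), lamL) and K
## depends on V only, so dF/dlamL is a row rescaling of F; dF/dV follows
## from d(r'^3)/dV = a_endo^3/V0.
kin_with_derivs <- function(geom, V, lamL) {
  if (V <= 0 || lamL <= 0) stop("V and lamL must be positive")
  q <- geom$q
  k <- geom$a_endo^3 * (V / geom$V0 - 1)
  r3 <- q$R^3 + k
  if (any(r3 <= 0)) stop("shell inversion: cavity volume too small for the wall")
  rp <- r3^(1 / 3)
  tt <- rp / q$R
  dr <- (q$R / rp)^2
  nr <- q$sq; nz <- q$mu
  d <- dr - tt
  Fs11 <- tt + d * nr * nr
  Fs12 <- d * nr * nz
  Fs22 <- tt + d * nz * nz
  sl <- 1 / sqrt(lamL)
  n <- length(q$R)
  Fm <- matrix(0, n, 9L)
  Fm[, 1L] <- sl * Fs11
  Fm[, 3L] <- sl * Fs12 / geom$e
  Fm[, 7L] <- lamL * geom$e * Fs12
  Fm[, 9L] <- lamL * Fs22
  Fm[, 5L] <- sl * tt

  ## dF/dlamL: rows 1-2 scale 1/sqrt(lamL), row 3 scales lamL
  dFl <- matrix(0, n, 9L)
  dFl[, c(1L, 3L, 5L)] <- -Fm[, c(1L, 3L, 5L)] / (2 * lamL)
  dFl[, c(7L, 9L)] <- Fm[, c(7L, 9L)] / lamL

  ## dF/dV (per ml): dk/dV = a_endo^3/V0, dr'/dk = 1/(3 r'^2)
  dk <- geom$a_endo^3 / geom$V0
  dtt <- dk / (3 * rp^2 * q$R)
  ddr <- -2 * q$R^2 / (3 * rp^5) * dk
  dd <- ddr - dtt
  dFv <- matrix(0, n, 9L)
  dFv[, 1L] <- sl * (dtt + dd * nr * nr)
  dFv[, 3L] <- sl * dd * nr * nz / geom$e
  dFv[, 7L] <- lamL * geom$e * dd * nr * nz
  dFv[, 9L] <- lamL * (dtt + dd * nz * nz)
  dFv[, 5L] <- sl * dtt
  list(F = Fm, dFl = dFl, dFv = dFv, t = tt)
}

## generalized internal forces conjugate to lamL and V:
## G_q = sum w * (J sigma F^-T) : dF/dq  (kPa mm^3 per unit q; G_V in kPa)
generalized_forces <- function(geom, V, lamL, params, active = NULL, t = 0) {
  q <- geom$q
  kin <- kin_with_derivs(geom, V, lamL)
  Fm <- kin$F
  Ta <- 0; n_s <- 0
  if (!is.null(active)) {
    fdef <- m3_vec(Fm, q$f0)
    I4f <- rowSums(fdef * fdef)   # |F f0|^2
    l <- active$lR * sqrt(I4f)
    Ta <- active_tension(t, l, q$h, active, warn_short = FALSE)
    n_s <- active$n_s
  }
  pk <- pk1_kernel(Fm, q$f0, q$s0, params, h = q$h, Ta = Ta, n_s = n_s)
  wp <- q$w
  list(lamL = sum(wp * m3_ddot(pk$P1, kin$dFl)),
       V = sum(wp * m3_ddot(pk$P1, kin$dFv)) / 1000,
       J = pk$J)
}

#' Equilibrium cavity pressure of the reduced ventricle
#'
#' At fixed cavity volume, solves the generalized-force balance
#' `dW_int/dlamL = 0` for the long-axis stretch (virtual work of the total
#' stress over the wall), then evaluates the cavity pressure as the
#' work-conjugate `P = dW_int/dV`. With `V = V0` and no active tension the
#' pressure is zero.
#'
#' @param geom a `ventricle_geometry`.
#' @param V cavity volume, ml.
#' @param material a [passive_params()].
#' @param active optional [active_params()]; when given, active tension at
#'   cycle time `t` is included.
#' @param t time since cycle start, ms.
#' @param lamL_init warm start for the long-axis stretch root solve.
#' @return list with `P` (mmHg), `lamL`, `long_axis` (deformed endocardial
#'   base-to-apex length, mm), `J_range` (pointwise volume-ratio range,
#'   identically 1 up to round-off for this kinematic family).
#' @export
equilibrium_pressure <- function(geom, V, material, active = NULL, t = 0,
                                 lamL_init = 1, slope_init = NULL) {
  last <- NULL
  res <- function(l) {
    last <<- generalized_forces(geom, V, l, material, active, t)
    last$lamL_at <- l
    last$lamL
  }
  scale0 <- max(abs(material$a * material$A) * geom$wall_volume * 1000, 1)
  sol <- solve_lamL(res, lamL_init, tol_f = 1e-4 * scale0,
                    slope = slope_init)
  lam <- sol$root
  gf <- if (!is.null(last) && identical(last$lamL_at, lam)) last else
    generalized_forces(geom, V, lam, material, active, t)
  ## deformed endocardial base-to-apex length
  t_endo <- (V / geom$V0)^(1 / 3)
  u0 <- min(geom$z_base / geom$c_endo, 1)
  long_axis <- lam * t_endo * geom$c_endo * (1 + u0)
  list(P = kpa_to_mmhg(gf$V), lamL = lam, long_axis = long_axis,
       J_range = range(gf$J), slope = sol$slope)
}

## robust 1-D root solve with warm start: Newton from a carried-over slope
## when available, secant otherwise, falling back to bracket expansion +
## uniroot; errors with residual history on failure. Returns the root and
## the latest slope estimate so callers can warm-start the next solve.
solve_lamL <- function(res, l0, tol_f, tol_x = 1e-8,
                       lower = 0.4, upper = 2.0, slope = NULL) {
  hist <- NULL
  f0 <- res(l0); hist <- rbind(hist, c(l0, f0))
  if (abs(f0) <= tol_f) return(list(root = l0, slope = slope))
  if (!is.null(slope) && is.finite(slope) && slope != 0 &&
      abs(f0 / slope) < 0.05) {
    l1 <- l0 - f0 / slope
  } else {
    l1 <- l0 * (1 + if (f0 > 0) -2e-4 else 2e-4)
  }
  f1 <- res(l1); hist <- rbind(hist, c(l1, f1))
  for (it in 1:40) {
    sl <- (f1 - f0) / (l1 - l0)
    if (abs(f1) <= tol_f) return(list(root = l1, slope = sl))
    if (f1 == f0) break
    step <- -f1 / sl
    step <- sign(step) * min(abs(step), 0.1)  # damp long extrapolations
    l2 <- l1 + step
    if (!is.finite(l2) || l2 <= lower || l2 >= upper) break
    l0 <- l1; f0 <- f1; l1 <- l2
    f1 <- res(l1); hist <- rbind(hist, c(l1, f1))
    if (abs(l1 - l0) < tol_x && abs(f1) < 1e3 * tol_f)
      return(list(root = l1, slope = (f1 - f0) / (l1 - l0)))
  }
  lb <- hist[which.min(abs(hist[, 2])), 1]
  for (half in c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8)) {
    lo <- max(lower, lb - half); hi <- min(upper, lb + half)
    flo <- res(lo); fhi <- res(hi)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0) {
      r <- stats::uniroot(res, c(lo, hi), f.lower = flo, f.upper = fhi,
                          tol = tol_x)
      return(list(root = r$root,
                  slope = (fhi - flo) / max(hi - lo, 1e-12)))
    }
  }
  stop("long-axis equilibrium did not converge; residual history:\n",
       paste(utils::capture.output(print(hist)), collapse = "\n"))
}

#' Passive inflation curve
#'
#' Quasistatic passive pressure-volume relation of the ventricle over an
#' increasing volume grid starting at the unloaded volume `V0` (where the
#' pressure is zero). This is the forward model of the passive-scaling
#' calibration.
#'
#' @param geom a `ventricle_geometry`.
#' @param material a [passive_params()].
#' @param V_grid increasing cavity volumes, ml, starting at `geom$V0`.
#' @return data.frame with columns `V` (ml), `P` (mmHg), `lamL`.
#' @export
passive_inflation_curve <- function(geom, material, V_grid) {
  if (is.unsorted(V_grid, strictly = TRUE))
    stop("V_grid must be strictly increasing")
  if (abs(V_grid[1] - geom$V0) > 1e-6 * geom$V0)
    stop("V_grid must start at the unloaded volume V0")
  lam <- 1
  out <- data.frame(V = V_grid, P = NA_real_, lamL = NA_real_)
  for (i in seq_along(V_grid)) {
    eq <- equilibrium_pressure(geom, V_grid[i], material, lamL_init = lam)
    lam <- eq$lamL
    out$P[i] <- eq$P
    out$lamL[i] <- lam
  }
  out
}

#' Left-ventricular long-axis shortening
#'
#' `LVLS = 100 (L_ED - L_ES) / L_ED` from a history of long-axis lengths
#' (any quantity proportional to length, e.g. the long-axis stretch).
#' Elongation at end systole yields a negative value.
#'
#' @param lengths numeric history of long-axis lengths (or stretches).
#' @param ed,es indices of the end-diastolic and end-systolic entries.
#' @return percent shortening.
#' @export
lvls <- function(lengths, ed = 1L, es = which.min(lengths)) {
  if (length(lengths) == 0 || is.na(ed) || is.na(es) ||
      ed > length(lengths) || es > length(lengths))
    stop("missing ED/ES phase markers")
  100 * (lengths[ed] - lengths[es]) / lengths[ed]
}

#' Deformed surface mesh of the reduced ventricle
#'
#' Triangulated endocardial or epicardial surface in the deformed
#' configuration, for cavity-volume checks, strain mapping and VTK export.
#'
#' @param geom a `ventricle_geometry`.
#' @param V cavity volume, ml.
#' @param lamL long-axis stretch.
#' @param surface `"endo"` or `"epi"`.
#' @param n_long,n_phi mesh resolution (longitudinal rings x sectors).
#' @return list with `vertices` (n x 3, mm), `triangles` (m x 3 indices),
#'   `apex` (row index of the apex vertex), `base_ring` (indices).
#' @export
deformed_surface <- function(geom, V, lamL, surface = c("endo", "epi"),
                             n_long = 24, n_phi = 48) {
  surface <- match.arg(surface)
  R <- if (surface == "endo") geom$a_endo else geom$a_epi
  k <- geom$a_endo^3 * (V / geom$V0 - 1)
  tt <- ((R^3 + k) / R^3)^(1 / 3)
  ap <- tt * R / sqrt(lamL)
  cp <- lamL * geom$e * tt * R
  u <- min(geom$z_base / (geom$e * R), 1)
  mu <- seq(u, -1, length.out = n_long + 1)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  verts <- NULL
  for (i in seq_len(n_long)) {   # rings, excluding the apex point
    m <- mu[i]
    verts <- rbind(verts, cbind(ap * sqrt(1 - m^2) * cos(phi),
                                ap * sqrt(1 - m^2) * sin(phi), cp * m))
  }
  verts <- rbind(verts, c(0, 0, -cp))
  napex <- nrow(verts)
  tri <- NULL
  vid <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  for (i in seq_len(n_long - 1L)) for (j in seq_len(n_phi)) {
    tri <- rbind(tri,
                 c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                 c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  }
  for (j in seq_len(n_phi))
    tri <- rbind(tri, c(vid(n_long, j), napex, vid(n_long, j + 1L)))
  list(vertices = verts, triangles = tri, apex = napex,
       base_ring = seq_len(n_phi))
}

## signed volume enclosed by a triangulated cap surface plus the planar
## basal closure (divergence theorem); independent check of cavity volume
mesh_cavity_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  vol <- 0
  for (r in seq_len(nrow(tr))) {
    p1 <- v[tr[r, 1], ]; p2 <- v[tr[r, 2], ]; p3 <- v[tr[r, 3], ]
    vol <- vol + det(rbind(p1, p2, p3)) / 6
  }
  ring <- v[mesh$base_ring, , drop = FALSE]
  cen <- colMeans(ring)
  nb <- nrow(ring)
  for (j in seq_len(nb)) {
    p1 <- ring[j, ]; p2 <- ring[(j %% nb) + 1L, ]
    vol <- vol + det(rbind(cen, p1, p2)) / 6
  }
  abs(vol) / 1000  # ml
}
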