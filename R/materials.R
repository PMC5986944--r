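## Passive orthotropic myocardium (Holzapfel-Ogden type) with continuous
## infarct homogenization, volumetric penalty, and a time-varying elastance
## active tension law.  Stress is assembled per material point from the
## deformation gradient and a local fiber/sheet/normal frame.

#' Passive orthotropic material parameters
#'
#' Constructs the parameter set of the orthotropic hyperelastic strain
#' energy used for passive myocardium: an isotropic exponential term
#' (`a`, `b`), fiber and sheet terms (`a_f`, `b_f`, `a_s`, `b_s`), a
#' fiber-sheet coupling term (`a_fs`, `b_fs`), a volumetric penalty modulus
#' `D`, and three homogenization/scaling constants: `A` (scalar multiplier
#' on all a-type terms), `B` (multiplier on all b-type terms) and `p`, the
#' pathological stiffness ratio of fully infarcted to healthy tissue.
#'
#' Defaults are the calibrated human-shear parameter set used throughout the
#' package, with `p = 4.56` (ratio of late-stage infarct to remote tissue
#' stiffness) and `D = 0.2` per MPa (bulk modulus `2/D` = 10 MPa).
#'
#' @param a,a_f,a_s,a_fs linear (stress-like) coefficients, kPa.
#' @param b,b_f,b_s,b_fs dimensionless exponential coefficients.
#' @param D volumetric penalty parameter, 1/MPa. Values outside (0.02, 20)
#'   raise a warning (outside the validated incompressibility range).
#' @param A dimensionless scalar multiplier applied to all a-type terms.
#' @param B dimensionless multiplier applied to all b-type terms.
#' @param p dimensionless pathological stiffness ratio (>= 1).
#' @param isochoric_split logical; apply the `J^(-2/3)` isochoric split to
#'   the isotropic invariant I1 (the anisotropic invariants are always
#'   unsplit, avoiding spurious fiber response under volume change).
#' @param tension_only logical; anisotropic I4 terms contribute only when
#'   the corresponding direction is in tension (I4 > 1).
#' @return object of class `passive_params`.
#' @export
passive_params <- function(a = 1.05, b = 7.542, a_f = 3.465, b_f = 14.472,
                           a_s = 0.481, b_s = 12.548, a_fs = 0.283,
                           b_fs = 3.088, D = 0.2, A = 1, B = 1, p = 4.56,
                           isochoric_split = TRUE, tension_only = TRUE) {
  vals <- c(a = a, b = b, a_f = a_f, b_f = b_f, a_s = a_s, b_s = b_s,
            a_fs = a_fs, b_fs = b_fs)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all a-type and b-type coefficients must be strictly positive")
  if (!is.finite(p) || p < 1) stop("pathological ratio p must be >= 1")
  if (A <= 0 || B <= 0) stop("scaling multipliers A and B must be positive")
  if (D <= 0) stop("volumetric parameter D must be positive")
  if (D <= 0.02 || D >= 20)
    warning("D = ", D, " per MPa is outside the validated range (0.02, 20)")
  structure(list(a = a, b = b, a_f = a_f, b_f = b_f, a_s = a_s, b_s = b_s,
                 a_fs = a_fs, b_fs = b_fs, D = D, A = A, B = B, p = p,
                 isochoric_split = isochoric_split,
                 tension_only = tension_only),
            class = "passive_params")
}

#' @export
print.passive_params <- function(x, ...) {
  cat("Passive orthotropic myocardium parameters (kPa)\n")
  cat(sprintf("  a    = %-8.4g b    = %-8.4g\n", x$a, x$b))
  cat(sprintf("  a_f  = %-8.4g b_f  = %-8.4g\n", x$a_f, x$b_f))
  cat(sprintf("  a_s  = %-8.4g b_s  = %-8.4g\n", x$a_s, x$b_s))
  cat(sprintf("  a_fs = %-8.4g b_fs = %-8.4g\n", x$a_fs, x$b_fs))
  cat(sprintf("  D = %g /MPa  A = %g  B = %g  p = %g\n", x$D, x$A, x$B, x$p))
  invisible(x)
}

#' Local fiber frame
#'
#' Orthonormal right-handed triad of fiber, sheet and sheet-normal unit
#' vectors at a material point.
#'
#' @param e_f,e_s,e_n unit 3-vectors. `e_n` defaults to `e_f x e_s`.
#' @return object of class `local_frame`.
#' @export
local_frame <- function(e_f, e_s, e_n = NULL) {
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  if (abs(sqrt(sum(e_f^2)) - 1) > 1e-9 || abs(sqrt(sum(e_s^2)) - 1) > 1e-9)
    stop("frame vectors must be unit length")
  if (abs(sum(e_f * e_s)) > 1e-9)
    stop("frame vectors must be pairwise orthogonal")
  if (is.null(e_n)) e_n <- cross(e_f, e_s)
  if (abs(sqrt(sum(e_n^2)) - 1) > 1e-9)
    stop("frame vectors must be unit length")
  if (abs(sum(e_f * e_n)) > 1e-9 || abs(sum(e_s * e_n)) > 1e-9)
    stop("frame vectors must be pairwise orthogonal")
  if (sum(cross(e_f, e_s) * e_n) <= 0)
    stop("frame must be right-handed (e_f x e_s . e_n > 0)")
  structure(list(e_f = e_f, e_s = e_s, e_n = e_n), class = "local_frame")
}

#' Kinematic state at a material point
#'
#' Wraps a deformation gradient `F` and derives the volume ratio
#' `J = det F` and the invariants I1, I4f, I4s and I8fs with respect to a
#' local frame.
#'
#' @param F 3x3 deformation gradient (dimensionless).
#' @param frame a [local_frame()].
#' @return object of class `deformation_state` with fields `F`, `J`, `I1`,
#'   `I4f`, `I4s`, `I8fs`.
#' @export
deformation_state <- function(F, frame) {
  if (!all(is.finite(F))) stop("deformation gradient contains non-finite entries")
  J <- det(F)
  if (J <= 0) stop("det F must be positive (J = ", signif(J, 4), ")")
  C <- t(F) %*% F
  f0 <- frame$e_f; s0 <- frame$e_s
  structure(list(F = F, J = J, C = C,
                 I1 = sum(diag(C)),
                 I4f = drop(f0 %*% C %*% f0),
                 I4s = drop(s0 %*% C %*% s0),
                 I8fs = drop(f0 %*% C %*% s0)),
            class = "deformation_state")
}

#' Homogenize passive stiffness coefficients with tissue health
#'
#' Effective a-type coefficients at a material point of health `h` (1 =
#' healthy, 0 = infarct): `a_bar_i = a_i * A * (h + (1 - h) p)`.  The
#' coefficient transitions linearly between the healthy value (h = 1) and
#' `p` times the healthy value (h = 0).
#'
#' @param params a [passive_params()].
#' @param h tissue health scalar (or vector) in \[0, 1\].
#' @return list with `a`, `a_f`, `a_s`, `a_fs` (effective, kPa, subject
#'   scaling `A` applied) and `b`, `b_f`, `b_s`, `b_fs` (with `B` applied).
#' @export
homogenize_params <- function(params, h) {
  if (any(!is.finite(h)) || any(h < 0) || any(h > 1))
    stop("tissue health h must lie in [0, 1]")
  fac <- params$A * (h + (1 - h) * params$p)
  list(a = params$a * fac, a_f = params$a_f * fac, a_s = params$a_s * fac,
       a_fs = params$a_fs * fac,
       b = params$b * params$B, b_f = params$b_f * params$B,
       b_s = params$b_s * params$B, b_fs = params$b_fs * params$B)
}

## guard against overflowing exponentials; surfaces pathological parameters
check_exponent <- function(x, term) {
  if (any(x > 700))
    stop("exponent overflow in ", term, " term (argument > 700); ",
         "check material parameters / deformation magnitude")
  x
}

#' Isochoric strain energy density
#'
#' Orthotropic exponential strain energy at a material point, using the
#' homogenized coefficients: isotropic I1 term plus tension-only fiber and
#' sheet I4 terms plus the fiber-sheet coupling I8 term. Units kPa.
#'
#' @param state a [deformation_state()].
#' @param frame a [local_frame()] (already encoded in `state` invariants;
#'   accepted for interface symmetry).
#' @param params a [passive_params()].
#' @param h tissue health in \[0,1\].
#' @return energy density, kPa.
#' @export
isochoric_energy <- function(state, frame, params, h = 1) {
  eff <- homogenize_params(params, h)
  I1 <- if (params$isochoric_split) state$J^(-2 / 3) * state$I1 else state$I1
  e1 <- check_exponent(eff$b * (I1 - 3), "isotropic I1")
  W <- eff$a / (2 * eff$b) * exp(e1)
  for (d in c("f", "s")) {
    I4 <- state[[paste0("I4", d)]]
    if (!params$tension_only || I4 > 1) {
      ai <- eff[[paste0("a_", d)]]; bi <- eff[[paste0("b_", d)]]
      e4 <- check_exponent(bi * (I4 - 1)^2, paste0("I4", d))
      W <- W + ai / (2 * bi) * (exp(e4) - 1)
    }
  }
  e8 <- check_exponent(eff$b_fs * state$I8fs^2, "I8fs")
  W + eff$a_fs / (2 * eff$b_fs) * (exp(e8) - 1)
}

#' Volumetric penalty energy
#'
#' `(1/D) ((J^2 - 1)/2 - ln J)`, zero and stationary at J = 1; `D` carries
#' units 1/MPa so the energy is returned in kPa (factor 1000).
#'
#' @param J volume ratio, > 0.
#' @param D volumetric parameter, 1/MPa.
#' @return energy density, kPa.
#' @export
volumetric_energy <- function(J, D) {
  if (any(J <= 0)) stop("J must be positive")
  if (D <= 0) stop("D must be positive")
  1000 / D * ((J^2 - 1) / 2 - log(J))
}

## ---- vectorized stress kernels -----------------------------------------
## Fm: n x 9 deformation gradients; f0, s0: n x 3 reference directions;
## h: length-n health. second_pk assembles the passive second Piola stress
## S = 2 dPsi/dC (kPa); stress_kernel pushes it to Cauchy stress and adds
## active tension; pk1_kernel returns the nominal stress P1 = F S (plus
## active parts) used in the ventricle virtual-work quadrature.

second_pk <- function(Fm, f0, s0, params, h = 1) {
  n <- nrow(Fm)
  eff <- homogenize_params(params, h)
  J <- m3_det(Fm)
  if (any(!is.finite(J)) || any(J <= 0)) stop("invalid deformation: J <= 0")
  ## invariants from pushed-forward directions: I1 = |F|_F^2, I4 = |F a0|^2
  fdef <- m3_vec(Fm, f0)
  sdef <- m3_vec(Fm, s0)
  I1 <- rowSums(Fm * Fm)
  I4f <- rowSums(fdef * fdef)
  I4s <- rowSums(sdef * sdef)
  I8 <- rowSums(fdef * sdef)

  if (params$isochoric_split) {
    C <- m3_mult(m3_t(Fm), Fm)
    Cinv <- m3_inv(C)
    I1b <- J^(-2 / 3) * I1
    psi1 <- eff$a / 2 * exp(check_exponent(eff$b * (I1b - 3), "isotropic I1"))
    ## S_iso1 = 2 psi1 J^(-2/3) (I - I1/3 Cinv)
    S <- 2 * psi1 * J^(-2 / 3) * (m3_identity(n) - (I1 / 3) * Cinv)
  } else {
    Cinv <- NULL
    psi1 <- eff$a / 2 * exp(check_exponent(eff$b * (I1 - 3), "isotropic I1"))
    S <- 2 * psi1 * m3_identity(n)
  }

  g4f <- I4f - 1; g4s <- I4s - 1
  on_f <- if (params$tension_only) as.numeric(g4f > 0) else 1
  on_s <- if (params$tension_only) as.numeric(g4s > 0) else 1
  psi4f <- on_f * eff$a_f * g4f * exp(check_exponent(eff$b_f * g4f^2, "I4f"))
  psi4s <- on_s * eff$a_s * g4s * exp(check_exponent(eff$b_s * g4s^2, "I4s"))
  psi8 <- eff$a_fs * I8 * exp(check_exponent(eff$b_fs * I8^2, "I8fs"))
  S <- S + 2 * psi4f * m3_outer(f0, f0) + 2 * psi4s * m3_outer(s0, s0) +
    psi8 * (m3_outer(f0, s0) + m3_outer(s0, f0))

  ## volumetric: S_vol = Psi'(J) J Cinv, Psi'(J) = (1000/D)(J - 1/J) kPa;
  ## vanishes identically at J = 1 so Cinv is only needed when J != 1
  pvol <- (1000 / params$D) * (J - 1 / J) * J
  if (any(pvol != 0)) {
    if (is.null(Cinv)) Cinv <- m3_inv(m3_mult(m3_t(Fm), Fm))
    S <- S + pvol * Cinv
  }
  list(S = S, J = J, I4f = I4f, I4s = I4s, fdef = fdef, sdef = sdef)
}

## Cauchy stress (n x 9, kPa), symmetric
stress_kernel <- function(Fm, f0, s0, params, h = 1, Ta = 0, n_s = 0) {
  n <- nrow(Fm)
  if (length(Ta) == 1L) Ta <- rep(Ta, n)
  pk <- second_pk(Fm, f0, s0, params, h)
  sig <- m3_mult(Fm, m3_mult(pk$S, m3_t(Fm))) / pk$J
  if (any(Ta != 0)) {
    ## push forward and renormalize fiber/sheet directions
    fdef <- m3_vec(Fm, f0); fdef <- fdef / sqrt(rowSums(fdef^2))
    sig <- sig + Ta * m3_outer(fdef, fdef)
    if (n_s != 0) {
      sdef <- m3_vec(Fm, s0); sdef <- sdef / sqrt(rowSums(sdef^2))
      sig <- sig + n_s * Ta * m3_outer(sdef, sdef)
    }
  }
  ## symmetrize (kills rounding asymmetry)
  (sig + m3_t(sig)) / 2
}

## nominal (first Piola) stress P1 = J sigma F^-T = F S + active terms;
## the active Cauchy stress Ta f x f pushes back to J Ta / I4 (F f0) x f0
pk1_kernel <- function(Fm, f0, s0, params, h = 1, Ta = 0, n_s = 0) {
  pk <- second_pk(Fm, f0, s0, params, h)
  P1 <- m3_mult(Fm, pk$S)
  if (any(Ta != 0)) {
    P1 <- P1 + (pk$J * Ta / pk$I4f) * m3_outer(pk$fdef, f0)
    if (n_s != 0)
      P1 <- P1 + (pk$J * n_s * Ta / pk$I4s) * m3_outer(pk$sdef, s0)
  }
  list(P1 = P1, J = pk$J, I4f = pk$I4f)
}

#' Passive Cauchy stress
#'
#' Analytic push-forward of the isochoric plus volumetric strain energy:
#' `sigma = (1/J) F S F'` with `S = 2 dPsi/dC`. Symmetric, exactly zero at
#' `F = I`, and objective.
#'
#' @param state a [deformation_state()] or a 3x3 deformation gradient.
#' @param frame a [local_frame()].
#' @param params a [passive_params()].
#' @param h tissue health in \[0,1\].
#' @return symmetric 3x3 Cauchy stress, kPa.
#' @export
passive_cauchy_stress <- function(state, frame, params, h = 1) {
  F <- if (inherits(state, "deformation_state")) state$F else state
  if (!all(is.finite(F))) stop("non-finite deformation gradient")
  sig <- stress_kernel(m3_from_mat(F), matrix(frame$e_f, 1), matrix(frame$e_s, 1),
                       params, h = h)
  matrix(sig, 3, 3, byrow = TRUE)
}

#' Active contraction parameters (time-varying elastance law)
#'
#' Parameters of the active tension law
#' `Ta(t, l) = Tmax * Ca0^2 / (Ca0^2 + ECa50(l)^2) * (1 - cos(omega(t, l)))/2 * h`
#' with length-dependent calcium sensitivity
#' `ECa50(l) = Ca0max / sqrt(exp(B_len (l - l0)) - 1)` and activation phase
#' `omega = pi t/t0` during contraction (`0 <= t < t0`), descending through
#' relaxation of duration `t_r = m_slope l + b_intercept`, zero otherwise.
#' Sarcomere length follows fiber stretch: `l = lR sqrt(I4f)`.
#'
#' Calcium and length constants are literature defaults for mammalian
#' myocardium; timing constants are package defaults sized so a full
#' twitch fits the 480 ms active phase. All are overridable.
#'
#' @param Tmax peak active tension, kPa.
#' @param Ca0,Ca0max calcium concentrations, uM.
#' @param B_len length-sensitivity constant, 1/um.
#' @param l0 sarcomere length below which no tension develops, um.
#' @param lR unloaded (reference) sarcomere length, um.
#' @param t0 time to peak tension, ms.
#' @param m_slope,b_intercept linear relaxation-duration law, ms/um and ms.
#' @param n_s fraction of active tension transferred to the sheet
#'   direction, dimensionless in \[0,1\].
#' @param period cardiac cycle length, ms (the time argument is taken
#'   modulo this).
#' @return object of class `active_params`.
#' @export
active_params <- function(Tmax = 118, Ca0 = 4.35, Ca0max = 4.35,
                          B_len = 4.75, l0 = 1.58, lR = 1.85, t0 = 220,
                          m_slope = 80, b_intercept = 50, n_s = 0.07,
                          period = 780) {
  if (Tmax < 0) stop("Tmax must be non-negative")
  if (n_s < 0 || n_s > 1) stop("n_s must lie in [0, 1]")
  if (!(lR > l0 && l0 > 0)) stop("need lR > l0 > 0")
  structure(list(Tmax = Tmax, Ca0 = Ca0, Ca0max = Ca0max, B_len = B_len,
                 l0 = l0, lR = lR, t0 = t0, m_slope = m_slope,
                 b_intercept = b_intercept, n_s = n_s, period = period),
            class = "active_params")
}

#' @export
print.active_params <- function(x, ...) {
  cat(sprintf("Active tension law: Tmax = %g kPa, n_s = %g\n", x$Tmax, x$n_s))
  cat(sprintf("  Ca0 = %g uM, Ca0max = %g uM, B = %g /um, l0 = %g um, lR = %g um\n",
              x$Ca0, x$Ca0max, x$B_len, x$l0, x$lR))
  cat(sprintf("  t0 = %g ms, t_r = %g l + %g ms, period = %g ms\n",
              x$t0, x$m_slope, x$b_intercept, x$period))
  invisible(x)
}

#' Active tension at a material point
#'
#' Time-varying elastance active tension, scaled by tissue health so fully
#' infarcted tissue (`h = 0`) develops no force. Vectorized over `t`, `l`
#' and `h`.
#'
#' @param t time since cycle start, ms (taken modulo the cycle period).
#' @param l sarcomere length, um. Lengths at or below `l0` yield zero
#'   tension with a warning (calcium sensitivity undefined there).
#' @param h tissue health in \[0,1\].
#' @param ap an [active_params()].
#' @param warn_short warn on l <= l0 (default TRUE; internal callers
#'   suppress during transient compressive states).
#' @return active tension Ta, kPa, in `[0, Tmax * h]`.
#' @export
active_tension <- function(t, l, h = 1, ap = active_params(),
                           warn_short = TRUE) {
  n <- max(length(t), length(l), length(h))
  t <- rep_len(t, n); l <- rep_len(l, n); h <- rep_len(h, n)
  if (any(t < 0)) stop("t must be non-negative")
  if (any(h < 0 | h > 1)) stop("tissue health h must lie in [0, 1]")
  short <- l <= ap$l0
  if (any(short) && warn_short)
    warning("sarcomere length at or below l0 at ", sum(short),
            " point(s); returning zero tension there")
  tm <- t %% ap$period
  tr <- ap$m_slope * l + ap$b_intercept
  omega <- ifelse(tm < ap$t0, pi * tm / ap$t0,
                  ifelse(tm < ap$t0 + tr, pi * (tm - ap$t0 + tr) / tr, 0))
  ## omega = 0 outside the activation window (1 - cos 0 = 0)
  omega[tm >= ap$t0 + tr] <- 0
  eca <- rep(Inf, n)
  ok <- !short
  eca[ok] <- ap$Ca0max / sqrt(exp(ap$B_len * (l[ok] - ap$l0)) - 1)
  ta <- ap$Tmax * ap$Ca0^2 / (ap$Ca0^2 + eca^2) * (1 - cos(omega)) / 2 * h
  ta[short] <- 0
  ta
}

#' Total Cauchy stress (passive + active)
#'
#' Adds active tension along the deformed (pushed-forward, renormalized)
#' fiber direction and a fraction `n_s` along the deformed sheet direction
#' to the passive stress.
#'
#' @inheritParams passive_cauchy_stress
#' @param Ta active tension, kPa (>= 0).
#' @param n_s sheet-direction active fraction in \[0,1\].
#' @return symmetric 3x3 Cauchy stress, kPa.
#' @export
total_stress <- function(state, frame, params, h = 1, Ta = 0, n_s = 0) {
  if (Ta < 0) stop("active tension Ta must be non-negative")
  F <- if (inherits(state, "deformation_state")) state$F else state
  sig <- stress_kernel(m3_from_mat(F), matrix(frame$e_f, 1),
                       matrix(frame$e_s, 1), params, h = h, Ta = Ta, n_s = n_s)
  matrix(sig, 3, 3, byrow = TRUE)
}

SHEAR_MODES <- c("fs", "fn", "sf", "sn", "nf", "ns")

#' Six-mode simple-shear stress response
#'
#' Simple shear in mode `"ij"`: the faces with normal `e_i` are translated
#' along `e_j`, i.e. `F = I + gamma e_j (x) e_i`, and the work-conjugate
#' shear component `sigma_ij` of the Cauchy stress is reported. This is the
#' convention of the tri-axial myocardium shear experiments the calibration
#' targets; note that the opposite ("ij = displacement plane") convention
#' also appears in the literature.
#'
#' @param mode one of `"fs"`, `"fn"`, `"sf"`, `"sn"`, `"nf"`, `"ns"`.
#' @param gammas numeric vector of shear amounts, |gamma| <= 0.6.
#' @param params a [passive_params()].
#' @param h tissue health in \[0,1\].
#' @return numeric vector of shear stresses (kPa), one per gamma; odd in
#'   gamma and zero at gamma = 0.
#' @export
simple_shear_curve <- function(mode, gammas, params, h = 1) {
  if (!mode %in% SHEAR_MODES)
    stop("unknown shear mode '", mode, "'; valid modes: ",
         paste(SHEAR_MODES, collapse = ", "))
  if (any(abs(gammas) > 0.6)) stop("|gamma| must be <= 0.6")
  ax <- c(f = 1L, s = 2L, n = 3L)
  i <- ax[[substr(mode, 1, 1)]]  # face normal
  j <- ax[[substr(mode, 2, 2)]]  # displacement direction
  n <- length(gammas)
  Fm <- m3_identity(n)
  Fm[, m3_idx(j, i)] <- Fm[, m3_idx(j, i)] + gammas
  f0 <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  s0 <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  sig <- stress_kernel(Fm, f0, s0, params, h = h)
  sig[, m3_idx(i, j)]
}
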