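test_that("homogenization is the prescribed linear blend of healthy and scar stiffness", {
  pp <- ref_params()
  eff1 <- homogenize_params(pp, 1)
  expect_identical(eff1$a, pp$a)
  expect_identical(eff1$a_fs, pp$a_fs)
  eff0 <- homogenize_params(pp, 0)
  expect_equal(eff0$a / eff1$a, 4.56)
  expect_equal(eff0$a_s, pp$a_s * 4.56)
  ## linear midpoint, a_i = 2 kPa, p = 4.56
  expect_equal(homogenize_params(passive_params(a = 2), 0.5)$a, 5.56)
  ## affine in h
  h <- seq(0, 1, by = 0.1)
  eff <- homogenize_params(pp, h)
  expect_equal(diff(eff$a_f, differences = 2), rep(0, length(h) - 2),
               tolerance = 1e-12)
  ## subject scaling A applies uniformly; B scales exponents
  ppA <- ref_params(A = 2.5, B = 0.7)
  expect_equal(homogenize_params(ppA, 0.3)$a,
               2.5 * homogenize_params(pp, 0.3)$a)
  expect_equal(homogenize_params(ppA, 1)$b_f, 0.7 * pp$b_f)
  expect_error(homogenize_params(pp, 1.2), "\\[0, 1\\]")
  expect_error(homogenize_params(pp, -0.1), "\\[0, 1\\]")
})

test_that("parameter constructors validate their domains", {
  expect_error(passive_params(a = -1), "positive")
  expect_error(passive_params(p = 0.5), "p must be")
  expect_warning(passive_params(D = 0.01), "outside the validated range")
  expect_error(active_params(n_s = 1.2), "n_s")
  expect_error(active_params(l0 = 2, lR = 1.8), "lR > l0")
  expect_error(local_frame(c(1, 0, 0), c(1, 1, 0) / sqrt(2)), "orthogonal")
  expect_error(local_frame(c(1, 0, 0), c(0.5, 0.5, 0)), "unit length")
  expect_error(local_frame(c(1, 0, 0), c(0, 1, 0), c(0, 0, -1)),
               "right-handed")
})

test_that("volumetric energy is zero and stationary at J = 1 with bulk modulus 2/D", {
  expect_identical(volumetric_energy(1, 0.2), 0)
  d <- 1e-6
  expect_lt(abs(volumetric_energy(1 + d, 0.2) - volumetric_energy(1 - d, 0.2)) /
              (2 * d), 1e-4)
  ## direct scalar evaluation: 5 MPa * ((1.21-1)/2 - ln 1.1) = 48.449 kPa
  expect_equal(volumetric_energy(1.1, 0.2), 48.4491009783757, tolerance = 1e-12)
  ## numeric curvature at J = 1 equals the bulk modulus 2/D = 10 MPa
  dd <- 1e-4
  curv <- (volumetric_energy(1 + dd, 0.2) - 2 * volumetric_energy(1, 0.2) +
             volumetric_energy(1 - dd, 0.2)) / dd^2
  expect_equal(curv, 10000, tolerance = 1e-4)  # kPa
  expect_error(volumetric_energy(-0.5, 0.2), "positive")
  expect_error(volumetric_energy(1, -1), "positive")
})

test_that("isochoric energy matches closed-form values and the tension-only switch", {
  pp <- ref_params()
  fr <- std_frame()
  st <- deformation_state(diag(3), fr)
  expect_equal(st$I1, 3)
  expect_equal(st$I4f, 1)
  expect_equal(st$I4s, 1)
  expect_equal(st$I8fs, 0)
  expect_equal(isochoric_energy(st, fr, pp), pp$a / (2 * pp$b))
  ## uniaxial fiber compression: fiber term contributes nothing
  Fc <- diag(c(0.9, 1 / sqrt(0.9), 1 / sqrt(0.9)))
  e1 <- isochoric_energy(deformation_state(Fc, fr), fr, pp)
  pp_nofiber <- ref_params(a_f = 1e-9)
  e2 <- isochoric_energy(deformation_state(Fc, fr), fr, pp_nofiber)
  expect_equal(e1, e2, tolerance = 1e-12)
  ## fs simple shear gamma = 0.1: frozen independent symbolic evaluation
  Ffs <- diag(3); Ffs[2, 1] <- 0.1
  expect_equal(isochoric_energy(deformation_state(Ffs, fr), fr, pp),
               0.07667368256318057, tolerance = 1e-12)
  expect_error(deformation_state(matrix(c(1, NA, 0, 0, 1, 0, 0, 0, 1), 3), fr),
               "non-finite")
})

test_that("exponential overflow is caught with the offending term named", {
  pp <- ref_params(b_f = 90)
  fr <- std_frame()
  F <- diag(c(2.4, 1, 1 / 2.4))
  expect_error(passive_cauchy_stress(F, fr, pp), "I4f")
})

test_that("passive stress is zero at the reference and matches energy finite differences", {
  pp <- ref_params()
  fr <- std_frame()
  expect_identical(passive_cauchy_stress(diag(3), fr, pp),
                   matrix(0, 3, 3))
  set.seed(11)
  worst <- 0
  for (k in 1:100) {
    F <- random_F()
    sig <- passive_cauchy_stress(F, fr, pp)
    expect_equal(sig, t(sig), tolerance = 1e-12)
    d <- 1e-6
    P1 <- matrix(0, 3, 3)
    for (m in 1:9) {
      e <- numeric(9); e[m] <- d
      P1[m] <- (total_energy(matrix(as.numeric(F) + e, 3, 3), fr, pp) -
                  total_energy(matrix(as.numeric(F) - e, 3, 3), fr, pp)) / (2 * d)
    }
    sig_fd <- P1 %*% t(F) / det(F)
    worst <- max(worst, max(abs(sig - sig_fd)) / max(abs(sig)))
  }
  expect_lt(worst, 1e-6)
})

test_that("passive stress is objective under rotations", {
  pp <- ref_params()
  fr <- std_frame()
  set.seed(21)
  F <- random_F()
  sig <- passive_cauchy_stress(F, fr, pp)
  for (k in 1:100) {
    Q <- cardiomech:::random_rotation()
    expect_equal(passive_cauchy_stress(Q %*% F, fr, pp),
                 Q %*% sig %*% t(Q), tolerance = 1e-8)
  }
})

test_that("active tension follows the elastance law, scaled by tissue health", {
  ap <- active_params()
  expect_identical(active_tension(100, 2.0, h = 0, ap), 0)
  expect_identical(active_tension(0, 2.0, h = 1, ap), 0)   # omega = 0
  ## peak at t = t0: bracket equals 1 (cos pi = -1)
  l <- 2.0
  eca <- ap$Ca0max / sqrt(exp(ap$B_len * (l - ap$l0)) - 1)
  expect_equal(active_tension(ap$t0, l, 1, ap),
               ap$Tmax * ap$Ca0^2 / (ap$Ca0^2 + eca^2))
  ## bounds over a dense grid, proportional to h
  tg <- seq(0, ap$period, by = 10)
  lg <- seq(1.7, 2.3, by = 0.1)
  for (h in c(0.3, 1)) {
    ta <- outer(tg, lg, function(t, l) active_tension(t, l, h, ap))
    expect_true(all(ta >= 0 & ta <= ap$Tmax * h + 1e-12))
  }
  expect_equal(active_tension(ap$t0, 2.1, 0.3, ap),
               0.3 * active_tension(ap$t0, 2.1, 1, ap))
  ## zero outside the activation window
  expect_identical(active_tension(ap$t0 + ap$m_slope * 2 + ap$b_intercept + 1,
                                  2.0, 1, ap), 0)
  ## short sarcomere: zero with warning
  expect_warning(ta <- active_tension(ap$t0, 1.5, 1, ap), "l0")
  expect_identical(ta, 0)
})

test_that("total stress adds active tension along the deformed fiber and sheet", {
  pp <- ref_params()
  fr <- std_frame()
  set.seed(5)
  F <- random_F()
  sp <- passive_cauchy_stress(F, fr, pp)
  expect_equal(total_stress(F, fr, pp, Ta = 0, n_s = 0.3), sp)
  ## at the reference the deformed directions are the frame axes
  s1 <- total_stress(diag(3), fr, pp, Ta = 12, n_s = 0.25)
  expect_equal(sum(diag(s1)), 12 * 1.25)
  expect_equal(s1[2, 2], 0.25 * 12)          # sheet share
  s0 <- total_stress(diag(3), fr, pp, Ta = 12, n_s = 0)
  expect_equal(s0[2, 2], 0)                  # n_s = 0: no sheet stress
  expect_error(total_stress(F, fr, pp, Ta = -1), "non-negative")
})

test_that("simple shear is odd, zero at the origin, and ordered f > s > n", {
  pp <- ref_params()
  g <- c(0.1, 0.3, 0.5)
  for (m in c("fs", "fn", "sf", "sn", "nf", "ns")) {
    expect_identical(simple_shear_curve(m, 0, pp), 0)
    expect_equal(simple_shear_curve(m, -g, pp), -simple_shear_curve(m, g, pp))
  }
  at05 <- vapply(c("fs", "fn", "sf", "sn", "nf", "ns"),
                 function(m) simple_shear_curve(m, 0.5, pp), 0)
  expect_true(min(at05[c("fs", "fn")]) > max(at05[c("sf", "sn")]))
  expect_true(min(at05[c("sf", "sn")]) > max(at05[c("nf", "ns")]))
  expect_error(simple_shear_curve("xy", 0.1, pp), "fs, fn, sf, sn, nf, ns")
  expect_error(simple_shear_curve("fs", 0.7, pp), "0.6")
})

test_that("single-point shear equals a homogeneous 27-cell assembly", {
  ## with uniform material and affine boundary displacement the deformation
  ## is spatially constant: volume-averaged cell stress equals the
  ## single-point evaluation
  pp <- ref_params()
  gam <- 0.35
  single <- simple_shear_curve("fs", gam, pp)
  F <- diag(3); F[2, 1] <- gam
  cells <- expand.grid(i = 1:3, j = 1:3, k = 1:3)  # 27 hex cell centers
  Fm <- do.call(rbind, replicate(27, as.numeric(t(F)), simplify = FALSE))
  f0 <- matrix(rep(c(1, 0, 0), each = 27), 27, 3)
  s0 <- matrix(rep(c(0, 1, 0), each = 27), 27, 3)
  sig <- cardiomech:::stress_kernel(Fm, f0, s0, pp)
  assembled <- mean(sig[, cardiomech:::m3_idx(1, 2)])
  expect_equal(assembled, single, tolerance = 1e-12)
})
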