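test_that("geometry volumes match closed forms and scaling laws", {
  g <- thick_sphere_geom(10, 14)
  expect_equal(g$V0, 4 / 3 * pi * 1000 / 1000, tolerance = 1e-12)
  ## quadrature weights integrate the wall volume
  expect_equal(sum(g$q$w) / 1000, g$wall_volume, tolerance = 5e-3)
  lv <- small_lv()
  expect_equal(sum(lv$q$w) / 1000, lv$wall_volume, tolerance = 5e-3)
  expect_equal(lv$V0, 17.5, tolerance = 1e-9)
  ## doubling all lengths multiplies V0 by 8
  lv2 <- ventricle_geometry(2 * lv$a_endo, 2 * lv$c_endo, 2 * lv$a_epi,
                            2 * lv$c_epi, 2 * lv$z_base)
  expect_equal(lv2$V0, 8 * lv$V0, tolerance = 1e-9)
  expect_error(ventricle_geometry(10, 20, 9, 18, 5), "non-nested")
  expect_error(ventricle_geometry(10, 20, 13, 20.1, 5), "similar")
})

test_that("kinematics reduce to identity at the reference and the thick-sphere map", {
  lv <- small_lv()
  kin <- kinematic_deformation(lv, lv$V0, 1)
  expect_equal(max(abs(kin$F - cardiomech:::m3_identity(nrow(kin$F)))), 0)
  ## spherical degenerate case: classical incompressible inflation
  g <- thick_sphere_geom(10, 14)
  V <- g$V0 * 1.8
  kin <- kinematic_deformation(g, V, 1)
  q <- g$q
  a3 <- 10^3 + (V - g$V0) * 1000 * 3 / (4 * pi)
  r <- (q$R^3 + (a3 - 10^3))^(1 / 3)
  for (i in seq(1, length(q$R), by = 7)) {
    Fi <- matrix(kin$F[i, ], 3, 3, byrow = TRUE)
    expect_equal(as.numeric(Fi %*% q$e_r[i, ]), (q$R[i] / r[i])^2 * q$e_r[i, ],
                 tolerance = 1e-12)
    expect_equal(as.numeric(Fi %*% q$e_l[i, ]), (r[i] / q$R[i]) * q$e_l[i, ],
                 tolerance = 1e-12)
  }
  ## exactly isochoric at any state
  expect_equal(max(abs(kinematic_deformation(lv, 2.5 * lv$V0, 1.12)$J - 1)),
               0, tolerance = 1e-12)
  ## for geometrically similar walls the inner radius stays positive for any
  ## V > 0, so only non-positive volumes are rejected
  expect_error(kinematic_deformation(lv, 0, 1), "positive")
})

test_that("deformed cavity volume matches a surface-integral oracle", {
  lv <- small_lv()
  for (case in list(c(17.5, 1), c(40, 1.05), c(57.8, 0.93))) {
    mesh <- deformed_surface(lv, case[1], case[2], "endo",
                             n_long = 80, n_phi = 96)
    expect_equal(cardiomech:::mesh_cavity_volume(mesh), case[1],
                 tolerance = 1e-3)
  }
})

test_that("equilibrium pressure vanishes at the unloaded state and obeys the Laplace limit", {
  lv <- small_lv()
  pp <- ref_params()
  eq0 <- equilibrium_pressure(lv, lv$V0, pp)
  expect_equal(eq0$P, 0, tolerance = 1e-10)
  expect_equal(eq0$lamL, 1, tolerance = 1e-8)
  ## thin-wall sphere with near-isotropic material: Laplace law within 5%
  A <- 25; th <- 0.5
  g <- ventricle_geometry(A, A, A + th, A + th, z_base = 2 * A)
  iso <- passive_params(a = 5, b = 2, a_f = 1e-6, b_f = 1, a_s = 1e-6,
                        b_s = 1, a_fs = 1e-6, b_fs = 1)
  V <- g$V0 * 1.1
  eq <- equilibrium_pressure(g, V, iso)
  kin <- kinematic_deformation(g, V, eq$lamL)
  sig <- cardiomech:::stress_kernel(kin$F, g$q$f0, g$q$s0, iso)
  st <- vapply(seq_len(nrow(sig)), function(i) {
    S <- matrix(sig[i, ], 3, 3, byrow = TRUE)
    el <- g$q$e_l[i, ]; ec <- c(0, 1, 0); er <- g$q$e_r[i, ]
    ## membrane stress: mean tangential minus radial (deviatoric difference)
    (el %*% S %*% el + ec %*% S %*% ec) / 2 - er %*% S %*% er
  }, 0)
  r_def <- (A^3 * V / g$V0)^(1 / 3)
  t_def <- th * (A / r_def)^2
  expect_equal(eq$P, kpa_to_mmhg(2 * mean(st) * t_def / r_def),
               tolerance = 0.05)
})

test_that("pressure rises monotonically with uniform active tension at fixed volume", {
  lv <- small_lv()
  pp <- ref_params(A = 0.1, B = 0.3)
  P <- vapply(c(20, 60, 100, 140), function(tmax) {
    ap <- active_params(Tmax = tmax)
    equilibrium_pressure(lv, 30, pp, active = ap, t = ap$t0)$P
  }, 0)
  expect_true(all(diff(P) > 0))
})

test_that("passive inflation is zero at V0, increasing, convex, and scales with the a-terms", {
  lv <- small_lv()
  pp <- ref_params(A = 0.1, B = 0.3)
  Vg <- seq(lv$V0, 45, length.out = 10)
  curve <- passive_inflation_curve(lv, pp, Vg)
  expect_equal(curve$P[1], 0, tolerance = 1e-10)
  expect_true(all(diff(curve$P) > 0))
  ## convex over the physiological filling range (just above the unloaded
  ## volume the tension-only fiber terms switch on and the curve is flat)
  phys <- curve$V >= 1.3 * lv$V0
  expect_true(all(diff(diff(curve$P[phys])) > 0))
  ## uniform a-scaling scales P exactly (b-terms fixed); the wall is
  ## kinematically incompressible so no volumetric term interferes
  pp2 <- pp; pp2$A <- 3 * pp$A
  curve2 <- passive_inflation_curve(lv, pp2, Vg)
  expect_equal(curve2$P, 3 * curve$P, tolerance = 1e-6)
  ## stiffer exponential multiplier: pointwise at least as stiff
  pp3 <- pp; pp3$B <- 1.4 * pp$B
  curve3 <- passive_inflation_curve(lv, pp3, Vg)
  expect_true(all(curve3$P[-1] >= curve$P[-1]))
  expect_error(passive_inflation_curve(lv, pp, c(20, 25)), "V0")
})

test_that("hyperelastic inflation is path independent (closed-loop work is zero)", {
  lv <- small_lv()
  pp <- ref_params(A = 0.1, B = 0.3)
  Vg <- seq(lv$V0, 40, length.out = 12)
  up <- passive_inflation_curve(lv, pp, Vg)$P
  ## deflation revisits identical states: quasistatic response has no memory
  lam <- 1.2
  down <- vapply(rev(Vg), function(V) {
    eq <- equilibrium_pressure(lv, V, pp, lamL_init = lam)
    lam <<- eq$lamL
    eq$P
  }, 0)
  work <- sum((up[-1] + up[-length(up)]) / 2 * diff(Vg)) +
    sum((down[-1] + down[-length(down)]) / 2 * diff(rev(Vg)))
  expect_lt(abs(work), 1e-6 * sum(abs(up)) * diff(range(Vg)))
})

test_that("long-axis shortening follows its definition and sign convention", {
  expect_equal(lvls(c(1, 1, 1)), 0)
  expect_equal(lvls(c(1.0, 0.95, 0.85, 0.9)), 15)
  expect_equal(lvls(c(1.0, 1.05), es = 2), -5)
  expect_error(lvls(numeric(0)), "ED/ES")
})

test_that("an infarct patch never increases ejected volume at fixed Tmax", {
  pp <- ref_params(A = 0.1, B = 0.3)
  mk <- function(h_fun, n_phi) preset_geometry("normal", "lv", h_fun = h_fun,
                                               n_phi = n_phi)
  patch <- function(s, mu, phi) {
    ifelse(abs(mu) < 0.4 & cos(phi) > 0.2, 0.15, 1)
  }
  model_h <- heart_model(lv = mk(1, 8), material = pp)
  model_i <- heart_model(lv = mk(patch, 8), material = pp)
  st <- initial_state(model_h, lv_edp = 10, rv_edp = 4)
  sv_h <- run_cycles(model_h, 1, init = st, keep_trace = FALSE)$summary$SV[1]
  st_i <- initial_state(model_i, lv_edp = 10, rv_edp = 4)
  sv_i <- run_cycles(model_i, 1, init = st_i, keep_trace = FALSE)$summary$SV[1]
  expect_lte(sv_i, sv_h + 1e-6)
})
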