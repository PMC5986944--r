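test_that("eigen-decomposition and FA match closed forms and stay rotation-invariant", {
  e <- tensor_eigen_fa(diag(3) * 1e-3)
  expect_equal(e$fa, 0)
  expect_equal(tensor_eigen_fa(diag(c(2, 1, 1)))$fa, sqrt(1 / 6))
  e3 <- tensor_eigen_fa(diag(c(3, 1, 1)))
  expect_equal(abs(e3$vectors[, 1]), c(1, 0, 0))
  expect_gte(sum(e3$vectors[, 1] * c(1, 0, 0)), 0)  # sign fixed by ref_dir
  expect_error(tensor_eigen_fa(matrix(1:9, 3)), "symmetric")
  set.seed(3)
  T0 <- crossprod(matrix(rnorm(9), 3))
  fa0 <- tensor_eigen_fa(T0)$fa
  expect_true(fa0 >= 0 && fa0 <= 1)
  for (k in 1:100) {
    Q <- cardiomech:::random_rotation()
    expect_equal(tensor_eigen_fa(Q %*% T0 %*% t(Q))$fa, fa0,
                 tolerance = 1e-10)
  }
})

test_that("QC gate keeps only strictly positive, sufficiently anisotropic voxels", {
  t6 <- array(0, c(3, 1, 1, 6))
  t6[1, 1, 1, ] <- c(2, 0, 1, 0, 0, 1) * 1e-3          # FA 0.41, positive
  t6[2, 1, 1, ] <- c(1, 0, 1, 0, 0, -1e-6)             # negative eigenvalue
  t6[3, 1, 1, ] <- c(1.05, 0, 1, 0, 0, 0.95) * 1e-3    # FA ~0.04 < 0.12
  keep <- qc_filter(dt_voxel_grid(t6))
  expect_identical(as.logical(keep), c(TRUE, FALSE, FALSE))
})

test_that("invariant interpolation reproduces nodes, constants and the coaxial closed form", {
  lam <- c(1.0, 0.7, 0.5) * 1e-3
  T1 <- diag(lam)
  t6 <- array(0, c(2, 2, 2, 6))
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    t6[i, j, k, ] <- c(T1[1, 1], T1[1, 2], T1[2, 2], T1[1, 3], T1[2, 3],
                       T1[3, 3])
  gr <- dt_voxel_grid(t6)
  expect_equal(interpolate_tensor(gr, c(0, 0, 0)), T1, tolerance = 1e-12)
  expect_equal(interpolate_tensor(gr, c(0.3, 0.6, 0.2)), T1,
               tolerance = 1e-12)
  ## coaxial midpoint: eigenvalues average, axes unchanged
  t2 <- array(0, c(2, 1, 1, 6))
  t2[1, 1, 1, ] <- c(lam[1], 0, lam[2], 0, 0, lam[3])
  t2[2, 1, 1, ] <- 2 * c(lam[1], 0, lam[2], 0, 0, lam[3])
  g2 <- dt_voxel_grid(t2)
  Tm <- interpolate_tensor(g2, c(0.5, 0, 0))
  expect_equal(Tm, diag(1.5 * lam), tolerance = 1e-10)
  ev <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))  # positive definite
  ## no valid support
  g2$mask[] <- FALSE
  expect_error(interpolate_tensor(g2, c(0.5, 0, 0)), "no tissue support")
})

test_that("inclination angle measures fiber elevation in the tangent plane", {
  circ <- c(1, 0, 0); long <- c(0, 0, 1)
  expect_equal(inclination_angle(circ, circ, long), 0)
  expect_equal(inclination_angle(long, circ, long), 90)
  expect_equal(inclination_angle((circ + long) / sqrt(2), circ, long), 45)
  ## antipodal fiber folds into (-90, 90]
  expect_equal(inclination_angle(-(circ + long) / sqrt(2), circ, long), 45)
  expect_equal(inclination_angle(c(-1, 0, 0.01), circ, long),
               inclination_angle(c(1, 0, -0.01), circ, long))
  ## near-radial fiber: undefined
  a <- inclination_angle(c(0, 1, 0), circ, long)
  expect_true(is.na(a))
  expect_true(isTRUE(attr(a, "undefined")))
  expect_error(inclination_angle(circ, circ, c(1, 0, 1)), "orthogonal")
})

test_that("AHA-17 assignment follows the standard layout and is frame-equivariant", {
  ax <- c(0, 0, -1); base <- c(0, 0, 10); apex <- c(0, 0, -40)
  ins <- c(25, 0, 5)
  ## mid-height point just counterclockwise of the insertion: region 7
  m <- aha17_assign(rbind(c(20, 1, -12)), ax, base, apex, ins)
  expect_identical(m$region, 7L)
  ## apical cap point on the long axis: region 17
  expect_identical(aha17_assign(rbind(c(0, 0, -40)), ax, base, apex,
                                ins)$region, 17L)
  ## beyond the basal plane: excluded with count
  m2 <- aha17_assign(rbind(c(20, 1, 15)), ax, base, apex, ins)
  expect_true(is.na(m2$region))
  expect_identical(attr(m2, "n_excluded"), 1L)
  ## rotating points and landmarks together leaves assignments unchanged
  set.seed(8)
  pts <- cbind(runif(50, -25, 25), runif(50, -25, 25), runif(50, -38, 9))
  m0 <- aha17_assign(pts, ax, base, apex, ins)
  Q <- cardiomech:::random_rotation()
  m1 <- aha17_assign(pts %*% t(Q), as.numeric(Q %*% ax),
                     as.numeric(Q %*% base), as.numeric(Q %*% apex),
                     as.numeric(Q %*% ins))
  expect_identical(m0$region, m1$region)
  expect_error(aha17_assign(pts, ax, base, base, ins), "degenerate")
})

test_that("transmural profiles recover the fiber rule and infarct fractions", {
  spec <- phantom_spec(seed = 42, noise_sd = 0, background_frac = 0)
  g <- gen_dt_grid(spec)
  tw <- g$truth
  pts <- cbind(tw$x, tw$y, tw$z)
  fr <- cardiomech:::phantom_frame(spec, pts)
  field <- data.frame(alpha = tw$alpha, h = 1)
  map <- aha17_assign(pts, c(0, 0, -1), c(0, 0, spec$z_base),
                      c(0, 0, -spec$c_epi), c(spec$a_epi, 0, 0),
                      transmural = 2 * tw$s - 1)
  prof <- suppressWarnings(transmural_profile(field, map, n_bins = 5))
  ## the recovered profile is linear in depth: each bin's mean equals the
  ## rule (-60 * transmural) evaluated at that bin's sample-mean depth
  breaks <- seq(-1, 1, length.out = 6)
  ok <- !is.na(map$region)
  bin <- findInterval(map$transmural, breaks, all.inside = TRUE)
  for (r in unique(prof$region)) for (b in unique(prof$depth_bin)) {
    sel <- ok & map$region == r & bin == b
    if (sum(sel) < 3) next
    expected <- -60 * mean(map$transmural[sel])
    got <- prof$alpha_mean[prof$region == r & prof$depth_bin == b]
    expect_lt(abs(got - expected), 2)
  }
  ## all-healthy: every infarct fraction is 0
  expect_true(all(prof$infarct_fraction == 0))
  ## fully infarcted region: fraction 1
  field2 <- field; field2$h <- 0
  prof2 <- suppressWarnings(transmural_profile(field2, map, n_bins = 2))
  expect_true(all(prof2$infarct_fraction == 1))
  ## empty bins are reported as NaN with a warning
  expect_warning(transmural_profile(field, map, n_bins = 25), "empty")
})

test_that("health fields interpolate the binary mask with trilinear weights", {
  bg <- list(values = array(1, c(4, 4, 4)), spacing = c(1, 1, 1),
             origin = c(0, 0, 0))
  bg$values[1:2, , ] <- 0
  expect_equal(health_field_from_segmentation(bg, rbind(c(3, 2, 2))), 1)
  expect_equal(health_field_from_segmentation(bg, rbind(c(0.5, 2, 2))), 0)
  expect_equal(health_field_from_segmentation(bg, rbind(c(1.5, 2, 2))), 0.5)
  expect_warning(h <- health_field_from_segmentation(bg, rbind(c(9, 2, 2))),
                 "outside the grid")
  expect_equal(h, 1)
  ## monotone: enlarging the infarct never increases h
  set.seed(2)
  pts <- cbind(runif(40, 0, 3), runif(40, 0, 3), runif(40, 0, 3))
  h1 <- health_field_from_segmentation(bg, pts)
  bg2 <- bg; bg2$values[3, , ] <- 0
  h2 <- health_field_from_segmentation(bg2, pts)
  expect_true(all(h2 <= h1 + 1e-12))
})

test_that("fiber pipeline recovers the transmural rule from a noisy phantom", {
  spec <- phantom_spec(seed = 99, noise_sd = 5, background_frac = 0.1,
                       spacing = c(2.5, 2.5, 2.5))
  g <- gen_dt_grid(spec)
  keep <- qc_filter(g$grid)
  tw <- g$truth
  vi <- t(vapply(seq_len(nrow(tw)), function(r)
    as.integer(round((c(tw$x[r], tw$y[r], tw$z[r]) - g$grid$origin) /
                       spec$spacing) + 1), integer(3)))
  kept <- keep[vi]
  ## >= 99% of isotropic background voxels rejected by the FA gate
  expect_gte(mean(!kept[tw$background]), 0.99)
  ## voxelwise inclination-angle recovery through the gated interpolation
  ## (the same per-voxel pipeline the regional profiling uses)
  g$grid$mask <- keep
  sel <- which(kept & !tw$background & tw$z < spec$z_base - 2)
  set.seed(1)
  sel <- sample(sel, 300)
  pts <- cbind(tw$x, tw$y, tw$z)[sel, ]
  fr <- cardiomech:::phantom_frame(spec, pts)
  err <- vapply(seq_len(nrow(pts)), function(m) {
    Tm <- interpolate_tensor(g$grid, pts[m, ])
    e <- tensor_eigen_fa(Tm, ref_dir = fr$e_f[m, ])
    a <- inclination_angle(e$vectors[, 1], fr$e_c[m, ], fr$e_l[m, ])
    a - fr$alpha[m]
  }, 0)
  ## per-depth-bin mean absolute error <= 3 degrees
  bins <- cut(pmin(pmax(fr$s, 0), 1), seq(0, 1, by = 0.25),
              include.lowest = TRUE)
  mae <- tapply(abs(err), bins, mean)
  expect_true(all(table(bins) > 20))
  expect_true(all(mae <= 3))
})
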