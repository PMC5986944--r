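make_motion <- function(..., seed = 3, n_long = 36, n_phi = 72)
  gen_motion_sequence(phantom_spec(seed = seed, ...),
                      n_long = n_long, n_phi = n_phi)

test_that("the 16-segment partition covers the surface with 12 quads and 4 triangles", {
  ## 35 rings x 71 sectors: no vertex sits exactly on a segment boundary,
  ## so the assignment is insensitive to round-off under rigid rotation
  mo <- make_motion(n_long = 35, n_phi = 71)
  part <- partition16(mo$sequence)
  expect_length(part$segments, 16)
  expect_identical(sum(vapply(part$segments, `[[`, TRUE, "triangular")), 4L)
  ## every vertex in exactly one segment
  expect_true(all(part$assign %in% 1:16))
  expect_identical(length(part$assign), dim(mo$sequence$vertices)[1])
  ## rigid motion of surface + landmarks leaves the layout unchanged
  Q <- rotmat_from_quat <- cardiomech:::rotmat_from_quat(c(0.2, 0.9, 0.1, 0.4))
  sq <- mo$sequence
  v2 <- sq$vertices
  for (f in seq_len(sq$n_frames)) v2[, , f] <- sq$vertices[, , f] %*% t(Q)
  sq2 <- surface_sequence(v2, sq$triangles, sq$ed_frame, sq$es_frame,
                          as.numeric(Q %*% sq$apex_point),
                          as.numeric(Q %*% sq$base_point),
                          as.numeric(Q %*% sq$long_axis),
                          as.numeric(Q %*% sq$ref_direction))
  part2 <- partition16(sq2)
  expect_identical(part$assign, part2$assign)
})

test_that("strains vanish at ED, under identity motion and under rigid-body motion", {
  mo <- make_motion(circ_shortening = 0.12, long_shortening = 0.1,
                    torsion_deg = 8, n_frames = 5)
  sq <- mo$sequence
  part <- partition16(sq)
  rep <- segment_strains(sq, part)
  ed <- rep$strains[rep$strains$frame == 1, ]
  expect_true(all(ed$long_strain_pct == 0))
  expect_true(all(ed$circ_strain_pct == 0))
  ## identity motion
  v0 <- sq$vertices
  for (f in 2:sq$n_frames) v0[, , f] <- v0[, , 1]
  rep0 <- segment_strains(surface_sequence(v0, sq$triangles, 1, sq$n_frames,
                                           sq$apex_point, sq$base_point,
                                           sq$long_axis, sq$ref_direction),
                          part)
  expect_true(all(abs(rep0$strains$long_strain_pct) < 1e-9))
  ## rigid rotation + translation per frame
  set.seed(12)
  vr <- sq$vertices
  for (f in 2:sq$n_frames) {
    Q <- cardiomech:::random_rotation()
    vr[, , f] <- sq$vertices[, , 1] %*% t(Q) +
      matrix(rnorm(3, sd = 5), dim(vr)[1], 3, byrow = TRUE)
  }
  repr <- segment_strains(surface_sequence(vr, sq$triangles, 1, sq$n_frames,
                                           sq$apex_point, sq$base_point,
                                           sq$long_axis, sq$ref_direction),
                          part)
  expect_lt(max(abs(repr$strains$long_strain_pct)), 1e-9)
  expect_lt(max(abs(repr$strains$circ_strain_pct)), 1e-9)
})

test_that("uniform isotropic scaling by 0.9 yields exactly -10% everywhere", {
  mo <- make_motion(n_frames = 3)
  sq <- mo$sequence
  v <- sq$vertices
  v[, , 2] <- 0.95 * v[, , 1]
  v[, , 3] <- 0.9 * v[, , 1]
  sq2 <- surface_sequence(v, sq$triangles, 1, 3, sq$apex_point,
                          sq$base_point, sq$long_axis, sq$ref_direction)
  rep <- segment_strains(sq2, partition16(sq2))
  es <- rep$strains[rep$strains$frame == 3, ]
  expect_equal(es$long_strain_pct, rep(-10, 16), tolerance = 1e-9)
  expect_equal(es$circ_strain_pct, rep(-10, 16), tolerance = 1e-9)
  expect_equal(rep$gls[3], -10, tolerance = 1e-9)
})

test_that("prescribed analytic motion is recovered segment by segment", {
  mo <- make_motion(circ_shortening = 0.15, long_shortening = 0.12,
                    torsion_deg = 10)
  rep <- segment_strains(mo$sequence, partition16(mo$sequence))
  es <- rep$strains[rep$strains$frame == rep$es_frame, ]
  expect_equal(es$circ_strain_pct, mo$truth_es$circ_strain_pct,
               tolerance = 0.5 / 15)   # within 0.5 percentage points of -15
  expect_equal(es$long_strain_pct, mo$truth_es$long_strain_pct,
               tolerance = 0.15)
  ## torsion alone produces no circumferential strain
  mot <- make_motion(circ_shortening = 0, long_shortening = 0,
                     torsion_deg = 12)
  rept <- segment_strains(mot$sequence, partition16(mot$sequence))
  est <- rept$strains[rept$strains$frame == rept$es_frame, ]
  expect_lt(max(abs(est$circ_strain_pct)), 1e-6)
})

test_that("arc lengths are converged with respect to spline sampling density", {
  ## segment-scale control lines are gentle arcs (here 60 degrees of a ring)
  th <- seq(0, pi / 3, length.out = 3)
  pts <- cbind(20 * cos(th), 20 * sin(th), rep(-5, 3))
  a64 <- cardiomech:::spline_arc_length(pts, n_sample = 64)
  a128 <- cardiomech:::spline_arc_length(pts, n_sample = 128)
  expect_lt(abs(a64 - a128) / a128, 1e-4)
  ## strain ratios converge even faster than raw lengths
  b64 <- cardiomech:::spline_arc_length(0.9 * pts, n_sample = 64)
  b128 <- cardiomech:::spline_arc_length(0.9 * pts, n_sample = 128)
  expect_lt(abs(b64 / a64 - b128 / a128), 1e-6)
  expect_error(cardiomech:::spline_arc_length(pts[1:2, ]), "at least 3")
})

test_that("report comparison measures per-segment differences", {
  mo <- make_motion(circ_shortening = 0.1)
  rep <- segment_strains(mo$sequence, partition16(mo$sequence))
  cmp <- compare_reports(rep, rep)
  expect_true(all(cmp$table$long_diff == 0))
  expect_equal(cmp$gls_diff, 0)
  ## constant +2% offset in the reference
  rep2 <- rep
  rep2$strains$long_strain_pct <- rep2$strains$long_strain_pct + 2
  rep2$strains$circ_strain_pct <- rep2$strains$circ_strain_pct + 2
  cmp2 <- compare_reports(rep2, rep)
  expect_equal(mean(cmp2$table$long_diff), 2, tolerance = 1e-12)
  expect_equal(unname(cmp2$mean_abs_diff["circ"]), 2, tolerance = 1e-12)
  ## seeded twin noise: mean |difference| matches the injected scale
  set.seed(14)
  na <- rep; nb <- rep
  sd_inj <- 0.8
  na$strains$circ_strain_pct <- na$strains$circ_strain_pct +
    rnorm(nrow(na$strains), 0, sd_inj)
  nb$strains$circ_strain_pct <- nb$strains$circ_strain_pct +
    rnorm(nrow(nb$strains), 0, sd_inj)
  cmp3 <- compare_reports(na, nb)
  ## |N(0, 2 sd^2)| has mean sd*sqrt(2)*sqrt(2/pi)
  expect_equal(unname(cmp3$mean_abs_diff["circ"]),
               sd_inj * sqrt(2) * sqrt(2 / pi), tolerance = 0.5)
  bad <- rep
  bad$strains <- bad$strains[bad$strains$frame == 1, ]
  expect_error(compare_reports(bad, rep), "mismatch")
})
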