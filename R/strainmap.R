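## 16-segment endocardial strain extraction: the endocardial surface is
## partitioned into 12 quadrilateral trunk segments and 4 triangular apical
## segments; control nodes at segment corners, edge midpoints and centers
## are tracked through the frames, natural cubic splines are fitted through
## them in the longitudinal and circumferential directions, and engineering
## strains referenced to end diastole follow from the change in spline arc
## length. Global strains (GLS/GCS) are area-weighted means over segments.

#' Endocardial surface sequence
#'
#' Vertex positions per time frame with constant triangulation, landmark
#' annotations and ED/ES frame indices.
#'
#' @param vertices array `c(n_vertices, 3, n_frames)`, mm.
#' @param triangles m x 3 vertex indices (constant topology).
#' @param ed_frame,es_frame frame indices of end diastole / end systole.
#' @param apex_point,base_point,long_axis landmarks at the ED frame; the
#'   long axis points from base toward apex.
#' @param ref_direction direction fixing the circumferential origin
#'   (sector-1 boundary); projected off the long axis.
#' @param times optional frame times, ms.
#' @return object of class `surface_sequence`.
#' @export
surface_sequence <- function(vertices, triangles, ed_frame = 1,
                             es_frame = NULL, apex_point, base_point,
                             long_axis, ref_direction = c(1, 0, 0),
                             times = NULL) {
  d <- dim(vertices)
  if (length(d) != 3 || d[2] != 3)
    stop("vertices must be an (n, 3, n_frames) array")
  if (ed_frame < 1 || ed_frame > d[3]) stop("ED frame index out of range")
  if (max(triangles) > d[1]) stop("triangle indices exceed vertex count")
  structure(list(vertices = vertices, triangles = triangles,
                 ed_frame = ed_frame,
                 es_frame = es_frame %||% d[3],
                 apex_point = apex_point, base_point = base_point,
                 long_axis = unit3(long_axis),
                 ref_direction = ref_direction,
                 times = times %||% seq_len(d[3]) - 1,
                 n_frames = d[3]),
            class = "surface_sequence")
}

#' @export
print.surface_sequence <- function(x, ...) {
  cat(sprintf("Endocardial surface sequence: %d vertices, %d triangles, %d frames (ED %d, ES %d)\n",
              dim(x$vertices)[1], nrow(x$triangles), x$n_frames,
              x$ed_frame, x$es_frame))
  invisible(x)
}

## surface-relative cylindrical coordinates of vertices at the ED frame
surface_coords <- function(seq) {
  v <- seq$vertices[, , seq$ed_frame]
  ax <- seq$long_axis
  rel <- sweep(v, 2, seq$base_point)
  L <- sum((seq$apex_point - seq$base_point) * ax)
  lf <- as.numeric(rel %*% ax) / L          # 0 base .. 1 apex
  u0 <- seq$ref_direction - sum(seq$ref_direction * ax) * ax
  u0 <- unit3(u0)
  ## same angular convention as aha17_assign (counterclockwise, apical view)
  v0 <- c(u0[2] * ax[3] - u0[3] * ax[2],
          u0[3] * ax[1] - u0[1] * ax[3],
          u0[1] * ax[2] - u0[2] * ax[1])
  theta <- (atan2(rel %*% v0, rel %*% u0) * 180 / pi + 360) %% 360
  list(lf = lf, theta = as.numeric(theta))
}

#' Partition an endocardial surface into the 16-segment model
#'
#' Basal, mid and apical longitudinal bands (thirds of the base-to-apex
#' extent) with 6, 6 and 4 circumferential sectors: 12 quadrilateral trunk
#' segments plus 4 triangular apical segments converging at the apex.
#' Control nodes (corners, edge midpoints, center: a 3 x 3 parametric grid
#' per segment) are snapped to the nearest surface vertices at the ED frame
#' and tracked by vertex identity thereafter, so the partition is
#' deterministic given the landmarks and rigid-motion equivariant.
#'
#' @param seq a [surface_sequence()].
#' @return object of class `segment_partition16`: per-segment band, sector,
#'   angular/longitudinal extents, control-node vertex indices, vertex
#'   assignment and ED areas.
#' @export
partition16 <- function(seq) {
  sc <- surface_coords(seq)
  if (!is.finite(sum(sc$lf)) || diff(range(sc$lf)) < 1e-6)
    stop("degenerate landmarks")
  bands <- list(basal = c(0, 1 / 3), mid = c(1 / 3, 2 / 3),
                apical = c(2 / 3, 1))
  n_sect <- c(basal = 6L, mid = 6L, apical = 4L)
  segs <- list()
  sid <- 0L
  for (b in names(bands)) {
    ns <- n_sect[[b]]
    width <- 360 / ns
    for (k in seq_len(ns)) {
      sid <- sid + 1L
      segs[[sid]] <- list(id = sid, band = b,
                          lf = bands[[b]], th = c((k - 1) * width, k * width),
                          triangular = b == "apical")
    }
  }
  ## vertex assignment (every vertex to exactly one segment)
  band_of <- findInterval(pmin(pmax(sc$lf, 0), 1 - 1e-12),
                          c(0, 1 / 3, 2 / 3), left.open = FALSE)
  assign <- integer(length(sc$lf))
  for (i in seq_along(sc$lf)) {
    b <- band_of[i]
    ns <- c(6L, 6L, 4L)[b]
    k <- pmin(floor(sc$theta[i] / (360 / ns)) + 1L, ns)
    assign[i] <- c(0L, 6L, 12L)[b] + k
  }
  ## control nodes: 3x3 parametric grid snapped to nearest vertex
  nearest <- function(lf_t, th_t) {
    dth <- pmin(abs(sc$theta - th_t), 360 - abs(sc$theta - th_t)) / 360
    which.min((sc$lf - lf_t)^2 + dth^2)
  }
  for (sgm in segs) {
    lf3 <- seq(sgm$lf[1], sgm$lf[2], length.out = 3)
    th3 <- seq(sgm$th[1], sgm$th[2], length.out = 3)
    ctrl <- matrix(0L, 3, 3)   # rows: longitudinal position, cols: theta
    for (i in 1:3) for (j in 1:3) ctrl[i, j] <- nearest(lf3[i], th3[j] %% 360)
    segs[[sgm$id]]$control <- ctrl
  }
  ## ED segment areas (sum of triangle areas by majority vertex assignment)
  v <- seq$vertices[, , seq$ed_frame]
  areas <- numeric(16)
  for (r in seq_len(nrow(seq$triangles))) {
    tri <- seq$triangles[r, ]
    a2 <- v[tri[2], ] - v[tri[1], ]; a3 <- v[tri[3], ] - v[tri[1], ]
    ar <- 0.5 * sqrt(sum(c(a2[2] * a3[3] - a2[3] * a3[2],
                           a2[3] * a3[1] - a2[1] * a3[3],
                           a2[1] * a3[2] - a2[2] * a3[1])^2))
    s <- assign[tri[1]]
    areas[s] <- areas[s] + ar
  }
  structure(list(segments = segs, assign = assign, areas = areas,
                 seq_ref = list(ed_frame = seq$ed_frame)),
            class = "segment_partition16")
}

#' @export
print.segment_partition16 <- function(x, ...) {
  nq <- sum(!vapply(x$segments, `[[`, TRUE, "triangular"))
  cat(sprintf("16-segment endocardial partition: %d quadrilateral + %d triangular segments\n",
              nq, 16 - nq))
  invisible(x)
}

## natural cubic spline arc length through points (k x 3) using
## chord-length parameterization; dense Gauss-type sampling
spline_arc_length <- function(pts, n_sample = 64) {
  k <- nrow(pts)
  if (k < 3) stop("spline requires at least 3 control points")
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-k, , drop = FALSE])^2))
  tpar <- c(0, cumsum(d))
  if (tpar[k] == 0) return(0)
  ts <- seq(0, tpar[k], length.out = n_sample)
  xyz <- vapply(1:3, function(c2)
    stats::spline(tpar, pts[, c2], xout = ts, method = "natural")$y,
    numeric(n_sample))
  sum(sqrt(rowSums(diff(xyz)^2)))
}

#' Per-segment engineering strains from tracked control nodes
#'
#' For each segment and frame, natural cubic splines are fitted through the
#' tracked control nodes along the three longitudinal and the three
#' circumferential control lines; engineering strain is the relative change
#' of mean spline arc length with respect to the ED frame, in percent.
#' Global longitudinal/circumferential strain (GLS/GCS) is the
#' area-weighted mean over segments (ED areas; unweighted mean available).
#'
#' @param seq a [surface_sequence()].
#' @param partition a [partition16()] of the same sequence.
#' @param weighted area-weight the global summaries (default TRUE).
#' @return object of class `segment_strain_report`: data.frame `strains`
#'   with `segment, frame, long_strain_pct, circ_strain_pct`, plus `gls`,
#'   `gcs` vectors per frame.
#' @export
segment_strains <- function(seq, partition, weighted = TRUE) {
  nf <- seq$n_frames
  segs <- partition$segments
  res <- expand.grid(segment = 1:16, frame = seq_len(nf))
  res$long_strain_pct <- NA_real_
  res$circ_strain_pct <- NA_real_
  L0 <- matrix(NA_real_, 16, 2)  # ED arc lengths (long, circ)
  arc_pair <- function(v, ctrl) {
    ## longitudinal lines: columns of ctrl; circumferential lines: rows
    al <- mean(vapply(1:3, function(j)
      spline_arc_length(v[ctrl[, j], , drop = FALSE]), 0))
    circ_rows <- 1:3
    ac_each <- vapply(circ_rows, function(i)
      spline_arc_length(v[ctrl[i, ], , drop = FALSE]), 0)
    list(al = al, ac = ac_each)
  }
  ed <- seq$ed_frame
  ac0 <- vector("list", 16)
  for (s in 1:16) {
    v <- seq$vertices[, , ed]
    ap <- arc_pair(v, segs[[s]]$control)
    ac0[[s]] <- ap$ac
    L0[s, 1] <- ap$al
    L0[s, 2] <- mean(ap$ac[ap$ac > 1e-9])
  }
  for (f in seq_len(nf)) {
    v <- seq$vertices[, , f]
    for (s in 1:16) {
      ap <- arc_pair(v, segs[[s]]$control)
      keep <- ac0[[s]] > 1e-9   # circumferential rows with finite ED length
      row <- res$segment == s & res$frame == f
      res$long_strain_pct[row] <- 100 * (ap$al - L0[s, 1]) / L0[s, 1]
      res$circ_strain_pct[row] <-
        100 * mean((ap$ac[keep] - ac0[[s]][keep]) / ac0[[s]][keep])
    }
  }
  w <- if (weighted) partition$areas else rep(1, 16)
  w <- w / sum(w)
  gls <- vapply(seq_len(nf), function(f)
    sum(w * res$long_strain_pct[res$frame == f]), 0)
  gcs <- vapply(seq_len(nf), function(f)
    sum(w * res$circ_strain_pct[res$frame == f]), 0)
  structure(list(strains = res, gls = gls, gcs = gcs,
                 ed_frame = ed, es_frame = seq$es_frame,
                 weighted = weighted),
            class = "segment_strain_report")
}

#' @export
print.segment_strain_report <- function(x, ...) {
  es <- x$es_frame
  cat(sprintf("16-segment strain report (%d frames; ED %d, ES %d)\n",
              max(x$strains$frame), x$ed_frame, es))
  cat(sprintf("  GLS at ES: %.2f%%   GCS at ES: %.2f%%\n",
              x$gls[es], x$gcs[es]))
  invisible(x)
}

#' Compare two 16-segment strain reports
#'
#' Per-segment differences at end systole (model minus reference) for both
#' strain directions, plus global differences and summary statistics.
#'
#' @param model,reference `segment_strain_report` objects with the same
#'   segment layout and frame count.
#' @return list with `table` (per-segment ES differences), `gls_diff`,
#'   `gcs_diff`, `mean_abs_diff`.
#' @export
compare_reports <- function(model, reference) {
  if (max(model$strains$segment) != max(reference$strains$segment) ||
      max(model$strains$frame) != max(reference$strains$frame))
    stop("segment layout / frame mismatch between reports")
  es_m <- model$es_frame; es_r <- reference$es_frame
  m <- model$strains[model$strains$frame == es_m, ]
  r <- reference$strains[reference$strains$frame == es_r, ]
  tab <- data.frame(segment = m$segment,
                    long_model = m$long_strain_pct,
                    long_ref = r$long_strain_pct,
                    long_diff = m$long_strain_pct - r$long_strain_pct,
                    circ_model = m$circ_strain_pct,
                    circ_ref = r$circ_strain_pct,
                    circ_diff = m$circ_strain_pct - r$circ_strain_pct)
  list(table = tab,
       gls_diff = model$gls[es_m] - reference$gls[es_r],
       gcs_diff = model$gcs[es_m] - reference$gcs[es_r],
       mean_abs_diff = c(long = mean(abs(tab$long_diff)),
                         circ = mean(abs(tab$circ_diff))))
}
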