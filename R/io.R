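## Format readers/writers: NIfTI tensor grids and masks (via RNifti),
## legacy-VTK ASCII polydata surfaces (minimal hand-written subset: no
## installed R package covers VTK polydata), CSV tables with stable column
## orders and full-precision floats, and JSON configs/results with run
## provenance.

#' Write / read a diffusion-tensor grid as NIfTI
#'
#' Tensors are stored as a 4-D NIfTI image with 6 volumes holding the
#' lower-triangular components (dxx, dxy, dyy, dxz, dyz, dzz); voxel
#' spacing and origin go through the NIfTI affine (RAS+, mm). An optional
#' companion uint8 mask marks valid voxels.
#'
#' @param grid a [dt_voxel_grid()].
#' @param path output `.nii` / `.nii.gz` path.
#' @param mask_path optional path for the validity mask.
#' @return `path`, invisibly.
#' @export
write_tensor_grid <- function(grid, path, mask_path = NULL) {
  img <- RNifti::asNifti(grid$tensors)
  affine <- diag(c(grid$spacing, 1))
  affine[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    m <- RNifti::asNifti(array(as.integer(grid$mask), dim(grid$mask)),
                         datatype = "uint8")
    m <- RNifti::`sform<-`(m, structure(affine, code = 2L))
    RNifti::writeNifti(m, mask_path)
  }
  invisible(path)
}

#' @rdname write_tensor_grid
#' @param path_mask optional mask file read alongside.
#' @return for the reader: a [dt_voxel_grid()].
#' @export
read_tensor_grid <- function(path, path_mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (!(length(d) == 4 && d[4] %in% c(6L, 9L)))
    stop("unrecognized tensor layout: expected a 4-D NIfTI with 6 ",
         "lower-triangular components (dxx,dxy,dyy,dxz,dyz,dzz) or 9 ",
         "full-tensor components")
  affine <- RNifti::xform(img)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  origin <- affine[1:3, 4]
  t6 <- if (d[4] == 6L) array(as.numeric(img), d) else {
    full <- array(as.numeric(img), c(d[1:3], 3, 3))
    dt_voxel_grid(full, spacing, origin)$tensors
  }
  mask <- NULL
  if (!is.null(path_mask)) {
    m <- RNifti::readNifti(path_mask)
    if (!identical(dim(m)[1:3], d[1:3]))
      stop("mask dimensions do not match the tensor grid")
    mask <- array(as.numeric(m) > 0, d[1:3])
  }
  dt_voxel_grid(t6, spacing = spacing, origin = origin, mask = mask)
}

#' Write / read legacy-VTK ASCII polydata surfaces
#'
#' Minimal POLYDATA subset (POINTS + POLYGONS), enough to exchange
#' triangulated endocardial surfaces with visualization tools.
#'
#' @param vertices n x 3 matrix, mm.
#' @param triangles m x 3 1-based vertex indices.
#' @param path `.vtk` file path.
#' @return `path` invisibly (writer); list with `vertices`, `triangles`
#'   (reader).
#' @export
write_vtk_polydata <- function(vertices, triangles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(vertices))), con)
  writeLines(apply(vertices, 1, function(p)
    paste(formatC(p, format = "g", digits = 17), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(triangles), 4 * nrow(triangles)),
             con)
  writeLines(apply(triangles, 1, function(tr)
    paste(c(3L, tr - 1L), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_vtk_polydata
#' @export
read_vtk_polydata <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  if (!length(ip)) stop("not a VTK POLYDATA file (no POINTS section)")
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):(ip + np)], quiet = TRUE)
  vertices <- matrix(pts, ncol = 3, byrow = TRUE)
  it <- grep("^POLYGONS", lines)
  if (!length(it)) stop("no POLYGONS section")
  nt <- as.integer(strsplit(lines[it], "\\s+")[[1]][2])
  tri <- scan(text = lines[(it + 1):(it + nt)], quiet = TRUE)
  tri <- matrix(tri, ncol = 4, byrow = TRUE)
  if (any(tri[, 1] != 3)) stop("only triangles are supported")
  list(vertices = vertices, triangles = tri[, 2:4, drop = FALSE] + 1L)
}

#' Write a surface sequence as VTK frames plus a JSON manifest
#'
#' @param seq a [surface_sequence()].
#' @param dir output directory (created).
#' @param prefix file name prefix.
#' @return manifest path, invisibly.
#' @export
write_surface_sequence <- function(seq, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(seq$n_frames)
  for (f in seq_len(seq$n_frames)) {
    files[f] <- file.path(dir, sprintf("%s_%03d.vtk", prefix, f))
    write_vtk_polydata(seq$vertices[, , f], seq$triangles, files[f])
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(
    list(files = basename(files), ed_frame = seq$ed_frame,
         es_frame = seq$es_frame, times = seq$times,
         apex_point = seq$apex_point, base_point = seq$base_point,
         long_axis = seq$long_axis, ref_direction = seq$ref_direction),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_surface_sequence
#' @param manifest_path path to the JSON manifest.
#' @export
read_surface_sequence <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  first <- read_vtk_polydata(file.path(dir, man$files[1]))
  nv <- nrow(first$vertices)
  verts <- array(0, c(nv, 3, length(man$files)))
  verts[, , 1] <- first$vertices
  for (f in seq_along(man$files)[-1])
    verts[, , f] <- read_vtk_polydata(file.path(dir, man$files[f]))$vertices
  surface_sequence(verts, first$triangles, ed_frame = man$ed_frame,
                   es_frame = man$es_frame, apex_point = man$apex_point,
                   base_point = man$base_point, long_axis = man$long_axis,
                   ref_direction = man$ref_direction, times = man$times)
}

#' Full-precision CSV writers with stable column order
#'
#' Thin wrappers around [utils::write.csv()] that format doubles with 17
#' significant digits so a write-read round trip is bit-exact.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], format = "g",
                                                 digits = 17)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize parameter sets to/from JSON with unit annotations
#'
#' @param x a `passive_params`, `active_params` or `circulation_params`.
#' @param path JSON path.
#' @return `path` invisibly (writer); the reconstructed object (reader).
#' @export
write_params_json <- function(x, path) {
  kind <- class(x)[1]
  units <- switch(kind,
    passive_params = list(a_type = "kPa", b_type = "dimensionless",
                          D = "1/MPa"),
    active_params = list(Tmax = "kPa", Ca = "uM", lengths = "um",
                         times = "ms"),
    circulation_params = list(kappa = "ml/mmHg", R = "mmHg*ms/ml",
                              T = "ms", V = "ml", P = "mmHg"),
    stop("unsupported parameter class: ", kind))
  jsonlite::write_json(list(kind = kind, units = units, values = unclass(x)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fun <- switch(obj$kind,
    passive_params = passive_params, active_params = active_params,
    circulation_params = circulation_params,
    stop("unknown parameter kind: ", obj$kind))
  ## derived fields (e.g. the cycle period) are recomputed by the constructor
  vals <- obj$values[intersect(names(obj$values), names(formals(fun)))]
  do.call(fun, vals)
}

#' Write run provenance
#'
#' Every pipeline output directory receives a provenance JSON sufficient to
#' reproduce the run: inputs, configuration, seed, package version and wall
#' time.
#'
#' @param dir output directory.
#' @param stage stage name.
#' @param config named list of stage configuration.
#' @param seed RNG seed used (or NA).
#' @param inputs character vector of input paths.
#' @param started `Sys.time()` at stage start.
#' @return path of the provenance file, invisibly.
#' @export
write_provenance <- function(dir, stage, config = list(), seed = NA,
                             inputs = character(), started = Sys.time()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(list(
    stage = stage, seed = seed, inputs = inputs, config = config,
    package = "cardiomech",
    version = as.character(utils::packageVersion("cardiomech")),
    r_version = R.version.string,
    timestamp = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    wall_time_s = as.numeric(difftime(Sys.time(), started, units = "secs"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
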