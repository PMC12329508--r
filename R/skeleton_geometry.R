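#' Triangle mesh constructor
#'
#' Minimal indexed triangle mesh: an `n x 3` vertex matrix (mm, world frame;
#' the z axis points downward into the skeleton so depth is positive and the
#' top face is minimum z) and an `m x 3` face index matrix (1-based).
#'
#' @param vertices Numeric matrix, one vertex per row (x, y, z in mm).
#' @param faces Integer matrix, one triangle per row.
#' @return A `triangle_mesh` object.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) == 0) stop("empty mesh")
  if (max(faces) > nrow(vertices) || min(faces) < 1)
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle mesh: %d vertices, %d faces, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces), is_watertight(x)))
  invisible(x)
}

#' Check mesh watertightness
#'
#' A closed 2-manifold has every undirected edge shared by exactly two faces.
#'
#' @param mesh A [triangle_mesh()].
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Repair a mesh by dropping degenerate faces and merging duplicate vertices
#'
#' @param mesh A [triangle_mesh()].
#' @param tol Vertex-merge tolerance, mm.
#' @return A repaired `triangle_mesh`.
#' @export
repair_mesh <- function(mesh, tol = 1e-9) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  v2 <- v[uk, , drop = FALSE]
  f2 <- matrix(map[mesh$faces], ncol = 3)
  degen <- f2[, 1] == f2[, 2] | f2[, 2] == f2[, 3] | f2[, 1] == f2[, 3]
  f2 <- f2[!degen, , drop = FALSE]
  if (nrow(f2) == 0) stop("empty mesh after repair")
  triangle_mesh(v2, f2)
}

#' Enclosed volume of a watertight mesh
#'
#' Signed tetrahedron sum; orientation-independent absolute value, mm^3.
#'
#' @param mesh A [triangle_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  s <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(s)) / 6
}

mesh_face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

## ---- STL I/O --------------------------------------------------------------

#' Read a triangulated surface from STL (ASCII or binary)
#'
#' @param path STL file path.
#' @return A [triangle_mesh()] with duplicate vertices merged.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 5)
  close(con)
  if (rawToChar(head) == "solid" && is_ascii_stl(path)) read_stl_ascii(path)
  else read_stl_binary(path)
}

is_ascii_stl <- function(path) {
  txt <- readBin(path, "raw", min(file.info(path)$size, 4096))
  !any(txt == as.raw(0)) && grepl("facet", rawToChar(txt), fixed = TRUE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (is.null(nums) || nrow(nums) %% 3 != 0) stop("malformed ASCII STL")
  f <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  repair_mesh(triangle_mesh(nums, f))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- readBin(con, "raw", ntri * 50)
  m <- matrix(rec, nrow = 50)
  vals <- readBin(as.vector(m[1:48, ]), "numeric", ntri * 12, size = 4,
                  endian = "little")
  vm <- matrix(vals, ncol = 12, byrow = TRUE)  # normal + 3 vertices
  v <- matrix(0, ntri * 3, 3)
  v[seq(1, 3 * ntri, 3), ] <- vm[, 4:6]
  v[seq(2, 3 * ntri, 3), ] <- vm[, 7:9]
  v[seq(3, 3 * ntri, 3), ] <- vm[, 10:12]
  f <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  repair_mesh(triangle_mesh(v, f))
}

#' Write a mesh to binary STL
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  ntri <- nrow(f)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  for (t in seq_len(ntri)) {
    writeBin(as.numeric(c(nrm[t, ], v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ])),
             con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

## ---- voxel model ----------------------------------------------------------

#' Voxel model constructor
#'
#' 3-D label grid with codes 0 background/air, 1 water, 2 superficial
#' skeleton, 3 volumetric skeleton, plus the voxel pitch, world origin and a
#' label-to-optical-properties map.
#'
#' @param labels 3-D integer array of codes in `{0, 1, 2, 3}`.
#' @param pitch_mm Isotropic voxel edge, mm.
#' @param origin World coordinates of the corner of voxel (1,1,1), mm.
#' @param property_map Named list mapping label codes (as character) to
#'   [optical_properties()].
#' @return A `voxel_model`.
#' @export
voxel_model <- function(labels, pitch_mm, origin = c(0, 0, 0),
                        property_map = list()) {
  stopifnot(length(dim(labels)) == 3)
  if (pitch_mm <= 0) stop("voxel pitch must be > 0")
  if (!all(labels %in% 0:3)) stop("labels must be in {0, 1, 2, 3}")
  structure(list(labels = labels, pitch_mm = pitch_mm, origin = origin,
                 property_map = property_map), class = "voxel_model")
}

#' @export
print.voxel_model <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:3))
  cat(sprintf(paste0("voxel model %d x %d x %d @ %.4g mm: ",
                     "%d background, %d water, %d superficial, %d volumetric\n"),
              dim(x$labels)[1], dim(x$labels)[2], dim(x$labels)[3],
              x$pitch_mm, tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Voxelize a watertight mesh into a solid label grid
#'
#' A voxel is solid (volumetric skeleton, label 3) when its centre lies
#' inside the mesh, determined by vertical ray-crossing parity. The grid is
#' the mesh bounding box (plus `pad_voxels` on every face) at the requested
#' resolution.
#'
#' @param mesh A [triangle_mesh()]; repaired and checked for watertightness.
#' @param resolution_px_per_cm Voxels per cm (300 reproduces a 33.3 um pitch).
#' @param pad_voxels Background padding added on each face.
#' @return A [voxel_model()] with labels 0/3.
#' @export
voxelize_mesh <- function(mesh, resolution_px_per_cm = 300, pad_voxels = 0) {
  mesh <- repair_mesh(mesh)
  if (!is_watertight(mesh)) stop("mesh is not watertight after repair")
  pitch <- 10 / resolution_px_per_cm
  v <- mesh$vertices
  lo <- apply(v, 2, min) - pad_voxels * pitch
  hi <- apply(v, 2, max) + pad_voxels * pitch
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / pitch - 1e-9)))
  tris <- cbind(v[mesh$faces[, 1], , drop = FALSE],
                v[mesh$faces[, 2], , drop = FALSE],
                v[mesh$faces[, 3], , drop = FALSE])
  lab <- .voxelize_tris(tris, pitch, lo, dims)
  lab <- array(lab * 3L, dim = dims)
  voxel_model(lab, pitch, origin = lo)
}

#' Split the skeleton into superficial and volumetric layers
#'
#' Skeleton voxels whose Euclidean centre-to-centre distance to the nearest
#' non-skeleton voxel is at most `shell_thickness_mm` become the superficial
#' layer (label 2); the remainder is volumetric (label 3). The partition is
#' exact and idempotent.
#'
#' @param model A [voxel_model()].
#' @param shell_thickness_mm Shell depth, mm (default 0.1 = 100 um).
#' @return The model with labels 2/3 assigned.
#' @export
split_layers <- function(model, shell_thickness_mm = 0.1) {
  if (shell_thickness_mm <= 0) stop("shell thickness must be > 0")
  lab <- model$labels
  skel <- lab == 2L | lab == 3L
  if (!any(skel)) stop("model has no skeleton voxels")
  sites <- array(as.integer(!skel), dim = dim(lab))
  d2 <- .edt3d_sq(as.integer(sites), dim(lab))
  dist_mm <- sqrt(d2) * model$pitch_mm
  shell <- skel & array(dist_mm <= shell_thickness_mm * (1 + 1e-9), dim(lab))
  lab[skel] <- 3L
  lab[shell] <- 2L
  model$labels <- lab
  model
}

#' Add an overlying water layer
#'
#' Pads the grid so that `n_water_voxels` full slabs lie above the highest
#' skeleton voxel, then labels as water (1) every background voxel reachable
#' from the top face by a 6-connected flood fill -- so concave grooves and
#' overhung pockets open to the water column are filled, while enclosed pores
#' stay background.
#'
#' @param model A [voxel_model()].
#' @param n_water_voxels Water slabs above the surface (default 100).
#' @return The model with water labels assigned (grid possibly padded).
#' @export
add_water_layer <- function(model, n_water_voxels = 100) {
  if (n_water_voxels < 0) stop("n_water_voxels must be >= 0")
  lab <- model$labels
  skel_k <- which(apply(lab == 2L | lab == 3L, 3, any))
  if (length(skel_k) == 0) stop("model has no skeleton voxels")
  k_top <- min(skel_k)  # top face = minimum z index
  pad <- n_water_voxels - (k_top - 1)
  if (pad > 0) {
    d <- dim(lab)
    lab2 <- array(0L, dim = c(d[1], d[2], d[3] + pad))
    lab2[, , (pad + 1):(d[3] + pad)] <- lab
    lab <- lab2
    model$origin[3] <- model$origin[3] - pad * model$pitch_mm
  }
  if (n_water_voxels > 0) {
    reached <- array(.flood_from_top(as.integer(lab), dim(lab)), dim(lab))
    lab[reached] <- 1L
  }
  model$labels <- lab
  model
}

#' Assign optical properties to voxel labels
#'
#' @param model A [voxel_model()].
#' @param water,superficial,volumetric [optical_properties()] for labels
#'   1, 2, 3. The default water is nearly transparent at 930 nm
#'   (`mu_a = 0.0425 mm^-1`, `mu_s = 0.001 mm^-1`, g = 0).
#' @param mu_a_floor Scoring floor applied to `mu_a` so fluence-from-
#'   absorption scoring stays defined (default 0.01 mm^-1, skeleton value).
#' @return The model with a complete `property_map`.
#' @export
assign_properties <- function(model,
                              water = optical_properties(0.0425, 0.001, 0, 1.33),
                              superficial,
                              volumetric,
                              mu_a_floor = 0.01) {
  floor_props <- function(p) {
    if (p$mu_a < mu_a_floor) p$mu_a <- mu_a_floor
    p
  }
  model$property_map <- list(
    "0" = optical_properties(0, 0, 0, 1),
    "1" = water,
    "2" = floor_props(superficial),
    "3" = floor_props(volumetric))
  model
}

#' Rugosity index of a surface region
#'
#' True 3-D surface area of the upward-facing skeletal surface within a
#' planar window, divided by the window's planar area; 1.0 for a flat plate
#' and >= 1 for any height-field surface. Computed on the triangulated
#' surface; triangles are attributed to the window by centroid. By default
#' only upward-facing triangles (seen from the water column above) count, so
#' closed meshes do not double-count their underside.
#'
#' @param mesh A [triangle_mesh()].
#' @param region List with `x = c(x0, x1)`, `y = c(y0, y1)` in mm; default is
#'   the full mesh footprint.
#' @param upward_only Count only triangles whose outward normal has a
#'   negative z component (z points down, so these face the water).
#' @return Dimensionless rugosity index.
#' @export
rugosity_index <- function(mesh, region = NULL, upward_only = TRUE) {
  v <- mesh$vertices
  if (is.null(region))
    region <- list(x = range(v[, 1]), y = range(v[, 2]))
  fx <- range(v[, 1]); fy <- range(v[, 2])
  if (region$x[1] < fx[1] - 1e-9 || region$x[2] > fx[2] + 1e-9 ||
      region$y[1] < fy[1] - 1e-9 || region$y[2] > fy[2] + 1e-9)
    stop("region extends outside the mesh footprint")
  f <- mesh$faces
  cx <- (v[f[, 1], 1] + v[f[, 2], 1] + v[f[, 3], 1]) / 3
  cy <- (v[f[, 1], 2] + v[f[, 2], 2] + v[f[, 3], 2]) / 3
  inside <- cx >= region$x[1] & cx <= region$x[2] &
    cy >= region$y[1] & cy <= region$y[2]
  if (upward_only) {
    e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    inside <- inside & nz < 0
  }
  area3d <- sum(mesh_face_areas(mesh)[inside])
  planar <- diff(region$x) * diff(region$y)
  area3d / planar
}
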