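#' Write / read a 3-D volume as NRRD
#'
#' Minimal single-file NRRD (raw little-endian encoding) for caching label
#' grids and fluence volumes between pipeline stages.
#'
#' @param x 3-D numeric or integer array.
#' @param path Output path.
#' @param spacings Voxel spacings, mm.
#' @export
write_nrrd <- function(x, path, spacings = c(1, 1, 1)) {
  stopifnot(length(dim(x)) == 3)
  type <- if (is.integer(x)) "int32" else "double"
  hdr <- paste0(
    "NRRD0004\n",
    "type: ", type, "\n",
    "dimension: 3\n",
    "sizes: ", paste(dim(x), collapse = " "), "\n",
    "spacings: ", paste(format(spacings, scientific = FALSE), collapse = " "), "\n",
    "encoding: raw\n",
    "endian: little\n\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(as.vector(x), con, size = if (type == "int32") 4L else 8L,
           endian = "little")
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    hdr <- c(hdr, ln)
  }
  field <- function(name) {
    ln <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^", name, ": "), "", ln[1])
  }
  sizes <- as.integer(strsplit(field("sizes"), " ")[[1]])
  type <- field("type")
  n <- prod(sizes)
  dat <- if (type == "int32") {
    readBin(con, "integer", n, size = 4, endian = "little")
  } else {
    readBin(con, "numeric", n, size = 8, endian = "little")
  }
  out <- array(dat, dim = sizes)
  sp <- field("spacings")
  if (!is.null(sp)) attr(out, "spacings") <- as.numeric(strsplit(sp, " ")[[1]])
  out
}

#' Save / load a voxel model (NRRD labels + JSON sidecar)
#'
#' @param model A [voxel_model()].
#' @param path Base path; writes `<path>.nrrd` and `<path>.json`.
#' @export
write_voxel_model <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for voxel-model sidecars")
  write_nrrd(model$labels, paste0(path, ".nrrd"),
             spacings = rep(model$pitch_mm, 3))
  side <- list(pitch_mm = model$pitch_mm, origin = model$origin,
               property_map = lapply(model$property_map, unclass))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_voxel_model
#' @export
read_voxel_model <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for voxel-model sidecars")
  lab <- read_nrrd(paste0(path, ".nrrd"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pm <- lapply(side$property_map, function(p)
    optical_properties(p$mu_a, p$mu_s, p$g, p$n))
  voxel_model(array(as.integer(lab), dim = dim(lab)), side$pitch_mm,
              origin = side$origin, property_map = pm)
}

#' Read a YAML run configuration
#'
#' Reads `instrument:` (passed to [instrument_constants()]) and
#' `simulation:` (passed to [simulation_config()]) sections; missing
#' sections fall back to defaults.
#'
#' @param path YAML file.
#' @return List with `instrument` and `simulation` objects.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read run configurations")
  cfg <- yaml::read_yaml(path)
  inst <- do.call(instrument_constants, as.list(cfg$instrument))
  sim <- do.call(simulation_config, as.list(cfg$simulation))
  list(instrument = inst, simulation = sim)
}
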