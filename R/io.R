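#' Write an image series as NIfTI plus a JSON sidecar
#'
#' The voxel array goes to a NIfTI file and the acquisition metadata (axis
#' kind and values, repeat count, pixel size, optional provenance note) to a
#' JSON sidecar next to it (`<stem>.json`). The pair round-trips losslessly
#' through [read_series()].
#'
#' @param series an [image_series()].
#' @param path output NIfTI path (`.nii` or `.nii.gz`).
#' @param provenance optional free-text provenance note stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, provenance = NULL) {
  if (!inherits(series, "image_series")) stop("not an image_series")
  RNifti::writeNifti(RNifti::asNifti(series$data), path, datatype = "double")
  sidecar <- list(
    axis = series$axis,
    values = series$values,
    repeats = series$repeats,
    pixel_size_mm = series$pixel_size_mm)
  if (!is.null(provenance)) sidecar$provenance <- provenance
  jsonlite::write_json(sidecar, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(stem, ".json")
}

#' Read an image series written by [write_series()]
#'
#' @param path NIfTI path; the JSON sidecar `<stem>.json` must be present.
#' @return an [image_series()].
#' @export
read_series <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path))
    stop(sprintf("missing sidecar JSON: %s", sc_path), call. = FALSE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  vol <- RNifti::readNifti(path)
  vol <- array(as.vector(vol), dim = dim(vol))  # plain array, no NIfTI attrs
  if (length(dim(vol)) == 2L) vol <- array(vol, dim = c(dim(vol), 1L))
  nframes <- dim(vol)[3]
  declared <- length(sc$values) * sc$repeats
  if (declared != nframes)
    stop(sprintf(
      "sidecar declares %d axis values x %d repeats = %d frames but volume has %d",
      length(sc$values), sc$repeats, declared, nframes), call. = FALSE)
  image_series(vol, axis = sc$axis, values = sc$values,
               repeats = as.integer(sc$repeats),
               pixel_size_mm = sc$pixel_size_mm)
}

#' Write a 2D map (or mask) as NIfTI
#'
#' Masks (`logical` input) are stored as unsigned 8-bit, continuous maps as
#' double precision.
#'
#' @param map numeric or logical matrix.
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (is.logical(map)) {
    storage.mode(map) <- "integer"
    RNifti::writeNifti(RNifti::asNifti(map), path, datatype = "uint8")
  } else {
    RNifti::writeNifti(RNifti::asNifti(map), path, datatype = "double")
  }
  invisible(path)
}

#' Read a 2D map written by [write_map()]
#'
#' @param path NIfTI path.
#' @param as_mask coerce to logical.
#' @return numeric (or logical) matrix.
#' @export
read_map <- function(path, as_mask = FALSE) {
  m <- RNifti::readNifti(path)
  m <- array(as.vector(m), dim = dim(m))
  if (length(dim(m)) > 2L) m <- array(m, dim = dim(m)[1:2])
  if (as_mask) m <- m != 0
  m
}
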