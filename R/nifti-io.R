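#' Read a 3D NIfTI volume
#'
#' Reads a `.nii` / `.nii.gz` file into a [scalar_volume()].  Voxel sizes are
#' taken from the header `pixdim`; the B0 direction is not stored in NIfTI
#' headers, so it is read from an optional JSON sidecar (same path with the
#' NIfTI extension replaced by `.json`, key `b0_dir`) and otherwise defaults
#' to (0, 0, 1).  Spatial axes are used in file order; no reorientation to a
#' canonical frame is attempted.
#'
#' @param path path to a 3D NIfTI file.
#' @param expected_kind kind tag to validate and attach (see
#'   [scalar_volume()]).
#' @return A [scalar_volume()] of the requested kind.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, expected_kind = "generic") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop(sprintf("expected a 3D volume, got %dD: %s", length(d), path))
  pd <- RNifti::pixdim(img)[1:3]
  b0 <- c(0, 0, 1)
  sidecar <- sidecar_path(path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$b0_dir)) b0 <- as.numeric(meta$b0_dir)
  }
  grid <- voxel_grid(d, as.numeric(pd), b0)
  scalar_volume(array(as.numeric(img), d), grid, expected_kind)
}

#' Write a volume to NIfTI
#'
#' Voxel data are stored as 32-bit float (8-bit unsigned for masks); the
#' header carries the voxel size.  The B0 direction is written to a JSON
#' sidecar next to the file, since NIfTI has no standard slot for it.
#'
#' @param vol a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param sidecar write the JSON sidecar with `b0_dir` and `kind`
#'   (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, sidecar = TRUE) {
  stopifnot(inherits(vol, "scalar_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  datatype <- if (vol$kind == "mask") "uint8" else "float"
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$grid$voxel_size_mm
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = datatype)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("could not write NIfTI file: ", path)
  if (sidecar) {
    jsonlite::write_json(list(b0_dir = vol$grid$b0_dir, kind = vol$kind),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a multi-echo GRE acquisition to disk
#'
#' Stores magnitude and phase as two 4D NIfTI files plus a JSON sidecar with
#' echo times (seconds), field strength (tesla) and B0 direction.
#'
#' @param gre a [multi_echo_gre()].
#' @param prefix path prefix; writes `<prefix>_mag.nii.gz`,
#'   `<prefix>_phase.nii.gz`, `<prefix>.json`.
#' @param b0_tesla field strength recorded in the sidecar.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_gre <- function(gre, prefix, b0_tesla = 3) {
  stopifnot(inherits(gre, "multi_echo_gre"))
  mag_path <- paste0(prefix, "_mag.nii.gz")
  phase_path <- paste0(prefix, "_phase.nii.gz")
  pd <- gre$grid$voxel_size_mm
  mag_img <- RNifti::asNifti(Mod(gre$echoes))
  RNifti::pixdim(mag_img) <- c(pd, 1)
  RNifti::writeNifti(mag_img, mag_path, datatype = "float")
  phase_img <- RNifti::asNifti(Arg(gre$echoes))
  RNifti::pixdim(phase_img) <- c(pd, 1)
  RNifti::writeNifti(phase_img, phase_path, datatype = "float")
  meta <- list(te_s = gre$te_s, b0_tesla = b0_tesla,
               b0_dir = gre$grid$b0_dir)
  json_path <- paste0(prefix, ".json")
  jsonlite::write_json(meta, json_path, auto_unbox = FALSE, digits = NA)
  invisible(c(magnitude = mag_path, phase = phase_path, sidecar = json_path))
}

#' Read a multi-echo GRE acquisition written by [write_gre()]
#'
#' @param prefix path prefix used at write time.
#' @return A list with `gre` (a [multi_echo_gre()]) and `b0_tesla`.
#' @export
read_gre <- function(prefix) {
  mag <- RNifti::readNifti(paste0(prefix, "_mag.nii.gz"))
  phase <- RNifti::readNifti(paste0(prefix, "_phase.nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  d <- dim(mag)
  if (length(d) != 4L) stop("expected 4D magnitude/phase files")
  grid <- voxel_grid(d[1:3], as.numeric(RNifti::pixdim(mag)[1:3]),
                     as.numeric(meta$b0_dir))
  echoes <- array(as.numeric(mag), d) * exp(1i * array(as.numeric(phase), d))
  list(gre = multi_echo_gre(echoes, as.numeric(meta$te_s), grid),
       b0_tesla = as.numeric(meta$b0_tesla))
}
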