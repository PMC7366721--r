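#' Write a phantom volume to disk
#'
#' Writes the voxel volume as NIfTI-1 (`.nii` / `.nii.gz`, via RNifti) or
#' NRRD (`.nrrd`, raw little-endian encoding written directly), chosen by
#' file extension. Voxel values round-trip bit-exactly (stored as
#' double); spacing is carried in the format header. The fiducial
#' geometry (endpoints and true diameters) is echoed to a JSON sidecar
#' next to the volume so the ground truth travels with the image.
#'
#' @param phantom A [build_phantom()] result (or a list with `volume` and
#'   `spacing_mm`).
#' @param path Output file ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @param sidecar Write the JSON geometry sidecar (default `TRUE` when
#'   fiducials are present).
#' @return `path`, invisibly.
#' @export
write_volume <- function(phantom, path, sidecar = !is.null(phantom$fiducials)) {
  if (!nzchar(path %||% "")) abort("`path` must be a non-empty file path.")
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    v <- phantom$volume
    attr(v, "pixdim") <- phantom$spacing_mm
    RNifti::writeNifti(RNifti::asNifti(v, datatype = "double"), path)
  } else {
    write_nrrd(phantom$volume, phantom$spacing_mm, path)
  }
  if (isTRUE(sidecar)) {
    f <- phantom$fiducials
    side <- list(
      spacing_mm = phantom$spacing_mm,
      fiducials = purrr::pmap(f, function(location_id, kind, endpoint_a_mm,
                                          endpoint_b_mm, true_diameter_mm, ...) {
        list(location_id = location_id, kind = kind,
             endpoint_a_mm = endpoint_a_mm, endpoint_b_mm = endpoint_b_mm,
             true_diameter_mm = true_diameter_mm)
      })
    )
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a phantom volume from disk
#'
#' Counterpart of [write_volume()]; format auto-detected from the
#' extension. Only the volume part of the phantom is reconstructed (plus
#' the fiducial table when the JSON sidecar is present).
#'
#' @param path File ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return A list with `volume` (3-D array), `spacing_mm`, and `fiducials`
#'   (tibble or `NULL`).
#' @export
read_volume <- function(path) {
  if (!nzchar(path %||% "") || !file.exists(path))
    abort(paste0("volume file not found: '", path, "'"))
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1:3]
    volume <- array(as.numeric(img), dim = dim(img))
  } else {
    nr <- read_nrrd(path)
    volume <- nr$volume
    spacing <- nr$spacing_mm
  }
  fid <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = FALSE)
    fid <- fiducial_tibble_from_json(side$fiducials)
  }
  list(volume = volume, spacing_mm = as.numeric(spacing), fiducials = fid)
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  abort(paste0("unknown volume extension on '", path,
               "': expected .nii, .nii.gz or .nrrd"))
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii\\.gz$|\\.nii$|\\.nrrd$", "", path, ignore.case = TRUE),
         ".json")
}

fiducial_tibble_from_json <- function(lst) {
  tibble::tibble(
    location_id = purrr::map_int(lst, ~ as.integer(.x$location_id)),
    kind = purrr::map_chr(lst, "kind"),
    endpoint_a_mm = purrr::map(lst, ~ as.numeric(unlist(.x$endpoint_a_mm))),
    endpoint_b_mm = purrr::map(lst, ~ as.numeric(unlist(.x$endpoint_b_mm))),
    true_diameter_mm = purrr::map_dbl(lst, "true_diameter_mm")
  )
}

# Minimal NRRD (raw little-endian double, attached header). No NRRD reader
# exists in the R stack used here, so the few header fields needed for a
# lossless round-trip are handled directly.
write_nrrd <- function(volume, spacing_mm, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "NRRD0004",
    "# orbitometry phantom volume",
    "type: double",
    "dimension: 3",
    paste("sizes:", paste(dim(volume), collapse = " ")),
    paste("spacings:", paste(format(spacing_mm, digits = 17), collapse = " ")),
    "endian: little",
    "encoding: raw",
    ""
  )
  writeLines(header, con, sep = "\n")
  writeBin(as.numeric(volume), con, size = 8L, endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) abort("corrupt NRRD header: missing magic.")
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) abort("corrupt NRRD header: no end of header.")
    if (!nzchar(line)) break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  if (!identical(fields[["encoding"]], "raw") ||
      !identical(fields[["type"]], "double"))
    abort("unsupported NRRD: only raw double volumes are handled.")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  n <- prod(sizes)
  vals <- readBin(con, what = "double", n = n, size = 8L,
                  endian = fields[["endian"]] %||% "little")
  if (length(vals) != n) abort("corrupt NRRD: truncated data block.")
  list(volume = array(vals, dim = sizes), spacing_mm = spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
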