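# Volume data model and IO. A volume is a 3D scalar grid ordered
# (slice, row, column), with per-axis voxel size in micrometres and a dtype
# tag describing the intensity convention. Axial slices live on axis 1.

DTYPE_MAX <- c(uint8 = 255, uint16 = 65535)

#' Construct a Volume
#'
#' @param data 3D numeric array ordered (slice, row, column).
#' @param voxel_size_um voxel size in micrometres; scalar or length 3.
#' @param dtype_tag one of "uint8", "uint16", "float01".
#' @param meta named list of free-form metadata (modality, sample id, ...).
#' @return an object of class `bsr_volume`.
#' @export
new_volume <- function(data, voxel_size_um, dtype_tag = "float01",
                       meta = list()) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array ordered (slice, row, column)")
  if (any(dim(data) < 1L)) stop("all extents must be >= 1")
  storage.mode(data) <- "double"
  voxel_size_um <- rep(as.numeric(voxel_size_um), length.out = 3L)
  if (any(!is.finite(voxel_size_um)) || any(voxel_size_um <= 0))
    stop("voxel_size_um must be positive on every axis")
  dtype_tag <- match.arg(dtype_tag, c("uint8", "uint16", "float01"))
  if (dtype_tag == "float01") {
    rng <- range(data)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("float01 volumes must have values in [0, 1]")
  }
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 dtype_tag = dtype_tag, meta = meta),
            class = "bsr_volume")
}

#' @export
print.bsr_volume <- function(x, ...) {
  cat(sprintf("<bsr_volume> %s, extents %s (slice,row,col), voxel %s um\n",
              x$dtype_tag, paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size_um, 6), collapse = "x")))
  invisible(x)
}

#' @export
dim.bsr_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "bsr_volume")

as_volume_data <- function(x) if (is_volume(x)) x$data else x

#' Map an anatomical plane to a grid axis
#'
#' The grid is ordered (slice, row, column) with the axial plane on axis 1:
#' an axial slice is `data[s, , ]`. Coronal maps to axis 2, sagittal to
#' axis 3. This convention is fixed package-wide.
#'
#' @param plane "axial", "coronal" or "sagittal".
#' @return axis index (1, 2 or 3).
#' @export
plane_axis <- function(plane) {
  switch(match.arg(plane, c("axial", "coronal", "sagittal")),
         axial = 1L, coronal = 2L, sagittal = 3L)
}

infer_format <- function(path) {
  if (dir.exists(path)) return("tiff_stack")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff_stack"
  else if (ext %in% c("nii", "gz")) "nifti"
  else if (ext == "raw") "raw_json"
  else stop("cannot infer volume format from path: ", path)
}

#' Read a volume from disk
#'
#' Supported formats: `tiff_stack` (a multi-page TIFF file, or a directory of
#' one-slice TIFFs in lexicographic filename order, with an optional JSON
#' sidecar holding `voxel_size_um`), `nifti` (NIfTI-1 via RNifti; pixdim in mm
#' is converted to micrometres), and `raw_json` (little-endian raw values in
#' column-major (slice,row,col) order plus a mandatory JSON sidecar with
#' `shape`, `dtype` and `voxel_size_um`).
#'
#' @param path file or directory path.
#' @param format one of "auto", "tiff_stack", "nifti", "raw_json".
#' @return a [new_volume()] object; axis order is normalized to
#'   (slice, row, column).
#' @export
read_volume <- function(path, format = "auto") {
  format <- match.arg(format, c("auto", "tiff_stack", "nifti", "raw_json"))
  if (format == "auto") format <- infer_format(path)
  if (!file.exists(path) && !dir.exists(path))
    stop("no such file or directory: ", path)
  switch(format,
         tiff_stack = read_tiff_stack(path),
         nifti = read_nifti_volume(path),
         raw_json = read_raw_volume(path))
}

sidecar_path <- function(path) {
  if (dir.exists(path)) file.path(path, "volume.json")
  else paste0(tools::file_path_sans_ext(path), ".json")
}

read_tiff_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop("no TIFF slices found in ", path)
    slices <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(slices)) slices <- list(slices)
  }
  shp <- dim(slices[[1]])
  if (length(shp) != 2L) stop("TIFF slices must be single-channel 2D images")
  ok <- vapply(slices, function(s) identical(dim(s), shp), logical(1))
  if (!all(ok)) stop("inconsistent slice shapes in TIFF stack")
  data <- array(0, c(length(slices), shp))
  for (s in seq_along(slices)) data[s, , ] <- slices[[s]]
  mx <- max(data)
  dtype <- if (mx > 255) "uint16" else "uint8"
  vox <- 1
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    info <- jsonlite::read_json(sc, simplifyVector = TRUE)
    vox <- info$voxel_size_um %||% 1
    meta <- info$meta %||% list()
    if (!is.null(info$dtype)) dtype <- info$dtype
  }
  new_volume(data, vox, dtype, meta)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  pd <- RNifti::pixdim(img)[seq_len(3)] * 1000  # mm -> um
  # datatype codes are not reliably round-tripped, so infer the tag from the
  # stored values: integral volumes keep their 8/16-bit convention
  integral <- all(arr == round(arr))
  dtype <- if (integral && max(arr) > 255) "uint16"
           else if (integral && max(arr) > 1) "uint8" else "float01"
  if (dtype == "float01") arr <- clip01(arr)
  new_volume(arr, pd, dtype)
}

read_raw_volume <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("raw volume requires a JSON sidecar: ", sc)
  info <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("shape", "dtype", "voxel_size_um"))
    if (is.null(info[[f]])) stop("raw sidecar is missing field `", f, "`")
  shape <- as.integer(info$shape)
  n <- prod(shape)
  con <- file(path, "rb"); on.exit(close(con))
  vals <- switch(info$dtype,
    uint8 = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    uint16 = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                endian = "little")),
    float01 = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported raw dtype: ", info$dtype))
  new_volume(array(vals, shape), info$voxel_size_um, info$dtype,
             info$meta %||% list())
}

#' Write a volume to disk
#'
#' Integer volumes round-trip bit-exactly through every format. Writing a
#' `float01` volume to a TIFF stack is an error: convert first with
#' [from_float01()] so the quantization step is explicit.
#'
#' @param v a [new_volume()] object.
#' @param path destination file (or directory for a per-slice TIFF stack).
#' @param format one of "auto", "tiff_stack", "nifti", "raw_json".
#' @return `invisible(path)`.
#' @export
write_volume <- function(v, path, format = "auto") {
  stopifnot(is_volume(v))
  format <- match.arg(format, c("auto", "tiff_stack", "nifti", "raw_json"))
  if (format == "auto") format <- infer_format(path)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  switch(format,
         tiff_stack = write_tiff_stack(v, path),
         nifti = write_nifti_volume(v, path),
         raw_json = write_raw_volume(v, path))
  invisible(path)
}

write_sidecar <- function(v, path) {
  jsonlite::write_json(
    list(shape = dim(v$data), dtype = v$dtype_tag,
         voxel_size_um = v$voxel_size_um, meta = v$meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

write_tiff_stack <- function(v, path) {
  if (v$dtype_tag == "float01")
    stop("float01 volumes cannot be written to TIFF; convert with from_float01() first")
  bits <- if (v$dtype_tag == "uint8") 8L else 16L
  mx <- DTYPE_MAX[[v$dtype_tag]]
  d <- dim(v$data)
  pages <- lapply(seq_len(d[1]), function(s) {
    m <- v$data[s, , , drop = TRUE]
    if (d[2] == 1L || d[3] == 1L) m <- matrix(m, d[2], d[3])
    m / mx
  })
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    dir.create(path, showWarnings = FALSE)
    for (s in seq_along(pages))
      tiff::writeTIFF(pages[[s]],
                      file.path(path, sprintf("slice_%05d.tif", s)),
                      bits.per.sample = bits)
  }
  write_sidecar(v, path)
}

write_nifti_volume <- function(v, path) {
  dt <- switch(v$dtype_tag, uint8 = "uint8", uint16 = "uint16",
               float01 = "double")
  a <- v$data
  attr(a, "pixdim") <- v$voxel_size_um / 1000  # um -> mm
  img <- RNifti::asNifti(a)
  RNifti::writeNifti(img, path, datatype = dt)
}

write_raw_volume <- function(v, path) {
  con <- file(path, "wb"); on.exit(close(con))
  x <- as.vector(v$data)
  if (v$dtype_tag == "uint8") {
    writeBin(as.raw(as.integer(round(x))), con)
  } else if (v$dtype_tag == "uint16") {
    xi <- as.integer(round(x))
    b <- as.raw(rbind(xi %% 256L, xi %/% 256L))  # little-endian pairs
    writeBin(b, con)
  } else {
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  }
  write_sidecar(v, path)
}

#' Min-max (or percentile-clipped) normalization to 8-bit
#'
#' Linearly maps the intensity range (optionally clipped at the given
#' percentiles) to 0..255 with round-half-to-even. A constant volume maps to
#' all zeros rather than NaN so degenerate inputs cannot poison a pipeline.
#'
#' @param v a volume (or 3D array, taken as raw intensities).
#' @param clip_percentiles optional `c(lo, hi)` percentiles in (0, 100).
#' @return a uint8 volume.
#' @export
normalize_to_8bit <- function(v, clip_percentiles = NULL) {
  arr <- as_volume_data(v)
  if (!is.null(clip_percentiles)) {
    if (length(clip_percentiles) != 2L || clip_percentiles[1] < 0 ||
        clip_percentiles[2] > 100 || clip_percentiles[1] >= clip_percentiles[2])
      stop("clip_percentiles must satisfy 0 <= lo < hi <= 100")
    rng <- quantile(arr, clip_percentiles / 100, names = FALSE)
  } else rng <- range(arr)
  if (rng[2] <= rng[1]) {
    out <- array(0, dim(arr))
  } else {
    out <- round(pmin(pmax((arr - rng[1]) / (rng[2] - rng[1]), 0), 1) * 255)
  }
  vox <- if (is_volume(v)) v$voxel_size_um else 1
  meta <- if (is_volume(v)) v$meta else list()
  new_volume(out, vox, "uint8", meta)
}

#' Convert a volume to the float01 intensity convention
#'
#' Integer volumes are divided by their dtype maximum; float01 input passes
#' through unchanged.
#'
#' @param v a volume.
#' @return a float01 volume.
#' @export
to_float01 <- function(v) {
  stopifnot(is_volume(v))
  if (v$dtype_tag == "float01") return(v)
  new_volume(v$data / DTYPE_MAX[[v$dtype_tag]], v$voxel_size_um, "float01",
             v$meta)
}

#' Convert a float01 volume back to an integer dtype
#'
#' @param v a float01 volume.
#' @param dtype "uint8" or "uint16".
#' @return an integer volume; values are scaled by the dtype maximum and
#'   rounded half-to-even.
#' @export
from_float01 <- function(v, dtype = "uint8") {
  stopifnot(is_volume(v))
  dtype <- match.arg(dtype, c("uint8", "uint16"))
  mx <- DTYPE_MAX[[dtype]]
  x <- if (v$dtype_tag == "float01") v$data
       else v$data / DTYPE_MAX[[v$dtype_tag]]
  new_volume(pmax(pmin(round(x * mx), mx), 0), v$voxel_size_um, dtype, v$meta)
}
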