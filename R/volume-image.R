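#' Volumetric scalar image
#'
#' Container for a CT/CBCT-like scalar volume: a 3-D array plus voxel spacing
#' and physical origin. All physical coordinates in the package live in one
#' fixed patient-space convention: +x right, +y anterior, +z superior
#' (RAS-like); readers reorient NIfTI headers into it. A voxel is a cell of
#' size `spacing` centred at `origin + index * spacing` (zero-based index),
#' so voxel-count volumetry is exact by construction.
#'
#' Axial slices are the planes of constant z; `spacing[3]` is the slice
#' thickness. Volumes thicker than 1 mm per slice trigger a warning because
#' reliable orbital volumetry needs sub-millimetre sampling.
#'
#' @param data 3-D numeric array of intensities (HU-like for CT; arbitrary
#'   units for CBCT).
#' @param spacing numeric length-3 voxel spacing in mm, strictly positive.
#' @param origin numeric length-3 physical position (mm) of voxel (1,1,1).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  if (any(dim(data) < 2L)) stop("volume must have at least 2 voxels per axis")
  if (spacing[3] > 1.0)
    warning(sprintf(paste0("slice thickness %.3g mm exceeds 1 mm; orbital ",
                           "volumetry needs sub-millimetre slices"), spacing[3]))
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin,
                 axis_convention = "RAS"),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("volume_image: %s voxels, spacing %s mm, origin %s mm [%s]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              paste(format(x$origin, digits = 4), collapse = ", "),
              x$axis_convention))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' Physical coordinates of voxel indices
#' @param volume A `volume_image` (or any list with `spacing`/`origin`).
#' @param idx Nx3 matrix of 1-based voxel indices.
#' @return Nx3 matrix of physical points (mm) at the voxel centres.
#' @export
voxel_to_world <- function(volume, idx) {
  idx <- as.matrix(idx)
  sweep(sweep(idx - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' Voxel indices of physical coordinates
#' @param volume A `volume_image`.
#' @param points Nx3 matrix of physical points (mm).
#' @return Nx3 matrix of (fractional) 1-based voxel indices.
#' @export
world_to_voxel <- function(volume, points) {
  points <- as_points(points)
  sweep(sweep(points, 2, volume$origin, "-"), 2, volume$spacing, "/") + 1
}

#' Read a volumetric image (NIfTI or NRRD)
#'
#' NIfTI volumes are reoriented into the package's RAS-like convention when
#' the header carries a valid orientation. NRRD support covers raw-encoded
#' files with diagonal space directions.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(read_nrrd(path))
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop("unsupported volume format (need .nii, .nii.gz or .nrrd): ", path)
  img <- RNifti::readNifti(path)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(orient) && nzchar(orient) && orient != "RAS")
    RNifti::orientation(img) <- "RAS"
  xf <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume header carries no usable voxel spacing: ", path)
  origin <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  arr <- as.array(img)
  volume_image(array(as.double(arr), dim = dim(arr)), spacing, origin)
}

#' Write a volumetric image (NIfTI or NRRD)
#'
#' @param volume A [volume_image()].
#' @param path destination ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(write_nrrd(volume, path))
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop("unsupported volume format (need .nii, .nii.gz or .nrrd): ", path)
  arr <- volume$data
  attr(arr, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  m <- diag(c(volume$spacing, 1))
  m[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- minimal NRRD (raw encoding, diagonal space directions) ---------------

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header: ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(k) {
    if (is.null(fields[[k]])) stop("NRRD header missing required field '", k, "': ", path)
    fields[[k]]
  }
  if (as.integer(need("dimension")) != 3L) stop("only 3-D NRRD supported: ", path)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  enc <- tolower(need("encoding"))
  if (!enc %in% c("raw")) stop("only raw NRRD encoding supported, got ", enc)
  type <- tolower(need("type"))
  endian <- tolower(fields[["endian"]] %||% "little")
  spacing <- NULL
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(vecs) != 3L) stop("need 3 space direction vectors: ", path)
    dirs <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    offdiag <- dirs; diag(offdiag) <- 0
    if (max(abs(offdiag)) > 1e-9)
      stop("only axis-aligned (diagonal) NRRD space directions supported: ", path)
    spacing <- abs(diag(dirs))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (is.null(spacing) || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NRRD header carries no usable voxel spacing (volumetry impossible): ", path)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  what <- switch(type,
    "double" = list(what = "double", size = 8L),
    "float" = list(what = "double", size = 4L),
    "short" = , "int16" = list(what = "integer", size = 2L),
    "int" = , "int32" = list(what = "integer", size = 4L),
    "uchar" = , "uint8" = list(what = "integer", size = 1L),
    stop("unsupported NRRD type: ", type))
  vals <- readBin(con, what = what$what, n = n, size = what$size,
                  endian = if (endian == "big") "big" else "little",
                  signed = !(type %in% c("uchar", "uint8")))
  if (length(vals) != n) stop("truncated NRRD data: ", path)
  volume_image(array(as.double(vals), dim = sizes), spacing, origin)
}

write_nrrd <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by orbitqc",
           "type: double",
           "dimension: 3",
           "space: right-anterior-superior",
           paste0("sizes: ", paste(dim(volume$data), collapse = " ")),
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   volume$spacing[1], volume$spacing[2], volume$spacing[3]),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: raw",
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   volume$origin[1], volume$origin[2], volume$origin[3]),
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.double(volume$data), con, size = 8L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
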