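#' Segmentation parameters
#'
#' @param bone_threshold lower intensity bound classifying bone. 300 is a
#'   sensible HU-like default for CT; CBCT intensities are uncalibrated, so
#'   pass a modality-specific value there.
#' @param closing_radius_mm morphological closing radius applied to the bone
#'   mask before cavity filling; bridges fracture defects so the flood fill
#'   does not leak out of the cavity.
#' @param max_volume_ml sanity cap on the filled cavity: a fill larger than
#'   this is reported as a leak.
#' @param cavity_seed optional length-3 voxel index (1-based) inside the
#'   cavity; when `NULL` the seed is derived from the side's landmarks
#'   (midpoint of rim centre and apex).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(bone_threshold = 300, closing_radius_mm = 1.0,
                                max_volume_ml = 50, cavity_seed = NULL) {
  stopifnot(closing_radius_mm >= 0, max_volume_ml > 0)
  if (!is.null(cavity_seed)) {
    cavity_seed <- as.integer(cavity_seed)
    stopifnot(length(cavity_seed) == 3L)
  }
  structure(list(bone_threshold = bone_threshold,
                 closing_radius_mm = closing_radius_mm,
                 max_volume_ml = max_volume_ml,
                 cavity_seed = cavity_seed),
            class = "segmentation_params")
}

#' Threshold bone voxels
#'
#' Classifies every voxel with intensity at or above `bone_threshold` as
#' bone. No morphology is applied here.
#'
#' @param volume A [volume_image()].
#' @param params A [segmentation_params()].
#' @return Logical 3-D array congruent with `volume`.
#' @export
threshold_bone <- function(volume, params = segmentation_params()) {
  mask <- volume$data >= params$bone_threshold
  if (!any(mask)) stop("no bone above threshold ", params$bone_threshold)
  mask
}

# offsets (voxel units) of an ellipsoidal ball of physical radius r_mm
ball_offsets <- function(r_mm, spacing) {
  rv <- pmax(0L, as.integer(floor(r_mm / spacing)))
  if (all(rv == 0L)) return(matrix(0L, 1, 3))
  g <- as.matrix(expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2], dz = -rv[3]:rv[3]))
  phys <- sweep(g, 2, spacing, "*")
  keep <- rowSums(phys^2) <= r_mm^2 + 1e-9
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

# morphological closing of a binary array with a ball of radius r_mm
binary_close <- function(mask, spacing, r_mm) {
  if (r_mm <= 0) return(mask)
  dims <- dim(mask)
  off <- ball_offsets(r_mm, spacing)
  dil <- .binary_dilate(as.logical(mask), dims, off)
  ero <- !.binary_dilate(!dil, dims, off)
  array(ero, dim = dims)
}

#' Segment one orbital cavity by bounded flood fill
#'
#' Seeded 6-connected flood fill of non-bone voxels, bounded by the
#' morphologically closed bone mask and, optionally, by an anterior stop
#' plane at the orbital rim (without it, the open rim lets the fill spill
#' into the rest of the head, exactly as leaving the anterior border
#' unmarked would in slice-wise manual segmentation). The result is a
#' single 6-connected component and is *not* yet anterior-clipped.
#'
#' A fill exceeding `max_volume_ml` is reported as a leak: the cavity has
#' escaped through a wall defect and the caller should raise
#' `closing_radius_mm`.
#'
#' @param volume A [volume_image()].
#' @param bone_mask logical array from [threshold_bone()].
#' @param params A [segmentation_params()].
#' @param side `"right"` or `"left"` tag for the resulting mask.
#' @param landmarks optional [landmark_set()]; used to derive the cavity
#'   seed (and the stop plane when `stop_plane = "landmarks"`).
#' @param stop_plane `NULL`, a [plane3()] bounding the fill anteriorly, or
#'   `"landmarks"` to build the L/M rim plane from `landmarks`.
#' @return An object of class `orbit_mask`: logical `mask`, `spacing`,
#'   `origin`, `side`, and `clipped = FALSE`.
#' @export
segment_cavity <- function(volume, bone_mask, params = segmentation_params(),
                           side = c("right", "left"), landmarks = NULL,
                           stop_plane = NULL) {
  side <- match.arg(side)
  dims <- dim(volume$data)
  stopifnot(identical(dim(bone_mask), dims))
  closed <- binary_close(bone_mask, volume$spacing, params$closing_radius_mm)
  seed <- params$cavity_seed
  if (is.null(seed)) {
    if (is.null(landmarks)) stop("need either params$cavity_seed or landmarks")
    s <- side_landmarks(landmarks, side)
    if (is.null(s$apex)) stop("seed derivation needs an apex landmark")
    p <- (s$L + s$M) / 2 * 0.5 + s$apex * 0.5
    seed <- as.integer(round(world_to_voxel(volume, p)))
  }
  if (any(seed < 1L) || any(seed > dims)) stop("cavity seed outside volume")
  if (closed[seed[1], seed[2], seed[3]])
    stop("cavity seed falls inside the (closed) bone mask")
  blocked <- closed
  if (identical(stop_plane, "landmarks")) {
    if (is.null(landmarks)) stop("stop_plane = 'landmarks' needs landmarks")
    s <- side_landmarks(landmarks, side)
    stop_plane <- anterior_clip_plane(s$L, s$M)
  }
  if (!is.null(stop_plane)) {
    stopifnot(inherits(stop_plane, "plane3"))
    d <- plane_signed_distance(stop_plane, voxel_centers(volume))
    blocked <- blocked | array(d >= 0, dim = dims)
  }
  max_vox <- params$max_volume_ml * 1000 / prod(volume$spacing)
  res <- .flood_fill6(as.logical(blocked), dims, seed, max_vox)
  if (res$leaked)
    stop("leak detected: cavity fill exceeded ", params$max_volume_ml,
         " ml; increase closing_radius_mm to bridge the wall defect")
  structure(list(mask = array(res$mask, dim = dims), spacing = volume$spacing,
                 origin = volume$origin, side = side, clipped = FALSE),
            class = "orbit_mask")
}

#' @export
print.orbit_mask <- function(x, ...) {
  cat(sprintf("orbit_mask (%s side%s): %d voxels, %.2f ml\n", x$side,
              if (x$clipped) ", clipped" else "", sum(x$mask),
              sum(x$mask) * prod(x$spacing) / 1000))
  invisible(x)
}

# physical coordinates of every voxel centre (Nx3, column-major order);
# accepts a volume_image, orbit_mask or anything with spacing/origin + array
voxel_centers <- function(volume) {
  dims <- dim(volume$data %||% volume$mask)
  cbind(rep(volume$origin[1] + (seq_len(dims[1]) - 1) * volume$spacing[1],
            times = dims[2] * dims[3]),
        rep(rep(volume$origin[2] + (seq_len(dims[2]) - 1) * volume$spacing[2],
                each = dims[1]), times = dims[3]),
        rep(volume$origin[3] + (seq_len(dims[3]) - 1) * volume$spacing[3],
            each = dims[1] * dims[2]))
}

#' Anterior clipping plane through the orbital rim points
#'
#' The anterior border of the orbit is the straight line through L (lateral
#' orbital rim) and M (medial orbital rim) drawn on every axial slice;
#' sweeping that line along the slice axis yields a plane containing L, M
#' and the axial direction. The normal is oriented anteriorly (+y in the
#' package's patient convention).
#'
#' @param L,M lateral and medial orbital rim points (mm).
#' @param axial_direction unit vector of the slice axis (default +z).
#' @return A [plane3()] with anteriorly oriented normal.
#' @export
anterior_clip_plane <- function(L, M, axial_direction = c(0, 0, 1)) {
  L <- as.numeric(L); M <- as.numeric(M)
  v <- M - L
  if (sqrt(sum(v^2)) < 1e-9) stop("L and M coincide")
  n <- c(v[2] * axial_direction[3] - v[3] * axial_direction[2],
         v[3] * axial_direction[1] - v[1] * axial_direction[3],
         v[1] * axial_direction[2] - v[2] * axial_direction[1])
  if (sqrt(sum(n^2)) < 1e-9)
    stop("axial direction is parallel to the L-M line (degenerate cross product)")
  if (n[2] < 0) n <- -n  # anterior = +y
  plane3(n, L)
}

#' Clip an orbit mask at the anterior border
#'
#' Removes voxels whose centres lie anterior to the rim plane (signed
#' distance >= 0, i.e. centres exactly on the plane go with the anterior
#' side) and sets the `clipped` flag.
#'
#' @param mask An `orbit_mask` from [segment_cavity()].
#' @param plane An anteriorly oriented [plane3()] (from
#'   [anterior_clip_plane()]).
#' @return The clipped `orbit_mask`.
#' @export
clip_anterior <- function(mask, plane) {
  stopifnot(inherits(mask, "orbit_mask"), inherits(plane, "plane3"))
  if (plane$normal[2] < 0)
    stop("clip plane normal must be oriented anteriorly (+y)")
  d <- plane_signed_distance(plane, voxel_centers(mask))
  keep <- array(d < 0, dim = dim(mask$mask))
  out <- mask
  out$mask <- mask$mask & keep
  if (!any(out$mask)) stop("anterior clipping removed the entire mask")
  out$clipped <- TRUE
  out
}

#' Voxel-count volume of a clipped orbit mask
#'
#' Volume = (number of mask voxels) x (voxel cell volume), reported in ml
#' (1 ml = 1000 mm^3). The count is exact; there is no partial-volume
#' weighting.
#'
#' @param mask A clipped `orbit_mask` (or a plain logical array when
#'   `spacing` is supplied).
#' @param spacing voxel spacing in mm; taken from `mask` when absent.
#' @return Volume in ml.
#' @export
compute_volume <- function(mask, spacing = NULL) {
  if (inherits(mask, "orbit_mask")) {
    if (!mask$clipped)
      stop("mask must be anterior-clipped before volumetry (see clip_anterior)")
    spacing <- mask$spacing
    m <- mask$mask
  } else {
    if (is.null(spacing)) stop("spacing required for a plain mask array")
    m <- mask
  }
  # plain double products (not prod(), which accumulates in extended
  # precision) so the result is bit-identical to count * cell volume
  sum(m) * ((spacing[1] * spacing[2]) * spacing[3]) / 1000
}

#' Per-axial-slice area and cumulative volume profile
#'
#' One row per axial slice (constant z): marked pixel count, area in mm^2,
#' slice subvolume and cumulative volume in ml. The per-slice voxel counts
#' partition the total count exactly; the subvolumes sum to
#' [compute_volume()] (bit-exactly whenever the cell volume is exactly
#' representable, e.g. at 0.5 or 1 mm isotropic spacing).
#'
#' @param mask A clipped `orbit_mask`.
#' @return A data.frame with columns `slice`, `n_voxels`, `area_mm2`,
#'   `subvolume_ml`, `cumulative_ml`.
#' @export
per_slice_profile <- function(mask) {
  stopifnot(inherits(mask, "orbit_mask"))
  if (!mask$clipped) stop("mask must be anterior-clipped first")
  counts <- apply(mask$mask, 3, sum)
  area <- counts * mask$spacing[1] * mask$spacing[2]
  sub <- counts * prod(mask$spacing) / 1000
  data.frame(slice = seq_along(counts), n_voxels = as.integer(counts),
             area_mm2 = area, subvolume_ml = sub, cumulative_ml = cumsum(sub))
}
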