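#' Names of the nine orbital wall regions
#'
#' The three walls analysed (medial wall, floor, lateral wall — the roof is
#' kept apart) crossed with the anterior/central/posterior thirds of the
#' orbital depth.
#' @return Character vector of 9 region names, e.g. `"floor_anterior"`.
#' @export
wall_region_names <- function() {
  as.vector(outer(c("medial", "floor", "lateral"),
                  c("anterior", "central", "posterior"), paste, sep = "_"))
}

#' Region labeling container
#' @param label character vector of per-vertex labels.
#' @return Object of class `region_labeling`.
#' @export
region_labeling <- function(label) {
  structure(list(label = as.character(label)), class = "region_labeling")
}

#' @export
print.region_labeling <- function(x, ...) {
  print(table(x$label))
  invisible(x)
}

# orbital axis frame from landmarks: origin at the rim centre, `axis`
# pointing into the orbit (rim centre -> apex), `down`/`medial` unit
# vectors spanning the rim plane
orbital_frame <- function(template, landmarks, side, mirror_plane,
                          rim_plane = NULL) {
  s <- side_landmarks(landmarks, side)
  rim_center <- (s$L + s$M) / 2
  if (is.null(rim_plane)) rim_plane <- anterior_clip_plane(s$L, s$M)
  apex <- s$apex
  if (is.null(apex)) {
    # deepest template point measured from the rim plane (most posterior)
    d <- -plane_signed_distance(rim_plane, template$vertices)
    if (max(d) <= 0) stop("apex landmark missing and not derivable from the template")
    apex <- template$vertices[which.max(d), ]
  }
  axis <- apex - rim_center
  depth <- sqrt(sum(axis^2))
  if (depth <= 0) stop("degenerate orbital axis (apex at the rim centre)")
  axis <- axis / depth
  up <- c(0, 0, 1)  # superior in the fixed patient convention
  up <- up - sum(up * axis) * axis
  if (sqrt(sum(up^2)) < 1e-6) stop("orbital axis is parallel to the z axis")
  up <- up / sqrt(sum(up^2))
  # medial = toward the midsagittal plane
  to_mid <- -sign(plane_signed_distance(mirror_plane, rim_center))
  medial <- to_mid * mirror_plane$normal
  medial <- medial - sum(medial * axis) * axis
  medial <- medial / sqrt(sum(medial^2))
  list(rim_center = rim_center, apex = apex, axis = axis, depth = depth,
       up = up, medial = medial, rim_plane = rim_plane)
}

#' Classify template vertices into orbital walls
#'
#' Vertices are classified by their angular sector around the orbital axis
#' (rim centre to apex): floor = inferior sector, roof = superior sector,
#' medial wall = sector facing the midsagittal plane, lateral wall = the
#' opposite one. With the default 45 degree half-angles this is an argmax
#' over the four cardinal directions; unequal half-angles bias the
#' boundaries accordingly. Vertices within `rim_band_mm` of the rim plane
#' are labeled `rim`; anything anterior of the rim plane is `unassigned`.
#'
#' @param template A [surface_mesh()] of the (mirrored) orbital cavity.
#' @param landmarks A [landmark_set()] carrying the side's L/M (and
#'   ideally apex) landmarks.
#' @param mirror_plane The midsagittal [plane3()].
#' @param side which side the template represents (after mirroring, the
#'   affected side).
#' @param half_angles_deg named numeric vector of sector half-angles for
#'   `floor`, `roof`, `medial`, `lateral` (default 45 each).
#' @param rim_band_mm depth of the anterior band labeled `rim`.
#' @return A [region_labeling()] with labels in
#'   `{medial, floor, lateral, roof, rim, unassigned}` plus the frame used
#'   (attribute `frame`).
#' @export
label_walls <- function(template, landmarks, mirror_plane,
                        side = c("right", "left"),
                        half_angles_deg = c(floor = 45, roof = 45,
                                            medial = 45, lateral = 45),
                        rim_band_mm = 1.5) {
  side <- match.arg(side)
  fr <- orbital_frame(template, landmarks, side, mirror_plane)
  v <- sweep(template$vertices, 2, fr$rim_center)
  ax_comp <- as.numeric(v %*% fr$axis)
  radial <- v - outer(ax_comp, fr$axis)
  rl <- sqrt(rowSums(radial^2))
  rl[rl == 0] <- 1
  rhat <- radial / rl
  dirs <- rbind(floor = -fr$up, roof = fr$up, medial = fr$medial,
                lateral = -fr$medial)
  ang <- sapply(rownames(dirs), function(nm) {
    cs <- pmin(1, pmax(-1, as.numeric(rhat %*% dirs[nm, ])))
    acos(cs) * 180 / pi / half_angles_deg[[nm]]
  })
  label <- rownames(dirs)[apply(ang, 1, which.min)]
  depth <- -plane_signed_distance(fr$rim_plane, template$vertices)
  label[depth >= 0 & depth < rim_band_mm] <- "rim"
  label[depth < 0] <- "unassigned"
  out <- region_labeling(label)
  attr(out, "frame") <- fr
  out
}

#' Subdivide wall labels into anterior/central/posterior thirds
#'
#' Each wall's vertices are split by normalised orbital depth
#' `d = (distance behind the rim plane) / (apex depth)` into the anterior
#' `[0, 1/3)`, central `[1/3, 2/3)` and posterior `[2/3, ...]` thirds
#' (boundaries closed on the right: a vertex exactly at 1/3 is central).
#' Roof, rim and unassigned labels pass through unchanged.
#'
#' @param labeling A [region_labeling()] from [label_walls()] (carries the
#'   orbital frame), or any labeling when `rim_plane` and `apex` are given.
#' @param template The labeled [surface_mesh()].
#' @param rim_plane,apex optional explicit geometry overriding the frame
#'   stored in `labeling`.
#' @return A [region_labeling()] with the nine wall regions.
#' @export
split_thirds <- function(labeling, template, rim_plane = NULL, apex = NULL) {
  stopifnot(inherits(labeling, "region_labeling"))
  fr <- attr(labeling, "frame")
  if (is.null(rim_plane)) rim_plane <- fr$rim_plane
  if (is.null(apex)) apex <- fr$apex
  if (is.null(rim_plane) || is.null(apex))
    stop("need a rim plane and apex (run label_walls first or pass them)")
  apex_depth <- -plane_signed_distance(rim_plane, matrix(apex, 1))
  if (apex_depth <= 0) stop("apex depth is not positive")
  d <- -plane_signed_distance(rim_plane, template$vertices) / apex_depth
  third <- ifelse(d < 1 / 3, "anterior", ifelse(d < 2 / 3, "central", "posterior"))
  label <- labeling$label
  wall <- label %in% c("medial", "floor", "lateral")
  label[wall] <- paste(label[wall], third[wall], sep = "_")
  out <- region_labeling(label)
  attr(out, "frame") <- fr
  out
}

#' Transition-zone band between medial wall and floor
#'
#' The junction of the medial orbital wall and the orbital floor is a
#' clinically critical reconstruction area; this returns the vertices
#' within `band_mm` of the medial/floor sector boundary as an additional,
#' clearly separated selection (it does not alter the nine-region
#' partition).
#'
#' @param labeling A wall [region_labeling()] (before or after thirds).
#' @param template The labeled [surface_mesh()].
#' @param band_mm half-width of the band (default 2 mm).
#' @return Logical per-vertex selection.
#' @export
transition_zone <- function(labeling, template, band_mm = 2) {
  fr <- attr(labeling, "frame")
  if (is.null(fr)) stop("labeling carries no orbital frame; run label_walls")
  v <- sweep(template$vertices, 2, fr$rim_center)
  ax_comp <- as.numeric(v %*% fr$axis)
  radial <- v - outer(ax_comp, fr$axis)
  rl <- sqrt(rowSums(radial^2))
  # boundary direction halfway between -up (floor) and medial
  bdir <- (-fr$up + fr$medial)
  bdir <- bdir / sqrt(sum(bdir^2))
  base <- grepl("^(medial|floor)", labeling$label)
  # arc distance from the sector boundary
  cs <- pmin(1, pmax(-1, as.numeric((radial / pmax(rl, 1e-12)) %*% bdir)))
  arc <- acos(cs) * rl
  base & arc <= band_mm
}

#' Segment radioopaque implant material
#'
#' Titanium mesh appears far above bone intensity; voxels at or above
#' `implant_threshold` form the implant mask, filtered to connected
#' components of at least `min_voxels` (6-connectivity). An empty result
#' (e.g. a pre-operative scan) yields a warning and an empty mask, not an
#' error.
#'
#' @param volume A post-operative [volume_image()].
#' @param implant_threshold intensity threshold above bone (default 2000
#'   for the phantom intensity model: bone 1200, implant 3000).
#' @param min_voxels smallest component kept.
#' @return Object of class `implant_mask`: logical `mask`, `spacing`,
#'   `origin`, `n_components`, `n_voxels`.
#' @export
segment_implant <- function(volume, implant_threshold = 2000, min_voxels = 20L) {
  raw <- volume$data >= implant_threshold
  dims <- dim(raw)
  n_comp <- 0L
  out <- array(FALSE, dims)
  if (any(raw)) {
    remaining <- raw
    comp_sizes <- integer()
    while (any(remaining)) {
      seedlin <- which(remaining)[1]
      seed <- arrayInd(seedlin, dims)[1, ]
      fill <- .flood_fill6(as.logical(!remaining), dims, as.integer(seed), Inf)
      comp <- array(fill$mask, dims)
      comp_sizes <- c(comp_sizes, sum(comp))
      if (sum(comp) >= min_voxels) {
        out <- out | comp
        n_comp <- n_comp + 1L
      }
      remaining <- remaining & !comp
    }
  }
  if (!any(out))
    warning("no implant material at or above intensity ", implant_threshold,
            " (empty implant mask)")
  structure(list(mask = out, spacing = volume$spacing, origin = volume$origin,
                 n_components = n_comp, n_voxels = sum(out)),
            class = "implant_mask")
}

#' Per-region implant coverage
#'
#' For each of the nine wall regions, the fraction of the region's surface
#' area whose vertices lie within `projection_distance_mm` of an implant
#' voxel (area-weighted by per-vertex Voronoi areas). Proximity is
#' evaluated by dilating the implant mask by a ball of the projection
#' radius and testing each vertex's containing voxel.
#'
#' @param labeling A nine-region [region_labeling()].
#' @param template The labeled [surface_mesh()] (same frame as the
#'   implant mask).
#' @param implant An [segment_implant()] result.
#' @param projection_distance_mm capture radius (default 2 mm: the implant
#'   sits on or just behind the reconstructed wall surface).
#' @return data.frame with `region`, `area_mm2`, `covered_area_mm2`,
#'   `coverage` for the nine wall regions.
#' @export
implant_coverage <- function(labeling, template, implant,
                             projection_distance_mm = 2) {
  stopifnot(inherits(implant, "implant_mask"), projection_distance_mm >= 0)
  lab <- labeling$label
  stopifnot(length(lab) == nrow(template$vertices))
  near <- rep(FALSE, nrow(template$vertices))
  if (any(implant$mask)) {
    off <- ball_offsets(projection_distance_mm, implant$spacing)
    dil <- array(.binary_dilate(as.logical(implant$mask), dim(implant$mask), off),
                 dim(implant$mask))
    idx <- round(world_to_voxel(implant, template$vertices))
    dims <- dim(implant$mask)
    inb <- idx[, 1] >= 1 & idx[, 2] >= 1 & idx[, 3] >= 1 &
      idx[, 1] <= dims[1] & idx[, 2] <= dims[2] & idx[, 3] <= dims[3]
    lin <- (idx[inb, 3] - 1) * dims[1] * dims[2] + (idx[inb, 2] - 1) * dims[1] +
      idx[inb, 1]
    near[inb] <- dil[lin]
  }
  va <- vertex_areas(template)
  rows <- lapply(wall_region_names(), function(rg) {
    sel <- lab == rg
    area <- sum(va[sel])
    cov_area <- sum(va[sel & near])
    data.frame(region = rg, area_mm2 = area, covered_area_mm2 = cov_area,
               coverage = if (area > 0) cov_area / area else 0)
  })
  do.call(rbind, rows)
}
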