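#' Signed minimal perpendicular distance map
#'
#' For every template vertex, the distance to the nearest point on the
#' target surface (vertex, edge and face-interior candidates all
#' considered), signed by the target surface orientation at the foot point
#' (angle-weighted pseudonormals). Sign convention: **positive** means the
#' reconstructed (target) surface lies *outside* the template cavity —
#' displaced toward bone, i.e. local enlargement; **negative** means it
#' lies inside, toward the globe. Template vertices with no target triangle
#' within `max_correspondence_mm` are flagged missing (`NA`), never zero.
#'
#' Both meshes must already be in the same frame: transform the template by
#' the [icp_register()] result first.
#'
#' @param template A [surface_mesh()] (registered mirror template).
#' @param target A [surface_mesh()] (reconstructed side).
#' @param max_correspondence_mm distance cap beyond which a vertex is
#'   flagged missing (default 10 mm).
#' @return An object of class `deviation_map`: numeric `deviation_mm` (one
#'   per template vertex, `NA` = missing), logical `missing`, and the
#'   unsigned `distance_mm`.
#' @export
signed_distance <- function(template, target, max_correspondence_mm = 10) {
  stopifnot(inherits(template, "surface_mesh"), inherits(target, "surface_mesh"),
            max_correspondence_mm > 0)
  cp <- .closest_point_mesh(target$vertices, target$faces, template$vertices,
                            max_correspondence_mm)
  # raw sign is positive when the template vertex lies outside the target
  # cavity; the reported convention is about where the *target* lies
  # relative to the template, hence the flip.
  dev <- -cp$signed_dist
  structure(list(deviation_mm = dev, missing = !is.finite(dev),
                 distance_mm = cp$dist),
            class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  v <- x$deviation_mm[!x$missing]
  cat(sprintf(paste0("deviation_map: %d vertices (%.1f%% missing), mean %.3f ",
                     "mm, sd %.3f mm, max |dev| %.3f mm\n"),
              length(x$deviation_mm), 100 * mean(x$missing),
              mean(v), stats::sd(v), max(abs(v))))
  invisible(x)
}

#' Color-code a deviation map
#'
#' Symmetric diverging colormap on the deviation scale: green at 0 (no
#' difference from the planned shape), red at `+clamp_mm`, blue at
#' `-clamp_mm`, linearly interpolated in between and saturated beyond.
#' Missing vertices are grey.
#'
#' @param map A [signed_distance()] result.
#' @param clamp_mm display clamp in mm (default 1.5 mm, the scale on which
#'   reconstruction deviations are clinically read).
#' @return Nx3 matrix of RGB values in [0,1].
#' @export
colorize <- function(map, clamp_mm = 1.5) {
  stopifnot(inherits(map, "deviation_map"), clamp_mm > 0)
  t <- pmin(1, pmax(-1, map$deviation_mm / clamp_mm))
  rgb <- cbind(red = pmax(0, t), green = 1 - abs(t), blue = pmax(0, -t))
  rgb[map$missing, ] <- 0.5
  rgb
}

#' Attach a deviation map (and colors) to a mesh
#'
#' Convenience wrapper so a colored deviation surface can be written to
#' PLY in one step.
#'
#' @param mesh the template [surface_mesh()] the map was computed on.
#' @param map A [signed_distance()] result.
#' @param clamp_mm passed to [colorize()].
#' @return The mesh with `scalar` (deviation, mm) and `color` channels.
#' @export
apply_deviation <- function(mesh, map, clamp_mm = 1.5) {
  stopifnot(nrow(mesh$vertices) == length(map$deviation_mm))
  surface_mesh(mesh$vertices, mesh$faces, scalar = map$deviation_mm,
               color = colorize(map, clamp_mm))
}

#' Per-region deviation summary
#'
#' Signed mean, SD, peak absolute deviation, vertex count and missing
#' fraction for every region label. Missing vertices are excluded from the
#' moments and reported via `missing_fraction`; a region with no valid
#' vertex is reported as empty (NA moments), not an error.
#'
#' @param map A [signed_distance()] result.
#' @param labels A [region_labeling()] (or plain character vector) covering
#'   the template vertices.
#' @param regions which labels to report; defaults to all present plus the
#'   nine wall regions.
#' @return A data.frame with one row per region: `region`, `n_vertices`,
#'   `n_valid`, `missing_fraction`, `mean_mm`, `sd_mm`, `max_abs_mm`, and
#'   `peak_abs_mm` (99th percentile of the absolute deviation — a peak
#'   estimate robust to isolated mesh-discretisation outliers).
#' @export
deviation_summary <- function(map, labels, regions = NULL) {
  lab <- if (inherits(labels, "region_labeling")) labels$label else
    as.character(labels)
  stopifnot(length(lab) == length(map$deviation_mm))
  if (is.null(regions))
    regions <- union(wall_region_names(), sort(unique(lab)))
  rows <- lapply(regions, function(rg) {
    sel <- lab == rg
    v <- map$deviation_mm[sel & !map$missing]
    data.frame(region = rg, n_vertices = sum(sel), n_valid = length(v),
               missing_fraction = if (sum(sel) > 0) 1 - length(v) / sum(sel) else NA_real_,
               mean_mm = if (length(v) > 0) mean(v) else NA_real_,
               sd_mm = if (length(v) > 1) stats::sd(v) else
                 if (length(v) == 1) 0 else NA_real_,
               max_abs_mm = if (length(v) > 0) max(abs(v)) else NA_real_,
               peak_abs_mm = if (length(v) > 0)
                 unname(stats::quantile(abs(v), 0.99, type = 7)) else NA_real_)
  })
  do.call(rbind, rows)
}
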