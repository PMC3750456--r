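#' Extract the cavity surface from an orbit mask
#'
#' Marching-tetrahedra isosurface of the binary mask at iso-level 0.5 over
#' the voxel-centre grid, producing a watertight, outward-oriented triangle
#' mesh in physical mm. A small Gaussian pre-smoothing of the indicator
#' field (default 1 voxel sigma) suppresses voxel staircase artefacts; set
#' `smooth_sigma_vox = 0` for the raw blocky surface.
#'
#' @param mask An `orbit_mask` (or plain logical array).
#' @param spacing,origin geometry; taken from `mask` when it is an
#'   `orbit_mask`.
#' @param smooth_sigma_vox Gaussian sigma in voxel units applied to the 0/1
#'   indicator before extraction.
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(mask, spacing = NULL, origin = NULL,
                            smooth_sigma_vox = 1.0) {
  if (inherits(mask, "orbit_mask")) {
    spacing <- mask$spacing
    origin <- mask$origin
    mask <- mask$mask
  }
  if (is.null(spacing)) stop("spacing required")
  if (is.null(origin)) origin <- c(0, 0, 0)
  if (!any(mask)) stop("cannot extract a surface from an empty mask")
  dims <- dim(mask)
  field <- as.double(mask)
  if (smooth_sigma_vox > 0)
    field <- .gauss_smooth3(field, dims, rep(smooth_sigma_vox, 3))
  res <- .marching_tets(field, dims, 0.5, as.double(spacing), as.double(origin))
  if (nrow(res$vertices) == 0L)
    stop("isosurface is empty (mask too thin for the smoothing applied?)")
  clean_mesh(surface_mesh(res$vertices, res$faces))
}

#' Estimate the midsagittal plane from midline landmarks
#'
#' Total-least-squares plane through the midline points (smallest principal
#' component of their covariance), with the normal oriented left-to-right
#' (+x in the package's patient convention).
#'
#' @param landmarks A [landmark_set()] with at least 3 non-collinear
#'   midline points, or a Kx3 matrix of points.
#' @return A [plane3()].
#' @export
estimate_midsagittal <- function(landmarks) {
  pts <- if (inherits(landmarks, "landmark_set")) landmarks$midline else
    as_points(landmarks)
  if (is.null(pts) || nrow(pts) < 3L)
    stop("at least 3 midline points required")
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("midline points are collinear; the midsagittal plane is undefined")
  n <- sv$v[, 3]
  if (n[1] < 0) n <- -n
  plane3(n, ctr)
}

#' Registration parameters for ROI-restricted ICP
#'
#' @param max_iterations iteration cap.
#' @param convergence_tol_mm stop once the mean correspondence distance
#'   changes by less than this between iterations.
#' @param trim_fraction fraction of the worst point pairs discarded each
#'   iteration (robustness against residual defects inside the ROI); must
#'   be in [0, 0.5).
#' @param max_correspondence_mm pairs farther than this are ignored.
#' @param max_points deterministic cap on the number of ROI vertices used
#'   (regular stride subsampling; no randomness).
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(max_iterations = 100, convergence_tol_mm = 1e-4,
                                trim_fraction = 0.1, max_correspondence_mm = 5,
                                max_points = 5000L) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5,
            convergence_tol_mm > 0, max_correspondence_mm > 0,
            max_iterations >= 1, max_points >= 10)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol_mm = convergence_tol_mm,
                 trim_fraction = trim_fraction,
                 max_correspondence_mm = max_correspondence_mm,
                 max_points = as.integer(max_points)),
            class = "registration_params")
}

#' ROI selector on a template mesh
#'
#' Logical per-vertex inclusion mask naming the vertices used for surface
#' matching. Restricting it to the orbital roof and other unaffected areas
#' prevents the matcher from absorbing the reconstruction error it is
#' supposed to measure.
#'
#' @param template A [surface_mesh()].
#' @param include logical vector (length = vertices) or integer vertex ids.
#' @param exclude_labels optional character vector of region labels to
#'   drop, paired with `labeling` (a [region_labeling()]).
#' @param labeling optional `region_labeling` used with `exclude_labels`.
#' @param min_vertices minimum size of the ROI (default 100).
#' @return Logical vector of class `roi_selector`.
#' @export
roi_selector <- function(template, include = NULL, exclude_labels = NULL,
                         labeling = NULL, min_vertices = 100L) {
  nv <- nrow(template$vertices)
  roi <- if (is.null(include)) rep(TRUE, nv)
  else if (is.logical(include)) {
    stopifnot(length(include) == nv)
    include
  } else {
    out <- rep(FALSE, nv)
    out[as.integer(include)] <- TRUE
    out
  }
  if (!is.null(exclude_labels)) {
    if (is.null(labeling)) stop("exclude_labels needs a region labeling")
    stopifnot(length(labeling$label) == nv)
    roi <- roi & !(labeling$label %in% exclude_labels)
  }
  if (sum(roi) < min_vertices)
    stop("ROI holds ", sum(roi), " vertices; at least ", min_vertices,
         " required for a stable registration")
  structure(roi, class = "roi_selector")
}

#' Rigid ROI-restricted surface registration (trimmed point-to-plane ICP)
#'
#' Aligns `template` to `target` using only the ROI vertices: each
#' iteration pairs every (subsampled) ROI vertex with its closest point on
#' the target surface, discards pairs beyond `max_correspondence_mm` and
#' the `trim_fraction` worst remainder, and solves the linearised
#' point-to-plane least-squares problem for a rigid update. Deterministic:
#' no randomised sampling anywhere.
#'
#' @param template A [surface_mesh()] (the mirrored unaffected-side
#'   template).
#' @param roi A [roi_selector()] on the template (or logical vector).
#' @param target A [surface_mesh()] (the reconstructed side).
#' @param params A [registration_params()].
#' @param initial initial `rigid_transform` (e.g. from landmark
#'   pre-alignment via [align_points()]); default identity.
#' @return A list of class `icp_result`: `transform` (maps template into
#'   target space), `iterations`, `converged`, and `residuals` (mean, rms,
#'   max of the final kept ROI distances, plus `n_used`).
#' @export
icp_register <- function(template, roi, target,
                         params = registration_params(),
                         initial = rigid_transform()) {
  stopifnot(inherits(template, "surface_mesh"), inherits(target, "surface_mesh"))
  roi <- as.logical(roi)
  stopifnot(length(roi) == nrow(template$vertices))
  if (!any(roi)) stop("ROI is empty after label exclusion")
  pts0 <- template$vertices[roi, , drop = FALSE]
  if (nrow(pts0) > params$max_points) {
    idx <- unique(as.integer(round(seq(1, nrow(pts0), length.out = params$max_points))))
    pts0 <- pts0[idx, , drop = FALSE]
  }
  trans <- initial
  prev_mean <- Inf
  converged <- FALSE
  it <- 0L
  stats <- c(mean = NA_real_, rms = NA_real_, max = NA_real_)
  n_used <- 0L
  for (it in seq_len(params$max_iterations)) {
    cur <- apply_transform(trans, pts0)
    cp <- .closest_point_mesh(target$vertices, target$faces, cur,
                              params$max_correspondence_mm)
    ok <- which(is.finite(cp$dist))
    if (length(ok) < 6L)
      stop("fewer than 6 ROI correspondences within max_correspondence_mm; ",
           "check the initial alignment")
    d <- cp$dist[ok]
    if (params$trim_fraction > 0) {
      keep_n <- max(6L, floor(length(ok) * (1 - params$trim_fraction)))
      ok <- ok[order(d)[seq_len(keep_n)]]
      d <- cp$dist[ok]
    }
    stats <- c(mean = mean(d), rms = sqrt(mean(d^2)), max = max(d))
    n_used <- length(ok)
    if (abs(prev_mean - stats[["mean"]]) < params$convergence_tol_mm) {
      converged <- TRUE
      break
    }
    prev_mean <- stats[["mean"]]
    p <- cur[ok, , drop = FALSE]
    q <- cp$point[ok, , drop = FALSE]
    n <- cp$normal[ok, , drop = FALSE]
    cxn <- cbind(p[, 2] * n[, 3] - p[, 3] * n[, 2],
                 p[, 3] * n[, 1] - p[, 1] * n[, 3],
                 p[, 1] * n[, 2] - p[, 2] * n[, 1])
    A <- cbind(cxn, n)
    b <- -rowSums((p - q) * n)
    x <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                  error = function(e) matrix(0, 6, 1))
    delta <- rigid_transform(rotation_from_omega(as.numeric(x[1:3])),
                             as.numeric(x[4:6]))
    trans <- compose_transform(delta, trans)
  }
  if (!converged)
    warning("ICP did not converge within ", params$max_iterations,
            " iterations; returning the best transform found")
  structure(list(transform = trans, iterations = it, converged = converged,
                 residuals = c(as.list(stats), n_used = n_used)),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf(paste0("icp_result: %s after %d iteration(s); ROI residual ",
                     "mean %.4g / rms %.4g / max %.4g mm (n=%d)\n"),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residuals$mean, x$residuals$rms,
              x$residuals$max, x$residuals$n_used))
  invisible(x)
}

#' Landmark-based rigid pre-alignment
#'
#' Closed-form least-squares fit mapping the template-side landmarks onto
#' the target-side ones, used to put ICP inside its basin of attraction.
#'
#' @param src_points,dst_points Nx3 matrices of corresponding landmark
#'   positions (N >= 3), e.g. mirrored L/M/apex versus the affected side's.
#' @return A `rigid_transform`.
#' @export
prealign_landmarks <- function(src_points, dst_points) {
  align_points(src_points, dst_points)
}
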