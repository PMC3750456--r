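#' Orbital landmark set
#'
#' Holds, per side, the lateral (`L`) and medial (`M`) orbital rim points
#' that define the anterior border of the orbit, an optional apex point, and
#' at least three midline points (e.g. nasion-, crista-galli- and
#' basion-like) used to estimate the midsagittal mirror plane. All points
#' are physical coordinates in mm.
#'
#' @param right,left named lists with elements `L`, `M` and optionally
#'   `apex`, each a length-3 point; either side may be `NULL`.
#' @param midline Kx3 matrix of midline points (K >= 3 for mirror-plane
#'   estimation).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(right = NULL, left = NULL, midline = NULL) {
  check_side <- function(s, nm) {
    if (is.null(s)) return(NULL)
    if (is.null(s$L)) stop("L_", nm, " required")
    if (is.null(s$M)) stop("M_", nm, " required")
    s$L <- as.numeric(s$L); s$M <- as.numeric(s$M)
    stopifnot(length(s$L) == 3L, length(s$M) == 3L)
    if (sqrt(sum((s$L - s$M)^2)) < 1e-9)
      stop("landmarks L_", nm, " and M_", nm, " coincide")
    if (!is.null(s$apex)) {
      s$apex <- as.numeric(s$apex)
      stopifnot(length(s$apex) == 3L)
    }
    s[c("L", "M", "apex")]
  }
  if (!is.null(midline)) {
    midline <- as_points(midline)
  }
  structure(list(right = check_side(right, "right"),
                 left = check_side(left, "left"),
                 midline = midline),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: sides {%s}, %d midline point(s)\n",
              paste(c("right", "left")[!vapply(x[c("right", "left")], is.null,
                                               logical(1))], collapse = ", "),
              if (is.null(x$midline)) 0L else nrow(x$midline)))
  invisible(x)
}

#' Landmarks of one side
#' @param landmarks A `landmark_set`.
#' @param side `"right"` or `"left"`.
#' @return List with `L`, `M` and possibly `apex`; errors if the side is absent.
#' @export
side_landmarks <- function(landmarks, side = c("right", "left")) {
  side <- match.arg(side)
  s <- landmarks[[side]]
  if (is.null(s)) stop("no landmarks for side '", side, "'")
  s
}

#' Read landmarks from JSON or CSV
#'
#' JSON dialect: named points `L_right`, `M_right`, `apex_right`, `L_left`,
#' `M_left`, `apex_left` (each `[x, y, z]`) plus `midline`, a list of
#' points. CSV dialect: columns `name,x,y,z` with the same point names and
#' midline points named `midline_1`, `midline_2`, ...
#'
#' @param path path ending in `.json` or `.csv`.
#' @param require_side optionally `"right"`/`"left"`; error if that side's
#'   `L`/`M` pair is missing.
#' @param require_midline if `TRUE`, error when fewer than 3 midline points
#'   are present (mirror-plane estimation would be impossible).
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, require_side = NULL, require_midline = FALSE) {
  if (!file.exists(path)) stop("cannot read landmarks: no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- obj[setdiff(names(obj), "midline")]
    midline <- if (!is.null(obj$midline)) {
      m <- obj$midline
      if (is.list(m)) do.call(rbind, m) else as.matrix(m)
    } else NULL
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need_cols <- c("name", "x", "y", "z")
    if (!all(need_cols %in% names(df)))
      stop("landmark CSV needs columns name,x,y,z: ", path)
    pts <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, c("x", "y", "z")]))
    names(pts) <- df$name
    mid <- grepl("^midline", names(pts))
    midline <- if (any(mid)) do.call(rbind, pts[mid]) else NULL
    pts <- pts[!mid]
  } else stop("unsupported landmark format (need .json or .csv): ", path)
  grab <- function(nm) if (nm %in% names(pts)) as.numeric(pts[[nm]]) else NULL
  mk_side <- function(side) {
    L <- grab(paste0("L_", side)); M <- grab(paste0("M_", side))
    apex <- grab(paste0("apex_", side))
    if (is.null(L) && is.null(M) && is.null(apex)) return(NULL)
    if (is.null(L)) stop("L_", side, " required")
    if (is.null(M)) stop("M_", side, " required")
    list(L = L, M = M, apex = apex)
  }
  lm <- landmark_set(right = mk_side("right"), left = mk_side("left"),
                     midline = midline)
  if (!is.null(require_side)) side_landmarks(lm, require_side)
  if (require_midline && (is.null(lm$midline) || nrow(lm$midline) < 3L))
    stop("at least 3 midline points required for mirror-plane estimation")
  lm
}

#' Write landmarks to JSON
#' @param landmarks A [landmark_set()].
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- list()
  for (side in c("right", "left")) {
    s <- landmarks[[side]]
    if (is.null(s)) next
    obj[[paste0("L_", side)]] <- s$L
    obj[[paste0("M_", side)]] <- s$M
    if (!is.null(s$apex)) obj[[paste0("apex_", side)]] <- s$apex
  }
  if (!is.null(landmarks$midline))
    obj$midline <- lapply(seq_len(nrow(landmarks$midline)),
                          function(i) as.numeric(landmarks$midline[i, ]))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Validate landmarks against a volume and the midsagittal plane
#'
#' Checks that all points fall inside the physical bounds of `volume` and,
#' when a midsagittal plane can be estimated, that each side's L/M pair
#' lies on the labelled side of it.
#'
#' @param landmarks A [landmark_set()].
#' @param volume A [volume_image()].
#' @return `TRUE` invisibly; errors describe the offending point.
#' @export
validate_landmarks <- function(landmarks, volume) {
  lo <- volume$origin - volume$spacing / 2
  hi <- volume$origin + (dim(volume$data) - 0.5) * volume$spacing
  all_pts <- list()
  for (side in c("right", "left")) {
    s <- landmarks[[side]]
    if (!is.null(s)) {
      all_pts[[paste0("L_", side)]] <- s$L
      all_pts[[paste0("M_", side)]] <- s$M
      if (!is.null(s$apex)) all_pts[[paste0("apex_", side)]] <- s$apex
    }
  }
  if (!is.null(landmarks$midline))
    for (i in seq_len(nrow(landmarks$midline)))
      all_pts[[paste0("midline_", i)]] <- landmarks$midline[i, ]
  for (nm in names(all_pts)) {
    p <- all_pts[[nm]]
    if (any(p < lo) || any(p > hi))
      stop("landmark ", nm, " lies outside the volume bounds")
  }
  if (!is.null(landmarks$midline) && nrow(landmarks$midline) >= 3L) {
    pl <- tryCatch(estimate_midsagittal(landmarks), error = function(e) NULL)
    if (!is.null(pl)) {
      for (side in c("right", "left")) {
        s <- landmarks[[side]]
        if (is.null(s)) next
        want <- if (side == "right") 1 else -1  # normal points right
        d <- plane_signed_distance(pl, rbind(s$L, s$M))
        if (any(sign(d) != want))
          stop("landmarks of side '", side,
               "' fall on the wrong side of the midsagittal plane")
      }
    }
  }
  invisible(TRUE)
}
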