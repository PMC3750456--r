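#' Triangulated surface mesh
#'
#' Vertices are physical points in mm; faces index vertices (1-based) with
#' consistent outward orientation for closed surfaces. Optional per-vertex
#' `scalar` (e.g. a deviation in mm) and `color` (Nx3 in [0,1]) channels
#' travel with the mesh and can be written to PLY.
#'
#' @param vertices Nx3 numeric matrix (mm).
#' @param faces Mx3 integer matrix of 1-based vertex indices.
#' @param scalar optional per-vertex numeric channel.
#' @param color optional Nx3 matrix of RGB values in [0,1].
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, scalar = NULL, color = NULL) {
  vertices <- as_points(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(faces) == 3L)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("faces index vertices outside 1..nrow(vertices)")
  if (!is.null(scalar)) stopifnot(length(scalar) == nrow(vertices))
  if (!is.null(color)) {
    color <- as.matrix(color)
    stopifnot(nrow(color) == nrow(vertices), ncol(color) == 3L)
  }
  structure(list(vertices = vertices, faces = unname(faces),
                 scalar = scalar, color = color),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$scalar)) ", scalar channel" else "",
              if (!is.null(x$color)) ", color channel" else ""))
  invisible(x)
}

#' Per-face areas of a mesh
#' @param mesh A `surface_mesh`.
#' @return Numeric vector of triangle areas (mm^2).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume; positive when face orientation is outward.
#' @param mesh A `surface_mesh`.
#' @return Signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Per-vertex Voronoi-style areas
#'
#' One third of each incident triangle's area is attributed to each of its
#' corners; the result sums to the total surface area.
#' @param mesh A `surface_mesh`.
#' @return Numeric vector (mm^2), one entry per vertex.
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh) / 3
  out <- numeric(nrow(mesh$vertices))
  for (j in 1:3) {
    acc <- tapply(fa, mesh$faces[, j], sum)
    out[as.integer(names(acc))] <- out[as.integer(names(acc))] + acc
  }
  out
}

#' Weld duplicate vertices
#'
#' Merges vertices with bit-identical coordinates (exact hash on the
#' coordinate triple, as produced by STL triangle soup) and drops
#' degenerate and unreferenced leftovers.
#'
#' @param mesh A `surface_mesh`.
#' @return A `surface_mesh` with a unique vertex set.
#' @export
weld_vertices <- function(mesh) {
  key <- paste(sprintf("%.17g", mesh$vertices[, 1]),
               sprintf("%.17g", mesh$vertices[, 2]),
               sprintf("%.17g", mesh$vertices[, 3]))
  uid <- match(key, key[!duplicated(key)])
  keep <- !duplicated(key)
  newv <- mesh$vertices[keep, , drop = FALSE]
  newf <- matrix(uid[mesh$faces], ncol = 3)
  # drop collapsed faces
  ok <- newf[, 1] != newf[, 2] & newf[, 2] != newf[, 3] & newf[, 1] != newf[, 3]
  surface_mesh(newv, newf[ok, , drop = FALSE],
               scalar = if (is.null(mesh$scalar)) NULL else mesh$scalar[keep],
               color = if (is.null(mesh$color)) NULL else
                 mesh$color[keep, , drop = FALSE])
}

#' Drop zero-area faces and unreferenced vertices
#' @param mesh A `surface_mesh`.
#' @param tol area tolerance in mm^2 (default 1e-12).
#' @return A cleaned `surface_mesh`.
#' @export
clean_mesh <- function(mesh, tol = 1e-12) {
  ok <- face_areas(mesh) > tol
  f <- mesh$faces[ok, , drop = FALSE]
  used <- sort(unique(as.integer(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE], matrix(remap[f], ncol = 3),
               scalar = if (is.null(mesh$scalar)) NULL else mesh$scalar[used],
               color = if (is.null(mesh$color)) NULL else
                 mesh$color[used, , drop = FALSE])
}

#' Reflect a mesh across a plane
#'
#' Vertices are mirrored; face winding is flipped so a closed mesh keeps its
#' outward orientation (reflection alone would turn it inside out).
#'
#' @param mesh A `surface_mesh`.
#' @param plane A [plane3()] mirror plane (e.g. the midsagittal plane).
#' @return The mirrored `surface_mesh`.
#' @export
reflect_mesh <- function(mesh, plane) {
  surface_mesh(reflect_points(plane, mesh$vertices),
               mesh$faces[, c(1, 3, 2), drop = FALSE],
               scalar = mesh$scalar, color = mesh$color)
}

#' Apply a rigid transform to a mesh
#' @param mesh A `surface_mesh`.
#' @param transform A `rigid_transform`.
#' @return The transformed `surface_mesh`.
#' @export
transform_mesh <- function(mesh, transform) {
  surface_mesh(apply_transform(transform, mesh$vertices), mesh$faces,
               scalar = mesh$scalar, color = mesh$color)
}

#' Read a surface mesh (STL or PLY)
#'
#' STL (ASCII or binary) triangle soup is welded to a unique vertex set on
#' read. ASCII PLY may carry per-vertex color (`red/green/blue`) and a
#' scalar `quality` property.
#'
#' @param path path ending in `.stl` or `.ply`.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  if (grepl("\\.stl$", path, ignore.case = TRUE)) read_stl(path)
  else if (grepl("\\.ply$", path, ignore.case = TRUE)) read_ply(path)
  else stop("unsupported mesh format (need .stl or .ply): ", path)
}

#' Write a surface mesh (STL or PLY)
#'
#' @param mesh A [surface_mesh()].
#' @param path destination ending in `.stl` or `.ply`.
#' @param with_colors write the per-vertex color channel (PLY only; STL
#'   cannot carry color and errors if requested).
#' @param binary for STL, write the binary flavour (default ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, with_colors = FALSE, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    if (with_colors) stop("STL cannot carry per-vertex colors; use PLY")
    write_stl(mesh, path, binary = binary)
  } else if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    write_ply(mesh, path, with_colors = with_colors)
  } else stop("unsupported mesh format (need .stl or .ply): ", path)
  invisible(path)
}

# --- STL ------------------------------------------------------------------

read_stl <- function(path) {
  # binary STL: 80-byte header, uint32 count, 50 bytes per facet
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(sz, 80L))
  is_binary <- TRUE
  if (length(head) >= 5 && rawToChar(head[1:5]) == "solid") {
    # might still be binary with a 'solid' header; check facet-count math
    if (sz >= 84) {
      nfac <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
      if (!isTRUE(sz == 84 + 50 * as.double(nfac))) is_binary <- FALSE
    } else is_binary <- FALSE
  } else {
    if (sz < 84) stop("not a valid STL file: ", path)
    nfac <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  }
  if (is_binary) {
    raw <- readBin(con, "raw", n = 50L * as.double(nfac))
    m <- matrix(raw, nrow = 50L)
    tri <- vapply(seq_len(nfac), function(i)
      readBin(m[13:48, i], "double", n = 9L, size = 4L, endian = "little"),
      numeric(9))
    verts <- matrix(as.numeric(tri), ncol = 3, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("malformed ASCII STL: ", path)
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  weld_vertices(surface_mesh(verts, faces))
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    block <- t(cbind(n, a, b, c_))  # 12 floats per facet
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(block[, i]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
    lines <- c("solid orbitqc",
               as.vector(rbind(paste0("  facet normal ", fmt(n)),
                               "    outer loop",
                               paste0("      vertex ", fmt(a)),
                               paste0("      vertex ", fmt(b)),
                               paste0("      vertex ", fmt(c_)),
                               "    endloop",
                               "  endfacet")),
               "endsolid orbitqc")
    writeLines(lines, path)
  }
  invisible(path)
}

# --- PLY (ASCII) ----------------------------------------------------------

write_ply <- function(mesh, path, with_colors = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  has_scalar <- !is.null(mesh$scalar)
  if (with_colors && is.null(mesh$color))
    stop("mesh has no color channel; run colorize() first")
  hdr <- c("ply", "format ascii 1.0", "comment generated by orbitqc",
           paste("element vertex", nv),
           "property float x", "property float y", "property float z")
  if (with_colors)
    hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
  if (has_scalar) hdr <- c(hdr, "property float quality")
  hdr <- c(hdr, paste("element face", nf),
           "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                mesh$vertices[, 3])
  if (with_colors) {
    rgb <- round(pmin(pmax(mesh$color, 0), 1) * 255)
    vl <- paste(vl, rgb[, 1], rgb[, 2], rgb[, 3])
  }
  if (has_scalar) {
    sc <- mesh$scalar
    sc[!is.finite(sc)] <- 0
    vl <- paste(vl, sprintf("%.9g", sc))
  }
  fl <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                mesh$faces[, 3] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3L || txt[1] != "ply") stop("not a PLY file: ", path)
  if (!grepl("ascii", txt[2])) stop("only ASCII PLY supported: ", path)
  endh <- match("end_header", txt)
  hdr <- txt[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  # vertex property order
  vprops <- character()
  in_vertex <- FALSE
  for (line in hdr) {
    if (grepl("^element vertex", line)) { in_vertex <- TRUE; next }
    if (grepl("^element ", line)) in_vertex <- FALSE
    if (in_vertex && grepl("^property ", line))
      vprops <- c(vprops, utils::tail(strsplit(line, "\\s+")[[1]], 1))
  }
  vlines <- txt[(endh + 1):(endh + nv)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
  colnames(vm) <- vprops[seq_len(ncol(vm))]
  verts <- vm[, c("x", "y", "z"), drop = FALSE]
  color <- if (all(c("red", "green", "blue") %in% vprops))
    vm[, c("red", "green", "blue"), drop = FALSE] / 255 else NULL
  scalar <- if ("quality" %in% vprops) vm[, "quality"] else NULL
  flines <- txt[(endh + nv + 1):(endh + nv + nf)]
  fm <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(p)
    as.integer(p[2:4]) + 1L))
  surface_mesh(verts, fm, scalar = scalar, color = color)
}

#' Watertightness check
#'
#' A closed orientable triangle mesh has every edge shared by exactly two
#' faces with opposite direction.
#' @param mesh A `surface_mesh`.
#' @return `TRUE` if every edge is used exactly twice (once per direction).
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  fwd <- paste(he[, 1], he[, 2])
  rev <- paste(he[, 2], he[, 1])
  !anyDuplicated(fwd) && all(fwd %in% rev)
}
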