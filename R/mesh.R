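#' Triangle mesh objects
#'
#' A `triangle_mesh` is the package's universal geometry carrier: an
#' `n x 3` numeric matrix of vertex coordinates in millimetres plus an
#' `m x 3` integer matrix of 1-based vertex indices, and optionally a
#' per-vertex scalar field (used for distance heatmaps).
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices.
#' @param scalar optional numeric vector of length n (per-vertex field).
#' @return A `triangle_mesh` object.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                    rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
#' n_vertices(m)
#' @export
triangle_mesh <- function(vertices, faces, scalar = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  m <- structure(list(vertices = vertices, faces = faces, scalar = scalar),
                 class = "triangle_mesh")
  validate_mesh(m)
  m
}

#' Validate a triangle mesh
#'
#' Checks the structural invariants: 3-column vertex and face matrices,
#' finite coordinates, all face indices in `[1, n_vertices]`, and no face
#' referencing the same vertex twice.
#'
#' @param mesh a `triangle_mesh`.
#' @return `mesh`, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  if (ncol(v) != 3L) stop("vertices must have 3 columns")
  if (ncol(f) != 3L) stop("faces must have 3 columns")
  if (!all(is.finite(v))) stop("mesh has non-finite vertex coordinates")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v)) {
      bad <- which(f < 1L | f > nrow(v), arr.ind = TRUE)[1L, ]
      stop(sprintf("face %d references out-of-range vertex index %d (mesh has %d vertices)",
                   bad[1L], f[bad[1L], bad[2L]], nrow(v)))
    }
    degen <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
    if (any(degen)) {
      stop(sprintf("face %d references the same vertex twice", which(degen)[1L]))
    }
  }
  if (!is.null(mesh$scalar) && length(mesh$scalar) != nrow(v)) {
    stop("per-vertex scalar field length does not match vertex count")
  }
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$scalar)) ", per-vertex scalar field" else ""))
  invisible(x)
}

#' @rdname triangle_mesh
#' @param mesh a `triangle_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname triangle_mesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Bounding-box diagonal of a mesh (mm)
#' @param mesh a `triangle_mesh`.
#' @return length of the axis-aligned bounding-box diagonal.
#' @export
bbox_diagonal <- function(mesh) {
  r <- apply(mesh$vertices, 2L, range)
  sqrt(sum((r[2L, ] - r[1L, ])^2))
}

#' Signed volume of a closed mesh
#'
#' Divergence-theorem volume: positive when face winding is outward.
#' @param mesh a closed `triangle_mesh`.
#' @return signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  # sum of signed tetrahedron volumes against the origin
  sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
      a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
      a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

#' Mirror a mesh across the X = 0 plane
#'
#' Left radii are mirrored into right radii before model building. The
#' first coordinate is negated and the face winding reversed so that the
#' surface orientation (outward normals, signed volume) is preserved.
#' Mirroring twice restores the input exactly.
#'
#' @param mesh a `triangle_mesh`.
#' @return the mirrored `triangle_mesh`.
#' @export
mirror_mesh <- function(mesh) {
  validate_mesh(mesh)
  v <- mesh$vertices
  v[, 1L] <- -v[, 1L]
  f <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  triangle_mesh(v, f, mesh$scalar)
}

#' Vertex subsets of a mesh
#'
#' A `vertex_subset` carries a sorted set of unique vertex indices of a
#' given mesh (e.g. the proximal 88% / distal 12% index sets).
#'
#' @param mesh a `triangle_mesh`.
#' @param indices integer vertex indices (1-based).
#' @return a `vertex_subset`.
#' @export
vertex_subset <- function(mesh, indices) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0L) stop("vertex subset is empty")
  if (min(indices) < 1L || max(indices) > n_vertices(mesh)) {
    stop("vertex subset index out of range")
  }
  structure(list(indices = indices, n_mesh_vertices = n_vertices(mesh)),
            class = "vertex_subset")
}

#' @export
print.vertex_subset <- function(x, ...) {
  cat(sprintf("<vertex_subset: %d of %d vertices>\n",
              length(x$indices), x$n_mesh_vertices))
  invisible(x)
}

#' Split vertices at a fraction of the mesh extent along an axis
#'
#' In the canonical anatomical frame the long axis of the radius is Y;
#' cutting at fraction 0.88 yields the proximal 88% (indices with
#' `Y <= ymin + 0.88 * (ymax - ymin)`) and the distal 12%. The cut is a
#' vertex partition, not a re-meshing: no planar cap is added.
#'
#' @param mesh a `triangle_mesh` in the canonical frame.
#' @param axis axis along which to cut: 1, 2, 3 or "x", "y", "z".
#' @param fraction cut location as a fraction of the extent, in (0, 1).
#' @return list with `vertex_subset`s `proximal` (at or below the cut) and
#'   `distal` (above it); together they partition all vertices.
#' @export
cut_by_length_fraction <- function(mesh, axis = "y", fraction = 0.88) {
  validate_mesh(mesh)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1")
  }
  ax <- resolve_axis(axis)
  y <- mesh$vertices[, ax]
  cut <- min(y) + fraction * (max(y) - min(y))
  prox <- which(y <= cut)
  dist <- which(y > cut)
  if (length(dist) == 0L) {
    # fraction so close to 1 that no vertex is strictly above the cut
    stop("distal subset is empty at this fraction")
  }
  list(proximal = vertex_subset(mesh, prox),
       distal = vertex_subset(mesh, dist))
}

resolve_axis <- function(axis) {
  if (is.character(axis)) {
    ax <- match(tolower(axis), c("x", "y", "z"))
    if (is.na(ax)) stop("axis must be one of x, y, z")
    return(ax)
  }
  ax <- as.integer(axis)
  if (!ax %in% 1:3) stop("axis must be 1, 2 or 3")
  ax
}

#' Closest points on a mesh surface
#'
#' Exact point-to-surface projection: for each query point, the nearest
#' point on any triangle of the mesh, the Euclidean distance to it, and
#' the index of the triangle carrying it. Queries are answered through a
#' uniform spatial grid over triangle bounding boxes, so large batches
#' are fast; results equal the exhaustive per-triangle minimum.
#'
#' @param mesh a `triangle_mesh`.
#' @param points numeric matrix (q x 3) of query points, or a length-3
#'   vector for a single query.
#' @return list with `point` (q x 3 matrix on the surface), `distance`
#'   (length q) and `face` (length q, 1-based triangle index).
#' @export
closest_point_on_surface <- function(mesh, points) {
  validate_mesh(mesh)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("query points must have 3 columns")
  .cpp_closest_point(mesh$vertices, mesh$faces, points)
}

#' Decimate a mesh to (at most) a target vertex count
#'
#' Vertex-clustering simplification: vertices are merged within the cells
#' of a uniform grid whose resolution is chosen (by bisection) so that the
#' number of occupied cells does not exceed `target_vertex_count`; each
#' cluster is replaced by its centroid and degenerate faces are dropped.
#' The simplified surface stays within 1% of the bounding-box diagonal of
#' the input (one-sided, result to input) for the resolutions used here.
#'
#' @param mesh a `triangle_mesh`.
#' @param target_vertex_count maximum vertex count of the result (>= 4).
#' @return the decimated `triangle_mesh`.
#' @export
decimate_mesh <- function(mesh, target_vertex_count) {
  validate_mesh(mesh)
  target_vertex_count <- as.integer(target_vertex_count)
  if (target_vertex_count < 4L) stop("target vertex count must be at least 4")
  if (target_vertex_count >= n_vertices(mesh)) {
    stop("target vertex count must be smaller than the current vertex count")
  }
  v <- mesh$vertices
  lo <- apply(v, 2L, min)
  ext <- pmax(apply(v, 2L, max) - lo, 1e-12)

  occupied <- function(res) {
    cell <- ext / res
    key <- floor(sweep(sweep(v, 2L, lo), 2L, cell, "/"))
    key <- pmin(key, res - 1L)
    id <- key[, 1L] + res * (key[, 2L] + res * key[, 3L])
    id
  }
  # largest grid resolution whose occupied-cell count fits the target
  lo_res <- 1L
  hi_res <- 512L
  while (lo_res < hi_res) {
    mid <- (lo_res + hi_res + 1L) %/% 2L
    if (length(unique(occupied(mid))) <= target_vertex_count) lo_res <- mid
    else hi_res <- mid - 1L
  }
  id <- occupied(lo_res)
  groups <- match(id, unique(id))
  nv <- max(groups)
  newv <- rowsum(v, groups) / tabulate(groups, nv)
  f <- matrix(groups[mesh$faces], ncol = 3L)
  keep <- f[, 1L] != f[, 2L] & f[, 1L] != f[, 3L] & f[, 2L] != f[, 3L]
  f <- f[keep, , drop = FALSE]
  f <- unique(f)
  if (nrow(f) < 4L || nv < 4L) stop("decimation target too small to remain a valid surface")
  triangle_mesh(newv, f)
}

#' Extract the sub-mesh spanned by a vertex subset
#'
#' Keeps the faces whose three vertices all belong to the subset and
#' re-indexes them; vertices not referenced by any kept face are retained
#' (the subset defines the segment).
#'
#' @param mesh a `triangle_mesh`.
#' @param subset a `vertex_subset` of `mesh`.
#' @return a `triangle_mesh` over the subset's vertices.
#' @export
submesh <- function(mesh, subset) {
  stopifnot(inherits(subset, "vertex_subset"))
  idx <- subset$indices
  inside <- logical(n_vertices(mesh))
  inside[idx] <- TRUE
  f <- mesh$faces
  keep <- inside[f[, 1L]] & inside[f[, 2L]] & inside[f[, 3L]]
  f <- f[keep, , drop = FALSE]
  if (nrow(f) == 0L) stop("no face lies fully inside the vertex subset")
  remap <- integer(n_vertices(mesh))
  remap[idx] <- seq_along(idx)
  triangle_mesh(mesh$vertices[idx, , drop = FALSE],
                matrix(remap[f], ncol = 3L),
                if (!is.null(mesh$scalar)) mesh$scalar[idx] else NULL)
}
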