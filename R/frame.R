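#' Anatomical landmarks of the radius
#'
#' Three landmarks define the radius coordinate system: the centre of the
#' radial head (the origin), the midpoint of the central ridge of the
#' distal radius (fixes the long Y axis), and a point in the middle of the
#' sigmoid notch (fixes the +Z direction). The three points must be
#' affinely independent.
#'
#' @param head_center,ridge_midpoint,notch_point length-3 numeric vectors (mm).
#' @return a `landmark_set`.
#' @export
landmark_set <- function(head_center, ridge_midpoint, notch_point) {
  pts <- rbind(head_center = as.numeric(head_center),
               ridge_midpoint = as.numeric(ridge_midpoint),
               notch_point = as.numeric(notch_point))
  if (ncol(pts) != 3L || !all(is.finite(pts))) stop("landmarks must be finite 3D points")
  structure(list(head_center = pts[1L, ], ridge_midpoint = pts[2L, ],
                 notch_point = pts[3L, ]), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>\n")
  for (nm in c("head_center", "ridge_midpoint", "notch_point")) {
    cat(sprintf("  %-15s %8.3f %8.3f %8.3f\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  }
  invisible(x)
}

#' Read landmarks from CSV
#'
#' Expects columns `name, x, y, z` (mm) with names exactly `head_center`,
#' `ridge_midpoint`, `notch_point`.
#'
#' @param path CSV path.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("head_center", "ridge_midpoint", "notch_point")
  if (!all(need %in% d$name)) {
    stop("landmark CSV must contain rows named head_center, ridge_midpoint, notch_point")
  }
  row <- function(nm) as.numeric(d[match(nm, d$name), c("x", "y", "z")])
  landmark_set(row("head_center"), row("ridge_midpoint"), row("notch_point"))
}

#' Write landmarks to CSV
#' @param landmarks a `landmark_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(data.frame(
    name = c("head_center", "ridge_midpoint", "notch_point"),
    x = c(landmarks$head_center[1], landmarks$ridge_midpoint[1], landmarks$notch_point[1]),
    y = c(landmarks$head_center[2], landmarks$ridge_midpoint[2], landmarks$notch_point[2]),
    z = c(landmarks$head_center[3], landmarks$ridge_midpoint[3], landmarks$notch_point[3])),
    path, row.names = FALSE)
  invisible(path)
}

#' Build the anatomical coordinate frame from landmarks
#'
#' The origin is the centre of the radial head. The Y axis points from the
#' origin to the midpoint of the central ridge of the distal radius; the
#' Z axis is the component of the direction to the sigmoid notch
#' orthogonal to Y; X = Y x Z completes a right-handed frame and points
#' dorsally. The construction is equivariant under rigid motions of the
#' landmarks.
#'
#' @param landmarks a `landmark_set`.
#' @return an `anatomical_frame`: list with `origin` (3-vector, mm) and
#'   `rotation` (3x3 orthonormal, columns = X, Y, Z axes, det +1).
#' @export
build_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  origin <- landmarks$head_center
  yv <- landmarks$ridge_midpoint - origin
  ny <- sqrt(sum(yv^2))
  if (ny < 1e-9) stop("degenerate frame: ridge midpoint coincides with head centre")
  y <- yv / ny
  zv <- landmarks$notch_point - origin
  zv <- zv - sum(zv * y) * y
  nz <- sqrt(sum(zv^2))
  if (nz < 1e-9) stop("degenerate frame: notch point is collinear with the long axis")
  z <- zv / nz
  x <- c(y[2L] * z[3L] - y[3L] * z[2L],
         y[3L] * z[1L] - y[1L] * z[3L],
         y[1L] * z[2L] - y[2L] * z[1L])
  rotation <- cbind(X = x, Y = y, Z = z)
  structure(list(origin = origin, rotation = rotation), class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>\n  origin:", sprintf("%.3f", x$origin), "\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' Map a mesh into its anatomical frame
#'
#' Rigidly transforms vertices by `v -> R^T (v - origin)`: the head centre
#' maps to the zero vector and the ridge midpoint onto the +Y axis. This
#' is an isometry (all pairwise distances preserved).
#'
#' @param mesh a `triangle_mesh`.
#' @param frame an `anatomical_frame`.
#' @return the canonical-frame `triangle_mesh`.
#' @export
canonicalize <- function(mesh, frame) {
  stopifnot(inherits(frame, "anatomical_frame"))
  v <- sweep(mesh$vertices, 2L, frame$origin) %*% frame$rotation
  triangle_mesh(v, mesh$faces, mesh$scalar)
}

#' Apply a frame to bare points
#' @param points n x 3 matrix or 3-vector.
#' @param frame an `anatomical_frame`.
#' @return transformed points, same shape as input.
#' @export
canonicalize_points <- function(points, frame) {
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, ncol = 3L)
  out <- sweep(points, 2L, frame$origin) %*% frame$rotation
  if (vec) as.vector(out) else out
}

#' Centre of gravity of the distal segment
#'
#' Area-weighted centroid of the triangles whose three vertices all lie in
#' the distal `fraction` of the mesh along Y (the secondary evaluation
#' origin in the distal radius). A surface centroid is used because cut
#' segments are open surfaces, for which a volume centroid is undefined.
#'
#' @param mesh canonical-frame `triangle_mesh`.
#' @param fraction distal fraction (default 0.12).
#' @return length-3 numeric centroid (mm).
#' @export
distal_origin <- function(mesh, fraction = 0.12) {
  cuts <- cut_by_length_fraction(mesh, axis = "y", fraction = 1 - fraction)
  seg <- submesh(mesh, cuts$distal)
  v <- seg$vertices
  f <- seg$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  area <- 0.5 * sqrt(rowSums(cr^2))
  if (sum(area) <= 0) stop("distal segment has zero area")
  centroids <- (a + b + c_) / 3
  colSums(centroids * area) / sum(area)
}
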