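#' Six-degree-of-freedom clinical error
#'
#' Prediction error of the distal radius expressed in the clinical degrees
#' of freedom: rotations about the anatomical axes — radial inclination
#' (phi_x), volar tilt (phi_z), axial rotation (phi_y), in degrees — and
#' translations along them — dorsal shift (delta_x), radial shift
#' (delta_z), lengthening (delta_y), in mm — plus the convention-free 3D
#' angle (axis-angle magnitude, degrees) and 3D distance (norm of the
#' translation, mm). Sign conventions: +X dorsal, +Y proximal-to-distal
#' (so +delta_y = lengthening), +Z radial (towards the sigmoid notch).
#'
#' @param phi_x,phi_z,phi_y rotations in degrees.
#' @param delta_x,delta_y,delta_z translations in mm.
#' @param angle_3d axis-angle magnitude in degrees.
#' @param dist_3d translation norm in mm.
#' @param gimbal_warning TRUE when the Euler decomposition was near its
#'   gimbal degeneracy (|phi_z| near 90 degrees).
#' @return a `six_dof_error`.
#' @export
six_dof_error <- function(phi_x = 0, phi_z = 0, phi_y = 0,
                          delta_x = 0, delta_y = 0, delta_z = 0,
                          angle_3d = 0, dist_3d = 0, gimbal_warning = FALSE) {
  structure(list(phi_x = phi_x, phi_z = phi_z, phi_y = phi_y,
                 delta_x = delta_x, delta_y = delta_y, delta_z = delta_z,
                 angle_3d = angle_3d, dist_3d = dist_3d,
                 gimbal_warning = isTRUE(gimbal_warning)),
            class = "six_dof_error")
}

#' @export
print.six_dof_error <- function(x, ...) {
  cat("<six_dof_error>\n")
  cat(sprintf("  rotation (deg):  inclination %7.3f  volar tilt %7.3f  axial %7.3f  | 3D angle %7.3f\n",
              x$phi_x, x$phi_z, x$phi_y, x$angle_3d))
  cat(sprintf("  translation (mm): dorsal %7.3f  radial %7.3f  length %7.3f  | 3D dist  %7.3f\n",
              x$delta_x, x$delta_z, x$delta_y, x$dist_3d))
  if (x$gimbal_warning) cat("  (near gimbal degeneracy; Euler angles unreliable)\n")
  invisible(x)
}

#' Extract the distal segment of a canonical-frame mesh
#'
#' Sub-mesh of the faces lying fully within the distal `fraction` of the
#' length along Y (0.12 for the clinical evaluation; 0.5 for the
#' comparison mode that registers the distal half).
#'
#' @param mesh canonical-frame `triangle_mesh`.
#' @param fraction distal fraction.
#' @return a `triangle_mesh`.
#' @export
extract_distal_segment <- function(mesh, fraction = 0.12) {
  cuts <- cut_by_length_fraction(mesh, "y", 1 - fraction)
  submesh(mesh, cuts$distal)
}

#' Rigid registration of a distal segment
#'
#' Global initialization (centroid alignment plus principal axes of the
#' vertex scatter, testing the four sign combinations that keep a
#' right-handed frame and keeping the best), followed by rigid-ICP
#' refinement. Returns the transform mapping the reference segment onto
#' the predicted segment — the deterministic surrogate for the "global
#' registration and manual adjustment" step of 3D surgical planning.
#'
#' Both segments arrive in the canonical anatomical frame, so candidate
#' initializations whose rotation exceeds `max_init_rotation_deg` from the
#' identity are discarded — mirroring the surgeon's manual adjustment,
#' which would never spin a distal radius by a half turn even when a
#' grossly wrong prediction makes the flipped fit score slightly better.
#'
#' @param predicted_segment,reference_segment `triangle_mesh`es.
#' @param max_iter,tol_mm ICP controls.
#' @param max_init_rotation_deg cap on the initialization rotation.
#' @return list with `transform` (a `rigid_transform`) and `residual_mm`.
#' @export
register_distal <- function(predicted_segment, reference_segment,
                            max_iter = 60L, tol_mm = 1e-9,
                            max_init_rotation_deg = 60) {
  vr <- reference_segment$vertices
  vp <- predicted_segment$vertices
  if (nrow(vr) < 4L || nrow(vp) < 4L) stop("degenerate segment: too few vertices")
  er <- eigen(stats::cov(vr), symmetric = TRUE)
  ep <- eigen(stats::cov(vp), symmetric = TRUE)
  if (er$values[3L] < 1e-9 * er$values[1L] || ep$values[3L] < 1e-9 * ep$values[1L]) {
    stop("degenerate segment: rank-deficient vertex scatter")
  }
  Br <- er$vectors
  if (det(Br) < 0) Br[, 3L] <- -Br[, 3L]
  Bp <- ep$vectors
  if (det(Bp) < 0) Bp[, 3L] <- -Bp[, 3L]
  cr <- colMeans(vr)
  cp_ <- colMeans(vp)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  inits <- list(rigid_transform(diag(3), cp_ - cr))  # centroid-only
  for (s in signs) {
    R0 <- Bp %*% diag(s) %*% t(Br)
    ang <- acos(min(max((sum(diag(R0)) - 1) / 2, -1), 1)) * 180 / pi
    if (ang <= max_init_rotation_deg) {
      inits[[length(inits) + 1L]] <- rigid_transform(R0, cp_ - as.vector(R0 %*% cr))
    }
  }
  best <- NULL
  for (init in inits) {
    fit <- rigid_icp(reference_segment, predicted_segment,
                     max_iter = max_iter, tol_mm = tol_mm, init = init)
    if (is.null(best) || fit$residual_mm < best$residual_mm) best <- fit
  }
  list(transform = best$transform, residual_mm = best$residual_mm)
}

#' Decompose a rigid transform into the six clinical degrees of freedom
#'
#' The transform is re-expressed about the distal origin (the centre of
#' gravity of the reference distal segment) in the anatomical frame. The
#' rotation is decomposed in intrinsic X -> Z -> Y Euler order
#' (`R = Rx(phi_x) Rz(phi_z) Ry(phi_y)`) — inclination, tilt, axial
#' rotation; the displacement of the distal origin gives the three
#' translations; the 3D angle is the convention-free axis-angle magnitude
#' and the 3D distance the norm of the translation (so
#' `dist_3d^2 = delta_x^2 + delta_y^2 + delta_z^2` exactly). Near the
#' Euler degeneracy (|phi_z| -> 90 degrees) values are still returned,
#' flagged by `gimbal_warning`.
#'
#' @param transform a `rigid_transform` (reference -> predicted).
#' @param distal_origin length-3 point, mm (see [distal_origin()]).
#' @param frame optional `anatomical_frame` when the meshes are not
#'   already canonical (default: identity frame).
#' @return a `six_dof_error`.
#' @export
decompose_6dof <- function(transform, distal_origin, frame = NULL) {
  R <- transform$rotation
  t_ <- transform$translation
  o <- as.numeric(distal_origin)
  d_world <- as.vector(R %*% o) + t_ - o
  if (!is.null(frame)) {
    F_ <- frame$rotation
    R <- t(F_) %*% R %*% F_
    d <- as.vector(t(F_) %*% d_world)
  } else {
    d <- d_world
  }
  # intrinsic X -> Z -> Y: R = Rx(a) Rz(c) Ry(b); R[1,2] = -sin(c)
  sc <- -R[1L, 2L]
  sc <- min(max(sc, -1), 1)
  phi_z <- asin(sc)
  gimbal <- abs(abs(sc) - 1) < 1e-9
  if (!gimbal) {
    phi_x <- atan2(R[3L, 2L], R[2L, 2L])
    phi_y <- atan2(R[1L, 3L], R[1L, 1L])
  } else {
    # freedom split: assign everything to phi_x
    phi_x <- atan2(-R[2L, 3L], R[3L, 3L])
    phi_y <- 0
  }
  tr <- (sum(diag(R)) - 1) / 2
  angle_3d <- acos(min(max(tr, -1), 1))
  deg <- 180 / pi
  six_dof_error(phi_x = phi_x * deg, phi_z = phi_z * deg, phi_y = phi_y * deg,
                delta_x = d[1L], delta_y = d[2L], delta_z = d[3L],
                angle_3d = angle_3d * deg, dist_3d = sqrt(sum(d^2)),
                gimbal_warning = gimbal)
}

#' Compose a rigid transform from six degrees of freedom
#'
#' Inverse of [decompose_6dof()]: builds the rotation
#' `Rx(phi_x) Rz(phi_z) Ry(phi_y)` about `distal_origin` (in the frame, if
#' given) with the stated displacement of that origin. Round-tripping
#' through [decompose_6dof()] is the identity for |angles| < 90 degrees.
#'
#' @param dof a `six_dof_error` (the `angle_3d`/`dist_3d` fields are
#'   ignored; they are derived quantities).
#' @param distal_origin length-3 point, mm.
#' @param frame optional `anatomical_frame`.
#' @return a `rigid_transform`.
#' @export
compose_6dof <- function(dof, distal_origin, frame = NULL) {
  rad <- pi / 180
  R <- axis_rotation(1L, dof$phi_x * rad) %*%
       axis_rotation(3L, dof$phi_z * rad) %*%
       axis_rotation(2L, dof$phi_y * rad)
  d <- c(dof$delta_x, dof$delta_y, dof$delta_z)
  if (!is.null(frame)) {
    F_ <- frame$rotation
    R <- F_ %*% R %*% t(F_)
    d <- as.vector(F_ %*% d)
  }
  o <- as.numeric(distal_origin)
  rigid_transform(R, o + d - as.vector(R %*% o))
}

#' Clinical 6-DOF error between a predicted and a reference bone
#'
#' End-to-end composition: extract the distal segment at `fraction` (0.12
#' for the clinical evaluation, 0.5 for the comparison mode), register the
#' reference segment onto the predicted one, and decompose the transform
#' about the reference's distal-segment centre of gravity.
#'
#' @param predicted_full,reference_full canonical-frame full
#'   `triangle_mesh`es.
#' @param fraction distal fraction (default 0.12).
#' @return a `six_dof_error` with the registration residual attached as
#'   attribute `residual_mm`.
#' @export
clinical_error <- function(predicted_full, reference_full, fraction = 0.12) {
  pseg <- extract_distal_segment(predicted_full, fraction)
  rseg <- extract_distal_segment(reference_full, fraction)
  reg <- register_distal(pseg, rseg)
  origin <- distal_origin(reference_full, fraction)
  out <- decompose_6dof(reg$transform, origin)
  attr(out, "residual_mm") <- reg$residual_mm
  out
}
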