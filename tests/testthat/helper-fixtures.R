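# Shared fixtures, built once per test run.

tetra_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
}

# small template + populations reused across files (cached)
.fixtures <- new.env()

small_template <- function() {
  if (is.null(.fixtures$tpl)) .fixtures$tpl <- make_template(n_vertices = 600)
  .fixtures$tpl
}

small_population <- function() {
  if (is.null(.fixtures$pop)) {
    .fixtures$pop <- generate_population(small_template(), n_shapes = 25,
                                         noise_sd_mm = 0.2, seed = 42)
  }
  .fixtures$pop
}

small_model <- function() {
  if (is.null(.fixtures$model)) {
    g <- gpa(small_population()$meshes)
    .fixtures$model <- build_ssm(g$aligned)
  }
  .fixtures$model
}

# independent brute-force point-to-triangle oracle (quadratic programming
# free closed form, kept deliberately separate from the package's C++ path)
bf_closest_point_triangle <- function(p, a, b, c) {
  # minimize |a + u*(b-a) + v*(c-a) - p|^2 over the triangle domain:
  # solve unconstrained, then clamp by checking all edges
  best <- NULL
  cand <- list()
  e1 <- b - a; e2 <- c - a
  M <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e2 * e1), sum(e2 * e2)))
  rhs <- c(sum(e1 * (p - a)), sum(e2 * (p - a)))
  if (abs(det(M)) > 1e-300) {
    uv <- solve(M, rhs)
    if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) {
      cand[[length(cand) + 1]] <- a + uv[1] * e1 + uv[2] * e2
    }
  }
  seg <- function(p0, p1) {
    t <- sum((p - p0) * (p1 - p0)) / sum((p1 - p0)^2)
    p0 + min(max(t, 0), 1) * (p1 - p0)
  }
  cand <- c(cand, list(seg(a, b), seg(b, c), seg(c, a)))
  d <- vapply(cand, function(q) sqrt(sum((q - p)^2)), 1)
  cand[[which.min(d)]]
}

bf_closest_point_mesh <- function(mesh, p) {
  best_d <- Inf
  best <- NULL
  for (f in seq_len(n_faces(mesh))) {
    q <- bf_closest_point_triangle(p,
                                   mesh$vertices[mesh$faces[f, 1], ],
                                   mesh$vertices[mesh$faces[f, 2], ],
                                   mesh$vertices[mesh$faces[f, 3], ])
    d <- sqrt(sum((q - p)^2))
    if (d < best_d) {
      best_d <- d
      best <- q
    }
  }
  list(point = best, distance = best_d)
}

# relative rotation angle (degrees) between two rotation matrices
kabsch_fit_angle_mats <- function(Ra, Rb) {
  R <- crossprod(Ra, Rb)
  acos(min(max((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

# rotation angle (degrees) of the least-squares rigid fit a -> b
kabsch_fit_angle <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  H <- crossprod(sweep(a, 2, ca), sweep(b, 2, cb))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  acos(min(max((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

# unit UV-sphere triangulation with roughly n vertices
sphere_mesh <- function(n) {
  nc <- max(8L, round(sqrt(n)))
  nr <- max(4L, (n - 2L) %/% nc)
  th <- 2 * pi * (seq_len(nc) - 1L) / nc
  ph <- pi * seq_len(nr) / (nr + 1L)
  v <- matrix(0, nr * nc + 2L, 3L)
  for (i in seq_len(nr)) {
    rows <- (i - 1L) * nc + seq_len(nc)
    v[rows, ] <- cbind(sin(ph[i]) * cos(th), cos(ph[i]), sin(ph[i]) * sin(th))
  }
  v[nr * nc + 1L, ] <- c(0, 1, 0)
  v[nr * nc + 2L, ] <- c(0, -1, 0)
  nxt <- c(seq_len(nc)[-1L], 1L)
  ring <- function(i) (i - 1L) * nc + seq_len(nc)
  f <- list()
  for (i in seq_len(nr - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    f[[i]] <- rbind(cbind(a, a[nxt], b[nxt]), cbind(a, b[nxt], b))
  }
  f[[nr]] <- cbind(ring(1L)[nxt], ring(1L), nr * nc + 1L)
  f[[nr + 1L]] <- cbind(ring(nr), ring(nr)[nxt], nr * nc + 2L)
  triangle_mesh(v, do.call(rbind, f))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
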