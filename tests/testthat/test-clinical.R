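test_that("distal segment extraction respects the cut fraction", {
  tpl <- make_template(n_vertices = 600, length_mm = 240)
  seg <- extract_distal_segment(tpl$mesh, 0.12)
  expect_true(all(seg$vertices[, 2] >= 0.88 * 240 - 1e-9))
  seg5 <- extract_distal_segment(tpl$mesh, 0.5)
  ext <- diff(range(seg5$vertices[, 2]))
  expect_equal(ext, 120, tolerance = 5)
})

test_that("identity and pure-translation transforms decompose exactly", {
  o <- c(0, 200, 5)
  z <- decompose_6dof(rigid_transform(), o)
  expect_equal(unlist(tidy(z)[1, 1:8]), setNames(rep(0, 8),
               c("phi_x", "phi_z", "phi_y", "delta_x", "delta_y", "delta_z",
                 "angle_3d", "dist_3d")))
  tr <- decompose_6dof(rigid_transform(diag(3), c(0, 2, 0)), o)
  expect_equal(tr$delta_y, 2)
  expect_equal(tr$dist_3d, 2)
  expect_equal(tr$angle_3d, 0)
  expect_equal(c(tr$phi_x, tr$phi_y, tr$phi_z), c(0, 0, 0))
})

test_that("pure single-axis rotations about the distal origin decompose exactly", {
  o <- c(2, 210, -3)
  for (case in list(c(1, 10), c(2, -7), c(3, 12))) {
    ax <- case[1]; deg <- case[2]
    R <- radssm:::axis_rotation(ax, deg * pi / 180)
    tf <- rigid_transform(R, o - as.vector(R %*% o))
    d <- decompose_6dof(tf, o)
    got <- c(d$phi_x, d$phi_y, d$phi_z)[ax]
    expect_equal(got, deg, tolerance = 1e-9)
    expect_equal(d$angle_3d, abs(deg), tolerance = 1e-9)
    expect_lt(d$dist_3d, 1e-9)
    # the 3D angle dominates each printed single-axis magnitude
    expect_gte(d$angle_3d + 1e-12, max(abs(c(d$phi_x, d$phi_y, d$phi_z))))
  }
})

test_that("compose/decompose round-trips are exact for angles below 30 degrees", {
  set.seed(14)
  o <- c(0, 211, 0)
  for (i in 1:25) {
    dof <- six_dof_error(phi_x = runif(1, -30, 30), phi_z = runif(1, -30, 30),
                         phi_y = runif(1, -30, 30), delta_x = runif(1, -5, 5),
                         delta_y = runif(1, -5, 5), delta_z = runif(1, -5, 5))
    frame <- if (i %% 2) NULL else build_frame(
      landmark_set(c(1, 2, 3), c(4, 250, 6), c(7, 100, 40)))
    tf <- compose_6dof(dof, o, frame)
    back <- decompose_6dof(tf, o, frame)
    for (f in c("phi_x", "phi_z", "phi_y", "delta_x", "delta_y", "delta_z")) {
      expect_equal(back[[f]], dof[[f]], tolerance = 1e-9)
    }
    expect_equal(back$dist_3d^2,
                 back$delta_x^2 + back$delta_y^2 + back$delta_z^2,
                 tolerance = 1e-12)
    # the 3D angle is convention-free: it matches the axis-angle of the
    # raw rotation matrix regardless of the frame used for the Euler split
    raw_angle <- acos(min(max((sum(diag(tf$rotation)) - 1) / 2, -1), 1)) * 180 / pi
    expect_equal(back$angle_3d, raw_angle, tolerance = 1e-9)
  }
})

test_that("gimbal-degenerate transforms are flagged but still reported", {
  o <- c(0, 200, 0)
  R <- radssm:::axis_rotation(3, 90 * pi / 180)
  d <- decompose_6dof(rigid_transform(R, o - as.vector(R %*% o)), o)
  expect_true(d$gimbal_warning)
  expect_equal(d$angle_3d, 90, tolerance = 1e-9)
})

test_that("register_distal recovers constructed transforms of a distal segment", {
  tpl <- make_template(n_vertices = 1000)
  seg <- extract_distal_segment(tpl$mesh, 0.12)
  reg0 <- register_distal(seg, seg)
  expect_lt(max(abs(reg0$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(reg0$transform$translation)), 1e-4)
  o <- distal_origin(tpl$mesh, 0.12)
  R <- radssm:::axis_rotation(1, 7 * pi / 180)
  moved <- apply_transform(rigid_transform(R, o - as.vector(R %*% o)), seg)
  reg <- register_distal(moved, seg)
  d <- decompose_6dof(reg$transform, o)
  expect_equal(d$phi_x, 7, tolerance = 0.1)
  expect_error(register_distal(seg, triangle_mesh(cbind(1:9 * 0, 1:9, 0) + 0,
                                                  rbind(c(1, 2, 3)))),
               "degenerate")
})

test_that("clinical_error recovers a generator-applied distal tilt", {
  tpl <- make_template(n_vertices = 1000)
  m <- tpl$mesh
  z <- clinical_error(m, m)
  expect_lt(abs(z$angle_3d), 1e-6)
  expect_lt(z$dist_3d, 1e-6)
  tilted <- apply_distal_rotation(m, 5, axis = 3, fraction = 0.88)
  ce <- clinical_error(tilted, m, fraction = 0.12)
  expect_equal(ce$phi_z, 5, tolerance = 0.5)
  expect_equal(ce$angle_3d, 5, tolerance = 0.5)
  expect_lt(abs(ce$phi_x), 0.5)
  # the comparison mode registering the distal half absorbs most of a
  # purely distal deformation into the alignment
  ch <- clinical_error(tilted, m, fraction = 0.5)
  expect_lt(abs(ch$phi_z), 1)
})
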