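# Midsagittal plane estimation, mirroring, rough alignment and ICP.

test_that("mirroring matches the Householder matrix oracle", {
  expect_equal(reflect_points(rbind(c(1, 2, 3)), plane3d(c(1, 0, 0), 0)),
               rbind(c(-1, 2, 3)))
  n <- c(1, 1, 1) / sqrt(3)
  H <- diag(3) - 2 * tcrossprod(n)
  p <- rbind(c(1, 0, 0), c(0.3, -2, 5))
  expect_equal(reflect_points(p, plane3d(n, 0)), p %*% t(H),
               tolerance = 1e-15)
})

test_that("mirror_mesh is an involution and an isometry", {
  for (seed in 1:5) {
    m <- random_shell(seed, n_side = 8)
    set.seed(seed + 100)
    pl <- plane3d(rnorm(3), rnorm(1, 0, 10))
    mm <- mirror_mesh(mirror_mesh(m, pl), pl)
    expect_equal(mm$vertices, m$vertices, tolerance = 1e-12)
    expect_identical(mm$faces, m$faces)
    d0 <- dist(m$vertices[1:20, ])
    d1 <- dist(mirror_mesh(m, pl)$vertices[1:20, ])
    expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-12)
  }
})

test_that("mirror_mesh reverses winding so normals stay outward", {
  m <- generate_base_face(face_params(n_vertices = 800))
  mm <- mirror_mesh(m, plane3d(c(1, 0, 0), 0))
  expect_gt(mean(vertex_normals(mm)[, 3]), 0.5)
})

test_that("the midsagittal plane of the symmetric face is x = 0", {
  m <- generate_base_face(face_params(n_vertices = 3000))
  pl <- estimate_midsagittal_plane(m)
  expect_lt(sqrt(sum((pl$normal - c(1, 0, 0))^2)), 1e-6)
  expect_lt(abs(pl$offset), 1e-6)
})

test_that("plane estimation is equivariant under a known rigid transform", {
  m <- generate_base_face(face_params(n_vertices = 3000))
  set.seed(21)
  tr <- random_rigid_transform(20, 30)
  pl <- estimate_midsagittal_plane(apply_transform(m, tr))
  n_true <- as.numeric(tr$rotation %*% c(1, 0, 0))
  d_true <- sum(n_true * tr$translation)   # image of the x = 0 plane
  if (sum(pl$normal * n_true) < 0) {
    n_true <- -n_true; d_true <- -d_true
  }
  ang <- acos(min(1, abs(sum(pl$normal * n_true)))) * 180 / pi
  expect_lt(ang, 0.01)
  expect_lt(abs(pl$offset - d_true), 1e-4 * max(1, abs(d_true)))
})

test_that("landmark planes are exact least-squares fits", {
  lm <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  pl <- estimate_midsagittal_plane(generate_base_face(face_params(n_vertices = 500)),
                                   landmarks = lm)
  expect_equal(abs(pl$normal), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(pl$offset, 0, tolerance = 1e-12)
  expect_error(estimate_midsagittal_plane(cube_mesh(),
                                          landmarks = rbind(c(0, 0, 0),
                                                            c(0, 1, 0),
                                                            c(0, 2, 0))),
               "collinear")
})

test_that("rough alignment recovers identity and exact landmark fits", {
  m <- generate_base_face(face_params(n_vertices = 1500))
  t_id <- rough_align(m, m)
  expect_equal(t_id$rotation, diag(3), tolerance = 1e-9)
  expect_equal(t_id$translation, c(0, 0, 0), tolerance = 1e-9)

  set.seed(31)
  tr <- random_rigid_transform(15, 20)
  lm_src <- m$vertices[c(10, 200, 400, 800), ]
  lm_tgt <- transform_points(lm_src, tr)
  fit <- rough_align(m, apply_transform(m, tr),
                     source_landmarks = lm_src, target_landmarks = lm_tgt)
  expect_equal(fit$rotation, tr$rotation, tolerance = 1e-9)
  expect_equal(fit$translation, tr$translation, tolerance = 1e-9)
  expect_error(rough_align(m, m, source_landmarks = lm_src[1:2, ],
                           target_landmarks = lm_tgt[1:2, ]), "3")
})

test_that("moment-based rough alignment lands inside ICP's basin", {
  m <- generate_base_face(face_params(n_vertices = 1500))
  set.seed(32)
  for (i in 1:5) {
    tr <- random_rigid_transform(10, 10)
    moved <- apply_transform(m, tr)
    fit <- rough_align(moved, m)
    truth <- invert_transform(tr)
    expect_lt(rotation_angle_deg(fit$rotation %*% t(truth$rotation)), 1)
    expect_lt(sqrt(sum((fit$translation - truth$translation)^2)), 1)
  }
})

test_that("Kabsch under landmark noise matches the optimizer oracle", {
  set.seed(41)
  m <- generate_base_face(face_params(n_vertices = 800))
  lm <- m$vertices[sample(nrow(m$vertices), 8), ]
  tr <- random_rigid_transform(12, 15)
  noisy_tgt <- transform_points(lm, tr) + matrix(rnorm(24, 0, 0.1), ncol = 3)
  fit <- kabsch(lm, noisy_tgt)
  expect_lt(rotation_angle_deg(fit$rotation %*% t(tr$rotation)), 0.5)
  oracle <- oracle_rigid_fit(lm, noisy_tgt)
  expect_lt(rotation_angle_deg(fit$rotation %*% t(oracle$rotation)), 0.05)
  expect_lt(sqrt(sum((fit$translation - oracle$translation)^2)), 0.05)
})

test_that("ICP is a fixed point on identical meshes", {
  m <- generate_base_face(face_params(n_vertices = 1500))
  fit <- icp_align(m, m)
  expect_true(fit$converged)
  expect_identical(fit$n_iterations, 1L)
  expect_lt(fit$rms_mm, 1e-9)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("ICP recovers a known rigid transform to fine tolerance", {
  m <- generate_base_face(face_params(n_vertices = 2000))
  set.seed(51)
  tr <- rigid_transform(mirrormorph:::rotation_xyz_deg(8, -3, 5),
                        c(4, -2, 3))   # 8 deg-scale rotation, 6 mm-scale shift
  src <- apply_transform(m, tr)
  truth <- invert_transform(tr)
  fit <- icp_align(src, m, init = rough_align(src, m))
  expect_lt(rotation_angle_deg(fit$transform$rotation %*% t(truth$rotation)),
            0.01)
  expect_lt(sqrt(sum((fit$transform$translation - truth$translation)^2)),
            1e-3)
  expect_lt(fit$rms_mm, 1e-6)
})

test_that("ICP iterates to convergence from a perturbed initialisation", {
  m <- generate_base_face(face_params(n_vertices = 2000))
  set.seed(52)
  for (i in 1:3) {
    tr <- random_rigid_transform(10, 10)
    src <- apply_transform(m, tr)
    truth <- invert_transform(tr)
    init <- compose_transforms(random_rigid_transform(3, 3), truth)
    fit <- icp_align(src, m, init = init)
    expect_gt(fit$n_iterations, 1L)
    expect_true(all(diff(fit$rms_history) <= 1e-12))   # monotone descent
    expect_lt(rotation_angle_deg(fit$transform$rotation %*% t(truth$rotation)),
              0.01)
    expect_lt(sqrt(sum((fit$transform$translation - truth$translation)^2)),
              1e-2)
  }
})

test_that("correspondence rejection makes ICP robust to gross outliers", {
  m <- generate_base_face(face_params(n_vertices = 2000))
  set.seed(53)
  tr <- random_rigid_transform(8, 6)
  src <- apply_transform(m, tr)
  v <- src$vertices
  out_idx <- sample(nrow(v), round(0.01 * nrow(v)))
  dirs <- matrix(rnorm(3 * length(out_idx)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  v[out_idx, ] <- v[out_idx, ] + 20 * dirs
  src2 <- triangle_mesh(v, src$faces)
  truth <- invert_transform(tr)
  fit <- icp_align(src2, m, init = rough_align(src2, m),
                   params = icp_params(max_correspondence_dist = 5))
  expect_lt(rotation_angle_deg(fit$transform$rotation %*% t(truth$rotation)),
            0.1)
  expect_lt(sqrt(sum((fit$transform$translation - truth$translation)^2)),
            0.05)
  expect_lt(fit$inlier_fraction, 1)
})

test_that("ICP fails loudly when no correspondences are acceptable", {
  m <- generate_base_face(face_params(n_vertices = 500))
  far <- apply_transform(m, rigid_transform(diag(3), c(500, 0, 0)))
  expect_error(icp_align(far, m,
                         params = icp_params(max_correspondence_dist = 1)),
               "iteration 1")
})

test_that("ICP parameter validation rejects nonsense", {
  expect_error(icp_params(max_iterations = 0), "max_iterations")
  expect_error(icp_params(convergence_tol = 0), "convergence_tol")
  expect_error(icp_params(normal_compat_min_cos = 2), "normal_compat")
})
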