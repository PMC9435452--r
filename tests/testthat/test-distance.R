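test_that("coincident surfaces give an all-zero map with + sign", {
  m <- generate_base_face(face_params(n_vertices = 1000))
  dm <- signed_distance_map(m, m)
  expect_equal(dm$absolute, rep(0, nrow(m$vertices)))
  expect_equal(dm$signed, rep(0, nrow(m$vertices)))
  expect_equal(abs(dm$signed), dm$absolute)
})

test_that("parallel flat patches 2 mm apart get distance 2 and the right sign", {
  g <- seq(0, 10, by = 1)
  xy <- as.matrix(expand.grid(x = g, y = g))
  idx <- matrix(seq_len(121), 11, 11)
  a <- idx[-11, -11]; b <- idx[-1, -11]; cc <- idx[-11, -1]; d <- idx[-1, -1]
  faces <- rbind(cbind(as.vector(a), as.vector(b), as.vector(d)),
                 cbind(as.vector(a), as.vector(d), as.vector(cc)))
  lower <- triangle_mesh(cbind(xy, 0), faces)    # CCW from +z: normals up
  upper <- triangle_mesh(cbind(xy, 2), faces)
  dm <- signed_distance_map(lower, upper)
  expect_equal(dm$absolute, rep(2, 121))
  # the upper patch lies along the lower patch's outward normal: sign +
  expect_equal(dm$signed, rep(2, 121))
  # and seen from the upper patch the lower one is behind its normal: sign -
  dm2 <- signed_distance_map(upper, lower)
  expect_equal(dm2$signed, rep(-2, 121))
})

test_that("accelerated distances equal the brute-force all-triangle oracle", {
  for (seed in 1:3) {
    target <- random_shell(seed, n_side = 10)
    set.seed(seed + 500)
    q <- target$vertices[sample(nrow(target$vertices), 60), ] +
      matrix(rnorm(180, 0, 4), ncol = 3)
    fast <- closest_points(q, target)$distance
    slow <- oracle_closest_distance(q, target)
    expect_equal(fast, slow, tolerance = 1e-9)
  }
})

test_that("lesioned-face distance maps match the brute-force oracle", {
  m <- generate_base_face(face_params(n_vertices = 700))
  lesioned <- apply_atrophy(m, test_lesion(depth = 3))
  mirrored <- mirror_mesh(lesioned, plane3d(c(1, 0, 0), 0))
  dm <- signed_distance_map(lesioned, mirrored)
  slow <- oracle_closest_distance(lesioned$vertices, mirrored)
  expect_equal(dm$absolute, slow, tolerance = 1e-9)
})

test_that("asymmetry summaries reproduce hand arithmetic", {
  dm <- structure(list(signed = c(0.5, -1.5, 3.0, -6.0),
                       absolute = c(0.5, 1.5, 3.0, 6.0),
                       mesh = NULL), class = "distance_map")
  rep <- summarize_asymmetry(dm, cutoffs = c(1, 2, 5))
  expect_equal(rep$t_mean_mm, 2.75)
  expect_equal(unname(rep$pct_within), c(25, 50, 75))
  # population SD (divide by n)
  expect_equal(rep$t_sd_mm, sqrt(mean((c(0.5, 1.5, 3, 6) - 2.75)^2)))

  null_dm <- structure(list(signed = rep(0, 5), absolute = rep(0, 5),
                            mesh = NULL), class = "distance_map")
  rep0 <- summarize_asymmetry(null_dm)
  expect_equal(rep0$t_mean_mm, 0)
  expect_equal(unname(rep0$pct_within), c(100, 100, 100))
})

test_that("cut-off percentages are inclusive and monotone in the cut-off", {
  dm <- structure(list(signed = c(1, 2, 5), absolute = c(1, 2, 5),
                       mesh = NULL), class = "distance_map")
  rep <- summarize_asymmetry(dm, cutoffs = c(1, 2, 5))
  expect_equal(unname(rep$pct_within), c(100 / 3, 200 / 3, 100))  # <= inclusive
  for (seed in 1:10) {
    set.seed(seed)
    a <- abs(rnorm(200, 1, 1.5))
    dmr <- structure(list(signed = a, absolute = a, mesh = NULL),
                     class = "distance_map")
    p <- summarize_asymmetry(dmr, cutoffs = c(1, 2, 5))$pct_within
    expect_true(all(diff(p) >= 0))
  }
  expect_error(summarize_asymmetry(dm, cutoffs = c(2, 1)), "ascending")
})

test_that("summary statistics are invariant to rigid motion and relabeling", {
  m <- generate_base_face(face_params(n_vertices = 700))
  lesioned <- apply_atrophy(m, test_lesion(depth = 2))
  mirrored <- mirror_mesh(lesioned, plane3d(c(1, 0, 0), 0))
  base_rep <- summarize_asymmetry(signed_distance_map(lesioned, mirrored))

  set.seed(61)
  tr <- random_rigid_transform(30, 40)
  rep_t <- summarize_asymmetry(signed_distance_map(
    apply_transform(lesioned, tr), apply_transform(mirrored, tr)))
  expect_equal(rep_t$t_mean_mm, base_rep$t_mean_mm, tolerance = 1e-9)
  expect_equal(rep_t$pct_within, base_rep$pct_within)

  # permute the vertices of the target surface: same surface, same stats
  perm <- sample(nrow(mirrored$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  shuffled <- triangle_mesh(mirrored$vertices[perm, ],
                            matrix(inv[mirrored$faces], ncol = 3))
  rep_p <- summarize_asymmetry(signed_distance_map(lesioned, shuffled))
  expect_equal(rep_p$t_mean_mm, base_rep$t_mean_mm, tolerance = 1e-12)
})

test_that("colour mapping hits the endpoints, midpoint and clips", {
  mesh <- generate_base_face(face_params(n_vertices = 150))
  signed <- rep(c(0, 5, -5, 10, -12, 2.5), length.out = nrow(mesh$vertices))
  dm <- structure(list(signed = signed, absolute = abs(signed), mesh = mesh),
                  class = "distance_map")
  col <- export_colour_map(dm, range_mm = 5)$colors
  expect_identical(col[1, ], c(255L, 255L, 255L))   # zero -> neutral white
  expect_identical(col[2, ], c(0L, 255L, 0L))       # +range -> pure green
  expect_identical(col[3, ], c(255L, 0L, 0L))       # -range -> pure red
  expect_identical(col[4, ], col[2, ])              # clipped above
  expect_identical(col[5, ], col[3, ])              # clipped below
  expect_error(export_colour_map(dm, range_mm = 0), "range_mm")
})

test_that("area weighting changes weights but keeps percentages in range", {
  m <- generate_base_face(face_params(n_vertices = 700))
  lesioned <- apply_atrophy(m, test_lesion(depth = 3))
  dm <- signed_distance_map(lesioned,
                            mirror_mesh(lesioned, plane3d(c(1, 0, 0), 0)))
  r1 <- summarize_asymmetry(dm)
  r2 <- summarize_asymmetry(dm, area_weighted = TRUE)
  expect_true(all(r2$pct_within >= 0 & r2$pct_within <= 100))
  expect_false(identical(r1$t_mean_mm, r2$t_mean_mm))
})
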