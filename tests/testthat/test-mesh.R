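test_that("signed volume and area match closed-form values", {
  expect_equal(mesh_volume(unit_cube_mesh()), 1)
  expect_equal(mesh_area(unit_cube_mesh()), 6)
  expect_equal(mesh_volume(unit_tetrahedron()), 1 / 6)
})

test_that("mesh validation rejects malformed input", {
  expect_error(triangle_mesh(rbind(c(0, 0, NA)), rbind(c(1, 1, 1))),
               "non-finite")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1, 2, 4))), "out of range")
  expect_error(validate_mesh(unit_tetrahedron()), NA)
  tiny <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3)))
  expect_error(validate_mesh(tiny, strict = TRUE), "too small")
})

test_that("mirroring reflects x, keeps positive volume, and is an involution", {
  m <- triangle_mesh(rbind(c(1, 2, 3), c(2, 2, 3), c(1, 3, 3), c(1, 2, 4)),
                     rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  m0 <- mirror_mesh(m, 0)
  expect_equal(m0$vertices[1, ], c(-1, 2, 3))
  expect_identical(mirror_mesh(mirror_mesh(m, 5), 5), m)
  cube <- unit_cube_mesh()
  expect_gt(mesh_volume(mirror_mesh(cube, 2)), 0)
})

test_that("noiseless left phantom is the exact mirror of the right", {
  spec <- test_spec()
  r <- make_leg(spec, "right")
  l <- make_leg(spec, "left")
  for (bone in names(r)) {
    expect_equal(mirror_mesh(l[[bone]], 0)$vertices, r[[bone]]$vertices)
    d <- mean_surface_distance(mirror_mesh(l[[bone]], 0), r[[bone]],
                               n = 2000, seed = 1)
    expect_lt(d, 1e-6)
  }
})

test_that("surface sampling is area-uniform and seed-deterministic", {
  # two coplanar triangles with area ratio 9:1
  m <- triangle_mesh(rbind(c(0, 0, 0), c(9, 0, 0), c(0, 2, 0),
                           c(10, 0, 0), c(9, 2, 0)),
                     rbind(c(1, 2, 3), c(2, 4, 5)))
  n <- 100000L
  p <- sample_surface(m, n, seed = 7)
  expect_equal(nrow(p), n)
  expect_true(all(abs(p[, 3]) < 1e-9))      # on the face planes
  counts <- tabulate(attr(p, "face"), 2)
  ratio <- 0.9
  sigma <- sqrt(n * ratio * (1 - ratio))
  expect_lt(abs(counts[1] - n * ratio), 3 * sigma)
  # chi-squared check of face frequencies against area weights
  chi <- sum((counts - n * c(0.9, 0.1))^2 / (n * c(0.9, 0.1)))
  expect_gt(stats::pchisq(chi, df = 1, lower.tail = FALSE), 0.001)
  expect_identical(sample_surface(m, 100, seed = 3),
                   sample_surface(m, 100, seed = 3))
  expect_error(sample_surface(m, 0), ">= 1")
})

test_that("sampled centre of mass converges to the exact surface centroid", {
  tib <- make_leg(test_spec(), "right")$tibia
  exact <- exact_surface_centroid(tib)
  com <- center_of_mass(tib, n = 100000L, seed = 1)
  # standard error of the mean surface sample, per axis
  p <- sample_surface(tib, 100000L, seed = 1)
  se <- apply(p, 2, sd) / sqrt(nrow(p))
  expect_true(all(abs(com - exact) < 3 * se))
  # translation equivariance at fixed seed
  com_shift <- center_of_mass(translate_mesh(tib, c(10, 0, 0)),
                              n = 5000, seed = 4)
  expect_equal(com_shift, center_of_mass(tib, n = 5000, seed = 4) +
                 c(10, 0, 0))
})

test_that("centre-of-mass standard error scales as 1/sqrt(n)", {
  tib <- make_leg(test_spec(), "right")$tibia
  reps <- 100
  spread <- function(n, off) {
    coms <- t(vapply(seq_len(reps),
                     function(s) center_of_mass(tib, n, seed = off + s),
                     numeric(3)))
    apply(coms, 2, sd)
  }
  s1 <- spread(1000, 100)
  s4 <- spread(4000, 900)
  expect_lt(abs(mean(s1 / s4) - 2), 0.4)   # factor-2 drop within 20 %
})

test_that("mesh merging re-offsets faces and preserves totals", {
  a <- unit_cube_mesh()
  b <- unit_cube_mesh(origin = c(5, 0, 0))
  m <- merge_meshes(list(a, b))
  expect_equal(nrow(m$vertices), 16)
  expect_equal(mesh_volume(m), 2)
  expect_error(merge_meshes(list()), "no meshes")
})
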