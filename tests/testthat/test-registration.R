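test_that("kabsch recovers exact transforms and rejects degenerate input", {
  set.seed(5)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch(P, P)$rotation, diag(3), tolerance = 1e-12)
  tr <- rigid_transform(axis_rotation("z", 30), c(1, 2, 3))
  Q <- apply_transform(tr, P)
  est <- kabsch(P, Q)
  expect_lt(max(abs(est$rotation - tr$rotation)), 1e-9)
  expect_lt(max(abs(est$translation - tr$translation)), 1e-9)
  expect_error(kabsch(P[1:2, ], Q[1:2, ]), ">= 3")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch(line, line + 1), "collinear")
  # determinant is forced to +1 even for mirrored targets
  Qm <- P %*% diag(c(-1, 1, 1))
  expect_equal(det(kabsch(P, Qm)$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch beats a large random-search oracle on noisy points", {
  set.seed(11)
  P <- matrix(rnorm(12), 4, 3)
  Q <- apply_transform(rigid_transform(axis_rotation("y", 25), c(1, 0, -2)),
                       P) + matrix(rnorm(12, 0, 0.1), 4, 3)
  est <- kabsch(P, Q)
  best <- sum((apply_transform(est, P) - Q)^2)
  n <- 100000L
  obj <- random_transform_objectives(P, Q, n, seed = 99)
  expect_lte(best, min(obj))
})

test_that("mean surface distance matches closed-form cases", {
  cube <- unit_cube_mesh()
  expect_lt(mean_surface_distance(cube, cube, n = 2000, seed = 1), 1e-9)
  # two parallel unit squares 0.5 mm apart
  sq <- function(z) triangle_mesh(rbind(c(0, 0, z), c(1, 0, z),
                                        c(1, 1, z), c(0, 1, z)),
                                  rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(mean_surface_distance(sq(0), sq(0.5), n = 2000, seed = 1),
               0.5, tolerance = 1e-12)
  # unit spheres 1 mm apart: compare with the closed-form expectation
  sph <- function(x) ctma:::ellipsoid_mesh(c(x, 0, 0), c(1, 1, 1),
                                           n_lat = 48, n_lon = 72)
  got <- mean_surface_distance(sph(0), sph(1), n = 20000, seed = 2)
  want <- stats::integrate(function(th)
    abs(2 * sin(th / 2) - 1) * sin(th) / 2, 0, pi)$value
  expect_equal(got, want, tolerance = 0.01)
})

test_that("initial alignment handles identity, large rotations and spheres", {
  tib <- make_leg(test_spec(), "right")$tibia
  t0 <- initial_align(tib, tib)
  expect_lt(rotation_angle(t0), 1)
  expect_lt(sqrt(sum(t0$translation^2)), 1)
  moved <- apply_transform(rigid_transform(axis_rotation("z", 170)), tib)
  t1 <- initial_align(moved, tib)
  resid <- compose_transform(t1, rigid_transform(axis_rotation("z", 170)))
  expect_lt(rotation_angle(resid), 20)
  # degenerate principal axes: falls back to centroid alignment
  sph <- ctma:::ellipsoid_mesh(c(5, 5, 5), c(10, 10, 10), 16, 24)
  t2 <- initial_align(sph, ctma:::ellipsoid_mesh(c(0, 0, 0), c(10, 10, 10),
                                                 16, 24))
  expect_equal(t2$rotation, diag(3))
  expect_equal(t2$translation, c(-5, -5, -5), tolerance = 0.5)
})

test_that("ICP recovers a known transform and its objective never increases", {
  tib <- make_leg(test_spec(), "right")$tibia
  tr <- rigid_transform(axis_rotation("z", 5), c(2, 0, 0))
  fixed <- apply_transform(tr, tib)
  res <- icp_register(tib, fixed, test_params())
  expect_lt(rotation_angle(compose_transform(invert_transform(tr),
                                             res$transform)), 0.01)
  expect_lt(max(abs(res$transform$translation - tr$translation)), 0.01)
  expect_lt(res$fit$mean_distance, 1e-3)
  expect_true(res$fit$passed_gate)
  expect_true(all(diff(res$history) <= 1e-12))
  # identical meshes: identity within 1e-6
  res0 <- icp_register(tib, tib, test_params())
  expect_lt(rotation_angle(res0$transform), 1e-4)
  expect_lt(sqrt(sum(res0$transform$translation^2)), 1e-4)
})

test_that("registration is equivariant to pre-rotation of the moving mesh", {
  tib <- make_leg(test_spec(resolution = 0.4), "right")$tibia
  fixed <- apply_transform(rigid_transform(axis_rotation("y", 4), c(1, 1, 0)),
                           tib)
  p <- test_params(convergence_tol = 1e-9, max_iterations = 200)
  base <- icp_register(tib, fixed, p)
  pre <- rigid_transform(axis_rotation("x", 7), c(0, 3, -2))
  moved <- apply_transform(pre, tib)
  res <- icp_register(moved, fixed, p,
                      init = compose_transform(base$transform,
                                               invert_transform(pre)))
  combined <- compose_transform(res$transform, pre)
  expect_lt(rotation_angle(compose_transform(invert_transform(base$transform),
                                             combined)), 1e-4)
  expect_lt(max(abs(combined$translation - base$transform$translation)),
            1e-3)
})

test_that("trimming makes registration robust to a welded artifact bump", {
  spec <- test_spec(resolution = 0.4)
  tib <- make_leg(spec, "right")$tibia
  tr <- rigid_transform(axis_rotation("z", 3), c(1, 0, 1))
  fixed <- apply_transform(tr, tib)
  # weld a spurious bump (~5 % of surface area) onto the moving mesh
  bump <- ctma:::ellipsoid_mesh(c(0, 18, 150), c(10, 10, 14), 10, 14)
  moving_bumped <- merge_meshes(list(tib, bump), "bumped")
  p <- test_params(trim_fraction = 0.1)
  clean <- icp_register(tib, fixed, p)
  bumped <- icp_register(moving_bumped, fixed, p)
  diff_rot <- rotation_angle(compose_transform(
    invert_transform(clean$transform), bumped$transform))
  expect_lt(diff_rot, 0.2)
})

test_that("fit quality is gated at the configured mean distance", {
  spec <- test_spec(resolution = 0.4)
  tib <- make_leg(spec, "right")$tibia
  res <- icp_register(tib, tib, test_params(fit_threshold = 0.5))
  expect_true(res$fit$passed_gate)
  expect_identical(res$fit$passed_gate,
                   res$fit$mean_distance <= res$fit$fit_threshold)
  expect_error(reg_params(trim_fraction = 0.7), "trim_fraction")
  expect_error(reg_params(fit_threshold = -1), "positive")
})
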