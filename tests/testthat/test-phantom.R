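test_that("phantom bones are closed, positively oriented and seeded", {
  bones <- make_leg(test_spec(), "right")
  for (m in bones) {
    expect_gt(mesh_volume(m), 0)
    edges <- rbind(m$faces[, c(1, 2)], m$faces[, c(2, 3)],
                   m$faces[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    expect_true(all(table(key) == 2))   # watertight
  }
  # generators are seed-deterministic
  a <- make_leg(test_spec(noise_sd = 0.3, seed = 5), "left")
  b <- make_leg(test_spec(noise_sd = 0.3, seed = 5), "left")
  expect_identical(a$tibia$vertices, b$tibia$vertices)
})

test_that("a golden STL hash pins the reference phantom geometry", {
  tib <- make_leg(phantom_spec(resolution = 0.4), "right")$tibia
  path <- tempfile(fileext = ".stl")
  write_stl(tib, path)
  expect_identical(unname(tools::md5sum(path)),
                   "ad9b22c47ff1b288b7f6b88949cd19c0")
})

test_that("sharp distal torsion rotates the distal cross-section frame", {
  ang <- 10
  spec <- test_spec(deformities = list(list(
    segment = "distal", axis = "z", angle_deg = ang, transition = "sharp")))
  right <- make_leg(spec, "right")$tibia
  left <- make_leg(spec, "left")$tibia
  # compare principal directions of matched distal ring vertices (the
  # meshes are vertex-matched by construction)
  sel <- right$vertices[, 3] < 40 & right$vertices[, 3] > 5
  vr <- right$vertices[sel, 1:2]
  vl <- cbind(-left$vertices[sel, 1], left$vertices[sel, 2])  # un-mirror
  vr <- sweep(vr, 2, colMeans(vr)); vl <- sweep(vl, 2, colMeans(vl))
  # angle of optimal 2D rotation aligning the matched point sets
  th <- atan2(sum(vr[, 1] * vl[, 2] - vr[, 2] * vl[, 1]),
              sum(vr[, 1] * vl[, 1] + vr[, 2] * vl[, 2]))
  # un-mirrored left carries the conjugated (sign-flipped) torsion
  expect_equal(th * 180 / pi, -ang, tolerance = 0.1)
})

test_that("surface noise has the half-normal displacement scale", {
  sd <- 0.3
  clean <- make_leg(test_spec(resolution = 0.8), "right")$tibia
  noisy <- make_leg(test_spec(resolution = 0.8, noise_sd = sd, seed = 12),
                    "right")$tibia
  # vertices are displaced along normals by N(0, sd): their mean distance
  # to the clean surface is the half-normal mean E|N(0, sd^2)|
  d <- mean(closest_surface_points(noisy$vertices, clean)$distance)
  expect_equal(d, sd * sqrt(2 / pi), tolerance = 0.1 * sd * sqrt(2 / pi))
})

test_that("cohort truth follows the requested deformity distribution", {
  coh <- make_cohort(50, sd_rot = 2, sd_trans = 1,
                     spec = test_spec(resolution = 0.2), seed = 21)
  expect_equal(nrow(coh$truth), 50)
  s <- sd(coh$truth$rotZ)
  # chi-squared bound on a sample sd of n = 50 draws at sigma = 2
  lim <- sqrt(qchisq(c(0.0013, 0.9987), df = 49) / 49) * 2
  expect_gt(s, lim[1]); expect_lt(s, lim[2])
  # degenerate distributions give an all-zero truth table
  coh0 <- make_cohort(4, sd_rot = 0, sd_trans = 0,
                      spec = test_spec(resolution = 0.2), seed = 3)
  expect_true(all(abs(as.matrix(coh0$truth[, -1])) < 1e-9))
  # determinism: the same seed reproduces the cohort exactly
  coh2 <- make_cohort(4, sd_rot = 0, sd_trans = 0,
                      spec = test_spec(resolution = 0.2), seed = 3)
  expect_identical(coh2$truth, coh0$truth)
  expect_identical(coh2$pairs[[1]]$right[[1]]$vertices,
                   coh0$pairs[[1]]$right[[1]]$vertices)
})

test_that("rasterization reproduces analytic volumes and rejects open meshes", {
  sph <- ctma:::ellipsoid_mesh(c(0, 0, 0), c(20, 20, 20), 36, 54)
  vol <- rasterize_meshes(sph, spacing = 1, hu_soft = -1000)
  count <- sum(vol$intensities >= 1000)
  analytic <- 4 / 3 * pi * 20^3
  # UV-sphere volume is slightly under the true ball; 2 % covers both
  expect_lt(abs(count - analytic) / analytic, 0.02)
  # HU levels present: bone and air
  expect_setequal(unique(as.vector(vol$intensities)), c(-1000, 1200))
  open <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3)))
  expect_error(rasterize_meshes(open), "non-closed")
})

test_that("the soft-tissue hull wraps the bone at intermediate HU", {
  cube <- unit_cube_mesh(edge = 8)
  vol <- rasterize_meshes(cube, spacing = 1, soft_mm = 3)
  expect_true(all(c(-1000, 40, 1200) %in% unique(as.vector(vol$intensities))))
  # soft voxels surround bone voxels
  d <- dim(vol$intensities)
  bone <- which(vol$intensities == 1200, arr.ind = TRUE)
  soft <- which(vol$intensities == 40, arr.ind = TRUE)
  expect_gt(nrow(soft), 0)
  expect_true(min(soft[, 1]) < min(bone[, 1]))
})

test_that("the packaged reference cohort passes its self-check", {
  ref <- load_reference_cohort()
  expect_equal(dim(ref), c(10L, 7L))
  expect_equal(ref$COMX_mm[2], -5.476)
  expect_equal(mean(ref$COMX_mm), -1.626, tolerance = 1e-3)
  printed <- c(-1.626, -0.739, 0.910, -0.264, 0.703, -1.184)
  expect_true(all(abs(colMeans(ref[, -1]) - printed) <= 0.01))
})

test_that("deformity specification is validated", {
  expect_error(phantom_spec(tibia_length = -1), "positive")
  expect_error(phantom_spec(noise_sd = -0.1), ">= 0")
  expect_error(phantom_spec(deformities = list(list(axis = "z",
                                                    angle_deg = 95))),
               "< 90")
})
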