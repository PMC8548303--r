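# analytic cylinder-pair volume: two parallel bone-like rods in air
cylinder_volume <- function(r_vox = 6, h = 30, sep = 20, d = c(50, 24, 34)) {
  hu <- array(-1000, d)
  idx <- arrayInd(seq_len(prod(d)), d)
  inz <- idx[, 3] > 2 & idx[, 3] <= 2 + h
  c1 <- (idx[, 1] - 13)^2 + (idx[, 2] - 12)^2 <= r_vox^2
  c2 <- (idx[, 1] - 13 - sep)^2 + (idx[, 2] - 12)^2 <= r_vox^2
  hu[inz & (c1 | c2)] <- 1200
  list(volume = voxel_volume(hu, spacing = c(1, 1, 1), origin = c(0, 0, 0)),
       count1 = sum(inz & c1), count2 = sum(inz & c2 & !c1))
}

test_that("seeded growing segments two cylinders into disjoint masks", {
  cv <- cylinder_volume()
  segs <- segment_bones(cv$volume,
                        list(seed_click(c(12, 11, 15), "tibia"),
                             seed_click(c(32, 11, 15), "fibula")),
                        hu_threshold = 250)
  n1 <- sum(segs$tibia$mask); n2 <- sum(segs$fibula$mask)
  expect_lt(abs(n1 - cv$count1) / cv$count1, 0.02)
  expect_lt(abs(n2 - cv$count2) / cv$count2, 0.02)
  # analytic cylinder volume within 2 % of pi r^2 h
  expect_lt(abs(n1 - pi * 36 * 30) / (pi * 36 * 30), 0.05)
  expect_false(any(segs$tibia$mask & segs$fibula$mask))
  expect_true(segs$tibia$mask[13, 12, 15])
})

test_that("a threshold above all intensities rejects the seed", {
  cv <- cylinder_volume()
  expect_error(segment_bones(cv$volume, seed_click(c(12, 11, 15), "tibia"),
                             hu_threshold = 2000), "below threshold")
  expect_error(segment_bones(cv$volume, seed_click(c(500, 0, 0), "x")),
               "outside")
})

test_that("two seeds in one region split it by the nearest-seed rule", {
  cv <- cylinder_volume()
  segs <- segment_bones(cv$volume,
                        list(seed_click(c(12, 11, 6), "lower"),
                             seed_click(c(12, 11, 28), "upper")),
                        hu_threshold = 250)
  expect_false(any(segs$lower$mask & segs$upper$mask))
  # union reproduces the full connected region
  expect_equal(sum(segs$lower$mask) + sum(segs$upper$mask), cv$count1)
  # voxels split by z proximity to the seeds
  zl <- range(arrayInd(which(segs$lower$mask), dim(segs$lower$mask))[, 3])
  zu <- range(arrayInd(which(segs$upper$mask), dim(segs$upper$mask))[, 3])
  expect_lt(zl[2], zu[1] + 1)
})

test_that("segmentation is idempotent on its own rasterization", {
  cv <- cylinder_volume()
  segs <- segment_bones(cv$volume, seed_click(c(12, 11, 15), "tibia"))
  hu2 <- array(-1000, dim(cv$volume$intensities))
  hu2[segs$tibia$mask] <- 1200
  segs2 <- segment_bones(voxel_volume(hu2), seed_click(c(12, 11, 15),
                                                       "tibia"))
  expect_identical(segs2$tibia$mask, segs$tibia$mask)
})

test_that("a region touching the volume border is flagged", {
  hu <- array(-1000, c(10, 10, 10))
  hu[1:4, 4:6, 4:6] <- 1200
  expect_warning(
    segs <- segment_bones(voxel_volume(hu), seed_click(c(1, 4, 4), "b")),
    "border")
  expect_true(segs$b$touches_border)
})

test_that("mask meshing reproduces analytic volumes", {
  hu <- array(-1000, c(16, 16, 16))
  hu[4:13, 4:13, 4:13] <- 1200   # 10x10x10 voxel cube at 1 mm spacing
  segs <- segment_bones(voxel_volume(hu), seed_click(c(8, 8, 8), "cube"))
  m_raw <- mask_to_mesh(segs$cube, smooth_iterations = 0)
  expect_equal(mesh_volume(m_raw), 1000, tolerance = 1e-9)
  m_smooth <- mask_to_mesh(segs$cube)
  expect_lt(abs(mesh_volume(m_smooth) - 1000), 50)
  # single isolated voxel: a small closed positive-volume mesh
  hu1 <- array(-1000, c(5, 5, 5)); hu1[3, 3, 3] <- 1200
  seg1 <- segment_bones(voxel_volume(hu1), seed_click(c(2, 2, 2), "dot"))
  m1 <- mask_to_mesh(seg1$dot, smooth_iterations = 0)
  expect_equal(mesh_volume(m1), 1, tolerance = 1e-12)
  expect_equal(nrow(m1$faces), 12)
  expect_error(mask_to_mesh(structure(list(mask = array(FALSE, c(2, 2, 2)),
                                           spacing = c(1, 1, 1),
                                           origin = c(0, 0, 0), label = "e"),
                                      class = "ctma_mask")), "empty")
})

test_that("meshed phantom mask stays within a voxel diagonal of the truth", {
  spec <- test_spec(resolution = 0.4, tibia_length = 150,
                    fibula_length = 145)
  bones <- make_leg(spec, "right")
  vol <- rasterize_meshes(bones, spacing = 1.25)
  segs <- segment_bones(vol, list(seed_click(c(0, 0, 75), "tibia"),
                                  seed_click(c(36, 5, 75), "fibula")))
  m <- mask_to_mesh(segs$tibia)
  d <- mean_surface_distance(m, bones$tibia, n = 4000, seed = 1)
  expect_lt(d, 1.25 * sqrt(3))
  # blob-like mask: signed volume within 5 % of voxel count x voxel volume
  vox_vol <- sum(segs$tibia$mask) * prod(vol$spacing)
  expect_lt(abs(mesh_volume(m) - vox_vol) / vox_vol, 0.05)
})
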