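# Shared fixtures: small meshes built in code, compact phantom settings and
# registration parameters sized for test runtime.

unit_tetrahedron <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)),
    label = "tet")
}

unit_cube_mesh <- function(origin = c(0, 0, 0), edge = 1) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * edge
  v <- sweep(v, 2, origin, "+")
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  triangle_mesh(v, f, label = "cube")
}

# small phantom + registration settings used across pipeline tests
test_spec <- function(...) {
  a <- list(...)
  if (is.null(a$resolution)) a$resolution <- 0.5
  do.call(phantom_spec, a)
}
test_params <- function(seed = 2L, ...)
  reg_params(n_points = 3000L, fit_points = 2000L, seed = seed, ...)

random_pose <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  rigid_transform(R, runif(3, -50, 50))
}

pose_pair <- function(pair, tr) {
  leg_pair(lapply(pair$right, function(m) apply_transform(tr, m)),
           lapply(pair$left, function(m) apply_transform(tr, m)),
           pair$subject)
}

max_report_error <- function(report, truth = rep(0, 6)) {
  max(abs(c(report$com, report$rot) - truth))
}

# distal injection realizing given report-convention targets
target_deformity <- function(rot = c(0, 0, 0), com = c(0, 0, 0),
                             spec = test_spec()) {
  ctma:::deformity_from_report(spec, rot = rot, com = com)
}

# vectorized objective of n random rigid transforms on paired points: the
# random-search oracle that a least-squares solution must dominate
random_transform_objectives <- function(P, Q, n, seed) {
  set.seed(seed)
  ax <- matrix(rnorm(3 * n), n, 3)
  ax <- ax / sqrt(rowSums(ax^2))
  ang <- runif(n, 0, pi)
  s <- sin(ang); cth <- cos(ang); C <- 1 - cth
  x <- ax[, 1]; y <- ax[, 2]; z <- ax[, 3]
  R11 <- cth + x * x * C; R12 <- x * y * C - z * s; R13 <- x * z * C + y * s
  R21 <- y * x * C + z * s; R22 <- cth + y * y * C; R23 <- y * z * C - x * s
  R31 <- z * x * C - y * s; R32 <- z * y * C + x * s; R33 <- cth + z * z * C
  tx <- runif(n, -5, 5); ty <- runif(n, -5, 5); tz <- runif(n, -5, 5)
  obj <- numeric(n)
  for (i in seq_len(nrow(P))) {
    dx <- R11 * P[i, 1] + R12 * P[i, 2] + R13 * P[i, 3] + tx - Q[i, 1]
    dy <- R21 * P[i, 1] + R22 * P[i, 2] + R23 * P[i, 3] + ty - Q[i, 2]
    dz <- R31 * P[i, 1] + R32 * P[i, 2] + R33 * P[i, 3] + tz - Q[i, 3]
    obj <- obj + dx^2 + dy^2 + dz^2
  }
  obj
}
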