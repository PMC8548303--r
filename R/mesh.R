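#' Triangle surface mesh
#'
#' Constructs a triangle mesh in patient coordinates (millimetres).  The
#' canonical frame of the package follows the radiological convention used
#' throughout: the X axis runs from left to right, Y from front to back and
#' Z from the feet towards the head.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param label free-text bone or segment name.
#' @return an object of class `ctma_mesh` with elements `vertices`, `faces`
#'   and `label`.
#' @export
triangle_mesh <- function(vertices, faces, label = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  mesh <- structure(list(vertices = vertices, faces = faces,
                         label = as.character(label)),
                    class = "ctma_mesh")
  validate_mesh(mesh)
  mesh
}

#' Validate a triangle mesh
#'
#' Checks finiteness of coordinates and validity of face indices.  With
#' `strict = TRUE` additionally requires at least 4 vertices and 4 faces,
#' the minimum for a surface usable in registration.
#'
#' @param mesh a `ctma_mesh`.
#' @param strict require registration-grade size.
#' @return the mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh, strict = FALSE) {
  if (!inherits(mesh, "ctma_mesh")) stop("not a ctma_mesh")
  if (!all(is.finite(mesh$vertices))) stop("non-finite vertex coordinates")
  if (nrow(mesh$faces) < 1L) stop("mesh has no faces")
  if (min(mesh$faces) < 1L || max(mesh$faces) > nrow(mesh$vertices))
    stop("face index out of range")
  if (strict && (nrow(mesh$vertices) < 4L || nrow(mesh$faces) < 4L))
    stop("mesh too small for registration (need >= 4 vertices and faces)")
  invisible(mesh)
}

#' @export
print.ctma_mesh <- function(x, ...) {
  cat(sprintf("ctma_mesh '%s': %d vertices, %d faces\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# per-face vertex coordinate arrays, used by several mesh reductions
face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-face areas of a mesh
#' @param mesh a `ctma_mesh`.
#' @return numeric vector of triangle areas (mm^2).
#' @export
face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- cross3(fc$b - fc$a, fc$c - fc$a)
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area (mm^2)
#' @param mesh a `ctma_mesh`.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Signed volume of a closed mesh
#'
#' Divergence-theorem volume: one sixth of the sum of scalar triple
#' products over faces.  Positive for consistently outward-wound closed
#' surfaces.
#'
#' @param mesh a `ctma_mesh`.
#' @return signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
}

#' Exact area-weighted surface centroid
#'
#' Closed-form surface centroid (area-weighted mean of face centroids);
#' serves as the analytic cross-check for the sampled centre of mass.
#'
#' @param mesh a `ctma_mesh`.
#' @return 3-vector (mm).
#' @export
exact_surface_centroid <- function(mesh) {
  ar <- face_areas(mesh)
  if (sum(ar) <= 0) stop("mesh has zero surface area")
  fc <- face_corners(mesh)
  centroids <- (fc$a + fc$b + fc$c) / 3
  colSums(centroids * ar) / sum(ar)
}

#' Mirror a mesh about a plane x = const
#'
#' Reflects the x coordinates about the plane `x = plane_x` (the YZ plane
#' shifted by `plane_x`), flipping the face winding so a closed mesh keeps
#' positive signed volume.  Mirroring twice returns the original mesh
#' bit-exactly.  This is the contralateral-comparison step: the mirrored
#' left leg becomes directly comparable to the right.
#'
#' @param mesh a `ctma_mesh`.
#' @param plane_x offset of the mirror plane along x (mm).
#' @return the mirrored `ctma_mesh`.
#' @export
mirror_mesh <- function(mesh, plane_x = 0) {
  validate_mesh(mesh)
  v <- mesh$vertices
  v[, 1] <- 2 * plane_x - v[, 1]
  structure(list(vertices = v,
                 faces = mesh$faces[, c(1L, 3L, 2L), drop = FALSE],
                 label = mesh$label),
            class = "ctma_mesh")
}

#' Area-uniform surface sampling
#'
#' Draws `n` points uniformly over the surface: faces are chosen with
#' probability proportional to area, positions uniformly (barycentric)
#' within the face.  Deterministic for a given seed.
#'
#' @param mesh a `ctma_mesh` with positive area.
#' @param n number of points.
#' @param seed RNG seed.
#' @return numeric n x 3 matrix of points (mm), with the sampled face index
#'   as attribute `"face"`.
#' @export
sample_surface <- function(mesh, n, seed = 0L) {
  validate_mesh(mesh)
  if (n < 1) stop("n must be >= 1")
  ar <- face_areas(mesh)
  tot <- sum(ar)
  if (!is.finite(tot) || tot <= 0) stop("mesh has zero surface area")
  with_seed(seed, {
    fi <- sample.int(length(ar), n, replace = TRUE, prob = ar)
    u <- runif(n); v <- runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]
    v[flip] <- 1 - v[flip]
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    cc <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    p <- a + u * (b - a) + v * (cc - a)
    attr(p, "face") <- fi
    p
  })
}

#' Sampled centre of mass of a surface
#'
#' Mean of an area-uniform surface sample.  This mimics how the clinical
#' software derives its centre of mass from a cloud of points spread over
#' the object: the result converges to the exact surface centroid as `n`
#' grows but is not bit-identical to it at finite `n`.
#'
#' @param mesh a `ctma_mesh`.
#' @param n number of sample points (default 10000).
#' @param seed RNG seed (default 0).
#' @return 3-vector (mm).
#' @export
center_of_mass <- function(mesh, n = 10000L, seed = 0L) {
  colMeans(sample_surface(mesh, n, seed))
}

#' Concatenate meshes into one surface
#'
#' Merges several meshes (e.g. tibia and fibula of one side) into a single
#' surface for joint registration; face indices are re-offset.
#'
#' @param meshes list of `ctma_mesh`.
#' @param label label for the merged mesh.
#' @return a `ctma_mesh`.
#' @export
merge_meshes <- function(meshes, label = "merged") {
  if (inherits(meshes, "ctma_mesh")) return(meshes)
  meshes <- Filter(Negate(is.null), meshes)
  if (length(meshes) == 0L) stop("no meshes to merge")
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices),
                              integer(1))))
  v <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  f <- do.call(rbind, Map(function(m, o) m$faces + o, meshes,
                          offs[seq_along(meshes)]))
  triangle_mesh(v, f, label)
}

#' Translate a mesh
#' @param mesh a `ctma_mesh`.
#' @param offset 3-vector (mm).
#' @return translated mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh
}

# area-weighted vertex normals (normalized); used for surface-noise
# injection in the phantom generator
vertex_normals <- function(mesh) {
  fc <- face_corners(mesh)
  fn <- cross3(fc$b - fc$a, fc$c - fc$a)  # length = 2*area, outward
  nv <- nrow(mesh$vertices)
  acc <- matrix(0, nv, 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (d in 1:3)
      acc[, d] <- acc[, d] + tabulate2(idx, fn[, d], nv)
  }
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  acc / len
}

# sum `w` into bins given by `idx` (like tabulate with weights)
tabulate2 <- function(idx, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}
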