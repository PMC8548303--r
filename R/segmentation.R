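#' Seed click for bone segmentation
#'
#' The user-supplied anatomical hint: a position inside the bone of
#' interest plus its label, emulating the click-to-segment interaction of
#' clinical 3D reconstruction software.
#'
#' @param position 3-vector (mm, canonical frame).
#' @param label bone name, e.g. `"tibia"` or `"fibula"`.
#' @return a `ctma_seed`.
#' @export
seed_click <- function(position, label) {
  structure(list(position = as.numeric(position),
                 label = as.character(label)),
            class = "ctma_seed")
}

#' Hounsfield-threshold seeded bone segmentation
#'
#' Thresholds the volume at `hu_threshold` and grows 26-connected regions
#' from each seed.  Where one connected region contains seeds of different
#' labels (bones touching at the threshold), its voxels are assigned to
#' the nearest seed by Euclidean distance in mm (ties to the
#' lexicographically lower label), so the resulting masks are always
#' disjoint.  A region touching the volume border is flagged as possibly
#' truncated.
#'
#' This seeded region growing is this package's own stand-in for the
#' proprietary two-parameter (click + HU) segmentation of clinical 3D
#' reconstruction software.
#'
#' @param volume a `ctma_volume`.
#' @param seeds a `ctma_seed` or list of them.
#' @param hu_threshold HU cutoff for bone (default 250; cortical and dense
#'   trabecular bone lie well above, soft tissue well below).
#' @param majority_filter apply one pass of a 3x3x3 majority filter to the
#'   thresholded grid before growing (partial-volume smoothing).
#' @return named list of `ctma_mask` objects (binary array, `label`,
#'   `spacing`, `origin`, `touches_border` flag), one per label.
#' @export
segment_bones <- function(volume, seeds, hu_threshold = 250,
                          majority_filter = FALSE) {
  if (inherits(seeds, "ctma_seed")) seeds <- list(seeds)
  if (length(seeds) == 0L) stop("at least one seed is required")
  d <- dim(volume$intensities)
  bone <- volume$intensities >= hu_threshold
  if (majority_filter) bone <- majority3(bone)
  seed_idx <- t(vapply(seeds, function(s) {
    ijk <- round(mm_to_index(volume, s$position))
    if (any(ijk < 1) || any(ijk > d))
      stop("seed '", s$label, "' lies outside the volume")
    ijk
  }, numeric(3)))
  labels <- vapply(seeds, `[[`, character(1), "label")
  below <- !bone[seed_idx]
  if (any(below))
    stop("seed(s) below threshold: ", paste(labels[below], collapse = ", "))
  comp <- array(.cpp_label_components(as.logical(bone), d[1], d[2], d[3]), d)
  seed_comp <- comp[seed_idx]
  assign_lab <- vector("list", length(unique(labels)))
  names(assign_lab) <- unique(labels)
  for (lb in unique(labels))
    assign_lab[[lb]] <- array(FALSE, d)
  for (cmp in unique(seed_comp)) {
    in_cmp <- which(seed_comp == cmp)
    owners <- unique(labels[in_cmp])
    vox <- comp == cmp
    if (length(owners) == 1L) {
      assign_lab[[owners]] <- assign_lab[[owners]] | vox
      next
    }
    # nearest-seed partition in mm; ties to lexicographically lower label
    lin <- which(vox)
    pos <- index_to_mm(volume, arrayInd(lin, d))
    ord <- in_cmp[order(labels[in_cmp])]
    dist <- vapply(ord, function(i) {
      p <- index_to_mm(volume, matrix(seed_idx[i, ], 1))
      sqrt(rowSums(sweep(pos, 2, as.numeric(p))^2))
    }, numeric(length(lin)))
    nearest <- labels[ord][max.col(-dist, ties.method = "first")]
    for (lb in owners) {
      m <- assign_lab[[lb]]
      m[lin[nearest == lb]] <- TRUE
      assign_lab[[lb]] <- m
    }
  }
  res <- list()
  for (lb in unique(labels)) {
    m <- assign_lab[[lb]]
    if (!any(m)) stop("empty segmentation for label '", lb, "'")
    ai <- arrayInd(which(m), d)
    touches <- any(ai == 1L) || any(sweep(ai, 2, d) == 0L)
    if (touches)
      warning("segment '", lb,
              "' touches the volume border (possible truncation)")
    res[[lb]] <- structure(list(mask = m, label = lb,
                                spacing = volume$spacing,
                                origin = volume$origin,
                                touches_border = touches,
                                majority_filtered = majority_filter),
                           class = "ctma_mask")
  }
  res
}

# one pass of 3^3 majority filter on a logical array
majority3 <- function(m) {
  d <- dim(m)
  acc <- array(0L, d)
  cnt <- array(0L, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    xd <- xs - dx; yd <- ys - dy; zd <- zs - dz
    acc[xd, yd, zd] <- acc[xd, yd, zd] + m[xs, ys, zs]
    cnt[xd, yd, zd] <- cnt[xd, yd, zd] + 1L
  }
  acc * 2L > cnt
}

#' Extract a surface mesh from a binary bone mask
#'
#' Builds the closed boundary surface of the mask in mm coordinates: every
#' exposed voxel face contributes two triangles with outward winding
#' (boundary-face extraction), so the signed volume of the raw surface
#' equals voxel count times voxel volume exactly.  Optional Taubin
#' lambda/mu smoothing (`smooth_iterations > 0`) relaxes the voxel
#' staircase while approximately preserving volume; the default of 10
#' passes removes most of the staircase bias that would otherwise enter
#' downstream registration.
#'
#' @param mask a `ctma_mask` from [segment_bones()].
#' @param smooth_iterations Taubin smoothing passes (0 disables).
#' @return a closed `ctma_mesh`.
#' @export
mask_to_mesh <- function(mask, smooth_iterations = 10L) {
  m <- mask$mask
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  verts <- list(); faces <- list(); nver <- 0L
  for (ax in 1:3) {
    n <- d[ax] + 2L
    lo <- switch(ax, pad[1:(n - 1), , , drop = FALSE],
                 pad[, 1:(n - 1), , drop = FALSE],
                 pad[, , 1:(n - 1), drop = FALSE])
    hi <- switch(ax, pad[2:n, , , drop = FALSE],
                 pad[, 2:n, , drop = FALSE],
                 pad[, , 2:n, drop = FALSE])
    for (dir in c(1L, -1L)) {
      trans <- if (dir > 0) lo & !hi else !lo & hi
      w <- which(trans)
      if (length(w) == 0L) next
      ai <- arrayInd(w, dim(trans))
      axes <- setdiff(1:3, ax)
      # corner-lattice coordinates (0-based): face plane along ax at
      # (slice index - 1); quad spans [idx-2, idx-1] on the other axes
      c00 <- ai
      c00[, ax] <- ai[, ax] - 1L
      c00[, axes] <- ai[, axes] - 2L
      mk <- function(da, db) {
        v <- c00
        v[, axes[1]] <- v[, axes[1]] + da
        v[, axes[2]] <- v[, axes[2]] + db
        v
      }
      vv <- rbind(mk(0L, 0L), mk(1L, 0L), mk(1L, 1L), mk(0L, 1L))
      nq <- nrow(c00)
      i1 <- seq_len(nq); i2 <- i1 + nq; i3 <- i2 + nq; i4 <- i3 + nq
      # cross(e_axes1, e_axes2) = +e_ax except for ax = 2 (axes 1,3)
      ccw <- xor(dir > 0, ax == 2L)
      f <- if (ccw) rbind(cbind(i1, i2, i3), cbind(i1, i3, i4))
           else rbind(cbind(i1, i3, i2), cbind(i1, i4, i3))
      faces[[length(faces) + 1L]] <- f + nver
      verts[[length(verts) + 1L]] <- vv
      nver <- nver + nrow(vv)
    }
  }
  V <- do.call(rbind, verts)
  Fc <- do.call(rbind, faces)
  key <- paste(V[, 1], V[, 2], V[, 3], sep = "|")
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  V <- V[uniq, , drop = FALSE]
  Fc <- matrix(map[Fc], ncol = 3L)
  # corner c (0-based) sits at origin + (c - 0.5) * spacing:
  # voxel i (centre origin + (i-1)*spacing) spans corners i-1..i
  Vmm <- sweep(sweep(V - 0.5, 2, mask$spacing, "*"), 2, mask$origin, "+")
  mesh <- triangle_mesh(Vmm, Fc, label = mask$label)
  if (mesh_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  if (smooth_iterations > 0)
    mesh$vertices <- .cpp_taubin_smooth(mesh$vertices, mesh$faces - 1L,
                                        as.integer(smooth_iterations),
                                        0.5, -0.53)
  mesh
}
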