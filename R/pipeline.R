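#' Paired right/left lower-leg surfaces
#'
#' @param right,left a `ctma_mesh` or list of meshes (e.g. tibia and
#'   fibula) for each side, in patient coordinates (mm).
#' @param subject subject identifier.
#' @return a `ctma_pair`.
#' @export
leg_pair <- function(right, left, subject = "") {
  as_list <- function(x) if (inherits(x, "ctma_mesh")) list(x) else x
  right <- as_list(right); left <- as_list(left)
  if (length(right) == 0L || length(left) == 0L)
    stop("both sides must have at least one mesh")
  lapply(c(right, left), validate_mesh)
  structure(list(right = right, left = left,
                 subject = as.character(subject)),
            class = "ctma_pair")
}

#' Proximal/distal segment definition
#'
#' Fractions of the bone's length (Z extent) taken from each end to form
#' the proximal (reference) and distal (moving) segments.  The defaults of
#' 0.30/0.30 cover the tibial plateau, fibular head and proximal
#' diaphysis, and the tibial plafond, distal fibula and distal diaphysis,
#' while leaving out the mid-shaft.
#'
#' @param proximal_fraction,distal_fraction fractions in (0, 0.5], summing
#'   to at most 1.
#' @return a `ctma_segdef`.
#' @export
segment_definition <- function(proximal_fraction = 0.30,
                               distal_fraction = 0.30) {
  if (proximal_fraction <= 0 || proximal_fraction > 0.5 ||
      distal_fraction <= 0 || distal_fraction > 0.5)
    stop("segment fractions must lie in (0, 0.5]")
  if (proximal_fraction + distal_fraction > 1)
    stop("segments overlap: fractions sum to more than 1")
  structure(list(proximal_fraction = proximal_fraction,
                 distal_fraction = distal_fraction),
            class = "ctma_segdef")
}

# clip a mesh to the half-space z >= zcut (above) or z <= zcut (below);
# triangles straddling the plane are cut at the plane
clip_mesh_z <- function(mesh, zcut, keep = c("above", "below")) {
  keep <- match.arg(keep)
  s <- mesh$vertices[, 3] - zcut
  if (keep == "below") s <- -s
  sv <- matrix(s[mesh$faces], ncol = 3L)
  all_in <- rowSums(sv >= 0) == 3L
  all_out <- rowSums(sv < 0) == 3L
  strad <- which(!all_in & !all_out)
  keep_faces <- mesh$faces[all_in, , drop = FALSE]
  verts <- mesh$vertices
  faces <- keep_faces
  for (k in seq_along(strad)) {
    fi <- strad[k]
    idx <- mesh$faces[fi, ]
    sf <- s[idx]
    v <- mesh$vertices[idx, , drop = FALSE]
    pos <- which(sf >= 0)
    inter <- function(i, j) {
      w <- sf[i] / (sf[i] - sf[j])
      v[i, ] + w * (v[j, ] - v[i, ])
    }
    if (length(pos) == 1L) {
      a <- pos
      nxt <- c(2L, 3L, 1L)
      b <- nxt[a]; cc <- nxt[b]
      p1 <- inter(a, b); p2 <- inter(cc, a)
      n0 <- nrow(verts)
      verts <- rbind(verts, v[a, ], p1, p2)
      faces <- rbind(faces, c(n0 + 1L, n0 + 2L, n0 + 3L))
    } else {
      a <- setdiff(1:3, pos)
      nxt <- c(2L, 3L, 1L)
      b <- nxt[a]; cc <- nxt[b]
      p_ab <- inter(a, b)
      p_ca <- inter(cc, a)
      n0 <- nrow(verts)
      verts <- rbind(verts, v[b, ], v[cc, ], p_ab, p_ca)
      faces <- rbind(faces,
                     c(n0 + 3L, n0 + 1L, n0 + 2L),
                     c(n0 + 3L, n0 + 2L, n0 + 4L))
    }
  }
  if (nrow(faces) == 0L) stop("empty segment after clipping")
  used <- sort(unique(as.vector(faces)))
  remap <- match(seq_len(nrow(verts)), used)
  triangle_mesh(verts[used, , drop = FALSE],
                matrix(remap[faces], ncol = 3L), mesh$label)
}

#' Split a bone surface into proximal and distal segments
#'
#' Cuts the mesh at fractions of its Z extent (the leg's long axis in the
#' canonical frame): vertices above the `1 - proximal_fraction` quantile
#' of the Z range form the proximal segment, those below the
#' `distal_fraction` quantile the distal segment.  Faces straddling a cut
#' are clipped at the plane.
#'
#' @param mesh a `ctma_mesh` (or list of meshes, merged first).
#' @param seg_def a [segment_definition()].
#' @param z_range optional explicit Z range `c(zmin, zmax)` defining the
#'   cut planes (defaults to the mesh's own extent); used by the pipeline
#'   to cut a pre-aligned moving leg at the reference leg's planes.
#' @return list with `proximal` and `distal` meshes and the cut planes
#'   `z_cut_proximal`, `z_cut_distal` (mm).
#' @export
split_segments <- function(mesh, seg_def = segment_definition(),
                           z_range = NULL) {
  mesh <- merge_meshes(mesh, label = if (inherits(mesh, "ctma_mesh"))
    mesh$label else "leg")
  if (is.null(z_range)) z_range <- range(mesh$vertices[, 3])
  zlen <- diff(z_range)
  if (zlen <= 0) stop("mesh has no Z extent")
  z_prox <- z_range[2] - seg_def$proximal_fraction * zlen
  z_dist <- z_range[1] + seg_def$distal_fraction * zlen
  prox <- clip_mesh_z(mesh, z_prox, "above")
  dist <- clip_mesh_z(mesh, z_dist, "below")
  prox$label <- paste0(mesh$label, ":proximal")
  dist$label <- paste0(mesh$label, ":distal")
  list(proximal = prox, distal = dist,
       z_cut_proximal = z_prox, z_cut_distal = z_dist)
}

# Iterated clip-and-register of one segment.  The cut on the moving side
# is only material-consistent with the reference cut once the relative
# transform is known, so after each registration the moving leg is re-cut
# at the reference plane mapped through the current estimate.  A
# centroid-difference start avoids the slow ICP slide along the diaphysis.
register_clip_loop <- function(moving_whole, ref_seg, zcut, keep, params,
                               passes = 3L) {
  t_tot <- rigid_transform()
  reg <- NULL; clip <- NULL
  for (pass in seq_len(passes)) {
    cur <- apply_transform(t_tot, moving_whole)
    clip <- clip_mesh_z(cur, zcut, keep)
    c_shift <- exact_surface_centroid(ref_seg) -
      exact_surface_centroid(clip)
    reg <- icp_register(clip, ref_seg, params,
                        init = rigid_transform(diag(3), c_shift))
    t_tot <- compose_transform(reg$transform, t_tot)
    if (pass > 1L && rotation_angle(reg$transform) < 0.05 &&
        sqrt(sum(reg$transform$translation^2)) < 0.05) break
  }
  list(transform = t_tot, fit = reg$fit,
       clip_pre = apply_transform(invert_transform(t_tot),
                                  apply_transform(reg$transform, clip)))
}

#' Analyze a leg pair for rotational and translational deformity
#'
#' The core contralateral-mirroring motion analysis.  The left leg is
#' mirrored about a sagittal (YZ) plane, coarsely aligned to the right
#' leg, and both legs are cut into proximal and distal segments.  The
#' proximal segments are registered and taken as the stationary reference:
#' the whole mirrored-left leg is brought into the proximally-aligned
#' frame.  The distal segments are then registered as the moving object;
#' the residual rigid transform is the deformity.  It is reported as the
#' displacement of the distal segment's centre of mass (origin
#' independent) and the three Euler rotations in the clinical sign
#' convention: rotX is recurvatum/antecurvatum, rotY varus/valgus, rotZ
#' internal/external rotation.
#'
#' Both registrations carry the mean-distance fit gate; if either gate
#' fails the report is flagged unreliable but values are still returned.
#' If the proximal registration needs a rotation of more than 90 degrees
#' on top of the coarse alignment, the sides are assumed mixed up (e.g. an
#' already-mirrored input) and an orientation error is raised.
#'
#' @param pair a [leg_pair()].
#' @param seg_def a [segment_definition()].
#' @param params a [reg_params()].
#' @param mirror_plane_x mirror plane offset (mm); default the x midpoint
#'   of the joint bounding box of both legs.  Registration absorbs the
#'   offset, so results are invariant to this choice.
#' @param com_points,com_seed sample size and seed for the centre-of-mass
#'   clouds.
#' @return a `ctma_report`: list with `com` (named 3-vector, mm), `rot`
#'   (named 3-vector, degrees), `proximal_fit`, `distal_fit`, `reliable`,
#'   `clinical` (mapping strings), `subject`.
#' @export
analyze_pair <- function(pair, seg_def = segment_definition(),
                         params = reg_params(), mirror_plane_x = NULL,
                         com_points = 10000L, com_seed = 0L) {
  stopifnot(inherits(pair, "ctma_pair"))
  right <- merge_meshes(pair$right, "right leg")
  left <- merge_meshes(pair$left, "left leg")

  # Segment cuts assume the leg's long axis runs roughly along Z.  If the
  # reference leg arrives badly tilted, rotate the problem into a frame
  # with its principal axis on Z (about the surface centroid); legs already
  # within 15 degrees of Z are left untouched so the reported axes are the
  # patient axes.
  ps <- sample_surface(right, 2000L, seed = params$seed + 11L)
  ax1 <- eigen(stats::cov(ps), symmetric = TRUE)$vectors[, 1]
  if (ax1[3] < 0) ax1 <- -ax1
  tilt <- acos(max(-1, min(1, ax1[3]))) * 180 / pi
  if (tilt > 15) {
    v <- c(ax1[2], -ax1[1], 0)                  # ax1 x z
    s <- sqrt(sum(v^2)); cth <- ax1[3]
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- if (s < 1e-12) diag(3) else
      diag(3) + K + K %*% K * ((1 - cth) / s^2)
    ctr <- colMeans(ps)
    canon <- rigid_transform(R, ctr - as.numeric(R %*% ctr))
    right <- apply_transform(canon, right)
    left <- apply_transform(canon, left)
  }
  if (is.null(mirror_plane_x)) {
    xr <- range(right$vertices[, 1], left$vertices[, 1])
    mirror_plane_x <- mean(xr)
  }
  ml <- mirror_mesh(left, mirror_plane_x)

  # coarse whole-leg alignment so segment cuts correspond materially
  t0 <- initial_align(ml, right, seed = params$seed + 101L)
  ml0 <- apply_transform(t0, ml)

  segs_r <- split_segments(right, seg_def)

  prox <- register_clip_loop(ml0, segs_r$proximal, segs_r$z_cut_proximal,
                             "above", params)
  if (rotation_angle(prox$transform) > 90)
    stop("orientation error: proximal registration required > 90 degree ",
         "rotation; check that sides are not mirrored/mixed up")
  ml1 <- apply_transform(prox$transform, ml0)

  dist <- register_clip_loop(ml1, segs_r$distal, segs_r$z_cut_distal,
                             "below", params)
  t_res <- dist$transform
  ml1_dist <- dist$clip_pre
  rot <- euler_angles(t_res)
  com0 <- center_of_mass(ml1_dist, n = com_points, seed = com_seed)
  com <- apply_transform(t_res, com0) - com0
  names(com) <- c("comX", "comY", "comZ")

  reliable <- prox$fit$passed_gate && dist$fit$passed_gate
  clinical <- c(
    rotX = if (rot[1] >= 0) "recurvatum" else "antecurvatum",
    rotY = if (rot[2] >= 0) "varus" else "valgus",
    rotZ = if (rot[3] >= 0) "internal rotation" else "external rotation")
  structure(list(com = com, rot = rot,
                 proximal_fit = prox$fit, distal_fit = dist$fit,
                 reliable = reliable, clinical = clinical,
                 subject = pair$subject),
            class = "ctma_report")
}

#' @export
print.ctma_report <- function(x, ...) {
  cat(sprintf("ctma_report%s%s\n",
              if (nzchar(x$subject)) paste0(" [", x$subject, "]") else "",
              if (x$reliable) "" else "  ** UNRELIABLE (fit gate failed) **"))
  cat(sprintf("  COM translation (mm):  X %+7.3f  Y %+7.3f  Z %+7.3f\n",
              x$com[1], x$com[2], x$com[3]))
  cat(sprintf("  Rotation (deg):        X %+7.3f  Y %+7.3f  Z %+7.3f\n",
              x$rot[1], x$rot[2], x$rot[3]))
  cat(sprintf("  (X: %s, Y: %s, Z: %s)\n", x$clinical[1], x$clinical[2],
              x$clinical[3]))
  cat(sprintf("  fit: proximal %.3f mm, distal %.3f mm (gate %.2f mm)\n",
              x$proximal_fit$mean_distance, x$distal_fit$mean_distance,
              x$distal_fit$fit_threshold))
  invisible(x)
}

#' Analyze a cohort of leg pairs
#'
#' Runs [analyze_pair()] on each pair; per-subject failures are recorded
#' without aborting the batch.
#'
#' @param pairs list of [leg_pair()] objects.
#' @param ... passed to [analyze_pair()].
#' @return a `data.frame` with columns `subject`, `COMX_mm`, `COMY_mm`,
#'   `COMZ_mm`, `ROTX_deg`, `ROTY_deg`, `ROTZ_deg`, `prox_fit_mm`,
#'   `dist_fit_mm`; failed subjects appear in attribute `"failures"`.
#' @export
batch_analyze <- function(pairs, ...) {
  if (length(pairs) == 0L) stop("empty list of pairs")
  rows <- list(); failures <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    subj <- if (nzchar(p$subject)) p$subject else as.character(i)
    rep <- tryCatch(analyze_pair(p, ...), error = function(e) e)
    if (inherits(rep, "error")) {
      failures[[subj]] <- conditionMessage(rep)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subj,
      COMX_mm = rep$com[[1]], COMY_mm = rep$com[[2]], COMZ_mm = rep$com[[3]],
      ROTX_deg = rep$rot[[1]], ROTY_deg = rep$rot[[2]],
      ROTZ_deg = rep$rot[[3]],
      prox_fit_mm = rep$proximal_fit$mean_distance,
      dist_fit_mm = rep$distal_fit$mean_distance)
  }
  if (length(rows) == 0L)
    stop("all subjects failed: ",
         paste(names(failures), unlist(failures), sep = ": ",
               collapse = "; "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(failures) > 0)
    warning(length(failures), " subject(s) failed: ",
            paste(names(failures), collapse = ", "))
  attr(out, "failures") <- failures
  out
}

#' Write a cohort table to CSV
#' @param cohort data.frame from [batch_analyze()].
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
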