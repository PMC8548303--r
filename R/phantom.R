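#' Parametric leg-pair phantom specification
#'
#' Describes a synthetic lower leg: the tibia as a tapered, slightly
#' elliptical and twisting tube with a flattened plateau bulb proximally
#' and a plafond bulb plus medial malleolus distally, and the fibula as a
#' slender offset tube with a head and a lateral malleolus.  The shapes
#' are deliberately simple: the analysis depends only on surface geometry
#' richness (no axial symmetry, observable torsion), not on anatomical
#' realism.  The left leg is generated as the exact mirror of the right
#' before any deformity is injected.
#'
#' @param tibia_length tibia length (mm).
#' @param tibia_radius_proximal,tibia_radius_distal shaft radii (mm).
#' @param plateau_radius,plafond_radius articular bulb radii (mm).
#' @param malleolus_offset medial malleolus offset from the shaft (mm).
#' @param fibula_length,fibula_radius,fibula_offset fibula geometry (mm).
#' @param twist_deg total torsion of the shaft cross-section over the
#'   tibia length (makes axial rotation observable on the diaphysis).
#' @param deformities list of deformity injections; each a list with
#'   `segment` ("distal" or "proximal"), optional `axis` + `angle_deg`
#'   (right-handed, left-leg frame) or `rotation` (3x3), optional
#'   `translation_mm` (3-vector), optional `center`, and `transition`
#'   ("sharp" or "smooth").
#' @param transition_mm width of the smooth blending band (mm).
#' @param inject_fraction fraction of the bone length (from the relevant
#'   end) that carries the full deformity.
#' @param noise_sd surface noise standard deviation (mm), applied along
#'   vertex normals independently per side.
#' @param resolution mesh resolution scale factor (1 = default density).
#' @param seed RNG seed for the noise.
#' @return a `ctma_phantom_spec`.
#' @export
phantom_spec <- function(tibia_length = 350,
                         tibia_radius_proximal = 13,
                         tibia_radius_distal = 11,
                         plateau_radius = 24,
                         plafond_radius = 16,
                         malleolus_offset = 14,
                         fibula_length = 340,
                         fibula_radius = 6,
                         fibula_offset = 36,
                         twist_deg = 20,
                         deformities = list(),
                         transition_mm = 20,
                         inject_fraction = 0.35,
                         noise_sd = 0,
                         resolution = 1,
                         seed = 0L) {
  spec <- structure(as.list(environment()), class = "ctma_phantom_spec")
  if (tibia_length <= 0 || fibula_length <= 0 || plateau_radius <= 0 ||
      tibia_radius_proximal <= 0 || tibia_radius_distal <= 0)
    stop("lengths and radii must be positive")
  if (noise_sd < 0) stop("noise sd must be >= 0")
  for (d in deformities)
    if (!is.null(d$angle_deg) && abs(d$angle_deg) >= 90)
      stop("injected angles must satisfy |angle| < 90 degrees")
  if (transition_mm >= tibia_length * (1 - 2 * inject_fraction))
    stop("transition band exceeds the undeformed mid-shaft")
  spec
}

# closed tube: rings at zs, elliptical cross-section with per-ring centre,
# radii and twist; capped with end fans
tube_mesh <- function(zs, cx, cy, rx, ry, twist, n_seg, label) {
  m <- length(zs)
  phi <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  verts <- matrix(0, m * n_seg, 3)
  for (i in seq_len(m)) {
    a <- phi + twist[i]
    rows <- (i - 1) * n_seg + seq_len(n_seg)
    verts[rows, 1] <- cx[i] + rx[i] * cos(a)
    verts[rows, 2] <- cy[i] + ry[i] * sin(a)
    verts[rows, 3] <- zs[i]
  }
  vid <- function(i, j) (i - 1) * n_seg + ((j - 1) %% n_seg) + 1
  f <- list()
  for (i in seq_len(m - 1)) {
    j <- seq_len(n_seg)
    f[[i]] <- rbind(cbind(vid(i, j), vid(i, j + 1), vid(i + 1, j)),
                    cbind(vid(i, j + 1), vid(i + 1, j + 1), vid(i + 1, j)))
  }
  faces <- do.call(rbind, f)
  c0 <- c(cx[1], cy[1], zs[1])
  c1 <- c(cx[m], cy[m], zs[m])
  nb <- nrow(verts)
  verts <- rbind(verts, c0, c1)
  j <- seq_len(n_seg)
  faces <- rbind(faces,
                 cbind(nb + 1L, vid(1, j + 1), vid(1, j)),
                 cbind(nb + 2L, vid(m, j), vid(m, j + 1)))
  triangle_mesh(verts, faces, label)
}

# closed UV ellipsoid
ellipsoid_mesh <- function(center, radii, n_lat = 12L, n_lon = 18L,
                           label = "bulb") {
  th <- pi * seq_len(n_lat - 1) / n_lat
  ph <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  grid <- expand.grid(ph = ph, th = th)
  verts <- cbind(center[1] + radii[1] * sin(grid$th) * cos(grid$ph),
                 center[2] + radii[2] * sin(grid$th) * sin(grid$ph),
                 center[3] + radii[3] * cos(grid$th))
  np <- nrow(verts)
  top <- np + 1L; bot <- np + 2L
  verts <- rbind(verts, center + c(0, 0, radii[3]),
                 center - c(0, 0, radii[3]))
  vid <- function(i, j) (i - 1) * n_lon + ((j - 1) %% n_lon) + 1
  f <- list()
  j <- seq_len(n_lon)
  f[[1]] <- cbind(top, vid(1, j), vid(1, j + 1))
  for (i in seq_len(n_lat - 2))
    f[[i + 1]] <- rbind(cbind(vid(i, j), vid(i + 1, j), vid(i, j + 1)),
                        cbind(vid(i, j + 1), vid(i + 1, j), vid(i + 1, j + 1)))
  f[[n_lat]] <- cbind(bot, vid(n_lat - 1, j + 1), vid(n_lat - 1, j))
  triangle_mesh(verts, do.call(rbind, f), label)
}

# right-leg bone meshes in the canonical frame (ankle at z = 0, knee at
# z = tibia_length; lateral = +x for the right leg)
make_right_bones <- function(spec) {
  res <- spec$resolution
  nr <- max(16L, round(64 * res))
  ns <- max(12L, round(36 * res))
  L <- spec$tibia_length
  t <- seq(0, 1, length.out = nr)
  zs <- t * L
  r <- spec$tibia_radius_distal +
    (spec$tibia_radius_proximal - spec$tibia_radius_distal) * t^1.4
  waist <- 1 - 0.10 * exp(-((t - 0.45) / 0.22)^2)
  r <- r * waist
  cy <- 2.5 * sin(pi * t)                    # slight bow: breaks symmetry
  tw <- spec$twist_deg * pi / 180 * t
  tib_shaft <- tube_mesh(zs, rep(0, nr), cy, 1.15 * r, 0.88 * r, tw, ns,
                         "tibia shaft")
  pr <- spec$plateau_radius
  plateau <- ellipsoid_mesh(c(0, 3, L - 0.35 * pr),
                            c(1.1 * pr, 0.95 * pr, 0.55 * pr),
                            max(8L, round(12 * res)),
                            max(12L, round(20 * res)), "tibial plateau")
  fr <- spec$plafond_radius
  plafond <- ellipsoid_mesh(c(0, 0, 0.3 * fr),
                            c(fr, 0.92 * fr, 0.62 * fr),
                            max(8L, round(12 * res)),
                            max(12L, round(20 * res)), "tibial plafond")
  mal <- ellipsoid_mesh(c(-spec$malleolus_offset, 1, -2),
                        c(7, 6, 9), max(6L, round(10 * res)),
                        max(10L, round(14 * res)), "medial malleolus")
  tibia <- merge_meshes(list(tib_shaft, plateau, plafond, mal), "tibia")

  Lf <- spec$fibula_length
  nf <- max(14L, round(56 * res))
  tf <- seq(0, 1, length.out = nf)
  zf <- -6 + tf * Lf
  rf <- spec$fibula_radius * (0.9 + 0.35 * tf^2)
  fib_shaft <- tube_mesh(zf, rep(spec$fibula_offset, nf), 4 + 2 * tf,
                         1.1 * rf, 0.9 * rf, 0.3 * tf, ns, "fibula shaft")
  head <- ellipsoid_mesh(c(spec$fibula_offset, 6, Lf - 10),
                         c(9, 8, 11), max(6L, round(10 * res)),
                         max(10L, round(14 * res)), "fibular head")
  lmal <- ellipsoid_mesh(c(spec$fibula_offset + 2, 3, -4),
                         c(6.5, 6, 10), max(6L, round(10 * res)),
                         max(10L, round(14 * res)), "lateral malleolus")
  fibula <- merge_meshes(list(fib_shaft, head, lmal), "fibula")
  list(tibia = tibia, fibula = fibula)
}

# full-effect z-band of an injection on the left leg
injection_band <- function(spec, segment) {
  zr <- c(-16, spec$tibia_length)            # full bone z range incl. malleoli
  len <- diff(zr)
  if (segment == "distal")
    list(full_below = zr[1] + spec$inject_fraction * len, sign = -1)
  else
    list(full_above = zr[2] - spec$inject_fraction * len, sign = +1)
}

# affine (rotation about center + translation) of one injection, left frame
injection_affine <- function(d, center) {
  R <- if (!is.null(d$rotation)) d$rotation
       else if (!is.null(d$axis))
         axis_rotation(d$axis, d$angle_deg, right_handed = TRUE)
       else diag(3)
  t0 <- d$translation_mm %||% c(0, 0, 0)
  ctr <- d$center %||% center
  # x -> R (x - ctr) + ctr + t
  list(R = R, t = as.numeric(ctr - R %*% ctr) + t0)
}

apply_affine_blend <- function(verts, aff, w) {
  moved <- sweep(verts %*% t(aff$R), 2, aff$t, "+")
  verts + w * (moved - verts)
}

#' Generate one synthetic leg
#'
#' Builds the tibia and fibula meshes for one side.  The left side is the
#' exact mirror (about the plane x = 0) of the right before deformities
#' are injected; injections rigidly transform the specified segment's
#' vertices (sharp) or blend the displacement over a transition band
#' (smooth).  Surface noise is then added along vertex normals.
#'
#' @param spec a [phantom_spec()].
#' @param side `"right"` or `"left"`.
#' @return list with `tibia` and `fibula` meshes.
#' @export
make_leg <- function(spec, side = c("right", "left")) {
  side <- match.arg(side)
  bones <- make_right_bones(spec)
  if (side == "left") {
    bones <- lapply(bones, mirror_mesh, plane_x = 0)
    for (d in spec$deformities) {
      seg <- d$segment %||% "distal"
      band <- injection_band(spec, seg)
      tr <- d$transition %||% "sharp"
      allv <- do.call(rbind, lapply(bones, `[[`, "vertices"))
      if (seg == "distal") {
        full <- allv[, 3] <= band$full_below
      } else full <- allv[, 3] >= band$full_above
      if (!any(full)) stop("deformity band lies outside the bone")
      ctr <- colMeans(allv[full, , drop = FALSE])
      aff <- injection_affine(d, ctr)
      for (nm in names(bones)) {
        v <- bones[[nm]]$vertices
        if (seg == "distal") {
          u <- (band$full_below + spec$transition_mm - v[, 3]) /
            spec$transition_mm
        } else {
          u <- (v[, 3] - (band$full_above - spec$transition_mm)) /
            spec$transition_mm
        }
        w <- if (tr == "smooth") {
          u <- pmin(pmax(u, 0), 1)
          u * u * (3 - 2 * u)              # smoothstep
        } else as.numeric(u >= 1)
        bones[[nm]]$vertices <- apply_affine_blend(v, aff, w)
      }
    }
  }
  if (spec$noise_sd > 0) {
    sd_off <- if (side == "right") 0L else 1L
    for (k in seq_along(bones)) {
      m <- bones[[k]]
      nrm <- vertex_normals(m)
      eps <- with_seed(spec$seed + 2L * k + sd_off,
                       rnorm(nrow(m$vertices), 0, spec$noise_sd))
      bones[[k]]$vertices <- m$vertices + eps * nrm
    }
  }
  bones
}

#' Generate a phantom leg pair with ground truth
#'
#' Convenience wrapper building both sides as a [leg_pair()] and the
#' six-parameter ground truth the analysis should recover, derived in
#' closed form from the injected transforms by conjugating with the
#' mirror.  Truth is defined for distal-segment injections (the moving
#' object of the analysis).
#'
#' @param spec a [phantom_spec()].
#' @param subject subject id.
#' @param seg_def segment definition used to locate the distal centre of
#'   mass for the translation truth.
#' @return list with `pair` (a `ctma_pair`) and `truth` (named 6-vector:
#'   comX/Y/Z mm, rotX/Y/Z deg in the report's clinical convention).
#' @export
make_pair <- function(spec, subject = "phantom",
                      seg_def = segment_definition()) {
  right <- make_leg(spec, "right")
  left <- make_leg(spec, "left")
  pair <- leg_pair(right, left, subject)
  truth <- injection_truth(spec, seg_def)
  list(pair = pair, truth = truth)
}

# closed-form report-convention truth for the injected distal deformity
injection_truth <- function(spec, seg_def = segment_definition()) {
  clean <- spec
  clean$deformities <- list()
  clean$noise_sd <- 0
  right <- merge_meshes(make_leg(clean, "right"), "right")
  com_B <- exact_surface_centroid(split_segments(right, seg_def)$distal)
  M <- diag(c(-1, 1, 1))
  R_tot <- diag(3); t_tot <- c(0, 0, 0)
  bones <- make_leg(clean, "left")
  for (d in spec$deformities) {
    if ((d$segment %||% "distal") != "distal")
      stop("ground truth is defined for distal injections")
    band <- injection_band(spec, "distal")
    allv <- do.call(rbind, lapply(bones, `[[`, "vertices"))
    full <- allv[, 3] <= band$full_below
    ctr <- colMeans(allv[full, , drop = FALSE])
    aff <- injection_affine(d, ctr)
    # accumulate D_L = aff o D_L, and keep bone vertices in step so later
    # injection centers match make_leg
    R_tot <- aff$R %*% R_tot
    t_tot <- as.numeric(aff$R %*% t_tot) + aff$t
    for (nm in names(bones))
      bones[[nm]]$vertices <-
        sweep(bones[[nm]]$vertices %*% t(aff$R), 2, aff$t, "+")
  }
  # T_res = (M D_L M)^{-1}; displacement measured at com0 = M D_L M com_B
  R_c <- M %*% R_tot %*% M
  t_c <- as.numeric(M %*% t_tot)
  com0 <- as.numeric(R_c %*% (com_B)) + t_c
  R_res <- t(R_c)
  t_res <- -as.numeric(R_res %*% t_c)
  rot <- euler_angles(R_res)
  com <- as.numeric(R_res %*% com0) + t_res - com0
  c(comX = com[1], comY = com[2], comZ = com[3],
    rotX = unname(rot[1]), rotY = unname(rot[2]), rotZ = unname(rot[3]))
}

# build the left-frame distal injection realizing given report-convention
# targets exactly (rotations deg, clinical sign; com displacement mm)
deformity_from_report <- function(spec, rot = c(0, 0, 0), com = c(0, 0, 0),
                                  seg_def = segment_definition()) {
  clean <- spec
  clean$deformities <- list()
  clean$noise_sd <- 0
  right <- merge_meshes(make_leg(clean, "right"), "right")
  com_B <- exact_surface_centroid(split_segments(right, seg_def)$distal)
  R_res <- rotation_from_euler(rot[1], rot[2], rot[3])
  # G = T_res^{-1} must satisfy G(com_B) = com_B - com
  R_G <- t(R_res)
  t_G <- (com_B - com) - as.numeric(R_G %*% com_B)
  M <- diag(c(-1, 1, 1))
  R_D <- M %*% R_G %*% M
  t_D <- as.numeric(M %*% t_G)
  # express as rotation about the injection centre + translation:
  # injection_affine uses x -> R(x - ctr) + ctr + t, so pass center = 0
  list(segment = "distal", rotation = R_D, translation_mm = t_D,
       center = c(0, 0, 0), transition = "sharp")
}

#' Generate a cohort of phantom pairs with known deformities
#'
#' Draws per-subject distal deformities from normal distributions on the
#' six report parameters (clinical sign convention) and builds the
#' corresponding leg pairs, returning the exact ground-truth table for
#' recovery testing.
#'
#' @param n_subjects number of pairs.
#' @param sd_rot standard deviations (deg) for rotX/Y/Z (recycled).
#' @param sd_trans standard deviations (mm) for comX/Y/Z (recycled).
#' @param spec base [phantom_spec()] (deformities are overwritten).
#' @param seed RNG seed; the cohort is fully reproducible.
#' @return list with `pairs` (list of `ctma_pair`) and `truth`
#'   (data.frame: subject plus the six parameters).
#' @export
make_cohort <- function(n_subjects, sd_rot = 1, sd_trans = 1,
                        spec = phantom_spec(), seed = 0L) {
  if (n_subjects < 1) stop("need at least one subject")
  sd_rot <- rep(sd_rot, length.out = 3)
  sd_trans <- rep(sd_trans, length.out = 3)
  draws <- with_seed(seed, {
    cbind(matrix(rnorm(3 * n_subjects, 0, rep(sd_trans, each = n_subjects)),
                 n_subjects, 3),
          matrix(rnorm(3 * n_subjects, 0, rep(sd_rot, each = n_subjects)),
                 n_subjects, 3))
  })
  colnames(draws) <- c("comX", "comY", "comZ", "rotX", "rotY", "rotZ")
  pairs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sp <- spec
    sp$seed <- spec$seed + 1000L * i
    sp$deformities <- list(deformity_from_report(
      spec, rot = draws[i, 4:6], com = draws[i, 1:3]))
    right <- make_leg(sp, "right")
    left <- make_leg(sp, "left")
    pairs[[i]] <- leg_pair(right, left, sprintf("phantom-%02d", i))
  }
  truth <- data.frame(subject = sprintf("phantom-%02d", seq_len(n_subjects)),
                      draws)
  list(pairs = pairs, truth = truth)
}

#' Rasterize bone meshes to a Hounsfield voxel volume
#'
#' Voxels inside any bone mesh receive `hu_bone`, voxels within a dilated
#' soft-tissue hull `hu_soft`, and the rest `hu_air`.  Inside/outside is
#' decided by parity ray casting, which requires closed meshes.
#'
#' @param meshes a `ctma_mesh` or list of them (must be closed).
#' @param spacing voxel size (mm), scalar or length 3.
#' @param hu_bone,hu_soft,hu_air intensities (HU).
#' @param margin_mm padding around the bone bounding box.
#' @param soft_mm thickness of the soft-tissue hull around bone.
#' @return a `ctma_volume`.
#' @export
rasterize_meshes <- function(meshes, spacing = 1, hu_bone = 1200,
                             hu_soft = 40, hu_air = -1000,
                             margin_mm = 6, soft_mm = 3) {
  if (inherits(meshes, "ctma_mesh")) meshes <- list(meshes)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (length(meshes) == 0L) {
    stop("rasterize_meshes needs a bounding region; provide >= 1 mesh")
  }
  for (m in meshes) {
    edges <- rbind(m$faces[, c(1, 2)], m$faces[, c(2, 3)], m$faces[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (any(table(key) != 2L))
      stop("open (non-closed) mesh '", m$label, "': cannot rasterize")
  }
  allv <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  lo <- apply(allv, 2, min) - margin_mm
  hi <- apply(allv, 2, max) + margin_mm
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  inside <- array(FALSE, dims)
  for (m in meshes) {
    r <- .cpp_rasterize(m$vertices, m$faces - 1L, dims[1], dims[2], dims[3],
                        lo, spacing)
    inside <- inside | array(r, dims)
  }
  hu <- array(hu_air, dims)
  if (hu_soft > hu_air) {
    soft <- inside
    for (k in seq_len(max(1L, round(soft_mm / max(spacing))))) {
      soft <- soft |
        dilate_shift(soft, 1) | dilate_shift(soft, -1) |
        dilate_shift(soft, 2) | dilate_shift(soft, -2) |
        dilate_shift(soft, 3) | dilate_shift(soft, -3)
    }
    hu[soft] <- hu_soft
  }
  hu[inside] <- hu_bone
  voxel_volume(hu, spacing = spacing, origin = lo)
}

# shift a logical array by one voxel along +/- axis (zero-padded)
dilate_shift <- function(m, ax) {
  d <- dim(m)
  out <- array(FALSE, d)
  a <- abs(ax); s <- sign(ax)
  n <- d[a]
  if (n < 2L) return(out)
  src <- if (s > 0) 1:(n - 1) else 2:n
  dst <- if (s > 0) 2:n else 1:(n - 1)
  idx_src <- lapply(seq_len(3), function(i) seq_len(d[i]))
  idx_dst <- idx_src
  idx_src[[a]] <- src; idx_dst[[a]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Load the packaged reference cohort
#'
#' Returns the packaged per-subject table of the six deformity parameters
#' (COM translations in mm, rotations in degrees) for the published
#' 10-subject reference cohort of healthy adult lower legs.  On load the
#' column means are checked against the published cohort means to within
#' 0.01; a mismatch indicates corrupt packaging.
#'
#' @return data.frame with `subject` and the six parameter columns.
#' @export
load_reference_cohort <- function() {
  path <- system.file("extdata", "reference_cohort.csv", package = "ctma",
                      mustWork = TRUE)
  tab <- read.csv(path)
  expected <- c(COMX_mm = -1.626, COMY_mm = -0.739, COMZ_mm = 0.910,
                ROTX_deg = -0.264, ROTY_deg = 0.703, ROTZ_deg = -1.184)
  got <- colMeans(tab[names(expected)])
  if (nrow(tab) != 10L || any(abs(got - expected) > 0.01))
    stop("fixture self-check failed: column means do not reproduce the ",
         "published cohort means (corrupt packaging?)")
  tab
}
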