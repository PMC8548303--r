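#' Read an STL surface file
#'
#' Reads binary or ASCII STL (auto-detected) into a [triangle_mesh()].
#' STL carries no unit metadata; coordinates are taken to be millimetres,
#' the unit CT-derived surfaces are exported in.  Duplicate vertices shared
#' between facets are welded exactly so downstream signed-volume and
#' adjacency computations see a connected surface.
#'
#' @param path file path.
#' @param label mesh label; defaults to the STL solid name or file name.
#' @return a `ctma_mesh`.
#' @export
read_stl <- function(path, label = NULL) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  if (length(head) < 80L) stop("malformed STL: header truncated at byte ",
                               length(head))
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  fsize <- file.info(path)$size
  is_binary <- length(ntri) == 1L && !is.na(ntri) &&
    fsize == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    raw <- readBin(con, "raw", 50L * ntri)
    if (length(raw) < 50L * ntri)
      stop("malformed STL: facet data truncated at byte ", 84 + length(raw))
    idx <- rep(seq(0L, ntri - 1L) * 50L, each = 36L) +
      rep(12L + seq_len(36L), times = ntri)  # skip the normal, keep 9 floats
    verts <- readBin(raw[idx], "numeric", 9L * ntri, size = 4L,
                     endian = "little")
    v <- matrix(verts, ncol = 3L, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("malformed STL: ASCII parse error near byte ",
           sum(nchar(txt[seq_len(min(5L, length(txt)))])) ,
           " (vertex count not a multiple of 3)")
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4]))
    v <- do.call(rbind, nums)
    if (anyNA(v)) stop("malformed STL: non-numeric vertex coordinate")
  }
  if (nrow(v) == 0L) stop("empty STL mesh")
  # weld identical coordinates
  key <- paste(v[, 1], v[, 2], v[, 3], sep = "|")
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  faces <- matrix(map, ncol = 3L, byrow = TRUE)
  if (is.null(label)) label <- basename(path)
  triangle_mesh(v[uniq, , drop = FALSE], faces, label = label)
}

#' Write an STL surface file
#'
#' Writes binary (default) or ASCII STL.  STL stores 32-bit floats, so a
#' write/read round trip preserves coordinates to about 1e-5 mm relative
#' precision.
#'
#' @param mesh a `ctma_mesh`.
#' @param path output path.
#' @param ascii write ASCII STL instead of binary.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  validate_mesh(mesh)
  fc <- face_corners(mesh)
  nrm <- cross3(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  ntri <- nrow(mesh$faces)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    name <- gsub("[^A-Za-z0-9_.-]", "_", mesh$label)
    writeLines(paste0("solid ", name), con)
    for (i in seq_len(ntri)) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e",
                nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e",
                c(fc$a[i, 1], fc$b[i, 1], fc$c[i, 1]),
                c(fc$a[i, 2], fc$b[i, 2], fc$c[i, 2]),
                c(fc$a[i, 3], fc$b[i, 3], fc$c[i, 3])),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(paste0("endsolid ", name), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", substr(mesh$label, 1, 70)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(ntri), con, size = 4L, endian = "little")
    # 12 floats + 2 attribute bytes per facet, assembled in one raw block
    dat <- cbind(nrm, fc$a, fc$b, fc$c)
    fl <- writeBin(as.numeric(t(dat)), raw(), size = 4L, endian = "little")
    blk <- matrix(as.raw(0L), nrow = 50L, ncol = ntri)
    blk[1:48, ] <- matrix(fl, nrow = 48L)
    writeBin(as.vector(blk), con)
  }
  invisible(path)
}
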