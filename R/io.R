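#' Depth image and point cloud I/O
#'
#' Depth maps are stored as 16-bit grayscale PNGs holding depth in
#' millimetres (0 = invalid; ceiling 65.535 m), with a JSON sidecar carrying
#' the intrinsics and camera pose. Point clouds and meshes round-trip through
#' ASCII PLY.
#'
#' @name depth-io
NULL

#' Write a depth image as a 16-bit millimetre PNG
#'
#' Depth in metres is rounded to the nearest millimetre and stored as 16-bit
#' grayscale. Depths beyond 65.535 m cannot be represented and raise an
#' error. When `meta` is supplied a JSON sidecar (same path, `.json`
#' extension) records intrinsics and pose.
#'
#' @param depth A `depth_image` (metres).
#' @param path Output PNG path.
#' @param k Optional `intrinsics` for the sidecar.
#' @param pose Optional `rigid_pose` for the sidecar (R stored row-major).
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(depth, path, k = NULL, pose = NULL, extra = NULL) {
  mm <- round_half_away(unclass(depth) * 1000)
  if (any(mm > 65535)) stop("depth exceeds the 65.535 m PNG ceiling")
  write_png16(mm, path)
  if (!is.null(k) || !is.null(pose) || !is.null(extra)) {
    meta <- c(
      if (!is.null(k)) list(fx = k$fx, fy = k$fy, cx = k$cx, cy = k$cy,
                            width = k$width, height = k$height),
      if (!is.null(pose)) list(R = as.numeric(t(pose$R)), T = pose$t),
      extra)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

sidecar_path <- function(path) sub("\\.png$", ".json", path)

#' Read a millimetre PNG depth image
#'
#' @param path PNG path written by [write_depth_png()].
#' @param with_meta Also parse the JSON sidecar if present.
#' @return A `depth_image` in metres; when `with_meta` and a sidecar exists,
#'   attributes `intrinsics` (an `intrinsics`) and `pose` (a `rigid_pose`,
#'   when stored) are attached.
#' @export
read_depth_png <- function(path, with_meta = TRUE) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  d <- depth_image(round(raw * 65535) / 1000)
  side <- sidecar_path(path)
  if (with_meta && file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$fx))
      attr(d, "intrinsics") <- intrinsics(meta$fx, meta$fy, meta$cx, meta$cy,
                                          meta$width, meta$height)
    if (!is.null(meta$R))
      attr(d, "pose") <- rigid_pose(matrix(meta$R, 3, 3, byrow = TRUE),
                                    meta$T)
    attr(d, "meta") <- meta
  }
  d
}

# --- minimal 16-bit grayscale PNG writer -----------------------------------
# The PNG libraries available write 8-bit only, so the container is emitted
# directly: IHDR (bit depth 16, colour type 0), one IDAT holding the zlib
# stream from memCompress, IEND.

write_png16 <- function(mm, path) {
  h <- nrow(mm); w <- ncol(mm)
  val <- as.integer(t(mm))                       # row-major scanlines
  hi <- val %/% 256L; lo <- val %% 256L
  px <- as.raw(rbind(hi, lo))                    # big-endian 16-bit
  dim(px) <- NULL
  rows <- matrix(px, nrow = 2L * w)
  scan <- as.raw(rbind(as.raw(0L), rows))        # filter byte 0 per scanline
  dim(scan) <- NULL
  zlib <- memCompress(scan, type = "gzip")       # R emits a zlib stream
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  ihdr <- c(int32_be(w), int32_be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  write_chunk(con, "IHDR", ihdr)
  write_chunk(con, "IDAT", zlib)
  write_chunk(con, "IEND", raw(0))
  invisible(path)
}

write_chunk <- function(con, type, data) {
  writeBin(int32_be(length(data)), con)
  body <- c(charToRaw(type), data)
  writeBin(body, con)
  hex <- digest::digest(body, algo = "crc32", serialize = FALSE)
  hex <- formatC(hex, width = 8, flag = "0")
  # parse in two halves: strtoi overflows R integers above 2^31
  crc <- strtoi(substr(hex, 1, 4), 16L) * 65536 + strtoi(substr(hex, 5, 8), 16L)
  writeBin(int32_be(crc), con)
}

int32_be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

# --- PLY -------------------------------------------------------------------

#' Write a point cloud or mesh as ASCII PLY
#'
#' @param x A `point_cloud` or `trimesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(x, path) {
  if (inherits(x, "point_cloud")) {
    v <- x$xyz; f <- NULL
  } else {
    v <- x$vertices; f <- x$faces
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               if (!is.null(f)) sprintf("element face %d", nrow(f)),
               if (!is.null(f)) "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  if (!is.null(f))
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  invisible(path)
}

#' Read an ASCII PLY file
#'
#' Supports the x/y/z vertex layout written by [write_ply()] (leading
#' vertex properties beyond x, y, z are ignored).
#'
#' @param path PLY path.
#' @param frame Frame label when the file holds a point cloud.
#' @return A `point_cloud` (no faces) or `trimesh` (with faces).
#' @export
read_ply <- function(path, frame = "world") {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  endh <- match("end_header", lines)
  head <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   head, value = TRUE)))
  nf_line <- grep("^element face", head, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("element face ", "", nf_line)) else 0L
  vl <- lines[endh + seq_len(nv)]
  v <- matrix(scan(text = vl, quiet = TRUE), nrow = nv, byrow = TRUE)[, 1:3,
                                                                     drop = FALSE]
  if (nf == 0) return(point_cloud(v, frame))
  fl <- lines[endh + nv + seq_len(nf)]
  fm <- matrix(scan(text = fl, quiet = TRUE), nrow = nf, byrow = TRUE)
  structure(list(vertices = v, faces = fm[, 2:4, drop = FALSE] + 1L),
            class = "trimesh")
}
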