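#' Read a streamline file (TRK or TCK)
#'
#' Reads TrackVis `.trk` or MRtrix `.tck` streamline files into a
#' [tractogram()]. Coordinates are always returned in world mm (RAS+)
#' regardless of the on-disk convention: TRK stores points in "voxel-mm"
#' with the origin at the corner of voxel (0,0,0) (voxel centers at
#' `(i + 0.5) * voxel_size`), which is converted through the header's
#' voxel-to-RAS matrix at read time; TCK already stores world mm.
#'
#' @param path Path to the file.
#' @param format `"trk"` or `"tck"`; inferred from the file extension when
#'   missing.
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path, format = c("auto", "trk", "tck")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("trk", "tck")) {
      stop("cannot infer streamline format from extension: ", path)
    }
  }
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format, trk = read_trk(path), tck = read_tck(path))
}

#' Write a streamline file (TRK or TCK)
#'
#' Inverse of [read_tractogram()]; world-mm coordinates are converted to the
#' format's native convention on write.
#'
#' @param t A [tractogram()].
#' @param path Output path.
#' @param format `"trk"` or `"tck"`; inferred from the extension when missing.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path, format = c("auto", "trk", "tck")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("trk", "tck")) {
      stop("cannot infer streamline format from extension: ", path)
    }
  }
  switch(format, trk = write_trk(t, path), tck = write_tck(t, path))
  invisible(path)
}

# ---- TRK (TrackVis) ---------------------------------------------------------
# 1000-byte little-endian header; body = per streamline: int32 n_points,
# n_points * (3 + n_scalars) float32, n_properties float32.

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1000L)
  if (length(hdr) < 1000L) stop("malformed TRK header: file shorter than 1000 bytes")
  id <- rawToChar(hdr[1:5])
  if (id != "TRACK") stop("malformed TRK header: bad magic '", id, "'")
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = "little")
  }
  dim3 <- rd(6L, "integer", 3L, 2L)
  voxel_size <- rd(12L, "double", 3L, 4L)
  n_scalars <- rd(36L, "integer", 1L, 2L)
  n_properties <- rd(238L, "integer", 1L, 2L)
  vox_to_ras <- matrix(rd(440L, "double", 16L, 4L), 4, 4, byrow = TRUE)
  n_count <- rd(988L, "integer", 1L, 4L)
  hdr_size <- rd(996L, "integer", 1L, 4L)
  if (hdr_size != 1000L) stop("malformed TRK header: hdr_size = ", hdr_size)
  if (any(voxel_size <= 0)) stop("malformed TRK header: non-positive voxel size")
  if (vox_to_ras[4, 4] == 0) {
    # legacy header without a stored affine: voxel-mm grid with corner origin
    vox_to_ras <- diag(c(voxel_size, 1))
  }

  streamlines <- list()
  i <- 0L
  repeat {
    n_pts <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(n_pts) == 0L) break
    if (n_pts <= 0L) stop("malformed TRK body: streamline with ", n_pts, " points")
    vals <- readBin(con, "double", n = n_pts * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_properties > 0L) {
      readBin(con, "double", n = n_properties, size = 4L, endian = "little")
    }
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # voxmm (corner origin) -> voxel -> world
    v <- sweep(m, 2, voxel_size, "/") - 0.5
    w <- cbind(v, 1) %*% t(vox_to_ras)
    i <- i + 1L
    streamlines[[i]] <- w[, 1:3, drop = FALSE]
  }
  if (n_count > 0L && i != n_count) {
    warning("TRK header declares ", n_count, " streamlines but ", i, " were read")
  }
  if (i == 0L) warning("TRK file contains zero streamlines")
  tractogram(streamlines, voxel_size = voxel_size, affine = vox_to_ras,
             space_tag = "trk")
}

write_trk <- function(t, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(1000L)
  put <- function(hdr, off, bytes) {
    hdr[(off + 1L):(off + length(bytes))] <- bytes
    hdr
  }
  hdr <- put(hdr, 0L, charToRaw("TRACK"))
  hdr <- put(hdr, 6L, writeBin(rep(1L, 3L), raw(), size = 2L, endian = "little"))
  hdr <- put(hdr, 12L, writeBin(as.numeric(t$voxel_size), raw(), size = 4L,
                                endian = "little"))
  hdr <- put(hdr, 36L, writeBin(0L, raw(), size = 2L, endian = "little"))   # n_scalars
  hdr <- put(hdr, 238L, writeBin(0L, raw(), size = 2L, endian = "little"))  # n_properties
  hdr <- put(hdr, 440L, writeBin(as.numeric(t(t$affine)), raw(), size = 4L,
                                 endian = "little"))
  hdr <- put(hdr, 948L, c(charToRaw("RAS"), as.raw(0L)))
  hdr <- put(hdr, 988L, writeBin(length(t$streamlines), raw(), size = 4L,
                                 endian = "little"))
  hdr <- put(hdr, 992L, writeBin(2L, raw(), size = 4L, endian = "little"))
  hdr <- put(hdr, 996L, writeBin(1000L, raw(), size = 4L, endian = "little"))
  writeBin(hdr, con)

  inv <- solve(t$affine)
  for (s in t$streamlines) {
    v <- cbind(s, 1) %*% t(inv)
    voxmm <- sweep(v[, 1:3, drop = FALSE] + 0.5, 2, t$voxel_size, "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

# ---- TCK (MRtrix) -----------------------------------------------------------
# ASCII key:value header terminated by END, then Float32LE triples in world
# mm; (NaN,NaN,NaN) separates streamlines, (Inf,Inf,Inf) terminates the file.

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(magic, "mrtrix tracks")) {
    stop("malformed TCK header: bad magic line")
  }
  fields <- list()
  offset <- NA_real_
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("malformed TCK header: no END line")
    if (line == "END") break
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) fields[[trimws(kv[1])]] <- trimws(kv[2])
  }
  datatype <- fields[["datatype"]]
  if (is.null(datatype) || datatype != "Float32LE") {
    stop("unsupported TCK datatype: ", datatype %||% "<missing>")
  }
  file_field <- fields[["file"]]
  if (is.null(file_field)) stop("malformed TCK header: missing file field")
  offset <- as.numeric(sub("^\\.\\s+", "", file_field))
  seek(con, where = offset, origin = "start")
  vals <- readBin(con, "double", n = file.size(path), size = 4L, endian = "little")
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  is_nan <- rowSums(is.na(m) & !is.infinite(m)) > 0
  is_inf <- is.infinite(m[, 1])
  end_row <- which(is_inf)[1]
  if (is.na(end_row)) stop("malformed TCK body: missing terminator triple")
  m <- m[seq_len(end_row - 1L), , drop = FALSE]
  breaks <- which(is_nan[seq_len(end_row - 1L)])
  bounds <- c(0L, breaks, end_row)
  streamlines <- list()
  k <- 0L
  for (b in seq_len(length(bounds) - 1L)) {
    rows <- (bounds[b] + 1L):(bounds[b + 1L] - 1L)
    if (length(rows) == 0L || bounds[b] + 1L > bounds[b + 1L] - 1L) next
    k <- k + 1L
    streamlines[[k]] <- m[rows, , drop = FALSE]
  }
  if (k == 0L) warning("TCK file contains zero streamlines")
  tractogram(streamlines, voxel_size = c(1, 1, 1), affine = diag(4),
             space_tag = "tck")
}

write_tck <- function(t, path) {
  body_header <- c("mrtrix tracks",
                   "datatype: Float32LE",
                   sprintf("count: %d", length(t$streamlines)))
  # the file offset includes its own digits; settle by iteration
  offset <- 0L
  for (i in 1:3) {
    lines <- c(body_header, sprintf("file: . %d", offset), "END")
    new_offset <- sum(nchar(lines, type = "bytes")) + length(lines)
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(body_header, sprintf("file: . %d", offset), "END"), con, sep = "\n")
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
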