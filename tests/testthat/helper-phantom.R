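# Shared fixtures and independent oracles for the test suite.

# The phantom atlas is moderately expensive to rasterize and dilate, so it is
# built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture_spec <- function() {
  if (is.null(.fixtures$spec)) .fixtures$spec <- phantom_spec()
  .fixtures$spec
}

fixture_atlas <- function() {
  if (is.null(.fixtures$atlas)) .fixtures$atlas <- build_phantom_atlas(fixture_spec())
  .fixtures$atlas
}

fixture_dilated <- function() {
  if (is.null(.fixtures$dilated)) .fixtures$dilated <- modal_dilate(fixture_atlas(), 1L)
  .fixtures$dilated
}

# A small axis-aligned test affine: 2 mm voxels, corner offset.
test_affine <- function(voxel = c(2, 2, 2), origin = c(-10, -20, -30)) {
  aff <- rbind(cbind(diag(voxel), origin), c(0, 0, 0, 1))
  dimnames(aff) <- NULL
  aff
}

# Independent voxel-lookup oracle: nearest-voxel ownership computed from
# first principles, one point at a time, without reusing package internals.
oracle_label_at <- function(vol, p) {
  v <- solve(vol$affine) %*% c(p, 1)
  ijk <- floor(v[1:3] + 0.5)
  d <- dim(vol$grid)
  if (any(ijk < 0) || any(ijk > d - 1)) return(0L)
  vol$grid[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1]
}

# Fine-sampling traversal oracle: voxelize a polyline at `step` mm (default
# 0.1) and return the sorted set of nonzero labels it passes through.
oracle_traversal <- function(s, vol, step = 0.1) {
  pts <- list(s[1, , drop = FALSE])
  for (i in seq_len(nrow(s) - 1)) {
    a <- s[i, ]; b <- s[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / step))
    tt <- seq_len(n) / n
    pts[[i + 1]] <- cbind(a[1] + tt * (b[1] - a[1]),
                          a[2] + tt * (b[2] - a[2]),
                          a[3] + tt * (b[3] - a[3]))
  }
  pts <- do.call(rbind, pts)
  labs <- vapply(seq_len(nrow(pts)),
                 function(i) as.integer(oracle_label_at(vol, pts[i, ])),
                 integer(1))
  sort(unique(labs[labs != 0L]))
}

# Byte-level TRK writer, independent of the package writer: assembles the
# 1000-byte header and voxel-mm point data directly so that read_tractogram
# is checked against the on-disk format, not against write_tractogram.
oracle_write_trk <- function(path, streamlines, voxel_size, affine) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(1000)
  poke <- function(hdr, at, bytes) {
    hdr[(at + 1):(at + length(bytes))] <- bytes
    hdr
  }
  hdr <- poke(hdr, 0, charToRaw("TRACK"))
  hdr <- poke(hdr, 6, writeBin(rep(1L, 3), raw(), size = 2, endian = "little"))
  hdr <- poke(hdr, 12, writeBin(as.numeric(voxel_size), raw(), size = 4,
                                endian = "little"))
  hdr <- poke(hdr, 440, writeBin(as.numeric(t(affine)), raw(), size = 4,
                                 endian = "little"))
  hdr <- poke(hdr, 948, c(charToRaw("RAS"), as.raw(0)))
  hdr <- poke(hdr, 988, writeBin(length(streamlines), raw(), size = 4,
                                 endian = "little"))
  hdr <- poke(hdr, 992, writeBin(2L, raw(), size = 4, endian = "little"))
  hdr <- poke(hdr, 996, writeBin(1000L, raw(), size = 4, endian = "little"))
  writeBin(hdr, con)
  inv <- solve(affine)
  for (s in streamlines) {
    writeBin(nrow(s), con, size = 4, endian = "little")
    for (i in seq_len(nrow(s))) {
      v <- (inv %*% c(s[i, ], 1))[1:3]        # 0-based voxel coordinates
      voxmm <- (v + 0.5) * voxel_size          # TRK corner-origin voxel mm
      writeBin(as.numeric(voxmm), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

# Straight-line streamline between two world points with a given number of
# intermediate vertices.
segment_streamline <- function(a, b, n = 10) {
  tt <- seq(0, 1, length.out = n)
  cbind(a[1] + tt * (b[1] - a[1]),
        a[2] + tt * (b[2] - a[2]),
        a[3] + tt * (b[3] - a[3]))
}

max_point_error <- function(s1, s2) {
  max(mapply(function(a, b) max(abs(a - b)), s1, s2))
}
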