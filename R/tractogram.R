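#' Tractogram objects
#'
#' A tractogram is a set of streamlines — ordered 3-D point sequences in
#' world coordinates (mm, RAS+) — together with the voxel geometry of the
#' space they were reconstructed in. Streamlines are stored as numeric
#' `n x 3` matrices; all dissection and termination analyses operate on
#' these world-mm coordinates.
#'
#' @param streamlines List of numeric matrices, each `n x 3` with `n >= 2`,
#'   finite coordinates, consecutive points distinct.
#' @param voxel_size Numeric length-3, voxel dimensions in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices), must be
#'   invertible.
#' @param space_tag Free-text description of the coordinate space.
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, voxel_size = c(2, 2, 2),
                       affine = NULL, space_tag = "native") {
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0),
            is.matrix(affine), all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("tractogram affine is singular")
  }
  streamlines <- lapply(streamlines, validate_streamline)
  structure(
    list(streamlines = streamlines,
         voxel_size = as.numeric(voxel_size),
         affine = affine,
         space_tag = space_tag),
    class = "tractogram"
  )
}

validate_streamline <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) < 2L) {
    stop("a streamline needs >= 2 points with 3 coordinates each")
  }
  if (!all(is.finite(points))) stop("streamline coordinates must be finite")
  seg <- diff(points)
  if (any(rowSums(seg^2) == 0)) stop("consecutive streamline points must be distinct")
  dimnames(points) <- NULL
  points
}

#' @export
print.tractogram <- function(x, ...) {
  cat("<tractogram>", length(x$streamlines), "streamlines,",
      "voxel size", paste(x$voxel_size, collapse = "x"), "mm,",
      "space:", x$space_tag, "\n")
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Number of streamlines in a tractogram
#' @param t A `tractogram`.
#' @return Integer count.
#' @export
n_streamlines <- function(t) length(t$streamlines)

subset_tractogram <- function(t, keep) {
  t$streamlines <- t$streamlines[keep]
  t
}

#' Streamline length
#'
#' Arc length of a streamline polyline: the sum of Euclidean lengths of its
#' consecutive segments, in mm. Used by the preparation filter that removes
#' extraneous streamlines shorter than a minimum length.
#'
#' @param s A streamline (`n x 3` numeric matrix, world mm).
#' @return Length in mm.
#' @export
streamline_length <- function(s) {
  s <- as.matrix(s)
  sum(sqrt(rowSums(diff(s)^2)))
}

#' Streamline lengths for a whole tractogram
#' @param t A `tractogram`.
#' @return Numeric vector of lengths in mm.
#' @export
streamline_lengths <- function(t) {
  vapply(t$streamlines, streamline_length, numeric(1))
}

# Resample a polyline so consecutive points are <= step mm apart.
# Original vertices are always retained (the polyline geometry is unchanged;
# points are only inserted). Fast path: already fine enough.
resample_polyline <- function(points, step) {
  seg <- diff(points)
  seg_len <- sqrt(rowSums(seg^2))
  if (all(seg_len <= step)) return(points)
  pieces <- vector("list", nrow(points) - 1L)
  for (i in seq_len(nrow(points) - 1L)) {
    n_sub <- ceiling(seg_len[i] / step)
    f <- seq(0, 1, length.out = n_sub + 1L)[-(n_sub + 1L)]
    pieces[[i]] <- cbind(points[i, 1] + f * seg[i, 1],
                         points[i, 2] + f * seg[i, 2],
                         points[i, 3] + f * seg[i, 3])
  }
  rbind(do.call(rbind, pieces), points[nrow(points), , drop = FALSE])
}
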