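#' Labeled atlas volumes
#'
#' A label volume couples a 3-D integer label grid (with its voxel-to-world
#' affine) with a label table giving, for every label id, its region name,
#' hemisphere, lobe, tissue class and terminal side. The tissue classes
#' follow the three large divisions used for streamline selection: cortical
#' gray matter (CGM), superficial white matter (SWM) beneath the gyri, and
#' deep white matter (DWM); `other` covers subcortical nuclei, cerebellum
#' and brainstem. `terminal_side` marks which end-set (anterior or
#' posterior) a cortical region belongs to for termination bookkeeping.
#'
#' @param grid 3-D integer array of label ids (0 = background).
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices, RAS+ mm).
#' @param table Label table, see [read_label_table()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, affine, table) {
  stopifnot(length(dim(grid)) == 3L, all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps) stop("label volume affine is singular")
  if (any(grid != round(grid))) stop("label grid must be integer-valued")
  storage.mode(grid) <- "integer"
  table <- validate_label_table(table)
  present <- sort(unique(as.integer(grid)))
  present <- present[present != 0L]
  missing <- setdiff(present, table$id)
  if (length(missing) > 0) {
    stop("labels present in image but absent from table: ",
         paste(missing, collapse = ", "))
  }
  structure(list(grid = grid, affine = affine, table = table),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume>", paste(dim(x$grid), collapse = "x"), "voxels,",
      nrow(x$table), "labels,",
      "voxel volume", format(voxel_volume(x)), "mm^3\n")
  invisible(x)
}

#' Voxel volume of a label volume or mask, in mm^3
#' @param vol A `label_volume` (or anything with a 4x4 `$affine`).
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(vol) abs(det(vol$affine[1:3, 1:3]))

#' Read a label table
#'
#' The label table is a TSV with columns `id`, `name`, `hemisphere`
#' (left/right/midline), `lobe`, `tissue` (CGM/SWM/DWM/other) and
#' `terminal_side` (anterior_set/posterior_set/none). Region `name` is the
#' base anatomical name shared by the left and right homologs; the
#' `hemisphere` column distinguishes them.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_label_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_label_table(tbl)
}

#' Write a label table to TSV
#' @param table Label table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

validate_label_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  needed <- c("id", "name", "hemisphere", "lobe", "tissue", "terminal_side")
  miss <- setdiff(needed, names(tbl))
  if (length(miss)) stop("label table missing columns: ", paste(miss, collapse = ", "))
  tbl$id <- as.integer(tbl$id)
  if (anyDuplicated(tbl$id)) stop("label ids must be unique")
  if (any(tbl$id <= 0)) stop("label ids must be > 0")
  stopifnot(all(tbl$hemisphere %in% c("left", "right", "midline")),
            all(tbl$tissue %in% c("CGM", "SWM", "DWM", "other")),
            all(tbl$terminal_side %in% c("anterior_set", "posterior_set", "none")))
  bad <- tbl$tissue == "CGM" & tbl$terminal_side == "none"
  if (any(bad)) {
    stop("every CGM label needs a terminal_side; offending ids: ",
         paste(tbl$id[bad], collapse = ", "))
  }
  tbl
}

#' Read a NIfTI label image with its label table
#'
#' @param path NIfTI-1 integer label image.
#' @param table A label-table tibble, or the path to its TSV (see
#'   [read_label_table()]).
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, table) {
  img <- RNifti::readNifti(path)
  grid <- as.array(img)
  if (any(grid != round(grid))) stop("label image contains non-integer voxel data")
  if (is.character(table)) table <- read_label_table(table)
  label_volume(grid, bare_affine(RNifti::xform(img)), table)
}

#' Write a label volume (NIfTI image + TSV table)
#'
#' @param vol A [label_volume()].
#' @param path Output NIfTI path.
#' @param table_path Optional output TSV path for the label table.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path, table_path = NULL) {
  write_nifti_array(vol$grid, vol$affine, path)
  if (!is.null(table_path)) write_label_table(vol$table, table_path)
  invisible(path)
}

write_nifti_array <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr + 0L)
  # pixdim must agree with the affine scale or the writer renormalizes srow
  img <- RNifti::`pixdim<-`(img, sqrt(colSums(affine[1:3, 1:3]^2)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# drop reader metadata so the affine is a plain 4x4 numeric matrix
bare_affine <- function(affine) {
  matrix(as.numeric(affine), nrow = 4, ncol = 4)
}

# world mm (n x 3) -> continuous 0-based voxel coordinates (n x 3)
world_to_voxel <- function(points, affine) {
  points <- matrix(points, ncol = 3)
  v <- cbind(points, 1) %*% t(solve(affine))
  v[, 1:3, drop = FALSE]
}

voxel_to_world <- function(idx, affine) {
  idx <- matrix(idx, ncol = 3)
  w <- cbind(idx, 1) %*% t(affine)
  w[, 1:3, drop = FALSE]
}

#' Label at a world point
#'
#' Maps points through the inverse affine and applies the nearest-voxel rule:
#' voxel `i` owns the half-open voxel-coordinate interval `[i - 0.5, i + 0.5)`
#' on each axis. Points outside the grid return 0 (background).
#'
#' @param vol A [label_volume()].
#' @param p World coordinate(s): length-3 vector or `n x 3` matrix.
#' @return Integer label id(s); 0 for background or out-of-grid points.
#' @export
label_at_point <- function(vol, p) {
  v <- world_to_voxel(p, vol$affine)
  idx <- floor(v + 0.5)  # [i - 0.5, i + 0.5) ownership
  d <- dim(vol$grid)
  inside <- idx[, 1] >= 0 & idx[, 1] < d[1] &
    idx[, 2] >= 0 & idx[, 2] < d[2] &
    idx[, 3] >= 0 & idx[, 3] < d[3]
  out <- integer(nrow(idx))
  if (any(inside)) {
    lin <- 1 + idx[inside, 1] + d[1] * (idx[inside, 2] + d[2] * idx[inside, 3])
    out[inside] <- vol$grid[lin]
  }
  out
}

#' Modal dilation of a label volume
#'
#' One pass assigns to every background voxel that has at least one nonzero
#' 26-neighbor the most frequent (modal) neighboring nonzero label; already
#' labeled voxels are never changed and no new label values appear. Ties are
#' broken toward the lowest label id, so the operation is deterministic.
#' Used once on the atlas to include the gray/white interface before
#' endpoint lookup.
#'
#' @param vol A [label_volume()].
#' @param iterations Number of dilation passes (>= 0); 0 returns the input.
#' @return A [label_volume()] with the dilated grid.
#' @export
modal_dilate <- function(vol, iterations = 1L) {
  stopifnot(iterations >= 0)
  grid <- vol$grid
  d <- dim(grid)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  for (it in seq_len(iterations)) {
    bg <- which(grid == 0L)
    if (length(bg) == 0L) break
    # 0-based coordinates of background voxels
    bg0 <- bg - 1L
    bx <- bg0 %% d[1]
    by <- (bg0 %/% d[1]) %% d[2]
    bz <- bg0 %/% (d[1] * d[2])
    nbr <- matrix(0L, nrow = length(bg), ncol = nrow(offsets))
    for (o in seq_len(nrow(offsets))) {
      nx <- bx + offsets[o, 1]; ny <- by + offsets[o, 2]; nz <- bz + offsets[o, 3]
      ok <- nx >= 0 & nx < d[1] & ny >= 0 & ny < d[2] & nz >= 0 & nz < d[3]
      vals <- integer(length(bg))
      if (any(ok)) {
        vals[ok] <- grid[1 + nx[ok] + d[1] * (ny[ok] + d[2] * nz[ok])]
      }
      nbr[, o] <- vals
    }
    has_nbr <- rowSums(nbr != 0L) > 0
    if (!any(has_nbr)) break
    nbr <- nbr[has_nbr, , drop = FALSE]
    labels <- sort(unique(as.integer(nbr)))
    labels <- labels[labels != 0L]
    best_count <- integer(nrow(nbr))
    best_label <- integer(nrow(nbr))
    for (L in labels) {  # ascending: ties keep the lowest label
      cnt <- rowSums(nbr == L)
      take <- cnt > best_count
      best_count[take] <- cnt[take]
      best_label[take] <- L
    }
    grid[bg[has_nbr]] <- best_label
  }
  vol$grid <- grid
  vol
}
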