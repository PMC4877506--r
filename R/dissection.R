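#' Tractogram preparation parameters
#'
#' @param min_length_mm Minimum streamline length retained (mm); shorter
#'   streamlines are removed as extraneous fragments.
#' @param sampling_step_mm Optional extra resampling step (mm) applied to
#'   each polyline before classification. Voxel traversal is computed
#'   exactly from the polyline geometry (see [classify_streamlines()]), so
#'   this does not change which voxels are visited; it is kept for
#'   workflows that want densified vertices.
#' @return An object of class `prep_params`.
#' @export
prep_params <- function(min_length_mm = 10, sampling_step_mm = NULL) {
  stopifnot(min_length_mm > 0, is.null(sampling_step_mm) || sampling_step_mm > 0)
  structure(list(min_length_mm = min_length_mm,
                 sampling_step_mm = sampling_step_mm),
            class = "prep_params")
}

# Exact voxel sweep of polylines given in continuous 0-based voxel
# coordinates. `v` stacks the vertices of all polylines and `sid` holds each
# vertex's polyline id (vertices of one polyline are contiguous). For every
# segment, the parameters where it crosses a half-integer boundary plane are
# enumerated per axis, and one sample is taken at the midpoint of each
# inter-crossing interval. Returns the polyline id and the 0-based voxel
# index of every sample.
traverse_voxels <- function(v, sid) {
  m <- nrow(v)
  seg <- which(sid[-m] == sid[-1])   # rows that start a segment
  a <- v[seg, , drop = FALSE]
  b <- v[seg + 1L, , drop = FALSE]
  nseg <- length(seg)
  cs <- vector("list", 3L)
  for (d in 1:3) {
    lo <- pmin(a[, d], b[, d]); hi <- pmax(a[, d], b[, d])
    nc <- as.integer(floor(hi + 0.5) - floor(lo + 0.5))
    hit <- which(nc > 0L)
    if (length(hit) == 0L) {
      cs[[d]] <- list(seg = integer(), t = numeric())
      next
    }
    sr <- rep(hit, nc[hit])
    plane <- floor(lo[sr] + 0.5) - 0.5 + sequence(nc[hit])
    cs[[d]] <- list(seg = sr, t = (plane - a[sr, d]) / (b[sr, d] - a[sr, d]))
  }
  segv <- c(seq_len(nseg), seq_len(nseg),
            cs[[1]]$seg, cs[[2]]$seg, cs[[3]]$seg)
  tsv <- c(rep(0, nseg), rep(1, nseg), cs[[1]]$t, cs[[2]]$t, cs[[3]]$t)
  ord <- order(segv, tsv)
  segv <- segv[ord]; tsv <- tsv[ord]
  pair <- which(segv[-length(segv)] == segv[-1])
  mid <- (tsv[pair] + tsv[pair + 1L]) / 2
  sm <- segv[pair]
  p <- a[sm, , drop = FALSE] + mid * (b[sm, , drop = FALSE] - a[sm, , drop = FALSE])
  list(id = sid[seg][sm], voxel = floor(p + 0.5))
}

# label at 0-based voxel indices; 0 outside the grid
grid_label <- function(grid, idx) {
  d <- dim(grid)
  inside <- idx[, 1] >= 0 & idx[, 1] < d[1] &
    idx[, 2] >= 0 & idx[, 2] < d[2] &
    idx[, 3] >= 0 & idx[, 3] < d[3]
  out <- integer(nrow(idx))
  if (any(inside)) {
    lin <- 1 + idx[inside, 1] + d[1] * (idx[inside, 2] + d[2] * idx[inside, 3])
    out[inside] <- grid[lin]
  }
  out
}

#' Classify the streamlines of a tractogram
#'
#' For every streamline: arc length; endpoint labels looked up on the
#' dilated volume; the sets of tissue classes and lobes traversed, looked up
#' on the undilated volume (background voxels do not contribute a class);
#' whether the path reaches strictly both sides of the mid-sagittal plane
#' x = 0; and whether it enters a cerebellum/brainstem label. These are the
#' raw ingredients of the preparation filters.
#'
#' Traversal is exact, not sampled: each segment between consecutive
#' vertices is swept in continuous voxel coordinates, the parameters where
#' it crosses a voxel boundary (a half-integer plane on any axis under the
#' nearest-voxel ownership rule) are enumerated, and the label is read at
#' the midpoint of every inter-crossing interval. Every voxel the polyline
#' passes through is therefore visited exactly, at any voxel size.
#'
#' @param t A [tractogram()].
#' @param vol,dilated The label volume and its modally dilated version.
#' @param params A [prep_params()].
#' @return Tibble with one row per streamline: `id`, `length_mm`,
#'   `end1_label`, `end2_label`, `tissues` and `lobes` (list columns of
#'   sorted unique classes), `crosses_midsagittal`,
#'   `enters_cerebellum_brainstem`.
#' @export
classify_streamlines <- function(t, vol, dilated, params = prep_params()) {
  n <- length(t$streamlines)
  lengths <- streamline_lengths(t)
  ends1 <- do.call(rbind, lapply(t$streamlines, function(s) s[1, ]))
  ends2 <- do.call(rbind, lapply(t$streamlines, function(s) s[nrow(s), ]))
  if (n == 0L) {
    return(tibble::tibble(id = integer(), length_mm = numeric(),
                          end1_label = integer(), end2_label = integer(),
                          tissues = list(), lobes = list(),
                          crosses_midsagittal = logical(),
                          enters_cerebellum_brainstem = logical()))
  }
  lines <- t$streamlines
  if (!is.null(params$sampling_step_mm)) {
    lines <- lapply(lines, resample_polyline, step = params$sampling_step_mm)
  }
  nv <- vapply(lines, nrow, integer(1))
  verts <- do.call(rbind, lines)
  vsid <- rep(seq_len(n), nv)
  tv <- traverse_voxels(world_to_voxel(verts, vol$affine), vsid)
  ids <- tv$id
  labels <- grid_label(vol$grid, tv$voxel)

  tissue_of <- stats::setNames(vol$table$tissue, vol$table$id)
  lobe_of <- stats::setNames(vol$table$lobe, vol$table$id)

  # unique (streamline, label) pairs; drop background
  keep <- labels != 0L
  key <- ids[keep] * (max(vol$table$id) + 1) + labels[keep]
  first <- !duplicated(key)
  pid <- ids[keep][first]
  plab <- labels[keep][first]
  ptis <- unname(tissue_of[as.character(plab)])
  plob <- unname(lobe_of[as.character(plab)])

  tissues <- rep(list(character(0)), n)
  lobes <- rep(list(character(0)), n)
  for (grp in split(seq_along(pid), pid)) {
    i <- pid[grp[1]]
    tissues[[i]] <- sort(unique(ptis[grp]))
    lobes[[i]] <- sort(unique(plob[grp]))
  }
  enters_cb <- vapply(lobes, function(l) "cerebellum_brainstem" %in% l, logical(1))

  # a piecewise-linear path attains its x extremes at vertices, so it
  # reaches both sides of x = 0 iff some vertex lies strictly on each side
  x <- verts[, 1]
  crosses <- as.logical(rowsum(as.integer(x < 0), vsid) > 0 &
                          rowsum(as.integer(x > 0), vsid) > 0)

  tibble::tibble(
    id = seq_len(n),
    length_mm = lengths,
    end1_label = label_at_point(dilated, ends1),
    end2_label = label_at_point(dilated, ends2),
    tissues = tissues,
    lobes = lobes,
    crosses_midsagittal = crosses,
    enters_cerebellum_brainstem = enters_cb)
}

#' Classify a single streamline
#'
#' @param s A streamline (`n x 3` matrix, world mm).
#' @inheritParams classify_streamlines
#' @return A one-row tibble, see [classify_streamlines()].
#' @export
classify_streamline <- function(s, vol, dilated, params = prep_params()) {
  t <- tractogram(list(s), voxel_size = diag(vol$affine)[1:3], affine = vol$affine)
  classify_streamlines(t, vol, dilated, params)
}

#' Prepare a whole-brain tractogram
#'
#' Removes, in order, (1) streamlines shorter than the minimum length,
#' (2) streamlines confined to cortical gray matter, (3) U-shaped
#' superficial streamlines that traverse only CGM/SWM and never enter deep
#' white matter, (4) streamlines entering the cerebellum or brainstem and
#' (5) streamlines crossing the inter-hemispheric fissure (x = 0). A
#' removed streamline is attributed to the first matching rule, so the
#' tally partitions the removed set.
#'
#' @inheritParams classify_streamlines
#' @return `list(tractogram, tally, kept, classification)`: the surviving
#'   tractogram, a tibble of per-rule removal counts, the indices of
#'   survivors in the input, and the full classification table.
#' @export
prepare_tractogram <- function(t, vol, dilated, params = prep_params()) {
  cl <- classify_streamlines(t, vol, dilated, params)
  has <- function(class) vapply(cl$tissues, function(x) class %in% x, logical(1))
  has_dwm <- has("DWM"); has_swm <- has("SWM"); has_other <- has("other")
  only_cgm <- !has_dwm & !has_swm & !has_other
  no_dwm <- !has_dwm & !has_other

  r1 <- cl$length_mm < params$min_length_mm
  r2 <- !r1 & only_cgm
  r3 <- !r1 & !r2 & no_dwm
  r4 <- !r1 & !r2 & !r3 & cl$enters_cerebellum_brainstem
  r5 <- !r1 & !r2 & !r3 & !r4 & cl$crosses_midsagittal
  kept <- which(!(r1 | r2 | r3 | r4 | r5))

  tally <- tibble::tibble(
    rule = c("short", "gm_confined", "u_fiber", "cerebellum_brainstem",
             "interhemispheric"),
    n_removed = c(sum(r1), sum(r2), sum(r3), sum(r4), sum(r5)))
  list(tractogram = subset_tractogram(t, kept), tally = tally, kept = kept,
       classification = cl)
}

# label ids used by the stem-exposure step, found by name/lobe in the table
exposure_label_ids <- function(table, tract) {
  insula <- table$id[table$lobe == "insula"]
  if (tract == "IFOF") {
    extra <- table$id[table$tissue == "CGM" &
                        table$name %in% c("TPO", "T.pole", "temporal_pole",
                                          "TemporalPole")]
  } else {
    extra <- table$id[table$tissue == "CGM" &
                        table$name %in% c("STG", "superior_temporal",
                                          "SuperiorTemporal")]
  }
  c(insula, extra)
}

#' Expose a tract stem
#'
#' Removes from a prepared tractogram the streamlines whose endpoints would
#' obscure the stem: for the IFOF, streamlines with either endpoint in the
#' insula or temporal pole; for the UF, streamlines with either endpoint in
#' the insula or superior temporal gyrus. The result is a visualization aid
#' for locating and drawing the stem ROI; extraction itself always runs on
#' the original whole-brain tractogram.
#'
#' @param prepared Output tractogram of [prepare_tractogram()].
#' @param dilated Dilated label volume (endpoint lookups).
#' @param tract `"IFOF"` or `"UF"`.
#' @param exclusion_labels Optional explicit label-id set overriding the
#'   name-based default.
#' @return A [tractogram()].
#' @export
expose_stem <- function(prepared, dilated, tract = c("IFOF", "UF"),
                        exclusion_labels = NULL) {
  tract <- match.arg(tract)
  ids <- exclusion_labels %||% exposure_label_ids(dilated$table, tract)
  e1 <- vapply(prepared$streamlines, function(s)
    label_at_point(dilated, s[1, , drop = FALSE]), integer(1))
  e2 <- vapply(prepared$streamlines, function(s)
    label_at_point(dilated, s[nrow(s), , drop = FALSE]), integer(1))
  keep <- !(e1 %in% ids | e2 %in% ids)
  subset_tractogram(prepared, which(keep))
}

orientation_axis <- function(orientation) {
  switch(orientation, coronal = 2L, axial = 3L,
         stop("orientation must be 'coronal' or 'axial'"))
}

#' Suggest the stem slice of an exposed bundle
#'
#' Scans candidate slices along the given orientation, collects the voxels
#' each slice shares with the bundle's streamlines, and proposes the slice
#' where the bundle's occupied cross-section is smallest — the compact
#' waist before the streamlines fan out to the cortex. Slices not crossed
#' by any streamline are ignored; ties go to the lower slice index. This
#' assists the manual stem-drawing step; externally drawn masks are equally
#' accepted by [extract_tract()].
#'
#' @param exposed Exposed tractogram ([expose_stem()] output), nonempty.
#' @param vol Label volume providing the voxel grid geometry.
#' @param orientation `"coronal"` (scan along y) or `"axial"` (along z).
#' @param search_range Integer slice range (0-based, inclusive) to scan.
#' @param tract_tag,hemisphere,operator Metadata stored on the candidate ROI.
#' @return `list(slice_index, mask, profile)`: the chosen slice, a
#'   [stem_roi()] of the occupied voxels on it, and a tibble of per-slice
#'   occupied-voxel counts.
#' @export
suggest_stem_slice <- function(exposed, vol, orientation = c("coronal", "axial"),
                               search_range, tract_tag = "IFOF",
                               hemisphere = "right", operator = "auto") {
  orientation <- match.arg(orientation)
  if (length(exposed$streamlines) == 0L) stop("exposed tractogram is empty")
  search_range <- as.integer(search_range)
  if (length(search_range) < 1L) stop("empty search range")
  axis <- orientation_axis(orientation)
  slices <- seq(min(search_range), max(search_range))

  step <- min(svd(vol$affine[1:3, 1:3])$d) / 2
  pts <- do.call(rbind, lapply(exposed$streamlines, resample_polyline, step = step))
  v <- world_to_voxel(pts, vol$affine)
  idx <- floor(v + 0.5)
  d <- dim(vol$grid)
  inside <- idx[, 1] >= 0 & idx[, 1] < d[1] & idx[, 2] >= 0 & idx[, 2] < d[2] &
    idx[, 3] >= 0 & idx[, 3] < d[3]
  idx <- idx[inside & idx[, axis] %in% slices, , drop = FALSE]
  if (nrow(idx) == 0L) stop("no streamline crosses the search range")
  lin <- idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3])
  idx <- idx[!duplicated(lin), , drop = FALSE]

  width <- table(factor(idx[, axis], levels = slices))
  profile <- tibble::tibble(slice = slices, width = as.integer(width))
  crossed <- profile[profile$width > 0L, ]
  best <- crossed$slice[which.min(crossed$width)]  # which.min takes first = lowest

  mask_vox <- idx[idx[, axis] == best, , drop = FALSE]
  roi <- stem_roi(voxels = mask_vox, grid_dim = d, affine = vol$affine,
                  orientation = orientation, tract_tag = tract_tag,
                  hemisphere = hemisphere, operator = operator)
  list(slice_index = best, mask = roi, profile = profile)
}

#' Stem region of interest
#'
#' A binary single-slice mask around a tract's stem: all nonzero voxels lie
#' on one slice along the orientation axis (coronal for the IFOF, axial for
#' the UF).
#'
#' @param voxels Integer `n x 3` matrix of 0-based voxel indices, or a 3-D
#'   logical/0-1 array (combined with `grid_dim`).
#' @param grid_dim Grid dimensions (needed when `voxels` is an index matrix).
#' @param affine 4x4 voxel-to-world matrix of the mask grid.
#' @param orientation `"coronal"` or `"axial"`.
#' @param tract_tag,hemisphere,operator Metadata.
#' @return An object of class `stem_roi`.
#' @export
stem_roi <- function(voxels, grid_dim = NULL, affine,
                     orientation = c("coronal", "axial"),
                     tract_tag = "IFOF", hemisphere = "right", operator = "") {
  orientation <- match.arg(orientation)
  if (is.array(voxels) && length(dim(voxels)) == 3L) {
    grid_dim <- dim(voxels)
    voxels <- which(voxels != 0, arr.ind = TRUE) - 1L
    dimnames(voxels) <- NULL
  } else {
    voxels <- matrix(as.integer(voxels), ncol = 3)
    if (is.null(grid_dim)) stop("grid_dim required with a voxel index matrix")
  }
  if (nrow(voxels) == 0L) stop("stem mask is empty")
  axis <- orientation_axis(orientation)
  slice <- unique(voxels[, axis])
  if (length(slice) != 1L) {
    stop("stem ROI voxels must lie on a single ", orientation, " slice")
  }
  structure(list(voxels = voxels, grid_dim = as.integer(grid_dim),
                 affine = affine, orientation = orientation,
                 slice_index = as.integer(slice), tract_tag = tract_tag,
                 hemisphere = hemisphere, operator = operator),
            class = "stem_roi")
}

#' @export
print.stem_roi <- function(x, ...) {
  cat("<stem_roi>", x$tract_tag, x$hemisphere, "—", nrow(x$voxels),
      "voxels on", x$orientation, "slice", x$slice_index,
      if (nzchar(x$operator)) paste0("(operator ", x$operator, ")") else "", "\n")
  invisible(x)
}

#' Write a stem ROI as a binary NIfTI mask
#' @param stem A [stem_roi()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stem_roi <- function(stem, path) {
  arr <- array(0L, dim = stem$grid_dim)
  arr[stem$voxels + 1L] <- 1L
  write_nifti_array(arr, stem$affine, path)
}

#' Read a stem ROI from a binary NIfTI mask
#' @param path NIfTI mask path.
#' @inheritParams stem_roi
#' @return A [stem_roi()].
#' @export
read_stem_roi <- function(path, orientation = c("coronal", "axial"),
                          tract_tag = "IFOF", hemisphere = "right",
                          operator = "") {
  img <- RNifti::readNifti(path)
  stem_roi(as.array(img) != 0, affine = bare_affine(RNifti::xform(img)),
           orientation = orientation, tract_tag = tract_tag,
           hemisphere = hemisphere, operator = operator)
}

#' Tract extraction rules
#'
#' The least-constraint rules applied at extraction time: label sets whose
#' traversal excludes a streamline (e.g. the temporal pole for the IFOF), an
#' optional exclusion half-space (e.g. a coronal plane posterior to the
#' external capsule for the UF), lobes whose terminations are recorded but
#' excluded from analysis (insula, subcortical nuclei), and whether broken
#' streamlines are discarded (default: retained, so they stay in the
#' normalized-density denominator).
#'
#' @param exclusion_labels Integer label ids; streamlines touching any are
#'   dropped.
#' @param exclusion_plane `NULL` or `list(axis =, coordinate =, side =)`
#'   with axis in `x`/`y`/`z` and side naming the excluded half-space
#'   (`"less"`/`"greater"`, or anatomical synonyms `posterior`/`anterior`,
#'   `inferior`/`superior`, `left`/`right`).
#' @param discard_terminal_lobes Lobe names whose endpoint terminations are
#'   flagged excluded-from-analysis.
#' @param discard_broken Drop streamlines with a non-cortical endpoint.
#' @return An object of class `extraction_rules`.
#' @export
extraction_rules <- function(exclusion_labels = integer(),
                             exclusion_plane = NULL,
                             discard_terminal_lobes = c("insula", "subcortical"),
                             discard_broken = FALSE) {
  if (!is.null(exclusion_plane)) {
    stopifnot(exclusion_plane$axis %in% c("x", "y", "z"))
    side <- exclusion_plane$side
    exclusion_plane$side <- switch(
      side,
      less = , posterior = , inferior = , left = "less",
      greater = , anterior = , superior = , right = "greater",
      stop("unknown plane side: ", side))
  }
  structure(list(exclusion_labels = as.integer(exclusion_labels),
                 exclusion_plane = exclusion_plane,
                 discard_terminal_lobes = discard_terminal_lobes,
                 discard_broken = isTRUE(discard_broken)),
            class = "extraction_rules")
}

#' Extract a tract through its stem
#'
#' Keeps every streamline of the *original* whole-brain tractogram that
#' intersects the stem mask, then applies the extraction rules: streamlines
#' touching an exclusion label or reaching beyond the exclusion plane are
#' dropped. Both endpoints of each kept streamline are labeled on the
#' dilated volume; endpoints in a discarded terminal lobe are flagged
#' excluded-from-analysis, and endpoints that are not cortical gray matter
#' (background, SWM or DWM) are flagged broken — streamlines that passed
#' the stem but stopped short of the cortex.
#'
#' @param original The original whole-brain [tractogram()].
#' @param stem A [stem_roi()].
#' @param rules An [extraction_rules()].
#' @param vol,dilated Label volume and its dilated version.
#' @return `list(tractogram, endpoints, tally)`: the extracted tract, a
#'   per-streamline endpoint table (`id` = index into `original`,
#'   `label_1`, `label_2`, `broken_1/2`, `excluded_1/2`) and a tally tibble
#'   (kept / excluded_by_label / excluded_by_plane / broken).
#' @export
extract_tract <- function(original, stem, rules, vol, dilated) {
  if (nrow(stem$voxels) == 0L) stop("stem mask is empty")
  n <- length(original$streamlines)
  d <- stem$grid_dim
  mask_lin <- stem$voxels[, 1] + d[1] * (stem$voxels[, 2] + d[2] * stem$voxels[, 3])
  step <- min(svd(vol$affine[1:3, 1:3])$d) / 2

  sampled <- lapply(original$streamlines, resample_polyline, step = step)
  sizes <- vapply(sampled, nrow, integer(1))
  ids <- rep(seq_len(n), sizes)
  pts <- do.call(rbind, sampled)
  v <- world_to_voxel(pts, stem$affine)
  idx <- floor(v + 0.5)
  inside <- idx[, 1] >= 0 & idx[, 1] < d[1] & idx[, 2] >= 0 & idx[, 2] < d[2] &
    idx[, 3] >= 0 & idx[, 3] < d[3]
  lin <- rep(-1, nrow(idx))
  lin[inside] <- idx[inside, 1] + d[1] * (idx[inside, 2] + d[2] * idx[inside, 3])
  hit_pt <- lin %in% mask_lin
  passes <- as.logical(rowsum(as.integer(hit_pt), ids) > 0)

  excl_label <- rep(FALSE, n)
  if (length(rules$exclusion_labels) > 0) {
    labels <- label_at_point(vol, pts)
    touch <- labels %in% rules$exclusion_labels
    excl_label <- as.logical(rowsum(as.integer(touch), ids) > 0)
  }
  excl_plane <- rep(FALSE, n)
  if (!is.null(rules$exclusion_plane)) {
    ax <- match(rules$exclusion_plane$axis, c("x", "y", "z"))
    coord <- pts[, ax]
    beyond <- if (rules$exclusion_plane$side == "less") {
      coord < rules$exclusion_plane$coordinate
    } else {
      coord > rules$exclusion_plane$coordinate
    }
    excl_plane <- as.logical(rowsum(as.integer(beyond), ids) > 0)
  }

  n_excl_label <- sum(passes & excl_label)
  n_excl_plane <- sum(passes & !excl_label & excl_plane)
  kept <- which(passes & !excl_label & !excl_plane)

  tissue_of <- stats::setNames(dilated$table$tissue, dilated$table$id)
  lobe_of <- stats::setNames(dilated$table$lobe, dilated$table$id)
  lab1 <- vapply(kept, function(i) {
    s <- original$streamlines[[i]]
    label_at_point(dilated, s[1, , drop = FALSE])
  }, integer(1))
  lab2 <- vapply(kept, function(i) {
    s <- original$streamlines[[i]]
    label_at_point(dilated, s[nrow(s), , drop = FALSE])
  }, integer(1))
  is_broken <- function(lab) {
    tis <- unname(tissue_of[as.character(lab)])
    lab == 0L | (!is.na(tis) & tis %in% c("SWM", "DWM"))
  }
  is_excluded <- function(lab) {
    lob <- unname(lobe_of[as.character(lab)])
    !is.na(lob) & lob %in% rules$discard_terminal_lobes
  }
  endpoints <- tibble::tibble(
    id = kept, label_1 = lab1, label_2 = lab2,
    broken_1 = is_broken(lab1), broken_2 = is_broken(lab2),
    excluded_1 = is_excluded(lab1), excluded_2 = is_excluded(lab2),
    y_1 = vapply(kept, function(i) original$streamlines[[i]][1, 2], numeric(1)),
    y_2 = vapply(kept, function(i) {
      s <- original$streamlines[[i]]
      s[nrow(s), 2]
    }, numeric(1)))
  n_broken <- sum(endpoints$broken_1 | endpoints$broken_2)
  if (rules$discard_broken) {
    drop <- endpoints$broken_1 | endpoints$broken_2
    endpoints <- endpoints[!drop, ]
    kept <- kept[!drop]
  }
  tally <- tibble::tibble(
    outcome = c("kept", "excluded_by_label", "excluded_by_plane", "broken"),
    n = c(length(kept), n_excl_label, n_excl_plane, n_broken))
  list(tractogram = subset_tractogram(original, kept), endpoints = endpoints,
       tally = tally)
}
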