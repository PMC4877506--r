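#' Phantom atlas specification
#'
#' Defines a deterministic block-layout brain phantom emulating a labeled
#' template with three tissue divisions. Two hemispheres are separated by
#' the mid-sagittal plane at world x = 0. Each hemisphere has a deep
#' white-matter (DWM) core; an anterior face of gyral cortical gray-matter
#' (CGM) blocks (orbito-frontal ORB, inferior/middle/superior frontal
#' IFG/MFG/SFG, precentral PRC, temporal pole TPO), each with a superficial
#' white-matter (SWM) layer between it and the DWM; a posterior face of
#' CGM blocks (superior temporal STG, lingual LG, middle occipital MOG,
#' superior parietal SPG) with their SWM layers; an insula (INS) and
#' subcortical (SUBC) block per hemisphere; and a midline
#' cerebellum/brainstem (CER) block below the cores.
#'
#' The voxel-to-world affine is diagonal with the grid centered so the
#' mid-sagittal plane falls exactly between the two central voxel columns.
#'
#' @param grid_shape Integer length-3 grid dimensions (default 60 x 72 x 60).
#' @param voxel_size Isotropic voxel size in mm (default 2).
#' @param cgm_thickness,swm_thickness Face layer thicknesses in voxels.
#' @return An object of class `phantom_spec` with the affine, the block
#'   layout table and the label table.
#' @export
phantom_spec <- function(grid_shape = c(60L, 72L, 60L), voxel_size = 2,
                         cgm_thickness = 5L, swm_thickness = 3L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0), voxel_size > 0,
            cgm_thickness >= 1L, swm_thickness >= 1L)
  vs <- rep(voxel_size, 3)
  affine <- diag(c(vs, 1))
  affine[1:3, 4] <- -(grid_shape / 2 - 0.5) * vs

  # right-hemisphere voxel index ranges (0-based, inclusive); left mirrored in i
  core_i <- c(38L, 48L)
  dwm_j <- c(12L, 59L)
  dwm_k <- c(14L, 46L)
  swm_a <- c(dwm_j[2] + 1L, dwm_j[2] + swm_thickness)
  cgm_a <- c(swm_a[2] + 1L, swm_a[2] + cgm_thickness)
  swm_p <- c(dwm_j[1] - swm_thickness, dwm_j[1] - 1L)
  cgm_p <- c(swm_p[1] - cgm_thickness, swm_p[1] - 1L)

  gyri <- tibble::tribble(
    ~name, ~lobe, ~terminal_side, ~face, ~k0,
    "TPO", "temporal",  "posterior_set", "anterior", 14L,
    "ORB", "frontal",   "anterior_set",  "anterior", 21L,
    "IFG", "frontal",   "anterior_set",  "anterior", 26L,
    "MFG", "frontal",   "anterior_set",  "anterior", 31L,
    "SFG", "frontal",   "anterior_set",  "anterior", 36L,
    "PRC", "frontal",   "anterior_set",  "anterior", 41L,
    "STG", "temporal",  "posterior_set", "posterior", 26L,
    "LG",  "occipital", "posterior_set", "posterior", 31L,
    "MOG", "occipital", "posterior_set", "posterior", 36L,
    "SPG", "parietal",  "posterior_set", "posterior", 41L
  )
  gyri$k1 <- gyri$k0 + 4L

  rows <- list()
  add <- function(name, hemisphere, tissue, lobe, terminal_side, i, j, k) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, hemisphere = hemisphere, tissue = tissue, lobe = lobe,
      terminal_side = terminal_side,
      i0 = i[1], i1 = i[2], j0 = j[1], j1 = j[2], k0 = k[1], k1 = k[2])
  }
  mirror <- function(i) c(grid_shape[1] - 1L - i[2], grid_shape[1] - 1L - i[1])
  for (h in c("left", "right")) {
    hi <- if (h == "right") core_i else mirror(core_i)
    for (r in seq_len(nrow(gyri))) {
      g <- gyri[r, ]
      cj <- if (g$face == "anterior") cgm_a else cgm_p
      sj <- if (g$face == "anterior") swm_a else swm_p
      add(g$name, h, "CGM", g$lobe, g$terminal_side, hi, cj, c(g$k0, g$k1))
      add(paste0("SWM_", g$name), h, "SWM", g$lobe, "none", hi, sj, c(g$k0, g$k1))
    }
    ins_i <- if (h == "right") c(50L, 52L) else mirror(c(50L, 52L))
    sub_i <- if (h == "right") c(34L, 36L) else mirror(c(34L, 36L))
    add("INS", h, "CGM", "insula", "posterior_set", ins_i, c(30L, 40L), c(24L, 34L))
    add("SUBC", h, "other", "subcortical", "none", sub_i, c(30L, 40L), c(24L, 34L))
    add("DWM", h, "DWM", "other", "none", hi, dwm_j, dwm_k)
  }
  add("CER", "midline", "other", "cerebellum_brainstem", "none",
      c(25L, 34L), c(12L, 30L), c(2L, 8L))
  blocks <- dplyr::bind_rows(rows)
  blocks$id <- seq_len(nrow(blocks))

  table <- blocks[, c("id", "name", "hemisphere", "lobe", "tissue", "terminal_side")]
  structure(
    list(grid_shape = grid_shape, voxel_size = vs, affine = affine,
         cgm_thickness = cgm_thickness, swm_thickness = swm_thickness,
         blocks = blocks, table = validate_label_table(table)),
    class = "phantom_spec")
}

#' Build the phantom label volume
#'
#' Deterministically rasterizes the block layout of a [phantom_spec()] into
#' a [label_volume()]. The spec is kept on the result (`$phantom`) so the
#' streamline simulator can place waypoints from the known layout.
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()].
#' @export
build_phantom_atlas <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  b <- spec$blocks
  if (any(b$i0 < 0 | b$j0 < 0 | b$k0 < 0 |
          b$i1 >= d[1] | b$j1 >= d[2] | b$k1 >= d[3])) {
    stop("phantom layout overflows the grid")
  }
  grid <- array(0L, dim = d)
  for (r in seq_len(nrow(b))) {
    grid[(b$i0[r]:b$i1[r]) + 1L, (b$j0[r]:b$j1[r]) + 1L, (b$k0[r]:b$k1[r]) + 1L] <-
      b$id[r]
  }
  vol <- label_volume(grid, spec$affine, spec$table)
  vol$phantom <- spec
  vol
}

# block row for a named region, as a plain list (fast to index)
phantom_block <- function(spec, name, hemisphere) {
  idx <- which(spec$blocks$name == name & spec$blocks$hemisphere == hemisphere)
  if (length(idx) != 1L) stop("no unique phantom block ", name, " / ", hemisphere)
  lapply(spec$blocks, `[`, idx)
}

# O(1) lookup table of all blocks keyed "name|hemisphere"
block_lookup <- function(spec) {
  out <- lapply(seq_len(nrow(spec$blocks)), function(i) lapply(spec$blocks, `[`, i))
  names(out) <- paste(spec$blocks$name, spec$blocks$hemisphere, sep = "|")
  out
}

phantom_label_id <- function(spec, name, hemisphere) {
  phantom_block(spec, name, hemisphere)$id
}

# world coordinate of a voxel center
phantom_voxel_center <- function(spec, ijk) {
  drop(voxel_to_world(matrix(ijk, ncol = 3), spec$affine))
}

# random voxel center inside a block (uniform over voxels), world mm
rand_block_center <- function(spec, block, margin = 0L) {
  i <- sample(seq(block$i0 + margin, block$i1 - margin), 1L)
  j <- sample(seq(block$j0 + margin, block$j1 - margin), 1L)
  k <- sample(seq(block$k0 + margin, block$k1 - margin), 1L)
  phantom_voxel_center(spec, c(i, j, k))
}

#' Default tract designs for the phantom
#'
#' Two ventral association bundles are emulated per hemisphere. The
#' IFOF-like tract runs from the frontal anterior face through a compact
#' waist (stem) on a single coronal slice of the DWM core to the posterior
#' occipito-temporo-parietal face. The UF-like tract hooks from the
#' orbito-frontal cortex down through a waist on a single axial slice and
#' back up to the temporal pole and superior temporal region. Termination
#' probability vectors (per hemisphere and end) carry designed asymmetries:
#' the IFOF's middle occipital terminations are right-lateralized
#' (0.30 vs 0.10, asymmetry index +0.5) and its lingual terminations
#' left-lateralized; the UF's temporal-pole terminations are mildly
#' right-lateralized. The precentral gyrus receives a 0.01 false-positive
#' termination rate for the IFOF (its designated FP region); the superior
#' parietal gyrus receives none for the UF.
#'
#' @param spec A [phantom_spec()].
#' @param n_per_hemisphere Streamlines per tract per hemisphere.
#' @return Named list of tract designs.
#' @export
default_tracts <- function(spec = phantom_spec(), n_per_hemisphere = 300L) {
  stem_vox <- function(ijk_right) {
    list(right = phantom_voxel_center(spec, ijk_right),
         left = phantom_voxel_center(
           spec, c(spec$grid_shape[1] - 1L - ijk_right[1], ijk_right[2], ijk_right[3])))
  }
  probs <- function(...) {
    p <- tibble::tribble(...)
    names(p) <- c("hemisphere", "side", "region", "prob")
    p
  }
  list(
    IFOF = list(
      name = "IFOF", orientation = "coronal",
      n_per_hemisphere = as.integer(n_per_hemisphere),
      stem_center = stem_vox(c(43L, 36L, 30L)),
      fp_region = "PRC",
      probs = probs(
        ~h, ~side, ~region, ~prob,
        "left",  "anterior",  "IFG", 0.45,
        "left",  "anterior",  "ORB", 0.25,
        "left",  "anterior",  "MFG", 0.15,
        "left",  "anterior",  "SFG", 0.14,
        "left",  "anterior",  "PRC", 0.01,
        "right", "anterior",  "IFG", 0.45,
        "right", "anterior",  "ORB", 0.25,
        "right", "anterior",  "MFG", 0.15,
        "right", "anterior",  "SFG", 0.14,
        "right", "anterior",  "PRC", 0.01,
        "left",  "posterior", "MOG", 0.10,
        "left",  "posterior", "LG",  0.40,
        "left",  "posterior", "STG", 0.30,
        "left",  "posterior", "SPG", 0.20,
        "right", "posterior", "MOG", 0.30,
        "right", "posterior", "LG",  0.20,
        "right", "posterior", "STG", 0.30,
        "right", "posterior", "SPG", 0.20)),
    UF = list(
      name = "UF", orientation = "axial",
      n_per_hemisphere = as.integer(n_per_hemisphere),
      stem_center = stem_vox(c(43L, 50L, 20L)),
      fp_region = "SPG",
      probs = probs(
        ~h, ~side, ~region, ~prob,
        "left",  "anterior",  "ORB", 0.60,
        "left",  "anterior",  "IFG", 0.25,
        "left",  "anterior",  "MFG", 0.15,
        "right", "anterior",  "ORB", 0.60,
        "right", "anterior",  "IFG", 0.25,
        "right", "anterior",  "MFG", 0.15,
        "left",  "posterior", "TPO", 0.50,
        "left",  "posterior", "STG", 0.50,
        "right", "posterior", "TPO", 0.60,
        "right", "posterior", "STG", 0.40))
  )
}

#' Cohort specification for the phantom simulator
#'
#' Fixes the study conditions for a simulated cohort: subject count, tract
#' designs with per-hemisphere termination probability vectors, the fraction
#' of prematurely stopping ("broken") streamlines, decoy streamline counts
#' per class, and the streamline step length. Per-subject seeds derive
#' deterministically from `seed`.
#'
#' @param spec A [phantom_spec()].
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer RNG seed for the cohort.
#' @param tracts Tract designs, see [default_tracts()].
#' @param broken_fraction Fraction of tract streamlines truncated at one
#'   (uniformly chosen) end inside deep white matter, in `[0, 1]`.
#' @param decoys Named integer vector of per-subject decoy counts with names
#'   `short`, `gm_confined`, `u_fiber`, `cerebellar`, `interhemispheric`,
#'   `stem_bypass` (counts are split across hemispheres except
#'   `interhemispheric`).
#' @param step_mm Streamline point spacing in mm.
#' @param stem_jitter_mm Per-axis uniform jitter applied to the stem
#'   waypoint; must stay below half a voxel so all tract streamlines pass
#'   the stem's central voxel.
#' @param sex Optional character vector of subject sex labels (`"F"`/`"M"`);
#'   default alternates.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(spec = phantom_spec(), n_subjects = 30L, seed = 42L,
                        tracts = default_tracts(spec),
                        broken_fraction = 0.2,
                        decoys = c(short = 50L, gm_confined = 40L, u_fiber = 30L,
                                   cerebellar = 20L, interhemispheric = 10L,
                                   stem_bypass = 100L),
                        step_mm = 1, stem_jitter_mm = 0.4, sex = NULL) {
  stopifnot(n_subjects >= 1L, broken_fraction >= 0, broken_fraction <= 1,
            step_mm > 0, stem_jitter_mm >= 0,
            stem_jitter_mm < min(spec$voxel_size) / 2)
  full <- c(short = 0L, gm_confined = 0L, u_fiber = 0L, cerebellar = 0L,
            interhemispheric = 0L, stem_bypass = 0L)
  stopifnot(all(names(decoys) %in% names(full)))
  full[names(decoys)] <- as.integer(decoys)
  for (tr in tracts) {
    sums <- tapply(tr$probs$prob, interaction(tr$probs$hemisphere, tr$probs$side),
                   sum)
    if (any(abs(sums - 1) > 1e-8)) {
      stop("termination probabilities must sum to 1 per hemisphere and side (",
           tr$name, ")")
    }
  }
  if (is.null(sex)) sex <- rep(c("F", "M"), length.out = n_subjects)
  structure(
    list(spec = spec, n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         tracts = tracts, broken_fraction = broken_fraction, decoys = full,
         step_mm = step_mm, stem_jitter_mm = stem_jitter_mm,
         sex = rep(sex, length.out = n_subjects)),
    class = "cohort_spec")
}

subject_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(subject_index) * 7919) %%
               2147483647)
}

#' Simulate one subject's tractogram with ground truth
#'
#' Tract streamlines are piecewise-linear polylines from a random voxel
#' center of a sampled anterior-set CGM region, through the tract's stem
#' center (plus bounded jitter), to a random voxel center of a sampled
#' posterior-set CGM region, resampled at `step_mm`. A `broken_fraction` of
#' them is truncated at a uniformly chosen interior DWM point on one
#' (uniformly chosen) end, keeping the stem passage. Decoy streamlines are
#' realized per class: U-fibers connect adjacent gyri through SWM without
#' entering DWM; GM-confined fragments stay inside one CGM block; shorts
#' are sub-10-mm DWM fragments; interhemispheric streamlines cross x = 0;
#' cerebellar streamlines descend into the cerebellum/brainstem block; and
#' stem-bypass streamlines cross the stem's slice far from the stem voxels
#' (the claustro-cortical decoy).
#'
#' @param atlas Phantom atlas from [build_phantom_atlas()].
#' @param cohort A [cohort_spec()].
#' @param subject_index Subject number (1-based).
#' @return `list(tractogram = , ground_truth = )`; the ground truth is a
#'   tibble with one row per streamline (`id`, `true_class`, `tract`,
#'   `hemisphere`, `anterior_label`, `posterior_label`, `broken_end`).
#' @export
simulate_subject <- function(atlas, cohort, subject_index) {
  spec <- atlas$phantom
  if (is.null(spec)) stop("atlas must come from build_phantom_atlas()")
  set.seed(subject_seed(cohort$seed, subject_index))
  n_total <- sum(vapply(cohort$tracts, function(tr) 2L * tr$n_per_hemisphere,
                        integer(1))) + sum(cohort$decoys)
  streamlines <- vector("list", n_total)
  gt_class <- character(n_total); gt_tract <- character(n_total)
  gt_hemi <- character(n_total); gt_ant <- integer(n_total)
  gt_post <- integer(n_total); gt_bend <- character(n_total)
  n_pushed <- 0L
  push <- function(pts, true_class, tract, hemisphere, ant, post, broken_end) {
    n_pushed <<- n_pushed + 1L
    streamlines[[n_pushed]] <<- pts
    gt_class[n_pushed] <<- true_class; gt_tract[n_pushed] <<- tract
    gt_hemi[n_pushed] <<- hemisphere; gt_ant[n_pushed] <<- as.integer(ant)
    gt_post[n_pushed] <<- as.integer(post); gt_bend[n_pushed] <<- broken_end
  }
  tissue_by_id <- stats::setNames(spec$table$tissue, spec$table$id)
  blocks <- block_lookup(spec)

  for (tr in cohort$tracts) {
    for (h in c("left", "right")) {
      p <- tr$probs[tr$probs$hemisphere == h, ]
      pa <- p[p$side == "anterior", ]
      pp <- p[p$side == "posterior", ]
      n <- tr$n_per_hemisphere
      ant_regions <- sample(pa$region, n, replace = TRUE, prob = pa$prob)
      post_regions <- sample(pp$region, n, replace = TRUE, prob = pp$prob)
      broken <- stats::runif(n) < cohort$broken_fraction
      broken_end <- ifelse(broken,
                           ifelse(stats::runif(n) < 0.5, "anterior", "posterior"),
                           "none")
      for (s in seq_len(n)) {
        a_blk <- blocks[[paste(ant_regions[s], h, sep = "|")]]
        p_blk <- blocks[[paste(post_regions[s], h, sep = "|")]]
        A <- rand_block_center(spec, a_blk)
        B <- rand_block_center(spec, p_blk)
        S <- tr$stem_center[[h]] +
          stats::runif(3, -cohort$stem_jitter_mm, cohort$stem_jitter_mm)
        leg1 <- resample_polyline(rbind(A, S), cohort$step_mm)
        leg2 <- resample_polyline(rbind(S, B), cohort$step_mm)
        pts <- rbind(leg1, leg2[-1L, , drop = FALSE])
        s_idx <- nrow(leg1)
        ant_id <- a_blk$id
        post_id <- p_blk$id
        cls <- "tract_whole"
        if (broken_end[s] != "none") {
          tis <- tissue_by_id[as.character(label_at_point(atlas, pts))]
          tis[is.na(tis)] <- "other"
          if (broken_end[s] == "posterior") {
            cand <- which(tis == "DWM")
            cand <- cand[cand > s_idx & cand < nrow(pts)]
            if (length(cand) > 0) {
              pts <- pts[seq_len(sample_one(cand)), , drop = FALSE]
              post_id <- 0L; cls <- "tract_broken"
            } else broken_end[s] <- "none"
          } else {
            cand <- which(tis == "DWM")
            cand <- cand[cand > 1L & cand < s_idx]
            if (length(cand) > 0) {
              pts <- pts[sample_one(cand):nrow(pts), , drop = FALSE]
              ant_id <- 0L; cls <- "tract_broken"
            } else broken_end[s] <- "none"
          }
        }
        push(pts, cls, tr$name, h, ant_id, post_id, broken_end[s])
      }
    }
  }

  dec <- cohort$decoys
  split_lr <- function(n) c(left = n %/% 2L + n %% 2L, right = n %/% 2L)
  step <- cohort$step_mm
  vx <- function(ijk) phantom_voxel_center(spec, ijk)
  mid <- function(b) c(round((b$i0 + b$i1) / 2), round((b$j0 + b$j1) / 2),
                       round((b$k0 + b$k1) / 2))

  for (h in c("left", "right")) {
    nh <- split_lr(dec[["short"]])[[h]]
    dwm <- phantom_block(spec, "DWM", h)
    for (s in seq_len(nh)) {
      P <- vx(c(sample(dwm$i0:dwm$i1, 1), sample((dwm$j0 + 4):(dwm$j1 - 4), 1),
                sample(dwm$k0:dwm$k1, 1)))
      pts <- rbind(P, P + c(0, 3, 0), P + c(0, 6, 0))
      push(resample_polyline(pts, step), "short", "none", h, 0L, 0L, "none")
    }
    nh <- split_lr(dec[["gm_confined"]])[[h]]
    sfg <- phantom_block(spec, "SFG", h)
    for (s in seq_len(nh)) {
      j <- sample((sfg$j0 + 1):(sfg$j1 - 1), 1); k <- sample(sfg$k0:sfg$k1, 1)
      pts <- rbind(vx(c(sfg$i0 + 1L, j, k)), vx(c(sfg$i1 - 1L, j, k)))
      push(resample_polyline(pts, step), "gm_confined", "none", h,
           sfg$id, sfg$id, "none")
    }
    nh <- split_lr(dec[["u_fiber"]])[[h]]
    ifg <- phantom_block(spec, "IFG", h); mfg <- phantom_block(spec, "MFG", h)
    swm_j <- round((phantom_block(spec, "SWM_IFG", h)$j0 +
                      phantom_block(spec, "SWM_IFG", h)$j1) / 2)
    for (s in seq_len(nh)) {
      i <- sample((ifg$i0 + 1):(ifg$i1 - 1), 1)
      cj <- ifg$j0 + 1L
      k1 <- round((ifg$k0 + ifg$k1) / 2); k2 <- round((mfg$k0 + mfg$k1) / 2)
      pts <- rbind(vx(c(i, cj, k1)), vx(c(i, swm_j, k1)),
                   vx(c(i, swm_j, k2)), vx(c(i, cj, k2)))
      push(resample_polyline(pts, step), "u_fiber", "none", h,
           ifg$id, mfg$id, "none")
    }
    nh <- split_lr(dec[["cerebellar"]])[[h]]
    cer <- phantom_block(spec, "CER", "midline")
    for (s in seq_len(nh)) {
      m <- mid(dwm)
      start <- c(m[1], 20L + sample(-2:2, 1), dwm$k0 + 2L)
      end_i <- if (h == "right") cer$i1 - 1L else cer$i0 + 1L
      end <- c(end_i, start[2], round((cer$k0 + cer$k1) / 2))
      push(resample_polyline(rbind(vx(start), vx(end)), step),
           "cerebellar", "none", h, 0L, 0L, "none")
    }
    nh <- split_lr(dec[["stem_bypass"]])[[h]]
    sfg <- phantom_block(spec, "SFG", h); spg <- phantom_block(spec, "SPG", h)
    w_ijk <- c(mid(dwm)[1], 36L, dwm$k1 - 2L)
    for (s in seq_len(nh)) {
      A <- rand_block_center(spec, sfg)
      B <- rand_block_center(spec, spg)
      W <- vx(w_ijk) + stats::runif(3, -0.4, 0.4)
      leg1 <- resample_polyline(rbind(A, W), step)
      leg2 <- resample_polyline(rbind(W, B), step)
      push(rbind(leg1, leg2[-1L, , drop = FALSE]), "stem_bypass", "none", h,
           sfg$id, spg$id, "none")
    }
  }
  n_ih <- dec[["interhemispheric"]]
  if (n_ih > 0) {
    dl <- phantom_block(spec, "DWM", "left"); dr <- phantom_block(spec, "DWM", "right")
    for (s in seq_len(n_ih)) {
      j <- 45L + sample(-2:2, 1); k <- 30L + sample(-2:2, 1)
      pts <- rbind(vx(c(mid(dl)[1], j, k)), vx(c(mid(dr)[1], j, k)))
      push(resample_polyline(pts, step), "interhemispheric", "none", "midline",
           0L, 0L, "none")
    }
  }

  stopifnot(n_pushed == n_total)
  gt <- tibble::tibble(
    id = seq_len(n_total), true_class = gt_class, tract = gt_tract,
    hemisphere = gt_hemi, anterior_label = gt_ant, posterior_label = gt_post,
    broken_end = gt_bend)
  list(tractogram = tractogram(streamlines, voxel_size = spec$voxel_size,
                               affine = spec$affine, space_tag = "phantom"),
       ground_truth = gt)
}

# sample() with the length-1 surprise removed
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Simulate a whole cohort
#'
#' @param atlas Phantom atlas from [build_phantom_atlas()].
#' @param cohort A [cohort_spec()].
#' @return `list(subjects = , subject_table = )`: `subjects` is a list of
#'   [simulate_subject()] results; the subject table carries `subject`,
#'   `sex` and the derived per-subject seed.
#' @export
simulate_cohort <- function(atlas, cohort) {
  subjects <- lapply(seq_len(cohort$n_subjects),
                     function(i) simulate_subject(atlas, cohort, i))
  tbl <- tibble::tibble(
    subject = seq_len(cohort$n_subjects),
    sex = cohort$sex,
    seed = vapply(seq_len(cohort$n_subjects),
                  function(i) subject_seed(cohort$seed, i), integer(1)))
  list(subjects = subjects, subject_table = tbl)
}

#' Count-level cohort simulation of termination tallies
#'
#' Draws per-subject termination tallies directly from the generative model
#' the geometric simulator realizes: per hemisphere, `n` tract streamlines
#' of which `Binomial(n, broken_fraction)` are broken at one uniformly
#' chosen end; surviving endpoints fall on regions by independent
#' multinomial draws from the designed termination probability vectors.
#' Exactly the distribution of tallies produced by running
#' [simulate_subject()] through the dissection pipeline, without the
#' geometry — used for replicate-heavy power and type-I-error studies.
#'
#' @param cohort A [cohort_spec()].
#' @param tract Tract name to simulate (default first tract).
#' @param seed Optional override of the cohort seed.
#' @return List of `termination_tally` objects, one per subject.
#' @export
simulate_termination_tables <- function(cohort, tract = NULL, seed = NULL) {
  tr <- if (is.null(tract)) cohort$tracts[[1]] else cohort$tracts[[tract]]
  if (is.null(tr)) stop("unknown tract: ", tract)
  if (!is.null(seed)) set.seed(as.integer(seed)) else set.seed(cohort$seed)
  n <- tr$n_per_hemisphere
  bf <- cohort$broken_fraction
  table <- cohort$spec$table
  lapply(seq_len(cohort$n_subjects), function(i) {
    counts <- list(); broken <- c(anterior = 0L, posterior = 0L)
    for (h in c("left", "right")) {
      n_broken <- stats::rbinom(1, n, bf)
      b_ant <- stats::rbinom(1, n_broken, 0.5)
      b_post <- n_broken - b_ant
      broken <- broken + c(anterior = b_ant, posterior = b_post)
      for (side in c("anterior", "posterior")) {
        p <- tr$probs[tr$probs$hemisphere == h & tr$probs$side == side, ]
        n_eff <- n - if (side == "anterior") b_ant else b_post
        draw <- as.integer(stats::rmultinom(1, n_eff, p$prob))
        counts[[length(counts) + 1L]] <- tibble::tibble(
          region = p$region, hemisphere = h, side = side, count = draw)
      }
    }
    new_termination_tally(
      counts = dplyr::bind_rows(counts),
      total_streamlines = 2L * n,
      broken = broken,
      excluded = tibble::tibble(region = character(), hemisphere = character(),
                                side = character(), count = integer()))
  })
}

#' Summary-level stem morphometry simulator
#'
#' Generates per-subject stem summaries (volume and center of mass per
#' tract, hemisphere and operator) from a simple additive model: volume =
#' tract baseline x hemisphere scale + subject effect + noise; the second
#' operator re-draws each stem with iid Gaussian center-of-mass jitter and
#' small volume disagreement. Baselines default to the published mean stem
#' coordinates (see [stem_reference_coordinates()]). Used for
#' inter-operator reliability and stem-volume ANOVA studies where the
#' quantity of interest is the morphometric summary, not the mask geometry.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param right_scale Multiplicative right-hemisphere volume effect.
#' @param subject_sd,noise_sd Volume variance components (mm^3).
#' @param operator_com_sd Per-axis SD (mm) of operator-2 COM jitter.
#' @param operator_vol_sd SD (mm^3) of operator-2 volume disagreement.
#' @return Tibble with columns `subject`, `sex`, `operator`, `tract`,
#'   `hemisphere`, `volume_mm3`, `com_x`, `com_y`, `com_z`.
#' @export
simulate_stem_summaries <- function(n_subjects = 30L, seed = 42L,
                                    right_scale = 1.2, subject_sd = 8,
                                    noise_sd = 10, operator_com_sd = 1,
                                    operator_vol_sd = 4) {
  set.seed(as.integer(seed))
  ref <- stem_reference_coordinates()
  ref <- ref[ref$operator == "GP", ]
  rows <- list()
  sexes <- rep(c("F", "M"), length.out = n_subjects)
  for (s in seq_len(n_subjects)) {
    subj_eff <- stats::rnorm(1, 0, subject_sd)
    for (r in seq_len(nrow(ref))) {
      base_vol <- mean(ref$volume[ref$tract == ref$tract[r]])
      scale <- if (ref$hemisphere[r] == "right") right_scale else 1
      vol1 <- max(8, base_vol * scale + subj_eff + stats::rnorm(1, 0, noise_sd))
      com1 <- c(ref$x[r], ref$y[r], ref$z[r]) + stats::rnorm(3, 0, 1.5)
      com2 <- com1 + stats::rnorm(3, 0, operator_com_sd)
      vol2 <- max(8, vol1 + stats::rnorm(1, 0, operator_vol_sd))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = s, sex = sexes[s],
        operator = c("op1", "op2"),
        tract = ref$tract[r], hemisphere = ref$hemisphere[r],
        volume_mm3 = c(vol1, vol2),
        com_x = c(com1[1], com2[1]), com_y = c(com1[2], com2[2]),
        com_z = c(com1[3], com2[3]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Published mean stem coordinates and volumes
#'
#' Mean stem volumes (mm^3) and mean stem center-of-mass coordinates (MNI
#' mm) for the IFOF and UF in each hemisphere as delineated by two
#' operators in a 60-subject cohort; used as morphometric baselines and for
#' consistency arithmetic on the inter-stem contrasts.
#'
#' @return Tibble with `tract`, `hemisphere`, `operator`, `volume`, `x`,
#'   `y`, `z`.
#' @export
stem_reference_coordinates <- function() {
  tibble::tribble(
    ~tract, ~hemisphere, ~operator, ~volume, ~x, ~y, ~z,
    "IFOF", "left",  "GP",  82.5, -30.6,  0.5,  -8.0,
    "IFOF", "left",  "JH",  88.7, -31.0, -1.0,  -9.0,
    "IFOF", "right", "GP", 100.3,  31.7,  0.6,  -7.4,
    "IFOF", "right", "JH",  91.2,  31.1, -0.1,  -8.6,
    "UF",   "left",  "GP",  74.0, -33.3, -2.4, -16.2,
    "UF",   "left",  "JH",  66.7, -33.8, -2.7, -16.8,
    "UF",   "right", "GP",  93.9,  33.6, -1.2, -17.2,
    "UF",   "right", "JH",  86.1,  33.1, -1.7, -17.6)
}
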