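# world center of phantom voxel (i, j, k)
vc <- function(i, j, k) {
  drop(fixture_atlas()$affine %*% c(i, j, k, 1))[1:3]
}

test_that("preparation removes each designed class and attributes by first matching rule", {
  atlas <- fixture_atlas()
  dil <- fixture_dilated()
  sl <- list(
    short    = segment_streamline(vc(43, 30, 30), vc(43, 32, 30), 3),  # 4 mm, DWM
    gm_conf  = segment_streamline(vc(40, 63, 26), vc(46, 67, 30), 12), # inside IFG
    u_fiber  = rbind(segment_streamline(vc(43, 65, 26), vc(43, 61, 28), 6),
                     segment_streamline(vc(43, 61, 28), vc(43, 65, 30), 6)[-1, ]),
    cerebell = segment_streamline(vc(43, 20, 20), vc(32, 20, 5), 20),
    crosser  = segment_streamline(vc(40, 30, 30), vc(19, 30, 30), 25),
    keepable = segment_streamline(vc(43, 65, 28), vc(43, 36, 30), 20),
    # precedence probes: short wins over cerebellar; cerebellar wins over
    # interhemispheric (this one lies inside CER *and* crosses x = 0)
    short_cer = segment_streamline(vc(30, 20, 5), vc(31, 20, 5), 3),   # 2 mm
    cer_cross = segment_streamline(vc(27, 20, 5), vc(33, 20, 5), 8)    # 12 mm
  )
  tg <- tractogram(unname(sl), voxel_size = c(2, 2, 2), affine = atlas$affine)
  prep <- prepare_tractogram(tg, atlas, dil)
  expect_equal(prep$tally$n_removed, c(2, 1, 1, 2, 1))
  expect_identical(prep$kept, 6L)   # only "keepable" survives

  cl <- prep$classification
  expect_identical(cl$tissues[[which(names(sl) == "gm_conf")]], "CGM")
  expect_identical(cl$tissues[[which(names(sl) == "u_fiber")]], c("CGM", "SWM"))
  expect_true(cl$enters_cerebellum_brainstem[[which(names(sl) == "cerebell")]])
  expect_true(cl$crosses_midsagittal[[which(names(sl) == "crosser")]])
  expect_true(cl$crosses_midsagittal[[which(names(sl) == "cer_cross")]])
  expect_equal(cl$length_mm[[1]], 4, tolerance = 1e-9)
})

test_that("endpoint labels use the dilated volume (sub-voxel overshoot tolerated)", {
  atlas <- fixture_atlas()
  dil <- fixture_dilated()
  # endpoint one voxel beyond the anterior IFG face (background on the
  # undilated atlas) still resolves to IFG after one modal dilation
  p_out <- vc(43, 68, 28)
  expect_identical(label_at_point(atlas, rbind(p_out)), 0L)
  ifg_id <- atlas$table$id[atlas$table$name == "IFG" &
                             atlas$table$hemisphere == "right"]
  expect_identical(label_at_point(dil, rbind(p_out)), ifg_id)
  cl <- classify_streamline(segment_streamline(p_out, vc(43, 36, 30), 20),
                            atlas, dil)
  expect_identical(cl$end1_label, ifg_id)
})

test_that("expose_stem removes tract-specific obscuring enders", {
  atlas <- fixture_atlas()
  dil <- fixture_dilated()
  sl <- list(
    ins_ender = segment_streamline(vc(51, 35, 29), vc(43, 35, 29), 10),
    tpo_ender = segment_streamline(vc(43, 65, 16), vc(43, 40, 16), 15),
    stg_ender = segment_streamline(vc(43, 6, 28), vc(43, 30, 28), 15),
    plain     = segment_streamline(vc(43, 65, 28), vc(43, 36, 30), 20))
  tg <- tractogram(unname(sl), voxel_size = c(2, 2, 2), affine = atlas$affine)
  prep <- prepare_tractogram(tg, atlas, dil)
  expect_identical(prep$kept, 1:4)   # all survive preparation
  ifof <- expose_stem(prep$tractogram, dil, "IFOF")
  uf <- expose_stem(prep$tractogram, dil, "UF")
  # IFOF exposure drops insula and temporal-pole enders
  expect_length(ifof$streamlines, 2)
  expect_identical(ifof$streamlines, prep$tractogram$streamlines[3:4])
  # UF exposure drops insula and superior-temporal enders
  expect_length(uf$streamlines, 2)
  expect_identical(uf$streamlines, prep$tractogram$streamlines[c(2, 4)])
  # explicit label override wins over the named defaults
  none <- expose_stem(prep$tractogram, dil, "IFOF", exclusion_labels = integer())
  expect_length(none$streamlines, 4)
})

test_that("suggest_stem_slice picks the narrowest crossed slice, lowest on ties", {
  atlas <- fixture_atlas()
  sl <- list(
    segment_streamline(vc(40, 20, 30), vc(40, 24, 30), 12),
    segment_streamline(vc(41, 20, 30), vc(41, 24, 30), 12),
    # a bulge confined to slice 22 widens it without touching 21 or 23
    segment_streamline(vc(43, 22, 30), vc(46, 22, 30), 10))
  tg <- tractogram(sl, voxel_size = c(2, 2, 2), affine = atlas$affine)
  sug <- suggest_stem_slice(tg, atlas, orientation = "coronal",
                            search_range = 21:23)
  # widths (2, >2, 2): tie between 21 and 23 resolves to the lower slice
  expect_identical(sug$slice_index, 21L)
  w <- sug$profile$width
  expect_identical(w[1], w[3])
  expect_gt(w[2], w[1])
  expect_identical(nrow(sug$mask$voxels), w[1])

  # slices never crossed are ignored, not treated as zero-width minima
  sug2 <- suggest_stem_slice(tg, atlas, orientation = "coronal",
                             search_range = 15:20)
  expect_identical(sug2$slice_index, 20L)
  expect_true(all(sug2$profile$width[sug2$profile$slice < 20] == 0))
  expect_error(suggest_stem_slice(tg, atlas, orientation = "coronal",
                                  search_range = 0:5), "crosses")
})

test_that("stem ROIs are single-slice, survive NIfTI round-trip and summarize correctly", {
  atlas <- fixture_atlas()
  vox <- rbind(c(42L, 36L, 29L), c(43L, 36L, 30L), c(44L, 36L, 31L))
  stem <- stem_roi(vox, grid_dim = dim(atlas$grid), affine = atlas$affine,
                   orientation = "coronal", tract_tag = "IFOF",
                   hemisphere = "right", operator = "op1")
  expect_identical(stem$slice_index, 36L)
  expect_error(stem_roi(rbind(c(42, 36, 29), c(42, 37, 29)),
                        grid_dim = dim(atlas$grid), affine = atlas$affine,
                        orientation = "coronal"), "single")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_stem_roi(stem, path)
  back <- read_stem_roi(path, orientation = "coronal", tract_tag = "IFOF",
                        hemisphere = "right", operator = "op1")
  expect_identical(back$voxels[order(back$voxels[, 1]), ], vox)
  s <- stem_summary(back)
  expect_identical(s$n_voxels, 3L)
  expect_equal(s$volume_mm3, 3 * 8)
  expect_equal(c(s$com_x, s$com_y, s$com_z), vc(43, 36, 30), tolerance = 1e-6)
})

test_that("extract_tract applies stem intersection, exclusion rules and broken bookkeeping", {
  atlas <- fixture_atlas()
  dil <- fixture_dilated()
  stem <- phantom_stem_roi(atlas, default_tracts(fixture_spec())$IFOF, "right")
  stem_pt <- vc(43, 36, 30)
  tpo_id <- atlas$table$id[atlas$table$name == "TPO" &
                             atlas$table$hemisphere == "right"]
  sl <- list(
    kept     = rbind(segment_streamline(vc(43, 65, 28), stem_pt, 15),
                     segment_streamline(stem_pt, vc(43, 6, 28), 15)[-1, ]),
    by_label = rbind(segment_streamline(vc(43, 65, 16), stem_pt, 15),
                     segment_streamline(stem_pt, vc(43, 6, 28), 15)[-1, ]),
    by_plane = rbind(segment_streamline(vc(43, 65, 28), stem_pt, 15),
                     segment_streamline(stem_pt, vc(43, 20, 5), 15)[-1, ]),
    both     = rbind(segment_streamline(vc(43, 65, 16), stem_pt, 15),
                     segment_streamline(stem_pt, vc(43, 20, 5), 15)[-1, ]),
    broken   = rbind(segment_streamline(vc(43, 65, 28), stem_pt, 15),
                     segment_streamline(stem_pt, vc(43, 20, 35), 10)[-1, ]),
    ins_end  = rbind(segment_streamline(vc(43, 65, 28), stem_pt, 15),
                     segment_streamline(stem_pt, vc(51, 35, 30), 10)[-1, ]),
    miss     = segment_streamline(vc(40, 65, 28), vc(40, 50, 28), 10))
  tg <- tractogram(unname(sl), voxel_size = c(2, 2, 2), affine = atlas$affine)
  rules <- extraction_rules(
    exclusion_labels = tpo_id,
    exclusion_plane = list(axis = "z", coordinate = -40, side = "inferior"))
  ex <- extract_tract(tg, stem, rules, atlas, dil)
  tally <- setNames(ex$tally$n, ex$tally$outcome)
  # "both" touches the exclusion label AND crosses the plane: label attributes
  expect_equal(tally[["excluded_by_label"]], 2)
  expect_equal(tally[["excluded_by_plane"]], 1)
  expect_equal(tally[["kept"]], 3)
  expect_equal(tally[["broken"]], 1)
  expect_setequal(ex$endpoints$id, c(1L, 5L, 6L))
  ep <- ex$endpoints[order(ex$endpoints$id), ]
  expect_true(ep$broken_1[2] | ep$broken_2[2])        # streamline 5
  expect_true(ep$excluded_1[3] | ep$excluded_2[3])    # insula ender
  # broken streamlines can be discarded instead
  strict <- extraction_rules(exclusion_labels = tpo_id, discard_broken = TRUE)
  ex2 <- extract_tract(tg, stem, strict, atlas, dil)
  expect_false(5L %in% ex2$endpoints$id)

  # plane-side anatomical synonyms resolve to half-space comparisons
  expect_identical(
    extraction_rules(exclusion_plane = list(axis = "y", coordinate = 0,
                                            side = "posterior"))$exclusion_plane$side,
    "less")
  expect_identical(
    extraction_rules(exclusion_plane = list(axis = "x", coordinate = 0,
                                            side = "right"))$exclusion_plane$side,
    "greater")
  expect_error(extraction_rules(exclusion_plane = list(axis = "y",
                                                       coordinate = 0,
                                                       side = "behind")),
               "side")
})
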