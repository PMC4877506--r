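test_that("TRK and TCK round-trips preserve geometry, metadata and order", {
  set.seed(101)
  aff <- test_affine()
  sl <- lapply(2:7, function(n) matrix(rnorm(3 * n, sd = 15), ncol = 3))
  tg <- tractogram(sl, voxel_size = c(2, 2, 2), affine = aff)
  for (fmt in c("trk", "tck")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_tractogram(tg, path)
    back <- read_tractogram(path)                     # auto-detected format
    expect_equal(length(back), length(tg))
    expect_equal(streamline_lengths(back), streamline_lengths(tg),
                 tolerance = 1e-4)
    expect_lt(max_point_error(back$streamlines, tg$streamlines), 1e-3)
    explicit <- read_tractogram(path, format = fmt)
    expect_identical(explicit$streamlines, back$streamlines)
  }
  expect_equal(read_tractogram(
    write_tractogram(tg, withr::local_tempfile(fileext = ".trk")))$affine,
    aff, tolerance = 1e-5)
  expect_error(read_tractogram(withr::local_tempfile(fileext = ".xyz")),
               "format")
})

test_that("read_trk decodes an independently written byte-level TRK file", {
  set.seed(7)
  aff <- test_affine(voxel = c(1.5, 2, 2.5), origin = c(-40, -50, -25))
  sl <- lapply(1:4, function(i) matrix(rnorm(3 * (i + 1), sd = 10), ncol = 3))
  path <- withr::local_tempfile(fileext = ".trk")
  oracle_write_trk(path, sl, voxel_size = c(1.5, 2, 2.5), affine = aff)
  back <- read_tractogram(path)
  expect_equal(length(back), 4L)
  expect_equal(back$affine, aff, tolerance = 1e-5)
  expect_equal(back$voxel_size, c(1.5, 2, 2.5), tolerance = 1e-6)
  expect_lt(max_point_error(back$streamlines, sl), 1e-3)
})

test_that("tractogram constructor validates streamlines", {
  aff <- test_affine()
  ok <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 3, byrow = TRUE)
  expect_silent(tractogram(list(ok), voxel_size = c(2, 2, 2), affine = aff))
  expect_error(tractogram(list(ok[1, , drop = FALSE]), c(2, 2, 2), aff),
               ">= 2 points")
  bad_na <- ok; bad_na[2, 1] <- NA
  expect_error(tractogram(list(bad_na), c(2, 2, 2), aff), "finite")
  dup <- rbind(ok, ok[2, ])
  expect_error(tractogram(list(dup), c(2, 2, 2), aff), "distinct")
})

test_that("streamline length and resampling match closed forms", {
  # radius-10 semicircle sampled at 100 points has length ~ 10*pi
  theta <- seq(0, pi, length.out = 100)
  semi <- cbind(10 * cos(theta), 10 * sin(theta), 0)
  expect_equal(streamline_length(semi), 10 * pi, tolerance = 0.005)

  # resampling keeps endpoints and vertices, and never exceeds the step
  s <- matrix(c(0, 0, 0, 9, 0, 0, 9, 4, 0), ncol = 3, byrow = TRUE)
  r <- stemdissect:::resample_polyline(s, step = 1)
  gaps <- sqrt(rowSums(diff(r)^2))
  expect_true(all(gaps <= 1 + 1e-9))
  expect_equal(r[1, ], s[1, ])
  expect_equal(r[nrow(r), ], s[3, ])
  expect_true(any(apply(r, 1, function(p) all(p == s[2, ]))))
  expect_equal(sum(gaps), streamline_length(s))
})

test_that("label tables round-trip and invalid tables are rejected", {
  tbl <- fixture_atlas()$table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_label_table(tbl, path)
  back <- read_label_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))

  dup <- tbl; dup$id[2] <- dup$id[1]
  expect_error(label_volume(fixture_atlas()$grid, fixture_atlas()$affine, dup),
               "unique")
  bad_tissue <- tbl; bad_tissue$tissue[1] <- "bone"
  expect_error(label_volume(fixture_atlas()$grid, fixture_atlas()$affine,
                            bad_tissue), "tissue")
  no_side <- tbl
  no_side$terminal_side[no_side$tissue == "CGM"][1] <- "none"
  expect_error(label_volume(fixture_atlas()$grid, fixture_atlas()$affine,
                            no_side), "terminal_side")
})

test_that("label_at_point implements nearest-voxel ownership", {
  atlas <- fixture_atlas()
  set.seed(33)
  pts <- cbind(runif(300, -70, 70), runif(300, -80, 80), runif(300, -70, 70))
  got <- label_at_point(atlas, pts)
  want <- vapply(seq_len(nrow(pts)),
                 function(i) as.integer(oracle_label_at(atlas, pts[i, ])),
                 integer(1))
  expect_identical(got, want)

  # half-voxel ownership boundary: [center - 1, center + 1) for 2 mm voxels,
  # probed across the DWM (j = 59) / SWM (j = 60) label change
  center <- drop(atlas$affine %*% c(43, 60, 28, 1))[1:3]
  inside_low <- center - c(0, 1, 0)         # boundary point belongs upward
  just_below <- center - c(0, 1 + 1e-6, 0)
  expect_identical(label_at_point(atlas, rbind(inside_low)),
                   label_at_point(atlas, rbind(center)))
  expect_false(label_at_point(atlas, rbind(just_below)) ==
                 label_at_point(atlas, rbind(center)))
  # out-of-grid points are background
  expect_identical(label_at_point(atlas, rbind(c(1e4, 0, 0))), 0L)
})

test_that("modal dilation fills background from the 26-neighborhood, lowest label wins ties", {
  grid <- array(0L, c(5, 5, 5))
  grid[2, 2, 2] <- 5L
  grid[4, 2, 2] <- 3L
  tbl <- tibble::tibble(
    id = c(3L, 5L), name = c("A", "B"), hemisphere = c("left", "left"),
    lobe = c("frontal", "frontal"), tissue = c("CGM", "CGM"),
    terminal_side = c("anterior_set", "anterior_set"))
  vol <- label_volume(grid, test_affine(origin = c(0, 0, 0)), tbl)
  d1 <- modal_dilate(vol, 1L)
  # voxel (3,2,2) touches one 5-voxel and one 3-voxel: tie -> lowest id
  expect_identical(d1$grid[3, 2, 2], 3L)
  # foreground voxels are never overwritten
  expect_identical(d1$grid[2, 2, 2], 5L)
  expect_identical(d1$grid[4, 2, 2], 3L)
  # voxels adjacent only to label 5 take it
  expect_identical(d1$grid[1, 1, 1], 5L)
  # one pass reaches exactly the 26-neighborhood
  expect_identical(d1$grid[5, 5, 5], 0L)
  expect_identical(modal_dilate(vol, 2L)$grid[5, 4, 3], 3L)
  # dilation is monotone: labeled set only grows
  expect_true(all(d1$grid[vol$grid != 0] == vol$grid[vol$grid != 0]))
})

test_that("NIfTI label volumes round-trip with affine and integer labels", {
  atlas <- fixture_atlas()
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_label_volume(atlas, nii, table_path = tsv)
  back <- read_label_volume(nii, tsv)
  expect_identical(dim(back$grid), dim(atlas$grid))
  expect_true(all(back$grid == atlas$grid))
  expect_equal(back$affine, atlas$affine, tolerance = 1e-4)
  expect_equal(voxel_volume(back), 8, tolerance = 1e-6)
})
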