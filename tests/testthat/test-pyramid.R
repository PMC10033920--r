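# Slide grouping, pyramid assembly, tile grids and region reads.

test_that("a volume/label/overview series groups into one slide", {
  bf <- smallBrightfield(seed = 21, baseSize = 128, tileSize = 64,
                         levels = c(1, 4))
  slide <- slideOf(bf$instances)
  expect_length(slide@channels, 1L)
  expect_length(volumeLevels(slide), 2L)
  expect_length(slide@label_images, 1L)
  expect_length(slide@overview_images, 1L)
})

test_that("distinct frames of reference yield distinct slides", {
  a <- smallBrightfield(seed = 22, baseSize = 64, tileSize = 64, levels = 1)
  b <- smallBrightfield(seed = 23, baseSize = 64, tileSize = 64, levels = 1)
  slides <- groupSlides(metasOf(c(a$instances, b$instances)))
  expect_length(slides, 2L)
})

test_that("multichannel fluorescence groups into one slide with per-level channels", {
  fl <- makeFluorescenceSeries(fixtureSpec(
    seed = 24, kind = "fluorescence", baseSize = 128, tileSize = 64,
    levels = c(1, 2), channels = c("DNA", "CD45", "CD3", "CD20")))
  slides <- groupSlides(metasOf(fl$instances))
  expect_length(slides, 1L)
  expect_setequal(slideChannels(slides[[1L]]),
                  c("DNA", "CD45", "CD3", "CD20"))
  for (ch in slideChannels(slides[[1L]]))
    expect_length(volumeLevels(slides[[1L]], ch), 2L)
})

test_that("downsample factors are ratios of total widths, including missing levels", {
  bf <- makeBrightfieldSeries(fixtureSpec(seed = 25, baseSize = 128,
                                          tileSize = 32,
                                          levels = c(1, 4, 16)))
  metas <- metasOf(bf$instances)
  volumes <- Filter(function(m) imageFlavor(m) == "VOLUME", metas)
  levels <- assemblePyramid(volumes)
  expect_equal(vapply(levels, function(l) l@downsample_col, 0), c(1, 4, 16))
  expect_equal(vapply(levels, function(l) l@downsample_row, 0), c(1, 4, 16))
  # drop the middle level: factors 1 and 16 remain
  gap <- assemblePyramid(volumes[c(1, 3)])
  expect_equal(vapply(gap, function(l) l@downsample_col, 0), c(1, 16))
})

test_that("physical-extent mismatches are rejected naming the instance", {
  bf <- smallBrightfield(seed = 26, baseSize = 64, tileSize = 64, levels = 1)
  other <- smallBrightfield(seed = 27, baseSize = 64, tileSize = 64,
                            levels = 1)
  m1 <- metasOf(bf$instances)[[1L]]
  m2 <- metasOf(other$instances)[[1L]]
  m2@frame_of_reference_uid <- m1@frame_of_reference_uid
  m2@pixel_spacing_row_mm <- m1@pixel_spacing_row_mm * 2
  m2@pixel_spacing_col_mm <- m1@pixel_spacing_col_mm * 2
  err <- expect_error(assemblePyramid(list(m1, m2)),
                      class = "dicomslide_assembly")
  expect_match(conditionMessage(err), "physical extent of instance")
  expect_true(grepl(m1@sop_instance_uid, conditionMessage(err), fixed = TRUE) ||
                grepl(m2@sop_instance_uid, conditionMessage(err), fixed = TRUE))
})

test_that("TILED_FULL frame numbering is row-major and 1-based", {
  md <- identityMetadata(size = 512)
  md@tile_rows <- 256; md@tile_cols <- 256; md@num_frames <- 4
  grid <- buildTileGrid(md)
  expect_identical(dim(grid@frame_map), c(2L, 2L))
  expect_identical(grid@frame_map[1, 1], 1L)  # tile (0,0) -> frame 1
  expect_identical(grid@frame_map[2, 1], 3L)  # tile (1,0) -> frame 3
  expect_identical(grid@frame_map[1, 2], 2L)
  expect_true(all(grid@frame_map >= 1 & grid@frame_map <= 4))
})

test_that("TILED_SPARSE with all tiles listed equals the TILED_FULL map", {
  full <- makeBrightfieldSeries(fixtureSpec(seed = 28, baseSize = 128,
                                            tileSize = 64, levels = 1))
  sparse <- makeBrightfieldSeries(fixtureSpec(seed = 28, kind = "sparse",
                                              baseSize = 128, tileSize = 64,
                                              levels = 1))
  g_full <- buildTileGrid(metasOf(full$instances)[[1L]])
  g_sparse <- buildTileGrid(metasOf(sparse$instances)[[1L]])
  expect_identical(g_sparse@frame_map, g_full@frame_map)
  # misaligned sparse positions are rejected
  md <- metasOf(sparse$instances)[[1L]]
  md@per_frame_positions[2, ] <- md@per_frame_positions[2, ] + 13L
  expect_error(buildTileGrid(md), class = "dicomslide_tile_alignment")
})

test_that("concatenated instances merge into one level with all tiles mapped", {
  bf <- makeBrightfieldSeries(fixtureSpec(seed = 29, kind = "concatenated",
                                          baseSize = 512, tileSize = 128,
                                          levels = 1))
  metas <- metasOf(bf$instances)
  volumes <- Filter(function(m) imageFlavor(m) == "VOLUME", metas)
  expect_length(volumes, 2L)   # two concatenation parts
  expect_identical(sort(vapply(volumes, function(m)
    m@concatenation_frame_offset, 0)), c(0, 8))
  levels <- assemblePyramid(volumes)
  expect_length(levels, 1L)
  expect_identical(sum(!is.na(levels[[1L]]@tile_grid@frame_map)), 16L)
  # the merged level mosaics identically to the unsplit ground truth
  dir <- withr::local_tempdir()
  store <- localStore(dir)
  storeInstances(store, bf$instances)
  slide <- slideOf(bf$instances)
  rr <- readRegion(store, slide, 1, c(0, 0, 512, 512))
  expect_identical(rr$pixels, bf$ground_truth[[1L]])
})

test_that("read_region mosaics tiles byte-exactly and crops edge tiles", {
  store <- sharedFixtureStore()
  bf <- sharedFixtures()$brightfield
  slide <- sharedBrightfieldSlide()
  # one whole tile: equals the decoded frame exactly
  one <- readRegion(store, slide, 1, c(0, 0, 128, 128))
  expect_identical(one$pixels, bf$ground_truth[[1L]][1:128, 1:128, ])
  expect_true(all(one$fetched))
  # a region spanning 4 tiles equals the ground-truth crop
  span <- readRegion(store, slide, 1, c(100, 100, 56, 56))
  expect_identical(span$pixels, bf$ground_truth[[1L]][101:156, 101:156, ])
  # fully outside -> range error
  expect_error(readRegion(store, slide, 1, c(600, 600, 4, 4)),
               class = "dicomslide_region")
})

test_that("missing sparse tiles are background-filled and flagged in the mask", {
  dir <- withr::local_tempdir()
  store <- localStore(dir)
  fl <- makeFluorescenceSeries(fixtureSpec(
    seed = 30, kind = "sparse", baseSize = 128, tileSize = 64, levels = 1,
    channels = "DNA", missingTiles = 3))   # bottom-right tile absent
  storeInstances(store, fl$instances)
  slide <- slideOf(fl$instances)
  rr <- readRegion(store, slide, 1, c(0, 0, 128, 128))
  expect_true(all(rr$pixels[65:128, 65:128, ] == 0))   # monochrome fill
  expect_true(all(!rr$fetched[65:128, 65:128]))
  expect_true(all(rr$fetched[1:64, 1:64]))
  expect_identical(rr$pixels[1:64, 1:64, 1],
                   fl$ground_truth$DNA[[1L]][1:64, 1:64])
  # brightfield missing tiles fill with white glass
  bfs <- makeBrightfieldSeries(fixtureSpec(
    seed = 31, kind = "sparse", baseSize = 128, tileSize = 64, levels = 1,
    missingTiles = 0))
  dir2 <- withr::local_tempdir(); store2 <- localStore(dir2)
  storeInstances(store2, bfs$instances)
  slide2 <- slideOf(bfs$instances)
  rr2 <- readRegion(store2, slide2, 1, c(0, 0, 64, 64))
  expect_true(all(rr2$pixels == 255L))
  expect_true(all(!rr2$fetched))
})

test_that("level pixels equal block-averaged base pixels (true pyramid)", {
  store <- sharedFixtureStore()
  bf <- sharedFixtures()$brightfield
  slide <- sharedBrightfieldSlide()
  lvl <- readRegion(store, slide, 2, c(0, 0, 64, 64))$pixels
  expect_lte(mean(abs(lvl - blockAverage(bf$ground_truth[[1L]], 4))), 2)
})

test_that("level selection returns the coarsest level at or below the request", {
  slide <- sharedBrightfieldSlide()
  levels <- volumeLevels(slide)
  base_sp <- levels[[1L]]@metadata@pixel_spacing_col_mm
  expect_identical(selectLevel(levels, base_sp), 1L)
  expect_identical(selectLevel(levels, base_sp * 2), 1L)  # between levels
  expect_identical(selectLevel(levels, base_sp * 4), 2L)
  expect_identical(selectLevel(levels, base_sp * 100), 2L)  # clamp coarse
  expect_identical(selectLevel(levels, base_sp / 10), 1L)   # finer than base
})
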