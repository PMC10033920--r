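# Segmentation and parametric-map overlays with real-world value
# mapping and colormap selection.

test_that("linear real-world value maps evaluate and invert exactly", {
  rwvm <- linearRealWorldValueMap(2 / 65535, -1)
  expect_equal(applyRealWorldValueMap(rwvm, 0), -1)
  expect_equal(applyRealWorldValueMap(rwvm, 65535), 1)
  expect_equal(rwvm@value_range, c(-1, 1))
  stored <- seq(0, 65535, by = 257)
  real <- applyRealWorldValueMap(rwvm, stored)
  expect_lt(max(abs(invertRealWorldValueMap(rwvm, real) - stored)), 1e-6)
})

test_that("colormap selection is a pure function of the real bounds", {
  expect_identical(selectColormap(-1, 1)$kind, "diverging")
  expect_identical(selectColormap(0, 1)$kind, "sequential")
  expect_identical(selectColormap(0.2, 7)$kind, "sequential")
  expect_identical(selectColormap(-5, -1)$kind, "sequential")
  expect_identical(selectColormap(-0.01, 0.01)$kind, "diverging")
})

test_that("the fixture parametric map maps its stored extremes to [-1, 1]", {
  pm <- sharedFixtures()$analysis$parametric_map
  rwvm <- parseRealWorldValueMap(pm)
  expect_equal(applyRealWorldValueMap(rwvm, 0), -1)
  expect_equal(applyRealWorldValueMap(rwvm, 65535), 1)
  res <- renderParametricMap(pm, c(0, 0, 16, 256))
  expect_identical(res$colormap, "diverging")
  expect_equal(res$value_range, c(-1, 1))
  # the diverging map is centered: real 0 renders near-white
  mid <- res$rgba[8, 128, 1:3]
  expect_true(all(mid > 200))
  # left edge (real -1) is blue-dominant, right edge (real +1) red-dominant
  expect_gt(res$rgba[8, 1, 3], res$rgba[8, 1, 1])
  expect_gt(res$rgba[8, 256, 1], res$rgba[8, 256, 3])
  # colorbar ticks span the value range
  expect_equal(res$colorbar$value, seq(-1, 1, length.out = 5))
  # missing mapping is a metadata error
  broken <- pm; broken[["RealWorldValueMappingSequence"]] <- NULL
  expect_error(renderParametricMap(broken, c(0, 0, 4, 4)),
               class = "dicomslide_metadata")
})

test_that("all-positive parametric maps select the sequential colormap", {
  bf <- smallBrightfield(seed = 81, baseSize = 64, tileSize = 64, levels = 1)
  vals <- matrix(seq(0, 1, length.out = 64 * 64), 64)
  pm <- buildParametricMapDataset(vals, bf$instances[[1L]]$dataset,
                                  realRange = c(0, 1),
                                  uids = uidFactory(81))
  res <- renderParametricMap(pm, c(0, 0, 8, 8))
  expect_identical(res$colormap, "sequential")
})

test_that("binary segmentations color the mask and leave background transparent", {
  fx <- sharedFixtures()$analysis
  seg <- fx$segmentation_binary
  rgba <- renderSegmentation(seg)
  expect_identical(sum(rgba[, , 4] > 0), sum(fx$mask))
  expect_true(all(rgba[, , 4][!fx$mask] == 0))
  expect_error(renderSegmentation(seg, segmentNumber = 9),
               class = "dicomslide_not_found")
})

test_that("fractional segmentations map the max stored fraction to real value 1", {
  fx <- sharedFixtures()$analysis
  seg <- fx$segmentation_fractional
  stored <- DicomSlide:::.datasetRegionArray(seg)
  maxf <- dcmValue(seg, "MaximumFractionalValue")
  expect_identical(max(stored), 255)
  real <- stored / maxf
  expect_identical(max(real), 1)
  rgba <- renderSegmentation(seg)
  top <- DicomSlide:::.colormapViridis()[256, ]
  hit <- which(fx$mask, arr.ind = TRUE)[1, ]
  expect_identical(rgba[hit[1], hit[2], 1:3], as.integer(top))
})

test_that("embedded palette LUTs take precedence over the default colormap", {
  fx <- sharedFixtures()$analysis
  seg <- fx$segmentation_fractional
  red <- colorRampLut(c(255, 0, 0), source = "embedded")
  seg_pal <- DicomSlide:::.paletteIntoDataset(seg, red)
  rgba <- renderSegmentation(seg_pal)
  hit <- which(fx$mask, arr.ind = TRUE)[1, ]
  expect_identical(rgba[hit[1], hit[2], 1:3], c(255L, 0L, 0L))
})

test_that("overlay compositing scales the alpha channel by opacity", {
  base <- array(0L, c(4, 4, 3))
  overlay <- array(0L, c(4, 4, 4))
  overlay[, , 1:3] <- 255L
  overlay[, , 4] <- 255L
  expect_identical(compositeOverlay(base, overlay, 0), base)
  expect_true(all(compositeOverlay(base, overlay, 1) == 255L))
  expect_true(all(compositeOverlay(base, overlay, 0.5) == 128L))
  # transparent overlay pixels leave the base untouched at any opacity
  overlay[2, 2, 4] <- 0L
  out <- compositeOverlay(base, overlay, 1)
  expect_identical(out[2, 2, ], c(0L, 0L, 0L))
  expect_error(compositeOverlay(base, overlay, 2),
               class = "dicomslide_parameter")
})

test_that("segmentation overlays reproduce the source polygon footprint", {
  bf <- smallBrightfield(seed = 82, baseSize = 64, tileSize = 64, levels = 1)
  src <- bf$instances[[1L]]$dataset
  poly <- cbind(c(5, 25, 25, 5), c(5, 5, 25, 25))
  res <- convertContourTable(
    data.frame(object_id = 1,
               vertices = paste(apply(poly, 1, paste, collapse = " "),
                                collapse = ";")),
    src, uidFactory(82))
  rgba <- renderSegmentation(res$segmentation)
  mask <- rasterizePolygons(list(poly), 64, 64)
  expect_identical(rgba[, , 4] > 0, mask)
})
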