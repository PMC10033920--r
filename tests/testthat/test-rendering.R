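# Pixel transformation sequences: decode, VOI, palette, blending,
# compositing, ICC.

test_that("frame decoding matches ground truth and rejects bad input", {
  fl <- makeFluorescenceSeries(fixtureSpec(
    seed = 41, kind = "fluorescence", baseSize = 64, tileSize = 64,
    levels = 1, channels = "DNA"))
  md <- metasOf(fl$instances)[[1L]]
  bytes <- dcmValue(fl$instances[[1L]]$dataset, "PixelData")
  arr <- decodeFrame(bytes, "application/octet-stream", md)
  expect_identical(arr[, , 1L], fl$ground_truth$DNA[[1L]])
  expect_error(decodeFrame(bytes[1:33], "application/octet-stream", md),
               class = "dicomslide_decode")
  expect_error(decodeFrame(bytes, "image/jp2", md),
               class = "dicomslide_negotiation")
  # corrupt JPEG stream
  expect_error(decodeFrame(as.raw(1:100), "image/jpeg", md),
               class = "dicomslide_decode")
})

test_that("VOI windowing follows the linear clip-and-rescale form", {
  w <- voiWindow(1000, 400)
  expect_equal(applyVoi(1000, w), 0.5)
  expect_equal(applyVoi(800, w), 0)
  expect_equal(applyVoi(799, w), 0)    # clamp floor
  expect_equal(applyVoi(900, w), 0.25)
  expect_equal(applyVoi(1200, w), 1)
  # monotone non-decreasing over random windows
  set.seed(42)
  for (i in 1:20) {
    w <- voiWindow(runif(1, 0, 65535), runif(1, 1, 65535))
    x <- sort(runif(200, -1e4, 7e4))
    expect_true(all(diff(applyVoi(x, w)) >= 0))
  }
  expect_error(voiWindow(100, 0), class = "dicomslide_parameter")
  # legacy variant differs by the w-1 denominator
  expect_equal(applyVoi(1000, voiWindow(1000, 400), "legacy"),
               0.5 / 399 + 0.5)
})

test_that("segmented palette descriptors expand per the interpolation oracle", {
  ramp <- list(list(kind = "discrete", length = 1, value = 0),
               list(kind = "linear", length = 255, value = 255))
  lut <- paletteColorLut(ramp, ramp, ramp)
  tables <- expandPalette(lut)
  # brute-force oracle: start at 0, append i * 255 / 255
  oracle <- c(0, vapply(1:255, function(i) 0 + (255 - 0) * i / 255, 0))
  expect_identical(tables$red, as.integer(round(oracle)))
  expect_identical(tables$red, 0:255)
  # constant discrete segment
  const <- paletteColorLut(list(list(kind = "discrete", length = 256,
                                     value = 37)),
                           list(list(kind = "discrete", length = 256,
                                     value = 37)),
                           list(list(kind = "discrete", length = 256,
                                     value = 37)))
  expect_identical(expandPalette(const)$green, rep(37L, 256))
  # mismatched channel lengths
  bad <- paletteColorLut(ramp, ramp,
                         list(list(kind = "discrete", length = 2, value = 0)))
  expect_error(expandPalette(bad), class = "dicomslide_descriptor")
  # linear segment with no predecessor
  orphan <- list(list(kind = "linear", length = 10, value = 255))
  expect_error(expandPalette(paletteColorLut(orphan, orphan, orphan)),
               class = "dicomslide_descriptor")
})

test_that("palette application rounds half away from zero on v * (L - 1)", {
  ramp <- list(list(kind = "discrete", length = 1, value = 0),
               list(kind = "linear", length = 255, value = 255))
  gray <- paletteColorLut(ramp, ramp, ramp)
  expect_identical(as.vector(applyPalette(0, gray)), c(0L, 0L, 0L))
  expect_identical(as.vector(applyPalette(0.5, gray)), c(128L, 128L, 128L))
  red <- colorRampLut(c(255, 0, 0))
  expect_identical(as.vector(applyPalette(1, red)), c(255L, 0L, 0L))
  # maximum attainable output equals the maximum table entry
  half <- colorRampLut(c(200, 0, 0))
  expect_identical(max(applyPalette(seq(0, 1, 0.01), half)), 200L)
  # monotone tables preserve scalar ordering
  v <- sort(runif(100))
  out <- applyPalette(v, gray)[, 1]
  expect_true(all(diff(out) >= 0))
})

test_that("additive blending clamps, commutes, and ignores zero channels", {
  a <- array(0L, c(2, 2, 3)); a[, , 1] <- 255L
  b <- array(0L, c(2, 2, 3)); b[, , 2] <- 128L
  ab <- blendAdditive(list(a, b))
  expect_identical(ab[1, 1, ], c(255L, 128L, 0L))
  expect_identical(blendAdditive(list(a)), a)
  c2 <- array(0L, c(2, 2, 3)); c2[, , 1] <- 200L
  d <- array(0L, c(2, 2, 3)); d[, , 1] <- 100L
  expect_true(all(blendAdditive(list(c2, d))[, , 1] == 255L))
  # permutation invariance and zero-channel idempotence
  zero <- array(0L, c(2, 2, 3))
  expect_identical(blendAdditive(list(a, b, c2)),
                   blendAdditive(list(c2, b, a)))
  expect_identical(blendAdditive(list(a, b, zero)),
                   blendAdditive(list(a, b)))
  expect_error(blendAdditive(list()), class = "dicomslide_parameter")
  expect_error(blendAdditive(list(a, array(0L, c(3, 2, 3)))),
               class = "dicomslide_shape")
})

test_that("alpha compositing interpolates with half-away rounding", {
  under <- array(0L, c(2, 2, 3))
  over <- array(255L, c(2, 2, 3))
  expect_identical(compositeAlpha(under, over, 0), under)
  expect_identical(compositeAlpha(under, over, 1), over)
  expect_true(all(compositeAlpha(under, over, 0.5) == 128L))
  expect_error(compositeAlpha(under, over, 1.5),
               class = "dicomslide_parameter")
})

test_that("identity ICC pairings reproduce input within one code value", {
  set.seed(7)
  rgb <- array(as.integer(sample.int(256, 48 * 3, TRUE) - 1), c(4, 12, 3))
  tr <- iccTransform(createIccProfile("identity"))
  out <- applyIcc(rgb, tr)
  expect_lte(max(abs(out - rgb)), 1)
})

test_that("swapped-primaries profiles move red energy into green", {
  # independent colorimetry oracle: with R and G primaries exchanged in
  # the input profile, a pure red patch contributes the green primary's
  # XYZ, so after conversion to the sRGB display space the green channel
  # dominates
  rgb <- array(0L, c(2, 2, 3)); rgb[, , 1] <- 230L
  out <- applyIcc(rgb, iccTransform(createIccProfile("swapped")))
  expect_true(all(out[, , 2] == apply(out, c(1, 2), max)))
  expect_gt(min(out[, , 2]), max(out[, , 1]))
})

test_that("neutral grays stay neutral through matrix profile pairs", {
  gray <- array(128L, c(2, 2, 3))
  for (variant in c("identity", "widegamut")) {
    out <- applyIcc(gray, iccTransform(createIccProfile(variant)))
    expect_lte(max(abs(out - 128L)), 2, )
  }
})

test_that("the vectorized grayscale chain equals the scalar oracle on 1e5 samples", {
  set.seed(2024)
  n <- 100000L
  x <- sample.int(65536L, n, replace = TRUE) - 1L
  center <- 20000; width <- 30000
  lut <- colorRampLut(c(255, 128, 0))
  tables <- expandPalette(lut)
  fast <- applyPalette(applyVoi(x, voiWindow(center, width)), lut)
  idx <- sample.int(n, 300)   # scalar oracle on a random subsample
  for (i in idx) {
    expect_identical(fast[i, ],
                     as.integer(oracleGrayscaleChain(x[i], center, width,
                                                     tables)))
  }
  # exactness of the full chain against a vector-built reference
  y <- pmin(pmax((x - (center - width / 2)) / width, 0), 1)
  ref_idx <- trunc(y * 255 + 0.5) + 1
  expect_identical(fast[seq_len(n)], tables$red[ref_idx])
})

test_that("intermediates stay continuous (no quantization below 1/65535)", {
  # full-range window over 16-bit input: all 65536 stored values map to
  # distinct normalized values, so no intermediate is quantized
  x <- 0:65535
  y <- applyVoi(x, voiWindow(32768, 65536))
  expect_identical(length(unique(y)), 65536L)
  expect_true(all(diff(y) > 0))
})

test_that("true-color rendering composes read, decode and ICC stages", {
  store <- sharedFixtureStore()
  bf <- sharedFixtures()$brightfield
  slide <- sharedBrightfieldSlide()
  out <- renderTruecolorRegion(store, slide, 1, c(0, 0, 64, 64))
  expect_lte(max(abs(out - bf$ground_truth[[1L]][1:64, 1:64, ])), 1)
  # without an ICC profile the raw mosaic is returned with a notice
  plain <- makeBrightfieldSeries(fixtureSpec(seed = 44, baseSize = 64,
                                             tileSize = 64, levels = 1))
  dir <- withr::local_tempdir(); store2 <- localStore(dir)
  storeInstances(store2, plain$instances)
  slide2 <- slideOf(plain$instances)
  expect_message(
    out2 <- renderTruecolorRegion(store2, slide2, 1, c(0, 0, 64, 64)),
    "no embedded ICC profile")
  expect_identical(out2, plain$ground_truth[[1L]])
  # swapped-primaries profile: output differs and matches stage oracle
  swapped <- makeBrightfieldSeries(fixtureSpec(seed = 44, baseSize = 64,
                                               tileSize = 64, levels = 1,
                                               withIcc = "swapped"))
  dir3 <- withr::local_tempdir(); store3 <- localStore(dir3)
  storeInstances(store3, swapped$instances)
  slide3 <- slideOf(swapped$instances)
  out3 <- renderTruecolorRegion(store3, slide3, 1, c(0, 0, 64, 64))
  expect_false(identical(out3, swapped$ground_truth[[1L]]))
  oracle <- applyIcc(swapped$ground_truth[[1L]],
                     iccTransform(createIccProfile("swapped")))
  expect_identical(out3, oracle)
})
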