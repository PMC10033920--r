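# Shared fixture builders. Stores and slide objects are memoised per
# test run; everything is generated in code under tempdir().

.fixture_env <- new.env(parent = emptyenv())

sharedFixtureStore <- function() {
  if (is.null(.fixture_env$store)) {
    dir <- file.path(tempdir(), "dicomslide-shared-store")
    unlink(dir, recursive = TRUE)
    .fixture_env$store <- suppressMessages(
      writeFixtureStore(dir, seed = 1, baseSize = 256, tileSize = 128))
  }
  .fixture_env$store
}

sharedFixtures <- function() attr(sharedFixtureStore(), "fixtures")

# Parse the generated instances into metadata, injecting the transfer
# syntax the store would report.
metasOf <- function(instances) {
  lapply(instances, function(x)
    parseImageMetadata(dcmSet(x$dataset, "TransferSyntaxUID",
                              x$transferSyntax)))
}

slideOf <- function(instances) {
  groupSlides(metasOf(instances))[[1L]]
}

sharedBrightfieldSlide <- function() {
  if (is.null(.fixture_env$bf_slide))
    .fixture_env$bf_slide <- slideOf(sharedFixtures()$brightfield$instances)
  .fixture_env$bf_slide
}

sharedFluorescenceSlide <- function() {
  if (is.null(.fixture_env$fl_slide))
    .fixture_env$fl_slide <- slideOf(sharedFixtures()$fluorescence$instances)
  .fixture_env$fl_slide
}

# A small standalone brightfield series (independent of the shared
# store) for tests that need custom geometry.
smallBrightfield <- function(seed = 3, baseSize = 128, tileSize = 64,
                             levels = c(1, 4), ...) {
  makeBrightfieldSeries(fixtureSpec(seed = seed, kind = "brightfield",
                                    baseSize = baseSize,
                                    tileSize = tileSize, levels = levels,
                                    ...))
}

# Identity-orientation metadata for geometry tests.
identityMetadata <- function(spacing = 0.001, origin = c(0, 0, 0),
                             orientation = c(1, 0, 0, 0, 1, 0),
                             size = 1000) {
  new("SlideImageMetadata",
      study_uid = "1.2", series_uid = "1.3", sop_instance_uid = "1.4",
      frame_of_reference_uid = "1.5", flavor = "VOLUME",
      total_rows = size, total_cols = size, tile_rows = 256, tile_cols = 256,
      num_frames = 16, samples_per_pixel = 1, bits_allocated = 8,
      bits_stored = 8, photometric = "MONOCHROME2",
      pixel_spacing_row_mm = spacing, pixel_spacing_col_mm = spacing,
      origin_x_mm = origin[1], origin_y_mm = origin[2],
      origin_z_mm = origin[3],
      orientation = orientation, dimension_organization = "TILED_FULL",
      concatenation_uid = NA_character_,
      concatenation_frame_offset = NA_real_,
      per_frame_positions = NULL,
      optical_paths = data.frame(identifier = "1", description = "",
                                 wavelength = NA_real_,
                                 stringsAsFactors = FALSE),
      staining_targets = list(), icc_profile = raw(0), palette_lut = NULL,
      transfer_syntax_uid = "1.2.840.10008.1.2.1")
}

# Independent even-odd point-in-polygon oracle (winding-free crossing
# count written differently from the implementation; boundary points
# are classified inside via an explicit on-segment test).
oraclePointInPolygon <- function(px, py, poly) {
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- abs((xs[j] - xs[i]) * (py - ys[i]) - (px - xs[i]) * (ys[j] - ys[i]))
    seglen2 <- (xs[j] - xs[i])^2 + (ys[j] - ys[i])^2
    if (seglen2 > 0 && d^2 / seglen2 < 1e-18) {
      t <- ((px - xs[i]) * (xs[j] - xs[i]) + (py - ys[i]) * (ys[j] - ys[i])) /
        seglen2
      if (t >= 0 && t <= 1) return(TRUE)
    }
  }
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if ((ys[i] <= py && ys[j] > py) || (ys[j] <= py && ys[i] > py)) {
      xint <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < xint) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# Scalar reference for the grayscale display chain.
oracleGrayscaleChain <- function(x, center, width, tables) {
  y <- (x - (center - width / 2)) / width
  y <- min(max(y, 0), 1)
  L <- length(tables$red)
  idx <- trunc(y * (L - 1) + 0.5) + 1
  c(tables$red[idx], tables$green[idx], tables$blue[idx])
}
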