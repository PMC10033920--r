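#' @title Grayscale and true-color pixel transformations
#'
#' @description The display pipeline for slide microscopy pixel data.
#'   Grayscale (fluorescence) channels pass through VOI windowing
#'   (clip and rescale stored values to [0, 1]), a palette color LUT
#'   (map normalized values to 8-bit RGB), and additive blending of
#'   the resulting pseudocolor channels. True-color (brightfield)
#'   images pass through the ICC profile connection space transform
#'   (see [applyIcc()]). Overlays are combined by alpha compositing.
#'   All intermediate arithmetic is carried in R doubles (64-bit) —
#'   well above the 32-bit floating point contract — and quantization
#'   to 8 bits happens exactly once, at the end of each chain.
#' @name rendering
NULL

#' Value-of-interest window
#'
#' @slot center Window center, stored-value units.
#' @slot width Window width, stored-value units (> 0).
#' @export
setClass("VoiWindow", representation(center = "numeric", width = "numeric"))

setValidity("VoiWindow", function(object) {
  if (length(object@width) != 1 || object@width <= 0)
    return("window width must be > 0")
  TRUE
})

#' @param center,width See slots.
#' @rdname VoiWindow-class
#' @export
voiWindow <- function(center, width) {
  if (width <= 0) dcmStop("parameter", "window width must be > 0")
  new("VoiWindow", center = as.numeric(center), width = as.numeric(width))
}

setMethod("show", "VoiWindow", function(object) {
  cat(sprintf("VoiWindow(center = %g, width = %g)\n", object@center,
              object@width))
})

#' Apply VOI windowing
#'
#' Default ("exact") variant: `y = clamp((x - (c - w/2)) / w, 0, 1)` —
#' a linear ramp from 0 at the lower window edge to 1 at the upper
#' edge, monotone non-decreasing in the stored value. The "legacy"
#' variant implements the historical form with the `w - 1`
#' denominator, `y = clamp((x - c + 0.5) / (w - 1) + 0.5, 0, 1)`;
#' the two differ by at most one part in `w` and the exact form is
#' the default because its window edges land exactly on 0 and 1.
#'
#' @param x Numeric array of stored grayscale values.
#' @param window A [VoiWindow-class].
#' @param variant "exact" or "legacy".
#' @return Numeric array in [0, 1], same shape as `x`.
#' @examples
#' applyVoi(900, voiWindow(1000, 400))   # 0.25
#' @export
applyVoi <- function(x, window, variant = c("exact", "legacy")) {
  variant <- match.arg(variant)
  c <- window@center; w <- window@width
  y <- if (variant == "exact") (x - (c - w / 2)) / w
       else (x - c + 0.5) / (w - 1) + 0.5
  pmin(pmax(y, 0), 1)
}

# ---- palette color LUTs ----------------------------------------------

#' Palette color lookup table
#'
#' Per-channel mapping of normalized grayscale to 8-bit color values.
#' Each channel is either an explicit table (integer vector) or a
#' segmented descriptor: an ordered list of segments, each
#' `list(kind = "discrete"|"linear", length = n, value = v)`. A
#' discrete segment repeats its value(s) across `n` entries; a linear
#' segment appends `n` entries interpolating from the previous table
#' entry to its end value. Segmented descriptors are how presentation
#' states encode color ramps compactly (two segments suffice for a
#' linear ramp: the first and the last color value).
#'
#' @slot red,green,blue Explicit table or list of segments.
#' @slot first_mapped First stored value mapped, stored-value units.
#' @slot source One of "user", "embedded", "presentation_state" —
#'   where the LUT came from, which drives override precedence: an
#'   image-embedded LUT always wins and cannot be overridden by user
#'   settings; a presentation-state LUT wins over ad-hoc user settings.
#' @export
setClass("PaletteColorLut", representation(
  red = "ANY", green = "ANY", blue = "ANY",
  first_mapped = "numeric", source = "character"
))

#' @param red,green,blue,firstMapped,source See slots.
#' @rdname PaletteColorLut-class
#' @examples
#' # identity gray ramp via segments, as a presentation state encodes it
#' ramp <- list(list(kind = "discrete", length = 1, value = 0),
#'              list(kind = "linear", length = 255, value = 255))
#' lut <- paletteColorLut(ramp, ramp, ramp)
#' range(expandPalette(lut)$red)    # 0 255
#' @export
paletteColorLut <- function(red, green, blue, firstMapped = 0,
                            source = "user") {
  new("PaletteColorLut", red = red, green = green, blue = blue,
      first_mapped = as.numeric(firstMapped), source = source)
}

#' A single-hue linear color ramp LUT
#'
#' @param rgb Length-3 numeric, the full-intensity color (0-255).
#' @param source LUT provenance (see [PaletteColorLut-class]).
#' @return A [PaletteColorLut-class] ramping black -> `rgb`.
#' @export
colorRampLut <- function(rgb, source = "user") {
  seg <- function(top) list(list(kind = "discrete", length = 1, value = 0),
                            list(kind = "linear", length = 255, value = top))
  paletteColorLut(seg(rgb[1]), seg(rgb[2]), seg(rgb[3]), source = source)
}

.expandChannel <- function(spec, channel) {
  if (is.numeric(spec) && !is.list(spec)) return(as.integer(spec))
  out <- numeric(0)
  for (seg in spec) {
    n <- seg$length
    if (seg$kind == "discrete") {
      vals <- seg$value
      if (length(vals) == 1L) vals <- rep(vals, n)
      if (length(vals) != n)
        dcmStop("descriptor",
                "discrete segment in %s channel: %d value(s) for length %d",
                channel, length(seg$value), n)
      out <- c(out, vals)
    } else if (seg$kind == "linear") {
      if (!length(out))
        dcmStop("descriptor",
                "linear segment without a preceding entry in %s channel",
                channel)
      prev <- out[length(out)]
      out <- c(out, prev + (seg$value - prev) * seq_len(n) / n)
    } else {
      dcmStop("descriptor", "unknown segment kind '%s'", seg$kind)
    }
  }
  as.integer(round(out))
}

#' Expand a palette LUT to explicit per-channel tables
#'
#' @param lut A [PaletteColorLut-class].
#' @return `list(red, green, blue)` of equal-length integer tables
#'   with entries in [0, 255].
#' @export
expandPalette <- function(lut) {
  tables <- list(red = .expandChannel(lut@red, "red"),
                 green = .expandChannel(lut@green, "green"),
                 blue = .expandChannel(lut@blue, "blue"))
  lens <- vapply(tables, length, 0L)
  if (length(unique(lens)) != 1L)
    dcmStop("descriptor",
            "expanded channel tables have inconsistent lengths (%s)",
            paste(lens, collapse = ", "))
  if (lens[1] < 2L)
    dcmStop("descriptor", "palette tables must have at least 2 entries")
  rng <- range(unlist(tables))
  if (rng[1] < 0 || rng[2] > 255)
    dcmStop("descriptor", "palette entries outside [0, 255]")
  tables
}

#' Map normalized values through a palette color LUT
#'
#' The table index is `round(v * (L - 1))` (half away from zero), so
#' `v = 1` reaches the last entry and the maximum attainable output
#' equals the maximum table entry.
#'
#' @param v Numeric array in [0, 1].
#' @param lut A [PaletteColorLut-class].
#' @return Integer 8-bit RGB array (`dim(v) x 3`).
#' @export
applyPalette <- function(v, lut) {
  tables <- expandPalette(lut)
  L <- length(tables$red)
  idx <- roundHalfAway(v * (L - 1)) + 1L
  d <- dim(v); if (is.null(d)) d <- length(v)
  out <- array(0L, dim = c(d, 3L))
  n <- prod(d)
  out[seq_len(n)] <- tables$red[idx]
  out[n + seq_len(n)] <- tables$green[idx]
  out[2 * n + seq_len(n)] <- tables$blue[idx]
  storage.mode(out) <- "integer"
  out
}

#' Additively blend pseudocolor channels
#'
#' Per pixel and per color channel the inputs are summed and clamped
#' to [0, 255]; the result is invariant under permutation of the
#' inputs and unchanged by all-zero channels.
#'
#' @param images List (>= 1) of equal-shape 8-bit RGB arrays.
#' @return Integer 8-bit RGB array.
#' @export
blendAdditive <- function(images) {
  if (!length(images)) dcmStop("parameter", "no channels to blend")
  d <- dim(images[[1L]])
  total <- array(0, dim = d)
  for (img in images) {
    if (!identical(dim(img), d))
      dcmStop("shape", "channel shapes differ: %s vs %s",
              paste(dim(img), collapse = "x"), paste(d, collapse = "x"))
    total <- total + img
  }
  out <- pmin(total, 255)
  storage.mode(out) <- "integer"
  out
}

#' Alpha-composite an overlay onto a base image
#'
#' `out = round(alpha * over + (1 - alpha) * under)`, rounding half
#' away from zero. `alpha` may be a scalar or a per-pixel matrix
#' (recycled across color channels).
#'
#' @param under,over Equal-shape 8-bit RGB arrays.
#' @param alpha Opacity in [0, 1].
#' @return Integer 8-bit RGB array.
#' @export
compositeAlpha <- function(under, over, alpha) {
  if (any(alpha < 0 | alpha > 1))
    dcmStop("parameter", "alpha must lie in [0, 1]")
  if (!identical(dim(under), dim(over)))
    dcmStop("shape", "under/over shapes differ")
  if (is.matrix(alpha) && length(dim(under)) == 3L)
    alpha <- array(alpha, dim = dim(under))
  out <- roundHalfAway(alpha * over + (1 - alpha) * under)
  storage.mode(out) <- "integer"
  out
}

#' Render a true-color region in display space
#'
#' Reads the raw region, then applies the ICC profile connection
#' space transform using the image's embedded input profile. When the
#' image carries no ICC profile the stage is skipped with a logged
#' notice and the raw mosaic is returned unchanged.
#'
#' @param store,slide,level,region,channel As in [readRegion()].
#' @param displayProfile Display ICC profile bytes (default built-in
#'   sRGB-targeting profile).
#' @param renderingIntent Passed to [iccTransform()].
#' @return Integer 8-bit RGB array (rows x cols x 3).
#' @export
renderTruecolorRegion <- function(store, slide, level, region, channel = 1L,
                                  displayProfile = createIccProfile("srgb"),
                                  renderingIntent = "perceptual") {
  lv <- if (is(level, "PyramidLevel")) level
        else volumeLevels(slide, channel)[[level]]
  raw <- readRegion(store, slide, lv, region, channel)$pixels
  prof <- lv@metadata@icc_profile
  if (!length(prof)) {
    dcmNotice("image has no embedded ICC profile; skipping color management")
    return(raw)
  }
  applyIcc(raw, iccTransform(prof, displayProfile, renderingIntent))
}

# ---- palette <-> DICOM encoding --------------------------------------

.encodeSegmentsWords <- function(spec) {
  words <- integer(0)
  for (seg in spec) {
    if (seg$kind == "discrete") {
      vals <- seg$value
      if (length(vals) == 1L) vals <- rep(vals, seg$length)
      words <- c(words, 0L, seg$length, vals)
    } else {
      words <- c(words, 1L, seg$length, seg$value)
    }
  }
  words
}

.decodeSegmentsWords <- function(words) {
  segs <- list(); i <- 1L
  while (i <= length(words)) {
    op <- words[i]; n <- words[i + 1L]
    if (op == 0) {
      vals <- words[(i + 2L):(i + 1L + n)]
      v <- if (length(unique(vals)) == 1L) vals[1] else vals
      segs[[length(segs) + 1L]] <- list(kind = "discrete", length = n,
                                        value = v)
      i <- i + 2L + n
    } else if (op == 1) {
      segs[[length(segs) + 1L]] <- list(kind = "linear", length = n,
                                        value = words[i + 2L])
      i <- i + 3L
    } else {
      dcmStop("descriptor", "unknown segmented LUT opcode %d", op)
    }
  }
  segs
}

# Writes a palette into `ds`: descriptors plus segmented or explicit
# data elements (16-bit words holding 8-bit display values).
.paletteIntoDataset <- function(ds, lut) {
  tables <- expandPalette(lut)   # validates; also yields entry count
  n <- length(tables$red)
  channels <- c(red = "Red", green = "Green", blue = "Blue")
  for (ch in names(channels)) {
    nm <- channels[[ch]]
    spec <- slot(lut, ch)
    ds <- dcmSet(ds, paste0(nm, "PaletteColorLookupTableDescriptor"),
                 c(n %% 65536, lut@first_mapped, 8L))
    if (is.list(spec)) {
      ds <- dcmSet(ds, paste0("Segmented", nm, "PaletteColorLookupTableData"),
                   packIntLE(.encodeSegmentsWords(spec), 2L))
    } else {
      ds <- dcmSet(ds, paste0(nm, "PaletteColorLookupTableData"),
                   packIntLE(as.integer(spec), 2L))
    }
  }
  ds
}

.parsePaletteFromDataset <- function(ds, source = "embedded") {
  channels <- c(red = "Red", green = "Green", blue = "Blue")
  out <- list()
  bits <- 8L
  for (ch in names(channels)) {
    nm <- channels[[ch]]
    desc <- dcmValue(ds, paste0(nm, "PaletteColorLookupTableDescriptor"))
    if (is.null(desc))
      dcmStop("descriptor", "missing %s palette descriptor", ch)
    bits <- desc[3]
    seg <- dcmValue(ds, paste0("Segmented", nm,
                               "PaletteColorLookupTableData"))
    if (!is.null(seg)) {
      out[[ch]] <- .decodeSegmentsWords(unpackIntLE(seg, 2L))
    } else {
      dat <- dcmValue(ds, paste0(nm, "PaletteColorLookupTableData"))
      if (is.null(dat))
        dcmStop("descriptor", "missing %s palette data", ch)
      vals <- unpackIntLE(dat, 2L)
      # 16-bit embedded tables are rescaled to 8-bit display values
      if (bits == 16) vals <- as.integer(round(vals / 257))
      out[[ch]] <- as.integer(vals)
    }
  }
  first <- dcmValue(ds, "RedPaletteColorLookupTableDescriptor")[2]
  paletteColorLut(out$red, out$green, out$blue, firstMapped = first,
                  source = source)
}

#' Resolve palette precedence
#'
#' An image-embedded palette LUT always wins (the manufacturer's
#' intent may not be overridden); otherwise a presentation-state LUT
#' wins over an ad-hoc user LUT. The VOI window, by contrast, is
#' always user-overridable.
#'
#' @param embedded,state,user `PaletteColorLut` or `NULL`.
#' @return The LUT to apply, or `NULL` if none given.
#' @export
resolvePalette <- function(embedded = NULL, state = NULL, user = NULL) {
  if (!is.null(embedded)) return(embedded)
  if (!is.null(state)) return(state)
  user
}
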