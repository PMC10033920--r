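#' @title Analysis-result overlays
#'
#' @description Renders Segmentation and Parametric Map objects as
#'   pseudocolor RGBA overlays. Stored values are first mapped to real
#'   world values (identity [0, 1] for segmentation fractions, a
#'   linear or table real-world value LUT for parametric maps), then
#'   colorized: an embedded palette color LUT always wins; otherwise a
#'   default colormap is chosen from the real-value bounds — viridis
#'   (sequential) when the range is one-signed, a blue-white-red
#'   diverging map centered at zero when the range crosses zero.
#'   Overlays are combined with the underlying image by alpha
#'   compositing scaled by the user's opacity.
#' @name overlays
NULL

#' Real-world value mapping
#'
#' @slot kind "linear" or "table".
#' @slot slope,intercept Linear mapping `real = slope * stored +
#'   intercept`.
#' @slot table Explicit stored -> real table (kind "table").
#' @slot first_mapped,last_mapped Stored-value domain.
#' @slot unit UCUM [CodedConcept-class].
#' @slot value_range Real-value image of the stored range.
#' @export
setClass("RealWorldValueMap", representation(
  kind = "character", slope = "numeric", intercept = "numeric",
  table = "numeric", first_mapped = "numeric", last_mapped = "numeric",
  unit = "CodedConcept", value_range = "numeric"
))

setValidity("RealWorldValueMap", function(object) {
  if (object@kind == "table" && is.unsorted(object@table) &&
      is.unsorted(rev(object@table)))
    return("table mapping must be monotone")
  TRUE
})

#' @param slope,intercept,firstMapped,lastMapped,unit See slots.
#' @rdname RealWorldValueMap-class
#' @export
linearRealWorldValueMap <- function(slope, intercept, firstMapped = 0,
                                    lastMapped = 65535,
                                    unit = CodedConcept("1", "UCUM",
                                                        "no units")) {
  rng <- sort(slope * c(firstMapped, lastMapped) + intercept)
  new("RealWorldValueMap", kind = "linear", slope = slope,
      intercept = intercept, table = numeric(0),
      first_mapped = firstMapped, last_mapped = lastMapped, unit = unit,
      value_range = rng)
}

#' Map stored values to real-world values
#' @param map A [RealWorldValueMap-class].
#' @param stored Numeric array of stored values.
#' @return Numeric array of real-world values.
#' @export
applyRealWorldValueMap <- function(map, stored) {
  if (map@kind == "linear") {
    map@slope * stored + map@intercept
  } else {
    map@table[pmin(pmax(stored - map@first_mapped, 0),
                   length(map@table) - 1) + 1]
  }
}

#' Invert a linear real-world value mapping
#' @param map A linear [RealWorldValueMap-class].
#' @param real Numeric array of real-world values.
#' @return Stored values.
#' @export
invertRealWorldValueMap <- function(map, real) {
  if (map@kind != "linear")
    dcmStop("parameter", "only linear mappings are invertible")
  (real - map@intercept) / map@slope
}

#' Extract the real-world value mapping of a parametric map dataset
#' @param ds A `DicomDataset`.
#' @return A [RealWorldValueMap-class].
#' @export
parseRealWorldValueMap <- function(ds) {
  seq <- dcmValue(ds, "RealWorldValueMappingSequence", list())
  if (!length(seq))
    dcmStop("metadata", "dataset carries no real world value mapping")
  item <- seq[[1L]]
  unit_seq <- dcmValue(item, "MeasurementUnitsCodeSequence", list())
  unit <- if (length(unit_seq)) codeFromItem(unit_seq[[1L]])
          else CodedConcept("1", "UCUM", "no units")
  lut <- dcmValue(item, "RealWorldValueLUTData")
  first <- dcmValue(item, "RealWorldValueFirstValueMapped", 0)
  last <- dcmValue(item, "RealWorldValueLastValueMapped", 65535)
  if (!is.null(lut)) {
    new("RealWorldValueMap", kind = "table", slope = NA_real_,
        intercept = NA_real_, table = lut, first_mapped = first,
        last_mapped = last, unit = unit, value_range = range(lut))
  } else {
    linearRealWorldValueMap(
      dcmValue(item, "RealWorldValueSlope", 1),
      dcmValue(item, "RealWorldValueIntercept", 0), first, last, unit)
  }
}

# ---- colormaps --------------------------------------------------------

.colormapViridis <- function(n = 256L) {
  t(grDevices::col2rgb(grDevices::hcl.colors(n, "viridis")))
}

.colormapDiverging <- function(n = 256L) {
  ramp <- grDevices::colorRamp(c("#0000FF", "#FFFFFF", "#FF0000"))
  round(ramp(seq(0, 1, length.out = n)))
}

#' Choose the default colormap for a real-value range
#'
#' Diverging (blue-white-red, centered at zero) iff the range crosses
#' zero (`lower < 0 < upper`), otherwise sequential (viridis). A pure
#' function of the bounds.
#'
#' @param lower,upper Real-value bounds.
#' @return `list(kind = "sequential"|"diverging", table = n x 3
#'   0-255)`.
#' @export
selectColormap <- function(lower, upper) {
  if (lower < 0 && upper > 0)
    list(kind = "diverging", table = .colormapDiverging())
  else
    list(kind = "sequential", table = .colormapViridis())
}

.applyColormapTable <- function(v, table) {
  idx <- roundHalfAway(pmin(pmax(v, 0), 1) * (nrow(table) - 1)) + 1L
  d <- dim(v); if (is.null(d)) d <- length(v)
  out <- array(0L, dim = c(d, 3L))
  n <- prod(d)
  out[seq_len(n)] <- table[idx, 1]
  out[n + seq_len(n)] <- table[idx, 2]
  out[2 * n + seq_len(n)] <- table[idx, 3]
  storage.mode(out) <- "integer"
  out
}

# ---- in-memory region extraction for derived objects ------------------

# Mosaic a region directly from an in-memory tiled dataset (the
# analysis objects are single-level and typically held in memory, not
# fetched tile-wise from a store). Handles 1-bit packed frames.
.datasetRegionArray <- function(ds, region = NULL) {
  md <- .parseTiledImageMetadata(ds)
  if (is.null(region)) region <- c(0, 0, md@total_rows, md@total_cols)
  grid <- buildTileGrid(md)
  px <- ds[["PixelData"]]
  if (is.null(px)) dcmStop("metadata", "dataset carries no pixel data")
  bits <- md@bits_allocated
  frame_px <- md@tile_rows * md@tile_cols
  frame_bytes <- if (bits == 1) ceiling(frame_px / 8) else frame_px * bits / 8
  getFrame <- function(f) {
    b <- px$value[((f - 1) * frame_bytes + 1):(f * frame_bytes)]
    if (bits == 1) {
      v <- as.integer(rawToBits(b))[seq_len(frame_px)]
      matrix(v, md@tile_rows, md@tile_cols, byrow = TRUE)
    } else {
      decodeFrameBytes(b, md@tile_rows, md@tile_cols, 1L, bits)[, , 1L]
    }
  }
  r0 <- region[1]; c0 <- region[2]; h <- region[3]; w <- region[4]
  out <- matrix(0, h, w)
  tr0 <- max(0L, floor(r0 / md@tile_rows))
  tr1 <- min(grid@grid_rows - 1L, floor((r0 + h - 1) / md@tile_rows))
  tc0 <- max(0L, floor(c0 / md@tile_cols))
  tc1 <- min(grid@grid_cols - 1L, floor((c0 + w - 1) / md@tile_cols))
  for (tr in tr0:tr1) for (tc in tc0:tc1) {
    f <- grid@frame_map[tr + 1L, tc + 1L]
    if (is.na(f)) next
    t_r0 <- tr * md@tile_rows; t_c0 <- tc * md@tile_cols
    rows_in <- intersect(seq(t_r0, min(t_r0 + md@tile_rows, md@total_rows) - 1),
                         seq(r0, r0 + h - 1))
    cols_in <- intersect(seq(t_c0, min(t_c0 + md@tile_cols, md@total_cols) - 1),
                         seq(c0, c0 + w - 1))
    if (!length(rows_in) || !length(cols_in)) next
    tile <- getFrame(f)
    out[rows_in - r0 + 1, cols_in - c0 + 1] <-
      tile[rows_in - t_r0 + 1, cols_in - t_c0 + 1]
  }
  out
}

.embeddedPalette <- function(ds) {
  pal_seq <- dcmValue(ds, "PaletteColorLookupTableSequence", list())
  if (length(pal_seq))
    return(.parsePaletteFromDataset(pal_seq[[1L]], source = "embedded"))
  if (dcmHas(ds, "RedPaletteColorLookupTableDescriptor"))
    return(.parsePaletteFromDataset(ds, source = "embedded"))
  NULL
}

.colorbarTicks <- function(lower, upper, colorize, n = 5L) {
  vals <- seq(lower, upper, length.out = n)
  cols <- colorize(vals)
  data.frame(value = vals,
             color = grDevices::rgb(cols[, 1], cols[, 2], cols[, 3],
                                    maxColorValue = 255))
}

#' Render a segmentation as an RGBA overlay
#'
#' Binary segments: foreground takes the overlay color, background is
#' fully transparent. Fractional segments: the stored fraction is
#' mapped to a real value in [0, 1] (stored / MaximumFractionalValue)
#' and colormapped — with the embedded palette color LUT when one is
#' present, else the default viridis sequential colormap.
#'
#' @param seg Segmentation `DicomDataset`.
#' @param region `c(row, col, height, width)` or `NULL` for the full
#'   matrix.
#' @param segmentNumber Segment to render.
#' @return Integer RGBA array (h x w x 4, 0-255).
#' @export
renderSegmentation <- function(seg, region = NULL, segmentNumber = 1L) {
  segs <- dcmValue(seg, "SegmentSequence", list())
  nums <- vapply(segs, function(s) as.numeric(dcmValue(s, "SegmentNumber", 0)),
                 0)
  if (!segmentNumber %in% nums)
    dcmStop("not_found", "segment %d not present", segmentNumber)
  stored <- .datasetRegionArray(seg, region)
  seg_type <- dcmValue(seg, "SegmentationType", "BINARY")
  pal <- .embeddedPalette(seg)
  d <- dim(stored)
  if (seg_type == "BINARY") {
    fg <- stored > 0
    rgb <- if (!is.null(pal)) applyPalette(fg * 1, pal)
           else .applyColormapTable(fg * 1, .colormapViridis())
    alpha <- 255L * fg
  } else {
    maxf <- dcmValue(seg, "MaximumFractionalValue", 255)
    real <- stored / maxf            # class probabilities in [0, 1]
    rgb <- if (!is.null(pal)) applyPalette(real, pal)
           else .applyColormapTable(real, .colormapViridis())
    alpha <- matrix(255L, d[1], d[2])
  }
  out <- array(0L, dim = c(d, 4L))
  out[, , 1:3] <- rgb
  out[, , 4L] <- alpha
  storage.mode(out) <- "integer"
  out
}

#' Render a parametric map as an RGBA overlay with colorbar data
#'
#' Stored values pass through the real world value LUT; embedded VOI
#' window and palette color LUT are honored when present, otherwise
#' the colormap is selected from the real-value bounds (diverging
#' centered at zero with symmetric range `max(|lower|, |upper|)` when
#' they cross zero, sequential viridis otherwise).
#'
#' @param pm Parametric Map `DicomDataset`.
#' @param region `c(row, col, height, width)` or `NULL`.
#' @param ticks Number of colorbar ticks.
#' @return `list(rgba = h x w x 4 array, colorbar = data.frame(value,
#'   color), value_range = c(lower, upper), colormap =
#'   "sequential"|"diverging")`.
#' @export
renderParametricMap <- function(pm, region = NULL, ticks = 5L) {
  rwvm <- parseRealWorldValueMap(pm)
  stored <- .datasetRegionArray(pm, region)
  real <- applyRealWorldValueMap(rwvm, stored)
  lower <- rwvm@value_range[1]; upper <- rwvm@value_range[2]
  pal <- .embeddedPalette(pm)
  voi <- if (dcmHas(pm, "WindowCenter"))
    voiWindow(dcmValue(pm, "WindowCenter"), dcmValue(pm, "WindowWidth"))
  else NULL
  if (!is.null(pal)) {
    v <- if (!is.null(voi)) applyVoi(stored, voi)
         else (stored - rwvm@first_mapped) /
              (rwvm@last_mapped - rwvm@first_mapped)
    rgb <- applyPalette(v, pal)
    colorize <- function(vals) {
      tables <- expandPalette(pal)
      L <- length(tables$red)
      vv <- (invertRealWorldValueMap(rwvm, vals) - rwvm@first_mapped) /
        (rwvm@last_mapped - rwvm@first_mapped)
      idx <- roundHalfAway(pmin(pmax(vv, 0), 1) * (L - 1)) + 1L
      cbind(tables$red[idx], tables$green[idx], tables$blue[idx])
    }
    kind <- "embedded"
  } else {
    cm <- selectColormap(lower, upper)
    if (cm$kind == "diverging") {
      R <- max(abs(lower), abs(upper))   # symmetric about zero
      norm <- function(x) (x + R) / (2 * R)
    } else {
      norm <- function(x) (x - lower) / (upper - lower)
    }
    rgb <- .applyColormapTable(norm(real), cm$table)
    colorize <- function(vals) {
      idx <- roundHalfAway(pmin(pmax(norm(vals), 0), 1) *
                             (nrow(cm$table) - 1)) + 1L
      cm$table[idx, , drop = FALSE]
    }
    kind <- cm$kind
  }
  d <- dim(real)
  rgba <- array(0L, dim = c(d, 4L))
  rgba[, , 1:3] <- rgb
  rgba[, , 4L] <- 255L
  storage.mode(rgba) <- "integer"
  list(rgba = rgba,
       colorbar = .colorbarTicks(lower, upper, colorize, ticks),
       value_range = c(lower, upper), colormap = kind)
}

#' Composite an RGBA overlay onto a base image
#'
#' The effective per-pixel alpha is the overlay's alpha channel
#' scaled by the user-chosen opacity; compositing delegates to
#' [compositeAlpha()].
#'
#' @param base Integer RGB array (h x w x 3).
#' @param overlay Integer RGBA array (h x w x 4).
#' @param opacity Scalar in [0, 1].
#' @return Integer RGB array.
#' @export
compositeOverlay <- function(base, overlay, opacity) {
  if (opacity < 0 || opacity > 1)
    dcmStop("parameter", "opacity must lie in [0, 1]")
  alpha <- overlay[, , 4L] / 255 * opacity
  compositeAlpha(base, overlay[, , 1:3, drop = FALSE], alpha)
}
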