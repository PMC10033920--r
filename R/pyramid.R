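#' @title Slides, pyramid levels and tile grids
#'
#' @description Whole-slide images are stored as one image object per
#'   resolution level, each a grid of tiled frames. This module groups
#'   instances into digital slides, determines the multi-resolution
#'   pyramid structure purely from metadata, merges concatenated
#'   instances, computes tile grids for both TILED_FULL and
#'   TILED_SPARSE organizations, and mosaics raw (pre-transform)
#'   regions from tile frames.
#' @name pyramid
NULL

#' Tile grid of one pyramid level
#'
#' @slot grid_rows,grid_cols Tile counts (ceil of matrix / tile size).
#' @slot frame_map Integer matrix `grid_rows x grid_cols` of global
#'   1-based frame numbers; `NA` marks a missing (sparse) tile.
#' @export
setClass("TileGrid", representation(
  grid_rows = "integer", grid_cols = "integer", frame_map = "matrix"
))

setValidity("TileGrid", function(object) {
  fm <- object@frame_map
  if (!all(dim(fm) == c(object@grid_rows, object@grid_cols)))
    return("frame_map dimensions must match grid_rows x grid_cols")
  v <- fm[!is.na(fm)]
  if (length(v) && any(v < 1)) return("frame numbers must be >= 1")
  TRUE
})

#' One level of a slide pyramid
#'
#' @slot metadata [SlideImageMetadata-class] of the level (after
#'   concatenation merge).
#' @slot downsample_row,downsample_col Unitless downsampling factors
#'   relative to the base (highest-resolution) level; floats, not
#'   forced integral.
#' @slot tile_grid [TileGrid-class].
#' @slot parts List of `list(sop_instance_uid, series_uid, study_uid,
#'   frame_offset, num_frames)` — the physical instances carrying this
#'   level's frames (several when the level was split into a
#'   concatenation).
#' @export
setClass("PyramidLevel", representation(
  metadata = "SlideImageMetadata",
  downsample_row = "numeric", downsample_col = "numeric",
  tile_grid = "TileGrid", parts = "list"
))

setValidity("PyramidLevel", function(object) {
  if (object@downsample_row < 1 - 1e-9 || object@downsample_col < 1 - 1e-9)
    return("downsample factors must be >= 1")
  TRUE
})

setMethod("show", "PyramidLevel", function(object) {
  cat(sprintf(
    "PyramidLevel %.0fx%.0f px (downsample %.3g x %.3g), grid %dx%d\n",
    object@metadata@total_rows, object@metadata@total_cols,
    object@downsample_row, object@downsample_col,
    object@tile_grid@grid_rows, object@tile_grid@grid_cols))
})

#' A digital slide
#'
#' All image instances sharing one frame of reference: per-channel
#' pyramids of VOLUME images plus any LABEL and OVERVIEW images.
#'
#' @slot identifier Deterministic slide identifier.
#' @slot frame_of_reference_uid Shared frame of reference.
#' @slot channels Named list (channel identifier -> list of
#'   [PyramidLevel-class], finest first).
#' @slot label_images,overview_images Lists of
#'   [SlideImageMetadata-class].
#' @export
setClass("Slide", representation(
  identifier = "character", frame_of_reference_uid = "character",
  channels = "list", label_images = "list", overview_images = "list"
))

setValidity("Slide", function(object) {
  if (!length(object@channels) ||
      !any(vapply(object@channels, length, 0L) >= 1))
    return("a slide needs at least one volume level")
  TRUE
})

setMethod("show", "Slide", function(object) {
  cat(sprintf("Slide %s\n  %d channel(s), %d label, %d overview\n",
              object@identifier, length(object@channels),
              length(object@label_images), length(object@overview_images)))
  for (ch in names(object@channels))
    cat(sprintf("  channel %s: %d level(s)\n", ch,
                length(object@channels[[ch]])))
})

#' Accessors for Slide
#' @param slide A [Slide-class].
#' @param channel Channel identifier or index (default first).
#' @name slide-accessors
NULL

#' @rdname slide-accessors
#' @export
slideChannels <- function(slide) names(slide@channels)

#' @rdname slide-accessors
#' @export
volumeLevels <- function(slide, channel = 1L) slide@channels[[channel]]

#' @rdname slide-accessors
#' @export
slideIdentifier <- function(slide) slide@identifier

#' Affine map of a slide (built from its highest-resolution image)
#' @param slide A [Slide-class].
#' @param channel Channel identifier or index.
#' @return An [AffineMap-class].
#' @export
pyramidAffineMap <- function(slide, channel = 1L) {
  buildPixelToSlide(volumeLevels(slide, channel)[[1L]]@metadata)
}

# ---- tile grids -------------------------------------------------------

#' Build the tile grid of one level
#'
#' TILED_FULL instances enumerate frames row-major over the grid
#' (frame = tile_row * grid_cols + tile_col + 1); TILED_SPARSE
#' instances list explicit per-frame positions, which must align to
#' the tile grid, and may leave tiles absent.
#'
#' @param metadata [SlideImageMetadata-class] (a concatenation-merged
#'   level is handled via its total frame count).
#' @return A [TileGrid-class].
#' @export
buildTileGrid <- function(metadata) {
  grid_rows <- as.integer(ceiling(metadata@total_rows / metadata@tile_rows))
  grid_cols <- as.integer(ceiling(metadata@total_cols / metadata@tile_cols))
  fm <- matrix(NA_integer_, grid_rows, grid_cols)
  if (metadata@dimension_organization == "TILED_FULL") {
    fm[] <- matrix(seq_len(grid_rows * grid_cols), grid_rows, grid_cols,
                   byrow = TRUE)
  } else {
    pos <- metadata@per_frame_positions
    for (i in seq_len(nrow(pos))) {
      r <- pos[i, 1] / metadata@tile_rows
      c <- pos[i, 2] / metadata@tile_cols
      if (r != floor(r) || c != floor(c))
        dcmStop("tile_alignment",
                "frame %d at pixel offset (%d, %d) is not aligned to the %gx%g tile grid",
                i, pos[i, 1], pos[i, 2], metadata@tile_rows,
                metadata@tile_cols)
      fm[r + 1, c + 1] <- i
    }
  }
  new("TileGrid", grid_rows = grid_rows, grid_cols = grid_cols,
      frame_map = fm)
}

# Merge concatenation partners into single per-level metadata objects.
.mergeConcatenations <- function(images) {
  keys <- vapply(images, function(m)
    if (is.na(m@concatenation_uid)) m@sop_instance_uid
    else m@concatenation_uid, "")
  out <- list()
  for (k in unique(keys)) {
    group <- images[keys == k]
    if (length(group) == 1L && is.na(group[[1L]]@concatenation_uid)) {
      m <- group[[1L]]
      parts <- list(list(sop_instance_uid = m@sop_instance_uid,
                         series_uid = m@series_uid, study_uid = m@study_uid,
                         frame_offset = 0L,
                         num_frames = as.integer(m@num_frames)))
      out[[length(out) + 1L]] <- list(metadata = m, parts = parts)
    } else {
      offs <- vapply(group, function(m)
        as.numeric(m@concatenation_frame_offset), 0)
      if (anyNA(offs)) offs[is.na(offs)] <- 0
      ord <- order(offs)
      group <- group[ord]; offs <- offs[ord]
      merged <- group[[1L]]
      merged@num_frames <- sum(vapply(group, function(m) m@num_frames, 0))
      merged@concatenation_uid <- NA_character_
      merged@concatenation_frame_offset <- NA_real_
      if (merged@dimension_organization == "TILED_SPARSE") {
        merged@per_frame_positions <- do.call(
          rbind, lapply(group, function(m) m@per_frame_positions))
      }
      parts <- lapply(seq_along(group), function(i)
        list(sop_instance_uid = group[[i]]@sop_instance_uid,
             series_uid = group[[i]]@series_uid,
             study_uid = group[[i]]@study_uid,
             frame_offset = as.integer(offs[i]),
             num_frames = as.integer(group[[i]]@num_frames)))
      out[[length(out) + 1L]] <- list(metadata = merged, parts = parts)
    }
  }
  out
}

#' Assemble a pyramid from VOLUME images
#'
#' Orders levels by descending total width, merging concatenation
#' partners first; downsampling factors are the ratio of the base
#' level's total size to each level's (floats — no power-of-two
#' assumption). The physical extent (total size times spacing) of each
#' level must agree with the base within 1e-2 relative tolerance,
#' which catches instances that belong to a different slide without
#' tripping on scanner spacing rounding.
#'
#' @param images List of VOLUME [SlideImageMetadata-class].
#' @return List of [PyramidLevel-class], finest first.
#' @export
assemblePyramid <- function(images) {
  if (!length(images))
    dcmStop("assembly", "no volume images to assemble")
  fors <- unique(vapply(images, function(m) m@frame_of_reference_uid, ""))
  if (length(fors) > 1)
    dcmStop("assembly", "volume images span multiple frames of reference")
  merged <- .mergeConcatenations(images)
  metas <- lapply(merged, `[[`, "metadata")
  ord <- order(-vapply(metas, function(m) m@total_cols, 0),
               vapply(metas, function(m) m@sop_instance_uid, ""))
  merged <- merged[ord]
  base <- merged[[1L]]$metadata
  base_w <- base@total_cols * base@pixel_spacing_col_mm
  base_h <- base@total_rows * base@pixel_spacing_row_mm
  lapply(merged, function(g) {
    m <- g$metadata
    w <- m@total_cols * m@pixel_spacing_col_mm
    h <- m@total_rows * m@pixel_spacing_row_mm
    if (abs(w - base_w) / base_w > 1e-2 || abs(h - base_h) / base_h > 1e-2)
      dcmStop("assembly",
              "physical extent of instance %s (%.4g x %.4g mm) does not match the base level (%.4g x %.4g mm)",
              m@sop_instance_uid, h, w, base_h, base_w)
    new("PyramidLevel", metadata = m,
        downsample_row = base@total_rows / m@total_rows,
        downsample_col = base@total_cols / m@total_cols,
        tile_grid = buildTileGrid(m), parts = g$parts)
  })
}

#' Group image instances into digital slides
#'
#' Partitions instances by (study, frame of reference); within each
#' slide, VOLUME images are grouped into channels (optical path
#' identifier when present, otherwise series) and assembled into
#' pyramids, while LABEL and OVERVIEW images are collected as-is.
#' Slides are returned in deterministic order of identifier; instances
#' that fail assembly are skipped with a warning.
#'
#' @param instances List of [SlideImageMetadata-class].
#' @return List of [Slide-class].
#' @export
groupSlides <- function(instances) {
  instances <- Filter(function(x) is(x, "SlideImageMetadata"), instances)
  keys <- vapply(instances, function(m)
    paste(m@study_uid, m@frame_of_reference_uid, sep = "|"), "")
  slides <- list()
  for (k in sort(unique(keys))) {
    members <- instances[keys == k]
    flavors <- vapply(members, function(m) m@flavor, "")
    volumes <- members[flavors == "VOLUME"]
    if (!length(volumes)) next
    chan_of <- vapply(volumes, function(m) {
      if (nrow(m@optical_paths) >= 1 && nzchar(m@optical_paths$identifier[1]))
        m@optical_paths$identifier[1]
      else m@series_uid
    }, "")
    channels <- list()
    for (ch in sort(unique(chan_of))) {
      lv <- tryCatch(assemblePyramid(volumes[chan_of == ch]),
                     error = function(e) {
                       dcmWarn("skipped_channel",
                               "skipping channel %s: %s", ch,
                               conditionMessage(e))
                       NULL
                     })
      if (!is.null(lv)) channels[[ch]] <- lv
    }
    if (!length(channels)) next
    slides[[length(slides) + 1L]] <- new(
      "Slide",
      identifier = members[[1L]]@frame_of_reference_uid,
      frame_of_reference_uid = members[[1L]]@frame_of_reference_uid,
      channels = channels,
      label_images = members[flavors == "LABEL"],
      overview_images = members[flavors == "OVERVIEW"])
  }
  ids <- vapply(slides, function(s) s@identifier, "")
  slides[order(ids)]
}

# Resolve a global frame number of a (possibly concatenated) level to
# the physical instance holding it.
.resolveFrame <- function(level, frame) {
  for (p in level@parts) {
    if (frame > p$frame_offset && frame <= p$frame_offset + p$num_frames)
      return(list(study = p$study_uid, series = p$series_uid,
                  instance = p$sop_instance_uid,
                  local_frame = frame - p$frame_offset))
  }
  dcmStop("frame_range", "frame %d not covered by any concatenation part",
          frame)
}

.backgroundValue <- function(metadata) {
  if (startsWith(metadata@photometric, "RGB") ||
      startsWith(metadata@photometric, "YBR")) 255L else 0L
}

#' Read a raw (pre-transform) region from a pyramid level
#'
#' Fetches only the tiles intersecting the region, decodes them, and
#' mosaics them into one array in the stored integer type. Missing
#' (sparse) tiles are filled with background — white (255) for RGB
#' brightfield, black (0) for monochrome fluorescence — and flagged in
#' the provenance mask. Edge tiles extending past the total pixel
#' matrix are cropped to the declared size.
#'
#' @param store Store holding the pixel data.
#' @param slide A [Slide-class].
#' @param level 1-based level index (or a [PyramidLevel-class]).
#' @param region Integer vector `c(row, col, height, width)`: 0-based
#'   top-left corner in this level's pixel coordinates plus size.
#' @param channel Channel identifier or index.
#' @return `list(pixels = <integer array h x w x samples>,
#'   fetched = <logical h x w provenance mask>)`.
#' @export
readRegion <- function(store, slide, level, region, channel = 1L) {
  lv <- if (is(level, "PyramidLevel")) level
        else volumeLevels(slide, channel)[[level]]
  md <- lv@metadata
  r0 <- region[1]; c0 <- region[2]; h <- region[3]; w <- region[4]
  if (h < 1 || w < 1) dcmStop("region", "region size must be positive")
  if (r0 + h <= 0 || c0 + w <= 0 || r0 >= md@total_rows ||
      c0 >= md@total_cols)
    dcmStop("region", "region lies entirely outside the total pixel matrix")
  samples <- as.integer(md@samples_per_pixel)
  bg <- .backgroundValue(md)
  out <- array(bg, dim = c(h, w, samples))
  fetched <- matrix(FALSE, h, w)
  grid <- lv@tile_grid
  tr0 <- max(0L, floor(r0 / md@tile_rows))
  tr1 <- min(grid@grid_rows - 1L, floor((r0 + h - 1) / md@tile_rows))
  tc0 <- max(0L, floor(c0 / md@tile_cols))
  tc1 <- min(grid@grid_cols - 1L, floor((c0 + w - 1) / md@tile_cols))
  for (tr in tr0:tr1) {
    for (tc in tc0:tc1) {
      frame <- grid@frame_map[tr + 1L, tc + 1L]
      # tile extent clipped to the total pixel matrix
      t_r0 <- tr * md@tile_rows; t_c0 <- tc * md@tile_cols
      rows_in <- intersect(seq(t_r0, min(t_r0 + md@tile_rows,
                                         md@total_rows) - 1),
                           seq(r0, r0 + h - 1))
      cols_in <- intersect(seq(t_c0, min(t_c0 + md@tile_cols,
                                         md@total_cols) - 1),
                           seq(c0, c0 + w - 1))
      if (!length(rows_in) || !length(cols_in)) next
      if (is.na(frame)) next  # background-filled, mask stays FALSE
      ref <- .resolveFrame(lv, frame)
      fr <- retrieveFrames(store, frameRequest(
        ref$study, ref$series, ref$instance, ref$local_frame))[[1L]]
      tile <- decodeFrame(fr$bytes, fr$mediaType, md)
      out[rows_in - r0 + 1, cols_in - c0 + 1, ] <-
        tile[rows_in - t_r0 + 1, cols_in - t_c0 + 1, , drop = FALSE]
      fetched[rows_in - r0 + 1, cols_in - c0 + 1] <- TRUE
    }
  }
  storage.mode(out) <- "integer"
  list(pixels = out, fetched = fetched)
}

#' Select the pyramid level for a requested resolution
#'
#' Returns the coarsest level whose pixel spacing does not exceed the
#' requested mm-per-pixel; if even the base level is coarser than the
#' request, the finest level is returned.
#'
#' @param levels List of [PyramidLevel-class], finest first.
#' @param mmPerPixel Requested spacing (> 0), mm.
#' @return 1-based level index.
#' @export
selectLevel <- function(levels, mmPerPixel) {
  stopifnot(mmPerPixel > 0)
  spacings <- vapply(levels, function(l) l@metadata@pixel_spacing_col_mm, 0)
  ok <- which(spacings <= mmPerPixel + 1e-12)
  if (!length(ok)) return(1L)
  ok[which.max(spacings[ok])]
}
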