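#' @title Frame pixel codec
#' @description Helpers converting between R integer arrays
#'   (row x column x sample) and DICOM frame byte streams. Uncompressed
#'   frames are row-major with interleaved samples (planar
#'   configuration 0), 8 or 16 bits per sample, little endian.
#' @name frame-codec
#' @keywords internal
NULL

MEDIA_OCTET_STREAM <- "application/octet-stream"
MEDIA_JPEG <- "image/jpeg"
MEDIA_JP2 <- "image/jp2"
MEDIA_JPX <- "image/jpx"
MEDIA_JLS <- "image/jls"
MEDIA_DICOM_JSON <- "application/dicom+json"
MEDIA_DICOM <- "application/dicom"

.mediaForSyntax <- function(ts) {
  switch(ts,
         "1.2.840.10008.1.2.1" = MEDIA_OCTET_STREAM,
         "1.2.840.10008.1.2.4.50" = MEDIA_JPEG,
         "1.2.840.10008.1.2.4.90" = MEDIA_JP2,
         "1.2.840.10008.1.2.4.80" = MEDIA_JLS,
         MEDIA_OCTET_STREAM)
}

# array [rows, cols, samples] (or matrix) -> uncompressed frame bytes
encodeFrameBytes <- function(arr, bits_allocated) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  v <- as.vector(aperm(arr, c(3L, 2L, 1L)))
  packIntLE(v, as.integer(bits_allocated) %/% 8L)
}

# uncompressed frame bytes -> array [rows, cols, samples]
decodeFrameBytes <- function(bytes, rows, cols, samples, bits_allocated) {
  nbytes <- as.integer(bits_allocated) %/% 8L
  expect <- rows * cols * samples * nbytes
  if (length(bytes) != expect)
    dcmStop("decode", "frame byte length %d does not match %dx%dx%d @%d bits",
            length(bytes), rows, cols, samples, bits_allocated)
  v <- unpackIntLE(bytes, nbytes)
  out <- aperm(array(v, dim = c(samples, cols, rows)), c(3L, 2L, 1L))
  storage.mode(out) <- "integer"
  out
}

encodeFrameJpeg <- function(arr, quality = 0.95) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  img <- arr / 255
  jpeg::writeJPEG(img, raw(), quality = quality)
}

decodeFrameJpeg <- function(bytes) {
  img <- tryCatch(jpeg::readJPEG(bytes),
                  error = function(e)
                    dcmStop("decode", "corrupt JPEG stream: %s",
                            conditionMessage(e)))
  arr <- roundHalfAway(img * 255)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  storage.mode(arr) <- "integer"
  arr
}

#' Decode one encoded frame into a pixel array
#'
#' @param bytes Raw frame byte stream.
#' @param mediaType Media type of `bytes` ("application/octet-stream"
#'   or "image/jpeg"; "image/jp2", "image/jpx" and "image/jls" are
#'   recognized but no codec is available for them and a negotiation
#'   error is raised).
#' @param metadata [SlideImageMetadata-class] describing the frame
#'   geometry and bit depth.
#' @return Integer array (tile_rows x tile_cols x samples).
#' @export
decodeFrame <- function(bytes, mediaType, metadata) {
  if (mediaType == MEDIA_OCTET_STREAM) {
    decodeFrameBytes(bytes, metadata@tile_rows, metadata@tile_cols,
                     metadata@samples_per_pixel, metadata@bits_allocated)
  } else if (mediaType == MEDIA_JPEG) {
    arr <- decodeFrameJpeg(bytes)
    if (!all(dim(arr)[1:2] == c(metadata@tile_rows, metadata@tile_cols)))
      dcmStop("decode", "decoded JPEG dimensions do not match tile metadata")
    arr
  } else if (mediaType %in% c(MEDIA_JP2, MEDIA_JPX, MEDIA_JLS)) {
    dcmStop("negotiation", "no codec available for media type %s", mediaType)
  } else {
    dcmStop("negotiation", "unsupported media type %s", mediaType)
  }
}

# Block-average downsampling (used to build pyramid levels and as the
# reference for the level-consistency property). `factor` integer >= 1.
blockAverage <- function(arr, factor) {
  if (factor == 1) return(arr)
  was_matrix <- is.matrix(arr)
  if (was_matrix) arr <- array(arr, dim = c(dim(arr), 1L))
  d <- dim(arr)
  out_r <- d[1] %/% factor
  out_c <- d[2] %/% factor
  arr <- arr[seq_len(out_r * factor), seq_len(out_c * factor), , drop = FALSE]
  out <- array(0, dim = c(out_r, out_c, d[3]))
  for (s in seq_len(d[3])) {
    m <- arr[, , s]
    m <- array(m, dim = c(factor, out_r, factor, out_c))
    out[, , s] <- apply(m, c(2, 4), mean)
  }
  out <- roundHalfAway(out)
  storage.mode(out) <- "integer"
  if (was_matrix) out <- out[, , 1L]
  out
}
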