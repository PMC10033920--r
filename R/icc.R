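#' @title ICC profile connection space transformation
#'
#' @description Color management for true-color brightfield images.
#'   DICOM images may embed an ICC input-device profile describing the
#'   scanner's color space; display requires transforming device RGB
#'   through the profile connection space (PCS, CIEXYZ relative to
#'   D50) into the display color space. This module constructs and
#'   parses matrix-shaper RGB profiles (3x3 primary matrix plus
#'   per-channel gamma tone curves) and applies the two-profile PCS
#'   transform. Matrix-shaper profiles are exact and analytically
#'   predictable, which is what the synthetic fixtures rely on;
#'   LUT-based vendor profiles are rejected with a profile error.
#' @name icc
NULL

# sRGB primaries adapted to D50 (Bradford), columns = R, G, B in XYZ.
.SRGB_D50 <- matrix(c(
  0.4360747, 0.2225045, 0.0139322,
  0.3850649, 0.7168786, 0.0971045,
  0.1430804, 0.0606169, 0.7141733
), nrow = 3)

# A wider-gamut primary set (opponent of sRGB in fixtures), D50.
.WIDE_D50 <- matrix(c(
  0.6097559, 0.3111242, 0.0194811,
  0.2052401, 0.6256560, 0.0608902,
  0.1492240, 0.0632197, 0.7448387
), nrow = 3)

.D50_WHITE <- c(0.9642, 1.0, 0.8249)

# big-endian helpers (ICC files are big endian)
.be32 <- function(v) {
  b <- packIntLE(v %% 2^32, 4L)
  b[4:1]
}
.be16 <- function(v) { b <- packIntLE(v, 2L); b[2:1] }
.rd_be32 <- function(raw, pos) {
  sum(as.integer(raw[pos:(pos + 3L)]) * c(2^24, 2^16, 2^8, 1))
}
.rd_s15f16 <- function(raw, pos) {
  v <- .rd_be32(raw, pos)
  if (v >= 2^31) v <- v - 2^32
  v / 65536
}

.xyz_tag <- function(xyz) {
  c(charToRaw("XYZ "), .be32(0),
    .be32(round(xyz[1] * 65536) %% 2^32),
    .be32(round(xyz[2] * 65536) %% 2^32),
    .be32(round(xyz[3] * 65536) %% 2^32))
}

.curv_tag <- function(gamma) {
  # curveType with a single u8Fixed8 gamma entry
  c(charToRaw("curv"), .be32(0), .be32(1), .be16(round(gamma * 256)))
}

.text_tag <- function(s) {
  c(charToRaw("text"), .be32(0), charToRaw(s), as.raw(0L))
}

#' Construct a synthetic matrix-shaper ICC profile
#'
#' Builds a valid RGB display-class ICC profile from a 3x3
#' primaries-to-XYZ matrix (D50-adapted) and per-channel gamma.
#' Variants: `"srgb"` (sRGB primaries), `"identity"` (alias of srgb —
#' pairing it with the srgb display profile yields an identity
#' transform), `"swapped"` (red and green primaries exchanged),
#' `"widegamut"` (wider primaries).
#'
#' @param variant Profile variant.
#' @param gamma Tone-curve exponent (default 2.2).
#' @param description Profile description text.
#' @return Raw vector of ICC profile bytes.
#' @export
createIccProfile <- function(variant = c("srgb", "identity", "swapped",
                                         "widegamut"),
                             gamma = 2.2, description = NULL) {
  variant <- match.arg(variant)
  M <- switch(variant,
              srgb = .SRGB_D50,
              identity = .SRGB_D50,
              swapped = .SRGB_D50[, c(2, 1, 3)],
              widegamut = .WIDE_D50)
  if (is.null(description)) description <- paste0("dicomslide ", variant)
  tags <- list(
    desc = .text_tag(description),
    wtpt = .xyz_tag(.D50_WHITE),
    rXYZ = .xyz_tag(M[, 1]), gXYZ = .xyz_tag(M[, 2]), bXYZ = .xyz_tag(M[, 3]),
    rTRC = .curv_tag(gamma), gTRC = .curv_tag(gamma), bTRC = .curv_tag(gamma),
    cprt = .text_tag("synthetic profile, no rights reserved")
  )
  sigs <- names(tags)
  n <- length(tags)
  tagtab_size <- 4 + 12 * n
  offset <- 128 + tagtab_size
  offsets <- integer(n); sizes <- integer(n)
  body <- raw(0)
  for (i in seq_len(n)) {
    tag <- tags[[i]]
    pad <- (4 - length(tag) %% 4) %% 4
    tag <- c(tag, raw(pad))
    offsets[i] <- offset + length(body)
    sizes[i] <- length(tags[[i]])
    body <- c(body, tag)
  }
  total <- 128 + tagtab_size + length(body)
  header <- c(
    .be32(total),                       # profile size
    charToRaw("none"),                  # preferred CMM
    .be32(0x02400000),                  # version 2.4
    charToRaw("mntr"),                  # device class
    charToRaw("RGB "),                  # data color space
    charToRaw("XYZ "),                  # PCS
    raw(12),                            # datetime (zeroed: deterministic)
    charToRaw("acsp"),
    raw(4),                             # platform
    .be32(0),                           # flags
    raw(8),                             # manufacturer, model
    raw(8),                             # attributes
    .be32(0),                           # rendering intent (perceptual)
    .be32(round(.D50_WHITE[1] * 65536)),
    .be32(round(.D50_WHITE[2] * 65536)),
    .be32(round(.D50_WHITE[3] * 65536)),
    raw(4),                             # creator
    raw(44)                             # reserved
  )
  stopifnot(length(header) == 128)
  tagtab <- .be32(n)
  for (i in seq_len(n))
    tagtab <- c(tagtab, charToRaw(sigs[i]), .be32(offsets[i]), .be32(sizes[i]))
  c(header, tagtab, body)
}

#' Parse a matrix-shaper ICC profile
#'
#' @param profile Raw profile bytes.
#' @return `list(matrix = 3x3 primaries-to-XYZ, gamma = length-3
#'   exponents, white = XYZ white point, description = text)`.
#' @export
parseIccProfile <- function(profile) {
  if (length(profile) < 132 ||
      rawToChar(profile[37:40]) != "acsp")
    dcmStop("profile", "not an ICC profile (missing 'acsp' signature)")
  ntags <- .rd_be32(profile, 129L)
  tags <- list()
  for (i in seq_len(ntags)) {
    base <- 132L + (i - 1L) * 12L
    sig <- rawToChar(profile[(base + 1):(base + 4)])
    off <- .rd_be32(profile, base + 5L)
    size <- .rd_be32(profile, base + 9L)
    tags[[sig]] <- profile[(off + 1):(off + size)]
  }
  need <- c("rXYZ", "gXYZ", "bXYZ", "rTRC", "gTRC", "bTRC")
  if (!all(need %in% names(tags)))
    dcmStop("profile",
            "profile is not matrix-shaper (missing %s); LUT profiles are not supported",
            paste(setdiff(need, names(tags)), collapse = ", "))
  read_xyz <- function(t) c(.rd_s15f16(t, 9L), .rd_s15f16(t, 13L),
                            .rd_s15f16(t, 17L))
  read_gamma <- function(t) {
    count <- .rd_be32(t, 9L)
    if (count == 0) return(1)
    if (count == 1)
      return((as.integer(t[13]) * 256 + as.integer(t[14])) / 256)
    dcmStop("profile", "sampled tone curves are not supported")
  }
  M <- cbind(read_xyz(tags$rXYZ), read_xyz(tags$gXYZ), read_xyz(tags$bXYZ))
  white <- if (!is.null(tags$wtpt)) read_xyz(tags$wtpt) else .D50_WHITE
  desc <- if (!is.null(tags$desc))
    rawToChar(.strip_pad(tags$desc[-(1:8)])) else ""
  list(matrix = M, gamma = c(read_gamma(tags$rTRC), read_gamma(tags$gTRC),
                             read_gamma(tags$bTRC)),
       white = white, description = desc)
}

#' ICC transform (input profile -> PCS -> display profile)
#'
#' @slot input_profile,display_profile Raw ICC profile bytes.
#' @slot rendering_intent One of "perceptual",
#'   "relative-colorimetric", "saturation", "absolute-colorimetric".
#'   Matrix-shaper pairs with a shared white point render identically
#'   under all intents; the slot records the request.
#' @export
setClass("IccTransform", representation(
  input_profile = "raw", display_profile = "raw",
  rendering_intent = "character"
))

setValidity("IccTransform", function(object) {
  ok <- tryCatch({
    parseIccProfile(object@input_profile)
    parseIccProfile(object@display_profile)
    TRUE
  }, error = function(e) conditionMessage(e))
  if (isTRUE(ok)) TRUE else ok
})

#' @param inputProfile Raw bytes of the image's input device profile.
#' @param displayProfile Raw bytes of the display profile (default:
#'   the built-in sRGB-targeting profile).
#' @param renderingIntent See slots.
#' @rdname IccTransform-class
#' @export
iccTransform <- function(inputProfile,
                         displayProfile = createIccProfile("srgb"),
                         renderingIntent = "perceptual") {
  new("IccTransform", input_profile = inputProfile,
      display_profile = displayProfile,
      rendering_intent = renderingIntent)
}

#' Apply an ICC transform to an 8-bit RGB array
#'
#' Device RGB is linearized with the input profile's tone curves,
#' mapped to PCS XYZ through its primary matrix, mapped back through
#' the inverse of the display profile's matrix, re-encoded with the
#' display tone curves and quantized to 8 bits. A pure function of the
#' input values; out-of-gamut PCS values are clipped to [0, 1] in
#' display-linear space.
#'
#' @param rgb Integer array (rows x cols x 3) of 8-bit values.
#' @param transform An [IccTransform-class].
#' @return Integer array of the same shape, display-space 8-bit.
#' @export
applyIcc <- function(rgb, transform) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L)
    dcmStop("profile", "applyIcc expects an rows x cols x 3 array")
  pin <- parseIccProfile(transform@input_profile)
  pout <- parseIccProfile(transform@display_profile)
  v <- matrix(as.numeric(rgb), ncol = 3L) / 255
  lin <- cbind(v[, 1]^pin$gamma[1], v[, 2]^pin$gamma[2], v[, 3]^pin$gamma[3])
  xyz <- lin %*% t(pin$matrix)
  lin2 <- xyz %*% t(solve(pout$matrix))
  lin2 <- pmin(pmax(lin2, 0), 1)
  enc <- cbind(lin2[, 1]^(1 / pout$gamma[1]), lin2[, 2]^(1 / pout$gamma[2]),
               lin2[, 3]^(1 / pout$gamma[3]))
  out <- array(roundHalfAway(enc * 255), dim = d)
  storage.mode(out) <- "integer"
  out
}
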