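#' @title Advanced Blending Presentation States
#'
#' @description Display settings for multiplexed immunofluorescence
#'   slides — which channels to show, each channel's VOI window and
#'   palette color LUT — persisted as DICOM Advanced Blending
#'   Presentation State objects so that they travel with the images
#'   and render identically on any conformant viewer. A presentation
#'   state never alters stored pixel values; it only specifies how
#'   they are transformed for display, and user overrides remain
#'   ephemeral (never written back into the state object).
#' @name presentation
NULL

#' One blended channel of a presentation state
#'
#' @slot study_uid,series_uid,sop_instance_uid Referenced image.
#' @slot optical_path Optical path identifier within the image.
#' @slot window [VoiWindow-class] for the channel.
#' @slot lut [PaletteColorLut-class] for the channel.
#' @export
setClass("BlendingChannel", representation(
  study_uid = "character", series_uid = "character",
  sop_instance_uid = "character", optical_path = "character",
  window = "VoiWindow", lut = "PaletteColorLut"
))

#' @param study,series,instance,opticalPath,window,lut See slots.
#' @rdname BlendingChannel-class
#' @export
blendingChannel <- function(study, series, instance, window, lut,
                            opticalPath = "") {
  new("BlendingChannel", study_uid = study, series_uid = series,
      sop_instance_uid = instance, optical_path = opticalPath,
      window = window, lut = lut)
}

#' A complete blending presentation state
#'
#' @slot label Human-readable state label.
#' @slot channels List of [BlendingChannel-class] (>= 1, unique
#'   references).
#' @slot study_uid Referenced study.
#' @export
setClass("BlendingState", representation(
  label = "character", channels = "list", study_uid = "character"
))

setValidity("BlendingState", function(object) {
  if (!length(object@channels)) return("a state needs at least one channel")
  refs <- vapply(object@channels, function(ch)
    paste(ch@sop_instance_uid, ch@optical_path), "")
  if (anyDuplicated(refs)) return("channel references must be unique")
  TRUE
})

#' @param label,channels,study See slots.
#' @rdname BlendingState-class
#' @export
blendingState <- function(label, channels, study) {
  new("BlendingState", label = label, channels = channels, study_uid = study)
}

setMethod("show", "BlendingState", function(object) {
  cat(sprintf("BlendingState \"%s\": %d channel(s)\n", object@label,
              length(object@channels)))
})

.slideInstanceUids <- function(slide) {
  unlist(lapply(slide@channels, function(levels)
    unlist(lapply(levels, function(lv)
      vapply(lv@parts, `[[`, "", "sop_instance_uid")))))
}

#' Encode a blending state as a DICOM presentation state dataset
#'
#' Window center/width and segmented palette descriptors are encoded
#' in binary form inside an Advanced Blending Sequence, one item per
#' channel. `parsePresentationState()` inverts the encoding.
#'
#' @param state A [BlendingState-class].
#' @param slide Optional [Slide-class]; when given, every channel
#'   reference is checked against the slide's instances and a dangling
#'   reference raises a reference error.
#' @param uids UID generator (see [uidFactory()]).
#' @return A `DicomDataset`.
#' @export
buildPresentationState <- function(state, slide = NULL, uids = uidFactory()) {
  if (!is.null(slide)) {
    known <- .slideInstanceUids(slide)
    for (ch in state@channels)
      if (!ch@sop_instance_uid %in% known)
        dcmStop("reference",
                "presentation state references instance %s not present in slide %s",
                ch@sop_instance_uid, slideIdentifier(slide))
  }
  items <- lapply(seq_along(state@channels), function(i) {
    ch <- state@channels[[i]]
    item <- dicomDataset(
      BlendingInputNumber = i,
      SeriesInstanceUID = ch@series_uid,
      OpticalPathIdentifier = ch@optical_path,
      ReferencedImageSequence = list(dicomDataset(
        ReferencedSOPClassUID = SOP_VL_WSI,
        ReferencedSOPInstanceUID = ch@sop_instance_uid)),
      SoftcopyVOILUTSequence = list(dicomDataset(
        WindowCenter = ch@window@center,
        WindowWidth = ch@window@width)),
      BlendingMode = "ADD"
    )
    pal <- .paletteIntoDataset(dicomDataset(), ch@lut)
    dcmSet(item, "PaletteColorLookupTableSequence", list(pal))
  })
  dicomDataset(
    SOPClassUID = SOP_ADV_BLENDING_PR,
    SOPInstanceUID = uids(),
    StudyInstanceUID = state@study_uid,
    SeriesInstanceUID = uids(),
    Modality = "PR",
    ContentLabel = gsub("[^A-Z0-9_ ]", "_", toupper(state@label)),
    ContentDescription = state@label,
    ContentCreatorName = "DICOMSLIDE",
    InstanceNumber = 1L,
    AdvancedBlendingSequence = items
  )
}

#' Decode a presentation state dataset back to a blending state
#'
#' @param ds A `DicomDataset` with the Advanced Blending Presentation
#'   State SOP class.
#' @return A [BlendingState-class].
#' @export
parsePresentationState <- function(ds) {
  if (!identical(dcmValue(ds, "SOPClassUID", ""), SOP_ADV_BLENDING_PR))
    dcmStop("wrong_sop_class",
            "dataset is not an Advanced Blending Presentation State")
  items <- dcmValue(ds, "AdvancedBlendingSequence", list())
  channels <- lapply(items, function(item) {
    refs <- dcmValue(item, "ReferencedImageSequence", list())
    if (!length(refs))
      dcmStop("descriptor", "blending item without image reference")
    voi <- dcmValue(item, "SoftcopyVOILUTSequence", list())
    if (!length(voi))
      dcmStop("descriptor", "blending item without VOI LUT")
    pal_seq <- dcmValue(item, "PaletteColorLookupTableSequence", list())
    if (!length(pal_seq))
      dcmStop("descriptor", "blending item without palette color LUT")
    blendingChannel(
      study = dcmValue(ds, "StudyInstanceUID", ""),
      series = dcmValue(item, "SeriesInstanceUID", ""),
      instance = dcmValue(refs[[1L]], "ReferencedSOPInstanceUID", ""),
      opticalPath = dcmValue(item, "OpticalPathIdentifier", ""),
      window = voiWindow(dcmValue(voi[[1L]], "WindowCenter"),
                         dcmValue(voi[[1L]], "WindowWidth")),
      lut = .parsePaletteFromDataset(pal_seq[[1L]],
                                     source = "presentation_state"))
  })
  blendingState(label = dcmValue(ds, "ContentDescription",
                                 dcmValue(ds, "ContentLabel", "")),
                channels = channels,
                study = dcmValue(ds, "StudyInstanceUID", ""))
}

#' Semantic equality of blending states
#'
#' Compares labels, channel references, window parameters and the
#' expanded palette tables (the binary segment layout may differ
#' while the color mapping is identical).
#'
#' @param a,b [BlendingState-class] objects.
#' @return Logical.
#' @export
blendingStateEqual <- function(a, b) {
  if (a@label != b@label || a@study_uid != b@study_uid ||
      length(a@channels) != length(b@channels)) return(FALSE)
  for (i in seq_along(a@channels)) {
    ca <- a@channels[[i]]; cb <- b@channels[[i]]
    if (ca@sop_instance_uid != cb@sop_instance_uid ||
        ca@optical_path != cb@optical_path ||
        ca@window@center != cb@window@center ||
        ca@window@width != cb@window@width) return(FALSE)
    if (!identical(expandPalette(ca@lut), expandPalette(cb@lut)))
      return(FALSE)
  }
  TRUE
}

.findChannelForReference <- function(slide, ch) {
  for (nm in names(slide@channels)) {
    levels <- slide@channels[[nm]]
    uids <- unlist(lapply(levels, function(lv)
      vapply(lv@parts, `[[`, "", "sop_instance_uid")))
    if (ch@sop_instance_uid %in% uids) return(nm)
    if (nzchar(ch@optical_path) && nm == ch@optical_path) return(nm)
  }
  dcmStop("reference", "no slide channel matches referenced instance %s",
          ch@sop_instance_uid)
}

#' Render a region under a blending presentation state
#'
#' For each referenced channel: read the raw region, apply the
#' channel's VOI window, map through its palette color LUT; then
#' additively blend the pseudocolor channels. Stored pixel data is
#' never modified.
#'
#' @param store,slide,level,region As in [readRegion()].
#' @param state A [BlendingState-class].
#' @return Integer 8-bit RGB array.
#' @export
renderWithState <- function(store, slide, level, region, state) {
  layers <- lapply(state@channels, function(ch) {
    nm <- .findChannelForReference(slide, ch)
    raw <- readRegion(store, slide, level, region, channel = nm)$pixels
    mono <- raw[, , 1L]
    applyPalette(applyVoi(mono, ch@window), ch@lut)
  })
  blendAdditive(layers)
}

# ---- default staining groups -----------------------------------------

#' Coded staining targets used by the default blending groups
#'
#' The canonical multiplexed immunofluorescence panel: DNA plus eight
#' antibody targets. Ships with placeholder codes under a private
#' coding scheme ("99DSL"); deployments matching vendor data should
#' substitute the codes their scanners write, since matching is on
#' (value, scheme).
#'
#' @return data.frame(name, code, scheme, meaning).
#' @export
stainingTargetCodes <- function() {
  data.frame(
    name = c("DNA", "CD45", "Pan-Cytokeratin", "Vimentin", "CD3", "CD68",
             "CD20", "E-cadherin", "PD1"),
    code = sprintf("ST-%03d", 1:9),
    scheme = "99DSL",
    meaning = c("DNA stain", "CD45 antigen", "Pan-cytokeratin",
                "Vimentin", "CD3 antigen", "CD68 antigen", "CD20 antigen",
                "E-cadherin", "Programmed cell death protein 1"),
    stringsAsFactors = FALSE
  )
}

.stainingConcept <- function(name) {
  tab <- stainingTargetCodes()
  row <- tab[tab$name == name, ]
  if (!nrow(row)) dcmStop("config", "unknown staining target %s", name)
  CodedConcept(row$code, row$scheme, row$meaning)
}

.default_group_targets <- list(
  "Group 1: DNA/CD45/Pan-Cytokeratin/Vimentin" =
    c("DNA", "CD45", "Pan-Cytokeratin", "Vimentin"),
  "Group 2: CD3/CD68/CD20" = c("CD3", "CD68", "CD20"),
  "Group 3: CD45/E-cadherin/PD1" = c("CD45", "E-cadherin", "PD1")
)

# Fixed palette cycle for generated states: positions within a group
# take successive hues so co-displayed targets stay distinguishable.
.palette_cycle <- list(
  c(0, 0, 255), c(0, 255, 0), c(255, 0, 0), c(255, 0, 255),
  c(0, 255, 255), c(255, 255, 0), c(255, 128, 0), c(255, 255, 255)
)

#' Build the default blending states for a multiplexed slide
#'
#' Creates one state per default staining group whose targets are
#' present on the slide (matched on coded-concept equality of the
#' channels' staining targets); groups with no matching channel are
#' omitted. Each channel gets a full-stored-range VOI window by
#' default (deterministic; an optimal-window estimator can be plugged
#' in via `windows`) and a single-hue linear ramp from a fixed
#' palette cycle.
#'
#' @param slide A [Slide-class] whose channels carry coded staining
#'   targets.
#' @param windows Optional named list (channel identifier ->
#'   [VoiWindow-class]) overriding the full-range default.
#' @return List of [BlendingState-class] (possibly empty).
#' @export
defaultStainingGroups <- function(slide, windows = NULL) {
  chan_targets <- lapply(slide@channels, function(levels) {
    md <- levels[[1L]]@metadata
    md@staining_targets
  })
  states <- list()
  for (label in names(.default_group_targets)) {
    targets <- .default_group_targets[[label]]
    channels <- list()
    hue <- 0L
    for (tg in targets) {
      concept <- .stainingConcept(tg)
      hue <- hue + 1L
      for (nm in names(chan_targets)) {
        hit <- any(vapply(chan_targets[[nm]], codedEqual, TRUE, b = concept))
        if (!hit) next
        md <- slide@channels[[nm]][[1L]]@metadata
        win <- if (!is.null(windows) && !is.null(windows[[nm]]))
          windows[[nm]]
        else voiWindow(2^(md@bits_stored - 1), 2^md@bits_stored)
        channels[[length(channels) + 1L]] <- blendingChannel(
          study = md@study_uid, series = md@series_uid,
          instance = md@sop_instance_uid,
          opticalPath = if (nrow(md@optical_paths))
            md@optical_paths$identifier[1] else "",
          window = win,
          lut = colorRampLut(.palette_cycle[[(hue - 1L) %%
                                               length(.palette_cycle) + 1L]],
                             source = "presentation_state"))
        break  # first matching channel carries the target
      }
    }
    if (length(channels))
      states[[length(states) + 1L]] <- blendingState(
        label, channels, channels[[1L]]@study_uid)
  }
  states
}
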