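#' @title DICOM JSON model conversion
#'
#' @description Converts between `DicomDataset` objects and the DICOM
#'   JSON model used by DICOMweb ("application/dicom+json"): one object
#'   per dataset keyed by eight-digit hexadecimal tag, each attribute an
#'   object with a `vr` member and a `Value` array (or `InlineBinary`
#'   base64 for bulk attributes). Pixel Data is never inlined; it is
#'   replaced by a `BulkDataURI` so metadata resources stay small, which
#'   matches how metadata is served over WADO-RS.
#' @name dicom-json
#' @keywords internal
NULL

#' Convert a dataset to the DICOM JSON model
#'
#' @param ds A `DicomDataset`.
#' @param bulkUriBase Base URI used to reference Pixel Data; `NULL`
#'   drops the Pixel Data attribute entirely.
#' @return A named list structured per the JSON model, ready for
#'   `jsonlite::toJSON(..., auto_unbox = TRUE)`.
#' @export
datasetToJsonModel <- function(ds, bulkUriBase = NULL) {
  out <- list()
  kws <- names(ds)
  ord <- order(vapply(kws, dcmTag, ""))
  for (kw in kws[ord]) {
    el <- ds[[kw]]
    tag <- dcmTag(kw)
    if (kw == "PixelData" || inherits(el$value, "dcm_encapsulated")) {
      if (!is.null(bulkUriBase)) {
        out[[tag]] <- list(vr = el$vr, BulkDataURI = paste0(bulkUriBase, "/pixeldata"))
      }
      next
    }
    entry <- list(vr = el$vr)
    if (el$vr == "SQ") {
      entry$Value <- lapply(el$value, datasetToJsonModel, bulkUriBase = bulkUriBase)
    } else if (is.raw(el$value)) {
      entry$InlineBinary <- jsonlite::base64_enc(el$value)
    } else if (el$vr == "PN") {
      entry$Value <- lapply(as.character(el$value),
                            function(p) list(Alphabetic = p))
    } else if (length(el$value) > 0) {
      entry$Value <- as.list(el$value)
    }
    out[[tag]] <- entry
  }
  out
}

#' Convert a DICOM JSON model object back to a dataset
#'
#' Inverse of [datasetToJsonModel()]; parsing is independent of the
#' ordering of attributes in the JSON document.
#'
#' @param obj A named list as produced by `jsonlite::fromJSON(...,
#'   simplifyVector = FALSE)`.
#' @return A `DicomDataset`.
#' @export
datasetFromJsonModel <- function(obj) {
  ds <- structure(list(), class = "DicomDataset")
  for (tag in sort(names(obj))) {
    entry <- obj[[tag]]
    kw <- .dcm_keyword_for_tag(toupper(tag))
    vr <- entry$vr
    if (!is.null(entry$BulkDataURI)) next  # bulk not resolved here
    if (vr == "SQ") {
      items <- lapply(entry$Value, datasetFromJsonModel)
      ds[[kw]] <- list(vr = "SQ", value = items)
    } else if (!is.null(entry$InlineBinary)) {
      ds[[kw]] <- list(vr = vr, value = jsonlite::base64_dec(entry$InlineBinary))
    } else {
      vals <- entry$Value
      if (is.null(vals) || length(vals) == 0) {
        value <- if (vr %in% c(.dcm_string_vrs, "IS", "DS")) character(0) else numeric(0)
        if (vr %in% .dcm_string_vrs) value <- character(0)
      } else if (vr == "PN") {
        value <- vapply(vals, function(p) {
          if (is.list(p)) as.character(p$Alphabetic) else as.character(p)
        }, "")
      } else if (vr %in% .dcm_string_vrs) {
        value <- vapply(vals, as.character, "")
      } else if (vr %in% c("IS", "US", "UL", "SS", "SL")) {
        value <- vapply(vals, as.numeric, 0)
      } else {
        value <- vapply(vals, as.numeric, 0)
      }
      ds[[kw]] <- list(vr = vr, value = value)
    }
  }
  ds
}

#' Serialize datasets to "application/dicom+json" text
#'
#' @param datasets List of `DicomDataset`s.
#' @param bulkUriBase See [datasetToJsonModel()].
#' @return A JSON string (array of dataset objects).
#' @export
datasetsToJson <- function(datasets, bulkUriBase = NULL) {
  models <- lapply(datasets, datasetToJsonModel, bulkUriBase = bulkUriBase)
  as.character(jsonlite::toJSON(models, auto_unbox = TRUE, digits = NA))
}

#' @rdname datasetsToJson
#' @param json JSON text as produced by `datasetsToJson()`.
#' @export
datasetsFromJson <- function(json) {
  objs <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  lapply(objs, datasetFromJsonModel)
}
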