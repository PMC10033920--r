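#' @title Query/retrieve/store interface
#'
#' @description A uniform interface over two backends: a local
#'   directory of DICOM Part-10 files with an on-disk index
#'   ([LocalStore-class]) and a DICOMweb service speaking QIDO-RS /
#'   WADO-RS / STOW-RS ([DicomWebStore-class]). The two are
#'   observationally equivalent: identical search results, identical
#'   metadata after canonicalization, and byte-identical uncompressed
#'   frames.
#' @name store
NULL

# ---- filters and requests --------------------------------------------

#' Search filter
#'
#' @slot level "study", "series" or "instance".
#' @slot constraints Named list of attribute keyword -> value.
#' @slot offset,limit Paging (0-based offset; limit > 0).
#' @export
setClass("SearchFilter", representation(
  level = "character", constraints = "list",
  offset = "numeric", limit = "numeric"
))

setValidity("SearchFilter", function(object) {
  if (!object@level %in% c("study", "series", "instance"))
    return("level must be study, series or instance")
  if (object@limit <= 0) return("limit must be > 0")
  TRUE
})

.supported_search_keys <- c("StudyInstanceUID", "SeriesInstanceUID",
                            "SOPInstanceUID", "SOPClassUID", "Modality")

#' @param level,constraints,offset,limit See slots.
#' @rdname SearchFilter-class
#' @export
searchFilter <- function(level = "study", constraints = list(),
                         offset = 0, limit = 10000) {
  bad <- setdiff(names(constraints), .supported_search_keys)
  if (length(bad))
    dcmStop("unsupported_filter",
            "unsupported filter attribute(s) %s; supported keys: %s",
            paste(bad, collapse = ", "),
            paste(.supported_search_keys, collapse = ", "))
  new("SearchFilter", level = level, constraints = constraints,
      offset = offset, limit = limit)
}

#' Frame retrieval request
#'
#' Frame numbers are 1-based (DICOM convention), unique and sorted.
#'
#' @slot study_uid,series_uid,instance_uid Instance reference.
#' @slot frames Integer vector of 1-based frame numbers.
#' @slot media_types Ordered vector of acceptable media types.
#' @export
setClass("FrameRequest", representation(
  study_uid = "character", series_uid = "character",
  instance_uid = "character", frames = "numeric", media_types = "character"
))

setValidity("FrameRequest", function(object) {
  f <- object@frames
  if (any(f < 1)) return("frame numbers must be >= 1")
  if (anyDuplicated(f)) return("frame numbers must be unique")
  if (is.unsorted(f)) return("frame numbers must be sorted")
  TRUE
})

#' @param study,series,instance,frames,mediaTypes See slots.
#' @rdname FrameRequest-class
#' @export
frameRequest <- function(study, series, instance, frames,
                         mediaTypes = c(MEDIA_OCTET_STREAM, MEDIA_JPEG)) {
  new("FrameRequest", study_uid = study, series_uid = series,
      instance_uid = instance, frames = as.numeric(frames),
      media_types = mediaTypes)
}

# ---- generics ---------------------------------------------------------

#' Store operations
#'
#' `searchObjects` runs a QIDO-style query; `retrieveMetadata` fetches
#' the full metadata of one instance (bulk pixel data excluded);
#' `retrieveFrames` fetches encoded frame pixel data; `storeInstances`
#' persists datasets and reports per-instance success.
#'
#' @param store A [LocalStore-class] or [DicomWebStore-class].
#' @param filter A [SearchFilter-class].
#' @return `searchObjects`: a list of named lists carrying the
#'   identifying UIDs of each result.
#' @export
setGeneric("searchObjects", function(store, filter) standardGeneric("searchObjects"))

#' @param study,series,instance UID strings.
#' @rdname searchObjects
#' @return `retrieveMetadata`: a `DicomDataset` (Pixel Data excluded).
#' @export
setGeneric("retrieveMetadata", function(store, study, series, instance)
  standardGeneric("retrieveMetadata"))

#' @param request A [FrameRequest-class].
#' @rdname searchObjects
#' @return `retrieveFrames`: a list, one entry per requested frame in
#'   request order, each `list(bytes = <raw>, mediaType = <string>)`.
#' @export
setGeneric("retrieveFrames", function(store, request)
  standardGeneric("retrieveFrames"))

#' @param datasets List of `DicomDataset`s (or `list(dataset,
#'   transferSyntax)` pairs for compressed pixel data).
#' @rdname searchObjects
#' @return `storeInstances`: a data.frame receipt with columns
#'   `sop_instance_uid`, `status` ("stored", "duplicate" or "failed")
#'   and `message`.
#' @export
setGeneric("storeInstances", function(store, datasets)
  standardGeneric("storeInstances"))

# ---- local store ------------------------------------------------------

#' Local directory store
#'
#' A directory tree of DICOM Part-10 files with a JSON index file
#' (rebuilt by scanning when absent).
#'
#' @slot path Directory path.
#' @export
setClass("LocalStore", representation(path = "character"))

#' @param path Directory (created if missing).
#' @rdname LocalStore-class
#' @export
localStore <- function(path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  new("LocalStore", path = path)
}

setMethod("show", "LocalStore", function(object) {
  idx <- .readIndex(object)
  cat(sprintf("LocalStore at %s: %d instance(s), %d study(ies)\n",
              object@path, nrow(idx), length(unique(idx$study))))
})

.indexPath <- function(store) file.path(store@path, "dicomslide-index.json")

.readIndex <- function(store) {
  empty <- data.frame(file = character(0), study = character(0),
                      series = character(0), instance = character(0),
                      sop_class = character(0), modality = character(0),
                      transfer_syntax = character(0),
                      stringsAsFactors = FALSE)
  p <- .indexPath(store)
  if (file.exists(p)) {
    idx <- jsonlite::fromJSON(p)
    if (length(idx) == 0 || is.null(dim(idx))) return(empty)
    return(as.data.frame(idx, stringsAsFactors = FALSE))
  }
  files <- list.files(store@path, pattern = "\\.dcm$", recursive = TRUE)
  if (!length(files)) return(empty)
  rows <- lapply(files, function(f) {
    parsed <- readDicomFile(file.path(store@path, f))
    ds <- parsed$dataset
    data.frame(file = f,
               study = dcmValue(ds, "StudyInstanceUID", ""),
               series = dcmValue(ds, "SeriesInstanceUID", ""),
               instance = dcmValue(ds, "SOPInstanceUID", ""),
               sop_class = dcmValue(ds, "SOPClassUID", ""),
               modality = dcmValue(ds, "Modality", ""),
               transfer_syntax = parsed$transferSyntax,
               stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, rows)
  .writeIndex(store, idx)
  idx
}

.writeIndex <- function(store, idx) {
  jsonlite::write_json(idx, .indexPath(store), dataframe = "rows")
}

.queryIndex <- function(idx, filter) {
  keep <- rep(TRUE, nrow(idx))
  cons <- filter@constraints
  colmap <- c(StudyInstanceUID = "study", SeriesInstanceUID = "series",
              SOPInstanceUID = "instance", SOPClassUID = "sop_class",
              Modality = "modality")
  for (k in names(cons)) keep <- keep & idx[[colmap[[k]]]] == cons[[k]]
  idx <- idx[keep, , drop = FALSE]
  lvl_cols <- switch(filter@level,
                     study = "study",
                     series = c("study", "series"),
                     instance = c("study", "series", "instance",
                                  "sop_class", "modality"))
  res <- unique(idx[, lvl_cols, drop = FALSE])
  res <- res[do.call(order, res), , drop = FALSE]
  lo <- filter@offset + 1
  hi <- min(nrow(res), filter@offset + filter@limit)
  if (lo > nrow(res)) return(res[0, , drop = FALSE])
  res[lo:hi, , drop = FALSE]
}

.resultNames <- c(study = "StudyInstanceUID", series = "SeriesInstanceUID",
                  instance = "SOPInstanceUID", sop_class = "SOPClassUID",
                  modality = "Modality")

.indexRowsToResults <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    out <- as.list(row)
    names(out) <- .resultNames[names(out)]
    out
  })
}

setMethod("searchObjects", "LocalStore", function(store, filter) {
  .indexRowsToResults(.queryIndex(.readIndex(store), filter))
})

.lookupInstance <- function(store, study, series, instance) {
  idx <- .readIndex(store)
  hit <- idx[idx$study == study & idx$series == series &
               idx$instance == instance, , drop = FALSE]
  if (nrow(hit) == 0)
    dcmStop("not_found", "instance %s not found in store", instance)
  hit[1, , drop = FALSE]
}

setMethod("retrieveMetadata", "LocalStore", function(store, study, series,
                                                     instance) {
  hit <- .lookupInstance(store, study, series, instance)
  parsed <- readDicomFile(file.path(store@path, hit$file))
  ds <- parsed$dataset
  ds[["PixelData"]] <- NULL
  # record the pixel-data transfer syntax so the parsed metadata knows
  # how frames will arrive (the file meta group is not part of the
  # metadata resource)
  dcmSet(ds, "TransferSyntaxUID", parsed$transferSyntax)
})

.extractFrames <- function(parsed, frames) {
  ds <- parsed$dataset
  nframes <- as.integer(dcmValue(ds, "NumberOfFrames", 1L))
  bad <- frames[frames > nframes]
  if (length(bad))
    dcmStop("frame_range", "frame %d out of range (instance has %d frames)",
            bad[1], nframes)
  px <- ds[["PixelData"]]
  if (is.null(px)) dcmStop("not_found", "instance carries no pixel data")
  if (inherits(px$value, "dcm_encapsulated")) {
    lapply(frames, function(f) unclass(px$value)[[f]])
  } else {
    rows <- dcmValue(ds, "Rows"); cols <- dcmValue(ds, "Columns")
    samples <- dcmValue(ds, "SamplesPerPixel", 1)
    nb <- dcmValue(ds, "BitsAllocated", 8) %/% 8
    fsize <- as.numeric(rows) * cols * samples * nb
    lapply(frames, function(f) {
      off <- (f - 1) * fsize
      px$value[(off + 1):(off + fsize)]
    })
  }
}

.negotiateMedia <- function(stored_media, accepted) {
  if (stored_media %in% accepted || "*/*" %in% accepted)
    return(list(media = stored_media, transcode = FALSE))
  if (MEDIA_OCTET_STREAM %in% accepted && stored_media == MEDIA_JPEG)
    return(list(media = MEDIA_OCTET_STREAM, transcode = TRUE))
  dcmStop("negotiation",
          "no acceptable media type: stored %s, accepted %s",
          stored_media, paste(accepted, collapse = ", "))
}

setMethod("retrieveFrames", "LocalStore", function(store, request) {
  hit <- .lookupInstance(store, request@study_uid, request@series_uid,
                         request@instance_uid)
  parsed <- readDicomFile(file.path(store@path, hit$file))
  stored_media <- .mediaForSyntax(parsed$transferSyntax)
  neg <- .negotiateMedia(stored_media, request@media_types)
  frames <- .extractFrames(parsed, request@frames)
  meta <- .parseTiledImageMetadata(
    dcmSet(parsed$dataset, "TransferSyntaxUID", parsed$transferSyntax))
  lapply(frames, function(fb) {
    if (neg$transcode) {
      arr <- decodeFrame(fb, stored_media, meta)
      fb <- encodeFrameBytes(arr, meta@bits_allocated)
    }
    list(bytes = fb, mediaType = neg$media)
  })
})

.normalizeStoredDataset <- function(d) {
  if (inherits(d, "DicomDataset"))
    list(dataset = d, transferSyntax = UID_EXPLICIT_VR_LE)
  else
    list(dataset = d$dataset,
         transferSyntax = if (is.null(d$transferSyntax)) UID_EXPLICIT_VR_LE
                          else d$transferSyntax)
}

setMethod("storeInstances", "LocalStore", function(store, datasets) {
  idx <- .readIndex(store)
  receipt <- data.frame(sop_instance_uid = character(0), status = character(0),
                        message = character(0), stringsAsFactors = FALSE)
  for (d in datasets) {
    d <- .normalizeStoredDataset(d)
    ds <- d$dataset
    uid <- dcmValue(ds, "SOPInstanceUID", "")
    if (!nzchar(uid)) {
      receipt <- rbind(receipt, data.frame(
        sop_instance_uid = "", status = "failed",
        message = "missing SOPInstanceUID", stringsAsFactors = FALSE))
      next
    }
    if (uid %in% idx$instance) {
      receipt <- rbind(receipt, data.frame(
        sop_instance_uid = uid, status = "duplicate",
        message = "SOP Instance UID already stored", stringsAsFactors = FALSE))
      next
    }
    fname <- paste0(uid, ".dcm")
    writeDicomFile(ds, file.path(store@path, fname),
                   transferSyntax = d$transferSyntax)
    idx <- rbind(idx, data.frame(
      file = fname,
      study = dcmValue(ds, "StudyInstanceUID", ""),
      series = dcmValue(ds, "SeriesInstanceUID", ""),
      instance = uid,
      sop_class = dcmValue(ds, "SOPClassUID", ""),
      modality = dcmValue(ds, "Modality", ""),
      transfer_syntax = d$transferSyntax,
      stringsAsFactors = FALSE))
    receipt <- rbind(receipt, data.frame(
      sop_instance_uid = uid, status = "stored", message = "",
      stringsAsFactors = FALSE))
  }
  .writeIndex(store, idx)
  receipt
})

# ---- multipart --------------------------------------------------------

buildMultipart <- function(parts, boundary) {
  crlf <- charToRaw("\r\n")
  chunks <- lapply(parts, function(p) {
    c(charToRaw(paste0("--", boundary, "\r\n",
                       "Content-Type: ", p$content_type, "\r\n",
                       "Content-Length: ", length(p$body), "\r\n\r\n")),
      p$body, crlf)
  })
  c(do.call(c, c(chunks, list(raw(0)))),
    charToRaw(paste0("--", boundary, "--\r\n")))
}

parseMultipart <- function(body, content_type) {
  if (!grepl("multipart/related", content_type, fixed = TRUE)) {
    return(list(list(content_type = sub(";.*$", "", content_type),
                     body = body)))
  }
  m <- regmatches(content_type,
                  regexec('boundary="?([^";]+)"?', content_type))[[1]]
  if (length(m) < 2) dcmStop("transport", "multipart body without boundary")
  delim <- charToRaw(paste0("--", m[2]))
  hits <- grepRaw(delim, body, fixed = TRUE, all = TRUE)
  parts <- list()
  hdr_sep <- charToRaw("\r\n\r\n")
  for (i in seq_len(length(hits) - 1L)) {
    seg <- body[(hits[i] + length(delim)):(hits[i + 1] - 1L)]
    # drop leading CRLF
    if (length(seg) >= 2 && seg[1] == charToRaw("\r")) seg <- seg[-(1:2)]
    split_at <- grepRaw(hdr_sep, seg, fixed = TRUE)
    if (length(split_at) == 0) next
    header <- rawToChar(seg[seq_len(split_at - 1L)])
    content <- seg[(split_at + 4L):length(seg)]
    # strip the trailing CRLF that precedes the next delimiter
    n <- length(content)
    if (n >= 2 && content[n - 1L] == charToRaw("\r")) content <- content[seq_len(n - 2L)]
    ct <- regmatches(header, regexec("Content-Type:\\s*([^\r\n]+)", header,
                                     ignore.case = TRUE))[[1]]
    parts[[length(parts) + 1L]] <- list(
      content_type = if (length(ct) >= 2) trimws(ct[2]) else "",
      body = content)
  }
  parts
}

# ---- DICOMweb store ---------------------------------------------------

#' DICOMweb client store
#'
#' Speaks the DICOMweb study service: Search (QIDO-RS), Retrieve
#' (WADO-RS) and Store (STOW-RS). HTTP is performed by a pluggable
#' `transport` function `(method, url, headers, body) -> list(status,
#' headers, body)`, which defaults to an HTTP transport built on the
#' curl package; [dicomwebHandler()] provides an in-process transport
#' serving a [LocalStore-class], used to exercise the full client
#' stack without a network.
#'
#' @slot base_url Service root URL.
#' @slot transport Transport function.
#' @slot token_provider `NULL`, or a function returning a bearer token
#'   injected as an `Authorization` header.
#' @export
setClass("DicomWebStore", representation(
  base_url = "character", transport = "function", token_provider = "ANY"
))

#' @param baseUrl,transport,tokenProvider See slots.
#' @rdname DicomWebStore-class
#' @export
dicomWebStore <- function(baseUrl, transport = NULL, tokenProvider = NULL) {
  if (is.null(transport)) transport <- .curlTransport
  new("DicomWebStore", base_url = sub("/$", "", baseUrl),
      transport = transport, token_provider = tokenProvider)
}

setMethod("show", "DicomWebStore", function(object) {
  cat("DicomWebStore at", object@base_url, "\n")
})

.curlTransport <- function(method, url, headers, body) {
  if (!requireNamespace("curl", quietly = TRUE))
    dcmStop("transport", "the curl package is required for HTTP transports")
  h <- curl::new_handle()
  curl::handle_setopt(h, customrequest = method)
  if (!is.null(body)) curl::handle_setopt(h, postfields = body)
  do.call(curl::handle_setheaders, c(list(h), as.list(headers)))
  resp <- tryCatch(curl::curl_fetch_memory(url, handle = h),
                   error = function(e)
                     dcmStop("transport", "HTTP request failed: %s",
                             conditionMessage(e)))
  hdrs <- curl::parse_headers_list(resp$headers)
  list(status = resp$status_code,
       headers = stats::setNames(unlist(hdrs), names(hdrs)),
       body = resp$content)
}

.webRequest <- function(store, method, path, headers = character(0),
                        body = NULL) {
  if (!is.null(store@token_provider))
    headers <- c(headers,
                 Authorization = paste("Bearer", store@token_provider()))
  resp <- store@transport(method, paste0(store@base_url, path), headers, body)
  if (resp$status >= 400)
    dcmStop("transport", "HTTP %d for %s %s", resp$status, method, path)
  resp
}

.headerValue <- function(headers, name) {
  hit <- which(tolower(names(headers)) == tolower(name))
  if (length(hit)) headers[[hit[1]]] else ""
}

.queryString <- function(params) {
  if (!length(params)) return("")
  paste0("?", paste(sprintf("%s=%s", names(params),
                            vapply(params, utils::URLencode, "",
                                   reserved = TRUE)),
                    collapse = "&"))
}

setMethod("searchObjects", "DicomWebStore", function(store, filter) {
  path <- switch(filter@level, study = "/studies", series = "/series",
                 instance = "/instances")
  params <- filter@constraints
  params$offset <- as.character(filter@offset)
  params$limit <- as.character(filter@limit)
  resp <- .webRequest(store, "GET", paste0(path, .queryString(params)),
                      headers = c(Accept = MEDIA_DICOM_JSON))
  if (resp$status == 204 || length(resp$body) == 0) return(list())
  datasets <- datasetsFromJson(rawToChar(resp$body))
  lapply(datasets, function(ds) {
    out <- list()
    for (kw in c("StudyInstanceUID", "SeriesInstanceUID", "SOPInstanceUID",
                 "SOPClassUID", "Modality"))
      if (dcmHas(ds, kw)) out[[kw]] <- dcmValue(ds, kw)
    out
  })
})

setMethod("retrieveMetadata", "DicomWebStore", function(store, study, series,
                                                        instance) {
  path <- sprintf("/studies/%s/series/%s/instances/%s/metadata",
                  study, series, instance)
  resp <- .webRequest(store, "GET", path,
                      headers = c(Accept = MEDIA_DICOM_JSON))
  datasets <- datasetsFromJson(rawToChar(resp$body))
  if (!length(datasets)) dcmStop("not_found", "no metadata returned")
  datasets[[1L]]
})

setMethod("retrieveFrames", "DicomWebStore", function(store, request) {
  path <- sprintf("/studies/%s/series/%s/instances/%s/frames/%s",
                  request@study_uid, request@series_uid,
                  request@instance_uid,
                  paste(format(request@frames, scientific = FALSE,
                               trim = TRUE), collapse = ","))
  accept <- paste(sprintf('multipart/related; type="%s"',
                          request@media_types), collapse = ", ")
  resp <- .webRequest(store, "GET", path, headers = c(Accept = accept))
  parts <- parseMultipart(resp$body,
                          .headerValue(resp$headers, "Content-Type"))
  lapply(parts, function(p) list(bytes = p$body, mediaType = p$content_type))
})

setMethod("storeInstances", "DicomWebStore", function(store, datasets) {
  boundary <- paste0("DicomSlideStow",
                     paste(sprintf("%02x", as.integer(
                       sample.int(256, 8, replace = TRUE) - 1)), collapse = ""))
  parts <- lapply(datasets, function(d) {
    d <- .normalizeStoredDataset(d)
    list(content_type = MEDIA_DICOM,
         body = writeDicomFile(d$dataset, NULL,
                               transferSyntax = d$transferSyntax))
  })
  body <- buildMultipart(parts, boundary)
  resp <- .webRequest(store, "POST", "/studies",
                      headers = c(
                        Accept = MEDIA_DICOM_JSON,
                        `Content-Type` = sprintf(
                          'multipart/related; type="%s"; boundary=%s',
                          MEDIA_DICOM, boundary)),
                      body = body)
  rec <- jsonlite::fromJSON(rawToChar(resp$body), simplifyVector = FALSE)
  do.call(rbind, lapply(rec, function(r)
    data.frame(sop_instance_uid = r$sop_instance_uid, status = r$status,
               message = if (is.null(r$message)) "" else r$message,
               stringsAsFactors = FALSE)))
})

# ---- in-process DICOMweb handler over a local store -------------------

#' In-process DICOMweb transport serving a local store
#'
#' Returns a transport function implementing the QIDO-RS / WADO-RS /
#' STOW-RS subset the client uses, backed by a [LocalStore-class].
#' Useful for tests, demos and air-gapped pipelines: a
#' [DicomWebStore-class] configured with this transport exercises the
#' complete client code path (URL construction, DICOM JSON, multipart
#' encoding) without a network.
#'
#' @param store A [LocalStore-class].
#' @return A transport function suitable for [dicomWebStore()].
#' @export
dicomwebHandler <- function(store) {
  force(store)
  function(method, url, headers, body) {
    path <- sub("^[a-z]+://[^/]+", "", url)
    query <- list()
    if (grepl("?", path, fixed = TRUE)) {
      qs <- sub("^[^?]*\\?", "", path)
      path <- sub("\\?.*$", "", path)
      for (kv in strsplit(qs, "&", fixed = TRUE)[[1]]) {
        p <- strsplit(kv, "=", fixed = TRUE)[[1]]
        query[[utils::URLdecode(p[1])]] <- utils::URLdecode(p[2])
      }
    }
    segs <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
    # tolerate a service prefix (e.g. /dicomweb/studies)
    root <- which(segs %in% c("studies", "series", "instances"))[1]
    if (!is.na(root) && root > 1) segs <- segs[root:length(segs)]
    ok_json <- function(x) list(
      status = 200L,
      headers = c(`Content-Type` = MEDIA_DICOM_JSON),
      body = charToRaw(x))

    if (method == "GET" && length(segs) == 1 &&
        segs[1] %in% c("studies", "series", "instances")) {
      level <- c(studies = "study", series = "series",
                 instances = "instance")[[segs[1]]]
      offset <- as.numeric(query$offset %||% 0)
      limit <- as.numeric(query$limit %||% 10000)
      query$offset <- NULL; query$limit <- NULL
      filter <- tryCatch(
        searchFilter(level, query, offset = offset, limit = limit),
        error = function(e) e)
      if (inherits(filter, "error"))
        return(list(status = 400L, headers = character(0),
                    body = charToRaw(conditionMessage(filter))))
      df <- .queryIndex(.readIndex(store), filter)
      models <- lapply(.indexRowsToResults(df), function(res) {
        ds <- structure(list(), class = "DicomDataset")
        for (kw in names(res)) ds <- dcmSet(ds, kw, res[[kw]])
        datasetToJsonModel(ds)
      })
      return(ok_json(as.character(jsonlite::toJSON(models,
                                                   auto_unbox = TRUE))))
    }

    if (method == "GET" && length(segs) == 7 && segs[7] == "metadata") {
      ds <- tryCatch(retrieveMetadata(store, segs[2], segs[4], segs[6]),
                     error = function(e) e)
      if (inherits(ds, "error"))
        return(list(status = 404L, headers = character(0),
                    body = charToRaw(conditionMessage(ds))))
      return(ok_json(datasetsToJson(list(ds))))
    }

    if (method == "GET" && length(segs) == 8 && segs[7] == "frames") {
      frames <- as.numeric(strsplit(segs[8], ",", fixed = TRUE)[[1]])
      accept <- .headerValue(headers, "Accept")
      types <- regmatches(accept, gregexpr('type="([^"]+)"', accept))[[1]]
      types <- sub('^type="', "", sub('"$', "", types))
      if (!length(types)) types <- "*/*"
      req <- tryCatch(frameRequest(segs[2], segs[4], segs[6], frames,
                                   mediaTypes = types),
                      error = function(e) e)
      out <- if (inherits(req, "error")) req else
        tryCatch(retrieveFrames(store, req), error = function(e) e)
      if (inherits(out, "error")) {
        status <- if (inherits(out, "dicomslide_negotiation")) 406L
                  else if (inherits(out, "dicomslide_frame_range")) 400L
                  else 404L
        return(list(status = status, headers = character(0),
                    body = charToRaw(conditionMessage(out))))
      }
      boundary <- "DicomSlideFrameBoundary"
      parts <- lapply(out, function(fr)
        list(content_type = fr$mediaType, body = fr$bytes))
      return(list(
        status = 200L,
        headers = c(`Content-Type` = sprintf(
          'multipart/related; type="%s"; boundary=%s',
          out[[1]]$mediaType, boundary)),
        body = buildMultipart(parts, boundary)))
    }

    if (method == "POST" && length(segs) == 1 && segs[1] == "studies") {
      parts <- parseMultipart(body, .headerValue(headers, "Content-Type"))
      datasets <- lapply(parts, function(p) {
        parsed <- readDicomFile(p$body)
        list(dataset = parsed$dataset, transferSyntax = parsed$transferSyntax)
      })
      receipt <- storeInstances(store, datasets)
      rec <- lapply(seq_len(nrow(receipt)), function(i) as.list(receipt[i, ]))
      return(ok_json(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))))
    }

    list(status = 404L, headers = character(0),
         body = charToRaw("no such resource"))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- multi-store configuration ---------------------------------------

#' Ordered store configuration with roles
#'
#' Deployments may keep images on one server and annotations on
#' another (e.g. a read-only image archive plus a writable annotation
#' store). `storeConfig` holds an ordered list of stores, each with a
#' set of roles from `images`, `annotations-read`, `annotations-write`;
#' `storeForRole` returns the first store carrying a role.
#'
#' @param stores List of store objects.
#' @param roles List of character vectors, parallel to `stores`.
#' @return `storeConfig`: an object of class `StoreConfig`.
#' @examples
#' s <- localStore(tempfile())
#' cfg <- storeConfig(list(s))   # one store, all roles
#' @export
storeConfig <- function(stores,
                        roles = rep(list(c("images", "annotations-read",
                                           "annotations-write")),
                                    length(stores))) {
  stopifnot(length(stores) == length(roles), length(stores) >= 1)
  structure(list(stores = stores, roles = roles), class = "StoreConfig")
}

#' @param config A `StoreConfig`.
#' @param role One of "images", "annotations-read", "annotations-write".
#' @rdname storeConfig
#' @export
storeForRole <- function(config, role) {
  for (i in seq_along(config$stores))
    if (role %in% config$roles[[i]]) return(config$stores[[i]])
  dcmStop("config", "no store configured with role %s", role)
}
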