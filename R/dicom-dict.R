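#' @title DICOM data dictionary subset
#' @description Tag numbers and value representations for the attributes
#'   used by the whole-slide imaging, presentation-state, structured
#'   reporting, bulk-annotation, segmentation and parametric-map objects
#'   this package reads and writes. Attributes are addressed by keyword
#'   throughout; unknown tags round-trip under a hexadecimal key.
#' @name dicom-dict
#' @keywords internal
NULL

# keyword, tag (GGGGEEEE uppercase hex), VR.  Ambiguous VRs ("US or SS",
# "OB or OW") are pinned to the variant used by the IODs in scope.
.dcm_dict_rows <- matrix(c(
  "FileMetaInformationGroupLength", "00020000", "UL",
  "FileMetaInformationVersion",     "00020001", "OB",
  "MediaStorageSOPClassUID",        "00020002", "UI",
  "MediaStorageSOPInstanceUID",     "00020003", "UI",
  "TransferSyntaxUID",              "00020010", "UI",
  "ImplementationClassUID",         "00020012", "UI",
  "ImplementationVersionName",      "00020013", "SH",
  "ImageType",                      "00080008", "CS",
  "InstanceCreationDate",           "00080012", "DA",
  "InstanceCreationTime",           "00080013", "TM",
  "SOPClassUID",                    "00080016", "UI",
  "SOPInstanceUID",                 "00080018", "UI",
  "StudyDate",                      "00080020", "DA",
  "ContentDate",                    "00080023", "DA",
  "StudyTime",                      "00080030", "TM",
  "ContentTime",                    "00080033", "TM",
  "AccessionNumber",                "00080050", "SH",
  "Modality",                       "00080060", "CS",
  "Manufacturer",                   "00080070", "LO",
  "CodeValue",                      "00080100", "SH",
  "CodingSchemeDesignator",         "00080102", "SH",
  "CodeMeaning",                    "00080104", "LO",
  "MappingResource",                "00080105", "CS",
  "TimezoneOffsetFromUTC",          "00080201", "SH",
  "SeriesDescription",              "0008103E", "LO",
  "ReferencedSeriesSequence",       "00081115", "SQ",
  "ReferencedImageSequence",        "00081140", "SQ",
  "ReferencedSOPClassUID",          "00081150", "UI",
  "ReferencedSOPInstanceUID",       "00081155", "UI",
  "ReferencedSOPSequence",          "00081199", "SQ",
  "SourceImageSequence",            "00082112", "SQ",
  "DerivationImageSequence",        "00089124", "SQ",
  "VolumetricProperties",           "00089206", "CS",
  "PatientName",                    "00100010", "PN",
  "PatientID",                      "00100020", "LO",
  "PatientBirthDate",               "00100030", "DA",
  "PatientSex",                     "00100040", "CS",
  "IlluminationWaveLength",         "00220055", "FL",
  "StudyInstanceUID",               "0020000D", "UI",
  "SeriesInstanceUID",              "0020000E", "UI",
  "StudyID",                        "00200010", "SH",
  "SeriesNumber",                   "00200011", "IS",
  "InstanceNumber",                 "00200013", "IS",
  "FrameOfReferenceUID",            "00200052", "UI",
  "SOPInstanceUIDOfConcatenationSource", "00200242", "UI",
  "PositionReferenceIndicator",     "00201040", "LO",
  "ConcatenationUID",               "00209161", "UI",
  "InConcatenationNumber",          "00209162", "US",
  "ConcatenationFrameOffsetNumber", "00209228", "UL",
  "DimensionOrganizationType",      "00209311", "CS",
  "SamplesPerPixel",                "00280002", "US",
  "PhotometricInterpretation",      "00280004", "CS",
  "PlanarConfiguration",            "00280006", "US",
  "NumberOfFrames",                 "00280008", "IS",
  "Rows",                           "00280010", "US",
  "Columns",                        "00280011", "US",
  "PixelSpacing",                   "00280030", "DS",
  "BitsAllocated",                  "00280100", "US",
  "BitsStored",                     "00280101", "US",
  "HighBit",                        "00280102", "US",
  "PixelRepresentation",            "00280103", "US",
  "BurnedInAnnotation",             "00280301", "CS",
  "LossyImageCompression",          "00282110", "CS",
  "RedPaletteColorLookupTableDescriptor",   "00281101", "US",
  "GreenPaletteColorLookupTableDescriptor", "00281102", "US",
  "BluePaletteColorLookupTableDescriptor",  "00281103", "US",
  "RedPaletteColorLookupTableData",         "00281201", "OW",
  "GreenPaletteColorLookupTableData",       "00281202", "OW",
  "BluePaletteColorLookupTableData",        "00281203", "OW",
  "SegmentedRedPaletteColorLookupTableData",   "00281221", "OW",
  "SegmentedGreenPaletteColorLookupTableData", "00281222", "OW",
  "SegmentedBluePaletteColorLookupTableData",  "00281223", "OW",
  "WindowCenter",                   "00281050", "DS",
  "WindowWidth",                    "00281051", "DS",
  "VOILUTFunction",                 "00281056", "CS",
  "LUTExplanation",                 "00283003", "LO",
  "SoftcopyVOILUTSequence",         "00283110", "SQ",
  "ICCProfile",                     "00282000", "OB",
  "ColorSpace",                     "00282002", "CS",
  "PixelMeasuresSequence",          "00289110", "SQ",
  "ReferencedFrameOfReferenceUID",  "30060024", "UI",
  "MeasurementUnitsCodeSequence",   "004008EA", "SQ",
  "PerformedProcedureStepStartDate","00400244", "DA",
  "PerformedProcedureStepStartTime","00400245", "TM",
  "ContainerIdentifier",            "00400512", "LO",
  "IssuerOfTheContainerIdentifierSequence", "00400513", "SQ",
  "ContainerTypeCodeSequence",      "00400518", "SQ",
  "SpecimenIdentifier",             "00400551", "LO",
  "SpecimenUID",                    "00400554", "UI",
  "AcquisitionContextSequence",     "00400555", "SQ",
  "SpecimenDescriptionSequence",    "00400560", "SQ",
  "SpecimenShortDescription",       "00400600", "LO",
  "SpecimenPreparationSequence",    "00400610", "SQ",
  "SpecimenPreparationStepContentItemSequence", "00400612", "SQ",
  "XOffsetInSlideCoordinateSystem", "0040072A", "DS",
  "YOffsetInSlideCoordinateSystem", "0040073A", "DS",
  "ZOffsetInSlideCoordinateSystem", "0040074A", "DS",
  "RealWorldValueMappingSequence",  "00409096", "SQ",
  "LUTLabel",                       "00409210", "SH",
  "RealWorldValueLastValueMapped",  "00409211", "US",
  "RealWorldValueLUTData",          "00409212", "FD",
  "RealWorldValueFirstValueMapped", "00409216", "US",
  "QuantityDefinitionSequence",     "00409220", "SQ",
  "RealWorldValueIntercept",        "00409224", "FD",
  "RealWorldValueSlope",            "00409225", "FD",
  "RelationshipType",               "0040A010", "CS",
  "ObservationDateTime",            "0040A032", "DT",
  "ValueType",                      "0040A040", "CS",
  "ConceptNameCodeSequence",        "0040A043", "SQ",
  "ContinuityOfContent",            "0040A050", "CS",
  "PersonName",                     "0040A123", "PN",
  "UID",                            "0040A124", "UI",
  "TextValue",                      "0040A160", "UT",
  "ConceptCodeSequence",            "0040A168", "SQ",
  "PurposeOfReferenceCodeSequence", "0040A170", "SQ",
  "AnnotationGroupNumber",          "0040A180", "US",
  "MeasuredValueSequence",          "0040A300", "SQ",
  "NumericValue",                   "0040A30A", "DS",
  "CurrentRequestedProcedureEvidenceSequence", "0040A375", "SQ",
  "CompletionFlag",                 "0040A491", "CS",
  "VerificationFlag",               "0040A493", "CS",
  "ContentTemplateSequence",        "0040A504", "SQ",
  "ContentSequence",                "0040A730", "SQ",
  "TemplateIdentifier",             "0040DB00", "CS",
  "ImagedVolumeWidth",              "00480001", "FL",
  "ImagedVolumeHeight",             "00480002", "FL",
  "ImagedVolumeDepth",              "00480003", "FL",
  "TotalPixelMatrixColumns",        "00480006", "UL",
  "TotalPixelMatrixRows",           "00480007", "UL",
  "TotalPixelMatrixOriginSequence", "00480008", "SQ",
  "SpecimenLabelInImage",           "00480010", "CS",
  "FocusMethod",                    "00480011", "CS",
  "ExtendedDepthOfField",           "00480012", "CS",
  "ImageOrientationSlide",          "00480102", "DS",
  "OpticalPathSequence",            "00480105", "SQ",
  "OpticalPathIdentifier",          "00480106", "SH",
  "OpticalPathDescription",         "00480107", "ST",
  "PaletteColorLookupTableSequence","00480120", "SQ",
  "PlanePositionSlideSequence",     "0048021A", "SQ",
  "ColumnPositionInTotalImagePixelMatrix", "0048021E", "SL",
  "RowPositionInTotalImagePixelMatrix",    "0048021F", "SL",
  "SegmentationType",               "00620001", "CS",
  "SegmentSequence",                "00620002", "SQ",
  "SegmentedPropertyCategoryCodeSequence", "00620003", "SQ",
  "SegmentNumber",                  "00620004", "US",
  "SegmentLabel",                   "00620005", "LO",
  "SegmentAlgorithmType",           "00620008", "CS",
  "SegmentAlgorithmName",           "00620009", "LO",
  "ReferencedSegmentNumber",        "0062000B", "US",
  "MaximumFractionalValue",         "0062000E", "US",
  "SegmentedPropertyTypeCodeSequence", "0062000F", "SQ",
  "SegmentationFractionalType",     "00620010", "CS",
  "PointCoordinatesData",           "00660016", "OF",
  "DoublePointCoordinatesData",     "00660022", "OD",
  "LongPrimitivePointIndexList",    "00660040", "OL",
  "MeasurementsSequence",           "00660121", "SQ",
  "FloatingPointValues",            "00660125", "OF",
  "MeasurementValuesSequence",      "00660132", "SQ",
  "AnnotationCoordinateType",       "006A0001", "CS",
  "AnnotationGroupSequence",        "006A0002", "SQ",
  "AnnotationGroupUID",             "006A0003", "UI",
  "AnnotationGroupLabel",           "006A0005", "LO",
  "AnnotationGroupDescription",     "006A0006", "UT",
  "AnnotationGroupGenerationType",  "006A0007", "CS",
  "AnnotationPropertyCategoryCodeSequence", "006A0009", "SQ",
  "AnnotationPropertyTypeCodeSequence",     "006A000A", "SQ",
  "NumberOfAnnotations",            "006A000C", "UL",
  "AnnotationAppliesToAllOpticalPaths", "006A000D", "CS",
  "AnnotationIndexList",            "006A0011", "OL",
  "GraphicData",                    "00700022", "FL",
  "GraphicType",                    "00700023", "CS",
  "ContentLabel",                   "00700080", "CS",
  "ContentDescription",             "00700081", "LO",
  "ContentCreatorName",             "00700084", "PN",
  "FiducialUID",                    "0070031A", "UI",
  "AdvancedBlendingSequence",       "00701B01", "SQ",
  "BlendingInputNumber",            "00701B02", "US",
  "BlendingDisplayInputSequence",   "00701B03", "SQ",
  "BlendingDisplaySequence",        "00701B04", "SQ",
  "BlendingMode",                   "00701B06", "CS",
  "PresentationLUTShape",           "20500020", "CS",
  "SharedFunctionalGroupsSequence", "52009229", "SQ",
  "PerFrameFunctionalGroupsSequence","52009230", "SQ",
  "FloatPixelData",                 "7FE00008", "OF",
  "PixelData",                      "7FE00010", "OW"
), ncol = 3, byrow = TRUE)

.dcm_dict <- local({
  d <- data.frame(keyword = .dcm_dict_rows[, 1], tag = .dcm_dict_rows[, 2],
                  vr = .dcm_dict_rows[, 3], stringsAsFactors = FALSE)
  rownames(d) <- d$keyword
  d
})

.dcm_tag_to_keyword <- local({
  x <- .dcm_dict$keyword
  names(x) <- .dcm_dict$tag
  x
})

#' Look up the tag or VR of a DICOM attribute keyword
#'
#' @param keyword Attribute keyword, e.g. `"SOPInstanceUID"`, or an
#'   eight-digit uppercase hexadecimal tag for attributes outside the
#'   built-in dictionary.
#' @return `dcmTag()` the `"GGGGEEEE"` tag string; `dcmVR()` the value
#'   representation code.
#' @keywords internal
dcmTag <- function(keyword) {
  if (grepl("^[0-9A-F]{8}$", keyword)) return(keyword)
  row <- .dcm_dict[keyword, ]
  if (is.na(row$tag[1L])) {
    stop(dcmCondition("dicom_unknown_keyword",
                      sprintf("unknown DICOM attribute keyword '%s'", keyword)))
  }
  row$tag
}

#' @rdname dcmTag
#' @keywords internal
dcmVR <- function(keyword) {
  if (grepl("^[0-9A-F]{8}$", keyword)) {
    kw <- .dcm_tag_to_keyword[keyword]
    if (!is.na(kw)) return(.dcm_dict[kw, "vr"])
    return("UN")
  }
  row <- .dcm_dict[keyword, ]
  if (is.na(row$vr[1L])) {
    stop(dcmCondition("dicom_unknown_keyword",
                      sprintf("unknown DICOM attribute keyword '%s'", keyword)))
  }
  row$vr
}

.dcm_keyword_for_tag <- function(tag) {
  kw <- .dcm_tag_to_keyword[tag]
  if (is.na(kw)) tag else unname(kw)
}
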