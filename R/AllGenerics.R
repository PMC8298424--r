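#' @rdname CoverageTrack-class
#' @param object,x a package object.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("normalization", function(x) standardGeneric("normalization"))

#' @rdname BinnedCounts-class
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname NBHMMFit-class
#' @export
setGeneric("enrichedPosterior", function(x) standardGeneric("enrichedPosterior"))

#' @rdname MetaplotMatrix-class
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))

#' @rdname MetaplotMatrix-class
#' @export
setGeneric("meanProfile", function(x) standardGeneric("meanProfile"))
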