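#' @rdname SiteEvidence-accessors
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))
#' @rdname SiteEvidence-accessors
#' @export
setGeneric("pos", function(x) standardGeneric("pos"))
#' @rdname SiteEvidence-accessors
#' @export
setGeneric("refBase", function(x) standardGeneric("refBase"))
#' @rdname SiteEvidence-accessors
#' @export
setGeneric("altBase", function(x) standardGeneric("altBase"))
#' @rdname SiteEvidence-accessors
#' @export
setGeneric("totalDepth", function(x) standardGeneric("totalDepth"))
#' @rdname SiteEvidence-accessors
#' @export
setGeneric("altDepth", function(x) standardGeneric("altDepth"))
#' @rdname SiteEvidence-accessors
#' @export
setGeneric("altFwd", function(x) standardGeneric("altFwd"))
#' @rdname SiteEvidence-accessors
#' @export
setGeneric("altRev", function(x) standardGeneric("altRev"))
#' @rdname SiteEvidence-accessors
#' @export
setGeneric("rrps", function(x) standardGeneric("rrps"))
#' @rdname SiteEvidence-accessors
#' @export
setGeneric("alignerId", function(x) standardGeneric("alignerId"))
#' @rdname SiteEvidence-accessors
#' @export
setGeneric("variantKey", function(x) standardGeneric("variantKey"))

#' @rdname siteStatistics
#' @export
setGeneric("alleleRatio", function(x) standardGeneric("alleleRatio"))
#' @rdname siteStatistics
#' @export
setGeneric("strandBiasRatio", function(x) standardGeneric("strandBiasRatio"))

#' @rdname EvalResult-accessors
#' @export
setGeneric("tpCount", function(x) standardGeneric("tpCount"))
#' @rdname EvalResult-accessors
#' @export
setGeneric("fpCount", function(x) standardGeneric("fpCount"))
#' @rdname EvalResult-accessors
#' @export
setGeneric("fnCount", function(x) standardGeneric("fnCount"))
#' @rdname EvalResult-accessors
#' @export
setGeneric("noCoverageCount", function(x) standardGeneric("noCoverageCount"))
#' @rdname EvalResult-accessors
#' @export
setGeneric("precisionOf", function(x) standardGeneric("precisionOf"))
#' @rdname EvalResult-accessors
#' @export
setGeneric("recallOf", function(x) standardGeneric("recallOf"))
#' @rdname EvalResult-accessors
#' @export
setGeneric("fScoreOf", function(x) standardGeneric("fScoreOf"))
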