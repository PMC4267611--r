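#' @import methods
#' @importFrom stats rbinom runif setNames
#' @importFrom utils read.table write.table
NULL

.BASES <- c("A", "C", "G", "T")

#' Per-site, per-aligner read evidence
#'
#' `SiteEvidence` holds one row per (site, alternate allele, aligner):
#' chromosome, 1-based position, reference and alternate base, total read
#' depth t, alternate-allele read depth aa, its forward/reverse strand
#' split, and (optionally) the read-position rank-sum Z-score comparing
#' within-read offsets of alternate- versus reference-supporting bases.
#'
#' @slot evidence a `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `totalDepth`, `altDepth`, `altFwd`, `altRev`, `rrps`, `alignerId`.
#'
#' @seealso [siteEvidence()] for the validated constructor,
#'   [applyFilters()] for the filter battery.
#' @export
setClass("SiteEvidence", slots = c(evidence = "data.frame"))

setValidity("SiteEvidence", function(object) {
  ev <- object@evidence
  need <- c("chrom", "pos", "ref", "alt", "totalDepth", "altDepth",
            "altFwd", "altRev", "rrps", "alignerId")
  if (!all(need %in% names(ev)))
    return(paste("missing columns:", paste(setdiff(need, names(ev)), collapse = ", ")))
  if (nrow(ev) == 0L) return(TRUE)
  if (any(ev$pos < 1L)) return("pos must be >= 1")
  if (!all(ev$ref %in% .BASES) || !all(ev$alt %in% .BASES))
    return("ref and alt must be single uppercase bases A/C/G/T")
  if (any(ev$ref == ev$alt)) return("ref must differ from alt")
  if (any(ev$totalDepth < 0L) || any(ev$altDepth < 0L))
    return("depths must be non-negative")
  if (any(ev$altDepth > ev$totalDepth))
    return("altDepth must not exceed totalDepth")
  if (any(ev$altFwd + ev$altRev != ev$altDepth))
    return("altFwd + altRev must equal altDepth")
  TRUE
})

#' Hard-filter threshold set
#'
#' Thresholds for the five-site filter battery. Depth minima are
#' inclusive (`>=`); the allele-fraction and strand-bias comparisons are
#' strict (`>`), with the high-coverage thresholds applied when total
#' depth reaches `depthSwitch`; the rank-sum bound is the open interval
#' (`rrpsLower`, `rrpsUpper`).
#'
#' @seealso [filterConfig()], [singleCellFilterConfig()], [applyFilters()]
#' @export
setClass("FilterConfig", slots = c(
  minTotalDepth = "integer",
  minAltDepth   = "integer",
  depthSwitch   = "integer",
  ratioLowCov   = "numeric",
  ratioHighCov  = "numeric",
  sbsLowCov     = "numeric",
  sbsHighCov    = "numeric",
  rrpsLower     = "numeric",
  rrpsUpper     = "numeric"
))

setValidity("FilterConfig", function(object) {
  if (object@minTotalDepth < 0L || object@minAltDepth < 0L)
    return("depth minima must be non-negative")
  if (!(object@ratioHighCov > 0 && object@ratioHighCov <= object@ratioLowCov &&
        object@ratioLowCov <= 1))
    return("need 0 < ratioHighCov <= ratioLowCov <= 1")
  if (!(object@sbsHighCov > 0 && object@sbsHighCov <= object@sbsLowCov &&
        object@sbsLowCov <= 1))
    return("need 0 < sbsHighCov <= sbsLowCov <= 1")
  if (!(object@rrpsLower < object@rrpsUpper))
    return("rrpsLower must be < rrpsUpper")
  TRUE
})

#' Benchmark truth set
#'
#' Genotyping-array ("chip") or exome-sequencing ("wes") truth. Each row
#' maps a position (and alternate allele, where known) to a truth genotype
#' in hom_ref / het / hom_alt. For the wes kind a per-position sequencing
#' `coverage` column gates the precision denominator.
#'
#' @slot table data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`, and `coverage` (NA allowed for chip).
#' @slot kind `"chip"` or `"wes"`.
#' @seealso [truthSet()], [evaluateCalls()]
#' @export
setClass("TruthSet", slots = c(table = "data.frame", kind = "character"))

setValidity("TruthSet", function(object) {
  if (!object@kind %in% c("chip", "wes")) return("kind must be 'chip' or 'wes'")
  tb <- object@table
  need <- c("chrom", "pos", "ref", "alt", "genotype", "coverage")
  if (!all(need %in% names(tb)))
    return(paste("missing columns:", paste(setdiff(need, names(tb)), collapse = ", ")))
  if (nrow(tb) == 0L) return(TRUE)
  if (anyDuplicated(paste(tb$chrom, tb$pos)))
    return("positions must be unique")
  if (!all(tb$genotype %in% c("hom_ref", "het", "hom_alt")))
    return("genotype must be hom_ref/het/hom_alt")
  if (object@kind == "wes" && any(is.na(tb$coverage) | tb$coverage < 0))
    return("wes coverage must be present and non-negative")
  TRUE
})

#' Benchmark result
#'
#' Counts and derived metrics from comparing a call set with a truth set:
#' TP/FP/FN, the number of calls dropped for lacking truth coverage,
#' precision TP/(TP+FP), recall TP/(TP+FN) and F = 2PR/(P+R).
#'
#' @seealso [evaluateCalls()], [evalFromCounts()], [evalFromTotals()]
#' @export
setClass("EvalResult", slots = c(
  tp = "integer", fp = "integer", fn = "integer",
  nNoCoverage = "integer",
  precision = "numeric", recall = "numeric", fScore = "numeric"
))

#' Simulation configuration
#'
#' Parameters of the synthetic paired-aligner evidence generator; see
#' [simConfig()] for field meanings and defaults.
#'
#' @seealso [simConfig()], [simulateEsnvData()]
#' @export
setClass("SimConfig", slots = c(
  seed = "integer",
  nSites = "integer",
  fracStrandBias = "numeric",
  fracEndClustered = "numeric",
  fracLowAltDepth = "numeric",
  fracHet = "numeric",
  hetAlleleFraction = "numeric",
  homAlleleFraction = "numeric",
  depthRange = "integer",
  endClusteredDepthRange = "integer",
  alignerConcordance = "numeric",
  alignerDropout = "numeric",
  knownFraction = "numeric",
  tsFraction = "numeric",
  regionMixture = "numeric",
  readLength = "integer",
  alignerIds = "character",
  nAssayedHomRef = "integer"
))

setValidity("SimConfig", function(object) {
  probs <- c(object@fracStrandBias, object@fracEndClustered,
             object@fracLowAltDepth, object@fracHet,
             object@hetAlleleFraction, object@homAlleleFraction,
             object@alignerConcordance, object@alignerDropout,
             object@knownFraction, object@tsFraction, object@regionMixture)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    return("probabilities must lie in [0, 1]")
  if (object@fracStrandBias + object@fracEndClustered + object@fracLowAltDepth > 1)
    return("artifact fractions must sum to at most 1")
  if (object@nSites < 1L) return("nSites must be >= 1")
  if (length(object@alignerIds) != 2L || anyDuplicated(object@alignerIds))
    return("alignerIds must be two distinct labels")
  if (abs(sum(object@regionMixture) - 1) > 1e-8)
    return("regionMixture must sum to 1")
  if (!all(names(object@regionMixture) %in% c(.REGION_CLASSES, "intergenic")))
    return("regionMixture names must be gene-model feature classes or 'intergenic'")
  if (object@depthRange[1] < 1L || object@depthRange[2] < object@depthRange[1])
    return("depthRange must be an increasing positive pair")
  TRUE
})
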