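#' Construct per-site read evidence
#'
#' Builds a validated [SiteEvidence-class] object, one row per
#' (site, alternate allele, aligner). When within-read offset lists are
#' supplied and `rrps` is missing, the read-position rank-sum Z-score is
#' computed with [readPosRankSum()]; a precomputed upstream value (for
#' example a VCF `ReadPosRankSum` INFO field) is accepted verbatim.
#'
#' @param chrom character, chromosome names.
#' @param pos integer, 1-based positions.
#' @param ref,alt single uppercase bases (A/C/G/T), `ref != alt`.
#' @param totalDepth total read depth t at the site (after any
#'   base-quality screen).
#' @param altDepth alternate-allele read depth aa.
#' @param altFwd,altRev forward/reverse-strand split of `altDepth`.
#' @param rrps read-position rank-sum Z-score, or `NA` when unavailable.
#' @param alignerId label of the aligner the evidence came from.
#' @param refPositions,altPositions optional lists of within-read offsets
#'   of reference-/alternate-supporting bases (one vector per site), used
#'   to fill missing `rrps` values.
#' @return a `SiteEvidence` object.
#' @examples
#' ev <- siteEvidence("chr1", 100L, "C", "A", totalDepth = 50L,
#'                    altDepth = 20L, altFwd = 11L, altRev = 9L,
#'                    alignerId = "tophat2")
#' alleleRatio(ev)
#' @export
siteEvidence <- function(chrom, pos, ref, alt, totalDepth, altDepth,
                         altFwd, altRev, rrps = NA_real_,
                         alignerId = "aligner1",
                         refPositions = NULL, altPositions = NULL) {
  n <- max(length(chrom), length(pos), length(ref), length(alt),
           length(totalDepth), length(altDepth))
  if (length(pos) == 0L) n <- 0L
  ev <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(toupper(as.character(ref)), n),
    alt = rep_len(toupper(as.character(alt)), n),
    totalDepth = rep_len(as.integer(totalDepth), n),
    altDepth = rep_len(as.integer(altDepth), n),
    altFwd = rep_len(as.integer(altFwd), n),
    altRev = rep_len(as.integer(altRev), n),
    rrps = rep_len(as.numeric(rrps), n),
    alignerId = rep_len(as.character(alignerId), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(refPositions) && !is.null(altPositions)) {
    fill <- which(is.na(ev$rrps))
    if (length(fill))
      ev$rrps[fill] <- mapply(readPosRankSum,
                              refPositions[fill], altPositions[fill])
  }
  new("SiteEvidence", evidence = ev)
}

.emptySiteEvidence <- function(alignerId = "aligner1") {
  siteEvidence(character(0), integer(0), character(0), character(0),
               integer(0), integer(0), integer(0), integer(0),
               numeric(0), alignerId = character(0))
}

#' Accessors for SiteEvidence
#'
#' Column accessors for [SiteEvidence-class]. `variantKey()` returns the
#' canonical `"chrom:pos:ref>alt"` key used for cross-aligner matching.
#'
#' @param x a `SiteEvidence` object.
#' @return a vector with one element per evidence row.
#' @name SiteEvidence-accessors
NULL

#' @rdname SiteEvidence-accessors
#' @export
setMethod("chrom", "SiteEvidence", function(x) x@evidence$chrom)
#' @rdname SiteEvidence-accessors
#' @export
setMethod("pos", "SiteEvidence", function(x) x@evidence$pos)
#' @rdname SiteEvidence-accessors
#' @export
setMethod("refBase", "SiteEvidence", function(x) x@evidence$ref)
#' @rdname SiteEvidence-accessors
#' @export
setMethod("altBase", "SiteEvidence", function(x) x@evidence$alt)
#' @rdname SiteEvidence-accessors
#' @export
setMethod("totalDepth", "SiteEvidence", function(x) x@evidence$totalDepth)
#' @rdname SiteEvidence-accessors
#' @export
setMethod("altDepth", "SiteEvidence", function(x) x@evidence$altDepth)
#' @rdname SiteEvidence-accessors
#' @export
setMethod("altFwd", "SiteEvidence", function(x) x@evidence$altFwd)
#' @rdname SiteEvidence-accessors
#' @export
setMethod("altRev", "SiteEvidence", function(x) x@evidence$altRev)
#' @rdname SiteEvidence-accessors
#' @export
setMethod("rrps", "SiteEvidence", function(x) x@evidence$rrps)
#' @rdname SiteEvidence-accessors
#' @export
setMethod("alignerId", "SiteEvidence", function(x) x@evidence$alignerId)
#' @rdname SiteEvidence-accessors
#' @export
setMethod("variantKey", "SiteEvidence", function(x)
  .makeKey(x@evidence$chrom, x@evidence$pos, x@evidence$ref, x@evidence$alt))

.makeKey <- function(chrom, pos, ref, alt) {
  if (length(chrom) == 0L) return(character(0))
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

#' @export
setMethod("length", "SiteEvidence", function(x) nrow(x@evidence))

#' @export
setMethod("[", "SiteEvidence", function(x, i, j, ..., drop = FALSE) {
  initialize(x, evidence = x@evidence[i, , drop = FALSE])
})

#' Combine SiteEvidence objects
#' @param x a `SiteEvidence` object.
#' @param ... further `SiteEvidence` objects.
#' @return a `SiteEvidence` with the rows of all arguments.
#' @export
setMethod("c", "SiteEvidence", function(x, ...) {
  rows <- lapply(list(x, ...), function(e) e@evidence)
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  initialize(x, evidence = df)
})

setMethod("show", "SiteEvidence", function(object) {
  cat("SiteEvidence with", length(object), "record(s) from aligner(s):",
      paste(unique(alignerId(object)), collapse = ", "), "\n")
  if (length(object)) {
    print(utils::head(object@evidence, 6L), row.names = FALSE)
    if (length(object) > 6L) cat("...", length(object) - 6L, "more record(s)\n")
  }
})

#' @export
#' @method as.data.frame SiteEvidence
as.data.frame.SiteEvidence <- function(x, row.names = NULL, optional = FALSE, ...) {
  x@evidence
}

setMethod("as.data.frame", "SiteEvidence", as.data.frame.SiteEvidence)

#' Per-site derived statistics
#'
#' `alleleRatio()` is the alternate-allele read fraction aa/t at a site.
#' `strandBiasRatio()` is min(aaFwd, aaRev) / max(aaFwd, aaRev), the
#' symmetric forward/reverse balance of alternate-supporting reads: 1 for
#' perfectly balanced support, 0 when all alternate reads come from one
#' strand (a classic sequencing-artifact signature).
#'
#' @param x a `SiteEvidence` object.
#' @return numeric vector, one value per evidence row, in \[0, 1\].
#' @examples
#' ev <- siteEvidence("chr1", 1L, "C", "A", 50L, 5L, 2L, 3L)
#' alleleRatio(ev)       # 0.1
#' strandBiasRatio(ev)   # 2/3
#' @name siteStatistics
NULL

#' @rdname siteStatistics
#' @export
setMethod("alleleRatio", "SiteEvidence", function(x) {
  t <- totalDepth(x)
  if (any(t == 0L))
    stop("allele ratio undefined at zero total depth (site ",
         paste(variantKey(x)[t == 0L][1L]), ")")
  altDepth(x) / t
})

#' @rdname siteStatistics
#' @export
setMethod("strandBiasRatio", "SiteEvidence", function(x) {
  aa <- altDepth(x)
  if (any(aa == 0L))
    stop("strand-bias ratio undefined with no alternate reads (site ",
         paste(variantKey(x)[aa == 0L][1L]), ")")
  f <- altFwd(x); r <- altRev(x)
  pmin(f, r) / pmax(f, r)
})

#' Read-position rank-sum Z-score
#'
#' Mann-Whitney rank-sum Z-statistic comparing the within-read offsets of
#' alternate-supporting bases against reference-supporting bases at a
#' site. Midranks are used for ties and the variance carries the standard
#' tie correction. The score is negative when the alternate bases sit at
#' lower offsets than the reference bases; with offsets measured as the
#' distance from the nearer read end, a strongly negative score means the
#' alternate allele clusters at the 5'/3' read ends - the false-positive
#' signature the rank-sum filter targets.
#'
#' @param refPositions,altPositions non-negative integer offsets of the
#'   reference-/alternate-supporting bases within their reads.
#' @return the Z-score, or `NA` when either group is empty or the
#'   permutation variance is zero (all offsets tied).
#' @examples
#' readPosRankSum(c(10, 20, 30), c(10, 20, 30))  # 0
#' readPosRankSum(c(30, 40, 50, 60), c(1, 2, 3, 4))
#' @export
readPosRankSum <- function(refPositions, altPositions) {
  refPositions <- as.numeric(refPositions)
  altPositions <- as.numeric(altPositions)
  nr <- length(refPositions); na <- length(altPositions)
  if (nr == 0L || na == 0L) return(NA_real_)
  pooled <- c(altPositions, refPositions)
  rk <- rank(pooled)                       # midranks
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nr
  ties <- table(pooled)
  tieCorr <- sum(ties^3 - ties) / (n * (n - 1))
  varU <- na * nr / 12 * ((n + 1) - tieCorr)
  if (varU <= 0) return(NA_real_)
  (u - na * nr / 2) / sqrt(varU)
}

#' Distance from the nearer read end
#'
#' Converts 0-based read cycles to the offset convention used by the
#' read-position rank-sum score: `min(cycle, readLength - 1 - cycle)`,
#' so that bases near either the 5' or the 3' end of a read get small
#' offsets.
#'
#' @param cycle 0-based position of the base within the read.
#' @param readLength read length in bases.
#' @return integer offsets in `[0, floor((readLength - 1) / 2)]`.
#' @export
nearerEndOffset <- function(cycle, readLength) {
  cycle <- as.integer(cycle)
  stopifnot(all(cycle >= 0L), all(cycle < readLength))
  pmin(cycle, readLength - 1L - cycle)
}
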