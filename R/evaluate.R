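#' Construct a benchmark truth set
#'
#' @param chrom,pos position of the assayed/validated site (1-based).
#' @param ref,alt reference and alternate allele; `alt` may be NA for
#'   hom_ref chip positions.
#' @param genotype `"hom_ref"`, `"het"` or `"hom_alt"`.
#' @param kind `"chip"` (genotyping array: assays both variant and
#'   hom_ref positions) or `"wes"` (exome mutation list plus coverage).
#' @param coverage per-position sequencing depth (required for wes).
#' @return a [TruthSet-class].
#' @export
truthSet <- function(chrom, pos, ref, alt, genotype,
                     kind = c("chip", "wes"), coverage = NA_real_) {
  kind <- match.arg(kind)
  n <- length(pos)
  tb <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = as.integer(pos),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n),
                   genotype = rep_len(as.character(genotype), n),
                   coverage = rep_len(as.numeric(coverage), n),
                   stringsAsFactors = FALSE)
  new("TruthSet", table = tb, kind = kind)
}

setMethod("show", "TruthSet", function(object) {
  tb <- object@table
  cat("TruthSet (", object@kind, ") with ", nrow(tb), " position(s); ",
      sum(tb$genotype != "hom_ref"), " variant(s)\n", sep = "")
})

#' Truth set from a 4-column TSV
#'
#' Reads `chrom pos alleles genotype` (alleles as `REF/ALT`; genotype as
#' hom_ref/het/hom_alt), with an optional fifth `coverage` column for
#' the wes kind.
#'
#' @param path path to the tab-separated file (no header).
#' @param kind `"chip"` or `"wes"`.
#' @return a [TruthSet-class].
#' @export
readTruthTsv <- function(path, kind = c("chip", "wes")) {
  kind <- match.arg(kind)
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  al <- strsplit(tb[[3L]], "/", fixed = TRUE)
  alt <- vapply(al, function(a) if (length(a) > 1L) a[2L] else NA_character_, "")
  alt[alt == "."] <- NA_character_
  truthSet(tb[[1L]], tb[[2L]],
           ref = vapply(al, `[`, "", 1L),
           alt = alt,
           genotype = tb[[4L]], kind = kind,
           coverage = if (ncol(tb) >= 5L) tb[[5L]] else NA_real_)
}

#' Truth set from a genotyped VCF
#'
#' Reads the first sample's GT field (`0/0`, `0/1`, `1/1`, phased or
#' unphased) of a VCF into a [TruthSet-class]; per-position coverage is
#' taken from the DP genotype field when present (wes kind).
#'
#' @param path path to the VCF.
#' @param kind `"chip"` or `"wes"`.
#' @param genome genome label passed to [VariantAnnotation::readVcf()].
#' @return a [TruthSet-class].
#' @export
readTruthVcf <- function(path, kind = c("chip", "wes"), genome = "unknown") {
  kind <- match.arg(kind)
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT[, 1L]
  genotype <- vapply(gsub("|", "/", gt, fixed = TRUE), function(g) {
    switch(g, "0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
           "1/1" = "hom_alt", NA_character_)
  }, character(1))
  altList <- VariantAnnotation::alt(vcf)
  alt1 <- vapply(seq_along(altList), function(i) {
    a <- as.character(altList[[i]])
    if (length(a)) a[1L] else NA_character_
  }, character(1))
  coverage <- if ("DP" %in% rownames(VariantAnnotation::geno(
    VariantAnnotation::header(vcf))))
    as.numeric(VariantAnnotation::geno(vcf)$DP[, 1L]) else NA_real_
  keep <- !is.na(genotype)
  truthSet(as.character(GenomicRanges::seqnames(rr))[keep],
           GenomicRanges::start(rr)[keep],
           as.character(VariantAnnotation::ref(vcf))[keep],
           alt1[keep], genotype[keep], kind = kind,
           coverage = if (length(coverage) > 1L) coverage[keep] else coverage)
}

.evalResult <- function(tp, fp, fn, nNoCoverage = 0L) {
  tp <- as.integer(tp); fp <- as.integer(fp); fn <- as.integer(fn)
  p <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f <- if (2L * tp + fp + fn > 0L) 2 * tp / (2 * tp + fp + fn) else NA_real_
  new("EvalResult", tp = tp, fp = fp, fn = fn,
      nNoCoverage = as.integer(nNoCoverage),
      precision = p, recall = r, fScore = f)
}

#' Benchmark metrics from raw counts
#'
#' `evalFromCounts()` turns TP/FP/FN counts into precision TP/(TP+FP),
#' recall TP/(TP+FN) and F = 2PR/(P+R). `evalFromTotals()` accepts the
#' count layout of published per-sample benchmark tables - validated
#' calls, total calls, calls without truth coverage, and the number of
#' expressed truth variants - and maps them to TP = validated,
#' FP = total - noCoverage - validated, FN = expressed - validated.
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative
#'   counts.
#' @param nNoCoverage calls excluded from the precision denominator for
#'   lacking truth coverage.
#' @return an [EvalResult-class].
#' @examples
#' res <- evalFromCounts(tp = 15753, fp = 15796 - 15753, fn = 17307 - 15753)
#' precisionOf(res)   # 0.9973
#' recallOf(res)      # 0.9102
#' @export
evalFromCounts <- function(tp, fp, fn, nNoCoverage = 0L) {
  .evalResult(tp, fp, fn, nNoCoverage)
}

#' @rdname evalFromCounts
#' @param validated calls confirmed by the truth set (TP).
#' @param total all calls submitted to the comparison.
#' @param noCoverage calls at positions the truth assay did not cover.
#' @param expressed truth variants expressed in the RNA (the recall
#'   denominator).
#' @export
evalFromTotals <- function(validated, total, noCoverage, expressed) {
  .evalResult(tp = validated, fp = total - noCoverage - validated,
              fn = expressed - validated, nNoCoverage = noCoverage)
}

#' @rdname EvalResult-accessors
#' @export
setMethod("tpCount", "EvalResult", function(x) x@tp)
#' @rdname EvalResult-accessors
#' @export
setMethod("fpCount", "EvalResult", function(x) x@fp)
#' @rdname EvalResult-accessors
#' @export
setMethod("fnCount", "EvalResult", function(x) x@fn)
#' @rdname EvalResult-accessors
#' @export
setMethod("noCoverageCount", "EvalResult", function(x) x@nNoCoverage)
#' @rdname EvalResult-accessors
#' @export
setMethod("precisionOf", "EvalResult", function(x) x@precision)
#' @rdname EvalResult-accessors
#' @export
setMethod("recallOf", "EvalResult", function(x) x@recall)
#' @rdname EvalResult-accessors
#' @export
setMethod("fScoreOf", "EvalResult", function(x) x@fScore)

#' Accessors for EvalResult
#'
#' Count and metric accessors for [EvalResult-class].
#' @param x an `EvalResult`.
#' @name EvalResult-accessors
NULL

setMethod("show", "EvalResult", function(object) {
  cat("EvalResult: TP =", object@tp, " FP =", object@fp, " FN =", object@fn,
      if (object@nNoCoverage > 0L)
        paste0(" (", object@nNoCoverage, " call(s) without truth coverage)"),
      "\n  precision =", .pct(object@precision),
      " recall =", .pct(object@recall),
      " F =", round(object@fScore, 3), "\n")
})

# percentages rounded half-up to one decimal, matching the usual
# reporting granularity of benchmark tables
.pct <- function(x, digits = 1L) {
  if (is.na(x)) return("NA")
  scl <- 10^digits
  paste0(floor(x * 100 * scl + 0.5) / scl, "%")
}

#' Round a proportion to a printed percentage
#'
#' Half-up rounding of a proportion to one-decimal percent (0.99728 ->
#' 99.7), the granularity benchmark percentages are reported at.
#'
#' @param x proportion in \[0,1\].
#' @param digits decimals of the percentage, default 1.
#' @return numeric percentage.
#' @export
asPercent <- function(x, digits = 1L) {
  scl <- 10^digits
  floor(x * 100 * scl + 0.5) / scl
}

#' Gate calls and truth for benchmarking
#'
#' Applies the expression- and coverage-aware gating that precedes
#' precision/recall scoring:
#'
#' * chip kind - calls are restricted to positions the array assayed;
#'   the truth-positive ("expressed") set is the array's variant
#'   positions with more than 3 alternate-allele-supporting RNA reads.
#' * wes kind - calls are restricted to positions with exome coverage of
#'   at least 4 reads (others are counted as `nNoCoverage`, excluded
#'   from the precision denominator); the truth-positive set is the
#'   exome mutation list, restricted to positions with any RNA coverage
#'   when RNA evidence is supplied.
#'
#' @param calls data.frame with `chrom`, `pos`, `ref`, `alt` (e.g. from
#'   [mergeCallSets()], typically pre-filtered to `conf == 2`).
#' @param truth a [TruthSet-class].
#' @param rnaEvidence a [SiteEvidence-class] giving per-position RNA
#'   read support (required for chip gating).
#' @param minAltReads chip expression gate: truth variants need strictly
#'   more than this many alternate RNA reads; default 3.
#' @param minWesCoverage wes coverage gate, default 4.
#' @return list with `assayableCalls` (data.frame), `expressedTruth`
#'   (data.frame of truth-positive variants), `nNoCoverage` (integer).
#' @export
gateAssayable <- function(calls, truth, rnaEvidence = NULL,
                          minAltReads = 3L, minWesCoverage = 4L) {
  stopifnot(is(truth, "TruthSet"))
  tb <- truth@table
  posKeyCalls <- paste(calls$chrom, calls$pos)
  posKeyTruth <- paste(tb$chrom, tb$pos)
  if (truth@kind == "chip") {
    if (is.null(rnaEvidence))
      stop("chip gating needs RNA evidence to determine expressed truth variants")
    assayable <- calls[posKeyCalls %in% posKeyTruth, , drop = FALSE]
    evd <- as.data.frame(rnaEvidence)
    evKey <- .makeKey(evd$chrom, evd$pos, evd$ref, evd$alt)
    truthVar <- tb[tb$genotype != "hom_ref", , drop = FALSE]
    tKey <- .makeKey(truthVar$chrom, truthVar$pos, truthVar$ref, truthVar$alt)
    aa <- evd$altDepth[match(tKey, evKey)]
    expressed <- truthVar[!is.na(aa) & aa > minAltReads, , drop = FALSE]
    nNoCov <- 0L
  } else {
    cov <- tb$coverage[match(posKeyCalls, posKeyTruth)]
    cov[is.na(cov)] <- 0
    assayable <- calls[cov >= minWesCoverage, , drop = FALSE]
    nNoCov <- sum(cov < minWesCoverage)
    expressed <- tb[tb$genotype != "hom_ref", , drop = FALSE]
    if (!is.null(rnaEvidence)) {
      evd <- as.data.frame(rnaEvidence)
      posEv <- paste(evd$chrom, evd$pos)
      t <- evd$totalDepth[match(paste(expressed$chrom, expressed$pos), posEv)]
      expressed <- expressed[!is.na(t) & t >= 1L, , drop = FALSE]
    }
  }
  list(assayableCalls = assayable, expressedTruth = expressed,
       nNoCoverage = as.integer(nNoCov))
}

#' Score gated calls against truth
#'
#' Counts TP (assayable calls matching an expressed truth variant on
#' position and alternate allele), FP (assayable calls the truth does
#' not confirm, including chip hom_ref positions), and FN (expressed
#' truth variants not called), then derives precision, recall and F.
#' The conservation identities TP + FP = |assayable calls| and
#' TP + FN = |expressed truth| are asserted on every run.
#'
#' @param gated a list from [gateAssayable()].
#' @return an [EvalResult-class].
#' @export
scoreCalls <- function(gated) {
  calls <- gated$assayableCalls
  truth <- gated$expressedTruth
  ck <- .makeKey(calls$chrom, calls$pos, calls$ref, calls$alt)
  tk <- .makeKey(truth$chrom, truth$pos, truth$ref, truth$alt)
  tp <- sum(ck %in% tk)
  fp <- length(ck) - tp
  fn <- sum(!tk %in% ck)
  stopifnot(tp + fp == nrow(calls), tp + fn == nrow(truth))
  .evalResult(tp, fp, fn, gated$nNoCoverage)
}

#' Benchmark a call set against a truth set
#'
#' Convenience wrapper: [gateAssayable()] then [scoreCalls()].
#'
#' @inheritParams gateAssayable
#' @return an [EvalResult-class].
#' @export
evaluateCalls <- function(calls, truth, rnaEvidence = NULL,
                          minAltReads = 3L, minWesCoverage = 4L) {
  scoreCalls(gateAssayable(calls, truth, rnaEvidence,
                           minAltReads, minWesCoverage))
}

#' Transition/transversion ratio
#'
#' Classifies each substitution as a transition (A<->G, C<->T) or a
#' transversion (the other eight base exchanges) and returns the count
#' ratio, a standard call-set quality indicator (around 2.6-3.0 for
#' human whole-genome/coding sets).
#'
#' @param ref,alt reference and alternate bases of the call set.
#' @return list with `nTs`, `nTv`, `ratio` (Inf with a warning when no
#'   transversions are present).
#' @export
tstvRatio <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(length(ref) == length(alt),
            all(ref %in% .BASES), all(alt %in% .BASES), all(ref != alt))
  ts <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  nTs <- sum(ts); nTv <- sum(!ts)
  if (nTv == 0L) {
    warning("no transversions: ts/tv ratio is infinite")
    return(list(nTs = nTs, nTv = 0L, ratio = Inf))
  }
  list(nTs = nTs, nTv = nTv, ratio = nTs / nTv)
}

#' Zygosity from the alternate-allele read fraction
#'
#' Classifies sites as hom_ref / het / hom_alt from f = aa/t: below
#' `lower` is hom_ref, above `upper` is hom_alt, between (inclusive) is
#' het. Sites with zero depth are no-calls (NA).
#'
#' @param altDepth,totalDepth read counts (vectors).
#' @param lower,upper classification bounds, defaults 0.1 and 0.9.
#' @return character vector in hom_ref/het/hom_alt, NA for no-calls.
#' @export
zygosityCall <- function(altDepth, totalDepth, lower = 0.1, upper = 0.9) {
  f <- ifelse(totalDepth > 0L, altDepth / totalDepth, NA_real_)
  ifelse(is.na(f), NA_character_,
         ifelse(f < lower, "hom_ref", ifelse(f > upper, "hom_alt", "het")))
}

.ZYG_LEVELS <- c("hom_ref", "het", "hom_alt")

#' Zygosity concordance between bulk and single-cell calls
#'
#' Tallies, over the variant keys callable in both data sets, the 3x3
#' matrix of bulk (rows) versus per-cell (columns) zygosity calls. With
#' single-cell libraries, bulk-heterozygous sites scatter across all
#' three per-cell classes (allelic dropout and bursty expression), while
#' bulk hom_alt sites stay hom_alt when covered - the cell-to-cell
#' heterogeneity readout.
#'
#' @param bulk a [SiteEvidence-class] for the multicellular sample.
#' @param cells a named list of [SiteEvidence-class], one per cell.
#' @param lower,upper bounds passed to [zygosityCall()].
#' @return integer matrix, rows = bulk zygosity, columns = cell
#'   zygosity, summed over all (cell, shared site) pairs.
#' @export
zygosityConcordance <- function(bulk, cells, lower = 0.1, upper = 0.9) {
  bulkKey <- variantKey(bulk)
  bulkZyg <- zygosityCall(altDepth(bulk), totalDepth(bulk), lower, upper)
  mat <- matrix(0L, 3L, 3L, dimnames = list(bulk = .ZYG_LEVELS,
                                            cell = .ZYG_LEVELS))
  for (ce in cells) {
    k <- variantKey(ce)
    shared <- intersect(k, bulkKey)
    if (!length(shared)) next
    bz <- bulkZyg[match(shared, bulkKey)]
    cz <- zygosityCall(altDepth(ce), totalDepth(ce), lower, upper)[match(shared, k)]
    ok <- !is.na(bz) & !is.na(cz)
    if (any(ok))
      mat <- mat + table(factor(bz[ok], .ZYG_LEVELS),
                         factor(cz[ok], .ZYG_LEVELS))
  }
  mat
}
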