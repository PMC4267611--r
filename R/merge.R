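.checkCallSets <- function(callSets) {
  if (is.null(names(callSets)) || any(!nzchar(names(callSets))) ||
      anyDuplicated(names(callSets)))
    stop("callSets must be a uniquely named list of SiteEvidence objects")
  for (id in names(callSets)) {
    if (!is(callSets[[id]], "SiteEvidence"))
      stop("call set '", id, "' is not a SiteEvidence object")
    k <- variantKey(callSets[[id]])
    if (anyDuplicated(k))
      stop("duplicate variant key in call set '", id, "': ",
           k[duplicated(k)][1L])
  }
  invisible(callSets)
}

.perAlignerColumns <- function(ev, verdict, keys) {
  idx <- match(keys, variantKey(ev))
  data.frame(
    t = totalDepth(ev)[idx], aa = altDepth(ev)[idx],
    aaFwd = altFwd(ev)[idx], aaRev = altRev(ev)[idx],
    rrps = rrps(ev)[idx], pass = verdict$passAll[idx],
    filter = c(filterCodes(verdict), NA_character_)[
      ifelse(is.na(idx), nrow(verdict) + 1L, idx)]
  )
}

#' Merge two aligners' call sets into confidence-ranked variants
#'
#' Takes the filtered evidence from two aligners and assigns each variant
#' (matched exactly on chrom, pos, ref, alt) a confidence level:
#' `CONF = 2` when the variant passed all filters under both aligners,
#' `CONF = 1` when only the user-designated preferred aligner supports
#' it, and `CONF = 0` when only the other aligner does. A site called by
#' both aligners but passing filters in only one counts as single-aligner
#' support; the failing aligner's evidence is still attached for
#' reporting. Variants failing filters in every set are dropped.
#'
#' @param callSets named list of exactly two [SiteEvidence-class]
#'   objects, one per aligner (names are the aligner labels).
#' @param preferred the label of the preferred aligner (typically the
#'   splice-aware one).
#' @param config [FilterConfig-class] applied to each set.
#' @return a `data.frame` sorted by (chrom, pos, alt) with columns
#'   `chrom`, `pos`, `ref`, `alt`, `conf`, `supp` (comma-joined
#'   supporting aligner labels) and per-aligner evidence columns
#'   `t.<id>`, `aa.<id>`, `aaFwd.<id>`, `aaRev.<id>`, `rrps.<id>`,
#'   `pass.<id>`, `filter.<id>`.
#' @examples
#' a <- siteEvidence("chr1", 1L, "C", "A", 60L, 30L, 14L, 16L, alignerId = "tophat2")
#' b <- siteEvidence("chr1", 1L, "C", "A", 40L, 22L, 10L, 12L, alignerId = "bwa")
#' mergeCallSets(list(tophat2 = a, bwa = b), preferred = "tophat2")
#' @export
mergeCallSets <- function(callSets, preferred, config = filterConfig()) {
  .checkCallSets(callSets)
  if (length(callSets) != 2L)
    stop("two-aligner merging requires exactly two call sets, got ",
         length(callSets))
  if (!preferred %in% names(callSets))
    stop("preferred aligner '", preferred, "' is not among the call sets (",
         paste(names(callSets), collapse = ", "), ")")
  ids <- names(callSets)
  verdicts <- lapply(callSets, applyFilters, config = config)
  passKeys <- lapply(ids, function(id)
    variantKey(callSets[[id]])[verdicts[[id]]$passAll])
  names(passKeys) <- ids

  keys <- sort(unique(unlist(passKeys)))
  if (length(keys) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      conf = integer(0), supp = character(0))
    return(out)
  }
  suppMat <- vapply(ids, function(id) keys %in% passKeys[[id]], logical(length(keys)))
  suppMat <- matrix(suppMat, nrow = length(keys), dimnames = list(NULL, ids))
  nSupp <- rowSums(suppMat)
  conf <- ifelse(nSupp == 2L, 2L,
                 ifelse(suppMat[, preferred], 1L, 0L))
  supp <- apply(suppMat, 1L, function(s) paste(ids[s], collapse = ","))

  parts <- do.call(rbind, strsplit(keys, "[:>]"))
  out <- data.frame(chrom = parts[, 1L], pos = as.integer(parts[, 2L]),
                    ref = parts[, 3L], alt = parts[, 4L],
                    conf = conf, supp = supp, stringsAsFactors = FALSE)
  for (id in ids) {
    cols <- .perAlignerColumns(callSets[[id]], verdicts[[id]], keys)
    names(cols) <- paste(names(cols), id, sep = ".")
    out <- cbind(out, cols)
  }
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-aligner concordance summary
#'
#' Generalizes the two-aligner merge to N aligners: every variant key
#' passing the filter battery in at least one call set is mapped to the
#' number of aligners supporting it, and the per-level totals are
#' tallied (the usual 3- and 4-way concordance tables).
#'
#' @param callSets named list of two or more [SiteEvidence-class]
#'   objects.
#' @param config [FilterConfig-class] applied to each set.
#' @return a list with `perKey` (data.frame: `chrom`, `pos`, `ref`,
#'   `alt`, `nSupporting`, `supp`) and `totals` (named integer vector,
#'   count of keys at each support level `1..N`).
#' @export
concordanceSummary <- function(callSets, config = filterConfig()) {
  .checkCallSets(callSets)
  if (length(callSets) < 2L)
    stop("concordance summary requires at least two call sets")
  ids <- names(callSets)
  passKeys <- lapply(callSets, function(ev)
    variantKey(ev)[applyFilters(ev, config)$passAll])
  keys <- sort(unique(unlist(passKeys)))
  suppMat <- vapply(ids, function(id) keys %in% passKeys[[id]], logical(length(keys)))
  suppMat <- matrix(suppMat, nrow = length(keys), dimnames = list(NULL, ids))
  nSupp <- as.integer(rowSums(suppMat))
  parts <- if (length(keys)) do.call(rbind, strsplit(keys, "[:>]")) else
    matrix(character(0), ncol = 4L)
  suppLab <- if (length(keys)) apply(suppMat, 1L, function(s)
    paste(ids[s], collapse = ",")) else character(0)
  perKey <- data.frame(chrom = parts[, 1L],
                       pos = as.integer(parts[, 2L]),
                       ref = parts[, 3L], alt = parts[, 4L],
                       nSupporting = nSupp,
                       supp = suppLab,
                       stringsAsFactors = FALSE)
  totals <- vapply(seq_along(ids), function(k) sum(nSupp == k), integer(1))
  names(totals) <- as.character(seq_along(ids))
  list(perKey = perKey, totals = totals)
}
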