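#' Parse one samtools-mpileup text line
#'
#' Single-pass parse of the 6-column mpileup format (chrom, pos, ref,
#' depth, bases, base qualities). Markers handled: `^X` read start (the
#' following mapping-quality character is consumed, no base call), `$`
#' read end, `+n.../-n...` insertions/deletions (the n inserted bases are
#' consumed, no base call), `*` deletion placeholder and `<`/`>`
#' reference skips (each consumes a quality character but contributes to
#' neither depth nor alleles), `.`/`,` reference match on the
#' forward/reverse strand, and upper-/lowercase base letters for
#' alternate alleles on the forward/reverse strand. `N`/`n` calls count
#' toward total depth but are never reported as alleles.
#'
#' Bases whose Phred quality is `<= minBaseQuality` are excluded from all
#' counts (the retained set is quality strictly greater than the
#' threshold). Mapping-quality screening is assumed to have been applied
#' by the pileup producer.
#'
#' @param line one mpileup text line.
#' @param minBaseQuality Phred base-quality screen; default 13.
#' @param alignerId label recorded on the emitted evidence.
#' @return a [SiteEvidence-class] with one record per distinct alternate
#'   allele that retains at least one supporting read (possibly zero
#'   records).
#' @examples
#' parseMpileupLine("chr1\t100\tC\t6\t.,.AAa\tIIIIII")
#' @export
parseMpileupLine <- function(line, minBaseQuality = 13L, alignerId = "aligner1") {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 4L)
    stop("malformed mpileup line (fewer than 4 columns): ", substr(line, 1L, 60L))
  chromName <- f[1L]
  position <- suppressWarnings(as.integer(f[2L]))
  if (is.na(position))
    stop("malformed mpileup line (non-integer position) at ", chromName)
  ref <- toupper(f[3L])
  where <- paste0(chromName, ":", position)
  if (length(f) < 6L || f[4L] == "0")
    return(.emptySiteEvidence())

  ch <- strsplit(f[5L], "", fixed = TRUE)[[1L]]
  qv <- utf8ToInt(f[6L]) - 33L
  n <- length(ch)
  calls <- character(0)
  i <- 1L
  while (i <= n) {
    cc <- ch[i]
    if (cc == "^") {
      if (i == n)
        stop("dangling '^' at ", where, ", column ", i)
      i <- i + 2L                       # skip the mapping-quality char
    } else if (cc == "$") {
      i <- i + 1L
    } else if (cc == "+" || cc == "-") {
      j <- i + 1L
      while (j <= n && ch[j] >= "0" && ch[j] <= "9") j <- j + 1L
      if (j == i + 1L)
        stop("indel length not parseable at ", where, ", column ", i)
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n)
        stop("indel sequence runs past end of base string at ", where,
             ", column ", i)
      i <- j + len                      # inserted/deleted bases: no call
    } else {
      calls <- c(calls, cc)
      i <- i + 1L
    }
  }
  if (length(calls) != length(qv))
    stop("base/quality length mismatch at ", where, " (",
         length(calls), " base calls vs ", length(qv), " qualities)")

  calls <- calls[qv > minBaseQuality]
  calls <- calls[!calls %in% c("*", "<", ">")]   # no base call carried
  isRefDot <- calls == "."
  isRefComma <- calls == ","
  up <- toupper(calls)
  isLetter <- up %in% c(.BASES, "N")
  # an explicit letter equal to the reference is a reference observation
  isRefLetter <- isLetter & up == ref
  isOther <- isLetter & up == "N"
  isAlt <- isLetter & !isRefLetter & !isOther
  totalDepth <- sum(isRefDot | isRefComma | isRefLetter | isOther | isAlt)

  altUp <- up[isAlt]
  altFwdStrand <- calls[isAlt] %in% .BASES       # uppercase = forward
  alleles <- sort(unique(altUp))
  if (length(alleles) == 0L) {
    out <- .emptySiteEvidence()
    if (totalDepth > 0L) attr(out, "totalDepth") <- totalDepth
    return(out)
  }
  fwd <- vapply(alleles, function(a) sum(altUp == a & altFwdStrand), integer(1))
  rev <- vapply(alleles, function(a) sum(altUp == a & !altFwdStrand), integer(1))
  siteEvidence(chromName, position, ref, alleles,
               totalDepth = totalDepth, altDepth = fwd + rev,
               altFwd = fwd, altRev = rev, alignerId = alignerId)
}

#' Read an mpileup text file into site evidence
#'
#' @param path path to a samtools-mpileup text file, or `NULL` when
#'   `text` is given.
#' @param minBaseQuality Phred base-quality screen; default 13.
#' @param alignerId label recorded on the emitted evidence.
#' @param text optional character vector of mpileup lines (instead of a
#'   file).
#' @return a [SiteEvidence-class] with all alternate-allele records from
#'   the file.
#' @export
readMpileup <- function(path = NULL, minBaseQuality = 13L,
                        alignerId = "aligner1", text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.emptySiteEvidence())
  parts <- lapply(lines, parseMpileupLine, minBaseQuality = minBaseQuality,
                  alignerId = alignerId)
  do.call(c, parts)
}
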