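.TSV_COLS <- c("chrom", "pos", "ref", "alt", "t", "aa", "aa_fwd", "aa_rev",
               "rrps", "aligner_id")

#' Site-evidence TSV dialect
#'
#' Reads/writes the package's internal evidence table: tab-separated,
#' header line, columns `chrom`, `pos` (1-based), `ref`, `alt`, `t`,
#' `aa`, `aa_fwd`, `aa_rev`, `rrps` (empty/NA when unavailable),
#' `aligner_id`.
#'
#' @param x a [SiteEvidence-class].
#' @param path file path.
#' @return `readSiteEvidenceTsv` returns a [SiteEvidence-class];
#'   `writeSiteEvidenceTsv` returns `path` invisibly.
#' @export
writeSiteEvidenceTsv <- function(x, path) {
  ev <- as.data.frame(x)
  out <- data.frame(chrom = ev$chrom, pos = ev$pos, ref = ev$ref,
                    alt = ev$alt, t = ev$totalDepth, aa = ev$altDepth,
                    aa_fwd = ev$altFwd, aa_rev = ev$altRev,
                    rrps = ev$rrps, aligner_id = ev$alignerId)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeSiteEvidenceTsv
#' @export
readSiteEvidenceTsv <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  missing <- setdiff(.TSV_COLS, names(tb))
  if (length(missing))
    stop("site-evidence TSV lacks column(s): ", paste(missing, collapse = ", "))
  siteEvidence(tb$chrom, tb$pos, tb$ref, tb$alt, tb$t, tb$aa,
               tb$aa_fwd, tb$aa_rev, tb$rrps, tb$aligner_id)
}

#' Read per-aligner variant evidence from a VCF
#'
#' Extracts per-site read evidence from a VCF 4.x file. Total depth is
#' taken from the first sample's `DP` genotype field (falling back to
#' INFO `DP`), allele depths from `AD` (Number=R: ref followed by alt
#' depths) and the strand split from `ADF`/`ADR`; all three are also
#' accepted as INFO fields. A precomputed `ReadPosRankSum` INFO value is
#' carried verbatim when present. Multi-allelic records are decomposed
#' into one biallelic evidence record per alternate allele; non-SNV
#' alleles are dropped.
#'
#' @param path path to the VCF (plain text or bgzipped).
#' @param alignerId label recorded on the evidence.
#' @param genome genome label passed to [VariantAnnotation::readVcf()].
#' @return a [SiteEvidence-class].
#' @export
readSiteEvidenceVcf <- function(path, alignerId = "aligner1",
                                genome = "unknown") {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = genome))
  rr <- SummarizedExperiment::rowRanges(vcf)
  nrec <- length(rr)
  if (nrec == 0L) return(.emptySiteEvidence(alignerId))
  hdr <- VariantAnnotation::header(vcf)
  genoFields <- rownames(VariantAnnotation::geno(hdr))
  infoData <- VariantAnnotation::info(vcf)

  getNum <- function(field) {
    if (field %in% genoFields) {
      v <- VariantAnnotation::geno(vcf)[[field]]
      as.numeric(v[, 1L])
    } else if (field %in% names(infoData)) {
      as.numeric(infoData[[field]])
    } else rep(NA_real_, nrec)
  }
  getList <- function(field) {
    src <- if (field %in% genoFields) {
      v <- VariantAnnotation::geno(vcf)[[field]]
      if (is.list(v)) v[, 1L] else lapply(seq_len(nrec), function(i) v[i, 1L, ])
    } else if (field %in% names(infoData)) {
      as.list(infoData[[field]])
    } else NULL
    src
  }

  dp <- getNum("DP")
  ad <- getList("AD"); adf <- getList("ADF"); adr <- getList("ADR")
  rprs <- if ("ReadPosRankSum" %in% names(infoData))
    as.numeric(infoData$ReadPosRankSum)
  else if ("RPRS" %in% names(infoData)) as.numeric(infoData$RPRS)
  else rep(NA_real_, nrec)

  refAll <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  chromAll <- as.character(GenomicRanges::seqnames(rr))
  posAll <- GenomicRanges::start(rr)

  rows <- list()
  for (i in seq_len(nrec)) {
    alts <- as.character(altList[[i]])
    if (!refAll[i] %in% .BASES) next
    for (j in seq_along(alts)) {
      if (!alts[j] %in% .BASES) next
      aaAll <- if (!is.null(ad)) suppressWarnings(as.numeric(ad[[i]][j + 1L]))
               else NA_real_
      fw <- if (!is.null(adf)) suppressWarnings(as.numeric(adf[[i]][j + 1L]))
            else NA_real_
      rv <- if (!is.null(adr)) suppressWarnings(as.numeric(adr[[i]][j + 1L]))
            else NA_real_
      if (is.na(aaAll)) aaAll <- sum(fw, rv, na.rm = TRUE)
      if (is.na(fw) && is.na(rv)) { fw <- aaAll; rv <- 0 }
      tdep <- dp[i]
      if (is.na(tdep)) tdep <- aaAll
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chromAll[i], pos = posAll[i], ref = refAll[i], alt = alts[j],
        t = as.integer(tdep), aa = as.integer(aaAll),
        fw = as.integer(fw), rv = as.integer(rv), rrps = rprs[i])
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.emptySiteEvidence(alignerId))
  df <- do.call(rbind, rows)
  siteEvidence(df$chrom, df$pos, df$ref, df$alt, df$t, df$aa, df$fw, df$rv,
               df$rrps, alignerId = alignerId)
}

.vcfHeaderCommon <- function(chroms) {
  c("##fileformat=VCFv4.2",
    "##source=esnvkit",
    paste0("##contig=<ID=", unique(chroms), ">"))
}

#' Write filtered evidence as a VCF
#'
#' One record per evidence row, with INFO keys `DP`, `AD` (ref,alt),
#' `ADF`, `ADR` (alt strand split) and `RPRS`, and the FILTER column set
#' to `PASS` or the semicolon-joined codes of the failed criteria
#' (`depth;alt_depth;ratio;strand_bias;rrps`).
#'
#' @param x a [SiteEvidence-class].
#' @param verdict verdict table from [applyFilters()] for `x`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFilteredVcf <- function(x, verdict, path) {
  stopifnot(length(x) == nrow(verdict))
  ev <- as.data.frame(x)
  hdr <- c(.vcfHeaderCommon(ev$chrom),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
    "##INFO=<ID=ADF,Number=R,Type=Integer,Description=\"Forward-strand ref,alt depths\">",
    "##INFO=<ID=ADR,Number=R,Type=Integer,Description=\"Reverse-strand ref,alt depths\">",
    "##INFO=<ID=RPRS,Number=1,Type=Float,Description=\"Read-position rank-sum Z\">",
    paste0("##FILTER=<ID=", c("depth", "alt_depth", "ratio", "strand_bias", "rrps"),
           ",Description=\"Failed ", c("total-depth", "alt-depth",
           "allele-fraction", "strand-bias", "rank-sum"), " criterion\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  refDepth <- ev$totalDepth - ev$altDepth   # other-allele reads folded into ref slot
  info <- paste0("DP=", ev$totalDepth,
                 ";AD=", refDepth, ",", ev$altDepth,
                 ";ADF=.,", ev$altFwd,
                 ";ADR=.,", ev$altRev,
                 ifelse(is.na(ev$rrps), "",
                        paste0(";RPRS=", formatC(ev$rrps, digits = 4,
                                                 format = "f"))))
  body <- paste(ev$chrom, ev$pos, ".", ev$ref, ev$alt, ".",
                filterCodes(verdict), info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write merged variants as a VCF
#'
#' One record per merged variant with INFO keys `CONF` (2/1/0), `SUPP`
#' (comma-joined supporting aligner labels) and the per-aligner depths
#' mirrored into suffixed keys `DP_<id>` and `AD_<id>`.
#'
#' @param merged data.frame from [mergeCallSets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMergedVcf <- function(merged, path) {
  ids <- sub("^t\\.", "", grep("^t\\.", names(merged), value = TRUE))
  safe <- gsub("[^A-Za-z0-9_]", "_", ids)
  hdr <- c(.vcfHeaderCommon(merged$chrom),
    "##INFO=<ID=CONF,Number=1,Type=Integer,Description=\"Aligner-concordance confidence (2 both, 1 preferred only, 0 other only)\">",
    "##INFO=<ID=SUPP,Number=.,Type=String,Description=\"Supporting aligners\">",
    unlist(lapply(seq_along(ids), function(k) c(
      paste0("##INFO=<ID=DP_", safe[k],
             ",Number=1,Type=Integer,Description=\"Total depth (", ids[k], ")\">"),
      paste0("##INFO=<ID=AD_", safe[k],
             ",Number=1,Type=Integer,Description=\"Alt depth (", ids[k], ")\">")))),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- paste0("CONF=", merged$conf, ";SUPP=", merged$supp)
  for (k in seq_along(ids)) {
    t <- merged[[paste0("t.", ids[k])]]
    aa <- merged[[paste0("aa.", ids[k])]]
    info <- paste0(info,
                   ifelse(is.na(t), "", paste0(";DP_", safe[k], "=", t)),
                   ifelse(is.na(aa), "", paste0(";AD_", safe[k], "=", aa)))
  }
  body <- paste(merged$chrom, merged$pos, ".", merged$ref, merged$alt,
                ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
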