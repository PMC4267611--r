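.REGION_CLASSES <- c("exonic", "UTR5", "UTR3", "intronic", "ncRNA",
                     "upstream", "downstream")

# fixed precedence when a position overlaps several transcript features
.REGION_PRECEDENCE <- c(exonic = 1L, ncRNA = 2L, UTR5 = 3L, UTR3 = 4L,
                        intronic = 5L, upstream = 6L, downstream = 7L)

#' Read a gene-model interval table
#'
#' Reads transcript feature intervals (exonic, UTR5, UTR3, intronic,
#' ncRNA, upstream, downstream) from a six-column table: chrom, start,
#' end, featureClass, gene, transcript. Two coordinate dialects are
#' accepted and must be declared: `"tsv"` (1-based, fully closed
#' intervals) or `"bed"` (0-based, half-open start as in BED).
#'
#' @param path path to the table (tab-separated, no header).
#' @param format `"tsv"` (1-based inclusive) or `"bed"` (0-based
#'   half-open).
#' @return a [GenomicRanges::GRanges] with metadata columns
#'   `featureClass`, `gene`, `transcript`.
#' @export
readGeneModel <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end",
                                        "featureClass", "gene", "transcript"))
  if (format == "bed") tb$start <- tb$start + 1L   # BED: 0-based half-open
  bad <- setdiff(unique(tb$featureClass), .REGION_CLASSES)
  if (length(bad))
    stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  GenomicRanges::GRanges(tb$chrom,
                         IRanges::IRanges(tb$start, tb$end),
                         featureClass = tb$featureClass,
                         gene = tb$gene, transcript = tb$transcript)
}

#' Classify variant positions against a gene model
#'
#' Assigns each position a single region label by overlapping it with the
#' gene-model intervals and resolving multi-transcript overlaps by the
#' fixed precedence exonic > ncRNA > UTR5 > UTR3 > intronic > upstream >
#' downstream (a position that is exonic in one transcript and intronic
#' in another is called exonic). Positions overlapping no interval are
#' `"intergenic"`.
#'
#' @param chrom,pos chromosome names and 1-based positions.
#' @param geneModel a `GRanges` as returned by [readGeneModel()].
#' @return a `data.frame` with columns `region` and `gene` (NA gene for
#'   intergenic positions).
#' @export
classifyRegion <- function(chrom, pos, geneModel) {
  query <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  # chromosomes absent from the model are a legitimate no-overlap case
  hits <- suppressWarnings(GenomicRanges::findOverlaps(query, geneModel))
  region <- rep("intergenic", length(query))
  gene <- rep(NA_character_, length(query))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    prec <- .REGION_PRECEDENCE[geneModel$featureClass[s]]
    best <- tapply(seq_along(q), q, function(ii) ii[which.min(prec[ii])])
    bi <- unlist(best)
    region[q[bi]] <- geneModel$featureClass[s[bi]]
    gene[q[bi]] <- geneModel$gene[s[bi]]
  }
  data.frame(region = region, gene = gene, stringsAsFactors = FALSE)
}

#' Join variants against a known-variant table
#'
#' Exact (chrom, pos, ref, alt) lookup; misses are novel.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param knownTable data.frame with `chrom`, `pos`, `ref`, `alt`, `id`
#'   (e.g. dbSNP-style identifiers); may have zero rows.
#' @return character vector of identifiers, `NA` where novel.
#' @export
joinKnown <- function(variants, knownTable) {
  if (is.null(knownTable) || nrow(knownTable) == 0L)
    return(rep(NA_character_, nrow(variants)))
  vk <- .makeKey(variants$chrom, variants$pos, variants$ref, variants$alt)
  kk <- .makeKey(knownTable$chrom, knownTable$pos, knownTable$ref, knownTable$alt)
  knownTable$id[match(vk, kk)]
}

#' Join variants against protein-domain intervals
#'
#' Lists all protein domains whose (genome-projected) intervals overlap
#' each variant position.
#'
#' @param chrom,pos chromosome names and 1-based positions.
#' @param domainTable a `GRanges` with a `domain` metadata column, or a
#'   data.frame with `chrom`, `start`, `end`, `domain` (1-based
#'   inclusive).
#' @return a list of character vectors (possibly empty) of overlapping
#'   domain names, one element per position.
#' @export
joinDomains <- function(chrom, pos, domainTable) {
  if (is.data.frame(domainTable))
    domainTable <- GenomicRanges::GRanges(
      domainTable$chrom,
      IRanges::IRanges(domainTable$start, domainTable$end),
      domain = domainTable$domain)
  query <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(query, domainTable))
  out <- vector("list", length(query))
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (length(hits)) {
    sp <- split(domainTable$domain[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    out[as.integer(names(sp))] <- lapply(sp, as.character)
  }
  out
}

#' Deleteriousness flag from a substitution-tolerance score
#'
#' A variant is flagged deleterious when a supplied score (SIFT-style:
#' low means intolerant) is present and strictly below 0.05.
#'
#' @param score numeric scores, NA where unavailable.
#' @param cutoff strict upper bound, default 0.05.
#' @return logical vector.
#' @export
flagDeleterious <- function(score, cutoff = 0.05) {
  !is.na(score) & score < cutoff
}

.GENETIC_CODE_ <- NULL

.translateCodon <- function(codon) {
  code <- c(TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
            ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
            TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
            ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
            TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
            AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
            TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
            AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  unname(code[toupper(codon)])
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Annotate merged variants
#'
#' Adds, for each merged variant: a region class and gene from the gene
#' model; a known-variant identifier (or novel flag); overlapping
#' protein-domain names; a deleteriousness flag from a supplied
#' tolerance-score table; and, when a codon-context table is supplied, a
#' synonymy call (synonymous/nonsynonymous) obtained by substituting the
#' alternate base into the reference codon. Without codon context,
#' exonic variants are labelled `"unknown"` and all others
#' `"noncoding"`.
#'
#' @param merged data.frame from [mergeCallSets()] (needs `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param geneModel `GRanges` from [readGeneModel()], or NULL to skip
#'   region classification.
#' @param knownTable known-variant table for [joinKnown()], or NULL.
#' @param domainTable domain intervals for [joinDomains()], or NULL.
#' @param scoreTable data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `score` (SIFT-style tolerance scores), or NULL.
#' @param codonTable data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `codon` (reference codon, coding strand), `frame` (0-2, position of
#'   the variant base within the codon) and `strand` (`"+"`/`"-"` of the
#'   coding sequence relative to the reference), or NULL.
#' @return `merged` with added columns `region`, `gene`, `knownId`,
#'   `novel`, `domains` (list column), `deleterious`, `synonymy`.
#' @export
annotateVariants <- function(merged, geneModel = NULL, knownTable = NULL,
                             domainTable = NULL, scoreTable = NULL,
                             codonTable = NULL) {
  n <- nrow(merged)
  if (!is.null(geneModel)) {
    rc <- classifyRegion(merged$chrom, merged$pos, geneModel)
    merged$region <- rc$region
    merged$gene <- rc$gene
  } else {
    merged$region <- rep(NA_character_, n)
    merged$gene <- rep(NA_character_, n)
  }
  merged$knownId <- joinKnown(merged, knownTable)
  merged$novel <- is.na(merged$knownId)
  merged$domains <- if (is.null(domainTable)) replicate(n, character(0)) else
    joinDomains(merged$chrom, merged$pos, domainTable)
  score <- rep(NA_real_, n)
  if (!is.null(scoreTable) && nrow(scoreTable)) {
    vk <- .makeKey(merged$chrom, merged$pos, merged$ref, merged$alt)
    sk <- .makeKey(scoreTable$chrom, scoreTable$pos, scoreTable$ref, scoreTable$alt)
    score <- scoreTable$score[match(vk, sk)]
  }
  merged$deleterious <- flagDeleterious(score)
  merged$synonymy <- ifelse(merged$region %in% "exonic", "unknown", "noncoding")
  if (!is.null(codonTable) && nrow(codonTable)) {
    vk <- .makeKey(merged$chrom, merged$pos, merged$ref, merged$alt)
    ck <- .makeKey(codonTable$chrom, codonTable$pos, codonTable$ref, codonTable$alt)
    m <- match(vk, ck)
    hit <- which(!is.na(m))
    for (i in hit) {
      row <- codonTable[m[i], ]
      altCoding <- if (identical(row$strand, "-"))
        .COMPLEMENT[[merged$alt[i]]] else merged$alt[i]
      codon <- toupper(row$codon)
      varCodon <- codon
      substr(varCodon, row$frame + 1L, row$frame + 1L) <- altCoding
      merged$synonymy[i] <- if (identical(.translateCodon(codon),
                                          .translateCodon(varCodon)))
        "synonymous" else "nonsynonymous"
    }
  }
  merged
}
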