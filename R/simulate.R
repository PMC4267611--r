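.DEFAULT_REGION_MIXTURE <- c(exonic = 0.37, UTR5 = 0.15, UTR3 = 0.23,
                             intronic = 0.14, ncRNA = 0.05,
                             upstream = 0.02, downstream = 0.02,
                             intergenic = 0.02)

#' Simulation configuration
#'
#' Parameters for the seeded synthetic-data generator. Sites are planted
#' as clean variants or as one of three artifact classes, each designed
#' to fail exactly one criterion of the default filter battery:
#'
#' * `fracStrandBias` - sites whose alternate reads all come from one
#'   strand (fails the strand-bias criterion);
#' * `fracEndClustered` - sites whose alternate bases sit in the outer
#'   10% of the read (fails the read-position rank-sum bound); these are
#'   drawn at depths of `endClusteredDepthRange` because the rank-sum
#'   score can only exceed the +/-8 bound with roughly 45 or more reads
#'   per group;
#' * `fracLowAltDepth` - sites with only 2-3 alternate-supporting reads
#'   (fails the alternate-depth minimum).
#'
#' The remainder are clean variants (heterozygous with probability
#' `fracHet`, else homozygous-alternate) drawn from the passing region
#' of the default thresholds. `alignerConcordance` is the probability
#' that the second aligner reports identical evidence at a site; with
#' the complementary probability its evidence is re-drawn independently
#' from the same planted truth (discordant read depths, not a missed
#' call). `alignerDropout` is the probability that a site is observed by
#' one aligner only. `tsFraction` is the transition probability when
#' drawing substitution types for true variants (0.75 gives an expected
#' ts/tv of 3). `regionMixture` places sites into a generated gene
#' model; region ground truth is recorded in the ledger.
#'
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param nSites number of planted sites.
#' @param fracStrandBias,fracEndClustered,fracLowAltDepth artifact
#'   fractions (the rest are clean variants).
#' @param fracHet fraction of clean variants that are heterozygous.
#' @param hetAlleleFraction mean alternate-allele fraction at het sites.
#' @param homAlleleFraction alternate-allele fraction at hom_alt sites
#'   (default 0.99, i.e. ~1% sequencing error).
#' @param depthRange total-depth range for clean/strand-bias/low-alt
#'   sites.
#' @param endClusteredDepthRange total-depth range for end-clustered
#'   artifacts (minimum 100).
#' @param alignerConcordance,alignerDropout see description.
#' @param knownFraction fraction of clean variants present in the
#'   known-variant table.
#' @param tsFraction transition probability for true-variant
#'   substitution types.
#' @param regionMixture named probabilities over region classes
#'   (including `intergenic`), summing to 1.
#' @param readLength nominal read length for within-read offsets.
#' @param alignerIds labels of the two simulated aligners.
#' @param nAssayedHomRef extra hom_ref positions carried on the chip
#'   truth set (default `nSites %/% 2`).
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, nSites = 1000L,
                      fracStrandBias = 0.05, fracEndClustered = 0.05,
                      fracLowAltDepth = 0, fracHet = 0.6,
                      hetAlleleFraction = 0.5, homAlleleFraction = 0.99,
                      depthRange = c(10L, 200L),
                      endClusteredDepthRange = c(120L, 200L),
                      alignerConcordance = 0.95, alignerDropout = 0,
                      knownFraction = 0.97, tsFraction = 0.75,
                      regionMixture = .DEFAULT_REGION_MIXTURE,
                      readLength = 100L,
                      alignerIds = c("tophat2", "bwa"),
                      nAssayedHomRef = NULL) {
  if (is.null(nAssayedHomRef)) nAssayedHomRef <- as.integer(nSites) %/% 2L
  new("SimConfig", seed = as.integer(seed), nSites = as.integer(nSites),
      fracStrandBias = fracStrandBias, fracEndClustered = fracEndClustered,
      fracLowAltDepth = fracLowAltDepth, fracHet = fracHet,
      hetAlleleFraction = hetAlleleFraction,
      homAlleleFraction = homAlleleFraction,
      depthRange = as.integer(depthRange),
      endClusteredDepthRange = as.integer(endClusteredDepthRange),
      alignerConcordance = alignerConcordance,
      alignerDropout = alignerDropout,
      knownFraction = knownFraction, tsFraction = tsFraction,
      regionMixture = regionMixture, readLength = as.integer(readLength),
      alignerIds = alignerIds, nAssayedHomRef = as.integer(nAssayedHomRef))
}

#' Single-cell scenario preset
#'
#' Shifts the depth distribution low (mean around 6 reads) to emulate
#' shallow per-cell mRNA-Seq libraries; pair with
#' [singleCellFilterConfig()] and a per-site allele-dropout step when
#' emulating per-cell zygosity scatter.
#'
#' @param ... overrides passed on to [simConfig()].
#' @return a [SimConfig-class].
#' @export
singleCellSimConfig <- function(...) {
  simConfig(depthRange = c(2L, 12L), ...)
}

# deterministic toy gene model: coding genes (upstream / UTR5 / 3 exons,
# 2 introns / UTR3 / downstream) and ncRNA genes laid out on 4
# chromosomes with intergenic gaps; scaled with nSites so every region
# class has room for the requested site mixture
.makeGeneModel <- function(nSites) {
  nGenes <- max(10L, ceiling(nSites / 100))
  chroms <- paste0("chr", 1:4)
  rows <- list()
  pools <- list()
  addIv <- function(chrom, start, end, cls, gene, tx) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, featureClass = cls,
      gene = gene, transcript = tx, stringsAsFactors = FALSE)
    pools[[length(pools) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, cls = cls,
      stringsAsFactors = FALSE)
  }
  for (g in seq_len(nGenes)) {
    chrom <- chroms[(g - 1L) %% 4L + 1L]
    s <- 1L + ((g - 1L) %/% 4L) * 10000L
    gene <- sprintf("GENE%04d", g)
    tx <- sprintf("TX%04d", g)
    if (g %% 5L == 0L) {                       # ncRNA gene
      addIv(chrom, s, s + 999L, "upstream", gene, tx)
      addIv(chrom, s + 1000L, s + 2999L, "ncRNA", gene, tx)
      addIv(chrom, s + 3000L, s + 3999L, "downstream", gene, tx)
      pools[[length(pools) + 1L]] <- data.frame(
        chrom = chrom, start = s + 4000L, end = s + 9999L,
        cls = "intergenic", stringsAsFactors = FALSE)
    } else {                                   # coding gene
      addIv(chrom, s, s + 999L, "upstream", gene, tx)
      addIv(chrom, s + 1000L, s + 1199L, "UTR5", gene, tx)
      addIv(chrom, s + 1200L, s + 1499L, "exonic", gene, tx)
      addIv(chrom, s + 1500L, s + 1999L, "intronic", gene, tx)
      addIv(chrom, s + 2000L, s + 2299L, "exonic", gene, tx)
      addIv(chrom, s + 2300L, s + 2799L, "intronic", gene, tx)
      addIv(chrom, s + 2800L, s + 3099L, "exonic", gene, tx)
      addIv(chrom, s + 3100L, s + 3599L, "UTR3", gene, tx)
      addIv(chrom, s + 3600L, s + 4599L, "downstream", gene, tx)
      pools[[length(pools) + 1L]] <- data.frame(
        chrom = chrom, start = s + 4600L, end = s + 9999L,
        cls = "intergenic", stringsAsFactors = FALSE)
    }
  }
  model <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(model$chrom,
                               IRanges::IRanges(model$start, model$end),
                               featureClass = model$featureClass,
                               gene = model$gene,
                               transcript = model$transcript)
  list(granges = gr, table = model, pools = do.call(rbind, pools))
}

# sample k distinct positions from the pooled intervals of one class
.samplePositions <- function(pools, cls, k) {
  iv <- pools[pools$cls == cls, , drop = FALSE]
  widths <- iv$end - iv$start + 1L
  total <- sum(widths)
  if (k > total)
    stop("region pool '", cls, "' too small (", total, " bp for ", k, " sites)")
  idx <- sort(sample.int(total, k))
  ivIdx <- findInterval(idx - 1L, cumsum(c(0L, widths)),
                        rightmost.closed = FALSE)
  offset <- idx - c(0L, cumsum(widths))[ivIdx] - 1L
  data.frame(chrom = iv$chrom[ivIdx], pos = iv$start[ivIdx] + offset,
             stringsAsFactors = FALSE)
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

.drawSubstitution <- function(n, tsProb) {
  ref <- sample(.BASES, n, replace = TRUE)
  isTs <- stats::runif(n) < tsProb
  alt <- character(n)
  alt[isTs] <- .TRANSITION[ref[isTs]]
  for (i in which(!isTs)) {
    choices <- setdiff(.BASES, c(ref[i], .TRANSITION[[ref[i]]]))
    alt[i] <- sample(choices, 1L)
  }
  list(ref = ref, alt = alt)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sample values (never indices) with replacement, safe for length-1 x
.sampleFrom <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

# draw per-aligner read evidence for the given site classes/zygosities;
# clean sites are drawn from the passing region of the default filter
# battery, each artifact class from the failure region of exactly one
# criterion
.drawEvidence <- function(cls, zyg, cfg) {
  n <- length(cls)
  d <- integer(n); aa <- integer(n); fwd <- integer(n)
  halfMax <- (cfg@readLength - 1L) %/% 2L
  # outer 10% at either read end => nearer-end offsets 0..(readLen/10 - 1)
  outer10 <- max(1L, as.integer(floor(cfg@readLength * 0.1))) - 1L

  iCS <- which(cls %in% c("clean", "strand_bias"))
  if (length(iCS)) {
    dd <- .sampleFrom(seq(cfg@depthRange[1L], cfg@depthRange[2L]), length(iCS))
    # strand-biased artifacts mimic het-like allele fractions
    hetLike <- cls[iCS] == "strand_bias" |
      (!is.na(zyg[iCS]) & zyg[iCS] == "het")
    af <- ifelse(hetLike,
                 .clip(stats::rnorm(length(iCS), cfg@hetAlleleFraction, 0.05),
                       0.3, 0.7),
                 cfg@homAlleleFraction)
    a <- stats::rbinom(length(iCS), dd, af)
    thr <- ifelse(dd >= 100L, 0.05, 0.1)
    aMin <- pmax(4L, as.integer(floor(thr * dd)) + 1L)
    a <- pmin(pmax(a, aMin), dd)
    d[iCS] <- dd; aa[iCS] <- a
  }
  iClean <- which(cls == "clean")
  if (length(iClean)) {
    a <- aa[iClean]
    f <- stats::rbinom(length(iClean), a, 0.5)
    thr <- ifelse(d[iClean] >= 100L, 0.05, 0.1)
    sbs <- ifelse(pmax(f, a - f) > 0L, pmin(f, a - f) / pmax(f, a - f), 0)
    f[sbs <= thr] <- a[sbs <= thr] %/% 2L    # re-balance one-sided draws
    fwd[iClean] <- f
  }
  iSB <- which(cls == "strand_bias")
  if (length(iSB))
    fwd[iSB] <- ifelse(stats::runif(length(iSB)) < 0.5, aa[iSB], 0L)
  iEC <- which(cls == "end_cluster")
  if (length(iEC)) {
    dd <- .sampleFrom(seq(cfg@endClusteredDepthRange[1L],
                          cfg@endClusteredDepthRange[2L]), length(iEC))
    a <- .clip(stats::rbinom(length(iEC), dd, 0.5), 50L, dd - 50L)
    d[iEC] <- dd; aa[iEC] <- as.integer(a)
    fwd[iEC] <- as.integer(a) %/% 2L
  }
  iLA <- which(cls == "low_alt")
  if (length(iLA)) {
    a <- sample(2:3, length(iLA), replace = TRUE)
    dd <- vapply(a, function(ai) sample(4:(10L * ai - 1L), 1L), integer(1))
    d[iLA] <- dd; aa[iLA] <- a; fwd[iLA] <- 1L
  }

  # within-read offsets (distance from the nearer read end) and rank-sum
  rr <- rep(NA_real_, n)
  nref <- d - aa
  for (i in seq_len(n)) {
    if (nref[i] == 0L) next
    refPos <- if (cls[i] == "end_cluster")
      sample((outer10 + 1L):halfMax, nref[i], replace = TRUE)
    else sample(0:halfMax, nref[i], replace = TRUE)
    altPos <- if (cls[i] == "end_cluster")
      sample(0:outer10, aa[i], replace = TRUE)
    else sample(0:halfMax, aa[i], replace = TRUE)
    rr[i] <- readPosRankSum(refPos, altPos)
  }
  data.frame(t = d, aa = aa, fwd = fwd, rev = aa - fwd, rrps = rr)
}

#' Generate a synthetic paired-aligner eSNV data set
#'
#' Plants `nSites` sites (clean variants plus filter-targeted artifact
#' classes) on a generated gene model and emits everything the pipeline
#' consumes: two per-aligner evidence sets, a chip-style truth set
#' (planted variants plus extra assayed hom_ref positions; artifact
#' positions are carried as hom_ref so a leaking artifact would score as
#' a false positive), the gene model, known-variant / protein-domain /
#' tolerance-score tables, and a ledger recording the planted ground
#' truth per site (class, zygosity, region, intended failing filter,
#' observing aligners).
#'
#' @param cfg a [SimConfig-class] from [simConfig()].
#' @return list with elements `callSets` (named list of two
#'   [SiteEvidence-class]), `truth` ([TruthSet-class]), `geneModel`
#'   (`GRanges`), `geneModelTable`, `knownTable`, `domainTable`,
#'   `scoreTable`, `ledger` (data.frame) and `config`.
#' @examples
#' sim <- simulateEsnvData(simConfig(seed = 7, nSites = 200))
#' table(sim$ledger$class)
#' @export
simulateEsnvData <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  if (cfg@endClusteredDepthRange[1L] < 100L)
    stop("endClusteredDepthRange must start at 100 or more: the rank-sum ",
         "score cannot exceed the +/-8 bound at lower depths")
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg@seed)

  n <- cfg@nSites
  gm <- .makeGeneModel(n)

  # site classes
  nSB <- round(n * cfg@fracStrandBias)
  nEC <- round(n * cfg@fracEndClustered)
  nLA <- round(n * cfg@fracLowAltDepth)
  cls <- sample(c(rep("strand_bias", nSB), rep("end_cluster", nEC),
                  rep("low_alt", nLA), rep("clean", n - nSB - nEC - nLA)))
  zyg <- ifelse(cls == "clean",
                ifelse(stats::runif(n) < cfg@fracHet, "het", "hom_alt"),
                NA_character_)

  # positions by region class (assayed hom_ref extras live intergenic)
  region <- sample(names(cfg@regionMixture), n, replace = TRUE,
                   prob = cfg@regionMixture)
  posTab <- data.frame(chrom = character(n), pos = integer(n),
                       stringsAsFactors = FALSE)
  for (rc in unique(region)) {
    ii <- which(region == rc)
    k <- length(ii)
    extra <- if (rc == "intergenic") cfg@nAssayedHomRef else 0L
    drawn <- .samplePositions(gm$pools, rc, k + extra)
    pick <- sample.int(k + extra, k)
    posTab[ii, ] <- drawn[pick, ]
    if (extra > 0L) homRefExtra <- drawn[-pick, , drop = FALSE]
  }
  if (cfg@nAssayedHomRef > 0L && !"intergenic" %in% region)
    homRefExtra <- .samplePositions(gm$pools, "intergenic", cfg@nAssayedHomRef)
  if (cfg@nAssayedHomRef == 0L)
    homRefExtra <- data.frame(chrom = character(0), pos = integer(0))

  sub <- .drawSubstitution(n, cfg@tsFraction)
  # artifacts mimic error processes: substitution type near-uniform
  art <- which(cls != "clean")
  if (length(art)) {
    s2 <- .drawSubstitution(length(art), 1 / 3)
    sub$ref[art] <- s2$ref; sub$alt[art] <- s2$alt
  }

  ev1 <- .drawEvidence(cls, zyg, cfg)
  concordant <- stats::runif(n) < cfg@alignerConcordance
  ev2 <- ev1
  if (any(!concordant)) {
    redraw <- .drawEvidence(cls[!concordant], zyg[!concordant], cfg)
    ev2[!concordant, ] <- redraw
  }
  observedBy <- rep("both", n)
  drop <- stats::runif(n) < cfg@alignerDropout
  observedBy[drop] <- sample(cfg@alignerIds, sum(drop), replace = TRUE)

  mk <- function(ev, keep, id)
    siteEvidence(posTab$chrom[keep], posTab$pos[keep], sub$ref[keep],
                 sub$alt[keep], ev$t[keep], ev$aa[keep], ev$fwd[keep],
                 ev$rev[keep], ev$rrps[keep], alignerId = id)
  keep1 <- observedBy %in% c("both", cfg@alignerIds[1L])
  keep2 <- observedBy %in% c("both", cfg@alignerIds[2L])
  callSets <- list(mk(ev1, keep1, cfg@alignerIds[1L]),
                   mk(ev2, keep2, cfg@alignerIds[2L]))
  names(callSets) <- cfg@alignerIds

  # chip-style truth: planted variants + artifact positions and extra
  # positions as assayed hom_ref
  isVar <- cls == "clean"
  truth <- truthSet(
    chrom = c(posTab$chrom, homRefExtra$chrom),
    pos = c(posTab$pos, homRefExtra$pos),
    ref = c(sub$ref, sample(.BASES, nrow(homRefExtra), replace = TRUE)),
    alt = c(ifelse(isVar, sub$alt, NA_character_),
            rep(NA_character_, nrow(homRefExtra))),
    genotype = c(ifelse(isVar, zyg, "hom_ref"),
                 rep("hom_ref", nrow(homRefExtra))),
    kind = "chip")

  iVar <- which(isVar)
  knownIdx <- iVar[sample.int(length(iVar),
                              round(length(iVar) * cfg@knownFraction))]
  knownTable <- data.frame(chrom = posTab$chrom[knownIdx],
                           pos = posTab$pos[knownIdx],
                           ref = sub$ref[knownIdx], alt = sub$alt[knownIdx],
                           id = sprintf("rs%07d", seq_along(knownIdx)),
                           stringsAsFactors = FALSE)

  exon1 <- gm$table[gm$table$featureClass == "exonic", , drop = FALSE]
  exon1 <- exon1[!duplicated(exon1$gene), , drop = FALSE]
  nDom <- max(1L, nrow(exon1) %/% 5L)
  domainTable <- data.frame(chrom = exon1$chrom[seq_len(nDom)],
                            start = exon1$start[seq_len(nDom)],
                            end = exon1$end[seq_len(nDom)],
                            domain = paste0("DOM_", exon1$gene[seq_len(nDom)]),
                            stringsAsFactors = FALSE)
  scoreTable <- data.frame(chrom = posTab$chrom[iVar], pos = posTab$pos[iVar],
                           ref = sub$ref[iVar], alt = sub$alt[iVar],
                           score = stats::runif(length(iVar)),
                           stringsAsFactors = FALSE)

  intended <- c(clean = "", strand_bias = "strand_bias",
                end_cluster = "rrps", low_alt = "alt_depth")[cls]
  ledger <- data.frame(
    chrom = posTab$chrom, pos = posTab$pos, ref = sub$ref, alt = sub$alt,
    key = .makeKey(posTab$chrom, posTab$pos, sub$ref, sub$alt),
    class = cls, zygosity = zyg, region = region,
    intendedFail = unname(intended),
    knownId = joinKnown(data.frame(chrom = posTab$chrom, pos = posTab$pos,
                                   ref = sub$ref, alt = sub$alt),
                        knownTable),
    observedBy = observedBy, concordant = concordant,
    stringsAsFactors = FALSE)

  list(callSets = callSets, truth = truth, geneModel = gm$granges,
       geneModelTable = gm$table, knownTable = knownTable,
       domainTable = domainTable, scoreTable = scoreTable,
       ledger = ledger, config = cfg)
}

#' Write a simulated data set to disk
#'
#' Emits the TSV/VCF dialects the pipeline consumes: per-aligner
#' site-evidence TSVs (`evidence_<aligner>.tsv`), a truth TSV
#' (`truth.tsv`), the gene model (`gene_model.tsv`, 1-based), the
#' known-variant, domain and score tables, and the ground-truth ledger
#' as JSON (`ledger.json`).
#'
#' @param sim a list from [simulateEsnvData()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(sim$callSets))
    writeSiteEvidenceTsv(sim$callSets[[id]],
                         file.path(dir, paste0("evidence_", id, ".tsv")))
  tb <- sim$truth@table
  utils::write.table(
    data.frame(tb$chrom, tb$pos,
               paste0(tb$ref, "/", ifelse(is.na(tb$alt), ".", tb$alt)),
               tb$genotype),
    file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$geneModelTable, file.path(dir, "gene_model.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(sim$knownTable, file.path(dir, "known.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$domainTable, file.path(dir, "domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$scoreTable, file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(sim$ledger, file.path(dir, "ledger.json"),
                         dataframe = "rows", na = "null")
  } else {
    utils::write.table(sim$ledger, file.path(dir, "ledger.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
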