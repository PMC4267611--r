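test_that("precision, recall and F follow their closed forms", {
  r <- evalFromCounts(tp = 80L, fp = 20L, fn = 20L)
  expect_equal(precisionOf(r), 0.8)
  expect_equal(recallOf(r), 0.8)
  expect_equal(fScoreOf(r), 0.8)
  # F identity: 2PR/(P+R) == 2TP/((TP+FP)+(TP+FN))
  set.seed(13)
  for (rep in 1:50) {
    tp <- sample(0:500, 1); fp <- sample(0:500, 1); fn <- sample(0:500, 1)
    r <- evalFromCounts(tp, fp, fn)
    if (tp + fp > 0 && tp + fn > 0 && tp > 0) {
      p <- precisionOf(r); rc <- recallOf(r)
      expect_equal(fScoreOf(r), 2 * p * rc / (p + rc), tolerance = 1e-12)
    }
  }
  # all-zero comparison: metrics unavailable, not an error
  r0 <- evalFromCounts(0L, 0L, 0L)
  expect_true(is.na(precisionOf(r0)))
  expect_true(is.na(recallOf(r0)))
  expect_true(is.na(fScoreOf(r0)))
})

test_that("table-style totals map onto TP/FP/FN correctly", {
  r <- evalFromTotals(validated = 90L, total = 110L, noCoverage = 10L,
                      expressed = 100L)
  expect_equal(tpCount(r), 90L)
  expect_equal(fpCount(r), 10L)
  expect_equal(fnCount(r), 10L)
  expect_equal(noCoverageCount(r), 10L)
})

test_that("chip gating keeps assayed positions and expressed truth variants", {
  truth <- truthSet(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                    ref = c("C", "C", "C", "C"),
                    alt = c("A", "A", "A", NA),
                    genotype = c("het", "het", "hom_alt", "hom_ref"),
                    kind = "chip")
  # RNA support: pos 10 expressed (aa=5), pos 20 at the gate (aa=3, not
  # expressed), pos 30 absent from RNA
  rna <- siteEvidence("chr1", c(10L, 20L), "C", "A",
                      totalDepth = c(20L, 20L), altDepth = c(5L, 3L),
                      altFwd = c(2L, 1L), altRev = c(3L, 2L))
  calls <- data.frame(chrom = "chr1", pos = c(10L, 40L, 99L),
                      ref = "C", alt = "A", stringsAsFactors = FALSE)
  g <- gateAssayable(calls, truth, rnaEvidence = rna)
  # pos 99 is not assayed by the chip; pos 40 is assayed (hom_ref)
  expect_equal(g$assayableCalls$pos, c(10L, 40L))
  expect_equal(g$expressedTruth$pos, 10L)
  r <- scoreCalls(g)
  expect_equal(tpCount(r), 1L)   # pos 10 confirmed
  expect_equal(fpCount(r), 1L)   # pos 40: chip says hom_ref
  expect_equal(fnCount(r), 0L)
  # empty truth: everything assayable is a false positive
  empty <- truthSet(character(0), integer(0), character(0), character(0),
                    character(0), kind = "chip")
  g2 <- gateAssayable(calls, empty, rnaEvidence = rna)
  expect_equal(nrow(g2$assayableCalls), 0L)
  expect_equal(scoreCalls(g2)@fp, 0L)
})

test_that("wes gating moves low-coverage calls out of the denominator", {
  truth <- truthSet(chrom = "chr1", pos = c(10L, 20L, 30L),
                    ref = "C", alt = "A",
                    genotype = c("het", "het", "het"),
                    kind = "wes", coverage = c(30, 3, 10))
  calls <- data.frame(chrom = "chr1", pos = c(10L, 20L, 50L),
                      ref = "C", alt = "A", stringsAsFactors = FALSE)
  g <- gateAssayable(calls, truth)
  # pos 20 has 3X exome coverage, pos 50 none at all
  expect_equal(g$assayableCalls$pos, 10L)
  expect_equal(g$nNoCoverage, 2L)
  r <- scoreCalls(g)
  expect_equal(tpCount(r), 1L)
  expect_equal(fnCount(r), 2L)       # pos 20 and 30 in the list, uncalled
  expect_equal(noCoverageCount(r), 2L)
  # conservation identities
  expect_equal(tpCount(r) + fpCount(r), nrow(g$assayableCalls))
  expect_equal(tpCount(r) + fnCount(r), nrow(g$expressedTruth))
})

test_that("ts/tv classification matches a per-pair tally", {
  expect_equal(suppressWarnings(tstvRatio("A", "G"))$nTs, 1L)
  r <- tstvRatio(c("A", "C", "A", "G"), c("G", "T", "C", "T"))
  expect_equal(r$ratio, 1)           # 2 transitions / 2 transversions
  expect_warning(r <- tstvRatio("C", "T"), "infinite")
  expect_equal(r$ratio, Inf)
  # brute-force oracle over all 12 substitution types
  set.seed(9)
  ref <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  tsPairs <- c("AG", "GA", "CT", "TC")
  brute <- sum(paste0(ref, alt) %in% tsPairs)
  r <- tstvRatio(ref, alt)
  expect_equal(r$nTs, brute)
  expect_equal(r$ratio, brute / (300 - brute))
})

test_that("zygosity calls respect their fraction bounds", {
  expect_equal(zygosityCall(c(10L, 0L, 5L, 1L, 9L), c(10L, 10L, 10L, 10L, 10L)),
               c("hom_alt", "hom_ref", "het", "het", "het"))
  expect_equal(zygosityCall(c(0L, 95L), c(0L, 100L)), c(NA, "hom_alt"))
  expect_equal(zygosityCall(5L, 10L, lower = 0.6, upper = 0.95), "hom_ref")
})

test_that("zygosity concordance captures single-cell scatter", {
  bulk <- siteEvidence("chr1", 1:3, "C", "A",
                       totalDepth = 100L, altDepth = c(50L, 98L, 50L),
                       altFwd = c(25L, 49L, 25L), altRev = c(25L, 49L, 25L))
  # cell1 drops the alt allele at site 1, keeps het at site 3
  cell1 <- siteEvidence("chr1", c(1L, 3L), "C", "A",
                        totalDepth = c(8L, 8L), altDepth = c(0L, 4L),
                        altFwd = 0L, altRev = c(0L, 4L))
  # cell2 drops the ref allele at site 1 and misses site 3
  cell2 <- siteEvidence("chr1", c(1L, 2L), "C", "A",
                        totalDepth = c(6L, 5L), altDepth = c(6L, 5L),
                        altFwd = c(3L, 2L), altRev = c(3L, 3L))
  mat <- zygosityConcordance(bulk, list(cell1 = cell1, cell2 = cell2))
  expect_equal(sum(mat), 4L)                       # shared callable pairs
  expect_equal(mat["het", "hom_ref"], 1L)
  expect_equal(mat["het", "het"], 1L)
  expect_equal(mat["het", "hom_alt"], 1L)
  expect_equal(mat["hom_alt", "hom_alt"], 1L)
  expect_equal(mat["hom_ref", "hom_alt"], 0L)
})

test_that("planted zygosities are recovered at depth >= 30", {
  sim <- simulateEsnvData(simConfig(seed = 101, nSites = 3000))
  led <- sim$ledger
  ev <- as.data.frame(sim$callSets[[1]])
  i <- match(led$key[led$class == "clean"], variantKey(sim$callSets[[1]]))
  truthZ <- led$zygosity[led$class == "clean"]
  deep <- !is.na(i) & ev$totalDepth[i] >= 30L
  called <- zygosityCall(ev$altDepth[i[deep]], ev$totalDepth[i[deep]])
  expect_gt(sum(deep), 1000)
  expect_lt(mean(called != truthZ[deep]), 0.01)
})

test_that("synthetic precision and recall match the planted rates", {
  sim <- simulateEsnvData(simConfig(seed = 55, nSites = 2000))
  m <- mergeCallSets(sim$callSets, preferred = "tophat2")
  calls <- m[m$conf == 2L, c("chrom", "pos", "ref", "alt")]
  r <- evaluateCalls(calls, sim$truth, rnaEvidence = sim$callSets[[1]])
  # generator plants no cross-contamination: both rates should be ~1
  # within binomial sampling error at n ~ 1800
  expect_gt(precisionOf(r), 0.99)
  expect_gt(recallOf(r), 0.99)
  expect_equal(tpCount(r) + fnCount(r), nrow(gateAssayable(
    calls, sim$truth, sim$callSets[[1]])$expressedTruth))
})

test_that("truth TSV and VCF readers agree on genotype semantics", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t10\tC/A\thet", "chr1\t20\tG/T\thom_alt",
               "chr2\t5\tT/.\thom_ref"), tsv)
  tr <- readTruthTsv(tsv, kind = "chip")
  expect_equal(tr@table$genotype, c("het", "hom_alt", "hom_ref"))
  expect_equal(tr@table$alt, c("A", "T", NA))

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t10\t.\tC\tA\t.\tPASS\t.\tGT:DP\t0/1:30",
    "chr1\t20\t.\tG\tT\t.\tPASS\t.\tGT:DP\t1/1:12",
    "chr1\t30\t.\tT\tC\t.\tPASS\t.\tGT:DP\t0|0:7"), vcf)
  tv <- readTruthVcf(vcf, kind = "wes")
  expect_equal(tv@table$genotype, c("het", "hom_alt", "hom_ref"))
  expect_equal(tv@table$coverage, c(30, 12, 7))
  expect_equal(tv@table$alt[1], "A")
})
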