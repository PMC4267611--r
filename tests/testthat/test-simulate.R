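test_that("identical seeds give identical simulations", {
  cfg <- simConfig(seed = 404, nSites = 300)
  s1 <- simulateEsnvData(cfg)
  s2 <- simulateEsnvData(cfg)
  expect_identical(s1$ledger, s2$ledger)
  expect_identical(as.data.frame(s1$callSets[[1]]),
                   as.data.frame(s2$callSets[[1]]))
  expect_identical(as.data.frame(s1$callSets[[2]]),
                   as.data.frame(s2$callSets[[2]]))
  s3 <- simulateEsnvData(simConfig(seed = 405, nSites = 300))
  expect_false(identical(s1$ledger$pos, s3$ledger$pos))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(fracStrandBias = 1.2), "probabilities")
  expect_error(simConfig(fracStrandBias = 0.6, fracEndClustered = 0.6),
               "sum")
  expect_error(simConfig(nSites = 0), "nSites")
  expect_error(simulateEsnvData(simConfig(endClusteredDepthRange = c(30L, 60L))),
               "rank-sum")
})

test_that("every planted failure mode trips exactly its intended filter", {
  sim <- simulateEsnvData(simConfig(seed = 88, nSites = 1500,
                                    fracLowAltDepth = 0.05))
  led <- sim$ledger
  for (id in names(sim$callSets)) {
    ev <- sim$callSets[[id]]
    v <- applyFilters(ev)
    i <- match(led$key, variantKey(ev))
    flagCol <- c(strand_bias = "passStrandBias", rrps = "passRrps",
                 alt_depth = "passAltDepth")
    for (cls in c("strand_bias", "end_cluster", "low_alt")) {
      rows <- which(led$class == cls & !is.na(i))
      fcol <- flagCol[[unique(led$intendedFail[led$class == cls])]]
      expect_true(all(!v[[fcol]][i[rows]]),
                  info = paste(id, cls, "intended flag"))
      others <- setdiff(c("passDepth", "passAltDepth", "passRatio",
                          "passStrandBias", "passRrps"), fcol)
      for (oc in others)
        expect_true(all(v[[oc]][i[rows]]),
                    info = paste(id, cls, "unrelated flag", oc))
    }
    clean <- which(led$class == "clean" & !is.na(i))
    expect_true(all(v$passAll[i[clean]]), info = paste(id, "clean sites"))
  }
})

test_that("artifact-free fully concordant runs recover everything as CONF=2", {
  sim <- simulateEsnvData(simConfig(seed = 12, nSites = 400,
                                    fracStrandBias = 0, fracEndClustered = 0,
                                    alignerConcordance = 1))
  m <- mergeCallSets(sim$callSets, preferred = "tophat2")
  expect_equal(nrow(m), 400L)
  expect_true(all(m$conf == 2L))
  expect_setequal(paste0(m$chrom, ":", m$pos, ":", m$ref, ">", m$alt),
                  sim$ledger$key)
})

test_that("planted strand-biased artifacts fail strand bias, site for site", {
  sim <- simulateEsnvData(simConfig(seed = 13, nSites = 600,
                                    fracStrandBias = 0.1,
                                    fracEndClustered = 0))
  k <- round(600 * 0.1)
  ev <- sim$callSets[[1]]
  v <- applyFilters(ev)
  failing <- variantKey(ev)[!v$passStrandBias]
  expect_equal(length(failing), k)
  expect_setequal(failing, sim$ledger$key[sim$ledger$class == "strand_bias"])
})

test_that("aligner dropout yields single-aligner confidence levels", {
  sim <- simulateEsnvData(simConfig(seed = 14, nSites = 500,
                                    fracStrandBias = 0, fracEndClustered = 0,
                                    alignerDropout = 0.3))
  led <- sim$ledger
  m <- mergeCallSets(sim$callSets, preferred = "tophat2")
  mk <- paste0(m$chrom, ":", m$pos, ":", m$ref, ">", m$alt)
  expect_setequal(mk[m$conf == 2L], led$key[led$observedBy == "both"])
  expect_setequal(mk[m$conf == 1L], led$key[led$observedBy == "tophat2"])
  expect_setequal(mk[m$conf == 0L], led$key[led$observedBy == "bwa"])
})

test_that("simulations serialize to the documented file dialects", {
  sim <- simulateEsnvData(simConfig(seed = 15, nSites = 120))
  dir <- withr::local_tempdir()
  writeSimulation(sim, dir)
  expect_true(file.exists(file.path(dir, "evidence_tophat2.tsv")))
  back <- readSiteEvidenceTsv(file.path(dir, "evidence_tophat2.tsv"))
  expect_equal(length(back), length(sim$callSets$tophat2))
  tr <- readTruthTsv(file.path(dir, "truth.tsv"), kind = "chip")
  expect_equal(nrow(tr@table), nrow(sim$truth@table))
  gm <- readGeneModel(file.path(dir, "gene_model.tsv"), format = "tsv")
  expect_equal(length(gm), length(sim$geneModel))
  expect_true(file.exists(file.path(dir, "ledger.json")))
})

test_that("filtered evidence round-trips through the VCF dialect", {
  set.seed(16)
  ev <- randomEvidence(25, alignerId = "bwa")
  v <- applyFilters(ev)
  path <- withr::local_tempfile(fileext = ".vcf")
  writeFilteredVcf(ev, v, path)
  back <- readSiteEvidenceVcf(path, alignerId = "bwa")
  # VCF is position-sorted only in our writer's input order; compare as sets
  kIn <- variantKey(ev); kOut <- variantKey(back)
  expect_setequal(kOut, kIn)
  i <- match(kIn, kOut)
  expect_equal(totalDepth(back)[i], totalDepth(ev))
  expect_equal(altDepth(back)[i], altDepth(ev))
  expect_equal(altFwd(back)[i], altFwd(ev))
  expect_equal(altRev(back)[i], altRev(ev))
  expect_equal(rrps(back)[i], round(rrps(ev), 4), tolerance = 1e-3)
})

test_that("sample-level VCF genotype fields are accepted as evidence", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr7>",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Z\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Fwd depths\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Rev depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr7\t55\t.\tG\tA\t.\t.\tReadPosRankSum=-1.25\tGT:DP:AD:ADF:ADR\t0/1:30:20,10:12,4:8,6",
    "chr7\t60\t.\tT\tC,G\t.\t.\t.\tGT:DP:AD:ADF:ADR\t1/2:40:10,18,12:5,9,7:5,9,5"),
    path)
  ev <- readSiteEvidenceVcf(path, alignerId = "bwa")
  df <- as.data.frame(ev)
  expect_equal(nrow(df), 3L)       # multi-allelic record decomposed
  expect_equal(df$totalDepth[1], 30L)
  expect_equal(df$altDepth[1], 10L)
  expect_equal(df$altFwd[1], 4L)
  expect_equal(df$altRev[1], 6L)
  expect_equal(df$rrps[1], -1.25)
  expect_equal(df$alt[2:3], c("C", "G"))
  expect_equal(df$altDepth[2:3], c(18L, 12L))
  expect_equal(df$altFwd[2:3], c(9L, 7L))
})
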