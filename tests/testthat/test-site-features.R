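test_that("mpileup lines parse to the hand-traced counts", {
  ev <- parseMpileupLine("chr1\t100\tC\t6\t.,.AAa\tIIIIII")
  expect_equal(length(ev), 1L)
  expect_equal(altBase(ev), "A")
  expect_equal(totalDepth(ev), 6L)
  expect_equal(altDepth(ev), 3L)
  expect_equal(altFwd(ev), 2L)
  expect_equal(altRev(ev), 1L)

  # markers carry no base calls
  ev <- parseMpileupLine("chr1\t5\tG\t2\t^~.$,\tII")
  expect_equal(length(ev), 0L)

  # low-quality reference base dropped, high-quality alt retained
  ev <- parseMpileupLine("chr1\t7\tC\t2\t.A\t#I")
  expect_equal(totalDepth(ev), 1L)
  expect_equal(altDepth(ev), 1L)
})

test_that("parser handles indels, deletions and multi-allele sites", {
  # +2AG insertion attached to the ref base: no extra calls
  ev <- parseMpileupLine("chr2\t10\tT\t3\t.+2AG,a\tIII")
  expect_equal(totalDepth(ev), 3L)
  expect_equal(altDepth(ev), 1L)
  expect_equal(altRev(ev), 1L)

  # '*' placeholder consumes a quality but counts nowhere
  ev <- parseMpileupLine("chr2\t11\tT\t4\t.*,A\tIIII")
  expect_equal(totalDepth(ev), 3L)
  expect_equal(altDepth(ev), 1L)

  # two alternate alleles give two records; N counts only toward depth
  ev <- parseMpileupLine("chr2\t12\tG\t6\t.AaCN,\tIIIIII")
  expect_equal(length(ev), 2L)
  df <- as.data.frame(ev)
  expect_equal(df$alt, c("A", "C"))
  expect_equal(df$totalDepth, c(6L, 6L))
  expect_equal(df$altDepth, c(2L, 1L))
  expect_equal(df$altFwd, c(1L, 1L))
})

test_that("malformed pileup lines raise named parse errors", {
  expect_error(parseMpileupLine("chr1\t9\tC\t1\t.^\tI"), "dangling")
  expect_error(parseMpileupLine("chr1\t9\tC\t2\t.+XA,\tII"),
               "indel length")
  expect_error(parseMpileupLine("chr1\t9\tC\t3\t.,\tIII"),
               "length mismatch")
})

test_that("parser agrees with an independent reference parse", {
  set.seed(42)
  lines <- list(
    c("..,,AAaa", "IIIIIIII", "C"),
    c("^I.$,*..Tt,", "IIIIIIII", "A"),
    c(".-1A,+3CCCa..N", "IIIIII", "G"),
    c(",,..aAcC<>*", "II##IIIIIII", "T"),
    c(".$.$..,,^].", "IIIIIII", "C")
  )
  for (ln in lines) {
    got <- parseMpileupLine(paste("chrX", 50, ln[3], 99, ln[1], ln[2],
                                  sep = "\t"))
    want <- referencePileupParse(ln[1], ln[2], ln[3])
    df <- as.data.frame(got)
    if (nrow(df)) {
      expect_true(all(df$totalDepth == want$total), info = ln[1])
      for (i in seq_len(nrow(df))) {
        expect_equal(unname(df$altFwd[i]), unname(want$alt[[df$alt[i]]]["fwd"]),
                     info = ln[1])
        expect_equal(unname(df$altRev[i]), unname(want$alt[[df$alt[i]]]["rev"]),
                     info = ln[1])
      }
      expect_equal(nrow(df), length(want$alt), info = ln[1])
    } else {
      expect_equal(length(want$alt), 0L, info = ln[1])
    }
  }
})

test_that("retained depth never exceeds the declared depth column", {
  set.seed(11)
  for (rep in 1:25) {
    nb <- sample(1:12, 1)
    calls <- sample(c(".", ",", "A", "a", "C", "t", "N"), nb, replace = TRUE)
    quals <- paste(sample(c("#", "5", "I"), nb, replace = TRUE), collapse = "")
    line <- paste("chr1", 10, "G", nb, paste(calls, collapse = ""), quals,
                  sep = "\t")
    ev <- parseMpileupLine(line)
    if (length(ev)) expect_lte(max(totalDepth(ev)), nb)
    # with all qualities above the screen, depth equals the declared depth
    ev2 <- parseMpileupLine(paste("chr1", 10, "G", nb,
                                  paste(calls, collapse = ""),
                                  strrep("I", nb), sep = "\t"))
    if (length(ev2)) expect_equal(unique(totalDepth(ev2)), nb)
  }
})

test_that("allele ratio and strand-bias ratio follow their definitions", {
  ev <- siteEvidence("chr1", 1:3, "C", "A",
                     totalDepth = c(50L, 10L, 7L),
                     altDepth = c(5L, 0L, 7L),
                     altFwd = c(2L, 0L, 4L), altRev = c(3L, 0L, 3L))
  expect_equal(alleleRatio(ev), c(0.1, 0, 1))

  ev <- siteEvidence("chr1", 1:3, "C", "A",
                     totalDepth = 20L, altDepth = c(8L, 10L, 5L),
                     altFwd = c(4L, 2L, 0L), altRev = c(4L, 8L, 5L))
  expect_equal(strandBiasRatio(ev), c(1, 0.25, 0))

  zero <- siteEvidence("chr1", 9L, "C", "A", 0L, 0L, 0L, 0L)
  expect_error(alleleRatio(zero), "undefined")
  expect_error(strandBiasRatio(zero), "undefined")
})

test_that("allele ratio is monotone in alt depth; strand bias is symmetric", {
  set.seed(3)
  for (rep in 1:20) {
    t <- sample(5:200, 1)
    aa <- sort(sample(1:t, 2))
    ev <- siteEvidence("chr1", 1:2, "C", "A", t, aa,
                       altFwd = aa, altRev = 0L)
    expect_lte(alleleRatio(ev)[1], alleleRatio(ev)[2])
    f <- sample(0:aa[2], 1)
    sw <- siteEvidence("chr1", 1:2, "C", "A", t, aa[2],
                       altFwd = c(f, aa[2] - f), altRev = c(aa[2] - f, f))
    expect_equal(strandBiasRatio(sw)[1], strandBiasRatio(sw)[2])
  }
})

test_that("read-position rank-sum matches its definition and edge cases", {
  expect_equal(readPosRankSum(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_true(is.na(readPosRankSum(numeric(0), c(5, 6))))
  expect_true(is.na(readPosRankSum(c(5, 6), numeric(0))))
  expect_true(is.na(readPosRankSum(c(4, 4, 4), c(4, 4))))  # all tied
  z <- readPosRankSum(c(30, 40, 50, 60), c(1, 2, 3, 4))
  expect_equal(z, oracleRankSumZ(c(30, 40, 50, 60), c(1, 2, 3, 4)),
               tolerance = 1e-12)
  expect_lt(z, 0)   # alt near read starts => negative
})

test_that("rank-sum agrees with exact permutation moments on tiny inputs", {
  set.seed(5)
  for (rep in 1:10) {
    refPos <- sample(0:6, sample(2:4, 1), replace = TRUE)
    altPos <- sample(0:6, sample(2:4, 1), replace = TRUE)
    z <- readPosRankSum(refPos, altPos)
    zp <- oracleRankSumZPermutation(refPos, altPos)
    if (is.na(z)) expect_true(is.na(zp)) else
      expect_equal(z, zp, tolerance = 1e-9)
  }
})

test_that("nearer-end offsets fold both read ends onto small values", {
  expect_equal(nearerEndOffset(c(0L, 99L, 49L, 50L), 100L),
               c(0L, 0L, 49L, 49L))
})

test_that("evidence TSV round-trips through the documented dialect", {
  set.seed(8)
  ev <- randomEvidence(20, alignerId = "tophat2")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSiteEvidenceTsv(ev, path)
  back <- readSiteEvidenceTsv(path)
  expect_equal(as.data.frame(back), as.data.frame(ev))
})

test_that("SiteEvidence enforces its invariants", {
  expect_error(siteEvidence("chr1", 1L, "C", "A", 5L, 3L, 1L, 1L),
               "altFwd")
  expect_error(siteEvidence("chr1", 1L, "C", "A", 2L, 3L, 2L, 1L),
               "exceed")
  expect_error(siteEvidence("chr1", 0L, "C", "A", 5L, 2L, 1L, 1L),
               "pos")
  expect_error(siteEvidence("chr1", 1L, "C", "C", 5L, 2L, 1L, 1L),
               "differ")
})
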