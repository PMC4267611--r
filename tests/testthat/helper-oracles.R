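# Independent oracles used across the suite. These deliberately take a
# different algorithmic route from the package implementation.

# Mann-Whitney Z by brute-force pairwise comparison: U counts alt>ref
# pairs (ties half), variance from the tie-count formula computed off a
# frequency table of the pooled values.
oracleRankSumZ <- function(refPos, altPos) {
  na <- length(altPos); nr <- length(refPos)
  if (na == 0L || nr == 0L) return(NA_real_)
  u <- 0
  for (a in altPos) for (r in refPos) u <- u + (a > r) + 0.5 * (a == r)
  n <- na + nr
  tcnt <- as.vector(table(c(altPos, refPos)))
  varU <- na * nr / 12 * ((n + 1) - sum(tcnt^3 - tcnt) / (n * (n - 1)))
  if (varU <= 0) return(NA_real_)
  (u - na * nr / 2) / sqrt(varU)
}

# Exact permutation moments of U: enumerate every assignment of na of
# the pooled values to the alt group (feasible for tiny N only).
oracleRankSumZPermutation <- function(refPos, altPos) {
  na <- length(altPos); nr <- length(refPos)
  pooled <- c(altPos, refPos)
  uStat <- function(aIdx) {
    a <- pooled[aIdx]; r <- pooled[-aIdx]
    u <- 0
    for (x in a) for (y in r) u <- u + (x > y) + 0.5 * (x == y)
    u
  }
  us <- apply(utils::combn(length(pooled), na), 2L, uStat)
  sdU <- sqrt(mean(us^2) - mean(us)^2)
  if (sdU <= 0) return(NA_real_)
  (uStat(seq_len(na)) - mean(us)) / sdU
}

# Reference mpileup parse, strip-markers-first algorithm (regex/substr
# based), as a cross-check on the package's single-pass state machine.
referencePileupParse <- function(bases, quals, ref, minBq = 13L) {
  s <- bases
  s <- gsub("\\^.", "", s)            # read starts + mapq char
  s <- gsub("$", "", s, fixed = TRUE) # read ends
  repeat {                            # indels: [+-]<len><len bases>
    m <- regexpr("[+-][0-9]+", s)
    if (m == -1L) break
    len <- as.integer(substr(s, m + 1L, m + attr(m, "match.length") - 1L))
    s <- paste0(substr(s, 1L, m - 1L),
                substr(s, m + attr(m, "match.length") + len, nchar(s)))
  }
  ch <- strsplit(s, "")[[1L]]
  qv <- utf8ToInt(quals) - 33L
  stopifnot(length(ch) == length(qv))
  ch <- ch[qv > minBq]
  ch <- ch[!ch %in% c("*", "<", ">")]
  ref <- toupper(ref)
  isRef <- ch %in% c(".", ",") | toupper(ch) == ref
  isN <- toupper(ch) == "N"
  alt <- ch[!isRef & !isN]
  counts <- list()
  for (b in unique(toupper(alt)))
    counts[[b]] <- c(fwd = sum(alt == b), rev = sum(alt == tolower(b)))
  list(total = length(ch), alt = counts)
}

# Random small SiteEvidence for merge/property tests; depths wide enough
# that some records pass and some fail the default battery.
randomEvidence <- function(n, chromPool = c("chr1", "chr2"),
                           alignerId = "a1", posPool = 1:200) {
  pos <- sample(posPool, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  t <- sample(2:150, n, replace = TRUE)
  aa <- pmin(t, sample(0:40, n, replace = TRUE) + 1L)
  fwd <- vapply(aa, function(a) sample(0:a, 1L), integer(1))
  siteEvidence(sample(chromPool, n, replace = TRUE), pos, ref, alt,
               t, aa, fwd, aa - fwd,
               rrps = round(stats::rnorm(n, 0, 4), 2),
               alignerId = alignerId)
}
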