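#' Hard-filter configuration
#'
#' Builds the threshold set for the five-criterion site filter battery:
#'
#' * total read depth `t >= minTotalDepth` (default 4);
#' * alternate-allele depth `aa >= minAltDepth` (default 4);
#' * alternate-allele fraction `aa/t` strictly greater than
#'   `ratioHighCov` (default 0.05) when `t >= depthSwitch` (default 100),
#'   else strictly greater than `ratioLowCov` (default 0.1);
#' * strand-bias ratio min/max of the per-strand alternate counts,
#'   strictly greater than `sbsHighCov`/`sbsLowCov` under the same
#'   depth-regime switch;
#' * read-position rank-sum score inside the open interval
#'   (`rrpsLower`, `rrpsUpper`), default (-8, 8); a missing score passes.
#'
#' The high-coverage thresholds are laxer so that low-frequency events
#' (subclonal mutations in impure tumors) remain detectable where depth
#' supports them.
#'
#' @param minTotalDepth,minAltDepth,depthSwitch,ratioLowCov,ratioHighCov,sbsLowCov,sbsHighCov,rrpsLower,rrpsUpper
#'   see description.
#' @return a validated [FilterConfig-class].
#' @seealso [singleCellFilterConfig()], [applyFilters()]
#' @export
filterConfig <- function(minTotalDepth = 4L, minAltDepth = 4L,
                         depthSwitch = 100L,
                         ratioLowCov = 0.1, ratioHighCov = 0.05,
                         sbsLowCov = 0.1, sbsHighCov = 0.05,
                         rrpsLower = -8, rrpsUpper = 8) {
  new("FilterConfig",
      minTotalDepth = as.integer(minTotalDepth),
      minAltDepth = as.integer(minAltDepth),
      depthSwitch = as.integer(depthSwitch),
      ratioLowCov = as.numeric(ratioLowCov),
      ratioHighCov = as.numeric(ratioHighCov),
      sbsLowCov = as.numeric(sbsLowCov),
      sbsHighCov = as.numeric(sbsHighCov),
      rrpsLower = as.numeric(rrpsLower),
      rrpsUpper = as.numeric(rrpsUpper))
}

#' Single-cell preset
#'
#' Identical to [filterConfig()] except that the alternate-allele depth
#' minimum is relaxed to two supporting reads, accommodating the shallow
#' per-cell sequencing depth of single-cell mRNA-Seq libraries.
#'
#' @param ... overrides passed on to [filterConfig()].
#' @return a [FilterConfig-class] with `minAltDepth = 2`.
#' @export
singleCellFilterConfig <- function(...) {
  filterConfig(minAltDepth = 2L, ...)
}

#' Read a filter configuration file
#'
#' Reads a YAML (or `key: value`) file whose keys mirror the snake_case
#' field names of the evidence TSV dialect: `min_total_depth`,
#' `min_alt_depth`, `depth_switch`, `ratio_low_cov`, `ratio_high_cov`,
#' `sbs_low_cov`, `sbs_high_cov`, `rrps_lower`, `rrps_upper`. Absent keys
#' keep their defaults; unknown keys are an error.
#'
#' @param path path to the config file.
#' @param ... overrides applied after the file (e.g. CLI flags).
#' @return a [FilterConfig-class].
#' @export
readFilterConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  map <- c(min_total_depth = "minTotalDepth", min_alt_depth = "minAltDepth",
           depth_switch = "depthSwitch",
           ratio_low_cov = "ratioLowCov", ratio_high_cov = "ratioHighCov",
           sbs_low_cov = "sbsLowCov", sbs_high_cov = "sbsHighCov",
           rrps_lower = "rrpsLower", rrps_upper = "rrpsUpper")
  unknown <- setdiff(names(vals), names(map))
  if (length(unknown))
    stop("unknown filter config key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(vals, map[names(vals)])
  args[names(list(...))] <- list(...)
  do.call(filterConfig, args)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig:\n",
      " total depth >=", object@minTotalDepth,
      "; alt depth >=", object@minAltDepth, "\n",
      " allele fraction >", object@ratioLowCov, "(t <", object@depthSwitch,
      ") / >", object@ratioHighCov, "(t >=", object@depthSwitch, ")\n",
      " strand bias >", object@sbsLowCov, "/ >", object@sbsHighCov,
      "(same depth regimes)\n",
      " rank-sum in (", object@rrpsLower, ",", object@rrpsUpper,
      "), missing passes\n")
})

#' Apply the hard-filter battery
#'
#' Evaluates all five criteria of the eSNV hard-filter battery on every
#' evidence record, unconditionally (no short-circuiting), so each
#' verdict is fully reportable. Degenerate evidence (zero total or
#' alternate depth) fails the corresponding fraction/strand criteria
#' rather than erroring.
#'
#' @param x a [SiteEvidence-class].
#' @param config a [FilterConfig-class]; default [filterConfig()].
#' @return a `data.frame` with logical columns `passDepth`,
#'   `passAltDepth`, `passRatio`, `passStrandBias`, `passRrps` and their
#'   conjunction `passAll`, one row per evidence record.
#' @examples
#' ev <- siteEvidence("chr1", c(1L, 2L), "C", "A",
#'                    totalDepth = c(50L, 200L), altDepth = c(5L, 11L),
#'                    altFwd = c(2L, 5L), altRev = c(3L, 6L))
#' applyFilters(ev)   # 5/50 = 0.1 is not > 0.1: first site fails ratio
#' @export
applyFilters <- function(x, config = filterConfig()) {
  stopifnot(is(x, "SiteEvidence"), is(config, "FilterConfig"))
  t <- totalDepth(x); aa <- altDepth(x)
  high <- t >= config@depthSwitch
  ratio <- ifelse(t > 0L, aa / t, NA_real_)
  sbs <- ifelse(aa > 0L, pmin(altFwd(x), altRev(x)) / pmax(altFwd(x), altRev(x)),
                NA_real_)
  rr <- rrps(x)
  out <- data.frame(
    passDepth = t >= config@minTotalDepth,
    passAltDepth = aa >= config@minAltDepth,
    passRatio = !is.na(ratio) &
      ratio > ifelse(high, config@ratioHighCov, config@ratioLowCov),
    passStrandBias = !is.na(sbs) &
      sbs > ifelse(high, config@sbsHighCov, config@sbsLowCov),
    passRrps = is.na(rr) | (rr > config@rrpsLower & rr < config@rrpsUpper)
  )
  out$passAll <- out$passDepth & out$passAltDepth & out$passRatio &
    out$passStrandBias & out$passRrps
  out
}

.FILTER_CODES <- c(passDepth = "depth", passAltDepth = "alt_depth",
                   passRatio = "ratio", passStrandBias = "strand_bias",
                   passRrps = "rrps")

#' Verdicts as VCF FILTER codes
#'
#' Collapses an [applyFilters()] verdict table to one FILTER string per
#' record: `"PASS"`, or the semicolon-joined codes of the failed
#' criteria (`depth`, `alt_depth`, `ratio`, `strand_bias`, `rrps`).
#'
#' @param verdict a data.frame as returned by [applyFilters()].
#' @return character vector of FILTER strings.
#' @export
filterCodes <- function(verdict) {
  vapply(seq_len(nrow(verdict)), function(i) {
    failed <- .FILTER_CODES[!unlist(verdict[i, names(.FILTER_CODES)])]
    if (length(failed) == 0L) "PASS" else paste(failed, collapse = ";")
  }, character(1))
}
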