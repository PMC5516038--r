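#' @useDynLib brainRegulome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Plain-TSV helpers used by every I/O surface.  All tables are written
# with a header, tab separation, no quoting and no row names so that
# round-trips are byte-stable.

readTsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

writeTsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

# Format numbers for report files deterministically (fixed significant
# digits, no locale dependence).
fmtNum <- function(x, digits = 10) {
  formatC(x, digits = digits, format = "g")
}

#' Derive a reproducible sub-seed for a pipeline stage
#'
#' All randomized stages draw their seed from a single base seed plus a
#' stage label (and optional index), so that any stage can be re-run in
#' isolation with identical results.  Seeds stay below 2^31 - 1.
#'
#' @param seed Integer base seed.
#' @param stage Character stage label.
#' @param index Optional integer sub-index (e.g. run number).
#' @return An integer seed.
#' @export
stageSeed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (as.double(seed) * 48271 + h * 1299721 + as.double(index) * 7919) %%
    2147483647
  as.integer(s) + 1L
}

#' Draw the per-run seed list for the five-run robustness protocol
#'
#' A pool of 500 unique random numbers is drawn from the base seed and
#' \code{n} of them are used to initialize the independent analysis runs.
#'
#' @param seed Integer base seed.
#' @param n Number of runs (default 5).
#' @param poolSize Size of the unique-seed pool (default 500).
#' @return Integer vector of \code{n} unique seeds.
#' @export
runSeeds <- function(seed, n = 5L, poolSize = 500L) {
  set.seed(stageSeed(seed, "seed-pool"))
  pool <- sample.int(2147480000L, poolSize)
  sample(pool, n)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper around \code{\link[stats]{p.adjust}} with
#' \code{method = "BH"}; exposed so every stage adjusts p-values through
#' one documented surface.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
adjustBH <- function(p) {
  stats::p.adjust(p, method = "BH")
}
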