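#' Exact hypergeometric upper-tail probability
#'
#' Computes \eqn{P(X \ge k)} for \eqn{X} hypergeometric: the probability
#' that two sets of sizes \code{nA} and \code{nB}, drawn independently from
#' a universe of \code{N} genes, share at least \code{k} members.  This is
#' the gene-set-overlap enrichment p-value in the
#' \code{phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)} convention.
#' The sum is evaluated term by term in log space
#' (\code{lchoose}), which keeps the tail accurate far below double
#' underflow of the individual binomials.
#'
#' @param k observed intersection size, \code{0 <= k <= min(nA, nB)}.
#' @param N universe size.
#' @param nA,nB sizes of the two sets, each \code{<= N}.
#' @param log when TRUE, return the natural log of the tail probability
#'   (useful when the tail underflows the double range).
#' @return \eqn{P(X \ge k)} in \eqn{[0, 1]} (or its log); \code{k = 0}
#'   gives exactly 1.
#' @examples
#' hypergeomSF(8, N = 100, nA = 10, nB = 20)
#' @export
hypergeomSF <- function(k, N, nA, nB, log = FALSE) {
  k <- as.integer(k); N <- as.integer(N)
  nA <- as.integer(nA); nB <- as.integer(nB)
  if (N < 0L || nA < 0L || nB < 0L || nA > N || nB > N)
    stop("need 0 <= nA, nB <= N")
  if (k < 0L || k > min(nA, nB))
    stop("need 0 <= k <= min(nA, nB)")
  if (k == 0L) return(if (log) 0 else 1)
  i <- k:min(nA, nB)
  logTerms <- lchoose(nA, i) + lchoose(N - nA, nB - i) - lchoose(N, nB)
  mx <- max(logTerms)
  lp <- mx + base::log(sum(exp(logTerms - mx)))
  lp <- min(lp, 0)
  if (log) lp else exp(lp)
}

#' Hypergeometric point probability P(X = k)
#'
#' @inheritParams hypergeomSF
#' @return \eqn{P(X = k)}.
#' @export
hypergeomPMF <- function(k, N, nA, nB) {
  if (k < max(0L, nA + nB - N) || k > min(nA, nB)) return(0)
  exp(lchoose(nA, k) + lchoose(N - nA, nB - k) - lchoose(N, nB))
}

#' Overlap report for two gene sets
#'
#' Computes the intersection of two identifier sets, both directional
#' overlap percentages (what fraction of A is also in B, and vice versa -
#' published overlap figures rarely say which denominator they used, so
#' both are always reported), and the exact hypergeometric enrichment
#' p-value \eqn{P(X \ge k)}.
#'
#' The universe is a required, explicit input: either the universe size or
#' the universe set itself (in which case both sets must be subsets of it).
#' No default universe is silently assumed.
#'
#' @param setA,setB character vectors of identifiers (uppercased and
#'   de-duplicated internally, as in [readGeneList()]).
#' @param universe either a single number (the universe size) or a
#'   character vector (the universe set).
#' @param labelA,labelB labels used in the report.
#' @return an [OverlapResult-class].
#' @examples
#' gs <- generateGeneSets(N = 100, nA = 10, nB = 20, k = 8, seed = 1)
#' overlapReport(gs$setA, gs$setB, universe = gs$universe)
#' @export
overlapReport <- function(setA, setB, universe,
                          labelA = "A", labelB = "B") {
  A <- unique(toupper(setA)); B <- unique(toupper(setB))
  if (is.character(universe)) {
    U <- unique(toupper(universe))
    outA <- setdiff(A, U); outB <- setdiff(B, U)
    if (length(outA) || length(outB))
      stop("identifiers outside the universe: ",
           paste(utils::head(c(outA, outB), 5L), collapse = ", "))
    N <- length(U)
  } else {
    N <- as.integer(universe)
    if (length(N) != 1L || is.na(N))
      stop("'universe' must be a universe set or a single size")
    if (N < length(union(A, B)))
      stop("universe size ", N, " is smaller than |A union B| = ",
           length(union(A, B)))
  }
  k <- length(intersect(A, B))
  new("OverlapResult", labelA = labelA, labelB = labelB,
      N = N, nA = length(A), nB = length(B), k = as.integer(k),
      pctOfA = 100 * k / length(A), pctOfB = 100 * k / length(B),
      pValue = hypergeomSF(k, N, length(A), length(B)))
}

#' Turn overlap results into a flat report table
#'
#' @param results list of [OverlapResult-class] objects (or a single one).
#' @param adjust when TRUE, adds Benjamini-Hochberg adjusted p-values
#'   across the supplied comparisons (useful for batched runs).
#' @return data.frame with one row per comparison.
#' @importFrom stats p.adjust
#' @export
overlapTable <- function(results, adjust = FALSE) {
  if (is(results, "OverlapResult")) results <- list(results)
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(set_a = r@labelA, set_b = r@labelB, universe = r@N,
               n_a = r@nA, n_b = r@nB, k = r@k,
               pct_of_a = r@pctOfA, pct_of_b = r@pctOfB,
               p_value = r@pValue, stringsAsFactors = FALSE)
  }))
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
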