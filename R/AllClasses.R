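#' @import methods
#' @importFrom stats setNames
NULL

AA_STANDARD20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

#' ConsensusPattern: residue-class + fixed-spacer motif grammar
#'
#' A consensus pattern is an ordered list of elements, each either a residue
#' class (one or more allowed residues at that position, e.g. \code{C} or
#' \code{(V/L)}) or a fixed-length any-residue spacer (\code{xN}).  The
#' minimum (and, for this grammar, exact) match length is the number of
#' residue-class positions plus the summed spacer lengths.  This is the
#' notation used for zinc-finger B-Box consensus structures such as
#' \code{Cx2Cx8Cx7Cx2Cx4Hx8H} and for short interaction motifs such as
#' \code{PF(V/L)FL} and \code{LxLxL}.
#'
#' @slot name single character label for the pattern.
#' @slot elements list of elements; each element is a list with \code{type}
#'   (\code{"class"} or \code{"spacer"}) and either \code{residues}
#'   (character vector of allowed residues) or \code{length} (spacer width).
#' @slot minMatchLength integer, the exact width of any match.
#'
#' @seealso [parseConsensus()], [scanConsensus()], [bboxPatterns()]
#' @exportClass ConsensusPattern
setClass("ConsensusPattern",
         representation(name = "character",
                        elements = "list",
                        minMatchLength = "integer"))

setValidity("ConsensusPattern", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  width <- 0L
  for (el in object@elements) {
    if (!is.list(el) || is.null(el$type) ||
        !el$type %in% c("class", "spacer")) {
      msg <- c(msg, "each element must be a list with type 'class' or 'spacer'")
      break
    }
    if (el$type == "class") {
      if (!all(el$residues %in% AA_STANDARD20))
        msg <- c(msg, "residue classes must use the 20 standard residues")
      width <- width + 1L
    } else {
      if (!is.numeric(el$length) || el$length < 1)
        msg <- c(msg, "spacer length must be a positive integer")
      else width <- width + as.integer(el$length)
    }
  }
  if (length(msg) == 0L && width != object@minMatchLength)
    msg <- c(msg, sprintf("minMatchLength (%d) does not equal element width sum (%d)",
                          object@minMatchLength, width))
  if (length(msg)) msg else TRUE
})

#' ScreenConfig: parameters of the microProtein screen
#'
#' Holds the tunable thresholds of the candidate screen: the strict size
#' cut-off (a candidate must be shorter than \code{maxLength} residues), the
#' whitelist of protein-interaction-capable domain accessions, and the
#' multi-domain requirement imposed on larger relatives before they count as
#' putative targets.
#'
#' @slot maxLength numeric; candidates must satisfy length < maxLength
#'   (default 140, strict).
#' @slot ppiDomains character vector of domain accessions deemed capable of
#'   mediating protein-protein interaction.
#' @slot requireMultidomainRelative logical; when TRUE a qualifying relative
#'   must carry extra distinct domains beyond the shared one.
#' @slot minRelativeExtraDomains integer >= 1; number of extra distinct
#'   domains a relative must carry (so a target has at least
#'   1 + minRelativeExtraDomains distinct domains... see [screenConfig()]).
#'
#' @seealso [screenConfig()], [screenMicroCandidates()]
#' @exportClass ScreenConfig
setClass("ScreenConfig",
         representation(maxLength = "numeric",
                        ppiDomains = "character",
                        requireMultidomainRelative = "logical",
                        minRelativeExtraDomains = "integer"))

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (length(object@maxLength) != 1L || object@maxLength <= 0)
    msg <- c(msg, "'maxLength' must be a single positive number")
  if (length(object@minRelativeExtraDomains) != 1L ||
      object@minRelativeExtraDomains < 1L)
    msg <- c(msg, "'minRelativeExtraDomains' must be >= 1")
  if (anyDuplicated(object@ppiDomains))
    msg <- c(msg, "'ppiDomains' must not contain duplicates")
  if (length(msg)) msg else TRUE
})

#' DomainArchitecture: resolved, non-overlapping domains of one protein
#'
#' @slot proteinId protein identifier.
#' @slot domains data.frame with columns \code{protein_id},
#'   \code{domain_accession}, \code{domain_name}, \code{start}, \code{end},
#'   \code{evalue}; rows ordered by start and pairwise non-overlapping under
#'   the retention rule of [resolveArchitecture()].
#' @slot nDistinct integer count of distinct domain accessions retained.
#'
#' @seealso [resolveArchitecture()]
#' @exportClass DomainArchitecture
setClass("DomainArchitecture",
         representation(proteinId = "character",
                        domains = "data.frame",
                        nDistinct = "integer"))

setValidity("DomainArchitecture", function(object) {
  msg <- character()
  d <- object@domains
  if (nrow(d) && is.unsorted(d$start))
    msg <- c(msg, "domains must be ordered by start")
  nd <- length(unique(d$domain_accession))
  if (object@nDistinct != nd)
    msg <- c(msg, sprintf("nDistinct (%d) != distinct accessions (%d)",
                          object@nDistinct, nd))
  if ((object@nDistinct == 0L) != (nrow(d) == 0L))
    msg <- c(msg, "nDistinct must be 0 exactly when no domain is retained")
  if (length(msg)) msg else TRUE
})

#' AlignmentResult: a global pairwise protein alignment
#'
#' @slot alignedA,alignedB equal-length gapped strings ('-' for gaps);
#'   removing the gaps recovers the input sequences.
#' @slot score alignment score under the substitution matrix and affine gap
#'   penalties used.
#' @slot nIdentical number of columns where both sequences carry the same
#'   residue.
#' @slot nColumns alignment length.
#' @slot identityPct percent identity under the convention the result was
#'   computed with (default: identical columns / alignment length).
#'
#' @seealso [globalAlign()], [percentIdentity()]
#' @exportClass AlignmentResult
setClass("AlignmentResult",
         representation(alignedA = "character",
                        alignedB = "character",
                        score = "numeric",
                        nIdentical = "integer",
                        nColumns = "integer",
                        identityPct = "numeric"))

setValidity("AlignmentResult", function(object) {
  msg <- character()
  if (nchar(object@alignedA) != nchar(object@alignedB))
    msg <- c(msg, "aligned strings must have equal length")
  if (nchar(object@alignedA) != object@nColumns)
    msg <- c(msg, "nColumns must equal the aligned string length")
  if (object@identityPct < 0 || object@identityPct > 100)
    msg <- c(msg, "identityPct must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' OverlapResult: overlap of two gene sets with hypergeometric p-value
#'
#' @slot labelA,labelB labels of the two sets.
#' @slot N universe size.
#' @slot nA,nB set sizes.
#' @slot k intersection size.
#' @slot pctOfA percentage of set A also found in B (100 k / nA).
#' @slot pctOfB percentage of set B also found in A (100 k / nB).
#' @slot pValue upper-tail hypergeometric probability P(X >= k), i.e. the
#'   enrichment p-value in the \code{phyper(k - 1, ..., lower.tail = FALSE)}
#'   convention.
#'
#' @seealso [overlapReport()], [hypergeomSF()]
#' @exportClass OverlapResult
setClass("OverlapResult",
         representation(labelA = "character", labelB = "character",
                        N = "integer", nA = "integer", nB = "integer",
                        k = "integer",
                        pctOfA = "numeric", pctOfB = "numeric",
                        pValue = "numeric"))

setValidity("OverlapResult", function(object) {
  msg <- character()
  if (object@k > min(object@nA, object@nB))
    msg <- c(msg, "k cannot exceed min(nA, nB)")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (object@k == 0L && object@pValue != 1)
    msg <- c(msg, "k = 0 forces pValue = 1")
  if (length(msg)) msg else TRUE
})
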