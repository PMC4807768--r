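#' @rdname ConsensusPattern-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("minMatchLength", function(x) standardGeneric("minMatchLength"))

#' @rdname DomainArchitecture-class
#' @export
setGeneric("nDistinct", function(x) standardGeneric("nDistinct"))

#' @rdname DomainArchitecture-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname AlignmentResult-class
#' @export
setGeneric("identityPct", function(x) standardGeneric("identityPct"))

#' @rdname AlignmentResult-class
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname AlignmentResult-class
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))

#' @rdname OverlapResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

setMethod("minMatchLength", "ConsensusPattern", function(x) x@minMatchLength)
setMethod("nDistinct", "DomainArchitecture", function(x) x@nDistinct)
setMethod("domains", "DomainArchitecture", function(x) x@domains)
setMethod("identityPct", "AlignmentResult", function(x) x@identityPct)
setMethod("alignmentScore", "AlignmentResult", function(x) x@score)
setMethod("alignedSeqs", "AlignmentResult",
          function(x) c(a = x@alignedA, b = x@alignedB))
setMethod("pValue", "OverlapResult", function(x) x@pValue)

#' @rdname ConsensusPattern-class
#' @export
setMethod("show", "ConsensusPattern", function(object) {
  cat("ConsensusPattern '", object@name, "': ",
      renderConsensus(object),
      " (match width ", object@minMatchLength, ")\n", sep = "")
})

#' @rdname ScreenConfig-class
#' @export
setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig: length <", object@maxLength, "aa;",
      length(object@ppiDomains), "PPI-capable domain accessions;",
      "relatives need >=", object@minRelativeExtraDomains,
      "extra distinct domain(s)\n")
})

#' @rdname DomainArchitecture-class
#' @export
setMethod("show", "DomainArchitecture", function(object) {
  cat("DomainArchitecture of", object@proteinId, "-",
      nrow(object@domains), "domain(s),", object@nDistinct, "distinct\n")
  if (nrow(object@domains))
    print(object@domains[, c("domain_accession", "domain_name",
                             "start", "end")], row.names = FALSE)
})

#' @rdname AlignmentResult-class
#' @export
setMethod("show", "AlignmentResult", function(object) {
  cat("Global alignment:", object@nColumns, "columns,",
      object@nIdentical, "identical, score", object@score,
      sprintf("(%.1f%% identity)\n", object@identityPct))
})

#' @rdname OverlapResult-class
#' @export
setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("Overlap %s (n=%d) vs %s (n=%d) in universe N=%d:\n",
              object@labelA, object@nA, object@labelB, object@nB, object@N))
  cat(sprintf("  k = %d shared (%.1f%% of A, %.1f%% of B), P(X >= k) = %.3g\n",
              object@k, object@pctOfA, object@pctOfB, object@pValue))
})
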