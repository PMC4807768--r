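#' Resolve raw domain hits into a non-overlapping architecture
#'
#' Raw domain scans routinely call several overlapping models over the same
#' region.  This resolver ranks all hits of one protein best-first by E-value
#' (ties broken by smaller start, then accession lexicographically) and keeps
#' a hit only if, against every already-kept hit, the number of shared
#' residues is at most \code{overlapFraction} times the length of the shorter
#' of the two hits.  The retained hits, sorted by start, form the protein's
#' domain architecture; the count of distinct accessions among them decides
#' single- versus multi-domain status in the screen.
#'
#' @param hits data.frame of domain hits for one protein (columns as from
#'   [readDomainHits()]); all rows must share one \code{protein_id}.
#' @param overlapFraction maximum tolerated shared-residue fraction of the
#'   shorter hit (default 0.5).
#' @param proteinLength optional protein length; when given, hits extending
#'   beyond it raise an error.
#' @return a [DomainArchitecture-class] object.
#' @examples
#' hits <- data.frame(protein_id = "P1",
#'                    domain_accession = c("PF00643", "PF00010"),
#'                    domain_name = c("zf-B_box", "HLH"),
#'                    start = c(5L, 100L), end = c(41L, 140L),
#'                    evalue = c(1e-10, 1e-8))
#' arch <- resolveArchitecture(hits)
#' nDistinct(arch)   # 2
#' @export
resolveArchitecture <- function(hits, overlapFraction = 0.5,
                                proteinLength = NULL) {
  pid <- unique(hits$protein_id)
  if (length(pid) > 1L)
    stop("hits span multiple proteins: ", paste(pid, collapse = ", "))
  if (length(pid) == 0L) pid <- NA_character_
  if (nrow(hits) == 0L) {
    return(new("DomainArchitecture", proteinId = pid,
               domains = hits, nDistinct = 0L))
  }
  if (!is.null(proteinLength)) {
    over <- hits$end > proteinLength | hits$start < 1L
    if (any(over))
      stop("domain hit outside protein ", pid, " (length ", proteinLength,
           "): ", hits$domain_accession[which(over)[1L]], " ",
           hits$start[which(over)[1L]], "-", hits$end[which(over)[1L]])
  }
  ord <- order(hits$evalue, hits$start, hits$domain_accession)
  ranked <- hits[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    ok <- TRUE
    for (j in kept) {
      if (!.hitsCompatible(ranked$start[i], ranked$end[i],
                           ranked$start[j], ranked$end[j],
                           overlapFraction)) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  dom <- ranked[kept, , drop = FALSE]
  dom <- dom[order(dom$start, dom$end, dom$domain_accession), , drop = FALSE]
  rownames(dom) <- NULL
  new("DomainArchitecture", proteinId = pid, domains = dom,
      nDistinct = length(unique(dom$domain_accession)))
}

# shared-residue overlap rule: compatible iff overlap <= frac * shorter length
.hitsCompatible <- function(s1, e1, s2, e2, frac) {
  shared <- min(e1, e2) - max(s1, s2) + 1L
  if (shared <= 0L) return(TRUE)
  shorter <- min(e1 - s1 + 1L, e2 - s2 + 1L)
  shared <= frac * shorter
}

#' Resolve architectures for a whole proteome
#'
#' @param hits data.frame of domain hits across proteins.
#' @param proteome optional [Biostrings::AAStringSet]; when given, proteins
#'   without any hit still receive an (empty) architecture and hit
#'   coordinates are checked against protein lengths.
#' @param overlapFraction passed to [resolveArchitecture()].
#' @return a named list of [DomainArchitecture-class] objects.
#' @importFrom Biostrings width
#' @export
resolveArchitectures <- function(hits, proteome = NULL,
                                 overlapFraction = 0.5) {
  ids <- unique(hits$protein_id)
  if (!is.null(proteome)) {
    unknown <- setdiff(ids, names(proteome))
    if (length(unknown))
      stop("domain hits for protein(s) absent from the proteome: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    ids <- names(proteome)
  }
  lens <- if (is.null(proteome)) NULL else
    stats::setNames(Biostrings::width(proteome), names(proteome))
  out <- lapply(ids, function(id) {
    resolveArchitecture(hits[hits$protein_id == id, , drop = FALSE],
                        overlapFraction = overlapFraction,
                        proteinLength = if (is.null(lens)) NULL else lens[[id]])
  })
  # empty-table architectures keep the protein id
  for (i in seq_along(out)) if (is.na(out[[i]]@proteinId))
    out[[i]]@proteinId <- ids[i]
  stats::setNames(out, ids)
}

#' Summarise domain usage across a set of architectures
#'
#' @param architectures list of [DomainArchitecture-class] objects.
#' @return data.frame with one row per domain accession and columns
#'   \code{domain_accession}, \code{n_proteins_carrying},
#'   \code{n_total_occurrences}, ordered by descending protein count and
#'   then accession.
#' @export
domainCensus <- function(architectures) {
  empty <- data.frame(domain_accession = character(),
                      n_proteins_carrying = integer(),
                      n_total_occurrences = integer(),
                      stringsAsFactors = FALSE)
  if (length(architectures) == 0L) return(empty)
  per <- lapply(architectures, function(a) a@domains$domain_accession)
  accs <- unlist(per, use.names = FALSE)
  if (length(accs) == 0L) return(empty)
  occ <- table(accs)
  carry <- table(unlist(lapply(per, unique), use.names = FALSE))
  out <- data.frame(domain_accession = names(occ),
                    n_proteins_carrying = as.integer(carry[names(occ)]),
                    n_total_occurrences = as.integer(occ),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_proteins_carrying, out$domain_accession), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
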