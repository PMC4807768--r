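#' Construct a microProtein screen configuration
#'
#' The screen keeps a protein as a microProtein candidate when it (1) is
#' small (strictly shorter than \code{maxLength} residues), (2) carries
#' exactly one distinct Pfam domain and that domain is on the
#' protein-interaction-capable whitelist, and (3) is related to at least one
#' strictly longer protein that shares the domain and carries additional
#' distinct domains.  The fourth property of a genuine microProtein - a
#' dominant-negative mode of action - is an experimental observation and is
#' deliberately not encoded.
#'
#' @param maxLength strict upper size bound in residues (default 140; a
#'   protein of exactly \code{maxLength} residues is rejected).
#' @param ppiDomains character vector of whitelisted domain accessions; the
#'   default is the list shipped in
#'   \code{system.file("extdata", "ppi_domains.tsv", package = "mipscan")},
#'   a seed covering zinc-finger (including the B-Box accession),
#'   helix-loop-helix and common plant transcription-factor domain classes.
#'   The whitelist is data, not code: pass your own for other lineages.
#' @param requireMultidomainRelative when TRUE (default) a relative only
#'   counts as a putative target if it carries extra distinct domains.
#' @param minRelativeExtraDomains minimum number of distinct domains a
#'   target must carry beyond the shared one (default 1, so targets have at
#'   least two distinct domains).
#' @return a [ScreenConfig-class] object.
#' @export
screenConfig <- function(maxLength = 140,
                         ppiDomains = defaultPPIDomains(),
                         requireMultidomainRelative = TRUE,
                         minRelativeExtraDomains = 1L) {
  new("ScreenConfig", maxLength = maxLength,
      ppiDomains = unique(as.character(ppiDomains)),
      requireMultidomainRelative = requireMultidomainRelative,
      minRelativeExtraDomains = as.integer(minRelativeExtraDomains))
}

#' Default whitelist of protein-interaction-capable domain accessions
#'
#' @param path a text file whose first (tab-separated) column holds domain
#'   accessions, one per line; a \code{domain_accession} header row is
#'   recognised and skipped.  Defaults to the whitelist shipped with the
#'   package.
#' @return character vector of accessions (version-stripped).
#' @export
defaultPPIDomains <- function(path = system.file("extdata",
                                                 "ppi_domains.tsv",
                                                 package = "mipscan")) {
  lines <- trimws(sub("\r$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  acc <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  if (length(acc) && identical(tolower(acc[1L]), "domain_accession"))
    acc <- acc[-1L]
  if (length(acc) == 0L) stop("no accessions in whitelist file: ", path)
  unique(stripAccessionVersion(acc))
}

# one row per (protein, distinct accession) + per-protein summary
.archIndex <- function(architectures, lens) {
  pid <- vapply(architectures, function(a) a@proteinId, character(1))
  nd <- vapply(architectures, nDistinct, integer(1))
  accs <- lapply(architectures, function(a) unique(a@domains$domain_accession))
  prot <- data.frame(protein_id = pid, n_distinct = nd,
                     length = as.integer(lens[pid]),
                     stringsAsFactors = FALSE)
  carrier <- data.frame(
    protein_id = rep(pid, lengths(accs)),
    domain_accession = unlist(accs, use.names = FALSE),
    stringsAsFactors = FALSE)
  list(prot = prot, carrier = carrier,
       firstDomain = lapply(architectures, function(a) a@domains))
}

#' Screen a proteome for microProtein candidates
#'
#' Applies the three computable microProtein criteria (see [screenConfig()])
#' to a proteome and its resolved domain architectures.  For every candidate
#' the putative larger targets are all proteins that share the candidate's
#' domain accession, are strictly longer, and (by default) carry at least
#' one extra distinct domain; targets are ordered by descending distinct
#' domain count, then descending length, then id.  Candidates are grouped
#' into families by their domain accession.
#'
#' @param proteome an [Biostrings::AAStringSet] from [readProteome()].
#' @param architectures named list of [DomainArchitecture-class] objects
#'   (see [resolveArchitectures()]); every architecture's protein must exist
#'   in the proteome.
#' @param config a [ScreenConfig-class]; default [screenConfig()].
#' @return data.frame with one row per candidate and columns
#'   \code{candidate_id}, \code{length}, \code{domain_accession},
#'   \code{domain_name}, \code{family}, \code{n_targets}, \code{target_ids}
#'   (comma-joined, in target order), sorted by family then candidate id.
#'   The attribute \code{"screen_counts"} records how many proteins survive
#'   each criterion in turn.
#' @examples
#' sim <- generateProteome(nFamilies = 2, candidatesPerFamily = 2, seed = 7)
#' arch <- resolveArchitectures(sim$hits, sim$proteome)
#' cand <- screenMicroCandidates(sim$proteome, arch,
#'                               screenConfig(ppiDomains = sim$ppiDomains))
#' cand$candidate_id
#' @importFrom Biostrings width
#' @export
screenMicroCandidates <- function(proteome, architectures,
                                  config = screenConfig()) {
  validObject(config)
  if (length(config@ppiDomains) == 0L)
    stop("configuration error: the PPI-capable domain whitelist is empty")
  pid <- vapply(architectures, function(a) a@proteinId, character(1))
  unknown <- setdiff(pid, names(proteome))
  if (length(unknown))
    stop("architectures reference protein(s) absent from the proteome: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  lens <- stats::setNames(Biostrings::width(proteome), names(proteome))
  ix <- .archIndex(architectures, lens)
  prot <- ix$prot

  small <- prot$length < config@maxLength
  single <- prot$n_distinct == 1L
  acc1 <- rep(NA_character_, nrow(prot))
  name1 <- rep(NA_character_, nrow(prot))
  for (i in which(single)) {
    d <- ix$firstDomain[[i]]
    acc1[i] <- d$domain_accession[1L]
    name1[i] <- d$domain_name[1L]
  }
  ppi <- single & acc1 %in% config@ppiDomains

  counts <- c(proteins = nrow(prot),
              small = sum(small),
              small_single_domain = sum(small & single),
              small_single_ppi = sum(small & ppi))

  rows <- list()
  for (i in which(small & ppi)) {
    tg <- .qualifyingTargets(prot$protein_id[i], acc1[i], prot$length[i],
                             ix, config)
    if (length(tg) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      candidate_id = prot$protein_id[i],
      length = prot$length[i],
      domain_accession = acc1[i],
      domain_name = name1[i],
      family = acc1[i],
      n_targets = length(tg),
      target_ids = paste(tg, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(candidate_id = character(), length = integer(),
               domain_accession = character(), domain_name = character(),
               family = character(), n_targets = integer(),
               target_ids = character(), stringsAsFactors = FALSE)
  out <- out[order(out$family, out$candidate_id), , drop = FALSE]
  rownames(out) <- NULL
  counts <- c(counts, candidates = nrow(out))
  attr(out, "screen_counts") <- counts
  out
}

.qualifyingTargets <- function(candId, accession, candLen, ix, config) {
  carriers <- ix$carrier$protein_id[ix$carrier$domain_accession == accession]
  carriers <- setdiff(carriers, candId)
  if (length(carriers) == 0L) return(character())
  prot <- ix$prot[match(carriers, ix$prot$protein_id), , drop = FALSE]
  minDistinct <- if (config@requireMultidomainRelative)
    1L + config@minRelativeExtraDomains else 1L
  ok <- prot$length > candLen & prot$n_distinct >= minDistinct
  prot <- prot[ok, , drop = FALSE]
  prot <- prot[order(-prot$n_distinct, -prot$length, prot$protein_id), ,
               drop = FALSE]
  prot$protein_id
}

#' Candidate counts per family
#'
#' @param candidates data.frame from [screenMicroCandidates()].
#' @return data.frame with columns \code{family}, \code{n_candidates}, one
#'   row per family, ordered by descending count then family; counts sum to
#'   the candidate total.
#' @export
familySummary <- function(candidates) {
  if (nrow(candidates) == 0L)
    return(data.frame(family = character(), n_candidates = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(candidates$family)
  out <- data.frame(family = names(tab), n_candidates = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_candidates, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ordered putative targets of one screened candidate
#'
#' Recomputes the target list of a candidate that passed the screen: all
#' strictly longer proteins sharing the candidate's domain accession and
#' satisfying the multi-domain requirement, ordered by descending distinct
#' domain count, then length, then id (the better-annotated relative first).
#'
#' @param candidateId protein id of a screen candidate.
#' @param proteome,architectures,config as in [screenMicroCandidates()].
#' @return character vector of target protein ids (possibly empty).
#' @importFrom Biostrings width
#' @export
pairTargets <- function(candidateId, proteome, architectures,
                        config = screenConfig()) {
  if (!candidateId %in% names(proteome))
    stop("unknown protein id: ", candidateId)
  arch <- architectures[[candidateId]]
  if (is.null(arch))
    stop("no architecture for protein: ", candidateId)
  if (nDistinct(arch) != 1L)
    stop("protein ", candidateId, " does not carry exactly one distinct ",
         "domain; it cannot have been a screen candidate")
  lens <- stats::setNames(Biostrings::width(proteome), names(proteome))
  ix <- .archIndex(architectures, lens)
  .qualifyingTargets(candidateId,
                     arch@domains$domain_accession[1L],
                     lens[[candidateId]], ix, config)
}
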