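#' Read a protein FASTA file into a validated AAStringSet
#'
#' Reads protein sequences with \code{Biostrings::readAAStringSet} and then
#' enforces the proteome contract used throughout the package: sequences are
#' uppercased, a single trailing stop character \code{'*'} (common in
#' translated ORFeome files) is stripped before lengths are computed,
#' residues must come from the 20 standard amino acids plus \code{X}, and
#' record identifiers (the first whitespace-delimited word of each header)
#' must be unique.  The remainder of the header is kept as the record
#' description in \code{mcols(x)$description}.
#'
#' @param path path to a protein FASTA file.
#' @return an [Biostrings::AAStringSet] named by protein id, with the
#'   description in its metadata columns.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 toy protein", "MKVLLE", ">p2", "MGA*"), fa)
#' prot <- readProteome(fa)
#' width(prot)   # 6 and 3: the trailing stop of p2 is stripped
#' @importFrom Biostrings readAAStringSet AAStringSet width
#' @importFrom S4Vectors mcols mcols<-
#' @export
readProteome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # validate the raw lines first: the Biostrings reader silently drops
  # codes outside its alphabet, which would mask corrupt input
  lineno <- .findBadResidueLine(readLines(path, warn = FALSE))
  if (!is.na(lineno))
    stop("invalid residue in ", path, " (line ", lineno,
         "); allowed: 20 standard residues, X, and a single trailing '*'")
  aa <- Biostrings::readAAStringSet(path, format = "fasta")
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 trimws(sub("^\\S+\\s+", "", headers)), "")
  if (any(!nzchar(ids))) stop("FASTA header with empty id in ", path)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate protein id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)        # single trailing translated stop
  bad <- grepl(paste0("[^", paste(AA_STANDARD20, collapse = ""), "X]"), seqs)
  if (any(bad)) {
    # locate the offending line for the error message
    lines <- readLines(path, warn = FALSE)
    lineno <- .findBadResidueLine(lines)
    stop("invalid residue in record '", ids[which(bad)[1L]],
         "' of ", path,
         if (!is.na(lineno)) paste0(" (line ", lineno, ")") else "",
         "; allowed: 20 standard residues, X, and a single trailing '*'")
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

.findBadResidueLine <- function(lines) {
  lines <- sub("\r$", "", lines)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, ">")) next
    body <- toupper(ln)
    body <- sub("\\*$", "", body)
    if (grepl(paste0("[^", paste(AA_STANDARD20, collapse = ""), "X]"), body))
      return(i)
  }
  NA_integer_
}

#' Write a proteome back to FASTA
#'
#' @param x an [Biostrings::AAStringSet] as returned by [readProteome()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @importFrom Biostrings writeXStringSet
#' @importFrom S4Vectors mcols
#' @export
writeProteome <- function(x, path) {
  desc <- S4Vectors::mcols(x)$description
  nm <- names(x)
  if (!is.null(desc)) {
    has <- nzchar(desc)
    nm[has] <- paste(nm[has], desc[has])
  }
  y <- x
  names(y) <- nm
  Biostrings::writeXStringSet(y, filepath = path)
  invisible(path)
}

#' Read per-protein domain annotations
#'
#' Two dialects are supported.  The \code{"tsv"} dialect is a plain
#' tab-separated table with columns \code{protein_id}, \code{domain_accession},
#' \code{domain_name}, \code{start}, \code{end}, \code{evalue} (a header row
#' naming these columns is recognised and skipped).  The \code{"domtblout"}
#' dialect is the HMMER3 \code{hmmscan --domtblout} per-domain table:
#' \code{'#'} comment lines are skipped, fields are whitespace-split, the
#' protein is the query (column 4), the domain is the target (name in
#' column 1, accession in column 2), alignment coordinates ("ali" from/to,
#' columns 18/19) give start/end, and the per-domain independent E-value
#' (column 13) is used as the ranking score.
#'
#' Version suffixes on accessions (\code{PF00643.25}) are stripped on ingest
#' so that distinct-domain counting is release-independent.  Coordinates are
#' 1-based inclusive.
#'
#' @param path file to read.
#' @param dialect \code{"tsv"} or \code{"domtblout"}.
#' @return a data.frame of domain hits with columns \code{protein_id},
#'   \code{domain_accession}, \code{domain_name}, \code{start}, \code{end},
#'   \code{evalue}, one row per hit in file order.
#' @export
readDomainHits <- function(path, dialect = c("tsv", "domtblout")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("domain table not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- nzchar(trimws(lines))
  if (dialect == "domtblout") keep <- keep & !startsWith(lines, "#")
  idx <- which(keep)
  rows <- vector("list", length(idx))
  j <- 0L
  for (i in idx) {
    ln <- lines[i]
    if (dialect == "tsv") {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      f <- trimws(f)
      if (length(f) >= 1L && identical(tolower(f[1L]), "protein_id")) next
      if (length(f) < 6L)
        stop("unparsable domain line ", i, " in ", path,
             ": expected 6 tab-separated fields")
      rec <- list(protein_id = f[1L],
                  domain_accession = f[2L],
                  domain_name = f[3L],
                  start = suppressWarnings(as.integer(f[4L])),
                  end = suppressWarnings(as.integer(f[5L])),
                  evalue = suppressWarnings(as.numeric(f[6L])))
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(f) < 22L)
        stop("unparsable domtblout line ", i, " in ", path,
             ": expected >= 22 whitespace-separated fields")
      rec <- list(protein_id = f[4L],
                  domain_accession = f[2L],
                  domain_name = f[1L],
                  start = suppressWarnings(as.integer(f[18L])),
                  end = suppressWarnings(as.integer(f[19L])),
                  evalue = suppressWarnings(as.numeric(f[13L])))
    }
    if (is.na(rec$start) || is.na(rec$end) || is.na(rec$evalue))
      stop("unparsable domain line ", i, " in ", path,
           ": non-numeric coordinate or E-value")
    if (rec$end < rec$start)
      stop("domain line ", i, " in ", path, ": end (", rec$end,
           ") < start (", rec$start, ")")
    j <- j + 1L
    rows[[j]] <- rec
  }
  rows <- rows[seq_len(j)]
  out <- if (j == 0L) {
    data.frame(protein_id = character(), domain_accession = character(),
               domain_name = character(), start = integer(), end = integer(),
               evalue = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  }
  out$domain_accession <- stripAccessionVersion(out$domain_accession)
  rownames(out) <- NULL
  out
}

#' Strip the version suffix from domain accessions
#'
#' @param x character vector of accessions, e.g. \code{"PF00643.25"}.
#' @return the accessions without a trailing \code{.N} version.
#' @export
stripAccessionVersion <- function(x) sub("\\.\\d+$", "", x)

#' Read a gene-identifier list
#'
#' One identifier per line; identifiers are whitespace-trimmed, uppercased
#' (AGI locus names such as \code{At3g21890} are case-insensitive in
#' practice) and de-duplicated; blank lines are ignored.
#'
#' @param path file with one gene id per line.
#' @return a character vector of unique uppercase identifiers.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  ids <- trimws(sub("\r$", "", readLines(path, warn = FALSE)))
  ids <- unique(toupper(ids[nzchar(ids)]))
  if (length(ids) == 0L)
    stop("gene list ", path, " contains no identifiers")
  ids
}

#' Write the candidate table of a screen run
#'
#' Writes a deterministic TSV report (header
#' \code{candidate_id, length, domain_accession, domain_name, family,
#' n_targets, target_ids}) sorted by family and then candidate id, so that
#' identical screen results always produce byte-identical files.
#'
#' @param candidates candidate data.frame as returned by
#'   [screenMicroCandidates()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @importFrom utils write.table
#' @export
writeCandidates <- function(candidates, path) {
  cols <- c("candidate_id", "length", "domain_accession", "domain_name",
            "family", "n_targets", "target_ids")
  if (nrow(candidates)) {
    candidates <- candidates[order(candidates$family,
                                   candidates$candidate_id), cols]
  } else {
    candidates <- candidates[, cols]
  }
  con <- file(path, open = "wb")    # fixed newline on every platform
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(candidates)) {
    body <- apply(candidates, 1L, function(r) paste(r, collapse = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
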