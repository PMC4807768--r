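.asAAString <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1L) stop("expected a single sequence")
  s
}

#' Parse a residue-class/spacer consensus pattern
#'
#' The grammar mirrors the notation in which zinc-finger B-Box consensus
#' structures are written: an uppercase letter is a fixed residue, a
#' bracketed alternative \code{(V/L)} allows any of the listed residues, and
#' a lowercase \code{x} is an any-residue spacer, optionally followed by an
#' integer repeat count (\code{x8} = eight arbitrary residues).  Whitespace
#' and underscores are ignored, so \code{Cx_2_Cx_8_...} and
#' \code{Cx2Cx8...} are the same pattern.  Adjacent spacers are merged.
#'
#' @param text pattern text, e.g. \code{"Cx2Cx7Cx7Cx2Cx4Hx8H"},
#'   \code{"PF(V/L)FL"} or \code{"LxLxL"}.
#' @param name optional label; defaults to the cleaned pattern text.
#' @return a [ConsensusPattern-class] object; its \code{minMatchLength} is
#'   the exact width of every match (residue-class positions plus spacer
#'   lengths).
#' @examples
#' minMatchLength(parseConsensus("Cx2Cx7Cx7Cx2Cx4Hx8H"))  # 37
#' minMatchLength(parseConsensus("Cx2Cx8Cx7Cx2Cx4Hx8H"))  # 38
#' minMatchLength(parseConsensus("PF(V/L)FL"))            # 5
#' @export
parseConsensus <- function(text, name = NULL) {
  if (length(text) != 1L || !nzchar(text))
    stop("pattern text must be a single non-empty string")
  clean <- gsub("[_[:space:]]", "", text)
  chars <- strsplit(clean, "", fixed = TRUE)[[1L]]
  elements <- list()
  i <- 1L
  n <- length(chars)
  addSpacer <- function(len) {
    last <- length(elements)
    if (last > 0L && elements[[last]]$type == "spacer") {
      elements[[last]]$length <<- elements[[last]]$length + len
    } else {
      elements[[last + 1L]] <<- list(type = "spacer", length = len)
    }
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "x") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- if (j > i + 1L)
        as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = "")) else 1L
      if (len < 1L)
        stop("parse error at position ", i, " of '", text,
             "': spacer length must be >= 1")
      addSpacer(len)
      i <- j
    } else if (ch == "(") {
      j <- i + 1L
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n)
        stop("parse error at position ", i, " of '", text,
             "': unclosed '('")
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      res <- strsplit(inner, "/", fixed = TRUE)[[1L]]
      if (length(res) < 1L || !all(res %in% AA_STANDARD20))
        stop("parse error at position ", i, " of '", text,
             "': alternatives must be standard residues separated by '/'")
      elements[[length(elements) + 1L]] <-
        list(type = "class", residues = res)
      i <- j + 1L
    } else if (ch %in% AA_STANDARD20) {
      elements[[length(elements) + 1L]] <-
        list(type = "class", residues = ch)
      i <- i + 1L
    } else {
      stop("parse error at position ", i, " of '", text,
           "': unexpected character '", ch, "'")
    }
  }
  if (length(elements) == 0L)
    stop("pattern '", text, "' contains no elements")
  width <- sum(vapply(elements, function(el)
    if (el$type == "class") 1L else as.integer(el$length), integer(1)))
  new("ConsensusPattern",
      name = if (is.null(name)) clean else name,
      elements = elements, minMatchLength = width)
}

#' Render a consensus pattern back to its text notation
#'
#' Inverse of [parseConsensus()]: \code{parseConsensus(renderConsensus(p))}
#' reproduces \code{p} (up to the label).
#'
#' @param pattern a [ConsensusPattern-class].
#' @return the pattern in text notation.
#' @export
renderConsensus <- function(pattern) {
  paste(vapply(pattern@elements, function(el) {
    if (el$type == "class") {
      if (length(el$residues) == 1L) el$residues
      else paste0("(", paste(el$residues, collapse = "/"), ")")
    } else {
      if (el$length == 1L) "x" else paste0("x", el$length)
    }
  }, character(1)), collapse = "")
}

.patternRegex <- function(pattern) {
  paste(vapply(pattern@elements, function(el) {
    if (el$type == "class") {
      if (length(el$residues) == 1L) el$residues
      else paste0("[", paste(el$residues, collapse = ""), "]")
    } else {
      paste0(".{", el$length, "}")
    }
  }, character(1)), collapse = "")
}

.emptyMatches <- function() {
  data.frame(pattern = character(), start = integer(), end = integer(),
             match = character(), stringsAsFactors = FALSE)
}

#' Scan a sequence for all matches of a consensus pattern
#'
#' Reports every start position at which the pattern matches, overlapping
#' matches included, in left-to-right order.  Spacer positions match any
#' residue; residue-class positions match only the listed residues.
#'
#' @param sequence a protein sequence (character or AAString).
#' @param pattern a [ConsensusPattern-class] or pattern text understood by
#'   [parseConsensus()].
#' @return data.frame of matches with columns \code{pattern}, \code{start},
#'   \code{end} (1-based inclusive), \code{match}; zero rows when the
#'   pattern does not occur.
#' @examples
#' pats <- bboxPatterns()
#' sim <- generateBBoxSequence("miP1-type", totalLength = 121, seed = 3)
#' scanConsensus(sim$sequence, pats[["miP1-type"]])$start == sim$offset
#' @export
scanConsensus <- function(sequence, pattern) {
  if (is.character(pattern)) pattern <- parseConsensus(pattern)
  s <- .asAAString(sequence)
  if (!nzchar(s) || nchar(s) < pattern@minMatchLength)
    return(.emptyMatches())
  rx <- paste0("(?=", .patternRegex(pattern), ")")
  m <- gregexpr(rx, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(.emptyMatches())
  starts <- as.integer(m)
  ends <- starts + pattern@minMatchLength - 1L
  keep <- ends <= nchar(s)    # zero-width lookahead can sit past a full match
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L) return(.emptyMatches())
  data.frame(pattern = pattern@name, start = starts, end = ends,
             match = substring(s, starts, ends), stringsAsFactors = FALSE)
}

#' Built-in zinc-finger B-Box consensus patterns
#'
#' Two structural variants of the B-Box zinc finger are distinguished by the
#' spacing between the second and third cysteine: the CONSTANS/COL-type
#' (\code{Cx2Cx8Cx7Cx2Cx4Hx8H}, 38-residue match) and the miP1-type, one
#' residue shorter (\code{Cx2Cx7Cx7Cx2Cx4Hx8H}, 37-residue match).
#'
#' @return named list of two [ConsensusPattern-class] objects,
#'   \code{"CO-type"} and \code{"miP1-type"}.
#' @export
bboxPatterns <- function() {
  list("CO-type" = parseConsensus("Cx2Cx8Cx7Cx2Cx4Hx8H", name = "CO-type"),
       "miP1-type" = parseConsensus("Cx2Cx7Cx7Cx2Cx4Hx8H",
                                    name = "miP1-type"))
}

#' Classify B-Box matches in a sequence
#'
#' Scans a sequence with both built-in B-Box consensus variants (see
#' [bboxPatterns()]).  Because the two patterns differ by exactly one spacer
#' residue, a span conforming to one variant cannot match the other at the
#' same offset.
#'
#' @param sequence protein sequence.
#' @return data.frame of matches of both patterns (columns as in
#'   [scanConsensus()]), CO-type first.
#' @export
classifyBBox <- function(sequence) {
  pats <- bboxPatterns()
  s <- .asAAString(sequence)
  if (!nzchar(s)) return(.emptyMatches())
  rbind(scanConsensus(s, pats[["CO-type"]]),
        scanConsensus(s, pats[["miP1-type"]]))
}

#' Built-in C-terminal TOPLESS-recruitment motifs
#'
#' @return named list with the terminal five-residue \code{"PFVL-type"}
#'   motif \code{PF(V/L)FL} and the \code{"EAR-type"} repression motif
#'   \code{LxLxL}.
#' @export
ctermMotifs <- function() {
  list("PFVL-type" = parseConsensus("PF(V/L)FL", name = "PFVL-type"),
       "EAR-type" = parseConsensus("LxLxL", name = "EAR-type"))
}

#' Scan for a C-terminal TOPLESS-recruitment motif
#'
#' The \code{"PFVL-type"} motif is defined as the last five amino acids of a
#' protein, so it is anchored: it either matches exactly the final five
#' residues or not at all.  The \code{"EAR-type"} (\code{LxLxL}) motif is
#' only known to be carboxy-terminal, so it is searched within the final
#' \code{window} residues and the rightmost match is reported.
#'
#' @param sequence protein sequence, at least as long as the motif.
#' @param motif \code{"PFVL-type"} or \code{"EAR-type"}.
#' @param window size of the C-terminal search window for the EAR-type
#'   motif (default 25 residues).
#' @return one-row match data.frame (columns as in [scanConsensus()],
#'   coordinates on the full sequence), or a zero-row frame when the motif
#'   is absent.
#' @examples
#' scanCTermMotif("MKAAEILRPFVFL", "PFVL-type")   # spans residues 9-13
#' @export
scanCTermMotif <- function(sequence, motif = c("PFVL-type", "EAR-type"),
                           window = 25L) {
  motif <- match.arg(motif)
  pat <- ctermMotifs()[[motif]]
  s <- .asAAString(sequence)
  n <- nchar(s)
  if (n < pat@minMatchLength)
    stop("sequence (", n, " aa) is shorter than the ", motif, " motif (",
         pat@minMatchLength, " aa)")
  if (motif == "PFVL-type") {
    tail5 <- substring(s, n - pat@minMatchLength + 1L, n)
    m <- scanConsensus(tail5, pat)
    if (nrow(m) == 0L) return(.emptyMatches())
    m$start <- m$start + n - pat@minMatchLength
    m$end <- m$end + n - pat@minMatchLength
    return(m)
  }
  from <- max(1L, n - as.integer(window) + 1L)
  m <- scanConsensus(substring(s, from, n), pat)
  if (nrow(m) == 0L) return(.emptyMatches())
  m <- m[nrow(m), , drop = FALSE]          # rightmost match wins
  m$start <- m$start + from - 1L
  m$end <- m$end + from - 1L
  rownames(m) <- NULL
  m
}

#' Knock out a B-Box by mutating its cysteines and histidines to alanine
#'
#' Builds the zinc-finger-dead protein variant: every C and H inside the
#' matched span is replaced by A; everything outside the span is untouched
#' and the length is preserved.  Applying the knockout twice changes
#' nothing, and the variant no longer matches any C/H-based consensus at
#' that offset.
#'
#' @param sequence protein sequence.
#' @param match a one-row match data.frame (from [scanConsensus()]) or any
#'   list with \code{start} and \code{end}.
#' @return the variant sequence, with the number of substituted residues in
#'   attribute \code{"substitutions"}.
#' @export
makeBBoxDead <- function(sequence, match) {
  s <- .asAAString(sequence)
  start <- as.integer(match$start[1L]); end <- as.integer(match$end[1L])
  if (is.na(start) || is.na(end) || start < 1L || end > nchar(s) ||
      start > end)
    stop("match span ", start, "-", end, " lies outside the sequence (",
         nchar(s), " aa)")
  span <- substring(s, start, end)
  nsub <- sum(strsplit(span, "")[[1L]] %in% c("C", "H"))
  dead <- chartr("CH", "AA", span)
  out <- paste0(substring(s, 1L, start - 1L), dead,
                substring(s, end + 1L, nchar(s)))
  attr(out, "substitutions") <- nsub
  out
}

#' Remove the C-terminal tail of a protein
#'
#' Builds the tail-deletion variant (e.g. removal of the five terminal
#' residues that form the PF(V/L)FL motif).
#'
#' @param sequence protein sequence, strictly longer than \code{n}.
#' @param n number of terminal residues to remove (default 5).
#' @return the truncated sequence (length reduced by exactly \code{n}).
#' @export
truncateCTerm <- function(sequence, n = 5L) {
  s <- .asAAString(sequence)
  n <- as.integer(n)
  if (nchar(s) <= n)
    stop("cannot remove ", n, " residues from a ", nchar(s),
         "-residue sequence")
  substring(s, 1L, nchar(s) - n)
}
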