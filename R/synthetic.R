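drawSeed <- function(seed, code) {
  # scope all randomness to a single integer seed without touching the
  # caller's RNG stream
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.randResidues <- function(n, exclude = character()) {
  pool <- setdiff(AA_STANDARD20, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

.logUnifEvalue <- function(n) 10^runif(n, min = -30, max = -6)

#' Generate a synthetic proteome with planted candidates and decoys
#'
#' Builds a fully seeded test universe for the microProtein screen: for
#' each family, small single-domain candidate proteins (60-139 residues,
#' carrying one protein-interaction domain) plus one strictly longer
#' multi-domain target sharing the family domain; a configurable number of
#' decoys, each violating exactly one screen criterion while satisfying the
#' others (\code{size}: >= 140 residues; \code{multidomain}: two distinct
#' domains; \code{nonppi}: its single domain is off the whitelist, with its
#' own larger multi-domain relative so only the whitelist test fails;
#' \code{norelative}: a unique whitelisted domain nobody else carries); and
#' undomained background proteins.  Identical seed and configuration give
#' byte-identical output.
#'
#' @param nFamilies number of candidate families (>= 1 when candidates are
#'   requested).
#' @param candidatesPerFamily candidates planted per family.
#' @param decoyCounts named integer vector with entries \code{size},
#'   \code{multidomain}, \code{nonppi}, \code{norelative}.
#' @param nBackground number of undomained background proteins.
#' @param seed integer seed controlling all randomness.
#' @return list with \code{proteome} (AAStringSet), \code{hits} (domain-hit
#'   data.frame as from [readDomainHits()]), \code{truth} (per-protein
#'   truth table: \code{protein_id}, \code{role}, \code{family},
#'   \code{length}, \code{planted_target}) and \code{ppiDomains} (the
#'   whitelist the bundle is meant to be screened with).
#' @examples
#' sim <- generateProteome(nFamilies = 2, candidatesPerFamily = 2, seed = 7)
#' table(sim$truth$role)
#' @importFrom Biostrings AAStringSet
#' @importFrom S4Vectors mcols<-
#' @export
generateProteome <- function(nFamilies = 3,
                             candidatesPerFamily = 2,
                             decoyCounts = c(size = 2, multidomain = 2,
                                             nonppi = 2, norelative = 2),
                             nBackground = 5,
                             seed) {
  if (missing(seed)) stop("a seed is required")
  if (nFamilies < 0 || candidatesPerFamily < 0 || nBackground < 0 ||
      any(decoyCounts < 0))
    stop("counts must be non-negative")
  if (nFamilies == 0 && candidatesPerFamily > 0)
    stop("candidates requested but nFamilies is 0")
  for (nm in c("size", "multidomain", "nonppi", "norelative"))
    if (!nm %in% names(decoyCounts)) decoyCounts[nm] <- 0L

  drawSeed(seed, {
    famAcc <- sprintf("PF9%04d", seq_len(max(nFamilies, 1)))[seq_len(nFamilies)]
    famName <- sprintf("synPPI_%d", seq_len(nFamilies))
    extraAcc <- sprintf("PF7%04d", 1:6)       # non-PPI filler domains
    nonPpiAcc <- "PF80001"                    # off-whitelist PPI-like domain
    uniqueAcc <- sprintf("PF95%03d", seq_len(max(decoyCounts["norelative"], 1)))
    ppi <- c(famAcc, uniqueAcc[seq_len(decoyCounts["norelative"])])

    seqs <- character(); ids <- character()
    hits <- list(); truth <- list()
    addHit <- function(pid, acc, nm, s, e) {
      hits[[length(hits) + 1L]] <<- data.frame(
        protein_id = pid, domain_accession = acc, domain_name = nm,
        start = s, end = e, evalue = .logUnifEvalue(1),
        stringsAsFactors = FALSE)
    }
    addProt <- function(pid, len, role, family = NA_character_,
                        target = NA_character_) {
      ids <<- c(ids, pid)
      seqs <<- c(seqs, .randResidues(len))
      truth[[length(truth) + 1L]] <<- data.frame(
        protein_id = pid, role = role, family = family, length = len,
        planted_target = target, stringsAsFactors = FALSE)
    }
    domSpan <- function(len, width = sample(30:50, 1)) {
      width <- min(width, len - 2L)
      s <- sample.int(len - width, 1)
      c(s, s + width - 1L)
    }

    # family targets first (every candidate needs one)
    tgtIds <- character(nFamilies)
    for (f in seq_len(nFamilies)) {
      pid <- sprintf("TGT_F%02d", f)
      tgtIds[f] <- pid
      len <- sample(200:400, 1)
      addProt(pid, len, "target", famAcc[f])
      # anchored layout: family domain first, then 1-2 distinct extra
      # domains, which always fit because len >= 200
      s1 <- sample(1:20, 1); w1 <- sample(30:45, 1)
      addHit(pid, famAcc[f], famName[f], s1, s1 + w1 - 1L)
      nExtra <- sample(1:2, 1)
      at <- s1 + w1 + 10L
      for (x in sample(extraAcc, nExtra)) {
        w <- sample(20:30, 1)
        stopifnot(at + w - 1L <= len)
        addHit(pid, x, "syn_extra", at, at + w - 1L)
        at <- at + w + 10L
      }
    }
    for (f in seq_len(nFamilies)) {
      for (k in seq_len(candidatesPerFamily)) {
        pid <- sprintf("CAND_F%02d_%02d", f, k)
        len <- sample(60:139, 1)
        addProt(pid, len, "candidate", famAcc[f], tgtIds[f])
        sp <- domSpan(len, sample(30:40, 1))
        addHit(pid, famAcc[f], famName[f], sp[1], sp[2])
      }
    }
    # decoys: each violates exactly one criterion
    for (d in seq_len(decoyCounts["size"])) {
      f <- sample.int(nFamilies, 1)
      pid <- sprintf("DECOY_SIZE_%02d", d)
      len <- sample(140:190, 1)    # too large, yet below every family target
      addProt(pid, len, "decoy_size", famAcc[f])
      sp <- domSpan(len, sample(30:40, 1))
      addHit(pid, famAcc[f], famName[f], sp[1], sp[2])
    }
    for (d in seq_len(decoyCounts["multidomain"])) {
      f <- sample.int(nFamilies, 1)
      pid <- sprintf("DECOY_MULTI_%02d", d)
      len <- sample(100:139, 1)
      addProt(pid, len, "decoy_multidomain", famAcc[f])
      addHit(pid, famAcc[f], famName[f], 5L, 40L)     # two distinct domains
      addHit(pid, sample(extraAcc, 1), "syn_extra", 55L, min(90L, len - 1L))
    }
    for (d in seq_len(decoyCounts["nonppi"])) {
      pid <- sprintf("DECOY_NONPPI_%02d", d)
      len <- sample(60:139, 1)
      addProt(pid, len, "decoy_nonppi")
      sp <- domSpan(len, sample(30:40, 1))
      addHit(pid, nonPpiAcc, "syn_offlist", sp[1], sp[2])
    }
    if (decoyCounts["nonppi"] > 0) {
      # larger multi-domain relative so the off-whitelist decoys fail only
      # the whitelist test, not the relative test
      pid <- "NONPPI_REL_01"
      len <- sample(250:400, 1)
      addProt(pid, len, "background")
      addHit(pid, nonPpiAcc, "syn_offlist", 10L, 45L)
      addHit(pid, sample(extraAcc, 1), "syn_extra", 60L, 100L)
    }
    for (d in seq_len(decoyCounts["norelative"])) {
      pid <- sprintf("DECOY_NOREL_%02d", d)
      len <- sample(60:139, 1)
      addProt(pid, len, "decoy_norelative", uniqueAcc[d])
      sp <- domSpan(len, sample(30:40, 1))
      addHit(pid, uniqueAcc[d], sprintf("syn_unique_%d", d), sp[1], sp[2])
    }
    for (b in seq_len(nBackground)) {
      addProt(sprintf("BG_%03d", b), sample(80:500, 1), "background")
    }

    proteome <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
    S4Vectors::mcols(proteome)$description <-
      rep("synthetic protein", length(proteome))
    hits <- do.call(rbind, hits)
    truth <- do.call(rbind, truth)
    rownames(hits) <- rownames(truth) <- NULL
    list(proteome = proteome, hits = hits, truth = truth, ppiDomains = ppi)
  })
}

#' Write a synthetic proteome bundle to disk
#'
#' @param sim result of [generateProteome()].
#' @param dir output directory (created if needed); writes
#'   \code{proteome.fa}, \code{domains.tsv}, \code{truth.tsv} and
#'   \code{ppi_domains.txt}.
#' @return invisibly, the directory.
#' @importFrom utils write.table
#' @export
writeSimBundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeProteome(sim$proteome, file.path(dir, "proteome.fa"))
  utils::write.table(sim$hits, file.path(dir, "domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$ppiDomains, file.path(dir, "ppi_domains.txt"))
  invisible(dir)
}

#' Generate a sequence with a planted B-Box consensus span
#'
#' Plants a span conforming to the requested B-Box consensus variant at a
#' random offset of an otherwise cysteine/histidine-free random background,
#' so the planted span is the unique match of that pattern; optionally ends
#' the sequence with the five-residue \code{PFVFL} tail.
#'
#' @param kind \code{"miP1-type"} (37-residue span) or \code{"CO-type"}
#'   (38-residue span).
#' @param withPfvflTail append the terminal \code{PFVFL} motif.
#' @param totalLength total sequence length; must accommodate the span
#'   (plus 5 when the tail is requested).
#' @param seed integer seed.
#' @return list with \code{sequence}, \code{offset} (planted span start)
#'   and \code{kind}.
#' @export
generateBBoxSequence <- function(kind = c("miP1-type", "CO-type"),
                                 withPfvflTail = FALSE,
                                 totalLength, seed) {
  kind <- match.arg(kind)
  pat <- bboxPatterns()[[kind]]
  tailLen <- if (withPfvflTail) 5L else 0L
  need <- pat@minMatchLength + tailLen
  if (totalLength < need)
    stop("totalLength must be >= ", need, " for ", kind,
         if (withPfvflTail) " with tail")
  drawSeed(seed, {
    core <- totalLength - tailLen
    offset <- sample.int(core - pat@minMatchLength + 1L, 1)
    bg <- strsplit(.randResidues(core, exclude = c("C", "H")), "")[[1L]]
    pos <- offset
    for (el in pat@elements) {
      if (el$type == "class") {
        bg[pos] <- if (length(el$residues) == 1L) el$residues
                   else sample(el$residues, 1)
        pos <- pos + 1L
      } else {
        pos <- pos + as.integer(el$length)    # spacers stay C/H-free
      }
    }
    seqn <- paste0(paste(bg, collapse = ""),
                   if (withPfvflTail) "PFVFL" else "")
    list(sequence = seqn, offset = offset, kind = kind)
  })
}

#' Generate gene-identifier sets with an exact planted overlap
#'
#' @param N universe size.
#' @param nA,nB set sizes.
#' @param k exact intersection size; requires \code{k <= min(nA, nB)} and
#'   \code{nA + nB - k <= N}.
#' @param seed integer seed.
#' @param labelA,labelB labels carried through for reporting.
#' @return list with \code{universe}, \code{setA}, \code{setB} (character
#'   vectors of synthetic gene ids) and the labels.
#' @export
generateGeneSets <- function(N, nA, nB, k, seed,
                             labelA = "A", labelB = "B") {
  if (k > min(nA, nB) || nA > N || nB > N || nA + nB - k > N)
    stop("infeasible gene-set parameters")
  drawSeed(seed, {
    universe <- sprintf("G%05d", seq_len(N))
    shared <- sample(universe, k)
    rest <- setdiff(universe, shared)
    aOnly <- sample(rest, nA - k)
    bOnly <- sample(setdiff(rest, aOnly), nB - k)
    list(universe = universe,
         setA = sort(c(shared, aOnly)),
         setB = sort(c(shared, bOnly)),
         labelA = labelA, labelB = labelB)
  })
}

#' Synthetic miP1a/miP1b exemplar pair
#'
#' Builds a pair of synthetic stand-in sequences for the two
#' \emph{Arabidopsis} miP1-type microProteins, reproducing their described
#' structural relationship rather than their (not bundled) real sequences:
#' the first protein is 121 residues with a miP1-type B-Box
#' (\code{Cx2Cx7Cx7Cx2Cx4Hx8H}) near the amino terminus, a degenerate
#' remnant of a second B-Box, and the terminal \code{PFVFL} motif; the
#' second is derived from it by deleting four residues downstream of the
#' second B-Box remnant (117 residues) and substituting residues outside
#' the conserved B-Box and tail until the pair diverges to the described
#' ~65.5 percent identity.  Both sequences are labelled synthetic.
#'
#' @param seed integer seed.
#' @param identityPctTarget planted pairwise identity on the
#'   alignment-length convention (default 65.5, the described divergence of
#'   the real pair).
#' @return an [Biostrings::AAStringSet] with elements
#'   \code{miP1a_synthetic} (121 aa) and \code{miP1b_synthetic} (117 aa).
#' @importFrom Biostrings AAStringSet
#' @importFrom S4Vectors mcols<-
#' @export
generateMiP1Exemplars <- function(seed = 1021, identityPctTarget = 65.5) {
  drawSeed(seed, {
    lenA <- 121L
    pat <- bboxPatterns()[["miP1-type"]]
    bboxStart <- 8L
    bboxEnd <- bboxStart + pat@minMatchLength - 1L     # 8..44
    a <- strsplit(.randResidues(lenA - 5L, exclude = c("C", "H")),
                  "")[[1L]]
    pos <- bboxStart
    for (el in pat@elements) {
      if (el$type == "class") {
        a[pos] <- if (length(el$residues) == 1L) el$residues
                  else sample(el$residues, 1)
        pos <- pos + 1L
      } else pos <- pos + as.integer(el$length)
    }
    # degenerate second B-Box remnant: conserved C/C/C/H skeleton only
    remStart <- bboxEnd + 6L                            # 50..
    remPos <- remStart + c(0L, 3L, 11L, 16L)
    a[remPos] <- c("C", "C", "C", "H")
    remEnd <- remStart + 20L
    seqA <- paste0(paste(a, collapse = ""), "PFVFL")

    # miP1b: drop 4 residues after the second B-Box remnant, then diverge
    b <- a
    delAt <- remEnd + 5L
    b <- b[-(delAt:(delAt + 3L))]
    lenB <- length(b) + 5L                              # 117 with tail
    conserved <- sort(c(bboxStart:bboxEnd, remPos))
    mutable <- setdiff(seq_along(b), conserved)
    # on a clean alignment (121 columns, 4 gaps) identity is
    # (117 - substitutions) / 121, so solve for the substitution count
    nIdentTarget <- round(identityPctTarget / 100 * lenA)
    nSub <- lenB - nIdentTarget
    nSub <- min(nSub, length(mutable))
    at <- sample(mutable, nSub)
    for (i in at) {
      b[i] <- sample(setdiff(AA_STANDARD20, c("C", "H", b[i])), 1)
    }
    seqB <- paste0(paste(b, collapse = ""), "PFVFL")

    out <- Biostrings::AAStringSet(c(miP1a_synthetic = seqA,
                                     miP1b_synthetic = seqB))
    S4Vectors::mcols(out)$description <- c(
      "synthetic stand-in, miP1a-like structure (121 aa)",
      "synthetic stand-in, miP1b-like structure (117 aa)")
    out
  })
}
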