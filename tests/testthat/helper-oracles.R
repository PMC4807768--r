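# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the scanner oracle walks positions one by one,
# the alignment oracle enumerates move sequences, the architecture oracle
# enumerates subsets, and the hypergeometric oracles use exact integer
# binomials (exact in doubles for N <= 30) and full draw enumeration.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

randomProtein <- function(n, exclude = character()) {
  paste(sample(setdiff(AA20, exclude), n, replace = TRUE), collapse = "")
}

# position-by-position consensus matcher
naiveScanOracle <- function(sequence, pattern) {
  s <- strsplit(toupper(sequence), "")[[1L]]
  w <- minMatchLength(pattern)
  starts <- integer(0)
  if (length(s) >= w) {
    for (st in seq_len(length(s) - w + 1L)) {
      pos <- st
      ok <- TRUE
      for (el in pattern@elements) {
        if (el$type == "class") {
          if (!s[pos] %in% el$residues) { ok <- FALSE; break }
          pos <- pos + 1L
        } else pos <- pos + as.integer(el$length)
      }
      if (ok) starts <- c(starts, st)
    }
  }
  starts
}

# exhaustive global-alignment score: recursion over move sequences with the
# affine cost "gap of length L costs open + extend * L"
bruteForceAlignScore <- function(a, b, S, gapOpen = 10, gapExtend = 0.5) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j, last) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      best <- max(best, rec(i - 1L, j - 1L, "m") + S[av[i], bv[j]])
    }
    if (i > 0L) {
      cost <- if (last == "x") gapExtend else gapOpen + gapExtend
      best <- max(best, rec(i - 1L, j, "x") - cost)
    }
    if (j > 0L) {
      cost <- if (last == "y") gapExtend else gapOpen + gapExtend
      best <- max(best, rec(i, j - 1L, "y") - cost)
    }
    best
  }
  rec(length(av), length(bv), "m")
}

# score a concrete pair of aligned (gapped) strings under the same scheme
scoreAlignmentStrings <- function(alignedA, alignedB, S,
                                  gapOpen = 10, gapExtend = 0.5) {
  ca <- strsplit(alignedA, "")[[1L]]; cb <- strsplit(alignedB, "")[[1L]]
  stopifnot(length(ca) == length(cb))
  score <- 0; inX <- FALSE; inY <- FALSE
  for (t in seq_along(ca)) {
    if (ca[t] != "-" && cb[t] != "-") {
      score <- score + S[ca[t], cb[t]]; inX <- inY <- FALSE
    } else if (cb[t] == "-") {
      score <- score - gapExtend - if (inX) 0 else gapOpen
      inX <- TRUE; inY <- FALSE
    } else {
      score <- score - gapExtend - if (inY) 0 else gapOpen
      inY <- TRUE; inX <- FALSE
    }
  }
  score
}

# rank-lexicographically best pairwise-compatible subset of domain hits:
# the exhaustive counterpart of best-score-first greedy retention
bestSubsetOracle <- function(hits, frac = 0.5) {
  ord <- order(hits$evalue, hits$start, hits$domain_accession)
  ranked <- hits[ord, , drop = FALSE]
  n <- nrow(ranked)
  compat <- function(idx) {
    if (length(idx) < 2L) return(TRUE)
    for (p in seq_len(length(idx) - 1L)) for (q in (p + 1L):length(idx)) {
      i <- idx[p]; j <- idx[q]
      shared <- min(ranked$end[i], ranked$end[j]) -
        max(ranked$start[i], ranked$start[j]) + 1L
      if (shared > 0L) {
        shorter <- min(ranked$end[i] - ranked$start[i] + 1L,
                       ranked$end[j] - ranked$start[j] + 1L)
        if (shared > frac * shorter) return(FALSE)
      }
    }
    TRUE
  }
  best <- integer(0); bestKey <- rep(0L, n)
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!compat(idx)) next
    key <- as.integer(seq_len(n) %in% idx)
    # descending lexicographic comparison of membership over ranks
    cmp <- key - bestKey
    nz <- which(cmp != 0L)
    if (length(nz) && cmp[nz[1L]] > 0L) { best <- idx; bestKey <- key }
  }
  sorted <- ranked[best, , drop = FALSE]
  sorted <- sorted[order(sorted$start, sorted$end, sorted$domain_accession),
                   , drop = FALSE]
  rownames(sorted) <- NULL
  sorted
}

# exact hypergeometric upper tail from integer binomials (exact for N <= 30)
exactHyperSF <- function(k, N, nA, nB) {
  if (k == 0L) return(1)
  i <- k:min(nA, nB)
  sum(choose(nA, i) * choose(N - nA, nB - i)) / choose(N, nB)
}

# full enumeration of all C(N, nB) draws (small N only)
enumHyperSF <- function(k, N, nA, nB) {
  draws <- utils::combn(N, nB)
  hit <- colSums(draws <= nA) >= k
  mean(hit)
}

randomDomainHits <- function(n, proteinLen = 200L) {
  starts <- sample.int(proteinLen - 30L, n, replace = TRUE)
  widths <- sample(10:60, n, replace = TRUE)
  data.frame(protein_id = "P",
             domain_accession = sample(sprintf("PF%05d", 1:4), n,
                                       replace = TRUE),
             domain_name = "dom",
             start = starts,
             end = pmin(starts + widths - 1L, proteinLen),
             evalue = 10^runif(n, -20, -2),
             stringsAsFactors = FALSE)
}

# hmmscan --domtblout dialect writer for fixtures
writeDomtblout <- function(hits, path, versioned = TRUE) {
  lines <- "# hmmscan per-domain output (synthetic fixture)"
  body <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    acc <- if (versioned) paste0(h$domain_accession, ".12") else
      h$domain_accession
    paste(h$domain_name, acc, 120, h$protein_id, "-", 500,
          h$evalue, 80.1, 0.1, 1, 1, h$evalue, h$evalue, 79.9, 0.1,
          2, 119, h$start, h$end, h$start, h$end, 0.98,
          "synthetic fixture", sep = " ")
  }, character(1))
  writeLines(c(lines, body, "#"), path)
}
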