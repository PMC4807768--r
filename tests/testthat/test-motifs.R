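test_that("consensus grammar computes match widths and round-trips", {
  expect_equal(minMatchLength(parseConsensus("Cx2Cx7Cx7Cx2Cx4Hx8H")), 37L)
  expect_equal(minMatchLength(parseConsensus("Cx2Cx8Cx7Cx2Cx4Hx8H")), 38L)
  expect_equal(minMatchLength(parseConsensus("PF(V/L)FL")), 5L)
  # underscore notation is accepted unchanged
  expect_equal(minMatchLength(parseConsensus("Cx_2_Cx_7_Cx_7_Cx_2_Cx_4_Hx_8_H")),
               37L)

  lx <- parseConsensus("LxLxL")
  expect_equal(minMatchLength(lx), 5L)
  expect_identical(vapply(lx@elements, `[[`, character(1), "type"),
                   c("class", "spacer", "class", "spacer", "class"))

  for (txt in c("Cx2Cx7Cx7Cx2Cx4Hx8H", "PF(V/L)FL", "LxLxL", "Cx12H")) {
    p <- parseConsensus(txt)
    p2 <- parseConsensus(renderConsensus(p))
    expect_identical(p2@elements, p@elements)
    expect_identical(minMatchLength(p2), minMatchLength(p))
  }
})

test_that("malformed patterns fail with a position", {
  expect_error(parseConsensus("C!C"), "position 2")
  expect_error(parseConsensus("PF(V/L"), "unclosed")
  expect_error(parseConsensus("PF(V/9)FL"), "alternatives")
  expect_error(parseConsensus(""), "non-empty")
})

test_that("scanner agrees with the naive position-by-position matcher", {
  set.seed(301)
  pats <- c(bboxPatterns(), ctermMotifs())
  for (rep in 1:30) {
    s <- randomProtein(200L)
    for (p in pats) {
      expect_identical(scanConsensus(s, p)$start, naiveScanOracle(s, p))
    }
  }
  # enriched in C/H so the B-Box patterns actually fire sometimes
  for (rep in 1:20) {
    s <- paste(sample(c("C", "H", "A", "L"), 200, replace = TRUE,
                      prob = c(.3, .2, .25, .25)), collapse = "")
    for (p in bboxPatterns()) {
      expect_identical(scanConsensus(s, p)$start, naiveScanOracle(s, p))
    }
  }
})

test_that("overlapping matches are all reported in order", {
  m <- scanConsensus("LLLLLLL", "LxLxL")
  expect_identical(m$start, 1:3)
  expect_true(all(m$end - m$start + 1L == 5L))
})

test_that("every reported match re-validates against its pattern", {
  set.seed(17)
  for (rep in 1:10) {
    s <- paste(sample(c("C", "H", "A", "L", "P", "F", "V"), 150,
                      replace = TRUE), collapse = "")
    for (p in c(bboxPatterns(), ctermMotifs())) {
      m <- scanConsensus(s, p)
      for (i in seq_len(nrow(m))) {
        span <- strsplit(m$match[i], "")[[1L]]
        pos <- 1L
        for (el in p@elements) {
          if (el$type == "class") {
            expect_true(span[pos] %in% el$residues)
            pos <- pos + 1L
          } else pos <- pos + as.integer(el$length)
        }
      }
    }
  }
})

test_that("B-Box classification separates the two structural variants", {
  pats <- bboxPatterns()
  expect_equal(minMatchLength(pats[["CO-type"]]) -
                 minMatchLength(pats[["miP1-type"]]), 1L)

  co <- generateBBoxSequence("CO-type", totalLength = 150, seed = 5)
  rep <- classifyBBox(co$sequence)
  expect_true(any(rep$pattern == "CO-type" & rep$start == co$offset))
  expect_false(any(rep$pattern == "miP1-type" & rep$start == co$offset))

  mi <- generateBBoxSequence("miP1-type", totalLength = 150, seed = 5)
  rep2 <- classifyBBox(mi$sequence)
  expect_true(any(rep2$pattern == "miP1-type" & rep2$start == mi$offset))

  expect_equal(nrow(classifyBBox(paste(rep("A", 100), collapse = ""))), 0L)
  expect_equal(nrow(classifyBBox("")), 0L)
})

test_that("the terminal five-residue motif is anchored to the C terminus", {
  expect_equal(scanCTermMotif("MKAAEILRPFVFL", "PFVL-type")$start, 9L)
  expect_equal(scanCTermMotif("MKAAEILRPFLFL", "PFVL-type")$start, 9L)
  # motif present internally but not terminal: no match
  expect_equal(nrow(scanCTermMotif("MKPFVFLAAEILR", "PFVL-type")), 0L)
  expect_error(scanCTermMotif("PFV", "PFVL-type"), "shorter")
})

test_that("the EAR-type motif is searched in a C-terminal window,
           rightmost match first", {
  s <- paste0(randomProtein(60, exclude = "L"), "LSLLL",
              randomProtein(10, exclude = "L"))
  m <- scanCTermMotif(s, "EAR-type", window = 25)
  expect_equal(m$start, 61L)
  expect_identical(m$match, "LSLLL")
  # two matches in the window: the rightmost wins
  s2 <- paste0(randomProtein(50, exclude = "L"), "LALALXXLSLLL")
  m2 <- scanCTermMotif(s2, "EAR-type", window = 25)
  expect_equal(m2$start, 58L)
  # outside the window the motif is not reported
  s3 <- paste0("LSLLL", randomProtein(40, exclude = "L"))
  expect_equal(nrow(scanCTermMotif(s3, "EAR-type", window = 25)), 0L)
})

test_that("the B-Box knockout mutates exactly the C/H residues of the span", {
  sim <- generateBBoxSequence("miP1-type", totalLength = 121, seed = 9)
  m <- scanConsensus(sim$sequence, bboxPatterns()[["miP1-type"]])
  dead <- makeBBoxDead(sim$sequence, m)
  # generator keeps spacers C/H-free: only the 5 C + 2 H class positions go
  expect_equal(attr(dead, "substitutions"), 7L)
  expect_equal(nchar(dead), nchar(sim$sequence))
  expect_equal(nrow(scanConsensus(dead, bboxPatterns()[["miP1-type"]])), 0L)
  # untouched outside the span
  expect_identical(as.character(substring(dead, 1, m$start - 1)),
                   substring(sim$sequence, 1, m$start - 1))

  # an extra spacer cysteine is also destroyed ('all C and H' rule)
  s <- sim$sequence
  spacerPos <- m$start + 1L        # first spacer position of the span
  substr(s, spacerPos, spacerPos) <- "C"
  dead2 <- makeBBoxDead(s, m)
  expect_equal(attr(dead2, "substitutions"), 8L)

  # idempotent
  expect_identical(as.character(makeBBoxDead(dead, m)), as.character(dead))
  expect_error(makeBBoxDead("MKV", list(start = 1, end = 10)), "outside")
})

test_that("C-terminal truncation removes exactly n residues and is
           inverted by re-appending the tail", {
  s <- paste0(randomProtein(116), "PFVFL")
  tr <- truncateCTerm(s, 5)
  expect_equal(nchar(tr), 116L)
  expect_identical(paste0(tr, "PFVFL"), s)
  expect_equal(nrow(scanCTermMotif(tr, "PFVL-type")), 0L)
  expect_error(truncateCTerm("MKV", 5), "cannot remove")
})
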