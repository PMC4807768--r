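test_that("proteome generation is byte-deterministic per seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimBundle(generateProteome(nFamilies = 2, candidatesPerFamily = 2,
                                  seed = 7), d1)
  writeSimBundle(generateProteome(nFamilies = 2, candidatesPerFamily = 2,
                                  seed = 7), d2)
  for (f in c("proteome.fa", "domains.tsv", "truth.tsv",
              "ppi_domains.txt")) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))))
  }
  other <- generateProteome(nFamilies = 2, candidatesPerFamily = 2,
                            seed = 8)
  expect_false(identical(as.character(other$proteome),
                         as.character(generateProteome(
                           nFamilies = 2, candidatesPerFamily = 2,
                           seed = 7)$proteome)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(55); before <- runif(3)
  set.seed(55); invisible(generateProteome(nFamilies = 1,
                                           candidatesPerFamily = 1,
                                           seed = 99))
  expect_identical(runif(3), before)
})

test_that("each decoy class violates exactly its own criterion", {
  sim <- generateProteome(nFamilies = 3, candidatesPerFamily = 2, seed = 13)
  truth <- sim$truth
  hits <- sim$hits
  lens <- stats::setNames(Biostrings::width(sim$proteome),
                          names(sim$proteome))
  nDistinctOf <- function(pid)
    length(unique(hits$domain_accession[hits$protein_id == pid]))

  for (pid in truth$protein_id[truth$role == "decoy_size"]) {
    expect_gte(lens[[pid]], 140L)             # violated: size
    expect_equal(nDistinctOf(pid), 1L)        # satisfied: single domain
    acc <- unique(hits$domain_accession[hits$protein_id == pid])
    expect_true(acc %in% sim$ppiDomains)      # satisfied: whitelist
  }
  for (pid in truth$protein_id[truth$role == "decoy_multidomain"]) {
    expect_lt(lens[[pid]], 140L)
    expect_equal(nDistinctOf(pid), 2L)        # violated: two domains
  }
  for (pid in truth$protein_id[truth$role == "decoy_nonppi"]) {
    expect_lt(lens[[pid]], 140L)
    expect_equal(nDistinctOf(pid), 1L)
    acc <- unique(hits$domain_accession[hits$protein_id == pid])
    expect_false(acc %in% sim$ppiDomains)     # violated: off the whitelist
    # but a larger multi-domain relative with that domain exists
    rel <- setdiff(unique(
      hits$protein_id[hits$domain_accession == acc]), pid)
    expect_true(any(lens[rel] > lens[[pid]] &
                      vapply(rel, nDistinctOf, integer(1)) >= 2L))
  }
  for (pid in truth$protein_id[truth$role == "decoy_norelative"]) {
    expect_lt(lens[[pid]], 140L)
    expect_equal(nDistinctOf(pid), 1L)
    acc <- unique(hits$domain_accession[hits$protein_id == pid])
    expect_true(acc %in% sim$ppiDomains)
    # violated: nobody else carries the domain
    expect_length(setdiff(
      unique(hits$protein_id[hits$domain_accession == acc]), pid), 0L)
  }
  # every candidate names exactly one planted target of its own family
  cand <- truth[truth$role == "candidate", ]
  expect_true(all(!is.na(cand$planted_target)))
  tgt <- truth[match(cand$planted_target, truth$protein_id), ]
  expect_true(all(tgt$role == "target"))
  expect_identical(tgt$family, cand$family)
  expect_true(all(cand$length >= 60 & cand$length <= 139))
  expect_true(all(tgt$length > cand$length))
})

test_that("planted B-Box spans are the unique consensus match", {
  for (seed in 1:5) {
    sim <- generateBBoxSequence("miP1-type", withPfvflTail = TRUE,
                                totalLength = 121, seed = seed)
    expect_equal(nchar(sim$sequence), 121L)
    m <- scanConsensus(sim$sequence, bboxPatterns()[["miP1-type"]])
    expect_identical(m$start, sim$offset)
    tail5 <- scanCTermMotif(sim$sequence, "PFVL-type")
    expect_equal(tail5$start, 117L)
  }
  co <- generateBBoxSequence("CO-type", totalLength = 60, seed = 2)
  m <- scanConsensus(co$sequence, bboxPatterns()[["CO-type"]])
  expect_equal(m$end - m$start + 1L, 38L)
  mi <- generateBBoxSequence("miP1-type", totalLength = 60, seed = 2)
  m2 <- scanConsensus(mi$sequence, bboxPatterns()[["miP1-type"]])
  expect_equal(m2$end - m2$start + 1L, 37L)

  expect_error(generateBBoxSequence("miP1-type", totalLength = 30,
                                    seed = 1), ">=")
  expect_identical(generateBBoxSequence("CO-type", totalLength = 80,
                                        seed = 4)$sequence,
                   generateBBoxSequence("CO-type", totalLength = 80,
                                        seed = 4)$sequence)
})

test_that("gene-set generation plants the exact requested overlap", {
  gs <- generateGeneSets(N = 100, nA = 10, nB = 20, k = 8, seed = 1)
  expect_length(gs$setA, 10L)
  expect_length(gs$setB, 20L)
  expect_length(intersect(gs$setA, gs$setB), 8L)
  expect_true(all(c(gs$setA, gs$setB) %in% gs$universe))

  disjoint <- generateGeneSets(50, 5, 6, 0, seed = 3)
  expect_length(intersect(disjoint$setA, disjoint$setB), 0L)

  expect_error(generateGeneSets(10, 8, 8, 2, seed = 1), "infeasible")
  expect_identical(generateGeneSets(100, 10, 20, 8, seed = 9),
                   generateGeneSets(100, 10, 20, 8, seed = 9))
})

test_that("the synthetic miP1 exemplar pair reproduces the described
           structure", {
  ex <- generateMiP1Exemplars()
  expect_identical(names(ex), c("miP1a_synthetic", "miP1b_synthetic"))
  expect_identical(Biostrings::width(ex), c(121L, 117L))
  for (i in 1:2) {
    s <- as.character(ex[[i]])
    m <- scanConsensus(s, bboxPatterns()[["miP1-type"]])
    expect_equal(nrow(m), 1L)                  # one intact miP1-type B-Box
    expect_equal(nrow(scanCTermMotif(s, "PFVL-type")), 1L)
  }
  expect_identical(as.character(generateMiP1Exemplars()),
                   as.character(generateMiP1Exemplars()))
})
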