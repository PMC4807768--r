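# small hand-built proteome: one qualifying candidate plus edge cases
miniProteome <- function(candLen = 121L, targetLen = 300L) {
  set.seed(99)
  seqs <- c(cand = randomProtein(candLen),
            target = randomProtein(targetLen),
            atLimit = randomProtein(140L),
            lonely = randomProtein(100L))
  prot <- Biostrings::AAStringSet(seqs)
  hits <- data.frame(
    protein_id = c("cand", "target", "target", "atLimit", "lonely"),
    domain_accession = c("PF00643", "PF00643", "PF70001",
                         "PF00643", "PF95001"),
    domain_name = c("zf-B_box", "zf-B_box", "extra", "zf-B_box", "unique"),
    start = c(5L, 10L, 80L, 5L, 5L),
    end = c(41L, 46L, 120L, 41L, 41L),
    evalue = rep(1e-10, 5), stringsAsFactors = FALSE)
  list(proteome = prot, hits = hits)
}

test_that("the three screen criteria gate candidacy as specified", {
  mp <- miniProteome()
  arch <- resolveArchitectures(mp$hits, mp$proteome)
  cfg <- screenConfig(ppiDomains = c("PF00643", "PF95001"))
  cand <- screenMicroCandidates(mp$proteome, arch, cfg)
  expect_identical(cand$candidate_id, "cand")
  expect_identical(cand$target_ids, "target")
  # 140-residue protein fails the strict 'below 140' size rule
  expect_false("atLimit" %in% cand$candidate_id)
  # single whitelisted domain but no longer multi-domain relative
  expect_false("lonely" %in% cand$candidate_id)

  # at exactly one residue shorter the size criterion passes
  mp2 <- miniProteome(candLen = 139L)
  arch2 <- resolveArchitectures(mp2$hits, mp2$proteome)
  expect_true("cand" %in%
                screenMicroCandidates(mp2$proteome, arch2, cfg)$candidate_id)
})

test_that("planted candidates are recovered exactly, decoys rejected", {
  for (seed in c(7L, 8L, 9L)) {
    sim <- generateProteome(nFamilies = 3, candidatesPerFamily = 2,
                            seed = seed)
    arch <- resolveArchitectures(sim$hits, sim$proteome)
    cand <- screenMicroCandidates(sim$proteome, arch,
                                  screenConfig(ppiDomains = sim$ppiDomains))
    truthCand <- sim$truth$protein_id[sim$truth$role == "candidate"]
    expect_setequal(cand$candidate_id, truthCand)
    decoys <- sim$truth$protein_id[startsWith(sim$truth$role, "decoy")]
    expect_length(intersect(cand$candidate_id, decoys), 0L)
  }
})

test_that("candidate output is invariant to proteome record order", {
  sim <- generateProteome(nFamilies = 2, candidatesPerFamily = 2, seed = 21)
  arch <- resolveArchitectures(sim$hits, sim$proteome)
  cfg <- screenConfig(ppiDomains = sim$ppiDomains)
  ref <- screenMicroCandidates(sim$proteome, arch, cfg)
  set.seed(1)
  perm <- sample(length(sim$proteome))
  shuffled <- screenMicroCandidates(sim$proteome[perm], arch[perm], cfg)
  attr(ref, "screen_counts") <- attr(shuffled, "screen_counts") <- NULL
  expect_identical(ref, shuffled)
})

test_that("relaxing the size bound only adds candidates; shrinking the
           whitelist only removes them", {
  sim <- generateProteome(nFamilies = 3, candidatesPerFamily = 3, seed = 33)
  arch <- resolveArchitectures(sim$hits, sim$proteome)
  base <- screenMicroCandidates(
    sim$proteome, arch, screenConfig(ppiDomains = sim$ppiDomains))
  wider <- screenMicroCandidates(
    sim$proteome, arch,
    screenConfig(maxLength = 200, ppiDomains = sim$ppiDomains))
  expect_true(all(base$candidate_id %in% wider$candidate_id))
  narrower <- screenMicroCandidates(
    sim$proteome, arch,
    screenConfig(ppiDomains = sim$ppiDomains[1L]))
  expect_true(all(narrower$candidate_id %in% base$candidate_id))
})

test_that("family summary partitions the candidate list", {
  sim <- generateProteome(nFamilies = 4, candidatesPerFamily = 2, seed = 12)
  arch <- resolveArchitectures(sim$hits, sim$proteome)
  cand <- screenMicroCandidates(sim$proteome, arch,
                                screenConfig(ppiDomains = sim$ppiDomains))
  fam <- familySummary(cand)
  expect_equal(nrow(fam), 4L)                 # one row per planted family
  expect_equal(sum(fam$n_candidates), nrow(cand))
  expect_equal(nrow(familySummary(cand[0, ])), 0L)
})

test_that("pairTargets ranks the planted multi-domain relative first", {
  sim <- generateProteome(nFamilies = 2, candidatesPerFamily = 2, seed = 7)
  arch <- resolveArchitectures(sim$hits, sim$proteome)
  cfg <- screenConfig(ppiDomains = sim$ppiDomains)
  truth <- sim$truth[sim$truth$role == "candidate", ]
  for (i in seq_len(nrow(truth))) {
    tg <- pairTargets(truth$protein_id[i], sim$proteome, arch, cfg)
    expect_gt(length(tg), 0L)
    expect_identical(tg[1L], truth$planted_target[i])
    expect_false(truth$protein_id[i] %in% tg)
  }
  expect_error(pairTargets("nope", sim$proteome, arch, cfg), "unknown")
})

test_that("an empty PPI whitelist is a configuration error", {
  mp <- miniProteome()
  arch <- resolveArchitectures(mp$hits, mp$proteome)
  cfg <- screenConfig(ppiDomains = character(0))
  expect_error(screenMicroCandidates(mp$proteome, arch, cfg),
               "whitelist is empty")
})

test_that("the shipped PPI whitelist loads and contains the B-Box domain", {
  ppi <- defaultPPIDomains()
  expect_true("PF00643" %in% ppi)
  expect_false(any(grepl("\\.\\d+$", ppi)))
})
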