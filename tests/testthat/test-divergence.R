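test_that("substitution counting matches simple hand cases and masks gaps", {
  expect_equal(countSubstitutions("ACGT", "ACGT"), 0L)
  expect_equal(countSubstitutions("ACGT", "ACGA"), 1L)
  ## gap and N positions never count as substitutions
  expect_equal(countSubstitutions("AC-TN", "ACGAA"), 1L)
  expect_equal(countSubstitutions("ACGT", "TGCA"), 4L)
  expect_error(countSubstitutions("ACG", "ACGT"), "equal length")
  ## symmetry
  expect_equal(countSubstitutions("ACGTAC", "TCGTAA"),
               countSubstitutions("TCGTAA", "ACGTAC"))
})

test_that("substitution counts agree exactly with a brute-force scan", {
  tr <- ape::rtree(8, rooted = TRUE)
  tr$edge.length <- tr$edge.length * 0.05
  aln <- simulateAlignment(tr, lengthBp = 2000, seed = 21)
  ids <- names(aln)
  chars <- as.character(aln)
  for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    expect_identical(countSubstitutions(chars[i], chars[j]),
                     bruteForceSubstitutions(chars[i], chars[j]))
  }
})

test_that("percent divergence reproduces the printed count/percent pairs", {
  expect_equal(roundDivergence(percentDivergence(14, 1594)), 0.88)
  expect_equal(roundDivergence(percentDivergence(18, 1594)), 1.1)
  expect_equal(roundDivergence(percentDivergence(41, 1594)), 2.6)
  expect_equal(roundDivergence(percentDivergence(288, 1594)), 18.1)
  expect_equal(roundDivergence(percentDivergence(292, 1594)), 18.3)
  expect_equal(roundDivergence(percentDivergence(6, 1594)), 0.38)
  expect_equal(percentDivergence(0, 1594), 0)
  ## linear in d, exact before rounding
  expect_equal(percentDivergence(2 * 7, 1594), 2 * percentDivergence(7, 1594))
  expect_error(percentDivergence(5, 0), "positive")
  expect_error(percentDivergence(-1, 100), "\\[0, L\\]")
})

test_that("group divergence equals an all-pairs brute-force scan", {
  tr <- ape::read.tree(text = paste0(
    "(((a1:0.01,a2:0.01):0.05,(b1:0.01,b2:0.01):0.05):0.05,",
    "(c1:0.01,c2:0.01):0.1);"))
  aln <- simulateAlignment(tr, lengthBp = 800, seed = 13)
  asn <- data.frame(id = names(aln),
                    group = substr(names(aln), 1, 1))
  summ <- groupDivergence(aln, asn)
  chars <- as.character(aln)
  pairs <- divergencePairs(summ)
  for (r in seq_len(nrow(pairs))) {
    ia <- names(aln)[asn$group == pairs$groupA[r]]
    ib <- names(aln)[asn$group == pairs$groupB[r]]
    d <- outer(ia, ib, Vectorize(function(x, y)
      bruteForceSubstitutions(chars[x], chars[y])))
    expect_equal(pairs$minCount[r], min(d))
    expect_equal(pairs$maxCount[r], max(d))
  }
})

test_that("degenerate group structures are handled", {
  aln <- Biostrings::DNAStringSet(c(a1 = "AAAAA", a2 = "AAAAA",
                                    b1 = "AATTT", b2 = "AATTT"))
  asn <- data.frame(id = names(aln), group = c("A", "A", "B", "B"))
  summ <- groupDivergence(aln, asn)
  p <- divergencePairs(summ)
  expect_equal(p$minCount, 3)           # fixed differences: min = max
  expect_equal(p$maxCount, 3)
  ## single-member groups
  aln1 <- Biostrings::DNAStringSet(c(x = "ACGT", y = "ACGA"))
  s1 <- groupDivergence(aln1, data.frame(id = c("x", "y"),
                                         group = c("X", "Y")))
  expect_equal(divergencePairs(s1)$minCount,
               divergencePairs(s1)$maxCount)
  expect_error(groupDivergence(aln, data.frame(id = names(aln),
                                               group = "A")),
               "two groups")
})

test_that("candidate delimitation applies the strict threshold rule", {
  L <- 1594
  mkseq <- function(at, base) {      # disjoint windows keep pairwise
    s <- rep("A", L)                 # distances additive and predictable
    s[at] <- base
    paste(s, collapse = "")
  }
  ## described d1-d2 differ by 14 (theta = 0.88%); undescribed u1 at 18
  ## from its closest relative (d1); u2 at 6 (below theta); u3 at exactly 14
  aln <- Biostrings::DNAStringSet(c(
    d1 = mkseq(integer(0), "A"), d2 = mkseq(1:14, "C"),
    u1 = mkseq(101:118, "G"), u2 = mkseq(201:206, "T"),
    u3 = mkseq(301:314, "G")))
  asn <- data.frame(id = names(aln), group = names(aln),
                    described = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  summ <- groupDivergence(aln, asn)
  dec <- delimitCandidates(summ, asn)
  dec <- dec[order(dec$group), ]
  expect_equal(dec$thresholdPct, rep(percentDivergence(14, L), 3))
  ## u1: closest is d1 at 18 subs > theta -> putative species
  expect_true(dec$putativeSpecies[dec$group == "u1"])
  ## u2: 6 subs from d1, within described intraspecific range -> not flagged
  expect_false(dec$putativeSpecies[dec$group == "u2"])
  ## boundary: exactly theta is NOT flagged (strict inequality)
  expect_false(dec$putativeSpecies[dec$group == "u3"])
  ## no described pairs -> threshold undefined
  asn2 <- asn; asn2$described <- FALSE
  expect_error(delimitCandidates(groupDivergence(aln, asn2), asn2),
               "threshold undefined")
})
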