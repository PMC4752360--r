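test_that("monophyly predicate handles trivial and fixture cases", {
  tr <- exampleRegionalTree()
  expect_true(isMonophyletic(tr, "O_validus"))
  expect_true(isMonophyletic(tr, tr$tip.label))
  ## the two Granitic Seychelles species do not form a clade: O. validus
  ## sits outside the main regional clade
  expect_false(isMonophyletic(tr, c("O_validus", "O_elegantulus")))
  ## the six Mascarene species do
  expect_true(isMonophyletic(tr, exampleMascareneTree()$tip.label))
  ## Pandanus-associated lineages are not monophyletic
  expect_false(isMonophyletic(tr, c("O_sp8", "O_sp9", "O_sp10")))
  expect_error(isMonophyletic(tr, "nosuchtip"), "unknown tip")
  expect_error(isMonophyletic(ape::unroot(tr), "O_validus"), "rooted")
})

test_that("Fitch count is 0 for constant characters and 2 on the fixture", {
  tr <- exampleMascareneTree()
  constant <- setNames(rep("dicot", 6), tr$tip.label)
  expect_equal(fitchMinChanges(tr, constant), 0L)
  ## two host shifts minimum between dicot- and Pandanus-association
  expect_equal(fitchMinChanges(tr, exampleHostStates()), 2L)
  ## and the same count on the full regional tree restricted to species
  ## with known host states
  wio <- ape::keep.tip(exampleRegionalTree(), names(exampleHostStates()))
  expect_equal(fitchMinChanges(wio, exampleHostStates()), 2L)
  expect_error(fitchMinChanges(tr, constant[-1]), "missing state")
})

test_that("Fitch equals exhaustive minimization on all 4-tip topologies", {
  states <- c(t1 = "P", t2 = "P", t3 = "D", t4 = "D")
  trees <- phangorn::allTrees(4, rooted = TRUE, tip.label = names(states))
  expect_equal(length(trees), 15)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    expect_equal(fitchMinChanges(tr, states),
                 bruteForceMinChanges(tr, states))
  }
})

test_that("Fitch matches the oracle and phangorn on random 6-tip trees", {
  set.seed(17)
  for (r in 1:10) {
    tr <- ape::rtree(6)
    states <- setNames(sample(c("A", "B"), 6, replace = TRUE),
                       tr$tip.label)
    mine <- fitchMinChanges(tr, states)
    expect_equal(mine, bruteForceMinChanges(tr, states))
    ## independent cross-check against phangorn's parsimony score
    pd <- phangorn::phyDat(matrix(states[tr$tip.label], ncol = 1,
                                  dimnames = list(tr$tip.label, NULL)),
                           type = "USER", levels = c("A", "B"))
    expect_equal(mine, as.integer(phangorn::fitch(tr, pd)))
    ## structural properties of the binary count
    if (mine == 0) expect_equal(length(unique(states)), 1L)
    if (length(unique(states)) == 2) {
      minority <- names(which.min(table(states)))
      mono <- isMonophyletic(tr, names(states)[states == minority])
      if (mono) expect_equal(mine, 1L)
      if (mine == 1L)
        expect_true(mono ||
          isMonophyletic(tr, names(states)[states != minority]))
    }
  }
})

test_that("archipelago classification reproduces both colonization scenarios", {
  tr <- exampleRegionalTree()
  occ <- exampleOccurrences()
  ct1 <- classifyArchipelagoSpecies(tr, occ, exampleScenario(1))
  ct2 <- classifyArchipelagoSpecies(tr, occ, exampleScenario(2))
  pick <- function(ct, arch, cat)
    sort(ct$species[ct$archipelago == arch & ct$category == cat])
  ## scenario 1: Chagos colonised from the older Granitic Seychelles
  expect_equal(pick(ct1, "Granitic_Seychelles", "anagenetic"),
               c("O_elegantulus", "O_validus"))
  expect_equal(pick(ct1, "Chagos", "immigrant"), "O_validus")
  ## scenario 2: the opposite direction
  expect_equal(pick(ct2, "Granitic_Seychelles", "immigrant"), "O_validus")
  expect_equal(pick(ct2, "Chagos", "anagenetic"), "O_validus")
  ## six Mascarene and two Comoros cladogenetic species in both scenarios
  for (ct in list(ct1, ct2)) {
    expect_equal(length(pick(ct, "Mascarenes", "cladogenetic")), 6)
    expect_equal(length(pick(ct, "Comoros", "cladogenetic")), 2)
    expect_equal(pick(ct, "Aldabra_Group", "anagenetic"), "O_syrticus")
    ## every (species, archipelago) pair categorized exactly once
    expect_equal(nrow(ct), nrow(occ))
    expect_equal(anyDuplicated(ct[c("species", "archipelago")]), 0L)
  }
  ## flipping the scenario swaps only the shared species' labels
  merged <- merge(ct1, ct2, by = c("archipelago", "species"))
  changed <- merged[merged$category.x != merged$category.y, ]
  expect_equal(sort(unique(changed$species)), "O_validus")
})

test_that("single endemics are anagenetic and conspecific tips collapse", {
  tr <- ape::read.tree(text = "((x1:1,x2:1):1,(y:1,z:1):1);")
  occ <- data.frame(species = c("X", "Y", "Z"),
                    archipelago = c("A", "B", "B"))
  ct <- classifyArchipelagoSpecies(tr, occ,
                                   tipSpecies = c(x1 = "X", x2 = "X",
                                                  y = "Y", z = "Z"))
  ## X endemic to A with sister outside: anagenetic despite two tips
  expect_equal(ct$category[ct$species == "X"], factor("anagenetic",
    levels = c("immigrant", "anagenetic", "cladogenetic")))
  ## Y + Z form a B-endemic clade of 2: cladogenetic
  expect_true(all(ct$category[ct$archipelago == "B"] == "cladogenetic"))
  ## contradictory scenario is rejected
  occ2 <- rbind(occ, data.frame(species = "X", archipelago = "B"))
  expect_error(classifyArchipelagoSpecies(tr, occ2,
    scenario = data.frame(species = "X", source = "C"),
    tipSpecies = c(x1 = "X", x2 = "X", y = "Y", z = "Z")),
    "contradictory")
})

test_that("radiation summary counts are conserved and geo-sorted", {
  ct <- classifyArchipelagoSpecies(exampleRegionalTree(),
                                   exampleOccurrences(),
                                   exampleScenario(1))
  geo <- exampleArchipelagoGeo()
  rs <- radiationSummary(ct, geo)
  ## Mascarene record: 6 cladogenetic, nothing else
  masc <- rs[rs$archipelago == "Mascarenes", ]
  expect_equal(masc$n_cladogenetic, 6)
  expect_equal(masc$n_anagenetic, 0)
  expect_equal(masc$n_immigrant, 0)
  ## conservation: per-archipelago counts sum to occurrence rows
  expect_equal(sum(rs$n_immigrant + rs$n_anagenetic + rs$n_cladogenetic),
               nrow(exampleOccurrences()))
  ## sorted by area then isolation
  expect_true(!is.unsorted(rs$area_km2))
  ## empty table -> empty summary
  expect_equal(nrow(radiationSummary(ct[0, ], geo)), 0)
  expect_error(radiationSummary(ct, geo[geo$archipelago != "Chagos", ]),
               "missing geo")
})
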