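# Independent oracles used across test files. Deliberately naive: these
# re-derive expected values by enumeration / position-by-position scans,
# not by calling the implementation under test.

# substitution count by explicit position scan
bruteForceSubstitutions <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  n <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% c("A", "C", "G", "T") &&
        cb[i] %in% c("A", "C", "G", "T") && ca[i] != cb[i]) n <- n + 1L
  }
  n
}

# minimum changes over ALL ancestral state assignments (exhaustive)
bruteForceMinChanges <- function(tree, tipStates) {
  states <- sort(unique(as.character(tipStates)))
  nTip <- length(tree$tip.label)
  internal <- (nTip + 1):(nTip + tree$Nnode)
  assign <- as.character(tipStates[tree$tip.label])
  grid <- expand.grid(rep(list(states), tree$Nnode),
                      stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    full <- c(assign, unlist(grid[r, ], use.names = FALSE))
    changes <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# expected p-distance under Jukes-Cantor at path distance d
jcExpectedP <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# raw rectangular-window periodogram peak (independent of the Welch
# estimator inside measureSong)
rawSpectralPeak <- function(wave, sampleRate, band = c(2000, 10000)) {
  pow <- Mod(fft(wave))^2
  freq <- (seq_along(wave) - 1) / length(wave) * sampleRate
  sel <- freq >= band[1] & freq <= band[2]
  freq[sel][which.max(pow[sel])]
}

# well-separated two/three-group feature tables for clustering tests
separatedTable <- function(nGroups = 2, nPerGroup = 20, sepSds = 10,
                           seed = 1) {
  means <- sapply(1:2, function(j) (seq_len(nGroups) - 1) * sepSds)
  means <- matrix(means, nrow = nGroups)
  colnames(means) <- c("trait1", "trait2")
  rownames(means) <- paste0("g", seq_len(nGroups))
  sds <- matrix(1, nGroups, 2, dimnames = dimnames(means))
  generateSongParameterTable(means, sds, nPerGroup, seed = seed)
}
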