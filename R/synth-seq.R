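#' Simulate a fixed-length alignment under the Jukes-Cantor model
#'
#' Evolves one sequence per tip of a rooted tree with branch lengths in
#' expected substitutions per site, site-independently under Jukes-Cantor
#' (flat rate matrix, equal base frequencies). Deterministic under a fixed
#' seed. The mitochondrial three-gene scale used for regional surveys is
#' 1594 bp, the default here.
#'
#' @param tree an `ape::phylo` with non-negative branch lengths.
#' @param lengthBp alignment length in base pairs (> 0).
#' @param seed integer RNG seed.
#' @return a [Biostrings::DNAStringSet] of equal-length sequences named by
#'   tip label.
#' @examples
#' tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.02,c:0.07);")
#' aln <- simulateAlignment(tr, lengthBp = 200, seed = 1)
#' Biostrings::width(aln)
#' @export
simulateAlignment <- function(tree, lengthBp = 1594L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (lengthBp < 1) stop("lengthBp must be >= 1")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  set.seed(as.integer(seed))
  sim <- phangorn::simSeq(tree, l = lengthBp, type = "DNA")
  mat <- toupper(as.character(sim))
  seqs <- apply(mat, 1L, paste, collapse = "")
  Biostrings::DNAStringSet(setNames(seqs, rownames(mat)))
}

#' Generate a song-parameter feature table with known group labels
#'
#' Gaussian draws around per-group trait means, retaining the true label
#' column for downstream clustering evaluation. Groups share a column set
#' (e.g. `fundamental_22`, `pulse_rate_22`, `P1_ms`, `sentence_period_22`).
#'
#' @param groupMeans numeric matrix (groups x traits) or a list of equal
#'   length vectors; row/list names become group labels.
#' @param groupSds matrix/list of the same shape; non-negative.
#' @param nPerGroup rows to draw per group.
#' @param seed integer RNG seed.
#' @param pattern optional integer vector (one per group) recorded in a
#'   `pattern` column, for stratified analyses.
#' @return a data.frame with a `group` factor column, optional `pattern`
#'   column, and one numeric column per trait.
#' @examples
#' m <- rbind(a = c(f = 5000, p1 = 80), b = c(f = 6500, p1 = 120))
#' s <- rbind(a = c(10, 2), b = c(10, 2))
#' head(generateSongParameterTable(m, s, nPerGroup = 5, seed = 1))
#' @export
generateSongParameterTable <- function(groupMeans, groupSds, nPerGroup = 20L,
                                       seed = 1L, pattern = NULL) {
  if (is.list(groupMeans)) groupMeans <- do.call(rbind, groupMeans)
  if (is.list(groupSds)) groupSds <- do.call(rbind, groupSds)
  groupMeans <- as.matrix(groupMeans)
  groupSds <- as.matrix(groupSds)
  if (!identical(dim(groupMeans), dim(groupSds)))
    stop("groupMeans and groupSds must have identical dimensions")
  if (any(groupSds < 0)) stop("groupSds must be non-negative")
  g <- nrow(groupMeans)
  labs <- rownames(groupMeans)
  if (is.null(labs)) labs <- paste0("group", seq_len(g))
  if (!is.null(pattern) && length(pattern) != g)
    stop("pattern must give one value per group")
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(g), function(i) {
    draws <- sapply(seq_len(ncol(groupMeans)), function(j)
      rnorm(nPerGroup, groupMeans[i, j], groupSds[i, j]))
    draws <- matrix(draws, nrow = nPerGroup)
    colnames(draws) <- colnames(groupMeans)
    df <- as.data.frame(draws)
    df$group <- labs[i]
    if (!is.null(pattern)) df$pattern <- as.integer(pattern[i])
    df
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = labs)
  rownames(out) <- NULL
  out
}

#' Generate a survey first-detection history under a logistic discovery curve
#'
#' Draws a first-detection night for each species so that the expected
#' cumulative species count follows Nspmax / (1 + (t/t50)^b). With
#' `method = "quantile"` species are placed at noiseless quantiles of the
#' curve (so exactly half are found by t50); with `method = "random"`
#' detection times are iid draws from the implied distribution.
#'
#' Defaults reproduce the regional survey conditions: 11 species, t50 =
#' 3.46 nights, b = -2.83, at which effort 20 nights recover >99 percent of
#' the expected species pool.
#'
#' @param nSpecies number of species in the pool.
#' @param t50 nights to detect half of the species (> 0).
#' @param b logistic shape (negative for a saturating curve).
#' @param maxNights survey length; species whose drawn time exceeds it are
#'   never detected and are absent from the log.
#' @param seed integer RNG seed (used by `method = "random"`).
#' @param region region label for the log.
#' @param method `"random"` or `"quantile"` (noiseless placement).
#' @return a detection-log data.frame with columns `region`, `night`
#'   (positive integer), `species`, plus the continuous detection `time`
#'   that `night` is the ceiling of; one row per detected species.
#' @examples
#' generateSurveyHistory(10, t50 = 3.46, b = -2.83, maxNights = 20,
#'                       seed = 1, method = "quantile")
#' @export
generateSurveyHistory <- function(nSpecies = 11L, t50 = 3.46, b = -2.83,
                                  maxNights = 40L, seed = 1L,
                                  region = "pooled",
                                  method = c("random", "quantile")) {
  method <- match.arg(method)
  if (t50 <= 0) stop("t50 must be positive")
  if (maxNights < 1) stop("maxNights must be positive")
  if (b >= 0) stop("b must be negative for a saturating discovery curve")
  u <- if (method == "quantile") {
    (seq_len(nSpecies) - 0.5) / nSpecies
  } else {
    set.seed(as.integer(seed))
    runif(nSpecies)
  }
  ## invert F(t) = 1/(1+(t/t50)^b): t = t50 * (1/u - 1)^(1/b)
  tCont <- t50 * (1 / u - 1)^(1 / b)
  night <- ceiling(tCont)
  night[night < 1] <- 1L
  keep <- night <= maxNights
  data.frame(
    region = region,
    night = as.integer(night[keep]),
    species = sprintf("sp%02d", seq_len(nSpecies))[keep],
    time = tCont[keep],
    stringsAsFactors = FALSE
  )
}
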