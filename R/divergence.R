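## Sequences are compared position-by-position over the full alignment
## length L. Positions where either sequence has a gap ("-") or an
## ambiguous base ("N") are masked: they never count as substitutions but
## stay in the denominator, matching the fixed-L percent convention.

.seqToChar <- function(s) {
  if (is(s, "DNAStringSet")) return(strsplit(toupper(as.character(s)), ""))
  if (is(s, "DNAString")) return(strsplit(toupper(as.character(s)), "")[[1]])
  if (is.character(s) && length(s) == 1) return(strsplit(toupper(s), "")[[1]])
  stop("expected a DNAString(Set) or a single character string")
}

#' Count substitutions between two aligned sequences
#'
#' Number of positions where both characters are unambiguous bases
#' (A, C, G, T) and differ. Positions with a gap or N in either sequence
#' are never counted as substitutions. Symmetric in its arguments.
#'
#' @param seqA,seqB equal-length aligned sequences (character strings,
#'   [Biostrings::DNAString] or single-element DNAStringSet).
#' @return integer substitution count.
#' @examples
#' countSubstitutions("ACGT", "ACGA")   # 1
#' countSubstitutions("AC-T", "ACGA")   # 1 (gap position masked)
#' @export
countSubstitutions <- function(seqA, seqB) {
  a <- .seqToChar(seqA)
  b <- .seqToChar(seqB)
  if (is.list(a)) a <- a[[1]]
  if (is.list(b)) b <- b[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  bases <- c("A", "C", "G", "T")
  sum(a %in% bases & b %in% bases & a != b)
}

#' Percent ("absolute") divergence from a substitution count
#'
#' D = 100 d / L on the full alignment length L. Exact in floating point
#' for the count scale involved; rounding to reporting precision is a
#' separate step ([roundDivergence()]).
#'
#' @param d substitution count, 0 <= d <= L.
#' @param L alignment length (> 0).
#' @return percent divergence (numeric, unrounded).
#' @examples
#' percentDivergence(14, 1594)   # 0.8783...
#' @export
percentDivergence <- function(d, L) {
  if (any(L <= 0)) stop("L must be positive")
  if (any(d < 0 | d > L)) stop("d must lie in [0, L]")
  100 * d / L
}

#' Round percent divergence to reporting precision
#'
#' Two decimals below 1 percent, one decimal at or above 1 percent --
#' the convention used when quoting absolute divergence values.
#'
#' @param pct numeric percent divergence.
#' @return rounded numeric.
#' @examples
#' roundDivergence(percentDivergence(c(14, 292), 1594))  # 0.88, 18.3
#' @export
roundDivergence <- function(pct) {
  ifelse(pct < 1, round(pct, 2), round(pct, 1))
}

#' Between-group divergence summary
#'
#' For every pair of groups, the minimum and maximum substitution count
#' (and percent divergence) over all cross-group sequence pairs.
#'
#' @param alignment a [Biostrings::DNAStringSet] of equal-length aligned
#'   sequences with unique names.
#' @param assignment data.frame with columns `id` (matching alignment
#'   names), `group`, and optionally `described` (logical; used by
#'   [delimitCandidates()]).
#' @return a [DivergenceSummary-class].
#' @export
groupDivergence <- function(alignment, assignment) {
  stopifnot(is(alignment, "DNAStringSet"))
  if (!all(c("id", "group") %in% names(assignment)))
    stop("assignment needs id and group columns")
  ids <- names(alignment)
  if (anyDuplicated(ids)) stop("alignment ids must be unique")
  if (!all(ids %in% assignment$id))
    stop("unassigned sequence id(s): ",
         paste(setdiff(ids, assignment$id), collapse = ", "))
  L <- unique(Biostrings::width(alignment))
  if (length(L) != 1) stop("sequences must share one alignment length")
  grp <- setNames(as.character(assignment$group), assignment$id)[ids]
  groups <- sort(unique(grp))
  if (length(groups) < 2) stop("need at least two groups")
  if (any(!assignment$group %in% grp))
    stop("group with zero aligned members: ",
         paste(setdiff(assignment$group, grp), collapse = ", "))
  described <- if ("described" %in% names(assignment)) {
    d <- tapply(assignment$described, assignment$group, unique)
    vapply(d, isTRUE, logical(1))
  } else setNames(rep(NA, length(groups)), groups)

  chars <- .seqToChar(alignment)
  pairRows <- list()
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    ia <- which(grp == groups[i]); ib <- which(grp == groups[j])
    d <- vapply(ia, function(x) vapply(ib, function(y) {
      a <- chars[[x]]; b <- chars[[y]]
      sum(a %in% c("A","C","G","T") & b %in% c("A","C","G","T") & a != b)
    }, numeric(1)), numeric(length(ib)))
    pairRows[[length(pairRows) + 1L]] <- data.frame(
      groupA = groups[i], groupB = groups[j],
      minCount = min(d), maxCount = max(d),
      minPct = percentDivergence(min(d), L),
      maxPct = percentDivergence(max(d), L),
      bothDescribed = isTRUE(described[[groups[i]]]) &&
        isTRUE(described[[groups[j]]]),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairRows)
  new("DivergenceSummary", pairs = pairs, lengthBp = as.integer(L),
      globalMinPct = min(pairs$minPct), globalMaxPct = max(pairs$maxPct))
}

#' @rdname divergenceAccessors
#' @name divergenceAccessors
#' @title Accessors for DivergenceSummary
#' @param x a [DivergenceSummary-class].
#' @return `divergencePairs`: the per-group-pair data.frame.
#' @export
setMethod("divergencePairs", "DivergenceSummary", function(x) x@pairs)

#' Flag undescribed groups as putative species
#'
#' The delimitation threshold is the minimum divergence between described
#' species: theta = min over described-described group pairs of the
#' pairwise minimum percent divergence. An undescribed group is flagged as
#' a putative species iff its minimum divergence to its closest other
#' group strictly exceeds theta ("exceeds" = strict inequality); groups at
#' or below theta fall within the intraspecific variation range.
#'
#' @param summary a [DivergenceSummary-class] built from an assignment
#'   with a `described` column.
#' @param assignment the same assignment data.frame (columns `id`,
#'   `group`, `described`).
#' @return data.frame with one row per undescribed group: `group`,
#'   `closestGroup`, `minPct` (divergence to the closest group),
#'   `thresholdPct` (theta), `putativeSpecies` (logical).
#' @export
delimitCandidates <- function(summary, assignment) {
  stopifnot(is(summary, "DivergenceSummary"))
  pairs <- summary@pairs
  if (!any(pairs$bothDescribed))
    stop("no described-described group pair: threshold undefined")
  theta <- min(pairs$minPct[pairs$bothDescribed])
  descByGroup <- tapply(assignment$described, assignment$group,
                        function(z) isTRUE(unique(z)))
  undescribed <- names(descByGroup)[!vapply(descByGroup, isTRUE, logical(1))]
  rows <- lapply(undescribed, function(g) {
    sel <- pairs$groupA == g | pairs$groupB == g
    if (!any(sel)) return(NULL)
    sub <- pairs[sel, ]
    iMin <- which.min(sub$minPct)
    closest <- ifelse(sub$groupA[iMin] == g, sub$groupB[iMin],
                      sub$groupA[iMin])
    data.frame(group = g, closestGroup = closest,
               minPct = sub$minPct[iMin], thresholdPct = theta,
               putativeSpecies = sub$minPct[iMin] > theta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
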