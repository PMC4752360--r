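#' Test whether a set of tips is monophyletic
#'
#' TRUE iff `tipSet` is exactly the full leaf set of some node of the
#' rooted tree. Thin wrapper over [ape::is.monophyletic()] with input
#' checks; unrooted trees are refused rather than auto-rooted, since clade
#' statements are only meaningful on a rooted topology.
#'
#' @param tree a rooted `ape::phylo`.
#' @param tipSet non-empty character vector of tip labels.
#' @return logical.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' isMonophyletic(tr, c("a", "b"))   # TRUE
#' isMonophyletic(tr, c("a", "c"))   # FALSE
#' @export
isMonophyletic <- function(tree, tipSet) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!length(tipSet)) stop("tipSet must be non-empty")
  unknown <- setdiff(tipSet, tree$tip.label)
  if (length(unknown))
    stop("unknown tip id(s): ", paste(unknown, collapse = ", "))
  ape::is.monophyletic(tree, tipSet)
}

#' Minimum number of character-state changes (Fitch parsimony)
#'
#' Small-parsimony count for a discrete character on a rooted bifurcating
#' tree: a single postorder pass in which every empty intersection of
#' child state sets forces a union and one change. Used here to count the
#' minimum number of host-association shifts (e.g. dicot vs Pandanus)
#' needed to explain tip states.
#'
#' @param tree a rooted, fully bifurcating `ape::phylo`.
#' @param tipStates named character/factor vector, one state per tip.
#' @return integer minimum number of changes (0 for a constant character).
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' fitchMinChanges(tr, c(a = "P", b = "P", c = "D", d = "D"))  # 1
#' @export
fitchMinChanges <- function(tree, tipStates) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be fully bifurcating")
  tips <- tree$tip.label
  missing <- setdiff(tips, names(tipStates))
  if (length(missing))
    stop("missing state for tip(s): ", paste(missing, collapse = ", "))
  states <- as.character(tipStates[tips])
  if (anyNA(states)) stop("NA tip state")
  nTip <- length(tips)
  sets <- vector("list", nTip + tree$Nnode)
  for (i in seq_len(nTip)) sets[[i]] <- states[i]
  edge <- reorder(tree, "postorder")$edge
  changes <- 0L
  for (nd in unique(edge[, 1])) {        # postorder: children first
    children <- edge[edge[, 1] == nd, 2]
    s <- sets[[children[1]]]
    for (ch in children[-1]) {
      inter <- intersect(s, sets[[ch]])
      if (length(inter)) {
        s <- inter
      } else {
        s <- union(s, sets[[ch]])
        changes <- changes + 1L
      }
    }
    sets[[nd]] <- s
  }
  changes
}

## collapse conspecific tips to one representative per species, renamed to
## the species label; refuses non-monophyletic species.
.speciesTree <- function(tree, tipSpecies) {
  if (is.null(tipSpecies)) return(tree)
  stopifnot(all(tree$tip.label %in% names(tipSpecies)))
  sp <- tipSpecies[tree$tip.label]
  for (s in unique(sp[duplicated(sp)])) {
    members <- tree$tip.label[sp == s]
    if (!ape::is.monophyletic(tree, members))
      stop("conspecific tips of ", s, " are not monophyletic")
    tree <- ape::drop.tip(tree, members[-1])
    sp <- tipSpecies[tree$tip.label]
  }
  tree$tip.label <- unname(tipSpecies[tree$tip.label])
  tree
}

#' Classify archipelago species as immigrant, anagenetic or cladogenetic
#'
#' Applies, per archipelago, the operational rules used for alternative
#' colonization scenarios:
#' \describe{
#'   \item{cladogenetic}{species belonging to a maximal archipelago-endemic
#'     clade of two or more species (in-situ diversification);}
#'   \item{anagenetic}{archipelago-endemic species whose sister lineage lies
#'     outside the archipelago (one colonization, in-situ divergence);}
#'   \item{immigrant}{species shared between archipelagos are immigrant in
#'     the scenario's recipient archipelago(s) and anagenetic in its source
#'     archipelago.}
#' }
#' Categories are mutually exclusive per (species, archipelago) pair.
#' Conspecific tips are collapsed to one per species before clade tests, so
#' within-species sampling cannot inflate cladogenesis counts.
#'
#' @param tree rooted `ape::phylo` covering all species in `occurrences`
#'   (tips may include continental/outgroup taxa).
#' @param occurrences data.frame with columns `species`, `archipelago`;
#'   one row per (species, archipelago).
#' @param scenario data.frame with columns `species`, `source` giving the
#'   source archipelago for every species present in more than one
#'   archipelago (direction of colonization). May be NULL when no species
#'   is shared.
#' @param tipSpecies optional named character vector mapping tip labels to
#'   species (default: tips are species).
#' @return data.frame (category table) with columns `archipelago`,
#'   `species`, `category` (factor: immigrant/anagenetic/cladogenetic).
#' @seealso [radiationSummary()], [exampleRegionalTree()]
#' @export
classifyArchipelagoSpecies <- function(tree, occurrences, scenario = NULL,
                                       tipSpecies = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!all(c("species", "archipelago") %in% names(occurrences)))
    stop("occurrences needs species and archipelago columns")
  if (anyNA(occurrences$archipelago))
    stop("species with no archipelago")
  if (anyDuplicated(occurrences[c("species", "archipelago")]))
    stop("duplicate (species, archipelago) rows")
  occurrences$species <- as.character(occurrences$species)
  occurrences$archipelago <- as.character(occurrences$archipelago)
  tree <- .speciesTree(tree, tipSpecies)
  spp <- unique(occurrences$species)
  absent <- setdiff(spp, tree$tip.label)
  if (length(absent))
    stop("species not in tree: ", paste(absent, collapse = ", "))

  archOf <- split(occurrences$archipelago, occurrences$species)
  multi <- names(archOf)[lengths(archOf) > 1]
  if (length(multi)) {
    if (is.null(scenario) ||
        !all(c("species", "source") %in% names(scenario)))
      stop("scenario with species and source columns required for ",
           "multi-archipelago species: ", paste(multi, collapse = ", "))
    src <- setNames(as.character(scenario$source), scenario$species)
    if (!all(multi %in% names(src)))
      stop("scenario missing species: ",
           paste(setdiff(multi, names(src)), collapse = ", "))
    bad <- multi[!mapply(function(s) src[[s]] %in% archOf[[s]], multi)]
    if (length(bad))
      stop("contradictory scenario: source archipelago not occupied by ",
           paste(bad, collapse = ", "))
  }

  ## clade tip sets of every internal node of the species tree
  cladeSets <- ape::prop.part(tree)
  labs <- attr(cladeSets, "labels")

  rows <- list()
  for (A in unique(occurrences$archipelago)) {
    endemic <- names(archOf)[vapply(archOf, function(a)
      identical(a, A), logical(1))]
    clado <- character(0)
    if (length(endemic) >= 2) {
      inA <- vapply(cladeSets, function(ss) all(labs[ss] %in% endemic),
                    logical(1))
      ## maximal endemic clades: not contained in a larger endemic clade
      idx <- which(inA)
      for (i in idx) {
        tipsI <- labs[cladeSets[[i]]]
        contained <- any(vapply(idx, function(j)
          j != i && all(tipsI %in% labs[cladeSets[[j]]]), logical(1)))
        if (!contained && length(tipsI) >= 2) clado <- c(clado, tipsI)
      }
    }
    ana <- setdiff(endemic, clado)
    for (s in clado) rows[[length(rows) + 1L]] <-
      data.frame(archipelago = A, species = s, category = "cladogenetic")
    for (s in ana) rows[[length(rows) + 1L]] <-
      data.frame(archipelago = A, species = s, category = "anagenetic")
  }
  for (s in multi) {
    for (A in archOf[[s]]) {
      cat <- if (A == src[[s]]) "anagenetic" else "immigrant"
      rows[[length(rows) + 1L]] <-
        data.frame(archipelago = A, species = s, category = cat)
    }
  }
  out <- do.call(rbind, rows)
  out$category <- factor(out$category,
                         levels = c("immigrant", "anagenetic",
                                    "cladogenetic"))
  out <- out[order(out$archipelago, out$category, out$species), ]
  rownames(out) <- NULL
  out
}

#' Per-archipelago species-category counts with geography
#'
#' Joins the category table with archipelago area and isolation, yielding
#' one record per archipelago for comparison against radiation-zone
#' predictions (cladogenetic species are expected only on archipelagos
#' that are both large and isolated).
#'
#' @param categoryTable output of [classifyArchipelagoSpecies()].
#' @param geo data.frame with columns `archipelago`, `area_km2` (> 0) and
#'   `isolation_km` (>= 0; minimum distance to the nearest other landmass).
#' @return data.frame sorted by area then isolation, with columns
#'   `archipelago`, `area_km2`, `isolation_km`, `n_immigrant`,
#'   `n_anagenetic`, `n_cladogenetic`.
#' @export
radiationSummary <- function(categoryTable, geo) {
  if (!nrow(categoryTable))
    return(data.frame(archipelago = character(0), area_km2 = numeric(0),
                      isolation_km = numeric(0), n_immigrant = integer(0),
                      n_anagenetic = integer(0),
                      n_cladogenetic = integer(0)))
  if (!all(c("archipelago", "area_km2", "isolation_km") %in% names(geo)))
    stop("geo needs archipelago, area_km2 and isolation_km columns")
  if (any(geo$area_km2 <= 0) || any(geo$isolation_km < 0))
    stop("area must be positive and isolation non-negative")
  archs <- unique(categoryTable$archipelago)
  missing <- setdiff(archs, geo$archipelago)
  if (length(missing))
    stop("missing geo record(s): ", paste(missing, collapse = ", "))
  counts <- table(categoryTable$archipelago, categoryTable$category)
  out <- data.frame(
    archipelago = archs,
    area_km2 = geo$area_km2[match(archs, geo$archipelago)],
    isolation_km = geo$isolation_km[match(archs, geo$archipelago)],
    n_immigrant = as.integer(counts[archs, "immigrant"]),
    n_anagenetic = as.integer(counts[archs, "anagenetic"]),
    n_cladogenetic = as.integer(counts[archs, "cladogenetic"]),
    stringsAsFactors = FALSE)
  out <- out[order(out$area_km2, out$isolation_km), ]
  rownames(out) <- NULL
  out
}
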