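#' Split a feature table by syllabic pattern
#'
#' Song types are clustered within each syllabic pattern (mono-, di-,
#' trisyllabic), since period columns are only comparable within a pattern.
#'
#' @param table data.frame with an integer `pattern` column (values 1--3).
#' @return named list of data.frames, one per pattern present, names
#'   `"1"`, `"2"`, `"3"`; empty list for an empty table.
#' @export
stratifyByPattern <- function(table) {
  if (!"pattern" %in% names(table)) stop("pattern column required")
  if (!nrow(table)) return(list())
  if (any(!table$pattern %in% 1:3))
    stop("unknown pattern value(s): ",
         paste(setdiff(unique(table$pattern), 1:3), collapse = ", "))
  split(table, factor(table$pattern, levels = sort(unique(table$pattern))))
}

## numeric feature matrix: all numeric columns except bookkeeping ones
.featureMatrix <- function(table, features = NULL) {
  drop <- c("group", "pattern", "aural_label", "recording_id",
            "temperature_C")
  if (is.null(features))
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        drop)
  if (!length(features)) stop("no numeric feature columns")
  x <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(x)) stop("missing values in feature columns: ",
                     paste(features[colSums(is.na(x)) > 0], collapse = ", "))
  x
}

#' K-means classification of song measurements
#'
#' Best-of-`nInit` Lloyd K-means, deterministic under a fixed seed.
#' Features are z-scored by default so that traits on Hz and ms scales
#' contribute comparably; centroids are reported on both the clustering
#' and the original scale.
#'
#' @param table data.frame of one pattern stratum (see
#'   [stratifyByPattern()]); non-feature columns `group`, `pattern`,
#'   `aural_label`, `recording_id`, `temperature_C` are ignored.
#' @param k number of clusters, 1 <= k <= nrow(table).
#' @param nInit number of random restarts.
#' @param seed integer RNG seed.
#' @param maxIter Lloyd iteration cap per restart.
#' @param standardize z-score feature columns before clustering?
#' @param features optional character vector naming the feature columns.
#' @return a [ClusteringResult-class].
#' @examples
#' tab <- generateSongParameterTable(
#'   rbind(a = c(f = 5000, p = 80), b = c(f = 6000, p = 140)),
#'   rbind(a = c(20, 2), b = c(20, 2)), nPerGroup = 10, seed = 1)
#' kmeansClassify(tab, k = 2, seed = 1)
#' @export
kmeansClassify <- function(table, k, nInit = 50L, seed = 1L,
                           maxIter = 100L, standardize = TRUE,
                           features = NULL) {
  x <- .featureMatrix(table, features)
  if (!nrow(x)) stop("empty table")
  if (k < 1 || k > nrow(x)) stop("k must lie in [1, nrow(table)]")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  xs <- if (standardize) scale(x, center = ctr, scale = scl) else x
  set.seed(as.integer(seed))
  km <- suppressWarnings(
    kmeans(xs, centers = k, iter.max = maxIter, nstart = nInit,
           algorithm = "Lloyd"))
  cen <- km$centers
  cenRaw <- if (standardize)
    sweep(sweep(cen, 2, scl, "*"), 2, ctr, "+") else cen
  new("ClusteringResult", labels = as.integer(km$cluster),
      centroids = unclass(cen), centroidsRaw = unclass(cenRaw),
      inertia = km$tot.withinss, k = as.integer(k),
      seed = as.integer(seed), nInit = as.integer(nInit),
      standardized = standardize, features = colnames(x))
}

#' Accessors for ClusteringResult
#'
#' @param x a [ClusteringResult-class].
#' @param scale `"clustering"` (z-scored when the fit standardized) or
#'   `"raw"` (original trait units).
#' @return `clusterLabels`: integer labels 1..k; `clusterCentroids`: k x p
#'   matrix; `clusterInertia`: total within-cluster sum of squares.
#' @name clusterAccessors
NULL

#' @rdname clusterAccessors
#' @export
setMethod("clusterLabels", "ClusteringResult", function(x) x@labels)

#' @rdname clusterAccessors
#' @export
setMethod("clusterCentroids", "ClusteringResult",
  function(x, scale = c("clustering", "raw")) {
    scale <- match.arg(scale)
    if (scale == "raw") x@centroidsRaw else x@centroids
  })

#' @rdname clusterAccessors
#' @export
setMethod("clusterInertia", "ClusteringResult", function(x) x@inertia)

#' Choose k by mean silhouette width
#'
#' Runs [kmeansClassify()] over `kRange` and returns the k maximizing the
#' mean silhouette width, with the full silhouette and inertia profile for
#' diagnostics (a flat, low profile indicates no cluster structure).
#'
#' @inheritParams kmeansClassify
#' @param kRange integer vector of candidate k, within [2, n-1].
#' @return list with `k` (selected), `profile` (data.frame k, silhouette,
#'   inertia), and `results` (the [ClusteringResult-class] per k).
#' @export
selectK <- function(table, kRange = 2:6, nInit = 50L, seed = 1L,
                    standardize = TRUE, features = NULL) {
  x <- .featureMatrix(table, features)
  kRange <- kRange[kRange >= 2 & kRange <= nrow(x) - 1]
  if (!length(kRange)) stop("kRange must contain values in [2, n-1]")
  if (all(dist(x) == 0)) stop("degenerate table: all rows identical")
  xs <- if (standardize) scale(x) else x
  d <- dist(xs)
  fits <- lapply(kRange, function(k)
    kmeansClassify(table, k, nInit = nInit, seed = seed,
                   standardize = standardize, features = features))
  sil <- vapply(fits, function(f) {
    s <- cluster::silhouette(f@labels, d)
    mean(s[, "sil_width"])
  }, numeric(1))
  inertia <- vapply(fits, clusterInertia, numeric(1))
  best <- which.max(sil)
  list(k = kRange[best],
       profile = data.frame(k = kRange, silhouette = sil,
                            inertia = inertia),
       results = setNames(fits, kRange))
}

#' Compare a clustering against reference labels
#'
#' Adjusted Rand index between two partitions plus an exact-match flag
#' that is TRUE iff the partitions are identical up to label permutation.
#'
#' @param predicted,reference equal-length label vectors.
#' @return list with `ari` (in [-1, 1]) and `exactMatch` (logical).
#' @examples
#' comparePartitions(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
comparePartitions <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  tab <- table(predicted, reference)
  exact <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
  list(ari = mclust::adjustedRandIndex(predicted, reference),
       exactMatch = exact)
}
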