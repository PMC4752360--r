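## Light CSV readers with column validation, plus FASTA passthrough.
## Standard formats go through the field's packages: FASTA via Biostrings,
## Newick via ape; CSV via base utils.

#' Read a survey detection log
#'
#' @param path CSV with columns `region`, `night`, `species` (one row per
#'   first detection).
#' @return validated data.frame.
#' @export
readDetectionLog <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "night", "species")
  if (!all(need %in% names(d)))
    stop("detection log needs columns: ", paste(need, collapse = ", "))
  if (any(d$night < 1 | d$night != round(d$night)))
    stop("nights must be positive integers")
  if (anyDuplicated(d[c("region", "species")]))
    stop("duplicate (region, species) first detection")
  d
}

#' Read a group assignment table for divergence analysis
#'
#' @param path CSV with columns `id`, `group` and optionally `described`
#'   (logical / 0-1).
#' @return validated data.frame with logical `described` when present.
#' @export
readGroupAssignment <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(d)))
    stop("assignment needs id and group columns")
  if ("described" %in% names(d)) d$described <- as.logical(d$described)
  d
}

#' Read an aligned FASTA file as a DNAStringSet
#'
#' @param path FASTA path (equal-length aligned sequences).
#' @return a [Biostrings::DNAStringSet].
#' @export
readAlignmentFasta <- function(path) {
  aln <- Biostrings::readDNAStringSet(path)
  if (length(unique(Biostrings::width(aln))) != 1)
    stop("sequences are not aligned (unequal lengths)")
  aln
}

#' Write an alignment to FASTA
#'
#' @param alignment a [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentFasta <- function(alignment, path) {
  Biostrings::writeXStringSet(alignment, path)
  invisible(path)
}

#' Read archipelago geography
#'
#' @param path CSV with columns `archipelago`, `area_km2`, `isolation_km`.
#' @return validated data.frame.
#' @export
readArchipelagoGeo <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("archipelago", "area_km2", "isolation_km")
  if (!all(need %in% names(d)))
    stop("geography needs columns: ", paste(need, collapse = ", "))
  if (any(d$area_km2 <= 0)) stop("area must be positive")
  if (any(d$isolation_km < 0)) stop("isolation must be non-negative")
  d
}

#' Write song measurements to CSV
#'
#' @param measurements a [SongMeasurement-class], list of them, or a
#'   measurement data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMeasurements <- function(measurements, path) {
  if (!is.data.frame(measurements))
    measurements <- asMeasurementFrame(measurements)
  write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}
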