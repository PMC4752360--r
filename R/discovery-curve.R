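#' Cumulative species-discovery curve from a detection log
#'
#' Counts distinct species first detected up to each survey night. With
#' `poolRegions = TRUE` every region's night index starts at 1 on a common
#' time axis and the per-region cumulative counts are summed at each night
#' (regions surveyed on different calendars are thus pooled on the same
#' effort scale).
#'
#' @param log data.frame with columns `region`, `night` (positive
#'   integers), `species`; at most one row per (region, species) -- the
#'   first detection.
#' @param poolRegions sum cumulative counts across regions on a common
#'   night axis?
#' @return data.frame with columns `night` (1..max night) and `nSpecies`
#'   (non-decreasing); with `poolRegions = FALSE`, an additional `region`
#'   column and one block per region. Empty log gives an empty series.
#' @examples
#' log <- data.frame(region = "r", night = c(1, 1, 3),
#'                   species = c("a", "b", "c"))
#' cumulativeCurve(log)
#' @export
cumulativeCurve <- function(log, poolRegions = TRUE) {
  empty <- data.frame(night = integer(0), nSpecies = integer(0))
  if (!nrow(log)) return(empty)
  if (!all(c("region", "night", "species") %in% names(log)))
    stop("log needs region, night and species columns")
  if (any(log$night < 1) || any(log$night != round(log$night)))
    stop("nights must be positive integers")
  if (anyDuplicated(log[c("region", "species")]))
    stop("duplicate first detection for a (region, species) pair")
  perRegion <- lapply(split(log, log$region), function(d) {
    nights <- seq_len(max(d$night))
    data.frame(region = d$region[1], night = nights,
               nSpecies = vapply(nights, function(t)
                 sum(d$night <= t), integer(1)))
  })
  if (!poolRegions) {
    out <- do.call(rbind, perRegion)
    rownames(out) <- NULL
    return(out)
  }
  tmax <- max(log$night)
  nights <- seq_len(tmax)
  total <- vapply(nights, function(t)
    sum(vapply(perRegion, function(d)
      if (t > nrow(d)) d$nSpecies[nrow(d)] else d$nSpecies[t],
      integer(1))), integer(1))
  data.frame(night = nights, nSpecies = total)
}

#' Fit the logistic species-discovery model
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' N(t) = Nspmax / (1 + (t/t50)^b) to a cumulative discovery series.
#' Starting values: Nspmax = max(N), t50 = median night, b = -2; Nspmax is
#' bounded in (0, 10 max(N)]. Fit quality is reported as the Pearson
#' correlation R between observed and fitted counts (R^2 also kept).
#'
#' @param series data.frame from [cumulativeCurve()] (columns `night`,
#'   `nSpecies`), with at least 4 points spanning both sides of the
#'   inflection.
#' @param maxIter optimizer iteration cap.
#' @return a [DiscoveryCurveFit-class].
#' @examples
#' t <- 1:30
#' series <- data.frame(night = t,
#'                      nSpecies = 10.59 / (1 + (t / 3.46)^-2.83))
#' fitLogistic(series)
#' @export
fitLogistic <- function(series, maxIter = 200L) {
  if (!all(c("night", "nSpecies") %in% names(series)))
    stop("series needs night and nSpecies columns")
  if (nrow(series) < 4) stop("need at least 4 points")
  if (length(unique(series$nSpecies)) < 2)
    stop("degenerate flat series")
  maxN <- max(series$nSpecies)
  fit <- minpack.lm::nlsLM(
    nSpecies ~ Nspmax / (1 + (night / t50)^b),
    data = series,
    start = list(Nspmax = maxN, t50 = median(series$night), b = -2),
    lower = c(Nspmax = 1e-8, t50 = 1e-8, b = -Inf),
    upper = c(Nspmax = 10 * maxN, t50 = Inf, b = Inf),
    control = minpack.lm::nls.lm.control(maxiter = maxIter))
  p <- coef(fit)
  fitted <- p["Nspmax"] / (1 + (series$night / p["t50"])^p["b"])
  R <- cor(series$nSpecies, fitted)
  new("DiscoveryCurveFit",
      Nspmax = unname(p["Nspmax"]), t50 = unname(p["t50"]),
      b = unname(p["b"]), fitQuality = R, R2 = R^2,
      data = data.frame(night = series$night,
                        nSpecies = series$nSpecies, fitted = fitted))
}

#' @rdname curveAccessors
#' @name curveAccessors
#' @title Accessors for DiscoveryCurveFit
#' @param x a [DiscoveryCurveFit-class].
#' @return `curveParams`: named numeric (Nspmax, t50, b, R, R2).
#' @export
setMethod("curveParams", "DiscoveryCurveFit", function(x)
  c(Nspmax = x@Nspmax, t50 = x@t50, b = x@b, R = x@fitQuality, R2 = x@R2))

#' Expected fraction of the species pool discovered after t nights
#'
#' Evaluates 1 / (1 + (t/t50)^b), the logistic discovery curve scaled to
#' its asymptote. For b < 0 this is non-decreasing in t, 0 at t -> 0+ and
#' 1 at t -> infinity.
#'
#' @param t survey effort in nights (> 0); vectorized.
#' @param t50 nights to half of the species (> 0).
#' @param b logistic shape (negative for a saturating curve).
#' @return fraction in [0, 1] for b < 0.
#' @examples
#' logisticFraction(20, t50 = 3.46, b = -2.83)   # ~0.993
#' @export
logisticFraction <- function(t, t50, b) {
  if (any(t <= 0)) stop("t must be positive")
  if (t50 <= 0) stop("t50 must be positive")
  1 / (1 + (t / t50)^b)
}
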