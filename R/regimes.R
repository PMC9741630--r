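# Rainfall-regime metrics and attribution: the fixed 90th-percentile
# intensity threshold, annual wet/intense hour fractions, ordinary
# least-squares trends with significance and percent change, and pairwise
# driver correlations on annual series.

#' Fixed rainfall-intensity threshold
#'
#' The 90th percentile (linear-interpolation convention) of hourly rainfall
#' over all rainy hours (P > 0) of the full record, computed once per cell.
#'
#' @param P full-period hourly precipitation
#' @param min_rainy minimum number of rainy hours (default 100)
#' @return p90 in mm h-1
#' @export
rainfall_threshold <- function(P, min_rainy = 100L) {
  rainy <- P[is.finite(P) & P > 0]
  if (length(rainy) < min_rainy)
    stop("too few rainy hours (", length(rainy), " < ", min_rainy,
         "); cell masked")
  unname(stats::quantile(rainy, 0.9, type = 7))
}

#' Annual wet-hour and intense-hour fractions
#'
#' F_rain counts hours with 0 < P < p90; I_rain counts hours with P > p90;
#' both are divided by the year's (non-gap) hour count.
#'
#' @param P hourly precipitation
#' @param year year index aligned with P
#' @param p90 threshold from [rainfall_threshold()]
#' @return data.frame per year: year, F_rain, I_rain, hours
#' @export
annual_fractions <- function(P, year, p90) {
  stopifnot(length(P) == length(year))
  ok <- is.finite(P)
  out <- lapply(split(which(ok), year[ok]), function(idx) {
    p <- P[idx]
    data.frame(F_rain = sum(p > 0 & p < p90) / length(p),
               I_rain = sum(p > p90) / length(p),
               hours = length(p))
  })
  cbind(year = as.integer(names(out)), do.call(rbind, out),
        row.names = NULL)
}

#' Ordinary least-squares trend of an annual series
#'
#' @param annual numeric vector (>= 5 values), one per year
#' @return list: slope (per year), p (two-sided t-test), percent_change
#'   (slope x (n-1) / mean x 100)
#' @export
linear_trend <- function(annual) {
  annual <- annual[is.finite(annual)]
  n <- length(annual)
  if (n < 5) stop("need at least 5 years")
  if (stats::sd(annual) == 0)
    return(list(slope = 0, p = 1, percent_change = 0))
  t <- seq_len(n)
  fit <- stats::lm(annual ~ t)
  sm <- summary(fit)$coefficients
  slope <- unname(sm["t", "Estimate"])
  list(slope = slope, p = unname(sm["t", "Pr(>|t|)"]),
       percent_change = slope * (n - 1) / mean(annual) * 100)
}

#' Pairwise Pearson correlations among annual driver series
#'
#' Raw (non-detrended) annual series; zero-variance series yield NA.
#'
#' @param ... named annual series of equal length (>= 5 years)
#' @return list of matrices r, p, n
#' @export
correlate_drivers <- function(...) {
  vars <- list(...)
  if (is.null(names(vars)) || any(names(vars) == ""))
    stop("series must be named")
  len <- unique(lengths(vars))
  if (length(len) != 1) stop("series must be aligned")
  if (len < 5) stop("need at least 5 years")
  k <- length(vars)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(names(vars),
                                                        names(vars)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cc <- .safe_cor(vars[[i]], vars[[j]])
    r[i, j] <- cc["r"]; p[i, j] <- cc["p"]; n[i, j] <- cc["n"]
  }
  list(r = r, p = p, n = n)
}
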