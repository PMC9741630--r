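# Tower-record ingest and quality control: CSV reading with a column map,
# half-hourly -> hourly aggregation, the standard flux-data filters
# (negative LE, poor-quality flags, freezing hours), IGBP PFT merging,
# LAI site-scaling, the humidity/rain LE bias correction and Bowen-ratio
# energy-balance closure.

.default_columns <- c(timestamp = "timestamp", Ta = "Ta", RH = "RH",
                      VPD = "VPD", Rn = "Rn", G = "G", H = "H", LE = "LE",
                      WS = "WS", P = "P", qc = "qc", LAI = "LAI")

#' Read an hourly or half-hourly tower CSV
#'
#' @param path CSV file
#' @param column_map named character vector mapping internal names
#'   (timestamp, Ta, RH, VPD, Rn, G, H, LE, WS, P, qc, LAI) to the file's
#'   column names; defaults assume the internal names. FLUXNET FULLSET
#'   names can be passed here (e.g. c(LE = "LE_F_MDS", Ta = "TA_F", ...)).
#' @param vpd_unit "kPa" or "hPa" (FLUXNET ships hPa); converted on read
#' @param meta list of site metadata (lat, lon, pft, canopy_height,
#'   tower_height, ec_system)
#' @return site_series data.frame; attribute meta carries the metadata and
#'   half_hourly flag
#' @export
read_site_csv <- function(path, column_map = NULL, vpd_unit = c("kPa", "hPa"),
                          meta = list()) {
  vpd_unit <- match.arg(vpd_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  cmap <- .default_columns
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(names(.default_columns), c("qc", "LAI"))
  missing <- required[!cmap[required] %in% names(raw)]
  if (length(missing))
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  ser <- data.frame(timestamp = raw[[cmap["timestamp"]]])
  for (v in setdiff(names(.default_columns), "timestamp")) {
    ser[[v]] <- if (cmap[v] %in% names(raw)) as.numeric(raw[[cmap[v]]])
                else if (v == "qc") 0 else NA_real_
  }
  if (is.character(ser$timestamp)) {
    ts <- as.POSIXct(ser$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                    "%Y%m%d%H%M"))
    if (any(is.na(ts)))
      stop("unparseable timestamps at rows: ",
           paste(utils::head(which(is.na(ts)), 10), collapse = ", "))
    step_h <- as.numeric(diff(as.numeric(ts))) / 3600
    ser$hod <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
    ser$doy <- as.integer(format(ts, "%j"))
    ser$timestamp <- as.numeric(ts)
  } else {
    step_h <- diff(ser$timestamp)
    ser$hod <- ser$timestamp %% 24
    ser$doy <- (floor(ser$timestamp / 24) %% 365) + 1
  }
  if (any(step_h <= 0)) stop("timestamps must be strictly increasing")
  half_hourly <- length(step_h) > 0 && stats::median(step_h) < 0.75
  if (vpd_unit == "hPa") ser$VPD <- ser$VPD / 10
  if (half_hourly) ser$P <- ser$P  # per-timestep depth kept; summed later
  m <- utils::modifyList(list(lat = NA_real_, lon = NA_real_,
                              pft = NA_character_, canopy_height = NA_real_,
                              tower_height = NA_real_, ec_system = "OP"),
                         meta)
  m$half_hourly <- half_hourly
  attr(ser, "meta") <- m
  class(ser) <- c("site_series", "data.frame")
  ser
}

#' Aggregate a half-hourly series to hourly
#'
#' States and fluxes are averaged, precipitation summed; an hour is valid
#' only when both half-hours are valid (otherwise it becomes a gap), and an
#' odd trailing half-hour is dropped with a warning.
#'
#' @param series half-hourly site_series
#' @return hourly site_series
#' @export
aggregate_to_hourly <- function(series) {
  meta <- attr(series, "meta")
  if (!isTRUE(meta$half_hourly)) stop("series is not half-hourly")
  n <- nrow(series)
  if (n %% 2L == 1L) {
    warning("odd trailing half-hour dropped")
    series <- series[-n, ]
    n <- n - 1L
  }
  idx <- rep(seq_len(n / 2L), each = 2L)
  avg_vars <- c("Ta", "RH", "VPD", "Rn", "G", "H", "LE", "WS")
  out <- data.frame(timestamp = series$timestamp[seq(1, n, by = 2)])
  for (v in avg_vars)
    out[[v]] <- tapply(series[[v]], idx, function(x) mean(x))
  out$P <- as.numeric(tapply(series$P, idx, sum))
  out$qc <- as.numeric(tapply(series$qc, idx, max))
  out$LAI <- as.numeric(tapply(series$LAI, idx, mean))
  out$hod <- floor(series$hod[seq(1, n, by = 2)])
  out$doy <- series$doy[seq(1, n, by = 2)]
  # both-halves rule: any NA half makes the hour a gap
  for (v in c(avg_vars, "P")) out[[v]] <- as.numeric(out[[v]])
  meta$half_hourly <- FALSE
  attr(out, "meta") <- meta
  class(out) <- c("site_series", "data.frame")
  out
}

#' Apply the standard flux-tower quality filters
#'
#' Hours with negative LE, a poor-quality flag, or freezing air temperature
#' (snowfall confound) are masked, not deleted, so event detection keeps
#' the original time axis.
#'
#' @param series site_series
#' @param qc_max largest acceptable QC flag value (larger flags mean
#'   gap-filled/poor data); default 1
#' @return list(series, report): series gains excluded + qc_rule columns;
#'   report tallies removals per rule
#' @export
apply_qc_filters <- function(series, qc_max = 1) {
  n <- nrow(series)
  rule <- rep(NA_character_, n)
  bad_le <- !is.na(series$LE) & series$LE < 0
  bad_qc <- !is.na(series$qc) & series$qc > qc_max
  bad_ta <- !is.na(series$Ta) & series$Ta < 0
  gap <- !stats::complete.cases(series[c("Ta", "VPD", "Rn", "G", "LE", "WS", "P")])
  rule[bad_ta] <- "freezing"
  rule[bad_qc] <- "poor_quality"
  rule[bad_le] <- "negative_LE"   # first-matching order: LE, quality, Ta
  rule[gap] <- "gap"
  series$excluded <- !is.na(rule)
  series$qc_rule <- rule
  report <- list(
    input = n,
    removed = sum(series$excluded),
    retained = n - sum(series$excluded),
    by_rule = table(factor(rule, levels = c("negative_LE", "poor_quality",
                                            "freezing", "gap")))
  )
  list(series = series, report = report)
}

#' Merge the 13 IGBP classes into the eight retained PFTs
#'
#' Woody savanna joins savanna; open and closed shrublands join shrubland.
#'
#' @param raw_pft IGBP code(s)
#' @return pft8 code(s)
#' @export
merge_pft <- function(raw_pft) {
  map <- c(EBF = "EBF", DBF = "DBF", ENF = "ENF", MF = "MF", SAV = "SAV",
           SHU = "SHU", GRA = "GRA", CRO = "CRO",
           WSA = "SAV", OSH = "SHU", CSH = "SHU")
  out <- map[raw_pft]
  if (any(is.na(out)))
    stop("unsupported PFT code(s): ",
         paste(unique(raw_pft[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Scale grid LAI to the site canopy
#'
#' Multiplies the grid-mean LAI by the ratio of site maximum LAI to grid
#' maximum LAI, removing the dilution by non-vegetated surfaces in the grid
#' cell.
#'
#' @param grid_lai LAI series extracted at the site's grid cell
#' @param site_max site maximum LAI (literature/field value)
#' @param grid_max grid-cell maximum LAI; defaults to max(grid_lai)
#' @return scaled LAI series
#' @export
scale_site_lai <- function(grid_lai, site_max, grid_max = max(grid_lai)) {
  if (!is.finite(grid_max) || grid_max <= 0) stop("grid_max must be > 0")
  if (missing(site_max) || !is.finite(site_max))
    stop("site_max missing: supply the nearest same-PFT site's value")
  grid_lai * (site_max / grid_max)
}

#' Correct the humidity/rain-dependent LE underestimation
#'
#' Open- and closed-path systems underestimate LE in humid and rainy hours.
#' A per-site neural network models the latent energy ratio
#' LER = LE/(Rn - G - H) from RH and log-transformed hourly P; every hour's
#' LE is then rescaled so its LER sits at the reference level for RH = 50%
#' and P = 0:
#'   LE_cor = LE x LER_pred at RH = 50, P = 0 / LER_pred .
#'
#' The model is fitted on hours with positive available-energy denominator;
#' prediction (and correction) covers all hours. Hours where the predicted
#' LER is non-positive are flagged and left uncorrected.
#'
#' @param series site_series
#' @param hidden hidden units of the per-site net (default 16)
#' @param p_offset offset inside log(P + offset) admitting P = 0 (mm)
#' @param seed RNG seed for the net fit
#' @return series with LE replaced by the corrected value; columns
#'   LE_raw, ler_factor, ler_flagged added
#' @export
correct_le_humidity_rain <- function(series, hidden = 16L, p_offset = 0.01,
                                     seed = 42L) {
  denom <- series$Rn - series$G - series$H
  fit_ok <- is.finite(denom) & denom > 0 & is.finite(series$LE) &
    is.finite(series$RH) & is.finite(series$P)
  if (sum(fit_ok) < 50L) stop("too few hours with positive available energy")
  df <- data.frame(ler = series$LE[fit_ok] / denom[fit_ok],
                   RH = series$RH[fit_ok],
                   logP = log(series$P[fit_ok] + p_offset))
  # trim absurd ratios from near-zero denominators before fitting
  keep <- is.finite(df$ler) & abs(df$ler) < 5
  df <- df[keep, ]
  mu <- c(RH = mean(df$RH), logP = mean(df$logP))
  sd_ <- c(RH = stats::sd(df$RH), logP = stats::sd(df$logP))
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  df$RHs <- (df$RH - mu["RH"]) / sd_["RH"]
  df$logPs <- (df$logP - mu["logP"]) / sd_["logP"]
  set.seed(seed)
  fit <- nnet::nnet(ler ~ RHs + logPs, data = df, size = hidden,
                    linout = TRUE, decay = 1e-3, maxit = 500, trace = FALSE)
  pred_at <- function(RH, P) {
    nd <- data.frame(RHs = (RH - mu["RH"]) / sd_["RH"],
                     logPs = (log(P + p_offset) - mu["logP"]) / sd_["logP"])
    as.numeric(stats::predict(fit, nd))
  }
  ler_ref <- pred_at(50, 0)
  ler_pred <- pred_at(series$RH, series$P)
  flagged <- !is.finite(ler_pred) | ler_pred <= 0
  factor_ <- ifelse(flagged, 1, ler_ref / ler_pred)
  series$LE_raw <- series$LE
  series$LE <- series$LE * factor_
  series$ler_factor <- factor_
  series$ler_flagged <- flagged
  series
}

#' Bowen-ratio energy-balance closure
#'
#' Redistributes the closure gap so LE + H = Rn - G exactly while keeping
#' the Bowen ratio H/LE: LE_cor = (Rn - G) LE/(LE + H). Hours with
#' LE + H <= 0 are flagged and left unchanged.
#'
#' @param series site_series
#' @return series with LE and H replaced by closed values; bowen_flagged
#'   column added
#' @export
bowen_closure <- function(series) {
  tot <- series$LE + series$H
  ok <- is.finite(tot) & tot > 0 & is.finite(series$Rn) & is.finite(series$G)
  A <- series$Rn - series$G
  le_cor <- ifelse(ok, A * series$LE / tot, series$LE)
  h_cor <- ifelse(ok, A - le_cor, series$H)
  series$LE <- le_cor
  series$H <- h_cor
  series$bowen_flagged <- !ok
  series
}
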