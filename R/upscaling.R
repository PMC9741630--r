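# Gridded application of the trained models: LAI interpolation, dominant
# PFT, the grid-window CWS normalization, vegetated-fraction masking and
# the sub-grid light-rain correction. The grid container is an in-memory
# structure (cell table + per-cell hourly series) with a plain-CSV
# round-trip; each cell is processed with the same event rules as a site.

# default canopy/tower heights per PFT for grid cells (m)
PFT_CANOPY_HEIGHT <- c(EBF = 30, DBF = 25, ENF = 22, MF = 24, SAV = 8,
                       SHU = 2.5, GRA = 0.8, CRO = 1.5)

#' Build a forcing grid
#'
#' @param cells data.frame with cell_id, lat, lon, pft, f_veg (between 0 and 1),
#'   and optionally canopy_height/tower_height (defaulted from the PFT)
#' @param series list of per-cell site_series aligned with cells rows
#' @return forcing_grid object
#' @export
forcing_grid <- function(cells, series) {
  stopifnot(nrow(cells) == length(series))
  if (any(cells$f_veg < 0 | cells$f_veg > 1)) stop("f_veg must lie in [0, 1]")
  if (any(sapply(series, function(s) any(s$P < 0, na.rm = TRUE))))
    stop("P must be non-negative")
  if (is.null(cells$canopy_height))
    cells$canopy_height <- unname(PFT_CANOPY_HEIGHT[cells$pft])
  if (is.null(cells$tower_height))
    cells$tower_height <- cells$canopy_height + pmax(0.3 * cells$canopy_height, 2)
  structure(list(cells = cells, series = series), class = "forcing_grid")
}

#' Single-cell grid built from one site series
#'
#' @param series a site_series (meta supplies lat and heights)
#' @param f_veg vegetated fraction of the cell
#' @return forcing_grid with one cell
#' @export
grid_from_site <- function(series, f_veg = 1) {
  meta <- attr(series, "meta")
  cells <- data.frame(cell_id = 1L, lat = meta$lat, lon = meta$lon,
                      pft = meta$pft, f_veg = f_veg,
                      canopy_height = meta$canopy_height,
                      tower_height = meta$tower_height)
  forcing_grid(cells, list(series))
}

#' Interpolate 8-day LAI composites to hourly
#'
#' Cubic smoothing spline through the composite points, evaluated at every
#' hour and clipped at zero. A constant composite stays constant.
#'
#' @param lai_8day composite LAI values (>= 4 points)
#' @param doy_8day composite timestamps (days)
#' @param hours_day hourly evaluation times in days
#' @return hourly LAI series
#' @export
interpolate_lai <- function(lai_8day, doy_8day, hours_day) {
  ok <- is.finite(lai_8day)
  if (!any(ok)) stop("all LAI composites missing")
  if (sum(ok) < 4) stop("need at least 4 composite points")
  y <- lai_8day[ok]; x <- doy_8day[ok]
  if (stats::sd(y) < 1e-12) return(rep(y[1], length(hours_day)))
  sp <- stats::smooth.spline(x, y, cv = FALSE)
  pmax(stats::predict(sp, hours_day)$y, 0)
}

#' Dominant PFT of a grid cell
#'
#' IGBP cover fractions are merged to the eight retained classes and the
#' largest wins; ties break by the fixed PFT order.
#'
#' @param fractions named numeric vector of IGBP cover fractions (sum <= 1)
#' @return pft8 code, or NA with an unvegetated attribute when all zero
#' @export
dominant_pft <- function(fractions) {
  if (sum(fractions) > 1 + 1e-9) stop("cover fractions must sum to <= 1")
  merged <- stats::setNames(numeric(length(PFT8)), PFT8)
  for (nm in names(fractions)) {
    tgt <- merge_pft(nm)
    merged[tgt] <- merged[tgt] + fractions[[nm]]
  }
  if (all(merged == 0)) return(structure(NA_character_, unvegetated = TRUE))
  PFT8[which.max(merged)]   # which.max takes the first maximum: fixed order
}

#' Light-rain interception for sub-event drizzle
#'
#' Outside detected events, hours with 0 < P < 0.5 mm still intercept.
#' The Ei/P ratio is linearly interpolated between the vegetated fraction
#' (the P -> 0 limit: all rain over canopy is intercepted) and the per-PFT
#' mean ratio of light events anchored at P = 0.6 mm:
#'   ratio(P) = f_veg + (ratio_at_0p6 - f_veg) P/0.6 .
#'
#' @param P rainfall amount (mm), must satisfy 0 < P < 0.5
#' @param f_veg vegetated fraction
#' @param ratio_at_0p6 per-PFT anchor ratio at P = 0.6 mm
#' @return Ei in mm
#' @export
light_rain_correction <- function(P, f_veg, ratio_at_0p6) {
  if (any(P <= 0 | P >= 0.5))
    stop("light-rain correction applies to 0 < P < 0.5 mm only")
  ratio <- f_veg + (ratio_at_0p6 - f_veg) * (P / 0.6)
  ratio * P
}

#' Per-PFT anchor ratio for the light-rain correction
#'
#' Mean event Ei/P over events whose mean hourly P lies between 0.5 and 0.7 mm
#' (the 0.6 mm anchor, widened for sample size).
#'
#' @param events event table from [aggregate_events()]
#' @return named vector of ratios per PFT (NA where no such events)
#' @export
light_rain_anchor <- function(events) {
  sel <- events$mean_hourly_P >= 0.5 & events$mean_hourly_P <= 0.7 &
    is.finite(events$ratio)
  out <- stats::setNames(rep(NA_real_, length(PFT8)), PFT8)
  if (any(sel)) {
    m <- tapply(events$ratio[sel], factor(events$pft[sel], levels = PFT8),
                mean)
    out[names(m)] <- m
  }
  out
}

#' Grid-window CWS normalization statistics
#'
#' The site-trained HM_wet standardizes CWS with site statistics; gridded
#' CWS is on a different scale, so grid predictions standardize it with the
#' mean/SD of CWS predicted over grid cells within a window around the site
#' locations, mapped back into the site-CWS space.
#'
#' @param grid forcing_grid
#' @param cws_model trained CWS net
#' @param site_locs data.frame with lat, lon of the training sites
#' @param window half-width sum (degrees) of the selection box (5 means a
#'   5 x 5 degree window)
#' @return list(mean, sd) of grid CWS over the selected cells
#' @export
cws_window_stats <- function(grid, cws_model, site_locs, window = 5) {
  half <- window / 2
  near <- sapply(seq_len(nrow(grid$cells)), function(i) {
    any(abs(grid$cells$lat[i] - site_locs$lat) <= half &
          abs(grid$cells$lon[i] - site_locs$lon) <= half)
  })
  if (!any(near)) stop("no grid cells fall inside the site windows")
  vals <- unlist(lapply(which(near), function(i) {
    cw <- .cell_cws(grid, i, cws_model)
    cw$cws
  }))
  if (!length(vals)) stop("no wet cell-hours near the sites")
  s <- stats::sd(vals)
  list(mean = mean(vals), sd = if (is.finite(s) && s > 0) s else 1)
}

# detect events in one cell and predict its raw CWS series
.cell_cws <- function(grid, i, cws_model) {
  ser <- grid$series[[i]]
  night <- if (!is.null(ser$night)) ser$night else
    solar_elevation(grid$cells$lat[i], ser$doy, ser$hod) < 0
  events <- detect_events(ser$P, night)
  if (!length(events))
    return(list(events = events, descr = NULL, cws = numeric(0)))
  descr <- event_descriptor_table(events, ser$P, ser$hod)
  descr$LAI <- ser$LAI[descr$hour_idx]
  descr$pft <- grid$cells$pft[i]
  list(events = events, descr = descr,
       cws = predict_cws(cws_model, descr))
}

#' Predict gridded interception loss
#'
#' Runs the site-level machinery per cell: event detection on the cell's P
#' series, rainfall descriptors, CWS prediction (standardized with the
#' grid-window statistics when supplied), HM_wet minus HM_dry on wet
#' cell-hours, masking by vegetated fraction, and the light-rain correction
#' for non-event drizzle when an anchor table is supplied.
#'
#' @param hm_wet,hm_dry trained hybrid models
#' @param cws_model trained CWS net
#' @param grid forcing_grid
#' @param cws_stats optional list(mean, sd) from [cws_window_stats()]
#' @param anchors optional per-PFT light-rain anchor ([light_rain_anchor()])
#' @return list of per-cell data.frames (hour_idx, P, Ei mm, source)
#' @export
predict_grid_ei <- function(hm_wet, hm_dry, cws_model, grid,
                            cws_stats = NULL, anchors = NULL) {
  site_mu <- hm_wet$stats$mean["CWS"]
  site_sd <- hm_wet$stats$sd["CWS"]
  lapply(seq_len(nrow(grid$cells)), function(i) {
    ser <- grid$series[[i]]
    f_veg <- grid$cells$f_veg[i]
    out <- data.frame(hour_idx = seq_len(nrow(ser)), P = ser$P,
                      Ei = 0, source = "none")
    cc <- .cell_cws(grid, i, cws_model)
    if (!is.null(cc$descr)) {
      cws <- cc$cws
      if (!is.null(cws_stats))  # map grid CWS into the site-CWS space
        cws <- site_mu + site_sd * (cws - cws_stats$mean) / cws_stats$sd
      ra <- aerodynamic_resistance(ser$WS, grid$cells$tower_height[i],
                                   grid$cells$canopy_height[i])
      samples <- data.frame(hour_idx = seq_len(nrow(ser)), Ta = ser$Ta,
                            VPD = ser$VPD, Rn = ser$Rn, WS = ser$WS,
                            LAI = ser$LAI, A = ser$Rn - ser$G, ra = ra,
                            pft = grid$cells$pft[i])
      wet <- samples[cc$descr$hour_idx, , drop = FALSE]
      wet$CWS <- cws
      le_wet <- predict_le(hm_wet, wet)
      le_dry <- predict_le(hm_dry, wet)
      d <- le_wet - le_dry
      ei <- ifelse(is.finite(d) & d > 0, energy_to_depth(d, wet$Ta), 0)
      out$Ei[cc$descr$hour_idx] <- ei * f_veg
      out$source[cc$descr$hour_idx] <- "event"
    }
    if (!is.null(anchors)) {
      anchor <- anchors[[grid$cells$pft[i]]]
      light <- out$source == "none" & ser$P > 0 & ser$P < 0.5
      if (is.finite(anchor) && any(light)) {
        out$Ei[light] <- light_rain_correction(ser$P[light], f_veg, anchor)
        out$source[light] <- "light_rain"
      }
    }
    out
  })
}
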