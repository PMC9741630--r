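# Hourly and event-level interception-loss estimates and the event-level
# driver analysis (rational fits against rainfall metrics, linear fits
# against LAI and wind speed).

#' Hourly interception-evaporation estimate
#'
#' E_i energy = LE(HM_wet) - LE(HM_dry) on identical wet-hour forcing;
#' negative differences (measurement noise) are removed, not zeroed; the
#' remainder is converted to depth with the latent heat of vaporization.
#'
#' @param hm_wet,hm_dry trained hybrid models
#' @param wet_samples data.frame of wet hours (from [build_samples()])
#' @param cws_model trained [train_cws_net()] model
#' @param descriptors descriptor rows aligned with wet_samples
#' @return data.frame: hour_idx, event_id, P, LE_wet_hat, LE_dry_hat,
#'   Ei_energy (W m-2), Ei (mm h-1), kept flag
#' @export
estimate_ei_hourly <- function(hm_wet, hm_dry, wet_samples, cws_model,
                               descriptors) {
  stopifnot(nrow(wet_samples) == nrow(descriptors))
  cws <- predict_cws(cws_model, descriptors)
  bad <- !is.finite(cws)
  ws <- wet_samples
  ws$CWS <- cws
  le_wet <- predict_le(hm_wet, ws)
  le_dry <- predict_le(hm_dry, ws)
  diff <- le_wet - le_dry
  kept <- !bad & is.finite(diff) & diff >= 0
  data.frame(hour_idx = ws$hour_idx, event_id = descriptors$event_id,
             P = ws$P, Ta = ws$Ta,
             LE_wet_hat = le_wet, LE_dry_hat = le_dry,
             Ei_energy = diff,
             Ei = ifelse(kept, energy_to_depth(diff, ws$Ta), NA_real_),
             kept = kept)
}

#' Aggregate hourly estimates to one rain event
#'
#' @param ei_hours output of [estimate_ei_hourly()] (any events)
#' @param event a rain_event
#' @return one-row data.frame: event id, duration, P (mm), Ei (mm), ratio
#'   Ei/P, n_skipped, low_confidence flag (> 20% of hours skipped)
#' @export
aggregate_event <- function(ei_hours, event) {
  rows <- ei_hours[ei_hours$event_id == event$id, , drop = FALSE]
  n_hours <- event$end_idx - event$start_idx + 1L
  skipped <- n_hours - sum(rows$kept)
  ei <- sum(rows$Ei[rows$kept])
  p <- event$total_P
  data.frame(event_id = event$id, duration_h = n_hours, P = p, Ei = ei,
             ratio = if (p > 0) ei / p else NA_real_,
             n_skipped = skipped,
             low_confidence = skipped > 0.2 * n_hours)
}

#' Event table with driver covariates
#'
#' @param ei_hours hourly estimates
#' @param events list of rain_event
#' @param samples site samples (for LAI/WS/pft covariates)
#' @return data.frame, one row per event, with max/mean hourly P, event-mean
#'   LAI and WS, and pft
#' @export
aggregate_events <- function(ei_hours, events, samples) {
  rows <- lapply(events, function(ev) {
    r <- aggregate_event(ei_hours, ev)
    hrs <- ev$start_idx:ev$end_idx
    sub <- samples[samples$hour_idx %in% hrs, , drop = FALSE]
    rain <- sub$P[sub$P > 0]
    r$max_hourly_P <- if (length(rain)) max(rain) else 0
    r$mean_hourly_P <- if (length(rain)) mean(rain) else 0
    r$LAI <- mean(sub$LAI)
    r$WS <- mean(sub$WS)
    r$pft <- sub$pft[1]
    r
  })
  do.call(rbind, rows)
}

.fit_rational <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  q0 <- stats::median(x)
  p0 <- stats::median(y) * (q0 + q0)
  fit <- try(minpack.lm::nlsLM(y ~ p / (x + q),
                               start = list(p = p0, q = q0),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(converged = FALSE, p = NA_real_, q = NA_real_))
  co <- stats::coef(fit)
  list(converged = TRUE, p = unname(co["p"]), q = unname(co["q"]),
       fitted = function(xx) co["p"] / (xx + co["q"]))
}

.fit_linear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  fit <- stats::lm(y ~ x, data = data.frame(x = x[ok], y = y[ok]))
  co <- stats::coef(fit)
  list(converged = TRUE, a = unname(co[1]), b = unname(co[2]))
}

.safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(x[ok], y[ok])
  c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Event-level driver analysis of the Ei/P ratio
#'
#' The ratio against the three rainfall metrics (event total P, maximum and
#' mean hourly P) is fitted with a rational curve ratio = p/(x + q); the
#' ratio against LAI and wind speed with a straight line. Pearson
#' correlations (two-sided) are reported pooled and per PFT.
#'
#' @param events event table from [aggregate_events()] (>= 30 events)
#' @return list with fits (per driver) and correlations (pooled, by_pft)
#' @export
driver_analysis <- function(events) {
  ev <- events[is.finite(events$ratio) & !events$low_confidence, , drop = FALSE]
  if (nrow(ev) < 30) stop("need at least 30 usable events")
  rational_vars <- c(total_P = "P", max_hourly_P = "max_hourly_P",
                     mean_hourly_P = "mean_hourly_P")
  linear_vars <- c(LAI = "LAI", WS = "WS")
  fits <- c(
    lapply(rational_vars, function(v) .fit_rational(ev[[v]], ev$ratio)),
    lapply(linear_vars, function(v) .fit_linear(ev[[v]], ev$ratio)))
  all_vars <- c(rational_vars, linear_vars)
  pooled <- t(sapply(all_vars, function(v) .safe_cor(ev[[v]], ev$ratio)))
  by_pft <- lapply(split(ev, ev$pft), function(sub)
    t(sapply(all_vars, function(v) .safe_cor(sub[[v]], sub$ratio))))
  list(fits = fits, correlations = list(pooled = pooled, by_pft = by_pft),
       n_events = nrow(ev))
}
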