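# Synthetic flux-tower generator: diurnal/seasonal meteorology, stochastic
# rain events, a prescribed Jarvis-style dry-canopy surface resistance, and
# an additive interception flux from a Rutter-type canopy water bucket.
# Its role is to provide a site series with a known interception ground
# truth so the whole inference chain can be tested end to end.

#' The eight retained plant functional types
#' @export
PFT8 <- c("EBF", "DBF", "ENF", "MF", "SAV", "SHU", "GRA", "CRO")

#' Configuration for the synthetic site generator
#'
#' @param n_years number of simulated years
#' @param lat site latitude (degrees)
#' @param pft one of the eight PFT codes
#' @param lai_range seasonal (min, max) LAI, m2 m-2
#' @param canopy_height,tower_height m
#' @param rain_event_rate mean rain-event arrivals per day (Poisson)
#' @param mean_event_hours mean rainy-spell duration, h (geometric)
#' @param intensity_shape,intensity_scale gamma parameters of hourly rain
#'   intensity, mm h-1
#' @param free_throughfall fraction of rain bypassing the canopy (1 - the
#'   interception efficiency)
#' @param storage_per_lai canopy storage capacity per unit LAI, mm
#' @param ta_mean,ta_seasonal_amp,ta_diurnal_amp air-temperature climate, degC
#' @param rn_max clear-sky noon net radiation scale, W m-2
#' @param noise_sd SD of additive Gaussian observation noise on LE, W m-2
#' @param seed integer; fixes the full output bit-for-bit
#' @return object of class synth_config
#' @export
synth_config <- function(n_years = 1L, lat = 45, pft = "DBF",
                         lai_range = c(1, 5), canopy_height = 15,
                         tower_height = 25, rain_event_rate = 0.5,
                         mean_event_hours = 4, intensity_shape = 1.2,
                         intensity_scale = 1.5, free_throughfall = 0.3,
                         storage_per_lai = 0.2, ta_mean = 18,
                         ta_seasonal_amp = 6, ta_diurnal_amp = 5,
                         rn_max = 700, noise_sd = 10, seed = 1L) {
  cfg <- list(n_years = as.integer(n_years), lat = lat, pft = pft,
              lai_range = lai_range, canopy_height = canopy_height,
              tower_height = tower_height, rain_event_rate = rain_event_rate,
              mean_event_hours = mean_event_hours,
              intensity_shape = intensity_shape,
              intensity_scale = intensity_scale,
              free_throughfall = free_throughfall,
              storage_per_lai = storage_per_lai, ta_mean = ta_mean,
              ta_seasonal_amp = ta_seasonal_amp,
              ta_diurnal_amp = ta_diurnal_amp, rn_max = rn_max,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$n_years < 1L) stop("n_years must be >= 1")
  if (!pft %in% PFT8) stop("pft must be one of: ", paste(PFT8, collapse = ", "))
  if (rain_event_rate < 0) stop("rain_event_rate must be >= 0")
  if (mean_event_hours < 1) stop("mean_event_hours must be >= 1")
  if (intensity_shape <= 0 || intensity_scale <= 0)
    stop("gamma intensity parameters must be > 0")
  if (storage_per_lai <= 0) stop("storage_per_lai must be > 0")
  if (free_throughfall < 0 || free_throughfall >= 1)
    stop("free_throughfall must lie in [0, 1)")
  if (lai_range[1] > lai_range[2] || lai_range[1] < 0)
    stop("lai_range must satisfy 0 <= min <= max")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (tower_height <= canopy_height) stop("tower must stand above the canopy")
  class(cfg) <- "synth_config"
  cfg
}

#' Solar elevation angle
#'
#' Declination from the day-of-year sinusoid; hour angle from local solar
#' time. Used for the night mask and the radiation arc.
#'
#' @param lat degrees
#' @param doy day of year (1-365)
#' @param hour local solar hour (0-23), hour centre used
#' @return elevation in degrees
#' @export
solar_elevation <- function(lat, doy, hour) {
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365)
  ha <- 15 * (hour + 0.5 - 12)                 # hour centre
  rad <- pi / 180
  sin_el <- sin(lat * rad) * sin(decl * rad) +
    cos(lat * rad) * cos(decl * rad) * cos(ha * rad)
  asin(pmin(pmax(sin_el, -1), 1)) / rad
}

# Poisson event arrivals, geometric rainy-spell durations, gamma hourly
# intensities. Returns the hourly P vector (overlapping spells add).
.simulate_rain <- function(n_hours, cfg) {
  P <- numeric(n_hours)
  if (cfg$rain_event_rate <= 0) return(P)
  rate_h <- cfg$rain_event_rate / 24
  n_ev <- rpois(1L, rate_h * n_hours)
  if (n_ev == 0L) return(P)
  starts <- sort(sample.int(n_hours, n_ev, replace = TRUE))
  durs <- rgeom(n_ev, prob = 1 / cfg$mean_event_hours) + 1L
  for (i in seq_len(n_ev)) {
    hrs <- starts[i]:min(starts[i] + durs[i] - 1L, n_hours)
    P[hrs] <- P[hrs] +
      rgamma(length(hrs), shape = cfg$intensity_shape,
             scale = cfg$intensity_scale)
  }
  P
}

#' Generate synthetic hourly tower forcing
#'
#' Diurnal + seasonal sinusoidal temperature with AR noise, solar-arc net
#' radiation damped during rain, relative humidity elevated in and around
#' rain with VPD kept consistent (VPD = esat(Ta) (1 - RH/100)), positive
#' wind speed, G = 0.1 Rn, and stochastic rainfall.
#'
#' @param config a [synth_config()]
#' @return site_series data.frame (no fluxes yet; see
#'   [generate_truth_fluxes()])
#' @export
generate_forcing <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_years * 365L * 24L
  doy <- rep(rep(1:365, each = 24), config$n_years)
  hod <- rep(0:23, 365L * config$n_years)
  elev <- solar_elevation(config$lat, doy, hod)
  night <- elev < 0

  P <- .simulate_rain(n, config)
  raining <- P > 0
  # wet spells keep the following hours humid too
  humid <- raining
  for (k in 1:3) humid <- humid | c(rep(FALSE, k), raining[seq_len(n - k)])

  seas <- sin(2 * pi * (doy - 105) / 365) * ifelse(config$lat >= 0, 1, -1)
  diur <- -cos(2 * pi * (hod + 0.5 - 14) / 24)
  ar <- stats::filter(rnorm(n, sd = 0.6), 0.8, method = "recursive")
  Ta <- config$ta_mean + config$ta_seasonal_amp * seas +
    config$ta_diurnal_amp * diur + as.numeric(ar)

  # per-day synoptic cloudiness so overcast dry days exist, as at real sites
  cloud_day <- rep(rbeta(365L * config$n_years, 2, 5) * 0.7, each = 24L)
  cloud <- pmax(cloud_day, ifelse(raining, 0.75, ifelse(humid, 0.5, 0)))
  Rn_day <- config$rn_max * pmax(sin(elev * pi / 180), 0) *
    (1 + 0.25 * seas) * (1 - cloud)
  Rn <- ifelse(night, 0, Rn_day)

  # diurnal humidity cycle approaching saturation before dawn
  RH <- 68 + 22 * cos(2 * pi * (hod - 5) / 24) + 15 * cloud_day +
    rnorm(n, sd = 5)
  RH[humid] <- 92 + runif(sum(humid), 0, 8)
  RH <- pmin(pmax(RH, 5), 100)
  VPD <- esat_curve(Ta)$esat * (1 - RH / 100)

  WS <- pmax(exp(rnorm(n, log(2.5), 0.4)), 0.2)
  G <- 0.1 * Rn
  LAI <- config$lai_range[1] + diff(config$lai_range) *
    pmax(sin(2 * pi * (doy - 105) / 365) * ifelse(config$lat >= 0, 1, -1), 0)

  ser <- data.frame(
    timestamp = seq_len(n), doy = doy, hod = hod,
    Ta = Ta, RH = RH, VPD = VPD, Rn = Rn, G = G,
    H = NA_real_, LE = NA_real_, WS = WS, P = P, qc = 0L,
    LAI = LAI, night = night
  )
  attr(ser, "meta") <- list(lat = config$lat, lon = 0, pft = config$pft,
                            canopy_height = config$canopy_height,
                            tower_height = config$tower_height,
                            ec_system = "OP", half_hourly = FALSE)
  class(ser) <- c("site_series", "data.frame")
  ser
}

#' Prescribed dry-canopy surface resistance (Jarvis-style)
#'
#' A smooth, monotone law in VPD, radiation and LAI used as the generator's
#' ground truth; the hybrid model has to recover it from data.
#'
#' @param VPD kPa
#' @param Rn W m-2
#' @param LAI m2 m-2
#' @return Rs in s m-1
#' @export
rs_dry_law <- function(VPD, Rn, LAI) {
  40 * (1 + 0.8 * VPD) * (1 + 600 / (Rn + 120)) / sqrt(pmax(LAI, 0.3))
}

#' Add flux truth: dry baseline, canopy bucket, observed LE
#'
#' The canopy bucket has capacity S = storage_per_lai x LAI. Each hour the
#' canopy intercepts min(S - C, (1 - free_throughfall) P). Evaporation is
#' generated on the Penman-Monteith manifold: the canopy's effective
#' surface resistance is the dry-law resistance scaled by the dry fraction,
#' Rs_eff = Rs_dry (1 - C/S) (a fully wet canopy evaporates at the Rs = 0
#' potential rate), and the interception flux is the wet-minus-dry
#' difference Ei = min(C, pm_forward(Rs_eff) - pm_forward(Rs_dry)) in
#' depth units. Observed LE is the dry baseline plus the interception flux
#' plus Gaussian noise, and H closes the energy balance up to that noise.
#' Composing the truth this way keeps every observation physically
#' reachable by a resistor-form model while preserving the additive
#' subtraction identity (LE = dry baseline + interception energy) that the
#' inference exploits.
#'
#' @param forcing output of [generate_forcing()]
#' @param config the same [synth_config()]
#' @return list(series, truth): series is the forcing with LE/H filled;
#'   truth holds LE_dry_true, Ei_true (mm h-1), store C and capacity S
#' @export
generate_truth_fluxes <- function(forcing, config) {
  stopifnot(inherits(forcing, "site_series"))
  need <- c("Ta", "VPD", "Rn", "G", "WS", "P", "LAI")
  gaps <- which(!stats::complete.cases(forcing[need]))
  if (length(gaps))
    stop("forcing gaps at hours: ", paste(utils::head(gaps, 10), collapse = ", "))
  set.seed(config$seed + 1000L)
  n <- nrow(forcing)
  ra <- aerodynamic_resistance(forcing$WS, config$tower_height,
                               config$canopy_height)
  st <- pm_state(forcing$Ta, forcing$VPD, forcing$Rn - forcing$G, ra)
  rs_dry <- rs_dry_law(forcing$VPD, forcing$Rn, forcing$LAI)
  le_dry <- pmax(pm_forward(rs_dry, st), 0)

  # per-hour quadratic coefficients, inlined so the bucket loop stays cheap
  rc <- st$rho * .cp
  k_a <- rc * st$curv / (2 * st$gamma)
  k_b0 <- rc / st$ra
  k_b1 <- rc * st$delta / st$gamma
  k_c1 <- rc * st$VPD / st$gamma
  A <- st$A
  lam <- st$lambda
  pm_le <- function(h, rs) {
    x <- st$ra[h] + rs
    a <- k_a[h] / x; b <- k_b0[h] + k_b1[h] / x; cc <- k_c1[h] / x - A[h]
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(0)
    A[h] - k_b0[h] * (-2 * cc / (b + sqrt(disc)))
  }

  S <- config$storage_per_lai * forcing$LAI
  eff <- 1 - config$free_throughfall
  C <- numeric(n + 1L)
  Ei <- numeric(n)
  for (h in seq_len(n)) {
    c_h <- min(C[h] + min(S[h] - C[h], eff * forcing$P[h]), S[h])
    if (c_h > 0 && S[h] > 0) {
      w <- c_h / S[h]
      le_wet <- pm_le(h, rs_dry[h] * (1 - w))
      pot_mm <- max(le_wet - le_dry[h], 0) * 3600 / lam[h]
      Ei[h] <- min(c_h, pot_mm)
    }
    C[h + 1L] <- c_h - Ei[h]
  }
  ei_energy <- depth_to_energy(Ei, forcing$Ta)
  noise <- rnorm(n, sd = config$noise_sd)
  series <- forcing
  series$LE <- le_dry + ei_energy + noise
  series$H <- forcing$Rn - forcing$G - le_dry - ei_energy
  truth <- data.frame(LE_dry_true = le_dry, Ei_true = Ei,
                      C = C[-1L], S = S, noise = noise)
  list(series = series, truth = truth)
}

#' Generate a complete synthetic site (forcing + fluxes + truth)
#'
#' @param config a [synth_config()]
#' @return list(series, truth) as in [generate_truth_fluxes()]
#' @export
generate_site <- function(config) {
  generate_truth_fluxes(generate_forcing(config), config)
}
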