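# Physical constants used throughout (SI unless noted)
.cp    <- 1013      # specific heat of air, J kg-1 K-1
.Pa    <- 101.325   # air pressure, kPa (site pressure not among tower inputs)
.kappa <- 0.41      # von Karman
.Rd    <- 287.05    # dry-air gas constant, J kg-1 K-1

#' Latent heat of vaporization
#'
#' @param Ta air temperature (degC)
#' @return lambda in J kg-1
#' @export
latent_heat <- function(Ta) (2.501 - 0.002361 * Ta) * 1e6

#' Psychrometric constant
#'
#' @param Ta air temperature (degC)
#' @return gamma in kPa K-1
#' @export
psychrometric_gamma <- function(Ta) .cp * .Pa / (0.622 * latent_heat(Ta))

#' Saturation vapor pressure curve and its first two derivatives
#'
#' Tetens form esat = 0.6108 exp(17.27 Ta / (Ta + 237.3)). The second
#' derivative is what makes the Penman-Monteith operator "quadratic": the
#' saturation curve is expanded to second order about air temperature rather
#' than linearized.
#'
#' @param Ta air temperature (degC), must lie in -40..60
#' @return list with esat (kPa), delta (kPa K-1), curv (kPa K-2)
#' @export
esat_curve <- function(Ta) {
  if (any(!is.finite(Ta)) || any(Ta < -40 | Ta > 60))
    stop("Ta out of supported range [-40, 60] degC")
  u <- 17.27 * Ta / (Ta + 237.3)
  esat <- 0.6108 * exp(u)
  # d/dTa [17.27 Ta/(Ta+237.3)] = 17.27*237.3/(Ta+237.3)^2
  up <- 17.27 * 237.3 / (Ta + 237.3)^2
  upp <- -2 * 17.27 * 237.3 / (Ta + 237.3)^3
  delta <- esat * up
  curv <- esat * (up^2 + upp)
  list(esat = esat, delta = delta, curv = curv)
}

#' Aerodynamic resistance from the neutral logarithmic wind profile
#'
#' d = 0.67 h, z0m = 0.123 h, z0h = 0.1 z0m. Wind speed is floored at
#' 0.5 m s-1 to avoid resistance blow-up in calm hours.
#'
#' @param WS wind speed (m s-1)
#' @param tower_height measurement height z (m)
#' @param canopy_height canopy height h (m)
#' @return ra in s m-1
#' @export
aerodynamic_resistance <- function(WS, tower_height, canopy_height) {
  if (any(canopy_height <= 0) || any(tower_height <= canopy_height))
    stop("require tower_height > canopy_height > 0")
  d <- 0.67 * canopy_height
  z0m <- 0.123 * canopy_height
  z0h <- 0.1 * z0m
  if (any(tower_height <= d)) stop("tower height below displacement height")
  ws <- pmax(WS, 0.5)
  log((tower_height - d) / z0m) * log((tower_height - d) / z0h) /
    (.kappa^2 * ws)
}

#' Assemble the Penman-Monteith state for one or more hours
#'
#' @param Ta air temperature (degC)
#' @param VPD vapor pressure deficit (kPa)
#' @param A available energy Rn - G (W m-2)
#' @param ra aerodynamic resistance (s m-1)
#' @return data.frame of class pm_state with psychrometrics attached
#' @export
pm_state <- function(Ta, VPD, A, ra) {
  if (any(ra <= 0)) stop("ra must be positive")
  sat <- esat_curve(Ta)
  st <- data.frame(
    Ta = Ta, VPD = VPD, A = A, ra = ra,
    esat = sat$esat, delta = sat$delta, curv = sat$curv,
    gamma = psychrometric_gamma(Ta),
    rho = .Pa * 1000 / (.Rd * (Ta + 273.15)),
    lambda = latent_heat(Ta)
  )
  class(st) <- c("pm_state", "data.frame")
  st
}

#' Quadratic Penman-Monteith forward operator
#'
#' Solves the coupled surface energy balance
#'   H  = rho cp dT / ra
#'   LE = (rho cp / gamma) (VPD + delta dT + 0.5 k dT^2) / (ra + Rs)
#'   A  = H + LE
#' for the surface-air temperature difference dT, keeping the saturation
#' curve to second order (curvature k). The root is the one continuous with
#' the classical (k = 0) Penman-Monteith solution.
#'
#' @param Rs surface resistance (s m-1), scalar or vector
#' @param state pm_state
#' @return LE in W m-2 (NA where no physical root exists)
#' @export
pm_forward <- function(Rs, state) {
  if (any(Rs < 0, na.rm = TRUE)) stop("Rs must be non-negative")
  rc <- state$rho * .cp
  x <- state$ra + Rs
  a <- rc * state$curv / (2 * state$gamma * x)
  b <- rc / state$ra + rc * state$delta / (state$gamma * x)
  cc <- rc * state$VPD / (state$gamma * x) - state$A
  disc <- b^2 - 4 * a * cc
  bad <- disc < 0
  disc[bad] <- 0
  # stable form of (-b + sqrt(disc)) / (2a); reduces to -c/b as k -> 0
  dT <- -2 * cc / (b + sqrt(disc))
  le <- state$A - rc * dT / state$ra
  le[bad] <- NA_real_
  le
}

#' Derivative of the forward operator with respect to surface resistance
#'
#' Implicit differentiation of the quadratic; used by the physics-constrained
#' training loss. Strictly negative wherever LE > 0.
#'
#' @inheritParams pm_forward
#' @return dLE/dRs in W m-2 per s m-1
#' @export
pm_forward_dRs <- function(Rs, state) {
  rc <- state$rho * .cp
  x <- state$ra + Rs
  a <- rc * state$curv / (2 * state$gamma * x)
  b <- rc / state$ra + rc * state$delta / (state$gamma * x)
  cc <- rc * state$VPD / (state$gamma * x) - state$A
  disc <- b^2 - 4 * a * cc
  bad <- disc < 0
  disc[bad] <- 0
  s <- sqrt(disc)
  dT <- -2 * cc / (b + s)
  le <- state$A - rc * dT / state$ra
  out <- -(rc / state$ra) * le / (x * pmax(s, 1e-12))
  out[bad] <- NA_real_
  out
}

#' Invert the quadratic Penman-Monteith equation for surface resistance
#'
#' Closed-form inversion: the energy balance fixes dT = (A - LE) ra/(rho cp),
#' the second-order saturation expansion gives the surface vapor pressure,
#' and the diffusion equation is solved for Rs.
#'
#' @param LE latent heat flux (W m-2), must be > 0 for a defined inversion
#' @param state pm_state
#' @return data.frame with Rs (clipped at 0), Rs_raw (unclipped), and
#'   defined (FALSE where the surface-air vapor gradient is non-positive)
#' @export
pm_invert <- function(LE, state) {
  rc <- state$rho * .cp
  dT <- (state$A - LE) * state$ra / rc
  es_surf <- state$esat + state$delta * dT + 0.5 * state$curv * dT^2
  ea <- state$esat - state$VPD
  grad <- es_surf - ea
  defined <- is.finite(LE) & LE > 0 & grad > 0
  rs_raw <- rc * grad / (state$gamma * LE) - state$ra
  rs_raw[!defined] <- NA_real_
  data.frame(Rs = pmax(rs_raw, 0), Rs_raw = rs_raw, defined = defined)
}

#' Classical Penman-Monteith (linearized saturation curve)
#'
#' The k = 0 limit of [pm_forward()]; kept as an independent closed form.
#'
#' @inheritParams pm_forward
#' @return LE in W m-2
#' @export
pm_classical <- function(Rs, state) {
  rc <- state$rho * .cp
  (state$delta * state$A + rc * state$VPD / state$ra) /
    (state$delta + state$gamma * (1 + Rs / state$ra))
}

#' Convert latent heat flux to water depth per hour
#'
#' @param LE latent heat flux (W m-2)
#' @param Ta air temperature (degC), sets lambda
#' @return depth in mm h-1
#' @export
energy_to_depth <- function(LE, Ta) LE * 3600 / latent_heat(Ta)

#' Convert water depth per hour to latent heat flux
#'
#' @param depth mm h-1
#' @param Ta air temperature (degC)
#' @return LE in W m-2
#' @export
depth_to_energy <- function(depth, Ta) depth * latent_heat(Ta) / 3600
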