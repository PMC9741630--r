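test_that("LAI spline interpolation is faithful on composites", {
  x8 <- seq(1, 361, by = 8)
  # constant composite stays constant
  expect_equal(interpolate_lai(rep(3, length(x8)), x8, 1:360),
               rep(3, 360))
  # linear ramp reproduced to < 1% of its range
  y <- 1 + 0.01 * x8
  out <- interpolate_lai(y, x8, seq(1, 361, by = 1 / 24))
  ref <- 1 + 0.01 * seq(1, 361, by = 1 / 24)
  expect_lt(max(abs(out - ref)) / diff(range(ref)), 0.01)
  # evaluation at the composite timestamps stays near the inputs
  set.seed(1)
  y2 <- pmax(3 + 2 * sin(2 * pi * x8 / 365) + rnorm(length(x8), sd = 0.05), 0)
  at8 <- interpolate_lai(y2, x8, x8)
  expect_lt(mean(abs(at8 - y2)), 0.1)
  expect_true(all(interpolate_lai(c(0.01, 0, 0.01, 0, 0.01, 0), 1:6,
                                  seq(1, 6, 0.1)) >= 0))
  expect_error(interpolate_lai(c(1, 2, NA), 1:3, 1), "4 composite")
  expect_error(interpolate_lai(rep(NA_real_, 5), 1:5, 1), "missing")
})

test_that("dominant PFT merges IGBP classes then takes the argmax", {
  expect_equal(dominant_pft(c(EBF = 0.6, GRA = 0.4)), "EBF")
  # WSA merges into SAV before the argmax: 0.6 beats GRA
  expect_equal(dominant_pft(c(WSA = 0.3, SAV = 0.3, GRA = 0.2)), "SAV")
  # ties break by the fixed PFT order (EBF first)
  expect_equal(dominant_pft(c(ENF = 0.5, EBF = 0.5)), "EBF")
  un <- dominant_pft(c(EBF = 0, GRA = 0))
  expect_true(is.na(un))
  expect_true(attr(un, "unvegetated"))
  expect_error(dominant_pft(c(EBF = 0.7, GRA = 0.5)), "sum")
})

test_that("light-rain correction interpolates between its two anchors", {
  # P -> 0: ratio -> f_veg (full interception over the vegetated part)
  p <- 1e-9
  expect_equal(light_rain_correction(p, 0.8, 0.5) / p, 0.8,
               tolerance = 1e-6)
  # worked point: f_veg = 1, anchor 0.5, P = 0.3 -> ratio 0.75
  expect_equal(light_rain_correction(0.3, 1, 0.5), 0.75 * 0.3)
  # anchor equal to f_veg: ratio constant
  P <- seq(0.05, 0.45, by = 0.05)
  expect_equal(light_rain_correction(P, 0.6, 0.6) / P, rep(0.6, length(P)))
  # linear in P on (0, 0.5): second differences of the ratio vanish
  r <- light_rain_correction(P, 0.9, 0.4) / P
  expect_lt(max(abs(diff(diff(r)))), 1e-12)
  expect_error(light_rain_correction(0.6, 1, 0.5), "0.5")
  expect_error(light_rain_correction(0, 1, 0.5), "0.5")
})

test_that("light-rain anchors are per-PFT means of near-0.6 mm events", {
  ev <- data.frame(mean_hourly_P = c(0.55, 0.65, 0.6, 1.2, 0.3),
                   ratio = c(0.4, 0.6, 0.2, 0.9, 0.9),
                   pft = c("DBF", "DBF", "ENF", "DBF", "ENF"))
  a <- light_rain_anchor(ev)
  expect_equal(unname(a["DBF"]), 0.5)   # events 1 and 2 only
  expect_equal(unname(a["ENF"]), 0.2)
  expect_true(is.na(a["GRA"]))
})

test_that("grid predictions are masked linearly by vegetated fraction", {
  fx <- recovery_fixture()
  ser <- fx$sites[[1]]$series
  m <- fx$pipe$models
  g1 <- grid_from_site(ser, f_veg = 1)
  g05 <- grid_from_site(ser, f_veg = 0.5)
  e1 <- suppressWarnings(predict_grid_ei(m$hm_wet, m$hm_dry, m$cws, g1))[[1]]
  e05 <- suppressWarnings(predict_grid_ei(m$hm_wet, m$hm_dry, m$cws, g05))[[1]]
  expect_equal(e05$Ei, e1$Ei / 2)
  # zero vegetation, zero interception
  g0 <- grid_from_site(ser, f_veg = 0)
  e0 <- suppressWarnings(predict_grid_ei(m$hm_wet, m$hm_dry, m$cws, g0))[[1]]
  expect_true(all(e0$Ei == 0))
})

test_that("light-rain hours outside events receive the interpolated ratio", {
  fx <- recovery_fixture()
  ser <- fx$sites[[1]]$series
  m <- fx$pipe$models
  anchors <- light_rain_anchor(fx$event_table)
  anchors[is.na(anchors)] <- 0.5
  g <- grid_from_site(ser, f_veg = 0.9)
  out <- suppressWarnings(
    predict_grid_ei(m$hm_wet, m$hm_dry, m$cws, g, anchors = anchors))[[1]]
  light <- out$source == "light_rain"
  if (any(light)) {
    expect_true(all(out$P[light] > 0 & out$P[light] < 0.5))
    expect_equal(out$Ei[light],
                 light_rain_correction(out$P[light], 0.9,
                                       anchors[[attr(ser, "meta")$pft]]))
  }
  # no double counting: light-rain hours are outside all events
  expect_false(any(out$source == "light_rain" & out$source == "event"))
})

test_that("grid-window CWS statistics select cells near sites", {
  fx <- recovery_fixture()
  ser <- fx$sites[[1]]$series
  g <- grid_from_site(ser, f_veg = 1)
  stats <- cws_window_stats(g, fx$pipe$models$cws,
                            data.frame(lat = attr(ser, "meta")$lat,
                                       lon = attr(ser, "meta")$lon))
  expect_true(is.finite(stats$mean) && stats$sd > 0)
  expect_error(cws_window_stats(g, fx$pipe$models$cws,
                                data.frame(lat = -60, lon = 120)),
               "inside")
})
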