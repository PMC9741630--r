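test_that("CSV reader types, flags and rejects as specified", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_site_fixture_csv(f, n = 3)
  ser <- read_site_csv(f, meta = list(lat = 45, pft = "DBF"))
  expect_s3_class(ser, "site_series")
  expect_equal(nrow(ser), 3)
  expect_false(attr(ser, "meta")$half_hourly)

  # missing LE -> schema error naming the column
  f2 <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(write_site_fixture_csv(f2, n = 3))
  df$LE <- NULL
  utils::write.csv(df, f2, row.names = FALSE)
  expect_error(read_site_csv(f2), "LE")

  # half-hourly spacing detected
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_site_fixture_csv(f3, n = 6, half_hourly = TRUE)
  ser3 <- read_site_csv(f3)
  expect_true(attr(ser3, "meta")$half_hourly)

  # hPa unit conversion at the boundary
  ser_hpa <- read_site_csv(f, vpd_unit = "hPa")
  expect_equal(ser_hpa$VPD, ser$VPD / 10)
})

test_that("half-hourly aggregation averages states, sums P, flags gaps", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_site_fixture_csv(f, n = 6, half_hourly = TRUE,
                         overrides = list(LE = c(100, 200, 150, 150, NA, 120),
                                          P = c(0.3, 0.2, 0, 0.1, 0, 0)))
  hr <- aggregate_to_hourly(read_site_csv(f))
  expect_equal(nrow(hr), 3)
  expect_equal(hr$LE[1], 150)           # mean of the two halves
  expect_equal(hr$P[1], 0.5)            # sum of the two halves
  expect_equal(hr$P[2], 0.1)
  expect_true(is.na(hr$LE[3]))          # one half missing -> gap

  # odd trailing half-hour dropped with a warning
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_site_fixture_csv(f2, n = 5, half_hourly = TRUE)
  expect_warning(out <- aggregate_to_hourly(read_site_csv(f2)), "odd")
  expect_equal(nrow(out), 2)
})

test_that("QC filters mask the stated rules and the accounting balances", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_site_fixture_csv(f, n = 6,
                         overrides = list(LE = c(180, -5, 180, 180, 180, 180),
                                          Ta = c(20, 20, -1, 20, 20, 20),
                                          qc = c(0, 0, 0, 3, 0, 0)))
  out <- apply_qc_filters(read_site_csv(f))
  expect_equal(out$series$qc_rule[2], "negative_LE")
  expect_equal(out$series$qc_rule[3], "freezing")
  expect_equal(out$series$qc_rule[4], "poor_quality")
  expect_equal(out$report$removed + out$report$retained, out$report$input)
  expect_equal(out$report$removed, 3)
  expect_equal(sum(out$report$by_rule), out$report$removed)

  # clean series: nothing removed
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_site_fixture_csv(f2, n = 4)
  clean <- apply_qc_filters(read_site_csv(f2))
  expect_equal(clean$report$removed, 0)
  expect_equal(clean$report$retained, 4)
})

test_that("IGBP classes merge into the eight retained PFTs", {
  expect_equal(merge_pft("WSA"), "SAV")
  expect_equal(merge_pft("OSH"), "SHU")
  expect_equal(merge_pft("CSH"), "SHU")
  expect_equal(merge_pft(PFT8), PFT8)
  expect_error(merge_pft("WET"), "unsupported")
})

test_that("LAI site-scaling applies the max-ratio and guards the input", {
  lai <- c(1, 2, 4, 3)
  expect_equal(scale_site_lai(lai, site_max = 4), lai)       # ratio 1
  expect_equal(scale_site_lai(lai, site_max = 2), lai / 2)   # grid max 4
  expect_error(scale_site_lai(lai, site_max = 2, grid_max = 0), "grid_max")
  expect_error(scale_site_lai(lai), "site_max")
})

test_that("humidity/rain LE correction is neutral at the reference level", {
  set.seed(77)
  n <- 2000
  A <- runif(n, 80, 500)
  ser <- data.frame(Rn = A / 0.9, G = A / 9, H = 0.3 * A,
                    RH = c(50, runif(n - 1, 20, 100)),
                    P = c(0, rexp(n - 1, 2) * rbinom(n - 1, 1, 0.2)))
  ser$LE <- 0.7 * A    # LER = 0.7 identically: independent of RH and P
  cor_ser <- correct_le_humidity_rain(ser, seed = 5)
  # hour 1 sits exactly at the reference (RH = 50, P = 0): factor exactly 1
  expect_equal(cor_ser$ler_factor[1], 1)
  # constant-LER site: statistically unchanged
  expect_lt(mean(abs(cor_ser$LE - ser$LE) / ser$LE), 0.01)
})

test_that("humidity/rain LE correction removes an imposed LER dependence", {
  set.seed(78)
  n <- 4000
  A <- runif(n, 80, 500)
  RH <- runif(n, 20, 100)
  P <- rexp(n, 2) * rbinom(n, 1, 0.25)
  bias <- 1 - 0.004 * (RH - 50) - 0.05 * log1p(P)  # underestimation factor
  ser <- data.frame(Rn = A / 0.9, G = A / 9, H = 0.3 * A, RH = RH, P = P)
  le_true <- 0.7 * A
  ser$LE <- le_true * bias
  cor_ser <- correct_le_humidity_rain(ser, seed = 6)
  # corrected LE is much closer to the unbiased values than the raw LE
  expect_lt(mean(abs(cor_ser$LE - le_true) / le_true),
            0.3 * mean(abs(ser$LE * 1 - le_true) / le_true) + 0.005)
})

test_that("Bowen closure preserves the Bowen ratio and closes exactly", {
  ser <- data.frame(Rn = c(160, 130, 100, 150), G = c(40, 10, 0, 30),
                    LE = c(60, 80, 0, 100), H = c(40, 40, 50, -120))
  out <- bowen_closure(ser)
  expect_equal(out$LE[1], 72)                      # (Rn-G) LE/(LE+H)
  expect_equal(out$LE[2], 80)                      # already closed
  expect_equal(out$LE[3], 0)                       # LE = 0 stays 0
  expect_true(out$bowen_flagged[4])                # LE + H <= 0: unchanged
  expect_equal(out$LE[4], 100)
  ok <- !out$bowen_flagged
  expect_equal(out$LE[ok] + out$H[ok], ser$Rn[ok] - ser$G[ok])
  # Bowen ratio preserved
  expect_equal(out$H[1] / out$LE[1], ser$H[1] / ser$LE[1], tolerance = 1e-12)
})
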