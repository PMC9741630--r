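# Shared fixtures. The trained-pipeline fixture is expensive, so it is
# memoized for the whole test run; small fixtures are rebuilt per use.

.fixture_env <- new.env(parent = emptyenv())

small_site <- function(seed = 3, n_years = 1, noise_sd = 10, ...) {
  generate_site(synth_config(n_years = n_years, seed = seed,
                             noise_sd = noise_sd, ...))
}

# the recovery-study fixture: 5 sites x 2 years, observation noise
# 10 W m-2, full pipeline with pooled training
recovery_fixture <- function() {
  if (!is.null(.fixture_env$recovery)) return(.fixture_env$recovery)
  pfts <- c("DBF", "ENF", "EBF", "GRA", "MF")
  lats <- c(45, 52, 5, 40, 48)
  cfgs <- lapply(1:5, function(i)
    synth_config(n_years = 2, seed = 200 + i, pft = pfts[i], lat = lats[i],
                 noise_sd = 10))
  sites <- lapply(cfgs, generate_site)
  pipe <- suppressWarnings(
    run_site_pipeline(lapply(sites, `[[`, "series"),
                      config = hybrid_config(seed = 11)))
  et <- attach_truth(pipe$event_table, pipe$events,
                     lapply(sites, `[[`, "truth"))
  .fixture_env$recovery <- list(cfgs = cfgs, sites = sites, pipe = pipe,
                                event_table = et)
  .fixture_env$recovery
}

# random-but-valid Penman-Monteith states
random_states <- function(n, seed = 1) {
  set.seed(seed)
  pm_state(Ta = runif(n, 1, 40), VPD = runif(n, 0.05, 4),
           A = runif(n, 0, 800), ra = runif(n, 5, 200))
}

write_site_fixture_csv <- function(path, n = 6, half_hourly = FALSE,
                                   overrides = list()) {
  step <- if (half_hourly) 0.5 else 1
  df <- data.frame(timestamp = seq(0, by = step, length.out = n),
                   Ta = 20, RH = 60, VPD = 0.9, Rn = 400, G = 40,
                   H = 120, LE = 180, WS = 2.5, P = 0, qc = 0, LAI = 3)
  for (nm in names(overrides)) df[[nm]] <- overrides[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  path
}
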