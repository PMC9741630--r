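# End-to-end site pipeline: QC -> event segmentation -> HM_dry -> CWS
# proxy and net -> HM_wet -> hourly and event-level interception loss.
# Training pools all supplied sites (global models, as in the site-network
# setting); event and hour indices are offset so pooled tables stay unique.

#' Run the full interception-inference pipeline over one or more sites
#'
#' @param sites list of site_series (observed LE/H filled). QC filters are
#'   applied; optionally the LE humidity/rain correction and Bowen closure.
#' @param config [hybrid_config()]
#' @param apply_ler,apply_bowen apply the LE bias correction / energy
#'   closure before modelling (default off: the corrections target
#'   instrument biases that a caller's data may or may not carry)
#' @param max_dry_samples cap on pooled HM_dry training rows
#' @return list: models (hm_dry, hm_wet, cws), samples (pooled, with site,
#'   label), descriptors (wet-hour descriptor table), ei_hours, events
#'   (flat list with global ids), event_table
#' @export
run_site_pipeline <- function(sites, config = hybrid_config(),
                              apply_ler = FALSE, apply_bowen = FALSE,
                              max_dry_samples = 30000L) {
  if (inherits(sites, "site_series")) sites <- list(sites)
  all_samples <- list(); all_descr <- list(); all_events <- list()
  hour_off <- 0L; ev_off <- 0L
  for (s in seq_along(sites)) {
    ser <- sites[[s]]
    if (apply_ler) ser <- correct_le_humidity_rain(ser)
    if (apply_bowen) ser <- bowen_closure(ser)
    qc <- apply_qc_filters(ser)
    ser <- qc$series
    night <- if (!is.null(ser$night)) ser$night else
      solar_elevation(attr(ser, "meta")$lat, ser$doy, ser$hod) < 0
    events <- detect_events(ser$P, night)
    labels <- label_hours(ser, events)
    samples <- build_samples(ser, labels)
    samples$site <- s
    samples$hour_idx <- samples$hour_idx + hour_off
    if (length(events)) {
      descr <- event_descriptor_table(events, ser$P, ser$hod)
      descr$LAI <- ser$LAI[descr$hour_idx]
      descr$pft <- attr(ser, "meta")$pft
      descr$excluded <- ser$excluded[descr$hour_idx] %in% TRUE
      descr$hour_idx <- descr$hour_idx + hour_off
      descr$event_id <- descr$event_id + ev_off
      all_descr[[s]] <- descr
      events <- lapply(events, function(ev) {
        ev$id <- ev$id + ev_off
        ev$start_idx <- ev$start_idx + hour_off
        ev$end_idx <- ev$end_idx + hour_off
        ev$pulses <- ev$pulses + hour_off
        ev$site <- s
        ev
      })
      ev_off <- ev_off + length(events)
      all_events <- c(all_events, events)
    }
    all_samples[[s]] <- samples
    hour_off <- hour_off + nrow(ser)
  }
  samples <- do.call(rbind, all_samples)
  descriptors <- do.call(rbind, all_descr)

  hm_dry <- train_hybrid(samples, "dry", config = config,
                         max_samples = max_dry_samples)

  # CWS proxy on usable (non-excluded) wet hours
  wet_idx <- descriptors$hour_idx[!descriptors$excluded]
  wet_rows <- match(wet_idx, samples$hour_idx)
  wet <- samples[wet_rows, , drop = FALSE]
  le_dry_hat <- predict_le(hm_dry, wet)
  proxy <- derive_cws_proxy(wet$LE_obs, le_dry_hat)
  wet_descr <- descriptors[!descriptors$excluded, , drop = FALSE]
  cws_model <- train_cws_net(wet_descr, proxy$cws, config = config)

  hm_wet <- train_hybrid(wet, "wet", cws = proxy$cws, config = config)

  ei_hours <- estimate_ei_hourly(hm_wet, hm_dry, wet, cws_model, wet_descr)
  event_table <- aggregate_events(ei_hours, all_events, samples)
  list(models = list(hm_dry = hm_dry, hm_wet = hm_wet, cws = cws_model),
       samples = samples, descriptors = descriptors, wet_samples = wet,
       cws_proxy = proxy, ei_hours = ei_hours, events = all_events,
       event_table = event_table)
}

#' Attach ground-truth event sums to an event table
#'
#' For synthetic sites with a known truth series: sums Ei_true over each
#' event's hours for recovery checks.
#'
#' @param event_table from [run_site_pipeline()]
#' @param events the pipeline's flat event list (global indices)
#' @param truths list of per-site truth data.frames (Ei_true column),
#'   concatenated in pipeline site order
#' @return event_table with an Ei_true column
#' @export
attach_truth <- function(event_table, events, truths) {
  ei_true <- unlist(lapply(truths, function(tr) tr$Ei_true))
  sums <- vapply(events, function(ev)
    sum(ei_true[ev$start_idx:ev$end_idx]), numeric(1))
  ids <- vapply(events, function(ev) as.numeric(ev$id), numeric(1))
  event_table$Ei_true <- sums[match(event_table$event_id, ids)]
  event_table
}
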