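# Rain-event segmentation: events start at P >= 0.5 mm, carry a 6 h tail
# (12 h when the last rain ceased at night) that restarts on every further
# qualifying rain hour, and spans longer than 60 h are re-segmented into
# sub-events starting at P >= 1 mm. Hours inside events are "wet"; rainy
# runs inside an event are "pulses".

EVENT_START_MM <- 0.5
SPLIT_START_MM <- 1.0
TAIL_DAY_H <- 6L
TAIL_NIGHT_H <- 12L
MAX_EVENT_H <- 60L

# core scan shared by first-pass detection and the >60 h re-segmentation
.scan_events <- function(P, night, thr) {
  n <- length(P)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (P[i] >= thr) {
      last_rain <- i
      tail_len <- if (night[i]) TAIL_NIGHT_H else TAIL_DAY_H
      j <- i + 1L
      while (j <= n && j <= last_rain + tail_len) {
        if (P[j] >= thr) {
          last_rain <- j
          tail_len <- if (night[j]) TAIL_NIGHT_H else TAIL_DAY_H
        }
        j <- j + 1L
      }
      end <- min(last_rain + tail_len, n)
      out[[length(out) + 1L]] <- c(start = i, end = end)
      i <- end + 1L
    } else i <- i + 1L
  }
  out
}

.pulse_runs <- function(P, start, end) {
  seg <- P[start:end] > 0
  r <- rle(seg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(matrix(integer(0), 0, 2))
  cbind(start = start - 1L + starts[keep], end = start - 1L + ends[keep])
}

.make_event <- function(id, start, end, P, sub_event_of = NA_integer_) {
  start <- unname(start); end <- unname(end)
  list(id = id, start_idx = start, end_idx = end,
       pulses = .pulse_runs(P, start, end),
       total_P = sum(P[start:end]), sub_event_of = sub_event_of)
}

#' Detect rain events in an hourly precipitation series
#'
#' @param P hourly precipitation (mm h-1), non-negative
#' @param night logical night mask aligned with P (solar elevation < 0)
#' @param split apply the 60 h re-segmentation (default TRUE)
#' @return list of rain_event objects (id, start_idx, end_idx inclusive,
#'   pulses matrix, total_P, sub_event_of)
#' @export
detect_events <- function(P, night, split = TRUE) {
  if (length(P) == 0L) return(list())
  stopifnot(length(P) == length(night))
  if (any(P < 0, na.rm = TRUE)) stop("P must be non-negative")
  P[is.na(P)] <- 0
  spans <- .scan_events(P, night, EVENT_START_MM)
  events <- list()
  for (sp in spans) {
    ev <- .make_event(length(events) + 1L, sp["start"], sp["end"], P)
    if (split) {
      for (e in split_long_event(ev, P, night)) {
        e$id <- length(events) + 1L
        events[[length(events) + 1L]] <- e
      }
    } else events[[length(events) + 1L]] <- ev
  }
  events
}

#' Re-segment an over-long rain event
#'
#' Events lasting more than 60 h (tail included) are re-scanned within
#' their span with a 1 mm start threshold; each sub-event receives its own
#' tail. A long span containing no hour with P >= 1 mm is discarded with a
#' warning. Applied once, not recursively.
#'
#' @param event a rain_event
#' @param P,night full site series
#' @return list of rain_event objects (possibly empty)
#' @export
split_long_event <- function(event, P, night) {
  dur <- event$end_idx - event$start_idx + 1L
  if (dur <= MAX_EVENT_H) return(list(event))
  span <- event$start_idx:event$end_idx
  if (!any(P[span] >= SPLIT_START_MM)) {
    warning("event of ", dur, " h has no hour with P >= ", SPLIT_START_MM,
            " mm; discarded")
    return(list())
  }
  sub <- .scan_events(P[span], night[span], SPLIT_START_MM)
  lapply(seq_along(sub), function(k) {
    s <- event$start_idx - 1L + sub[[k]]["start"]
    e <- min(event$start_idx - 1L + sub[[k]]["end"], length(P))
    .make_event(k, s, e, P, sub_event_of = event$id)
  })
}

#' Label every hour wet, dry or excluded
#'
#' In-event hours are wet; QC-excluded hours are excluded (taking
#' precedence); everything else is dry.
#'
#' @param series site_series with an `excluded` logical column (absent means
#'   nothing excluded)
#' @param events list from [detect_events()]
#' @return factor with levels wet, dry, excluded
#' @export
label_hours <- function(series, events) {
  n <- nrow(series)
  in_event <- rep(FALSE, n)
  for (ev in events) {
    idx <- ev$start_idx:ev$end_idx
    if (any(in_event[idx])) stop("overlapping events: internal inconsistency")
    in_event[idx] <- TRUE
  }
  lab <- ifelse(in_event, "wet", "dry")
  excl <- series$excluded
  if (!is.null(excl)) lab[excl %in% TRUE] <- "excluded"
  factor(lab, levels = c("wet", "dry", "excluded"))
}

#' Per-hour rainfall descriptors within an event
#'
#' The eight rainfall-characteristics features, computed causally (only
#' hours up to the target hour are used): cumulative, mean and maximum
#' hourly P since event start; current-hour P; cumulative and maximum P of
#' the last (possibly ongoing) pulse; dry hours since that pulse ended; and
#' the local solar hour-of-day at which it ended.
#'
#' @param event a rain_event
#' @param hour_idx absolute hour index, must lie inside the event
#' @param P precipitation series
#' @param hod hour-of-day series aligned with P (values in 0-23)
#' @return one-row data.frame with the eight descriptors
#' @export
compute_descriptors <- function(event, hour_idx, P, hod) {
  if (hour_idx < event$start_idx || hour_idx > event$end_idx)
    stop("hour ", hour_idx, " lies outside the event")
  sofar <- P[event$start_idx:hour_idx]
  pulses <- event$pulses
  started <- which(pulses[, "start"] <= hour_idx)
  if (length(started)) {
    pu <- pulses[max(started), , drop = TRUE]
    p_end <- min(pu["end"], hour_idx)           # causal view of the pulse
    pp <- P[pu["start"]:p_end]
    dry_since <- max(0L, hour_idx - p_end)
    cum_pulse <- sum(pp); max_pulse <- max(pp)
    end_hod <- hod[p_end]
  } else {  # inside an event whose first >=0.5 hour starts it: cannot happen
    dry_since <- hour_idx - event$start_idx
    cum_pulse <- 0; max_pulse <- 0; end_hod <- hod[event$start_idx]
  }
  data.frame(
    cum_P_event = sum(sofar),
    mean_P_event = mean(sofar),
    max_P_event = max(sofar),
    P_now = P[hour_idx],
    cum_P_last_pulse = cum_pulse,
    max_P_last_pulse = max_pulse,
    dry_hours_since_pulse = dry_since,
    last_pulse_end_hod = end_hod
  )
}

#' Descriptor table for all hours of all events
#'
#' Vectorized convenience over [compute_descriptors()].
#'
#' @param events list of rain_event
#' @param P,hod aligned series
#' @return data.frame with hour_idx, event_id and the eight descriptors
#' @export
event_descriptor_table <- function(events, P, hod) {
  rows <- lapply(events, function(ev) {
    hrs <- ev$start_idx:ev$end_idx
    d <- do.call(rbind, lapply(hrs, compute_descriptors, event = ev,
                               P = P, hod = hod))
    cbind(hour_idx = hrs, event_id = ev$id, d)
  })
  do.call(rbind, rows)
}
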