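# Independent brute-force re-implementation of the event rules, written as
# a set-based fixed point rather than the package's single left-to-right
# scan, so the two can disagree if either is wrong.

oracle_scan <- function(P, night, thr) {
  n <- length(P)
  consumed <- rep(FALSE, n)
  spans <- list()
  repeat {
    starts <- which(P >= thr & !consumed)
    if (!length(starts)) break
    s <- starts[1]
    # grow the event: repeatedly jump to the next qualifying rain hour
    # inside the current tail window until none remains
    last_rain <- s
    repeat {
      tail_len <- if (night[last_rain]) 12L else 6L
      if (last_rain + 1L > n) break
      window <- seq(last_rain + 1L, min(last_rain + tail_len, n))
      q <- window[P[window] >= thr]
      if (!length(q)) break
      last_rain <- q[1]
    }
    tail_len <- if (night[last_rain]) 12L else 6L
    e <- min(last_rain + tail_len, n)
    spans[[length(spans) + 1L]] <- c(s, e)
    consumed[seq_len(e)] <- TRUE   # scan is left-to-right: consume prefix
  }
  spans
}

# full three-rule oracle returning per-hour membership labels
oracle_events <- function(P, night) {
  spans <- oracle_scan(P, night, 0.5)
  member <- integer(length(P))
  k <- 0L
  for (sp in spans) {
    if (sp[2] - sp[1] + 1L > 60L) {
      idx <- sp[1]:sp[2]
      if (!any(P[idx] >= 1)) next
      subs <- oracle_scan(P[idx], night[idx], 1.0)
      for (ss in subs) {
        k <- k + 1L
        lo <- sp[1] - 1L + ss[1]
        hi <- min(sp[1] - 1L + ss[2], length(P))
        member[lo:hi] <- k
      }
    } else {
      k <- k + 1L
      member[sp[1]:sp[2]] <- k
    }
  }
  member
}

events_to_membership <- function(events, n) {
  member <- integer(n)
  for (i in seq_along(events))
    member[events[[i]]$start_idx:events[[i]]$end_idx] <- i
  member
}

random_p_series <- function(n, rain_frac = 0.15) {
  P <- numeric(n)
  wet <- runif(n) < rain_frac
  P[wet] <- rgamma(sum(wet), shape = 0.9, scale = 1.2)
  P
}
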