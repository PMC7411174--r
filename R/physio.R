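#' Extract breath-wise end-tidal CO2 from a capnograph trace
#'
#' Breaths are segmented as contiguous runs of samples at or above
#' `min_height_frac` of the trace's robust maximum (98th percentile) —
#' which rejects the inspiratory troughs and cardiogenic ripples —
#' separated by at least `min_breath_interval`. Within each breath the
#' end-tidal value is the mean over the alveolar plateau (samples within
#' `plateau_frac` of the breath maximum), which is far less sensitive to
#' measurement noise than the single maximum sample; the breath time is
#' the plateau centroid.
#'
#' @param trace A `capno_trace` (columns `time`, `co2`).
#' @param min_breath_interval Minimum spacing between breaths, s.
#' @param min_height_frac Breath-detection threshold as a fraction of the
#'   robust maximum.
#' @param plateau_frac Samples within this fraction of the breath maximum
#'   form the alveolar plateau.
#'
#' @return An `etco2_series`: tibble with `breath_time` (s) and `etco2`
#'   (mmHg), with attribute `lag_applied = 0`.
#' @export
extract_etco2 <- function(trace, min_breath_interval = 2,
                          min_height_frac = 0.5, plateau_frac = 0.98) {
  time <- trace$time
  co2 <- trace$co2
  if (length(time) < 3L) stop("trace too short")
  robust_max <- stats::quantile(co2, 0.98, names = FALSE)
  above <- co2 >= min_height_frac * robust_max
  if (!any(above) || all(above)) {
    stop("no breaths detected in the CO2 trace")
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= 2L
  bt <- et <- numeric(0)
  for (r in which(keep)) {
    idx <- starts[r]:ends[r]
    vmax <- max(co2[idx])
    plateau <- idx[co2[idx] >= plateau_frac * vmax]
    bt <- c(bt, mean(time[plateau]))
    et <- c(et, mean(co2[plateau]))
  }
  if (!length(bt)) stop("no breaths detected in the CO2 trace")
  # enforce the minimum breath spacing: of two crowding detections keep
  # the one with the larger end-tidal value
  ok <- rep(TRUE, length(bt))
  for (i in seq_along(bt)[-1]) {
    j <- max(which(ok[seq_len(i - 1L)]))
    if (bt[i] - bt[j] < min_breath_interval) {
      if (et[i] > et[j]) ok[j] <- FALSE else ok[i] <- FALSE
    }
  }
  new_etco2_series(bt[ok], et[ok], lag_applied = 0)
}

#' Construct an end-tidal CO2 series
#'
#' @param breath_time Per-breath peak times, s.
#' @param etco2 Per-breath end-tidal values, mmHg (sanity bounds
#'   5--100 mmHg).
#' @param lag_applied Temporal shift already applied, s.
#' @return An `etco2_series` tibble.
#' @export
new_etco2_series <- function(breath_time, etco2, lag_applied = 0) {
  if (any(etco2 < 5 | etco2 > 100)) {
    warning("EtCO2 values outside the physiological 5-100 mmHg range")
  }
  out <- tibble::tibble(breath_time = breath_time, etco2 = etco2)
  attr(out, "lag_applied") <- lag_applied
  class(out) <- c("etco2_series", class(out))
  out
}

#' Align the EtCO2 series to the whole-brain BOLD time course
#'
#' Interpolates the breath-wise EtCO2 series onto the BOLD time grid
#' (linear, nearest-value extension at the edges) and computes the Pearson
#' correlation for every candidate lag in `[0, max_lag]`: candidate lag L
#' models the brain as following the lung with delay L, i.e. the BOLD
#' sample at time t is compared against EtCO2 at time t - L. The lag
#' maximizing the correlation is returned (ties broken toward the
#' smallest lag), and the series' breath times are shifted by +lag so
#' they live on the brain clock.
#'
#' @param etco2 An `etco2_series` (from [extract_etco2()]).
#' @param wb_bold Whole-brain BOLD time course: a `processed_series` or a
#'   numeric vector.
#' @param sampling_interval Seconds between BOLD samples (taken from the
#'   series if one is supplied).
#' @param max_lag,lag_step Lag search grid, s (defaults 0--60 by 1). The
#'   search is one-sided: the lung-to-brain transit delay is nonnegative.
#'
#' @return A `cvr_alignment` list: `lag` (s), `aligned` (the shifted
#'   `etco2_series`), `correlation` (at the chosen lag) and `profile`
#'   (tibble of lag vs correlation).
#' @export
align_etco2 <- function(etco2, wb_bold, sampling_interval = NULL,
                        max_lag = 60, lag_step = 1) {
  if (inherits(wb_bold, "processed_series")) {
    sampling_interval <- wb_bold$sampling_interval
    wb_bold <- as.numeric(wb_bold$values)
  }
  if (is.null(sampling_interval)) {
    stop("sampling_interval is required when wb_bold is a bare vector")
  }
  if (stats::sd(wb_bold) == 0 || stats::sd(etco2$etco2) == 0) {
    stop("correlation undefined: constant BOLD or EtCO2 input")
  }
  t_bold <- (seq_along(wb_bold) - 1L) * sampling_interval
  lags <- seq(0, max_lag, by = lag_step)
  cors <- vapply(lags, function(L) {
    reg <- stats::approx(etco2$breath_time, etco2$etco2,
                         xout = t_bold - L, rule = 2)$y
    if (stats::sd(reg) == 0) return(-Inf)
    stats::cor(reg, wb_bold)
  }, numeric(1))
  if (!any(is.finite(cors))) stop("correlation undefined at every lag")
  best <- which.max(cors)  # first maximum: ties go to the smallest lag
  lag <- lags[best]
  aligned <- new_etco2_series(etco2$breath_time + lag, etco2$etco2,
                              lag_applied = attr(etco2, "lag_applied") + lag)
  structure(list(lag = lag, aligned = aligned, correlation = cors[best],
                 profile = tibble::tibble(lag = lags, correlation = cors)),
            class = "cvr_alignment")
}

#' @export
print.cvr_alignment <- function(x, ...) {
  cat(sprintf("<cvr_alignment> lag %.3g s (r = %.4f over %d candidates)\n",
              x$lag, x$correlation, nrow(x$profile)))
  invisible(x)
}

#' Epoch-averaged end-tidal CO2
#'
#' Means of the (aligned) breath-wise EtCO2 values over half-open
#' room-air and hypercapnic windows. The same operation serves the 4-min
#' ASL/BOLD epochs and the 30-s phase-contrast scan windows.
#'
#' @param aligned An `etco2_series` (typically the `aligned` element of
#'   [align_etco2()]).
#' @param window_ra,window_hc Two-element `[t0, t1)` windows, s.
#'
#' @return An `etco2_epochs` object: `etco2_ra`, `etco2_hc` (mmHg) and
#'   breath counts. Warns (does not error) if `etco2_hc <= etco2_ra`.
#' @export
epoch_etco2 <- function(aligned, window_ra, window_hc) {
  in_ra <- aligned$breath_time >= window_ra[1] &
    aligned$breath_time < window_ra[2]
  in_hc <- aligned$breath_time >= window_hc[1] &
    aligned$breath_time < window_hc[2]
  if (sum(in_ra) < 2L || sum(in_hc) < 2L) {
    stop("each window must contain at least 2 breaths")
  }
  ra <- mean(aligned$etco2[in_ra])
  hc <- mean(aligned$etco2[in_hc])
  if (hc <= ra) {
    warning("etco2_hc <= etco2_ra: no hypercapnic EtCO2 increase detected")
  }
  structure(list(etco2_ra = ra, etco2_hc = hc,
                 n_ra = sum(in_ra), n_hc = sum(in_hc)),
            class = "etco2_epochs")
}

#' @export
print.etco2_epochs <- function(x, ...) {
  cat(sprintf("<etco2_epochs> RA %.2f mmHg (%d breaths); HC %.2f mmHg (%d breaths)\n",
              x$etco2_ra, x$n_ra, x$etco2_hc, x$n_hc))
  invisible(x)
}
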