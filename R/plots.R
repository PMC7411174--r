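#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a capnograph trace with extracted end-tidal values
#'
#' @param object A `capno_trace`.
#' @param etco2 Optional `etco2_series` overlaid as points.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.capno_trace <- function(object, etco2 = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$co2)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = expression(CO[2] ~ "(mmHg)")) +
    ggplot2::theme_minimal()
  if (!is.null(etco2)) {
    p <- p + ggplot2::geom_point(
      data = etco2,
      ggplot2::aes(x = .data$breath_time, y = .data$etco2),
      colour = "firebrick", size = 0.8)
  }
  p
}

#' Plot the lag-search correlation profile of an alignment
#'
#' @param object A `cvr_alignment` (from [align_etco2()]).
#' @param ... Ignored.
#' @return A ggplot with the chosen lag marked.
#' @export
autoplot.cvr_alignment <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$lag, y = .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lag, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "candidate lag (s)", y = "Pearson r",
                  title = sprintf("EtCO2-BOLD alignment: lag %g s",
                                  object$lag)) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a CVR map
#'
#' @param object A `cvr_map`.
#' @param slice Axial (z) slice index; defaults to the middle slice.
#' @param ... Ignored.
#' @return A ggplot raster of CVR in %/mmHg.
#' @export
autoplot.cvr_map <- function(object, slice = NULL, ...) {
  d <- dim(object$values)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$cvr <- as.vector(object$values[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$cvr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "black",
                                  name = "CVR (%/mmHg)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s CVR map, slice %d",
                                  toupper(object$modality), slice)) +
    ggplot2::theme_void()
}

#' Plot whole-brain ASL and BOLD time courses of a processed subject
#'
#' @param asl,bold `processed_series` ROI time courses (1D).
#' @param timeline An [acquisition_timeline()]; epoch windows are shaded.
#' @return A ggplot, one facet per modality.
#' @export
plot_time_courses <- function(asl, bold, timeline) {
  mk <- function(s, label) {
    tibble::tibble(
      time = (seq_along(s$values) - 1L) * s$sampling_interval,
      value = as.numeric(s$values), modality = label)
  }
  df <- dplyr::bind_rows(mk(asl, "perfusion-weighted (ASL)"),
                         mk(bold, "BOLD"))
  win <- tibble::tibble(
    t0 = c(timeline$ra_window[1], timeline$hc_window[1]),
    t1 = c(timeline$ra_window[2], timeline$hc_window[2]),
    epoch = c("room air", "hypercapnia"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_rect(data = win, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$t0, xmax = .data$t1,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$epoch), alpha = 0.15) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~modality, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)", fill = NULL) +
    ggplot2::theme_minimal()
}
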