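# Shift an array along `axis` by `k` voxels (zero fill), used by the
# separable Gaussian convolution.
.shift_axis <- function(arr, k, axis) {
  d <- dim(arr)
  n <- d[axis]
  out <- array(0, dim = d)
  if (abs(k) >= n) return(out)
  src <- if (k >= 0) seq_len(n - k) else seq.int(1 - k, n)
  dst <- if (k >= 0) seq.int(1 + k, n) else seq_len(n + k)
  idx_src <- rep(list(quote(expr = )), length(d))
  idx_dst <- idx_src
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out_call <- as.call(c(list(quote(`[<-`), quote(out)), idx_dst,
                        list(as.call(c(list(quote(`[`), quote(arr)), idx_src)))))
  eval(out_call)
}

#' Volume-wise 3D Gaussian smoothing
#'
#' Separable Gaussian smoothing of a 3D volume or 4D time series, with
#' sigma = `fwhm / (2 * sqrt(2 * log(2)))` per axis in mm, converted to
#' voxels using the (possibly anisotropic) voxel size. Edges are
#' renormalized (the kernel is divided by its in-volume mass), so a
#' constant image stays exactly constant. `fwhm = 0` returns the input
#' unchanged.
#'
#' @param series 3D or 4D numeric array (x, y, z\[, t\]).
#' @param fwhm Full-width-at-half-maximum, mm (default 4, >= 0).
#' @param voxel_size Voxel edge lengths, mm (scalar recycled to 3).
#'
#' @return Array of the same shape.
#' @export
smooth_gaussian <- function(series, fwhm = 4, voxel_size = c(3.4, 3.4, 6)) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(series)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  d <- dim(series)
  if (!length(d) %in% c(3L, 4L)) stop("series must be a 3D or 4D array")
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  out <- series
  norm <- array(1, dim = d[1:3])
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / voxel_size[axis]
    radius <- max(1L, ceiling(3 * sigma_vox))
    offs <- seq.int(-radius, radius)
    w <- exp(-offs^2 / (2 * sigma_vox^2))
    w <- w / sum(w)
    acc <- array(0, dim = d)
    nacc <- array(0, dim = d[1:3])
    for (j in seq_along(offs)) {
      acc <- acc + w[j] * .shift_axis(out, offs[j], axis)
      nacc <- nacc + w[j] * .shift_axis(norm, offs[j], axis)
    }
    out <- acc
    norm <- nacc
  }
  if (length(d) == 4L) {
    out / as.vector(norm)  # norm recycles over t (first 3 dims contiguous)
  } else {
    out / norm
  }
}

# 6-connected component labeling of a logical 3D array (BFS flood fill).
# Returns an integer array of labels (0 = background).
.label_components_3d <- function(mask) {
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  labels <- array(0L, dim = d)
  todo <- which(mask)
  lab <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    frontier <- start
    labels[start] <- lab
    while (length(frontier)) {
      ai <- arrayInd(frontier, d)
      nb <- integer(0)
      for (off in list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                       c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))) {
        cand <- sweep(ai, 2L, off, `+`)
        ok <- cand[, 1] >= 1L & cand[, 1] <= nx &
          cand[, 2] >= 1L & cand[, 2] <= ny &
          cand[, 3] >= 1L & cand[, 3] <= nz
        if (!any(ok)) next
        cand <- cand[ok, , drop = FALSE]
        lin <- cand[, 1] + (cand[, 2] - 1L) * nx + (cand[, 3] - 1L) * nx * ny
        nb <- c(nb, lin[mask[lin] & labels[lin] == 0L])
      }
      nb <- unique(nb)
      labels[nb] <- lab
      frontier <- nb
    }
  }
  labels
}

#' Whole-brain mask from a mean volume
#'
#' Thresholds the mean image at `threshold_frac` of its robust maximum
#' (the 98th percentile) and keeps the largest 6-connected component,
#' emulating segmentation of the raw image.
#'
#' @param mean_volume 3D numeric array.
#' @param threshold_frac Fraction of the robust maximum (default 0.25); 0
#'   keeps every strictly positive voxel.
#' @param robust_quantile Quantile defining the robust maximum.
#'
#' @return Logical 3D mask.
#' @export
compute_wb_mask <- function(mean_volume, threshold_frac = 0.25,
                            robust_quantile = 0.98) {
  if (length(mean_volume) == 0) stop("empty volume")
  thr <- threshold_frac *
    stats::quantile(mean_volume, robust_quantile, names = FALSE)
  mask <- mean_volume > thr
  if (!any(mask)) stop("no voxel passes the whole-brain threshold")
  labels <- .label_components_3d(mask)
  tab <- tabulate(labels[labels > 0L])
  labels == which.max(tab)
}

# Apply a centered two-neighbor stencil along the last dimension of a 4D
# array or a vector. fun(s, prev, nxt) is vectorized; endpoints get the
# single available neighbor for both prev and nxt.
.surround_apply <- function(x, fun) {
  if (is.null(dim(x))) {
    nt <- length(x)
    if (nt < 3L) stop("need at least 3 time points")
    prev <- x[c(1L, seq_len(nt - 1L))]; prev[1] <- x[2]
    nxt <- x[c(seq.int(2L, nt), nt)]; nxt[nt] <- x[nt - 1L]
    return(fun(x, prev, nxt, seq_len(nt)))
  }
  d <- dim(x)
  nt <- d[length(d)]
  if (nt < 3L) stop("need at least 3 time points")
  idx_prev <- c(2L, seq_len(nt - 1L))   # endpoint: use the single neighbor
  idx_next <- c(seq.int(2L, nt), nt - 1L)
  slab <- prod(d[-length(d)])
  xm <- matrix(x, nrow = slab)
  out <- fun(xm, xm[, idx_prev, drop = FALSE], xm[, idx_next, drop = FALSE],
             seq_len(nt))
  array(out, dim = d)
}

#' Surround subtraction: perfusion-weighted time course from echo 1
#'
#' Forms the control-minus-label difference series \eqn{\Delta M} at the
#' full temporal resolution: each volume is differenced against the mean
#' of its two temporal neighbors (which carry the opposite label sense),
#' signed so that \eqn{\Delta M > 0} when control exceeds label. Interior
#' points use both neighbors (which cancels any purely linear drift);
#' endpoints fall back to a two-point subtraction with the single
#' available neighbor.
#'
#' @param echo1 4D array (x,y,z,t) or numeric vector, ASL-weighted signal.
#' @param first_volume_type `"control"` or `"label"`: sense of volume 1.
#' @param tr Sampling interval (TR), seconds.
#'
#' @return A `processed_series` with `kind = "perfusion-weighted"`, same
#'   t length as the input.
#' @export
surround_subtract <- function(echo1, first_volume_type = c("control", "label"),
                              tr = 4.006) {
  first_volume_type <- match.arg(first_volume_type)
  sgn0 <- if (first_volume_type == "control") 1 else -1
  vals <- .surround_apply(echo1, function(s, prev, nxt, ti) {
    sgn <- sgn0 * (-1)^(ti - 1)
    if (is.matrix(s)) {
      sweep(s - (prev + nxt) / 2, 2L, sgn, `*`)
    } else {
      (s - (prev + nxt) / 2) * sgn
    }
  })
  new_processed_series(vals, "perfusion-weighted", tr)
}

#' Surround addition: BOLD time course from echo 2
#'
#' Averages each volume with the mean of its two temporal neighbors,
#' cancelling the control/label alternation while preserving the slow
#' BOLD response: \eqn{B_i = (s_i + (s_{i-1} + s_{i+1})/2) / 2}.
#' Endpoints average with the single available neighbor.
#'
#' @param echo2 4D array (x,y,z,t) or numeric vector, BOLD-weighted signal.
#' @param tr Sampling interval (TR), seconds.
#'
#' @return A `processed_series` with `kind = "bold"`.
#' @export
surround_add <- function(echo2, tr = 4.006) {
  vals <- .surround_apply(echo2, function(s, prev, nxt, ti) {
    (s + (prev + nxt) / 2) / 2
  })
  new_processed_series(vals, "bold", tr)
}

#' Construct a processed (perfusion-weighted or BOLD) series
#'
#' @param values 4D array or numeric vector.
#' @param kind `"perfusion-weighted"` or `"bold"`.
#' @param sampling_interval Seconds between samples.
#' @return A `processed_series` object.
#' @export
new_processed_series <- function(values,
                                 kind = c("perfusion-weighted", "bold"),
                                 sampling_interval) {
  kind <- match.arg(kind)
  structure(list(values = values, kind = kind,
                 sampling_interval = sampling_interval),
            class = "processed_series")
}

#' @export
print.processed_series <- function(x, ...) {
  d <- dim(x$values)
  shape <- if (is.null(d)) sprintf("%d time points", length(x$values)) else
    paste(d, collapse = "x")
  cat(sprintf("<processed_series> %s, %s, dt %.3f s\n", x$kind, shape,
              x$sampling_interval))
  invisible(x)
}

#' Mean time course over an ROI
#'
#' Unweighted mean of a 4D processed series over a 3D mask, per time point.
#'
#' @param series A `processed_series` holding a 4D array.
#' @param mask Logical 3D array on the same grid.
#'
#' @return A `processed_series` holding the 1D ROI time course.
#' @export
roi_time_course <- function(series, mask) {
  vals <- series$values
  d <- dim(vals)
  if (is.null(d) || length(d) != 4L) stop("series must hold a 4D array")
  if (!identical(dim(mask), d[1:3])) stop("mask grid does not match series")
  if (!any(mask)) stop("mask is empty")
  m <- matrix(vals, nrow = prod(d[1:3]))
  tc <- colMeans(m[as.vector(mask), , drop = FALSE])
  new_processed_series(tc, series$kind, series$sampling_interval)
}

#' Epoch averages over the room-air and hypercapnic windows
#'
#' Averages the processed series over volumes whose acquisition time
#' (`index * sampling_interval`, 0-based, half-open window convention)
#' falls inside the timeline's room-air and hypercapnic windows; the
#' transition volumes in between are discarded.
#'
#' @param series A `processed_series` (1D ROI course or 4D array).
#' @param timeline An [acquisition_timeline()] (its `tr` must match the
#'   series sampling interval).
#'
#' @return An `epoch_means` object: `s_ra`, `s_hc` (scalars or 3D arrays)
#'   and the per-window volume counts.
#' @export
epoch_average <- function(series, timeline) {
  nt <- if (is.null(dim(series$values))) length(series$values) else
    dim(series$values)[4]
  t_acq <- (seq_len(nt) - 1L) * series$sampling_interval
  in_ra <- t_acq >= timeline$ra_window[1] & t_acq < timeline$ra_window[2]
  in_hc <- t_acq >= timeline$hc_window[1] & t_acq < timeline$hc_window[2]
  if (sum(in_ra) < 2L || sum(in_hc) < 2L) {
    stop("each epoch window must contain at least 2 volumes")
  }
  avg <- function(keep) {
    if (is.null(dim(series$values))) {
      mean(series$values[keep])
    } else {
      d <- dim(series$values)
      m <- matrix(series$values, nrow = prod(d[1:3]))
      array(rowMeans(m[, keep, drop = FALSE]), dim = d[1:3])
    }
  }
  structure(list(s_ra = avg(in_ra), s_hc = avg(in_hc),
                 n_ra = sum(in_ra), n_hc = sum(in_hc)),
            class = "epoch_means")
}

#' Motion-correction hook (no-op)
#'
#' Rigid-body realignment is part of the standard preprocessing of in vivo
#' acquisitions but is deliberately a pass-through here: the synthetic
#' subjects are motion-free, and realignment of real data should be done
#' with a dedicated registration tool before entering this pipeline.
#'
#' @param series 4D array.
#' @return The input, unchanged.
#' @export
motion_correct <- function(series) series
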