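#' CVR from epoch means and epoch EtCO2
#'
#' The core reactivity quotient: percent signal change between the
#' hypercapnic and room-air epochs, normalized by the EtCO2 change,
#' \deqn{CVR = 100 \, \frac{(S_{HC} - S_{RA}) / S_{RA}}{EtCO2_{HC} -
#' EtCO2_{RA}}}{CVR = 100 * ((S_HC - S_RA)/S_RA) / (EtCO2_HC - EtCO2_RA)}
#' in %/mmHg, applied to a scalar (ROI) or elementwise to 3D epoch-mean
#' volumes. The same expression serves the ASL (perfusion-weighted), BOLD
#' and flux signals.
#'
#' @param s An `epoch_means` object (scalars or 3D arrays).
#' @param e An `etco2_epochs` object with `etco2_hc != etco2_ra`.
#'
#' @return Scalar or 3D array, %/mmHg. Voxels with `s_ra <= 0` yield
#'   `NA` (they are masked and counted by [make_cvr_map()]).
#' @export
#' @examples
#' s <- structure(list(s_ra = 5, s_hc = 6), class = "epoch_means")
#' e <- structure(list(etco2_ra = 40, etco2_hc = 50), class = "etco2_epochs")
#' cvr_from_epochs(s, e)  # 2 %/mmHg
cvr_from_epochs <- function(s, e) {
  d_et <- e$etco2_hc - e$etco2_ra
  if (d_et == 0) stop("etco2_hc equals etco2_ra: CVR undefined")
  out <- 100 * (s$s_hc - s$s_ra) / s$s_ra / d_et
  if (length(out) > 1L) out[s$s_ra <= 0] <- NA_real_
  out
}

#' ROI CVR: mask-mean time course first, then the reactivity quotient
#'
#' The canonical WB/GM/WM summary: the series is averaged over the ROI at
#' every time point, the ROI time course is epoch-averaged, and the CVR
#' quotient is applied to the two epoch means. Under noise this differs
#' from averaging a voxelwise CVR map over the ROI (the quotient is
#' nonlinear); the time-course-first order matches how whole-brain values
#' are computed from the raw time courses.
#'
#' @param series A `processed_series` holding a 4D array.
#' @param mask Logical 3D ROI mask.
#' @param timeline An [acquisition_timeline()].
#' @param e An `etco2_epochs`.
#'
#' @return Scalar CVR, %/mmHg.
#' @export
roi_cvr <- function(series, mask, timeline, e) {
  tc <- roi_time_course(series, mask)
  cvr_from_epochs(epoch_average(tc, timeline), e)
}

#' Voxelwise CVR map
#'
#' Epoch-averages the series per voxel and applies the reactivity
#' quotient elementwise. Voxels with non-positive room-air baseline
#' (possible in noisy perfusion-difference data) are removed from the
#' map's mask and tallied, not clipped: CVR is undefined there.
#'
#' @param series A `processed_series` holding a 4D array.
#' @param wb_mask Logical 3D analysis mask.
#' @param timeline An [acquisition_timeline()].
#' @param e An `etco2_epochs`.
#'
#' @return A `cvr_map`: `values` (3D, %/mmHg, `NA` outside the mask),
#'   `modality` (`"asl"` or `"bold"`), `mask`, and `n_excluded` (voxels
#'   dropped for non-positive baseline).
#' @export
make_cvr_map <- function(series, wb_mask, timeline, e) {
  em <- epoch_average(series, timeline)
  vals <- cvr_from_epochs(em, e)
  bad <- wb_mask & (em$s_ra <= 0)
  mask <- wb_mask & !bad
  vals[!mask] <- NA_real_
  modality <- if (series$kind == "perfusion-weighted") "asl" else "bold"
  structure(list(values = vals, modality = modality, mask = mask,
                 n_excluded = sum(bad)),
            class = "cvr_map")
}

#' @export
print.cvr_map <- function(x, ...) {
  cat(sprintf(
    "<cvr_map> %s: %d voxels, median %.3g %%/mmHg, %d excluded (s_ra <= 0)\n",
    toupper(x$modality), sum(x$mask),
    stats::median(x$values[x$mask]), x$n_excluded))
  invisible(x)
}

#' Mean CVR of a map over an ROI
#'
#' @param map A `cvr_map`.
#' @param roi Logical 3D mask (intersected with the map's valid mask).
#' @return Scalar mean CVR, %/mmHg.
#' @export
map_roi_mean <- function(map, roi) {
  sel <- map$mask & roi
  if (!any(sel)) stop("ROI does not intersect the map's valid mask")
  mean(map$values[sel])
}
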