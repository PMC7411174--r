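#' Grow a vessel ROI on the complex-difference image
#'
#' Seeded region growing standing in for a manually drawn
#' superior-sagittal-sinus ROI: starting from a seed voxel on the vessel,
#' the 4-connected region of voxels whose complex-difference magnitude is
#' at least `threshold_frac` times the seed intensity is grown. An
#' externally supplied mask is accepted verbatim instead.
#'
#' @param pair A `pc_image_pair`.
#' @param seed Two-element integer index of the seed voxel, or `NULL` to
#'   use the brightest voxel of the complex-difference image.
#' @param threshold_frac Inclusion threshold as a fraction of the seed
#'   intensity (default 0.5).
#' @param mask Optional logical 2D mask used verbatim (the manual-ROI
#'   escape hatch).
#'
#' @return A `vessel_roi`: logical `mask`, `area` (cm^2), `n_voxels`.
#'   Warns if the grown region touches the image border.
#' @export
grow_vessel_roi <- function(pair, seed = NULL, threshold_frac = 0.5,
                            mask = NULL) {
  d <- dim(pair$cd_magnitude)
  if (!is.null(mask)) {
    if (!identical(dim(mask), d)) stop("mask dimensions do not match image")
    if (!any(mask)) stop("supplied mask is empty")
    return(structure(list(mask = mask, area = sum(mask) * pair$voxel_area,
                          n_voxels = sum(mask)),
                     class = "vessel_roi"))
  }
  cd <- pair$cd_magnitude
  if (is.null(seed)) {
    seed <- arrayInd(which.max(cd), d)[1, ]
  }
  seed <- as.integer(seed)
  if (any(seed < 1L) || any(seed > d)) stop("seed outside image")
  sv <- cd[seed[1], seed[2]]
  if (sv <= 0) stop("seed voxel has no complex-difference signal")
  robust_max <- stats::quantile(cd, 0.98, names = FALSE)
  if (sv < 0.5 * robust_max) {
    stop("seed intensity far below the vessel signal: seed not on vessel")
  }
  thr <- threshold_frac * sv
  grown <- array(FALSE, dim = d)
  grown[seed[1], seed[2]] <- TRUE
  frontier <- matrix(seed, ncol = 2)
  while (nrow(frontier)) {
    nb <- rbind(frontier + rep(c(1L, 0L), each = nrow(frontier)),
                frontier + rep(c(-1L, 0L), each = nrow(frontier)),
                frontier + rep(c(0L, 1L), each = nrow(frontier)),
                frontier + rep(c(0L, -1L), each = nrow(frontier)))
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * d[1]
    keep <- !grown[lin] & cd[lin] >= thr
    lin <- unique(lin[keep])
    grown[lin] <- TRUE
    frontier <- cbind((lin - 1L) %% d[1] + 1L, (lin - 1L) %/% d[1] + 1L)
  }
  if (any(grown[1, ]) || any(grown[d[1], ]) ||
      any(grown[, 1]) || any(grown[, d[2]])) {
    warning("vessel ROI touches the image border")
  }
  structure(list(mask = grown, area = sum(grown) * pair$voxel_area,
                 n_voxels = sum(grown)),
            class = "vessel_roi")
}

#' @export
print.vessel_roi <- function(x, ...) {
  cat(sprintf("<vessel_roi> %d voxels, %.4g cm^2\n", x$n_voxels, x$area))
  invisible(x)
}

#' Blood flux through a vessel ROI
#'
#' Flux = ROI area (cm^2) x mean through-plane velocity over the ROI
#' (cm/s) x 60, in ml/min — identically the sum of per-voxel velocity x
#' voxel area x 60.
#'
#' @param pair A `pc_image_pair`.
#' @param roi A `vessel_roi`.
#'
#' @return Flux in ml/min. Warns if the ROI mean velocity is not
#'   positive (flow direction or ROI misplacement).
#' @export
compute_flux <- function(pair, roi) {
  if (!any(roi$mask)) stop("empty ROI")
  v_mean <- mean(pair$velocity[roi$mask])
  if (v_mean <= 0) {
    warning("mean ROI velocity <= 0: check flow sign convention or ROI placement")
  }
  roi$area * v_mean * 60
}

#' Phase-contrast CVR
#'
#' \deqn{PC\,CVR = 100 \, \frac{(Flux_{HC} - Flux_{RA}) / Flux_{RA}}{
#' EtCO2_{HC} - EtCO2_{RA}}}{PC CVR = 100 * ((Flux_HC - Flux_RA)/Flux_RA)
#' / (EtCO2_HC - EtCO2_RA)} in %/mmHg, with the EtCO2 epochs taken over
#' the two 30-s phase-contrast scan windows.
#'
#' @param flux A `flux_pair` (or list with `flux_ra`, `flux_hc`, ml/min).
#' @param e An `etco2_epochs`.
#' @return Scalar PC CVR, %/mmHg.
#' @export
pc_cvr <- function(flux, e) {
  if (flux$flux_ra <= 0) stop("flux_ra must be > 0")
  d_et <- e$etco2_hc - e$etco2_ra
  if (d_et == 0) stop("etco2_hc equals etco2_ra: CVR undefined")
  100 * (flux$flux_hc - flux$flux_ra) / flux$flux_ra / d_et
}

#' Construct a normocapnic/hypercapnic flux pair
#'
#' @param flux_ra,flux_hc Fluxes in ml/min (both > 0).
#' @return A `flux_pair` object.
#' @export
flux_pair <- function(flux_ra, flux_hc) {
  if (flux_ra <= 0 || flux_hc <= 0) stop("fluxes must be > 0")
  structure(list(flux_ra = flux_ra, flux_hc = flux_hc), class = "flux_pair")
}

#' Basal cerebral blood flow from normocapnic SSS flux
#'
#' \deqn{CBF = \frac{Flux_{RA}}{V_{brain} \times 1.06} \times 100 \times
#' \frac{1}{0.46}}{CBF = Flux_RA / (V_brain * 1.06) * 100 / 0.46}
#' in ml/100g/min: the superior sagittal sinus drains 46% of whole-brain
#' flow, brain tissue has density 1.06 g/ml, and the factor 100 expresses
#' flow per 100 g of tissue.
#'
#' @param flux_ra Normocapnic SSS flux, ml/min.
#' @param brain_volume Brain volume, ml (> 0).
#' @param k [quant_constants()].
#' @return Basal CBF, ml/100g/min.
#' @export
#' @examples
#' basal_cbf(320, 1400)  # 46.88 ml/100g/min
basal_cbf <- function(flux_ra, brain_volume, k = quant_constants()) {
  if (brain_volume <= 0) stop("brain_volume must be > 0")
  flux_ra / (brain_volume * k$brain_density) * k$per100 / k$sss_to_wb_ratio
}

#' Brain volume from tissue masks
#'
#' Whole-brain voxel count times voxel volume, converted mm^3 to ml.
#'
#' @param masks A `tissue_masks` object.
#' @return Volume in ml.
#' @export
brain_volume_from_masks <- function(masks) {
  sum(masks$wb) * prod(masks$voxel_size) / 1000
}
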