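#' Process one subject end to end
#'
#' Runs the full single-subject analysis on a `cvr_subject` (simulated by
#' [simulate_subject()] or assembled from files with [read_subject()]):
#'
#' 1. motion-correction hook (pass-through) and volume-wise Gaussian
#'    smoothing of both echoes;
#' 2. whole-brain mask segmentation from the smoothed mean echo-1 image;
#' 3. surround subtraction (echo 1, perfusion-weighted) and surround
#'    addition (echo 2, BOLD) time courses;
#' 4. end-tidal CO2 extraction from the capnograph trace and
#'    cross-correlation alignment to the whole-brain BOLD time course;
#' 5. epoch-averaged EtCO2 over the 4-min room-air/hypercapnic epochs and
#'    over the two 30-s phase-contrast scan windows;
#' 6. ROI CVR (time-course first) for WB/GM/WM in both modalities, and
#'    optionally voxelwise CVR maps;
#' 7. vessel ROI growth on both phase-contrast states, flux
#'    quantification, PC CVR and basal CBF.
#'
#' @param subject A `cvr_subject` list (`dual_echo`, `masks`, `capno`,
#'   `timeline`, `pc_ra`, `pc_hc`, `pc_ra_window`, `pc_hc_window`).
#' @param fwhm Smoothing kernel FWHM, mm (default 4).
#' @param max_lag,lag_step EtCO2 lag search grid, s.
#' @param make_maps Also compute voxelwise ASL/BOLD CVR maps.
#' @param wb_from_data Segment the whole-brain analysis mask from the
#'   smoothed mean echo-1 image (default); if `FALSE`, use the supplied
#'   `masks$wb`.
#' @param k [quant_constants()].
#'
#' @return A `cvr_fit`: `summary` (tibble: modality, compartment, cvr),
#'   `lag` (s), `etco2` (ASL and PC epoch objects), `flux` (`flux_pair`),
#'   `basal_cbf`, `brain_volume` (ml), `alignment`, `maps` (if requested),
#'   and `qc` (excluded-voxel tallies).
#' @export
process_subject <- function(subject, fwhm = 4, max_lag = 60, lag_step = 1,
                            make_maps = FALSE, wb_from_data = TRUE,
                            k = quant_constants()) {
  tl <- subject$timeline
  vs <- subject$masks$voxel_size

  e1 <- smooth_gaussian(motion_correct(subject$dual_echo$echo1), fwhm, vs)
  e2 <- smooth_gaussian(motion_correct(subject$dual_echo$echo2), fwhm, vs)

  mean_e1 <- array(rowMeans(matrix(e1, nrow = prod(dim(e1)[1:3]))),
                   dim = dim(e1)[1:3])
  wb <- if (wb_from_data) compute_wb_mask(mean_e1) else subject$masks$wb

  asl <- surround_subtract(e1, tl$first_volume_type, tl$tr)
  bold <- surround_add(e2, tl$tr)
  wb_bold_tc <- roi_time_course(bold, wb)

  etco2 <- extract_etco2(subject$capno)
  al <- align_etco2(etco2, wb_bold_tc, max_lag = max_lag,
                    lag_step = lag_step)
  e_asl <- epoch_etco2(al$aligned, tl$ra_window, tl$hc_window)
  e_pc <- epoch_etco2(al$aligned, subject$pc_ra_window, subject$pc_hc_window)

  rois <- list(wb = wb, gm = subject$masks$gm, wm = subject$masks$wm)
  summary_rows <- purrr::map(c("asl", "bold"), function(mod) {
    series <- if (mod == "asl") asl else bold
    purrr::imap(rois, function(mask, comp) {
      tibble::tibble(modality = mod, compartment = comp,
                     cvr = roi_cvr(series, mask, tl, e_asl))
    })
  })

  roi_ra <- grow_vessel_roi(subject$pc_ra)
  roi_hc <- grow_vessel_roi(subject$pc_hc)
  fl <- flux_pair(compute_flux(subject$pc_ra, roi_ra),
                  compute_flux(subject$pc_hc, roi_hc))
  pc <- pc_cvr(fl, e_pc)
  vol <- brain_volume_from_masks(subject$masks)
  cbf <- basal_cbf(fl$flux_ra, vol, k)

  summary <- dplyr::bind_rows(
    tibble::tibble(modality = "pc", compartment = "wb", cvr = pc),
    dplyr::bind_rows(purrr::flatten(summary_rows)))

  maps <- qc <- NULL
  if (make_maps) {
    maps <- list(asl = make_cvr_map(asl, wb, tl, e_asl),
                 bold = make_cvr_map(bold, wb, tl, e_asl))
    qc <- list(asl_excluded = maps$asl$n_excluded,
               bold_excluded = maps$bold$n_excluded)
  }

  structure(list(summary = summary, lag = al$lag, alignment = al,
                 etco2 = list(asl = e_asl, pc = e_pc),
                 flux = fl, basal_cbf = cbf, brain_volume = vol,
                 wb_mask = wb, maps = maps, qc = qc),
            class = "cvr_fit")
}

#' @export
print.cvr_fit <- function(x, ...) {
  cat("<cvr_fit>\n")
  cat(sprintf("  lag %.3g s; EtCO2 %.1f -> %.1f mmHg (ASL epochs)\n",
              x$lag, x$etco2$asl$etco2_ra, x$etco2$asl$etco2_hc))
  cat(sprintf("  SSS flux %.1f -> %.1f ml/min; basal CBF %.1f ml/100g/min\n",
              x$flux$flux_ra, x$flux$flux_hc, x$basal_cbf))
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.cvr_fit <- function(x, ...) {
  x$summary
}

#' @export
glance.cvr_fit <- function(x, ...) {
  tibble::tibble(
    lag = x$lag,
    etco2_ra = x$etco2$asl$etco2_ra, etco2_hc = x$etco2$asl$etco2_hc,
    flux_ra = x$flux$flux_ra, flux_hc = x$flux$flux_hc,
    basal_cbf = x$basal_cbf, brain_volume = x$brain_volume,
    alignment_r = x$alignment$correlation
  )
}

#' Process a cohort of synthetic subjects into a CVR record table
#'
#' Simulates and processes each subject of a [make_cohort()] design in
#' turn (constant memory), returning the long per-subject CVR table that
#' [summarize_cohort()] consumes, joined with group/sex/site labels and
#' basal CBF.
#'
#' @param cohort A `cvr_cohort`.
#' @param grid_dims,voxel_size Phantom geometry per subject.
#' @param ... Passed to [process_subject()].
#'
#' @return A tibble: `subject_id`, `group`, `sex`, `site`, `modality`,
#'   `compartment`, `cvr`, `basal_cbf`, `lag`.
#' @export
process_cohort <- function(cohort, grid_dims = c(32L, 32L, 16L),
                           voxel_size = c(3.4, 3.4, 6), ...) {
  purrr::map2(cohort$params, seq_len(nrow(cohort$truth)), function(p, i) {
    subj <- simulate_subject(p, grid_dims = grid_dims,
                             voxel_size = voxel_size)
    fit <- process_subject(subj, ...)
    dplyr::mutate(fit$summary,
                  subject_id = cohort$truth$subject_id[i],
                  group = cohort$truth$group[i],
                  sex = cohort$truth$sex[i],
                  site = cohort$truth$site[i],
                  basal_cbf = fit$basal_cbf, lag = fit$lag)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("subject_id", "group", "sex", "site", "modality",
                  "compartment", "cvr", "basal_cbf", "lag")
}
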