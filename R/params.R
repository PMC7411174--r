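#' Ground-truth parameters for a synthetic subject
#'
#' Bundles every generative quantity the synthetic modality models need:
#' true CVR values per modality and tissue, basal superior-sagittal-sinus
#' (SSS) flux, the end-tidal CO2 (EtCO2) step, the lung-to-brain transit
#' lag, the hypercapnic labeling-efficiency confound, and noise/drift
#' levels. Defaults are the cohort point estimates of the study this
#' pipeline models: ASL CVR 5.6 (GM) / 5.1 (WM) %/mmHg, BOLD CVR 0.33 /
#' 0.19 %/mmHg, PC CVR 6.15 %/mmHg.
#'
#' @param cvr_true_gm,cvr_true_wm True ASL (perfusion) CVR in grey and
#'   white matter, %/mmHg.
#' @param bold_cvr_true_gm,bold_cvr_true_wm True BOLD CVR per tissue,
#'   %/mmHg.
#' @param pc_cvr_true True global (phase-contrast) CVR, %/mmHg.
#' @param basal_flux_sss Normocapnic SSS blood flux, ml/min. The default is
#'   matched to the default phantom's brain volume so that basal CBF comes
#'   out physiological (~60 ml/100g/min); see the methods vignette.
#' @param brain_volume Brain volume in ml, or `NA` to derive it from the
#'   tissue masks at simulation time.
#' @param etco2_baseline Normocapnic end-tidal CO2, mmHg.
#' @param etco2_step Hypercapnic EtCO2 increase, mmHg (must be >= 0).
#' @param lung_to_brain_lag Delay between the gas switch seen at the mouth
#'   and the brain response, seconds (>= 0).
#' @param labeling_efficiency_hc Fractional pCASL labeling efficiency
#'   retained during hypercapnia, in (0, 1]. Values below 1 reproduce the
#'   reduced-labeling-efficiency confound that biases ASL CVR low.
#' @param noise_sd_asl,noise_sd_bold Gaussian noise SD added to the raw
#'   echo-1 / echo-2 volumes, signal a.u.
#' @param drift_slope Linear scanner drift added to both echoes, a.u./s.
#' @param seed Integer seed; all randomness in the generator flows
#'   through it.
#'
#' @return An object of class `ground_truth_params` (a named list).
#' @export
#' @examples
#' p <- ground_truth_params(seed = 1)
#' p$cvr_true_gm
ground_truth_params <- function(cvr_true_gm = 5.6,
                                cvr_true_wm = 5.1,
                                bold_cvr_true_gm = 0.33,
                                bold_cvr_true_wm = 0.19,
                                pc_cvr_true = 6.15,
                                basal_flux_sss = 120,
                                brain_volume = NA_real_,
                                etco2_baseline = 40,
                                etco2_step = 9,
                                lung_to_brain_lag = 12,
                                labeling_efficiency_hc = 1,
                                noise_sd_asl = 2,
                                noise_sd_bold = 12,
                                drift_slope = 0,
                                seed = 1L) {
  p <- list(
    cvr_true_gm = cvr_true_gm, cvr_true_wm = cvr_true_wm,
    bold_cvr_true_gm = bold_cvr_true_gm, bold_cvr_true_wm = bold_cvr_true_wm,
    pc_cvr_true = pc_cvr_true,
    basal_flux_sss = basal_flux_sss, brain_volume = brain_volume,
    etco2_baseline = etco2_baseline, etco2_step = etco2_step,
    lung_to_brain_lag = lung_to_brain_lag,
    labeling_efficiency_hc = labeling_efficiency_hc,
    noise_sd_asl = noise_sd_asl, noise_sd_bold = noise_sd_bold,
    drift_slope = drift_slope, seed = as.integer(seed)
  )
  cvrs <- c(cvr_true_gm, cvr_true_wm, bold_cvr_true_gm, bold_cvr_true_wm,
            pc_cvr_true)
  if (!all(is.finite(cvrs))) stop("all CVR values must be finite")
  if (labeling_efficiency_hc <= 0 || labeling_efficiency_hc > 1) {
    stop("labeling_efficiency_hc must be in (0, 1]")
  }
  if (etco2_step < 0) stop("etco2_step must be >= 0")
  if (lung_to_brain_lag < 0) stop("lung_to_brain_lag must be >= 0")
  if (noise_sd_asl < 0 || noise_sd_bold < 0) stop("noise SDs must be >= 0")
  structure(p, class = "ground_truth_params")
}

#' Acquisition timeline of the dual-echo ASL/BOLD scan
#'
#' Defaults reproduce the 10-min dual-echo pCASL protocol: TR 4.006 s, 150
#' volumes, gas switch from room air to 5% CO2 at 4 min, room-air epoch
#' = first 4 min, hypercapnic epoch = last 4 min, middle 2 min discarded
#' (physiology not in steady state). Windows are half-open `[t0, t1)` and
#' a volume's time is its start time, `index * TR` (0-based).
#'
#' @param tr Repetition time, seconds.
#' @param n_volumes Number of volumes (must be even: alternating
#'   control/label).
#' @param gas_switch_time Time of the room-air to CO2 switch, seconds from
#'   scan start.
#' @param ra_window,hc_window Two-element numeric `[t0, t1)` windows (s)
#'   used as the room-air and hypercapnic averaging epochs.
#' @param first_volume_type `"control"` or `"label"`.
#'
#' @return An `acquisition_timeline` object.
#' @export
#' @examples
#' tl <- acquisition_timeline()
#' volume_times(tl)[1:4]
acquisition_timeline <- function(tr = 4.006,
                                 n_volumes = 150L,
                                 gas_switch_time = 240,
                                 ra_window = c(0, 240),
                                 hc_window = c(360, 600.9),
                                 first_volume_type = c("control", "label")) {
  first_volume_type <- match.arg(first_volume_type)
  n_volumes <- as.integer(n_volumes)
  if (n_volumes %% 2L != 0L) stop("n_volumes must be even")
  if (tr <= 0) stop("tr must be positive")
  stopifnot(length(ra_window) == 2L, length(hc_window) == 2L)
  if (ra_window[2] > hc_window[1]) stop("ra_window and hc_window must be disjoint")
  if (hc_window[1] < gas_switch_time) {
    stop("hc_window must start at or after the gas switch")
  }
  structure(list(tr = tr, n_volumes = n_volumes,
                 gas_switch_time = gas_switch_time,
                 ra_window = as.numeric(ra_window),
                 hc_window = as.numeric(hc_window),
                 first_volume_type = first_volume_type),
            class = "acquisition_timeline")
}

#' Acquisition time of each volume (seconds, volume start)
#'
#' @param timeline An [acquisition_timeline()].
#' @return Numeric vector of length `n_volumes`.
#' @export
volume_times <- function(timeline) {
  (seq_len(timeline$n_volumes) - 1L) * timeline$tr
}

#' Control/label parity of each volume
#'
#' @param timeline An [acquisition_timeline()].
#' @return Character vector, `"control"`/`"label"` per volume.
#' @export
volume_parity <- function(timeline) {
  first <- timeline$first_volume_type
  other <- if (first == "control") "label" else "control"
  rep(c(first, other), length.out = timeline$n_volumes)
}

#' Quantification constants for SSS flux to whole-brain CBF conversion
#'
#' @param sss_to_wb_ratio Fraction of whole-brain blood flow drained by the
#'   superior sagittal sinus (dimensionless, default 0.46).
#' @param brain_density Mass density of brain tissue, g/ml (default 1.06).
#'
#' @return A `quant_constants` object.
#' @export
quant_constants <- function(sss_to_wb_ratio = 0.46, brain_density = 1.06) {
  if (sss_to_wb_ratio <= 0 || brain_density <= 0) {
    stop("constants must be positive")
  }
  structure(list(sss_to_wb_ratio = sss_to_wb_ratio,
                 brain_density = brain_density, per100 = 100),
            class = "quant_constants")
}

#' @export
print.ground_truth_params <- function(x, ...) {
  cat("<ground_truth_params>\n")
  cat(sprintf("  ASL CVR  GM/WM : %.3g / %.3g %%/mmHg\n",
              x$cvr_true_gm, x$cvr_true_wm))
  cat(sprintf("  BOLD CVR GM/WM : %.3g / %.3g %%/mmHg\n",
              x$bold_cvr_true_gm, x$bold_cvr_true_wm))
  cat(sprintf("  PC CVR         : %.3g %%/mmHg\n", x$pc_cvr_true))
  cat(sprintf("  EtCO2          : %.3g + %.3g mmHg, lag %.3g s\n",
              x$etco2_baseline, x$etco2_step, x$lung_to_brain_lag))
  cat(sprintf("  labeling eff HC: %.3g; noise ASL/BOLD %.3g/%.3g; seed %d\n",
              x$labeling_efficiency_hc, x$noise_sd_asl, x$noise_sd_bold,
              x$seed))
  invisible(x)
}

#' @export
print.acquisition_timeline <- function(x, ...) {
  cat(sprintf(
    "<acquisition_timeline> TR %.3f s x %d vols; switch %g s; RA [%g,%g); HC [%g,%g); first %s\n",
    x$tr, x$n_volumes, x$gas_switch_time, x$ra_window[1], x$ra_window[2],
    x$hc_window[1], x$hc_window[2], x$first_volume_type))
  invisible(x)
}
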