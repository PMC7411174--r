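#' @keywords internal
#' Smoothstep ramp from 0 to 1 over `rise` seconds, starting at u = 0.
.ramp <- function(u, rise = 20) {
  x <- pmin(pmax(u / rise, 0), 1)
  x * x * (3 - 2 * x)
}

# Tissue-dependent signal levels of the generator (a.u.). M0: equilibrium
# magnetization seen by echo 1; dm: perfusion-weighted control-label
# difference at normocapnia; b0: echo-2 (BOLD-weighted) baseline.
.tissue_levels <- list(
  m0 = c(gm = 1000, wm = 750, other = 600),
  dm = c(gm = 12, wm = 5, other = 2),
  b0 = c(gm = 900, wm = 700, other = 550)
)

#' Nested-ellipsoid tissue phantom
#'
#' Builds deterministic grey-matter (GM), white-matter (WM) and whole-brain
#' (WB) masks on a shared grid: a WB ellipsoid filling most of the grid, a
#' WM ellipsoidal core, and a GM shell between the WM core and an outer
#' GM boundary. GM and WM are disjoint; both lie inside WB. The remaining
#' WB tissue is split into `peri_wm` / `peri_gm` halves (bordering the WM
#' core and the GM shell respectively) so that the generator can assign
#' boundary tissue the reactivity of its neighboring ROI — keeping
#' ROI means unbiased under spatial smoothing.
#'
#' @param grid_dims Integer vector of 3 grid sizes (each >= 8).
#' @param voxel_size Numeric vector of 3 voxel edge lengths in mm (a scalar
#'   is recycled).
#'
#' @return A `tissue_masks` object: logical 3D arrays `gm`, `wm`, `wb`
#'   (plus generator-internal `peri_gm`, `peri_wm`) and `voxel_size` (mm).
#' @export
#' @examples
#' m <- make_phantom_masks(c(16, 16, 8), 3)
#' sum(m$gm & m$wm)  # disjoint
make_phantom_masks <- function(grid_dims = c(32L, 32L, 16L),
                               voxel_size = c(3.4, 3.4, 6)) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 8L)) {
    stop("grid_dims must be 3 integers, each >= 8")
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be strictly positive")

  centre <- (grid_dims + 1) / 2
  semi <- (grid_dims - 1) / 2 * c(0.9, 0.9, 0.85)
  idx <- lapply(seq_len(3L), function(a) {
    (seq_len(grid_dims[a]) - centre[a]) / semi[a]
  })
  # squared normalized ellipsoidal radius on the full grid
  r2 <- outer(outer(idx[[1]]^2, idx[[2]]^2, `+`), idx[[3]]^2, `+`)
  wb <- r2 <= 1
  wm <- r2 <= 0.42^2
  gm <- r2 <= 0.85^2 & r2 > 0.56^2
  peri_wm <- r2 > 0.42^2 & r2 <= 0.49^2
  peri_gm <- wb & !wm & !gm & !peri_wm
  structure(list(gm = gm, wm = wm, wb = wb,
                 peri_gm = peri_gm, peri_wm = peri_wm,
                 voxel_size = voxel_size),
            class = "tissue_masks")
}

#' @export
print.tissue_masks <- function(x, ...) {
  cat(sprintf("<tissue_masks> grid %s; voxel %s mm; wb/gm/wm voxels %d/%d/%d\n",
              paste(dim(x$wb), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              sum(x$wb), sum(x$gm), sum(x$wm)))
  invisible(x)
}

#' Simulate a capnograph CO2 waveform
#'
#' Generates a rounded-sawtooth breathing waveform (fast rise to the
#' end-tidal plateau during exhalation, fast fall on inspiration) whose
#' per-breath maximum equals `etco2_baseline` before the gas switch and
#' `etco2_baseline + etco2_step` after it, with a smooth transition
#' completing within 20 s. The trace itself steps at the switch time; the
#' lung-to-brain lag is applied to the brain signal by
#' [simulate_dual_echo()], not here — that asymmetry is what the
#' cross-correlation alignment later has to recover.
#'
#' @param params [ground_truth_params()].
#' @param duration Trace duration, seconds.
#' @param sample_rate Sampling rate, Hz (>= 4).
#' @param breath_period Breathing period, seconds (>= 2).
#' @param gas_switch_time Time of the gas switch on the trace clock, s.
#' @param start_time Time of the first sample, s (may be negative so the
#'   trace covers phase-contrast scans acquired before the main scan).
#' @param noise_sd SD of additive Gaussian measurement noise, mmHg.
#'
#' @return A `capno_trace`: tibble with columns `time` (s) and `co2`
#'   (mmHg), with a `sample_rate` attribute.
#' @export
simulate_etco2_trace <- function(params,
                                 duration = 720,
                                 sample_rate = 10,
                                 breath_period = 4,
                                 gas_switch_time = 240,
                                 start_time = -60,
                                 noise_sd = 0) {
  if (sample_rate < 4) stop("sample_rate must be >= 4 Hz")
  if (breath_period < 2) stop("breath_period must be >= 2 s")
  if (start_time + duration <= gas_switch_time) {
    stop("duration must extend past the gas switch time")
  }
  time <- seq(start_time, start_time + duration - 1 / sample_rate,
              by = 1 / sample_rate)
  # end-tidal envelope: steps at the switch, smooth over 20 s
  env <- params$etco2_baseline +
    params$etco2_step * .ramp(time - gas_switch_time)
  phase <- ((time - start_time) %% breath_period) / breath_period
  # exhalation: fast rise, then a flat alveolar plateau at the end-tidal
  # value; inspiration: fast fall toward near-zero inspired CO2
  shape <- ifelse(phase < 0.4,
                  0.12 + 0.88 * (phase / 0.4)^0.4,
                  ifelse(phase <= 0.7, 1,
                         1 - 0.88 * ((phase - 0.7) / 0.3)^1.5))
  co2 <- env * shape
  if (noise_sd > 0) {
    co2 <- co2 + withr::with_seed(params$seed + 101L,
                                  stats::rnorm(length(co2), 0, noise_sd))
    co2 <- pmax(co2, 0)
  }
  new_capno_trace(time, co2, sample_rate)
}

#' Construct a capnograph trace object
#'
#' @param time Sample times, s (strictly increasing).
#' @param co2 CO2 partial pressure, mmHg (non-negative).
#' @param sample_rate Sampling rate, Hz.
#' @return A `capno_trace` tibble.
#' @export
new_capno_trace <- function(time, co2, sample_rate) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(co2 < 0)) stop("co2 must be >= 0")
  out <- tibble::tibble(time = time, co2 = co2)
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("capno_trace", class(out))
  out
}

# Brain-side EtCO2 change (mmHg above baseline) at acquisition times t:
# delayed by the lung-to-brain lag relative to the trace's gas switch.
.brain_dco2 <- function(t, params, gas_switch_time) {
  params$etco2_step * .ramp(t - gas_switch_time - params$lung_to_brain_lag)
}

# Hypercapnic labeling-efficiency factor over time (1 at normocapnia,
# labeling_efficiency_hc once the hypercapnic plateau is reached).
.label_eff <- function(t, params, gas_switch_time) {
  1 + (params$labeling_efficiency_hc - 1) *
    .ramp(t - gas_switch_time - params$lung_to_brain_lag)
}

#' Simulate a dual-echo pCASL/BOLD acquisition
#'
#' Echo 1 (ASL-weighted) control volumes carry the M0 map; label volumes
#' carry M0 minus the perfusion-weighted difference signal
#' \eqn{\Delta M(t)}, which is tissue dependent, scales with the (lagged)
#' EtCO2 change through the true ASL CVR, and is multiplied by the
#' hypercapnic labeling efficiency. Echo 2 (BOLD-weighted) volumes carry a
#' fractional BOLD step of `bold_cvr_true * dEtCO2(t)` percent over
#' baseline (GM amplitude > WM), plus a small control/label alternation
#' that surround addition must cancel. An optional shared linear drift and
#' seeded Gaussian noise are added last.
#'
#' @param params [ground_truth_params()].
#' @param masks [make_phantom_masks()] output (or compatible).
#' @param timeline [acquisition_timeline()].
#' @param label_contamination Fractional echo-2 signal reduction on label
#'   volumes (the labeling effect the BOLD stream must average out).
#'
#' @return A `dual_echo_series`: 4D arrays `echo1`, `echo2` (x,y,z,t) and
#'   the `timeline`.
#' @export
simulate_dual_echo <- function(params, masks, timeline,
                               label_contamination = 0.005) {
  dims <- dim(masks$wb)
  nt <- timeline$n_volumes
  t_acq <- volume_times(timeline)
  total <- nt * timeline$tr
  if (timeline$ra_window[2] > total || timeline$hc_window[2] > total + timeline$tr) {
    stop("timeline windows must fit within n_volumes * tr")
  }

  # peri_* tissue borders the corresponding ROI and carries its CVR ratio
  # (amplitudes stay low): smoothing then cannot bias the ROI means.
  tissue <- array("none", dim = dims)
  tissue[masks$wb] <- "peri_gm"
  if (!is.null(masks$peri_wm)) tissue[masks$peri_wm] <- "peri_wm"
  tissue[masks$gm] <- "gm"
  tissue[masks$wm] <- "wm"

  amp <- function(lvl) {
    key <- c(gm = "gm", wm = "wm", peri_gm = "other", peri_wm = "other")
    out <- array(0, dim = dims)
    for (tt in names(key)) {
      out[tissue == tt] <- .tissue_levels[[lvl]][[key[[tt]]]]
    }
    out
  }
  m0 <- amp("m0")
  dm0 <- amp("dm")
  b0 <- amp("b0")

  cvr_map <- array(0, dim = dims)
  cvr_map[tissue %in% c("gm", "peri_gm")] <- params$cvr_true_gm
  cvr_map[tissue %in% c("wm", "peri_wm")] <- params$cvr_true_wm
  bold_map <- array(0, dim = dims)
  bold_map[tissue %in% c("gm", "peri_gm")] <- params$bold_cvr_true_gm
  bold_map[tissue %in% c("wm", "peri_wm")] <- params$bold_cvr_true_wm

  dco2 <- .brain_dco2(t_acq, params, timeline$gas_switch_time)
  eff <- .label_eff(t_acq, params, timeline$gas_switch_time)
  parity <- volume_parity(timeline)

  nvox <- prod(dims)
  echo1 <- array(0, dim = c(dims, nt))
  echo2 <- array(0, dim = c(dims, nt))
  for (i in seq_len(nt)) {
    dm_t <- dm0 * (1 + cvr_map * dco2[i] / 100) * eff[i]
    v1 <- if (parity[i] == "control") m0 else m0 - dm_t
    v2 <- b0 * (1 + bold_map * dco2[i] / 100)
    if (parity[i] == "label") v2 <- v2 * (1 - label_contamination)
    drift <- params$drift_slope * t_acq[i]
    echo1[, , , i] <- v1 + drift
    echo2[, , , i] <- v2 + drift
  }
  if (params$noise_sd_asl > 0 || params$noise_sd_bold > 0) {
    withr::with_seed(params$seed + 202L, {
      if (params$noise_sd_asl > 0) {
        echo1 <- echo1 + stats::rnorm(nvox * nt, 0, params$noise_sd_asl)
      }
      if (params$noise_sd_bold > 0) {
        echo2 <- echo2 + stats::rnorm(nvox * nt, 0, params$noise_sd_bold)
      }
    })
  }
  structure(list(echo1 = echo1, echo2 = echo2, timeline = timeline),
            class = "dual_echo_series")
}

#' @export
print.dual_echo_series <- function(x, ...) {
  d <- dim(x$echo1)
  cat(sprintf("<dual_echo_series> %dx%dx%d x %d volumes, TR %.3f s\n",
              d[1], d[2], d[3], d[4], x$timeline$tr))
  invisible(x)
}

#' Simulate a phase-contrast image pair (normocapnia + hypercapnia)
#'
#' Builds a 2D complex-difference magnitude image and a velocity map with
#' an elliptical vessel (the superior sagittal sinus seen in cross
#' section) carrying a parabolic through-plane velocity profile. The
#' discrete vessel velocities are scaled so that integrated flux
#' (sum of velocity x voxel area x 60) equals `basal_flux_sss` ml/min at
#' normocapnia and `basal_flux_sss * (1 + pc_cvr_true * etco2_step / 100)`
#' at hypercapnia. Background velocity is small zero-mean noise.
#'
#' @param params [ground_truth_params()].
#' @param slice_dims Two integers, image matrix size.
#' @param voxel_area In-plane voxel area, cm^2.
#' @param venc Velocity-encoding limit, cm/s; requested fluxes implying a
#'   peak velocity at or above it are rejected.
#' @param vessel_semiaxes Vessel ellipse semi-axes in voxels.
#' @param background_noise_sd SD of background velocity noise, cm/s.
#'
#' @return A list with elements `ra` and `hc`, each a `pc_image_pair`:
#'   `cd_magnitude`, `velocity`, `voxel_area`, `venc`, `state`, and the
#'   ground-truth `vessel_mask`.
#' @export
simulate_pc_pair <- function(params,
                             slice_dims = c(64L, 64L),
                             voxel_area = 0.0052,
                             venc = 80,
                             vessel_semiaxes = c(7, 5),
                             background_noise_sd = 0.3) {
  if (params$basal_flux_sss <= 0) stop("basal_flux_sss must be > 0")
  slice_dims <- as.integer(slice_dims)
  centre <- (slice_dims + 1) / 2
  xi <- (seq_len(slice_dims[1]) - centre[1]) / vessel_semiaxes[1]
  yi <- (seq_len(slice_dims[2]) - centre[2]) / vessel_semiaxes[2]
  r2 <- outer(xi^2, yi^2, `+`)
  vessel <- r2 < 1
  if (!any(vessel)) stop("vessel ellipse contains no voxels")
  profile <- ifelse(vessel, 1 - r2, 0)  # parabolic through-plane profile

  flux_hc <- params$basal_flux_sss *
    (1 + params$pc_cvr_true * params$etco2_step / 100)

  make_state <- function(flux, state, seed_off) {
    # ml/min = sum(v) * voxel_area * 60; solve for the peak velocity
    vmax <- flux / (sum(profile) * voxel_area * 60)
    if (vmax >= venc) {
      stop(sprintf(
        "requested flux %.1f ml/min implies peak velocity %.1f >= venc %.1f cm/s",
        flux, vmax, venc))
    }
    velocity <- vmax * profile
    cd <- ifelse(vessel, 100 * (0.8 + 0.2 * profile), 0)
    withr::with_seed(params$seed + seed_off, {
      if (background_noise_sd > 0) {
        noise <- stats::rnorm(length(velocity), 0, background_noise_sd)
        velocity <- velocity + ifelse(vessel, 0, noise)
      }
      cd <- cd + abs(stats::rnorm(length(cd), 0, 1.5))
    })
    velocity <- array(velocity, dim = slice_dims)
    cd <- array(cd, dim = slice_dims)
    structure(list(cd_magnitude = cd, velocity = velocity,
                   voxel_area = voxel_area, venc = venc, state = state,
                   vessel_mask = vessel),
              class = "pc_image_pair")
  }
  list(ra = make_state(params$basal_flux_sss, "RA", 303L),
       hc = make_state(flux_hc, "HC", 404L))
}

#' @export
print.pc_image_pair <- function(x, ...) {
  cat(sprintf("<pc_image_pair> %s state, %dx%d, venc %g cm/s, vessel %d voxels\n",
              x$state, dim(x$velocity)[1], dim(x$velocity)[2], x$venc,
              sum(x$vessel_mask)))
  invisible(x)
}

#' Simulate one complete synthetic subject
#'
#' Bundles the full single-subject dataset the pipeline consumes: tissue
#' masks, the capnograph trace, the dual-echo ASL/BOLD series and the
#' normocapnic/hypercapnic phase-contrast pair, together with the
#' ground-truth parameters. If `params$brain_volume` is `NA` it is filled
#' in from the phantom masks.
#'
#' @param params [ground_truth_params()].
#' @param grid_dims,voxel_size Passed to [make_phantom_masks()].
#' @param timeline [acquisition_timeline()].
#' @param capno_noise_sd Measurement noise on the CO2 trace, mmHg.
#' @param ... Passed to [simulate_pc_pair()].
#'
#' @return A `cvr_subject` list: `params`, `masks`, `timeline`, `capno`,
#'   `dual_echo`, `pc_ra`, `pc_hc`, and suggested PC epoch windows
#'   `pc_ra_window` / `pc_hc_window` (the 30-s phase-contrast scans before
#'   and after the main acquisition).
#' @export
simulate_subject <- function(params = ground_truth_params(),
                             grid_dims = c(32L, 32L, 16L),
                             voxel_size = c(3.4, 3.4, 6),
                             timeline = acquisition_timeline(),
                             capno_noise_sd = 0.3,
                             ...) {
  masks <- make_phantom_masks(grid_dims, voxel_size)
  if (is.na(params$brain_volume)) {
    params$brain_volume <- brain_volume_from_masks(masks)
  }
  total <- timeline$n_volumes * timeline$tr
  capno <- simulate_etco2_trace(
    params, duration = total + 120, sample_rate = 10, breath_period = 4,
    gas_switch_time = timeline$gas_switch_time, start_time = -60,
    noise_sd = capno_noise_sd)
  de <- simulate_dual_echo(params, masks, timeline)
  pc <- simulate_pc_pair(params, ...)
  structure(list(params = params, masks = masks, timeline = timeline,
                 capno = capno, dual_echo = de,
                 pc_ra = pc$ra, pc_hc = pc$hc,
                 pc_ra_window = c(-45, -15),
                 pc_hc_window = c(total + 15, total + 45)),
            class = "cvr_subject")
}

#' @export
print.cvr_subject <- function(x, ...) {
  cat("<cvr_subject>\n")
  print(x$params)
  print(x$timeline)
  print(x$masks)
  invisible(x)
}

#' Default between-group effects for a synthetic cohort
#'
#' Group means and between-subject SDs used by [make_cohort()], one row
#' per generative parameter. Defaults follow the study cohort this
#' pipeline models (young/old PC CVR 6.59/5.46, ASL GM 5.74/5.31, ASL WM
#' 5.27/4.86, BOLD GM 0.33/0.33, BOLD WM 0.19/0.21 %/mmHg; basal CBF
#' 68.2/51.5 ml/100g/min), with SDs recovered from the reported standard
#' errors (SE x sqrt(n), n = 32 young / 17 old).
#'
#' @return A tibble with columns `param`, `young_mean`, `old_mean`,
#'   `young_sd`, `old_sd`.
#' @export
cohort_effects <- function() {
  tibble::tribble(
    ~param,             ~young_mean, ~old_mean, ~young_sd, ~old_sd,
    "pc_cvr_true",        6.59,        5.46,    0.41 * sqrt(32), 0.32 * sqrt(17),
    "cvr_true_gm",        5.74,        5.31,    0.35 * sqrt(32), 0.60 * sqrt(17),
    "cvr_true_wm",        5.27,        4.86,    0.53 * sqrt(32), 0.58 * sqrt(17),
    "bold_cvr_true_gm",   0.33,        0.33,    0.01 * sqrt(32), 0.01 * sqrt(17),
    "bold_cvr_true_wm",   0.19,        0.21,    0.01 * sqrt(32), 0.02 * sqrt(17),
    "basal_cbf",         68.2,        51.5,     3.9 * sqrt(32),  3.5 * sqrt(17)
  )
}

#' Generate a synthetic cohort
#'
#' Draws per-subject ground-truth parameters from group (young/old) normal
#' distributions, assigns sex and site labels, and returns a truth table
#' plus one [ground_truth_params()] object per subject. Image data are
#' simulated on demand with [simulate_subject()] on a per-subject params
#' object, keeping memory bounded.
#'
#' Basal CBF is drawn per subject and converted to an SSS flux via the
#' flux = CBF x volume x density x SSS-fraction / 100 relation, using the
#' default phantom volume, so that the phase-contrast stream reproduces
#' the drawn CBF.
#'
#' @param n_young,n_old Group sizes (each >= 2).
#' @param effects Tibble as returned by [cohort_effects()]; SDs must be
#'   non-negative (zero collapses a group onto its mean).
#' @param seed Integer master seed.
#' @param ... Overrides passed to every subject's [ground_truth_params()]
#'   (e.g. `labeling_efficiency_hc`, noise levels).
#'
#' @return A `cvr_cohort` list: `truth` (tibble: subject_id, group, sex,
#'   site, every drawn parameter, per-subject seed) and `params` (list of
#'   `ground_truth_params`).
#' @export
make_cohort <- function(n_young = 32L, n_old = 17L,
                        effects = cohort_effects(), seed = 1L, ...) {
  if (n_young < 2L || n_old < 2L) stop("need >= 2 subjects per group")
  if (any(effects$young_sd < 0) || any(effects$old_sd < 0)) {
    stop("between-subject sd must be >= 0")
  }
  n <- n_young + n_old
  group <- rep(c("young", "old"), c(n_young, n_old))
  # balanced deterministic assignment within group; sex pattern offset by
  # site so neither is collinear with the other
  sex <- site <- character(n)
  for (g in c("young", "old")) {
    i <- which(group == g)
    site[i] <- rep(c("siteA", "siteB"), length.out = length(i))
    sex[i] <- rep(c("M", "F", "F", "M"), length.out = length(i))
  }

  phantom_vol <- brain_volume_from_masks(make_phantom_masks())
  kc <- quant_constants()

  draws <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n), function(i) {
      g <- group[i]
      vals <- purrr::pmap_dbl(effects, function(param, young_mean, old_mean,
                                                young_sd, old_sd) {
        m <- if (g == "young") young_mean else old_mean
        s <- if (g == "young") young_sd else old_sd
        stats::rnorm(1, m, s)
      })
      stats::setNames(vals, effects$param)
    })
  })

  truth <- tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group, sex = sex, site = site
  )
  dm <- do.call(rbind, draws)
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(dm))
  truth$basal_flux_sss <- truth$basal_cbf * phantom_vol *
    kc$brain_density * kc$sss_to_wb_ratio / 100
  truth$seed <- as.integer(seed) + 1000L * seq_len(n)

  extra <- list(...)
  params <- purrr::map(seq_len(n), function(i) {
    args <- c(
      list(cvr_true_gm = truth$cvr_true_gm[i],
           cvr_true_wm = truth$cvr_true_wm[i],
           bold_cvr_true_gm = truth$bold_cvr_true_gm[i],
           bold_cvr_true_wm = truth$bold_cvr_true_wm[i],
           pc_cvr_true = truth$pc_cvr_true[i],
           basal_flux_sss = truth$basal_flux_sss[i],
           brain_volume = phantom_vol,
           seed = truth$seed[i]),
      extra)
    do.call(ground_truth_params, args)
  })
  structure(list(truth = truth, params = params), class = "cvr_cohort")
}

#' @export
print.cvr_cohort <- function(x, ...) {
  tab <- table(x$truth$group)
  cat(sprintf("<cvr_cohort> %d subjects (%s)\n", nrow(x$truth),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
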