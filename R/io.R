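#' Write a capnograph trace as delimited text
#'
#' Tab-separated columns `time_s`, `co2_mmHg`.
#'
#' @param trace A `capno_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_capno <- function(trace, path) {
  utils::write.table(
    data.frame(time_s = trace$time, co2_mmHg = trace$co2),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a capnograph trace from delimited text
#'
#' Expects columns `time_s` and `co2_mmHg` (tab- or comma-separated).
#'
#' @param path File path.
#' @return A `capno_trace`.
#' @export
read_capno <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "")
  if (!all(c("time_s", "co2_mmHg") %in% names(df))) {
    df <- utils::read.table(path, header = TRUE, sep = ",")
  }
  sr <- 1 / stats::median(diff(df$time_s))
  new_capno_trace(df$time_s, df$co2_mmHg, sr)
}

#' Export a processed ROI time course as delimited text
#'
#' @param series A `processed_series` holding a 1D time course.
#' @param path Output file path (tab-separated `time_s`, `value`).
#' @return `path`, invisibly.
#' @export
write_time_course <- function(series, path) {
  if (!is.null(dim(series$values))) stop("series must hold a 1D time course")
  t_s <- (seq_along(series$values) - 1L) * series$sampling_interval
  utils::write.table(data.frame(time_s = t_s, value = series$values),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic subject to a directory
#'
#' Materializes the dataset in standard formats: the dual echoes as two
#' 4D NIfTI files suffixed `_e1`/`_e2`, the tissue masks and
#' phase-contrast images as NIfTI, the capnograph trace as tab-separated
#' text, and the ground-truth parameters and PC scan windows as JSON.
#'
#' @param subject A `cvr_subject`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- subject$masks$voxel_size
  wr <- function(arr, name, pix = vs) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- pix
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(subject$dual_echo$echo1, "asl_e1", c(vs, subject$timeline$tr))
  wr(subject$dual_echo$echo2, "asl_e2", c(vs, subject$timeline$tr))
  for (m in c("gm", "wm", "wb")) {
    wr(subject$masks[[m]] * 1, paste0("mask_", m))
  }
  pc_pix <- rep(sqrt(subject$pc_ra$voxel_area) * 10, 2)  # cm^2 -> mm
  for (st in c("pc_ra", "pc_hc")) {
    wr(subject[[st]]$cd_magnitude, paste0(st, "_cd"), pc_pix)
    wr(subject[[st]]$velocity, paste0(st, "_velocity"), pc_pix)
  }
  write_capno(subject$capno, file.path(dir, "capno.tsv"))
  meta <- list(
    params = unclass(subject$params),
    timeline = unclass(subject$timeline),
    pc_ra_window = subject$pc_ra_window,
    pc_hc_window = subject$pc_hc_window,
    pc_voxel_area = subject$pc_ra$voxel_area,
    pc_venc = subject$pc_ra$venc)
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a subject dataset from a directory written by [write_subject()]
#'
#' @param dir Directory path.
#' @return A `cvr_subject`.
#' @export
read_subject <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  timeline <- do.call(acquisition_timeline, meta$timeline[
    c("tr", "n_volumes", "gas_switch_time", "ra_window", "hc_window",
      "first_volume_type")])
  params <- do.call(ground_truth_params, meta$params)
  rd <- function(name) {
    arr <- RNifti::readNifti(file.path(dir, paste0(name, ".nii.gz")))
    array(as.numeric(arr), dim = dim(arr))
  }
  masks <- structure(list(gm = rd("mask_gm") > 0.5, wm = rd("mask_wm") > 0.5,
                          wb = rd("mask_wb") > 0.5,
                          voxel_size = NULL),
                     class = "tissue_masks")
  hdr <- RNifti::niftiHeader(
    RNifti::readNifti(file.path(dir, "mask_wb.nii.gz")))
  masks$voxel_size <- hdr$pixdim[2:4]
  de <- structure(list(echo1 = rd("asl_e1"), echo2 = rd("asl_e2"),
                       timeline = timeline),
                  class = "dual_echo_series")
  mk_pc <- function(st, state) {
    structure(list(cd_magnitude = rd(paste0(st, "_cd")),
                   velocity = rd(paste0(st, "_velocity")),
                   voxel_area = meta$pc_voxel_area, venc = meta$pc_venc,
                   state = state, vessel_mask = NULL),
              class = "pc_image_pair")
  }
  structure(list(params = params, masks = masks, timeline = timeline,
                 capno = read_capno(file.path(dir, "capno.tsv")),
                 dual_echo = de,
                 pc_ra = mk_pc("pc_ra", "RA"), pc_hc = mk_pc("pc_hc", "HC"),
                 pc_ra_window = meta$pc_ra_window,
                 pc_hc_window = meta$pc_hc_window),
            class = "cvr_subject")
}

#' Write a CVR map as NIfTI
#'
#' @param map A `cvr_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel size, mm.
#' @return `path`, invisibly.
#' @export
write_cvr_map <- function(map, path, voxel_size = c(3.4, 3.4, 6)) {
  vals <- map$values
  vals[is.na(vals)] <- 0
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write single-subject quantitative results as JSON
#'
#' Flux pair, PC CVR, basal CBF, recovered lag and the per-compartment
#' CVR summary of a fit, in one JSON sidecar.
#'
#' @param fit A `cvr_fit`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(
    lag_s = fit$lag,
    etco2 = list(asl_ra = fit$etco2$asl$etco2_ra,
                 asl_hc = fit$etco2$asl$etco2_hc,
                 pc_ra = fit$etco2$pc$etco2_ra,
                 pc_hc = fit$etco2$pc$etco2_hc),
    flux_ra = fit$flux$flux_ra, flux_hc = fit$flux$flux_hc,
    basal_cbf = fit$basal_cbf, brain_volume = fit$brain_volume,
    cvr = fit$summary)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
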