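# ---- file formats ----------------------------------------------------------
# Long-format text tables with explicit units in the headers; YAML for
# configuration and calibration sessions; 16-bit TIFF + YAML sidecar for
# photon-count images.

#' Write a correlation curve to a tabular text file
#'
#' Tab-separated columns `lag_s`, `G`, preceded by commented header lines
#' carrying the channel, duration and mean intensity.
#'
#' @param curve a [correlation_curve()].
#' @param path output file.
#' @export
write_correlation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# channel: %s", curve$channel),
    sprintf("# duration_s: %.10g", curve$duration),
    sprintf("# mean_intensity_kHz: %.10g", curve$mean_intensity),
    sprintf("# run_id: %d", curve$run_id),
    "lag_s\tG"
  ), con)
  utils::write.table(data.frame(lag_s = curve$lags, G = curve$G), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
}

#' Read a correlation curve written by [write_correlation_curve()]
#'
#' @param path input file.
#' @return a [correlation_curve()].
#' @export
read_correlation_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    sub(paste0("^# ", key, ":\\s*"), "", m[1])
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  correlation_curve(
    lags = tab$lag_s, G = tab$G,
    channel = get("channel", "unknown"),
    mean_intensity = as.numeric(get("mean_intensity_kHz")),
    duration = as.numeric(get("duration_s")),
    run_id = as.integer(as.numeric(get("run_id", 1)))
  )
}

#' Write a calibration session file
#'
#' YAML with one entry per laser line: beam waist, axis ratio, derived
#' volumes, the standard dye used and the measurement conditions.
#'
#' @param calibrations named list of [effective_volume()] objects (names =
#'   laser lines or channel labels).
#' @param path output YAML file.
#' @param meta optional named list merged into the file header.
#' @export
write_calibration_session <- function(calibrations, path, meta = list()) {
  entry <- function(cal) {
    list(laser_line_nm = cal$laser_line, w0_um = cal$w0, z0_um = cal$z0,
         AR = cal$AR, V_eff_um3 = cal$V_eff, A_eff_um2 = cal$A_eff,
         timestamp = if (is.null(cal$timestamp)) NA else
           as.character(cal$timestamp))
  }
  yaml::write_yaml(c(meta, list(calibrations = lapply(calibrations, entry))),
                   path)
}

#' Read a calibration session file
#'
#' @param path YAML written by [write_calibration_session()].
#' @return named list of [effective_volume()] objects.
#' @export
read_calibration_session <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$calibrations)) stop("read_calibration_session: no calibrations")
  lapply(y$calibrations, function(e) {
    effective_volume(w0 = e$w0_um, AR = e$AR, laser_line = e$laser_line_nm,
                     timestamp = e$timestamp)
  })
}

#' Write per-cell quantification results as CSV
#'
#' @param cells list of `cell_quantification` objects (or one).
#' @param path output CSV.
#' @export
write_cell_csv <- function(cells, path) {
  if (inherits(cells, "cell_quantification")) cells <- list(cells)
  rows <- lapply(cells, function(q) data.frame(
    cell_id = as.character(q$cell_id),
    N_ref = q$N_ref, N_click = q$N_click, N_ligand = q$N_ligand,
    CE = q$CE, occupancy = q$occupancy, density_per_um2 = q$density,
    flags = paste(q$flags, collapse = ";")
  ))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read a titration CSV
#'
#' Columns: `c_molar`, `sigma_c`, `theta`, `sigma_theta`, `n_cells`.
#'
#' @param path CSV file.
#' @return a [titration_dataset()].
#' @export
read_titration_csv <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("c_molar", "theta") %in% names(tab)))
  titration_dataset(
    c = tab$c_molar, theta = tab$theta,
    sigma_c = if ("sigma_c" %in% names(tab)) tab$sigma_c else 0,
    sigma_theta = if ("sigma_theta" %in% names(tab)) tab$sigma_theta else 0,
    n_cells = if ("n_cells" %in% names(tab)) tab$n_cells else NA_integer_
  )
}

#' Write a titration dataset as CSV
#'
#' @param data a [titration_dataset()].
#' @param path output CSV.
#' @export
write_titration_csv <- function(data, path) {
  utils::write.csv(data.frame(
    c_molar = data$c, sigma_c = data$sigma_c, theta = data$theta,
    sigma_theta = data$sigma_theta, n_cells = data$n_cells
  ), path, row.names = FALSE)
}

#' Write a photon-count channel image as 16-bit TIFF with YAML sidecar
#'
#' Counts are stored losslessly as 16-bit samples; acquisition metadata
#' (dwell time, pixel size, laser line, power, channel) goes into
#' `<path>.yaml`.
#'
#' @param img a [channel_image()].
#' @param path output TIFF path.
#' @export
write_channel_tiff <- function(img, path) {
  stopifnot(inherits(img, "channel_image"))
  if (max(img$pixels) > 65535) stop("write_channel_tiff: counts exceed 16-bit range")
  tiff::writeTIFF(img$pixels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  yaml::write_yaml(list(
    dwell_time_us = img$dwell_time * 1e6,
    pixel_size_um = img$pixel_size,
    laser_line_nm = img$laser_line,
    P_tot_uW = img$P_tot,
    channel = img$channel
  ), paste0(path, ".yaml"))
}

#' Read a channel image written by [write_channel_tiff()]
#'
#' @param path TIFF path (expects `<path>.yaml` sidecar).
#' @return a [channel_image()].
#' @export
read_channel_tiff <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path)) {
    stop(sprintf("read_channel_tiff: missing metadata sidecar '%s'", meta_path))
  }
  m <- yaml::read_yaml(meta_path)
  for (k in c("dwell_time_us", "channel")) {
    if (is.null(m[[k]])) stop(sprintf("read_channel_tiff: metadata field '%s' missing", k))
  }
  channel_image(matrix(as.integer(round(px)), nrow = nrow(px)),
                dwell_time = m$dwell_time_us * 1e-6,
                pixel_size = if (is.null(m$pixel_size_um)) NA_real_ else m$pixel_size_um,
                channel = m$channel,
                laser_line = if (is.null(m$laser_line_nm)) NA_real_ else m$laser_line_nm,
                P_tot = if (is.null(m$P_tot_uW)) NA_real_ else m$P_tot_uW)
}

#' Read a per-site click-efficiency pattern CSV
#'
#' Columns: `site`, `condition` ("free"/"occupied"), `ce_mean`, `ce_sem`,
#' optionally `n_cells`.
#'
#' @param path CSV file.
#' @return data.frame suitable for [differential_ce()].
#' @export
read_pattern_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "condition", "ce_mean", "ce_sem")
  if (!all(need %in% names(tab))) {
    stop("read_pattern_csv: required columns: ", paste(need, collapse = ", "))
  }
  tab
}
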