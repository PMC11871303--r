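#' Write / read a 2D spectrum as a plain gridded-array file
#'
#' The intensity grid is stored as a whitespace-delimited text matrix
#' (rows = 1H points, columns = 15N points) with a DCF-format sidecar
#' (`<file>.meta`) recording the ppm axis ranges, point counts, nucleus
#' labels and noise level, so a spectrum round-trips without loss of axis
#' information.
#'
#' @param spectrum A [spectrum2d()] object.
#' @param path Output path for the grid; the sidecar is `<path>.meta`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(format(spectrum$intensities, digits = 10, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- matrix(c(
    range_H = paste(range(spectrum$axis_H), collapse = " "),
    range_N = paste(range(spectrum$axis_N), collapse = " "),
    n_H = as.character(length(spectrum$axis_H)),
    n_N = as.character(length(spectrum$axis_N)),
    nucleus_direct = "1H", nucleus_indirect = "15N",
    noise_sigma = as.character(spectrum$noise_sigma)), nrow = 1,
    dimnames = list(NULL, c("range_H", "range_N", "n_H", "n_N",
                            "nucleus_direct", "nucleus_indirect", "noise_sigma")))
  write.dcf(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  meta <- as.list(read.dcf(paste0(path, ".meta"))[1, ])
  rH <- as.numeric(strsplit(meta$range_H, " ")[[1]])
  rN <- as.numeric(strsplit(meta$range_N, " ")[[1]])
  I <- as.matrix(utils::read.table(path))
  dimnames(I) <- NULL
  spectrum2d(I, seq(rH[1], rH[2], length.out = as.integer(meta$n_H)),
             seq(rN[1], rN[2], length.out = as.integer(meta$n_N)),
             noise_sigma = suppressWarnings(as.numeric(meta$noise_sigma)))
}

#' Write / read a fitted peak list as TSV
#'
#' Columns: `residue_id`, `center_H_ppm`, `center_N_ppm`, `fwhm_H_ppm`,
#' `fwhm_N_ppm`, `amplitude`, `volume`, `converged`, `flags`.
#'
#' @param peaks Data frame of fitted peaks ([fit_peak()] rows).
#' @param path TSV path.
#' @return `path` invisibly / the peak data frame.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.frame(residue_id = peaks$residue_id,
                    center_H_ppm = peaks$center_H, center_N_ppm = peaks$center_N,
                    fwhm_H_ppm = peaks$fwhm_H, fwhm_N_ppm = peaks$fwhm_N,
                    amplitude = peaks$amplitude, volume = peaks$volume,
                    converged = peaks$converged, flags = peaks$flags,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  data.frame(residue_id = raw$residue_id,
             center_H = raw$center_H_ppm, center_N = raw$center_N_ppm,
             fwhm_H = raw$fwhm_H_ppm, fwhm_N = raw$fwhm_N_ppm,
             amplitude = raw$amplitude, volume = raw$volume,
             converged = raw$converged,
             flags = ifelse(is.na(raw$flags), "", raw$flags),
             stringsAsFactors = FALSE)
}

#' Write an assay table as CSV
#'
#' Normalises any of the simulators' outputs to the common long format
#' `(ligand_id, series, x_value, x_units, response, replicate)` where
#' `series` is the peptide or gene and `x_value` the concentration.
#'
#' @param table Simulator output (TR-FRET, FP).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(table, path) {
  if (!is.null(table$concentration_M)) {
    out <- data.frame(ligand_id = table$ligand_id, series = table$peptide,
                      x_value = table$concentration_M, x_units = "M",
                      response = table$response, replicate = table$replicate)
  } else if (!is.null(table$protein_M)) {
    out <- data.frame(ligand_id = table$ligand_id, series = table$peptide,
                      x_value = table$protein_M, x_units = "M",
                      response = table$response, replicate = table$replicate)
  } else {
    stop_invalid("unrecognised assay table layout")
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
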