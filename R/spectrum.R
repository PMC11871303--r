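#' Construct a 2D spectrum object
#'
#' A `Spectrum2D` is a gridded intensity surface with a direct 1H ppm axis
#' and an indirect 15N ppm axis. Axes are stored ascending internally;
#' inputs with descending axes (the usual display convention) are flipped
#' on construction together with the intensity grid, so all downstream
#' results in ppm are independent of storage direction.
#'
#' @param intensities Numeric matrix, `length(axis_H)` rows by
#'   `length(axis_N)` columns.
#' @param axis_H,axis_N Strictly monotone ppm coordinate vectors.
#' @param noise_sigma Optional known/estimated noise standard deviation.
#' @return An object of class `Spectrum2D`.
#' @export
spectrum2d <- function(intensities, axis_H, axis_N, noise_sigma = NA_real_) {
  if (!is.matrix(intensities)) stop_invalid("`intensities` must be a matrix")
  if (nrow(intensities) != length(axis_H) || ncol(intensities) != length(axis_N)) {
    stop_invalid("axis lengths must match the intensity grid dimensions")
  }
  for (ax in list(H = axis_H, N = axis_N)) {
    d <- diff(ax)
    if (length(ax) < 2L || !(all(d > 0) || all(d < 0))) {
      stop_invalid("axes must be strictly monotone with >= 2 points")
    }
  }
  if (is.unsorted(axis_H)) {
    axis_H <- rev(axis_H)
    intensities <- intensities[rev(seq_len(nrow(intensities))), , drop = FALSE]
  }
  if (is.unsorted(axis_N)) {
    axis_N <- rev(axis_N)
    intensities <- intensities[, rev(seq_len(ncol(intensities))), drop = FALSE]
  }
  structure(list(intensities = intensities,
                 axis_H = as.numeric(axis_H),
                 axis_N = as.numeric(axis_N),
                 noise_sigma = noise_sigma),
            class = "Spectrum2D")
}

#' @export
print.Spectrum2D <- function(x, ...) {
  cat(sprintf("Spectrum2D: %d x %d points, 1H %.3f..%.3f ppm, 15N %.2f..%.2f ppm\n",
              length(x$axis_H), length(x$axis_N),
              min(x$axis_H), max(x$axis_H), min(x$axis_N), max(x$axis_N)))
  if (!is.na(x$noise_sigma)) cat(sprintf("  noise sigma: %.4g\n", x$noise_sigma))
  invisible(x)
}

# Separable 2D Lorentzian evaluated on the full grid; fwhm convention:
# I = A / ((1 + (2(dH-cH)/wH)^2) (1 + (2(dN-cN)/wN)^2)), analytic volume
# A (pi/2)^2 wH wN.
lorentzian2d_grid <- function(axis_H, axis_N, amplitude, center_H, center_N,
                              fwhm_H, fwhm_N) {
  lh <- 1 / (1 + (2 * (axis_H - center_H) / fwhm_H)^2)
  ln <- 1 / (1 + (2 * (axis_N - center_N) / fwhm_N)^2)
  amplitude * outer(lh, ln)
}

#' Analytic volume of a separable 2D Lorentzian peak
#'
#' @param amplitude Peak height.
#' @param fwhm_H,fwhm_N FWHM linewidths (ppm).
#' @return Volume in intensity * ppm^2: `(pi/2)^2 * amplitude * fwhm_H * fwhm_N`.
#' @export
lorentzian_volume <- function(amplitude, fwhm_H, fwhm_N) {
  (pi / 2)^2 * amplitude * fwhm_H * fwhm_N
}

#' Simulate a two-state slow-exchange 2D spectrum for one ligand
#'
#' Realises the slow-exchange two-state peak model: for each reporter
#' residue the spectrum contains a repressive-state peak and an
#' active-state peak (pure 2D Lorentzians) whose volumes are
#' `f_rep * volume_total` and `(1 - f_rep) * volume_total`. At the
#' population endpoints (`f_rep` 0 or 1) exactly one peak is present.
#' Additive i.i.d. Gaussian noise is applied with standard deviation
#' `max(noiseless intensity) / snr`; `snr = Inf` gives a noiseless surface.
#'
#' An optional "decoy" peak (an unrelated residue stabilised in the same
#' spectral region, creating partial overlap) can be injected to exercise
#' overlap-exclusion logic downstream.
#'
#' @param ligand One-row subset of a [make_ligand_series()] data frame (or
#'   any list with `f_rep` and `ligand_id`).
#' @param residues Data frame of residue geometries, one row per residue,
#'   as from [residue_state_shifts()].
#' @param grid Named list with `range_H`, `range_N` (ppm, length-2) and
#'   `n_H`, `n_N` (points). Default covers the default residue geometry
#'   with >= 5 grid points per linewidth.
#' @param snr Signal-to-noise ratio (max peak height / noise sd); may be `Inf`.
#' @param seed Integer seed for the noise stream.
#' @param volume_total Common per-residue total volume scale (intensity * ppm^2).
#' @param decoy Optional list `(center_H, center_N, volume)` for the overlap
#'   decoy peak; linewidths follow the first residue.
#' @return A [spectrum2d()] object with attribute `"true_peaks"` (data frame
#'   of the noiseless peak parameters).
#' @export
simulate_spectrum <- function(ligand, residues = residue_state_shifts(),
                              grid = default_grid(residues),
                              snr = Inf, seed = 1L,
                              volume_total = 1e4, decoy = NULL) {
  f_rep <- ligand$f_rep
  check_number(f_rep, "f_rep", lower = 0, upper = 1)
  check_number(snr, "snr", lower = 0, allow_inf = TRUE)
  if (snr <= 0) stop_invalid("`snr` must be positive")
  axis_H <- seq(grid$range_H[1], grid$range_H[2], length.out = grid$n_H)
  axis_N <- seq(grid$range_N[1], grid$range_N[2], length.out = grid$n_N)
  step_H <- diff(axis_H[1:2]); step_N <- diff(axis_N[1:2])

  peaks <- list()
  for (i in seq_len(nrow(residues))) {
    r <- residues[i, ]
    if (r$lw_H / step_H < 5 - 1e-9 || r$lw_N / step_N < 5 - 1e-9) {
      stop_invalid("grid too coarse: need >= 5 points per linewidth for residue ", r$residue_id)
    }
    for (state in c("rep", "act")) {
      cH <- if (state == "rep") r$delta_H_rep else r$delta_H_act
      cN <- if (state == "rep") r$delta_N_rep else r$delta_N_act
      if (cH < min(axis_H) || cH > max(axis_H) || cN < min(axis_N) || cN > max(axis_N)) {
        stop_invalid("peak centre outside grid for residue ", r$residue_id)
      }
      vol <- volume_total * if (state == "rep") f_rep else 1 - f_rep
      if (vol > 0) {
        peaks[[length(peaks) + 1L]] <- data.frame(
          residue_id = r$residue_id, state = state,
          center_H = cH, center_N = cN, fwhm_H = r$lw_H, fwhm_N = r$lw_N,
          volume = vol,
          amplitude = vol / ((pi / 2)^2 * r$lw_H * r$lw_N),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(decoy)) {
    r1 <- residues[1, ]
    peaks[[length(peaks) + 1L]] <- data.frame(
      residue_id = "decoy", state = "unlabeled",
      center_H = decoy$center_H, center_N = decoy$center_N,
      fwhm_H = r1$lw_H, fwhm_N = r1$lw_N, volume = decoy$volume,
      amplitude = decoy$volume / ((pi / 2)^2 * r1$lw_H * r1$lw_N),
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peaks)

  surface <- matrix(0, length(axis_H), length(axis_N))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    surface <- surface + lorentzian2d_grid(axis_H, axis_N, p$amplitude,
                                           p$center_H, p$center_N,
                                           p$fwhm_H, p$fwhm_N)
  }
  sigma <- if (is.finite(snr)) max(surface) / snr else 0
  if (sigma > 0) {
    noise <- with_seed(derive_seed(seed, "spectrum", ligand$ligand_id %||% "x"),
                       stats::rnorm(length(surface), 0, sigma))
    surface <- surface + matrix(noise, nrow(surface), ncol(surface))
  }
  sp <- spectrum2d(surface, axis_H, axis_N,
                   noise_sigma = if (sigma > 0) sigma else NA_real_)
  attr(sp, "true_peaks") <- peaks
  sp
}

#' Default acquisition grid for a residue set
#'
#' Chooses ppm ranges padded beyond all state centres and point counts
#' giving ~5-6 grid points per linewidth in each dimension.
#'
#' @param residues Residue geometry data frame.
#' @return List with `range_H`, `range_N`, `n_H`, `n_N`.
#' @export
default_grid <- function(residues = residue_state_shifts()) {
  hs <- c(residues$delta_H_rep, residues$delta_H_act)
  ns <- c(residues$delta_N_rep, residues$delta_N_act)
  pad_H <- 10 * max(residues$lw_H)
  pad_N <- 5 * max(residues$lw_N)
  range_H <- c(min(hs) - pad_H, max(hs) + pad_H)
  range_N <- c(min(ns) - pad_N, max(ns) + pad_N)
  step_H <- min(residues$lw_H) / 6
  step_N <- min(residues$lw_N) / 6
  list(range_H = range_H, range_N = range_N,
       n_H = ceiling(diff(range_H) / step_H) + 1L,
       n_N = ceiling(diff(range_N) / step_N) + 1L)
}

#' Numerically integrate a spectrum over its full grid
#'
#' Grid-sum approximation `sum(I) * dH * dN`, used as the independent
#' volume oracle against analytic Lorentzian integrals.
#'
#' @param spectrum A [spectrum2d()] object.
#' @return Total integral in intensity * ppm^2.
#' @export
grid_integral <- function(spectrum) {
  dH <- mean(diff(spectrum$axis_H))
  dN <- mean(diff(spectrum$axis_N))
  sum(spectrum$intensities) * dH * dN
}
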