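#' Generate a synthetic ligand series with ground-truth state populations
#'
#' Builds the latent "ground truth" for a synthetic conformation-activity
#' study: a series of ligands, each carrying a repressive-state fraction
#' `f_rep` in \[0, 1\] that drives every downstream synthetic observable
#' (NMR peak volumes, coregulator-recruitment efficacies, binding
#' affinities, reporter activity and target-gene expression). The design
#' emulates a covalent ligand series spanning the full pharmacological
#' spectrum from inverse agonism (`f_rep` near 1, corepressor-selective)
#' to agonism (`f_rep` near 0, coactivator-selective).
#'
#' With `f_rep_spacing = "uniform"` the fractions are placed at
#' `seq(0, 1, length.out = n_ligands)`, so the series always contains the
#' two pure-state endpoints. A custom numeric vector of fractions may be
#' supplied instead. Latent assay potencies (log10 EC50, molar) are drawn
#' once per ligand from a seeded normal distribution; efficacy and potency
#' are deliberately unlinked, matching the behaviour of covalent series in
#' which occupancy-driven potency carries no information about efficacy.
#'
#' @param n_ligands Number of ligands (>= 2).
#' @param f_rep_spacing Either `"uniform"` or a numeric vector of length
#'   `n_ligands` with values in \[0, 1\].
#' @param seed Integer master seed; the series is a pure function of
#'   `(n_ligands, f_rep_spacing, seed)`.
#' @param potency_mean,potency_sd Mean and sd of the latent log10 EC50
#'   (molar) across the series. Defaults centre on ~300 nM, a typical
#'   potency for a cell-permeable covalent ligand after short incubation.
#' @return A data frame of class `ligand_series` with columns `ligand_id`,
#'   `f_rep`, `exchange_regime`, `potency_log10_M` and `seed` (the derived
#'   per-ligand seed).
#' @examples
#' make_ligand_series(5, seed = 1)$f_rep  # 0.00 0.25 0.50 0.75 1.00
#' @export
make_ligand_series <- function(n_ligands, f_rep_spacing = "uniform", seed,
                               potency_mean = -6.5, potency_sd = 0.3) {
  check_number(n_ligands, "n_ligands", lower = 2)
  check_number(seed, "seed")
  if (identical(f_rep_spacing, "uniform")) {
    f_rep <- seq(0, 1, length.out = n_ligands)
  } else if (is.numeric(f_rep_spacing)) {
    if (length(f_rep_spacing) != n_ligands) {
      stop_invalid("custom `f_rep_spacing` must have length `n_ligands`")
    }
    if (any(f_rep_spacing < 0 | f_rep_spacing > 1)) {
      stop_invalid("`f_rep_spacing` values must lie in [0, 1]")
    }
    f_rep <- as.numeric(f_rep_spacing)
  } else {
    stop_invalid("`f_rep_spacing` must be \"uniform\" or a numeric vector")
  }
  ids <- sprintf("L%02d", seq_len(n_ligands))
  potency <- with_seed(derive_seed(seed, "potency"),
                       stats::rnorm(n_ligands, potency_mean, potency_sd))
  out <- data.frame(
    ligand_id = ids,
    f_rep = f_rep,
    exchange_regime = "slow",
    potency_log10_M = potency,
    seed = vapply(ids, function(id) derive_seed(seed, "ligand", id), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("ligand_series", "data.frame")
  out
}

#' Default two-state chemical-shift geometry for an ensemble-reporter residue
#'
#' Returns the per-residue peak geometry used by [simulate_spectrum()]: the
#' (1H, 15N) ppm centres of the repressive-like and active-like state peaks
#' and the full-width-at-half-maximum linewidths. The default emulates a
#' glycine backbone amide near the coregulator (AF-2) surface whose two
#' slow-exchange peaks are well resolved: the 1H separation (0.30 ppm) is
#' 15 linewidths, so volume integration of the two states is unambiguous.
#'
#' @param residue_id Residue label.
#' @param delta_H_rep,delta_N_rep Repressive-state peak centre (ppm).
#' @param delta_H_act,delta_N_act Active-state peak centre (ppm).
#' @param lw_H,lw_N FWHM linewidths (ppm), strictly positive.
#' @return One-row data frame with the fields above.
#' @export
residue_state_shifts <- function(residue_id = "G399",
                                 delta_H_rep = 8.35, delta_N_rep = 109.8,
                                 delta_H_act = 8.05, delta_N_act = 108.9,
                                 lw_H = 0.02, lw_N = 0.15) {
  if (lw_H <= 0 || lw_N <= 0) stop_invalid("linewidths must be strictly positive")
  if (delta_H_rep == delta_H_act && delta_N_rep == delta_N_act) {
    stop_invalid("repressive and active state centres must be distinct")
  }
  data.frame(residue_id = residue_id,
             delta_H_rep = delta_H_rep, delta_N_rep = delta_N_rep,
             delta_H_act = delta_H_act, delta_N_act = delta_N_act,
             lw_H = lw_H, lw_N = lw_N,
             stringsAsFactors = FALSE)
}

#' @export
print.ligand_series <- function(x, ...) {
  cat(sprintf("Synthetic ligand series: %d ligands, f_rep in [%.3g, %.3g]\n",
              nrow(x), min(x$f_rep), max(x$f_rep)))
  NextMethod()
}
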