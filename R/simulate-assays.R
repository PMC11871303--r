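#' Simulate a TR-FRET coregulator-recruitment dose-response curve
#'
#' Generates plate data for a time-resolved FRET peptide-interaction assay
#' following the three-parameter sigmoidal model (Hill slope 1):
#' `y = bottom + (top - bottom) / (1 + EC50 / x)`. The plateau (`top`) is
#' tied monotonically to the ligand's ground-truth repressive fraction:
#' the corepressor (NCoR1) peptide plateau increases linearly with `f_rep`
#' and the coactivator (MED1) plateau decreases, so across a series the
#' noiseless efficacies are strictly monotone in the ensemble position.
#' Noise is multiplicative Gaussian with coefficient of variation
#' `noise_cv`, the usual error structure of ratiometric plate readers.
#'
#' Default response units are the TR-FRET ratio (520 nm / 495 nm); the
#' baseline is a DMSO-like bottom of 0.15 ratio units and the plateau
#' spans 0.20-0.70 depending on peptide and `f_rep`.
#'
#' @param ligand One row of a [make_ligand_series()] frame.
#' @param peptide `"NCoR1"` or `"MED1"`.
#' @param concentrations Ligand concentrations, molar, all > 0.
#' @param noise_cv Multiplicative noise CV (fraction); 0 gives noiseless data.
#' @param seed Integer master seed.
#' @param n_replicates Technical replicates per concentration.
#' @return Data frame with columns `ligand_id`, `peptide`,
#'   `concentration_M`, `response`, `replicate`, plus attribute
#'   `"true_params"` (bottom, top, EC50).
#' @export
simulate_trfret_curve <- function(ligand, peptide = c("NCoR1", "MED1"),
                                  concentrations = default_dose_series(),
                                  noise_cv = 0.02, seed = 1L,
                                  n_replicates = 3L) {
  peptide <- match.arg(peptide)
  if (length(concentrations) == 0) stop_invalid("empty concentration list")
  if (any(concentrations <= 0)) stop_invalid("concentrations must be > 0")
  check_number(noise_cv, "noise_cv", lower = 0)
  f_rep <- ligand$f_rep
  bottom <- 0.15
  top <- if (peptide == "NCoR1") 0.20 + 0.50 * f_rep else 0.20 + 0.50 * (1 - f_rep)
  ec50 <- 10^ligand$potency_log10_M
  x <- rep(concentrations, each = n_replicates)
  y <- bottom + (top - bottom) / (1 + ec50 / x)
  if (noise_cv > 0) {
    y <- with_seed(derive_seed(seed, "trfret", ligand$ligand_id, peptide),
                   y * (1 + stats::rnorm(length(y), 0, noise_cv)))
  }
  out <- data.frame(ligand_id = ligand$ligand_id, peptide = peptide,
                    concentration_M = x, response = y,
                    replicate = rep(seq_len(n_replicates), times = length(concentrations)),
                    stringsAsFactors = FALSE)
  attr(out, "true_params") <- c(bottom = bottom, top = top, ec50 = ec50)
  out
}

#' Default 12-point 3-fold ligand dilution series (molar)
#'
#' Spans 10 uM down to ~56 pM, bracketing typical sub-micromolar potencies.
#' @return Numeric vector of 12 molar concentrations, descending.
#' @export
default_dose_series <- function() 1e-5 / 3^(0:11)

#' Default 12-point 2-fold protein titration for FP assays (molar)
#'
#' Tops out at 45 uM, a practical ceiling for concentrated receptor stocks;
#' weak-affinity conditions therefore do not saturate.
#' @return Numeric vector of 12 molar concentrations, descending.
#' @export
default_protein_series <- function() 45e-6 / 2^(0:11)

#' Map a repressive fraction to peptide binding affinity
#'
#' The default affinity link used by [simulate_fp_curve()]: pKd is linear
#' in `f_rep`, ranging from 4.2 (Kd ~ 63 uM, non-saturating at a 45 uM
#' protein ceiling) to 6.1 (Kd ~ 0.8 uM) for the corepressor peptide, and
#' mirrored for the coactivator peptide.
#'
#' @param f_rep Repressive fraction in \[0, 1\].
#' @param peptide `"NCoR1"` or `"MED1"`.
#' @return Kd in molar.
#' @export
default_kd_link <- function(f_rep, peptide = c("NCoR1", "MED1")) {
  peptide <- match.arg(peptide)
  frac <- if (peptide == "NCoR1") f_rep else 1 - f_rep
  10^-(4.2 + 1.9 * frac)
}

#' Simulate a fluorescence-polarization saturation binding curve
#'
#' Protein is titrated against a fixed tracer peptide; the noiseless signal
#' follows the one-site hyperbola `Y = Bmax * X / (Kd + X) + background`
#' with additive Gaussian noise (millipolarization units). With the
#' default affinity link, weak-affinity conditions have Kd above the
#' highest protein concentration and therefore do not saturate -- the
#' situation that motivates fitting all curves with a consistent, fixed
#' Bmax estimated from the high-affinity conditions.
#'
#' @param ligand One row of a ligand series.
#' @param peptide `"NCoR1"` or `"MED1"`.
#' @param protein_concentrations Protein concentrations, molar, > 0.
#' @param kd_link Function `(f_rep, peptide) -> Kd (molar)`.
#' @param Bmax Specific-signal span, mP (> 0).
#' @param background Free-tracer polarization, mP.
#' @param noise_sd Additive noise sd, mP.
#' @param seed Integer master seed.
#' @return Data frame `ligand_id`, `peptide`, `protein_M`, `response`,
#'   `replicate` with attribute `"true_params"` (Kd, Bmax, background).
#' @export
simulate_fp_curve <- function(ligand, peptide = c("NCoR1", "MED1"),
                              protein_concentrations = default_protein_series(),
                              kd_link = default_kd_link,
                              Bmax = 120, background = 60,
                              noise_sd = 1.5, seed = 1L, n_replicates = 3L) {
  peptide <- match.arg(peptide)
  if (any(protein_concentrations <= 0)) stop_invalid("protein concentrations must be > 0")
  if (Bmax <= 0) stop_invalid("`Bmax` must be positive")
  kd <- kd_link(ligand$f_rep, peptide)
  x <- rep(protein_concentrations, each = n_replicates)
  y <- Bmax * x / (kd + x) + background
  if (noise_sd > 0) {
    y <- with_seed(derive_seed(seed, "fp", ligand$ligand_id, peptide),
                   y + stats::rnorm(length(y), 0, noise_sd))
  }
  out <- data.frame(ligand_id = ligand$ligand_id, peptide = peptide,
                    protein_M = x, response = y,
                    replicate = rep(seq_len(n_replicates), times = length(protein_concentrations)),
                    stringsAsFactors = FALSE)
  attr(out, "true_params") <- c(Kd = kd, Bmax = Bmax, background = background)
  out
}

#' Simulate a single-dose transcriptional reporter readout
#'
#' Luciferase reporter activity for cells treated at one saturating ligand
#' concentration, normalized so the vehicle (DMSO) control is 1. Activity
#' decreases linearly with the repressive fraction: full agonist-like
#' ligands (`f_rep = 0`) activate ~5-fold over vehicle while full inverse
#' agonists (`f_rep = 1`) repress below baseline, with multiplicative
#' Gaussian noise across biological replicates.
#'
#' @param ligand One row of a ligand series.
#' @param n_replicates Biological replicates (default 4).
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer master seed.
#' @return Data frame `ligand_id`, `replicate`, `activity` with attribute
#'   `"true_activity"`.
#' @export
simulate_reporter <- function(ligand, n_replicates = 4L, noise_cv = 0.05,
                              seed = 1L) {
  if (n_replicates < 1) stop_invalid("`n_replicates` must be >= 1")
  truth <- 0.3 + 4.7 * (1 - ligand$f_rep)
  act <- with_seed(derive_seed(seed, "reporter", ligand$ligand_id),
                   truth * (1 + stats::rnorm(n_replicates, 0, noise_cv)))
  out <- data.frame(ligand_id = ligand$ligand_id,
                    replicate = seq_len(n_replicates), activity = act,
                    stringsAsFactors = FALSE)
  attr(out, "true_activity") <- truth
  out
}

#' Simulate a qPCR Ct table for target-gene expression
#'
#' Builds raw cycle-threshold values for a PPAR-target-like gene and a
#' housekeeping gene under a ligand condition and a vehicle calibrator,
#' structured so the comparative-Ct (ddCt) method recovers a relative
#' expression that decreases with the repressive fraction:
#' `delta-Ct(ligand) = delta-Ct(calibrator) + expression_span * f_rep`, so
#' the true `RQ = 2^(-expression_span * f_rep)`. Gaussian noise is added
#' per well on the Ct scale.
#'
#' @param ligand One row of a ligand series.
#' @param n_replicates Replicate wells per (gene, condition) (>= 1).
#' @param seed Integer master seed.
#' @param noise_sd_ct Additive Ct noise sd (cycles).
#' @param expression_span Cycles of ddCt between `f_rep = 0` and 1
#'   (default 3, i.e. up to 8-fold repression).
#' @param target,housekeeping,calibrator Labels for genes and the vehicle
#'   condition.
#' @return Long data frame `condition`, `gene`, `replicate`, `ct` with
#'   attribute `"true_rq"`.
#' @export
simulate_expression <- function(ligand, n_replicates = 3L, seed = 1L,
                                noise_sd_ct = 0.15, expression_span = 3,
                                target = "aP2", housekeeping = "TBP",
                                calibrator = "DMSO") {
  if (n_replicates < 1) stop_invalid("`n_replicates` must be >= 1")
  ct_hk <- 18
  dct_cal <- 6
  rows <- expand.grid(condition = c(calibrator, ligand$ligand_id),
                      gene = c(target, housekeeping),
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  dct <- ifelse(rows$condition == calibrator, dct_cal,
                dct_cal + expression_span * ligand$f_rep)
  ct <- ifelse(rows$gene == housekeeping, ct_hk, ct_hk + dct)
  if (noise_sd_ct > 0) {
    ct <- with_seed(derive_seed(seed, "qpcr", ligand$ligand_id),
                    ct + stats::rnorm(length(ct), 0, noise_sd_ct))
  }
  out <- data.frame(rows, ct = ct, stringsAsFactors = FALSE)
  attr(out, "true_rq") <- 2^(-expression_span * ligand$f_rep)
  out
}
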