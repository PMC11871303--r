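---
title: "Quantifying a two-state conformational ensemble and its conformation-activity relationship"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a two-state conformational ensemble and its conformation-activity relationship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carnmr)
```

## The scientific problem

Nuclear-receptor ligand-binding domains (LBDs) exchange between
transcriptionally active and repressive conformations. When a ligand slows
that exchange into the slow regime on the NMR time scale, a single backbone
amide reports the ensemble directly: a 2D [^1^H,^15^N] correlation spectrum
shows one peak per long-lived conformation, and the integrated peak volumes
are proportional to the state populations. A ligand series with graded
pharmacology — from corepressor-selective inverse agonists to
coactivator-selective agonists — should therefore shift a reporter
residue's peak volumes continuously between a repressive-like and an
active-like position, and that shift should track every functional readout
of the receptor: corepressor/coactivator peptide recruitment (TR-FRET),
peptide binding affinity (fluorescence polarization), transcriptional
reporter activity, and target-gene expression.

`carnmr` implements that conformation-activity relationship (CAR) analysis
as a reusable, tested pipeline:

1. **nmr_spectra** — noise estimation, peak picking, separable 2D
   Lorentzian fitting, elliptical volume integration, and assignment
   transfer by minimum chemical-shift perturbation (CSP);
2. **ensemble_analysis** — state labeling against reference anchors, state
   populations from volumes, and the population-weighted ^1^H shift
   $\bar\delta = \sum_i V_i\,\delta_{H,i} / \sum_i V_i$;
3. **pharmacology** — three-parameter sigmoidal dose-response fits,
   one-site total-binding fits with a shared fixed $B_\max$, coregulator
   bias factors, and comparative-Ct (ddCt) relative expression;
4. **car_correlation** — pairwise Spearman correlations with two-sided
   p-values (exact permutation for small n, t-approximation otherwise);
5. **structure_compare** — Kabsch C$\alpha$ superposition and pairwise
   RMSD matrices for crystal-structure comparison;
6. **synthetic_data** — a generator that emulates the whole study design
   from a per-ligand ground-truth repressive fraction, so every step of
   the pipeline can be validated by parameter recovery.

## The two-state peak model

For a reporter residue the simulator places two 2D Lorentzian peaks at the
repressive-state and active-state (^1^H, ^15^N) positions. A separable
Lorentzian with amplitude $A$ and full widths at half maximum $w_H$, $w_N$
has the closed-form volume

$$V = \left(\frac{\pi}{2}\right)^2 A\, w_H\, w_N,$$

which is what `fit_peak()` reports for the fitted model and what the tests
check against grid integration. Volumes are set to $f_\mathrm{rep} V_0$ and
$(1-f_\mathrm{rep}) V_0$ with a common total $V_0$, so noiseless
populations are exact by construction and total volume is conserved across
the series — the central assumption (volume $\propto$ population) that the
analysis inherits from slow exchange.

The slow-exchange assumption itself is validated with a two-site
Bloch–McConnell simulator (`simulate_lineshape_mcconnell()`), solved in the
frequency domain by inverting the $2\times 2$ complex Liouvillian per
offset. Its limits behave as theory requires: at $k_\mathrm{ex} = 0$ two
Lorentzians with areas $(p_A, p_B)$; at $k_\mathrm{ex} \gg |\Delta\omega|$
a single peak at the population-weighted offset. Consistency between the
two readings of "ensemble position" — the two-peak volume-weighted mean in
slow exchange versus the single averaged peak in fast exchange — holds to
well under 1% of the site separation across $p_A \in [0.1, 0.9]$. The
exchange rate is deliberately a free parameter of the simulator: the
experimental work establishes the regime (slow), not a rate, so no value is
asserted.

## Default geometry and acquisition grid

The default reporter-residue geometry (`residue_state_shifts()`) is a
glycine-like amide with the repressive peak at (8.35, 109.8) ppm and the
active peak at (8.05, 108.9) ppm, linewidths 0.02 ppm (^1^H) and 0.15 ppm
(^15^N). The 0.30 ppm ^1^H separation is 15 linewidths, so the two states
are fully resolved and volume integration is unambiguous — the
well-resolved situation the analysis is restricted to. The default grid
(`default_grid()`) covers all centres with six points per linewidth, above
the five-point floor the simulator enforces for faithful lineshapes.

Noise is additive i.i.d. Gaussian with $\sigma =
\max(\text{signal})/\mathrm{snr}$; the study-level default is
$\mathrm{snr} = 50$. TR-FRET noise is multiplicative (CV 2% by default),
FP noise additive (1.5 mP on a 120 mP $B_\max$), and qPCR noise additive
on the Ct scale (0.15 cycles) — the simplest error structures matching the
three instrument classes.

## Peak processing choices

* **Noise estimation** uses $1.4826 \times \mathrm{MAD}$ over a
  signal-free region; by default the grid is split into $4\times4$ tiles
  and the lowest-mean-|intensity| quartile of tiles is pooled. This keeps
  the estimator unbiased on pure noise and robust when peaks occupy a few
  percent of the grid.
* **Picking** takes strict 8-neighbour local maxima above
  `threshold_sigma` (default 5) times the noise, greedily suppressing
  maxima within `min_separation` (default 0.03/0.3 ppm) of a stronger one;
  intensity ties break toward lower ^1^H then lower ^15^N ppm, so picking
  is deterministic.
* **Deduplication.** Noise on the heavy Lorentzian tails can seed several
  picks that all converge to the same peak, and sums of separable
  lineshapes have weak "cross-ridge" maxima where one peak's ^1^H tail
  crosses another's ^15^N tail. `process_spectrum()` therefore drops seeds
  below 2% of the tallest seed and collapses fitted peaks whose centres
  agree within one linewidth, keeping the larger volume. The 2% floor
  matches `min_volume_fraction` in `state_populations()`: a second state
  below 2% of the total volume is not counted, because at realistic noise
  levels such calls are artefacts.
* **Volumes** are reported two ways: the analytic integral of the fitted
  model and the direct elliptical grid sum
  (`integrate_elliptical()`, semi-axes three linewidths, local-median
  baseline). The elliptical sum systematically recovers about 79% of the
  analytic volume for a pure Lorentzian — the in-ellipse mass at three
  linewidths — so the two conventions differ by a stable shape factor, and
  either can be used consistently; the pipeline uses the model integral.
* **Overlap policy.** Peaks flagged as overlapped (e.g. an unrelated
  residue stabilised in the same spectral region; the simulator can inject
  such a decoy) are excluded from volume analysis rather than
  deconvolved.

Assignment transfer minimises total CSP,
$\sqrt{\Delta\delta_H^2 + (\alpha_N \Delta\delta_N)^2}$ with
$\alpha_N = 0.14$ by default (0.2 appropriate for glycines), over
one-to-one matchings via the Hungarian algorithm, subject to a
`max_csp` ceiling (default 0.1 ppm) above which a residue is reported
unmatched. Enumeration on small instances confirms global optimality.

## State labeling and the weighted shift

Peaks are labeled repressive- or active-like by the nearer of two anchor
positions (the pure-state peak positions) in CSP distance; when two peaks
claim one anchor the closer keeps it. A peak exactly midway is labeled
repressive-like — a documented, deterministic tie-break that only arises
on the degenerate midpoint. Populations are normalised volumes;
single-peak observations give (1, 0) or (0, 1). The weighted shift uses
the ^1^H dimension only, matching the published measurement; because the
anchors are colinear with the shifting peaks, $\bar\delta$ equals
$p_\mathrm{rep}\delta_{H,\mathrm{rep}} +
p_\mathrm{act}\delta_{H,\mathrm{act}}$ whenever fitted centres sit at the
anchors, which ties the two summaries together.

```{r weighted-shift}
weighted_shift(data.frame(delta_H = c(8.00, 8.20), volume = c(3, 1)))
```

## Pharmacology conventions

Dose-response curves use the three-parameter sigmoidal model with Hill
slope fixed at 1,
$y = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom})/(1 +
\mathrm{EC}_{50}/x)$, fitted by Levenberg–Marquardt on
$\log_{10}\mathrm{EC}_{50}$ bounded within $[\min(x)/100,\ 100\max(x)]$,
with self-starting values from response quantiles. Flat data return a
non-converged fit with bottom = top = mean rather than an error.

FP saturation data follow $Y = B_\max X/(K_d + X) + \mathrm{background}$
with no linear nonspecific term: protein, not tracer, is titrated, and the
fixed-$B_\max$ convention implies the specific-site hyperbola. Because
weak-affinity conditions do not saturate at the 45 µM protein ceiling,
$B_\max$ is estimated once (`estimate_shared_bmax()`) by a joint fit over
the curves that do saturate (max concentration at least five apparent
$K_d$) and then fixed for every fit in the analysis set.

The coregulator bias factor is the MED1 value subtracted from the NCoR1
value. For TR-FRET it is a difference of efficacies on the response scale;
for FP the default scale is $\mathrm{p}K_d = -\log_{10} K_d$, since
differences of raw $K_d$ are dominated by the weakest binder; the linear
option exists for a literal reading. Relative expression follows the
comparative-Ct method, $RQ = 2^{-\Delta\Delta C_t}$, with replicate spread
propagated as $RQ$ evaluated at $\Delta\Delta C_t \mp \mathrm{sd}$ — a
declared convention, since the dispersion definition behind published
"upper and lower limits" is software-specific.

## Correlation conventions

Spearman's $s$ is the Pearson correlation of average ranks. The two-sided
p-value is exact for small samples — full enumeration of all $n!$
permutations, counting $|s_\mathrm{perm}| \ge |s_\mathrm{obs}|$ — and the
$t$-approximation with $n-2$ degrees of freedom for larger samples, where
enumeration is infeasible and the approximation error is far below any
decision threshold. Every result carries its method label. No
multiple-comparison adjustment is applied; raw p-values are reported with
per-cell sample sizes. Missing ligands (for example, compounds absent from
the expression assay) are removed pairwise, so one incomplete column never
shrinks the rest of the matrix.

```{r spearman}
spearman(1:5, c(1, 3, 2, 5, 4))
```

## Structure comparison

`read_calpha()` extracts one chain's C$\alpha$ trace (first alternate
location, chosen model) via `bio3d`; `kabsch_rmsd()` performs the
closed-form optimal rigid superposition with the SVD determinant
correction so reflections are never returned; `pairwise_rmsd_matrix()`
reports all pairwise RMSDs over residue-number intersections together with
the pair counts. For near-identical structures of the same construct this
rigid superposition is the appropriate reading of a flexible-alignment
result; residues missing from either model (disordered termini, loops)
are dropped by the intersection pairing.

## What the generator emulates — and what it does not

Per ligand, one latent repressive fraction $f_\mathrm{rep} \in [0,1]$
drives everything: NMR peak volumes directly; the TR-FRET plateau
(corepressor top increasing, coactivator top decreasing, linearly); the FP
affinity ($\mathrm{p}K_d$ linear in $f_\mathrm{rep}$, 4.2–6.1, so the
weakest binders stay non-saturating at 45 µM); reporter activity
(decreasing); and expression ($\Delta\Delta C_t$ spanning 3 cycles, about
8-fold repression at $f_\mathrm{rep}=1$). Latent potencies are drawn
independently of efficacy, reproducing the covalent-series property that
potency carries no efficacy information. All randomness flows from one
master seed through counter-style derived streams
(`derive_seed()`), so every output is bit-reproducible.

The generator does **not** emulate: raw time-domain acquisition,
apodization or phasing; peak-shape distortions from intermediate-timescale
dynamics (the main caveat the volume-population assumption carries on real
data); plate-position artefacts beyond i.i.d. noise; or covalent binding
kinetics (time-dependent potency shifts). Passing recovery tests therefore
demonstrates that the analysis is correct *given* the two-state
slow-exchange model with well-resolved peaks — not that real spectra
always satisfy that model. On real data, the overlap-exclusion flags and
the reported QC columns are the guardrails.

## Problem sizes and numerical tolerances

The validation suite uses a 22-ligand uniform series at snr 50 with 2%
assay CV (matching the study design), 200-curve fit-recovery batteries,
100-replicate peak-fit simulations, 20 master seeds for the end-to-end
correlation check, and full permutation enumeration up to $n = 9$. Key
tolerances: noiseless volume recovery within 1%; population recovery mean
absolute error below 0.05 with rank correlation above 0.95; fast/slow
consistency within 1% of the site separation; EC50 recovery within 10% in
at least 95% of triplicate curves. Degenerate inputs (flat dose-response
data, all-zero FP signal, constant correlation inputs, collinear
coordinates) return flagged results or informative errors, never silent
numbers.

## Running the full study

```{r study}
study <- run_car_study(n_ligands = 8, seed = 1)
study
head(study$car[, c("ligand_id", "delta_bar_H", "p_rep",
                   "ncor1_efficacy", "rq_expression")])
```

## Known limitations

* Populations come from volumes only; no exchange-rate fitting
  (relaxation dispersion, ZZ-exchange) is attempted.
* Two states at most are modeled per residue; observations with more
  peaks are flagged and trimmed to the two largest.
* The elliptical-integration region convention of external peak-fitting
  software is not standardised; both volume conventions are exposed so
  either can be matched.
* Flexible structural alignment is out of scope; the RMSD utility assumes
  near-identical constructs where rigid superposition suffices.
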