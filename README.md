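# carnmr

Conformation-activity relationship (CAR) analysis for two-state protein
conformational ensembles measured by 2D NMR.

## The problem

Nuclear-receptor ligand-binding domains exchange between transcriptionally
active and repressive conformations. When a bound ligand slows that
exchange into the slow regime on the NMR time scale, a well-resolved
backbone amide shows one 2D [¹H,¹⁵N] peak per long-lived conformation, and
the integrated peak volumes are proportional to the state populations. The
position of the ensemble can then be summarised by the population-weighted
¹H chemical shift

    δ̄ = Σᵢ Vᵢ δ_H,i / Σᵢ Vᵢ ,

and across a ligand series with graded pharmacology — inverse agonists to
agonists — δ̄ should correlate with every functional readout of the
receptor: corepressor/coactivator peptide recruitment efficacy (TR-FRET),
peptide binding affinity (fluorescence polarization), coregulator bias
(NCoR1 value minus MED1 value), transcriptional reporter activity, and
target-gene expression (ddCt). `carnmr` implements this analysis end to
end for anyone quantifying ligand-dependent ensemble shifts:

* 2D peak picking, separable Lorentzian lineshape fitting (volume
  `V = (π/2)² A·fwhm_H·fwhm_N`), elliptical volume integration, robust
  noise estimation, and assignment transfer by minimum chemical-shift
  perturbation (Hungarian matching, `csp = sqrt(ΔδH² + (α_N ΔδN)²)`);
* state labeling, volume-derived populations, and the weighted-shift
  statistic;
* a two-site Bloch–McConnell exchange-lineshape simulator used to verify
  the slow/fast-exchange consistency of the statistic;
* assay fitting: three-parameter sigmoidal dose-response (Hill slope 1),
  one-site total binding `Y = Bmax·X/(Kd+X) + bg` with a shared fixed
  Bmax estimated from the saturating curves, bias factors, and
  comparative-Ct relative expression `RQ = 2^(−ΔΔCt)`;
* pairwise Spearman correlation matrices with two-sided p-values (exact
  n! permutation for small samples, t-approximation otherwise);
* Kabsch Cα superposition and pairwise RMSD matrices for comparing the
  associated crystal structures;
* a synthetic-data generator that emulates the full study design from a
  per-ligand ground-truth repressive fraction `f_rep`, so the whole
  pipeline is validated by parameter recovery.

## Worked example

Simulate and analyse an 8-ligand study (spectra at snr 50, triplicate
TR-FRET and FP plates at 2% CV, reporter and qPCR data), then correlate
the ensemble position with function:

```r
library(carnmr)
study <- run_car_study(n_ligands = 8, seed = 1)
study
#> Conformation-activity study: 8 ligands
#> Spearman s of weighted 1H shift vs functional readouts:
#>    ncor1_efficacy     med1_efficacy         ncor1_pkd          med1_pkd
#>                 1                -1                 1                -1
#>       trfret_bias           fp_bias reporter_activity     rq_expression
#>                 1                 1                -1                -1
```

The recovered repressive populations track the generator's ground truth,
and the weighted shift moves linearly between the active-state (8.05 ppm)
and repressive-state (8.35 ppm) ¹H positions:

```r
merge(study$ensemble, study$ground_truth, by = "ligand_id")[,
      c("ligand_id", "f_rep", "p_rep", "delta_bar_H")]
#>   ligand_id f_rep p_rep delta_bar_H
#> 1       L01 0.000 0.000        8.05
#> 2       L02 0.143 0.147        8.09
#> 3       L03 0.286 0.283        8.14
#> 4       L04 0.429 0.433        8.18
#> 5       L05 0.571 0.570        8.22
#> 6       L06 0.714 0.709        8.26
#> 7       L07 0.857 0.860        8.31
#> 8       L08 1.000 1.000        8.35

spearman(study$car$delta_bar_H, study$car$ncor1_efficacy)
#>   s  p_two_sided n_used            method flag
#> 1 1 4.960317e-05      8 exact permutation
```

A perfectly monotone 8-point pair gives s = 1 with the exact two-sided
permutation p of 2/8! ≈ 5.0e-5: only the identity and the full reversal
reach |s| = 1.

## Package layout

| Path | Contents |
| --- | --- |
| `R/ligand-series.R`, `R/simulate-assays.R`, `R/spectrum.R`, `R/mcconnell.R` | synthetic-data generators |
| `R/peaks.R`, `R/assignments.R`, `R/io.R` | 2D peak processing and formats |
| `R/ensemble.R` | populations and weighted shift |
| `R/pharmacology.R` | assay models |
| `R/correlation.R` | Spearman machinery and the CAR table |
| `R/structure.R` | Cα superposition |
| `R/pipeline.R` | `run_car_study()` end-to-end driver |
| `vignettes/conformation-activity.Rmd` | methods and design rationale |
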