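# nitrileIR

Detecting covalent small-molecule binding in live cells with genetically
encoded nitrile infrared probes.

A nitrile (C&#8801;N) installed at a chosen site in a protein absorbs near
2200–2250 cm⁻¹, a window almost free of cellular background. Its stretch
frequency reports on the local electric field and, with opposite sign, on
hydrogen bonding to the nitrile nitrogen. When a drug-like molecule binds
covalently to the target — modelled here by p-coumaric acid forming a
thioester with Cys69 of photoactive yellow protein (PYP) — the probe's
hydrogen-bonding environment changes and the band shifts by up to ~15 cm⁻¹,
directly readable in intact bacteria with a balanced dual-beam quantum
cascade laser (QCL) spectrometer.

`nitrileIR` implements the full computational chain around that
measurement:

* **Balanced-detection processing** — gain calibration from blank-blank
  sweeps, absorbance reconstruction
  `A = −log₁₀((g·V_ref + V_bal)/(g·V_ref)) − A₀` in which correlated
  source fluctuation cancels exactly, phase correction, Savitzky–Golay and
  Fourier filtering, polynomial baseline correction, replicate averaging.
* **Band fitting** — pseudo-Voigt profiles + local linear baseline by
  bounded Levenberg–Marquardt; centers with standard errors; apo→holo
  frequency shifts with quadrature-propagated uncertainty and a binding
  call (|Δν| > 2 cm⁻¹ and > 3σ).
* **Sensitivity analysis** — calibration lines, LOD = 3.3·σ/slope, and the
  Beer–Lambert pathlength-scaling prediction (50 → 250 µm ⇒ 5×).
* **Trajectory field analysis** — bond-projected point-charge Coulomb
  fields (1 e at 1 Å = 1439.96 MV/cm), geometric hydrogen-bond
  classification (N···D ≤ 4.0 Å, angle ≤ 30°, inclusive), state-resolved
  and replicate-aggregated field summaries.
* **Structure context** — nearest N/O heavy-atom contacts to the nitrile
  nitrogen and probe-ring ↔ chromophore-ring centroid distances from PDB
  structures.
* **Synthetic generators** — a forward instrument model (correlated QCL
  fluctuation, detector noise, water band at ~2100 cm⁻¹, cellular drift,
  Beer–Lambert bands at the measured in-cell frequencies) and a two-state
  Markov trajectory generator with solved charges, so every stage is
  testable against known ground truth with no instrument or MD engine.

## Worked example

Simulate the four-variant in-cell binding assay (20 seeded acquisitions per
condition at raw SNR 20) and the instrument LOD comparison:

```r
library(nitrileIR)

report <- runBindingAssay(nSeeds = 20, seed = 1)
report
#> AssayReport (threshold 2 cm-1, k = 3 ):
#>       variant apo_center     apo_se holo_center    holo_se       shift  uncertainty  call
#>       F28oCNF   2230.790 0.02046436    2231.109 0.01759053  0.31944330   0.02698549 FALSE
#>       F62oCNF   2227.482 0.01822271    2228.103 0.01848406  0.62047013   0.02595626 FALSE
#>       F92oCNF   2226.416 0.02112551    2241.301 0.01594193 14.88455605   0.02646568  TRUE
#>       F96oCNF   2227.575 0.01616759    2233.900 0.01881018  6.32528185   0.02480351  TRUE
#>  F96oCNF_C69A   2227.582 0.01945404    2227.592 0.02316297  0.01071778   0.03024869 FALSE
```

The two probes near the chromophore pocket (F92, F96) blue-shift by ~+14.9
and ~+6.3 cm⁻¹ and are called bound; the distal probes (F28, F62) shift by
only a few tenths of cm⁻¹, and the C69A control — which cannot form the
covalent linkage — stays at its apo frequency, confirming the shift is a
covalent-binding readout.

```r
lod <- runLodExperiment(nSeeds = 20, seed = 1)
lod$table[, c("preset", "pathlength_um", "lod_uM")]
#>   preset pathlength_um   lod_uM
#> 1    qcl           250 18.05595
#> 2   ftir            50 80.18261
lod$ratios["ftir", "qcl"]    # ~4.4x measured; analytic pathlength ratio = 5
```

The balanced QCL configuration at 250 µm reaches an ~18 µM benzonitrile
LOD versus ~80 µM for the 50 µm FTIR configuration — comfortably below the
~140 µM in-cell probe concentration.

Why the shifts happen, in the trajectory picture:

```r
tr <- generateTrajectory(trajectoryPreset("holo_F92"), seed = 1)
analyzeTrajectory(tr)$summary
#> FieldSummary (MV/cm):
#>   bonded: mean -74.9, sd 21.4, population 0.822
#>   free: mean -29.6, sd 19.4, population 0.178
#>   overall -66.8; replicate aggregate -66.8 (n=4 replicates)
```

The holo-F92 preset exchanges between a hydrogen-bonded high-field state
and a free low-field state; binding raises the bonded population
(0.82 vs 0.31 apo), moving the mean projected field from −44 to −67 MV/cm —
the electrostatic signature behind the +14.9 cm⁻¹ blue shift.

See `vignettes/nitrile-probe-workflow.Rmd` for the models, parameter
choices and their rationale.

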