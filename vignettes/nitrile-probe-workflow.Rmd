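---
title: "Detecting covalent binding with nitrile IR probes: models and methods"
author: "nitrileIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting covalent binding with nitrile IR probes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrileIR)
```

# The measurement this package models

A nitrile (C&#8801;N) group installed site-specifically in a protein absorbs
near 2200--2250 cm^-1^, in a window almost free of cellular background. Its
stretching frequency reports on the local electrostatic field (vibrational
Stark effect) and, with opposite sign, on hydrogen bonding to the nitrile
nitrogen, which blue-shifts the band. When a small molecule binds covalently
to the target protein, the resulting structural rearrangement changes the
probe's hydrogen-bonding environment and shifts the band by up to ~15
cm^-1^ -- a direct, label-free, in-cell readout of target engagement.

Measuring this in live cells requires sensitivity that conventional FTIR
instruments lack: water's combination band near 2100 cm^-1^ limits their
usable pathlength to ~50 um. A tunable quantum cascade laser (QCL) delivers
enough power for 250 um cells, but its intensity fluctuations dominate the
noise. The remedy is balanced detection: the beam is split into a sample
and a blank path, the two are subtracted on matched detectors, and the
correlated source fluctuation cancels in the intensity ratio.

`nitrileIR` implements the complete computational chain around this
experiment -- the balanced-detection signal processing, pseudo-Voigt band
fitting and shift detection, calibration-curve limit-of-detection (LOD)
analysis, and the trajectory electric-field / hydrogen-bond analysis that
explains the observed shifts -- together with synthetic generators that
stand in for the instrument and for MD engines, so every stage is testable
with known ground truth.

# The synthetic instrument

The generator emits demodulated per-wavenumber voltages (lock-in
time-domain processing is out of scope). Per grid point:

$$V_\mathrm{ref}(\nu) = g^{-1}\,P(\nu)\,(1+f(\nu))\,T_\mathrm{blank}(\nu) + \epsilon_1,
\qquad
V_\mathrm{bal}(\nu) = P(\nu)\,(1+f(\nu))\,\bigl(T_\mathrm{sample}(\nu)-T_\mathrm{blank}(\nu)\bigr) + \epsilon_2,$$

with $T = 10^{-A}$, $P(\nu)$ a smooth positive laser power profile,
$f(\nu)$ the multiplicative source fluctuation **identical in both
channels** at each grid point, $\epsilon_i$ independent additive detector
noise, and $g$ the reference-channel gain imbalance. The temporal (1/f)
structure of real QCL noise is collapsed to per-point correlated noise; the
instrument's noise spectrum is not modelled, and the stand-in is calibrated
only by the balanced-cancellation property it must reproduce.

Samples are Beer--Lambert: pseudo-Voigt bands with peak absorbance
$\varepsilon\,c\,L$ ($\varepsilon$ in OD mM^-1^ cm^-1^, default 0.2, a
typical aromatic-nitrile strength), a Gaussian water combination band
centered at 2100 cm^-1^, and a polynomial cellular baseline drift applied
to the sample cell only. The default grid is 2000--2300 cm^-1^ at 0.5
cm^-1^ (fine enough to resolve 10 cm^-1^ bands); default in-cell probe
concentration is 140 uM at 250 um pathlength, matching the estimated
working concentration of an expressed protein probe.

Cell-spectrum band centers come from a packaged frequency fixture
(`frequencyFixture()`): apo centers 2230.8 / 2227.5 / 2226.4 / 2227.6
cm^-1^ for the four PYP variants F28/F62/F92/F96-oCNF, shifts +0.3 / +0.6
/ +14.9 / +6.3 cm^-1^ on chromophore binding, holo centers derived as apo
+ shift, plus free oCNF in water (2232.3), sfGFP Y66oCNF (2225.8) and
aqueous benzonitrile (~2235). The C69A variant, which cannot form the
covalent linkage, keeps its apo center under the `no_binding_control`
condition.

# Absorbance reconstruction and the gain factor

The processing chain reconstructs

$$A(\nu) = -\log_{10}\frac{g\,V_\mathrm{ref}+V_\mathrm{bal}}{g\,V_\mathrm{ref}} - A_0(\nu),$$

whose parenthesised ratio is exactly the sample/blank beam-intensity ratio,
in which $(1+f)$ cancels. A subtlety worth documenting: on a true
blank-blank calibration record $V_\mathrm{bal}\equiv 0$, so the
reconstruction is invariant in $g$ and **the gain cannot be identified from
the calibration record's voltages**. On real balanced spectrometers the
gain ratio is a hardware calibration; accordingly `calibrateBalance()`
takes $g$ from the instrument setting carried in sweep metadata (or an
explicit argument), and uses the blank-blank record to estimate the
residual baseline $A_0$ (smoothed by a low-order polynomial so detector
noise does not propagate) and to verify balance quality.

The filter order is fixed as: phase correction &#8594; absorbance &#8594;
Savitzky--Golay &#8594; Fourier low-pass &#8594; polynomial baseline
through anchor windows, each stage appending a history record; any stage
can be disabled. Both filters use mirror (even) extension at the edges to
avoid wrap-around artifacts -- the cost is that polynomial invariance of
the Savitzky--Golay filter holds only away from the first/last half-window
of points, which is why the fit windows sit well inside the grid. Phase
correction rotates each channel's (in-phase, quadrature) pair; when only
magnitudes were recorded the quadrature is taken as zero and stored after
rotation, so the operation stays invertible.

Defaults: Savitzky--Golay window 11 points, order 3; Fourier cutoff 0.25
of Nyquist (a 10 cm^-1^ band concentrates well below it, a 3 cm^-1^ etalon
fringe well above); baseline order 2 through anchors at 2150--2170,
2185--2205 and 2265--2285 cm^-1^, flanking the nitrile region.

One practical consequence of smoothing: it correlates neighbouring
residuals, so least-squares covariance from a fit to a *smoothed* spectrum
understates the center uncertainty. For single-spectrum uncertainties, fit
the unfiltered absorbance; `runBindingAssay()` instead derives its
uncertainties from the scatter of fitted centers across seeded replicate
acquisitions (SD/sqrt(n)), which is calibrated regardless of noise
correlation.

# Band fitting and the binding call

Bands are modelled as pseudo-Voigt profiles (weighted Gaussian/Lorentzian
sum sharing center and FWHM; Gaussian fraction 0.5 by default, fixed
unless requested, with Gaussian and Lorentzian as the degenerate
settings) plus a local linear baseline, fitted by Levenberg--Marquardt
with box bounds inside a window of about +/-25 cm^-1^. Initial centers
come from prominence-ranked local maxima; near-duplicate candidates are
collapsed to the more prominent one and the ambiguity is recorded on the
result. Non-convergence is always flagged, never silent. Standard errors
come from the Gauss--Newton covariance $s^2 (J^\top J)^{-1}$; a bootstrap
was considered and rejected for routine use on speed grounds.

A frequency shift is the difference of two fitted centers with
uncertainties combined in quadrature. The binding call in the assay report
requires both $|\Delta\nu| > 2$ cm^-1^ (fixed threshold; the observed
no-binding shifts are a few tenths of cm^-1^, the binding shifts are >6
cm^-1^, so the threshold sits comfortably between) and
$|\Delta\nu| > 3\sigma$.

# Limit of detection

The calibration line is ordinary least squares of response versus
concentration, residual SD with the $n-2$ denominator, and

$$\mathrm{LOD} = \frac{3.3\,\sigma_\mathrm{resid}}{\mathrm{slope}},$$

the standard calibration-line convention (the 3.3 factor is configurable,
3.0 being the common alternative, and is always recorded in the result).
The default response is the fitted peak height. For a calibration standard
whose band is known (benzonitrile at ~2235 cm^-1^), the height is
estimated as the linear least-squares coefficient of the *fixed* band
profile plus a local linear baseline: unlike a free-center nonlinear fit,
this estimator is linear in the data, unbiased at zero concentration and
free of the heavy upper tail that noise-chasing fits produce in blank
spectra.

The two instrument presets are anchored to the characterized performance
of the instruments they emulate: the "qcl" preset (250 um, correlated
source fluctuation 10^-2^, gain 1.02) has its detector noise set so the
simulated benzonitrile series reproduces the ~18 uM LOD, and the "ftir"
preset (50 um, no correlated term) likewise its ~80 uM LOD. These two
numbers are consistency anchors, not predictions -- they depend on real
instrument noise that is not desk-reproducible -- and the analytic
Beer--Lambert statement is kept separate: at equal absorbance noise, LOD
scales as $L_\mathrm{ref}/L_\mathrm{new}$, so 50 &#8594; 250 um predicts
exactly a five-fold improvement.

# Trajectory electric fields and hydrogen bonding

The field analysis is a direct point-charge Coulomb sum (no periodic
images; polarizable-force-field induced dipoles and higher multipoles are
explicitly out of scope):

$$\mathbf{E}(\mathbf{p}) = k_e \sum_i q_i \frac{\mathbf{p}-\mathbf{r}_i}{|\mathbf{p}-\mathbf{r}_i|^3},
\qquad k_e\,e/\mathrm{\AA}^2 = 14.3996\ \mathrm{V/\AA} = 1439.96\ \mathrm{MV/cm}.$$

The projected field is the average of the fields at the carbon and the
nitrogen, dotted with the C&#8594;N unit vector (midpoint evaluation is
available behind a flag; which convention the original field calculations
used cannot be determined, and the two differ by well under the state
separation here). The probe's own residue is excluded from the sum. With
this sign convention a hydrogen-bond donor approaching the nitrogen
produces a *negative* projected field.

Hydrogen bonds are classified geometrically: heavy-atom N&#183;&#183;&#183;D distance
&#8804; 4.0 &#197; and angle &#8804; 30&#176;, both inclusive. The angle's vertex is
ambiguous in the usual shorthand ("donor--acceptor--hydrogen"); the default
places it at the donor heavy atom, between D&#8594;H and D&#8594;N, with a
hydrogen-vertex alternative (deviation of D--H&#183;&#183;&#183;A from linearity)
selectable and recorded in the output. Histogram bins default to 2 MV/cm.

## The two-state trajectory generator

The generator emulates the central observation of the MD analysis: the
probe samples a hydrogen-bonded (high-field) and a free (low-field) state.
Geometry: C at the origin, N at 1.16 &#197; (standard nitrile bond length),
a single donor group on the bond axis at 2.9 &#197; (bonded, H oriented at
the nitrogen) or 6.5 &#197; (free, H turned away), a fixed axial background
charge standing in for the mean protein field, and a shell of
alternating-sign solvent charges at ~8 &#197;, resampled every frame --
zero-mean, so it broadens the field distribution (SD ~20 MV/cm, matching
the observation that simulated field distributions are far broader than
the measured linewidths) without biasing state means. All non-probe atoms
get 0.05 &#197; positional jitter. State switching is a two-state Markov
chain with stationary occupancy $p$ and switching scale 0.8, initialised
from the stationary distribution so the empirical occupancy is unbiased at
finite length.

The donor-charge scale and background charge are *solved*, not tuned: given
requested state means $(F_\mathrm{hb}, F_\mathrm{free})$, the construction
inverts the linear system formed by the noiseless unit-field geometry.
The four presets share variant-specific state means and differ only in
occupancy, chosen so the overall mean $p F_\mathrm{hb} + (1-p)
F_\mathrm{free}$ equals the reported values: F92 uses (-75, -30) MV/cm
with $p = 0.31$ (apo, mean -44) and $p = 0.82$ (holo, mean -67); F96 uses
(-35, -20) with $p = 0.20$ (apo, -23) and $p = 0.40$ (holo, -26). The
F92 picture is a strong protein donor (a threonine hydroxyl) whose
occupancy rises sharply on binding; F96 is a weaker, solvent-dominated
donor with a small occupancy increase -- mirroring the reported
interpretation. Default size is 2500 frames x 4 replicates, mirroring the
four-replicate 25 ns design; the aggregate is the mean of replicate means.

What the generator does **not** emulate: real force-field energetics,
protein conformational sampling, explicit water, polarization, or any
coupling between field and frequency (no Stark tuning rate is applied).
Passing the recovery tests therefore demonstrates that the analysis
machinery -- classification, state-resolved averaging, replicate
aggregation -- is correct, not that the physics of the original
simulations is reproduced.

# Structure observables

`readStructure()` parses PDB files via bio3d, resolving alternate
locations to the highest-occupancy conformer (ties keep altloc A; the
underlying structures are high resolution, so this is rarely consequential).
`nearestDonors()` reports whitelist-element (N/O) heavy atoms within a
cutoff of the nitrile nitrogen -- crystal structures carry no hydrogens,
so this is heavy-atom contact geometry, not full hydrogen-bond
classification -- and `ringToRingDistance()` the centroid--centroid
distance between ring-atom selections, with the oCNF/pCA atom names
packaged in `ringAtomMap()`. Chain selection defaults to a single chain
('A' in the synthetic models) and is configurable.

Because this package ships no deposited coordinates, the module is
demonstrated on `syntheticSite()` models -- programmatically built,
explicitly synthetic stand-ins embodying the reported site geometry: F92
with a threonine hydroxyl at 2.9 &#197; and a water at 3.2 &#197;; F28 with a
single water at 3.2 &#197;; F62 and F96 with carbon-only environments within
3.5 &#197;; chromophore-ring centroids at 15 / 10 / 12 / 5 &#197;. Pointing
`readStructure()` at locally downloaded deposited files reproduces the
same observables from real data; distances quoted with "~" should be read
at &#177;1 &#197;.

# Numerical choices and problem sizes

* Tolerances: noiseless round-trips are checked to 10^-6^ OD; Coulomb
  equivalence against an independently coded brute-force sum to 10^-8^
  MV/cm; rigid-motion invariances to 10^-9^.
* Degenerate inputs: flat spectra yield flagged non-convergence;
  non-positive intensity ratios, singular charge placements and ambiguous
  atom selections raise errors naming the offending grid point or atom.
* Tie-breaks: coincident peak candidates collapse by prominence; altloc
  ties keep 'A'.
* Reported simulation sizes (chosen to make Monte-Carlo error comfortably
  smaller than the quantities of interest): 20 seeded acquisitions per
  condition for shift recovery; 20 series x 8 levels per preset for the
  LOD comparison; 10^4^ frames per preset for field recovery; 200 seeds
  for the LOD-estimator recovery check.

# Known limitations

* The noise model is per-point white (correlated across channels, not
  across wavenumber); real QCL sweeps have structured noise the
  balanced-cancellation property only partially constrains.
* Fit standard errors assume white residuals; see the note on smoothing
  above.
* The LOD presets are anchored, not predictive; transferring them to a
  different band strength or pathlength requires re-anchoring.
* The trajectory generator is a geometric emulator with a single explicit
  donor; multi-donor competition and exchange dynamics beyond a two-state
  Markov chain are not represented.
* Beer--Lambert pathlength scaling assumes equal absorbance noise across
  pathlengths, i.e. it ignores the transmission loss from the water band
  that in practice sets the usable pathlength itself.
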