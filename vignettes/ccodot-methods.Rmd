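---
title: "Broadband DOT of hemoglobin and cytochrome c oxidase: models and methods"
author: "ccodot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Broadband DOT of hemoglobin and cytochrome c oxidase: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Functional near-infrared spectroscopy (fNIRS) monitors changes in
oxy-hemoglobin (HbO2) and deoxy-hemoglobin (HHb) concentration in the brain
through multi-wavelength attenuation measurements between scalp optodes.
Broadband systems additionally resolve the redox state of cytochrome c
oxidase (oxCCO), the terminal enzyme of the mitochondrial respiratory chain,
whose concentration is roughly an order of magnitude below hemoglobin. With
overlapping, multidistance channels, diffuse optical tomography (DOT)
reconstructs volumetric images of these concentration changes rather than
channel-wise summaries. `ccodot` implements that pipeline end to end on
synthetic phantoms: acquisition emulation, attenuation preprocessing,
channel-space (UCLn) spectroscopy as the comparison baseline,
diffusion-approximation forward modelling, multispectral regularized image
reconstruction of two or three chromophores, and the two- versus
three-chromophore residual-spectrum analysis that asks whether an oxCCO
signature is present in the data.

# Measurement model

Attenuation at wavelength $\lambda$ is $A_\lambda = \log_{10}(I_0 /
I_\lambda)$ with an arbitrary reference intensity $I_0 = 10^5$; attenuation
*changes* are independent of $I_0$. The linearized (Rytov) forward model
relates attenuation changes to absorption changes through the sensitivity
(Jacobian) matrix $J_\lambda$, and absorption changes to chromophore
concentration changes through the specific absorption coefficients
$\epsilon_\lambda^c$:

$$\Delta A_{\lambda} = J_\lambda \, \Delta\mu_{a,\lambda}, \qquad
  \Delta\mu_{a,\lambda} = \sum_c \epsilon_\lambda^c \, \Delta C_c .$$

Stacking wavelengths gives the multispectral system whose block
$(\lambda, c)$ is $J_\lambda \epsilon_\lambda^c$; `ccodot` never
materializes these blocks, applying the operator and its adjoint
matrix-free (`ms_apply()`), with adjoint consistency tested to $10^{-10}$.

# Acquisition emulation

The synthetic acquisition mirrors a broadband visual-stimulation protocol:
4 sources in a central row and 14 detectors in two flanking rows, each
source paired with its 8 nearest detectors (32 overlapping channels at two
source-detector distances, roughly 16.8 and 27.0 mm at the default 15-mm
pitch); 1-Hz sampling; 20 s stimulation / 20 s rest over 10 epochs (400 s);
wavelengths 740–900 nm. The default phantom is a 120 x 72 x 40 mm layered
slab (6 mm scalp, 6 mm skull, 2 mm CSF, brain below) so the full array fits
on the surface with margin.

The activation is a spherical raised-cosine blob restricted to brain
tissue, radius 15 mm, centred under the array at 16 mm depth — i.e. at the
cortical surface just below the CSF. Those two numbers are the package's own
design choices: a full-field inverting checkerboard drives an extended patch
of visual cortex, and cortical activations sit at the top of the cortex, not
deep in the volume. Peak amplitudes default to +1.0 uM HbO2, −0.3 uM HHb and
+0.1 uM oxCCO (oxCCO an order of magnitude below hemoglobin), with a
trapezoidal time course (5 s rise, plateau to stimulus end, 10 s fall).
Measurement noise is additive Gaussian on attenuation with default standard
deviation 5e-4 OD per 1-Hz sample, fully seeded. The generator can simulate
on a finer grid than the reconstruction (`simulation_geometry`) so recovery
tests can avoid the matched-operator "inverse crime".

What the generator does *not* emulate: physiological noise (cardiac, Mayer
waves), superficial-layer confounds, motion, optode-coupling drift, and
subject anatomy. Passing recovery tests on this phantom therefore
demonstrates correctness of the algorithms under the stated model, not
field performance on human data.

# Preprocessing

Raw intensities are converted to attenuation, band-pass filtered with a
fifth-order Butterworth (0.01–0.25 Hz), block-averaged over epochs into a
40-s mean trace, and subsampled to 17 wavelengths (740 to 900 nm in 10-nm
steps). Two conventions are deliberate choices, exposed as options:

* **Zero-phase filtering** (forward–backward `filtfilt`): a causal pass
  would delay the averaged hemodynamic response; each trace is demeaned
  first to suppress the start-up transient.
* **Epoch re-zeroing**: each epoch window has its value at stimulus onset
  subtracted before averaging, so the output is the mean change relative to
  onset (`rezero = FALSE` disables it).

Wavelength subsampling takes the nearest measured sample (ties toward the
lower wavelength) rather than interpolating, because broadband spectrometer
bins are dense relative to the 10-nm grid.

# Spectra and channel-space spectroscopy

The packaged extinction tables for HbO2, HHb and the oxidized-minus-reduced
oxCCO difference spectrum are smooth parametric stand-ins anchored to
widely cited literature values, at 2-nm resolution over 700–1000 nm — they
are labelled synthetic in the file headers and are not digitized copies of
any compendium. The oxCCO entry is the *difference* spectrum (the quantity
that multiplies a redox-state change), stored as a non-negative magnitude
with its broad band centred near 830 nm. All forward and inverse
computations in the package share one table, so every correctness statement
is self-consistent; the exact digitization affects realism only. The same
holds for the differential-pathlength-factor (DPF) table (a smooth decline
from about 6.3 at 740 nm to 5.2 at 900 nm) and the per-tissue optical
properties. A constant-DPF fallback (default 6.0) is available and warns
that channel concentrations are then uniformly scaled.

`ucln_fit()` solves the modified Beer–Lambert model
$\Delta A(\lambda) = \epsilon(\lambda)\,\Delta C \, d \, \mathrm{DPF}(\lambda)$
per channel and time point by unweighted least squares over wavelengths
(pseudoinverse of the DPF-scaled extinction matrix), in either the
three-chromophore or the hemoglobin-only mode. Source–detector distances
are Euclidean distances from the optode array.

# Forward model

Continuous-wave light transport uses the diffusion approximation
$-\nabla\!\cdot(\kappa\nabla\Phi) + \mu_a \Phi = q$,
$\kappa = 1/\bigl(3(\mu_a + \mu_s')\bigr)$, discretized with a 7-point
finite-volume stencil on the regular voxel grid — the same continuous model
as a tetrahedral FEM, but exactly testable against closed forms at desk
scale. The boundary condition defaults to the partial-current (Robin)
condition with the internal-reflection parameter for refractive index 1.4;
pure Neumann is available (`bc = "neumann"`) for comparison with analyses
that state it. Optodes are modelled as Gaussian boundary profiles
($\sigma = 2$ mm, truncated at $3\sigma$, unit power), snapped to the
nearest boundary face; a point-source mode supports analytic benchmarks.

Jacobians use the adjoint method in Rytov form,
$J(\mathrm{ch}, v) = \Phi_s(v)\,\Phi_d(v)\,V_v / (m_{\mathrm{ch}} \ln 10)$,
which is the exact derivative of the discrete model's log10 attenuation
with respect to voxel absorption; reciprocity holds by symmetry of the
discrete operator. Verified properties: depth decay against the
semi-infinite Green's function with effective source depth $1/\mu_s'$
(within 10% beyond 3 mm at 2-mm spacing), finite-difference consistency
(2% for a uniform 1e-4 mm$^{-1}$ bump, 5% for random sparse fields up to
1e-3 mm$^{-1}$), and grid-refinement convergence of channel predictions.
`project_to_grid()` moves fields between grids by exact cell-overlap
integration, conserving the field integral to well under 0.5%.

# Inverse problem

The reconstruction minimizes
$\|\Delta A - J\,\Delta C\|^2_{\Gamma_e^{-1}} + \lambda\,
 \|\nabla(\Delta C)\|^2_{\Gamma_x^{-1}}$
with $\Gamma_e^{-1}$ the identity and
$\Gamma_x^{-1} = \mathrm{diag}(C_b^{-2})$ built from background
concentrations (56 uM HbO2, 24 uM HHb, 12.8 uM oxCCO — the doubled oxCCO
value reflecting its higher concentration in visual cortex). Dividing each
chromophore image by its background ("sphering") makes the first-order
Tikhonov penalty weigh all chromophores equally. Concretely the solver
works in sphered variables $y_c = x_c / C_b^c$ on the augmented
least-squares system $[\,A S;\ \sqrt{\lambda} L\,]\,y = [\,\Delta A;\ 0\,]$
with $S = \mathrm{diag}(C_b)$ and $L$ the per-chromophore forward-difference
gradient (zero-gradient far boundary, so constants are unpenalized and the
image mean is not suppressed). The spec-level question of whether $\lambda$
applies before or after sphering is fixed by this formulation: the penalty
is $\lambda\|L y\|^2$, equal to the stated functional exactly, and the
equivalence is tested against a dense SVD oracle.

LSQR (Paige–Saunders) solves the augmented system matrix-free, starting
from zero (deterministic), capped at 50 iterations with tolerance 1e-5 by
default and $\lambda = 10^{-4}$; `lcurve_select()` reconstructs over a
$\lambda$ grid and picks the maximum-curvature point of the log–log
(residual, penalty) curve. Reconstruction is independent per time point
(default frames 2, 10, 20, 30 and 40 s); iteration counts are recorded on
every image. Numerical edge cases: zero data short-circuits to the exact
zero image; non-finite iterates abort with an error; a rank-deficiency of
the augmented operator (constants visible only through the data term) is
handled by LSQR's minimum-norm behaviour.

Two caveats documented deliberately:

* With a 50-iteration cap the solution is *semi-converged*; this acts as
  additional regularization and in practice yields more compact images than
  the exact minimizer, which extends a near-constant, penalty-free tail
  into the deeply insensitive part of the volume.
* The stated sphering-equivariance folklore (scale one chromophore's
  background and true signal jointly and the reconstruction scales exactly)
  is only approximate: the transformation leaves the penalty invariant but
  not the data term. The tests assert the exactly-true properties
  (penalty invariance; linearity of the converged solution in the data).

# Residual analysis

For one measured frame reconstructed with both chromophore sets,
`residual_difference()` forms $r_k = \Delta A - J\,\Delta C_k$ in
reconstruction voxel space (before any surface mapping) and returns
$r_2 - r_3$ per channel: the spectral structure the hemoglobin-only model
cannot explain. With a genuine oxCCO change in the data this difference
takes the shape of the oxCCO difference spectrum in channels over the
activation (quantified by `spectrum_similarity()`: Pearson correlation and
the peak of a 3-point moving average) and is near nil in distant channels.
The nesting property $\|r_3\| \le \|r_2\|$ holds because the
two-chromophore model is the three-chromophore model restricted to a zero
oxCCO image at identical settings. Averaging across participants is
replaced by averaging across simulation repetitions. No formal model
comparison (AIC, likelihood ratios) is attempted — the analysis argues by
spectral shape, and residuals of an ill-posed regularized inversion deserve
caution.

# Problem sizes and study conditions

The package's standard problem sizes, chosen once as desk-scale defaults:
the default phantom reconstructs on its 2-mm grid (60 x 36 x 20 voxels,
about 130k unknowns for three chromophores); the test suite exercises the
same analyses at 3-mm spacing, with a 4-mm reconstruction of 2-mm data for
the mismatched-resolution check; dense-oracle comparisons use toys of at
most a few hundred unknowns. Wider arrays, finer grids (e.g. the 50 x 60 x
50 grid used with atlas head models) and an unstructured-mesh forward
backend are configuration or extension points, not defaults.

Under these conditions the pipeline localizes the activation centroid to
within a fraction of the blob radius and recovers the correct signs of all
three chromophores from noiseless data, and the residual-difference spectra
over the activation correlate strongly with the oxCCO spectrum. Two honest
limitations, visible in the acceptance outputs rather than hidden: the
brain-voxel correlation between reconstructed and true images plateaus
around 0.45–0.55 (first-order Tikhonov has no depth weighting, so the
focal target is reconstructed wider and shallower than truth), and with the
default noise level the tiny oxCCO component (~1e-5 OD of signal against
~1e-4 OD of block-averaged noise) has a seed-dependent reconstructed sign.
Both are properties of the method under the stated conditions, not solver
defects — the solver itself matches dense oracles to near machine
precision.

# Known limitations

* The diffusion approximation is poor inside low-scattering CSF; the thin
  CSF layer uses a reduced-scattering floor, as is common in head models.
* Extinction, DPF and tissue-optics tables are synthetic stand-ins;
  absolute concentration scales inherit their uncertainty, self-consistent
  analyses do not.
* No scattering reconstruction, no nonlinear (iterated) updates, no
  temporal regularization, no physiological-noise model.
* The channel-space UCLn baseline weights wavelengths uniformly; weighted
  variants would need a noise model per wavelength.
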