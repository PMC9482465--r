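---
title: "Simulating and decomposing gas- and liquid-phase electron diffraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decomposing gas- and liquid-phase electron diffraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumediff)
```

plumediff models the diffraction signal of a pulsed-source experiment in
which a single sample delivery system produces, at different probe delays,
isolated gas-phase molecules and nanoscale liquid domains of the same
substance (glycerol is the shipped reference). The package simulates both
phases from atomic coordinates, synthesizes realistic noisy detector images,
reduces images back to one-dimensional curves, inverts them to real-space
pair distributions, and quantifies the gas/liquid composition of a measured
curve. This vignette is the package's account of the underlying models, the
parameters that matter, and the choices made where the methodology was
genuinely open.

## The independent atom model

All scattering is computed in the independent atom model (IAM): each atom
scatters with its isolated-atom elastic amplitude $f_i(s)$, and molecular
structure enters only through interatomic distances. With the
momentum-transfer magnitude $s = (4\pi/\lambda)\sin(\theta/2)$ (Å⁻¹), the
two coherent components are

$$I_{atom}(s) = \sum_{i=1}^{N} |f_i(s)|^2, \qquad
  I_{mol}(s) = \sum_{i=1}^{N}\sum_{j \ne i} |f_i||f_j|
  \cos(\eta_i - \eta_j)\,\frac{\sin(s\,r_{ij})}{s\,r_{ij}},$$

where $r_{ij}$ are internuclear distances and $\eta_i$ scattering phases.
The $s \to 0$ limit of $\sin x / x$ is taken analytically as 1, never by
grid exclusion. Amplitudes use the Peng–Ren–Dudarev–Whelan five-Gaussian
parametrization for H, C, O; phases default to zero, which is accurate for
light elements at ~100 kV, but the phase slot is honoured throughout so the
general interference term is implemented in full. A measured total is
modelled as $I_{tot} = I_{atom} + I_{mol} + I_{bg}$ with $I_{bg}$ a smooth
experimental background.

The electron wavelength is the relativistically corrected de Broglie value
($\lambda = 0.0370$ Å at the default 100 kV; the accelerating voltage is a
parameter because the source energy of any given instrument is
configuration, not physics).

For large atom sets the pairwise sum is evaluated through a per-element-pair
distance histogram with 0.002 Å bins — the standard Debye accelerator. The
maximal phase error $s\,\Delta r/2 \le 0.01$ rad over the working range is
negligible; the direct pair loop is retained as the reference path and the
two are cross-checked in the test suite, as is the exact equivalence of the
direct path with an independent double-loop oracle.

`molecular_intensity()` evaluates the sum, `atomic_intensity()` the atomic
term, `total_intensity()` their combination (accepting a molecule, a liquid
configuration, or an ensemble of configurations), and `s2_weighted()`
applies the $I \times s^2$ display convention in which detector patterns
are customarily shown.

## The liquid model: random-packed rigid droplets

A liquid's diffraction differs from the gas by intermolecular pair
correlations. The package's structural model is deliberately minimal: $n$
rigid copies of the molecule, uniformly random orientations, packed into a
sphere whose radius is fixed by the target mass density (default
1.26 g/cm³ for glycerol, giving ~18 Å for 200 molecules), under a hard
minimum intermolecular heavy-atom distance (default 3.2 Å, a van der Waals
contact). The Debye sum then runs over the flattened atom set, so every
intra- and intermolecular pair contributes, and curves are averaged over an
ensemble of packing seeds (default 10) recorded in the output metadata.

Plain sequential rejection sampling cannot reach liquid glycerol density
under this contact constraint — random sequential addition saturates near
38% packing fraction, below what 1.26 g/cm³ demands. `pack_droplet()`
therefore seeds the configuration by rejection sampling in a sphere
inflated by 1.35× and compresses it radially (in the manner of Jodrey–Tory
hard-sphere packing): all centers shrink by 1.5% per step, violated
contacts are resolved by pushing the two molecules apart along their center
line, and the loop ends when the target radius is reached with the
constraint exactly satisfied. The result is deterministic for a given seed,
and genuinely infeasible requests still fail loudly with the attempt count.

**What this model reproduces and what it does not.** It produces a
well-defined nearest-neighbour shell (center-of-mass spacing ~4.5–5.5 Å at
the default density) and hence a low-$s$ intermolecular diffraction ring
that is entirely absent from the single-molecule curve — the qualitative
liquid signature. It does not reproduce hydrogen bonding: with a 3.2 Å hard
floor, the O···O contacts near 2.7–2.8 Å that dominate real glycerol's
short-range order are excluded by construction. The consequence is
quantitative: the simulated ring sits near 1.33 Å⁻¹ (set by the
density-limited center spacing, $\approx 2\pi/4.8$ Å), whereas the
experimental liquid-glycerol ring is near 1.6 Å⁻¹, reflecting those closer
hydrogen-bonded heavy-atom shells. Equilibrating the packed droplet by
hard-constraint Monte Carlo moves does not move the ring; the displacement
is structural, not an artifact of the packing algorithm. A physically
faithful ring position would require either an experimentally informed
pair-correlation model or a contact criterion that admits hydrogen-bond
distances; both are outside the present scope, and tests that compare the
ring position against the experimental value are expected to fail for this
reason. Droplet-boundary small-angle scattering decays rapidly and is
negligible above ~1 Å⁻¹, so it does not contaminate the ring window.

## Detector forward model and reduction

`render_image()` maps a 1D curve to an isotropic image: each pixel's $s$
follows from its radial distance via $\theta = \arctan(r/L)$ and the exact
$s$ formula, the curve is linearly interpolated at the pixel's $s$ (the
0.02 Å⁻¹ grid makes higher-order interpolation irrelevant), expectations
are normalized to a requested total count (or left on the curve's own
scale with `total_counts = NULL`, which matters when relative scales of
several curves must survive rendering), and Poisson counts are drawn per
pixel under a seed; `seed = NULL` returns the expectation image. The
default geometry is 1024×1024 pixels, 0.0575 mm pitch, 500 mm camera
length, 100 kV — chosen so the largest fully sampled annulus lands at
~9.98 Å⁻¹, just inside the default simulation grid. Corner pixels beyond
the curve's range are masked rather than extrapolated. No solid-angle or
flat-detector correction is applied: in this small-angle regime the effect
is below one percent. A configurable central beam-stop mask exists and is
off by default.

`radial_average()` bins usable pixels into annuli (default width 0.02 Å⁻¹,
matching the grid) and reports per-bin means, pixel counts, and standard
errors; empty bins are reported as missing, never silently interpolated.
The curve abscissa is the mean pixel $s$ per bin rather than the geometric
bin center, which removes the binning bias of the sparse innermost annuli.
`find_center()` refines a beam center by minimizing pooled within-annulus
variance over a two-stage (integer, then quarter-pixel) local search; a
flat image is refused with a warning rather than "refined".

## Inversion to real space

The reduced observable of gas electron diffraction is the modified
molecular scattering $sM(s) = s\,I_{mol}/I_{atom}$. Its damped sine
transform

$$f(r) = \int_0^{s_{max}} sM(s)\,\sin(s r)\,e^{-k s^2}\,ds$$

peaks at interatomic distances weighted by scattering power. Quadrature is
trapezoidal on the curve's own uniform grid (no resampling); $f(0) = 0$
holds exactly because the sine kernel vanishes. Defaults: $s_{max} =
10$ Å⁻¹; damping $k = -\ln(0.1)/s_{max}^2 \approx 0.023$ Å², the
conventional choice that reduces the integrand to 10% at the cutoff and
suppresses truncation ringing; $r$ grid 0–8 Å in 0.01 Å steps. Because the
small-angle region of measured patterns is unreliable, `splice_low_s()`
substitutes the theoretical $sM$ below a cutoff (default 0.8 Å⁻¹) with a
0.2 Å⁻¹ linear cross-fade so no step is introduced.

**Baseline removal.** `extract_sm()` separates $I_{mol}$ from a total curve
by modelling the non-molecular remainder of $I_{tot} - I_{atom}$ as a
low-order polynomial in $s$. This is less innocent than it looks: after
division by $I_{atom}$, which is small at high $s$, tiny baseline errors
are strongly amplified, and the slowest genuine interference components
(bonded C–H/O–H pairs complete fewer than two oscillation periods over the
working range) are nearly degenerate with any smooth baseline family. The
implemented estimator is two linear stages: a least-squares fit of the
baseline images $s^{j+1}/I_{atom}$ weighted by the square root of the
Gaussian damping window, followed by removal of the baseline combination
that minimizes the damped transform content below 0.3 Å — distances below
any chemical bond, where genuine molecular scattering leaves almost
nothing but residual baseline maps strongly (the classic
flatness-below-bond-distances criterion), with a small ridge (0.01) for
stability. Both stage parameters were fixed by forward-model validation:
on synthetic totals the recovered $sM$ agrees with the true curve to 0.7%
(background-free, order 0) and 1.7% (cubic background, order 3) relative
RMS in the damping-weighted metric — the metric in which $sM$ errors
propagate into $f(r)$ — and real-space peak positions are preserved to
better than 0.03 Å. Full-range unweighted RMS is larger (a few percent)
because the high-$s$ tail beyond the damping window is intrinsically
ill-determined; consumers of the undamped tail should treat it with
caution.

## Mixture decomposition

`fit_mixture()` is the package's fitted-model object. An observed curve is
modelled as

$$I_{obs}(s) \approx c_g\,I_{gas}(s) + c_l\,I_{liq}(s) + \sum_{j=0}^{p} b_j s^j$$

by least squares on $I \times s^2$ over a fit window (default
0.8–8 Å⁻¹: the weighting and window emphasize the discriminating liquid
ring and the interference oscillations over the steep, unreliable
small-angle region). The physical coefficients $c_g, c_l$ are constrained
non-negative; with only two constrained coefficients the non-negative
solution is found exactly by enumerating the active sets, so no iterative
NNLS is needed. Background coefficients are unconstrained. Near-collinear
basis pairs are rejected by a condition-number check after projecting out
the background. Reported percentages are intensity fractions
$100\,c_i/(c_g + c_l)$, invariant under any rescaling of the observation;
with per-molecule-normalized bases they coincide with molecular fractions.
An unconstrained diagnostic fit is available behind `nonneg = FALSE`, and
`delay_series()` maps the fit over a delay-indexed set of observations,
flagging failed rows and continuing.

Two practical points matter for unbiased fractions. First, when observed
curves have passed through the detector (rendering, binning), the basis
curves must pass through the *same* linear operator — `end_to_end_check()`
renders both bases noiselessly on their own scale and radially averages
them before fitting. Renormalizing each projected basis separately would
destroy their relative scattering power and bias the fractions by several
points. Second, the default quadratic background of `fit_mixture()` cannot
absorb an exponential-shaped background without a ~2-point bias; the
end-to-end recovery check therefore uses order 4, which nests the
generator's smooth background family to well below 0.1 point. The fitter's
own default stays at 2, appropriate when no strong smooth background is
present.

## The synthetic experiment generator

`scenario_config()` + `generate_scenario()` emulate a delay-indexed
measurement series: for each delay the expected curve is
$(1-x)\,I_{gas} + x\,I_{liq}$ on a per-molecule scale plus a smooth
background, rendered to a Poisson-noisy image at a per-delay seed. Defaults
are the reference study conditions: delays 4, 6, 8, 10 µs with liquid
fractions 0.39, 0.41, 0.35, 0.26; 10⁷ expected counts per image (enough
that the liquid ring is far above shot noise); background = exponential
decay (constant 3 Å⁻¹) plus a 5% floor, scaled to 20% of the image counts —
the physical origins of the experimental background (inelastic and multiple
scattering) fix no functional form, so the simplest smooth two-parameter
shape is used; liquid basis from 200 molecules averaged over 10 packing
seeds. Bundles regenerate bit-identically from their configuration, and
`write_scenario()` lays a bundle out as a manifest, a truth table, basis
curves, and 16-bit TIFF images with plain-text sidecars.

What the generator emulates: isotropic count-limited patterns that are
count-weighted two-phase mixtures with a smooth background and known truth.
What it does not: beam anisotropy and polarization of the source,
shot-to-shot jitter, detector point-spread and readout noise, inelastic
background structure, and — inherited from the droplet model — the
hydrogen-bond-driven position of the liquid ring. Passing recovery tests
therefore demonstrate the correctness and statistical efficiency of the
reduction-and-unmixing chain under the stated noise model, not fidelity of
the liquid structure itself.

`end_to_end_check()` runs radial averaging and mixture fitting over a
bundle and reports recovered versus true fractions. Under the default
conditions the recovered liquid percentages match truth to within 0.1
percentage point on expectation (noiseless) images and within 2 points at
10⁷ Poisson counts; both margins are asserted by the test suite, which also
verifies that the error shrinks monotonically as counts grow from 10³ to
10⁷ and that the low-count regime is flagged.

## Numerical and scale choices

* Exact arithmetic where exactness is the point: `consumption()` converts
  to integer femtoliters before multiplying, so decimal picoliter inputs
  produce exact nanoliter outputs.
* Seeded operations (`pack_droplet`, `render_image`, scenario generation)
  save and restore the caller's RNG state; a seed argument never has the
  side effect of reseeding the session.
* Problem sizes: the default simulation grid is 501 points (0–10 Å⁻¹); the
  test suite exercises droplets of 30–100 molecules and 128–256 px
  detectors, while the slower end-to-end checks run the full reference
  conditions (200 molecules × 10 seeds, 1024² pixels, 10⁷ counts) — sizes
  chosen so the entire suite completes in a few minutes on one core.
* Degenerate inputs are handled explicitly: single atoms (zero molecular
  sum), single-molecule "droplets" (identical to gas), zero curves (render
  to zero images), flat images (center refinement refused), fully masked
  images and empty fit windows (errors).

## Known limitations

* One fixed conformer; conformational averaging is out of scope, and peak
  positions in $f(r)$ shift by a few hundredths of an Ångström across
  plausible conformers.
* The liquid ring position is structurally displaced from the
  hydrogen-bonded experimental value, as discussed above.
* The IAM ignores chemical bonding effects on scattering factors and all
  inelastic processes; backgrounds are phenomenological.
* The two-phase decomposition assumes exactly two basis spectra; a
  temperature-dependent liquid basis or a third phase is not modelled.
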