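---
title: "Monte-Carlo diffusion-MRI simulation: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte-Carlo diffusion-MRI simulation: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdsim)
```

# The problem

Monte-Carlo diffusion simulation (MCDS) is the standard way to produce
ground-truth diffusion-weighted MRI signals for geometries where no closed
form exists: random walkers emulate water molecules diffusing among
impermeable barriers, and their accumulated spin phase under a pulsed
gradient spin-echo (PGSE) sequence yields the signal. The quality of such
ground truth depends on choices that are easy to get wrong: too few
particles or time steps, idealized straight-cylinder axons, or
extra-axonal spaces built from too few cells. `mcdsim` implements the
simulation stack and a set of study drivers that quantify exactly those
sensitivities.

# Signal model

For one walker, the phase accumulated under a rectangular-pulse PGSE
sequence with gradient vector $G$, pulse duration $\delta$, separation
$\Delta$ and echo time $TE$ is

$$\phi = \gamma \sum_k a(t_k)\, G \cdot x(t_k)\, w_k,$$

where $x(t)$ is the walker's displacement from its start, $a(t)$ is $+1$
before the refocusing pulse and $-1$ after, and $w_k$ is the gradient-on
time within step $k$. The normalized signal is the modulus of the complex
ensemble mean $\langle e^{-i\phi}\rangle$; per-compartment signals use the
(constant) walker labels assigned at initialization. Compartments are
impermeable, so intra/extra separation is exact and the total complex mean
is the label-weighted mixture of the compartment complex means to machine
precision (asserted in the tests).

Two numerical details matter:

* **Exact pulse-window weights.** The weight $w_k$ is the exact overlap of
  the step interval with the two pulse windows (sign included), not the
  value of $G(t)$ at a sampled instant. The weights then sum to zero
  exactly over the echo, so a static spin refocuses to machine precision —
  with instant sampling this identity holds only to $O(dt)$. The sequence
  is centered in the echo: the first pulse starts at $(TE-\Delta-\delta)/2$.
* **Unwrapped displacements.** Phase uses the unwrapped displacement from
  the start position; wrapping into the periodic voxel applies only to
  collision queries. On periodic substrates this distinction is essential —
  wrapped coordinates would produce spurious phase jumps.

Steps have the fixed Einstein length $r = \sqrt{6 D\, dt}$ with uniformly
random orientation; fixed (rather than Gaussian) step lengths reduce the
fluctuation of the mean squared displacement. Barriers reflect specularly:
at each hit the residual step is mirrored about the surface normal until
the full length is consumed, with a $10^{-12}$ m off-surface nudge to
avoid re-intersection from floating-point residue. A walker exceeding 100
reflections in one step keeps its last safe position and a counter is
incremented (reported in the run attributes, never an exception mid-run).
Cylinder collisions are solved analytically in the 2D cross-section;
meshes use ray–triangle intersection on a uniform spatial grid.
Point-in-mesh tests take a majority vote over three skewed rays so that
rays through triangle edges cannot flip the classification.

Reproducibility is bitwise: every walker owns a counter-seeded xoshiro256++
stream derived from the master seed, so results are independent of
execution order.

# Analytic references

The Gaussian Phase Distribution (GPD) approximation gives the
perpendicular attenuation of an impermeable cylinder as a series over the
roots of $J_1'$; `gpd_perpendicular_attenuation()` truncates the series
when the next term contributes less than $10^{-10}$ relative, against a
table of 1024 roots computed once by bracketed bisection to $10^{-14}$.
(64 roots suffice for micrometer radii; the larger table lets the same
tolerance hold for near-free cylinders of hundreds of micrometers.) A full
cylinder signal multiplies the GPD term by $\exp(-b_\parallel D)$ for the
parallel gradient component; populations combine cylinders by
cross-sectional-area weights (common length cancels). Scalar formulas
provided alongside: the resolution limit
$d_{min}=(768\sigma D/7\gamma^2\delta|G|^2)^{1/4}$, the undulation
tortuosity $\lambda=\sqrt{(2\pi A/L)^2+1}$, and the effective radius
$r_{eff}=(\langle r^6\rangle/\langle r^2\rangle)^{1/4}$.

Errors between signal vectors are summarized by the relative mean absolute
error (RMAE, percent) with the first argument as ground truth; references
below $10^{-12}$ raise rather than being skipped, so studies never drop
measurements silently.

# Substrates

* **Packed parallel cylinders.** Diameters are gamma draws (optionally
  floor-truncated by rejection, which preserves the shape above the
  floor); the voxel side is set so $\sum\pi r_i^2/\mathrm{side}^2$ equals
  the target ICVF; placement is random sequential addition in descending
  radius order with minimum-image overlap tests (periodic boundaries).
  RSA reliably reaches ICVF $\le 0.7$; denser requests are refused. The
  default ICVF is 0.60.
* **Undulating axons.** A tube of constant circular cross-section swept
  along the helix $U(z)=(A\cos(2\pi z/L), A\sin(2\pi z/L), z)$ with a
  parallel-transport frame (a Frenet frame would flip at inflections).
  Meshes are closed with end caps, watertight and outward-oriented by
  construction; a tube whose radius exceeds the centerline's radius of
  curvature is refused before meshing. End caps mildly restrict axial
  diffusion near the ends, so study meshes span many wavelengths (default
  8) to keep walkers away from the caps on the diffusion length scale.
* **Strand systems.** Crossing bundles are built from strands (polylines
  with radius). The energy $E = w_o J_o + w_c J_c + w_l J_l$ penalizes
  capsule–capsule overlap, turning angles, and excess length over the
  endpoint chord; all three terms are dimensionless (penetration is
  normalized by the pair's radius sum) so the default weights
  $w_o=10^3, w_c=w_l=1$ compare like with like and overlap dominates. The
  optimizer is greedy stochastic descent over interior control points with
  pinned endpoints — reproducible and adequate at desk scale (tens of
  strands); a simulated-annealing schedule was deliberately avoided to
  keep the energy trace non-increasing and testable. Parent strands are
  subdivided by packing gamma-law disks (floor-truncated at 0.2 um
  diameter) inside the parent cross-section and sweeping them along the
  parent's transported frame; disks that do not fit are skipped, which
  under-represents the tail of the diameter distribution — the same
  qualitative bias any in-disk packing shows, and the reason the effective
  radius of a subdivided bundle falls short of the parent law's.

# Acquisition protocols

Built-ins store the published pulse parameters: the four-shell ex-vivo
ActiveAx protocol (including its two printed-identical shells, kept as
printed) at $TE=0.054$ s, the three-shell optimized ex-vivo protocol at
$TE=0.0359$ s, and a radial xy-plane probe ($G=0.3$ T/m, $\delta=0.010$ s,
configurable $\Delta$ list, 180 in-plane directions, $TE=0.075$ s). The
printed shell b-values of the ActiveAx protocol are not perfectly
consistent with b computed from the printed $(G,\delta,\Delta)$; the
package stores the pulse parameters and computes b, documenting rather
than resolving the discrepancy. Direction tables for the published
protocols are not available, so direction sets are electrostatic-repulsion
point sets with a fixed internal seed. Scheme files use the de facto text
standard for MC simulators: one header line, then
`gx gy gz |G| Delta delta TE` per row, SI units.

# Study drivers and their scaled sizes

The three drivers are exact re-implementations of the experiment designs,
sized for a desk run; each derives per-cell seeds from one master seed and
is reproducible end to end.

* **Confidence study**: per (particle count, step count) cell, repeated
  simulations against the analytic intra-axonal mixture (or a high-count
  simulated gold standard for the extra-axonal space), summarized by mean
  RMAE per cell. The packaged acceptance run uses a 30-cylinder ICVF-0.60
  substrate, 24 directions per shell, counts $\{10^3,10^4,10^5\}$, 500
  steps and 10 repetitions: large enough that the $1/\sqrt{N}$ error law
  is measurable, small enough to run in minutes.
* **Undulation study**: per (diameter, amplitude, wavelength) cell, an
  undulating mesh, an intra-axonal simulation, and an exhaustive-search
  diameter fit on the 0.4–8.0 um grid with 0.01 um spacing and a 1%-of-
  minimum plausibility interval (the contiguous grid run containing the
  argmin; ties break toward the smaller diameter). The packaged extreme
  cell (1 um diameter, $A=2.6$ um, $L=4$ um) uses 4000 walkers and 2000
  steps — the undulation bias it measures is an order of magnitude larger
  than the Monte-Carlo noise at that size.
* **Voxel-size study**: per cylinder count, a fresh gamma sample, an
  ICVF-0.60 periodic packing, an extra-axonal-only simulation under the
  radial probe, and per-$\Delta$ mean radial signal and anisotropy
  (std/mean). The driver defaults to an extra-axonal diffusivity of
  $0.6\times10^{-10}$ m$^2$/s: with $G=0.3$ T/m and $\Delta$ up to 0.060 s
  the probe's b-values reach $\sim3.6\times10^4$ s/mm$^2$, and only this
  diffusivity regime keeps all shells in a measurable attenuation range
  (every other driver defaults to the ex-vivo $0.6\times10^{-9}$).
  The packaged run uses counts $\{50, 500, 5000\}$ with $2\times10^4$
  walkers and 4 values of $\Delta$.

# What the tests do and do not show

The synthetic substrates emulate the geometry of coherent white matter —
gamma-distributed parallel axons, regular helical undulation, interdigitated
crossings — under noiseless, relaxation-free acquisition (no T1/T2, no
noise floor, no exchange). Passing tests therefore validate the simulation
machinery and the geometric biases it measures, not the behavior of any
estimator on scanner data. Known limitations: compartments are
impermeable; only rectangular PGSE waveforms are supported; mesh substrates
are bounded (reflective box walls stand in for the unbounded extra-axonal
space); full-scale runs ($2\times10^6$–$10^8$ walkers) are out of desk
scope and are represented by the scaled sizes above.

One property check deserves a caveat: the single-cylinder engine-vs-GPD
comparison at $10^5$ walkers carries an irreducible Monte-Carlo noise
floor. The optimized ex-vivo protocol attenuates near-axis measurements of
a 4 um cylinder to $S/S_0\approx 4\times10^{-3}$, where the per-measurement
sampling error of the complex-mean modulus is tens of percent; summed into
the RMAE this contributes more than the 1% headline tolerance all by
itself. The RMAE the suite measures at that size is dominated by this
floor, not by collision or phase-integration bias (the free-diffusion,
refocusing and containment checks bound those independently); reaching 1%
requires roughly the $\ge 5\times10^5$ walkers of a full-scale run.

# Numerical choices, collected

| Choice | Value | Why |
|---|---|---|
| GPD truncation | next term $<10^{-10}$ relative, 1024-root table | series exactness at all radii used |
| Collision nudge | $10^{-12}$ m along the normal | prevents re-intersection from rounding |
| Bounce budget | 100 per step | pathological corners end safely, counted |
| Fit grid | 0.4–8.0 um, 0.01 um step | matches the published fitting procedure |
| Plausibility threshold | 1% above minimum RMAE | matches the published procedure |
| Packing | RSA, descending radii, $10^4$ tries | reproducible stand-in for the cited packer |
| Tube frame | parallel transport | no frame flips on helices |
| RNG | per-walker xoshiro256++ | bitwise reproducibility, order-independent |

# Session info

```{r}
sessionInfo()
```
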