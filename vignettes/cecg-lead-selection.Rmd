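---
title: "Model-based selection of capacitive ECG leads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based selection of capacitive ECG leads: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecglead)
```

`cecglead` simulates the complete chain behind personalized capacitive ECG
(cECG) lead selection for a person seated against electrode-equipped
furniture: a volume-conductor model of the thorax, a forward solver for the
cardiac dipole, a capacitive-electrode model with motion-artifact
sensitivities, an exhaustive electrode-pair search, trace synthesis with an
acquisition chain, and QRS-detection scoring.  This vignette explains the
underlying models, the defaults and their units, the numerical choices, and
what conclusions the simulations do and do not support.

## The volume conductor

The electric potential $\varphi$ generated by the cardiac source
$\mathbf{J}_h$ in a body of conductivity $\sigma(\mathbf{x})$ obeys the
quasi-static equation
$\nabla\!\cdot\!\sigma\nabla\varphi = -\nabla\!\cdot\!\mathbf{J}_h$
with the insulating boundary condition
$\partial\varphi/\partial n = 0$ on the skin.  Quasi-statics is justified
because tissue relaxation times are far below the ECG band; capacitive
tissue effects are neglected accordingly.

Because no individual anatomy is shipped with the package, the torso is a
parametric solid: an elliptic cylinder (semi-axes 0.17 m and 0.13 m, height
0.423 m) containing a heart-wall ellipsoid filled with a blood ellipsoid,
two lung ellipsoids, and a sub-diaphragm half-space.  Conductivities follow
standard low-frequency tissue values: heart muscle 0.2 S/m, blood 0.5 S/m,
lungs 0.05 S/m, thoracic wall and abdominal compartment 0.1 S/m.  The
coordinate frame has $x$ toward the left shoulder, $y$ from back to front
and $z$ upward; the torso dimensions were chosen once so that the heart
base lands at the reference position $(0.1, 0.03, 0)$ m, and are otherwise
free parameters.  Anatomical fidelity is deliberately modest — smoothed
convex organs, no ribs, spine or great vessels (their conductivities are
close to the wall/abdomen values they are merged into), no
respiration-dependent lung conductivity.  The geometry reproduces the
*qualitative* structure of the surface potential (bipolar pattern on the
back, stronger chest potentials), which is what lead selection rests on.

### Meshing and compartment labelling

Meshes are structured: a cube grid is split into six tetrahedra per cell
(Freudenthal subdivision, conforming across cells) and mapped onto the
target solid, so generation is fully deterministic — no meshing randomness
exists to seed.  Boundary vertices of the sphere geometry lie exactly on
the sphere, which makes the analytic comparisons clean.  Tetrahedra are
labelled by compartment with a volume-preserving rule: interface-straddling
tetrahedra are assigned by decreasing inside-fraction (35-point barycentric
lattice) until the labelled volume matches the quadrature volume of the
true intersection.  A plain centroid rule is biased low for small convex
bodies (the blood volume error reached several percent at coarse
resolutions); the volume-preserving rule keeps per-label volumes consistent
within 2% across the resolutions used here.  The grid is additionally
aligned with the diaphragm plane so the half-space cut is
resolution-independent.  Geometry errors (overlapping non-nested
compartments, a compartment poking out of the torso) are detected by
sampled membership audits and abort the build with the offending
compartment named.

The default resolution is 0.015 m (on the order of $10^5$ tetrahedra);
0.02–0.025 m presets are used in the tests and the study pipeline, where
the quantities of interest (lead ranking, amplitude ratios) are already
stable at that size.

## The forward solver

P1 (linear) tetrahedral elements with per-element conductivity and a direct
sparse Cholesky factorization; the factor and element geometry are cached
on the mesh, so repeated solves (the three-basis lead field) cost one
assembly.  The pure-Neumann system is singular; we pin one vertex for the
solve and then remove the constant by the *zero-boundary-mean gauge*.  Lead
voltages are differences of surface potentials and therefore gauge-free; a
test asserts invariance under potential shifts.  The solve is accepted only
if the relative residual is below $10^{-8}$.

The dipole is discretized as monopole pairs $\pm m_i/\delta$ separated by
$\delta$ (default 2 mm) along each coordinate axis, each distributed onto
the vertices of its containing tetrahedron with barycentric weights.  The
axis-decomposed form was chosen over a single pair along the moment
direction because it is *exactly* linear in the moment vector: superposing
the unit-moment basis solutions then reproduces a direct solve to solver
precision rather than to $O(\delta^2)$, and the lead-field basis is exact
by construction.  The load entries sum to zero, which is the compatibility
condition of the Neumann problem; an unbalanced load is rejected.

Accuracy is audited against the closed-form potential of a central dipole
in a homogeneous sphere with insulating boundary,
$\varphi(R,\theta) = 3p\cos\theta/(4\pi\sigma R^2)$: at ~48k tetrahedra the
relative surface $L^2$ error is below 1% and the pole value
(2.387 mV for $p = 2\times10^{-5}$ A·m, $\sigma = 0.2$ S/m, $R = 0.1$ m)
is matched within 2%, improving under refinement.  Surface fields are
recovered from the piecewise-constant element gradients by volume-weighted
averaging onto boundary vertices; the tangential component (the quantity
entering artifact susceptibility) agrees with the analytic
$3p\sin\theta/(4\pi\sigma R^3)$ at the equator within a few percent.

On the angle conventions: azimuth is measured from the $+x$ axis in the
$x$–$y$ plane and elevation as the polar angle from $+z$.  The elevation
reference is a genuine convention choice — nothing in the problem fixes it —
so both angle-based and explicit moment-vector construction are accepted
everywhere (`angles_to_moment()`, `dipole_source(moment = ...)`).

## The capacitive electrode

The electrode (default radius 0.01 m, i.e. a 2 cm disk) is equipotential;
ignoring the measurement system, its potential is the specific-capacitance
weighted average of the body-surface potential under it, with
$C_e = \varepsilon_0\varepsilon_r/d$.  The default gap is 1 mm with
$\varepsilon_r = 1$: a thin cotton layer's capacitance is dominated by the
air gap.  The frequency cancels from the ratio; this is asserted, not
assumed.  The model presumes the plate regime (diameter larger than the
gap) and the electrode's admittance being far below the body's; the first
is flagged with a warning when violated, the second is recorded as an
assumption because no quantitative threshold is available to enforce.

Discretely, the patch is the set of boundary triangles whose centroid lies
within the electrode radius of the centre (an unbiased area estimate whose
boundary-band errors cancel; vertex fallback on very coarse meshes), with
lumped one-third area weights.  Patch membership is Euclidean rather than
geodesic — in the gap ≪ radius regime the difference is negligible at desk
scale.  Electrode centres are snapped to the nearest boundary point first:
physically the electrode rests against the body, and numerically this makes
placements produced by rotations of a lead on a curved surface
well-defined.  Two gap profiles exist: `"uniform"`, and `"plate"`, where a
rigid flat plate's local gap grows with the surface's sag away from the
tangent plane.  A uniform profile cancels exactly from the potential ratio
(implemented as an exact cancellation, not merely to roundoff), so gap
(normal) motion produces *no* artifact; the plate profile is therefore the
one that generates realistic normal-motion artifacts.

Motion sensitivities are explicit finite differences of the potential
ratio, mirroring the two limiting displacement regimes: normal motion
perturbs the gap at fixed potential distribution; tangential motion slides
the patch at a fixed coupling law.  Finite differences were preferred over
symbolic derivatives because each regime has an independent check: the
tangential sensitivity must equal the coupling-weighted mean tangential
field (first-order expansion), which holds within 10% on the sphere oracle,
and both must vanish identically on an equipotential surface.  The artifact
susceptibility score of a site is the magnitude of the coupling-weighted
mean tangential field — large where sliding changes the picked-up
potential fastest.

## Lead optimization

Candidate centres are a deterministic farthest-point subsample of the patch
vertices at the requested spacing (default 0.02 m, the electrode
diameter).  Every non-overlapping pair is evaluated — with per-site
electrode potentials precomputed, exhaustive search over ~40k pairs is
instantaneous — and ranked by

$$\text{combined} = |V_{e,A} - V_{e,B}| \; - \; \lambda \, L \,
(s_A + s_B),$$

where $s$ is the susceptibility score and $L$ the electrode separation
(supplying the length scale that turns V/m into V).  The default is
$\lambda = 0$: maximum R-wave amplitude is the primary published criterion,
and the artifact term is exposed as a tunable secondary penalty rather than
folded in silently, because no joint objective is canonically defined.
Ties break toward lower susceptibility, then lexicographic position, making
the ranking fully deterministic.

On the sphere oracle the optimal pair straddles the dipole's surface
projection: the best axis aligns with the heart axis to within one
grid-step angle, and brute-force re-evaluation of all pairs confirms the
ranking.  `amplitude_vs_angle()` rotates the lead about the surface normal
through its midpoint with fixed separation (how misaligned leads are placed
is otherwise unspecified, and this is the symmetric choice); on dipolar
fields the amplitude falls monotonically through 15° and 30° and returns
at 180° (sign flip).  Rotations can be restricted to the admissible patch —
without that restriction a rotated lead on the full torso can wrap toward
the chest, where potentials are larger, and the comparison would no longer
be between back-surface leads.

## The synthetic signal generator

The generator's purpose is to produce traces whose *R-instant physics* is
exactly the forward model's, with a plausible surrounding waveform:

* **Dipole loop.**  A sum of Gaussian components in cycle phase (P, Q, R,
  S, T at phase fractions 0.15/0.27/0.30/0.33/0.55, widths
  0.008–0.04 cycles) with the R magnitude $2\times10^{-5}$ A·m along the
  heart axis and physiological relative amplitudes (P 0.15, Q −0.10,
  S −0.25, T 0.30 of R).  Only the R instant is anchored to the reference
  parameterization; the loop around it is package plumbing, chosen so the
  trace looks physiological and the inter-beat T-to-P segment is genuinely
  quiet.
* **Acquisition chain.**  Sampling at 2.3 kHz, then averaging
  downsampling to 72 Hz over half-open output intervals — the exact
  specification of an "averaging filter" decimation for the non-integer
  ratio 2300/72.  The hardware's band-shaping is not modelled (no filter
  parameters are available), so the acquisition filter is the identity.
* **Motion artifacts.**  Seeded raised-cosine gap excursions (default
  2 events/min, 2 mm on the 1 mm baseline gap, 1 s long, contact never
  lost) applied to electrode A with the electrode potential recomputed
  sample-by-sample from the perturbed coupling at fixed surface potential —
  the normal-displacement regime, which dominates for backrest contact.
  Tangential slide events are not simulated.  Artifacts are
  multiplicative: they vanish identically on an equipotential surface, so
  the generator produces no artifact energy without cardiac signal —
  triboelectric charging, which does, is out of scope.
* **Noise.**  White Gaussian noise added at the output rate, with
  $\sigma = V_R\,10^{-\mathrm{SNR}/20}$ calibrated from the clean trace's
  measured R amplitude.  The measured SNR (T-to-P definition below) then
  lands within ±1 dB of the target; the residual bias (≈0.02 dB low at
  20 dB) comes from motion-artifact energy leaking into quiet windows and
  noise inflating the measured peaks.

Everything is seeded and reproducible; two runs of a configuration are
bit-identical.

What passing tests on these traces show — and what they do not: they
validate the *relative* claims (optimal vs misaligned lead, SNR-detection
coupling, artifact placement sensitivity) under a stationary dipole loop
with white noise.  Real recordings add baseline wander, powerline
interference, heart-rate variability, electrode charging and posture
drift; absolute SE/PPV values here are therefore optimistic upper bounds,
not predictions.

## QRS detection and scoring

The detector is the classic Pan–Tompkins chain with canonical parameters
(5–15 Hz band-pass, 5-point derivative, squaring, 150 ms moving-window
integral, dual adaptive thresholds with 200 ms refractory period, 360 ms
T-wave slope test, search-back at 1.66× the running RR average); all
windows are specified in seconds and rounded to the trace rate, and the
band-pass is zero-phase so detected fiducials align with the true R times
without group-delay correction.  The published description names the
approach without parameters; the canonical values are used unchanged.

SNR follows the definition $20\log_{10}(V_R/\sigma_N)$ with $V_R$ the mean
peak |value| within ±80 ms of each beat and $\sigma_N$ the standard
deviation in the inter-beat window $[R + 0.45\,RR,\; R + 0.80\,RR]$ — an
operationalization of "between the T and P waves" that stays clear of both
neighbouring waves at normal rates; the fractions are exposed as a
parameter.

Detections are matched to ground truth by greedy nearest one-to-one
matching within a tolerance (default 100 ms, roughly half a beat at rest;
none is canonically specified).  Two PPV variants are reported side by
side: the standard $TP/(TP+FP)$ and the inclusive $TP/(TP+FN+FP)$, because
published detection tables are not always consistent about which is meant —
for the reference counts (TP 13,948, FN 139, FP 259) the two give 98.18%
and 97.23%.  Printed rows truncate percentages to two decimals rather than
rounding (97.2257 → 97.22), matching the convention evident in such tables.

## Degenerate inputs and error behaviour

Zero dipole moment yields the zero potential (and the pipeline aborts lead
optimization with "no admissible signal"); an empty electrode patch, an
electrode centre far from the surface, a gap excursion that would reverse
contact, non-monotone beat lists, and a downsampling target at or above the
input rate are all errors, not silent degradation.  A gap comparable to the
electrode diameter — outside the plate regime — is recorded as a warning on
the coupling object rather than an error, since the formula degrades
gracefully.

## Problem sizes

The shipped tests and the acceptance script run the sphere oracle at
24k–83k tetrahedra, the thorax at ~32k tetrahedra, and the detection study
on ten 15-minute traces at 2.3 kHz synthesis/72 Hz analysis.  These sizes
were chosen as the smallest at which the reported quantities are stable
(mesh-refinement and resolution-consistency tests guard this); larger
meshes sharpen the oracle errors but do not change the lead ranking.

## Known limitations

* Parametric convex organs; no individual anatomy, no ribs/spine/vessels.
* Isotropic, frequency-independent conductivities; no respiration effects.
* Single fixed equivalent dipole; no propagation sequence, no moving
  dipole, no multi-dipole sources.
* Amplifier input impedance, charge/triboelectric artifacts and fabric
  dielectrics beyond a single $\varepsilon_r$ are not modelled.
* The optimizer works on one R-instant field; it does not optimize over
  electrode size or multi-lead fusion.
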