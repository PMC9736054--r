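# cecglead

Capacitive (non-contact) electrocardiography picks up the heart's electrical
activity through an insulating gap — for instance through a cotton shirt,
from electrodes embedded in the backrest of an armchair.  Which pair of
back-surface positions makes the best lead differs from person to person:
it depends on the direction of the electrical heart axis, and a badly chosen
pair yields a trace in which QRS complexes cannot be detected reliably.
`cecglead` implements the full model-based selection workflow for such a
system, aimed at biomedical-engineering users who want to study electrode
placement, motion-artifact susceptibility and downstream beat-detection
quality in simulation.

## What the package computes

**Forward problem.**  The body-surface potential of a cardiac equivalent
dipole **J**ₕ is obtained from the quasi-static problem

    div( sigma grad phi ) = I_SV,     I_SV = -div J_h,     dphi/dn = 0 on S,

solved with P1 finite elements on a synthetic five-tissue thorax (heart
muscle 0.2 S/m, blood 0.5 S/m, lungs 0.05 S/m, thoracic wall and
sub-diaphragm region 0.1 S/m).  The dipole default is |m| = 2×10⁻⁵ A·m at
azimuth 5π/6 and elevation 3π/4, positioned at the heart base
(0.1, 0.03, 0) m.  The pure-Neumann constant is fixed by a zero
boundary-mean gauge, so lead voltages are gauge-free.  A homogeneous-sphere
geometry with the closed-form surface potential
φ(θ) = 3p·cosθ/(4πσR²) serves as the built-in accuracy oracle.

**Capacitive electrode.**  An electrode of area S at gap d couples through
C = ε₀εᵣS/d; being equipotential, its voltage is the coupling-weighted
surface average

    Ve = ∬ V·Ce dS / ∬ Ce dS,      Ce = ε₀εᵣ/d(x,y,z),

independent of frequency.  Motion sensitivity splits into a normal (gap)
mode — Ce changes, potential fixed — and a tangential (slide) mode, which
is governed by the tangential electric field under the electrode; regions
of low tangential field are robust against motion artifacts.

**Lead selection.**  All candidate electrode pairs on the dorsal patch are
evaluated exhaustively; the score is the R-instant lead amplitude
|Ve_A − Ve_B|, optionally penalized by the electrodes' tangential-field
susceptibility.  The optimal lead aligns with the projection of the
electrical heart axis, and its amplitude decays as the lead is rotated away
(15°, 30°) from the optimum.

**Signal synthesis and QRS scoring.**  A Gaussian-component dipole loop
(P, Q, R, S, T) drives the lead-field basis at 2.3 kHz; traces get
electrode-gap motion artifacts and Gaussian noise calibrated to a target
SNR = 20·log₁₀(V_R/σ_N) (noise measured in the T-to-P window), then are
averaged down to 72 Hz.  A Pan–Tompkins detector (5–15 Hz band-pass,
derivative, squaring, 150 ms integration, adaptive thresholds with
search-back) is scored against the ground-truth beats as TP/FN/FP,
TE = FN+FP, SE = TP/(TP+FN) and PPV — both the standard TP/(TP+FP) and the
inclusive TP/(TP+FN+FP) variant found in published detection tables.

## Worked example

```r
library(cecglead)

mesh  <- build_synthetic_thorax(resolution = 0.02)
basis <- lead_field_basis(mesh, c(0.1, 0.03, 0))
field <- surface_field_map(basis_solution(basis,
            angles_to_moment(2e-5, 5 * pi / 6, 3 * pi / 4)))
back  <- extract_back_patch(mesh, 0.4)
optimize_lead(field, back, spacing = 0.02)
#> Lead search: 283 candidate sites, 39903 pairs (spacing 0.02 m, lambda 0)
#> Top pairs:
#>   amplitude susceptibility combined    ax     ay     az    bx     by    bz
#> 1  0.002353       0.022258 0.002353 0.159 -0.046 -0.193 0.159 -0.046 0.025
#> ...
```

The best pair sits 0.218 m apart along the surface projection of the heart
axis and delivers 2.35 mV at the R instant.  The full study analog —
optimal and deliberately suboptimal lead, noisy 72 Hz traces with motion
events, detection scoring — runs from one configuration object:

```r
res <- run_pipeline(study_config(sim = list(duration = 300, n_traces = 3)),
                    quiet = TRUE)
res
#> Simulated cECG lead-selection study
#>   geometry: thorax, 32256 tets; dipole |m| = 2e-05 A*m
#>   optimal lead amplitude: 0.00235 V (separation 0.218 m)
#>   amplitude vs lead-angle deviation:
#>        0 deg: 0.00235 V
#>       15 deg: 0.00186 V
#>       30 deg: 0.00134 V
#>   optimal lead: mean SNR 19.9 dB | 900 | 900 | 0 | 5 | 5 | 100.00% | 99.44%
#>   suboptimal:   mean SNR 6.1 dB | 900 | 414 | 486 | 1,869 | 2,355 | 46.00% | 14.95%
```

Read the two table rows as `Actual | TP | FN | FP | TE | SE | PPV`: at the
20 dB operating point the optimal lead loses none of 900 beats (5 false
positives), while the same noise on a near-orthogonal lead drops the
sensitivity to 46% — the misaligned configuration is practically
uninterpretable.  `run_pipeline(..., out_dir = "report")` additionally
writes VTK surface maps, CSV lead/trace tables and a JSON manifest.

## The methods vignette

`vignettes/cecg-lead-selection.Rmd` documents the model assumptions, the
synthetic-data generator, numerical choices and known limitations.
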