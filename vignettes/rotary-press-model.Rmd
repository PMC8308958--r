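---
title: "An agent-based model of rotary-press tableting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of rotary-press tableting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotapress)
```

## The model

`rotapress` simulates direct compression on a rotary tablet press as a
sequence of discrete die-fill events. The machine is decomposed into agents —
hopper, filling pipe, feed frame, die — each with a simple physical behavior,
and material parcels that carry composition with lot-level provenance from
the feed to every tablet. One die-fill event occurs every
$60/(\mathrm{turret\ rpm}\cdot n_\mathrm{stations})$ seconds (0.75 s, i.e.
80 tablets/min, at the defaults), and each event runs the chain: fill the die
from the feed frame, rotate the paddle wheel, top up compartments from the
pipe, compress, eject one tablet.

### Powder flow

**Filling pipe.** Powder does not move as a uniform plug through the feed
pipe: the center flows faster than the wall region. The pipe is therefore
modeled as two concentric plug-flow streams, a *midstream* of configurable
diameter (default 33 mm inside a 45 mm pipe) moving at a fixed velocity
ratio (default 2:1) to the *outer ring*. Any volume extracted at the bottom
is split between the streams in the ratio $A_\mathrm{outer} : r\,
A_\mathrm{mid}$, and the same volume of current hopper material is added at
the top, so the pipe stays full. The conceptual layer height is chosen so
that one fill event advances the outer ring by exactly one layer and the
midstream by $r$ layers:
$h_\mathrm{layer} = V_\mathrm{dos}/(A_\mathrm{outer} + r\,A_\mathrm{mid})$.
Internally the streams are exact parcel queues, so extraction volumes need
not be multiples of a layer and mass is conserved to machine precision. A
feed step change consequently reaches the die in two waves: the midstream
breaks through after roughly half the pipe transit time, the outer ring
after the full transit time.

**Feed frame.** The twelve paddle interspaces are modeled as twelve
compartments behaving as independent continuous stirred tank reactors:
incoming pipe material mixes instantaneously and ideally with the residual
content. Compartments are bound to twelve rotating positions; position 1
sits under the pipe outlet and position 5 over the die. Per fill event the
wheel advances by
$k = \mathrm{round}(\mathrm{paddle\ rpm} \cdot n_\mathrm{comp} /
(\mathrm{turret\ rpm} \cdot n_\mathrm{stations}))$
positions ($k = 9$ at the defaults). Every compartment that sweeps past
position 1 during the rotation is topped up to capacity; this passing-based
rule matters because $\gcd(9, 12) = 3$, so a compartment *lands* on only
four of the twelve positions and a landing-based rule would starve most of
the wheel. The die is filled by the compartment over it plus the next
compartments to arrive, with descending volume shares (default 40/35/25 of
the dosing volume).

The rotation quantization leaves a deterministic fingerprint: tablets
interleave the three compartment classes in a 4-event cycle, so per-tablet
series carry a micro-pattern of that period. Its amplitude is about $10^{-8}$
(relative) in the bundled case study and grows in deliberately small test
configurations; monotonicity properties of the model are therefore stated
phase-wise at lag 4, or with reversals bounded by $10^{-4}$ of the signal
range.

### Compaction physics

Blend densities follow the volume-additive rule
$1/\rho_\mathrm{mix} = \sum_i x_i/\rho_i$ throughout (fill density, in-die
densities, recovery-state densities, and the mixture solid density used for
porosity — the last is a design choice; volume additivity is the one
assumption applied uniformly). Tablet weight is
$m_T = \pi (D/2)^2 h_\mathrm{dos}\, \rho_\mathrm{fill,mix}$.

The compression stress follows from inverting the Kawakita mixture model
$$\frac{1}{\rho(P)} = \sum_i \frac{x_i}{\rho_{0,i}}
\frac{1+(1-a_i)b_iP}{1+b_iP}$$
at the in-die density set by the punch distance. For one component the
inversion is linear, for two components it is an exact quadratic (pq
formula; the admissible root is the positive one at which the forward model
reproduces the target), and for more components a bracketed root search on
the strictly monotone forward model is used (bracket $[0, 10^4]$ MPa,
tolerance $10^{-9}$ MPa). Densities outside the attainable range
$(\rho(0), \rho_\infty)$ raise an explicit "unreachable density" error, and
evaluation below 20 MPa triggers a warning because the Kawakita form is not
calibrated for very low pressures.

The punch distance during compression is affine in the compression force,
$h = h_\mathrm{min} + d_0 + c\,F$, representing the elastic deformation of
the press; with a perfectly stiff press ($d_0 = c = 0$) the stress inversion
is direct, otherwise the scalar self-consistency equation
$\rho_\mathrm{target}(h(P)) = \rho_\mathrm{Kawakita}(P)$ has a strictly
monotone residual and is solved with `uniroot` to $10^{-10}$ MPa (plain
fixed-point iteration oscillates for soft presses).

After ejection the density relaxes by two elastic-recovery contributions: an
instantaneous in-die term modeled linear in stress
($\Delta\rho_\mathrm{in\text{-}die} = kP + l$, the line drawn exactly
through two calibration stresses) and a slow term taken as the arithmetic
mean of its two calibration values. For blends, the calibration-state
densities of the pure substances are first mixed volume-additively, then the
line is re-derived at blend level. A scalar measured-minus-predicted
correction offset per material (blended linearly by mass fraction, default
0) absorbs systematic calibration error; being scalar, it reproduces the
calibration points exactly only when the slow term is equal at both
stresses.

Tensile strength follows Ryshkewitch–Duckworth,
$\sigma = \sigma_0(x)\,e^{-k_b(x)\,\varepsilon}$, with the composition
dependence $\sigma_0(x) = c_1 e^{x c_2} + c_3$ (solved exactly through three
support compositions) and $k_b(x) = m x + n$ (least squares), where $x$ is
the mass fraction of the coarse component.

## Parameters

| Parameter | Units | Default | Role |
|---|---|---|---|
| `die_diameter` | mm | 11.28 | Euro-D flat-faced punch |
| `dosing_height` | mm | 7 | sets the dosing volume (0.6995 cm³) |
| `min_punch_distance` | mm | 3.2 | punch gap set point at compression |
| `turret_rpm`, `n_stations` | 1/min, – | 20, 4 | 80 fill events/min |
| `paddle_rpm`, `n_compartments` | 1/min, – | 60, 12 | rotation quantum k = 9 |
| `fill_ratios` | – | 0.40/0.35/0.25 | die-filling shares (calibrated) |
| `midstream_diameter` | mm | 33 | pipe flow profile (calibrated) |
| `velocity_ratio` | – | 2 | midstream : outer ring velocity |
| `pipe_inner_diameter`, `pipe_height` | mm | 45, 200 | pipe hold-up, hence transit time |
| `compartment_capacity` | cm³ | 3 dosing volumes | worst-case drain always covered |
| `machine_compliance`, `punch_offset` | mm/kN, mm | 0, 0 | affine press deformation |

The pipe geometry (inner diameter, height) and the compartment capacity are
not measurable machine constants here but structural model parameters; the
defaults give a pipe hold-up of several minutes of throughput and a
compartment turnover of a few seconds, which set the two time scales of the
changeover response.

## The bundled case study

`build_case_study()` assembles a material changeover between two grades of
anhydrous dicalcium phosphate — coarse DCPA A150 and fine DCPA A60, both
lubricated with 1 wt% magnesium stearate and characterized as such — with
the feed switching to the fine grade at minute 1 and back at minute 13
(25 min total, 2000 tablets; tablets sampled every minute except every two
minutes between minutes 8 and 18). Fill computations use the apparent
consolidated bulk density after filling (0.73 / 1.41 g/cm³), which exceeds
the cylinder bulk density (0.68 / 1.33 g/cm³) because forced paddle feeding
consolidates these free-flowing powders in the die; the cylinder value
remains selectable via `use_consolidated_density = FALSE`.

Two case-study inputs are not measured constants and deserve emphasis:

* **Press deformation.** The fine grade's Kawakita asymptote
  ($\rho_0/(1-a) = 3.18$ g/cm³) lies *above* its solid density
  (2.849 g/cm³), and a pure fine-grade fill compressed to the rigid 3.2 mm
  gap would imply an in-die density above the solid density. A real press
  deflects; `calibrate_punch_affine()` fits $(d_0, c)$ from two steady
  operating points (60 MPa for the pure coarse grade, 200 MPa at 75 wt%
  fine grade), giving $d_0 \approx 0.116$ mm and
  $c \approx 0.036$ mm/kN. This mirrors the practice of determining the
  actual punch distance beforehand on a compaction simulator.
* **Elastic recovery.** The recovery triplets are *synthetic*: in-die
  densities at the 30/400 MPa calibration stresses come from the fitted
  Kawakita curves, with an instantaneous recovery of
  $10^{-4}$ g/cm³ per MPa and a slow recovery of 0.005 g/cm³ for both
  grades — small values representative of a brittle filler. They are
  plain `material_spec` inputs and can be replaced by fitted values from
  `fit_recovery()` whenever measured state densities are available.

With these conditions the changeover produces co-moving CQA trajectories:
weight, stress and strength rise with the fine-grade fraction and relax
back after the reversal. One caveat the model itself exposes: the
equilibrium strength-versus-composition curve has a very shallow local
minimum near 1–2 wt% fine grade (depth about $10^{-4}$ of the signal
range), because the exponential $\sigma_0(x)$ mixing rule initially loses
strength faster than the porosity gain compensates. Strength
co-monotonicity is therefore a statement up to that bounded reversal, not a
strict one.

## Synthetic data and what passing tests mean

The fixture generators emulate the three calibration measurements:
compressibility curves (Kawakita densities at 30–400 MPa, multiplicative
Gaussian noise), compactability curves (strengths over a porosity grid,
multiplicative lognormal noise), and reference tablet-weight series
(simulator output at the sampling schedule, optional 1.5% CV measurement
noise). All are deterministic under a fixed seed.

Because the generators share the forward models with the simulator, recovery
tests demonstrate *identifiability and correctness of the fitting code*, not
the physical adequacy of the models; likewise the sweep self-consistency
tests (the generating midstream diameter and fill ratios score $f = 0$
against their own output and every other candidate scores strictly worse)
validate the calibration *logic*, not the calibrated values. Features of
real data deliberately absent from the generators: powder segregation in
hopper and pipe, inter-compartment powder exchange in the feed frame,
humidity and temperature effects, volume contraction on mixing (real blend
densities exceed the volume-additive prediction), and particle-scale
mechanics.

## Numerical choices and degenerate inputs

* Mass conservation is checked at every event against a running ledger
  (initial inventory + hopper feed = pipe + feed frame + tablets) at
  relative $10^{-9}$; the simulation aborts on violation. Observed errors
  are at the $10^{-14}$ level.
* Compositions are stored as named mass vectors over (material, lot) keys;
  volumes are always derived from mass through the per-key fill densities,
  so mass and volume cannot drift apart under splitting and mixing.
* Underfilled compartments abort the run with a diagnostic (partial die
  filling is not modeled); overfilling a compartment is an error.
* Degenerate calibration inputs are rejected explicitly: fewer than four
  compressibility points, identical recovery stresses, (near-)constant
  porosity support, non-monotone $\sigma_0$ support.
* Adjacent same-composition pipe parcels are coalesced — pure bookkeeping
  that keeps queues short; it does not alter the physics.

Problem sizes used by the test suite: the full case study (25 min, 2000
tablets) for the acceptance-level checks, and reduced scenarios (50–60 mm
pipe, 3–8 min) for dynamic unit tests and sweep logic, chosen so the whole
suite exercises every code path at comfortably interactive run times.

## Known limitations

* The strength mixing rule is the weakest sub-model: small porosity errors
  are amplified exponentially, and the $\sigma_0(x)$/$k_b(x)$ forms are
  empirical interpolations through three support compositions.
* Volume additivity underestimates blend densities when fine particles fill
  the pores of the coarse fraction — exactly the blends this case study
  concerns; the model carries no volume-contraction term.
* The affine press-deformation model is a two-parameter surrogate
  calibrated at two operating points; outside that stress range it
  extrapolates.
* The feed frame as independent CSTRs ignores powder exchange across
  compartments, which visual observations on transparent feed frames show;
  at high paddle-to-turret speed ratios the idealization is reported to be
  good, but it has not been established for poorly flowing materials.
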