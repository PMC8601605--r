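---
title: "Modeling multicellular calcium signaling in the wing-disc pouch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multicellular calcium signaling in the wing-disc pouch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capouch)
```

`capouch` simulates intercellular Ca²⁺ signaling in the *Drosophila*
wing imaginal disc pouch, an epithelium in which four qualitatively
distinct classes of spontaneous activity are observed as agonist
stimulation increases: single-cell Ca²⁺ spikes, intercellular Ca²⁺
transients (ICTs), intercellular Ca²⁺ waves (ICWs), and a global
"fluttering" state. The package couples a single-cell
IP₃/Ca²⁺/IP₃-receptor oscillator across a synthetic Voronoi epithelium
through gap junctions, and provides the analysis machinery needed to
study how the spatial organization of stimulation strength selects
among those classes.

## The single-cell model

Each cell carries three dynamical variables: cytosolic IP₃
concentration $p$ (µM), cytosolic Ca²⁺ concentration $c$ (µM), and the
fraction $r \in [0,1]$ of IP₃ receptors (IP₃R) not yet inactivated by
Ca²⁺. The ER Ca²⁺ concentration $s$ is slaved algebraically to $c$
through conservation of total cellular Ca²⁺,

$$ s = \frac{c_{tot} - c}{\beta}, $$

where $\beta$ is the effective ER/cytosol volume ratio. Eliminating $s$
(rather than integrating it) makes the conservation law
$c + \beta s = c_{tot}$ exact at every step by construction.

IP₃ is produced by phospholipase C (PLC), activated by Ca²⁺ with a
Hill form, and degraded with first-order kinetics:

$$ \frac{dp}{dt} = J_p + V_{PLC}\frac{c^2}{K_{PLC}^2 + c^2} - k_{5P}\,p. $$

$V_{PLC}$, the maximal IP₃ production rate, is the model's control
parameter: it lumps the strength of upstream hormonal stimulation
(GPCR/Gαq and receptor-tyrosine-kinase signaling converging on PLC
isoforms). It is deliberately *not* a member of
[`model_params()`] but a per-cell field ([`assign_vplc()`]), because its
spatial heterogeneity is the object of study.

Cytosolic Ca²⁺ follows IP₃R-gated release from the ER, a passive ER
leak, and SERCA reuptake:

$$ \frac{dc}{dt} = J_c + \left[k_1\left(\frac{r\,c}{K_a+c}\cdot
   \frac{p}{K_p+p}\right)^{3} + k_2\right](s - c)
   - \frac{V_{SERCA}\,c^2}{c^2 + K_{SERCA}^2}. $$

Plasma-membrane Ca²⁺ fluxes are ignored: the modeled dynamics in this
tissue are ER-driven, and the cell's total Ca²⁺ is treated as constant.

Receptor inactivation is the slow process that paces oscillations. The
default (`receptor_variant = "modified"`) makes the inactivation rate
itself Ca²⁺-dependent,

$$ \frac{dr}{dt} = \frac{k_\tau^4 + c^4}{\tau_{max}\,k_\tau^4}
   \left(1 - r\,\frac{K_r + c}{K_r}\right), $$

so that recovery is slow (time scale $\tau_{max}$) at resting Ca²⁺ and
accelerates as $c$ approaches $k_\tau$. A constant-time-scale variant
(`"constant_tau"`, rate $1/\tau_r$) is retained for comparison; the two
coincide at $c = 0$ when $\tau_r = \tau_{max}$. With $c$ clamped, $r$
relaxes exponentially to $K_r/(K_r+c)$ at rate
$\varphi(c)\,(K_r+c)/K_r$ with $\varphi$ the prefactor above — the
package's property tests assert this closed form.

A note on units: the published parameter table prints $\tau_{max}$ with
units of s⁻¹, but a time *constant* in s⁻¹ is dimensionally
inconsistent with the receptor equation; `capouch` interprets
$\tau_{max} = 800$ s. All concentrations are µM and all times seconds.

### Baseline parameters

`model_params()` defaults to the published baseline set: $k_{5P}=0.66$
s⁻¹, $K_{PLC}=0.2$ µM, $\beta=0.185$, $V_{SERCA}=0.9$ µM s⁻¹,
$K_{SERCA}=0.1$ µM, $k_1=1.11$ s⁻¹, $k_2=0.0203$ s⁻¹, $K_a=0.08$ µM,
$K_r=0.4$ µM, $K_p=0.13$ µM, $\tau_{max}=800$ s, $k_\tau=1.5$ µM,
$F_p=0.005$, $F_c=0.0005$, $c_{tot}=2$ µM. $V_{PLC}$ spans 0.1–1.5
µM s⁻¹ across scenarios.

## Gap-junction coupling

Neighbouring cells exchange IP₃ and Ca²⁺ diffusively through gap
junctions, in proportion to the length $l_{ij}$ of their shared
boundary:

$$ J_{x,i} = F_x \sum_{j \in N_i} l_{ij}\,(x_j - x_i), \qquad x \in \{p, c\}. $$

This is the standard discrete graph-Laplacian exchange: it vanishes on
a uniform field and conserves the tissue total exactly (pairwise
antisymmetry). The printed form of the coupling sum in the source
material does not vanish at uniform concentration (its second term sums
over the neighbour's value rather than the cell's own); the Laplacian
reading is the only one consistent with the stated meaning of
diffusion between cells, and is what `gj_flux()` implements.

Lengths are expressed in units of the mean cell diameter (see below),
so $l_{ij}$ is dimensionless and the permeabilities $F_p, F_c$ apply
as printed. The tissue boundary is no-flux: cells exchange only across
listed edges, with no ghost cells.

## The synthetic epithelium

Real-image segmentation is replaced by a synthetic generator
(`generate_tissue()`): `n_cells` points are sampled uniformly in an
elliptical, pouch-like domain (default aspect ratio 1.3), a bounded
Voronoi tessellation is computed, and four rounds of Lloyd relaxation
(each generator moves to its cell's centroid) drive the packing toward
the near-hexagonal topology of the segmented epithelium — relaxed
tissues have interior mean neighbour counts of ~6, and the package
tests require 5.5–6.5 for tissues of 100+ cells. The tessellation is
computed by exact half-plane clipping: each cell's polygon is clipped
against bisectors with other generators in order of increasing
distance, stopping once the bisector distance exceeds the polygon's
current circumradius (which makes the nearest-first restriction exact,
not approximate). Shared-boundary lengths are read off the clip labels
and symmetrized; sliver edges below 10⁻¹² are dropped.

Coordinates are rescaled so the mean cell diameter (diameter of the
area-equivalent circle) is 1. A hand-built regular hexagonal lattice
passed through the same extraction (`voronoi_tessellation()`) yields
exactly six neighbours and equal $l_{ij}$ for lattice-interior cells —
the package's constructed oracle for the extraction step.

What the generator does *not* emulate: cell mechanics, growth,
division, rearrangement, apical-area heterogeneity beyond what Lloyd
relaxation leaves, the peripodial layer, or any anatomical axis beyond
the elliptical outline. Passing tests on synthetic tissues therefore
says nothing about segmentation quality on real images; it validates
the signaling model on a topologically realistic substrate.

## Initiator and standby cells

A `ca_vplc` field partitions the tissue into a few **initiator cells**
(high $V_{PLC}$, drawn uniformly from [1.4, 1.5] µM s⁻¹ in the pattern
scenarios) and **standby cells** whose range determines the signaling
class: [0.1, 0.5] yields isolated spikes, [0.25, 0.60] ICTs,
[0.4, 0.8] ICWs, and [1.4, 1.5] — every cell effectively an initiator —
fluttering. The default initiator count is 2% of the tissue (at least
one): the published scenarios state only that a small set of initiator
cells is present, and 2% of a 200-cell tissue (4 cells) reproduces the
described sparse nucleation. Initiators are placed uniformly at random
without replacement.

## Numerical integration

The coupled $3N$-dimensional system is stiff (relaxation oscillations
with sharp upstrokes) and sparsely coupled. `simulate_tissue()` packs
the parameters and edge list into a single vector consumed by a
compiled right-hand side and integrates with `deSolve::lsodes`
(sparse stiff BDF; the Jacobian sparsity is detected from the adjacency
structure). Defaults: `rtol = 1e-6`, `atol = 1e-9`, 1 h of simulated
time sampled every 10 s — the duration and frame interval of the
live-imaging experiments the model mirrors. A 200-cell hour integrates
in about a second; property tests verify that halving the tolerances
moves sampled trajectories by less than 10⁻⁴ relative.

**Initial condition.** All cells start at the resting fixed point of an
unstimulated cell ($V_{PLC}=0$; `resting_state()`), optionally with a
small seeded perturbation of $c$ for homogeneous tissues. The spatial
heterogeneity of $V_{PLC}$ breaks symmetry in all standard scenarios.

**Onset transients and the settle window.** Starting a stimulated cell
from the unstimulated resting state fires exactly one stimulus-onset
excursion (the receptor pool is fully recovered at rest), roughly 30 s
into the run. For the pattern scenarios this is appropriate — they
model the response of a quiet tissue to freshly applied agonist. For
comparisons that concern *equilibrated* activity (the gap-junction
block comparison, parameter sweeps, developmental scaling: all
experimental counterparts are discs equilibrated in culture before the
1 h imaging window), `sim_config(settle = 1200)` integrates 1200 s
beyond the reported window and discards them, with times rebased to
zero. Without this, the enabled-gap-junction comparison would count
one artifactual onset spike per initiator.

## Bifurcation analysis

An isolated cell crosses from rest to oscillation through a Hopf
bifurcation as $V_{PLC}$ rises. `steady_state()` closes $r^*$ and $p^*$
algebraically and solves the remaining scalar Ca²⁺ balance by bracketed
root finding on a 2001-point scan of $c$; where the branch structure is
folded, the lowest-$c$ root (the branch carrying the first Hopf point)
is returned. `model_jacobian()` is analytic, validated against central
finite differences. `hopf_threshold()` scans $V_{PLC}$, brackets the
first sign change of the real part of the oscillatory eigenvalue pair,
and bisects to `tol` (default 10⁻⁴); a real-eigenvalue crossing is
reported as a distinct (saddle-node) event, not a Hopf. At baseline the
threshold is 0.774 µM s⁻¹ (to the printed precision) — for *both*
receptor variants with $\tau_r = \tau_{max}$, because the fixed point
sits at $c^* \approx 0.073$ µM where the Ca²⁺-dependent prefactor is
within 10⁻⁵ of 1. For the same reason the threshold is insensitive to
$k_\tau$ but shifts measurably with $\tau_{max}$.

The single-stimulated-cell-with-neighbours analysis models the
unstimulated neighbourhood as a clamped reservoir at the resting state,
adding linear leak terms $-F_p L (p - p_{rest})$ and
$-F_c L (c - c_{rest})$ with total shared boundary $L = 6$ (a hexagonal
cell with unit sides; configurable). The published material does not
specify the neighbour model; a resting reservoir is the minimal reading
of "unstimulated neighbours". Increasing $F_p$ raises the threshold —
coupling to quiet neighbours drains IP₃ and stabilizes rest.

`bifurcation_diagram()` records, per grid point, the fixed point, its
leading eigenvalue, and — where unstable — the stable limit cycle's
Ca²⁺ extrema and period from a long integration (first 20 min
discarded; near-onset points, whose periods exceed 2000 s, are retried
with a tripled window). Unstable limit cycles are not tracked: they
would require continuation machinery out of proportion to their role
here. Two verified features worth noting: the stable cycle is already
full-amplitude immediately above the threshold (consistent with the
subcritical onset structure of the published diagram), and the period
falls monotonically with $V_{PLC}$.

## Quantification

Traces are normalized as F/F₀ with F₀ the 10th percentile of each
cell's series — a robust stand-in for the inter-spike baseline that
tolerates long active episodes (the published normalization does not
define F₀). `detect_spikes()` finds maximal excursions above an F/F₀
threshold of 1.5, merges excursions separated by less than 20 s, and
measures width at half maximum relative to baseline by linear
interpolation (a triangular pulse of base 20 s and apex 2 has WHM
exactly 10 s — the analytic case the conventions were chosen to make
exact). Detection is invariant to uniform scaling of the raw trace.
Frequency is the reciprocal mean peak-to-peak interval and is reported
as absent (not zero) with fewer than two events.

### Pattern classification

`classify_pattern()` is an automated rubric standing in for
classification by eye. Per frame a cell is active if F/F₀ > 1.5;
activity is grouped into events as connected components of the
spatiotemporal graph (active neighbours within a frame; the same active
cell across consecutive frames). In order of precedence:

* **none** — no events;
* **fluttering** — at least half the tissue active in at least half the
  frames, *or* some frame with at least half the tissue simultaneously
  active;
* **ICW** — some event reaches 10% of the tissue *and* its per-frame
  active centroid travels more than 2 mean cell diameters;
* **ICT** — some event involves more than 3 cells;
* **spikes** — everything else.

The second fluttering trigger deserves explanation. The model's
fluttering state is *periodic global flashing*: the whole tissue
lights up in synchrony, but each flash lasts roughly a third of the
period, so sustained-occupancy alone (the natural first formalization
of "global activity") never reaches 50% of frames and would relegate
the state to ICW. Propagating waves, by contrast, engage only about a
third of the tissue at any instant. A near-global simultaneous flash is
therefore the discriminating signature of fluttering, and the rubric
was calibrated on exactly the four scenario classes it must separate.
All thresholds are exposed as arguments and frozen at the defaults
above for the package's tests.

Two caveats. First, the rubric counts an event's *total* cells over its
lifetime, so long-lived components can accumulate cells without ever
being large simultaneously; the propagation requirement keeps such
events out of the ICW class. Second, the ICT/ICW boundary (10% of the
tissue) is genuinely marginal for 200-cell ICW scenarios, whose largest
events hover at 7–10% — classification there flips between ICT and ICW
on a minority of seeds, mirroring the one boundary disagreement
observed among the published blinded classification runs.

`integrated_activity()` is the time–tissue sum of the suprabasal
normalized signal, $\sum_i \sum_t \max(F/F_0 - 1, 0)\,\Delta t$;
`make_kymograph()` orders the cells intersecting a line by projection
and returns their F/F₀ over time.

## Scenario runners

* `pattern_scenario()` — the four stimulation regimes above.
* `gj_block_scenario()` — initiators pinned exactly at the threshold
  (0.774), standby in [0.1, 0.5]; with gap junctions enabled the
  sub-threshold neighbourhood drains the initiators (no activity), with
  $F_p = F_c = 0$ the isolated initiators spike. Uses the 1200 s settle
  window.
* `scaling_scenario()` — two hypotheses for the developmental decline
  of integrated Ca²⁺ activity, simulated across tissue sizes:
  initiator scaling, $N_{init} = \mathrm{round}(8000\,N^{-0.8})$
  (floored at 1, clamped at $N$ with a warning) at constant
  permeability; and permeability scaling, $F_p = 800\,N^{-1.8}$ with
  $F_c = 0.1 F_p$ at a constant 65 initiators. Standby cells sit at
  0.40, initiators in [1.3, 1.5]. At the smallest test size (100
  cells) the initiator rule saturates — every cell becomes an
  initiator — and the permeability rule gives 40× baseline coupling,
  so both produce globally synchronized activity that the rubric
  (consistently with the fluttering scenario's definition) labels
  fluttering rather than a wave class; per-cell integrated activity
  nevertheless falls monotonically with size and the largest size
  shows sparse spikes, which is the substance of the scaling claim.
* `sensitivity_sweep()` — re-simulates one frozen wave baseline
  (standby [0.7, 1.0]) while scaling a single parameter across
  percentages of baseline ($F_p$/$F_c$ jointly if requested), so
  differences are attributable to the parameter alone.

Independent draws are used at each size of a scaling series; whether
the published scenarios nested initiator sets across sizes is
unstated.

## Problem sizes and reproducibility

The package's tests and its acceptance script run pattern scenarios at
200 cells over 5 seeds, the decoupling check at 50 cells over a full
hour, and scaling series over {100, 200, 400, 800} cells — sizes chosen
so the whole suite completes in a few minutes while each phenomenon is
comfortably above its onset scale. Every source of randomness (point
sampling, $V_{PLC}$ draws, initiator placement, initial-condition
perturbations) flows through explicit integer seeds; identical seeds
reproduce geometries and trajectories bit-for-bit.

## Known limitations

* Intracellular diffusion is neglected (well-stirred cells); the model
  cannot resolve sub-cellular Ca²⁺ microdomains.
* No cell mechanics, growth or division: "developmental scaling" is a
  comparison across static tissues of different sizes, not a growing
  simulation.
* Stochastic channel gating is absent; all variability enters through
  the $V_{PLC}$ field and geometry.
* The classifier rubric is a deterministic stand-in for human
  classification; its thresholds are conventions, and the ICT/ICW
  boundary in particular is scale-dependent.
* Unstable limit cycles are not computed, so the bifurcation diagram
  shows the subcritical structure only through its consequences
  (full-amplitude onset), not the unstable branch itself.
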