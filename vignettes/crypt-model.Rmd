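---
title: "A multi-scale agent-based model of the mouse intestinal crypt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale agent-based model of the mouse intestinal crypt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptabm)
```

## The model

`cryptabm` simulates a single mouse small-intestinal crypt as a
self-organizing population of single-cell agents on a fixed crypt surface:
a hemispherical niche of radius $R$ smoothly joined to a cylinder of
height $H$, with the crypt mouth at $z = H$ feeding a villus compartment.
Nothing in the model prescribes where cell types live or how many there
are; the composition and its spatial organisation emerge from the
interaction of five mechanisms:

1. **Surface-tethered Wnt.** Paneth cells and a fixed mesenchymal emitter
   ring near the crypt base tether Wnt to any cell within a short range
   $r_\mathrm{wnt}$ at rate $k_\mathrm{tether}\,\varphi$ per source.
   Tethered Wnt is never removed except by division, which splits it
   exactly in half between the daughters, so migrating, dividing cells
   deplete their Wnt geometrically — this is what creates the declining
   Wnt gradient along the axis.  The factor
   $\varphi = \min\{1, (N^*/N_\mathrm{stem})^h\}$ is a ZNRF3/RNF43-like
   negative feedback: when the stem pool exceeds its homeostatic size
   $N^*$, tethering is attenuated and the niche stops expanding.  With
   $\varphi \equiv 1$ the niche grows without bound (the knockout
   phenotype); the test suite exercises both regimes.
2. **Notch lateral inhibition.** Secretory cells (Paneth, secretory
   progenitors, goblet, enteroendocrine) present Delta; contacting cells
   accumulate Notch activation with first-order decay
   ($\dot N = k_\mathrm{notch} m - \lambda N$ for $m$ presenting
   neighbours).  In the niche this produces the familiar alternating
   on/off pattern: stem cells (Notch-on) wedged between Paneth cells
   (Notch-off).  On a triangular packing a perfect two-colouring is
   impossible, so the pattern is predominant rather than exact.
3. **BMP with enterocyte feedback.** BMP is evaluated as an analytic
   axial profile $B(z,t) = \beta\,E(t)\,g(z)\,a(z)$: proportional to the
   current number of mature enterocytes $E(t)$ on the villus (a
   hedgehog-like relay), increasing in $z$ through a normalized logistic
   $g$, and suppressed by a factor $a(z) < 1$ in an antagonist zone
   covering the niche plus one cell diameter.  A PDE solve would add cost
   without observable consequences at this resolution, because every
   mechanism the model needs from BMP is axial and monotone.
4. **Cell-cycle protein network with contact inhibition.** Every
   proliferative cell integrates an eight-species cyclin/CDK relay
   oscillator (below).  Intercellular pressure — the stiffness-weighted
   sum of positive contact overlaps — sets the production rate of p27
   through a saturating Hill function, so crowded cells cycle slowly
   (contact inhibition of proliferation, the YAP–Hippo phenomenology) and
   cells in the sparse transit-amplifying region cycle fast.
5. **Off-lattice mechanics.** Cells are overlapping spheres on the crypt
   surface; the pair force is a linear (Hookean) overlap spring inside
   contact plus a short-range adhesive well just outside it (a cohesive
   epithelium), and motion is overdamped with drag proportional to
   stiffness.  Paneth cells are larger (radius factor 1.5), stiffer
   (factor 5), anchored at the base by extra drag, and their contact
   interfaces are interdigitated (pair rest length 0.8 of the radius
   sum), which maintains permanent compression at Paneth contacts — the
   persistent niche pressure that long stem-cell cycles require.
   Proliferation pushes the column towards the mouth; there is no
   imposed migration velocity.

Fate is re-read continuously from the current signals, which makes every
decision reversible by construction: high Wnt with Notch-on maintains
STEM; high Wnt with Notch-off gives PANETH; low Wnt with Notch-on gives
absorptive progenitors; low Wnt with Notch-off gives secretory
progenitors.  An absorptive progenitor terminally differentiates into an
enterocyte when the local BMP exceeds the Wnt-dependent trade-off
$B > \alpha\,w + \beta_0$ after 3 completed divisions, and
unconditionally after 5.  Paneth cells, absorptive progenitors and
secretory progenitors (the quiescent-stem pool) revert to STEM whenever
they regain stem-level Wnt and Notch — dedifferentiation, the engine of
recovery after niche injury.  Fate switches commit only after the decision has
persisted for a dwell time: 0.5 h for ordinary switches (numerical
debouncing), but biologically graded for the slow commitments —
reprogramming to the stem state needs stem-level signals held for 8 h
(progenitors) or 9 h (Paneth) together with Wnt at 2.6 times the
maintenance threshold (reprogramming hysteresis: committed cells must
regain far more Wnt than maintenance requires, which is why
dedifferentiation is rare in homeostasis and why Paneth cells, whose
tethered Wnt only ever grows, dominate regeneration), the Paneth fate
needs 4 h of sustained Notch-off at 1.2 times threshold Wnt, and
secretory maturation needs 2 h outside the niche.

## The cell-cycle network

The oscillator is a reduced relay in the Novák–Tyson tradition with
species CycE (total pool), CycA, CycB, Wee1, p27, p21, Cdc20 and Cdh1.
Free CycE activity is obtained by tight-binding titration of the total
pool against the stoichiometric inhibitors p27 + p21.  The loop runs:

* **G1.** Cdh1 is active and keeps CycA/CycB at zero; Wee1 is high; the
  CycE pool accumulates until it titrates past the inhibitor pool, when
  autocatalytic free-CycE ignition fires Start.  G1 duration is therefore
  nearly linear in the p27 production rate while the other phases are
  untouched — the G1-targeting that distinguishes slow niche cycles from
  fast transit-amplifying cycles, where G1 is shortened or omitted.
* **S.** Free CycE drives CycA accumulation and inactivates Cdh1.
* **G2.** High CycA switches on CycB production; rising CycB inactivates
  Wee1 (its fall marks the S/G2 boundary) and suppresses further CycE
  synthesis.
* **M.** High CycB activates Cdc20, which degrades CycA (its fall marks M
  entry) and then CycB; the CycB down-crossing is the division event,
  after which Cdh1 reactivates and the daughters restart G1.

Phase annotation uses the marker crossings in this fixed order: free CycE
rises through its threshold (G1→S), Wee1 falls (S→G2), CycA falls
(G2→M), CycB falls (M→division).  Thresholds are half-maximum crossings
frozen from the unperturbed limit cycle.  A uniform `tempo` factor
rescales the whole network so the base (zero-p27) period is 8.1 h;
realized birth-to-division intervals of transit-amplifying cells then
average just under 10 h, and the pressure map is calibrated (below) so
niche-resident stem cells average 17-20 h, below the 21.5 h bound.

**Mass.** Cells grow logistically towards an absolute target mass
(`mass_cap`, 2.2 A.U., about twice the birth mass of 1) at a rate tied
to the expected period for their p27 state.  The absolute anchor makes
cell size self-correcting across generations — a relative
(birth-mass-anchored) target lets small errors compound into runaway
miniaturization.  A division-less cycle restart doubles the target
(replicated genome without cytokinesis), which is how oversized cells
arise.  Mass is bookkeeping for size and the giant-cell logic; it does
not gate the cycle.

**CDK1 inhibition** multiplies the production terms of CycA and CycB by
$1-s$ (inhibitor strength $s \approx 0.95$) and destabilizes the
existing complexes (kinase-dead complexes are degraded at `kd_cdk1i`).
The network then sorts cells into the three observed outcome classes:
cells early in the cycle proceed (their G1/S machinery is untouched),
stall briefly at the G2 boundary and divide after the pulse; cells in
late G2/M cannot sustain CycB, CycE rises early, and the cycle restarts
at G1 without division — the cell keeps its accumulated mass, its growth
target doubles, and on crossing the giant-mass cap (three times the
normal division mass, reached after two division-less cycles) it is
permanently arrested as a giant cell; cells caught
in a full-strength mitosis — CycB falling below 20% of its M-entry value
while still in M during inhibition — are eligible for mitotic death,
which strikes a fraction (`p_mitotic_death`, 0.35) of them, the
remainder failing cytokinesis into the oversized-restart path.  The
probabilistic split stands in for cell-level heterogeneity the
deterministic network lacks; with a deterministic criterion the pulsed
schedule entrains the surviving cells and then removes the entire
proliferative pool, which contradicts the observed recovery.

**Damage coupling.** DNA damage above a floor drives p21 production,
which joins p27 in the titration pool (a G1/S brake); RNA damage scales
all protein production by $\sigma = 1/(1+k\,\mathrm{rna})$.  Both
lengthen the cycle continuously.  The cell is flagged ARRESTED when RNA
damage pushes $\sigma$ below `sigma_arrest`, or when the accumulated p21
pool exceeds `p21_arrest`; the pool builds slowly, so lethally damaged
cells reach their next checkpoint (and die there) before the arrest
engages.

## Pharmacokinetics and 5-FU injury

5-FU PK is a linear cascade — bolus parent with first-order elimination
and first-order formation/elimination of FUTP, FdUMP and FdUTP — advanced
by the exact piecewise-exponential solution, so the trace is
deterministic and exactly linear in dose, with near-complete washout
between 12-hourly doses.  FdUMP is tracked but has no downstream effect.
FUTP damages the RNA of proliferative cells in any phase; FdUTP damages
DNA only during S-phase.  Damage is read at the G1/S and G2/M
checkpoints: above the apoptosis threshold the cell dies (1 h clearance);
above the p21 floor it continues but slower.  The DNA damage coefficient
is calibrated so that a full S-phase spanning the 50 mg/kg peak
accumulates just over threshold damage — a cell entering S at dosing dies
at the following G2/M checkpoint, while a cell at the end of S finishes
its cycle — and the 20 mg/kg dose scales the same exposure to ~0.4, below
threshold, reproducing the minor impact of the low dose.

## The villus compartment

The villus is a one-dimensional conveyor of typed records, not a
mechanical domain: every observable the model needs from it (the
enterocyte count driving BMP, total counts, transit order) depends only
on counts and order.  Cells crossing the crypt mouth enqueue at the base;
tip shedding is residence-time based with the transit time fixed at
initialization from the homeostatic balance (villus size / crypt
outflux, about 3 days).  Residence-based shedding is what lets the villus
shrink, with a delay, when crypt output collapses after stem-cell
ablation or chemotherapy; a conveyor shed only by displacement could
never decline.  The homeostatic villus holds ~3.5 cells per crypt cell.

## Calibration

The pressure-p27 map is a saturating Hill function (exponent 2) of the
pressure in excess of an activation threshold,
$q(P) = q_\mathrm{sat}\,(P-P_0)_+^2 / (K_P^2 + (P-P_0)_+^2)$.
The threshold $P_0$ reflects that weak contact forces do not engage the
mechanosensing pathway; it is also structurally necessary here: the
realized pressure distributions put transit-amplifying cells around
0.1-0.5 A.U. and niche cells around 1-3 A.U., and no origin-anchored
Hill-2 curve can be simultaneously near zero over the first range and
near saturation over the second.  $(P_0, K_P, q_\mathrm{sat})$ were
calibrated by iterating simulation and adjustment until the pooled
birth-to-division intervals of niche-resident stem cells and of
transit-amplifying progenitors settled just below the two reported
bounds (up to 21.5 h and up to 10 h on average).  Realized means are
about 17-20 h and 9.5-10.3 h; the means sit below the bounds because
division-frequency weighting over-samples the faster cells of each
compartment.

Other calibrated choices: the BMP scale and profile midpoint put the
terminal-differentiation boundary where absorptive progenitors have
completed about four divisions; the Wnt tethering rate makes the niche
Wnt band comfortably exceed the stemness threshold at niche cycle times;
BrdU detectability (0.04) sits between 1/32 and 1/16 so the label
survives exactly four divisions.

## Scales, numerics, and what the tests do and do not show

Lengths are in cell diameters (10 um), time in hours.  The default crypt
(radius 1.6, height 14) holds roughly 150-250 cells — a desk-scale crypt
with 15-20 cell positions per hemi-crypt column rather than the ~30 of a
real mouse crypt; the villus is proportionally scaled.  The global step
is 0.05 h with two RK4 sub-steps for the cycle network (the period is
unchanged at a quarter of that step) and 0.005 h mechanical sub-steps
(explicit overdamped integration stays well below the stability bound;
the integrator aborts if any displacement exceeds half a diameter per
sub-step rather than integrating garbage).  Scenario burn-in is 5
simulated days: initialization already places a checkerboard niche,
graded progenitors and a pre-filled villus, so composition settles within
2-3 days; burn-in length is configurable.

The simulated crypt is a single crypt with a deterministic geometry and
seeded stochasticity confined to division placement, fate maturation
draws and initial staggering.  Passing tests show that the implemented
mechanisms interact to reproduce the qualitative and quantitative
behaviours described above at desk scale; they do not show quantitative
agreement with any particular mouse dataset, fit of the PK constants to
measured plasma profiles, or robustness to crypt-to-crypt geometric
variation, none of which are modelled.

## Known limitations

* Low-position retrograde motion in this model is dominated by
  division-driven jostling.  After stem-cell ablation the niche
  repopulates by downward migration, but the per-interval retrograde
  fraction at the lowest positions does not rise above its homeostatic
  value: division noise falls with the proliferative pool, and the
  emptied niche positions are largely occupied by anchored Paneth cells
  whose near-zero velocities classify as forward under the tie-break.
  The reported elevation of retrograde frequency under ablation is
  therefore not reproduced, and the corresponding test records that
  honestly.
* After stem-cell ablation the model reproduces the dedifferentiation
  flux composition (Paneth cells dominate the origins of
  reprogrammed stem cells, absorptive progenitors second, secretory
  progenitors a small minority) and the niche is empty at the 6 h
  analysis point, but the Paneth *census* does not drop by the reported
  75-100%: with the niche feedback released, Wnt floods the empty niche
  and secretory progenitors continuously reconstitute Paneth cells during
  the treatment, roughly balancing the cells lost through
  dedifferentiation-and-ablation.  Suppressing that reconstitution
  (higher Wnt bar, slower maturation, stem-only Paneth fate) collapses
  the homeostatic Paneth pool, which the same flux maintains, so the
  model keeps the flux and reports the census as computed.

* The cycle network is a reduced relay, not a full mammalian cycle
  model; it reproduces marker orderings and phase-duration control but
  not protein stoichiometries.
* Mechanics is cell-centre with linear springs on a rigid surface; no
  crypt deformation, fission, or basement-membrane mechanics.
* The villus has no spatial mechanics; villus positional statistics are
  limited to counts and order.
* Mesenchymal cells are not agents; their Wnt/BMP-antagonist activity is
  a fixed geometric field.
* Whether mature goblet/enteroendocrine/enterocytes can dedifferentiate
  is configurable but off by default; the plastic set matches the
  origins the recovery statistic tabulates.
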