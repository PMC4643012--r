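---
title: "Variability-shaped spatiotemporal patterns: models, detectors and ensemble statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variability-shaped spatiotemporal patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Colonies of excitable cells — the canonical example being starving
*Dictyostelium discoideum* amoebae relaying pulses of extracellular cAMP
— self-organise into target waves (concentric rings emitted by pacemaker
sites) and spiral waves (self-sustained rotors organised around phase
singularities).  A central question is how *fixed cell-to-cell
variability* — quenched differences in excitability, firing propensity
or developmental timing, as opposed to dynamic noise — shapes where
these pattern elements appear.  This package provides the complete
computational tool chain for studying that question in silico:

1. five lattice simulators spanning the abstraction range from a
   three-state cellular automaton to the reduced Martiel–Goldbeter cAMP
   relay model;
2. a pattern-event extraction layer that converts any spatiotemporal
   movie (simulated or measured) into a *pattern event plot*: target
   wave origins plus chirality-resolved spiral tips located via phase
   singularities;
3. ensemble statistics that relate per-site cell-property maps to event
   occupancy maps: Gaussian-filtered Spearman correlation curves and
   Voronoi-edge proximity tests.

All movies travel through one container, the `SpaceTimeCube` (an
`nx x ny x nt` array with a recording interval), cell properties through
`CellPropertyMap`, and detected events through `EventPlot`.

# The models

## Three-state cellular automaton

Sites are susceptible (S), excited (E) or refractory (R); S becomes E
when a von Neumann neighbour is excited, E always becomes R, and R
recovers after `r` steps (deterministically) or with probability `p` per
step (stochastic variant, which also allows spontaneous excitation with
rate `f`).  Its role here is conceptual: an open wavefront (an excited
half-row backed by a refractory row) curls at its free end and becomes a
rotating structure that never dies, while a full-width front simply runs
off the lattice.  `caOpenWavefrontInit()` builds exactly this initial
condition.

## Schnakenberg system

The two-species activator–substrate Turing model with kinetic constants
`c1 = 0.05`, `c-1 = 1`, `c3 = 1`, `gamma = 2`, `Du = 1`, `Dv = 20`;
`c2 = 1.00` yields spots and `c2 = 1.57` stripes, starting from uniform
random perturbations in ±0.01.  `turingDispersion()` gives the linear
growth rate of each spatial mode about the homogeneous steady state
`u* = (c1 + c2)/c-1`, `v* = c2/(c3 u*^2)`.  Because spots-versus-stripes
is a judgement by eye in the literature, `classifyTuringPattern()`
implements an operational rule (threshold at the median, connected
components via EBImage; many round components are spots, elongated
components are stripes) — the rule, not the eye, is what the tests pin
down.

## FitzHugh–Nagumo lattice

`du/dt = (1/eps)((a-u)(u-1)u - v) + D lap5(u)`,
`dv/dt = b u - gamma v + c`, with `a = -1`, `b = gamma = 0.12`,
`eps = 1`, `D = 0.1`, `dx = 1` (the printed parameter list writes
"g = b = 0.12"; we read `g` as the recovery coefficient `gamma`, the
only symbol of that role in the equations).  The excitability parameter
`c` carries the biological variability, either as a static per-site map
(Gaussian, or a base value with a low-excitability fraction and a
central pacemaker at `c = 0`) or along the developmental path
`c(t) = c0 tanh[(t - tc + dt)/Tc]` with per-site exponential time
offsets (mean `Delta`).  For the default constants the uncoupled element
has a unique rest state `u* = (-c/gamma)^{1/3}`; it is oscillatory for
|c| below about 0.019, excitable outside, and the oscillation frequency
peaks at `c = 0` — `fhnClassifyRegime()` verifies the linear-stability
picture with an explicit limit-cycle run and a standardised
suprathreshold kick (`u -> u + 0.5`, spike = excursion above 0.5).

## Hybrid cellular-automaton/ODE cAMP model

Cells with discrete phases (ready, firing, absolute refractory, relative
refractory) are coupled to continuous extracellular cAMP `c`
(degradation `Gamma`, production `rF` while firing, eight-point
Laplacian diffusion `D`) and excitability `E` (`dE/dt = eta + beta c`,
capped at `eMax`).  A ready or relative-refractory cell fires when `c`
exceeds `[cMax - A tau/(tau + tARP)](1 - E)` with
`A = (tRRP + tARP)(cMax - cMin)/tRRP`; pacemakers also fire
spontaneously with probability `pF` per step.  Only `beta`, `pF`, the
pacemaker fraction and the starting excitability are fixed by the
published experiments; the remaining constants are *reconstructed
defaults* chosen once so that the model supports propagating waves with
several wavelengths per 60-site lattice, wave break-up and persistent
rotors (`Gamma = 1`, `rF = 0.05`, `D = 0.1`, `cMax = 0.1`,
`cMin = 0.0025`, `tARP = 2`, `tRRP = 8`, firing duration 1, `dt = 0.1`).
Two reconstruction choices deserve emphasis:

* **pF and the step length.**  A per-step probability is only meaningful
  together with the source model's (unpublished) step length.  At our
  `dt = 0.1` the literal 0.002 per step makes pacemaker regions a
  permanently firing defect mush; the default `pF = 0.05` per step (a
  pacemaker fires almost as soon as it is ready) corresponds to reading
  the printed value against a coarser step and restores the regime in
  which pacemaker-dense regions outpace rotors.
* **E never resets.**  Excitability only grows to its cap, consistent
  with its description as monotone.

`pacemakerLayout()` provides the ensemble layouts: scattered (Bernoulli
sites), clustered (two lateral bands flanking a pacemaker-free central
avenue) and five fixed pacemakers with optional random extras that can
be silenced initially (the fixed set's time advantage).

## Reduced cAMP relay model with a developmental path

The three-variable reduction of the Martiel–Goldbeter receptor-
desensitisation model (active receptor fraction `rho`, intracellular
`beta`, extracellular `gamma`; equations in `?goldbeterParams`), with
the standard literature kinetic constants (`k1 = 0.036`, `k2 = 0.666`,
`L1 = 10`, `L2 = 0.005`, `c = 10`, `q = 4000`, `ki = 1.7`, `kt = 0.9`,
`h = 5`, `lambda = theta = 0.01`, `eps = 1`, `alpha = 3`, times in
minutes).  Development is modelled as sigmoidal drifts of adenylate
cyclase activity `sigma` and extracellular phosphodiesterase `ke`,
with a shared per-site exponential time offset (mean `Delta`): each cell
traverses steady -> excitable -> oscillatory -> excitable, and the
offsets spread the colony along this path.  The sigmoid constants are
not published for this printed form of the synthesis function; the
shipped defaults (`sigma`: 0.15 to 0.95 centred at 80 min, width 40;
`ke`: 2 to 6 centred at 170 min, width 35) were reconstructed *once* by
requiring exactly that regime traversal with a wide relay (excitable)
phase — the single-element regime map over the `(sigma, ke)` plane has
the canonical structure of an oscillatory island at low `ke` bordered by
relay-competent territory.

Two operational choices:

* **Regime probe.**  The excitability probe uses an additive `gamma`
  pulse of twice the rest concentration, floored at 0.05 normalised
  units: deep in the quiescent region the rest concentration vanishes,
  so a pure multiple of it cannot test relay competence, and the floor
  represents the physiological scale of a suprathreshold cAMP pulse.
* **Effective pacemakers.**  `effectivePacemakers()` marks the cells in
  the top `qFrac` offset quantile that are still oscillatory at the
  first global time at which excitable is the majority regime — the
  cells that drive colony-scale waves while the rest can only relay
  them.  Because the regime label depends on global time and offset only
  through their sum, the classification is done once along a
  one-dimensional path coordinate and memoised.

The sigmoid width of the first printed path denominator is interpreted
as `T_sigma` (matching the `ke` line and the FHN path formula); the
printed nesting `1 + alpha` in the synthesis function is used exactly as
printed.

# Event detection

`buildEventPlot()` chains four steps, all deliberately defined on the
recorded scalar movie so that the same detector serves every simulator
and measured image stacks:

1. **Dominant period** (`estimateDominantPeriod`): median spectral-peak
   period over clearly oscillating sites.
2. **Phase embedding** (`phaseEmbed`): per site,
   `phase(t) = atan2(x(t - delay) - ref, x(t) - ref)` with
   `delay = period/4` and `ref` the trailing two-period mean.  The
   windowed reference centres sites that begin oscillating midway
   through a movie and tracks duty-cycled spike trains; the amplitude
   scale cancels inside `atan2`, making the phase invariant under affine
   intensity rescaling.  Site-frames whose trailing peak-to-peak range
   falls below 30% of the movie's oscillation amplitude scale are
   masked: a phase is only defined where something oscillates.
3. **Tips** (`detectSpiralTips`): the wrapped phase differences around
   every 2x2 plaquette are summed; a winding of ±2pi marks a phase
   singularity at the plaquette centre.  Positive (counter-clockwise)
   winding is labelled "left".  Detections are linked frame-to-frame
   (radius 2, gaps of up to 2 frames bridged) and a track is emitted
   only once it spans a full dominant rotation period: a rotor, by
   definition, rotates; transient wave-collision defects do not.  Each
   track carries its majority chirality.
4. **Target origins** (`detectTargetOrigins`): an upward crossing of the
   activation threshold (midpoint of the movie's 5th/95th intensity
   percentiles) at a site with no crossing within radius 10 during the
   preceding period, followed by growth of the locally activated area
   over the next half period.  Movies that open with established waves
   skip the historyless first window; quiet-opening movies are scanned
   from the start.

The synthetic generators (`makeSpiralMovie`, `makeTargetMovie`) provide
the analytic ground truth for all of this: kinematic Archimedean spirals
and expanding ring systems, rendered as non-negative dark-field-like
intensities, partitioned between competing sources by first arrival
(colliding wave systems annihilate; on the equal-arrival seam of
synchronized sources the phases agree, so the composite is continuous),
plus i.i.d. Gaussian noise.  On a twenty-movie suite with 5% noise the
detectors achieve perfect precision, recall and chirality with
sub-site localisation error; the tests pin precision/recall at 0.9 and
localisation at 2 sites.  What the kinematic movies deliberately do not
emulate: amplitude dynamics near rotor cores, meander, or photometric
realism of dark-field optics.

# Ensemble statistics

`occupancyMap()` accumulates per-site event counts over runs.
`gaussianSmooth()` is a separable convolution (sigma = "radius",
truncated at four sigma) with half-sample reflecting boundaries, which
preserves total mass to numerical precision — the property the tests
check.  `spearmanMap()` is the rank correlation over sites;
`correlationVsRadius()` smooths event and property maps at a grid of
radii ({1, 2, 4, 8, 16} by default, "intermediate" = 4) and reports the
mean and standard error (sd/sqrt(n)) of the per-run coefficients, with
the property map either shared or per-run (developmental-path offsets
are redrawn each run).  `voronoiEdgeStat()` measures the mean distance
of event points to the Voronoi edge set of a seed set — edges are
constructed by brute-force sampling of pairwise bisectors at 0.25-site
resolution, keeping samples whose two generating seeds are jointly
nearest — against a uniform re-placement null.

# Numerical choices

* Forward Euler throughout, with `dt` chosen per model against the
  diffusive stability bound (`dt < dx^2/(2 s D)` with `s` the stencil
  weight sum): 0.01 for Schnakenberg and FHN, 0.1 for the hybrid model,
  0.005 min for the relay model.  Blow-ups raise an error naming the
  step.
* Boundaries default to no-flux (mirrored ghost cells; the Laplacians
  then conserve mass exactly), with periodic available everywhere.
* The eight-point Laplacian uses equal weights (sum of eight neighbours
  minus eight times the centre).
* The relay model clamps `rho` to [0, 1] and `beta`, `gamma` to
  non-negative values after each step, absorbing Euler overshoot of the
  physical bounds.
* One seeded RNG per run; ensemble member `k` derives its seed as
  `base + k`.  All simulators are bit-reproducible given (seed, config).

# Reduced study scales and what the shipped analyses show

The full study scale (100x100 lattices, hundreds to a thousand runs) is
available through the parameters, but the shipped tests and the
acceptance script run the package's reduced-scale defaults chosen to
exercise every mechanism on one CPU: 60x60 lattices; 50-run ensembles
per Levine layout; 20 relay-model runs of 300 min; 64x64 Turing
patterns over 10 seeds.

At these scales the analyses reproduce: spiral genesis from an open
wavefront (and annihilation of a closed one); the FHN regime anchors and
the frequency maximum at `c = 0`; the four-stage developmental regime
traversal; detector validation on synthetic ground truth; the negative
Spearman correlation between pacemaker maps and spiral-tip occupancy,
stronger for clustered than scattered layouts; the positive correlation
of target-origin occupancy with developmental time offsets; and the
proximity of relay-model spiral tips to the Voronoi edges of effective
pacemakers.

# Known limitations

* All constants of the hybrid and relay models that their sources leave
  unprinted are reconstructions; quantitative features that depend on
  their exact values (oscillation periods, wave speeds, spiral
  densities) should not be compared numerically against the original
  figures, only structurally.
* In this reconstruction the relay-model tip occupancy splits into a
  mid-path contribution (wave-in-wave conversion defects near the most
  advanced cells) and a late contribution (anchored rotors away from
  them).  The two nearly cancel in the whole-run tip-offset
  correlation, which therefore comes out much weaker than the clearly
  positive origin-offset correlation and can fluctuate in sign between
  small ensembles.
* The detectors assume a single dominant oscillation period per movie;
  media with strongly drifting frequency would need windowed period
  estimates.
* The event-plot persistence rule certifies rotors only after a full
  rotation, so rotors living less than one period (e.g. at the very end
  of a movie) are not counted.
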