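---
title: "Methods: breathing-coupled chain Monte Carlo for DNA cyclization"
author: "cyclizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breathing-coupled chain Monte Carlo for DNA cyclization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The Jacobson–Stockmayer J-factor measures the propensity of a DNA fragment to
form a closed loop: it is the equilibrium concentration (mol/L) of one end in
the reactive neighbourhood of the other, relative to bimolecular association.
For fragments longer than a couple of persistence lengths the classical
wormlike-chain picture describes measured J-factors well, but ultra-short
fragments (below ~100 bp) cyclize orders of magnitude more readily than a
uniformly elastic rod allows. One proposed resolution is thermal "breathing":
transient, sequence-dependent local strand separations that act as flexible
single-stranded hinges in an otherwise stiff duplex. `cyclizer` implements a
computational version of that hypothesis by coupling two models:

1. a nonlinear-lattice model of base-pair opening (an extended
   Peyrard–Bishop–Dauxois, "EPBD", lattice) sampled by Metropolis Monte Carlo,
   which yields a per-base-pair probability of being in the open
   (single-stranded) state, and
2. a rigid base-pair chain model in which a DNA conformation is a chain of
   base-pair frames related by sampled tilt/roll/twist angles around
   sequence-dependent trinucleotide equilibrium values, from which the
   J-factor is estimated by direct Monte Carlo counting of near-closed
   chains.

In the coupled mode, each generated chain first draws a hinge mask from the
opening profile; open base pairs use much wider angular fluctuations
(single-stranded DNA is roughly fifty times floppier than the duplex), which
concentrates closure probability on conformations with sharp, entropically
paid-for kinks.

## The lattice model of base-pair opening

Each base pair `n` carries two transverse displacements `u_n` (right strand)
and `v_n` (left strand), in Angstrom. The potential is a sum over base pairs
of an on-site Morse term

    U_n = D_n (exp(-a_n (u_n - v_n)) - 1)^2,

representing hydrogen bonding plus backbone electrostatics, and a stacking
term between consecutive base pairs

    W_n = K_u/2 (u_n - u_{n-1})^2 + K_v/2 (v_n - v_{n-1})^2
        + rho/4 exp(-beta_anh [(u_n - v_n) + (u_{n-1} - v_{n-1})])
          (sqrt(K_u)(u_n - u_{n-1}) - sqrt(K_v)(v_n - v_{n-1}))^2,

whose exponential factor weakens stacking when either base pair is displaced
out of the stack — the nonlinearity that makes opening cooperative. The pair
stretch `y_n = u_n - v_n` is the opening coordinate; a base pair is counted
open when `y_n > 2.5` Å (a local-melting criterion), and the opening
probability is the fraction of sampled lattice states in which that holds.

Parameters (see `epbd_params()`): Morse depth 0.05 eV (A·T) and 0.075 eV
(G·C) with inverse widths 4.2 and 6.9 /Å — the two- versus
three-hydrogen-bond asymmetry — anharmonicity `rho = 2`, `beta_anh = 0.35`
/Å, and a dinucleotide- and strand-resolved stacking table defaulting to a
homogeneous 0.025 eV/Å². These are the standard values of the PBD/EPBD
literature; sequence-dependent stacking tables fitted to melting data can be
supplied as YAML (`read_epbd_params()`). The lattice boundary is periodic by
default, matching the periodic sequence extension used by the chain model.

Numerical choices worth knowing:

- **Plateau cap.** The Morse plateau is flat, so a dissociated pair would
  random-walk indefinitely; the sampler caps `y <= y_max` (default 50 Å) by
  rejection. The opening probability of strongly melted states depends on
  this cap — it is a confinement choice, not a fitted constant — and mixing
  across the open/closed barrier is much faster with a small cap. The test
  suite uses `y_max = 5` Å with matched quadrature oracles for precisely this
  reason.
- **Proposal width.** Single-site uniform displacement proposals of
  half-width 0.5 Å give ~50% acceptance at 300 K; the sampler warns (never
  fails) when the acceptance rate leaves [0.2, 0.6].
- **Sweep schedule.** One sweep is one proposal per site per strand (u sweep
  then v sweep). Defaults (2,000 equilibration + 20,000 sampling sweeps,
  thinning 5) are desk-scale; production profiles of long sequences warrant
  an order of magnitude more, with the blocked standard errors returned in
  the profile attributes as the convergence diagnostic.
- **Mismatches.** A mismatched base pair (e.g. C:C) is modelled as
  permanently open: its profile entry is forced to exactly 1
  (`set_mismatch()`), which is how a nucleotide modification enters the
  coupled model.

```{r}
library(cyclizer)
s <- read_sequences(system.file("extdata", "example60.fa",
                                package = "cyclizer"))[[1]]
prof <- sample_opening_profile(s, seed = 1)
free_energy_equivalent(prof)$mean  # descriptive -log p diagnostic, kT units
```

## The rigid base-pair chain model

A conformation is a chain of base-pair frames (origin plus right-handed
orthonormal triad whose third axis is the base-pair normal). Consecutive
frames are related by six step parameters — tilt, roll, twist (degrees) and
shift, slide, rise (Å) — composed in the symmetric mid-step convention: the
net bend `Gamma = sqrt(tilt^2 + roll^2)` is applied about an in-plane axis at
angle `phi = atan2(tilt, roll)`, split around the half-twist, and the
translation is taken in the half-rotated mid-step frame. This convention is
invariant under strand relabelling; the readable reference construction is
`step_transform()`, and the compiled chain generator is verified against it
to 1e-10 in the tests.

Equilibrium step values come from a 64-entry trinucleotide table: the step
entering base pair `n` uses the context `(n-1, n, n+1)`. Appending the first
two base pairs to the end of the sequence (`extend_periodic()`) guarantees a
full context for the terminal steps and makes base pair N+1 the periodic
image of base pair 1, which is what the closure observables compare. Only the
three angles fluctuate — independent Gaussians centred on the equilibrium
values — while shift/slide/rise are held at equilibrium; flexibility is
therefore fully described by two RMS triples (`flexibility_model()`):

- duplex: 4.84° (tilt), 4.84° (roll), 4.09° (twist) — isotropic bending
  corresponding to a persistence length of ~147 bp;
- single-stranded (hinge): 30.08°, 30.08°, 27.96° — a persistence length of
  a few bp.

The small-angle relation `L_p = 2 / (sigma_tilt^2 + sigma_roll^2)` (radians)
gives 140.1 bp for the duplex numbers;
`estimate_persistence_length()` fits the exponential decay of the
normal-vector autocorrelation over simulated chains and lands within ~2% of
that closed form (and within 10% of 147 bp). The general framework would
allow a full 6x6 elastic matrix per step; the diagonal-RMS special case
implemented here is the one the two RMS triples above parameterize, and the
API accepts custom triples wherever a `flexibility_model` is taken.

The shipped trinucleotide table (`synthetic_step_table()`, also installed as
`extdata/step_table_synthetic.tsv`) is a synthetic stand-in assembled from
representative B-DNA dinucleotide step means (the XYZ entry averages XY and
YZ); it carries realistic intrinsic curvature but is not an experimental
dataset. Supply a measured table with `load_step_table()` (a `col_map`
argument tolerates other column layouts) for production use.

## From closures to J-factors

For each chain the closure observables are the end-to-end distance `r`
between the first frame and the periodic-image frame, the normal alignment
`cos gamma`, and the torsional register `cos phi` (first frame's in-plane
long axis against the last frame's long axis projected onto the first
base-pair plane — the in-plane axis choice cancels in distribution). Nested
counts through the gates `r < 30` Å, `cos gamma > 0.86`, `cos phi > 0.86`
estimate the three factors of the ring-closure factorization

    J = (4 pi / N_A) W(r ~ 0) Gamma(cos gamma ~ 1) Phi(phi ~ 0),

with each pass fraction converted to a density at the target value: `W`
divides by the capture-sphere volume in liters, `Gamma` by the cos-gamma
window `1 - 0.86`, and `Phi` by the angular window `2 arccos(0.86)` radians.
Two identities anchor this normalization: a fully orientation-decorrelated
chain reduces `J` to `W/N_A`, the classical end-concentration, and uniform
orientations give `Gamma = 0.5` (the uniform density on cos gamma). Both are
asserted in the tests, and the Gaussian-limit end concentration of a 3,000-bp
chain is reproduced within ~10–20%. As an external benchmark, the torsion-free
closure density of a straight 500-bp chain agrees with a
Shimada–Yamakawa-type wormlike-chain closed form (`sy_closure_density()`)
within a few percent — far inside the factor-of-2 band the test enforces.
Note the windowed estimators measure densities at finite resolution; with
the default gates, closure statistics for stiff sub-100-bp duplexes are in
the 1e-9-and-below per-chain regime, so meaningful counts at such lengths
need either very large chain numbers or open (hinge-rich) profiles.

Uncertainty is reported as the binomial standard errors of the three nested
ratios combined in quadrature on log J; zero fully-closed chains yield
`J = 0` with an `insufficient_sampling` flag (and `low_counts` below 10).

**Randomness and reproducibility.** All draws go through R's RNG, so
`seed` makes every estimate bit-reproducible. Per chain the draw order is
fixed: one hinge uniform per step — consumed only when the profile has any
positive entry, so an all-zero profile is stream-identical to no profile —
then tilt, roll, twist normals per step. Counts are additive: large runs can
be partitioned across seeds and merged with `combine_counts()`.

## The coupled mode and what it changes

`estimate_jfactor(..., profile = )` switches between the two modes. With a
profile, each chain draws an independent hinge mask (`U <= p` per base pair)
and the step entering an open base pair uses the single-stranded RMS triple.
A permanent central hinge on a sub-persistence-length sequence raises the
capture-sphere closure density by over an order of magnitude in the tests;
the full J rises monotonically but needs correspondingly more chains to
resolve, because closures of kinked chains pass the orientation gates less
often than smooth near-circular ones.

## The synthetic data generators

`make_synthetic_panel()` emulates the structure of an experimental
cyclization panel: by default 86 random sequences of 50–325 bp with GC
content 0.3–0.7, synthetic opening profiles with a 1e-5–1e-3 baseline and
AT-tract hotspots up to 1e-2 (`synthetic_profile()`), and toy "experimental"
J-factors generated by running the coupled pipeline itself and perturbing by
0.3-decade lognormal noise. What it deliberately does not emulate: real
profiles have correlated multi-base-pair bubbles (the lattice sampler here
reports per-site marginals only), real step tables are measured rather than
assembled from dinucleotide means, and real panels carry experimental error
structure far from lognormal. Passing benchmark tests on the synthetic panel
therefore demonstrates that the machinery — profile coupling, estimation,
stratified order-of-magnitude statistics — is correct and that the
hinge-aware model recovers a hinge-generated truth where the hinge-free model
cannot; it does not certify predictive accuracy on laboratory data.

## Problem sizes used by the shipped tests

Chosen so the whole suite runs on a single desk-scale core: persistence fits
use 6,000–10,000 chains of 500–600 steps; the lattice-vs-quadrature oracle
uses a 2-bp lattice with a 4 Å cap and ~1.2M sweeps; J-factor property tests
use 2e4–1e6 chains; the mismatch contrast uses 2e6 chains per arm at widened
gates (50 Å / 0.3 / 0.3), because at the production gates the closure
probability of a quiet ~100-bp duplex is of order 1e-9 per chain and the
published regime needs ~1e10 chains per arm; the synthetic benchmark panel
uses six 50–80 bp sequences with strongly breathing profiles at 2e5 chains
per estimate. Production settings (default gates, 1e7+ chains, full-length
panels) are reached through the same functions by changing those arguments.

## Known limitations

- Opening probabilities are per-site marginals; correlated bubble statistics
  are out of scope, and profiles depend on the plateau cap and temperature.
- The EPBD stacking default is homogeneous across dinucleotides until a
  fitted table is supplied; sequence dependence of opening then comes only
  from the A·T/G·C Morse asymmetry and flanking effects.
- No excluded volume, electrostatics, or supercoiling bookkeeping; closure
  is judged purely on the three observables.
- The Shimada–Yamakawa reference is an interpolation valid around a few
  persistence lengths of contour; do not use it far outside that range.
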