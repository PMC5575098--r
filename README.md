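# cyclizer

Monte Carlo estimation of DNA cyclization J-factors with thermal-breathing
"flexible hinges".

## The problem

The Jacobson–Stockmayer J-factor (mol/L) measures how readily a DNA fragment
loops back on itself: the effective concentration of one end in the reactive
neighbourhood of the other. Classical elastic-rod (wormlike-chain) models
reproduce measured J-factors for fragments beyond a couple of persistence
lengths but under-predict ultra-short (< 100 bp) cyclization by orders of
magnitude. `cyclizer` implements a breathing-coupled model of that anomaly
for structural-DNA researchers: transient, sequence-dependent base-pair
openings — computed from a nonlinear Peyrard–Bishop–Dauxois-type lattice —
act as single-stranded hinges inside a rigid base-pair chain model, and the
J-factor is estimated by direct Monte Carlo ring-closure counting.

## The model

**Base-pair opening.** Each base pair carries strand displacements
(u<sub>n</sub>, v<sub>n</sub>) with a Morse on-site potential
D<sub>n</sub>(e<sup>−a<sub>n</sub>(u−v)</sup> − 1)² and anharmonically
modulated stacking between neighbours. Metropolis sampling of this lattice
gives, per base pair, the probability p<sub>n</sub> that the pair stretch
exceeds 2.5 Å (local melting). A mismatched base pair is permanently open
(p = 1).

**Chain model.** A conformation is a chain of base-pair frames related by
tilt/roll/twist rotations (mid-step convention) around trinucleotide
equilibrium values, with Gaussian angular fluctuations: RMS
4.84°/4.84°/4.09° for duplex steps (persistence length ≈ 147 bp) and
30.08°/30.08°/27.96° for open (single-stranded) steps (persistence length a
few bp). Per chain, a hinge mask is drawn against the opening profile.

**J-factor.** With N<sub>A</sub> Avogadro's number,

J = (4π/N<sub>A</sub>) · W(r ≈ 0) · Γ(cos γ ≈ 1) · Φ(φ ≈ 0)

estimated from nested counts of chains passing r < 30 Å, cos γ > 0.86,
cos φ > 0.86 (end-to-end distance, normal alignment, torsional register),
each pass fraction normalized to a density at its target value.

## Worked example

Estimate the persistence length encoded by the duplex fluctuation widths and
the J-factor of a short, strongly breathing fragment, with and without a
permanent central hinge:

```r
library(cyclizer)

estimate_persistence_length(n_chains = 4000, chain_length = 500, seed = 1)
#> <persistence_fit> L_p = 137.5 bp (SE 3.45); small-angle form 140.1 bp

tab <- synthetic_step_table()           # synthetic trinucleotide fixture
set.seed(60)
s <- random_dna(90, gc = 0.5, id = "demo90")

plain <- estimate_jfactor(s, tab, n_chains = 2e5, seed = 2)
breathing <- estimate_jfactor(s, tab, n_chains = 2e5, seed = 2,
                              profile = opening_profile(rep(0.3, 90)))
plain
#> <jfactor_estimate> J = 0.000E+00 mol/L (mode cso)
#>   counts: total 200000 | r 0 | gamma 0 | phi 0
#>   flags: insufficient_sampling
breathing
#> <jfactor_estimate> J = 1.107E-04 mol/L (mode cso_epbd)
#>   counts: total 200000 | r 1572 | gamma 82 | phi 18
#>   stderr = 2.61E-05 mol/L
```

The fitted persistence length (137.5 ± 3.5 bp) matches the small-angle
closed form 2/(σ²<sub>tilt</sub> + σ²<sub>roll</sub>) = 140.1 bp encoded by
the duplex widths. A rigid 90-bp duplex never closes at these chain numbers
(J reported as 0 with an `insufficient_sampling` flag), while the same
sequence with a deliberately extreme breathing profile (every base pair open
30% of the time) passes all three closure gates 18 times in 200,000 chains,
giving J ≈ 1.1×10⁻⁴ mol/L with its binomial standard error — the hinge
mechanism in one picture. Realistic profiles from the lattice sampler are
orders of magnitude quieter, and resolving their J-factors at the production
gates needs correspondingly larger `n_chains`.

Opening profiles come from the lattice sampler
(`sample_opening_profile()`), from TSV files (`read_profile()`), or from the
synthetic generator (`synthetic_profile()`); benchmark comparisons against
experimental panels run through `run_benchmark()`. A thin command-line
front end with `epbd-profile`, `jfactor`, `benchmark` and `make-fixture`
subcommands is installed at `inst/cli/cyclizer.R`.

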