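---
title: "Methods: water structure, hydrogen bonding and mobility in glucan hydrogels"
author: "hydroglucan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water structure, hydrogen bonding and mobility in glucan hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroglucan)
```

## The scientific problem

Callose is a linear β-(1,3)-glucan that plants deposit at wound sites,
plasmodesmata and growing cell plates; cellulose, its β-(1,4) cousin, forms
the crystalline scaffold of the cell wall. A long-standing conjecture holds
that callose strengthens the wall through a peculiar interaction with
water: the regular ~4.8 Å spacing of its hydroxyl oxygens matches a
characteristic O–O correlation distance of water (the six-ring motif of
hexagonal ice), so callose might template an ice-like ordering of its
hydration shell. Testing this requires large MD simulations of
polysaccharide networks in water and a specific battery of analyses:
per-population static structure factors, a geometric hydrogen-bond census,
displacement-distribution analysis of water mobility, restricted-population
radial distribution functions, Monte-Carlo volume partitioning, and
Young's-modulus estimation under uniaxial load.

`hydroglucan` implements that battery as a reusable, tested R toolkit. The
MD itself (force fields, integrators, barostats) is out of scope; instead
the package ships synthetic-data generators whose ground truth is known
exactly, so that every estimator can be validated end to end. Passing those
tests demonstrates that the *analysis machinery* is correct — it does not by
itself validate any physical claim about real gels, whose configurations
are produced by interacting dynamics the generators deliberately do not
model.

## Data model and conventions

A `labeled_trajectory` holds an ordered sequence of frames — time (ps),
orthorhombic box edges (nm), and an N × 3 coordinate matrix (nm) — plus an
immutable per-site label table (element; role such as `water_O`,
`poly_hydroxyl_O`; polymer identity; chain id; ring index; carbon
attachment of hydroxyl oxygens). Coordinates are wrapped into `[0, L)` on
ingest; unwrapping is a separate, explicit operation so every analysis
states its periodic-image convention. Triclinic boxes are rejected rather
than silently truncated.

Units follow the field's mixed conventions deliberately: coordinates and
boxes in nm (the GRO convention), times in ps, diffusion coefficients in
cm²/s, and all radial/wavevector arguments of the structure-factor and rdf
machinery in Å / Å⁻¹, converted internally. All indices (sites, frames,
chains, rings) are 1-based, as is idiomatic in R; GRO serial numbers map
directly.

## The gel builder

The builder reproduces the reference construction protocol geometrically:
a single glucose residue template is replicated 48 times at a fixed rise
(default 0.52 nm, so a chain spans ≈ 25 nm); 64 chains are laid along each
Cartesian axis on 8 × 8 transverse lattices (successive axes offset by half
a lattice cell to avoid contacts), each chain shifted along its own axis by
a seeded uniform random distance so that chains wrap through the periodic
boundaries. The default network therefore has 192 chains and 9216 rings.
Solvation fills the box with water on a cubic lattice at the liquid-water
number density (33.37 nm⁻³), carves out an exclusion zone (default 0.25 nm)
around polymer heavy atoms, and thins randomly to an exact molecule count
or to a weight-percent target via the closed-form mass balance
`n_w = wt/(100 − wt) · m_ring n_rings / m_water` (18.0153 and 162.141
g/mol; the +18 g/mol chain-terminal correction is ignored — below 0.03 % at
48 rings). A dilution cascade removes random whole molecules to sweep the
concentration series.

The residue template is deliberately coarse: ring heavy atoms on a puckered
hexagon, hydroxyl oxygens on radial stubs placed so that the intra-ring
pair distances the rdf analyses probe are preserved — callose O2–O4 at
4.80 Å, O2–O6 at ≈ 3.4 Å, O4–O6 at ≈ 4.3 Å; cellulose O2–O3 at ≈ 2.8 Å,
with no special ~4.8 Å pair. It claims no chemical accuracy, and no
relaxation is emulated: the analyses are validated on synthetic dynamics,
not on force-field physics. Consequently builder output shows none of the
chain meandering, entanglement cross-links, or thermal disorder of a real
gel, and conclusions about real samples cannot be read off it.

## Synthetic dynamics

Brownian walkers provide the mobility ground truth. Each walker draws a
mixture component by weight and takes Gaussian steps of per-axis variance
`2 D dt`. The displacement-magnitude distribution of a component over lag
`t` is the radial 3-D propagator

$$p(r) = 4\pi r^2 (4\pi D t)^{-3/2} e^{-r^2/(4Dt)},$$

and the package adopts this radial-Jacobian convention as the default
(the distribution is plotted over the distance r, which carries the
4πr² measure); a per-coordinate (half-normal) convention is available
behind a flag for comparison. Optional box "breathing" rescales the box
sinusoidally (default one period per trajectory) with affinely rescaled
wrapped positions — a minimal stand-in for barostat fluctuations, sufficient
to exercise the unwrapping contract but with none of a real barostat's
stochastic dynamics.

Reference lattices serve the structure analyses: a simple-cubic lattice
(rdf and S(k) peaks at the spacing and its reciprocal), an ideal gas
(g = 1, S = 1), and an "ice-like" lattice with wurtzite topology, the
four-coordinated network of hexagonal-ice oxygens. For an ideal tetrahedral
network the six-ring correlation shell sits at `nn·√(8/3) = 1.633·nn`. The
default nearest-neighbour distance is 2.97 Å, chosen so that this ring
shell falls at 4.85 Å — the reference periodicity the hydroxyl-spacing
comparison is made against; the crystallographic ice value (2.76 Å, ring
shell at 4.51 Å) is available by argument. The two targets (real-ice bond
length, 4.7–4.9 Å ring shell) cannot be met simultaneously by an ideal
lattice, and the package resolves the tension in favour of the ring-shell
position, which is what the rdf machinery is tested against.

The stress–strain generator produces
`⟨L⟩(σ) = L0·(1 + (σ − 0.1)/Y) + ε`, with strain referenced to the
0.1 MPa ambient state whose mean length defines `L0` — the same reference
the estimator uses, so the noiseless series inverts exactly.

## Structure factors

For a site selection of size N the package computes
`ρ_k = Σ_j exp(i k·r_j)` exactly and `S(k) = ⟨|ρ_k|²⟩/N`, averaging over
frames (treated as independent configurations; the frame stride, default
10, is the user's statement of independence) and over all box-commensurate
wavevectors `k = 2π(n_x/L_x, n_y/L_y, n_z/L_z)` within each `|k|` shell.
Only a half space of integer triples is enumerated (inversion symmetry).
Defaults `k_max = 3.0 Å⁻¹` and `Δk = 0.02 Å⁻¹` resolve both the low-k
prepeak region and the main liquid-water peak at
`k_nn = 2π/2.85 Å⁻¹ ≈ 2.2 Å⁻¹`. For fluctuating (NPT-style) boxes the
commensurate grid is regenerated per frame while shell edges stay fixed in
Å⁻¹, so shell membership may vary frame to frame — the documented contract.
The prepeak finder smooths S(k) with a 3-point moving average and reports
the largest interior local maximum strictly below `k_nn` (or none if
monotone); a prepeak signals alternating water/polymer domains, and its
position tracks the domain periodicity.

The cost of the exact sum scales as (k_max·L)³ per frame times N; it is
meant for the desk-scale systems of the test battery, not for
million-atom frames.

## Hydrogen-bond census

An O–H···O triplet is a hydrogen bond when the O–O distance is *strictly*
less than 3.2 Å and the O–H–O angle at the hydrogen *strictly* wider than
140° (the stated boundary convention; both cuts are exclusive). Covalent
O–H ownership is assigned geometrically — a hydrogen belongs to the nearest
oxygen within 1.2 Å — so the census works on label-only inputs without
topology tables. A water hydrogen with no oxygen within 1.2 Å is a
malformed input and raises an error naming the site; a polymer hydrogen
with none is carbon-bound and simply not a donor; two oxygens within 1.2 Å
of one hydrogen is ambiguous and errors rather than guessing. Each donor
hydrogen participates in at most one bond per frame: the widest-angle
acceptor wins, distance breaking ties — this cap prevents double counting
in the per-glucose aggregates. Neighbour search uses cell lists, falling
back to all-pairs in boxes smaller than three cells per axis; the two paths
are tested for exact agreement.

Bonds are classified as water–water, donated by the chains to water,
donated by water to the chains, intrachain or interchain. Per-glucose
aggregates count donated and accepted bonds separately: hydroxyls alone can
donate (they carry the proton), while every chain oxygen — hydroxyl, ring
or glycosidic — may accept. Wire statistics build the directed graph whose
nodes are chain oxygens and whose edges are waters that simultaneously
accept from one chain oxygen and donate to another, reporting maximal path
lengths in water units; bridging waters are those whose chain-involving
bonds span at least two chain ids, counted against all water molecules.

## Water mobility

Unwrapping uses the toroidal scheme: the displacement between consecutive
frames is the minimum-image difference evaluated in the *current* frame's
box, then accumulated. Under a constant box this equals classical
unwrapping; under a fluctuating box it avoids the spurious drift that
position-based schemes accumulate. Any inter-frame minimum-image
displacement reaching half the box aborts with frame and site.

MSD curves average over multiple time origins; the Einstein estimate
`D = slope/6` is fit over a window (default: the last half of the curve)
and warns — without failing — when a quadratic term is significant at two
standard errors, since short-lag MSD in crowded systems is visibly
nonlinear. Displacement distributions at a fixed lag (default origin
stride: the lag itself, giving non-overlapping origins that limit serial
correlation) feed the mixture fit. The 30 ps default lag sits above the
~10 ps H-bond lifetime (short enough that bound and free populations have
not yet exchanged away their identity) while keeping displacement
signal above the noise.

`fit_brownian()` maximises the mixture likelihood in transformed
parameters (log D, logit weight) with five seeded multistarts spanning
dispersed D ratios; standard errors come from the observed information via
the delta method, components are reported fast-to-slow, and the
log-likelihood supports the one- versus two-population comparison. A
binned least-squares mode reproduces figure-style fits. Posterior
responsibilities assign each molecule a fast/slow label (products over its
observations), and the population-weighted mean `Σ w_i D_i` gives the
overall diffusion coefficient implied by the fit. Whether the original
analysis fitted the histogram or the likelihood is not documented;
maximum likelihood is the default here because it is the efficient choice
for raw magnitudes, and the least-squares mode covers the other reading.

## Radial distribution functions

`rdf()` histograms minimum-image pair distances between a reference and a
target selection (defaults `Δr = 0.05 Å`, `r_max = 12 Å`, covering the
4.8 Å peak and the 7–10 Å medium range). Two normalisations are provided:
the textbook `bulk_density` mode divides by the ideal-gas shell expectation
`4πr²Δr·ρ_target·N_ref`, and `shell_count` reports raw average neighbour
counts per reference. For restricted populations — e.g. only waters
H-bonded to the chains, selected frame by frame from the census — the
population is neither homogeneous nor isotropic, the radial variable is a
1-D projection, and g(r) need not approach 1; `shell_count` is the honest
default there and the normalisation mode is recorded on the result.

The ~4.8 Å hydroxyl peak is decomposed by pair category inside a window
(default 4.55–5.15 Å): same-ring C2–C4, same-ring C4–C6, neighbouring-ring
C2–C4, other intrachain, interchain, with same-ring taking precedence over
neighbour-ring over the generic classes. Chain-terminal hydroxyls carry no
carbon attachment and are excluded.

## Volume partition

The polysaccharide/water volume split uses Monte-Carlo integration with a
Voronoi-type rule: uniform random points are assigned the phase of the
nearest site under minimum image, and phase fractions estimate volume
fractions with binomial standard errors. Heavy atoms only by default —
hydrogens bias the plain nearest-site rule toward the phase with more
hydrogens per heavy atom — and an optional radius-weighted mode subtracts
van der Waals radii (O 1.52, C 1.70, H 1.20 Å) before comparison. The two
modes bracket the reasonable readings of a nearest-site volume rule; the
plain heavy-atom rule is the default because it is the simplest and fully
specified.

## Elastic response

Given a tension schedule (default: 0.1 MPa reference, 0.5 MPa steps to
3 MPa, 1 MPa steps to 10 MPa) and mean box lengths along the stressed
axis, `young_modulus()` forms relative strains about the 0.1 MPa reference
length, fits strain on stress by (optionally weighted) least squares with
a free intercept, and reports `Y = 1/slope` with the propagated error.
The intercept is not forced through the reference point; for a clean
series it sits at exactly `−0.1/Y` and is reported as a diagnostic, so a
reference-state offset is visible rather than absorbed.

## Numerical choices and degenerate inputs

Strict inequalities at both H-bond thresholds; ambiguous covalent
assignments error; empty selections error rather than returning empty
results silently; a negative MSD slope clips D at zero with a warning; a
non-positive stress–strain slope errors ("no elastic response detected");
single-phase frames return degenerate volume fractions with zero error
without sampling; mixture components with equal D are ordered by the
fitted weight and a degenerate two-component fit on one-population data is
expected to collapse (tiny weight or coincident D) rather than fail.
Optimiser non-convergence after all multistarts is an error carrying the
sample size and lag.

## Problem sizes used by the test battery

The shipped tests run at desk scale by design: mixture recovery at 10⁵
displacement magnitudes (the reference analysis scale) with replicate
bias checks at 12 × 10⁵; hydrogen-bond cross-validation on up to 1500
random molecules; structure-factor brute-force equivalence at N ≤ 25 with
exact 10⁻¹⁰ tolerances; Monte-Carlo volume checks against 50³–60³
deterministic grids; and 40–100-seed Monte-Carlo loops for the elastic
estimator. The full default network (192 chains, 9216 rings, ~1.9 × 10⁵
polymer sites) is built and counted; million-atom solvated frames are
exercised only through the exact lattice arithmetic of the solvation
module.

## Known limitations

The builder's idealized geometry carries no thermal disorder, so
rdf/structure-factor features are delta-like rather than broadened; the
box-breathing model is deterministic and sinusoidal; the H-bond census has
no lifetime/autocorrelation notion; XTC trajectories are not read (convert
to DCD or multi-GRO); and the exact structure-factor sum is not intended
for production-scale frames. None of these affect the estimator contracts
the tests pin down.
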