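# hydroglucan

Analysis toolkit for MD-style trajectories of glucan hydrogels — networks of
callose (β-1,3-glucan) or cellulose (β-1,4-glucan) chains in water. It is
aimed at people who study whether and how these polysaccharides structure
their hydration water: the package provides the full analysis battery such a
study needs, together with synthetic-data generators with exact ground
truth, so every estimator is validated end to end without running any MD.

## What it computes

**Static structure factors per oxygen population.** For a selected
population (water oxygens, chain oxygens, or their union) of size *N*,

    rho_k = sum_j exp(i k . r_j),      S(k) = <|rho_k|^2> / N,

on box-commensurate wavevectors, shell-binned in |k| and averaged over
frames, with detection of the low-*k* prepeak that signals alternating
water/polymer nanodomains (below the main liquid-water peak at
k_nn = 2π/2.85 Å⁻¹).

**Geometric hydrogen-bond census.** An O–H···O triplet is a bond when the
O–O distance is < 3.2 Å and the O–H–O angle at the hydrogen is > 140°
(both strict). Bonds are classified water–water, chain→water, water→chain,
intrachain, interchain; per-glucose donated/accepted averages, alternating
water–chain "wire" lengths and chain-bridging waters are derived.

**Water mobility.** NPT-safe trajectory unwrapping (toroidal scheme:
minimum-image inter-frame displacements accumulated in the current box),
multiple-origin MSD and Einstein-relation diffusion estimates, and the
displacement-magnitude distribution at a fixed lag *t* fitted by a one- or
two-population Brownian mixture

    p(r) = sum_i w_i 4 pi r^2 (4 pi D_i t)^(-3/2) exp(-r^2 / (4 D_i t)),

by maximum likelihood with multistart, giving fast/slow diffusion
coefficients, population weights, standard errors and per-molecule
posterior population labels.

**Restricted-population rdfs** (including "only waters H-bonded to the
chains", selected per frame from the census), with decomposition of the
~4.8 Å hydroxyl–hydroxyl peak by pair category (same-ring C2–C4, same-ring
C4–C6, neighbour-ring C2–C4, other intrachain, interchain).

**Monte-Carlo Voronoi volume partition** (nearest heavy atom under minimum
image) and **Young's modulus** from uniaxial tension → box-length series,
`Y = 1/slope` of strain on stress with propagated error.

**Generators.** A geometric gel builder (48-ring chains replicated on a
3-axis lattice — 192 chains / 9216 rings by default — with lattice solvation
to exact counts or weight percent and a random dilution cascade), Brownian
single/two-population walkers, reference lattices (simple cubic, ice-like
wurtzite network, ideal gas), and noisy linear stress–strain series.

GRO is the canonical file format (PDB and DCD are read through bio3d;
multi-frame GRO trajectories round-trip).

## Worked example

```r
library(hydroglucan)

# a small gel: 48 chains of 6 rings on a 3-axis lattice, solvated to 50 wt %
net <- place_network(network_spec(rings_per_chain = 6, chains_per_axis = 4,
                                  box_side = 6, seed = 1))
gel <- solvate_lattice(net, target = list(wt_pct = 50), seed = 1)
composition_summary(sum(gel$labels$role == "water_O"),
                    network_counts(gel)$n_rings)
#> $water_wt_pct    49.99949
#> $waters_per_ring  9

hbond_census(gel)
#> H-bond census over 1 frame(s): 133 bonds
#>            ww poly_to_water water_to_poly    intrachain    interchain
#>           129             2             2             0             0
#>   n_HB per glucose: donated 0.028, accepted 0.028

# two-population water mobility at a 30 ps lag: draw 1e5 displacement
# magnitudes from a fast/slow mixture and recover its parameters
sp <- brownian_spec(data.frame(D = c(1.93e-5, 2.30e-6), weight = c(0.85, 0.15)),
                    n_walkers = 1e5, seed = 1)
fit <- fit_brownian(displacement_samples(sp, t = 30), n_components = 2)
fit
#> Brownian mixture fit (2 component(s), ml, radial convention), n = 100000, t = 30 ps
#>   D1 = 1.93e-05 cm^2/s (se 6.5e-08), w1 = 0.851 (se 0.0023)
#>   D2 = 2.302e-06 cm^2/s (se 3.8e-08), w2 = 0.149 (se 0.0023)
#>   logLik = 2724.312
weighted_D(fit)
#> 1.68e-05

# Young's modulus from a noisy synthetic loading series (truth: 200 MPa)
series <- simulate_stress_strain(stress_strain_spec(Y_true = 200, L0 = 25,
                                                    noise_sd = 0.15, seed = 1))
young_modulus(series)
#> Young's modulus: Y = 218 +/- 25 MPa
```

The census counts are sparse because the builder places idealized, rigid
geometry (lattice water in a fixed orientation); the numbers are exactly
reproducible under the seeds shown. The mixture fit recovers the fast
coefficient to three figures and both weights to a few tenths of a percent;
the modulus estimate brackets the generating value within one standard
error.

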