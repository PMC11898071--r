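Package: hydroglucan
Title: Structure, Hydrogen Bonding and Water Mobility in Glucan Hydrogel Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics-style trajectories of
    polysaccharide (callose/cellulose) hydrogels in water. Builds synthetic
    gel-network configurations and ground-truth Brownian dynamics, computes
    per-population static structure factors with prepeak detection, performs a
    geometric hydrogen-bond census with donor/acceptor classification (H-bond
    wires, bridging waters, per-glucose aggregates), unwraps NPT trajectories
    by the toroidal scheme, estimates diffusion coefficients and fits one- or
    two-population Brownian mixtures to displacement distributions, computes
    radial distribution functions over restricted oxygen populations, performs
    Monte-Carlo Voronoi-type volume partitioning, and estimates Young's
    modulus from uniaxial stress-strain series. Reads and writes GRO
    coordinate files and multi-frame trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
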