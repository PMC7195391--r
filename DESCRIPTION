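Package: kinkgate
Title: Two-Gate Crosstalk Analysis of Potassium-Channel Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory-analysis pipeline for tetrameric potassium channels
    (MthK-like) linking the kinked/bent conformational equilibrium of the
    inner helix to selectivity-filter and central-cavity gating and to ion
    current. Reads PDB/GRO topologies and DCD or multi-model PDB
    trajectories; computes gating descriptors (backbone hydrogen-bond
    distances, inner-helix bending angle, Thr59 O-gamma ring opening,
    Phe87-CoF distance), classifies subunits as kinked or bent, counts
    potassium permeation events and converts them to currents, builds axial
    density/"free energy" and pore-radius profiles, and performs
    partial-least-squares functional mode analysis. Includes a synthetic
    trajectory generator that plants the assumed statistical structure
    (two-state Markov gating, configuration-dependent Poisson permeation,
    gate geometry coupling) with full ground truth, so every pipeline stage
    is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
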