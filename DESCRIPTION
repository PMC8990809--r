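Package: pipsites
Title: Phosphoinositide Binding-Site Mapping for Symmetric Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-docking analysis of phosphoinositide headgroup poses and
    coarse-grained trajectory lipid-contact analysis for C_n-symmetric
    membrane proteins. Reduces docked headgroup poses to three-centroid
    vectors, applies a membrane-orientation acceptance filter, rotates
    accepted poses into a reference symmetry wedge, clusters them by
    centroid proximity, and identifies contacting residues. For
    trajectories, detects lipid-residue contacts with a dual-cutoff state
    machine, computes per-residue and per-site occupancies and residence
    times, clusters binding sites by residue co-contact, and builds
    membrane-plane lipid density maps. Ships deterministic synthetic-fixture
    generators (toy oligomers, planted pose sets, scripted dwell
    trajectories) so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
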