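Package: bltpgeom
Title: Geometric Profiling of Bridge-Like Lipid Transfer Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic, scriptable geometry analysis for bridge-like lipid
    transfer protein (BLTP) structures and other elongated protein channels or
    grooves. Fits the channel axis of an atomic model by principal component
    analysis, partitions atoms into perpendicular slabs (5 Angstrom by
    default), and computes per-slice lumen cross-sectional area and channel
    width (largest inscribed circle and maximum chord), integrated lumen
    volume and lipid-capacity estimates, hydropathy profiles of the
    channel-lining versus exterior residues, and solvent-accessible surface
    areas (Shrake-Rupley) with group-versus-group buried-surface (interface)
    quantification. Includes a synthetic-structure generator with analytic
    ground truth (open grooves, sphere systems) so every stage is testable
    without downloading deposited coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv
Config/testthat/edition: 3
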