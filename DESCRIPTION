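Package: mrprep
Title: Search-Model Preparation and Triage for Molecular Replacement with
    Predicted Protein Structures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prepares coarse-grained predicted protein structures (Calpha,
    Cbeta, O per residue) for use as molecular-replacement search models.
    Reads single- and multi-model PDB ensembles, computes per-residue
    root-mean-square fluctuations over a trajectory window and converts them
    to crystallographic B factors, trims flexible residues above an r.m.s.f.
    cutoff, scores models against templates and references with
    distance-difference similarity metrics (Qw, Q over template-aligned
    regions, GDT-TS), compares Calpha contact maps, clusters prediction
    ensembles by mutual Q to judge sampling convergence, and triages
    molecular-replacement trial statistics (TFZ, LLG, R-free, map CC)
    against an R-free based success criterion. Includes a synthetic-fixture
    generator so the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    bio3d,
    pheatmap
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, Clustering
RoxygenNote: 7.3.3
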