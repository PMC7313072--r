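Package: TRArep
Title: Simulation and Clonotype Analysis of T-Cell Receptor Alpha Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for T-cell receptor alpha (TRA) chain
    amplicon repertoire analysis: TRAV/TRAJ gene segment assignment by local
    alignment against an IMGT-style reference, CDR3 junction extraction
    between the conserved Cys-104 and Phe-118 anchor codons, clonotype
    collapse with copy counting, ranking and percentage frequencies, V-J
    usage matrices, invariant T-cell (MAIT, iNKT) flagging by canonical
    V-J pairs, and detection of clonotypes shared between samples. Includes
    a ground-truthed V(D)J recombination read simulator (skewed clone
    abundances, junctional trimming and N-insertion, per-base substitution
    error, invariant spike-ins, planted cross-sample shared clones) for
    benchmarking recovery when no real sequencing data are available.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, ImmunoOncology, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'align.R'
    'cli.R'
    'clonotype.R'
    'invariant.R'
    'io.R'
    'reference.R'
    'simulate.R'
    'utils.R'
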