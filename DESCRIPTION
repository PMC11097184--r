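Package: molmask
Title: Frequency-Weighted Atom Masking for Molecular Graph Pretraining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Self-supervised pretraining of molecular graph neural networks
    with a per-molecule, atom-type-frequency-weighted masking sampler (WMM).
    Atoms are masked with probability proportional to ln(k*(n+1))/n, where n
    is the within-molecule count of the atom's element, so that rare
    ("trace") elements such as halogens are masked more often than under
    uniform random masking. The package provides SMILES input/output and
    graph featurization, the weighted sampler with an exact enumeration
    oracle, a graph isomorphism network (GIN) encoder with masked-atom
    prediction (AttrMask) and masked-autoencoder (GraphMAE-style)
    objectives, Bemis-Murcko scaffold splitting, multi-task fine-tuning
    with ROC-AUC evaluation, and a synthetic corpus generator that emulates
    the imbalanced atom-type distribution of drug-like molecule libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    pROC,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
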