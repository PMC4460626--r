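Package: procars
Title: Progressive Reconstruction of Contiguous Ancestral Regions from
    Signed Synteny-Block Orders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the ancestral gene order at a tagged internal
    node of a rooted species tree from the signed synteny-block orders of
    the extant genomes at its leaves. Starting from one single-block
    Contiguous Ancestral Region (CAR) per block, the method iteratively
    detects CAR adjacencies in the extant genomes (tolerating
    micro-rearrangements at CAR ends), classifies them by homoplasy cost
    against the ingroup/outgroup partition induced by the tagged node,
    resolves conflicts by a minimum-mutation-cost small-parsimony
    criterion, detects rearrangement-supported (DCJ-reliable)
    adjacencies, and assembles the retained non-conflicting adjacencies
    into CARs. Includes a DCJ-based genome evolution simulator and
    evaluation metrics (breakpoint distance, shared-adjacency
    accounting, precision/recall against a simulated ancestor).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
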