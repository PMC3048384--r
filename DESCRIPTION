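Package: causalflow
Title: Causal Gene and Dysregulated Pathway Discovery by Current Flow on
    Molecular Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates tumor/control gene expression, copy-number profiles
    and a typed molecular interaction network to prioritize causal genes and
    the pathways through which they dysregulate target genes.  Target genes
    are chosen by a greedy minimum multi-set cover over per-case differential
    expression calls; copy-number loci are compressed into tag loci and
    associated with targets by linear regression (an eQTL scan); candidate
    causal genes inside associated regions are ranked by solving an electric
    circuit problem on the interaction network with expression-correlation
    conductances, a transcription-factor constraint at the target and a
    degree-preserving permutation null; the final causal set is picked by a
    greedy weighted multi-set cover over the cases each gene explains, and
    maximum-current (bottleneck) paths trace the intermediate pathway nodes.
    A synthetic-cohort generator with planted causal structure supports
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
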