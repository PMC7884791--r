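Package: ftpnet
Title: Constructing Binary Recurrent Networks from State-Transition Graphs
Version: 0.1.0
Authors@R:
    person("ftpnet", "maintainers", email = "ftpnet@example.org", role = c("aut", "cre"))
Description: Builds binary threshold recurrent neural networks whose synaptic
    weights are obtained by solving a consistent linear system assembled from a
    task's state-transition graph (the firing-to-parameter approach), rather
    than by iterative optimisation. Supports a two-stimulus sequence-memory
    task encoded on a binary de Bruijn graph, random transition graphs with a
    controlled fraction of bicoloured (relative-coding) states, control of
    firing rate and pairwise correlation at construction time, a genetic
    algorithm over activation bases, sampling of the isofunction weight space,
    projected gradient descent in the null space of the coefficient matrix to
    impose structural constraints (no self-connections, Dale's principle,
    sparsity), and the firing and connectivity statistics (Spearman pairwise
    correlation, inter-spike-interval shuffling, reciprocity, normality of
    weight distributions) used to probe structure-function relationships.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
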