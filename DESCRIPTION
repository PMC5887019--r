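Package: synthor
Title: Synthesis Planning as Shortest Hyperpaths in Hypergraphs of Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models retrosynthetic planning of a molecular skeleton as a
    combinatorial optimization problem on directed B-hypergraphs. A target
    molecule together with a bond set (or an explicit list of construction
    reactions and starting materials) induces a hypergraph of reactions
    (HoR) in which every synthesis plan appears as a directed hyperpath
    from a dummy source to the target. The package builds HoRs by
    recursive bond breaking, enumerates non-isomorphic bond sets of a
    skeleton under its automorphism group, validates and manipulates
    hyperpaths, evaluates additive plan-quality measures such as the total
    weight of starting materials (TW) under retro yields, and ranks the K
    best plans by a Yen-style K-shortest-hyperpaths search over the HoR.
    The decalin (bicyclo[4.4.0]decane) skeleton is included as a built-in
    worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
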