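Package: hishapes
Title: Helix-Index Shape Analysis of RNA Folding Spaces and Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained analysis of RNA secondary-structure folding spaces
    based on helix index shapes (hishapes). Maps pseudoknot-free, lonely-pair-free
    secondary structures to decorated helix-index lists at four abstraction levels,
    filters the folding space to strictly negative structures, estimates
    folding-pathway energy barriers with a fuzzy-related-hishape anchored
    minimax-Dijkstra heuristic over width-k breadth-first direct paths, and
    simulates folding kinetics as a continuous-time Markov chain with Arrhenius
    transition rates derived from hishape ensemble energies. Ships a compact
    pluggable nearest-neighbor energy model, an exact landscape oracle for small
    instances, and deterministic synthetic-sequence generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    seqinr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
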