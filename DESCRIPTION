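Package: domorth
Title: Domain-Level Orthology Inference for Proteome Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers orthology between two species at the level of protein
    domains rather than full-length sequences. Proteomes are cut into
    domain-equivalent sequences (Pfam domain instances, long unannotated
    regions, and orphan full-length proteins), an InParanoid-style
    reciprocal-best-hit clustering with inparalog recruitment is run on the
    cuts, and the resulting ortholog groups of domains are projected back
    onto proteins through the alpha statistic (the fraction of a protein
    pair's domain instances that fall in shared ortholog groups). Detects
    discordant domain orthology (different domains of one protein
    orthologous to different partner proteins, the signature of gene fusion,
    fission and domain shuffling), merges domain-based calls with
    full-length ortholog groups, and ships a synthetic proteome-evolution
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
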