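---
title: "Domain-level orthology inference: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-level orthology inference: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domorth)
```

## The problem

Orthology is usually inferred between full-length protein sequences. But
proteins are mosaics of domains, and recombination — gene fusion, fission,
domain shuffling — lets individual domains follow different evolutionary
histories. A pair of genuinely orthologous domains can then sit inside
proteins whose overall architectures are so different that a full-length
method never pairs them: the orthologous region may cover less than half of
the longer protein and be discarded by coverage filters, or the similarity
signal may be diluted by unrelated flanking domains.

`domorth` inverts the unit of analysis. Proteomes of two species are cut
into *domain-equivalent sequences*, an InParanoid-style reciprocal-best-hit
clustering is run on the cuts, and the resulting ortholog groups of domains
are then (a) mined for *discordant domain orthology* — one protein whose
domains are orthologous to different partner proteins — and (b) projected
back onto proteins through the *alpha* statistic.

## Domain-equivalent sequences

Three kinds of cuts are produced per protein, from externally supplied
Pfam-style annotations (`read_pfamscan()`; envelope coordinates define the
extent — the standard Pfam notion of the domain region):

* **Domain cuts** — one per kept annotation. Annotations typed `Repeat` are
  excluded first: repeat arrays produce many near-identical sequences whose
  cross-matches swamp reciprocal-best-hit logic. Then overlaps are
  resolved: if two annotations overlap by more than
  `overlap_discard_fraction` (default 0.5) of the *shorter* one, the
  shorter is discarded. Resolution runs in order of decreasing length
  (ties: smaller start coordinate), so the longest annotation always
  survives and the outcome is independent of input order. Overlaps at or
  below the fraction are tolerated, so kept cuts may still overlap
  moderately — that is intentional, and mirrors how nested or shifted Pfam
  envelopes are treated in practice.
* **Unknown regions** — every maximal unannotated region, terminal regions
  included, strictly longer than `min_unknown_len` (default 30 residues)
  becomes a cut labelled `UNK1`, `UNK2`, ... N→C. Shorter regions are
  regarded as linkers or termini and dropped. The boundary is strict: a
  30-residue gap emits nothing, a 31-residue gap is kept. Terminal regions
  are included because an unassigned terminus longer than the threshold is
  just as likely to harbour an undetected domain as an interdomain region.
* **Orphans** — a protein with no kept annotation enters whole, as a single
  full-length cut. Nothing about a missing Pfam hit implies the protein has
  no orthologs.

## Similarity and filtering

Cuts are compared all-vs-all across species (and within each species, to
score candidate inparalogs) by Smith–Waterman local alignment under
BLOSUM62 with affine gaps (open 11, extend 1), the BLASTP defaults. Raw
scores are converted to bits with the gapped Karlin–Altschul constants
λ = 0.267, K = 0.041 for this scheme:
bits = (λ·S − ln K)/ln 2. Precomputed BLAST tabular hits
(`-outfmt 6`) can be supplied instead; both routes produce identically
structured hit tables and flow through the same filters. The built-in
scorer performs no low-complexity (SEG) masking; when fidelity to BLAST
matters — compositionally biased proteomes in particular — import BLAST
output.

Hits are kept when three conditions hold (`apply_hit_filters()`):
bitscore ≥ 40 bits; the union of matched segments covers ≥ 50% of the
longer sequence; and the summed aligned span is ≥ 50% of the longer
sequence. The two coverage measures coincide for single-segment hits and
differ only for multi-HSP BLAST imports (summed span counts overlapping
segments twice, capped at 1). For multi-HSP pairs the pair bitscore is the
maximum over HSPs — the conservative reading when no score-summing
convention is given. Setting both coverage cutoffs to 0 reduces filtering
to the bitscore alone, which is the configuration to use when hunting
domain matches inside much longer partners.

## Clustering: seeds, inparalogs, conflicts

* **Seeds** (`find_seed_orthologs()`): a cross-species pair is a seed
  ortholog iff each member is the other's best-scoring partner (reciprocal
  best hit). Scores are symmetrised over orientation by taking the maximum;
  best-partner ties break towards the lexicographically smallest id, so
  results are deterministic.
* **Inparalog recruitment** (`recruit_inparalogs()`): a within-species
  sequence joins a seed's group iff its bitscore with the same-species seed
  member *does not fall below* the seed pair's score — an inclusive
  boundary, so a score exactly equal to the seed score recruits. Higher
  bitscore proxies shorter evolutionary distance: such sequences duplicated
  after the speciation and are co-orthologous to the partner.
* **Conflict resolution** (`resolve_group_conflicts()`): recruitment can
  place one sequence in several groups. Groups are ranked by decreasing
  seed score (ties: lexicographically smaller seed pair); in rank order
  each group keeps the members not yet claimed by a surviving stronger
  group; a group left without both species is deleted *before* claiming,
  releasing its members to weaker groups. This is a deliberate
  simplification of InParanoid 4.1's multi-rule overlap merging (which
  involves bootstrap values and group-fusion heuristics); it implements
  exactly the keep-the-stronger-seed principle and nothing more. The whole
  seeds → recruitment → resolution path is verified against an
  independently written brute-force implementation on hundreds of random
  score matrices in the test suite.

## Protein-level projection: alpha

For a cross-species protein pair sharing at least one ortholog group, alpha
is the fraction of the pair's domain-equivalent instances that are
orthologous between the two proteins: an instance counts as *shared* when
its group also contains an instance from the partner protein; the
denominator counts **every** instance on both proteins — UNK regions and
orphans included, grouped or not. A three-domain protein X {A, B, C} and a
two-domain partner Y {A, C} with the A and C instances co-grouped share
4 of their 5 instances, alpha = 4/5:

```{r alpha}
dm <- data.frame(id = c("X/A", "X/B", "X/C", "Y/A", "Y/C"),
                 protein_id = c("X", "X", "X", "Y", "Y"),
                 species = c("hs", "hs", "hs", "ec", "ec"))
gr <- data.frame(group_id = c(1L, 1L, 2L, 2L), seed_score = 100,
                 member_id = c("X/A", "Y/A", "X/C", "Y/C"),
                 species = c("hs", "ec", "hs", "ec"),
                 score_to_seed = 100, is_seed = TRUE)
compute_alpha("X", "Y", dm, gr)
```

Pairs with alpha at or above `alpha_threshold` are called orthologous. The
default 0.3 maximises consensus with full-length InParanoid-style calls
while keeping conflicts minimal; `alpha_sweep()` reproduces that
calibration machinery for any dataset (eleven thresholds 0.0–1.0 by
default, with the Jaccard index of the two pair sets per row). When
domain-based pairs *enrich* a full-length set (`merge_with_fulllength()`),
a stricter 0.4 default applies (`alpha_threshold_merge`): enrichment should
only add well-supported pairs. On merge conflicts — both proteins assigned
by the full-length method, but never to a common group — the full-length
call wins, as full-length inferences are the benchmark-validated reference.

## Discordant domain orthology

`find_discordant()` reports every *primary* protein whose domains are
orthologous to domains on more than one partner protein, with the subset of
primary domains each partner matches. The default (`strict`) flag requires
at least two partners with *mutually exclusive* (disjoint) subsets — the
conservative definition, the fingerprint of fusion/fission. A `weak` mode
flags any two partners with merely *different* subsets; it is exposed
because the looser reading is also defensible, but it admits
nested-architecture cases that are better explained by annotation
granularity than by recombination. The flag depends only on the bipartite
domain-orthology structure, not on group labels.

## The synthetic benchmark

`synthesize_proteomes()` generates two proteomes with known history so
every stage is testable without external data:

* An alphabet of `n_ancestral_domains` families (default 20; lengths
  60–120 residues, uniform residue composition) and `n_proteins` ancestral
  proteins (default 30), each an architecture of 1–3 distinct families
  joined by linkers of 15–60 residues — deliberately straddling the
  30-residue UNK threshold so both emitted and discarded unannotated
  regions are exercised.
* Each drawn instance is mutated away from its family consensus by
  `paralog_divergence` (default 0.3). This models ancestral paralog
  divergence: with a 20-family alphabet re-used across 30 proteins,
  same-family instances on different proteins would otherwise be identical
  strings and reciprocal-best-hit seeding would be ill-posed at low
  divergence. 0.3 keeps paralogs clearly separable from vertical copies
  (which differ by at most twice `substitution_rate`) while remaining
  alignable.
* Per protein, at most one architecture event with probabilities
  `p_fusion`, `p_fission`, `p_duplication`, `p_loss` (defaults 0.05 each —
  a minority of proteins, as in real proteome pairs): fusion concatenates
  two ancestral architectures in species A only; fission splits a
  multi-domain architecture in species A; duplication creates two species-B
  inparalogs; loss drops one domain from the species-A copy. Then every
  residue mutates independently along each lineage at `substitution_rate`
  (substitutions only, no indels, so annotation coordinates stay exact;
  indels are a documented extension).
* Ground truth records all cross-species placements of each ancestral
  domain instance (as extraction-scheme cut ids), all protein pairs sharing
  an ancestral protein, and the discordant primaries created by
  construction (fused A proteins; intact B partners of fissioned
  ancestors). Truth covers annotated domain instances only: linker-derived
  UNK regions also descend from common ancestors, but 31–60-residue
  fast-evolving linkers are not reliably identifiable targets, so recovery
  is scored on the annotated universe (inferred pairs are filtered to
  annotated cuts before comparison, keeping precision and recall on the
  same footing).

What the generator does *not* emulate: repeat arrays, nested/overlapping
annotations, low-complexity sequence, indels, biased residue composition,
and more than two species. Passing the recovery tests therefore shows the
machinery is correct under the stated model, not that real-proteome
annotation noise is handled gracefully — the repeat and overlap filters are
exercised by dedicated unit fixtures instead.

Test and acceptance runs use the default problem size (20 families, 30
proteins per species, ~110 domain-equivalent cuts per species), which keeps
a full pipeline run around half a minute; unit-level end-to-end tests use
an 8-protein scenario.

## Numerical and degenerate-input choices

* All external coordinates are 1-based inclusive (PfamScan/BLAST
  convention); internal interval arithmetic works on the same closed
  intervals throughout, so no conversion step exists to get wrong.
* Equal-length annotation overlap ties keep the earlier-starting one;
  best-hit and group-rank ties are lexicographic; every output table is
  sorted. Two runs on the same inputs are byte-identical.
* An empty annotation table makes every protein an orphan; a comment-only
  PfamScan file is valid and empty; two empty pair sets have no defined
  Jaccard index (error rather than a silent 0/0).
* The Jaccard of a non-empty against an empty set is 0; precision of an
  empty inferred set is defined as 1.
* Inference is fully deterministic; the only randomness in the package is
  the synthetic generator, driven by a single `rng_seed`.

## Scope and limitations

* Two species per run; multi-species analyses are outer loops.
* The clustering implements the published seed/inparalog rules plus the
  simplified conflict resolution above — no bootstrap confidence values,
  no InParanoid group-merging heuristics.
* Whole-proteome results for *H. sapiens* / *E. coli* and
  benchmarking-service metrics require the QfO 2018 reference proteomes,
  Pfam 32.0 annotations, BLAST 2.2.18 and an external evaluation service;
  they are out of scope here and not reproduced at package-test scale.
* The command-line tool (`inst/scripts/domorth`, or `domorth_main()` from
  R) exposes `run`, `extract` and `simulate`; stage-wise re-analysis uses
  the exported functions on the tables `run` materialises, rather than one
  subcommand per stage.
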