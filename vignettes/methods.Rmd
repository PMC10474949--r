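---
title: "Methods: coarse-grained RNA model assembly with SAXS restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained RNA model assembly with SAXS restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamason)
```

`rnamason` builds coarse-grained three-dimensional RNA models from a
sequence and a secondary structure, optionally restrained by a small-angle
X-ray scattering (SAXS) curve. This vignette documents the methods behind
each stage of the pipeline.

## Representation

Every residue is reduced to three pseudo-atoms: the phosphate `P`, the
ribose `C4'`, and the glycosidic nitrogen (`N9` for purines, `N1` for
pyrimidines). This is the smallest atom set that still fixes backbone
continuity, helix geometry, and base-pair registration, and it is what
fragment files, models, and all scoring terms operate on.

## Secondary structure and pseudoknot removal

`parse_dotbracket()` accepts the bracket families `()`, `[]`, `{}`, `<>`
and `Aa`–`Dd`, so pseudoknotted inputs are written naturally with several
families. All matched pairs enter a single pool; any pair must span at
least two unpaired positions (`j - i >= 3`).

`remove_pseudoknots()` splits the pool into a maximum-cardinality
crossing-free (nested) set and the remaining pseudoknot pairs, using an
exact interval dynamic program. Among equally large solutions, the
solution whose lexicographically smallest removed pair is largest is
selected, which makes the result deterministic without a random seed.
Each removed pair is not discarded: it becomes a flat-bottom
tertiary-contact restraint on the glycosidic-nitrogen distance (target
9 Å by default), so the pseudoknot still shapes the tertiary fold during
refinement. The test suite verifies optimality against exhaustive
enumeration of every pairing of length up to 12 (over 37,000 structures).

```{r pk-example}
res <- remove_pseudoknots(parse_dotbracket("GGGAAAACCCUUUCCC",
                                           "(((..[[.)))..]]."))
res$ss$nested
res$restraints
```

## Motif graph

`decompose_motifs()` compiles the nested structure into a tree of motifs:
maximal helices become *stem* nodes; loop regions become *hairpin*,
*internal loop*, or *junction* nodes that include their closing-pair
nucleotides; unpaired 5'/3' tails become *single strand* nodes. Edges
record the closing pair shared by two adjacent motifs, so the graph is a
tree and neighboring motifs overlap in exactly one pair of residues.

## Fragment library

Fragments are keyed by a topology signature (`stem:4`,
`hairpin:6`, `internal:2-3`, `junction:3:2-2-2`, `ss:5`, ...). The bundled
generator produces idealized coarse-grained fragments procedurally:
A-form-like helices for stems, and loops laid out on the circle that
closes the cycle formed by their closing-pair chords (10.3 Å across a
pair) and single-residue steps (5.9 Å), with optional Gaussian jitter.

`match_fragments()` finds candidates for a motif node by exact signature
lookup, then widens the pool when needed: circular permutations of
junction and internal-loop fragments (re-rooting the cycle at another
closing pair), growth of smaller loops by geometric interpolation of
inserted residues, and coarse-grained mutation to the node's target
sequence (re-deriving the glycosidic-nitrogen position from the base
class). Libraries round-trip to disk as one PDB file per fragment plus a
TSV index.

## Starting-model assembly

`assemble_starting_model()` performs a deterministic leaf-first beam
search. Nodes are placed in increasing order of candidate count (rarest
leaf first, then outward along the tree); each candidate placement is
anchored by least-squares superposition onto the closing pair shared with
the already-placed neighbor, and rejected when the anchor deviates beyond
a tolerance. Partial assemblies are ranked by accumulated clash count
(glycosidic nitrogens of non-adjacent, non-paired residues closer than
6 Å, counted with a spatial grid), with the anchored-superposition RMSD
as tie-break, and only the best `beam_width` assemblies survive each
step.

## Scoring

The total score is

    S = E_potential + 10 * E_restraint + 5 * n_clash

* `E_potential` — a knowledge-based distance potential derived from the
  fragment library itself: distances between the six unordered
  pseudo-atom type pairs, in 0.5 Å bins up to 20 Å, scored as
  `-ln((obs + 1) / (ref + 1))` against a uniform-in-the-sphere reference
  and clamped to ±5.
* `E_restraint` — flat-bottom harmonic terms
  `w * max(0, |d - target| - width)^2` on glycosidic-nitrogen distances,
  fed by removed pseudoknots and by user restraint files.
* `n_clash` — the grid-counted clash number.

When an experimental curve is supplied, the model curve is computed with
the Debye formula over `C4'` beads carrying Gaussian form factors
(`f(q) = F0 exp(-q^2 r^2 / 2)`, bead width `r = 2.5` Å, `F0` 165 for
purines and 140 for pyrimidines), evaluated on a 256-point grid and
interpolated onto the experimental grid. The goodness of fit is the
reduced `chi^2` with the analytically optimal scale factor. The fit is
folded into the score through a two-Gaussian correction factor

```{r factor}
saxs_correction_factor(1)
```

which is maximal at `chi^2 = 1`: negative (favorable) scores are
multiplied by the factor and positive scores are divided by a capped
version of it, so improving the SAXS fit always improves the total.

## Refinement

`run_refinement()` runs replica-exchange Monte Carlo over the *discrete*
space of fragment choices. A move re-picks the fragment of one motif node
and rebuilds the model deterministically, so whole subtrees move rigidly
while the secondary structure is preserved by construction at every step.
Replicas follow a geometric temperature ladder (default 8 replicas, 0.5
to 16); nearest-neighbor swaps with the standard exchange probability are
attempted every 50 steps, alternating even and odd pairs. Each replica
consumes an independent, reproducible random stream derived from the
master seed. The best model ever visited is returned with its score
recomputed from scratch, together with a trace table and acceptance
statistics.

The test suite validates the sampler itself: on a fully enumerable toy
landscape the per-temperature state occupancies match the Boltzmann
distribution within three standard errors over 100,000 steps, and the
global optimum of an exhaustively enumerated 64-combination system is
found reliably across seeds.

## Model annotation and I/O

`annotate_secondary_structure()` recovers canonical pairs from
coordinates alone: candidate residues must form a Watson–Crick or GU
combination with a glycosidic-nitrogen distance in [7.5, 10.5] Å and a
`C4'`–`C4'` distance in [9.0, 11.5] Å; candidates are accepted greedily,
preferring pairs supported by helix neighbors and closest to the ideal
8.9 Å nitrogen separation. `pair_recovery()` quantifies agreement with a
reference structure.

Models read and write PDB and mmCIF (`read_model()`, `write_model()`);
on output, the B-factor column flags residues involved in clashes so
problem regions are easy to color in a viewer. SAXS curves and restraint
files are plain whitespace-delimited text.

## A complete run

```{r pipeline, eval = FALSE}
lib_dir <- tempfile("lib")
out_dir <- tempfile("run")
write_fragment_library(
  generate_synthetic_library(c("stem:4" = 10, "hairpin:4" = 10), seed = 1),
  lib_dir)
seq_file <- tempfile(fileext = ".seq"); writeLines("GGGGAAAACCCC", seq_file)
ss_file <- tempfile(fileext = ".ss"); writeLines("((((....))))", ss_file)
cfg <- run_config("build", seq = seq_file, ss = ss_file, library = lib_dir,
                  out = out_dir, seed = 7, n_steps = 500)
run_pipeline(cfg)
```

The output directory then holds `model.pdb`, the refinement `trace.tsv`,
the annotated secondary structure, `score.json`, `run.log`, and a
`manifest.json` recording the configuration, seed, package and R
versions, and MD5 checksums of all inputs. The same pipeline is exposed
on the command line through `exec/rnamason` (`build`, `refine`, `score`,
`simulate-saxs`, `make-library`).
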