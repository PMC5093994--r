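---
title: "Predicting plant resistance gene analogs from domain architecture"
author: "rgascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plant resistance gene analogs from domain architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgascan)
```

## The problem

Plant immunity rests on two receptor layers: cell-surface
pattern-recognition receptors — receptor-like kinases (RLK: ectodomain +
transmembrane helix + intracellular kinase) and receptor-like proteins
(RLP: the same without the kinase) — and intracellular effector receptors,
most of them NBS-LRR proteins built from an N-terminal TIR or coiled-coil
(CC) module, a central NB-ARC nucleotide-binding domain and C-terminal
leucine-rich repeats. Because these architectures are strongly conserved,
*resistance gene analogs* (RGAs) can be predicted from protein sequence
alone: detect the seven relevant domains and motifs — NB-ARC, TIR, CC,
LRR, LysM, serine/threonine-tyrosine kinase and transmembrane (TM)
helices — and read the class off the domain composition.

rgascan implements this as a pipeline over the *output formats* of the
standard detectors (BLASTP tabular, InterProScan TSV, pfam_scan, Phobius,
and a coiled-coil segment table), so predictions are reproducible offline
from saved detector runs, and the whole pipeline can be validated against
synthetic proteomes with planted, known architectures.

## Pipeline stages

1. **Prefilter.** RGAs are a small fraction of a proteome. Queries are
   aligned against a curated resistance-protein reference set by BLASTP
   and only queries with at least one hit at `evalue <= cutoff` (default
   `1e-5`, adjustable per species) continue. The comparison is inclusive
   and any hit qualifies — the filter operates on proteins, not
   alignments. Retention is monotone in the cutoff by construction.
2. **Reference curation.** `curate_reference()` builds the reference set
   the prefilter uses: case-insensitive substring matching retains records
   whose description carries at least one include keyword (default
   `resistance`, `disease`) and no exclude keyword (default the abiotic
   false friends: aluminum/aluminium, drought, cold, DNA-damage,
   herbicide, UVB); unannotated records are dropped and exact duplicate
   sequences collapse to the first-seen record. The operation is
   idempotent, so re-curating a curated set is a no-op.
3. **Evidence.** Each detector's dialect parses into one unified hit
   model (protein, canonical motif, source, signature, 1-based inclusive
   coordinates, score). A configurable signature map translates raw
   accessions to the canonical motif vocabulary; unknown signatures become
   `UNMAPPED` and never abort a run. Phobius signal peptides are parsed
   and reported but never used for classification.
4. **Mode filter.** `quick` mode consults Pfam and Gene3D through
   InterProScan; `deep` adds SMART and Superfamily; `free` is any
   user-chosen source set. The dedicated channels — pfam_scan (NB-ARC),
   Phobius (TM), coils (CC) — always pass in quick and deep, since they
   sit outside the InterProScan database choice. The practical difference
   between quick and deep is mostly LRR sensitivity: an LRR detected only
   by Superfamily or SMART upgrades an NBS call to NL under deep.
5. **Classification.** See below.
6. **Outputs.** Plain-text exports: the candidate table, per-family id
   lists and FASTA subsets, the unified domain table, a summary, and —
   when a GFF3/GTF is supplied — a binned per-chromosome distribution
   table of RGA families.

## The decision tree

Presence flags (never counts or coordinates) feed an ordered rule list;
the first match wins, which makes the classifier total and tie-free over
all 128 flag combinations:

| # | condition | class |
|---|-----------|-------|
| 1 | TIR ∧ CC | OTHER |
| 2 | TIR ∧ NB ∧ LRR | TNL |
| 3 | TIR ∧ NB | TN |
| 4 | TIR | TX |
| 5 | NB ∧ CC ∧ LRR | CNL |
| 6 | NB ∧ CC | CN |
| 7 | NB ∧ LRR | NL |
| 8 | NB | NBS |
| 9 | TM ∧ kinase ∧ (LRR ∨ LysM) | RLK |
| 10 | TM ∧ (LRR ∨ LysM) | RLP |
| 11 | TM ∧ CC | TM-CC |
| 12 | — | non-RGA |

Design choices where the architecture grammar is genuinely open:

* **TIR + CC is OTHER regardless of NB-ARC.** The combination is a
  chimeric architecture worth manual review, and conditioning on NB-ARC
  would leave holes in the tree. OTHER proteins should be inspected via
  the exported domain table.
* **TX is TIR without NB and without CC, whatever else is present** — any
  non-CC companion counts as the "unknown" part.
* **RLK requires an ectodomain** (LRR or LysM) on top of TM + kinase,
  mirroring the canonical receptor-kinase architecture (extracellular
  sensor, membrane anchor, intracellular kinase). This is stricter than
  some genome annotations; `strict_rlk = FALSE` relaxes it to TM + kinase.
* **TM-CC is the residual membrane class**: rule order means it never has
  a kinase-plus-ectodomain or a bare ectodomain.
* The NBS branch precedes the membrane branch, so NB-ARC or TIR always
  wins over TM — a TNL with a spurious TM helix stays a TNL.
* Proteins with only an LRR (no NB, TIR or TM) are non-RGA.

The test suite checks the tree against an independently hand-coded nested
evaluator on all 128 combinations.

## Coiled-coil detection

CC has no HMM in the evidence stack; it is detected by heptad
periodicity. For every window placement and each of the 7 heptad frames,
the window score is the weighted geometric mean of per-residue,
per-position propensities; a residue's score is its best covering window;
a two-Gaussian likelihood ratio (coiled-coil vs globular score models)
converts scores to probabilities; maximal runs with `P >= 0.9` and length
`>= 7` (one heptad) become CC segments. Defaults: window 21 residues
(three heptads, the conventional choice), threshold 0.9 (community
convention for calling a coil), minimum segment one heptad; all exposed
in `coils_params()`.

The shipped propensity table is **synthetic** — constructed from heptad
biology (hydrophobic L/M/I/V favoured at core positions a/d,
charged/polar E/Q/K/R at exposed positions, proline penalized
everywhere), not a published matrix — and the default Gaussians are
calibrated to it (ideal heptads score near the coil mean of 2.4, random
sequence near the globular mean of 0.8). Correctness never rests on these
constants: every numerical test uses small toy tables and an exhaustive
window-by-frame enumeration oracle (agreement to 1e-9), plus invariance
properties (threshold monotonicity; exact coordinate shifts under
anti-coil prefixes). Residue `X` is neutral (propensity 1); other
ambiguity codes are rejected with the offending position named.

## Numerical and format conventions

* Coordinates are 1-based inclusive on the protein everywhere, matching
  InterProScan/pfam_scan output.
* pfam_scan accession version suffixes (`PF00931.23`) are stripped before
  signature-map lookup, for Pfam-release independence.
* Duplicate hits (same protein, motif, source, start, end) collapse to
  one; overlapping hits of the same motif are *not* merged — presence is
  all the classifier needs, and raw spans are what the domain table
  reports.
* Hits extending past a known protein length are kept but flagged
  (`clamped`), with a warning.
* Both Phobius dialects (short one-line table and long `FT` feature
  blocks) are auto-detected, since detector archives come in either.
* Proteins map to genes by stripping one trailing `.n`/`-n` transcript
  suffix (configurable function); when transcripts of one gene disagree,
  the gene takes the class that fires earliest in the tree. Distribution
  bins are half-open `[i·bin, (i+1)·bin)` over the gene start coordinate,
  default 1 Mb.
* Chunked execution (`workers`) is a deterministic contiguous partition
  whose results are merged in input order, so outputs are byte-identical
  for any worker count; concurrency is an implementation detail the
  contract deliberately excludes.
* Malformed detector rows follow a strict/skip policy: strict (default)
  stops with the line number, skip drops the row with a warning.

## The synthetic-data generator

`generate_synthetic_set()` plants, per class, an archetypal layout — CC
near the N-terminus, TIR then a central NB-ARC, C-terminal LRRs; for
membrane classes an N-terminal ectodomain (alternating LRR and LysM), a
TM anchor and, for RLK, an intracellular kinase. Protein lengths are
drawn from 150–1500 residues (raised to each class's minimum layout
span), classes are allocated by deterministic largest-remainder from the
requested mix, and genes are tiled over three synthetic chromosomes.
Planted CC regions are written as ideal heptad repeats so the built-in
scorer — not only the emitted segment table — can find them; planted TM
regions are hydrophobic stretches. Every architecture is verified at
generation time to classify to its planted class, and output is
byte-reproducible under a fixed seed.

`emit_detector_outputs()` writes matched evidence in every dialect,
routed through the channel each detector owns (NB-ARC via pfam_scan, TM
via Phobius, CC via the segment table, LRR/LysM/kinase/TIR via
InterProScan), plus a BLAST table in which every planted RGA has a
1e-50 hit and planted non-RGAs alternate between no hit and a weak 1e-3
hit — both far from the 1e-5 boundary, which is exercised separately in
the prefilter unit tests. Setting `lrr_source = "Superfamily"` plants the
quick/deep divergence on demand.

What the fixtures do *not* emulate: realistic sequence evolution, Pfam
score distributions, overlapping or fragmented domains, detector
disagreement, or annotation errors. Passing the end-to-end recovery tests
therefore demonstrates that the plumbing — parsing, integration, mode
logic, classification, exports — is faithful, not that any upstream
detector is accurate on real proteomes.

## Validation sizes

The shipped validation uses desk-scale problems: the full 128-row
classifier truth table; a 500-protein uniform-mix proteome for end-to-end
recovery and worker-count invariance (k = 1, 2, 8); 50 random sequences
of length ≤ 50 against the exhaustive coiled-coil oracle; 20-record
curation sets; and 60-protein runs for mode divergence and distribution
histograms.

## Worked example

```{r example, eval = FALSE}
root <- tempfile()
tr <- generate_synthetic_set(60, seed = 7, out_dir = root)
emit_detector_outputs(tr, file.path(root, "ev"))
res <- run_pipeline(pipeline_config(
  file.path(root, "proteins.fasta"),
  gff = file.path(root, "genes.gff3"),
  evidence_dir = file.path(root, "ev"),
  output_dir = file.path(root, "out")))
res$summary
```

## Known limitations

* The classifier sees presence only; split NB-ARC domains, tandem
  chimeras beyond TIR+CC, and degenerate motifs are outside its grammar.
* The shipped coiled-coil constants are synthetic stand-ins; for
  production use on real proteomes, supply segments from a dedicated
  coiled-coil scanner via the segment table, or fit propensities and
  Gaussians to curated data.
* The reference-curation keywords operate on description lines as given;
  retrieval conventions of the source databases are the user's concern.
* External detectors are consumed via their output files (or optional
  command-template adapters); the package never validates their internal
  settings.
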