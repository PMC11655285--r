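---
title: "Building non-redundant collections of paired antibody variable regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building non-redundant collections of paired antibody variable regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abforge)
```

## The problem

Public antibody (immunoglobulin) sequence resources overlap heavily and
disagree in detail. The same antibody is deposited under different
identifiers, chains are annotated with free-text headers of uneven quality,
light and heavy labels are occasionally exchanged, sequences are reported
with or without leader peptides and constant-region fragments, and the same
chain may appear under several species entries. Assembling a single
collection of *unique* paired light/heavy variable regions — the input that
machine-learning models and repertoire analyses need — therefore requires a
disciplined pipeline rather than a concatenation of downloads.

`abforge` implements such a pipeline for protein FASTA inputs. Each source
contributes records carrying a metadata header
(`GROUPID_MEMBER|description|Species (taxid)`, with a free-text fallback),
and the pipeline turns them into a deduplicated, standardized, provenance-
tracked collection with stable content-derived identifiers.

## Pipeline stages and their assumptions

### Ingest: classification, grouping, containment pruning

Records are classified from their header description with keyword lists:
light keywords (`light`, `kappa`, `lambda`), heavy keywords (`heavy`,
`alpha`, `gamma`, `delta`, `epsilon`, `mu` — the five isotype class names),
and irrelevant keywords (antigens, co-crystallized proteins, ...) which
take precedence and discard a record outright. Matching is case-insensitive
on **whole words**: `"prothrombin"` does not match `thrombin`, and
`"lightning"` is not a light chain. A raw-substring mode
(`substring_match = TRUE`) is available for sources known to concatenate
tokens. Species filtering accepts a keyword match in the species field or
the raw header, or an exact taxon-id match.

Within a group (records sharing a group id, e.g. one PDB entry), a sequence
fully contained in a larger sequence of the *same* chain class is discarded
(the smallest loses; exact duplicates keep the first). Containment pruning
is deliberately restricted to one class: a short light chain can be
contained in a long heavy chain by chance, and cross-class pruning would
delete valid chains.

### Pairing: a four-strategy cascade

Within each group, light and heavy chains are paired by the first strategy
able to resolve them:

1. **S1 — header containment.** Descriptions are normalized (lowercased,
   chain keywords and keyword-only parentheses removed, whitespace
   collapsed); a light and a heavy member pair when one normalized
   description contains the other. Ties are matched greedily in input
   order; the order is logged so it can be audited.
2. **S2 — two-member groups.** Fires only when the S1 leftover has exactly
   two members, one light and one heavy.
3. **S3 — sequence evidence.** Two members pair when their sequences are
   equal to, contained in, or containing the two chains of a previously
   paired antibody from a reference set. Header classes are bypassed: the
   member matching the reference light gets the light slot, which rescues
   records whose headers are mislabeled. The reference set is static during
   a run — pairs produced mid-run are not appended — so results cannot
   depend on input order.
4. **S4 — curated decisions.** A decisions table (group, light member,
   heavy member, `pair`/`skip`) resolves what no automatic strategy could.
   The pipeline never guesses: groups without a decision are reported as
   unresolved, and odd leftover members (e.g. a constant-domain fragment in
   a three-member group) are reported rather than silently dropped.

Each member joins at most one pair, and the strategy attributed to a group
is the lowest-numbered one that resolved it.

### Standardization: swap correction, trimming, length bounds

Variable regions are delimited by configurable start and end motif lists
per chain class. Three operations run in order:

* **Label-swap correction** exchanges the slots of a pair only on
  *both-sided* evidence: the light slot contains heavy start motifs and no
  light start motif, and vice versa for the heavy slot. One-sided evidence
  only warns — a single spurious motif should never flip a pair.
* **Trimming** keeps, among all substrings that begin at a start-motif
  occurrence and end at the final residue of an end-motif occurrence, the
  longest one (leftmost start on ties). Chains with no motif-bounded region
  are discarded — this removes records that are not antibody chains at all.
* **The length filter** keeps a pair only if both trimmed chains are within
  80–150 amino acids (inclusive at both ends; chains of 79 or 151 residues
  are discarded). Typical light variable domains are ~107–110 aa and heavy
  ones ~115–125 aa, so these defaults retain complete Fv domains while
  rejecting fragments and unsplit multi-domain sequences.

The shipped motif lists are **illustrative, not a published reference
set**: a few common germline V starts (`EVQL`, `QVQL`, `QVHL`, `QMQL`,
`DIQM`, `EIVL`, `QSVL`, `DIVM`) and J-region ends (`VTVSS`, `VTVVS`,
`VTVF`, `VTV`; `VEIK`, `VELK`, `VLG`, `LEIK`). Production use should
supply curated lists via `read_pattern_set()`. The end list deliberately
includes `VTV`, the common stem of the `VTVSS`/`VTVVS`/`VTVF` J-end
variants, so that chains merged across such variants still end at a known
motif (see below).

### Merging: containment, terminal divergence, ambiguity, cross-species

Merging pools all standardized per-source pairs and runs, per species:

1. **Containment fixed point.** Two pairs merge when on *both* sides the
   sequences are equal or one contains the other; the longer sequence wins
   per side, headers are concatenated with the `|||` separator and each
   entry carries its `;SOURCE` tag, and source sets are unioned. Passes
   repeat until no merge fires, which makes the retained sequence *set*
   independent of input order.
2. **Terminal-divergence resolution.** Pairs that still share a chain are
   grouped into connected components. For each component the longest common
   substring (LCS) of each side's variants is computed; the merge succeeds
   only if every variant is `prefix + LCS + suffix` with both flanks at
   most `max_trim = 10` residues — i.e. the divergence is strictly
   terminal, as with alternative J-segment ends. The cap prevents nonsense
   merges of barely-related chains whose LCS happens to be anchored. A
   merged chain must then **re-pass standardization** (trimming and length
   bounds); failures are demoted to ambiguity clusters, never silently
   kept.
3. **Ambiguity clusters.** Components that cannot be resolved — e.g. two
   heavies differing by an interior deletion while sharing a light, or
   chains of identical-chain pairs linked transitively — are excluded from
   the collection and reported as clusters. Sharing is exact sequence
   equality on any side, plus same-side containment that failed to merge;
   this is the most conservative reading that still excludes
   interior-divergent duos.
4. **Cross-species duplicates.** A chain sequence occurring in two species
   (humanized antibodies, chimeras, mis-annotated entries) cannot be
   attributed; every antibody containing it is removed in every species.

The merge report balances exactly:
`input = retained + collapsed + ambiguous + cross-species removed`, and
this identity is asserted at run time.

### Identifiers and storage

Every final record gets a SHA-256 identifier of
`species + "|" + light + "|" + heavy` (UTF-8, uppercase sequences). The
separator is a deliberate safety choice — bare concatenation cannot
distinguish `("AB", "C")` from `("A", "BC")` — and
`legacy_concat = TRUE` reproduces separator-free hashing for compatibility.
Collections are sorted by id for diff-stable output and exported as JSON
Lines and as paired FASTA (two files, index-synchronized, id as first
header token on both sides).

### V-segment annotation

`assign_v_gene()` is a generic best-hit scorer: each chain is aligned
locally (Smith–Waterman, BLOSUM62, gap open 11 / extend 1) against a
user-supplied germline V reference, and the best-scoring gene (ties broken
by lexicographically smallest name, so reference order never matters) is
attached to the record. It is *not* a framework-aware annotator; best-hit
output from an external annotation tool can be imported instead with
`read_v_assignments()`. `tally_cluster_frequencies()` bins assignments
into the seven phylogenetic IGHV families (plus `other`) for repertoire
composition profiles.

## The synthetic fixture generator

`generate_fixture()` produces a complete multi-source test collection with
machine-readable ground truth, so the whole pipeline is testable without
any download. It emulates: cross-source duplication (identical and
contained copies), within-group contained duplicates, terminal-divergence
families (heavy variants ending `VTVSS`/`VTVVS`/`VTVF`, mirroring
J-segment end variation), interior-deletion duos (unresolvable, must
cluster), chained ambiguous triples (L1/H1, L1/H2, L3/H2), swapped chain
labels, irrelevant contaminant records, out-of-bounds chains, and
header styles resolvable only by each pairing strategy.

Design choices worth knowing:

* Chains are built as *start motif + random core + end motif* with totals
  drawn from 93–133 aa. Cores are drawn uniformly from the 17 residues
  that occur in **no** default motif (V, Q and L are excluded), so random
  cores can never create spurious motif occurrences and every planted
  boundary, swap evidence and trimming outcome is exact by construction.
  This also means the generator makes no attempt at realistic germline
  residue statistics — the pipeline under test is sequence-content-
  agnostic except for motifs and lengths, so passing tests demonstrate the
  bookkeeping and merge semantics, not performance on real repertoire
  data (real headers are messier, real motif lists are longer, and real
  chains can contain incidental motif occurrences).
* Each phenomenon draws from its own seeded stream derived from the master
  seed, so changing one count does not reshuffle unrelated records; output
  is byte-identical under a fixed seed.
* The spec-level fixture configuration carries per-strategy counts
  (`strategy_counts`) and an optional `cross_species_count`; groups not
  assigned to S2/S3/S4 are S1-styled.

`verify_against_truth()` compares a pipeline result with the planted truth:
retained pair set (species, chains, source sets), cluster membership,
planted discards with reasons, and per-strategy attribution.

## Numerical and degenerate-input choices

* Longest common substring: implemented by scanning substrings of the
  shortest variant from longest to shortest (leftmost on ties); the test
  suite checks it against exhaustive substring-set intersection.
* Trimming tie-break: leftmost start among equally long spans.
* `merge_two_pairs` on exact duplicates keeps the first pair's sequences
  and concatenates headers A-then-B.
* Empty inputs (empty FASTA, empty group, empty collection) return empty
  tables of the right shape; empty-sequence FASTA records are skipped with
  a warning, never silently.
* All randomness in the generator flows from one integer seed; the
  pipeline itself uses none.

## Problem sizes

The shipped tests run the full pipeline on fixtures of 5–200 antibodies
over 1–3 sources, with oracle cross-checks at 500 randomized LCS cases
(≤ 30 aa), 100 randomized clustering cases (≤ 50 pairs) and 20 randomized
V-assignment queries; these sizes exercise every code path while keeping
the suite fast enough to run on every change. The merge stage is
quadratic in the number of pooled pairs, which is adequate at curated-
database scale; very large repertoire sources would need a pre-bucketing
step (e.g. by exact sequence hash) before pairwise containment, which the
module boundaries leave room for.

## Known limitations

* Keyword classification is only as good as the configured lists; the
  defaults are minimal and meant to be extended per source.
* Trimming anchors on explicit motif lists, not on alignment or numbering
  schemes (Kabat/Chothia/IMGT numbering is out of scope), so chains whose
  variable region starts with an unlisted motif are discarded.
* The V-segment assigner is a best-hit scorer, not a recombination-aware
  annotator; D/J segments and CDR delimitation are out of scope.
* Cross-species removal uses exact chain equality; borderline containment
  across species is not treated as duplication.
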