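---
title: "Mining bacterial genomes for mazEF/pemIK-family toxin-antitoxin operons"
author: "taMiner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining bacterial genomes for mazEF/pemIK-family toxin-antitoxin operons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Type II toxin–antitoxin (TA) systems of the mazEF/pemIK family are
bicistronic bacterial operons: a labile antitoxin gene followed by a
stable endoribonuclease toxin gene, the two open reading frames
typically overlapping or separated by less than 100 bp. Because the
toxins are short (roughly 80–150 aa), the antitoxins shorter still
(50–100 aa), and both evolve quickly, no single homology search
reliably enumerates the family across a large set of assemblies.
taMiner implements a battery of five complementary strategies over a
self-contained alignment engine, filters every candidate by the operon
arrangement and by domain/length inclusion criteria, groups the
accepted loci into named homologue families, and summarises occurrence
and host associations. A simulator plants operons and decoys with
exact coordinates so that every stage can be validated against ground
truth without any external downloads.

## ORF calling

ORFs are found by a naive six-frame scan: a qualifying start codon
followed in-frame by a stop with no intervening stop. Seven start
codons are honoured (ATG plus the alternatives ATA, ATC, ATT, CTG,
GTG, TTG — config-removable), the minimal length is 100 nt measured
start **through stop codon inclusive** (so a 102-nt ORF with 33
residues passes and a 99-nt construct does not), and per (strand,
frame, stop) only the longest variant — the most upstream qualifying
start after the previous stop — is kept. Alternative initiators are
translated as Met (the table-11 initiation convention); internal
codons follow NCBI translation table 11. ORFs containing N are
skipped rather than ambiguously translated: shotgun contigs carry N
runs, and a partially defined protein would poison the downstream
similarity arithmetic. Circular topology is recorded but
origin-spanning ORFs are not searched; each contig is treated
independently, which is how fragmented shotgun assemblies must be
handled anyway.

## The alignment engine

All five strategies sit on one engine:

* `alignPair()` — exact Smith–Waterman local alignment under BLOSUM62
  with affine gaps (a gap of length $L$ costs $11 + L$, the BLAST
  defaults, config-overridable). Identity and similarity are fractions
  of aligned columns (BLAST "Identities"/"Positives" convention); gap
  columns count toward the alignment length only. The length ratio is
  subject protein length over query protein length — whole proteins,
  not aligned spans, which is why the admissible window is asymmetric
  (0.55–1.65).
* `estimateEvalue()` — the Karlin–Altschul form
  $E = K \, m \, n \, e^{-\lambda S}$ with the gapped BLOSUM62 (gap
  11/1) constants $\lambda = 0.267$, $K = 0.041$, matching the
  engine's actual scoring scheme. The distinction matters: with the
  ungapped constants a gapped chance alignment scoring in the low 40s
  reads as E ≈ 0.1 when its true expectation is above 1, and in an
  iterative cascade one such admitted chance hit can seed a
  self-reinforcing family of spurious queries. The cutoffs (0.1
  pairwise, 0.001 for profiles) remain permissive pre-filters ahead of
  the decisive similarity and arrangement criteria.
* `buildPssm()` / `searchPssm()` — position-specific score matrices
  anchored on a seed. Observed residue frequencies per position are
  smoothed with a background-proportional pseudocount of total mass 1
  (so the background's weight decays with alignment depth) and
  converted to half-bit log-odds against the Robinson–Robinson
  background; positions no hit covers fall back to the seed's BLOSUM62
  row, keeping all scores on the familiar matrix scale. Profile hits
  report `profile_coverage`, and their similarity/identity are
  **profile-anchored**: positive-scoring (or top-choice) profile
  positions divided by the profile length. A per-aligned-column
  convention would let a 15-column spurious local match report
  similarity 1.0 and sail past the review floor; anchoring on the
  profile makes short junk hits self-penalising while leaving genuine
  full-length homologues untouched.
* `clusterProteins()` — blastclust-style single linkage: two proteins
  are linked when aligned-column identity is at least 0.60 and the
  aligned span covers at least 0.55 of the **longer** sequence;
  clusters are connected components with deterministic ids.

## Arrangement and inclusion criteria

`isTaArrangement()` demands the same contig, co-orientation (the
default; relaxable by config since the requirement is implied rather
than stated for this family), the antitoxin upstream in coding
orientation, and an intergenic distance strictly below 100 nt, any
overlap permitted.

A pairwise hit is reportable only when its aligned span covers at
least the clustering coverage threshold (0.55) of the longer of query
and subject — the same coverage notion blastclust-style clustering
uses for membership. This is the mechanised form of reviewing a
borderline match by eye: a 20-odd-column local alignment of a
115-residue query can carry an honest E-value just under 0.1 and a
positives fraction above the review floor, yet no reviewer would call
it a homologue; and in an iterative cascade one such accepted chance
match becomes a query that validates itself at similarity 1.0 in the
next round. Genuine family alignments cover 0.9 or more, so the rule
costs no sensitivity.

`applyInclusionCriteria()` mechanises the acceptance decision:

1. **accepted_high_similarity** — both components align to their
   queries at similarity ≥ 0.80 with in-window length ratios. Both
   components, not one: a single high-similarity partner must not drag
   an arbitrary neighbour in (the undersized-antitoxin decoy exists
   precisely to catch that failure mode).
2. **accepted_by_criteria** — at least one component has supporting
   evidence (a sequence hit above the 0.50 review floor with an
   in-window ratio, or a domain-profile hit), *and* the toxin has a
   complete toxin-domain hit or a length within 80–150 aa, *and* the
   antitoxin has a complete antitoxin-domain hit or a length within
   50–100 aa. "Complete domain" means profile coverage ≥ 0.90.
3. otherwise **rejected**, with a reason retained for the
   `--review-report` dump (the mechanised counterpart of reviewing the
   0.50–0.80 band by hand).

One further rule resolves candidates into loci: a gene can belong to
at most one operon. Accepted candidates are ranked (high-similarity
decision first, then the number of evidenced components, then the
smallest absolute gap, then similarity) and resolved greedily so no
ORF is used twice. Six-frame ORF calling produces spurious ORFs
overlapping real operon junctions; without this rule such an ORF of
convenient length can ride in as a second "toxin" for an
already-paired antitoxin.

## The five strategies

* **cascade** — conservative iterative search: seed proteins query
  every strain's translated ORF set; accepted loci contribute their
  toxins and antitoxins as new queries; iterate until a round adds no
  locus. Termination is guaranteed because the query set grows
  monotonically inside the finite ORF universe. Rounds restrict the
  pairwise scan to subjects inside the length-ratio window — an
  optimisation that cannot change the result, because both acceptance
  routes require an in-window ratio.
* **extensive** — single pass at the E-value pre-filter, neighbour
  augmentation (a hit's arrangement-satisfying neighbours join the
  result list), blastclust-style clustering of the union, and a
  co-localisation report for every cluster pair that co-occurs in at
  least one strain. The co-localisation coefficient — strains with an
  adjacent member pair over strains with any member — is 1.0 for a
  family that always travels as an operon and decays as members occur
  solo.
* **psi** — per seed, iterative PSSM refinement (inclusion threshold
  E ≤ 0.002, at most 5 rounds, stopping when the inclusion set is
  stable), then extensive-style post-processing of the final profile
  hits.
* **rps** — every ORF scored against the bundled domain profiles at
  E ≤ 0.001; profile hits supply role assignment and complete-domain
  evidence. A toxin whose domain escapes the scan can still be
  recovered through a detectable-domain antitoxin next door.
* **delta** — seeds first query the profile database; matched profiles
  then search the ORFs, with extensive post-processing.

`strategyConcordance()` reports per-strategy totals, uniques,
intersection and union.

## Classification and statistics

`groupHomologues()` forms single-linkage components over pairwise
toxin similarity at the 0.80 grouping threshold and names groups in
descending strain-count order (a seed-name map preserves published
names). Grouping similarity is coverage-aware — positive-scoring
aligned columns over the longer toxin's length. For genuine homologues
the local alignment spans the proteins and the value coincides with
the per-column positives fraction; between unrelated toxins a short
high-scoring local match would otherwise read as "80% similar" and
single linkage would chain distinct families together. `summarizeOccurrence()` emits species/strain counts with
percentages rounded half-up to two decimals — the printed-table
convention, not R's round-half-even. Replicon calls are annotation
propagation only: the original "putatively plasmid" judgements came
from manual context reading, which is out of scope, so the operation
accepts external labels and otherwise reports `undetermined`.

`compareHostDistributions()` is the Pearson chi-square of carrier
counts against reference-proportional expectations with
expected-below-1 categories pooled. `subgroupEnrichment()` gives the
upper hypergeometric tail — `choose(m, k) / choose(n, k)` when all
carriers fall in the focal category — with a seeded permutation
cross-check that agrees within Monte-Carlo error. Host labels are used
verbatim; a synonym map is supported but no ontology mapping is
attempted.

## The simulator and what it does (and does not) emulate

`generateScenario()` produces a deterministic corpus from a seed:
i.i.d. background sequence at GC 0.33 (staphylococcal-like), planted
family operons, decoys, per-family domain-profile fixtures, and host
metadata with a configurable carrier–host association. Profile
fixtures are built from each family's alignment — near mutants of the
ancestor plus, for lineage families, the planted intermediates and
the family centre — so a profile spans its family's realised
diversity the way a curated domain model would.

A planted family is an ancestor pair (the search seeds), a family
*centre* derived from the ancestor at a controlled divergence
(optionally through several lineage steps, leaving stepping-stone
intermediates planted in early carrier strains), and members drawn
around the centre at 2% jitter. This structure lets the divergence
from the seed span 5–25% in the default scenario while within-family
pairwise similarity stays ≥ 0.95 and between-family similarity stays
below 0.78 — the regime in which homologue grouping at 0.80 must
recover the family labels exactly. Mutations substitute exactly
`round(d · L)` positions with BLOSUM62-biased replacements, so
realised identity is `1 − d` by construction.

Planted cassettes are guarded: a stop-in-every-frame block abuts each
antitoxin start, gaps of ≥ 3 nt end with an in-frame stop before the
toxin, and synonymous codon choices are rejection-sampled until no
qualifying start codon sits between the toxin start and the last
in-frame stop upstream — making both planted ORFs recoverable verbatim
under the longest-variant rule. Overlaps use the canonical −1 (TAA/ATG
fusion) and −4 (stop/start fusion) arrangements; arbitrary overlaps
would over-constrain the two reading frames once both proteins are
fixed. Each strain is verified after construction (exact ORF recovery;
no background ORF of partner-compatible length adjacent to a decoy)
and re-drawn deterministically if the check fails.

Decoy classes: orphan toxins, wide-gap pairs (150 nt), opposite-strand
pairs, domain-free oversized (195 aa) "toxins" beside genuine
antitoxins, and undersized (40 aa) partners beside review-band toxins.
Each class targets one clause of the acceptance logic.

The default scenario is 20 strains over 4 species, one 12-kb contig
each — deliberately desk-scale. What the simulator does **not**
emulate: real staphylococcal gene density and codon usage, repeats and
mobile elements, assembly fragmentation, and the 6,132-genome corpus
scale. Passing tests therefore demonstrate the correctness of the
procedure's logic and its selectivity against the planted confounders,
not field performance on real assemblies; corpus-scale counts such as
the published 73/83/101/110 cluster totals are inherently
irreproducible at this scale and are not asserted anywhere.

A dedicated rescue corpus (`rescueCorpus()`) plants one toxin whose
most conserved profile positions carry worst-scoring residues until
the direct profile E-value exceeds 0.001 — a domain invisible to the
direct scan — beside an intact-domain antitoxin. At that point the
toxin's pairwise similarity to the seed has fallen to roughly
0.35–0.45, below the review floor, so recovery genuinely depends on
the neighbour rule, which is exactly the behaviour the scenario
exists to exercise.

## Numerical choices and degenerate inputs

* Thresholds live in one validated S4 object (`pipelineConfig()`);
  every number above is a slot with these defaults.
* Similarity ties in candidate resolution break deterministically
  (decision rank, evidence count, |gap|, similarity, then locus id);
  cluster ids are the lexicographically smallest member; identical
  inputs give byte-identical reports.
* Empty inputs: empty genomes abort before stage 1; an empty profile
  database is a configuration error for rps/delta; a seed matching no
  profile yields an empty delta result with a warning; cascade on
  hit-free genomes converges in one round.
* All randomness flows from explicit seeds; the permutation test and
  the simulator restore the caller's RNG state.

## Problem sizes used by the validation suite

The bundled suite runs the default 20-strain corpus for recovery,
concordance and grouping; an 8-strain lineage corpus (5 steps at 22%
per step) for the high-divergence comparisons; a 7-strain corpus for
the rescue scenario; 500 random instances up to 60 aa for the
brute-force alignment oracles; and 10^5 permutation draws for the
enrichment cross-check. These sizes were chosen so the full suite
exercises every code path in a few minutes on a laptop while leaving
the statistical assertions comfortable margins.

## Known limitations

* The E-value model is ungapped Karlin–Altschul applied to gapped
  scores; it orders hits correctly and filters chance matches at these
  database sizes but is not calibrated probability. The thresholds
  that decide acceptance are similarity- and arrangement-based, not
  E-value-based, by design.
* The engine does not implement composition-based statistics or
  translated searches.
* Replicon calling never infers plasmid origin from sequence context.
* Real-corpus properties reported in the literature (e.g. the 95%
  within-set similarity of named homologues) are reported by the
  tooling where observed, never asserted.
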