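---
title: "Pan-genome and mobilome analysis with mobilomeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome and mobilome analysis with mobilomeR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mobilomeR)
```

`mobilomeR` implements a comparative-genomics pipeline for bacterial
mobile genetic elements: ortholog clustering with pan/core statistics, IS
discovery and census, composite-transposon calling, cross-species
homology (HGT) detection, plasmid-integration mapping, and ICE
characterization with in-silico excision testing. This vignette explains
the models and procedures, the parameters that matter, the numerical
choices, and what the synthetic test suite does and does not demonstrate.

## Genome containers and coordinate conventions

Genomes are S3 record objects: a `genome` holds `replicon`s (sequence,
topology, feature tibble), one of them flagged as the chromosome. All
coordinates are **1-based inclusive on the forward strand**, the native
convention of GenBank records and of R string functions; input files need
no conversion and off-by-one surface area is minimized. Features that
span the origin of a circular replicon are stored unwrapped (`end` beyond
the replicon length, `wraps = TRUE`) so no feature is ever split; interval
arithmetic reduces modulo the length.

Chromosomes are rotated so that coordinate 1 is the first base of the
intergenic region immediately upstream of the replication initiator gene
*dnaA*, identified by its annotation keyword (case-insensitive). With
zero or several candidates the rotation aborts and lists them — silent
guessing would make positional statistics incomparable across strains.
Rotation is an isometry on circular coordinates: pairwise distances
modulo the length are preserved (a tested invariant).

Functional categorization of gene products is a deterministic keyword
table (`inst/extdata/functional_categories.tsv`, `category<TAB>pattern`,
first match wins, iron-related patterns deliberately ordered before
generic transport so iron-uptake transporters land in the iron class).
A keyword table cannot reproduce a curated subsystem annotation
bit-for-bit; determinism and editability were chosen over fidelity, and
the table ships as a versioned text resource users can replace.

## Alignment engine

All stages share one set of primitives.

**Protein identity and coverage.** Pairs are aligned ends-free
(overlap-type global alignment, BLOSUM62, gap open 10 / extend 0.5,
via `Biostrings::pairwiseAlignment`). Identity is matches over alignment
columns excluding terminal gaps; coverage is the aligned span of the
**longer** sequence over its length. The longer-sequence convention is
symmetric and conservative: a short perfect fragment cannot claim a long
protein. An exact 70% prefix therefore has identity 1.0 but coverage
0.70 and fails a 75% coverage rule.

**Nucleotide local search** is seed-and-extend in the megablast regime:
exact 13-mers (data.table-indexed, both strands, N-containing words
skipped) are grouped by near-constant diagonal (band 50 bp), chained
greedily into colinear anchor sets (chains split at gaps beyond 1,000
bp), inter-anchor gaps closed by direct comparison (equal lengths) or
dynamic programming (unequal lengths), and block ends extended ungapped
under an x-drop rule (match +1, mismatch −2, gap open −5 / extend −2,
x-drop 20). Two consequences are worth knowing: sensitivity below ~85%
identity decays (a deliberate non-goal — the thresholds downstream are
90%+), and an ungapped end extension cannot cross indel-rich boundaries.
Circular subjects are searched across the origin by indexing an extended
copy of the sequence and folding coordinates back. The whole procedure is
checked against a hand-written affine-gap Smith–Waterman on small
subjects: identical block counts and locus-wise identical scores.

**Repeat finders.** Terminal inverted repeats are sought exhaustively
within terminal windows (defaults: window 150 bp, arms 10–50 bp, up to 3
mismatches), ranked by arm length, then mismatches, then terminal
proximity; since a long arm with some mismatches outranks a short perfect
one, a planted perfect IR may be reported as part of a slightly longer,
imperfect arm pair. Direct repeats flanking an island are seed-matched at
the requested length around both boundaries and extended while bases keep
matching exactly.

**In-silico PCR** reports a product for every pair of primer sites on
opposite strands pointing toward each other within the size limit. The
3'-terminal base must match exactly; up to 2 mismatches are tolerated
elsewhere. Annealing thermodynamics are intentionally not modelled (the
laboratory analogue runs at a fixed annealing temperature; sequence-level
site matching is what the excision logic needs). On circular templates
the product set is rotation-invariant and products never exceed the
template length; on linear templates no product spans position 1.

## Pan-genome model

Clustering is greedy centroid assignment: proteins sorted by length
descending (ties by locus tag, then genome — fixing the order makes the
partition deterministic and independent of input file order), each
joining the first existing centroid with identity ≥ 0.60 and coverage ≥
0.75, else founding a cluster. A provably safe length prefilter skips
centroid comparisons that cannot reach the thresholds (identity over ≥
75% of the longer forces shorter/longer > 0.45), which the brute-force
all-pairs oracle in the test suite confirms changes nothing. Paralogs
may co-occur in one cluster; presence per genome is binary.

Pan and core curves are cumulative unions/intersections over genome
orderings — all orderings when n! ≤ 5,000 (n ≤ 6), otherwise 100 random
orderings under a seed. ORFans are the clusters present in exactly one
genome (k = 1 of the spectrum); their positional density is counted in
non-overlapping windows along origin-normalized chromosomes.

## IS, composite transposon, HGT and ICE procedures

IS discovery mirrors manual curation of annotated genomes: transposase /
mobile-element products (integrases are tallied separately, not used as
IS anchors) grouped by identical translation length; candidates extracted
with 1,000 bp flanks; multi-copy status confirmed by aligning the
candidate to all genomes. Because the source locus also matches across
its flanks, the element region is estimated as the maximal run of query
positions covered by at least two loci, and boundaries are the interval
shared by all full copies. Two confirmed loci suffice for IS status.
Copy-confirmation thresholds (identity ≥ 0.90 over ≥ 0.80 of the element)
are configurable assumptions: tolerant of within-family divergence,
exclusive of distant relatives. Partial copies are tallied separately and
never counted in the census. Near-identical discovered elements are
collapsed at 95% identity.

A composite-transposon candidate is any ordered pair of full IS copies on
one replicon with cargo gap ≤ 20 kb whose transposases share ≥ 60%
amino-acid identity and whose IRs (when both elements have them) share ≥
60% nucleotide identity. The floors generalize the observed single-case
regime (~65% transposase, ~73% IR identity) instead of hard-coding it;
candidates are exactly that — candidates with their cargo gene lists.

HGT regions are raw alignment blocks filtered at > 2,000 bp and > 90%
identity, **then** merged per partner across gaps ≤ 1,000 bp; both the
raw aligned length and the merged span are reported, since published
region sizes rarely state their merging rules. "Other species" is
operationalized by the `species_label` field — taxonomy lookup is out of
scope, and same-species partners are excluded with a warning. Plasmid
integration uses stricter defaults (≥ 95% identity, blocks ≥ 500 bp)
projected onto plasmid coordinates; coverage is merged covered bp over
plasmid length.

ICE excision bookkeeping: the excised circle is the att-bounded island
segment taken intact and circularized, so its junction carries the
boundary repeat from both ends; the re-sealed chromosome joins the flanks
across a single att copy. Hence circle + re-sealed = chromosome + att, an
exact, tested identity. The copy arithmetic of site-specific
recombination intermediates is not modelled further; the PCR logic —
which primer pairs amplify on which of the three molecular forms — is
insensitive to the att copy count at the junction. The island size range
accepted by default is 20–150 kb.

## The synthetic data generator

`simulate_genome_set()` builds the whole study structure from one seeded
configuration: a shared core gene pool (the first core gene is *dnaA*),
shell genes present in random subsets, per-genome ORFans (a configurable
fraction placed at a positional hotspot), an rRNA/tRNA operon, IS
elements with terminal IRs planted at 5–13 and 2–4 copies per genome for
the two default families (a fraction inserted inside ORFan genes,
splitting the host CDS annotation), one composite transposon with an
iron-uptake cargo, cross-species HGT blocks at 92–99% identity copied
from a partner genome, an att-bounded 30 kb island carrying the ICE
signature roster, and a 7.6 kb partner plasmid 80% of which is integrated
into one recipient in three fragments. Identity targets are hit exactly
(a fixed number of substituted positions), so planted identities are
reproducible to ±0.5%.

Scale choices: chromosomes default to 400 kb rather than the several-Mb
genomes of real brevibacteria. The value is the smallest at which up to
13 same-family IS copies can keep pairwise distances above the
composite-transposon cargo limit (20 kb) — spacing enforced so that
composite detection has a planted precision of exactly 1 — while full
pipeline runs stay in the minutes range. Correspondingly the ICE island
is 30 kb (the real exemplar is ~96–100 kb; boundary logic does not depend
on interior length), and gene density is lower than in real genomes.
Intergenic background is i.i.d. nucleotide sequence at 62.7% G+C with no
codon model: every detection method in the package is identity-based,
not composition-based, so compositional realism would add nothing the
tests could detect. In-gene IS insertions choose ORFan hosts so that the
expected pan-genome spectrum remains exactly computable (disrupting a
core gene would change core counts in ways that depend on placement).

Random number streams are per planting phase (sequence content,
placement, divergence, HGT, plasmid, island, IS) with seeds derived
arithmetically from the master seed, so changing one spec field does not
reshuffle unrelated structure; the same seed yields byte-identical
genomes and ledgers.

The truth ledger records every planted interval (shifted as later
insertions move coordinates), the expected k-spectrum, census, disruption
and composite tables, and round-trips losslessly through JSON.

**What passing tests show — and do not show.** On this suite, planted
recovery is exact: spectrum equality, IS copy precision and recall 1.0 at
zero noise (recall ≥ 0.95 at 5% per-copy substitution noise), HGT
boundaries within ±50 bp, island boundaries exact. Real data differ in
ways the generator does not emulate: annotation errors and missing
translations, IS families with internal deletions and nested elements,
HGT from multiple diverged donors, compositional heterogeneity, and
assembly artifacts. Results on real genomes therefore depend on
annotation quality in ways these tests cannot certify; thresholds are
surfaced as configuration for that reason.

## Pipeline and outputs

`run_pipeline()` executes the stages on a list of genomes with a single
configuration (R list or YAML path); every threshold is a named key with
the study defaults (`cluster_identity` 0.60, `cluster_coverage` 0.75,
`hgt_min_length` 2000, `hgt_min_identity` 0.90, `is_flank` 1000,
`att_repeat_length` 12, ...). Results come back as tibbles (with
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures) and,
when an output directory is set, as TSV/FASTA/GFF3 reports plus a JSON
summary whose internal consistency (ORFans = k-spectrum at k = 1,
category counts summing to gene totals, census row sums) is tested.
The package's functions and this vignette are the interface; there is no
separate shell entry point, `scripts/acceptance.R` being a worked example
of scripting the full pipeline end to end.

## Known limitations

* The local search is tuned for recent transfers (≥ ~85–90% identity);
  divergent homology needs a dedicated sensitive aligner.
* IS family assignment against public IS databases, target-site
  duplication inference and insertion dating are out of scope.
* Direct-repeat boundary refinement prefers the longest repeat pair and,
  among equals, the outermost; a chance repeat pair of equal length and
  wider span than the true att site would win (probability on the order
  of a few percent per island at the default 500 bp windows).
* Primer design for the excision test is the user's responsibility; the
  package predicts products for given primers but does not design them.
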