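---
title: "Methods: building and evaluating ecosystem-specific 16S reference databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating ecosystem-specific 16S reference databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotaxdb)
```

## The problem

Universal 16S rRNA reference databases classify environmental amplicon
sequence variants (ASVs) poorly at genus and species level: many soil and
plant-associated lineages have no named relatives, so taxonomy strings
simply stop at family or order. An ecosystem-specific database built from
near-full-length, essentially error-free 16S genes of the same habitat fixes
this in two ways: it supplies high-identity references for the ASVs actually
observed, and it fills the unnamed ranks with systematic *de novo*
placeholder names so that every reference carries a complete seven-rank
taxonomy (domain to species) that downstream community profiling can use.

`ecotaxdb` implements that workflow — database construction, a bootstrap
k-mer classifier, the evaluation suite (novelty, coverage, classification
rates, in-silico amplicon resolution), and primer-bias scoring — together
with seeded simulators that generate every input type with planted ground
truth.

## Database construction

`build_database()` runs four stages:

1. **Trim** (`trim_to_primer_window()`): each oriented input sequence is cut
   to the window strictly between the forward primer site and the
   reverse-complemented reverse primer site (defaults 27f/1391r for
   bacteria). Site finding is degenerate-exact: an IUPAC-degenerate primer
   base matches exactly the bases of its set, and no mismatches are
   tolerated — the inputs are assembled consensus sequences whose primer
   sites are intact, so mismatch-tolerant search would only add ambiguity.
   With multiple candidate sites the outermost pair wins. Sequences missing
   either site are discarded with a reason flag.
2. **Dereplicate** (`resolve_flasvs()`): identical trimmed strings collapse
   into full-length ASVs (FL-ASVs) whose abundance is the copy count;
   records are ordered by descending abundance (ties by first occurrence)
   and named `FLASV1..n`. That ordinal order is the database order all later
   stages use, which makes every downstream step deterministic.
3. **Inherit** (`inherit_taxonomy()`): every FL-ASV is mapped against a
   universal reference database by exhaustive top-hit search and copies the
   hit's names from domain down to the deepest rank whose identity threshold
   is met. The default thresholds are the widely used rank cutoffs:

   | rank | minimum identity (%) |
   |---|---|
   | phylum | 75.0 |
   | class | 78.5 |
   | order | 82.0 |
   | family | 86.5 |
   | genus | 94.5 |
   | species | 98.7 |

   The boundary is inclusive: an identity exactly equal to a cutoff is
   assignable at that rank, because the novelty categories are defined as
   strictly *below* threshold. Identities are compared as exact floating
   values, without rounding — the alternative (rounding to one decimal
   first) is not documented anywhere we could anchor it, and exact
   comparison keeps `rank_for_identity()` a pure function of its inputs.
4. **Complete** (`assign_denovo_placeholders()`): for each rank from phylum
   to species, records still unnamed at that rank are clustered greedily at
   the rank threshold *within groups sharing identical taxonomy at all
   higher ranks* — a placeholder genus may never span two families, since
   the output format could not represent it. Processing in database order,
   the first unnamed record seeds a cluster named
   `<prefix>_<rank letter>_<seed ordinal>` (e.g. `ECO_g_42`); later records
   join the first seed they match at or above the threshold, else seed new
   clusters. Seed-ordinal numbering makes placeholder names reproducible
   across reruns. This greedy seed-centroid scheme is our documented
   stand-in for the original pipeline's clustering, whose exact
   centroid-update rules live in prior work; the contracts the tests assert
   (completeness, parent-consistency, members within threshold of their
   seed) hold either way.

## Alignment identity

All identity values come from one fixed definition
(`global_identity()`): an optimal global alignment is computed under
match +1, mismatch −1, gap open −2, gap extend −1 (the opening charge
applies to a gap's first column, extension to each additional column), and

> identity = 100 × matches / (alignment columns − terminal-gap columns).

Three determinism conventions matter and are part of the definition:

* **Canonical argument order.** Among equally optimal alignments the
  traceback must pick one; picking differently for `(a,b)` and `(b,a)`
  would make identity asymmetric. Arguments are therefore ordered
  byte-wise before aligning.
* **Terminal-gap preference.** Among equal-score alignments the one with
  the most terminal-gap columns is preferred (implemented as a
  lexicographic objective — score first, then terminal columns — which is
  per-move decomposable because a gap move on a boundary row/column of the
  dynamic-programming matrix is exactly a terminal column). Without this, a
  short sequence that occurs verbatim inside a longer one could be reported
  below 100% identity whenever an equal-cost alignment splits its flanking
  gaps internally.
* **Fixed traceback priorities** (diagonal over gaps, and a fixed state
  order) resolve all remaining ties.

`top_hit()` searches exhaustively — every reference is aligned, nothing is
pruned — and breaks ties by database order. For speed the matrix is
restricted to a *provably exact* band: any alignment path leaving the band
would score strictly below a trivially computable gapless baseline, so the
banded result (including tie-breaking) is identical to the full matrix.
This is an exact reformulation, not a result-changing heuristic; the test
suite checks exact equality against a full-matrix reference implementation
on hundreds of randomized pairs, including indel cases.

## The classifier

`classify()` is a SINTAX-style bootstrap k-mer classifier: per iteration it
samples, with replacement, a fixed number of the query's unique k-mers and
lets the reference sharing most of them win (ties to the lowest record
ordinal). The reported lineage is the modal winner's; each rank's
confidence is the fraction of iterations whose winner carries that name.
Because records sharing a name at rank r share all names above r in a
completed database, these confidences are non-increasing down the lineage,
and the taxonomy is truncated at the deepest contiguous rank meeting the
confidence cutoff. Defaults follow the published SINTAX description
(k = 8, 100 iterations, 32 draws) with a 0.8 cutoff and both-strand search
(the orientation with the larger summed confidence wins, ties to plus). The
sampler is seeded; outputs are bit-identical for fixed inputs. This is a
behavioural stand-in, not a byte-compatible reimplementation of any
specific tool — only the cutoff and strand conventions are fixed by the
evaluation contracts.

## Evaluation definitions

* **Sequence novelty** (`sequence_novelty()`): a record is novel at rank r
  if its best-hit identity against the universal database is strictly below
  threshold(r). The categories are nested, so counts grow monotonically
  from phylum to species; the property suite asserts this on randomized
  inputs.
* **Taxonomy novelty** (`taxonomy_novelty()`): per rank, the fraction of
  distinct taxa whose name is a placeholder. Note that *de novo* species
  include known species that full-length 16S cannot resolve.
* **Coverage** (`coverage_eval()`): per sample, ASVs at ≥ 0.01% relative
  abundance are kept; the fraction of kept ASVs with a top hit at ≥ 99%
  identity and the summed relative abundance they represent are reported
  with mean ± sd across samples. The abundance filter is applied per
  sample (an ASV may be kept in one sample and dropped in another): the
  figures this mirrors are per-sample summaries, which only makes sense
  under a per-sample filter.
* **Classification rates** (`classification_rate()`): fraction of
  (abundance-filtered) ASVs whose classification reaches genus resp.
  species at the cutoff.
* **In-silico resolution** (`extract_insilico_asvs()` +
  `resolution_eval()`): each database record's inter-primer sub-region is
  extracted (redundantly — duplicates kept, one per parent) and classified
  against the full-length database on the plus strand; at genus and species
  a prediction is *correct* if it equals the parent's name, *wrong* if
  non-empty and different, *not classified* if empty. Rank names, not whole
  paths, are compared; an empty prediction is never "wrong". The three
  fractions partition unity by construction.

## Primer-bias scoring

`score_primer()` finds the placement of a degenerate primer on a template —
primer fully aligned, template local, gaps allowed — minimising the overall
weighted score (OWS): 0.40 per non-3' mismatch, 1.00 per 3' mismatch
(within the last five primer bases), 3.00 for a terminal-base mismatch,
1.00 per non-3' gap and 3.00 per 3' gap. Categories: perfect (0), partial
((0, 1]), poor (> 1); `survey_database()` scores both primers of a pair
(reverse primer against the reverse complement) and lets the worse primer
govern the record's category.

Two conventions are ours to fix, and are used consistently in tests:

* the terminal-base penalty *replaces* the generic 3' per-mismatch penalty
  (3.00, not 4.00) — the source lists it as a distinct, dominant case;
* a gap is 3' when its template-consumed position falls within the
  last-five-base block, and among equal-minimal placements the scorer
  prefers the rightmost template end and diagonal moves, so a terminal
  mismatch is reported as a mismatch rather than an equal-cost terminal gap.

One subtlety the property tests respect: "adding one more mismatch never
lowers the score" is only true while the planted site remains the cheapest
placement — mutating a template base can *improve* an overlapping
alternative placement. The monotonicity suite therefore certifies each
planted case with an independent placement scan before asserting additive
growth (0 → 0.40 → 0.80).

## The simulators

`simulate_reference()` emulates the study conditions the package is tested
under: a small universal reference set (default 4 phyla × 2 lineages,
1,300 bp gene regions, full seven-rank names) and 200 query sequences on a
divergence ladder — per planted "deepest inheritable rank", a substitution
count is drawn so the query's nearest-universal identity lands inside the
rank's threshold band (margin 0.15 points from each boundary), then
*verified* with the package aligner and redrawn if outside. Substitutions
avoid the planted primer sites; emitted queries are full-length
(trim-primer sites flanking the region) with Poisson-distributed copy
numbers for dereplication truth. The default ladder (120 species, 40
genus, 20 family, 10 order, 6 class, 4 phylum) gives the nested novelty
counts 0/4/10/20/40/80 that the acceptance suite recovers exactly.

`simulate_amplicon_dataset()` extracts each record's amplicon, assigns
log-normal community abundances (meanlog 0, sdlog 1.5 — a typical
several-orders-of-magnitude microbial abundance spread), and draws
per-sample counts multinomially at depth 50,000 over 6 samples; ASVs can be
pinned below the 0.01% abundance filter to exercise the filtering logic.
`plant_primer_mutations()` injects mismatches or gaps of a chosen
positional class into primer sites and records the expected OWS from the
penalty table; each plant is certified by the placement scan, and records
whose flanking context always admits a cheaper placement are skipped
(rejection sampling) rather than planted ambiguously.

What the simulators deliberately do not model: chimeras and PCR/sequencing
error (the upstream assembly protocol is essentially error-free), indel
evolution (substitution-only divergence keeps identity analytically
controllable; indel robustness is exercised separately in the aligner
oracle tests), rate variation across lineages, and realistic phylogenetic
tree shapes. Passing tests therefore demonstrate the correctness of the
algorithms under controlled conditions, not the ecological fidelity of any
particular simulated community.

## Problem sizes and runtime choices

The test and acceptance workloads are sized for a desk-scale run: the
full simulated study uses 200 queries of 1,300 bp against 8 universal
records (a few thousand banded alignments, about a minute); oracle
equivalence uses 500 random pairs up to 60 bp and 200 random
primer/template pairs; the property suites run 1,000 randomized cases
each. Unit tests use shorter sequences (300–1,000 bp) solely to keep the
feedback loop fast; none of the algorithms have length-dependent special
cases.

## Known limitations

* The de novo clustering is greedy and order-dependent by design; a
  different input order yields different (but equally valid and fully
  reproducible) placeholder assignments.
* `rank_for_identity()` consumes a single top-hit identity; it does not
  combine evidence across multiple near-best hits.
* The classifier's bootstrap confidence is a resampling heuristic, not a
  calibrated posterior; cutoff 0.8 is a convention, not an error rate.
* Mixed-orientation input is not handled: sequences must be co-oriented
  before building (orientation tools exist upstream), and `top_hit()`
  searches the plus strand only.
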