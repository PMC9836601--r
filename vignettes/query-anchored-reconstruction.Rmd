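---
title: "Query-anchored mitogenome reconstruction: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Query-anchored mitogenome reconstruction: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoanchor)
```

## The problem

Museum specimens collected in the 19th century were never intended for
genetics. Their DNA survives, if at all, as short fragments carrying
hydrolytic deamination damage, and a shotgun library from such a specimen is
dominated by exogenous reads: the mitochondrial fraction can be on the order
of 0.2% of pairs. De novo assembly generally fails on such data. What does
work is *query-anchored reconstruction*: take the complete mitogenome of a
closely related species (~95% identical), find every read that aligns to it,
and rewrite the query base-by-base wherever the reads say so — ambiguity
codes where reads disagree, `N` where nothing aligned. The result lives in
the query's coordinate frame, which also lets the query's annotation be
reused directly.

This package automates that procedure and pairs it with a synthetic
degraded-library simulator, so every stage can be validated against known
truth at desk scale.

## The model, stage by stage

### Alignment (module `kalign`)

Reads are placed on the circular query by k-mer seeding followed by banded
local alignment (Smith–Waterman with affine gaps, implemented in C++).
Circularity is handled by indexing the query extended with its first
`k - 1 + read_len` bases and reporting positions modulo the length, so reads
spanning the origin align exactly as they would after any rotation of the
query (a tested invariant).

Two stringency presets stand in for the high- and moderate-similarity passes
of a web nucleotide search, whose exact effective parameters are not
published:

| preset | k | min identity | min length |
|--------|---|--------------|------------|
| high   | 16 | 0.92 | 40 |
| low    | 11 | 0.80 | 30 |

with match +1, mismatch −2, gap open −4, gap extend −2, band ±8 throughout.
These defaults cleanly separate ~95%-identical congeneric reads from random
background and are fully configurable. Mates are aligned independently (the
manual procedure treated reads individually), one best alignment is kept per
read, and a read that scores equally well at two distinct loci is dropped as
ambiguous rather than risk a NUMT-like misplacement inflating the pileup.
On planted instances the emitted scores equal an exhaustive Smith–Waterman
oracle (`Biostrings::pairwiseAlignment`) with the identical scoring scheme —
the test suite checks 200 such instances plus the rotation and
strand-symmetry invariants.

### Consensus (module `consensus`)

Aligned columns are aggregated into a per-query-position count matrix
(minus-strand reads complemented into query orientation). Each site is then
called:

* depth < `min_depth_call` → `N`, status *missing*;
* alleles = bases with count ≥ `min_minor_count` **and** frequency ≥
  `min_minor_frac` (both inclusive);
* one allele → that base (*concordant* if it equals the query base,
  *substituted* otherwise);
* two or more alleles → the IUPAC code denoting exactly that base set,
  status *ambiguous*.

Defaults are `min_depth_call = 1`, `min_minor_count = 1`,
`min_minor_frac = 0.25`. Accepting single-read evidence reflects the
very-low-coverage regime this method exists for; the 25% minor-allele floor
suppresses lone damaged or erroneous bases at well-covered sites.
Thresholds are inclusive so that a 1-of-4 minority is kept — this reproduces
two-base ambiguity behaviour at the low depths where it matters. The policy
is recorded in the reconstruction's provenance.

Indels are deliberately not called: read insertions are skipped, deletions
only counted. The reconstruction therefore always has exactly the query's
length. This mirrors the method's positional anchoring — real length
differences in non-coding regions make the total length of any such
reconstruction inexact, which is a known and accepted property of the
approach. Degenerate corner: an allele set of all four bases would have to
be written `N`; we treat it as uninformative (*missing*), keeping the
invariant that `N` ⟺ missing. Query positions that are themselves `N` are
callable from reads like any other position, since the reads, not the query,
carry the evidence.

### Damage statistics (module `damage`)

Deamination converts C→U near fragment termini; the polymerase reads U as T,
so against the plus strand the library shows C→T and G→A mismatches. In the
consensus this surfaces as Y calls at query-C sites and R calls at query-G
sites. `deamination_asymmetry()` counts these *consistent* calls against all
other multi-base calls:

```
asymmetry_ratio = (Y@C + R@G) / (all other ambiguity calls + pseudocount)
```

with pseudocount 1 guarding the division on clean data, and attaches a
one-sided exact binomial test of the consistent count among ambiguous calls
at C/G query sites against a null proportion of 1/3 (each of C and G admits
three two-base codes, of which deamination explains exactly one; the three
are exchangeable under symmetric noise). A Y at a non-C site counts as
"other": deamination cannot create a C/T mixture where no C existed. The
null proportion is configurable; the binomial formalization is this
package's own — the original argument was made on raw counts.

Two numerical facts worth knowing when interpreting the ratio. First, under
a symmetric sequencing-error null the expected ratio is ~0.2, not exactly 1
(consistent classes are 2 of the 12 error-driven two-base outcomes weighted
by base composition); "order unity" is the right reading, and the damage-on
regime sits an order of magnitude above it. Second, *strictly terminal*
damage is largely invisible: a mismatch at the very end of a read is trimmed
by any score-maximizing local aligner (ours, and equally the web-search
alignments the manual procedure used). The observable signature is carried
by interior (residual-rate) and flanked near-terminal conversions. The
dose-response test therefore uses a slow positional decay (0.9) so the dose
acts on retained columns.

### Liftover and validation (modules `liftover`, `validate`)

Because the consensus output has the query's length, annotation liftover is
the identity map on coordinates, which is precisely what reusing the query's
annotation on the reconstructed genome means. Per feature we report length,
N count, %N and ambiguous count; a feature whose whole interval is N is
flagged `fully_missing` — the fate of a short tRNA gene that happens to
attract no reads. Ambiguity codes count as recovered sequence, since the
published genome retains its ambiguity sites.

`query_independence()` re-runs the reconstruction against two or more
different queries and compares calls over sites called (non-N) in *all*
reconstructions — the intersection, matching the implicit base-for-base
comparison over recovered bases. Whether such comparisons should include
ambiguity symbols is genuinely open; we compare full IUPAC symbols and also
report the tally restricted to unambiguous calls. Queries of unequal length
are reconciled by a global pairwise alignment of the queries themselves
(indel columns excluded). Fewer than 50 co-called sites is reported as
`insufficient-overlap`, not a pass: a vacuous comparison should not certify
anything.

## The simulator and what a green test establishes

`simulate_library()` states the emulated world explicitly:

* **150 bp paired-end reads** and an **endogenous fraction of 0.2%** by
  default — the documented regime of the motivating data set;
* insert sizes from a normal distribution truncated to [30, 2·mean], default
  mean 100 sd 40 — the motivating study reports no fragment-length
  distribution, so these are an uncalibrated but realistic choice for
  historical-DNA inserts, made once;
* deamination as a geometric positional profile: a C at distance *i* from a
  physical strand's 5' end converts with probability
  `d_max · decay^i + floor` (defaults 0.3, 0.5, 0.01). Two parameters
  reproduce the C→T/G→A excess without modelling full fragment chemistry.
  Both physical strands are damaged; both mates of a pair read the
  post-amplification consensus of the fragment, so a damaged position
  appears in both mates;
* uniform fragment starts on the circle, uniform strand, sequencing error as
  uniform substitution; background reads from an i.i.d. random genome
  (default 50 kb) — the pipeline only needs non-mitochondrial distractors;
* constant Q37 quality strings, because base qualities are unused
  downstream.

What the simulator does **not** emulate: adapter read-through content, PCR
duplicates, quality-dependent errors, NUMT-bearing nuclear background,
length-variable control regions, or indel divergence between truth and
query. A green parameter-recovery test therefore establishes that the
pipeline inverts *this* generative model — substitution divergence, terminal
damage, uniform error, circular coordinates — at the stated sizes, not that
it is robust to every artefact of real libraries. That is exactly the role
the checks on real data (query-independence, damage asymmetry, annotation
completeness) play in the field.

## Numerical and design choices

* Internal coordinates are 0-based half-open; all file formats (FASTA, TSV,
  feature table) speak 1-based inclusive. Lowercase input is canonicalized
  to uppercase; U is accepted and mapped to T.
* Allele thresholds compare with ≥ and a 1e-9 slack so that exact fractions
  (1/4 at depth 4) are kept deterministically.
* Alignment tie-breaks: (score, leftmost query start, plus strand), making
  output independent of evaluation order; full determinism under a fixed
  seed is a tested pipeline invariant.
* The dedicated config format is JSON rather than YAML: the target
  environment ships no R YAML parser, and `jsonlite` is universally
  available. The config records the seed; the run log (JSON lines) echoes
  every parameter so each report number can be re-derived.
* Simulation sizes in the test suite are scaled (3–8 kb genomes for the
  damage, independence and monotonicity properties; the headline
  parameter-recovery check runs at the full 16 kb) to keep the suite
  comfortably inside desk-scale runtime on one CPU.

## Known limitations

* No quality-weighted or likelihood-based genotype calling; the caller is a
  transparent counting rule, by design.
* Length variation relative to the query cannot be represented; reported
  totals inherit the query's length.
* The annotation fixture is a synthetic canonical vertebrate gene map
  (correct complement and strand layout, plausible coordinates), not a real
  accession; it exercises structure, not biology.
* Reconstruction from the real archived libraries is an integration exercise
  requiring multi-gigabyte downloads and is out of scope for the test suite.
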