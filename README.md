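# mitoanchor

Query-anchored mitogenome reconstruction from degraded shotgun reads.

## The problem

DNA from historical museum specimens survives as short, deaminated fragments
buried in an overwhelmingly exogenous shotgun library (the mitochondrial
fraction can be ~0.2% of read pairs). De novo assemblers fail on such data,
but a *query-anchored* strategy works: align every read against the complete
mitogenome of a closely related species (~95% identical) and rewrite that
query base-by-base wherever the reads demand it — the read base where reads
agree against the query, an IUPAC ambiguity code where they disagree, and
`N` where nothing aligned. The result lives in the query's coordinate frame,
so the query's annotation can be lifted over directly, and the spectrum of
ambiguity codes itself carries the signature of post-mortem damage.

`mitoanchor` automates this procedure for people working with historical or
otherwise low-input samples, and ships a synthetic degraded-library
simulator so every stage is testable against known truth.

## Method in brief

* **Alignment** — k-mer seeded, banded local alignment (Smith–Waterman with
  affine gaps, match +1 / mismatch −2 / gap open −4 / extend −2, in C++)
  on the circular query, with `high` (k=16, identity ≥ 0.92) and `low`
  (k=11, identity ≥ 0.80) stringency presets. One best placement per read;
  reads scoring equally at two loci are dropped.
* **Consensus** — per-site calling from the query-anchored pileup: depth 0
  → `N`; alleles are bases with count ≥ 1 and frequency ≥ 0.25 (inclusive);
  one allele → that base (*concordant*/*substituted*); several → the IUPAC
  code of exactly that set (e.g. {C,T} → `Y`). Output length always equals
  the query length.
* **Damage** — deamination makes C→T (and, plus-strand, G→A) mismatches, so
  damaged libraries show an excess of `Y`-at-C and `R`-at-G calls:
  `asymmetry_ratio = (Y@C + R@G) / (other ambiguity calls + 1)`, with a
  one-sided exact binomial test against a null proportion of 1/3.
* **Liftover & validation** — identity-map annotation transfer with
  per-feature %N and `fully_missing` flags; a query-independence check that
  reconstructions against different related queries agree base-for-base
  over co-called sites.

## Worked example

Simulate a damaged 16 kb library, reconstruct it against a 5%-diverged
congeneric query, and profile the damage:

```r
library(mitoanchor)

truth <- random_genome(16000, seed = 11)
query <- mutate_genome(truth, 0.05, seed = 12); query$id <- "congeneric_query"

lib <- simulate_library(truth,
  library_params(n_pairs = 1100, endogenous_fraction = 1, seq_error = 0, seed = 13),
  damage = damage_params(d_max = 0.3, decay = 0.5, floor = 0.01))

aset <- align_library(c(lib$reads1, lib$reads2), query, align_preset("low"))
#> <alignment_set> vs congeneric_query (preset low): 2192/2200 reads aligned (99.6%)

rec <- reconstruct(build_pileup(aset, query), query)
#> <reconstruction> congeneric_query_reconstruction: 16000 bp, 0 N (0.0%),
#>   829 substituted, ambiguous: R=36 Y=31

deamination_asymmetry(summarize_ambiguities(rec, query))
#> Deamination damage report
#>   consistent (Y@C + R@G): 58
#>   other ambiguity calls : 9
#>   asymmetry ratio       : 5.80 (pseudocount 1)
#>   exact binomial p      : 8.42e-27 (null 0.333 over 59 C/G sites)
```

Reading the numbers: at ~13.6× effective depth every site is covered (0 N),
829 sites were flipped from the query base to the read-supported truth base
(the ~5% divergence being undone), and the ambiguity calls are dominated by
deamination-consistent classes — 58 of 67 are `Y` at a query `C` or `R` at a
query `G`, a 5.8-fold excess over all other classes that symmetric noise
cannot produce (binomial p ≈ 1e-26). The reconstruction here matches the
withheld truth at 99.6% of all 16,000 sites (the residual being ambiguity
codes at damaged low-depth sites, which by construction contain the truth
base).

The one-command pipeline does the same from a JSON config (or real FASTQ
inputs) and writes a full artifact bundle — reconstruction FASTA, per-site
calls TSV, tally JSON, damage report, per-feature recovery table, GenBank
feature table, run log:

```r
run_end_to_end(list(seed = 7,
                    simulate = list(truth_length = 16000, divergence = 0.05,
                                    depth = 20, damage = list(d_max = 0.3)),
                    align = list(preset = "low")),
               outdir = "run1")
```

A CLI wrapper with `simulate / align / reconstruct / damage / liftover /
validate / run` subcommands lives at `inst/scripts/mitoanchor.R`.

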