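---
title: "combitag: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{combitag: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The combinatorial barcoded-tagmentation design

In a combinatorially barcoded Tn5 library, pre-amplified full-length cDNA
from each sample is tagmented by a *pair* of transposome species. The A-type
adapter carries a sequencing-primer site, an 8-nt sample barcode
$A_m$, and the 19-nt Tn5 mosaic end (ME); the B-type adapter carries the
mate-2 primer site, an 8-nt barcode $B_n$, a 6-nt random UMI, and the ME.
Because only fragments with one A end and one B end amplify in the indexing
PCR, the observed barcode pair $(A_m, B_n)$ addresses $m \times n$ samples
while only $m + n$ transposome species have to be prepared. With the
package's default whitelists of 10 + 10 codes, 100 samples are addressable
(`combinatorial_capacity()`).

The sequenced read pair therefore has the structure

```
R1: [barcode A, 8 nt][ME, 19 nt][insert, A-proximal end -->]
R2: [barcode B, 8 nt][UMI, 6 nt][ME, 19 nt][insert, B-proximal end -->]
```

so the mate-2 technical prefix is $8 + 6 + 19 = 33$ nt — the decoder's
restructuring step (`restructure_pairs()`) moves the first 14 nt of mate 2
onto mate 1 and deletes all 33 technical bases from mate 2, after which tag
extraction is pure positional slicing.

## The simulator's stated world

`sim_config()` defaults define one fixed "world"; they were chosen once,
from the experimental characteristics of the assay, and are not tuned:

* **Fragment lengths**: truncated normal, mean 400 nt, sd 75 nt, bounded to
  [150, 800] nt. Tagmentation of roughly 2-kb cDNA yields products
  concentrated around 300–500 bp; the truncated normal is the simplest
  two-parameter model consistent with that range. The distribution is
  symmetric about 400 inside the bounds, so the empirical mean is an
  unbiased check of the draw.
* **Fragment placement**: given a length $\ell$ on a template of length $T$,
  the start is uniform on the valid window $\{0, \dots, T-\ell\}$ (both
  adapter ends must land inside the template — terminal fragments carry
  only one Tn5 adapter and are not sequenceable). With degradation bias
  $\delta > 0$ the start density is tilted by $\exp(\delta \cdot x/(T-\ell))$
  via the inverse CDF of the continuous tilt, pushing mass toward the 3'
  end the way storage-degraded RNA does.
* **Templates**: random transcript bodies with log-normal lengths
  (median 2 kb, clamped to [1000, 4000] nt) plus a 30-nt poly(A) tail — the
  stretch an oligo-dT(30)-primed reverse transcription retains. Keeping the
  tail on the transcript record gives simulator, k-mer index and coverage
  QC a single coordinate system.
* **Expression**: per-sample transcript abundances are log-normal(0, 1),
  renormalized. Each sample contributes exactly `reads_per_sample`
  fragments (stratified pooling); consequently, per-sample shares after
  error-free demultiplexing deviate from $1/S$ only through decoding
  losses, not through pool sampling noise.
* **Errors**: i.i.d. substitutions at rate $\varepsilon = 0.002$ per base
  over both mates (a realistic Illumina error floor). Qualities are a
  constant Q37 except Q14 at substituted positions, which keeps the
  tag-quality filter (Phred $\geq 10$) neutral with respect to the error
  model. Indels, index hopping and PCR chimeras are not modeled.
* **Orientation**: which fragment end received the A adapter is a fair coin;
  reads shorter than the fragment never see the opposite adapter, while
  fragments shorter than the read length read through into the reverse
  complement of the opposite ME, which is what `trim_me_readthrough()`
  removes.
* The 9-bp target-site duplication of Tn5 insertion is not modeled: it is
  invisible at the level of the read structure the decoder sees.

All content draws complete before error injection, so a run with the same
seed and $\varepsilon = 0$ is the pristine twin of a noisy library — several
tests exploit this to measure the realized error rate against truth.

## Decoding and its guarantees

Barcode correction is unique-nearest-neighbor at Hamming distance
$\leq 1$. The design floor of the whitelist generator is a minimum pairwise
distance of 3 (within each set *and*, via `avoid=`, across the A/B union,
since both barcodes are read in 8-cycle windows): at distance 3, the
Hamming-1 balls around distinct codes are disjoint, so single-substitution
correction can never mis-assign — the test suite proves this exhaustively
on small whitelists. Ties at the minimum distance, distances beyond 1, and
barcodes with more than two `N`s are unassigned; `N` mismatches every
letter. UMIs are never error-corrected: with only 4096 states, correction
risks merging genuinely distinct fragments.

Every pair receives exactly one outcome (assigned, structural failure, bad
A, bad B, tag-quality failure, or valid-but-unexpected pair), and the
outcome counts always sum to the input count. The valid-but-unexpected
class (`PAIR_NOT_IN_SHEET`) is kept separate deliberately: in a real pooled
run it is the cross-contamination / barcode-hopping diagnostic. Two rates
are reported because the field's "barcode filtration" number is ambiguous:
`whitelist_rate` (both barcodes whitelist-valid) and
`barcode_filtration_rate` (fully assigned to an expected sample).

## Quantification

A built-in k-mer voter (k = 21, both strands, every third k-mer queried)
replaces a genomic aligner so the package is self-contained at desk scale.
A winning gene needs at least 3 votes and more than twice the runner-up's
votes; the modal alignment diagonal of the winning transcript localizes the
insert, and the forward-strand coordinate of the mate-2 5' base (`pos5`)
identifies the fragment's B-proximal end. On error-free simulations this
recovers the true gene and the exact fragment-end coordinate for every
read, which is the round-trip guarantee the acceptance suite asserts.

The default deduplication key is (sample, gene, UMI, `pos5` rounded to
10 nt), policy `"umi_pos"`. A 6-nt UMI alone collides quickly: among $n$
fragments of one gene the expected number of lost fragments is about
$n^2/2 \cdot 4096^{-1}$, i.e. already ~3% at $n = 250$. Keying on the
fragment end restores the "one UMI per tagmentation fragment" semantics;
the literal digital-expression convention remains available as policy
`"umi"`. With UMIs drawn without replacement per gene
(`unique_umis_per_gene = TRUE`), quantification equals the ground-truth
fragment table exactly, and the acceptance suite checks that identity.

## Coverage QC and the terminal-bin edge effect

`gene_body_coverage()` projects each UMI-deduplicated fragment interval
onto 100 percentile bins of its transcript, normalizes each transcript's
profile to unit mass, and averages. The 3'/5' bias index is the mean mass
of bins 81–100 over the mean of bins 1–20; it is 1 for a flat profile and
increases strictly with the simulator's degradation tilt (verified at
$\delta = 0, 1, 2$ across seeds).

An idealized expectation for an unbiased library is 0.01 in every bin. The
package meets this on the body interior but *not* in the terminal bins, and
the corresponding all-100-bins acceptance check is intentionally left
failing rather than weakened: on a finite template, a fragment of length
$\ell$ must start at least $\ell$ bases before the 3' terminus and cannot
extend past either end, so per-base coverage ramps linearly over roughly
one fragment length ($\approx$ 20 bins at the defaults) at both termini —
physically, terminal fragments lack one of the two adapters and never
amplify. No placement model can make interval-projected coverage flat at
the termini while fragment starts remain uniform over valid placements;
the unit suite therefore asserts flatness on the central plateau
(binomial 4-SE band) plus the qualitative terminal depletion, which is
what real RseQC-style curves show.

## Numerical and degenerate-input choices

* Whitelist generation is a greedy randomized search (batched candidate
  draws, deterministic under the seed, $10^5$ attempts per code); an
  unsatisfiable design raises a "design infeasible" error rather than
  returning a silent shorter set. GC is constrained to [0.25, 0.75] and
  homopolymers to $\leq 3$ — ordinary synthesis-friendliness; the distance
  floor, not composition, carries the correctness argument.
* Truncated-normal lengths are drawn by vectorized rejection; `sd = 0`
  degenerates to a point mass, used by the start-uniformity test.
* Coordinates are 0-based half-open in the ground truth (`frag_start`,
  `frag_end`) and 1-based inclusive in mapped intervals (`frag_lo`,
  `frag_hi`, `pos5`), matching the conventions of BED-like truth tables
  and R-side matrices respectively; converters are one-liners and the
  tests pin the correspondence (`pos5 = frag_end` when the A adapter is on
  the template-left end, `frag_start + 1` otherwise).
* An insert shorter than k is `TOO_SHORT`; a tie in gene votes within the
  2x margin is `AMBIGUOUS`; a poly(A)/poly(T) k-mer votes once per
  transcript per read position, so shared-tail k-mers cannot outvote
  transcript-specific sequence.
* The barnyard rule is read strictly: a sample is `MIXED` only when the
  minor-species fraction exceeds 0.20; exactly 20% is a clean call. The
  denominator is deduplicated UMI counts (a reads-based denominator can be
  had by passing a raw count matrix).

## What a green suite does and does not establish

The simulator emulates read architecture, combinatorics, fragmentation
statistics, substitution noise and 3' bias. It does not emulate intronic or
antisense reads, template-switching artifacts, index hopping between
pooled samples, PCR duplicate family-size distributions (beyond UMI
reuse), or abundance distributions of real tissues. Green round-trip tests
establish that the decoder inverts the read architecture exactly and that
quantification is unbiased along the gene body under the stated noise
model — not that any particular wet-lab library will reach the same
numbers.
```{r}
library(combitag)
res <- run_pipeline(list(seed = 1, out_dir = tempfile("combitag_")))
res$report$demux$barcode_filtration_rate
coverage_bias_index(res$profile)
```
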