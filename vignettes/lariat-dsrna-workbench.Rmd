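---
title: "Methods: intron lariats, IR Alu elements, and cytoplasmic dsRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intron lariats, IR Alu elements, and cytoplasmic dsRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lariatdsrna)
```

`lariatdsrna` implements the computational machinery for asking two linked
questions: how much double-stranded RNA (dsRNA) can a transcript region form,
and how do intron lariats — which accumulate in the cytoplasm when the
debranching enzyme DBR1 is lost — deliver inverted-repeat (IR) Alu duplexes to
cytoplasmic dsRNA sensors. This vignette documents the models, the tunable
parameters, the synthetic-data conditions under which the package validates
itself, and the numerical and design choices a maintainer should know about.

## Composition-level structure potential

### The MBP metric

`mbp()` evaluates the maximum base pairing metric directly from base
proportions:

$$\mathrm{MBP} = 1 - \left[\max(A-U,0) + \max(C-G,0) +
  \bigl|\max(U-A,0) - \max(G-C,0)\bigr|\right]$$

It answers: if we could pair bases freely (A–U, C–G, and the G–U wobble),
what fraction of this sequence's bases could be in a pair? It is an upper
bound on any structure a folding algorithm could predict, and — because it
ignores order entirely — it is invariant under sequence shuffling, which is
what makes it a useful composition-only null.

`mbp_matching_oracle()` computes the same quantity the hard way, as a maximum
matching over base counts: it enumerates every feasible number of G–U wobble
pairs and takes the best completion with A–U and C–G pairs. The test suite
proves the closed form against this oracle on the exhaustive grid of all
compositions with up to 40 bases (135,750 compositions). Two properties
deserve emphasis:

* **Wobble makes MBP strand-asymmetric.** `AAAATTCC` scores 0.5 while its
  reverse complement `GGAATTTT` scores 1.0 (the G's pair with the U's). The
  formula is implemented exactly as stated, asymmetry included; both values
  are pinned by the matching oracle in the tests.
* **Ambiguity handling.** `N` and other IUPAC codes are excluded from both
  numerator and denominator of all composition fractions. Sequences with any
  amount of ambiguity can still be scored here; the 5% ambiguity *filter*
  belongs to the read-mapping pipeline, not to composition scoring.

### k-mer full-pairing probability

`kmer_fully_paired_prob()` estimates the chance that a random k-mer drawn from
a sequence's composition could be fully paired, with k matched to the sensor
footprints (17, 22, 33 nt). The source analyses do not pin down the estimator,
so the package adopts the independence definition MBP^k as the default —
it is deterministic, monotone in both arguments, and exactly reproduces the
certainty limits (MBP = 1 gives 1 for every k; MBP = 0 gives 0). A Monte-Carlo
alternative (`method = "montecarlo"`: draw k bases i.i.d. from the
composition, test whether that draw's own matching saturates) is provided for
sensitivity analysis; for k = 2 the two definitions coincide in expectation,
which the tests use as a calibration point.

### Shuffles

`shuffle_sequence()` performs uniform mononucleotide permutation — the
neutral reading of "randomly shuffled". Dinucleotide-preserving shuffles are
deliberately out of scope: the downstream deviation statistic asks what
composition alone predicts, and a dinucleotide shuffle answers a different
question. All stochastic functions take an explicit integer seed and restore
the caller's RNG state.

## Structure statistics

### Folding is a contract, not a dependency

Every structure-consuming function accepts a `folder`: a function from a
sequence to a `fold_result` (dot-bracket plus energy). Production analyses
should wire a thermodynamic predictor (`rnafold_folder()` adapts any
RNAfold-compatible binary). The package ships `fold_builtin()`, a
Nussinov-style pairing-maximization dynamic program (minimum hairpin loop 3
nt, wobble allowed, energy surrogate −1 kcal/mol per pair, deterministic
traceback preferring an unpaired 5′ base and then the smallest pairing
partner). Tests validate it against exhaustive enumeration of all legal
structures on sequences up to 12 nt. Two consequences:

* absolute energies from the built-in folder are pair counts, not kcal/mol —
  usable for deviations and site counts, not comparable to RNAfold output;
* the dynamic program is cubic in length, so the built-in folder is intended
  for constructs up to a few hundred nt (the test suite folds up to ~800 nt
  introns once); the 5,000-nt `max_length` cap on
  `count_sensor_sites_for_regions()` matches the practical limit of
  thermodynamic predictors, and over-long regions are skipped and reported
  rather than silently dropped.

### Stretches and sensor sites

`extract_stretches()` splits a structure into maximal runs of consecutively
stacked pairs. The strict rule — *any* departure from perfect stacking,
including a single-nucleotide bulge, terminates a stretch — reflects the
dependence of dsRNA sensors on uninterrupted A-form helix. The paired-base
total is conserved exactly (tested against a stack-based oracle on 1,000
folded random sequences). `sensor_sites()` then applies the floor statistic
with the default panel OAS1 = 17 bp, RIG-I = 22 bp, PKR = 33 bp. Both raw and
length-normalized energies are carried through the region table since either
may be wanted in scatter summaries.

### Ensemble deviations

`ensemble_deviation()` folds a sequence and n = 10 shuffles (both
configurable) and reports `observed − mean(shuffled)`: more structure than
composition predicts is negative. The sign convention, ensemble size and
shuffle type are the quantities to hold fixed when comparing across studies.
A homopolymer is its own shuffle, so its deviation is exactly zero — a useful
smoke test. The acceptance suite builds 100 constructs `s + spacer +
revcomp(s)` (25-nt arms, 8-nt spacer), confirms a strongly negative sign
pattern, and confirms that re-shuffled constructs (same composition, no
planted repeat) show deviations balanced around zero.

## IR Alu cataloguing

Regions are classified by their Alu content: `NONE`, `SINGLE`, `MULTI_SAME`
(≥2 insertions, one element strand) or `IR` (≥2 insertions with both strands
present). Three choices matter:

* **Orientation is the element's annotated strand in genome coordinates.**
  IR status is a *disequality* between element strands, which is invariant to
  the host gene's strand, so gene strand is never consulted.
* **Assignment threshold.** The analyses' upstream data do not state an
  overlap rule, so ≥50% of the element's length is the stated, configurable
  default (`min_overlap_fraction`). An element can be assigned to several
  overlapping regions; nested and overlapping Alus count separately.
* **Real-genome reproduction is out of scope.** Published category counts
  depend on a specific genome build, annotation and repeat catalogue; the
  package validates category logic on planted synthetic annotations instead,
  where recovery must be exact.

## The lariat mapper

The pipeline stages and their defaults (all configurable on
`map_lariat_reads()`):

| stage | rule | default |
|---|---|---|
| ambiguity filter | non-ACGT(U) fraction ≤ threshold | 0.05 |
| genome prefilter | drop reads with any end-to-end alignment | constraint triple |
| 5′SS key | first k nt of each intron, exact, unique | k = 20 |
| prefix rule | retained prefix length ≥ minimum | 20 nt |
| branch alignment | ≤5 mismatches, ≤10% rate, ≤1 indel ≤3 nt | — |
| scoring | +1 match, −1 mismatch, −2 gap open, −1/gap base | — |

Design decisions:

* **The ≥20-nt rule applies to the retained prefix** (the segment that is
  re-mapped). The alternative reading — the removed suffix must be ≥20 nt —
  is available as `rule = "removed_suffix"` on `trim_for_branchpoint()`.
* **Map, then filter.** The aligner reports each locus's best-scoring
  alignment (gapless and single-indel variants compete by score) and the
  constraint triple is applied to that alignment afterwards. Filtering
  *during* the search would let a worse-scoring in-budget variant stand in
  for a locus whose true best alignment is out of budget, silently rescuing
  reads that a score-driven aligner would discard.
* **Same gene, inverted order.** Candidates must lie in the 5′SS hit's gene,
  on its strand, with the branch segment downstream of the intron's 5′SS in
  transcription orientation and the called base inside the intron. Ties are
  broken by score, then smallest genomic start, then intron id; the
  branchpoint is the final aligned base in transcription orientation.
  Minus-strand genes are handled by reverse-complementing once at index and
  simulation time; no reverse-complement key search is done in reads (a
  stranded library protocol is assumed, as in the source experiments).
* **The built-in aligner** is an exhaustive seed-and-verify design (fixed
  12-nt exact seeds, pigeonhole count `mismatches + indels + 1`, vectorized
  verification of the gapless and every single-indel placement), intended for
  synthetic genomes up to a few Mb. External alignments can be ingested as a
  SAM subset for the prefilter stage instead.

Quantification reports both raw read counts and unique branchpoint counts per
intron (both interpretations of "lariat reads" are defensible; emitting both
costs nothing), normalized per million mapped reads, with fold changes between
libraries using a configurable pseudocount (default 0; division by zero is
reported as `Inf` and flagged, never imputed).

## Alu hybridization trials

`run_hybrid_trials()` emulates the annealing of a mixed pool of sense and
antisense Alu transcripts: 10,000 weighted draws (with replacement) of one
plus-pool and one minus-pool member, a duplex prediction per sampled pair, and
sensor-site tallies over the duplex's stretches. The hybridizer is injected
like the folder; the built-in one maximizes non-crossing intermolecular pairs
by dynamic programming, so two exact reverse complements of length L give a
single perfect stretch of L pairs and exactly `floor(L/threshold)` sites per
sensor. Hybridizations are memoized per member pair (pools are small; trials
are many). Failed hybridizations are excluded from the summary and tallied —
the conservative reading of how failed trials should be handled.

## RIP-seq quantification

`rpkm_table()` and `rpkm_to_tpm()` implement the standard normalizations
(RPKM = count / (length/1e3) / (total/1e6); TPM rescales RPKM to sum to 1e6
per library). `ir_alu_enrichment()` is the mean over IR Alu insertion sites of
the per-site IP/total coverage ratio; the direction of the ratio is exposed as
an argument because axis conventions for "enrichment" differ, and sites with
zero denominator coverage are excluded and counted rather than imputed.
`intron_vs_utr_expression()` compares summed intron TPM to summed 3′UTR TPM
within each Alu category. Strand-aware counting is assumed done upstream; this
module consumes count tables.

## The synthetic-data generator

`make_genome()` builds single-chromosome genomes of genes (5′UTR / exon /
intron / exon / 3′UTR, alternating strands) separated by intergenic
background, with each intron's Alu content planted per plan from the bundled
282-nt consensus Alu — the forward copy on the `+` element strand, the
reverse complement on `-`, so IR introns contain a perfect-complement pair of
the full consensus length (an optional per-base mutation rate emulates
genetic drift between copies). Default region sizes (150-nt exons, 100/300-nt
UTRs, 800–1,500-nt introns) are ordinary human gene proportions at desk
scale.

Two guarantees underpin exact parameter recovery:

* **k-mer uniqueness.** After assembly, background windows are resampled until
  no 20-mer occurs twice in either orientation (`duplicate_kmer_positions()`
  validates this post hoc). Planted Alu copies are exempt — repeated and
  reverse-complemented k-mers are the biological point of the insertions — so
  the uniqueness property, and the exact-recovery claims that rest on it, are
  stated for Alu-free genomes.
* **Genuinely chimeric junction reads.** `simulate_lariat_reads()` constructs
  each read as the branch segment (genomic bases ending at the branchpoint,
  transcription orientation) followed by the intron's first 20 nt. When the
  generator chooses the branchpoint itself (default: 30 nt upstream of the
  intron's 3′ end, the neighborhood where real branchpoints concentrate), it
  walks the position upstream until the clean junction read has no end-to-end
  genomic alignment under the mapper's own tolerance — otherwise a genome
  region that happens to resemble the 5′SS key would make the prefilter
  legitimately discard the read. A caller-pinned branchpoint is used exactly
  as given.

Noise is applied to the branch segment only: an exact number of substitutions
at random positions, and at most one indel planted in the segment's central
half — an edge indel is indistinguishable from a shorter indel plus a trimmed
flank, which would blur the constraint boundary the simulations probe.

Count simulation (`simulate_counts()`, `simulate_ip_coverage()`) uses a
hierarchical model of the generator's own choosing (no count model is given in
the source): total-library counts are negative-binomial with mean
`expression × length/1e3` and size 100 (site-level coverage defaults to mean
300), and IP counts resample the same molecule pool as
`Poisson(enrichment × total)` with the planted enrichment (default 2.2, the
middle of the 2–2.5× range the J2 immunoprecipitation analyses report) applied
at IR regions. Conditioning the IP draw on the realized total makes the
per-site IP/total ratio unbiased for the planted enrichment — which is what
the mean-ratio statistic estimates — while `noise = "none"` gives the
deterministic limit for exact tests.

### What the generator does and does not emulate

It emulates the *statistical geometry* the pipeline depends on: unique 5′SS
keys, inverted segment order, constraint-bounded noise, orientation-coded Alu
insertions, and IP enrichment concentrated at IR sites. It does not emulate
Alu subfamily structure, splice-site motifs, branchpoint sequence preferences,
position-dependent sequencing error profiles, or fragment-length effects.
Passing tests therefore demonstrate algorithmic correctness under controlled
conditions, not performance on real libraries — where repetitive sequence and
alignment ambiguity, deliberately excluded here, dominate the error budget.

## Numerical choices and problem sizes

* Coordinates are 0-based half-open internally; 1-based only at GTF file
  boundaries. All matching happens in transcription orientation.
* Mismatch-rate comparisons use a 1e-9 slack so that exact-boundary cases
  (e.g. 10% exactly) are retained, immune to floating-point representation.
* The test suite uses: the exhaustive ≤40-base composition grid (~136k
  cases); a 2-Mb Alu-free genome with 10 genes and 500 noise-free reads
  (100% exact branchpoint recovery, plus zero calls for 6-mismatch, 4-nt
  indel, and 19-nt prefix violations); 100 inverted-repeat constructs of
  58 nt with 10-shuffle ensembles; 10,000 hybridization trials over 5-member
  pools (chi-square goodness of fit at alpha = 0.001); and 1,000 coverage
  sites for enrichment recovery within three standard errors. These sizes
  were chosen so the full suite completes in a few minutes while every
  stochastic check retains conventional power.

## Known limitations

* The built-in folder maximizes pair counts; it has no thermodynamics, no
  dangles, no coaxial stacking, and its deviations are in pairs, not
  kcal/mol. Wire a thermodynamic predictor for publication-grade folding.
* The built-in aligner is exhaustive by design and sized for synthetic
  genomes (few Mb); it is not a general-purpose read aligner and does not
  implement FM-index search, quality-aware scoring, or paired-end logic.
* Absolute reproduction of published distributions (MFE distributions, real
  IR Alu category counts, real enrichment values) requires the original
  genome builds, annotations and deposited libraries and is explicitly out of
  scope; the in-package checks cover the formulas, the algorithms and their
  boundary behavior.
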