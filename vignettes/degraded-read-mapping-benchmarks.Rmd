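---
title: "Benchmarking read-mapping parameters for degraded DNA with mapsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking read-mapping parameters for degraded DNA with mapsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

DNA from ancient, historical or otherwise degraded specimens arrives as
short fragments (tens of bp), carries terminal deamination damage (cytosine
read as thymine near the 5' end, complementarily G>A near the 3' end on
double-stranded libraries), is often diverged from the nearest available
reference genome, and is swamped by contaminant molecules from humans,
domestic animals, bacteria and fungi. Mapping such reads is a trade-off:
relaxing the aligner's mismatch stringency recovers more endogenous
fragments, but may let contaminants map too. Which parameter combination is
best depends on the dataset — fragment lengths, divergence to the
reference, and the contaminant spectrum — so it should be measured, not
guessed.

mapsweep measures it. It simulates a read set whose properties mirror a
real dataset of interest, with the true origin of every read recorded; runs
an arbitrary external mapper over every combination of candidate parameter
values; and classifies each read's primary alignment against its truth
record. Because the truth is known, the three quantities that matter are
directly computable per run:

* **sensitivity** — the fraction of all endogenous reads mapped to their
  true coordinates;
* **specificity** — the fraction of all contaminant reads that fail to map;
* **false-positive rate (FPR)** — mapped contaminant reads over all mapped
  reads.

## The simulation model

Reads are generated source by source. A *source* is one genome (multi-FASTA
of any assembly) with a role — endogenous or contaminant — a mixture
fraction, a divergence rate, and an optional damage profile.

**Composition** is exact, not multinomial: each source receives
`floor(n_reads * fraction)` reads and the shortfall is assigned by largest
remainder. A declared 26% endogenous fraction is therefore realized to the
read, which keeps the denominator of every metric exactly known.

**Fragment length** is `min_length + floor(X)` with
`X ~ Exponential(mean = decay_length)` — the standard exponential-decay
model for degraded DNA fragmentation. We interpret the decay length as the
mean of the exponential tail above the minimum (the scale parameter); with
`min_length = 30` and `decay_length = 15` the expected read length is
`30 + exp(-1/15)/(1 - exp(-1/15)) ≈ 44.53` bp. Lengths longer than every
contig of the source are redrawn (bounded, default 100 attempts) rather
than truncated, which would bias the tail.

**Placement** is uniform over all valid (contig, start) positions
genome-wide: a contig of length L can host a fragment of length len at
`L - len + 1` starts and is weighted accordingly, so fragments never span
contig boundaries by construction. Strand is +/- with probability 1/2.

**Divergence** models the evolutionary distance between the simulated
target and the mapping reference: each A/C/G/T base is independently
substituted with the given probability by one of the other three bases,
uniformly. We deliberately use no transition/transversion bias — a
dataset-specific substitution model would be a refinement, and the uniform
model is symmetric under reverse complement, which keeps strand handling
simple. Divergence is applied in fragment (plus-strand) orientation, before
reverse-complementing minus-strand fragments.

**Damage** is applied last, in read orientation, because measured damage
profiles (e.g. mapDamage's per-position frequency tables) are defined on
sequenced reads: position i from the 5' end turns C into T with probability
`ct5[i]`, position j from the 3' end turns G into A with probability
`ga3[j]`. Profiles can be parsed from mapDamage output or built
parametrically (`geometric_profile()`: terminal probability `p0` decaying by
a constant factor per position, mirroring the exponential fall-off of
deamination away from fragment ends). The 5' rule is evaluated first; since
it only converts C to T and the 3' rule only examines G, the rules never
compete for a base. Contaminant sources default to undamaged — damage can
be attached per source when contaminants are themselves degraded.

The truth table (TSV: read id, source, role, contig, 0-based half-open
start/end, strand, length) is written alongside the FASTQ. Read names are
opaque serials; the truth table, not the name, carries provenance, so
contig names with unusual characters can never break parsing. All base
qualities are a single constant character (default 'I', Phred 40): the
package does not model sequencing error separately from damage, and a
constant quality makes that explicit.

A single integer seed drives the whole generation; two runs from one
configuration are byte-identical.

## The sweep

Candidate parameter values are declared as an ordered grid, e.g.

```yaml
grid:
  "n": ["0.04", "0.01", "0.004", "0.001", "0.0004", "0.0001"]
  "l": ["8", "16", "32", "64", "1000"]
```

(the keys are quoted because bare `n`/`y` are YAML booleans). The sweep is
the full Cartesian product — here 6 x 5 = 30 runs — in lexicographic order
of the declared parameter order. Values are passed as verbatim text, never
coerced through numbers, so `0.0001` or a seed length of `1000` (larger
than any fragment, i.e. seeding disabled) render into the mapper call
exactly as written.

The mapper is fully external and user-declared through a command template
with `{placeholders}`:

```yaml
mapper:
  template: >-
    bwa aln -n {n} -l {l} {reference} {reads} > {output}.sai &&
    bwa samse {reference} {output}.sai {reads} > {output}
  setup: "bwa index {reference}"
```

Any tool that reads FASTQ and writes SAM fits this contract; no
mapper-specific logic exists in the package. The setup command runs once
before the sweep (indexing does not depend on the swept parameters) and
must succeed; individual run failures are recorded in the manifest and
flagged in the report rather than aborting the sweep. Wall time and child
CPU time are both recorded per run, since either may be the relevant cost
of a stringency choice.

## Evaluation

Only primary alignment records count (secondary 0x100 and supplementary
0x800 flags are ignored; if a mapper emits several primary-looking records
for one read, the first wins — a documented tie-break, since SAM emitters
differ). A truth read absent from the SAM is scored unmapped, because many
mappers omit unmapped reads. SAM's 1-based leftmost coordinate is converted
to the package's internal 0-based, half-open convention at this boundary
and nowhere else.

An endogenous read is **correct** when contig and strand match the truth
and the reported leftmost position is within `tolerance` bases of the true
fragment start. The default tolerance is 0: without simulated indels, a
correct gapless alignment's leftmost base equals the fragment start
exactly. Mappers that soft-clip damaged read termini shift the reported
position, so a tolerance of at least 5 is advisable whenever clipping is
possible; for minus-strand truth the comparison is still leftmost-to-
leftmost, as both coordinates are leftmost by construction. A contaminant
read is a false positive wherever and however it maps.

Each run is scored twice: over all reads, and after treating mapped reads
with MapQ below a threshold as unmapped. The filter keeps reads with
`mapq >= threshold`, default 30 — stated as "keeps", because "removing
below" and "keeping above" disagree at the boundary and the boundary
matters for reproducibility. The report has one row per (run, filter
state), with class counts, the three metrics, a mapped-bases column (sum of
read lengths of mapped reads — a coverage proxy), runtimes, and, when a
baseline run is named, fold-change columns for mapped reads, sensitivity
and mapped bases relative to that baseline at the same filter state.

## The built-in testbed

Two fixtures make the full loop verifiable offline:

* `generate_genome()` — i.i.d. random genomes with chosen GC content,
  deterministic per seed. On a 100 kb random genome, 30-mers are unique
  with overwhelming probability, so a read simulated without divergence or
  damage has exactly one placement.
* `oracle_align()` — an exhaustive gapless aligner: every read is compared
  at every position of every contig on both strands, keeping hits with at
  most `max_mismatch` mismatches. A unique best hit is emitted with MapQ
  60; tied best hits are emitted at the first tied position in scan order
  with MapQ 0 (the 60/0 convention is arbitrary but fixed, and exercises
  the MapQ filter); no hit yields an unmapped record. It is O(genome x
  reads) on purpose — correctness is transparent, speed is not the point —
  and is usable through the sweep's command template like any external
  mapper, with `max_mismatch` as a sweepable parameter.

On this testbed the pipeline has exact expectations: simulating without
divergence or damage and aligning with `max_mismatch = 0` must give
sensitivity 1 and specificity 1 (up to k-mer collisions, which the tests
check for explicitly rather than assume away); relaxing `max_mismatch` can
only add hits, so mapped counts and sensitivity are non-decreasing — the
testbed analogue of the empirical finding that relaxing a mapper's
mismatch stringency raises sensitivity. The test suite also recovers the
generator's own parameters from simulated output (divergence rate, terminal
damage probability, mean fragment length) within four-standard-deviation
bands, and cross-checks the aligner against an independent quadratic-time
re-scan on sub-kilobase instances.

What the testbed does *not* emulate: real genomes' repeat structure and
base composition (random genomes have no repeats, so ambiguous placements
are far rarer than in practice), indels (not simulated; a future
refinement), sequencing-error profiles distinct from damage, library-
preparation biases, and paired-end layout. Passing the testbed therefore
demonstrates the bookkeeping — composition, coordinates, classification,
metric arithmetic — not that any particular real mapper is well tuned;
conclusions about a real dataset come from running the sweep on that
dataset's own reference genomes and composition estimates.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so
the whole suite completes in minutes while keeping the statistics sharp:
fixture genomes of 8-200 kb, read sets of 150 to 10,000 for end-to-end
loops, and 100,000 reads for parameter-recovery checks (at that size the
four-standard-deviation bands are a fraction of a percentage point wide).
Monte-Carlo assertions use fixed seeds and 4-sigma bands; the
length-distribution goodness-of-fit uses a chi-square over the binned
geometric tail (the floored exponential is geometric with
`p = 1 - exp(-1/decay_length)`). Composition fractions must sum to 1
within 1e-9; probabilities are validated to [0, 1]; degenerate inputs have
defined behaviour (zero reads yield an empty FASTQ and header-only truth
table; an all-unmapped run reports sensitivity 0, specificity 1 and an
undefined FPR, written as NA rather than 0, since 0/0 is a statement about
the data, not about the mapper).

## Configuration dialect

All stages share one YAML configuration (`validate_config()` fills
defaults: MapQ threshold 30, tolerance 0, quality 'I'; every validation
failure names its section and key, and failures are aggregated so a config
is fixed in one pass). YAML was chosen as the configuration dialect because
it is the established, human-editable config format in the R ecosystem
with a mature parser; the structure — sources, simulation, mapper, grid,
evaluation — is what matters, not the surface syntax. Relative paths
resolve against the config file's directory, so a config and its genomes
travel together.

## Known limitations

* No indel simulation; evaluation is therefore exact-coordinate by default
  and mappers that open gaps need a nonzero tolerance.
* The divergence model is uniform per base; lineage-specific substitution
  spectra are not represented.
* One seed drives one sequential generator stream; reads are generated
  source by source, so per-source streams are not independently seedable.
* The exhaustive aligner is a correctness fixture; sweeping it beyond a
  few thousand reads by megabase of genome is slow by design.
* PCR duplicates, nucleotide-composition bias and quality-score models are
  out of scope; composition estimation (what fraction of a real library is
  endogenous) is an input, produced by tools built for that question.
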