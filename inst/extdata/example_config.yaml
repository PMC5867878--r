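# Example parameter-assessment config: a degraded sample mapped against a
# divergent reference, with a four-way endogenous/contaminant mixture
# (26% endogenous; 1% + 3% + 70% contaminants), minimum fragment length
# 30 bp with a 15 bp exponential decay tail, 5% divergence of the
# endogenous source from the mapping reference, and terminal C>T
# deamination damage. The grid sweeps BWA aln's mismatch value (n) and
# seed length (l); l = 1000 exceeds any fragment, i.e. disables seeding.
# Genome FASTAs are expected next to this file; generate fixtures with
#   mapsweep oracle-genome --out endo.fa --length 100000 --seed 11
# (and contaminant genomes with different seeds), or point the paths at
# real assemblies.
sources:
  - id: endo
    fasta: endo.fa
    role: endogenous
    fraction: 0.26
    divergence: 0.05
    damage: {p0: 0.3, decay: 0.5, positions: 15}
  - id: human
    fasta: contam_human.fa
    role: contaminant
    fraction: 0.01
  - id: dog
    fasta: contam_dog.fa
    role: contaminant
    fraction: 0.03
  - id: microbial
    fasta: contam_microbial.fa
    role: contaminant
    fraction: 0.70

simulation:
  n_reads: 5000
  min_length: 30
  decay_length: 15
  seed: 42
  quality_char: I

mapper:
  template: >-
    bwa aln -n {n} -l {l} {reference} {reads} > {output}.sai &&
    bwa samse {reference} {output}.sai {reads} > {output}
  setup: "bwa index {reference}"
  workdir: runs

# note: the key must be quoted -- bare n/y are YAML booleans
grid:
  "n": ["0.04", "0.004"]
  "l": ["32", "1000"]

evaluation:
  mapq_threshold: 30
  tolerance: 0
  baseline_run: run001
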