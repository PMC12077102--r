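---
title: "Recovering eukaryote genomes from metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering eukaryote genomes from metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microbial eukaryotes are a small minority of the DNA in most whole-genome
shotgun metagenomes, and reference databases cover them poorly. Classifiers
tuned for prokaryotes either discard eukaryotic reads or mislabel them, so
eukaryote genomes are routinely lost from metagenome-assembled genome (MAG)
catalogs. `eukmag` implements a recovery strategy built on two ideas:

1. **Never discard the unclassifiable.** Reads and contigs are routed into
   five categories — archaea, bacteria, viruses, eukaryotes, and *unknown* —
   and the union of the eukaryote and unknown fractions (the *EUnk* pool)
   is carried forward. A eukaryote absent from every database still ends up
   in the assembly, via the unknown route.
2. **Let orthogonal evidence decide at the contig level.** After assembly,
   a supervised binning step combines k-mer composition clusterings, read
   depth, rRNA/mitochondrial marker calls and nucleotide-alignment taxonomy
   to separate eukaryotic nuclear and mitochondrial contigs from leftover
   prokaryotic material.

## The routing model

Each item (read or contig) is classified in two stages.

**Stage 1 — k-mer classifier.** A hit is accepted when its `hit_length`
(query bases covered by matching k-mers, in bp) reaches a minimum: **40 bp
for reads, 100 bp for contigs and long reads**. When a classifier reports
several equal-score hits, the category is used only if all tied taxids agree
on it; otherwise the item stays unknown. This is deliberately conservative:
ambiguity keeps a sequence in the retained pool rather than excluding it.

**Stage 2 — alignment fallback.** Items still unknown are re-routed by
their best tabular-alignment hit, kept only if *e*-value ≤ 0.01, percent
identity ≥ 70 and query coverage ≥ 30% (all inclusive at the boundary; the
`lenient` preset — *e*-value 0.1, identity 50, coverage 10 — is a documented
stand-in for permissive searches against mismatched databases and warns on
use). The best survivor is chosen by bitscore, with ties broken by *e*-value
and then subject id so results are reproducible.

The short-read workflow runs stage 1+2 on reads, reconciles mate pairs
(a pair with exactly one retained mate becomes unknown, keeping pairs
together for assembly; a pair discordant between two excluded categories
keeps its per-mate labels, since both are excluded either way), assembles
the EUnk pool, drops contigs under **1,000 bp**, and reclassifies the
contigs with the contig profile. The fallback in round 2 runs on
classifier-unknown contigs only; `reclassify_all = TRUE` applies alignment
evidence to every contig instead — the original tooling is ambiguous on
this point, so both behaviors are exposed.

Read preparation trims both read ends with a sliding window (width 4,
minimum mean quality Q25), drops reads shorter than 40 bp after trimming,
and moves a surviving read whose mate died to the unpaired output. Adapter
removal and host-read subtraction are external-tool concerns and are not
re-implemented here.

## The binning model

Binning input is the EUnk contig set. Three composition clusterings are
computed — canonical (strand-symmetric) 4-mer, 5-mer, and concatenated
5+6-mer frequency vectors, each k block L1-normalized — because different
k ranges are differently sensitive to genome-specific composition signal.
The "5-6-mer" space is the concatenation of the 5-mer and 6-mer blocks:
that is the only reading that yields a single clustering per k-set. The
clusterer is a deliberate stand-in for heavier external binners:
standardize, project to ≤ 10 principal components, k-medoids with the
cluster count chosen by average silhouette width over k ∈ 2..min(10, n−1).
It is deterministic given the input and seed, and external cluster
assignments can be supplied as TSV to use a real binner's output instead.

A cluster is *flagged eukaryotic* when a strict majority of its
taxonomically labeled contigs are eukaryotic (labels come from the routing
category, falling back to the best nucleotide hit; unknown is
uninformative) or when it contains a eukaryotic SSU marker contig. A
contig is a *candidate* when it sits in a flagged cluster in **at least 2
of the 3** clusterings. Candidates then pass through the inclusion rules:

- **Depth cap.** Mean depth may not *exceed* (strictly) that of the SSU
  rRNA contig of the candidate set. Eukaryote rDNA arrays are multi-copy,
  so the SSU contig's apparent depth sits well above the single-copy
  average; prokaryotic contamination, typically at higher depth than a
  minority eukaryote, is cut off. Without an SSU contig the criterion is
  skipped with a warning rather than silently inverted.
- **Prokaryote hit.** The best nucleotide hit may not be a prokaryote or
  virus at > 90% identity over ≥ 1,000 aligned bp (a conjunction: a short
  strong hit or a long weak hit does not reject).
- **Taxonomic coherence.** A contig labeled by any source but never as
  eukaryotic is rejected; contigs with eukaryotic evidence from any source,
  or with no labels at all, are retained. A strictly conjunctive reading
  ("must be identified as eukaryotic") would discard every evidence-free
  contig and with it the reference-free recovery path, so coherence rather
  than positive proof is required.
- **Mitochondrial bin.** Contigs with a mitochondrial marker call **and** a
  mitochondrial best hit form the mitochondrial bin. Organelle genomes
  have their own composition and much higher copy number than the nuclear
  genome, so the mitochondrial bin is exempt from both the depth cap and
  the cluster consensus; requiring either would discard exactly the
  contigs the rule is meant to recover.

Marker calls are pre-filtered at aligned length > 300 bp and identity
> 90% (both strict). Retained contigs are grouped into nuclear bins by
connected components of the "shared a flagged cluster in ≥ 2 clusterings"
relation. Every rejected contig carries exactly one reason code
(`DEPTH_GT_SSU`, `PROK_HIT`, `CONSENSUS_LT2`, `CONFLICTING_TAXONOMY`), and
the bins plus rejections always partition the input — both properties are
re-asserted in the test suite.

Read depth can be supplied as a MetaBAT2-style jgi depth table or
estimated internally: each read goes to the contig maximizing k-mer
coverage (ties dropped), and mean depth is assigned read bases over contig
length — the same quantity a jgi table reports.

## The built-in classifier

The classifier database indexes every canonical k-mer (default k = 31,
odd, 11–31; canonical = lexicographic minimum of a k-mer and its reverse
complement, 2-bit encoded) of a set of reference sequences with taxids.
Classification reports, per query, the reference(s) maximizing the union
length of matched k-mer intervals — the same bp-denominated `hit_length`
semantics as the external classifier output it stands in for, verified
against a brute-force per-base coverage oracle in the tests. It is an
exact-match index, not an FM-index, and is meant for desk-scale databases
(megabases, not terabases).

## What the simulator emulates — and what it does not

The mock-community generator reproduces the benchmark design of a
staggered prokaryote background plus titrated eukaryote reads, with full
per-read ground truth. Defaults are the desk-scale study condition:

| parameter | default | why |
|---|---|---|
| background genomes | 10 × 500 kb | staggered mix, GC 0.35–0.65 |
| background abundances | log-spaced over 3 orders | "staggered molar amounts" |
| background reads | 200,000 | ≈ 30× top genome, ≈ 0 × bottom |
| eukaryote genome | 200 kb, GC 0.30 | composition-separable minority |
| mitochondrial replicon | 15 kb at 6× molar | organelle copy-number excess |
| rDNA locus sampling | 10× | collapsed multi-copy rDNA array |
| titration levels | 2k, 5k, 10k, 20k reads × 2 replicates | completeness-vs-depth trend |
| reads | 150 bp pairs, insert 350 ± 30, errors 0.002, Q30 | short-read defaults |

Genomes are drawn from genome-specific second-order Markov models with the
per-context GC pinned to the genome's target (so realized GC matches to
within a fraction of a percent) and log-normal dinucleotide bias (so
composition clustering has signal to learn). The eukaryote carries one
rDNA (SSU+LSU) locus sampled at 10-fold depth — emulating the collapsed
multi-copy rDNA arrays of real eukaryote assemblies, whose depth excess is
precisely what the SSU depth-cap criterion presumes; with a single-copy
rDNA the cap would sit at the noise level of low-coverage contigs and the
criterion would be meaningless. Ten single-copy genes and the
mitochondrial marker come from bundled templates that are **synthetic,
tagged sequences, not real rRNA or genes** — tests match them by identity,
not biology.

The classifier database indexes a contiguous 85% fragment of each genome:
complete reference coverage is unrealistic, and the uncovered remainders
feed a steady trickle of genuinely unknown reads through the EUnk path, in
both the background and the eukaryote.

The simulator does **not** model indels, quality decay along the read,
GC-coverage bias, repeats beyond the planted rDNA array, strain variation,
or chimeric assembly; the perfect-assembly fixture (truth-interval unions
split at coverage gaps, filtered at a minimum length) has no misassemblies
by construction. Passing tests therefore demonstrate that the routing and
binning logic implements its stated rules and recovers a planted genome
under clean conditions — not that the pipeline is robust to real
sequencing artifacts or assembler behavior.

## Evaluation metrics

Precision = TP/(TP+FP) and recall = TP/(TP+FN) over contig sets, at both
contig-count and base-pair weight (contig-level is primary; the
base-weighted figures are reported alongside because a single long contig
matters more than many short ones). NG50 is the length at which the
descending cumulative contig length first reaches half the reference
length, LG50 its rank; both are NA when the assembly never gets there.
Genome fraction is the unioned share of reference bases recovered —
overlaps count once. Weighted single-copy-gene completeness sums per-gene
fractional completeness (best local-alignment match per gene, tolerance
one mismatch per 100 aligned bases, minimum 100 matched bases to guard
against spurious short local hits) rather than counting presence/absence;
the exact correction formula behind the original score is not published,
so this fractional-sum reading is a documented interpretation.

## Numerical and design choices

- All thresholds are inclusive at their stated boundary values; the depth
  cap's "exceed" is strict, as are the marker filters (> 300 bp, > 90%).
- All randomized steps take an explicit seed (default 1234); clustering,
  simulation and the full pipeline are byte-reproducible at a fixed seed.
- m8 coordinates stay 1-based inclusive at the I/O boundary and are
  orientation-normalized on read (`q_start ≤ q_end`).
- FASTQ qualities are Phred+33 only; other encodings are rejected, never
  guessed. Gzip input is auto-detected by magic bytes.
- Degenerate clustering inputs: two contigs become singletons (k-medoids
  needs k < n); identical composition vectors collapse to one cluster with
  a warning.
- The mitochondrial taxid categorizes as eukaryotic in routing;
  mitochondrial separation is binning's job, not routing's.
- Problem sizes in the tests and the acceptance script are the desk-scale
  defaults above (8 communities of ~0.2M reads against a 5.2 Mb database);
  they were chosen so the full titration, ablation and metric suite
  complete on a single CPU in minutes while leaving every rule of the
  method exercised at its boundaries.
- The ≥ 99% eukaryote-retention / ≤ 1% contamination check is evaluated on
  the most complete community (top titration level): at the 2k-read level
  (~1× nuclear coverage) individual 1 kb contigs are ≥ 4% of recovered
  bases, so a per-community 99% bar is not meaningful there; the
  completeness trend across levels is checked by monotonicity instead.

## Known limitations

- The built-in clusterer is a stand-in; on real data MyCC-class binners
  (t-SNE + affinity propagation) will produce different, usually better,
  partitions. Supply their assignments via TSV when available.
- The depth cap assumes the rDNA array is collapsed (multi-copy). For
  organisms or assemblers where rDNA resolves into separate copies at
  single-copy depth, the cap can reject valid contigs; it can be
  overridden (`ssu_cap`) or skipped.
- The k-mer classifier is exact-match only; it has no notion of the
  mutation tolerance a spaced-seed or FM-index classifier achieves, so its
  sensitivity decays faster with evolutionary distance than the tools it
  stands in for.
- Marker identification in the pipeline consumes Metaxa2-style tables (or
  the simulator's truth-consistent fixtures); no HMM search is performed
  natively.
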