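---
title: "Methods: Hemiptera COI metabarcoding of honey eDNA"
author: "honeytrace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hemiptera COI metabarcoding of honey eDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honeytrace)
```

## The problem

Honeydew honeys — and, it turns out, most blossom honeys — contain DNA of
the plant-sucking insects (order Hemiptera: aphids, planthoppers, true
bugs) whose sugary excretions the bees foraged. A short mitochondrial COI
fragment amplified directly from honey DNA therefore carries an
*entomological signature*: which honeydew producers contributed, roughly in
what proportion, and even which within-species mitochondrial haplotypes
(mitotypes) were present in the foraging area. honeytrace implements that
analysis as a reusable, fully testable pipeline: in-silico amplicon
extraction from a taxonomy-annotated COI reference set, read QC, threshold
taxonomic assignment, categorical community profiling, and mitotype calling
— plus a simulator that generates honey-like amplicon libraries with known
ground truth, so the entire pipeline is validated without any external
sequencing data.

## Reference amplicons (in-silico PCR)

The degenerate primer pair (forward `TGGAWCAGGAACAGGATGAAC`, reverse
`AAATGAARTTGATTGCTCCTA`, written 5'→3' on sense and antisense strands
respectively) targets a 135–140 bp COI fragment conserved across the main
plant-sucking Hemiptera families. `extract_amplicon()` scans both strands
of each reference record for a forward-primer site followed, within a
100–200 bp span, by a site matching the reverse complement of the reverse
primer, and keeps the 5'-most valid product. Primer matching is
IUPAC-aware Hamming distance only (default budget 2 mismatches): reference
sequences are high quality, and indel tolerance belongs to read alignment,
not site discovery. An `N` in the subject matches nothing, so
low-information reference positions cannot fake a site. Coordinates are
0-based, half-open, always on the stored (+) strand, with the amplified
strand recorded.

Taxonomy travels inside FASTA headers
(`accession|order|suborder|family|genus|species`), so the package needs no
external taxonomy service. The honey-bee host (*Apis mellifera*) is an
ordinary reference record flagged `is_host`: host reads are *assigned* and
then excluded from Hemiptera profiles, reproducing the bookkeeping in
which honey-bee reads are the complement of the Hemiptera reads rather
than a silent loss. The mismatch tolerance used by the original primer
design is not documented anywhere we could rely on; it is exposed as a
parameter (default 2) rather than claimed.

`build_database()` indexes the with-primers amplicons with an 11-mer
table. On a ~140 bp query at the 97% identity threshold an alignment has
at most ~5 edits, so by pigeonhole it must contain an exact 11-mer; seed
gathering therefore never discards a hit that could pass the thresholds.

## Read QC

Reads are primer-trimmed and oriented to the forward strand first (primer
search within 25 bases of either end), then end-trimmed: trailing windows
(default 10 bp) with mean Phred below 20 and trailing bases below 20 are
removed until neither rule applies — a fixpoint, which makes trimming, and
hence the retention decision, idempotent. Retention requires ≥ 50 bp and
mean quality ≥ Q20 after trimming. "Quality ≥ Q20" is interpreted as
*mean* read quality (the usual convention for Ion Torrent single-end
amplicon data); the per-window rule handles localized quality collapses.
Every input read lands in exactly one disposition bucket (retained /
too short / low quality), checked length-first.

## Taxonomic assignment

The assignment core is a banded semi-global aligner written for this
package (Rcpp): the full query is aligned within the target with free
leading/trailing target gaps, scoring +1 match, −1 mismatch, −2 per gap
position (linear). The band restricts the dynamic program to the corridor
`i − band ≤ j ≤ i + (n − m) + band`, which provably contains the optimal
path whenever its indel count is at most the band (default 16); the band
is widened automatically when it cannot connect the corners. Identity is
matching columns over *all* alignment columns (gaps count against, the
conservative BLAST-like convention); coverage is query bases aligned to
target bases over query length, so "95% coverage to 100%" reads as
coverage ∈ [0.95, 1] with 1 attainable — an upper bound below 100% would
exclude perfect hits and is not meaningful.

A read is assigned its best passing hit (identity ≥ 0.97, coverage
≥ 0.95). When two or more *species* tie within the score margin (default
0: exact ties), the read is assigned at the deepest rank shared by the
tied lineages — genus, else family, else left unassigned. This
lowest-common-ancestor fallback is our design; the published evidence for
it is the existence of genus-level ("*Cinara sp.*") and family-level
("*Aphididae spp.*") rows in real profiles. A tie that mixes the host and
a Hemiptera lineage has no meaningful shared rank and is left unassigned.
Raw alignment scores never drive biology directly — only the
identity/coverage thresholds do — which makes the decisions robust to the
particular scoring scheme at these divergences.

## Community profiles

Per-library taxon counts become fractions over the *Hemiptera-assigned*
denominator, and fractions become categorical labels: high > 30%, medium
5–30% (closed: both boundaries are medium), low < 5%. Read proportions in
amplicon metabarcoding are not quantitative (priming bias, PCR
stochasticity, unknown DNA content of honeydew), hence categories rather
than abundances; the package deliberately offers no diversity indices or
differential abundance on these data. The denominator choice matters: the
published category labels are only arithmetically consistent with the
Hemiptera-assigned denominator (e.g. a medium label at 14.6% of 1,011
Hemiptera reads would be low at 1.5% of all 10,054 sequenced reads), so
that is the default, with `denominator = "all"` exposed for the
alternative reading. `load_count_table()` drives the same profile code
from a pre-made per-species count table; the packaged
`extdata/table2_counts.tsv` ships the 13 published honey libraries in that
format, and `worked_example_report()` checks every printed percentage and
category label against what the profile code computes.

## Mitotype calling

Reads assigned to one species are aligned to that species' amplicon and
projected onto the insert (between-primers) region: read-relative
insertions are dropped, and a read with a deletion against the reference,
or one not spanning the full insert, is left *unplaced*. This asymmetric
treatment reflects the platform: single-base indels are the dominant Ion
Torrent error mode, while true mitotypes in this system differ by
substitutions only, so indels are evidence of error, not biology. Exact
insert sequences are the grouping key.

A candidate mitotype is **reliable** iff it has ≥ 20 supporting reads AND
(it matches a known haplotype exactly OR it reaches ≥ 5% of the species'
mitotypable reads). The sentence defining this rule admits a second parse,
`(≥20 AND known) OR ≥5%`; we fix the first as default because the 20-read
floor is explicitly the error-noise guard and should never be bypassable,
and expose the alternative via `precedence = "alternative"`. Fractions use
mitotypable (placed) reads as denominator, making the unplaced-read
accounting explicit.

Known haplotypes are typically defined over a longer reference region than
the amplicon; `project_haplotypes()` collapses them into equivalence
classes of identical insert sequence (summing database entry counts), so a
single called mitotype may legitimately correspond to several long-region
haplotypes. `make_projection_fixture()` reconstructs the canonical
situation in which 19 long-region haplotypes collapse to 11 amplicon
classes. Species are eligible for mitotype analysis when they top the
overall read count or reach ≥ 10 reads in ≥ 2 libraries.

## The simulator: what it emulates, and what it does not

`simulate_library()` draws each read's source multinomially — host first,
then species, then mitotype — takes the with-primers amplicon, reverse
complements it with probability 0.5 (fragment-ligation libraries read
either strand), applies the error model, and writes Phred+33 qualities
drawn from Normal(mean, sd) clamped to [2, 40], alongside a per-read truth
manifest. The error model draws substitutions per base and indels per base
with the indel rate multiplied (default ×3) inside homopolymer runs ≥ 3 —
the signature Ion Torrent failure mode. Defaults (substitution 0.005,
indel 0.005, quality mean 30, sd 5) are our stated defaults for a
PGM-like run, not published values: no per-run error estimates exist for
the original data.

`make_reference_fixture()` generates the study-like conditions the tests
run under: one reference set with planted exact primer sites, six species
(one of which carries two mitotypes), pairwise inter-species amplicon
identity < 0.97 (enforced as ≥ 6 insert differences, so the bound holds
with or without primers in the query), within-species mitotypes 1–2
substitutions apart (identity ≥ 0.97), a divergent honey-bee host record,
and a community of one dominant species (65%) plus minor species (15%, 8%,
4%, 4%, 4%) over a host background — mirroring the dominant-planthopper /
minor-aphids structure of real honeys. Every mitotype is deposited as its
own reference record, as public databases do.

What the simulator does *not* model: chimeras, PCR duplicates,
barcode/adapter read-through, quality values correlated with true errors,
taxon-specific amplification bias, and reference databases containing
unrelated or partially overlapping sequences. Passing tests therefore
demonstrate the correctness of the pipeline's logic under its stated error
model — not that real honey libraries are free of those additional
artefacts.

## Numerical choices and problem sizes

All randomness flows from one seed through R's generator; fixtures and
simulated libraries are bit-reproducible. Fraction sums are validated to
1e-9; category boundaries are closed as stated above and unit-tested
explicitly at 0.05/0.30. Alignment ties are broken deterministically
(smallest end position, diagonal-first traceback); candidate and profile
rows sort by count descending with lexicographic tie-breaks. Degenerate
inputs (empty batches, zero-denominator profiles, reads shorter than the
seed k-mer, bands too narrow to connect) return empty results, warnings,
or typed errors rather than propagating nonsense.

The validation suite runs at sizes chosen to make the statistics sharp but
the suite quick: 500 random pairs for the alignment oracle, 10,000 reads
for the zero-error round trip and the 1%-error fraction recovery (3
multinomial SE tolerance), 5,000 reads for the 85/15 two-mitotype mixture,
and 100 seeded replicates of 2,000 single-mitotype reads at 0.5%
substitution error for the reliability filter, which is required to
produce zero spurious reliable mitotypes in ≥ 95 of them.

A note on error rates and recovery: with a 0.97 identity threshold on a
~139 bp amplicon, a read carrying more than 4 edits cannot be assigned, and
at 1% per-base error that happens to ~1.4% of reads (binomial tail). Loss
is uniform across taxa, so community *fractions* remain unbiased — which
is what the recovery tests assert — but no implementation can assign ~99%
of reads under those conditions, and the package does not pretend to.

## Pipeline and configuration

`run_pipeline()` chains build-db → simulate/ingest → QC → assign →
profile → mitotypes, writing every stage's outputs plus a run manifest
(parameters, seed, package version, md5 of each file) into one directory;
identical config and seed reproduce identical bytes. Configuration is a
plain R list or a YAML file — YAML because it is the human-editable
config format with first-class R support in this stack — and every
parameter block is validated before any compute starts. A thin CLI
(`inst/cli/honeytrace`) exposes the same operations as shell subcommands;
the R functions remain the primary interface.

## Known limitations

- Assignment quality is bounded by the reference set: taxa absent from the
  database are at best assigned to a relative at a higher rank, at worst
  unassigned — the fundamental eDNA database-completeness caveat.
- Identity thresholds on a ~100 bp fragment cannot separate species less
  than ~3% divergent over the insert; such complexes surface as
  genus-level assignments.
- The reliability filter is tuned for substitution-dominated mitotype
  structure; a true mitotype defined by an indel would be systematically
  unplaced.
- Categorical abundance is deliberate; do not feed the fractions into
  quantitative downstream statistics.
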