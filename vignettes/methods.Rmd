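---
title: "Methods: barcode assignment, UMI clustering and duplicate marking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode assignment, UMI clustering and duplicate marking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umidemux)
```

# Scope and data model

`umidemux` processes multiplexed sequencing libraries in three stages:
routing reads to samples by barcode (inline or from index files), moving UMI
bases into read headers, and UMI-aware duplicate marking on coordinate-sorted
alignments. Reads are held as plain data frames (name, comment, bases,
Phred+33 qualities) and processed in bounded-size chunks streamed from disk,
so memory use is independent of file size. Gzip input is detected from the
leading magic bytes, never from the file extension. Alignments are held as
the eleven mandatory SAM columns plus a joined tag column, which round-trips
text SAM byte-exactly; BAM is converted through Rsamtools when present.

# Barcode assignment

## Distance model

An observed sequence $o$ is compared with a candidate barcode $b$ of equal
length by a generalized Hamming distance with three asymmetric rules:

* `N` in the **barcode** is a degenerate position and matches any observed
  base at zero cost (iCLIP-style degenerate barcodes);
* `N` in the **observed** read costs 1 — an unreadable base is evidence of
  nothing;
* an observed base with quality below `min_quality` (default Phred 10) is
  treated as `N`, i.e. costs 1 against any non-degenerate barcode position.

Unifying the quality rule with the `N` rule was a deliberate design choice:
one cost model covers both sources of uncertainty, and it makes the
distance's asymmetry explicit and testable. Published descriptions of
comparable tools do not pin down an exact N/quality cost model, so this one
is declared here as this package's own convention.

## Decision rule

Against a sample sheet, the read is assigned to the sample whose best
barcode minimises the distance $d$, subject to all of: $d \le$ `max_mm`
(default 1, common practice for 6-mers); the gap to the best *other* sample
is at least `min_gap` (default 1, so exact ties always unassign — a read is
never silently mis-assigned); and the minimum is achieved by exactly one
sample. Failing reads go to the unassigned output with an `ambiguous` flag
when a tie caused the rejection.

With barcodes at both ends of a pair, two per-end matches are reconciled by
strategy `BOTH` (both ends must agree on the sample; per-end mismatches
summed; the stringent option that exploits barcode redundancy for
specificity) or `EITHER` (the assigned end with fewer mismatches wins; equal
mismatches pointing at different samples unassign). When the sheet gives
each sample a distinct `end1:end2` barcode pair and a per-end barcode is
shared between samples, only the combination identifies the sample; the
package detects this combinatorial case automatically, matches each end
against the per-end barcode sets, and looks the pair up in the combination
table — `strategy` is then irrelevant.

The barcode sheet grammar (TSV; `|` joins alternative barcodes, `:` joins
the two ends) is likewise this package's own: upstream protocol descriptions
show such configurations only diagrammatically, so a concrete, documented
syntax had to be chosen. One grammar covers single barcodes, alternatives,
redundant PE barcoding and combinatorial dual coding.

# Read layouts

The technical prefix of a read is declared with the token grammar
`U<len>` / `B<len>` / `S<len>` (UMI, sample barcode — at most one per read —
and discarded spacer), concatenated left to right from base 1, e.g. `U4B6U4`
for a composite barcode. An `I<len>` token retains bases in place for exotic
designs. The remainder of the read after the token block is the biological
insert; `extra_clip` removes additional bases after the block (removed
entirely) and `extra_trim` removes bases from the read tail. UMI segments
are concatenated read-1-first, left to right — a fixed, documented order so
repeated runs and mates agree.

UMIs are appended to the canonical read name after a separator (default
`:`, which survives mappers that truncate names at whitespace), identically
on both mates, as required by mappers that insist on equal mate names.
Reads shorter than their layout are routed to the unassigned output with
everything else. **Unassigned reads are always written raw** — un-clipped,
un-annotated — so no information is destroyed for later rescue or debugging;
whether upstream tools write them clipped is unspecified, and raw is the
lossless choice.

# UMI-aware duplicate marking

## Position grouping

The duplicate-grouping key extends the conventional position-based scheme:
reference, strand, and *unclipped 5′ position* — the mapped start pushed
outward by leading soft/hard clips on the forward strand, or the rightmost
aligned base plus trailing clips on the reverse strand — so that reads
trimmed differently still canonicalise to the molecule's true 5′ end. Pairs
use both ends' keys, canonically ordered so mate order is irrelevant, and
live in a separate key space from single fragments: a pair and a fragment
are never duplicates of each other (the convention of the standard
position-only tools this module extends). Unmapped, secondary and
supplementary records pass through untouched. The UMI of a pair is the
single concatenated tag both mates carry in their shared name; comparing
per-mate UMI halves separately would be an alternative, but the concatenated
form is what the demultiplexing stage writes and is used as-is.

## Greedy frequency-ranked clustering

Within a position group, UMI counts are clustered greedily: sort UMIs by
descending count (ties broken lexicographically); repeatedly take the most
frequent unassigned UMI as a group representative and absorb every
unassigned UMI within `umi_max_mm` mismatches of it. The rationale: a
sequencing error in a UMI produces a rare variant one or two mismatches away
from an abundant parent, so frequency-ranked absorption attributes errors to
their parent while genuinely distinct UMIs — which are rarely within one
mismatch of each other when UMI space is large — stay separate. The greedy
scheme is deterministic, $O(k^2)$ in the number of distinct UMIs per
position group (small in practice), and standard in the field; a
network/adjacency-based clustering is a reasonable alternative and would
satisfy the same qualitative description, but greedy was chosen for
determinism and simplicity, and all tests pin its documented behaviour
(including the three-UMI case where `AAAA` absorbs `AAAT` but not `AATT`,
two mismatches from the representative).

With a **predefined UMI list** (kits that ship a fixed UMI set), each
observed UMI is instead assigned to the nearest list entry when that entry
is unique and within `umi_max_mm`; equidistant or too-distant UMIs
conservatively keep their own singleton group rather than being guessed
into a family.

`N` handling is a three-way policy: `MATCH` (default; `N` on either side
matches at zero cost), `MISMATCH` (any `N` costs 1), `DISCARD` (N-containing
UMIs are excluded from clustering and kept as singleton groups).

## Representative selection and metrics

Per UMI group exactly one member stays unmarked: highest sum of base
qualities (default), total mapped reference length, or a seeded random
draw; score ties always resolve to the lexicographically smallest read name,
so output is deterministic. All other members receive SAM flag 0x400 (both
mates of a pair together), or are dropped with `remove = TRUE`. Optical
duplicates (same tile, x/y within `pixel_distance` of the representative,
parsed from Illumina-style name fields 5–7) are counted separately and never
alter the primary metrics.

The metrics file reports `READS_EXAMINED` (fragments/pairs inspected),
`POSITIONAL_UNIQUE` ($U_{pos}$, what a position-only marker would keep),
`UMI_AWARE_UNIQUE` ($U_{umi}$), `DUPLICATES_MARKED`, `OPTICAL_DUPLICATES`
and `GAIN_PERCENT` $= 100,(U_{umi}-U_{pos})/U_{pos}$ — the fraction of
duplicate reads reassigned as unique molecules by UMI awareness, relative to
the position-only unique count. $U_{umi} \ge U_{pos}$ always, since UMI
clustering only ever subdivides position groups.

# The synthetic-library generator

The generators emulate the study conditions of high-duplication UMI-tagged
libraries (scRNA-seq, iCLIP) at desk scale, with complete per-read ground
truth (sample, molecule, UMI, copy index):

* sample barcodes are generated with pairwise Hamming distance $\ge 3$, so
  a single sequencing error can never make one sample's barcode look like
  another's — assignment truth is well-defined at `max_mm = 1`;
* PCR copy counts are $1 + \mathrm{Geometric}(1/\bar d)$ with mean
  `dup_mean` — heavy-tailed like PCR amplification, support $\ge 1$, one
  parameter. Defaults use `dup_mean = 5`, a high-duplication regime;
* errors are uniform substitutions at `error_rate` (no indels — the entire
  suite's barcode/UMI logic is substitution-based), injected after read
  construction;
* the aligned-library generator places loci 1000 bp apart on one reference,
  forward strand, with distinct UMIs per locus, so the true molecule count
  and positional-unique count are exact by construction;
* all randomness derives from the single `seed`; identical seeds give
  byte-identical files.

What the generator does **not** emulate: realistic transcriptome structure,
quality-score error profiles (qualities are constant), indels, chimeras, or
strand mixtures. Passing tests therefore demonstrate the correctness of the
assignment/clustering logic under its stated model, not robustness to every
artefact of real data.

# Numerical and degenerate-case choices

* At `error_rate = 0` the validation suite uses `umi_max_mm = 0`: with
  error-free UMIs there is no reason to tolerate mismatches, and molecule
  recovery is then exact. With random UMIs, two distinct molecules can land
  within one mismatch by chance, so at `umi_max_mm = 1` a tiny deterministic
  undercount is expected and accounted for in the tolerance of the
  error-rate checks. At 1% per-base UMI error and `umi_max_mm = 1`,
  molecule counts on $\ge 10^3$ simulated molecules stay within 2%
  relative error (dominated by the rare two-error UMIs that escape
  absorption).
* Empty inputs: an empty FASTQ yields an empty stream; empty sample sheets
  are an error; `compute_gain` requires $U_{pos} \ge 1$.
* Problem sizes in the test suite were chosen for thorough coverage at
  interactive speed: 50 randomized duplicate-marking libraries of up to a
  few hundred reads, 100 randomized demultiplexing runs, truth-recovery
  runs of 1000 molecules (about 5000 reads); the full suite runs in well
  under a minute.
* Determinism is asserted bit-exactly: two runs on identical input produce
  byte-identical outputs, including gzip streams and md5 sidecars.

# Known limitations

* Barcodes are fixed-length and fixed-position; variable-length or shifted
  barcode designs are out of scope (specialised debarcoding tools cover that
  niche), as are interleaved FASTQ, colorspace, BCL and CRAM inputs.
* Duplicate marking loads the alignment into memory; it is intended for
  desk-scale and per-chromosome workflows rather than multi-hundred-gigabyte
  BAMs.
* No consensus-sequence assembly from UMI families: duplicates are flagged
  or removed, never merged.
* All reads in one input are treated as a single library: read-group/library
  tags are not folded into the duplicate-grouping key. Process libraries in
  separate files if they must not be compared.
* Simultaneous use of an index file and an inline read-2 barcode is
  rejected as a configuration error; the semantics of mixing the two are
  undefined upstream and guessing would be worse than refusing.
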