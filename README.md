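# umidemux

Demultiplexing and UMI-aware PCR-duplicate marking for multiplexed
high-throughput sequencing libraries.

## The problem

Multiplexed libraries mix reads from many samples in one FASTQ file, each
read tagged with a fixed-length **sample barcode**. Protocols additionally
attach a random **unique molecular identifier (UMI)** to every DNA molecule
before PCR, so that after mapping, reads at the same position can be split
into biological duplicates (different UMIs, different molecules) and PCR
duplicates (same UMI). Real designs are messy: the barcode can sit inline at
the read start or arrive in a separate Illumina index file; paired-end reads
can carry the same barcode redundantly, different barcodes whose combination
encodes the sample, or a barcode on one end and a UMI on the other; and UMI
bases can flank the sample index inside one composite prefix. `umidemux`
handles all of these layouts end to end — demultiplexing, UMI extraction
into read headers, and UMI-aware duplicate marking on coordinate-sorted
SAM/BAM — plus a seeded synthetic-library generator with complete ground
truth, so every stage is testable without external data.

## The method in brief

**Barcode assignment.** A read's observed barcode *o* is compared with every
candidate barcode *b* by a generalized Hamming distance: a degenerate `N` in
*b* matches anything at zero cost; an `N` in *o* costs 1; an observed base
with Phred quality below `min_quality` is treated as `N`. The read is
assigned to the sample with minimal distance *d* only if *d* ≤ `max_mm`, the
runner-up sample is at least `min_gap` further away, and the minimum is
unique — ties are never broken arbitrarily. For redundant paired-end
barcodes, per-end matches are reconciled with strategy `BOTH` (ends must
agree; mismatches summed) or `EITHER` (closer end wins; conflicting ties
unassign).

**Read layouts.** The technical prefix of each read is described by a token
grammar: `U<len>` (UMI), `B<len>` (sample barcode), `S<len>` (discarded
spacer) — e.g. `U4B6U4` is a composite barcode with 4 random bases on each
side of a 6-base index. All technical bases are clipped from the output and
the concatenated UMI is appended to the read name (`name:UMI`), identically
on both mates.

**Duplicate marking.** Mapped reads (pairs) are grouped by reference, strand
/ orientation and *unclipped 5′ position* (mapped start adjusted outward by
soft/hard clips). Within each position group, UMIs are clustered greedily:
sorted by descending count, each unassigned UMI in turn becomes a
representative and absorbs all unassigned UMIs within `umi_max_mm`
mismatches. One read per UMI group keeps SAM flag 0x400 clear (best sum of
base qualities, ties by name); all others are flagged (or removed). The
headline statistic is the **UMI gain**

```
gain% = 100 · (U_umi − U_pos) / U_pos
```

where `U_pos` is the unique-read count a position-only duplicate marker
would report and `U_umi` the count after UMI subdivision — the percentage of
duplicate reads rescued as genuine molecules.

## Worked example

```r
library(umidemux)
dir <- tempfile("demo_"); dir.create(dir)

# 3 samples x 200 molecules, mean 5 PCR copies, 1% per-base error,
# 8-base UMI followed by a 6-base inline barcode
cfg <- sim_config(n_samples = 3, molecules_per_sample = 200, layout1 = "U8B6",
                  dup_mean = 5, error_rate = 0.01, seed = 42)
sim <- simulate_multiplexed_fastq(cfg, dir)

metrics <- demultiplex_run(sim$fastq1, sheet = sim$sheet, layout1 = "U8B6",
                           max_mm = 1, out_dir = file.path(dir, "demux"))
print(metrics)
#> demux_metrics: 2681 reads; 2675 assigned over 3 samples; 6 unassigned ( 0 ambiguous )
metrics$per_sample
#>  S01  S02  S03
#>  856  925  894
```

2681 reads were simulated (200 molecules × 3 samples, geometric copy
counts); at 1% base error with one mismatch allowed, 6 reads carry barcodes
mutated beyond rescue and land in `unassigned_1.fastq`, never silently
mis-assigned. Per-sample FASTQ files now have UMI-annotated headers, ready
for mapping. Downstream, on an aligned library:

```r
acfg <- sim_config(n_positions = 50, molecules_per_position = 10,
                   dup_mean = 5, error_rate = 0.01, seed = 43)
asim <- simulate_aligned_library(acfg, out_sam = file.path(dir, "sim.sam"))
res <- mark_duplicates(file.path(dir, "sim.sam"),
                       output = file.path(dir, "marked.sam"),
                       metrics_out = file.path(dir, "dup_metrics.tsv"),
                       umi_max_mm = 1)
print(res$metrics)
#> dup_metrics: 2486 examined; 50 unique by position; 510 unique with UMIs; 1976 duplicates; gain 920.00%

evaluate_against_truth(asim$truth, dup = res$metrics)
#> dedup: 500 molecules, 510 recovered (rel. err 0.0200); gain 920.00% (predicted 900.00%)
```

A position-only marker would keep 50 reads (one per locus); using UMIs, 510
of the 2486 reads are recognised as distinct molecules — within 2% of the
500 simulated — and the measured gain tracks the truth-table prediction.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/umidemux.R", package = "umidemux"))')
Rscript $CLI demultiplex --fastq1 lane1_1.fastq.gz --barcodes sheet.tsv \
    --layout1 U8B6 --max-mismatches 1 --out-dir demux/
Rscript $CLI markdupes --input sorted.bam --output marked.bam \
    --metrics dup_metrics.tsv --umi-max-mismatches 1
```

Subcommands: `demultiplex`, `demultiplex-illu`, `clip`, `markdupes`,
`simulate`; `--help` lists each option. Exit codes: 0 success, 2 usage
error, 1 runtime error.

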