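#' Configuration for the synthetic-library generators
#'
#' Bundles the parameters of the simulated experiment. Defaults emulate a
#' small UMI-tagged multiplexed library of the kind produced by scRNA-seq
#' or iCLIP protocols: a handful of samples with 6-base sample barcodes, an
#' 8-base UMI, heavy PCR duplication (geometric copy counts) and a low
#' per-base substitution error rate.
#'
#' @param n_samples number of multiplexed samples.
#' @param barcode_len sample-barcode length (bases). Barcodes are generated
#'   with pairwise Hamming distance >= 3 so single errors stay unambiguous.
#' @param umi_len total UMI length (bases), split across the `U` tokens of
#'   the layouts in order.
#' @param layout1,layout2 read layouts used to build the reads (see
#'   [parse_layout()]); `layout2 = NULL` for single-end libraries.
#' @param molecules_per_sample distinct molecules simulated per sample
#'   (FASTQ generator).
#' @param molecules_per_position distinct molecules per genomic position
#'   (alignment generator).
#' @param n_positions genomic positions (alignment generator).
#' @param dup_mean mean PCR copy count per molecule; copies are
#'   `1 + Geometric(1/dup_mean)`, a heavy-tailed model of amplification
#'   with support >= 1.
#' @param error_rate per-base substitution probability (no indels; the
#'   suite's barcode/UMI logic is substitution-based throughout).
#' @param read_len read length (bases).
#' @param seed integer seed fixing all randomness.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 4L, barcode_len = 6L, umi_len = 8L,
                       layout1 = "U8B6", layout2 = NULL,
                       molecules_per_sample = 100L,
                       molecules_per_position = 10L, n_positions = 50L,
                       dup_mean = 5, error_rate = 0, read_len = 50L,
                       seed = 1L) {
  stopifnot(n_samples >= 1L, barcode_len >= 1L, umi_len >= 0L,
            molecules_per_sample >= 0L, molecules_per_position >= 0L,
            n_positions >= 0L, dup_mean >= 1,
            error_rate >= 0, error_rate <= 1, read_len >= 1L)
  l1 <- if (is.character(layout1)) parse_layout(layout1) else layout1
  l2 <- if (is.character(layout2)) parse_layout(layout2) else layout2
  total_u <- l1$umi_len + if (is.null(l2)) 0L else l2$umi_len
  if (total_u != umi_len)
    stop("layout U tokens total ", total_u, " bases but umi_len is ", umi_len)
  if (l1$prefix_len > read_len ||
      (!is.null(l2) && l2$prefix_len > read_len))
    stop("layout longer than read_len")
  structure(list(n_samples = n_samples, barcode_len = barcode_len,
                 umi_len = umi_len, layout1 = l1, layout2 = l2,
                 molecules_per_sample = molecules_per_sample,
                 molecules_per_position = molecules_per_position,
                 n_positions = n_positions, dup_mean = dup_mean,
                 error_rate = error_rate, read_len = read_len,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = len)
  apply(m, 2L, paste, collapse = "")
}

#' Generate sample barcodes with guaranteed separation
#'
#' Random fixed-length barcodes with pairwise Hamming distance at least
#' `min_dist`, so that up to `floor((min_dist-1)/2)` errors can never make
#' one sample's barcode look closer to another's.
#'
#' @param n number of barcodes.
#' @param len barcode length.
#' @param min_dist minimum pairwise Hamming distance.
#' @return character vector of `n` barcodes.
#' @export
random_barcodes <- function(n, len, min_dist = 3L) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    cand <- random_dna(1L, len)
    ok <- all(vapply(out, function(b)
      sum(strsplit(cand, "")[[1L]] != strsplit(b, "")[[1L]]) >= min_dist, TRUE))
    if (ok) out <- c(out, cand)
    tries <- tries + 1L
    if (tries > 10000L * n)
      stop("cannot place ", n, " barcodes of length ", len,
           " at pairwise distance ", min_dist)
  }
  out
}

# geometric-with-support->=1 copy counts, mean = dup_mean
draw_copies <- function(n, dup_mean) {
  if (dup_mean == 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / dup_mean)
}

inject_errors <- function(seqs, rate) {
  if (rate == 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1L])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = L)
  hit <- which(stats::runif(length(m)) < rate)
  if (length(hit)) {
    # substitute with one of the three other bases, uniformly
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
    m[hit] <- vapply(m[hit], function(b)
      sample(alt[[b]], 1L), "", USE.NAMES = FALSE)
  }
  apply(m, 2L, paste, collapse = "")
}

# build read sequences from layout segments: U slices consume the molecule
# UMI left-to-right (read 1 then read 2), B is the sample barcode, S random
build_reads <- function(layout, barcode, umi, umi_offset, read_len) {
  n <- length(barcode)
  seg <- layout$segments
  parts <- character(n); parts[] <- ""
  off <- umi_offset
  for (i in seq_len(nrow(seg))) {
    piece <- switch(seg$type[i],
      U = substr(umi, off + 1L, off + seg$len[i]),
      B = barcode,
      S = random_dna(n, seg$len[i]),
      I = random_dna(n, seg$len[i]))
    if (seg$type[i] == "U") off <- off + seg$len[i]
    parts <- paste0(parts, piece)
  }
  insert_len <- read_len - layout$prefix_len
  paste0(parts, random_dna(n, insert_len))
}

#' Simulate a multiplexed FASTQ library with known ground truth
#'
#' Builds reads segment-by-segment according to the configured layouts: the
#' barcode of the read's true sample, a random UMI shared by all PCR copies
#' of a molecule, random spacer and insert bases. Per-base substitution
#' errors are injected over the finished read at `error_rate`. Everything is
#' deterministic under the configured seed.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param prefix basename prefix for the FASTQ file(s).
#' @param gzip write gzip-compressed FASTQ.
#' @return list with `fastq1` (and `fastq2` for paired layouts), `sheet`
#'   (the matching `sample_sheet`), `barcodes`, and `truth`: a data frame
#'   with one row per read -- `read` (name), `sample`, `molecule` (unique
#'   across the run), `umi` (error-free), `copy` and `duplicated`
#'   (`copy > 1`).
#' @export
simulate_multiplexed_fastq <- function(config, out_dir, prefix = "sim",
                                       gzip = FALSE) {
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paired <- !is.null(config$layout2)
  barcodes <- random_barcodes(config$n_samples, config$barcode_len)
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  sheet <- sample_sheet(samples, barcodes)

  n_mol <- config$n_samples * config$molecules_per_sample
  mol_sample <- rep(samples, each = config$molecules_per_sample)
  mol_umi <- random_dna(n_mol, config$umi_len)
  copies <- draw_copies(n_mol, config$dup_mean)

  mol_of_read <- rep.int(seq_len(n_mol), copies)
  copy_idx <- sequence(copies)
  n_reads <- length(mol_of_read)
  ord <- sample.int(n_reads)          # shuffle reads like a real lane
  mol_of_read <- mol_of_read[ord]; copy_idx <- copy_idx[ord]
  name <- sprintf("r%06d", seq_len(n_reads))

  truth <- data.frame(read = name,
                      sample = mol_sample[mol_of_read],
                      molecule = mol_of_read,
                      umi = mol_umi[mol_of_read],
                      copy = copy_idx,
                      duplicated = copy_idx > 1L,
                      stringsAsFactors = FALSE)

  bc_of_read <- barcodes[match(truth$sample, samples)]
  r1 <- build_reads(config$layout1, bc_of_read, truth$umi, 0L, config$read_len)
  r1 <- inject_errors(r1, config$error_rate)
  qual <- strrep("I", config$read_len)
  fq1 <- file.path(out_dir, paste0(prefix, "_1.fastq", if (gzip) ".gz"))
  write_fastq(read_record(name, r1, rep(qual, n_reads)), fq1, gzip = gzip)
  fq2 <- NULL
  if (paired) {
    r2 <- build_reads(config$layout2, bc_of_read, truth$umi,
                      config$layout1$umi_len, config$read_len)
    r2 <- inject_errors(r2, config$error_rate)
    fq2 <- file.path(out_dir, paste0(prefix, "_2.fastq", if (gzip) ".gz"))
    write_fastq(read_record(name, r2, rep(qual, n_reads)), fq2, gzip = gzip)
  }
  list(fastq1 = fq1, fastq2 = fq2, sheet = sheet, barcodes = barcodes,
       truth = truth)
}

#' Simulate a coordinate-sorted aligned library with known ground truth
#'
#' Emulates the input of the duplicate-marking stage: `n_positions` loci on
#' one reference; at each locus, `molecules_per_position` molecules with
#' distinct UMIs; per molecule, a geometric number of PCR copies, all
#' mapping to the same position on the forward strand. The observed UMI of
#' each copy (embedded in the read name after `separator`) carries per-base
#' substitution errors at `error_rate`; the truth table records the
#' error-free molecule UMI.
#'
#' @param config a [sim_config()].
#' @param out_sam optional path; when given the library is written there
#'   (SAM, or BAM with a `.bam` suffix).
#' @param separator UMI separator for read names.
#' @return list with `aln` (alignment list), `out_sam` (or `NULL`), and
#'   `truth`: per read `read` (final name), `locus`, `position`, `molecule`,
#'   `umi` (true), `umi_observed`, `copy`, `duplicated`; plus attributes
#'   `n_molecules` and `n_positions`.
#' @export
simulate_aligned_library <- function(config, out_sam = NULL, separator = ":") {
  set.seed(config$seed)
  n_mol <- config$n_positions * config$molecules_per_position
  locus <- rep(seq_len(config$n_positions), each = config$molecules_per_position)
  pos <- 1000L * locus
  # distinct UMIs within a locus so molecule counts are exact ground truth
  mol_umi <- character(n_mol)
  for (l in seq_len(config$n_positions)) {
    i <- which(locus == l)
    repeat {
      u <- random_dna(length(i), config$umi_len)
      if (!anyDuplicated(u)) break
    }
    mol_umi[i] <- u
  }
  copies <- draw_copies(n_mol, config$dup_mean)
  mol_of_read <- rep.int(seq_len(n_mol), copies)
  copy_idx <- sequence(copies)
  n_reads <- length(mol_of_read)

  umi_obs <- inject_errors(mol_umi[mol_of_read], config$error_rate)
  base <- sprintf("m%05d_c%03d", mol_of_read, copy_idx)
  qname <- paste0(base, separator, umi_obs)
  read_pos <- pos[mol_of_read]
  o <- order(read_pos, qname)

  ref_len <- max(pos) + config$read_len + 1000L
  reads <- data.frame(qname = qname[o], flag = 0L, rname = "chr1",
                      pos = read_pos[o], mapq = 60L,
                      cigar = paste0(config$read_len, "M"),
                      rnext = "*", pnext = 0L, tlen = 0L,
                      seq = random_dna(n_reads, config$read_len)[seq_len(n_reads)],
                      qual = strrep("I", config$read_len),
                      tags = "", stringsAsFactors = FALSE)
  aln <- list(header = c("@HD\tVN:1.6\tSO:coordinate",
                         paste0("@SQ\tSN:chr1\tLN:", ref_len)),
              reads = reads)
  truth <- data.frame(read = qname[o],
                      locus = locus[mol_of_read][o],
                      position = read_pos[o],
                      molecule = mol_of_read[o],
                      umi = mol_umi[mol_of_read][o],
                      umi_observed = umi_obs[o],
                      copy = copy_idx[o],
                      duplicated = copy_idx[o] > 1L,
                      stringsAsFactors = FALSE)
  attr(truth, "n_molecules") <- n_mol
  attr(truth, "n_positions") <- length(unique(truth$locus))
  if (!is.null(out_sam)) write_sam(aln, out_sam)
  list(aln = aln, out_sam = out_sam, truth = truth)
}

#' Write / read a truth table
#'
#' @param truth truth data frame from a simulator.
#' @param path TSV path.
#' @return `path` / the truth data frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
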