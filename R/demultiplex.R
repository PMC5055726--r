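#' @title Demultiplex inline-barcoded FASTQ files
#'
#' @description
#' Routes reads of a multiplexed FASTQ file (or file pair) to per-sample
#' output files. The sample barcode is sequenced at the start of the read
#' ("inline"), possibly mixed with UMI bases into a composite prefix; the
#' whole technical block is clipped off the output reads and any UMI bases
#' are appended to the read header, ready for UMI-aware duplicate marking
#' downstream.
#'
#' Paired-end designs are declared through the two layouts: a `B` token in
#' one layout (barcode on that end only), or in both (redundant or
#' end-specific barcoding; see `strategy`). When the sample sheet gives a
#' distinct barcode per end and per-end barcodes are shared between samples,
#' the end-1/end-2 barcode \emph{combination} identifies the sample
#' (combinatorial indexing) and `strategy` is ignored.
#'
#' Unassigned reads are written raw (untrimmed) to the unassigned files so
#' that no information is lost for rescue or debugging.
#'
#' @param fastq1 path to the read-1 FASTQ (optionally gzipped).
#' @param fastq2 optional path to the read-2 FASTQ for paired-end input.
#' @param sheet a `sample_sheet` (see [read_sample_sheet()]).
#' @param layout1,layout2 layout strings or `read_layout` objects (see
#'   [parse_layout()]); `layout2` only for paired-end input.
#' @param strategy how to reconcile two per-end matches: `"BOTH"` (ends must
#'   agree; the default, exploiting redundancy for specificity) or
#'   `"EITHER"` (best end wins).
#' @param max_mm maximum barcode mismatches per end.
#' @param min_gap minimum mismatch gap to the runner-up sample.
#' @param min_quality bases below this Phred quality are treated as `N`
#'   when matching barcodes.
#' @param extra_clip,extra_trim additional bases removed after the technical
#'   block / off the read tail (see [extract_segments()]).
#' @param separator character between read name and UMI in output headers.
#' @param out_dir output directory (created if needed).
#' @param gzip,md5 output compression / checksum sidecars.
#' @param chunk_size records processed per streaming chunk.
#' @return a `demux_metrics` object (also written to
#'   `<out_dir>/demux_metrics.tsv`): per-sample read counts, unassigned and
#'   ambiguous counts, and the total. Counts are per input read (pair).
#' @export
demultiplex_run <- function(fastq1, fastq2 = NULL, sheet, layout1,
                            layout2 = NULL,
                            strategy = c("BOTH", "EITHER"),
                            max_mm = 1L, min_gap = 1L, min_quality = 10L,
                            extra_clip = 0L, extra_trim = 0L,
                            separator = ":", out_dir,
                            gzip = FALSE, md5 = FALSE,
                            chunk_size = 100000L) {
  strategy <- match.arg(strategy)
  if (is.character(layout1)) layout1 <- parse_layout(layout1)
  if (is.character(layout2)) layout2 <- parse_layout(layout2)
  paired <- !is.null(fastq2)
  if (!paired && !is.null(layout2)) stop("layout2 given without fastq2")
  if (is.null(layout2)) layout2 <- parse_layout(NULL)
  b1 <- layout1$blen > 0L; b2 <- layout2$blen > 0L
  if (!b1 && !b2)
    stop("no sample-barcode (B) token in any layout; use clip_run() for ",
         "UMI extraction without demultiplexing")
  if (b2 && !paired) stop("layout2 declares a barcode but no fastq2 given")
  if (b1 && layout1$blen != sheet$blen1)
    stop("read-1 barcode length (", layout1$blen, ") does not match sheet (",
         sheet$blen1, ")")
  blen2_expected <- if (sheet$dual) sheet$blen2 else sheet$blen1
  if (b2 && layout2$blen != blen2_expected)
    stop("read-2 barcode length (", layout2$blen, ") does not match sheet (",
         blen2_expected, ")")
  if (sheet$dual && !(b1 && b2))
    stop("sheet declares end-specific barcodes but layouts do not put a ",
         "barcode on both ends")

  assign_fun <- function(ex1, ex2) {
    if (b1 && b2) {
      if (sheet$combinatorial) {
        cand1 <- data.frame(sample = unique(unlist(sheet$end1)),
                            barcode = unique(unlist(sheet$end1)))
        cand2 <- data.frame(sample = unique(unlist(sheet$end2)),
                            barcode = unique(unlist(sheet$end2)))
        m1 <- assign_sample(ex1$barcode, cand1, ex1$barcode_quals,
                            max_mm, min_gap, min_quality)
        m2 <- assign_sample(ex2$barcode, cand2, ex2$barcode_quals,
                            max_mm, min_gap, min_quality)
        combo <- combo_lookup(sheet)
        key <- paste0(m1$sample, ":", m2$sample)
        sample <- ifelse(!is.na(m1$sample) & !is.na(m2$sample),
                         unname(combo[key]), UNASSIGNED)
        data.frame(sample = sample,
                   mismatches = m1$mismatches + m2$mismatches,
                   observed = paste0(m1$observed, ":", m2$observed),
                   ambiguous = m1$ambiguous | m2$ambiguous,
                   second_best_gap = pmin(m1$second_best_gap,
                                          m2$second_best_gap),
                   stringsAsFactors = FALSE)
      } else {
        m1 <- assign_sample(ex1$barcode, sheet_candidates(sheet, 1L),
                            ex1$barcode_quals, max_mm, min_gap, min_quality)
        m2 <- assign_sample(ex2$barcode,
                            sheet_candidates(sheet, if (sheet$dual) 2L else 1L),
                            ex2$barcode_quals, max_mm, min_gap, min_quality)
        combine_pair_matches(m1, m2, strategy)
      }
    } else if (b1) {
      assign_sample(ex1$barcode, sheet_candidates(sheet, 1L),
                    ex1$barcode_quals, max_mm, min_gap, min_quality)
    } else {
      assign_sample(ex2$barcode, sheet_candidates(sheet, 1L),
                    ex2$barcode_quals, max_mm, min_gap, min_quality)
    }
  }

  stream_pipeline(fastq1, fastq2, layout1, layout2, extra_clip, extra_trim,
                  separator, out_dir, gzip, md5, chunk_size,
                  samples = sheet$samples, assign_fun = assign_fun)
}

# combo "b1:b2" -> sample lookup for combinatorial dual-coded sheets
combo_lookup <- function(sheet) {
  combos <- mapply(function(b1, b2) as.vector(outer(b1, b2, paste, sep = ":")),
                   sheet$end1, sheet$end2, SIMPLIFY = FALSE)
  stats::setNames(rep(sheet$samples, lengths(combos)), unlist(combos))
}

#' Extract UMIs without demultiplexing
#'
#' The degenerate case of [demultiplex_run()] for libraries that are not
#' multiplexed (or already demultiplexed) but carry UMI/spacer bases at the
#' read start: the technical block is clipped, UMIs are moved into the read
#' headers, and a single output stream is written. Layouts must not contain
#' a `B` token.
#'
#' @inheritParams demultiplex_run
#' @param out_name basename for the output files (`<out_name>_1.fastq` etc.).
#' @return a `demux_metrics` object (single "sample" named `out_name`).
#' @export
clip_run <- function(fastq1, fastq2 = NULL, layout1, layout2 = NULL,
                     extra_clip = 0L, extra_trim = 0L, separator = ":",
                     out_dir, out_name = "clipped", gzip = FALSE, md5 = FALSE,
                     chunk_size = 100000L) {
  if (is.character(layout1)) layout1 <- parse_layout(layout1)
  if (is.character(layout2)) layout2 <- parse_layout(layout2)
  if (is.null(layout2)) layout2 <- parse_layout(NULL)
  if (layout1$blen > 0L || layout2$blen > 0L)
    stop("clip_run() layouts must not contain a sample-barcode (B) token")
  assign_fun <- function(ex1, ex2) {
    n <- length(ex1$too_short)
    data.frame(sample = rep(out_name, n), mismatches = 0L,
               observed = "", ambiguous = FALSE, second_best_gap = Inf,
               stringsAsFactors = FALSE)
  }
  stream_pipeline(fastq1, fastq2, layout1, layout2, extra_clip, extra_trim,
                  separator, out_dir, gzip, md5, chunk_size,
                  samples = out_name, assign_fun = assign_fun)
}

# Shared streaming engine: reads chunks, extracts layout segments, calls
# assign_fun(ex1, ex2) for the sample decision, annotates headers with UMIs,
# and routes records to per-sample writers. Index-file demultiplexing passes
# extra index readers whose sequences feed assign_fun instead.
stream_pipeline <- function(fastq1, fastq2, layout1, layout2, extra_clip,
                            extra_trim, separator, out_dir, gzip, md5,
                            chunk_size, samples, assign_fun,
                            index1 = NULL, index2 = NULL,
                            index_assign_fun = NULL) {
  paired <- !is.null(fastq2)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  new_writer <- function(base, end)
    fastq_writer(file.path(out_dir, paste0(base, "_", end, ext)),
                 gzip = gzip, md5 = md5)
  writers <- lapply(stats::setNames(nm = c(samples, "unassigned")), function(s) {
    list(w1 = new_writer(s, 1L), w2 = if (paired) new_writer(s, 2L))
  })
  rdr1 <- fastq_reader(fastq1, chunk_size)
  rdr2 <- if (paired) fastq_reader(fastq2, chunk_size)
  irdr1 <- if (!is.null(index1)) fastq_reader(index1, chunk_size)
  irdr2 <- if (!is.null(index2)) fastq_reader(index2, chunk_size)
  on.exit({
    rdr1$close(); if (paired) rdr2$close()
    if (!is.null(irdr1)) irdr1$close(); if (!is.null(irdr2)) irdr2$close()
    for (w in writers) { w$w1$close(); if (paired) w$w2$close() }
  }, add = TRUE)

  counts <- stats::setNames(numeric(length(samples)), samples)
  unassigned <- 0; ambiguous <- 0; total <- 0

  repeat {
    c1 <- rdr1$read_chunk()
    c2 <- if (paired) rdr2$read_chunk()
    i1 <- if (!is.null(irdr1)) irdr1$read_chunk()
    i2 <- if (!is.null(irdr2)) irdr2$read_chunk()
    if (is.null(c1)) {
      if (paired && !is.null(c2))
        stop("paired input out of sync: ", fastq2, " has extra records")
      if (!is.null(irdr1) && !is.null(i1))
        stop("index input out of sync: ", index1, " has extra records")
      break
    }
    check_sync <- function(other, label, path) {
      if (is.null(other) || nrow(other) != nrow(c1))
        stop(label, " input out of sync at record ", total + nrow(c1), ": ",
             path)
      bad <- which(canonical_name(other$name) != canonical_name(c1$name))
      if (length(bad))
        stop(label, " read-name mismatch at record ", total + bad[1L], ": '",
             c1$name[bad[1L]], "' vs '", other$name[bad[1L]], "'")
    }
    if (paired) check_sync(c2, "paired", fastq2)
    if (!is.null(irdr1)) check_sync(i1, "index", index1)
    if (!is.null(irdr2)) check_sync(i2, "index", index2)

    ex1 <- extract_segments(c1$bases, c1$quals, layout1, extra_clip, extra_trim)
    ex2 <- if (paired)
      extract_segments(c2$bases, c2$quals, layout2, extra_clip, extra_trim)
    else list(barcode = character(nrow(c1)), barcode_quals = character(nrow(c1)),
              umi = rep("", nrow(c1)), too_short = rep(FALSE, nrow(c1)))

    match <- if (is.null(index_assign_fun)) assign_fun(ex1, ex2)
             else index_assign_fun(i1, i2)
    too_short <- ex1$too_short | ex2$too_short
    sample <- match$sample
    sample[too_short] <- UNASSIGNED

    # UMI segments from read 1 then read 2, concatenated
    umi <- paste0(ex1$umi, ex2$umi)
    assigned <- !is.na(sample)

    out1 <- c1; out1$bases <- ex1$out_bases; out1$quals <- ex1$out_quals
    out2 <- if (paired) {
      o <- c2; o$bases <- ex2$out_bases; o$quals <- ex2$out_quals; o
    }
    has_umi <- assigned & nzchar(umi)
    if (any(has_umi)) {
      out1[has_umi, ] <- annotate_header(out1[has_umi, , drop = FALSE],
                                         umi[has_umi], separator)
      if (paired)
        out2[has_umi, ] <- annotate_header(out2[has_umi, , drop = FALSE],
                                           umi[has_umi], separator)
    }

    for (s in unique(sample[assigned])) {
      rows <- which(!is.na(sample) & sample == s)
      writers[[s]]$w1$write(out1[rows, , drop = FALSE])
      if (paired) writers[[s]]$w2$write(out2[rows, , drop = FALSE])
      counts[s] <- counts[s] + length(rows)
    }
    if (any(!assigned)) {
      rows <- which(!assigned)
      # unassigned reads are written raw (never clipped): lossless rescue
      writers[["unassigned"]]$w1$write(c1[rows, , drop = FALSE])
      if (paired) writers[["unassigned"]]$w2$write(c2[rows, , drop = FALSE])
      unassigned <- unassigned + length(rows)
      ambiguous <- ambiguous + sum(match$ambiguous[rows] & !too_short[rows])
    }
    total <- total + nrow(c1)
  }
  for (w in writers) { w$w1$close(); if (paired) w$w2$close() }

  metrics <- demux_metrics(counts, unassigned, ambiguous, total)
  write_demux_metrics(metrics, file.path(out_dir, "demux_metrics.tsv"))
  metrics
}

#' Demultiplexing metrics
#'
#' @param per_sample named numeric vector of per-sample read counts.
#' @param unassigned,ambiguous,total scalar counts; ambiguous reads are a
#'   subset of the unassigned ones.
#' @return object of class `demux_metrics`.
#' @export
demux_metrics <- function(per_sample, unassigned, ambiguous, total) {
  stopifnot(sum(per_sample) + unassigned == total, ambiguous <= unassigned)
  structure(list(per_sample = per_sample, unassigned = unassigned,
                 ambiguous = ambiguous, total = total),
            class = "demux_metrics")
}

#' @export
print.demux_metrics <- function(x, ...) {
  cat("demux_metrics:", x$total, "reads;",
      sum(x$per_sample), "assigned over", length(x$per_sample), "samples;",
      x$unassigned, "unassigned (", x$ambiguous, "ambiguous )\n")
  invisible(x)
}

write_demux_metrics <- function(metrics, path) {
  df <- data.frame(sample = c(names(metrics$per_sample), "__unassigned__",
                              "__ambiguous__", "__total__"),
                   read_count = c(unname(metrics$per_sample),
                                  metrics$unassigned, metrics$ambiguous,
                                  metrics$total))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a demultiplexing metrics file
#'
#' @param path a `demux_metrics.tsv` written by [demultiplex_run()].
#' @return a `demux_metrics` object.
#' @export
read_demux_metrics <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  special <- c("__unassigned__", "__ambiguous__", "__total__")
  per <- df[!df$sample %in% special, ]
  get <- function(k) df$read_count[df$sample == k]
  demux_metrics(stats::setNames(per$read_count, per$sample),
                get("__unassigned__"), get("__ambiguous__"), get("__total__"))
}
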