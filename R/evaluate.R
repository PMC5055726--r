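#' Collect per-read sample assignments from a demultiplexing output directory
#'
#' Reads every per-sample FASTQ written by [demultiplex_run()] /
#' [demultiplex_illu()] and returns which sample each input read ended up
#' in. Output read names may carry a UMI suffix; it is stripped to recover
#' the original name.
#'
#' @param out_dir the demultiplexing output directory.
#' @param samples sample names (as in the sheet).
#' @param separator UMI separator used in the run.
#' @param gzip whether outputs were gzip-compressed.
#' @return data frame `read`, `sample` (`NA` for unassigned reads).
#' @export
demux_assignments <- function(out_dir, samples, separator = ":",
                              gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  strip_umi <- function(name)
    sub(paste0(separator, "[ACGTN]+$"), "", name, fixed = FALSE)
  out <- list()
  for (s in c(samples, "unassigned")) {
    f <- file.path(out_dir, paste0(s, "_1", ext))
    if (!file.exists(f)) next
    rec <- read_fastq(f)
    if (nrow(rec) == 0L) next
    nm <- if (s == "unassigned") canonical_name(rec$name)
          else strip_umi(canonical_name(rec$name))
    out[[s]] <- data.frame(read = nm,
                           sample = if (s == "unassigned") NA_character_ else s,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Score pipeline outputs against simulated ground truth
#'
#' Compares demultiplexing assignments and/or duplicate-marking results with
#' a simulator truth table.
#'
#' For demultiplexing: `precision` is the fraction of assigned reads whose
#' assigned sample matches the truth; `recall` the fraction of all reads
#' assigned to their true sample.
#'
#' For duplicate marking: the molecule-count relative error compares the
#' UMI-aware unique count with the true number of molecules, and the
#' measured gain is set against the gain predicted from the truth table
#' alone, `100 * (molecules - positional_unique) / positional_unique`.
#'
#' @param truth a simulator truth table.
#' @param assignments optional data frame `read`, `sample` from
#'   [demux_assignments()].
#' @param dup optional `dup_metrics` from [mark_duplicates()].
#' @return list of class `truth_eval` with components `demux` (precision,
#'   recall, n_assigned, n_correct, n_reads) and/or `dedup`
#'   (true_molecules, umi_aware_unique, molecule_count_rel_error,
#'   predicted_gain, measured_gain).
#' @export
evaluate_against_truth <- function(truth, assignments = NULL, dup = NULL) {
  res <- list()
  if (!is.null(assignments)) {
    m <- merge(truth, assignments, by = "read", all.x = TRUE,
               suffixes = c(".true", ".called"))
    assigned <- !is.na(m$sample.called)
    correct <- assigned & m$sample.called == m$sample.true
    res$demux <- list(
      precision = if (any(assigned)) sum(correct) / sum(assigned) else NA_real_,
      recall = sum(correct) / nrow(m),
      n_assigned = sum(assigned), n_correct = sum(correct),
      n_reads = nrow(m))
  }
  if (!is.null(dup)) {
    n_mol <- attr(truth, "n_molecules")
    if (is.null(n_mol))
      n_mol <- length(unique(truth$molecule))
    u_pos_truth <- if (!is.null(truth$position))
      length(unique(truth$position)) else NA_integer_
    res$dedup <- list(
      true_molecules = n_mol,
      umi_aware_unique = dup$umi_aware_unique,
      molecule_count_rel_error = abs(dup$umi_aware_unique - n_mol) / n_mol,
      predicted_gain = if (!is.na(u_pos_truth))
        compute_gain(n_mol, u_pos_truth) else NA_real_,
      measured_gain = dup$gain_percent)
  }
  structure(res, class = "truth_eval")
}

#' @export
print.truth_eval <- function(x, ...) {
  if (!is.null(x$demux))
    cat(sprintf("demux: precision %.4f recall %.4f (%d/%d assigned)\n",
                x$demux$precision, x$demux$recall, x$demux$n_assigned,
                x$demux$n_reads))
  if (!is.null(x$dedup))
    cat(sprintf(
      "dedup: %d molecules, %d recovered (rel. err %.4f); gain %.2f%% (predicted %.2f%%)\n",
      x$dedup$true_molecules, x$dedup$umi_aware_unique,
      x$dedup$molecule_count_rel_error, x$dedup$measured_gain,
      x$dedup$predicted_gain))
  invisible(x)
}
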