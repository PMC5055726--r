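#' Generalized Hamming distance between an observed sequence and a barcode
#'
#' Counts positions at which the observed sequence fails to match the
#' barcode, under the rules used throughout the suite:
#' \itemize{
#'   \item an `N` in the \emph{barcode} (a degenerate position) matches any
#'     observed base at zero cost;
#'   \item an `N` in the \emph{observed} sequence costs 1;
#'   \item an observed base whose quality is below `min_quality` is treated
#'     as `N` (costs 1).
#' }
#' The function is therefore deliberately asymmetric in its arguments.
#'
#' @param observed character vector of observed sequences (equal lengths).
#' @param barcode a single barcode of the same length.
#' @param quals optional Phred+33 quality strings parallel to `observed`;
#'   required when `min_quality > 0`.
#' @param min_quality Phred threshold below which an observed base is
#'   N-ified before matching.
#' @return integer vector of mismatch counts, one per observed sequence.
#' @export
mismatch_count <- function(observed, barcode, quals = NULL, min_quality = 0L) {
  n <- length(observed)
  if (n == 0L) return(integer())
  L <- nchar(barcode)
  if (any(nchar(observed) != L))
    stop("observed sequence and barcode must have equal length")
  bc <- strsplit(barcode, "", fixed = TRUE)[[1L]]
  obs <- matrix(unlist(strsplit(observed, "", fixed = TRUE), use.names = FALSE),
                nrow = L)
  low_q <- if (min_quality > 0L) {
    if (is.null(quals)) stop("quals required when min_quality > 0")
    if (any(nchar(quals) != L)) stop("quality strings must match barcode length")
    q <- matrix(utf8ToInt(paste(quals, collapse = "")), nrow = L) - 33L
    q < min_quality
  } else FALSE
  mism <- (bc != "N") & (obs == "N" | low_q | obs != bc)
  as.integer(colSums(matrix(mism, nrow = L)))
}

UNASSIGNED <- NA_character_

#' Assign observed barcode sequences to samples
#'
#' For each observed sequence, finds the candidate barcode minimising
#' [mismatch_count()]. The read is assigned to the corresponding sample only
#' when (a) the minimum distance is at most `max_mm`, (b) the distance gap
#' to the best \emph{other} sample is at least `min_gap`, and (c) exactly
#' one sample achieves the minimum. Ties between samples leave the read
#' unassigned and flagged ambiguous, never arbitrarily resolved.
#'
#' @param observed character vector of observed barcode sequences.
#' @param candidates data frame with columns `sample` and `barcode`
#'   (several rows per sample encode alternative barcodes).
#' @param quals,min_quality see [mismatch_count()].
#' @param max_mm maximum mismatches for an assignment.
#' @param min_gap minimum distance gap to the runner-up sample.
#' @return data frame with one row per observed sequence: `sample`
#'   (`NA` when unassigned), `mismatches`, `observed`, `ambiguous`, and
#'   `second_best_gap` (`Inf` when only one sample is in play).
#' @export
assign_sample <- function(observed, candidates, quals = NULL,
                          max_mm = 1L, min_gap = 1L, min_quality = 0L) {
  if (nrow(candidates) == 0L) stop("empty candidate barcode set")
  n <- length(observed)
  samples <- unique(candidates$sample)
  # NA observed sequences (e.g. too-short reads) are never assignable
  blen <- nchar(candidates$barcode[1L])
  missing_obs <- is.na(observed)
  if (any(missing_obs)) {
    observed[missing_obs] <- strrep("N", blen)
    if (!is.null(quals)) quals[missing_obs] <- strrep("!", blen)
  }
  # distance of every read to every candidate barcode, then per-sample min
  d_bc <- vapply(candidates$barcode, function(b)
    mismatch_count(observed, b, quals, min_quality),
    integer(n), USE.NAMES = FALSE)
  d_bc <- matrix(d_bc, nrow = n)
  d_sample <- matrix(NA_integer_, nrow = n, ncol = length(samples))
  for (j in seq_along(samples)) {
    cols <- which(candidates$sample == samples[j])
    d_sample[, j] <- if (length(cols) == 1L) d_bc[, cols]
      else do.call(pmin, lapply(cols, function(c) d_bc[, c]))
  }
  if (length(samples) == 1L) {
    best <- d_sample[, 1L]
    gap <- rep(Inf, n)
    n_best <- rep(1L, n)
    best_j <- rep(1L, n)
  } else {
    best_j <- max.col(-d_sample, ties.method = "first")
    best <- d_sample[cbind(seq_len(n), best_j)]
    n_best <- rowSums(d_sample == best)
    second <- apply(d_sample, 1L, function(r) sort.int(r, partial = 2L)[2L])
    gap <- second - best
  }
  ok <- best <= max_mm & n_best == 1L & gap >= min_gap & !missing_obs
  data.frame(sample = ifelse(ok, samples[best_j], UNASSIGNED),
             mismatches = as.integer(best),
             observed = ifelse(missing_obs, NA_character_, observed),
             ambiguous = n_best > 1L & best <= max_mm & !missing_obs,
             second_best_gap = gap,
             stringsAsFactors = FALSE)
}

#' Combine the two per-end match results of a read pair
#'
#' With redundant paired-end barcoding the same sample barcode is read at
#' both fragment ends; the two independent match results are reconciled by
#' one of two strategies. `BOTH` requires both ends to agree on the same
#' sample (mismatches summed) -- the stringent option that exploits the
#' redundancy for specificity. `EITHER` accepts an assignment from either
#' end, preferring the one with fewer mismatches; when both ends are
#' assigned to \emph{different} samples with equal mismatches the pair is
#' left unassigned rather than picked arbitrarily.
#'
#' @param m1,m2 match-result data frames from [assign_sample()], row-aligned.
#' @param strategy `"BOTH"` or `"EITHER"`.
#' @return a combined match-result data frame of the same shape.
#' @export
combine_pair_matches <- function(m1, m2, strategy = c("BOTH", "EITHER")) {
  strategy <- match.arg(strategy)
  n <- nrow(m1)
  stopifnot(nrow(m2) == n)
  a1 <- !is.na(m1$sample); a2 <- !is.na(m2$sample)
  if (strategy == "BOTH") {
    ok <- a1 & a2 & m1$sample == m2$sample
    sample <- ifelse(ok, m1$sample, UNASSIGNED)
    mism <- ifelse(ok, m1$mismatches + m2$mismatches,
                   pmin(m1$mismatches, m2$mismatches))
    ambiguous <- !ok & (m1$ambiguous | m2$ambiguous)
  } else {
    conflict <- a1 & a2 & m1$sample != m2$sample
    tie <- conflict & m1$mismatches == m2$mismatches
    use1 <- a1 & (!a2 | (!tie & m1$mismatches <= m2$mismatches))
    use2 <- a2 & !use1 & !tie
    sample <- rep(UNASSIGNED, n)
    sample[use1] <- m1$sample[use1]
    sample[use2] <- m2$sample[use2]
    mism <- ifelse(use1, m1$mismatches, ifelse(use2, m2$mismatches,
                                               pmin(m1$mismatches, m2$mismatches)))
    ambiguous <- tie | (is.na(sample) & (m1$ambiguous | m2$ambiguous))
  }
  data.frame(sample = sample, mismatches = as.integer(mism),
             observed = paste0(m1$observed, ":", m2$observed),
             ambiguous = ambiguous,
             second_best_gap = pmin(m1$second_best_gap, m2$second_best_gap),
             stringsAsFactors = FALSE)
}
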