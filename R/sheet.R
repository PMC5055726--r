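#' Sample sheets
#'
#' A sample sheet maps each sample to the barcode(s) that identify it. The
#' on-disk format is a headerless TSV with at least two columns:
#' `sample_name TAB barcode-spec`, where the barcode spec joins alternative
#' barcodes with `|` and, for paired-end designs with a distinct barcode on
#' each fragment end, joins the end-1 and end-2 specs with `:`. Lines
#' starting with `#` are ignored. Examples:
#'
#' ```
#' sampleA   ACGTGG
#' sampleB   TTAACC|GGTTAA
#' sampleC   ACGTGG:CCAATT
#' ```
#'
#' Barcodes may contain `N` at degenerate positions (as in iCLIP designs);
#' an `N` in a barcode matches any read base at zero cost.
#'
#' @param path sample sheet file.
#' @return an object of class `sample_sheet`: a list with `samples`
#'   (character), `end1` and `end2` (lists of character vectors of
#'   alternative barcodes per sample; `end2` entries empty for single-end
#'   designs), `blen1`/`blen2` (barcode lengths), and `combinatorial`
#'   (`TRUE` when a per-end barcode is shared between samples so that only
#'   the end1:end2 combination identifies the sample).
#' @export
read_sample_sheet <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty sample sheet: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("sample sheet lines need at least 2 tab-separated columns")
  samples <- vapply(fields, `[[`, "", 1L)
  specs <- vapply(fields, `[[`, "", 2L)
  sample_sheet(samples, specs)
}

#' Build a sample sheet from sample names and barcode specs
#'
#' @param samples character vector of unique, filesystem-safe sample names.
#' @param specs barcode specs, one per sample (grammar as in
#'   [read_sample_sheet()]).
#' @return a `sample_sheet` object.
#' @export
sample_sheet <- function(samples, specs) {
  if (anyDuplicated(samples))
    stop("duplicate sample name: ", samples[duplicated(samples)][1L])
  if (any(grepl("[^A-Za-z0-9._-]", samples)))
    stop("sample names must be filesystem-safe ([A-Za-z0-9._-])")
  ends <- strsplit(specs, ":", fixed = TRUE)
  if (any(lengths(ends) > 2L)) stop("barcode spec has more than one ':'")
  end1 <- lapply(ends, function(e) strsplit(e[[1L]], "|", fixed = TRUE)[[1L]])
  end2 <- lapply(ends, function(e)
    if (length(e) > 1L) strsplit(e[[2L]], "|", fixed = TRUE)[[1L]] else character())
  if (any(lengths(end2) > 0L) && any(lengths(end2) == 0L))
    stop("either all samples or none must declare an end-2 barcode")
  check_end <- function(bcs, end) {
    all_bc <- unlist(bcs)
    if (any(grepl("[^ACGTN]", all_bc)))
      stop("barcodes restricted to the alphabet {A,C,G,T,N}")
    if (length(all_bc) && length(unique(nchar(all_bc))) > 1L)
      stop("all end-", end, " barcodes must have equal length")
    if (length(all_bc)) nchar(all_bc[1L]) else 0L
  }
  blen1 <- check_end(end1, 1L)
  blen2 <- check_end(end2, 2L)
  dual <- blen2 > 0L

  # uniqueness: a barcode (or, in dual-coded sheets, an end1:end2 pair) must
  # identify exactly one sample
  if (dual) {
    combos <- mapply(function(b1, b2) as.vector(outer(b1, b2, paste, sep = ":")),
                     end1, end2, SIMPLIFY = FALSE)
    owner <- rep(samples, lengths(combos))
    combos <- unlist(combos)
    if (anyDuplicated(combos)) {
      d <- combos[duplicated(combos)][1L]
      stop("barcode combination ", d, " maps to samples ",
           paste(unique(owner[combos == d]), collapse = " and "))
    }
    shared_across <- function(end) {
      owner <- rep(samples, lengths(end))
      bc <- unlist(end)
      any(vapply(split(owner, bc), function(s) length(unique(s)), 1L) > 1L)
    }
    combinatorial <- shared_across(end1) || shared_across(end2)
    if (!combinatorial) {
      for (end in list(end1, end2)) {
        bc <- unlist(end)
        owner1 <- rep(samples, lengths(end))
        if (anyDuplicated(bc)) {
          d <- bc[duplicated(bc)][1L]
          stop("barcode ", d, " maps to samples ",
               paste(unique(owner1[bc == d]), collapse = " and "))
        }
      }
    }
  } else {
    bc <- unlist(end1)
    owner <- rep(samples, lengths(end1))
    if (anyDuplicated(bc)) {
      d <- bc[duplicated(bc)][1L]
      stop("barcode ", d, " maps to samples ",
           paste(unique(owner[bc == d]), collapse = " and "))
    }
    combinatorial <- FALSE
  }
  structure(list(samples = samples, end1 = end1, end2 = end2,
                 blen1 = blen1, blen2 = blen2, dual = dual,
                 combinatorial = combinatorial),
            class = "sample_sheet")
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat("sample_sheet:", length(x$samples), "samples, end-1 barcode length",
      x$blen1, if (x$dual) paste0(", end-2 length ", x$blen2), "\n")
  invisible(x)
}

#' Serialize a sample sheet back to its TSV form
#'
#' Inverse of [read_sample_sheet()].
#'
#' @param sheet a `sample_sheet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  spec <- vapply(seq_along(sheet$samples), function(i) {
    s <- paste(sheet$end1[[i]], collapse = "|")
    if (sheet$dual) s <- paste0(s, ":", paste(sheet$end2[[i]], collapse = "|"))
    s
  }, "")
  writeLines(paste(sheet$samples, spec, sep = "\t"), path)
  invisible(path)
}

# (sample, barcode) candidate table for one end, used by assign_sample()
sheet_candidates <- function(sheet, end = 1L) {
  bcs <- if (end == 1L) sheet$end1 else sheet$end2
  data.frame(sample = rep(sheet$samples, lengths(bcs)),
             barcode = unlist(bcs), stringsAsFactors = FALSE)
}
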