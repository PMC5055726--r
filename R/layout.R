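#' Parse a read-layout specification
#'
#' Each read of a (pair of) multiplexed read(s) may start with a block of
#' technical bases. The layout grammar describes that block as a
#' concatenation of tokens, read left to right from base 1:
#' \describe{
#'   \item{`U<len>`}{random UMI bases, extracted into the read header;}
#'   \item{`B<len>`}{the sample barcode (at most one per read);}
#'   \item{`S<len>`}{spacer bases, discarded;}
#'   \item{`I<len>`}{insert bases retained in place (rarely needed; the
#'     remainder of the read after the token block is always insert).}
#' }
#' `"U4B6U4"` describes a composite barcode: 4 random bases, a 6-base
#' sample index, then 4 more random bases, with the biological insert
#' starting at base 15. The grammar is this tool's own; upstream protocols
#' describe such configurations only diagrammatically.
#'
#' @param spec layout string, or `""`/`NULL` for "no technical bases".
#' @return an object of class `read_layout`: list with `segments`
#'   (data frame `type`, `start`, `len`, 1-based), `blen` (sample-barcode
#'   length, 0 if none), `barcode_start`, `umi_len` and `prefix_len` (total
#'   technical block length).
#' @export
parse_layout <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) {
    return(structure(list(segments = data.frame(type = character(),
                                                start = integer(),
                                                len = integer()),
                          blen = 0L, barcode_start = NA_integer_,
                          umi_len = 0L, prefix_len = 0L),
                     class = "read_layout"))
  }
  m <- gregexpr("[UBSI][0-9]+", spec)[[1L]]
  tokens <- regmatches(spec, gregexpr("[UBSI][0-9]+", spec))[[1L]]
  if (sum(nchar(tokens)) != nchar(spec) || length(tokens) == 0L)
    stop("malformed layout spec: ", spec)
  type <- substr(tokens, 1L, 1L)
  len <- as.integer(substring(tokens, 2L))
  if (any(len == 0L)) stop("zero-length layout token in: ", spec)
  if (sum(type == "B") > 1L)
    stop("at most one sample-barcode (B) token per read: ", spec)
  start <- cumsum(c(1L, len))[seq_along(len)]
  segments <- data.frame(type = type, start = start, len = len,
                         stringsAsFactors = FALSE)
  structure(list(segments = segments,
                 blen = if (any(type == "B")) len[type == "B"] else 0L,
                 barcode_start = if (any(type == "B")) start[type == "B"] else NA_integer_,
                 umi_len = sum(len[type == "U"]),
                 prefix_len = sum(len)),
            class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  if (nrow(x$segments) == 0L) cat("read_layout: (empty)\n")
  else cat("read_layout:",
           paste0(x$segments$type, x$segments$len, collapse = ""), "\n")
  invisible(x)
}

#' Extract layout segments from reads
#'
#' Slices the technical block off a vector of reads according to a layout:
#' the sample barcode and UMI bases (with their qualities) are returned
#' separately, spacer bases are discarded, and the output read is what
#' remains -- optionally minus `extra_clip` additional bases after the
#' technical block (removed and not recorded anywhere) and `extra_trim`
#' bases off the read tail.
#'
#' Reads shorter than the layout (plus `extra_clip`) are flagged
#' `too_short`; their output fields are `NA` and callers route them to the
#' unassigned output.
#'
#' @param bases,quals character vectors (parallel).
#' @param layout a `read_layout` from [parse_layout()].
#' @param extra_clip bases removed after the technical block (`XT`-style).
#' @param extra_trim bases removed from the read tail (`ZT`-style).
#' @return list with `barcode`, `barcode_quals`, `umi`, `out_bases`,
#'   `out_quals`, `too_short`.
#' @export
extract_segments <- function(bases, quals, layout, extra_clip = 0L,
                             extra_trim = 0L) {
  n <- length(bases)
  need <- layout$prefix_len + extra_clip
  too_short <- nchar(bases) < need
  seg <- layout$segments
  slice <- function(x, start, len) substr(x, start, start + len - 1L)
  pick <- function(x, type) {
    rows <- which(seg$type == type)
    if (!length(rows)) return(rep("", n))
    parts <- lapply(rows, function(r) slice(x, seg$start[r], seg$len[r]))
    do.call(paste0, parts)
  }
  barcode <- pick(bases, "B")
  barcode_quals <- pick(quals, "B")
  umi <- pick(bases, "U")
  kept_prefix_b <- pick(bases, "I")
  kept_prefix_q <- pick(quals, "I")
  tail_from <- layout$prefix_len + extra_clip + 1L
  out_bases <- paste0(kept_prefix_b, substring(bases, tail_from))
  out_quals <- paste0(kept_prefix_q, substring(quals, tail_from))
  if (extra_trim > 0L) {
    keep <- pmax(nchar(out_bases) - extra_trim, 0L)
    out_bases <- substr(out_bases, 1L, keep)
    out_quals <- substr(out_quals, 1L, keep)
  }
  barcode[too_short] <- NA_character_
  umi[too_short] <- NA_character_
  out_bases[too_short] <- NA_character_
  out_quals[too_short] <- NA_character_
  list(barcode = barcode, barcode_quals = barcode_quals, umi = umi,
       out_bases = out_bases, out_quals = out_quals, too_short = too_short)
}

#' Append a UMI to read names
#'
#' The UMI is appended to the canonical read name after `separator`, the
#' convention expected by the duplicate-marking stage. Both mates of a pair
#' must receive the identical transformation so their names stay equal (as
#' read mappers require).
#'
#' @param records record data frame.
#' @param umi character vector of UMIs (non-empty), recycled if length 1.
#' @param separator single character, must not occur inside any UMI.
#' @return the records with rewritten `name`.
#' @export
annotate_header <- function(records, umi, separator = ":") {
  if (any(!nzchar(umi))) stop("UMIs must be non-empty")
  if (any(grepl(separator, umi, fixed = TRUE)))
    stop("separator '", separator, "' occurs inside a UMI")
  records$name <- paste0(canonical_name(records$name), separator, umi)
  records
}
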