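#' Read an alignment file (SAM, or BAM via Rsamtools)
#'
#' Alignments are held as a plain data frame over the eleven mandatory SAM
#' columns plus a `tags` column with the remaining fields joined by tabs --
#' a representation that round-trips byte-exactly and keeps flag surgery
#' (duplicate marking) a vectorised integer operation. BAM input is
#' converted through Rsamtools when available.
#'
#' @param path a `.sam` (text) or `.bam` file.
#' @return list with `header` (character vector of `@` lines) and `reads`
#'   (data frame: `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`,
#'   `pnext`, `tlen`, `seq`, `qual`, `tags`).
#' @export
read_sam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading BAM requires the Rsamtools package; convert to SAM first")
    sam <- tempfile(fileext = ".sam")
    on.exit(unlink(sam))
    Rsamtools::asSam(path, sub("\\.sam$", "", sam), overwrite = TRUE)
    path <- sam
  }
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  if (length(body) == 0L) {
    reads <- data.frame(qname = character(), flag = integer(),
                        rname = character(), pos = integer(),
                        mapq = integer(), cigar = character(),
                        rnext = character(), pnext = integer(),
                        tlen = integer(), seq = character(),
                        qual = character(), tags = character(),
                        stringsAsFactors = FALSE)
    return(list(header = header, reads = reads))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L))
    stop("SAM record with fewer than 11 fields in ", path)
  col <- function(i) vapply(fields, `[[`, "", i)
  tags <- vapply(fields, function(f)
    if (length(f) > 11L) paste(f[-(1:11)], collapse = "\t") else "", "")
  reads <- data.frame(qname = col(1L), flag = as.integer(col(2L)),
                      rname = col(3L), pos = as.integer(col(4L)),
                      mapq = as.integer(col(5L)), cigar = col(6L),
                      rnext = col(7L), pnext = as.integer(col(8L)),
                      tlen = as.integer(col(9L)), seq = col(10L),
                      qual = col(11L), tags = tags, stringsAsFactors = FALSE)
  list(header = header, reads = reads)
}

#' Write an alignment file (SAM, or BAM via Rsamtools)
#'
#' @param aln a list with `header` and `reads` as returned by [read_sam()].
#' @param path output path; `.bam` suffix triggers conversion through
#'   Rsamtools.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path) {
  to_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  sam_path <- if (to_bam) tempfile(fileext = ".sam") else path
  r <- aln$reads
  body <- paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, r$rnext,
                r$pnext, r$tlen, r$seq, r$qual, sep = "\t")
  has_tags <- nzchar(r$tags)
  body[has_tags] <- paste(body[has_tags], r$tags[has_tags], sep = "\t")
  con <- file(sam_path, "wb")
  writeLines(c(aln$header, body), con, sep = "\n")
  close(con)
  if (to_bam) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("writing BAM requires the Rsamtools package")
    Rsamtools::asBam(sam_path, sub("\\.bam$", "", path), overwrite = TRUE,
                     indexDestination = FALSE)
    unlink(sam_path)
  }
  invisible(path)
}

# CIGAR arithmetic ----------------------------------------------------------

parse_cigar <- function(cigar) {
  lapply(regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar)), function(ops) {
    list(len = as.integer(sub("[MIDNSHP=X]", "", ops)),
         op = sub("[0-9]+", "", ops))
  })
}

cigar_ref_len <- function(cigar) {
  vapply(parse_cigar(cigar), function(c)
    sum(c$len[c$op %in% c("M", "D", "N", "=", "X")]), 1L)
}

leading_clip <- function(cigar) {
  vapply(parse_cigar(cigar), function(c) {
    i <- 1L; tot <- 0L
    while (i <= length(c$op) && c$op[i] %in% c("S", "H")) {
      tot <- tot + c$len[i]; i <- i + 1L
    }
    tot
  }, 1L)
}

trailing_clip <- function(cigar) {
  vapply(parse_cigar(cigar), function(c) {
    i <- length(c$op); tot <- 0L
    while (i >= 1L && c$op[i] %in% c("S", "H")) {
      tot <- tot + c$len[i]; i <- i - 1L
    }
    tot
  }, 1L)
}

#' Unclipped 5' position of an aligned read
#'
#' The duplicate-grouping coordinate: the mapped start adjusted outward by
#' soft/hard-clipped bases, so that reads trimmed differently at their ends
#' still canonicalise to the molecule's true 5' position. On the forward
#' strand this is `pos` minus leading clips; on the reverse strand the
#' rightmost aligned base plus trailing clips.
#'
#' @param pos 1-based leftmost mapped position.
#' @param cigar CIGAR strings.
#' @param reverse logical; read on the reverse strand.
#' @return integer vector of unclipped 5' coordinates.
#' @export
unclipped_5prime <- function(pos, cigar, reverse) {
  if (any(cigar == "*")) stop("mapped read without CIGAR")
  ifelse(reverse,
         pos + cigar_ref_len(cigar) - 1L + trailing_clip(cigar),
         pos - leading_clip(cigar))
}

# flag helpers
flag_has <- function(flag, bit) bitwAnd(flag, bit) != 0L
FLAG_PAIRED <- 1L; FLAG_UNMAPPED <- 4L; FLAG_MATE_UNMAPPED <- 8L
FLAG_REVERSE <- 16L; FLAG_SECONDARY <- 256L; FLAG_DUP <- 1024L
FLAG_SUPPLEMENTARY <- 2048L
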