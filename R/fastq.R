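#' Read records
#'
#' FASTQ records are represented as a plain data frame with columns
#' `name` (header up to the first whitespace, without the leading `@`),
#' `comment` (header remainder after the first whitespace, `""` when absent),
#' `bases` and `quals` (Phred+33). This keeps per-record manipulation
#' (slicing barcodes, rewriting headers) vectorised and transparent.
#'
#' @param name,comment,bases,quals character vectors of equal length.
#' @return a `data.frame` with one row per read.
#' @export
read_record <- function(name, bases, quals, comment = "") {
  n <- length(name)
  if (length(comment) == 1L) comment <- rep(comment, n)
  if (length(bases) == 1L) bases <- rep(bases, n)
  if (length(quals) == 1L) quals <- rep(quals, n)
  stopifnot(length(bases) == n, length(quals) == n, length(comment) == n)
  if (any(!nzchar(name))) stop("read names must be non-empty")
  if (any(nchar(bases) != nchar(quals)))
    stop("bases and quals must have equal length in every record")
  if (any(grepl("[^ACGTN]", bases)))
    stop("bases restricted to the alphabet {A,C,G,T,N}")
  data.frame(name = name, comment = comment, bases = bases, quals = quals,
             stringsAsFactors = FALSE)
}

#' Canonical read name
#'
#' Strips a trailing `/1` or `/2` mate suffix. Mates of a proper pair have
#' identical canonical names; this is the key used to verify paired files
#' stay synchronised.
#'
#' @param name character vector of read names.
#' @return character vector.
#' @export
canonical_name <- function(name) sub("/[12]$", "", name)

is_gzip_file <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Open a streaming FASTQ reader
#'
#' Returns a reader object that yields successive chunks of records, so
#' memory use is bounded by `chunk_size` rather than file size. Plain and
#' gzip-compressed files are detected from the leading magic bytes, never
#' from the file extension.
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @param chunk_size maximum number of records per chunk.
#' @return an object of class `fastq_reader` with elements
#'   `read_chunk()` (returns a record data frame, or `NULL` at end of file)
#'   and `close()`.
#' @export
fastq_reader <- function(path, chunk_size = 100000L) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (is_gzip_file(path)) gzfile(path, "rt") else file(path, "rt")
  n_seen <- 0L
  open_flag <- TRUE
  close_fn <- function() {
    if (open_flag) { close(con); open_flag <<- FALSE }
    invisible(NULL)
  }
  read_chunk <- function() {
    lines <- readLines(con, n = 4L * as.integer(chunk_size))
    if (length(lines) == 0L) return(NULL)
    if (length(lines) %% 4L != 0L) {
      close_fn()
      stop("truncated FASTQ record at record ", n_seen + length(lines) %/% 4L + 1L,
           " in ", path)
    }
    idx <- seq(1L, length(lines), by = 4L)
    hdr <- lines[idx]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad))
      stop("malformed FASTQ header at record ", n_seen + bad[1L], " in ", path)
    hdr <- substring(hdr, 2L)
    ws <- regexpr("[ \t]", hdr)
    name <- ifelse(ws > 0L, substr(hdr, 1L, ws - 1L), hdr)
    comment <- ifelse(ws > 0L, substring(hdr, ws + 1L), "")
    bases <- lines[idx + 1L]
    quals <- lines[idx + 3L]
    bad <- which(nchar(bases) != nchar(quals))
    if (length(bad))
      stop("bases/quals length mismatch at record ", n_seen + bad[1L], " in ", path)
    n_seen <<- n_seen + length(idx)
    data.frame(name = name, comment = comment, bases = bases, quals = quals,
               stringsAsFactors = FALSE)
  }
  structure(list(read_chunk = read_chunk, close = close_fn, path = path),
            class = "fastq_reader")
}

#' Read a whole FASTQ file
#'
#' Convenience wrapper around [fastq_reader()] that concatenates all chunks.
#' For large files prefer the streaming reader.
#'
#' @inheritParams fastq_reader
#' @return record data frame (zero rows for an empty file).
#' @export
read_fastq <- function(path, chunk_size = 100000L) {
  rdr <- fastq_reader(path, chunk_size)
  on.exit(rdr$close())
  out <- list()
  repeat {
    chunk <- rdr$read_chunk()
    if (is.null(chunk)) break
    out[[length(out) + 1L]] <- chunk
  }
  if (length(out) == 0L)
    return(data.frame(name = character(), comment = character(),
                      bases = character(), quals = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

format_fastq <- function(records) {
  hdr <- paste0("@", records$name,
                ifelse(nzchar(records$comment), paste0(" ", records$comment), ""))
  as.vector(rbind(hdr, records$bases, "+", records$quals))
}

#' Open a streaming FASTQ writer
#'
#' @param path output path.
#' @param gzip write gzip-compressed output.
#' @param md5 on close, write a `<path>.md5` sidecar containing the hex MD5
#'   digest of the exact bytes written.
#' @return an object of class `fastq_writer` with elements
#'   `write(records)` and `close()` (returns `path`).
#' @export
fastq_writer <- function(path, gzip = FALSE, md5 = FALSE) {
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  # "wb" + explicit "\n" keeps output byte-identical across platforms
  write <- function(records) {
    if (nrow(records)) writeLines(format_fastq(records), con, sep = "\n")
    invisible(NULL)
  }
  open_flag <- TRUE
  close_fn <- function() {
    if (open_flag) {
      close(con)
      open_flag <<- FALSE
      if (md5) {
        digest <- unname(tools::md5sum(path))
        writeLines(paste0(digest, "  ", basename(path)), paste0(path, ".md5"))
      }
    }
    path
  }
  structure(list(write = write, close = close_fn, path = path),
            class = "fastq_writer")
}

#' Write records to a FASTQ file
#'
#' @param records record data frame (see [read_record()]).
#' @inheritParams fastq_writer
#' @return the output path, invisibly.
#' @export
write_fastq <- function(records, path, gzip = FALSE, md5 = FALSE) {
  w <- fastq_writer(path, gzip = gzip, md5 = md5)
  w$write(records)
  w$close()
  invisible(path)
}
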