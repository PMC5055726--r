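#' Extract the UMI from a read name
#'
#' The demultiplexing/clipping stages append the UMI to the read name after
#' a separator; this recovers it (the substring after the \emph{last}
#' separator, validated over `{A,C,G,T,N}`).
#'
#' @param name character vector of read names.
#' @param separator the separator used when annotating.
#' @param on_missing `"error"` (default) or `"skip"`: what to do when a name
#'   has no separator or a non-DNA suffix. With `"skip"` the UMI is `NA`
#'   and a warning is raised once.
#' @return character vector of UMIs (`NA` for skipped reads).
#' @export
extract_umi_from_name <- function(name, separator = ":",
                                  on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  pos <- vapply(gregexpr(separator, name, fixed = TRUE), max, 1L)
  umi <- ifelse(pos > 0L, substring(name, pos + nchar(separator)), NA_character_)
  bad <- is.na(umi) | !nzchar(umi) | grepl("[^ACGTN]", umi)
  if (any(bad)) {
    if (on_missing == "error")
      stop("no UMI found in read name '", name[which(bad)[1L]],
           "' (separator '", separator, "')")
    warning(sum(bad), " read name(s) without a valid UMI suffix; skipped")
    umi[bad] <- NA_character_
  }
  umi
}

umi_distance_matrix <- function(a, b, n_policy = "MATCH") {
  # pairwise generalized Hamming distances, length(a) x length(b)
  L <- nchar(a[1L])
  am <- matrix(unlist(strsplit(a, "", fixed = TRUE), use.names = FALSE), nrow = L)
  bm <- matrix(unlist(strsplit(b, "", fixed = TRUE), use.names = FALSE), nrow = L)
  out <- matrix(0L, length(a), length(b))
  for (j in seq_along(b)) {
    cmp <- am != bm[, j]
    is_n <- am == "N" | bm[, j] == "N"
    d <- if (n_policy == "MATCH") cmp & !is_n else cmp | is_n
    out[, j] <- colSums(matrix(d, nrow = L))
  }
  out
}

#' Cluster UMIs observed at one position
#'
#' Reads sharing a mapping position are subdivided by UMI so that distinct
#' molecules amplified onto the same coordinate are not collapsed. Two modes:
#'
#' \strong{Free mode} (`predefined = NULL`): greedy frequency-ranked
#' clustering. UMIs are sorted by descending count (ties broken
#' lexicographically); repeatedly, the most frequent unassigned UMI becomes
#' a group representative and absorbs every unassigned UMI within `max_mm`
#' mismatches of it. This attributes sequencing errors in a UMI to its
#' abundant parent while keeping genuinely distinct UMIs apart, and is
#' deterministic.
#'
#' \strong{Predefined mode}: each observed UMI is assigned to the nearest
#' entry of the supplied UMI list when that entry is unique and within
#' `max_mm`; equidistant or too-distant UMIs conservatively keep their own
#' group rather than being rescued.
#'
#' `N` handling (`n_policy`): `"MATCH"` -- an `N` on either side matches at
#' zero cost; `"MISMATCH"` -- any position involving an `N` costs 1;
#' `"DISCARD"` -- UMIs containing `N` are excluded from clustering and each
#' forms its own singleton group.
#'
#' @param umi_counts named integer vector: observed UMI -> count.
#' @param max_mm mismatches tolerated between two UMIs considered identical.
#' @param n_policy `"MATCH"`, `"MISMATCH"` or `"DISCARD"`.
#' @param predefined optional character vector of expected UMIs.
#' @return data frame with columns `umi`, `count`, `representative`; rows in
#'   input order. Groups are the sets of rows sharing a representative.
#' @export
cluster_umis <- function(umi_counts, max_mm = 1L,
                         n_policy = c("MATCH", "MISMATCH", "DISCARD"),
                         predefined = NULL) {
  n_policy <- match.arg(n_policy)
  umis <- names(umi_counts)
  if (length(umis) == 0L)
    return(data.frame(umi = character(), count = integer(),
                      representative = character(), stringsAsFactors = FALSE))
  if (length(unique(nchar(umis))) > 1L) stop("UMIs must all have equal length")
  rep_of <- stats::setNames(rep(NA_character_, length(umis)), umis)
  has_n <- grepl("N", umis, fixed = TRUE)
  if (n_policy == "DISCARD") {
    rep_of[has_n] <- umis[has_n]
    active <- umis[!has_n]
  } else active <- umis
  dist_policy <- if (n_policy == "DISCARD") "MISMATCH" else n_policy

  if (length(active)) {
    if (is.null(predefined)) {
      ord <- active[order(-umi_counts[active], active)]
      D <- umi_distance_matrix(ord, ord, dist_policy)
      assigned <- rep(FALSE, length(ord))
      for (i in seq_along(ord)) {
        if (assigned[i]) next
        members <- which(!assigned & D[i, ] <= max_mm)
        rep_of[ord[members]] <- ord[i]
        assigned[members] <- TRUE
      }
    } else {
      if (length(unique(nchar(predefined))) > 1L ||
          nchar(predefined[1L]) != nchar(active[1L]))
        stop("predefined UMIs must match the observed UMI length")
      D <- umi_distance_matrix(active, predefined, dist_policy)
      best <- apply(D, 1L, min)
      n_best <- rowSums(D == best)
      ok <- best <= max_mm & n_best == 1L
      rep_of[active] <- ifelse(ok, predefined[max.col(-D, "first")],
                               active)
    }
  }
  data.frame(umi = umis, count = as.integer(umi_counts),
             representative = unname(rep_of[umis]), stringsAsFactors = FALSE)
}

#' Choose the representative read of a duplicate group
#'
#' @param ids character vector of member identifiers (read/pair names).
#' @param scores numeric scores parallel to `ids` (ignored for `"RANDOM"`).
#' @param strategy `"SUM_OF_BASE_QUALITIES"` and
#'   `"TOTAL_MAPPED_REFERENCE_LENGTH"` pick the highest score, ties broken
#'   by the lexicographically smallest id; `"RANDOM"` draws one member from
#'   the currently seeded RNG stream (reproducible given a seed).
#' @return the chosen id.
#' @export
select_representative <- function(ids, scores = NULL,
                                  strategy = c("SUM_OF_BASE_QUALITIES",
                                               "TOTAL_MAPPED_REFERENCE_LENGTH",
                                               "RANDOM")) {
  strategy <- match.arg(strategy)
  if (length(ids) == 1L) return(ids)
  if (strategy == "RANDOM") return(sort(ids)[sample.int(length(ids), 1L)])
  stopifnot(length(scores) == length(ids))
  best <- which(scores == max(scores))
  ids[best][order(ids[best])][1L]
}

sum_base_qualities <- function(qual) {
  vapply(qual, function(q) {
    if (q == "*") return(0L)
    sum(utf8ToInt(q) - 33L)
  }, 1L, USE.NAMES = FALSE)
}

#' Duplicate-marking metrics
#'
#' `gain_percent` is the fraction of duplicate reads reassigned as unique
#' once UMIs are taken into account, expressed relative to the number of
#' unique reads a position-only duplicate marker would report:
#' `100 * (umi_aware_unique - positional_unique) / positional_unique`.
#'
#' @param reads_examined primary mapped fragments/pairs inspected.
#' @param positional_unique unique count by mapping position alone.
#' @param umi_aware_unique unique count after UMI subdivision.
#' @param optical_duplicates duplicates attributed to optical proximity.
#' @return object of class `dup_metrics`.
#' @export
dup_metrics <- function(reads_examined, positional_unique, umi_aware_unique,
                        optical_duplicates = 0L) {
  stopifnot(umi_aware_unique >= positional_unique,
            reads_examined >= umi_aware_unique)
  structure(list(reads_examined = reads_examined,
                 positional_unique = positional_unique,
                 umi_aware_unique = umi_aware_unique,
                 duplicates_marked = reads_examined - umi_aware_unique,
                 optical_duplicates = optical_duplicates,
                 gain_percent = compute_gain(umi_aware_unique,
                                             positional_unique)),
            class = "dup_metrics")
}

#' @export
print.dup_metrics <- function(x, ...) {
  cat("dup_metrics:", x$reads_examined, "examined;",
      x$positional_unique, "unique by position;",
      x$umi_aware_unique, "unique with UMIs;",
      x$duplicates_marked, "duplicates; gain",
      sprintf("%.2f%%", x$gain_percent), "\n")
  invisible(x)
}

#' UMI gain in unique reads
#'
#' The number of duplicate reads reassigned as unique reads once UMIs are
#' taken into account, as a percentage of the unique reads identified
#' without UMIs.
#'
#' @param umi_aware_unique,positional_unique unique-read counts with and
#'   without UMI awareness.
#' @return percentage (>= 0 whenever `umi_aware_unique >= positional_unique`).
#' @export
compute_gain <- function(umi_aware_unique, positional_unique) {
  if (positional_unique < 1L) stop("positional_unique must be >= 1")
  if (umi_aware_unique < positional_unique)
    stop("umi_aware_unique cannot be below positional_unique")
  100 * (umi_aware_unique - positional_unique) / positional_unique
}

write_dup_metrics <- function(metrics, path) {
  df <- data.frame(READS_EXAMINED = metrics$reads_examined,
                   POSITIONAL_UNIQUE = metrics$positional_unique,
                   UMI_AWARE_UNIQUE = metrics$umi_aware_unique,
                   DUPLICATES_MARKED = metrics$duplicates_marked,
                   OPTICAL_DUPLICATES = metrics$optical_duplicates,
                   GAIN_PERCENT = metrics$gain_percent)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- position grouping ------------------------------------------------------

# Entities are the units of duplicate comparison: a pair of primary mapped
# mates, or a single fragment. Pairs and fragments live in disjoint key
# spaces and are never duplicates of one another.
build_entities <- function(reads, eligible) {
  idx <- which(eligible)
  r <- reads[idx, , drop = FALSE]
  strand <- ifelse(flag_has(r$flag, FLAG_REVERSE), "-", "+")
  u5 <- unclipped_5prime(r$pos, r$cigar, strand == "-")
  pairable <- flag_has(r$flag, FLAG_PAIRED) & !flag_has(r$flag, FLAG_MATE_UNMAPPED)
  pair_id <- ifelse(pairable, r$qname, NA_character_)
  tab <- table(pair_id[pairable])
  full_pair <- pairable & pair_id %in% names(tab)[tab == 2L]

  ent_rows <- list(); ent_key <- character(); ent_name <- character()
  if (any(full_pair)) {
    sp <- split(which(full_pair), pair_id[full_pair])
    keys <- vapply(sp, function(j) {
      ends <- data.frame(rname = r$rname[j], u5 = u5[j], strand = strand[j])
      o <- order(ends$rname, ends$u5, ends$strand)
      ends <- ends[o, ]
      paste("P", ends$rname[1L], ends$u5[1L], ends$strand[1L],
            ends$rname[2L], ends$u5[2L], ends$strand[2L], sep = "|")
    }, "")
    ent_rows <- c(ent_rows, lapply(sp, function(j) idx[j]))
    ent_key <- c(ent_key, keys)
    ent_name <- c(ent_name, names(sp))
  }
  frag <- which(!full_pair)
  if (length(frag)) {
    ent_rows <- c(ent_rows, lapply(frag, function(j) idx[j]))
    ent_key <- c(ent_key, paste("F", r$rname[frag], u5[frag], strand[frag],
                                sep = "|"))
    ent_name <- c(ent_name, r$qname[frag])
  }
  list(rows = ent_rows, key = ent_key, name = ent_name)
}

check_coordinate_sorted <- function(reads, header) {
  mapped <- reads[!flag_has(reads$flag, FLAG_UNMAPPED), , drop = FALSE]
  if (nrow(mapped) < 2L) return(invisible(TRUE))
  runs <- rle(mapped$rname)
  if (anyDuplicated(runs$values))
    stop("input not coordinate-sorted: reference blocks interleaved")
  if (any(unlist(tapply(mapped$pos, factor(mapped$rname, unique(mapped$rname)),
                        function(p) diff(p) < 0L))))
    stop("input not coordinate-sorted: positions decrease within a reference")
  invisible(TRUE)
}

parse_optical_coords <- function(names, separator) {
  canon <- sub(paste0(separator, "[^", separator, "]*$"), "", names)
  parts <- strsplit(canon, ":", fixed = TRUE)
  ok <- lengths(parts) >= 7L
  tile <- x <- y <- rep(NA_integer_, length(names))
  if (any(ok)) {
    tile[ok] <- suppressWarnings(as.integer(vapply(parts[ok], `[[`, "", 5L)))
    x[ok] <- suppressWarnings(as.integer(vapply(parts[ok], `[[`, "", 6L)))
    y[ok] <- suppressWarnings(as.integer(vapply(parts[ok], `[[`, "", 7L)))
  }
  data.frame(tile = tile, x = x, y = y)
}

#' Mark or remove PCR duplicates using mapping position and UMIs
#'
#' Extends position-based duplicate marking with the UMIs embedded in read
#' names by the demultiplexing/clipping stages. Reads (pairs) are first
#' grouped by library-independent alignment geometry -- reference, strand
#' (orientation for pairs) and unclipped 5' coordinate(s) -- exactly the
#' grouping a position-only duplicate marker uses. Each position group is
#' then subdivided by UMI via [cluster_umis()]; within every UMI group one
#' representative (per `strategy`) keeps flag bit 1024 (0x400) clear and
#' all other members are marked duplicates (or dropped when
#' `remove = TRUE`). Unmapped, secondary and supplementary records pass
#' through untouched.
#'
#' Pairs and single fragments are compared in disjoint key spaces. The UMI
#' of a pair is the single concatenated tag both mates carry in their
#' (identical) name.
#'
#' @param input path to a coordinate-sorted SAM/BAM file, or an alignment
#'   list from [read_sam()].
#' @param output optional path for the marked SAM/BAM.
#' @param metrics_out optional path for the metrics TSV.
#' @param separator UMI separator in read names.
#' @param umi_max_mm mismatches tolerated between UMIs of one molecule.
#' @param n_policy,predefined see [cluster_umis()]; `predefined` may be a
#'   character vector or the path of a text file with one UMI per line.
#' @param strategy representative choice, see [select_representative()].
#' @param remove drop duplicates instead of flagging them.
#' @param on_missing_umi see [extract_umi_from_name()]; skipped reads pass
#'   through unmarked and uncounted.
#' @param optical also count optical duplicates (same tile, x/y within
#'   `pixel_distance`, coordinates parsed from Illumina-style name fields
#'   5-7); they remain ordinary duplicates in the output, the count is
#'   informational.
#' @param pixel_distance optical proximity threshold in pixels.
#' @return list with `aln` (the marked alignment list) and `metrics`
#'   (a `dup_metrics`), invisibly when `output` is given.
#' @export
mark_duplicates <- function(input, output = NULL, metrics_out = NULL,
                            separator = ":", umi_max_mm = 1L,
                            n_policy = c("MATCH", "MISMATCH", "DISCARD"),
                            predefined = NULL,
                            strategy = c("SUM_OF_BASE_QUALITIES",
                                         "TOTAL_MAPPED_REFERENCE_LENGTH",
                                         "RANDOM"),
                            remove = FALSE,
                            on_missing_umi = c("error", "skip"),
                            optical = FALSE, pixel_distance = 100L) {
  n_policy <- match.arg(n_policy)
  strategy <- match.arg(strategy)
  on_missing_umi <- match.arg(on_missing_umi)
  aln <- if (is.character(input)) read_sam(input) else input
  reads <- aln$reads
  check_coordinate_sorted(reads, aln$header)
  if (length(predefined) == 1L && file.exists(predefined))
    predefined <- readLines(predefined)

  eligible <- !flag_has(reads$flag, FLAG_UNMAPPED) &
    !flag_has(reads$flag, FLAG_SECONDARY) &
    !flag_has(reads$flag, FLAG_SUPPLEMENTARY)
  umi_all <- rep(NA_character_, nrow(reads))
  if (any(eligible))
    umi_all[eligible] <- extract_umi_from_name(reads$qname[eligible],
                                               separator, on_missing_umi)
  skipped <- eligible & is.na(umi_all)
  eligible <- eligible & !is.na(umi_all)

  ents <- build_entities(reads, eligible)
  n_ent <- length(ents$rows)
  ent_umi <- vapply(ents$rows, function(j) umi_all[j[1L]], "")
  ent_score <- switch(strategy,
    SUM_OF_BASE_QUALITIES = vapply(ents$rows, function(j)
      sum(sum_base_qualities(reads$qual[j])), 1),
    TOTAL_MAPPED_REFERENCE_LENGTH = vapply(ents$rows, function(j)
      sum(cigar_ref_len(reads$cigar[j])), 1),
    RANDOM = rep(0, n_ent))

  is_dup <- rep(FALSE, n_ent)
  n_pos_groups <- 0L; n_umi_groups <- 0L; n_optical <- 0L
  opt <- if (optical) parse_optical_coords(reads$qname, separator)

  for (g in split(seq_len(n_ent), ents$key)) {
    n_pos_groups <- n_pos_groups + 1L
    counts <- table(ent_umi[g])
    cl <- cluster_umis(stats::setNames(as.integer(counts), names(counts)),
                       max_mm = umi_max_mm, n_policy = n_policy,
                       predefined = predefined)
    rep_of <- stats::setNames(cl$representative, cl$umi)
    for (ug in split(g, rep_of[ent_umi[g]])) {
      n_umi_groups <- n_umi_groups + 1L
      keep <- select_representative(ents$name[ug], ent_score[ug], strategy)
      dup <- ug[ents$name[ug] != keep]
      is_dup[dup] <- TRUE
      if (optical && length(dup)) {
        rep_row <- ents$rows[[ug[ents$name[ug] == keep][1L]]][1L]
        for (d in dup) {
          drow <- ents$rows[[d]][1L]
          if (!is.na(opt$tile[drow]) && !is.na(opt$tile[rep_row]) &&
              opt$tile[drow] == opt$tile[rep_row] &&
              abs(opt$x[drow] - opt$x[rep_row]) <= pixel_distance &&
              abs(opt$y[drow] - opt$y[rep_row]) <= pixel_distance)
            n_optical <- n_optical + 1L
        }
      }
    }
  }

  # apply flags at the record level
  flag <- reads$flag
  elig_rows <- unlist(ents$rows[!is_dup])
  dup_rows <- unlist(ents$rows[is_dup])
  flag[elig_rows] <- bitwAnd(flag[elig_rows], bitwNot(FLAG_DUP))
  if (length(dup_rows)) flag[dup_rows] <- bitwOr(flag[dup_rows], FLAG_DUP)
  reads$flag <- flag
  if (remove && length(dup_rows))
    reads <- reads[-dup_rows, , drop = FALSE]
  aln$reads <- reads

  metrics <- dup_metrics(reads_examined = n_ent,
                         positional_unique = n_pos_groups,
                         umi_aware_unique = n_umi_groups,
                         optical_duplicates = n_optical)
  if (!is.null(output)) write_sam(aln, output)
  if (!is.null(metrics_out)) write_dup_metrics(metrics, metrics_out)
  if (any(skipped))
    message(sum(skipped), " reads without UMI passed through unexamined")
  res <- list(aln = aln, metrics = metrics)
  if (is.null(output)) res else invisible(res)
}
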