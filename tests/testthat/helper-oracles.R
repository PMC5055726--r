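# Independent oracle implementations, written as plain loops so they share
# no code path with the package internals they check.

# per-read brute-force sample assignment under the declared N/quality rules
oracle_assign <- function(observed, quals, candidates, max_mm, min_gap,
                          min_quality) {
  dist1 <- function(obs, q, bc) {
    d <- 0L
    for (i in seq_len(nchar(bc))) {
      b <- substr(bc, i, i)
      if (b == "N") next
      o <- substr(obs, i, i)
      qv <- utf8ToInt(substr(q, i, i)) - 33L
      if (o == "N" || qv < min_quality || o != b) d <- d + 1L
    }
    d
  }
  out_sample <- character(length(observed))
  for (r in seq_along(observed)) {
    per_sample <- tapply(seq_len(nrow(candidates)), candidates$sample,
                         function(rows) min(vapply(rows, function(k)
                           dist1(observed[r], quals[r], candidates$barcode[k]),
                           1L)))
    per_sample <- sort(unlist(per_sample))
    best <- per_sample[1L]
    gap <- if (length(per_sample) > 1L) per_sample[2L] - best else Inf
    unique_best <- sum(per_sample == best) == 1L
    out_sample[r] <- if (best <= max_mm && gap >= min_gap && unique_best)
      names(per_sample)[1L] else NA_character_
  }
  out_sample
}

# independent greedy frequency-ranked UMI clustering (free mode, N = MATCH)
oracle_greedy_umis <- function(umi_counts, max_mm) {
  hamming_n <- function(a, b) {
    d <- 0L
    for (i in seq_len(nchar(a))) {
      ca <- substr(a, i, i); cb <- substr(b, i, i)
      if (ca != "N" && cb != "N" && ca != cb) d <- d + 1L
    }
    d
  }
  # stable ordering: count desc, then lexicographic
  umis <- names(umi_counts)[order(-umi_counts, names(umi_counts))]
  rep_of <- stats::setNames(rep(NA_character_, length(umis)), umis)
  for (u in umis) {
    if (!is.na(rep_of[u])) next
    rep_of[u] <- u
    for (v in umis) {
      if (!is.na(rep_of[v])) next
      if (hamming_n(u, v) <= max_mm) rep_of[v] <- u
    }
  }
  rep_of
}

# position-only duplicate marker: groups primary mapped reads by reference,
# strand and unclipped 5' coordinate(s), keeps the highest-quality member of
# each group (ties by name), marks the rest. Own CIGAR arithmetic.
oracle_mark_positional <- function(aln) {
  r <- aln$reads
  cig_ops <- function(cigar) {
    m <- gregexpr("([0-9]+)([A-Z=])", cigar)[[1L]]
    toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1L]]
    list(len = as.integer(sub(".$", "", toks)), op = sub("^[0-9]+", "", toks))
  }
  u5 <- function(pos, cigar, rev) {
    c <- cig_ops(cigar)
    if (!rev) {
      lead <- 0L
      for (i in seq_along(c$op)) {
        if (c$op[i] %in% c("S", "H")) lead <- lead + c$len[i] else break
      }
      pos - lead
    } else {
      reflen <- sum(c$len[c$op %in% c("M", "D", "N", "=", "X")])
      trail <- 0L
      for (i in rev(seq_along(c$op))) {
        if (c$op[i] %in% c("S", "H")) trail <- trail + c$len[i] else break
      }
      pos + reflen - 1L + trail
    }
  }
  qsum <- function(q) if (q == "*") 0L else sum(utf8ToInt(q) - 33L)
  elig <- bitwAnd(r$flag, 4L + 256L + 2048L) == 0L
  key <- rep(NA_character_, nrow(r))
  for (i in which(elig)) {
    rev <- bitwAnd(r$flag[i], 16L) != 0L
    key[i] <- paste(r$rname[i], if (rev) "-" else "+",
                    u5(r$pos[i], r$cigar[i], rev))
  }
  dup <- rep(FALSE, nrow(r))
  for (k in unique(key[!is.na(key)])) {
    g <- which(!is.na(key) & key == k)
    scores <- vapply(g, function(i) qsum(r$qual[i]), 1L)
    keepers <- g[scores == max(scores)]
    keep <- keepers[order(r$qname[keepers])][1L]
    dup[setdiff(g, keep)] <- TRUE
  }
  flag <- bitwAnd(r$flag, bitwNot(1024L))
  flag[dup] <- bitwOr(flag[dup], 1024L)
  list(flag = flag, n_groups = length(unique(key[!is.na(key)])))
}

# random valid sample sheet for round-trip / conservation properties
random_sheet <- function(n_samples, blen, dual = FALSE, n_alt = 1L) {
  b1 <- random_barcodes(n_samples * n_alt, blen)
  end1 <- split(b1, rep(seq_len(n_samples), each = n_alt))
  specs <- vapply(end1, paste, "", collapse = "|")
  if (dual) {
    b2 <- random_barcodes(n_samples, blen)
    specs <- paste0(specs, ":", b2)
  }
  sample_sheet(sprintf("S%02d", seq_len(n_samples)), unname(specs))
}

make_sam <- function(qname, flag, pos, cigar, rname = "chr1", qual = NULL,
                     mapq = 60L, rnext = "*", pnext = 0L, tlen = 0L,
                     seq = NULL, sort_by_pos = TRUE) {
  n <- length(qname)
  rlen <- vapply(cigar, function(c) {
    toks <- regmatches(c, gregexpr("[0-9]+[A-Z=]", c))[[1L]]
    sum(as.integer(sub(".$", "", toks))[!sub("^[0-9]+", "", toks) %in%
                                          c("D", "N", "H", "P")])
  }, 1L)
  if (is.null(seq)) seq <- unname(vapply(rlen, function(l)
    paste(rep("A", max(l, 1L)), collapse = ""), ""))
  if (is.null(qual)) qual <- unname(vapply(rlen, function(l)
    paste(rep("I", max(l, 1L)), collapse = ""), ""))
  reads <- data.frame(qname = qname, flag = as.integer(flag),
                      rname = rep_len(rname, n), pos = as.integer(pos),
                      mapq = rep_len(as.integer(mapq), n), cigar = cigar,
                      rnext = rep_len(rnext, n),
                      pnext = rep_len(as.integer(pnext), n),
                      tlen = rep_len(as.integer(tlen), n), seq = seq,
                      qual = qual, tags = "", stringsAsFactors = FALSE)
  if (sort_by_pos) reads <- reads[order(reads$rname, reads$pos), ]
  list(header = c("@HD\tVN:1.6\tSO:coordinate",
                  "@SQ\tSN:chr1\tLN:100000", "@SQ\tSN:chr2\tLN:100000"),
       reads = reads)
}

random_records <- function(n, len = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                 prob = c(.24, .24, .24, .24, .04)), collapse = ""), "")
  quals <- vapply(seq_len(n), function(i)
    intToUtf8(sample(33:73, len, replace = TRUE)), "")
  read_record(sprintf("read%05d", seq_len(n)), bases, quals,
              comment = ifelse(seq_len(n) %% 3L == 0L, "extra info", ""))
}
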