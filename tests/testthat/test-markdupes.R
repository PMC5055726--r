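test_that("unclipped 5' positions follow hand CIGAR arithmetic", {
  expect_equal(unclipped_5prime(100L, "50M", FALSE), 100L)
  expect_equal(unclipped_5prime(100L, "5S45M", FALSE), 95L)
  expect_equal(unclipped_5prime(100L, "45M5S", TRUE), 149L)
  expect_equal(unclipped_5prime(100L, "3H2S45M", FALSE), 95L)
  # deletions/introns consume reference, insertions do not
  expect_equal(unclipped_5prime(100L, "20M5D20M", TRUE), 144L)
  expect_equal(unclipped_5prime(100L, "20M5I20M", TRUE), 139L)
  expect_error(unclipped_5prime(100L, "*", FALSE), "CIGAR")
})

test_that("UMI extraction validates and takes the last separator field", {
  expect_equal(extract_umi_from_name("r1:ACGT"), "ACGT")
  expect_equal(extract_umi_from_name("a:b:GGTT"), "GGTT")
  expect_error(extract_umi_from_name("nofield"), "no UMI")
  expect_error(extract_umi_from_name("r1:ACGU"), "no UMI")
  expect_warning(u <- extract_umi_from_name(c("r1:ACGT", "bad"),
                                            on_missing = "skip"), "skipped")
  expect_equal(u, c("ACGT", NA))
})

test_that("greedy UMI clustering matches hand checks and the independent
           oracle", {
  cl <- cluster_umis(c(AAAA = 5L, AAAT = 1L), max_mm = 1L)
  expect_equal(unique(cl$representative), "AAAA")
  expect_equal(sum(cl$count), 6L)

  cl <- cluster_umis(c(AAAA = 3L, TTTT = 3L), max_mm = 0L)
  expect_equal(sort(unique(cl$representative)), c("AAAA", "TTTT"))

  # documented greedy outcome: AAAA (first by tie-broken rank) absorbs AAAT;
  # AATT is 2 mismatches from the representative AAAA so stays separate
  cl <- cluster_umis(c(AAAA = 2L, AAAT = 2L, AATT = 2L), max_mm = 1L)
  rep_of <- stats::setNames(cl$representative, cl$umi)
  expect_equal(unname(rep_of[c("AAAA", "AAAT", "AATT")]),
               c("AAAA", "AAAA", "AATT"))

  set.seed(99)
  for (trial in 1:25) {
    k <- sample(2:12, 1)
    umis <- unique(replicate(k, paste(sample(c("A", "C", "G", "T"), 4, TRUE),
                                      collapse = "")))
    counts <- stats::setNames(sample(1:20, length(umis), TRUE), umis)
    mm <- sample(0:2, 1)
    got <- cluster_umis(counts, max_mm = mm)
    want <- oracle_greedy_umis(counts, mm)
    expect_equal(stats::setNames(got$representative, got$umi), want[got$umi])
  }
})

test_that("UMI group count is non-increasing in max_mm", {
  set.seed(111)
  for (trial in 1:15) {
    umis <- unique(replicate(sample(3:15, 1),
                             paste(sample(c("A", "C", "G", "T"), 5, TRUE),
                                   collapse = "")))
    counts <- stats::setNames(sample(1:9, length(umis), TRUE), umis)
    sizes <- vapply(0:5, function(mm)
      length(unique(cluster_umis(counts, max_mm = mm)$representative)), 1L)
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("N policies behave as declared", {
  expect_equal(unique(cluster_umis(c(AANA = 2L, AAAA = 5L), 0L,
                                   n_policy = "MATCH")$representative), "AAAA")
  cl <- cluster_umis(c(AANA = 2L, AAAA = 5L), 0L, n_policy = "MISMATCH")
  expect_equal(length(unique(cl$representative)), 2L)
  cl <- cluster_umis(c(AANA = 2L, AAAA = 5L, AAAT = 1L), 1L,
                     n_policy = "DISCARD")
  rep_of <- stats::setNames(cl$representative, cl$umi)
  expect_equal(unname(rep_of["AANA"]), "AANA")  # own singleton group
  expect_equal(unname(rep_of["AAAT"]), "AAAA")
})

test_that("predefined UMI lists assign to nearest entry, conservatively", {
  pre <- c("AAAA", "CCCC")
  cl <- cluster_umis(c(AAAT = 3L, CCCA = 1L, GGGG = 2L), max_mm = 1L,
                     predefined = pre)
  rep_of <- stats::setNames(cl$representative, cl$umi)
  expect_equal(unname(rep_of[c("AAAT", "CCCA")]), c("AAAA", "CCCC"))
  expect_equal(unname(rep_of["GGGG"]), "GGGG")  # too far: own group
  # equidistant to two list entries: kept as own group, never guessed
  cl <- cluster_umis(c(AACC = 4L), max_mm = 2L, predefined = pre)
  expect_equal(cl$representative, "AACC")
})

test_that("representative selection is deterministic with documented ties", {
  expect_equal(select_representative("only", 5), "only")
  expect_equal(select_representative(c("a", "b"), c(30, 40)), "b")
  expect_equal(select_representative(c("b", "a"), c(7, 7)), "a")
})

test_that("three reads, two UMIs: exactly one duplicate flagged bit-exactly", {
  aln <- make_sam(qname = c("r1:AAAA", "r2:AAAA", "r3:TTTT"),
                  flag = 0L, pos = 100L, cigar = "50M")
  res <- mark_duplicates(aln, umi_max_mm = 0L)
  flags <- res$aln$reads$flag
  expect_equal(sum(bitwAnd(flags, 1024L) == 1024L), 1L)
  expect_equal(res$metrics$positional_unique, 1L)
  expect_equal(res$metrics$umi_aware_unique, 2L)
  expect_equal(res$metrics$duplicates_marked, 1L)
  expect_equal(res$metrics$gain_percent, 100)
  # the marked read is one of the AAAA pair, chosen by base-quality then name
  marked <- res$aln$reads$qname[bitwAnd(flags, 1024L) == 1024L]
  expect_equal(marked, "r2:AAAA")
})

test_that("remove = TRUE drops duplicates instead of flagging", {
  aln <- make_sam(qname = c("r1:AAAA", "r2:AAAA", "r3:TTTT"),
                  flag = 0L, pos = 100L, cigar = "50M")
  res <- mark_duplicates(aln, umi_max_mm = 0L, remove = TRUE)
  expect_equal(nrow(res$aln$reads), 2L)
  expect_true(all(bitwAnd(res$aln$reads$flag, 1024L) == 0L))
})

test_that("soft-clipped reads duplicate-group with unclipped ones", {
  aln <- make_sam(qname = c("r1:AAAA", "r2:AAAA"),
                  flag = 0L, pos = c(100L, 95L), cigar = c("5S45M", "50M"))
  # both have unclipped 5' = 95 -> same position group, same UMI -> 1 kept
  res <- mark_duplicates(aln)
  expect_equal(res$metrics$umi_aware_unique, 1L)
  expect_equal(res$metrics$duplicates_marked, 1L)
})

test_that("unmapped, secondary and supplementary records pass through", {
  aln <- make_sam(qname = c("r1:AAAA", "r2:AAAA", "u1:AAAA", "s1:AAAA"),
                  flag = c(0L, 0L, 4L, 256L),
                  pos = c(100L, 100L, 0L, 100L),
                  cigar = c("50M", "50M", "*", "50M"))
  res <- mark_duplicates(aln)
  expect_equal(res$metrics$reads_examined, 2L)
  passthrough <- res$aln$reads[res$aln$reads$qname %in% c("u1:AAAA", "s1:AAAA"), ]
  expect_true(all(bitwAnd(passthrough$flag, 1024L) == 0L))
  # even with remove: pass-through records are never dropped
  res <- mark_duplicates(aln, remove = TRUE)
  expect_equal(nrow(res$aln$reads), 3L)
})

test_that("pairs group by both unclipped ends and never mix with fragments", {
  pair_reads <- function(base, pos1, pos2, umi) {
    nm <- paste0(base, ":", umi)
    make_sam(qname = c(nm, nm, paste0("frag_", base, ":", umi)),
             flag = c(99L, 147L, 0L),
             pos = c(pos1, pos2, pos1),
             cigar = "50M")$reads
  }
  reads <- rbind(pair_reads("p1", 100L, 300L, "AAAA"),
                 pair_reads("p2", 100L, 300L, "AAAA"))
  reads <- reads[order(reads$pos), ]
  aln <- list(header = c("@HD\tVN:1.6\tSO:coordinate",
                         "@SQ\tSN:chr1\tLN:100000"), reads = reads)
  res <- mark_duplicates(aln)
  # 2 pair entities (one dup) + 2 fragment entities at one position (one dup)
  expect_equal(res$metrics$reads_examined, 4L)
  expect_equal(res$metrics$positional_unique, 2L)
  expect_equal(res$metrics$umi_aware_unique, 2L)
  r <- res$aln$reads
  dup_pair <- unique(r$qname[bitwAnd(r$flag, 1024L) == 1024L &
                               bitwAnd(r$flag, 1L) == 1L])
  expect_length(dup_pair, 1L)  # exactly one whole pair marked
  expect_equal(sum(bitwAnd(r$flag, 1024L) == 1024L), 3L)  # 2 mates + 1 frag
})

test_that("within each position group UMI groups partition the reads", {
  set.seed(123)
  cfg <- sim_config(n_positions = 8L, molecules_per_position = 6L,
                    dup_mean = 4, umi_len = 6L, layout1 = "U6B6",
                    error_rate = 0.02, seed = 321L)
  sim <- simulate_aligned_library(cfg)
  res <- mark_duplicates(sim$aln, umi_max_mm = 1L)
  r <- res$aln$reads
  expect_equal(res$metrics$reads_examined, nrow(r))
  expect_equal(res$metrics$reads_examined - res$metrics$umi_aware_unique,
               sum(bitwAnd(r$flag, 1024L) == 1024L))
  # one representative per UMI group: unique count equals unmarked count
  expect_equal(res$metrics$umi_aware_unique,
               sum(bitwAnd(r$flag, 1024L) == 0L))
  expect_gte(res$metrics$umi_aware_unique, res$metrics$positional_unique)
})

test_that("all-identical UMIs reduce to the position-only oracle, flag by
           flag", {
  set.seed(222)
  for (trial in 1:5) {
    n <- 60L
    aln <- make_sam(qname = paste0(sprintf("r%03d", 1:n), ":ACGTACGT"),
                    flag = sample(c(0L, 16L), n, TRUE),
                    pos = sample(100:110, n, TRUE),
                    cigar = sample(c("50M", "5S45M", "45M5S"), n, TRUE),
                    rname = sample(c("chr1", "chr2"), n, TRUE))
    res <- mark_duplicates(aln)
    oracle <- oracle_mark_positional(aln)
    expect_identical(res$aln$reads$flag, oracle$flag)
    expect_equal(res$metrics$positional_unique, oracle$n_groups)
    expect_equal(res$metrics$umi_aware_unique, oracle$n_groups)
    expect_equal(res$metrics$gain_percent, 0)
  }
})

test_that("unsorted input and gain edge cases are rejected", {
  aln <- make_sam(qname = c("r1:AAAA", "r2:AAAA"), flag = 0L,
                  pos = c(200L, 100L), cigar = "50M", sort_by_pos = FALSE)
  expect_error(mark_duplicates(aln), "not coordinate-sorted")
  expect_equal(compute_gain(124L, 100L), 24)
  expect_equal(compute_gain(77L, 77L), 0)
  expect_error(compute_gain(5L, 0L), ">= 1")
  expect_error(compute_gain(4L, 5L), "cannot be below")
})

test_that("metrics TSV round-trips through the documented columns", {
  aln <- make_sam(qname = c("r1:AAAA", "r2:AAAA", "r3:TTTT"),
                  flag = 0L, pos = 100L, cigar = "50M")
  td <- withr::local_tempdir()
  out <- file.path(td, "marked.sam"); mtr <- file.path(td, "metrics.tsv")
  mark_duplicates(aln, output = out, metrics_out = mtr)
  df <- read.table(mtr, header = TRUE, sep = "\t")
  expect_equal(names(df), c("READS_EXAMINED", "POSITIONAL_UNIQUE",
                            "UMI_AWARE_UNIQUE", "DUPLICATES_MARKED",
                            "OPTICAL_DUPLICATES", "GAIN_PERCENT"))
  expect_equal(df$READS_EXAMINED, 3L)
  expect_equal(df$GAIN_PERCENT, 100)
  back <- read_sam(out)
  expect_equal(sum(bitwAnd(back$reads$flag, 1024L) == 1024L), 1L)
})

test_that("optical duplicates are counted from Illumina-style coordinates", {
  nm <- function(tile, x, y, umi)
    paste0("M1:5:FC:1:", tile, ":", x, ":", y, ":", umi)
  aln <- make_sam(qname = c(nm(7, 1000, 1000, "AAAA"),
                            nm(7, 1010, 1005, "AAAA"),
                            nm(7, 9000, 9000, "AAAA")),
                  flag = 0L, pos = 100L, cigar = "50M")
  res <- mark_duplicates(aln, optical = TRUE, pixel_distance = 100L)
  expect_equal(res$metrics$duplicates_marked, 2L)
  expect_equal(res$metrics$optical_duplicates, 1L)
})
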