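demux_dir <- function() withr::local_tempdir(.local_envir = parent.frame())

test_that("exact-barcode reads route to their samples", {
  td <- demux_dir()
  sheet <- sample_sheet(c("s1", "s2"), c("AAAACC", "GGTTGG"))
  reads <- read_record(sprintf("r%02d", 1:20),
                       paste0(rep(c("AAAACC", "GGTTGG"), each = 10),
                              strrep("ACGT", 5)),
                       strrep("I", 26))
  fq <- file.path(td, "in.fastq"); write_fastq(reads, fq)
  m <- demultiplex_run(fq, sheet = sheet, layout1 = "B6",
                       max_mm = 0L, out_dir = file.path(td, "out"))
  expect_equal(unname(m$per_sample), c(10, 10))
  expect_equal(m$unassigned, 0)
  out <- read_fastq(file.path(td, "out", "s1_1.fastq"))
  expect_equal(nrow(out), 10L)
  expect_equal(unique(nchar(out$bases)), 20L)  # barcode clipped

  metrics_file <- read_demux_metrics(file.path(td, "out", "demux_metrics.tsv"))
  expect_equal(metrics_file$per_sample, m$per_sample)
  expect_equal(metrics_file$total, 20)
})

test_that("reads beyond max_mm go to unassigned, kept raw and unclipped", {
  td <- demux_dir()
  sheet <- sample_sheet("s1", "AAAACC")
  reads <- read_record(c("ok", "bad"), c("AAAACCGGGG", "AATTCCGGGG"),
                       strrep("I", 10))
  fq <- file.path(td, "in.fastq"); write_fastq(reads, fq)
  m <- demultiplex_run(fq, sheet = sheet, layout1 = "B6", max_mm = 1L,
                       out_dir = file.path(td, "out"))
  expect_equal(m$unassigned, 1)
  un <- read_fastq(file.path(td, "out", "unassigned_1.fastq"))
  expect_equal(un$name, "bad")
  expect_equal(un$bases, "AATTCCGGGG")  # raw, not clipped
})

test_that("too-short reads are routed to unassigned", {
  td <- demux_dir()
  sheet <- sample_sheet("s1", "AAAA")
  reads <- read_record(c("r1", "r2"), c("AAAAGGGG", "AAA"), c(strrep("I", 8), "III"))
  fq <- file.path(td, "in.fastq"); write_fastq(reads, fq)
  m <- demultiplex_run(fq, sheet = sheet, layout1 = "B4",
                       out_dir = file.path(td, "out"))
  expect_equal(m$unassigned, 1)
  expect_equal(sum(m$per_sample), 1)
})

test_that("zero-error synthetic runs recover the truth table exactly", {
  td <- demux_dir()
  for (layout in list(c("U8B6", NA), c("U4B6U4", NA), c("B6", "U8"))) {
    l2 <- if (is.na(layout[2])) NULL else layout[2]
    cfg <- sim_config(n_samples = 3L, molecules_per_sample = 30L,
                      layout1 = layout[1], layout2 = l2,
                      dup_mean = 2, error_rate = 0, seed = 101L)
    sim <- simulate_multiplexed_fastq(cfg, file.path(td, layout[1]))
    out <- file.path(td, layout[1], "out")
    demultiplex_run(sim$fastq1, sim$fastq2, sim$sheet, cfg$layout1,
                    if (!is.null(l2)) cfg$layout2, out_dir = out)
    ev <- evaluate_against_truth(
      sim$truth, assignments = demux_assignments(out, sim$sheet$samples))
    expect_equal(ev$demux$precision, 1.0)
    expect_equal(ev$demux$recall, 1.0)
  }
})

test_that("UMIs land in headers of both mates and pair files stay in step", {
  td <- demux_dir()
  cfg <- sim_config(n_samples = 2L, molecules_per_sample = 25L,
                    layout1 = "B6", layout2 = "U8", dup_mean = 1.5,
                    seed = 55L)
  sim <- simulate_multiplexed_fastq(cfg, td)
  out <- file.path(td, "out")
  demultiplex_run(sim$fastq1, sim$fastq2, sim$sheet, cfg$layout1, cfg$layout2,
                  out_dir = out)
  for (s in sim$sheet$samples) {
    r1 <- read_fastq(file.path(out, paste0(s, "_1.fastq")))
    r2 <- read_fastq(file.path(out, paste0(s, "_2.fastq")))
    expect_equal(canonical_name(r1$name), canonical_name(r2$name))
    expect_true(all(grepl(":[ACGTN]{8}$", r1$name)))
    # header UMI equals the molecule UMI recorded in the truth table
    orig <- sub(":[ACGTN]{8}$", "", r1$name)
    umi <- extract_umi_from_name(r1$name)
    expect_equal(umi, sim$truth$umi[match(orig, sim$truth$read)])
  }
})

test_that("desynchronised mate files abort with the record index", {
  td <- demux_dir()
  sheet <- sample_sheet("s1", "AAAA")
  r1 <- read_record(c("a", "b"), c("AAAAGG", "AAAAGG"), rep(strrep("I", 6), 2))
  r2 <- read_record(c("a", "x"), c("TTTTGG", "TTTTGG"), rep(strrep("I", 6), 2))
  f1 <- file.path(td, "r1.fastq"); f2 <- file.path(td, "r2.fastq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_error(
    demultiplex_run(f1, f2, sheet, "B4", out_dir = file.path(td, "out")),
    "record 2")
})

test_that("conservation holds over random sheets, layouts and options", {
  set.seed(77)
  for (trial in 1:10) {
    td <- withr::local_tempdir()
    paired <- sample(c(TRUE, FALSE), 1)
    layout1 <- sample(c("B6", "U4B6", "U2B6U2", "S2B6"), 1)
    layout2 <- if (paired) sample(c(NA, "U4", "B6"), 1) else NA
    cfg <- sim_config(n_samples = sample(2:4, 1),
                      umi_len = parse_layout(layout1)$umi_len +
                        (if (!is.na(layout2)) parse_layout(layout2)$umi_len else 0L),
                      layout1 = layout1,
                      layout2 = if (!is.na(layout2)) layout2,
                      molecules_per_sample = 20L, dup_mean = 2,
                      error_rate = runif(1, 0, 0.05), read_len = 40L,
                      seed = sample.int(1e6, 1))
    sim <- simulate_multiplexed_fastq(cfg, td)
    m <- demultiplex_run(sim$fastq1, sim$fastq2, sim$sheet, cfg$layout1,
                         cfg$layout2,
                         strategy = sample(c("BOTH", "EITHER"), 1),
                         max_mm = sample(0:2, 1), min_gap = sample(0:1, 1),
                         out_dir = file.path(td, "out"))
    expect_equal(sum(m$per_sample) + m$unassigned, m$total)
    expect_equal(m$total, nrow(sim$truth))
    expect_lte(m$ambiguous, m$unassigned)
  }
})

test_that("two runs on identical input produce byte-identical outputs", {
  td <- demux_dir()
  cfg <- sim_config(n_samples = 2L, molecules_per_sample = 30L,
                    error_rate = 0.01, seed = 9L)
  sim <- simulate_multiplexed_fastq(cfg, td)
  for (run in c("a", "b"))
    demultiplex_run(sim$fastq1, sheet = sim$sheet, layout1 = cfg$layout1,
                    out_dir = file.path(td, run), gzip = TRUE, md5 = TRUE)
  fa <- list.files(file.path(td, "a"), full.names = TRUE)
  for (f in fa) {
    g <- file.path(td, "b", basename(f))
    expect_identical(readBin(f, "raw", file.size(f)),
                     readBin(g, "raw", file.size(g)), label = basename(f))
  }
})

test_that("end-specific dual barcodes identify combined sample identities", {
  td <- demux_dir()
  # combinatorial: end-1 barcode shared, only the pair resolves the sample
  sheet <- sample_sheet(c("s1", "s2"), c("AAAACC:GGGGTT", "AAAACC:CCCCAA"))
  r1 <- read_record(c("a", "b"), rep("AAAACCGGGG", 2), rep(strrep("I", 10), 2))
  r2 <- read_record(c("a", "b"), c("GGGGTTAAAA", "CCCCAAAAAA"),
                    rep(strrep("I", 10), 2))
  f1 <- file.path(td, "r1.fastq"); f2 <- file.path(td, "r2.fastq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  m <- demultiplex_run(f1, f2, sheet, "B6", "B6", out_dir = file.path(td, "out"))
  expect_equal(unname(m$per_sample), c(1, 1))
  expect_equal(read_fastq(file.path(td, "out", "s1_1.fastq"))$name, "a")
  expect_equal(read_fastq(file.path(td, "out", "s2_1.fastq"))$name, "b")
})

test_that("clip extracts UMIs without demultiplexing", {
  td <- demux_dir()
  reads <- read_record(sprintf("r%d", 1:5),
                       paste0(c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT"),
                              strrep("G", 10)),
                       strrep("I", 14))
  fq <- file.path(td, "in.fastq"); write_fastq(reads, fq)
  m <- clip_run(fq, layout1 = "U4", out_dir = file.path(td, "out"))
  out <- read_fastq(file.path(td, "out", "clipped_1.fastq"))
  expect_equal(nrow(out), 5L)
  expect_equal(unique(nchar(out$bases)), 10L)
  expect_equal(out$name, paste0(reads$name, ":", substr(reads$bases, 1, 4)))
  expect_error(clip_run(fq, layout1 = "B4", out_dir = td), "B")
})

test_that("clip equals demultiplexing with an all-degenerate one-sample sheet", {
  td <- demux_dir()
  cfg <- sim_config(n_samples = 1L, molecules_per_sample = 40L,
                    layout1 = "U8B6", dup_mean = 2, seed = 13L)
  sim <- simulate_multiplexed_fastq(cfg, td)
  # clip treats the barcode block as a spacer; demux matches it against NNNNNN
  clip_run(sim$fastq1, layout1 = "U8S6", out_dir = file.path(td, "clip"))
  sheet <- sample_sheet("clipped", "NNNNNN")
  demultiplex_run(sim$fastq1, sheet = sheet, layout1 = "U8B6",
                  out_dir = file.path(td, "dm"))
  a <- read_fastq(file.path(td, "clip", "clipped_1.fastq"))
  b <- read_fastq(file.path(td, "dm", "clipped_1.fastq"))
  expect_identical(a, b)
})
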