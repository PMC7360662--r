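sim_fusion <- function() {
  ref <- get_test_reference()
  build_fusion_transcript(ref$models$KIAA1549, 16, ref$models$BRAF, 9)
}

test_that("fusion transcript is the 5' part through exon5 plus the 3' part from exon3", {
  ft <- build_fusion_transcript(toy_model5(), 2, toy_model3(), 1)
  expect_equal(ft$seq, paste0("AAAACCCC", "GGTTGGTT"))
  expect_equal(ft$breakpoint_offset, 8L)

  # last exon of model5 + exon 1 of model3 = full-length concatenation
  ref <- get_test_reference()
  m5 <- ref$models$KIAA1549; m3 <- ref$models$BRAF
  full <- build_fusion_transcript(m5, nrow(m5$exons), m3, 1)
  expect_equal(full$seq, paste0(m5$spliced_seq, m3$spliced_seq))

  # a junction with flanks >= both transcript lengths equals the transcript
  ft2 <- sim_fusion()
  j <- build_junction(m5, 16, m3, 9,
                      flank_target = max(nchar(m5$spliced_seq),
                                         nchar(m3$spliced_seq)))
  expect_equal(j$contig, ft2$seq)
  expect_equal(j$breakpoint_offset, ft2$breakpoint_offset)
})

test_that("simulation is deterministic and honors the no-fusion configuration", {
  dir <- withr::local_tempdir()
  wt <- toy_transcripts()
  cfg <- simulation_config(400, wt, fusion = NULL, fusion_fraction = 0,
                           seed = 5L)
  s1 <- simulate_sample(cfg, file.path(dir, "a"))
  s2 <- simulate_sample(cfg, file.path(dir, "b"))
  expect_identical(unname(tools::md5sum(s1$fastq1_path)),
                   unname(tools::md5sum(s2$fastq1_path)))
  expect_identical(unname(tools::md5sum(s1$fastq2_path)),
                   unname(tools::md5sum(s2$fastq2_path)))
  expect_identical(readLines(s1$truth_path), readLines(s2$truth_path))

  truth <- read_truth(s1$truth_path)
  expect_equal(nrow(truth), 400L)
  expect_false(any(truth$spans_junction))
  expect_true(all(truth$source %in% names(wt)))

  # fusion_fraction > 0 without a fusion transcript is an error
  cfg_bad <- simulation_config(10, wt, fusion = NULL, fusion_fraction = 0.5)
  expect_error(simulate_sample(cfg_bad, file.path(dir, "c")),
               "no fusion transcript")

  # a different seed changes the reads
  s3 <- simulate_sample(simulation_config(400, wt, fusion_fraction = 0,
                                          seed = 6L), file.path(dir, "d"))
  expect_false(identical(unname(tools::md5sum(s1$fastq1_path)),
                         unname(tools::md5sum(s3$fastq1_path))))
})

test_that("reads are exact (rc-)substrings of their source at error rate 0", {
  dir <- withr::local_tempdir()
  wt <- toy_transcripts()
  ft <- sim_fusion()
  cfg <- simulation_config(300, wt, fusion = ft, fusion_fraction = 0.2,
                           error_rate = 0, seed = 8L)
  s <- simulate_sample(cfg, file.path(dir, "s"))
  truth <- read_truth(s$truth_path)
  r1 <- as.character(Biostrings::readDNAStringSet(s$fastq1_path,
                                                  format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(s$fastq2_path,
                                                  format = "fastq"))
  sources <- c(wt, stats::setNames(ft$seq, ft$id))
  for (i in seq_len(nrow(truth))) {
    src <- sources[[truth$source[i]]]
    for (r in c(r1[[i]], r2[[i]])) {
      expect_true(grepl(r, src, fixed = TRUE) ||
                    grepl(oracle_revcomp(r), src, fixed = TRUE),
                  info = sprintf("fragment %d not a substring of %s",
                                 i, truth$source[i]))
    }
  }

  # truth placement recomputes the reads exactly
  for (i in which(truth$read1_from_antisense == FALSE)[1:20]) {
    src <- sources[[truth$source[i]]]
    expect_equal(r1[[i]], substr(src, truth$read1_start[i] + 1,
                                 truth$read1_start[i] + 100))
    expect_equal(r2[[i]], oracle_revcomp(substr(src, truth$read2_start[i] + 1,
                                                truth$read2_start[i] + 100)))
  }
})

test_that("truth overhangs match an independent recomputation", {
  dir <- withr::local_tempdir()
  wt <- toy_transcripts()
  ft <- sim_fusion()
  cfg <- simulation_config(2000, wt, fusion = ft, fusion_fraction = 0.5,
                           seed = 9L)
  s <- simulate_sample(cfg, file.path(dir, "s"))
  truth <- read_truth(s$truth_path)
  b <- ft$breakpoint_offset
  fus <- truth$source == ft$id
  expect_true(any(fus))
  for (i in which(fus)) {
    for (m in 1:2) {
      w <- truth[[sprintf("read%d_start", m)]][i]
      o5 <- b - w; o3 <- w + 100 - b
      covers <- o5 >= 1 && o3 >= 1
      got5 <- truth[[sprintf("read%d_overhang5", m)]][i]
      if (covers) {
        expect_equal(got5, o5)
        expect_equal(truth[[sprintf("read%d_overhang3", m)]][i], o3)
        expect_equal(got5 + truth[[sprintf("read%d_overhang3", m)]][i], 100L)
      } else {
        expect_true(is.na(got5))
      }
    }
    win_cover <- vapply(1:2, function(m) {
      w <- truth[[sprintf("read%d_start", m)]][i]
      (b - w) >= 1 && (w + 100 - b) >= 1
    }, logical(1))
    expect_equal(truth$spans_junction[i], any(win_cover))
  }
  expect_false(any(truth$spans_junction[!fus]))
})

test_that("injected substitution rate is recovered within 3 standard errors", {
  dir <- withr::local_tempdir()
  wt <- toy_transcripts()
  e <- 0.004
  cfg <- simulation_config(6000, wt, fusion_fraction = 0, error_rate = e,
                           fragment_length_sd = 0, seed = 10L)
  s <- simulate_sample(cfg, file.path(dir, "s"))
  truth <- read_truth(s$truth_path)
  r1 <- as.character(Biostrings::readDNAStringSet(s$fastq1_path,
                                                  format = "fastq"))
  mm <- vapply(seq_along(r1), function(i) {
    src <- wt[[truth$source[i]]]
    win <- substr(src, truth$read1_start[i] + 1, truth$read1_start[i] + 100)
    if (truth$read1_from_antisense[i]) win <- oracle_revcomp(win)
    sum(utf8ToInt(r1[[i]]) != utf8ToInt(win))
  }, numeric(1))
  n_bases <- 100 * length(mm)
  se <- sqrt(e * (1 - e) * n_bases)
  expect_lt(abs(sum(mm) - e * n_bases), 3 * se)
})

test_that("closed-form spanning expectation matches brute-force enumeration", {
  wt <- toy_transcripts()
  ft <- sim_fusion()
  L <- nchar(ft$seq); b <- ft$breakpoint_offset
  R <- 100L

  mkcfg <- function(Fl, ff = 0.01, n = 1e5)
    simulation_config(n, wt, fusion = ft, fusion_fraction = ff,
                      read_length = R, fragment_length_mean = Fl,
                      fragment_length_sd = 0)

  # disjoint read-start windows: F > 2R gives |S| = 2 (R - 2o + 1) = 162
  ex <- expected_spanning_fragments(mkcfg(210), min_overhang = 10)
  expect_equal(ex, 1e5 * 0.01 * 162 / (L - 210 + 1))
  for (Fl in c(120L, 150L, 180L, 210L, 250L)) {
    for (o in c(10L, 25L, 50L)) {
      ex <- expected_spanning_fragments(mkcfg(Fl), min_overhang = o)
      n_oracle <- oracle_spanning_starts(L, Fl, R, b, o)
      expect_equal(ex, 1e5 * 0.01 * n_oracle / (L - Fl + 1),
                   info = sprintf("F=%d o=%d", Fl, o))
    }
  }

  # o = R/2: each window contributes exactly one start
  ex <- expected_spanning_fragments(mkcfg(210), min_overhang = 50)
  expect_equal(ex, 1e5 * 0.01 * 2 / (L - 210 + 1))

  # no fusion fragments, no expectation
  expect_equal(expected_spanning_fragments(mkcfg(210, ff = 0)), 0)

  # the formula refuses configurations it cannot describe
  expect_error(expected_spanning_fragments(
    simulation_config(10, wt, fusion = ft, fusion_fraction = 0.5,
                      fragment_length_sd = 30)), "fixed fragment length")
  near_end <- list(id = "x", seq = ft$seq, breakpoint_offset = 40L)
  expect_error(expected_spanning_fragments(
    simulation_config(10, wt, fusion = near_end, fusion_fraction = 0.5,
                      fragment_length_sd = 0)), "transcript ends")
})

test_that("simulated spanning counts follow the closed form (single seed)", {
  dir <- withr::local_tempdir()
  wt <- toy_transcripts()
  ft <- sim_fusion()
  cfg <- simulation_config(3e4, wt, fusion = ft, fusion_fraction = 0.02,
                           fragment_length_mean = 250, fragment_length_sd = 0,
                           seed = 12L)
  s <- simulate_sample(cfg, file.path(dir, "s"))
  truth <- read_truth(s$truth_path)
  o <- 10L
  spans <- with(truth, spans_junction &
                  (pmin(read1_overhang5, read1_overhang3) >= o |
                     pmin(read2_overhang5, read2_overhang3) >= o))
  spans[is.na(spans)] <- FALSE
  expected <- expected_spanning_fragments(cfg, min_overhang = o)
  p <- expected / cfg$n_fragments
  se <- sqrt(cfg$n_fragments * p * (1 - p))
  expect_lt(abs(sum(spans) - expected), 3 * se)
})
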