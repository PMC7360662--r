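test_that("exact breakpoint windows are found in both orientations", {
  set.seed(21)
  contig <- rand_dna(200)
  j <- toy_junction(contig, 100L)
  p <- scan_params()

  # 40 bp window centered on the breakpoint: offsets b-20 .. b+19
  read <- substr(contig, 81, 120)
  h <- scan_read(read, j, p)
  expect_equal(h$overhang5, 20L)
  expect_equal(h$overhang3, 20L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$contig_start, 80L)
  expect_equal(h$orientation, "forward")

  hrc <- scan_read(oracle_revcomp(read), j, p)
  expect_equal(hrc$orientation, "revcomp")
  expect_equal(hrc$overhang5, 20L)
  expect_equal(hrc$overhang3, 20L)

  # only 5 bases on the 3' side of the breakpoint: below min_overhang 10
  short3 <- substr(contig, 66, 105)
  expect_null(scan_read(short3, j, p))
  # but accepted once min_overhang allows it
  expect_false(is.null(scan_read(short3, j, scan_params(min_overhang = 5))))

  # reads that cannot span are skipped with a warning
  expect_warning(res <- scan_read(substr(contig, 95, 110), j,
                                  scan_params(min_overhang = 10)),
                 "cannot span")
  expect_null(res)
})

test_that("mismatch budget and N-as-mismatch policy are enforced", {
  set.seed(22)
  contig <- rand_dna(200)
  j <- toy_junction(contig, 100L)
  read <- substr(contig, 71, 130)

  mutate_at <- function(s, i) {
    cur <- substr(s, i, i)
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    s
  }
  r2 <- mutate_at(mutate_at(read, 5), 40)
  expect_equal(scan_read(r2, j, scan_params())$mismatches, 2L)
  r3 <- mutate_at(r2, 55)
  expect_null(scan_read(r3, j, scan_params(max_mismatches = 2)))
  expect_equal(scan_read(r3, j, scan_params(max_mismatches = 3))$mismatches, 3L)
  # strict exact mode mirrors a plain grep
  expect_null(scan_read(r2, j, scan_params(max_mismatches = 0)))
  expect_equal(scan_read(read, j, scan_params(max_mismatches = 0))$mismatches,
               0L)

  # N is a mismatch, never a wildcard: 3 Ns kill a 2-mismatch budget
  rn <- read
  substr(rn, 10, 12) <- "NNN"
  expect_null(scan_read(rn, j, scan_params(max_mismatches = 2)))
  expect_equal(scan_read(rn, j, scan_params(max_mismatches = 3))$mismatches, 3L)
})

test_that("scan_read agrees with the brute-force oracle on random cases", {
  set.seed(23)
  n_cases <- 250
  for (case in seq_len(n_cases)) {
    L <- sample(60:300, 1)
    b <- sample(20:(L - 20), 1)
    contig <- rand_dna(L)
    j <- toy_junction(contig, b)
    p <- scan_params(min_overhang = sample(1:15, 1),
                     max_mismatches = sample(0:4, 1),
                     seed_length = sample(8:20, 1),
                     min_aligned_fraction = sample(c(0.3, 0.5, 0.8, 1), 1),
                     both_orientations = sample(c(TRUE, FALSE), 1))
    w <- sample(30:120, 1)
    kind <- sample(3, 1)
    read <- if (kind == 1) {
      rand_dna(w)                                    # unrelated
    } else {
      # planted window overlapping the breakpoint, optionally mutated/rc'd
      s <- b - sample(0:(w - 1), 1)
      win <- substring(paste0(rand_dna(w), contig, rand_dna(w)),
                       s + w + 1, s + w + w)
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        at <- sample(w, nmut)
        for (i in at)
          substr(win, i, i) <- sample(c("A", "C", "G", "T", "N"), 1)
      }
      if (kind == 3) oracle_revcomp(win) else win
    }
    got <- suppressWarnings(scan_read(read, j, p))
    want <- oracle_scan(read, contig, b, p)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$mismatches, want$mismatches)
      expect_equal(got$contig_start, want$contig_start)
      expect_equal(got$aligned_length, want$aligned_length)
      expect_equal(got$overhang5, want$overhang5)
      expect_equal(got$overhang3, want$overhang3)
      expect_equal(got$orientation, want$orientation)
    }
  }
})

test_that("scan_fastq finds the planted spanning read and keeps counts", {
  set.seed(24)
  contig <- rand_dna(300)
  j <- toy_junction(contig, 150L)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "r1.fastq.gz"); f2 <- file.path(dir, "r2.fastq.gz")

  ids <- sprintf("frag%03d", 1:20)
  r1 <- vapply(1:20, function(i) rand_dna(100), "")
  r2 <- vapply(1:20, function(i) rand_dna(100), "")
  r1[7] <- substr(contig, 101, 200)   # spans with 50/50 overhangs
  write_test_fastq(paste0(ids, "/1"), r1, f1)
  write_test_fastq(paste0(ids, "/2"), r2, f2)

  res <- scan_fastq(f1, f2, j)
  expect_equal(res$stats$reads_scanned, 40L)
  expect_equal(res$stats$fragments_scanned, 20L)
  expect_equal(nrow(res$hits), 1L)
  expect_equal(res$hits$read_id, "frag007")
  expect_equal(res$hits$mate, 1L)
  expect_equal(res$hits$overhang5, 50L)

  # empty FASTQ pair
  write_test_fastq(character(0), character(0), f1)
  write_test_fastq(character(0), character(0), f2)
  res0 <- scan_fastq(f1, f2, j)
  expect_equal(res0$stats$reads_scanned, 0L)
  expect_equal(nrow(res0$hits), 0L)

  # desynchronized mates
  write_test_fastq(c("a/1", "b/1"), c(rand_dna(50), rand_dna(50)), f1)
  write_test_fastq(c("a/2", "c/2"), c(rand_dna(50), rand_dna(50)), f2)
  expect_error(scan_fastq(f1, f2, j), "desynchronized at record 2")
})

test_that("scan_fastq decisions equal per-read scan_read decisions", {
  set.seed(25)
  contig <- rand_dna(250)
  js <- list(toy_junction(contig, 100L, id = "A:B|e1:e1", "A", "B", 1L, 1L),
             toy_junction(rand_dna(240), 120L, id = "C:D|e2:e3",
                          "C", "D", 2L, 3L))
  p <- scan_params(min_overhang = 8, max_mismatches = 2)
  n <- 120
  mk <- function() {
    k <- sample(3, 1)
    if (k == 1) return(rand_dna(100))
    jx <- js[[sample(2, 1)]]
    s <- jx$breakpoint_offset - sample(10:90, 1)
    win <- substr(jx$contig, max(1, s + 1), max(1, s + 1) + 99)
    if (nchar(win) < 30) win <- rand_dna(100)
    if (k == 3) oracle_revcomp(win) else win
  }
  r1 <- vapply(seq_len(n), function(i) mk(), "")
  r2 <- vapply(seq_len(n), function(i) mk(), "")
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "m1.fq.gz"); f2 <- file.path(dir, "m2.fq.gz")
  ids <- sprintf("f%04d", seq_len(n))
  write_test_fastq(paste0(ids, "/1"), r1, f1)
  write_test_fastq(paste0(ids, "/2"), r2, f2)
  res <- scan_fastq(f1, f2, js, p)

  expected <- list()
  for (i in seq_len(n)) for (mate in 1:2) for (jx in js) {
    h <- suppressWarnings(
      scan_read(list(read_id = ids[i], mate = mate,
                     sequence = if (mate == 1) r1[i] else r2[i]), jx, p))
    if (!is.null(h)) expected[[length(expected) + 1L]] <- h
  }
  expected <- do.call(rbind, expected)
  got <- res$hits[order(res$hits$read_id, res$hits$mate, res$hits$junction_id), ]
  expected <- expected[order(expected$read_id, expected$mate,
                             expected$junction_id), ]
  rownames(got) <- rownames(expected) <- NULL
  expect_equal(got, expected)
})

test_that("hit counts are monotone in the contracts and scans are deterministic", {
  set.seed(26)
  contig <- rand_dna(260)
  j <- toy_junction(contig, 130L)
  reads <- character(80)
  for (i in seq_along(reads)) {
    s <- 130 - sample(5:95, 1)
    win <- substr(contig, s + 1, s + 100)
    at <- sample(100, sample(0:4, 1))
    for (q in at) substr(win, q, q) <- sample(c("A", "C", "G", "T"), 1)
    reads[i] <- win
  }
  n_hits <- function(p) sum(!vapply(reads, function(r)
    is.null(suppressWarnings(scan_read(r, j, p))), logical(1)))
  base <- n_hits(scan_params(min_overhang = 5, max_mismatches = 3))
  expect_lte(n_hits(scan_params(min_overhang = 10, max_mismatches = 3)), base)
  expect_lte(n_hits(scan_params(min_overhang = 20, max_mismatches = 3)),
             n_hits(scan_params(min_overhang = 10, max_mismatches = 3)))
  expect_lte(n_hits(scan_params(min_overhang = 5, max_mismatches = 1)), base)
  expect_lte(n_hits(scan_params(min_overhang = 5, max_mismatches = 0)),
             n_hits(scan_params(min_overhang = 5, max_mismatches = 1)))

  # byte-identical hit TSVs across two runs on identical inputs
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "d1.fq.gz"); f2 <- file.path(dir, "d2.fq.gz")
  ids <- sprintf("r%03d", seq_along(reads))
  write_test_fastq(paste0(ids, "/1"), reads, f1)
  write_test_fastq(paste0(ids, "/2"), rev(reads), f2)
  t1 <- file.path(dir, "h1.tsv"); t2 <- file.path(dir, "h2.tsv")
  write_hits(scan_fastq(f1, f2, j)$hits, t1)
  write_hits(scan_fastq(f1, f2, j)$hits, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("support is per fragment: overlapping mates count once", {
  h <- function(id, mate, jid) data.frame(
    read_id = id, mate = mate, junction_id = jid, contig_start = 1L,
    aligned_length = 50L, mismatches = 0L, overhang5 = 25L, overhang3 = 25L,
    orientation = "forward", stringsAsFactors = FALSE)

  both_mates <- rbind(h("F", 1L, "J"), h("F", 2L, "J"))
  expect_equal(compute_fragment_support(both_mates)$support, 1L)

  two_frags <- rbind(h("F1", 1L, "J"), h("F2", 2L, "J"))
  expect_equal(compute_fragment_support(two_frags)$support, 2L)

  expect_equal(nrow(compute_fragment_support(both_mates[0, ])), 0L)

  # zero-support junctions appear when the junction set is supplied
  js <- list(toy_junction(rand_dna(60), 30L, id = "J", "A", "B", 1L, 1L),
             toy_junction(rand_dna(60), 30L, id = "K", "A", "B", 2L, 1L))
  sup <- compute_fragment_support(both_mates, js)
  expect_equal(sup$support[sup$junction_id == "J"], 1L)
  expect_equal(sup$support[sup$junction_id == "K"], 0L)
  expect_equal(sup$gene5, c("A", "A"))
})

test_that("PCR-duplicate collapsing is optional and counted", {
  set.seed(27)
  contig <- rand_dna(200)
  j <- toy_junction(contig, 100L)
  span <- substr(contig, 61, 160)
  other <- rand_dna(100)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "p1.fq.gz"); f2 <- file.path(dir, "p2.fq.gz")
  write_test_fastq(c("a/1", "b/1", "c/1"), c(span, span, span), f1)
  write_test_fastq(c("a/2", "b/2", "c/2"), c(other, other, rand_dna(100)), f2)

  plain <- scan_fastq(f1, f2, j)
  expect_equal(compute_fragment_support(plain$hits)$support, 3L)
  dd <- scan_fastq(f1, f2, j, dedup = TRUE)
  expect_equal(dd$stats$duplicates_removed, 1L)
  expect_equal(compute_fragment_support(dd$hits)$support, 2L)
})
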