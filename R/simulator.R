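#' Build the full-length chimeric fusion transcript
#'
#' Concatenates the 5' partner's spliced transcript through the end of exon
#' `exon5` with the 3' partner's spliced transcript from the start of exon
#' `exon3`. This is the expressed chimeric mRNA (the tool never models the
#' underlying genomic tandem duplication). Equivalent to [build_junction()]
#' with flanks at least as long as both transcripts.
#'
#' @inheritParams build_junction
#' @return a list of class `fusion_transcript` with fields `id`, `seq`,
#'   `breakpoint_offset` (0-based index of the first 3'-partner base).
#' @export
build_fusion_transcript <- function(model5, exon5, model3, exon3) {
  j <- build_junction(model5, exon5, model3, exon3,
                      flank_target = max(nchar(model5$spliced_seq),
                                         nchar(model3$spliced_seq)),
                      min_overhang = 0L)
  structure(list(id = j$junction_id, seq = j$contig,
                 breakpoint_offset = j$breakpoint_offset),
            class = "fusion_transcript")
}

#' Simulation configuration
#'
#' Describes one simulated RNA-Seq library: a mixture of wildtype
#' transcripts and (optionally) one fusion transcript, sequenced as
#' paired-end reads. The defaults emulate a 2 x 100 bp paired-end TruSeq
#' library with a ~250 bp insert. `fusion_fraction` is the probability that
#' a fragment originates from the fusion transcript; it operationalizes the
#' drivers of fusion detectability (fusion-partner expression level and
#' tumor-cell content), which dilute fusion-derived fragments in the
#' library.
#'
#' @param n_fragments number of sequenced fragments (read pairs).
#' @param transcripts named character vector of wildtype spliced transcript
#'   sequences (sampled length-weighted, i.e. at fragment level).
#' @param fusion a [build_fusion_transcript()] object (or any list with
#'   `id`, `seq`, `breakpoint_offset`); required when `fusion_fraction > 0`.
#' @param fusion_fraction probability in `[0, 1]` that a fragment derives
#'   from the fusion transcript (default 0).
#' @param read_length read length in bases (default 100).
#' @param fragment_length_mean,fragment_length_sd normal insert-size model
#'   in bases (defaults 250 and 30); draws are rounded and clamped to
#'   `[read_length, transcript length]`, with clamping flagged in the truth
#'   table.
#' @param error_rate per-base substitution probability (default 0.001).
#'   Substitution-only: the downstream scanner is ungapped.
#' @param seed RNG seed; identical configurations produce byte-identical
#'   outputs.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_fragments, transcripts, fusion = NULL,
                              fusion_fraction = 0, read_length = 100L,
                              fragment_length_mean = 250,
                              fragment_length_sd = 30,
                              error_rate = 0.001, seed = 1L) {
  if (!.is_count(n_fragments, 1L)) .stopf("n_fragments must be >= 1")
  if (!.is_count(read_length, 1L)) .stopf("read_length must be >= 1")
  if (!is.numeric(fusion_fraction) || fusion_fraction < 0 ||
      fusion_fraction > 1)
    .stopf("fusion_fraction must be in [0, 1]")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1)
    .stopf("error_rate must be in [0, 1]")
  if (fragment_length_mean < read_length)
    .stopf("fragment_length_mean (%g) must be >= read_length (%d)",
           fragment_length_mean, read_length)
  if (fragment_length_sd < 0) .stopf("fragment_length_sd must be >= 0")
  stopifnot(is.character(transcripts), length(transcripts) >= 1L,
            !is.null(names(transcripts)), all(nzchar(names(transcripts))))
  transcripts <- toupper(transcripts)
  if (any(nchar(transcripts) < read_length))
    .stopf("every wildtype transcript must be at least read_length bases")
  if (!is.null(fusion)) {
    stopifnot(is.list(fusion),
              all(c("id", "seq", "breakpoint_offset") %in% names(fusion)))
    fusion$seq <- toupper(fusion$seq)
    if (nchar(fusion$seq) < read_length)
      .stopf("fusion transcript must be at least read_length bases")
  }
  structure(list(n_fragments = as.integer(n_fragments),
                 transcripts = transcripts, fusion = fusion,
                 fusion_fraction = fusion_fraction,
                 read_length = as.integer(read_length),
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# write a FASTQ block (constant quality) to a gzipped file; low compression
# level keeps cohort simulation IO-bound work modest
.write_fastq_gz <- function(ids, reads, qual, path) {
  con <- gzfile(path, "wb", compression = 1L)
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Simulate a paired-end RNA-Seq sample with ground truth
#'
#' For each fragment: the source transcript is the fusion with probability
#' `fusion_fraction`, otherwise a wildtype transcript chosen with
#' probability proportional to its length; the fragment length is drawn
#' from the normal insert model (rounded, clamped to transcript bounds);
#' the start is uniform over valid placements; read 1 is the first
#' `read_length` bases of the fragment and read 2 the reverse complement of
#' its last `read_length` bases, with the fragment strand randomized
#' (unstranded simulation); substitution errors are applied at
#' `error_rate`; qualities are constant `"I"`. The truth table records, per
#' fragment, the source transcript, whether it spans the fusion breakpoint,
#' the exact junction overhangs of each read, and the fragment placement
#' (0-based start, length, per-read transcript windows, strand flip) so
#' every recorded quantity can be recomputed independently.
#'
#' @param config a [simulation_config()] object.
#' @param out_prefix output path prefix; writes `<prefix>_1.fastq.gz`,
#'   `<prefix>_2.fastq.gz`, `<prefix>_truth.tsv`, `<prefix>_config.json`.
#' @return an object of class `simulated_sample`: list with `fastq1_path`,
#'   `fastq2_path`, `truth_path`, `config_path`, `config`.
#' @export
simulate_sample <- function(config, out_prefix) {
  stopifnot(inherits(config, "sim_config"))
  if (config$fusion_fraction > 0 && is.null(config$fusion))
    .stopf("fusion_fraction > 0 but no fusion transcript configured")
  n <- config$n_fragments
  R <- config$read_length

  wt <- config$transcripts
  src_names <- names(wt)
  has_fusion <- !is.null(config$fusion)
  fus_seq <- if (has_fusion) config$fusion$seq else ""
  b <- if (has_fusion) config$fusion$breakpoint_offset else NA_integer_

  out <- with_seed(config$seed, {
    from_fusion <- runif(n) < config$fusion_fraction
    wt_idx <- sample.int(length(wt), n, replace = TRUE, prob = nchar(wt))
    src <- src_names[wt_idx]
    seqs <- unname(wt[wt_idx])
    if (has_fusion) {
      src[from_fusion] <- config$fusion$id
      seqs[from_fusion] <- fus_seq
    }
    L <- nchar(seqs)
    Fl <- as.integer(round(rnorm(n, config$fragment_length_mean,
                                 config$fragment_length_sd)))
    truncated <- Fl > L | Fl < R
    Fl <- pmax(R, pmin(Fl, L))
    s0 <- as.integer(floor(runif(n) * (L - Fl + 1)))  # 0-based fragment start
    winA <- s0               # transcript window of the fragment's 5' read
    winB <- s0 + Fl - R      # transcript window of the fragment's 3' read
    a1 <- substring(seqs, winA + 1L, winA + R)
    a2 <- substring(seqs, winB + 1L, winB + R)
    rc_a2 <- revcomp(a2)
    flip <- runif(n) < 0.5   # fragment sampled from the antisense strand
    read1 <- a1; read1[flip] <- rc_a2[flip]
    read2 <- rc_a2; read2[flip] <- a1[flip]
    read1_win <- winA; read1_win[flip] <- winB[flip]
    read2_win <- winB; read2_win[flip] <- winA[flip]
    ne1 <- rbinom(n, R, config$error_rate)
    ne2 <- rbinom(n, R, config$error_rate)
    read1 <- as.character(.inject_errors_cpp(read1, ne1))
    read2 <- as.character(.inject_errors_cpp(read2, ne2))
    list(src = src, from_fusion = from_fusion, read1 = read1, read2 = read2,
         read1_win = read1_win, read2_win = read2_win, s0 = s0, Fl = Fl,
         flip = flip, truncated = truncated)
  })

  ov <- function(w, fus) {
    o5 <- ifelse(fus, b - w, NA_integer_)
    o3 <- ifelse(fus, w + R - b, NA_integer_)
    cover <- fus & !is.na(o5) & o5 >= 1L & o3 >= 1L
    list(o5 = ifelse(cover, o5, NA_integer_),
         o3 = ifelse(cover, o3, NA_integer_), cover = cover)
  }
  ov1 <- ov(out$read1_win, out$from_fusion)
  ov2 <- ov(out$read2_win, out$from_fusion)

  fid <- sprintf("frag%07d", seq_len(n))
  qual <- strrep("I", R)
  f1 <- paste0(out_prefix, "_1.fastq.gz")
  f2 <- paste0(out_prefix, "_2.fastq.gz")
  .write_fastq_gz(paste0(fid, "/1"), out$read1, qual, f1)
  .write_fastq_gz(paste0(fid, "/2"), out$read2, qual, f2)

  truth <- data.frame(
    fragment_id = fid, source = out$src,
    spans_junction = out$from_fusion & (ov1$cover | ov2$cover),
    read1_overhang5 = ov1$o5, read1_overhang3 = ov1$o3,
    read2_overhang5 = ov2$o5, read2_overhang3 = ov2$o3,
    fragment_start = out$s0, fragment_length = out$Fl,
    read1_start = out$read1_win, read2_start = out$read2_win,
    read1_from_antisense = out$flip,
    truncated = out$truncated, stringsAsFactors = FALSE)
  truth_path <- paste0(out_prefix, "_truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  config_path <- paste0(out_prefix, "_config.json")
  echo <- list(n_fragments = config$n_fragments,
               read_length = config$read_length,
               fragment_length_mean = config$fragment_length_mean,
               fragment_length_sd = config$fragment_length_sd,
               fusion_fraction = config$fusion_fraction,
               error_rate = config$error_rate, seed = config$seed,
               wildtype_transcripts = as.list(nchar(config$transcripts)),
               fusion = if (has_fusion)
                 list(id = config$fusion$id, length = nchar(fus_seq),
                      breakpoint_offset = b) else NULL)
  jsonlite::write_json(echo, config_path, auto_unbox = TRUE, pretty = TRUE)

  structure(list(fastq1_path = f1, fastq2_path = f2, truth_path = truth_path,
                 config_path = config_path, config = config),
            class = "simulated_sample")
}

#' Read the truth table written by [simulate_sample()]
#' @param path truth TSV path.
#' @return truth data.frame.
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Expected number of junction-spanning fragments (closed form)
#'
#' For a fixed fragment length F, read length R and an interior breakpoint
#' at offset b on a fusion transcript of length L, a fragment starting at s
#' has a read covering the breakpoint with at least `min_overhang` bases on
#' each side when s lies in `[b - R + o, b - o]` (read 1 window) or
#' `[b - F + o, b - F + R - o]` (read 2 window); each interval holds
#' `R - 2 o + 1` starts and their overlap is removed exactly. The expected
#' count is `n_fragments * fusion_fraction * |S| / (L - F + 1)` with S the
#' union of the two intervals. Used as the design-verification oracle for
#' the simulator's calibration.
#'
#' @param config a [simulation_config()] with `fragment_length_sd = 0` (the
#'   formula requires a fixed fragment length) and a fusion transcript whose
#'   breakpoint is interior: both start intervals must lie inside the valid
#'   start range, otherwise an error is thrown (formula invalid near
#'   transcript ends).
#' @param min_overhang required matched bases on each side of the
#'   breakpoint (`o` above); must satisfy `R >= 2 o`.
#' @return expected spanning-fragment count (double).
#' @export
expected_spanning_fragments <- function(config, min_overhang = 10L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$fragment_length_sd != 0)
    .stopf("closed form requires a fixed fragment length (fragment_length_sd = 0)")
  if (is.null(config$fusion))
    .stopf("no fusion transcript configured")
  o <- as.integer(min_overhang)
  R <- config$read_length
  Fl <- as.integer(round(config$fragment_length_mean))
  L <- nchar(config$fusion$seq)
  b <- config$fusion$breakpoint_offset
  if (R < 2L * o) .stopf("read_length must be >= 2 * min_overhang")
  if (Fl < R || Fl > L) .stopf("fragment length outside [read_length, L]")
  i1 <- c(b - R + o, b - o)            # read-1 start interval (0-based)
  i2 <- c(b - Fl + o, b - Fl + R - o)  # read-2 start interval
  smax <- L - Fl
  if (i1[1] < 0L || i1[2] > smax || i2[1] < 0L || i2[2] > smax)
    .stopf("breakpoint too close to transcript ends for the closed form")
  len <- function(iv) max(0L, iv[2] - iv[1] + 1L)
  inter <- c(max(i1[1], i2[1]), min(i1[2], i2[2]))
  n_starts <- len(i1) + len(i2) - len(inter)
  config$n_fragments * config$fusion_fraction * n_starts / (smax + 1)
}
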