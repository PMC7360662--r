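#' Scanner parameters
#'
#' Contracts for calling a read junction-spanning. A placement qualifies only
#' if it crosses the breakpoint with at least `min_overhang` aligned bases on
#' each side (anchoring the STAR fix `--peOverlapNbasesMin 10`), covers at
#' least `min_aligned_fraction` of the read (anchoring
#' `--alignSplicedMateMapLminOverLmate 0.5`), and has at most
#' `max_mismatches` Hamming mismatches over the aligned span. Matching is
#' ungapped; `N` in read or contig always counts as a mismatch.
#'
#' @param min_overhang minimum aligned bases on each side of the breakpoint
#'   (default 10).
#' @param max_mismatches maximum Hamming mismatches in the aligned span
#'   (default 2; set 0 for a strict exact-match mode mirroring a plain
#'   `grep` of the junction sequence).
#' @param seed_length exact-match k-mer length used to trigger verification
#'   (default 12, maximum 32). Whenever the pigeonhole completeness bound
#'   for this seed length does not hold for the given read length and
#'   mismatch budget, the scanner transparently falls back to evaluating
#'   every breakpoint-crossing placement, so decisions never depend on
#'   seeding.
#' @param min_aligned_fraction minimum fraction of the read that must lie
#'   within the contig alignment (default 0.5); placements may clip at
#'   contig ends subject to this bound.
#' @param both_orientations also scan the reverse complement of each read
#'   (default TRUE).
#' @return an object of class `scan_params`.
#' @export
scan_params <- function(min_overhang = 10L, max_mismatches = 2L,
                        seed_length = 12L, min_aligned_fraction = 0.5,
                        both_orientations = TRUE) {
  if (!.is_count(min_overhang, 1L)) .stopf("min_overhang must be >= 1")
  if (!.is_count(max_mismatches, 0L)) .stopf("max_mismatches must be >= 0")
  if (!.is_count(seed_length, 8L) || seed_length > 32L)
    .stopf("seed_length must be in [8, 32]")
  if (!is.numeric(min_aligned_fraction) || length(min_aligned_fraction) != 1L ||
      min_aligned_fraction <= 0 || min_aligned_fraction > 1)
    .stopf("min_aligned_fraction must be in (0, 1]")
  structure(list(min_overhang = as.integer(min_overhang),
                 max_mismatches = as.integer(max_mismatches),
                 seed_length = as.integer(seed_length),
                 min_aligned_fraction = min_aligned_fraction,
                 both_orientations = isTRUE(both_orientations)),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat(sprintf(paste0("<scan_params> min_overhang=%d max_mismatches=%d ",
                     "seed_length=%d min_aligned_fraction=%g ",
                     "both_orientations=%s\n"),
              x$min_overhang, x$max_mismatches, x$seed_length,
              x$min_aligned_fraction, x$both_orientations))
  invisible(x)
}

# run the compiled seed-and-verify core; returns the raw placement matrix
.scan_core <- function(seqs, junctions, params) {
  .scan_reads_cpp(seqs, lapply(junctions, unclass),
                  params$min_overhang, params$max_mismatches,
                  params$seed_length, params$min_aligned_fraction,
                  params$both_orientations)
}

.empty_hits <- function() {
  data.frame(read_id = character(0), mate = integer(0),
             junction_id = character(0), contig_start = integer(0),
             aligned_length = integer(0), mismatches = integer(0),
             overhang5 = integer(0), overhang3 = integer(0),
             orientation = character(0), stringsAsFactors = FALSE)
}

#' Scan a single read against a junction contig
#'
#' Searches every ungapped placement of the read (and of its reverse
#' complement when `both_orientations`) on the junction contig for one that
#' crosses the breakpoint under the [scan_params()] contracts. Among
#' qualifying placements the one with fewest mismatches is returned, ties
#' broken by smallest contig offset, then forward before reverse complement.
#'
#' @param read the read: a plain sequence string, or a list with fields
#'   `read_id`, `mate`, `sequence` (and optionally `qualities`).
#' @param junction a `junction` from [build_junction()].
#' @param params a [scan_params()] object.
#' @return a one-row data.frame (columns `read_id`, `mate`, `junction_id`,
#'   `contig_start`, `aligned_length`, `mismatches`, `overhang5`,
#'   `overhang3`, `orientation`) or `NULL` when no placement qualifies.
#'   Reads shorter than `2 * min_overhang` cannot span and are skipped with
#'   a warning.
#' @export
scan_read <- function(read, junction, params = scan_params()) {
  stopifnot(inherits(junction, "junction"), inherits(params, "scan_params"))
  if (is.character(read)) read <- list(read_id = NA_character_,
                                       mate = NA_integer_, sequence = read)
  seq <- toupper(read$sequence)
  if (nchar(seq) == 0L) .stopf("read sequence is empty")
  if (nchar(seq) < 2L * params$min_overhang) {
    .warnf("read shorter than 2 * min_overhang (%d < %d): cannot span; skipped",
           nchar(seq), 2L * params$min_overhang)
    return(NULL)
  }
  m <- .scan_core(seq, list(junction), params)
  if (nrow(m) == 0L) return(NULL)
  data.frame(read_id = read$read_id, mate = read$mate,
             junction_id = junction$junction_id,
             contig_start = m[1L, "contig_start"],
             aligned_length = m[1L, "aligned_length"],
             mismatches = m[1L, "mismatches"],
             overhang5 = m[1L, "overhang5"],
             overhang3 = m[1L, "overhang3"],
             orientation = c("forward", "revcomp")[m[1L, "orient"]],
             stringsAsFactors = FALSE)
}

# strip a trailing /1 or /2 mate suffix and any comment after whitespace
.clean_read_ids <- function(x) {
  sub("/[12]$", "", sub("\\s.*$", "", x))
}

#' Scan paired FASTQ files for junction-spanning reads
#'
#' Applies the [scan_read()] decision rule to every read of a record-
#' synchronized FASTQ pair against every junction contig, using a shared
#' k-mer seed index over all contigs. Decisions are identical to calling
#' [scan_read()] on each read. Output order is deterministic: file record
#' order, then mate, then `junction_id`.
#'
#' @param fastq1_path,fastq2_path paths to mate-1 and mate-2 FASTQ files
#'   (plain or gzipped), record-synchronized.
#' @param junctions list of `junction` objects, a single `junction`, or the
#'   path of a FASTA written by [write_junction_fasta()].
#' @param params a [scan_params()] object.
#' @param dedup collapse PCR duplicates, i.e. fragments with an identical
#'   (sequence1, sequence2) pair, before scanning (default FALSE).
#' @return list with elements `hits` (data.frame as in [scan_read()]) and
#'   `stats` (list: `reads_scanned`, `fragments_scanned`,
#'   `reads_skipped_short`, `reads_with_N`, `duplicates_removed`,
#'   `hits_per_junction`).
#' @export
scan_fastq <- function(fastq1_path, fastq2_path, junctions,
                       params = scan_params(), dedup = FALSE) {
  stopifnot(inherits(params, "scan_params"))
  if (is.character(junctions)) junctions <- read_junction_fasta(junctions)
  junctions <- .as_junction_list(junctions)
  jids <- vapply(junctions, `[[`, "", "junction_id")
  if (anyDuplicated(jids)) .stopf("duplicate junction_id in junction set")

  read_fq <- function(path) {
    tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
             error = function(e)
               .stopf("malformed FASTQ '%s': %s", path, conditionMessage(e)))
  }
  r1 <- read_fq(fastq1_path)
  r2 <- read_fq(fastq2_path)
  if (length(r1) != length(r2))
    .stopf("mate files desynchronized: %d vs %d records",
           length(r1), length(r2))
  id1 <- .clean_read_ids(names(r1))
  id2 <- .clean_read_ids(names(r2))
  bad <- which(id1 != id2)
  if (length(bad) > 0L)
    .stopf("mate files desynchronized at record %d: '%s' vs '%s'",
           bad[1L], id1[bad[1L]], id2[bad[1L]])
  n_frag <- length(r1)

  dup_removed <- 0L
  s1 <- as.character(r1); s2 <- as.character(r2)
  if (isTRUE(dedup) && n_frag > 0L) {
    keep_frag <- !duplicated(paste(s1, s2, sep = "\r"))
    dup_removed <- sum(!keep_frag)
    s1 <- s1[keep_frag]; s2 <- s2[keep_frag]; id1 <- id1[keep_frag]
  }
  nf <- length(s1)

  seqs <- c(s1, s2)
  ids <- c(id1, id1)
  mate <- rep(c(1L, 2L), each = nf)
  rec <- rep(seq_len(nf), 2L)
  n_with_N <- 0L
  skipped_short <- 0L

  hits <- .empty_hits()
  if (length(seqs) > 0L) {
    m <- .scan_core(seqs, junctions, params)
    n_with_N <- attr(m, "n_with_N")
    skipped_short <- attr(m, "n_short")
    if (nrow(m) > 0L) {
      ri <- m[, "read"]
      hits <- data.frame(
        read_id = ids[ri], mate = mate[ri],
        junction_id = jids[m[, "junction"]],
        contig_start = m[, "contig_start"],
        aligned_length = m[, "aligned_length"],
        mismatches = m[, "mismatches"],
        overhang5 = m[, "overhang5"], overhang3 = m[, "overhang3"],
        orientation = c("forward", "revcomp")[m[, "orient"]],
        stringsAsFactors = FALSE)
      ord <- order(rec[ri], mate[ri], hits$junction_id)
      hits <- hits[ord, , drop = FALSE]
      rownames(hits) <- NULL
    }
  }
  hpj <- table(factor(hits$junction_id, levels = sort(jids)))
  stats <- list(reads_scanned = 2L * n_frag,
                fragments_scanned = n_frag,
                reads_skipped_short = as.integer(skipped_short),
                reads_with_N = as.integer(n_with_N),
                duplicates_removed = dup_removed,
                hits_per_junction = as.list(hpj))
  list(hits = hits, stats = stats)
}

#' Write scanner hits to TSV
#' @param hits hits data.frame from [scan_fastq()].
#' @param path output TSV path.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hits TSV written by [write_hits()]
#' @param path hits TSV path.
#' @return hits data.frame.
#' @export
read_hits <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(read_id = "character"))
}

#' Aggregate junction hits to fragment-level support
#'
#' Support is counted per sequenced fragment, not per mate: a pair whose two
#' mates both span the same junction (overlapping paired-end reads over a
#' short insert) contributes exactly one supporting fragment, as does a read
#' hitting in both orientations.
#'
#' @param hits hits data.frame from [scan_fastq()] / [scan_read()].
#' @param junctions optional junction list; when given, junctions without
#'   any hit are included with support 0 and gene metadata columns are
#'   attached (required downstream by [call_fusions()]).
#' @return data.frame of class `fragment_support` with columns
#'   `junction_id`, `support` and a `fragment_ids` list-column (plus
#'   `gene5`, `gene3`, `exon5`, `exon3` when `junctions` is supplied).
#' @export
compute_fragment_support <- function(hits, junctions = NULL) {
  sp <- if (nrow(hits) > 0L)
    lapply(split(hits$read_id, hits$junction_id), function(x) sort(unique(x)))
  else list()
  if (!is.null(junctions)) {
    junctions <- .as_junction_list(junctions)
    jids <- vapply(junctions, `[[`, "", "junction_id")
    extra <- setdiff(names(sp), jids)
    if (length(extra) > 0L)
      .stopf("hits reference junctions not in the junction set: %s",
             paste(extra, collapse = ", "))
    full <- stats::setNames(vector("list", length(jids)), jids)
    full[names(sp)] <- sp
    full[vapply(full, is.null, logical(1))] <- list(character(0))
    sp <- full
  }
  df <- data.frame(junction_id = names(sp),
                   support = vapply(sp, length, integer(1)),
                   stringsAsFactors = FALSE)
  df$fragment_ids <- I(unname(sp))
  if (!is.null(junctions)) {
    jids <- vapply(junctions, `[[`, "", "junction_id")
    m <- match(df$junction_id, jids)
    df$gene5 <- vapply(junctions, `[[`, "", "gene5")[m]
    df$gene3 <- vapply(junctions, `[[`, "", "gene3")[m]
    df$exon5 <- vapply(junctions, `[[`, 0L, "exon5")[m]
    df$exon3 <- vapply(junctions, `[[`, 0L, "exon3")[m]
  }
  rownames(df) <- NULL
  class(df) <- c("fragment_support", "data.frame")
  df
}
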