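# Toy builders shared across the test files. Everything is generated in
# code; no fixture files.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a junction object with an arbitrary contig and breakpoint, for scanner
# tests that do not care about gene models
toy_junction <- function(contig, b, id = "G5:G3|e2:e1",
                         gene5 = "G5", gene3 = "G3", exon5 = 2L, exon3 = 1L) {
  structure(list(junction_id = id, gene5 = gene5, gene3 = gene3,
                 exon5 = exon5, exon3 = exon3,
                 seq5 = substr(contig, 1, b),
                 seq3 = substr(contig, b + 1, nchar(contig)),
                 contig = contig, breakpoint_offset = b,
                 flank_target = max(b, nchar(contig) - b)),
            class = "junction")
}

# the two-exon toy models used in the junction-construction examples
toy_model5 <- function() {
  gene_model("g5", "GENE5", "c1", "+",
             data.frame(start = c(1L, 5L), end = c(4L, 8L)), "AAAACCCC")
}
toy_model3 <- function() {
  gene_model("g3", "GENE3", "c1", "+",
             data.frame(start = c(11L, 18L), end = c(14L, 21L)), "GGTTGGTT")
}

# write a toy genome FASTA + GTF for parser tests; exons is a data.frame
# with columns start, end (1-based genomic); returns the two paths
write_toy_reference <- function(dir, contig_seq, exons, strand = "+",
                                gene = "TOY", chrom = "c1",
                                transcript = paste0(gene, ".t1"),
                                shuffle = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  writeLines(c(paste0(">", chrom), contig_seq), fa)
  rows <- sprintf(paste0("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t",
                         'gene_id "%s"; transcript_id "%s"; gene_name "%s";'),
                  chrom, exons$start, exons$end, strand, gene, transcript,
                  gene)
  if (shuffle) rows <- rev(rows)
  gtf <- file.path(dir, "annotation.gtf")
  writeLines(rows, gtf)
  list(genome = fa, annotation = gtf)
}

# write a gzipped FASTQ from parallel id/sequence vectors
write_test_fastq <- function(ids, seqs, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  if (length(ids) > 0L)
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), con)
  invisible(path)
}

# small wildtype transcript set for simulator tests
toy_transcripts <- function(seed = 99L, n = 2L, len = 1500L) {
  set.seed(seed)
  stats::setNames(vapply(seq_len(n), function(i) rand_dna(len), ""),
                  paste0("WT", seq_len(n)))
}

# shared synthetic reference, built once per test run
ref_cache <- new.env(parent = emptyenv())
get_test_reference <- function() {
  if (is.null(ref_cache$ref))
    ref_cache$ref <- synthetic_reference(
      dir = file.path(tempdir(), "jscan_test_ref"))
  ref_cache$ref
}
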