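#' Synthetic KIAA1549/BRAF-like reference (genome, annotation, whitelist)
#'
#' Generates a small fully synthetic reference emulating the 7q34 locus
#' structure relevant to the KIAA1549:BRAF fusion: a KIAA1549-like gene and
#' a BRAF-like gene (both on the minus strand, as in the human genome, with
#' enough exons to express the 16:9 and 15:9 fusion variants) plus a
#' housekeeping filler gene, all on one synthetic contig. Sequences are
#' random DNA from a fixed seed; nothing in them derives from the human
#' genome, so the files are labelled synthetic. The same seed always yields
#' the same reference.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the synthetic sequence (default fixed, so every
#'   call reproduces the same reference).
#' @return list with paths `genome` (`synthetic_genome.fa`), `annotation`
#'   (`synthetic_annotation.gtf`), `whitelist` (`known_fusions.tsv`) and
#'   the vector `genes` of gene names.
#' @export
write_synthetic_reference <- function(dir, seed = 20240917L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- list(
    list(name = "KIAA1549", strand = "-", n_exons = 17L),
    list(name = "BRAF",     strand = "-", n_exons = 18L),
    list(name = "PPIA",     strand = "+", n_exons = 4L))

  ref <- with_seed(seed, {
    gtf <- character(0)
    chrom <- "chr7s"
    pos <- 1L          # next free 1-based genomic position
    gap <- function() sample(400:800, 1L)
    chrom_parts <- character(0)
    for (g in genes) {
      pos <- pos + {
        glen <- gap()
        chrom_parts <- c(chrom_parts,
                         paste(sample(.BASES, glen, replace = TRUE),
                               collapse = ""))
        glen
      }
      ex_len <- sample(90:240, g$n_exons, replace = TRUE)
      in_len <- sample(300:700, g$n_exons - 1L, replace = TRUE)
      # genomic layout ascending; exon rank follows strand
      starts <- integer(g$n_exons); ends <- integer(g$n_exons)
      p <- pos
      for (i in seq_len(g$n_exons)) {
        starts[i] <- p; ends[i] <- p + ex_len[i] - 1L
        seg <- paste(sample(.BASES, ex_len[i], replace = TRUE), collapse = "")
        chrom_parts <- c(chrom_parts, seg)
        p <- ends[i] + 1L
        if (i < g$n_exons) {
          chrom_parts <- c(chrom_parts,
                           paste(sample(.BASES, in_len[i], replace = TRUE),
                                 collapse = ""))
          p <- p + in_len[i]
        }
      }
      pos <- p
      rank <- if (g$strand == "+") seq_len(g$n_exons) else rev(seq_len(g$n_exons))
      attr_fmt <- paste0('gene_id "%s"; transcript_id "%s.t1"; ',
                         'gene_name "%s"; exon_number "%d";')
      gtf <- c(gtf, sprintf(
        "%s\tjunctionscan_synthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
        chrom, starts, ends, g$strand,
        sprintf(attr_fmt, g$name, g$name, g$name, rank)))
    }
    tail_len <- gap()
    chrom_parts <- c(chrom_parts,
                     paste(sample(.BASES, tail_len, replace = TRUE),
                           collapse = ""))
    list(chrom = chrom, seq = paste(chrom_parts, collapse = ""), gtf = gtf)
  })

  genome_path <- file.path(dir, "synthetic_genome.fa")
  gseq <- Biostrings::DNAStringSet(ref$seq)
  names(gseq) <- paste(ref$chrom, "synthetic sequence")
  Biostrings::writeXStringSet(gseq, genome_path)

  gtf_path <- file.path(dir, "synthetic_annotation.gtf")
  writeLines(c("##description: synthetic annotation (junctionscan)", ref$gtf),
             gtf_path)

  wl_path <- file.path(dir, "known_fusions.tsv")
  write_known_fusions(
    known_fusions("KIAA1549", "BRAF", c(16L, 15L), c(9L, 9L)), wl_path)

  list(genome = genome_path, annotation = gtf_path, whitelist = wl_path,
       genes = vapply(genes, `[[`, "", "name"))
}

#' Load the synthetic reference as gene models, junctions and whitelist
#'
#' Convenience wrapper: writes the synthetic reference (see
#' [write_synthetic_reference()]) into `dir`, parses it back through the
#' standard GTF/FASTA path, and enumerates the whitelisted junctions.
#'
#' @param dir directory for the reference files (default: a session
#'   temporary directory).
#' @param flank_target junction flank length (default 200, twice the 100 bp
#'   read length of the emulated design).
#' @param seed seed forwarded to [write_synthetic_reference()].
#' @return list with `models` (named list of [gene_model()]), `junctions`
#'   (list of `junction`), `whitelist` ([known_fusions()]), `paths`.
#' @export
synthetic_reference <- function(dir = file.path(tempdir(), "jscan_ref"),
                                flank_target = 200L, seed = 20240917L) {
  paths <- write_synthetic_reference(dir, seed = seed)
  whitelist <- read_known_fusions(paths$whitelist)
  models <- parse_gene_models(paths$annotation, paths$genome, paths$genes)
  junctions <- enumerate_known_junctions(whitelist, models,
                                         flank_target = flank_target)
  list(models = models, junctions = junctions, whitelist = whitelist,
       paths = paths)
}
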