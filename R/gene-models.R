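#' Construct a gene model
#'
#' A gene model is one gene's exon chain (a single transcript) together with
#' its spliced transcript sequence. Exons are kept in transcription order:
#' ascending genomic coordinates on the \code{+} strand, descending on
#' \code{-}. Genomic coordinates are 1-based inclusive (GTF convention);
#' everything downstream of the annotation boundary uses 0-based half-open
#' offsets on the spliced transcript.
#'
#' @param gene_id gene identifier (string).
#' @param gene_name gene symbol used in fusion names (string).
#' @param chrom chromosome/contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (1-based inclusive
#'   genomic coordinates) and optionally `rank`; rows must be in
#'   transcription order. If `rank` is missing it is assigned 1..n.
#' @param spliced_seq spliced transcript sequence over `A`,`C`,`G`,`T`,`N`
#'   (lowercase accepted, normalised to uppercase). Its length must equal the
#'   summed exon lengths.
#' @return an object of class `gene_model`.
#' @seealso [parse_gene_models()] to build models from a genome FASTA and GTF.
#' @export
gene_model <- function(gene_id, gene_name, chrom, strand, exons, spliced_seq) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(gene_name), length(gene_name) == 1L, nzchar(gene_name),
            is.data.frame(exons), nrow(exons) >= 1L,
            all(c("start", "end") %in% names(exons)))
  if (!strand %in% c("+", "-"))
    .stopf("strand must be '+' or '-', got '%s'", strand)
  if (is.null(exons$rank)) exons$rank <- seq_len(nrow(exons))
  exons <- exons[order(exons$rank), c("start", "end", "rank"), drop = FALSE]
  rownames(exons) <- NULL
  if (!identical(as.integer(exons$rank), seq_len(nrow(exons))))
    .stopf("exon ranks for %s must be consecutive starting at 1", gene_name)
  if (any(exons$start > exons$end))
    .stopf("exon with start > end in gene %s", gene_name)
  starts <- exons$start
  if (nrow(exons) > 1L) {
    ok <- if (strand == "+") all(diff(starts) > 0) else all(diff(starts) < 0)
    if (!ok)
      .stopf("exons of %s are not in transcription order for strand %s",
             gene_name, strand)
  }
  spliced_seq <- toupper(spliced_seq)
  widths <- exons$end - exons$start + 1L
  if (nchar(spliced_seq) != sum(widths))
    .stopf("spliced sequence length (%d) != total exon length (%d) for %s",
           nchar(spliced_seq), sum(widths), gene_name)
  structure(
    list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
         strand = strand, exons = exons, spliced_seq = spliced_seq),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s, %d exons, spliced length %d bp\n",
              x$gene_name, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              nchar(x$spliced_seq)))
  invisible(x)
}

# cumulative 1-based transcript end coordinate of each exon
exon_cum_ends <- function(model) {
  cumsum(model$exons$end - model$exons$start + 1L)
}

#' Parse gene models from a GTF annotation and genome FASTA
#'
#' Reads exon records for the requested genes, orders them into transcription
#' order, and extracts the spliced transcript sequence (per-exon
#' reverse-complement for `-`-strand genes). The tool operates on a single
#' exon chain per gene, so genes annotated with several transcripts require
#' an explicit `transcript_id` selection.
#'
#' @param annotation_path GTF file with exon features carrying `gene_name`
#'   (and, when relevant, `transcript_id`) attributes.
#' @param genome_path genome FASTA (plain or gzipped). Sequence names are
#'   truncated at the first whitespace.
#' @param gene_names character vector of gene symbols to extract.
#' @param transcript_id optional named character vector (or single string)
#'   selecting one transcript per gene for multi-transcript annotations.
#' @return named list of [gene_model()] objects (one per requested gene).
#' @export
parse_gene_models <- function(annotation_path, genome_path, gene_names,
                              transcript_id = NULL) {
  stopifnot(length(gene_names) >= 1L)
  gr <- rtracklayer::import(annotation_path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!"gene_name" %in% names(meta))
    .stopf("annotation has no gene_name attribute: %s", annotation_path)
  ex <- gr[!is.na(meta$type) & meta$type == "exon"]
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom_cache <- new.env(parent = emptyenv())
  get_chrom <- function(chrom) {
    if (!exists(chrom, envir = chrom_cache)) {
      if (!chrom %in% names(genome))
        .stopf("chromosome '%s' not present in genome FASTA", chrom)
      assign(chrom, toupper(as.character(genome[[chrom]])), envir = chrom_cache)
    }
    get(chrom, envir = chrom_cache)
  }

  models <- lapply(gene_names, function(g) {
    gex <- ex[!is.na(S4Vectors::mcols(ex)$gene_name) &
                S4Vectors::mcols(ex)$gene_name == g]
    if (length(gex) == 0L) .stopf("gene not found in annotation: %s", g)
    m <- S4Vectors::mcols(gex)
    tx_sel <- if (is.null(transcript_id)) NULL
      else if (!is.null(names(transcript_id))) unname(transcript_id[g])
      else transcript_id
    if (!is.null(m$transcript_id)) {
      txs <- unique(m$transcript_id[!is.na(m$transcript_id)])
      if (!is.null(tx_sel) && !is.na(tx_sel)) {
        gex <- gex[!is.na(m$transcript_id) & m$transcript_id == tx_sel]
        if (length(gex) == 0L)
          .stopf("transcript '%s' not found for gene %s", tx_sel, g)
      } else if (length(txs) > 1L) {
        .stopf("gene %s has %d transcripts (%s); supply transcript_id",
               g, length(txs), paste(txs, collapse = ", "))
      }
    }
    chrom <- unique(as.character(GenomicRanges::seqnames(gex)))
    strand <- unique(as.character(BiocGenerics::strand(gex)))
    if (length(chrom) != 1L || length(strand) != 1L)
      .stopf("gene %s has exons on multiple chromosomes/strands", g)
    if (!strand %in% c("+", "-"))
      .stopf("gene %s has undefined strand in annotation", g)
    chrom_seq <- get_chrom(chrom)
    st <- BiocGenerics::start(gex); en <- BiocGenerics::end(gex)
    if (min(st) < 1L || max(en) > nchar(chrom_seq))
      .stopf("exon of gene %s outside bounds of contig %s (length %d)",
             g, chrom, nchar(chrom_seq))
    ord <- if (strand == "+") order(st) else order(st, decreasing = TRUE)
    st <- st[ord]; en <- en[ord]
    seqs <- substring(chrom_seq, st, en)
    if (strand == "-") seqs <- revcomp(seqs)
    gene_id <- if (!is.null(m$gene_id)) unique(m$gene_id)[1L] else g
    gene_model(gene_id = gene_id, gene_name = g, chrom = chrom,
               strand = strand,
               exons = data.frame(start = st, end = en,
                                  rank = seq_along(st)),
               spliced_seq = paste(seqs, collapse = ""))
  })
  names(models) <- gene_names
  models
}
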