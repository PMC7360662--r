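#' Build a breakpoint junction contig for a known fusion
#'
#' A junction contig is the sequence context a breakpoint-spanning read must
#' match: the 3'-terminal flank of the 5' partner's spliced transcript up to
#' the end of exon `exon5`, concatenated with the 5'-initial flank of the 3'
#' partner's spliced transcript starting at exon `exon3`. The breakpoint
#' offset is the 0-based index of the first 3'-partner base in the contig
#' (equivalently the length of the 5' flank).
#'
#' Flanks are truncated at transcript bounds, so the realised flank lengths
#' may be shorter than `flank_target`. The default `flank_target` of twice a
#' typical read length (200 bp for 2 x 100 bp libraries) guarantees that any
#' read placement over the breakpoint lies fully within the contig.
#'
#' @param model5,model3 [gene_model()] objects for the 5' and 3' partners.
#' @param exon5,exon3 exon ranks (transcription order, 1-based) at which the
#'   partners are joined; `"KIAA1549:BRAF|e16:e9"` joins KIAA1549 exon 16 to
#'   BRAF exon 9.
#' @param flank_target requested flank length in bases on each side.
#' @param min_overhang scanner minimum overhang used only to warn when the
#'   junction is too short to be detectable.
#' @return an object of class `junction` with fields `junction_id`, `gene5`,
#'   `gene3`, `exon5`, `exon3`, `seq5`, `seq3`, `contig`,
#'   `breakpoint_offset`, `flank_target`.
#' @export
build_junction <- function(model5, exon5, model3, exon3,
                           flank_target = 200L, min_overhang = 10L) {
  stopifnot(inherits(model5, "gene_model"), inherits(model3, "gene_model"))
  if (!.is_count(flank_target, min = 1L))
    .stopf("flank_target must be a positive integer")
  exon5 <- as.integer(exon5); exon3 <- as.integer(exon3)
  flank_target <- as.integer(flank_target)
  ends5 <- exon_cum_ends(model5)
  ends3 <- exon_cum_ends(model3)
  if (is.na(exon5) || exon5 < 1L || exon5 > length(ends5))
    .stopf("exon rank out of range for %s: %s", model5$gene_name, exon5)
  if (is.na(exon3) || exon3 < 1L || exon3 > length(ends3))
    .stopf("exon rank out of range for %s: %s", model3$gene_name, exon3)
  if (flank_target < min_overhang)
    .warnf("flank_target (%d) < min_overhang (%d): junction undetectable",
           flank_target, min_overhang)
  end5 <- ends5[exon5]
  seq5 <- substr(model5$spliced_seq, max(1L, end5 - flank_target + 1L), end5)
  start3 <- if (exon3 == 1L) 1L else ends3[exon3 - 1L] + 1L
  L3 <- nchar(model3$spliced_seq)
  seq3 <- substr(model3$spliced_seq, start3,
                 min(L3, start3 + flank_target - 1L))
  structure(
    list(junction_id = sprintf("%s:%s|e%d:e%d", model5$gene_name,
                               model3$gene_name, exon5, exon3),
         gene5 = model5$gene_name, gene3 = model3$gene_name,
         exon5 = exon5, exon3 = exon3,
         seq5 = seq5, seq3 = seq3, contig = paste0(seq5, seq3),
         breakpoint_offset = nchar(seq5), flank_target = flank_target),
    class = "junction")
}

#' @export
print.junction <- function(x, ...) {
  cat(sprintf("<junction> %s: contig %d bp, breakpoint at offset %d (flanks %d + %d)\n",
              x$junction_id, nchar(x$contig), x$breakpoint_offset,
              nchar(x$seq5), nchar(x$seq3)))
  invisible(x)
}

.as_junction_list <- function(junctions) {
  if (inherits(junctions, "junction")) junctions <- list(junctions)
  stopifnot(length(junctions) >= 1L,
            all(vapply(junctions, inherits, logical(1), "junction")))
  junctions
}

#' Known-fusion whitelist
#'
#' A curated list of known fusions keyed by ordered gene pair
#' (5' partner, 3' partner), optionally with exon-variant pairs. Duplicated
#' (gene5, gene3, variant) triples are collapsed.
#'
#' @param gene5,gene3 character vectors of partner gene symbols (recycled).
#' @param exon5,exon3 optional integer vectors of exon-variant ranks; `NA`
#'   marks a pair-only entry with no specific variant.
#' @return data.frame of class `known_fusions` with columns `gene5`, `gene3`,
#'   `exon5`, `exon3`.
#' @export
known_fusions <- function(gene5, gene3, exon5 = NA_integer_,
                          exon3 = NA_integer_) {
  df <- data.frame(gene5 = as.character(gene5), gene3 = as.character(gene3),
                   exon5 = as.integer(exon5), exon3 = as.integer(exon3),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L && any(!nzchar(df$gene5) | !nzchar(df$gene3) |
                           is.na(df$gene5) | is.na(df$gene3)))
    .stopf("whitelist gene names must be nonempty")
  df <- unique(df)
  df <- df[order(df$gene5, df$gene3, df$exon5, df$exon3), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("known_fusions", "data.frame")
  df
}

#' Read a known-fusion whitelist from TSV
#'
#' Expected columns: `gene5`, `gene3` and optionally `variants`, a
#' semicolon-separated list of exon pairs such as `"16:9;15:9"` (a leading
#' `e` on either rank is accepted, as in `"e16:e9"`).
#'
#' @param path TSV file path.
#' @return a [known_fusions()] object.
#' @export
read_known_fusions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene5", "gene3") %in% names(df)))
    .stopf("whitelist must have columns gene5, gene3: %s", path)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    v <- if ("variants" %in% names(df)) df$variants[i] else NA_character_
    if (is.na(v) || !nzchar(trimws(v)))
      return(data.frame(gene5 = df$gene5[i], gene3 = df$gene3[i],
                        exon5 = NA_integer_, exon3 = NA_integer_))
    parts <- strsplit(trimws(strsplit(v, ";", fixed = TRUE)[[1]]), ":",
                      fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2L
    if (any(bad)) .stopf("malformed variant '%s' for %s:%s", v,
                         df$gene5[i], df$gene3[i])
    e5 <- suppressWarnings(as.integer(sub("^e", "", vapply(parts, `[`, "", 1L))))
    e3 <- suppressWarnings(as.integer(sub("^e", "", vapply(parts, `[`, "", 2L))))
    if (anyNA(e5) || anyNA(e3))
      .stopf("malformed variant '%s' for %s:%s", v, df$gene5[i], df$gene3[i])
    data.frame(gene5 = df$gene5[i], gene3 = df$gene3[i],
               exon5 = e5, exon3 = e3)
  })
  all <- do.call(rbind, rows)
  known_fusions(all$gene5, all$gene3, all$exon5, all$exon3)
}

#' Write a known-fusion whitelist to TSV
#' @param known a [known_fusions()] object.
#' @param path output TSV path.
#' @export
write_known_fusions <- function(known, path) {
  stopifnot(inherits(known, "known_fusions"))
  sp <- split(seq_len(nrow(known)), paste(known$gene5, known$gene3, sep = "\r"))
  sp <- sp[order(vapply(sp, min, integer(1)))]
  out <- do.call(rbind, lapply(sp, function(ix) {
    e5 <- known$exon5[ix]; e3 <- known$exon3[ix]
    has <- !is.na(e5) & !is.na(e3)
    data.frame(gene5 = known$gene5[ix[1]], gene3 = known$gene3[ix[1]],
               variants = paste(sprintf("%d:%d", e5[has], e3[has]),
                                collapse = ";"))
  }))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# is the ordered pair (optionally the exact variant) whitelisted?
is_whitelisted <- function(known, gene5, gene3, exon5 = NA, exon3 = NA,
                           variant_strict = FALSE) {
  if (is.null(known) || nrow(known) == 0L) return(FALSE)
  hit <- known$gene5 == gene5 & known$gene3 == gene3
  if (!variant_strict) return(any(hit))
  # pair-only entries (NA variant) whitelist every variant of the pair
  any(hit & (is.na(known$exon5) |
               (known$exon5 == exon5 & known$exon3 == exon3)))
}

#' Enumerate junction contigs for a whitelist of known fusions
#'
#' Builds one junction per (gene pair, exon variant) entry. Pair-only
#' entries (no exon variant) still whitelist the pair for the caller's
#' rescue rule but contribute no junction contig here.
#'
#' @param known a [known_fusions()] object.
#' @param models named list of [gene_model()] objects (names are gene
#'   symbols); every gene in `known` must be present.
#' @param flank_target flank length passed to [build_junction()].
#' @return list of `junction` objects.
#' @export
enumerate_known_junctions <- function(known, models, flank_target = 200L) {
  stopifnot(inherits(known, "known_fusions"))
  genes <- unique(c(known$gene5, known$gene3))
  missing <- setdiff(genes, names(models))
  if (length(missing) > 0L)
    .stopf("no gene model for whitelisted gene(s): %s",
           paste(missing, collapse = ", "))
  has_var <- which(!is.na(known$exon5) & !is.na(known$exon3))
  lapply(has_var, function(i) {
    build_junction(models[[known$gene5[i]]], known$exon5[i],
                   models[[known$gene3[i]]], known$exon3[i],
                   flank_target = flank_target)
  })
}

#' Write junction contigs to FASTA
#'
#' Headers carry the breakpoint offset and requested flank so that a written
#' junction set round-trips through [read_junction_fasta()]:
#' `>junction_id breakpoint_offset=<int> flank=<int>`.
#'
#' @param junctions list of `junction` objects (or a single one).
#' @param path output FASTA path.
#' @export
write_junction_fasta <- function(junctions, path) {
  junctions <- .as_junction_list(junctions)
  seqs <- Biostrings::DNAStringSet(vapply(junctions, `[[`, "", "contig"))
  names(seqs) <- vapply(junctions, function(j)
    sprintf("%s breakpoint_offset=%d flank=%d", j$junction_id,
            j$breakpoint_offset, j$flank_target), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read junction contigs from a FASTA written by [write_junction_fasta()]
#' @param path junction FASTA path.
#' @return list of `junction` objects.
#' @export
read_junction_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    hdr <- names(seqs)[i]
    id <- sub("\\s.*$", "", hdr)
    b <- suppressWarnings(as.integer(
      sub(".*breakpoint_offset=(\\d+).*", "\\1", hdr)))
    fl <- suppressWarnings(as.integer(sub(".*flank=(\\d+).*", "\\1", hdr)))
    m <- regmatches(id, regexec("^(.+):(.+)\\|e(\\d+):e(\\d+)$", id))[[1]]
    if (length(m) != 5L || is.na(b))
      .stopf("malformed junction FASTA header: %s", hdr)
    contig <- as.character(seqs[[i]])
    structure(
      list(junction_id = id, gene5 = m[2], gene3 = m[3],
           exon5 = as.integer(m[4]), exon3 = as.integer(m[5]),
           seq5 = substr(contig, 1L, b),
           seq3 = substr(contig, b + 1L, nchar(contig)),
           contig = contig, breakpoint_offset = b,
           flank_target = fl),
      class = "junction")
  })
}

#' Write junction metadata to TSV
#' @param junctions list of `junction` objects.
#' @param path output TSV path.
#' @export
write_junction_tsv <- function(junctions, path) {
  junctions <- .as_junction_list(junctions)
  df <- data.frame(
    junction_id = vapply(junctions, `[[`, "", "junction_id"),
    gene5 = vapply(junctions, `[[`, "", "gene5"),
    gene3 = vapply(junctions, `[[`, "", "gene3"),
    exon5 = vapply(junctions, `[[`, 0L, "exon5"),
    exon3 = vapply(junctions, `[[`, 0L, "exon3"),
    breakpoint_offset = vapply(junctions, `[[`, 0L, "breakpoint_offset"),
    contig_length = vapply(junctions, function(j) nchar(j$contig), 0L),
    flank_target = vapply(junctions, `[[`, 0L, "flank_target"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
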