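#' Caller parameters
#'
#' Non-whitelisted fusions need at least `min_support` supporting fragments
#' to be reported; events below that threshold are discarded. Fusions on the
#' known-fusion whitelist are rescued down to a single supporting fragment,
#' mirroring the one-read rescue rule introduced in Arriba v1.2.0 for
#' curated known fusions. Whitelist matching is by ordered gene pair
#' (5' partner, 3' partner) regardless of exon variant; set
#' `variant_strict = TRUE` to require the exact exon variant (whitelist
#' entries without a variant then still match any variant of their pair).
#'
#' @param min_support fragments required for a non-whitelisted fusion
#'   (default 2; must be >= 1).
#' @param whitelist a [known_fusions()] object (or NULL for none).
#' @param variant_strict match the whitelist at exon-variant level.
#' @return an object of class `caller_params`.
#' @export
caller_params <- function(min_support = 2L, whitelist = NULL,
                          variant_strict = FALSE) {
  if (!.is_count(min_support, 1L)) .stopf("min_support must be >= 1")
  if (!is.null(whitelist)) stopifnot(inherits(whitelist, "known_fusions"))
  structure(list(min_support = as.integer(min_support), whitelist = whitelist,
                 variant_strict = isTRUE(variant_strict)),
            class = "caller_params")
}

# closed-form status function: the whole rescue rule in one place
.call_status <- function(support, whitelisted, min_support) {
  if (support == 0L) "absent"
  else if (support >= min_support) "reported"
  else if (whitelisted) "reported"
  else "discarded"
}

#' Call fusions from fragment-level support
#'
#' Assigns each junction variant a status: `reported` when support reaches
#' `min_support`; `reported` with `rescued = TRUE` when support is below the
#' threshold but positive and the gene pair is whitelisted; `discarded` when
#' support is positive but below threshold and not whitelisted; `absent`
#' when support is zero. Exon variants of the same gene pair are called
#' independently; the variant with highest support is flagged `primary`
#' (ties broken by lower 5' exon rank, then lower 3' exon rank).
#'
#' @param supports a `fragment_support` data.frame from
#'   [compute_fragment_support()]. It must carry gene metadata columns
#'   (`gene5`, `gene3`, `exon5`, `exon3`), which it does when
#'   [compute_fragment_support()] was given the junction set; alternatively
#'   pass `junctions` here. Supports must cover every scanned junction,
#'   including zero-support ones.
#' @param params a [caller_params()] object.
#' @param junctions optional junction list supplying gene metadata (and
#'   zero-support rows) when `supports` lacks it.
#' @return data.frame of class `fusion_calls` with columns `junction_id`,
#'   `gene5`, `gene3`, `exon5`, `exon3`, `support`, `whitelisted`,
#'   `rescued`, `status`, `primary`, ordered by gene pair then exon ranks.
#' @export
call_fusions <- function(supports, params = caller_params(),
                         junctions = NULL) {
  stopifnot(inherits(params, "caller_params"))
  if (!is.null(junctions))
    supports <- .merge_support_metadata(supports, junctions)
  need <- c("junction_id", "support", "gene5", "gene3", "exon5", "exon3")
  miss <- setdiff(need, names(supports))
  if (length(miss) > 0L)
    .stopf("junction without gene metadata: supports lack column(s) %s%s",
           paste(miss, collapse = ", "),
           " (pass junctions= or build supports with the junction set)")
  df <- as.data.frame(supports)[, need]
  df$support <- as.integer(df$support)
  df$whitelisted <- vapply(seq_len(nrow(df)), function(i)
    is_whitelisted(params$whitelist, df$gene5[i], df$gene3[i],
                   df$exon5[i], df$exon3[i],
                   variant_strict = params$variant_strict), logical(1))
  df$status <- vapply(seq_len(nrow(df)), function(i)
    .call_status(df$support[i], df$whitelisted[i], params$min_support), "")
  df$rescued <- df$status == "reported" & df$support < params$min_support
  df <- df[order(df$gene5, df$gene3, df$exon5, df$exon3), , drop = FALSE]
  df$primary <- logical(nrow(df))
  for (ix in split(seq_len(nrow(df)), paste(df$gene5, df$gene3, sep = "\r"))) {
    top <- ix[order(-df$support[ix], df$exon5[ix], df$exon3[ix])][1L]
    df$primary[top] <- TRUE
  }
  df <- df[, c("junction_id", "gene5", "gene3", "exon5", "exon3", "support",
               "whitelisted", "rescued", "status", "primary")]
  rownames(df) <- NULL
  class(df) <- c("fusion_calls", "data.frame")
  df
}

.merge_support_metadata <- function(supports, junctions) {
  junctions <- .as_junction_list(junctions)
  jids <- vapply(junctions, `[[`, "", "junction_id")
  extra <- setdiff(supports$junction_id, jids)
  if (length(extra) > 0L)
    .stopf("junction without gene metadata: %s", paste(extra, collapse = ", "))
  m <- match(jids, supports$junction_id)
  data.frame(junction_id = jids,
             support = ifelse(is.na(m), 0L,
                              as.integer(supports$support)[m]),
             gene5 = vapply(junctions, `[[`, "", "gene5"),
             gene3 = vapply(junctions, `[[`, "", "gene3"),
             exon5 = vapply(junctions, `[[`, 0L, "exon5"),
             exon3 = vapply(junctions, `[[`, 0L, "exon3"),
             stringsAsFactors = FALSE)
}

#' @export
print.fusion_calls <- function(x, ...) {
  cat(sprintf("<fusion_calls> %d junction variant(s): %d reported (%d rescued), %d discarded, %d absent\n",
              nrow(x), sum(x$status == "reported"), sum(x$rescued),
              sum(x$status == "discarded"), sum(x$status == "absent")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write fusion calls to TSV
#'
#' Column naming follows common fusion-caller conventions: `gene1`, `gene2`,
#' `exon1`, `exon2`, `split_reads` (fragment support), `whitelisted`,
#' `rescued`, `status`; one row per junction variant, ordered by gene pair
#' then exon ranks.
#'
#' @param calls a `fusion_calls` data.frame from [call_fusions()].
#' @param path output TSV path.
#' @export
write_calls <- function(calls, path) {
  out <- data.frame(gene1 = calls$gene5, gene2 = calls$gene3,
                    exon1 = calls$exon5, exon2 = calls$exon3,
                    split_reads = calls$support,
                    whitelisted = calls$whitelisted,
                    rescued = calls$rescued, status = calls$status)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fusion calls written by [write_calls()]
#'
#' The `primary` flag is not serialized; it is recomputed (it is a
#' deterministic function of the supports).
#'
#' @param path calls TSV path.
#' @return a `fusion_calls` data.frame.
#' @export
read_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(
    junction_id = sprintf("%s:%s|e%d:e%d", df$gene1, df$gene2, df$exon1,
                          df$exon2),
    gene5 = df$gene1, gene3 = df$gene2,
    exon5 = as.integer(df$exon1), exon3 = as.integer(df$exon2),
    support = as.integer(df$split_reads),
    whitelisted = as.logical(df$whitelisted),
    rescued = as.logical(df$rescued), status = df$status,
    stringsAsFactors = FALSE)
  out <- out[order(out$gene5, out$gene3, out$exon5, out$exon3), , drop = FALSE]
  out$primary <- logical(nrow(out))
  for (ix in split(seq_len(nrow(out)),
                   paste(out$gene5, out$gene3, sep = "\r"))) {
    top <- ix[order(-out$support[ix], out$exon5[ix], out$exon3[ix])][1L]
    out$primary[top] <- TRUE
  }
  rownames(out) <- NULL
  class(out) <- c("fusion_calls", "data.frame")
  out
}
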