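.POS_STATUSES <- c("reported", "discarded", "missed")
.NEG_STATUSES <- c("true_negative", "false_positive")
.ALL_STATUSES <- c(.POS_STATUSES, .NEG_STATUSES)

.parse_target_pair <- function(target_pair) {
  if (length(target_pair) == 1L && grepl(":", target_pair)) {
    p <- strsplit(target_pair, ":", fixed = TRUE)[[1]]
    if (length(p) != 2L) .stopf("malformed target pair: %s", target_pair)
    target_pair <- p
  }
  if (length(target_pair) != 2L)
    .stopf("target_pair must be c(gene5, gene3) or 'GENE5:GENE3'")
  as.character(target_pair)
}

#' Score one sample's detection outcome for a target fusion
#'
#' Maps the per-junction call statuses of the target gene pair to the
#' sample-level reported/discarded/missed taxonomy. For a truth-positive
#' sample (one known or simulated to carry the fusion): `reported` if any
#' target variant is reported, else `discarded` if any is discarded, else
#' `missed` (the sample-level name for call-level `absent`). For a
#' truth-negative sample: `false_positive` if any target variant is
#' reported or discarded (i.e. any split-read evidence was found), else
#' `true_negative`.
#'
#' @param calls a `fusion_calls` data.frame covering the target pair's
#'   junction variants.
#' @param truth_positive does the sample truly carry the fusion?
#' @param target_pair `c(gene5, gene3)` or a `"GENE5:GENE3"` string.
#' @param sample_id optional sample label.
#' @return one-row data.frame of class `sample_outcome` with columns
#'   `sample_id`, `truth_positive`, `status`.
#' @export
evaluate_sample <- function(calls, truth_positive, target_pair,
                            sample_id = NA_character_) {
  tp <- .parse_target_pair(target_pair)
  sel <- calls$gene5 == tp[1] & calls$gene3 == tp[2]
  if (!any(sel))
    .stopf("target pair %s:%s absent from junction set", tp[1], tp[2])
  st <- calls$status[sel]
  status <- if (isTRUE(truth_positive)) {
    if (any(st == "reported")) "reported"
    else if (any(st == "discarded")) "discarded"
    else "missed"
  } else {
    if (any(st %in% c("reported", "discarded"))) "false_positive"
    else "true_negative"
  }
  out <- data.frame(sample_id = sample_id,
                    truth_positive = isTRUE(truth_positive),
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("sample_outcome", "data.frame")
  out
}

#' Summarize detection outcomes over a cohort
#'
#' Counts samples per status and reports relative frequencies within each
#' truth stratum (they sum to 100% per stratum), sensitivity
#' (reported / truth-positives), the merged "detected" rate
#' ((reported + discarded) / truth-positives, the grouping used when
#' relating detection to sample covariates), and specificity
#' (true negatives / truth-negatives).
#'
#' @param outcomes data.frame of stacked [evaluate_sample()] rows.
#' @return an object of class `cohort_summary`: list with `counts` (named
#'   integer vector over all five statuses), `frequencies` (percentages
#'   within stratum, rounded to 1 decimal place), `n_positive`,
#'   `n_negative`, `sensitivity`, `detected_rate`, `specificity`.
#' @export
summarize_cohort <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0L)
    .stopf("cannot summarize an empty cohort")
  if (!all(outcomes$status %in% .ALL_STATUSES))
    .stopf("unknown status value(s): %s",
           paste(setdiff(outcomes$status, .ALL_STATUSES), collapse = ", "))
  counts <- table(factor(outcomes$status, levels = .ALL_STATUSES))
  counts <- stats::setNames(as.integer(counts), .ALL_STATUSES)
  n_pos <- sum(counts[.POS_STATUSES])
  n_neg <- sum(counts[.NEG_STATUSES])
  freq <- rep(NA_real_, length(.ALL_STATUSES))
  names(freq) <- .ALL_STATUSES
  if (n_pos > 0L)
    freq[.POS_STATUSES] <- round(100 * counts[.POS_STATUSES] / n_pos, 1L)
  if (n_neg > 0L)
    freq[.NEG_STATUSES] <- round(100 * counts[.NEG_STATUSES] / n_neg, 1L)
  structure(
    list(counts = counts, frequencies = freq,
         n_positive = n_pos, n_negative = n_neg,
         sensitivity = if (n_pos > 0L) counts[["reported"]] / n_pos else NA_real_,
         detected_rate = if (n_pos > 0L)
           (counts[["reported"]] + counts[["discarded"]]) / n_pos else NA_real_,
         specificity = if (n_neg > 0L)
           counts[["true_negative"]] / n_neg else NA_real_),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  truth-positives: %d  truth-negatives: %d\n",
              x$n_positive, x$n_negative))
  for (s in names(x$counts))
    if (x$counts[[s]] > 0L || (s %in% .POS_STATUSES && x$n_positive > 0L) ||
        (s %in% .NEG_STATUSES && x$n_negative > 0L))
      cat(sprintf("  %-14s %4d  (%s%%)\n", s, x$counts[[s]],
                  format(x$frequencies[[s]], nsmall = 1)))
  if (!is.na(x$sensitivity))
    cat(sprintf("  sensitivity %.3f  detected-rate %.3f\n",
                x$sensitivity, x$detected_rate))
  if (!is.na(x$specificity))
    cat(sprintf("  specificity %.3f\n", x$specificity))
  invisible(x)
}

#' Cross-cohort contingency table of detection outcomes
#'
#' Builds the status-by-cohort table of absolute counts underlying
#' cross-cohort comparisons (e.g. a chi-square test in the user's
#' statistics environment; significance testing itself is out of scope
#' here).
#'
#' @param summary_a,summary_b [summarize_cohort()] objects.
#' @param labels column labels (length 2).
#' @return integer matrix, statuses as rows, cohorts as columns.
#' @export
compare_cohorts <- function(summary_a, summary_b,
                            labels = c("cohort_a", "cohort_b")) {
  stopifnot(inherits(summary_a, "cohort_summary"),
            inherits(summary_b, "cohort_summary"), length(labels) == 2L)
  m <- cbind(summary_a$counts, summary_b$counts)
  colnames(m) <- labels
  m
}

#' Evaluate a cohort from a manifest of per-sample call files
#'
#' The manifest is a TSV with columns `sample_id`, `truth_positive`
#' (logical) and `calls_path` (path of a TSV written by [write_calls()];
#' relative paths are resolved against the manifest's directory).
#'
#' @param manifest_path manifest TSV path.
#' @param target_pair target fusion, as in [evaluate_sample()].
#' @return list with `outcomes` (data.frame) and `summary`
#'   ([summarize_cohort()] object).
#' @export
evaluate_manifest <- function(manifest_path, target_pair) {
  mf <- read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "truth_positive", "calls_path")
  if (!all(need %in% names(mf)))
    .stopf("manifest must have columns %s", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  outcomes <- do.call(rbind, lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$calls_path[i]
    if (!file.exists(p)) p <- file.path(base, mf$calls_path[i])
    evaluate_sample(read_calls(p), as.logical(mf$truth_positive[i]),
                    target_pair, sample_id = as.character(mf$sample_id[i]))
  }))
  list(outcomes = outcomes, summary = summarize_cohort(outcomes))
}
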