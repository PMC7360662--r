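#' Run the full detection pipeline on one simulated sample
#'
#' Chains simulate -> scan -> call -> evaluate: simulates a paired-end
#' sample from `config`, scans the FASTQ pair against the junction contigs,
#' aggregates fragment-level support, calls fusions with the whitelist
#' rescue rule, and scores the sample-level outcome for `target_pair`.
#'
#' @param config a [simulation_config()] object.
#' @param junctions junction list (e.g. from [enumerate_known_junctions()]).
#' @param dir working directory for the sample's files.
#' @param sample_id sample label (also the file prefix).
#' @param target_pair target fusion for [evaluate_sample()]; defaults to
#'   the gene pair of the first junction.
#' @param scan a [scan_params()] object.
#' @param caller a [caller_params()] object.
#' @param truth_positive whether the sample truly carries the fusion;
#'   defaults to `config$fusion_fraction > 0`.
#' @param keep_files keep the simulated FASTQ/truth files (default FALSE:
#'   they are deleted after scanning to bound disk use in cohort runs).
#' @return list with `sample_id`, `outcome` (one-row data.frame), `calls`,
#'   `support`, `scan_stats`, `paths` (NULL unless `keep_files`).
#' @export
run_simulated_sample <- function(config, junctions, dir = tempdir(),
                                 sample_id = "sample1", target_pair = NULL,
                                 scan = scan_params(),
                                 caller = caller_params(),
                                 truth_positive = NULL,
                                 keep_files = FALSE) {
  junctions <- .as_junction_list(junctions)
  if (is.null(target_pair))
    target_pair <- c(junctions[[1]]$gene5, junctions[[1]]$gene3)
  if (is.null(truth_positive)) truth_positive <- config$fusion_fraction > 0
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_sample(config, file.path(dir, sample_id))
  res <- scan_fastq(sim$fastq1_path, sim$fastq2_path, junctions, scan)
  support <- compute_fragment_support(res$hits, junctions)
  calls <- call_fusions(support, caller)
  outcome <- evaluate_sample(calls, truth_positive, target_pair,
                             sample_id = sample_id)
  paths <- NULL
  if (keep_files) {
    paths <- sim[c("fastq1_path", "fastq2_path", "truth_path", "config_path")]
  } else {
    unlink(c(sim$fastq1_path, sim$fastq2_path, sim$truth_path,
             sim$config_path))
  }
  list(sample_id = sample_id, outcome = outcome, calls = calls,
       support = support, scan_stats = res$stats, paths = paths)
}

#' Run the pipeline over a cohort of simulated samples
#'
#' @param configs list of [simulation_config()] objects (names become
#'   sample ids).
#' @param junctions junction list.
#' @param ... forwarded to [run_simulated_sample()].
#' @return list with `outcomes` (stacked data.frame), `summary`
#'   ([summarize_cohort()]), `samples` (per-sample results).
#' @export
run_simulated_cohort <- function(configs, junctions, ...) {
  stopifnot(length(configs) >= 1L)
  ids <- names(configs)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_along(configs))
  samples <- lapply(seq_along(configs), function(i)
    run_simulated_sample(configs[[i]], junctions, sample_id = ids[i], ...))
  outcomes <- do.call(rbind, lapply(samples, `[[`, "outcome"))
  list(outcomes = outcomes, summary = summarize_cohort(outcomes),
       samples = samples)
}
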