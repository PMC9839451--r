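#' Run the full spurious-transcription pipeline on synthetic data
#'
#' Generates a synthetic dataset from `config`, then runs the three
#' evidence streams and their integration:
#'
#' 1. exon-ratio call on knockout RNA-seq counts
#'    ([call_spurious_by_exon_ratio()]);
#' 2. knockout-specific sense-strand intragenic CTSS call
#'    ([ko_specific_intragenic_genes()]);
#' 3. Pol II pSer5 gene-body log2 fold change from depth-normalized,
#'    input-subtracted tracks ([depth_normalize()], [input_subtract()],
#'    [gene_body_log2fc()]);
#' 4. the final conjunction ([call_spurious_genes()]).
#'
#' @param config A [sim_config()].
#' @param params A [pipeline_params()].
#' @param keep_genome Keep the genome sequence in the result (needed for
#'   downstream motif analysis; default `FALSE` to save memory).
#' @return A list of class `spurcatch_result`: `call`
#'   (`spurious_call`), `exon` (`exon_ratio_call`), `ctss`
#'   (`ctss_call`), `polII_fc`, `truth`, `genes`, `config`, `params`,
#'   and `genome` when requested.
#' @seealso [evaluate_calls()] for precision/recall against the truth.
#' @export
run_pipeline <- function(config = sim_config(), params = pipeline_params(),
                         keep_genome = FALSE) {
  sim <- simulate_genome(config)
  mat <- simulate_rnaseq_counts(config, sim)
  exon_res <- call_spurious_by_exon_ratio(mat, params, condition = "KO")

  cage <- simulate_cage(config, sim)
  conds <- vapply(cage, `[[`, "", "condition")
  ctss_res <- ko_specific_intragenic_genes(cage[conds == "KO"],
                                           cage[conds == "Ctrl"],
                                           sim$genes, params)

  chip <- simulate_chip(config, sim, tracks = c("pser5", "input"))
  corr_ko <- input_subtract(depth_normalize(chip$pser5_ko),
                            depth_normalize(chip$input_ko), params$window_nt)
  corr_ctrl <- input_subtract(depth_normalize(chip$pser5_ctrl),
                              depth_normalize(chip$input_ctrl), params$window_nt)
  fc <- gene_body_log2fc(corr_ko, corr_ctrl, sim$genes, params$track_pseudocount)

  final <- call_spurious_genes(exon_res$genes, ctss_res$genes, fc, params)
  out <- list(call = final, exon = exon_res, ctss = ctss_res, polII_fc = fc,
              truth = sim$truth, genes = sim$genes, config = config,
              params = params)
  if (keep_genome) out$genome <- sim$genome
  structure(out, class = "spurcatch_result")
}

#' @export
print.spurcatch_result <- function(x, ...) {
  ev <- evaluate_calls(x$call$genes, x$truth)
  cat(sprintf(paste0("spurcatch_result: %d genes called spurious ",
                     "(precision %.3f, recall %.3f vs planted truth)\n"),
              length(x$call$genes), ev$precision, ev$recall))
  invisible(x)
}

#' Precision and recall of a gene call against planted truth
#'
#' @param called Character vector of called gene ids.
#' @param truth A `truth_table` (from [simulate_genome()]).
#' @return List with `precision` (`NA` when nothing is called),
#'   `recall`, `tp`, `fp`, `fn`.
#' @export
evaluate_calls <- function(called, truth) {
  spur <- truth$genes$gene_id[truth$genes$is_spurious]
  tp <- length(intersect(called, spur))
  fp <- length(setdiff(called, spur))
  fn <- length(setdiff(spur, called))
  list(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       recall = if (length(spur) == 0) NA_real_ else tp / length(spur),
       tp = tp, fp = fp, fn = fn)
}
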