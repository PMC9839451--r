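#' Pipeline parameters
#'
#' Bundles every threshold used by the spurious-transcription pipeline.
#' Defaults follow the published analysis workflow this package
#' implements; all are overridable.
#'
#' @param min_exons Minimum number of exons a gene must have to enter the
#'   exon-ratio analysis ("more than four exons", hence 5).
#' @param log2_ratio_min Exon-ratio call threshold: a gene is called when
#'   its mean knockout log2(intermediate/first exon RPKM) is strictly
#'   greater than this value.
#' @param ctss_min_tags CTSS raw-tag threshold; positions with tags
#'   strictly greater than this count as bona fide start sites.
#' @param ctss_fold Minimum knockout/control fold change of the
#'   TPM-normalized intragenic CTSS signal.
#' @param window_nt Window length (nt) for ChIP input subtraction.
#' @param promoter_flank Promoter half-width around the TSS (nt).
#' @param motif_flank Half-width of sequence windows extracted around
#'   cryptic CTSSs for motif analysis (nt).
#' @param polII_fc_min Minimum gene-body Pol II log2 fold change counted
#'   as "enhanced intragenic entry" (strictly greater than; may be 0).
#' @param rpkm_pseudocount Pseudocount (RPKM units) added to numerator
#'   and denominator of the exon-ratio statistic.
#' @param track_pseudocount Pseudocount added to region scores before
#'   track log2 ratios.
#'
#' @return A list of class `pipeline_params`.
#' @examples
#' p <- pipeline_params(min_exons = 6)
#' p$min_exons
#' @export
pipeline_params <- function(min_exons = 5L,
                            log2_ratio_min = 1.0,
                            ctss_min_tags = 8L,
                            ctss_fold = 1.3,
                            window_nt = 50L,
                            promoter_flank = 5000L,
                            motif_flank = 50L,
                            polII_fc_min = 0.0,
                            rpkm_pseudocount = 0.1,
                            track_pseudocount = 1.0) {
  p <- list(
    min_exons = as.integer(min_exons),
    log2_ratio_min = log2_ratio_min,
    ctss_min_tags = ctss_min_tags,
    ctss_fold = ctss_fold,
    window_nt = as.integer(window_nt),
    promoter_flank = as.integer(promoter_flank),
    motif_flank = as.integer(motif_flank),
    polII_fc_min = polII_fc_min,
    rpkm_pseudocount = rpkm_pseudocount,
    track_pseudocount = track_pseudocount
  )
  if (p$min_exons < 2L) stop("min_exons must be >= 2")
  pos <- c("log2_ratio_min", "ctss_min_tags", "ctss_fold", "window_nt",
           "promoter_flank", "motif_flank", "track_pseudocount")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("parameter '%s' must be a single positive number", nm))
  }
  if (!is.finite(p$rpkm_pseudocount) || p$rpkm_pseudocount < 0)
    stop("rpkm_pseudocount must be >= 0")
  if (!is.finite(p$polII_fc_min) || p$polII_fc_min < 0)
    stop("polII_fc_min must be >= 0")
  structure(p, class = "pipeline_params")
}
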