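#' Relative expression by the delta-delta-Ct method
#'
#' Per condition, `dCt = Ct_reference - Ct_target`; the fold change of
#' the treated relative to the control condition is
#' `2^(dCt_trt - dCt_ctrl)`.  The control fold is 1 by construction.
#' Invariant under adding a constant to all four Cts (plate offset).
#'
#' @param ct_target_ctrl,ct_ref_ctrl Target / reference-gene Ct in the
#'   control condition (cycles).
#' @param ct_target_trt,ct_ref_trt Same in the treated condition.
#' @return Fold change (treated vs control).
#' @examples
#' ddct_fold(25, 20, 23, 20)   # 4
#' @export
ddct_fold <- function(ct_target_ctrl, ct_ref_ctrl, ct_target_trt, ct_ref_trt) {
  cts <- c(ct_target_ctrl, ct_ref_ctrl, ct_target_trt, ct_ref_trt)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  d_ctrl <- ct_ref_ctrl - ct_target_ctrl
  d_trt <- ct_ref_trt - ct_target_trt
  2^(d_trt - d_ctrl)
}

#' hMeDIP percent recovery
#'
#' `%recovery = 2^((Ct(10% input) - k) - Ct(IP)) * 100`, where the
#' input-dilution constant `k` corrects the 10% input to 100%.  The
#' published arithmetic uses the printed constant 3.32; set
#' `high_precision = TRUE` to use `log2(10)` instead.
#'
#' @param ct_input_10pct Ct of the 10% input (cycles).
#' @param ct_ip Ct of the immunoprecipitate.
#' @param high_precision Use `log2(10)` rather than the printed 3.32.
#' @return Percent recovery.
#' @examples
#' hmedip_recovery(25.00, 21.68)   # 100
#' @export
hmedip_recovery <- function(ct_input_10pct, ct_ip, high_precision = FALSE) {
  if (!is.finite(ct_input_10pct) || !is.finite(ct_ip))
    stop("Ct values must be finite")
  k <- if (high_precision) log2(10) else 3.32
  2^((ct_input_10pct - k) - ct_ip) * 100
}

#' hMeDIP enrichment over the IgG control
#'
#' Ratio of the locus-specific percent recovery to the IgG recovery.
#'
#' @param recovery_locus Percent recovery at the locus of interest.
#' @param recovery_igg Percent recovery of the IgG control (> 0).
#' @return Enrichment ratio.
#' @examples
#' hmedip_enrichment(40, 5)   # 8
#' @export
hmedip_enrichment <- function(recovery_locus, recovery_igg) {
  if (recovery_igg <= 0) stop("IgG recovery must be > 0: enrichment undefined")
  recovery_locus / recovery_igg
}

#' Average technical replicates on the Ct scale
#'
#' @param ct Numeric vector of technical-replicate Ct values.
#' @return Their mean (cycles).
#' @export
average_ct <- function(ct) {
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  mean(ct)
}
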