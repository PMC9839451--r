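#' Exon count matrix
#'
#' Per-gene, per-exon raw counts for a set of samples, plus per-sample
#' library totals.  Exons are stored in transcription order (exon 1 is
#' the 5'-most exon).
#'
#' @param counts Data frame with columns `gene_id`, `exon_index`
#'   (1-based, transcription order), `exon_len` (bp) and one non-negative
#'   integer count column per sample.
#' @param samples Data frame with columns `sample`, `condition` and
#'   `total_mapped` (total mapped reads, > 0).
#' @return A list of class `exon_count_matrix` with elements `counts`
#'   (data.table) and `samples` (data.frame).
#' @export
exon_count_matrix <- function(counts, samples) {
  counts <- data.table::as.data.table(counts)
  need <- c("gene_id", "exon_index", "exon_len")
  if (!all(need %in% names(counts)))
    stop("counts needs columns gene_id, exon_index, exon_len")
  if (!all(c("sample", "condition", "total_mapped") %in% names(samples)))
    stop("samples needs columns sample, condition, total_mapped")
  miss <- setdiff(samples$sample, names(counts))
  if (length(miss))
    stop(sprintf("count column(s) missing for sample(s): %s", paste(miss, collapse = ", ")))
  if (any(samples$total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(counts$exon_len <= 0)) stop("exon_len must be > 0")
  for (s in samples$sample) {
    v <- counts[[s]]
    if (any(v < 0) || any(v != round(v))) stop(sprintf("counts of '%s' must be non-negative integers", s))
  }
  data.table::setorder(counts, gene_id, exon_index)
  bad <- counts[, .(ok = identical(as.integer(exon_index), seq_len(.N))), by = gene_id][!(ok)]
  if (nrow(bad))
    stop(sprintf("exon_index of gene '%s' is not 1..n in order", bad$gene_id[1L]))
  structure(list(counts = counts, samples = as.data.frame(samples)),
            class = "exon_count_matrix")
}

#' @export
print.exon_count_matrix <- function(x, ...) {
  cat(sprintf("exon_count_matrix: %d genes, %d exon rows, %d samples (%s)\n",
              data.table::uniqueN(x$counts$gene_id), nrow(x$counts),
              nrow(x$samples), paste(x$samples$sample, collapse = ", ")))
  invisible(x)
}

#' Reads per kilobase per million mapped reads
#'
#' `count / ((exon_len_bp / 1000) * (total_mapped / 1e6))`.  Vectorized
#' over all arguments.
#'
#' @param count Raw read count(s), >= 0.
#' @param exon_len_bp Feature length(s) in bp, > 0.
#' @param total_mapped Library total(s), > 0.
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)   # 10
#' @export
rpkm <- function(count, exon_len_bp, total_mapped) {
  if (any(exon_len_bp <= 0)) stop("exon_len_bp must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count / ((exon_len_bp / 1000) * (total_mapped / 1e6))
}

#' Intermediate-versus-first-exon log2 RPKM ratio
#'
#' The per-gene, per-sample statistic
#' `log2((mean RPKM over intermediate exons + eps) / (RPKM of exon 1 + eps))`,
#' where the intermediate exons are exons `2..n-1` by default (the last
#' exon is excluded; set `intermediate = "include_last"` for `2..n`) and
#' `eps` is `params$rpkm_pseudocount`.
#'
#' @param counts Raw counts per exon (transcription order) for one
#'   sample.
#' @param lengths Exon lengths (bp), same order.
#' @param total_mapped Sample library total.
#' @param params [pipeline_params()]; `min_exons` gates the statistic and
#'   `rpkm_pseudocount` sets `eps`.
#' @param intermediate `"drop_last"` (exons 2..n-1) or `"include_last"`
#'   (exons 2..n).
#' @return The log2 ratio (finite, thanks to the pseudocount).  Genes
#'   with fewer than `params$min_exons` exons raise a classed error
#'   (`spurcatch_filtered`) rather than returning a number.
#' @examples
#' exon_ratio_statistic(c(20, 40, 40, 40, 10), rep(1000, 5), 1e6)
#' @export
exon_ratio_statistic <- function(counts, lengths, total_mapped,
                                 params = pipeline_params(),
                                 intermediate = c("drop_last", "include_last")) {
  intermediate <- match.arg(intermediate)
  n <- length(counts)
  if (length(lengths) != n) stop("counts and lengths must be parallel")
  if (n < params$min_exons)
    stop_classed("spurcatch_filtered",
                 "gene has %d exon(s); exon-ratio analysis requires >= %d", n, params$min_exons)
  r <- rpkm(counts, lengths, total_mapped)
  hi <- if (intermediate == "drop_last") n - 1L else n
  eps <- params$rpkm_pseudocount
  log2((mean(r[2:hi]) + eps) / (r[1L] + eps))
}

#' Call genes by the exon-ratio criterion
#'
#' A gene is called when it has at least `params$min_exons` exons
#' ("more than four") and its across-replicate mean log2
#' intermediate/first exon RPKM ratio in the chosen condition is
#' strictly greater than `params$log2_ratio_min`.  Replicates are
#' averaged on the log2 scale.
#'
#' @param mat An [exon_count_matrix()].
#' @param params [pipeline_params()].
#' @param condition Condition whose samples drive the call (default
#'   `"KO"`).
#' @param intermediate See [exon_ratio_statistic()].
#' @return A list of class `exon_ratio_call` with elements
#'   `genes` (called gene ids) and `table` (one row per gene:
#'   `gene_id`, `n_exons`, per-condition mean `rpkm_first_*`,
#'   `rpkm_intermediate_*` and `log2_ratio_*`, `passes_exon_filter`,
#'   `called`).
#' @export
call_spurious_by_exon_ratio <- function(mat, params = pipeline_params(),
                                        condition = "KO",
                                        intermediate = c("drop_last", "include_last")) {
  intermediate <- match.arg(intermediate)
  stopifnot(inherits(mat, "exon_count_matrix"))
  samp <- mat$samples
  if (!condition %in% samp$condition)
    stop(sprintf("condition '%s' absent; available: %s", condition,
                 paste(unique(samp$condition), collapse = ", ")))
  cnt <- mat$counts
  eps <- params$rpkm_pseudocount
  gn <- cnt[, .(n_exons = .N), by = gene_id]
  tab <- gn
  conds <- unique(samp$condition)
  per_sample_ratio <- list()
  for (s in samp$sample) {
    total <- samp$total_mapped[samp$sample == s]
    r <- rpkm(cnt[[s]], cnt$exon_len, total)
    n_per <- gn$n_exons[match(cnt$gene_id, gn$gene_id)]
    hi <- if (intermediate == "drop_last") n_per - 1L else n_per
    is_interm <- cnt$exon_index >= 2L & cnt$exon_index <= hi
    first <- r[cnt$exon_index == 1L]
    names(first) <- cnt$gene_id[cnt$exon_index == 1L]
    im_sum <- rowsum(r[is_interm], cnt$gene_id[is_interm])
    im_n <- rowsum(rep(1, sum(is_interm)), cnt$gene_id[is_interm])
    im_mean <- stats::setNames(as.numeric(im_sum / im_n), rownames(im_sum))
    per_sample_ratio[[s]] <- list(
      first = first,
      interm = im_mean[names(first)],
      ratio = log2((im_mean[names(first)] + eps) / (first + eps))
    )
  }
  ids <- gn$gene_id
  for (cond in conds) {
    ss <- samp$sample[samp$condition == cond]
    fmat <- sapply(ss, function(s) per_sample_ratio[[s]]$first[ids])
    imat <- sapply(ss, function(s) per_sample_ratio[[s]]$interm[ids])
    rmat <- sapply(ss, function(s) per_sample_ratio[[s]]$ratio[ids])
    if (is.null(dim(rmat))) { fmat <- cbind(fmat); imat <- cbind(imat); rmat <- cbind(rmat) }
    tab[[paste0("rpkm_first_", cond)]] <- rowMeans(fmat)
    tab[[paste0("rpkm_intermediate_", cond)]] <- rowMeans(imat)
    tab[[paste0("log2_ratio_", cond)]] <- rowMeans(rmat)
  }
  tab$passes_exon_filter <- tab$n_exons >= params$min_exons
  ratio_col <- paste0("log2_ratio_", condition)
  # genes with too few exons for any intermediate exon get NA, never a call
  too_few <- tab$n_exons < (if (intermediate == "drop_last") 3L else 2L)
  for (cond in conds) {
    tab[[paste0("log2_ratio_", cond)]][too_few] <- NA_real_
    tab[[paste0("rpkm_intermediate_", cond)]][too_few] <- NA_real_
  }
  tab$called <- tab$passes_exon_filter & !is.na(tab[[ratio_col]]) &
    tab[[ratio_col]] > params$log2_ratio_min
  structure(list(genes = tab$gene_id[tab$called], table = tab,
                 condition = condition),
            class = "exon_ratio_call")
}

#' @export
print.exon_ratio_call <- function(x, ...) {
  cat(sprintf("exon_ratio_call: %d of %d genes called (condition %s)\n",
              length(x$genes), nrow(x$table), x$condition))
  invisible(x)
}
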