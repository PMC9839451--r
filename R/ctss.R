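#' CTSS set
#'
#' Single-base CAGE tag start sites for one sample: per
#' `(chrom, pos, strand)` the number of 5' read ends observed there.
#' `total_tags` is the library size used for tags-per-million (TPM)
#' normalization; it is carried through filtering so subsets keep the
#' original denominator.
#'
#' @param records Data frame with columns `chrom`, `pos` (0-based single
#'   base), `strand` (`"+"`/`"-"`), `tags` (positive integers).
#'   Duplicate keys are summed.
#' @param sample_id Sample identifier.
#' @param condition Condition label (e.g. `"Ctrl"`, `"KO"`).
#' @param total_tags Normalization denominator; defaults to the sum of
#'   `tags`.
#' @return A list of class `ctss_set` with elements `records`
#'   (data.table), `sample_id`, `condition`, `total_tags`.
#' @export
ctss_set <- function(records, sample_id = "sample", condition = NA_character_,
                     total_tags = NULL) {
  records <- data.table::as.data.table(records)
  if (nrow(records)) {
    if (!all(c("chrom", "pos", "strand", "tags") %in% names(records)))
      stop("records need columns chrom, pos, strand, tags")
    if (!all(records$strand %in% c("+", "-")))
      stop("every CTSS record must be stranded ('+' or '-')")
    if (any(records$tags < 1) || any(records$tags != round(records$tags)))
      stop("tags must be integers >= 1")
    records <- records[, .(tags = sum(tags)), by = .(chrom, pos, strand)]
    data.table::setorder(records, chrom, pos, strand)
  } else {
    records <- data.table::data.table(chrom = character(), pos = numeric(),
                                      strand = character(), tags = numeric())
  }
  structure(list(records = records, sample_id = sample_id,
                 condition = condition,
                 total_tags = total_tags %||% sum(records$tags)),
            class = "ctss_set")
}

#' @export
print.ctss_set <- function(x, ...) {
  cat(sprintf("ctss_set '%s' (%s): %d positions, %.0f total tags\n",
              x$sample_id, x$condition, nrow(x$records), x$total_tags))
  invisible(x)
}

#' Collapse mapped CAGE reads to single-base CTSSs
#'
#' Each read contributes one tag at its 5' base: `start` for a plus-
#' strand read, `end - 1` for a minus-strand read (0-based half-open
#' read intervals, e.g. from [read_bed6()]).  Tags are accumulated per
#' `(chrom, pos, strand)`; `total_tags` equals the number of input
#' reads.
#'
#' @param reads Data frame with columns `chrom`, `start`, `end`,
#'   `strand`; every record must be stranded.
#' @param sample_id,condition Passed to [ctss_set()].
#' @return A `ctss_set`.
#' @examples
#' r <- data.frame(chrom = "chr1", start = 100, end = 127, strand = "-")
#' collapse_five_prime(r)$records   # tag at pos 126
#' @export
collapse_five_prime <- function(reads, sample_id = "sample",
                                condition = NA_character_) {
  reads <- data.table::as.data.table(reads)
  if (nrow(reads) == 0L)
    return(ctss_set(data.frame(), sample_id, condition, total_tags = 0))
  if (!all(reads$strand %in% c("+", "-")))
    stop("every CAGE read must carry a strand")
  pos <- ifelse(reads$strand == "+", reads$start, reads$end - 1)
  ctss_set(data.table::data.table(chrom = reads$chrom, pos = pos,
                                  strand = reads$strand, tags = 1),
           sample_id, condition, total_tags = nrow(reads))
}

#' Filter CTSSs by the raw tag threshold
#'
#' Retains positions whose raw tag count is strictly greater than
#' `min_tags` (so `tags = 8` is removed at the default threshold of 8).
#' The parent set's `total_tags` is preserved as the TPM denominator.
#'
#' @param set A `ctss_set`.
#' @param min_tags Exclusive threshold (>= 1); default 8.
#' @return A filtered `ctss_set`.
#' @export
threshold_ctss <- function(set, min_tags = 8L) {
  stopifnot(inherits(set, "ctss_set"))
  if (min_tags < 1) stop("min_tags must be >= 1")
  ctss_set(set$records[tags > min_tags], set$sample_id, set$condition,
           total_tags = set$total_tags)
}

#' TPM of CTSS records
#'
#' @param set A `ctss_set`.
#' @return The records table with an added `tpm` column
#'   (`tags * 1e6 / total_tags`).
#' @export
ctss_tpm <- function(set) {
  out <- data.table::copy(set$records)
  out[, tpm := tags * 1e6 / set$total_tags]
  out[]
}

#' Sense-strand intragenic CAGE signal of one gene
#'
#' Sums tags over CTSS records that (i) lie on the gene's strand and
#' (ii) fall inside the transcript span minus every base of exon 1
#' (introns included; see [intragenic_region()]).  TPM uses the parent
#' set's `total_tags`.
#'
#' @param gene A `gene_model` with >= 2 exons.
#' @param set A `ctss_set` (raw or thresholded).
#' @return List with `tag_sum`, `tpm_sum` and `positions` (the matching
#'   records).
#' @export
intragenic_sense_signal <- function(gene, set) {
  reg <- intragenic_region(gene)
  rec <- set$records[chrom == reg$chrom & strand == gene$strand &
                       pos >= reg$start & pos < reg$end]
  list(tag_sum = sum(rec$tags),
       tpm_sum = sum(rec$tags) * 1e6 / max(set$total_tags, 1),
       positions = rec)
}

# intragenic interval table for a gene list (internal)
intragenic_table <- function(genes) {
  rows <- lapply(genes, function(g) {
    if (g$n_exons < 2L) return(NULL)
    reg <- intragenic_region(g)
    data.table::data.table(gene_id = g$gene_id, chrom = reg$chrom,
                           start = reg$start, end = reg$end,
                           strand = g$strand)
  })
  data.table::rbindlist(rows)
}

# per-gene sense intragenic sums for one ctss_set (internal)
intragenic_sums <- function(set, regions) {
  if (nrow(set$records) == 0L || nrow(regions) == 0L)
    return(data.table::data.table(gene_id = character(), tag_sum = numeric(),
                                  tpm_sum = numeric()))
  rec <- data.table::copy(set$records)
  rec[, `:=`(rs = pos, re = pos + 1)]
  reg <- data.table::copy(regions)
  data.table::setkey(reg, chrom, start, end)
  hit <- data.table::foverlaps(rec, reg, by.x = c("chrom", "rs", "re"),
                               type = "within", nomatch = NULL)
  hit <- hit[strand == i.strand]
  out <- hit[, .(tag_sum = sum(tags)), by = gene_id]
  out[, tpm_sum := tag_sum * 1e6 / max(set$total_tags, 1)]
  out[]
}

#' Call genes with knockout-specific intragenic CTSSs
#'
#' A gene is called (`ko_specific`) when both hold:
#'
#' * **(a) position-level specificity** — some sense-strand intragenic
#'   position has raw tags strictly greater than `params$ctss_min_tags`
#'   in at least one knockout sample while staying at or below that
#'   threshold in every control sample;
#' * **(b) gene-level fold** — the across-replicate mean TPM-normalized
#'   intragenic sum satisfies
#'   `(mean_KO + 1) / (mean_Ctrl + 1) >= params$ctss_fold`.
#'
#' @param ko_sets,ctrl_sets Lists of `ctss_set` (>= 1 each).
#' @param genes List of `gene_model`s (single-exon genes are skipped).
#' @param params [pipeline_params()].
#' @return A list of class `ctss_call` with `genes` (called ids),
#'   `table` (per-gene sums, condition means, fold, flags) and
#'   `positions` (knockout-specific positions with gene assignment).
#' @export
ko_specific_intragenic_genes <- function(ko_sets, ctrl_sets, genes,
                                         params = pipeline_params()) {
  stopifnot(length(ko_sets) >= 1L, length(ctrl_sets) >= 1L)
  regions <- intragenic_table(genes)
  set_chroms <- unique(unlist(lapply(c(ko_sets, ctrl_sets),
                                     function(s) unique(s$records$chrom))))
  if (nrow(regions) && length(set_chroms) &&
      !any(regions$chrom %in% set_chroms)) {
    warning("no chromosome shared between gene annotation and CTSS sets")
    return(structure(list(genes = character(0),
                          table = data.table::data.table(),
                          positions = data.table::data.table()),
                     class = "ctss_call"))
  }
  ids <- regions$gene_id
  # per-gene tpm sums per sample
  mean_tpm <- function(sets) {
    m <- sapply(sets, function(s) {
      su <- intragenic_sums(s, regions)
      stats::setNames(su$tpm_sum[match(ids, su$gene_id)], ids)
    })
    m[is.na(m)] <- 0
    if (is.null(dim(m))) m <- cbind(m)
    rowMeans(m)
  }
  ko_mean <- mean_tpm(ko_sets)
  ctrl_mean <- mean_tpm(ctrl_sets)
  fold <- (ko_mean + 1) / (ctrl_mean + 1)

  # candidate positions: above threshold somewhere in KO, inside a gene
  thr <- params$ctss_min_tags
  cand <- data.table::rbindlist(lapply(ko_sets, function(s) {
    d <- s$records[tags > thr]
    if (nrow(d)) d[, sample_id := s$sample_id]
    d
  }), fill = TRUE)
  if (nrow(cand)) {
    cand[, `:=`(rs = pos, re = pos + 1)]
    reg <- data.table::copy(regions)
    data.table::setkey(reg, chrom, start, end)
    cand <- data.table::foverlaps(cand, reg, by.x = c("chrom", "rs", "re"),
                                  type = "within", nomatch = NULL)
    cand <- cand[strand == i.strand,
                 .(gene_id, chrom, pos, strand, tags, sample_id)]
    # keep positions quiet (<= thr) in every control sample
    for (cs in ctrl_sets) {
      high_ctrl <- cs$records[tags > thr, .(chrom, pos, strand)]
      if (nrow(high_ctrl))
        cand <- cand[!high_ctrl, on = c("chrom", "pos", "strand")]
    }
  } else {
    cand <- data.table::data.table(gene_id = character(), chrom = character(),
                                   pos = numeric(), strand = character(),
                                   tags = numeric(), sample_id = character())
  }
  spec_genes <- unique(cand$gene_id)
  tab <- data.table::data.table(
    gene_id = ids,
    ko_mean_tpm = as.numeric(ko_mean),
    ctrl_mean_tpm = as.numeric(ctrl_mean),
    fold = as.numeric(fold),
    n_ko_specific_positions = as.integer(
      cand[, .N, by = gene_id][match(ids, gene_id), N]),
    stringsAsFactors = FALSE
  )
  tab[is.na(n_ko_specific_positions), n_ko_specific_positions := 0L]
  tab[, ko_specific := n_ko_specific_positions > 0L & fold >= params$ctss_fold]
  structure(list(genes = tab$gene_id[tab$ko_specific], table = tab[],
                 positions = cand),
            class = "ctss_call")
}

#' @export
print.ctss_call <- function(x, ...) {
  cat(sprintf("ctss_call: %d of %d genes with knockout-specific intragenic CTSS\n",
              length(x$genes), nrow(x$table)))
  invisible(x)
}

#' Write a CTSS set as BED6 (score = tag count)
#' @param set A `ctss_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ctss_bed <- function(set, path) {
  r <- set$records
  write_bed6(data.table::data.table(chrom = r$chrom, start = r$pos,
                                    end = r$pos + 1, name = ".",
                                    score = r$tags, strand = r$strand),
             path)
}

#' Read a pre-collapsed CTSS BED6 file (score = tag count)
#' @param path BED6 path.
#' @param sample_id,condition Passed to [ctss_set()].
#' @return A `ctss_set`.
#' @export
read_ctss_bed <- function(path, sample_id = "sample",
                          condition = NA_character_) {
  b <- read_bed6(path)
  ctss_set(data.table::data.table(chrom = b$chrom, pos = b$start,
                                  strand = b$strand, tags = b$score),
           sample_id, condition)
}
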