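#' Integrated spurious-gene call
#'
#' Combines the three evidence streams: a gene is finally called
#' spurious when it passes the exon-ratio criterion, has
#' knockout-specific sense-strand intragenic CTSSs, **and** shows
#' enhanced Pol II intragenic entry (gene-body log2 fold change strictly
#' greater than `params$polII_fc_min`).
#'
#' @param exon_genes Character vector of genes passing the exon-ratio
#'   call (e.g. `call_spurious_by_exon_ratio(...)$genes`).
#' @param ctss_genes Character vector of genes with knockout-specific
#'   intragenic CTSSs (e.g. `ko_specific_intragenic_genes(...)$genes`).
#' @param polII_fc Named numeric vector of gene-body Pol II log2 fold
#'   changes ([gene_body_log2fc()]); genes absent from it fail the
#'   Pol II criterion.
#' @param params [pipeline_params()].
#' @return A list of class `spurious_call`:
#'   * `genes` — the final called set;
#'   * `table` — per-gene flags `exon_ratio_pass`, `ctss_pass`,
#'     `polII_pass`, `final`, with the Pol II fold change carried
#'     through;
#'   * `venn` — sizes of the seven exclusive regions of the three-set
#'     Venn diagram (they sum to the size of the union);
#'   * `fraction` — `|final| / |ctss_genes|` (0 with a warning when the
#'     CTSS set is empty) and `pct`, the same rounded to a whole
#'     percent.
#' @examples
#' call_spurious_genes(c("A", "B", "C"), c("B", "C", "D"),
#'                     c(B = 1, D = 2))$genes   # "B"
#' @export
call_spurious_genes <- function(exon_genes, ctss_genes, polII_fc,
                                params = pipeline_params()) {
  pol_genes <- names(polII_fc)[polII_fc > params$polII_fc_min]
  universe <- sort(unique(c(exon_genes, ctss_genes, names(polII_fc))))
  e <- universe %in% exon_genes
  c_ <- universe %in% ctss_genes
  p <- universe %in% pol_genes
  tab <- data.table::data.table(
    gene_id = universe,
    exon_ratio_pass = e, ctss_pass = c_, polII_pass = p,
    polII_log2fc = as.numeric(polII_fc[universe]),
    final = e & c_ & p
  )
  venn <- c(
    exon_only = sum(e & !c_ & !p),
    ctss_only = sum(!e & c_ & !p),
    polII_only = sum(!e & !c_ & p),
    exon_ctss = sum(e & c_ & !p),
    exon_polII = sum(e & !c_ & p),
    ctss_polII = sum(!e & c_ & p),
    all_three = sum(e & c_ & p)
  )
  if (length(ctss_genes) == 0L) {
    warning("empty CTSS gene set: fraction reported as 0")
    fraction <- 0
  } else {
    fraction <- sum(tab$final) / length(unique(ctss_genes))
  }
  structure(list(genes = tab$gene_id[tab$final], table = tab, venn = venn,
                 fraction = fraction, pct = round(100 * fraction)),
            class = "spurious_call")
}

#' @export
print.spurious_call <- function(x, ...) {
  cat(sprintf("spurious_call: %d final genes (%d%% of the CTSS set)\n",
              length(x$genes), x$pct))
  print(x$venn)
  invisible(x)
}

#' Extract sense-oriented sequence windows around CTSSs
#'
#' Returns the `2 * flank + 1`-nt window centered on each position;
#' minus-strand windows are reverse-complemented so that index
#' `flank + 1` is always the CTSS base read on the sense strand.
#' Positions whose window does not fit on the chromosome are skipped
#' with a warning.
#'
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @param positions Data frame with columns `chrom`, `pos` (0-based),
#'   `strand`.
#' @param flank Half-width in nt; default 50 (101-nt windows).
#' @return A `DNAStringSet` named `chrom:pos:strand`.
#' @export
extract_ctss_windows <- function(genome, positions, flank = 50L) {
  positions <- data.table::as.data.table(positions)
  positions <- unique(positions[, .(chrom, pos, strand)])
  lens <- Biostrings::width(genome)[match(positions$chrom, names(genome))]
  ok <- !is.na(lens) & positions$pos - flank >= 0 & positions$pos + flank < lens
  if (any(!ok))
    warning(sprintf("%d window(s) skipped: outside chromosome bounds", sum(!ok)))
  positions <- positions[ok]
  if (nrow(positions) == 0L) return(Biostrings::DNAStringSet())
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(positions)), function(i) {
    as.character(Biostrings::subseq(genome[[positions$chrom[i]]],
                                    positions$pos[i] - flank + 1,
                                    positions$pos[i] + flank + 1))
  }, ""))
  minus <- positions$strand == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- sprintf("%s:%d:%s", positions$chrom,
                         as.integer(positions$pos), positions$strand)
  seqs
}

#' Sample background windows from intragenic space
#'
#' Draws `n` uniform random sense-strand intragenic positions (exon 1
#' excluded) from the given genes, avoiding an excluded position set,
#' and extracts their sequence windows.  Deterministic for a fixed
#' seed.
#'
#' @param genes List of `gene_model`s.
#' @param genome A `DNAStringSet` named by chromosome.
#' @param n Number of background windows (>= 1; at least the foreground
#'   size in enrichment use).
#' @param seed RNG seed.
#' @param exclude Optional data frame (`chrom`, `pos`, `strand`) of
#'   positions that must not be sampled (typically the foreground).
#' @param flank Window half-width; default 50.
#' @return A `DNAStringSet` of background windows.
#' @export
sample_background_windows <- function(genes, genome, n, seed = 17L,
                                      exclude = NULL, flank = 50L) {
  if (n < 1L) stop("background must be non-empty (n >= 1)")
  regions <- intragenic_table(genes)
  if (nrow(regions) == 0L) stop("no intragenic space to sample from")
  # clip to window-fitting space
  lens <- Biostrings::width(genome)[match(regions$chrom, names(genome))]
  regions$start <- pmax(regions$start, flank)
  regions$end <- pmin(regions$end, lens - flank)
  regions <- regions[regions$end > regions$start, ]
  widths <- regions$end - regions$start
  if (sum(widths) < n) stop("insufficient eligible intragenic space")
  excl_key <- character(0)
  if (!is.null(exclude) && nrow(exclude))
    excl_key <- sprintf("%s:%d:%s", exclude$chrom, as.integer(exclude$pos),
                        exclude$strand)
  with_seed(seed, {
    picked <- data.table::data.table(chrom = character(), pos = numeric(),
                                     strand = character())
    tries <- 0L
    while (nrow(picked) < n) {
      tries <- tries + 1L
      if (tries > 50L) stop("could not sample enough background positions")
      k <- n - nrow(picked)
      ri <- sample.int(nrow(regions), k, replace = TRUE, prob = widths)
      off <- floor(runif(k) * widths[ri])
      cand <- data.table::data.table(chrom = regions$chrom[ri],
                                     pos = regions$start[ri] + off,
                                     strand = regions$strand[ri])
      key <- sprintf("%s:%d:%s", cand$chrom, as.integer(cand$pos), cand$strand)
      cand <- cand[!(key %in% excl_key)]
      picked <- unique(rbind(picked, cand))
    }
    picked <- picked[seq_len(n)]
  })
  extract_ctss_windows(genome, picked, flank)
}

# two-sided permutation p-value for a difference in means (internal)
perm_p_value <- function(x, y, n_perm, seed) {
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  nx <- length(x)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), nx)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    }, numeric(1)) >= obs - 1e-12)
  })
  (1 + exceed) / (n_perm + 1)
}

#' CpG dinucleotide enrichment in CTSS windows
#'
#' Compares the mean number of CG dinucleotides per foreground window
#' with the background mean.  Significance comes from a two-sided
#' permutation test on the difference of means (label shuffles of the
#' pooled windows), reported with the +1 correction so
#' `p >= 1 / (n_perm + 1)`.
#'
#' @param fg,bg `DNAStringSet`s of equal-length windows (both
#'   non-empty); see [extract_ctss_windows()] and
#'   [sample_background_windows()].
#' @param n_perm Number of permutations; default 999.
#' @param seed RNG seed for the permutation.
#' @return List with `fold` (fg mean / bg mean; `Inf` when the
#'   background mean is 0), `p`, `fg_mean`, `bg_mean`.
#' @export
cpg_enrichment <- function(fg, bg, n_perm = 999L, seed = 17L) {
  if (length(fg) == 0L || length(bg) == 0L)
    stop("foreground and background must be non-empty")
  fgc <- Biostrings::vcountPattern("CG", fg)
  bgc <- Biostrings::vcountPattern("CG", bg)
  fold <- if (mean(bgc) == 0) Inf else mean(fgc) / mean(bgc)
  list(fold = fold, p = perm_p_value(fgc, bgc, n_perm, seed),
       fg_mean = mean(fgc), bg_mean = mean(bgc))
}

#' Consensus motif scan of CTSS windows
#'
#' A window "hits" a motif when the IUPAC consensus matches anywhere on
#' the given (sense) orientation.  Per motif, hit counts in foreground
#' and background, the fold of hit rates, and a permutation p-value on
#' the hit indicators (as in [cpg_enrichment()]) are reported.  A motif
#' absent from all foreground windows has fold 0.
#'
#' @param fg,bg `DNAStringSet`s of windows.
#' @param motifs Character vector of IUPAC consensus strings.
#' @param n_perm,seed Permutation settings.
#' @return A `data.table` with one row per motif: `motif`, `fg_hits`,
#'   `bg_hits`, `fg_rate`, `bg_rate`, `fold`, `p`.
#' @export
motif_scan <- function(fg, bg, motifs, n_perm = 999L, seed = 17L) {
  if (length(fg) == 0L || length(bg) == 0L)
    stop("foreground and background must be non-empty")
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  for (m in motifs) {
    ch <- strsplit(toupper(m), "")[[1]]
    bad <- setdiff(ch, valid)
    if (length(bad))
      stop(sprintf("invalid IUPAC character '%s' in motif '%s'", bad[1L], m))
  }
  rows <- lapply(seq_along(motifs), function(i) {
    m <- toupper(motifs[i])
    fgh <- as.integer(Biostrings::vcountPattern(m, fg, fixed = FALSE) > 0)
    bgh <- as.integer(Biostrings::vcountPattern(m, bg, fixed = FALSE) > 0)
    fold <- if (mean(fgh) == 0) 0
            else if (mean(bgh) == 0) Inf
            else mean(fgh) / mean(bgh)
    data.table::data.table(
      motif = motifs[i], fg_hits = sum(fgh), bg_hits = sum(bgh),
      fg_rate = mean(fgh), bg_rate = mean(bgh), fold = fold,
      p = perm_p_value(fgh, bgh, n_perm, seed + i - 1L)
    )
  })
  data.table::rbindlist(rows)
}
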