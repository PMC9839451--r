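#' Depth-normalize a signal track
#'
#' Scales every value by `1e6 / total_mass`, so the returned track has
#' total mass 1e6 (per-million units).  Idempotent on tracks whose mass
#' is already 1e6.
#'
#' @param track A `signal_track` with positive total mass.
#' @return A normalized `signal_track`.
#' @export
depth_normalize <- function(track) {
  m <- track_total(track)
  if (m <= 0) stop("cannot depth-normalize a track with zero total mass")
  f <- 1e6 / m
  signal_track(lapply(track$values, function(v) as.numeric(v) * f),
               strand = track$strand)
}

#' Median-of-ratios size factors
#'
#' The standard median-of-ratios normalization: for each region with
#' all-positive counts, compute the geometric mean across samples; the
#' size factor of a sample is the median over those regions of
#' `count / geometric mean`.  Factors are reported unscaled.
#'
#' @param counts Numeric matrix, regions x samples (>= 2 samples).
#' @return Numeric vector of per-sample factors.
#' @examples
#' size_factors(cbind(a = c(4, 10), b = c(9, 10)))
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("size factors need >= 2 samples")
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) stop("no region with positive counts in all samples")
  lc <- log(counts[use, , drop = FALSE])
  lgm <- rowMeans(lc)
  apply(lc, 2L, function(x) exp(stats::median(x - lgm)))
}

#' Windowed input subtraction with zero clamping
#'
#' Partitions each chromosome into consecutive windows of `window` nt
#' anchored at coordinate 0 (the final window may be shorter).  The
#' window value is the treatment sum minus the input sum, clamped at 0
#' where input exceeds treatment; the per-base corrected value is the
#' window value divided by the window's true length.  Both tracks are
#' expected to be depth-normalized (see [depth_normalize()]).
#'
#' @param treatment,input `signal_track`s.  Chromosomes missing from the
#'   input are treated as zero input, with a warning.
#' @param window Window length in nt (>= 1); default 50.
#' @return A `signal_track` subclassed `corrected_track`, with
#'   attributes `window_nt`, `treatment_id`, `input_id`.
#' @export
input_subtract <- function(treatment, input, window = 50L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  chroms <- names(treatment$values)
  miss <- setdiff(chroms, names(input$values))
  if (length(miss))
    warning(sprintf("chromosome(s) %s missing from input; treated as zero",
                    paste(miss, collapse = ", ")))
  vals <- lapply(chroms, function(ch) {
    tv <- as.numeric(treatment$values[[ch]])
    iv <- as.numeric(input$values[[ch]] %||% numeric(0))
    n <- max(length(tv), length(iv))
    if (length(tv) < n) tv <- c(tv, numeric(n - length(tv)))
    if (length(iv) < n) iv <- c(iv, numeric(n - length(iv)))
    nb <- ceiling(n / window)
    ends <- pmin(seq_len(nb) * window, n)
    cs_t <- cumsum(tv); cs_i <- cumsum(iv)
    tsum <- cs_t[ends] - c(0, cs_t[head(ends, -1L)])
    isum <- cs_i[ends] - c(0, cs_i[head(ends, -1L)])
    lens <- diff(c(0, ends))
    rep(pmax(0, tsum - isum) / lens, times = lens)
  })
  names(vals) <- chroms
  out <- signal_track(vals)
  class(out) <- c("corrected_track", class(out))
  attr(out, "window_nt") <- window
  attr(out, "treatment_id") <- attr(treatment, "track_id") %||% "treatment"
  attr(out, "input_id") <- attr(input, "track_id") %||% "input"
  out
}

#' Mean signal over a region
#'
#' Average per-base signal over a genomic interval, with uncovered
#' bases (beyond the track's data or on short chromosomes) counted as 0
#' ("mean0" semantics).  `mode = "sum"` returns the plain sum instead.
#'
#' @param track A `signal_track` or `corrected_track`.
#' @param region A `genomic_interval`.
#' @param mode `"mean0"` (default) or `"sum"`.
#' @return A single number; regions on chromosomes absent from the
#'   track score 0 with a warning.
#' @export
region_score <- function(track, region, mode = c("mean0", "sum")) {
  mode <- match.arg(mode)
  v <- track$values[[region$chrom]]
  if (is.null(v)) {
    warning(sprintf("chromosome '%s' not in track; region scored 0", region$chrom))
    return(0)
  }
  lo <- region$start + 1
  hi <- min(region$end, length(v))
  s <- if (lo <= hi) sum(v[lo:hi]) else 0
  if (mode == "sum") s else s / interval_width(region)
}

#' Gene-body log2 fold change between two corrected tracks
#'
#' `log2((score_KO + c) / (score_Ctrl + c))` over each gene's
#' exon2-to-TES body, with `c = pseudocount`.  Genes without a body
#' (single exon) are omitted with a warning.
#'
#' @param ko,ctrl `corrected_track`s produced with the same window.
#' @param genes List of `gene_model`s.
#' @param pseudocount Additive constant `c` (> 0); default 1.
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
gene_body_log2fc <- function(ko, ctrl, genes, pseudocount = 1.0) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  res <- vapply(genes, function(g) {
    body <- tryCatch(gene_body(g, "exon2_to_tes"),
                     spurcatch_no_gene_body = function(e) NULL)
    if (is.null(body)) return(NA_real_)
    log2((region_score(ko, body) + pseudocount) /
           (region_score(ctrl, body) + pseudocount))
  }, numeric(1))
  names(res) <- vapply(genes, `[[`, "", "gene_id")
  if (anyNA(res)) {
    warning(sprintf("%d single-exon gene(s) omitted from gene-body fold change",
                    sum(is.na(res))))
    res <- res[!is.na(res)]
  }
  res
}

# shared grouping core: descending by value, ties by id, remainder to top
group_split <- function(values, k, labels) {
  ids <- names(values)
  ord <- order(-values, ids)
  n <- length(values)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  data.table::data.table(gene_id = ids[ord],
                         group = rep(labels, times = sizes),
                         value = values[ord])
}

#' Assign genes to quartiles of a score
#'
#' Genes are sorted descending by value (ties broken by gene id,
#' lexicographically) and split into four contiguous groups `a`
#' (highest) to `d` (lowest) whose sizes differ by at most 1; remainder
#' genes go to the top groups.
#'
#' @param values Named numeric vector (>= 4 genes).
#' @return A `data.table` of class `group_assignment` with columns
#'   `gene_id`, `group`, `value`; attribute `scheme = "quartile"`.
#' @export
assign_quartiles <- function(values) {
  if (length(values) < 4L) stop("quartile assignment needs >= 4 genes")
  if (is.null(names(values))) stop("values must be named by gene id")
  out <- group_split(values, 4L, letters[1:4])
  data.table::setattr(out, "scheme", "quartile")
  data.table::setattr(out, "class", c("group_assignment", class(out)))
  out
}

#' Assign genes to expression quintiles
#'
#' Quintile `1` holds the most expressed genes, `5` the least, with the
#' same sorting and size rules as [assign_quartiles()].  Additionally
#' the bottom `bottom_pct`% of genes (lowest expression,
#' `floor(n * bottom_pct / 100)` of them) are flagged.
#'
#' @param expression Named numeric vector (>= 5 genes).
#' @param bottom_pct Percentage flagged as very low expressed; default 5.
#' @return A `data.table` of class `group_assignment` with columns
#'   `gene_id`, `group` (`"1"`..`"5"`), `value`, `bottom_flag`;
#'   attribute `scheme = "quintile"`.
#' @export
assign_expression_quintiles <- function(expression, bottom_pct = 5) {
  if (length(expression) < 5L) stop("quintile assignment needs >= 5 genes")
  if (is.null(names(expression))) stop("expression must be named by gene id")
  out <- group_split(expression, 5L, as.character(1:5))
  n <- nrow(out)
  n_bottom <- floor(n * bottom_pct / 100)
  out[, bottom_flag := FALSE]
  if (n_bottom > 0) out[(n - n_bottom + 1):n, bottom_flag := TRUE]
  data.table::setattr(out, "scheme", "quintile")
  data.table::setattr(out, "class", c("group_assignment", class(out)))
  out
}

# per-gene metagene vector (internal)
metagene_vector <- function(v, gene, body_bins, flank, flank_bin) {
  val_at <- function(p) {
    out <- numeric(length(p))
    ok <- p >= 0 & p < length(v)
    out[ok] <- v[p[ok] + 1]
    out
  }
  if (gene$strand == "+") {
    body <- gene$tss:gene$tes
    up <- (gene$tss - flank):(gene$tss - 1)
    down <- (gene$tes + 1):(gene$tes + flank)
  } else {
    body <- seq(gene$tss, gene$tes, by = -1L)
    up <- seq(gene$tss + flank, gene$tss + 1, by = -1L)
    down <- seq(gene$tes - 1, gene$tes - flank, by = -1L)
  }
  bin_means <- function(x, k) {
    idx <- floor((seq_along(x) - 1) * k / length(x)) + 1
    as.numeric(rowsum(x, idx) / tabulate(idx, k))
  }
  flank_means <- function(p) {
    m <- matrix(val_at(p), nrow = flank_bin)
    colMeans(m)
  }
  c(flank_means(up), bin_means(val_at(body), body_bins), flank_means(down))
}

#' Metagene profile
#'
#' For each gene, signal over the transcript span (TSS to TES, oriented
#' in transcription direction; minus-strand genes are reversed) is
#' rescaled to `body_bins` bins of mean signal, and fixed-width flanks
#' of `flank` nt are binned at `flank_bin` nt.  Per-gene vectors are
#' averaged into a mean profile.  Bases outside the track are 0.
#'
#' @param track A `signal_track` or `corrected_track`.
#' @param genes List of `gene_model`s; genes spanning fewer than
#'   `body_bins` bases (or on chromosomes absent from the track) are
#'   skipped with a warning.
#' @param body_bins Number of body bins; default 100.
#' @param flank Flank width in nt; default 2000 (must be a multiple of
#'   `flank_bin`).
#' @param flank_bin Flank bin width in nt; default 50.
#' @return A list of class `metagene_profile`: `profile` (mean vector),
#'   `per_gene` (matrix, genes x bins), `n_flank_bins`, `body_bins`.
#' @export
metagene_profile <- function(track, genes, body_bins = 100L, flank = 2000L,
                             flank_bin = 50L) {
  if (flank %% flank_bin != 0) stop("flank must be a multiple of flank_bin")
  rows <- list()
  skipped <- 0L
  for (g in genes) {
    v <- track$values[[g$chrom]]
    span <- abs(g$tes - g$tss) + 1
    if (is.null(v) || span < body_bins) { skipped <- skipped + 1L; next }
    rows[[g$gene_id]] <- metagene_vector(v, g, body_bins, flank, flank_bin)
  }
  if (skipped)
    warning(sprintf("%d gene(s) skipped (short span or unknown chromosome)", skipped))
  if (!length(rows)) stop("no usable gene for metagene profile")
  m <- do.call(rbind, rows)
  structure(list(profile = colMeans(m), per_gene = m,
                 n_flank_bins = flank %/% flank_bin, body_bins = body_bins),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: %d genes, %d flank + %d body + %d flank bins\n",
              nrow(x$per_gene), x$n_flank_bins, x$body_bins, x$n_flank_bins))
  invisible(x)
}
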