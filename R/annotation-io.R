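#' Genomic interval
#'
#' A simple half-open interval on a named chromosome.  All coordinates in
#' this package are 0-based half-open (`[start, end)`), the native
#' convention of BED and bedGraph; GTF is converted on read/write.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded).
#' @return A list of class `genomic_interval` with fields `chrom`,
#'   `start`, `end`, `strand`.
#' @examples
#' genomic_interval("chr1", 100, 200, "+")
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end)
    stop("interval requires 0 <= start < end")
  if (!strand %in% c("+", "-", "*")) stop("strand must be '+', '-' or '*'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%.0f-%.0f(%s)>\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

#' Interval width in bases
#' @param x A `genomic_interval`.
#' @return Number of bases spanned.
#' @export
interval_width <- function(x) x$end - x$start

#' Gene model
#'
#' A gene as an ordered set of exons.  Exons are stored in transcription
#' order: exon 1 is the 5'-most exon in the direction of transcription,
#' so for a minus-strand gene the exon list runs from high to low genomic
#' coordinates.  The TSS is the first transcribed base and the TES the
#' last transcribed base (both 0-based single positions).
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Parallel vectors of 0-based half-open
#'   exon coordinates in transcription order.
#' @return A list of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `exon_starts`, `exon_ends`, `n_exons`, `tss`, `tes`.
#' @examples
#' g <- gene_model("g1", "chr1", "+", c(100, 300), c(200, 400))
#' g$tss; g$tes
#' @export
gene_model <- function(gene_id, chrom, strand, exon_starts, exon_ends) {
  if (!strand %in% c("+", "-")) stop("gene strand must be '+' or '-'")
  n <- length(exon_starts)
  if (n < 1L || length(exon_ends) != n) stop("need >= 1 exon with matching starts/ends")
  exon_starts <- as.numeric(exon_starts); exon_ends <- as.numeric(exon_ends)
  if (any(exon_starts < 0) || any(exon_starts >= exon_ends))
    stop("each exon requires 0 <= start < end")
  # transcription order: genomically ascending on '+', descending on '-'
  if (n > 1L) {
    ord_ok <- if (strand == "+") all(diff(exon_starts) > 0) else all(diff(exon_starts) < 0)
    if (!ord_ok) stop(sprintf("exons of '%s' not in transcription order", gene_id))
    gs <- sort(exon_starts); ge <- exon_ends[order(exon_starts)]
    if (any(gs[-1] < ge[-n])) stop(sprintf("exons of '%s' overlap", gene_id))
  }
  tss <- if (strand == "+") exon_starts[1L] else exon_ends[1L] - 1
  tes <- if (strand == "+") exon_ends[n] - 1 else exon_starts[n]
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exon_starts = exon_starts, exon_ends = exon_ends,
                 n_exons = n, tss = tss, tes = tes),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s(%s) %d exon(s), tss=%.0f tes=%.0f\n",
              x$gene_id, x$chrom, x$strand, x$n_exons, x$tss, x$tes))
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Parses exon features (1-based inclusive coordinates) into
#' [gene_model()] objects with 0-based half-open internal coordinates.
#' Exons are grouped by `gene_id` and ordered in transcription direction.
#'
#' @param path Path to a GTF file.
#' @return Named list of `gene_model` objects (one per gene with at least
#'   one exon feature). Genes appearing only through non-exon features
#'   are skipped with a warning.
#' @seealso [write_gtf()]
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  dat <- which(!grepl("^\\s*(#|$)", lines))
  if (length(dat)) {
    nf <- vapply(strsplit(lines[dat], "\t", fixed = TRUE), length, 1L)
    bad <- dat[nf < 9L]
    if (length(bad))
      stop(sprintf("malformed GTF record at line %d of '%s' (%d field(s), need 9)",
                   bad[1L], path, nf[match(bad[1L], dat)]))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) return(list())
  ids_all <- unique(as.character(gr$gene_id))
  ex <- gr[!is.na(gr$type) & gr$type == "exon"]
  ids_ex <- unique(as.character(ex$gene_id))
  dropped <- setdiff(ids_all, ids_ex)
  if (length(dropped))
    warning(sprintf("skipping %d gene(s) without exon features: %s",
                    length(dropped), paste(head(dropped, 5L), collapse = ", ")))
  dt <- data.table::data.table(
    gene_id = as.character(ex$gene_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1,   # to 0-based half-open
    end = as.numeric(GenomicRanges::end(ex)),
    strand = as.character(GenomicRanges::strand(ex))
  )
  out <- lapply(split(dt, by = "gene_id", sorted = FALSE), function(d) {
    strand <- d$strand[1L]
    if (!strand %in% c("+", "-"))
      stop(sprintf("gene '%s' has no usable strand", d$gene_id[1L]))
    ord <- order(d$start, decreasing = (strand == "-"))
    gene_model(d$gene_id[1L], d$chrom[1L], strand, d$start[ord], d$end[ord])
  })
  out[ids_ex]
}

#' Write gene models to a GTF file
#'
#' Emits one exon feature per exon, converting back to 1-based inclusive
#' coordinates. `read_gtf(write_gtf(genes))` reproduces the input models.
#'
#' @param genes List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  rows <- data.table::rbindlist(lapply(genes, function(g) {
    gs <- sort(g$exon_starts)
    ge <- g$exon_ends[order(g$exon_starts)]
    data.table::data.table(chrom = g$chrom, start = gs + 1, end = ge,
                           strand = g$strand, gene_id = g$gene_id)
  }))
  gr <- GenomicRanges::GRanges(
    rows$chrom, IRanges::IRanges(rows$start, rows$end), strand = rows$strand,
    type = "exon", source = "spurcatch",
    gene_id = rows$gene_id, transcript_id = rows$gene_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Gene body interval
#'
#' Two conventions are supported. `"exon2_to_tes"` (the default used by
#' all intragenic scoring in this package) spans from the
#' transcription-order start of exon 2 to the TES, excluding every base
#' of exon 1; `"tss_to_tes"` is the full transcript span, used for
#' metagene display.
#'
#' @param gene A `gene_model`.
#' @param definition `"exon2_to_tes"` or `"tss_to_tes"`.
#' @return A `genomic_interval` on the gene's strand.
#' @examples
#' g <- gene_model("g", "chr1", "+", c(0, 200, 400), c(100, 300, 500))
#' gene_body(g)                      # [200, 500)
#' gene_body(g, "tss_to_tes")        # [0, 500)
#' @export
gene_body <- function(gene, definition = c("exon2_to_tes", "tss_to_tes")) {
  definition <- match.arg(definition)
  if (definition == "tss_to_tes") {
    if (gene$strand == "+")
      return(genomic_interval(gene$chrom, gene$tss, gene$tes + 1, gene$strand))
    return(genomic_interval(gene$chrom, gene$tes, gene$tss + 1, gene$strand))
  }
  if (gene$n_exons < 2L)
    stop_classed("spurcatch_no_gene_body",
                 "gene '%s' has a single exon: no exon2-to-TES gene body", gene$gene_id)
  if (gene$strand == "+")
    genomic_interval(gene$chrom, gene$exon_starts[2L], gene$tes + 1, gene$strand)
  else
    genomic_interval(gene$chrom, gene$tes, gene$exon_ends[2L], gene$strand)
}

#' Promoter interval
#'
#' The window of `2 * flank + 1` bases centered on the TSS
#' (TSS +/- `flank` nt), left-clipped at coordinate 0.
#'
#' @param gene A `gene_model`.
#' @param flank Half-width in nt (> 0); default 5000.
#' @return A `genomic_interval` (unstranded window centered on the TSS).
#' @examples
#' g <- gene_model("g", "chr1", "+", 10000, 12000)
#' promoter(g)         # [5000, 15001)
#' @export
promoter <- function(gene, flank = 5000L) {
  if (!is.numeric(flank) || flank <= 0) stop("flank must be > 0")
  genomic_interval(gene$chrom, max(0, gene$tss - flank), gene$tss + flank + 1,
                   gene$strand)
}

#' Intragenic interval (transcript span minus exon 1)
#'
#' The genomic span of a gene with every base of exon 1 removed; introns
#' are included since CTSSs are genomic, not exonic, events.  This is
#' the region over which intragenic CAGE signal is quantified.
#'
#' @param gene A `gene_model` with at least 2 exons.
#' @return A `genomic_interval` on the gene's strand.
#' @export
intragenic_region <- function(gene) {
  if (gene$n_exons < 2L)
    stop_classed("spurcatch_no_gene_body",
                 "gene '%s' has a single exon: no intragenic region", gene$gene_id)
  if (gene$strand == "+")
    genomic_interval(gene$chrom, gene$exon_ends[1L], gene$tes + 1, gene$strand)
  else
    genomic_interval(gene$chrom, gene$tes, gene$exon_starts[1L], gene$strand)
}

# ---------------------------------------------------------------------------
# Signal tracks

#' Per-base signal track
#'
#' A dense per-base numeric signal, one vector per chromosome. Position
#' `p` (0-based) of chromosome `ch` is `values[[ch]][p + 1]`. Raw
#' coverage and tag tracks are non-negative everywhere; background
#' corrected tracks (see [input_subtract()]) additionally carry window
#' metadata.
#'
#' @param values Named list of finite numeric vectors.
#' @param strand Optional strand label (`"+"`, `"-"`).
#' @return A list of class `signal_track`.
#' @examples
#' t <- signal_track(list(chr1 = c(0, 0, 3, 3, 0)))
#' track_total(t)
#' @export
signal_track <- function(values, strand = NULL) {
  if (!is.list(values) || (length(values) && is.null(names(values))))
    stop("values must be a named list of numeric vectors")
  for (ch in names(values)) {
    v <- values[[ch]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop(sprintf("track values on '%s' must be finite numbers", ch))
  }
  structure(list(values = values, strand = strand), class = "signal_track")
}

#' Total mass of a signal track
#' @param track A `signal_track`.
#' @return Sum of all per-base values.
#' @export
track_total <- function(track) {
  sum(vapply(track$values, function(v) sum(as.numeric(v)), numeric(1)))
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), %.0f bases, total mass %.6g\n",
              length(x$values), sum(lengths(x$values)), track_total(x)))
  invisible(x)
}

#' Read a bedGraph file into a signal track
#'
#' Intervals must be 0-based half-open and non-overlapping per
#' chromosome; bases not covered by any record are 0.
#'
#' @param path Path to a bedGraph file.
#' @param seqlengths Optional named vector of chromosome lengths; when
#'   given, vectors are padded with zeros to these lengths (zero runs may
#'   have been omitted on write).
#' @return A `signal_track`.
#' @seealso [write_bedgraph()]
#' @export
read_bedgraph <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) {
    vals <- list()
    if (!is.null(seqlengths))
      vals <- lapply(seqlengths, function(n) numeric(n))
    return(signal_track(vals))
  }
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    score = as.numeric(gr$score)
  )
  data.table::setorder(dt, chrom, start)
  ov <- dt[, .(bad = which(start[-1] < end[-.N])[1]), by = chrom][!is.na(bad)]
  if (nrow(ov)) {
    d <- dt[chrom == ov$chrom[1L]]
    i <- ov$bad[1L]
    stop(sprintf("overlapping bedGraph intervals on %s: [%.0f,%.0f) and [%.0f,%.0f)",
                 ov$chrom[1L], d$start[i], d$end[i], d$start[i + 1L], d$end[i + 1L]))
  }
  vals <- lapply(split(dt, by = "chrom", sorted = TRUE), function(d) {
    n <- max(d$end)
    v <- numeric(n)
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1):d$end[i]] <- d$score[i]
    v
  })
  if (!is.null(seqlengths)) {
    for (ch in names(seqlengths)) {
      n <- seqlengths[[ch]]
      v <- vals[[ch]] %||% numeric(0)
      if (length(v) < n) v <- c(v, numeric(n - length(v)))
      vals[[ch]] <- v
    }
  }
  signal_track(vals)
}

#' Write a signal track to bedGraph
#'
#' Consecutive equal values are merged into single records; zero-valued
#' runs are omitted.
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$values), function(ch) {
    r <- rle(as.numeric(track$values[[ch]]))
    ends <- cumsum(r$lengths)
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = ch,
                           start = (ends - r$lengths)[keep] + 1,  # 1-based for GRanges
                           end = ends[keep],
                           score = r$values[keep])
  })
  rows <- data.table::rbindlist(rows)
  if (nrow(rows) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(rows$chrom, IRanges::IRanges(rows$start, rows$end),
                               score = rows$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# ---------------------------------------------------------------------------
# BED6

#' Read a BED6 file
#'
#' @param path Path to a BED file with at least 6 columns.
#' @return A `data.table` with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    name = if (!is.null(gr$name)) as.character(gr$name) else ".",
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write BED6 records
#'
#' @param records Data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(records, path) {
  records <- data.table::as.data.table(records)
  gr <- GenomicRanges::GRanges(
    records$chrom,
    IRanges::IRanges(records$start + 1, records$end),
    strand = if ("strand" %in% names(records)) records$strand else "*"
  )
  gr$name <- if ("name" %in% names(records)) records$name else "."
  gr$score <- if ("score" %in% names(records)) records$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
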