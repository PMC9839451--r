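# Shared fixtures: small simulation configs and brute-force scalar
# oracles used to cross-check the vectorized implementations.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 60L, genes_per_chrom = 30L, library_size = 4e5),
    list(...))
  do.call(sim_config, args)
}

# three-exon plus-strand gene on chr1: exons [0,100), [200,300), [400,500)
toy_gene_plus <- function(id = "gP") {
  gene_model(id, "chr1", "+", c(0, 200, 400), c(100, 300, 500))
}

# same exons on the minus strand (transcription order high -> low)
toy_gene_minus <- function(id = "gM") {
  gene_model(id, "chr1", "-", c(400, 200, 0), c(500, 300, 100))
}

# --- independent scalar oracles -------------------------------------------

oracle_exon_ratio <- function(counts, lengths, total, eps, drop_last = TRUE) {
  r <- numeric(length(counts))
  for (i in seq_along(counts))
    r[i] <- counts[i] / ((lengths[i] / 1000) * (total / 1e6))
  hi <- if (drop_last) length(counts) - 1 else length(counts)
  acc <- 0
  for (i in 2:hi) acc <- acc + r[i]
  log2((acc / (hi - 1) + eps) / (r[1] + eps))
}

oracle_input_subtract <- function(tv, iv, window) {
  n <- max(length(tv), length(iv))
  tv <- c(tv, rep(0, n - length(tv)))
  iv <- c(iv, rep(0, n - length(iv)))
  out <- numeric(n)
  w0 <- 1
  while (w0 <= n) {
    w1 <- min(w0 + window - 1, n)
    ts <- 0; is <- 0
    for (j in w0:w1) { ts <- ts + tv[j]; is <- is + iv[j] }
    val <- ts - is
    if (val < 0) val <- 0
    for (j in w0:w1) out[j] <- val / (w1 - w0 + 1)
    w0 <- w1 + 1
  }
  out
}

oracle_region_score <- function(v, start, end) {
  acc <- 0
  for (p in start:(end - 1)) if (p + 1 <= length(v)) acc <- acc + v[p + 1]
  acc / (end - start)
}

# median of count/geomean ratios per sample, taken on the log scale so
# an even number of usable regions averages the middle pair geometrically
oracle_size_factors <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gm <- numeric(nr); usable <- logical(nr)
  for (r in seq_len(nr)) {
    pos <- TRUE
    for (s in seq_len(nc)) if (m[r, s] <= 0) pos <- FALSE
    usable[r] <- pos
    if (pos) gm[r] <- exp(sum(log(m[r, ])) / nc)
  }
  out <- numeric(nc)
  for (s in seq_len(nc)) {
    ratios <- sort(log(m[usable, s] / gm[usable]))
    k <- length(ratios)
    mid <- if (k %% 2 == 1) ratios[(k + 1) / 2]
           else (ratios[k / 2] + ratios[k / 2 + 1]) / 2
    out[s] <- exp(mid)
  }
  out
}

expect_rel_equal <- function(x, y, tol = 1e-9) {
  denom <- pmax(abs(y), 1e-12)
  expect_true(all(abs(x - y) / denom <= tol))
}
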