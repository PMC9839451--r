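# Depth normalization, input subtraction, region scoring, grouping and
# metagene profiles.

test_that("depth normalization scales tracks to per-million mass and is idempotent there", {
  tr <- signal_track(list(chr1 = rep(4, 5e5), chr2 = rep(0, 1e3)))
  n1 <- depth_normalize(tr)   # mass 2e6 -> factor 0.5
  expect_equal(n1$values$chr1[1], 2)
  expect_equal(track_total(n1), 1e6)
  n2 <- depth_normalize(n1)
  expect_equal(n2$values, n1$values)
  expect_error(depth_normalize(signal_track(list(chr1 = numeric(10)))), "zero")
})

test_that("size factors follow the median-of-ratios definition", {
  expect_equal(size_factors(cbind(a = c(5, 9, 12), b = c(5, 9, 12))), c(a = 1, b = 1))
  m <- cbind(a = c(10, 20, 7), b = c(20, 40, 14))
  expect_equal(size_factors(m), c(a = 1 / sqrt(2), b = sqrt(2)))
  expect_equal(size_factors(cbind(a = 4, b = 9)), c(a = 2 / 3, b = 3 / 2))
  # rows with a zero in any sample are ignored; all-zero-usable errors
  expect_equal(size_factors(cbind(a = c(4, 0), b = c(9, 5))), c(a = 2 / 3, b = 3 / 2))
  expect_error(size_factors(cbind(a = c(0, 1), b = c(1, 0))), "no region")
  expect_error(size_factors(cbind(a = 1:3)), "2 samples")
})

test_that("size factors agree with the established median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(11)
  m <- matrix(rnbinom(300, mu = 50, size = 5), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  m[, 2] <- m[, 2] * 2
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("input subtraction clamps negative windows at zero and averages per window", {
  tr <- signal_track(list(chr1 = c(rep(2, 4), rep(0.5, 4))))
  inp <- signal_track(list(chr1 = c(rep(1, 4), rep(1, 4))))
  corr <- input_subtract(tr, inp, window = 4)
  # window 1: 8 - 4 = 4 over 4 bases -> 1; window 2: 2 - 4 -> clamped 0
  expect_equal(corr$values$chr1, c(rep(1, 4), rep(0, 4)))
  expect_equal(attr(corr, "window_nt"), 4)
  # zero input: corrected equals per-window-averaged treatment
  zero <- signal_track(list(chr1 = numeric(8)))
  ident <- input_subtract(tr, zero, window = 4)
  expect_equal(ident$values$chr1, c(rep(2, 4), rep(0.5, 4)))
  # missing chromosome in input is treated as zero, with a warning
  expect_warning(
    two <- input_subtract(signal_track(list(chr1 = rep(1, 4), chr2 = rep(3, 4))),
                          signal_track(list(chr1 = rep(1, 4))), window = 2),
    "chr2")
  expect_equal(two$values$chr2, rep(3, 4))
})

test_that("corrected tracks are non-negative and bounded by windowed treatment", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(300:1200, 1)
    tr <- signal_track(list(c1 = rpois(n, 2)))
    inp <- signal_track(list(c1 = rpois(n, 2)))
    w <- sample(c(7, 50, 64), 1)
    corr <- input_subtract(tr, inp, w)
    expect_true(all(corr$values$c1 >= 0))
    base <- input_subtract(tr, signal_track(list(c1 = numeric(n))), w)
    expect_true(all(corr$values$c1 <= base$values$c1 + 1e-12))
  }
})

test_that("input subtraction and region scores match a brute-force per-base oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(500:2000, 1)
    tv <- rpois(n, 3) * runif(1, 0.5, 2)
    iv <- rpois(n, 3) * runif(1, 0.5, 2)
    w <- sample(c(13, 50, 128), 1)
    got <- input_subtract(signal_track(list(x = tv)), signal_track(list(x = iv)), w)
    want <- oracle_input_subtract(tv, iv, w)
    expect_rel_equal(got$values$x, want)
    a <- sample.int(n - 10, 1); b <- a + sample.int(n - a, 1)
    reg <- genomic_interval("x", a, b)
    expect_rel_equal(region_score(got, reg), oracle_region_score(want, a, b))
  }
})

test_that("region scores use mean0 semantics with uncovered bases as zero", {
  tr <- signal_track(list(chr1 = c(2, 2, 2, 0, 0, 0)))
  expect_equal(region_score(tr, genomic_interval("chr1", 0, 6)), 1)
  expect_equal(region_score(tr, genomic_interval("chr1", 0, 3)), 2)
  # region extending beyond the data: missing bases count as zero
  expect_equal(region_score(tr, genomic_interval("chr1", 3, 12)), 0)
  expect_equal(region_score(tr, genomic_interval("chr1", 0, 12)), 0.5)
  expect_equal(region_score(tr, genomic_interval("chr1", 0, 6), mode = "sum"), 6)
  expect_warning(z <- region_score(tr, genomic_interval("chrX", 0, 5)), "chrX")
  expect_equal(z, 0)
})

test_that("gene-body log2 fold change uses the pseudocount and omits bodyless genes", {
  g <- toy_gene_plus()
  ko <- structure(signal_track(list(chr1 = rep(3, 500))), class = c("corrected_track", "signal_track"))
  ctrl <- structure(signal_track(list(chr1 = rep(1, 500))), class = c("corrected_track", "signal_track"))
  fc <- gene_body_log2fc(ko, ctrl, list(g), pseudocount = 1)
  expect_equal(unname(fc), 1)   # log2((3+1)/(1+1))
  zero <- structure(signal_track(list(chr1 = numeric(500))), class = c("corrected_track", "signal_track"))
  expect_equal(unname(gene_body_log2fc(zero, zero, list(g), 1)), 0)
  single <- gene_model("s1", "chr1", "+", 0, 100)
  expect_warning(fc2 <- gene_body_log2fc(ko, ctrl, list(g, single), 1), "single-exon")
  expect_named(fc2, "gP")
})

test_that("quartile assignment sorts descending with deterministic ties and balanced sizes", {
  v <- c(g1 = 10, g2 = 9, g3 = 8, g4 = 7, g5 = 6, g6 = 5, g7 = 4, g8 = 3)
  q <- assign_quartiles(v)
  expect_equal(as.vector(table(q$group)), rep(2, 4))
  expect_equal(q$group[q$gene_id == "g1"], "a")
  expect_equal(q$group[q$gene_id == "g8"], "d")
  # all-tied values: assignment by gene id, sizes still balanced
  tied <- setNames(rep(1, 8), paste0("g", 1:8))
  qt <- assign_quartiles(tied)
  expect_equal(as.vector(table(qt$group)), rep(2, 4))
  expect_equal(qt$gene_id[qt$group == "a"], c("g1", "g2"))
  # remainder goes to the top groups: n = 10 -> 3,3,2,2
  q10 <- assign_quartiles(setNames(10:1, paste0("g", sprintf("%02d", 1:10))))
  expect_equal(as.vector(table(q10$group)[letters[1:4]]), c(3, 3, 2, 2))
  # idempotent in membership when re-grouping by rank of the same values
  q2 <- assign_quartiles(v[q$gene_id])
  expect_equal(q2$group, q$group)
  expect_error(assign_quartiles(c(a = 1, b = 2, c = 3)), ">= 4")
})

test_that("expression quintiles flag the bottom tail", {
  v <- setNames(100:1, sprintf("g%03d", 1:100))
  q <- assign_expression_quintiles(v)
  expect_equal(as.vector(table(q$group)), rep(20, 5))
  expect_equal(sum(q$bottom_flag), 5)
  expect_true(all(q$group[q$bottom_flag] == "5"))   # bottom tail inside quintile 5
  q5 <- assign_expression_quintiles(setNames(5:1, letters[1:5]))
  expect_equal(as.vector(table(q5$group)), rep(1, 5))
  expect_error(assign_expression_quintiles(c(a = 1)), ">= 5")
})

test_that("metagene profiles are flat on uniform tracks and transcription-oriented", {
  genes <- list(
    gene_model("g1", "chr1", "+", 3000, 3600),
    gene_model("g2", "chr1", "-", 5000, 5900)
  )
  uni <- signal_track(list(chr1 = rep(2.5, 10000)))
  prof <- metagene_profile(uni, genes, body_bins = 100, flank = 1000, flank_bin = 50)
  expect_equal(length(prof$profile), 20 + 100 + 20)
  expect_true(all(abs(prof$profile - 2.5) < 1e-12))
  # signal only at the TSS of a minus-strand gene lands at the TSS edge
  v <- numeric(10000); v[5900] <- 60   # 0-based 5899 = TSS of g2
  tssed <- signal_track(list(chr1 = v))
  p2 <- metagene_profile(tssed, genes[2], body_bins = 100, flank = 1000, flank_bin = 50)
  body <- p2$profile[21:120]
  expect_gt(body[1], 0)
  expect_true(all(body[-1] == 0))
  # mean profile is the average of per-gene vectors
  p_all <- metagene_profile(tssed, genes, body_bins = 100, flank = 1000, flank_bin = 50)
  expect_equal(p_all$profile, colMeans(p_all$per_gene))
  expect_equal(nrow(p_all$per_gene), 2)
  # genes shorter than the bin count are skipped
  shorty <- gene_model("tiny", "chr1", "+", 100, 150)
  expect_warning(metagene_profile(uni, list(genes[[1]], shorty), body_bins = 100,
                                  flank = 1000, flank_bin = 50), "skipped")
})
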