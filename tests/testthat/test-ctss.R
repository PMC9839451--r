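# CTSS collapsing, thresholding, intragenic quantification and the
# knockout-specificity call.

test_that("reads collapse to their 5' base with strand-aware positions", {
  r <- data.frame(chrom = "chr1", start = c(100, 100, 100, 100),
                  end = c(127, 127, 127, 130),
                  strand = c("+", "-", "+", "+"))
  s <- collapse_five_prime(r)
  expect_equal(s$total_tags, 4)
  rec <- s$records
  expect_equal(rec[rec$strand == "+" & rec$pos == 100, ]$tags, 3)  # accumulation
  expect_equal(rec[rec$strand == "-", ]$pos, 126)                  # end - 1
  # conservation: total tags equal number of reads
  expect_equal(sum(rec$tags), nrow(r))
  expect_error(collapse_five_prime(data.frame(chrom = "c", start = 1, end = 5,
                                              strand = "*")), "strand")
  empty <- collapse_five_prime(data.frame())
  expect_equal(empty$total_tags, 0)
  expect_equal(nrow(empty$records), 0)
})

test_that("the tag threshold is strict and preserves the TPM denominator", {
  s <- ctss_set(data.frame(chrom = "chr1", pos = c(10, 20, 30),
                           strand = "+", tags = c(8, 9, 100)))
  f <- threshold_ctss(s, 8)
  expect_equal(f$records$tags, c(9, 100))     # tags = 8 removed, 9 retained
  expect_equal(f$total_tags, 117)             # parent denominator kept
  e <- threshold_ctss(ctss_set(data.frame()), 8)
  expect_equal(nrow(e$records), 0)
})

test_that("intragenic sense signal excludes exon 1 and the antisense strand but counts introns", {
  g <- toy_gene_plus()   # exons [0,100),[200,300),[400,500); intragenic [100,500)
  s <- ctss_set(data.frame(
    chrom = "chr1",
    pos = c(0, 150, 250, 250, 600),
    strand = c("+", "+", "+", "-", "+"),
    tags = c(50, 10, 5, 99, 7)), total_tags = 1e6)
  sig <- intragenic_sense_signal(g, s)
  # TSS tag (exon 1) excluded, antisense excluded, downstream-of-gene excluded;
  # the intron-1 tag (pos 150) and exon-2 tag count
  expect_equal(sig$tag_sum, 15)
  expect_equal(sig$tpm_sum, 15)
  expect_setequal(sig$positions$pos, c(150, 250))
  expect_error(intragenic_sense_signal(gene_model("s", "chr1", "+", 0, 100), s),
               class = "spurcatch_no_gene_body")
  # monotone filters: sense-only and exon-1 exclusion never increase the sum
  expect_lte(sig$tag_sum, sum(s$records$tags))
})

test_that("TPM sums are invariant under joint scaling of tags and totals", {
  g <- toy_gene_plus()
  base <- data.frame(chrom = "chr1", pos = c(150, 250), strand = "+",
                     tags = c(4, 6))
  s1 <- ctss_set(base, total_tags = 1000)
  s3 <- ctss_set(transform(base, tags = tags * 3), total_tags = 3000)
  expect_equal(intragenic_sense_signal(g, s1)$tpm_sum,
               intragenic_sense_signal(g, s3)$tpm_sum)
})

test_that("the knockout-specificity call applies both the position and the fold criterion", {
  g <- toy_gene_plus()
  mk_set <- function(pos, tags, id, cond)
    ctss_set(data.frame(chrom = "chr1", pos = pos, strand = "+", tags = tags),
             sample_id = id, condition = cond, total_tags = 1e6)
  # (a) + (b): specific position (9 > 8, silent in control), fold 15/11 >= 1.3
  ko <- mk_set(c(250, 260), c(9, 5), "ko1", "KO")
  ctrl <- mk_set(260, 10, "c1", "Ctrl")
  res <- ko_specific_intragenic_genes(list(ko), list(ctrl), list(g))
  expect_equal(res$genes, "gP")
  expect_equal(res$table$fold, 15 / 11)
  expect_equal(res$positions$pos, 250)
  # fold below 1.3 fails despite a specific position: (12+1)/(10+1) ~ 1.18
  ko2 <- mk_set(c(250, 260), c(9, 3), "ko1", "KO")
  res2 <- ko_specific_intragenic_genes(list(ko2), list(ctrl), list(g))
  expect_length(res2$genes, 0)
  expect_equal(res2$table$fold, 13 / 11, tolerance = 1e-12)
  # no knockout-specific position fails despite high signal: control is
  # already above threshold at the same base
  ko3 <- mk_set(260, 13, "ko1", "KO")
  res3 <- ko_specific_intragenic_genes(list(ko3), list(ctrl), list(g))
  expect_length(res3$genes, 0)
  expect_equal(res3$table$n_ko_specific_positions, 0L)
})

test_that("disjoint chromosome sets yield a warning and an empty call", {
  g <- toy_gene_plus()
  other <- ctss_set(data.frame(chrom = "chr9", pos = 250, strand = "+",
                               tags = 20), condition = "KO")
  expect_warning(
    res <- ko_specific_intragenic_genes(list(other), list(other), list(g)),
    "no chromosome")
  expect_length(res$genes, 0)
})

test_that("every planted cryptic site is recovered as knockout-specific on synthetic data", {
  cfg <- small_config(n_genes = 100L, genes_per_chrom = 50L)
  sim <- simulate_genome(cfg)
  cage <- simulate_cage(cfg, sim)
  conds <- vapply(cage, `[[`, "", "condition")
  res <- ko_specific_intragenic_genes(cage[conds == "KO"], cage[conds == "Ctrl"],
                                      sim$genes)
  spur <- sim$truth$genes$gene_id[sim$truth$genes$is_spurious]
  expect_setequal(res$genes, spur)
  cs <- sim$truth$cryptic_sites
  found <- unique(res$positions[, c("chrom", "pos", "strand")])
  planted <- unique(cs[, c("chrom", "pos", "strand")])
  expect_true(all(
    paste(planted$chrom, planted$pos, planted$strand) %in%
      paste(found$chrom, found$pos, found$strand)))
})

test_that("CTSS BED6 files round trip with score as tag count", {
  s <- ctss_set(data.frame(chrom = c("chr1", "chr2"), pos = c(5, 11),
                           strand = c("+", "-"), tags = c(12, 3)),
                sample_id = "x", condition = "KO")
  path <- tempfile(fileext = ".bed")
  write_ctss_bed(s, path)
  back <- read_ctss_bed(path, "x", "KO")
  expect_equal(back$records, s$records)
  expect_equal(back$total_tags, s$total_tags)
})
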