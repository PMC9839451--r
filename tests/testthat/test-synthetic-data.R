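# Determinism, planted-truth consistency, and the statistical laws the
# generator is supposed to follow.

test_that("the generator is fully deterministic for a fixed seed", {
  cfg <- small_config(n_genes = 20L, genes_per_chrom = 20L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$genes, b$truth$genes)
  expect_identical(a$truth$cryptic_sites, b$truth$cryptic_sites)
  expect_identical(simulate_rnaseq_counts(cfg, a)$counts,
                   simulate_rnaseq_counts(cfg, b)$counts)
  ca <- simulate_cage(cfg, a); cb <- simulate_cage(cfg, b)
  expect_identical(lapply(ca, `[[`, "records"), lapply(cb, `[[`, "records"))
  ta <- simulate_chip(cfg, a, "pser5"); tb <- simulate_chip(cfg, b, "pser5")
  expect_identical(ta$pser5_ko$values, tb$pser5_ko$values)
  # on-disk outputs are byte-identical across runs
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_dataset(cfg, d1, tracks = "input")
  simulate_dataset(cfg, d2, tracks = "input")
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("spurious genes are planted at the configured count with in-body cryptic sites", {
  cfg <- small_config(n_genes = 100L, genes_per_chrom = 50L,
                      fraction_spurious = 0.10)
  sim <- simulate_genome(cfg)
  expect_equal(sum(sim$truth$genes$is_spurious), 10)
  cs <- sim$truth$cryptic_sites
  expect_gt(nrow(cs), 0)
  for (i in seq_len(nrow(cs))) {
    g <- sim$genes[[cs$gene_id[i]]]
    b <- gene_body(g, "exon2_to_tes")
    expect_equal(cs$strand[i], g$strand)
    expect_true(cs$pos[i] > b$start && cs$pos[i] < b$end - 1)
    # the sense-strand motif is planted at the cryptic start site
    win <- extract_ctss_windows(sim$genome,
                                cs[i, c("chrom", "pos", "strand")], flank = 10)
    expect_equal(as.character(Biostrings::subseq(win[[1]], 11, 16)),
                 cfg$motif_consensus)
  }
  none <- simulate_genome(small_config(fraction_spurious = 0))
  expect_equal(sum(none$truth$genes$is_spurious), 0)
  expect_equal(nrow(none$truth$cryptic_sites), 0)
})

test_that("a unit spurious effect leaves knockout and control exon ratios at parity", {
  cfg <- sim_config(n_genes = 200L, genes_per_chrom = 50L, library_size = 1e6,
                    spurious_effect = 1)
  sim <- simulate_genome(cfg)
  mat <- simulate_rnaseq_counts(cfg, sim)
  res <- call_spurious_by_exon_ratio(mat)
  delta <- res$table$log2_ratio_KO - res$table$log2_ratio_Ctrl
  expect_lt(abs(mean(delta, na.rm = TRUE)), 0.2)
})

test_that("exon counts approach Poisson in the zero-dispersion limit", {
  draws <- spurcatch:::nb_sample(1e4, mu = 20, dispersion = 0)
  expect_lt(abs(var(draws) / mean(draws) - 1), 0.1)
  # and are over-dispersed otherwise: variance ~ mu + disp * mu^2
  od <- spurcatch:::nb_sample(2e4, mu = 20, dispersion = 0.1)
  expect_gt(var(od), 1.5 * mean(od))
})

test_that("a 4-fold spurious gain shifts the knockout exon ratio by ~2 log2 units", {
  cfg <- sim_config(n_genes = 300L, genes_per_chrom = 50L, library_size = 3e6)
  sim <- simulate_genome(cfg)
  mat <- simulate_rnaseq_counts(cfg, sim)
  res <- call_spurious_by_exon_ratio(mat)
  spur <- sim$truth$genes$gene_id[sim$truth$genes$is_spurious]
  tab <- res$table[res$table$gene_id %in% spur, ]
  delta <- mean(tab$log2_ratio_KO - tab$log2_ratio_Ctrl)
  expect_lt(abs(delta - 2), 0.15)
})

test_that("CAGE control samples carry no strong intragenic start sites while planted knockout sites exceed the tag threshold", {
  cfg <- small_config(n_genes = 100L, genes_per_chrom = 50L)
  sim <- simulate_genome(cfg)
  cage <- simulate_cage(cfg, sim)
  conds <- vapply(cage, `[[`, "", "condition")
  for (s in cage[conds == "Ctrl"]) {
    for (g in sim$genes) {
      sig <- intragenic_sense_signal(g, threshold_ctss(s, 8))
      expect_equal(sig$tag_sum, 0)
    }
  }
  cs <- sim$truth$cryptic_sites
  for (s in cage[conds == "KO"]) {
    hit <- s$records[cs, on = c("chrom", "pos", "strand")]
    tags <- ifelse(is.na(hit$tags), 0, hit$tags)   # absent site = 0 tags
    expect_gte(mean(tags > 8), 0.95)
  }
  # strand bookkeeping: minus-strand genes produce minus-strand tags
  minus_ids <- sim$truth$genes$gene_id[sim$truth$genes$strand == "-"]
  g <- sim$genes[[minus_ids[1]]]
  ko1 <- cage[conds == "KO"][[1]]
  at_tss <- ko1$records[chrom == g$chrom & abs(pos - g$tss) <= 2]
  expect_true(all(at_tss$strand == "-"))
})

test_that("ChIP tracks follow the configured structure", {
  cfg <- small_config(n_genes = 100L, genes_per_chrom = 50L)
  sim <- simulate_genome(cfg)
  chip <- simulate_chip(cfg, sim, tracks = c("input", "hmc"))
  # input is uniform Poisson noise at input_rate
  imean <- track_total(chip$input_ctrl) /
    sum(lengths(chip$input_ctrl$values))
  expect_lt(abs(imean / cfg$input_rate - 1), 0.05)
  # 5hmC body signal grows with expression tier in control
  tiers <- sim$truth$genes$tier
  scores <- vapply(sim$genes, function(g)
    region_score(chip$hmc_ctrl, gene_body(g)), numeric(1))
  tier_means <- tapply(scores, tiers, mean)
  expect_true(all(diff(tier_means) >= 0))
  # no planted spurious genes: knockout and control tracks agree in law
  cfg0 <- small_config(fraction_spurious = 0)
  sim0 <- simulate_genome(cfg0)
  p0 <- simulate_chip(cfg0, sim0, tracks = "pser5")
  m_ko <- track_total(p0$pser5_ko); m_ctrl <- track_total(p0$pser5_ctrl)
  expect_lt(abs(m_ko / m_ctrl - 1), 0.05)
})
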