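#' Simulation configuration
#'
#' Parameters of the synthetic dataset generator.  The defaults define
#' the reference benchmark conditions used throughout the package: 2,000
#' genes, 10% of them planted as spurious with a 4-fold gain on
#' intermediate-exon knockout means, ~30 expected CAGE tags at each
#' planted cryptic start site, negative-binomial exon counts with
#' dispersion 0.1, two replicates per condition, seed 17.
#'
#' @param n_genes Number of genes.
#' @param genes_per_chrom Genes per synthetic chromosome (~50).
#' @param exon_count_range Exons per gene, inclusive range.
#' @param exon_len_range Exon length range (bp).
#' @param intron_len_range Intron length range (bp).
#' @param intergenic_gap Gap between consecutive genes (bp).
#' @param max_chrom_len Optional chromosome length budget; a gene that
#'   cannot fit raises a sizing error.
#' @param fraction_spurious Fraction of genes planted as spurious (in
#'   `[0, 1)`); exactly `round(n_genes * fraction_spurious)` genes.
#' @param spurious_effect Multiplicative gain on intermediate-exon
#'   knockout means of spurious genes (>= 1; 1 disables the effect).
#' @param spurious_gain_last Also apply the gain to the last exon
#'   (default `FALSE`: intermediate = exons 2..n-1).
#' @param expression_log_mean,expression_log_sd Log-normal parameters of
#'   baseline gene expression.
#' @param nb_dispersion Negative-binomial dispersion of exon counts
#'   (`variance = mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param library_size Expected informative units per RNA-seq sample.
#' @param cage_canonical_rate Expected canonical-TSS tags per expression
#'   unit.
#' @param cage_cryptic_tags Expected tags at each planted cryptic site
#'   in knockout samples (0 disables cryptic tags).
#' @param cage_noise_rate Expected stray tags per base per strand
#'   (uniform noise floor, single-tag positions).
#' @param leaky_control_rate Fraction of `cage_cryptic_tags` leaking
#'   into control samples at cryptic sites (default 0: cryptic
#'   initiation is knockout-specific).
#' @param pser5_peak_height Pol II pSer5 TSS peak scale (per-base mean
#'   at the summit is `pser5_peak_height * log1p(expression)`).
#' @param pser5_peak_sd TSS peak standard deviation (bp).
#' @param pser5_body_rate Pol II body plateau mean (per base).
#' @param pser5_body_gain Plateau multiplier over spurious-gene bodies
#'   in knockout samples.
#' @param pser5_cryptic_peak Summit height of secondary knockout peaks
#'   at cryptic sites.
#' @param hmc_body_scale,k36_body_scale Per-base body mean per
#'   expression-tier unit for the 5hmC and H3K36me3 tracks.
#' @param spurious_body_loss Multiplier on 5hmC/H3K36me3 over
#'   spurious-gene bodies in knockout samples (default 0.3).
#' @param input_rate Uniform per-base mean of the input tracks.
#' @param motif_consensus CpG-containing consensus written at cryptic
#'   sites on the sense strand.
#' @param n_cryptic_range Cryptic sites per spurious gene (range).
#' @param n_replicates Replicates per condition (RNA-seq and CAGE).
#' @param seed Master seed; every generator derives its stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       genes_per_chrom = 50L,
                       exon_count_range = c(5L, 12L),
                       exon_len_range = c(200L, 1000L),
                       intron_len_range = c(200L, 2000L),
                       intergenic_gap = 1000L,
                       max_chrom_len = NULL,
                       fraction_spurious = 0.10,
                       spurious_effect = 4.0,
                       spurious_gain_last = FALSE,
                       expression_log_mean = 3.0,
                       expression_log_sd = 1.0,
                       nb_dispersion = 0.1,
                       library_size = 2e6,
                       cage_canonical_rate = 2.0,
                       cage_cryptic_tags = 30,
                       cage_noise_rate = 1e-4,
                       leaky_control_rate = 0,
                       pser5_peak_height = 0.4,
                       pser5_peak_sd = 150,
                       pser5_body_rate = 0.1,
                       pser5_body_gain = 4,
                       pser5_cryptic_peak = 0.5,
                       hmc_body_scale = 0.08,
                       k36_body_scale = 0.08,
                       spurious_body_loss = 0.3,
                       input_rate = 0.2,
                       motif_consensus = "CCGCCC",
                       n_cryptic_range = c(1L, 3L),
                       n_replicates = 2L,
                       seed = 17L) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  if (cfg$fraction_spurious < 0 || cfg$fraction_spurious >= 1)
    stop("fraction_spurious must be in [0, 1)")
  if (cfg$spurious_effect < 1) stop("spurious_effect must be >= 1")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$cage_cryptic_tags < 0) stop("cage_cryptic_tags must be >= 0")
  for (nm in c("library_size", "cage_canonical_rate", "cage_noise_rate",
               "pser5_peak_height", "pser5_body_rate", "pser5_body_gain",
               "hmc_body_scale", "k36_body_scale", "input_rate"))
    if (cfg[[nm]] <= 0) stop(sprintf("'%s' must be > 0", nm))
  if (!grepl("^[ACGT]+$", cfg$motif_consensus))
    stop("motif_consensus must be a plain ACGT string")
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1")
  structure(cfg, class = "sim_config")
}

# counts sampler shared by the RNA-seq generator: NB with
# variance = mu + dispersion mu^2, Poisson in the dispersion -> 0 limit
nb_sample <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a toy genome with planted spurious genes
#'
#' Builds a multi-chromosome genome (~`genes_per_chrom` genes per
#' chromosome, i.i.d. background sequence with CpG frequency ~0.01),
#' gene models with ordered exons on random strands, log-normal baseline
#' expression with quintile tiers, and — for a planted spurious subset —
#' 1-3 cryptic CTSS positions strictly inside the exon2-to-TES gene
#' body, each carrying the configured CpG motif on the sense strand.
#' Fully deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `spur_sim` with elements `genome`
#'   (`DNAStringSet`), `genes` (named list of `gene_model`), `truth`
#'   (class `truth_table`: `$genes` with `is_spurious`, `tier`,
#'   `expression`; `$cryptic_sites` with genomic positions), `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    n_ex <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], n, TRUE)
    strands <- sample(c("+", "-"), n, TRUE)
    expr <- stats::rlnorm(n, cfg$expression_log_mean, cfg$expression_log_sd)
    tier <- ceiling(rank(expr, ties.method = "first") * 5 / n)
    n_spur <- round(n * cfg$fraction_spurious)
    spur <- logical(n)
    if (n_spur > 0) spur[sample.int(n, n_spur)] <- TRUE
    ex_len <- sample(cfg$exon_len_range[1]:cfg$exon_len_range[2], sum(n_ex), TRUE)
    in_len <- sample(cfg$intron_len_range[1]:cfg$intron_len_range[2],
                     sum(pmax(n_ex - 1L, 0L)), TRUE)
    ex_idx <- rep(seq_len(n), n_ex)
    in_idx <- rep(seq_len(n), pmax(n_ex - 1L, 0L))

    n_chrom <- ceiling(n / cfg$genes_per_chrom)
    chrom_of <- rep(seq_len(n_chrom), each = cfg$genes_per_chrom)[seq_len(n)]
    chrom_names <- sprintf("chr%d", seq_len(n_chrom))
    cursor <- stats::setNames(numeric(n_chrom), chrom_names)

    ids <- sprintf("g%04d", seq_len(n))
    genes <- vector("list", n)
    for (i in seq_len(n)) {
      el <- ex_len[ex_idx == i]
      il <- in_len[in_idx == i]
      span <- sum(el) + sum(il)
      ch <- chrom_names[chrom_of[i]]
      gstart <- cursor[ch] + cfg$intergenic_gap
      if (!is.null(cfg$max_chrom_len) && gstart + span + cfg$intergenic_gap > cfg$max_chrom_len)
        stop(sprintf("sizing error: gene %s (%d bp) exceeds the chromosome budget of %d bp",
                     ids[i], span, cfg$max_chrom_len))
      starts_g <- gstart + cumsum(c(0, head(el, -1L) + il))
      ends_g <- starts_g + el
      cursor[ch] <- gstart + span
      if (strands[i] == "+")
        genes[[i]] <- gene_model(ids[i], ch, "+", starts_g, ends_g)
      else
        genes[[i]] <- gene_model(ids[i], ch, "-", rev(starts_g), rev(ends_g))
    }
    names(genes) <- ids
    chrom_len <- cursor + cfg$intergenic_gap

    # cryptic sites: strictly inside exon2_to_tes, sense strand, with the
    # motif planted so the sense-strand read starts at the CTSS base
    mot <- strsplit(cfg$motif_consensus, "")[[1]]
    mot_rc <- rev(chartr("ACGT", "TGCA", mot))
    L <- length(mot)
    cry <- list()
    for (i in which(spur)) {
      g <- genes[[i]]
      body <- gene_body(g, "exon2_to_tes")
      lo <- body$start + 60
      hi <- body$end - 60 - L
      grid <- seq(lo, hi, by = 150)
      k <- min(sample(cfg$n_cryptic_range[1]:cfg$n_cryptic_range[2], 1L),
               length(grid))
      pos <- sort(sample(grid, k))
      cry[[g$gene_id]] <- data.table::data.table(
        gene_id = g$gene_id, chrom = g$chrom, pos = as.numeric(pos),
        strand = g$strand)
    }
    cryptic <- data.table::rbindlist(cry)
    if (nrow(cryptic) == 0L)
      cryptic <- data.table::data.table(gene_id = character(), chrom = character(),
                                        pos = numeric(), strand = character())

    # background sequence: i.i.d. bases with P(C) = P(G) = 0.1, so the
    # CpG dinucleotide frequency is ~0.01
    seqs <- lapply(chrom_names, function(ch) {
      s <- sample(c("A", "C", "G", "T"), chrom_len[ch], TRUE,
                  prob = c(0.4, 0.1, 0.1, 0.4))
      on_ch <- cryptic[chrom == ch]
      for (j in seq_len(nrow(on_ch))) {
        p <- on_ch$pos[j]
        if (on_ch$strand[j] == "+") s[(p + 1):(p + L)] <- mot
        else s[(p - L + 2):(p + 1)] <- mot_rc
      }
      paste(s, collapse = "")
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- chrom_names

    truth <- structure(list(
      genes = data.table::data.table(
        gene_id = ids, chrom = chrom_names[chrom_of], strand = strands,
        n_exons = n_ex, is_spurious = spur, tier = as.integer(tier),
        expression = expr),
      cryptic_sites = cryptic), class = "truth_table")
    structure(list(genome = genome, genes = genes, truth = truth,
                   config = cfg), class = "spur_sim")
  })
}

#' @export
print.spur_sim <- function(x, ...) {
  cat(sprintf("spur_sim: %d genes on %d chromosome(s), %d spurious, seed %d\n",
              length(x$genes), length(x$genome),
              sum(x$truth$genes$is_spurious), x$config$seed))
  invisible(x)
}

#' Simulate per-exon RNA-seq counts
#'
#' Exon counts are negative binomial with mean
#' `expression * exon_len_kb * depth_factor` (the depth factor scales
#' expected totals to `library_size`) and dispersion `nb_dispersion`.
#' In knockout samples of spurious genes, the means of exons `2..n-1`
#' (optionally `2..n`) are multiplied by `spurious_effect`; exon 1 is
#' never altered.  Per-sample totals are the realized column sums.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()] run on the same config.
#' @return An [exon_count_matrix()] with samples `Ctrl_1..r, KO_1..r`.
#' @export
simulate_rnaseq_counts <- function(config, sim) {
  cfg <- config
  with_seed(cfg$seed + 1L, {
    cnt <- data.table::rbindlist(lapply(sim$genes, function(g) {
      data.table::data.table(gene_id = g$gene_id,
                             exon_index = seq_len(g$n_exons),
                             exon_len = g$exon_ends - g$exon_starts)
    }))
    expr <- sim$truth$genes$expression[match(cnt$gene_id, sim$truth$genes$gene_id)]
    n_per <- sim$truth$genes$n_exons[match(cnt$gene_id, sim$truth$genes$gene_id)]
    base_mu <- expr * cnt$exon_len / 1000
    depth <- cfg$library_size / sum(base_mu)
    spur <- sim$truth$genes$is_spurious[match(cnt$gene_id, sim$truth$genes$gene_id)]
    hi <- if (cfg$spurious_gain_last) n_per else n_per - 1L
    gain_row <- spur & cnt$exon_index >= 2L & cnt$exon_index <= hi
    samples <- data.frame(
      sample = c(paste0("Ctrl_", seq_len(cfg$n_replicates)),
                 paste0("KO_", seq_len(cfg$n_replicates))),
      condition = rep(c("Ctrl", "KO"), each = cfg$n_replicates),
      total_mapped = NA_real_)
    for (i in seq_len(nrow(samples))) {
      mu <- base_mu * depth
      if (samples$condition[i] == "KO") mu[gain_row] <- mu[gain_row] * cfg$spurious_effect
      cnt[[samples$sample[i]]] <- nb_sample(nrow(cnt), mu, cfg$nb_dispersion)
    }
    samples$total_mapped <- vapply(samples$sample, function(s) sum(cnt[[s]]), 0)
    exon_count_matrix(cnt, samples)
  })
}

#' Simulate CAGE CTSS sets
#'
#' Canonical initiation: per gene and sample, Poisson tags (rate
#' `cage_canonical_rate * expression`) at the TSS with +/-2 bp jitter,
#' on the sense strand.  Cryptic initiation: in knockout samples only
#' (unless `leaky_control_rate > 0`), Poisson(`cage_cryptic_tags`) tags
#' at each planted cryptic position.  A uniform single-tag noise floor
#' (`cage_noise_rate` per base per strand) is scattered genome-wide.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @return Named list of [ctss_set()]s (`Ctrl_1..r, KO_1..r`).
#' @export
simulate_cage <- function(config, sim) {
  cfg <- config
  with_seed(cfg$seed + 2L, {
    tg <- sim$truth$genes
    tss <- vapply(sim$genes, `[[`, 0, "tss")[tg$gene_id]
    chrom <- tg$chrom; strand <- tg$strand
    chrom_len <- stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
    total_len <- sum(chrom_len)
    jitter_w <- c(0.05, 0.2, 0.5, 0.2, 0.05)
    samples <- c(paste0("Ctrl_", seq_len(cfg$n_replicates)),
                 paste0("KO_", seq_len(cfg$n_replicates)))
    conds <- rep(c("Ctrl", "KO"), each = cfg$n_replicates)
    out <- vector("list", length(samples))
    names(out) <- samples
    for (si in seq_along(samples)) {
      tot <- stats::rpois(nrow(tg), cfg$cage_canonical_rate * tg$expression)
      offs <- vapply(tot, function(k) stats::rmultinom(1, k, jitter_w)[, 1],
                     integer(5))
      canon <- data.table::data.table(
        chrom = rep(chrom, each = 5L),
        pos = as.numeric(rep(tss, each = 5L) + rep(-2:2, times = nrow(tg))),
        strand = rep(strand, each = 5L),
        tags = as.numeric(offs))
      canon <- canon[tags > 0]
      rate <- if (conds[si] == "KO") cfg$cage_cryptic_tags
              else cfg$cage_cryptic_tags * cfg$leaky_control_rate
      cs <- sim$truth$cryptic_sites
      if (nrow(cs) && rate > 0) {
        ctags <- stats::rpois(nrow(cs), rate)
        cryp <- data.table::data.table(chrom = cs$chrom, pos = cs$pos,
                                       strand = cs$strand, tags = as.numeric(ctags))
        cryp <- cryp[tags > 0]
      } else cryp <- NULL
      n_noise <- stats::rpois(1, cfg$cage_noise_rate * 2 * total_len)
      if (n_noise > 0) {
        nch <- sample(names(chrom_len), n_noise, TRUE, prob = chrom_len)
        noise <- data.table::data.table(
          chrom = nch,
          pos = floor(stats::runif(n_noise) * chrom_len[nch]),
          strand = sample(c("+", "-"), n_noise, TRUE),
          tags = 1)
      } else noise <- NULL
      rec <- data.table::rbindlist(list(canon, cryp, noise))
      out[[si]] <- ctss_set(rec, sample_id = samples[si], condition = conds[si])
    }
    out
  })
}

# build one chip track (integer Poisson counts around a composed mean)
chip_track <- function(what, condition, cfg, sim, seed) {
  tg <- sim$truth$genes
  chrom_len <- stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
  with_seed(seed, {
    vals <- lapply(names(chrom_len), function(ch) {
      len <- chrom_len[[ch]]
      mu <- rep(if (what == "input") cfg$input_rate else 0, len)
      if (what != "input") {
        for (gid in tg$gene_id[tg$chrom == ch]) {
          g <- sim$genes[[gid]]
          row <- tg[gene_id == gid]
          body <- gene_body(g, "exon2_to_tes")
          bidx <- (body$start + 1):body$end
          if (what == "pser5") {
            sdp <- cfg$pser5_peak_sd
            h <- cfg$pser5_peak_height * log1p(row$expression)
            pk <- max(0, g$tss - 4 * sdp):min(len - 1, g$tss + 4 * sdp)
            mu[pk + 1] <- mu[pk + 1] + h * exp(-0.5 * ((pk - g$tss) / sdp)^2)
            rate <- cfg$pser5_body_rate
            if (condition == "KO" && row$is_spurious) {
              rate <- rate * cfg$pser5_body_gain
              cs <- sim$truth$cryptic_sites[gene_id == gid]
              for (p in cs$pos) {
                ck <- max(0, p - 4 * sdp):min(len - 1, p + 4 * sdp)
                mu[ck + 1] <- mu[ck + 1] +
                  cfg$pser5_cryptic_peak * exp(-0.5 * ((ck - p) / sdp)^2)
              }
            }
            mu[bidx] <- mu[bidx] + rate
          } else {
            scale <- if (what == "hmc") cfg$hmc_body_scale else cfg$k36_body_scale
            rate <- scale * row$tier
            if (condition == "KO" && row$is_spurious)
              rate <- rate * cfg$spurious_body_loss
            mu[bidx] <- mu[bidx] + rate
          }
        }
      }
      as.numeric(stats::rpois(len, mu))
    })
    names(vals) <- names(chrom_len)
    tr <- signal_track(vals)
    attr(tr, "track_id") <- paste0(what, "_", tolower(condition))
    tr
  })
}

#' Simulate ChIP-style coverage tracks
#'
#' Pol II pSer5: Gaussian TSS peak (height scaling with log expression)
#' plus a low gene-body plateau; in knockout samples, spurious genes
#' gain secondary peaks at their cryptic sites and a
#' `pser5_body_gain`-fold elevated plateau.  H3K36me3 and 5hmC:
#' body-wide signal proportional to the expression tier, multiplied by
#' `spurious_body_loss` over spurious-gene bodies in the knockout.
#' Input: uniform Poisson noise at `input_rate`.  All tracks are
#' non-negative integer counts; each track draws from its own derived
#' seed, so any subset of tracks is reproducible.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @param tracks Which track families to generate: any of `"pser5"`,
#'   `"input"`, `"h3k36me3"`, `"hmc"`.
#' @return Named list of `signal_track`s
#'   (`<family>_ctrl`, `<family>_ko`).
#' @export
simulate_chip <- function(config, sim,
                          tracks = c("pser5", "input", "h3k36me3", "hmc")) {
  tracks <- match.arg(tracks, several.ok = TRUE)
  cfg <- config
  fam_seed <- c(pser5 = 31L, input = 33L, h3k36me3 = 35L, hmc = 37L)
  out <- list()
  for (fam in tracks) {
    for (cond in c("Ctrl", "KO")) {
      off <- fam_seed[[fam]] + (cond == "KO")
      out[[paste0(fam, "_", tolower(cond))]] <-
        chip_track(fam, cond, cfg, sim, seed = cfg$seed + off)
    }
  }
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Writes `genome.fa`, `genes.gtf`, `exon_counts.tsv`, `samples.tsv`,
#' one `ctss_<sample>.bed` per CAGE sample, one `<track>.bedgraph` per
#' ChIP track, `truth.json`, and `config.json` (the full configuration,
#' for provenance).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param tracks Track families passed to [simulate_chip()].
#' @return `dir`, invisibly.
#' @export
simulate_dataset <- function(config, dir,
                             tracks = c("pser5", "input", "h3k36me3", "hmc")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$genes, file.path(dir, "genes.gtf"))
  mat <- simulate_rnaseq_counts(config, sim)
  data.table::fwrite(mat$counts, file.path(dir, "exon_counts.tsv"), sep = "\t")
  data.table::fwrite(mat$samples, file.path(dir, "samples.tsv"), sep = "\t")
  cage <- simulate_cage(config, sim)
  for (nm in names(cage))
    write_ctss_bed(cage[[nm]], file.path(dir, sprintf("ctss_%s.bed", nm)))
  chip <- simulate_chip(config, sim, tracks)
  for (nm in names(chip))
    write_bedgraph(chip[[nm]], file.path(dir, sprintf("%s.bedgraph", nm)))
  jsonlite::write_json(
    list(genes = sim$truth$genes, cryptic_sites = sim$truth$cryptic_sites),
    file.path(dir, "truth.json"), dataframe = "columns", digits = NA)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
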