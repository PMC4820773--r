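# Synthetic data with the statistical structure the analyses assume:
# references with known exon structure, capture counts with per-probe
# efficiencies, and family/population genotypes with optional collapsed
# paralogs and null alleles. Every simulator is a pure function of its
# arguments and seed.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the motivating experiment:
#' a panel of 248 probes in 24 individuals, circa 6.4e5 read pairs per
#' sample, 22.7% off-target reads before rebalancing (62.7% after), 5.6%
#' probe dropout, and log10 capture efficiencies spread with SD 0.5.
#'
#' @param n_genes Number of genes in the synthetic reference.
#' @param exon_meanlog,exon_sdlog Log-normal exon length parameters
#'   (defaults: median 250 bp, sdlog 0.45).
#' @param intron_meanlog,intron_sdlog Log-normal intron length parameters
#'   (median 300 bp).
#' @param mutation_rate Per-base substitution rate applied to transcripts
#'   relative to the gene models, emulating ortholog divergence
#'   (default 0.05).
#' @param n_mips Panel size.
#' @param n_samples Individuals per capture experiment.
#' @param reads_per_sample Read pairs per sample.
#' @param efficiency_sdlog10 SD of log10 per-probe capture efficiency.
#' @param off_target_fraction Fraction of reads off target (0.227 for an
#'   equimolar pool; 0.627 after rebalancing).
#' @param dropout_prob Probability a probe yields no reads at all.
#' @param sigma_sample SD (log scale) of the per-sample jitter on probe
#'   weights.
#' @param probe_excess Probe-to-target molar excess (documentation only;
#'   does not enter the count model).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 248, exon_meanlog = log(250), exon_sdlog = 0.45,
                       intron_meanlog = log(300), intron_sdlog = 0.5,
                       mutation_rate = 0.05,
                       n_mips = 248, n_samples = 24, reads_per_sample = 6.4e5,
                       efficiency_sdlog10 = 0.5,
                       off_target_fraction = 0.227, dropout_prob = 0.056,
                       sigma_sample = 0.15, probe_excess = 1000, seed = 1) {
  stopifnot(n_genes >= 1, off_target_fraction >= 0, off_target_fraction <= 1,
            dropout_prob >= 0, dropout_prob <= 1, efficiency_sdlog10 > 0,
            reads_per_sample >= 0, mutation_rate >= 0, mutation_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Simulate a genome, gene models and transcripts
#'
#' Each gene gets 1-10 exons (binomial around a mean of 5) with log-normal
#' lengths, separated by log-normal introns, placed on its own contig with
#' short flanks; half the genes sit on the minus strand. Transcripts are the
#' exact exon concatenations, so the true exon boundaries (cumulative exon
#' lengths) are known. The gene models receive `mutation_rate` substitutions
#' relative to the genome/transcripts, emulating an ortholog annotation from
#' a diverged relative (model coordinates still index the study genome, as
#' a projected annotation).
#'
#' @param cfg A [sim_config()].
#' @return List: `genome` (`DNAStringSet`), `models` (`gene_model_set`),
#'   `transcripts` (`DNAStringSet`), and `truth` with per-gene exon lengths
#'   and true transcript boundaries.
#' @export
simulate_reference <- function(cfg) {
  with_seed(cfg$seed, {
    chroms <- list(); rows <- list(); tx <- character(); truth <- list()
    for (g in seq_len(cfg$n_genes)) {
      gid <- sprintf("gene%03d", g)
      n_ex <- 1L + stats::rbinom(1L, 9L, 4 / 9)
      ex_len <- pmax(60L, round(stats::rlnorm(n_ex, cfg$exon_meanlog, cfg$exon_sdlog)))
      in_len <- if (n_ex > 1L) {
        pmax(40L, round(stats::rlnorm(n_ex - 1L, cfg$intron_meanlog, cfg$intron_sdlog)))
      } else integer(0)
      exon_seqs <- vapply(ex_len, rand_dna, character(1))
      introns <- vapply(in_len, rand_dna, character(1))
      flank5 <- rand_dna(100L); flank3 <- rand_dna(100L)
      body <- exon_seqs[1]
      starts <- integer(n_ex); starts[1] <- 100L
      if (n_ex > 1L) {
        for (i in 2:n_ex) {
          body <- paste0(body, introns[i - 1L], exon_seqs[i])
          starts[i] <- starts[i - 1L] + ex_len[i - 1L] + in_len[i - 1L]
        }
      }
      plus_chrom <- paste0(flank5, body, flank3)
      strand <- sample(c("+", "-"), 1L)
      chrom_len <- nchar(plus_chrom)
      if (strand == "+") {
        chroms[[gid]] <- plus_chrom
        coord <- data.frame(start = starts, end = starts + ex_len)
      } else {
        chroms[[gid]] <- revcomp(plus_chrom)
        coord <- data.frame(start = chrom_len - (starts + ex_len),
                            end = chrom_len - starts)
        coord <- coord[order(coord$start), , drop = FALSE]
      }
      rows[[gid]] <- data.frame(gene = gid, chrom = gid, start = coord$start,
                                end = coord$end, strand = strand,
                                stringsAsFactors = FALSE)
      tx[paste0("tx_", gid)] <- paste(exon_seqs, collapse = "")
      truth[[gid]] <- list(exon_lengths = ex_len,
                           boundaries = cumsum(ex_len)[-n_ex])
    }
    genome <- Biostrings::DNAStringSet(unlist(chroms))
    models <- build_gene_models(do.call(rbind, rows), genome)
    for (g in names(models)) {
      models[[g]]$exons <- vapply(models[[g]]$exons, mutate_dna, character(1),
                                  rate = cfg$mutation_rate, USE.NAMES = FALSE)
    }
    list(genome = genome, models = models,
         transcripts = Biostrings::DNAStringSet(tx), truth = truth)
  })
}

#' Write a gene model set as GFF3
#'
#' Emits one `gene` and its `exon` features per gene (1-based closed
#' coordinates, `gene_id` attribute), the inverse of [load_gene_models()].
#'
#' @param models A `gene_model_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (g in names(models)) {
    co <- models[[g]]$coords
    lo <- min(co$start); hi <- max(co$end)
    lines <- c(lines, paste(co$chrom[1], "mipkit", "gene", lo + 1L, hi,
                            ".", co$strand[1], ".", paste0("ID=", g),
                            sep = "\t"))
    for (i in seq_len(nrow(co))) {
      lines <- c(lines, paste(co$chrom[i], "mipkit", "exon",
                              co$start[i] + 1L, co$end[i], ".",
                              co$strand[i], ".",
                              paste0("ID=", g, ".e", i, ";Parent=", g,
                                     ";gene_id=", g),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a capture experiment's read counts
#'
#' Per sample, the on-target read total is binomial with success probability
#' `1 - off_target_fraction`; on-target reads are apportioned to probes by a
#' multinomial whose weights are `efficiency x concentration_factor`,
#' jittered by a per-sample log-normal effect. Dropout probes get weight 0
#' in every sample.
#'
#' @param efficiencies Positive per-probe capture efficiencies (named, or
#'   names `M001...` are generated).
#' @param concentration_factors Per-probe pool concentration multipliers
#'   (default all 1).
#' @param n_samples Number of samples.
#' @param reads_per_sample Total reads per sample.
#' @param off_target_fraction Expected off-target read fraction.
#' @param dropout_prob Probability each probe is a total dropout.
#' @param sigma_sample SD of the log-normal per-sample weight jitter.
#' @param seed Integer seed.
#' @return A [count_matrix()] with per-sample `off_target` counts; the
#'   dropout set is attached as `attr(, "dropout")`.
#' @export
simulate_capture <- function(efficiencies, concentration_factors = NULL,
                             n_samples = 24, reads_per_sample = 6.4e5,
                             off_target_fraction = 0.227, dropout_prob = 0.056,
                             sigma_sample = 0.15, seed = 1) {
  if (any(efficiencies < 0)) stop("negative efficiency")
  n <- length(efficiencies)
  if (is.null(names(efficiencies))) {
    names(efficiencies) <- sprintf("M%03d", seq_len(n))
  }
  if (is.null(concentration_factors)) concentration_factors <- rep(1, n)
  stopifnot(length(concentration_factors) == n, reads_per_sample >= 0)
  with_seed(seed, {
    dropped <- stats::runif(n) < dropout_prob
    w_base <- efficiencies * concentration_factors
    w_base[dropped] <- 0
    counts <- matrix(0, n, n_samples,
                     dimnames = list(names(efficiencies),
                                     sprintf("S%02d", seq_len(n_samples))))
    off <- numeric(n_samples)
    for (s in seq_len(n_samples)) {
      on_total <- stats::rbinom(1L, reads_per_sample, 1 - off_target_fraction)
      off[s] <- reads_per_sample - on_total
      w <- w_base * stats::rlnorm(n, 0, sigma_sample)
      counts[, s] <- stats::rmultinom(1L, on_total, w)
    }
    out <- count_matrix(counts, stats::setNames(off, colnames(counts)))
    attr(out, "dropout") <- names(efficiencies)[dropped]
    out
  })
}

# collapse two biallelic genotypes (allele-index strings) as if the two
# loci mapped to one marker: report hom only when both loci are hom for
# the same allele class
collapse_paralog <- function(g1, g2) {
  both <- c(strsplit(g1, "/")[[1]], strsplit(g2, "/")[[1]])
  u <- sort(unique(both))
  if (length(u) == 1L) paste(u, u, sep = "/") else paste(u[1], u[2], sep = "/")
}

drop_null_allele <- function(g, f_null) {
  al <- strsplit(g, "/")[[1]]
  if (al[1] != al[2] && stats::runif(1) < f_null) {
    keep <- sample(al, 1L)
    paste(keep, keep, sep = "/")
  } else g
}

draw_dp_gq <- function(n, miss_frac, dp_mean = 100) {
  fail <- stats::runif(n) < miss_frac
  dp <- ifelse(fail & stats::runif(n) < 0.5,
               sample(0:15, n, replace = TRUE),
               16L + stats::rpois(n, dp_mean - 16))
  gq <- ifelse(fail & dp >= 16,
               sample(0:29, n, replace = TRUE),
               sample(60:99, n, replace = TRUE))
  list(dp = dp, gq = gq)
}

#' Simulate an intercross family at diagnostic sites
#'
#' Both parents are heterozygous at every diagnostic site (an F1 intercross
#' between alternative homozygotes); offspring genotypes are drawn 1:2:1
#' per site. Markers in `paralog_markers` are generated as the superposition
#' of two independent loci whose allele union is reported (inflating
#' heterozygotes and distorting segregation); markers in
#' `null_allele_markers` drop one allele of a heterozygote with probability
#' `f_null`, so it reports as a homozygote. DP and GQ are drawn so that a
#' fraction `miss_frac` of calls fails the DP/GQ missingness filters.
#'
#' @param n_markers Number of markers.
#' @param sites_per_marker Diagnostic sites per marker (default 7).
#' @param n_offspring Number of offspring (default 21).
#' @param paralog_markers,null_allele_markers Marker names (or indices)
#'   simulated with collapsed-paralog / null-allele contamination.
#' @param f_null Per-call allele-drop probability for null-allele markers.
#' @param miss_frac Fraction of calls drawn to fail the DP<16 / GQ<30
#'   filters (default 0).
#' @param seed Integer seed.
#' @param marker_ids Optional explicit marker names (length `n_markers`).
#' @return List: `genotypes` (a [genotype_table()]), `design` (a
#'   [study_design()]: 2 parents + offspring), `truth` (contamination sets).
#' @export
simulate_family <- function(n_markers, sites_per_marker = 7, n_offspring = 21,
                            paralog_markers = character(0),
                            null_allele_markers = character(0),
                            f_null = 0.5, miss_frac = 0, seed = 1,
                            marker_ids = NULL) {
  stopifnot(n_offspring >= 1, n_markers >= 1)
  markers <- if (is.null(marker_ids)) sprintf("M%03d", seq_len(n_markers)) else marker_ids
  stopifnot(length(markers) == n_markers)
  paralog_markers <- if (is.numeric(paralog_markers)) markers[paralog_markers] else paralog_markers
  null_allele_markers <- if (is.numeric(null_allele_markers)) markers[null_allele_markers] else null_allele_markers
  samples <- c("P1", "P2", sprintf("O%02d", seq_len(n_offspring)))
  with_seed(seed, {
    sites <- do.call(rbind, lapply(markers, function(m) {
      pos <- sort(sample.int(112L, sites_per_marker)) - 1L
      data.frame(marker = m, pos = pos, ref = "A", alt = "T",
                 stringsAsFactors = FALSE)
    }))
    gt <- matrix(NA_character_, nrow(sites), length(samples),
                 dimnames = list(NULL, samples))
    draw_clean <- function() {
      sample(c("0/0", "0/1", "1/1"), 1L, prob = c(0.25, 0.5, 0.25))
    }
    for (i in seq_len(nrow(sites))) {
      m <- sites$marker[i]
      is_par <- m %in% paralog_markers
      is_null <- m %in% null_allele_markers
      gt[i, "P1"] <- "0/1"; gt[i, "P2"] <- "0/1"
      for (o in seq_len(n_offspring)) {
        g <- if (is_par) collapse_paralog(draw_clean(), draw_clean()) else draw_clean()
        if (is_null) g <- drop_null_allele(g, f_null)
        gt[i, 2L + o] <- g
      }
      if (is_null) {
        gt[i, "P1"] <- drop_null_allele(gt[i, "P1"], f_null)
        gt[i, "P2"] <- drop_null_allele(gt[i, "P2"], f_null)
      }
    }
    qual <- draw_dp_gq(length(gt), miss_frac)
    gtab <- genotype_table(sites, samples, gt,
                           matrix(qual$dp, nrow(sites)),
                           matrix(qual$gq, nrow(sites)))
    design <- study_design(data.frame(
      sample_id = samples,
      role = c("parent", "parent", rep("offspring", n_offspring)),
      group = "", stringsAsFactors = FALSE))
    list(genotypes = gtab, design = design,
         truth = list(paralog = paralog_markers, null_allele = null_allele_markers))
  })
}

#' Simulate population genotypes under inbreeding
#'
#' Genotype probabilities are `(p^2 + Fpq, 2pq(1-F), q^2 + Fpq)` for the
#' reference homozygote, heterozygote and alternate homozygote, where `p`
#' is the per-site reference allele frequency. Collapsed-paralog and
#' null-allele contamination are modeled as in [simulate_family()].
#'
#' @param sites data.frame with columns `marker`, `pos`, `p` (reference
#'   allele frequency in `(0,1)`).
#' @param n_individuals Individuals to draw (>= 2).
#' @param inbreeding_f Inbreeding coefficient `F` in `[0, 1)`.
#' @param paralog_markers,null_allele_markers Contaminated marker names.
#' @param f_null Allele-drop probability for null-allele markers.
#' @param pop_name Population label used in the returned design.
#' @param sample_prefix Prefix for generated sample ids.
#' @param miss_frac Fraction of calls failing DP/GQ filters.
#' @param seed Integer seed.
#' @return List: `genotypes`, `design` (population roles), `truth`.
#' @export
simulate_population <- function(sites, n_individuals = 18, inbreeding_f = 0,
                                paralog_markers = character(0),
                                null_allele_markers = character(0),
                                f_null = 0.5, pop_name = "pop1",
                                sample_prefix = pop_name, miss_frac = 0,
                                seed = 1) {
  stopifnot(all(sites$p > 0), all(sites$p < 1), n_individuals >= 2)
  if (inbreeding_f < 0 || inbreeding_f >= 1) stop("F must lie in [0, 1)")
  samples <- sprintf("%s_%02d", sample_prefix, seq_len(n_individuals))
  with_seed(seed, {
    gt <- matrix(NA_character_, nrow(sites), n_individuals,
                 dimnames = list(NULL, samples))
    for (i in seq_len(nrow(sites))) {
      p <- sites$p[i]; q <- 1 - p; f <- inbreeding_f
      probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
      draw <- function() sample(c("0/0", "0/1", "1/1"), 1L, prob = probs)
      m <- sites$marker[i]
      is_par <- m %in% paralog_markers
      is_null <- m %in% null_allele_markers
      for (s in seq_len(n_individuals)) {
        g <- if (is_par) collapse_paralog(draw(), draw()) else draw()
        if (is_null) g <- drop_null_allele(g, f_null)
        gt[i, s] <- g
      }
    }
    site_df <- data.frame(marker = sites$marker, pos = sites$pos,
                          ref = "A", alt = "T", stringsAsFactors = FALSE)
    qual <- draw_dp_gq(length(gt), miss_frac)
    gtab <- genotype_table(site_df, samples, gt,
                           matrix(qual$dp, nrow(site_df)),
                           matrix(qual$gq, nrow(site_df)))
    design <- study_design(data.frame(sample_id = samples, role = "population",
                                      group = pop_name, stringsAsFactors = FALSE))
    list(genotypes = gtab, design = design,
         truth = list(paralog = paralog_markers, null_allele = null_allele_markers))
  })
}

#' Simulate replicate genotyping of existing samples
#'
#' Re-genotypes the chosen samples with an independent per-call error: with
#' probability `error_rate` a call is replaced by one of the other two
#' biallelic genotypes. Replicate columns are appended as
#' `<sample>_rep`, and the corresponding `replicate` design rows returned.
#'
#' @param gt A biallelic [genotype_table()].
#' @param samples Samples to replicate.
#' @param error_rate Per-call genotyping error probability applied to the
#'   replicate side (default 0.0055; with the both-hom-ref exclusion this
#'   puts the non-reference discrepancy rate of simulated replicates near
#'   0.008 at intermediate allele frequencies, i.e. >99% concordance).
#' @param seed Integer seed.
#' @return List: `genotypes` (original plus replicate columns), `design`
#'   (a [study_design()] fragment with `replicate` roles).
#' @export
simulate_replicates <- function(gt, samples, error_rate = 0.0055, seed = 1) {
  stopifnot(all(samples %in% gt$samples))
  with_seed(seed, {
    reps <- paste0(samples, "_rep")
    new_gt <- gt$gt[, samples, drop = FALSE]
    cats <- c("0/0", "0/1", "1/1")
    flip <- matrix(stats::runif(length(new_gt)) < error_rate, nrow(new_gt))
    for (i in which(flip & !is.na(new_gt))) {
      new_gt[i] <- sample(setdiff(cats, new_gt[i]), 1L)
    }
    colnames(new_gt) <- reps
    combined <- genotype_table(gt$sites, c(gt$samples, reps),
                               cbind(gt$gt, new_gt),
                               cbind(gt$dp, gt$dp[, samples, drop = FALSE]),
                               cbind(gt$gq, gt$gq[, samples, drop = FALSE]))
    # raw design rows: a bare replicate fragment cannot be validated alone
    # (its group column references samples outside the fragment)
    design <- data.frame(sample_id = reps, role = "replicate",
                         group = samples, stringsAsFactors = FALSE)
    list(genotypes = combined, design = design)
  })
}

#' Combine genotype tables over the same sites
#'
#' Column-binds samples of several genotype tables that share an identical
#' site table (e.g. populations simulated per-population).
#'
#' @param ... `genotype_table` objects.
#' @return A single `genotype_table`.
#' @export
combine_genotype_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  base <- tabs[[1]]
  for (t in tabs[-1]) {
    if (!identical(base$sites, t$sites)) stop("site tables differ")
  }
  genotype_table(base$sites,
                 unlist(lapply(tabs, `[[`, "samples")),
                 do.call(cbind, lapply(tabs, `[[`, "gt")),
                 do.call(cbind, lapply(tabs, `[[`, "dp")),
                 do.call(cbind, lapply(tabs, `[[`, "gq")))
}
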