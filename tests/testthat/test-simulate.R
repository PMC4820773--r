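test_that("reference simulation is deterministic and structurally sound", {
  cfg <- sim_config(n_genes = 4, seed = 3)
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.character(a$transcripts), as.character(b$transcripts))
  # transcripts are exact exon concatenations of the genome genes
  gm <- build_gene_models(do.call(rbind, lapply(names(a$models), function(g) {
    co <- a$models[[g]]$coords
    data.frame(gene = g, chrom = co$chrom, start = co$start, end = co$end,
               strand = co$strand)
  })), a$genome)
  for (g in names(gm)) {
    expect_identical(paste(gm[[g]]$exons, collapse = ""),
                     as.character(a$transcripts[[paste0("tx_", g)]]))
  }
  # mutation rate 0 leaves models identical to the genome exons
  c0 <- simulate_reference(sim_config(n_genes = 3, mutation_rate = 0, seed = 5))
  for (g in names(c0$models)) {
    expect_identical(paste(c0$models[[g]]$exons, collapse = ""),
                     as.character(c0$transcripts[[paste0("tx_", g)]]))
  }
})

test_that("exon counts fluctuate around the binomial mean", {
  cfg <- sim_config(n_genes = 100, seed = 31)
  ref <- simulate_reference(cfg)
  total <- sum(vapply(ref$truth, function(t) length(t$exon_lengths), integer(1)))
  # n_exons - 1 ~ Binomial(9, 4/9) per gene: mean 500, sd = sqrt(100*9*(4/9)*(5/9))
  expect_lt(abs(total - 500), 4 * sqrt(100 * 9 * (4 / 9) * (5 / 9)))
})

test_that("capture counts follow the multinomial mean structure", {
  # single probe, no dropout, no off-target: FMR is exactly 1
  cm <- simulate_capture(c(M1 = 2), n_samples = 4, reads_per_sample = 1000,
                         off_target_fraction = 0, dropout_prob = 0, seed = 2)
  expect_true(all(compute_fmr(cm)$fmr == 1))

  # doubling a concentration factor doubles that probe's relative weight
  eff <- rep(1, 4)
  tot1 <- tot2 <- 0
  for (s in 1:60) {
    c1 <- simulate_capture(eff, rep(1, 4), n_samples = 1,
                           reads_per_sample = 2e4, off_target_fraction = 0,
                           dropout_prob = 0, sigma_sample = 0, seed = s)
    c2 <- simulate_capture(eff, c(2, 1, 1, 1), n_samples = 1,
                           reads_per_sample = 2e4, off_target_fraction = 0,
                           dropout_prob = 0, sigma_sample = 0, seed = 1000 + s)
    tot1 <- tot1 + compute_fmr(c1)$fmr[1, 1]
    tot2 <- tot2 + compute_fmr(c2)$fmr[1, 1]
  }
  # expected FMR: 1/4 -> 2/5
  expect_equal(tot1 / 60, 0.25, tolerance = 0.05)
  expect_equal(tot2 / 60, 0.4, tolerance = 0.05)
  expect_error(simulate_capture(c(-1, 1), seed = 1), "negative")
})

test_that("capture marginal means match the analytic multinomial expectation", {
  eff <- c(4, 2, 1, 1)
  p_exp <- eff / sum(eff)
  reps <- 100
  fmr_acc <- matrix(0, 4, reps)
  for (s in seq_len(reps)) {
    cm <- simulate_capture(eff, n_samples = 1, reads_per_sample = 1e4,
                           off_target_fraction = 0.2, dropout_prob = 0,
                           sigma_sample = 0, seed = s)
    fmr_acc[, s] <- compute_fmr(cm)$fmr[, 1]
  }
  est <- rowMeans(fmr_acc)
  se <- apply(fmr_acc, 1, stats::sd) / sqrt(reps)
  expect_true(all(abs(est - p_exp) < 3 * pmax(se, 1e-6)))
})

test_that("family simulation respects parental heterozygosity and limits", {
  fam <- simulate_family(4, sites_per_marker = 3, n_offspring = 21, seed = 9)
  gt <- fam$genotypes
  expect_true(all(gt$gt[, c("P1", "P2")] == "0/1"))
  expect_equal(length(fam$design$sample_id), 23L)
  expect_false(any(is.na(gt$gt)))

  # f_null = 1 removes every heterozygote at affected markers
  fam2 <- simulate_family(2, null_allele_markers = 1, f_null = 1, seed = 10)
  m1 <- fam2$genotypes$sites$marker == "M001"
  expect_false(any(fam2$genotypes$gt[m1, ] == "0/1"))
  expect_true(any(fam2$genotypes$gt[!m1, ] == "0/1"))

  # paralog superposition inflates heterozygotes (expected 7/8 vs 1/2)
  fam3 <- simulate_family(2, paralog_markers = 1, n_offspring = 50,
                          sites_per_marker = 10, seed = 11)
  m1 <- fam3$genotypes$sites$marker == "M001"
  off <- sprintf("O%02d", 1:50)
  het_par <- mean(fam3$genotypes$gt[m1, off] == "0/1")
  het_clean <- mean(fam3$genotypes$gt[!m1, off] == "0/1")
  expect_gt(het_par, het_clean + 0.2)
})

test_that("population genotypes follow the inbreeding model", {
  sites <- data.frame(marker = "M1", pos = 0L, p = 0.5)
  pop <- simulate_population(sites, n_individuals = 5000, inbreeding_f = 0,
                             seed = 21)
  het <- mean(pop$genotypes$gt == "0/1")
  expect_lt(abs(het - 0.5), 4 * sqrt(0.25 / 5000))
  # F -> 1 limit: about (1-F) * 2pq heterozygotes
  pop2 <- simulate_population(sites, n_individuals = 2000,
                              inbreeding_f = 0.999, seed = 22)
  expect_lt(mean(pop2$genotypes$gt == "0/1"), 0.01)
  expect_error(simulate_population(sites, inbreeding_f = 1, seed = 1), "F must")
  expect_error(simulate_population(data.frame(marker = "M", pos = 0, p = 0),
                                   seed = 1))
})

test_that("collapsed paralogs exceed Hardy-Weinberg heterozygosity", {
  sites <- data.frame(marker = rep(c("par", "clean"), each = 4),
                      pos = rep(0:3, 2), p = 0.5)
  excess <- replicate(20, NA_real_)
  for (s in seq_len(20)) {
    pop <- simulate_population(sites, n_individuals = 50,
                               paralog_markers = "par", seed = 100 + s)
    par_rows <- pop$genotypes$sites$marker == "par"
    excess[s] <- mean(pop$genotypes$gt[par_rows, ] == "0/1") -
      mean(pop$genotypes$gt[!par_rows, ] == "0/1")
  }
  expect_gt(mean(excess), 0.2)
})

test_that("simulators are pure functions of their seeds", {
  f1 <- simulate_family(3, seed = 77)
  f2 <- simulate_family(3, seed = 77)
  expect_identical(f1$genotypes$gt, f2$genotypes$gt)
  s <- data.frame(marker = "M", pos = 0L, p = 0.4)
  p1 <- simulate_population(s, seed = 78)
  p2 <- simulate_population(s, seed = 78)
  expect_identical(p1$genotypes$gt, p2$genotypes$gt)
  c1 <- simulate_capture(1:3, seed = 79)
  c2 <- simulate_capture(1:3, seed = 79)
  expect_identical(c1$counts, c2$counts)
})

test_that("replicate simulation plants the requested discordance", {
  sites <- data.frame(marker = rep("M1", 50), pos = 0:49, p = 0.5)
  pop <- simulate_population(sites, n_individuals = 6, seed = 41)
  reps <- simulate_replicates(pop$genotypes, pop$genotypes$samples[1:3],
                              error_rate = 0, seed = 42)
  nr <- nrd(reps$genotypes,
            data.frame(sample_a = pop$genotypes$samples[1:3],
                       sample_b = paste0(pop$genotypes$samples[1:3], "_rep")))
  expect_equal(nr$pooled, 0)
  expect_identical(reps$design$role, rep("replicate", 3))
})
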