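test_that("DP/GQ filters mask exactly the failing calls", {
  gt <- make_gt("M1", matrix(c("0/1", "0/1", "0/1", "0/1"), 1,
                             dimnames = list(NULL, c("a", "b", "c", "d"))),
                dp = matrix(c(15, 16, 40, NA), 1),
                gq = matrix(c(99, 30, 29, NA), 1))
  filt <- apply_genotype_filters(gt)
  expect_true(is.na(filt$gt[1, "a"]))   # DP 15 < 16
  expect_identical(filt$gt[1, "b"], "0/1")  # DP 16, GQ 30: boundary passes
  expect_true(is.na(filt$gt[1, "c"]))   # GQ 29 < 30
  expect_identical(filt$gt[1, "d"], "0/1")  # absent annotations pass
  expect_equal(attr(filt, "n_masked"), 2L)
  strict <- apply_genotype_filters(gt, absent = "fail")
  expect_true(is.na(strict$gt[1, "d"]))
})

test_that("expected segregation follows Mendel for every parental cross", {
  hh <- expected_segregation("0/1", "0/1")
  expect_equal(hh$prob[match(c("0/0", "0/1", "1/1"), hh$genotype)],
               c(0.25, 0.5, 0.25))
  ha <- expected_segregation("0/1", "0/0")
  expect_equal(ha$prob[match(c("0/0", "0/1"), ha$genotype)], c(0.5, 0.5))
  aa_bb <- expected_segregation("0/0", "1/1")
  expect_equal(aa_bb$genotype, "0/1")
  expect_equal(aa_bb$prob, 1)
  expect_null(expected_segregation("0/0", "0/0"))  # monomorphic
  expect_null(expected_segregation(NA, "0/1"))     # untestable
})

test_that("exact multinomial test equals brute-force enumeration", {
  expect_equal(exact_multinomial_test(c(1, 1), c(0.5, 0.5)), 1)
  expect_equal(exact_multinomial_test(c(0, 21), c(0.5, 0.5)), 2 * 0.5^21)

  # the Mendelian case: all 253 outcomes of 21 offspring in 3 classes
  p_pkg <- exact_multinomial_test(c(0, 21, 0), c(0.25, 0.5, 0.25))
  p_orc <- oracle_multinomial_p(c(0, 21, 0), c(0.25, 0.5, 0.25))
  expect_equal(p_pkg, p_orc, tolerance = 1e-12)

  withr::with_seed(17, {
    for (i in 1:20) {
      k <- sample(2:3, 1)
      probs <- as.numeric(rmultinom(1, 40, rep(1, k))) + 1
      probs <- probs / sum(probs)
      n <- sample(5:25, 1)
      obs <- as.numeric(rmultinom(1, n, probs))
      expect_equal(exact_multinomial_test(obs, probs),
                   oracle_multinomial_p(obs, probs), tolerance = 1e-10)
    }
  })

  # positive count in a zero-probability cell
  p0 <- exact_multinomial_test(c(2, 3, 1), c(0.5, 0.5, 0))
  expect_equal(as.numeric(p0), 0)
  expect_true(attr(p0, "impossible_cell"))
  expect_error(exact_multinomial_test(c(1, 1), c(0.5, 0.5, 0)), "length")
})

test_that("family paralog flags respect missingness and thresholds", {
  off <- sprintf("O%02d", 1:10)
  samples <- c("P1", "P2", off)
  # marker A: clean het x het; marker B: one missing offspring call
  gts <- rbind(c("0/1", "0/1", rep(c("0/0", "0/1", "1/1"), c(3, 5, 2))),
               c("0/1", "0/1", rep("0/1", 9), NA))
  gt <- make_gt(c("A", "B"), matrix(gts, 2, dimnames = list(NULL, samples)))
  res <- flag_paralogs_family(gt, family_design(10))
  expect_identical(res$status[res$marker == "A"], "tested")
  expect_identical(res$status[res$marker == "B"], "untested_missing")
  expect_false(res$paralog_family[res$marker == "A"])

  # all-heterozygote offspring from het x het is a paralog signature
  gt2 <- make_gt("C", matrix(c("0/1", "0/1", rep("0/1", 21)), 1,
                             dimnames = list(NULL, c("P1", "P2",
                                                     sprintf("O%02d", 1:21)))))
  res2 <- flag_paralogs_family(gt2, family_design(21))
  expect_true(res2$paralog_family)
  expect_true(res2$zero_class)
  expect_equal(res2$p_min, oracle_multinomial_p(c(0, 21, 0), c(.25, .5, .25)),
               tolerance = 1e-12)

  # identical homozygous parents leave nothing to test
  gt3 <- make_gt("D", matrix(rep("0/0", 12), 1,
                             dimnames = list(NULL, c("P1", "P2",
                                                     sprintf("O%02d", 1:10)))))
  expect_identical(flag_paralogs_family(gt3, family_design(10))$status,
                   "monomorphic")
})

test_that("paralog simulations are flagged far more often than clean markers", {
  flags <- matrix(NA, 40, 2)
  for (s in seq_len(40)) {
    fam <- simulate_family(2, sites_per_marker = 3, n_offspring = 21,
                           paralog_markers = 2, seed = 300 + s)
    res <- flag_paralogs_family(fam$genotypes, fam$design)
    flags[s, ] <- res$paralog_family[match(c("M001", "M002"), res$marker)]
  }
  clean_rate <- mean(flags[, 1])
  paralog_rate <- mean(flags[, 2])
  expect_gt(paralog_rate, clean_rate + 0.3)
  expect_gt(paralog_rate, 0.5)
})

test_that("HWE exact distribution matches combinatorial pairing enumeration", {
  res <- hwe_exact(1, 0, 1)
  expect_equal(res$distribution$prob, c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(res$p_excess, 1)
  expect_equal(res$p_deficit, 1 / 3)

  withr::with_seed(23, {
    for (i in 1:15) {
      n <- sample(3:8, 1)
      nAA <- sample(0:n, 1); rest <- n - nAA
      nAa <- sample(0:rest, 1); naa <- rest - nAa
      nA <- 2 * nAA + nAa; na <- 2 * naa + nAa
      if (nA == 0 || na == 0) next
      pkg <- hwe_exact(nAA, nAa, naa)
      orc <- oracle_hwe_dist(nA, na)
      expect_equal(pkg$distribution$h, orc$h)
      expect_equal(pkg$distribution$prob, orc$prob, tolerance = 1e-10)
      # distribution sums to one; one-sided p-values share the observed atom
      expect_equal(sum(pkg$distribution$prob), 1, tolerance = 1e-12)
      expect_gte(pkg$p_excess + pkg$p_deficit, 1 - 1e-12)
    }
  })
  # all individuals heterozygous: deficit side saturates
  all_het <- hwe_exact(0, 6, 0)
  expect_equal(all_het$p_deficit, 1)
  expect_lte(all_het$p_excess, 1)
  expect_error(hwe_exact(5, 0, 0), "monomorphic")
})

test_that("BH step-up rejects exactly the right hypotheses", {
  res <- bh_fdr(c(0.01, 0.02, 0.04, 0.9), q = 0.05)
  expect_identical(res$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$q_values, p.adjust(c(0.01, 0.02, 0.04, 0.9), "BH"))
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  expect_true(bh_fdr(0.04, q = 0.05)$significant)
})

test_that("population flags separate paralogs, nulls and clean markers", {
  sites <- data.frame(marker = rep(c("par", "nul", "cln"), each = 5),
                      pos = rep(0:4, 3), p = 0.5)
  hits <- matrix(0, 30, 3, dimnames = list(NULL, c("par", "nul", "cln")))
  for (s in seq_len(30)) {
    pop <- simulate_population(sites, n_individuals = 40,
                               paralog_markers = "par",
                               null_allele_markers = "nul", f_null = 0.7,
                               seed = 600 + s)
    fl <- flag_population_markers(pop$genotypes, pop$design)
    mf <- fl$marker_flags
    hits[s, "par"] <- mf$paralog_population[mf$marker == "par"]
    hits[s, "nul"] <- mf$null_allele[mf$marker == "nul"]
    hits[s, "cln"] <- mf$paralog_population[mf$marker == "cln"] ||
      mf$null_allele[mf$marker == "cln"]
  }
  expect_gt(mean(hits[, "par"]), 0.6)
  expect_gt(mean(hits[, "nul"]), 0.6)
  expect_lt(mean(hits[, "cln"]), 0.2)
})

test_that("NRD follows its definition and symmetries", {
  # 10 sites: 6 both hom-ref, 3 concordant non-ref, 1 discordant -> 1/4
  a <- c(rep("0/0", 6), "0/1", "0/1", "1/1", "0/1")
  b <- c(rep("0/0", 6), "0/1", "0/1", "1/1", "1/1")
  gt <- make_gt(rep("M", 10), cbind(r1 = a, r2 = b))
  res <- nrd(gt, data.frame(sample_a = "r1", sample_b = "r2"))
  expect_equal(res$pooled, 0.25)
  # symmetric in the replicates, invariant to site order
  res2 <- nrd(gt, data.frame(sample_a = "r2", sample_b = "r1"))
  expect_equal(res2$pooled, 0.25)
  perm <- make_gt(rep("M", 10), cbind(r1 = rev(a), r2 = rev(b)))
  expect_equal(nrd(perm, data.frame(sample_a = "r1", sample_b = "r2"))$pooled,
               0.25)
  # identical replicates: NRD 0
  gt0 <- make_gt(rep("M", 4), cbind(r1 = a[7:10], r2 = a[7:10]))
  expect_equal(nrd(gt0, data.frame(sample_a = "r1", sample_b = "r2"))$pooled, 0)
  # unphased representation does not create false discordance
  gtp <- make_gt("M", cbind(r1 = "1/0", r2 = "0/1"))
  expect_equal(nrd(gtp, data.frame(sample_a = "r1", sample_b = "r2"))$pooled, 0)
  # no comparable sites
  gtn <- make_gt("M", cbind(r1 = "0/0", r2 = "0/0"))
  expect_error(nrd(gtn, data.frame(sample_a = "r1", sample_b = "r2")),
               "no comparable")
})

test_that("NRD on independent genotypes approaches its analytic expectation", {
  # two independent draws at HWE p=0.5: genotype probs (1/4, 1/2, 1/4);
  # P(discordant) / P(not both hom-ref)
  p <- c(0.25, 0.5, 0.25)
  p_same <- sum(p^2)
  p_bothref <- p[1]^2
  expected <- (1 - p_same) / (1 - p_bothref)
  sites <- data.frame(marker = "M", pos = seq_len(3000) - 1L, p = 0.5)
  g1 <- simulate_population(sites, n_individuals = 2, seed = 81)$genotypes
  g2 <- simulate_population(sites, n_individuals = 2, seed = 82)$genotypes
  colnames(g2$gt) <- colnames(g2$dp) <- colnames(g2$gq) <- c("x1", "x2")
  g2$samples <- c("x1", "x2")
  both <- combine_genotype_tables(g1, g2)
  obs <- nrd(both, data.frame(sample_a = g1$samples[1], sample_b = "x1"))$pooled
  expect_lt(abs(obs - expected), 4 * sqrt(expected * (1 - expected) / 3000))
})

test_that("marker classification applies the documented precedence", {
  markers <- c("m1", "m2", "m3", "m4", "m5", "m6")
  counts <- count_matrix(matrix(c(0, rep(10, 5), 0, rep(10, 5)),
                                6, 2, dimnames = list(markers, c("s1", "s2"))))
  family <- data.frame(marker = markers,
                       status = c("tested", "monomorphic", "tested", "tested",
                                  "tested", "tested"),
                       p_min = 0.5, n_sites_tested = 1, zero_class = FALSE,
                       paralog_family = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  population <- data.frame(marker = markers,
                           paralog_population = c(FALSE, FALSE, TRUE, TRUE,
                                                  FALSE, FALSE),
                           null_allele = c(FALSE, FALSE, FALSE, TRUE, TRUE,
                                           FALSE))
  rep <- classify_markers(markers, counts, family = family,
                          population = population)
  st <- setNames(rep$per_marker$status, rep$per_marker$marker)
  expect_identical(unname(st[c("m1", "m2", "m3", "m4", "m5", "m6")]),
                   c("no_reads", "monomorphic", "paralog_family",
                     "paralog_population", "null_allele", "validated"))
  # co-occurring flags are both recorded on the marker
  m4 <- rep$per_marker[rep$per_marker$marker == "m4", ]
  expect_true(m4$paralog_population && m4$null_allele)
  expect_false(rep$per_marker$validated[rep$per_marker$marker == "m3"])
  # empty input yields an empty report
  empty <- classify_markers(character(0))
  expect_equal(nrow(empty$per_marker), 0L)
})
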