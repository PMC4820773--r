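test_that("melting temperature is duplex-symmetric and GC-monotone", {
  withr::with_seed(5, {
    for (i in 1:10) {
      s <- rand_seq(sample(16:24, 1))
      expect_equal(melting_temp(s), melting_temp(revcomp(s)), tolerance = 1e-12)
    }
  })
  expect_gt(melting_temp(strrep("GC", 8)), melting_temp(strrep("AT", 8)))
  expect_error(melting_temp("ACGTN"), "non-ACGT|shorter")
  expect_error(melting_temp("ACGTACGTACGTACGTACGN"), "non-ACGT")
})

test_that("melting temperature matches an independent NN hand computation", {
  # oracle: direct dH/dS table summation over the 16 dinucleotide stacks,
  # transcribed independently of the implementation's 10-key table
  oracle_tm <- function(seq) {
    dh16 <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
              CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
              GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
              TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
    ds16 <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
              CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
              GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
              TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
    b <- strsplit(seq, "")[[1]]
    st <- paste0(b[-length(b)], b[-1])
    gc_end <- function(x) if (x %in% c("G", "C")) c(0.1, -2.8) else c(2.3, 4.1)
    dh <- sum(dh16[st]) + gc_end(b[1])[1] + gc_end(b[length(b)])[1]
    ds <- sum(ds16[st]) + gc_end(b[1])[2] + gc_end(b[length(b)])[2] +
      0.368 * (length(b) - 1) * log(0.05)
    1000 * dh / (ds + 1.9872 * log(0.25e-6 / 4)) - 273.15
  }
  fixed20 <- "TTGCCCTGCCCTTGTCGGTC"
  expect_equal(melting_temp(fixed20), oracle_tm(fixed20), tolerance = 0.1 / 60)
  withr::with_seed(9, {
    for (i in 1:20) {
      s <- rand_seq(sample(16:24, 1))
      expect_equal(melting_temp(s), oracle_tm(s), tolerance = 1e-9)
    }
  })
})

test_that("diagnostic SNPs require complete homozygous species contrast", {
  gt <- make_gt(rep("t1", 3),
                matrix(c("0/0", "0/0", "1/1", "1/1",   # diagnostic
                         "0/0", "0/1", "1/1", "1/1",   # het present
                         "0/0", NA,    "1/1", "1/1"),  # incomplete
                       nrow = 3, byrow = TRUE,
                       dimnames = list(NULL, c("a1", "a2", "b1", "b2"))))
  design <- study_design(data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    role = "population", group = c("sp1", "sp1", "sp2", "sp2")))
  d <- find_diagnostic_snps(gt, design)
  expect_equal(nrow(d), 1L)
  expect_equal(d$pos, 0L)
  expect_equal(d$allele1, 0L)
  expect_equal(d$allele2, 1L)
  bad <- study_design(data.frame(sample_id = c("a1", "zz"), role = "population",
                                 group = c("sp1", "sp2")))
  expect_error(find_diagnostic_snps(gt, bad), "unknown sample")
})

test_that("target enumeration honors footprint arithmetic", {
  # minimal-arm footprint is 20 + L + 16; an exon one bp short fits nothing
  expect_equal(nrow(enumerate_targets(147, NULL, 112)), 0L)
  # exactly 112+16+20 forces a single placement
  one <- enumerate_targets(148, NULL, 112)
  expect_equal(nrow(one), 1L)
  expect_equal(one$s, 20L)
  # combinatorial count on a 400 bp single-exon transcript
  expect_equal(nrow(enumerate_targets(400, NULL, 112)), 400 - 148 + 1)
  # margin applies only at internal boundaries
  b <- structure(list(boundaries = 200L, confidence = "high",
                      transcript_len = 400L), class = "boundary_set")
  w0 <- enumerate_targets(400, b, 112, boundary_margin = 0)
  w5 <- enumerate_targets(400, b, 112, boundary_margin = 5)
  expect_equal(nrow(w0), (200 - 148 + 1) * 2)
  expect_equal(nrow(w5), (200 - 148 - 5 + 1) * 2)
})

test_that("arm design minimizes the Tm objective over the admissible pairs", {
  withr::with_seed(13, {
    for (i in 1:10) {
      tx <- rand_seq(300)
      a <- design_arms(tx, 100, 212)
      # brute-force oracle over the 5 (ext, lig) pairs via melting_temp
      costs <- sapply(16:20, function(ext) {
        lig <- 40 - ext
        abs(melting_temp(revcomp(substr(tx, 213, 212 + ext))) - 60) +
          abs(melting_temp(revcomp(substr(tx, 101 - lig, 100))) - 60)
      })
      expect_equal(-a$score, min(costs), tolerance = 1e-9)
      expect_equal(a$ext_len + a$lig_len, 40)
    }
  })
  # window flush against the transcript end leaves no admissible pair
  tx <- rand_seq(300, seed = 14)
  expect_error(design_arms(tx, 10, 122), "no admissible arm")
})

test_that("assembled probes have the mandated geometry", {
  tx <- rand_seq(300, seed = 17)
  a <- design_arms(tx, 100, 212)
  p <- assemble_probe("m1", "tx", tx, 100, 212, a)
  expect_equal(nchar(p$probe_seq), 70L)
  expect_equal(nchar(p$ext_arm) + nchar(p$lig_arm), 40L)
  expect_identical(p$probe_seq, paste0(p$lig_arm, p$linker, p$ext_arm))
  # extension arm on an all-A flank is all T
  tx2 <- paste0(substr(tx, 1, 212), strrep("A", 20), substr(tx, 233, 300))
  a2 <- design_arms(tx2, 100, 212)
  expect_identical(a2$ext_arm, strrep("T", a2$ext_len))
  expect_error(assemble_probe("m", "tx", tx, 100, 212, a, linker = "ACGT"),
               "linker")
})

test_that("in-silico capture reconstructs the designed target", {
  tx <- rand_seq(400, seed = 19)
  a <- design_arms(tx, 150, 262)
  p <- assemble_probe("m1", "tx", tx, 150, 262, a)
  chk <- in_silico_capture_check(p, tx)
  expect_identical(chk$status, "ok")
  expect_identical(chk$insert, substr(tx, 151, 262))
  expect_equal(c(chk$s, chk$e), c(150, 262))
  # capture works from the minus strand of a larger reference too
  chk_rc <- in_silico_capture_check(p, revcomp(paste0(rand_seq(50, 20), tx)))
  expect_identical(chk_rc$status, "ok")
  expect_identical(chk_rc$insert, substr(tx, 151, 262))

  # swapped arms break colinearity
  swapped <- p
  swapped$ext_arm <- p$lig_arm
  swapped$lig_arm <- p$ext_arm
  swapped$target_len <- NULL
  expect_error(in_silico_capture_check(swapped, tx), "order|geometry|no perfect")

  # a duplicated exon makes the arm sites ambiguous
  dup <- paste0(tx, tx)
  expect_warning(chk2 <- in_silico_capture_check(p, dup), "multiple loci")
  expect_identical(chk2$status, "multi_site")
})

test_that("panel selection is seeded, filtered, and order-invariant", {
  tx <- rand_seq(500, seed = 23)
  cand <- design_candidates("t1", tx, gene_id = "g1")
  cand2 <- design_candidates("t2", rand_seq(500, seed = 24), gene_id = "g2")
  all_cand <- rbind(cand, cand2)
  diag <- data.frame(marker = c("t1", "t2"), pos = c(250L, 250L))
  sel1 <- rank_and_select(all_cand, diag, seed = 7)
  expect_equal(nrow(sel1), 2L)
  expect_setequal(sel1$gene_id, c("g1", "g2"))
  # determinism and permutation invariance
  sel2 <- rank_and_select(all_cand, diag, seed = 7)
  expect_identical(sel1, sel2)
  shuffled <- all_cand[rev(seq_len(nrow(all_cand))), ]
  sel3 <- rank_and_select(shuffled, diag, seed = 7)
  expect_identical(sel1$marker_id, sel3$marker_id)
  # different seed may pick a different probe but still one per gene
  sel4 <- rank_and_select(all_cand, diag, seed = 8)
  expect_equal(nrow(sel4), 2L)
  # every selected target contains its diagnostic site
  expect_true(all(sel1$s <= 250 & sel1$e > 250))
  # a diagnostic SNP inside an arm disqualifies under the arm policy
  in_arm <- data.frame(marker = "t1", pos = cand$s[1] - 1L)
  sel5 <- rank_and_select(cand[1, ], in_arm, seed = 1)
  expect_equal(nrow(sel5), 0L)
  sel6 <- rank_and_select(cand[1, ], in_arm, seed = 1, arms_snp_free = FALSE)
  expect_equal(nrow(sel6), 0L)  # still fails: site not inside the target
  expect_error(rank_and_select(cand, diag, seed = NULL), "seed")
})
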