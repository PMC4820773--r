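# Shared fixture builders. Everything is generated in code; no binary data.

rand_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

write_tmp_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "seqs.fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

# a tiny two-gene genome + GFF3 on both strands, with known exon sequences
make_gff_fixture <- function(dir) {
  chrom <- paste0(strrep("A", 10), "CCCCCGGGGG", strrep("T", 10),
                  "ACGTACGTAC", strrep("G", 20))
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">chr1", chrom), fa)
  gff <- file.path(dir, "models.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\texon\t11\t20\t.\t+\t.\tgene_id=gplus",
    "chr1\ttest\texon\t31\t40\t.\t+\t.\tgene_id=gplus",
    "chr1\ttest\texon\t11\t20\t.\t-\t.\tgene_id=gminus",
    "chr1\ttest\texon\t31\t40\t.\t-\t.\tgene_id=gminus"
  ), gff)
  list(genome = fa, gff = gff, chrom = chrom)
}

# genotype table fixture: explicit genotypes, full DP/GQ
make_gt <- function(markers, gt_mat, dp = NULL, gq = NULL, pos = NULL) {
  n_site <- nrow(gt_mat)
  sites <- data.frame(marker = markers,
                      pos = if (is.null(pos)) seq_len(n_site) - 1L else pos,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_table(sites, colnames(gt_mat), gt_mat, dp, gq)
}

family_design <- function(n_offspring) {
  study_design(data.frame(
    sample_id = c("P1", "P2", sprintf("O%02d", seq_len(n_offspring))),
    role = c("parent", "parent", rep("offspring", n_offspring)),
    group = ""))
}

# independent brute-force multinomial p-value: enumerate outcomes with
# dmultinom, no shared code with the implementation
oracle_multinomial_p <- function(obs, probs) {
  n <- sum(obs)
  k <- length(obs)
  grid <- expand.grid(rep(list(0:n), k - 1))
  grid$last <- n - rowSums(grid)
  grid <- as.matrix(grid[grid$last >= 0, , drop = FALSE])
  p_all <- apply(grid, 1, function(x) stats::dmultinom(x, prob = probs))
  p_obs <- stats::dmultinom(obs, prob = probs)
  sum(p_all[p_all <= p_obs * (1 + 1e-12)])
}

# independent HWE conditional distribution: conditional on allele counts,
# genotypes arise by random pairing of exchangeable alleles, i.e. uniformly
# over the C(2n, nA) placements of the A alleles into 2n ordered slots
# paired consecutively. Pure combinatorial enumeration, no closed form.
oracle_hwe_dist <- function(nA, na) {
  slots <- nA + na
  placements <- utils::combn(slots, nA)
  h_counts <- apply(placements, 2, function(ix) {
    al <- rep(0L, slots); al[ix] <- 1L
    sum(al[seq(1, slots, 2)] != al[seq(2, slots, 2)])
  })
  tab <- table(h_counts) / ncol(placements)
  data.frame(h = as.integer(names(tab)), prob = as.numeric(tab))
}
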