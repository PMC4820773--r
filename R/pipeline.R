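# End-to-end wiring: design probes on a (simulated or user-supplied)
# reference, simulate capture, compute performance metrics, rebalance,
# validate markers and summarize diversity and cost. The command-line
# interface in inst/cli/mipkit is a thin dispatcher over these functions.

#' Read a run configuration
#'
#' YAML configuration of pipeline thresholds; unspecified keys take the
#' documented defaults (dp_min 16, gq_min 30, p_cut 0.015, fdr_q 0.05,
#' low_cut 0.001, n_top 1, boost 100, reduce 0.1, t_opt 60, target_len 112).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Named list of resolved parameters.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(dp_min = 16, gq_min = 30, p_cut = 0.015, fdr_q = 0.05,
                   low_cut = 0.001, n_top = 1, boost = 100, reduce = 0.1,
                   t_opt = 60, target_len = 112, linker = MIP_LINKER,
                   ambiguity_margin = 0.8, min_identity = 60, min_len = 30,
                   boundary_margin = 5, score_cutoff = -Inf)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0L) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, user)
}

#' Design a probe panel from transcripts and gene models
#'
#' For every transcript: assign the best gene model (discarding ambiguous
#' and unmapped transcripts), call exon boundaries, enumerate
#' exon-contained windows, design arms, and finally select one
#' diagnostic-SNP-bearing probe per gene.
#'
#' @param transcripts Named `DNAStringSet` (or character vector).
#' @param models A `gene_model_set`.
#' @param diagnostics data.frame of diagnostic sites (`marker` = transcript
#'   id, `pos`).
#' @param seed Integer seed for the per-gene probe draw.
#' @param config Run configuration from [read_run_config()].
#' @return List: `panel` (selected `mip_probe` rows), `candidates`,
#'   `assignments` (per transcript status), `boundaries` (per transcript
#'   `boundary_set`).
#' @export
design_panel <- function(transcripts, models, diagnostics, seed,
                         config = read_run_config()) {
  tx_ids <- names(transcripts)
  assignments <- data.frame(transcript = tx_ids, status = "NO_HIT",
                            gene = NA_character_, stringsAsFactors = FALSE)
  cand <- list(); bounds <- list()
  for (i in seq_along(tx_ids)) {
    seq_i <- as.character(transcripts[[i]])
    abg <- assign_best_gene(seq_i, models,
                            ambiguity_margin = config$ambiguity_margin,
                            min_identity = config$min_identity,
                            min_len = config$min_len)
    assignments$status[i] <- abg$status
    if (abg$status != "OK") next
    assignments$gene[i] <- abg$gene_id
    b <- call_boundaries(abg$mapping)
    bounds[[tx_ids[i]]] <- b
    cc <- design_candidates(tx_ids[i], seq_i, b,
                            target_len = config$target_len,
                            t_opt = config$t_opt, linker = config$linker,
                            gene_id = abg$gene_id,
                            boundary_margin = config$boundary_margin)
    if (nrow(cc) > 0L) cand[[length(cand) + 1L]] <- cc
  }
  candidates <- if (length(cand) > 0L) do.call(rbind, cand) else data.frame()
  panel <- if (nrow(candidates) > 0L) {
    rank_and_select(candidates, diagnostics, seed = seed,
                    score_cutoff = config$score_cutoff)
  } else candidates
  list(panel = panel, candidates = candidates, assignments = assignments,
       boundaries = bounds)
}

#' Write a probe table as TSV
#' @param panel data.frame of `mip_probe` rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write probe targets as BED
#'
#' 0-based half-open target intervals in transcript coordinates.
#' @param panel data.frame of `mip_probe` rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets_bed <- function(panel, path) {
  bed <- data.frame(panel$transcript_id, panel$s, panel$e, panel$marker_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the bundled demonstration pipeline
#'
#' Simulates a reference, designs a probe panel on it, verifies capture
#' geometry, simulates pre- and post-rebalancing capture experiments and a
#' validation study (hybrid family, three populations, replicates with
#' planted paralog and null-allele markers), and writes all artifacts plus
#' a JSON report. Problem sizes are deliberately desk-scale.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every stochastic stage (mandatory).
#' @param n_genes Genes in the synthetic reference.
#' @param n_samples Samples per capture experiment.
#' @param reads_per_sample Read pairs per sample.
#' @param config Run configuration.
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_demo <- function(out_dir, seed, n_genes = 40, n_samples = 24,
                     reads_per_sample = 2e5, config = read_run_config()) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(n_genes = n_genes, n_samples = n_samples,
                    reads_per_sample = reads_per_sample, seed = seed)
  ref <- simulate_reference(cfg)
  write_sequences(ref$genome, file.path(out_dir, "genome.fa"))
  write_sequences(ref$transcripts, file.path(out_dir, "transcripts.fa"))
  write_gene_models_gff3(ref$models, file.path(out_dir, "models.gff3"))

  # diagnostic sites: one per transcript, inside the widest exon block
  diagnostics <- do.call(rbind, lapply(names(ref$truth), function(g) {
    lens <- ref$truth[[g]]$exon_lengths
    k <- which.max(lens)
    start <- c(0, cumsum(lens))[k]
    data.frame(marker = paste0("tx_", g), pos = start + lens[k] %/% 2L,
               stringsAsFactors = FALSE)
  }))
  dsg <- design_panel(ref$transcripts, ref$models, diagnostics, seed = seed,
                      config = config)
  panel <- dsg$panel
  if (nrow(panel) == 0L) stop("demo design produced no probes")
  write_probe_table(panel, file.path(out_dir, "design.tsv"))
  write_targets_bed(panel, file.path(out_dir, "targets.bed"))
  gene_of <- sub("^tx_", "", panel$transcript_id)
  geom_ok <- vapply(seq_len(nrow(panel)), function(i) {
    chk <- tryCatch(in_silico_capture_check(panel[i, ], ref$genome[[gene_of[i]]]),
                    error = function(e) list(status = "fail"),
                    warning = function(w) list(status = "multi_site"))
    identical(chk$status, "ok")
  }, logical(1))

  n_probes <- nrow(panel)
  eff <- with_seed(seed + 1L, {
    stats::setNames(10^stats::rnorm(n_probes, 0, cfg$efficiency_sdlog10),
                    panel$marker_id)
  })
  counts1 <- simulate_capture(eff, n_samples = n_samples,
                              reads_per_sample = reads_per_sample,
                              off_target_fraction = 0.227,
                              dropout_prob = cfg$dropout_prob, seed = seed + 2L)
  write_counts(counts1, file.path(out_dir, "counts.tsv"))
  fmr1 <- compute_fmr(counts1)
  uni <- summarize_uniformity(fmr1)
  factors <- select_rebalancing(uni$median_fmr, low_cut = config$low_cut,
                                n_top = config$n_top, boost = config$boost,
                                reduce = config$reduce)
  counts2 <- simulate_capture(eff, factors, n_samples = n_samples,
                              reads_per_sample = reads_per_sample,
                              off_target_fraction = 0.627,
                              dropout_prob = cfg$dropout_prob, seed = seed + 3L)
  fmr2 <- compute_fmr(counts2)
  boosted <- names(factors)[factors > 1]
  reb <- if (length(boosted) >= 4L) {
    wilcoxon_signed_rank(apply(fmr1$fmr[boosted, , drop = FALSE], 1, stats::median),
                         apply(fmr2$fmr[boosted, , drop = FALSE], 1, stats::median))
  } else NULL

  # validation study with planted contamination (~10% paralogs, ~5% nulls)
  n_par <- max(1L, round(0.1 * n_probes))
  n_null <- max(1L, round(0.05 * n_probes))
  planted <- with_seed(seed + 4L, sample(panel$marker_id, n_par + n_null))
  par_set <- planted[seq_len(n_par)]
  null_set <- planted[n_par + seq_len(n_null)]
  fam <- simulate_family(n_probes, n_offspring = 21,
                         paralog_markers = par_set,
                         null_allele_markers = null_set,
                         seed = seed + 5L, marker_ids = panel$marker_id)
  write_genotypes_vcf(fam$genotypes, file.path(out_dir, "family.vcf"))
  fam_gt <- apply_genotype_filters(fam$genotypes, config$dp_min, config$gq_min)
  fam_res <- flag_paralogs_family(fam_gt, fam$design, p_cut = config$p_cut)

  pop_sites <- with_seed(seed + 6L, {
    data.frame(marker = rep(panel$marker_id, each = 3),
               pos = rep(c(10L, 55L, 100L), n_probes),
               p = stats::runif(3L * n_probes, 0.2, 0.8))
  })
  pops <- lapply(seq_len(3L), function(k) {
    simulate_population(pop_sites, n_individuals = 18,
                        paralog_markers = par_set,
                        null_allele_markers = null_set,
                        pop_name = paste0("pop", k), seed = seed + 6L + k)
  })
  pop_gt <- do.call(combine_genotype_tables, lapply(pops, `[[`, "genotypes"))
  pop_design <- study_design(do.call(rbind, lapply(pops, function(p)
    as.data.frame(p$design))))
  write_genotypes_vcf(pop_gt, file.path(out_dir, "pops.vcf"))
  pop_res <- flag_population_markers(
    apply_genotype_filters(pop_gt, config$dp_min, config$gq_min),
    pop_design, q = config$fdr_q)

  rep_samples <- pops[[1]]$genotypes$samples[1:16]
  reps <- simulate_replicates(pop_gt, rep_samples, seed = seed + 10L)
  nrd_res <- nrd(reps$genotypes,
                 data.frame(sample_a = rep_samples,
                            sample_b = paste0(rep_samples, "_rep")))

  report_cls <- classify_markers(panel$marker_id, counts = counts1,
                                 family = fam_res,
                                 population = pop_res$marker_flags)

  div <- lapply(seq_len(3L), function(k) {
    s <- pops[[k]]$genotypes$samples
    L <- n_probes * config$target_len
    list(population = paste0("pop", k),
         S = segregating_sites(pop_gt, s),
         pi = nucleotide_diversity(pop_gt, s, L))
  })

  report <- list(
    seed = seed,
    config = config[setdiff(names(config), "score_cutoff")],
    design = list(n_transcripts = length(ref$transcripts),
                  n_assigned = sum(dsg$assignments$status == "OK"),
                  n_candidates = nrow(dsg$candidates),
                  n_probes = n_probes,
                  geometry_pass_fraction = mean(geom_ok)),
    performance = list(
      mean_on_target = mean(fmr1$on_target_fraction),
      decade_fraction = uni$decade_fraction,
      frac_fold_lt5 = uni$frac_fold_lt5,
      n_zero_median = uni$n_zero_median,
      n_boosted = sum(factors > 1), n_reduced = sum(factors < 1),
      rebalance_V = if (!is.null(reb)) reb$V else NA,
      rebalance_p = if (!is.null(reb)) reb$p_value else NA),
    validation = list(status_counts = as.list(report_cls$counts),
                      nrd_pooled = nrd_res$pooled,
                      truth = list(paralog = par_set, null_allele = null_set)),
    diversity = div,
    cost = cost_table()
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(efficiencies = as.list(eff),
                            paralog = par_set, null_allele = null_set,
                            dropout = attr(counts1, "dropout")),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
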