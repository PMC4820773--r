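# Population summary statistics and the panel cost model.

#' Number of segregating sites in a population
#'
#' A site segregates when at least two distinct alleles occur among the
#' called genotypes of the population's samples.
#'
#' @param gt A [genotype_table()].
#' @param samples Sample ids of the population.
#' @return Integer `S`.
#' @export
segregating_sites <- function(gt, samples) {
  cols <- match(samples, gt$samples)
  stopifnot(!any(is.na(cols)))
  sum(vapply(seq_len(nrow(gt$sites)), function(i) {
    calls <- gt$gt[i, cols]
    calls <- calls[!is.na(calls)]
    if (length(calls) == 0L) return(FALSE)
    length(unique(unlist(strsplit(calls, "/", fixed = TRUE)))) >= 2L
  }, logical(1)))
}

#' Nucleotide diversity per site
#'
#' `pi = (1/L) sum_s [n_s/(n_s - 1)] (1 - sum_a p_a^2)` with `n_s` the
#' called chromosomes and `p_a` the allele frequencies at site `s`; sites
#' with fewer than 2 called chromosomes are skipped. `L` is the total
#' number of surveyed sites (monomorphic positions included), putting `pi`
#' on the per-site scale.
#'
#' @param gt A [genotype_table()].
#' @param samples Sample ids of the population.
#' @param L Total surveyed sites (>= number of polymorphic sites).
#' @return Nucleotide diversity `pi`.
#' @export
nucleotide_diversity <- function(gt, samples, L) {
  stopifnot(L >= 1)
  cols <- match(samples, gt$samples)
  stopifnot(!any(is.na(cols)))
  per_site <- vapply(seq_len(nrow(gt$sites)), function(i) {
    calls <- gt$gt[i, cols]
    calls <- calls[!is.na(calls)]
    alleles <- unlist(strsplit(calls, "/", fixed = TRUE))
    ns <- length(alleles)
    if (ns < 2L) return(0)
    p <- table(alleles) / ns
    ns / (ns - 1) * (1 - sum(p^2))
  }, numeric(1))
  n_poly <- sum(per_site > 0)
  if (L < n_poly) {
    stop("L (", L, ") smaller than the number of polymorphic sites (", n_poly, ")")
  }
  sum(per_site) / L
}

#' Panel cost model
#'
#' @param probe_cost_per_mip Synthesis cost per probe in dollars (default
#'   9.1; independent of the number of samples).
#' @param reagent_cost_per_sample Wet-lab reagent cost per sample in
#'   dollars (default 7.4; independent of the number of probes).
#' @return A list of class `cost_model`.
#' @export
cost_model <- function(probe_cost_per_mip = 9.1, reagent_cost_per_sample = 7.4) {
  stopifnot(probe_cost_per_mip > 0, reagent_cost_per_sample > 0)
  structure(list(probe_cost_per_mip = probe_cost_per_mip,
                 reagent_cost_per_sample = reagent_cost_per_sample),
            class = "cost_model")
}

#' Per-sample cost of a MIP experiment
#'
#' Probe synthesis is a one-off cost amortized over samples:
#' `cost = probe_cost x n_mips / n_samples + reagent_cost`.
#'
#' @param n_mips Number of probes (>= 1).
#' @param n_samples Number of samples (>= 1).
#' @param model A [cost_model()].
#' @return Cost in dollars (full precision; round to 0.1 for display).
#' @export
cost_per_sample <- function(n_mips, n_samples, model = cost_model()) {
  stopifnot(n_mips >= 1, n_samples >= 1)
  model$probe_cost_per_mip * n_mips / n_samples + model$reagent_cost_per_sample
}

#' Per-genotype cost of a MIP experiment
#'
#' @inheritParams cost_per_sample
#' @return Cost in dollars (round to 0.001 for display).
#' @export
cost_per_genotype <- function(n_mips, n_samples, model = cost_model()) {
  cost_per_sample(n_mips, n_samples, model) / n_mips
}

# display rounding: half-up (so e.g. $0.0165 per genotype prints as 0.017),
# unlike round()'s half-to-even
round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Cost table over panel and cohort sizes
#'
#' @param n_mips,n_samples Vectors of panel and cohort sizes to cross.
#' @param model A [cost_model()].
#' @return data.frame with per-sample and per-genotype costs for every
#'   combination, display-rounded (half-up) to 0.1 and 0.001 dollars.
#' @export
cost_table <- function(n_mips = c(100, 1000, 5000),
                       n_samples = c(100, 1000, 10000),
                       model = cost_model()) {
  grid <- expand.grid(n_samples = n_samples, n_mips = n_mips)
  grid$per_sample <- round_half_up(
    mapply(cost_per_sample, grid$n_mips, grid$n_samples,
           MoreArgs = list(model = model)), 1)
  grid$per_genotype <- round_half_up(
    mapply(cost_per_genotype, grid$n_mips, grid$n_samples,
           MoreArgs = list(model = model)), 3)
  grid[, c("n_mips", "n_samples", "per_sample", "per_genotype")]
}
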