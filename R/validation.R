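# Marker validation: DP/GQ missingness filters, exact Mendelian
# segregation tests in the mapping family, exact Hardy-Weinberg tests for
# heterozygote excess (collapsed paralogs) and deficit (null alleles) in
# natural populations, replicate concordance (NRD), and the final
# per-marker classification.

#' Mask genotype calls failing depth/quality filters
#'
#' Calls with `DP < dp_min` or `GQ < gq_min` become missing. Calls lacking
#' a DP or GQ annotation pass by default (`absent = "pass"`); set
#' `absent = "fail"` to mask them instead.
#'
#' @param gt A [genotype_table()].
#' @param dp_min Minimum retained depth (default 16; `DP = 16` passes).
#' @param gq_min Minimum retained genotype quality in phred (default 30).
#' @param absent Policy for calls without DP/GQ annotations.
#' @return The filtered `genotype_table`, with `attr(,"n_masked")`.
#' @export
apply_genotype_filters <- function(gt, dp_min = 16, gq_min = 30,
                                   absent = c("pass", "fail")) {
  absent <- match.arg(absent)
  stopifnot(dp_min >= 0, gq_min >= 0)
  dp <- gt$dp; gq <- gt$gq
  if (absent == "pass") {
    dp[is.na(dp)] <- Inf; gq[is.na(gq)] <- Inf
  } else {
    dp[is.na(dp)] <- -Inf; gq[is.na(gq)] <- -Inf
  }
  mask <- (dp < dp_min | gq < gq_min) & !is.na(gt$gt)
  out <- gt
  out$gt[mask] <- NA_character_
  attr(out, "n_masked") <- sum(mask)
  out
}

sort_gt <- function(g) {
  # normalize an unphased call to "min/max"
  al <- strsplit(g, "/", fixed = TRUE)
  vapply(al, function(a) {
    a <- sort(as.integer(a))
    paste(a[1], a[2], sep = "/")
  }, character(1))
}

#' Expected offspring genotype distribution from two parents
#'
#' Enumerates the four equally likely parental allele transmissions. A
#' cross of identical homozygotes is monomorphic and excluded from testing.
#'
#' @param parent1,parent2 Unphased genotype strings (`"0/1"`); a missing
#'   parent makes the site untestable.
#' @return data.frame with `genotype` (sorted allele pairs) and `prob`, or
#'   `NULL` when the site is untestable (missing parent) or monomorphic.
#' @export
expected_segregation <- function(parent1, parent2) {
  if (is.na(parent1) || is.na(parent2)) return(NULL)
  a1 <- as.integer(strsplit(parent1, "/", fixed = TRUE)[[1]])
  a2 <- as.integer(strsplit(parent2, "/", fixed = TRUE)[[1]])
  stopifnot(length(a1) == 2L, length(a2) == 2L)
  if (a1[1] == a1[2] && a2[1] == a2[2] && a1[1] == a2[1]) return(NULL)
  combos <- expand.grid(m = a1, f = a2)
  g <- apply(combos, 1, function(x) paste(min(x), max(x), sep = "/"))
  tab <- table(g) / 4
  data.frame(genotype = names(tab), prob = as.numeric(tab),
             stringsAsFactors = FALSE)
}

#' Exact multinomial goodness-of-fit test
#'
#' Exact p-value by the probability-ordering rule: the sum, over all
#' outcome vectors of `n` trials in `k` cells, of the multinomial
#' probabilities no larger than the observed outcome's probability (a
#' relative tolerance of 1e-12 tames floating-point ties). Full enumeration
#' is feasible for `k <= 4` and `n <= 200`. A positive count in a
#' zero-probability cell gives `p = 0`, flagged via
#' `attr(,"impossible_cell")`.
#'
#' @param observed Non-negative integer counts, length `k`.
#' @param probs Cell probabilities summing to 1.
#' @return The exact p-value.
#' @export
exact_multinomial_test <- function(observed, probs) {
  stopifnot(length(observed) == length(probs), all(observed >= 0),
            all(probs >= 0), abs(sum(probs) - 1) < 1e-9)
  n <- sum(observed); k <- length(observed)
  if (n < 1) stop("need at least one trial")
  if (k > 4L || n > 200L) stop("exact enumeration supported for k <= 4, n <= 200")
  if (any(observed > 0 & probs == 0)) {
    out <- 0
    attr(out, "impossible_cell") <- TRUE
    return(out)
  }
  grid <- compositions(n, k)
  lp <- log(probs)
  logprob <- lgamma(n + 1) - rowSums(lgamma(grid + 1)) +
    rowSums(sweep(grid, 2, lp, function(x, l) ifelse(x == 0, 0, x * l)))
  obs_lp <- lgamma(n + 1) - sum(lgamma(observed + 1)) +
    sum(ifelse(observed == 0, 0, observed * lp))
  keep <- logprob <= obs_lp + 1e-12
  sum(exp(logprob[keep]))
}

# all k-part compositions of n, as a matrix with one row per outcome
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  if (k == 2L) {
    x <- 0:n
    return(cbind(x, n - x, deparse.level = 0))
  }
  parts <- lapply(0:n, function(x1) {
    rest <- compositions(n - x1, k - 1L)
    cbind(rep(x1, nrow(rest)), rest, deparse.level = 0)
  })
  do.call(rbind, parts)
}

#' Test family markers for Mendelian segregation and flag paralogs
#'
#' Markers with any missing family genotype are excluded from testing
#' (status `untested_missing`); markers with no site polymorphic between
#' the parents are `monomorphic`. For every testable site the observed
#' offspring genotype counts are tested against the parental expectation
#' with [exact_multinomial_test()]; a marker is flagged as a potential
#' paralog when its smallest site p-value falls below `p_cut`. Whether an
#' expected genotype class had zero observations is reported alongside;
#' with `strict_conjunction = TRUE` the flag additionally requires such a
#' missing class.
#'
#' @param family A [genotype_table()] of the family.
#' @param design A [study_design()] with 2 parents and the offspring.
#' @param p_cut Flagging threshold on the per-marker minimum p (default
#'   0.015).
#' @param strict_conjunction Require a completely missing expected genotype
#'   class in addition to `p < p_cut` (default `FALSE`).
#' @return data.frame per marker: `marker`, `status` (`tested`,
#'   `untested_missing`, `monomorphic`), `p_min`, `n_sites_tested`,
#'   `zero_class`, `paralog_family`.
#' @export
flag_paralogs_family <- function(family, design, p_cut = 0.015,
                                 strict_conjunction = FALSE) {
  parents <- design$sample_id[design$role == "parent"]
  offspring <- design$sample_id[design$role == "offspring"]
  stopifnot(length(parents) == 2L, length(offspring) >= 1L)
  fam <- c(parents, offspring)
  markers <- unique(family$sites$marker)
  rows <- lapply(markers, function(m) {
    idx <- which(family$sites$marker == m)
    calls <- family$gt[idx, fam, drop = FALSE]
    if (any(is.na(calls))) {
      return(data.frame(marker = m, status = "untested_missing",
                        p_min = NA_real_, n_sites_tested = 0L,
                        zero_class = NA, paralog_family = FALSE))
    }
    p_site <- c(); zero_any <- FALSE
    for (i in idx) {
      exp <- expected_segregation(family$gt[i, parents[1]],
                                  family$gt[i, parents[2]])
      if (is.null(exp)) next
      obs <- sort_gt(family$gt[i, offspring])
      cats <- union(exp$genotype, unique(obs))
      probs <- exp$prob[match(cats, exp$genotype)]
      probs[is.na(probs)] <- 0
      counts <- as.integer(table(factor(obs, levels = cats)))
      p_site <- c(p_site, as.numeric(exact_multinomial_test(counts, probs)))
      zero_any <- zero_any ||
        any(probs > 0 & counts == 0)
    }
    if (length(p_site) == 0L) {
      return(data.frame(marker = m, status = "monomorphic", p_min = NA_real_,
                        n_sites_tested = 0L, zero_class = NA,
                        paralog_family = FALSE))
    }
    flag <- min(p_site) < p_cut
    if (strict_conjunction) flag <- flag && zero_any
    data.frame(marker = m, status = "tested", p_min = min(p_site),
               n_sites_tested = length(p_site), zero_class = zero_any,
               paralog_family = flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact Hardy-Weinberg test for heterozygote excess and deficit
#'
#' Conditional on the observed allele counts, the probability of `h`
#' heterozygotes among `n` diploids is
#' `n! / (n_AA! n_Aa! n_aa!) * 2^h * n_A! n_a! / (2n)!`, summed over the
#' admissible `h` of matching parity. One-sided p-values share the observed
#' atom: `p_excess = P(h >= observed)`, `p_deficit = P(h <= observed)`.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (`n >= 2`, biallelic).
#' @return List with `p_excess`, `p_deficit`, and the conditional
#'   distribution (`h`, `prob`).
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  stopifnot(n >= 2)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) stop("monomorphic site: HWE test undefined")
  # h shares the parity of nA (and of na, since nA + na = 2n is even)
  h_set <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- vapply(h_set, function(h) {
    aa <- (nA - h) / 2; bb <- (na - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- n_Aa
  list(p_excess = min(1, sum(prob[h_set >= obs])),
       p_deficit = min(1, sum(prob[h_set <= obs])),
       distribution = data.frame(h = h_set, prob = prob))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param q FDR level in `(0, 1)` (default 0.05).
#' @return List: `significant` (logical), `q_values` (BH-adjusted, monotone).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), q > 0, q < 1)
  qv <- stats::p.adjust(p_values, method = "BH")
  list(significant = !is.na(qv) & qv <= q, q_values = qv)
}

#' Flag population markers by Hardy-Weinberg disequilibrium
#'
#' Per population, every site polymorphic in that population is tested with
#' [hwe_exact()]. The excess p-values across all sites and populations form
#' one BH family and the deficit p-values another, each controlled at level
#' `q`. A marker becomes `paralog_population` when any excess site is
#' significant in any population, and `null_allele` when any deficit site
#' is; the two flags may co-occur. Sites with more than two alleles are
#' reduced to their two most frequent alleles, with a warning.
#'
#' @param pops A [genotype_table()] of population individuals.
#' @param design A [study_design()] with `population` roles.
#' @param q FDR level (default 0.05).
#' @return List: `site_tests` (per population x site p- and q-values) and
#'   `marker_flags` (per marker logicals `paralog_population`,
#'   `null_allele`).
#' @export
flag_population_markers <- function(pops, design, q = 0.05) {
  pop_list <- population_samples(design)
  stopifnot(length(pop_list) >= 1L)
  tests <- list()
  for (pn in names(pop_list)) {
    cols <- intersect(pop_list[[pn]], pops$samples)
    for (i in seq_len(nrow(pops$sites))) {
      calls <- pops$gt[i, cols]
      calls <- calls[!is.na(calls)]
      if (length(calls) < 2L) next
      al <- strsplit(sort_gt(calls), "/", fixed = TRUE)
      allele_counts <- sort(table(unlist(al)), decreasing = TRUE)
      if (length(allele_counts) < 2L) next
      if (length(allele_counts) > 2L) {
        warning("site ", pops$sites$marker[i], ":", pops$sites$pos[i],
                " has >2 alleles; reduced to the two most frequent")
        top2 <- names(allele_counts)[1:2]
        keep <- vapply(al, function(a) all(a %in% top2), logical(1))
        al <- al[keep]
        if (length(al) < 2L) next
      }
      alleles <- sort(unique(unlist(al)))
      is_het <- vapply(al, function(a) a[1] != a[2], logical(1))
      hom1 <- vapply(al, function(a) all(a == alleles[1]), logical(1))
      res <- hwe_exact(sum(hom1), sum(is_het), sum(!is_het & !hom1))
      tests[[length(tests) + 1L]] <- data.frame(
        population = pn, marker = pops$sites$marker[i],
        pos = pops$sites$pos[i], n = length(al), n_het = sum(is_het),
        p_excess = res$p_excess, p_deficit = res$p_deficit,
        stringsAsFactors = FALSE)
    }
  }
  markers <- unique(pops$sites$marker)
  if (length(tests) == 0L) {
    return(list(site_tests = data.frame(),
                marker_flags = data.frame(marker = markers,
                                          paralog_population = FALSE,
                                          null_allele = FALSE)))
  }
  st <- do.call(rbind, tests)
  exc <- bh_fdr(st$p_excess, q)
  def <- bh_fdr(st$p_deficit, q)
  st$q_excess <- exc$q_values
  st$q_deficit <- def$q_values
  st$sig_excess <- exc$significant
  st$sig_deficit <- def$significant
  flags <- data.frame(
    marker = markers,
    paralog_population = vapply(markers, function(m)
      any(st$sig_excess[st$marker == m]), logical(1)),
    null_allele = vapply(markers, function(m)
      any(st$sig_deficit[st$marker == m]), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(site_tests = st, marker_flags = flags)
}

#' Non-reference discrepancy rate between replicate samples
#'
#' For each replicate pair, sites called in both replicates are compared;
#' pairs where both calls are homozygous reference are excluded from the
#' denominator. `NRD = discordant / compared`.
#'
#' @param gt A [genotype_table()] containing both replicates.
#' @param pairs data.frame with columns `sample_a`, `sample_b` (e.g. from
#'   [replicate_pairs()]).
#' @return List: `per_pair` (data.frame with `n_compared`, `n_discordant`,
#'   `nrd`) and `pooled` (overall NRD).
#' @export
nrd <- function(gt, pairs) {
  stopifnot(nrow(pairs) >= 1L)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- sort_gt_keep_na(gt$gt[, pairs$sample_a[i]])
    b <- sort_gt_keep_na(gt$gt[, pairs$sample_b[i]])
    ok <- !is.na(a) & !is.na(b)
    both_ref <- ok & a == "0/0" & b == "0/0"
    cmp <- ok & !both_ref
    data.frame(sample_a = pairs$sample_a[i], sample_b = pairs$sample_b[i],
               n_compared = sum(cmp), n_discordant = sum(cmp & a != b),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, res)
  if (sum(per$n_compared) == 0L) stop("no comparable sites in any pair")
  per$nrd <- ifelse(per$n_compared > 0, per$n_discordant / per$n_compared, NA)
  list(per_pair = per,
       pooled = sum(per$n_discordant) / sum(per$n_compared))
}

sort_gt_keep_na <- function(g) {
  out <- rep(NA_character_, length(g))
  ok <- !is.na(g)
  out[ok] <- sort_gt(g[ok])
  out
}

#' Classify markers from all validation stages
#'
#' Applies the precedence `no_reads` > `uncallable` > `monomorphic` >
#' `paralog_family` > population flags (`paralog_population` and
#' `null_allele`, which may co-occur) > `validated`.
#'
#' @param markers Character vector of all panel marker ids.
#' @param counts Optional [count_matrix()]; markers with zero reads in
#'   every sample become `no_reads`.
#' @param callable Optional named logical: markers genotypable at all
#'   (`FALSE` becomes `uncallable`). Defaults to all callable.
#' @param family Optional result of [flag_paralogs_family()].
#' @param population Optional `marker_flags` from
#'   [flag_population_markers()].
#' @return An object of class `validation_report`: list with `per_marker`
#'   (marker, status, sub-flags) and `counts` (status tally).
#' @export
classify_markers <- function(markers, counts = NULL, callable = NULL,
                             family = NULL, population = NULL) {
  if (length(markers) == 0L) {
    return(structure(list(per_marker = data.frame(), counts = table(character())),
                     class = "validation_report"))
  }
  status <- rep("validated", length(markers))
  names(status) <- markers
  par_pop <- stats::setNames(rep(FALSE, length(markers)), markers)
  null_al <- par_pop
  par_fam <- par_pop
  if (!is.null(population)) {
    idx <- match(population$marker, markers)
    par_pop[idx[!is.na(idx)]] <- population$paralog_population[!is.na(idx)]
    null_al[idx[!is.na(idx)]] <- population$null_allele[!is.na(idx)]
    status[names(par_pop)[par_pop]] <- "paralog_population"
    status[names(null_al)[null_al & !par_pop]] <- "null_allele"
  }
  if (!is.null(family)) {
    idx <- match(family$marker, markers)
    par_fam[idx[!is.na(idx)]] <- family$paralog_family[!is.na(idx)]
    status[names(par_fam)[par_fam]] <- "paralog_family"
    mono <- family$marker[family$status %in% c("monomorphic", "untested_missing")]
    status[intersect(mono, markers)] <- "monomorphic"
  }
  if (!is.null(callable)) {
    status[names(callable)[!callable]] <- "uncallable"
  }
  if (!is.null(counts)) {
    dead <- rownames(counts$counts)[rowSums(counts$counts) == 0]
    status[intersect(dead, markers)] <- "no_reads"
  }
  per <- data.frame(marker = markers, status = unname(status[markers]),
                    paralog_family = unname(par_fam[markers]),
                    paralog_population = unname(par_pop[markers]),
                    null_allele = unname(null_al[markers]),
                    stringsAsFactors = FALSE)
  per$validated <- per$status == "validated"
  structure(list(per_marker = per,
                 counts = table(factor(per$status,
                                       levels = c("no_reads", "uncallable",
                                                  "monomorphic", "paralog_family",
                                                  "paralog_population",
                                                  "null_allele", "validated")))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", nrow(x$per_marker), "markers\n")
  print(x$counts)
  invisible(x)
}
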