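# Per-probe capture performance. The Fraction of Mapped Reads (FMR) is a
# probe's share of all on-target reads within one sample; its per-sample
# columns therefore sum to one, and any per-sample rescaling of counts
# leaves it unchanged.

#' Compute the FMR matrix from read counts
#'
#' `FMR[i, s] = counts[i, s] / sum_j counts[j, s]`. When per-sample
#' off-target totals are present, the per-sample on-target fraction
#' `on / (on + off)` is computed as well.
#'
#' @param cm A [count_matrix()].
#' @return An object of class `fmr_matrix`: list with `fmr` (markers x
#'   samples, columns summing to 1) and `on_target_fraction` (per sample,
#'   or `NULL`).
#' @export
compute_fmr <- function(cm) {
  tot <- colSums(cm$counts)
  zero <- names(tot)[tot == 0]
  if (length(zero) > 0L) {
    stop("sample(s) with no mapped reads: ", paste(zero, collapse = ", "))
  }
  fmr <- sweep(cm$counts, 2, tot, "/")
  otf <- if (!is.null(cm$off_target)) tot / (tot + cm$off_target) else NULL
  structure(list(fmr = fmr, on_target_fraction = otf), class = "fmr_matrix")
}

#' @export
print.fmr_matrix <- function(x, ...) {
  cat("fmr_matrix:", nrow(x$fmr), "markers x", ncol(x$fmr), "samples")
  if (!is.null(x$on_target_fraction)) {
    cat(sprintf("; mean on-target %.1f%%", 100 * mean(x$on_target_fraction)))
  }
  cat("\n")
  invisible(x)
}

#' Summarize capture uniformity
#'
#' Reports per-marker median FMR, the best "decade" fraction — the maximal
#' share of markers whose medians fall into a sliding 10-fold window
#' `[x, 10x]`, each observed median tried as the anchor — and per-marker
#' cross-sample fold p90/p10 (type-7 percentiles) with the fraction of
#' markers under 5-fold. Markers with zero median FMR (dropouts) are
#' excluded from the metrics and counted separately.
#'
#' @param fmr An `fmr_matrix`.
#' @return List: `median_fmr` (named, all markers), `n_zero_median`,
#'   `decade_fraction`, `decade_window` (the winning `[x, 10x]`),
#'   `fold` (named p90/p10 per non-zero marker), `frac_fold_lt5`.
#' @export
summarize_uniformity <- function(fmr) {
  m <- fmr$fmr
  stopifnot(nrow(m) >= 2L, ncol(m) >= 1L)
  med <- apply(m, 1, stats::median)
  nz <- med > 0
  med_nz <- med[nz]
  frac <- vapply(med_nz, function(x) mean(med_nz >= x & med_nz <= 10 * x),
                 numeric(1))
  best <- which.max(frac)
  q <- t(apply(m[nz, , drop = FALSE], 1, stats::quantile,
               probs = c(0.1, 0.9), type = 7))
  fold <- ifelse(q[, 1] > 0, q[, 2] / q[, 1], Inf)
  names(fold) <- rownames(m)[nz]
  list(median_fmr = med,
       n_zero_median = sum(!nz),
       decade_fraction = unname(frac[best]),
       decade_window = c(med_nz[best], 10 * med_nz[best]),
       fold = fold,
       frac_fold_lt5 = mean(fold < 5))
}

#' Select probes for pool rebalancing
#'
#' Markers whose median FMR falls below `low_cut` get their concentration
#' boosted (default 100x); the `n_top` best-performing markers get theirs
#' reduced (default to 0.1x); everything else stays at 1.
#'
#' @param median_fmr Named per-marker median FMR.
#' @param low_cut Boost threshold (default 0.001).
#' @param n_top Number of top markers to reduce (default 1).
#' @param boost,reduce Concentration multipliers (defaults 100 and 0.1).
#' @return Named numeric vector of concentration factors.
#' @export
select_rebalancing <- function(median_fmr, low_cut = 0.001, n_top = 1,
                               boost = 100, reduce = 0.1) {
  stopifnot(low_cut > 0 || low_cut == 0, n_top >= 0)
  low <- which(median_fmr < low_cut)
  top <- if (n_top > 0) order(median_fmr, decreasing = TRUE)[seq_len(n_top)] else integer(0)
  if (length(intersect(low, top)) > 0L) {
    stop("marker(s) selected for both boost and reduction: ",
         paste(names(median_fmr)[intersect(low, top)], collapse = ", "))
  }
  f <- rep(1, length(median_fmr))
  names(f) <- names(median_fmr)
  f[low] <- boost
  f[top] <- reduce
  f
}
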