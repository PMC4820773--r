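# Exon boundary identification in transcripts via local alignment to
# ortholog gene models. Transcripts come from an assembly of the study
# species; the models from an annotated relative, so alignments tolerate
# substantial divergence but must stay colinear with the exon order.

#' Align a transcript to the exons of one gene model
#'
#' Runs a local alignment (match +1, mismatch -2, gap open 5, gap extend 2)
#' of the transcript against every exon of the gene, keeps hits of at least
#' `min_identity` percent identity over at least `min_len` aligned bases, and
#' chains the per-exon hits into a colinear, non-overlapping set maximizing
#' the total alignment score.
#'
#' @param transcript A DNA string (character scalar or `DNAString`).
#' @param exons Character vector of exon sequences in transcript order.
#' @param min_identity Minimum percent identity of a kept hit (default 60).
#' @param min_len Minimum aligned length of a kept hit in bp (default 30).
#' @return An object of class `exon_mapping`: list with `blocks`, a
#'   data.frame (`exon`, `t_start`, `t_end`, `e_start`, `e_end`, `pid`,
#'   `score`; transcript and exon intervals 0-based half-open) and
#'   `transcript_len`. Zero rows is a valid result.
#' @export
align_transcript_to_gene <- function(transcript, exons, min_identity = 60,
                                     min_len = 30) {
  tseq <- Biostrings::DNAString(as.character(transcript))
  stopifnot(length(tseq) > 0L, length(exons) > 0L, all(nchar(exons) > 0L))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = TRUE)
  hits <- lapply(seq_along(exons), function(i) {
    aln <- Biostrings::pairwiseAlignment(tseq, Biostrings::DNAString(exons[i]),
                                         type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 5, gapExtension = 2)
    alen <- Biostrings::nchar(aln)
    pid <- Biostrings::pid(aln)
    if (alen < min_len || pid < min_identity) return(NULL)
    pat <- Biostrings::pattern(aln); sub <- Biostrings::subject(aln)
    data.frame(exon = i,
               t_start = Biostrings::start(pat) - 1L,
               t_end = Biostrings::end(pat),
               e_start = Biostrings::start(sub) - 1L,
               e_end = Biostrings::end(sub),
               pid = pid, score = Biostrings::score(aln))
  })
  blocks <- do.call(rbind, hits)
  if (is.null(blocks)) {
    blocks <- data.frame(exon = integer(), t_start = integer(), t_end = integer(),
                         e_start = integer(), e_end = integer(),
                         pid = numeric(), score = numeric())
  } else {
    blocks <- chain_blocks(blocks)
  }
  structure(list(blocks = blocks, transcript_len = length(tseq)),
            class = "exon_mapping")
}

# Weighted colinear chaining: keep a subset of blocks with strictly
# increasing exon index and non-overlapping, increasing transcript
# intervals, maximizing summed alignment score. O(n^2) DP; n is tiny.
chain_blocks <- function(blocks) {
  b <- blocks[order(blocks$t_start, blocks$exon), , drop = FALSE]
  n <- nrow(b)
  best <- b$score
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (b$t_end[j] <= b$t_start[i] && b$exon[j] < b$exon[i] &&
          best[j] + b$score[i] > best[i]) {
        best[i] <- best[j] + b$score[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  keep <- integer()
  while (i > 0L) { keep <- c(i, keep); i <- prev[i] }
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.exon_mapping <- function(x, ...) {
  cat("exon_mapping:", nrow(x$blocks), "block(s) on a", x$transcript_len,
      "bp transcript\n")
  invisible(x)
}

#' Total chained alignment score of a mapping
#' @param mapping An `exon_mapping`.
#' @return Numeric scalar (0 for an empty mapping).
#' @export
mapping_score <- function(mapping) {
  if (nrow(mapping$blocks) == 0L) 0 else sum(mapping$blocks$score)
}

# k-mer seeding: number of distinct transcript k-mers occurring in any
# exon of the gene. Chance hits between unrelated sequences of a few kb
# are near zero at k = 12, so genes below min_seed_hits are skipped
# without alignment.
kmer_hits <- function(transcript, exons, k = 12L) {
  tk <- unique_kmers(transcript, k)
  ek <- unlist(lapply(exons, unique_kmers, k = k))
  length(intersect(tk, unique(ek)))
}

unique_kmers <- function(seq, k) {
  seq <- as.character(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Assign a transcript to its best-matching gene model
#'
#' Genes are first screened by shared 12-mer seeds; genes passing the
#' screen are aligned and the top-scoring gene is returned
#' only when the runner-up's chained score stays below `ambiguity_margin`
#' times the best score. Ties or near-ties (e.g. recent paralogs) yield
#' `"AMBIGUOUS"`; no gene with any block yields `"NO_HIT"`. The result does
#' not depend on the order of genes in `models`.
#'
#' @param transcript A DNA string.
#' @param models A `gene_model_set`.
#' @param ambiguity_margin Runner-up/best score ratio above which the
#'   assignment is ambiguous (default 0.8).
#' @param min_seed_hits Minimum shared 12-mers for a gene to be aligned at
#'   all (default 2).
#' @inheritParams align_transcript_to_gene
#' @return List with `status` (`"OK"`, `"AMBIGUOUS"`, `"NO_HIT"`), `gene_id`
#'   (`NA` unless OK) and `mapping` (the winning `exon_mapping`, or `NULL`).
#' @export
assign_best_gene <- function(transcript, models, ambiguity_margin = 0.8,
                             min_identity = 60, min_len = 30,
                             min_seed_hits = 2L) {
  stopifnot(length(models) > 0L)
  ids <- sort(names(models))
  hits <- vapply(ids, function(g) kmer_hits(transcript, models[[g]]$exons),
                 numeric(1))
  maps <- lapply(ids, function(g) {
    if (hits[[g]] < min_seed_hits) return(NULL)
    align_transcript_to_gene(transcript, models[[g]]$exons,
                             min_identity = min_identity, min_len = min_len)
  })
  scores <- vapply(maps, function(m) if (is.null(m)) 0 else mapping_score(m),
                   numeric(1))
  if (all(scores <= 0)) {
    return(list(status = "NO_HIT", gene_id = NA_character_, mapping = NULL))
  }
  ord <- order(scores, decreasing = TRUE)
  best <- scores[ord[1]]
  runner <- if (length(scores) > 1L) scores[ord[2]] else 0
  if (runner >= ambiguity_margin * best) {
    return(list(status = "AMBIGUOUS", gene_id = NA_character_, mapping = NULL))
  }
  list(status = "OK", gene_id = ids[ord[1]], mapping = maps[[ord[1]]])
}

#' Call exon boundaries from a chained mapping
#'
#' Places one boundary per adjacent block pair: at the shared endpoint when
#' the blocks abut, otherwise at the midpoint of the inter-block gap (ties
#' resolved toward the lower coordinate). A single-block mapping yields no
#' boundaries (single-exon transcript). Junction gaps wider than `max_gap`
#' are flagged low-confidence.
#'
#' @param mapping An `exon_mapping` with at least one block.
#' @param max_gap Gap width (bp) above which a boundary is low-confidence
#'   (default 30).
#' @return An object of class `boundary_set`: list with `boundaries`
#'   (integer vector, strictly increasing, transcript coordinates),
#'   `confidence` (`"high"`/`"low"` per boundary) and `transcript_len`.
#' @export
call_boundaries <- function(mapping, max_gap = 30) {
  b <- mapping$blocks
  stopifnot(nrow(b) >= 1L)
  if (nrow(b) > 1L && any(b$t_start[-1] < b$t_end[-nrow(b)])) {
    stop("mapping blocks overlap in transcript coordinates")
  }
  bounds <- integer(0); conf <- character(0)
  if (nrow(b) > 1L) {
    for (i in seq_len(nrow(b) - 1L)) {
      gap <- b$t_start[i + 1L] - b$t_end[i]
      pos <- (b$t_end[i] + b$t_start[i + 1L]) %/% 2L
      bounds <- c(bounds, pos)
      conf <- c(conf, if (gap > max_gap) "low" else "high")
    }
  }
  stopifnot(all(bounds > 0L), all(bounds < mapping$transcript_len),
            !is.unsorted(bounds, strictly = TRUE))
  structure(list(boundaries = bounds, confidence = conf,
                 transcript_len = mapping$transcript_len),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("boundary_set:", length(x$boundaries), "boundaries in", x$transcript_len,
      "bp:", paste(x$boundaries, collapse = ", "), "\n")
  invisible(x)
}

#' Exon blocks of a transcript implied by its boundary set
#'
#' @param boundaries A `boundary_set`.
#' @return data.frame with 0-based half-open `start`, `end` per exon block.
#' @export
exon_blocks <- function(boundaries) {
  edges <- c(0L, boundaries$boundaries, boundaries$transcript_len)
  data.frame(start = edges[-length(edges)], end = edges[-1])
}
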