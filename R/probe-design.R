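# MIP probe design. A probe is a 70-nt oligo: 5' ligation arm (20-24 nt) +
# 30-nt common linker + 3' extension arm (16-20 nt). The two arms hybridize
# to the plus strand flanking a target of >= 112 bp; gap filling copies the
# target into the circularized probe. Arms always sum to 40 nt so the oligo
# is exactly 70 nt.

#' Default 30-nt linker joining the two arms
#'
#' A fixed spacer free of long self-complementary stretches, used when the
#' run configuration supplies none. Any 30-mer carrying the PCR primer
#' sites of the chosen amplification chemistry may be substituted.
#' @export
MIP_LINKER <- "CTTCAGCTTCCCGATATCCGACGGTAGTGT"

ARM_EXT_RANGE <- 16:20
ARM_TOTAL <- 40L

#' Find species-diagnostic SNPs in a resequencing panel
#'
#' A site is diagnostic when every panel individual is called and
#' homozygous, all individuals of one species share one allele, all of the
#' other species share another, and the two alleles differ. Such sites are
#' maximally informative for mapping in interspecific crosses.
#'
#' @param panel A [genotype_table()] of the resequenced individuals.
#' @param design A [study_design()] whose `population` roles name the two
#'   species.
#' @return data.frame with `marker`, `pos`, `allele1`, `allele2` (allele
#'   indices of species 1 and 2, in alphabetical species order).
#' @export
find_diagnostic_snps <- function(panel, design) {
  sp <- population_samples(design)
  if (length(sp) != 2L) stop("need exactly 2 species groups, found ", length(sp))
  missing_samp <- setdiff(unlist(sp), panel$samples)
  if (length(missing_samp) > 0L) {
    stop("species assignment names unknown sample(s): ",
         paste(missing_samp, collapse = ", "))
  }
  sp <- sp[order(names(sp))]
  g1 <- panel$gt[, sp[[1]], drop = FALSE]
  g2 <- panel$gt[, sp[[2]], drop = FALSE]
  hom_allele <- function(g) {
    # per row: the shared homozygous allele index, or NA
    apply(g, 1, function(r) {
      if (any(is.na(r))) return(NA_integer_)
      al <- strsplit(r, "/", fixed = TRUE)
      if (any(vapply(al, function(a) a[1] != a[2], logical(1)))) return(NA_integer_)
      u <- unique(vapply(al, `[`, character(1), 1L))
      if (length(u) == 1L) as.integer(u) else NA_integer_
    })
  }
  a1 <- hom_allele(g1); a2 <- hom_allele(g2)
  keep <- !is.na(a1) & !is.na(a2) & a1 != a2
  data.frame(marker = panel$sites$marker[keep], pos = panel$sites$pos[keep],
             allele1 = a1[keep], allele2 = a2[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enumerate exon-contained candidate target windows
#'
#' Lists every window `[s, e)` of the requested target length whose probe
#' footprint stays inside a single exon block for at least the minimal arm
#' lengths (ligation 20 nt to the left, extension 16 nt to the right).
#' Arm-length feasibility for the full 40-nt arm budget is re-checked by
#' [design_arms()].
#'
#' @param transcript_len Transcript length in bp.
#' @param boundaries A `boundary_set` for the transcript (from
#'   [call_boundaries()]), or `NULL` for a single-exon transcript.
#' @param target_len Target length(s) in bp; each must lie in `[100, 300]`.
#' @param boundary_margin Safety margin in bp kept clear of *internal*
#'   (called, hence uncertain) exon boundaries; transcript ends are exact
#'   and get no margin. Default 0.
#' @return data.frame of candidate windows: `s`, `e`, `block_start`,
#'   `block_end` (all 0-based half-open, transcript coordinates), ordered by
#'   position. Possibly zero rows.
#' @export
enumerate_targets <- function(transcript_len, boundaries = NULL,
                              target_len = 112, boundary_margin = 0) {
  stopifnot(all(target_len >= 100), all(target_len <= 300))
  blocks <- if (is.null(boundaries)) {
    data.frame(start = 0L, end = transcript_len)
  } else exon_blocks(boundaries)
  lig_min <- min(ARM_TOTAL - ARM_EXT_RANGE)  # 20
  ext_min <- min(ARM_EXT_RANGE)              # 16
  out <- list()
  for (L in sort(unique(target_len))) {
    for (k in seq_len(nrow(blocks))) {
      pad_lo <- if (blocks$start[k] > 0L) boundary_margin else 0L
      pad_hi <- if (blocks$end[k] < transcript_len) boundary_margin else 0L
      s_lo <- blocks$start[k] + lig_min + pad_lo
      s_hi <- blocks$end[k] - ext_min - L - pad_hi
      if (s_hi < s_lo) next
      s <- s_lo:s_hi
      out[[length(out) + 1L]] <- data.frame(
        s = s, e = s + L, block_start = blocks$start[k], block_end = blocks$end[k])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(s = integer(), e = integer(),
                      block_start = integer(), block_end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$s, res$e), , drop = FALSE]
}

#' Choose arm lengths for a target window by melting temperature
#'
#' Among the admissible `(extension, ligation)` length pairs — extension
#' 16-20 nt, ligation `40 - extension` nt, both arms inside the exon block —
#' picks the pair minimizing `|Tm_ext - t_opt| + |Tm_lig - t_opt|`. Ties go
#' to the smaller arm-Tm difference, then the shorter extension arm. The
#' score is the negated Tm cost, so higher is better.
#'
#' @param seq Transcript sequence (plus strand, character).
#' @param s,e Target window, 0-based half-open.
#' @param block_start,block_end Exon block containing the window.
#' @param t_opt Optimal arm melting temperature in degrees C (default 60).
#' @param profile Optional precomputed Tm profile of `seq` (internal reuse
#'   across windows of one transcript).
#' @return List: `ext_len`, `lig_len`, `ext_arm`, `lig_arm` (probe-oriented,
#'   i.e. reverse complements of the flanking plus strand), `tm_ext`,
#'   `tm_lig`, `score`.
#' @export
design_arms <- function(seq, s, e, block_start = 0L,
                        block_end = nchar(seq), t_opt = 60, profile = NULL) {
  seq <- as.character(seq)
  if (is.null(profile)) profile <- tm_profile(seq)
  cand <- list()
  for (ext in ARM_EXT_RANGE) {
    lig <- ARM_TOTAL - ext
    if (s - lig < block_start || e + ext > block_end) next
    ext_site <- substr(seq, e + 1L, e + ext)       # plus strand [e, e+ext)
    lig_site <- substr(seq, s - lig + 1L, s)       # plus strand [s-lig, s)
    ext_arm <- revcomp(ext_site)
    lig_arm <- revcomp(lig_site)
    tm_e <- profile(e, e + ext); tm_l <- profile(s - lig, s)
    cand[[length(cand) + 1L]] <- list(
      ext_len = ext, lig_len = lig, ext_arm = ext_arm, lig_arm = lig_arm,
      tm_ext = tm_e, tm_lig = tm_l,
      cost = abs(tm_e - t_opt) + abs(tm_l - t_opt))
  }
  if (length(cand) == 0L) {
    stop("no admissible arm-length pair fits the exon block for window [",
         s, ",", e, ")")
  }
  cost <- vapply(cand, `[[`, numeric(1), "cost")
  dtm <- vapply(cand, function(x) abs(x$tm_ext - x$tm_lig), numeric(1))
  ext <- vapply(cand, `[[`, numeric(1), "ext_len")
  best <- cand[[order(cost, dtm, ext)[1]]]
  best$score <- -best$cost
  best$cost <- NULL
  best
}

#' Assemble a MIP probe record
#'
#' Builds the 70-nt oligo `ligation arm + linker + extension arm` (5'->3')
#' for a designed window. With the captured plus strand as template, the
#' extension arm is the reverse complement of plus-strand `[e, e+len_ext)`
#' and the ligation arm the reverse complement of `[s-len_lig, s)`.
#'
#' @param marker_id Probe/marker name.
#' @param transcript_id Source transcript id.
#' @param seq Transcript sequence.
#' @param s,e Target window (0-based half-open).
#' @param arms Result of [design_arms()].
#' @param linker 30-nt linker sequence (default [MIP_LINKER]).
#' @param gene_id Optional source gene id.
#' @return One-row data.frame of class `mip_probe` with the probe fields
#'   (arms, linker, full `probe_seq`, target coordinates, Tm values, score,
#'   `concentration_factor = 1`).
#' @export
assemble_probe <- function(marker_id, transcript_id, seq, s, e, arms,
                           linker = MIP_LINKER, gene_id = NA_character_) {
  seq <- as.character(seq)
  if (nchar(linker) != 30L) stop("linker must be 30 nt, got ", nchar(linker))
  if (!(arms$ext_len %in% 16:20) || !(arms$lig_len %in% 20:24) ||
      arms$ext_len + arms$lig_len != 40L) {
    stop("invalid arm lengths: ext ", arms$ext_len, ", lig ", arms$lig_len)
  }
  if (e - s < 100L) stop("target shorter than 100 bp")
  if (s - arms$lig_len < 0L || e + arms$ext_len > nchar(seq)) {
    stop("arm footprint outside transcript")
  }
  if (!identical(arms$ext_arm, revcomp(substr(seq, e + 1L, e + arms$ext_len))) ||
      !identical(arms$lig_arm, revcomp(substr(seq, s - arms$lig_len + 1L, s)))) {
    stop("arms do not match the flanks of [", s, ",", e, ")")
  }
  probe_seq <- paste0(arms$lig_arm, linker, arms$ext_arm)
  stopifnot(nchar(probe_seq) == 70L)
  structure(data.frame(
    marker_id = marker_id, transcript_id = transcript_id, gene_id = gene_id,
    s = s, e = e, target_len = e - s,
    ext_arm = arms$ext_arm, lig_arm = arms$lig_arm, linker = linker,
    probe_seq = probe_seq, tm_ext = arms$tm_ext, tm_lig = arms$tm_lig,
    score = arms$score, concentration_factor = 1,
    stringsAsFactors = FALSE
  ), class = c("mip_probe", "data.frame"))
}

#' Simulate capture of a probe on a reference sequence
#'
#' Locates the single perfect-match site of each arm on the reference plus
#' strand, checks the geometry (ligation-arm site strictly upstream of the
#' extension-arm site), and reconstructs the gap-filled insert between them.
#' The insert is returned in plus-strand orientation and must equal the
#' designed target.
#'
#' @param probe A `mip_probe` row.
#' @param ref Reference sequence (character or `DNAString`).
#' @return List: `status` (`"ok"` or `"multi_site"`), `insert`, `s`, `e`
#'   (insert interval on the reference), and for multi-site cases the match
#'   loci per arm. Geometry violations are errors.
#' @export
in_silico_capture_check <- function(probe, ref) {
  ref <- Biostrings::DNAString(as.character(ref))
  ext_site <- Biostrings::DNAString(revcomp(probe$ext_arm))  # plus-strand site
  lig_site <- Biostrings::DNAString(revcomp(probe$lig_arm))
  ext_hits <- Biostrings::matchPattern(ext_site, ref)
  lig_hits <- Biostrings::matchPattern(lig_site, ref)
  if (length(ext_hits) == 0L && length(lig_hits) == 0L) {
    # the target may sit on the reference minus strand; capture geometry is
    # strand-symmetric, so check against the reverse complement
    rc <- Biostrings::reverseComplement(ref)
    if (length(Biostrings::matchPattern(ext_site, rc)) > 0L) {
      return(in_silico_capture_check(probe, as.character(rc)))
    }
  }
  if (length(ext_hits) == 0L || length(lig_hits) == 0L) {
    stop("arm has no perfect-match site on the reference")
  }
  if (length(ext_hits) > 1L || length(lig_hits) > 1L) {
    loci <- list(ext = BiocGenerics::start(ext_hits) - 1L,
                 lig = BiocGenerics::start(lig_hits) - 1L)
    warning("arm matches multiple loci (ext: ", length(ext_hits),
            ", lig: ", length(lig_hits), ")")
    return(list(status = "multi_site", insert = NA_character_,
                s = NA_integer_, e = NA_integer_, loci = loci))
  }
  lig_end <- BiocGenerics::end(lig_hits)          # 1-based closed end == s
  ext_start <- BiocGenerics::start(ext_hits) - 1L # 0-based start == e
  s <- lig_end; e <- ext_start
  if (e <= s) stop("arm sites out of order on the reference (geometry error)")
  # gap fill runs 3'->5' along the template, i.e. synthesizes the reverse
  # complement of plus-strand [s, e); report in plus orientation
  synthesized <- revcomp(as.character(Biostrings::subseq(ref, s + 1L, e)))
  insert <- revcomp(synthesized)
  if (!is.null(probe$target_len) && nchar(insert) != probe$target_len) {
    stop("gap-filled insert length ", nchar(insert),
         " differs from designed target ", probe$target_len)
  }
  list(status = "ok", insert = insert, s = s, e = e)
}

#' Design every candidate probe for one transcript
#'
#' Enumerates exon-contained windows and designs arms for each, silently
#' dropping windows with no admissible arm pair.
#'
#' @param transcript_id Transcript id.
#' @param seq Transcript sequence.
#' @param boundaries `boundary_set` or `NULL` (single exon).
#' @param target_len Target length(s).
#' @param t_opt Optimal arm Tm.
#' @param linker Linker sequence.
#' @param gene_id Optional gene id annotation.
#' @param boundary_margin Safety margin (bp) kept clear of internal exon
#'   boundaries (default 5, absorbing typical boundary-call uncertainty).
#' @return data.frame of `mip_probe` rows (possibly empty).
#' @export
design_candidates <- function(transcript_id, seq, boundaries = NULL,
                              target_len = 112, t_opt = 60,
                              linker = MIP_LINKER, gene_id = NA_character_,
                              boundary_margin = 5) {
  seq <- as.character(seq)
  if (nchar(linker) != 30L) stop("linker must be 30 nt")
  wins <- enumerate_targets(nchar(seq), boundaries, target_len, boundary_margin)
  profile <- tm_profile(seq)
  arms <- lapply(seq_len(nrow(wins)), function(i) {
    tryCatch(design_arms(seq, wins$s[i], wins$e[i], wins$block_start[i],
                         wins$block_end[i], t_opt = t_opt, profile = profile),
             error = function(e) NULL)
  })
  keep <- !vapply(arms, is.null, logical(1))
  if (!any(keep)) return(data.frame())
  wins <- wins[keep, , drop = FALSE]
  arms <- arms[keep]
  pull <- function(f, mode = numeric(1)) vapply(arms, `[[`, mode, f)
  ext_arm <- pull("ext_arm", character(1))
  lig_arm <- pull("lig_arm", character(1))
  out <- data.frame(
    marker_id = paste0(transcript_id, "_", wins$s, "_", wins$e),
    transcript_id = transcript_id, gene_id = gene_id,
    s = wins$s, e = wins$e, target_len = wins$e - wins$s,
    ext_arm = ext_arm, lig_arm = lig_arm, linker = linker,
    probe_seq = paste0(lig_arm, linker, ext_arm),
    tm_ext = pull("tm_ext"), tm_lig = pull("tm_lig"),
    score = pull("score"), concentration_factor = 1,
    stringsAsFactors = FALSE)
  class(out) <- c("mip_probe", "data.frame")
  rownames(out) <- NULL
  out
}

#' Filter candidates and select one probe per gene
#'
#' Keeps candidates whose target contains at least one diagnostic SNP and
#' whose score passes `score_cutoff`; optionally rejects candidates with a
#' known polymorphic site inside an arm (limits allele dropout). Candidates
#' are then grouped by gene and one is drawn uniformly at random per gene.
#' Selection is a function of the candidate set and the seed only: inputs
#' are sorted before sampling, so input order never changes the panel.
#'
#' @param candidates data.frame of `mip_probe` rows annotated with `gene_id`
#'   and `transcript_id`.
#' @param diagnostics Diagnostic sites (data.frame `marker`, `pos` with
#'   `marker` matching `transcript_id`).
#' @param seed Integer seed for the per-gene draw (mandatory).
#' @param score_cutoff Minimum score (default `-Inf`, i.e. no cutoff).
#' @param arms_snp_free Reject candidates with a polymorphic site inside an
#'   arm footprint (default `TRUE`).
#' @param polymorphic_sites Optional data.frame (`marker`, `pos`) of all
#'   known polymorphic sites for the arm policy; defaults to `diagnostics`.
#' @return data.frame of selected `mip_probe` rows, one per gene.
#' @export
rank_and_select <- function(candidates, diagnostics, seed,
                            score_cutoff = -Inf, arms_snp_free = TRUE,
                            polymorphic_sites = diagnostics) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for panel selection")
  if (nrow(candidates) == 0L) return(candidates)
  cand <- candidates[order(candidates$gene_id, candidates$transcript_id,
                           candidates$s, candidates$e, nchar(candidates$ext_arm)), ,
                     drop = FALSE]
  has_diag <- vapply(seq_len(nrow(cand)), function(i) {
    d <- diagnostics[diagnostics$marker == cand$transcript_id[i], , drop = FALSE]
    any(d$pos >= cand$s[i] & d$pos < cand$e[i])
  }, logical(1))
  ok <- has_diag & cand$score >= score_cutoff
  if (arms_snp_free && nrow(polymorphic_sites) > 0L) {
    in_arm <- vapply(seq_len(nrow(cand)), function(i) {
      p <- polymorphic_sites[polymorphic_sites$marker == cand$transcript_id[i], , drop = FALSE]
      lig_len <- nchar(cand$lig_arm[i]); ext_len <- nchar(cand$ext_arm[i])
      any((p$pos >= cand$s[i] - lig_len & p$pos < cand$s[i]) |
            (p$pos >= cand$e[i] & p$pos < cand$e[i] + ext_len))
    }, logical(1))
    ok <- ok & !in_arm
  }
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  picked <- integer(0)
  rng <- local_rng(seed)
  for (g in sort(unique(cand$gene_id))) {
    idx <- which(cand$gene_id == g)
    picked <- c(picked, idx[rng$sample_int(length(idx))])
  }
  out <- cand[picked, , drop = FALSE]
  rownames(out) <- NULL
  out
}
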