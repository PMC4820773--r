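#' Load transcript or genome sequences from FASTA
#'
#' Reads a DNA FASTA file into a [Biostrings::DNAStringSet], uppercasing
#' sequences and validating that every record has a non-empty, unique id and
#' a sequence of length at least one over the alphabet `A,C,G,T,N`.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`.
#' @export
load_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file is empty: ", path)
  # keep only the first whitespace-delimited token as the id, like most tools
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(seqs) < 1L)) stop("zero-length sequence in ", path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", as.character(seqs))
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs A named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Ortholog gene models as ordered exon sequences
#'
#' Constructs a `gene_model_set`: for every gene an ordered list of exon
#' sequences (5'->3' in transcript order) with their source coordinates.
#' Internal coordinates are 0-based half-open; conversion from GFF's 1-based
#' closed convention happens here and only here.
#'
#' @param gff Path to a GFF3 file with exon features whose attributes resolve
#'   to a gene id (attribute `gene_id`, `gene`, `Parent` or `ID`, first found).
#' @param genome Path to the genome FASTA the GFF coordinates refer to.
#' @return An object of class `gene_model_set`: a named list, one element per
#'   gene, each a list with `exons` (character vector of exon sequences in
#'   transcript order) and `coords` (data.frame with `chrom`, `start`, `end`
#'   0-based half-open, `strand`).
#' @export
load_gene_models <- function(gff, genome) {
  gr <- rtracklayer::import(gff)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", gff)
  md <- S4Vectors::mcols(gr)
  gene_ids <- NULL
  for (key in c("gene_id", "gene", "Parent", "ID")) {
    if (key %in% colnames(md)) {
      v <- md[[key]]
      if (methods::is(v, "List")) v <- vapply(v, function(x) x[1], character(1))
      v <- as.character(v)
      if (!all(is.na(v))) { gene_ids <- v; break }
    }
  }
  if (is.null(gene_ids)) stop("exon features carry no resolvable gene attribute")
  gseq <- load_sequences(genome)
  build_gene_models(
    data.frame(
      gene = gene_ids,
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      # GFF 1-based closed -> 0-based half-open
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      stringsAsFactors = FALSE
    ),
    gseq
  )
}

#' Build a gene model set from an exon table and genome sequences
#'
#' Lower-level constructor behind [load_gene_models()], useful when exon
#' coordinates come from somewhere other than a GFF3 file.
#'
#' @param exons data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param gseq Named `DNAStringSet` of chromosome sequences.
#' @return A `gene_model_set`.
#' @export
build_gene_models <- function(exons, gseq) {
  stopifnot(all(c("gene", "chrom", "start", "end", "strand") %in% names(exons)))
  models <- list()
  for (g in unique(exons$gene)) {
    ex <- exons[exons$gene == g, , drop = FALSE]
    if (nrow(ex) == 0L) next
    strand <- ex$strand[1]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in gene ", g)
    }
    seqs <- character(nrow(ex))
    for (i in seq_len(nrow(ex))) {
      chrom <- ex$chrom[i]
      if (!chrom %in% names(gseq)) stop("unknown chromosome ", chrom, " for gene ", g)
      len <- length(gseq[[chrom]])
      if (ex$start[i] < 0L || ex$end[i] > len || ex$start[i] >= ex$end[i]) {
        stop("exon of gene ", g, " outside [0,", len, ") on ", chrom)
      }
      seqs[i] <- as.character(Biostrings::subseq(gseq[[chrom]], ex$start[i] + 1L, ex$end[i]))
    }
    if (identical(strand, "-")) {
      seqs <- rev(vapply(seqs, revcomp, character(1), USE.NAMES = FALSE))
      ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    }
    models[[g]] <- list(
      exons = seqs,
      coords = data.frame(chrom = ex$chrom, start = as.integer(ex$start),
                          end = as.integer(ex$end),
                          strand = ex$strand, stringsAsFactors = FALSE)
    )
  }
  empty <- setdiff(unique(exons$gene), names(models))
  if (length(empty) > 0L) warning("genes with zero exons skipped: ", paste(empty, collapse = ", "))
  structure(models, class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  nex <- vapply(x, function(g) length(g$exons), integer(1))
  cat("gene_model_set:", length(x), "genes,", sum(nex), "exons",
      sprintf("(%d-%d exons/gene)\n", min(nex), max(nex)))
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param x A single DNA string over `A,C,G,T,N`.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", as.character(x)), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

# ---- genotype tables --------------------------------------------------------

#' Construct a genotype table
#'
#' Sites x samples diploid genotypes with per-call depth (DP) and genotype
#' quality (GQ). Genotypes are stored as unphased allele-index strings
#' (`"0/1"`); `NA` is a missing call. Positions are 0-based within marker.
#'
#' @param sites data.frame with columns `marker`, `pos` (0-based), `ref`,
#'   `alt` (comma-separated alternate alleles, may be `""`).
#' @param samples Character vector of sample ids.
#' @param gt Character matrix sites x samples of `"a/b"` calls or `NA`.
#' @param dp,gq Numeric matrices of the same shape, `NA` where the
#'   annotation is absent.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(sites, samples, gt, dp = NULL, gq = NULL) {
  stopifnot(is.data.frame(sites), all(c("marker", "pos", "ref", "alt") %in% names(sites)))
  n_site <- nrow(sites); n_samp <- length(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  gt <- matrix(as.character(gt), n_site, n_samp)
  if (is.null(dp)) dp <- matrix(NA_real_, n_site, n_samp)
  if (is.null(gq)) gq <- matrix(NA_real_, n_site, n_samp)
  stopifnot(identical(dim(gt), dim(dp)), identical(dim(gt), dim(gq)))
  if (any(dp < 0, na.rm = TRUE) || any(gq < 0, na.rm = TRUE)) stop("negative DP or GQ")
  n_alt <- ifelse(nzchar(sites$alt), lengths(strsplit(sites$alt, ",", fixed = TRUE)), 0L)
  idx <- suppressWarnings(apply(gt, 2, function(col) {
    m <- regmatches(col, regexec("^([0-9]+)[/|]([0-9]+)$", col))
    ok <- lengths(m) == 3L
    a <- rep(NA_integer_, length(col)); b <- a
    a[ok] <- as.integer(vapply(m[ok], `[`, character(1), 2L))
    b[ok] <- as.integer(vapply(m[ok], `[`, character(1), 3L))
    pmax(a, b)
  }))
  idx <- matrix(idx, n_site, n_samp)
  bad <- which(idx > n_alt, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("allele index out of range at site ", bad[1, 1], " sample ", bad[1, 2])
  }
  dimnames(gt) <- dimnames(dp) <- dimnames(gq) <-
    list(paste(sites$marker, sites$pos, sep = ":"), samples)
  structure(list(sites = sites, samples = samples, gt = gt, dp = dp, gq = gq),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$sites), "sites x", length(x$samples), "samples;",
      length(unique(x$sites$marker)), "markers;",
      sum(is.na(x$gt)), "missing calls\n")
  invisible(x)
}

#' Number of sites in a genotype table
#' @param gt A `genotype_table`.
#' @return Integer count of sites.
#' @export
n_sites <- function(gt) nrow(gt$sites)

#' Read genotypes from a VCF file
#'
#' CHROM is interpreted as the marker id and POS (1-based) is converted to a
#' 0-based position within the marker. Per-call DP and GQ are read when
#' present in FORMAT; absent annotations are stored as `NA` (treated as
#' passing filters under the default lenient policy). Malformed GT fields
#' become missing calls, counted in `attr(,"n_malformed")`.
#'
#' @param path Path to a VCF (v4.x) file.
#' @return A [genotype_table()].
#' @export
load_genotypes <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  sites <- data.frame(
    marker = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = as.character(fix[, "REF"]),
    alt = ifelse(is.na(fix[, "ALT"]), "", as.character(fix[, "ALT"])),
    stringsAsFactors = FALSE
  )
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_raw)
  norm <- gsub("|", "/", gt_raw, fixed = TRUE)
  ok <- grepl("^[0-9]+/[0-9]+$", norm)
  n_malformed <- sum(!ok & !is.na(norm) & !grepl("^\\.?(/\\.)?\\.?$", norm))
  if (n_malformed > 0L) warning(n_malformed, " malformed GT field(s) set to missing")
  norm[!ok] <- NA_character_
  grab_num <- function(el) {
    m <- tryCatch(vcfR::extract.gt(v, element = el, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) matrix(NA_real_, nrow(sites), length(samples)) else m
  }
  out <- genotype_table(sites, samples, norm, grab_num("DP"), grab_num("GQ"))
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Write a genotype table as VCF
#'
#' Minimal VCF v4.2 writer, the inverse of [load_genotypes()]: marker ids go
#' to CHROM and 0-based positions become 1-based POS; DP and GQ are emitted
#' only when present.
#'
#' @param gt A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gt, path) {
  has_dp <- !all(is.na(gt$dp)); has_gq <- !all(is.na(gt$gq))
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ"), collapse = ":")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (has_gq) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            gt$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gt$sites)), function(i) {
    cells <- vapply(seq_along(gt$samples), function(j) {
      g <- gt$gt[i, j]
      parts <- c(if (is.na(g)) "./." else g,
                 if (has_dp) ifelse(is.na(gt$dp[i, j]), ".", format(gt$dp[i, j])),
                 if (has_gq) ifelse(is.na(gt$gq[i, j]), ".", format(gt$gq[i, j])))
      paste(parts, collapse = ":")
    }, character(1))
    alt <- gt$sites$alt[i]
    paste(c(gt$sites$marker[i], gt$sites$pos[i] + 1L, ".", gt$sites$ref[i],
            if (nzchar(alt)) alt else ".", ".", ".", ".", fmt, cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- count matrices ---------------------------------------------------------

#' Construct a read-count matrix
#'
#' @param counts Non-negative integer matrix, markers x samples, with unique
#'   dimnames.
#' @param off_target Optional named numeric vector of per-sample off-target
#'   read counts.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, off_target = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix needs marker rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("marker and sample labels must be unique")
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  if (!is.null(off_target)) {
    off_target <- off_target[colnames(counts)]
    if (any(is.na(off_target)) || any(off_target < 0)) {
      stop("off_target must cover every sample with non-negative counts")
    }
  }
  structure(list(counts = counts, off_target = off_target), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "markers x", ncol(x$counts), "samples,",
      format(sum(x$counts), big.mark = ","), "on-target reads\n")
  invisible(x)
}

#' Read per-marker read counts
#'
#' TSV input: header row of sample ids, first column marker ids, integer
#' cells. SAM input: one file per sample with marker ids as reference
#' names; only read pairs whose two mates map to the same marker are
#' counted (one count per pair), while unmapped reads and pairs split
#' across markers accumulate into the per-sample `off_target` total.
#'
#' @param path For TSV, a single file; for SAM, a character vector of files
#'   (one per sample, sample id taken from the file name).
#' @param format `"tsv"` or `"sam"`; guessed from the extension by default.
#' @return A [count_matrix()].
#' @export
load_counts <- function(path, format = c("auto", "tsv", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (all(grepl("\\.sam$", path, ignore.case = TRUE))) "sam" else "tsv"
  }
  if (format == "tsv") load_counts_tsv(path) else load_counts_sam(path)
}

load_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or headerless counts TSV: ", path)
  markers <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric count at row ", bad[1, 1], ", column ", bad[1, 2] + 1L)
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("negative or non-integer count at row ", bad[1, 1], " (", markers[bad[1, 1]],
         "), column ", bad[1, 2] + 1L)
  }
  rownames(m) <- markers
  count_matrix(m)
}

#' Write a count matrix as TSV
#' @param cm A `count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(marker = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Minimal SAM reading: FLAG, RNAME, RNEXT of primary records only. SAM
# support is read-only; mapping itself is out of scope, so no BAM layer.
load_counts_sam <- function(paths) {
  per_sample <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("SAM file not found: ", p)
    lines <- readLines(p)
    sq <- lines[startsWith(lines, "@SQ")]
    markers <- sub(".*SN:([^\t]+).*", "\\1", sq)
    lines <- lines[!startsWith(lines, "@")]
    counts <- stats::setNames(numeric(length(markers)), markers)
    off <- 0
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      flag <- as.integer(f[2]); rname <- f[3]; rnext <- f[7]
      if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) next
      if (bitwAnd(flag, 4L) > 0L || bitwAnd(flag, 8L) > 0L ||
          (rnext != "=" && rnext != rname)) {
        off <- off + 1
      } else {
        counts[rname] <- counts[rname] + 1
      }
    }
    if (any(counts %% 2 != 0)) warning("odd read count for a marker in ", p,
                                       "; expected complete pairs")
    list(counts = counts / 2, off = off)
  })
  samples <- tools::file_path_sans_ext(basename(paths))
  markers <- rownames <- names(per_sample[[1]]$counts)
  m <- vapply(per_sample, function(x) x$counts[markers], numeric(length(markers)))
  m <- matrix(m, nrow = length(markers), dimnames = list(markers, samples))
  count_matrix(m, stats::setNames(vapply(per_sample, `[[`, numeric(1), "off"), samples))
}

# ---- study designs ----------------------------------------------------------

#' Construct or read a study design
#'
#' Assigns each sample a role: `"parent"` or `"offspring"` (a family),
#' `"population"` with the population name in `group`, or `"replicate"`
#' with the replicated sample's id in `group`.
#'
#' @param x Either a data.frame with columns `sample_id`, `role`, `group`,
#'   or a path to a TSV with those columns.
#' @return An object of class `study_design` (a validated data.frame).
#' @export
study_design <- function(x) {
  df <- if (is.character(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE, colClasses = "character")
  } else as.data.frame(x, stringsAsFactors = FALSE)
  if (!"group" %in% names(df)) df$group <- ""
  stopifnot(all(c("sample_id", "role", "group") %in% names(df)))
  df$group[is.na(df$group)] <- ""
  ok_roles <- c("parent", "offspring", "population", "replicate")
  bad <- setdiff(unique(df$role), ok_roles)
  if (length(bad) > 0L) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design")
  n_par <- sum(df$role == "parent")
  if (n_par > 0L && n_par != 2L) stop("a family must have exactly 2 parents, found ", n_par)
  reps <- df[df$role == "replicate", ]
  missing_ref <- setdiff(reps$group, df$sample_id)
  if (length(missing_ref) > 0L) {
    stop("replicate-of references unknown sample(s): ", paste(missing_ref, collapse = ", "))
  }
  structure(df[, c("sample_id", "role", "group")], class = c("study_design", "data.frame"))
}

#' Write a study design as TSV
#' @param design A `study_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Samples belonging to each population in a design
#' @param design A `study_design`.
#' @return Named list of character vectors of sample ids, one per population.
#' @export
population_samples <- function(design) {
  pops <- design[design$role == "population", ]
  split(pops$sample_id, pops$group)
}

#' Replicate sample pairs in a design
#' @param design A `study_design`.
#' @return data.frame with columns `sample_a`, `sample_b`.
#' @export
replicate_pairs <- function(design) {
  reps <- design[design$role == "replicate", ]
  data.frame(sample_a = reps$group, sample_b = reps$sample_id,
             stringsAsFactors = FALSE)
}
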