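# NGS-like read processing and repertoire statistics: paired-end merge,
# three-frame translation, anchor-based extraction of diversified residues,
# uniqueness/cumulative-frequency summaries, enrichment ratios and the
# cap-driven training-set rule.

.revcomp <- function(dna) {
  vapply(dna, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Merge a forward/reverse read pair by exact overlap
#'
#' Joins a forward read to the reverse-complement of its mate at the longest
#' suffix/prefix overlap of at least `min_overlap` bases. Overlap matching is
#' exact by default; `max_mismatch` relaxes it.
#'
#' @param forward,reverse DNA reads over A/C/G/T/N (reverse as sequenced,
#'   i.e. it is reverse-complemented internally).
#' @param min_overlap Minimum acceptable overlap length.
#' @param max_mismatch Mismatches tolerated inside the overlap (default 0).
#' @return Merged DNA string, or `NA_character_` when no acceptable overlap
#'   exists.
#' @export
merge_read_pair <- function(forward, reverse, min_overlap = 10L,
                            max_mismatch = 0L) {
  stopifnot(length(forward) == 1L, length(reverse) == 1L)
  if (grepl("[^ACGTN]", forward) || grepl("[^ACGTN]", reverse))
    stop("reads must be over the alphabet A/C/G/T/N")
  rc <- .revcomp(reverse)
  nf <- nchar(forward); nr <- nchar(rc)
  fchars <- strsplit(forward, "")[[1]]
  rchars <- strsplit(rc, "")[[1]]
  for (k in seq(min(nf, nr), min_overlap)) {
    mism <- sum(fchars[(nf - k + 1L):nf] != rchars[1:k])
    if (mism <= max_mismatch)
      return(paste0(forward, substr(rc, k + 1L, nr)))
  }
  NA_character_
}

.translate_codons <- function(codons) {
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"   # any codon containing N or other ambiguity
  unname(aa)
}

#' Translate a DNA sequence in the three forward frames
#'
#' @param dna DNA string, length at least 3.
#' @return Character vector of 3 amino-acid strings (frames 0, 1, 2). Stops
#'   are `*`; codons containing N translate to `X`; trailing partial codons
#'   are dropped.
#' @export
translate_frames <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L, nchar(dna) >= 3L)
  vapply(0:2, function(off) {
    n <- nchar(dna) - off
    ncod <- n %/% 3L
    if (ncod == 0L) return("")
    starts <- off + 1L + 3L * (seq_len(ncod) - 1L)
    paste(.translate_codons(substring(dna, starts, starts + 2L)),
          collapse = "")
  }, "")
}

#' Read a framework template file
#'
#' The template is a single amino-acid string in which `X` marks diversified
#' positions (in design order) and every other residue is a constant
#' framework anchor. Lines starting with `#` are comments.
#'
#' @param path Path to the template file. Defaults to the bundled synthetic
#'   F02 scaffold.
#' @return The template string.
#' @export
read_template <- function(path = system.file("extdata",
                                             "f02_template_synthetic.txt",
                                             package = "phagelm",
                                             mustWork = TRUE)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 1L)
    stop("template file must contain exactly one sequence line")
  trimws(lines)
}

#' Extract diversified-residue vectors by framework anchor matching
#'
#' Locates the constant framework of `template` inside each translated read
#' by exact matching (diversified `X` slots match any residue) and pulls out
#' the residues at the diversified slots. A read fails if the framework does
#' not match exactly and in register (frameshifted or indel-containing
#' reads), and is rejected if a stop (`*`) or ambiguous (`X`) residue falls
#' in a diversified slot.
#'
#' @param aa_seqs Character vector of amino-acid sequences.
#' @param template Framework template string from [read_template()].
#' @return Character vector of extracted vectors, `NA` where extraction
#'   failed.
#' @export
extract_vectors <- function(aa_seqs, template) {
  slots <- gregexpr("X", template, fixed = TRUE)[[1]]
  if (slots[1] == -1L) stop("template has no diversified 'X' slot")
  pattern <- gsub("X", ".", template, fixed = TRUE)
  hit <- regexpr(pattern, aa_seqs)
  out <- rep(NA_character_, length(aa_seqs))
  ok <- hit != -1L
  if (any(ok)) {
    starts <- hit[ok]
    out[ok] <- vapply(seq_along(starts), function(i) {
      s <- aa_seqs[ok][i]
      paste(substring(s, starts[i] + slots - 1L, starts[i] + slots - 1L),
            collapse = "")
    }, "")
    bad <- grepl("[*X]", out[ok])
    out[ok][bad] <- NA_character_
  }
  out
}

#' Process reads into a counted vector table for one panning round
#'
#' Full read pipeline: (optionally) merge pairs, translate in three forward
#' frames, extract the diversified vector from the first frame in which the
#' framework matches, and tally counts per unique vector.
#'
#' @param fwd,rev Character vectors of DNA reads (`rev = NULL` for
#'   pre-merged reads), or paths to FASTQ files (detected by file existence;
#'   reading FASTQ requires the Biostrings package).
#' @param template Framework template string.
#' @param round_id Integer panning round label (0 = primary library).
#' @param min_overlap,max_mismatch Passed to [merge_read_pair()].
#' @return `data.frame(vector, count, round)` sorted by decreasing count,
#'   with attributes `n_reads`, `n_merged`, `n_extracted`.
#' @export
process_reads <- function(fwd, rev = NULL, template = read_template(),
                          round_id = 0L, min_overlap = 10L,
                          max_mismatch = 0L) {
  if (length(fwd) == 1L && file.exists(fwd)) fwd <- read_fastq(fwd)
  if (!is.null(rev) && length(rev) == 1L && file.exists(rev))
    rev <- read_fastq(rev)
  n_reads <- length(fwd)
  if (is.null(rev)) {
    merged <- fwd
  } else {
    stopifnot(length(rev) == n_reads)
    merged <- vapply(seq_len(n_reads), function(i)
      merge_read_pair(fwd[i], rev[i], min_overlap, max_mismatch), "")
    merged <- merged[!is.na(merged)]
  }
  n_merged <- length(merged)
  vecs <- rep(NA_character_, n_merged)
  for (off in 0:2) {
    todo <- is.na(vecs)
    if (!any(todo)) break
    aa <- vapply(merged[todo], function(d) translate_frames(d)[off + 1L], "",
                 USE.NAMES = FALSE)
    vecs[todo] <- extract_vectors(aa, template)
  }
  vecs <- vecs[!is.na(vecs)]
  tab <- sort(table(vecs), decreasing = TRUE)
  structure(
    data.frame(vector = names(tab), count = as.integer(tab),
               round = as.integer(round_id), stringsAsFactors = FALSE,
               row.names = NULL),
    n_reads = n_reads, n_merged = n_merged, n_extracted = length(vecs))
}

#' Read a FASTQ file into a character vector of sequences
#'
#' Thin wrapper over `Biostrings::readDNAStringSet(format = "fastq")`;
#' qualities are parsed but discarded.
#'
#' @param path FASTQ path.
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTQ requires the Biostrings package")
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Summarize a repertoire of counted sequences
#'
#' Computes totals, the unique/total ratio, the cumulative read fraction of
#' the top-k most frequent sequences (k = 1..100), and the number of unique
#' sequences at or above each read-count threshold.
#'
#' @param counts `data.frame` with columns `vector` and `count` for one
#'   panning round.
#' @param top_k Depth of the cumulative-frequency curve (default 100).
#' @return Object of class `repertoire_summary`: list with `total_reads`,
#'   `unique_sequences`, `unique_over_total`, `cumulative_top` (length
#'   `min(top_k, n)`) and `retained_at_count` (named vector over thresholds
#'   1..max count).
#' @export
repertoire_summary <- function(counts, top_k = 100L) {
  stopifnot(is.data.frame(counts), nrow(counts) > 0L,
            all(c("vector", "count") %in% names(counts)))
  if (anyDuplicated(counts$vector))
    stop("counts table must have one row per unique vector")
  cnt <- sort(as.integer(counts$count), decreasing = TRUE)
  if (any(cnt < 1L)) stop("counts must be positive")
  total <- sum(cnt)
  k <- seq_len(min(top_k, length(cnt)))
  curve_a <- cumsum(cnt[k]) / total
  thresholds <- seq_len(max(cnt))
  curve_b <- vapply(thresholds, function(c0) sum(cnt >= c0), 1L)
  structure(list(
    total_reads = total,
    unique_sequences = length(cnt),
    unique_over_total = length(cnt) / total,
    cumulative_top = curve_a,
    retained_at_count = setNames(curve_b, thresholds)),
    class = "repertoire_summary")
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat(sprintf("Repertoire: %d reads, %d unique (unique/total = %.3f)\n",
              x$total_reads, x$unique_sequences, x$unique_over_total))
  cat(sprintf("Top-%d sequences carry %.1f%% of reads\n",
              length(x$cumulative_top),
              100 * x$cumulative_top[length(x$cumulative_top)]))
  invisible(x)
}

#' Observed per-position residue frequencies of a counted repertoire
#'
#' Read-count-weighted residue frequencies at each diversified position.
#'
#' @param counts `data.frame` with columns `vector`, `count`.
#' @param design A `library_design` (fixes row order and vector length).
#' @return Matrix positions x 20 residues; rows sum to 1.
#' @export
positional_frequencies <- function(counts, design) {
  stopifnot(inherits(design, "library_design"))
  n <- length(design)
  if (any(nchar(counts$vector) != n))
    stop("vectors must have length ", n)
  m <- matrix(0, n, length(AA_ALPHABET),
              dimnames = list(design$positions$label, AA_ALPHABET))
  chars <- matrix(unlist(strsplit(counts$vector, "")), nrow = n)
  w <- as.numeric(counts$count)
  for (j in seq_len(n)) {
    tab <- tapply(w, chars[j, ], sum)
    m[j, names(tab)] <- tab
  }
  sweep(m, 1, rowSums(m), "/")
}

#' Per-residue enrichment ratios between two panning states
#'
#' ER(position, residue) = frequency after / frequency before. Cells are
#' classified as enriched (ER > high), neutral (low < ER <= high ... strictly
#' between the thresholds) or intolerant (ER < low); cells with nonzero
#' after-frequency but zero before-frequency get `Inf` and are flagged.
#'
#' @param after,before Frequency matrices from [positional_frequencies()] or
#'   [theoretical_distribution()], same dimensions.
#' @param low,high Classification thresholds (defaults 0.8 and 1.2).
#' @return Object of class `enrichment_table`: list with the `er` matrix,
#'   a same-shaped `class` matrix (`"enriched"`, `"neutral"`,
#'   `"intolerant"`), per-class cell counts `n_enriched`, `n_neutral`,
#'   `n_intolerant`, total `n_cells`, and `n_flagged` (Inf cells).
#' @export
enrichment_ratio <- function(after, before, low = 0.8, high = 1.2) {
  stopifnot(identical(dim(after), dim(before)))
  er <- matrix(NA_real_, nrow(after), ncol(after), dimnames = dimnames(after))
  pos <- before > 0
  er[pos] <- after[pos] / before[pos]
  er[!pos & after == 0] <- 0        # absent on both sides
  er[!pos & after > 0] <- Inf
  cls <- matrix("neutral", nrow(er), ncol(er), dimnames = dimnames(er))
  cls[er >= high] <- "enriched"
  cls[er <= low] <- "intolerant"
  cls[er > low & er < high] <- "neutral"
  structure(list(
    er = er, class = cls,
    thresholds = c(low = low, high = high),
    n_enriched = sum(cls == "enriched"),
    n_neutral = sum(cls == "neutral"),
    n_intolerant = sum(cls == "intolerant"),
    n_cells = length(er),
    n_flagged = sum(is.infinite(er))), class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf(
    "Enrichment table: %d cells; %d enriched (ER > %.1f), %d neutral, %d intolerant (ER < %.1f)%s\n",
    x$n_cells, x$n_enriched, x$thresholds["high"], x$n_neutral,
    x$n_intolerant, x$thresholds["low"],
    if (x$n_flagged) sprintf("; %d flagged Inf", x$n_flagged) else ""))
  invisible(x)
}

#' Select a training set by the cap-driven count threshold
#'
#' Takes sequences in descending read-count order so that the selected set
#' never exceeds `cap` sequences: the threshold c* is the smallest count c
#' such that the number of sequences with count >= c is at most `cap`, and
#' every sequence at or above c* is kept. Selection depends only on counts.
#'
#' @param counts `data.frame` with columns `vector`, `count`.
#' @param cap Maximum training-set size (default 1000).
#' @return List with `records` (the selected subset, sorted by decreasing
#'   count), `threshold` (c*), and `n_selected`.
#' @export
select_training <- function(counts, cap = 1000L) {
  stopifnot(is.data.frame(counts), all(counts$count >= 1L))
  if (cap < 1L) stop("cap must be at least 1")
  cnt <- as.integer(counts$count)
  cstar <- 1L
  while (sum(cnt >= cstar) > cap) cstar <- cstar + 1L
  keep <- counts[cnt >= cstar, , drop = FALSE]
  keep <- keep[order(-keep$count, keep$vector), , drop = FALSE]
  row.names(keep) <- NULL
  list(records = keep, threshold = cstar, n_selected = nrow(keep))
}

#' Read / write counted-vector tables
#'
#' TSV with columns `vector`, `count`, `round`.
#'
#' @param counts Count table (`data.frame`).
#' @param path File path.
#' @return `read_counts` returns the `data.frame`; `write_counts` returns
#'   `path` invisibly.
#' @export
write_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, colClasses = c(vector = "character"))
  stopifnot(all(c("vector", "count") %in% names(df)))
  df
}
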