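# Synthetic phage-display panning simulator with known ground truth:
# library sampling from the design, Boltzmann selection under a
# position-weight binding-energy model, and sequencing with optional
# substitution errors -- so enrichment analysis, LSTM training and NLL
# ranking can be validated by parameter recovery.

#' Ground-truth position-weight binding model
#'
#' Each (position, residue) pair carries an additive binding energy; lower
#' total energy means tighter binding. During a panning round a variant
#' with total energy E survives with weight `epsilon + exp(-beta * E)`:
#' Boltzmann retention at stringency `beta` plus a nonspecific background
#' `epsilon` so no variant has exactly zero survival. An optional pairwise
#' coupling table adds epistatic terms.
#'
#' @param design A `library_design`.
#' @param energies Optional `data.frame(label, residue, energy)` of nonzero
#'   entries; unlisted pairs have energy 0.
#' @param beta Selection stringency (> 0).
#' @param epsilon Background survival (> 0).
#' @param couplings Optional `data.frame(label1, residue1, label2, residue2,
#'   energy)` pairwise terms (off by default).
#' @return Object of class `fitness_model` with an `energy` matrix
#'   (positions x 20 residues).
#' @export
fitness_model <- function(design, energies = NULL, beta = 1,
                          epsilon = 1e-6, couplings = NULL) {
  stopifnot(inherits(design, "library_design"), beta >= 0, epsilon > 0)
  E <- matrix(0, length(design), length(AA_ALPHABET),
              dimnames = list(design$positions$label, AA_ALPHABET))
  if (!is.null(energies)) {
    stopifnot(all(c("label", "residue", "energy") %in% names(energies)))
    for (i in seq_len(nrow(energies))) {
      lab <- as.character(energies$label[i])
      res <- energies$residue[i]
      if (!lab %in% rownames(E)) stop("unknown position label ", lab)
      if (!res %in% AA_ALPHABET) stop("unknown residue ", res)
      E[lab, res] <- energies$energy[i]
    }
  }
  structure(list(energy = E, beta = beta, epsilon = epsilon,
                 couplings = couplings), class = "fitness_model")
}

#' Total binding energy of variants under a fitness model
#'
#' @param fitness A [fitness_model()].
#' @param vectors Character vector of residue strings (design length).
#' @return Numeric vector of additive energies (plus coupling terms if
#'   configured); lower = tighter binder.
#' @export
variant_energy <- function(fitness, vectors) {
  stopifnot(inherits(fitness, "fitness_model"))
  K <- nrow(fitness$energy)
  if (any(nchar(vectors) != K)) stop("vectors must have length ", K)
  cv <- matrix(unlist(strsplit(vectors, "")), ncol = K, byrow = TRUE)
  e <- numeric(length(vectors))
  for (j in seq_len(K))
    e <- e + fitness$energy[j, ][cv[, j]]
  e <- unname(e)
  cp <- fitness$couplings
  if (!is.null(cp)) {
    labs <- rownames(fitness$energy)
    for (i in seq_len(nrow(cp))) {
      j1 <- match(as.character(cp$label1[i]), labs)
      j2 <- match(as.character(cp$label2[i]), labs)
      hit <- cv[, j1] == cp$residue1[i] & cv[, j2] == cp$residue2[i]
      e[hit] <- e[hit] + cp$energy[i]
    }
  }
  e
}

#' Sample a naive library population from a design
#'
#' Draws `n` variants i.i.d., each position from the design's codon-weighted
#' theoretical residue distribution, and aggregates identical variants.
#'
#' @param design A `library_design`.
#' @param n Number of phage sampled.
#' @param seed Integer seed.
#' @param weighting Passed to [theoretical_distribution()].
#' @return `data.frame(vector, count)` with `sum(count) == n`.
#' @export
sample_library <- function(design, n, seed = 1L, weighting = "codon") {
  stopifnot(inherits(design, "library_design"), n >= 1)
  probs <- theoretical_distribution(design, weighting)
  set.seed(seed)
  K <- length(design)
  cols <- lapply(seq_len(K), function(j)
    sample(AA_ALPHABET, n, replace = TRUE, prob = probs[j, ]))
  vecs <- do.call(paste0, cols)
  tab <- sort(table(vecs), decreasing = TRUE)
  data.frame(vector = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' One round of panning selection
#'
#' Each variant's retention weight is `epsilon + exp(-beta * E)`; the next
#' population is drawn multinomially with probabilities proportional to
#' `count * weight`, preserving total population size.
#'
#' @param population `data.frame(vector, count)`.
#' @param fitness A [fitness_model()].
#' @param seed Integer seed.
#' @return `data.frame(vector, count)` with the same total count (variants
#'   drawn zero times are dropped).
#' @export
panning_round <- function(population, fitness, seed = 1L) {
  stopifnot(nrow(population) > 0, all(population$count >= 1))
  e <- variant_energy(fitness, population$vector)
  w <- fitness$epsilon + exp(-fitness$beta * e)
  size <- sum(population$count)
  set.seed(seed)
  counts <- as.integer(rmultinom(1, size, prob = population$count * w))
  keep <- counts > 0L
  out <- data.frame(vector = population$vector[keep], count = counts[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$vector), , drop = FALSE]
}

## fixed concrete codon for each constant residue / per-position residue
## codon maps consistent with the design's degenerate codons
.codon_for <- function(residue) {
  names(GENETIC_CODE_TABLE)[match(residue, GENETIC_CODE_TABLE)]
}

.design_codon_maps <- function(design) {
  lapply(seq_len(length(design)), function(j) {
    bases <- strsplit(design$positions$codon[j], "")[[1]]
    grid <- expand.grid(IUPAC_MAP[[bases[1]]], IUPAC_MAP[[bases[2]]],
                        IUPAC_MAP[[bases[3]]], stringsAsFactors = FALSE)
    codons <- paste0(grid[[1]], grid[[2]], grid[[3]])
    aa <- GENETIC_CODE_TABLE[codons]
    map <- codons[!duplicated(aa) & aa != "*"]
    setNames(map, aa[!duplicated(aa) & aa != "*"])
  })
}

#' Build the DNA coding sequence of a variant within the framework template
#'
#' Constant framework residues use a fixed codon; diversified slots use a
#' concrete codon drawn from the design's degenerate codon that encodes the
#' variant residue. Round-tripping through [translate_frames()] and
#' [extract_vectors()] recovers the variant exactly.
#'
#' @param vectors Character vector of diversified-residue strings.
#' @param design A `library_design`.
#' @param template Framework template from [read_template()].
#' @return Character vector of DNA sequences (3x template length).
#' @export
encode_variant_dna <- function(vectors, design, template = read_template()) {
  slots <- gregexpr("X", template, fixed = TRUE)[[1]]
  if (length(slots) != length(design))
    stop("template has ", length(slots), " slots but design has ",
         length(design), " positions")
  tchars <- strsplit(template, "")[[1]]
  codons <- character(length(tchars))
  const <- tchars != "X"
  codons[const] <- vapply(tchars[const], .codon_for, "")
  maps <- .design_codon_maps(design)
  vapply(vectors, function(v) {
    res <- strsplit(v, "")[[1]]
    cv <- codons
    for (j in seq_along(slots)) {
      cd <- maps[[j]][res[j]]
      if (is.na(cd))
        stop("residue ", res[j], " not encodable at position ",
             design$positions$label[j])
      cv[slots[j]] <- cd
    }
    paste(cv, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Sequence a population: multinomial reads with optional errors
#'
#' Draws `depth` reads multinomially from the population. Without a FASTQ
#' request the result is an error-free count table (sequencing errors are a
#' read-level phenomenon and only apply on the FASTQ path). With
#' `fastq_prefix`, each read is rendered as DNA in the framework template,
#' per-base substitution errors are applied at `error_rate`, and
#' overlapping paired-end reads are written to `<prefix>_R1.fastq` /
#' `<prefix>_R2.fastq`.
#'
#' @param population `data.frame(vector, count)`.
#' @param depth Number of reads.
#' @param seed Integer seed.
#' @param round_id Round label recorded in the count table.
#' @param error_rate Per-base substitution probability on the FASTQ path.
#' @param fastq_prefix If non-NULL, path prefix for paired FASTQ output.
#' @param design,template Needed for the FASTQ path.
#' @param read_length Length of each mate (default 220 of the 360 nt
#'   amplicon, giving an 80 nt overlap).
#' @return `data.frame(vector, count, round)`; with FASTQ output the file
#'   paths are attached as attribute `fastq`.
#' @export
sequence_population <- function(population, depth, seed = 1L, round_id = 0L,
                                error_rate = 0, fastq_prefix = NULL,
                                design = NULL, template = read_template(),
                                read_length = 220L) {
  stopifnot(depth >= 1, nrow(population) > 0)
  set.seed(seed)
  counts <- as.integer(rmultinom(1, depth, prob = population$count))
  keep <- counts > 0L
  tab <- data.frame(vector = population$vector[keep], count = counts[keep],
                    round = as.integer(round_id), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$vector), , drop = FALSE]
  row.names(tab) <- NULL
  if (is.null(fastq_prefix)) return(tab)
  if (is.null(design)) stop("FASTQ output needs the library design")
  dna <- encode_variant_dna(tab$vector, design, template)
  reads <- rep(dna, tab$count)
  reads <- reads[sample(length(reads))]
  if (error_rate > 0) {
    nb <- nchar(reads[1])
    chars <- matrix(unlist(strsplit(reads, "")), nrow = nb)
    hit <- which(matrix(runif(length(chars)) < error_rate, nrow = nb))
    if (length(hit)) {
      ## substitute with one of the three other bases
      cur <- chars[hit]
      chars[hit] <- vapply(cur, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    reads <- apply(chars, 2, paste, collapse = "")
  }
  L <- nchar(reads[1])
  rl <- min(read_length, L)
  fwd <- substr(reads, 1L, rl)
  rev_ <- .revcomp(substr(reads, L - rl + 1L, L))
  qual <- strrep("I", rl)
  f1 <- paste0(fastq_prefix, "_R1.fastq")
  f2 <- paste0(fastq_prefix, "_R2.fastq")
  ids <- sprintf("@sim_%d_%06d", round_id, seq_along(reads))
  plus <- rep("+", length(reads))
  quals <- rep(qual, length(reads))
  writeLines(c(rbind(ids, fwd, plus, quals)), f1)
  writeLines(c(rbind(ids, rev_, plus, quals)), f2)
  attr(tab, "fastq") <- c(f1, f2)
  tab
}

#' Simulate a full multi-round panning experiment
#'
#' Samples a naive library, applies `n_rounds` of Boltzmann selection, and
#' sequences the population before panning (round 0) and after each round.
#' All randomness derives deterministically from `seed`.
#'
#' @param design A `library_design`.
#' @param fitness A [fitness_model()].
#' @param n_library Library size (phage particles sampled).
#' @param n_rounds Number of panning rounds (the reference workflow used 2).
#' @param depth Sequencing reads per round.
#' @param seed Master seed.
#' @param out_dir Optional directory: writes `counts_round<r>.tsv` and
#'   `truth_energies.tsv`.
#' @param ... Passed to [sequence_population()] (e.g. `error_rate`,
#'   `fastq_prefix` is derived per round when `fastq = TRUE`).
#' @param fastq Also write paired FASTQ per round (requires `out_dir`).
#' @return List with `counts` (list of count tables, rounds 0..n_rounds),
#'   `population` (final full population), `fitness`, `seeds`.
#' @export
simulate_panning <- function(design, fitness, n_library = 1e5, n_rounds = 2L,
                             depth = 1e5, seed = 1L, out_dir = NULL,
                             fastq = FALSE, ...) {
  seeds <- seed + seq_len(2L * n_rounds + 2L)   # derived round seeds
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- sample_library(design, n_library, seed = seeds[1])
  counts <- vector("list", n_rounds + 1L)
  seq1 <- function(p, r, s) {
    pre <- if (fastq) {
      if (is.null(out_dir)) stop("fastq = TRUE requires out_dir")
      file.path(out_dir, sprintf("round%d", r))
    } else NULL
    sequence_population(p, depth, seed = s, round_id = r,
                        fastq_prefix = pre, design = design, ...)
  }
  counts[[1]] <- seq1(pop, 0L, seeds[2])
  for (r in seq_len(n_rounds)) {
    pop <- panning_round(pop, fitness, seed = seeds[2L * r + 1L])
    counts[[r + 1L]] <- seq1(pop, r, seeds[2L * r + 2L])
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in 0:n_rounds)
      write_counts(counts[[r + 1L]],
                   file.path(out_dir, sprintf("counts_round%d.tsv", r)))
    et <- as.data.frame(as.table(fitness$energy),
                        stringsAsFactors = FALSE)
    names(et) <- c("label", "residue", "energy")
    write.table(et[et$energy != 0, ],
                file.path(out_dir, "truth_energies.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(counts = counts, population = pop, fitness = fitness, seeds = seeds)
}
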