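# Degenerate-codon combinatorial library model: IUPAC expansion, theoretical
# diversity and per-position residue distributions.

#' @importFrom stats quantile setNames rnorm runif rmultinom median cor lm coef var sd
#' @importFrom utils read.delim write.table head
NULL

## 20 proteinogenic residues, fixed package-wide order
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## standard genetic code, codon -> 1-letter residue ('*' = stop)
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

## IUPAC nucleotide ambiguity codes
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Expand an IUPAC degenerate codon into its encoded residue multiset
#'
#' Enumerates the Cartesian product of the three IUPAC base sets against the
#' standard genetic code and tallies how many concrete codons encode each
#' residue. Stop codons are handled according to `stop_policy`: either
#' dropped (the distribution over residues is implicitly renormalized
#' downstream), or -- for amber-suppressor hosts -- TAG read through as
#' glutamine while ochre/opal are dropped.
#'
#' @param codon Length-3 string of IUPAC nucleotide symbols, e.g. `"NNK"`.
#' @param stop_policy `"exclude_and_renormalize"` (default) or `"amber_as_Q"`.
#' @return Named integer vector mapping residue to codon multiplicity.
#'   `"NNK"` yields all 20 residues with total multiplicity 31 under the
#'   default policy (32 codons minus the amber stop).
#' @examples
#' expand_degenerate_codon("VTT")   # I, L, V each once
#' expand_degenerate_codon("NNK")
#' @export
expand_degenerate_codon <- function(codon,
                                    stop_policy = c("exclude_and_renormalize",
                                                    "amber_as_Q")) {
  stop_policy <- match.arg(stop_policy)
  stopifnot(is.character(codon), length(codon) == 1L)
  codon <- toupper(codon)
  if (nchar(codon) != 3L)
    stop("degenerate codon must have exactly 3 symbols, got '", codon, "'")
  bases <- strsplit(codon, "")[[1]]
  bad <- setdiff(bases, names(IUPAC_MAP))
  if (length(bad))
    stop("invalid IUPAC nucleotide symbol '", bad[[1]], "' in codon '",
         codon, "'")
  grid <- expand.grid(IUPAC_MAP[[bases[1]]], IUPAC_MAP[[bases[2]]],
                      IUPAC_MAP[[bases[3]]], stringsAsFactors = FALSE)
  codons <- paste0(grid[[1]], grid[[2]], grid[[3]])
  aa <- unname(GENETIC_CODE_TABLE[codons])
  if (stop_policy == "amber_as_Q")
    aa[codons == "TAG"] <- "Q"
  aa <- aa[aa != "*"]
  if (!length(aa))
    stop("codon '", codon, "' encodes only stop codons under policy '",
         stop_policy, "'")
  tab <- table(aa)
  out <- setNames(as.integer(tab), names(tab))
  out[order(match(names(out), AA_ALPHABET))]
}

#' Construct a combinatorial library design
#'
#' A library design is an ordered list of diversified positions, each with an
#' antibody-numbering label (opaque text such as `"100a"`), an IUPAC
#' degenerate codon and the parental residue at that position. The allowed
#' residue set of each position is derived from its codon.
#'
#' @param labels Character vector of unique position labels, in vector order.
#' @param codons IUPAC degenerate codons, one per position.
#' @param parental Parental (wild-type) residues, one per position.
#' @param stop_policy Stop-codon policy passed to [expand_degenerate_codon()].
#' @return An object of class `library_design`.
#' @seealso [f02_design()], [read_library_design()]
#' @export
library_design <- function(labels, codons, parental,
                           stop_policy = c("exclude_and_renormalize",
                                           "amber_as_Q")) {
  stop_policy <- match.arg(stop_policy)
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("position labels must be unique")
  if (length(codons) != length(labels) || length(parental) != length(labels))
    stop("labels, codons and parental must have equal length")
  mult <- lapply(codons, expand_degenerate_codon, stop_policy = stop_policy)
  allowed <- lapply(mult, names)
  for (j in seq_along(labels)) {
    if (!parental[j] %in% allowed[[j]])
      stop("parental residue '", parental[j], "' at position ", labels[j],
           " is not encoded by codon ", codons[j])
  }
  structure(list(
    positions = data.frame(label = labels,
                           ordinal = seq_along(labels) - 1L,
                           codon = toupper(codons),
                           parental = parental,
                           stringsAsFactors = FALSE),
    multiplicity = mult,
    allowed = allowed,
    stop_policy = stop_policy), class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat("Combinatorial library design:", nrow(x$positions),
      "diversified positions, stop policy", x$stop_policy, "\n")
  df <- x$positions
  df$allowed <- vapply(x$allowed, paste, "", collapse = "")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
length.library_design <- function(x) nrow(x$positions)

#' Read a library design from a TSV file
#'
#' Expects columns `label`, `codon`, `parental`.
#'
#' @inheritParams library_design
#' @param path Path to the design TSV.
#' @return A `library_design`.
#' @export
read_library_design <- function(path,
                                stop_policy = c("exclude_and_renormalize",
                                                "amber_as_Q")) {
  df <- read.delim(path, colClasses = "character")
  need <- c("label", "codon", "parental")
  if (!all(need %in% names(df)))
    stop("design file must have columns: ", paste(need, collapse = ", "))
  library_design(df$label, df$codon, df$parental,
                 stop_policy = match.arg(stop_policy))
}

#' The bundled 17-position F02 heavy-chain library design
#'
#' Seventeen diversified heavy-chain positions (antibody numbering 28 to
#' 100c). Five positions carry restricted degenerate codons (VTT at 51,
#' RGT at 55, SCG at 97 and 100b, CRT at 100c); the rest are NNK.
#'
#' @inheritParams library_design
#' @return A `library_design` with 17 positions.
#' @export
f02_design <- function(stop_policy = c("exclude_and_renormalize",
                                       "amber_as_Q")) {
  read_library_design(
    system.file("extdata", "f02_design.tsv", package = "phagelm",
                mustWork = TRUE),
    stop_policy = match.arg(stop_policy))
}

## exact product of small positive integers as a decimal string
.big_prod <- function(factors) {
  digits <- 1L                    # little-endian decimal digits
  for (m in factors) {
    digits <- digits * as.integer(m)
    carry <- 0L
    for (i in seq_along(digits)) {
      v <- digits[i] + carry
      digits[i] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  paste(rev(digits), collapse = "")
}

## round a positive decimal-string integer to one significant figure,
## half away from zero; returns list(mantissa, exponent)
.round_1sf <- function(dec) {
  d1 <- as.integer(substr(dec, 1, 1))
  d2 <- if (nchar(dec) >= 2) as.integer(substr(dec, 2, 2)) else 0L
  expo <- nchar(dec) - 1L
  if (d2 >= 5L) d1 <- d1 + 1L
  if (d1 == 10L) { d1 <- 1L; expo <- expo + 1L }
  list(mantissa = d1, exponent = expo)
}

#' Theoretical diversity of a library design
#'
#' The number of distinct amino-acid sequences the design can encode: the
#' product over positions of the allowed-residue counts, computed exactly in
#' arbitrary precision. Also reports the value rounded half-away-from-zero
#' to one significant figure, the convention behind headline figures such as
#' "2 x 10^17 variants".
#'
#' @param design A `library_design`.
#' @return List with `exact` (decimal string), `value` (double),
#'   `per_position` (integer vector of allowed counts) and `headline`
#'   (one-significant-figure string such as `"2e+17"`).
#' @export
theoretical_diversity <- function(design) {
  stopifnot(inherits(design, "library_design"))
  counts <- vapply(design$allowed, length, 1L)
  exact <- .big_prod(counts)
  r <- .round_1sf(exact)
  list(exact = exact,
       value = as.numeric(exact),
       per_position = setNames(counts, design$positions$label),
       headline = sprintf("%de+%02d", r$mantissa, r$exponent))
}

#' Theoretical per-position residue distribution of a design
#'
#' For each diversified position, the probability of each residue in the
#' naive (pre-selection) library. With `weighting = "codon"` residues are
#' weighted by how many concrete codons encode them within the position's
#' degenerate codon (e.g. leucine gets 3/31 under NNK); `"uniform"` spreads
#' mass equally over the allowed residues.
#'
#' @param design A `library_design`.
#' @param weighting `"codon"` (default) or `"uniform"`.
#' @return Numeric matrix, positions x 20 residues; rows sum to 1.
#' @export
theoretical_distribution <- function(design, weighting = c("codon", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(design, "library_design"))
  n <- length(design)
  out <- matrix(0, n, length(AA_ALPHABET),
                dimnames = list(design$positions$label, AA_ALPHABET))
  for (j in seq_len(n)) {
    m <- design$multiplicity[[j]]
    if (weighting == "uniform") m[] <- 1L
    out[j, names(m)] <- m / sum(m)
  }
  out
}
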