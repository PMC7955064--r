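# Sequence generation and likelihood-based prioritization: temperature-
# controlled softmax sampling from the trained model, NLL scoring, the
# position-novelty filter and assembly of the three candidate groups.

#' Negative log-likelihood of sequences under a trained model
#'
#' `NLL = -sum_{k=1..K} log p(x_k)` in nats, where `p(x_k)` is the model's
#' teacher-forced predictive probability of the true residue at position k
#' (conditioning starts from the start token). Lower NLL is interpreted as
#' a prediction of tighter antigen binding. The start token itself is never
#' scored; probabilities are floored at 1e-12 with a warning.
#'
#' @param model A trained `lstm_model`.
#' @param vectors Character vector of residue strings of length `model$K`.
#' @return Named numeric vector of NLL values (nonnegative).
#' @export
nll <- function(model, vectors) {
  stopifnot(inherits(model, "lstm_model"))
  idx <- .encode_indices(vectors, model$vocab)
  K <- ncol(idx) - 1L
  xs <- .onehot_steps(idx[, 1:K, drop = FALSE], model$vocab$size)
  fw <- .net_forward(model$params, xs)
  B <- nrow(idx)
  tot <- numeric(B)
  flo <- FALSE
  for (t in seq_len(K)) {
    p <- fw$probs[[t]][cbind(seq_len(B), idx[, t + 1L])]
    if (any(p < 1e-12)) { flo <- TRUE; p <- pmax(p, 1e-12) }
    tot <- tot - log(p)
  }
  if (flo) warning("predictive probability underflow; floored at 1e-12")
  setNames(tot, vectors)
}

#' Sample sequences from the model with a temperature factor
#'
#' Generation starts at the start token and draws K residues sequentially.
#' At each step the dense-head scores y are turned into sampling
#' probabilities `P_i = exp(y_i / T) / sum_i' exp(y_i' / T)` over the 20
#' residue tokens only (start and padding tokens are excluded from the
#' support and the distribution renormalized). `T = 1` reproduces the model
#' softmax restricted to residues; `T -> 0` approaches greedy argmax
#' decoding (`temperature = 0` is implemented as exact greedy); `T > 1`
#' flattens the distribution and diversifies samples.
#'
#' @param model A trained `lstm_model`.
#' @param n Number of sequences to draw.
#' @param temperature Positive temperature, or 0 for greedy decoding.
#' @param seed Integer seed.
#' @return Character vector of `n` sequences of length `model$K` (duplicates
#'   possible; see [novelty_filter()] and [select_groups()] for downstream
#'   handling).
#' @export
sample_sequences <- function(model, n, temperature = 1, seed = 1L) {
  stopifnot(inherits(model, "lstm_model"), n >= 1, temperature >= 0)
  vocab <- model$vocab
  A <- vocab$size
  ridx <- vocab$residue_indices
  set.seed(seed)
  L <- model$config$n_layers
  N <- model$config$n_blocks
  h <- lapply(seq_len(L), function(l) matrix(0, n, N))
  cc <- lapply(seq_len(L), function(l) matrix(0, n, N))
  cur <- rep(vocab$start_index, n)
  out <- matrix("", n, model$K)
  U <- upper.tri(diag(length(ridx)), diag = TRUE) * 1  # row cumsum helper
  for (k in seq_len(model$K)) {
    x <- matrix(0, n, A)
    x[cbind(seq_len(n), cur)] <- 1
    inp <- x
    for (l in seq_len(L)) {
      st <- .cell_forward(inp, h[[l]], cc[[l]], model$params$layers[[l]])
      h[[l]] <- st$h
      cc[[l]] <- st$c
      inp <- st$h
    }
    y <- sweep(tcrossprod(inp, model$params$dense$W), 2,
               model$params$dense$b, "+")[, ridx, drop = FALSE]
    if (temperature == 0) {
      pick <- max.col(y, ties.method = "first")
    } else {
      p <- .softmax_rows(y / temperature)
      cum <- p %*% U
      pick <- 1L + rowSums(cum < runif(n))
    }
    cur <- ridx[pick]
    out[, k] <- vocab$symbols[cur]
  }
  apply(out, 1, paste, collapse = "")
}

#' Position-novelty filter
#'
#' Retains a candidate only if, at every position, its residue occurs at
#' that position somewhere in the training set. Removes sequences carrying
#' residues in positional contexts never seen during training.
#'
#' @param vectors Candidate sequences (equal length).
#' @param training Training sequences (same length).
#' @return List with `retained` (character vector), `n_rejected`, and the
#'   logical `keep` mask aligned with `vectors`.
#' @export
novelty_filter <- function(vectors, training) {
  stopifnot(length(training) >= 1)
  K <- nchar(training[1])
  if (any(nchar(vectors) != K) || any(nchar(training) != K))
    stop("all sequences must have length ", K)
  tr <- matrix(unlist(strsplit(training, "")), ncol = K, byrow = TRUE)
  seen <- lapply(seq_len(K), function(j) unique(tr[, j]))
  cv <- matrix(unlist(strsplit(vectors, "")), ncol = K, byrow = TRUE)
  keep <- rep(TRUE, length(vectors))
  for (j in seq_len(K)) keep <- keep & (cv[, j] %in% seen[[j]])
  list(retained = vectors[keep], n_rejected = sum(!keep), keep = keep)
}

#' Assemble the three experimental candidate groups
#'
#' Group `ML`: the 10 distinct generated sequences with lowest NLL, sorted
#' ascending. Group `grid`: for each value of the NLL grid (default 10.0 to
#' 25.5 in steps of 0.5, 32 values), the not-yet-used generated sequence
#' whose NLL is nearest to it (ties toward the lower NLL); no sequence is
#' reused across grid values or taken from group ML. Group `Freq`: the 10
#' most frequent sequences of the panning count table (count ties broken
#' lexicographically).
#'
#' @param scored `data.frame` with columns `vector`, `nll` (deduplicated
#'   generated sequences with scores).
#' @param ngs_counts `data.frame` with columns `vector`, `count` (NGS table
#'   from the final panning round).
#' @param n_low Size of the lowest-NLL group (default 10).
#' @param grid NLL grid for the spread group (default `seq(10, 25.5, 0.5)`).
#' @param n_freq Size of the frequency group (default 10).
#' @return List of three `data.frame`s: `ml` (vector, nll), `grid` (vector,
#'   nll, grid_value), `freq` (vector, count). Partial groups trigger a
#'   warning.
#' @export
select_groups <- function(scored, ngs_counts, n_low = 10L,
                          grid = seq(10, 25.5, by = 0.5), n_freq = 10L) {
  stopifnot(all(c("vector", "nll") %in% names(scored)),
            all(c("vector", "count") %in% names(ngs_counts)))
  if (anyDuplicated(scored$vector))
    stop("scored table must be deduplicated")
  scored <- scored[order(scored$nll, scored$vector), , drop = FALSE]
  row.names(scored) <- NULL
  n1 <- min(n_low, nrow(scored))
  if (n1 < n_low) warning("fewer candidates than requested for group ML")
  ml <- scored[seq_len(n1), c("vector", "nll"), drop = FALSE]
  pool <- if (n1 > 0) scored[-seq_len(n1), , drop = FALSE] else scored
  gsel <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    if (!nrow(pool)) break
    d <- abs(pool$nll - grid[gi])
    j <- order(d, pool$nll)[1]   # nearest; ties toward lower NLL
    gsel[[gi]] <- data.frame(vector = pool$vector[j], nll = pool$nll[j],
                             grid_value = grid[gi])
    pool <- pool[-j, , drop = FALSE]
  }
  gdf <- do.call(rbind, gsel)
  if (is.null(gdf))
    gdf <- data.frame(vector = character(), nll = numeric(),
                      grid_value = numeric())
  if (nrow(gdf) < length(grid))
    warning("fewer candidates than grid values for group grid")
  fr <- ngs_counts[order(-ngs_counts$count, ngs_counts$vector), , drop = FALSE]
  n3 <- min(n_freq, nrow(fr))
  if (n3 < n_freq) warning("fewer NGS sequences than requested for group Freq")
  freq <- fr[seq_len(n3), c("vector", "count"), drop = FALSE]
  row.names(freq) <- NULL
  row.names(gdf) <- NULL
  list(ml = ml, grid = gdf, freq = freq)
}
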