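# Autoregressive LSTM language model over diversified-residue vectors.
#
# The cell, the softmax head, backpropagation through time and the Adam
# optimizer are implemented directly in vectorized base R (matrix products
# go through BLAS). Sequences are short (a start token plus K residues) and
# fully batched, so the per-epoch cost is a few hundred small matrix
# multiplications.

FORMAT_VERSION <- 1L

#' The 22-token model vocabulary
#'
#' Twenty natural amino-acid letters, a start token `"B"`, and a padding
#' token `"-"`. The order is fixed; token indices are stable across runs.
#'
#' @return List with `symbols` (length 22), `size`, `start_index`,
#'   `pad_index`, `residue_indices` (indices of the 20 residue tokens).
#' @export
aa_vocabulary <- function() {
  symbols <- c(AA_ALPHABET, "B", "-")
  list(symbols = symbols,
       size = length(symbols),
       start_index = match("B", symbols),
       pad_index = match("-", symbols),
       residue_indices = seq_along(AA_ALPHABET))
}

## character vectors -> integer index matrix B x (K+1), column 1 = start token
.encode_indices <- function(vectors, vocab) {
  if (!length(vectors)) stop("no sequences to encode")
  K <- nchar(vectors[1])
  if (any(nchar(vectors) != K)) stop("sequences must have equal length")
  chars <- matrix(unlist(strsplit(vectors, "")), ncol = K, byrow = TRUE)
  idx <- matrix(match(chars, vocab$symbols), nrow = length(vectors))
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("unknown symbol(s) not in vocabulary: ",
         paste(sQuote(bad), collapse = ", "))
  }
  cbind(rep(vocab$start_index, length(vectors)), idx)
}

#' One-hot encode a residue vector (start token prepended)
#'
#' @param vector Residue string of length K.
#' @param vocab Vocabulary from [aa_vocabulary()].
#' @return `(K+1) x 22` binary matrix; row 1 encodes the start token.
#' @export
encode_onehot <- function(vector, vocab = aa_vocabulary()) {
  idx <- .encode_indices(vector, vocab)[1, ]
  m <- matrix(0L, length(idx), vocab$size,
              dimnames = list(NULL, vocab$symbols))
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Decode a one-hot matrix back to a residue string
#'
#' Inverse of [encode_onehot()]; the leading start-token row is dropped.
#'
#' @param onehot `(K+1) x 22` one-hot matrix.
#' @inheritParams encode_onehot
#' @return Residue string of length K.
#' @export
decode_onehot <- function(onehot, vocab = aa_vocabulary()) {
  if (any(abs(rowSums(onehot) - 1) > 1e-9))
    stop("each one-hot row must sum to 1")
  idx <- max.col(onehot, ties.method = "first")
  syms <- vocab$symbols[idx]
  if (syms[1] != "B") stop("row 1 must encode the start token")
  paste(syms[-1], collapse = "")
}

#' Model hyperparameter configuration
#'
#' Grid values follow the architecture search: one or two LSTM layers,
#' block counts from \{24, 32, 64, 128, 256, 512\}, dropout 0.1 or 0.2,
#' Adam with learning rate 0.01 over up to 500 epochs.
#'
#' @param n_layers 1 or 2 stacked LSTM layers.
#' @param n_blocks Hidden units N per layer.
#' @param dropout Dropout rate applied to each LSTM layer's output during
#'   training.
#' @param learning_rate Adam learning rate.
#' @param max_epochs Training epochs.
#' @param seed Integer seed controlling initialization, the train/validation
#'   split and dropout masks.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_layers = 2L, n_blocks = 64L, dropout = 0.2,
                         learning_rate = 0.01, max_epochs = 500L,
                         seed = 42L) {
  stopifnot(n_layers %in% 1:2, n_blocks >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, max_epochs >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 n_blocks = as.integer(n_blocks),
                 dropout = dropout, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "model_config")
}

## Glorot-uniform initialization of one LSTM layer (input width `a`,
## hidden width `n`). Forget-gate bias starts at 1 (standard practice for
## stable early training); other biases at 0.
.init_layer <- function(a, n) {
  gu <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  list(Wz = gu(n, a), Wi = gu(n, a), Wf = gu(n, a), Wo = gu(n, a),
       Rz = gu(n, n), Ri = gu(n, n), Rf = gu(n, n), Ro = gu(n, n),
       bz = numeric(n), bi = numeric(n), bf = rep(1, n), bo = numeric(n))
}

.init_params <- function(config, A) {
  N <- config$n_blocks
  layers <- vector("list", config$n_layers)
  a <- A
  for (l in seq_len(config$n_layers)) {
    layers[[l]] <- .init_layer(a, N)
    a <- N
  }
  lim <- sqrt(6 / (A + N))
  list(layers = layers,
       dense = list(W = matrix(runif(A * N, -lim, lim), A, N),
                    b = numeric(A)))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell step
#'
#' Applies the six cell equations: block input
#' `z = tanh(Wz x + Rz h + bz)`, input gate `i = sigmoid(Wi x + Ri h + bi)`,
#' forget gate `f = sigmoid(Wf x + Rf h + bf)`, memory cell
#' `c = z * i + c_prev * f`, output gate `o = sigmoid(Wo x + Ro h + bo)`,
#' block output `h = o * tanh(c)` (elementwise products).
#'
#' @param x Input: length-A vector or `B x A` matrix (batched).
#' @param h_prev,c_prev Previous block output / memory cell: length-N vector
#'   or `B x N` matrix.
#' @param weights Layer weights: list with `Wz,Wi,Wf,Wo` (`N x A`),
#'   `Rz,Ri,Rf,Ro` (`N x N`), `bz,bi,bf,bo` (length N).
#' @return List with `h` and `c` (same shape as `h_prev`); gate activations
#'   `z`, `i`, `f`, `o` are attached for inspection.
#' @export
lstm_step <- function(x, h_prev, c_prev, weights) {
  vec_in <- is.null(dim(x))
  if (vec_in) {
    x <- matrix(x, 1); h_prev <- matrix(h_prev, 1); c_prev <- matrix(c_prev, 1)
  }
  N <- nrow(weights$Rz)
  if (ncol(x) != ncol(weights$Wz) || ncol(h_prev) != N || ncol(c_prev) != N)
    stop("shape mismatch between inputs and layer weights")
  st <- .cell_forward(x, h_prev, c_prev, weights)
  out <- list(h = st$h, c = st$c, z = st$z, i = st$i, f = st$f, o = st$o)
  if (vec_in) out <- lapply(out, drop)
  out
}

## batched cell forward, keeping intermediates for backprop
.cell_forward <- function(x, h_prev, c_prev, w) {
  z <- tanh(sweep(tcrossprod(x, w$Wz) + tcrossprod(h_prev, w$Rz), 2, w$bz, "+"))
  i <- .sigmoid(sweep(tcrossprod(x, w$Wi) + tcrossprod(h_prev, w$Ri), 2, w$bi, "+"))
  f <- .sigmoid(sweep(tcrossprod(x, w$Wf) + tcrossprod(h_prev, w$Rf), 2, w$bf, "+"))
  o <- .sigmoid(sweep(tcrossprod(x, w$Wo) + tcrossprod(h_prev, w$Ro), 2, w$bo, "+"))
  cc <- z * i + c_prev * f
  tc <- tanh(cc)
  list(z = z, i = i, f = f, o = o, c = cc, tanh_c = tc, h = o * tc,
       h_prev = h_prev, c_prev = c_prev)
}

.softmax_rows <- function(logits) {
  m <- logits - apply(logits, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

## Forward pass over T input steps.
## xs: list of T one-hot matrices (B x A). masks: NULL, or
## masks[[layer]][[t]] inverted-dropout masks. Returns per-step caches and
## the B x A probability matrices.
.net_forward <- function(params, xs, masks = NULL) {
  Tn <- length(xs)
  B <- nrow(xs[[1]])
  L <- length(params$layers)
  N <- nrow(params$layers[[1]]$Rz)
  caches <- lapply(seq_len(L), function(l) vector("list", Tn))
  dropped <- lapply(seq_len(L), function(l) vector("list", Tn))
  probs <- vector("list", Tn)
  logits <- vector("list", Tn)
  h <- lapply(seq_len(L), function(l) matrix(0, B, N))
  cc <- lapply(seq_len(L), function(l) matrix(0, B, N))
  for (t in seq_len(Tn)) {
    inp <- xs[[t]]
    for (l in seq_len(L)) {
      st <- .cell_forward(inp, h[[l]], cc[[l]], params$layers[[l]])
      caches[[l]][[t]] <- st
      h[[l]] <- st$h
      cc[[l]] <- st$c
      out <- st$h
      if (!is.null(masks)) out <- out * masks[[l]][[t]]
      dropped[[l]][[t]] <- out
      inp <- out
    }
    lg <- sweep(tcrossprod(inp, params$dense$W), 2, params$dense$b, "+")
    logits[[t]] <- lg
    probs[[t]] <- .softmax_rows(lg)
  }
  list(caches = caches, dropped = dropped, probs = probs, logits = logits)
}

## Backward pass (BPTT). targets: B x T index matrix of next tokens;
## weight of padded targets is zero. Returns gradient tree mirroring params.
.net_backward <- function(params, xs, fw, targets, pad_index, masks = NULL) {
  Tn <- length(xs)
  B <- nrow(xs[[1]])
  A <- nrow(params$dense$W)
  L <- length(params$layers)
  N <- nrow(params$layers[[1]]$Rz)
  w <- (targets != pad_index) * 1
  denom <- sum(w)
  g <- list(layers = lapply(params$layers, function(ly) lapply(ly, function(p) p * 0)),
            dense = list(W = params$dense$W * 0, b = params$dense$b * 0))
  ## dense head and gradient w.r.t. each layer's (dropped) output per step
  dout <- lapply(seq_len(L), function(l) vector("list", Tn))
  for (t in seq_len(Tn)) {
    dlg <- fw$probs[[t]]
    dlg[cbind(seq_len(B), targets[, t])] <-
      dlg[cbind(seq_len(B), targets[, t])] - 1
    dlg <- dlg * (w[, t] / denom)
    g$dense$W <- g$dense$W + crossprod(dlg, fw$dropped[[L]][[t]])
    g$dense$b <- g$dense$b + colSums(dlg)
    dout[[L]][[t]] <- dlg %*% params$dense$W
  }
  for (l in seq(L, 1)) {
    ly <- params$layers[[l]]
    gl <- g$layers[[l]]
    dh_rec <- matrix(0, B, N)
    dc_rec <- matrix(0, B, N)
    for (t in seq(Tn, 1)) {
      st <- fw$caches[[l]][[t]]
      dh <- dh_rec
      if (!is.null(dout[[l]][[t]])) {
        d <- dout[[l]][[t]]
        if (!is.null(masks)) d <- d * masks[[l]][[t]]
        dh <- dh + d
      }
      do_ <- dh * st$tanh_c
      dc <- dh * st$o * (1 - st$tanh_c^2) + dc_rec
      dzb <- (dc * st$i) * (1 - st$z^2)
      dib <- (dc * st$z) * st$i * (1 - st$i)
      dfb <- (dc * st$c_prev) * st$f * (1 - st$f)
      dob <- do_ * st$o * (1 - st$o)
      xin <- if (l == 1) xs[[t]] else fw$dropped[[l - 1]][[t]]
      gl$Wz <- gl$Wz + crossprod(dzb, xin)
      gl$Wi <- gl$Wi + crossprod(dib, xin)
      gl$Wf <- gl$Wf + crossprod(dfb, xin)
      gl$Wo <- gl$Wo + crossprod(dob, xin)
      gl$Rz <- gl$Rz + crossprod(dzb, st$h_prev)
      gl$Ri <- gl$Ri + crossprod(dib, st$h_prev)
      gl$Rf <- gl$Rf + crossprod(dfb, st$h_prev)
      gl$Ro <- gl$Ro + crossprod(dob, st$h_prev)
      gl$bz <- gl$bz + colSums(dzb)
      gl$bi <- gl$bi + colSums(dib)
      gl$bf <- gl$bf + colSums(dfb)
      gl$bo <- gl$bo + colSums(dob)
      dh_rec <- dzb %*% ly$Rz + dib %*% ly$Ri + dfb %*% ly$Rf + dob %*% ly$Ro
      dc_rec <- dc * st$f
      if (l > 1) {
        dx <- dzb %*% ly$Wz + dib %*% ly$Wi + dfb %*% ly$Wf + dob %*% ly$Wo
        dout[[l - 1]][[t]] <- if (is.null(dout[[l - 1]][[t]])) dx else
          dout[[l - 1]][[t]] + dx
      }
    }
    g$layers[[l]] <- gl
  }
  g
}

## elementwise walk over two parameter trees
.tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .tree_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

.tree_map <- function(a, f) {
  if (is.list(a)) lapply(a, .tree_map, f = f) else f(a)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .tree_map2(state$m, state$v,
                    function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- .tree_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

## per-position mean categorical cross-entropy over a forward pass
.mean_ce <- function(probs, targets, pad_index) {
  B <- nrow(targets)
  w <- targets != pad_index
  tot <- 0
  for (t in seq_len(ncol(targets))) {
    p <- probs[[t]][cbind(seq_len(B), targets[, t])]
    tot <- tot + sum(-log(pmax(p, 1e-12)) * w[, t])
  }
  tot / sum(w)
}

## build list of T one-hot matrices from an index matrix (inputs = columns
## 1..T of idx; targets = columns 2..T+1)
.onehot_steps <- function(idx_in, A) {
  B <- nrow(idx_in)
  lapply(seq_len(ncol(idx_in)), function(t) {
    m <- matrix(0, B, A)
    m[cbind(seq_len(B), idx_in[, t])] <- 1
    m
  })
}

#' Categorical cross-entropy of predicted rows against targets
#'
#' `L = -sum_k log y_k[target_k]` over the K positions, in nats. Predicted
#' probabilities are floored at 1e-12 (with a warning) to guard zero.
#'
#' @param pred `K x A` matrix of predictive distributions (rows sum to 1).
#' @param target Length-K integer token indices, or a `K x A` one-hot
#'   matrix.
#' @param per_position If `TRUE`, return the mean per position instead of
#'   the sum.
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(pred, target, per_position = FALSE) {
  if (is.matrix(target)) target <- max.col(target, ties.method = "first")
  stopifnot(nrow(pred) == length(target))
  p <- pred[cbind(seq_along(target), target)]
  if (any(p < 1e-12)) {
    warning("predicted probability underflow; flooring at 1e-12")
    p <- pmax(p, 1e-12)
  }
  s <- sum(-log(p))
  if (per_position) s / length(target) else s
}

#' Train the autoregressive LSTM
#'
#' Next-token objective with teacher forcing: the start token plus residues
#' 1..K-1 predict residues 1..K. Full-batch Adam; inverted dropout on each
#' LSTM layer's output during training only. The weights snapshotted at the
#' epoch with minimum validation loss are returned (no retraining).
#'
#' @param vectors Character vector of training sequences (equal length), or
#'   a count table `data.frame` with a `vector` column (counts are not used
#'   as weights; the unique sequences are the training set).
#' @param config A [model_config()].
#' @param val_fraction Fraction held out for validation (seeded split).
#' @param split Optional list with integer indices `train` and `val`,
#'   overriding `val_fraction`.
#' @param verbose Print the loss every 25 epochs.
#' @return Object of class `lstm_model`: `params`, `vocab`, `config`,
#'   `best_epoch`, `best_val_loss`, `curves` (data.frame epoch /
#'   train_loss / val_loss, per-position means in nats), `K`,
#'   `format_version`.
#' @export
train_lstm <- function(vectors, config = model_config(),
                       val_fraction = 0.2, split = NULL, verbose = FALSE) {
  if (is.data.frame(vectors)) vectors <- vectors$vector
  if (length(vectors) < 10L)
    stop("need at least 10 sequences to split into train and validation")
  vocab <- aa_vocabulary()
  idx <- .encode_indices(vectors, vocab)
  K <- ncol(idx) - 1L
  set.seed(config$seed)
  if (is.null(split)) {
    n_val <- max(1L, round(val_fraction * length(vectors)))
    val_idx <- sample(length(vectors), n_val)
    split <- list(train = setdiff(seq_along(vectors), val_idx), val = val_idx)
  }
  A <- vocab$size
  xs_tr <- .onehot_steps(idx[split$train, 1:K, drop = FALSE], A)
  tg_tr <- idx[split$train, 2:(K + 1L), drop = FALSE]
  xs_va <- .onehot_steps(idx[split$val, 1:K, drop = FALSE], A)
  tg_va <- idx[split$val, 2:(K + 1L), drop = FALSE]
  params <- .init_params(config, A)
  state <- list(m = .tree_map(params, function(p) p * 0),
                v = .tree_map(params, function(p) p * 0), t = 0L)
  B <- length(split$train)
  N <- config$n_blocks
  L <- config$n_layers
  keep <- 1 - config$dropout
  curves <- data.frame(epoch = seq_len(config$max_epochs),
                       train_loss = NA_real_, val_loss = NA_real_)
  best <- list(val = Inf, epoch = NA_integer_, params = NULL)
  for (epoch in seq_len(config$max_epochs)) {
    masks <- if (config$dropout > 0) {
      lapply(seq_len(L), function(l)
        lapply(seq_len(K), function(t)
          matrix((runif(B * N) < keep) / keep, B, N)))
    } else NULL
    fw <- .net_forward(params, xs_tr, masks)
    gr <- .net_backward(params, xs_tr, fw, tg_tr, vocab$pad_index, masks)
    ad <- .adam_step(params, gr, state, config$learning_rate)
    params <- ad$params
    state <- ad$state
    curves$train_loss[epoch] <- .mean_ce(fw$probs, tg_tr, vocab$pad_index)
    fv <- .net_forward(params, xs_va)
    curves$val_loss[epoch] <- .mean_ce(fv$probs, tg_va, vocab$pad_index)
    if (curves$val_loss[epoch] < best$val) {
      best <- list(val = curves$val_loss[epoch], epoch = epoch,
                   params = params)
    }
    if (verbose && epoch %% 25L == 0L)
      message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                      curves$train_loss[epoch], curves$val_loss[epoch]))
  }
  structure(list(params = best$params, vocab = vocab, config = config,
                 best_epoch = best$epoch, best_val_loss = best$val,
                 curves = curves, K = K,
                 format_version = FORMAT_VERSION),
            class = "lstm_model")
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf(
    "LSTM language model: %d layer(s) x %d blocks, dropout %.1f, K = %d\n",
    x$config$n_layers, x$config$n_blocks, x$config$dropout, x$K))
  cat(sprintf("best epoch %d, validation loss %.4f (per position, nats)\n",
              x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Teacher-forced forward pass: per-step predictive distributions
#'
#' Row t of the result for a sequence is the model's distribution over the
#' 22 tokens for the residue at position t, conditioned on the start token
#' and the true residues before t. Dropout is inactive.
#'
#' @param model A trained `lstm_model`.
#' @param vectors Character vector of sequences of length `model$K`.
#' @return A list of `K x 22` probability matrices, one per sequence (rows
#'   sum to 1).
#' @export
forward_probs <- function(model, vectors) {
  stopifnot(inherits(model, "lstm_model"))
  idx <- .encode_indices(vectors, model$vocab)
  K <- ncol(idx) - 1L
  xs <- .onehot_steps(idx[, 1:K, drop = FALSE], model$vocab$size)
  fw <- .net_forward(model$params, xs)
  lapply(seq_len(nrow(idx)), function(b) {
    m <- do.call(rbind, lapply(fw$probs, function(p) p[b, ]))
    colnames(m) <- model$vocab$symbols
    m
  })
}

#' Number of trainable parameters of a configuration
#'
#' @param config A [model_config()].
#' @param A Vocabulary size.
#' @return Integer parameter count.
#' @export
n_parameters <- function(config, A = 22L) {
  N <- config$n_blocks
  a <- A
  tot <- 0L
  for (l in seq_len(config$n_layers)) {
    tot <- tot + 4L * (N * a + N * N + N)
    a <- N
  }
  tot + A * N + A
}

#' Five-fold cross-validation over an architecture grid
#'
#' For each configuration, trains on k-1 folds with the held-out fold as
#' validation and scores it by the mean over folds of the minimum
#' validation loss (the loss at each run's best epoch). The configuration
#' with the lowest mean score wins; ties break toward fewer parameters.
#'
#' @param vectors Training sequences (character vector or count table).
#' @param grid List of [model_config()] objects.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold partition.
#' @return List with `best_config`, `scores` (data.frame: one row per
#'   config with mean and per-fold losses), `folds`.
#' @export
cross_validate <- function(vectors, grid, k = 5L, seed = 1L) {
  if (is.data.frame(vectors)) vectors <- vectors$vector
  if (!length(grid)) stop("empty configuration grid")
  n <- length(vectors)
  if (n < k) stop("need at least k sequences")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  scores <- matrix(NA_real_, length(grid), k)
  for (ci in seq_along(grid)) {
    for (fi in seq_len(k)) {
      sp <- list(train = which(fold != fi), val = which(fold == fi))
      fit <- train_lstm(vectors, grid[[ci]], split = sp)
      scores[ci, fi] <- fit$best_val_loss
    }
  }
  mean_score <- rowMeans(scores)
  npar <- vapply(grid, n_parameters, 1L)
  best_i <- order(mean_score, npar)[1]
  df <- data.frame(config = seq_along(grid),
                   n_layers = vapply(grid, `[[`, 1L, "n_layers"),
                   n_blocks = vapply(grid, `[[`, 1L, "n_blocks"),
                   dropout = vapply(grid, `[[`, 0.1, "dropout"),
                   n_parameters = npar, mean_val_loss = mean_score)
  df <- cbind(df, setNames(as.data.frame(scores),
                           paste0("fold", seq_len(k))))
  list(best_config = grid[[best_i]], scores = df, folds = fold)
}

#' Save / load a trained model
#'
#' The archive holds the configuration, all weight arrays, the vocabulary
#' order and a format-version field; loading a mismatched version fails.
#'
#' @param model An `lstm_model`.
#' @param path File path.
#' @return `read_model` returns the model; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "lstm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "lstm_model"))
    stop("file does not contain an lstm_model")
  if (!identical(m$format_version, FORMAT_VERSION))
    stop("model format version ", m$format_version,
         " does not match supported version ", FORMAT_VERSION)
  m
}
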