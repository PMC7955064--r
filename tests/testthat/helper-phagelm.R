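# Shared test fixtures and independent oracles.

## Independent reference LSTM cell: scalar loops straight off the six cell
## equations, written without reference to the package's vectorized code.
ref_lstm_step <- function(x, h_prev, c_prev, w) {
  N <- length(h_prev)
  z <- i <- f <- o <- h <- cc <- numeric(N)
  sig <- function(v) 1 / (1 + exp(-v))
  for (n in seq_len(N)) {
    az <- w$bz[n]; ai <- w$bi[n]; af <- w$bf[n]; ao <- w$bo[n]
    for (a in seq_along(x)) {
      az <- az + w$Wz[n, a] * x[a]
      ai <- ai + w$Wi[n, a] * x[a]
      af <- af + w$Wf[n, a] * x[a]
      ao <- ao + w$Wo[n, a] * x[a]
    }
    for (m in seq_len(N)) {
      az <- az + w$Rz[n, m] * h_prev[m]
      ai <- ai + w$Ri[n, m] * h_prev[m]
      af <- af + w$Rf[n, m] * h_prev[m]
      ao <- ao + w$Ro[n, m] * h_prev[m]
    }
    z[n] <- tanh(az); i[n] <- sig(ai); f[n] <- sig(af); o[n] <- sig(ao)
    cc[n] <- z[n] * i[n] + c_prev[n] * f[n]
    h[n] <- o[n] * tanh(cc[n])
  }
  list(h = h, c = cc)
}

random_layer_weights <- function(n, a) {
  rm <- function(r, c) matrix(rnorm(r * c, sd = 0.5), r, c)
  list(Wz = rm(n, a), Wi = rm(n, a), Wf = rm(n, a), Wo = rm(n, a),
       Rz = rm(n, n), Ri = rm(n, n), Rf = rm(n, n), Ro = rm(n, n),
       bz = rnorm(n), bi = rnorm(n), bf = rnorm(n), bo = rnorm(n))
}

zero_layer_weights <- function(n, a) {
  zm <- function(r, c) matrix(0, r, c)
  list(Wz = zm(n, a), Wi = zm(n, a), Wf = zm(n, a), Wo = zm(n, a),
       Rz = zm(n, n), Ri = zm(n, n), Rf = zm(n, n), Ro = zm(n, n),
       bz = numeric(n), bi = numeric(n), bf = numeric(n), bo = numeric(n))
}

## hand-built model whose predictive distribution is softmax(bias) at every
## step (all LSTM and dense weights zero except the dense bias)
bias_only_model <- function(K, bias) {
  vocab <- aa_vocabulary()
  A <- vocab$size
  stopifnot(length(bias) == A)
  cfg <- model_config(n_layers = 1, n_blocks = 4, dropout = 0,
                      max_epochs = 1, seed = 1)
  params <- list(layers = list(zero_layer_weights(4, A)),
                 dense = list(W = matrix(0, A, 4), b = bias))
  structure(list(params = params, vocab = vocab, config = cfg,
                 best_epoch = 1L, best_val_loss = NA_real_,
                 curves = NULL, K = K, format_version = phagelm:::FORMAT_VERSION),
            class = "lstm_model")
}

## two-position toy design: {G,S} x {A,P}
toy_design <- function() {
  library_design(labels = c("1", "2"), codons = c("RGT", "SCG"),
                 parental = c("G", "A"))
}

## the standard recovery ground truth used by simulator/acceptance tests:
## five strongly favorable residues (dE = -2) and five unfavorable (+2)
recovery_fitness <- function(design, beta = 1) {
  fav <- data.frame(label = c("28", "31", "33", "52", "96"),
                    residue = c("W", "R", "L", "S", "R"), energy = -2)
  unf <- data.frame(label = c("50", "54", "56", "99", "100a"),
                    residue = c("D", "A", "K", "E", "G"), energy = 2)
  fitness_model(design, energies = rbind(fav, unf), beta = beta)
}

recovery_favorable <- function() {
  data.frame(label = c("28", "31", "33", "52", "96"),
             residue = c("W", "R", "L", "S", "R"))
}

recovery_unfavorable <- function() {
  data.frame(label = c("50", "54", "56", "99", "100a"),
             residue = c("D", "A", "K", "E", "G"))
}

## random residue strings
random_vectors <- function(n, K) {
  aa <- phagelm:::AA_ALPHABET
  vapply(seq_len(n), function(i)
    paste(sample(aa, K, replace = TRUE), collapse = ""), "")
}
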