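test_that("the vocabulary has 22 stable tokens", {
  vocab <- aa_vocabulary()
  expect_identical(vocab$size, 22L)
  expect_identical(length(vocab$symbols), 22L)
  expect_setequal(vocab$symbols,
                  c(phagelm:::AA_ALPHABET, "B", "-"))
  expect_identical(vocab$symbols[vocab$start_index], "B")
  expect_identical(vocab$symbols[vocab$pad_index], "-")
})

test_that("one-hot encoding prepends the start token and round-trips", {
  m <- encode_onehot("AC")
  expect_identical(dim(m), c(3L, 22L))
  expect_equal(unname(rowSums(m)), rep(1, 3))
  expect_identical(decode_onehot(m), "AC")
  expect_error(encode_onehot("AZ"), "Z")
  set.seed(3)
  for (v in random_vectors(50, 17))
    expect_identical(decode_onehot(encode_onehot(v)), v)
})

test_that("lstm_step matches its closed forms", {
  w <- zero_layer_weights(3, 4)
  s <- lstm_step(rep(1, 4), rep(0, 3), rep(0, 3), w)
  expect_equal(s$h, rep(0, 3))
  expect_equal(s$c, rep(0, 3))
  expect_equal(s$i, rep(0.5, 3))
  expect_equal(s$f, rep(0.5, 3))
  expect_equal(s$o, rep(0.5, 3))
  ## scalar hand calculation: Wz = Rz = 1, gates all zero-weight
  w1 <- zero_layer_weights(1, 1)
  w1$Wz <- matrix(1, 1, 1); w1$Rz <- matrix(1, 1, 1)
  s1 <- lstm_step(1, 0, 0, w1)
  expect_equal(s1$c, 0.5 * tanh(1), tolerance = 1e-12)
  expect_equal(s1$h, 0.5 * tanh(0.5 * tanh(1)), tolerance = 1e-12)
  expect_error(lstm_step(rep(1, 5), rep(0, 3), rep(0, 3), w), "shape")
})

test_that("vectorized cell equals the scalar reference cell on random draws", {
  set.seed(21)
  for (trial in 1:100) {
    n <- sample(1:6, 1); a <- sample(1:8, 1)
    w <- random_layer_weights(n, a)
    x <- rnorm(a); h0 <- rnorm(n); c0 <- rnorm(n)
    got <- lstm_step(x, h0, c0, w)
    ref <- ref_lstm_step(x, h0, c0, w)
    expect_lt(max(abs(got$h - ref$h)), 1e-6)
    expect_lt(max(abs(got$c - ref$c)), 1e-6)
  }
})

test_that("forward rows are distributions; zero weights give uniform", {
  set.seed(4)
  cfg <- model_config(n_layers = 2, n_blocks = 8, dropout = 0,
                      max_epochs = 2, seed = 4)
  m <- train_lstm(random_vectors(20, 6), cfg)
  pr <- forward_probs(m, random_vectors(3, 6))
  for (p in pr) {
    expect_identical(dim(p), c(6L, 22L))
    expect_equal(unname(rowSums(p)), rep(1, 6), tolerance = 1e-9)
  }
  mz <- bias_only_model(5, rep(0, 22))
  pz <- forward_probs(mz, "ACDEF")[[1]]
  expect_equal(unname(pz), matrix(1 / 22, 5, 22), tolerance = 1e-12)
})

test_that("cross-entropy loss matches closed forms", {
  ## uniform over 22 -> ln 22 per position
  pred <- matrix(1 / 22, 4, 22)
  expect_equal(cross_entropy_loss(pred, c(1, 5, 9, 2), per_position = TRUE),
               log(22))
  ## perfect predictions -> 0
  perfect <- diag(22)[c(3, 7), ]
  expect_equal(cross_entropy_loss(perfect, c(3, 7)), 0)
  ## hand example: probabilities 0.5 and 0.25 at the targets -> ln 8
  pr <- rbind(c(0.5, 0.5, rep(0, 20)), c(0.25, 0.75, rep(0, 20)))
  expect_equal(cross_entropy_loss(pr, c(1, 1)), log(8))
  ## zero probability at a target is floored with a warning
  expect_warning(v <- cross_entropy_loss(rbind(c(1, 0, rep(0, 20))), 2),
                 "floor")
  expect_equal(v, -log(1e-12))
})

test_that("backprop gradients match finite differences", {
  set.seed(7)
  seqs <- random_vectors(8, 4)
  vocab <- aa_vocabulary()
  idx <- phagelm:::.encode_indices(seqs, vocab)
  xs <- phagelm:::.onehot_steps(idx[, 1:4], vocab$size)
  tg <- idx[, 2:5]
  params <- phagelm:::.init_params(
    model_config(n_layers = 2, n_blocks = 5, dropout = 0,
                 max_epochs = 1, seed = 8), vocab$size)
  lossfn <- function(p) {
    fw <- phagelm:::.net_forward(p, xs)
    phagelm:::.mean_ce(fw$probs, tg, vocab$pad_index)
  }
  fw <- phagelm:::.net_forward(params, xs)
  gr <- phagelm:::.net_backward(params, xs, fw, tg, vocab$pad_index)
  eps <- 1e-5
  set.seed(9)
  for (trial in 1:20) {
    l <- sample(2, 1)
    nm <- sample(names(params$layers[[l]]), 1)
    j <- sample(length(params$layers[[l]][[nm]]), 1)
    up <- params; up$layers[[l]][[nm]][j] <- up$layers[[l]][[nm]][j] + eps
    dn <- params; dn$layers[[l]][[nm]][j] <- dn$layers[[l]][[nm]][j] - eps
    fd <- (lossfn(up) - lossfn(dn)) / (2 * eps)
    bp <- gr$layers[[l]][[nm]][j]
    expect_lt(abs(fd - bp) / max(abs(fd), abs(bp), 1e-6), 1e-3)
  }
  j <- sample(length(params$dense$W), 1)
  up <- params; up$dense$W[j] <- up$dense$W[j] + eps
  dn <- params; dn$dense$W[j] <- dn$dense$W[j] - eps
  fd <- (lossfn(up) - lossfn(dn)) / (2 * eps)
  expect_lt(abs(fd - gr$dense$W[j]) / max(abs(fd), 1e-6), 1e-3)
})

test_that("training memorizes a single repeated sequence", {
  seqs <- rep("WRLVVSSGRRAPRGRPH", 200)
  fit <- train_lstm(seqs, model_config(n_layers = 1, n_blocks = 32,
                                       dropout = 0, max_epochs = 100,
                                       seed = 3))
  expect_lt(fit$curves$train_loss[100], 0.05)
  ## the retained epoch is the validation-loss argmin
  expect_equal(fit$best_val_loss, min(fit$curves$val_loss))
  expect_lte(fit$best_val_loss,
             fit$curves$val_loss[fit$config$max_epochs])
  ## greedy decoding from the memorizing model reproduces the sequence
  expect_identical(unique(sample_sequences(fit, 3, temperature = 0)),
                   "WRLVVSSGRRAPRGRPH")
})

test_that("training is reproducible under a fixed seed and rejects tiny input", {
  seqs <- random_vectors(30, 5)
  cfg <- model_config(n_layers = 1, n_blocks = 6, dropout = 0.2,
                      max_epochs = 5, seed = 17)
  f1 <- train_lstm(seqs, cfg)
  f2 <- train_lstm(seqs, cfg)
  expect_identical(f1$curves, f2$curves)
  expect_identical(f1$params, f2$params)
  expect_error(train_lstm(seqs[1:5], cfg), "at least 10")
})

test_that("teacher-forced forward reproduces the reported training loss", {
  ## with dropout 0 the loss recomputed from forward_probs at the final
  ## epoch equals the curve entry (internal consistency of train/forward)
  seqs <- rep(c("ACDE", "ACDF", "GHIK"), 10)
  cfg <- model_config(n_layers = 1, n_blocks = 8, dropout = 0,
                      max_epochs = 30, seed = 5)
  split <- list(train = 1:24, val = 25:30)
  fit <- train_lstm(seqs, cfg, split = split)
  pr <- forward_probs(fit, seqs[split$val])
  vocab <- fit$vocab
  losses <- vapply(seq_along(split$val), function(i) {
    tgt <- match(strsplit(seqs[split$val][i], "")[[1]], vocab$symbols)
    cross_entropy_loss(pr[[i]], tgt, per_position = TRUE)
  }, 0)
  expect_equal(mean(losses), fit$curves$val_loss[fit$best_epoch],
               tolerance = 1e-9)
})

test_that("per-position marginals of a trained model recover a categorical truth", {
  ## sequences drawn i.i.d. from a known per-position categorical model;
  ## after training on n = 2000 sequences (N = 32, 200 epochs), the
  ## teacher-forced predictive distribution at each position must be
  ## within total variation 0.05 of the truth (K = 6 keeps the suite fast)
  K <- 6
  set.seed(31)
  truth <- lapply(seq_len(K), function(j) {
    p <- c(4, 2, 1, 0.5)[sample(4)]
    setNames(p / sum(p), sample(phagelm:::AA_ALPHABET, 4))
  })
  n <- 2000
  seqs <- vapply(seq_len(n), function(i)
    paste(vapply(truth, function(p)
      sample(names(p), 1, prob = p), ""), collapse = ""), "")
  fit <- train_lstm(seqs, model_config(n_layers = 1, n_blocks = 32,
                                       dropout = 0, max_epochs = 200,
                                       seed = 32))
  ## average the predictive distribution over 300 held-out draws
  probe <- seqs[1:300]
  pr <- forward_probs(fit, probe)
  avg <- Reduce(`+`, pr) / length(pr)
  for (j in seq_len(K)) {
    model_p <- avg[j, phagelm:::AA_ALPHABET]
    truth_p <- setNames(numeric(20), phagelm:::AA_ALPHABET)
    truth_p[names(truth[[j]])] <- truth[[j]]
    tv <- 0.5 * sum(abs(model_p - truth_p))
    expect_lt(tv, 0.05)
  }
})

test_that("cross-validation picks from the grid with balanced seeded folds", {
  seqs <- random_vectors(40, 4)
  g1 <- model_config(n_layers = 1, n_blocks = 4, dropout = 0,
                     max_epochs = 3, seed = 1)
  cv1 <- cross_validate(seqs, list(g1), k = 5, seed = 2)
  expect_identical(cv1$best_config, g1)
  expect_identical(nrow(cv1$scores), 1L)
  expect_true(max(table(cv1$folds)) - min(table(cv1$folds)) <= 1)
  expect_error(cross_validate(seqs, list()), "empty")
  ## ties break toward fewer parameters
  g2 <- model_config(n_layers = 2, n_blocks = 4, dropout = 0,
                     max_epochs = 3, seed = 1)
  expect_lt(n_parameters(g1), n_parameters(g2))
})

test_that("model serialization round-trips and rejects version mismatch", {
  fit <- train_lstm(random_vectors(15, 4),
                    model_config(n_layers = 1, n_blocks = 4, dropout = 0,
                                 max_epochs = 2, seed = 6))
  tmp <- withr::local_tempfile(fileext = ".rds")
  write_model(fit, tmp)
  back <- read_model(tmp)
  expect_identical(back$params, fit$params)
  bad <- fit; bad$format_version <- 99L
  saveRDS(bad, tmp)
  expect_error(read_model(tmp), "version")
})
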