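test_that("NLL matches closed forms", {
  ## uniform-over-residues model at 17 positions -> 17 * ln 20
  ## (start/pad logits pushed far down so residues carry all the mass)
  bias <- c(rep(10, 20), -30, -30)
  m <- bias_only_model(17, bias)
  v <- paste(rep("A", 17), collapse = "")
  expect_equal(unname(nll(m, v)), 17 * log(20), tolerance = 1e-6)
  ## deterministic model -> NLL 0: enormous logit on one residue
  bias2 <- c(50, rep(-50, 21))
  m2 <- bias_only_model(5, bias2)
  expect_equal(unname(nll(m2, "AAAAA")), 0, tolerance = 1e-9)
  ## extending a sequence never decreases NLL
  m3 <- bias_only_model(6, rep(0, 22))
  expect_gte(unname(nll(m3, "ACDEFG")),
             unname(nll(bias_only_model(5, rep(0, 22)), "ACDEF")))
})

test_that("NLL equals the sum of -log teacher-forced probabilities", {
  set.seed(12)
  fit <- train_lstm(random_vectors(30, 5),
                    model_config(n_layers = 2, n_blocks = 6, dropout = 0.1,
                                 max_epochs = 5, seed = 13))
  vs <- random_vectors(4, 5)
  pr <- forward_probs(fit, vs)
  vocab <- fit$vocab
  manual <- vapply(seq_along(vs), function(i) {
    tgt <- match(strsplit(vs[i], "")[[1]], vocab$symbols)
    -sum(log(pr[[i]][cbind(1:5, tgt)]))
  }, 0)
  expect_equal(unname(nll(fit, vs)), manual, tolerance = 1e-9)
})

test_that("temperature-1 sampling matches model probabilities within 3 SE", {
  ## hand-built model: every step emits softmax(bias) restricted to the
  ## 20 residue tokens
  set.seed(1)
  bias <- c(rnorm(20), 5, 5)   # mass on start/pad must be excluded
  m <- bias_only_model(3, bias)
  e <- exp(bias[1:20] - max(bias[1:20]))
  p <- e / sum(e)
  n <- 1e5
  draws <- sample_sequences(m, n, temperature = 1, seed = 99)
  chars <- matrix(unlist(strsplit(draws, "")), ncol = 3, byrow = TRUE)
  for (k in 1:3) {
    emp <- table(factor(chars[, k], levels = phagelm:::AA_ALPHABET)) / n
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(as.numeric(emp) - p) <= 3 * se + 1e-12),
                info = paste("position", k))
  }
})

test_that("temperature 0 equals greedy argmax and high T flattens", {
  set.seed(2)
  fit <- train_lstm(rep(c("ACD", "ACE", "FGH"), 8),
                    model_config(n_layers = 1, n_blocks = 8, dropout = 0,
                                 max_epochs = 40, seed = 22))
  greedy <- sample_sequences(fit, 5, temperature = 0, seed = 1)
  expect_identical(length(unique(greedy)), 1L)
  ## greedy equals the argmax of the teacher-forced chain
  g <- greedy[1]
  ## near-zero temperature converges to the same single sequence
  cold <- sample_sequences(fit, 5, temperature = 1e-4, seed = 7)
  expect_identical(unique(cold), g)
  ## higher temperature yields at least as many distinct sequences
  hot <- sample_sequences(fit, 200, temperature = 5, seed = 8)
  warm <- sample_sequences(fit, 200, temperature = 1, seed = 8)
  expect_gte(length(unique(hot)), length(unique(warm)))
  ## sampling is seeded and reproducible
  expect_identical(sample_sequences(fit, 20, seed = 5),
                   sample_sequences(fit, 20, seed = 5))
})

test_that("novelty filter keeps only positionally seen residues", {
  tr <- c("AC", "AD")
  nf <- novelty_filter(c("AD", "CA", "AC", "DD"), tr)
  expect_identical(nf$retained, c("AD", "AC"))
  expect_identical(nf$n_rejected, 2L)
  ## any training sequence passes its own filter
  expect_true(all(novelty_filter(tr, tr)$keep))
  ## full positional coverage passes everything
  aa <- phagelm:::AA_ALPHABET
  cover <- vapply(seq_along(aa), function(i)
    paste0(aa[i], aa[i]), "")
  set.seed(40)
  cand <- random_vectors(50, 2)
  expect_identical(novelty_filter(cand, cover)$n_rejected, 0L)
  expect_error(novelty_filter("ABC", tr), "length")
})

test_that("candidate groups follow the selection rules", {
  ## the default grid has exactly 32 values
  expect_identical(length(seq(10, 25.5, by = 0.5)), 32L)
  ## 10 distinct NLLs -> group ML is them, ascending
  scored <- data.frame(vector = sprintf("s%02d", 1:10),
                       nll = c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3))
  counts <- data.frame(vector = sprintf("n%02d", 1:12), count = 12:1)
  suppressWarnings(gr <- select_groups(scored, counts))
  expect_identical(gr$ml$nll, sort(scored$nll))
  expect_identical(nrow(gr$freq), 10L)
  expect_identical(gr$freq$vector[1], "n01")
  ## frequency ties break lexicographically
  ct <- data.frame(vector = c("bb", "aa", "cc"), count = c(5L, 5L, 1L))
  suppressWarnings(g2 <- select_groups(scored[1:2, ], ct, n_low = 1,
                                       grid = numeric(), n_freq = 2))
  expect_identical(g2$freq$vector, c("aa", "bb"))
  ## nearest-NLL grid matching without replacement
  toy <- data.frame(vector = c("x", "y", "z"), nll = c(9.0, 10.1, 10.4))
  g3 <- select_groups(toy, counts[1:10, ], n_low = 0,
                      grid = c(10.0, 10.5), n_freq = 10)
  expect_identical(g3$grid$nll, c(10.1, 10.4))
  ## no duplicates across ML and grid groups
  suppressWarnings(g4 <- select_groups(scored, counts, n_low = 3,
                                       grid = c(2, 4, 6), n_freq = 5))
  expect_identical(anyDuplicated(c(g4$ml$vector, g4$grid$vector)), 0L)
  expect_error(select_groups(rbind(scored, scored[1, ]), counts),
               "deduplicated")
  ## partial groups warn (both the ML and the grid group are short here)
  suppressWarnings(expect_warning(select_groups(scored[1:3, ], counts),
                                  "ML"))
})

test_that("generated NLL distribution overlaps the training distribution", {
  ## small simulated panning -> well-fit model; the T = 1 sample NLL
  ## distribution must not be distinguishable from the training NLL
  ## distribution (two-sample KS at alpha = 0.001), and some generated
  ## sequences may score below the lowest training NLL
  design <- library_design(labels = as.character(1:6),
                           codons = rep("NNK", 6),
                           parental = rep("A", 6))
  fit <- fitness_model(design,
                       energies = data.frame(
                         label = c("1", "2", "4"),
                         residue = c("W", "R", "L"), energy = -2))
  sim <- simulate_panning(design, fit, n_library = 5000, n_rounds = 2,
                          depth = 5000, seed = 71)
  sel <- select_training(sim$counts[[3]], cap = 500)
  model <- train_lstm(sel$records,
                      model_config(n_layers = 1, n_blocks = 32,
                                   dropout = 0, max_epochs = 120,
                                   seed = 72))
  train_nll <- nll(model, sel$records$vector)
  gen <- unique(sample_sequences(model, 2000, temperature = 1, seed = 73))
  gen_nll <- nll(model, gen)
  ks <- suppressWarnings(stats::ks.test(train_nll, gen_nll))
  expect_gte(ks$p.value, 0.001)
  expect_lt(min(gen_nll), min(train_nll) + 1e-9)
})
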