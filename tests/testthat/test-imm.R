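test_that("fitted chains match a direct-count oracle exactly", {
  # codon alphabet, tiny corpus: 6 codons of which 3 are GCT
  seqs <- c("GCTGCTGCTAAAAAGAAT")
  ab <- alphabet("codon")
  for (k in 0:1) {
    fitted <- fit_chain(seqs, "codon", k)
    oracle <- chain_oracle(lapply(seqs, orfclass:::encode_units, alphabet = ab),
                           B = 61L, k = k)
    expect_equal(unname(fitted$prob), unname(oracle), tolerance = 1e-12)
  }
  # 0-order fixed point: observed symbols keep their empirical frequency
  f0 <- fit_chain(seqs, "codon", 0)
  expect_equal(f0$prob[1, match("GCT", ab$symbols)], 0.5, tolerance = 1e-9)
  # unseen pretext row follows the 0-order distribution
  f1 <- fit_chain(seqs, "codon", 1)
  unseen <- setdiff(seq_len(61), match(c("GCT", "AAA", "AAG"), ab$symbols))[1]
  p0 <- tabulate(match(c("GCT", "GCT", "GCT", "AAA", "AAG", "AAT"),
                       ab$symbols), 61) / 6
  expect_equal(f1$prob[unseen, ], (p0 + 1e-12) / sum(p0 + 1e-12),
               tolerance = 1e-10)
})

test_that("every conditional distribution is normalized and positive", {
  set.seed(5)
  seqs <- replicate(8, toy_orf(sample(alphabet("codon")$symbols, 30, TRUE)))
  seqs <- vapply(seqs, strip_start_and_stops, character(1), USE.NAMES = FALSE)
  for (a in c("dna", "codon")) {
    for (k in 0:2) {
      ch <- fit_chain(seqs, a, k)
      probs <- if (ch$frame_stratified) ch$prob else list(ch$prob)
      for (P in probs) {
        expect_true(all(P > 0))
        expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9)
      }
    }
  }
  prot <- vapply(seqs, translate_codons, character(1), USE.NAMES = FALSE)
  ch <- fit_chain(prot, "protein", 1)
  expect_true(all(ch$prob > 0))
  expect_error(fit_chain(character(0), "codon", 0), "empty")
})

test_that("stored probabilities equal the published parameter budget", {
  set.seed(6)
  seqs <- replicate(5, strrep("GCTAAAGATCCA", 8))
  for (a in c("dna", "codon")) {
    K <- if (a == "dna") 3L else 1L
    chains <- lapply(0:K, function(k) fit_chain(seqs, a, k))
    stored <- sum(vapply(chains, function(ch) {
      if (ch$frame_stratified) sum(vapply(ch$prob, length, numeric(1)))
      else length(ch$prob)
    }, numeric(1)))
    expect_equal(stored, cumulative_parameter_count(a, K))
  }
})

test_that("EM weights are convex, monotone in likelihood, and trivial at K=0", {
  set.seed(8)
  seqs <- replicate(10, paste(
    sample(c("GCT", "AAA", "CCC", "GGG"), 60, TRUE, prob = c(.4, .3, .2, .1)),
    collapse = ""))
  chains0 <- list(fit_chain(seqs, "codon", 0))
  expect_equal(fit_interpolation_weights(chains0, seqs)$weights, 1)

  chains <- lapply(0:1, function(k) fit_chain(seqs, "codon", k))
  w <- fit_interpolation_weights(chains, seqs, max_iter = 200)
  expect_true(all(w$weights >= 0))
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)

  # manual EM trace: the log-likelihood never decreases
  ab <- alphabet("codon")
  M <- do.call(rbind, lapply(
    lapply(seqs, orfclass:::encode_units, alphabet = ab),
    orfclass:::component_matrix, chains = chains))
  wv <- c(0.5, 0.5)
  ll_prev <- -Inf
  for (i in 1:50) {
    mix <- as.vector(M %*% wv)
    ll <- sum(log(mix))
    expect_gte(ll, ll_prev - 1e-10)
    ll_prev <- ll
    wv <- wv * colMeans(M / mix)
    wv <- wv / sum(wv)
  }
})

test_that("mixture predictive distribution recovers a 0-order generator", {
  # i.i.d. codons: at K = 1 the interpolated model's predictive probabilities
  # must approach the generating distribution whatever the weights do
  set.seed(9)
  gen_symbols <- c("GCT", "AAA", "CCC", "GGG")
  gen_p <- c(0.4, 0.3, 0.2, 0.1)
  big <- replicate(50, paste(sample(gen_symbols, 1000, TRUE, gen_p),
                             collapse = ""))
  chains <- lapply(0:1, function(k) fit_chain(big, "codon", k))
  w <- fit_interpolation_weights(chains, big)$weights
  ab <- alphabet("codon")
  idx <- match(gen_symbols, ab$symbols)
  for (ctx in idx) {
    pred <- w[1] * chains[[1]]$prob[1, idx] +
      w[2] * chains[[2]]$prob[ctx, idx]
    expect_equal(unname(pred), gen_p, tolerance = 0.02)
  }
})

test_that("scores sum per-position log-probabilities and ties go negative", {
  seqs <- c("GCTAAAGCTAAA", "AAAGCTAAAGCT")
  orfs <- data.frame(seq = rep(seqs, 2), label = rep(c(1L, -1L), each = 2),
                     stringsAsFactors = FALSE)
  model <- imm_train(orfs, "codon", K = 0)
  # identical class training sets: scores equal, tie classified -1
  s <- imm_score(model, orfs[1:2, ])
  expect_equal(s[, 1], s[, 2], tolerance = 1e-12)
  expect_equal(imm_classify(model, orfs[1:2, ]), c(-1L, -1L))
  # additivity over concatenation for a 0-order model
  s1 <- unname(imm_score(model, "GCTAAA")[1, 1])
  s2 <- unname(imm_score(model, "GCTGCT")[1, 1])
  s12 <- unname(imm_score(model, "GCTAAAGCTGCT")[1, 1])
  expect_equal(s12, s1 + s2, tolerance = 1e-10)
  # longer sequences score lower
  expect_lt(imm_score(model, "GCTAAAGCT")[1, 1], imm_score(model, "GCT")[1, 1])
  # hand-computable: 1-codon test scores log of fitted 0-order probability
  p_gct <- model$positive$chains[[1]]$prob[1, match("GCT",
                                                   alphabet("codon")$symbols)]
  expect_equal(unname(imm_score(model, "GCT")[1, 1]), log(p_gct),
               tolerance = 1e-12)
})

test_that("strongly contrasting codon usage is classified correctly", {
  orfs <- contrast_dataset(30, 60, seed = 2)
  model <- imm_train(orfs, "codon", K = 1)
  expect_equal(imm_classify(model, orfs), orfs$label)
  # dna and protein representations also separate these vocabularies
  for (rep_ in c("dna", "protein")) {
    m <- imm_train(orfs, rep_, K = default_order(rep_))
    expect_gte(mean(imm_classify(m, orfs) == orfs$label), 0.95)
  }
  # prior shifts the decision threshold
  expect_true(all(imm_classify(model, orfs, prior_logodds = -1e6) == -1L))
})

test_that("IMM models survive a JSON round-trip", {
  orfs <- contrast_dataset(10, 30, seed = 3)
  for (rep_ in c("codon", "dna")) {
    model <- imm_train(orfs, rep_, K = if (rep_ == "dna") 2L else 1L)
    path <- tempfile(fileext = ".json")
    write_imm(model, path)
    back <- read_imm(path)
    expect_equal(imm_score(back, orfs[c(1, 15), ]),
                 imm_score(model, orfs[c(1, 15), ]), tolerance = 1e-9)
  }
})
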