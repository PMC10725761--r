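test_that("n-gram training counts all sub-sequences at every order", {
  st <- ngram_store(max_order = 1)
  ngram_train(st, c("A", "B", "A", "B"))
  expect_equal(ngram_counts(st, "A")[["B"]], 2)
  expect_equal(ngram_counts(st, "B")[["A"]], 1)
  expect_equal(sum(ngram_counts(st)), 4)       # order-0 sees every event
  # additivity: training twice doubles every count
  ngram_train(st, c("A", "B", "A", "B"))
  expect_equal(ngram_counts(st, "A")[["B"]], 4)
  # a length-L sequence contributes L - k contexts of order k
  st2 <- ngram_store(max_order = 3)
  tokens <- c("a", "b", "c", "d", "e", "f")
  ngram_train(st2, tokens)
  for (k in 1:3) {
    total_k <- sum(vapply(seq_len(length(tokens) - k), function(i) {
      cnt <- ngram_counts(st2, tokens[i:(i + k - 1)])
      if (is.null(cnt)) 0 else sum(cnt)
    }, numeric(1)))
    expect_equal(total_k, length(tokens) - k)
  }
})

test_that("ppm_predict is a strictly positive distribution", {
  st <- ngram_store(max_order = 2)
  vocab <- c("A", "B", "C")
  # empty store: uniform
  expect_equal(unname(ppm_predict(st, character(0), vocab)), rep(1 / 3, 3))
  ngram_train(st, c("A", "B", "A", "B", "A"))
  for (ctx in list(character(0), "A", "B", c("A", "B"), c("B", "A"), "C")) {
    p <- ppm_predict(st, ctx, vocab)
    expect_true(all(p > 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  # counts dominate: after A, B is much likelier than A
  p <- ppm_predict(st, "A", vocab)
  expect_gt(p[["B"]], p[["A"]])
})

test_that("ppm_predict matches the brute-force escape recursion oracle", {
  vocab <- c("v", "w", "x", "y", "z")
  set.seed(42)
  seqs <- list(sample(vocab, 15, replace = TRUE),
               sample(vocab, 15, replace = TRUE))
  for (escape in c("C", "A", "D")) {
    for (max_order in c(1, 3, 10)) {
      st <- ngram_store(max_order = max_order)
      for (s in seqs) ngram_train(st, s)
      # every observed context of every order, plus unseen ones
      ctxs <- list(character(0), "z", c("z", "z", "z"))
      for (s in seqs) {
        for (i in seq_along(s)) {
          for (k in 0:min(max_order, i - 1)) {
            ctxs <- c(ctxs, list(if (k == 0) character(0)
                                 else s[(i - k):(i - 1)]))
          }
        }
      }
      for (ctx in ctxs) {
        got <- ppm_predict(st, ctx, vocab, escape = escape)
        want <- oracle_ppm_predict(seqs, ctx, vocab, max_order, escape)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("observing a symbol in a context never decreases its probability", {
  vocab <- c("A", "B", "C")
  set.seed(7)
  for (rep in 1:10) {
    tokens <- sample(vocab, 12, replace = TRUE)
    st <- ngram_store(max_order = 3)
    ngram_train(st, tokens)
    ctx <- sample(vocab, sample(0:2, 1), replace = TRUE)
    sym <- sample(vocab, 1)
    before <- ppm_predict(st, ctx, vocab)[[sym]]
    add_seq <- c(ctx, sym)
    ngram_train(st, add_seq)
    after <- ppm_predict(st, ctx, vocab)[[sym]]
    expect_gte(after, before - 1e-12)
  }
})

test_that("online short-term prediction accumulates within-song evidence", {
  # the short-term component predicts each event from the song's proper
  # prefix; on a constant song the probability of the repeated chord grows
  vocab <- c("A", "B")
  p_at <- function(i) {
    st <- ngram_store(max_order = Inf)
    ngram_train(st, rep("A", i - 1))
    ppm_predict(st, rep("A", i - 1), vocab)[["A"]]
  }
  expect_equal(p_at(1), 0.5)             # empty prefix: uniform
  expect_gt(p_at(4), p_at(2))
  expect_gt(p_at(8), p_at(4))
  # unbounded order: the full prefix is usable as context
  st <- ngram_store(max_order = Inf)
  ngram_train(st, c("A", "B", "A", "B", "A", "B", "A"))
  long_ctx <- c("A", "B", "A", "B", "A", "B", "A")
  expect_gt(ppm_predict(st, long_ctx, vocab)[["B"]], 0.5)
})

test_that("geometric-mean combination is idempotent and normalized", {
  p <- c(A = 0.5, B = 0.3, C = 0.2)
  expect_equal(combine_geometric(p, p), p)
  u <- c(A = 1, B = 1, C = 1) / 3
  q <- combine_geometric(u, p)
  expect_equal(unname(q), unname(sqrt(p) / sum(sqrt(p))))
  expect_equal(sum(combine_geometric(p, rev(p)[names(p)])), 1,
               tolerance = 1e-9)
  expect_error(combine_geometric(p, p[1:2]), "support")
})

test_that("information content and entropy follow their closed forms", {
  p4 <- stats::setNames(rep(0.25, 4), letters[1:4])
  expect_equal(information_content(p4, "a"), 2)
  expect_equal(entropy_bits(p4), 2)
  p1 <- c(a = 1)
  expect_equal(information_content(p1, "a"), 0)
  expect_equal(entropy_bits(p1), 0)
  p1024 <- stats::setNames(c(1 / 1024, rep(1023 / 1024 / 3, 3)),
                           letters[1:4])
  expect_equal(information_content(p1024, "a"), 10)
  expect_error(information_content(p4, "zz"), "support")
  # entropy bounded by log2 |S|
  set.seed(1)
  for (rep in 1:20) {
    w <- stats::rexp(6)
    expect_lte(entropy_bits(w / sum(w)), log2(6) + 1e-12)
  }
})

test_that("cross-validated expectancy partitions songs and is deterministic", {
  corp <- generate_corpus(n_songs = 8, length_range = c(8, 10),
                          vocab_size = 5, seed = 11)
  ef <- chord_expectancy(corp, max_order = 3, folds = 4, seed = 5)
  # every chord got exactly one IC and one entropy
  expect_equal(nrow(ef), nrow(corp))
  expect_true(all(ef$ic_bits >= 0))
  expect_true(all(ef$entropy_bits <= log2(5) + 1e-12))
  # fold assignment is a partition of the songs
  fa <- attr(ef, "fold_assignment")
  expect_setequal(names(fa), unique(corp$song_id))
  expect_true(all(table(fa) >= 1))
  # determinism: same seed, bit-for-bit equal
  ef2 <- chord_expectancy(corp, max_order = 3, folds = 4, seed = 5)
  expect_identical(ef$ic_bits, ef2$ic_bits)
  expect_identical(attr(ef, "fold_assignment"), attr(ef2, "fold_assignment"))
  # leave-one-out limit: folds = number of songs
  ef3 <- chord_expectancy(corp, max_order = 3, folds = 8, seed = 5)
  expect_equal(sort(unique(unname(attr(ef3, "fold_assignment")))), 1:8)
  expect_error(chord_expectancy(corp, folds = 9, seed = 1), "songs")
})

test_that("bigram variant truncates context to one chord", {
  corp <- generate_corpus(n_songs = 6, length_range = c(8, 10),
                          vocab_size = 4, seed = 3)
  ef <- chord_expectancy(corp, folds = 3, seed = 2, bigram = TRUE)
  expect_true(all(ef$ic_bits >= 0))
  # explicit truncation: a long context behaves as its last token
  st <- ngram_store(max_order = 1)
  ngram_train(st, c("A", "B", "A", "C"))
  expect_equal(ppm_predict(st, c("C", "B", "A"), c("A", "B", "C")),
               ppm_predict(st, "A", c("A", "B", "C")))
})

test_that("mean cross-validated IC approaches the chain's conditional entropy", {
  # corpus drawn from a known first-order Markov chain: with enough data,
  # the model's average surprise converges to the source entropy rate
  corp <- generate_corpus(n_songs = 300, length_range = c(30, 38),
                          vocab_size = 5, concentration = 1, seed = 77)
  P <- attr(corp, "transition")
  # stationary distribution of the chain
  ev <- eigen(t(P))
  pi_s <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_s <- pi_s / sum(pi_s)
  h_cond <- -sum(vapply(seq_len(nrow(P)), function(i) {
    pi_s[i] * sum(ifelse(P[i, ] > 0, P[i, ] * log2(P[i, ]), 0))
  }, numeric(1)))
  ef <- chord_expectancy(corp, max_order = 2, folds = 5, seed = 9,
                         components = "ltm")
  # first positions have no context; drop them for the rate comparison
  ic <- ef$ic_bits[ef$position > 1]
  expect_lt(abs(mean(ic) - h_cond) / h_cond, 0.05)
})

test_that("synthetic corpora give left-skewed information content", {
  corp <- generate_corpus(n_songs = 30, vocab_size = 24,
                          concentration = 0.1, seed = 13)
  ef <- chord_expectancy(corp, max_order = 5, folds = 5, seed = 4)
  expect_lt(median(ef$ic_bits), mean(ef$ic_bits))
})
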