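# Independent oracles and fixture builders shared across the suite.

# Brute-force interpolated-PPM recursion computing counts by scanning the
# raw sequences (no count store); independent of the package's
# implementation path.
oracle_ppm_predict <- function(seqs, context, vocab, max_order,
                               escape = "C") {
  count_after <- function(ctx) {
    cnt <- stats::setNames(numeric(length(vocab)), vocab)
    k <- length(ctx)
    for (s in seqs) {
      L <- length(s)
      for (i in seq_len(L)) {
        if (i - k < 1) next
        if (k == 0 || identical(s[(i - k):(i - 1)], ctx)) {
          cnt[s[i]] <- cnt[s[i]] + 1
        }
      }
    }
    cnt
  }
  rec <- function(ctx) {
    if (length(ctx) == 0) {
      cnt <- count_after(character(0))
      n <- sum(cnt)
      base <- rep(1 / length(vocab), length(vocab))
      if (n == 0) return(base)
      tt <- sum(cnt > 0)
      return(switch(escape,
        C = cnt / (n + tt) + (tt / (n + tt)) * base,
        A = cnt / (n + 1) + (1 / (n + 1)) * base,
        D = pmax(cnt - 0.5, 0) / n + (tt / (2 * n)) * base))
    }
    cnt <- count_after(ctx)
    n <- sum(cnt)
    if (n == 0) return(rec(ctx[-1]))
    lower <- rec(ctx[-1])
    tt <- sum(cnt > 0)
    switch(escape,
      C = cnt / (n + tt) + (tt / (n + tt)) * lower,
      A = cnt / (n + 1) + (1 / (n + 1)) * lower,
      D = pmax(cnt - 0.5, 0) / n + (tt / (2 * n)) * lower)
  }
  if (length(context) > max_order) {
    context <- context[(length(context) - max_order + 1):length(context)]
  }
  out <- rec(context)
  stats::setNames(as.numeric(out), vocab)
}

# Conjugate Gaussian mean model: exact leave-one-out log predictive
# densities and posterior draws for the PSIS-LOO oracle.
conjugate_mean_model <- function(y, sigma = 1, tau0 = 1, S = 4000,
                                 seed = 1) {
  post <- function(yy) {
    v <- 1 / (length(yy) / sigma^2 + 1 / tau0^2)
    m <- v * sum(yy) / sigma^2
    c(m = m, v = v)
  }
  set.seed(seed)
  p <- post(y)
  mu_draws <- rnorm(S, p["m"], sqrt(p["v"]))
  ll <- vapply(y, function(yi) dnorm(yi, mu_draws, sigma, log = TRUE),
               numeric(S))
  exact <- vapply(seq_along(y), function(i) {
    pi <- post(y[-i])
    dnorm(y[i], pi["m"], sqrt(pi["v"] + sigma^2), log = TRUE)
  }, numeric(1))
  list(loglik = ll, exact_loo = sum(exact))
}

# Group-level rating data simulated at the study's effect sizes, ready for
# fitting: standardized predictors, first chords dropped.
make_group_ratings <- function(seed, n_songs = 30, length_range = c(30, 38),
                               innovation_sd = 0.35, song_effect_sd = 0.1,
                               ar1_rho = 0.3,
                               betas = NULL) {
  stim <- chordexpect::generate_stimulus_set(
    n_songs = n_songs, length_range = length_range, vocab_size = 12,
    seed = seed
  )
  n <- nrow(stim)
  spec_args <- list(
    n_subjects = c(musician = 1, nonmusician = 1),
    innovation_sd = innovation_sd, song_effect_sd = song_effect_sd,
    ar1_rho = ar1_rho
  )
  if (!is.null(betas)) spec_args$betas <- betas
  rs <- do.call(chordexpect::rater_spec, spec_args)
  set.seed(seed + 1000)
  frames <- stim
  frames$ic <- rnorm(n)
  frames$tonal_dissimilarity <- rnorm(n)
  frames <- chordexpect::simulate_covariates(frames, seed = seed + 2000)
  rat <- chordexpect::simulate_ratings(frames, rs, seed = seed + 3000)
  rat <- dplyr::ungroup(dplyr::filter(dplyr::group_by(rat, song_id),
                                      position > 1))
  chordexpect::standardize(rat, c("ic", "tonal_dissimilarity", "valence",
                                  "arousal"))
}

fit_quick <- function(data, spec, seed = 1, chains = 2, warmup = 300,
                      iter = 300) {
  suppressWarnings(chordexpect::fit_expectancy_model(
    data, spec, chains = chains, warmup = warmup, iter = iter, seed = seed
  ))
}
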