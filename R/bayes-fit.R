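riw <- function(df, scale) {
  # inverse-Wishart draw via the Wishart of the inverse scale
  solve(stats::rWishart(1, df, solve(scale))[, , 1])
}

rmvnorm_prec <- function(mean, prec_chol) {
  mean + backsolve(prec_chol, rnorm(length(mean)))
}

gibbs_chain <- function(des, n_keep, warmup, seed, nu = 2, A = 1,
                        rho_grid = seq(-0.99, 0.99, length.out = 199)) {
  y <- des$y; X <- des$X
  n <- length(y); p <- ncol(X); d <- p
  song <- des$song; J <- max(song)
  first <- des$first
  idx_by_song <- split(seq_len(n), song)
  ylag <- c(0, y[-n]); Xlag <- rbind(0, X[-n, , drop = FALSE])
  set.seed(seed)
  beta <- rnorm(p, 0, 0.1)
  b <- matrix(0, J, d)
  sig2 <- 1; a_sig <- 1
  rho <- 0
  Sigma <- diag(d); Omega_inv <- diag(d)
  a_vec <- rep(1, d)
  S1 <- sum(first); nf <- !first
  keep_beta <- matrix(NA_real_, n_keep, p)
  keep_sig <- numeric(n_keep); keep_rho <- numeric(n_keep)
  keep_tau <- matrix(NA_real_, n_keep, d)
  keep_b <- array(NA_real_, c(n_keep, J, d))
  lg1 <- 0.5 * log(1 - rho_grid^2)
  for (it in seq_len(warmup + n_keep)) {
    # quasi-difference at the current rho
    a1 <- sqrt(1 - rho^2)
    ys <- y - rho * ylag; ys[first] <- a1 * y[first]
    Xs <- X - rho * Xlag; Xs[first, ] <- a1 * X[first, , drop = FALSE]
    zb <- rowSums(Xs * b[song, , drop = FALSE])
    # population coefficients | rest  (prior N(0, 1))
    prec <- crossprod(Xs) / sig2 + diag(p)
    ch <- chol(prec)
    mu <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, ys - zb) / sig2))
    beta <- rmvnorm_prec(drop(mu), ch)
    xb <- drop(Xs %*% beta)
    # song-level effects | rest
    for (j in seq_len(J)) {
      ix <- idx_by_song[[j]]
      Zj <- Xs[ix, , drop = FALSE]
      rj <- ys[ix] - xb[ix]
      precj <- crossprod(Zj) / sig2 + Omega_inv
      chj <- chol(precj)
      muj <- backsolve(chj, forwardsolve(t(chj), crossprod(Zj, rj) / sig2))
      b[j, ] <- rmvnorm_prec(drop(muj), chj)
    }
    zb <- rowSums(Xs * b[song, , drop = FALSE])
    # innovation variance | rest  (Half-Cauchy(0,1) via IG mixture)
    ss <- sum((ys - xb - zb)^2)
    sig2 <- 1 / stats::rgamma(1, shape = (n + 1) / 2, rate = 1 / a_sig + ss / 2)
    a_sig <- 1 / stats::rgamma(1, shape = 1, rate = 1 + 1 / sig2)
    # song-effect covariance | rest  (Huang-Wand hierarchical IW)
    Sb <- crossprod(b)
    Sigma <- riw(nu + d - 1 + J, 2 * nu * diag(1 / a_vec, d) + Sb)
    Omega_inv <- solve(Sigma)
    a_vec <- 1 / stats::rgamma(d, shape = (nu + d) / 2,
                               rate = nu * diag(Omega_inv) + 1 / A^2)
    # AR(1) coefficient | rest  (uniform prior, griddy Gibbs)
    e <- y - drop(X %*% beta) - rowSums(X * b[song, , drop = FALSE])
    elag <- c(0, e[-n])
    A2 <- sum(e[nf]^2); B2 <- sum(e[nf] * elag[nf]); C2 <- sum(elag[nf]^2)
    FF <- sum(e[first]^2)
    ll <- S1 * lg1 - (1 - rho_grid^2) * FF / (2 * sig2) -
      (A2 - 2 * rho_grid * B2 + rho_grid^2 * C2) / (2 * sig2)
    pr <- exp(ll - max(ll))
    rho <- rho_grid[sample.int(length(rho_grid), 1, prob = pr)]
    if (it > warmup) {
      k <- it - warmup
      keep_beta[k, ] <- beta
      keep_sig[k] <- sqrt(sig2)
      keep_rho[k] <- rho
      keep_tau[k, ] <- sqrt(diag(Sigma))
      keep_b[k, , ] <- b
    }
  }
  list(beta = keep_beta, sigma = keep_sig, rho = keep_rho, tau = keep_tau,
       b = keep_b)
}

#' Fit the multilevel AR(1) regression by blocked Gibbs sampling
#'
#' Gaussian likelihood with population-level coefficients, song-level
#' varying effects on every term, and AR(1) residuals within each series
#' (song, or song x group). Priors: Normal(0,1) on coefficients,
#' Half-Cauchy(0,1) on the innovation scale, a Huang-Wand hierarchical
#' inverse-Wishart (nu = 2, A = 1; Half-t(2,1) scale margins, uniform
#' correlation margins) on the song-effect covariance, and uniform(-1,1)
#' on the AR(1) coefficient. All full conditionals are conjugate except
#' the AR(1) coefficient, which is drawn on a fine grid.
#'
#' @param data Merged rating/predictor tibble, or an `expectancy_design`.
#' @param spec A [regression_spec()]; ignored when `data` is already a
#'   design.
#' @param chains Number of chains (default 4).
#' @param warmup,iter Warmup and kept iterations per chain (defaults 2500
#'   and 2500, giving 10000 kept draws across 4 chains).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @return An object of class `expectancy_fit` with elements `draws`
#'   (kept draws x parameters, with chain ids), `b` (song-effect draws),
#'   `design`, `diagnostics` (split R-hat and effective sample size per
#'   parameter). A warning is raised if any split R-hat exceeds 1.01.
#' @export
fit_expectancy_model <- function(data, spec = NULL, chains = 4,
                                 warmup = 2500, iter = 2500, seed = 1L) {
  des <- if (inherits(data, "expectancy_design")) data
         else build_design(data, spec)
  p <- ncol(des$X)
  res <- purrr::map(seq_len(chains), function(ch) {
    gibbs_chain(des, n_keep = iter, warmup = warmup, seed = seed + ch)
  })
  terms <- colnames(des$X)
  draws <- do.call(rbind, purrr::map(res, function(r) {
    cbind(r$beta, sigma = r$sigma, rho = r$rho, r$tau)
  }))
  colnames(draws) <- c(paste0("b_", terms), "sigma", "rho",
                       paste0("tau_", terms))
  b_arr <- do.call(abind1, purrr::map(res, "b"))
  dimnames(b_arr) <- list(NULL, des$song_ids, terms)
  chain_id <- rep(seq_len(chains), each = iter)
  diag_tb <- mcmc_diagnostics(draws, chain_id)
  bad <- diag_tb$rhat > 1.01
  if (any(bad, na.rm = TRUE)) {
    warning("convergence warning: split R-hat > 1.01 for ",
            paste(diag_tb$parameter[which(bad)], collapse = ", "),
            call. = FALSE)
  }
  structure(list(draws = draws, b = b_arr, chain = chain_id, design = des,
                 spec = des$spec, diagnostics = diag_tb, chains = chains,
                 warmup = warmup, iter = iter, seed = seed),
            class = "expectancy_fit")
}

abind1 <- function(...) {
  arrs <- list(...)
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1], 1L)),
                           dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

split_rhat <- function(x, chain) {
  halves <- paste(chain, ave(seq_along(x), chain, FUN = function(i) {
    as.integer(seq_along(i) > length(i) / 2)
  }))
  m <- tapply(x, halves, mean)
  v <- tapply(x, halves, var)
  nn <- mean(tapply(x, halves, length))
  W <- mean(v)
  B <- nn * var(as.numeric(m))
  if (W == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_basic <- function(x, chain) {
  # initial-positive-sequence estimator pooled across chains
  chains <- split(x, chain)
  n <- length(chains[[1]])
  rho_sum <- 0
  maxlag <- min(n - 1, 200)
  acfs <- purrr::map(chains, function(z) {
    stats::acf(z, lag.max = maxlag, plot = FALSE)$acf[-1]
  })
  rho <- Reduce(`+`, acfs) / length(acfs)
  for (k in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (is.na(pair) || pair < 0) break
    rho_sum <- rho_sum + pair
  }
  length(x) / (1 + 2 * rho_sum)
}

mcmc_diagnostics <- function(draws, chain) {
  tibble::tibble(
    parameter = colnames(draws),
    rhat = apply(draws, 2, split_rhat, chain = chain),
    ess = apply(draws, 2, ess_basic, chain = chain)
  )
}

#' @export
print.expectancy_fit <- function(x, ...) {
  cat("Multilevel AR(1) expectancy model (", x$spec$preset, ")\n", sep = "")
  cat(nrow(x$design$X), "observations,", length(x$design$song_ids),
      "songs,", x$chains, "chains x", x$iter, "kept draws\n")
  print(generics::tidy(x), n = Inf)
  invisible(x)
}

#' Tidy method for fitted expectancy models
#'
#' @param x An `expectancy_fit`.
#' @param ... Unused.
#' @return Tibble with one row per population-level term plus the
#'   innovation scale and AR(1) coefficient: posterior mean, 95% credible
#'   interval (2.5-97.5 percentiles), split R-hat and effective sample
#'   size.
#' @method tidy expectancy_fit
#' @export
tidy.expectancy_fit <- function(x, ...) {
  pars <- c(paste0("b_", colnames(x$design$X)), "sigma", "rho")
  tb <- tibble::tibble(
    term = pars,
    estimate = colMeans(x$draws[, pars, drop = FALSE]),
    conf.low = apply(x$draws[, pars, drop = FALSE], 2, stats::quantile, 0.025),
    conf.high = apply(x$draws[, pars, drop = FALSE], 2, stats::quantile, 0.975)
  )
  dplyr::left_join(tb, x$diagnostics, by = c(term = "parameter"))
}

#' Glance method for fitted expectancy models
#'
#' @param x An `expectancy_fit`.
#' @param ... Unused.
#' @return One-row tibble with sampler and convergence summaries.
#' @method glance expectancy_fit
#' @export
glance.expectancy_fit <- function(x, ...) {
  tibble::tibble(
    nobs = nrow(x$design$X),
    n_songs = length(x$design$song_ids),
    chains = x$chains,
    draws = nrow(x$draws),
    sigma = mean(x$draws[, "sigma"]),
    rho = mean(x$draws[, "rho"]),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}

#' Per-group slopes of a predictor (draw-wise contrasts)
#'
#' For a predictor with a musicianship interaction (musicianship coded
#' +0.5 / -0.5), computes the musician slope, the non-musician slope and
#' their difference draw-wise before summarizing.
#'
#' @param fit An `expectancy_fit`.
#' @param predictor Predictor term name (e.g. `"ic"`).
#' @return Tibble with rows `musician`, `nonmusician`, `difference`.
#' @export
group_slopes <- function(fit, predictor) {
  main <- fit$draws[, paste0("b_", predictor)]
  int_col <- paste0("b_", predictor, ":musicianship")
  inter <- if (int_col %in% colnames(fit$draws)) fit$draws[, int_col] else 0
  draws <- cbind(musician = main + 0.5 * inter,
                 nonmusician = main - 0.5 * inter,
                 difference = inter)
  tibble::tibble(
    term = colnames(draws),
    estimate = colMeans(draws),
    conf.low = apply(draws, 2, stats::quantile, 0.025),
    conf.high = apply(draws, 2, stats::quantile, 0.975)
  )
}

#' Prior predictive draws of the response
#'
#' Simulates response vectors from the model's priors on the design of a
#' fitted or built model, for checking that the implied scale is
#' compatible with standardized data.
#'
#' @param design An `expectancy_design`.
#' @param n_draws Number of prior draws.
#' @param seed Integer seed.
#' @return Numeric vector: the sd of each simulated response.
#' @export
prior_predictive_sd <- function(design, n_draws = 100, seed = 1L) {
  X <- design$X; p <- ncol(X)
  song <- design$song; J <- max(song)
  with_seed(seed, {
    vapply(seq_len(n_draws), function(s) {
      beta <- rnorm(p)
      tau <- abs(stats::rcauchy(p, 0, 1))
      tau <- pmin(tau, 5)
      b <- matrix(rnorm(J * p), J, p) * rep(tau, each = J)
      sig <- min(abs(stats::rcauchy(1, 0, 1)), 5)
      rho <- runif(1, -1, 1)
      eta <- drop(X %*% beta) + rowSums(X * b[song, , drop = FALSE])
      e <- numeric(length(eta))
      for (ix in split(seq_along(eta), design$series)) {
        e[ix] <- ar1_series(length(ix), rho, sig)
      }
      sd(eta + e)
    }, numeric(1))
  })
}
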