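series_lag1_cor <- function(y, series) {
  first <- !duplicated(series)
  ylag <- c(NA, y[-length(y)])
  ok <- !first & !is.na(ylag)
  cor(y[ok], ylag[ok])
}

#' Posterior predictive check
#'
#' Draws replicated response series from random posterior draws, including
#' the AR(1) residual structure per series, and compares observed summary
#' statistics (mean, sd, lag-1 autocorrelation within series) against
#' their replicated distributions.
#'
#' @param fit An `expectancy_fit`.
#' @param n_draws Number of replicated datasets (default 200).
#' @param seed Integer seed; replicates are reproducible bit-for-bit.
#' @return A `ppc_result`: list with `summary` (tibble: statistic,
#'   observed value, central 95% replicated interval, tail probability)
#'   and `yrep` (observations x `n_draws` matrix).
#' @export
posterior_predictive_check <- function(fit, n_draws = 200, seed = 1L) {
  des <- fit$design
  X <- des$X; song <- des$song; series <- des$series
  n <- nrow(X); d <- dim(fit$b)[3]
  terms <- colnames(X)
  ix_series <- split(seq_len(n), series)
  with_seed(seed, {
    picks <- sample.int(nrow(fit$draws), n_draws, replace = n_draws > nrow(fit$draws))
    yrep <- matrix(NA_real_, n, n_draws)
    for (r in seq_len(n_draws)) {
      s <- picks[r]
      beta <- fit$draws[s, paste0("b_", terms)]
      bs <- matrix(fit$b[s, , ], ncol = d)
      eta <- drop(X %*% beta) + rowSums(X * bs[song, , drop = FALSE])
      e <- numeric(n)
      for (ix in ix_series) {
        e[ix] <- ar1_series(length(ix), fit$draws[s, "rho"],
                            fit$draws[s, "sigma"])
      }
      yrep[, r] <- eta + e
    }
    stats_fun <- list(
      mean = function(y) mean(y),
      sd = function(y) sd(y),
      lag1_autocor = function(y) series_lag1_cor(y, series)
    )
    summ <- purrr::imap(stats_fun, function(f, nm) {
      obs <- f(des$y)
      rep_vals <- apply(yrep, 2, f)
      tibble::tibble(
        statistic = nm, observed = obs,
        rep_lower = stats::quantile(rep_vals, 0.025),
        rep_upper = stats::quantile(rep_vals, 0.975),
        p_two_sided = 2 * min(mean(rep_vals >= obs), mean(rep_vals <= obs))
      )
    }) |> dplyr::bind_rows()
    structure(list(summary = summ, yrep = yrep), class = "ppc_result")
  })
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("Posterior predictive check (", ncol(x$yrep), " replicates)\n", sep = "")
  print(x$summary)
  invisible(x)
}
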