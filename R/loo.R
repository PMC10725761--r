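logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Pointwise log-likelihood matrix of a fitted model
#'
#' Log density of every observation under every posterior draw, using the
#' AR(1) innovation decomposition: each observation is conditioned on the
#' previous observation of its series, and the first observation of each
#' series uses the stationary marginal (variance sigma^2 / (1 - rho^2)).
#'
#' @param fit An `expectancy_fit`.
#' @return Matrix of dimension draws x observations.
#' @export
pointwise_loglik <- function(fit) {
  des <- fit$design
  y <- des$y; X <- des$X; song <- des$song; first <- des$first
  n <- length(y)
  terms <- colnames(X)
  beta_d <- fit$draws[, paste0("b_", terms), drop = FALSE]
  sig_d <- fit$draws[, "sigma"]
  rho_d <- fit$draws[, "rho"]
  S <- nrow(beta_d)
  ll <- matrix(NA_real_, S, n)
  ylag_ok <- !first
  d <- dim(fit$b)[3]
  for (s in seq_len(S)) {
    bs <- matrix(fit$b[s, , ], ncol = d)
    e <- y - drop(X %*% beta_d[s, ]) - rowSums(X * bs[song, , drop = FALSE])
    elag <- c(0, e[-n])
    innov <- e - rho_d[s] * elag
    out <- stats::dnorm(innov, 0, sig_d[s], log = TRUE)
    out[first] <- stats::dnorm(e[first], 0,
                               sig_d[s] / sqrt(1 - rho_d[s]^2), log = TRUE)
    ll[s, ] <- out
  }
  ll
}

# Zhang & Stephens (2009) posterior-mean fit of the generalized Pareto
# shape/scale to exceedances x > 0
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || stats::sd(x) == 0) return(list(k = NA_real_, sigma = NA_real_))
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  xq <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * xq)
  k_j <- -vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- exp(l_j - max(l_j)); w <- w / sum(w)
  th_hat <- sum(w * theta)
  k <- -mean(log1p(-th_hat * x))
  list(k = k, sigma = k / th_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

psis_smooth <- function(lr) {
  # lr: raw log importance ratios for one observation (length S)
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1):S]
  cut_lw <- lr[ord[S - M]]
  exc <- exp(lr[tail_ids]) - exp(cut_lw)
  fit <- gpd_fit(exc)
  k <- fit$k
  if (is.finite(k)) {
    k_reg <- (M * k + 5) / (M + 10)  # shrink towards 0.5 with prior weight 10
    q <- vapply((seq_len(M) - 0.5) / M, qgpd, numeric(1),
                k = k_reg, sigma = fit$sigma)
    lr[tail_ids] <- log(q + exp(cut_lw))
    lr <- pmin(lr, 0)  # truncate at the largest raw weight
  } else {
    k_reg <- NA_real_
  }
  list(lw = lr, k = if (is.finite(k)) k_reg else k)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Approximate leave-one-out cross-validation from a single posterior
#' sample: per observation, importance ratios proportional to the inverse
#' likelihood are stabilized by fitting a generalized Pareto distribution
#' to the largest 20% of ratios, replacing that tail by its expected order
#' statistics, and truncating; the ELPD is then the weighted log predictive
#' density. Observations with Pareto shape k above 0.7 are flagged as
#' unreliable.
#'
#' @param ll Pointwise log-likelihood matrix (draws x observations), e.g.
#'   from [pointwise_loglik()], or an `expectancy_fit`.
#' @return An `elpd_result`: list with `pointwise` (tibble `elpd_i`,
#'   `pareto_k`), `elpd` (total), `se`, `n_bad_k`.
#' @export
psis_loo <- function(ll) {
  if (inherits(ll, "expectancy_fit")) ll <- pointwise_loglik(ll)
  if (!all(is.finite(ll))) stop("non-finite log-likelihood at observation(s) ",
                                paste(utils::head(which(!apply(is.finite(ll),
                                                               2, all))),
                                      collapse = ", "), call. = FALSE)
  N <- ncol(ll)
  elpd_i <- numeric(N); k_i <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-ll[, i])
    elpd_i[i] <- logsumexp(sm$lw + ll[, i]) - logsumexp(sm$lw)
    k_i[i] <- sm$k
  }
  structure(list(
    pointwise = tibble::tibble(elpd_i = elpd_i, pareto_k = k_i),
    elpd = sum(elpd_i),
    se = sqrt(N * var(elpd_i)),
    n_bad_k = sum(k_i > 0.7, na.rm = TRUE)
  ), class = "elpd_result")
}

#' @export
print.elpd_result <- function(x, ...) {
  cat("PSIS-LOO: elpd =", round(x$elpd, 1), "(se", round(x$se, 1), "),",
      nrow(x$pointwise), "observations,", x$n_bad_k, "with Pareto k > 0.7\n")
  invisible(x)
}

#' Compare models by ELPD differences
#'
#' Ranks models by PSIS-LOO ELPD and reports each model's difference to
#' the best model with the standard error of the pointwise differences.
#'
#' @param ... Named `elpd_result` objects (or a single named list of them).
#' @return Tibble: `model`, `elpd`, `se`, `elpd_diff`, `se_diff`, ranked
#'   best first.
#' @export
compare_elpd <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && !inherits(dots[[1]], "elpd_result")) {
    dots <- dots[[1]]
  }
  stopifnot(length(dots) >= 2, !is.null(names(dots)),
            all(purrr::map_lgl(dots, inherits, "elpd_result")))
  ns <- purrr::map_int(dots, ~ nrow(.x$pointwise))
  if (length(unique(ns)) != 1L) {
    stop("models were fitted to different numbers of observations",
         call. = FALSE)
  }
  elpds <- purrr::map_dbl(dots, "elpd")
  best <- names(dots)[which.max(elpds)]
  N <- ns[[1]]
  tibble::tibble(
    model = names(dots),
    elpd = unname(elpds),
    se = unname(purrr::map_dbl(dots, "se")),
    elpd_diff = unname(purrr::map_dbl(dots, function(r) {
      sum(r$pointwise$elpd_i - dots[[best]]$pointwise$elpd_i)
    })),
    se_diff = unname(purrr::map_dbl(dots, function(r) {
      d <- r$pointwise$elpd_i - dots[[best]]$pointwise$elpd_i
      sqrt(N * var(d))
    }))
  ) |> dplyr::arrange(dplyr::desc(.data$elpd))
}

#' Bayesian stacking of predictive distributions
#'
#' Finds simplex weights over candidate models maximizing the summed log
#' of the weighted pointwise leave-one-out predictive densities. The
#' objective is concave in the weights; optimization runs on the softmax
#' parameterization from the uniform start, so exchangeable (identical)
#' models keep equal weights.
#'
#' @param ... Named `elpd_result` objects (or one named list of them), or
#'   a single numeric matrix of pointwise log predictive densities
#'   (observations x models, named columns).
#' @return A `stacking_weights` object: tibble `model`, `weight`, plus the
#'   achieved log score as attribute `logscore`.
#' @export
model_stacking <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.matrix(dots[[1]])) {
    lpd <- dots[[1]]
  } else {
    if (length(dots) == 1L && !inherits(dots[[1]], "elpd_result")) {
      dots <- dots[[1]]
    }
    stopifnot(all(purrr::map_lgl(dots, inherits, "elpd_result")))
    lpd <- do.call(cbind, purrr::map(dots, ~ .x$pointwise$elpd_i))
    colnames(lpd) <- names(dots)
  }
  K <- ncol(lpd)
  stopifnot(K >= 2)
  shift <- apply(lpd, 1, max)
  P <- exp(lpd - shift)
  score <- function(w) sum(log(P %*% w) + shift)
  degenerate <- all(apply(lpd, 2, function(cl) {
    isTRUE(all.equal(cl, lpd[, 1], tolerance = 1e-12))
  }))
  if (degenerate) {
    w <- rep(1 / K, K)
  } else {
    obj <- function(z) {
      w <- exp(c(z, 0)); w <- w / sum(w)
      -score(w)
    }
    opt <- stats::optim(rep(0, K - 1), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    w <- exp(c(opt$par, 0)); w <- w / sum(w)
  }
  out <- tibble::tibble(model = colnames(lpd), weight = w)
  attr(out, "logscore") <- score(w)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("stacking_weights", class(out))
  out
}
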