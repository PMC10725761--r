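test_that("presets expand to the documented term lists", {
  expect_equal(regression_spec("exp1_null")$terms,
               c("intercept", "musicianship", "valence", "arousal"))
  add1 <- regression_spec("exp1_additive")$terms
  expect_setequal(add1, c("intercept", "musicianship", "valence", "arousal",
                          "ic", "ic:musicianship", "tonal_dissimilarity",
                          "tonal_dissimilarity:musicianship"))
  sup1 <- regression_spec("exp1_supra")$terms
  expect_true(all(c("ic:tonal_dissimilarity",
                    "ic:tonal_dissimilarity:musicianship") %in% sup1))
  single <- regression_spec("exp1_single", predictor = "spectral_distance")
  expect_true(all(c("spectral_distance",
                    "spectral_distance:musicianship") %in% single$terms))
  expect_error(regression_spec("exp1_single"), "predictor")
  # pleasantness presets always carry the acoustic covariates
  for (p in c("exp2_null", "exp2_idyom", "exp2_pp", "exp2_additive",
              "exp2_supra")) {
    expect_true(all(c("dissonance", "spectral_centroid",
                      "spectral_complexity") %in%
                    regression_spec(p)$terms))
  }
  sup2 <- regression_spec("exp2_supra")$terms
  expect_true(all(c("tonal_dissimilarity:ic:entropy",
                    "tonal_dissimilarity:ic",
                    "tonal_dissimilarity:entropy") %in% sup2))
})

test_that("build_design forms interaction columns and AR(1) series indices", {
  dat <- make_group_ratings(seed = 51, n_songs = 6,
                            length_range = c(8, 10))
  des <- build_design(dat, regression_spec("exp1_additive"))
  expect_equal(colnames(des$X)[1], "intercept")
  expect_true(all(des$X[, "intercept"] == 1))
  # interaction column is the elementwise product of its parents
  ord <- des$data
  expect_equal(des$X[, "ic:musicianship"],
               ord$ic * ord$musicianship, ignore_attr = TRUE)
  # two series per song (one per group), each starting exactly once
  expect_equal(max(des$series), 12)
  expect_equal(sum(des$first), 12)
  expect_error(build_design(dplyr::select(dat, -ic),
                            regression_spec("exp1_additive")), "missing")
  bad <- dat
  bad$ic <- bad$ic * 10
  expect_error(build_design(bad, regression_spec("exp1_additive")),
               "standardized")
})

test_that("the sampler recovers known parameters from simulated data", {
  dat <- make_group_ratings(seed = 61, n_songs = 30)
  fit <- fit_quick(dat, regression_spec("exp1_additive"), seed = 3)
  gs_ic <- group_slopes(fit, "ic")
  gs_td <- group_slopes(fit, "tonal_dissimilarity")
  # posterior means within 2 posterior SDs of truth
  half_width <- (gs_ic$conf.high - gs_ic$conf.low) / 2
  expect_lt(abs(gs_ic$estimate[1] - 0.53), 2 * half_width[1])
  expect_lt(abs(gs_ic$estimate[2] - 0.32), 2 * half_width[2])
  expect_lt(abs(gs_td$estimate[1] - 0.19), 2 * half_width[1])
  expect_lt(abs(gs_td$estimate[2] - 0.17), 2 * half_width[2])
  # AR(1) coefficient and innovation scale
  tb <- generics::tidy(fit)
  rho_row <- tb[tb$term == "rho", ]
  expect_gt(0.3, rho_row$conf.low)
  expect_lt(0.3, rho_row$conf.high + 0.05)
  expect_equal(unname(tb[tb$term == "sigma", ]$estimate), 0.35,
               tolerance = 0.1)
})

test_that("posterior means agree with an independent mixed-model fit", {
  # on data without autocorrelation the population-level posterior means
  # should track the restricted-maximum-likelihood estimates of the same
  # varying-slope model fitted by lme4
  skip_if_not_installed("lme4")
  dat <- make_group_ratings(seed = 121, n_songs = 25, ar1_rho = 0)
  fit <- fit_quick(dat, regression_spec("exp1_null"), seed = 11)
  lf <- lme4::lmer(
    rating ~ musicianship + valence + arousal +
      (1 + musicianship + valence + arousal | song_id),
    data = dat,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  ours <- generics::tidy(fit)
  theirs <- lme4::fixef(lf)
  for (tm in c("musicianship")) {
    row <- ours[ours$term == paste0("b_", tm), ]
    se <- (row$conf.high - row$conf.low) / 4
    expect_lt(abs(row$estimate - theirs[[tm]]), 3 * se)
  }
  row <- ours[ours$term == "b_intercept", ]
  se <- (row$conf.high - row$conf.low) / 4
  expect_lt(abs(row$estimate - theirs[["(Intercept)"]]), 3 * se)
})

test_that("zero-autocorrelation data concentrate rho near zero", {
  dat <- make_group_ratings(seed = 71, n_songs = 20, ar1_rho = 0)
  fit <- fit_quick(dat, regression_spec("exp1_null"), seed = 5)
  rho_hat <- mean(fit$draws[, "rho"])
  expect_lt(abs(rho_hat), 0.1)
})

test_that("AR(1) pointwise log-likelihood matches its closed forms", {
  dat <- make_group_ratings(seed = 81, n_songs = 6, length_range = c(8, 10))
  fit <- fit_quick(dat, regression_spec("exp1_null"), seed = 7,
                   warmup = 50, iter = 20)
  ll <- pointwise_loglik(fit)
  expect_equal(dim(ll), c(2 * 20, nrow(dat)))
  expect_true(all(is.finite(ll)))
  # recompute one draw by hand
  des <- fit$design
  s <- 5
  beta <- fit$draws[s, paste0("b_", colnames(des$X))]
  bs <- fit$b[s, , ]
  e <- des$y - drop(des$X %*% beta) -
    rowSums(des$X * bs[des$song, , drop = FALSE])
  sig <- fit$draws[s, "sigma"]; rho <- fit$draws[s, "rho"]
  i1 <- which(des$first)[2]
  expect_equal(ll[s, i1],
               unname(dnorm(e[i1], 0, sig / sqrt(1 - rho^2), log = TRUE)))
  i2 <- which(!des$first)[10]
  expect_equal(ll[s, i2],
               unname(dnorm(e[i2] - rho * e[i2 - 1], 0, sig, log = TRUE)))
  # peak value: a zero-residual observation scores -0.5 log(2 pi sigma^2)
  expect_equal(unname(dnorm(0, 0, sig, log = TRUE)),
               unname(-0.5 * log(2 * pi * sig^2)))
})

test_that("stationary AR(1) covariance has the geometric closed form", {
  # simulate long series and compare empirical covariances
  set.seed(99)
  rho <- 0.6; sig <- 0.8
  y <- as.numeric(stats::arima.sim(list(ar = rho), 2e5, sd = sig))
  v <- sig^2 / (1 - rho^2)
  for (lag in 0:3) {
    emp <- cov(y[1:(length(y) - lag)], y[(1 + lag):length(y)])
    expect_equal(emp, v * rho^lag, tolerance = 0.03)
  }
})

test_that("prior predictive scale is compatible with standardized data", {
  dat <- make_group_ratings(seed = 91, n_songs = 8, length_range = c(8, 10))
  des <- build_design(dat, regression_spec("exp1_null"))
  # the scale kernel of the model: intercept-only design (each additional
  # N(0,1) slope on a standardized predictor adds ~1 to the prior variance,
  # so the band applies to the per-term scale, checked on one term)
  des$X <- des$X[, "intercept", drop = FALSE]
  sds <- prior_predictive_sd(des, n_draws = 200, seed = 2)
  expect_gt(median(sds), 0.5)
  expect_lt(median(sds), 3)
})

test_that("tidy, glance and plots expose the fit coherently", {
  dat <- make_group_ratings(seed = 101, n_songs = 6, length_range = c(8, 10))
  fit <- fit_quick(dat, regression_spec("exp1_null"), seed = 2,
                   warmup = 50, iter = 50)
  tb <- generics::tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "rhat",
                    "ess") %in% names(tb)))
  expect_true(all(tb$conf.low <= tb$conf.high))
  gl <- generics::glance(fit)
  expect_equal(gl$nobs, nrow(dat))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(plot_expectancy_profile(
    dplyr::mutate(dat, ic_bits = ic), song = dat$song_id[1]), "ggplot")
  expect_output(print(fit), "Multilevel AR")
})

test_that("posterior predictive replicates are calibrated and reproducible", {
  dat <- make_group_ratings(seed = 111, n_songs = 10,
                            length_range = c(10, 12))
  fit <- fit_quick(dat, regression_spec("exp1_additive"), seed = 9,
                   warmup = 200, iter = 200)
  ppc1 <- posterior_predictive_check(fit, n_draws = 100, seed = 3)
  ppc2 <- posterior_predictive_check(fit, n_draws = 100, seed = 3)
  expect_identical(ppc1$yrep, ppc2$yrep)
  expect_equal(dim(ppc1$yrep), c(nrow(dat), 100))
  # on well-specified data the observed statistics sit inside the
  # replicated intervals
  s <- ppc1$summary
  expect_true(all(s$observed >= s$rep_lower & s$observed <= s$rep_upper))
})
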