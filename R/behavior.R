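#' Symmetric median filter for slider traces
#'
#' Replaces each sample by the median of a symmetric window (default five
#' samples), removing single-sample slider glitches while preserving level
#' changes. Edges use shrunken symmetric windows.
#'
#' @param x Numeric vector of slider samples.
#' @param width Odd window width (default 5).
#' @return Filtered numeric vector, same length.
#' @export
median_filter <- function(x, width = 5) {
  stopifnot(width %% 2 == 1)
  n <- length(x)
  h <- (width - 1) / 2
  if (n < width) {
    edge <- seq_len(n)
  } else {
    out <- as.numeric(stats::runmed(x, k = width, endrule = "keep"))
    edge <- c(seq_len(h), (n - h + 1):n)
  }
  if (n < width) out <- numeric(n)
  for (i in edge) {
    hh <- min(h, i - 1, n - i)
    out[i] <- median(x[(i - hh):(i + hh)])
  }
  out
}

# smallest-value tie-break mode
window_mode <- function(values) {
  tab <- table(values)
  as.numeric(names(tab)[which.max(tab)][1])
}

#' Extract per-chord ratings from a continuous trace
#'
#' Samples the modal slider value for each chord in the window from
#' `delay` seconds after its onset up to (exclusive) the next chord's
#' onset, accounting for the delayed manual reaction to each chord. Ties
#' are broken by the smallest value. The last chord's window closes at its
#' onset plus `chord_duration`.
#'
#' @param trace Tibble with columns `t` (seconds) and `value`.
#' @param onsets Increasing numeric vector of chord onset times (seconds).
#' @param chord_duration Seconds per chord (default 2.4).
#' @param delay Reaction delay excluded from each window (default 1 s).
#' @return Numeric vector of per-chord modal values.
#' @export
extract_chord_rating <- function(trace, onsets, chord_duration = 2.4,
                                 delay = 1) {
  stopifnot(all(diff(onsets) > 0))
  ends <- c(onsets[-1], onsets[length(onsets)] + chord_duration)
  vapply(seq_along(onsets), function(i) {
    sel <- trace$t >= onsets[i] + delay & trace$t < ends[i]
    if (!any(sel)) {
      stop("empty rating window for chord ", i, call. = FALSE)
    }
    window_mode(trace$value[sel])
  }, numeric(1))
}

#' Preprocess raw slider traces into per-subject chord ratings
#'
#' Median-filters each subject x song trace and extracts per-chord modal
#' ratings in the delayed window.
#'
#' @param traces Tibble with `subject_id`, `song_id`, `t`, `value` (and
#'   optionally `group`).
#' @param chords Tibble with `song_id`, `position`, `onset` giving the
#'   chord grid of each song.
#' @inheritParams extract_chord_rating
#' @param filter_width Median filter width (default 5).
#' @return Tibble `subject_id`, (`group`,) `song_id`, `position`, `rating`.
#' @export
preprocess_traces <- function(traces, chords, chord_duration = 2.4,
                              filter_width = 5, delay = 1) {
  grids <- chords |>
    dplyr::arrange(.data$song_id, .data$position) |>
    dplyr::group_by(.data$song_id) |>
    dplyr::summarise(onsets = list(.data$onset), .groups = "drop")
  has_group <- "group" %in% names(traces)
  keys <- c("subject_id", if (has_group) "group", "song_id")
  traces |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)), .data$t) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      ons <- grids$onsets[[match(key$song_id, grids$song_id)]]
      filt <- df
      filt$value <- median_filter(df$value, filter_width)
      tibble::tibble(
        position = seq_along(ons),
        rating = extract_chord_rating(filt, ons, chord_duration, delay)
      )
    }) |>
    dplyr::ungroup()
}

#' Discard first-chord ratings and average within groups
#'
#' Drops the first chord of every song (each trial starts with the slider
#' reset, so that rating is uninformative) and mean-averages the remaining
#' ratings across subjects within each group. With G groups, S songs and
#' a total of C chords, the result has (C - S) x G rows.
#'
#' @param ratings Tibble with `subject_id`, `song_id`, `position`, `rating`
#'   and a grouping column.
#' @param group Unquoted grouping column (default `group`); every group
#'   must have at least one subject.
#' @return Tibble `song_id`, `position`, group column, `rating`,
#'   `n_subjects`.
#' @export
discard_first_and_average <- function(ratings, group = group) {
  out <- ratings |>
    dplyr::group_by(.data$song_id) |>
    dplyr::filter(.data$position > min(.data$position)) |>
    dplyr::group_by(.data$song_id, .data$position, {{ group }}) |>
    dplyr::summarise(rating = mean(.data$rating),
                     n_subjects = dplyr::n_distinct(.data$subject_id),
                     .groups = "drop")
  if (any(out$n_subjects == 0)) stop("group with zero subjects", call. = FALSE)
  out
}

#' Standardize columns to zero mean and unit variance
#'
#' Centers and scales the named columns; the means and standard deviations
#' are stored in the `"standardization"` attribute so the transform can be
#' inverted with [unstandardize()]. Zero-variance columns are an error.
#'
#' @param data A data frame.
#' @param cols Character vector of column names to standardize.
#' @return `data` with the named columns standardized.
#' @export
standardize <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  scales <- purrr::map(cols, function(cl) {
    x <- data[[cl]]
    m <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("zero variance in column '", cl, "'", call. = FALSE)
    }
    c(mean = m, sd = s)
  })
  names(scales) <- cols
  for (cl in cols) {
    data[[cl]] <- (data[[cl]] - scales[[cl]]["mean"]) / scales[[cl]]["sd"]
  }
  attr(data, "standardization") <- scales
  data
}

#' Invert a standardization
#'
#' @param data A data frame previously returned by [standardize()].
#' @param cols Columns to invert (default: all recorded).
#' @return `data` with the columns restored to their original scale.
#' @export
unstandardize <- function(data, cols = NULL) {
  scales <- attr(data, "standardization")
  if (is.null(scales)) stop("no standardization attribute", call. = FALSE)
  if (is.null(cols)) cols <- names(scales)
  for (cl in cols) {
    data[[cl]] <- data[[cl]] * scales[[cl]]["sd"] + scales[[cl]]["mean"]
  }
  attr(data, "standardization") <- NULL
  data
}

#' Augmented Dickey-Fuller stationarity test
#'
#' Regression with drift: the first difference is regressed on the lagged
#' level and `lag` lagged differences; the test statistic is the t-ratio of
#' the lagged-level coefficient. The lag order is chosen by AIC over
#' 0..`max_lag`. The 5% critical value uses the MacKinnon (2010)
#' finite-sample response surface for the constant-only case.
#'
#' @param x Numeric series (length >= 10, positive variance).
#' @param max_lag Maximum augmentation lag considered (default 10).
#' @return One-row tibble: `statistic`, `lag`, `n`, `crit_5pct`,
#'   `reject_unit_root`.
#' @export
adf_test <- function(x, max_lag = 10) {
  x <- as.numeric(x)
  if (length(x) < 10) stop("series too short for ADF test", call. = FALSE)
  if (sd(x) == 0) stop("zero-variance series", call. = FALSE)
  dx <- diff(x)
  fits <- purrr::map(0:max_lag, function(p) {
    n <- length(dx)
    if (n - p < 5) return(NULL)
    idx <- (p + 1):n
    X <- cbind(lag_level = x[idx], intercept = 1)
    if (p > 0) {
      for (j in seq_len(p)) X <- cbind(X, dx[idx - j])
    }
    fit <- stats::lm.fit(X, dx[idx])
    k <- ncol(X)
    rss <- sum(fit$residuals^2)
    nn <- length(idx)
    aic <- nn * log(rss / nn) + 2 * (k + 1)
    se <- sqrt(rss / (nn - k) * solve(crossprod(X))[1, 1])
    list(stat = fit$coefficients[1] / se, lag = p, aic = aic, n = nn)
  })
  fits <- purrr::compact(fits)
  best <- fits[[which.min(purrr::map_dbl(fits, "aic"))]]
  n <- best$n
  crit <- -2.86154 - 2.8903 / n - 4.234 / n^2 - 40.04 / n^3
  tibble::tibble(statistic = unname(best$stat), lag = best$lag, n = n,
                 crit_5pct = crit,
                 reject_unit_root = unname(best$stat) < crit)
}

#' Per-song stationarity check of a rating table
#'
#' Applies [adf_test()] to each song's (and group's, if present) rating
#' series.
#'
#' @param rating_table Tibble with `song_id`, `position`, `rating` and
#'   optionally `group`.
#' @param max_lag Maximum ADF augmentation lag.
#' @return Tibble of per-series ADF results.
#' @export
stationarity_check <- function(rating_table, max_lag = 10) {
  keys <- intersect(c("song_id", "group"), names(rating_table))
  rating_table |>
    dplyr::arrange(.data$song_id, .data$position) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ adf_test(.x$rating, max_lag = max_lag)) |>
    dplyr::ungroup()
}
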