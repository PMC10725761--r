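rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

default_vocabulary <- function(vocab_size) {
  qualities <- c("maj", "min", "dom7", "min7", "maj7", "dim", "sus", "aug",
                 "other")
  grid <- expand.grid(root = 0:11, quality = qualities,
                      stringsAsFactors = FALSE)
  if (vocab_size > nrow(grid)) {
    stop("vocab_size cannot exceed ", nrow(grid), call. = FALSE)
  }
  format_chord_token(grid$root[seq_len(vocab_size)],
                     grid$quality[seq_len(vocab_size)])
}

# lengths within [lo, hi], optionally nudged to hit an exact total
sample_lengths <- function(n, length_range, total = NULL) {
  lo <- length_range[1]; hi <- length_range[2]
  len <- sample(lo:hi, n, replace = TRUE)
  if (!is.null(total)) {
    if (total < n * lo || total > n * hi) {
      stop("total chord count ", total, " unreachable with ", n,
           " songs of length ", lo, "-", hi, call. = FALSE)
    }
    while (sum(len) != total) {
      i <- sample.int(n, 1)
      step <- sign(total - sum(len))
      cand <- len[i] + step
      if (cand >= lo && cand <= hi) len[i] <- cand
    }
  }
  len
}

#' Generate a synthetic chord corpus
#'
#' Songs are sampled from a seeded first-order Markov chain over a chord
#' vocabulary whose transition rows are drawn from a sparse Dirichlet, so
#' chord usage is skewed: most transitions are predictable with a few rare
#' surprising ones, emulating the left-skewed information-content profile
#' of pop-song chord corpora. Larger `concentration` values flatten the
#' chain towards uniform usage.
#'
#' @param n_songs Number of songs.
#' @param length_range Inclusive range of song lengths in chords
#'   (default 30-38, matching the stimulus set emulated).
#' @param vocab_size Number of chord tokens (default 24).
#' @param concentration Dirichlet concentration per transition cell
#'   (default 0.1; smaller = sparser rows = more skew).
#' @param seed Integer seed.
#' @param total_chords Optional exact total chord count across songs.
#' @param chord_duration Seconds per chord (default 2.4).
#' @return Corpus tibble (`song_id`, `position`, `root`, `quality`,
#'   `token`, `onset`) with attributes `transition`, `initial`,
#'   `vocabulary`, `seed`.
#' @export
generate_corpus <- function(n_songs, length_range = c(30, 38),
                            vocab_size = 24, concentration = 0.1,
                            seed = 1L, total_chords = NULL,
                            chord_duration = 2.4) {
  stopifnot(vocab_size >= 2, n_songs >= 1)
  vocab <- default_vocabulary(vocab_size)
  with_seed(seed, {
    P <- t(vapply(seq_len(vocab_size),
                  function(i) rdirichlet_one(rep(concentration, vocab_size)),
                  numeric(vocab_size)))
    dimnames(P) <- list(vocab, vocab)
    init <- rdirichlet_one(rep(concentration, vocab_size))
    names(init) <- vocab
    len <- sample_lengths(n_songs, length_range, total_chords)
    songs <- purrr::map(seq_len(n_songs), function(s) {
      idx <- integer(len[s])
      idx[1] <- sample.int(vocab_size, 1, prob = init)
      for (i in 2:len[s]) {
        idx[i] <- sample.int(vocab_size, 1, prob = P[idx[i - 1], ])
      }
      tibble::tibble(
        song_id = sprintf("song%03d", s),
        position = seq_len(len[s]),
        token = vocab[idx],
        onset = (seq_len(len[s]) - 1) * chord_duration
      )
    })
    out <- dplyr::bind_rows(songs) |>
      dplyr::mutate(root = token_root(.data$token),
                    quality = token_quality(.data$token)) |>
      dplyr::select("song_id", "position", "root", "quality", "token",
                    "onset")
    attr(out, "transition") <- P
    attr(out, "initial") <- init
    attr(out, "vocabulary") <- vocab
    attr(out, "seed") <- seed
    out
  })
}

#' Generate a synthetic stimulus set
#'
#' Draws a set of chord progressions (default 30 songs of 30-38 chords)
#' from the same kind of Markov chain as [generate_corpus()], optionally
#' constrained to an exact total chord count.
#'
#' @inheritParams generate_corpus
#' @param n_songs Number of progressions (default 30).
#' @return Corpus tibble as in [generate_corpus()], with an added
#'   `n_chords` attribute giving the total chord count.
#' @export
generate_stimulus_set <- function(n_songs = 30, length_range = c(30, 38),
                                  vocab_size = 24, concentration = 0.1,
                                  seed = 1L, total_chords = NULL,
                                  chord_duration = 2.4) {
  out <- generate_corpus(n_songs, length_range, vocab_size, concentration,
                         seed, total_chords, chord_duration)
  attr(out, "n_chords") <- nrow(out)
  out
}

#' Simulate behavioural and acoustic covariates
#'
#' Adds the covariate columns the regression models condition on: `valence`
#' and `arousal` (post-stimulus affect ratings; constant within a song) and
#' per-chord `dissonance`, `spectral_centroid` and `spectral_complexity`.
#' All are Gaussian on roughly the standardized scale; per-chord covariates
#' can be given a target correlation with `tonal_dissimilarity` when that
#' column is present.
#'
#' @param frames Per-chord tibble with `song_id` and `position`.
#' @param seed Integer seed.
#' @param cor_with_td Target correlation of the acoustic covariates with
#'   `tonal_dissimilarity` (default 0).
#' @return `frames` with the five covariate columns appended.
#' @export
simulate_covariates <- function(frames, seed = 1L, cor_with_td = 0) {
  with_seed(seed, {
    songs <- unique(frames$song_id)
    song_cov <- tibble::tibble(
      song_id = songs,
      valence = rnorm(length(songs)),
      arousal = rnorm(length(songs))
    )
    n <- nrow(frames)
    base <- if (abs(cor_with_td) > 0 &&
                "tonal_dissimilarity" %in% names(frames)) {
      td <- frames$tonal_dissimilarity
      td[is.na(td)] <- 0
      tds <- as.numeric(scale(td))
      function() cor_with_td * tds + sqrt(1 - cor_with_td^2) * rnorm(n)
    } else {
      function() rnorm(n)
    }
    frames |>
      dplyr::left_join(song_cov, by = "song_id") |>
      dplyr::mutate(dissonance = base(),
                    spectral_centroid = base(),
                    spectral_complexity = base())
  })
}

#' Rater specification for simulated listeners
#'
#' Effect sizes default to the study conditions this generator emulates:
#' per-group information-content slopes 0.53 (musicians) / 0.32
#' (non-musicians), tonal-dissimilarity slopes 0.19 / 0.17, a musician
#' intercept shift of -0.28, arousal 0.18 and valence 0.03, all on the
#' standardized scale; AR(1) residual correlation 0.3.
#'
#' @param betas Named list; each element is a length-2 vector
#'   `c(musician, nonmusician)` giving the group slopes of that predictor.
#' @param n_subjects Named vector of subjects per group.
#' @param song_effect_sd Standard deviation of song-level random effects
#'   (intercept and every slope).
#' @param ar1_rho AR(1) residual correlation in (-1, 1).
#' @param innovation_sd AR(1) innovation standard deviation.
#' @return A list of class `rater_spec`.
#' @export
rater_spec <- function(betas = list(intercept = c(-0.14, 0.14),
                                    ic = c(0.53, 0.32),
                                    tonal_dissimilarity = c(0.19, 0.17),
                                    valence = c(0.03, 0.03),
                                    arousal = c(0.18, 0.18)),
                       n_subjects = c(musician = 13, nonmusician = 12),
                       song_effect_sd = 0.1,
                       ar1_rho = 0.3,
                       innovation_sd = 0.6) {
  stopifnot(abs(ar1_rho) < 1, innovation_sd > 0, song_effect_sd >= 0)
  structure(list(betas = betas, n_subjects = n_subjects,
                 song_effect_sd = song_effect_sd, ar1_rho = ar1_rho,
                 innovation_sd = innovation_sd),
            class = "rater_spec")
}

ar1_series <- function(n, rho, sd_innov) {
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd_innov / sqrt(1 - rho^2))
  for (t in seq_len(n)[-1]) e[t] <- rho * e[t - 1] + rnorm(1, 0, sd_innov)
  e
}

#' Simulate per-subject latent chord ratings
#'
#' Generates ratings as the generative mirror of the regression model: a
#' linear combination of the (standardized) predictor columns with
#' group-specific population slopes, plus song-level random effects shared
#' across subjects, plus an AR(1) residual chain per song x subject.
#' Musicianship is coded numerically as +0.5 (musician) / -0.5
#' (non-musician) in the output.
#'
#' @param frames Per-chord tibble with `song_id`, `position` and every
#'   predictor named in `spec$betas` (except `intercept`). Missing leading
#'   values (first-chord sensory predictors) are treated as zero.
#' @param spec A [rater_spec()].
#' @param seed Integer seed.
#' @return Tibble with one row per subject x chord: `subject_id`, `group`,
#'   `musicianship`, `song_id`, `position`, predictors, `rating`.
#' @export
simulate_ratings <- function(frames, spec = rater_spec(), seed = 1L) {
  stopifnot(inherits(spec, "rater_spec"))
  preds <- setdiff(names(spec$betas), "intercept")
  miss <- setdiff(preds, names(frames))
  if (length(miss)) stop("missing predictor column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  frames <- frames |> dplyr::arrange(.data$song_id, .data$position)
  songs <- unique(frames$song_id)
  terms <- names(spec$betas)
  with_seed(seed, {
    b_song <- matrix(rnorm(length(songs) * length(terms), 0,
                           spec$song_effect_sd),
                     nrow = length(songs),
                     dimnames = list(songs, terms))
    groups <- names(spec$n_subjects)
    out <- purrr::map(groups, function(g) {
      mus <- if (g == "musician") 0.5 else -0.5
      gi <- match(g, c("musician", "nonmusician"))
      purrr::map(seq_len(spec$n_subjects[[g]]), function(s) {
        df <- frames
        eta <- numeric(nrow(df))
        for (tm in terms) {
          xval <- if (tm == "intercept") rep(1, nrow(df)) else df[[tm]]
          xval[is.na(xval)] <- 0
          eta <- eta + spec$betas[[tm]][gi] * xval +
            b_song[df$song_id, tm] * xval
        }
        resid <- numeric(nrow(df))
        for (ix in split(seq_len(nrow(df)), df$song_id)) {
          resid[ix] <- ar1_series(length(ix), spec$ar1_rho,
                                  spec$innovation_sd)
        }
        df$subject_id <- sprintf("%s%02d", substr(g, 1, 3), s)
        df$group <- g
        df$musicianship <- mus
        df$rating <- as.numeric(eta + resid)
        df
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    dplyr::relocate(out, "subject_id", "group", "musicianship")
  })
}

#' Render latent ratings as 20 Hz slider traces
#'
#' Produces the raw instrument stream the preprocessing pipeline consumes:
#' for each subject x song, a step trace sampled at `rate` Hz that starts
#' at 0 (the slider reset), holds its value, and jumps to each chord's
#' target `delay` seconds after the chord onset. Latent ratings are mapped
#' affinely to the 0-1023 integer scale (`value = round(center + scale *
#' rating)`, clipped), with optional Gaussian jitter.
#'
#' @param ratings Output of [simulate_ratings()].
#' @param chord_duration Seconds per chord (default 2.4).
#' @param rate Sampling rate in Hz (default 20).
#' @param delay Reaction delay in seconds before the slider reaches each
#'   chord's target (default 1).
#' @param jitter_sd Jitter standard deviation in slider units (default 0).
#' @param center,scale Affine map from latent units to slider units.
#' @param seed Integer seed (used only when `jitter_sd > 0`).
#' @return Tibble `subject_id`, `group`, `song_id`, `t`, `value`.
#' @export
render_slider_trace <- function(ratings, chord_duration = 2.4, rate = 20,
                                delay = 1, jitter_sd = 0, center = 512,
                                scale = 170, seed = 1L) {
  with_seed(seed, {
    ratings |>
      dplyr::arrange(.data$subject_id, .data$song_id, .data$position) |>
      dplyr::group_by(.data$subject_id, .data$group, .data$song_id) |>
      dplyr::group_modify(function(df, key) {
        L <- nrow(df)
        targets <- pmin(pmax(round(center + scale * df$rating), 0), 1023)
        t <- seq(0, L * chord_duration - 1 / rate, by = 1 / rate)
        onset_idx <- floor(t / chord_duration) + 1   # chord sounding at t
        reached <- t >= (onset_idx - 1) * chord_duration + delay
        # before a chord's target is reached, hold the previous target
        eff <- ifelse(reached, onset_idx, onset_idx - 1L)
        value <- ifelse(eff >= 1, targets[pmax(eff, 1L)], 0)
        if (jitter_sd > 0) {
          value <- value + round(rnorm(length(value), 0, jitter_sd))
        }
        tibble::tibble(t = t, value = pmin(pmax(value, 0), 1023))
      }) |>
      dplyr::ungroup()
  })
}
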