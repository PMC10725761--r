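#' Idealized harmonic spectrum of a chord on a pitch-class log-frequency axis
#'
#' Each chord tone contributes `n_harmonics` overtones; the i-th overtone of
#' a tone carries weight `i^-rolloff` and lands at the bin nearest its
#' pitch class on a circular log-frequency (cents) axis with
#' `bins_per_octave` bins. Octave-shifted pitch sets therefore produce
#' identical vectors.
#'
#' @param pitches Integer vector of MIDI pitches (non-empty).
#' @param n_harmonics Number of overtones per tone (default 12).
#' @param rolloff Harmonic roll-off exponent (default 0.75; weight i^-0.75).
#' @param bins_per_octave Bins on the circular axis (default 1200, i.e.
#'   cents).
#' @return Non-negative numeric vector of length `bins_per_octave`.
#' @export
harmonic_spectrum <- function(pitches, n_harmonics = 12, rolloff = 0.75,
                              bins_per_octave = 1200) {
  if (length(pitches) == 0L) stop("empty pitch set", call. = FALSE)
  v <- numeric(bins_per_octave)
  i <- seq_len(n_harmonics)
  w <- i^(-rolloff)
  for (p in pitches) {
    cents <- (p %% 12) * (bins_per_octave / 12) +
      bins_per_octave * log2(i)
    bin <- (round(cents) %% bins_per_octave) + 1L
    for (k in seq_along(bin)) v[bin[k]] <- v[bin[k]] + w[k]
  }
  v
}

#' Circular Gaussian smoothing of a spectral vector
#'
#' Convolves with a unit-mass circular Gaussian kernel; total mass is
#' preserved. Models perceptual blurring of spectral position.
#'
#' @param v Numeric vector on the circular axis.
#' @param sigma Kernel width in bins (default 6.83).
#' @return Smoothed vector, same length and total mass.
#' @export
gaussian_smooth <- function(v, sigma = 6.83) {
  L <- length(v)
  d <- pmin(0:(L - 1), L - (0:(L - 1)))
  kern <- exp(-d^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  out <- Re(stats::fft(stats::fft(v) * stats::fft(kern), inverse = TRUE)) / L
  pmax(out, 0)
}

#' Cosine distance between two spectral vectors
#'
#' 1 minus the cosine similarity: 0 for identically-directed spectra, 1 for
#' orthogonal (disjoint-support) spectra.
#'
#' @param a,b Non-negative, non-zero spectral vectors of equal length.
#' @return Distance in \[0, 1\].
#' @export
spectral_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero spectral vector", call. = FALSE)
  d <- 1 - sum(a * b) / (na * nb)
  min(max(d, 0), 1)
}

#' Smoothed spectral vector of a chord token
#'
#' Convenience wrapper: token -> pitches -> harmonic spectrum -> smoothing.
#'
#' @param token Chord token like `"0:maj"`.
#' @inheritParams harmonic_spectrum
#' @inheritParams gaussian_smooth
#' @param base_octave Voicing anchor passed to [chord_to_pitches()].
#' @return Smoothed spectral vector.
#' @export
chord_spectrum <- function(token, n_harmonics = 12, rolloff = 0.75,
                           bins_per_octave = 1200, sigma = 6.83,
                           base_octave = 4L) {
  gaussian_smooth(
    harmonic_spectrum(chord_to_pitches(token, base_octave = base_octave),
                      n_harmonics, rolloff, bins_per_octave),
    sigma
  )
}

#' Per-chord spectral distance along chord sequences
#'
#' Adds a `spectral_distance` column: the cosine distance between the
#' smoothed spectra of each chord and its predecessor within a song. The
#' first chord of each song is missing (no predecessor).
#'
#' @param corpus Tibble with `song_id`, `position`, `token`.
#' @inheritParams chord_spectrum
#' @return The input with a `spectral_distance` column appended.
#' @export
sd_sequence <- function(corpus, n_harmonics = 12, rolloff = 0.75,
                        bins_per_octave = 1200, sigma = 6.83,
                        base_octave = 4L) {
  toks <- unique(corpus$token)
  spectra <- purrr::map(toks, chord_spectrum, n_harmonics = n_harmonics,
                        rolloff = rolloff, bins_per_octave = bins_per_octave,
                        sigma = sigma, base_octave = base_octave)
  names(spectra) <- toks
  corpus |>
    dplyr::arrange(.data$song_id, .data$position) |>
    dplyr::group_by(.data$song_id) |>
    dplyr::mutate(spectral_distance = {
      tk <- .data$token
      out <- rep(NA_real_, length(tk))
      if (length(tk) > 1) {
        for (i in 2:length(tk)) {
          out[i] <- spectral_distance(spectra[[tk[i - 1]]], spectra[[tk[i]]])
        }
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Idealized periodicity-pitch image of a chord
#'
#' Approximates the periodicity analysis of the auditory periphery by
#' subharmonic summation over the chord's (octave-spread, unfolded)
#' harmonic spectrum: the evidence for a periodicity candidate at semitone
#' `c` is the roll-off-weighted spectral mass found at its integer
#' multiples, each multiple m discounted by 1/m.
#'
#' @param pitches Integer vector of MIDI pitches.
#' @param midi_range Candidate periodicity bins as MIDI note numbers
#'   (default 24:96).
#' @param n_harmonics Overtones per chord tone (default 12).
#' @param rolloff Overtone roll-off exponent (default 0.75).
#' @param subharmonic_depth Number of harmonic multiples summed per
#'   candidate (default 12).
#' @return Non-negative numeric vector over `midi_range` bins.
#' @export
periodicity_image <- function(pitches, midi_range = 24:96, n_harmonics = 12,
                              rolloff = 0.75, subharmonic_depth = 12) {
  if (length(pitches) == 0L) stop("empty pitch set", call. = FALSE)
  top <- max(midi_range) + round(12 * log2(subharmonic_depth)) +
    round(12 * log2(n_harmonics)) + 1L
  spec <- numeric(top + 1L)
  i <- seq_len(n_harmonics)
  w <- i^(-rolloff)
  for (p in pitches) {
    midi <- p + round(12 * log2(i))
    keep <- midi >= 0 & midi <= top
    for (k in which(keep)) spec[midi[k] + 1L] <- spec[midi[k] + 1L] + w[k]
  }
  m <- seq_len(subharmonic_depth)
  offs <- round(12 * log2(m))
  img <- vapply(midi_range, function(cand) {
    idx <- cand + offs + 1L
    ok <- idx >= 1L & idx <= length(spec)
    sum(spec[idx[ok]] / m[ok])
  }, numeric(1))
  stats::setNames(img, midi_range)
}

#' Leaky integration of auditory images
#'
#' Exponential-decay memory update over an interval: the previous image
#' decays by `exp(-duration/tau)` and the incoming image fills the
#' remainder. With `duration = 0` the previous image is returned; with
#' `duration >> tau` the output approaches the incoming image.
#'
#' @param previous,incoming Numeric image vectors with identical layout.
#' @param duration Elapsed time in seconds.
#' @param tau Decay time constant in seconds.
#' @return Updated image vector.
#' @export
leaky_integrate <- function(previous, incoming, duration, tau) {
  if (length(previous) != length(incoming)) {
    stop("image layouts do not match", call. = FALSE)
  }
  a <- exp(-duration / tau)
  a * previous + (1 - a) * incoming
}

#' Tonal dissimilarity between global and local pitch images
#'
#' Minus the z-transformed (Fisher arctanh) Pearson correlation between the
#' slowly-decaying global image (echoic-memory context) and the fast local
#' image (the incoming chord). High values mean the incoming chord
#' mismatches its context. The correlation is clamped to +/-(1 - 1e-6)
#' before the arctanh so identical images give a finite minimum.
#'
#' @param global_img,local_img Image vectors with positive variance.
#' @return Dissimilarity in z-units.
#' @export
tonal_dissimilarity <- function(global_img, local_img) {
  if (sd(global_img) == 0 || sd(local_img) == 0) {
    stop("zero-variance pitch image", call. = FALSE)
  }
  r <- cor(global_img, local_img)
  r <- min(max(r, -(1 - 1e-6)), 1 - 1e-6)
  -atanh(r)
}

#' Per-chord tonal dissimilarity along chord sequences
#'
#' Runs the periodicity-pitch memory model over each song: every chord's
#' instantaneous periodicity image updates a fast local image (time constant
#' `tau_local`) and a slow global image (`tau_global`) over the chord
#' duration, and each chord from the second onward is scored by the
#' dissimilarity between the global image carried from the previous chord's
#' end and the current local image. The first chord of each song is missing.
#'
#' @param corpus Tibble with `song_id`, `position`, `token`.
#' @param tau_global Global (context) decay constant in seconds (default 4).
#' @param tau_local Local (incoming-chord) decay constant in seconds
#'   (default 0.5).
#' @param chord_duration Seconds per chord (default 2.4).
#' @param global_includes_current If `TRUE`, the global image is updated
#'   with the current chord before the comparison (the non-strict variant).
#' @inheritParams periodicity_image
#' @param base_octave Voicing anchor passed to [chord_to_pitches()].
#' @return The input with a `tonal_dissimilarity` column appended.
#' @export
pp_sequence <- function(corpus, tau_global = 4, tau_local = 0.5,
                        chord_duration = 2.4,
                        global_includes_current = FALSE,
                        midi_range = 24:96, n_harmonics = 12, rolloff = 0.75,
                        subharmonic_depth = 12, base_octave = 4L) {
  stopifnot(tau_global > tau_local, tau_local > 0)
  toks <- unique(corpus$token)
  imgs <- purrr::map(toks, function(tk) {
    periodicity_image(chord_to_pitches(tk, base_octave = base_octave),
                      midi_range, n_harmonics, rolloff, subharmonic_depth)
  })
  names(imgs) <- toks
  corpus |>
    dplyr::arrange(.data$song_id, .data$position) |>
    dplyr::group_by(.data$song_id) |>
    dplyr::mutate(tonal_dissimilarity = {
      tk <- .data$token
      out <- rep(NA_real_, length(tk))
      glob <- numeric(length(midi_range))
      loc <- numeric(length(midi_range))
      for (i in seq_along(tk)) {
        inst <- imgs[[tk[i]]]
        loc <- leaky_integrate(loc, inst, chord_duration, tau_local)
        if (global_includes_current) {
          glob <- leaky_integrate(glob, inst, chord_duration, tau_global)
        }
        if (i > 1L) out[i] <- tonal_dissimilarity(glob, loc)
        if (!global_includes_current) {
          glob <- leaky_integrate(glob, inst, chord_duration, tau_global)
        }
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Sensory expectancy columns for a corpus
#'
#' Convenience wrapper adding both sensory predictors: `spectral_distance`
#' (adjacent-chord cosine distance) and `tonal_dissimilarity`
#' (periodicity-pitch memory model).
#'
#' @inheritParams pp_sequence
#' @param sigma Spectral smoothing width in bins.
#' @param bins_per_octave Bins of the circular spectral axis.
#' @return The input with both sensory columns appended.
#' @export
sensory_expectancy <- function(corpus, tau_global = 4, tau_local = 0.5,
                               chord_duration = 2.4, sigma = 6.83,
                               bins_per_octave = 1200, base_octave = 4L) {
  corpus |>
    sd_sequence(bins_per_octave = bins_per_octave, sigma = sigma,
                base_octave = base_octave) |>
    pp_sequence(tau_global = tau_global, tau_local = tau_local,
                chord_duration = chord_duration, base_octave = base_octave)
}
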