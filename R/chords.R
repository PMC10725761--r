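#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats cor median rnorm runif sd var
NULL

NOTE_PC <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)

#' Chord quality classes and their interval templates
#'
#' The symbolic vocabulary reduces chords to a root pitch class crossed with
#' nine quality classes. Each quality has a deterministic interval template
#' (semitones above the root) used when a chord is rendered to pitches.
#'
#' @return A named list of integer vectors, one per quality class.
#' @export
#' @examples
#' quality_templates()[["maj"]]
quality_templates <- function() {
  list(
    maj  = c(0L, 4L, 7L),
    min  = c(0L, 3L, 7L),
    dom7 = c(0L, 4L, 7L, 10L),
    maj7 = c(0L, 4L, 7L, 11L),
    min7 = c(0L, 3L, 7L, 10L),
    dim  = c(0L, 3L, 6L),
    aug  = c(0L, 4L, 8L),
    sus  = c(0L, 5L, 7L),
    other = c(0L, 4L, 7L)
  )
}

# Raw Harte quality shorthand -> reduced quality class. Anything not listed
# (and not matching the suffix heuristics below) falls into "other".
HARTE_QUALITY_MAP <- c(
  "maj" = "maj", "min" = "min", "minor" = "min",
  "7" = "dom7", "dom7" = "dom7", "9" = "dom7", "11" = "dom7", "13" = "dom7",
  "maj7" = "maj7", "maj9" = "maj7", "maj6" = "maj7",
  "min7" = "min7", "min9" = "min7", "min11" = "min7", "min6" = "min7",
  "minmaj7" = "min7",
  "dim" = "dim", "dim7" = "dim", "hdim7" = "dim",
  "aug" = "aug",
  "sus2" = "sus", "sus4" = "sus", "sus" = "sus",
  "5" = "other", "1" = "other", "other" = "other"
)

#' The reserved token for no-chord events
#' @return The string used to mark "N" (no chord) labels.
#' @export
no_chord_token <- function() ".N"

parse_one_label <- function(label) {
  if (label == "N" || label == "X") {
    return(list(root = NA_integer_, quality = NA_character_,
                token = no_chord_token()))
  }
  m <- regmatches(label, regexec("^([A-G])([#b]*)(?::(.*))?$", label))[[1]]
  if (length(m) == 0L) {
    stop("unparseable chord label: '", label, "'", call. = FALSE)
  }
  root <- NOTE_PC[[m[2]]]
  accs <- strsplit(m[3], "")[[1]]
  root <- (root + sum(accs == "#") - sum(accs == "b")) %% 12L
  raw_q <- if (is.na(m[4]) || m[4] == "") "maj" else m[4]
  # strip inversions and added-note lists: "maj7/5", "maj(9)" -> "maj7", "maj"
  raw_q <- sub("/.*$", "", raw_q)
  raw_q <- sub("\\(.*$", "", raw_q)
  quality <- unname(HARTE_QUALITY_MAP[raw_q])
  if (is.na(quality)) {
    quality <- if (grepl("^min", raw_q)) "min" else
      if (grepl("^maj", raw_q)) "maj" else "other"
  }
  list(root = as.integer(root), quality = quality,
       token = paste0(root, ":", quality))
}

#' Parse Harte-style chord labels
#'
#' Parses labels such as `"C:maj"`, `"A#:min7"` or `"Bb:7"` into a root pitch
#' class (0-11, C = 0), a reduced quality class (see [quality_templates()])
#' and a canonical token `"root:quality"` used as the symbolic-model
#' vocabulary item. The no-chord label `"N"` maps to a reserved token with
#' missing root and quality.
#'
#' @param label Character vector of Harte-style chord labels.
#' @return A tibble with columns `label`, `root`, `quality`, `token`.
#' @export
#' @examples
#' parse_chord_label(c("C:maj", "A#:min7", "G:7"))
parse_chord_label <- function(label) {
  stopifnot(is.character(label))
  parsed <- purrr::map(label, parse_one_label)
  tibble::tibble(
    label = label,
    root = purrr::map_int(parsed, "root"),
    quality = purrr::map_chr(parsed, "quality"),
    token = purrr::map_chr(parsed, "token")
  )
}

#' Format a chord token from root and quality
#'
#' Inverse of the token construction in [parse_chord_label()]:
#' `format_chord_token(0, "maj")` is `"0:maj"`.
#'
#' @param root Integer pitch class 0-11.
#' @param quality Quality class name.
#' @return Character vector of tokens.
#' @export
format_chord_token <- function(root, quality) {
  stopifnot(all(root %in% 0:11), all(quality %in% names(quality_templates())))
  paste0(as.integer(root), ":", quality)
}

token_root <- function(token) {
  as.integer(sub(":.*$", "", token))
}

token_quality <- function(token) {
  sub("^[0-9]+:", "", token)
}

#' Transpose chord sequences to C
#'
#' Shifts every chord root by minus the song's key of transcription (mod 12)
#' so that all songs share a common tonic, mirroring stimuli that are
#' transposed to C major before presentation. Transposing a song already in
#' C (key 0) is the identity.
#'
#' @param chords A tibble with columns `root` and `quality` (e.g. from
#'   [parse_chord_label()] joined to song structure), plus a key column.
#' @param key Column giving the original key as a pitch class 0-11
#'   (unquoted column name, default `key`).
#' @return The input tibble with `root` and `token` rewritten in C.
#' @export
transpose_to_c <- function(chords, key = key) {
  key_vals <- dplyr::pull(chords, {{ key }})
  stopifnot(all(key_vals %in% 0:11))
  chords |>
    dplyr::mutate(
      root = (.data$root - key_vals) %% 12L,
      token = format_chord_token(.data$root, .data$quality)
    )
}

#' Render a chord to MIDI pitches
#'
#' Deterministic root-position closed voicing: the root is placed in
#' `base_octave` (MIDI octave numbering where octave 4 starts at MIDI 60 for
#' C) and the quality's interval template is stacked above it.
#'
#' @param root Integer pitch class 0-11, or a token string like `"0:maj"`.
#' @param quality Quality class; ignored when `root` is a token.
#' @param base_octave MIDI octave anchor (default 4).
#' @return Integer vector of MIDI pitches, lowest first.
#' @export
#' @examples
#' chord_to_pitches(0, "maj") # C major triad: 60 64 67
chord_to_pitches <- function(root, quality = NULL, base_octave = 4L) {
  if (is.character(root) && grepl(":", root)) {
    quality <- token_quality(root)
    root <- token_root(root)
  }
  stopifnot(length(root) == 1L, root %in% 0:11)
  tmpl <- quality_templates()[[quality]]
  if (is.null(tmpl)) stop("unknown chord quality: '", quality, "'", call. = FALSE)
  as.integer(12L * (base_octave + 1L) + root + tmpl)
}

#' Read a chord corpus from CSV
#'
#' Expects columns `song_id`, `position`, `chord_label`, `key` with one row
#' per chord. Labels are parsed, no-chord events dropped, sequences
#' transposed to C, and per-song positions re-indexed 1..L. Positions must be
#' strictly increasing within each song.
#'
#' @param path CSV file path.
#' @param chord_duration Seconds per chord (default 2.4).
#' @return A corpus tibble: `song_id`, `position`, `root`, `quality`,
#'   `token`, `onset` (seconds).
#' @export
read_chord_corpus <- function(path, chord_duration = 2.4) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    song_id = readr::col_character(),
    position = readr::col_integer(),
    chord_label = readr::col_character(),
    key = readr::col_integer()
  ))
  bad <- raw |>
    dplyr::group_by(.data$song_id) |>
    dplyr::summarise(ok = all(diff(.data$position) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0L) {
    stop("non-increasing chord positions in song(s): ",
         paste(bad$song_id, collapse = ", "), call. = FALSE)
  }
  parsed <- parse_chord_label(raw$chord_label)
  raw |>
    dplyr::bind_cols(parsed[c("root", "quality", "token")]) |>
    dplyr::filter(.data$token != no_chord_token()) |>
    transpose_to_c(key = .data$key) |>
    dplyr::group_by(.data$song_id) |>
    dplyr::mutate(position = dplyr::row_number(),
                  onset = (.data$position - 1) * chord_duration) |>
    dplyr::ungroup() |>
    dplyr::select("song_id", "position", "root", "quality", "token", "onset")
}

#' Vocabulary of a corpus
#'
#' @param corpus A corpus tibble with a `token` column.
#' @return Sorted character vector of distinct tokens.
#' @export
corpus_vocabulary <- function(corpus) {
  sort(unique(corpus$token))
}
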