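#' Regression specification presets
#'
#' Expands a named preset into the response and term list of the
#' corresponding multilevel model. Every term enters both as a
#' population-level coefficient and as a song-level varying effect
#' (hierarchical centering), and reported effects are the population-level
#' means. Interaction terms are written `a:b` and expand to elementwise
#' products of their (standardized) parents.
#'
#' Surprise-rating presets (group-averaged ratings, two groups):
#' `exp1_null` (intercept, musicianship, valence, arousal),
#' `exp1_single` (null plus one model simulation and its musicianship
#' interaction; name the simulation column via `predictor`),
#' `exp1_additive` (null plus information content and tonal dissimilarity,
#' each with its musicianship interaction), and `exp1_supra` (additive plus
#' the ic x tonal-dissimilarity interaction and its musicianship
#' interaction).
#'
#' Pleasantness presets (single group, acoustic covariates): `exp2_null`,
#' `exp2_idyom` (ic, entropy, ic:entropy), `exp2_pp` (tonal dissimilarity),
#' `exp2_additive`, `exp2_supra`.
#'
#' @param preset Preset name.
#' @param predictor Simulation column for `exp1_single` (e.g. `"ic"`,
#'   `"tonal_dissimilarity"`, `"spectral_distance"`).
#' @param response Response column (default `"rating"`).
#' @return An object of class `regression_spec`.
#' @export
regression_spec <- function(preset = c("exp1_null", "exp1_single",
                                       "exp1_additive", "exp1_supra",
                                       "exp2_null", "exp2_idyom", "exp2_pp",
                                       "exp2_additive", "exp2_supra"),
                            predictor = NULL, response = "rating") {
  preset <- match.arg(preset)
  null1 <- c("intercept", "musicianship", "valence", "arousal")
  base2 <- c("intercept", "valence", "arousal", "dissonance",
             "spectral_centroid", "spectral_complexity")
  idyom2 <- c("ic", "entropy", "ic:entropy")
  terms <- switch(preset,
    exp1_null = null1,
    exp1_single = {
      if (is.null(predictor)) {
        stop("exp1_single needs a `predictor` column name", call. = FALSE)
      }
      c(null1, predictor, paste0(predictor, ":musicianship"))
    },
    exp1_additive = c(null1, "ic", "ic:musicianship", "tonal_dissimilarity",
                      "tonal_dissimilarity:musicianship"),
    exp1_supra = c(null1, "ic", "ic:musicianship", "tonal_dissimilarity",
                   "tonal_dissimilarity:musicianship",
                   "ic:tonal_dissimilarity",
                   "ic:tonal_dissimilarity:musicianship"),
    exp2_null = base2,
    exp2_idyom = c(base2, idyom2),
    exp2_pp = c(base2, "tonal_dissimilarity"),
    exp2_additive = c(base2, "tonal_dissimilarity", idyom2),
    exp2_supra = c(base2, "tonal_dissimilarity", idyom2,
                   "tonal_dissimilarity:ic", "tonal_dissimilarity:entropy",
                   "tonal_dissimilarity:ic:entropy")
  )
  structure(list(preset = preset, response = response, terms = terms),
            class = "regression_spec")
}

term_column <- function(data, term) {
  if (term == "intercept") return(rep(1, nrow(data)))
  parents <- strsplit(term, ":", fixed = TRUE)[[1]]
  Reduce(`*`, lapply(parents, function(v) data[[v]]))
}

#' Build a model-ready design from a merged rating/predictor table
#'
#' Validates the inputs (all named columns present, predictors on the
#' standardized scale, no missing values), constructs the population and
#' song-level design matrices (identical term sets, hierarchical
#' centering), and indexes the AR(1) residual series: one series per song,
#' or per song x group when a `group` column is present (the two
#' group-averaged series of a song are separate chains sharing one rho).
#'
#' @param data Tibble with the response, predictor columns, `song_id`,
#'   `position`, and optionally `group`.
#' @param spec A [regression_spec()].
#' @return An object of class `expectancy_design`.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "regression_spec"))
  vars <- unique(unlist(strsplit(setdiff(spec$terms, "intercept"), ":")))
  need <- c(spec$response, vars, "song_id", "position")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(data[, need])) {
    stop("missing values in model columns; drop first-chord rows first",
         call. = FALSE)
  }
  for (v in vars) {
    m <- mean(data[[v]]); s <- sd(data[[v]])
    if (abs(m) > 0.25 || s < 0.25 || s > 2) {
      stop("column '", v, "' does not look standardized ",
           "(mean ", signif(m, 3), ", sd ", signif(s, 3),
           "); standardize() predictors first", call. = FALSE)
    }
  }
  has_group <- "group" %in% names(data)
  keys <- c("song_id", if (has_group) "group", "position")
  data <- dplyr::arrange(data, dplyr::across(dplyr::all_of(keys)))
  series_id <- if (has_group) {
    paste(data$song_id, data$group, sep = "\r")
  } else {
    data$song_id
  }
  X <- vapply(spec$terms, function(tm) term_column(data, tm),
              numeric(nrow(data)))
  colnames(X) <- spec$terms
  structure(list(
    y = data[[spec$response]],
    X = X,
    song = match(data$song_id, unique(data$song_id)),
    song_ids = unique(data$song_id),
    series = match(series_id, unique(series_id)),
    first = !duplicated(series_id),
    data = data,
    spec = spec
  ), class = "expectancy_design")
}
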