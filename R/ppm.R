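#' n-gram count store for variable-order Markov modelling
#'
#' Creates an empty store of context -> continuation counts for all context
#' lengths 0..`max_order`. The store is an environment and is updated in
#' place by [ngram_train()].
#'
#' @param max_order Maximum context length (use `Inf` for an unbounded
#'   short-term store).
#' @return An object of class `ngram_store`.
#' @export
ngram_store <- function(max_order = 10) {
  stopifnot(max_order >= 1)
  store <- new.env(parent = emptyenv())
  store$tab <- new.env(hash = TRUE, parent = emptyenv())
  store$max_order <- max_order
  store$n_events <- 0L
  class(store) <- "ngram_store"
  store
}

ctx_key <- function(context) {
  # environments cannot hold a zero-length name, so the empty (order-0)
  # context gets a sentinel key
  if (length(context) == 0L) "\x01" else paste(context, collapse = "\r")
}

add_count <- function(store, context, sym) {
  key <- ctx_key(context)
  cnt <- store$tab[[key]]
  if (is.null(cnt)) {
    cnt <- stats::setNames(1, sym)
  } else if (is.na(match(sym, names(cnt)))) {
    cnt[sym] <- 1
  } else {
    cnt[sym] <- cnt[sym] + 1
  }
  assign(key, cnt, envir = store$tab)
}

#' Train an n-gram store on a token sequence
#'
#' Adds, for every event, one count for each context of length
#' 0..min(`max_order`, number of preceding events). Training is additive:
#' training twice on the same sequence doubles every count.
#'
#' @param store An [ngram_store()]; modified in place.
#' @param tokens Character vector, one song's ordered tokens.
#' @return The store, invisibly.
#' @export
ngram_train <- function(store, tokens) {
  stopifnot(inherits(store, "ngram_store"))
  L <- length(tokens)
  for (i in seq_len(L)) {
    kmax <- min(store$max_order, i - 1L)
    for (k in 0:kmax) {
      ctx <- if (k == 0L) character(0) else tokens[(i - k):(i - 1L)]
      add_count(store, ctx, tokens[i])
    }
  }
  store$n_events <- store$n_events + L
  invisible(store)
}

#' Continuation counts observed after a context
#'
#' @param store An [ngram_store()].
#' @param context Character vector of context tokens (may be empty).
#' @return Named numeric vector of counts, or `NULL` if the context was
#'   never observed.
#' @export
ngram_counts <- function(store, context = character(0)) {
  store$tab[[ctx_key(context)]]
}

#' Predictive distribution by interpolated PPM
#'
#' Blends n-gram models of all orders using prediction by partial matching
#' with interpolated smoothing. The recursion starts at the longest suffix
#' of `context` (capped at the store's `max_order`) that has been observed,
#' and escapes recursively down to a uniform distribution over `vocab`
#' (the order -1 floor), so every symbol receives strictly positive mass.
#'
#' Escape methods: `"C"` (default; escape mass proportional to the number of
#' distinct continuations), `"A"` (add-one escape) and `"D"` (half-count
#' discounting).
#'
#' @param store An [ngram_store()].
#' @param context Character vector of preceding tokens (empty for the first
#'   event).
#' @param vocab Character vector, the prediction alphabet.
#' @param escape Escape method, one of `"C"`, `"A"`, `"D"`.
#' @return Named numeric vector over `vocab`; strictly positive, sums to 1.
#' @export
ppm_predict <- function(store, context, vocab, escape = c("C", "A", "D")) {
  escape <- match.arg(escape)
  stopifnot(length(vocab) > 0L, !anyDuplicated(vocab))
  k <- length(context)
  if (is.finite(store$max_order)) k <- min(k, store$max_order)
  context <- if (k > 0L) context[(length(context) - k + 1L):length(context)]
             else character(0)
  # longest matching context: trim from the left until seen
  while (length(context) > 0L && is.null(store$tab[[ctx_key(context)]])) {
    context <- context[-1L]
  }
  p <- rep(1 / length(vocab), length(vocab))
  for (j in 0:length(context)) {
    ctx <- if (j == 0L) character(0)
           else context[(length(context) - j + 1L):length(context)]
    cnt <- store$tab[[ctx_key(ctx)]]
    if (is.null(cnt)) next
    n <- sum(cnt)
    if (n == 0) next
    tt <- sum(cnt > 0)
    ca <- cnt[match(vocab, names(cnt))]
    ca[is.na(ca)] <- 0
    p <- switch(escape,
      C = ca / (n + tt) + (tt / (n + tt)) * p,
      A = ca / (n + 1) + (1 / (n + 1)) * p,
      D = pmax(ca - 0.5, 0) / n + (tt / (2 * n)) * p
    )
  }
  stats::setNames(as.numeric(p), vocab)
}

#' Geometric-mean combination of two predictive distributions
#'
#' Element-wise square root of the product, renormalized to sum 1. The
#' supports must match exactly.
#'
#' @param p_ltm,p_stm Named probability vectors over the same support.
#' @return Named probability vector.
#' @export
combine_geometric <- function(p_ltm, p_stm) {
  if (length(p_ltm) != length(p_stm) ||
      !identical(names(p_ltm), names(p_stm))) {
    stop("distribution supports do not match", call. = FALSE)
  }
  g <- sqrt(p_ltm * p_stm)
  g / sum(g)
}

#' Information content of an observed symbol
#'
#' The model's surprise: negative log2 probability of the observed symbol
#' under the predictive distribution.
#'
#' @param dist Named probability vector.
#' @param observed A symbol in the support of `dist`.
#' @return Information content in bits (non-negative).
#' @export
information_content <- function(dist, observed) {
  idx <- match(observed, names(dist))
  if (is.na(idx)) stop("observed symbol '", observed,
                       "' not in distribution support", call. = FALSE)
  -log2(dist[[idx]])
}

#' Shannon entropy of a predictive distribution
#'
#' The model's uncertainty: expected information content over all possible
#' continuations, in bits. Bounded by log2 of the support size, attained
#' only by the uniform distribution.
#'
#' @param dist Probability vector.
#' @return Entropy in bits.
#' @export
entropy_bits <- function(dist) {
  p <- dist[dist > 0]
  -sum(p * log2(p))
}

# run one song through LTM + online STM, emitting per-event IC and entropy
song_expectancy <- function(tokens, ltm, vocab, escape, stm_max_order = Inf,
                            components = "both") {
  stm <- ngram_store(max_order = stm_max_order)
  L <- length(tokens)
  ic <- numeric(L)
  h <- numeric(L)
  for (i in seq_len(L)) {
    ctx <- if (i == 1L) character(0) else tokens[1:(i - 1L)]
    p <- switch(components,
      ltm = ppm_predict(ltm, ctx, vocab, escape),
      stm = ppm_predict(stm, ctx, vocab, escape),
      both = combine_geometric(ppm_predict(ltm, ctx, vocab, escape),
                               ppm_predict(stm, ctx, vocab, escape))
    )
    ic[i] <- information_content(p, tokens[i])
    h[i] <- entropy_bits(p)
    # ingest the event into the STM after predicting it
    kmax <- min(stm$max_order, i - 1L)
    for (k in 0:kmax) {
      c2 <- if (k == 0L) character(0) else tokens[(i - k):(i - 1L)]
      add_count(stm, c2, tokens[i])
    }
  }
  list(ic = ic, entropy = h)
}

#' Cross-validated symbolic chord expectancy
#'
#' Computes per-chord information content and entropy from a variable-order
#' Markov model with a long-term component (trained on the other
#' cross-validation folds) and a short-term component (trained online on the
#' current song's prefix), combined by geometric mean. Songs are partitioned
#' into folds by a seeded shuffle, so every chord is predicted by a
#' long-term model that never saw its song.
#'
#' @param corpus Corpus tibble with columns `song_id`, `position`, `token`.
#' @param max_order Maximum long-term context length (default 10).
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param escape PPM escape method (see [ppm_predict()]).
#' @param bigram If `TRUE`, cap the context at one chord in both the
#'   long-term and short-term components (the bigram control model).
#' @param components Which model components drive the predictive
#'   distribution: `"both"` (default; geometric-mean combination),
#'   `"ltm"` (corpus-trained model only) or `"stm"` (online within-song
#'   model only).
#' @return A tibble `song_id`, `position`, `token`, `ic_bits`,
#'   `entropy_bits`, with attributes `vocabulary`, `seed`, `fold_assignment`.
#' @export
chord_expectancy <- function(corpus, max_order = 10, folds = 10, seed = 1L,
                             escape = "C", bigram = FALSE,
                             components = c("both", "ltm", "stm")) {
  components <- match.arg(components)
  stopifnot(all(c("song_id", "position", "token") %in% names(corpus)),
            folds >= 2, max_order >= 1)
  if (bigram) max_order <- 1
  songs <- split(corpus$token[order(corpus$song_id, corpus$position)],
                 corpus$song_id[order(corpus$song_id, corpus$position)])
  ids <- names(songs)
  if (length(ids) < folds) {
    stop("need at least as many songs (", length(ids), ") as folds (",
         folds, ")", call. = FALSE)
  }
  vocab <- sort(unique(corpus$token))
  fold_of <- with_seed(seed, {
    stats::setNames(rep_len(seq_len(folds), length(ids)), sample(ids))
  })
  out <- vector("list", folds)
  for (f in seq_len(folds)) {
    held <- ids[fold_of[ids] == f]
    ltm <- ngram_store(max_order = max_order)
    for (id in setdiff(ids, held)) ngram_train(ltm, songs[[id]])
    res <- purrr::map(held, function(id) {
      e <- song_expectancy(songs[[id]], ltm, vocab, escape,
                           stm_max_order = if (bigram) 1 else Inf,
                           components = components)
      tibble::tibble(song_id = id,
                     position = seq_along(songs[[id]]),
                     token = songs[[id]],
                     ic_bits = e$ic, entropy_bits = e$entropy)
    })
    out[[f]] <- dplyr::bind_rows(res)
  }
  res <- dplyr::bind_rows(out) |> dplyr::arrange(.data$song_id, .data$position)
  attr(res, "vocabulary") <- vocab
  attr(res, "seed") <- seed
  attr(res, "fold_assignment") <- fold_of
  res
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
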