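#' Remove punctuation tokens and stop-words
#'
#' Filtering precedes featurization: tokens tagged `PUNCT` and tokens whose
#' surface form is on the stop-word list are removed, order preserved.
#' Symbol-tagged tokens (`SYM`) are deliberately retained - in transcribed
#' speech the symbol category carries silence marks and similar non-lexical
#' material, which is signal, not punctuation. Because filtering happens
#' first, transition features are computed between filtered neighbours,
#' which may not have been adjacent in the raw transcript.
#'
#' @param tokens An `annotated_tokens` data frame.
#' @param space A [feature_space()] (supplies the stop-word list).
#' @return The filtered token table.
#' @export
filter_tokens <- function(tokens, space = feature_space()) {
  keep <- tokens$pos_tag != "PUNCT" &
    !(tokens$surface_form %in% space$stopwords)
  tokens[keep, , drop = FALSE]
}

#' Tag-frequency features
#'
#' Relative frequency of each vocabulary tag among the supplied tags: the
#' count of the tag divided by the total number of tags. An empty input
#' yields the all-zero vector.
#'
#' @param tags Character vector of tags (already filtered).
#' @param vocab Ordered tag vocabulary.
#' @return Named numeric vector of length `length(vocab)` summing to 1 (or
#'   all zero when `tags` is empty).
#' @export
#' @examples
#' tag_frequencies(c("NOUN", "ADP", "NOUN", "VERB"), c("NOUN", "ADP", "VERB"))
tag_frequencies <- function(tags, vocab) {
  counts <- table(factor(tags, levels = vocab))
  out <- as.numeric(counts)
  names(out) <- vocab
  if (length(tags)) out / length(tags) else out
}

#' Adjacent-tag-transition features
#'
#' Collects all ordered pairs of adjacent tags, counts each unique
#' combination and divides by the total number of pairs N. Under the default
#' `within_utterance` boundary mode pairs never straddle utterance
#' boundaries; under `across_all` the whole assessment is treated as one
#' sequence. When N = 0 (fewer than two tags in every utterance) the
#' all-zero vector is returned.
#'
#' @param tags Character vector of tags (already filtered).
#' @param vocab Ordered tag vocabulary.
#' @param utterance_index Integer vector parallel to `tags`; ignored under
#'   `across_all` and optional (one utterance assumed) when `NULL`.
#' @param boundary_mode `"within_utterance"` (default) or `"across_all"`.
#' @return Named numeric vector of length `length(vocab)^2` in the row-major
#'   pair order of [feature_space()], summing to 1 when N >= 1.
#' @export
#' @examples
#' tag_transitions(c("NOUN", "ADP", "NOUN", "NOUN", "VERB"),
#'                 c("NOUN", "ADP", "VERB"))
tag_transitions <- function(tags, vocab, utterance_index = NULL,
                            boundary_mode = c("within_utterance",
                                              "across_all")) {
  boundary_mode <- match.arg(boundary_mode)
  k <- length(vocab)
  out <- numeric(k * k)
  names(out) <- transition_names(vocab)
  n <- length(tags)
  if (n < 2L) return(out)
  from <- tags[-n]
  to <- tags[-1L]
  if (boundary_mode == "within_utterance" && !is.null(utterance_index)) {
    same <- utterance_index[-n] == utterance_index[-1L]
    from <- from[same]
    to <- to[same]
  }
  if (!length(from)) return(out)
  counts <- table(factor(from, levels = vocab), factor(to, levels = vocab))
  # counts is |vocab| x |vocab| with rows = first tag; flatten row-major
  out[] <- as.vector(t(counts)) / length(from)
  out
}

#' Build the feature vector for one assessment
#'
#' Concatenates, in the fixed layout of the [feature_space()]: POS
#' frequencies, POS transitions, dependency frequencies, dependency
#' transitions. Tokens are first passed through [filter_tokens()].
#' Out-of-vocabulary tags are dropped with a message under the default
#' lenient mode (the token is removed before counting for the affected tag
#' type) and raise an error naming the tag under strict mode.
#'
#' @param assessment A list with at least `tokens`; typically an element of
#'   a `speech_corpus`'s `assessments`.
#' @param space A [feature_space()].
#' @param boundary_mode Passed to [tag_transitions()].
#' @param oov `"lenient"` (drop + message) or `"strict"` (error).
#' @return Named numeric vector of length `space$dimension`, each block a
#'   probability vector (or all-zero when no counted material exists).
#' @export
build_feature_vector <- function(assessment, space = feature_space(),
                                 boundary_mode = c("within_utterance",
                                                   "across_all"),
                                 oov = c("lenient", "strict")) {
  boundary_mode <- match.arg(boundary_mode)
  oov <- match.arg(oov)
  tokens <- filter_tokens(assessment$tokens, space)
  pos_block <- tag_blocks(tokens$pos_tag, tokens$utterance_index,
                          space$pos_vocab, boundary_mode, oov, "POS")
  dep_block <- tag_blocks(tokens$dep_tag, tokens$utterance_index,
                          space$dep_vocab, boundary_mode, oov, "dependency")
  out <- c(pos_block$freq, pos_block$trans, dep_block$freq, dep_block$trans)
  names(out) <- space$feature_names
  out
}

# frequency + transition block for one tag type, with OOV handling
tag_blocks <- function(tags, utt, vocab, boundary_mode, oov, what) {
  known <- tags %in% vocab
  if (!all(known)) {
    bad <- unique(tags[!known])
    if (oov == "strict") {
      stop(sprintf("out-of-vocabulary %s tag(s): %s", what,
                   paste(bad, collapse = ", ")))
    }
    message(sprintf("dropping %d token(s) with out-of-vocabulary %s tag(s): %s",
                    sum(!known), what, paste(bad, collapse = ", ")))
    tags <- tags[known]
    utt <- utt[known]
  }
  list(
    freq = tag_frequencies(tags, vocab),
    trans = tag_transitions(tags, vocab, utt, boundary_mode)
  )
}

#' Build the feature matrix for a corpus
#'
#' One row per assessment (never per subject - repeated visits stay separate
#' rows), in corpus order; columns are the feature space's `feature_names`.
#'
#' @param corpus A `speech_corpus` containing only AD/HC assessments.
#' @param space A [feature_space()].
#' @param ... Passed to [build_feature_vector()].
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix), `labels` (character), `subject_id`, `visit_id`, `space`.
#' @export
build_feature_matrix <- function(corpus, space = feature_space(), ...) {
  stopifnot(inherits(corpus, "speech_corpus"))
  labels <- vapply(corpus$assessments, `[[`, character(1), "label")
  if (any(labels == "EXCLUDED")) {
    stop("corpus contains EXCLUDED assessments; rebuild with drop_excluded = TRUE")
  }
  rows <- lapply(corpus$assessments, build_feature_vector, space = space, ...)
  x <- do.call(rbind, rows)
  subject_id <- vapply(corpus$assessments, `[[`, character(1), "subject_id")
  visit_id <- vapply(corpus$assessments, `[[`, character(1), "visit_id")
  rownames(x) <- paste(subject_id, visit_id, sep = ":")
  structure(
    list(x = x, labels = labels, subject_id = subject_id,
         visit_id = visit_id, space = space),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$x), " assessments x ", ncol(x$x),
      " features (", sum(x$labels == "AD"), " AD, ",
      sum(x$labels == "HC"), " HC)\n", sep = "")
  invisible(x)
}

#' Export a feature matrix as delimited text
#'
#' Writes a tab-delimited table with `subject_id`, `visit_id`, `label`
#' columns followed by one column per feature.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(subject_id = fm$subject_id, visit_id = fm$visit_id,
                   label = fm$labels, fm$x, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
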