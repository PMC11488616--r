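#' Universal part-of-speech tag set
#'
#' The 17 universal part-of-speech (UPOS) categories of the Universal
#' Dependencies annotation scheme, in alphabetical order.
#'
#' @return Character vector of 17 tags.
#' @export
#' @examples
#' upos_tags()
upos_tags <- function() {
  c("ADJ", "ADP", "ADV", "AUX", "CCONJ", "DET", "INTJ", "NOUN", "NUM",
    "PART", "PRON", "PROPN", "PUNCT", "SCONJ", "SYM", "VERB", "X")
}

#' Default dependency-relation tag set
#'
#' A 24-relation subset of the Universal Dependencies relation inventory used
#' as the default dependency vocabulary. The membership is configuration, not
#' a fixed standard: any parser-specific relation set can be supplied to
#' [feature_space()] instead. The default covers the core argument, modifier
#' and function-word relations produced by UD parsers for Japanese, including
#' `det`, `cc`, `obl`, `nmod`, `nummod` and `mark`.
#'
#' @return Character vector of 24 relation labels.
#' @export
ud_dep_tags <- function() {
  c("acl", "advcl", "advmod", "amod", "aux", "case", "cc", "ccomp",
    "compound", "conj", "cop", "csubj", "dep", "det", "fixed", "iobj",
    "mark", "nmod", "nsubj", "nummod", "obj", "obl", "punct", "root")
}

#' Define the feature-vector layout
#'
#' A feature space fixes the ordered part-of-speech and dependency
#' vocabularies and thereby the layout of every feature vector: POS
#' frequencies (one per POS tag), POS transitions (row-major over ordered
#' POS-tag pairs), dependency frequencies, dependency transitions. With the
#' default vocabularies (17 POS tags, 24 dependency relations) the dimension
#' is 17 + 17^2 + 24 + 24^2 = 906.
#'
#' Transition feature names join the two tags with an underscore, e.g.
#' `NOUN_ADP` is "noun followed by adposition" and `obl_nmod` is "oblique
#' nominal followed by nominal modifier". POS tags are upper-case and
#' dependency relations lower-case, so the two blocks never collide.
#'
#' @param pos_vocab Ordered character vector of part-of-speech tags.
#' @param dep_vocab Ordered character vector of dependency-relation tags.
#' @param stopwords Character vector of surface forms removed before
#'   featurization (default empty).
#' @return An object of class `feature_space` with elements `pos_vocab`,
#'   `dep_vocab`, `stopwords`, `feature_names` and `dimension`.
#' @export
#' @examples
#' sp <- feature_space()
#' sp$dimension               # 906
#' head(sp$feature_names, 3)
feature_space <- function(pos_vocab = upos_tags(), dep_vocab = ud_dep_tags(),
                          stopwords = character()) {
  stopifnot(is.character(pos_vocab), is.character(dep_vocab))
  if (anyDuplicated(pos_vocab)) stop("duplicate tags in pos_vocab")
  if (anyDuplicated(dep_vocab)) stop("duplicate tags in dep_vocab")
  if (!length(pos_vocab) || !length(dep_vocab)) {
    stop("vocabularies must be non-empty")
  }
  space <- list(
    pos_vocab = pos_vocab,
    dep_vocab = dep_vocab,
    stopwords = as.character(stopwords),
    feature_names = c(
      pos_vocab,
      transition_names(pos_vocab),
      dep_vocab,
      transition_names(dep_vocab)
    )
  )
  space$dimension <- length(space$feature_names)
  stopifnot(space$dimension ==
    length(pos_vocab) + length(pos_vocab)^2 +
    length(dep_vocab) + length(dep_vocab)^2)
  structure(space, class = "feature_space")
}

# Row-major pair names: first tag varies slowest.
transition_names <- function(vocab) {
  as.vector(t(outer(vocab, vocab, paste, sep = "_")))
}

#' @export
print.feature_space <- function(x, ...) {
  cat("<feature_space> ", length(x$pos_vocab), " POS tags, ",
      length(x$dep_vocab), " dependency tags, ",
      x$dimension, " features\n", sep = "")
  invisible(x)
}
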