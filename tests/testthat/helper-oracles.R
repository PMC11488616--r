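# Independent brute-force oracles and small fixture builders.

# Enumerate every adjacent tag pair explicitly (optionally within utterance
# groups), then tabulate by nested loops over the vocabulary. Deliberately
# slow and independent of tag_transitions().
oracle_transitions <- function(tags, vocab, utterance_index = NULL,
                               within = TRUE) {
  pairs_from <- character(0)
  pairs_to <- character(0)
  if (length(tags) >= 2) {
    groups <- if (within && !is.null(utterance_index)) {
      split(tags, utterance_index)
    } else {
      list(tags)
    }
    for (g in groups) {
      if (length(g) >= 2) {
        for (j in seq_len(length(g) - 1)) {
          pairs_from <- c(pairs_from, g[[j]])
          pairs_to <- c(pairs_to, g[[j + 1]])
        }
      }
    }
  }
  out <- numeric(length(vocab)^2)
  names(out) <- as.vector(t(outer(vocab, vocab, paste, sep = "_")))
  n <- length(pairs_from)
  if (n == 0) return(out)
  for (a in seq_along(vocab)) {
    for (b in seq_along(vocab)) {
      out[(a - 1) * length(vocab) + b] <-
        sum(pairs_from == vocab[[a]] & pairs_to == vocab[[b]]) / n
    }
  }
  out
}

# All-pairs AUC: mean over (AD, HC) score pairs of 1/0.5/0.
oracle_auc <- function(scores, labels) {
  s_pos <- scores[labels == "AD"]
  s_neg <- scores[labels == "HC"]
  if (!length(s_pos) || !length(s_neg)) return(NA_real_)
  total <- 0
  for (a in s_pos) {
    for (h in s_neg) {
      total <- total + if (a > h) 1 else if (a == h) 0.5 else 0
    }
  }
  total / (length(s_pos) * length(s_neg))
}

# Quick token table from parallel tag vectors.
toks <- function(pos, dep = rep("dep", length(pos)),
                 utt = rep(0L, length(pos)),
                 surface = paste0("w", seq_along(pos))) {
  annotated_tokens(surface, pos, dep, utt)
}

# Tiny feature space for layout tests.
toy_space <- function() {
  feature_space(pos_vocab = c("NOUN", "ADP", "VERB"),
                dep_vocab = c("nsubj", "case"))
}

# Random tag sequence split into utterances, for property tests.
random_tagged_sequence <- function(vocab, max_len = 50) {
  n <- sample(0:max_len, 1)
  if (n == 0) {
    return(list(tags = character(0), utt = integer(0)))
  }
  tags <- sample(vocab, n, replace = TRUE)
  n_utt <- sample(1:min(4, n), 1)
  bounds <- sort(sample(seq_len(n), n_utt - 1)) # split points
  utt <- integer(n)
  if (n_utt > 1) utt <- findInterval(seq_len(n) - 1, bounds)
  list(tags = tags, utt = as.integer(utt))
}
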