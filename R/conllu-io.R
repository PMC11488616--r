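#' Construct a token table
#'
#' Tokens are stored as a data frame with one row per token, carrying the
#' surface form, the universal part-of-speech tag, the dependency relation,
#' and the 0-based index of the utterance (sentence) the token belongs to.
#'
#' @param surface_form Character vector.
#' @param pos_tag Character vector of part-of-speech tags.
#' @param dep_tag Character vector of dependency-relation tags.
#' @param utterance_index Non-negative integer vector, non-decreasing.
#' @return A data frame of class `annotated_tokens`.
#' @export
annotated_tokens <- function(surface_form = character(),
                             pos_tag = character(),
                             dep_tag = character(),
                             utterance_index = integer()) {
  tok <- data.frame(
    surface_form = as.character(surface_form),
    pos_tag = as.character(pos_tag),
    dep_tag = as.character(dep_tag),
    utterance_index = as.integer(utterance_index),
    stringsAsFactors = FALSE
  )
  validate_tokens(tok)
  class(tok) <- c("annotated_tokens", "data.frame")
  tok
}

validate_tokens <- function(tok) {
  if (nrow(tok) == 0L) return(invisible(tok))
  if (any(!nzchar(tok$pos_tag)) || any(is.na(tok$pos_tag))) {
    stop("pos_tag must be a non-empty string for every token")
  }
  if (any(!nzchar(tok$dep_tag)) || any(is.na(tok$dep_tag))) {
    stop("dep_tag must be a non-empty string for every token")
  }
  if (any(tok$utterance_index < 0L)) {
    stop("utterance_index must be non-negative")
  }
  if (is.unsorted(tok$utterance_index)) {
    stop("utterance_index must be non-decreasing within an assessment")
  }
  invisible(tok)
}

#' Read one assessment from a CoNLL-U file
#'
#' Parses the standard 10-column tab-separated CoNLL-U format. Sentences are
#' separated by blank lines and define the utterance index (0-based, in file
#' order); comment lines (`#`) are ignored, as are multiword-range lines
#' (ids like `1-2`) and empty-node lines (ids like `3.1`), neither of which
#' shifts the utterance index. Column 4 (UPOS) supplies the part-of-speech
#' tag and column 8 (DEPREL) the dependency relation.
#'
#' @param path Path to a CoNLL-U file, or a character vector of lines via
#'   `text`.
#' @param text Optional character vector of lines (used instead of `path`).
#' @return An `annotated_tokens` data frame (zero rows for a file with no
#'   token lines).
#' @export
#' @examples
#' lines <- c("# speaker = S1",
#'            "1\tinu\tinu\tNOUN\t_\t_\t2\tnsubj\t_\t_",
#'            "2\thashiru\thashiru\tVERB\t_\t_\t0\troot\t_\t_")
#' read_conllu(text = lines)
read_conllu <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  n <- length(lines)
  surface <- character(n); pos <- character(n); dep <- character(n)
  utt <- integer(n)
  k <- 0L
  utt_now <- 0L
  sentence_open <- FALSE
  for (i in seq_len(n)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) {
      if (sentence_open) {
        utt_now <- utt_now + 1L
        sentence_open <- FALSE
      }
      next
    }
    if (startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10L) {
      stop(sprintf("malformed CoNLL-U line %d: expected 10 tab-separated columns, found %d",
                   i, length(fields)))
    }
    id <- fields[[1]]
    # multiword ranges ("1-2") and empty nodes ("3.1") carry no tags of their own
    if (grepl("-", id, fixed = TRUE) || grepl(".", id, fixed = TRUE)) next
    k <- k + 1L
    surface[[k]] <- fields[[2]]
    pos[[k]] <- fields[[4]]
    dep[[k]] <- fields[[8]]
    utt[[k]] <- utt_now
    sentence_open <- TRUE
  }
  annotated_tokens(surface[seq_len(k)], pos[seq_len(k)], dep[seq_len(k)],
                   utt[seq_len(k)])
}

#' Write one assessment as a CoNLL-U file
#'
#' Emits valid CoNLL-U that [read_conllu()] round-trips: the part-of-speech
#' tag, dependency relation and utterance grouping of every token are
#' preserved. Distinct utterance indices are renumbered consecutively from 0
#' on write (the reader always produces consecutive indices, so canonical
#' token tables round-trip exactly). Head indices are written as 0 and
#' unused columns as `_`; the writer imposes no tag vocabulary.
#'
#' @param tokens An `annotated_tokens` data frame (may be empty).
#' @param path Output file path; when `NULL` the lines are returned invisibly
#'   instead of written.
#' @return Invisibly, the character vector of lines written.
#' @export
write_conllu <- function(tokens, path = NULL) {
  validate_tokens(tokens)
  out <- character()
  if (nrow(tokens) > 0L) {
    utts <- split(tokens, factor(tokens$utterance_index,
                                 levels = unique(tokens$utterance_index)))
    blocks <- lapply(utts, function(u) {
      ids <- seq_len(nrow(u))
      c(paste(ids, u$surface_form, "_", u$pos_tag, "_", "_", "0",
              u$dep_tag, "_", "_", sep = "\t"), "")
    })
    out <- unlist(blocks, use.names = FALSE)
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read the subject/visit metadata table
#'
#' Reads a delimited text file (comma or tab, auto-detected from the header
#' line) whose header names the six required columns `subject_id`,
#' `visit_id`, `mmse`, `cdr`, `logical_memory_ii`, `education_years` in any
#' order; extra columns (e.g. `age`) are carried through untouched but
#' unused. The clinical scores are validated: MMSE in 0-30, CDR in
#' \{0, 0.5, 1, 2, 3\}, Logical Memory II and education non-negative.
#' `(subject_id, visit_id)` pairs must be unique.
#'
#' @param path Path to the metadata file.
#' @param text Optional character vector of lines (used instead of `path`).
#' @return A data frame with one row per (subject, visit) assessment.
#' @export
read_metadata <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  if (!length(lines)) stop("empty metadata stream")
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  required <- c("subject_id", "visit_id", "mmse", "cdr",
                "logical_memory_ii", "education_years")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("metadata schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  for (col in c("mmse", "cdr", "logical_memory_ii", "education_years")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad)) {
      stop(sprintf("metadata row(s) %s: non-numeric value in column '%s'",
                   paste(bad, collapse = ", "), col))
    }
    df[[col]] <- val
  }
  bad_mmse <- which(!is.na(df$mmse) & (df$mmse < 0 | df$mmse > 30))
  if (length(bad_mmse)) {
    stop("metadata row(s) ", paste(bad_mmse, collapse = ", "),
         ": MMSE outside 0-30")
  }
  bad_cdr <- which(!is.na(df$cdr) & !(df$cdr %in% c(0, 0.5, 1, 2, 3)))
  if (length(bad_cdr)) {
    stop("metadata row(s) ", paste(bad_cdr, collapse = ", "),
         ": CDR not in {0, 0.5, 1, 2, 3}")
  }
  for (col in c("logical_memory_ii", "education_years")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) {
      stop("metadata row(s) ", paste(bad, collapse = ", "),
           ": negative ", col)
    }
  }
  key <- paste(df$subject_id, df$visit_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("subject_id", "visit_id"), drop = FALSE]
    stop("duplicate (subject_id, visit_id) pair(s): ",
         paste(paste(dup$subject_id, dup$visit_id, sep = "/"), collapse = ", "))
  }
  df
}

#' Write a metadata table
#'
#' Tab-delimited counterpart of [read_metadata()].
#'
#' @param metadata Data frame with the six required metadata columns.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
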