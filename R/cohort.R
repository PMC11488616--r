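#' Education-adjusted Logical Memory II threshold
#'
#' The ADNI-2 labeling rules threshold the WMS-R Logical Memory II delayed
#' recall score by years of education. For the AD rule the score must be at
#' or below 8 / 4 / 2 for >=16 / 8-15 / <=7 years of education; for the HC
#' rule it must be at or above 9 / 5 / 3 for the same strata.
#'
#' @param education_years Non-negative integer vector.
#' @param group `"AD"` or `"HC"` - which rule's threshold to return.
#' @return Integer vector of thresholds.
#' @export
#' @examples
#' logical_memory_threshold(16, "AD")  # 8
#' logical_memory_threshold(10, "HC")  # 5
logical_memory_threshold <- function(education_years, group = c("AD", "HC")) {
  group <- match.arg(group)
  stopifnot(all(education_years >= 0, na.rm = TRUE))
  stratum <- ifelse(education_years >= 16, 3L,
                    ifelse(education_years >= 8, 2L, 1L))
  table <- if (group == "AD") c(2L, 4L, 8L) else c(3L, 5L, 9L)
  table[stratum]
}

#' Assign the AD / HC / EXCLUDED label for one visit
#'
#' Applies the ADNI-2 score rules per visit: AD requires MMSE <= 23,
#' CDR >= 0.5 and Logical Memory II at or below the education-adjusted AD
#' threshold; HC requires MMSE >= 24, CDR exactly 0 and Logical Memory II at
#' or above the HC threshold. Visits satisfying neither rule - and visits
#' with any missing score - are EXCLUDED. The two rule sets are mutually
#' exclusive (the MMSE ranges are disjoint), so the function is total and
#' single-valued. Labels are per visit, never per subject: the same subject
#' may carry different labels at different visits.
#'
#' @param mmse MMSE score, 0-30.
#' @param cdr Clinical Dementia Rating, one of 0, 0.5, 1, 2, 3.
#' @param logical_memory_ii WMS-R Logical Memory II delayed recall score.
#' @param education_years Years of education.
#' @return Character vector over `"AD"`, `"HC"`, `"EXCLUDED"` (vectorized).
#' @export
#' @examples
#' assign_label(18, 1, 3, 12)   # "AD"
#' assign_label(29, 0, 12, 16)  # "HC"
#' assign_label(25, 0.5, 3, 12) # "EXCLUDED"
assign_label <- function(mmse, cdr, logical_memory_ii, education_years) {
  n <- max(length(mmse), length(cdr), length(logical_memory_ii),
           length(education_years))
  mmse <- rep_len(mmse, n); cdr <- rep_len(cdr, n)
  lm2 <- rep_len(logical_memory_ii, n)
  edu <- rep_len(education_years, n)
  complete <- !(is.na(mmse) | is.na(cdr) | is.na(lm2) | is.na(edu))
  out <- rep("EXCLUDED", n)
  ad <- complete & mmse <= 23 & cdr >= 0.5 &
    lm2 <= logical_memory_threshold(pmax(edu, 0), "AD")
  hc <- complete & mmse >= 24 & cdr == 0 &
    lm2 >= logical_memory_threshold(pmax(edu, 0), "HC")
  out[ad] <- "AD"
  out[hc] <- "HC"
  out
}

#' Assemble assessments into a labeled corpus
#'
#' Takes raw assessment records - each a list with `subject_id`, `visit_id`,
#' `tokens` (an `annotated_tokens` data frame) and the four clinical scores -
#' assigns a per-visit label with [assign_label()], and optionally drops
#' EXCLUDED visits. Visits from the same subject are kept as separate
#' assessments; they are never averaged or merged.
#'
#' @param records List of raw assessment records.
#' @param drop_excluded Drop EXCLUDED assessments (default `TRUE`).
#' @return An object of class `speech_corpus`: a list with `assessments`
#'   (each record augmented with `label`), `subjects` (unique subject ids)
#'   and `n_excluded` (number of visits removed or flagged).
#' @export
build_corpus <- function(records, drop_excluded = TRUE) {
  stopifnot(is.list(records))
  key <- vapply(records, function(r) paste(r$subject_id, r$visit_id, sep = "\r"),
                character(1))
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, visit_id) among records")
  }
  labeled <- lapply(records, function(r) {
    r$label <- assign_label(r$mmse, r$cdr, r$logical_memory_ii,
                            r$education_years)
    r
  })
  labels <- vapply(labeled, `[[`, character(1), "label")
  n_excluded <- sum(labels == "EXCLUDED")
  if (n_excluded > 0L) {
    message(n_excluded, " assessment(s) did not satisfy the AD or HC criteria",
            if (drop_excluded) " and were excluded" else "")
  }
  if (drop_excluded) labeled <- labeled[labels != "EXCLUDED"]
  if (!length(labeled)) {
    stop("no eligible assessments: every visit was EXCLUDED; ",
         "check the clinical scores or relax drop_excluded")
  }
  structure(
    list(
      assessments = labeled,
      subjects = unique(vapply(labeled, `[[`, character(1), "subject_id")),
      n_excluded = n_excluded
    ),
    class = "speech_corpus"
  )
}

#' @export
print.speech_corpus <- function(x, ...) {
  labels <- vapply(x$assessments, `[[`, character(1), "label")
  cat("<speech_corpus> ", length(x$assessments), " assessments from ",
      length(x$subjects), " subjects (",
      paste(sprintf("%s: %d", names(table(labels)), table(labels)),
            collapse = ", "),
      "); ", x$n_excluded, " excluded\n", sep = "")
  invisible(x)
}

#' Read a corpus from CoNLL-U files plus a metadata table
#'
#' For every row of the metadata table, reads the file
#' `<subject_id>_<visit_id>.conllu` under `dir` and assembles the raw
#' records, then labels them with [build_corpus()].
#'
#' @param dir Directory containing one CoNLL-U file per assessment.
#' @param metadata_path Path to the metadata table ([read_metadata()]).
#' @param drop_excluded Passed to [build_corpus()].
#' @return A `speech_corpus`.
#' @export
read_corpus <- function(dir, metadata_path, drop_excluded = TRUE) {
  meta <- read_metadata(metadata_path)
  if (!nrow(meta)) stop("no assessments found: metadata table is empty")
  files <- file.path(dir, paste0(meta$subject_id, "_", meta$visit_id,
                                 ".conllu"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("no CoNLL-U file for assessment(s): ",
         paste(basename(files[missing]), collapse = ", "))
  }
  records <- lapply(seq_len(nrow(meta)), function(i) {
    list(
      subject_id = meta$subject_id[[i]],
      visit_id = meta$visit_id[[i]],
      tokens = read_conllu(files[[i]]),
      mmse = meta$mmse[[i]],
      cdr = meta$cdr[[i]],
      logical_memory_ii = meta$logical_memory_ii[[i]],
      education_years = meta$education_years[[i]]
    )
  })
  build_corpus(records, drop_excluded = drop_excluded)
}
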