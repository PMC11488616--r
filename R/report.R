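#' Group-wise feature-distribution summaries
#'
#' Box-plot-style five-number summaries of selected features, computed
#' separately per label group. Quartiles use the midpoint-interpolation
#' convention: the quantile at probability p of n sorted values is the
#' average of the values at positions floor(h) and ceiling(h) for
#' h = (n - 1) p + 1. With `drop_zeros`, zero feature values are excluded
#' from the quantile computation (they would otherwise collapse the boxes
#' of sparse features) but are still counted in `n_zero`; a feature/group
#' with no nonzero values then gets `n = 0` and `NA` quantiles.
#'
#' @param fm A `feature_matrix`.
#' @param features Character vector of feature names to summarize.
#' @param drop_zeros Exclude zero values from the quantiles (default
#'   `FALSE`).
#' @return Data frame with columns `feature`, `group`, `min`, `q1`,
#'   `median`, `q3`, `max`, `n`, `n_zero`.
#' @export
summarize_distributions <- function(fm, features, drop_zeros = FALSE) {
  unknown <- setdiff(features, colnames(fm$x))
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  groups <- sort(unique(fm$labels))
  rows <- list()
  for (f in features) {
    for (g in groups) {
      v <- fm$x[fm$labels == g, f]
      n_zero <- sum(v == 0)
      if (drop_zeros) v <- v[v != 0]
      q <- midpoint_quantiles(v)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group = g,
        min = q[[1]], q1 = q[[2]], median = q[[3]], q3 = q[[4]], max = q[[5]],
        n = length(v), n_zero = n_zero, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# five-number summary with midpoint interpolation at p = 0, .25, .5, .75, 1
midpoint_quantiles <- function(v) {
  if (!length(v)) return(rep(NA_real_, 5))
  v <- sort(v)
  n <- length(v)
  vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    h <- (n - 1) * p + 1
    (v[floor(h)] + v[ceiling(h)]) / 2
  }, numeric(1))
}
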