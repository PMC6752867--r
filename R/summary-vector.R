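#' Construct a summary-statistic vector
#'
#' A named numeric vector of fixed dimension with an attached per-statistic
#' admissible range. The range travels with the statistics so that local
#' interpolators can clamp their predictions to values a summarizer could
#' actually produce (e.g. a proportion of zeros stays in `[0, 1]`).
#'
#' @param values numeric statistics.
#' @param names statistic labels.
#' @param valid_range `2 x R` matrix (rows: min, max) of admissible values.
#' @return a `summary_vector`: named numeric with a `valid_range` attribute.
#' @export
summary_vector <- function(values, names, valid_range = NULL) {
  stopifnot(length(values) == length(names))
  if (is.null(valid_range))
    valid_range <- rbind(rep(-Inf, length(values)), rep(Inf, length(values)))
  stopifnot(nrow(valid_range) == 2, ncol(valid_range) == length(values))
  colnames(valid_range) <- names
  structure(stats::setNames(as.numeric(values), names),
            valid_range = valid_range, class = "summary_vector")
}

stat_range <- function(s) attr(s, "valid_range")

clamp_stats <- function(m, valid_range) {
  m <- as.matrix(m)
  for (j in seq_len(ncol(m)))
    m[, j] <- pmin(pmax(m[, j], valid_range[1, j]), valid_range[2, j])
  m
}
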