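#' Read and write observed data files
#'
#' Count series are plain text, one nonnegative integer per line (a single
#' unnamed column of a CSV also parses). Community snapshots are CSV with
#' columns `species_index`, `trait`, `abundance` and, for a series of
#' snapshots, `snapshot`.
#'
#' @param path file path.
#' @return `read_count_series`: integer vector; `read_community_csv`: a
#'   `community_series` (see [simulate_trait()]).
#' @export
read_count_series <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  x <- utils::read.table(path, header = FALSE, sep = "",
                         comment.char = "#")[[1]]
  if (any(x != round(x)) || any(x < 0))
    stop("count series must contain nonnegative integers")
  as.integer(x)
}

#' @param series integer counts.
#' @rdname read_count_series
#' @export
write_count_series <- function(series, path) {
  writeLines(format(as.integer(series), scientific = FALSE), path)
  invisible(path)
}

#' @rdname read_count_series
#' @export
read_community_csv <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  d <- utils::read.csv(path)
  need <- c("species_index", "trait", "abundance")
  if (!all(need %in% names(d)))
    stop("community CSV needs columns: ", paste(need, collapse = ", "))
  if (!("snapshot" %in% names(d))) d$snapshot <- 1L
  species <- sort(unique(d$species_index))
  snaps <- sort(unique(d$snapshot))
  trait <- d$trait[match(species, d$species_index)]
  ab <- matrix(0L, length(snaps), length(species))
  for (k in seq_along(snaps)) {
    dk <- d[d$snapshot == snaps[k], ]
    ab[k, match(dk$species_index, species)] <- as.integer(dk$abundance)
  }
  structure(list(abundance = ab, trait = trait), class = "community_series")
}

#' @param series_c a `community_series`.
#' @rdname read_count_series
#' @export
write_community_csv <- function(series_c, path) {
  ab <- series_c$abundance
  if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1)
  rows <- do.call(rbind, lapply(seq_len(nrow(ab)), function(k) {
    data.frame(snapshot = k, species_index = seq_len(ncol(ab)),
               trait = series_c$trait, abundance = ab[k, ])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
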