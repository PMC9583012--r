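## Nearest-neighbour species identification tests (best match /
## best close match) over a K2P distance matrix.

match_report <- function(outcomes, threshold) {
  included <- outcomes[outcomes$included, , drop = FALSE]
  n <- nrow(included)
  rate <- function(v) if (n == 0L) NA_real_ else 100 * sum(included$verdict == v) / n
  structure(list(
    outcomes = outcomes,
    n_queries = n,
    rates = c(correct = rate("correct"), incorrect = rate("incorrect"),
              ambiguous = rate("ambiguous"), no_match = rate("no_match")),
    threshold = threshold), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("Match report: %d queries%s\n", x$n_queries,
              if (is.finite(x$threshold))
                sprintf(" (threshold %.5f)", x$threshold) else ""))
  print(round(x$rates, 2))
  invisible(x)
}

## Shared engine: best match with an optional distance threshold.
match_engine <- function(dm, species_of, threshold) {
  acc <- dm$accessions
  missing_sp <- setdiff(acc, names(species_of))
  if (length(missing_sp) > 0L)
    stopf("unlabeled accessions: %s", paste(missing_sp, collapse = ", "))
  sp <- species_of[acc]
  singleton <- sp %in% names(which(table(sp) == 1L))
  rows <- lapply(seq_along(acc), function(i) {
    d <- dm$d[i, ]; d[i] <- NA
    defined <- !is.na(d)
    if (!any(defined)) {
      return(data.frame(accession = acc[i], species = sp[i],
                        nearest = NA_character_, distance = NA_real_,
                        verdict = "undefined", included = FALSE))
    }
    dmin <- min(d[defined])
    nn <- acc[defined & d == dmin]
    nn_sp <- unique(sp[nn])
    verdict <- if (dmin > threshold) {
      "no_match"
    } else if (length(nn_sp) > 1L) {
      "ambiguous"
    } else if (nn_sp == sp[i]) "correct" else "incorrect"
    data.frame(accession = acc[i], species = sp[i],
               nearest = paste(nn, collapse = ","), distance = dmin,
               verdict = verdict, included = !singleton[i])
  })
  match_report(do.call(rbind, rows), threshold)
}

#' Best-match species identification
#'
#' Each accession queries the distance matrix for its nearest non-self
#' neighbour(s). The identification is correct when all equally nearest
#' neighbours are conspecific, incorrect when all are heterospecific,
#' and ambiguous when the tied nearest set spans more than one species.
#' Queries whose species has a single accession are reported but
#' excluded from the rate denominator (no conspecific match exists), as
#' are queries with no defined distance.
#'
#' @param dm a `k2p_dist` from [distance_matrix()].
#' @param species_of named character vector accession -> species;
#'   defaults to the labels carried by `dm`.
#' @return object of class `match_report`: list with `outcomes`
#'   (per-query data.frame), `n_queries`, `rates` (percentages summing
#'   to 100 over included queries) and `threshold` (`Inf` here).
#' @export
best_match <- function(dm, species_of = dm$species) {
  match_engine(dm, species_of, Inf)
}

#' Intraspecific distance threshold for best close match
#'
#' The given percentile of all intraspecific pairwise distances, with
#' linear interpolation between order statistics (the TAXONDNA
#' convention uses the 95th percentile).
#'
#' @param ds a [distance_summary()].
#' @param percentile percentile in `[0, 100]`.
#' @return the threshold distance, or `NA` when no intraspecific pairs
#'   exist.
#' @export
intraspecific_threshold <- function(ds, percentile = 95) {
  if (length(ds$intra) == 0L) return(NA_real_)
  unname(stats::quantile(ds$intra, percentile / 100, type = 7))
}

#' Best-close-match species identification
#'
#' As [best_match()], but a query whose nearest distance exceeds the
#' threshold is not recognized (`no_match`).
#'
#' @param dm a `k2p_dist`.
#' @param species_of named character vector accession -> species.
#' @param threshold distance threshold, typically from
#'   [intraspecific_threshold()].
#' @return a `match_report`; with `threshold = Inf` it reproduces
#'   [best_match()] exactly.
#' @export
best_close_match <- function(dm, species_of = dm$species, threshold) {
  if (is.na(threshold)) stopf("threshold is undefined")
  match_engine(dm, species_of, threshold)
}

#' Combined identification-rate table across markers
#'
#' Aggregates best-match / best-close-match reports for single barcodes
#' and barcode combinations into one table of correct / incorrect /
#' ambiguous / no-match percentages.
#'
#' @param reports named list of `match_report` objects (names are the
#'   marker or combination labels).
#' @return data.frame with one row per report: `marker`, `n_queries`,
#'   `correct`, `incorrect`, `ambiguous`, `no_match`, `threshold`.
#' @export
bba_summary <- function(reports) {
  if (length(reports) == 0L) stopf("no reports to summarize")
  if (is.null(names(reports)))
    names(reports) <- paste0("marker_", seq_along(reports))
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(marker = nm, n_queries = r$n_queries,
               correct = r$rates[["correct"]],
               incorrect = r$rates[["incorrect"]],
               ambiguous = r$rates[["ambiguous"]],
               no_match = r$rates[["no_match"]],
               threshold = r$threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-query match outcomes as TSV
#' @param report a `match_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(report, path) {
  utils::write.table(report$outcomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
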