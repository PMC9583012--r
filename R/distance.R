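#' Kimura two-parameter distance between two aligned sequences
#'
#' Restricts the pair to sites where both characters are unambiguous
#' bases (pairwise deletion of gaps and `N`), counts the transition
#' proportion P and transversion proportion Q, and returns
#' `d = -log(1 - 2P - Q)/2 - log(1 - 2Q)/4`. The distance is `NA`
#' (undefined, saturated) when a log argument is non-positive or no
#' comparable sites remain; it is never silently truncated.
#'
#' @param seq_a,seq_b character vectors of single characters (rows of a
#'   [locus_alignment()] matrix) or single aligned strings, equal length.
#' @return list with `distance` (substitutions/site, or `NA`) and
#'   `comparable_sites` (integer).
#' @examples
#' k2p_distance("ACGTACGTAC", "ACGTACGTAC")  # 0 over 10 sites
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (length(seq_a) == 1L && nchar(seq_a[1L]) > 1L) seq_a <- strsplit(seq_a, "")[[1L]]
  if (length(seq_b) == 1L && nchar(seq_b[1L]) > 1L) seq_b <- strsplit(seq_b, "")[[1L]]
  if (length(seq_a) != length(seq_b)) stopf("sequences differ in aligned length")
  ok <- seq_a %in% BASES & seq_b %in% BASES
  n <- sum(ok)
  if (n == 0L) return(list(distance = NA_real_, comparable_sites = 0L))
  a <- seq_a[ok]; b <- seq_b[ok]
  diff <- a != b
  ts <- sum(diff & (a %in% PURINES) == (b %in% PURINES))
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  d <- if (arg1 <= 0 || arg2 <= 0) NA_real_ else -0.5 * log(arg1) - 0.25 * log(arg2)
  list(distance = d, comparable_sites = as.integer(n))
}

#' Pairwise K2P distance matrix for an alignment
#'
#' All-vs-all [k2p_distance()] under pairwise deletion. Undefined
#' (saturated) pairs are kept as `NA` and propagated as flags rather
#' than substituted.
#'
#' @param aln a [locus_alignment()] with at least 2 accessions.
#' @return object of class `k2p_dist`: list with `accessions`, `species`
#'   (named), `d` (symmetric numeric matrix, zero diagonal, `NA` =
#'   undefined) and `comparable_sites` (symmetric integer matrix).
#' @export
distance_matrix <- function(aln) {
  n <- length(aln$accessions)
  if (n < 2L) stopf("need at least 2 accessions")
  d <- matrix(0, n, n, dimnames = list(aln$accessions, aln$accessions))
  cs <- matrix(0L, n, n, dimnames = dimnames(d))
  diag(cs) <- as.integer(rowSums(matrix(aln$seqs %in% BASES, n)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k2p_distance(aln$seqs[i, ], aln$seqs[j, ])
      d[i, j] <- d[j, i] <- k$distance
      cs[i, j] <- cs[j, i] <- k$comparable_sites
    }
  }
  structure(list(accessions = aln$accessions, species = aln$species,
                 d = d, comparable_sites = cs),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  nu <- sum(is.na(x$d[upper.tri(x$d)]))
  cat(sprintf("K2P distance matrix: %d accessions, %d undefined pairs\n",
              length(x$accessions), nu))
  invisible(x)
}

#' Intraspecific / interspecific distance summary (barcoding gap)
#'
#' Partitions all defined pairwise distances into conspecific (intra)
#' and heterospecific (inter) sets and reports their arithmetic means
#' and the intra/inter ratio, computed from the unrounded means.
#' Species represented by a single accession contribute no intraspecific
#' pairs (they are not treated as zero). Undefined pairs are excluded
#' and counted in `n_undefined`.
#'
#' @param dm a `k2p_dist` from [distance_matrix()].
#' @param species_of optional named character vector accession ->
#'   species; defaults to the labels carried by `dm`.
#' @return object of class `distance_summary`: list with `intra`,
#'   `inter` (numeric vectors), `mean_intra`, `mean_inter`, `ratio`
#'   (all unrounded; `NA` when undefined) and `n_undefined`.
#' @export
distance_summary <- function(dm, species_of = dm$species) {
  acc <- dm$accessions
  missing_sp <- setdiff(acc, names(species_of))
  if (length(missing_sp) > 0L)
    stopf("unlabeled accessions: %s", paste(missing_sp, collapse = ", "))
  sp <- species_of[acc]
  n <- length(acc)
  same <- outer(sp, sp, "==")
  up <- upper.tri(dm$d)
  vals <- dm$d[up]
  intra <- vals[same[up] & !is.na(vals)]
  inter <- vals[!same[up] & !is.na(vals)]
  mean_intra <- if (length(intra)) mean(intra) else NA_real_
  mean_inter <- if (length(inter)) mean(inter) else NA_real_
  ratio <- if (is.na(mean_intra) || is.na(mean_inter) || mean_inter == 0)
    NA_real_ else mean_intra / mean_inter
  structure(list(intra = intra, inter = inter,
                 mean_intra = mean_intra, mean_inter = mean_inter,
                 ratio = ratio, n_undefined = sum(is.na(vals))),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  fmt <- function(v, d) if (is.na(v)) "undefined" else formatC(v, digits = d, format = "f")
  cat(sprintf(
    "Barcoding-gap summary: %d intraspecific / %d interspecific pairs\n",
    length(x$intra), length(x$inter)))
  cat(sprintf("  mean intra = %s  mean inter = %s  ratio = %s\n",
              fmt(x$mean_intra, 4), fmt(x$mean_inter, 4),
              if (is.na(x$ratio)) "undefined" else signif(x$ratio, 3)))
  if (x$n_undefined > 0)
    cat(sprintf("  %d undefined (saturated) pairs excluded\n", x$n_undefined))
  invisible(x)
}

#' Binned intra/inter distance distributions
#'
#' Histogram counts of the intraspecific and interspecific distance
#' distributions over a common set of bins of width `bin_width`
#' covering `[0, max distance]`, plus an overlap flag (any
#' intraspecific value >= any interspecific value), the signature of a
#' broken barcoding gap.
#'
#' @param ds a [distance_summary()].
#' @param bin_width positive bin width (substitutions/site).
#' @return list with `breaks`, `intra_counts`, `inter_counts`,
#'   `overlap`.
#' @export
barcoding_gap_histogram <- function(ds, bin_width = 0.005) {
  if (bin_width <= 0) stopf("bin_width must be positive")
  vals <- c(ds$intra, ds$inter)
  if (length(vals) == 0L)
    return(list(breaks = numeric(0), intra_counts = integer(0),
                inter_counts = integer(0), overlap = FALSE))
  nb <- max(1L, ceiling(max(vals) / bin_width + 1e-12))
  breaks <- seq(0, nb * bin_width, by = bin_width)
  count <- function(v) {
    if (length(v) == 0L) return(integer(nb))
    idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE,
                                  left.open = FALSE), 1L), nb)
    tabulate(idx, nbins = nb)
  }
  overlap <- length(ds$intra) > 0 && length(ds$inter) > 0 &&
    max(ds$intra) >= min(ds$inter)
  list(breaks = breaks, intra_counts = count(ds$intra),
       inter_counts = count(ds$inter), overlap = overlap)
}

#' Write a distance matrix as TSV or PHYLIP
#' @param dm a `k2p_dist`.
#' @param path output path.
#' @param format `"tsv"` (square tab-delimited with header) or
#'   `"phylip"` (square PHYLIP distance format).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(accession = dm$accessions, dm$d, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$accessions)), con)
    for (i in seq_along(dm$accessions))
      writeLines(paste(c(formatC(dm$accessions[i], width = -10),
                         formatC(dm$d[i, ], digits = 6, format = "f")),
                       collapse = " "), con)
  }
  invisible(path)
}
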