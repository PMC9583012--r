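#' Count of segregating (variable) sites
#'
#' A site is segregating when at least two distinct unambiguous bases
#' (`A,C,G,T`) are observed among the sequences at that column; gaps and
#' `N` are excluded from the comparison, and pure indel columns never
#' count (substitutions only).
#'
#' @param aln a [locus_alignment()] with >= 2 sequences.
#' @return integer count of variable characters.
#' @export
segregating_sites <- function(aln) {
  if (length(aln$accessions) < 2L) stopf("need at least 2 sequences")
  sum(apply(aln$seqs, 2L, function(col) {
    length(unique(col[col %in% BASES])) >= 2L
  }))
}

## Per-pair substitution differences and comparable sites under
## pairwise deletion; shared backbone for pi and Tajima's D.
pairwise_differences <- function(aln) {
  n <- length(aln$accessions)
  pairs <- utils::combn(n, 2L)
  diffs <- integer(ncol(pairs)); comp <- integer(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- aln$seqs[pairs[1L, k], ]; b <- aln$seqs[pairs[2L, k], ]
    ok <- a %in% BASES & b %in% BASES
    comp[k] <- sum(ok)
    diffs[k] <- sum(a[ok] != b[ok])
  }
  list(diffs = diffs, comparable = comp)
}

#' Nucleotide diversity (pi)
#'
#' Mean per-site p-distance over all sequence pairs under pairwise
#' deletion: for each pair, substitution differences divided by the
#' pair's comparable sites, averaged over pairs (pairs with no
#' comparable sites are excluded).
#'
#' @param aln a [locus_alignment()] with >= 2 sequences.
#' @return nucleotide diversity per site.
#' @export
nucleotide_diversity <- function(aln) {
  if (length(aln$accessions) < 2L) stopf("need at least 2 sequences")
  pd <- pairwise_differences(aln)
  ok <- pd$comparable > 0L
  if (!any(ok)) return(NA_real_)
  mean(pd$diffs[ok] / pd$comparable[ok])
}

#' Tajima's D and per-locus diversity summary
#'
#' The standard Tajima (1989) statistic contrasting mean pairwise
#' differences with the segregating-site estimate of theta:
#' `D = (Pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the usual constants
#' `a1, a2, b1, b2, c1, c2, e1, e2` from the sample size `n`. `Pi` is
#' the mean pairwise difference *count*; with missing data each pair's
#' count is rescaled by `L_eff / comparable sites`, where `L_eff` is the
#' number of sites with at least two unambiguous bases, so it reduces to
#' the raw count on complete data. Negative D indicates an excess of
#' rare alleles relative to neutrality.
#'
#' @param aln a [locus_alignment()].
#' @return object of class `diversity_result`: list with `n`, `L`
#'   (alignment length), `L_eff`, `S`, `pi` (per site), `Pi` (mean
#'   pairwise difference count), `theta_w` (S/a1), `tajima_D` (`NA` when
#'   undefined) and `reason` (why D is undefined, or `NA`).
#' @export
tajimas_d <- function(aln) {
  n <- length(aln$accessions)
  if (n < 2L) stopf("need at least 2 sequences")
  S <- segregating_sites(aln)
  L_eff <- sum(apply(aln$seqs, 2L, function(col) sum(col %in% BASES) >= 2L))
  pd <- pairwise_differences(aln)
  ok <- pd$comparable > 0L
  Pi <- if (any(ok)) mean(pd$diffs[ok] / pd$comparable[ok]) * L_eff else NA_real_
  pi <- nucleotide_diversity(aln)
  res <- list(n = n, L = ncol(aln$seqs), L_eff = L_eff, S = S, pi = pi,
              Pi = Pi, theta_w = NA_real_, tajima_D = NA_real_,
              reason = NA_character_)
  if (S == 0L) {
    res$reason <- "no segregating sites"
  } else if (n < 4L) {
    res$reason <- "fewer than 4 sequences"
  } else {
    i <- seq_len(n - 1L)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    res$theta_w <- S / a1
    res$tajima_D <- (Pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  class(res) <- "diversity_result"
  res
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("Diversity: n=%d L=%d S=%d pi=%.5f Pi=%.3f Tajima's D=%s\n",
              x$n, x$L, x$S, x$pi, x$Pi,
              if (is.na(x$tajima_D)) paste0("undefined (", x$reason, ")")
              else sprintf("%.3f", x$tajima_D)))
  invisible(x)
}

#' Per-locus diversity report
#'
#' One row per locus with the columns of a barcode genetic-diversity
#' table: aligned length, variable characters, nucleotide diversity and
#' Tajima's D.
#'
#' @param alignments named list of [locus_alignment()] objects.
#' @return data.frame with columns `locus`, `aligned_length`,
#'   `variable_characters`, `pi`, `tajima_D`.
#' @export
diversity_report <- function(alignments) {
  rows <- lapply(alignments, function(aln) {
    d <- tajimas_d(aln)
    data.frame(locus = aln$locus_name, aligned_length = d$L,
               variable_characters = d$S, pi = d$pi, tajima_D = d$tajima_D)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
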